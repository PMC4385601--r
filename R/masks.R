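#' Labeled mask container
#'
#' A `labeled_mask` wraps a 2-D integer label grid: 0 is background, each
#' positive integer `k` is one region. The coordinate convention throughout
#' the package is 0-based `(x, y) = (col, row)` with `y` increasing downward;
#' internally pixels are addressed with R's 1-based `[row, col]` indexing.
#'
#' @param labels integer matrix; 0 = background, k > 0 = region k.
#' @return An object of class `labeled_mask` with elements `labels`,
#'   `height`, `width`.
#' @export
labeled_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  if (anyNA(labels)) stop("`labels` contains NA", call. = FALSE)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  if (any(labels != round(labels))) {
    stop("non-integer pixel data in label mask", call. = FALSE)
  }
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  structure(
    list(labels = labels, height = nrow(labels), width = ncol(labels)),
    class = "labeled_mask"
  )
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf(
    "<labeled_mask> %d x %d px, %d region(s)\n",
    x$height, x$width, n_labels(x)
  ))
  invisible(x)
}

#' Number of distinct positive labels in a mask
#' @param mask a [labeled_mask()].
#' @return integer count of regions.
#' @export
n_labels <- function(mask) {
  length(setdiff(unique(as.vector(mask$labels)), 0L))
}

#' Read a label mask from a PNG file
#'
#' Grayscale PNGs are interpreted directly as label values (8-bit: 0-255,
#' 16-bit: 0-65535). RGB PNGs are interpreted as base-256 encoded labels
#' (`label = R*65536 + G*256 + B`), the encoding [write_label_mask()] uses
#' when more than 255 regions must be stored in an 8-bit file. A grayscale
#' image whose only positive value is the maximum representable one
#' (255 or 65535) is treated as binary and connected-component labeled
#' with 8-connectivity; `binary = TRUE` forces that path.
#'
#' @param path PNG file path. TIFF is not supported in this build.
#' @param binary force connected-component labeling of `value > 0` pixels.
#' @return a [labeled_mask()].
#' @export
load_label_mask <- function(path, binary = FALSE) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("TIFF masks are not supported; convert to PNG", call. = FALSE)
  }
  if (!file.exists(path)) stop("cannot read mask file: ", path, call. = FALSE)
  img <- tryCatch(png::readPNG(path, info = TRUE),
    error = function(e) stop("unreadable PNG: ", path, " (", conditionMessage(e), ")", call. = FALSE)
  )
  info <- attr(img, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  scale <- 2^depth - 1
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    ch <- round(img[, , 1:3] * scale)
    lab <- ch[, , 1] * (scale + 1)^2 + ch[, , 2] * (scale + 1) + ch[, , 3]
  } else {
    if (length(dim(img)) == 3L) img <- img[, , 1]
    lab <- round(img * scale)
    pos <- unique(lab[lab > 0])
    if (binary || (length(pos) == 1L && pos == scale)) {
      return(labeled_mask(label_components(lab > 0)))
    }
  }
  if (binary) {
    return(labeled_mask(label_components(lab > 0)))
  }
  labeled_mask(lab)
}

#' Write a label mask to PNG
#'
#' Masks with at most 255 labels are written as 8-bit grayscale with the
#' pixel value equal to the label; larger label ranges are encoded across
#' the RGB channels base-256 (see [load_label_mask()]).
#'
#' @param mask a [labeled_mask()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  mx <- max(lab, 0L)
  if (mx <= 255L) {
    png::writePNG(lab / 255, path)
  } else {
    arr <- array(0, dim = c(nrow(lab), ncol(lab), 3))
    arr[, , 1] <- (lab %/% 65536L) / 255
    arr[, , 2] <- ((lab %/% 256L) %% 256L) / 255
    arr[, , 3] <- (lab %% 256L) / 255
    png::writePNG(arr, path)
  }
  invisible(path)
}

#' Connected-component labeling of a binary image (8-connectivity)
#'
#' @param bin logical matrix (TRUE = foreground).
#' @return integer matrix of labels, 0 background, components numbered in
#'   column-major scan order of their first pixel.
#' @export
label_components <- function(bin) {
  stopifnot(is.matrix(bin))
  bin <- bin > 0
  nr <- nrow(bin)
  nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  seeds <- which(bin)
  if (length(seeds) == 0L) return(lab)
  # linear-index offsets of the 8-neighborhood, with the row delta of each
  # offset kept alongside to reject column wrap-around
  off <- c(-1L, 1L, -nr - 1L, -nr, -nr + 1L, nr - 1L, nr, nr + 1L)
  droff <- c(-1L, 1L, -1L, 0L, 1L, -1L, 0L, 1L)
  npix <- nr * nc
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      base <- rep(frontier, each = 8L)
      cand <- base + off
      newr <- ((base - 1L) %% nr) + 1L + droff
      ok <- cand >= 1L & cand <= npix & newr >= 1L & newr <= nr
      cand <- unique(cand[ok])
      cand <- cand[bin[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  g
}

shift_or <- function(bin, offs, reduce = `|`, pad = FALSE) {
  nr <- nrow(bin)
  nc <- ncol(bin)
  out <- NULL
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]
    dc <- offs$dc[i]
    sh <- matrix(pad, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- bin[rs - dr, cs - dc]
    out <- if (is.null(out)) sh else reduce(out, sh)
  }
  out
}

#' Binary morphology on logical matrices
#'
#' Disk-structuring-element dilation and erosion, and hole filling
#' (background components not connected to the image border become
#' foreground). Building blocks of [morph_cleanup()].
#'
#' @param bin logical (or 0/1) matrix.
#' @param radius disk radius in pixels.
#' @return logical matrix.
#' @export
binary_dilate <- function(bin, radius = 1) {
  shift_or(bin > 0, disk_offsets(radius), `|`, pad = FALSE)
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(bin, radius = 1) {
  shift_or(bin > 0, disk_offsets(radius), `&`, pad = FALSE)
}

#' @rdname binary_dilate
#' @export
binary_fill <- function(bin) {
  # holes = background components not connected to the image border
  bg <- label_components(!(bin > 0))
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  (bin > 0) | (bg > 0 & !(bg %in% border))
}

#' Morphological cleanup of a label mask
#'
#' Applies the named binary operators in order, each region treated as an
#' independent binary image (so regions do not bleed into each other).
#' When dilation makes two regions contest a pixel, the lower label keeps it.
#'
#' @param mask a [labeled_mask()].
#' @param ops character vector, each one of `"dilate"`, `"erode"`,
#'   `"open"`, `"close"`, `"fill"`, applied left to right.
#' @param radius structuring-element (disk) radius in pixels, >= 1.
#' @return a cleaned [labeled_mask()].
#' @export
morph_cleanup <- function(mask, ops, radius = 1) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  known <- c("dilate", "erode", "open", "close", "fill")
  bad <- setdiff(ops, known)
  if (length(bad)) {
    stop("unknown morphological operator(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  labs <- setdiff(sort(unique(as.vector(mask$labels))), 0L)
  out <- matrix(0L, mask$height, mask$width)
  for (k in labs) {
    bin <- mask$labels == k
    for (op in ops) {
      bin <- switch(op,
        dilate = binary_dilate(bin, radius),
        erode  = binary_erode(bin, radius),
        open   = binary_dilate(binary_erode(bin, radius), radius),
        close  = binary_erode(binary_dilate(bin, radius), radius),
        fill   = binary_fill(bin)
      )
    }
    out[bin & out == 0L] <- k
  }
  labeled_mask(out)
}

#' Read an RGB image as an 8-bit integer array
#'
#' @param path PNG file path.
#' @return integer array `height x width x 3` with values in 0..255.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  arr <- round(img[, , 1:3] * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Write an 8-bit RGB integer array to PNG
#' @param image integer array `h x w x 3`, values 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
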