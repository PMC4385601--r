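#' @title Synthetic stained-cell scenes with exact ground truth
#' @name synthetic
#' @description
#' Generates Papanicolaou-like scenes: larger pale cytoplasm blobs with an
#' elliptical-to-lobed nucleus inside, per-stage color bands (jacinth
#' cytoplasm for LSIL-like cells, dark nuclei for SCC-like cells) and
#' Gaussian channel noise. Every drawn region's exact rasterized pixel
#' count and centroid are recorded, so the full measurement pipeline can
#' be validated without clinical material.
NULL

#' Nucleus/cytoplasm shape specifications
#'
#' Star-shaped outlines are defined by a polar radius function about the
#' shape center: constant (circle), the ellipse radius, or
#' `r(theta) = R * (1 + amplitude * cos(lobes * theta))`.
#'
#' @param axis_ratio ellipse major/minor ratio, >= 1.
#' @param lobes number of lobes, >= 2.
#' @param amplitude lobe depth as a fraction of the base radius, in [0, 1).
#' @param rotation orientation in radians.
#' @return a shape spec list with a `type` field.
#' @export
shape_circle <- function() list(type = "circle")

#' @rdname shape_circle
#' @export
shape_ellipse <- function(axis_ratio, rotation = 0) {
  stopifnot(axis_ratio >= 1)
  list(type = "ellipse", axis_ratio = axis_ratio, rotation = rotation)
}

#' @rdname shape_circle
#' @export
shape_star <- function(lobes, amplitude, rotation = 0) {
  stopifnot(lobes >= 2, amplitude >= 0, amplitude < 1)
  list(type = "star", lobes = lobes, amplitude = amplitude, rotation = rotation)
}

# polar radius r(theta) and maximum radius for a shape scaled to `area`
shape_radius <- function(shape, area) {
  switch(shape$type,
    circle = {
      R <- sqrt(area / pi)
      list(r = function(theta) rep(R, length(theta)), rmax = R)
    },
    ellipse = {
      q <- shape$axis_ratio
      a <- sqrt(area * q / pi)
      b <- a / q
      phi <- shape$rotation %||% 0
      list(
        r = function(theta) {
          t2 <- theta - phi
          a * b / sqrt((b * cos(t2))^2 + (a * sin(t2))^2)
        },
        rmax = a
      )
    },
    star = {
      amp <- shape$amplitude
      R <- sqrt(area / (pi * (1 + amp^2 / 2)))
      phi <- shape$rotation %||% 0
      list(
        r = function(theta) R * (1 + amp * cos(shape$lobes * (theta - phi))),
        rmax = R * (1 + amp)
      )
    },
    stop("unknown shape type: ", shape$type, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rasterize a star-shaped region: pixels (row, col) on an infinite canvas,
# center in 0-based (x, y)
rasterize_shape <- function(shape, area, center_x, center_y) {
  s <- shape_radius(shape, area)
  r <- ceiling(s$rmax) + 1L
  cx <- round(center_x)
  cy <- round(center_y)
  cols <- (cx - r):(cx + r)
  rows <- (cy - r):(cy + r)
  g <- expand.grid(row = rows + 1L, col = cols + 1L) # to 1-based
  dx <- (g$col - 1L) - center_x
  dy <- (g$row - 1L) - center_y
  dist <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  inside <- dist <= s$r(theta)
  as.matrix(g[inside, c("row", "col"), drop = FALSE])
}

#' Specification of one synthetic cell
#'
#' @param stage one of `"NORMAL"`, `"LSIL"`, `"HSIL"`, `"SCC"` (drives the
#'   recorded expected grade; the geometry/colors are whatever you pass).
#' @param nucleus_shape,cytoplasm_shape shape specs ([shape_circle()] and
#'   friends); cytoplasm defaults to a circle.
#' @param nucleus_area,cell_area target areas in pixels,
#'   `nucleus_area < cell_area`.
#' @param nucleus_rgb,cytoplasm_rgb 8-bit fill colors.
#' @param noise_sd Gaussian channel noise standard deviation (default 5,
#'   a typical camera-noise level for 8-bit microscopy).
#' @param nucleus_offset nucleus center displacement `c(dx, dy)` from the
#'   cell center.
#' @return object of class `cell_spec`.
#' @export
cell_spec <- function(stage, nucleus_shape, nucleus_area, cell_area,
                      nucleus_rgb, cytoplasm_rgb, noise_sd = 5,
                      cytoplasm_shape = shape_circle(),
                      nucleus_offset = c(0, 0)) {
  stage <- match.arg(stage, c("NORMAL", "LSIL", "HSIL", "SCC"))
  if (nucleus_area >= cell_area) {
    stop("geometry error: nucleus_area must be < cell_area", call. = FALSE)
  }
  if (any(c(nucleus_rgb, cytoplasm_rgb) < 0 | c(nucleus_rgb, cytoplasm_rgb) > 255)) {
    stop("channels must be in [0, 255]", call. = FALSE)
  }
  structure(
    list(
      stage = stage, nucleus_shape = nucleus_shape,
      cytoplasm_shape = cytoplasm_shape,
      nucleus_area = nucleus_area, cell_area = cell_area,
      nucleus_rgb = stats::setNames(as.numeric(nucleus_rgb), c("R", "G", "B")),
      cytoplasm_rgb = stats::setNames(as.numeric(cytoplasm_rgb), c("R", "G", "B")),
      noise_sd = noise_sd, nucleus_offset = nucleus_offset
    ),
    class = "cell_spec"
  )
}

background_rgb <- c(R = 235, G = 233, B = 238)

# expected shape-descriptor count for a drawn nucleus, given the default
# extrema tolerance
expected_N <- function(shape, amp_tol = 0.03) {
  switch(shape$type,
    circle = 0L,
    ellipse = {
      q <- shape$axis_ratio
      if ((q - 1) / (q + 1) > amp_tol) 4L else 0L
    },
    star = if (shape$amplitude > amp_tol) 2L * shape$lobes else 0L
  )
}

assemble_scene <- function(side, placements, noise_sd, seed) {
  img <- lapply(background_rgb, function(v) matrix(v, side, side))
  cell_lab <- matrix(0L, side, side)
  nuc_lab <- matrix(0L, side, side)
  truth <- list()
  for (p in placements) {
    id <- p$id
    spec <- p$spec
    cpx <- p$cell_px
    npx <- p$nuc_px
    ci <- (cpx[, 2] - 1L) * side + cpx[, 1]
    ni <- (npx[, 2] - 1L) * side + npx[, 1]
    for (ch in 1:3) {
      img[[ch]][ci] <- spec$cytoplasm_rgb[ch]
      img[[ch]][ni] <- spec$nucleus_rgb[ch]
    }
    cell_lab[ci] <- id
    nuc_lab[ni] <- id
    truth[[id]] <- data.frame(
      cell_id = id, stage = spec$stage,
      nucleus_shape = spec$nucleus_shape$type,
      nucleus_area = nrow(npx), cell_area = nrow(cpx),
      nucleus_cx = mean(npx[, 2]) - 1, nucleus_cy = mean(npx[, 1]) - 1,
      cell_cx = mean(cpx[, 2]) - 1, cell_cy = mean(cpx[, 1]) - 1,
      nuc_R = spec$nucleus_rgb["R"], nuc_G = spec$nucleus_rgb["G"],
      nuc_B = spec$nucleus_rgb["B"],
      cyt_R = spec$cytoplasm_rgb["R"], cyt_G = spec$cytoplasm_rgb["G"],
      cyt_B = spec$cytoplasm_rgb["B"],
      expected_N = expected_N(spec$nucleus_shape),
      expected_grade = if (spec$stage == "NORMAL") "NORMAL" else spec$stage,
      row.names = NULL
    )
  }
  for (ch in 1:3) {
    m <- img[[ch]]
    if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
    m <- round(pmin(pmax(m, 0), 255))
    storage.mode(m) <- "integer"
    img[[ch]] <- m
  }
  image <- array(0L, dim = c(side, side, 3))
  for (ch in 1:3) image[, , ch] <- img[[ch]]
  structure(
    list(
      image = image,
      cell_mask = labeled_mask(cell_lab),
      nucleus_mask = labeled_mask(nuc_lab),
      truth = do.call(rbind, truth),
      seed = seed
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px, %d cell(s): %s\n",
    dim(x$image)[1], dim(x$image)[2], nrow(x$truth),
    paste(sprintf("%s=%d", names(table(x$truth$stage)), table(x$truth$stage)),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Draw a single synthetic cell
#'
#' Rasterizes the cytoplasm blob and the nucleus shape on a canvas sized
#' to fit, fills with the spec colors plus clipped Gaussian channel noise,
#' and records exact ground truth from the rasterized masks.
#'
#' @param spec a [cell_spec()].
#' @param seed RNG seed (noise only).
#' @return object of class `synthetic_scene`: `image` (integer RGB array),
#'   `cell_mask`, `nucleus_mask` ([labeled_mask()]s), `truth` (data.frame),
#'   `seed`.
#' @export
make_cell <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell_spec"))
  set.seed(seed)
  cs <- shape_radius(spec$cytoplasm_shape, spec$cell_area)
  side <- 2L * (ceiling(cs$rmax) + 4L)
  cx <- (side - 1) / 2
  cy <- (side - 1) / 2
  cell_px <- rasterize_shape(spec$cytoplasm_shape, spec$cell_area, cx, cy)
  nuc_px <- rasterize_shape(
    spec$nucleus_shape, spec$nucleus_area,
    cx + spec$nucleus_offset[1], cy + spec$nucleus_offset[2]
  )
  if (any(nuc_px[, 1] < 1 | nuc_px[, 1] > side | nuc_px[, 2] < 1 | nuc_px[, 2] > side)) {
    stop("geometry error: shape overflows the canvas", call. = FALSE)
  }
  key_c <- cell_px[, 1] * 1e6 + cell_px[, 2]
  key_n <- nuc_px[, 1] * 1e6 + nuc_px[, 2]
  if (!all(key_n %in% key_c)) {
    stop("geometry error: nucleus not contained in cell", call. = FALSE)
  }
  assemble_scene(side,
    list(list(id = 1L, spec = spec, cell_px = cell_px, nuc_px = nuc_px)),
    spec$noise_sd, seed
  )
}

# per-stage randomized parameter profile; draws from the current RNG stream
stage_profile <- function(stage, ref) {
  jit <- function(base, amp) base + stats::runif(3, -amp, amp)
  switch(stage,
    NORMAL = list(
      grad_A = stats::runif(1, 0.85, 1.15),
      grad_P = stats::runif(1, 0.8, 1.3),
      nucleus_shape = shape_circle(),
      nucleus_rgb = jit(c(125, 110, 205), 8),
      cytoplasm_rgb = jit(c(205, 160, 215), 8)
    ),
    LSIL = list(
      grad_A = stats::runif(1, 2.8, 3.5),
      grad_P = stats::runif(1, 2.5, 4.0),
      nucleus_shape = shape_ellipse(stats::runif(1, 1.2, 1.4), stats::runif(1, 0, pi)),
      nucleus_rgb = jit(c(150, 95, 150), 10),
      cytoplasm_rgb = jit(c(145, 105, 155), 10)
    ),
    HSIL = list(
      grad_A = stats::runif(1, 1.6, 2.3),
      grad_P = stats::runif(1, 5.5, 9.0),
      nucleus_shape = shape_ellipse(stats::runif(1, 1.15, 1.3), stats::runif(1, 0, pi)),
      nucleus_rgb = jit(c(102, 95, 198), 6),
      cytoplasm_rgb = jit(c(190, 150, 215), 8)
    ),
    SCC = list(
      grad_A = stats::runif(1, 2.6, 3.6),
      grad_P = stats::runif(1, 11, 14),
      nucleus_shape = shape_ellipse(stats::runif(1, 1.1, 1.2), stats::runif(1, 0, pi)),
      nucleus_rgb = jit(c(78, 75, 150), 8),
      cytoplasm_rgb = jit(c(180, 150, 200), 8)
    )
  )
}

#' Generate a multi-cell synthetic population
#'
#' Cell counts per stage follow `stage_mix` exactly (largest-remainder
#' rounding). Geometry and colors are drawn from per-stage profiles built
#' so that, with the matching [normal_reference()], NORMAL cells trigger
#' no criterion, LSIL cells sit inside the Criterion-4 cytoplasm band with
#' `grad_A >= 2.8` and grade LSIL, SCC cells sit below the Criterion-5
#' bounds with `grad_P > 10` and grade SCC, and HSIL cells trigger
#' Criterion 1 while failing the SCC and LSIL grading rules. Cells are
#' placed without overlap by rejection sampling.
#'
#' @param n number of cells.
#' @param stage_mix named fractions over
#'   `NORMAL`/`LSIL`/`HSIL`/`SCC`, summing to 1.
#' @param ref the [normal_reference()] the profiles are calibrated to.
#' @param seed RNG seed; the whole scene is a deterministic function of it.
#' @param noise_sd Gaussian channel noise sd.
#' @return a `synthetic_scene` (see [make_cell()]).
#' @export
make_population <- function(n,
                            stage_mix = c(NORMAL = 0.1, LSIL = 0.3, HSIL = 0.3, SCC = 0.3),
                            ref = normal_reference(), seed = 1L,
                            noise_sd = 5) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (abs(sum(stage_mix) - 1) > 1e-8) {
    stop("stage_mix fractions must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  stages <- names(stage_mix)
  raw <- n * stage_mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stage_of <- sample(rep(stages, counts))
  # draw all specs first, then place large-to-small
  specs <- lapply(stage_of, function(st) {
    p <- stage_profile(st, ref)
    A_nuc <- p$grad_A * ref$A_normal
    P <- p$grad_P * ref$P_normal
    A_cell <- A_nuc * (1 + 1 / P)
    cyt_shape <- if (st == "SCC") {
      shape_circle()
    } else {
      shape_ellipse(stats::runif(1, 1.05, 1.2), stats::runif(1, 0, pi))
    }
    ncs <- shape_radius(p$nucleus_shape, A_nuc)
    ccs <- shape_radius(cyt_shape, A_cell)
    # minimum cytoplasm radius bounds the admissible nucleus offset
    rmin_c <- if (cyt_shape$type == "circle") ccs$rmax else ccs$rmax / cyt_shape$axis_ratio
    slack <- max(rmin_c - ncs$rmax - 2, 0)
    off <- stats::runif(2, -1, 1) * min(3, slack)
    cell_spec(
      stage = st, nucleus_shape = p$nucleus_shape,
      cytoplasm_shape = cyt_shape,
      nucleus_area = A_nuc, cell_area = A_cell,
      nucleus_rgb = p$nucleus_rgb, cytoplasm_rgb = p$cytoplasm_rgb,
      noise_sd = noise_sd, nucleus_offset = off
    )
  })
  bound <- vapply(specs, function(s) {
    shape_radius(s$cytoplasm_shape, s$cell_area)$rmax + 3
  }, numeric(1))
  side <- ceiling(sqrt(sum(pi * bound^2) / 0.30))
  side <- max(side, 2 * max(bound) + 10)
  ord <- order(bound, decreasing = TRUE)
  centers <- matrix(NA_real_, n, 2)
  for (i in ord) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      cand <- stats::runif(2, bound[i] + 1, side - bound[i] - 2)
      prev <- which(!is.na(centers[, 1]))
      if (length(prev) == 0L ||
        all(sqrt((centers[prev, 1] - cand[1])^2 + (centers[prev, 2] - cand[2])^2) >
          bound[prev] + bound[i] + 1)) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: canvas too crowded after bounded retries", call. = FALSE)
    }
  }
  placements <- lapply(seq_len(n), function(i) {
    spec <- specs[[i]]
    cx <- centers[i, 1]
    cy <- centers[i, 2]
    cell_px <- rasterize_shape(spec$cytoplasm_shape, spec$cell_area, cx, cy)
    nuc_px <- rasterize_shape(
      spec$nucleus_shape, spec$nucleus_area,
      cx + spec$nucleus_offset[1], cy + spec$nucleus_offset[2]
    )
    list(id = i, spec = spec, cell_px = cell_px, nuc_px = nuc_px)
  })
  scene <- assemble_scene(as.integer(side), placements, noise_sd, seed)
  scene$truth$grad_A_target <- vapply(specs, function(s) s$nucleus_area / ref$A_normal, numeric(1))
  scene$truth$grad_P_target <- vapply(
    specs,
    function(s) (s$nucleus_area / (s$cell_area - s$nucleus_area)) / ref$P_normal,
    numeric(1)
  )
  scene
}

#' Write a synthetic scene to disk
#'
#' Writes `image.png`, `cell_mask.png`, `nucleus_mask.png` and `truth.csv`
#' into `dir`.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rgb_image(scene$image, file.path(dir, "image.png"))
  write_label_mask(scene$cell_mask, file.path(dir, "cell_mask.png"))
  write_label_mask(scene$nucleus_mask, file.path(dir, "nucleus_mask.png"))
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
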