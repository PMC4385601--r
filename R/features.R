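#' Normal-cell reference values and criterion thresholds
#'
#' Bundles the normal-cell calibration (nucleus area `A_normal` in pixels
#' and nucleus-to-cytoplasm ratio `P_normal`) with the thresholds of the
#' five abnormality criteria: the relative size thresholds `grad_A0`,
#' `grad_P0`, the shape thresholds `C0` (circularity), `E0` (solidity) and
#' `N0` (radial-signature extrema count), the hyperkeratosis RGB band
#' (jacinth cytoplasm, open intervals) and the deep-stain RGB upper bounds
#' (dark nucleus).
#'
#' The threshold defaults are the published operating point of the method
#' (`grad_P0 = 2`, `grad_A0 = 2.5`, `C0 = 0.8`, `E0 = 0.7`, `N0 = 4`,
#' band 120-170 / 70-140 / 120-190, dark bounds 90 / 90 / 190).
#' `A_normal` and `P_normal` have no published value and must be calibrated
#' per staining protocol and magnification; the defaults (900 px, 0.1) are
#' the ones the synthetic generator is built around.
#'
#' @param A_normal normal nucleus area, pixels.
#' @param P_normal normal N/C ratio (nucleus over cytoplasm-only area).
#' @param grad_A0,grad_P0 relative size thresholds of Criterion 1.
#' @param C0,E0 shape thresholds of Criterion 2, each in (0, 1].
#' @param N0 extrema-count threshold of Criterion 3.
#' @param lsil_band list with elements `R`, `G`, `B`, each `c(low, high)`:
#'   the open cytoplasm color band of Criterion 4.
#' @param scc_dark named vector `c(R=, G=, B=)`: the strict nucleus upper
#'   bounds of Criterion 5.
#' @return object of class `normal_reference`.
#' @export
normal_reference <- function(A_normal = 900, P_normal = 0.1,
                             grad_A0 = 2.5, grad_P0 = 2,
                             C0 = 0.8, E0 = 0.7, N0 = 4,
                             lsil_band = list(
                               R = c(120, 170), G = c(70, 140), B = c(120, 190)
                             ),
                             scc_dark = c(R = 90, G = 90, B = 190)) {
  if (A_normal <= 0) stop("config error: A_normal must be > 0", call. = FALSE)
  if (P_normal <= 0) stop("config error: P_normal must be > 0", call. = FALSE)
  if (C0 <= 0 || C0 > 1) stop("config error: C0 must be in (0, 1]", call. = FALSE)
  if (E0 <= 0 || E0 > 1) stop("config error: E0 must be in (0, 1]", call. = FALSE)
  if (N0 < 0) stop("config error: N0 must be >= 0", call. = FALSE)
  for (ch in c("R", "G", "B")) {
    b <- lsil_band[[ch]]
    if (is.null(b) || length(b) != 2L || b[1] >= b[2]) {
      stop("config error: lsil_band$", ch, " must be c(low, high), low < high",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      A_normal = A_normal, P_normal = P_normal,
      grad_A0 = grad_A0, grad_P0 = grad_P0,
      C0 = C0, E0 = E0, N0 = N0,
      lsil_band = lsil_band, scc_dark = scc_dark
    ),
    class = "normal_reference"
  )
}

#' Relative nucleus size
#'
#' `grad_A = A / A_normal`: how many times larger than a normal nucleus
#' the detected nucleus is.
#'
#' @param A nucleus area, pixels.
#' @param A_normal normal nucleus area, pixels.
#' @return numeric ratio.
#' @export
area_ratio <- function(A, A_normal) {
  if (any(A_normal <= 0)) stop("config error: A_normal must be > 0", call. = FALSE)
  A / A_normal
}

#' Nucleus-to-cytoplasm ratio
#'
#' Default denominator is the cytoplasm-only area (`cell - nucleus`); the
#' whole-cell denominator is available for protocols that define N/C that
#' way.
#'
#' @param nucleus_A,cell_A areas in pixels; `cell_A > nucleus_A > 0`.
#' @param denominator `"cytoplasm"` (default) or `"cell"`.
#' @return numeric ratio `P`.
#' @export
nc_ratio <- function(nucleus_A, cell_A, denominator = c("cytoplasm", "cell")) {
  denominator <- match.arg(denominator)
  if (any(nucleus_A <= 0)) stop("geometry error: nucleus area must be > 0", call. = FALSE)
  if (any(cell_A <= nucleus_A)) {
    stop("geometry error: cell area must exceed nucleus area", call. = FALSE)
  }
  if (denominator == "cytoplasm") nucleus_A / (cell_A - nucleus_A) else nucleus_A / cell_A
}

#' Circularity (isoperimetric quotient)
#'
#' `C = 4 * pi * A / perimeter^2`, 1 for an ideal disk, capped at 1.05 to
#' absorb digitization overshoot. Degenerate regions (1-2 pixels) return 1
#' by convention and should never reach Criterion 2.
#'
#' @param region a [region_record()], or a list with `area` and `perimeter`.
#' @return numeric in (0, 1.05].
#' @export
circularity <- function(region) {
  if (region$area <= 2) return(1)
  if (region$perimeter <= 0) stop("geometry error: perimeter must be > 0", call. = FALSE)
  min(4 * pi * region$area / region$perimeter^2, 1.05)
}

# polygon area by the shoelace formula
shoelace <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Compactness (solidity) of a region
#'
#' Default variant is solidity: pixel area over the area of the convex
#' hull of the pixel *corners* (each pixel contributes its unit-square
#' footprint), so convex digitized shapes score 1 within digitization
#' tolerance and concave outlines score low. The `"extent"` variant uses
#' the bounding-box area instead.
#'
#' @param region a [region_record()].
#' @param variant `"solidity"` (default) or `"extent"`.
#' @return numeric in (0, 1] (tiny digitization overshoot possible).
#' @export
compactness <- function(region, variant = c("solidity", "extent")) {
  variant <- match.arg(variant)
  if (region$area <= 2) return(1)
  if (variant == "extent") {
    bb <- region$bbox
    return(unname(region$area / ((bb["xmax"] - bb["xmin"] + 1) * (bb["ymax"] - bb["ymin"] + 1))))
  }
  b <- region$boundary
  cx <- c(b[, "x"] - 0.5, b[, "x"] + 0.5, b[, "x"] - 0.5, b[, "x"] + 0.5)
  cy <- c(b[, "y"] - 0.5, b[, "y"] - 0.5, b[, "y"] + 0.5, b[, "y"] + 0.5)
  h <- grDevices::chull(cx, cy)
  region$area / shoelace(cx[h], cy[h])
}

#' Radial boundary signature of a region
#'
#' For every traced boundary pixel, the Euclidean distance
#' `d = sqrt((x0 - x)^2 + (y0 - y)^2)` to the region centroid is computed;
#' points are ordered by polar angle about the centroid and duplicate
#' angles are averaged. If the centroid pixel lies outside the region
#' (strongly non-star-shaped outline) the signature is still returned with
#' the `"non_star_shaped"` flag.
#'
#' @param region a [region_record()] with at least 8 boundary points.
#' @return object of class `radial_signature`: `angles` (radians,
#'   strictly increasing in `[0, 2*pi)`), `distances` (pixels),
#'   `mean_distance`, `centroid`, `flags`.
#' @export
radial_signature <- function(region) {
  b <- region$boundary
  if (nrow(b) < 8L) {
    stop("degenerate input: boundary has fewer than 8 points", call. = FALSE)
  }
  dx <- b[, "x"] - region$centroid["x"]
  dy <- b[, "y"] - region$centroid["y"]
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  key <- round(theta, 9)
  agg <- tapply(d, key, mean)
  angles <- as.numeric(names(agg))
  o <- order(angles)
  flags <- character()
  px <- round(region$centroid["x"]) + 1L
  py <- round(region$centroid["y"]) + 1L
  if (!any(region$pixels[, 1] == py & region$pixels[, 2] == px)) {
    flags <- c(flags, "non_star_shaped")
  }
  structure(
    list(
      angles = angles[o], distances = as.numeric(agg)[o],
      mean_distance = mean(d), centroid = region$centroid, flags = flags
    ),
    class = "radial_signature"
  )
}

fit_signature <- function(sig, fit_order, method, grid_n = 720L) {
  th <- sig$angles
  d <- sig$distances
  m <- length(th)
  grid <- seq(0, 2 * pi, length.out = grid_n + 1L)[-(grid_n + 1L)]
  if (method == "fourier") {
    k <- min(fit_order, (m - 1L) %/% 2L)
    if (k < 1L) stop("degenerate input: too few points to fit", call. = FALSE)
    X <- cbind(1, do.call(cbind, lapply(seq_len(k), function(j) {
      cbind(cos(j * th), sin(j * th))
    })))
    beta <- qr.solve(qr(X), d)
    Xg <- cbind(1, do.call(cbind, lapply(seq_len(k), function(j) {
      cbind(cos(j * grid), sin(j * grid))
    })))
    fitted <- as.numeric(Xg %*% beta)
  } else {
    if (m < fit_order + 1L) {
      stop("degenerate input: fewer points than fit_order + 1", call. = FALSE)
    }
    # plain polynomial in the angle; endpoint behavior depends on where the
    # traversal started, which is why "fourier" is the default
    X <- stats::poly(th, degree = fit_order, raw = FALSE)
    fit <- stats::lm.fit(cbind(1, X), d)
    Xg <- stats::predict(X, pmin(pmax(grid, min(th)), max(th)))
    fitted <- as.numeric(cbind(1, Xg) %*% fit$coefficients)
  }
  list(grid = grid, fitted = fitted)
}

#' Radial-signature shape descriptor N
#'
#' Fits a smooth periodic curve to the angle-ordered centroid-to-boundary
#' distances and counts the local maxima and minima whose value departs
#' from the mean radius by more than `amp_tol * mean(d)`. The count `N`
#' measures boundary lobedness: 0 for a disk, 4 for an ellipse (2 peaks +
#' 2 valleys), `2k` for a `k`-lobed outline.
#'
#' @param sig a [radial_signature()].
#' @param fit_order harmonic order of the truncated Fourier fit (default 8)
#'   or polynomial degree when `method = "polynomial"` (default then 10).
#' @param amp_tol extrema amplitude tolerance as a fraction of the mean
#'   radius, in `[0, 1)`; default 0.03 suppresses digitization ripple.
#' @param min_amp absolute floor on the tolerance, pixels (default 1):
#'   boundary coordinates are quantized to the pixel grid, so
#'   peak-to-valley swings below about one pixel are measurement noise
#'   regardless of the nucleus size.
#' @param method `"fourier"` (default; periodic, start-point invariant) or
#'   `"polynomial"` (literal high-order polynomial over the angle).
#' @return integer `N` with attribute `"extrema"` (data.frame of angle,
#'   value, type) and `"fitted"` (list with `grid`, `fitted`).
#' @export
string_shape_descriptor <- function(sig, fit_order = NULL, amp_tol = 0.03,
                                    min_amp = 1,
                                    method = c("fourier", "polynomial")) {
  method <- match.arg(method)
  if (is.null(fit_order)) fit_order <- if (method == "fourier") 8L else 10L
  if (method == "polynomial" && fit_order < 4L) {
    stop("fit_order must be >= 4", call. = FALSE)
  }
  if (amp_tol < 0 || amp_tol >= 1) stop("amp_tol must be in [0, 1)", call. = FALSE)
  f <- fit_signature(sig, fit_order, method)
  v <- f$fitted
  n <- length(v)
  prv <- c(v[n], v[-n])
  nxt <- c(v[-1], v[1])
  peak <- v > prv & v > nxt
  valley <- v < prv & v < nxt
  idx <- which(peak | valley)
  # prominence pruning on the cyclic alternating extrema sequence: cancel
  # the adjacent peak/valley pair with the smallest height difference until
  # every swing exceeds the amplitude tolerance; low-amplitude ripple near
  # a genuine extremum is absorbed instead of double-counted
  tol <- max(amp_tol * sig$mean_distance, min_amp)
  while (length(idx) >= 2L) {
    vals <- v[idx]
    swings <- abs(vals - c(vals[-1], vals[1]))
    j <- which.min(swings)
    if (swings[j] > tol) break
    drop <- if (j == length(idx)) c(j, 1L) else c(j, j + 1L)
    idx <- idx[-drop]
  }
  if (length(idx) == 1L) idx <- integer(0)
  ex <- data.frame(
    angle = f$grid[idx], value = v[idx],
    type = ifelse(peak[idx], "peak", "valley")
  )
  structure(length(idx), extrema = ex, fitted = f)
}

#' Mean staining strength of a region
#'
#' Per-channel arithmetic mean of the 8-bit RGB values over the region's
#' pixels.
#'
#' @param image integer array `h x w x 3` (see [read_rgb_image()]).
#' @param region a [region_record()], or a 2-column `(row, col)` pixel
#'   matrix.
#' @return named numeric vector `c(R=, G=, B=)` in `[0, 255]`.
#' @export
color_strength <- function(image, region) {
  px <- if (inherits(region, "region_record")) region$pixels else region
  if (any(px[, 1] < 1 | px[, 1] > dim(image)[1] |
    px[, 2] < 1 | px[, 2] > dim(image)[2])) {
    stop("geometry error: region out of image bounds", call. = FALSE)
  }
  c(
    R = mean(image[cbind(px[, 1], px[, 2], 1L)]),
    G = mean(image[cbind(px[, 1], px[, 2], 2L)]),
    B = mean(image[cbind(px[, 1], px[, 2], 3L)])
  )
}

#' Construct a feature vector manually
#'
#' Mostly useful for tests and for feeding the decision rules from a
#' feature table; [extract_features()] builds these from images.
#'
#' @param A nucleus area (pixels); `grad_A`, `P`, `grad_P` relative size
#'   and N/C descriptors; `C` circularity; `E` solidity; `N` shape
#'   descriptor; `nucleus_rgb`, `cytoplasm_rgb` named `c(R=,G=,B=)` means.
#' @param grad_A,P,grad_P,C,E,N see above.
#' @param nucleus_rgb,cytoplasm_rgb per-compartment mean colors.
#' @param flags character vector of quality flags.
#' @return object of class `feature_vector`.
#' @export
feature_vector <- function(A, grad_A, P, grad_P, C, E, N,
                           nucleus_rgb, cytoplasm_rgb, flags = character()) {
  for (v in list(A, grad_A, P, grad_P)) {
    if (!is.finite(v) || v <= 0) {
      stop("validation error: size descriptors must be finite and > 0", call. = FALSE)
    }
  }
  if (C <= 0 || C > 1.05) stop("validation error: C out of (0, 1.05]", call. = FALSE)
  if (E <= 0 || E > 1.05) stop("validation error: E out of (0, 1.05]", call. = FALSE)
  if (N < 0 || N != round(N)) stop("validation error: N must be a non-negative integer", call. = FALSE)
  ok_rgb <- function(x) length(x) == 3L && all(x >= 0 & x <= 255)
  if (!ok_rgb(nucleus_rgb) || !ok_rgb(cytoplasm_rgb)) {
    stop("validation error: RGB means must be 3 channels in [0, 255]", call. = FALSE)
  }
  structure(
    list(
      A = A, grad_A = grad_A, P = P, grad_P = grad_P,
      C = C, E = E, N = as.integer(N),
      nucleus_rgb = stats::setNames(as.numeric(nucleus_rgb), c("R", "G", "B")),
      cytoplasm_rgb = stats::setNames(as.numeric(cytoplasm_rgb), c("R", "G", "B")),
      flags = flags
    ),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<feature_vector> A=%d px, gradA=%.2f, P=%.3f, gradP=%.2f, C=%.3f, ",
      "E=%.3f, N=%d\n  nucleus RGB (%.0f, %.0f, %.0f), cytoplasm RGB (%.0f, %.0f, %.0f)\n"
    ),
    x$A, x$grad_A, x$P, x$grad_P, x$C, x$E, x$N,
    x$nucleus_rgb[1], x$nucleus_rgb[2], x$nucleus_rgb[3],
    x$cytoplasm_rgb[1], x$cytoplasm_rgb[2], x$cytoplasm_rgb[3]
  ))
  invisible(x)
}

#' Quantify all descriptors for one cell-nucleus pair
#'
#' Composes [area_ratio()], [nc_ratio()], [circularity()], [compactness()],
#' [radial_signature()] + [string_shape_descriptor()] and
#' [color_strength()]. Cytoplasm color is averaged over cell-minus-nucleus
#' pixels, nucleus color over nucleus pixels.
#'
#' @param pair a `cell_nucleus_pair` from [pair_nucleus_to_cell()].
#' @param image integer RGB array (see [read_rgb_image()]).
#' @param ref a [normal_reference()].
#' @param nc_denominator passed to [nc_ratio()].
#' @param compactness_variant passed to [compactness()].
#' @param fit_order,amp_tol,fit_method passed to [string_shape_descriptor()].
#' @return a [feature_vector()].
#' @export
extract_features <- function(pair, image, ref = normal_reference(),
                             nc_denominator = "cytoplasm",
                             compactness_variant = "solidity",
                             fit_order = NULL, amp_tol = 0.03,
                             fit_method = "fourier") {
  stopifnot(inherits(pair, "cell_nucleus_pair"))
  nuc <- pair$nucleus
  cell <- pair$cell
  P <- nc_ratio(nuc$area, cell$area, nc_denominator)
  sig <- radial_signature(nuc)
  N <- string_shape_descriptor(sig,
    fit_order = fit_order, amp_tol = amp_tol, method = fit_method
  )
  key_cell <- cell$pixels[, 1] * 1e6 + cell$pixels[, 2]
  key_nuc <- nuc$pixels[, 1] * 1e6 + nuc$pixels[, 2]
  cyt_px <- cell$pixels[!(key_cell %in% key_nuc), , drop = FALSE]
  if (nrow(cyt_px) == 0L) {
    stop("geometry error: no cytoplasm pixels (nucleus covers cell)", call. = FALSE)
  }
  feature_vector(
    A = nuc$area,
    grad_A = area_ratio(nuc$area, ref$A_normal),
    P = P,
    grad_P = P / ref$P_normal,
    C = circularity(nuc),
    E = compactness(nuc, compactness_variant),
    N = as.integer(N),
    nucleus_rgb = color_strength(image, nuc),
    cytoplasm_rgb = color_strength(image, cyt_px),
    flags = unique(c(pair$flags, nuc$flags, sig$flags))
  )
}

#' Feature table for a list of pairs
#'
#' @param pairs list of `cell_nucleus_pair`s.
#' @inheritParams extract_features
#' @return data.frame with one row per pair: `pair_id`, `cell_label`,
#'   `nucleus_label`, `A`, `grad_A`, `P`, `grad_P`, `C`, `E`, `N`,
#'   `nuc_R`..`cyt_B`, `flags`.
#' @export
features_table <- function(pairs, image, ref = normal_reference(), ...) {
  rows <- lapply(seq_along(pairs), function(i) {
    fv <- extract_features(pairs[[i]], image, ref, ...)
    data.frame(
      pair_id = i,
      cell_label = pairs[[i]]$cell$label,
      nucleus_label = pairs[[i]]$nucleus$label,
      A = fv$A, grad_A = fv$grad_A, P = fv$P, grad_P = fv$grad_P,
      C = fv$C, E = fv$E, N = fv$N,
      nuc_R = fv$nucleus_rgb["R"], nuc_G = fv$nucleus_rgb["G"],
      nuc_B = fv$nucleus_rgb["B"],
      cyt_R = fv$cytoplasm_rgb["R"], cyt_G = fv$cytoplasm_rgb["G"],
      cyt_B = fv$cytoplasm_rgb["B"],
      flags = paste(fv$flags, collapse = ";"),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Estimate reference values from a set of normal cells
#'
#' Area-weighted (default) or plain mean of nucleus area, N/C, circularity
#' and solidity over a list of reference pairs; a calibration helper for
#' building a [normal_reference()] from screened-normal material.
#'
#' @param pairs list of `cell_nucleus_pair`s of normal cells.
#' @param weighted use area weights (default) or a plain mean.
#' @param ... passed to [extract_features()]; requires `image` when color
#'   calibration is wanted, otherwise geometric features only.
#' @param image RGB array for the pairs.
#' @return named list with `A_normal`, `P_normal`, `C0`, `E0` estimates.
#' @export
estimate_reference <- function(pairs, image, weighted = TRUE, ...) {
  fvs <- lapply(pairs, extract_features, image = image, ...)
  A <- vapply(fvs, `[[`, numeric(1), "A")
  w <- if (weighted) A / sum(A) else rep(1 / length(A), length(A))
  list(
    A_normal = sum(w * A),
    P_normal = sum(w * vapply(fvs, `[[`, numeric(1), "P")),
    C0 = sum(w * vapply(fvs, `[[`, numeric(1), "C")),
    E0 = sum(w * vapply(fvs, `[[`, numeric(1), "E"))
  )
}
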