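# Independent brute-force oracles, deliberately kept free of the package's
# own geometry code paths: shapes are rasterized by direct inequality tests
# on the lattice.

disk_mask <- function(r, pad = 4L) {
  n <- 2L * (ceiling(r) + pad)
  c0 <- (n + 1) / 2
  m <- outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
  m
}

ellipse_mask <- function(a, b, pad = 4L) {
  n <- 2L * (ceiling(max(a, b)) + pad)
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) ((j - c0) / a)^2 + ((i - c0) / b)^2 <= 1)
}

square_mask <- function(s, pad = 4L) {
  n <- s + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- TRUE
  m
}

star_mask <- function(lobes, amp, R, rotation = 0, pad = 4L) {
  n <- 2L * (ceiling(R * (1 + amp)) + pad)
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    d <- sqrt((i - c0)^2 + (j - c0)^2)
    th <- atan2(i - c0, j - c0)
    d <= R * (1 + amp * cos(lobes * (th - rotation)))
  })
}

annulus_mask <- function(r_out, r_in, pad = 4L) {
  disk_mask(r_out, pad) & !disk_mask(r_in, pad + (ceiling(r_out) - ceiling(r_in)))
}

as_mask <- function(bin) labeled_mask(matrix(as.integer(bin), nrow(bin), ncol(bin)))

region_of <- function(bin, ...) extract_regions(as_mask(bin), ...)[[1]]

# Ramanujan ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# random 1-D clustering instance: 2-3 well-separated Gaussian blobs with at
# least 3 points each (the regime where the exemplar set is identifiable)
blob_instance <- function() {
  k <- sample(2:3, 1)
  n <- sample(seq(3 * k, 12), 1)
  centers <- cumsum(c(stats::runif(1, 0, 10), stats::runif(k - 1, 25, 60)))
  sizes <- rep(3L, k)
  extra <- n - 3L * k
  if (extra > 0) sizes <- sizes + tabulate(sample(k, extra, replace = TRUE), k)
  blob <- sample(rep(seq_len(k), sizes))
  stats::rnorm(length(blob), centers[blob], 1)
}

# k-medoids objective of a given exemplar set (independent of AP internals)
km_objective <- function(S, ex) {
  diag(S) <- 0
  owner <- vapply(seq_len(nrow(S)), function(i) {
    if (i %in% ex) i else ex[which.max(S[i, ex])]
  }, integer(1))
  sum(S[cbind(seq_len(nrow(S)), owner)])
}

# a partition matches the exhaustive k-medoids optimum if the labels agree
# or the objectives tie (symmetric clusters have interchangeable medoids)
ap_matches_kmedoids <- function(v, ap) {
  S <- -outer(v, v, "-")^2
  km <- k_medoids_search(S, ap$n_clusters)
  identical(ap$labels, km$labels) ||
    abs(km_objective(S, ap$exemplars) - km$objective) <=
      1e-9 * max(1, abs(km$objective))
}

# random but valid feature vector for decision-rule property tests
random_fv <- function() {
  feature_vector(
    A = stats::runif(1, 100, 4000),
    grad_A = stats::runif(1, 0.3, 4),
    P = stats::runif(1, 0.02, 2),
    grad_P = stats::runif(1, 0.3, 15),
    C = stats::runif(1, 0.3, 1.05),
    E = stats::runif(1, 0.3, 1.05),
    N = sample(0:8, 1),
    nucleus_rgb = stats::runif(3, 0, 255),
    cytoplasm_rgb = stats::runif(3, 0, 255)
  )
}

# a feature vector that triggers nothing under default thresholds
normal_fv <- function(...) {
  args <- list(
    A = 900, grad_A = 1, P = 0.1, grad_P = 1, C = 0.95, E = 0.95, N = 0,
    nucleus_rgb = c(R = 125, G = 110, B = 205),
    cytoplasm_rgb = c(R = 205, G = 160, B = 215)
  )
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(feature_vector, args)
}
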