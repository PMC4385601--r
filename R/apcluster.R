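#' Affinity propagation configuration
#'
#' @param damping message damping factor in `[0.5, 1)`; higher is more
#'   stable, slower. Default 0.9.
#' @param max_iter maximum message-passing iterations.
#' @param convergence_iter stop when the exemplar set is unchanged this
#'   many consecutive iterations.
#' @param preference self-similarity `s(k, k)`: a scalar, or `"median"`
#'   (default) for the median off-diagonal similarity, the standard
#'   moderate-cluster-count choice.
#' @return object of class `ap_config`.
#' @export
ap_config <- function(damping = 0.9, max_iter = 1000L,
                      convergence_iter = 50L, preference = "median") {
  if (damping < 0.5 || damping >= 1) {
    stop("config error: damping must be in [0.5, 1)", call. = FALSE)
  }
  if (max_iter < convergence_iter || convergence_iter < 1L) {
    stop("config error: need max_iter >= convergence_iter >= 1", call. = FALSE)
  }
  structure(
    list(
      damping = damping, max_iter = as.integer(max_iter),
      convergence_iter = as.integer(convergence_iter), preference = preference
    ),
    class = "ap_config"
  )
}

#' Affinity propagation clustering
#'
#' Frey-Dueck exemplar clustering by damped responsibility/availability
#' message passing on a similarity matrix. The update is fully
#' deterministic; ties in exemplar selection resolve to the lowest index.
#' After convergence the exemplar of each cluster is refined to the member
#' maximizing the within-cluster similarity sum.
#'
#' @param similarity square numeric matrix `s(i, k)`, larger = more
#'   similar (e.g. negative squared distance). The diagonal is overwritten
#'   by the preference.
#' @param cfg an [ap_config()].
#' @return object of class `ap_result`: `exemplars` (indices),
#'   `labels` (cluster id per sample, clusters numbered by exemplar
#'   index order), `n_clusters`, `n_iter`, `converged`, `net_similarity`.
#' @export
affinity_propagation <- function(similarity, cfg = ap_config()) {
  S <- as.matrix(similarity)
  if (nrow(S) != ncol(S)) stop("validation error: similarity must be square", call. = FALSE)
  if (any(!is.finite(S))) stop("validation error: similarity must be finite", call. = FALSE)
  n <- nrow(S)
  if (n < 2L) stop("validation error: need n >= 2 samples", call. = FALSE)
  pref <- cfg$preference
  if (identical(pref, "median")) {
    pref <- stats::median(S[row(S) != col(S)])
  }
  diag(S) <- pref
  # deterministic degeneracy-breaking: near-equivalent points can lock the
  # message passing into an unstable all-exemplar fixed point; a relative
  # perturbation of ~1e-16 (from a fixed internal seed, so the result is a
  # pure function of (similarity, cfg)) tips it into the stable one
  rs <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(20150322L)
  S <- S + (.Machine$double.eps * S + .Machine$double.xmin * 100) *
    matrix(stats::rnorm(n * n), n, n)
  if (is.null(rs)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", rs, envir = globalenv())
  }
  lam <- cfg$damping
  R <- A <- matrix(0, n, n)
  ex_prev <- rep(FALSE, n)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  idx <- seq_len(n)
  while (it < cfg$max_iter) {
    it <- it + 1L
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    AS <- A + S
    mx1 <- apply(AS, 1, max)
    am <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(idx, am)] <- -Inf
    mx2 <- apply(AS2, 1, max)
    Mx <- matrix(mx1, n, n)
    Mx[cbind(idx, am)] <- mx2
    R <- lam * R + (1 - lam) * (S - Mx)
    # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew) # = sum_{i' != k} max(0, r(i',k))
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- lam * A + (1 - lam) * Anew
    ex <- (diag(A) + diag(R)) > 0
    if (identical(ex, ex_prev) && any(ex)) {
      stable <- stable + 1L
      if (stable >= cfg$convergence_iter) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    ex_prev <- ex
  }
  exemplars <- which((diag(A) + diag(R)) > 0)
  if (length(exemplars) == 0L) {
    exemplars <- which.max(diag(A) + diag(R))
  }
  assign_to <- function(ex_set) {
    vapply(idx, function(i) {
      if (i %in% ex_set) return(i)
      ex_set[which.max(S[i, ex_set])]
    }, integer(1))
  }
  owner <- assign_to(exemplars)
  # refine: per cluster pick the member maximizing within-cluster similarity
  refined <- vapply(sort(unique(owner)), function(e) {
    members <- which(owner == e)
    score <- vapply(members, function(j) sum(S[members, j]), numeric(1))
    members[which.max(score)]
  }, integer(1))
  refined <- sort(unique(refined))
  owner <- assign_to(refined)
  labels <- match(owner, refined)
  structure(
    list(
      exemplars = refined,
      labels = labels,
      n_clusters = length(refined),
      n_iter = it,
      converged = converged,
      net_similarity = sum(S[cbind(idx, refined[labels])])
    ),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf(
    "<ap_result> %d cluster(s), exemplars {%s}, %d iteration(s), converged = %s\n",
    x$n_clusters, paste(x$exemplars, collapse = ", "), x$n_iter, x$converged
  ))
  invisible(x)
}

#' Cluster one feature's per-sample values
#'
#' Builds the similarity `s(i, j) = -(v_i - v_j)^2`, runs
#' [affinity_propagation()], and reports per-cluster value ranges
#' ("scope of feature values"), with clusters sorted by range minimum.
#' All-identical values yield a single width-zero cluster.
#'
#' @param values numeric vector (optionally named by sample id), length >= 2.
#' @param cfg an [ap_config()].
#' @return an `ap_result` with extra elements `values`, `cluster_ranges`
#'   (data.frame `cluster`, `exemplar`, `exemplar_value`, `min`, `max`,
#'   `n`) and `members` (list of sample indices per cluster).
#' @export
cluster_feature <- function(values, cfg = ap_config()) {
  v <- as.numeric(values)
  if (length(v) < 2L) stop("validation error: need >= 2 samples", call. = FALSE)
  if (diff(range(v)) == 0) {
    res <- structure(
      list(
        exemplars = 1L, labels = rep(1L, length(v)), n_clusters = 1L,
        n_iter = 0L, converged = TRUE, net_similarity = 0
      ),
      class = "ap_result"
    )
  } else {
    S <- -outer(v, v, "-")^2
    res <- affinity_propagation(S, cfg)
  }
  ord <- order(vapply(seq_len(res$n_clusters), function(k) min(v[res$labels == k]), numeric(1)))
  relabel <- match(seq_len(res$n_clusters), ord)
  res$labels <- relabel[res$labels]
  res$exemplars <- res$exemplars[ord]
  res$values <- v
  res$members <- lapply(seq_len(res$n_clusters), function(k) which(res$labels == k))
  res$cluster_ranges <- data.frame(
    cluster = seq_len(res$n_clusters),
    exemplar = res$exemplars,
    exemplar_value = v[res$exemplars],
    min = vapply(res$members, function(m) min(v[m]), numeric(1)),
    max = vapply(res$members, function(m) max(v[m]), numeric(1)),
    n = lengths(res$members)
  )
  res
}

#' Suggest decision thresholds from cluster value ranges
#'
#' Cut points are placed at the midpoint of the gap between adjacent
#' cluster ranges and snapped to a rounding grid (0.5 suits ratio
#' features, 10 suits 8-bit color channels). Overlapping adjacent ranges
#' produce a warning and use the midpoint of the overlap.
#'
#' @param result an `ap_result` from [cluster_feature()], or a list /
#'   data.frame of ranges with `min` and `max`.
#' @param grid rounding grid for the cuts.
#' @return numeric vector of cut points (empty for a single cluster).
#' @export
suggest_thresholds <- function(result, grid = 0.5) {
  ranges <- if (inherits(result, "ap_result")) {
    result$cluster_ranges
  } else if (is.data.frame(result)) {
    result
  } else {
    data.frame(
      min = vapply(result, function(r) r[[1]], numeric(1)),
      max = vapply(result, function(r) r[[2]], numeric(1))
    )
  }
  ranges <- ranges[order(ranges$min), , drop = FALSE]
  k <- nrow(ranges)
  if (k < 2L) return(numeric(0))
  cuts <- numeric(k - 1L)
  for (i in seq_len(k - 1L)) {
    lo <- ranges$max[i]
    hi <- ranges$min[i + 1L]
    if (hi < lo) {
      warning("overlapping adjacent cluster ranges; using overlap midpoint")
    }
    cuts[i] <- (lo + hi) / 2
  }
  floor(cuts / grid + 0.5) * grid
}

#' Exhaustive exemplar-search oracle for small instances
#'
#' Enumerates every non-empty exemplar subset, assigns each sample to its
#' most similar exemplar, and maximizes the same net-similarity objective
#' affinity propagation optimizes (sum of member-to-exemplar similarities
#' plus exemplar preferences). Exact MAP for `n <= ~15`; used as the
#' independent oracle in tests.
#'
#' @param similarity square similarity matrix (diagonal ignored).
#' @param preference scalar or `"median"` as in [ap_config()].
#' @return list with `exemplars`, `labels`, `net_similarity`.
#' @export
exemplar_search <- function(similarity, preference = "median") {
  S <- as.matrix(similarity)
  n <- nrow(S)
  if (n > 20L) stop("exhaustive search limited to n <= 20", call. = FALSE)
  if (identical(preference, "median")) {
    preference <- stats::median(S[row(S) != col(S)])
  }
  diag(S) <- preference
  best <- NULL
  best_score <- -Inf
  for (m in seq_len(2^n - 1L)) {
    ex <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    owner <- vapply(seq_len(n), function(i) {
      if (i %in% ex) return(i)
      ex[which.max(S[i, ex])]
    }, integer(1))
    score <- sum(S[cbind(seq_len(n), owner)])
    if (score > best_score) {
      best_score <- score
      best <- list(exemplars = ex, labels = match(owner, ex), net_similarity = score)
    }
  }
  best
}

#' Exhaustive k-medoids oracle for small instances
#'
#' Enumerates all exemplar subsets of size `k` and maximizes the summed
#' member-to-exemplar similarity. Used as the independent oracle for the
#' AP partition at AP's own cluster count.
#'
#' @param similarity square similarity matrix (diagonal ignored).
#' @param k number of medoids.
#' @return list with `exemplars`, `labels`, `objective`.
#' @export
k_medoids_search <- function(similarity, k) {
  S <- as.matrix(similarity)
  n <- nrow(S)
  if (n > 20L) stop("exhaustive search limited to n <= 20", call. = FALSE)
  diag(S) <- 0
  best <- NULL
  best_score <- -Inf
  for (ex in utils::combn(n, k, simplify = FALSE)) {
    owner <- vapply(seq_len(n), function(i) {
      if (i %in% ex) return(i)
      ex[which.max(S[i, ex])]
    }, integer(1))
    score <- sum(S[cbind(seq_len(n), owner)])
    if (score > best_score) {
      best_score <- score
      best <- list(exemplars = ex, labels = match(owner, ex), objective = score)
    }
  }
  best
}
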