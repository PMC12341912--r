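# Cluster-based permutation inference over 1D time courses and 2D
# (train x test) grids, with sign-flip nulls, optional exact enumeration,
# and enclosed-hole filling for 2D masks.

# Label 4-connected components of a logical matrix by iterative minimum-label
# propagation (faces only; diagonal neighbors are not connected).
label_components_2d <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  repeat {
    shifted <- lab
    up <- rbind(lab[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, lab[-nrow(lab), , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    for (nb in list(up, dn, lf, rt)) {
      cand <- mask & nb > 0L & (lab == 0L | nb < lab)
      shifted[cand] <- nb[cand]
    }
    if (identical(shifted, lab)) break
    lab <- shifted
  }
  lab
}

# Clusters of a suprathreshold mask; returns a list of integer index vectors
# (into the flattened domain). 1D domains use run-length contiguity.
find_clusters <- function(mask, domain_dim) {
  if (length(domain_dim) == 1) {
    r <- rle(as.vector(mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    Map(function(s, e) s:e, starts[r$values], ends[r$values])
  } else {
    lab <- label_components_2d(matrix(mask, domain_dim[1], domain_dim[2]))
    ids <- setdiff(unique(as.vector(lab)), 0L)
    lapply(ids, function(i) which(as.vector(lab) == i))
  }
}

max_cluster_mass <- function(tv, tcrit, domain_dim, tail) {
  best <- 0
  if (tail %in% c("two.sided", "greater")) {
    for (cl in find_clusters(tv > tcrit, domain_dim)) best <- max(best, sum(tv[cl]))
  }
  if (tail %in% c("two.sided", "less")) {
    for (cl in find_clusters(tv < -tcrit, domain_dim)) best <- max(best, -sum(tv[cl]))
  }
  best
}

# Fill enclosed holes of a logical matrix: complement cells not reachable
# from the border (4-connectivity flood fill) are added to the mask.
fill_holes_2d <- function(mask) {
  comp <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- comp[1, ]; reach[nrow(mask), ] <- comp[nrow(mask), ]
  reach[, 1] <- reach[, 1] | comp[, 1]; reach[, ncol(mask)] <- reach[, ncol(mask)] | comp[, ncol(mask)]
  repeat {
    up <- rbind(reach[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, reach[-nrow(mask), , drop = FALSE])
    lf <- cbind(reach[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, reach[, -ncol(mask), drop = FALSE])
    new <- comp & (up | dn | lf | rt | reach)
    if (identical(new, reach)) break
    reach <- new
  }
  mask | (comp & !reach)
}

# t statistics for sign-flipped unit x point data, from precomputed sums.
# signs: n_perm x units; d: units x points. Zero-variance points yield
# non-finite t; the caller caps them.
t_matrix_from_signs <- function(signs, d) {
  n <- nrow(d)
  m <- (signs %*% d) / n
  ssq <- matrix(colSums(d^2), nrow(signs), ncol(d), byrow = TRUE)
  v <- (ssq - n * m^2) / (n - 1)
  v[v < 0] <- 0
  m / sqrt(v / n)
}

cap_nonfinite <- function(tv) {
  bad <- !is.finite(tv)
  if (any(bad)) {
    finite_max <- suppressWarnings(max(abs(tv[!bad])))
    if (!is.finite(finite_max)) finite_max <- 100
    tv[bad] <- sign(tv[bad]) * finite_max
    tv[is.na(tv)] <- 0
  }
  tv
}

#' Cluster-based permutation test
#'
#' Pointwise paired t statistics (condition a minus condition b, or a against
#' 0) are thresholded at the cluster-forming alpha; suprathreshold points
#' form contiguous (1D) or 4-connected (2D) clusters whose mass is the sum of
#' t values. The null distribution is the maximum cluster mass over random
#' within-unit sign flips of the paired differences (condition swaps), with
#' positive and negative cluster families compared against the common
#' max-|mass| null for two-sided tests. Exact enumeration of all sign
#' patterns replaces random sampling when there are at most 12 units. Units
#' (participants) are the exchangeable quantity; nothing is ever permuted
#' across units.
#'
#' @param cond_a units x points matrix (1D domain) or units x r x c array
#'   (2D domain).
#' @param cond_b matching array for the paired comparison, or NULL / 0 to
#'   test `cond_a` against zero.
#' @param n_perm number of random sign flips (ignored when enumerating).
#' @param cluster_alpha cluster-forming pointwise alpha (two-sided pointwise
#'   p < `cluster_alpha` paired t).
#' @param alpha cluster-level significance level.
#' @param tail "two.sided" (default), "greater" or "less".
#' @param fill_holes for 2D domains, add nonsignificant points fully enclosed
#'   by a significant cluster to the significance mask.
#' @param seed integer seed for the sign flips.
#' @return object of class `cluster_test`: `clusters` data.frame (mass,
#'   p, n_points), `members` list of flattened index vectors, `sig_mask`
#'   logical array over the domain, `t` the pointwise t map, `params`.
#' @export
cluster_permutation_test <- function(cond_a, cond_b = NULL, n_perm = 1000,
                                     cluster_alpha = 0.05, alpha = 0.05,
                                     tail = c("two.sided", "greater", "less"),
                                     fill_holes = FALSE, seed = 1) {
  tail <- match.arg(tail)
  a <- unclass(cond_a)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  domain_dim <- dim(a)[-1]
  n <- dim(a)[1]
  d <- a
  dim(d) <- c(n, prod(domain_dim))
  if (!is.null(cond_b) && !(length(cond_b) == 1 && cond_b == 0)) {
    b <- unclass(cond_b)
    if (!all(dim(b) == dim(a))) stopf("cluster_permutation_test: condition shapes differ")
    dim(b) <- c(n, prod(domain_dim))
    d <- d - b
  }
  if (n < 2) stopf("cluster_permutation_test: need >= 2 units")
  if (n_perm < 100) warnf("cluster_permutation_test: n_perm = %d is very low; p values will be coarse", n_perm)

  t_obs <- pointwise_t(d)
  if (any(!is.finite(t_obs))) {
    warnf("cluster_permutation_test: zero-variance points encountered; t capped at the largest finite |t|")
    t_obs <- cap_nonfinite(t_obs)
  }
  tcrit <- if (tail == "two.sided") qt(1 - cluster_alpha / 2, n - 1) else qt(1 - cluster_alpha, n - 1)

  members <- list()
  masses <- numeric(0)
  if (tail %in% c("two.sided", "greater")) {
    pos <- find_clusters(t_obs > tcrit, domain_dim)
    members <- c(members, pos)
    masses <- c(masses, vapply(pos, function(cl) sum(t_obs[cl]), numeric(1)))
  }
  if (tail %in% c("two.sided", "less")) {
    neg <- find_clusters(t_obs < -tcrit, domain_dim)
    members <- c(members, neg)
    masses <- c(masses, vapply(neg, function(cl) sum(t_obs[cl]), numeric(1)))
  }

  exact <- n <= 12
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  }
  tm <- cap_nonfinite(t_matrix_from_signs(signs, d))
  null_max <- vapply(seq_len(nrow(tm)), function(i) {
    max_cluster_mass(tm[i, ], tcrit, domain_dim, tail)
  }, numeric(1))

  pvals <- vapply(masses, function(m) {
    if (exact) mean(null_max >= abs(m)) else (1 + sum(null_max >= abs(m))) / (1 + nrow(signs))
  }, numeric(1))

  sig <- array(FALSE, dim = domain_dim)
  for (i in seq_along(members)) if (length(pvals) && pvals[i] <= alpha) sig[members[[i]]] <- TRUE
  filled <- sig
  if (fill_holes && length(domain_dim) == 2 && any(sig)) {
    filled <- fill_holes_2d(matrix(sig, domain_dim[1], domain_dim[2]))
  }
  ord <- order(pvals)
  structure(list(
    clusters = if (length(masses)) {
      data.frame(mass = masses, p = pvals,
                 n_points = vapply(members, length, integer(1)))[ord, , drop = FALSE]
    } else data.frame(mass = numeric(0), p = numeric(0), n_points = integer(0)),
    members = members[ord],
    sig_mask = filled,
    sig_mask_unfilled = sig,
    t = array(t_obs, dim = domain_dim),
    params = list(n_perm = if (exact) nrow(signs) else n_perm, exact = exact,
                  cluster_alpha = cluster_alpha, alpha = alpha, tail = tail,
                  fill_holes = fill_holes, seed = seed, n_units = n)
  ), class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d units, %s sign flips (%s), tail %s\n",
              x$params$n_units, x$params$n_perm,
              if (x$params$exact) "exact" else "sampled", x$params$tail))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Onset latency of a significant cluster
#'
#' @param test a `cluster_test` over a 1D time domain.
#' @param times latency vector matching the tested domain.
#' @param alpha significance level (defaults to the test's alpha).
#' @param cluster `"largest"` (default) reports the onset of the
#'   significant cluster with the largest |mass| — the cluster carrying the
#'   detected effect — so an isolated spurious blip elsewhere cannot
#'   masquerade as the effect's onset; `"any"` reports the earliest latency
#'   covered by any significant cluster.
#' @return onset latency (ms), or NA if no cluster is significant.
#' @export
cluster_onset <- function(test, times, alpha = test$params$alpha,
                          cluster = c("largest", "any")) {
  cluster <- match.arg(cluster)
  if (!nrow(test$clusters)) return(NA_real_)
  sig <- which(test$clusters$p <= alpha)
  if (!length(sig)) return(NA_real_)
  idx <- if (cluster == "any") {
    sort(unique(unlist(test$members[sig])))
  } else {
    test$members[[sig[which.max(abs(test$clusters$mass[sig]))]]]
  }
  times[min(idx)]
}
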