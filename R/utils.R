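# Internal numerical and RNG helpers shared across modules.

#' Run code with a temporary, seeded RNG state
#'
#' Evaluates `code` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded operations never disturb the global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a deterministic child seed from a master seed and a stream name
#'
#' Polynomial string hash folded into [0, 2^31 - 2] so that adding a stage
#' never shifts another stage's random stream.
#' @param seed master seed (integer).
#' @param ... character or integer stream identifiers (stage name, repetition).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(parts)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ledoit-Wolf style shrinkage covariance toward a scaled identity
#'
#' @param x matrix of observations (rows) x variables (columns); rows are
#'   assumed already centered (residuals).
#' @param shrinkage "auto" for the analytic intensity, or a number in [0, 1].
#' @return list with `sigma` (shrunk covariance), `lambda` (intensity used),
#'   `sample` (the raw sample covariance).
#' @export
shrink_cov <- function(x, shrinkage = "auto") {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2) stop("shrink_cov: need at least 2 observations")
  S <- crossprod(x) / n
  mu <- sum(diag(S)) / p
  if (identical(shrinkage, "auto")) {
    d2 <- sum((S - diag(mu, p))^2) / p
    # E||x_k x_k' - S||^2_F / n^2, using sum ||x_k||^4 = sum(rowSums(x^2)^2)
    b2 <- (sum(rowSums(x^2)^2) / n - sum(S^2)) / (n * p)
    b2 <- min(b2, d2)
    lambda <- if (d2 > 0) b2 / d2 else 1
    lambda <- min(1, max(0, lambda))
  } else {
    lambda <- as.numeric(shrinkage)
    if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
      stop("shrink_cov: shrinkage must be 'auto' or a number in [0, 1]")
    }
  }
  sigma <- (1 - lambda) * S
  diag(sigma) <- diag(sigma) + lambda * mu
  list(sigma = sigma, lambda = lambda, sample = S)
}

#' Symmetric inverse square root of a positive-definite matrix
#' @noRd
inv_sqrtm <- function(sigma, tol = 1e-12) {
  e <- eigen(sigma, symmetric = TRUE)
  vals <- e$values
  if (any(vals <= tol * max(vals, tol))) {
    stop("inv_sqrtm: matrix is not positive definite")
  }
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Pointwise paired/one-sample t statistics for a units x points matrix
#'
#' Zero-variance points get a t of +/-Inf which callers must handle
#' (the cluster engine caps them; see its documentation).
#' @noRd
pointwise_t <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  m / sqrt(v / n)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
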