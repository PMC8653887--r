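# Internal helpers shared across modules.

#' Derive a per-stage substream seed from a master seed
#'
#' Stochastic stages each receive their own deterministic substream so they
#' can be re-run independently of one another. The derivation is a fixed
#' integer hash of (seed, stage label), kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed for the stage.
#' @export
substreamSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- (seed %% 2147483647)
  for (k in codes) h <- (h * 31 + k) %% 2147483629
  as.integer(h %% 2147483647)
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Symmetric positive-definite solve via Cholesky with a small jitter
# fallback; fails loudly on badly conditioned matrices (rcond < 1e-12).
cholSolve <- function(A, b = NULL) {
  R <- tryCatch(chol(A), error = function(e) {
    jitter <- 1e-10 * mean(diag(A))
    chol(A + diag(jitter, nrow(A)))
  })
  rc <- (min(diag(R)) / max(diag(R)))^2
  if (!is.finite(rc) || rc < 1e-12) {
    stop("covariance matrix is numerically singular (rcond < 1e-12)")
  }
  if (is.null(b)) chol2inv(R) else backsolve(R, forwardsolve(t(R), b))
}

# log-determinant of an SPD matrix via Cholesky.
cholLogDet <- function(A) {
  2 * sum(log(diag(chol(A))))
}

# Coerce a DistanceMatrix-like input (dist or square matrix) to a validated
# square symmetric matrix with zero diagonal and labels.
asDistanceMatrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop(sprintf("'%s' must be a square matrix or 'dist' object", arg))
  }
  if (any(!is.finite(d))) stop(sprintf("'%s' contains non-finite values", arg))
  if (max(abs(d - t(d))) > 1e-8) stop(sprintf("'%s' is not symmetric", arg))
  if (max(abs(diag(d))) > 1e-8) stop(sprintf("'%s' has a nonzero diagonal", arg))
  if (min(d) < -1e-12) stop(sprintf("'%s' has negative entries", arg))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}

# Lower-triangle unfold in a fixed (column-major) order.
lowerTri <- function(m) m[lower.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
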