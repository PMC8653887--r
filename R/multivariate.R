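# Distance-based and factor-analytic statistics: Bray-Curtis, factor
# analysis with varimax rotation, ANOSIM, multiple regression on distance
# matrices (MRM), and 2D nonmetric multidimensional scaling.

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) on nonnegative abundance
#' vectors, bounded in [0, 1]. Computed on absolute amounts by default (the
#' convention for comparing sterol profiles weighted by content); set
#' \code{proportions = TRUE} to compare compositional shape only.
#'
#' @param x a \linkS4class{SterolExperiment} or species x compound matrix.
#' @param proportions logical; convert rows to proportions first.
#' @return a \code{dist} object over species.
#' @export
brayCurtis <- function(x, proportions = FALSE) {
  m <- .asSpeciesMatrix(x)
  if (proportions) m <- computeProportions(m)
  tot <- rowSums(m)
  zero <- which(tot == 0)
  if (length(zero) >= 2) {
    stop("Bray-Curtis undefined for pairs of all-zero profiles: ",
         paste(rownames(m)[zero], collapse = ", "))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    num <- colSums(abs(t(m[(i + 1):n, , drop = FALSE]) - xi))
    den <- tot[(i + 1):n] + tot[i]
    d[(i + 1):n, i] <- d[i, (i + 1):n] <- num / den
  }
  stats::as.dist(d)
}

#' Factor analysis of compound proportions
#'
#' Principal-component extraction: eigen-decomposition of the Pearson
#' correlation matrix of per-species compound proportions, retention of
#' factors with eigenvalue strictly above \code{cutoff}, and varimax
#' rotation (Kaiser-normalized) of the retained loadings. Proportion of
#' variance is eigenvalue / number of variables. Rotation preserves each
#' variable's communality.
#'
#' @param x species x compound proportions matrix (or SterolExperiment /
#'   amounts matrix, converted to proportions).
#' @param cutoff eigenvalue retention criterion (default 1).
#' @return list with \code{eigenvalues}, \code{retained}, \code{loadings}
#'   (rotated), \code{unrotated}, \code{proportion_variance},
#'   \code{communality}, \code{rotmat}.
#' @export
factorAnalysis <- function(x, cutoff = 1) {
  pr <- if (methods::is(x, "SterolExperiment")) sterolProportions(x) else as.matrix(x)
  if (is.null(colnames(pr))) colnames(pr) <- paste0("v", seq_len(ncol(pr)))
  v <- apply(pr, 2, stats::var)
  if (any(v == 0)) {
    stop("constant compounds (zero variance): ",
         paste(colnames(pr)[v == 0], collapse = ", "))
  }
  if (ncol(pr) < 2) stop("at least two variable compounds required")
  if (nrow(pr) <= ncol(pr)) {
    warning("fewer species than compounds; correlation matrix is rank-deficient")
  }
  R <- stats::cor(pr)
  ee <- eigen(R, symmetric = TRUE)
  vals <- ee$values
  k <- sum(vals > cutoff)
  L <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(L) <- colnames(pr)
  rot <- if (k >= 2) stats::varimax(L, normalize = TRUE) else list(loadings = L, rotmat = diag(k))
  Lr <- unclass(rot$loadings)
  list(eigenvalues = vals,
       retained = k,
       loadings = Lr,
       unrotated = L,
       proportion_variance = vals / ncol(pr),
       communality = rowSums(L^2),
       rotmat = rot$rotmat)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All n(n-1)/2 distances are ranked
#' (midranks for ties) and R = (mean between-group rank - mean within-group
#' rank) / (M/2), bounded in [-1, 1]. Significance from random permutations
#' of the group labels, one-sided on R >= observed, with the add-one
#' convention p = (1 + #{R_perm >= R_obs}) / (1 + nPerm).
#'
#' @param d distance matrix (\code{dist} or square matrix) over species.
#' @param groups group labels, one per species (names matched to labels of
#'   \code{d} when present). Groups smaller than \code{minGroupSize} are
#'   dropped with a message (singleton guilds carry no within-group
#'   information).
#' @param nPerm number of label permutations.
#' @param seed integer seed (mandatory; recorded in the result).
#' @param minGroupSize smallest group retained.
#' @return list with \code{statistic} (R), \code{p_value}, \code{n_perm},
#'   \code{seed}, \code{groups_used}, \code{n}.
#' @export
anosimTest <- function(d, groups, nPerm = 10000, seed, minGroupSize = 2) {
  if (missing(seed)) stop("a seed is required")
  dm <- asDistanceMatrix(d)
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[rownames(dm)]
  if (length(groups) != nrow(dm)) stop("groups must match the distance labels")
  tab <- table(groups)
  keep <- groups %in% names(tab)[tab >= minGroupSize]
  if (sum(!keep)) {
    message("dropping groups below minimum size: ",
            paste(setdiff(names(tab), names(tab)[tab >= minGroupSize]),
                  collapse = ", "))
    dm <- dm[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least two groups of size >= 2")
  n <- nrow(dm)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(lowerTri(dm))  # midranks
  rk <- rk + t(rk)
  M <- n * (n - 1) / 2
  statR <- function(g) {
    same <- outer(g, g, "==")
    within <- mean(rk[lower.tri(rk)][same[lower.tri(same)]])
    between <- mean(rk[lower.tri(rk)][!same[lower.tri(same)]])
    (between - within) / (M / 2)
  }
  obs <- statR(groups)
  perm <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) statR(sample(groups)), numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (1 + nPerm)
  list(statistic = obs, p_value = p, n_perm = nPerm, seed = seed,
       groups_used = sort(unique(groups)), n = n)
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the unfolded lower triangle of a response
#' distance matrix on those of one or more predictor matrices (additive
#' linear model with intercept). Significance by simultaneously permuting
#' the rows and columns of the response matrix and recomputing: p-values
#' are two-sided on coefficients (|b_perm| >= |b_obs|) and one-sided on r^2,
#' both with the add-one convention.
#'
#' @param response distance matrix (dist or square matrix).
#' @param predictors named list of distance matrices sharing the response's
#'   labels and order.
#' @param nPerm number of matrix permutations.
#' @param seed integer seed.
#' @return list with \code{coefficients}, \code{p_coef}, \code{r_squared},
#'   \code{p_r2}, \code{n_perm}, \code{seed}.
#' @export
mrmTest <- function(response, predictors, nPerm = 10000, seed) {
  if (missing(seed)) stop("a seed is required")
  if (!is.list(predictors)) predictors <- list(predictor = predictors)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("X", seq_along(predictors))
  }
  R <- asDistanceMatrix(response, "response")
  Xs <- lapply(predictors, asDistanceMatrix, arg = "predictor")
  n <- nrow(R)
  for (Xi in Xs) {
    if (nrow(Xi) != n) stop("all matrices must share the species set")
  }
  y <- lowerTri(R)
  X <- cbind(`(Intercept)` = 1, vapply(Xs, lowerTri, numeric(length(y))))
  sv <- svd(X)$d
  if (min(sv) == 0 || max(sv) / min(sv) > 1e10) {
    stop(sprintf("collinear predictors (condition number %.3g)",
                 max(sv) / max(min(sv), .Machine$double.xmin)))
  }
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  H <- solve(crossprod(X), t(X))  # coef = H y, reused across permutations
  lt <- lower.tri(R)
  sst <- sum((y - mean(y))^2)
  hat <- X %*% H
  perm <- withSeed(seed, {
    out <- matrix(NA_real_, nPerm, length(b) + 1)
    for (i in seq_len(nPerm)) {
      pi <- sample.int(n)
      yp <- R[pi, pi][lt]
      bp <- drop(H %*% yp)
      rp <- 1 - sum((yp - drop(hat %*% yp))^2) / sum((yp - mean(yp))^2)
      out[i, ] <- c(bp, rp)
    }
    out
  })
  pCoef <- vapply(seq_along(b), function(j) {
    (1 + sum(abs(perm[, j]) >= abs(b[j]))) / (1 + nPerm)
  }, numeric(1))
  names(pCoef) <- names(b)
  pR2 <- (1 + sum(perm[, length(b) + 1] >= r2)) / (1 + nPerm)
  list(coefficients = b, p_coef = pCoef, r_squared = r2, p_r2 = pR2,
       n_perm = nPerm, seed = seed)
}

# Pool-adjacent-violators: least-squares monotone nondecreasing fit.
.pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  ghat <- y
  wt <- w
  # block representation
  val <- y; wts <- w; len <- rep(1L, n); nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wts[nb] <- w[i]; len[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      wsum <- wts[nb - 1L] + wts[nb]
      val[nb - 1L] <- (wts[nb - 1L] * val[nb - 1L] + wts[nb] * val[nb]) / wsum
      wts[nb - 1L] <- wsum
      len[nb - 1L] <- len[nb - 1L] + len[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], len[seq_len(nb)])
}

#' 2D nonmetric multidimensional scaling
#'
#' Minimizes Kruskal stress-1,
#' sqrt(sum((dhat - disparity)^2) / sum(dhat^2)), by alternating monotone
#' (isotonic, pool-adjacent-violators) regression of configuration
#' distances on the rank order of the dissimilarities with Guttman-transform
#' configuration updates. Ties in the dissimilarities are handled by
#' Kruskal's primary approach (untied within tie blocks). The first start is
#' initialized from classical metric scaling, the rest at random; the
#' lowest-stress solution is returned. Stress is non-increasing within a
#' start (iteration stops if an update fails to improve).
#'
#' @param d distance matrix (dist or square matrix), n >= 4.
#' @param nStarts number of starts (first is classical-scaling seeded).
#' @param maxIter iteration cap per start.
#' @param tol relative stress-change convergence tolerance.
#' @param seed integer seed for the random starts.
#' @return list with \code{points} (n x 2, centered), \code{stress},
#'   \code{iterations}, \code{start}, \code{seed}.
#' @export
nmds2d <- function(d, nStarts = 8, maxIter = 500, tol = 1e-8, seed = 1) {
  dm <- asDistanceMatrix(d)
  n <- nrow(dm)
  if (n < 4) stop("NMDS needs at least 4 objects")
  dv <- lowerTri(dm)
  if (any(!is.finite(dv))) stop("non-finite distances")
  lt <- lower.tri(dm)
  runStart <- function(X) {
    prevStress <- Inf
    best <- list(X = X, stress = Inf)
    iters <- 0L
    for (it in seq_len(maxIter)) {
      iters <- it
      Dhat <- as.matrix(stats::dist(X))
      dh <- Dhat[lt]
      ord <- order(dv, dh)  # primary tie approach: within ties, order by dh
      disp <- numeric(length(dh))
      disp[ord] <- .pava(dh[ord])
      num <- sum((dh - disp)^2)
      den <- sum(dh^2)
      stress <- if (den > 0) sqrt(num / den) else 0
      if (stress < best$stress) best <- list(X = X, stress = stress)
      if (!is.finite(stress) || stress > prevStress + 1e-15) break
      if (stress < 1e-12 || abs(prevStress - stress) <= tol * max(prevStress, 1e-300)) break
      prevStress <- stress
      # Guttman transform with disparities
      Dm <- matrix(0, n, n)
      Dm[lt] <- disp
      Dm <- Dm + t(Dm)
      W <- ifelse(Dhat > 0, Dm / Dhat, 0)
      B <- -W
      diag(B) <- rowSums(W)
      X <- (B %*% X) / n
      X <- sweep(X, 2, colMeans(X))
    }
    list(X = best$X, stress = best$stress, iterations = iters)
  }
  inits <- withSeed(seed, {
    lapply(seq_len(nStarts), function(s) {
      if (s == 1) {
        X0 <- suppressWarnings(stats::cmdscale(dm, k = 2))
        if (ncol(X0) < 2) X0 <- cbind(X0, 0)
        X0 + matrix(stats::rnorm(n * 2, sd = 1e-8), n, 2)
      } else {
        matrix(stats::rnorm(n * 2), n, 2)
      }
    })
  })
  runs <- lapply(inits, runStart)
  stresses <- vapply(runs, `[[`, numeric(1), "stress")
  k <- which.min(stresses)
  X <- runs[[k]]$X
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- rownames(dm)
  colnames(X) <- c("NMDS1", "NMDS2")
  list(points = X, stress = runs[[k]]$stress,
       iterations = runs[[k]]$iterations, start = k, seed = seed)
}
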