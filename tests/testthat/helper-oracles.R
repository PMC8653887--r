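# Independent oracles used across the suite. These deliberately use a
# different route than the package implementation they check.

# GLS slope of y on x with intercept, under covariance C, by direct matrix
# inversion (the matrix dual of contrast regression through the origin).
glsSlope <- function(y, x, C) {
  Ci <- solve(C)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  beta[2]
}

# Convex-hull volume of a 3D cloud by brute-force facet enumeration:
# a triple is a hull facet iff all remaining points lie on one side of its
# plane; volume by summing signed tetrahedra against the centroid.
# O(n^4) but exact for small general-position clouds.
bruteHullVolume <- function(P) {
  n <- nrow(P)
  ctr <- colMeans(P)
  vol <- 0
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; cc <- P[tri[3], ]
    u <- b - a; v <- cc - a
    nv <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    s <- sign(round((P[-tri, , drop = FALSE] -
                       matrix(a, n - 3, 3, byrow = TRUE)) %*% nv, 12))
    if (all(s <= 0) || all(s >= 0)) {
      vol <- vol + abs(det(rbind(a - ctr, b - ctr, cc - ctr))) / 6
    }
  }
  vol
}

# Direct-formula Shannon equitability, written independently of the package.
directShannon <- function(p) {
  p <- p[p > 0]
  if (length(p) <= 1) return(0)
  -sum(p * log(p)) / log(length(p))
}

# 95% acceptance band (as rates) for a rejection count ~ Binomial(n, 0.05).
binomBand <- function(n, alpha = 0.05) {
  c(qbinom(0.025, n, alpha), qbinom(0.975, n, alpha)) / n
}

# A small random ultrametric test tree with a fixed seed.
testTree <- function(n, seed) simYuleTree(n, birthRate = 1, seed = seed)
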