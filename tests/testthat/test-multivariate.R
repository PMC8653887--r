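test_that("Bray-Curtis matches its formula, bounds and vegan", {
  m <- rbind(s1 = c(1, 2, 0), s2 = c(0, 2, 2), s3 = c(1, 2, 0))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["s1", "s2"], 3 / 7)
  expect_equal(d["s1", "s3"], 0)
  disj <- rbind(a = c(1, 2, 0, 0), b = c(0, 0, 3, 1))
  expect_equal(as.numeric(brayCurtis(disj)), 1)
  skip_if_not_installed("vegan")
  set.seed(3)
  x <- matrix(rexp(20 * 6), 20, 6, dimnames = list(paste0("s", 1:20), NULL))
  expect_equal(as.matrix(brayCurtis(x)),
               as.matrix(vegan::vegdist(x, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Bray-Curtis ignores all-zero compounds and rejects all-zero pairs", {
  set.seed(4)
  x <- matrix(rexp(24), 6, 4)
  xPad <- cbind(x, 0, 0)
  expect_equal(as.matrix(brayCurtis(x)), as.matrix(brayCurtis(xPad)),
               ignore_attr = TRUE)
  bad <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_error(brayCurtis(bad), "all-zero")
})

test_that("factor analysis extracts correlation-matrix eigenstructure", {
  # block correlation [[1,1,0],[1,1,0],[0,0,1]]: eigenvalues (2,1,0),
  # one factor retained under the strict > 1 criterion
  set.seed(1)
  z <- rnorm(4000)
  x <- cbind(a = z, b = z, c = rnorm(4000))
  fa <- factorAnalysis(x)
  expect_equal(fa$eigenvalues, c(2, 1, 0), tolerance = 0.06)
  expect_equal(fa$retained, 1)
  expect_equal(sum(fa$eigenvalues), 3, tolerance = 1e-6)
  expect_equal(fa$proportion_variance, fa$eigenvalues / 3)
  expect_error(factorAnalysis(cbind(x, k = rep(1, 4000))), "k")
})

test_that("varimax rotation preserves communalities and total variance", {
  tr <- testTree(40, seed = 9)
  sim <- simProfiles(tr, nCompounds = 10, seed = 10)
  fa <- factorAnalysis(sim$experiment)
  expect_gte(fa$retained, 2)
  expect_equal(rowSums(fa$loadings^2), rowSums(fa$unrotated^2),
               tolerance = 1e-8)
  expect_equal(sum(fa$loadings^2), sum(fa$unrotated^2), tolerance = 1e-8)
})

test_that("ANOSIM reproduces hand-ranked fixtures and vegan", {
  fx <- canonicalFixtures()
  r1 <- anosimTest(fx$anosimR1$d, fx$anosimR1$groups, nPerm = 99, seed = 1)
  expect_identical(r1$statistic, 1)
  r0 <- anosimTest(fx$anosimR0$d, fx$anosimR0$groups, nPerm = 99, seed = 1)
  expect_identical(r0$statistic, 0)
  skip_if_not_installed("vegan")
  set.seed(5)
  x <- matrix(rexp(18 * 5), 18, 5, dimnames = list(paste0("s", 1:18), NULL))
  g <- rep(c("A", "B", "C"), each = 6)
  d <- brayCurtis(x)
  mine <- anosimTest(d, g, nPerm = 199, seed = 7)
  ref <- vegan::anosim(stats::as.dist(as.matrix(d)), g, permutations = 199)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM R is bounded, zero on tied distances, and drops singletons", {
  set.seed(6)
  for (i in 1:10) {
    x <- matrix(rexp(12 * 4), 12, 4)
    g <- sample(rep(c("A", "B"), each = 6))
    r <- anosimTest(dist(x), g, nPerm = 19, seed = i)
    expect_gte(r$statistic, -1)
    expect_lte(r$statistic, 1)
  }
  dTie <- matrix(1, 6, 6) - diag(6)
  rownames(dTie) <- colnames(dTie) <- paste0("s", 1:6)
  rt <- anosimTest(dTie, rep(c("A", "B"), each = 3), nPerm = 19, seed = 1)
  expect_equal(rt$statistic, 0)
  g2 <- c(rep("A", 3), rep("B", 2), "wind")
  expect_message(
    rs <- anosimTest(dTie, g2, nPerm = 19, seed = 1, minGroupSize = 2),
    "wind")
  expect_equal(rs$n, 5)
  expect_error(anosimTest(dTie, rep("A", 6), nPerm = 19, seed = 1),
               "two groups")
})

test_that("MRM recovers constructed linear systems on distance matrices", {
  set.seed(8)
  D1 <- as.matrix(dist(rnorm(12)))
  m1 <- mrmTest(3 * D1, list(x = D1), nPerm = 99, seed = 2)
  expect_equal(unname(m1$coefficients["x"]), 3, tolerance = 1e-10)
  expect_equal(m1$r_squared, 1, tolerance = 1e-10)
  D2 <- as.matrix(dist(rnorm(12)))
  resp <- 2 * D1 - 1 * D2
  # a valid dissimilarity is not guaranteed for a difference; shift the
  # off-diagonal to keep it nonnegative without changing the coefficients
  resp <- resp + (abs(min(resp)) + 1) * (1 - diag(12))
  m2 <- mrmTest(resp, list(a = D1, b = D2), nPerm = 99, seed = 2)
  expect_equal(unname(m2$coefficients[c("a", "b")]), c(2, -1),
               tolerance = 1e-10)
  expect_error(mrmTest(D1, list(a = D2, b = 2 * D2), nPerm = 9, seed = 1),
               "condition")
})

test_that("single-predictor MRM equals the simple Mantel regression", {
  set.seed(9)
  for (i in 1:5) {
    D1 <- as.matrix(dist(rnorm(10)))
    DY <- as.matrix(dist(rnorm(10)))
    mine <- mrmTest(DY, list(x = D1), nPerm = 19, seed = i)
    ref <- lm(DY[lower.tri(DY)] ~ D1[lower.tri(D1)])
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-10)
    expect_equal(mine$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("NMDS finds exact embeddings and beats a naive single start", {
  set.seed(10)
  X <- matrix(rnorm(20), 10, 2)
  fit <- nmds2d(dist(X), seed = 4)
  expect_lt(fit$stress, 1e-6)
  # four collinear points embed exactly in the plane
  dLine <- dist(cbind(c(0, 1, 2, 4), 0))
  expect_lt(nmds2d(dLine, seed = 4)$stress, 1e-8)
  expect_error(nmds2d(dist(cbind(1:3))), "at least 4")
})

test_that("NMDS multi-start stress is near the exhaustive-start oracle", {
  set.seed(12)
  x <- matrix(rexp(10 * 5), 10, 5)
  d <- brayCurtis(x)
  fit <- nmds2d(d, nStarts = 8, seed = 3)
  oracle <- nmds2d(d, nStarts = 50, seed = 999)
  expect_lte(fit$stress, oracle$stress + 0.01)
  # stress is scale-free and reproducible under the same seed
  fit2 <- nmds2d(d, nStarts = 8, seed = 3)
  expect_identical(fit$stress, fit2$stress)
})
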