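test_that("newick reading validates labels and polytomy resolution counts nodes", {
  tr <- readNewickTree(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_error(readNewickTree(text = "((A,A),B);"), "duplicate")
  # already binary: unchanged topology
  expect_equal(resolvePolytomies(tr, seed = 1)$Nnode, tr$Nnode)
  tri <- readNewickTree(text = "(A:1,B:1,C:1,D:1);")  # 4-tip star
  res <- resolvePolytomies(tri, seed = 1)
  expect_true(ape::is.binary(res))
  expect_equal(res$Nnode, 3)  # two inserted nodes
  expect_equal(sum(res$edge.length == 0), 2)  # inserted branches length 0
  # one trichotomy: one new zero-length internal branch
  tri3 <- readNewickTree(text = "((A:1,B:1,C:1):1,D:2);")
  res3 <- resolvePolytomies(tri3, seed = 2)
  expect_equal(res3$Nnode, tri3$Nnode + 1)
  expect_identical(ape::write.tree(resolvePolytomies(tri, seed = 7)),
                   ape::write.tree(resolvePolytomies(tri, seed = 7)))
})

test_that("Grafen lengths give the hand-derived heights and are ultrametric", {
  tr <- grafenLengths(readNewickTree(text = "((A,B),C);"))
  # root height 1, cherry 0.5: branches cherry tips 0.5, root->cherry 0.5,
  # root->C 1
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(1, 3))
  expect_equal(sort(tr$edge.length), c(0.5, 0.5, 0.5, 1))
  for (rho in c(0.3, 1, 2.5)) {
    big <- grafenLengths(testTree(25, seed = 3), rho = rho)
    dep <- ape::node.depth.edgelength(big)[1:25]
    expect_lt(max(dep) - min(dep), 1e-10)
  }
  skip_if_not_installed("ape")
  ref <- ape::compute.brlen(testTree(12, seed = 4), method = "Grafen")
  mine <- grafenLengths(testTree(12, seed = 4))
  expect_equal(mine$edge.length, ref$edge.length, tolerance = 1e-12)
})

test_that("Brownian covariance matches hand fixtures, vcv, and the patristic identity", {
  two <- readNewickTree(text = "(A:1,B:1);")
  expect_equal(unname(bmCov(two)$C), diag(2))
  bal <- readNewickTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  C <- bmCov(bal)$C
  expect_equal(unname(C[1:2, 1:2]), matrix(c(2, 1, 1, 2), 2))
  expect_equal(unname(C[1:2, 3:4]), matrix(0, 2, 2))
  star <- ape::stree(5, "star")
  star$edge.length <- rep(2, 5)
  expect_equal(unname(bmCov(star)$C), 2 * diag(5))
  tr <- testTree(30, seed = 8)
  bc <- bmCov(tr)
  expect_equal(bc$C, ape::vcv(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-12)
  expect_equal(bc$patristic,
               outer(diag(bc$C), diag(bc$C), "+") - 2 * bc$C)
  expect_equal(max(abs(bc$patristic - t(bc$patristic))), 0)
  bad <- tr; bad$edge.length[1] <- -0.1
  expect_error(bmCov(bad), "negative")
})

test_that("Pagel's lambda agrees with an independent ML implementation", {
  skip_if_not_installed("phytools")
  tr <- testTree(60, seed = 21)
  for (lam in c(0.2, 0.9)) {
    z <- simBMTraits(tr, sigma2 = 1, lambdaTrue = lam, seed = 100 + lam * 10)
    mine <- pagelLambda(z, bmCov(tr))
    ref <- phytools::phylosig(tr, z, method = "lambda")
    if (ref$lambda <= 1) {  # the package caps the search at 1 by design
      expect_equal(mine$lambda, ref$lambda, tolerance = 1e-3)
      expect_equal(mine$logLik, ref$logL, tolerance = 1e-5)
    } else {
      expect_equal(mine$lambda, 1, tolerance = 1e-6)
    }
  }
})

test_that("lambda is flagged unidentifiable on star trees and bounded otherwise", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, 8)
  z <- stats::setNames(rnorm(8), star$tip.label)
  fit <- pagelLambda(z, bmCov(star))
  expect_false(fit$identifiable)
  expect_true(is.na(fit$lambda))
  tr <- testTree(20, seed = 22)
  z2 <- simBMTraits(tr, seed = 23)
  fit2 <- pagelLambda(z2, bmCov(tr))
  expect_gte(fit2$lambda, 0)
  expect_lte(fit2$lambda, 1)
  expect_error(pagelLambda(rep(1, 20), bmCov(tr)), "constant")
  # the lambda = 1 transform is the identity on C (generic-path check)
  C <- bmCov(tr)$C
  V <- 1 * C; diag(V) <- diag(C)
  expect_identical(V, C)
})

test_that("lambda randomization test is seed-reproducible and near-null on shuffled data", {
  tr <- testTree(40, seed = 31)
  z <- simBMTraits(tr, sigma2 = 1, lambdaTrue = 1, seed = 32)
  f1 <- pagelLambda(z, bmCov(tr), nPerm = 49, seed = 5)
  f2 <- pagelLambda(z, bmCov(tr), nPerm = 49, seed = 5)
  expect_identical(f1$p_perm, f2$p_perm)
  expect_lt(f1$p_perm, 0.05)  # strong planted signal
})

test_that("Blomberg's K matches hand algebra and an independent implementation", {
  fx <- canonicalFixtures()
  k <- blombergK(fx$balanced4$trait, bmCov(fx$balanced4$tree), nPerm = 0)
  expect_equal(k$K, 1.8, tolerance = 1e-12)
  star <- ape::stree(7, "star")
  star$edge.length <- rep(1.5, 7)
  z <- stats::setNames(rnorm(7), star$tip.label)
  expect_equal(blombergK(z, bmCov(star), nPerm = 0)$K, 1, tolerance = 1e-12)
  # affine invariance
  tr <- testTree(25, seed = 41)
  z2 <- simBMTraits(tr, seed = 42)
  k0 <- blombergK(z2, bmCov(tr), nPerm = 0)$K
  expect_equal(blombergK(-3 * z2 + 7, bmCov(tr), nPerm = 0)$K, k0,
               tolerance = 1e-10)
  skip_if_not_installed("phytools")
  expect_equal(k0, as.numeric(phytools::phylosig(tr, z2, method = "K")),
               tolerance = 1e-8)
})

test_that("independent contrasts match Felsenstein pruning by hand and ape", {
  two <- readNewickTree(text = "(A:1,B:1);")
  u <- picContrasts(c(A = 3, B = 1), two)
  expect_equal(unname(u$contrasts), sqrt(2))
  tr <- testTree(30, seed = 51)
  zc <- stats::setNames(rep(4.2, 30), tr$tip.label)
  expect_equal(max(abs(picContrasts(zc, tr)$contrasts)), 0)
  z <- simBMTraits(tr, seed = 52)
  mine <- picContrasts(z, tr)
  ref <- ape::pic(z[tr$tip.label], tr)
  expect_equal(abs(mine$contrasts[names(ref)]), abs(ref), tolerance = 1e-10)
  poly <- readNewickTree(text = "((A:1,B:1,C:1):1,D:2);")
  expect_error(picContrasts(c(A = 1, B = 2, C = 3, D = 4), poly), "polytom")
})

test_that("contrast variance estimates the simulating Brownian rate", {
  tr <- testTree(50, seed = 61)
  sims <- simBMTraits(tr, sigma2 = 2.5, seed = 62, nTraits = 400)
  s2 <- apply(sims, 2, function(z) {
    picContrasts(stats::setNames(z, rownames(sims)), tr)$sigma2_hat
  })
  expect_lt(abs(mean(s2) / 2.5 - 1), 0.05)  # relative bias under 5%
})

test_that("contrast regression through the origin matches lm and handles edge cases", {
  x <- c(1, -2, 3, 0.5)
  y <- 2 * x
  fit <- picRegression(y, x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  yo <- c(1, 0.5, 0, -1)
  xo <- c(0, 0, 1, 0)  # sum(xy) = 0
  expect_equal(picRegression(yo, xo)$slope, 0)
  expect_equal(picRegression(yo, xo)$r_squared, 0)
  set.seed(71)
  xr <- rnorm(12); yr <- 1.3 * xr + rnorm(12, sd = 0.4)
  mine <- picRegression(yr, xr)
  ref <- summary(lm(yr ~ xr - 1))
  expect_equal(mine$slope, unname(coef(ref)[1, 1]), tolerance = 1e-12)
  expect_equal(mine$p_value, unname(coef(ref)[1, 4]), tolerance = 1e-12)
  expect_error(picRegression(yr, rep(0, 12)), "all-zero")
})

test_that("phylogenetic ANOVA reproduces the hand-computed F and its symmetries", {
  tr <- readNewickTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  z <- c(A = 1, B = 2, C = 4, D = 5)
  g <- c(A = "g1", B = "g1", C = "g2", D = "g2")
  fit <- phyloAnova(z, g, tr, nSim = 99, seed = 3)
  expect_equal(fit$F, 18)  # SSB 9, SSW 1, df 1 and 2
  # relabelling the groups leaves F unchanged
  g2 <- c(A = "x", B = "x", C = "y", D = "y")
  expect_equal(phyloAnova(z, g2, tr, nSim = 99, seed = 3)$F, 18)
  expect_error(phyloAnova(z, c(A = "a", B = "b", C = "b", D = "b"), tr,
                          nSim = 9, seed = 1), "singleton")
  fit2 <- phyloAnova(z, g, tr, nSim = 99, seed = 3)
  expect_identical(fit$p_phyl, fit2$p_phyl)
  expect_true(all(fit$pairwise$p_holm >= fit$pairwise$p))
})

test_that("phylogenetic ANOVA null F matches the F distribution on a star tree", {
  # on a star tree the Brownian null is i.i.d. normal, so simulated F must
  # follow F(k-1, n-k)
  star <- ape::stree(16, "star")
  star$edge.length <- rep(1, 16)
  g <- rep(c("a", "b"), each = 8)
  names(g) <- star$tip.label
  C <- chol(bmCov(star)$C)
  set.seed(81)
  Fs <- replicate(2000, {
    z <- stats::setNames(crossprod(C, rnorm(16))[, 1], star$tip.label)
    m <- tapply(z, g, mean)
    ssb <- 8 * sum((m - mean(z))^2)
    ssw <- sum((z - m[g])^2)
    (ssb / 1) / (ssw / 14)
  })
  ks <- suppressWarnings(ks.test(Fs, pf, df1 = 1, df2 = 14))
  expect_gt(ks$p.value, 0.001)
})
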