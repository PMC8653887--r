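test_that("proportions divide amounts by species totals", {
  cases <- list(
    list(amounts = c(2, 2, 0), expected = c(0.5, 0.5, 0)),
    list(amounts = c(1, 0, 0), expected = c(1, 0, 0)),
    list(amounts = c(1, 2, 1), expected = c(0.25, 0.5, 0.25)))
  for (cs in cases) {
    p <- computeProportions(matrix(cs$amounts, nrow = 1))
    expect_equal(as.numeric(p), cs$expected)
  }
  m <- rbind(a = c(1, 1), b = c(0, 0), c = c(2, 3))
  expect_error(computeProportions(m), "b")
})

test_that("Shannon equitability matches the direct formula and its limits", {
  expect_identical(shannonEquitability(c(1, 0, 0)), 0)
  for (S in 2:6) {
    expect_equal(shannonEquitability(rep(1 / S, S)), 1)
  }
  expect_equal(shannonEquitability(c(0.7, 0.2, 0.1)), 0.7299, tolerance = 1e-4)
  set.seed(41)
  for (i in 1:25) {
    p <- rexp(sample(2:12, 1))
    p <- p / sum(p)
    expect_equal(shannonEquitability(p), directShannon(p), tolerance = 1e-12)
  }
  expect_error(shannonEquitability(numeric(0)), "empty")
  expect_error(shannonEquitability(c(0.5, 0.2)), "sum")
})

test_that("H is invariant to rescaling and increases when mass is split evenly", {
  set.seed(42)
  for (i in 1:10) {
    amounts <- rexp(8)
    p <- amounts / sum(amounts)
    for (k in c(0.01, 3, 1000)) {
      expect_equal(shannonEquitability((k * amounts) / sum(k * amounts)),
                   shannonEquitability(p), tolerance = 1e-12)
    }
    # split the dominant compound evenly over the whole support, including
    # previously absent compounds: equitability must strictly increase
    pAbsent <- c(p, 0, 0)
    j <- which.max(pAbsent)
    split <- rep(pAbsent[j] / length(pAbsent), length(pAbsent))
    pSplit <- pAbsent
    pSplit[j] <- 0
    pSplit <- pSplit + split
    expect_gt(shannonEquitability(pSplit), shannonEquitability(pAbsent))
  }
})

test_that("a fixed global richness base is available as an option", {
  p <- c(0.5, 0.5, 0)
  expect_equal(shannonEquitability(p), 1)
  expect_equal(shannonEquitability(p, globalS = 25), log(2) / log(25))
})

test_that("commonness counts species above the detection threshold", {
  m <- rbind(s1 = c(1, 1, 0.05), s2 = c(2, 0, 0.2),
             s3 = c(3, 0, 0.0), s4 = c(4, 0, 0.3))
  expect_equal(unname(commonness(m)), c(1, 0.25, 0.75))
  expect_equal(unname(commonness(m, threshold = 0.1)), c(1, 0.25, 0.5))
})

test_that("relative abundance averages per-species proportions and sums to 1", {
  m <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  expect_equal(unname(relativeAbundance(m)), c(0.5, 0.5))
  m2 <- rbind(s1 = c(0.2, 0.8), s2 = c(0.6, 0.4))
  expect_equal(unname(relativeAbundance(m2)), c(0.4, 0.6))
  set.seed(7)
  m3 <- matrix(rexp(60), 10, 6)
  expect_equal(sum(relativeAbundance(m3)), 1, tolerance = 1e-9)
})

test_that("commonness and relative abundance are species-order equivariant", {
  set.seed(11)
  m <- matrix(rexp(48), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("c", 1:6)))
  perm <- sample(8)
  expect_equal(commonness(m), commonness(m[perm, ]))
  expect_equal(relativeAbundance(m), relativeAbundance(m[perm, ]))
})

test_that("group sums partition proportions by biosynthetic class", {
  m <- rbind(sp1 = c(0.5, 0.3, 0.2), sp2 = c(1, 1, 2))
  colnames(m) <- c("cA", "cB", "cC")
  meta <- data.frame(compound = c("cA", "cB", "cC"),
                     delta_class = c("D5", "D5", "D7"),
                     c24_class = c("C0", "C1", "C2"))
  gs <- groupSums(m, meta)
  expect_equal(unname(unlist(gs["sp1", c("C0", "C1", "C2")])), c(0.5, 0.3, 0.2))
  expect_equal(rowSums(gs[, c("C0", "C1", "C2")]), c(sp1 = 1, sp2 = 1),
               tolerance = 1e-9)
  expect_equal(rowSums(gs[, c("D0", "D5", "D7", "D8")]), c(sp1 = 1, sp2 = 1),
               tolerance = 1e-9)
  # single-class profiles concentrate the full mass
  metaC1 <- data.frame(compound = colnames(m),
                       delta_class = "D5", c24_class = "C1")
  gs2 <- groupSums(m, metaC1)
  expect_equal(unname(gs2$C1), c(1, 1))
  expect_equal(unname(gs2$C0 + gs2$C2), c(0, 0))
  expect_equal(unname(gs2$D5), c(1, 1))
  metaBad <- meta[1:2, ]
  expect_error(groupSums(m, metaBad), "cC")
})

test_that("total content is the row sum, with an optional log transform", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(0.5, 0.25, 0))
  expect_equal(unname(totalContent(m)), c(6, 0.75))
  expect_equal(unname(totalContent(m, log = TRUE)), log(c(6, 0.75)))
  m0 <- rbind(s1 = c(1, 1), s2 = c(0, 0))
  expect_warning(tc <- totalContent(m0), "s2")
  expect_equal(unname(tc), c(2, 0))
})

test_that("richness statistics use the sample standard deviation", {
  m <- rbind(s1 = c(1, 2, 0, 0), s2 = c(1, 2, 3, 4))
  rs <- richnessStats(m)
  expect_equal(rs$mean, 3)
  expect_equal(rs$sd, sqrt(2))
  mk <- rbind(s1 = c(1, 1, 0), s2 = c(2, 0, 2), s3 = c(0, 3, 3))
  rsk <- richnessStats(mk)
  expect_equal(rsk$mean, 2)
  expect_equal(rsk$sd, 0)
})

test_that("the SterolExperiment container validates and summarizes", {
  m <- rbind(spA = c(1, 2, 1), spB = c(0, 2, 2))
  colnames(m) <- c("cholesterol", "sitosterol", "campesterol")
  meta <- data.frame(compound = colnames(m),
                     delta_class = c("D5", "D5", "D7"),
                     c24_class = c("C0", "C2", "C1"))
  se <- SterolExperiment(m, compoundData = meta, speciesAsRows = TRUE)
  expect_s4_class(se, "SterolExperiment")
  expect_equal(unname(sterolTotals(se)), c(4, 4))
  expect_equal(colSums(t(sterolProportions(se))), c(spA = 1, spB = 1))
  expect_equal(nrow(compoundClasses(se)), 3)
  expect_output(show(se), "2 species")
  mBad <- m; mBad[1, ] <- 0
  expect_error(SterolExperiment(mBad, speciesAsRows = TRUE), "spA")
  expect_error(SterolExperiment(-m, speciesAsRows = TRUE), "nonnegative")
  # replicate averaging on load
  m2 <- rbind(sp = c(1, 0, 1), sp = c(3, 0, 1), spB = c(0, 2, 2))
  colnames(m2) <- colnames(m)
  se2 <- SterolExperiment(m2, speciesAsRows = TRUE, averageReplicates = TRUE)
  expect_equal(unname(sterolAmounts(se2)[, "sp"]), c(2, 0, 1))
})

test_that("profileSummary assembles per-species and per-compound tables", {
  tr <- testTree(12, seed = 5)
  sim <- simProfiles(tr, nCompounds = 8, seed = 6)
  ps <- profileSummary(sim$experiment)
  expect_equal(nrow(ps$species), 12)
  expect_equal(nrow(ps$compounds), 8)
  expect_equal(sum(ps$compounds$relative_abundance), 1, tolerance = 1e-9)
  expect_true(all(ps$species$shannon_H >= 0 & ps$species$shannon_H <= 1))
  expect_equal(rowSums(ps$species[, c("C0", "C1", "C2")]), rep(1, 12),
               ignore_attr = TRUE, tolerance = 1e-9)
})
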