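# Synthetic-data generation: Yule trees, Brownian traits, compositional
# sterol profiles with phylogenetic covariance, guild labels with planted
# effects, and occurrence tables with planted cleaning violations. Defaults
# emulate the structure of a 122-species x 25-compound pollen sterol survey.

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation starting from the root split (two lineages at time
#' zero): waiting times between speciation events are exponential with rate
#' (number of lineages) x \code{birthRate}, the splitting lineage is chosen
#' uniformly, and after the (n-1)th split all lineages are extended by one
#' final exponential waiting time. The result is a rooted, ultrametric,
#' strictly bifurcating tree with exactly \code{nTips} tips.
#'
#' @param nTips number of tips (>= 2).
#' @param birthRate speciation rate per lineage per unit time.
#' @param seed integer seed.
#' @return an \code{ape::phylo} tree, tips labelled t1..tn.
#' @export
simYuleTree <- function(nTips, birthRate = 1, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(nTips >= 2, birthRate > 0)
  withSeed(seed, {
    # active lineages carry their birth time; assemble an edge list
    nNode <- nTips - 1L
    edge <- matrix(0L, 2L * nTips - 2L, 2)
    edgeLen <- numeric(2L * nTips - 2L)
    nextTip <- 1L
    nextNode <- nTips + 2L  # root is nTips + 1
    t0 <- 0
    # each active lineage: parent node id and birth time
    act_parent <- c(nTips + 1L, nTips + 1L)
    act_birth <- c(0, 0)
    ne <- 0L
    k <- 2L
    while (k < nTips) {
      t0 <- t0 + stats::rexp(1, rate = birthRate * k)
      j <- sample.int(k, 1)
      node <- nextNode; nextNode <- nextNode + 1L
      ne <- ne + 1L
      edge[ne, ] <- c(act_parent[j], node)
      edgeLen[ne] <- t0 - act_birth[j]
      act_parent[j] <- node; act_birth[j] <- t0
      act_parent <- c(act_parent, node); act_birth <- c(act_birth, t0)
      k <- k + 1L
    }
    t0 <- t0 + stats::rexp(1, rate = birthRate * k)
    for (j in seq_len(k)) {
      ne <- ne + 1L
      edge[ne, ] <- c(act_parent[j], nextTip)
      edgeLen[ne] <- t0 - act_birth[j]
      nextTip <- nextTip + 1L
    }
    tr <- list(edge = edge[seq_len(ne), , drop = FALSE],
               edge.length = edgeLen[seq_len(ne)],
               tip.label = paste0("t", seq_len(nTips)),
               Nnode = nNode)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    tr
  })
}

#' Simulate Brownian traits on a tree
#'
#' Draws one trait vector from the multivariate normal with mean
#' \code{root} and covariance sigma2 x V(lambda), where V(lambda) is the
#' Brownian covariance of the tree with off-diagonals multiplied by
#' \code{lambdaTrue}, via Cholesky factorization. \code{nTraits > 1} returns
#' a matrix of independent replicate traits (tips x traits).
#'
#' @param tree phylo tree (or a precomputed \code{bmCov} result).
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param lambdaTrue signal strength in [0, 1] (default 1 = pure Brownian).
#' @param root root state.
#' @param seed integer seed.
#' @param nTraits number of independent traits.
#' @return named numeric vector (or tips x nTraits matrix).
#' @export
simBMTraits <- function(tree, sigma2 = 1, lambdaTrue = 1, root = 0, seed,
                        nTraits = 1) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(sigma2 >= 0, lambdaTrue >= 0, lambdaTrue <= 1)
  C <- .asBMCov(tree)
  labels <- rownames(C)
  n <- nrow(C)
  if (sigma2 == 0) {
    z <- matrix(root, n, nTraits, dimnames = list(labels, NULL))
    return(if (nTraits == 1) stats::setNames(z[, 1], labels) else z)
  }
  V <- lambdaTrue * C
  diag(V) <- diag(C)
  R <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-10 * mean(diag(V)), n))
  })
  z <- withSeed(seed, {
    eps <- matrix(stats::rnorm(n * nTraits), n, nTraits)
    root + sqrt(sigma2) * crossprod(R, eps)
  })
  rownames(z) <- labels
  if (nTraits == 1) stats::setNames(z[, 1], labels) else z
}

#' Simulate phylogenetically structured sterol profiles
#'
#' Per compound, a latent trait evolves on the tree (Brownian motion with
#' rate \code{sigma2Phylo} and signal \code{lambdaTrue}) around a
#' compound-specific baseline (normal with sd \code{baselineSD}, creating
#' common/dominant versus rare compounds), plus independent tip noise with
#' sd \code{sigmaEnv}. A softmax across compounds turns the latent matrix
#' into per-species proportions (a logistic-normal composition, so each
#' compound's proportion inherits phylogenetic covariance). Total sterol
#' content is lognormal(\code{contentMeanlog}, \code{contentSdlog}),
#' optionally sharing Brownian structure, and absolute amounts are
#' proportions x content. Compounds are assigned ring-B and C-24 classes at
#' random.
#'
#' @param tree phylo tree over the species.
#' @param nCompounds number of compounds (default 25).
#' @param sigma2Phylo Brownian rate of the latent compound traits.
#' @param lambdaTrue signal strength of the latent traits.
#' @param baselineSD sd of compound baseline effects.
#' @param sigmaEnv sd of non-phylogenetic tip noise on the latent scale.
#' @param contentMeanlog,contentSdlog lognormal parameters of total content
#'   (ug per mg pollen).
#' @param contentPhylo logical; give log total content Brownian structure
#'   (scaled to variance contentSdlog^2) instead of i.i.d. noise.
#' @param detectionLimit amounts below this (ug per mg) are censored to
#'   zero, emulating a chromatography quantification floor so profiles
#'   contain genuine absences; detected amounts are re-closed to the
#'   species' total content. The per-species maximum is never censored.
#'   Set to 0 for uncensored compositions.
#' @param seed integer seed.
#' @return list with \code{experiment} (a \linkS4class{SterolExperiment}),
#'   \code{latent} (species x compound latent traits), \code{meta}
#'   (compound class table), and the generating parameters.
#' @export
simProfiles <- function(tree, nCompounds = 25, sigma2Phylo = 1.5,
                        lambdaTrue = 1, baselineSD = 1.5, sigmaEnv = 0.5,
                        contentMeanlog = 1, contentSdlog = 0.8,
                        contentPhylo = TRUE, detectionLimit = 0.01, seed) {
  if (missing(seed)) stop("a seed is required")
  cov <- bmCov(tree)
  n <- nrow(cov$C)
  species <- rownames(cov$C)
  depth <- mean(diag(cov$C))
  latent <- simBMTraits(cov, sigma2 = sigma2Phylo / depth,
                        lambdaTrue = lambdaTrue, root = 0,
                        seed = substreamSeed(seed, "latent"),
                        nTraits = nCompounds)
  extras <- withSeed(substreamSeed(seed, "baseline"), {
    list(base = stats::rnorm(nCompounds, 0, baselineSD),
         noise = matrix(stats::rnorm(n * nCompounds, 0, sigmaEnv),
                        n, nCompounds))
  })
  latent <- sweep(latent + extras$noise, 2, extras$base, "+")
  colnames(latent) <- sprintf("sterol%02d", seq_len(nCompounds))
  if (contentPhylo) {
    zc <- simBMTraits(cov, sigma2 = contentSdlog^2 / depth, lambdaTrue = 1,
                      root = contentMeanlog,
                      seed = substreamSeed(seed, "content"))
    content <- exp(zc)
  } else {
    content <- withSeed(substreamSeed(seed, "content"),
                        stats::rlnorm(n, contentMeanlog, contentSdlog))
    names(content) <- species
  }
  meta <- withSeed(substreamSeed(seed, "classes"), data.frame(
    compound = colnames(latent),
    delta_class = sample(.DELTA_LEVELS, nCompounds, replace = TRUE,
                         prob = c(0.15, 0.5, 0.25, 0.1)),
    c24_class = sample(.C24_LEVELS, nCompounds, replace = TRUE)))
  prop <- exp(latent - apply(latent, 1, max))
  prop <- prop / rowSums(prop)
  amounts <- prop * content
  rownames(amounts) <- species
  if (detectionLimit > 0) {
    keepMax <- cbind(seq_len(n), max.col(amounts))
    censored <- amounts < detectionLimit
    censored[keepMax] <- FALSE
    amounts[censored] <- 0
    amounts <- amounts * (content / rowSums(amounts))  # re-close to totals
  }
  se <- SterolExperiment(amounts, compoundData = meta, speciesAsRows = TRUE)
  list(experiment = se, latent = latent, meta = meta,
       content = content,
       params = list(nCompounds = nCompounds, sigma2Phylo = sigma2Phylo,
                     lambdaTrue = lambdaTrue, baselineSD = baselineSD,
                     sigmaEnv = sigmaEnv, contentMeanlog = contentMeanlog,
                     contentSdlog = contentSdlog,
                     contentPhylo = contentPhylo,
                     detectionLimit = detectionLimit, seed = seed))
}

#' Simulate pollinator-guild labels with an optional planted effect
#'
#' Assigns species to \code{kGroups} balanced groups (sizes within one of
#' each other). With \code{delta = 0} the groups are exchangeable with
#' respect to the profiles (a null dataset for calibrating ANOSIM /
#' phylogenetic ANOVA); with \code{delta > 0} the latent traits of
#' \code{effectCompounds} are shifted by \code{delta} in group 1 and the
#' profile matrix is rebuilt, planting a real compositional difference.
#'
#' @param profiles a \code{\link{simProfiles}} result.
#' @param kGroups number of guilds (>= 2).
#' @param effectCompounds compound names (or indices) shifted in group 1.
#' @param delta latent-scale shift size.
#' @param seed integer seed.
#' @return list with \code{groups} (named factor), \code{experiment}
#'   (shifted \linkS4class{SterolExperiment}; the input one when delta = 0),
#'   \code{delta}.
#' @export
simGuilds <- function(profiles, kGroups = 4, effectCompounds = 1:3,
                      delta = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(kGroups >= 2)
  latent <- profiles$latent
  species <- rownames(latent)
  n <- length(species)
  g <- withSeed(substreamSeed(seed, "labels"), {
    sample(rep_len(paste0("guild", seq_len(kGroups)), n))
  })
  names(g) <- species
  se <- profiles$experiment
  if (delta != 0) {
    if (is.numeric(effectCompounds)) {
      effectCompounds <- colnames(latent)[effectCompounds]
    }
    latent[g == "guild1", effectCompounds] <-
      latent[g == "guild1", effectCompounds] + delta
    prop <- exp(latent - apply(latent, 1, max))
    prop <- prop / rowSums(prop)
    amounts <- prop * profiles$content[species]
    se <- SterolExperiment(amounts, compoundData = profiles$meta,
                           speciesAsRows = TRUE)
  }
  list(groups = factor(g), experiment = se, delta = delta)
}

#' Simulate an occurrence table with planted cleaning violations
#'
#' Emits \code{nClean} valid records, each in its own 10-arcmin grid cell
#' (so thinning removes none of them), plus planted violations of each
#' cleaning filter in known numbers. The ground-truth survivor count
#' (\code{nClean}) is returned alongside, so the cleaning chain can be
#' checked end to end.
#'
#' @param nClean number of valid, distinct-cell records.
#' @param violations named list of planted violation counts:
#'   \code{missing}, \code{zero_zero}, \code{lat_eq_lon}, \code{old},
#'   \code{flagged}, \code{uncertain}, \code{duplicate}, \code{cocell}
#'   (extra records in an already-used cell).
#' @param extent c(lonmin, lonmax, latmin, latmax) sampling window.
#' @param species species label for the records.
#' @param seed integer seed.
#' @return list with \code{records} (shuffled data.frame),
#'   \code{n_survivors} (ground truth), \code{violations}.
#' @export
simOccurrences <- function(nClean, violations = list(), extent = c(-20, 40, 20, 60),
                           species = "sp1", seed) {
  if (missing(seed)) stop("a seed is required")
  v <- utils::modifyList(list(missing = 0, zero_zero = 0, lat_eq_lon = 0,
                              old = 0, flagged = 0, uncertain = 0,
                              duplicate = 0, cocell = 0), violations)
  withSeed(seed, {
    cellDeg <- 10 / 60
    nx <- floor((extent[2] - extent[1]) / cellDeg)
    ny <- floor((extent[4] - extent[3]) / cellDeg)
    if (nClean > nx * ny) stop("extent too small for distinct-cell records")
    cells <- sample.int(nx * ny, nClean)
    cx <- (cells - 1) %% nx
    cy <- (cells - 1) %/% nx
    lon <- extent[1] + (cx + stats::runif(nClean, 0.1, 0.9)) * cellDeg
    lat <- extent[3] + (cy + stats::runif(nClean, 0.1, 0.9)) * cellDeg
    # guard against accidental lat == lon or (0, 0)
    bump <- lon == lat | (lon == 0 & lat == 0)
    lon[bump] <- lon[bump] + cellDeg / 100
    rec <- function(lon, lat, year = 2000, unc = 100, flag = FALSE) {
      k <- length(lon)
      data.frame(species = rep(species, k), longitude = lon, latitude = lat,
                 year = rep(year, k)[seq_len(k)],
                 uncertainty_m = rep(unc, k)[seq_len(k)],
                 fossil = rep(flag, k)[seq_len(k)],
                 centroid = FALSE, sea = FALSE, cultivated = FALSE)
    }
    clean <- rec(lon, lat)
    bad <- list()
    if (v$missing) bad$missing <- rec(rep(NA_real_, v$missing), rep(NA_real_, v$missing))
    if (v$zero_zero) bad$zz <- rec(rep(0, v$zero_zero), rep(0, v$zero_zero))
    if (v$lat_eq_lon) {
      q <- stats::runif(v$lat_eq_lon, extent[3] + 1, min(extent[2], extent[4]) - 1)
      bad$ll <- rec(q, q)
    }
    if (v$old) {
      i <- sample.int(nClean, v$old, replace = TRUE)
      bad$old <- rec(lon[i] + cellDeg / 50, lat[i], year = 1900)
    }
    if (v$flagged) {
      i <- sample.int(nClean, v$flagged, replace = TRUE)
      bad$flag <- rec(lon[i] + cellDeg / 60, lat[i], flag = TRUE)
    }
    if (v$uncertain) {
      i <- sample.int(nClean, v$uncertain, replace = TRUE)
      bad$unc <- rec(lon[i] + cellDeg / 70, lat[i], unc = 50000)
    }
    if (v$duplicate) {
      i <- sample.int(nClean, v$duplicate, replace = TRUE)
      bad$dup <- rec(lon[i], lat[i])
    }
    if (v$cocell) {
      i <- sample.int(nClean, v$cocell, replace = TRUE)
      # same cell, different exact point
      bad$cocell <- rec(extent[1] + (cx[i] + 0.95) * cellDeg,
                        extent[3] + (cy[i] + 0.95) * cellDeg)
    }
    records <- do.call(rbind, c(list(clean), unname(bad)))
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    rownames(records) <- NULL
    list(records = records, n_survivors = nClean, violations = v)
  })
}

#' Canonical hand-checkable fixtures
#'
#' Small instances whose expected statistics were derived by hand and are
#' used across the test suite: the balanced 4-tip tree and trait with
#' Blomberg's K exactly 1.8; the ((A,B),C) Grafen-lengths tree; distance
#' matrices with ANOSIM R exactly 1 and exactly 0 for two groups of two;
#' the Bray-Curtis 3/7 pair; the 8 unit-cube corners (alpha-shape volume 1);
#' and the 10-record occurrence table whose cleaning chain leaves exactly
#' one survivor.
#'
#' @return named list of fixtures, each carrying its expected value.
#' @export
canonicalFixtures <- function() {
  balanced4 <- readNewickTree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  kTrait <- c(A = 1, B = 1, C = -1, D = -1)
  grafen3 <- readNewickTree(text = "((A,B),C);")
  mkDist <- function(w, b) {
    # two groups of two: within-group distances w (length 2),
    # between-group distances b (length 4)
    m <- matrix(0, 4, 4, dimnames = list(c("a1", "a2", "b1", "b2"),
                                         c("a1", "a2", "b1", "b2")))
    m["a1", "a2"] <- w[1]; m["b1", "b2"] <- w[2]
    m["a1", "b1"] <- b[1]; m["a1", "b2"] <- b[2]
    m["a2", "b1"] <- b[3]; m["a2", "b2"] <- b[4]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 8 records: one per violation (missing coords, 0/0, lat==lon, pre-1950,
  # flagged, >20 km uncertainty) plus two clean points sharing one
  # 10-arcmin cell, so exactly one record survives the chain.
  occ <- data.frame(
    species = "sp",
    longitude = c(NA, 0, 25, 10.01, 10.02, 10.03, 10.05, 10.06),
    latitude = c(10, 0, 25, 50.01, 50.02, 50.03, 50.05, 50.06),
    year = c(2000, 2000, 2000, 1900, 2000, 2000, 2000, 2000),
    uncertainty_m = c(100, 100, 100, 100, 100, 50000, 100, 100),
    fossil = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    centroid = FALSE, sea = FALSE, cultivated = FALSE)
  list(
    balanced4 = list(tree = balanced4, trait = kTrait, K = 1.8),
    grafen3 = list(tree = grafen3,
                   heights = c(root = 1, cherry = 0.5)),
    anosimR1 = list(d = mkDist(c(1, 2), c(10, 11, 12, 13)),
                    groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                    R = 1),
    anosimR0 = list(d = mkDist(c(3, 4), c(1, 2, 5, 6)),
                    groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                    R = 0),
    brayCurtis = list(x = rbind(s1 = c(1, 2, 0), s2 = c(0, 2, 2)),
                      d = 3 / 7),
    unitCube = list(points = cube, volume = 1),
    cleaning = list(records = occ, survivors = 1L),
    shannon = list(p = c(0.7, 0.2, 0.1), H = 0.7299)
  )
}
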