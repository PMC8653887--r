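# Format round-tripping and pipeline orchestration. CSV dialect: UTF-8,
# comma-separated, header row. Species names are matched between tables and
# trees exactly, after underscore/space normalization.

.normName <- function(x) gsub(" ", "_", trimws(x))

#' Read a sterol profile CSV
#'
#' First column: species identifier; remaining columns: absolute compound
#' amounts (ug per mg pollen) named in the header. Rows sharing a species
#' identifier are replicate measurements and can be averaged.
#'
#' @param path profile CSV path.
#' @param metaPath optional compound metadata CSV (columns compound,
#'   delta_class, c24_class).
#' @param averageReplicates average replicate rows per species.
#' @return a \linkS4class{SterolExperiment}.
#' @export
readSterolCSV <- function(path, metaPath = NULL, averageReplicates = TRUE) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2) stop("profile CSV needs a species column plus compounds")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric amounts in ", path)
  rownames(m) <- .normName(as.character(tab[[1]]))
  meta <- if (!is.null(metaPath)) readCompoundMeta(metaPath) else NULL
  SterolExperiment(m, compoundData = meta, speciesAsRows = TRUE,
                   averageReplicates = averageReplicates)
}

#' Read a compound metadata CSV (compound, delta_class, c24_class)
#' @param path CSV path.
#' @return data.frame.
#' @export
readCompoundMeta <- function(path) {
  meta <- utils::read.csv(path)
  need <- c("compound", "delta_class", "c24_class")
  if (!all(need %in% names(meta))) {
    stop("compound metadata needs columns: ", paste(need, collapse = ", "))
  }
  meta
}

#' Read a two-column trait CSV (species, value) as a named vector
#' @param path CSV path.
#' @return named numeric vector.
#' @export
readTraitCSV <- function(path) {
  tab <- utils::read.csv(path)
  stats::setNames(as.numeric(tab[[2]]), .normName(as.character(tab[[1]])))
}

#' Read a two-column group CSV (species, group) as a named character vector
#' @param path CSV path.
#' @return named character vector.
#' @export
readGroupsCSV <- function(path) {
  tab <- utils::read.csv(path)
  stats::setNames(as.character(tab[[2]]), .normName(as.character(tab[[1]])))
}

#' Write / read a square labelled distance matrix CSV
#' @param d dist or square matrix.
#' @param path CSV path.
#' @return \code{writeDistanceCSV}: invisibly, the path;
#'   \code{readDistanceCSV}: a square matrix.
#' @export
writeDistanceCSV <- function(d, path) {
  m <- asDistanceMatrix(d)
  utils::write.csv(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   path, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistanceCSV
#' @export
readDistanceCSV <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  asDistanceMatrix(m, path)
}

#' Write a tree to newick
#' @param tree phylo tree.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Prune an experiment and tree to their common species; warn on drops.
.harmonize <- function(se, tree) {
  sp <- .normName(colnames(se))
  colnames(se) <- sp
  tree$tip.label <- .normName(tree$tip.label)
  common <- intersect(sp, tree$tip.label)
  if (!length(common)) stop("no species shared between profiles and tree")
  dropT <- setdiff(tree$tip.label, common)
  dropS <- setdiff(sp, common)
  if (length(dropT)) warning("tips absent from profiles, pruned: ",
                             paste(dropT, collapse = ", "))
  if (length(dropS)) warning("species absent from tree, dropped: ",
                             paste(dropS, collapse = ", "))
  if (length(dropT)) tree <- ape::drop.tip(tree, dropT)
  list(se = se[, tree$tip.label], tree = tree)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on the configured inputs and
#' writes one tidy CSV/JSON per stage plus a manifest (package version,
#' seeds, parameters, input MD5 hashes) to \code{outDir}. Stages run only
#' when their inputs are configured:
#' \describe{
#'   \item{profiles}{per-species and per-compound summary tables;}
#'   \item{factors}{factor analysis of compound proportions;}
#'   \item{ordination}{Bray-Curtis distances, NMDS, and (with guild labels)
#'     ANOSIM;}
#'   \item{signal}{Pagel's lambda and Blomberg's K for Shannon H, log total
#'     content, each biosynthetic group sum, and each compound proportion
#'     (needs the tree);}
#'   \item{phyloanova}{phylogenetic ANOVA of log total content across
#'     guilds (needs tree and guilds);}
#'   \item{mrm}{MRM of Bray-Curtis on environmental PC distances and
#'     patristic distance (needs tree and an env score table);}
#'   \item{niche}{occurrence cleaning, env extraction, PCA, niche
#'     position/breadth (needs occurrences and layers).}
#' }
#'
#' @param config named list or path to a YAML file. Recognised fields:
#'   \code{profiles}, \code{compound_meta}, \code{tree}, \code{guilds},
#'   \code{env_scores}, \code{occurrences}, \code{layers} (directory of
#'   .asc grids), \code{stages}, \code{seed}, \code{n_perm}, \code{n_sim},
#'   \code{alpha}, \code{lambda_perm} (0 = LRT only).
#' @param outDir output directory (created if missing).
#' @return invisibly, a list of stage results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(seed = 1, n_perm = 10000, n_sim = 1000, alpha = 2,
         lambda_perm = 0,
         stages = c("profiles", "factors", "ordination", "signal",
                    "phyloanova", "mrm", "niche")),
    config)
  if (is.null(cfg$profiles)) stop("config must name a 'profiles' CSV")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  se <- readSterolCSV(cfg$profiles, metaPath = cfg$compound_meta)
  tree <- NULL
  if (!is.null(cfg$tree)) {
    tree <- readNewickTree(cfg$tree)
    if (!ape::is.binary(tree)) {
      tree <- resolvePolytomies(tree, substreamSeed(cfg$seed, "resolve"))
    }
    h <- .harmonize(se, tree)
    se <- h$se; tree <- h$tree
  }
  guilds <- if (!is.null(cfg$guilds)) readGroupsCSV(cfg$guilds) else NULL
  stage <- function(name) name %in% cfg$stages
  saveJSON <- function(x, file) {
    jsonlite::write_json(x, file.path(outDir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  if (stage("profiles")) {
    ps <- profileSummary(se)
    utils::write.csv(ps$species, file.path(outDir, "profile_species.csv"),
                     row.names = FALSE)
    utils::write.csv(ps$compounds, file.path(outDir, "profile_compounds.csv"),
                     row.names = FALSE)
    res$profiles <- ps
  }
  if (stage("factors")) {
    pr <- sterolProportions(se)
    keepC <- apply(pr, 2, stats::var) > 0
    if (any(!keepC)) {
      warning("dropping constant compounds from factor analysis: ",
              paste(colnames(pr)[!keepC], collapse = ", "))
    }
    fa <- factorAnalysis(pr[, keepC, drop = FALSE])
    utils::write.csv(
      data.frame(compound = rownames(fa$loadings), fa$loadings),
      file.path(outDir, "factor_loadings.csv"), row.names = FALSE)
    saveJSON(list(eigenvalues = fa$eigenvalues, retained = fa$retained,
                  proportion_variance = fa$proportion_variance),
             "factors.json")
    res$factors <- fa
  }
  d <- NULL
  if (stage("ordination") || stage("mrm")) d <- brayCurtis(se)
  if (stage("ordination")) {
    writeDistanceCSV(d, file.path(outDir, "bray_curtis.csv"))
    nm <- nmds2d(d, seed = substreamSeed(cfg$seed, "nmds"))
    utils::write.csv(data.frame(species = rownames(nm$points), nm$points),
                     file.path(outDir, "nmds.csv"), row.names = FALSE)
    res$nmds <- nm
    if (!is.null(guilds)) {
      an <- anosimTest(d, guilds[colnames(se)], nPerm = cfg$n_perm,
                       seed = substreamSeed(cfg$seed, "anosim"))
      saveJSON(an[c("statistic", "p_value", "n_perm", "seed", "groups_used")],
               "anosim.json")
      res$anosim <- an
    }
  }
  if (stage("signal") && !is.null(tree)) {
    cov <- bmCov(tree, epsilon = 1e-8)
    gs <- tryCatch(groupSums(se), error = function(e) NULL)
    traits <- cbind(shannon_H = shannonEquitability(se),
                    log_total_content = sterolTotals(se, log = TRUE))
    if (!is.null(gs)) traits <- cbind(traits, as.matrix(gs))
    traits <- cbind(traits, t(sterolAmounts(se)) /
                      sterolTotals(se))  # compound proportions
    sig <- do.call(rbind, lapply(colnames(traits), function(tn) {
      z <- traits[, tn]
      if (stats::var(z) == 0) return(NULL)
      la <- pagelLambda(z, cov, nPerm = cfg$lambda_perm,
                        seed = substreamSeed(cfg$seed, paste0("lam_", tn)))
      kk <- blombergK(z, cov, nPerm = 999,
                      seed = substreamSeed(cfg$seed, paste0("K_", tn)))
      data.frame(trait = tn, lambda = la$lambda, p_lambda = la$p_lambda,
                 p_lambda_perm = la$p_perm, K = kk$K, p_K = kk$p_K)
    }))
    utils::write.csv(sig, file.path(outDir, "signal.csv"), row.names = FALSE)
    res$signal <- sig
  }
  if (stage("phyloanova") && !is.null(tree) && !is.null(guilds)) {
    g <- guilds[tree$tip.label]
    keep <- names(table(g))[table(g) >= 2]
    tips <- tree$tip.label[g %in% keep]
    tr2 <- ape::keep.tip(tree, tips)
    pa <- phyloAnova(sterolTotals(se, log = TRUE)[tips], g[tips], tr2,
                     nSim = cfg$n_sim,
                     seed = substreamSeed(cfg$seed, "phyloanova"))
    saveJSON(list(F = pa$F, p_phyl = pa$p_phyl, sigma2_hat = pa$sigma2_hat,
                  n_sim = pa$n_sim, seed = pa$seed, pairwise = pa$pairwise),
             "phyloanova.json")
    res$phyloanova <- pa
  }
  if (stage("mrm") && !is.null(tree) && !is.null(cfg$env_scores)) {
    env <- utils::read.csv(cfg$env_scores, row.names = 1)
    rownames(env) <- .normName(rownames(env))
    sp <- intersect(colnames(se), rownames(env))
    if (length(sp) >= 4) {
      dresp <- as.matrix(d)[sp, sp]
      preds <- lapply(colnames(env)[1:min(3, ncol(env))], function(pc) {
        as.matrix(stats::dist(env[sp, pc]))
      })
      names(preds) <- colnames(env)[1:min(3, ncol(env))]
      preds$phylo <- bmCov(ape::keep.tip(tree, sp))$patristic[sp, sp]
      mr <- mrmTest(dresp, preds, nPerm = cfg$n_perm,
                    seed = substreamSeed(cfg$seed, "mrm"))
      saveJSON(mr, "mrm.json")
      res$mrm <- mr
    }
  }
  if (stage("niche") && !is.null(cfg$occurrences)) {
    occ <- utils::read.csv(cfg$occurrences)
    cl <- cleanOccurrences(occ)
    utils::write.csv(data.frame(filter = names(cl$counts),
                                removed = as.integer(cl$counts)),
                     file.path(outDir, "cleaning_audit.csv"),
                     row.names = FALSE)
    res$cleaning <- cl
    if (!is.null(cfg$layers)) {
      files <- list.files(cfg$layers, pattern = "\\.asc$", full.names = TRUE)
      layers <- lapply(files, readAsciiGrid)
      names(layers) <- sub("\\.asc$", "", basename(files))
      ex <- extractEnv(cl$records, layers)
      pca <- envPCA(ex$values)  # environmental space across occurrence points
      ns <- nicheSummary(pca$scores, cl$records$species[ex$kept],
                         alpha = cfg$alpha)
      utils::write.csv(ns, file.path(outDir, "niche.csv"), row.names = FALSE)
      res$niche <- list(pca = pca, table = ns)
    }
  }
  inputs <- unlist(cfg[intersect(names(cfg),
                                 c("profiles", "compound_meta", "tree",
                                   "guilds", "env_scores", "occurrences"))])
  manifest <- list(
    package = "chemphylo",
    version = as.character(utils::packageVersion("chemphylo")),
    seed = cfg$seed, n_perm = cfg$n_perm, n_sim = cfg$n_sim,
    alpha = cfg$alpha, stages = cfg$stages,
    inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
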