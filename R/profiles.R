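# Profile-level summaries of sterol tables: proportions, Shannon
# equitability, commonness, relative abundance, biosynthetic group sums,
# total content and richness.

# Accept a SterolExperiment or a species x compound matrix; return a
# species x compound numeric matrix of absolute amounts.
.asSpeciesMatrix <- function(x) {
  if (methods::is(x, "SterolExperiment")) return(t(sterolAmounts(x)))
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("amounts must be numeric")
  if (any(!is.finite(m))) stop("amounts must be finite")
  if (any(m < 0)) stop("amounts must be nonnegative")
  if (is.null(rownames(m))) rownames(m) <- paste0("species", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("compound", seq_len(ncol(m)))
  m
}

#' Per-species compound proportions
#'
#' Converts absolute amounts to within-species proportions,
#' p_i = amount_i / sum(amounts). Each species' proportions sum to one.
#'
#' @param x a \linkS4class{SterolExperiment} or species x compound matrix of
#'   nonnegative amounts.
#' @return matrix of the same shape; rows (species) sum to 1.
#' @export
computeProportions <- function(x) {
  m <- .asSpeciesMatrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("species with zero total sterol content: ",
         paste(rownames(m)[tot <= 0], collapse = ", "))
  }
  sweep(m, 1, tot, "/")
}

#' Shannon equitability of a compositional profile
#'
#' Shannon entropy computed in the base of the profile's own richness S
#' (the number of compounds with p_i > 0), i.e.
#' H = -sum(p_i * log(p_i)) / log(S). This normalisation (Shannon's
#' equitability, Pielou's J) scales the index to [0, 1], 1 meaning all
#' present compounds are equally abundant. A single-compound profile
#' (S = 1) is defined to have H = 0, the zero-diversity limit.
#'
#' @param p numeric vector of proportions (nonnegative, summing to 1), or a
#'   matrix/\linkS4class{SterolExperiment} for per-species values.
#' @param globalS optional fixed richness to use as the log base instead of
#'   each profile's own (e.g. the study-wide compound count).
#' @return numeric H in [0, 1] (vector of per-species H for matrix input).
#' @export
shannonEquitability <- function(p, globalS = NULL) {
  if (methods::is(p, "SterolExperiment") || is.matrix(p)) {
    pr <- if (is.matrix(p)) computeProportions(p) else sterolProportions(p)
    return(apply(pr, 1, shannonEquitability, globalS = globalS))
  }
  if (length(p) == 0) stop("empty profile")
  if (any(p < 0)) stop("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  pos <- p[p > 0]
  S <- if (is.null(globalS)) length(pos) else globalS
  if (S <= 1) return(0)
  -sum(pos * log(pos)) / log(S)
}

#' Compound commonness
#'
#' The fraction of species in which a compound is present, presence meaning
#' amount strictly above \code{threshold}. The default threshold 0 treats
#' any detected amount as presence; a positive value models a detection
#' limit for censored chromatography zeros.
#'
#' @inheritParams computeProportions
#' @param threshold presence threshold on absolute amount (ug/mg).
#' @return named numeric vector, one fraction in [0, 1] per compound.
#' @export
commonness <- function(x, threshold = 0) {
  m <- .asSpeciesMatrix(x)
  if (nrow(m) < 1) stop("at least one species required")
  colMeans(m > threshold)
}

#' Compound relative abundance
#'
#' The average within-species proportion of each compound across all
#' species. The vector sums to one.
#'
#' @inheritParams computeProportions
#' @return named numeric vector of per-compound mean proportions.
#' @export
relativeAbundance <- function(x) {
  colMeans(computeProportions(x))
}

#' Biosynthetic group sums
#'
#' Per-species sums of compound proportions within each C-24 alkylation
#' class (C0/C1/C2) and each ring-B double-bond class (D0/D5/D7/D8). When
#' every compound is classified, the C sums and the D sums each total 1 per
#' species.
#'
#' @param x a \linkS4class{SterolExperiment} carrying compound classes, or a
#'   species x compound matrix plus \code{meta}.
#' @param meta data.frame with columns compound, delta_class, c24_class;
#'   required for matrix input.
#' @return data.frame, one row per species, columns C0,C1,C2,D0,D5,D7,D8.
#' @export
groupSums <- function(x, meta = NULL) {
  pr <- computeProportions(x)
  if (methods::is(x, "SterolExperiment") && is.null(meta)) {
    meta <- compoundClasses(x)
  }
  if (is.null(meta)) stop("compound metadata required")
  meta <- as.data.frame(meta)
  meta$delta_class <- gsub("Δ", "D", as.character(meta$delta_class))
  idx <- match(colnames(pr), meta$compound)
  if (anyNA(idx)) {
    stop("unclassified compounds: ",
         paste(colnames(pr)[is.na(idx)], collapse = ", "))
  }
  cc <- factor(meta$c24_class[idx], levels = .C24_LEVELS)
  dc <- factor(meta$delta_class[idx], levels = .DELTA_LEVELS)
  sumBy <- function(f) {
    s <- sapply(levels(f), function(l) rowSums(pr[, f == l, drop = FALSE]))
    if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = list(rownames(pr), levels(f)))
    s
  }
  out <- data.frame(sumBy(cc), sumBy(dc), check.names = FALSE)
  rownames(out) <- rownames(pr)
  out
}

#' Total sterol content
#'
#' Row sums of the absolute amounts: total sterol per species in ug per mg
#' pollen, optionally natural-log transformed (as used for display and for
#' downstream signal/regression analyses of content).
#'
#' @inheritParams computeProportions
#' @param log logical; return log(total).
#' @return named numeric vector.
#' @export
totalContent <- function(x, log = FALSE) {
  m <- .asSpeciesMatrix(x)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("species with all-zero profiles: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
  }
  if (log) log(tot) else tot
}

#' Richness summary across species
#'
#' Mean and sample standard deviation (n-1 denominator) of the per-species
#' count of present compounds.
#'
#' @inheritParams commonness
#' @return list with elements \code{counts}, \code{mean}, \code{sd}.
#' @export
richnessStats <- function(x, threshold = 0) {
  m <- .asSpeciesMatrix(x)
  counts <- rowSums(m > threshold)
  list(counts = counts, mean = mean(counts),
       sd = if (length(counts) >= 2) stats::sd(counts) else NA_real_)
}

#' Full profile summary
#'
#' Assembles the per-species table (richness, Shannon equitability, total
#' content, group sums) and the per-compound table (commonness, relative
#' abundance).
#'
#' @inheritParams groupSums
#' @param threshold presence threshold for richness/commonness.
#' @return list with data.frames \code{species} and \code{compounds}.
#' @export
profileSummary <- function(x, meta = NULL, threshold = 0) {
  m <- .asSpeciesMatrix(x)
  rs <- richnessStats(m, threshold)
  sp <- data.frame(
    species = rownames(m),
    richness = rs$counts,
    shannon_H = shannonEquitability(m),
    total_content = totalContent(m),
    row.names = NULL)
  gs <- tryCatch(
    groupSums(if (methods::is(x, "SterolExperiment")) x else m, meta),
    error = function(e) NULL)
  if (!is.null(gs)) sp <- cbind(sp, gs)
  cmp <- data.frame(
    compound = colnames(m),
    commonness = commonness(m, threshold),
    relative_abundance = relativeAbundance(m),
    row.names = NULL)
  list(species = sp, compounds = cmp)
}
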