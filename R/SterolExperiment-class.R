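#' SterolExperiment: a container for pollen sterol profiles
#'
#' An S4 class extending \link[SummarizedExperiment]{SummarizedExperiment}
#' that stores a compounds x species matrix of absolute sterol amounts
#' (ug per mg pollen) in the \code{"amounts"} assay. Per-compound
#' biosynthetic classes live in \code{rowData}: \code{delta_class}, the
#' position (or absence) of the ring-B double bond (one of
#' \code{"D0","D5","D7","D8"}), and \code{c24_class}, the C-24 side-chain
#' alkylation state (\code{"C0","C1","C2"}: none, methyl, ethyl). Optional
#' per-species annotations (pollinator guild, niche scores) live in
#' \code{colData}.
#'
#' Validity requires nonnegative finite amounts, unique species and compound
#' identifiers, and a positive total for every species (a species with no
#' detected sterols carries no compositional information).
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass SterolExperiment
setClass("SterolExperiment", contains = "SummarizedExperiment")

setValidity("SterolExperiment", function(object) {
  msg <- character()
  if (!"amounts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'amounts' is required")
  } else {
    a <- SummarizedExperiment::assay(object, "amounts")
    if (any(!is.finite(a))) msg <- c(msg, "amounts must be finite")
    else if (any(a < 0)) msg <- c(msg, "amounts must be nonnegative")
    else {
      tot <- colSums(a)
      if (any(tot <= 0)) {
        msg <- c(msg, paste0("species with zero total sterol content: ",
                             paste(colnames(a)[tot <= 0], collapse = ", ")))
      }
    }
  }
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate species identifiers")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate compound identifiers")
  if (length(msg)) msg else TRUE
})

.DELTA_LEVELS <- c("D0", "D5", "D7", "D8")
.C24_LEVELS <- c("C0", "C1", "C2")

#' Construct a SterolExperiment
#'
#' @param amounts numeric matrix of absolute sterol amounts, ug per mg
#'   pollen. Accepted in either orientation; if rows are species (the usual
#'   CSV layout) set \code{speciesAsRows = TRUE} and it is transposed so
#'   compounds become rows.
#' @param compoundData optional data.frame with columns \code{compound},
#'   \code{delta_class} and \code{c24_class} classifying every compound.
#' @param colData optional per-species annotation data.frame.
#' @param speciesAsRows logical; is \code{amounts} species x compounds?
#' @param averageReplicates logical; average rows sharing one species
#'   identifier (replicate measurements) before assembly.
#' @return a \linkS4class{SterolExperiment}.
#' @examples
#' m <- rbind(spA = c(1, 2, 1), spB = c(0, 2, 2))
#' colnames(m) <- c("cholesterol", "sitosterol", "campesterol")
#' se <- SterolExperiment(m, speciesAsRows = TRUE)
#' sterolTotals(se)
#' @export
SterolExperiment <- function(amounts, compoundData = NULL, colData = NULL,
                             speciesAsRows = FALSE,
                             averageReplicates = FALSE) {
  amounts <- as.matrix(amounts)
  if (speciesAsRows) {
    if (averageReplicates && anyDuplicated(rownames(amounts))) {
      amounts <- rowsum(amounts, rownames(amounts), reorder = FALSE) /
        as.vector(table(rownames(amounts))[unique(rownames(amounts))])
    }
    amounts <- t(amounts)
  }
  if (is.null(rownames(amounts))) {
    rownames(amounts) <- paste0("compound", seq_len(nrow(amounts)))
  }
  if (is.null(colnames(amounts))) {
    colnames(amounts) <- paste0("species", seq_len(ncol(amounts)))
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(amounts))
  if (!is.null(compoundData)) {
    compoundData <- as.data.frame(compoundData)
    key <- if ("compound" %in% names(compoundData)) {
      compoundData$compound
    } else {
      rownames(compoundData)
    }
    idx <- match(rownames(amounts), key)
    if (anyNA(idx)) {
      stop("compounds missing from compoundData: ",
           paste(rownames(amounts)[is.na(idx)], collapse = ", "))
    }
    dc <- gsub("Δ", "D", as.character(compoundData$delta_class[idx]))
    cc <- as.character(compoundData$c24_class[idx])
    if (!all(dc %in% .DELTA_LEVELS)) {
      stop("delta_class values must be one of ",
           paste(.DELTA_LEVELS, collapse = "/"))
    }
    if (!all(cc %in% .C24_LEVELS)) {
      stop("c24_class values must be one of ",
           paste(.C24_LEVELS, collapse = "/"))
    }
    rd$delta_class <- dc
    rd$c24_class <- cc
  }
  cd <- if (is.null(colData)) {
    S4Vectors::DataFrame(row.names = colnames(amounts))
  } else {
    S4Vectors::DataFrame(colData, row.names = colnames(amounts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(amounts = amounts), rowData = rd, colData = cd)
  methods::new("SterolExperiment", se)
}

#' @describeIn SterolExperiment absolute amounts matrix (compounds x species).
#' @param x,object a SterolExperiment.
#' @export
sterolAmounts <- function(x) SummarizedExperiment::assay(x, "amounts")

#' @describeIn SterolExperiment per-species proportions (columns sum to 1).
#' @export
sterolProportions <- function(x) {
  a <- sterolAmounts(x)
  computeProportions(t(a))
}

#' @describeIn SterolExperiment per-species total content, ug per mg pollen.
#' @param log logical; return natural-log totals.
#' @export
sterolTotals <- function(x, log = FALSE) {
  totalContent(t(sterolAmounts(x)), log = log)
}

#' @describeIn SterolExperiment compound class table (delta and C-24).
#' @export
compoundClasses <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!all(c("delta_class", "c24_class") %in% colnames(rd))) {
    stop("no compound classification stored; supply compoundData on construction")
  }
  data.frame(compound = rownames(x),
             delta_class = rd$delta_class,
             c24_class = rd$c24_class,
             row.names = NULL)
}

#' @export
setMethod("show", "SterolExperiment", function(object) {
  a <- sterolAmounts(object)
  cat(sprintf("SterolExperiment: %d compounds x %d species\n",
              nrow(a), ncol(a)))
  cat(sprintf("  total content (ug/mg): median %.3g, range [%.3g, %.3g]\n",
              stats::median(colSums(a)), min(colSums(a)), max(colSums(a))))
  rd <- SummarizedExperiment::rowData(object)
  if ("delta_class" %in% colnames(rd)) {
    cat("  delta classes: ",
        paste(sprintf("%s:%d", names(table(rd$delta_class)),
                      table(rd$delta_class)), collapse = " "), "\n")
  }
  invisible(NULL)
})
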