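# Occurrence-record cleaning, environmental extraction, environmental-space
# PCA, and per-species niche position / alpha-shape breadth.

.FLAG_COLS <- c("fossil", "centroid", "sea", "cultivated")

#' Clean occurrence records
#'
#' Applies the standard occurrence-cleaning filter chain in a fixed order,
#' reporting the number of records removed by each step:
#' \enumerate{
#'   \item missing coordinates;
#'   \item latitude and longitude both zero;
#'   \item latitude equal to longitude;
#'   \item recorded before \code{minYear} (missing year kept);
#'   \item provenance-flagged records (fossil / centroid / sea / cultivated);
#'   \item coordinate uncertainty above \code{maxUncertainty} metres
#'     (missing uncertainty kept);
#'   \item exact duplicates (same species and coordinates; first kept);
#'   \item spatial thinning to one record per \code{cellMinutes}-arcmin grid
#'     cell per species (cell index \code{floor(coord * 60 / cellMinutes)},
#'     half-open cells, first record in input order kept).
#' }
#' The chain is idempotent and the per-filter counts sum to the difference
#' between input and output sizes.
#'
#' @param records data.frame with columns \code{species}, \code{longitude},
#'   \code{latitude} and optionally \code{year}, \code{uncertainty_m} and
#'   logical flag columns \code{fossil}, \code{centroid}, \code{sea},
#'   \code{cultivated}.
#' @param minYear oldest year retained (default 1950).
#' @param maxUncertainty largest coordinate uncertainty retained, metres
#'   (default 20000, i.e. 20 km).
#' @param cellMinutes thinning cell size in arc-minutes (default 10).
#' @return list with \code{records} (the cleaned table), \code{counts}
#'   (named integer vector of removals per filter), \code{n_input},
#'   \code{n_output}.
#' @export
cleanOccurrences <- function(records, minYear = 1950,
                             maxUncertainty = 20000, cellMinutes = 10) {
  r <- as.data.frame(records)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(r))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  nIn <- nrow(r)
  counts <- integer(8)
  names(counts) <- c("missing_coords", "zero_zero", "lat_eq_lon",
                     "pre_cutoff_year", "flagged", "high_uncertainty",
                     "duplicate", "thinned")
  drop <- function(bad, which) {
    bad[is.na(bad)] <- FALSE
    counts[which] <<- counts[which] + sum(bad)
    r[!bad, , drop = FALSE]
  }
  r <- drop(is.na(r$longitude) | is.na(r$latitude), "missing_coords")
  r <- drop(r$longitude == 0 & r$latitude == 0, "zero_zero")
  r <- drop(r$longitude == r$latitude, "lat_eq_lon")
  if ("year" %in% names(r)) {
    bad <- !is.na(r$year) & r$year < minYear
    r <- drop(bad, "pre_cutoff_year")
  }
  flagCols <- intersect(.FLAG_COLS, names(r))
  if (length(flagCols)) {
    bad <- Reduce(`|`, lapply(flagCols, function(f) {
      v <- r[[f]]
      !is.na(v) & as.logical(v)
    }))
    r <- drop(bad, "flagged")
  }
  if ("uncertainty_m" %in% names(r)) {
    bad <- !is.na(r$uncertainty_m) & r$uncertainty_m > maxUncertainty
    r <- drop(bad, "high_uncertainty")
  }
  r <- drop(duplicated(r[, c("species", "longitude", "latitude")]),
            "duplicate")
  cell <- paste(r$species,
                floor(r$longitude * 60 / cellMinutes),
                floor(r$latitude * 60 / cellMinutes))
  r <- drop(duplicated(cell), "thinned")
  if (!nrow(r)) warning("no records survive the filter chain")
  stopifnot(sum(counts) == nIn - nrow(r))
  rownames(r) <- NULL
  list(records = r, counts = counts, n_input = nIn, n_output = nrow(r))
}

#' Read an ESRI-ASCII-style grid
#'
#' Plain-text raster: a six-line header (\code{ncols}, \code{nrows},
#' \code{xllcorner}, \code{yllcorner}, \code{cellsize},
#' \code{NODATA_value}) followed by \code{nrows} rows of values, northmost
#' row first.
#'
#' @param path file path.
#' @return list with \code{values} (nrows x ncols matrix, row 1 = north),
#'   \code{ncols}, \code{nrows}, \code{xll}, \code{yll}, \code{cellsize},
#'   \code{nodata}.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  list(values = m, ncols = hdr$ncols, nrows = hdr$nrows,
       xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write an ESRI-ASCII-style grid
#'
#' @param grid a grid list as returned by \code{\link{readAsciiGrid}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeAsciiGrid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncols),
    paste("nrows", grid$nrows),
    paste("xllcorner", format(grid$xll, digits = 15)),
    paste("yllcorner", format(grid$yll, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("NODATA_value", grid$nodata)), con)
  utils::write.table(grid$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Nearest-cell lookup of one grid at lon/lat points; NA outside / nodata.
.gridLookup <- function(grid, lon, lat) {
  xmax <- grid$xll + grid$ncols * grid$cellsize
  ymax <- grid$yll + grid$nrows * grid$cellsize
  outside <- lon < grid$xll | lon > xmax | lat < grid$yll | lat > ymax
  if (any(outside)) {
    stop(sum(outside), " point(s) outside the grid extent")
  }
  col <- pmin(floor((lon - grid$xll) / grid$cellsize) + 1L, grid$ncols)
  rowFromS <- pmin(floor((lat - grid$yll) / grid$cellsize) + 1L, grid$nrows)
  row <- grid$nrows - rowFromS + 1L
  v <- grid$values[cbind(row, col)]
  v[v == grid$nodata] <- NA_real_
  v
}

#' Extract environmental variables at occurrence points
#'
#' Nearest-cell lookup of each gridded layer at each record, then
#' per-species means of each variable. Records falling on nodata cells in
#' any layer are dropped (counted).
#'
#' @param records cleaned occurrence data.frame (species, longitude,
#'   latitude).
#' @param layers named list of grids (see \code{\link{readAsciiGrid}}).
#' @return list with \code{values} (per-record matrix),
#'   \code{speciesMeans} (species x variable matrix), \code{n_nodata}.
#' @export
extractEnv <- function(records, layers) {
  r <- as.data.frame(records)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- paste0("var", seq_along(layers))
  }
  V <- vapply(layers, .gridLookup, numeric(nrow(r)),
              lon = r$longitude, lat = r$latitude)
  if (nrow(r) == 1L) V <- matrix(V, 1, dimnames = list(NULL, names(layers)))
  ok <- stats::complete.cases(V)
  nNodata <- sum(!ok)
  V <- V[ok, , drop = FALSE]
  sp <- r$species[ok]
  means <- rowsum(V, sp) / as.vector(table(sp)[sort(unique(sp))])
  list(values = V, speciesMeans = means, n_nodata = nNodata,
       kept = which(ok))
}

#' Environmental-space PCA
#'
#' Standardizes the species x variable table (z-scores, i.e. a
#' correlation-matrix PCA — the variables are on incommensurable scales),
#' eigen-decomposes, and projects. The first \code{retain} axes define the
#' environmental space for niche position and breadth. Sign convention:
#' each loading vector's largest-magnitude element is made positive.
#'
#' @param x species x variable numeric table.
#' @param retain number of leading axes kept (default 3).
#' @return list with \code{scores} (species x retained axes),
#'   \code{allScores}, \code{loadings}, \code{eigenvalues},
#'   \code{proportion_variance}, \code{cumulative_variance},
#'   \code{retained}.
#' @export
envPCA <- function(x, retain = 3) {
  m <- as.matrix(x)
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop("constant variables: ", paste(colnames(m)[v == 0], collapse = ", "))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  sc <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  retain <- min(retain, ncol(sc))
  list(scores = sc[, seq_len(retain), drop = FALSE],
       allScores = sc, loadings = rot, eigenvalues = ev,
       proportion_variance = ev / ncol(m),
       cumulative_variance = cumsum(ev) / ncol(m),
       retained = retain)
}

#' Niche position: mean on the retained axes
#'
#' @param points n x k matrix of a species' occurrence coordinates in the
#'   environmental PC space.
#' @return numeric vector of per-axis means.
#' @export
nichePosition <- function(points) {
  p <- as.matrix(points)
  if (!nrow(p)) stop("no points")
  colMeans(p)
}

#' Per-species niche table: position and alpha-shape breadth
#'
#' For each species with occurrence scores in the 3D environmental space,
#' computes the niche position (mean on each axis) and, where at least 5
#' distinct non-degenerate points exist, the alpha-shape niche breadth.
#' Species whose breadth cannot be computed are kept with NA breadth and an
#' explicit reason, mirroring the discard rule of alpha-shape niche
#' quantification.
#'
#' @param scores data.frame or matrix of per-record PC coordinates.
#' @param species species label per record.
#' @param alpha circumradius threshold (default 2).
#' @return data.frame with species, n_records, PC means, niche_breadth,
#'   reason (NA when computed).
#' @export
nicheSummary <- function(scores, species, alpha = 2) {
  S <- as.matrix(scores)
  if (ncol(S) != 3) stop("scores must have 3 columns (PC1-PC3)")
  species <- as.character(species)
  out <- lapply(split(seq_len(nrow(S)), species), function(idx) {
    P <- S[idx, , drop = FALSE]
    pos <- nichePosition(P)
    br <- tryCatch(list(v = alphaShapeVolume(P, alpha)$volume, why = NA_character_),
                   error = function(e) list(v = NA_real_, why = conditionMessage(e)))
    data.frame(n_records = nrow(P), PC1 = pos[1], PC2 = pos[2], PC3 = pos[3],
               niche_breadth = br$v, reason = br$why)
  })
  res <- do.call(rbind, out)
  data.frame(species = names(out), res, row.names = NULL)
}
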