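# 3D Delaunay tetrahedralization (Bowyer-Watson) and alpha-shape volume.
# No computational-geometry dependency is used: point clouds here are small
# (tens to a few hundred occurrence points per species), so an O(n^2)
# incremental construction is ample.

# Circumsphere of a tetrahedron (rows of v): center and squared radius.
# Degenerate (coplanar) tetrahedra get r2 = Inf.
.circumsphere <- function(v) {
  A <- 2 * (v[2:4, , drop = FALSE] - matrix(v[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
  ctr <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(ctr) || any(!is.finite(ctr))) {
    return(list(center = c(0, 0, 0), r2 = Inf))
  }
  list(center = ctr, r2 = sum((v[1, ] - ctr)^2))
}

.tetraVolume <- function(v) {
  abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
}

# Randomized-incremental Delaunay tetrahedralization on an n x 3 point
# matrix assumed to be in general position (callers joggle). Returns an
# m x 4 matrix of point indices.
#
# The triangulation carries one symbolic vertex "at infinity" (index n + 1):
# every hull facet bounds an infinite cell. Conflict predicates: a finite
# cell conflicts with a point inside its circumsphere; an infinite cell
# conflicts with a point strictly outside its (outward-oriented) hull
# facet plane -- the visibility rule. Outward orientation is fixed against
# an interior reference point (the centroid of the starting tetrahedron,
# which stays strictly inside the growing hull). Using a finite "super
# tetrahedron" instead of the symbolic vertex would make boundary
# circumspheres finite and punch sliver holes next to nearly coplanar hull
# facets.
.delaunay3d <- function(P) {
  n <- nrow(P)
  INF <- n + 1L
  # well-spread starting tetrahedron (greedy farthest-point choices)
  i1 <- 1L
  d1 <- rowSums(sweep(P, 2, P[i1, ])^2)
  i2 <- which.max(d1)
  e1 <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  crossN2 <- (rel[, 2] * e1[3] - rel[, 3] * e1[2])^2 +
    (rel[, 3] * e1[1] - rel[, 1] * e1[3])^2 +
    (rel[, 1] * e1[2] - rel[, 2] * e1[1])^2
  i3 <- which.max(crossN2)
  e2 <- P[i3, ] - P[i1, ]
  nv0 <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  vol4 <- abs(rel %*% nv0)
  i4 <- which.max(vol4)
  if (vol4[i4] <= 0) stop("degenerate point set")
  first4 <- c(i1, i2, i3, i4)
  c0 <- colMeans(P[first4, ])  # interior for every later hull

  cap <- 8L * n + 64L
  verts <- matrix(0L, cap, 4)
  geomA <- matrix(0, cap, 3)  # circumcenter (finite) / outward normal (inf)
  geomB <- numeric(cap)       # squared radius (finite) / plane offset (inf)
  isInf <- logical(cap)
  alive <- logical(cap)
  nt <- 0L
  addCell <- function(tri, apex) {
    idx <- c(tri, apex)
    if (nt == cap) {
      cap2 <- 2L * cap
      verts <<- rbind(verts, matrix(0L, cap2 - cap, 4))
      geomA <<- rbind(geomA, matrix(0, cap2 - cap, 3))
      geomB <<- c(geomB, numeric(cap2 - cap))
      isInf <<- c(isInf, logical(cap2 - cap))
      alive <<- c(alive, logical(cap2 - cap))
      cap <<- cap2
    }
    nt <<- nt + 1L
    if (any(idx == INF)) {
      fin <- idx[idx != INF]
      a <- P[fin[1], ]
      u <- P[fin[2], ] - a
      w <- P[fin[3], ] - a
      nv <- c(u[2] * w[3] - u[3] * w[2],
              u[3] * w[1] - u[1] * w[3],
              u[1] * w[2] - u[2] * w[1])
      if (sum(nv * (c0 - a)) > 0) nv <- -nv  # point away from the interior
      geomA[nt, ] <<- nv
      geomB[nt] <<- sum(nv * a)
      isInf[nt] <<- TRUE
    } else {
      cs <- .circumsphere(P[idx, ])
      geomA[nt, ] <<- cs$center
      geomB[nt] <<- cs$r2
      isInf[nt] <<- FALSE
    }
    verts[nt, ] <<- idx
    alive[nt] <<- TRUE
  }
  addCell(first4[1:3], first4[4])
  addCell(c(first4[1], first4[2], INF), first4[3])
  addCell(c(first4[1], first4[2], INF), first4[4])
  addCell(c(first4[1], first4[3], INF), first4[4])
  addCell(c(first4[2], first4[3], INF), first4[4])

  for (i in setdiff(seq_len(n), first4)) {
    p <- P[i, ]
    live <- which(alive[seq_len(nt)])
    s <- geomA[live, 1] * p[1] + geomA[live, 2] * p[2] +
      geomA[live, 3] * p[3]
    inf <- isInf[live]
    conflict <- logical(length(live))
    # infinite cell: p strictly beyond the hull facet plane
    conflict[inf] <- s[inf] > geomB[live[inf]]
    # finite cell: p inside the circumsphere
    fin <- !inf
    lf <- live[fin]
    conflict[fin] <- (p[1] - geomA[lf, 1])^2 + (p[2] - geomA[lf, 2])^2 +
      (p[3] - geomA[lf, 3])^2 < geomB[lf]
    bad <- live[conflict]
    if (!length(bad)) stop("point in no conflict region; degenerate input")
    # cavity boundary: faces of conflicting cells appearing exactly once
    f <- rbind(verts[bad, c(1, 2, 3), drop = FALSE],
               verts[bad, c(1, 2, 4), drop = FALSE],
               verts[bad, c(1, 3, 4), drop = FALSE],
               verts[bad, c(2, 3, 4), drop = FALSE])
    lo <- pmin(f[, 1], f[, 2], f[, 3])
    hi <- pmax(f[, 1], f[, 2], f[, 3])
    mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
    key <- (lo * (n + 3) + mid) * (n + 3) + hi
    once <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    for (j in which(once)) addCell(f[j, ], i)
  }
  keep <- which(alive[seq_len(nt)] & !isInf[seq_len(nt)])
  verts[keep, , drop = FALSE]
}

# Sanity checks of a candidate tetrahedralization: every triangular face
# shared by at most two cells, and no point strictly inside any cell's
# circumsphere (the Delaunay empty-sphere property, with a small relative
# slack for rounding).
.validTriangulation <- function(P, tets) {
  if (!nrow(tets)) return(FALSE)
  f <- rbind(tets[, c(1, 2, 3), drop = FALSE],
             tets[, c(1, 2, 4), drop = FALSE],
             tets[, c(1, 3, 4), drop = FALSE],
             tets[, c(2, 3, 4), drop = FALSE])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  if (max(table(key)) > 2) return(FALSE)
  for (k in seq_len(nrow(tets))) {
    cs <- .circumsphere(P[tets[k, ], , drop = FALSE])
    if (!is.finite(cs$r2)) return(FALSE)
    dd <- (P[, 1] - cs$center[1])^2 + (P[, 2] - cs$center[2])^2 +
      (P[, 3] - cs$center[3])^2
    inside <- which(dd < cs$r2 * (1 - 1e-9))
    if (length(setdiff(inside, tets[k, ]))) return(FALSE)
  }
  TRUE
}

#' Alpha-shape volume of a 3D point cloud
#'
#' Delaunay-tetrahedralizes the points and sums the volumes of tetrahedra
#' whose circumsphere radius is at most \code{alpha}; this is the niche
#' breadth used for species occurrence clouds in the 3D environmental PC
#' space. \code{alpha = Inf} gives the convex-hull volume; volume is
#' monotone non-decreasing in alpha. Exact duplicates are removed first.
#'
#' For robustness the triangulation is built on points with a tiny
#' deterministic joggle (1e-9 of the cloud's extent, so cospherical inputs
#' such as box corners triangulate cleanly); volumes and circumradii are
#' evaluated on the original coordinates.
#'
#' @param points n x 3 numeric matrix (n >= 5 after deduplication).
#' @param alpha circumradius threshold, in the units of \code{points}
#'   (default 2, the conventional choice on standardized PC axes).
#' @return list with \code{volume}, \code{n_points}, \code{n_tetrahedra},
#'   \code{n_retained}, \code{alpha}.
#' @export
alphaShapeVolume <- function(points, alpha = 2) {
  P <- as.matrix(points)
  if (ncol(P) != 3) stop("points must be n x 3")
  if (any(!is.finite(P))) stop("non-finite coordinates")
  P <- unique(P)
  n <- nrow(P)
  if (n < 5) stop("alpha shapes need at least 5 distinct points (have ", n, ")")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  s <- max(abs(Pc))
  if (s == 0 || svd(Pc)$d[3] / s < 1e-9) {
    stop("degenerate (coplanar or collinear) point set")
  }
  Ps <- Pc / s
  # The joggle must stay above the rounding noise of circumcenter solves on
  # near-degenerate tetrahedra (condition ~ 1/flatness), or the incremental
  # predicates become inconsistent on gridded/cospherical data. Start tiny
  # for accuracy and escalate only if the resulting triangulation fails
  # validation (empty-sphere property and face-manifold counts on the
  # joggled points); volumes and radii are always evaluated on the
  # unperturbed coordinates.
  jitterU <- withSeed(982451653, matrix(stats::runif(3 * n, -1, 1), n, 3))
  tets <- NULL
  for (jog in c(1e-9, 1e-6, 1e-4)) {
    Pj <- Ps + jitterU * jog
    cand <- tryCatch(.delaunay3d(Pj), error = function(e) NULL)
    if (!is.null(cand) && .validTriangulation(Pj, cand)) {
      tets <- cand
      break
    }
  }
  if (is.null(tets)) {
    stop("could not build a consistent tetrahedralization (degenerate input)")
  }
  m <- nrow(tets)
  vol <- numeric(m)
  rad <- numeric(m)
  for (k in seq_len(m)) {
    v <- P[tets[k, ], , drop = FALSE]
    vol[k] <- .tetraVolume(v)
    rad[k] <- sqrt(.circumsphere(v)$r2)
  }
  keep <- rad <= alpha
  list(volume = sum(vol[keep]), n_points = n, n_tetrahedra = m,
       n_retained = sum(keep), alpha = alpha)
}
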