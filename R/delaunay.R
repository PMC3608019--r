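# Planar Delaunay triangulation (Bowyer-Watson incremental insertion).
# Coordinates are plain lon/lat degrees; the synthetic extents are small
# enough that the planar approximation holds.

# counter-clockwise orientation test (positive when c lies left of a->b)
orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Returns a 2-column matrix of point-index pairs (i < j).
delaunay_edges_xy <- function(x, y) {
  n <- length(x)
  if (n < 2) return(matrix(integer(0), 0, 2))
  if (n == 2) return(matrix(c(1L, 2L), 1, 2))

  # fully collinear inputs degrade to a path along the line
  dx <- x - x[1]; dy <- y - y[1]
  ref <- which.max(dx^2 + dy^2)
  cross <- dx * dy[ref] - dy * dx[ref]
  scale2 <- max(dx^2 + dy^2)
  if (all(abs(cross) < 1e-12 * max(scale2, 1))) {
    ord <- order(dx * dx[ref] + dy * dy[ref])
    return(cbind(pmin(ord[-n], ord[-1]), pmax(ord[-n], ord[-1])))
  }

  # super-triangle enclosing all points; it must dwarf the point cloud or
  # its finite circumcircles distort the triangulation near the convex hull
  cx <- mean(range(x)); cy <- mean(range(y))
  d <- max(diff(range(x)), diff(range(y)), 1e-6) * 1e5
  px <- c(x, cx - 2 * d, cx + 2 * d, cx)
  py <- c(y, cy - d, cy - d, cy + 2 * d)

  # triangles stored CCW; membership tested with the in-circumcircle
  # determinant predicate (numerically stabler than explicit circumcenters)
  as_ccw <- function(a, b, c) {
    if (orient2d(px[a], py[a], px[b], py[b], px[c], py[c]) < 0) c(a, c, b)
    else c(a, b, c)
  }
  tri <- matrix(as_ccw(n + 1L, n + 2L, n + 3L), 1, 3)

  in_circle <- function(p) {
    a <- tri[, 1]; b <- tri[, 2]; c <- tri[, 3]
    adx <- px[a] - px[p]; ady <- py[a] - py[p]
    bdx <- px[b] - px[p]; bdy <- py[b] - py[p]
    cdx <- px[c] - px[p]; cdy <- py[c] - py[p]
    ad2 <- adx^2 + ady^2; bd2 <- bdx^2 + bdy^2; cd2 <- cdx^2 + cdy^2
    adx * (bdy * cd2 - cdy * bd2) -
      ady * (bdx * cd2 - cdx * bd2) +
      ad2 * (bdx * cdy - cdx * bdy)
  }

  for (p in seq_len(n)) {
    det <- in_circle(p)
    bad <- which(det > 0)
    if (!length(bad)) bad <- which.max(det)  # on-circle fallback
    # cavity boundary = edges used exactly once among bad triangles
    eds <- rbind(tri[bad, c(1, 2), drop = FALSE],
                 tri[bad, c(2, 3), drop = FALSE],
                 tri[bad, c(1, 3), drop = FALSE])
    eds <- cbind(pmin(eds[, 1], eds[, 2]), pmax(eds[, 1], eds[, 2]))
    key <- paste(eds[, 1], eds[, 2])
    boundary <- eds[key %in% names(which(table(key) == 1)), , drop = FALSE]

    tri <- tri[-bad, , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      v <- boundary[e, ]
      tri <- rbind(tri, as_ccw(v[1], v[2], p))
    }
  }

  real <- tri[apply(tri <= n, 1, all), , drop = FALSE]
  eds <- rbind(real[, c(1, 2), drop = FALSE], real[, c(2, 3), drop = FALSE],
               real[, c(1, 3), drop = FALSE])
  eds <- cbind(pmin(eds[, 1], eds[, 2]), pmax(eds[, 1], eds[, 2]))
  eds <- unique(eds)
  eds[order(eds[, 1], eds[, 2]), , drop = FALSE]
}

#' Delaunay network over the populations of one species
#'
#' Planar Delaunay triangulation of population coordinates; the resulting
#' edge list is the connectivity network along which among-population genetic
#' divergence is computed. Two populations give a single edge; fully
#' collinear sets give a path graph along the line; duplicate coordinates are
#' jittered by about 1e-6 degrees with a warning.
#'
#' @param populations Data frame with columns `population`, `lon`, `lat`.
#' @return Data frame `from,to` of population-id pairs (undirected, unique).
#' @export
delaunay_network <- function(populations) {
  if (!all(c("population", "lon", "lat") %in% names(populations)))
    stop("populations must have columns population, lon, lat")
  x <- populations$lon
  y <- populations$lat
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    warning("duplicate population coordinates jittered by 1e-6 degrees")
    dup_rank <- stats::ave(seq_along(key), key, FUN = seq_along) - 1
    x <- x + 1e-6 * dup_rank
    y <- y + 1.3e-6 * dup_rank
  }
  eds <- delaunay_edges_xy(x, y)
  data.frame(from = populations$population[eds[, 1]],
             to = populations$population[eds[, 2]],
             stringsAsFactors = FALSE)
}
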