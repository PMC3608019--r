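#' Within-population genetic diversity (mean pairwise differences)
#'
#' The mean number of pairwise nucleotide differences over all unordered
#' pairs of individuals in a population (identical pairs contribute 0).
#' Unresolved sites (`N`, `-`) are excluded pairwise.
#'
#' @param sequences Character vector of aligned sequences (length >= 2).
#' @return The diversity value, in units of nucleotide differences.
#' @export
population_pi <- function(sequences) {
  n <- length(sequences)
  if (n < 2)
    stop("population_pi requires at least 2 sequences")
  cnt <- mismatch_matrices(sequences)$count
  sum(cnt[upper.tri(cnt)]) / (n * (n - 1) / 2)
}

#' Per-population diversity over a whole alignment
#'
#' Populations represented by a single sequence are skipped with a logged
#' message (their diversity would trivially be zero) and reported as `NA`.
#'
#' @param aln An [mtdna_alignment()].
#' @param populations Data frame `population,lon,lat` (coordinates attached
#'   to the value points).
#' @return Data frame `population,species,lon,lat,n,value,kind` with
#'   `kind = "pi"`; singleton populations carry `value = NA`.
#' @export
populations_pi <- function(aln, populations) {
  pops <- unique(aln$population)
  out <- lapply(pops, function(p) {
    sel <- aln$population == p
    n <- sum(sel)
    val <- if (n >= 2) population_pi(aln$sequence[sel]) else {
      message("skipping population '", p, "' for diversity (single sequence)")
      NA_real_
    }
    m <- match(p, populations$population)
    data.frame(population = p, species = aln$species[sel][1],
               lon = populations$lon[m], lat = populations$lat[m],
               n = n, value = val, kind = "pi", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Among-population divergence at Delaunay edge midpoints
#'
#' For each network edge, the mean proportion of mismatched nucleotide sites
#' over all cross-population sequence pairs, positioned at the arithmetic
#' midpoint of the two population coordinates.
#'
#' @param aln An [mtdna_alignment()] (introgressed mtDNA already excluded).
#' @param populations Data frame `population,lon,lat`.
#' @param edges Data frame `from,to` from [delaunay_network()].
#' @return Data frame `from,to,lon,lat,value,kind` with `kind = "zi"`.
#' @export
edge_genetic_distance <- function(aln, populations, edges) {
  if (nrow(edges) == 0)
    return(data.frame(from = character(), to = character(), lon = numeric(),
                      lat = numeric(), value = numeric(), kind = character(),
                      stringsAsFactors = FALSE))
  seqs_by_pop <- split(aln$sequence, aln$population)
  out <- lapply(seq_len(nrow(edges)), function(e) {
    a <- edges$from[e]; b <- edges$to[e]
    sa <- seqs_by_pop[[a]]; sb <- seqs_by_pop[[b]]
    if (is.null(sa) || is.null(sb))
      stop("edge ", a, "-", b, " references a population without sequences")
    prop <- mismatch_matrices(c(sa, sb))$proportion
    z <- mean(prop[seq_along(sa), length(sa) + seq_along(sb)])
    ma <- match(a, populations$population); mb <- match(b, populations$population)
    data.frame(from = a, to = b,
               lon = (populations$lon[ma] + populations$lon[mb]) / 2,
               lat = (populations$lat[ma] + populations$lat[mb]) / 2,
               value = z, kind = "zi", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Each cell takes the weighted mean of its `k` nearest value points with
#' weights `d^-power` (planar Euclidean distance in degrees). A cell whose
#' center coincides with a point (distance < 1e-9) takes that point's value
#' exactly.
#'
#' @param points Data frame with `lon`, `lat`, `value` (rows with `NA` value
#'   are dropped).
#' @param grid A [grid_spec()].
#' @param power Distance decay exponent (> 0); default 2.
#' @param k Number of nearest neighbours used; default 12.
#' @return An [rf_raster()].
#' @export
idw_interpolate <- function(points, grid, power = 2, k = 12) {
  points <- points[!is.na(points$value), , drop = FALSE]
  if (nrow(points) == 0) stop("no value points to interpolate")
  if (power <= 0) stop("power must be positive")
  cc <- cell_centers(grid)
  np <- nrow(points)
  k <- min(k, np)
  D <- outer(cc$lon, points$lon, "-")^2 + outer(cc$lat, points$lat, "-")^2
  D <- sqrt(D)
  vals <- numeric(nrow(cc))
  v <- points$value
  for (i in seq_len(nrow(cc))) {
    d <- D[i, ]
    nb <- if (np > k) order(d)[seq_len(k)] else seq_len(np)
    dn <- d[nb]
    if (dn[which.min(dn)] < 1e-9) {
      vals[i] <- v[nb[which.min(dn)]]
    } else {
      w <- dn^(-power)
      vals[i] <- sum(w * v[nb]) / sum(w)
    }
  }
  rf_raster(matrix(vals, grid$n_rows, grid$n_cols), grid)
}

#' Crop a raster to a range polygon
#'
#' Cells whose centers fall outside the polygon become nodata; inside cells
#' are unchanged. Point-in-polygon follows the even-odd rule, so a list of
#' rings can encode multi-part ranges and holes.
#'
#' @param raster An [rf_raster()].
#' @param polygon A two-column matrix/data frame of ring vertices (lon, lat),
#'   or a list of such rings.
#' @return The cropped [rf_raster()].
#' @export
crop_to_range <- function(raster, polygon) {
  rings <- if (is.data.frame(polygon) || is.matrix(polygon)) list(polygon)
           else polygon
  bnd <- do.call(rbind, lapply(rings, function(r) {
    r <- as.matrix(r)[, 1:2, drop = FALSE]
    rbind(r, c(NA, NA))
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  cc <- cell_centers(raster$grid)
  inside <- mgcv::in.out(bnd, cbind(cc$lon, cc$lat))
  v <- raster$values
  v[cc$cell[!inside]] <- NA
  if (all(is.na(v)))
    warning("polygon is disjoint from the raster; all cells are nodata")
  rf_raster(v, raster$grid)
}

#' Rescale per-species landscapes to a common or species-specific [0,1] scale
#'
#' `"global"` performs min-max scaling over the union of all species'
#' non-nodata cells (making species directly comparable, at the risk that
#' genetically poor species are flattened); `"per_species"` scales each
#' species over its own range (better expressing intraspecific structure).
#' Constant rasters map to 0.5 by convention.
#'
#' @param landscapes Named list of [rf_raster()]s, one per species.
#' @param mode `"global"` or `"per_species"`.
#' @return Named list of rescaled rasters with values in `[0, 1]`.
#' @export
composite_scale <- function(landscapes, mode = c("global", "per_species")) {
  mode <- match.arg(mode)
  if (!length(landscapes)) stop("no landscapes supplied")
  rescale <- function(r, lo, hi) {
    v <- r$values
    v[] <- if (hi - lo < 1e-12) ifelse(is.na(v), NA, 0.5)
           else (v - lo) / (hi - lo)
    rf_raster(v, r$grid)
  }
  if (mode == "global") {
    allv <- unlist(lapply(landscapes, function(r) r$values))
    lo <- min(allv, na.rm = TRUE); hi <- max(allv, na.rm = TRUE)
    lapply(landscapes, rescale, lo = lo, hi = hi)
  } else {
    lapply(landscapes, function(r) {
      v <- r$values[!is.na(r$values)]
      rescale(r, min(v), max(v))
    })
  }
}

#' Refugial contrast of interpolated genetic-diversity surfaces
#'
#' For each species, the difference between the mean interpolated value
#' inside its true refugium and outside it (within the cropped range), after
#' species-specific min-max scaling; the species-specific scale prevents
#' genetically rich species from overwhelming poor ones in the composite,
#' and the per-species contrast avoids weighting species by range area.
#'
#' @param landscapes Named list of cropped [rf_raster()]s (one per species).
#' @param refugium_masks Named list of logical matrices (true refugia).
#' @return List with `per_species` (named vector of contrasts) and `mean`.
#' @export
refugial_contrast <- function(landscapes, refugium_masks) {
  scaled <- composite_scale(landscapes, "per_species")
  d <- vapply(names(scaled), function(sp) {
    r <- scaled[[sp]]$values
    ref <- refugium_masks[[sp]]
    mean(r[ref & !is.na(r)]) - mean(r[!ref & !is.na(r)])
  }, 0)
  list(per_species = d, mean = mean(d))
}
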