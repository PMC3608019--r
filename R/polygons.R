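# Range polygons: GeoJSON IO and mask-to-polygon boundary tracing.

#' Read range polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon/MultiPolygon features; each feature
#' becomes one named entry (name from the `species` or `name` property, else
#' `feature_i`), represented as a list of rings (two-column lon/lat
#' matrices) interpreted under the even-odd rule.
#'
#' @param path GeoJSON file path.
#' @return Named list of polygons (each a list of rings).
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- if (!is.null(f$geometry)) f$geometry else f
    nm <- f$properties$species
    if (is.null(nm)) nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("feature_", i)
    ring_of <- function(rr) {
      m <- do.call(rbind, lapply(rr, function(pt) c(pt[[1]], pt[[2]])))
      colnames(m) <- c("lon", "lat")
      m
    }
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_of),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_of)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    out[[nm]] <- rings
  }
  out
}

#' Write named polygons as a GeoJSON FeatureCollection
#'
#' @param polygons Named list of polygons (each a list of lon/lat rings).
#' @param path Output path.
#' @export
write_geojson_polygons <- function(polygons, path) {
  feats <- lapply(names(polygons), function(nm) {
    rings <- lapply(polygons[[nm]], function(r) {
      r <- as.matrix(r)
      if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])  # close ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(species = nm),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Trace the boundary polygons of a raster mask
#'
#' Converts a logical mask into a list of closed rings following the cell
#' boundaries (even-odd rule compatible: outer boundaries and holes are all
#' emitted as rings). Cropping a raster to the returned polygon reproduces
#' the mask.
#'
#' @param mask Logical matrix (`n_rows x n_cols`, row 1 = north).
#' @param grid The matching [grid_spec()].
#' @return A list of rings (two-column lon/lat matrices).
#' @export
mask_to_polygons <- function(mask, grid) {
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # directed boundary segments on the corner lattice (x in 0..nc, y in 0..nr,
  # y measured from the grid's south edge), inside kept on the left
  segs <- list()
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    if (!mask[r, cl]) next
    y <- nr - r
    if (!inside(r, cl - 1))  # left edge, walk south
      segs[[length(segs) + 1]] <- c(cl - 1, y + 1, cl - 1, y)
    if (!inside(r, cl + 1))  # right edge, walk north
      segs[[length(segs) + 1]] <- c(cl, y, cl, y + 1)
    if (!inside(r + 1, cl))  # bottom edge, walk east
      segs[[length(segs) + 1]] <- c(cl - 1, y, cl, y)
    if (!inside(r - 1, cl))  # top edge, walk west
      segs[[length(segs) + 1]] <- c(cl, y + 1, cl - 1, y + 1)
  }
  if (!length(segs)) return(list())
  S <- do.call(rbind, segs)
  start_key <- paste(S[, 1], S[, 2])
  avail <- rep(TRUE, nrow(S))
  by_start <- split(seq_len(nrow(S)), start_key)
  rings <- list()
  for (s0 in seq_len(nrow(S))) {
    if (!avail[s0]) next
    path <- matrix(S[s0, 1:2], 1, 2)
    cur <- s0
    repeat {
      avail[cur] <- FALSE
      nxt_key <- paste(S[cur, 3], S[cur, 4])
      path <- rbind(path, S[cur, 3:4])
      cand <- by_start[[nxt_key]]
      cand <- cand[avail[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    lon <- grid$origin_lon + path[, 1] * grid$cell_size
    lat <- grid$origin_lat + path[, 2] * grid$cell_size
    rings[[length(rings) + 1]] <- cbind(lon = lon, lat = lat)
  }
  rings
}
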