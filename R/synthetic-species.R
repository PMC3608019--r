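#' Generate a multi-species system with known ranges, refugia and contact zones
#'
#' Each species responds to a subset of climate layers through a product of
#' Gaussian response curves; suitability is rescaled so the best current cell
#' equals 1 (the same factor is applied to the glacial scenario so the two are
#' comparable). The range mask is `suitability >= range_threshold` under
#' current climate; the refugium mask contains cells passing the threshold
#' under BOTH scenarios; the contact zone of a species holds its range cells
#' 8-adjacent to any other species' range.
#'
#' @param stack_pair List with `current` and `glacial` [raster_stack()]s, as
#'   returned by [generate_climate_stack()].
#' @param n_species Number of species (at least 2).
#' @param niche_centers Optional `n_species x length(niche_layers)` matrix of
#'   niche optima (layer units, i.e. standard deviations). Default: drawn at
#'   the climate values of random cells, which guarantees attainable niches.
#' @param niche_breadths Niche tolerance (Gaussian sd) per layer; scalar or
#'   matrix like `niche_centers`.
#' @param niche_layers Names of the layers the niches are defined on (at
#'   least 2).
#' @param range_threshold Suitability cutoff defining the range mask.
#' @param seed Integer seed.
#' @return An object of class `truth_record`: per-species suitability rasters
#'   (current and glacial), range/refugium masks, contact-zone cells, plus
#'   empty slots (`founders`, `introgression`) filled by
#'   [simulate_sequences()].
#' @export
generate_species_system <- function(stack_pair, n_species = 2,
                                    niche_centers = NULL,
                                    niche_breadths = 1,
                                    niche_layers = NULL,
                                    range_threshold = 0.25, seed = 1) {
  cur <- stack_pair$current
  gla <- stack_pair$glacial
  if (n_species < 2) stop("n_species must be at least 2")
  if (is.null(niche_layers)) niche_layers <- utils::head(names(cur$layers), 2)
  if (length(niche_layers) < 2) stop("niches must be defined on >= 2 layers")
  grid <- cur$grid
  ncell <- grid$n_rows * grid$n_cols
  set.seed(seed)
  Vc <- layer_values(cur, vars = niche_layers)
  Vg <- layer_values(gla, vars = niche_layers)
  if (is.null(niche_centers)) {
    anchors <- sample.int(ncell, n_species)
    niche_centers <- Vc[anchors, , drop = FALSE]
  }
  niche_centers <- matrix(niche_centers, n_species, length(niche_layers))
  B <- matrix(niche_breadths, n_species, length(niche_layers))

  species <- paste0("species_", seq_len(n_species))
  suit_cur <- suit_gla <- range_mask <- refug_mask <- list()
  for (s in seq_len(n_species)) {
    g_of <- function(V) {
      z <- sweep(V, 2, niche_centers[s, ])
      z <- sweep(z, 2, B[s, ], "/")
      exp(-0.5 * rowSums(z^2))
    }
    sc <- g_of(Vc)
    sg <- g_of(Vg)
    scale_f <- max(sc)
    if (scale_f <= 0) stop("species ", s, " has zero suitability everywhere; adjust niche_centers or reduce range_threshold")
    sc <- sc / scale_f
    sg <- sg / scale_f
    mc <- matrix(sc, grid$n_rows, grid$n_cols)
    mg <- matrix(sg, grid$n_rows, grid$n_cols)
    rm_ <- mc >= range_threshold
    if (!any(rm_))
      stop("species ", s, " has an empty range mask; reduce range_threshold")
    suit_cur[[species[s]]] <- mc
    suit_gla[[species[s]]] <- mg
    range_mask[[species[s]]] <- rm_
    refug_mask[[species[s]]] <- rm_ & (mg >= range_threshold)
  }

  contact <- list()
  for (s in seq_len(n_species)) {
    others <- Reduce(`|`, range_mask[-s])
    contact[[species[s]]] <- range_mask[[species[s]]] & dilate8(others)
  }

  structure(
    list(species = species, grid = grid,
         niche_layers = niche_layers, niche_centers = niche_centers,
         niche_breadths = B, range_threshold = range_threshold,
         suitability_current = suit_cur, suitability_glacial = suit_gla,
         range_mask = range_mask, refugium_mask = refug_mask,
         contact_zone = contact,
         founders = NULL, introgression = NULL, populations = NULL),
    class = "truth_record")
}

# 8-neighbourhood dilation, excluding the cell itself: TRUE where at least one
# of the 8 neighbours is TRUE.
dilate8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (i in seq_len(nrow(shifts))) {
    dr <- shifts$dr[i]; dc <- shifts$dc[i]
    src_r <- max(1, 1 - dr):min(nr, nr - dr)
    src_c <- max(1, 1 - dc):min(nc, nc - dc)
    out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] |
      mask[src_r, src_c]
  }
  out
}

# Connected components of a logical mask (8-connectivity). Returns an integer
# matrix of component labels (0 = background).
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> %d species on %d x %d grid\n",
              length(x$species), x$grid$n_rows, x$grid$n_cols))
  for (s in x$species)
    cat(sprintf("  %s: range %d cells, refugium %d, contact %d\n", s,
                sum(x$range_mask[[s]]), sum(x$refugium_mask[[s]]),
                sum(x$contact_zone[[s]])))
  if (!is.null(x$introgression))
    cat(sprintf("  planted introgressions: %d\n", nrow(x$introgression)))
  invisible(x)
}
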