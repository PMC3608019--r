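# Sequence simulation: refugial deep structure, star-like expansions, and
# planted mitochondrial introgression at contact zones.

BASES <- c("A", "C", "G", "T")

random_sequence <- function(length) sample(BASES, length, replace = TRUE)

# n single-site Jukes-Cantor substitutions: uniform site, uniform different
# base. Repeated hits at one site are allowed.
mutate_sequence <- function(x, n) {
  if (n <= 0) return(x)
  sites <- sample.int(length(x), n, replace = TRUE)
  for (s in sites) x[s] <- sample(setdiff(BASES, x[s]), 1)
  x
}

# Simulate a within-population genealogy rooted at `founder` and return the
# tip sequences: random coalescent topology, Poisson(mut_rate) substitutions
# per branch.
simulate_population_seqs <- function(founder, n, mut_rate) {
  if (n == 1)
    return(list(mutate_sequence(founder, stats::rpois(1, mut_rate))))
  tr <- ape::rcoal(n)
  tr <- stats::reorder(tr, "cladewise")
  nodeseq <- vector("list", n + tr$Nnode)
  root <- n + 1L
  nodeseq[[root]] <- founder
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    nodeseq[[child]] <- mutate_sequence(nodeseq[[par]],
                                        stats::rpois(1, mut_rate))
  }
  nodeseq[seq_len(n)]
}

#' Simulate aligned sequences over a synthetic species system
#'
#' Each species receives one founder haplotype per refugium patch (connected
#' component of the refugium mask). Populations placed in refugia carry a
#' coalescent-style genealogy with Poisson(`mut_rate`) substitutions per
#' branch (deep structure); populations in postglacially colonised range are
#' seeded from the nearest refugium founder with 0-2 private substitutions
#' each (star-like purity). Individuals in populations at or next to a
#' contact zone carry the neighbouring species' local haplotype with
#' probability `introgression_prob`; every such replacement is logged in the
#' truth record. An outgroup sequence is emitted for downstream rooting.
#'
#' @param truth A `truth_record` from [generate_species_system()].
#' @param n_pops_per_species Populations per species.
#' @param n_per_pop Individuals per population.
#' @param seq_length Alignment length in sites (>= 100).
#' @param mut_rate Expected substitutions per genealogy branch.
#' @param introgression_prob Per-individual replacement probability in
#'   contact-zone populations.
#' @param species_divergence Substitutions between the common ancestor and
#'   each species' ancestral haplotype (controls inter-species divergence).
#' @param founder_depth Branch count separating a refugium-patch founder from
#'   the species ancestor (expected substitutions = `founder_depth*mut_rate`).
#' @param outgroup_divergence Substitutions between the common ancestor and
#'   the outgroup sequence.
#' @param seed Integer seed.
#' @return A list: `alignment` ([mtdna_alignment()]), `populations` (data
#'   frame `population,species,lon,lat,class`), `outgroup` (named sequence
#'   string), and `truth` (input record with `founders`, `introgression`,
#'   `populations` and `haplotypes_by_species` filled in).
#' @export
simulate_sequences <- function(truth, n_pops_per_species = 12, n_per_pop = 6,
                               seq_length = 658, mut_rate = 1.5,
                               introgression_prob = 0.5,
                               species_divergence = 30, founder_depth = 2,
                               outgroup_divergence = 80, seed = 1) {
  if (seq_length < 100) stop("seq_length must be at least 100")
  set.seed(seed)
  grid <- truth$grid
  root <- random_sequence(seq_length)

  pop_rows <- list()
  ind_rows <- list()
  founders <- list()
  for (s in truth$species) {
    anc <- mutate_sequence(root, species_divergence)
    refug <- truth$refugium_mask[[s]]
    range_cells <- which(truth$range_mask[[s]])
    if (n_pops_per_species > length(range_cells))
      stop("species ", s, ": requested ", n_pops_per_species,
           " populations but range has only ", length(range_cells), " cells")
    lab <- connected_components(refug)
    n_patch <- max(lab)
    if (n_patch == 0L) {
      # no cell habitable under both scenarios: fall back to a single
      # pseudo-refugium at the best current cell
      best <- which.max(truth$suitability_current[[s]])
      lab[best] <- 1L
      n_patch <- 1L
    }
    patch_cells <- lapply(seq_len(n_patch), function(k) which(lab == k))
    sp_founders <- lapply(seq_len(n_patch), function(k)
      mutate_sequence(anc, stats::rpois(1, founder_depth * mut_rate)))
    founders[[s]] <- list(patch_cells = patch_cells,
                          sequences = vapply(sp_founders, paste, "",
                                             collapse = ""))

    n_ref <- min(ceiling(n_pops_per_species / 3), n_pops_per_species)
    # refugial populations sit away from the contact front where possible:
    # refugia retain long-term residents, while introgression is a feature
    # of the postglacially (re)colonised margin
    contact_rc <- which(truth$contact_zone[[s]], arr.ind = TRUE)
    away_from_contact <- function(cells) {
      if (!nrow(contact_rc) || !length(cells)) return(cells)
      cc <- cell_centers(grid, cells)
      cheb <- vapply(seq_along(cells), function(i)
        min(pmax(abs(contact_rc[, 1] - cc$row[i]),
                 abs(contact_rc[, 2] - cc$col[i]))), 0)
      safe <- cells[cheb > 1]
      if (length(safe)) safe else cells
    }
    # assign refugial populations round-robin over patches, largest first
    # (single-cell patches are thresholding noise and only host populations
    # when the refugial quota exceeds the number of sizeable patches)
    patch_order <- order(lengths(patch_cells), decreasing = TRUE)
    patch_of_pop <- rep(patch_order, length.out = n_ref)
    used <- integer(0)
    ref_cell <- integer(n_ref)
    for (i in seq_len(n_ref)) {
      cand <- away_from_contact(setdiff(patch_cells[[patch_of_pop[i]]], used))
      if (!length(cand)) cand <- away_from_contact(setdiff(which(lab > 0), used))
      if (!length(cand)) cand <- setdiff(range_cells, used)
      ref_cell[i] <- if (length(cand) == 1) cand else sample(cand, 1)
      used <- c(used, ref_cell[i])
    }
    exp_pool <- setdiff(range_cells[!(range_cells %in% which(lab > 0))], used)
    n_exp <- n_pops_per_species - n_ref
    if (n_exp > length(exp_pool)) {
      extra <- setdiff(range_cells, c(used, exp_pool))
      exp_pool <- c(exp_pool, extra)
    }
    exp_cell <- if (n_exp > 0) sample(exp_pool, n_exp) else integer(0)

    cells <- c(ref_cell, exp_cell)
    classes <- rep(c("refugium", "expansion"), c(n_ref, n_exp))
    cc <- cell_centers(grid, cells)
    centers_of_patch <- lapply(patch_cells, function(pc) cell_centers(grid, pc))
    for (p in seq_along(cells)) {
      pid <- sprintf("%s_p%02d", s, p)
      if (classes[p] == "refugium") {
        founder <- sp_founders[[patch_of_pop[p]]]
        seqs <- simulate_population_seqs(founder, n_per_pop, mut_rate)
      } else {
        # nearest patch founder, by distance to the closest patch cell
        d <- vapply(centers_of_patch, function(pc)
          min((pc$lon - cc$lon[p])^2 + (pc$lat - cc$lat[p])^2), 0)
        founder <- sp_founders[[which.min(d)]]
        # 0-2 private substitutions per colonist (star-like purity); none at
        # all when the clock is switched off entirely
        seqs <- lapply(seq_len(n_per_pop), function(i)
          mutate_sequence(founder, if (mut_rate > 0) sample(0:2, 1) else 0L))
      }
      pop_rows[[pid]] <- data.frame(
        population = pid, species = s, lon = cc$lon[p], lat = cc$lat[p],
        row = cc$row[p], col = cc$col[p], class = classes[p],
        stringsAsFactors = FALSE)
      for (i in seq_len(n_per_pop)) {
        iid <- sprintf("%s_i%d", pid, i)
        ind_rows[[iid]] <- list(individual = iid, population = pid,
                                species = s, row = cc$row[p], col = cc$col[p],
                                seq = seqs[[i]])
      }
    }
  }
  pops <- do.call(rbind, pop_rows)
  rownames(pops) <- NULL

  # pre-introgression haplotype pool per species (ground truth for donors)
  seq_str <- vapply(ind_rows, function(r) paste(r$seq, collapse = ""), "")
  ind_species <- vapply(ind_rows, `[[`, "", "species")
  ind_pop <- vapply(ind_rows, `[[`, "", "population")
  haps_by_species <- lapply(split(seq_str, ind_species), unique)

  # plant introgression: individuals in populations within one cell of their
  # species' contact zone swap to the nearest foreign population's haplotype
  intro <- list()
  if (introgression_prob > 0) {
    contact_rc <- lapply(truth$species, function(s) which(truth$contact_zone[[s]], arr.ind = TRUE))
    names(contact_rc) <- truth$species
    for (k in seq_along(ind_rows)) {
      r <- ind_rows[[k]]
      crc <- contact_rc[[r$species]]
      if (!nrow(crc)) next
      cheb <- min(pmax(abs(crc[, 1] - r$row), abs(crc[, 2] - r$col)))
      if (cheb > 1) next
      if (stats::runif(1) >= introgression_prob) next
      other <- pops[pops$species != r$species, ]
      d2 <- (other$row - r$row)^2 + (other$col - r$col)^2
      donor_pop <- other$population[which.min(d2)]
      donor_members <- which(ind_pop == donor_pop)
      donor_ind <- donor_members[sample.int(length(donor_members), 1)]
      ind_rows[[k]]$seq <- strsplit(seq_str[donor_ind], "")[[1]]
      intro[[length(intro) + 1]] <- data.frame(
        individual = r$individual, species = r$species,
        population = r$population,
        donor_species = ind_species[donor_ind],
        donor_individual = names(ind_rows)[donor_ind],
        stringsAsFactors = FALSE)
    }
  }
  intro <- if (length(intro)) do.call(rbind, intro) else
    data.frame(individual = character(), species = character(),
               population = character(), donor_species = character(),
               donor_individual = character(), stringsAsFactors = FALSE)

  aln <- mtdna_alignment(
    vapply(ind_rows, `[[`, "", "individual"),
    vapply(ind_rows, `[[`, "", "population"),
    vapply(ind_rows, `[[`, "", "species"),
    vapply(ind_rows, function(r) paste(r$seq, collapse = ""), ""))

  outgroup <- paste(mutate_sequence(root, outgroup_divergence), collapse = "")
  names(outgroup) <- "outgroup"

  truth$founders <- founders
  truth$introgression <- intro
  truth$populations <- pops
  truth$haplotypes_by_species <- haps_by_species

  list(alignment = aln,
       populations = pops[, c("population", "species", "lon", "lat", "class")],
       outgroup = outgroup, truth = truth)
}

#' Sample occurrence localities proportional to suitability
#'
#' Cell centers are drawn without replacement with probability proportional
#' to suitability; only strictly positive cells are eligible.
#'
#' @param suitability An [rf_raster()] of suitability values.
#' @param n_points Number of localities to draw.
#' @param seed Integer seed.
#' @param jitter If `TRUE`, points are jittered uniformly within their cell.
#' @return Data frame `lon,lat,cell,row,col`.
#' @export
sample_occurrences <- function(suitability, n_points, seed = 1,
                               jitter = FALSE) {
  v <- as.vector(suitability$values)
  pos <- which(!is.na(v) & v > 0)
  if (!length(pos)) stop("suitability has no positive cells")
  if (n_points > length(pos))
    stop("n_points (", n_points, ") exceeds positive-suitability cells (",
         length(pos), ")")
  set.seed(seed)
  take <- pos[sample.int(length(pos), n_points, prob = v[pos])]
  cc <- cell_centers(suitability$grid, take)
  if (jitter) {
    half <- suitability$grid$cell_size / 2
    cc$lon <- cc$lon + stats::runif(n_points, -half, half)
    cc$lat <- cc$lat + stats::runif(n_points, -half, half)
  }
  cc[, c("lon", "lat", "cell", "row", "col")]
}
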