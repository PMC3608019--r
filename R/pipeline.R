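#' Default run configuration for the synthetic study system
#'
#' One structured list drives simulation and both analysis stages; every
#' parameter is echoed into the run manifests for provenance. The defaults
#' define the package's reference study conditions: a 60 x 60 grid of
#' 0.05-degree cells, four equicorrelated climate layers with a glacial
#' shift on the first niche layer, two parapatric species, 55 populations of
#' 5 individuals each per species on a 658-site locus (mirroring the
#' sampling density of a dense multi-species survey), and contact-zone
#' introgression at probability 0.5.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    grid = list(n_rows = 60, n_cols = 60, origin_lon = 0, origin_lat = 40,
                cell_size = 0.05),
    climate = list(n_layers = 4, autocorr_length = 6, inter_layer_corr = 0.2,
                   glacial_shift = c(-1.2, 0, 0.5, 0)),
    species = list(n_species = 2, niche_breadths = 0.8,
                   range_threshold = 0.3),
    sequences = list(n_pops_per_species = 55, n_per_pop = 5,
                     seq_length = 658, mut_rate = 1.5,
                     introgression_prob = 0.5, species_divergence = 30,
                     founder_depth = 2, outgroup_divergence = 80),
    occurrences = list(n_per_species = 40),
    tree = list(bootstrap = 100, support_threshold = 80),
    landscape = list(idw_power = 2, idw_k = 12, exclusion = "population"),
    sdm = list(n_background = 500, buffer_km = 200, n_knots = 10, beta = 1,
               n_null = 99, screen_threshold = 0.7))
}

# Niche anchor selection in environment space. Species' range masks are
# environmental balls of radius breadth*sqrt(2*ln(1/threshold)); anchors are
# chosen so consecutive species sit slightly closer than two radii apart,
# which makes ranges parapatric (adjacent, with a contact band) rather than
# coincident or disjoint.
pick_anchors <- function(V, n_species, breadth, threshold) {
  radius <- breadth * sqrt(2 * log(1 / threshold))
  target <- 1.4 * radius  # < 2*radius: masks overlap in a narrow band
  cand <- sample.int(nrow(V), min(400, nrow(V)))
  sel <- cand[1]
  for (k in seq_len(n_species - 1)) {
    d <- vapply(cand, function(i)
      sqrt(min(colSums((t(V[sel, , drop = FALSE]) - V[i, ])^2))), 0)
    sel <- c(sel, cand[which.min(abs(d - target))])
  }
  sel
}

#' Generate and write a full synthetic input bundle
#'
#' Runs the whole synthetic-data module under one configuration and writes a
#' self-contained directory consumable by [run_phylogeography()] and
#' [run_sdm()]: aligned FASTA (+outgroup), population and locality CSVs,
#' current and glacial ESRI ASCII rasters, range polygons as GeoJSON, and
#' the truth record as JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [default_config()]-style list.
#' @return Invisibly, the in-memory bundle: `stacks`, `truth`, `alignment`,
#'   `populations`, `outgroup`, `localities`, `ranges`.
#' @export
simulate_bundle <- function(out_dir, config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- do.call(grid_spec, config$grid)
  cl <- config$climate
  stacks <- generate_climate_stack(g, cl$n_layers, cl$autocorr_length,
                                   cl$inter_layer_corr, cl$glacial_shift,
                                   seed = config$seed)
  sp <- config$species
  niche_layers <- utils::head(names(stacks$current$layers), 2)
  set.seed(config$seed + 1)
  V <- layer_values(stacks$current, vars = niche_layers)
  anchors <- pick_anchors(V, sp$n_species, sp$niche_breadths,
                          sp$range_threshold)
  truth <- generate_species_system(stacks, sp$n_species,
                                   niche_centers = V[anchors, , drop = FALSE],
                                   niche_breadths = sp$niche_breadths,
                                   niche_layers = niche_layers,
                                   range_threshold = sp$range_threshold,
                                   seed = config$seed + 1)
  sq <- config$sequences
  sim <- simulate_sequences(truth, sq$n_pops_per_species, sq$n_per_pop,
                            sq$seq_length, sq$mut_rate,
                            sq$introgression_prob, sq$species_divergence,
                            sq$founder_depth, sq$outgroup_divergence,
                            seed = config$seed + 2)
  truth <- sim$truth

  # occurrence localities per species, suitability-biased
  localities <- list()
  for (i in seq_along(truth$species)) {
    s <- truth$species[i]
    suit <- rf_raster(truth$suitability_current[[s]], g)
    localities[[s]] <- sample_occurrences(suit, config$occurrences$n_per_species,
                                          seed = config$seed + 10 + i)
  }

  ranges <- lapply(truth$species, function(s)
    mask_to_polygons(truth$range_mask[[s]], g))
  names(ranges) <- truth$species

  # ---- write everything ----
  write_alignment_fasta(sim$alignment, file.path(out_dir, "alignment.fasta"))
  writeLines(c(">outgroup", unname(sim$outgroup)),
             file.path(out_dir, "outgroup.fasta"))
  ind_meta <- sim$alignment[, c("individual", "population", "species")]
  pm <- match(ind_meta$population, sim$populations$population)
  ind_meta$lon <- sim$populations$lon[pm]
  ind_meta$lat <- sim$populations$lat[pm]
  utils::write.csv(ind_meta, file.path(out_dir, "populations.csv"),
                   row.names = FALSE)
  for (s in truth$species)
    utils::write.csv(localities[[s]],
                     file.path(out_dir, paste0("localities_", s, ".csv")),
                     row.names = FALSE)
  utils::write.csv(do.call(rbind, localities),
                   file.path(out_dir, "localities_genus.csv"),
                   row.names = FALSE)
  for (nm in names(stacks$current$layers)) {
    write_ascii_grid(rf_raster(stacks$current$layers[[nm]], g),
                     file.path(out_dir, paste0("current_", nm, ".asc")))
    write_ascii_grid(rf_raster(stacks$glacial$layers[[nm]], g),
                     file.path(out_dir, paste0("lgm_", nm, ".asc")))
  }
  write_geojson_polygons(ranges, file.path(out_dir, "ranges.geojson"))
  truth_json <- list(
    species = truth$species,
    introgression = truth$introgression,
    populations = truth$populations,
    range_cells = lapply(truth$range_mask, which),
    refugium_cells = lapply(truth$refugium_mask, which),
    contact_cells = lapply(truth$contact_zone, which),
    founder_haplotypes = lapply(truth$founders, `[[`, "sequences"))
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(stacks = stacks, truth = truth, alignment = sim$alignment,
                 populations = sim$populations, outgroup = sim$outgroup,
                 localities = localities, ranges = ranges, grid = g,
                 config = config))
}

#' Run the genetic (phylogeographic) stage end to end
#'
#' Read, collapse, tree + bootstrap + root, assign lineages, flag and
#' exclude introgressed mtDNA, then per species compute diversity (pi) and
#' divergence (Z_i) points, interpolate by IDW, crop to the species range
#' and assemble composite surfaces under both scaling modes. All
#' intermediates are written under `out_dir`; the returned manifest records
#' the per-species retention counts (kept-for-pi, kept-for-Z_i, total).
#'
#' @param input_dir Directory produced by [simulate_bundle()] (or
#'   equivalently structured real data).
#' @param out_dir Output directory.
#' @param config A [default_config()]-style list (tree/landscape sections
#'   used).
#' @return The manifest list (also written as `manifest_phylogeo.json`).
#' @export
run_phylogeography <- function(input_dir, out_dir,
                               config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_alignment(file.path(input_dir, "alignment.fasta"),
                        file.path(input_dir, "populations.csv"))
  aln <- inp$alignment
  pops <- inp$populations
  og <- ape::read.FASTA(file.path(input_dir, "outgroup.fasta"))
  og_seq <- toupper(paste(as.character(og)[[1]], collapse = ""))
  og_label <- names(og)[1]

  haps <- collapse_haplotypes(aln)
  hap_seqs <- stats::setNames(haps$haplotypes$sequence,
                              haps$haplotypes$haplotype)
  all_seqs <- c(hap_seqs, stats::setNames(og_seq, og_label))
  d <- p_distance_matrix(all_seqs)
  tree <- nj_tree(d)
  B <- config$tree$bootstrap
  if (B > 0)
    tree <- bootstrap_support(all_seqs, tree, B = B,
                              seed = config$seed + 20)
  rooted <- root_with_outgroup(tree, og_label)
  haps <- assign_lineages(rooted, haps, outgroup = og_label)
  flags <- flag_introgression(haps)

  ape::write.tree(rooted, file.path(out_dir, "haplotypes.nwk"))
  utils::write.csv(flags$individuals,
                   file.path(out_dir, "introgression_flags.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(haps$assignment$lineage),
                    haps$assignment$haplotype),
    file.path(out_dir, "lineages.json"), auto_unbox = TRUE)

  kept <- exclude_introgressed(aln, flags, config$landscape$exclusion)
  grid <- read_ascii_grid(list.files(input_dir, "^current_.*\\.asc$",
                                     full.names = TRUE)[1])$grid
  ranges <- read_geojson_polygons(file.path(input_dir, "ranges.geojson"))

  species <- sort(unique(aln$species))
  pi_land <- zi_land <- list()
  manifest_species <- list()
  all_points <- list()
  for (s in species) {
    sub <- kept[kept$species == s, , drop = FALSE]
    attr(sub, "aln_length") <- attr(kept, "aln_length")
    class(sub) <- class(kept)
    total <- length(unique(aln$population[aln$species == s]))
    sp_pops <- pops[pops$population %in% unique(sub$population), ,
                    drop = FALSE]
    kept_zi <- nrow(sp_pops)
    if (kept_zi == 0) {
      manifest_species[[s]] <- list(total = total, kept_zi = 0, kept_pi = 0)
      next
    }
    pi_pts <- populations_pi(sub, sp_pops)
    kept_pi <- sum(!is.na(pi_pts$value))
    zi_pts <- if (kept_zi >= 2) {
      edges <- delaunay_network(sp_pops)
      edge_genetic_distance(sub, sp_pops, edges)
    } else {
      data.frame(from = character(), to = character(), lon = numeric(),
                 lat = numeric(), value = numeric(), kind = character())
    }
    all_points[[s]] <- list(pi = pi_pts, zi = zi_pts)
    rng <- ranges[[s]]
    if (is.null(rng)) rng <- ranges[[1]]
    if (kept_pi >= 1)
      pi_land[[s]] <- crop_to_range(
        idw_interpolate(pi_pts, grid, config$landscape$idw_power,
                        config$landscape$idw_k), rng)
    if (nrow(zi_pts) >= 1)
      zi_land[[s]] <- crop_to_range(
        idw_interpolate(zi_pts, grid, config$landscape$idw_power,
                        config$landscape$idw_k), rng)
    utils::write.csv(pi_pts, file.path(out_dir, paste0("pi_points_", s, ".csv")),
                     row.names = FALSE)
    utils::write.csv(zi_pts, file.path(out_dir, paste0("zi_points_", s, ".csv")),
                     row.names = FALSE)
    manifest_species[[s]] <- list(total = total, kept_zi = kept_zi,
                                  kept_pi = kept_pi)
  }

  for (kind in c("pi", "zi")) {
    lands <- if (kind == "pi") pi_land else zi_land
    if (!length(lands)) next
    for (mode in c("global", "per_species")) {
      scaled <- composite_scale(lands, mode)
      for (s in names(scaled))
        write_ascii_grid(scaled[[s]],
                         file.path(out_dir, sprintf("%s_%s_%s.asc", kind, s,
                                                    mode)))
    }
    for (s in names(lands))
      write_ascii_grid(lands[[s]],
                       file.path(out_dir, sprintf("%s_%s_raw.asc", kind, s)))
  }

  manifest <- list(
    n_individuals = nrow(aln),
    n_haplotypes = nrow(haps$haplotypes),
    n_introgressed = sum(flags$individuals$status == "introgressed"),
    monophyly = as.list(attr(haps$assignment, "monophyly")),
    exclusion_mode = config$landscape$exclusion,
    species = manifest_species,
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest_phylogeo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$landscapes <- list(pi = pi_land, zi = zi_land)
  manifest$flags <- flags
  manifest$points <- all_points
  manifest$tree <- rooted
  invisible(manifest)
}

# Read the scenario raster stacks written by simulate_bundle().
read_scenario_stacks <- function(input_dir) {
  out <- list()
  for (scen in c("current", "lgm")) {
    files <- list.files(input_dir, paste0("^", scen, "_.*\\.asc$"),
                        full.names = TRUE)
    if (!length(files)) next
    layers <- list()
    g <- NULL
    for (f in files) {
      r <- read_ascii_grid(f)
      nm <- sub("\\.asc$", "", sub(paste0("^", scen, "_"), "", basename(f)))
      layers[[nm]] <- r$values
      g <- r$grid
    }
    out[[scen]] <- raster_stack(layers, g, scen)
  }
  out
}

#' Run the species-distribution-modeling stage end to end
#'
#' Variable screening, buffered background construction, per-species
#' hinge-feature entropy model fitting, the 99-replicate null-model AUC
#' test, projection onto every scenario stack, cropping to species ranges
#' and composite assembly. Models failing the null test are flagged in the
#' manifest.
#'
#' @param input_dir Directory produced by [simulate_bundle()].
#' @param out_dir Output directory.
#' @param config A [default_config()]-style list (`sdm` section used).
#' @return The manifest list (written as `manifest_sdm.json`).
#' @export
run_sdm <- function(input_dir, out_dir, config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stacks <- read_scenario_stacks(input_dir)
  if (!"current" %in% names(stacks)) stop("no current-scenario rasters found")
  cur <- stacks$current
  sc <- config$sdm
  genus <- utils::read.csv(file.path(input_dir, "localities_genus.csv"))
  bg <- build_background(genus, cur, sc$buffer_km, sc$n_background,
                         seed = config$seed + 30)
  vars <- screen_variables(cur, bg$cells$cell, sc$screen_threshold)
  ranges <- read_geojson_polygons(file.path(input_dir, "ranges.geojson"))

  loc_files <- list.files(input_dir, "^localities_.*\\.csv$",
                          full.names = TRUE)
  loc_files <- loc_files[!grepl("genus", loc_files)]
  species <- sub("^localities_(.*)\\.csv$", "\\1", basename(loc_files))

  manifest_species <- list()
  proj <- list()
  models <- list()
  for (i in seq_along(species)) {
    s <- species[i]
    loc <- utils::read.csv(loc_files[i])
    model <- fit_entropy_model(loc, bg, cur, vars = vars,
                               n_knots = sc$n_knots, beta = sc$beta)
    nt <- null_model_test(loc, bg, cur, vars = vars, n_knots = sc$n_knots,
                          beta = sc$beta, n_null = sc$n_null,
                          seed = config$seed + 40 + i)
    models[[s]] <- model
    jsonlite::write_json(
      list(vars = model$vars, weights = model$weights,
           features = model$features, logZ = model$logZ,
           entropy = model$entropy, beta = model$beta),
      file.path(out_dir, paste0("model_", s, ".json")), digits = NA)
    utils::write.csv(data.frame(replicate = seq_along(nt$null),
                                auc = nt$null),
                     file.path(out_dir, paste0("null_aucs_", s, ".csv")),
                     row.names = FALSE)
    rng <- ranges[[s]]
    for (scen in names(stacks)) {
      p <- project_model(model, stacks[[scen]])
      cropped <- if (!is.null(rng)) crop_to_range(p$logistic, rng)
                 else p$logistic
      proj[[scen]][[s]] <- cropped
      write_ascii_grid(p$logistic,
                       file.path(out_dir, sprintf("sdm_%s_%s_full.asc", s,
                                                  scen)))
    }
    manifest_species[[s]] <- list(
      auc = nt$observed, null_rank = nt$rank, significant = nt$significant,
      n_presence = model$n_presence, active_features =
        sum(abs(model$weights) > 1e-8))
  }

  for (scen in names(proj)) {
    for (mode in c("global", "per_species")) {
      scaled <- composite_scale(proj[[scen]], mode)
      for (s in names(scaled))
        write_ascii_grid(scaled[[s]],
                         file.path(out_dir, sprintf("sdm_%s_%s_%s.asc", s,
                                                    scen, mode)))
    }
  }

  manifest <- list(vars_retained = vars,
                   n_background = nrow(bg$cells),
                   buffer_km = bg$buffer_km,
                   species = manifest_species,
                   config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest_sdm.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$projections <- proj
  manifest$models <- models
  invisible(manifest)
}
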