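# Independent brute-force oracles used by the tests. These deliberately avoid
# the package's own code paths: plain loops and textbook formulas only.

# mismatches / compared sites between two sequence strings, pairwise deletion
oracle_pair_diff <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  mm <- 0L; comp <- 0L
  for (i in seq_along(x)) {
    if (x[i] %in% c("A", "C", "G", "T") && y[i] %in% c("A", "C", "G", "T")) {
      comp <- comp + 1L
      if (x[i] != y[i]) mm <- mm + 1L
    }
  }
  c(mismatches = mm, compared = comp)
}

# mean pairwise difference count over all unordered pairs
oracle_pi <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + oracle_pair_diff(seqs[i], seqs[j])["mismatches"]
  tot / (n * (n - 1) / 2)
}

# mean cross-pair mismatch proportion between two sequence sets
oracle_zi <- function(sa, sb) {
  tot <- 0
  for (a in sa) for (b in sb) {
    d <- oracle_pair_diff(a, b)
    tot <- tot + d["mismatches"] / d["compared"]
  }
  tot / (length(sa) * length(sb))
}

# Delaunay edges by empty-circumcircle enumeration over all triples; points
# must be in general position (no 4 co-circular, no 3 collinear).
oracle_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    D <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) +
                x[k] * (y[i] - y[j]))
    if (abs(D) < 1e-12) next
    ux <- ((x[i]^2 + y[i]^2) * (y[j] - y[k]) +
             (x[j]^2 + y[j]^2) * (y[k] - y[i]) +
             (x[k]^2 + y[k]^2) * (y[i] - y[j])) / D
    uy <- ((x[i]^2 + y[i]^2) * (x[k] - x[j]) +
             (x[j]^2 + y[j]^2) * (x[i] - x[k]) +
             (x[k]^2 + y[k]^2) * (x[j] - x[i])) / D
    r2 <- (x[i] - ux)^2 + (y[i] - uy)^2
    empty <- TRUE
    for (p in seq_len(n)) {
      if (p %in% c(i, j, k)) next
      if ((x[p] - ux)^2 + (y[p] - uy)^2 < r2 * (1 - 1e-9)) {
        empty <- FALSE
        break
      }
    }
    if (empty)
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# even-odd ray casting for a single ring (matrix of vertices)
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

oracle_point_in_polygon <- function(px, py, rings) {
  crossings <- vapply(rings, function(r) oracle_point_in_ring(px, py, r), TRUE)
  sum(crossings) %% 2 == 1
}

# random sequences over ACGT
random_seqs <- function(n, L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
}

# a tiny two-species study system built in memory (no files); small sizes
# keep unit tests quick while exercising the same generator path as the
# full bundle
tiny_system <- function(seed = 1, n_rows = 40, n_cols = 40,
                        n_pops = 14, n_per_pop = 4) {
  g <- grid_spec(n_rows, n_cols, cell_size = 0.05)
  st <- generate_climate_stack(g, 3, 5, 0.1, c(-1.2, 0, 0), seed = seed)
  set.seed(seed + 1)
  V <- layer_values(st$current, vars = c("env1", "env2"))
  cand <- sample.int(nrow(V), 200)
  sel <- cand[1]
  radius <- 0.8 * sqrt(2 * log(1 / 0.3))
  d <- sqrt(colSums((t(V[cand, ]) - V[sel, ])^2))
  sel <- c(sel, cand[which.min(abs(d - 1.4 * radius))])
  truth <- generate_species_system(st, 2, niche_centers = V[sel, ],
                                   niche_breadths = 0.8,
                                   niche_layers = c("env1", "env2"),
                                   range_threshold = 0.3, seed = seed + 1)
  sim <- simulate_sequences(truth, n_pops_per_species = n_pops,
                            n_per_pop = n_per_pop, seq_length = 300,
                            mut_rate = 1.5, introgression_prob = 0.5,
                            seed = seed + 2)
  c(sim, list(stacks = st, grid = g))
}
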