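test_that("within-population diversity matches brute-force enumeration", {
  s <- "ACGTACGT"
  t2 <- "ACGAACGA"  # differs from s at sites 4 and 8
  expect_equal(population_pi(c(s, s)), 0)
  expect_equal(population_pi(c(s, t2)), 2)
  # {s, s, t} -> pairs (0, 2, 2) -> 4/3
  expect_equal(population_pi(c(s, s, t2)), 4 / 3)
  expect_error(population_pi("ACGT"), "at least 2")
})

test_that("diversity equals the haplotype-frequency-weighted form", {
  set.seed(41)
  for (rep in 1:20) {
    seqs <- sample(random_seqs(3, 30), 7, replace = TRUE)
    # frequency-weighted oracle: sum p_i p_j d_ij over ordered pairs of
    # distinct haplotypes, times n^2/(n(n-1)/2)/2
    uniq <- unique(seqs)
    n <- length(seqs)
    tot <- 0
    if (length(uniq) > 1) {
      for (i in seq_along(uniq)) for (j in seq_along(uniq)) {
        if (i == j) next
        ni <- sum(seqs == uniq[i]); nj <- sum(seqs == uniq[j])
        dij <- oracle_pair_diff(uniq[i], uniq[j])["mismatches"]
        tot <- tot + ni * nj * dij
      }
    }
    expected <- tot / 2 / (n * (n - 1) / 2)
    expect_equal(population_pi(seqs), unname(expected))
  }
})

test_that("diversity is invariant to sequence order", {
  set.seed(42)
  seqs <- random_seqs(6, 50)
  expect_equal(population_pi(seqs), population_pi(rev(seqs)))
  expect_equal(population_pi(seqs), population_pi(sample(seqs)))
})

test_that("singleton populations are skipped with a message, not an error", {
  aln <- mtdna_alignment(c("i1", "i2", "i3"), c("p1", "p1", "p2"),
                         rep("s", 3), c("ACGT", "ACGA", "ACGT"))
  pops <- data.frame(population = c("p1", "p2"), lon = c(0, 1),
                     lat = c(0, 1))
  expect_message(pts <- populations_pi(aln, pops), "p2")
  expect_equal(pts$value[pts$population == "p1"], 1)
  expect_true(is.na(pts$value[pts$population == "p2"]))
})

test_that("edge divergence equals the cross-pair mean at the midpoint", {
  L <- 658
  base <- random_seqs(1, L)
  flip_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(k)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  s5 <- flip_at(base, 5)
  s4 <- flip_at(base, 4)
  aln <- mtdna_alignment(c("a1", "b1", "c1", "c2"),
                         c("pa", "pb", "pc", "pc"),
                         rep("sp", 4), c(base, s5, base, s4))
  pops <- data.frame(population = c("pa", "pb", "pc"),
                     lon = c(0, 1, 3), lat = c(0, 2, 1))
  # identical monomorphic populations -> 0
  aln0 <- mtdna_alignment(c("x1", "y1"), c("px", "py"), rep("sp", 2),
                          c(base, base))
  z0 <- edge_genetic_distance(aln0,
                              data.frame(population = c("px", "py"),
                                         lon = c(0, 2), lat = c(0, 0)),
                              data.frame(from = "px", to = "py"))
  expect_equal(z0$value, 0)
  expect_equal(c(z0$lon, z0$lat), c(1, 0))
  # single sequences differing at 5 of 658 sites
  z1 <- edge_genetic_distance(aln, pops, data.frame(from = "pa", to = "pb"))
  expect_equal(z1$value, 5 / 658)
  # A = {s}, B = {s, t}, d(s, t) = 4/658 -> mean of {0, 4/658}
  z2 <- edge_genetic_distance(aln, pops, data.frame(from = "pa", to = "pc"))
  expect_equal(z2$value, mean(c(0, 4 / 658)))
  expect_equal(c(z2$lon, z2$lat), c(1.5, 0.5))
  # oracle agreement on a synthetic population pair
  sys <- tiny_system(seed = 8)
  two <- sys$truth$populations$population[1:2]
  sel <- sys$alignment[sys$alignment$population %in% two, ]
  attr(sel, "aln_length") <- attr(sys$alignment, "aln_length")
  class(sel) <- class(sys$alignment)
  z3 <- edge_genetic_distance(sel, sys$truth$populations,
                              data.frame(from = two[1], to = two[2]))
  expect_equal(z3$value,
               unname(oracle_zi(sel$sequence[sel$population == two[1]],
                                sel$sequence[sel$population == two[2]])))
})

test_that("Delaunay networks match the textbook cases", {
  p3 <- data.frame(population = c("a", "b", "c"),
                   lon = c(0, 1, 0.4), lat = c(0, 0.2, 1))
  expect_equal(nrow(delaunay_network(p3)), 3)

  # unit square: 4 sides plus exactly one diagonal
  sq <- data.frame(population = c("a", "b", "c", "d"),
                   lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
  e <- delaunay_network(sq)
  expect_equal(nrow(e), 5)
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  sides <- c("a b", "b c", "c d", "a d")
  expect_true(all(sides %in% key))
  expect_equal(sum(key %in% c("a c", "b d")), 1)

  # two points: a single edge
  p2 <- data.frame(population = c("a", "b"), lon = c(0, 2), lat = c(1, 1))
  expect_equal(nrow(delaunay_network(p2)), 1)

  # collinear points: a path along the line
  pl <- data.frame(population = letters[1:4],
                   lon = c(3, 0, 1, 2), lat = c(3, 0, 1, 2))
  el <- delaunay_network(pl)
  expect_equal(nrow(el), 3)
  key <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
  expect_setequal(key, c("b c", "c d", "a d"))

  # duplicate coordinates are jittered with a warning
  pd <- data.frame(population = c("a", "b", "c"),
                   lon = c(0, 0, 1), lat = c(0, 0, 1))
  expect_warning(ed <- delaunay_network(pd), "jitter")
  expect_gte(nrow(ed), 2)
})

test_that("Delaunay networks agree with the empty-circumcircle oracle", {
  set.seed(50)
  for (rep in 1:50) {
    n <- 20
    x <- runif(n); y <- runif(n)
    pops <- data.frame(population = sprintf("p%02d", 1:n), lon = x, lat = y)
    e <- delaunay_network(pops)
    got <- sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    o <- oracle_delaunay_edges(x, y)
    want <- sort(paste(pops$population[o[, 1]], pops$population[o[, 2]]))
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("IDW honors the data and stays within neighbor bounds", {
  g <- grid_spec(10, 10, cell_size = 0.1)
  one <- data.frame(lon = 0.55, lat = 40.35, value = 7)
  r <- idw_interpolate(one, g)
  expect_equal(max(abs(r$values - 7)), 0, tolerance = 1e-12)

  # equidistant cell between two points averages them
  cc <- cell_centers(g)
  two <- data.frame(lon = cc$lon[1] - 0.2, lat = cc$lat[1],
                    value = c(0, 10))
  two$lon[2] <- cc$lon[1] + 0.2
  r2 <- idw_interpolate(two, g, k = 2)
  expect_equal(r2$values[cc$row[1], cc$col[1]], 5)

  set.seed(60)
  for (rep in 1:10) {
    pts <- data.frame(lon = runif(8, 0, 1), lat = runif(8, 40, 41),
                      value = rnorm(8))
    # snap two points onto cell centers to test exactness
    pts$lon[1] <- cc$lon[13]; pts$lat[1] <- cc$lat[13]
    pts$lon[2] <- cc$lon[77]; pts$lat[2] <- cc$lat[77]
    r3 <- idw_interpolate(pts, g, power = 2, k = 4)
    expect_equal(r3$values[cc$row[13], cc$col[13]], pts$value[1])
    expect_equal(r3$values[cc$row[77], cc$col[77]], pts$value[2])
    expect_true(all(r3$values >= min(pts$value) - 1e-12))
    expect_true(all(r3$values <= max(pts$value) + 1e-12))
  }
  expect_error(idw_interpolate(data.frame(lon = 1, lat = 1,
                                          value = NA_real_), g),
               "no value points")
})

test_that("cropping respects polygons and matches ray casting", {
  g <- grid_spec(10, 10, origin_lon = 0, origin_lat = 0, cell_size = 0.1)
  r <- rf_raster(matrix(1:100, 10, 10), g)
  whole <- cbind(lon = c(-1, 2, 2, -1), lat = c(-1, -1, 2, 2))
  expect_equal(crop_to_range(r, whole)$values, r$values)

  left <- cbind(lon = c(-1, 0.5, 0.5, -1), lat = c(-1, -1, 2, 2))
  cl <- crop_to_range(r, left)
  cc <- cell_centers(g)
  expect_true(all(is.na(cl$values[cc$cell[cc$lon > 0.5]])))
  expect_true(all(!is.na(cl$values[cc$cell[cc$lon < 0.5]])))

  expect_warning(crop_to_range(r, whole + 100), "disjoint")

  set.seed(70)
  for (rep in 1:5) {
    # random star-shaped polygon around the grid center
    ang <- sort(runif(7, 0, 2 * pi))
    rad <- runif(7, 0.15, 0.6)
    ring <- cbind(lon = 0.5 + rad * cos(ang), lat = 0.5 + rad * sin(ang))
    cr <- crop_to_range(r, ring)
    inside_oracle <- vapply(seq_len(nrow(cc)), function(i)
      oracle_point_in_polygon(cc$lon[i], cc$lat[i], list(ring)), TRUE)
    expect_equal(!is.na(cr$values[cc$cell]), inside_oracle)
  }
})

test_that("composite scaling behaves in both modes", {
  g <- grid_spec(8, 8)
  mk <- function(vals) rf_raster(matrix(vals, 8, 8), g)
  one <- list(s1 = mk(seq(0, 4, length.out = 64)))
  for (mode in c("global", "per_species")) {
    sc <- composite_scale(one, mode)
    expect_equal(range(sc$s1$values), c(0, 1))
  }
  two <- list(A = mk(seq(0, 1, length.out = 64)),
              B = mk(seq(0, 10, length.out = 64)))
  glob <- composite_scale(two, "global")
  expect_equal(range(glob$A$values), c(0, 0.1))
  per <- composite_scale(two, "per_species")
  expect_equal(range(per$A$values), c(0, 1))
  flat <- composite_scale(list(s = mk(rep(2, 64))), "global")
  expect_true(all(flat$s$values == 0.5))
})
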