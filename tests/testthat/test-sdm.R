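make_sdm_world <- function(seed = 1, n_layers = 3, rho = 0) {
  g <- grid_spec(30, 30)
  st <- generate_climate_stack(g, n_layers, 4, rho, 0, seed = seed)
  bgc <- seq(1, 900, by = 3)
  list(grid = g, stack = st$current, bg_cells = bgc)
}

test_that("correlation screening keeps an uncorrelated subset", {
  w <- make_sdm_world()
  st <- w$stack
  st$layers$dup <- st$layers$env1
  kept <- screen_variables(st, w$bg_cells,
                           priority = c("env1", "dup", "env2", "env3"))
  expect_true("env1" %in% kept)
  expect_false("dup" %in% kept)

  # independent layers: all retained
  kept2 <- screen_variables(w$stack, w$bg_cells)
  expect_setequal(kept2, c("env1", "env2", "env3"))

  # reversed priority: retained set may differ, pairwise |r| < 0.7 always
  wc <- make_sdm_world(seed = 9, n_layers = 4, rho = 0.6)
  for (pr in list(names(wc$stack$layers), rev(names(wc$stack$layers)))) {
    kept3 <- screen_variables(wc$stack, wc$bg_cells, priority = pr)
    V <- layer_values(wc$stack, wc$bg_cells, kept3)
    if (length(kept3) > 1) {
      cors <- abs(cor(V)[upper.tri(diag(length(kept3)))])
      expect_true(all(cors < 0.7))
    }
  }

  st$layers$flat <- st$layers$env1 * 0
  expect_warning(kept4 <- screen_variables(st, w$bg_cells,
                                           priority = c("flat", "env1")),
                 "constant")
  expect_false("flat" %in% kept4)
})

test_that("background cells stay inside the buffer (haversine oracle)", {
  skip_if_not_installed("geosphere")
  w <- make_sdm_world()
  loc <- data.frame(lon = 0.75, lat = 40.75)
  bg <- build_background(loc, w$stack, buffer_km = 60, n_background = 100,
                         seed = 3)
  d_hav <- geosphere::distHaversine(cbind(loc$lon, loc$lat),
                                    cbind(bg$cells$lon, bg$cells$lat)) / 1000
  # planar-with-cosine distances match haversine to well under a cell at
  # this extent; allow half a cell of slack at the rim
  expect_true(all(d_hav <= 60 + 3))
  expect_true(all(bg$cells$cell %in% bg$pool))
  expect_false(anyDuplicated(bg$cells$cell) > 0)

  bg2 <- build_background(loc, w$stack, 60, 100, seed = 3)
  expect_identical(bg, bg2)

  expect_warning(build_background(loc, w$stack, 30, 1e5, seed = 1),
                 "using all")
})

test_that("a full-grid buffer samples uniformly from all cells", {
  w <- make_sdm_world()
  loc <- data.frame(lon = 0.75, lat = 40.75)
  bg <- build_background(loc, w$stack, buffer_km = 1e5,
                         n_background = 900, seed = 1)
  expect_equal(length(bg$pool), 900)
  expect_equal(nrow(bg$cells), 900)
})

test_that("hinge features honor knots, normalization and clamping", {
  w <- make_sdm_world()
  bgv <- layer_values(w$stack, w$bg_cells)
  feats <- hinge_basis(bgv, "env1", n_knots = 5)
  fw <- feats[feats$dir == "forward", ]
  x <- matrix(fw$knot[2], 1, 1, dimnames = list(NULL, "env1"))
  expect_equal(refugia:::eval_hinge(fw[2, ], x)[1, 1], 0)
  xmax <- matrix(max(bgv[, "env1"]), 1, 1, dimnames = list(NULL, "env1"))
  expect_true(all(refugia:::eval_hinge(fw, xmax) == 1))
  beyond <- matrix(max(bgv[, "env1"]) + 10, 1, 1,
                   dimnames = list(NULL, "env1"))
  expect_equal(refugia:::eval_hinge(feats, beyond),
               refugia:::eval_hinge(feats, xmax))
})

test_that("a separable niche earns a positive weight and higher scores", {
  w <- make_sdm_world(seed = 4)
  st <- w$stack
  v <- layer_values(st, vars = "env1")[, 1]
  presence <- order(v, decreasing = TRUE)[1:25]
  loc <- cell_centers(w$grid)
  bg <- build_background(loc[seq(1, 900, by = 2), ], st, 1e5, 300, seed = 2)
  m <- fit_entropy_model(presence, bg, st, vars = "env1", n_knots = 8)
  p <- project_model(m, st)
  expect_gt(mean(p$raw$values[presence]),
            mean(p$raw$values[-presence]))
})

test_that("extreme regularization shrinks to the uniform distribution", {
  w <- make_sdm_world(seed = 5)
  loc <- cell_centers(w$grid)
  bg <- build_background(loc[seq(1, 900, by = 2), ], w$stack, 1e5, 200,
                         seed = 2)
  m <- fit_entropy_model(sample(bg$pool, 20), bg, w$stack, n_knots = 6,
                         beta = 1e9)
  expect_true(all(m$weights == 0))
  p <- project_model(m, w$stack)
  # raw scores uniform over the normalization set: 1/N each
  expect_equal(unname(p$raw$values[m$norm_cells]),
               rep(1 / length(m$norm_cells), length(m$norm_cells)))
  expect_equal(sd(p$logistic$values), 0)
})

test_that("the fitted objective beats a dense brute-force weight grid", {
  # <= 12 background cells, 2 hand-made hinge features
  g <- grid_spec(8, 8)
  set.seed(6)
  st <- raster_stack(list(env1 = matrix(runif(64), 8, 8),
                          env2 = matrix(runif(64), 8, 8)), g)
  pool <- 1:12
  bg <- structure(list(cells = cell_centers(g, pool),
                       values = layer_values(st, pool),
                       pool = pool, buffer_km = Inf),
                  class = "background_set")
  feats <- rbind(hinge_basis(bg$values, "env1", 2)[1, ],
                 hinge_basis(bg$values, "env2", 2)[1, ])
  presence <- c(1, 3, 5, 7, 9)
  m <- fit_entropy_model(presence, bg, st, features = feats, beta = 0.5)

  F_bg <- refugia:::eval_hinge(feats, bg$values)
  F_pr <- refugia:::eval_hinge(feats, layer_values(st, presence))
  n <- length(presence)
  objective <- function(w) {
    eta <- F_bg %*% w
    sum(F_pr %*% w) - n * log(sum(exp(eta))) - sum(m$lambda * abs(w))
  }
  grid_w <- seq(-3, 3, by = 0.05)
  best <- -Inf
  for (w1 in grid_w) for (w2 in grid_w)
    best <- max(best, objective(c(w1, w2)))
  expect_gte(m$objective, best - 1e-4)
})

test_that("projection normalizes, clamps, and names missing layers", {
  w <- make_sdm_world(seed = 7)
  loc <- cell_centers(w$grid)
  bg <- build_background(loc[seq(1, 900, by = 4), ], w$stack, 1e5, 150,
                         seed = 3)
  v <- layer_values(w$stack, vars = "env1")[, 1]
  presence <- order(v)[1:15]
  m <- fit_entropy_model(presence, bg, w$stack, n_knots = 6)
  p <- project_model(m, w$stack)
  expect_equal(sum(p$raw$values[m$norm_cells]), 1, tolerance = 1e-9)
  expect_true(all(p$logistic$values > 0 & p$logistic$values < 1))

  # a shifted stack beyond the training range equals the manually clamped one
  shifted <- w$stack
  for (nm in names(shifted$layers))
    shifted$layers[[nm]] <- shifted$layers[[nm]] + 100
  clamped <- w$stack
  for (nm in names(clamped$layers)) {
    f <- m$features[m$features$var == nm, ]
    hi <- if (nrow(f)) f$vmax[1] else max(layer_values(w$stack, vars = nm))
    clamped$layers[[nm]][] <- pmin(shifted$layers[[nm]], hi)
  }
  expect_equal(project_model(m, shifted)$raw$values,
               project_model(m, clamped)$raw$values)

  bad <- w$stack
  bad$layers$env1 <- NULL
  expect_error(project_model(m, bad), "env1")
})

test_that("no random perturbation improves the penalized objective", {
  w <- make_sdm_world(seed = 8)
  loc <- cell_centers(w$grid)
  bg <- build_background(loc[seq(1, 900, by = 4), ], w$stack, 1e5, 150,
                         seed = 4)
  v <- layer_values(w$stack, vars = "env2")[, 1]
  presence <- order(v, decreasing = TRUE)[1:15]
  m <- fit_entropy_model(presence, bg, w$stack, n_knots = 6)
  F_nm <- refugia:::eval_hinge(m$features, layer_values(w$stack, m$norm_cells))
  F_pr <- refugia:::eval_hinge(m$features, layer_values(w$stack, presence))
  objective <- function(w) {
    sum(F_pr %*% w) - length(presence) * log(sum(exp(F_nm %*% w))) -
      sum(m$lambda * abs(w))
  }
  base <- objective(m$weights)
  set.seed(9)
  for (rep in 1:50) {
    pert <- m$weights + rnorm(length(m$weights), sd = 0.01)
    expect_lte(objective(pert), base + 1e-8)
  }
})
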