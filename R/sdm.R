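#' Greedy correlation screening of environmental layers
#'
#' Layers are visited in priority order; a layer is retained iff its absolute
#' Pearson correlation with every already-retained layer, computed over the
#' background cells, stays below the threshold. Constant (zero-variance)
#' layers are dropped with a warning.
#'
#' @param stack A [raster_stack()].
#' @param background_cells Cell indices over which correlations are computed.
#' @param threshold Correlation cutoff; default 0.7.
#' @param priority Layer names in preference order; default stack order.
#' @return Character vector of retained layer names.
#' @export
screen_variables <- function(stack, background_cells, threshold = 0.7,
                             priority = names(stack$layers)) {
  if (length(stack$layers) < 2) stop("need at least 2 layers to screen")
  V <- layer_values(stack, background_cells, priority)
  keep <- character(0)
  for (nm in priority) {
    x <- V[, nm]
    if (stats::sd(x) < 1e-12) {
      warning("layer '", nm, "' is constant over the background; dropped")
      next
    }
    ok <- all(vapply(keep, function(k)
      abs(stats::cor(x, V[, k])) < threshold, TRUE))
    if (ok) keep <- c(keep, nm)
  }
  keep
}

#' Build a buffered background (pseudo-absence) set
#'
#' The accessible area is the union of circles of radius `buffer_km` around
#' the supplied genus localities (distances via the planar approximation
#' 1 degree latitude = 111.32 km with a latitude-cosine correction for
#' longitude). `n_background` cells are sampled uniformly without replacement
#' from the in-buffer, non-nodata cells.
#'
#' @param localities Data frame with `lon`, `lat` (all genus records).
#' @param stack A [raster_stack()] providing the grid and nodata mask.
#' @param buffer_km Buffer radius in kilometres; default 200.
#' @param n_background Background sample size.
#' @param seed Integer seed.
#' @return An object of class `background_set`: `cells` (data frame
#'   `cell,row,col,lon,lat`), `values` (layer-value matrix over those cells),
#'   `pool` (all eligible in-buffer cell indices) and `buffer_km`.
#' @export
build_background <- function(localities, stack, buffer_km = 200,
                             n_background = 1000, seed = 1) {
  if (nrow(localities) < 1) stop("need at least one locality")
  cc <- cell_centers(stack$grid)
  V <- layer_values(stack)
  ok <- !apply(is.na(V), 1, any)
  mind <- rep(Inf, nrow(cc))
  for (i in seq_len(nrow(localities))) {
    dx <- (cc$lon - localities$lon[i]) * 111.32 *
      cos((cc$lat + localities$lat[i]) / 2 * pi / 180)
    dy <- (cc$lat - localities$lat[i]) * 111.32
    mind <- pmin(mind, sqrt(dx^2 + dy^2))
  }
  pool <- cc$cell[ok & mind <= buffer_km]
  if (!length(pool)) stop("buffer contains no usable cells")
  set.seed(seed)
  if (n_background >= length(pool)) {
    if (n_background > length(pool))
      warning("n_background exceeds available in-buffer cells (",
              length(pool), "); using all of them")
    take <- pool
  } else {
    take <- sort(sample(pool, n_background))
  }
  structure(
    list(cells = cell_centers(stack$grid, take),
         values = layer_values(stack, take),
         pool = pool, buffer_km = buffer_km),
    class = "background_set")
}

#' Hinge feature basis over background values
#'
#' Forward hinges `max(0, x - k)/(max - k)` and reverse hinges
#' `max(0, k - x)/(k - min)` with knots at `n_knots` equally spaced quantiles
#' of the background values of each variable. Evaluation clamps inputs into
#' the background range (the "clamping" convention for projection beyond the
#' training range).
#'
#' @param background_values Numeric matrix of layer values over background
#'   cells (named columns).
#' @param vars Variables to build features for; default all columns.
#' @param n_knots Knots per direction; default 30.
#' @return A `hinge_features` data frame: `var,knot,dir,vmin,vmax`, one row
#'   per feature.
#' @export
hinge_basis <- function(background_values, vars = colnames(background_values),
                        n_knots = 30) {
  defs <- list()
  for (v in vars) {
    x <- background_values[, v]
    if (stats::sd(x) < 1e-12)
      stop("variable '", v, "' is constant over the background")
    ks <- unique(as.vector(stats::quantile(x, seq(0, 1, length.out = n_knots))))
    vmin <- min(x); vmax <- max(x)
    fw <- ks[ks < vmax]
    rv <- ks[ks > vmin]
    defs[[v]] <- rbind(
      data.frame(var = v, knot = fw, dir = "forward", vmin = vmin,
                 vmax = vmax, stringsAsFactors = FALSE),
      data.frame(var = v, knot = rv, dir = "reverse", vmin = vmin,
                 vmax = vmax, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, defs)
  rownames(out) <- NULL
  class(out) <- c("hinge_features", "data.frame")
  out
}

# Evaluate hinge features (with clamping) on a matrix of layer values.
eval_hinge <- function(features, values) {
  n <- nrow(values)
  F <- matrix(0, n, nrow(features))
  vr <- features$var; kn <- features$knot; dr <- features$dir
  lo <- features$vmin; hi <- features$vmax
  for (v in unique(vr)) {
    idx <- which(vr == v)
    x <- values[, v]
    for (j in idx) {
      xc <- pmin(pmax(x, lo[j]), hi[j])
      F[, j] <- if (dr[j] == "forward") pmax(0, xc - kn[j]) / (hi[j] - kn[j])
                else pmax(0, kn[j] - xc) / (kn[j] - lo[j])
    }
  }
  F
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit an L1-penalised hinge-feature maximum-entropy model
#'
#' Maximises the penalised Gibbs log-likelihood
#' `sum_presence eta(x) - n * log sum_background exp(eta(x)) -
#' sum_j lambda_j |w_j|` with `eta` linear in the hinge features and
#' `lambda_j = beta * s_j / sqrt(n)` (`s_j` = feature standard deviation over
#' the presence sample, floored at 0.05). Presence samples are added to the
#' background (normalization) set, the reference tool's convention, which
#' also keeps the objective bounded for separable data. The convex problem
#' is solved by L-BFGS-B on the positive/negative weight split with a
#' proximal-gradient polish; convergence is verified against the KKT
#' conditions at tolerance `tol` (scaled by `n`).
#'
#' @param presence Presence cell indices, or a data frame with `lon`,`lat`
#'   (rasterised to cells and deduplicated).
#' @param background A [build_background()] result.
#' @param stack The training [raster_stack()].
#' @param vars Variables to use; default all background columns.
#' @param n_knots Hinge knots per direction; default 30.
#' @param beta Regularisation multiplier; default 1.
#' @param features Optional precomputed [hinge_basis()] (overrides
#'   `vars`/`n_knots`).
#' @param max_iter Optimiser iteration cap.
#' @param tol KKT tolerance (gradient scale); default 1e-5.
#' @param bg_features Optional precomputed `eval_hinge(features,
#'   background$values)` matrix (an optimisation for repeated fits over one
#'   background, e.g. in the null-model test).
#' @return An object of class `entropy_model`.
#' @export
fit_entropy_model <- function(presence, background, stack,
                              vars = colnames(background$values),
                              n_knots = 30, beta = 1, features = NULL,
                              max_iter = 2000, tol = 1e-5,
                              bg_features = NULL) {
  if (is.data.frame(presence)) {
    presence <- unique(cell_at(stack$grid, presence$lon, presence$lat))
    presence <- presence[!is.na(presence)]
  }
  presence <- unique(as.integer(presence))
  if (length(presence) < 5) stop("need at least 5 presence cells")
  if (is.null(features)) features <- hinge_basis(background$values, vars,
                                                 n_knots)
  vars <- unique(features$var)
  F_bg <- if (is.null(bg_features)) eval_hinge(features, background$values)
          else bg_features
  P <- layer_values(stack, presence, vars)
  if (any(is.na(P))) {
    keep <- !apply(is.na(P), 1, any)
    presence <- presence[keep]
    P <- P[keep, , drop = FALSE]
    if (length(presence) < 5) stop("fewer than 5 presence cells with data")
  }
  F_pr <- eval_hinge(features, P)
  n <- length(presence)
  # presence samples are added to the normalization (background) set — the
  # convention of the reference maximum-entropy tool. Without it the
  # penalized likelihood is unbounded whenever some feature direction
  # separates every presence from every sampled background cell.
  extra <- which(!(presence %in% background$cells$cell))
  F_nm <- rbind(F_bg, F_pr[extra, , drop = FALSE])
  norm_cells <- c(background$cells$cell, presence[extra])
  # feature sd over presence, floored: features constant on the presence
  # sample would otherwise be unpenalized, letting near-separable fits drift
  # to arbitrarily large weights
  s <- pmax(apply(F_pr, 2, stats::sd), 0.05)
  lambda <- beta * s / sqrt(n)
  J <- ncol(F_bg)
  pr_sum <- colSums(F_pr)

  obj <- function(par) {
    w <- par[1:J] - par[J + 1:J]
    eta <- as.vector(F_nm %*% w)
    lse <- log_sum_exp(eta)
    -sum(pr_sum * w) + n * lse + sum(lambda * (par[1:J] + par[J + 1:J]))
  }
  grad <- function(par) {
    w <- par[1:J] - par[J + 1:J]
    eta <- as.vector(F_nm %*% w)
    q <- exp(eta - log_sum_exp(eta))
    gw <- -pr_sum + n * as.vector(crossprod(F_nm, q))
    c(gw + lambda, -gw + lambda)
  }
  kkt_violation <- function(w) {
    eta <- as.vector(F_nm %*% w)
    q <- exp(eta - log_sum_exp(eta))
    g <- -pr_sum + n * as.vector(crossprod(F_nm, q))
    v <- ifelse(abs(w) > 1e-9, abs(g + sign(w) * lambda),
                pmax(0, abs(g) - lambda))
    max(v)
  }

  par <- rep(0, 2 * J)
  fit <- stats::optim(par, obj, grad, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = max_iter,
                                                factr = 10, pgtol = 0))
  w <- fit$par[1:J] - fit$par[J + 1:J]
  kkt <- kkt_violation(w)
  if (kkt > tol * max(1, n)) {
    # proximal-gradient polish: soft-thresholded descent with backtracking
    # cleans up the active set where L-BFGS-B on the split problem stalls
    smooth_f <- function(w) {
      eta <- as.vector(F_nm %*% w)
      -sum(pr_sum * w) + n * log_sum_exp(eta)
    }
    smooth_g <- function(w) {
      eta <- as.vector(F_nm %*% w)
      q <- exp(eta - log_sum_exp(eta))
      -pr_sum + n * as.vector(crossprod(F_nm, q))
    }
    # FISTA with adaptive restart
    step <- 1 / max(1, n)
    y <- w
    w_prev <- w
    tk <- 1
    for (it in seq_len(20000)) {
      g <- smooth_g(y)
      fy <- smooth_f(y)
      repeat {
        w_new <- sign(y - step * g) * pmax(abs(y - step * g) - step * lambda, 0)
        dw <- w_new - y
        f_new <- smooth_f(w_new)
        if (f_new <= fy + sum(g * dw) + sum(dw^2) / (2 * step) + 1e-12) break
        step <- step / 2
        if (step < 1e-16) break
      }
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      if (sum((y - w_new) * (w_new - w_prev)) > 0) {  # restart momentum
        y <- w_new
        tk <- 1
      } else {
        y <- w_new + ((tk - 1) / t_new) * (w_new - w_prev)
        tk <- t_new
      }
      w_prev <- w_new
      step <- step * 1.1
      if (it %% 50 == 0) {
        kkt <- kkt_violation(w_new)
        if (kkt <= tol * max(1, n)) break
      }
    }
    w <- w_prev
    kkt <- kkt_violation(w)
    if (kkt > tol * max(1, n))
      stop("entropy model did not converge: KKT residual ", signif(kkt, 4),
           " exceeds ", signif(tol * max(1, n), 4), " (", J,
           " features, n = ", n, ")")
  }
  eta_nm <- as.vector(F_nm %*% w)
  logZ <- log_sum_exp(eta_nm)
  q <- exp(eta_nm - logZ)
  H <- -sum(q[q > 0] * log(q[q > 0]))
  penalized <- sum(pr_sum * w) - n * logZ - sum(lambda * abs(w))
  structure(
    list(features = features, weights = w, lambda = lambda, beta = beta,
         vars = vars, logZ = logZ, entropy = H,
         background_cells = background$cells$cell, norm_cells = norm_cells,
         n_presence = n, presence_cells = presence, objective = penalized,
         kkt = kkt),
    class = "entropy_model")
}

#' @export
print.entropy_model <- function(x, ...) {
  cat(sprintf(
    "<entropy_model> %d hinge features on %s; %d active weights, beta = %g\n",
    nrow(x$features), paste(x$vars, collapse = ", "),
    sum(abs(x$weights) > 1e-8), x$beta))
  cat(sprintf("  n_presence = %d, background entropy = %.4f\n", x$n_presence,
              x$entropy))
  invisible(x)
}

#' Project a fitted entropy model onto a raster stack
#'
#' Raw output `exp(eta(x)) / Z` is normalised so it sums to 1 over the
#' training background cells; the logistic transform
#' `c * raw / (1 + c * raw)` with `c = exp(H)` (H the entropy of the fitted
#' background distribution) maps suitability into (0,1). Out-of-range values
#' are clamped to the training range.
#'
#' @param model An [fit_entropy_model()] result.
#' @param stack Any scenario [raster_stack()] containing the model variables.
#' @return List with `raw` and `logistic` [rf_raster()]s.
#' @export
project_model <- function(model, stack) {
  miss <- setdiff(model$vars, names(stack$layers))
  if (length(miss))
    stop("stack lacks layer(s) required by the model: ",
         paste(miss, collapse = ", "))
  g <- stack$grid
  V <- layer_values(stack, vars = model$vars)
  ok <- !apply(is.na(V), 1, any)
  raw <- rep(NA_real_, nrow(V))
  F <- eval_hinge(model$features, V[ok, , drop = FALSE])
  eta <- as.vector(F %*% model$weights)
  raw[ok] <- exp(eta - model$logZ)
  cc <- exp(model$entropy)
  logi <- cc * raw / (1 + cc * raw)
  list(raw = rf_raster(matrix(raw, g$n_rows, g$n_cols), g),
       logistic = rf_raster(matrix(logi, g$n_rows, g$n_cols), g))
}
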