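#' Generate paired current/glacial synthetic climate stacks
#'
#' Each layer is a spatially autocorrelated Gaussian random field: white noise
#' smoothed with a Gaussian kernel of standard deviation `autocorr_length`
#' cells, then standardized to mean 0 and unit variance over cells. A common
#' equicorrelation structure of strength `inter_layer_corr` is imposed across
#' layers by orthonormalizing the smoothed fields and mixing them through the
#' Cholesky factor of the equicorrelation matrix, so the realized sample
#' correlation matches the request exactly. The glacial counterpart of each layer is the
#' current field plus a constant per-layer offset (in standard-deviation
#' units), emulating a shifted palaeoclimate.
#'
#' @param spec A [grid_spec()].
#' @param n_layers Number of layers (at least 2).
#' @param autocorr_length Smoothing kernel sd in cells (at least 1).
#' @param inter_layer_corr Target pairwise correlation between layers. Must
#'   lie in `(-1/(n_layers-1), 1]`; `|r| = 1` with more than two layers is
#'   over-constrained and rejected.
#' @param glacial_shift Per-layer additive offsets for the glacial stack
#'   (recycled to `n_layers`).
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @return A list with elements `current` and `glacial`, both
#'   [raster_stack()]s with layers `env1 ... envK`.
#' @export
generate_climate_stack <- function(spec, n_layers = 4, autocorr_length = 4,
                                   inter_layer_corr = 0,
                                   glacial_shift = -1.5, seed = 1) {
  if (!inherits(spec, "grid_spec")) stop("spec must be a grid_spec")
  if (n_layers < 2) stop("n_layers must be at least 2")
  if (autocorr_length < 1) stop("autocorr_length must be at least 1")
  rho <- inter_layer_corr
  if (abs(rho) > 1) stop("inter_layer_corr must lie in [-1, 1]")
  if (abs(rho) == 1 && n_layers > 2)
    stop("|inter_layer_corr| = 1 with more than 2 layers is over-constrained")
  if (rho < -1 / (n_layers - 1))
    stop("inter_layer_corr below -1/(n_layers-1) is not a valid ",
         "equicorrelation")
  glacial_shift <- rep_len(glacial_shift, n_layers)

  set.seed(seed)
  ncell <- spec$n_rows * spec$n_cols
  Z <- matrix(NA_real_, ncell, n_layers)
  for (k in seq_len(n_layers)) {
    f <- gaussian_smooth(matrix(stats::rnorm(ncell), spec$n_rows), autocorr_length)
    Z[, k] <- f - mean(f)
  }
  # orthonormalize the centered smoothed fields so their SAMPLE correlation
  # is exactly zero (smoothing leaves few effective degrees of freedom, so
  # raw sample correlations would wander), then impose the requested
  # equicorrelation through the Cholesky factor: X = Zo U with U'U = R has
  # sample correlation exactly R.
  Zo <- qr.Q(qr(Z))
  Zo <- sweep(Zo, 2, apply(Zo, 2, stats::sd), "/")
  X <- if (rho == 1) {
    Zo[, rep(1L, n_layers), drop = FALSE]
  } else if (rho == -1) {
    cbind(Zo[, 1], -Zo[, 1])
  } else if (rho == 0) {
    Zo
  } else {
    R <- matrix(rho, n_layers, n_layers); diag(R) <- 1
    Zo %*% chol(R)
  }
  layers_cur <- list()
  layers_gla <- list()
  for (k in seq_len(n_layers)) {
    x <- (X[, k] - mean(X[, k])) / stats::sd(X[, k])
    m <- matrix(x, spec$n_rows, spec$n_cols)
    nm <- paste0("env", k)
    layers_cur[[nm]] <- m
    layers_gla[[nm]] <- m + glacial_shift[k]
  }
  list(current = raster_stack(layers_cur, spec, "current"),
       glacial = raster_stack(layers_gla, spec, "lgm"))
}
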