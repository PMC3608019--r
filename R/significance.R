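#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random presence score exceeds a random background
#' score, counting ties as one half; computed exactly via the rank formula.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0 || n0 == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Null-model significance test for a species distribution model
#'
#' The observed model's training AUC is ranked against `n_null` AUC values
#' from models fitted to the same number of localities drawn uniformly at
#' random from the buffered background region, using identical model
#' settings and the same background sample. Pooling the observed value as
#' the 100th, the model is deemed significant iff it is strictly greater
#' than the 95th smallest pooled value (ties count against significance).
#'
#' @param presence Observed presence cells (indices or lon/lat data frame).
#' @param background A [build_background()] result (its `pool` supplies the
#'   random-locality region).
#' @param stack Training [raster_stack()].
#' @param vars,n_knots,beta Model settings shared by observed and null fits.
#' @param n_null Number of null replicates; default 99.
#' @param seed Integer seed.
#' @return An object of class `null_test_result`: `observed`, `null`
#'   (length `n_null`), `rank` (ascending rank of the observed value among
#'   the pooled `n_null + 1`), `significant`, `seed`.
#' @export
null_model_test <- function(presence, background, stack,
                            vars = colnames(background$values),
                            n_knots = 30, beta = 1, n_null = 99, seed = 1) {
  if (is.data.frame(presence)) {
    presence <- unique(cell_at(stack$grid, presence$lon, presence$lat))
    presence <- presence[!is.na(presence)]
  }
  n_loc <- length(presence)
  if (n_loc < 5) stop("need at least 5 presence localities")
  if (length(background$pool) < n_loc)
    stop("buffer region has fewer cells (", length(background$pool),
         ") than requested localities (", n_loc, ")")
  features <- hinge_basis(background$values, vars, n_knots)
  bgF <- eval_hinge(features, background$values)

  model_auc <- function(cells) {
    m <- fit_entropy_model(cells, background, stack, features = features,
                           beta = beta, bg_features = bgF)
    pr <- eval_hinge(features, layer_values(stack, m$presence_cells,
                                            m$vars)) %*% m$weights
    bg <- bgF %*% m$weights
    auc(as.vector(pr), as.vector(bg))
  }

  observed <- model_auc(presence)
  set.seed(seed)
  null_auc <- numeric(n_null)
  for (b in seq_len(n_null)) {
    cells <- sample(background$pool, n_loc)
    null_auc[b] <- model_auc(cells)
  }
  pooled <- sort(c(null_auc, observed))
  cutoff <- pooled[ceiling(0.95 * (n_null + 1))]
  structure(
    list(observed = observed, null = null_auc,
         rank = sum(null_auc < observed) + 1L,
         significant = observed > cutoff, seed = seed),
    class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf(
    "<null_test_result> observed AUC %.4f, rank %d/%d, %ssignificant\n",
    x$observed, x$rank, length(x$null) + 1L,
    if (x$significant) "" else "not "))
  invisible(x)
}
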