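#' Mean squared error times 100
#'
#' The evaluation score used throughout the transfer-testing harness:
#' `100 * mean((pred - target)^2)`. Symmetric, nonnegative, zero iff the
#' vectors are equal, invariant to permuting problems.
#'
#' @param pred,target Equal-length numeric vectors of choice rates.
#' @return A single nonnegative number.
#' @export
mse100 <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 1) {
    stop("pred and target must have equal length >= 1", call. = FALSE)
  }
  100 * mean((pred - target)^2)
}

#' Transfer-testing matrix
#'
#' Evaluates every model on every dataset split at the (problem, block)
#' grain and reports the MSE x 100, mirroring the classic transfer-testing
#' table: models fit on one dataset family evaluated against all families'
#' train and test splits. A model fit on a biased dataset shows markedly
#' larger error off-family than on-family.
#'
#' @param models Named list of models accepted by [predict_rates()].
#' @param splits Named list of canonical observation tibbles (each with a
#'   `b_rate` column).
#' @return A tibble with one row per (model, split): columns `model`,
#'   `split`, `n` and `mse100`, of class `transfer_matrix`.
#' @export
transfer_matrix <- function(models, splits) {
  stopifnot(length(models) >= 1, length(splits) >= 1,
            !is.null(names(models)), !is.null(names(splits)))
  out <- tidyr::expand_grid(model = names(models), split = names(splits))
  out <- dplyr::mutate(out, n = NA_integer_, mse100 = NA_real_)
  for (i in seq_len(nrow(out))) {
    d <- splits[[out$split[i]]]
    p <- predict_rates(models[[out$model[i]]], d)
    out$n[i] <- nrow(d)
    out$mse100[i] <- mse100(p, d$b_rate)
  }
  class(out) <- c("transfer_matrix", class(out))
  out
}

#' Per-problem difference between two models' predictions
#'
#' The model-disagreement field: `predict(model_a) - predict(model_b)` per
#' row, conventionally oriented as lab-trained minus online-trained model.
#' Its structure over the problem space is what the feature regressions and
#' Shapley attributions explain.
#'
#' @param model_a,model_b Models accepted by [predict_rates()].
#' @param problems Canonical problems tibble.
#' @return Numeric vector in `[-1, 1]`, one value per row.
#' @export
nn_difference <- function(model_a, model_b, problems) {
  predict_rates(model_a, problems) - predict_rates(model_b, problems)
}
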