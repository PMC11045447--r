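#' Linear regression of a target on a feature group
#'
#' Ordinary least squares of a per-problem target (typically the
#' model-disagreement field from [nn_difference()]) on a set of feature
#' columns; reports in-sample MSE and R-squared. Rank-deficient designs are
#' handled by R's pivoting least-squares solve (aliased columns dropped),
#' equivalent to a pseudo-inverse fit.
#'
#' @param features Feature tibble (e.g. [feature_table()] output).
#' @param target Numeric target, one value per row of `features`.
#' @param cols Character vector of feature columns to regress on.
#' @return A one-row tibble: `n_features`, `mse`, `r_squared`.
#' @export
fit_group_regression <- function(features, target, cols = names(features)) {
  stopifnot(length(target) == nrow(features), nrow(features) >= 2)
  X <- as.data.frame(features[, cols, drop = FALSE])
  fit <- stats::lm(target ~ ., data = cbind(target = target, X))
  pred <- stats::fitted(fit)
  mse <- mean((pred - target)^2)
  tss <- sum((target - mean(target))^2)
  r2 <- if (tss > 0) 1 - sum((target - pred)^2) / tss else 0
  tibble::tibble(n_features = length(cols), mse = mse, r_squared = r2)
}

#' Nested feature-group regression table
#'
#' Reproduces the cumulative regression layout: base features, then
#' + naive, + psychological, + higher-order stochastic dominance, each row
#' regressing the target on the union of groups so far. The baseline row
#' predicts the mean (MSE = variance of the target, R-squared = 0).
#' In-sample R-squared is nondecreasing down the rows.
#'
#' @param features A [feature_table()] tibble.
#' @param target Numeric target aligned with `features`.
#' @return A tibble with one row per nested group set (plus the baseline).
#' @export
regression_table <- function(features, target) {
  fg <- feature_groups(features)
  sets <- list(
    "Baseline (mean)" = character(0),
    "Base" = fg$base,
    "Base + naive" = c(fg$base, fg$naive),
    "Base + naive + psych" = c(fg$base, fg$naive, fg$psych),
    "Base + naive + psych + HOSD" = c(fg$base, fg$naive, fg$psych, fg$hosd)
  )
  purrr::imap_dfr(sets, function(cols, label) {
    if (length(cols) == 0) {
      row <- tibble::tibble(n_features = 0L,
                            mse = mean((target - mean(target))^2),
                            r_squared = 0)
    } else {
      row <- fit_group_regression(features, target, cols)
    }
    dplyr::bind_cols(tibble::tibble(features_used = label), row)
  })
}

#' Single-feature R-squared with confidence interval
#'
#' Univariate regression R-squared between one feature and the target, with
#' a 95 percent (or `conf_level`) confidence interval from the Fisher
#' z-transform of the correlation.
#'
#' @param x Numeric feature vector.
#' @param y Numeric target vector.
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `r_squared`, `conf.low`, `conf.high`. A
#'   zero-variance feature gives `r_squared = 0` with a warning.
#' @export
per_feature_r2 <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; R-squared set to 0", call. = FALSE)
    return(tibble::tibble(r_squared = 0, conf.low = 0, conf.high = 0))
  }
  r <- stats::cor(x, y)
  n <- length(x)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_r <- tanh(c(z - q * se, z + q * se))
  # map the correlation interval to R^2: interval of r^2 over the r-interval
  lo <- if (ci_r[1] <= 0 && ci_r[2] >= 0) 0 else min(ci_r^2)
  hi <- max(ci_r^2)
  tibble::tibble(r_squared = r^2, conf.low = lo, conf.high = hi)
}

#' R-squared of every feature against a target
#'
#' Convenience wrapper applying [per_feature_r2()] to every feature column,
#' keeping the group annotation for plotting.
#'
#' @param features A [feature_table()] tibble.
#' @param target Numeric target aligned with `features`.
#' @param conf_level Confidence level.
#' @return Tibble with `feature`, `group`, `r_squared`, `conf.low`,
#'   `conf.high`.
#' @export
feature_r2_table <- function(features, target, conf_level = 0.95) {
  fg <- feature_groups(features)
  purrr::imap_dfr(fg, function(cols, group) {
    purrr::map_dfr(cols, function(cl) {
      res <- suppressWarnings(per_feature_r2(features[[cl]], target,
                                             conf_level))
      dplyr::bind_cols(tibble::tibble(feature = cl, group = group), res)
    })
  })
}

# Shapley kernel weight for a coalition of size s out of m features
shap_kernel_weight <- function(m, s) {
  (m - 1) / (choose(m, s) * s * (m - s))
}

#' Shapley additive attributions of a tabular function
#'
#' Kernel-style Shapley value estimation for an arbitrary function of a
#' feature table (typically the model-disagreement field as a function of
#' the problem descriptors). Missing features in a coalition are integrated
#' out against a marginal background sample. When the full coalition
#' enumeration (`2^m - 2` subsets) fits within `nsamples`, the solve is
#' exact; otherwise coalitions are sampled by their Shapley kernel weight.
#'
#' The attributions satisfy local accuracy by construction: for every row,
#' `base value + sum of attributions = f(row)`. A feature that never changes
#' the function's value receives attribution 0. For a linear function the
#' attributions equal `coefficient * (value - background mean)`.
#'
#' @param f Function mapping a data frame of feature columns to a numeric
#'   vector (one value per row).
#' @param X Data frame / tibble of instances to explain.
#' @param background Data frame of background rows (marginal reference
#'   distribution); typically ~100 dataset rows.
#' @param nsamples Coalition budget per instance (default 2048).
#' @param seed Integer seed used when coalition sampling is needed.
#' @return A matrix of attributions (rows = instances of `X`, columns =
#'   features), with the scalar base value in attribute `"base_value"`.
#' @export
shap_attributions <- function(f, X, background, nsamples = 2048L, seed = 1L) {
  X <- as.data.frame(X)
  background <- as.data.frame(background)
  if (nrow(background) == 0) stop("background must be nonempty", call. = FALSE)
  m <- ncol(X)
  stopifnot(m >= 2, identical(names(X), names(background)))
  n_full <- 2^m - 2
  if (n_full <= nsamples) {
    Z <- as.matrix(expand.grid(rep(list(0:1), m)))[-c(1, 2^m), , drop = FALSE]
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sizes <- sample(1:(m - 1), nsamples, replace = TRUE,
                    prob = vapply(1:(m - 1), function(s) {
                      shap_kernel_weight(m, s) * choose(m, s)
                    }, numeric(1)))
    Z <- t(vapply(sizes, function(s) {
      z <- integer(m)
      z[sample.int(m, s)] <- 1L
      z
    }, integer(m)))
    Z <- unique(Z)
  }
  colnames(Z) <- names(X)
  sz <- rowSums(Z)
  w <- shap_kernel_weight(m, sz)

  base_value <- mean(f(background))
  fx <- f(X)
  nb <- nrow(background)
  nz <- nrow(Z)

  phi <- matrix(0, nrow(X), m, dimnames = list(NULL, names(X)))
  # coalition value: mean over background of f with present features from x
  big_bg <- background[rep(seq_len(nb), nz), , drop = FALSE]
  zrep <- Z[rep(seq_len(nz), each = nb), , drop = FALSE]
  for (i in seq_len(nrow(X))) {
    mix <- big_bg
    for (j in seq_len(m)) {
      on <- zrep[, j] == 1L
      if (any(on)) mix[on, j] <- X[i, j]
    }
    v <- rowsum(f(mix), group = rep(seq_len(nz), each = nb)) / nb
    v <- as.numeric(v)
    # weighted least squares with the local-accuracy constraint imposed by
    # eliminating the last coefficient
    ylin <- v - base_value - Z[, m] * (fx[i] - base_value)
    A <- Z[, -m, drop = FALSE] - Z[, m]
    fit <- stats::lm.wfit(x = A, y = ylin, w = w)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    phi[i, -m] <- beta
    phi[i, m] <- (fx[i] - base_value) - sum(beta)
  }
  attr(phi, "base_value") <- base_value
  phi
}

#' Regress one feature on all Shapley attribution columns
#'
#' Multivariate OLS of a feature on the full attribution matrix; the
#' R-squared measures how linearly recoverable the feature is from the
#' attributions.
#'
#' @param feature Numeric vector, one value per explained instance.
#' @param shap Attribution matrix from [shap_attributions()].
#' @return R-squared (a single number in `[0, 1]`).
#' @export
regress_feature_on_shap <- function(feature, shap) {
  stopifnot(length(feature) == nrow(shap))
  dat <- as.data.frame(shap)
  fit <- stats::lm(feature ~ ., data = cbind(feature = feature, dat))
  tss <- sum((feature - mean(feature))^2)
  if (tss == 0) return(0)
  max(0, min(1, 1 - sum(stats::resid(fit)^2) / tss))
}
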