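#' Log-odds rescaling of a choice probability
#'
#' Multiplies the log odds of `p` by `f` and maps back:
#' `sigmoid(f * logit(p))`. For `0 < f < 1` this shrinks probabilities
#' toward equipreference (0.5) — a standard model of decision noise, or
#' equivalently of limited internal computational precision. `f = 1` is the
#' identity; 0.5 is a fixed point for every `f`; the map is strictly
#' increasing in `p` and symmetric: `rescale(1 - p) = 1 - rescale(p)`.
#'
#' Inputs are clipped to `[1e-6, 1 - 1e-6]` before the logit so that
#' degenerate rates of exactly 0 or 1 stay finite.
#'
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @param f Positive log-odds multiplier.
#' @return Rescaled probabilities in `(0, 1)`.
#' @examples
#' logodds_rescale(0.9, 0.6236)
#' @export
logodds_rescale <- function(p, f) {
  stopifnot(f > 0)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  stats::plogis(f * stats::qlogis(p))
}

#' Mixture prediction of the hybrid decision-noise model
#'
#' The hybrid generative model assumes a proportion `p_guess` of participants
#' guess at random (choice probability 0.5) while the rest choose according
#' to the lab-calibrated rate rescaled in log-odds space:
#' `(1 - p_guess) * logodds_rescale(p_cpc, f) + 0.5 * p_guess`.
#' The output is therefore confined to
#' `[0.5 * p_guess, 1 - 0.5 * p_guess]`.
#'
#' @param p_cpc Lab-model choice rates in `[0, 1]` (vectorized).
#' @param f Positive log-odds multiplier.
#' @param p_guess Guessing proportion in `[0, 1]`.
#' @return Mixture choice probabilities.
#' @export
mixture_predict <- function(p_cpc, f, p_guess) {
  stopifnot(p_guess >= 0, p_guess <= 1)
  (1 - p_guess) * logodds_rescale(p_cpc, f) + 0.5 * p_guess
}

NOISE_MODEL_JAGS <- "
model {
  f ~ dunif(0, f_max)
  p_guess ~ dunif(0, 1)
  for (i in 1:N) {
    p1[i] <- ilogit(f * logit(p[i]))
    pf[i] <- (1 - p_guess) * p1[i] + 0.5 * p_guess
    k[i] ~ dbin(pf[i], n[i])
  }
}
"

#' Fit the hybrid decision-noise model by MCMC
#'
#' Posterior inference over the two noise parameters `(f, p_guess)` under the
#' likelihood `k_i ~ Binomial(n_i, mixture_predict(p_cpc_i, f, p_guess))`,
#' with priors `f ~ Uniform(0, f_max)` and `p_guess ~ Uniform(0, 1)`.
#' Sampling uses JAGS; by default 10,000 retained draws after 1,000
#' adaptation and 1,000 burn-in iterations on a single chain (use
#' `n_chains = 4` for a split-chain convergence check).
#'
#' Non-convergence (multi-chain R-hat above 1.05) is flagged with a warning
#' and recorded in the returned object, never silently ignored.
#'
#' @param p_cpc Lab-model choice rates per problem, in `[0, 1]`.
#' @param k Observed B-choice counts per problem.
#' @param n Participants per problem (scalar or vector).
#' @param n_samples Retained posterior draws (default 10,000).
#' @param n_warmup Burn-in iterations after adaptation (default 1,000).
#' @param n_chains Number of chains (default 1).
#' @param f_max Upper bound of the uniform prior on `f` (default 2, covering
#'   both the shrinkage regime `f < 1` and expansion `f > 1`).
#' @param seed Integer seed for the sampler.
#' @return A `noise_fit` object: posterior `samples` tibble, posterior
#'   `means` and `sds`, effective sample sizes, R-hat (when `n_chains > 1`),
#'   and a kernel-density unimodality check per parameter.
#' @export
fit_noise_model <- function(p_cpc, k, n, n_samples = 10000L,
                            n_warmup = 1000L, n_chains = 1L, f_max = 2,
                            seed = 1L) {
  stopifnot(length(p_cpc) == length(k), length(p_cpc) >= 1,
            all(k >= 0), all(n >= 1), all(k <= rep(n, length.out = length(k))))
  n <- as.integer(rep(n, length.out = length(k)))
  dat <- list(k = as.integer(round(k)), n = n,
              p = pmin(pmax(p_cpc, 1e-6), 1 - 1e-6),
              N = length(k), f_max = f_max)
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(f = 1, p_guess = 0.1,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + 1000L * (ch - 1L)) %% 2147483647L)
  })
  jm <- rjags::jags.model(textConnection(NOISE_MODEL_JAGS), data = dat,
                          inits = inits, n.chains = n_chains, n.adapt = 1000,
                          quiet = TRUE)
  stats::update(jm, n_warmup, progress.bar = "none")
  per_chain <- ceiling(n_samples / n_chains)
  mc <- rjags::coda.samples(jm, c("f", "p_guess"), n.iter = per_chain,
                            progress.bar = "none")

  samples <- dplyr::bind_rows(lapply(seq_along(mc), function(ch) {
    m <- as.matrix(mc[[ch]])
    tibble::tibble(chain = ch, iteration = seq_len(nrow(m)),
                   f = m[, "f"], p_guess = m[, "p_guess"])
  }))
  means <- c(f = mean(samples$f), p_guess = mean(samples$p_guess))
  sds <- c(f = stats::sd(samples$f), p_guess = stats::sd(samples$p_guess))
  ess <- tryCatch(coda::effectiveSize(mc), error = function(e) c(f = NA_real_,
                                                                 p_guess = NA_real_))
  rhat <- c(f = NA_real_, p_guess = NA_real_)
  if (n_chains > 1) {
    gd <- tryCatch(coda::gelman.diag(mc, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) NULL)
    if (!is.null(gd)) rhat <- c(f = gd[["f"]], p_guess = gd[["p_guess"]])
  }
  converged <- all(is.na(rhat)) || all(rhat < 1.05, na.rm = TRUE)
  if (!converged) {
    warning("noise model MCMC did not converge (R-hat > 1.05)", call. = FALSE)
  }
  out <- structure(list(samples = samples, means = means, sds = sds,
                        ess = ess, rhat = rhat, converged = converged,
                        unimodal = c(f = is_unimodal(samples$f),
                                     p_guess = is_unimodal(samples$p_guess)),
                        n_obs = length(k), n_chains = n_chains,
                        f_max = f_max, seed = seed),
                   class = "noise_fit")
  out
}

# crude unimodality check: count local maxima of a smoothed kernel density
# that exceed 5% of the global mode
is_unimodal <- function(x) {
  if (stats::sd(x) == 0) return(TRUE)
  d <- stats::density(x, n = 256)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] > 0.05 * max(y)) <= 1
}

#' @export
print.noise_fit <- function(x, ...) {
  cat("Hybrid decision-noise model fit (", x$n_obs, " problems, ",
      nrow(x$samples), " posterior draws)\n", sep = "")
  cat(sprintf("  f       = %.4f (sd %.4f)\n", x$means["f"], x$sds["f"]))
  cat(sprintf("  p_guess = %.4f (sd %.4f)\n", x$means["p_guess"],
              x$sds["p_guess"]))
  if (!x$converged) cat("  WARNING: R-hat > 1.05, not converged\n")
  invisible(x)
}

#' Tidy a decision-noise model fit
#'
#' @param x A `noise_fit` object.
#' @param conf_level Width of the central credible interval.
#' @param ... Unused.
#' @return One row per parameter with posterior mean, s.d. and central
#'   credible interval.
#' @export
tidy.noise_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  tibble::tibble(
    term = c("f", "p_guess"),
    estimate = unname(x$means),
    std.error = unname(x$sds),
    conf.low = c(stats::quantile(x$samples$f, a),
                 stats::quantile(x$samples$p_guess, a)),
    conf.high = c(stats::quantile(x$samples$f, 1 - a),
                  stats::quantile(x$samples$p_guess, 1 - a))
  )
}

#' @rdname tidy.noise_fit
#' @export
glance.noise_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_draws = nrow(x$samples), n_chains = x$n_chains,
    ess_f = unname(x$ess["f"]), ess_p_guess = unname(x$ess["p_guess"]),
    rhat_f = unname(x$rhat["f"]), rhat_p_guess = unname(x$rhat["p_guess"]),
    unimodal_f = unname(x$unimodal["f"]),
    unimodal_p_guess = unname(x$unimodal["p_guess"]),
    converged = x$converged
  )
}

#' Posterior predictive choice rates
#'
#' Draws simulated online-like choice rates: for each problem a binomial
#' sample of size `n` at the mixture probability. If `params` is a
#' `noise_fit`, one posterior draw of `(f, p_guess)` is used per problem
#' (posterior predictive); a named list or vector with elements `f` and
#' `p_guess` gives a plug-in predictive at fixed parameters.
#'
#' @param params A `noise_fit` or `list(f =, p_guess =)`.
#' @param p_cpc Lab-model choice rates in `[0, 1]`.
#' @param n Participants per problem (scalar or vector).
#' @param seed Integer seed.
#' @return Numeric vector of sampled rates `k / n` in `[0, 1]`.
#' @export
posterior_predictive <- function(params, p_cpc, n, seed = 1L) {
  m <- length(p_cpc)
  n <- rep(n, length.out = m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (inherits(params, "noise_fit")) {
    idx <- sample.int(nrow(params$samples), m, replace = TRUE)
    f <- params$samples$f[idx]
    pg <- params$samples$p_guess[idx]
    pf <- vapply(seq_len(m), function(i) {
      mixture_predict(p_cpc[i], f[i], pg[i])
    }, numeric(1))
  } else {
    pf <- mixture_predict(p_cpc, params$f, params$p_guess)
  }
  stats::rbinom(m, size = n, prob = pf) / n
}
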