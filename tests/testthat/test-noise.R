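test_that("log-odds rescaling has its fixed point, identity and symmetry", {
  ps <- seq(0.05, 0.95, by = 0.05)
  fs <- c(0.3, 0.6236, 1, 1.7)
  for (f in fs) {
    expect_equal(logodds_rescale(0.5, f), 0.5)
    # symmetry: rescale(1 - p) = 1 - rescale(p)
    expect_equal(logodds_rescale(1 - ps, f), 1 - logodds_rescale(ps, f),
                 tolerance = 1e-12)
    # strictly increasing
    expect_true(all(diff(logodds_rescale(ps, f)) > 0))
  }
  expect_equal(logodds_rescale(ps, 1), ps, tolerance = 1e-12)
  # frozen high-precision oracle value
  expect_equal(logodds_rescale(0.9, 0.6236), 0.7974107274554705,
               tolerance = 1e-12)
  # shrinkage toward equipreference is strict for 0 < f < 1
  for (f in c(0.3, 0.6, 0.9)) {
    r <- logodds_rescale(ps[ps != 0.5], f)
    expect_true(all(abs(r - 0.5) < abs(ps[ps != 0.5] - 0.5)))
  }
  expect_error(logodds_rescale(1.2, 1), "\\[0, 1\\]")
  expect_error(logodds_rescale(0.5, 0), "f > 0")
})

test_that("the mixture prediction interpolates to guessing and is bounded", {
  ps <- seq(0, 1, by = 0.05)
  expect_equal(mixture_predict(ps, f = 2, p_guess = 1), rep(0.5, length(ps)))
  expect_equal(mixture_predict(ps, f = 1, p_guess = 0),
               pmin(pmax(ps, 1e-6), 1 - 1e-6), tolerance = 1e-9)
  # interval arithmetic: output confined to [pg/2, 1 - pg/2]
  out <- mixture_predict(ps, f = 1.4, p_guess = 0.2757)
  expect_true(all(out >= 0.13785 & out <= 0.86215))
})

test_that("posterior predictive draws match the mixture mean", {
  params <- list(f = 0.6, p_guess = 0.25)
  # Monte Carlo check at a single gamble
  draws <- posterior_predictive(params, rep(0.8, 10000), n = 50, seed = 3)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - mixture_predict(0.8, 0.6, 0.25)), 0.01)
  # large-n convergence to the mixture probability
  one <- posterior_predictive(params, 0.8, n = 1e6, seed = 4)
  expect_lt(abs(one - mixture_predict(0.8, 0.6, 0.25)), 3 / sqrt(1e6))
  # deterministic given the seed
  expect_identical(posterior_predictive(params, c(0.2, 0.7), 100, seed = 5),
                   posterior_predictive(params, c(0.2, 0.7), 100, seed = 5))
})

test_that("the identity limit concentrates the posterior near (1, 0)", {
  set.seed(10)
  p <- runif(300, 0.05, 0.95)
  k <- rbinom(300, 200, p) # f = 1, p_guess = 0: untouched binomial data
  fit <- fit_noise_model(p, k, 200, n_samples = 3000, n_warmup = 500,
                         seed = 2)
  expect_lt(abs(fit$means["f"] - 1), 0.05)
  expect_lt(fit$means["p_guess"], 0.05)
  expect_true(all(fit$unimodal))
  td <- tidy(fit)
  expect_setequal(td$term, c("f", "p_guess"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("multi-chain fits report diagnostics and flag non-convergence", {
  set.seed(11)
  p <- runif(150, 0.1, 0.9)
  pf <- mixture_predict(p, 0.7, 0.2)
  k <- rbinom(150, 100, pf)
  warns <- character()
  fit <- withCallingHandlers(
    fit_noise_model(p, k, 100, n_samples = 2000, n_warmup = 300,
                    n_chains = 2, seed = 3),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  g <- glance(fit)
  expect_equal(g$n_chains, 2)
  # split-chain R-hat and effective sample sizes are always reported
  expect_false(is.na(g$rhat_f) || is.na(g$rhat_p_guess))
  expect_gt(g$ess_f, 0)
  # the convergence flag matches the R-hat criterion, and non-convergence is
  # surfaced as a warning rather than silently ignored
  expect_equal(g$converged, all(c(g$rhat_f, g$rhat_p_guess) < 1.05))
  expect_equal(any(grepl("converge", warns)), !g$converged)
  # posterior means remain close to the generating values either way
  expect_lt(abs(fit$means["f"] - 0.7), 0.15)
  expect_lt(abs(fit$means["p_guess"] - 0.2), 0.1)
  # posterior predictive path accepts a full fit
  pp <- posterior_predictive(fit, p[1:20], 100, seed = 6)
  expect_length(pp, 20)
  expect_true(all(pp >= 0 & pp <= 1))
})

test_that("fitted noise improves transfer of lab predictions to noisy data", {
  # synthetic analogue of augmenting a lab model with decision noise
  pr <- tiny_problems(250, seed = 61)
  lab <- generate_lab_rates(pr, beast_config(n_agents = 800, seed = 3), 100)
  online <- corrupt_with_noise(lab, f = 0.6, p_guess = 0.25, n = 100,
                               seed = 7)
  k <- round(online$b_rate * 100)
  fit <- fit_noise_model(lab$b_rate, k, 100, n_samples = 3000,
                         n_warmup = 500, seed = 8)
  plain <- mse100(lab$b_rate, online$b_rate)
  noised <- mse100(mixture_predict(lab$b_rate, fit$means["f"],
                                   fit$means["p_guess"]),
                   online$b_rate)
  expect_lt(noised, plain)
})
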