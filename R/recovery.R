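#' End-to-end parameter-recovery experiment
#'
#' The package's headline validation: generate a synthetic problem space,
#' produce lab-like choice rates with BEAST, corrupt them into online-like
#' rates with known noise parameters `(f, p_guess)`, obtain lab-model
#' predictions, fit the decision-noise model by MCMC, and check that the
#' generating parameters are recovered.
#'
#' With `model = "oracle"` the lab-model predictions are the generating lab
#' rates themselves, isolating the inference stage; `model = "rf"` inserts a
#' random forest trained on the lab data, exercising the full pipeline
#' (model error then propagates into the posterior, as it does with real
#' data).
#'
#' @param config A [synth_config()]; its `noise_f`/`noise_p_guess` are the
#'   ground truth.
#' @param beast A [beast_config()] for the lab-rate stage.
#' @param model `"oracle"` or `"rf"` (see above).
#' @param n_samples,n_warmup,n_chains MCMC settings for [fit_noise_model()].
#' @param tol Recovery tolerance on the absolute error of each posterior
#'   mean (default 0.05).
#' @param seed Integer seed driving every stage.
#' @return A `recovery_report`: tibble `summary` (per parameter: truth,
#'   posterior mean, absolute error, credible interval, coverage), the
#'   underlying `noise_fit`, and `passed` (all errors within `tol` and truth
#'   inside the central 95 percent interval).
#' @export
run_recovery_experiment <- function(config = synth_config(),
                                    beast = beast_config(),
                                    model = c("oracle", "rf"),
                                    n_samples = 10000L, n_warmup = 1000L,
                                    n_chains = 1L, tol = 0.05, seed = 1L) {
  model <- match.arg(model)
  config$seed <- as.integer(seed)
  problems <- sample_problem_space(config)
  lab <- generate_lab_rates(problems, beast,
                            n_participants = config$n_participants)
  online <- corrupt_with_noise(lab, f = config$noise_f,
                               p_guess = config$noise_p_guess,
                               n = config$n_participants, seed = seed + 1L)
  p_cpc <- if (model == "oracle") {
    lab$b_rate
  } else {
    fit <- train_choice_model("rf", lab, seed = seed + 2L)
    predict_rates(fit, lab)
  }
  k <- round(online$b_rate * online$n_participants)
  nf <- fit_noise_model(p_cpc, k, online$n_participants,
                        n_samples = n_samples, n_warmup = n_warmup,
                        n_chains = n_chains, seed = seed + 3L)
  td <- tidy(nf)
  truth <- c(f = config$noise_f, p_guess = config$noise_p_guess)
  summary <- dplyr::mutate(
    td,
    truth = unname(truth[td$term]),
    abs_error = abs(.data$estimate - .data$truth),
    covered = .data$truth >= .data$conf.low & .data$truth <= .data$conf.high
  )
  passed <- all(summary$abs_error <= tol) && all(summary$covered)
  structure(list(summary = summary, fit = nf, model = model,
                 tol = tol, passed = passed, seed = seed,
                 n_problems = config$n_problems,
                 n_participants = config$n_participants),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery experiment (", x$n_problems, " problems, n = ",
      x$n_participants, ", lab model: ", x$model, ")\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat(if (x$passed) "PASSED" else "FAILED",
      sprintf(" (tolerance %.3f on posterior means, 95%% coverage)\n", x$tol))
  invisible(x)
}
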