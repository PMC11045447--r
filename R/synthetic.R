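#' Configuration for the synthetic problem/choice generator
#'
#' The generator emulates the laboratory problem space: pairs of gambles in
#' the CPC15 parameterization with payoff magnitudes log-uniform in a range,
#' probabilities on a fixed grid, option-B lottery shapes, ambiguity and
#' feedback conditions at configurable rates. "Lab-like" choice rates are
#' produced by the BEAST simulator ([generate_lab_rates()]) and "online-like"
#' rates by corrupting them with the guess/log-odds decision-noise model and
#' binomial sampling at `n_participants` ([corrupt_with_noise()]).
#'
#' Defaults are the package's reference study conditions: 1,000 problems,
#' 100 participants per problem, noise parameters `f = 0.6` and
#' `p_guess = 0.25`.
#'
#' @param n_problems Number of problems to generate.
#' @param seed Integer seed; generation is deterministic given it.
#' @param payoff_range Two positive numbers; high payoffs are log-uniform in
#'   this range (currency units).
#' @param prob_grid Allowed probability values for `pHa` and `pHb`.
#' @param amb_rate Fraction of problems with an ambiguous option B.
#' @param fb_rate Fraction of problems played with feedback.
#' @param n_participants Participants per problem for the binomial stage.
#' @param noise_f Log-odds multiplier used when corrupting (`> 0`).
#' @param noise_p_guess Guessing proportion used when corrupting (`[0, 1]`).
#' @param n_blocks Number of 5-trial blocks per problem.
#' @param shape_probs Sampling weights of the four option-B lottery shapes.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_problems = 1000L,
                         seed = 1L,
                         payoff_range = c(1, 100),
                         prob_grid = c(0.01, seq(0.05, 0.95, by = 0.05),
                                       0.99, 1.0),
                         amb_rate = 0.2,
                         fb_rate = 0.5,
                         n_participants = 100L,
                         noise_f = 0.6,
                         noise_p_guess = 0.25,
                         n_blocks = 1L,
                         shape_probs = c(none = 0.7, symmetric = 0.1,
                                         right_skewed = 0.1,
                                         left_skewed = 0.1)) {
  stopifnot(n_problems >= 1, length(payoff_range) == 2,
            all(payoff_range > 0), diff(payoff_range) > 0,
            all(prob_grid >= 0 & prob_grid <= 1), length(prob_grid) >= 1,
            amb_rate >= 0, amb_rate <= 1, fb_rate >= 0, fb_rate <= 1,
            n_participants >= 1, noise_f > 0,
            noise_p_guess >= 0, noise_p_guess <= 1, n_blocks >= 1,
            all(shape_probs >= 0), sum(shape_probs) > 0,
            setequal(names(shape_probs), LOT_SHAPES))
  structure(list(n_problems = as.integer(n_problems), seed = as.integer(seed),
                 payoff_range = payoff_range, prob_grid = prob_grid,
                 amb_rate = amb_rate, fb_rate = fb_rate,
                 n_participants = as.integer(n_participants),
                 noise_f = noise_f, noise_p_guess = noise_p_guess,
                 n_blocks = as.integer(n_blocks),
                 shape_probs = shape_probs[LOT_SHAPES]),
            class = "synth_config")
}

#' Sample a synthetic problem space
#'
#' Draws `n_problems` CPC15-format problems. Option A's high payoff is
#' log-uniform in `payoff_range`, its low payoff uniform below it, and its
#' probability from `prob_grid`. Option B is coupled to A's expected value
#' (a multiplicative factor uniform in `[0.6, 1.4]`) so that problems are
#' informative rather than one-sided; its high payoff is then solved from the
#' target expected value. Each problem appears once per block.
#'
#' @param config A [synth_config()].
#' @return A canonical problems tibble (without choice-rate columns).
#' @export
sample_problem_space <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$n_problems
  lo <- log(config$payoff_range[1])
  hi <- log(config$payoff_range[2])

  ha <- round(exp(stats::runif(n, lo, hi)), 1)
  la <- round(stats::runif(n, 0, 0.9) * ha, 1)
  p_ha <- sample(config$prob_grid, n, replace = TRUE)

  ev_a <- p_ha * ha + (1 - p_ha) * la
  target_ev_b <- ev_a * stats::runif(n, 0.6, 1.4)
  p_hb <- sample(config$prob_grid, n, replace = TRUE)
  lb <- round(stats::runif(n, 0, 0.8) * target_ev_b, 1)
  hb <- ifelse(p_hb > 0,
               (target_ev_b - (1 - p_hb) * lb) / pmax(p_hb, 1e-12),
               target_ev_b)
  hb <- round(pmax(hb, lb + 0.1), 1)

  shape <- sample(LOT_SHAPES, n, replace = TRUE,
                  prob = config$shape_probs / sum(config$shape_probs))
  lot_num <- integer(n)
  lot_num[shape == "none"] <- 1L
  n_sym <- sum(shape == "symmetric")
  if (n_sym > 0) lot_num[shape == "symmetric"] <- sample(c(3L, 5L, 7L, 9L),
                                                         n_sym, replace = TRUE)
  n_sk <- sum(shape %in% c("right_skewed", "left_skewed"))
  if (n_sk > 0) lot_num[shape %in% c("right_skewed", "left_skewed")] <-
    sample(2:7, n_sk, replace = TRUE)

  probs <- tibble::tibble(
    id = sprintf("syn%06d", seq_len(n)),
    ha = ha, p_ha = p_ha, la = la,
    hb = hb, p_hb = p_hb, lb = lb,
    lot_shape_b = shape, lot_num_b = lot_num,
    ambiguity = as.integer(stats::runif(n) < config$amb_rate),
    correlation = sample(c(-1L, 0L, 1L), n, replace = TRUE,
                         prob = c(0.1, 0.8, 0.1)),
    feedback = as.integer(stats::runif(n) < config$fb_rate)
  )
  out <- tidyr::crossing(probs, block = seq_len(config$n_blocks))
  dplyr::arrange(out, .data$id, .data$block)
}

#' Generate lab-like choice rates with BEAST
#'
#' Attaches a `b_rate` column holding the BEAST-predicted proportion of
#' agents choosing option B for each (problem, block) row, plus the
#' participant count used downstream. This is the synthetic stand-in for a
#' laboratory dataset.
#'
#' @param problems Canonical problems tibble (e.g. from
#'   [sample_problem_space()]).
#' @param beast A [beast_config()].
#' @param n_participants Participant count recorded on the observations.
#' @return A canonical observations tibble.
#' @export
generate_lab_rates <- function(problems, beast = beast_config(),
                               n_participants = 100L) {
  out <- beast_predict(problems, beast)
  out$b_rate <- out$b_rate_pred
  out$b_rate_pred <- NULL
  out$n_participants <- as.integer(n_participants)
  out
}

#' Corrupt lab-like rates into online-like rates
#'
#' Applies the hybrid decision-noise model to each observation: the lab rate
#' is shrunk toward equipreference in log-odds space by factor `f`, mixed
#' with a guessing proportion `p_guess` at 0.5, and then resampled as a
#' binomial proportion over `n` participants:
#' `p_final = (1 - p_guess) * rescale(b_rate, f) + 0.5 * p_guess`,
#' `b_rate' = k / n` with `k ~ Binomial(n, p_final)`.
#'
#' @param obs Canonical observations tibble with `b_rate`.
#' @param f Log-odds multiplier (`> 0`).
#' @param p_guess Guessing proportion in `[0, 1]`.
#' @param n Participants per observation for the binomial draw.
#' @param seed Integer seed; deterministic given it.
#' @return The observations tibble with corrupted `b_rate` (and
#'   `n_participants = n`); the noiseless mixture probability is kept in
#'   column `p_final`.
#' @export
corrupt_with_noise <- function(obs, f, p_guess, n, seed = 1L) {
  stopifnot(f > 0, p_guess >= 0, p_guess <= 1, n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p_final <- mixture_predict(obs$b_rate, f = f, p_guess = p_guess)
  k <- stats::rbinom(length(p_final), size = n, prob = p_final)
  obs$p_final <- p_final
  obs$b_rate <- k / n
  obs$n_participants <- as.integer(n)
  obs
}
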