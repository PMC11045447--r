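#' BEAST simulator configuration
#'
#' BEAST (Best Estimation And Sampling Tools) predicts the aggregate choice
#' rate for a pair of gambles by simulating a population of heterogeneous
#' agents. Each agent combines (i) the difference in best-estimate expected
#' values of the two gambles, (ii) the mean of a small number of draws from
#' four outcome-sampling tools, and (iii) Gaussian decision noise, and picks
#' gamble A iff the sum is positive. Agent properties are drawn uniformly
#' between 0 and per-property upper bounds.
#'
#' The agent properties are: `sigma` (decision-noise s.d.), `kappa` (number
#' of sampling-tool draws, an integer of at least 1), four tool-tendency
#' weights (`w_uniform`, `w_sign`, `w_pess`, `w_regret`), the pessimism blend
#' weight used to estimate ambiguous probabilities (`amb_pess`, capped at 1)
#' and the reliance on experienced (feedback) information after the first
#' block (`fb_rel`, capped at 1).
#'
#' @param n_agents Number of simulated agents (default 4000).
#' @param upper_bounds Named vector of per-property upper bounds of the
#'   uniform distributions (lower bounds are all 0).
#' @param seed Integer seed; the prediction is deterministic given the seed.
#' @return A `beast_config` object.
#' @export
beast_config <- function(n_agents = 4000L,
                         upper_bounds = c(sigma = 7, kappa = 3,
                                          w_uniform = 1, w_sign = 1,
                                          w_pess = 1, w_regret = 1,
                                          amb_pess = 1, fb_rel = 1),
                         seed = 1L) {
  need <- c("sigma", "kappa", "w_uniform", "w_sign", "w_pess", "w_regret",
            "amb_pess", "fb_rel")
  miss <- setdiff(need, names(upper_bounds))
  if (length(miss) > 0) {
    stop("upper_bounds missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_agents >= 1, all(upper_bounds >= 0))
  structure(list(n_agents = as.integer(n_agents),
                 upper_bounds = upper_bounds[need], seed = as.integer(seed)),
            class = "beast_config")
}

# sample the agent population implied by a config
sample_agents <- function(config) {
  ub <- config$upper_bounds
  n <- config$n_agents
  tibble::tibble(
    sigma = stats::runif(n, 0, ub["sigma"]),
    kappa = pmax(1L, as.integer(ceiling(stats::runif(n, 0, max(ub["kappa"], 1e-12))))),
    w_uniform = stats::runif(n, 0, ub["w_uniform"]),
    w_sign = stats::runif(n, 0, ub["w_sign"]),
    w_pess = stats::runif(n, 0, ub["w_pess"]),
    w_regret = stats::runif(n, 0, ub["w_regret"]),
    amb_pess = stats::runif(n, 0, min(ub["amb_pess"], 1)),
    fb_rel = stats::runif(n, 0, min(ub["fb_rel"], 1))
  )
}

# inverse CDF draw for a lottery at uniform quantiles u
lottery_quantile <- function(lot, u) {
  lot$outcomes[findInterval(u, c(0, cumsum(lot$probs)), rightmost.closed = TRUE)]
}

# best-estimate EV of lottery B for an ambiguous problem: blend of a uniform
# outcome estimate and a point mass on the minimum, weighted by pessimism a
bev_ambiguous <- function(lot, a) {
  (1 - a) * mean(lot$outcomes) + a * lottery_min(lot)
}

#' Simulate agent choices for one problem
#'
#' Low-level vectorized core of the BEAST simulator: given an agent
#' population (one row per agent) and one problem row, returns each agent's
#' choice. Gaussian noise is halved when one lottery first-order
#' stochastically dominates the other, reflecting that dominated gambles are
#' easier decisions.
#'
#' @param problem A single-row problems tibble (canonical columns).
#' @param agents Agent tibble as produced by the internal sampler; columns
#'   `sigma`, `kappa`, `w_uniform`, `w_sign`, `w_pess`, `w_regret`,
#'   `amb_pess`, `fb_rel`.
#' @param block Block index (feedback information is available from block 2
#'   onwards when the problem has feedback).
#' @return Character vector of `"A"`/`"B"`, one per agent.
#' @export
beast_agent_choices <- function(problem, agents, block = problem$block[1]) {
  stopifnot(nrow(problem) == 1)
  ex <- expand_problem(problem)
  lot_a <- ex$lot_a[[1]]
  lot_b <- ex$lot_b[[1]]
  n <- nrow(agents)

  dom <- dominance(lot_a, lot_b, order = 1L)
  sigma_eff <- if (dom != 0L) agents$sigma / 2 else agents$sigma

  # best-estimate EVs
  bev_a <- lottery_ev(lot_a)
  ev_b <- lottery_ev(lot_b)
  if (problem$ambiguity[1] > 0) {
    bev_b0 <- bev_ambiguous(lot_b, agents$amb_pess)
    if (problem$feedback[1] > 0 && block > 1) {
      # feedback reveals the true distribution; agents rely on it partially
      bev_b <- agents$fb_rel * ev_b + (1 - agents$fb_rel) * bev_b0
    } else {
      bev_b <- bev_b0
    }
  } else {
    bev_b <- rep(ev_b, n)
  }

  # sampling-tool draws: each agent takes kappa draws, each draw picks one of
  # the four tools with probability proportional to the agent's tendencies
  w <- as.matrix(agents[, c("w_uniform", "w_sign", "w_pess", "w_regret")])
  wsum <- rowSums(w)
  active <- wsum > 0
  st_diff <- numeric(n)
  if (any(active)) {
    idx <- which(active)
    kap <- agents$kappa[idx]
    aid <- rep(idx, kap) # agent index per draw
    nd <- length(aid)
    cw <- w[aid, , drop = FALSE] / wsum[aid]
    cw[, 2] <- cw[, 1] + cw[, 2]
    cw[, 3] <- cw[, 2] + cw[, 3]
    u_tool <- stats::runif(nd)
    tool <- 1L + (u_tool > cw[, 1]) + (u_tool > cw[, 2]) + (u_tool > cw[, 3])

    max_abs <- max(abs(c(lot_a$outcomes, lot_b$outcomes)))
    da <- numeric(nd)
    db <- numeric(nd)
    # tool 1: equal weighting over distinct outcomes
    t1 <- tool == 1L
    if (any(t1)) {
      da[t1] <- lot_a$outcomes[ceiling(stats::runif(sum(t1)) * length(lot_a$outcomes))]
      db[t1] <- lot_b$outcomes[ceiling(stats::runif(sum(t1)) * length(lot_b$outcomes))]
    }
    # tool 2: best payoff sign (payoffs replaced by sign * problem magnitude)
    t2 <- tool == 2L
    if (any(t2)) {
      da[t2] <- sign(lottery_quantile(lot_a, stats::runif(sum(t2)))) * max_abs
      db[t2] <- sign(lottery_quantile(lot_b, stats::runif(sum(t2)))) * max_abs
    }
    # tool 3: pessimism (worst outcome)
    t3 <- tool == 3L
    if (any(t3)) {
      da[t3] <- lottery_min(lot_a)
      db[t3] <- lottery_min(lot_b)
    }
    # tool 4: regret minimization via a shared quantile for both lotteries
    t4 <- tool == 4L
    if (any(t4)) {
      uq <- stats::runif(sum(t4))
      da[t4] <- lottery_quantile(lot_a, uq)
      db[t4] <- lottery_quantile(lot_b, uq)
    }
    st_diff[idx] <- as.numeric(rowsum(da - db, group = aid)) / kap
  }

  e <- stats::rnorm(n) * sigma_eff
  score <- (bev_a - bev_b) + st_diff + e
  ifelse(score > 0, "A", "B")
}

#' Predict aggregate B-choice rates with BEAST
#'
#' Simulates the configured agent population for every (problem, block) row
#' and returns the fraction of agents choosing gamble B. Deterministic given
#' the config seed: the agent population is drawn once per call, and each row
#' uses an RNG substream derived from the seed and the row index.
#'
#' @param problems Canonical problems/observations tibble.
#' @param config A [beast_config()].
#' @return The input tibble with a `b_rate_pred` column in `[0, 1]`.
#' @export
beast_predict <- function(problems, config = beast_config()) {
  stopifnot(inherits(config, "beast_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  agents <- sample_agents(config)
  n <- nrow(problems)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(as.integer((config$seed * 7919 + i * 2654435) %% 2147483647))
    ch <- beast_agent_choices(problems[i, ], agents,
                              block = problems$block[i])
    pred[i] <- mean(ch == "B")
  }
  problems$b_rate_pred <- pred
  problems
}

#' Fit BEAST upper bounds by grid search
#'
#' Evaluates the mean-squared error of BEAST predictions against observed
#' choice rates for every candidate vector of property upper bounds and
#' returns the configuration minimizing it. Ties are broken by the
#' lexicographically smallest bounds vector.
#'
#' @param train Canonical observations tibble with a `b_rate` column.
#' @param grid A list of named upper-bound vectors (each as accepted by
#'   [beast_config()]).
#' @param n_agents,seed Passed to [beast_config()].
#' @return The winning [beast_config()], with the achieved training MSE
#'   attached as attribute `"mse"`.
#' @export
fit_upper_bounds <- function(train, grid, n_agents = 4000L, seed = 1L) {
  if (length(grid) == 0) stop("empty grid", call. = FALSE)
  stopifnot(nrow(train) >= 1, "b_rate" %in% names(train))
  scores <- vapply(grid, function(ub) {
    cfg <- beast_config(n_agents = n_agents, upper_bounds = ub, seed = seed)
    pred <- beast_predict(train, cfg)$b_rate_pred
    mean((pred - train$b_rate)^2)
  }, numeric(1))
  best <- which(scores <= min(scores) + 1e-12)
  if (length(best) > 1) {
    key <- vapply(grid[best], function(ub) paste(sprintf("%020.10f", ub),
                                                 collapse = ","), character(1))
    best <- best[order(key)][1]
  } else {
    best <- best[1]
  }
  out <- beast_config(n_agents = n_agents, upper_bounds = grid[[best]],
                      seed = seed)
  attr(out, "mse") <- scores[best]
  out
}
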