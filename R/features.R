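#' Per-problem feature table
#'
#' Computes four groups of features for each (problem, block) row, all
#' oriented so that positive values favour gamble B (the quantity models
#' predict is P(B)):
#'
#' * **base** — the raw problem descriptors: `ha`, `p_ha`, `la`, `hb`,
#'   `p_hb`, `lb`, `ambiguity`, `correlation`, `feedback`, `block`.
#' * **naive** — direct arithmetic on the expanded lotteries: `diff_ev`
#'   (`EV(B) - EV(A)`), `diff_sds` (`SD(B) - SD(A)`), `diff_min`, `diff_max`.
#' * **psych** — psychology-motivated quantities: `dom` (first-order
#'   stochastic dominance, `+1` when B dominates, `-1` when A does),
#'   `p_bet_unbiased1` (net probability that B pays more under independent
#'   draws, as in a no-feedback block), `p_bet_unbiased_fb` (the same under
#'   the problem's experienced payoff correlation), `diff_bev0` (difference
#'   in best-estimate EVs without feedback, ambiguous probabilities replaced
#'   by a half-pessimistic estimate) and `diff_bev_fb` (the same once
#'   feedback has revealed the true distribution).
#' * **hosd** — higher-order stochastic dominance: `sosd`, `tosd` in
#'   `{-1, 0, 1}` with the same orientation as `dom`.
#'
#' @param problems Canonical problems/observations tibble.
#' @return A tibble with `id`, `block` and all feature columns; the
#'   group-to-column mapping is attached as attribute `"feature_groups"`
#'   (see [feature_groups()]).
#' @export
feature_table <- function(problems) {
  ex <- expand_problem(problems)
  n <- nrow(ex)

  ev_a <- vapply(ex$lot_a, lottery_ev, numeric(1))
  ev_b <- vapply(ex$lot_b, lottery_ev, numeric(1))
  sd_a <- vapply(ex$lot_a, lottery_sd, numeric(1))
  sd_b <- vapply(ex$lot_b, lottery_sd, numeric(1))
  min_a <- vapply(ex$lot_a, lottery_min, numeric(1))
  min_b <- vapply(ex$lot_b, lottery_min, numeric(1))
  max_a <- vapply(ex$lot_a, lottery_max, numeric(1))
  max_b <- vapply(ex$lot_b, lottery_max, numeric(1))

  dom1 <- integer(n); dom2 <- integer(n); dom3 <- integer(n)
  pb1 <- numeric(n); pbfb <- numeric(n)
  for (i in seq_len(n)) {
    a <- ex$lot_a[[i]]; b <- ex$lot_b[[i]]
    dom1[i] <- -dominance(a, b, 1L) # orient: +1 means B dominates
    dom2[i] <- -dominance(a, b, 2L)
    dom3[i] <- -dominance(a, b, 3L)
    pb1[i] <- p_better(a, b, 0L)
    pbfb[i] <- p_better(a, b, as.integer(ex$correlation[i]))
  }

  # best-estimate EV of B before feedback: ambiguous problems use a
  # half-pessimistic estimate (the prior mean of the agents' blend weight)
  bev_b0 <- ifelse(ex$ambiguity > 0,
                   vapply(ex$lot_b, bev_ambiguous, numeric(1), a = 0.5),
                   ev_b)

  out <- tibble::tibble(
    id = ex$id,
    ha = ex$ha, p_ha = ex$p_ha, la = ex$la,
    hb = ex$hb, p_hb = ex$p_hb, lb = ex$lb,
    ambiguity = as.numeric(ex$ambiguity),
    correlation = as.numeric(ex$correlation),
    feedback = as.numeric(ex$feedback),
    block = as.numeric(ex$block),
    diff_ev = ev_b - ev_a,
    diff_sds = sd_b - sd_a,
    diff_min = min_b - min_a,
    diff_max = max_b - max_a,
    dom = as.numeric(dom1),
    p_bet_unbiased1 = pb1,
    p_bet_unbiased_fb = pbfb,
    diff_bev0 = bev_b0 - ev_a,
    diff_bev_fb = ev_b - ev_a,
    sosd = as.numeric(dom2),
    tosd = as.numeric(dom3)
  )
  attr(out, "feature_groups") <- list(
    base = c("ha", "p_ha", "la", "hb", "p_hb", "lb", "ambiguity",
             "correlation", "feedback", "block"),
    naive = c("diff_ev", "diff_sds", "diff_min", "diff_max"),
    psych = c("dom", "p_bet_unbiased1", "p_bet_unbiased_fb", "diff_bev0",
              "diff_bev_fb"),
    hosd = c("sosd", "tosd")
  )
  out
}

#' Feature group annotation of a feature table
#'
#' @param features A tibble produced by [feature_table()].
#' @return Named list mapping group (`base`, `naive`, `psych`, `hosd`) to
#'   column names.
#' @export
feature_groups <- function(features) {
  fg <- attr(features, "feature_groups")
  if (is.null(fg)) stop("not a feature table (no feature_groups attribute)",
                        call. = FALSE)
  fg
}

#' Prevalence of stochastic dominance in a problem set
#'
#' Fraction of problems in which one gamble dominates the other at first,
#' second and third order. Lower order implies higher order, so the three
#' prevalences are nondecreasing.
#'
#' @param problems Canonical problems tibble (blocks deduplicated by `id`).
#' @return A tibble with columns `order` and `prevalence`.
#' @export
dominance_prevalence <- function(problems) {
  probs <- dplyr::distinct(problems, .data$id, .keep_all = TRUE)
  ex <- expand_problem(probs)
  counts <- vapply(1:3, function(ord) {
    mean(vapply(seq_len(nrow(ex)), function(i) {
      dominance(ex$lot_a[[i]], ex$lot_b[[i]], ord) != 0L
    }, logical(1)))
  }, numeric(1))
  tibble::tibble(order = c("FOSD", "SOSD", "TOSD"), prevalence = counts)
}
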