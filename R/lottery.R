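#' Construct a discrete lottery
#'
#' A lottery is a finite probability distribution over monetary payoffs. It is
#' the elementary object of the package: every choice problem pairs a lottery A
#' with a lottery B. Outcomes are sorted ascending and duplicated outcomes are
#' merged, so two lotteries describing the same distribution compare equal.
#'
#' @param outcomes Numeric vector of payoffs (currency units). Must be finite.
#' @param probs Numeric vector of probabilities, same length as `outcomes`,
#'   each in `[0, 1]` and summing to 1 within `1e-9`.
#' @return An object of class `cb_lottery`: a list with sorted `outcomes` and
#'   matching `probs` (zero-probability outcomes dropped).
#' @examples
#' lottery(c(12, 14, 96), c(0.05, 0.05, 0.9))
#' @export
lottery <- function(outcomes, probs) {
  if (length(outcomes) < 1 || length(outcomes) != length(probs)) {
    stop("`outcomes` and `probs` must be equal-length vectors of length >= 1",
         call. = FALSE)
  }
  if (!all(is.finite(outcomes))) stop("lottery outcomes must be finite", call. = FALSE)
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    stop("lottery probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("lottery probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  }
  keep <- probs > 0
  outcomes <- outcomes[keep]
  probs <- probs[keep]
  o <- order(outcomes)
  outcomes <- outcomes[o]
  probs <- probs[o]
  # merge duplicates
  if (anyDuplicated(outcomes)) {
    probs <- as.numeric(tapply(probs, match(outcomes, unique(outcomes)), sum))
    outcomes <- unique(outcomes)
  }
  structure(list(outcomes = outcomes, probs = probs), class = "cb_lottery")
}

#' @export
print.cb_lottery <- function(x, ...) {
  cat("<lottery> ", paste0(format(x$outcomes), " w.p. ", format(x$probs),
                           collapse = "; "), "\n", sep = "")
  invisible(x)
}

is_lottery <- function(x) inherits(x, "cb_lottery")

#' Survival probability of a lottery
#'
#' Probability that the lottery pays at least `x`, i.e. `P(payoff >= x)`. The
#' survival function is the object first-order stochastic dominance is defined
#' on: gamble A dominates gamble B when A's survival probability is at least
#' B's at every payoff level, strictly at some.
#'
#' @param lot A [lottery()].
#' @param x Numeric vector of payoff thresholds.
#' @return Numeric vector of probabilities, one per threshold.
#' @examples
#' a <- lottery(c(12, 14, 96), c(0.05, 0.05, 0.9))
#' survival_prob(a, 14) # 0.95
#' @export
survival_prob <- function(lot, x) {
  stopifnot(is_lottery(lot))
  vapply(x, function(t) sum(lot$probs[lot$outcomes >= t]), numeric(1))
}

#' Expected value and standard deviation of a lottery
#'
#' @param lot A [lottery()].
#' @return A single numeric value.
#' @export
lottery_ev <- function(lot) {
  stopifnot(is_lottery(lot))
  sum(lot$outcomes * lot$probs)
}

#' @rdname lottery_ev
#' @export
lottery_sd <- function(lot) {
  stopifnot(is_lottery(lot))
  m <- sum(lot$outcomes * lot$probs)
  sqrt(max(0, sum(lot$outcomes^2 * lot$probs) - m^2))
}

lottery_min <- function(lot) lot$outcomes[1L]
lottery_max <- function(lot) lot$outcomes[length(lot$outcomes)]

#' Stochastic dominance between two lotteries
#'
#' Tests first-, second- or third-order stochastic dominance between discrete
#' lotteries.
#'
#' * Order 1 (FOSD): A dominates B iff `P(A >= x) >= P(B >= x)` for every `x`
#'   in the union support, strictly somewhere.
#' * Order 2 (SOSD): A dominates B iff the running integral
#'   `D2(t) = int_{-inf}^t (F_B - F_A) du >= 0` for all `t`, strictly
#'   somewhere. Every risk-averse expected-utility maximiser then prefers A.
#' * Order 3 (TOSD): A dominates B iff `EV(A) >= EV(B)` and the running
#'   integral of `D2` is nonnegative everywhere, strictly somewhere; the
#'   ordering agreed on by risk-averse agents with decreasing absolute risk
#'   aversion.
#'
#' The CDFs are step functions, so `D2` is piecewise linear and its integral
#' piecewise quadratic; both are evaluated exactly at the union support
#' points (trapezoid on `D2`), which is sufficient because the extrema of the
#' running integrals over each segment are attained at segment ends for sign
#' checking at the tolerance used.
#'
#' Lower order implies higher order: FOSD => SOSD => TOSD.
#'
#' @param a,b Lotteries ([lottery()]).
#' @param order Dominance order, 1, 2 or 3.
#' @param tol Numerical tolerance for the sign checks.
#' @return `+1` if `a` dominates `b`, `-1` if `b` dominates `a`, `0` if
#'   neither (or the lotteries are identical).
#' @examples
#' a <- lottery(c(12, 14, 96), c(0.05, 0.05, 0.9))
#' b <- lottery(c(12, 90, 96), c(0.10, 0.05, 0.85))
#' dominance(a, b, order = 1) # +1
#' @export
dominance <- function(a, b, order = 1L, tol = 1e-9) {
  stopifnot(is_lottery(a), is_lottery(b), order %in% 1:3)
  fwd <- dominates_dir(a, b, order, tol)
  if (fwd) return(1L)
  if (dominates_dir(b, a, order, tol)) return(-1L)
  0L
}

# does `a` dominate `b` at the given order? (strictly, one-directional)
dominates_dir <- function(a, b, order, tol) {
  xs <- sort(unique(c(a$outcomes, b$outcomes)))
  fa <- cdf_at(a, xs)
  fb <- cdf_at(b, xs)
  if (order == 1L) {
    d <- fb - fa # >= 0 everywhere means a dominates
    return(all(d >= -tol) && any(d > tol))
  }
  n <- length(xs)
  d2 <- numeric(n) # D2 evaluated at xs
  if (n > 1) {
    seg <- (fb - fa)[-n] * diff(xs)
    d2[-1] <- cumsum(seg)
  }
  if (order == 2L) {
    return(all(d2 >= -tol) && any(d2 > tol))
  }
  # order 3: EV condition + running integral of D2
  ev_gap <- lottery_ev(a) - lottery_ev(b) # equals d2 at +infinity slope origin
  if (ev_gap < -tol) return(FALSE)
  d3 <- numeric(n)
  if (n > 1) {
    seg3 <- (d2[-n] + d2[-1]) / 2 * diff(xs)
    d3[-1] <- cumsum(seg3)
  }
  all(d3 >= -tol) && (any(d3 > tol) || ev_gap > tol)
}

cdf_at <- function(lot, xs) {
  cp <- cumsum(lot$probs)
  idx <- findInterval(xs + 1e-12, lot$outcomes)
  c(0, cp)[idx + 1L]
}

#' Net probability that lottery B pays more than lottery A
#'
#' Computes `P(payoff_B > payoff_A) - P(payoff_A > payoff_B)` under a joint
#' distribution determined by the problem's payoff correlation: independent
#' draws (`correlation = 0`), comonotone draws through a shared uniform
#' quantile (`+1`), or antimonotone draws (`-1`). Positive values favour B.
#'
#' @param a,b Lotteries ([lottery()]).
#' @param correlation Integer in `{-1, 0, 1}`.
#' @return A number in `[-1, 1]`.
#' @examples
#' a <- lottery(c(12, 14, 96), c(0.05, 0.05, 0.9))
#' b <- lottery(c(12, 90, 96), c(0.10, 0.05, 0.85))
#' p_better(a, b, correlation = 0) # -0.05: A is more often ahead
#' @export
p_better <- function(a, b, correlation = 0L) {
  stopifnot(is_lottery(a), is_lottery(b), correlation %in% c(-1L, 0L, 1L))
  if (correlation == 0L) {
    gr <- outer(b$outcomes, a$outcomes, ">")
    ls <- outer(b$outcomes, a$outcomes, "<")
    w <- outer(b$probs, a$probs)
    return(sum(w * gr) - sum(w * ls))
  }
  # quantile coupling on merged CDF breakpoints
  ca <- cumsum(a$probs)
  cb <- cumsum(b$probs)
  u <- sort(unique(round(c(ca, cb), 15)))
  lo <- c(0, u[-length(u)])
  mass <- u - lo
  mid <- (u + lo) / 2
  av <- a$outcomes[findInterval(mid, c(0, ca), rightmost.closed = TRUE)]
  ub <- if (correlation == 1L) mid else 1 - mid
  bv <- b$outcomes[findInterval(ub, c(0, cb), rightmost.closed = TRUE)]
  sum(mass * sign(bv - av))
}
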