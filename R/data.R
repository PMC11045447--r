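#' @importFrom rlang .data
NULL

# canonical column schema for choice observations (one row per problem x block)
CANONICAL_COLS <- c(
  "id", "ha", "p_ha", "la", "hb", "p_hb", "lb",
  "lot_shape_b", "lot_num_b", "ambiguity", "correlation", "feedback",
  "block", "n_participants", "b_rate"
)

LOT_SHAPES <- c("none", "symmetric", "right_skewed", "left_skewed")

# external shape coding used by the CPC-style files
SHAPE_CODES <- c("-" = "none", "Symm" = "symmetric",
                 "R-skew" = "right_skewed", "L-skew" = "left_skewed")

# per-dialect column dictionaries: external name -> canonical name
DIALECTS <- list(
  canonical = stats::setNames(CANONICAL_COLS, CANONICAL_COLS),
  cpc15 = c(Problem = "id", Ha = "ha", pHa = "p_ha", La = "la",
            Hb = "hb", pHb = "p_hb", Lb = "lb", LotShape = "lot_shape_b",
            LotNum = "lot_num_b", Amb = "ambiguity", Corr = "correlation",
            Feedback = "feedback", Block = "block", N = "n_participants",
            B_rate = "b_rate"),
  cpc18 = c(Problem = "id", Ha = "ha", pHa = "p_ha", La = "la",
            Hb = "hb", pHb = "p_hb", Lb = "lb", LotShapeB = "lot_shape_b",
            LotNumB = "lot_num_b", Amb = "ambiguity", Corr = "correlation",
            Feedback = "feedback", Block = "block", N = "n_participants",
            B_rate = "b_rate"),
  choices13k = c(Problem = "id", Ha = "ha", pHa = "p_ha", La = "la",
                 Hb = "hb", pHb = "p_hb", Lb = "lb", LotShapeB = "lot_shape_b",
                 LotNumB = "lot_num_b", Amb = "ambiguity", Corr = "correlation",
                 Feedback = "feedback", Block = "block", n = "n_participants",
                 bRate = "b_rate")
)

#' Validate a tibble of choice observations
#'
#' Checks the canonical schema and the domain invariants: probabilities and
#' choice rates in `[0, 1]`, payoffs finite, `lot_shape_b` one of
#' `r paste(LOT_SHAPES, collapse = ", ")`, `correlation` in `{-1, 0, 1}`,
#' blocks and participant counts at least 1, and that every row expands to two
#' valid lotteries.
#'
#' @param data A tibble with the canonical columns.
#' @param expand Also check lottery expansion (slower). Default `TRUE`.
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_observations <- function(data, expand = TRUE) {
  miss <- setdiff(CANONICAL_COLS, names(data))
  if (length(miss) > 0) {
    stop("format error: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("format error: no observations", call. = FALSE)
  with(data, {
    stopifnot(
      all(p_ha >= 0 & p_ha <= 1), all(p_hb >= 0 & p_hb <= 1),
      all(is.finite(ha)), all(is.finite(la)), all(is.finite(hb)),
      all(is.finite(lb)),
      all(lot_shape_b %in% LOT_SHAPES), all(lot_num_b >= 1),
      all(ambiguity %in% c(0, 1)), all(correlation %in% c(-1, 0, 1)),
      all(feedback %in% c(0, 1)), all(block >= 1),
      all(n_participants >= 1), all(b_rate >= 0 & b_rate <= 1)
    )
  })
  if (expand) invisible(expand_problem(dplyr::distinct(
    data, .data$id, .keep_all = TRUE)))
  invisible(data)
}

#' Expand CPC-format problems into explicit lottery pairs
#'
#' A problem row parameterizes lottery A as `{Ha w.p. pHa; La w.p. 1 - pHa}`
#' and lottery B by `(Hb, pHb, Lb)` plus a lottery shape: `Hb` may stand for a
#' multi-outcome distribution. `symmetric` spreads `pHb` binomially over
#' `lot_num_b` integer-spaced outcomes centred on `Hb`; the skewed shapes
#' spread it geometrically (weights \eqn{0.5^i}, the last doubled) over
#' outcomes `Hb + C +/- 2^i` with `C = -(1 + k)` (right) or `C = 1 + k`
#' (left), `k = lot_num_b`. All three expansions preserve the conditional
#' mean: the expanded branch of B has expected value `Hb`.
#'
#' @param problems Tibble with (at least) the problem columns of the
#'   canonical schema.
#' @return The input tibble with two added list-columns, `lot_a` and `lot_b`,
#'   holding [lottery()] objects.
#' @examples
#' p <- tibble::tibble(id = "x", ha = 50, p_ha = 1, la = 0, hb = 90,
#'                     p_hb = 0.05, lb = 12, lot_shape_b = "none",
#'                     lot_num_b = 1, ambiguity = 0, correlation = 0,
#'                     feedback = 0, block = 1)
#' expand_problem(p)$lot_b[[1]]
#' @export
expand_problem <- function(problems) {
  need <- c("ha", "p_ha", "la", "hb", "p_hb", "lb", "lot_shape_b", "lot_num_b")
  miss <- setdiff(need, names(problems))
  if (length(miss) > 0) {
    stop("format error: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  problems$lot_a <- purrr::pmap(
    list(problems$ha, problems$p_ha, problems$la),
    function(h, p, l) lottery(c(h, l), c(p, 1 - p))
  )
  problems$lot_b <- purrr::pmap(
    list(problems$hb, problems$p_hb, problems$lb,
         problems$lot_shape_b, problems$lot_num_b),
    expand_lottery_b
  )
  problems
}

# expansion of option B for one row
expand_lottery_b <- function(hb, p_hb, lb, shape, num) {
  if (!shape %in% LOT_SHAPES) {
    stop("format error: unknown lot shape '", shape, "'", call. = FALSE)
  }
  num <- as.integer(num)
  if (shape == "none") {
    if (num != 1L) stop("format error: lot_shape 'none' requires lot_num 1",
                        call. = FALSE)
    return(lottery(c(hb, lb), c(p_hb, 1 - p_hb)))
  }
  if (num < 2L) stop("format error: shaped lotteries need lot_num >= 2",
                     call. = FALSE)
  if (shape == "symmetric") {
    if (num %% 2L == 0L) stop("format error: symmetric shape needs odd lot_num",
                              call. = FALSE)
    k <- num - 1L
    outs <- hb + seq(-k / 2, k / 2)
    w <- stats::dbinom(0:k, k, 0.5)
  } else {
    i <- seq_len(num)
    w <- 0.5^i
    w[num] <- w[num] * 2 # geometric tail folded into the last outcome
    if (shape == "right_skewed") {
      outs <- hb - (1 + num) + 2^i
    } else {
      outs <- hb + (1 + num) - 2^i
    }
  }
  lottery(c(outs, lb), c(w * p_hb, 1 - p_hb))
}

#' Read a choice dataset
#'
#' Reads a CSV of aggregate binary risky choices in one of four dialects:
#' `cpc15`, `cpc18`, `choices13k` (column dictionaries mirroring the published
#' files of the respective studies) or `canonical` (this package's snake_case
#' schema). Output is one row per (problem, block) with the aggregate rate of
#' choosing option B.
#'
#' For `cpc18`, the newer format allows option A to carry a lottery shape;
#' such rows cannot be represented in the earlier format and are dropped
#' (compatibility filter: keep rows with `LotShapeA == "-"` and
#' `LotNumA <= 1`).
#'
#' @param path CSV file path (comma-separated, UTF-8, header row).
#' @param dialect One of `"canonical"`, `"cpc15"`, `"cpc18"`, `"choices13k"`.
#' @return A validated tibble of choice observations in canonical form.
#' @export
read_choice_data <- function(path,
                             dialect = c("canonical", "cpc15", "cpc18",
                                         "choices13k")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop("format error: empty file: ", path, call. = FALSE)
  map <- DIALECTS[[dialect]]
  miss <- setdiff(names(map), names(raw))
  if (length(miss) > 0) {
    stop("format error: dialect '", dialect, "' missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (dialect == "cpc18") {
    if (all(c("LotShapeA", "LotNumA") %in% names(raw))) {
      raw <- dplyr::filter(raw, .data$LotShapeA == "-", .data$LotNumA <= 1)
      if (nrow(raw) == 0) {
        stop("format error: no format-compatible rows in ", path, call. = FALSE)
      }
    }
  }
  out <- raw[, names(map)]
  names(out) <- unname(map)
  if (dialect != "canonical") {
    out$lot_shape_b <- unname(SHAPE_CODES[as.character(out$lot_shape_b)])
    out$feedback <- as.integer(as.logical(out$feedback))
    out$ambiguity <- as.integer(as.logical(out$ambiguity))
  }
  out$id <- as.character(out$id)
  out <- tibble::as_tibble(out)
  validate_observations(out, expand = FALSE)
  out
}

#' Write choice observations to CSV
#'
#' @param data Canonical tibble of choice observations.
#' @param path Output CSV path.
#' @param dialect Output dialect (see [read_choice_data()]).
#' @return `path`, invisibly.
#' @export
write_choice_data <- function(data, path,
                              dialect = c("canonical", "cpc15", "cpc18",
                                          "choices13k")) {
  dialect <- match.arg(dialect)
  validate_observations(data, expand = FALSE)
  map <- DIALECTS[[dialect]]
  out <- data[, unname(map)]
  names(out) <- names(map)
  if (dialect != "canonical") {
    inv <- stats::setNames(names(SHAPE_CODES), SHAPE_CODES)
    shape_col <- names(map)[map == "lot_shape_b"]
    out[[shape_col]] <- unname(inv[as.character(out[[shape_col]])])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split observations into train and test sets at the problem level
#'
#' All blocks of a problem end up on the same side, so no information about a
#' test problem leaks into training. The split is stratified by the problem's
#' feedback condition to avoid condition imbalance, and is deterministic given
#' `seed`.
#'
#' @param data Canonical tibble of choice observations.
#' @param fraction Train fraction in `(0, 1)`. Default `0.8`.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  probs <- dplyr::summarise(dplyr::group_by(data, .data$id),
                            fb = as.integer(any(.data$feedback > 0)),
                            .groups = "drop")
  n <- nrow(probs)
  if (n < 2) stop("need at least 2 problems to split", call. = FALSE)
  n_train <- round(fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  # largest-remainder allocation of the train quota across strata
  strata <- split(probs$id, probs$fb)
  quota <- vapply(strata, length, integer(1)) * n_train / n
  base <- floor(quota)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train_ids <- unlist(purrr::map2(strata, base, function(ids, k) {
    if (k >= length(ids)) return(ids)
    sample(ids, k)
  }), use.names = FALSE)
  list(
    train = dplyr::filter(data, .data$id %in% train_ids),
    test = dplyr::filter(data, !(.data$id %in% train_ids))
  )
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
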