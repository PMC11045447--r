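# shared fixtures: the worked dominance example and small problem builders

worked_lottery_a <- function() lottery(c(12, 14, 96), c(0.05, 0.05, 0.90))
worked_lottery_b <- function() lottery(c(12, 90, 96), c(0.10, 0.05, 0.85))

# small synthetic problem set (one block) at a fixed seed
tiny_problems <- function(n = 20, seed = 101, ...) {
  sample_problem_space(synth_config(n_problems = n, seed = seed, ...))
}

# minimal canonical observations tibble built by hand
make_obs <- function(n = 4, b_rate = NULL, n_blocks = 1, feedback = 0) {
  base <- tibble::tibble(
    id = sprintf("p%02d", seq_len(n)),
    ha = 50 + seq_len(n), p_ha = 0.5, la = 10,
    hb = 60 + seq_len(n), p_hb = 0.4, lb = 5,
    lot_shape_b = "none", lot_num_b = 1L,
    ambiguity = 0L, correlation = 0L,
    feedback = as.integer(rep_len(feedback, n))
  )
  out <- tidyr::crossing(base, block = seq_len(n_blocks))
  out$n_participants <- 25L
  out$b_rate <- if (is.null(b_rate)) {
    rep_len(seq(0.1, 0.9, length.out = n), nrow(out))
  } else rep_len(b_rate, nrow(out))
  out
}

# locate a real study CSV (not distributed with the package; see README):
# looked up under options(choicebias.data_dir=), then ./data-raw
real_data_file <- function(file) {
  for (dir in c(getOption("choicebias.data_dir", "data-raw"),
                file.path("..", "..", "data-raw"))) {
    p <- file.path(dir, file)
    if (file.exists(p)) return(p)
  }
  file.path(getOption("choicebias.data_dir", "data-raw"), file)
}
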