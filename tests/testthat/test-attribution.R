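test_that("group regression recovers exact and null relationships", {
  set.seed(21)
  n <- 5000
  feats <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * feats$a - feats$b + rnorm(n, sd = 0.01)
  # regressing the target on itself is perfect
  self <- fit_group_regression(tibble::tibble(y = y), y, "y")
  expect_equal(self$r_squared, 1, tolerance = 1e-12)
  # pure-noise target: R^2 near zero
  null <- fit_group_regression(feats, rnorm(n), c("a", "b", "c"))
  expect_lt(null$r_squared, 0.01)
  # rank-deficient design (duplicated column) is handled
  feats$a2 <- feats$a
  dup <- fit_group_regression(feats, y, c("a", "a2", "b"))
  expect_gt(dup$r_squared, 0.99)
})

test_that("nested feature groups never decrease in-sample R-squared", {
  pr <- tiny_problems(300, seed = 71)
  ft <- feature_table(pr)
  set.seed(22)
  target <- 0.3 * ft$dom + 0.2 * tanh(ft$diff_ev / 10) + rnorm(300, sd = 0.05)
  tab <- regression_table(ft, target)
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$r_squared) >= -1e-9))
  expect_true(all(diff(tab$mse) <= 1e-9))
  expect_equal(tab$r_squared[1], 0)
})

test_that("single-feature R-squared and its Fisher interval behave", {
  set.seed(23)
  y <- rnorm(500)
  perfect <- per_feature_r2(y, y)
  expect_equal(perfect$r_squared, 1)
  indep <- per_feature_r2(rnorm(500), y)
  expect_lt(indep$r_squared, 0.02)
  expect_equal(indep$conf.low, 0) # interval covers zero
  expect_warning(zv <- per_feature_r2(rep(1, 500), y), "zero-variance")
  expect_equal(zv$r_squared, 0)
  tabl <- feature_r2_table(feature_table(tiny_problems(50, seed = 81)),
                           rnorm(50))
  expect_true(all(c("feature", "group", "r_squared") %in% names(tabl)))
  expect_true(all(tabl$r_squared >= 0 & tabl$r_squared <= 1))
})

test_that("Shapley attributions match the linear closed form exactly", {
  set.seed(24)
  X <- data.frame(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(8))
  bg <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60), d = rnorm(60))
  f <- function(dd) 1.5 * dd$a - 2 * dd$b + 0.25 * dd$c # d unused
  phi <- shap_attributions(f, X, bg, seed = 1)
  closed <- cbind(1.5 * (X$a - mean(bg$a)), -2 * (X$b - mean(bg$b)),
                  0.25 * (X$c - mean(bg$c)), 0 * X$d)
  expect_equal(unname(phi[, ]), unname(closed), tolerance = 1e-10)
  # null-feature axiom: the unused feature gets zero attribution
  expect_true(all(abs(phi[, "d"]) < 1e-10))
  # local accuracy on every row
  expect_true(all(abs(attr(phi, "base_value") + rowSums(phi) - f(X)) < 1e-3))
  expect_error(shap_attributions(f, X, bg[0, ]), "nonempty")
})

test_that("local accuracy also holds for a nonlinear function", {
  set.seed(25)
  X <- data.frame(a = rnorm(6), b = rnorm(6), c = rnorm(6))
  bg <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  f <- function(dd) tanh(dd$a * dd$b) + dd$c^2
  phi <- shap_attributions(f, X, bg, seed = 2)
  expect_true(all(abs(attr(phi, "base_value") + rowSums(phi) - f(X)) < 1e-3))
})

test_that("features linearly encoded in the function are recoverable from SHAP", {
  set.seed(26)
  n <- 120
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  bg <- X[sample.int(n, 40), ]
  f <- function(dd) 2 * dd$a - dd$b
  phi <- shap_attributions(f, X, bg, seed = 3)
  expect_gt(regress_feature_on_shap(X$a, phi), 0.99)
  r_rand <- regress_feature_on_shap(rnorm(n), phi)
  expect_lt(r_rand, 0.2)
  expect_gte(r_rand, 0)
})
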