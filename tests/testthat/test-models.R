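test_that("context-network encoding pads and normalizes correctly", {
  p <- make_obs(1)
  p$ha <- 7; p$p_ha <- 1; p$la <- 0 # sure thing
  p$hb <- 20; p$p_hb <- 0.6; p$lb <- 1
  p$lot_shape_b <- "symmetric"; p$lot_num_b <- 3L
  X <- to_context_input(p, max_support = 10)
  pa <- X[1, 11:20]
  pb <- X[1, 31:40]
  # sure-thing lottery: exactly one probability entry, equal to 1
  expect_equal(sum(pa > 0), 1)
  expect_equal(sum(pa), 1)
  # expanded B: binomial branch (3) + low outcome, probabilities sum to 1
  expect_equal(sum(pb > 0), 4)
  expect_equal(sum(pb), 1, tolerance = 1e-12)
  # padding entries are hard zeros
  expect_true(all(pa[2:10] == 0))
  expect_error(to_context_input(p, max_support = 2), "max_support")
})

test_that("SET step conserves connections and removes near-zero weights", {
  net <- mlp_new(c(5, 2, 1), activation = "sigmoid", density = 0.5, seed = 8)
  # hand-built 5-weight toy layer: 3 positive, 2 negative actives
  ly <- net$layers[[1]]
  ly$mask[] <- FALSE
  ly$W[] <- 0
  slots <- c(1, 3, 5, 7, 9)
  ly$mask[slots] <- TRUE
  ly$W[slots] <- c(0.01, 0.5, -0.02, -0.7, 0.3)
  net$layers[[1]] <- ly
  before <- mlp_connections(net)
  out <- set_step(net, 0.5)
  after <- mlp_connections(out)
  expect_identical(before, after)
  # removed: smallest positive (0.01 at slot 1), largest negative (-0.02 at 5)
  expect_false(out$layers[[1]]$mask[1] && abs(out$layers[[1]]$W[1]) > 0.05)
  expect_false(out$layers[[1]]$mask[5] && abs(out$layers[[1]]$W[5]) > 0.05)
  # survivors untouched
  expect_equal(out$layers[[1]]$W[3], 0.5)
  expect_equal(out$layers[[1]]$W[7], -0.7)
  expect_equal(out$layers[[1]]$W[9], 0.3)
  # zeta = 0 is the identity
  expect_identical(set_step(net, 0), net)
})

test_that("an unregularized context network can drive train error to zero", {
  obs <- make_obs(10, b_rate = seq(0.15, 0.85, length.out = 10))
  sched <- train_schedule(context_epochs = 4000L, context_lr = 5e-3,
                          batch_size = 10L)
  m <- train_choice_model("peterson", obs, schedule = sched, seed = 2)
  pred <- predict_rates(m, obs)
  expect_true(all(pred > 0 & pred < 1))
  expect_lt(mean((pred - obs$b_rate)^2), 1e-3) # overfit sanity
})

test_that("the sparse perceptron trains reproducibly through pre-training", {
  pr <- tiny_problems(120, seed = 41)
  lab <- generate_lab_rates(pr, beast_config(n_agents = 300, seed = 2), 50)
  sp <- split_train_test(lab, 0.75, seed = 1)
  sched <- train_schedule(pretrain_epochs = 15L, finetune_epochs = 10L,
                          finetune_lr = 1e-4)
  m1 <- train_choice_model("bourgin", sp$train, pretrain = lab,
                           schedule = sched, seed = 3)
  p1 <- predict_rates(m1, sp$test)
  expect_true(all(p1 > 0 & p1 < 1))
  m2 <- train_choice_model("bourgin", sp$train, pretrain = lab,
                           schedule = sched, seed = 3)
  expect_identical(p1, predict_rates(m2, sp$test))
  # sparse masks stay sparse through training
  g <- glance(m1)
  expect_lt(g$n_connections, 14 * 200 + 200 * 275 + 275 * 100 + 100)
  expect_equal(g$kind, "bourgin")
})

test_that("random forest and SVM train on the handcrafted feature set", {
  pr <- tiny_problems(80, seed = 51)
  lab <- generate_lab_rates(pr, beast_config(n_agents = 300, seed = 2), 50)
  for (kind in c("rf", "svm")) {
    m <- train_choice_model(kind, lab, seed = 4)
    p <- predict_rates(m, lab)
    expect_true(all(p >= 0 & p <= 1))
    # fitted models track the training signal far better than the mean
    expect_lt(mse100(p, lab$b_rate), mse100(rep(mean(lab$b_rate), nrow(lab)),
                                            lab$b_rate))
  }
})
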