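#' Training schedule for the neural choice models
#'
#' Defaults follow the published training recipes: the sparse perceptron is
#' pre-trained for 300 epochs at learning rate `1e-3` (RMSProp) with epoch
#' checkpointing on held-out validation loss, then fine-tuned at `1e-6`; the
#' context network trains with Adam at `1e-3` for 100 epochs with an
#' optional 20-epoch pre-training. Tests and small studies pass reduced
#' epoch counts; the architecture is unchanged.
#'
#' @param pretrain_epochs,pretrain_lr Pre-training epochs / learning rate.
#' @param finetune_epochs,finetune_lr Fine-tuning epochs / learning rate
#'   (use ~100 for a large online-style dataset, ~3000 for a small
#'   laboratory-style dataset).
#' @param batch_size Minibatch size.
#' @param set_epsilon Fraction of connections present in the sparse layers.
#' @param set_zeta SET rewire fraction per pre-training epoch.
#' @param dropout Per-layer dropout rate of the sparse perceptron.
#' @param val_fraction Fraction of the pre-training data held out for
#'   checkpoint selection.
#' @param context_epochs,context_lr,context_pretrain_epochs Context-network
#'   training epochs, learning rate and optional pre-training epochs.
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(pretrain_epochs = 300L, pretrain_lr = 1e-3,
                           finetune_epochs = 100L, finetune_lr = 1e-6,
                           batch_size = 32L, set_epsilon = 0.2,
                           set_zeta = 0.3, dropout = 0.15,
                           val_fraction = 0.1, context_epochs = 100L,
                           context_lr = 1e-3, context_pretrain_epochs = 20L) {
  structure(list(pretrain_epochs = pretrain_epochs, pretrain_lr = pretrain_lr,
                 finetune_epochs = finetune_epochs, finetune_lr = finetune_lr,
                 batch_size = batch_size, set_epsilon = set_epsilon,
                 set_zeta = set_zeta, dropout = dropout,
                 val_fraction = val_fraction, context_epochs = context_epochs,
                 context_lr = context_lr,
                 context_pretrain_epochs = context_pretrain_epochs),
            class = "train_schedule")
}

# numeric design matrix of the problem descriptors for the sparse perceptron
base_input_matrix <- function(problems) {
  cbind(
    ha = problems$ha, p_ha = problems$p_ha, la = problems$la,
    hb = problems$hb, p_hb = problems$p_hb, lb = problems$lb,
    lot_num_b = as.numeric(problems$lot_num_b),
    shape_symmetric = as.numeric(problems$lot_shape_b == "symmetric"),
    shape_right = as.numeric(problems$lot_shape_b == "right_skewed"),
    shape_left = as.numeric(problems$lot_shape_b == "left_skewed"),
    ambiguity = as.numeric(problems$ambiguity),
    correlation = as.numeric(problems$correlation),
    feedback = as.numeric(problems$feedback),
    block = as.numeric(problems$block)
  )
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

#' Context-network input encoding of a problem
#'
#' Expands each problem into the two lotteries and encodes them as four
#' fixed-length vectors `(xA, pA, xB, pB)`: outcome values and their
#' probabilities, zero-padded to `max_support` entries per lottery. The
#' context flags (ambiguity, correlation, feedback, block) are deliberately
#' not encoded — the context network sees only the payoff distributions.
#'
#' @param problems Canonical problems tibble.
#' @param max_support Maximum number of outcomes per lottery (default 10,
#'   which covers all CPC-format expansions).
#' @return Numeric matrix with `4 * max_support` columns.
#' @export
to_context_input <- function(problems, max_support = 10L) {
  ex <- expand_problem(problems)
  n <- nrow(ex)
  X <- matrix(0, n, 4L * max_support)
  pad <- function(v, k) c(v, rep(0, k - length(v)))
  for (i in seq_len(n)) {
    a <- ex$lot_a[[i]]
    b <- ex$lot_b[[i]]
    if (length(a$outcomes) > max_support || length(b$outcomes) > max_support) {
      stop("lottery support exceeds max_support = ", max_support,
           call. = FALSE)
    }
    X[i, ] <- c(pad(a$outcomes, max_support), pad(a$probs, max_support),
                pad(b$outcomes, max_support), pad(b$probs, max_support))
  }
  colnames(X) <- c(paste0("xa", seq_len(max_support)),
                   paste0("pa", seq_len(max_support)),
                   paste0("xb", seq_len(max_support)),
                   paste0("pb", seq_len(max_support)))
  X
}

#' Train a reference choice model
#'
#' Trains one of the four model families on aggregate B-choice rates:
#'
#' * `"bourgin"` — sparse multilayer perceptron on the problem descriptors:
#'   hidden layers of 200, 275 and 100 SReLU units, dropout 0.15, sigmoid
#'   output, RMSProp, sparse evolutionary training during pre-training,
#'   validation-checkpointed pre-training followed by low-learning-rate
#'   fine-tuning. Inputs are standardized with statistics fitted on the
#'   first dataset the network sees.
#' * `"peterson"` — context network `P(A) = g(xA, pA, xB, pB)` with two
#'   32-unit sigmoid hidden layers, Adam; no regularization (on very small
#'   datasets this class overfits, which is a property of the model family,
#'   not a bug).
#' * `"rf"` — random forest (500 trees, minimum node size 5, 4 candidate
#'   features per split) on base + naive + psychological features.
#' * `"svm"` — RBF-kernel support vector regression (`C = 1`, standardized
#'   features) on base + naive + psychological features; predictions are
#'   clipped to `[0, 1]`.
#'
#' @param kind Model family (see above).
#' @param train Canonical observations tibble with `b_rate`.
#' @param pretrain Optional observations tibble for pre-training (synthetic
#'   lab-model data, the "cognitive model prior").
#' @param schedule A [train_schedule()].
#' @param seed Integer seed; training is reproducible given it.
#' @return A `choice_model` object; predict with [predict_rates()].
#' @export
train_choice_model <- function(kind = c("bourgin", "peterson", "rf", "svm"),
                               train, pretrain = NULL,
                               schedule = train_schedule(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(nrow(train) >= 1, "b_rate" %in% names(train))
  obj <- switch(kind,
    bourgin = train_bourgin(train, pretrain, schedule, seed),
    peterson = train_peterson(train, pretrain, schedule, seed),
    rf = train_rf(train, seed),
    svm = train_svm(train, seed)
  )
  obj$kind <- kind
  obj$seed <- seed
  obj$n_train <- nrow(train)
  class(obj) <- c(paste0("choice_model_", kind), "choice_model")
  obj
}

train_bourgin <- function(train, pretrain, schedule, seed) {
  first <- if (!is.null(pretrain)) pretrain else train
  scaler <- fit_scaler(base_input_matrix(first))
  net <- mlp_new(c(14L, 200L, 275L, 100L, 1L), activation = "srelu",
                 dropout = schedule$dropout, density = schedule$set_epsilon,
                 seed = seed)
  if (!is.null(pretrain)) {
    X <- apply_scaler(base_input_matrix(pretrain), scaler)
    y <- pretrain$b_rate
    n <- nrow(X)
    n_val <- max(1L, round(schedule$val_fraction * n))
    old <- .Random.seed_save(); set.seed(seed + 17L)
    val_idx <- sample.int(n, n_val)
    .Random.seed_restore(old)
    net <- mlp_train(net, X[-val_idx, , drop = FALSE], y[-val_idx],
                     epochs = schedule$pretrain_epochs,
                     lr = schedule$pretrain_lr, optimizer = "rmsprop",
                     batch_size = schedule$batch_size,
                     zeta = schedule$set_zeta,
                     X_val = X[val_idx, , drop = FALSE], y_val = y[val_idx],
                     seed = seed)
    lr <- schedule$finetune_lr
  } else {
    lr <- schedule$pretrain_lr # from-scratch training needs the high rate
  }
  Xt <- apply_scaler(base_input_matrix(train), scaler)
  net <- mlp_train(net, Xt, train$b_rate, epochs = schedule$finetune_epochs,
                   lr = lr, optimizer = "rmsprop",
                   batch_size = schedule$batch_size, zeta = NULL,
                   seed = seed + 1L)
  list(net = net, scaler = scaler, schedule = schedule)
}

train_peterson <- function(train, pretrain, schedule, seed) {
  net <- mlp_new(c(40L, 32L, 32L, 1L), activation = "sigmoid",
                 dropout = 0, density = NULL, seed = seed)
  if (!is.null(pretrain)) {
    Xp <- to_context_input(pretrain)
    net <- mlp_train(net, Xp, 1 - pretrain$b_rate,
                     epochs = schedule$context_pretrain_epochs,
                     lr = schedule$context_lr, optimizer = "adam",
                     batch_size = schedule$batch_size, seed = seed)
  }
  X <- to_context_input(train)
  net <- mlp_train(net, X, 1 - train$b_rate, # network outputs P(A)
                   epochs = schedule$context_epochs,
                   lr = schedule$context_lr, optimizer = "adam",
                   batch_size = schedule$batch_size, seed = seed + 1L)
  list(net = net)
}

model_feature_matrix <- function(problems) {
  ft <- feature_table(problems)
  fg <- feature_groups(ft)
  as.matrix(ft[, c(fg$base, fg$naive, fg$psych)])
}

train_rf <- function(train, seed) {
  X <- model_feature_matrix(train)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = train$b_rate, ntree = 500,
                                    nodesize = 5, mtry = 4)
  list(fit = fit)
}

train_svm <- function(train, seed) {
  X <- model_feature_matrix(train)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- e1071::svm(x = X, y = train$b_rate, kernel = "radial", cost = 1,
                    scale = apply(X, 2, stats::sd) > 0)
  list(fit = fit)
}

#' Predict aggregate B-choice rates
#'
#' Generic over the model families produced by [train_choice_model()]; plain
#' functions of a problems tibble are accepted too (useful for stub models).
#'
#' @param model A `choice_model` or a function `problems -> rates`.
#' @param problems Canonical problems tibble.
#' @return Numeric vector of predicted P(B) in `[0, 1]`.
#' @export
predict_rates <- function(model, problems) UseMethod("predict_rates")

#' @export
predict_rates.function <- function(model, problems) {
  p <- model(problems)
  stopifnot(length(p) == nrow(problems))
  pmin(pmax(p, 0), 1)
}

#' @export
predict_rates.choice_model_bourgin <- function(model, problems) {
  X <- apply_scaler(base_input_matrix(problems), model$scaler)
  mlp_predict(model$net, X)
}

#' @export
predict_rates.choice_model_peterson <- function(model, problems) {
  1 - mlp_predict(model$net, to_context_input(problems))
}

#' @export
predict_rates.choice_model_rf <- function(model, problems) {
  p <- unname(stats::predict(model$fit, model_feature_matrix(problems)))
  pmin(pmax(p, 0), 1)
}

#' @export
predict_rates.choice_model_svm <- function(model, problems) {
  p <- unname(stats::predict(model$fit, model_feature_matrix(problems)))
  pmin(pmax(p, 0), 1)
}

#' @export
print.choice_model <- function(x, ...) {
  cat("<choice_model:", x$kind, "> trained on", x$n_train, "observations\n")
  invisible(x)
}

#' One-row summary of a trained choice model
#'
#' @param x A `choice_model`.
#' @param ... Unused.
#' @return A tibble with the model family, training size and (for the
#'   neural families) the active connection count.
#' @export
glance.choice_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_train = x$n_train,
    n_connections = if (!is.null(x$net)) sum(mlp_connections(x$net)) else NA_integer_
  )
}
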