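# Minimal dense/sparse multilayer perceptron engine used by the reference
# choice models. Implements: SReLU and sigmoid hidden activations, inverted
# dropout, RMSProp / Adam / SGD updates, mean-squared-error loss on a
# sigmoid output unit, static sparse connectivity masks, and the sparse
# evolutionary training (SET) prune-and-regrow step.

#' Create a multilayer perceptron
#'
#' @param sizes Integer vector of layer widths, input first, output last
#'   (the output layer always has a sigmoid activation so predictions live
#'   in (0, 1)).
#' @param activation Hidden activation: `"srelu"` (S-shaped rectified linear
#'   unit with four learnable parameters per unit — left/right thresholds
#'   and slopes, initialized to near-identity behaviour) or `"sigmoid"`.
#' @param dropout Dropout rate applied to each hidden layer's activations
#'   during training (inverted dropout; 0 disables).
#' @param density Fraction of connections initially present per layer
#'   (`NULL` or 1 for dense). Sparse layers carry a binary mask that the SET
#'   step rewires.
#' @param seed Integer seed for weight initialization.
#' @return An `mlp` object.
#' @export
mlp_new <- function(sizes, activation = c("srelu", "sigmoid"),
                    dropout = 0, density = NULL, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nl <- length(sizes) - 1L
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    W <- matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
                fan_in, fan_out)
    mask <- NULL
    if (!is.null(density) && density < 1) {
      mask <- matrix(stats::runif(fan_in * fan_out) < density, fan_in, fan_out)
      # ensure nonempty mask so the layer is trainable
      if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
      W <- W * mask
    }
    act <- if (l == nl) "output" else activation
    sp <- NULL
    if (act == "srelu") {
      sp <- list(tl = rep(0, fan_out), al = rep(0.2, fan_out),
                 tr = rep(1, fan_out), ar = rep(1, fan_out))
    }
    layers[[l]] <- list(W = W, b = rep(0, fan_out), mask = mask,
                        act = act, sp = sp)
  }
  structure(list(sizes = sizes, layers = layers, dropout = dropout,
                 opt_state = NULL),
            class = "mlp")
}

srelu_fwd <- function(Z, sp) {
  TL <- matrix(sp$tl, nrow(Z), ncol(Z), byrow = TRUE)
  AL <- matrix(sp$al, nrow(Z), ncol(Z), byrow = TRUE)
  TR <- matrix(sp$tr, nrow(Z), ncol(Z), byrow = TRUE)
  AR <- matrix(sp$ar, nrow(Z), ncol(Z), byrow = TRUE)
  lo <- Z <= TL
  hi <- Z >= TR
  A <- Z
  A[lo] <- (TL + AL * (Z - TL))[lo]
  A[hi] <- (TR + AR * (Z - TR))[hi]
  list(A = A, lo = lo, hi = hi)
}

#' Forward pass / prediction
#'
#' @param net An [mlp_new()] object.
#' @param X Numeric matrix, one row per example.
#' @return Numeric vector of outputs in (0, 1).
#' @export
mlp_predict <- function(net, X) {
  A <- as.matrix(X)
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- sweep(A %*% ly$W, 2, ly$b, "+")
    A <- switch(ly$act,
                output = stats::plogis(Z),
                sigmoid = stats::plogis(Z),
                srelu = srelu_fwd(Z, ly$sp)$A)
  }
  as.numeric(A)
}

# one optimizer update; st is an environment holding slot caches
opt_update <- function(st, key, g, lr, optimizer, t) {
  if (optimizer == "sgd") return(-lr * g)
  if (optimizer == "rmsprop") {
    c0 <- st[[key]]
    if (is.null(c0)) c0 <- g * 0
    c1 <- 0.9 * c0 + 0.1 * g^2
    st[[key]] <- c1
    return(-lr * g / (sqrt(c1) + 1e-8))
  }
  # adam
  m0 <- st[[paste0(key, ".m")]]
  v0 <- st[[paste0(key, ".v")]]
  if (is.null(m0)) { m0 <- g * 0; v0 <- g * 0 }
  m1 <- 0.9 * m0 + 0.1 * g
  v1 <- 0.999 * v0 + 0.001 * g^2
  st[[paste0(key, ".m")]] <- m1
  st[[paste0(key, ".v")]] <- v1
  mh <- m1 / (1 - 0.9^t)
  vh <- v1 / (1 - 0.999^t)
  -lr * mh / (sqrt(vh) + 1e-8)
}

#' Train a multilayer perceptron on choice rates
#'
#' Minibatch training with mean-squared-error loss on the sigmoid output.
#' When `zeta` is given and the network has sparse masks, a SET
#' prune-and-regrow step ([set_step()]) runs after every epoch. When a
#' validation set is given, the weights achieving the best validation loss
#' are restored at the end (epoch checkpointing).
#'
#' @param net An [mlp_new()] object.
#' @param X,y Training inputs (matrix) and targets in `[0, 1]`.
#' @param epochs Number of passes over the data.
#' @param lr Learning rate.
#' @param optimizer `"rmsprop"`, `"adam"` or `"sgd"`.
#' @param batch_size Minibatch size.
#' @param zeta SET rewire fraction per epoch (`NULL` disables).
#' @param X_val,y_val Optional validation set for checkpoint selection.
#' @param seed Integer seed for shuffling, dropout and rewiring.
#' @return The trained `mlp`, with the realized training-loss trace in
#'   attribute `"loss"` (and `"val_loss"` if validation was used).
#' @export
mlp_train <- function(net, X, y, epochs, lr, optimizer = "rmsprop",
                      batch_size = 32L, zeta = NULL, X_val = NULL,
                      y_val = NULL, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  t <- 0L
  nl <- length(net$layers)
  n <- nrow(X)
  loss_trace <- numeric(epochs)
  val_trace <- numeric(epochs)
  best_val <- Inf
  best_layers <- NULL
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + batch_size - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      m <- length(rows)
      t <- t + 1L

      # forward with caches
      caches <- vector("list", nl)
      A <- Xb
      for (l in seq_len(nl)) {
        ly <- net$layers[[l]]
        Z <- sweep(A %*% ly$W, 2, ly$b, "+")
        cache <- list(A_prev = A, Z = Z)
        if (ly$act %in% c("output", "sigmoid")) {
          A2 <- stats::plogis(Z)
        } else {
          sf <- srelu_fwd(Z, ly$sp)
          A2 <- sf$A
          cache$lo <- sf$lo
          cache$hi <- sf$hi
        }
        if (l < nl && net$dropout > 0) {
          keep <- matrix(stats::runif(length(A2)) >= net$dropout,
                         nrow(A2), ncol(A2))
          A2 <- A2 * keep / (1 - net$dropout)
          cache$keep <- keep
        }
        caches[[l]] <- cache
        A <- A2
      }
      yhat <- as.numeric(A)

      # backward
      delta <- matrix(2 * (yhat - yb) / m, ncol = 1) # dL/dA at output
      for (l in rev(seq_len(nl))) {
        ly <- net$layers[[l]]
        ca <- caches[[l]]
        if (!is.null(ca$keep)) {
          delta <- delta * ca$keep / (1 - net$dropout)
        }
        if (ly$act %in% c("output", "sigmoid")) {
          sig <- stats::plogis(ca$Z)
          dZ <- delta * sig * (1 - sig)
        } else {
          AL <- matrix(ly$sp$al, nrow(ca$Z), ncol(ca$Z), byrow = TRUE)
          AR <- matrix(ly$sp$ar, nrow(ca$Z), ncol(ca$Z), byrow = TRUE)
          TLm <- matrix(ly$sp$tl, nrow(ca$Z), ncol(ca$Z), byrow = TRUE)
          TRm <- matrix(ly$sp$tr, nrow(ca$Z), ncol(ca$Z), byrow = TRUE)
          slope <- matrix(1, nrow(ca$Z), ncol(ca$Z))
          slope[ca$lo] <- AL[ca$lo]
          slope[ca$hi] <- AR[ca$hi]
          dZ <- delta * slope
          # parameter gradients of the activation
          g_tl <- colSums(delta * (1 - AL) * ca$lo)
          g_al <- colSums(delta * (ca$Z - TLm) * ca$lo)
          g_tr <- colSums(delta * (1 - AR) * ca$hi)
          g_ar <- colSums(delta * (ca$Z - TRm) * ca$hi)
          ly$sp$tl <- ly$sp$tl + opt_update(st, paste0("tl", l), g_tl, lr,
                                            optimizer, t)
          ly$sp$al <- ly$sp$al + opt_update(st, paste0("al", l), g_al, lr,
                                            optimizer, t)
          ly$sp$tr <- ly$sp$tr + opt_update(st, paste0("tr", l), g_tr, lr,
                                            optimizer, t)
          ly$sp$ar <- ly$sp$ar + opt_update(st, paste0("ar", l), g_ar, lr,
                                            optimizer, t)
        }
        gW <- crossprod(ca$A_prev, dZ)
        gb <- colSums(dZ)
        if (!is.null(ly$mask)) gW <- gW * ly$mask
        delta <- dZ %*% t(ly$W) # propagate before updating W
        ly$W <- ly$W + opt_update(st, paste0("W", l), gW, lr, optimizer, t)
        if (!is.null(ly$mask)) ly$W <- ly$W * ly$mask
        ly$b <- ly$b + opt_update(st, paste0("b", l), gb, lr, optimizer, t)
        net$layers[[l]] <- ly
      }
    }
    if (!is.null(zeta) && zeta > 0) net <- set_step(net, zeta)
    loss_trace[ep] <- mean((mlp_predict(net, X) - y)^2)
    if (!is.null(X_val)) {
      val_trace[ep] <- mean((mlp_predict(net, X_val) - y_val)^2)
      if (val_trace[ep] < best_val) {
        best_val <- val_trace[ep]
        best_layers <- net$layers
      }
    }
  }
  if (!is.null(best_layers)) net$layers <- best_layers
  attr(net, "loss") <- loss_trace
  if (!is.null(X_val)) attr(net, "val_loss") <- val_trace
  net
}

#' Sparse evolutionary training rewiring step
#'
#' For every sparse layer, removes the fraction `zeta` of the smallest
#' positive and of the largest (closest to zero) negative active weights —
#' the connections contributing least — and adds the same number of new
#' connections at random inactive positions with small random weights, so
#' the total connection count is conserved exactly.
#'
#' @param net An [mlp_new()] object with sparse masks.
#' @param zeta Rewire fraction in `[0, 1)`.
#' @return The rewired `mlp`.
#' @export
set_step <- function(net, zeta) {
  stopifnot(zeta >= 0, zeta < 1)
  if (zeta == 0) return(net)
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    if (is.null(ly$mask)) next
    w <- ly$W
    act <- which(ly$mask)
    pos <- act[w[act] > 0]
    neg <- act[w[act] < 0]
    rm_pos <- if (length(pos) > 0) {
      pos[order(w[pos])][seq_len(floor(zeta * length(pos)))]
    } else integer(0)
    rm_neg <- if (length(neg) > 0) {
      neg[order(w[neg], decreasing = TRUE)][seq_len(floor(zeta * length(neg)))]
    } else integer(0)
    drop <- c(rm_pos, rm_neg)
    if (length(drop) == 0) next
    ly$mask[drop] <- FALSE
    ly$W[drop] <- 0
    inactive <- which(!ly$mask)
    grow <- if (length(inactive) <= length(drop)) inactive else {
      inactive[sample.int(length(inactive), length(drop))]
    }
    ly$mask[grow] <- TRUE
    ly$W[grow] <- stats::rnorm(length(grow), sd = 0.01)
    net$layers[[l]] <- ly
  }
  net
}

#' Number of active connections per layer
#'
#' @param net An [mlp_new()] object.
#' @return Integer vector: active (mask `TRUE`, or all for dense layers)
#'   connection counts per layer.
#' @export
mlp_connections <- function(net) {
  vapply(net$layers, function(ly) {
    if (is.null(ly$mask)) length(ly$W) else sum(ly$mask)
  }, integer(1))
}
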