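## Model fitting: Adam on categorical cross-entropy with early stopping.

#' Training protocol configuration
#'
#' Defaults follow the study protocol: Adam at learning rate 0.001,
#' categorical cross-entropy, parameter updates after every 300 inputs,
#' at most 200 epochs, and early stopping after 20 epochs without
#' improvement. The monitored quantity defaults to the training loss — under
#' subject-disjoint cross-validation the held-out fold must not steer
#' training — but validation monitoring is available.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Inputs per parameter update.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without strict improvement before stopping.
#' @param monitor `"train_loss"`, `"train_acc"`, `"val_loss"` or
#'   `"val_acc"`.
#' @param beta1,beta2,epsilon Adam moment constants.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 300,
                         max_epochs = 200, patience = 20,
                         monitor = c("train_loss", "train_acc",
                                     "val_loss", "val_acc"),
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  monitor <- match.arg(monitor)
  stopifnot(batch_size >= 1, patience >= 1, patience < max_epochs)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 monitor = monitor, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon), class = "train_config")
}

## Early-stopping rule as a pure function: given the sequence of monitored
## values (oriented so smaller is better), the patience and the epoch cap,
## return the 1-based epoch after which training stops and the best epoch.
## "Improvement" is a strict decrease.
stopping_epoch <- function(monitor_values, patience, max_epochs) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(monitor_values)) {
    if (monitor_values[e] < best) {
      best <- monitor_values[e]; best_epoch <- e; wait <- 0L
    } else wait <- wait + 1L
    if (wait >= patience || e >= max_epochs)
      return(list(stop_epoch = e, best_epoch = best_epoch))
  }
  list(stop_epoch = length(monitor_values), best_epoch = best_epoch)
}

## Flatten/apply Adam state over the nested weight structure.
adam_update <- function(weights, grads, state, cfg, t) {
  lr_t <- cfg$learning_rate * sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  upd <- function(w, g, m, v) {
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
    w <- w - lr_t * m / (sqrt(v) + cfg$epsilon)
    list(w = w, m = m, v = v)
  }
  for (l in seq_along(weights$leads))
    for (s in seq_along(weights$leads[[l]]))
      for (j in seq_along(weights$leads[[l]][[s]])) {
        for (nm in c("W", "b")) {
          r <- upd(weights$leads[[l]][[s]][[j]][[nm]],
                   grads$leads[[l]][[s]][[j]][[nm]],
                   state$leads[[l]][[s]][[j]][[paste0("m", nm)]],
                   state$leads[[l]][[s]][[j]][[paste0("v", nm)]])
          weights$leads[[l]][[s]][[j]][[nm]] <- r$w
          state$leads[[l]][[s]][[j]][[paste0("m", nm)]] <- r$m
          state$leads[[l]][[s]][[j]][[paste0("v", nm)]] <- r$v
        }
      }
  for (nm in c("W", "b")) {
    r <- upd(weights$head[[nm]], grads$head[[nm]],
             state$head[[paste0("m", nm)]], state$head[[paste0("v", nm)]])
    weights$head[[nm]] <- r$w
    state$head[[paste0("m", nm)]] <- r$m
    state$head[[paste0("v", nm)]] <- r$v
  }
  list(weights = weights, state = state)
}

init_adam_state <- function(weights) {
  zero_like <- function(x) { x[] <- 0; x }
  leads <- lapply(weights$leads, function(lead)
    lapply(lead, function(path)
      lapply(path, function(layer)
        list(mW = zero_like(layer$W), vW = zero_like(layer$W),
             mb = zero_like(layer$b), vb = zero_like(layer$b)))))
  list(leads = leads,
       head = list(mW = zero_like(weights$head$W), vW = zero_like(weights$head$W),
                   mb = zero_like(weights$head$b), vb = zero_like(weights$head$b)))
}

one_hot <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  if (anyNA(match(labels, classes)))
    stop_ecgmi("labels outside the declared class set")
  y
}

#' Fit a multi-lead feature-concatenate network
#'
#' The single fitting entry point of the package: trains an N-Net
#' (`scales = 1`) or MSN-Net (`scales > 1`) on beat windows with Adam,
#' categorical cross-entropy, mini-batches, dropout before the output layer
#' and early stopping. Deterministic for fixed seeds: `seed` controls
#' weight initialization and dropout; `order_seed` controls the within-epoch
#' data order (the same `order_seed` yields the same input order across
#' different model configurations, keeping grid comparisons paired).
#'
#' @param x Beat windows: array 12 x L x n, or a `beat_set`, or an
#'   `ecg_bundle` (in which case `y` is taken from the bundle labels).
#' @param y Class labels (character or factor, length n). Ignored when `x`
#'   is an `ecg_bundle`.
#' @param config A [model_config()] (or arguments via `...` to build one).
#' @param train A [train_config()].
#' @param seed Weight-initialization / dropout seed.
#' @param order_seed Data-order seed (defaults to `seed`).
#' @param validation Optional list(x =, y =) monitored per epoch.
#' @param classes Class levels; defaults to the sorted unique labels (or
#'   the bundle's class set).
#' @param ... Arguments forwarded to [model_config()] when `config` is
#'   missing.
#' @return An object of class `mi_net`: weights, layer spec, training
#'   history and the class levels.
#' @export
mi_net <- function(x, y = NULL, config = NULL, train = train_config(),
                   seed = 1, order_seed = seed, validation = NULL,
                   classes = NULL, ...) {
  if (inherits(x, "ecg_bundle")) {
    if (is.null(classes)) classes <- x$classes
    y <- x$beats$meta$label
    x <- x$beats$x
  } else if (inherits(x, "beat_set")) {
    x <- x$x
  }
  stopifnot(length(dim(x)) == 3, dim(x)[1] == 12)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (is.null(config)) config <- model_config(classes = length(classes),
                                              input_length = dim(x)[2], ...)
  if (config$classes != length(classes))
    stop_ecgmi("config declares %d classes but %d labels present",
               config$classes, length(classes))
  n <- dim(x)[3]
  if (n == 0) stop_ecgmi("empty training set")
  if (length(y) != n) stop_ecgmi("length(y) != number of beat windows")
  spec <- build_model_spec(config)
  Y <- one_hot(y, classes)
  weights <- init_weights(spec, seed)
  state <- init_adam_state(weights)

  val <- NULL
  if (!is.null(validation)) {
    vx <- if (inherits(validation$x, "beat_set")) validation$x$x else validation$x
    val <- list(x = vx, y = one_hot(as.character(validation$y), classes))
  }
  monitor_needs_val <- train$monitor %in% c("val_loss", "val_acc")
  if (monitor_needs_val && is.null(val))
    stop_ecgmi("monitor = %s requires validation data", train$monitor)

  history <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  best_val <- Inf; best_weights <- weights; best_epoch <- 0L; wait <- 0L
  step <- 0L
  drop_rate <- config$dropout_rate

  for (epoch in seq_len(train$max_epochs)) {
    ord <- with_seed(derive_seed(order_seed, "order", epoch), sample(n))
    epoch_loss <- 0; epoch_correct <- 0
    for (start in seq(1L, n, by = train$batch_size)) {
      idx <- ord[start:min(start + train$batch_size - 1L, n)]
      xb <- x[, , idx, drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      step <- step + 1L
      mask <- if (drop_rate > 0)
        with_seed(derive_seed(seed, "drop", step),
                  matrix(stats::rbinom(length(idx) * spec$feature_width, 1,
                                       1 - drop_rate) / (1 - drop_rate),
                         length(idx), spec$feature_width))
      fwd <- net_forward(weights, xb, spec, dropout_mask = mask)
      grads <- net_backward(weights, xb, yb, fwd, spec, dropout_mask = mask)
      r <- adam_update(weights, grads, state, train, step)
      weights <- r$weights; state <- r$state
      epoch_loss <- epoch_loss + cross_entropy(fwd$probs, yb) * length(idx)
      epoch_correct <- epoch_correct +
        sum(max.col(fwd$probs, ties.method = "first") == max.col(yb, ties.method = "first"))
    }
    loss <- epoch_loss / n; acc <- epoch_correct / n
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(val)) {
      vf <- net_forward(weights, val$x, spec)
      val_loss <- cross_entropy(vf$probs, val$y)
      val_acc <- mean(max.col(vf$probs, ties.method = "first") == max.col(val$y, ties.method = "first"))
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = loss, acc = acc,
                                         val_loss = val_loss, val_acc = val_acc))
    mon <- switch(train$monitor, train_loss = loss, train_acc = -acc,
                  val_loss = val_loss, val_acc = -val_acc)
    if (mon < best_val) {
      best_val <- mon; best_weights <- weights; best_epoch <- epoch; wait <- 0L
    } else wait <- wait + 1L
    if (wait >= train$patience) break
  }

  structure(list(weights = best_weights, spec = spec, classes = classes,
                 history = history, best_epoch = best_epoch,
                 epochs_run = nrow(history), train = train,
                 seed = seed, order_seed = order_seed,
                 n_train = n), class = "mi_net")
}

#' @export
print.mi_net <- function(x, ...) {
  cfg <- x$spec$config
  cat(sprintf("%s: 12-lead feature-concatenate network (S=%d, F=%d, C=%d)\n",
              if (cfg$scales == 1) "N-Net" else "MSN-Net",
              cfg$scales, cfg$filters, cfg$classes))
  cat(sprintf("  %d trainable parameters; trained %d epochs (best at %d) on %d beats\n",
              x$spec$n_parameters, x$epochs_run, x$best_epoch, x$n_train))
  cat(sprintf("  final training loss %.4f, accuracy %.2f%%\n",
              x$history$loss[nrow(x$history)],
              100 * x$history$acc[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.mi_net <- function(object, ...) {
  print(object)
  cat("\nLayer plan (one lead branch, replicated over 12 leads):\n")
  print(object$spec$layers, row.names = FALSE)
  invisible(object)
}

#' @export
coef.mi_net <- function(object, ...) object$weights

#' Predict method for fitted networks
#'
#' @param object A fitted `mi_net`.
#' @param newdata Array 12 x L x n, `beat_set` or `ecg_bundle`.
#' @param type `"prob"` for per-class soft-max probabilities, `"class"`
#'   for hard labels.
#' @param ... Unused.
#' @return n x C probability matrix or a character vector of labels.
#' @export
predict.mi_net <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "ecg_bundle")) newdata$beats$x
       else if (inherits(newdata, "beat_set")) newdata$x else newdata
  probs <- net_forward(object$weights, x, object$spec)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, ties.method = "first")]
}

#' Plot training history
#'
#' @param x A fitted `mi_net`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mi_net <- function(x, ...) {
  h <- x$history
  has_val <- !all(is.na(h$val_loss))
  graphics::par(mfrow = c(1, 2))
  graphics::matplot(h$epoch, cbind(h$loss, if (has_val) h$val_loss),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::matplot(h$epoch, cbind(h$acc, if (has_val) h$val_acc),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy", ...)
  invisible(x)
}
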