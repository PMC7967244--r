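## Multi-lead multi-scale feature-concatenate networks (N-Net / MSN-Net).
##
## Every lead has its own branch. A branch holds S parallel scale paths:
## path s first applies (s - 1) learnable pooling convolutions (kernel =
## stride = pooling factor), then two valid kernel-3 convolutions, all with
## F filters and ReLU, then global average pooling, yielding F features.
## The 12 * S * F features are concatenated, passed through dropout and one
## soft-max output layer of C units. S = 1 is the N-Net; S > 1 the MSN-Net.

#' Network configuration
#'
#' @param scales Number of parallel scale paths S (1-5). 1 gives the
#'   single-scale N-Net, more the multi-scale MSN-Net.
#' @param filters Filters per convolution F (>= 1).
#' @param classes Output classes C (2 for detection, 6 for locating).
#' @param input_length Samples per beat window (default 400).
#' @param dropout_rate Dropout rate before the output layer.
#' @param pool_factor Kernel = stride of the learnable pooling convolutions.
#' @param input_scale Fixed multiplier applied to the input signal before
#'   the first convolution. Beat windows carry microvolt amplitudes; the
#'   default 1e-3 presents them to the network in millivolt, the physical
#'   unit clinical ECG tooling works in, keeping activations near unit
#'   scale.
#' @return Object of class `model_config`.
#' @export
model_config <- function(scales = 1, filters = 9, classes = 2,
                         input_length = 400, dropout_rate = 0.5,
                         pool_factor = 2, input_scale = 1e-3) {
  stopifnot(scales >= 1, filters >= 1, classes >= 2, input_length > 2,
            pool_factor >= 2, dropout_rate >= 0, dropout_rate < 1)
  len <- input_length
  for (s in seq_len(scales)) {
    l <- len
    for (p in seq_len(s - 1)) l <- floor((l - pool_factor) / pool_factor) + 1
    if (l - 4 < 1)
      stop_ecgmi("scale %d leaves length %d; two kernel-3 convolutions need length > 4", s, l)
  }
  structure(list(scales = as.integer(scales), filters = as.integer(filters),
                 classes = as.integer(classes),
                 input_length = as.integer(input_length),
                 num_leads = 12L, dropout_rate = dropout_rate,
                 pool_factor = as.integer(pool_factor),
                 input_scale = input_scale),
            class = "model_config")
}

#' Layer-by-layer model specification
#'
#' Expands a configuration into the ordered per-scale layer table of one
#' lead branch (replicated with independent weights across the 12 leads),
#' the concatenation width and the classifier head, with temporal lengths
#' and per-layer parameter counts. Feature-extraction convolutions are
#' unpadded, so each shortens the temporal axis by exactly 2.
#'
#' @param config A [model_config()].
#' @return Object of class `model_spec` with elements `layers`
#'   (data.frame), `feature_width` (12 * S * F), `n_parameters` and the
#'   config.
#' @export
build_model_spec <- function(config) {
  stopifnot(inherits(config, "model_config"))
  F <- config$filters; P <- config$pool_factor
  rows <- list()
  for (s in seq_len(config$scales)) {
    len <- config$input_length
    cin <- 1L
    for (p in seq_len(s - 1)) {
      out_len <- floor((len - P) / P) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        scale = s, layer = sprintf("pool%d", p), kind = "conv",
        kernel = P, stride = P, filters = F, cin = cin,
        in_len = len, out_len = out_len, activation = "relu",
        params = (P * cin + 1L) * F)
      len <- out_len; cin <- F
    }
    for (j in 1:2) {
      out_len <- len - 2L
      rows[[length(rows) + 1L]] <- data.frame(
        scale = s, layer = sprintf("conv%d", j), kind = "conv",
        kernel = 3L, stride = 1L, filters = F, cin = cin,
        in_len = len, out_len = out_len, activation = "relu",
        params = (3L * cin + 1L) * F)
      len <- out_len; cin <- F
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scale = s, layer = "gap", kind = "gap", kernel = NA, stride = NA,
      filters = F, cin = F, in_len = len, out_len = 1L,
      activation = "none", params = 0L)
  }
  layers <- do.call(rbind, rows)
  width <- 12L * config$scales * F
  head_params <- (width + 1L) * config$classes
  structure(list(config = config, layers = layers, feature_width = width,
                 n_parameters = 12L * sum(layers$params) + head_params,
                 head_params = head_params), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<model_spec  %s  S=%d F=%d C=%d  features %d  parameters %d>\n",
              if (cfg$scales == 1) "N-Net" else "MSN-Net",
              cfg$scales, cfg$filters, cfg$classes, x$feature_width,
              x$n_parameters))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Closed-form trainable parameter count
#'
#' Per lead, scale path s costs (s - 1) pooling convolutions of
#' (P * cin + 1) * F parameters plus two kernel-3 convolutions of
#' (3 * cin + 1) * F, where cin is 1 at the path entry and F afterwards;
#' the head costs (12 * S * F + 1) * C. Computed independently of the layer
#' table so the two routes cross-check each other.
#'
#' @param config A [model_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "model_config"))
  S <- config$scales; F <- config$filters; C <- config$classes
  P <- config$pool_factor
  per_lead <- 0
  for (s in seq_len(S)) {
    cin <- 1
    for (p in seq_len(s - 1)) { per_lead <- per_lead + (P * cin + 1) * F; cin <- F }
    per_lead <- per_lead + (3 * cin + 1) * F
    per_lead <- per_lead + (3 * F + 1) * F
  }
  as.integer(12 * per_lead + (12 * S * F + 1) * C)
}

#' Hyperparameter grid of the study
#'
#' Detection: scales 1-5 crossed with filters 1-10 (50 configurations).
#' Locating: the same grid plus single-scale filters 11-15 (55
#' configurations). Deterministic order: scale-major, then filters.
#'
#' @param task `"detection"` or `"locating"`.
#' @param scales,filters Optional overrides restricting the grid.
#' @return List of [model_config()] objects.
#' @export
enumerate_grid <- function(task = c("detection", "locating"),
                           scales = NULL, filters = NULL) {
  task <- match.arg(task)
  classes <- if (task == "detection") 2L else 6L
  grid <- list()
  for (s in if (is.null(scales)) 1:5 else scales) {
    fmax_default <- if (task == "locating" && s == 1) 15L else 10L
    for (f in if (is.null(filters)) seq_len(fmax_default) else filters)
      grid[[length(grid) + 1L]] <- model_config(scales = s, filters = f,
                                                classes = classes)
  }
  grid
}

## ---- weights, forward and backward passes -------------------------------

## Weight container: list over leads, each a list over scales, each a list
## of conv layers (W: array K x cin x F, b: length F); plus head W, b.
init_weights <- function(spec, seed = 1) {
  cfg <- spec$config
  with_seed(derive_seed(seed, "init"), {
    leads <- lapply(seq_len(cfg$num_leads), function(l) {
      lapply(seq_len(cfg$scales), function(s) {
        convs <- spec$layers[spec$layers$scale == s & spec$layers$kind == "conv", ]
        lapply(seq_len(nrow(convs)), function(j) {
          K <- convs$kernel[j]; cin <- convs$cin[j]; F <- convs$filters[j]
          sd <- sqrt(2 / (K * cin))                       # He initialization
          list(W = array(rnorm(K * cin * F, sd = sd), dim = c(K, cin, F)),
               b = numeric(F), stride = convs$stride[j])
        })
      })
    })
    head <- list(W = matrix(rnorm(spec$feature_width * cfg$classes,
                                  sd = sqrt(2 / spec$feature_width)),
                            spec$feature_width, cfg$classes),
                 b = numeric(cfg$classes))
  })
  list(leads = leads, head = head)
}

n_weight_elements <- function(weights) {
  n <- length(weights$head$W) + length(weights$head$b)
  for (lead in weights$leads)
    for (path in lead)
      for (layer in path) n <- n + length(layer$W) + length(layer$b)
  as.integer(n)
}

## im2col: x array (n, L, cin) -> matrix (n * Lout, K * cin)
im2col <- function(x, K, stride) {
  n <- dim(x)[1]; L <- dim(x)[2]; cin <- dim(x)[3]
  Lout <- floor((L - K) / stride) + 1L
  pos <- seq.int(1L, by = stride, length.out = Lout)
  out <- matrix(0, n * Lout, K * cin)
  for (ci in seq_len(cin))
    for (k in seq_len(K))
      out[, (ci - 1L) * K + k] <- x[, pos + (k - 1L), ci]
  out
}

col2im <- function(dcol, dims, K, stride) {
  n <- dims[1]; L <- dims[2]; cin <- dims[3]
  Lout <- floor((L - K) / stride) + 1L
  pos <- seq.int(1L, by = stride, length.out = Lout)
  dx <- array(0, dim = dims)
  for (ci in seq_len(cin))
    for (k in seq_len(K)) {
      m <- matrix(dcol[, (ci - 1L) * K + k], n, Lout)
      dx[, pos + (k - 1L), ci] <- dx[, pos + (k - 1L), ci] + m
    }
  dx
}

## Hot path: compiled kernels. The caches hold only the layer input and
## (ReLU-masked) output; the backward kernel recovers the mask from a > 0.
conv_forward <- function(x, layer) {
  a <- .Call(C_conv1d_forward, x, layer$W, layer$b, layer$stride)
  list(a = a, x = x)
}

conv_backward <- function(dA, cache, layer, need_dx = TRUE) {
  .Call(C_conv1d_backward, dA, cache$x, cache$a, layer$W, layer$stride,
        need_dx)
}

## Pure-R reference implementations of the same kernels, kept as an
## independent oracle for the compiled code (see the network tests).
conv_forward_ref <- function(x, layer) {
  K <- dim(layer$W)[1]; cin <- dim(layer$W)[2]; F <- dim(layer$W)[3]
  n <- dim(x)[1]
  Lout <- floor((dim(x)[2] - K) / layer$stride) + 1L
  Xcol <- im2col(x, K, layer$stride)
  Z <- Xcol %*% matrix(layer$W, K * cin, F)
  Z <- Z + rep(layer$b, each = n * Lout)
  mask <- Z > 0
  A <- Z
  A[!mask] <- 0
  list(a = array(A, dim = c(n, Lout, F)), xcol = Xcol, mask = mask,
       in_dims = dim(x))
}

conv_backward_ref <- function(dA, cache, layer, need_dx = TRUE) {
  K <- dim(layer$W)[1]; cin <- dim(layer$W)[2]; F <- dim(layer$W)[3]
  dZ <- matrix(dA, ncol = F) * cache$mask
  dW <- array(crossprod(cache$xcol, dZ), dim = dim(layer$W))
  db <- colSums(dZ)
  dx <- NULL
  if (need_dx) {
    dXcol <- dZ %*% t(matrix(layer$W, K * cin, F))
    dx <- col2im(dXcol, cache$in_dims, K, layer$stride)
  }
  list(dx = dx, dW = dW, db = db)
}

## Forward pass over the whole network.
## x: array (12, L, n) of beat windows; returns concatenated features,
## probabilities and caches for the backward pass.
net_forward <- function(weights, x, spec, dropout_mask = NULL) {
  cfg <- spec$config
  n <- dim(x)[3]
  F <- cfg$filters
  feats <- matrix(0, n, spec$feature_width)
  caches <- vector("list", cfg$num_leads)
  xp <- aperm(x, c(3, 2, 1)) * cfg$input_scale      # n x L x 12, one permute
  col <- 0L
  for (l in seq_len(cfg$num_leads)) {
    x_l <- xp[, , l, drop = FALSE]
    lead_cache <- vector("list", cfg$scales)
    for (s in seq_len(cfg$scales)) {
      a <- x_l
      path <- weights$leads[[l]][[s]]
      path_cache <- vector("list", length(path))
      for (j in seq_along(path)) {
        fwd <- conv_forward(a, path[[j]])
        path_cache[[j]] <- fwd
        a <- fwd$a
      }
      gap <- matrix(0, n, F)                              # n x F
      for (f in seq_len(F)) gap[, f] <- rowMeans(matrix(a[, , f], n))
      feats[, (col + 1L):(col + F)] <- gap
      lead_cache[[s]] <- list(path = path_cache, gap_len = dim(a)[2])
      col <- col + F
    }
    caches[[l]] <- lead_cache
  }
  h <- if (is.null(dropout_mask)) feats else feats * dropout_mask
  logits <- sweep(h %*% weights$head$W, 2, weights$head$b, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, feats = feats, h = h, caches = caches)
}

## Backward pass for categorical cross-entropy. y: n x C one-hot.
net_backward <- function(weights, x, y, fwd, spec, dropout_mask = NULL) {
  cfg <- spec$config
  n <- dim(x)[3]; F <- cfg$filters
  dlogits <- (fwd$probs - y) / n
  grads <- list(head = list(W = crossprod(fwd$h, dlogits),
                            b = colSums(dlogits)),
                leads = vector("list", cfg$num_leads))
  dh <- dlogits %*% t(weights$head$W)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  col <- 0L
  for (l in seq_len(cfg$num_leads)) {
    lead_grads <- vector("list", cfg$scales)
    for (s in seq_len(cfg$scales)) {
      dgap <- dh[, (col + 1L):(col + F), drop = FALSE]
      gl <- fwd$caches[[l]][[s]]$gap_len
      dA <- array(0, dim = c(n, gl, F))
      for (f in seq_len(F)) dA[, , f] <- dgap[, f] / gl
      path <- weights$leads[[l]][[s]]
      path_cache <- fwd$caches[[l]][[s]]$path
      path_grads <- vector("list", length(path))
      for (j in rev(seq_along(path))) {
        ## the input gradient of the first layer is never consumed
        bk <- conv_backward(dA, path_cache[[j]], path[[j]], need_dx = j > 1L)
        path_grads[[j]] <- list(W = bk$dW, b = bk$db)
        dA <- bk$dx
      }
      lead_grads[[s]] <- path_grads
      col <- col + F
    }
    grads$leads[[l]] <- lead_grads
  }
  grads
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(rowSums(probs * y), 1e-12)))
}
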