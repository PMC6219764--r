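#' Small convolutional classifier specification
#'
#' Describes the compact CNN used throughout the pipeline: a stack of
#' 3x3 same-padding convolution + ReLU + 2x2 max-pool blocks reducing
#' the input to a `g x g x K` final feature map, global average pooling,
#' an optional linear bottleneck (default width 15 for multi-label models,
#' mirroring the reduced-dimension bottleneck attached ahead of the output
#' head), and a per-output sigmoid (multi-label) or softmax (multiclass)
#' head. The bottleneck is kept linear so the per-class head composes to an
#' exact linear map over the K pooled channels, which makes the subregion
#' activation-map identity (see [extract_final_features()]) hold to
#' floating-point precision.
#'
#' @param task `"multilabel"` or `"multiclass"`.
#' @param n_outputs Number of output findings (multilabel) or classes
#'   (multiclass, >= 2).
#' @param input_size Input image side length in pixels; must be divisible
#'   by `2^length(channels)`.
#' @param channels Integer vector of convolution channel counts, one per
#'   block; the last entry is K, the number of final feature channels.
#' @param bottleneck_dim Width of the linear bottleneck between pooled
#'   features and the head, or `NULL` for a direct linear head. Defaults to
#'   15 for multilabel and `NULL` (direct head, the exact activation-map
#'   form) for multiclass.
#' @param class_names Optional output names.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(task = c("multilabel", "multiclass"),
                            n_outputs,
                            input_size = 32L,
                            channels = c(4L, 8L),
                            bottleneck_dim = if (task[1] == "multilabel") 15L else NULL,
                            class_names = NULL) {
  task <- match.arg(task)
  stopifnot(n_outputs >= 1, length(channels) >= 1, all(channels >= 1))
  if (task == "multiclass" && n_outputs < 2)
    stop("multiclass task requires n_outputs >= 2")
  g <- input_size / 2^length(channels)
  if (g != round(g) || g < 2)
    stop("input_size must be divisible by 2^n_blocks with a final grid >= 2")
  if (!is.null(bottleneck_dim)) stopifnot(bottleneck_dim >= 1)
  if (!is.null(class_names)) stopifnot(length(class_names) == n_outputs)
  structure(list(task = task, n_outputs = as.integer(n_outputs),
                 input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 bottleneck_dim = if (is.null(bottleneck_dim)) NULL else
                   as.integer(bottleneck_dim),
                 grid = as.integer(g), class_names = class_names),
            class = "classifier_spec")
}

#' Training schedule: SGD with momentum and plateau learning-rate decay
#'
#' The optimization recipe used for every model in the pipeline:
#' cross-entropy loss minimized by stochastic gradient descent with
#' momentum 0.9, initial learning rate 0.01 and weight decay 1e-4. After
#' each epoch whose tune-set loss fails to improve on the best seen so far,
#' the learning rate is divided by `lr_decay_factor`; training stops after
#' `patience_stop` consecutive non-improving epochs, and the parameters
#' from the best tune-loss epoch are retained.
#'
#' @param initial_lr,momentum,weight_decay SGD hyperparameters.
#' @param lr_decay_factor Factor the learning rate is divided by on plateau.
#' @param patience_decay Non-improving epochs before each decay (fixed 1:
#'   decay after every epoch with no improvement).
#' @param patience_stop Consecutive non-improving epochs before stopping.
#' @param batch_size Minibatch size.
#' @param max_epochs Hard cap on epochs (a practical bound; plateau
#'   stopping almost always triggers first).
#' @param seed Seed controlling initialization and minibatch shuffling.
#' @return An object of class `train_schedule`.
#' @export
train_schedule <- function(initial_lr = 0.01, momentum = 0.9,
                           weight_decay = 1e-4, lr_decay_factor = 10,
                           patience_decay = 1L, patience_stop = 3L,
                           batch_size = 8L, max_epochs = 25L, seed = 1L) {
  stopifnot(initial_lr > 0, momentum >= 0, weight_decay >= 0,
            lr_decay_factor > 1, patience_stop >= patience_decay,
            patience_decay == 1L, batch_size >= 1, max_epochs >= 1)
  structure(list(initial_lr = initial_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 patience_decay = as.integer(patience_decay),
                 patience_stop = as.integer(patience_stop),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_schedule")
}

#' Reference plateau scheduler on a fixed tune-loss sequence
#'
#' Pure step-through of the learning-rate schedule: improvement is a strict
#' decrease of tune loss versus the best so far; the rate is divided by
#' `factor` after every non-improving epoch; the run stops after
#' `patience_stop` consecutive non-improving epochs. Used both as the
#' trainer's contract and as an independent reference in tests.
#'
#' @param tune_losses Numeric vector of per-epoch tune losses.
#' @param initial_lr Starting learning rate.
#' @param factor Decay divisor.
#' @param patience_stop Consecutive non-improving epochs before stopping.
#' @return Data frame with one row per epoch actually run: `epoch`,
#'   `tune_loss`, `improved`, `lr` (rate used during the epoch), and
#'   `lr_next` (rate after any end-of-epoch decay); attribute `stopped`
#'   marks whether the plateau rule fired before the sequence ran out, and
#'   `best_epoch` the epoch whose parameters would be retained.
#' @export
plateau_schedule <- function(tune_losses, initial_lr = 0.01, factor = 10,
                             patience_stop = 3L) {
  lr <- initial_lr
  best <- Inf
  best_epoch <- 0L
  bad <- 0L
  rows <- list()
  stopped <- FALSE
  for (e in seq_along(tune_losses)) {
    lr_used <- lr
    improved <- tune_losses[e] < best
    if (improved) {
      best <- tune_losses[e]
      best_epoch <- e
      bad <- 0L
    } else {
      bad <- bad + 1L
      lr <- lr / factor
    }
    rows[[e]] <- data.frame(epoch = e, tune_loss = tune_losses[e],
                            improved = improved, lr = lr_used, lr_next = lr)
    if (bad >= patience_stop) { stopped <- TRUE; break }
  }
  out <- do.call(rbind, rows)
  attr(out, "stopped") <- stopped
  attr(out, "best_epoch") <- best_epoch
  out
}

## ---- network internals -----------------------------------------------------
## Feature maps are stored one sample per column, flattened in (row, col,
## channel) order. Convolutions are evaluated as a single GEMM per batch via
## im2col index gathers precomputed at build time.

.conv_layer <- function(c_in, c_out, H, W, k = 3L) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  pad_idx <- as.vector(outer(outer(seq_len(H) + p, (seq_len(W) + p - 1L) * Hp, "+"),
                             (seq_len(c_in) - 1L) * Hp * Wp, "+"))
  off <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"),
                         (seq_len(c_in) - 1L) * Hp * Wp, "+"))
  base <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  idx <- as.vector(outer(off, base, "+"))
  fan_in <- c_in * k * k
  list(type = "conv", c_in = c_in, c_out = c_out, k = k,
       n_pad = c_in * Hp * Wp, pad_idx = pad_idx, idx = idx,
       uidx = sort(unique(idx)), P = H * W, kkc = fan_in,
       W = matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
                  c_out, fan_in),
       b = numeric(c_out))
}

.pool_layer <- function(C, H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  mk <- function(dh, dw)
    as.vector(outer(outer(2L * seq_len(Ho) - 1L + dh,
                          (2L * seq_len(Wo) - 2L + dw) * H, "+"),
                    (seq_len(C) - 1L) * H * W, "+"))
  list(type = "pool", C = C, h = H, w = W,
       i00 = mk(0L, 0L), i10 = mk(1L, 0L), i01 = mk(0L, 1L), i11 = mk(1L, 1L))
}

.dense_layer <- function(d_in, d_out, sd = sqrt(1 / d_in)) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = matrix(stats::rnorm(d_out * d_in, sd = sd), d_out, d_in),
       b = numeric(d_out))
}

.build_network <- function(spec) {
  layers <- list()
  H <- spec$input_size; c_in <- 1L
  for (c_out in spec$channels) {
    layers[[length(layers) + 1L]] <- .conv_layer(c_in, c_out, H, H)
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <- .pool_layer(c_out, H, H)
    H <- H %/% 2L
    c_in <- c_out
  }
  layers[[length(layers) + 1L]] <- list(type = "gap", C = c_in, P = H * H)
  if (!is.null(spec$bottleneck_dim)) {
    layers[[length(layers) + 1L]] <- .dense_layer(c_in, spec$bottleneck_dim)
    layers[[length(layers) + 1L]] <- .dense_layer(spec$bottleneck_dim,
                                                  spec$n_outputs)
  } else {
    layers[[length(layers) + 1L]] <- .dense_layer(c_in, spec$n_outputs)
  }
  layers
}

.layer_forward <- function(lay, X) {
  switch(lay$type,
    conv = {
      B <- ncol(X)
      Xp <- matrix(0, lay$n_pad, B)
      Xp[lay$pad_idx, ] <- X
      cols <- Xp[lay$idx, , drop = FALSE]
      dim(cols) <- c(lay$kkc, lay$P * B)
      out <- lay$W %*% cols + lay$b
      dim(out) <- c(lay$c_out, lay$P, B)
      out <- aperm(out, c(2L, 1L, 3L))
      dim(out) <- c(lay$P * lay$c_out, B)
      out
    },
    relu = pmax(X, 0),
    pool = pmax(pmax(X[lay$i00, , drop = FALSE], X[lay$i10, , drop = FALSE]),
                pmax(X[lay$i01, , drop = FALSE], X[lay$i11, , drop = FALSE])),
    gap = {
      arr <- X
      dim(arr) <- c(lay$P, lay$C, ncol(X))
      colMeans(arr, dims = 1L)
    },
    dense = lay$W %*% X + lay$b)
}

# Forward pass; keep_acts retains each layer's input for backprop.
.net_forward <- function(layers, X, keep_acts = FALSE) {
  acts <- if (keep_acts) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    if (keep_acts) acts[[i]] <- X
    X <- .layer_forward(layers[[i]], X)
  }
  list(out = X, acts = acts)
}

# Backward pass from output gradient dY; returns list of gradients
# (dW, db per parametric layer) aligned with layers.
.net_backward <- function(layers, acts, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    lay <- layers[[i]]
    X <- acts[[i]]
    if (lay$type == "dense") {
      grads[[i]] <- list(dW = tcrossprod(dY, X), db = rowSums(dY))
      dY <- crossprod(lay$W, dY)
    } else if (lay$type == "gap") {
      dY <- dY[rep(seq_len(lay$C), each = lay$P), , drop = FALSE] / lay$P
    } else if (lay$type == "pool") {
      B <- ncol(dY)
      a <- X[lay$i00, , drop = FALSE]; b <- X[lay$i10, , drop = FALSE]
      cc <- X[lay$i01, , drop = FALSE]; d <- X[lay$i11, , drop = FALSE]
      M <- pmax(pmax(a, b), pmax(cc, d))
      ta <- a == M
      tb <- (b == M) & !ta
      tc <- (cc == M) & !ta & !tb
      td <- !(ta | tb | tc)
      dX <- matrix(0, lay$C * lay$h * lay$w, B)
      dX[lay$i00, ] <- dY * ta; dX[lay$i10, ] <- dY * tb
      dX[lay$i01, ] <- dY * tc; dX[lay$i11, ] <- dY * td
      dY <- dX
    } else if (lay$type == "relu") {
      dY <- dY * (X > 0)
    } else if (lay$type == "conv") {
      B <- ncol(dY)
      dim(dY) <- c(lay$P, lay$c_out, B)
      dY <- aperm(dY, c(2L, 1L, 3L))
      dim(dY) <- c(lay$c_out, lay$P * B)
      Xp <- matrix(0, lay$n_pad, B)
      Xp[lay$pad_idx, ] <- X
      cols <- Xp[lay$idx, , drop = FALSE]
      dim(cols) <- c(lay$kkc, lay$P * B)
      grads[[i]] <- list(dW = tcrossprod(dY, cols), db = rowSums(dY))
      dcols <- crossprod(lay$W, dY)
      dim(dcols) <- c(lay$kkc * lay$P, B)
      dXp <- matrix(0, lay$n_pad, B)
      dXp[lay$uidx, ] <- rowsum(dcols, lay$idx)
      dY <- dXp[lay$pad_idx, , drop = FALSE]
    }
  }
  grads
}

.softmax_cols <- function(Z) {
  Z <- exp(sweep(Z, 2L, apply(Z, 2L, max)))
  sweep(Z, 2L, colSums(Z), "/")
}

# Loss and output-layer gradient. Y: n_outputs x B target matrix
# (binary for multilabel, one-hot for multiclass).
.loss_grad <- function(task, Z, Y) {
  B <- ncol(Z)
  if (task == "multilabel") {
    # Cross-entropy summed over the binary findings (mean over the batch),
    # so every head trains at full gradient scale regardless of how many
    # findings the model carries.
    P <- stats::plogis(Z)
    eps <- 1e-12
    loss <- -sum(Y * log(P + eps) + (1 - Y) * log(1 - P + eps)) / B
    list(loss = loss, dZ = (P - Y) / B)
  } else {
    P <- .softmax_cols(Z)
    loss <- -mean(log(colSums(P * Y) + 1e-12))
    list(loss = loss, dZ = (P - Y) / B)
  }
}

.eval_loss <- function(task, layers, X, Y, batch = 512L) {
  n <- ncol(X)
  tot <- 0
  for (s in seq(1L, n, by = batch)) {
    j <- s:min(n, s + batch - 1L)
    Z <- .net_forward(layers, X[, j, drop = FALSE])$out
    tot <- tot + .loss_grad(task, Z, Y[, j, drop = FALSE])$loss * length(j)
  }
  tot / n
}

.snapshot_params <- function(layers)
  lapply(layers, function(l) if (!is.null(l$W)) list(W = l$W, b = l$b))

.restore_params <- function(layers, snap) {
  for (i in seq_along(layers))
    if (!is.null(snap[[i]])) { layers[[i]]$W <- snap[[i]]$W
                               layers[[i]]$b <- snap[[i]]$b }
  layers
}

# Coerce images (H x W x N array, or one H x W matrix) to the column-major
# sample matrix the network consumes, normalizing pixel intensities to
# roughly zero mean and unit scale ((x - 0.5) / 0.25) so early layers see
# standardized inputs.
.images_to_matrix <- function(images, input_size) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  if (length(d) != 3L || d[1] != input_size || d[2] != input_size)
    stop(sprintf("images must be %d x %d (got %s)",
                 input_size, input_size, paste(d, collapse = " x ")))
  (matrix(images, d[1] * d[2], d[3]) - 0.5) / 0.25
}

# Targets to n_outputs x B matrix; multiclass labels become one-hot rows
# ordered by spec$class_names (set from sorted unique labels if absent).
.targets_to_matrix <- function(y, spec) {
  if (spec$task == "multilabel") {
    y <- as.matrix(y)
    if (ncol(y) != spec$n_outputs) stop("label matrix has wrong width")
    t(y)
  } else {
    cls <- spec$class_names
    y <- as.character(y)
    if (any(!y %in% cls)) stop("labels outside spec class_names")
    Y <- matrix(0, spec$n_outputs, length(y))
    Y[cbind(match(y, cls), seq_along(y))] <- 1
    Y
  }
}

#' Train the small CNN with the plateau schedule
#'
#' Minimizes cross-entropy by minibatch SGD with momentum and weight decay.
#' After every epoch the tune-set loss is evaluated: an epoch that fails to
#' improve on the best tune loss so far divides the learning rate by the
#' decay factor, and `patience_stop` consecutive such epochs end training.
#' The parameters achieving the best tune loss are retained. Fully
#' deterministic given `schedule$seed`.
#'
#' @param x_train,x_tune Image arrays (`size x size x n`); train and tune
#'   sets must be disjoint by patient (the caller's responsibility --
#'   use [split_by_patient()]).
#' @param y_train,y_tune Multilabel: `n x n_outputs` binary matrices.
#'   Multiclass: character/factor label vectors.
#' @param spec A [classifier_spec()].
#' @param schedule A [train_schedule()].
#' @return An object of class `cnn_classifier` with the trained layers, the
#'   spec and schedule, and a per-epoch training `log` (tune loss, learning
#'   rate, improvement flag).
#' @export
train_classifier <- function(x_train, y_train, x_tune, y_tune, spec,
                             schedule = train_schedule()) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(schedule, "train_schedule"))
  if (spec$task == "multiclass") {
    observed <- sort(unique(as.character(c(y_train, y_tune))))
    if (is.null(spec$class_names)) spec$class_names <- observed
    if (length(observed) < 2L)
      stop("multiclass training labels contain a single class")
  }
  if (spec$task == "multilabel" && is.null(spec$class_names))
    spec$class_names <- colnames(as.matrix(y_train))
  Xtr <- .images_to_matrix(x_train, spec$input_size)
  Xtu <- .images_to_matrix(x_tune, spec$input_size)
  if (ncol(Xtr) == 0L) stop("empty train set")
  if (ncol(Xtu) == 0L) stop("empty tune set")
  Ytr <- .targets_to_matrix(y_train, spec)
  Ytu <- .targets_to_matrix(y_tune, spec)
  set.seed(schedule$seed)
  layers <- .build_network(spec)
  vel <- lapply(layers, function(l)
    if (!is.null(l$W)) list(vW = l$W * 0, vb = l$b * 0))
  n <- ncol(Xtr)
  lr <- schedule$initial_lr
  best_loss <- Inf
  best_snap <- .snapshot_params(layers)
  bad <- 0L
  log_rows <- list()
  for (epoch in seq_len(schedule$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = schedule$batch_size)) {
      j <- perm[s:min(n, s + schedule$batch_size - 1L)]
      fw <- .net_forward(layers, Xtr[, j, drop = FALSE], keep_acts = TRUE)
      lg <- .loss_grad(spec$task, fw$out, Ytr[, j, drop = FALSE])
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
      ep_loss <- ep_loss + lg$loss * length(j)
      grads <- .net_backward(layers, fw$acts, lg$dZ)
      for (i in seq_along(layers)) {
        if (is.null(grads[[i]])) next
        gW <- grads[[i]]$dW + schedule$weight_decay * layers[[i]]$W
        vel[[i]]$vW <- schedule$momentum * vel[[i]]$vW + gW
        vel[[i]]$vb <- schedule$momentum * vel[[i]]$vb + grads[[i]]$db
        layers[[i]]$W <- layers[[i]]$W - lr * vel[[i]]$vW
        layers[[i]]$b <- layers[[i]]$b - lr * vel[[i]]$vb
      }
    }
    tune_loss <- .eval_loss(spec$task, layers, Xtu, Ytu)
    if (!is.finite(tune_loss))
      stop(sprintf("training diverged: non-finite tune loss at epoch %d", epoch))
    improved <- tune_loss < best_loss
    if (improved) {
      best_loss <- tune_loss
      best_snap <- .snapshot_params(layers)
      bad <- 0L
    } else {
      bad <- bad + 1L
      lr <- lr / schedule$lr_decay_factor
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                    tune_loss = tune_loss,
                                    improved = improved, lr_next = lr)
    if (bad >= schedule$patience_stop) break
  }
  layers <- .restore_params(layers, best_snap)
  structure(list(spec = spec, schedule = schedule, layers = layers,
                 log = do.call(rbind, log_rows), best_tune_loss = best_loss),
            class = "cnn_classifier")
}

#' Predicted probabilities from a trained classifier
#'
#' @param model A `cnn_classifier`.
#' @param images `size x size x n` array (or a single `size x size` matrix).
#' @param batch Evaluation batch size.
#' @return `n x n_outputs` matrix of probabilities (columns named by the
#'   spec's class names); multiclass rows sum to 1.
#' @export
predict_proba <- function(model, images, batch = 512L) {
  stopifnot(inherits(model, "cnn_classifier"))
  X <- .images_to_matrix(images, model$spec$input_size)
  n <- ncol(X)
  out <- matrix(NA_real_, n, model$spec$n_outputs)
  for (s in seq(1L, n, by = batch)) {
    j <- s:min(n, s + batch - 1L)
    Z <- .net_forward(model$layers, X[, j, drop = FALSE])$out
    out[j, ] <- t(if (model$spec$task == "multilabel") stats::plogis(Z)
                  else .softmax_cols(Z))
  }
  colnames(out) <- model$spec$class_names
  out
}

#' @exportS3Method base::print
print.cnn_classifier <- function(x, ...) {
  cat(sprintf("<cnn_classifier> %s, %d output(s), input %dx%d, blocks [%s], grid %dx%d\n",
              x$spec$task, x$spec$n_outputs, x$spec$input_size,
              x$spec$input_size, paste(x$spec$channels, collapse = ","),
              x$spec$grid, x$spec$grid))
  cat(sprintf("  trained %d epoch(s), best tune loss %.4f\n",
              nrow(x$log), x$best_tune_loss))
  invisible(x)
}

#' Final convolutional feature map and effective linear head weights
#'
#' Returns, for one image, the activations `X[k, i, j]` of the K final
#' convolutional channels on the `g x g` grid, together with the per-class
#' weight vectors `B` and intercepts `B0` of the (effective) linear head
#' over the globally average-pooled features. When the model has a linear
#' bottleneck, head and bottleneck compose into a single linear map, so for
#' every class the grid-average of the subregion score map equals the
#' model's own logit exactly.
#'
#' @param model A trained `cnn_classifier`.
#' @param image A `size x size` matrix.
#' @return List with `X` (`K x g x g` array), `B` (`n_outputs x K` matrix),
#'   `B0` (length-`n_outputs` intercepts), and grid size `g`.
#' @export
extract_final_features <- function(model, image) {
  stopifnot(inherits(model, "cnn_classifier"))
  spec <- model$spec
  X <- .images_to_matrix(image, spec$input_size)
  if (ncol(X) != 1L) stop("extract_final_features expects a single image")
  gap_at <- which(vapply(model$layers, `[[`, "", "type") == "gap")
  for (i in seq_len(gap_at - 1L))
    X <- .layer_forward(model$layers[[i]], X)
  g <- spec$grid
  K <- spec$channels[length(spec$channels)]
  fmap <- array(X[, 1L], c(g, g, K))        # (row, col, channel)
  dense <- model$layers[(gap_at + 1L):length(model$layers)]
  if (length(dense) == 2L) {
    B <- dense[[2L]]$W %*% dense[[1L]]$W
    B0 <- as.vector(dense[[2L]]$W %*% dense[[1L]]$b + dense[[2L]]$b)
  } else {
    B <- dense[[1L]]$W
    B0 <- dense[[1L]]$b
  }
  rownames(B) <- spec$class_names
  names(B0) <- spec$class_names
  list(X = aperm(fmap, c(3L, 1L, 2L)), B = B, B0 = B0, g = g, K = K)
}

#' Save / restore a trained classifier as portable text artifacts
#'
#' Weights and biases are written to a single JSON checkpoint at full
#' precision together with a sidecar description (spec, schedule) so the
#' network can be rebuilt exactly; the per-epoch training log goes to a
#' CSV next to it.
#'
#' @param model A `cnn_classifier`.
#' @param path Checkpoint path (`.json`); the training log is written to
#'   `<path>.log.csv`.
#' @return `write_classifier` invisibly returns `path`;
#'   `read_classifier` returns the restored `cnn_classifier`.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "cnn_classifier"))
  parametric <- which(vapply(model$layers, function(l) !is.null(l$W), TRUE))
  params <- lapply(parametric, function(i)
    list(layer = i, W = as.vector(model$layers[[i]]$W),
         dim = dim(model$layers[[i]]$W), b = model$layers[[i]]$b))
  payload <- list(spec = unclass(model$spec),
                  schedule = unclass(model$schedule),
                  params = params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.csv(model$log, paste0(path, ".log.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  spec_args <- obj$spec[intersect(c("task", "n_outputs", "input_size",
                                    "channels", "class_names"),
                                  names(obj$spec))]
  spec_args$bottleneck_dim <- obj$spec$bottleneck_dim   # NULL when absent
  spec <- do.call(classifier_spec, spec_args)
  schedule <- do.call(train_schedule, obj$schedule[names(obj$schedule)])
  layers <- .build_network(spec)
  for (p in obj$params) {
    i <- p$layer
    layers[[i]]$W <- matrix(as.numeric(p$W), p$dim[1], p$dim[2])
    layers[[i]]$b <- as.numeric(p$b)
  }
  log <- tryCatch(utils::read.csv(paste0(path, ".log.csv")),
                  error = function(e) NULL)
  structure(list(spec = spec, schedule = schedule, layers = layers,
                 log = log,
                 best_tune_loss = if (!is.null(log)) min(log$tune_loss) else
                   NA_real_),
            class = "cnn_classifier")
}
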