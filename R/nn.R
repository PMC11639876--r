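# Fully connected network core: swish hidden activations, softmax output,
# categorical cross-entropy, adam updates, per-epoch validation checkpointing
# with best-epoch restoration. Written against plain base-R matrices; all
# randomness (initialization, minibatch shuffling) comes from R's global RNG
# so a single set.seed() upstream makes training bit-reproducible.

#' Channel architecture specification
#'
#' A deep fully connected network with exactly ten hidden layers whose sizes
#' lie in 50..750 (default: the descending ladder 750, 650, 550, 450, 350,
#' 300, 250, 150, 100, 50 spanning that range), swish hidden activations and
#' a four-way softmax output.
#'
#' @param n_inputs Number of input features (signature genes).
#' @param hidden_sizes Ten integers in `[50, 750]`.
#' @return List of class `ov_channel_spec`.
#' @export
channel_spec <- function(n_inputs,
                         hidden_sizes = c(750, 650, 550, 450, 350,
                                          300, 250, 150, 100, 50)) {
  if (length(hidden_sizes) != 10)
    stop("the channel network has exactly 10 hidden layers")
  if (any(hidden_sizes < 50 | hidden_sizes > 750))
    stop("hidden layer sizes must lie in [50, 750]")
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden_sizes = as.integer(hidden_sizes),
                 n_outputs = 4L),
            class = "ov_channel_spec")
}

#' Training configuration
#'
#' Adam with learning rate 0.003, categorical cross-entropy, at most 500
#' epochs with per-epoch checkpointing; the restored model is the epoch
#' maximizing Cohen's kappa on an internal stratified validation carve-out of
#' the training set. Training stops early once the validation metric has not
#' improved for `patience` epochs (the checkpoint contract makes further
#' epochs on a flat plateau irrelevant).
#'
#' @param learning_rate Adam step size (default 0.003).
#' @param max_epochs Upper bound on epochs (default 500).
#' @param batch_size Minibatch size (default 32).
#' @param validation_fraction Fraction of the training units carved out for
#'   checkpoint metric evaluation (default 0.1, stratified).
#' @param patience Epochs without validation improvement before stopping
#'   (default 30).
#' @param split_ratio Train:test ratio as a length-2 vector (default 2:1).
#' @param augment Multiplatform training augmentation: stratified halves of
#'   the training samples additionally enter as depth-downsampled views
#'   emulating Visium spots (log-normal depth around 5e4, dropout 0-0.3) and
#'   droplet cells (log-normal depth around 8e3, dropout 0.5-0.85), so the
#'   bulk-trained channels learn the detection-floor regime of shallow units
#'   (default TRUE).
#' @param seed Integer seed controlling split, initialization and shuffling.
#' @return List of class `ov_train_config`.
#' @export
train_config <- function(learning_rate = 0.003, max_epochs = 500L,
                         batch_size = 32L, validation_fraction = 0.1,
                         patience = 30L, split_ratio = c(2, 1),
                         augment = TRUE, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1,
            length(split_ratio) == 2, all(split_ratio > 0))
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 split_ratio = split_ratio,
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "ov_train_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
swish <- function(x) x * sigmoid(x)

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# He-scaled initialization; weights W[[l]] are (out x in), biases b[[l]] out-vectors.
nn_init <- function(spec) {
  sizes <- c(spec$n_inputs, spec$hidden_sizes, spec$n_outputs)
  W <- vector("list", length(sizes) - 1)
  b <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1] * sizes[l], sd = sqrt(2 / sizes[l])),
                     sizes[l + 1], sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass on an (inputs x batch) matrix; keeps pre-activations for backprop.
nn_forward <- function(par, X, keep = FALSE) {
  L <- length(par$W)
  A <- X
  Zs <- if (keep) vector("list", L) else NULL
  As <- if (keep) vector("list", L + 1) else NULL
  if (keep) As[[1]] <- X
  for (l in seq_len(L)) {
    Z <- par$W[[l]] %*% A + par$b[[l]]
    A <- if (l < L) swish(Z) else softmax_cols(Z)
    if (keep) { Zs[[l]] <- Z; As[[l + 1]] <- A }
  }
  if (keep) list(P = A, Zs = Zs, As = As) else A
}

# Gradients of mean categorical cross-entropy wrt all parameters.
# crossprod/tcrossprod avoid materializing transposes.
nn_backward <- function(par, fwd, Y) {
  L <- length(par$W)
  B <- ncol(Y)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- (fwd$P - Y) / B
  for (l in L:1) {
    dW[[l]] <- tcrossprod(delta, fwd$As[[l]])
    db[[l]] <- rowSums(delta)
    if (l > 1) {
      s <- sigmoid(fwd$Zs[[l - 1]])
      dswish <- s + fwd$Zs[[l - 1]] * s * (1 - s)
      delta <- crossprod(par$W[[l]], delta) * dswish
    }
  }
  list(dW = dW, db = db)
}

adam_init <- function(par) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros(par$W), vW = zeros(par$W),
       mb = zeros(par$b), vb = zeros(par$b), t = 0L)
}

# One adam step. Mutates par and state in place through the compiled kernel;
# the caller owns both exclusively (checkpoints are deep-copied).
adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  .adam_update_inplace(par$W, par$b, state$mW, state$vW, state$mb, state$vb,
                       grad$dW, grad$db, lr, beta1, beta2, eps, state$t)
  list(par = par, state = state)
}

# Guaranteed deep copy of a parameter list (in-place updates must never
# write through to a checkpoint snapshot).
copy_params <- function(par) unserialize(serialize(par, NULL))

one_hot <- function(labels) {
  lv <- subtype_levels()
  Y <- matrix(0, 4, length(labels), dimnames = list(lv, names(labels)))
  Y[cbind(match(as.character(labels), lv), seq_along(labels))] <- 1
  Y
}

# Multi-class Cohen's kappa from label vectors.
kappa_score <- function(pred, truth) {
  lv <- subtype_levels()
  cm <- table(factor(pred, levels = lv), factor(truth, levels = lv))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

argmax_labels <- function(P) {
  # ties break toward the first subtype in canonical order (max.col "first")
  subtype_levels()[max.col(t(P), ties.method = "first")]
}

#' Train one channel network
#'
#' Runs minibatch adam on scaled features, evaluates Cohen's kappa on the
#' validation units after every epoch, keeps a snapshot of the best-scoring
#' epoch, and restores it at the end. Training stops at `max_epochs` or after
#' `patience` epochs without validation improvement.
#'
#' @param features Scaled feature matrix (signature genes by units).
#' @param labels Named subtype factor/character for the units.
#' @param spec [channel_spec()].
#' @param cfg [train_config()].
#' @param val_ids Unit ids used for validation; the rest are trained on. When
#'   `NULL`, a stratified `validation_fraction` carve-out is drawn.
#' @return List of class `ov_channel`: `par` (restored weights), `spec`,
#'   `best_epoch`, `best_kappa`, `trace` (per-epoch loss and validation kappa).
#' @export
train_channel <- function(features, labels, spec, cfg = train_config(),
                          val_ids = NULL) {
  stopifnot(nrow(features) == spec$n_inputs)
  units <- colnames(features)
  lab <- labels[units]
  if (anyNA(lab)) stop("all units must be labeled")
  if (is.null(val_ids)) {
    val_ids <- stratified_sample(lab, cfg$validation_fraction)
  }
  tr_ids <- setdiff(units, val_ids)
  Xtr <- features[, tr_ids, drop = FALSE]
  Ytr <- one_hot(lab[tr_ids])
  if (!all(is.finite(Xtr))) stop("non-finite training features")
  provider <- function() list(X = Xtr, Y = Ytr)
  ch <- train_channel_core(provider,
                           Xval = features[, val_ids, drop = FALSE],
                           yval = as.character(lab[val_ids]),
                           spec = spec, cfg = cfg)
  ch$val_ids <- val_ids
  ch
}

# Core training loop over a data provider (called once per epoch, so
# augmentation can resample fresh views while the validation set stays
# fixed for checkpoint comparability).
train_channel_core <- function(provider, Xval, yval, spec, cfg) {
  par <- nn_init(spec)
  state <- adam_init(par)
  best <- list(kappa = -Inf, epoch = 0L, par = copy_params(par))
  trace <- data.frame(epoch = integer(), loss = numeric(), val_kappa = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    batch <- provider()
    n <- ncol(batch$X)
    idx <- sample.int(n)
    loss_sum <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      take <- idx[start:min(start + cfg$batch_size - 1, n)]
      fwd <- nn_forward(par, batch$X[, take, drop = FALSE], keep = TRUE)
      loss_sum <- loss_sum -
        sum(log(pmax(colSums(fwd$P * batch$Y[, take, drop = FALSE]), 1e-12)))
      grad <- nn_backward(par, fwd, batch$Y[, take, drop = FALSE])
      upd <- adam_step(par, grad, state, cfg$learning_rate)
      par <- upd$par; state <- upd$state
    }
    loss <- loss_sum / n
    if (!is.finite(loss))
      stop("training diverged (non-finite loss); reduce the learning rate")
    val_kappa <- kappa_score(argmax_labels(nn_forward(par, Xval)), yval)
    trace <- rbind(trace, data.frame(epoch = epoch, loss = loss,
                                     val_kappa = val_kappa))
    if (val_kappa > best$kappa) {
      best <- list(kappa = val_kappa, epoch = epoch, par = copy_params(par))
    }
    if (epoch - best$epoch >= cfg$patience) break
  }
  structure(list(par = best$par, spec = spec, best_epoch = best$epoch,
                 best_kappa = best$kappa, trace = trace),
            class = "ov_channel")
}

# Deterministic stratified sampling of ~fraction units per class (>= 1 each).
stratified_sample <- function(labels, fraction) {
  units <- names(labels)
  unlist(lapply(split(units, labels), function(u) {
    if (!length(u)) return(character())
    k <- max(1L, round(length(u) * fraction))
    sample(u, k)
  }), use.names = FALSE)
}
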