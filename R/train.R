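#' Training configuration
#'
#' The optimization protocol: Adam with an exponentially decayed learning
#' rate (initial 1e-3, multiplied by `decay_rate` every `decay_step` epochs),
#' batch size 2048, 1000 epochs, softmax cross-entropy loss. These defaults
#' are the reference protocol; desk-scale runs typically reduce `epochs` and
#' `batch_size`.
#'
#' @param lr0 Initial learning rate.
#' @param decay_step Epochs between learning-rate decays.
#' @param decay_rate Multiplicative decay factor.
#' @param batch_size Minibatch size (capped at the dataset size).
#' @param epochs Number of passes over the training data.
#' @param seed Integer run seed; every random stream (shuffling, init) is a
#'   [subseed()] of it.
#' @param variant Network variant to train (see [mbnet_forward()]).
#' @param standardize Per-band standardization of the spectra using training
#'   data statistics (default `TRUE`); the fitted scaler travels with the
#'   model and is applied to new data at prediction time, so test folds never
#'   contribute to it.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer
#'   (conventional defaults).
#' @param device Execution target; only `"cpu"` is available.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-3, decay_step = 10, decay_rate = 0.9,
                         batch_size = 2048, epochs = 1000, seed = 0,
                         variant = "bidirectional", standardize = TRUE,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         device = "cpu") {
  stopifnot(lr0 > 0, decay_step >= 1, decay_rate > 0, decay_rate <= 1,
            batch_size >= 2, epochs >= 1, variant %in% .mbnet_variants,
            identical(device, "cpu"))
  structure(list(lr0 = lr0, decay_step = as.integer(decay_step),
                 decay_rate = decay_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 variant = variant, standardize = isTRUE(standardize),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 device = device),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Staircase exponential decay:
#' `lr(e) = lr0 * decay_rate^floor(e / decay_step)` with 0-based epochs, so
#' epochs 0-9 use `lr0`, epochs 10-19 use `lr0 * decay_rate`, and so on.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param cfg A [train_config].
#' @return Learning rate(s).
#' @export
#' @examples
#' lr_schedule(c(0, 10, 25), train_config())
lr_schedule <- function(epoch, cfg = train_config()) {
  stopifnot(all(epoch >= 0))
  cfg$lr0 * cfg$decay_rate^floor(epoch / cfg$decay_step)
}

# recursive Adam step over the gradient tree; `state` mirrors the tree with
# first/second moment accumulators. Updates params in place (functionally).
.adam_step <- function(params, grads, state, lr, b1, b2, eps, t) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.list(g)) {
      res <- .adam_step(params[[nm]], g, state[[nm]], lr, b1, b2, eps, t)
      params[[nm]] <- res$params
      state[[nm]] <- res$state
    } else if (is.numeric(g)) {
      if (is.null(state[[nm]])) {
        state[[nm]] <- list(m = g * 0, v = g * 0)
      }
      m <- b1 * state[[nm]]$m + (1 - b1) * g
      v <- b2 * state[[nm]]$v + (1 - b2) * g * g
      state[[nm]]$m <- m
      state[[nm]]$v <- v
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.cross_entropy <- function(probs, y) {
  # y: 0-based labels
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

.fit_scaler <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s < 1e-8] <- 1
  list(mean = mu, sd = s)
}

.apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  B <- nrow(x)
  (x - rep(scaler$mean, each = B)) / rep(scaler$sd, each = B)
}

# minibatch index chunks; a trailing singleton is folded into the previous
# chunk so BatchNorm always sees >= 2 samples
.batch_chunks <- function(idx, batch_size) {
  n <- length(idx)
  starts <- seq(1L, n, by = batch_size)
  chunks <- lapply(starts, function(s) idx[s:min(s + batch_size - 1L, n)])
  k <- length(chunks)
  if (k > 1 && length(chunks[[k]]) == 1L) {
    chunks[[k - 1L]] <- c(chunks[[k - 1L]], chunks[[k]])
    chunks[[k]] <- NULL
  }
  chunks
}

#' Train the bidirectional spectral network
#'
#' Minimizes mean softmax cross-entropy with Adam under the staircase
#' exponential learning-rate schedule, using exact analytic gradients of the
#' whole network (including through the selective scan). Fully seeded: the
#' same `(dataset, cfg, net_config)` always reproduces the same fit on a
#' fixed platform. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param dataset A [spectral_dataset] with at least two classes present.
#' @param cfg A [train_config].
#' @param net_config An [mbnet_config]; defaults to one sized to the dataset
#'   (`n_bands`, `n_classes` taken from the data).
#' @return An object of class `mbnet_fit`: the trained parameters, the
#'   configs, the fitted per-band scaler (if any) and a `history` tibble with
#'   one row per epoch (`epoch`, `loss`, `lr`).
#' @export
mbnet_train <- function(dataset, cfg = train_config(), net_config = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(cfg, "train_config"))
  y <- dataset$labels
  if (length(unique(y)) < 2) {
    stop("training requires at least two classes present", call. = FALSE)
  }
  C <- length(dataset$class_names)
  D <- ncol(dataset$spectra)
  if (is.null(net_config)) {
    net_config <- mbnet_config(n_bands = D, n_classes = C)
  }
  stopifnot(net_config$n_bands == D, net_config$n_classes >= max(y) + 1)

  scaler <- if (cfg$standardize) .fit_scaler(dataset$spectra) else NULL
  x <- .apply_scaler(dataset$spectra, scaler)
  N <- nrow(x)

  params <- mbnet(net_config, seed = cfg$seed)
  state <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subseed(cfg$seed, "shuffle"))

  history <- matrix(NA_real_, cfg$epochs, 3,
                    dimnames = list(NULL, c("epoch", "loss", "lr")))
  t_adam <- 0L
  bs <- min(cfg$batch_size, N)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_schedule(epoch, cfg)
    perm <- sample.int(N)
    chunks <- .batch_chunks(perm, bs)
    losses <- numeric(length(chunks))
    for (ci in seq_along(chunks)) {
      idx <- chunks[[ci]]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- .mbnet_forward_full(xb, params, cfg$variant, training = TRUE,
                                keep_cache = TRUE)
      probs <- .softmax(fw$logits)
      loss <- .cross_entropy(probs, yb)
      if (!is.finite(loss)) {
        stop(sprintf(paste0("training aborted: non-finite loss at epoch %d ",
                            "(lr = %g); consider a smaller learning rate"),
                     epoch, lr), call. = FALSE)
      }
      losses[ci] <- loss
      onehot <- matrix(0, length(yb), net_config$n_classes)
      onehot[cbind(seq_along(yb), yb + 1L)] <- 1
      glogits <- (probs - onehot) / length(yb)
      grads <- .mbnet_backward_full(glogits, fw$cache, params)
      t_adam <- t_adam + 1L
      res <- .adam_step(params, grads, state, lr, cfg$beta1, cfg$beta2,
                        cfg$adam_eps, t_adam)
      params <- res$params
      state <- res$state
      params <- .mbnet_update_bn(params, fw$cache)
    }
    history[epoch + 1L, ] <- c(epoch, mean(losses), lr)
  }

  structure(list(
    params = params,
    net_config = net_config,
    train_config = cfg,
    scaler = scaler,
    history = tibble::as_tibble(as.data.frame(history)),
    class_names = dataset$class_names,
    wavelengths = dataset$wavelengths,
    dataset_hash = dataset_hash(dataset)
  ), class = "mbnet_fit")
}

#' @export
print.mbnet_fit <- function(x, ...) {
  cat(sprintf("<mbnet_fit> variant=%s, %d bands -> %d classes, %d epochs, final loss %.4f\n",
              x$train_config$variant, x$net_config$n_bands,
              x$net_config$n_classes, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Predict from a trained network
#'
#' Applies the stored per-band scaler (fitted on the training data only) and
#' runs an eval-mode forward pass (BatchNorm uses running statistics, so
#' single spectra are fine and repeated calls are identical).
#'
#' @param object An `mbnet_fit`.
#' @param newdata A [spectral_dataset] or a `[B x D]` matrix.
#' @param type `"class"` (0-based labels), `"prob"`, or `"logits"`.
#' @param ... Unused.
#' @return Integer labels, or a `[B x C]` matrix for `"prob"` / `"logits"`.
#' @export
predict.mbnet_fit <- function(object, newdata,
                              type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "spectral_dataset")) newdata$spectra else
    as.matrix(newdata)
  if (ncol(x) != object$net_config$n_bands) {
    stop(sprintf("newdata has %d bands; the model expects %d", ncol(x),
                 object$net_config$n_bands), call. = FALSE)
  }
  x <- .apply_scaler(x, object$scaler)
  logits <- mbnet_forward(x, object$params,
                          variant = object$train_config$variant,
                          training = FALSE)
  switch(type,
         logits = logits,
         prob = .softmax(logits),
         class = max.col(logits, ties.method = "first") - 1L)
}

#' @method tidy mbnet_fit
#' @export
tidy.mbnet_fit <- function(x, ...) x$history

#' @method glance mbnet_fit
#' @export
glance.mbnet_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$train_config$variant,
    epochs = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    n_bands = x$net_config$n_bands,
    n_classes = x$net_config$n_classes
  )
}
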