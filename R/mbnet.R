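#' Network configuration
#'
#' Hyperparameters of the bidirectional spectral network. Defaults follow the
#' reference setting: 260 bands over 400-1000 nm, 6 burn-temperature classes,
#' a 100-unit compression layer in the head, and standard Mamba-block
#' internals (state size 16, expansion 2, convolution width 4). `model_dim`
#' (the per-band channel width created by the padding/embedding step) is not
#' fixed by the architecture description; 16 is the package default.
#'
#' @param n_bands Number of spectral bands D.
#' @param n_classes Number of classes C.
#' @param model_dim Channel width of the band embedding.
#' @param state_dim Hidden-state size of the selective SSM.
#' @param expand Inner-width multiplier of the Mamba block.
#' @param conv_width Depthwise causal convolution length.
#' @param depth Number of stacked Mamba blocks per branch (1 = the reference
#'   single-block branch).
#' @param head_hidden Width of the first head layer (100 in the reference).
#' @param leaky_slope Negative slope of LeakyReLU activations.
#' @param bn_eps,bn_momentum BatchNorm stabilizer and running-stat momentum.
#' @return A list of class `mbnet_config`.
#' @export
mbnet_config <- function(n_bands = 260, n_classes = 6, model_dim = 16,
                         state_dim = 16, expand = 2, conv_width = 4,
                         depth = 1, head_hidden = 100, leaky_slope = 0.01,
                         bn_eps = 1e-5, bn_momentum = 0.1) {
  stopifnot(n_bands >= 1, n_classes >= 2, model_dim >= 1, depth >= 1,
            head_hidden >= 1, leaky_slope > 0)
  structure(list(n_bands = as.integer(n_bands),
                 n_classes = as.integer(n_classes),
                 model_dim = as.integer(model_dim),
                 state_dim = as.integer(state_dim),
                 expand = as.integer(expand),
                 conv_width = as.integer(conv_width),
                 depth = as.integer(depth),
                 head_hidden = as.integer(head_hidden),
                 leaky_slope = leaky_slope,
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "mbnet_config")
}

.new_bn <- function(D) {
  list(gamma = rep(1, D), beta = rep(0, D),
       run_mean = rep(0, D), run_var = rep(1, D))
}

.new_branch <- function(cfg) {
  list(blocks = lapply(seq_len(cfg$depth), function(i)
         mamba_block_params(cfg$model_dim, cfg$state_dim, cfg$expand,
                            cfg$conv_width)),
       bn = .new_bn(cfg$n_bands))
}

#' Initialise the bidirectional spectral network
#'
#' Creates the full parameter set: a learned scalar-to-`model_dim` band
#' embedding shared by both branches, two independent Mamba branches
#' (sequential = ascending wavelength, reverse = descending) each with its own
#' BatchNorm, and the two-layer compression head (D -> 100 -> C). The two
#' branches never share weights.
#'
#' @param config An [mbnet_config].
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `mbnet_params`.
#' @export
#' @examples
#' net <- mbnet(mbnet_config(n_bands = 20, model_dim = 4, state_dim = 4), seed = 1)
mbnet <- function(config = mbnet_config(), seed = 0) {
  stopifnot(inherits(config, "mbnet_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subseed(seed, "init"))
  m <- config$model_dim
  structure(list(
    config = config,
    embed = list(w = runif(m, -0.5, 0.5), b = runif(m, -0.1, 0.1)),
    seq = .new_branch(config),
    rev = .new_branch(config),
    head = list(W1 = init_linear(config$n_bands, config$head_hidden),
                b1 = init_bias(config$n_bands, config$head_hidden),
                W2 = init_linear(config$head_hidden, config$n_classes),
                b2 = init_bias(config$head_hidden, config$n_classes))
  ), class = "mbnet_params")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Expand a batch of spectra to the scanning shape
#'
#' The dimensional padding step: each band's scalar reflectance is mapped to a
#' `model_dim`-wide feature vector by the learned affine embedding
#' `x * w + b`, so a `[B x D]` batch becomes a `[B x D x model_dim]` array
#' while the sequence length stays equal to the band count.
#'
#' @param Yin Numeric matrix `[B x D]` of reflectance values.
#' @param params An [mbnet()] parameter object (its `embed` field is used).
#' @return Numeric array `[B x D x model_dim]`.
#' @export
pad_spectrum <- function(Yin, params) {
  Yin <- as.matrix(Yin)
  check_finite(Yin, "spectra")
  B <- nrow(Yin); D <- ncol(Yin); m <- params$config$model_dim
  X <- outer(as.vector(Yin), params$embed$w) +
    rep(params$embed$b, each = B * D)
  array(X, c(B, D, m))
}

# batchnorm over columns of a [B x D] matrix
.bn_forward <- function(x, bn, eps, training) {
  B <- nrow(x)
  if (training) {
    if (B < 2) stop("BatchNorm requires batch size >= 2 in training mode",
                    call. = FALSE)
    mu <- colMeans(x)
    xc <- x - rep(mu, each = B)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- colscale(xc, invstd)
  } else {
    mu <- bn$run_mean
    invstd <- 1 / sqrt(bn$run_var + eps)
    xhat <- colscale(x - rep(mu, each = B), invstd)
    v <- bn$run_var
  }
  out <- colscale(xhat, bn$gamma) + rep(bn$beta, each = B)
  list(out = out, xhat = xhat, invstd = invstd, mu = mu, var = v)
}

.bn_backward <- function(gout, fwd, bn, training) {
  B <- nrow(gout)
  ggamma <- colSums(gout * fwd$xhat)
  gbeta <- colSums(gout)
  if (training) {
    gx <- colscale(
      gout - rep(gbeta / B, each = B) - colscale(fwd$xhat, ggamma / B),
      bn$gamma * fwd$invstd)
  } else {
    gx <- colscale(gout, bn$gamma * fwd$invstd)
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# one directional branch on the [B*L x m] embedded matrix; returns the
# [B x D] post-activation feature and caches
.branch_forward_internal <- function(X, branch, direction, cfg, B, L,
                                     training, keep_cache = FALSE) {
  perm <- if (direction == "reverse") flip_perm(B, L) else NULL
  Xb <- if (is.null(perm)) X else X[perm, , drop = FALSE]
  block_caches <- vector("list", length(branch$blocks))
  h <- Xb
  for (i in seq_along(branch$blocks)) {
    bf <- .block_forward(h, branch$blocks[[i]], B, L, keep_cache = keep_cache)
    block_caches[[i]] <- bf$cache
    h <- bf$y
  }
  if (!is.null(perm)) h <- h[perm, , drop = FALSE]  # back to natural band order
  pooled <- matrix(rowMeans(h), B, L)
  bnf <- .bn_forward(pooled, branch$bn, cfg$bn_eps, training)
  act <- leaky_relu(bnf$out, cfg$leaky_slope)
  cache <- NULL
  if (keep_cache) {
    cache <- list(perm = perm, block_caches = block_caches, pooled = pooled,
                  bnf = bnf, bnout = bnf$out, B = B, L = L)
  }
  list(act = act, cache = cache, pooled = pooled)
}

.branch_backward_internal <- function(gact, cache, branch, cfg, training) {
  B <- cache$B; L <- cache$L
  m <- branch$blocks[[1]]$model_dim
  gbn_out <- gact * leaky_relu_grad(cache$bnout, cfg$leaky_slope)
  bb <- .bn_backward(gbn_out, cache$bnf, branch$bn, training)
  gpooled <- bb$gx
  gh <- matrix(rep(as.vector(gpooled) / m, times = m), B * L, m)
  if (!is.null(cache$perm)) gh <- gh[cache$perm, , drop = FALSE]
  gblocks <- vector("list", length(branch$blocks))
  for (i in rev(seq_along(branch$blocks))) {
    bw <- .block_backward(gh, cache$block_caches[[i]], branch$blocks[[i]])
    gblocks[[i]] <- bw$grads
    gh <- bw$gX
  }
  if (!is.null(cache$perm)) gh <- gh[cache$perm, , drop = FALSE]
  list(grads = list(blocks = gblocks,
                    bn = list(gamma = bb$ggamma, beta = bb$gbeta)),
       gX = gh)
}

#' Run one directional branch of the network
#'
#' Applies a single branch — Mamba block(s), channel mean-pooling, BatchNorm
#' over each band position, LeakyReLU — to an embedded batch. For the reverse
#' direction the band axis is flipped before the Mamba block and the block
#' output is flipped back, so the returned features are aligned with the
#' natural (ascending-wavelength) band order of the sequential branch and the
#' two can be fused positionwise.
#'
#' @param x Numeric array `[B x D x model_dim]` from [pad_spectrum()].
#' @param direction `"sequential"` (ascending wavelength) or `"reverse"`.
#' @param params An [mbnet()] parameter object.
#' @param training Logical; `TRUE` uses batch statistics in BatchNorm
#'   (requires B >= 2), `FALSE` uses the stored running statistics.
#' @return Numeric matrix `[B x D]`.
#' @export
branch_forward <- function(x, direction = c("sequential", "reverse"), params,
                           training = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(dim(x)) == 3)
  B <- dim(x)[1]; L <- dim(x)[2]; m <- dim(x)[3]
  X <- matrix(x, B * L, m)
  branch <- if (direction == "sequential") params$seq else params$rev
  .branch_forward_internal(X, branch, direction, params$config, B, L,
                           training = training)$act
}

#' Fuse the two directional branch outputs
#'
#' The bidirectional fusion is an elementwise sum of the sequential-branch and
#' reverse-branch features.
#'
#' @param Yout_seq,Yout_rev Numeric matrices `[B x D]` of identical shape.
#' @return Their elementwise sum.
#' @export
fuse <- function(Yout_seq, Yout_rev) {
  if (!identical(dim(Yout_seq), dim(Yout_rev))) {
    stop("fuse: shape mismatch between branch outputs", call. = FALSE)
  }
  Yout_seq + Yout_rev
}

#' Two-layer compression head
#'
#' Compresses the fused `[B x D]` spectral feature to class logits:
#' a linear layer to exactly `head_hidden` (100) units, LeakyReLU, and a
#' linear layer to the class count.
#'
#' @param Yout Numeric matrix `[B x D]`.
#' @param params An [mbnet()] parameter object.
#' @return Logit matrix `[B x C]`.
#' @export
classify_head <- function(Yout, params) {
  h <- params$head
  if (ncol(Yout) != nrow(h$W1)) {
    stop(sprintf("head width mismatch: features have %d bands, head expects %d",
                 ncol(Yout), nrow(h$W1)), call. = FALSE)
  }
  B <- nrow(Yout)
  Z1 <- Yout %*% h$W1 + rep(h$b1, each = B)
  H <- leaky_relu(Z1, params$config$leaky_slope)
  H %*% h$W2 + rep(h$b2, each = B)
}

.mbnet_variants <- c("bidirectional", "sequential_only", "reverse_only",
                     "no_mamba")

# full forward pass; returns logits plus (optionally) every cache needed for
# the analytic backward pass
.mbnet_forward_full <- function(Yin, params, variant, training,
                                keep_cache = FALSE) {
  cfg <- params$config
  Yin <- as.matrix(Yin)
  check_finite(Yin, "spectra")
  if (ncol(Yin) != cfg$n_bands) {
    stop(sprintf("input has %d bands but the network was built for %d",
                 ncol(Yin), cfg$n_bands), call. = FALSE)
  }
  B <- nrow(Yin); L <- cfg$n_bands; m <- cfg$model_dim
  yv <- as.vector(Yin)
  X <- outer(yv, params$embed$w) + rep(params$embed$b, each = B * L)

  branches <- list()
  caches <- list()
  if (variant == "no_mamba") {
    pooled <- matrix(rowMeans(X), B, L)
    bnf <- .bn_forward(pooled, params$seq$bn, cfg$bn_eps, training)
    act <- leaky_relu(bnf$out, cfg$leaky_slope)
    Yout <- act
    caches$no_mamba <- list(bnf = bnf, bnout = bnf$out)
  } else {
    if (variant %in% c("bidirectional", "sequential_only")) {
      r <- .branch_forward_internal(X, params$seq, "sequential", cfg, B, L,
                                    training, keep_cache)
      branches$seq <- r$act
      caches$seq <- r$cache
    }
    if (variant %in% c("bidirectional", "reverse_only")) {
      r <- .branch_forward_internal(X, params$rev, "reverse", cfg, B, L,
                                    training, keep_cache)
      branches$rev <- r$act
      caches$rev <- r$cache
    }
    Yout <- if (variant == "bidirectional") {
      fuse(branches$seq, branches$rev)
    } else if (variant == "sequential_only") branches$seq else branches$rev
  }

  h <- params$head
  Z1 <- Yout %*% h$W1 + rep(h$b1, each = B)
  H <- leaky_relu(Z1, cfg$leaky_slope)
  logits <- H %*% h$W2 + rep(h$b2, each = B)

  cache <- NULL
  if (keep_cache) {
    cache <- list(Yin = Yin, yv = yv, X = X, branches = branches,
                  caches = caches, Yout = Yout, Z1 = Z1, H = H,
                  B = B, L = L, variant = variant, training = training)
  }
  list(logits = logits, cache = cache, branch_outputs = branches, Yout = Yout)
}

# zero gradients shaped exactly like the gradient trees the backward pass
# emits (dimension fields of the parameter objects are not gradients)
.zero_block_grads <- function(p) {
  z <- function(a) a * 0
  list(W_in = z(p$W_in), b_in = z(p$b_in),
       conv_w = z(p$conv_w), conv_b = z(p$conv_b),
       ssm = list(A_log = z(p$ssm$A_log), D_skip = z(p$ssm$D_skip),
                  W_B = z(p$ssm$W_B), b_B = z(p$ssm$b_B),
                  W_C = z(p$ssm$W_C), b_C = z(p$ssm$b_C),
                  W_dt = z(p$ssm$W_dt), b_dt = z(p$ssm$b_dt)),
       W_out = z(p$W_out), b_out = z(p$b_out))
}

.zero_branch_grads <- function(branch) {
  list(blocks = lapply(branch$blocks, .zero_block_grads),
       bn = list(gamma = branch$bn$gamma * 0, beta = branch$bn$beta * 0))
}

# gradient of every trainable parameter given dLoss/dlogits
.mbnet_backward_full <- function(glogits, cache, params) {
  cfg <- params$config
  B <- cache$B; L <- cache$L; m <- cfg$model_dim
  h <- params$head
  gW2 <- crossprod(cache$H, glogits)
  gb2 <- colSums(glogits)
  gH <- tcrossprod(glogits, h$W2)
  gZ1 <- gH * leaky_relu_grad(cache$Z1, cfg$leaky_slope)
  gW1 <- crossprod(cache$Yout, gZ1)
  gb1 <- colSums(gZ1)
  gYout <- tcrossprod(gZ1, h$W1)

  gX <- matrix(0, B * L, m)
  grads <- list(embed = NULL, seq = NULL, rev = NULL,
                head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))

  if (cache$variant == "no_mamba") {
    nm <- cache$caches$no_mamba
    gbn_out <- gYout * leaky_relu_grad(nm$bnout, cfg$leaky_slope)
    bb <- .bn_backward(gbn_out, nm$bnf, params$seq$bn, cache$training)
    gX <- gX + matrix(rep(as.vector(bb$gx) / m, times = m), B * L, m)
    gseq <- .zero_branch_grads(params$seq)
    gseq$bn$gamma <- bb$ggamma
    gseq$bn$beta <- bb$gbeta
    grads$seq <- gseq
    grads$rev <- .zero_branch_grads(params$rev)
  } else {
    if (!is.null(cache$caches$seq)) {
      r <- .branch_backward_internal(gYout, cache$caches$seq, params$seq, cfg,
                                     cache$training)
      grads$seq <- r$grads
      gX <- gX + r$gX
    } else {
      grads$seq <- .zero_branch_grads(params$seq)
    }
    if (!is.null(cache$caches$rev)) {
      r <- .branch_backward_internal(gYout, cache$caches$rev, params$rev, cfg,
                                     cache$training)
      grads$rev <- r$grads
      gX <- gX + r$gX
    } else {
      grads$rev <- .zero_branch_grads(params$rev)
    }
  }
  # remove running stats from bn grads (they are state, not parameters)
  grads$seq$bn <- grads$seq$bn[c("gamma", "beta")]
  grads$rev$bn <- grads$rev$bn[c("gamma", "beta")]
  grads$embed <- list(w = drop(crossprod(gX, cache$yv)), b = colSums(gX))
  grads
}

# update BatchNorm running statistics after a training-mode forward
.mbnet_update_bn <- function(params, cache) {
  cfg <- params$config
  upd <- function(bn, bnf) {
    bn$run_mean <- (1 - cfg$bn_momentum) * bn$run_mean + cfg$bn_momentum * bnf$mu
    bn$run_var <- (1 - cfg$bn_momentum) * bn$run_var + cfg$bn_momentum * bnf$var
    bn
  }
  if (cache$variant == "no_mamba") {
    params$seq$bn <- upd(params$seq$bn, cache$caches$no_mamba$bnf)
  } else {
    if (!is.null(cache$caches$seq)) {
      params$seq$bn <- upd(params$seq$bn, cache$caches$seq$bnf)
    }
    if (!is.null(cache$caches$rev)) {
      params$rev$bn <- upd(params$rev$bn, cache$caches$rev$bnf)
    }
  }
  params
}

#' Full network forward pass
#'
#' Runs the complete pipeline — band embedding (padding), the directional
#' Mamba branch(es), additive fusion, and the two-layer compression head —
#' and returns class logits. The `variant` argument selects the ablation
#' configurations: `"bidirectional"` uses both branches and their sum,
#' `"sequential_only"` / `"reverse_only"` use a single branch with no fusion
#' term, and `"no_mamba"` bypasses the Mamba blocks entirely (embedding,
#' pooling, BatchNorm, LeakyReLU and head only — essentially an MLP).
#'
#' @param Yin Numeric matrix `[B x D]`, or a [spectral_dataset].
#' @param params An [mbnet()] parameter object.
#' @param variant One of `"bidirectional"`, `"sequential_only"`,
#'   `"reverse_only"`, `"no_mamba"`.
#' @param training Logical BatchNorm mode flag (see [branch_forward()]).
#' @return Logit matrix `[B x C]`.
#' @export
mbnet_forward <- function(Yin, params, variant = "bidirectional",
                          training = FALSE) {
  if (inherits(Yin, "spectral_dataset")) Yin <- Yin$spectra
  if (!variant %in% .mbnet_variants) {
    stop(sprintf("unknown variant '%s'; expected one of: %s", variant,
                 paste(.mbnet_variants, collapse = ", ")), call. = FALSE)
  }
  .mbnet_forward_full(Yin, params, variant, training)$logits
}
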