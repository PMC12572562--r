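# User-facing building blocks: squeeze-and-excitation, attention gates and the
# encoder/decoder convolution blocks, as standalone functions over explicit
# weight lists. build_network() composes the same internals into full models.

#' Squeeze-and-excitation configuration
#'
#' @param channels Number of feature-map channels `C`.
#' @param reduction_ratio Bottleneck reduction ratio `r`; the excitation MLP
#'   maps `C -> C/r -> C`. Defaults to 64, the value that reproduces the
#'   published parameter budget of the attention models. `C` need not be
#'   divisible by `r`; the bottleneck width is `max(floor(C/r), 1)`.
#' @param use_bias Whether the two fully connected layers carry biases.
#'   Default `FALSE` (bias-free excitation).
#' @return A list of class `se_config`.
#' @export
se_config <- function(channels, reduction_ratio = 64L, use_bias = FALSE) {
  channels <- as.integer(channels)
  reduction_ratio <- as.integer(reduction_ratio)
  if (channels < 1L) stop("`channels` must be a positive integer")
  if (reduction_ratio < 1L) stop("`reduction_ratio` must be a positive integer")
  if (use_bias) stop("biased excitation layers are not supported")
  structure(list(channels = channels, reduction_ratio = reduction_ratio,
                 bottleneck = max(channels %/% reduction_ratio, 1L),
                 use_bias = FALSE),
            class = "se_config")
}

#' Initialise squeeze-and-excitation weights
#'
#' Glorot-uniform initialisation of the two bias-free excitation layers.
#'
#' @param cfg An [se_config()].
#' @return List with `w1` (`C x C/r`) and `w2` (`C/r x C`) matrices.
#' @export
se_init <- function(cfg) {
  stopifnot(inherits(cfg, "se_config"))
  list(w1 = .glorot(c(cfg$channels, cfg$bottleneck)),
       w2 = .glorot(c(cfg$bottleneck, cfg$channels)))
}

#' Number of parameters of a squeeze-and-excitation block
#'
#' Bias-free blocks hold `2 * C^2 / r` weights (two `C x C/r` matrices).
#'
#' @param cfg An [se_config()].
#' @return Integer parameter count.
#' @export
se_param_count <- function(cfg) {
  stopifnot(inherits(cfg, "se_config"))
  2L * cfg$channels * cfg$bottleneck
}

#' Squeeze-and-excitation channel recalibration
#'
#' Global average pooling compresses each channel of `x` to one descriptor
#' ("squeeze"); two fully connected layers with ReLU then sigmoid produce one
#' scale in (0,1) per channel ("excitation"), which multiplies the channel.
#'
#' @param x Feature map, 4-d array `(batch, row, col, channel)`.
#' @param cfg An [se_config()] whose `channels` must match `dim(x)[4]`.
#' @param weights List with `w1`, `w2` as produced by [se_init()].
#' @return Recalibrated feature map with the shape of `x`.
#' @export
squeeze_excite <- function(x, cfg, weights) {
  stopifnot(inherits(cfg, "se_config"))
  .check_fmap(x)
  if (dim(x)[4] != cfg$channels) {
    stop(sprintf("channel mismatch: x has %d channels, config expects %d",
                 dim(x)[4], cfg$channels))
  }
  if (!identical(dim(weights$w1), c(cfg$channels, cfg$bottleneck)) ||
      !identical(dim(weights$w2), c(cfg$bottleneck, cfg$channels))) {
    stop("excitation weight shapes do not match the configuration")
  }
  .se_fw(x, weights$w1, weights$w2)$y
}

#' Attention-gate configuration
#'
#' @param skip_channels Channels `F_l` of the skip-connection feature map.
#' @param gating_channels Channels `F_g` of the gating signal.
#' @param inter_channels Width `F_int` of the additive bottleneck. Default
#'   `max(gating_channels %/% 4, 1)`, the calibration that reproduces the
#'   published parameter budget of the gated models.
#' @param use_bias Whether the three 1x1 projections carry biases (default
#'   `TRUE`, part of the same calibration).
#' @param use_batchnorm Batch normalisation after the final projection;
#'   not part of the calibrated design and therefore unsupported.
#' @return A list of class `ag_config`.
#' @export
ag_config <- function(skip_channels, gating_channels,
                      inter_channels = NULL, use_bias = TRUE,
                      use_batchnorm = FALSE) {
  skip_channels <- as.integer(skip_channels)
  gating_channels <- as.integer(gating_channels)
  if (is.null(inter_channels)) inter_channels <- max(gating_channels %/% 4L, 1L)
  inter_channels <- as.integer(inter_channels)
  if (min(skip_channels, gating_channels, inter_channels) < 1L) {
    stop("all channel counts must be positive integers")
  }
  if (!use_bias) stop("bias-free gate projections are not supported")
  if (use_batchnorm) stop("batch-normalised gates are not supported")
  structure(list(skip_channels = skip_channels,
                 gating_channels = gating_channels,
                 inter_channels = inter_channels,
                 use_bias = TRUE, use_batchnorm = FALSE),
            class = "ag_config")
}

#' Initialise attention-gate weights
#'
#' @param cfg An [ag_config()].
#' @return List of 1x1 convolution weights and biases: `theta_w/theta_b`
#'   (skip projection, applied with stride 2), `phi_w/phi_b` (gating
#'   projection) and `psi_w/psi_b` (final projection to one channel).
#' @export
ag_init <- function(cfg) {
  stopifnot(inherits(cfg, "ag_config"))
  list(theta_w = .glorot(c(1L, 1L, cfg$skip_channels, cfg$inter_channels)),
       theta_b = numeric(cfg$inter_channels),
       phi_w = .glorot(c(1L, 1L, cfg$gating_channels, cfg$inter_channels)),
       phi_b = numeric(cfg$inter_channels),
       psi_w = .glorot(c(1L, 1L, cfg$inter_channels, 1L)),
       psi_b = numeric(1))
}

#' Number of parameters of an attention gate
#'
#' @param cfg An [ag_config()].
#' @return Integer parameter count of the three biased 1x1 projections.
#' @export
ag_param_count <- function(cfg) {
  k <- cfg$inter_channels
  (cfg$skip_channels * k + k) + (cfg$gating_channels * k + k) + (k + 1L)
}

#' Additive attention gate on a skip connection
#'
#' The skip features `x` are projected to `F_int` channels by a stride-2 1x1
#' convolution so they align with the coarser gating grid; the gating signal
#' `g` is projected by a 1x1 convolution; the sum passes through ReLU, a 1x1
#' projection to one channel and a sigmoid, yielding attention coefficients
#' `alpha` in (0,1) at the coarse grid. `alpha` is upsampled (nearest
#' neighbour) back to the skip grid and multiplies `x` across all channels.
#'
#' @param x Skip feature map `(batch, row, col, F_l)`; even spatial extents.
#' @param g Gating signal `(batch, row/2, col/2, F_g)` from the coarser
#'   decoder level.
#' @param cfg An [ag_config()].
#' @param weights List from [ag_init()].
#' @return List with `gated` (same shape as `x`) and `alpha`
#'   (`(batch, row, col, 1)`, values strictly inside (0,1)).
#' @export
attention_gate <- function(x, g, cfg, weights) {
  stopifnot(inherits(cfg, "ag_config"))
  .check_fmap(x)
  .check_fmap(g)
  dx <- dim(x)
  dg <- dim(g)
  if (dx[4] != cfg$skip_channels) stop("x channels do not match `skip_channels`")
  if (dg[4] != cfg$gating_channels) stop("g channels do not match `gating_channels`")
  if (any(dx[2:3] %% 2L != 0L)) stop("skip extents must be even")
  if (!all(dg[2:3] * 2L == dx[2:3])) {
    stop(sprintf(paste0("gating signal must live on the half-resolution grid: ",
                        "x is %dx%d so g must be %dx%d, got %dx%d"),
                 dx[2], dx[3], dx[2] / 2, dx[3] / 2, dg[2], dg[3]))
  }
  r <- .ag_fw(x, g, weights)
  list(gated = r$gated, alpha = r$alpha)
}

#' Encoder convolution block
#'
#' `n_convs` consecutive 3x3 same-padding convolutions with ReLU, followed by
#' 2x2 max pooling. Returns both the pre-pooling features (used as the skip
#' connection) and the pooled map.
#'
#' @param x Feature map `(batch, row, col, channel)` with even spatial extents.
#' @param weights List of `w1,b1,...,wn,bn` conv weights; use
#'   [encoder_block_init()].
#' @return List with `features` (pre-pooling) and `pooled` (halved extents).
#' @export
encoder_block <- function(x, weights) {
  .check_fmap(x)
  if (any(dim(x)[2:3] %% 2L != 0L)) stop("spatial extents must be even")
  n <- length(weights) / 2L
  h <- x
  for (j in seq_len(n)) {
    h <- .relu(.conv_fw(h, weights[[2L * j - 1L]], weights[[2L * j]]))
  }
  list(features = h, pooled = .pool_fw(h)$y)
}

#' Initialise encoder-block weights
#'
#' @param in_channels,out_channels Channel widths.
#' @param n_convs 2 or 3 consecutive 3x3 convolutions.
#' @return Weight list `w1,b1,...` (biased convolutions).
#' @export
encoder_block_init <- function(in_channels, out_channels, n_convs = 2L) {
  stopifnot(n_convs %in% c(2L, 3L))
  w <- list()
  cin <- in_channels
  for (j in seq_len(n_convs)) {
    w[[2L * j - 1L]] <- .glorot(c(3L, 3L, cin, out_channels))
    w[[2L * j]] <- numeric(out_channels)
    cin <- out_channels
  }
  names(w) <- paste0(rep(c("w", "b"), n_convs), rep(seq_len(n_convs), each = 2))
  w
}

#' Decoder convolution block
#'
#' A 2x2 transposed convolution doubles the spatial extents of `x`; the result
#' is concatenated along channels with the skip features (optionally gated by
#' an attention gate), passed through two 3x3 convolution + batch-norm + ReLU
#' stages, and optionally recalibrated by a squeeze-and-excitation block.
#'
#' @param x Coarse feature map `(batch, row, col, channel)`.
#' @param skip Skip feature map with twice the spatial extents of `x`.
#' @param weights List from [decoder_block_init()].
#' @param attention Optional list `(cfg, weights)` for the attention gate.
#' @param se Optional list `(cfg, weights)` for squeeze-and-excitation.
#' @param batchnorm Apply batch-norm after each 3x3 convolution (inference
#'   statistics; `TRUE` matches the VGG16-backbone decoder).
#' @return Feature map with the skip's spatial extents and `out_channels`
#'   channels.
#' @export
decoder_block <- function(x, skip, weights, attention = NULL, se = NULL,
                          batchnorm = TRUE) {
  .check_fmap(x)
  .check_fmap(skip)
  if (!all(dim(skip)[2:3] == 2L * dim(x)[2:3])) {
    stop("skip extents must be exactly twice those of x")
  }
  up <- .convt_fw(x, weights$up_w, weights$up_b)
  s <- skip
  if (!is.null(attention)) {
    s <- attention_gate(skip, x, attention$cfg, attention$weights)$gated
  }
  h <- .concat_ch(up, s)
  for (j in 1:2) {
    h <- .conv_fw(h, weights[[paste0("w", j)]], weights[[paste0("b", j)]])
    if (batchnorm) {
      bn <- weights[[paste0("bn", j)]]
      h <- .bn_fw(h, bn$gamma, bn$beta, bn$rmean, bn$rvar, train = FALSE)$y
    }
    h <- .relu(h)
  }
  if (!is.null(se)) h <- squeeze_excite(h, se$cfg, se$weights)
  h
}

#' Initialise decoder-block weights
#'
#' @param in_channels Channels of the coarse input `x`.
#' @param skip_channels Channels of the skip features.
#' @param out_channels Output width of the block.
#' @param batchnorm Include batch-norm parameters after each convolution.
#' @return Weight list: `up_w/up_b` (2x2 transposed convolution), `w1/b1`,
#'   `w2/b2` (3x3 convolutions) and, if `batchnorm`, `bn1`, `bn2`.
#' @export
decoder_block_init <- function(in_channels, skip_channels, out_channels,
                               batchnorm = TRUE) {
  w <- list(up_w = .glorot(c(2L, 2L, in_channels, out_channels)),
            up_b = numeric(out_channels),
            w1 = .glorot(c(3L, 3L, out_channels + skip_channels, out_channels)),
            b1 = numeric(out_channels),
            w2 = .glorot(c(3L, 3L, out_channels, out_channels)),
            b2 = numeric(out_channels))
  if (batchnorm) {
    w$bn1 <- .bn_init(out_channels)
    w$bn2 <- .bn_init(out_channels)
  }
  w
}

.bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C), rmean = numeric(C), rvar = rep(1, C))
}

.concat_ch <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

.check_fmap <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop("feature maps must be 4-d arrays (batch, row, col, channel)")
  }
  if (any(dim(x) < 1L)) stop("all extents must be >= 1")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(TRUE)
}
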