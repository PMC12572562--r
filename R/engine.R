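# Internal compute engine.
#
# Feature maps are dense 4-d arrays with axes (batch, row, col, channel).
# Convolution weights are (k, k, in_channels, out_channels); fully connected
# weights are (in, out) matrices. The C++ kernels work on one image at a time
# as (row, col, channel) cubes; these wrappers handle the batch axis and keep
# the caches needed for backpropagation.

.slice3 <- function(x4, b) {
  d <- dim(x4)
  array(x4[b, , , ], dim = d[2:4])
}

.pack4 <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(length(lst), d))
  for (b in seq_along(lst)) out[b, , , ] <- lst[[b]]
  out
}

.relu <- function(x) .relu_fw(x)

.sigmoid <- function(x) .sigmoid_fw(x)

.glorot <- function(dims) {
  # fan-in/fan-out for conv (k,k,cin,cout) and dense (cin,cout) tensors
  n <- length(dims)
  rf <- if (n == 4) dims[1] * dims[2] else 1
  fan_in <- rf * dims[n - 1]
  fan_out <- rf * dims[n]
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# ---- convolution -----------------------------------------------------------

.conv_fw <- function(x4, w, bias, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  cout <- dim(w)[4]
  if (is.null(pad)) pad <- if (stride == 1L) (k - 1L) %/% 2L else 0L
  .conv2d_fw(x4, w, bias, k, cout, stride, pad)
}

.conv_bw <- function(x4, w, dy4, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- if (stride == 1L) (k - 1L) %/% 2L else 0L
  r <- .conv2d_bw(x4, w, dy4, k, stride, pad)
  list(dx = r$dx, dw = array(r$dw, dim(w)), db = as.numeric(r$db))
}

.convt_fw <- function(x4, w, bias) {
  cout <- dim(w)[4]
  B <- dim(x4)[1]
  .pack4(lapply(seq_len(B), function(b) .convt2_fw(.slice3(x4, b), w, bias, cout)))
}

.convt_bw <- function(x4, w, dy4) {
  B <- dim(x4)[1]
  dw <- array(0, dim(w))
  db <- numeric(dim(w)[4])
  dxs <- vector("list", B)
  for (b in seq_len(B)) {
    r <- .convt2_bw(.slice3(x4, b), w, .slice3(dy4, b))
    dxs[[b]] <- r$dx
    dw <- dw + array(r$dw, dim(w))
    db <- db + as.numeric(r$db)
  }
  list(dx = .pack4(dxs), dw = dw, db = db)
}

# ---- pooling / resampling --------------------------------------------------

.pool_fw <- function(x4) {
  B <- dim(x4)[1]
  ys <- vector("list", B)
  idx <- vector("list", B)
  for (b in seq_len(B)) {
    r <- .maxpool2_fw(.slice3(x4, b))
    ys[[b]] <- r$y
    idx[[b]] <- r$idx
  }
  list(y = .pack4(ys), idx = idx)
}

.pool_bw <- function(dy4, idx) {
  B <- dim(dy4)[1]
  .pack4(lapply(seq_len(B), function(b) .maxpool2_bw(.slice3(dy4, b), idx[[b]])))
}

.up_fw <- function(x4) {
  B <- dim(x4)[1]
  .pack4(lapply(seq_len(B), function(b) .upsample2_fw(.slice3(x4, b))))
}

.up_bw <- function(dy4) {
  B <- dim(dy4)[1]
  .pack4(lapply(seq_len(B), function(b) .upsample2_bw(.slice3(dy4, b))))
}

# ---- batch normalisation ---------------------------------------------------
# Channelwise over (batch, row, col); biased batch variance; moving statistics
# updated by exponential moving average (momentum 0.99, eps 1e-3).

.bn_fw <- function(x4, gamma, beta, rmean, rvar, train,
                   momentum = 0.99, eps = 1e-3, keep = train) {
  d <- dim(x4)
  C <- d[4]
  xm <- matrix(x4, ncol = C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    new_rmean <- momentum * rmean + (1 - momentum) * mu
    new_rvar <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean
    v <- rvar
    new_rmean <- rmean
    new_rvar <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- .col_affine(xm, inv, -mu * inv)
  y <- .col_affine(xhat, gamma, beta)
  list(y = array(y, d),
       cache = if (keep) list(xhat = xhat, inv = inv, d = d),
       rmean = new_rmean, rvar = new_rvar)
}

.bn_bw <- function(cache, gamma, dy4) {
  d <- cache$d
  C <- d[4]
  n <- prod(d[1:3])
  dym <- matrix(dy4, ncol = C)
  xhat <- cache$xhat
  prod <- dym * xhat
  dgamma <- colSums(prod)
  dbeta <- colSums(dym)
  dxhat <- .col_affine(dym, gamma, numeric(C))
  cs2 <- colSums(dxhat * xhat)
  t1 <- .col_affine(dxhat, rep(1, C), -colSums(dxhat) / n)
  t2 <- .col_affine(xhat, cs2 / n, numeric(C))
  dx <- .col_affine(t1 - t2, cache$inv, numeric(C))
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- squeeze-and-excitation ------------------------------------------------
# Squeeze: global average pool to one descriptor per channel. Excitation: two
# bias-free fully connected layers (ReLU then sigmoid) produce channel scales.

.se_fw <- function(x4, w1, w2) {
  d <- dim(x4)
  hw <- d[2] * d[3]
  C <- d[4]
  S <- .spatial_mean(x4, d[1], hw, C)    # B x C
  z1 <- S %*% w1
  a1 <- .relu(z1)
  sc <- .sigmoid(a1 %*% w2)              # B x C scales in (0,1)
  y <- .bc_scale(x4, sc, d[1], hw, C)
  list(y = y, cache = list(x4 = x4, S = S, z1 = z1, a1 = a1, sc = sc))
}

.se_bw <- function(cache, w1, w2, dy4) {
  d <- dim(dy4)
  hw <- d[2] * d[3]
  C <- d[4]
  dsc <- .spatial_mean(dy4 * cache$x4, d[1], hw, C) * hw
  dx <- .bc_scale(dy4, cache$sc, d[1], hw, C)
  dz2 <- dsc * cache$sc * (1 - cache$sc)
  dw2 <- t(cache$a1) %*% dz2
  da1 <- dz2 %*% t(w2)
  dz1 <- da1 * (cache$z1 > 0)
  dw1 <- t(cache$S) %*% dz1
  dS <- dz1 %*% t(w1)
  dx <- .bc_add(dx, dS / hw, d[1], hw, C)
  list(dx = dx, dw1 = dw1, dw2 = dw2)
}

# ---- additive attention gate -----------------------------------------------
# x: skip features at full resolution (F_l channels); g: gating signal at the
# coarser decoder resolution (F_g channels). Both are linearly projected to
# F_int channels (x via a stride-2 1x1 conv so the grids align), summed,
# ReLU'd, projected to one channel and squashed to attention coefficients,
# which are upsampled back to the skip grid and applied multiplicatively.

.ag_fw <- function(x4, g4, p) {
  theta <- .conv_fw(x4, p$theta_w, p$theta_b, stride = 2L, pad = 0L)
  phi <- .conv_fw(g4, p$phi_w, p$phi_b)
  a <- .relu(theta + phi)
  psi <- .conv_fw(a, p$psi_w, p$psi_b)
  alpha_c <- .sigmoid(psi)
  alpha <- .up_fw(alpha_c)
  d <- dim(x4)
  gated <- .bcast_mul(x4, alpha, prod(d[1:3]), d[4])
  list(gated = gated, alpha = alpha,
       cache = list(x4 = x4, g4 = g4, a = a, alpha_c = alpha_c,
                    alpha = alpha))
}

.ag_bw <- function(cache, p, dgated) {
  x4 <- cache$x4
  d <- dim(x4)
  C <- d[4]
  bhw <- prod(d[1:3])
  dx <- .bcast_mul(dgated, cache$alpha, bhw, C)
  dalpha <- array(.chan_dot(dgated, x4, bhw, C), c(d[1:3], 1))
  dalpha_c <- .up_bw(dalpha)
  dpsi <- dalpha_c * cache$alpha_c * (1 - cache$alpha_c)
  bw_psi <- .conv_bw(cache$a, p$psi_w, dpsi)
  da <- .relu_bw(bw_psi$dx, cache$a)
  bw_theta <- .conv_bw(x4, p$theta_w, da, stride = 2L, pad = 0L)
  bw_phi <- .conv_bw(cache$g4, p$phi_w, da)
  dx <- dx + bw_theta$dx
  list(dx = dx, dg = bw_phi$dx,
       dtheta_w = bw_theta$dw, dtheta_b = bw_theta$db,
       dphi_w = bw_phi$dw, dphi_b = bw_phi$db,
       dpsi_w = bw_psi$dw, dpsi_b = bw_psi$db)
}
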