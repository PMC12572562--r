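# Independent scalar oracles: explicit-loop reimplementations of the blocks,
# used to cross-check the engine. Deliberately naive and slow.

rand_fmap <- function(B, H, W, C, scale = 1) {
  array(rnorm(B * H * W * C, sd = scale), c(B, H, W, C))
}

# squeeze-and-excitation by explicit loops
oracle_se <- function(x, w1, w2) {
  d <- dim(x)
  out <- array(0, d)
  for (b in seq_len(d[1])) {
    s <- numeric(d[4])
    for (cc in seq_len(d[4])) s[cc] <- mean(x[b, , , cc])
    z1 <- numeric(ncol(w1))
    for (j in seq_len(ncol(w1))) z1[j] <- max(sum(s * w1[, j]), 0)
    sc <- numeric(d[4])
    for (cc in seq_len(d[4])) sc[cc] <- 1 / (1 + exp(-sum(z1 * w2[, cc])))
    for (cc in seq_len(d[4])) out[b, , , cc] <- x[b, , , cc] * sc[cc]
  }
  out
}

# additive attention gate by explicit loops; g lives on the half grid
oracle_ag <- function(x, g, wt) {
  d <- dim(x)
  dg <- dim(g)
  k <- dim(wt$theta_w)[4]
  gated <- array(0, d)
  alpha <- array(0, c(d[1:3], 1))
  for (b in seq_len(d[1])) {
    for (hg in seq_len(dg[2])) {
      for (wg in seq_len(dg[3])) {
        a <- numeric(k)
        for (kk in seq_len(k)) {
          th <- sum(x[b, 2 * hg - 1, 2 * wg - 1, ] * wt$theta_w[1, 1, , kk]) +
            wt$theta_b[kk]
          ph <- sum(g[b, hg, wg, ] * wt$phi_w[1, 1, , kk]) + wt$phi_b[kk]
          a[kk] <- max(th + ph, 0)
        }
        psi <- sum(a * wt$psi_w[1, 1, , 1]) + wt$psi_b[1]
        al <- 1 / (1 + exp(-psi))
        for (dh in 0:1) for (dw in 0:1) {
          alpha[b, 2 * hg - 1 + dh, 2 * wg - 1 + dw, 1] <- al
        }
      }
    }
    for (cc in seq_len(d[4])) {
      gated[b, , , cc] <- x[b, , , cc] * alpha[b, , , 1]
    }
  }
  list(gated = gated, alpha = alpha)
}

# naive same-padding 3x3 convolution for one image (H, W, Cin) -> (H, W, Cout)
oracle_conv3 <- function(x, w, bias) {
  d <- dim(x)
  cout <- dim(w)[4]
  y <- array(0, c(d[1], d[2], cout))
  for (co in seq_len(cout)) {
    for (h in seq_len(d[1])) {
      for (ww in seq_len(d[2])) {
        acc <- bias[co]
        for (ci in seq_len(d[3])) {
          for (i in 1:3) {
            for (j in 1:3) {
              hi <- h + i - 2
              wi <- ww + j - 2
              if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2]) {
                acc <- acc + x[hi, wi, ci] * w[i, j, ci, co]
              }
            }
          }
        }
        y[h, ww, co] <- acc
      }
    }
  }
  y
}

rand_mask <- function(H, W, p = 0.3) {
  matrix(rbinom(H * W, 1, p), H, W)
}

small_scenes <- function(n, rows = 64, cols = 64, seed = 5) {
  generate_dataset(n, synth_config(rows = rows, cols = cols, seed = seed))
}
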