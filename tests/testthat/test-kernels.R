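# The compiled convolution/pooling kernels against naive loop oracles.

# single-image wrappers over the batched kernels
conv_fw1 <- function(x, w, b, k, cout, stride, pad) {
  y <- woundseg:::.conv2d_fw(array(x, c(1L, dim(x))), w, b, k, cout, stride, pad)
  array(y[1, , , ], dim(y)[2:4])
}
conv_bw1 <- function(x, w, dy, k, stride, pad) {
  r <- woundseg:::.conv2d_bw(array(x, c(1L, dim(x))), w,
                             array(dy, c(1L, dim(dy))), k, stride, pad)
  list(dx = array(r$dx[1, , , ], dim(x)), dw = r$dw, db = r$db)
}

test_that("conv2d forward matches the naive loop oracle", {
  set.seed(1)
  x <- array(rnorm(12 * 10 * 4), c(12, 10, 4))
  w <- array(rnorm(3 * 3 * 4 * 5) * 0.3, c(3, 3, 4, 5))
  b <- rnorm(5)
  y <- conv_fw1(x, w, b, 3L, 5L, 1L, 1L)
  expect_equal(y, oracle_conv3(x, w, b), tolerance = 1e-12)
})

test_that("conv2d backward is the exact adjoint of the forward map", {
  # <dy, conv(x)> must equal <col2im-backprop dx, x> + weight-gradient terms;
  # checked via directional derivatives of the linear map
  set.seed(2)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4))
  b <- numeric(4)
  dy <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  bw <- conv_bw1(x, w, dy, 3L, 1L, 1L)
  # adjoint identity for dx: <dy, conv(v)> = <dx(v-independent? linear)>; use
  # linearity: conv(x + t v) - conv(x) = t conv(v)
  v <- array(rnorm(length(x)), dim(x))
  lhs <- sum(dy * conv_fw1(v, w, b, 3L, 4L, 1L, 1L))
  rhs <- sum(bw$dx * v)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # weight gradient via finite difference on one coordinate
  eps <- 1e-6
  w2 <- w; w2[2, 3, 1, 2] <- w2[2, 3, 1, 2] + eps
  num <- sum(dy * (conv_fw1(x, w2, b, 3L, 4L, 1L, 1L) -
                     conv_fw1(x, w, b, 3L, 4L, 1L, 1L))) / eps
  expect_equal(num, array(bw$dw, dim(w))[2, 3, 1, 2], tolerance = 1e-5)
})

test_that("stride-2 1x1 convolution subsamples the even grid", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(1 * 1 * 2 * 3), c(1, 1, 2, 3))
  b <- rnorm(3)
  y <- conv_fw1(x, w, b, 1L, 3L, 2L, 0L)
  expect_equal(dim(y), c(3L, 3L, 3L))
  for (co in 1:3) {
    expect_equal(y[2, 3, co], sum(x[3, 5, ] * w[1, 1, , co]) + b[co],
                 tolerance = 1e-12)
  }
})

test_that("transposed 2x2 convolution doubles extents and places windows", {
  set.seed(4)
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  w <- array(rnorm(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  b <- rnorm(2)
  y <- woundseg:::.convt2_fw(x, w, b, 2L)
  expect_equal(dim(y), c(8L, 10L, 2L))
  for (a in 1:2) for (bb in 1:2) for (co in 1:2) {
    expect_equal(y[2 * 2 - 2 + a, 2 * 3 - 2 + bb, co],
                 sum(x[2, 3, ] * w[a, bb, , co]) + b[co], tolerance = 1e-12)
  }
  # adjoint identity
  dy <- array(rnorm(8 * 10 * 2), c(8, 10, 2))
  bw <- woundseg:::.convt2_bw(x, w, dy)
  v <- array(rnorm(length(x)), dim(x))
  lhs <- sum(dy * woundseg:::.convt2_fw(v, w, numeric(2), 2L))
  expect_equal(lhs, sum(bw$dx * v), tolerance = 1e-9)
})

test_that("max pooling tracks argmax and routes gradients to it", {
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(c(1, 5, 2, 0,
                       3, 4, 8, 1,
                       0, 2, 1, 1,
                       9, 1, 1, 2), 4, 4, byrow = TRUE)
  r <- woundseg:::.maxpool2_fw(x)
  expect_equal(r$y[, , 1], matrix(c(5, 8, 9, 2), 2, 2, byrow = TRUE))
  dy <- array(1, c(2, 2, 1))
  dx <- woundseg:::.maxpool2_bw(dy, r$idx)
  expect_equal(sum(dx), 4)
  expect_equal(dx[1, 2, 1], 1)  # the 5
  expect_equal(dx[4, 1, 1], 1)  # the 9
})

test_that("nearest upsampling and its adjoint are consistent", {
  set.seed(5)
  x <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  y <- woundseg:::.upsample2_fw(x)
  expect_equal(dim(y), c(6L, 8L, 2L))
  expect_equal(y[3, 5, 1], x[2, 3, 1])
  expect_equal(y[4, 6, 1], x[2, 3, 1])
  dy <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  expect_equal(sum(dy * woundseg:::.upsample2_fw(x)),
               sum(woundseg:::.upsample2_bw(dy) * x), tolerance = 1e-10)
})

test_that("fused Adam update reproduces the reference formulas", {
  set.seed(6)
  p <- rnorm(20)
  g <- rnorm(20)
  m <- rnorm(20) * 0.1
  v <- abs(rnorm(20)) * 0.1
  m0 <- m + 0; v0 <- v + 0  # force copies
  t <- 3; b1 <- 0.9; b2 <- 0.999; lr <- 1e-3; eps <- 1e-8
  out <- woundseg:::.adam_update(p, g, m, v, lr, b1, b2, eps,
                                 1 - b1^t, 1 - b2^t)
  m_ref <- b1 * m0 + (1 - b1) * g
  v_ref <- b2 * v0 + (1 - b2) * g^2
  p_ref <- p - lr * (m_ref / (1 - b1^t)) / (sqrt(v_ref / (1 - b2^t)) + eps)
  expect_equal(out, p_ref, tolerance = 1e-14)
  expect_equal(m, m_ref, tolerance = 1e-14)  # state updated in place
  expect_equal(v, v_ref, tolerance = 1e-14)
})

test_that("the batched kernel equals per-image computation on each slice", {
  set.seed(9)
  x4 <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  w <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4))
  b <- rnorm(4)
  y4 <- woundseg:::.conv2d_fw(x4, w, b, 3L, 4L, 1L, 1L)
  for (bb in 1:2) {
    xb <- array(x4[bb, , , ], c(8, 8, 3))
    expect_equal(array(y4[bb, , , ], c(8, 8, 4)), oracle_conv3(xb, w, b),
                 tolerance = 1e-12)
  }
})
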