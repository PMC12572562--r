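# Squeeze-and-excitation, attention gates and the encoder/decoder blocks.

test_that("zero excitation weights halve the input (sigmoid(0) = 1/2)", {
  cfg <- se_config(8, reduction_ratio = 4)
  w <- list(w1 = matrix(0, 8, 2), w2 = matrix(0, 2, 8))
  x <- rand_fmap(1, 4, 4, 8)
  expect_equal(squeeze_excite(x, cfg, w), 0.5 * x, tolerance = 1e-12)
})

test_that("squeeze-excite cannot create mass from a zero input", {
  cfg <- se_config(4, reduction_ratio = 2)
  set.seed(1)
  w <- se_init(cfg)
  x <- array(0, c(1, 4, 4, 4))
  expect_equal(squeeze_excite(x, cfg, w), x)
})

test_that("squeeze-excite matches the scalar loop oracle on seeded inputs", {
  worst <- 0
  for (trial in 1:100) {
    set.seed(trial)
    C <- sample(c(2L, 4L, 8L), 1)
    H <- sample(2:4, 1)
    cfg <- se_config(C, reduction_ratio = 2)
    w <- se_init(cfg)
    x <- rand_fmap(1, H, H, C)
    got <- squeeze_excite(x, cfg, w)
    want <- oracle_se(x, w$w1, w$w2)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-5)
})

test_that("squeeze-excite attenuates every channel", {
  set.seed(2)
  cfg <- se_config(8, reduction_ratio = 4)
  w <- se_init(cfg)
  x <- rand_fmap(2, 4, 4, 8, scale = 3)
  y <- squeeze_excite(x, cfg, w)
  for (cc in 1:8) {
    expect_lte(max(abs(y[, , , cc])), max(abs(x[, , , cc])))
  }
})

test_that("squeeze-excite validates channel and weight shapes", {
  cfg <- se_config(8)
  w <- se_init(cfg)
  expect_error(squeeze_excite(rand_fmap(1, 4, 4, 4), cfg, w), "channel mismatch")
  bad <- list(w1 = matrix(0, 4, 1), w2 = matrix(0, 1, 4))
  expect_error(squeeze_excite(rand_fmap(1, 4, 4, 8), cfg, bad), "shapes")
})

test_that("SE parameter count is 2*C^2/r for the bias-free block", {
  for (C in c(64L, 128L, 256L, 512L)) {
    cfg <- se_config(C, reduction_ratio = 64)
    expect_identical(se_param_count(cfg), 2L * C * (C %/% 64L))
    w <- se_init(cfg)
    expect_identical(length(w$w1) + length(w$w2), se_param_count(cfg))
  }
  # the nine insertion sites of the attention models sum to the published delta
  sites <- c(64, 128, 256, 512, 512, 512, 256, 128, 64)
  expect_identical(sum(vapply(sites, function(C)
    se_param_count(se_config(C)), integer(1))), 29952L)
})

test_that("a zeroed final projection gives alpha = 1/2 everywhere", {
  cfg <- ag_config(4, 8)
  set.seed(3)
  w <- ag_init(cfg)
  w$psi_w[] <- 0
  w$psi_b[] <- 0
  x <- rand_fmap(1, 4, 4, 4)
  g <- rand_fmap(1, 2, 2, 8)
  r <- attention_gate(x, g, cfg, w)
  expect_equal(r$alpha, array(0.5, c(1, 4, 4, 1)))
  expect_equal(r$gated, 0.5 * x, tolerance = 1e-12)
})

test_that("a saturated final projection passes the skip through", {
  cfg <- ag_config(4, 8)
  set.seed(4)
  w <- ag_init(cfg)
  w$psi_w[] <- 0
  w$psi_b[] <- 20
  x <- rand_fmap(1, 4, 4, 4)
  g <- rand_fmap(1, 2, 2, 8)
  r <- attention_gate(x, g, cfg, w)
  expect_lt(max(abs(r$gated - x)), 1e-6)
})

test_that("attention gate matches the scalar loop oracle on seeded inputs", {
  worst <- 0
  for (trial in 1:100) {
    set.seed(trial + 200)
    Fl <- sample(c(2L, 4L, 8L), 1)
    Fg <- sample(c(2L, 4L, 8L), 1)
    H <- 2L * sample(1:2, 1)
    cfg <- ag_config(Fl, Fg, inter_channels = sample(2:4, 1))
    w <- ag_init(cfg)
    w$theta_b <- rnorm(cfg$inter_channels) * 0.1
    w$phi_b <- rnorm(cfg$inter_channels) * 0.1
    w$psi_b <- rnorm(1) * 0.1
    x <- rand_fmap(1, H, H, Fl)
    g <- rand_fmap(1, H / 2, H / 2, Fg)
    got <- attention_gate(x, g, cfg, w)
    want <- oracle_ag(x, g, w)
    worst <- max(worst, max(abs(got$gated - want$gated)),
                 max(abs(got$alpha - want$alpha)))
  }
  expect_lt(worst, 1e-5)
})

test_that("attention coefficients lie strictly inside (0,1) and attenuate", {
  set.seed(5)
  cfg <- ag_config(8, 8)
  w <- ag_init(cfg)
  x <- rand_fmap(2, 8, 8, 8, scale = 2)
  g <- rand_fmap(2, 4, 4, 8, scale = 2)
  r <- attention_gate(x, g, cfg, w)
  expect_true(all(r$alpha > 0 & r$alpha < 1))
  expect_true(all(abs(r$gated) <= abs(x)))
})

test_that("attention gate rejects incompatible gating grids", {
  cfg <- ag_config(4, 4)
  set.seed(6)
  w <- ag_init(cfg)
  x <- rand_fmap(1, 4, 4, 4)
  expect_error(attention_gate(x, rand_fmap(1, 4, 4, 4), cfg, w),
               "half-resolution")
})

test_that("attention-gate parameter count reproduces the published delta", {
  # four gates: skips (512,256,128,64), gates (512,512,256,128), F_int = F_g/4
  lv <- list(c(512, 512), c(256, 512), c(128, 256), c(64, 128))
  total <- sum(vapply(lv, function(p)
    ag_param_count(ag_config(p[1], p[2])), integer(1)))
  expect_identical(total, 261156L)
})

test_that("encoder block honours its shape contract", {
  set.seed(7)
  w <- encoder_block_init(3, 16, n_convs = 2)
  x <- rand_fmap(1, 32, 32, 3)
  r <- encoder_block(x, w)
  expect_equal(dim(r$features), c(1L, 32L, 32L, 16L))
  expect_equal(dim(r$pooled), c(1L, 16L, 16L, 16L))
  expect_error(encoder_block(rand_fmap(1, 15, 16, 3), w), "even")
  # one 3->64 convolution with bias holds 1792 parameters
  w64 <- encoder_block_init(3, 64)
  expect_identical(length(w64$w1) + length(w64$b1), 1792L)
})

test_that("zeroed encoder weights yield identically zero features", {
  w <- encoder_block_init(3, 8)
  for (nm in names(w)) w[[nm]][] <- 0
  r <- encoder_block(rand_fmap(1, 16, 16, 3), w)
  expect_true(all(r$features == 0))
})

test_that("decoder block honours its shape contract", {
  set.seed(8)
  w <- decoder_block_init(32, 16, 16, batchnorm = TRUE)
  x <- rand_fmap(1, 8, 8, 32)
  skip <- rand_fmap(1, 16, 16, 16)
  y <- decoder_block(x, skip, w)
  expect_equal(dim(y), c(1L, 16L, 16L, 16L))
  expect_error(decoder_block(x, rand_fmap(1, 8, 8, 16), w), "twice")
})

test_that("decoder with zero-excitation SE halves the plain block output", {
  set.seed(9)
  w <- decoder_block_init(8, 4, 4, batchnorm = FALSE)
  x <- rand_fmap(1, 4, 4, 8)
  skip <- rand_fmap(1, 8, 8, 4)
  plain <- decoder_block(x, skip, w, batchnorm = FALSE)
  se <- list(cfg = se_config(4, reduction_ratio = 2),
             weights = list(w1 = matrix(0, 4, 2), w2 = matrix(0, 2, 4)))
  withse <- decoder_block(x, skip, w, se = se, batchnorm = FALSE)
  expect_equal(withse, 0.5 * plain, tolerance = 1e-12)
})

test_that("feature maps with non-finite values are rejected", {
  x <- rand_fmap(1, 4, 4, 2)
  x[1, 1, 1, 1] <- NaN
  expect_error(woundseg:::.check_fmap(x), "non-finite")
})
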