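test_that("dense convolution grows channels linearly and preserves space", {
  x <- array(rnorm(6 * 6 * 4 * 16), c(6, 6, 4, 16))
  y <- dense_conv(x, growth_rate = 16)
  expect_identical(dim(y), c(6L, 6L, 4L, 32L))
  y2 <- dense_conv(y, growth_rate = 16)
  expect_identical(dim(y2)[4], 48L)
  # the input features pass through the concatenation untouched
  expect_identical(y[, , , 1:16], x)
  # zero input with zero bias: the fresh channels are zero after ReLU
  z <- dense_conv(array(0, c(4, 4, 4, 3)), growth_rate = 5)
  expect_true(all(z == 0))
})

test_that("dense downsampling halves space (ceiling) and adds growth channels", {
  x <- array(rnorm(8 * 6 * 5 * 4), c(8, 6, 5, 4))
  y <- dense_downsample(x, growth_rate = 3)
  expect_identical(dim(y), c(4L, 3L, 3L, 7L))
  # the max-pool branch of a constant volume is the constant
  cst <- array(2, c(4, 4, 4, 2))
  yc <- dense_downsample(cst, growth_rate = 2)
  expect_true(all(yc[, , , 1:2] == 2))
  expect_error(dense_downsample(array(0, c(4, 4, 1, 2))), "axis of size 1")
})

test_that("attention coefficients live in [0,1] and gate the skip features", {
  set.seed(21)
  for (i in 1:20) {
    skip <- array(rnorm(5 * 5 * 3 * 6, 0, 3), c(5, 5, 3, 6))
    gat <- array(rnorm(5 * 5 * 3 * 4, 0, 3), c(5, 5, 3, 4))
    r <- attention_gate(skip, gat, ag_features = 8, seed = i)
    expect_true(all(r$alpha >= 0 & r$alpha <= 1))
    expect_identical(dim(r$output), dim(skip))
  }
  skip <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  gat <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  # saturate the final projection: alpha ~ 1 and the skip passes through
  hi <- attention_gate(skip, gat, ag_features = 4, seed = 1, final_bias = 50)
  expect_true(all(hi$alpha > 0.999))
  expect_lt(max(abs(hi$output - skip)), 1e-3 * max(abs(skip)))
  # drive it the other way: alpha ~ 0 and the output vanishes
  lo <- attention_gate(skip, gat, ag_features = 4, seed = 1, final_bias = -50)
  expect_true(all(lo$alpha < 1e-3))
  expect_lt(max(abs(lo$output)), 1e-3 * max(abs(skip)))
  # a coarser gating map is resampled onto the skip grid
  gat2 <- array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3))
  r2 <- attention_gate(skip, gat2, ag_features = 4, seed = 2)
  expect_identical(dim(r2$output), dim(skip))
})

test_that("built models honor the spatial shape contract on even and odd grids", {
  cfg <- arch_config("hda", levels = 3, growth_rate = 4, ag_features = 8,
                     in_channels = 3)
  m <- build_model(cfg, seed = 2)
  for (shape in list(c(16L, 12L, 8L), c(11L, 9L, 7L))) {
    x <- array(rnorm(prod(shape) * 3), c(shape, 3L))
    y <- hdadose:::net_predict(m, x)
    expect_identical(dim(y), shape)
    expect_true(all(is.finite(y)))
  }
  # evaluation mode is bitwise deterministic
  x <- array(rnorm(16 * 12 * 8 * 3), c(16, 12, 8, 3))
  expect_identical(hdadose:::net_predict(m, x), hdadose:::net_predict(m, x))
  # an input too small for the halving hierarchy names the required padding
  expect_error(hdadose:::net_predict(m, array(0, c(2, 16, 16, 3))), "pad axes")
})

test_that("parameter counting is exact for known layer sizes", {
  # a single 3x3x3 convolution 1 -> 1 with bias: 27 weights + 1 bias
  cfg <- arch_config("hd", levels = 2, growth_rate = 1, in_channels = 1)
  m <- hdadose:::new_model_env(cfg)
  hdadose:::add_conv3(m, "c", 1, 1)
  expect_identical(count_parameters(m), 28)
  # a 1x1x1 convolution 64 -> 1 with bias
  m2 <- hdadose:::new_model_env(cfg)
  hdadose:::add_conv1(m2, "c", 64, 1)
  expect_identical(count_parameters(m2), 65)
})

test_that("the HDA/HD parameter difference equals the gate + batch-norm formula", {
  mk <- function(variant) build_model(
    arch_config(variant, levels = 4, growth_rate = 8, ag_features = 16,
                in_channels = 5), seed = 1)
  hda <- mk("hda"); hd <- mk("hd")
  # closed form: per level, gate (c_skip + ag + 1) projections to ag/ag/1 with
  # biases, plus 2 batch-norm scalars per convolution output channel
  g <- 8; ag <- 16
  c <- 5; skips <- integer(0)
  bn <- 0
  for (l in 1:3) {
    c <- c + 2 * g; skips[l] <- c; c <- c + g
    bn <- bn + 3 * 2 * g
  }
  bn <- bn + 4 * 2 * g            # bottom convolutions
  gates <- 0
  for (l in 3:1) {
    bn <- bn + 2 * ag + 2 * 2 * g # up-conv + two decoder dense convolutions
    gates <- gates + (skips[l] * ag + ag) + (ag * ag + ag) + (ag + 1)
  }
  expect_identical(count_parameters(hda) - count_parameters(hd), gates + bn)
})

test_that("channel growth along dense paths is linear in the growth rate", {
  x <- array(rnorm(16 * 16 * 16 * 4), c(16, 16, 16, 4))
  h <- x
  for (k in 1:4) {
    h <- dense_downsample(h, growth_rate = 6, seed = k)
    expect_identical(dim(h)[4], 4L + k * 6L)
  }
})
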