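test_that("build_model is reproducible and its name set depends only on the config", {
  cfg <- tiny_backbone()
  expect_identical(build_model(cfg, 7L), build_model(cfg, 7L))
  a <- build_model(cfg, 1L)
  b <- build_model(cfg, 2L)
  expect_identical(names(a$tensors), names(b$tensors))
  expect_false(identical(a$tensors, b$tensors))
  expect_true(all(vapply(a$tensors, function(t) all(is.finite(t)), logical(1))))
})

test_that("parameter count matches a hand-counted closed form", {
  # residual, stages (4, 8, 16), 1 block each, fpn 8:
  cfg <- backbone_config("residual", stage_channels = c(4L, 8L, 16L),
                         blocks_per_stage = c(1L, 1L, 1L), fpn_channels = 8L)
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  gn <- function(c) 2 * c
  expected <- 0
  cin <- 1
  for (cs in c(4, 8, 16)) {
    expected <- expected + conv(3, cin, cs) + gn(cs) +        # entry conv + GN
      2 * (conv(3, cs, cs) + gn(cs))                          # residual block
    cin <- cs
  }
  expected <- expected + sum(sapply(c(4, 8, 16), function(cs) conv(1, cs, 8))) +  # laterals
    conv(3, 8, 8) + gn(8) +                                   # head conv + GN
    conv(1, 8, 1)                                             # output head
  built <- build_model(cfg, 1L)
  expect_equal(sum(vapply(built$tensors, length, integer(1))), expected)
})

test_that("dense family requires growth_rate; config invariants enforced", {
  expect_error(backbone_config("dense", c(4, 8, 16), c(1, 1, 1), fpn_channels = 8),
               "growth_rate")
  expect_error(backbone_config("residual", c(4, 8), c(1, 1), fpn_channels = 8),
               "3 encoder stages")
  expect_error(backbone_config("residual", c(4, 8, 16), c(1, 1), fpn_channels = 8),
               "equal length")
})

test_that("forward preserves spatial shape across random valid sizes and families", {
  set.seed(5)
  for (family in c("residual", "dense")) {
    cfg <- tiny_backbone(family)
    params <- build_model(cfg, 3L)
    for (rep in 1:3) {
      H <- 8L * sample(2:5, 1L)
      W <- 8L * sample(2:5, 1L)
      logits <- forward(params, matrix(runif(H * W), H, W))
      expect_equal(dim(logits), c(H, W))
      expect_true(all(is.finite(logits)))
    }
    expect_error(forward(params, matrix(0, 20, 16)), "divisible")
  }
})

test_that("zeroed final head propagates its bias to every logit", {
  cfg <- tiny_backbone()
  params <- build_model(cfg, 1L)
  params$tensors[["head.out.w"]][] <- 0
  params$tensors[["head.out.b"]][] <- 0.73
  logits <- forward(params, matrix(runif(256), 16, 16))
  expect_true(all(abs(logits - 0.73) < 1e-12))
})

test_that("the model responds to input contrast (not constant)", {
  cfg <- tiny_backbone()
  params <- build_model(cfg, 11L)
  set.seed(2)
  x <- matrix(runif(256), 16, 16)
  expect_gt(max(abs(forward(params, 2 * x) - forward(params, x))), 0)
})

test_that("residual block with F = 0 is the identity on non-negative inputs", {
  cs <- 4L
  w <- list(c1.w = array(0, c(3, 3, cs, cs)), c1.b = rep(0, cs),
            gn1.g = rep(1, cs), gn1.bt = rep(0, cs),
            c2.w = array(0, c(3, 3, cs, cs)), c2.b = rep(0, cs),
            gn2.g = rep(1, cs), gn2.bt = rep(0, cs))
  set.seed(3)
  x <- array(runif(8 * 8 * cs), c(8, 8, cs))  # non-negative
  expect_equal(residual_block(x, w), x, tolerance = 1e-12)
})

test_that("residual arithmetic: x = 2, F(x) = 3 gives y = 5", {
  # 1x1 image, single channel: both group-norms see one element, so their
  # outputs collapse to their beta shifts; beta2 = 3 makes F constant at 3.
  w <- list(c1.w = array(0, c(3, 3, 1, 1)), c1.b = 0,
            gn1.g = 1, gn1.bt = 0,
            c2.w = array(0, c(3, 3, 1, 1)), c2.b = 0,
            gn2.g = 1, gn2.bt = 3)
  x <- array(2, c(1, 1, 1))
  expect_equal(as.vector(residual_block(x, w)), 5, tolerance = 1e-9)
})

test_that("the identity path contributes a unit derivative (dy/dx = 1 + dF/dx)", {
  # same construction: F is constant, so dF/dx = 0 and dy/dx must be 1
  w <- list(c1.w = array(0, c(3, 3, 1, 1)), c1.b = 0,
            gn1.g = 1, gn1.bt = 0,
            c2.w = array(0, c(3, 3, 1, 1)), c2.b = 0,
            gn2.g = 1, gn2.bt = 0.4)
  f <- function(xv) as.vector(residual_block(array(xv, c(1, 1, 1)), w))
  h <- 1e-6
  dydx <- (f(1.3 + h) - f(1.3 - h)) / (2 * h)
  expect_equal(dydx, 1, tolerance = 1e-4)
})

test_that("dense block concatenation: channel count and input preservation", {
  growth <- 4L
  mk_w <- function(layers, cin, zero_l1 = FALSE, seed = 1L) {
    set.seed(seed)
    w <- list()
    cacc <- cin
    for (l in seq_len(layers)) {
      p <- sprintf("l%d", l)
      w[[paste0(p, ".c.w")]] <- array(rnorm(9 * cacc * growth, sd = 0.2),
                                      c(3, 3, cacc, growth))
      if (zero_l1 && l == 1L) w[[paste0(p, ".c.w")]][] <- 0
      w[[paste0(p, ".c.b")]] <- rep(0, growth)
      w[[paste0(p, ".gn.g")]] <- rep(1, growth)
      w[[paste0(p, ".gn.bt")]] <- rep(0, growth)
      cacc <- cacc + growth
    }
    w
  }
  set.seed(9)
  x <- array(runif(6 * 6 * 8), c(6, 6, 8))
  out <- dense_block(x, mk_w(2L, 8L), layers = 2L, growth = growth)
  expect_equal(dim(out)[3], 8L + 2L * growth)   # 16 channels

  # layers = 1 with zero conv: first channel slots equal the input exactly
  out1 <- dense_block(x, mk_w(1L, 8L, zero_l1 = TRUE), layers = 1L, growth = growth)
  expect_identical(out1[, , 1:8], x)

  # zeroing layer 1 changes what layer 2 consumes (direct access to all
  # preceding feature maps)
  a <- dense_block(x, mk_w(2L, 8L, zero_l1 = FALSE, seed = 4L), 2L, growth)
  b <- dense_block(x, mk_w(2L, 8L, zero_l1 = TRUE, seed = 4L), 2L, growth)
  l2_slots <- 8L + growth + seq_len(growth)
  expect_gt(max(abs(a[, , l2_slots] - b[, , l2_slots])), 0)
})

test_that("predict_mask binarizes at the threshold with ties counted positive", {
  expect_true(all(predict_mask(matrix(-100, 4, 4))$mask == 0L))
  expect_equal(predict_mask(matrix(0, 2, 2), threshold = 0.5)$mask,
               matrix(1L, 2, 2))
  set.seed(6)
  lg <- matrix(rnorm(64), 8, 8)
  expect_identical(predict_mask(lg, 0.3)$mask,
                   matrix(as.integer(1 / (1 + exp(-lg)) >= 0.3), 8, 8))
})

test_that("checkpoints round-trip tensors and config", {
  cfg <- tiny_backbone()
  params <- build_model(cfg, 2L)
  tmp <- tempfile(fileext = ".ckpt")
  save_checkpoint(params, tmp)
  back <- load_checkpoint(tmp)
  expect_identical(back$tensors, params$tensors)
  expect_identical(back$config$stage_channels, cfg$stage_channels)
})
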