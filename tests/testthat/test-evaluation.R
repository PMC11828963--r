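test_that("iou and f1 match hand counts and boundary conventions", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L            # 4-pixel square
  b <- matrix(0L, 4, 4); b[2:3, 1:2] <- 1L            # shifted: overlap 2
  expect_equal(iou(a, b), 2 / 6)
  expect_equal(f1(a, b), 0.5)                         # 2*2/(4+4)
  expect_equal(iou(a, a), 1)
  expect_equal(f1(a, a), 1)
  disj <- matrix(0L, 4, 4); disj[4, 4] <- 1L
  expect_equal(iou(a, disj), 0)
  expect_equal(f1(a, disj), 0)
  empty <- matrix(0L, 4, 4)
  expect_equal(iou(empty, empty), 1)                  # both-empty convention
  expect_equal(f1(empty, empty), 1)
  expect_error(iou(a, matrix(0L, 3, 3)), "shapes differ")
  expect_error(f1(a, matrix(0L, 4, 5)), "shapes differ")
})

test_that("f1 = 2*iou/(1+iou) exactly, and both metrics are symmetric", {
  set.seed(13)
  for (i in 1:200) {
    p <- matrix(rbinom(64, 1, runif(1, 0, 0.6)), 8, 8)
    g <- matrix(rbinom(64, 1, runif(1, 0, 0.6)), 8, 8)
    J <- iou(p, g)
    expect_equal(f1(p, g), 2 * J / (1 + J), tolerance = 1e-12)
    # exact form of the same identity: f1 = 2|∩| / (|∩| + |∪|)
    if (sum(p | g) > 0) {
      expect_identical(f1(p, g), 2 * sum(p & g) / (sum(p & g) + sum(p | g)))
    }
    expect_identical(iou(g, p), J)
    expect_identical(f1(g, p), f1(p, g))
  }
})

test_that("percent_nonvitrified is exact and additive over disjoint tiles", {
  expect_equal(percent_nonvitrified(matrix(0L, 10, 10)), 0)
  expect_equal(percent_nonvitrified(matrix(1L, 10, 10)), 100)
  m <- matrix(0L, 10, 10); m[1:5, 1:5] <- 1L
  expect_equal(percent_nonvitrified(m), 25)
  # area-weighted mean over a disjoint tiling equals the whole-image value
  set.seed(3)
  big <- matrix(rbinom(16 * 20, 1, 0.3), 16, 20)
  tiles <- list(big[1:8, 1:10], big[1:8, 11:20], big[9:16, 1:10], big[9:16, 11:20])
  weighted <- sum(vapply(tiles, function(t) percent_nonvitrified(t) * length(t),
                         numeric(1))) / length(big)
  expect_equal(weighted, percent_nonvitrified(big))
})

test_that("aggregate_ci matches the closed form and scales as 1/sqrt(n)", {
  ci <- aggregate_ci(c(1, 2, 3))
  expect_equal(unname(ci["mean"]), 2)
  expect_equal(unname(ci["halfwidth"]), qnorm(0.975) / sqrt(3), tolerance = 1e-9)
  expect_error(aggregate_ci(5), "at least 2")
  expect_equal(unname(aggregate_ci(rep(4.2, 6))["halfwidth"]), 0)
  # repeated constant-variance samples: halfwidth ~ 1/sqrt(n)
  set.seed(1)
  x <- rnorm(400)
  h1 <- unname(aggregate_ci(x[1:100])["halfwidth"])
  h4 <- unname(aggregate_ci(x)["halfwidth"])
  expect_equal(h4 / h1, sqrt(100 / 400) * sd(x) / sd(x[1:100]), tolerance = 1e-9)
})

test_that("dataset reports format as mean% ± halfwidth%", {
  rep <- dataset_report(c(1, 2, 3))
  expect_match(format(rep), "^2\\.00% ± 1\\.13%$")
  g <- glance(rep)
  expect_equal(g$n_images, 3L)
  expect_equal(g$mean_percent, 2)
})

test_that("kshot_curve with a stub fine-tuner equals direct evaluation", {
  cfg <- tiny_backbone()
  model <- fpn_model(cfg)
  theta <- build_model(cfg, 6L)
  prior <- synthetic_prior(image_size = c(16L, 16L))
  prior$patch_scale_px <- c(2, 4)
  tasks <- lapply(1:2, function(i)
    make_task(sample_dataset_config(prior, seed = i), k_support = 6L,
              n_query = 2L, seed = i))
  # identity fine-tuner: every k must reproduce theta's own query metrics
  curve <- kshot_curve(model, list(fixed = theta), tasks, ks = c(1L, 3L, 6L),
                       cfg = meta_config(), finetuner = function(th, lab, held) th)
  direct <- mean(vapply(tasks, function(task) {
    preds <- model_predict(model, theta$tensors, task$query)
    mean(vapply(seq_along(preds), function(i)
      iou((preds[[i]] >= 0.5) * 1L, task$query[[i]]$mask$mask), numeric(1)))
  }, numeric(1)))
  expect_equal(nrow(curve$summary), 3L)                 # one row per k per method
  expect_true(all(curve$summary$iou == curve$summary$iou[1]))
  expect_equal(curve$summary$iou[1], direct)
  expect_true(all(curve$summary$iou >= 0 & curve$summary$iou <= 1))
  expect_true(all(curve$summary$f1 >= 0 & curve$summary$f1 <= 1))
  # k beyond the support size is rejected
  expect_error(kshot_curve(model, list(fixed = theta), tasks, ks = 7L,
                           cfg = meta_config()), "insufficient support")
  # tidy/autoplot surfaces
  td <- tidy(curve)
  expect_equal(nrow(td), 6L)
  expect_s3_class(autoplot(curve), "ggplot")
})
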