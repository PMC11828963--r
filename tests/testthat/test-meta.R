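test_that("segmentation losses match closed forms and brute-force recomputation", {
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  # saturated logits: both losses vanish
  perfect <- ifelse(m == 1, 100, -100)
  expect_lt(segmentation_loss(perfect, m, "bce"), 1e-3)
  expect_lt(segmentation_loss(perfect, m, "dice"), 1e-3)
  # all-zero logits: bce = ln 2 exactly
  expect_equal(segmentation_loss(matrix(0, 8, 8), m, "bce"), log(2))
  # random case vs elementwise recomputation
  set.seed(4)
  z <- matrix(rnorm(64), 8, 8)
  p <- 1 / (1 + exp(-z))
  bce_ref <- mean(-m * log(p) - (1 - m) * log(1 - p))
  expect_equal(segmentation_loss(z, m, "bce"), bce_ref, tolerance = 1e-12)
  dice_ref <- 1 - (2 * sum(p * m) + 1) / (sum(p) + sum(m) + 1)
  expect_equal(segmentation_loss(z, m, "dice"), dice_ref, tolerance = 1e-12)
  expect_equal(segmentation_loss(z, m, "bce_plus_dice"), bce_ref + dice_ref,
               tolerance = 1e-12)
})

test_that("inner_adapt follows hand-iterated gradient descent on the toy model", {
  tm <- toy_quadratic_model()
  sup <- list(list(A = matrix(2), c = 3))     # L(w) = (w - 3)^2, grad 2(w-3)
  r1 <- inner_adapt(tm, list(w = 0), sup, meta_config(inner_lr = 0.1, inner_steps = 1L))
  expect_equal(unname(r1$phi$w), 0.6)
  r2 <- inner_adapt(tm, list(w = 0), sup, meta_config(inner_lr = 0.1, inner_steps = 2L))
  expect_equal(unname(r2$phi$w), 1.08)
  expect_length(r2$support_loss_trace, 3L)    # pre-adaptation + one per step
  expect_equal(r2$support_loss_trace[1], 9)   # (0-3)^2
  # inner_steps = 0: adaptation is the identity
  r0 <- inner_adapt(tm, list(w = 0.4), sup, meta_config(inner_steps = 0L))
  expect_identical(r0$phi, list(w = 0.4))
  expect_length(r0$support_loss_trace, 1L)
})

test_that("meta_step with no inner steps collapses to a plain gradient step", {
  tm <- toy_quadratic_model()
  tasks <- lapply(1:3, function(s) toy_task(2L, s))
  th0 <- list(w = c(0.5, -1))
  cfg2 <- meta_config(inner_steps = 0L, outer_lr = 0.3, second_order = TRUE)
  cfg1 <- meta_config(inner_steps = 0L, outer_lr = 0.3, second_order = FALSE)
  s2 <- meta_step(tm, th0, tasks, cfg2)
  s1 <- meta_step(tm, th0, tasks, cfg1)
  expect_identical(s2$w, s1$w)   # bitwise: first- and second-order coincide
  # plain step on the mean query loss, accumulated the same way
  acc <- NULL
  for (task in tasks) {
    g <- model_loss_grad(tm, th0, task$query)$grads
    acc <- if (is.null(acc)) g else Map(`+`, acc, g)
  }
  plain <- th0$w - 0.3 * (acc$w / length(tasks))
  expect_identical(s2$w, plain)
  # inner_lr = 0 is the same as inner_steps = 0
  cfg0 <- meta_config(inner_lr = 0, inner_steps = 4L, outer_lr = 0.3, second_order = TRUE)
  expect_equal(meta_step(tm, th0, tasks, cfg0)$w, s2$w, tolerance = 1e-12)
})

test_that("second-order meta-gradients match central finite differences", {
  tm <- toy_quadratic_model()
  tasks <- lapply(1:3, function(s) toy_task(3L, 10L + s))
  cfg <- meta_config(inner_lr = 0.07, inner_steps = 3L, outer_lr = 1, second_order = TRUE)
  w0 <- c(0.3, -0.2, 0.8)
  stepped <- meta_step(tm, list(w = w0), tasks, cfg)
  mg <- (w0 - stepped$w) / cfg$outer_lr
  eps <- 1e-6
  fd <- vapply(seq_along(w0), function(i) {
    e <- numeric(3); e[i] <- eps
    (toy_meta_objective(tm, w0 + e, tasks, cfg) -
       toy_meta_objective(tm, w0 - e, tasks, cfg)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(mg - fd) / pmax(abs(fd), 1e-12)), 1e-5)
})

test_that("FOMAML differs from full MAML once adaptation actually happens", {
  tm <- toy_quadratic_model()
  tasks <- lapply(1:2, function(s) toy_task(2L, 20L + s))
  th0 <- list(w = c(0.3, -0.2))
  cfg2 <- meta_config(inner_lr = 0.1, inner_steps = 2L, outer_lr = 1, second_order = TRUE)
  cfg1 <- meta_config(inner_lr = 0.1, inner_steps = 2L, outer_lr = 1, second_order = FALSE)
  expect_gt(max(abs(meta_step(tm, th0, tasks, cfg2)$w -
                    meta_step(tm, th0, tasks, cfg1)$w)), 1e-8)
})

test_that("train_supervised and inner_adapt trace identical trajectories", {
  cfg <- tiny_backbone()
  model <- fpn_model(cfg)
  theta0 <- build_model(cfg, 5L)
  data <- lapply(1:2, function(s) tiny_pair(s))
  mcfg <- meta_config(inner_lr = 0.05, inner_steps = 3L)
  via_inner <- inner_adapt(model, theta0, data, mcfg)$phi
  via_supervised <- train_supervised(model, theta0, data, epochs = 3L, lr = 0.05)
  expect_identical(via_inner$tensors, via_supervised$tensors)
  # epochs = 0 leaves parameters untouched
  expect_identical(train_supervised(model, theta0, data, 0L, 0.05)$tensors,
                   theta0$tensors)
})

test_that("full-batch descent decreases the loss on a fixed dataset", {
  cfg <- tiny_backbone()
  model <- fpn_model(cfg)
  theta0 <- build_model(cfg, 8L)
  data <- lapply(1:2, function(s) tiny_pair(100L + s))
  trained <- train_supervised(model, theta0, data, epochs = 6L, lr = 0.05)
  log <- attr(trained, "log")
  expect_true(all(diff(log$loss) <= 1e-8))
})

test_that("meta_train is deterministic and a no-op at zero iterations", {
  cfg <- tiny_backbone()
  model <- fpn_model(cfg)
  theta0 <- build_model(cfg, 2L)
  prior <- synthetic_prior(image_size = c(16L, 16L))
  prior$patch_scale_px <- c(2, 4)
  sampler <- synthetic_task_sampler(prior, k_support = 2L, n_query = 2L)
  mcfg0 <- meta_config(meta_iterations = 0L, seed = 3L)
  expect_identical(meta_train(model, theta0, sampler, mcfg0)$tensors, theta0$tensors)
  mcfg <- meta_config(inner_lr = 0.05, inner_steps = 1L, outer_lr = 0.05,
                      meta_batch_tasks = 2L, meta_iterations = 3L,
                      second_order = FALSE, seed = 3L)
  a <- meta_train(model, theta0, sampler, mcfg)
  b <- meta_train(model, theta0, sampler, mcfg)
  expect_identical(a$tensors, b$tensors)
  expect_equal(nrow(attr(a, "log")), 3L)
})

test_that("k-shot fine-tuning selects the best held-out epoch, earliest on ties", {
  expect_equal(select_best_epoch(c(0.2, 0.6, 0.5)), 2L)
  expect_equal(select_best_epoch(c(0.2, 0.6, 0.6)), 2L)
  cfg <- tiny_backbone()
  model <- fpn_model(cfg)
  theta0 <- build_model(cfg, 4L)
  labeled <- list(tiny_pair(1L))
  heldout <- list(tiny_pair(2L))
  mcfg <- meta_config(inner_lr = 0.05)
  expect_error(finetune_kshot(model, theta0, rep(labeled, 11L), heldout, mcfg),
               "1 to 10")
  expect_error(finetune_kshot(model, theta0, list(), heldout, mcfg), "1 to 10")
  phi <- finetune_kshot(model, theta0, labeled, heldout, mcfg, epochs = 4L)
  trace <- attr(phi, "iou_trace")
  expect_length(trace, 5L)
  # no-harm: the selected snapshot is at least as good as the unadapted start
  expect_gte(max(trace), trace[1])
  expect_equal(attr(phi, "best_epoch"), select_best_epoch(trace) - 1L)
  expect_warning(finetune_kshot(model, theta0, labeled, list(), mcfg, epochs = 2L),
                 "held-out")
})

test_that("non-finite losses abort with diagnostics instead of propagating NaN", {
  tm <- toy_quadratic_model()
  sup <- list(list(A = matrix(1e300), c = 1e300))
  expect_error(inner_adapt(tm, list(w = 0), sup, meta_config(inner_steps = 1L)),
               "non-finite")
})
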