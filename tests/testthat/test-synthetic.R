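test_that("dataset configs are reproducible and honor degenerate priors", {
  expect_identical(sample_dataset_config(seed = 5L), sample_dataset_config(seed = 5L))
  prior <- synthetic_prior()
  prior$noise_sd <- c(0.07, 0.07)
  prior$ice_fraction_target <- c(0.04, 0.04)
  prior$n_phases <- c(1L, 1L)
  prior$phases <- "cubic"
  cfg <- sample_dataset_config(prior, seed = 3L)
  expect_equal(cfg$noise_sd, 0.07)
  expect_equal(cfg$ice_fraction_target, 0.04)
  expect_identical(cfg$phases[[1]]$phase, "cubic")
  prior$phases <- character(0)
  expect_error(sample_dataset_config(prior, seed = 3L), "phase prior")
})

test_that("sampled ice fractions average to the prior midpoint (law of large numbers)", {
  draws <- vapply(seq_len(1000), function(s)
    sample_dataset_config(seed = s)$ice_fraction_target, numeric(1))
  expect_lt(abs(mean(draws) - 0.06), 0.005)
})

test_that("rendering is deterministic and ice fraction lands in the rejection band", {
  cfg <- sample_dataset_config(seed = 42L)
  r1 <- render_micrograph(cfg, image_seed = 7L)
  r2 <- render_micrograph(cfg, image_seed = 7L)
  expect_identical(r1$micrograph$image, r2$micrograph$image)
  expect_identical(r1$mask$mask, r2$mask$mask)
  expect_true(all(is.finite(r1$micrograph$image)))

  prior <- synthetic_prior()
  prior$ice_fraction_target <- c(0.10, 0.10)
  for (s in 1:4) {
    cfg <- sample_dataset_config(prior, seed = s)
    frac <- mean(render_micrograph(cfg, image_seed = s)$mask$mask)
    expect_gte(frac, 0.05)
    expect_lte(frac, 0.20)
  }
})

test_that("a zero ice-fraction target yields an exactly empty mask", {
  prior <- synthetic_prior()
  prior$ice_fraction_target <- c(0, 0)
  cfg <- sample_dataset_config(prior, seed = 1L)
  r <- render_micrograph(cfg, image_seed = 3L)
  expect_true(all(r$mask$mask == 0L))
})

test_that("crystalline texture carries more gradient energy than background", {
  grad_energy <- function(img) {
    gx <- img[, -1] - img[, -ncol(img)]
    gy <- img[-1, ] - img[-nrow(img), ]
    e <- matrix(0, nrow(img), ncol(img))
    e[, -1] <- e[, -1] + gx^2
    e[-1, ] <- e[-1, ] + gy^2
    e
  }
  for (s in 1:5) {
    cfg <- sample_dataset_config(seed = s)   # default prior has contrast >= 1
    r <- render_micrograph(cfg, image_seed = s)
    m <- r$mask$mask > 0
    e <- grad_energy(r$micrograph$image)
    expect_gt(mean(e[m]) / mean(e[!m]), 2)
  }
})

test_that("domain shift across configs exceeds within-config variability (KS)", {
  prior_a <- synthetic_prior()
  prior_a$contrast <- c(1.0, 1.3)
  prior_a$noise_sd <- c(0.02, 0.05)
  prior_a$ice_fraction_target <- c(0.02, 0.04)
  prior_a$background_smoothness_px <- c(4, 6)
  prior_b <- synthetic_prior()
  prior_b$contrast <- c(2.2, 2.5)
  prior_b$noise_sd <- c(0.30, 0.40)
  prior_b$ice_fraction_target <- c(0.08, 0.10)
  prior_b$background_smoothness_px <- c(12, 16)
  ks_stat <- function(x, y) suppressWarnings(stats::ks.test(x, y)$statistic)
  wins <- 0L
  for (s in 1:10) {
    ca <- sample_dataset_config(prior_a, seed = s)
    cb <- sample_dataset_config(prior_b, seed = 1000L + s)
    across <- ks_stat(as.vector(render_micrograph(ca, 1L)$micrograph$image),
                      as.vector(render_micrograph(cb, 1L)$micrograph$image))
    within <- ks_stat(as.vector(render_micrograph(ca, 2L)$micrograph$image),
                      as.vector(render_micrograph(ca, 3L)$micrograph$image))
    if (across > within) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("tasks have disjoint support/query with shared provenance and bounded k", {
  cfg <- sample_dataset_config(seed = 8L)
  task <- make_task(cfg, k_support = 1L, n_query = 2L, seed = 4L)
  expect_length(task$support, 1L)
  expect_length(task$query, 2L)
  expect_identical(task$dataset_id, cfg$dataset_id)
  all_pairs <- c(task$support, task$query)
  ids <- vapply(all_pairs, function(p)
    paste(p$micrograph$lamella_id, p$micrograph$series_id, p$micrograph$tilt_index),
    character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(vapply(all_pairs, function(p) p$micrograph$source_id, character(1))
                  == cfg$dataset_id))
  expect_silent(task10 <- make_task(cfg, 10L, 1L, seed = 1L))
  expect_error(make_task(cfg, 11L, 1L, seed = 1L), "1 and 10")
  expect_error(make_task(cfg, 0L, 1L, seed = 1L), "1 and 10")
})

test_that("make_task is a pure function of (config, seed)", {
  cfg <- sample_dataset_config(seed = 15L)
  t1 <- make_task(cfg, 2L, 2L, seed = 99L)
  t2 <- make_task(cfg, 2L, 2L, seed = 99L)
  expect_identical(t1$support[[1]]$micrograph$image, t2$support[[1]]$micrograph$image)
  expect_identical(t1$query[[2]]$mask$mask, t2$query[[2]]$mask$mask)
})
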