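# Synthetic crystalline-ice micrograph generator.
#
# A synthetic "dataset" plays the role of one acquisition: all images drawn
# from the same SyntheticDatasetConfig share rendering parameters (microscope
# configuration, sample content and preparation stay fixed within a dataset),
# while different configs drawn from the prior realize the domain shift the
# meta-learner must overcome. Crystalline ice is emulated at the level a
# segmentation network sees it: bright, high-frequency, anisotropic texture
# patches over a smooth cellular background -- hexagonal ice as three
# sinusoidal carriers 60 degrees apart, cubic ice as a single carrier, and
# stacking-disordered ice as a mixture of 2-3 random orientations. Dark round
# contamination blobs and bright-rimmed bubbles are rendered as distractors
# and never enter the positive mask.

#' Rendering parameters of one crystalline-ice phase
#'
#' @param phase `"hexagonal"`, `"cubic"` or `"stacking_disordered"`
#' @param carrier_freq spatial frequency of the texture carrier in
#'   cycles/pixel, in (0, 0.5) (below Nyquist)
#' @param orientation_deg base orientation of the carrier(s), degrees
#' @param contrast positive amplitude multiplier of the texture
#' @param patch_scale_px characteristic patch radius in pixels
#' @export
ice_phase_params <- function(phase = c("hexagonal", "cubic", "stacking_disordered"),
                             carrier_freq = 0.2, orientation_deg = 0,
                             contrast = 1.5, patch_scale_px = 8) {
  phase <- match.arg(phase)
  stopifnot(carrier_freq > 0, carrier_freq < 0.5, contrast > 0, patch_scale_px > 0)
  structure(list(phase = phase, carrier_freq = carrier_freq,
                 orientation_deg = orientation_deg, contrast = contrast,
                 patch_scale_px = patch_scale_px),
            class = "ice_phase_params")
}

#' Default prior over synthetic dataset configurations
#'
#' Intervals are uniform sampling bounds; the phase set is drawn by subset
#' sampling from `phases`. The ice-fraction band reflects realistic class
#' imbalance for vitrification screening (a few percent of the field of view).
#' @param image_size image dimensions (rows, cols); fixed, not sampled
#' @export
synthetic_prior <- function(image_size = c(64L, 64L)) {
  list(
    image_size = as.integer(image_size),
    background_smoothness_px = c(4, 16),
    noise_sd = c(0.05, 0.15),
    ice_fraction_target = c(0.02, 0.10),
    carrier_freq = c(0.12, 0.35),
    orientation_deg = c(0, 180),
    contrast = c(1.0, 2.5),
    patch_scale_px = c(5, 12),
    artifact_rate = c(0, 0.5),
    n_phases = c(1L, 3L),
    phases = c("hexagonal", "cubic", "stacking_disordered")
  )
}

runif1 <- function(bounds) stats::runif(1, bounds[1], bounds[2])

#' Periodic Gaussian blur via the FFT (handles sigma comparable to the image)
#' @noRd
gauss_blur_fft <- function(x, sigma) {
  d <- dim(x)
  fy <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) / d[1]
  fx <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1)) / d[2]
  H <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / length(x)
}

#' Draw one synthetic dataset configuration from a prior
#'
#' Each field is drawn independently from its interval; the phase set by
#' subset sampling. Fully reproducible from `seed`.
#' @param prior a [synthetic_prior()]-shaped list of bounds
#' @param seed integer seed
#' @return a `synthetic_dataset_config`
#' @export
sample_dataset_config <- function(prior = synthetic_prior(), seed = 1L) {
  if (length(prior$phases) < 1L) stop("phase prior must be non-empty", call. = FALSE)
  local_seed(seed, {
    n_ph <- if (diff(range(prior$n_phases)) == 0) prior$n_phases[1] else {
      sample(seq(prior$n_phases[1], prior$n_phases[2]), 1L)
    }
    n_ph <- min(n_ph, length(prior$phases))
    chosen <- if (length(prior$phases) == 1L) prior$phases else sample(prior$phases, n_ph)
    phases <- lapply(chosen, function(p) {
      ice_phase_params(phase = p,
                       carrier_freq = runif1(prior$carrier_freq),
                       orientation_deg = runif1(prior$orientation_deg),
                       contrast = runif1(prior$contrast),
                       patch_scale_px = runif1(prior$patch_scale_px))
    })
    structure(list(
      dataset_id = sprintf("synth-%09d", as.integer(seed)),
      image_size = prior$image_size,
      background_smoothness_px = runif1(prior$background_smoothness_px),
      noise_sd = runif1(prior$noise_sd),
      ice_fraction_target = runif1(prior$ice_fraction_target),
      phases = phases,
      artifact_rate = runif1(prior$artifact_rate),
      seed = as.integer(seed)
    ), class = "synthetic_dataset_config")
  })
}

ellipse_support <- function(H, W, cy, cx, a, b, theta) {
  r <- matrix(seq_len(H) - 1, H, W) - cy
  cl <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  u <- cl * cos(theta) + r * sin(theta)
  v <- -cl * sin(theta) + r * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

carrier_texture <- function(H, W, freq, theta_deg) {
  r <- matrix(seq_len(H) - 1, H, W)
  cl <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  th <- theta_deg * pi / 180
  phase <- stats::runif(1, 0, 2 * pi)
  sin(2 * pi * freq * (cl * cos(th) + r * sin(th)) + phase)
}

phase_texture <- function(H, W, pp) {
  angles <- switch(pp$phase,
                   cubic = pp$orientation_deg,
                   hexagonal = pp$orientation_deg + c(0, 60, 120),
                   stacking_disordered = pp$orientation_deg +
                     stats::runif(sample(2:3, 1L), 0, 180))
  tex <- 0
  for (a in angles) tex <- tex + carrier_texture(H, W, pp$carrier_freq, a)
  tex / length(angles)
}

#' Render one synthetic micrograph / ground-truth mask pair
#'
#' Deterministic in `(cfg, image_seed)`. Crystalline patches are elliptical
#' supports filled with oriented sinusoidal carriers and added at the phase's
#' contrast; the mask is the union of patch supports, grown by rejection until
#' its foreground fraction lies in `[0.5, 2] x ice_fraction_target` (exactly
#' empty when the target is 0). Contamination discs and bubble artifacts may
#' be added to the image but never to the mask (overlap with the mask is
#' capped at 10% of the artifact area).
#'
#' @param cfg a [sample_dataset_config()] result
#' @param image_seed per-image seed
#' @return list(micrograph = [micrograph()], mask = [seg_mask()])
#' @export
render_micrograph <- function(cfg, image_seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_dataset_config"))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  local_seed(seed_combine(cfg$seed, image_seed), {
    bgz <- matrix(stats::rnorm(H * W), H, W)
    bg <- gauss_blur_fft(bgz, cfg$background_smoothness_px)
    sbg <- stats::sd(bg)
    if (sbg > 0) bg <- bg / sbg * 0.1
    img <- 0.5 + bg + matrix(stats::rnorm(H * W, sd = cfg$noise_sd), H, W)
    mask <- matrix(FALSE, H, W)
    patches <- list()
    tgt <- cfg$ice_fraction_target
    if (tgt > 0) {
      frac <- 0
      tries <- 0L
      rejects <- 0L
      shrink <- 1
      while (frac < tgt && tries < 400L) {
        tries <- tries + 1L
        pp <- cfg$phases[[sample(length(cfg$phases), 1L)]]
        sc <- pp$patch_scale_px * shrink
        a <- sc * stats::runif(1, 0.7, 1.3)
        b <- sc * stats::runif(1, 0.5, 1.1)
        cy <- stats::runif(1, 0, H - 1)
        cx <- stats::runif(1, 0, W - 1)
        th <- stats::runif(1, 0, pi)
        supp <- ellipse_support(H, W, cy, cx, a, b, th)
        new_frac <- mean(mask | supp)
        if (new_frac > 2 * tgt) {
          rejects <- rejects + 1L
          if (rejects %% 5L == 0L) shrink <- shrink * 0.7
          next
        }
        mask <- mask | supp
        tex <- phase_texture(H, W, pp)
        img[supp] <- img[supp] + 0.6 * pp$contrast * tex[supp]
        patches[[length(patches) + 1L]] <- list(cy = cy, cx = cx, a = a, b = b,
                                                theta = th, phase = pp$phase)
        frac <- new_frac
      }
      if (frac < 0.5 * tgt) {
        stop(sprintf("patch placement failed: achieved fraction %.4f of target %.4f",
                     frac, tgt), call. = FALSE)
      }
    }
    n_art <- stats::rpois(1L, cfg$artifact_rate)
    for (k in seq_len(n_art)) {
      for (try in 1:20) {
        rad <- stats::runif(1, 3, 6)
        cy <- stats::runif(1, 0, H - 1)
        cx <- stats::runif(1, 0, W - 1)
        supp <- ellipse_support(H, W, cy, cx, rad, rad, 0)
        if (sum(supp & mask) <= 0.1 * sum(supp)) {
          if (stats::runif(1) < 0.5) {
            img[supp] <- img[supp] - 0.4          # dark contamination disc
          } else {
            # bright-rimmed bubble: bright ring, slightly dark interior
            core <- ellipse_support(H, W, cy, cx, rad * 0.6, rad * 0.6, 0)
            img[supp & !core] <- img[supp & !core] + 0.5
            img[core & supp] <- img[core & supp] - 0.2
          }
          break
        }
      }
    }
    m <- micrograph(img, source_id = cfg$dataset_id)
    list(micrograph = m,
         mask = seg_mask(matrix(as.integer(mask), H, W), image_ref = cfg$dataset_id),
         patches = patches)
  })
}

#' An episodic task: support and query sets from one dataset
#' @param support,query non-empty, disjoint lists of
#'   `list(micrograph=, mask=)` pairs sharing `dataset_id`
#' @param dataset_id identifier of the originating dataset
#' @export
ice_task <- function(support, query, dataset_id) {
  stopifnot(length(support) >= 1L, length(query) >= 1L)
  structure(list(support = support, query = query, dataset_id = dataset_id),
            class = "ice_task")
}

#' Sample a k-shot task from a synthetic dataset configuration
#'
#' Renders `k_support + n_query` distinct pairs from `cfg` with distinct image
#' seeds and distinct (lamella, series, tilt) identifiers; the first
#' `k_support` form the support set. `k_support` is bounded to `[1, 10]`, the
#' annotation budget the fine-tuning workflow accepts.
#' @param cfg dataset configuration
#' @param k_support support-set size (1..10)
#' @param n_query query-set size (>= 1)
#' @param seed task seed
#' @return an [ice_task()]
#' @export
make_task <- function(cfg, k_support, n_query, seed = 1L) {
  if (k_support < 1L || k_support > 10L) {
    stop("k_support must be between 1 and 10 micrographs", call. = FALSE)
  }
  stopifnot(n_query >= 1L)
  n <- k_support + n_query
  image_seeds <- local_seed(seed_combine(seed, 7919L), sample.int(2147483600L, n))
  pairs <- lapply(seq_len(n), function(i) {
    p <- render_micrograph(cfg, image_seeds[i])
    m <- p$micrograph
    m$lamella_id <- sprintf("lamella-%02d", i)
    m$series_id <- sprintf("ts-%02d", i)
    m$tilt_index <- i - 1L
    list(micrograph = m, mask = p$mask)
  })
  ice_task(pairs[seq_len(k_support)], pairs[(k_support + 1L):n], cfg$dataset_id)
}

#' Task sampler over the synthetic task distribution
#'
#' Returns a function `f(n)` producing `n` fresh i.i.d. tasks, each from a
#' newly drawn dataset configuration. The sampler consumes the caller's RNG
#' stream (seed it via [meta_config()]'s seed in [meta_train()]).
#' @param prior config prior, see [synthetic_prior()]
#' @param k_support,n_query task dimensions
#' @export
synthetic_task_sampler <- function(prior = synthetic_prior(), k_support = 3L,
                                   n_query = 3L) {
  function(n) {
    lapply(seq_len(n), function(i) {
      s <- sample.int(2147483600L, 2L)
      cfg <- sample_dataset_config(prior, seed = s[1])
      make_task(cfg, k_support, n_query, seed = s[2])
    })
  }
}
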