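# The end-user workflow as library calls and a command-line front end:
# simulate -> preprocess -> annotate (CVAT) -> finetune -> infer -> analyze.
# Every stage is a pure function of (inputs, config, seed) so two runs with
# the same configuration produce byte-identical reports.

#' Run inference over a tilt-series stack and quantify non-vitrified area
#'
#' Each micrograph is preprocessed, zero-padded so its sides divide the
#' network stride, segmented, and the logits cropped back to image geometry.
#' Per-image masks, percent values and a [dataset_report()] are returned and,
#' when `out_dir` is given, written there (masks as 0/255 PNG, the report as
#' CSV and JSON).
#'
#' @param model an [fpn_model()] handle
#' @param theta [model_parameters()] for the model
#' @param stack a [tilt_series_stack()] (may be empty)
#' @param threshold binarization threshold in (0, 1)
#' @param target_long_side,clip_sigma preprocessing parameters (see
#'   [preprocess()])
#' @param out_dir optional output directory
#' @param predictor optional override: `function(image_matrix) -> logit
#'   matrix` used in place of the network forward pass (stubbing / custom
#'   segmenters)
#' @return list(report = [dataset_report()], masks = list of [seg_mask()])
#' @export
run_inference <- function(model, theta, stack, threshold = 0.5,
                          target_long_side = 64L, clip_sigma = 3,
                          out_dir = NULL, predictor = NULL) {
  stopifnot(inherits(stack, "tilt_series_stack"))
  f <- 2L^length(model$config$stage_channels)
  tensors <- params_tensors(theta)
  masks <- vector("list", length(stack))
  percents <- numeric(length(stack))
  ids <- character(length(stack))
  for (i in seq_along(stack$micrographs)) {
    m <- preprocess(stack$micrographs[[i]], target_long_side, clip_sigma)
    if (is.null(predictor)) {
      pd <- pad_to_multiple(m$image, f)
      logits <- forward(model_parameters(tensors, model$config), pd$image)
      logits <- logits[seq_len(pd$orig[1]), seq_len(pd$orig[2]), drop = FALSE]
    } else {
      logits <- predictor(m$image)
    }
    ids[i] <- sprintf("%s#%03d", m$source_id, m$tilt_index)
    masks[[i]] <- predict_mask(logits, threshold, image_ref = ids[i])
    percents[i] <- percent_nonvitrified(masks[[i]])
  }
  report <- dataset_report(percents, image_ids = if (length(stack)) ids else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(masks)) {
      write_mask_png(masks[[i]], file.path(out_dir, sprintf("mask_%03d.png", i - 1L)))
    }
    write_report(report, out_dir)
  }
  list(report = report, masks = masks)
}

#' Write a dataset report as deterministic CSV + JSON
#' @param report a [dataset_report()]
#' @param out_dir directory (created if needed)
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out_dir, "report.csv")
  utils::write.csv(tibble::as_tibble(report), csv, row.names = FALSE)
  js <- list(
    n_images = nrow(report),
    mean_percent = attr(report, "mean_percent"),
    ci95_halfwidth = attr(report, "ci95_halfwidth"),
    ci_method = attr(report, "ci_method"),
    formatted = format(report),
    per_image = as.list(stats::setNames(report$percent_nonvitrified,
                                        as.character(report$image)))
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Indices of images passing a crystallization-percentage cutoff
#'
#' @param report a [dataset_report()]
#' @param max_percent pass threshold: images with percent non-vitrified
#'   `<= max_percent` pass
#' @return 1-based integer indices of passing images
#' @export
filter_by_percent <- function(report, max_percent) {
  which(report$percent_nonvitrified <= max_percent)
}

ellipse_polygon <- function(p, n = 24L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- p$a * cos(t); v <- p$b * sin(t)
  cbind(col = p$cx + u * cos(p$theta) - v * sin(p$theta),
        row = p$cy + u * sin(p$theta) + v * cos(p$theta))
}

#' Export a synthetic dataset as MRC stack + CVAT XML + ground-truth PNGs
#'
#' @param cfg a [sample_dataset_config()] result
#' @param n_images number of micrograph/mask pairs to render
#' @param out_dir output directory
#' @param seed base seed for the per-image seeds
#' @return invisibly, the output directory
#' @export
export_synthetic_dataset <- function(cfg, n_images, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  image_seeds <- local_seed(seed_combine(seed, 104729L),
                            sample.int(2147483600L, n_images))
  imgs <- vector("list", n_images)
  annots <- list()
  for (i in seq_len(n_images)) {
    p <- render_micrograph(cfg, image_seeds[i])
    name <- sprintf("image_%03d", i - 1L)
    imgs[[i]] <- p$micrograph$image
    write_mask_png(p$mask, file.path(out_dir, paste0(name, "_gt.png")))
    for (pt in p$patches) {
      annots[[length(annots) + 1L]] <-
        polygon_annotation(ellipse_polygon(pt), label = "crystalline_ice",
                           image_name = name)
    }
  }
  write_mrc_stack(imgs, file.path(out_dir, "stack.mrc"))
  write_cvat_xml(annots, width = cfg$image_size[2], height = cfg$image_size[1],
                 path = file.path(out_dir, "annotations.xml"))
  yaml::write_yaml(list(dataset_id = cfg$dataset_id,
                        image_size = cfg$image_size,
                        n_images = n_images, seed = seed),
                   file.path(out_dir, "dataset.yaml"))
  invisible(out_dir)
}

# --- CLI ------------------------------------------------------------------------

parse_cli_args <- function(args) {
  if (length(args) == 0) stop(cli_usage(), call. = FALSE)
  cmd <- args[1]
  rest <- args[-1]
  opts <- list()
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(rest) || startsWith(rest[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- rest[i + 1L]
      i <- i + 2L
    }
  }
  list(cmd = cmd, opts = opts)
}

cli_usage <- function() {
  paste(
    "usage: cryoice <command> [--options]",
    "commands:",
    "  simulate   --out DIR [--seed N] [--n-images N] [--image-size N]",
    "  preprocess --in STACK --out STACK.mrc [--target-long-side N] [--clip-sigma X]",
    "  meta-train --out CKPT [--iterations N] [--seed N] [--image-size N]",
    "  finetune   --in STACK --annotations XML --out DIR --shots K",
    "             [--checkpoint CKPT] [--epochs N] [--lr X] [--seed N]",
    "  infer      --in STACK --checkpoint CKPT --out DIR [--threshold X]",
    "             [--target-long-side N]",
    "  analyze    --report DIR/report.csv --max-percent X --out CSV",
    sep = "\n")
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}
opt_int <- function(opts, key, default) as.integer(opt_num(opts, key, default))
opt_chr <- function(opts, key, default = NULL) {
  v <- opts[[key]] %||% default
  if (is.null(v)) stop(sprintf("missing required option --%s", gsub("_", "-", key)),
                       call. = FALSE)
  v
}

default_cli_config <- function(image_size = 64L) {
  backbone_config(family = "residual", stage_channels = c(8L, 16L, 32L),
                  blocks_per_stage = c(1L, 1L, 1L), fpn_channels = 16L)
}

persist_effective_config <- function(out_dir, cmd, opts) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(c(list(command = cmd), opts),
                   file.path(out_dir, "run_config.yaml"))
}

#' Command-line entry point
#'
#' Subcommands mirror the workflow: `simulate` (synthetic dataset export),
#' `preprocess`, `meta-train`, `finetune` (k-shot, k in 1..10), `infer`
#' (masks + percent-non-vitrified report) and `analyze` (filter by
#' percentage). Installed as `inst/cli/cryoice.R`; also callable in-process.
#'
#' @param args character vector of command-line arguments
#' @return invisibly, the primary output path of the subcommand
#' @export
cryoice_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  pa <- parse_cli_args(args)
  opts <- pa$opts
  switch(pa$cmd,
    simulate = {
      out <- opt_chr(opts, "out")
      seed <- opt_int(opts, "seed", 1L)
      n <- opt_int(opts, "n_images", 6L)
      sz <- opt_int(opts, "image_size", 64L)
      prior <- synthetic_prior(image_size = c(sz, sz))
      cfg <- sample_dataset_config(prior, seed = seed)
      export_synthetic_dataset(cfg, n, out, seed = seed)
      persist_effective_config(out, "simulate", opts)
      ci_log("simulate", "wrote %d synthetic micrographs to %s", n, out)
      invisible(out)
    },
    preprocess = {
      stack <- load_micrograph_stack(opt_chr(opts, "in"))
      tls <- opt_int(opts, "target_long_side", 64L)
      cs <- opt_num(opts, "clip_sigma", 3)
      pre <- lapply(stack$micrographs, preprocess, target_long_side = tls,
                    clip_sigma = cs)
      out <- opt_chr(opts, "out")
      write_mrc_stack(tilt_series_stack(pre, stack$stack_path), out)
      ci_log("preprocess", "wrote %d preprocessed micrographs to %s", length(pre), out)
      invisible(out)
    },
    `meta-train` = {
      out <- opt_chr(opts, "out")
      sz <- opt_int(opts, "image_size", 64L)
      bc <- default_cli_config(sz)
      model <- fpn_model(bc)
      cfg <- meta_config(inner_lr = opt_num(opts, "inner_lr", 0.05),
                         inner_steps = opt_int(opts, "inner_steps", 2L),
                         outer_lr = opt_num(opts, "outer_lr", 0.02),
                         meta_batch_tasks = opt_int(opts, "meta_batch", 2L),
                         meta_iterations = opt_int(opts, "iterations", 100L),
                         second_order = FALSE,
                         seed = opt_int(opts, "seed", 1L))
      theta0 <- build_model(bc, init_seed = cfg$seed)
      sampler <- synthetic_task_sampler(synthetic_prior(c(sz, sz)),
                                        k_support = 3L, n_query = 3L)
      theta <- meta_train(model, theta0, sampler, cfg)
      save_checkpoint(theta, out)
      ci_log("meta-train", "saved meta-trained checkpoint to %s", out)
      invisible(out)
    },
    finetune = {
      stack <- load_micrograph_stack(opt_chr(opts, "in"))
      k <- opt_int(opts, "shots", NA)
      if (is.na(k) || k < 1L || k > 10L) {
        stop("--shots must be between 1 and 10", call. = FALSE)
      }
      annots <- parse_cvat_xml(opt_chr(opts, "annotations"))
      out <- opt_chr(opts, "out")
      d <- dim(stack$micrographs[[1]]$image)
      by_img <- split(annots, vapply(annots, function(a) a$image_name, character(1)))
      nm <- sprintf("image_%03d", seq_along(stack$micrographs) - 1L)
      pairs <- lapply(seq_along(stack$micrographs), function(i) {
        list(micrograph = stack$micrographs[[i]],
             mask = rasterize(by_img[[nm[i]]] %||% list(), d[1], d[2]))
      })
      ckpt_path <- opts$checkpoint
      theta <- if (!is.null(ckpt_path)) load_checkpoint(ckpt_path) else {
        build_model(default_cli_config(d[1]), init_seed = opt_int(opts, "seed", 1L))
      }
      model <- fpn_model(theta$config)
      mcfg <- meta_config(inner_lr = opt_num(opts, "lr", 0.05),
                          seed = opt_int(opts, "seed", 1L))
      phi <- finetune_kshot(model, theta, pairs[seq_len(k)],
                            pairs[setdiff(seq_along(pairs), seq_len(k))],
                            mcfg, epochs = opt_int(opts, "epochs", 10L),
                            lr = opt_num(opts, "lr", 0.05))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(phi, file.path(out, "finetuned.ckpt"))
      trace <- attr(phi, "iou_trace")
      if (!is.null(trace)) {
        utils::write.csv(tibble::tibble(epoch = seq_along(trace) - 1L, iou = trace),
                         file.path(out, "finetune_log.csv"), row.names = FALSE)
      }
      persist_effective_config(out, "finetune", opts)
      ci_log("finetune", "best epoch %s, checkpoint in %s",
             format(attr(phi, "best_epoch")), out)
      invisible(out)
    },
    infer = {
      stack <- load_micrograph_stack(opt_chr(opts, "in"))
      theta <- load_checkpoint(opt_chr(opts, "checkpoint"))
      out <- opt_chr(opts, "out")
      model <- fpn_model(theta$config)
      res <- run_inference(model, theta, stack,
                           threshold = opt_num(opts, "threshold", 0.5),
                           target_long_side = opt_int(opts, "target_long_side", 64L),
                           out_dir = out)
      persist_effective_config(out, "infer", opts)
      ci_log("infer", "%d image(s), non-vitrified area %s",
             nrow(res$report), format(res$report))
      invisible(out)
    },
    analyze = {
      rep_csv <- utils::read.csv(opt_chr(opts, "report"))
      maxp <- opt_num(opts, "max_percent", 100)
      pass <- which(rep_csv$percent_nonvitrified <= maxp)
      out <- opt_chr(opts, "out")
      utils::write.csv(
        data.frame(index = pass,
                   image = rep_csv$image[pass],
                   percent_nonvitrified = rep_csv$percent_nonvitrified[pass]),
        out, row.names = FALSE)
      ci_log("analyze", "%d of %d image(s) pass at <= %.2f%%",
             length(pass), nrow(rep_csv), maxp)
      invisible(out)
    },
    stop(cli_usage(), call. = FALSE)
  )
}
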