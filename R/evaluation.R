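# Segmentation metrics, percent-non-vitrified quantification with confidence
# intervals, and k-shot evaluation curves comparing adaptation strategies.

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop(sprintf("mask shapes differ: (%s) vs (%s)",
                 paste(dim(a), collapse = ","), paste(dim(b), collapse = ",")),
         call. = FALSE)
  }
}

#' Intersection over Union of two binary masks
#'
#' Convention: two empty masks score 1 (a clean lamella predicted clean is a
#' success).
#' @param pred,gt [seg_mask()] objects or 0/1 matrices of equal shape
#' @return IoU in \[0, 1\]
#' @export
iou <- function(pred, gt) {
  p <- as_mask_matrix(pred); g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  uni <- sum(p | g)
  if (uni == 0) return(1)
  sum(p & g) / uni
}

#' F1 (Dice) score of two binary masks
#'
#' `2|pred & gt| / (|pred| + |gt|)`; both-empty scores 1. Satisfies
#' `f1 = 2 iou / (1 + iou)` exactly.
#' @inheritParams iou
#' @export
f1 <- function(pred, gt) {
  p <- as_mask_matrix(pred); g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

#' Percent of non-vitrified (crystalline) area in a mask
#'
#' The tool's headline quantity: `100 * foreground / total` pixels.
#' @param mask a [seg_mask()] or 0/1 matrix
#' @return percentage in \[0, 100\]
#' @export
percent_nonvitrified <- function(mask) {
  m <- as_mask_matrix(mask)
  100 * sum(m) / length(m)
}

#' Mean and normal-approximation confidence half-width
#'
#' `mean +/- z_(1+level)/2 * s / sqrt(n)` with sample standard deviation `s`;
#' the unit of replication is the micrograph (per-image percentages), matching
#' how dataset-level ice percentages are reported.
#' @param values numeric vector, length >= 2
#' @param level confidence level (default 0.95, z = 1.959964)
#' @return named vector `c(mean =, halfwidth =)`
#' @export
aggregate_ci <- function(values, level = 0.95) {
  if (length(values) < 2L) {
    stop("aggregate_ci needs at least 2 values (halfwidth undefined for n < 2)",
         call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  c(mean = mean(values), halfwidth = z * stats::sd(values) / sqrt(length(values)))
}

#' Per-dataset quantification report
#'
#' @param per_image_percent per-micrograph percent non-vitrified values
#' @param level confidence level for the mean's interval
#' @param image_ids optional identifiers (defaults to the index)
#' @return a `dataset_report`: tibble of per-image rows plus `mean_percent`,
#'   `ci95_halfwidth` and `ci_method` attributes
#' @export
dataset_report <- function(per_image_percent, level = 0.95, image_ids = NULL) {
  stopifnot(all(per_image_percent >= 0 & per_image_percent <= 100))
  n <- length(per_image_percent)
  tb <- tibble::tibble(
    image = image_ids %||% (if (n) seq_len(n) else integer(0)),
    percent_nonvitrified = as.numeric(per_image_percent)
  )
  ci <- if (n >= 2L) aggregate_ci(per_image_percent, level) else {
    c(mean = if (n == 1L) per_image_percent else NA_real_, halfwidth = NA_real_)
  }
  structure(tb, class = c("dataset_report", class(tb)),
            mean_percent = unname(ci["mean"]),
            ci95_halfwidth = unname(ci["halfwidth"]),
            ci_level = level,
            ci_method = "normal approximation, per-image replication")
}

#' @export
format.dataset_report <- function(x, ...) {
  m <- attr(x, "mean_percent"); hw <- attr(x, "ci95_halfwidth")
  if (is.na(m)) return("empty report")
  if (is.na(hw)) return(sprintf("%.2f%% (single image)", m))
  sprintf("%.2f%% ± %.2f%%", m, hw)
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(sprintf("Non-vitrified area over %d micrograph(s): %s\n", nrow(x), format(x)))
  if (nrow(x)) print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.dataset_report <- function(x, ...) {
  tibble::tibble(n_images = nrow(x),
                 mean_percent = attr(x, "mean_percent"),
                 ci95_halfwidth = attr(x, "ci95_halfwidth"),
                 ci_level = attr(x, "ci_level"))
}

# --- k-shot curves -------------------------------------------------------------

#' k-shot adaptation curves for several initializations
#'
#' For every method (named entry of `thetas`, e.g. `maml`, `baseline`,
#' `random`) and every `k` in `ks`, fine-tunes on the first `k` support pairs
#' of each task (supports are nested across k so curves are comparable) and
#' evaluates mean IoU/F1 on the task's query set.
#'
#' @param model model handle
#' @param thetas named list of parameter sets, one per method
#' @param tasks evaluation tasks ([ice_task()]); each support must hold at
#'   least `max(ks)` pairs
#' @param ks increasing integer vector within 1..10
#' @param cfg a [meta_config()] (fine-tuning rate)
#' @param epochs fine-tuning epochs per (task, k)
#' @param threshold binarization threshold
#' @param finetuner optional override `function(theta, labeled, heldout)`
#'   returning adapted parameters (used for stubbing in tests)
#' @return a `kshot_curve` object; see [tidy.kshot_curve()]
#' @export
kshot_curve <- function(model, thetas, tasks, ks, cfg, epochs = 10L,
                        threshold = 0.5, finetuner = NULL) {
  stopifnot(length(tasks) >= 1L, all(ks >= 1L), all(ks <= 10L))
  ks <- sort(unique(as.integer(ks)))
  min_support <- min(vapply(tasks, function(t) length(t$support), integer(1)))
  if (max(ks) > min_support) {
    stop(sprintf("insufficient support: max k = %d but smallest support set has %d pairs",
                 max(ks), min_support), call. = FALSE)
  }
  if (is.null(finetuner)) {
    finetuner <- function(theta, labeled, heldout) {
      finetune_kshot(model, theta, labeled, heldout, cfg, epochs = epochs,
                     threshold = threshold)
    }
  }
  rows <- list()
  per_method <- stats::setNames(vector("list", length(thetas)), names(thetas))
  for (method in names(thetas)) {
    mat <- matrix(NA_real_, length(ks), 2, dimnames = list(NULL, c("iou", "f1")))
    for (ki in seq_along(ks)) {
      k <- ks[ki]
      ious <- f1s <- numeric(length(tasks))
      for (ti in seq_along(tasks)) {
        task <- tasks[[ti]]
        phi <- finetuner(thetas[[method]], task$support[seq_len(k)], task$query)
        preds <- model_predict(model, params_tensors(phi), task$query)
        pm <- lapply(preds, function(p) (p >= threshold) * 1L)
        ious[ti] <- mean(vapply(seq_along(pm), function(i)
          iou(pm[[i]], batch_pair_mask(task$query[[i]])), numeric(1)))
        f1s[ti] <- mean(vapply(seq_along(pm), function(i)
          f1(pm[[i]], batch_pair_mask(task$query[[i]])), numeric(1)))
      }
      mat[ki, ] <- c(mean(ious), mean(f1s))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = method, k = k, iou = mean(ious), f1 = mean(f1s))
    }
    per_method[[method]] <- mat
  }
  structure(list(k_values = ks, per_method = per_method,
                 summary = do.call(rbind, rows)),
            class = "kshot_curve")
}

#' Tidy a k-shot curve into a long tibble
#' @param x a `kshot_curve`
#' @param ... unused
#' @importFrom generics tidy
#' @export
tidy.kshot_curve <- function(x, ...) {
  tb <- x$summary
  tidyr_longer <- function(tb) {
    out <- rbind(
      tibble::tibble(method = tb$method, k = tb$k, metric = "iou", value = tb$iou),
      tibble::tibble(method = tb$method, k = tb$k, metric = "f1", value = tb$f1)
    )
    out[order(out$method, out$k, out$metric), ]
  }
  tidyr_longer(tb)
}

#' @export
print.kshot_curve <- function(x, ...) {
  cat("k-shot adaptation curves\n")
  print(x$summary, ...)
  invisible(x)
}

#' Plot IoU and F1 k-shot panels
#' @param object a `kshot_curve`
#' @param ... unused
#' @importFrom ggplot2 autoplot
#' @export
autoplot.kshot_curve <- function(object, ...) {
  df <- tidy(object)
  df$metric <- toupper(df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = k, y = value, colour = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_continuous(breaks = object$k_values) +
    ggplot2::labs(x = "k (annotated micrographs)", y = "score",
                  colour = "initialization") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
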