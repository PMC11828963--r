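# Trainers: regular gradient descent (pre-training / vanilla transfer
# baseline), MAML bi-level optimization, and k-shot fine-tuning with
# automatic best-model selection.
#
# The exact second-order meta-gradient is computed by reverse-mode
# differentiation through the unrolled inner loop:
#   phi_i = phi_{i-1} - a * g_s(phi_{i-1})
#   d L_q / d theta = prod_i (I - a * H_s(phi_{i-1}))^T  grad_q(phi_n)
# applied right-to-left as a sequence of Hessian-vector products, each
# evaluated by a complex-step directional derivative of the gradient
# (machine-precision, no finite-difference cancellation). With
# second_order = FALSE the products are dropped (FOMAML).

#' Meta-learning configuration
#'
#' @param inner_lr inner-loop (task adaptation) step size
#' @param inner_steps full-batch gradient steps on the support set (>= 0;
#'   0 makes adaptation the identity)
#' @param outer_lr meta (outer) step size, plain SGD
#' @param meta_batch_tasks tasks per meta-step
#' @param meta_iterations number of meta-steps in [meta_train()]
#' @param second_order TRUE: exact MAML meta-gradient; FALSE: first-order
#'   approximation (FOMAML), much cheaper on large networks
#' @param loss segmentation loss: `"bce"`, `"dice"` or `"bce_plus_dice"`
#' @param seed RNG seed governing task sampling
#' @export
meta_config <- function(inner_lr = 0.01, inner_steps = 5L, outer_lr = 1e-3,
                        meta_batch_tasks = 4L, meta_iterations = 0L,
                        second_order = TRUE,
                        loss = c("bce_plus_dice", "bce", "dice"), seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(inner_lr >= 0, inner_steps >= 0L, outer_lr > 0,
            meta_batch_tasks >= 1L, meta_iterations >= 0L)
  structure(list(inner_lr = inner_lr, inner_steps = as.integer(inner_steps),
                 outer_lr = outer_lr, meta_batch_tasks = as.integer(meta_batch_tasks),
                 meta_iterations = as.integer(meta_iterations),
                 second_order = isTRUE(second_order), loss = loss,
                 seed = as.integer(seed)),
            class = "meta_config")
}

# named-tensor-list arithmetic
tl_axpy <- function(a, x, y) Map(function(xi, yi) yi + a * xi, x, y)
tl_add <- function(x, y) Map(`+`, x, y)

check_finite_loss <- function(loss, where) {
  if (!is.finite(Re(loss))) {
    stop(sprintf("non-finite loss (%s) in %s: aborting (check learning rates / inputs)",
                 format(loss), where), call. = FALSE)
  }
}

params_tensors <- function(theta) {
  if (inherits(theta, "model_parameters")) theta$tensors else theta
}

rewrap <- function(theta, tensors) {
  if (inherits(theta, "model_parameters")) model_parameters(tensors, theta$config)
  else tensors
}

#' Segmentation loss between a logit map and a binary mask
#'
#' `"bce"` is mean per-pixel binary cross-entropy with logits; `"dice"` is
#' `1 - (2|soft * gt| + eps) / (|soft| + |gt| + eps)` with `soft =
#' sigmoid(logits)` and `eps = 1`; `"bce_plus_dice"` (default elsewhere) is
#' their sum, robust to the few-percent foreground fractions typical of
#' vitrification screening.
#' @param logits logit matrix
#' @param mask 0/1 matrix or [seg_mask()] of the same shape
#' @param kind loss kind
#' @return non-negative scalar
#' @export
segmentation_loss <- function(logits, mask, kind = c("bce", "dice", "bce_plus_dice")) {
  kind <- match.arg(kind)
  y <- as_mask_matrix(mask)
  stopifnot(all(dim(logits) == dim(y)))
  bce <- function() mean(softplus_c(logits) - logits * y)
  dice <- function() {
    s <- sigmoid_c(logits)
    1 - (2 * sum(s * y) + 1) / (sum(s) + sum(y) + 1)
  }
  switch(kind, bce = bce(), dice = dice(), bce_plus_dice = bce() + dice())
}

#' Adapt parameters to a task's support set (MAML inner loop)
#'
#' Runs `cfg$inner_steps` full-batch gradient steps on the support set from
#' `theta`. The loss trace has length `inner_steps + 1` (entry 1 is the
#' pre-adaptation loss, the last entry the post-adaptation loss).
#'
#' @param model a model handle (e.g. [fpn_model()])
#' @param theta [model_parameters()] (or bare tensor list) to adapt from
#' @param support non-empty list of (micrograph, mask) pairs
#' @param cfg a [meta_config()]
#' @param query optional query pairs; when given, post-adaptation mean
#'   IoU/F1 are reported in `query_metrics`
#' @return `adaptation_result`: list(phi, support_loss_trace, query_metrics)
#' @export
inner_adapt <- function(model, theta, support, cfg, query = NULL) {
  stopifnot(length(support) >= 1L)
  phi <- params_tensors(theta)
  trace <- numeric(cfg$inner_steps + 1L)
  for (s in seq_len(cfg$inner_steps)) {
    lg <- model_loss_grad(model, phi, support)
    check_finite_loss(lg$loss, sprintf("inner_adapt step %d", s))
    trace[s] <- Re(lg$loss)
    phi <- tl_axpy(-cfg$inner_lr, lg$grads, phi)
  }
  final <- model_loss(model, phi, support)
  check_finite_loss(final, "inner_adapt (final)")
  trace[cfg$inner_steps + 1L] <- Re(final)
  qm <- NULL
  if (!is.null(query) && length(query) > 0) {
    preds <- model_predict(model, phi, query)
    ious <- f1s <- numeric(length(query))
    for (i in seq_along(query)) {
      pm <- (preds[[i]] >= 0.5) * 1L
      gt <- batch_pair_mask(query[[i]])
      ious[i] <- iou(pm, gt)
      f1s[i] <- f1(pm, gt)
    }
    qm <- c(iou = mean(ious), f1 = mean(f1s))
  }
  structure(list(phi = rewrap(theta, phi), support_loss_trace = trace,
                 query_metrics = qm),
            class = "adaptation_result")
}

maml_task_gradient <- function(model, theta_t, task, cfg) {
  # unroll the inner loop, keeping the visited iterates
  phis <- vector("list", cfg$inner_steps + 1L)
  phis[[1]] <- theta_t
  for (s in seq_len(cfg$inner_steps)) {
    lg <- model_loss_grad(model, phis[[s]], task$support)
    check_finite_loss(lg$loss, "meta_step inner loop")
    phis[[s + 1L]] <- tl_axpy(-cfg$inner_lr, lg$grads, phis[[s]])
  }
  qg <- model_loss_grad(model, phis[[cfg$inner_steps + 1L]], task$query)
  check_finite_loss(qg$loss, "meta_step query loss")
  g <- qg$grads
  if (cfg$second_order && cfg$inner_steps > 0L && cfg$inner_lr != 0) {
    for (s in seq(cfg$inner_steps, 1L)) {
      hv <- model_hvp(model, phis[[s]], task$support, g)
      g <- tl_axpy(-cfg$inner_lr, hv, g)
    }
  }
  list(grad = g, query_loss = Re(qg$loss))
}

#' One MAML meta-optimization step over a batch of tasks
#'
#' Updates the shared initialization:
#' `theta <- theta - outer_lr * grad_theta mean_tasks L(adapt(theta, support); query)`.
#' With `second_order = TRUE` the gradient is exact (differentiates through
#' the inner loop); otherwise inner gradients are treated as constants
#' (FOMAML). With `inner_steps = 0` both reduce, bitwise, to a plain gradient
#' step on the mean query loss.
#'
#' @param model model handle
#' @param theta current shared parameters
#' @param task_batch non-empty list of [ice_task()]-shaped tasks
#' @param cfg a [meta_config()]
#' @return updated parameters, with attribute `"query_loss"` (mean, pre-update)
#' @export
meta_step <- function(model, theta, task_batch, cfg) {
  stopifnot(length(task_batch) >= 1L)
  theta_t <- params_tensors(theta)
  acc <- NULL
  qloss <- 0
  for (task in task_batch) {
    tg <- maml_task_gradient(model, theta_t, task, cfg)
    acc <- if (is.null(acc)) tg$grad else tl_add(acc, tg$grad)
    qloss <- qloss + tg$query_loss
  }
  g_mean <- lapply(acc, function(g) g / length(task_batch))
  out <- rewrap(theta, tl_axpy(-cfg$outer_lr, g_mean, theta_t))
  attr(out, "query_loss") <- qloss / length(task_batch)
  out
}

#' Meta-train a shared initialization over an episodic task stream
#'
#' Runs `cfg$meta_iterations` calls of [meta_step()] on freshly sampled task
#' batches. Fully reproducible from `cfg$seed`. The per-iteration mean query
#' loss is attached as a tibble in attribute `"log"`.
#'
#' @param model model handle
#' @param theta0 initial parameters
#' @param task_sampler function(n) returning n i.i.d. tasks (e.g.
#'   [synthetic_task_sampler()])
#' @param cfg a [meta_config()]
#' @return meta-trained parameters
#' @export
meta_train <- function(model, theta0, task_sampler, cfg) {
  theta <- theta0
  losses <- numeric(cfg$meta_iterations)
  local_seed(cfg$seed, {
    for (it in seq_len(cfg$meta_iterations)) {
      batch <- task_sampler(cfg$meta_batch_tasks)
      if (length(batch) < 1L) stop("task sampler returned no tasks", call. = FALSE)
      theta <- meta_step(model, theta, batch, cfg)
      losses[it] <- attr(theta, "query_loss")
      if (it %% 25L == 0L) {
        ci_log("meta-train", "iteration %d/%d mean query loss %.4f",
               it, cfg$meta_iterations, mean(losses[max(1, it - 24):it]))
      }
    }
  })
  attr(theta, "log") <- tibble::tibble(iteration = seq_len(cfg$meta_iterations),
                                       query_loss = losses)
  theta
}

#' Supervised training by (mini-)batch gradient descent
#'
#' Regular gradient descent on the segmentation loss: this is both the
#' pre-training path and the vanilla transfer-learning baseline. With the
#' default `batch_size = NULL` each epoch is one full-batch step, so the
#' parameter trajectory coincides exactly with [inner_adapt()] given the same
#' data, learning rate, and step count.
#'
#' @param model model handle
#' @param theta0 initial parameters
#' @param dataset non-empty list of (micrograph, mask) pairs
#' @param epochs number of epochs (0 returns `theta0` unchanged)
#' @param lr learning rate
#' @param batch_size optional mini-batch size; shuffling is seeded
#' @param seed shuffle seed (mini-batch mode only)
#' @return trained parameters with attribute `"log"` (per-epoch loss tibble)
#' @export
train_supervised <- function(model, theta0, dataset, epochs, lr,
                             batch_size = NULL, seed = 1L) {
  stopifnot(length(dataset) >= 1L, epochs >= 0L, lr >= 0)
  theta <- params_tensors(theta0)
  losses <- numeric(epochs)
  run_epoch <- function(theta, order) {
    if (is.null(batch_size)) {
      lg <- model_loss_grad(model, theta, dataset)
      check_finite_loss(lg$loss, "train_supervised")
      list(theta = tl_axpy(-lr, lg$grads, theta), loss = Re(lg$loss))
    } else {
      tot <- 0
      for (start in seq(1L, length(dataset), by = batch_size)) {
        sel <- order[start:min(start + batch_size - 1L, length(dataset))]
        lg <- model_loss_grad(model, theta, dataset[sel])
        check_finite_loss(lg$loss, "train_supervised")
        theta <- tl_axpy(-lr, lg$grads, theta)
        tot <- tot + Re(lg$loss) * length(sel)
      }
      list(theta = theta, loss = tot / length(dataset))
    }
  }
  local_seed(seed, {
    for (e in seq_len(epochs)) {
      ord <- if (is.null(batch_size)) seq_along(dataset) else sample(seq_along(dataset))
      st <- run_epoch(theta, ord)
      theta <- st$theta
      losses[e] <- st$loss
    }
  })
  out <- rewrap(theta0, theta)
  attr(out, "log") <- tibble::tibble(epoch = seq_len(epochs), loss = losses)
  out
}

#' Index of the best epoch: maximal held-out IoU, earliest on ties
#' @param ious numeric vector of per-epoch IoUs (entry 1 may be epoch 0)
#' @export
select_best_epoch <- function(ious) which(ious == max(ious))[1]

#' k-shot fine-tuning with automatic best-model selection
#'
#' Fine-tunes `theta_pretrained` on `k = length(labeled)` annotated pairs
#' (k must lie in 1..10), evaluating mean IoU on `heldout` after every epoch
#' (the un-adapted parameters count as epoch 0), and returns the snapshot
#' with maximal held-out IoU; ties go to the earliest epoch (the less
#' overfit snapshot). An empty held-out set falls back to the final epoch
#' with a warning.
#'
#' @param model model handle
#' @param theta_pretrained starting parameters
#' @param labeled list of k (micrograph, mask) pairs, 1 <= k <= 10
#' @param heldout list of (micrograph, mask) pairs used for model selection
#' @param cfg a [meta_config()] (supplies `inner_lr` as the default rate)
#' @param epochs fine-tuning epochs
#' @param lr learning rate (defaults to `cfg$inner_lr`)
#' @param threshold binarization threshold for the selection IoU
#' @return selected parameters with attributes `"iou_trace"` and `"best_epoch"`
#' @export
finetune_kshot <- function(model, theta_pretrained, labeled, heldout, cfg,
                           epochs = 10L, lr = cfg$inner_lr, threshold = 0.5) {
  k <- length(labeled)
  if (k < 1L || k > 10L) {
    stop("k-shot fine-tuning accepts 1 to 10 labeled micrographs", call. = FALSE)
  }
  eval_iou <- function(tensors) {
    preds <- model_predict(model, tensors, heldout)
    mean(vapply(seq_along(heldout), function(i) {
      iou((preds[[i]] >= threshold) * 1L, batch_pair_mask(heldout[[i]]))
    }, numeric(1)))
  }
  theta <- params_tensors(theta_pretrained)
  if (length(heldout) == 0L) {
    warning("empty held-out set: returning the final epoch without model selection",
            call. = FALSE)
    for (e in seq_len(epochs)) {
      lg <- model_loss_grad(model, theta, labeled)
      check_finite_loss(lg$loss, "finetune_kshot")
      theta <- tl_axpy(-lr, lg$grads, theta)
    }
    out <- rewrap(theta_pretrained, theta)
    attr(out, "best_epoch") <- epochs
    return(out)
  }
  ious <- numeric(epochs + 1L)
  ious[1] <- eval_iou(theta)
  best <- theta
  for (e in seq_len(epochs)) {
    lg <- model_loss_grad(model, theta, labeled)
    check_finite_loss(lg$loss, "finetune_kshot")
    theta <- tl_axpy(-lr, lg$grads, theta)
    ious[e + 1L] <- eval_iou(theta)
    if (ious[e + 1L] > max(ious[seq_len(e)])) best <- theta
  }
  out <- rewrap(theta_pretrained, best)
  attr(out, "iou_trace") <- ious
  attr(out, "best_epoch") <- select_best_epoch(ious) - 1L
  out
}

# --- toy model ----------------------------------------------------------------

#' Minimal quadratic-loss model for validating the trainers
#'
#' A didactic model with loss `L(w; batch) = 0.5 * (w - c)' A (w - c)` for a
#' task-specific center `c` and positive-definite `A`. Batches are lists of
#' `list(A =, c =)` terms, averaged. Its gradient is linear in `w`, so
#' meta-gradients have a closed form, making it the reference instrument for
#' checking MAML's second-order machinery against finite differences.
#' @export
toy_quadratic_model <- function() {
  structure(list(), class = c("toy_quadratic_model", "cryoice_model"))
}

#' @export
model_loss_grad.toy_quadratic_model <- function(model, tensors, batch) {
  w <- tensors$w
  loss <- 0
  grad <- 0 * w
  for (term in batch) {
    d <- w - term$c
    Ad <- as.vector(term$A %*% d)
    loss <- loss + 0.5 * sum(d * Ad)
    grad <- grad + Ad
  }
  n <- length(batch)
  list(loss = loss / n, grads = list(w = grad / n))
}

#' @export
model_predict.toy_quadratic_model <- function(model, tensors, batch) {
  lapply(batch, function(term) tensors$w)
}
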