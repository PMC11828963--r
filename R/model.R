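# Feature Pyramid Network segmentation model with residual or densely
# connected encoder stages.
#
# The forward pass is *functional*: all weights live in a flat named list and
# are passed in on every call. Nothing is mutated, so task-adapted parameter
# sets phi can be evaluated alongside the shared initialization theta --
# the property MAML's inner loop depends on.

#' Backbone / FPN configuration
#'
#' @param family `"residual"` (identity skip, `y = F(x) + x`) or `"dense"`
#'   (each layer concatenates all preceding feature maps).
#' @param stage_channels integer vector, output channels of each encoder
#'   stage, coarsest last; length >= 3 so the pyramid has at least 3 levels.
#'   Each stage downsamples by 2 (strided 3x3 conv), so valid inputs have
#'   sides divisible by `2^length(stage_channels)`.
#' @param blocks_per_stage integer vector, same length: residual blocks (or
#'   dense layers) per stage.
#' @param growth_rate channels added by each dense layer; required iff
#'   `family = "dense"`.
#' @param fpn_channels channels of the pyramid (lateral 1x1 outputs and
#'   top-down maps).
#' @param out_classes number of logit channels (1: crystalline vs vitreous).
#' @return a `backbone_config` object.
#' @export
backbone_config <- function(family = c("residual", "dense"),
                            stage_channels = c(8L, 16L, 32L),
                            blocks_per_stage = rep(1L, length(stage_channels)),
                            growth_rate = NULL,
                            fpn_channels = 16L,
                            out_classes = 1L) {
  family <- match.arg(family)
  stage_channels <- as.integer(stage_channels)
  blocks_per_stage <- as.integer(blocks_per_stage)
  if (length(stage_channels) != length(blocks_per_stage)) {
    stop("stage_channels and blocks_per_stage must have equal length", call. = FALSE)
  }
  if (length(stage_channels) < 3L) {
    stop("an FPN needs at least 3 encoder stages", call. = FALSE)
  }
  if (any(stage_channels <= 0L) || any(blocks_per_stage <= 0L)) {
    stop("stage_channels and blocks_per_stage must be positive", call. = FALSE)
  }
  if (family == "dense" && is.null(growth_rate)) {
    stop("dense family requires growth_rate", call. = FALSE)
  }
  if (!is.null(growth_rate)) growth_rate <- as.integer(growth_rate)
  structure(list(family = family, stage_channels = stage_channels,
                 blocks_per_stage = blocks_per_stage, growth_rate = growth_rate,
                 fpn_channels = as.integer(fpn_channels),
                 out_classes = as.integer(out_classes)),
            class = "backbone_config")
}

gn_groups <- function(C) {
  for (g in c(8L, 4L, 2L)) if (C %% g == 0L) return(g)
  1L
}

#' Shapes of every tensor implied by a config (structural contract)
#' @noRd
param_shapes <- function(cfg) {
  sh <- list()
  conv <- function(name, k, cin, cout) {
    sh[[paste0(name, ".w")]] <<- c(k, k, cin, cout)
    sh[[paste0(name, ".b")]] <<- cout
  }
  gn <- function(name, c) {
    sh[[paste0(name, ".g")]] <<- c
    sh[[paste0(name, ".bt")]] <<- c
  }
  S <- length(cfg$stage_channels)
  cin <- 1L
  for (s in seq_len(S)) {
    cs <- cfg$stage_channels[s]
    conv(sprintf("s%d.down", s), 3L, cin, cs)
    gn(sprintf("s%d.down.gn", s), cs)
    if (cfg$family == "residual") {
      for (b in seq_len(cfg$blocks_per_stage[s])) {
        p <- sprintf("s%d.b%d", s, b)
        conv(paste0(p, ".c1"), 3L, cs, cs); gn(paste0(p, ".gn1"), cs)
        conv(paste0(p, ".c2"), 3L, cs, cs); gn(paste0(p, ".gn2"), cs)
      }
    } else {
      cacc <- cs
      for (l in seq_len(cfg$blocks_per_stage[s])) {
        p <- sprintf("s%d.l%d", s, l)
        conv(paste0(p, ".c"), 3L, cacc, cfg$growth_rate)
        gn(paste0(p, ".gn"), cfg$growth_rate)
        cacc <- cacc + cfg$growth_rate
      }
      conv(sprintf("s%d.tr", s), 1L, cacc, cs)
    }
    cin <- cs
  }
  for (s in seq_len(S)) conv(sprintf("lat%d", s), 1L, cfg$stage_channels[s], cfg$fpn_channels)
  conv("head.c1", 3L, cfg$fpn_channels, cfg$fpn_channels)
  gn("head.gn", cfg$fpn_channels)
  conv("head.out", 1L, cfg$fpn_channels, cfg$out_classes)
  sh
}

#' Bundle of named weight tensors plus the config that implies them
#' @param tensors named list of arrays/vectors
#' @param config a [backbone_config()], or NULL for non-network models
#' @export
model_parameters <- function(tensors, config = NULL) {
  structure(list(tensors = tensors, config = config), class = "model_parameters")
}

#' Initialize network parameters
#'
#' He-style initialization for convolution weights, zeros for biases and
#' group-norm shifts, ones for group-norm scales; reproducible from
#' `init_seed`. The name set of the result depends only on the config.
#'
#' @param cfg a [backbone_config()]
#' @param init_seed integer seed
#' @return a [model_parameters()] object
#' @export
build_model <- function(cfg, init_seed = 1L) {
  stopifnot(inherits(cfg, "backbone_config"))
  sh <- param_shapes(cfg)
  tensors <- local_seed(init_seed, {
    lapply(stats::setNames(names(sh), names(sh)), function(nm) {
      d <- sh[[nm]]
      if (endsWith(nm, ".w")) {
        fan_in <- prod(d[-length(d)])
        array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), d)
      } else if (endsWith(nm, ".g")) {
        rep(1, d)
      } else {
        rep(0, d)
      }
    })
  })
  model_parameters(tensors, cfg)
}

n_parameters <- function(params) {
  sum(vapply(params$tensors, length, integer(1)))
}

# --- tape graph --------------------------------------------------------------

t_residual_block_graph <- function(tp, x, L, prefix, cs) {
  g <- gn_groups(cs)
  h <- t_conv2d(tp, x, L[[paste0(prefix, ".c1.w")]], L[[paste0(prefix, ".c1.b")]], 1L, 1L)
  h <- t_group_norm(tp, h, L[[paste0(prefix, ".gn1.g")]], L[[paste0(prefix, ".gn1.bt")]], g)
  h <- t_relu(tp, h)
  h <- t_conv2d(tp, h, L[[paste0(prefix, ".c2.w")]], L[[paste0(prefix, ".c2.b")]], 1L, 1L)
  h <- t_group_norm(tp, h, L[[paste0(prefix, ".gn2.g")]], L[[paste0(prefix, ".gn2.bt")]], g)
  t_relu(tp, t_add(tp, h, x))
}

t_dense_layer_graph <- function(tp, x, L, prefix, growth) {
  h <- t_conv2d(tp, x, L[[paste0(prefix, ".c.w")]], L[[paste0(prefix, ".c.b")]], 1L, 1L)
  h <- t_group_norm(tp, h, L[[paste0(prefix, ".gn.g")]], L[[paste0(prefix, ".gn.bt")]], gn_groups(growth))
  h <- t_relu(tp, h)
  t_concat_c(tp, x, h)
}

#' Build the FPN logits graph on a tape; returns the logits node id
#' @noRd
fpn_graph <- function(tp, L, x_id, cfg) {
  S <- length(cfg$stage_channels)
  feats <- integer(S)
  h <- x_id
  for (s in seq_len(S)) {
    cs <- cfg$stage_channels[s]
    # stride-2 entry conv (downsample), then blocks
    hc <- t_conv2d(tp, h, L[[sprintf("s%d.down.w", s)]], L[[sprintf("s%d.down.b", s)]], 2L, 1L)
    hc <- t_group_norm(tp, hc, L[[sprintf("s%d.down.gn.g", s)]],
                       L[[sprintf("s%d.down.gn.bt", s)]], gn_groups(cs))
    h <- t_relu(tp, hc)
    if (cfg$family == "residual") {
      for (b in seq_len(cfg$blocks_per_stage[s])) {
        h <- t_residual_block_graph(tp, h, L, sprintf("s%d.b%d", s, b), cs)
      }
    } else {
      for (l in seq_len(cfg$blocks_per_stage[s])) {
        h <- t_dense_layer_graph(tp, h, L, sprintf("s%d.l%d", s, l), cfg$growth_rate)
      }
      h <- t_conv2d(tp, h, L[[sprintf("s%d.tr.w", s)]], L[[sprintf("s%d.tr.b", s)]], 1L, 0L)
    }
    feats[s] <- h
  }
  # top-down pathway with lateral 1x1 connections, summed
  p <- t_conv2d(tp, feats[S], L[[sprintf("lat%d.w", S)]], L[[sprintf("lat%d.b", S)]], 1L, 0L)
  for (s in seq(S - 1L, 1L)) {
    lat <- t_conv2d(tp, feats[s], L[[sprintf("lat%d.w", s)]], L[[sprintf("lat%d.b", s)]], 1L, 0L)
    p <- t_add(tp, lat, t_upsample2(tp, p))
  }
  # head at the finest pyramid level (stride 2), then upsample to full res
  h <- t_conv2d(tp, p, L[["head.c1.w"]], L[["head.c1.b"]], 1L, 1L)
  h <- t_group_norm(tp, h, L[["head.gn.g"]], L[["head.gn.bt"]], gn_groups(cfg$fpn_channels))
  h <- t_relu(tp, h)
  h <- t_conv2d(tp, h, L[["head.out.w"]], L[["head.out.b"]], 1L, 0L)
  t_upsample2(tp, h)
}

as_image_array <- function(img) {
  if (inherits(img, "micrograph")) img <- img$image
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  img
}

make_leaves <- function(tp, tensors) {
  lapply(tensors, function(t) t_leaf(tp, t))
}

check_forward_geometry <- function(d, cfg) {
  f <- 2L^length(cfg$stage_channels)
  if (d[1] %% f != 0L || d[2] %% f != 0L) {
    stop(sprintf("image sides (%d, %d) must be divisible by %d for %d encoder stages",
                 d[1], d[2], f, length(cfg$stage_channels)), call. = FALSE)
  }
}

#' Forward pass: per-pixel crystalline-ice logits
#'
#' @param params a [model_parameters()] built by [build_model()]
#' @param images a single image (matrix or [micrograph()]) or a list of them;
#'   sides must be divisible by `2^n_stages`.
#' @return a logit matrix with the input's spatial shape, or a list of them
#' @export
forward <- function(params, images) {
  stopifnot(inherits(params, "model_parameters"), !is.null(params$config))
  single <- !is.list(images) || inherits(images, "micrograph")
  if (single) images <- list(images)
  out <- lapply(images, function(img) {
    x <- as_image_array(img)
    check_forward_geometry(dim(x), params$config)
    tp <- tape_new()
    L <- make_leaves(tp, params$tensors)
    logits <- fpn_graph(tp, L, t_leaf(tp, x), params$config)
    v <- tv(tp, logits)
    matrix(v[, , 1L], dim(v)[1], dim(v)[2])
  })
  if (single) out[[1]] else out
}

# --- standalone block operations ---------------------------------------------

#' Residual block: y = ReLU(F(x) + x), F = conv-norm-ReLU-conv-norm
#'
#' @param x feature array (H, W, C)
#' @param weights named list: `c1.w, c1.b, gn1.g, gn1.bt, c2.w, c2.b, gn2.g,
#'   gn2.bt`, and optionally `proj.w, proj.b` (1x1 projection, inserted when
#'   input/output channels differ).
#' @return feature array, same spatial shape
#' @export
residual_block <- function(x, weights) {
  cs <- dim(weights$c1.w)[4]
  g <- gn_groups(cs)
  h <- conv2d_forward(x, weights$c1.w, weights$c1.b, 1L, 1L)$y
  h <- group_norm_forward(h, weights$gn1.g, weights$gn1.bt, g)$y
  h <- relu_forward(h)$y
  h <- conv2d_forward(h, weights$c2.w, weights$c2.b, 1L, 1L)$y
  h <- group_norm_forward(h, weights$gn2.g, weights$gn2.bt, g)$y
  skip <- x
  if (dim(x)[3] != cs) {
    if (is.null(weights$proj.w)) stop("channel mismatch requires proj.w/proj.b", call. = FALSE)
    skip <- conv2d_forward(x, weights$proj.w, weights$proj.b, 1L, 0L)$y
  }
  relu_forward(h + skip)$y
}

#' Dense block: each layer consumes the concatenation of the input and all
#' previous layers' outputs; output has `channels(x) + layers * growth` channels.
#'
#' @param x feature array (H, W, C)
#' @param weights named list with `l<j>.c.w, l<j>.c.b, l<j>.gn.g, l<j>.gn.bt`
#'   for j = 1..layers
#' @param layers number of dense layers (>= 1)
#' @param growth channels added per layer
#' @export
dense_block <- function(x, weights, layers, growth) {
  stopifnot(layers >= 1L)
  h <- x
  for (l in seq_len(layers)) {
    p <- sprintf("l%d", l)
    new <- conv2d_forward(h, weights[[paste0(p, ".c.w")]], weights[[paste0(p, ".c.b")]], 1L, 1L)$y
    new <- group_norm_forward(new, weights[[paste0(p, ".gn.g")]],
                              weights[[paste0(p, ".gn.bt")]], gn_groups(growth))$y
    new <- relu_forward(new)$y
    d <- dim(h)
    h <- array(c(h, new), c(d[1], d[2], d[3] + growth))
  }
  h
}

#' Binarize a logit map into a segmentation mask
#'
#' A pixel is labeled crystalline when `sigmoid(logit) >= threshold`
#' (ties count as positive).
#' @param logits logit matrix
#' @param threshold probability threshold in (0, 1)
#' @param image_ref identifier copied into the mask
#' @export
predict_mask <- function(logits, threshold = 0.5, image_ref = "") {
  stopifnot(all(is.finite(logits)), threshold > 0, threshold < 1)
  m <- (sigmoid_c(logits) >= threshold) * 1L
  seg_mask(matrix(as.integer(m), nrow(logits), ncol(logits)), image_ref)
}

# --- model interface used by the trainers ------------------------------------

#' FPN segmentation model handle (config + loss choice)
#'
#' The handle owns no weights; trainers pass `model_parameters` explicitly.
#' @param config a [backbone_config()]
#' @param loss one of `"bce"`, `"dice"`, `"bce_plus_dice"`
#' @export
fpn_model <- function(config, loss = c("bce_plus_dice", "bce", "dice")) {
  loss <- match.arg(loss)
  structure(list(config = config, loss = loss), class = c("fpn_model", "cryoice_model"))
}

#' Loss and gradient of a model at given parameters on a batch (generic)
#' @param model a model handle (e.g. [fpn_model()])
#' @param tensors named list of parameter tensors
#' @param batch model-specific batch (for FPN: list of `(micrograph, mask)` pairs)
#' @return list(loss = scalar, grads = named list matching `tensors`)
#' @export
model_loss_grad <- function(model, tensors, batch) UseMethod("model_loss_grad")

#' Loss only (generic); default recomputes via model_loss_grad
#' @rdname model_loss_grad
#' @export
model_loss <- function(model, tensors, batch) UseMethod("model_loss")

#' @export
model_loss.default <- function(model, tensors, batch) {
  model_loss_grad(model, tensors, batch)$loss
}

#' Hessian-vector product of the batch loss (generic)
#'
#' The default method is a complex-step directional derivative of the
#' gradient: exact to machine precision wherever the loss is piecewise
#' analytic, with no subtractive cancellation.
#' @param v named list of direction tensors matching `tensors`
#' @export
model_hvp <- function(model, tensors, batch, v) UseMethod("model_hvp")

#' @export
model_hvp.default <- function(model, tensors, batch, v) {
  h <- 1e-30
  tc <- Map(function(t, vi) t + (0 + 1i) * h * vi, tensors, v)
  g <- model_loss_grad(model, tc, batch)$grads
  lapply(g, function(gi) Im(gi) / h)
}

batch_pair_image <- function(pair) {
  if (inherits(pair, "micrograph")) stop("batch elements must be (micrograph, mask) pairs", call. = FALSE)
  as_image_array(pair$micrograph %||% pair$image %||% pair[[1]])
}

batch_pair_mask <- function(pair) {
  m <- pair$mask %||% pair[[2]]
  as_mask_matrix(m)
}

fpn_loss_node <- function(tp, L, x, y, cfg, kind) {
  logits <- fpn_graph(tp, L, t_leaf(tp, x), cfg)
  if (kind == "bce") return(t_bce_loss(tp, logits, y))
  if (kind == "dice") return(t_dice_loss(tp, logits, y))
  t_sum_scalars(tp, c(t_bce_loss(tp, logits, y), t_dice_loss(tp, logits, y)))
}

#' @export
model_loss_grad.fpn_model <- function(model, tensors, batch) {
  stopifnot(length(batch) >= 1L)
  total <- NULL
  grads <- NULL
  for (pair in batch) {
    x <- batch_pair_image(pair)
    y <- array(batch_pair_mask(pair), dim(x))
    check_forward_geometry(dim(x), model$config)
    tp <- tape_new()
    L <- make_leaves(tp, tensors)
    loss_id <- fpn_loss_node(tp, L, x, y, model$config, model$loss)
    gr <- tape_backward(tp, loss_id)
    gi <- lapply(L, function(id) {
      g <- gr[[id]]
      if (is.null(g)) 0 * tv(tp, id) else g
    })
    total <- if (is.null(total)) tv(tp, loss_id) else total + tv(tp, loss_id)
    grads <- if (is.null(grads)) gi else Map(`+`, grads, gi)
  }
  n <- length(batch)
  list(loss = total / n, grads = lapply(grads, function(g) g / n))
}

#' Per-image sigmoid probability maps (generic)
#' @export
model_predict <- function(model, tensors, batch) UseMethod("model_predict")

#' @export
model_predict.fpn_model <- function(model, tensors, batch) {
  params <- model_parameters(tensors, model$config)
  lapply(batch, function(pair) {
    sigmoid_c(forward(params, batch_pair_image(pair)[, , 1L]))
  })
}

# --- checkpoints --------------------------------------------------------------

#' Save / load a named-tensor checkpoint with its embedded config
#' @param params a [model_parameters()]
#' @param path file path
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  obj <- list(format_version = 1L, tensors = params$tensors, config = params$config)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported checkpoint format version", call. = FALSE)
  }
  model_parameters(obj$tensors, obj$config)
}
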