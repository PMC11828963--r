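# Shared fixtures, all generated in code.

options(cryoice.quiet = TRUE)

tiny_backbone <- function(family = "residual", ...) {
  backbone_config(family = family, stage_channels = c(4L, 4L, 8L),
                  blocks_per_stage = c(1L, 1L, 1L), fpn_channels = 4L,
                  growth_rate = if (family == "dense") 2L else NULL, ...)
}

# random (micrograph, mask) pair at a network-compatible size
tiny_pair <- function(seed = 1L, n = 16L) {
  set.seed(seed)
  list(micrograph = matrix(runif(n * n), n, n),
       mask = matrix(rbinom(n * n, 1L, 0.15), n, n))
}

# float32-representable random matrix (dyadic values): MRC mode-2 round trips
# are then bit-exact
dyadic_matrix <- function(nr, nc, seed = 1L) {
  set.seed(seed)
  matrix(round(runif(nr * nc) * 4096) / 256, nr, nc)
}

# a random convex polygon: points on a circle at sorted angles
random_convex_polygon <- function(n_vert, cx, cy, radius, seed = 1L) {
  set.seed(seed)
  ang <- sort(runif(n_vert, 0, 2 * pi))
  r <- radius * runif(n_vert, 0.8, 1)
  cbind(col = cx + r * cos(ang), row = cy + r * sin(ang))
}

# toy quadratic meta-learning tasks (support/query = single quadratic term)
toy_task <- function(p, seed) {
  set.seed(seed)
  spd <- function() {
    M <- matrix(rnorm(p * p), p)
    crossprod(M) / p + diag(p) * 0.5
  }
  list(support = list(list(A = spd(), c = rnorm(p))),
       query = list(list(A = spd(), c = rnorm(p))),
       dataset_id = paste0("toy-", seed))
}

toy_meta_objective <- function(model, w0, tasks, cfg) {
  mean(vapply(tasks, function(task) {
    r <- inner_adapt(model, list(w = w0), task$support, cfg)
    model_loss(model, r$phi, task$query)
  }, numeric(1)))
}
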