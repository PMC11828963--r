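# Minimal reverse-mode autodiff tape.
#
# Nodes are created in topological order; tape_backward walks them in reverse,
# accumulating gradients. Values are arrays (or scalars); every op is written
# so that a complex-valued parameter propagates through both the forward and
# the backward pass, which is what makes complex-step Hessian-vector products
# (and hence exact second-order MAML) possible on top of first-order code.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tape_push <- function(tp, value, parents = integer(0), backward = NULL) {
  force(value); force(parents); force(backward)
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(value = value, parents = parents, backward = backward)
  tp$n
}

tv <- function(tp, id) {
  # force the id before touching tp$nodes: nested op calls in argument
  # position push nodes onto the tape as they are evaluated
  force(id)
  tp$nodes[[id]]
}$value

t_leaf <- function(tp, value) tape_push(tp, value)

#' Backward pass: gradients of scalar node `loss_id` w.r.t. every node
#' @return list indexed by node id (NULL where no gradient flows)
#' @noRd
tape_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq(loss_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

t_conv2d <- function(tp, x, w, b, stride = 1L, pad = 1L) {
  fw <- conv2d_forward(tv(tp, x), tv(tp, w), tv(tp, b), stride, pad)
  tape_push(tp, fw$y, c(x, w, b), function(g) {
    bk <- conv2d_backward(g, fw$cache)
    list(bk$dx, bk$dw, bk$db)
  })
}

t_group_norm <- function(tp, x, gamma, beta, groups, eps = 1e-5) {
  fw <- group_norm_forward(tv(tp, x), tv(tp, gamma), tv(tp, beta), groups, eps)
  tape_push(tp, fw$y, c(x, gamma, beta), function(g) {
    bk <- group_norm_backward(g, fw$cache)
    list(bk$dx, bk$dgamma, bk$dbeta)
  })
}

t_relu <- function(tp, x) {
  fw <- relu_forward(tv(tp, x))
  tape_push(tp, fw$y, x, function(g) list(relu_backward(g, fw$cache)))
}

t_add <- function(tp, a, b) {
  tape_push(tp, tv(tp, a) + tv(tp, b), c(a, b), function(g) list(g, g))
}

t_upsample2 <- function(tp, x) {
  tape_push(tp, upsample2_forward(tv(tp, x)), x,
            function(g) list(upsample2_backward(g)))
}

t_concat_c <- function(tp, a, b) {
  va <- tv(tp, a); vb <- tv(tp, b)
  da <- dim(va); db_ <- dim(vb)
  val <- array(c(va, vb), c(da[1], da[2], da[3] + db_[3]))
  tape_push(tp, val, c(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db_[3]), drop = FALSE])
  })
}

# --- losses (scalar nodes, analytic gradients w.r.t. logits) ----------------

t_bce_loss <- function(tp, logits, target) {
  z <- tv(tp, logits)
  y <- target
  n <- length(z)
  val <- sum(softplus_c(z) - z * y) / n
  tape_push(tp, val, logits, function(g) {
    list(g * (sigmoid_c(z) - y) / n)
  })
}

t_dice_loss <- function(tp, logits, target, eps = 1) {
  z <- tv(tp, logits)
  y <- target
  s <- sigmoid_c(z)
  num <- 2 * sum(s * y) + eps
  den <- sum(s) + sum(y) + eps
  val <- 1 - num / den
  tape_push(tp, val, logits, function(g) {
    dnum_ds <- 2 * y
    # d(1 - num/den)/ds = -(dnum*den - num)/den^2, elementwise through sigmoid
    ds <- -(dnum_ds * den - num) / den^2
    list(g * ds * s * (1 - s))
  })
}

t_scale <- function(tp, x, s) {
  tape_push(tp, tv(tp, x) * s, x, function(g) list(g * s))
}

t_sum_scalars <- function(tp, ids) {
  val <- 0
  for (id in ids) val <- val + tv(tp, id)
  tape_push(tp, val, ids, function(g) rep(list(g), length(ids)))
}
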