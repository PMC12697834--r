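# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix. Nodes are environments holding the
# value, the parent nodes and a backward closure mapping the incoming gradient to
# per-parent gradients. Node ids increase monotonically at creation time, so
# sorting by id gives a topological order for the backward sweep.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0L

ad_next_id <- function() {
  .ad_state$counter <- .ad_state$counter + 1L
  .ad_state$counter
}

ad_node <- function(val, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$id <- ad_next_id()
  class(e) <- "ad_node"
  e
}

#' @noRd
ad_const <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  ad_node(x)
}

ad_param <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- ad_node(x)
  n$is_param <- TRUE
  n
}

ad_val <- function(x) x$val

# ---- arithmetic -------------------------------------------------------------

ad_mm <- function(a, b) {
  ad_node(a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), crossprod(a$val, g))
  })
}

ad_add <- function(a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  ad_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

# a (n x k) + bias b (1 x k), broadcast over rows (rank-1 BLAS product)
ad_add_bias <- function(a, b) {
  k <- ncol(a$val)
  val <- a$val + matrix(1, nrow(a$val), 1L) %*% b$val
  ad_node(val, list(a, b), function(g) {
    list(g, matrix(colSums(g), 1L, k))
  })
}

ad_sub <- function(a, b) {
  ad_node(a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  ad_node(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

ad_scale <- function(a, s) {
  ad_node(a$val * s, list(a), function(g) list(g * s))
}

# ---- nonlinearities ---------------------------------------------------------

ad_relu <- function(a) {
  mask <- a$val > 0
  ad_node(a$val * mask, list(a), function(g) list(g * mask))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

# fused affine map: x %*% W + bias (optionally followed by ReLU) in one node
ad_affine <- function(x, W, b, relu = FALSE) {
  val <- x$val %*% W$val + matrix(1, nrow(x$val), 1L) %*% b$val
  mask <- NULL
  if (relu) {
    mask <- val > 0
    val <- val * mask
  }
  k <- ncol(val)
  ad_node(val, list(x, W, b), function(g) {
    if (relu) g <- g * mask
    list(g %*% t(W$val), crossprod(x$val, g), matrix(colSums(g), 1L, k))
  })
}

# fused attention-input: q[dst, ] - k[src, ] + delta
ad_qk_rel <- function(q, k, delta, src, dst) {
  val <- q$val[dst, , drop = FALSE] - k$val[src, , drop = FALSE] + delta$val
  nr <- nrow(q$val); nc <- ncol(q$val)
  scatter <- function(g, idx) {
    z <- matrix(0, nr, nc)
    rs <- rowsum(g, idx)
    z[as.integer(rownames(rs)), ] <- rs
    z
  }
  ad_node(val, list(q, k, delta), function(g) {
    list(scatter(g, dst), -scatter(g, src), g)
  })
}

# fused message: alpha * (v[src, ] + delta), aggregated later by segment sum
ad_msg <- function(alpha, v, delta, src) {
  vs <- v$val[src, , drop = FALSE] + delta$val
  val <- alpha$val * vs
  nr <- nrow(v$val); nc <- ncol(v$val)
  ad_node(val, list(alpha, v, delta), function(g) {
    ga <- g * vs
    gvd <- g * alpha$val
    z <- matrix(0, nr, nc)
    rs <- rowsum(gvd, src)
    z[as.integer(rownames(rs)), ] <- rs
    list(ga, z, gvd)
  })
}

# row-wise layer normalization with learnable gain/bias (1 x k each)
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  k <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  ones <- matrix(1, nrow(x), 1L)
  val <- xhat * (ones %*% gamma$val) + ones %*% beta$val
  ad_node(val, list(a, gamma, beta), function(g) {
    gmat <- matrix(1, nrow(x), 1L) %*% gamma$val
    dxh <- g * gmat
    dx <- inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
    list(dx, matrix(colSums(g * xhat), 1L, k), matrix(colSums(g), 1L, k))
  })
}

# ---- indexing and segment reductions ---------------------------------------

# rows a[idx, ]; backward scatter-adds into the parent
ad_gather <- function(a, idx) {
  nr <- nrow(a$val)
  nc <- ncol(a$val)
  ad_node(a$val[idx, , drop = FALSE], list(a), function(g) {
    z <- matrix(0, nr, nc)
    rs <- rowsum(g, idx)
    z[as.integer(rownames(rs)), ] <- rs
    list(z)
  })
}

segment_sum_mat <- function(x, seg, nseg) {
  z <- matrix(0, nseg, ncol(x))
  rs <- rowsum(x, seg)
  z[as.integer(rownames(rs)), ] <- rs
  z
}

ad_segment_sum <- function(a, seg, nseg) {
  ad_node(segment_sum_mat(a$val, seg, nseg), list(a), function(g) {
    list(g[seg, , drop = FALSE])
  })
}

# softmax over rows sharing a segment id, independently per column
# (vector attention normalization over each node's neighborhood)
ad_segment_softmax <- function(a, seg, nseg) {
  x <- a$val
  e <- exp(x - max(x))               # global shift for overflow safety
  denom <- segment_sum_mat(e, seg, nseg)
  out <- e / denom[seg, , drop = FALSE]
  ad_node(out, list(a), function(g) {
    s <- segment_sum_mat(out * g, seg, nseg)
    list(out * (g - s[seg, , drop = FALSE]))
  })
}

# column-wise max within segments; backward routes gradient to the argmax rows.
# vectorized by sorting each column within segments: the last row of each
# segment block in the sorted order is its maximum
ad_segment_max <- function(a, seg, nseg) {
  x <- a$val
  nc <- ncol(x)
  nr <- nrow(x)
  out <- matrix(-Inf, nseg, nc)
  arg <- matrix(NA_integer_, nseg, nc)
  for (j in seq_len(nc)) {
    o <- order(seg, x[, j])
    s <- seg[o]
    ends <- c(which(s[-1L] != s[-length(s)]), length(s))
    rows <- o[ends]
    out[cbind(s[ends], j)] <- x[rows, j]
    arg[cbind(s[ends], j)] <- rows
  }
  ad_node(out, list(a), function(g) {
    z <- matrix(0, nr, nc)
    ok <- !is.na(arg)
    z[cbind(arg[ok], col(arg)[ok])] <- g[ok]
    list(z)
  })
}

# ---- losses -----------------------------------------------------------------

ad_log_softmax <- function(a) {
  x <- a$val
  m <- apply(x, 1L, max)
  xs <- x - m
  lse <- log(rowSums(exp(xs)))
  out <- xs - lse
  ad_node(out, list(a), function(g) {
    list(g - exp(out) * rowSums(g))
  })
}

# mean negative log-likelihood of integer labels y (1-based) under log-probs
ad_nll <- function(logp, y) {
  n <- nrow(logp$val)
  pick <- cbind(seq_len(n), y)
  val <- matrix(-mean(logp$val[pick]), 1L, 1L)
  ad_node(val, list(logp), function(g) {
    z <- matrix(0, n, ncol(logp$val))
    z[pick] <- -as.numeric(g)[1L] / n
    list(z)
  })
}

# ---- backward sweep ---------------------------------------------------------

ad_backward <- function(root) {
  nodes <- vector("list", 64L)
  nn <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  root$grad <- matrix(1, nrow(root$val), ncol(root$val))
  for (i in ord) {
    n <- nodes[[i]]
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    for (j in seq_along(n$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}
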