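# Minimal tape-based reverse-mode automatic differentiation over R matrices.
#
# Every differentiable quantity is an "ad node": an environment holding a
# numeric matrix value, an optional gradient of the same shape, and a
# backward closure that routes the incoming gradient to the node's parents.
# Nodes are registered on a tape in creation order; ad_backward() walks the
# tape in reverse, which is a valid topological order because operands are
# always created before the operations consuming them.
#
# Constants may be passed to any op as plain matrices/vectors; they receive
# no gradient. Broadcasting is deliberately restricted to the cases the
# models need: scalar (1x1), row vector (1xn, e.g. biases) and column
# vector (mx1, e.g. per-example masks and step sizes) against an m x n
# matrix.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

is_adnode <- function(x) inherits(x, "ad_node")

ad_val <- function(x) if (is_adnode(x)) x$value else x

new_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd$id <- n
  class(nd) <- "ad_node"
  nd
}

ad_leaf <- function(tape, value) {
  new_node(tape, as_matrix(value))
}

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, root, seed_grad = NULL) {
  if (is.null(seed_grad)) {
    seed_grad <- matrix(1, nrow(root$value), ncol(root$value))
  }
  root$grad <- seed_grad
  for (i in seq.int(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# reduce a full-size gradient back to the broadcast shape of the operand
reduce_to_shape <- function(g, dims) {
  gd <- dim(g)
  if (identical(gd, dims)) return(g)
  if (all(dims == c(1L, 1L))) return(matrix(sum(g), 1L, 1L))
  if (dims[1L] == 1L && dims[2L] == gd[2L]) return(matrix(colSums(g), 1L))
  if (dims[2L] == 1L && dims[1L] == gd[1L]) return(matrix(rowSums(g), ncol = 1L))
  stop2("autodiff: cannot reduce gradient of shape ", paste(gd, collapse = "x"),
        " to ", paste(dims, collapse = "x"))
}

broadcast_val <- function(x, out_dims) {
  d <- dim(x)
  if (identical(d, out_dims)) return(x)
  if (all(d == c(1L, 1L))) return(matrix(x[1L], out_dims[1L], out_dims[2L]))
  if (d[1L] == 1L) return(matrix(x, out_dims[1L], out_dims[2L], byrow = TRUE))
  if (d[2L] == 1L) return(matrix(x, out_dims[1L], out_dims[2L]))
  stop2("autodiff: incompatible shapes")
}

bcast_dims <- function(da, db) {
  c(max(da[1L], db[1L]), max(da[2L], db[2L]))
}

ad_binary <- function(tape, a, b, fval, fga, fgb) {
  va <- as_matrix(ad_val(a)); vb <- as_matrix(ad_val(b))
  od <- bcast_dims(dim(va), dim(vb))
  va_b <- broadcast_val(va, od); vb_b <- broadcast_val(vb, od)
  out <- new_node(tape, fval(va_b, vb_b))
  an <- if (is_adnode(a)) a else NULL
  bn <- if (is_adnode(b)) b else NULL
  if (!is.null(an) || !is.null(bn)) {
    out$backward <- function(g) {
      if (!is.null(an)) ad_accum(an, reduce_to_shape(fga(g, va_b, vb_b), dim(va)))
      if (!is.null(bn)) ad_accum(bn, reduce_to_shape(fgb(g, va_b, vb_b), dim(vb)))
    }
  }
  out
}

ad_add <- function(tape, a, b) {
  ad_binary(tape, a, b, function(x, y) x + y,
            function(g, x, y) g, function(g, x, y) g)
}

ad_sub <- function(tape, a, b) {
  ad_binary(tape, a, b, function(x, y) x - y,
            function(g, x, y) g, function(g, x, y) -g)
}

ad_mul <- function(tape, a, b) {
  ad_binary(tape, a, b, function(x, y) x * y,
            function(g, x, y) g * y, function(g, x, y) g * x)
}

ad_div <- function(tape, a, b) {
  ad_binary(tape, a, b, function(x, y) x / y,
            function(g, x, y) g / y, function(g, x, y) -g * x / y^2)
}

ad_pmax2 <- function(tape, a, b) {
  ad_binary(tape, a, b, function(x, y) pmax(x, y),
            function(g, x, y) g * (x >= y), function(g, x, y) g * (x < y))
}

ad_matmul <- function(tape, a, b) {
  va <- as_matrix(ad_val(a)); vb <- as_matrix(ad_val(b))
  out <- new_node(tape, va %*% vb)
  an <- if (is_adnode(a)) a else NULL
  bn <- if (is_adnode(b)) b else NULL
  if (!is.null(an) || !is.null(bn)) {
    out$backward <- function(g) {
      if (!is.null(an)) ad_accum(an, g %*% t(vb))
      if (!is.null(bn)) ad_accum(bn, t(va) %*% g)
    }
  }
  out
}

ad_unary <- function(tape, a, fval, fgrad) {
  va <- as_matrix(ad_val(a))
  y <- fval(va)
  out <- new_node(tape, y)
  if (is_adnode(a)) {
    out$backward <- function(g) ad_accum(a, fgrad(g, va, y))
  }
  out
}

ad_neg <- function(tape, a) ad_unary(tape, a, function(x) -x, function(g, x, y) -g)
ad_exp <- function(tape, a) ad_unary(tape, a, exp, function(g, x, y) g * y)
ad_log <- function(tape, a) ad_unary(tape, a, log, function(g, x, y) g / x)
ad_tanh <- function(tape, a) ad_unary(tape, a, tanh, function(g, x, y) g * (1 - y^2))
ad_sigmoid <- function(tape, a) ad_unary(tape, a, sigmoid, function(g, x, y) g * y * (1 - y))
ad_softplus <- function(tape, a) ad_unary(tape, a, softplus, function(g, x, y) g * sigmoid(x))
ad_square <- function(tape, a) ad_unary(tape, a, function(x) x^2, function(g, x, y) 2 * g * x)

ad_scale <- function(tape, a, k) {
  ad_unary(tape, a, function(x) x * k, function(g, x, y) g * k)
}

ad_sum <- function(tape, a) {
  va <- as_matrix(ad_val(a))
  out <- new_node(tape, matrix(sum(va), 1L, 1L))
  if (is_adnode(a)) {
    out$backward <- function(g) ad_accum(a, matrix(g[1L], nrow(va), ncol(va)))
  }
  out
}

ad_mean <- function(tape, a) {
  va <- as_matrix(ad_val(a))
  n <- length(va)
  out <- new_node(tape, matrix(mean(va), 1L, 1L))
  if (is_adnode(a)) {
    out$backward <- function(g) ad_accum(a, matrix(g[1L] / n, nrow(va), ncol(va)))
  }
  out
}

# gather rows of an embedding-like matrix; gradient scatter-adds per row
ad_rows <- function(tape, a, idx) {
  va <- as_matrix(ad_val(a))
  idx <- as.integer(idx)
  out <- new_node(tape, va[idx, , drop = FALSE])
  if (is_adnode(a)) {
    out$backward <- function(g) {
      z <- matrix(0, nrow(va), ncol(va))
      rs <- rowsum(g, group = idx, reorder = FALSE)
      z[as.integer(rownames(rs)), ] <- rs
      ad_accum(a, z)
    }
  }
  out
}

ad_cbind <- function(tape, parts) {
  vals <- lapply(parts, function(p) as_matrix(ad_val(p)))
  widths <- vapply(vals, ncol, 0L)
  out <- new_node(tape, do.call(cbind, vals))
  nodes <- parts[vapply(parts, is_adnode, TRUE)]
  if (length(nodes)) {
    ends <- cumsum(widths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    out$backward <- function(g) {
      for (i in seq_along(parts)) {
        if (is_adnode(parts[[i]])) {
          ad_accum(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
        }
      }
    }
  }
  out
}

ad_col <- function(tape, a, j) {
  va <- as_matrix(ad_val(a))
  out <- new_node(tape, va[, j, drop = FALSE])
  if (is_adnode(a)) {
    out$backward <- function(g) {
      z <- matrix(0, nrow(va), ncol(va))
      z[, j] <- g
      ad_accum(a, z)
    }
  }
  out
}

# row-wise softmax restricted to positions where mask == 1; masked
# positions get exactly zero weight. Rows with no live entry at all get an
# all-zero weight row (used to give event-free streams a zero context).
ad_softmax_rows <- function(tape, a, mask) {
  va <- as_matrix(ad_val(a))
  mask <- as_matrix(mask)
  x <- ifelse(mask > 0, va, -Inf)
  mx <- apply(x, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(x - mx)
  e[mask <= 0] <- 0
  rs <- rowSums(e)
  rs[rs == 0] <- 1
  y <- e / rs
  out <- new_node(tape, y)
  if (is_adnode(a)) {
    out$backward <- function(g) {
      dot <- rowSums(g * y)
      ad_accum(a, y * (g - dot))
    }
  }
  out
}

# fused, numerically stable class-weighted binary cross-entropy on logits:
# loss = reduce( w * (softplus(l) - y * l) )
ad_bce_logits <- function(tape, logits, y, w = 1, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  vl <- as_matrix(ad_val(logits))
  y <- as_matrix(y)
  wv <- if (length(w) == 1L) matrix(w, nrow(vl), 1L) else as_matrix(w)
  per <- wv * (softplus(vl) - y * vl)
  denom <- if (reduce == "mean") length(vl) else 1
  out <- new_node(tape, matrix(sum(per) / denom, 1L, 1L))
  if (is_adnode(logits)) {
    out$backward <- function(g) {
      ad_accum(logits, g[1L] * wv * (sigmoid(vl) - y) / denom)
    }
  }
  out
}
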