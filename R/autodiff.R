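# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). Nodes are
# integer ids into the tape; each op records its parents and a closure that
# maps the node's output gradient to gradients for the parents. Sparse
# (Matrix::dgCMatrix) operands are allowed only as constants, which covers all
# the graph bookkeeping (gather/scatter, message routing, GCN propagation)
# because molecular topology never requires gradients.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$val <- list()
  tp$parents <- list()
  tp$back <- list()
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_push <- function(tp, val, parents = integer(0), back = NULL) {
  # force args before touching the counter: argument expressions may
  # themselves push nodes (R promises are lazy)
  force(val); force(parents); force(back)
  tp$n <- tp$n + 1L
  tp$val[[tp$n]] <- val
  tp$parents[[tp$n]] <- as.integer(parents)
  tp$back[[tp$n]] <- back
  tp$n
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# constants and parameters are both leaves; the caller keeps track of which
# node ids correspond to trainable parameters
ad_leaf <- function(tp, x) ad_push(tp, as_mat(x))

ad_val <- function(tp, i) tp$val[[i]]

# matrix product a %*% b
ad_mm <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  ad_push(tp, av %*% bv, c(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# a %*% t(b): used throughout because weight matrices are stored in the
# conventional (out x in) orientation while activations are row-major
ad_mmt <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  ad_push(tp, tcrossprod(av, bv), c(a, b), function(g) {
    list(g %*% bv, crossprod(g, av))
  })
}

# constant sparse matrix times variable dense matrix
ad_spmm <- function(tp, S, b) {
  force(b)
  bv <- tp$val[[b]]
  ad_push(tp, as.matrix(S %*% bv), b, function(g) {
    list(as.matrix(Matrix::crossprod(S, g)))
  })
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$val[[a]] + tp$val[[b]], c(a, b), function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$val[[a]] - tp$val[[b]], c(a, b), function(g) list(g, -g))
}

# a (n x k) plus row-vector bias b (1 x k), broadcast over rows
ad_addbias <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  ad_push(tp, sweep(av, 2L, as.vector(bv), "+"), c(a, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1L))
  })
}

# elementwise product, identical shapes
ad_mul <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  ad_push(tp, av * bv, c(a, b), function(g) list(g * bv, g * av))
}

# multiply by a fixed scalar
ad_smul <- function(tp, a, s) {
  force(a)
  ad_push(tp, tp$val[[a]] * s, a, function(g) list(g * s))
}

ad_relu <- function(tp, a) {
  force(a)
  av <- tp$val[[a]]
  ad_push(tp, pmax(av, 0), a, function(g) list(g * (av > 0)))
}

ad_tanh <- function(tp, a) {
  force(a)
  v <- tanh(tp$val[[a]])
  ad_push(tp, v, a, function(g) list(g * (1 - v^2)))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  v <- 1 / (1 + exp(-tp$val[[a]]))
  ad_push(tp, v, a, function(g) list(g * v * (1 - v)))
}

ad_log <- function(tp, a) {
  force(a)
  av <- tp$val[[a]]
  ad_push(tp, log(av), a, function(g) list(g / av))
}

# clip into [lo, hi]; gradient passes only through unclipped entries
ad_clip <- function(tp, a, lo, hi) {
  force(a)
  av <- tp$val[[a]]
  keep <- (av > lo) & (av < hi)
  ad_push(tp, pmin(pmax(av, lo), hi), a, function(g) list(g * keep))
}

# gather rows: out[i, ] = a[idx[i], ]
ad_rows <- function(tp, a, idx) {
  force(a)
  av <- tp$val[[a]]
  n <- nrow(av)
  idx <- as.integer(idx)
  ad_push(tp, av[idx, , drop = FALSE], a, function(g) {
    list(group_sum(g, idx, n))
  })
}

# select one column, kept as n x 1
ad_col <- function(tp, a, j) {
  force(a)
  av <- tp$val[[a]]
  ad_push(tp, av[, j, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, j] <- g
    list(out)
  })
}

ad_cbind <- function(tp, ...) {
  ids <- c(...)
  vals <- lapply(ids, function(i) tp$val[[i]])
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_push(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# scale rows of a (n x k) by vector node v (n x 1)
ad_colscale <- function(tp, a, v) {
  force(a); force(v)
  av <- tp$val[[a]]; vv <- as.vector(tp$val[[v]])
  ad_push(tp, av * vv, c(a, v), function(g) {
    list(g * vv, matrix(rowSums(g * av), ncol = 1L))
  })
}

# per-row sum -> n x 1
ad_rowsum <- function(tp, a) {
  force(a)
  av <- tp$val[[a]]
  k <- ncol(av)
  ad_push(tp, matrix(rowSums(av), ncol = 1L), a, function(g) {
    list(matrix(rep(as.vector(g), k), ncol = k))
  })
}

# sum rows within groups: out is G x k, groups[i] in 1..G
ad_gsum <- function(tp, a, groups, G) {
  force(a)
  groups <- as.integer(groups)
  ad_push(tp, group_sum(tp$val[[a]], groups, G), a, function(g) {
    list(g[groups, , drop = FALSE])
  })
}

ad_sum <- function(tp, a) {
  force(a)
  av <- tp$val[[a]]
  ad_push(tp, matrix(sum(av), 1L, 1L), a, function(g) {
    list(matrix(as.vector(g), nrow(av), ncol(av)))
  })
}

# numerically stable softmax across each row
ad_softmax_rows <- function(tp, a) {
  force(a)
  av <- tp$val[[a]]
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  p <- e / rowSums(e)
  ad_push(tp, p, a, function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# softmax of a column vector (n x 1) within groups 1..G; empty groups allowed
ad_softmax_groups <- function(tp, a, groups, G) {
  force(a)
  av <- as.vector(tp$val[[a]])
  groups <- as.integer(groups)
  m <- group_max(av, groups, G)
  e <- exp(av - m[groups])
  denom <- group_sum(matrix(e, ncol = 1L), groups, G)
  p <- e / as.vector(denom)[groups]
  pm <- matrix(p, ncol = 1L)
  ad_push(tp, pm, a, function(g) {
    s <- group_sum(g * pm, groups, G)
    list(pm * (g - as.vector(s)[groups]))
  })
}

# reverse sweep; returns list of gradients indexed by node id (NULL if unused)
ad_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  rv <- tp$val[[root]]
  grads[[root]] <- matrix(1, nrow(rv), ncol(rv))
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    bk <- tp$back[[i]]
    if (is.null(g) || is.null(bk)) next
    pg <- bk(g)
    ps <- tp$parents[[i]]
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# ---- group reductions shared by the ops above ----------------------------

group_sum <- function(x, groups, G) {
  x <- as_mat(x)
  out <- matrix(0, G, ncol(x))
  if (nrow(x) == 0L) return(out)
  r <- rowsum(x, groups)
  out[as.integer(rownames(r)), ] <- r
  out
}

group_max <- function(x, groups, G) {
  out <- rep(-Inf, G)
  if (length(x) == 0L) return(out)
  agg <- tapply(x, groups, max)
  out[as.integer(names(agg))] <- agg
  out
}

# two-layer perceptron: relu hidden layer, linear output; weights (out x in)
ad_mlp2 <- function(tp, x, W1, b1, W2, b2, drop_mask = NULL) {
  h <- ad_relu(tp, ad_addbias(tp, ad_mmt(tp, x, W1), b1))
  if (!is.null(drop_mask)) h <- ad_mul(tp, h, drop_mask)
  ad_addbias(tp, ad_mmt(tp, h, W2), b2)
}
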