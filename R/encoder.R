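# The molecular encoder: directed bond-level message passing over T radii,
# graph self-adaptive pooling (GSAPooling) readouts per radius, radius
# attention, and per-atom substructure features.
#
# These functions operate on one molecule with plain matrices so that each
# step can be checked against hand-computed values; training runs the same
# computation batched on the autodiff tape (see model.R), and a unit test
# pins the two paths to each other.

#' Initialize directed-edge hidden states
#'
#' For every directed edge p->q, the radius-0 hidden state is the average of
#' three linear maps: `(W_p x_p + W_q x_q + W_pq x_pq) / 3`, mixing the source
#' atom, target atom and bond features.
#'
#' @param graph A `mol_graph`.
#' @param edges Its `directed_edges` from [build_directed_edges()].
#' @param params List with matrices `Wp`, `Wq` (f x d) and `Wpq` (f x d').
#' @return Matrix of size `n_edges` x f (row e = hidden state of edge e).
#' @export
init_edge_hidden <- function(graph, edges, params) {
  d <- ncol(graph$X); dp <- ncol(edges$E)
  if (ncol(params$Wp) != d || ncol(params$Wq) != d || ncol(params$Wpq) != dp) {
    stop("encoder weight dimensions do not match the feature encoding",
         call. = FALSE)
  }
  if (edges$n_edges == 0L) return(matrix(0, 0L, nrow(params$Wp)))
  (graph$X[edges$src, , drop = FALSE] %*% t(params$Wp) +
     graph$X[edges$dst, , drop = FALSE] %*% t(params$Wq) +
     edges$E %*% t(params$Wpq)) / 3
}

#' One step of directed (non-backtracking) edge message passing
#'
#' Updates every directed edge p->q as
#' `h^(t) = act( h^(0) + W_m * sum over incoming edges k->p with k != q of
#' h_kp^(t-1) )`. The reverse edge is excluded so information never flows
#' straight back, the D-MPNN update.
#'
#' @param h_prev Edge states at step t-1 (`n_edges` x f).
#' @param h0 Initial edge states from [init_edge_hidden()].
#' @param edges The `directed_edges`.
#' @param Wm Message transform (f x f).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return Edge states at step t.
#' @export
propagate_edge_messages <- function(h_prev, h0, edges, Wm,
                                    activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  ne <- edges$n_edges
  msum <- matrix(0, ne, ncol(h_prev))
  for (e in seq_len(ne)) {
    inc <- which(edges$dst == edges$src[e])
    inc <- inc[inc != edges$rev[e]]
    if (length(inc) > 0L) {
      msum[e, ] <- colSums(h_prev[inc, , drop = FALSE])
    }
  }
  z <- h0 + msum %*% t(Wm)
  if (activation == "relu") pmax(z, 0) else z
}

#' Graph self-adaptive pooling scores
#'
#' Importance scores over the rows of a feature matrix: a mix of a one-layer
#' GCN score (local structure) and a per-row linear score (row features),
#' `beta = softmax( alpha * GCN(A, X) + (1 - alpha) * FC(X) )`, with the
#' softmax taken over all rows of the (single) graph. Works at bond level
#' (rows = directed edges, A = line-graph adjacency) and at atom level
#' (rows = atoms, A = atom adjacency).
#'
#' @param X Feature matrix (n x f).
#' @param A Raw 0/1 adjacency over the n rows (symmetric, zero diagonal);
#'   it is GCN-normalized (with self-loops) internally.
#' @param params List with `wg`, `bg`, `wl`, `bl` (f x 1 score weights and
#'   1 x 1 biases).
#' @param alpha Mixing weight in `[0, 1]`, default 0.6.
#' @param uniform If `TRUE` (the mean-pooling ablation) scores are bypassed
#'   and `beta` is exactly uniform.
#' @return Numeric vector `beta` of length n, non-negative, summing to 1;
#'   length 0 for an empty graph.
#' @export
gsapooling_scores <- function(X, A, params, alpha = 0.6, uniform = FALSE) {
  n <- nrow(X)
  if (n == 0L) return(numeric(0))
  if (uniform) return(rep(1 / n, n))
  L <- as.matrix(gcn_normalize(A))
  gcn <- as.vector(L %*% (X %*% params$wg + as.vector(params$bg)))
  lin <- as.vector(X %*% params$wl + as.vector(params$bl))
  z <- alpha * gcn + (1 - alpha) * lin
  e <- exp(z - max(z))
  e / sum(e)
}

#' Bond-level graph readout
#'
#' Weighted sum of directed-edge states, `g_b = sum_e beta_e h_e`; with no
#' bonds the readout is the zero vector (the convention that keeps bare-ion
#' fragments flowing through the model).
#'
#' @param h Edge states (`n_edges` x f).
#' @param beta Pooling scores over the same edges.
#' @param f Hidden width, needed only for the zero-bond case.
#' @return Numeric vector of length f.
#' @export
bond_level_readout <- function(h, beta, f = ncol(h)) {
  if (length(beta) == 0L) return(numeric(f))
  as.vector(colSums(h * beta))
}

#' Attention over neighborhood radii
#'
#' Scores each radius t from its bond-level readout,
#' `e^(t) = c^(t) . tanh(W_b g_b^(t) + b_e)`, and softmax-normalizes over
#' t = 1..T. A graph with all-zero readouts (no bonds) gets exactly uniform
#' weights by convention.
#'
#' @param g_list List of T readout vectors (length f each).
#' @param params List with `Wb` (f' x f), `be` (1 x f') and `C` (T x f',
#'   row t = the per-step transformation vector c^(t)).
#' @return List with raw scores `e` and normalized weights `lambda`
#'   (both length T; `sum(lambda) == 1`).
#' @export
radius_attention <- function(g_list, params) {
  T_steps <- length(g_list)
  e <- vapply(seq_len(T_steps), function(t) {
    sum(params$C[t, ] * tanh(as.vector(params$Wb %*% g_list[[t]]) +
                               as.vector(params$be)))
  }, 1)
  x <- exp(e - max(e))
  list(e = e, lambda = x / sum(x))
}

#' Blend edge states across radii
#'
#' `h_e = sum_t lambda^(t) h_e^(t)`: a convex combination of the per-radius
#' hidden states, so each edge's final feature mixes substructures of all
#' sizes with graph-specific weights.
#'
#' @param h_list List of T edge-state matrices.
#' @param lambda Normalized radius weights.
#' @return Matrix of the same shape as each `h_list[[t]]`.
#' @export
aggregate_radii <- function(h_list, lambda) {
  out <- h_list[[1L]] * lambda[1L]
  for (t in seq_along(h_list)[-1L]) out <- out + h_list[[t]] * lambda[t]
  out
}

#' Per-atom substructure features
#'
#' Aggregates the blended incoming edge states at each atom and combines them
#' with the atom's own (projected) features through a two-layer perceptron:
#' `s_p = f_s( W_proj x_p + sum over incoming edges q->p of h_qp )`. Isolated
#' atoms simply get `f_s(W_proj x_p)`.
#'
#' @param graph A `mol_graph`.
#' @param edges Its `directed_edges`.
#' @param h Radius-blended edge states from [aggregate_radii()].
#' @param params List with `Wproj` (f x d) and MLP weights `fs_W1`, `fs_b1`,
#'   `fs_W2`, `fs_b2`.
#' @return Matrix `n_atoms` x f of substructure features `s_p`.
#' @export
node_substructure_features <- function(graph, edges, h, params) {
  f <- nrow(params$Wproj)
  insum <- matrix(0, graph$n_atoms, f)
  for (e in seq_len(edges$n_edges)) {
    insum[edges$dst[e], ] <- insum[edges$dst[e], ] + h[e, ]
  }
  z <- graph$X %*% t(params$Wproj) + insum
  mlp2(z, params$fs_W1, params$fs_b1, params$fs_W2, params$fs_b2)
}

# plain (non-tape) two-layer perceptron, weights (out x in)
mlp2 <- function(x, W1, b1, W2, b2) {
  h <- pmax(sweep(x %*% t(W1), 2L, as.vector(b1), "+"), 0)
  sweep(h %*% t(W2), 2L, as.vector(b2), "+")
}

#' Encode one molecule
#'
#' Runs the full encoder on a single molecule: edge initialization, T rounds
#' of directed message passing, per-radius GSAPooling readouts, radius
#' attention, radius blending and per-atom substructure extraction. A
#' zero-bond molecule short-circuits to uniform radius weights and
#' substructure features that depend on the atom features alone.
#'
#' @param graph A `mol_graph`.
#' @param params Encoder parameter list (see [ddi_init_params()]).
#' @param T_steps Number of message-passing radii (T >= 1).
#' @param alpha GSAPooling mixing weight.
#' @param mean_pool If `TRUE`, pooling weights are uniform (ablation).
#' @param activation Nonlinearity of the edge update.
#' @return List with `S` (`n_atoms` x f substructure features), `lambda`
#'   (radius weights), `beta` (list of per-radius pooling scores over
#'   directed edges), `g_b` (list of per-radius readouts) and `h_final`.
#' @export
encode_molecule <- function(graph, params, T_steps, alpha = 0.6,
                            mean_pool = FALSE,
                            activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  edges <- build_directed_edges(graph)
  Ad <- directed_line_adj(edges, graph)
  h0 <- init_edge_hidden(graph, edges, params)
  pool_par <- list(wg = params$pb_wg, bg = params$pb_bg,
                   wl = params$pb_wl, bl = params$pb_bl)

  h_list <- vector("list", T_steps)
  beta_list <- vector("list", T_steps)
  g_list <- vector("list", T_steps)
  h_prev <- h0
  for (t in seq_len(T_steps)) {
    h_t <- propagate_edge_messages(h_prev, h0, edges, params$Wm, activation)
    beta_t <- gsapooling_scores(h_t, Ad, pool_par, alpha, uniform = mean_pool)
    h_list[[t]] <- h_t
    beta_list[[t]] <- beta_t
    g_list[[t]] <- bond_level_readout(h_t, beta_t, f = nrow(params$Wp))
    h_prev <- h_t
  }

  att <- if (graph$n_bonds == 0L) {
    list(e = rep(0, T_steps), lambda = rep(1 / T_steps, T_steps))
  } else {
    radius_attention(g_list, params)
  }
  h_final <- aggregate_radii(h_list, att$lambda)
  S <- node_substructure_features(graph, edges, h_final, params)
  list(S = S, lambda = att$lambda, beta = beta_list, g_b = g_list,
       h_final = h_final)
}
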