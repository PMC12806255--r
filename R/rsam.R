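# Relation-aware substructure interaction: initial graph readout, the
# drug-relation interactive perception (DRIP) residual co-update, and the
# substructure-drug perception (SDUP) importance scoring.
#
# Pure single-tuple implementations; training uses the batched tape in
# model.R, pinned to these by tests.

#' Initial graph-level drug representation
#'
#' Atom-level GSAPooling over the substructure features:
#' `g_init = sum_p beta_p s_p` with `sum(beta) = 1`, so the initial drug
#' vector is a convex combination of its atom-centred substructures.
#'
#' @param S Substructure features (`n_atoms` x f) from [encode_molecule()].
#' @param graph The corresponding `mol_graph`.
#' @param params List with atom-pooling weights `pa_wg`, `pa_bg`, `pa_wl`,
#'   `pa_bl`.
#' @param alpha GSAPooling mixing weight.
#' @param mean_pool Uniform weights (ablation) if `TRUE`.
#' @return List with `g` (length-f vector) and `beta` (per-atom weights).
#' @export
initial_graph_repr <- function(S, graph, params, alpha = 0.6,
                               mean_pool = FALSE) {
  pool_par <- list(wg = params$pa_wg, bg = params$pa_bg,
                   wl = params$pa_wl, bl = params$pa_bl)
  beta <- gsapooling_scores(S, atom_adjacency(graph), pool_par, alpha,
                            uniform = mean_pool)
  list(g = as.vector(colSums(S * beta)), beta = beta)
}

#' DRIP: co-update of drug and relation representations
#'
#' From the shared context `o = Concat(W_h g_x, W_t g_y, r_z)` three residual
#' updates are produced: `g_x_mid = g_x + f_h(o)`, `g_y_mid = g_y + f_t(o)`
#' and `r_z_new = r_z + f_r(o)`. The updated relation vector is transient
#' (per tuple); only gradient descent changes the stored embedding table.
#'
#' @param gx_init,gy_init Initial drug representations (length f).
#' @param r_z Relation embedding (length f).
#' @param params List with `Wh`, `Wt` (f x f) and MLP weights `fh_*`, `ft_*`,
#'   `fr_*`.
#' @param no_drip If `TRUE` (the relation-ablation variant) the update is
#'   skipped entirely: mid = init and `r_z_new = r_z`.
#' @return List with `gx_mid`, `gy_mid`, `r_new`, and the context `o`.
#' @export
drip_update <- function(gx_init, gy_init, r_z, params, no_drip = FALSE) {
  if (no_drip) {
    return(list(gx_mid = gx_init, gy_mid = gy_init, r_new = r_z, o = NULL))
  }
  o <- matrix(c(as.vector(params$Wh %*% gx_init),
                as.vector(params$Wt %*% gy_init),
                r_z), nrow = 1L)
  list(
    gx_mid = gx_init + as.vector(mlp2(o, params$fh_W1, params$fh_b1,
                                      params$fh_W2, params$fh_b2)),
    gy_mid = gy_init + as.vector(mlp2(o, params$ft_W1, params$ft_b1,
                                      params$ft_W2, params$ft_b2)),
    r_new = r_z + as.vector(mlp2(o, params$fr_W1, params$fr_b1,
                                 params$fr_W2, params$fr_b2)),
    o = o
  )
}

#' SDUP: substructure importance against the partner drug
#'
#' Scores every atom-centred substructure of one drug against the partner
#' drug's mid-stage representation,
#' `mu_q = softmax_q( f_mu( Concat(W_u g_partner_mid, W_v s_q) ) )`.
#'
#' @param g_other_mid The partner drug's mid-stage representation (length f).
#' @param S Substructure features of the drug being scored (`n_atoms` x f).
#' @param params List with `Wu`, `Wv` (f' x f) and MLP weights `fmu_*`.
#' @return Numeric vector `mu` over atoms, non-negative, summing to 1.
#' @export
sdup_importance <- function(g_other_mid, S, params) {
  n <- nrow(S)
  u <- as.vector(params$Wu %*% g_other_mid)
  V <- S %*% t(params$Wv)
  Z <- cbind(matrix(rep(u, each = n), nrow = n), V)
  z <- as.vector(mlp2(Z, params$fmu_W1, params$fmu_b1,
                      params$fmu_W2, params$fmu_b2))
  e <- exp(z - max(z))
  e / sum(e)
}

#' Final drug representation by weighted substructure aggregation
#'
#' `g_fin = sum_q mu_q s_q`: a convex combination, so the final representation
#' lies inside the elementwise envelope of the substructure vectors.
#'
#' @param S Substructure features (`n_atoms` x f).
#' @param mu Importance weights from [sdup_importance()] (`sum(mu) = 1`).
#' @return Length-f vector.
#' @export
final_graph_repr <- function(S, mu) {
  as.vector(colSums(S * mu))
}

#' Full relation-aware interaction for one drug pair
#'
#' Composes the initial readouts, DRIP and the two (parameter-shared) SDUP
#' directions: `mu` for drug y is driven by `gx_mid` and vice versa; one
#' shared updated relation vector per tuple.
#'
#' @param Sx,Sy Substructure features of the two drugs.
#' @param graph_x,graph_y Their `mol_graph`s.
#' @param r_z Relation embedding (length f).
#' @param params Parameter list (see [ddi_init_params()]).
#' @param alpha,mean_pool,no_drip See the component functions.
#' @return List with `gx_fin`, `gy_fin`, `r_new`, `mu_x`, `mu_y`,
#'   `gx_init`, `gy_init`, `gx_mid`, `gy_mid`.
#' @export
rsam_forward <- function(Sx, Sy, graph_x, graph_y, r_z, params, alpha = 0.6,
                         mean_pool = FALSE, no_drip = FALSE) {
  ix <- initial_graph_repr(Sx, graph_x, params, alpha, mean_pool)
  iy <- initial_graph_repr(Sy, graph_y, params, alpha, mean_pool)
  dr <- drip_update(ix$g, iy$g, r_z, params, no_drip)
  mu_y <- sdup_importance(dr$gx_mid, Sy, params)
  mu_x <- sdup_importance(dr$gy_mid, Sx, params)
  list(
    gx_fin = final_graph_repr(Sx, mu_x),
    gy_fin = final_graph_repr(Sy, mu_y),
    r_new = dr$r_new,
    mu_x = mu_x, mu_y = mu_y,
    gx_init = ix$g, gy_init = iy$g,
    gx_mid = dr$gx_mid, gy_mid = dr$gy_mid,
    beta_x = ix$beta, beta_y = iy$beta
  )
}

#' Interaction probability for one tuple
#'
#' `P = sigmoid( r_z_new . f_w(Concat(g_x_fin, g_y_fin)) )`: the probability
#' that the pair interacts through relation z. The concatenation is
#' order-sensitive because many interaction types are directional.
#'
#' @param gx_fin,gy_fin Final drug representations (length f).
#' @param r_new Updated relation vector (length f).
#' @param params List with MLP weights `fw_W1`, `fw_b1`, `fw_W2`, `fw_b2`.
#' @return Probability in (0, 1).
#' @export
predict_interaction <- function(gx_fin, gy_fin, r_new, params) {
  h <- as.vector(mlp2(matrix(c(gx_fin, gy_fin), nrow = 1L),
                      params$fw_W1, params$fw_b1, params$fw_W2, params$fw_b2))
  1 / (1 + exp(-sum(r_new * h)))
}

#' Binary cross-entropy loss
#'
#' `Loss = -(1/J) sum( y log p + (1 - y) log(1 - p) )` with probabilities
#' clipped into `(eps, 1 - eps)` for numerical safety.
#'
#' @param probabilities Predicted probabilities.
#' @param labels 0/1 labels of the same length.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
bce_loss <- function(probabilities, labels, eps = 1e-7) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have equal length", call. = FALSE)
  }
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
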