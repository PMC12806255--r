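# Model assembly and training: parameter initialization, the batched
# autodiff forward pass, Adam with an exponentially decaying learning rate,
# prediction, evaluation and attribution export.

#' Training configuration
#'
#' Defaults follow the published configuration for full-scale data
#' (T = 8 radii, 128-dimensional substructure features, learning rate 1e-3
#' decayed by 0.96 per epoch, batches of 256, 100 epochs); desk-scale
#' examples and tests shrink `hidden`, `T` and `epochs`.
#'
#' @param T Number of message-passing radii (T >= 1).
#' @param hidden Hidden width f of edge states and substructure features.
#' @param att_hidden Width f' of the radius-attention / SDUP projections
#'   (defaults to `hidden`).
#' @param alpha GSAPooling mixing weight in `[0, 1]`.
#' @param lr Initial Adam learning rate.
#' @param decay Per-epoch exponential decay base of the learning rate.
#' @param batch_size Tuples per mini-batch.
#' @param epochs Training epochs.
#' @param dropout Dropout rate (applied after the substructure MLP and inside
#'   the prediction head; intended for inductive runs), 0 disables.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param mean_pool Ablation: replace all pooling weights by exact uniforms.
#' @param no_drip Ablation: disable the relation-aware co-update (mid = init,
#'   relation embedding passed through unchanged).
#' @return A list of class `ddi_config`.
#' @export
ddi_config <- function(T = 8L, hidden = 128L, att_hidden = hidden,
                       alpha = 0.6, lr = 1e-3, decay = 0.96,
                       batch_size = 256L, epochs = 100L, dropout = 0,
                       seed = 1L, mean_pool = FALSE, no_drip = FALSE) {
  stopifnot(T >= 1L, hidden >= 1L, att_hidden >= 1L,
            alpha >= 0, alpha <= 1, lr > 0, decay > 0, decay <= 1,
            batch_size >= 1L, epochs >= 1L, dropout >= 0, dropout < 1)
  structure(list(T = as.integer(T), hidden = as.integer(hidden),
                 att_hidden = as.integer(att_hidden), alpha = alpha,
                 lr = lr, decay = decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 seed = as.integer(seed), mean_pool = isTRUE(mean_pool),
                 no_drip = isTRUE(no_drip)),
            class = "ddi_config")
}

#' Learning-rate schedule
#'
#' The learning rate at epoch `epoch` (0-based) is `lr * decay^epoch`, the
#' exponentially decaying schedule used for training.
#'
#' @param lr Initial learning rate.
#' @param epoch 0-based epoch index (vectorized).
#' @param decay Decay base, default 0.96.
#' @return Numeric vector of learning rates.
#' @export
lr_schedule <- function(lr, epoch, decay = 0.96) {
  lr * decay^epoch
}

glorot <- function(nout, nin) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -a, a), nout, nin)
}

#' Initialize all model parameters
#'
#' Glorot-uniform weights and zero biases for the encoder, the relation-aware
#' interaction module, the relation embedding table and the prediction head.
#'
#' @param cfg A [ddi_config()].
#' @param n_relations Size of the relation vocabulary.
#' @param d,dp Atom / bond feature dimensions (defaults to the package
#'   encoding).
#' @return Named list of parameter matrices, shaped (out x in).
#' @export
ddi_init_params <- function(cfg, n_relations, d = atom_feature_dim(),
                            dp = bond_feature_dim()) {
  f <- cfg$hidden; fp <- cfg$att_hidden; Tt <- cfg$T
  set.seed(cfg$seed %% .Machine$integer.max)
  list(
    Wp = glorot(f, d), Wq = glorot(f, d), Wpq = glorot(f, dp),
    Wm = glorot(f, f),
    pb_wg = glorot(f, 1L), pb_bg = matrix(0, 1L, 1L),
    pb_wl = glorot(f, 1L), pb_bl = matrix(0, 1L, 1L),
    Wb = glorot(fp, f), be = matrix(0, 1L, fp), C = glorot(Tt, fp),
    Wproj = glorot(f, d),
    fs_W1 = glorot(f, f), fs_b1 = matrix(0, 1L, f),
    fs_W2 = glorot(f, f), fs_b2 = matrix(0, 1L, f),
    pa_wg = glorot(f, 1L), pa_bg = matrix(0, 1L, 1L),
    pa_wl = glorot(f, 1L), pa_bl = matrix(0, 1L, 1L),
    Wh = glorot(f, f), Wt = glorot(f, f),
    Rtab = glorot(n_relations, f),
    fh_W1 = glorot(f, 3L * f), fh_b1 = matrix(0, 1L, f),
    fh_W2 = glorot(f, f), fh_b2 = matrix(0, 1L, f),
    ft_W1 = glorot(f, 3L * f), ft_b1 = matrix(0, 1L, f),
    ft_W2 = glorot(f, f), ft_b2 = matrix(0, 1L, f),
    fr_W1 = glorot(f, 3L * f), fr_b1 = matrix(0, 1L, f),
    fr_W2 = glorot(f, f), fr_b2 = matrix(0, 1L, f),
    Wu = glorot(fp, f), Wv = glorot(fp, f),
    fmu_W1 = glorot(fp, 2L * fp), fmu_b1 = matrix(0, 1L, fp),
    fmu_W2 = glorot(1L, fp), fmu_b2 = matrix(0, 1L, 1L),
    fw_W1 = glorot(f, 2L * f), fw_b1 = matrix(0, 1L, f),
    fw_W2 = glorot(f, f), fw_b2 = matrix(0, 1L, f)
  )
}

# push every parameter onto a tape; returns named list of node ids
push_params <- function(tp, params) {
  lapply(params, function(w) ad_leaf(tp, w))
}

# uniform pooling weights (1 / graph size) as a constant column, used by the
# mean-pooling ablation; groups indexes rows into graphs
uniform_weights <- function(groups, G) {
  cnt <- tabulate(groups, nbins = G)
  matrix(1 / cnt[groups], ncol = 1L)
}

# GSAPooling scores on the tape: alpha * L(Xw_g + b_g) + (1-alpha) * (Xw_l + b_l),
# softmax within groups
tape_pool_scores <- function(tp, P, Xn, L, groups, G, alpha, prefix,
                             uniform = FALSE) {
  if (uniform) return(ad_leaf(tp, uniform_weights(groups, G)))
  gcn <- ad_spmm(tp, L, ad_addbias(tp, ad_mm(tp, Xn, P[[paste0(prefix, "_wg")]]),
                                   P[[paste0(prefix, "_bg")]]))
  lin <- ad_addbias(tp, ad_mm(tp, Xn, P[[paste0(prefix, "_wl")]]),
                    P[[paste0(prefix, "_bl")]])
  z <- ad_add(tp, ad_smul(tp, gcn, alpha), ad_smul(tp, lin, 1 - alpha))
  ad_softmax_groups(tp, z, groups, G)
}

# Full batched forward pass on the tape.
#   bd  : batch_graphs() output for the drug library in play
#   tix : list(xg, yg, rel, label) with graph indices per tuple plus the
#         precomputed SDUP expansion indices
# Returns named node ids for every quantity the callers need.
tape_forward <- function(tp, P, bd, tix, cfg, drop_masks = NULL) {
  G <- bd$n_graphs
  f <- cfg$hidden
  Xn <- ad_leaf(tp, bd$X)
  J <- length(tix$xg)

  # ---- encoder -----------------------------------------------------------
  h0 <- if (bd$n_edges > 0L) {
    En <- ad_leaf(tp, bd$E)
    ad_smul(tp, ad_add(tp, ad_add(tp,
      ad_mmt(tp, ad_rows(tp, Xn, bd$src), P$Wp),
      ad_mmt(tp, ad_rows(tp, Xn, bd$dst), P$Wq)),
      ad_mmt(tp, En, P$Wpq)), 1 / 3)
  } else {
    ad_leaf(tp, matrix(0, 0L, f))
  }

  h_steps <- vector("list", cfg$T)
  e_cols <- vector("list", cfg$T)
  beta_steps <- vector("list", cfg$T)
  h_prev <- h0
  for (t in seq_len(cfg$T)) {
    h_t <- if (bd$n_edges > 0L) {
      ad_relu(tp, ad_add(tp, h0,
        ad_mmt(tp, ad_spmm(tp, bd$A_msg, h_prev), P$Wm)))
    } else {
      h0
    }
    h_steps[[t]] <- h_t
    if (bd$n_edges > 0L) {
      beta_t <- tape_pool_scores(tp, P, h_t, bd$L_dir, bd$edge_graph, G,
                                 cfg$alpha, "pb", uniform = cfg$mean_pool)
      beta_steps[[t]] <- beta_t
      gb_t <- ad_gsum(tp, ad_colscale(tp, h_t, beta_t), bd$edge_graph, G)
    } else {
      gb_t <- ad_leaf(tp, matrix(0, G, f))
    }
    ct <- ad_rows(tp, P$C, t)
    e_cols[[t]] <- ad_mmt(tp, ad_tanh(tp, ad_addbias(tp, ad_mmt(tp, gb_t, P$Wb),
                                                     P$be)), ct)
    h_prev <- h_t
  }

  # zero-bond graphs get all-zero scores, hence exactly uniform lambda
  e_mat <- ad_colscale(tp, do.call(ad_cbind, c(list(tp), e_cols)),
                       ad_leaf(tp, matrix(as.numeric(bd$has_bonds), ncol = 1L)))
  lambda <- ad_softmax_rows(tp, e_mat)                      # G x T

  h_fin <- NULL
  for (t in seq_len(cfg$T)) {
    lam_e <- ad_rows(tp, ad_col(tp, lambda, t), bd$edge_graph)
    term <- ad_colscale(tp, h_steps[[t]], lam_e)
    h_fin <- if (is.null(h_fin)) term else ad_add(tp, h_fin, term)
  }

  S <- ad_mlp2(tp, ad_add(tp, ad_mmt(tp, Xn, P$Wproj),
                          ad_spmm(tp, bd$A_in, h_fin)),
               P$fs_W1, P$fs_b1, P$fs_W2, P$fs_b2)
  if (!is.null(drop_masks$fs)) S <- ad_mul(tp, S, drop_masks$fs)

  # ---- initial graph representations (atom-level GSAPooling) -------------
  beta_atom <- tape_pool_scores(tp, P, S, bd$L_atom, bd$atom_graph, G,
                                cfg$alpha, "pa", uniform = cfg$mean_pool)
  Ginit <- ad_gsum(tp, ad_colscale(tp, S, beta_atom), bd$atom_graph, G)

  # ---- DRIP --------------------------------------------------------------
  GX <- ad_rows(tp, Ginit, tix$xg)
  GY <- ad_rows(tp, Ginit, tix$yg)
  Rz <- ad_rows(tp, P$Rtab, tix$rel)
  if (cfg$no_drip) {
    gx_mid <- GX; gy_mid <- GY; r_new <- Rz
  } else {
    o <- ad_cbind(tp, ad_mmt(tp, GX, P$Wh), ad_mmt(tp, GY, P$Wt), Rz)
    gx_mid <- ad_add(tp, GX, ad_mlp2(tp, o, P$fh_W1, P$fh_b1, P$fh_W2, P$fh_b2))
    gy_mid <- ad_add(tp, GY, ad_mlp2(tp, o, P$ft_W1, P$ft_b1, P$ft_W2, P$ft_b2))
    r_new <- ad_add(tp, Rz, ad_mlp2(tp, o, P$fr_W1, P$fr_b1, P$fr_W2, P$fr_b2))
  }

  # ---- SDUP (shared parameters, two directions) --------------------------
  sdup <- function(g_other_mid, atom_idx, grp) {
    U <- ad_rows(tp, ad_mmt(tp, g_other_mid, P$Wu), grp)
    Sv <- ad_rows(tp, S, atom_idx)
    V <- ad_mmt(tp, Sv, P$Wv)
    z <- ad_mlp2(tp, ad_cbind(tp, U, V), P$fmu_W1, P$fmu_b1, P$fmu_W2, P$fmu_b2)
    mu <- ad_softmax_groups(tp, z, grp, J)
    gfin <- ad_gsum(tp, ad_colscale(tp, Sv, mu), grp, J)
    list(mu = mu, gfin = gfin)
  }
  sy <- sdup(gx_mid, tix$y_atoms, tix$y_grp)
  sx <- sdup(gy_mid, tix$x_atoms, tix$x_grp)

  # ---- prediction head ---------------------------------------------------
  hw <- ad_mlp2(tp, ad_cbind(tp, sx$gfin, sy$gfin),
                P$fw_W1, P$fw_b1, P$fw_W2, P$fw_b2,
                drop_mask = drop_masks$fw)
  prob <- ad_sigmoid(tp, ad_rowsum(tp, ad_mul(tp, r_new, hw)))

  eps <- 1e-7
  pc <- ad_clip(tp, prob, eps, 1 - eps)
  y <- ad_leaf(tp, matrix(tix$label, ncol = 1L))
  ycomp <- ad_leaf(tp, matrix(1 - tix$label, ncol = 1L))
  ones <- ad_leaf(tp, matrix(1, J, 1L))
  ll <- ad_add(tp, ad_mul(tp, y, ad_log(tp, pc)),
               ad_mul(tp, ycomp, ad_log(tp, ad_sub(tp, ones, pc))))
  loss <- ad_smul(tp, ad_sum(tp, ll), -1 / J)

  list(loss = loss, prob = prob, lambda = lambda, S = S,
       mu_x = sx$mu, mu_y = sy$mu, beta_atom = beta_atom,
       beta_steps = beta_steps, Ginit = Ginit,
       gx_mid = gx_mid, gy_mid = gy_mid, GX = GX, GY = GY, r_new = r_new,
       gx_fin = sx$gfin, gy_fin = sy$gfin)
}

# tuple-level index bundle for tape_forward
build_tuple_indices <- function(xg, yg, rel, label, bd) {
  x_atoms <- unlist(bd$atoms_of[xg], use.names = FALSE)
  y_atoms <- unlist(bd$atoms_of[yg], use.names = FALSE)
  sizes_x <- lengths(bd$atoms_of)[xg]
  sizes_y <- lengths(bd$atoms_of)[yg]
  list(
    xg = xg, yg = yg, rel = rel, label = label,
    x_atoms = x_atoms, x_grp = rep(seq_along(xg), sizes_x),
    y_atoms = y_atoms, y_grp = rep(seq_along(yg), sizes_y)
  )
}

# loss and gradients for one batch; the unit the optimizer consumes and the
# quantity the finite-difference test checks
ddi_loss_grads <- function(params, bd, tix, cfg, drop_masks = NULL,
                           want_grads = TRUE) {
  tp <- ad_tape()
  P <- push_params(tp, params)
  out <- tape_forward(tp, P, bd, tix, cfg, drop_masks)
  loss <- as.vector(ad_val(tp, out$loss))
  if (!want_grads) {
    return(list(loss = loss, prob = as.vector(ad_val(tp, out$prob))))
  }
  grads_all <- ad_backward(tp, out$loss)
  grads <- lapply(P, function(i) {
    g <- grads_all[[i]]
    if (is.null(g)) matrix(0, nrow(ad_val(tp, i)), ncol(ad_val(tp, i))) else g
  })
  list(loss = loss, prob = as.vector(ad_val(tp, out$prob)), grads = grads)
}

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Fit the DDI prediction model
#'
#' Trains the full architecture (directed-edge encoder, relation-aware
#' interaction module and probabilistic head) on labelled DDI tuples with
#' Adam, mini-batches and the `lr * decay^epoch` learning-rate schedule.
#' All randomness (initialization, shuffling, dropout) derives from
#' `config$seed`.
#'
#' @param tuples Tibble with columns `drug_x`, `drug_y`, `relation`,
#'   `label` (0/1).
#' @param drugs Tibble with columns `drug_id`, `smiles`; must cover every
#'   drug mentioned in `tuples` (and may include extra drugs that prediction
#'   will later need).
#' @param config A [ddi_config()].
#' @param relations Optional full relation vocabulary (character/integer
#'   vector); defaults to the relations observed in `tuples`.
#' @param verbose Print per-epoch loss and learning rate.
#' @return An object of class `ddi_fit` holding the trained parameters, the
#'   configuration, vocabulary maps, the drug graphs and a per-epoch history
#'   tibble (`epoch`, `loss`, `lr`).
#' @export
ddi_fit <- function(tuples, drugs, config = ddi_config(),
                    relations = NULL, verbose = FALSE) {
  stopifnot(all(c("drug_x", "drug_y", "relation", "label") %in% names(tuples)),
            all(c("drug_id", "smiles") %in% names(drugs)))
  if (nrow(tuples) == 0L) stop("no training tuples supplied", call. = FALSE)
  if (anyDuplicated(drugs$drug_id)) stop("duplicate drug_id", call. = FALSE)

  missing <- setdiff(unique(c(tuples$drug_x, tuples$drug_y)), drugs$drug_id)
  if (length(missing) > 0L) {
    stop("tuples mention drugs absent from the drug table: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(tuples$drug_x == tuples$drug_y)) {
    stop("self-pair tuples (drug_x == drug_y) are not allowed", call. = FALSE)
  }

  rel_vocab <- if (is.null(relations)) sort(unique(tuples$relation)) else relations
  rel_idx <- match(tuples$relation, rel_vocab)
  if (anyNA(rel_idx)) stop("tuple relation outside the vocabulary", call. = FALSE)

  graphs <- lapply(drugs$smiles, parse_smiles)
  bd <- batch_graphs(graphs)
  drug_index <- stats::setNames(seq_len(nrow(drugs)), drugs$drug_id)

  params <- ddi_init_params(config, n_relations = length(rel_vocab))
  state <- adam_init(params)

  xg_all <- drug_index[tuples$drug_x]
  yg_all <- drug_index[tuples$drug_y]
  lab_all <- as.numeric(tuples$label)
  J <- nrow(tuples)

  history <- vector("list", config$epochs)
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr_e <- lr_schedule(config$lr, epoch, config$decay)
    perm <- sample.int(J)
    starts <- seq(1L, J, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, J)]
      tix <- build_tuple_indices(xg_all[idx], yg_all[idx], rel_idx[idx],
                                 lab_all[idx], bd)
      masks <- make_dropout_masks(config, bd$n_atoms, length(idx))
      lg <- ddi_loss_grads(params, bd, tix, config, masks)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d (lr %.3g); aborting",
                     epoch, lr_e), call. = FALSE)
      }
      upd <- adam_step(params, lg$grads, state, lr_e)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + lg$loss * length(idx)
    }
    history[[epoch + 1L]] <- tibble::tibble(epoch = epoch,
                                            loss = epoch_loss / J, lr = lr_e)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  lr %.3g", epoch,
                      epoch_loss / J, lr_e))
    }
  }

  structure(list(
    params = params, config = config, relations = rel_vocab,
    drugs = drugs, graphs = graphs, bd = bd, drug_index = drug_index,
    history = dplyr::bind_rows(history)
  ), class = "ddi_fit")
}

make_dropout_masks <- function(cfg, n_atoms, n_tuples) {
  if (cfg$dropout <= 0) return(NULL)
  keep <- 1 - cfg$dropout
  list(
    fs = matrix(stats::rbinom(n_atoms * cfg$hidden, 1L, keep) / keep,
                n_atoms, cfg$hidden),
    fw = matrix(stats::rbinom(n_tuples * cfg$hidden, 1L, keep) / keep,
                n_tuples, cfg$hidden)
  )
}

# forward pass over arbitrary tuples with a fitted model (dropout off)
fit_forward <- function(object, tuples, nodes = c("prob")) {
  drug_index <- object$drug_index
  missing <- setdiff(unique(c(tuples$drug_x, tuples$drug_y)),
                     names(drug_index))
  if (length(missing) > 0L) {
    stop("unknown drug id(s): ", paste(utils::head(missing, 5L),
                                       collapse = ", "), call. = FALSE)
  }
  rel <- match(tuples$relation, object$relations)
  if (anyNA(rel)) stop("unknown relation id", call. = FALSE)
  label <- if ("label" %in% names(tuples)) as.numeric(tuples$label) else
    rep(0, nrow(tuples))
  tix <- build_tuple_indices(drug_index[tuples$drug_x],
                             drug_index[tuples$drug_y], rel, label, object$bd)
  tp <- ad_tape()
  P <- push_params(tp, object$params)
  out <- tape_forward(tp, P, object$bd, tix, object$config, NULL)
  res <- lapply(out[nodes], function(i) ad_val(tp, i))
  res$tix <- tix
  res
}

#' Predict interaction probabilities
#'
#' @param object A fitted `ddi_fit`.
#' @param tuples Tibble with `drug_x`, `drug_y`, `relation` (labels, if
#'   present, are carried through).
#' @param ... Unused.
#' @return The input tibble with a `.prob` column appended.
#' @export
predict.ddi_fit <- function(object, tuples, ...) {
  res <- fit_forward(object, tuples, "prob")
  dplyr::mutate(tuples, .prob = as.vector(res$prob))
}

#' Evaluate a fitted model on labelled tuples
#'
#' Computes ACC, AUC, F1, precision, recall and average precision from the
#' predicted probabilities (threshold 0.5 for the thresholded metrics). With
#' a single-class label set the ranking metrics are `NA`.
#'
#' @param object A fitted `ddi_fit`.
#' @param tuples Labelled tuples.
#' @return One-row tibble with the six metrics and `n`.
#' @export
ddi_evaluate <- function(object, tuples) {
  stopifnot("label" %in% names(tuples))
  pred <- predict(object, tuples)
  ddi_metrics(pred$label, pred$.prob)
}

#' Per-atom and per-radius attribution for drug pairs
#'
#' For every tuple, exports the substructure-importance weights `mu` of each
#' atom of both drugs (the quantity that highlights which substructure drives
#' the predicted interaction) together with the radius-attention weights
#' `lambda` of each drug, which size the substructure around the top atom.
#'
#' @param object A fitted `ddi_fit`.
#' @param tuples Tibble with `drug_x`, `drug_y`, `relation`.
#' @return A list of class `ddi_explain` with tibbles `atoms` (columns
#'   `pair`, `role`, `drug_id`, `atom`, `element`, `mu`) and `radii`
#'   (`pair`, `role`, `drug_id`, `radius`, `lambda`), plus `prob` per pair.
#' @export
ddi_explain <- function(object, tuples) {
  res <- fit_forward(object, tuples, c("prob", "lambda", "mu_x", "mu_y"))
  tix <- res$tix
  J <- nrow(tuples)

  atom_tbl <- function(role, drug_ids, atom_idx, grp, mu) {
    gi <- object$drug_index[drug_ids]
    tibble::tibble(
      pair = grp,
      role = role,
      drug_id = drug_ids[grp],
      atom = local_atom_index(object$bd, atom_idx),
      element = unlist(lapply(object$graphs[gi], function(g) g$atoms$element),
                       use.names = FALSE),
      mu = as.vector(mu)
    )
  }
  atoms <- dplyr::bind_rows(
    atom_tbl("x", tuples$drug_x, tix$x_atoms, tix$x_grp, res$mu_x),
    atom_tbl("y", tuples$drug_y, tix$y_atoms, tix$y_grp, res$mu_y)
  )
  atoms <- dplyr::arrange(atoms, .data$pair, .data$role, .data$atom)

  lam <- res$lambda
  radii <- dplyr::bind_rows(lapply(seq_len(J), function(j) {
    tibble::tibble(
      pair = j,
      role = rep(c("x", "y"), each = ncol(lam)),
      drug_id = rep(c(tuples$drug_x[j], tuples$drug_y[j]), each = ncol(lam)),
      radius = rep(seq_len(ncol(lam)), 2L),
      lambda = c(lam[tix$xg[j], ], lam[tix$yg[j], ])
    )
  }))

  structure(list(atoms = atoms, radii = radii,
                 prob = as.vector(res$prob), tuples = tuples),
            class = "ddi_explain")
}

# global atom index -> index within its own molecule
local_atom_index <- function(bd, atom_idx) {
  offsets <- cumsum(c(0L, lengths(bd$atoms_of)))
  atom_idx - offsets[bd$atom_graph[atom_idx]]
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<ddi_fit> %d relations, %d drugs\n",
    "  T = %d radii, hidden = %d, alpha = %.2f%s%s\n",
    "  final training loss %.4f after %d epochs\n"),
    length(x$relations), nrow(x$drugs), x$config$T, x$config$hidden,
    x$config$alpha,
    if (x$config$mean_pool) ", mean-pool ablation" else "",
    if (x$config$no_drip) ", no-DRIP ablation" else "",
    utils::tail(x$history$loss, 1L), nrow(x$history)))
  invisible(x)
}

#' @export
print.ddi_explain <- function(x, ...) {
  cat(sprintf("<ddi_explain> %d pair(s); top atoms by mu:\n",
              length(x$prob)))
  top <- dplyr::slice_max(dplyr::group_by(x$atoms, .data$pair, .data$role),
                          .data$mu, n = 1L, with_ties = FALSE)
  print(dplyr::ungroup(top))
  invisible(x)
}
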