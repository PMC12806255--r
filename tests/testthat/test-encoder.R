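# Encoder operations: hand-computed oracles, the non-backtracking walk
# oracle, normalization invariants and permutation equivariance.

test_that("edge initialization reproduces hand-computed values", {
  # f = 1 scalar maps on a single-bond toy: (2*1 + 3*1 + 6*0.5)/3 = 8/3
  g <- parse_smiles("CC")
  g$X <- matrix(1, 2L, 1L)
  de <- build_directed_edges(g)
  de$E <- matrix(0.5, 2L, 1L)
  params <- list(Wp = matrix(2), Wq = matrix(3), Wpq = matrix(6))
  h0 <- init_edge_hidden(g, de, params)
  expect_equal(as.vector(h0), rep((2 + 3 + 3) / 3, 2L))

  # all-zero features give zero states
  g$X <- matrix(0, 2L, 1L); de$E <- matrix(0, 2L, 1L)
  expect_equal(init_edge_hidden(g, de, params), matrix(0, 2L, 1L))

  # identity maps on equal vectors return the vector itself
  g2 <- parse_smiles("CC")
  f <- 3L
  g2$X <- matrix(rep(c(0.3, -1, 2), each = 2L), 2L)
  de2 <- build_directed_edges(g2)
  de2$E <- g2$X
  idp <- list(Wp = diag(f), Wq = diag(f), Wpq = diag(f))
  expect_equal(init_edge_hidden(g2, de2, idp), g2$X)

  # dimension mismatch is a configuration error
  expect_error(init_edge_hidden(parse_smiles("CC"),
                                build_directed_edges(parse_smiles("CC")),
                                params), "dimensions")
})

test_that("message passing boundary cases", {
  g <- parse_smiles("CCC")   # chain a-b-c
  de <- build_directed_edges(g)
  f <- 2L
  h0 <- matrix(rnorm(de$n_edges * f), de$n_edges, f)
  # W_m = 0: every step is just act(h0)
  h1 <- propagate_edge_messages(h0, h0, de, matrix(0, f, f))
  expect_equal(h1, pmax(h0, 0))
  # edge a->b has no incoming edges at a besides the excluded reverse
  Wm <- diag(f)
  h1 <- propagate_edge_messages(h0, h0, de, Wm, activation = "identity")
  e_ab <- which(de$src == 1L & de$dst == 2L)
  expect_equal(h1[e_ab, ], h0[e_ab, ])
})

test_that("message passing agrees with the non-backtracking walk oracle", {
  set.seed(11)
  for (smi in small_molecules) {
    g <- parse_smiles(smi)
    de <- build_directed_edges(g)
    if (de$n_edges == 0L) next
    for (T_steps in 1:3) {
      h0 <- matrix(rnorm(de$n_edges), ncol = 1L)
      Wm <- matrix(runif(1, 0.5, 1.5))
      expect_equal(propagate_T(g, h0, Wm, T_steps),
                   walk_oracle(g, h0, Wm, T_steps),
                   tolerance = 1e-10, info = paste(smi, T_steps))
    }
  }
  # and once with f = 3 and a full message matrix
  g <- parse_smiles("CC1CC1")
  de <- build_directed_edges(g)
  h0 <- matrix(rnorm(de$n_edges * 3L), de$n_edges, 3L)
  Wm <- matrix(rnorm(9L) / 2, 3L, 3L)
  expect_equal(propagate_T(g, h0, Wm, 3L), walk_oracle(g, h0, Wm, 3L),
               tolerance = 1e-10)
})

test_that("pooling scores are a proper distribution and honor alpha = 0", {
  g <- parse_smiles("C1CC1")
  de <- build_directed_edges(g)
  Ad <- molddi:::directed_line_adj(de, g)
  X <- matrix(rnorm(de$n_edges * 3L), de$n_edges, 3L)
  params <- list(wg = matrix(rnorm(3L), ncol = 1L), bg = matrix(0.2),
                 wl = matrix(0, 3L, 1L), bl = matrix(1))
  # alpha = 0 with a constant linear score: exactly uniform
  b0 <- gsapooling_scores(X, Ad, params, alpha = 0)
  expect_equal(b0, rep(1 / de$n_edges, de$n_edges))
  # any alpha: sums to one, non-negative
  b <- gsapooling_scores(X, Ad, params, alpha = 0.6)
  expect_equal(sum(b), 1)
  expect_true(all(b >= 0))
  # empty graph: empty score vector
  g1 <- parse_smiles("C")
  expect_identical(gsapooling_scores(matrix(0, 0L, 3L),
                                     matrix(0, 0L, 0L), params), numeric(0))
  # uniform flag bypasses the scores exactly
  expect_identical(gsapooling_scores(X, Ad, params, uniform = TRUE),
                   rep(1 / de$n_edges, de$n_edges))
})

test_that("bond-level readout is the beta-weighted edge sum", {
  # single bond: two directed edges with weights beta, 1 - beta
  h <- matrix(c(2, 6), 2L, 1L)
  expect_equal(bond_level_readout(h, c(0.25, 0.75)), 0.25 * 2 + 0.75 * 6)
  # uniform weights reduce to the mean
  h4 <- matrix(1:4, 4L, 1L)
  expect_equal(bond_level_readout(h4, rep(0.25, 4L)), mean(1:4))
  # propane hand evaluation, 4 directed edges
  hp <- matrix(c(1, 2, 3, 4), 4L, 1L)
  bp <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(bond_level_readout(hp, bp), sum(hp * bp))
  # zero-bond graph: zero vector of width f
  expect_equal(bond_level_readout(matrix(0, 0L, 3L), numeric(0), f = 3L),
               rep(0, 3L))
})

test_that("radius attention reproduces closed-form softmax values", {
  f <- 2L; fp <- 2L
  # T = 1: lambda = 1 regardless of parameters
  params <- list(Wb = matrix(rnorm(fp * f), fp, f), be = matrix(0, 1L, fp),
                 C = matrix(rnorm(fp), 1L, fp))
  att <- radius_attention(list(rnorm(f)), params)
  expect_equal(att$lambda, 1)
  # identical readouts and shared c: uniform weights
  params$C <- matrix(rep(c(0.3, -0.2), each = 3L), 3L, fp)
  gb <- rnorm(f)
  att <- radius_attention(list(gb, gb, gb), params)
  expect_equal(att$lambda, rep(1 / 3, 3L))
  # e = (ln 1, ln 3) must give lambda = (0.25, 0.75); engineer it with
  # Wb = 0 so tanh(be) is shared, and c^(t) scaled to hit the scores
  be <- matrix(c(1, 1), 1L, 2L)
  tb <- tanh(1)
  C <- matrix(c(0, 0, log(3) / (2 * tb), log(3) / (2 * tb)), 2L, 2L,
              byrow = TRUE)
  params2 <- list(Wb = matrix(0, 2L, f), be = be, C = C)
  att2 <- radius_attention(list(rnorm(f), rnorm(f)), params2)
  expect_equal(att2$e, c(0, log(3)))
  expect_equal(att2$lambda, c(0.25, 0.75))
})

test_that("radius aggregation is the lambda-convex combination", {
  h1 <- matrix(0, 2L, 1L); h2 <- matrix(4, 2L, 1L)
  expect_equal(aggregate_radii(list(h1, h2), c(0.25, 0.75)),
               matrix(3, 2L, 1L))
  # one-hot lambda selects a single radius
  expect_equal(aggregate_radii(list(h1, h2), c(0, 1)), h2)
  # equal states are a fixed point
  expect_equal(aggregate_radii(list(h2, h2, h2), c(0.2, 0.5, 0.3)), h2)
})

test_that("substructure features aggregate incoming edges per atom", {
  g <- parse_smiles("CCC")
  de <- build_directed_edges(g)
  f <- 1L
  # f_s = identity via W1 = I on the positive part, W2 = I, biases large-0
  # instead: use explicit linear MLP with W1 = I, b1 = big to stay positive
  big <- 100
  params <- list(Wproj = matrix(1, f, atom_feature_dim()),
                 fs_W1 = diag(f), fs_b1 = matrix(big, 1L, f),
                 fs_W2 = diag(f), fs_b2 = matrix(-big, 1L, f))
  h <- matrix(c(1, 2, 3, 4), de$n_edges, f)  # edges: 1-2, 2-3, 2-1, 3-2
  S <- node_substructure_features(g, de, h, params)
  proj <- g$X %*% t(params$Wproj)
  # incoming of atom 2: edges 1->2 and 3->2
  inc2 <- sum(h[de$dst == 2L, ])
  expect_equal(S[2, ], proj[2, ] + inc2)
  # terminal atom 1 receives only 2->1
  expect_equal(S[1, ], proj[1, ] + h[de$src == 2L & de$dst == 1L, ])
  # isolated atom: only its own projected features
  g1 <- parse_smiles("C")
  de1 <- build_directed_edges(g1)
  S1 <- node_substructure_features(g1, de1, matrix(0, 0L, f), params)
  expect_equal(S1, g1$X %*% t(params$Wproj))
})

test_that("full encoder output is shaped and normalized correctly", {
  cfg <- tiny_config(T = 3L, hidden = 5L, att = 4L)
  params <- ddi_init_params(cfg, n_relations = 2L)
  for (smi in c("CCS(=O)(=O)NC", "c1ccncc1", "C", "[Ca+2].[O-]C([O-])=O")) {
    g <- parse_smiles(smi)
    enc <- encode_molecule(g, params, cfg$T, cfg$alpha)
    expect_identical(dim(enc$S), c(g$n_atoms, cfg$hidden), info = smi)
    expect_equal(sum(enc$lambda), 1, tolerance = 1e-9, info = smi)
    expect_true(all(enc$lambda >= 0), info = smi)
    for (b in enc$beta) {
      if (length(b) > 0L) expect_equal(sum(b), 1, tolerance = 1e-9, info = smi)
    }
  }
  # zero-bond molecule: uniform lambda by convention
  enc0 <- encode_molecule(parse_smiles("C"), params, cfg$T, cfg$alpha)
  expect_equal(enc0$lambda, rep(1 / 3, 3L))
})

test_that("encoder is equivariant under atom permutation", {
  cfg <- tiny_config(T = 2L, hidden = 4L, att = 3L)
  params <- ddi_init_params(cfg, n_relations = 2L)
  # the same molecule written with different atom orders
  variants <- list(
    c("CCO", "OCC"),
    c("CC(=O)O", "OC(C)=O"),
    c("CC(C)N", "NC(C)C")
  )
  for (v in variants) {
    g1 <- parse_smiles(v[1]); g2 <- parse_smiles(v[2])
    e1 <- encode_molecule(g1, params, cfg$T, cfg$alpha)
    e2 <- encode_molecule(g2, params, cfg$T, cfg$alpha)
    # lambda and readouts are permutation-invariant
    expect_equal(e1$lambda, e2$lambda, tolerance = 1e-9, info = v[1])
    # substructure features permute with the atoms: match rows by sorting
    expect_equal(apply(e1$S, 2L, sort), apply(e2$S, 2L, sort),
                 tolerance = 1e-8, info = v[1])
  }
})

test_that("batched tape forward equals the straight-line per-molecule path", {
  cfg <- tiny_config(T = 3L, hidden = 5L, att = 4L, seed = 21L)
  params <- ddi_init_params(cfg, n_relations = 3L)
  smi <- c("CCS(=O)(=O)NC", "Cc1ccncc1")
  graphs <- lapply(smi, parse_smiles)
  e1 <- encode_molecule(graphs[[1]], params, cfg$T, cfg$alpha)
  e2 <- encode_molecule(graphs[[2]], params, cfg$T, cfg$alpha)
  rf <- rsam_forward(e1$S, e2$S, graphs[[1]], graphs[[2]], params$Rtab[2, ],
                     params, cfg$alpha)
  p_pure <- predict_interaction(rf$gx_fin, rf$gy_fin, rf$r_new, params)

  bd <- molddi:::batch_graphs(graphs)
  tix <- molddi:::build_tuple_indices(1L, 2L, 2L, 1, bd)
  tp <- molddi:::ad_tape()
  P <- molddi:::push_params(tp, params)
  out <- molddi:::tape_forward(tp, P, bd, tix, cfg)
  expect_equal(as.vector(molddi:::ad_val(tp, out$prob)), p_pure,
               tolerance = 1e-12)
  expect_equal(molddi:::ad_val(tp, out$S), rbind(e1$S, e2$S),
               tolerance = 1e-12)
  expect_equal(molddi:::ad_val(tp, out$lambda), rbind(e1$lambda, e2$lambda),
               tolerance = 1e-12)
  expect_equal(as.vector(molddi:::ad_val(tp, out$mu_x)), rf$mu_x,
               tolerance = 1e-12)
  expect_equal(as.vector(molddi:::ad_val(tp, out$mu_y)), rf$mu_y,
               tolerance = 1e-12)
})
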