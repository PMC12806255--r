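# Relation-aware interaction module: hand oracles and structural properties.

zero_mlps <- function(params) {
  # zero the second-layer weights and biases of f_h/f_t/f_r so their output
  # is identically zero while the first layer stays arbitrary
  for (p in c("fh", "ft", "fr")) {
    params[[paste0(p, "_W2")]][] <- 0
    params[[paste0(p, "_b2")]][] <- 0
  }
  params
}

test_that("initial graph representation is the beta-weighted atom sum", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  # single-atom drug: g_init = s_1 regardless of pooling parameters
  g1 <- parse_smiles("C")
  S1 <- matrix(rnorm(cfg$hidden), 1L)
  ir <- initial_graph_repr(S1, g1, params, cfg$alpha)
  expect_equal(ir$g, as.vector(S1))
  expect_equal(ir$beta, 1)
  # uniform pooling: the mean of substructure vectors
  g3 <- parse_smiles("CCC")
  S3 <- matrix(rnorm(3L * cfg$hidden), 3L)
  irm <- initial_graph_repr(S3, g3, params, cfg$alpha, mean_pool = TRUE)
  expect_equal(irm$g, colMeans(S3))
  # hand evaluation with pinned beta: f = 1, beta = (.5,.3,.2), s = (1,2,4)
  expect_equal(sum(c(0.5, 0.3, 0.2) * c(1, 2, 4)), 1.9)
  expect_equal(final_graph_repr(matrix(c(1, 2, 4), 3L), c(0.5, 0.3, 0.2)), 1.9)
})

test_that("DRIP residual updates behave as defined", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  f <- cfg$hidden
  gx <- rnorm(f); gy <- rnorm(f); rz <- rnorm(f)
  # zero MLPs: mid = init, r unchanged
  pz <- zero_mlps(params)
  d0 <- drip_update(gx, gy, rz, pz)
  expect_equal(d0$gx_mid, gx)
  expect_equal(d0$gy_mid, gy)
  expect_equal(d0$r_new, rz)
  # residual identity: gx_mid - gx equals f_h(o) exactly
  d <- drip_update(gx, gy, rz, params)
  fh_o <- as.vector(molddi:::mlp2(d$o, params$fh_W1, params$fh_b1,
                                  params$fh_W2, params$fh_b2))
  expect_equal(d$gx_mid - gx, fh_o)
  # hand evaluation, f = 1: W_h = W_t = I, f_h = sum of o entries,
  # gx = 1, gy = 2, r = 3 -> o = (1,2,3), gx_mid = 1 + 6 = 7
  p1 <- list(Wh = matrix(1), Wt = matrix(1),
             fh_W1 = matrix(1, 1L, 3L), fh_b1 = matrix(0),
             fh_W2 = matrix(1), fh_b2 = matrix(0),
             ft_W1 = matrix(0, 1L, 3L), ft_b1 = matrix(0),
             ft_W2 = matrix(0), ft_b2 = matrix(0),
             fr_W1 = matrix(0, 1L, 3L), fr_b1 = matrix(0),
             fr_W2 = matrix(0), fr_b2 = matrix(0))
  d1 <- drip_update(1, 2, 3, p1)
  expect_equal(d1$gx_mid, 7)
  # no_drip flag is exactly the zero-MLP behaviour
  dn <- drip_update(gx, gy, rz, params, no_drip = TRUE)
  expect_equal(dn$gx_mid, gx)
  expect_equal(dn$r_new, rz)
})

test_that("SDUP importances are a distribution with closed-form cases", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  f <- cfg$hidden
  # single substructure: mu = 1
  mu1 <- sdup_importance(rnorm(f), matrix(rnorm(f), 1L), params)
  expect_equal(mu1, 1)
  # constant f_mu (zero weights): uniform
  pz <- params
  pz$fmu_W2[] <- 0; pz$fmu_b2[] <- 0.7
  mu_u <- sdup_importance(rnorm(f), matrix(rnorm(5L * f), 5L), pz)
  expect_equal(mu_u, rep(0.2, 5L))
  # raw scores (0, ln 4) -> (0.2, 0.8); engineer via a linear f_mu that
  # reads a single coordinate of W_v s
  fp <- cfg$att_hidden
  pe <- params
  pe$Wu[] <- 0
  pe$Wv[] <- 0; pe$Wv[1L, 1L] <- 1
  pe$fmu_W1[] <- 0
  pe$fmu_W1[1L, fp + 1L] <- 1          # hidden1 = relu(Wv s)[1]
  pe$fmu_b1[] <- 0
  pe$fmu_W2[] <- 0; pe$fmu_W2[1L, 1L] <- 1
  pe$fmu_b2[] <- 0
  S <- matrix(0, 2L, f)
  S[2L, 1L] <- log(4)
  mu <- sdup_importance(rnorm(f), S, pe)
  expect_equal(mu, c(0.2, 0.8))
  # general case: sums to one, non-negative
  mu_g <- sdup_importance(rnorm(f), matrix(rnorm(7L * f), 7L), params)
  expect_equal(sum(mu_g), 1, tolerance = 1e-9)
  expect_true(all(mu_g >= 0))
})

test_that("final representation is convex aggregation", {
  S <- matrix(c(5, 10), 2L)
  expect_equal(final_graph_repr(S, c(0.2, 0.8)), 9)
  # one-hot mu selects the substructure
  expect_equal(final_graph_repr(S, c(0, 1)), 10)
  # identical substructures are a fixed point
  S2 <- matrix(rep(c(1, 2, 3), each = 4L), 4L)
  expect_equal(final_graph_repr(S2, c(0.1, 0.2, 0.3, 0.4)), c(1, 2, 3))
  # envelope property on random input
  set.seed(8)
  S3 <- matrix(rnorm(15L), 5L)
  mu <- runif(5L); mu <- mu / sum(mu)
  gf <- final_graph_repr(S3, mu)
  expect_true(all(gf <= apply(S3, 2L, max) + 1e-12))
  expect_true(all(gf >= apply(S3, 2L, min) - 1e-12))
})

test_that("rsam_forward composes the pieces symmetrically", {
  cfg <- tiny_config(T = 2L, hidden = 4L, att = 3L, seed = 13L)
  params <- tiny_params(cfg)
  gx <- parse_smiles("CCO"); gy <- parse_smiles("CCN")
  Sx <- matrix(rnorm(3L * cfg$hidden), 3L)
  Sy <- matrix(rnorm(3L * cfg$hidden), 3L)
  rz <- rnorm(cfg$hidden)
  # all-zero DRIP MLPs + uniform pooling: fin still depends on SDUP, but
  # mid = init; with constant f_mu too, gx_fin collapses to the mean
  pz <- zero_mlps(params)
  pz$fmu_W2[] <- 0
  out <- rsam_forward(Sx, Sy, gx, gy, rz, pz, mean_pool = TRUE)
  expect_equal(out$gx_fin, colMeans(Sx))
  expect_equal(out$gy_fin, colMeans(Sy))
  expect_equal(out$gx_init, colMeans(Sx))
  expect_equal(out$r_new, rz)
  # swapping roles swaps the outputs when the parameters are tied AND the
  # shared context MLPs are symmetric in the two drug blocks of o
  f <- cfg$hidden
  pt <- params
  pt$Wt <- pt$Wh
  pt$fh_W1[, (f + 1L):(2L * f)] <- pt$fh_W1[, 1L:f]
  pt$fr_W1[, (f + 1L):(2L * f)] <- pt$fr_W1[, 1L:f]
  pt$ft_W1 <- pt$fh_W1; pt$ft_b1 <- pt$fh_b1
  pt$ft_W2 <- pt$fh_W2; pt$ft_b2 <- pt$fh_b2
  o1 <- rsam_forward(Sx, Sy, gx, gy, rz, pt)
  o2 <- rsam_forward(Sy, Sx, gy, gx, rz, pt)
  expect_equal(o1$gx_fin, o2$gy_fin)
  expect_equal(o1$gy_fin, o2$gx_fin)
  # mu distributions normalize per drug
  expect_equal(sum(o1$mu_x), 1, tolerance = 1e-9)
  expect_equal(sum(o1$mu_y), 1, tolerance = 1e-9)
})

test_that("relation gradients flow only through tuples using that relation", {
  cfg <- tiny_config(T = 2L, hidden = 4L, att = 3L, seed = 3L)
  params <- ddi_init_params(cfg, n_relations = 4L)
  pair <- random_drug_pair_batch()
  tix <- molddi:::build_tuple_indices(c(1L, 1L), c(2L, 2L), c(2L, 3L),
                                      c(1, 0), pair$bd)
  lg <- molddi:::ddi_loss_grads(params, pair$bd, tix, cfg)
  gR <- lg$grads$Rtab
  expect_true(all(gR[c(1L, 4L), ] == 0))   # unused relations: zero gradient
  expect_true(any(gR[2L, ] != 0))
  expect_true(any(gR[3L, ] != 0))
})
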