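# Shared fixtures: tiny parameter sets and molecule collections built in code.

tiny_config <- function(T = 2L, hidden = 4L, att = 3L, seed = 7L, ...) {
  ddi_config(T = T, hidden = hidden, att_hidden = att, seed = seed, ...)
}

tiny_params <- function(cfg = tiny_config(), n_relations = 3L) {
  ddi_init_params(cfg, n_relations = n_relations)
}

# connected molecular graphs with <= 6 heavy atoms: all trees (paths, stars,
# branched) and the small rings reachable as molecules
small_molecules <- c(
  "C", "CC", "CCC", "CCCC", "CC(C)C", "CCCCC", "CC(C)CC", "CC(C)(C)C",
  "CCCCCC", "CC(C)CCC", "CC(C)(C)CC", "CCC(C)CC", "CC(C)C(C)C",
  "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "CC1CC1", "CCC1CC1",
  "CC1CCC1", "CC1CC1C", "c1ccccc1", "c1ccncc1", "CC(=O)O", "CS(=O)(=O)N"
)

# brute-force non-backtracking recursion for directed edge message passing
# with identity activation; independent of the sparse-matrix implementation
walk_oracle <- function(graph, h0, Wm, T_steps) {
  de <- build_directed_edges(graph)
  ne <- de$n_edges
  # incoming sets by double loop over directed edge pairs
  inc <- lapply(seq_len(ne), function(e) {
    out <- integer(0)
    for (ep in seq_len(ne)) {
      if (de$dst[ep] == de$src[e] && de$src[ep] != de$dst[e]) {
        out <- c(out, ep)
      }
    }
    out
  })
  h_of <- function(e, t) {
    if (t == 0L) return(h0[e, ])
    s <- rep(0, ncol(h0))
    for (ep in inc[[e]]) s <- s + h_of(ep, t - 1L)
    h0[e, ] + as.vector(Wm %*% s)
  }
  res <- vapply(seq_len(ne), function(e) h_of(e, T_steps), numeric(ncol(h0)))
  if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
}

# run propagate_edge_messages T times (identity activation)
propagate_T <- function(graph, h0, Wm, T_steps) {
  de <- build_directed_edges(graph)
  h <- h0
  for (t in seq_len(T_steps)) {
    h <- propagate_edge_messages(h, h0, de, Wm, activation = "identity")
  }
  h
}

random_drug_pair_batch <- function(seed = 42L, smiles = c("CCS(=O)(=O)NC",
                                                          "Cc1ccncc1")) {
  graphs <- lapply(smiles, parse_smiles)
  list(graphs = graphs, bd = molddi:::batch_graphs(graphs))
}
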