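# Directed-edge sets and bond-level (line-graph) adjacency, plus batching of
# many molecules into one block-diagonal structure for the encoder.

#' Build the directed-edge set of a molecular graph
#'
#' Each undirected bond yields two directed edges carrying identical bond
#' features. The reverse map pairs every edge with its opposite direction and
#' is involutive; it is what lets the encoder exclude the immediate
#' back-edge during message passing.
#'
#' @param graph A `mol_graph` from [parse_smiles()].
#' @return A list of class `directed_edges` with integer vectors `src`, `dst`,
#'   `bond` (underlying undirected bond), `rev` (index of the reverse edge),
#'   the edge feature matrix `E` (2·n_bonds x d') and `n_edges`.
#' @export
build_directed_edges <- function(graph) {
  nb <- graph$n_bonds
  if (nb == 0L) {
    de <- list(src = integer(0), dst = integer(0), bond = integer(0),
               rev = integer(0), E = matrix(0, 0L, bond_feature_dim()),
               n_edges = 0L)
    class(de) <- "directed_edges"
    return(de)
  }
  src <- c(graph$bonds$i, graph$bonds$j)
  dst <- c(graph$bonds$j, graph$bonds$i)
  de <- list(
    src = src,
    dst = dst,
    bond = rep(seq_len(nb), 2L),
    rev = c(seq_len(nb) + nb, seq_len(nb)),
    E = rbind(graph$E, graph$E),
    n_edges = 2L * nb
  )
  class(de) <- "directed_edges"
  de
}

#' Bond-level (line-graph) adjacency of a molecule
#'
#' Square 0/1 matrix over the undirected bonds: entry (s, t) is 1 exactly
#' when bonds s and t share an endpoint atom. Symmetric with a zero diagonal;
#' a molecule with no bonds gives a 0 x 0 matrix.
#'
#' @param graph A `mol_graph`.
#' @return A base numeric matrix of size `n_bonds` x `n_bonds`.
#' @export
build_line_graph_adjacency <- function(graph) {
  nb <- graph$n_bonds
  A <- matrix(0, nb, nb)
  if (nb < 2L) return(A)
  ends <- cbind(graph$bonds$i, graph$bonds$j)
  for (s in seq_len(nb - 1L)) {
    for (t in (s + 1L):nb) {
      if (length(intersect(ends[s, ], ends[t, ])) > 0L) {
        A[s, t] <- 1
        A[t, s] <- 1
      }
    }
  }
  A
}

# symmetric GCN normalization D^-1/2 (A + I) D^-1/2 as a sparse matrix
gcn_normalize <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(Matrix::Matrix(0, 0L, 0L, sparse = TRUE))
  Ahat <- A + diag(n)
  d <- 1 / sqrt(rowSums(Ahat))
  Matrix::Matrix(Ahat * outer(d, d), sparse = TRUE)
}

# Line-graph adjacency lifted to directed edges: two directed edges are
# adjacent iff their underlying bonds share an atom, or they are the two
# directions of the same bond.
directed_line_adj <- function(de, graph) {
  Ab <- build_line_graph_adjacency(graph)
  Ad <- matrix(0, de$n_edges, de$n_edges)
  for (e1 in seq_len(de$n_edges)) {
    for (e2 in seq_len(de$n_edges)) {
      if (e1 == e2) next
      b1 <- de$bond[e1]; b2 <- de$bond[e2]
      if (b1 == b2 || Ab[b1, b2] == 1) Ad[e1, e2] <- 1
    }
  }
  Ad
}

# atom-level adjacency (0/1, undirected)
atom_adjacency <- function(graph) {
  Aa <- matrix(0, graph$n_atoms, graph$n_atoms)
  if (graph$n_bonds > 0L) {
    Aa[cbind(graph$bonds$i, graph$bonds$j)] <- 1
    Aa[cbind(graph$bonds$j, graph$bonds$i)] <- 1
  }
  Aa
}

# Assemble a list of mol_graphs into one block-diagonal batch with global
# indices. Precomputes every constant sparse operator the encoder needs:
#  - A_msg : directed-edge -> directed-edge message routing (non-backtracking)
#  - A_in  : directed-edge -> target-atom incidence (incoming sum)
#  - L_dir : GCN-normalized line-graph adjacency over directed edges
#  - L_atom: GCN-normalized atom adjacency
batch_graphs <- function(graphs) {
  ng <- length(graphs)
  n_atoms <- vapply(graphs, function(g) g$n_atoms, 1L)
  n_bonds <- vapply(graphs, function(g) g$n_bonds, 1L)
  atom_off <- cumsum(c(0L, n_atoms[-ng]))
  n_edges <- 2L * n_bonds
  edge_off <- cumsum(c(0L, n_edges[-ng]))

  X <- do.call(rbind, lapply(graphs, function(g) g$X))
  atom_graph <- rep(seq_len(ng), n_atoms)

  src <- dst <- rev_idx <- edge_graph <- integer(0)
  E <- matrix(0, 0L, bond_feature_dim())
  msg_from <- msg_to <- integer(0)   # pairs (incoming edge, receiving edge)
  lg_i <- lg_j <- lg_x <- numeric(0) # normalized directed line graph triplets
  la_i <- la_j <- la_x <- numeric(0) # normalized atom adjacency triplets

  for (gi in seq_len(ng)) {
    g <- graphs[[gi]]
    de <- build_directed_edges(g)
    if (de$n_edges > 0L) {
      src <- c(src, de$src + atom_off[gi])
      dst <- c(dst, de$dst + atom_off[gi])
      rev_idx <- c(rev_idx, de$rev + edge_off[gi])
      edge_graph <- c(edge_graph, rep(gi, de$n_edges))
      E <- rbind(E, de$E)

      # message routing: edge e' = (k -> p) feeds edge e = (p -> q), e' != rev(e)
      for (e in seq_len(de$n_edges)) {
        inc <- which(de$dst == de$src[e])
        inc <- inc[inc != de$rev[e]]
        if (length(inc) > 0L) {
          msg_from <- c(msg_from, inc + edge_off[gi])
          msg_to <- c(msg_to, rep(e + edge_off[gi], length(inc)))
        }
      }

      Ln <- as.matrix(gcn_normalize(directed_line_adj(de, g)))
      nz <- which(Ln != 0, arr.ind = TRUE)
      lg_i <- c(lg_i, nz[, 1L] + edge_off[gi])
      lg_j <- c(lg_j, nz[, 2L] + edge_off[gi])
      lg_x <- c(lg_x, Ln[nz])
    }

    La <- as.matrix(gcn_normalize(atom_adjacency(g)))
    nz <- which(La != 0, arr.ind = TRUE)
    la_i <- c(la_i, nz[, 1L] + atom_off[gi])
    la_j <- c(la_j, nz[, 2L] + atom_off[gi])
    la_x <- c(la_x, La[nz])
  }

  tot_edges <- sum(n_edges)
  tot_atoms <- sum(n_atoms)
  list(
    n_graphs = ng,
    n_atoms = tot_atoms,
    n_edges = tot_edges,
    atom_graph = atom_graph,
    edge_graph = edge_graph,
    atoms_of = split(seq_len(tot_atoms), atom_graph),
    X = X,
    E = E,
    src = src,
    dst = dst,
    rev = rev_idx,
    A_msg = Matrix::sparseMatrix(i = msg_to, j = msg_from, x = 1,
                                 dims = c(tot_edges, tot_edges)),
    A_in = Matrix::sparseMatrix(i = dst, j = seq_len(tot_edges), x = 1,
                                dims = c(tot_atoms, tot_edges)),
    L_dir = Matrix::sparseMatrix(i = lg_i, j = lg_j, x = lg_x,
                                 dims = c(tot_edges, tot_edges)),
    L_atom = Matrix::sparseMatrix(i = la_i, j = la_j, x = la_x,
                                  dims = c(tot_atoms, tot_atoms)),
    has_bonds = n_bonds > 0L
  )
}
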