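# Hand-written parser for the OpenSMILES subset this package needs.
#
# Supported: organic-subset atoms (B C N O P S F Cl Br I and aromatic
# b c n o p s), bracket atoms with isotope / chirality (@, @@) / explicit H
# count / formal charge / atom class, branches, ring-bond closures (digits and
# %nn), explicit bond symbols - = # : (/ and \ are read as single bonds,
# directionality is dropped), and '.' fragment separators. Hydrogens are
# suppressed: bracket H counts and implied hydrogens become an atom property.
#
# Atom order is order of first appearance in the string, so parsing is
# deterministic and attribution indices are reproducible.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# smallest allowed valence >= bond-order sum decides the implicit H count
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

smiles_error <- function(smiles, msg) {
  stop(sprintf("invalid SMILES '%s': %s", smiles, msg), call. = FALSE)
}

#' Parse a SMILES string into an attributed molecular graph
#'
#' Converts a single SMILES string into a hydrogen-suppressed molecular graph
#' with per-atom and per-bond chemical attributes plus their fixed-length
#' numeric feature encodings (see [featurize_atom()] for the encoding).
#' Multi-fragment strings (e.g. salts written with `.`) are kept as one graph
#' with several connected components; a molecule with no bonds at all (a bare
#' ion such as `[Ca+2]`) is a valid degenerate graph.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `mol_graph`: a list with `atoms` and `bonds`
#'   tibbles, atom/bond feature matrices `X` (`n_atoms` x d) and `E`
#'   (`n_bonds` x d'), and counts `n_atoms`, `n_bonds`. Bonds are undirected
#'   records with endpoint indices `i < j`.
#' @examples
#' g <- parse_smiles("CC(=O)O")   # acetic acid
#' g$n_atoms
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single character string", call. = FALSE)
  }
  if (!nzchar(smiles)) stop("empty SMILES string", call. = FALSE)

  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # element, aromatic, charge, h_explicit (NA if implied), chirality
  bonds <- list()   # i, j, order ("single","double","triple","aromatic")
  prev <- NA_integer_         # atom awaiting the next bond
  pending_bond <- NA_character_
  stack <- integer(0)
  ring <- list()              # ring number -> list(atom, bond)

  add_atom <- function(element, aromatic, charge = 0L, h = NA_integer_,
                       chirality = "none") {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge,
      h_explicit = h, chirality = chirality
    )
    length(atoms)
  }

  add_bond <- function(i, j, order) {
    if (i == j) smiles_error(smiles, "self-loop bond")
    bonds[[length(bonds) + 1L]] <<- list(i = min(i, j), j = max(i, j), order = order)
  }

  bond_order_between <- function(sym, i, j) {
    if (!is.na(sym)) {
      return(switch(sym,
        "-" = "single", "/" = "single", "\\" = "single",
        "=" = "double", "#" = "triple", ":" = "aromatic"
      ))
    }
    if (atoms[[i]]$aromatic && atoms[[j]]$aromatic) "aromatic" else "single"
  }

  connect <- function(i) {
    if (!is.na(prev)) {
      add_bond(prev, i, bond_order_between(pending_bond, prev, i))
    }
    prev <<- i
    pending_bond <<- NA_character_
  }

  close_ring <- function(num) {
    if (is.na(prev)) smiles_error(smiles, "ring closure before any atom")
    key <- as.character(num)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, bond = pending_bond)
    } else {
      open <- ring[[key]]
      sym <- if (!is.na(pending_bond)) pending_bond else open$bond
      add_bond(open$atom, prev, bond_order_between(sym, open$atom, prev))
      ring[[key]] <<- NULL
    }
    pending_bond <<- NA_character_
  }

  pos <- 1L
  while (pos <= n) {
    ch <- chars[pos]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      pos <- pos + 1L
    } else if (ch == "(") {
      if (is.na(prev)) smiles_error(smiles, "branch opened before any atom")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_error(smiles, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch))
      pos <- pos + 1L
    } else if (ch == "%") {
      if (pos + 2L > n) smiles_error(smiles, "truncated %nn ring closure")
      num <- suppressWarnings(as.integer(paste0(chars[pos + 1L], chars[pos + 2L])))
      if (is.na(num)) smiles_error(smiles, "malformed %nn ring closure")
      close_ring(num)
      pos <- pos + 3L
    } else if (ch == "[") {
      close_pos <- pos
      while (close_pos <= n && chars[close_pos] != "]") close_pos <- close_pos + 1L
      if (close_pos > n) smiles_error(smiles, "unmatched '['")
      body <- paste0(chars[(pos + 1L):(close_pos - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$h, at$chirality)
      connect(idx)
      pos <- close_pos + 1L
    } else {
      two <- if (pos < n) paste0(ch, chars[pos + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE)
        connect(idx)
        pos <- pos + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        idx <- add_atom(ch, FALSE)
        connect(idx)
        pos <- pos + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        idx <- add_atom(toupper(ch), TRUE)
        connect(idx)
        pos <- pos + 1L
      } else {
        smiles_error(smiles, sprintf("unexpected character '%s' at position %d", ch, pos))
      }
    }
  }
  if (length(stack) > 0L) smiles_error(smiles, "unmatched '('")
  if (length(ring) > 0L) smiles_error(smiles, "unclosed ring bond")
  if (length(atoms) == 0L) smiles_error(smiles, "no atoms")

  finalize_mol_graph(atoms, bonds, smiles)
}

# bracket atom body, e.g. "13CH4", "O-", "Ca+2", "N+", "C@@H", "nH"
parse_bracket_atom <- function(body, smiles) {
  rx <- "^([0-9]*)([A-Z][a-z]?|[a-z])(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$"
  m <- regmatches(body, regexec(rx, body))[[1]]
  if (length(m) == 0L) smiles_error(smiles, sprintf("malformed bracket atom [%s]", body))
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  chirality <- if (m[4] == "@") "@" else if (m[4] == "@@") "@@" else "none"
  h <- if (m[5] == "") 0L else if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
  chg <- m[6]
  charge <- if (chg == "") {
    0L
  } else if (grepl("^[+-][0-9]+$", chg)) {
    as.integer(chg)
  } else {
    s <- if (substr(chg, 1L, 1L) == "+") 1L else -1L
    s * nchar(chg)
  }
  list(element = element, aromatic = aromatic, charge = charge, h = h,
       chirality = chirality)
}

finalize_mol_graph <- function(atoms, bonds, smiles) {
  n_atoms <- length(atoms)
  n_bonds <- length(bonds)

  bi <- vapply(bonds, function(b) b$i, 1L)
  bj <- vapply(bonds, function(b) b$j, 1L)
  border <- vapply(bonds, function(b) b$order, "")
  if (anyDuplicated(paste(bi, bj))) smiles_error(smiles, "duplicate bond")

  order_num <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

  degree <- tabulate(c(bi, bj), nbins = n_atoms)
  bond_sum <- rep(0, n_atoms)
  for (s in seq_len(n_bonds)) {
    o <- order_num[[border[s]]]
    bond_sum[bi[s]] <- bond_sum[bi[s]] + o
    bond_sum[bj[s]] <- bond_sum[bj[s]] + o
  }

  element <- vapply(atoms, function(a) a$element, "")
  aromatic <- vapply(atoms, function(a) a$aromatic, TRUE)
  charge <- vapply(atoms, function(a) a$charge, 1L)
  h_explicit <- vapply(atoms, function(a) a$h_explicit, 1L)
  chirality <- vapply(atoms, function(a) a$chirality, "")

  n_h <- integer(n_atoms)
  for (a in seq_len(n_atoms)) {
    if (!is.na(h_explicit[a])) {
      n_h[a] <- h_explicit[a]
    } else {
      vals <- DEFAULT_VALENCES[[element[a]]]
      need <- ceiling(bond_sum[a])
      v <- vals[vals >= need][1]
      n_h[a] <- if (is.na(v)) 0L else as.integer(v - need)
    }
  }

  # ring membership: a bond is in a ring iff it is not a bridge
  in_ring <- bond_in_ring(n_atoms, bi, bj)

  # hybridization heuristic from explicit bond orders (no lone-pair perception)
  hyb <- character(n_atoms)
  n_double <- n_triple <- integer(n_atoms)
  for (s in seq_len(n_bonds)) {
    if (border[s] == "double") {
      n_double[bi[s]] <- n_double[bi[s]] + 1L
      n_double[bj[s]] <- n_double[bj[s]] + 1L
    } else if (border[s] == "triple") {
      n_triple[bi[s]] <- n_triple[bi[s]] + 1L
      n_triple[bj[s]] <- n_triple[bj[s]] + 1L
    }
  }
  for (a in seq_len(n_atoms)) {
    hyb[a] <- if (!element[a] %in% names(DEFAULT_VALENCES)) {
      "other"
    } else if (aromatic[a]) {
      "sp2"
    } else if (n_triple[a] >= 1L || n_double[a] >= 2L) {
      "sp"
    } else if (n_double[a] >= 1L) {
      "sp2"
    } else {
      "sp3"
    }
  }

  # conjugation heuristic: aromatic bonds, or bonds both of whose endpoints
  # also touch some other multiple/aromatic bond (no lone-pair perception)
  multi_count <- n_double + n_triple + as.integer(aromatic)
  conjugated <- logical(n_bonds)
  for (s in seq_len(n_bonds)) {
    own <- as.integer(border[s] %in% c("double", "triple"))
    conjugated[s] <- border[s] == "aromatic" ||
      (multi_count[bi[s]] - own > 0L && multi_count[bj[s]] - own > 0L)
  }

  atoms_tbl <- tibble::tibble(
    atom = seq_len(n_atoms), element = element, aromatic = aromatic,
    degree = degree, charge = charge, n_h = n_h, hybridization = hyb,
    chirality = chirality
  )
  bonds_tbl <- tibble::tibble(
    bond = seq_len(n_bonds), i = bi, j = bj, order = border,
    conjugated = conjugated, in_ring = in_ring
  )

  g <- list(
    smiles = smiles,
    atoms = atoms_tbl,
    bonds = bonds_tbl,
    X = featurize_atoms(atoms_tbl),
    E = featurize_bonds(bonds_tbl),
    n_atoms = n_atoms,
    n_bonds = n_bonds
  )
  class(g) <- "mol_graph"
  g
}

# bridge detection by connectivity check after bond removal; molecules are
# tiny so the quadratic cost is irrelevant
bond_in_ring <- function(n_atoms, bi, bj) {
  n_bonds <- length(bi)
  if (n_bonds == 0L) return(logical(0))
  adj <- vector("list", n_atoms)
  for (s in seq_len(n_bonds)) {
    adj[[bi[s]]] <- c(adj[[bi[s]]], s)
    adj[[bj[s]]] <- c(adj[[bj[s]]], s)
  }
  other_end <- function(s, a) if (bi[s] == a) bj[s] else bi[s]
  vapply(seq_len(n_bonds), function(s) {
    # can we still reach bj[s] from bi[s] without using bond s?
    seen <- logical(n_atoms)
    queue <- bi[s]
    seen[bi[s]] <- TRUE
    while (length(queue) > 0L) {
      a <- queue[1L]; queue <- queue[-1L]
      for (t in adj[[a]]) {
        if (t == s) next
        b <- other_end(t, a)
        if (!seen[b]) {
          if (b == bj[s]) return(TRUE)
          seen[b] <- TRUE
          queue <- c(queue, b)
        }
      }
    }
    FALSE
  }, TRUE)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s\n  %d atoms, %d bonds\n",
              x$smiles, x$n_atoms, x$n_bonds))
  invisible(x)
}
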