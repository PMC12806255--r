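# Download-free synthetic world: a library of small valid molecules built
# from simple scaffolds, and DDI tuples generated by planted
# substructure-pair rules (relation z fires iff drug x carries motif A and
# drug y carries motif B), with optional symmetric label noise. The planted
# ground truth (which atoms form the causal motif) is recorded per tuple so
# attribution can be scored.

MOTIF_NAMES <- c("sulfonamide", "carboxylic_acid", "amide", "ether",
                 "pyridine_n")

#' Find occurrences of a chemical motif in a molecular graph
#'
#' Structural pattern matching for the small motif vocabulary the synthetic
#' generator plants: sulfonamide (S(=O)(=O)N), carboxylic acid (C(=O)OH),
#' amide (C(=O)N), dialkyl ether (C-O-C away from carbonyls) and pyridine-type
#' aromatic nitrogen.
#'
#' @param graph A `mol_graph`.
#' @param motif One of `"sulfonamide"`, `"carboxylic_acid"`, `"amide"`,
#'   `"ether"`, `"pyridine_n"`.
#' @return List of integer vectors, one per match, each giving the atom
#'   indices of the matched motif; empty list if absent.
#' @export
detect_motif <- function(graph, motif) {
  motif <- match.arg(motif, MOTIF_NAMES)
  at <- graph$atoms
  bd <- graph$bonds
  nb_of <- function(a) {
    rows <- which(bd$i == a | bd$j == a)
    lapply(rows, function(s) {
      list(atom = if (bd$i[s] == a) bd$j[s] else bd$i[s],
           order = bd$order[s])
    })
  }
  matches <- list()
  add <- function(atoms) matches[[length(matches) + 1L]] <<- sort(unique(atoms))

  if (motif == "sulfonamide") {
    for (a in which(at$element == "S")) {
      nb <- nb_of(a)
      dbl_o <- vapply(nb, function(x) x$order == "double" &&
                        at$element[x$atom] == "O", TRUE)
      sgl_n <- vapply(nb, function(x) x$order == "single" &&
                        at$element[x$atom] == "N", TRUE)
      if (sum(dbl_o) >= 2L && any(sgl_n)) {
        o_atoms <- vapply(nb[dbl_o], function(x) x$atom, 1L)[1:2]
        n_atom <- vapply(nb[sgl_n], function(x) x$atom, 1L)[1L]
        add(c(a, o_atoms, n_atom))
      }
    }
  } else if (motif == "carboxylic_acid") {
    for (a in which(at$element == "C" & !at$aromatic)) {
      nb <- nb_of(a)
      dbl_o <- vapply(nb, function(x) x$order == "double" &&
                        at$element[x$atom] == "O", TRUE)
      oh <- vapply(nb, function(x) x$order == "single" &&
                     at$element[x$atom] == "O" &&
                     at$n_h[x$atom] >= 1L, TRUE)
      if (any(dbl_o) && any(oh)) {
        add(c(a, vapply(nb[dbl_o], function(x) x$atom, 1L)[1L],
              vapply(nb[oh], function(x) x$atom, 1L)[1L]))
      }
    }
  } else if (motif == "amide") {
    for (a in which(at$element == "C" & !at$aromatic)) {
      nb <- nb_of(a)
      dbl_o <- vapply(nb, function(x) x$order == "double" &&
                        at$element[x$atom] == "O", TRUE)
      sgl_n <- vapply(nb, function(x) x$order == "single" &&
                        at$element[x$atom] == "N", TRUE)
      if (any(dbl_o) && any(sgl_n)) {
        add(c(a, vapply(nb[dbl_o], function(x) x$atom, 1L)[1L],
              vapply(nb[sgl_n], function(x) x$atom, 1L)[1L]))
      }
    }
  } else if (motif == "ether") {
    for (a in which(at$element == "O" & !at$aromatic & at$degree == 2L &
                      at$n_h == 0L)) {
      nb <- nb_of(a)
      carbons <- vapply(nb, function(x) x$order == "single" &&
                          at$element[x$atom] == "C", TRUE)
      if (!all(carbons)) next
      # exclude esters/acids: neighbor carbons must not carry a C=O
      carbonyl <- vapply(nb, function(x) {
        any(vapply(nb_of(x$atom), function(y) y$order == "double" &&
                     at$element[y$atom] == "O", TRUE))
      }, TRUE)
      if (any(carbonyl)) next
      add(c(a, vapply(nb, function(x) x$atom, 1L)))
    }
  } else if (motif == "pyridine_n") {
    for (a in which(at$element == "N" & at$aromatic)) {
      nb <- nb_of(a)
      arom_nb <- vapply(nb, function(x) x$order == "aromatic", TRUE)
      if (sum(arom_nb) >= 2L) {
        add(c(a, vapply(nb[arom_nb], function(x) x$atom, 1L)))
      }
    }
  }
  matches
}

#' The default planted substructure-pair rules
#'
#' Three relations, each firing exactly when drug x carries `motif_x` and
#' drug y carries `motif_y`. The motifs echo the functional groups that DDI
#' attribution studies typically highlight (sulfonamide, carbonyl-bearing
#' groups), so the attribution export is chemically meaningful on synthetic
#' data.
#'
#' @return Tibble with columns `relation`, `motif_x`, `motif_y`.
#' @export
default_planted_rules <- function() {
  tibble::tibble(
    relation = 1:3,
    motif_x = c("sulfonamide", "amide", "ether"),
    motif_y = c("carboxylic_acid", "pyridine_n", "sulfonamide")
  )
}

alkyl_smiles <- function(len, branch = FALSE, deco = "") {
  if (len <= 0L) return("")
  base <- if (branch && len >= 3L) {
    paste0("CC(C)", strrep("C", len - 3L))
  } else {
    strrep("C", len)
  }
  # optional single substituent (halogen or methyl) on the first carbon
  if (nzchar(deco) && len >= 2L) {
    paste0(substr(base, 1L, 1L), "(", deco, ")",
           substr(base, 2L, nchar(base)))
  } else {
    base
  }
}

#' Generate a synthetic molecule library
#'
#' Builds `n_drugs` unique, parseable molecules (up to ~25 heavy atoms) from
#' simple scaffold classes: sulfonamides, carboxylic acids, amides, dialkyl
#' ethers, alkyl pyridines, alkyl benzenes and plain alkanes. At least 5
#' molecules per planted motif are guaranteed by cycling through the classes
#' before sampling them at random.
#'
#' @param n_drugs Library size (>= 10).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return Tibble with `drug_id`, `smiles`, one logical column per motif
#'   (e.g. `has_sulfonamide`), and a `motif_atoms` list-column mapping motif
#'   name to matched atom indices.
#' @export
generate_library <- function(n_drugs = 200L, seed = 1L) {
  stopifnot(n_drugs >= 10L)
  set.seed(seed %% .Machine$integer.max)

  make_class <- function(class) {
    len <- sample(1:7, 1L)
    len2 <- sample(1:4, 1L)
    br <- stats::runif(1) < 0.3
    deco <- sample(c("", "", "F", "Cl", "C"), 1L)
    switch(class,
      sulfonamide = paste0(alkyl_smiles(len, br, deco), "S(=O)(=O)N",
                           alkyl_smiles(len2 - 1L)),
      carboxylic_acid = paste0(alkyl_smiles(len, br, deco), "C(=O)O"),
      amide = paste0(alkyl_smiles(len, br, deco), "C(=O)N",
                     alkyl_smiles(len2 - 1L)),
      ether = paste0(alkyl_smiles(len + 1L, br, deco), "O",
                     alkyl_smiles(len2)),
      pyridine = paste0(alkyl_smiles(len - 1L, FALSE, deco), "c1ccncc1"),
      benzene = paste0(alkyl_smiles(len - 1L, FALSE, deco), "c1ccccc1"),
      alkane = alkyl_smiles(len + sample(2:8, 1L), br, deco)
    )
  }

  classes <- c("sulfonamide", "carboxylic_acid", "amide", "ether",
               "pyridine", "benzene", "alkane")
  # quota first (5 per class), then random fill
  plan <- c(rep(classes, each = 5L),
            sample(classes, max(0L, n_drugs - 5L * length(classes)),
                   replace = TRUE))
  plan <- plan[seq_len(n_drugs)]

  seen <- character(0)
  smiles <- character(n_drugs)
  for (i in seq_len(n_drugs)) {
    for (try in 1:200) {
      s <- make_class(plan[i])
      if (!s %in% seen) break
    }
    if (s %in% seen) {
      # bounded deterministic fallback family (halogenated alkanes <= 25
      # heavy atoms) that cannot collide forever
      k <- 0L
      repeat {
        k <- k + 1L
        s <- paste0(c("", "CC(C)")[1L + (k %/% 90L) %% 2L],
                    strrep("C", 6L + (k %% 18L)),
                    c("", "F", "Cl", "Br", "I")[1L + (k %/% 18L) %% 5L])
        if (!s %in% seen) break
      }
    }
    seen <- c(seen, s)
    smiles[i] <- s
  }

  lib <- tibble::tibble(drug_id = sprintf("D%03d", seq_len(n_drugs)),
                        smiles = smiles)
  annotate_motifs(lib)
}

# add per-motif presence flags and matched-atom lists to a drug table
annotate_motifs <- function(lib) {
  graphs <- lapply(lib$smiles, parse_smiles)
  motif_atoms <- lapply(graphs, function(g) {
    found <- lapply(MOTIF_NAMES, function(m) {
      hits <- detect_motif(g, m)
      if (length(hits) == 0L) integer(0) else sort(unique(unlist(hits)))
    })
    stats::setNames(found, MOTIF_NAMES)
  })
  for (m in MOTIF_NAMES) {
    lib[[paste0("has_", m)]] <- vapply(motif_atoms,
                                       function(x) length(x[[m]]) > 0L, TRUE)
  }
  lib$motif_atoms <- motif_atoms
  lib
}

#' Generate DDI tuples from planted rules
#'
#' Positives are drug pairs satisfying a rule (x carries the relation's
#' `motif_x`, y carries `motif_y`); negatives are pairs violating it, one per
#' positive. Labels are then flipped independently with probability `noise`.
#' For each genuine positive the causal motif atoms of both drugs are
#' recorded so attribution can be scored against the planted truth.
#'
#' @param library Output of [generate_library()] (or any drug table passed
#'   through the same motif annotation).
#' @param rules Tibble of rules, see [default_planted_rules()].
#' @param n_per_relation Positives generated per relation.
#' @param noise Label-flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return Tibble with `drug_x`, `drug_y`, `relation`, `label`, `genuine`
#'   (rule-satisfying before noise) and list-columns `x_motif_atoms`,
#'   `y_motif_atoms`.
#' @export
generate_tuples <- function(library, rules = default_planted_rules(),
                            n_per_relation = 100L, noise = 0.05, seed = 1L) {
  stopifnot(noise >= 0, noise < 0.5)
  set.seed((seed + 1337L) %% .Machine$integer.max)
  key <- function(x, y, r) paste(x, y, r, sep = "\r")

  out <- list()
  for (k in seq_len(nrow(rules))) {
    rel <- rules$relation[k]
    mx <- rules$motif_x[k]
    my <- rules$motif_y[k]
    xs <- library$drug_id[library[[paste0("has_", mx)]]]
    ys <- library$drug_id[library[[paste0("has_", my)]]]
    if (length(xs) == 0L || length(ys) == 0L) {
      stop(sprintf("rule for relation %s is unsatisfiable in this library",
                   rel), call. = FALSE)
    }
    pos_keys <- character(0)
    px <- py <- character(n_per_relation)
    j <- 1L
    guard <- 0L
    while (j <= n_per_relation) {
      guard <- guard + 1L
      if (guard > 200L * n_per_relation) {
        stop("could not generate enough distinct positive pairs", call. = FALSE)
      }
      x <- sample(xs, 1L)
      y <- sample(ys, 1L)
      if (x == y || key(x, y, rel) %in% pos_keys) next
      px[j] <- x; py[j] <- y
      pos_keys <- c(pos_keys, key(x, y, rel))
      j <- j + 1L
    }

    # negatives: violate the rule (x lacks motif_x or y lacks motif_y)
    nx <- ny <- character(n_per_relation)
    neg_keys <- character(0)
    j <- 1L
    guard <- 0L
    all_ids <- library$drug_id
    while (j <= n_per_relation) {
      guard <- guard + 1L
      if (guard > 200L * n_per_relation) {
        stop("could not generate enough distinct negative pairs", call. = FALSE)
      }
      x <- sample(all_ids, 1L)
      y <- sample(all_ids, 1L)
      if (x == y) next
      sat <- library[[paste0("has_", mx)]][match(x, all_ids)] &&
        library[[paste0("has_", my)]][match(y, all_ids)]
      if (sat) next
      if (key(x, y, rel) %in% neg_keys) next
      nx[j] <- x; ny[j] <- y
      neg_keys <- c(neg_keys, key(x, y, rel))
      j <- j + 1L
    }

    ma <- library$motif_atoms[match(px, all_ids)]
    mb <- library$motif_atoms[match(py, all_ids)]
    out[[length(out) + 1L]] <- tibble::tibble(
      drug_x = c(px, nx), drug_y = c(py, ny),
      relation = rel,
      genuine = rep(c(TRUE, FALSE), each = n_per_relation),
      label = rep(c(1L, 0L), each = n_per_relation),
      x_motif_atoms = c(lapply(ma, function(x) x[[mx]]),
                        rep(list(integer(0)), n_per_relation)),
      y_motif_atoms = c(lapply(mb, function(x) x[[my]]),
                        rep(list(integer(0)), n_per_relation))
    )
  }
  tuples <- dplyr::bind_rows(out)
  if (noise > 0) {
    flip <- stats::runif(nrow(tuples)) < noise
    tuples$label <- ifelse(flip, 1L - tuples$label, tuples$label)
  }
  tuples
}

#' Score attribution against the planted motifs
#'
#' For every genuinely positive tuple, checks in both directions whether the
#' top-importance atom (argmax of the SDUP weights `mu`) lies inside the
#' causal motif planted by the generating rule.
#'
#' @param fit A fitted `ddi_fit`.
#' @param tuples Tuples from [generate_tuples()] carrying `genuine`,
#'   `x_motif_atoms` and `y_motif_atoms`.
#' @return List with `recovery` (fraction of directions recovered) and the
#'   per-direction tibble `detail`.
#' @export
ddi_motif_recovery <- function(fit, tuples) {
  pos <- tuples[tuples$genuine & tuples$label == 1L, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no genuine positives to score", call. = FALSE)
  ex <- ddi_explain(fit, pos)
  top <- dplyr::slice_max(dplyr::group_by(ex$atoms, .data$pair, .data$role),
                          .data$mu, n = 1L, with_ties = FALSE)
  top <- dplyr::ungroup(top)
  truth <- dplyr::bind_rows(
    tibble::tibble(pair = seq_len(nrow(pos)), role = "x",
                   motif = pos$x_motif_atoms),
    tibble::tibble(pair = seq_len(nrow(pos)), role = "y",
                   motif = pos$y_motif_atoms)
  )
  detail <- dplyr::left_join(top, truth, by = c("pair", "role"))
  detail$hit <- mapply(function(a, m) a %in% m, detail$atom, detail$motif)
  list(recovery = mean(detail$hit), detail = detail)
}
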