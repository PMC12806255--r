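# Fixed-length numeric encodings for atoms and bonds.
#
# Seven atom properties (one-hot blocks except the aromatic bit):
#   element {C,N,O,S,F,Cl,Br,I,P,other} | degree 0..5 | formal charge -2..+2 |
#   hybridization {sp,sp2,sp3,sp3d,sp3d2,other} | aromatic flag |
#   total H count 0..4 | chirality {none,@,@@,other}
# Three bond properties:
#   bond type {single,double,triple,aromatic} | conjugated | in-ring

ATOM_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
HYB_LEVELS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
CHIRAL_LEVELS <- c("none", "@", "@@")
BOND_ORDERS <- c("single", "double", "triple", "aromatic")

one_hot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# index into levels with a trailing "other" slot
slot_index <- function(x, levels) {
  i <- match(x, levels)
  i[is.na(i)] <- length(levels) + 1L
  i
}

#' Encode one atom as a fixed-length feature vector
#'
#' Concatenates one-hot encodings of seven atom properties: element, heavy
#' degree, formal charge, hybridization, aromaticity, total hydrogen count and
#' chirality tag. Elements outside the supported set fall into an "other"
#' slot rather than erroring.
#'
#' @param atom A one-row data frame with columns `element`, `degree`,
#'   `charge`, `hybridization`, `aromatic`, `n_h`, `chirality` (a row of
#'   `mol_graph$atoms`).
#' @return A numeric vector of length [atom_feature_dim()].
#' @export
featurize_atom <- function(atom) {
  as.vector(featurize_atoms(atom))
}

featurize_atoms <- function(atoms) {
  cbind(
    one_hot(slot_index(atoms$element, ATOM_ELEMENTS), length(ATOM_ELEMENTS) + 1L),
    one_hot(pmin(atoms$degree, 5L) + 1L, 6L),
    one_hot(pmin(pmax(atoms$charge, -2L), 2L) + 3L, 5L),
    one_hot(slot_index(atoms$hybridization, HYB_LEVELS), length(HYB_LEVELS) + 1L),
    matrix(as.numeric(atoms$aromatic), ncol = 1L),
    one_hot(pmin(atoms$n_h, 4L) + 1L, 5L),
    one_hot(slot_index(atoms$chirality, CHIRAL_LEVELS), length(CHIRAL_LEVELS) + 1L)
  )
}

featurize_bonds <- function(bonds) {
  if (nrow(bonds) == 0L) return(matrix(0, 0L, bond_feature_dim()))
  cbind(
    one_hot(match(bonds$order, BOND_ORDERS), 4L),
    matrix(as.numeric(bonds$conjugated), ncol = 1L),
    matrix(as.numeric(bonds$in_ring), ncol = 1L)
  )
}

#' Dimensions of the atom and bond feature encodings
#'
#' @return The fixed length of the atom (respectively bond) feature vector.
#' @export
atom_feature_dim <- function() {
  (length(ATOM_ELEMENTS) + 1L) + 6L + 5L + (length(HYB_LEVELS) + 1L) + 1L +
    5L + (length(CHIRAL_LEVELS) + 1L)
}

#' @rdname atom_feature_dim
#' @export
bond_feature_dim <- function() 6L
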