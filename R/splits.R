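# Evaluation protocols: negative sampling by drug corruption, stratified
# transductive splitting, and the inductive (cold-start) partition with its
# constrained negative-sample ranges.

#' Sample one negative tuple per positive by drug corruption
#'
#' For every positive tuple, one side (heads or tails, coin flip) is replaced
#' by a uniform draw from `drug_pool` such that the corrupted
#' `(drug_x, drug_y, relation)` is not a known positive, is not a self-pair,
#' and actually differs from the original. Deterministic under `seed`.
#'
#' @param positives Tibble of positive tuples (`drug_x`, `drug_y`,
#'   `relation`).
#' @param drug_pool Character vector of candidate replacement drug ids.
#' @param seed Integer seed.
#' @param known_positives Optional larger tuple set to reject against
#'   (defaults to `positives`); pass the full positive set so negatives never
#'   collide with positives outside this split.
#' @param max_tries Bounded retries per tuple before erroring.
#' @return Tibble of the same height with `label = 0`.
#' @export
sample_negatives <- function(positives, drug_pool, seed = 1L,
                             known_positives = positives, max_tries = 200L) {
  if (length(drug_pool) == 0L) stop("empty drug pool", call. = FALSE)
  set.seed(seed %% .Machine$integer.max)
  key <- function(x, y, r) paste(x, y, r, sep = "\r")
  pos_keys <- key(known_positives$drug_x, known_positives$drug_y,
                  known_positives$relation)
  n <- nrow(positives)
  out_x <- positives$drug_x
  out_y <- positives$drug_y
  for (j in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      corrupt_x <- stats::runif(1) < 0.5
      cand <- drug_pool[sample.int(length(drug_pool), 1L)]
      nx <- if (corrupt_x) cand else positives$drug_x[j]
      ny <- if (corrupt_x) positives$drug_y[j] else cand
      if (nx == ny) next
      if (nx == positives$drug_x[j] && ny == positives$drug_y[j]) next
      if (key(nx, ny, positives$relation[j]) %in% pos_keys) next
      out_x[j] <- nx
      out_y[j] <- ny
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf("negative sampling failed for tuple %d after %d tries",
                   j, max_tries), call. = FALSE)
    }
  }
  tibble::tibble(drug_x = out_x, drug_y = out_y,
                 relation = positives$relation, label = 0L)
}

#' Stratified transductive split
#'
#' Partitions tuples into train/validation/test at the given fractions,
#' stratified by relation type so every split holds the same relation mix.
#' Relation types with fewer than `min_stratum` tuples are pooled into one
#' rare-type stratum before splitting. `repeat_index` gives independent
#' repetitions under one seed.
#'
#' @param tuples Tuple tibble with a `relation` column.
#' @param frac Length-3 fractions summing to 1 (default 60/20/20).
#' @param seed Integer seed.
#' @param repeat_index Repetition number (1, 2, 3, ...).
#' @param min_stratum Smallest relation count kept as its own stratum.
#' @return The input tibble with a `split` factor column
#'   (`train`/`valid`/`test`).
#' @export
split_transductive <- function(tuples, frac = c(0.6, 0.2, 0.2), seed = 1L,
                               repeat_index = 1L, min_stratum = 5L) {
  if (nrow(tuples) == 0L) stop("empty tuple set", call. = FALSE)
  stopifnot(length(frac) == 3L, abs(sum(frac) - 1) < 1e-8)
  set.seed((seed + 7919L * (repeat_index - 1L)) %% .Machine$integer.max)

  counts <- table(tuples$relation)
  rare <- names(counts)[counts < min_stratum]
  stratum <- as.character(tuples$relation)
  stratum[stratum %in% rare] <- ".rare"

  split <- character(nrow(tuples))
  for (st in unique(stratum)) {
    idx <- which(stratum == st)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_train <- round(frac[1] * n)
    n_valid <- round(frac[2] * n)
    n_valid <- min(n_valid, n - n_train)
    split[idx[seq_len(n_train)]] <- "train"
    if (n_valid > 0L) split[idx[n_train + seq_len(n_valid)]] <- "valid"
    rest <- idx[setdiff(seq_len(n), seq_len(n_train + n_valid))]
    split[rest] <- "test"
  }
  dplyr::mutate(tuples, split = factor(split, c("train", "valid", "test")))
}

#' Inductive (cold-start) partition
#'
#' Selects one-fifth of the drugs as novel (`Dnew`) and partitions the
#' positive tuples accordingly: `Ms1` has both drugs novel, `Ms2` exactly
#' one, and `Mtrain` none. The three subsets are disjoint and cover all
#' tuples.
#'
#' @param tuples Positive tuple tibble.
#' @param drugs Drug table (or character vector of drug ids).
#' @param seed Integer seed.
#' @param repeat_index Repetition number.
#' @return The tuples with a `subset` factor column
#'   (`Mtrain`/`Ms1`/`Ms2`) and the novel drug ids in `attr(, "d_new")`.
#' @export
split_inductive <- function(tuples, drugs, seed = 1L, repeat_index = 1L) {
  ids <- if (is.data.frame(drugs)) drugs$drug_id else drugs
  if (length(ids) < 5L) stop("need at least 5 drugs", call. = FALSE)
  set.seed((seed + 7919L * (repeat_index - 1L)) %% .Machine$integer.max)
  d_new <- sort(sample(ids, floor(length(ids) / 5)))
  in_new_x <- tuples$drug_x %in% d_new
  in_new_y <- tuples$drug_y %in% d_new
  subset <- dplyr::case_when(
    in_new_x & in_new_y ~ "Ms1",
    xor(in_new_x, in_new_y) ~ "Ms2",
    TRUE ~ "Mtrain"
  )
  out <- dplyr::mutate(tuples, subset = factor(subset,
                                               c("Mtrain", "Ms1", "Ms2")))
  attr(out, "d_new") <- d_new
  out
}

#' Range-constrained negatives for the inductive protocol
#'
#' Applies [sample_negatives()] per subset with the cold-start pool
#' constraints: `Mtrain` negatives draw replacement drugs only from drugs not
#' in `Dnew`; `Ms1` negatives only from drugs present in both `Dnew` and
#' `Ms1`; `Ms2` follows the same rule as `Ms1`, applied to its own drugs
#' (replacements from `Dnew` intersected with the drugs of `Ms2`).
#'
#' @param partition Output of [split_inductive()] (must carry the `d_new`
#'   attribute or it can be passed explicitly).
#' @param drugs Drug table or character vector of all drug ids.
#' @param seed Integer seed.
#' @param d_new Novel drug set (defaults to `attr(partition, "d_new")`).
#' @return Tibble of negatives (label 0) with the same `subset` column.
#' @export
constrained_negatives <- function(partition, drugs, seed = 1L,
                                  d_new = attr(partition, "d_new")) {
  if (is.null(d_new)) stop("novel drug set d_new is missing", call. = FALSE)
  ids <- if (is.data.frame(drugs)) drugs$drug_id else drugs
  out <- list()
  for (ss in levels(partition$subset)) {
    pos <- dplyr::filter(partition, .data$subset == ss)
    if (nrow(pos) == 0L) next
    pool <- switch(ss,
      Mtrain = setdiff(ids, d_new),
      Ms1 = intersect(d_new, unique(c(pos$drug_x, pos$drug_y))),
      Ms2 = intersect(d_new, unique(c(pos$drug_x, pos$drug_y)))
    )
    if (length(pool) == 0L) {
      stop(sprintf("empty negative-sampling pool for subset %s", ss),
           call. = FALSE)
    }
    neg <- sample_negatives(pos, pool, seed = seed + match(ss, levels(partition$subset)),
                            known_positives = partition)
    neg$subset <- factor(ss, levels(partition$subset))
    out[[ss]] <- neg
  }
  dplyr::bind_rows(out)
}
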