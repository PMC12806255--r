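# Delimited-text readers/writers for drug and tuple tables, and a JSON
# checkpoint format for fitted models.

#' Read and write drug / tuple tables
#'
#' Drug tables are tab-separated with columns `drug_id`, `smiles`; tuple
#' tables with `drug_x`, `drug_y`, `relation`, and optionally `label`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_drug_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    drug_id = readr::col_character(), smiles = readr::col_character()))
}

#' @rdname read_drug_table
#' @export
read_tuple_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  tb$drug_x <- as.character(tb$drug_x)
  tb$drug_y <- as.character(tb$drug_y)
  tb
}

#' @rdname read_drug_table
#' @param x Tibble to write.
#' @export
write_ddi_table <- function(x, path) {
  readr::write_tsv(dplyr::select(x, !dplyr::where(is.list)), path)
  invisible(path)
}

#' Save or load a fitted model
#'
#' The checkpoint is a single JSON file holding the configuration, the
#' relation vocabulary, the drug table, and every parameter matrix with its
#' shape manifest — plain text, re-loadable anywhere.
#'
#' @param fit A `ddi_fit`.
#' @param path Target JSON path.
#' @return `ddi_save` returns `path` invisibly; `ddi_load` returns the
#'   restored `ddi_fit`.
#' @export
ddi_save <- function(fit, path) {
  obj <- list(
    config = unclass(fit$config),
    relations = fit$relations,
    drugs = fit$drugs[, c("drug_id", "smiles")],
    history = fit$history,
    params = lapply(fit$params, function(w) {
      list(dim = dim(w), data = as.vector(w))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname ddi_save
#' @export
ddi_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(ddi_config, obj$config[names(obj$config) %in%
                                          names(formals(ddi_config))])
  params <- lapply(obj$params, function(w) {
    matrix(w$data, nrow = w$dim[1], ncol = w$dim[2])
  })
  drugs <- tibble::as_tibble(obj$drugs)
  graphs <- lapply(drugs$smiles, parse_smiles)
  relations <- obj$relations
  structure(list(
    params = params, config = cfg, relations = relations, drugs = drugs,
    graphs = graphs, bd = batch_graphs(graphs),
    drug_index = stats::setNames(seq_len(nrow(drugs)), drugs$drug_id),
    history = tibble::as_tibble(obj$history)
  ), class = "ddi_fit")
}
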