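# broom-style accessors and ggplot2 autoplot methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted model
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `lr`.
#' @export
tidy.ddi_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return Tibble with the key configuration values, the number of drugs and
#'   relations, and the final training loss.
#' @export
glance.ddi_fit <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x$drugs),
    n_relations = length(x$relations),
    T = x$config$T,
    hidden = x$config$hidden,
    alpha = x$config$alpha,
    epochs = nrow(x$history),
    final_loss = utils::tail(x$history$loss, 1L),
    mean_pool = x$config$mean_pool,
    no_drip = x$config$no_drip
  )
}

#' Training-loss curve
#'
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @return A ggplot of loss against epoch.
#' @export
autoplot.ddi_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "DDI model training") +
    ggplot2::theme_minimal()
}

#' Substructure-importance profile of explained pairs
#'
#' Bar chart of the per-atom importance weights `mu` for each drug of each
#' explained pair; the tallest bar marks the substructure the model holds
#' responsible for the interaction.
#'
#' @param object A `ddi_explain` from [ddi_explain()].
#' @param ... Unused.
#' @return A ggplot faceted by pair and drug role.
#' @export
autoplot.ddi_explain <- function(object, ...) {
  ggplot2::ggplot(object$atoms,
                  ggplot2::aes(x = factor(.data$atom), y = .data$mu,
                               fill = .data$element)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ pair + role + drug_id, scales = "free_x") +
    ggplot2::labs(x = "atom", y = expression(mu),
                  title = "Substructure importance") +
    ggplot2::theme_minimal()
}
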