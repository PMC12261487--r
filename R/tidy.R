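# broom-style accessors and ggplot2 displays for fitted models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a synergy fit
#'
#' @param x A `synergy_fit`.
#' @param ... Unused.
#' @return The per-epoch log: losses (total and the three components),
#'   validation loss and validation AUC-ROC.
#' @method tidy synergy_fit
#' @export
tidy.synergy_fit <- function(x, ...) {
  x$epoch_log
}

#' One-row summary of a synergy fit
#'
#' @param x A `synergy_fit`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch, best validation loss,
#'   scenario, and sample counts per partition.
#' @method glance synergy_fit
#' @export
glance.synergy_fit <- function(x, ...) {
  tab <- table(x$assignment$part)
  tibble::tibble(
    epochs = nrow(x$epoch_log),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    scenario = if (is.null(x$split)) "full-data" else x$split$scenario,
    n_train = as.integer(tab[["train"]]),
    n_val = as.integer(tab[["val"]]),
    n_test = if ("test" %in% names(tab)) as.integer(tab[["test"]]) else 0L
  )
}

#' Training-curve plot for a synergy fit
#'
#' @param object A `synergy_fit`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss across epochs.
#' @method autoplot synergy_fit
#' @export
autoplot.synergy_fit <- function(object, ...) {
  df <- object$epoch_log |>
    dplyr::select("epoch", train = "loss_total", validation = "val_loss") |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of order-independence predictions
#'
#' @param oi Result of [order_independence()].
#' @return A ggplot of forward-order versus swapped-order probabilities.
#' @export
plot_order_independence <- function(oi) {
  ggplot2::ggplot(oi$scatter, ggplot2::aes(.data$prob_fwd, .data$prob_rev)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "P(synergy | drug1, drug2)",
      y = "P(synergy | drug2, drug1)",
      subtitle = sprintf("Pearson r = %.3f", oi$pcc)
    ) +
    ggplot2::theme_minimal()
}

#' Atom-importance profile plot
#'
#' @param importance Result of [explain_drug()].
#' @return A ggplot of per-layer normalized atom importance.
#' @export
plot_atom_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(factor(.data$atom), .data$score,
                               fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~layer, ncol = 1L,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "atom index", y = "importance (min-max per layer)") +
    ggplot2::theme_minimal()
}
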