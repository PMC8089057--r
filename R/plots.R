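#' Plot a contact map
#'
#' Raster view of a predicted (probability) or true (binary) contact map;
#' residue 1 at the top-left, as conventional for contact maps.
#'
#' @param object a [contact_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  d <- tidy.contact_map(object)
  d2 <- tibble::tibble(i = d$j, j = d$i, value = d$value)
  dd <- rbind(d, d2)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue j", y = "residue i",
                  fill = if (object$kind == "binary") "contact" else "P(contact)") +
    ggplot2::theme_minimal()
}

#' Plot the training trajectory
#'
#' @param object a `train_state` from [train()].
#' @param ... unused.
#' @return a ggplot object: loss and validation precision by epoch.
#' @method autoplot train_state
#' @export
autoplot.train_state <- function(object, ...) {
  d <- object$log
  dd <- rbind(
    tibble::tibble(epoch = d$epoch, value = d$loss, metric = "training loss"),
    tibble::tibble(epoch = d$epoch, value = d$val_precision,
                   metric = "validation top-L/2 long-range precision"))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ROC and precision-recall curves
#'
#' @param curves result of [roc_pr()], or a named list of such results to
#'   overlay (names become the legend).
#' @return a ggplot object with ROC and PR panels.
#' @export
plot_roc_pr <- function(curves) {
  if (!is.null(curves$roc)) curves <- list(model = curves)
  dd <- list()
  for (nm in names(curves)) {
    cu <- curves[[nm]]
    dd[[length(dd) + 1L]] <- tibble::tibble(
      x = cu$roc$fpr, y = cu$roc$tpr, panel = "ROC", model = nm)
    dd[[length(dd) + 1L]] <- tibble::tibble(
      x = cu$pr$recall, y = cu$pr$precision, panel = "Precision-Recall",
      model = nm)
  }
  dd <- do.call(rbind, dd)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
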