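#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-epoch training log
#'
#' @param x a `train_state` from [train()].
#' @param ... unused.
#' @return tibble with `epoch`, `loss`, `val_precision`, `phase`.
#' @method tidy train_state
#' @export
tidy.train_state <- function(x, ...) x$log

#' One-row training summary
#'
#' @param x a `train_state` from [train()].
#' @param ... unused.
#' @return tibble with `epochs`, `best_epoch`, `best_val_precision`,
#'   `final_loss`, `n_parameters`.
#' @method glance train_state
#' @export
glance.train_state <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_precision = x$log$val_precision[x$log$epoch == x$best_epoch],
    final_loss = x$log$loss[nrow(x$log)],
    n_parameters = n_parameters(x$model$params))
}

#' Tidy a contact map into long pair form
#'
#' @param x a [contact_map()].
#' @param ... unused.
#' @return tibble with `i`, `j`, `value` (upper triangle only).
#' @method tidy contact_map
#' @export
tidy.contact_map <- function(x, ...) {
  v <- map_values(x)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], value = v[idx])
}
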