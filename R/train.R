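# Training protocol: binary cross-entropy on pairs with sequence separation
# >= 6, batch size 1, Adam (lr 0.001) for the first 30 epochs then SGD with
# momentum (lr 0.01, momentum 0.9), per-epoch checkpointing, and model
# selection by top-L/2 long-range precision on the validation set.

#' Training schedule
#'
#' @param phase1_lr Adam learning rate (first phase, default 0.001).
#' @param phase2_lr SGD learning rate (second phase, default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param switch_epoch first epoch (0-based) of the SGD phase (default 30).
#' @param stop_epoch training stops when this epoch is reached (default 60).
#' @param batch_size optimization batch size; fixed at 1 protein per step.
#' @return object of class `train_schedule`.
#' @export
train_schedule <- function(phase1_lr = 0.001, phase2_lr = 0.01, momentum = 0.9,
                           switch_epoch = 30L, stop_epoch = 60L,
                           batch_size = 1L) {
  stopifnot(switch_epoch < stop_epoch, phase1_lr > 0, phase2_lr > 0,
            batch_size == 1L)
  structure(list(phase1_lr = phase1_lr, phase2_lr = phase2_lr,
                 momentum = momentum, switch_epoch = as.integer(switch_epoch),
                 stop_epoch = as.integer(stop_epoch), batch_size = 1L),
            class = "train_schedule")
}

#' Optimizer specification for an epoch
#'
#' Epochs 0 to `switch_epoch - 1` use the adaptive-moment optimizer (Adam)
#' at `phase1_lr`; epochs up to `stop_epoch - 1` use SGD with momentum;
#' from `stop_epoch` on, training stops.
#'
#' @param epoch 0-based epoch index.
#' @param schedule a [train_schedule()].
#' @return list with `kind` (`"adam"`, `"sgd"` or `"stop"`) and, when
#'   applicable, `lr` and `momentum`.
#' @export
optimizer_phase <- function(epoch, schedule = train_schedule()) {
  stopifnot(epoch >= 0L)
  if (epoch >= schedule$stop_epoch) return(list(kind = "stop"))
  if (epoch < schedule$switch_epoch) {
    list(kind = "adam", lr = schedule$phase1_lr)
  } else {
    list(kind = "sgd", lr = schedule$phase2_lr, momentum = schedule$momentum)
  }
}

loss_pair_mask <- function(L, truth = NULL, min_sep = 6L) {
  sep <- abs(outer(seq_len(L), seq_len(L), `-`))
  w <- (sep >= min_sep) * 1
  if (!is.null(truth) && inherits(truth, "contact_map") && !is.null(truth$valid)) {
    w <- w * truth$valid
  }
  w
}

#' Masked binary cross-entropy contact loss
#'
#' Mean binary cross-entropy over pair weights `mask` (by default all pairs
#' with sequence separation >= 6, intersected with the truth's validity
#' mask). Predictions are clipped away from 0/1 for finiteness.
#'
#' @param pred probability [contact_map()] or matrix.
#' @param truth binary [contact_map()] or matrix.
#' @param mask optional numeric/logical weight matrix.
#' @return scalar loss.
#' @export
contact_loss <- function(pred, truth, mask = NULL) {
  p <- map_values(pred)
  y <- map_values(truth)
  stopifnot(identical(dim(p), dim(y)))
  if (is.null(mask)) mask <- loss_pair_mask(nrow(p), truth)
  mask <- mask * 1
  if (sum(mask) == 0) stop("contact_loss: all pairs masked")
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  li <- -(y * log(p) + (1 - y) * log(1 - p))
  sum(mask * li) / sum(mask)
}

# one optimization step on a single protein; returns updated params/opt + loss
train_step <- function(pl, cfg, item, opt, spec) {
  fs <- item$features
  tape <- ad_tape()
  plh <- lapply(pl, function(v) ad_leaf(tape, v))
  fw <- forward_graph(tape, fs, plh, cfg)
  y <- matrix(map_values(item$contacts), ncol = 1L)
  w <- matrix(loss_pair_mask(fs$L, item$contacts), ncol = 1L)
  loss_node <- ad_bce_masked(fw$logits, y, w)
  loss <- as.numeric(ad_value(loss_node))
  if (!is.finite(loss)) {
    stop("train: non-finite loss on protein '", fs$record$id %||% "?", "'")
  }
  grads_all <- ad_backward(tape, loss_node)
  grads <- stats::setNames(
    lapply(names(pl), function(nm) grads_all[[plh[[nm]]$id]]), names(pl))
  st <- opt_step(opt, pl, grads, spec)
  list(params = st$params, opt = st$state, loss = loss)
}

validation_precision <- function(pl, cfg, valset, divisor = 2L) {
  model <- contact_model(cfg, params = pl)
  vals <- vapply(valset, function(it) {
    pred <- symmetrize(predict_contacts(model, it$features)$map)
    top_ln_precision(pred, it$contacts, range = "long", divisor = divisor)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Train a contact prediction module
#'
#' One protein per optimization step (batch size 1). At the end of each
#' epoch the weights are checkpointed and the top-L/2 long-range precision
#' on the validation set is logged; the returned model is the checkpoint
#' with the best validation score (ties broken by earliest epoch). Fully
#' deterministic given `seed` (initialization and data order).
#'
#' @param dataset list of items from [make_dataset()] (fields `features`,
#'   `contacts`).
#' @param valset validation items, same structure.
#' @param config a [model_config()].
#' @param schedule a [train_schedule()].
#' @param seed integer seed.
#' @param epochs optional cap on trained epochs (default `stop_epoch`).
#' @param checkpoint_dir directory for per-epoch checkpoints.
#' @param verbose print per-epoch progress?
#' @return object of class `train_state`: fields `log` (tibble: epoch, loss,
#'   val_precision, phase), `checkpoints`, `best_epoch` (0-based), `model`
#'   (the selected [contact_model()]), `config`, `seed`.
#' @export
train <- function(dataset, valset, config, schedule = train_schedule(),
                  seed = 1L, epochs = NULL,
                  checkpoint_dir = tempfile("ckpt"), verbose = FALSE) {
  stopifnot(length(dataset) > 0, length(valset) > 0)
  dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  n_ep <- min(epochs %||% schedule$stop_epoch, schedule$stop_epoch)
  with_local_seed(subseed(seed, 0L, salt = 21L), {
    pl <- init_model_params(config, seed = subseed(seed, 1L, salt = 22L))
    opt <- NULL
    kind_prev <- ""
    log_epoch <- integer(0); log_loss <- numeric(0)
    log_val <- numeric(0); log_phase <- character(0)
    ckpts <- character(0)
    for (e in seq_len(n_ep) - 1L) {
      spec <- optimizer_phase(e, schedule)
      if (spec$kind == "stop") break
      if (spec$kind != kind_prev) {
        opt <- opt_init(spec$kind, pl)
        kind_prev <- spec$kind
      }
      ord <- sample(length(dataset))
      losses <- numeric(length(ord))
      for (s in seq_along(ord)) {
        st <- train_step(pl, config, dataset[[ord[s]]], opt, spec)
        pl <- st$params; opt <- st$opt; losses[s] <- st$loss
      }
      val <- validation_precision(pl, config, valset)
      ck <- file.path(checkpoint_dir, sprintf("epoch_%03d.rds", e))
      saveRDS(list(format = "contattn_checkpoint", epoch = e, params = pl,
                   config = config, val_precision = val,
                   mean_loss = mean(losses)), ck)
      ckpts <- c(ckpts, ck)
      log_epoch <- c(log_epoch, e); log_loss <- c(log_loss, mean(losses))
      log_val <- c(log_val, val); log_phase <- c(log_phase, spec$kind)
      if (verbose) {
        message(sprintf("epoch %d [%s] loss %.4f val top-L/2 long %.3f",
                        e, spec$kind, mean(losses), val))
      }
    }
    # ties -> earliest epoch; if no epoch produced a finite validation score
    # (e.g. every validation target too short for long-range pairs), keep the
    # final epoch
    vals <- ifelse(is.finite(log_val), log_val, -Inf)
    best <- if (all(vals == -Inf)) length(vals) else which.max(vals)
    best_ck <- readRDS(ckpts[best])
    structure(list(
      log = tibble::tibble(epoch = log_epoch, loss = log_loss,
                           val_precision = log_val, phase = log_phase),
      checkpoints = ckpts, best_epoch = log_epoch[best],
      model = contact_model(config, params = best_ck$params),
      config = config, seed = seed),
      class = "train_state")
  })
}

#' Load a training checkpoint
#'
#' @param path checkpoint file written during [train()].
#' @return list with `model` (a [contact_model()]), `epoch`,
#'   `val_precision`, `mean_loss`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "contattn_checkpoint")) {
    stop("load_checkpoint: not a checkpoint file: ", path)
  }
  list(model = contact_model(x$config, params = x$params), epoch = x$epoch,
       val_precision = x$val_precision, mean_loss = x$mean_loss)
}

#' @export
print.train_state <- function(x, ...) {
  cat("<train_state> ", nrow(x$log), " epochs; best epoch ", x$best_epoch,
      " (val top-L/2 long-range precision ",
      sprintf("%.3f", x$log$val_precision[x$log$epoch == x$best_epoch]),
      ")\n", sep = "")
  invisible(x)
}
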