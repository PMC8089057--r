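# Assembly of the two prediction branches: the sequence attention module
# (profile -> 1D conv -> BiLSTM -> multi-head attention -> tiled to 2D) and
# the regional attention module (tiled profile + couplings -> residual trunk
# -> windowed regional attention), each ending in a 1x1 convolution with
# sigmoid to an L x L contact probability map.

# builds the forward graph; pl entries may be raw matrices (inference) or
# tape leaves (training). Returns logits (P x 1 node) and attention nodes.
forward_graph <- function(tape, fs, pl, cfg) {
  L <- fs$L
  P <- L * L
  plm_mat <- map_to_mat(fs$plm)
  att1d <- NULL; att2d <- NULL
  if (cfg$variant == "sequence") {
    x1 <- ad_leaf(tape, fs$pssm)
    x1 <- ad_instance_norm(x1, pl[["in1d.gamma"]], pl[["in1d.beta"]])
    x1 <- ad_relu(bld_conv(x1, pl[["conv1d.W"]], pl[["conv1d.b"]],
                           conv_idx1d(L, cfg$conv1d_kernel)))
    h <- cfg$lstm_hidden
    enc <- ad_cbind(
      bld_lstm_dir(x1, pl[["lstm.fwd.W"]], pl[["lstm.fwd.b"]], L, h, FALSE),
      bld_lstm_dir(x1, pl[["lstm.bwd.W"]], pl[["lstm.bwd.b"]], L, h, TRUE))
    if (cfg$use_attention) {
      att1d <- bld_att1d(enc, pl, cfg$n_heads, cfg$d_att)
      Z <- att1d$Z
    } else {
      Z <- enc
    }
    tz <- bld_tile(Z, L)
    p2 <- ad_leaf(tape, plm_mat)
    p2 <- ad_relu(ad_instance_norm(p2, pl[["in2d.gamma"]], pl[["in2d.beta"]]))
    p2 <- ad_maxout(ad_add(ad_matmul(p2, pl[["convin.W"]]), pl[["convin.b"]]))
    x <- ad_cbind(tz, p2)
  } else {
    ti <- tile_idx(L)
    xin <- cbind(plm_mat,
                 fs$pssm[ti[, 1], , drop = FALSE],
                 fs$pssm[ti[, 2], , drop = FALSE])
    x <- ad_leaf(tape, xin)
    x <- ad_relu(ad_instance_norm(x, pl[["in2d.gamma"]], pl[["in2d.beta"]]))
    x <- ad_maxout(ad_add(ad_matmul(x, pl[["convin.W"]]), pl[["convin.b"]]))
  }
  x <- bld_trunk(x, pl, cfg$repeats, L)
  if (cfg$variant == "regional") {
    x <- ad_relu(bld_conv(x, pl[["conv32.W"]], pl[["conv32.b"]],
                          conv_idx2d(L, 3L)))
    if (cfg$use_attention) {
      att2d <- bld_att2d(x, pl, L, cfg$att2d_channels, cfg$region_n,
                         cfg$n_heads, cfg$att2d_d)
      x <- att2d$out
    }
  }
  logits <- ad_add(ad_matmul(x, pl[["out.W"]]), pl[["out.b"]])
  list(logits = logits, att1d = att1d, att2d = att2d)
}

#' Captured attention weights for one forward pass
#'
#' @param seq_W sequence attention weights, `n_heads x L x L` (rows
#'   row-stochastic) or NULL.
#' @param reg_W regional attention weights, `(L, L, n_heads, n^2)` or NULL.
#' @param reg_mask in-bounds window mask `(L, L, n^2)` or NULL.
#' @param protein_id,variant provenance.
#' @return object of class `attention_record`.
#' @export
attention_record <- function(seq_W = NULL, reg_W = NULL, reg_mask = NULL,
                             protein_id = NA_character_, variant = NA_character_) {
  structure(list(seq_W = seq_W, reg_W = reg_W, reg_mask = reg_mask,
                 protein_id = protein_id, variant = variant),
            class = "attention_record")
}

#' Contact prediction model
#'
#' A configuration plus its flat parameter list.
#'
#' @param config a [model_config()].
#' @param params optional parameter list; initialized from `seed` when NULL.
#' @param seed seed for [init_model_params()].
#' @return object of class `contact_model`.
#' @export
contact_model <- function(config, params = NULL, seed = 1L) {
  if (is.null(params)) params <- init_model_params(config, seed)
  structure(list(config = config, params = params), class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat("<contact_model> variant =", x$config$variant,
      if (!x$config$use_attention) "(no attention)",
      "| preset =", x$config$preset,
      "|", n_parameters(x$params), "parameters\n")
  invisible(x)
}

#' Predict a contact map
#'
#' Runs the module forward pass and returns the L x L contact probability
#' map. With `capture = TRUE` the attention weights of the pass are stored
#' in an [attention_record()]; capture never changes the predictions.
#'
#' @param model a [contact_model()] or [contact_ensemble()].
#' @param fs a [feature_set()].
#' @param capture store attention weights?
#' @param ... unused.
#' @return list of class `prediction_output` with fields `map` (probability
#'   [contact_map()]) and `attention` (an `attention_record` or NULL).
#' @export
predict_contacts <- function(model, fs, capture = FALSE, ...) {
  UseMethod("predict_contacts")
}

#' @export
predict_contacts.contact_model <- function(model, fs, capture = FALSE, ...) {
  cfg <- model$config
  check_fs_model(fs, cfg)
  tape <- ad_tape()
  fw <- forward_graph(tape, fs, model$params, cfg)
  map <- matrix(stats::plogis(ad_value(fw$logits)), fs$L, fs$L)
  att <- NULL
  if (capture) {
    L <- fs$L
    seq_W <- NULL; reg_W <- NULL; reg_mask <- NULL
    if (!is.null(fw$att1d)) {
      seq_W <- array(0, dim = c(cfg$n_heads, L, L))
      for (h in seq_len(cfg$n_heads)) seq_W[h, , ] <- ad_value(fw$att1d$W[[h]])
    }
    if (!is.null(fw$att2d)) {
      n2 <- cfg$region_n^2
      reg_W <- array(0, dim = c(L, L, cfg$n_heads, n2))
      for (h in seq_len(cfg$n_heads)) {
        reg_W[, , h, ] <- array(ad_value(fw$att2d$W[[h]]), dim = c(L, L, n2))
      }
      reg_mask <- array(fw$att2d$mask, dim = c(L, L, n2))
    }
    att <- attention_record(seq_W, reg_W, reg_mask,
                            protein_id = fs$record$id %||% NA_character_,
                            variant = cfg$variant)
  }
  structure(list(map = contact_map(map, "probability"), attention = att),
            class = "prediction_output")
}

check_fs_model <- function(fs, cfg) {
  if (fs$C != cfg$plm_channels) {
    stop("feature set has ", fs$C, " coupling channels but the model expects ",
         cfg$plm_channels)
  }
  if (ncol(fs$pssm) != cfg$pssm_cols) {
    stop("feature set PSSM has ", ncol(fs$pssm), " columns; expected ", cfg$pssm_cols)
  }
  if (fs$L < 8L) stop("module forward passes require L >= 8, got L = ", fs$L)
  invisible(TRUE)
}

#' Sequence attention module forward pass
#'
#' @inheritParams predict_contacts
#' @return a `prediction_output`.
#' @export
sequence_module_forward <- function(model, fs, capture = FALSE) {
  stopifnot(model$config$variant == "sequence")
  predict_contacts(model, fs, capture = capture)
}

#' Regional attention module forward pass
#'
#' @inheritParams predict_contacts
#' @return a `prediction_output`.
#' @export
regional_module_forward <- function(model, fs, capture = FALSE) {
  stopifnot(model$config$variant == "regional")
  predict_contacts(model, fs, capture = capture)
}

#' Two-module ensemble
#'
#' @param sequence_model,regional_model fitted [contact_model()]s.
#' @return object of class `contact_ensemble`.
#' @export
contact_ensemble <- function(sequence_model, regional_model) {
  stopifnot(sequence_model$config$variant == "sequence",
            regional_model$config$variant == "regional")
  structure(list(sequence = sequence_model, regional = regional_model),
            class = "contact_ensemble")
}

#' @export
predict_contacts.contact_ensemble <- function(model, fs, capture = FALSE, ...) {
  a <- predict_contacts(model$sequence, fs, capture = capture)
  b <- predict_contacts(model$regional, fs, capture = capture)
  att <- NULL
  if (capture) {
    att <- attention_record(
      seq_W = a$attention$seq_W, reg_W = b$attention$reg_W,
      reg_mask = b$attention$reg_mask,
      protein_id = fs$record$id %||% NA_character_, variant = "ensemble")
  }
  structure(list(map = ensemble_predict(a$map, b$map), attention = att),
            class = "prediction_output")
}

#' Average two predicted contact maps
#'
#' The final prediction is the elementwise mean of the two modules' maps.
#'
#' @param a,b probability [contact_map()]s of the same size.
#' @return probability [contact_map()].
#' @export
ensemble_predict <- function(a, b) {
  va <- map_values(a); vb <- map_values(b)
  if (!identical(dim(va), dim(vb))) stop("ensemble_predict: shape mismatch")
  contact_map((va + vb) / 2, "probability")
}

#' Symmetrize a contact map
#'
#' `out = (m + t(m)) / 2`; applied before ranking and evaluation.
#'
#' @param m a [contact_map()] or plain matrix.
#' @return symmetrized [contact_map()] (probability kind preserved).
#' @export
symmetrize <- function(m) {
  v <- map_values(m)
  kind <- if (inherits(m, "contact_map")) m$kind else "probability"
  contact_map((v + t(v)) / 2, kind)
}
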