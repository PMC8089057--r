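#' Model configuration
#'
#' Collects every architectural hyperparameter of the two prediction modules.
#' Two presets are provided: `"paper"` mirrors the published architecture
#' (441 coevolution channels, 64-kernel trunk with residual repeats 3-4-6-3,
#' 4 attention heads of width 32, 5x5 attention regions) and `"tiny"` is a
#' desk-scale configuration suitable for CPU training on synthetic data
#' (16 channels, width-16 trunk with repeats 1-1-1-1).
#'
#' @param variant `"sequence"` or `"regional"`; which prediction branch the
#'   configuration describes.
#' @param preset `"tiny"` or `"paper"`.
#' @param use_attention if `FALSE`, the attention layer of the branch is
#'   removed (the no-attention baseline variant; both branches minus their
#'   attention layers, ensembled, form the baseline model).
#' @param ... named overrides for individual fields (e.g. `plm_channels`).
#'
#' @return An object of class `model_config`: a named list with fields
#'   `plm_channels`, `pssm_cols`, `conv1d_filters`, `conv1d_kernel`,
#'   `lstm_hidden`, `n_heads`, `d_att`, `att2d_channels`, `att2d_d`,
#'   `region_n`, `trunk_width`, `reduce_width`, `repeats`, `se_ratio`,
#'   `out_bias_init`, `variant`, `use_attention`.
#' @export
model_config <- function(variant = c("sequence", "regional"),
                         preset = c("tiny", "paper"),
                         use_attention = TRUE, ...) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(plm_channels = 441L, pssm_cols = 20L,
         conv1d_filters = 64L, conv1d_kernel = 5L, lstm_hidden = 64L,
         n_heads = 4L, d_att = 32L,
         att2d_channels = 32L, att2d_d = 32L, region_n = 5L,
         trunk_width = 64L, reduce_width = 128L, repeats = c(3L, 4L, 6L, 3L),
         se_ratio = 16L, out_bias_init = -2)
  } else {
    list(plm_channels = 16L, pssm_cols = 20L,
         conv1d_filters = 16L, conv1d_kernel = 5L, lstm_hidden = 16L,
         n_heads = 2L, d_att = 8L,
         att2d_channels = 8L, att2d_d = 8L, region_n = 5L,
         trunk_width = 16L, reduce_width = 32L, repeats = c(1L, 1L, 1L, 1L),
         se_ratio = 4L, out_bias_init = -2)
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown model_config field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  stopifnot(all(cfg$repeats >= 1L), cfg$trunk_width >= 1L,
            cfg$reduce_width %% 2L == 0L, cfg$region_n %% 2L == 1L)
  cfg$variant <- variant
  cfg$use_attention <- isTRUE(use_attention)
  cfg$preset <- preset
  structure(cfg, class = "model_config")
}

# truncated normal init (resample beyond 2 sd), He-style fan-in scaling
trunc_normal <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

init_w <- function(nr, nc, fan_in = nr) {
  matrix(trunc_normal(nr * nc, sqrt(2 / fan_in)), nr, nc)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Initialize model parameters
#'
#' Weights are drawn from a truncated normal (values beyond two standard
#' deviations resampled) with He fan-in scaling; biases start at zero except
#' the LSTM forget gate (1) and the output convolution bias
#' (`config$out_bias_init`, a prior log-odds for the rare contact class).
#'
#' @param config a [model_config()].
#' @param seed integer seed; initialization is fully deterministic given it.
#' @return flat named list of parameter matrices.
#' @export
init_model_params <- function(config, seed = 1L) {
  with_local_seed(seed, {
    pl <- list()
    tw <- config$trunk_width
    if (config$variant == "sequence") {
      f <- config$conv1d_filters; h <- config$lstm_hidden
      k <- config$conv1d_kernel
      pl[["in1d.gamma"]] <- matrix(1, 1L, config$pssm_cols)
      pl[["in1d.beta"]] <- matrix(0, 1L, config$pssm_cols)
      pl[["conv1d.W"]] <- init_w(k * config$pssm_cols, f)
      pl[["conv1d.b"]] <- matrix(0, 1L, f)
      for (dir in c("fwd", "bwd")) {
        W <- init_w(f + h, 4L * h, fan_in = f + h)
        b <- matrix(0, 1L, 4L * h)
        b[1L, (h + 1L):(2L * h)] <- 1  # forget gate bias
        pl[[paste0("lstm.", dir, ".W")]] <- W
        pl[[paste0("lstm.", dir, ".b")]] <- b
      }
      enc <- 2L * h
      if (config$use_attention) {
        H <- config$n_heads; da <- config$d_att
        pl[["att1d.Win"]] <- init_w(enc, H * da)
        pl[["att1d.bin"]] <- matrix(0, 1L, H * da)
        for (hh in seq_len(H)) {
          pl[[sprintf("att1d.h%d.Wq", hh)]] <- init_w(da, da)
          pl[[sprintf("att1d.h%d.Wk", hh)]] <- init_w(da, da)
          pl[[sprintf("att1d.h%d.Wv", hh)]] <- init_w(da, da)
        }
        tile_d <- H * da
      } else {
        tile_d <- enc
      }
      c2 <- config$plm_channels
      trunk_in <- tw + 2L * tile_d
    } else {
      c2 <- config$plm_channels + 2L * config$pssm_cols
      trunk_in <- tw
    }
    pl[["in2d.gamma"]] <- matrix(1, 1L, c2)
    pl[["in2d.beta"]] <- matrix(0, 1L, c2)
    pl[["convin.W"]] <- init_w(c2, config$reduce_width)
    pl[["convin.b"]] <- matrix(0, 1L, config$reduce_width)
    # residual trunk
    cin <- trunk_in
    r <- max(1L, tw %/% config$se_ratio)
    for (b in seq_along(config$repeats)) {
      cc <- cin
      for (rep_i in seq_len(config$repeats[b])) {
        pre <- sprintf("trunk.blk%d.c%d.", b, rep_i)
        pl[[paste0(pre, "gamma")]] <- matrix(1, 1L, cc)
        pl[[paste0(pre, "beta")]] <- matrix(0, 1L, cc)
        pl[[paste0(pre, "W")]] <- init_w(9L * cc, tw)
        pl[[paste0(pre, "b")]] <- matrix(0, 1L, tw)
        cc <- tw
      }
      pre <- sprintf("trunk.blk%d.", b)
      pl[[paste0(pre, "short.W")]] <- init_w(cin, tw)
      pl[[paste0(pre, "short.b")]] <- matrix(0, 1L, tw)
      pl[[paste0(pre, "se.W1")]] <- init_w(tw, r)
      pl[[paste0(pre, "se.b1")]] <- matrix(0, 1L, r)
      pl[[paste0(pre, "se.W2")]] <- init_w(r, tw)
      pl[[paste0(pre, "se.b2")]] <- matrix(0, 1L, tw)
      cin <- tw
    }
    if (config$variant == "regional") {
      ca <- config$att2d_channels
      pl[["conv32.W"]] <- init_w(9L * tw, ca)
      pl[["conv32.b"]] <- matrix(0, 1L, ca)
      if (config$use_attention) {
        H <- config$n_heads; d2 <- config$att2d_d
        for (hh in seq_len(H)) {
          pl[[sprintf("att2d.h%d.Wq", hh)]] <- init_w(ca, d2)
          pl[[sprintf("att2d.h%d.Wk", hh)]] <- init_w(ca, d2)
          pl[[sprintf("att2d.h%d.Wv", hh)]] <- init_w(ca, d2)
        }
        pl[["att2d.Wo"]] <- init_w(H * d2, ca)
        pl[["att2d.bo"]] <- matrix(0, 1L, ca)
      }
      pl[["out.W"]] <- init_w(ca, 1L)
    } else {
      pl[["out.W"]] <- init_w(tw, 1L)
    }
    pl[["out.b"]] <- matrix(config$out_bias_init, 1L, 1L)
    pl
  })
}

#' Count trainable parameters
#'
#' @param x a `model_config` or a flat parameter list.
#' @param ... unused.
#' @return integer scalar.
#' @export
n_parameters <- function(x, ...) {
  pl <- if (inherits(x, "model_config")) init_model_params(x, seed = 1L) else x
  sum(vapply(pl, length, integer(1)))
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(kind, pl) {
  if (kind == "adam") {
    list(kind = "adam", t = 0L,
         m = lapply(pl, function(p) p * 0),
         v = lapply(pl, function(p) p * 0))
  } else {
    list(kind = "sgd", vel = lapply(pl, function(p) p * 0))
  }
}

opt_step <- function(state, pl, grads, spec) {
  if (state$kind == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    for (nm in names(pl)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
      mh <- state$m[[nm]] / (1 - b1^state$t)
      vh <- state$v[[nm]] / (1 - b2^state$t)
      pl[[nm]] <- pl[[nm]] - spec$lr * mh / (sqrt(vh) + eps)
    }
  } else {
    for (nm in names(pl)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      state$vel[[nm]] <- spec$momentum * state$vel[[nm]] - spec$lr * g
      pl[[nm]] <- pl[[nm]] + state$vel[[nm]]
    }
  }
  list(state = state, params = pl)
}
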