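# Shared fixtures built in code. The trained acceptance models are cached in
# a session-level environment because several tests interrogate the same fit.

.fixture_cache <- new.env(parent = emptyenv())

tiny_cfgs <- function(...) {
  list(sequence = model_config("sequence", "tiny", ...),
       regional = model_config("regional", "tiny", ...))
}

# small dataset for fast unit tests
small_dataset <- function(n = 4, L_min = 20, L_max = 26, seed = 11) {
  key <- paste("ds", n, L_min, L_max, seed, sep = ".")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_dataset(
      synth_config(n, L_min, L_max, plm_channels = 16, signal_channels = 4,
                   signal_to_noise = 5, seed = seed))
  }
  .fixture_cache[[key]]
}

# the desk-scale study fit: tiny-preset sequence and regional modules trained
# 10 epochs on 30 synthetic proteins (L 24-48, signal-to-noise 5, fixed seed),
# with separate validation (6) and held-out test (10) sets
acceptance_fit <- function() {
  if (!is.null(.fixture_cache$fit)) return(.fixture_cache$fit)
  train_set <- make_dataset(synth_config(30, 24, 48, seed = 101))
  val_set <- make_dataset(synth_config(6, 24, 48, seed = 202))
  test_set <- make_dataset(synth_config(10, 24, 48, seed = 303))
  st_seq <- train(train_set, val_set, model_config("sequence", "tiny"),
                  seed = 7, epochs = 10)
  st_reg <- train(train_set, val_set, model_config("regional", "tiny"),
                  seed = 7, epochs = 10)
  .fixture_cache$fit <- list(
    train = train_set, val = val_set, test = test_set,
    seq = st_seq, reg = st_reg,
    ensemble = contact_ensemble(st_seq$model, st_reg$model))
  .fixture_cache$fit
}

held_out_predictions <- function(fit, model) {
  lapply(fit$test, function(it) {
    list(pred = symmetrize(predict_contacts(model, it$features)$map),
         truth = it$contacts, id = it$record$id)
  })
}

mean_top_precision <- function(targets, range = "long", divisor = 5L) {
  v <- vapply(targets, function(t) {
    top_ln_precision(t$pred, t$truth, range, divisor)
  }, numeric(1))
  mean(v, na.rm = TRUE)
}

# long-range contact density of the truth = precision of a random ranking
contact_density <- function(items, range = "long") {
  v <- vapply(items, function(it) {
    y <- it$contacts$values
    m <- range_mask(nrow(y), range) & upper.tri(y)
    if (sum(m) == 0) return(NA_real_)
    sum(y[m]) / sum(m)
  }, numeric(1))
  mean(v, na.rm = TRUE)
}

# finite-difference gradient of scalar-valued f at x (matrix), central diff
fd_grad <- function(f, x, eps = 1e-5, probes = NULL) {
  g <- array(NA_real_, dim = dim(x))
  idx <- if (is.null(probes)) seq_along(x) else probes
  for (k in idx) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
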