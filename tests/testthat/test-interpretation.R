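rand_row_stochastic <- function(L) {
  m <- matrix(rexp(L * L), L, L)
  m / rowSums(m)
}

test_that("sequence importance is conserved and matches the loop oracle", {
  set.seed(3)
  L <- 9
  # uniform weights -> every importance exactly 1
  W <- array(1 / L, dim = c(3, L, L))
  expect_equal(sequence_importance(W), rep(1, L), tolerance = 1e-12)
  for (rep in 1:10) {
    H <- sample(1:4, 1)
    W <- array(0, dim = c(H, L, L))
    for (h in seq_len(H)) W[h, , ] <- rand_row_stochastic(L)
    imp <- sequence_importance(W)
    expect_equal(imp, naive_seq_importance(W), tolerance = 1e-12)
    expect_equal(sum(imp), L, tolerance = 1e-9)  # row-normalization conservation
  }
  ph <- per_head_importance(W)
  expect_equal(dim(ph), c(dim(W)[1], L))
  expect_equal(colMeans(ph), sequence_importance(W), tolerance = 1e-12)
})

test_that("received regional attention conserves mass and matches a quadruple loop", {
  set.seed(5)
  L <- 6; n <- 3; H <- 2
  mk_weights <- function(uniform = FALSE) {
    idx <- contattn:::conv_idx2d(L, n)
    inb <- matrix(idx <= L * L, L * L, n * n)
    W <- array(0, dim = c(L, L, H, n * n))
    for (h in seq_len(H)) {
      wm <- matrix(0, L * L, n * n)
      for (p in seq_len(L * L)) {
        k <- sum(inb[p, ])
        raw <- if (uniform) rep(1, k) else rexp(k)
        wm[p, inb[p, ]] <- raw / sum(raw)
      }
      W[, , h, ] <- array(wm, dim = c(L, L, n * n))
    }
    W
  }
  # uniform weights: interior cells receive exactly 1, borders less
  Wu <- mk_weights(uniform = TRUE)
  Mu <- regional_score_map(Wu)
  expect_equal(Mu[3, 3], 1, tolerance = 1e-12)
  expect_lt(Mu[1, 1], 1)
  expect_equal(sum(Mu), L * L, tolerance = 1e-9)  # conservation
  # random weights vs the explicit accumulation loop
  W <- mk_weights()
  M <- regional_score_map(W)
  expect_equal(M, naive_received_attention(W, n), tolerance = 1e-12)
  expect_equal(sum(M), L * L, tolerance = 1e-9)
})

test_that("regional importance folds row and column sums to a unit-sum profile", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE)
  imp <- regional_importance(m)
  rs <- rowSums(m) / sum(m); cs <- colSums(m) / sum(m)
  expect_equal(imp, (rs + cs) / 2, tolerance = 1e-12)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  # symmetric map -> importance proportional to row sums alone
  s <- m + t(m)
  expect_equal(regional_importance(s), rowSums(s) / sum(s), tolerance = 1e-12)
})

test_that("center selection respects groups, extremes, and the sort oracle", {
  set.seed(8)
  L <- 40
  truth <- contacts_from_coords(sample_chain(L, seed = 12))
  noisy <- truth$values + matrix(rnorm(L * L, sd = 0.4), L, L)
  noisy <- (noisy + t(noisy)) / 2
  pred <- contact_map((noisy - min(noisy)) / diff(range(noisy)), "probability")
  score <- matrix(runif(L * L), L, L)
  k <- n_true_positives(pred, truth)
  expect_gte(k, 1)
  expect_lte(k, max(1, L %/% 5))
  hi <- select_centers(score, pred, truth, k, "highest", "TP")
  lo <- select_centers(score, pred, truth, k, "lowest", "TP")
  # full-sort oracle within the TP group
  cl <- contattn:::classify_pairs(pred, truth)
  tp_pairs <- cl$pairs[cl$label == "TP", , drop = FALSE]
  o <- order(-score[tp_pairs])
  expect_equal(score[hi], score[tp_pairs[o[seq_len(nrow(hi))], , drop = FALSE]])
  # highest and lowest are disjoint when the group is large enough
  if (2 * k <= nrow(tp_pairs)) {
    expect_equal(nrow(merge(as.data.frame(hi), as.data.frame(lo))), 0)
  }
  tn <- select_centers(score, pred, truth, k, "highest", "TN")
  expect_true(all(truth$values[tn] == 0))
})

test_that("permuting a constant-channel window changes nothing", {
  items <- small_dataset(n = 2, L_min = 28, L_max = 32, seed = 77)
  it <- items[[1]]
  fs <- it$features
  # make every channel vector constant inside the window around (10, 20)
  for (di in 9:11) for (dj in 19:21) {
    fs$plm[di, dj, ] <- fs$plm[di, dj, 1]
    fs$plm[dj, di, ] <- fs$plm[dj, di, 1]
  }
  mdl <- contact_model(model_config("regional", "tiny"), seed = 4)
  ab <- permutation_ablation(mdl, fs, it$contacts,
                             centers = cbind(10L, 20L), m = 3L, seed = 9)
  expect_equal(ab$delta_precision, 0)
  expect_equal(ab$delta_tp, 0)
  # empty center list -> empty table
  ab0 <- permutation_ablation(mdl, fs, it$contacts,
                              centers = matrix(integer(0), 0, 2), m = 3L)
  expect_equal(nrow(ab0), 0)
  expect_error(permutation_ablation(mdl, fs, it$contacts,
                                    centers = cbind(5L, 9L), m = 2L))
})

test_that("ablation supports the published window sizes 1, 3 and 5", {
  items <- small_dataset(n = 2, L_min = 28, L_max = 32, seed = 77)
  it <- items[[2]]
  mdl <- contact_model(model_config("regional", "tiny"), seed = 4)
  for (m in c(1L, 3L, 5L)) {
    ab <- permutation_ablation(mdl, it$features, it$contacts,
                               centers = cbind(8L, 22L), m = m, seed = 2)
    expect_equal(nrow(ab), 1)
    expect_true(is.finite(ab$delta_precision))
  }
})

test_that("phi comparison recovers perfect correlation and exact rank-sum floors", {
  set.seed(11)
  L <- 30
  phi_vals <- pmax(0, sin(seq_len(L) / 4)) + runif(L, 0, 0.05)
  phi <- phi_profile(phi_vals, peak_halfwidth = 3)
  expect_equal(phi_compare(phi_vals, phi)$pearson_r, 1.0, tolerance = 1e-12)
  # peak strictly above all outside values -> minimal exact one-sided p
  imp <- runif(L, 0, 0.4)
  imp[phi$peak] <- 1 + runif(length(phi$peak))
  got <- phi_compare(imp, phi)
  n1 <- length(phi$peak); n2 <- L - n1
  expect_equal(got$wilcoxon_p, 1 / choose(n1 + n2, n1), tolerance = 1e-9)
})

test_that("phi comparison p-values are calibrated under an independent null", {
  set.seed(13)
  L <- 40
  phi <- phi_profile(c(rep(0.1, 15), 0.9, 1.0, 0.9, rep(0.1, L - 18)),
                     peak_halfwidth = 2)
  ps <- vapply(1:400, function(k) {
    phi_compare(sample(runif(L)), phi)$wilcoxon_p
  }, numeric(1))
  # uniform p under the null: check coverage at two nominal levels
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.05)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.08)
})

test_that("phi files read into masked profiles", {
  fp <- tempfile(fileext = ".txt")
  writeLines(c("1 0.2", "2 0.8", "4 0.1"), fp)
  phi <- read_phi(fp, L = 5)
  expect_equal(phi$values, c(0.2, 0.8, NA, 0.1, NA))
  expect_equal(phi$mask, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_true(2 %in% phi$peak)
})
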