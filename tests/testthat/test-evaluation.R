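test_that("top-L/n precision counts, boundaries and degenerate cases are exact", {
  L <- 10
  truth_v <- matrix(0, L, L)
  # two medium-range contacts (sep 12 impossible at L=10; use short range)
  truth_v[1, 8] <- truth_v[8, 1] <- 1
  truth <- contact_map(truth_v, "binary")
  # L = 10, n = 5 -> exactly 2 pairs selected; construct 1 of top 2 correct
  pred_v <- matrix(0, L, L)
  pred_v[1, 8] <- 0.9   # true (sep 7, short range)
  pred_v[2, 9] <- 0.8   # false (sep 7)
  pred_v[1, 9] <- 0.7
  pred <- symmetrize(contact_map(pred_v, "probability"))
  expect_equal(top_ln_precision(pred, truth, "short", 5), 0.5)
  # all selected correct -> 1.0
  pred_v2 <- truth_v * 0.9
  expect_equal(top_ln_precision(symmetrize(contact_map(pred_v2, "probability")),
                                truth, "short", 10), 1.0)
  # no candidate pairs in range -> NA
  expect_true(is.na(top_ln_precision(pred, truth, "long", 5)))
})

test_that("a pair at separation 23 never counts as long-range", {
  L <- 30
  truth_v <- matrix(0, L, L)
  truth_v[1, 24] <- truth_v[24, 1] <- 1   # sep 23: medium
  truth_v[1, 25] <- truth_v[25, 1] <- 1   # sep 24: long
  truth <- contact_map(truth_v, "binary")
  pred_v <- matrix(0, L, L)
  pred_v[1, 24] <- 0.99
  pred_v[1, 25] <- 0.98
  pred <- symmetrize(contact_map(pred_v, "probability"))
  # top-1 long-range selection must pick (1,25), not the higher-scored (1,24)
  expect_equal(top_ln_precision(pred, truth, "long", 30), 1.0)
  expect_equal(top_ln_precision(pred, truth, "medium", 30), 1.0)
})

test_that("evaluating the true map against itself gives precision 1 at every depth and range", {
  items <- small_dataset(n = 2, L_min = 40, L_max = 44, seed = 55)
  for (it in items) {
    self <- contact_map(it$contacts$values * 1, "probability")
    tab <- evaluate_contacts(list(list(pred = self, truth = it$contacts)))
    ok <- !is.na(tab$precision)
    expect_true(all(tab$precision[ok] == 1))
    expect_true(any(ok))
  }
})

test_that("precision is non-increasing in selection depth on synthetic ensembles", {
  items <- small_dataset(n = 6, L_min = 36, L_max = 44, seed = 66)
  p5 <- c(); p1 <- c()
  for (it in items) {
    noisy <- it$contacts$values + matrix(rnorm(it$record$L^2, sd = 0.6),
                                         it$record$L)
    noisy <- (noisy + t(noisy)) / 2
    noisy <- (noisy - min(noisy)) / diff(range(noisy))
    pred <- contact_map(noisy, "probability")
    p5 <- c(p5, top_ln_precision(pred, it$contacts, "long", 5))
    p1 <- c(p1, top_ln_precision(pred, it$contacts, "long", 1))
  }
  expect_gte(mean(p5, na.rm = TRUE), mean(p1, na.rm = TRUE))
})

test_that("ROC/PR curves match the exhaustive threshold oracle on small instances", {
  set.seed(77)
  for (rep in 1:20) {
    L <- 52
    n_pairs <- sample(4:12, 1)
    pairs <- candidate <- which(range_mask(L, "long") & upper.tri(diag(L)),
                                arr.ind = TRUE)
    pick <- pairs[sample(nrow(pairs), n_pairs), , drop = FALSE]
    y <- matrix(0, L, L); v <- matrix(0, L, L)
    labs <- rbinom(n_pairs, 1, 0.5)
    if (all(labs == 1)) labs[1] <- 0
    if (all(labs == 0)) labs[1] <- 1
    scores <- round(runif(n_pairs), 2)  # rounded to force ties sometimes
    y[pick] <- labs; y[pick[, c(2, 1)]] <- labs
    v[pick] <- scores; v[pick[, c(2, 1)]] <- scores
    subset <- matrix(FALSE, L, L)
    subset[pick] <- TRUE
    got <- roc_pr(list(list(pred = contact_map(v, "probability"),
                            truth = contact_map(y, "binary"))),
                  subset = list(subset))
    want <- exhaustive_roc_pr(scores, labs)
    expect_equal(got$auc_roc, want$auc_roc, tolerance = 1e-9)
    expect_equal(got$auc_pr, want$auc_pr, tolerance = 1e-9)
  }
})

test_that("ROC area is 1 under perfect separation and near 0.5 for random scores", {
  L <- 60
  truth <- contacts_from_coords(sample_chain(L, seed = 5))
  perfect <- contact_map(truth$values * 0.9 + 0.05, "probability")
  got <- roc_pr(list(list(pred = perfect, truth = truth)))
  expect_equal(got$auc_roc, 1.0, tolerance = 1e-9)
  # random scores on ~1e4 pooled pairs
  set.seed(12)
  targets <- lapply(1:20, function(k) {
    tr <- contacts_from_coords(sample_chain(L, seed = 100 + k))
    v <- matrix(runif(L * L), L, L)
    list(pred = contact_map((v + t(v)) / 2, "probability"), truth = tr)
  })
  got <- roc_pr(targets)
  expect_gt(got$n_pairs, 1e4)
  expect_lt(abs(got$auc_roc - 0.5), 0.05)
})

test_that("our ROC area agrees with an established implementation", {
  skip_if_not_installed("pROC")
  L <- 60
  set.seed(31)
  truth <- contacts_from_coords(sample_chain(L, seed = 9))
  sig <- truth$values + matrix(rnorm(L * L, sd = 0.8), L, L)
  sig <- (sig + t(sig)) / 2
  sig <- (sig - min(sig)) / diff(range(sig))
  pred <- contact_map(sig, "probability")
  got <- roc_pr(list(list(pred = pred, truth = truth)))
  m <- range_mask(L, "long") & upper.tri(diag(L))
  ref <- pROC::auc(pROC::roc(truth$values[m], pred$values[m], quiet = TRUE))
  expect_equal(got$auc_roc, as.numeric(ref), tolerance = 1e-9)
})

test_that("roc_pr rejects single-class pooled labels", {
  L <- 40
  v <- matrix(runif(L * L), L, L)
  y <- matrix(0, L, L)
  expect_error(roc_pr(list(list(pred = contact_map((v + t(v)) / 2, "probability"),
                                truth = contact_map(y, "binary")))),
               "single class")
})

test_that("the union-of-top-L/5 subset has its set-algebra properties", {
  L <- 50
  set.seed(41)
  mk <- function() {
    v <- matrix(runif(L * L), L, L)
    contact_map((v + t(v)) / 2, "probability")
  }
  a <- mk(); b <- mk(); c2 <- mk()
  u <- union_top_subset(list(a, b, c2))
  k <- L %/% 5
  pairs <- which(range_mask(L, "long") & upper.tri(diag(L)), arr.ind = TRUE)
  # contains each model's own top-k
  for (m in list(a, b, c2)) {
    sc <- m$values[pairs]
    top <- pairs[order(-sc, pairs[, 1], pairs[, 2])[1:k], , drop = FALSE]
    expect_true(all(u[top]))
  }
  expect_gte(sum(u[upper.tri(u)]), k)
  expect_lte(sum(u[upper.tri(u)]), 3 * k)
  # identical maps -> union equals the single top set
  u1 <- union_top_subset(list(a, a, a))
  expect_equal(sum(u1[upper.tri(u1)]), k)
})
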