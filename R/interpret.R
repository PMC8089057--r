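# Attention-based interpretability: residue importance from the sequence
# attention (column sums of head-averaged weights), received-attention maps
# and L x 1 importance from the regional attention, permutation ablation
# around high/low-attention locations, and comparison against experimental
# phi-values.

#' Residue importance from sequence attention
#'
#' Head matrices are averaged (each row of each head sums to 1), then the
#' column sum gives the overall importance of each residue: entry (i, j) of
#' the attention matrix is the importance of residue j to residue i, so
#' importances sum to L.
#'
#' @param W sequence attention weights: `n_heads x L x L` array, an
#'   [attention_record()], or the `W` element of [multihead_attention_1d()].
#' @return numeric length-L importance vector.
#' @export
sequence_importance <- function(W) {
  W <- as_seq_weights(W)
  avg <- apply(W, c(2, 3), mean)
  colSums(avg)
}

as_seq_weights <- function(W) {
  if (inherits(W, "attention_record")) W <- W$seq_W
  if (is.null(W)) stop("no sequence attention weights available")
  stopifnot(length(dim(W)) == 3L)
  W
}

#' Per-head residue importance profiles
#'
#' @inheritParams sequence_importance
#' @return `n_heads x L` matrix of per-head column sums.
#' @export
per_head_importance <- function(W) {
  W <- as_seq_weights(W)
  t(apply(W, 1, colSums))
}

#' Received-attention map from regional attention
#'
#' Folds the `(L, L, n_heads, n^2)` window-stochastic weight tensor back
#' onto the pair map: entry (p, q) accumulates, over every center whose
#' window covers (p, q) and averaged over heads, the weight that center
#' assigns to the cell. Total received mass equals L^2 (each center
#' distributes one unit).
#'
#' @param W regional attention weights (`(L, L, n_heads, n^2)` array or an
#'   [attention_record()]).
#' @param n window size; inferred from the tensor when omitted.
#' @return `L x L` received-attention score matrix.
#' @export
regional_score_map <- function(W, n = NULL) {
  if (inherits(W, "attention_record")) W <- W$reg_W
  if (is.null(W)) stop("no regional attention weights available")
  d <- dim(W)
  L <- d[1]; n2 <- d[4]
  if (is.null(n)) n <- as.integer(round(sqrt(n2)))
  stopifnot(n * n == n2)
  idx <- conv_idx2d(L, n)
  P <- L * L
  wm <- apply(W, c(1, 2, 4), mean)      # head-averaged, (L, L, n2)
  wmat <- matrix(wm, P, n2)
  acc <- numeric(P + 1L)                 # last slot absorbs out-of-bounds
  for (w in seq_len(n2)) {
    agg <- rowsum(wmat[, w], group = idx[, w])
    acc[as.integer(rownames(agg))] <- acc[as.integer(rownames(agg))] + agg[, 1]
  }
  matrix(acc[seq_len(P)], L, L)
}

#' Fold a received-attention map to per-residue importance
#'
#' Row sums and column sums are each normalized to sum 1, added, and the
#' result rescaled to sum 1.
#'
#' @param score_map `L x L` matrix from [regional_score_map()].
#' @return numeric length-L importance vector summing to 1.
#' @export
regional_importance <- function(score_map) {
  rs <- rowSums(score_map); cs <- colSums(score_map)
  imp <- rs / sum(rs) + cs / sum(cs)
  imp / sum(imp)
}

# classify long-range upper-triangle cells at top-L/5 depth
classify_pairs <- function(pred, truth, divisor = 5L, range = "long") {
  p <- map_values(symmetrize(pred))
  y <- map_values(truth)
  L <- nrow(p)
  valid <- if (inherits(truth, "contact_map")) truth$valid else NULL
  pairs <- candidate_pairs(L, range, valid)
  sc <- p[pairs]
  ord <- rank_pairs(sc, pairs)
  ord <- ord[sc[ord] > 0]  # unlisted (zero-probability) pairs never selected
  k <- min(max(1L, L %/% divisor), length(ord))
  sel <- logical(nrow(pairs)); sel[ord[seq_len(k)]] <- TRUE
  lab <- ifelse(sel & y[pairs] == 1, "TP",
         ifelse(sel & y[pairs] == 0, "FP",
         ifelse(!sel & y[pairs] == 1, "FN", "TN")))
  list(pairs = pairs, label = lab, selected = sel)
}

#' Select permutation-ablation centers
#'
#' Within the requested prediction group at top-L/5 depth (true positives,
#' true negatives, ...), picks the k cells with the highest or lowest
#' attention score; ties broken by (i, j) ascending. By the published
#' protocol k is the target's true-positive count at that depth.
#'
#' @param score_map `L x L` attention score matrix
#'   (see [regional_score_map()]).
#' @param pred probability map; @param truth binary map.
#' @param k number of centers (>= 1).
#' @param which `"highest"` or `"lowest"` attention scores.
#' @param group prediction group: `"TP"`, `"FP"`, `"FN"` or `"TN"`.
#' @param divisor ranking depth divisor (default 5).
#' @return integer matrix with columns `i`, `j` (i < j), at most k rows.
#' @export
select_centers <- function(score_map, pred, truth, k,
                           which = c("highest", "lowest"),
                           group = "TP", divisor = 5L) {
  which <- match.arg(which)
  stopifnot(k >= 1L)
  cl <- classify_pairs(pred, truth, divisor)
  cand <- cl$pairs[cl$label == group, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  sc <- score_map[cand]
  o <- if (which == "highest") order(-sc, cand[, 1], cand[, 2]) else
    order(sc, cand[, 1], cand[, 2])
  cand[o[seq_len(min(k, nrow(cand)))], , drop = FALSE]
}

#' Count of top-L/5 true positives (the published choice of k)
#'
#' @inheritParams classify_pairs
#' @return integer.
#' @export
n_true_positives <- function(pred, truth, divisor = 5L) {
  cl <- classify_pairs(pred, truth, divisor)
  sum(cl$label == "TP")
}

# shuffle the channel vector of each PLM cell in an m x m window centred at
# (i, j), mirrored at (j, i) to preserve the tensor's pair symmetry
permute_window <- function(plm, i, j, m) {
  L <- dim(plm)[1]
  h <- (m - 1L) %/% 2L
  for (di in max(1L, i - h):min(L, i + h)) {
    for (dj in max(1L, j - h):min(L, j + h)) {
      perm <- sample(dim(plm)[3])
      plm[di, dj, ] <- plm[di, dj, perm]
      plm[dj, di, ] <- plm[dj, di, perm]
    }
  }
  plm
}

#' Permutation ablation around attention centers
#'
#' For each center, the channel-axis values of every coupling-tensor cell in
#' the `m x m` window around it are shuffled (seeded), the prediction is
#' re-run, and the change in top-L/5 precision and true-positive count
#' relative to the unperturbed prediction is recorded. A window whose
#' channel vectors are constant is unchanged by the shuffle, giving zero
#' delta; an empty center list returns an empty table.
#'
#' @param model a [contact_model()] or [contact_ensemble()].
#' @param fs the protein's [feature_set()].
#' @param truth binary [contact_map()].
#' @param centers integer matrix of (i, j) centers from [select_centers()].
#' @param m odd region size (1, 3 or 5).
#' @param seed integer seed for the shuffles.
#' @param divisor ranking depth divisor (default 5).
#' @return tibble with one row per center: `i`, `j`, `delta_precision`,
#'   `delta_tp`.
#' @export
permutation_ablation <- function(model, fs, truth, centers, m = 3L, seed = 1L,
                                 divisor = 5L) {
  stopifnot(m %% 2L == 1L)
  base_pred <- predict_contacts(model, fs)$map
  prec0 <- top_ln_precision(symmetrize(base_pred), truth, "long", divisor)
  tp0 <- n_true_positives(base_pred, truth, divisor)
  n <- nrow(centers)
  dp <- numeric(n); dt <- numeric(n)
  for (ci in seq_len(n)) {
    i <- centers[ci, 1]; j <- centers[ci, 2]
    plm2 <- with_local_seed(subseed(seed, ci, salt = 31L),
                            permute_window(fs$plm, i, j, m))
    fs2 <- feature_set(fs$pssm, plm2, contacts = fs$contacts,
                       record = fs$record)
    pred2 <- predict_contacts(model, fs2)$map
    dp[ci] <- top_ln_precision(symmetrize(pred2), truth, "long", divisor) - prec0
    dt[ci] <- n_true_positives(pred2, truth, divisor) - tp0
  }
  tibble::tibble(i = centers[, 1], j = centers[, 2],
                 delta_precision = dp, delta_tp = dt)
}

# ---- phi-value comparison ---------------------------------------------------

#' Per-residue phi-value profile
#'
#' Experimental folding phi-values with a missing-value mask and the
#' contiguous peak region around the maximum (half-width `peak_halfwidth`,
#' clipped to the sequence).
#'
#' @param values numeric length-L vector (NA = missing).
#' @param peak_halfwidth half-width of the peak region (default 3).
#' @return object of class `phi_profile` with fields `values`, `mask`,
#'   `peak` (integer index range).
#' @export
phi_profile <- function(values, peak_halfwidth = 3L) {
  mask <- !is.na(values)
  if (!any(mask)) stop("phi_profile: all values missing")
  pk <- which.max(ifelse(mask, values, -Inf))
  lo <- max(1L, pk - peak_halfwidth)
  hi <- min(length(values), pk + peak_halfwidth)
  structure(list(values = values, mask = mask, peak = lo:hi),
            class = "phi_profile")
}

#' Read a two-column phi-value text file
#'
#' Plain text, one row per residue with a value: `index value`.
#'
#' @param path file path.
#' @param L protein length (defaults to the maximum index present).
#' @param peak_halfwidth passed to [phi_profile()].
#' @return a [phi_profile()]; residues absent from the file are masked.
#' @export
read_phi <- function(path, L = NULL, peak_halfwidth = 3L) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("index", "value"))
  if (is.null(L)) L <- max(d$index)
  v <- rep(NA_real_, L)
  v[d$index] <- d$value
  phi_profile(v, peak_halfwidth)
}

#' Compare an importance profile with phi-values
#'
#' One-sided Wilcoxon rank-sum test of the importances inside the phi peak
#' region against those outside (masked residues excluded), plus the
#' Pearson correlation between importance and phi over unmasked residues.
#'
#' @param importance numeric length-L importance vector (e.g. from
#'   [sequence_importance()] or [regional_importance()]).
#' @param phi a [phi_profile()].
#' @return list with `wilcoxon_p` (one-sided, peak > rest) and `pearson_r`.
#' @export
phi_compare <- function(importance, phi) {
  stopifnot(inherits(phi, "phi_profile"),
            length(importance) == length(phi$values))
  inside <- intersect(phi$peak, which(phi$mask))
  outside <- setdiff(which(phi$mask), phi$peak)
  if (length(inside) < 1L || length(outside) < 3L) {
    stop("phi_compare: need phi values on both sides of the peak region")
  }
  xi <- importance[inside]; xo <- importance[outside]
  # exact rank-sum p only when it is defined (no ties across groups)
  wt <- stats::wilcox.test(xi, xo, alternative = "greater",
                           exact = anyDuplicated(c(xi, xo)) == 0)
  r <- stats::cor(importance[phi$mask], phi$values[phi$mask])
  list(wilcoxon_p = wt$p.value, pearson_r = r)
}
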