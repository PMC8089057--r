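# CASP-style scoring: top-L/n precision by sequence-separation range,
# pooled ROC / precision-recall curves, and the union-of-top-L/5 subset
# restriction.

# upper-triangle candidate pairs for a range, honouring the validity mask
candidate_pairs <- function(L, range, valid = NULL) {
  m <- range_mask(L, range) & upper.tri(matrix(0, L, L))
  if (!is.null(valid)) m <- m & valid
  which(m, arr.ind = TRUE)
}

rank_pairs <- function(scores, pairs) {
  order(-scores, pairs[, 1], pairs[, 2])
}

#' Top-L/n precision of predicted contacts
#'
#' Ranks unordered residue pairs (i < j) within the separation range by
#' descending score (ties broken by (i, j) ascending), selects the top
#' `floor(L / divisor)` (at least 1, at most the number of candidate pairs),
#' and returns the fraction that are true contacts. Pairs with probability
#' exactly 0 count as unlisted (the RR-format convention) and are never
#' selected; dense sigmoid outputs are unaffected.
#'
#' @param pred probability [contact_map()] or matrix (symmetrize first;
#'   see [symmetrize()]).
#' @param truth binary [contact_map()] or matrix.
#' @param range `"long"` (separation >= 24), `"medium"` (12-23) or
#'   `"short"` (6-11).
#' @param divisor n in top-L/n (1, 2 or 5).
#' @param valid optional logical validity matrix; defaults to the truth
#'   map's own mask when present.
#' @return precision in \[0, 1\], or `NA_real_` when the range holds no
#'   candidate pairs (short protein); such targets are excluded from
#'   dataset means.
#' @export
top_ln_precision <- function(pred, truth, range = "long", divisor = 5L,
                             valid = NULL) {
  stopifnot(divisor >= 1L)
  p <- map_values(pred)
  y <- map_values(truth)
  stopifnot(identical(dim(p), dim(y)))
  L <- nrow(p)
  if (is.null(valid) && inherits(truth, "contact_map")) valid <- truth$valid
  pairs <- candidate_pairs(L, range, valid)
  if (nrow(pairs) == 0L) return(NA_real_)
  sc <- p[pairs]
  # zero-probability pairs are unlisted predictions in the RR sense and are
  # never selected; for dense sigmoid outputs (all > 0) this has no effect
  pos <- sc > 0
  if (!any(pos)) return(NA_real_)
  pairs <- pairs[pos, , drop = FALSE]
  sc <- sc[pos]
  ord <- rank_pairs(sc, pairs)
  k <- min(max(1L, L %/% divisor), nrow(pairs))
  sel <- pairs[ord[seq_len(k)], , drop = FALSE]
  sum(y[sel]) / k
}

#' Evaluate predictions over a dataset
#'
#' Per-target top-L/n precision for every separation range and divisor,
#' mirroring the standard contact-assessment table layout.
#'
#' @param targets list of items, each with `pred` (probability map), `truth`
#'   (binary map) and optionally `id`.
#' @param ranges separation ranges to score.
#' @param divisors top-list divisors (default 5, 2, 1).
#' @return tibble with columns `id`, `range`, `divisor`, `precision`
#'   (`NA` where a target has no candidate pairs in a range).
#' @export
evaluate_contacts <- function(targets, ranges = c("short", "medium", "long"),
                              divisors = c(5L, 2L, 1L)) {
  rows <- list()
  for (t in seq_along(targets)) {
    it <- targets[[t]]
    id <- it$id %||% sprintf("target%03d", t)
    pred <- symmetrize(it$pred)
    for (rg in ranges) for (dv in divisors) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, range = rg, divisor = dv,
        precision = top_ln_precision(pred, it$truth, rg, dv))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_result", class(out))
  out
}

#' Dataset-mean precision table
#'
#' Unweighted average of per-target precisions; targets without candidate
#' pairs in a range are excluded from that range's mean rather than scored 0.
#'
#' @param x an `eval_result` tibble from [evaluate_contacts()].
#' @return tibble with `range`, `divisor`, `mean_precision`, `n_targets`.
#' @export
summarize_precision <- function(x) {
  key <- interaction(x$range, x$divisor, drop = TRUE)
  parts <- split(x, key)
  out <- lapply(parts, function(d) tibble::tibble(
    range = d$range[1], divisor = d$divisor[1],
    mean_precision = mean(d$precision, na.rm = TRUE),
    n_targets = sum(!is.na(d$precision))))
  out <- do.call(rbind, out)
  out[order(match(out$range, c("short", "medium", "long")), out$divisor,
            decreasing = c(FALSE, TRUE), method = "radix"), ]
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Pooled ROC and precision-recall curves
#'
#' Pools the scored pairs of all targets within the separation range
#' (optionally restricted per target by `subset` masks, e.g. from
#' [union_top_subset()]), sweeps every distinct score as a threshold, and
#' integrates the step curves by the trapezoidal rule.
#'
#' @param targets list of items with `pred` and `truth` (as in
#'   [evaluate_contacts()]).
#' @param range separation range (default `"long"`).
#' @param subset optional list of logical `L x L` matrices, one per target,
#'   restricting which pairs are pooled.
#' @return list with `roc` (tibble `fpr`, `tpr`), `pr` (tibble `recall`,
#'   `precision`), `auc_roc`, `auc_pr`, `n_pairs`.
#' @export
roc_pr <- function(targets, range = "long", subset = NULL) {
  scores <- numeric(0); labels <- numeric(0)
  for (t in seq_along(targets)) {
    it <- targets[[t]]
    p <- map_values(symmetrize(it$pred))
    y <- map_values(it$truth)
    L <- nrow(p)
    valid <- if (inherits(it$truth, "contact_map")) it$truth$valid else NULL
    pairs <- candidate_pairs(L, range, valid)
    if (!is.null(subset)) {
      keep <- subset[[t]][pairs]
      pairs <- pairs[keep, , drop = FALSE]
    }
    if (nrow(pairs) == 0L) next
    scores <- c(scores, p[pairs])
    labels <- c(labels, y[pairs])
  }
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    stop("roc_pr: pooled labels contain a single class (", P, " positives, ",
         N, " negatives)")
  }
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  at <- which(c(diff(s) != 0, TRUE))  # last index of each distinct score
  tpr <- c(0, tp[at] / P); fpr <- c(0, fp[at] / N)
  prec <- tp[at] / (tp[at] + fp[at])
  rec <- tp[at] / P
  prec <- c(prec[1], prec); rec <- c(0, rec)
  list(roc = tibble::tibble(fpr = fpr, tpr = tpr),
       pr = tibble::tibble(recall = rec, precision = prec),
       auc_roc = trapezoid(fpr, tpr), auc_pr = trapezoid(rec, prec),
       n_pairs = length(s))
}

#' Union of per-model top-L/5 pairs
#'
#' The set of residue pairs ranked in the top `floor(L / n)` of the given
#' separation range by any of the supplied prediction maps; used to restrict
#' [roc_pr()] to the high-confidence subset.
#'
#' @param pred_maps list of probability maps sharing the same L.
#' @param n top-list divisor (default 5).
#' @param range separation range (default `"long"`).
#' @return symmetric logical `L x L` matrix marking the union pairs.
#' @export
union_top_subset <- function(pred_maps, n = 5L, range = "long") {
  L <- nrow(map_values(pred_maps[[1]]))
  out <- matrix(FALSE, L, L)
  pairs <- candidate_pairs(L, range)
  k <- min(max(1L, L %/% n), nrow(pairs))
  for (m in pred_maps) {
    v <- map_values(symmetrize(m))
    stopifnot(nrow(v) == L)
    ord <- rank_pairs(v[pairs], pairs)
    sel <- pairs[ord[seq_len(k)], , drop = FALSE]
    out[sel] <- TRUE
    out[sel[, c(2, 1), drop = FALSE]] <- TRUE
  }
  out
}
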