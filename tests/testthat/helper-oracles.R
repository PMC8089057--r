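# Independent naive reference implementations ("oracles"): explicit loops
# and per-position arithmetic, deliberately written without reusing any of
# the package's vectorized code paths.

row_softmax <- function(z) {
  t(apply(z, 1, function(r) {
    ok <- is.finite(r)
    e <- rep(0, length(r))
    e[ok] <- exp(r[ok] - max(r[ok]))
    e / sum(e)
  }))
}

naive_att1d <- function(X, params) {
  L <- nrow(X)
  H <- params$n_heads; da <- params$d_att
  Xp <- X %*% params$Win + matrix(params$bin, L, H * da, byrow = TRUE)
  Z <- NULL
  W <- array(0, dim = c(H, L, L))
  for (h in seq_len(H)) {
    Xh <- Xp[, ((h - 1) * da + 1):(h * da), drop = FALSE]
    Q <- Xh %*% params$heads[[h]]$Wq
    K <- Xh %*% params$heads[[h]]$Wk
    V <- Xh %*% params$heads[[h]]$Wv
    A <- matrix(0, L, L)
    for (i in seq_len(L)) {
      s <- numeric(L)
      for (j in seq_len(L)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(da)
      e <- exp(s - max(s))
      A[i, ] <- e / sum(e)
    }
    W[h, , ] <- A
    Zh <- matrix(0, L, da)
    for (i in seq_len(L)) for (j in seq_len(L)) Zh[i, ] <- Zh[i, ] + A[i, j] * V[j, ]
    Z <- cbind(Z, Zh)
  }
  list(Z = Z, W = W)
}

naive_tile <- function(Z) {
  L <- nrow(Z); d <- ncol(Z)
  out <- array(0, dim = c(L, L, 2 * d))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    out[i, j, 1:d] <- Z[i, ]
    out[i, j, (d + 1):(2 * d)] <- Z[j, ]
  }
  out
}

# row-major window offsets for odd n
window_offsets <- function(n) {
  h <- (n - 1) / 2
  off <- NULL
  for (dr in -h:h) for (dc in -h:h) off <- rbind(off, c(dr, dc))
  off
}

naive_region_stretch <- function(F, n) {
  d <- dim(F); L <- d[1]; cc <- d[3]
  off <- window_offsets(n)
  out <- array(0, dim = c(L, L, cc, n * n))
  mask <- array(FALSE, dim = c(L, L, n * n))
  for (i in seq_len(L)) for (j in seq_len(L)) for (w in seq_len(n * n)) {
    ii <- i + off[w, 1]; jj <- j + off[w, 2]
    if (ii >= 1 && ii <= L && jj >= 1 && jj <= L) {
      out[i, j, , w] <- F[ii, jj, ]
      mask[i, j, w] <- TRUE
    }
  }
  list(out = out, mask = mask)
}

naive_regional_attention <- function(F, params) {
  d <- dim(F); L <- d[1]; cc <- d[3]
  n <- params$n; H <- params$n_heads; da <- params$d_att
  off <- window_offsets(n)
  heads_out <- array(0, dim = c(L, L, H * da))
  W <- array(0, dim = c(L, L, H, n * n))
  for (h in seq_len(H)) {
    ph <- params$heads[[h]]
    for (i in seq_len(L)) for (j in seq_len(L)) {
      q <- as.vector(F[i, j, ] %*% ph$Wq)
      lg <- rep(-Inf, n * n)
      vals <- matrix(0, n * n, da)
      for (w in seq_len(n * n)) {
        ii <- i + off[w, 1]; jj <- j + off[w, 2]
        if (ii >= 1 && ii <= L && jj >= 1 && jj <= L) {
          kv <- as.vector(F[ii, jj, ] %*% ph$Wk)
          vals[w, ] <- F[ii, jj, ] %*% ph$Wv
          lg[w] <- sum(q * kv) / sqrt(da)
        }
      }
      ok <- is.finite(lg)
      a <- rep(0, n * n)
      a[ok] <- exp(lg[ok] - max(lg[ok]))
      a <- a / sum(a)
      W[i, j, h, ] <- a
      heads_out[i, j, ((h - 1) * da + 1):(h * da)] <-
        colSums(vals * a)
    }
  }
  out <- array(0, dim = c(L, L, params$c_out))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    out[i, j, ] <- heads_out[i, j, ] %*% params$Wo + params$bo
  }
  out
}

naive_maxout <- function(F) {
  d <- dim(F); cc <- d[length(d)]
  m <- cc / 2
  M <- matrix(F, prod(d) / cc, cc)
  out <- matrix(0, nrow(M), m)
  for (r in seq_len(nrow(M))) for (k in seq_len(m)) {
    out[r, k] <- max(M[r, 2 * k - 1], M[r, 2 * k])
  }
  array(out, dim = c(d[-length(d)], m))
}

naive_se <- function(F, params) {
  d <- dim(F); cc <- d[3]
  s <- numeric(cc)
  for (ch in seq_len(cc)) s[ch] <- mean(F[, , ch])
  z <- pmax(as.vector(s %*% params$W1) + as.vector(params$b1), 0)
  gate <- 1 / (1 + exp(-(as.vector(z %*% params$W2) + as.vector(params$b2))))
  out <- F
  for (ch in seq_len(cc)) out[, , ch] <- F[, , ch] * gate[ch]
  out
}

naive_bce <- function(pred, truth, mask) {
  tot <- 0; nw <- 0
  L <- nrow(pred)
  eps <- 1e-7
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (mask[i, j] > 0) {
      p <- min(max(pred[i, j], eps), 1 - eps)
      tot <- tot + mask[i, j] * (-(truth[i, j] * log(p) + (1 - truth[i, j]) * log(1 - p)))
      nw <- nw + mask[i, j]
    }
  }
  tot / nw
}

# exhaustive-threshold ROC/PR for small pooled instances
exhaustive_roc_pr <- function(scores, labels) {
  P <- sum(labels == 1); N <- sum(labels == 0)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- 0; fpr <- 0; prec <- NULL; rec <- 0
  for (t in th) {
    sel <- scores >= t
    tpr <- c(tpr, sum(labels[sel] == 1) / P)
    fpr <- c(fpr, sum(labels[sel] == 0) / N)
    prec <- c(prec, sum(labels[sel] == 1) / sum(sel))
    rec <- c(rec, sum(labels[sel] == 1) / P)
  }
  prec <- c(prec[1], prec)
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(auc_roc = trap(fpr, tpr), auc_pr = trap(rec, prec),
       fpr = fpr, tpr = tpr, rec = rec, prec = prec)
}

naive_seq_importance <- function(W) {
  H <- dim(W)[1]; L <- dim(W)[2]
  avg <- matrix(0, L, L)
  for (h in seq_len(H)) avg <- avg + W[h, , ] / H
  imp <- numeric(L)
  for (j in seq_len(L)) for (i in seq_len(L)) imp[j] <- imp[j] + avg[i, j]
  imp
}

naive_received_attention <- function(W, n) {
  d <- dim(W); L <- d[1]; H <- d[3]
  off <- window_offsets(n)
  M <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) for (h in seq_len(H)) {
    for (w in seq_len(n * n)) {
      ii <- i + off[w, 1]; jj <- j + off[w, 2]
      if (ii >= 1 && ii <= L && jj >= 1 && jj <= L) {
        M[ii, jj] <- M[ii, jj] + W[i, j, h, w] / H
      }
    }
  }
  M
}
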