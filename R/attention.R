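# The attention operators at the heart of the predictor: multi-head scaled
# dot-product attention over the 1D sequence encoding, the 1D -> 2D tiling
# that lifts it onto the pair map, the fixed region-stretching gather, and
# windowed regional attention over the 2D feature map.

#' Parameters for multi-head sequence attention
#'
#' The encoder output (width `d_in`) is first linearly projected to
#' `n_heads * d_att` and split into per-head slices; each head owns three
#' trainable `d_att x d_att` matrices producing query, key and value.
#'
#' @param d_in input (encoder) width.
#' @param n_heads number of attention heads (default 4, the best published
#'   configuration).
#' @param d_att per-head attention width (default 32).
#' @param seed seed for initialization.
#' @return object of class `attention1d_params`.
#' @export
attention1d_params <- function(d_in, n_heads = 4L, d_att = 32L, seed = 1L) {
  with_local_seed(seed, {
    heads <- lapply(seq_len(n_heads), function(h) {
      list(Wq = init_w(d_att, d_att), Wk = init_w(d_att, d_att),
           Wv = init_w(d_att, d_att))
    })
    structure(list(Win = init_w(d_in, n_heads * d_att),
                   bin = matrix(0, 1L, n_heads * d_att),
                   heads = heads, n_heads = n_heads, d_att = d_att,
                   d_in = d_in),
              class = "attention1d_params")
  })
}

# flat-list adapter so the model forward and the standalone op share one path
att1d_flat <- function(params) {
  pl <- list(att1d.Win = params$Win, att1d.bin = params$bin)
  for (h in seq_len(params$n_heads)) {
    pl[[sprintf("att1d.h%d.Wq", h)]] <- params$heads[[h]]$Wq
    pl[[sprintf("att1d.h%d.Wk", h)]] <- params$heads[[h]]$Wk
    pl[[sprintf("att1d.h%d.Wv", h)]] <- params$heads[[h]]$Wv
  }
  pl
}

bld_att1d <- function(X, pl, n_heads, d_att) {
  Xp <- ad_add(ad_matmul(X, pl[["att1d.Win"]]), pl[["att1d.bin"]])
  zs <- vector("list", n_heads)
  Ws <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * d_att + 1L):(h * d_att)
    Xh <- ad_cols(Xp, cols)
    Q <- ad_matmul(Xh, pl[[sprintf("att1d.h%d.Wq", h)]])
    K <- ad_matmul(Xh, pl[[sprintf("att1d.h%d.Wk", h)]])
    V <- ad_matmul(Xh, pl[[sprintf("att1d.h%d.Wv", h)]])
    A <- ad_softmax_rows(ad_scale(ad_matmul_bt(Q, K), 1 / sqrt(d_att)))
    zs[[h]] <- ad_matmul(A, V)
    Ws[[h]] <- A
  }
  list(Z = do.call(ad_cbind, zs), W = Ws)
}

#' Multi-head scaled dot-product sequence attention
#'
#' Computes, per head, `Z_h = softmax(Q K' / sqrt(d_att)) V` on the projected
#' per-head slice of `X`, and concatenates head outputs. The row-stochastic
#' attention weights are returned for interpretation: entry (i, j) of a head
#' is the importance of residue j to residue i, and each row sums to 1.
#'
#' @param X numeric matrix `L x d_in` (encoder output).
#' @param params an [attention1d_params()].
#' @return list with `Z` (`L x n_heads*d_att`) and `W`
#'   (`n_heads x L x L` array of attention weights).
#' @export
multihead_attention_1d <- function(X, params) {
  stopifnot(is.matrix(X), ncol(X) == params$d_in)
  if (!all(is.finite(X))) stop("multihead_attention_1d: non-finite input")
  tape <- ad_tape()
  Xn <- ad_leaf(tape, X)
  res <- bld_att1d(Xn, att1d_flat(params), params$n_heads, params$d_att)
  L <- nrow(X)
  W <- array(0, dim = c(params$n_heads, L, L))
  for (h in seq_len(params$n_heads)) W[h, , ] <- ad_value(res$W[[h]])
  list(Z = ad_value(res$Z), W = W)
}

#' Tile a 1D encoding to the 2D pair map
#'
#' `out[i, j, 1:d] = Z[i, ]` and `out[i, j, d + (1:d)] = Z[j, ]`: the row
#' block carries residue i's encoding, the column block residue j's.
#'
#' @param Z numeric matrix `L x d`.
#' @return array `(L, L, 2d)`.
#' @export
tile_1d_to_2d <- function(Z) {
  stopifnot(is.matrix(Z))
  L <- nrow(Z)
  ti <- tile_idx(L)
  out <- cbind(Z[ti[, 1], , drop = FALSE], Z[ti[, 2], , drop = FALSE])
  array(out, dim = c(L, L, 2L * ncol(Z)))
}

bld_tile <- function(Z, L) {
  ti <- tile_idx(L)
  # two single-offset gathers: row-source block then column-source block
  ad_cbind(ad_gather(Z, ti[, 1, drop = FALSE]),
           ad_gather(Z, ti[, 2, drop = FALSE]))
}

#' Region stretching
#'
#' Rewrites each cell of an `(L, L, c)` map as the flattened `n x n` window
#' around it (row-major offset order), zero-padding out-of-bounds cells. This
#' is the fixed-filter convolution that prepares windowed regional attention.
#'
#' @param F numeric array `(L, L, c)`.
#' @param n odd window size (default 5).
#' @return list with `out`, an `(L, L, c, n^2)` array, and `mask`, an
#'   `(L, L, n^2)` logical array marking in-bounds window cells.
#' @export
region_stretch <- function(F, n = 5L) {
  if (n %% 2L != 1L) stop("region_stretch: window size n must be odd, got ", n)
  d <- dim(F)
  L <- d[1]; cc <- d[3]
  idx <- conv_idx2d(L, n)
  P <- L * L
  Fp <- rbind(map_to_mat(F), matrix(0, 1L, cc))
  out <- array(0, dim = c(L, L, cc, n * n))
  for (w in seq_len(n * n)) {
    out[, , , w] <- array(Fp[idx[, w], , drop = FALSE], dim = c(L, L, cc))
  }
  mask <- array(idx <= P, dim = c(L, L, n * n))
  list(out = out, mask = mask)
}

#' Parameters for windowed regional attention
#'
#' Each head maps the center cell's channel vector to a query and every
#' window cell's channel vector to a key and value; concatenated head
#' outputs are projected back to `c_out` channels.
#'
#' @param c_in input channels of the 2D feature map.
#' @param n odd attention window size (default 5).
#' @param n_heads number of heads (default 4).
#' @param d_att per-head query/key/value width.
#' @param c_out output channels (default `c_in`).
#' @param seed seed for initialization.
#' @return object of class `regional_attention_params`.
#' @export
regional_attention_params <- function(c_in, n = 5L, n_heads = 4L, d_att = 32L,
                                      c_out = c_in, seed = 1L) {
  stopifnot(n %% 2L == 1L, n >= 1L)
  with_local_seed(seed, {
    heads <- lapply(seq_len(n_heads), function(h) {
      list(Wq = init_w(c_in, d_att), Wk = init_w(c_in, d_att),
           Wv = init_w(c_in, d_att))
    })
    structure(list(heads = heads, Wo = init_w(n_heads * d_att, c_out),
                   bo = matrix(0, 1L, c_out), n = n, n_heads = n_heads,
                   d_att = d_att, c_in = c_in, c_out = c_out),
              class = "regional_attention_params")
  })
}

att2d_flat <- function(params) {
  pl <- list(att2d.Wo = params$Wo, att2d.bo = params$bo)
  for (h in seq_len(params$n_heads)) {
    pl[[sprintf("att2d.h%d.Wq", h)]] <- params$heads[[h]]$Wq
    pl[[sprintf("att2d.h%d.Wk", h)]] <- params$heads[[h]]$Wk
    pl[[sprintf("att2d.h%d.Wv", h)]] <- params$heads[[h]]$Wv
  }
  pl
}

# F: (P x c) node; returns list(out = (P x c_out) node, W = list of (P x n^2)
# weight nodes per head, mask = P x n^2 logical)
bld_att2d <- function(F, pl, L, cc, n, n_heads, d_att) {
  idx <- conv_idx2d(L, n)
  P <- L * L
  n2 <- n * n
  inb <- idx <= P
  mask_add <- matrix(0, P, n2)
  mask_add[!inb] <- -Inf
  G <- ad_gather(F, idx)  # P x (n2 * c), block w = window cell w's channels
  outs <- vector("list", n_heads)
  Ws <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    Wq <- pl[[sprintf("att2d.h%d.Wq", h)]]
    Wk <- pl[[sprintf("att2d.h%d.Wk", h)]]
    Wv <- pl[[sprintf("att2d.h%d.Wv", h)]]
    q <- ad_matmul(F, Wq)
    lg <- vector("list", n2)
    Vs <- vector("list", n2)
    for (w in seq_len(n2)) {
      blk <- ad_cols(G, ((w - 1L) * cc + 1L):(w * cc))
      lg[[w]] <- ad_scale(ad_rowdot(q, ad_matmul(blk, Wk)), 1 / sqrt(d_att))
      Vs[[w]] <- ad_matmul(blk, Wv)
    }
    A <- ad_softmax_rows(do.call(ad_cbind, lg), mask_add)
    acc <- NULL
    for (w in seq_len(n2)) {
      term <- ad_colmul(ad_cols(A, w), Vs[[w]])
      acc <- if (is.null(acc)) term else ad_add(acc, term)
    }
    outs[[h]] <- acc
    Ws[[h]] <- A
  }
  out <- ad_add(ad_matmul(do.call(ad_cbind, outs), pl[["att2d.Wo"]]),
                pl[["att2d.bo"]])
  list(out = out, W = Ws, mask = inb)
}

#' Windowed regional attention over a 2D feature map
#'
#' Every position (i, j) attends over its `n x n` surrounding window: the
#' query comes from the center cell, keys and values from the stretched
#' window cells; logits are scaled by `1/sqrt(d_att)` and out-of-bounds
#' cells are masked to `-Inf` before the softmax, so each center distributes
#' exactly one unit of attention over its in-bounds window.
#'
#' @param F numeric array `(L, L, c_in)`.
#' @param params a [regional_attention_params()].
#' @return list with `out` (`(L, L, c_out)` array), `W` (attention weights,
#'   `(L, L, n_heads, n^2)` array; out-of-bounds cells exactly 0), and
#'   `mask` (`(L, L, n^2)` logical in-bounds mask).
#' @export
regional_attention <- function(F, params) {
  d <- dim(F)
  stopifnot(length(d) == 3L, d[1] == d[2], d[3] == params$c_in)
  if (!all(is.finite(F))) stop("regional_attention: non-finite input")
  L <- d[1]; n <- params$n
  tape <- ad_tape()
  Fn <- ad_leaf(tape, map_to_mat(F))
  res <- bld_att2d(Fn, att2d_flat(params), L, params$c_in, n,
                   params$n_heads, params$d_att)
  W <- array(0, dim = c(L, L, params$n_heads, n * n))
  for (h in seq_len(params$n_heads)) {
    W[, , h, ] <- array(ad_value(res$W[[h]]), dim = c(L, L, n * n))
  }
  list(out = mat_to_map(ad_value(res$out), L), W = W,
       mask = array(res$mask, dim = c(L, L, n * n)))
}
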