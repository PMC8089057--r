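# Shared network building blocks. Internally every 2D feature map of shape
# (L, L, c) is handled as a dense (L*L) x c matrix in column-major pixel
# order, p = i + (j-1)*L, so array(M, c(L, L, c)) and matrix(F, L*L, c) are
# exact inverses.

map_to_mat <- function(F) {
  d <- dim(F)
  matrix(F, d[1] * d[2], d[3])
}

mat_to_map <- function(M, L) array(M, dim = c(L, L, ncol(M)))

# cache of gather index matrices, keyed by (L, k, dims)
.idx_cache <- new.env(parent = emptyenv())

# (L*L) x k^2 gather indices for a k x k window, offsets in row-major order
# (row offset outer, column offset inner); out-of-bounds cells point at the
# zero pad row L*L + 1
conv_idx2d <- function(L, k) {
  key <- paste0("c2.", L, ".", k)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  h <- (k - 1L) %/% 2L
  P <- L * L
  i <- rep(seq_len(L), times = L)
  j <- rep(seq_len(L), each = L)
  idx <- matrix(P + 1L, P, k * k)
  w <- 0L
  for (dr in -h:h) for (dc in -h:h) {
    w <- w + 1L
    ii <- i + dr; jj <- j + dc
    ok <- ii >= 1L & ii <= L & jj >= 1L & jj <= L
    idx[ok, w] <- ii[ok] + (jj[ok] - 1L) * L
  }
  .idx_cache[[key]] <- idx
  idx
}

conv_idx1d <- function(L, k) {
  key <- paste0("c1.", L, ".", k)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  h <- (k - 1L) %/% 2L
  idx <- matrix(L + 1L, L, k)
  w <- 0L
  for (d in -h:h) {
    w <- w + 1L
    t <- seq_len(L) + d
    ok <- t >= 1L & t <= L
    idx[ok, w] <- t[ok]
  }
  .idx_cache[[key]] <- idx
  idx
}

# tile indices: for pixel p = (i, j), row block source i, column block source j
tile_idx <- function(L) {
  key <- paste0("t.", L)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  i <- rep(seq_len(L), times = L)
  j <- rep(seq_len(L), each = L)
  .idx_cache[[key]] <- cbind(i, j)
  .idx_cache[[key]]
}

bld_conv <- function(x, W, b, idx) ad_add(ad_matmul(ad_gather(x, idx), W), b)

bld_lstm_dir <- function(X, W, b, L, h, reverse = FALSE) {
  hp <- matrix(0, 1L, h)
  cp <- matrix(0, 1L, h)
  outs <- vector("list", L)
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  ih <- seq_len(h)
  for (t in steps) {
    xt <- ad_row(X, t)
    z <- ad_add(ad_matmul(ad_cbind(xt, hp), W), b)
    gi <- ad_sigmoid(ad_cols(z, ih))
    gf <- ad_sigmoid(ad_cols(z, h + ih))
    go <- ad_sigmoid(ad_cols(z, 2L * h + ih))
    gg <- ad_tanh(ad_cols(z, 3L * h + ih))
    cc <- ad_add(ad_mul(gf, cp), ad_mul(gi, gg))
    hh <- ad_mul(go, ad_tanh(cc))
    cp <- cc; hp <- hh
    outs[[t]] <- hh
  }
  ad_rbind(outs)
}

bld_se <- function(F, pl, prefix) {
  g <- function(nm) pl[[paste0(prefix, nm)]]
  s <- ad_colmeans(F)
  z <- ad_relu(ad_add(ad_matmul(s, g("W1")), g("b1")))
  gate <- ad_sigmoid(ad_add(ad_matmul(z, g("W2")), g("b2")))
  ad_rowmul(gate, F)
}

bld_trunk <- function(x, pl, repeats, L, prefix = "trunk.") {
  idx <- conv_idx2d(L, 3L)
  for (b in seq_along(repeats)) {
    inb <- x
    for (r in seq_len(repeats[b])) {
      pre <- sprintf("%sblk%d.c%d.", prefix, b, r)
      x <- ad_instance_norm(x, pl[[paste0(pre, "gamma")]], pl[[paste0(pre, "beta")]])
      x <- ad_relu(x)
      x <- bld_conv(x, pl[[paste0(pre, "W")]], pl[[paste0(pre, "b")]], idx)
    }
    pre <- sprintf("%sblk%d.", prefix, b)
    short <- ad_add(ad_matmul(inb, pl[[paste0(pre, "short.W")]]),
                    pl[[paste0(pre, "short.b")]])
    x <- ad_add(x, short)
    x <- bld_se(x, pl, paste0(pre, "se."))
  }
  x
}

# ---- user-facing building blocks -------------------------------------------

#' Maxout channel-pair reduction
#'
#' Halves the trailing (channel) dimension by taking the maximum over
#' consecutive channel pairs: `out[..., k] = max(F[..., 2k-1], F[..., 2k])`.
#'
#' @param F a numeric array whose last dimension is even (e.g. 128 -> 64).
#' @return an array with the last dimension halved.
#' @export
maxout_reduce <- function(F) {
  d <- dim(F)
  if (is.null(d)) d <- length(F)
  cc <- d[length(d)]
  if (cc %% 2L != 0L) stop("maxout_reduce: last dimension must be even, got ", cc)
  M <- matrix(F, prod(d) / cc, cc)
  m <- cc %/% 2L
  out <- pmax(M[, 2L * seq_len(m) - 1L, drop = FALSE],
              M[, 2L * seq_len(m), drop = FALSE])
  array(out, dim = c(d[-length(d)], m))
}

#' Squeeze-and-excitation parameters
#'
#' Two-layer gating network: channel means -> dense reduction (`c/ratio`,
#' ReLU) -> dense expansion (`c`, sigmoid) -> per-channel multiplicative gate.
#'
#' @param c number of channels to recalibrate.
#' @param ratio bottleneck reduction ratio (default 16).
#' @param seed seed for weight initialization.
#' @return list with `W1`, `b1`, `W2`, `b2`.
#' @export
se_params <- function(c, ratio = 16L, seed = 1L) {
  r <- max(1L, c %/% ratio)
  with_local_seed(seed, list(
    W1 = init_w(c, r), b1 = matrix(0, 1L, r),
    W2 = init_w(r, c), b2 = matrix(0, 1L, c)
  ))
}

#' Squeeze-and-excitation channel recalibration
#'
#' @param F numeric array `(L, L, c)`.
#' @param params from [se_params()] (fields `W1`, `b1`, `W2`, `b2`).
#' @return array of the same shape, each channel scaled by its gate in (0,1).
#' @export
squeeze_excite <- function(F, params) {
  L <- dim(F)[1]
  x <- map_to_mat(F)
  tape <- ad_tape()
  xn <- ad_leaf(tape, x)
  pl <- list(se.W1 = params$W1, se.b1 = params$b1,
             se.W2 = params$W2, se.b2 = params$b2)
  out <- bld_se(xn, pl, "se.")
  mat_to_map(ad_value(out), L)
}

#' Parameters for a residual trunk
#'
#' @param c_in input channel count.
#' @param width trunk width (64 in the published architecture).
#' @param repeats convolutions per residual block (default `c(3, 4, 6, 3)`).
#' @param se_ratio squeeze-and-excitation bottleneck ratio.
#' @param seed seed for initialization.
#' @return flat named parameter list (prefix `trunk.`).
#' @export
residual_stack_params <- function(c_in, width = 64L, repeats = c(3L, 4L, 6L, 3L),
                                  se_ratio = 16L, seed = 1L) {
  cfg <- list(repeats = repeats, trunk_width = width, se_ratio = se_ratio)
  with_local_seed(seed, {
    pl <- list()
    cin <- c_in
    r <- max(1L, width %/% se_ratio)
    for (b in seq_along(repeats)) {
      cc <- cin
      for (rep_i in seq_len(repeats[b])) {
        pre <- sprintf("trunk.blk%d.c%d.", b, rep_i)
        pl[[paste0(pre, "gamma")]] <- matrix(1, 1L, cc)
        pl[[paste0(pre, "beta")]] <- matrix(0, 1L, cc)
        pl[[paste0(pre, "W")]] <- init_w(9L * cc, width)
        pl[[paste0(pre, "b")]] <- matrix(0, 1L, width)
        cc <- width
      }
      pre <- sprintf("trunk.blk%d.", b)
      pl[[paste0(pre, "short.W")]] <- init_w(cin, width)
      pl[[paste0(pre, "short.b")]] <- matrix(0, 1L, width)
      pl[[paste0(pre, "se.W1")]] <- init_w(width, r)
      pl[[paste0(pre, "se.b1")]] <- matrix(0, 1L, r)
      pl[[paste0(pre, "se.W2")]] <- init_w(r, width)
      pl[[paste0(pre, "se.b2")]] <- matrix(0, 1L, width)
      cin <- width
    }
    attr(pl, "repeats") <- repeats
    pl
  })
}

#' Residual trunk forward pass
#'
#' Four residual blocks; each applies (instance norm -> ReLU -> 3x3
#' convolution) `repeats[b]` times, adds a 1x1-convolution shortcut of the
#' block input, then recalibrates channels with a squeeze-and-excitation
#' gate. Spatial dimensions are preserved for any L.
#'
#' @param F numeric array `(L, L, c_in)`.
#' @param params from [residual_stack_params()].
#' @return array `(L, L, width)`.
#' @export
residual_stack <- function(F, params) {
  L <- dim(F)[1]
  repeats <- attr(params, "repeats")
  tape <- ad_tape()
  x <- ad_leaf(tape, map_to_mat(F))
  out <- bld_trunk(x, params, repeats, L)
  mat_to_map(ad_value(out), L)
}
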