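# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Values are always dense base-R matrices (rows = positions/pixels, columns =
# channels) so every heavy operation lands in BLAS. A node records its value,
# the tape ids of its differentiable parents, and a closure mapping the
# incoming gradient to per-parent gradients. Creation order is a topological
# order, so backpropagation is a single reverse sweep.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 1024L)
  e$n <- 0L
  e
}

is_ad <- function(x) inherits(x, "ad_handle")

ad_new <- function(tape, value, parents = list(), backward = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- n
  tape$nodes[[n]] <- list(
    value = value,
    parents = vapply(parents, function(p) p$id, integer(1)),
    backward = backward
  )
  structure(list(tape = tape, id = n), class = "ad_handle")
}

# leaf with gradient tracking (parameters and differentiable inputs)
ad_leaf <- function(tape, value) ad_new(tape, value, list(), backward = NULL)

ad_value <- function(x) if (is_ad(x)) x$tape$nodes[[x$id]]$value else x

#' @noRd
ad_backward <- function(tape, out, seed = NULL) {
  grads <- vector("list", tape$n)
  v <- tape$nodes[[out$id]]$value
  grads[[out$id]] <- if (is.null(seed)) array(1, dim = dim(v) %||% length(v)) else seed
  for (i in seq(out$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$backward) || length(nd$parents) == 0L) next
    pg <- nd$backward(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- primitive operations ---------------------------------------------------

ad_matmul <- function(a, b) {
  stopifnot(is_ad(a) || is_ad(b))
  tape <- if (is_ad(a)) a$tape else b$tape
  va <- ad_value(a); vb <- ad_value(b)
  parents <- Filter(is_ad, list(a, b))
  ad_new(tape, va %*% vb, parents, backward = function(g) {
    out <- list()
    if (is_ad(a)) out <- c(out, list(g %*% t(vb)))
    if (is_ad(b)) out <- c(out, list(crossprod(va, g)))
    out
  })
}

# addition with row-vector (1 x c) or scalar broadcasting on either side
ad_add <- function(a, b) {
  tape <- if (is_ad(a)) a$tape else b$tape
  va <- ad_value(a); vb <- ad_value(b)
  val <- if (is.matrix(va) && is.matrix(vb) && nrow(vb) == 1L && nrow(va) > 1L) {
    sweep(va, 2L, as.vector(vb), "+")
  } else if (is.matrix(vb) && is.matrix(va) && nrow(va) == 1L && nrow(vb) > 1L) {
    sweep(vb, 2L, as.vector(va), "+")
  } else {
    va + vb
  }
  reduce_to <- function(g, v) {
    if (length(v) == 1L) return(sum(g))
    if (is.matrix(v) && nrow(v) == 1L && nrow(g) > 1L) {
      return(matrix(colSums(g), 1L))
    }
    g
  }
  parents <- Filter(is_ad, list(a, b))
  ad_new(tape, val, parents, backward = function(g) {
    out <- list()
    if (is_ad(a)) out <- c(out, list(reduce_to(g, va)))
    if (is_ad(b)) out <- c(out, list(reduce_to(g, vb)))
    out
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

# a %*% t(b)
ad_matmul_bt <- function(a, b) {
  tape <- if (is_ad(a)) a$tape else b$tape
  va <- ad_value(a); vb <- ad_value(b)
  parents <- Filter(is_ad, list(a, b))
  ad_new(tape, tcrossprod(va, vb), parents, backward = function(g) {
    out <- list()
    if (is_ad(a)) out <- c(out, list(g %*% vb))
    if (is_ad(b)) out <- c(out, list(crossprod(g, va)))
    out
  })
}

ad_scale <- function(a, k) {
  if (!is_ad(a)) return(a * k)
  ad_new(a$tape, ad_value(a) * k, list(a), backward = function(g) list(g * k))
}

ad_mul <- function(a, b) {
  tape <- if (is_ad(a)) a$tape else b$tape
  va <- ad_value(a); vb <- ad_value(b)
  stopifnot(identical(dim(va), dim(vb)))
  parents <- Filter(is_ad, list(a, b))
  ad_new(tape, va * vb, parents, backward = function(g) {
    out <- list()
    if (is_ad(a)) out <- c(out, list(g * vb))
    if (is_ad(b)) out <- c(out, list(g * va))
    out
  })
}

# (1 x c) row vector times (P x c) matrix, broadcast over rows
ad_rowmul <- function(r, m) {
  tape <- if (is_ad(r)) r$tape else m$tape
  vr <- ad_value(r); vm <- ad_value(m)
  val <- sweep(vm, 2L, as.vector(vr), "*")
  parents <- Filter(is_ad, list(r, m))
  ad_new(tape, val, parents, backward = function(g) {
    out <- list()
    if (is_ad(r)) out <- c(out, list(matrix(colSums(g * vm), 1L)))
    if (is_ad(m)) out <- c(out, list(sweep(g, 2L, as.vector(vr), "*")))
    out
  })
}

# (P x 1) column vector times (P x c) matrix, broadcast over columns
ad_colmul <- function(v, m) {
  tape <- if (is_ad(v)) v$tape else m$tape
  vv <- ad_value(v); vm <- ad_value(m)
  val <- vm * as.vector(vv)
  parents <- Filter(is_ad, list(v, m))
  ad_new(tape, val, parents, backward = function(g) {
    out <- list()
    if (is_ad(v)) out <- c(out, list(matrix(rowSums(g * vm), ncol = 1L)))
    if (is_ad(m)) out <- c(out, list(g * as.vector(vv)))
    out
  })
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ad_value(a)))
  ad_new(a$tape, s, list(a), backward = function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  t <- tanh(ad_value(a))
  ad_new(a$tape, t, list(a), backward = function(g) list(g * (1 - t * t)))
}

ad_relu <- function(a) {
  v <- ad_value(a)
  keep <- v > 0
  ad_new(a$tape, v * keep, list(a), backward = function(g) list(g * keep))
}

# row-wise softmax; `mask_add` is a constant additive mask (-Inf = excluded)
ad_softmax_rows <- function(a, mask_add = NULL) {
  z <- ad_value(a)
  if (!is.null(mask_add)) z <- z + mask_add
  zm <- z - apply(z, 1L, max)
  zm[is.nan(zm)] <- -Inf  # rows where masked cells stay -Inf
  e <- exp(zm)
  s <- e / rowSums(e)
  ad_new(a$tape, s, list(a), backward = function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# row-wise dot product: (P x d) . (P x d) -> (P x 1)
ad_rowdot <- function(a, b) {
  tape <- if (is_ad(a)) a$tape else b$tape
  va <- ad_value(a); vb <- ad_value(b)
  val <- matrix(rowSums(va * vb), ncol = 1L)
  parents <- Filter(is_ad, list(a, b))
  ad_new(tape, val, parents, backward = function(g) {
    gv <- as.vector(g)
    out <- list()
    if (is_ad(a)) out <- c(out, list(vb * gv))
    if (is_ad(b)) out <- c(out, list(va * gv))
    out
  })
}

ad_cbind <- function(...) {
  args <- list(...)
  tape <- NULL
  for (x in args) if (is_ad(x)) { tape <- x$tape; break }
  vals <- lapply(args, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  parents <- Filter(is_ad, args)
  ad_new(tape, do.call(cbind, vals), parents, backward = function(g) {
    out <- list()
    for (k in seq_along(args)) {
      if (is_ad(args[[k]])) {
        out <- c(out, list(g[, starts[k]:ends[k], drop = FALSE]))
      }
    }
    out
  })
}

ad_cols <- function(a, idx) {
  v <- ad_value(a)
  ad_new(a$tape, v[, idx, drop = FALSE], list(a), backward = function(g) {
    gz <- matrix(0, nrow(v), ncol(v))
    gz[, idx] <- g
    list(gz)
  })
}

ad_row <- function(a, i) {
  v <- ad_value(a)
  ad_new(a$tape, v[i, , drop = FALSE], list(a), backward = function(g) {
    gz <- matrix(0, nrow(v), ncol(v))
    gz[i, ] <- g
    list(gz)
  })
}

ad_rbind <- function(rows) {
  tape <- NULL
  for (x in rows) if (is_ad(x)) { tape <- x$tape; break }
  vals <- lapply(rows, ad_value)
  parents <- Filter(is_ad, rows)
  ad_new(tape, do.call(rbind, vals), parents, backward = function(g) {
    out <- list()
    at <- 0L
    for (k in seq_along(rows)) {
      nr <- nrow(vals[[k]])
      if (is_ad(rows[[k]])) out <- c(out, list(g[(at + 1L):(at + nr), , drop = FALSE]))
      at <- at + nr
    }
    out
  })
}

# Row gather with zero padding: idx is a (P x K) integer matrix of source rows
# in x (value n+1 selects an implicit all-zero pad row). Output is P x (K*c)
# with block k holding x[idx[, k], ]. Backward scatter-adds via rowsum().
ad_gather <- function(x, idx) {
  v <- ad_value(x)
  n <- nrow(v); c <- ncol(v)
  vp <- rbind(v, matrix(0, 1L, c))
  K <- ncol(idx)
  val <- matrix(0, nrow(idx), K * c)
  for (k in seq_len(K)) {
    val[, ((k - 1L) * c + 1L):(k * c)] <- vp[idx[, k], , drop = FALSE]
  }
  ad_new(x$tape, val, list(x), backward = function(g) {
    gx <- matrix(0, n, c)
    for (k in seq_len(K)) {
      gk <- g[, ((k - 1L) * c + 1L):(k * c), drop = FALSE]
      src <- idx[, k]
      ok <- src <= n
      if (!any(ok)) next
      agg <- rowsum(gk[ok, , drop = FALSE], group = src[ok])
      rows <- as.integer(rownames(agg))
      gx[rows, ] <- gx[rows, , drop = FALSE] + agg
    }
    list(gx)
  })
}

# Maxout over channel pairs: (P x 2m) -> (P x m), out[, k] = max over pair k
ad_maxout <- function(a) {
  v <- ad_value(a)
  m <- ncol(v) %/% 2L
  stopifnot(ncol(v) %% 2L == 0L)
  i1 <- 2L * seq_len(m) - 1L
  i2 <- 2L * seq_len(m)
  take1 <- v[, i1, drop = FALSE] >= v[, i2, drop = FALSE]
  val <- ifelse(take1, v[, i1, drop = FALSE], v[, i2, drop = FALSE])
  ad_new(a$tape, val, list(a), backward = function(g) {
    gz <- matrix(0, nrow(v), ncol(v))
    gz[, i1] <- g * take1
    gz[, i2] <- g * (!take1)
    list(gz)
  })
}

# Instance normalization: each column (channel) standardized over rows
# (positions), then scaled/shifted by 1 x c parameters gamma/beta.
ad_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  v <- ad_value(x)
  vg <- as.vector(ad_value(gamma)); vb <- as.vector(ad_value(beta))
  N <- nrow(v)
  mu <- colMeans(v)
  d <- sweep(v, 2L, mu, "-")
  var <- colMeans(d * d)
  inv_sd <- 1 / sqrt(var + eps)
  xh <- sweep(d, 2L, inv_sd, "*")
  val <- sweep(sweep(xh, 2L, vg, "*"), 2L, vb, "+")
  parents <- Filter(is_ad, list(x, gamma, beta))
  ad_new(x$tape, val, parents, backward = function(g) {
    out <- list()
    if (is_ad(x)) {
      dxh <- sweep(g, 2L, vg, "*")
      s1 <- colSums(dxh)
      s2 <- colSums(dxh * xh)
      dx <- sweep(sweep(dxh, 2L, s1 / N, "-") - sweep(xh, 2L, s2 / N, "*"),
                  2L, inv_sd, "*")
      out <- c(out, list(dx))
    }
    if (is_ad(gamma)) out <- c(out, list(matrix(colSums(g * xh), 1L)))
    if (is_ad(beta)) out <- c(out, list(matrix(colSums(g), 1L)))
    out
  })
}

ad_colmeans <- function(a) {
  v <- ad_value(a)
  N <- nrow(v)
  ad_new(a$tape, matrix(colMeans(v), 1L), list(a), backward = function(g) {
    list(matrix(rep(as.vector(g) / N, each = N), N))
  })
}

# Numerically stable mean binary cross-entropy from logits, over weights w
# (typically a 0/1 mask); y and w are constants.
ad_bce_masked <- function(logits, y, w) {
  z <- ad_value(logits)
  sw <- sum(w)
  stopifnot(sw > 0)
  li <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  val <- sum(w * li) / sw
  ad_new(logits$tape, val, list(logits), backward = function(g) {
    p <- 1 / (1 + exp(-z))
    list(as.vector(g) * w * (p - y) / sw)
  })
}
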