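# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a "node": an environment holding the
# forward value (`val`), an accumulated gradient (`grad`), a requires-grad
# flag (`rg`) and, for non-leaf nodes recorded on the active tape, a
# backward closure (`bw`) that pushes the node's gradient into its parents.
# The tape is a flat list in creation order; backpropagation walks it once
# in reverse.  Values are base-R matrices (feature maps are stored as
# (h*w) x channels matrices in row-major token order), so all heavy lifting
# is BLAS matmul plus vectorised arithmetic.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L
.ag$recording <- FALSE

#' Start recording operations on a fresh gradient tape
#'
#' Subsequent `ag_*` operations append backward closures to the tape so
#' that [ag_backward()] can propagate gradients.  Call [ag_tape_stop()]
#' (or let the training step do it) to drop the tape and free memory.
#' @return Invisibly `NULL`.
#' @keywords internal
#' @export
ag_tape_start <- function() {
  .ag$tape <- vector("list", 2048L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  invisible(NULL)
}

#' @rdname ag_tape_start
#' @export
ag_tape_stop <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  .ag$recording <- FALSE
  invisible(NULL)
}

ag_record <- function(e, bw) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) {
    .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  }
  .ag$tape[[n]] <- e
  .ag$n <- n
  e$bw <- bw
  e
}

#' Create an autodiff node
#'
#' @param val Numeric matrix (or scalar) forward value.
#' @param rg Does this node require a gradient?
#' @param bw Backward closure `function(g)` distributing `g` to parents;
#'   only recorded while a tape is active.
#' @return The node (an environment with `val`, `grad`, `rg`).
#' @keywords internal
#' @export
ag_node <- function(val, rg = FALSE, bw = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$rg <- rg
  if (rg && !is.null(bw) && .ag$recording) ag_record(e, bw)
  e
}

#' @rdname ag_node
#' @param x Numeric value to wrap.
#' @export
ag_const <- function(x) ag_node(x, rg = FALSE)

#' @rdname ag_node
#' @export
ag_param <- function(x) ag_node(x, rg = TRUE)

ag_accum <- function(node, g) {
  if (isTRUE(node$rg)) {
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  }
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#'
#' Seeds the root gradient with 1 and walks the active tape in reverse
#' creation order.  Leaf nodes created with [ag_param()] end up with their
#' gradient in `$grad`.
#' @param root Scalar node returned by a loss operation.
#' @return Invisibly `NULL`.
#' @keywords internal
#' @export
ag_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  root$grad <- 1
  if (.ag$n > 0L) {
    for (i in seq.int(.ag$n, 1L)) {
      nd <- .ag$tape[[i]]
      if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
    }
  }
  invisible(NULL)
}

# ---- elementwise / linear algebra ------------------------------------------

#' Elementwise and linear-algebra autodiff operations
#'
#' The `ag_*` operation family mirrors the handful of primitives the
#' detector needs: sums, products, matrix multiplication, affine layers,
#' row/column gather-scatter, layer normalisation, GELU, sparse linear
#' maps (used for bilinear resizing and RoI-Align sampling), max pooling,
#' windowed multi-head attention and the loss reductions.  Each returns a
#' new node; gradients flow to any parent with `rg = TRUE`.
#'
#' @param a,b,x Input nodes.
#' @name ag-ops
#' @keywords internal
NULL

#' @rdname ag-ops
#' @export
ag_add <- function(a, b) {
  rg <- a$rg || b$rg
  ag_node(a$val + b$val, rg, function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  })
}

#' @rdname ag-ops
#' @param k Plain numeric scalar.
#' @export
ag_scale <- function(a, k) {
  ag_node(a$val * k, a$rg, function(g) ag_accum(a, g * k))
}

#' @rdname ag-ops
#' @export
ag_mul <- function(a, b) {
  av <- a$val
  bv <- b$val
  ag_node(av * bv, a$rg || b$rg, function(g) {
    ag_accum(a, g * bv)
    ag_accum(b, g * av)
  })
}

#' @rdname ag-ops
#' @export
ag_matmul <- function(a, b) {
  av <- a$val
  bv <- b$val
  ag_node(av %*% bv, a$rg || b$rg, function(g) {
    if (a$rg) ag_accum(a, tcrossprod(g, bv))
    if (b$rg) ag_accum(b, crossprod(av, g))
  })
}

#' @rdname ag-ops
#' @param W Weight node (in_dim x out_dim); `bias` an optional vector node.
#' @param bias Optional bias node (length out_dim vector).
#' @export
ag_linear <- function(x, W, bias = NULL) {
  xv <- x$val
  wv <- W$val
  y <- xv %*% wv
  if (!is.null(bias)) y <- y + rep(bias$val, each = nrow(y))
  rg <- x$rg || W$rg || (!is.null(bias) && bias$rg)
  ag_node(y, rg, function(g) {
    if (x$rg) ag_accum(x, g %*% t(wv))
    if (W$rg) ag_accum(W, crossprod(xv, g))
    if (!is.null(bias) && bias$rg) ag_accum(bias, colSums(g))
  })
}

# ---- gather / scatter ------------------------------------------------------

#' @rdname ag-ops
#' @param idx Integer row indices; 0 selects an all-zero row (used for
#'   zero padding at borders).
#' @export
ag_rows <- function(x, idx) {
  xv <- x$val
  nr <- nrow(xv)
  has_zero <- any(idx == 0L)
  y <- if (has_zero) {
    rbind(matrix(0, 1L, ncol(xv)), xv)[idx + 1L, , drop = FALSE]
  } else {
    xv[idx, , drop = FALSE]
  }
  ag_node(y, x$rg, function(g) {
    dx <- matrix(0, nr, ncol(xv))
    if (!has_zero && !anyDuplicated(idx)) {
      dx[idx, ] <- g
    } else {
      rs <- rowsum(g, group = idx, reorder = FALSE)
      keep <- rownames(rs) != "0"
      dx[as.integer(rownames(rs)[keep]), ] <- rs[keep, , drop = FALSE]
    }
    ag_accum(x, dx)
  })
}

#' @rdname ag-ops
#' @export
ag_cols <- function(x, idx) {
  xv <- x$val
  ag_node(xv[, idx, drop = FALSE], x$rg, function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[, idx] <- g
    ag_accum(x, dx)
  })
}

#' @rdname ag-ops
#' @param xs List of nodes with equal row (for cbind) or column (for
#'   rbind) counts.
#' @export
ag_cbind <- function(xs) {
  vals <- lapply(xs, function(e) e$val)
  ncols <- vapply(vals, ncol, 0L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  rg <- any(vapply(xs, function(e) e$rg, FALSE))
  ag_node(do.call(cbind, vals), rg, function(g) {
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

#' @rdname ag-ops
#' @export
ag_rbind <- function(xs) {
  vals <- lapply(xs, function(e) e$val)
  nrows <- vapply(vals, nrow, 0L)
  ends <- cumsum(nrows)
  starts <- ends - nrows + 1L
  rg <- any(vapply(xs, function(e) e$rg, FALSE))
  ag_node(do.call(rbind, vals), rg, function(g) {
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

#' @rdname ag-ops
#' @param perm Permutation of element (column-major) positions;
#'   `dims` the output dimension.
#' @param dims Output `c(nrow, ncol)`.
#' @export
ag_permute_elems <- function(x, perm, dims) {
  xv <- x$val
  y <- matrix(as.vector(xv)[perm], dims[1L], dims[2L])
  ag_node(y, x$rg, function(g) {
    dx <- numeric(length(xv))
    dx[perm] <- as.vector(g)
    ag_accum(x, matrix(dx, nrow(xv), ncol(xv)))
  })
}

# ---- nonlinearities --------------------------------------------------------

#' @rdname ag-ops
#' @export
ag_gelu <- function(x) {
  xv <- x$val
  ph <- stats::pnorm(xv)
  ag_node(xv * ph, x$rg, function(g) {
    ag_accum(x, g * (ph + xv * stats::dnorm(xv)))
  })
}

#' @rdname ag-ops
#' @export
ag_relu <- function(x) {
  xv <- x$val
  pos <- xv > 0
  ag_node(xv * pos, x$rg, function(g) ag_accum(x, g * pos))
}

#' @rdname ag-ops
#' @param gamma,beta Per-channel scale/shift parameter nodes.
#' @param eps Variance floor.
#' @export
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  n <- nrow(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  gv <- gamma$val
  y <- xhat * rep(gv, each = n) + rep(beta$val, each = n)
  ag_node(y, x$rg || gamma$rg || beta$rg, function(g) {
    if (gamma$rg) ag_accum(gamma, colSums(g * xhat))
    if (beta$rg) ag_accum(beta, colSums(g))
    if (x$rg) {
      dxh <- g * rep(gv, each = n)
      ag_accum(x, inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)))
    }
  })
}

# ---- sparse linear (resize / RoI sampling) ---------------------------------

#' @rdname ag-ops
#' @param S A `dgCMatrix` of fixed sampling weights (rows: output
#'   positions, cols: input positions); applied per channel.
#' @export
ag_sparse_linear <- function(S, x) {
  xv <- x$val
  ag_node(as.matrix(S %*% xv), x$rg, function(g) {
    ag_accum(x, as.matrix(Matrix::crossprod(S, g)))
  })
}

# ---- max pooling -----------------------------------------------------------

#' @rdname ag-ops
#' @param h,w Spatial dims of `x` (rows are row-major tokens); `s` the
#'   pooling kernel = stride.
#' @param s Pooling factor.
#' @export
ag_maxpool <- function(x, h, w, s) {
  stopifnot(h %% s == 0L, w %% s == 0L)
  xv <- x$val
  ho <- h %/% s
  wo <- w %/% s
  nc <- ncol(xv)
  nout <- ho * wo
  ro <- rep(seq_len(ho), each = wo)
  co <- rep(seq_len(wo), times = ho)
  best <- matrix(-Inf, nout, nc)
  argr <- matrix(0L, nout, nc)
  for (dy in 0:(s - 1L)) {
    for (dx in 0:(s - 1L)) {
      src <- ((ro - 1L) * s + dy) * w + (co - 1L) * s + dx + 1L
      cand <- xv[src, , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      argr[upd] <- rep(src, times = nc)[upd]
    }
  }
  ag_node(best, x$rg, function(g) {
    lin <- as.vector(argr) + (rep(seq_len(nc), each = nout) - 1L) * nrow(xv)
    dx <- numeric(nrow(xv) * nc)
    rs <- rowsum(as.vector(g), group = lin, reorder = FALSE)
    dx[as.integer(rownames(rs))] <- rs[, 1L]
    ag_accum(x, matrix(dx, nrow(xv), nc))
  })
}

# ---- windowed multi-head attention -----------------------------------------

#' @rdname ag-ops
#' @param q,k,v Nodes of shape (nwin*T) x C, rows ordered window-major.
#' @param nwin Number of windows; `heads` number of attention heads
#'   (C must be divisible by `heads`).
#' @param heads Number of heads.
#' @param bias_tab Optional node: relative-position bias table,
#'   (2M-1)^2 x heads, looked up through `rel_idx`.
#' @param rel_idx Integer T x T matrix of bias-table rows.
#' @param masks Optional list (length nwin) of additive T x T matrices
#'   (0 for allowed pairs, large negative for forbidden pairs).
#' @export
ag_attention <- function(q, k, v, nwin, heads, bias_tab = NULL,
                         rel_idx = NULL, masks = NULL) {
  qv <- q$val
  kv <- k$val
  vv <- v$val
  C <- ncol(qv)
  stopifnot(C %% heads == 0L)
  d <- C %/% heads
  Tn <- nrow(qv) %/% nwin
  scl <- 1 / sqrt(d)
  y <- matrix(0, nrow(qv), C)
  P_store <- vector("list", nwin * heads)
  bias_mats <- NULL
  if (!is.null(bias_tab)) {
    bias_mats <- lapply(seq_len(heads), function(hh) {
      matrix(bias_tab$val[rel_idx, hh], Tn, Tn)
    })
  }
  for (wi in seq_len(nwin)) {
    rows <- ((wi - 1L) * Tn + 1L):(wi * Tn)
    for (hh in seq_len(heads)) {
      cls <- ((hh - 1L) * d + 1L):(hh * d)
      Qh <- qv[rows, cls, drop = FALSE]
      Kh <- kv[rows, cls, drop = FALSE]
      Vh <- vv[rows, cls, drop = FALSE]
      S <- tcrossprod(Qh, Kh) * scl
      if (!is.null(bias_mats)) S <- S + bias_mats[[hh]]
      if (!is.null(masks)) S <- S + masks[[wi]]
      S <- S - apply(S, 1L, max)
      P <- exp(S)
      P <- P / rowSums(P)
      P_store[[(wi - 1L) * heads + hh]] <- P
      y[rows, cls] <- P %*% Vh
    }
  }
  rg <- q$rg || k$rg || v$rg || (!is.null(bias_tab) && bias_tab$rg)
  ag_node(y, rg, function(g) {
    dq <- matrix(0, nrow(qv), C)
    dk <- matrix(0, nrow(qv), C)
    dv <- matrix(0, nrow(qv), C)
    dbias <- if (!is.null(bias_tab)) matrix(0, Tn * Tn, heads) else NULL
    for (wi in seq_len(nwin)) {
      rows <- ((wi - 1L) * Tn + 1L):(wi * Tn)
      for (hh in seq_len(heads)) {
        cls <- ((hh - 1L) * d + 1L):(hh * d)
        P <- P_store[[(wi - 1L) * heads + hh]]
        dO <- g[rows, cls, drop = FALSE]
        Vh <- vv[rows, cls, drop = FALSE]
        dv[rows, cls] <- dv[rows, cls] + crossprod(P, dO)
        dP <- tcrossprod(dO, Vh)
        dS <- P * (dP - rowSums(dP * P))
        dq[rows, cls] <- dS %*% kv[rows, cls, drop = FALSE] * scl
        dk[rows, cls] <- crossprod(dS, qv[rows, cls, drop = FALSE]) * scl
        if (!is.null(dbias)) dbias[, hh] <- dbias[, hh] + as.vector(dS)
      }
    }
    ag_accum(q, dq)
    ag_accum(k, dk)
    ag_accum(v, dv)
    if (!is.null(bias_tab) && bias_tab$rg) {
      dt <- rowsum(dbias, group = as.vector(rel_idx), reorder = FALSE)
      full <- matrix(0, nrow(bias_tab$val), heads)
      full[as.integer(rownames(dt)), ] <- dt
      ag_accum(bias_tab, full)
    }
  })
}

# ---- reductions / losses ---------------------------------------------------

#' @rdname ag-ops
#' @export
ag_mean_all <- function(x) {
  n <- length(x$val)
  ag_node(sum(x$val) / n, x$rg, function(g) {
    ag_accum(x, array(g / n, dim = dim(x$val) %||% length(x$val)))
  })
}

#' @rdname ag-ops
#' @export
ag_sum_all <- function(x) {
  ag_node(sum(x$val), x$rg, function(g) {
    ag_accum(x, array(g, dim = dim(x$val) %||% length(x$val)))
  })
}

#' @rdname ag-ops
#' @param logits Node of logits; `target` plain numeric 0/1 vector.
#' @param target Plain numeric target vector/matrix.
#' @export
ag_sigmoid_bce <- function(logits, target) {
  z <- logits$val
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * target + log1p(exp(-abs(z)))) / n
  ag_node(loss, logits$rg, function(g) {
    p <- 1 / (1 + exp(-z))
    dz <- (p - target) * (g / n)
    ag_accum(logits, if (is.matrix(z)) matrix(dz, nrow(z)) else dz)
  })
}

#' @rdname ag-ops
#' @param labels Integer class labels in 1..K (rows of `logits`).
#' @export
ag_softmax_ce <- function(logits, labels) {
  z <- logits$val
  n <- nrow(z)
  zs <- z - apply(z, 1L, max)
  ez <- exp(zs)
  P <- ez / rowSums(ez)
  loss <- -sum(log(pmax(P[cbind(seq_len(n), labels)], 1e-12))) / n
  ag_node(loss, logits$rg, function(g) {
    dz <- P
    dz[cbind(seq_len(n), labels)] <- dz[cbind(seq_len(n), labels)] - 1
    ag_accum(logits, dz * (g / n))
  })
}

#' @rdname ag-ops
#' @param pred Node of predicted regression values; `target` plain
#'   numeric of the same shape; `beta` the smooth-L1 transition point;
#'   `denom` the normalising count.
#' @param beta Smooth-L1 transition point (> 0).
#' @param denom Normalising divisor for the summed loss.
#' @export
ag_smooth_l1_loss <- function(pred, target, beta, denom = length(target)) {
  x <- pred$val - target
  ax <- abs(x)
  quad <- ax < beta
  l <- ifelse(quad, 0.5 * x * x / beta, ax - 0.5 * beta)
  loss <- sum(l) / denom
  ag_node(loss, pred$rg, function(g) {
    dx <- ifelse(quad, x / beta, sign(x)) * (g / denom)
    ag_accum(pred, if (is.matrix(x)) matrix(dx, nrow(x)) else dx)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
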