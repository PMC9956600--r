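# Index bookkeeping for token grids.
#
# Feature maps are (h*w) x c matrices whose rows enumerate the spatial
# grid row-major: token (r, c) lives in row (r-1)*w + c.  All spatial
# rearrangements (window partition, cyclic shift, 2x2 merge/expand,
# zero-padding, 3x3 neighbourhood gather) reduce to integer index
# vectors, memoised here, that feed `ag_rows` / `ag_permute_elems`.
# Resampling (bilinear resize, RoI-Align) is precomputed as a sparse
# weight matrix applied per channel through `ag_sparse_linear`.

.ix_memo <- new.env(parent = emptyenv())

ix_memo <- function(key, fn) {
  if (!is.null(.ix_memo[[key]])) return(.ix_memo[[key]])
  v <- fn()
  assign(key, v, envir = .ix_memo)
  v
}

tok_row <- function(r, c, w) (r - 1L) * w + c

#' Window partition permutation
#'
#' Returns the permutation that reorders row-major tokens of an h x w
#' grid into window-major order (windows enumerated row-major, tokens
#' row-major within each M x M window), its inverse, and the window
#' count.
#' @param h,w Grid size (must be divisible by `M`).
#' @param M Window side in tokens.
#' @return list(perm, inv, nwin, ntok)
#' @keywords internal
#' @export
ix_window <- function(h, w, M) {
  stopifnot(h %% M == 0L, w %% M == 0L)
  ix_memo(sprintf("win_%d_%d_%d", h, w, M), function() {
    wy <- rep(seq_len(h %/% M), each = (w %/% M) * M * M)
    base <- expand.grid(dx = seq_len(M), dy = seq_len(M))
    perm <- integer(h * w)
    i <- 1L
    for (by in seq_len(h %/% M)) {
      for (bx in seq_len(w %/% M)) {
        rr <- (by - 1L) * M + rep(seq_len(M), each = M)
        cc <- (bx - 1L) * M + rep(seq_len(M), times = M)
        perm[i:(i + M * M - 1L)] <- tok_row(rr, cc, w)
        i <- i + M * M
      }
    }
    inv <- integer(length(perm))
    inv[perm] <- seq_along(perm)
    list(perm = perm, inv = inv, nwin = (h %/% M) * (w %/% M), ntok = M * M)
  })
}

#' Cyclic shift source indices
#'
#' Index vector such that `X[idx, ]` is the grid cyclically shifted by
#' `(-s, -s)` (content moves up-left, wrapping around).
#' @param h,w Grid size; `s` shift in tokens.
#' @param s Shift amount.
#' @keywords internal
#' @export
ix_shift <- function(h, w, s) {
  ix_memo(sprintf("shift_%d_%d_%d", h, w, s), function() {
    r <- rep(seq_len(h), each = w)
    c <- rep(seq_len(w), times = h)
    sr <- ((r - 1L + s) %% h) + 1L
    sc <- ((c - 1L + s) %% w) + 1L
    tok_row(sr, sc, w)
  })
}

#' Relative-position index table for an M x M window
#'
#' T x T matrix (T = M^2) giving, for each (query, key) token pair, the
#' row of the (2M-1)^2-entry learned bias table indexed by their relative
#' coordinate (dy, dx) in -(M-1)..(M-1).
#' @param M Window side.
#' @keywords internal
#' @export
ix_relpos <- function(M) {
  ix_memo(sprintf("relpos_%d", M), function() {
    ry <- rep(seq_len(M), each = M)
    rx <- rep(seq_len(M), times = M)
    dy <- outer(ry, ry, "-") + (M - 1L)
    dx <- outer(rx, rx, "-") + (M - 1L)
    matrix(as.integer(dy * (2L * M - 1L) + dx + 1L), M * M, M * M)
  })
}

#' Attention masks for shifted windows
#'
#' For a cyclic shift of `s`, tokens from different pre-shift contiguous
#' regions can share a window; their attention logits receive a large
#' negative additive mask.  Regions are the standard 3 x 3 slicing of
#' rows/cols at boundaries (h-M) and (h-s).
#' @param h,w Grid size; `M` window side; `s` shift.
#' @param M,s Window side and shift.
#' @return list of per-window T x T additive masks (NULL-free), or NULL
#'   when s == 0.
#' @keywords internal
#' @export
ix_shift_masks <- function(h, w, M, s) {
  if (s == 0L) return(NULL)
  ix_memo(sprintf("smask_%d_%d_%d_%d", h, w, M, s), function() {
    reg1 <- function(n) {
      # region id along one axis for 0-based coordinate vector
      v <- integer(n)
      co <- seq_len(n) - 1L
      v[co >= n - M & co < n - s] <- 1L
      v[co >= n - s] <- 2L
      v
    }
    ry <- reg1(h)
    rx <- reg1(w)
    r <- rep(seq_len(h), each = w)
    c <- rep(seq_len(w), times = h)
    region <- ry[r] * 3L + rx[c]          # per original token
    shifted <- region[ix_shift(h, w, s)]  # region of each shifted position
    iw <- ix_window(h, w, M)
    regw <- shifted[iw$perm]
    lapply(seq_len(iw$nwin), function(wi) {
      rows <- ((wi - 1L) * iw$ntok + 1L):(wi * iw$ntok)
      rg <- regw[rows]
      m <- outer(rg, rg, "!=") * -1e9
      m
    })
  })
}

#' 2x2 patch-merging gather indices
#'
#' Four index vectors (top-left, top-right, bottom-left, bottom-right)
#' over the input grid; cbinding the four gathers yields the 4c-channel
#' merged map on the (h/2) x (w/2) grid.
#' @param h,w Input grid size (even).
#' @keywords internal
#' @export
ix_merge <- function(h, w) {
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  ix_memo(sprintf("merge_%d_%d", h, w), function() {
    r <- rep(seq_len(h %/% 2L), each = w %/% 2L)
    c <- rep(seq_len(w %/% 2L), times = h %/% 2L)
    list(
      tl = tok_row(2L * r - 1L, 2L * c - 1L, w),
      tr = tok_row(2L * r - 1L, 2L * c, w),
      bl = tok_row(2L * r, 2L * c - 1L, w),
      br = tok_row(2L * r, 2L * c, w)
    )
  })
}

#' Patch-expanding interleave permutation
#'
#' After the c -> 2c linear map, the 2c channels are split into four
#' c/2-channel quadrant blocks (TL, TR, BL, BR); this permutation
#' interleaves the rbind-ed quadrant rows into the (2h) x (2w) grid.
#' Returns indices into the stacked (4*h*w)-row matrix for each output
#' row.
#' @param h,w Input grid size.
#' @keywords internal
#' @export
ix_expand <- function(h, w) {
  ix_memo(sprintf("expand_%d_%d", h, w), function() {
    H <- 2L * h
    W <- 2L * w
    R <- rep(seq_len(H), each = W)
    C <- rep(seq_len(W), times = H)
    dy <- (R - 1L) %% 2L
    dx <- (C - 1L) %% 2L
    r <- (R + 1L) %/% 2L
    c <- (C + 1L) %/% 2L
    q <- dy * 2L + dx           # 0=TL 1=TR 2=BL 3=BR
    q * (h * w) + tok_row(r, c, w)
  })
}

#' Zero-padding gather indices
#'
#' Maps an h x w grid into the top-left corner of a ph x pw grid; padded
#' positions get index 0 (an all-zero row under `ag_rows`).  `inv` crops
#' back.
#' @param h,w Input size; `ph,pw` padded size.
#' @param ph,pw Padded size.
#' @keywords internal
#' @export
ix_pad <- function(h, w, ph, pw) {
  ix_memo(sprintf("pad_%d_%d_%d_%d", h, w, ph, pw), function() {
    R <- rep(seq_len(ph), each = pw)
    C <- rep(seq_len(pw), times = ph)
    idx <- ifelse(R <= h & C <= w, tok_row(pmin(R, h), pmin(C, w), w), 0L)
    r <- rep(seq_len(h), each = w)
    c <- rep(seq_len(w), times = h)
    list(pad = as.integer(idx), crop = tok_row(r, c, pw))
  })
}

#' 3x3 neighbourhood gather indices (zero padded)
#'
#' (h*w) x 9 matrix of row indices (0 = outside the grid) enumerating the
#' 3 x 3 neighbourhood of every token, (dy, dx) row-major.  Concatenating
#' the nine gathers implements a 3x3 convolution as one linear layer.
#' @param h,w Grid size.
#' @keywords internal
#' @export
ix_conv3 <- function(h, w) {
  ix_memo(sprintf("conv3_%d_%d", h, w), function() {
    r <- rep(seq_len(h), each = w)
    c <- rep(seq_len(w), times = h)
    out <- matrix(0L, h * w, 9L)
    j <- 1L
    for (dy in -1L:1L) {
      for (dx in -1L:1L) {
        rr <- r + dy
        cc <- c + dx
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        out[, j] <- ifelse(ok, tok_row(pmax(rr, 1L), pmax(cc, 1L), w), 0L)
        j <- j + 1L
      }
    }
    out
  })
}

#' Patch-partition gather table
#'
#' For an H x W x 3 image array and patch size p, returns an
#' (H/p * W/p) x (3 p^2) matrix of linear indices into the array such
#' that row t is the flattened raw patch of token t.  Flattening order:
#' dx fastest, then dy, then channel.
#' @param H,W Image size (multiples of `p`); `p` patch size.
#' @param p Patch size.
#' @keywords internal
#' @export
ix_patch <- function(H, W, p) {
  ix_memo(sprintf("patch_%d_%d_%d", H, W, p), function() {
    hh <- H %/% p
    ww <- W %/% p
    r <- rep(seq_len(hh), each = ww)
    c <- rep(seq_len(ww), times = hh)
    n <- hh * ww
    out <- matrix(0L, n, 3L * p * p)
    for (ch in 0:2) {
      for (dy in 0:(p - 1L)) {
        for (dx in 0:(p - 1L)) {
          j <- ch * p * p + dy * p + dx + 1L
          py <- (r - 1L) * p + dy + 1L
          px <- (c - 1L) * p + dx + 1L
          out[, j] <- py + (px - 1L) * H + ch * H * W
        }
      }
    }
    out
  })
}

#' Row-block flattening permutation
#'
#' Element permutation turning a (nblock*T) x C matrix (rows grouped by
#' block) into an nblock x (T*C) matrix whose row b is block b flattened
#' (token-major, channels fastest).
#' @param nblock,T,C Block count, rows per block, channels.
#' @keywords internal
#' @export
ix_flatten_blocks <- function(nblock, T, C) {
  key <- sprintf("flat_%d_%d_%d", nblock, T, C)
  ix_memo(key, function() {
    b <- rep(seq_len(nblock), times = T * C)
    colout <- rep(seq_len(T * C), each = nblock)
    j <- (colout - 1L) %/% C + 1L   # token within block
    ch <- (colout - 1L) %% C + 1L
    row_in <- (b - 1L) * T + j
    src <- row_in + (ch - 1L) * (nblock * T)
    list(perm = as.integer(src), dims = c(nblock, T * C))
  })
}

#' Bilinear resize weights (half-pixel centres)
#'
#' Sparse (ho*wo) x (hi*wi) matrix resampling a row-major token grid by
#' bilinear interpolation with the half-pixel-centre convention
#' (src = (dst + 0.5) * scale - 0.5, clamped to the valid range).
#' @param hi,wi Input grid; `ho,wo` output grid.
#' @param ho,wo Output grid.
#' @keywords internal
#' @export
mk_bilinear <- function(hi, wi, ho, wo) {
  ix_memo(sprintf("bilin_%d_%d_%d_%d", hi, wi, ho, wo), function() {
    axis <- function(n_in, n_out) {
      src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
      src <- pmin(pmax(src, 0), n_in - 1)
      i0 <- floor(src)
      f <- src - i0
      i1 <- pmin(i0 + 1, n_in - 1)
      list(i0 = i0 + 1, i1 = i1 + 1, w0 = 1 - f, w1 = f)
    }
    ay <- axis(hi, ho)
    ax <- axis(wi, wo)
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (qy in 1:2) {
      for (qx in 1:2) {
        iy <- if (qy == 1) ay$i0 else ay$i1
        wy <- if (qy == 1) ay$w0 else ay$w1
        jx <- if (qx == 1) ax$i0 else ax$i1
        wx <- if (qx == 1) ax$w0 else ax$w1
        r <- rep(seq_len(ho), each = wo)
        c <- rep(seq_len(wo), times = ho)
        rows <- c(rows, tok_row(r, c, wo))
        cols <- c(cols, tok_row(iy[r], jx[c], wi))
        vals <- c(vals, wy[r] * wx[c])
      }
    }
    Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                         dims = c(ho * wo, hi * wi))
  })
}

#' RoI-Align sampling weights
#'
#' Builds the sparse ((nbox * out^2) x (h*w)) matrix whose product with a
#' level's (h*w) x C feature matrix yields, for every box, the out x out
#' pooled patch (rows box-major, bins row-major).  Each bin averages
#' `samples`^2 regular bilinear sample points; boxes are given in level
#' coordinates (pixels / stride), 0-based half-open.
#' @param h,w Level grid size.
#' @param boxes Matrix (n x 4) of (x1, y1, x2, y2) in level units.
#' @param out Output bin grid side (default 7).
#' @param samples Sample points per bin axis (default 2).
#' @keywords internal
#' @export
mk_roi_sampler <- function(h, w, boxes, out = 7L, samples = 2L) {
  nb <- nrow(boxes)
  npt <- out * out * samples * samples
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  bw_ <- pmax(boxes[, 3] - boxes[, 1], 1e-4)
  bh_ <- pmax(boxes[, 4] - boxes[, 2], 1e-4)
  # sample point offsets within a bin (0-based fractions)
  so <- (seq_len(samples) - 0.5) / samples
  binr <- rep(seq_len(out), each = out * samples * samples)
  binc <- rep(rep(seq_len(out), each = samples * samples), times = out)
  sy <- rep(rep(so, each = samples), times = out * out)
  sx <- rep(rep(so, times = samples), times = out * out)
  for (b in seq_len(nb)) {
    ys <- boxes[b, 2] + (binr - 1 + sy) * bh_[b] / out
    xs <- boxes[b, 1] + (binc - 1 + sx) * bw_[b] / out
    # continuous coords -> token grid (centres at integer+0.5)
    yy <- pmin(pmax(ys - 0.5, 0), h - 1)
    xx <- pmin(pmax(xs - 0.5, 0), w - 1)
    y0 <- floor(yy); x0 <- floor(xx)
    fy <- yy - y0;  fx <- xx - x0
    y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
    rr <- (b - 1L) * out * out + (binr - 1L) * out + binc
    wgt <- 1 / (samples * samples)
    for (q in 1:4) {
      iy <- if (q <= 2) y0 else y1
      ix <- if (q %% 2 == 1) x0 else x1
      wq <- switch(q,
                   (1 - fy) * (1 - fx),
                   (1 - fy) * fx,
                   fy * (1 - fx),
                   fy * fx)
      rows <- c(rows, rr)
      cols <- c(cols, iy * w + ix + 1)
      vals <- c(vals, wq * wgt)
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(nb * out * out, h * w))
}
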