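# Hierarchical shifted-window attention backbone.
#
# An H x W x 3 tile is cut into non-overlapping patches, linearly
# embedded, and processed by four stages of windowed multi-head
# self-attention blocks.  Between stages a patch-merging step halves the
# spatial resolution and doubles the channel count, so the stage outputs
# U1..U4 have shapes H/4 x W/4 x C, H/8 x W/8 x 2C, H/16 x W/16 x 4C and
# H/32 x W/32 x 8C.  Attention alternates between plain windows (W-MSA)
# and cyclically shifted windows (SW-MSA) whose additive mask forbids
# attention between tokens that were not contiguous before the shift.

#' Backbone hyper-parameters
#'
#' @param patch_size Patch side in pixels (default 4).
#' @param channels Base channel count C of stage 1 (default 96, the
#'   usual "tiny" transformer width).
#' @param depths Integer vector of block counts per stage (default
#'   `c(2, 2, 6, 2)`).  Blocks alternate W-MSA / SW-MSA; an odd depth
#'   ends with a lone W-MSA block.
#' @param window Attention window side M in tokens (default 7).
#' @param heads Heads per stage (default `c(3, 6, 12, 24)`); each
#'   stage's channel count must be divisible by its head count.
#' @param mlp_ratio Expansion factor of the per-token MLP (default 4).
#' @return A `swin_config` list.
#' @export
swin_config <- function(patch_size = 4L, channels = 96L,
                        depths = c(2L, 2L, 6L, 2L), window = 7L,
                        heads = c(3L, 6L, 12L, 24L), mlp_ratio = 4) {
  stopifnot(patch_size >= 1L, channels >= 1L, length(depths) == 4L,
            all(depths >= 1L), window >= 2L, length(heads) == 4L)
  ch <- channels * 2L^(0:3)
  if (any(ch %% heads != 0L)) {
    stop("stage channels must be divisible by the head counts")
  }
  structure(list(patch_size = as.integer(patch_size),
                 channels = as.integer(channels),
                 depths = as.integer(depths),
                 window = as.integer(window),
                 heads = as.integer(heads),
                 mlp_ratio = mlp_ratio),
            class = "swin_config")
}

#' Reduced backbone profile for CPU-scale experiments
#'
#' C = 24, window 4, depths (1, 1, 2, 1): the same architecture at a
#' size that trains in minutes on one core.
#' @export
swin_config_tiny <- function() {
  swin_config(patch_size = 4L, channels = 24L, depths = c(1L, 1L, 2L, 1L),
              window = 4L, heads = c(1L, 2L, 4L, 8L), mlp_ratio = 2)
}

stage_channels <- function(cfg) cfg$channels * 2L^(0:3)

rnorm_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialise backbone parameters
#'
#' Truncated-normal-style (sd 0.02) linear weights, unit layer-norm
#' gains, zero biases and a zero relative-position bias table per block.
#' Names are prefixed so backbone, neck and head parameters can live in
#' one flat list.
#' @param cfg A [swin_config()].
#' @param prefix Name prefix (default `"bb."`).
#' @return Named list of numeric arrays.
#' @export
swin_init_params <- function(cfg, prefix = "bb.") {
  P <- list()
  p2 <- cfg$patch_size^2 * 3L
  ch <- stage_channels(cfg)
  M <- cfg$window
  P[[paste0(prefix, "pe.W")]] <- rnorm_mat(p2, ch[1L])
  P[[paste0(prefix, "pe.b")]] <- numeric(ch[1L])
  P[[paste0(prefix, "pe.ln.g")]] <- rep(1, ch[1L])
  P[[paste0(prefix, "pe.ln.b")]] <- numeric(ch[1L])
  for (s in 1:4) {
    C <- ch[s]
    for (l in seq_len(cfg$depths[s])) {
      pb <- sprintf("%sst%d.bl%d.", prefix, s, l)
      P[[paste0(pb, "ln1.g")]] <- rep(1, C)
      P[[paste0(pb, "ln1.b")]] <- numeric(C)
      P[[paste0(pb, "qkv.W")]] <- rnorm_mat(C, 3L * C)
      P[[paste0(pb, "qkv.b")]] <- numeric(3L * C)
      P[[paste0(pb, "bias")]] <- matrix(0, (2L * M - 1L)^2, cfg$heads[s])
      P[[paste0(pb, "proj.W")]] <- rnorm_mat(C, C)
      P[[paste0(pb, "proj.b")]] <- numeric(C)
      P[[paste0(pb, "ln2.g")]] <- rep(1, C)
      P[[paste0(pb, "ln2.b")]] <- numeric(C)
      hid <- round(C * cfg$mlp_ratio)
      P[[paste0(pb, "mlp.W1")]] <- rnorm_mat(C, hid)
      P[[paste0(pb, "mlp.b1")]] <- numeric(hid)
      P[[paste0(pb, "mlp.W2")]] <- rnorm_mat(hid, C)
      P[[paste0(pb, "mlp.b2")]] <- numeric(C)
    }
    if (s < 4L) {
      pb <- sprintf("%smg%d.", prefix, s)
      P[[paste0(pb, "ln.g")]] <- rep(1, 4L * C)
      P[[paste0(pb, "ln.b")]] <- numeric(4L * C)
      P[[paste0(pb, "W")]] <- rnorm_mat(4L * C, 2L * C)
    }
  }
  P
}

# Wrap a flat parameter list as autodiff nodes (trainable or frozen).
bind_params <- function(P, trainable = TRUE) {
  lapply(P, if (trainable) ag_param else ag_const)
}

# Combined gather indices + masks for (shifted-)window attention on a
# possibly padded grid.  Memoised.
ix_attn <- function(h, w, M, shift) {
  key <- sprintf("attn_%d_%d_%d_%d", h, w, M, shift)
  ix_memo(key, function() {
    ph <- as.integer(ceiling(h / M) * M)
    pw <- as.integer(ceiling(w / M) * M)
    pad <- ix_pad(h, w, ph, pw)
    iw <- ix_window(ph, pw, M)
    if (shift > 0L) {
      sh <- ix_shift(ph, pw, shift)
      fwd_pos <- pad$pad[sh][iw$perm]       # windowed row -> original row (0 = pad)
    } else {
      fwd_pos <- pad$pad[iw$perm]
    }
    # reverse: original token t sits at windowed row bwd[t]
    bwd <- integer(h * w)
    bwd[fwd_pos[fwd_pos > 0L]] <- which(fwd_pos > 0L)
    # masks: invalid keys (padding) and, when shifted, region mismatches
    valid <- fwd_pos > 0L
    masks <- NULL
    need_valid_mask <- any(!valid)
    region_masks <- if (shift > 0L) ix_shift_masks(ph, pw, M, shift) else NULL
    if (need_valid_mask || !is.null(region_masks)) {
      masks <- lapply(seq_len(iw$nwin), function(wi) {
        rows <- ((wi - 1L) * iw$ntok + 1L):(wi * iw$ntok)
        m <- if (is.null(region_masks)) matrix(0, iw$ntok, iw$ntok) else region_masks[[wi]]
        if (need_valid_mask) {
          bad <- !valid[rows]
          if (any(bad)) m[, bad] <- -1e9
        }
        m
      })
    }
    list(fwd = fwd_pos, bwd = bwd, nwin = iw$nwin, ntok = iw$ntok,
         masks = masks)
  })
}

# One transformer block: x + proj(attn(LN(x))) then x + MLP(LN(x)).
swin_block_fwd <- function(x, h, w, P, pb, heads, M, shift, C) {
  ia <- ix_attn(h, w, M, shift)
  xn <- ag_layernorm(x, P[[paste0(pb, "ln1.g")]], P[[paste0(pb, "ln1.b")]])
  qkv <- ag_linear(xn, P[[paste0(pb, "qkv.W")]], P[[paste0(pb, "qkv.b")]])
  qkvw <- ag_rows(qkv, ia$fwd)
  q <- ag_cols(qkvw, 1:C)
  k <- ag_cols(qkvw, (C + 1L):(2L * C))
  v <- ag_cols(qkvw, (2L * C + 1L):(3L * C))
  att <- ag_attention(q, k, v, nwin = ia$nwin, heads = heads,
                      bias_tab = P[[paste0(pb, "bias")]],
                      rel_idx = ix_relpos(M), masks = ia$masks)
  att <- ag_rows(att, ia$bwd)
  x <- ag_add(x, ag_linear(att, P[[paste0(pb, "proj.W")]],
                           P[[paste0(pb, "proj.b")]]))
  xn <- ag_layernorm(x, P[[paste0(pb, "ln2.g")]], P[[paste0(pb, "ln2.b")]])
  hmid <- ag_gelu(ag_linear(xn, P[[paste0(pb, "mlp.W1")]],
                            P[[paste0(pb, "mlp.b1")]]))
  ag_add(x, ag_linear(hmid, P[[paste0(pb, "mlp.W2")]],
                      P[[paste0(pb, "mlp.b2")]]))
}

# Patch merging: gather 2x2 neighbourhoods, LN, linear 4c -> 2c.
patch_merge_fwd <- function(x, h, w, lng, lnb, W) {
  im <- ix_merge(h, w)
  cat4 <- ag_cbind(list(ag_rows(x, im$tl), ag_rows(x, im$tr),
                        ag_rows(x, im$bl), ag_rows(x, im$br)))
  ag_matmul(ag_layernorm(cat4, lng, lnb), W)
}

# Patch expanding: linear c -> 2c, rearrange channel quarters into a
# 2x2 spatial block; output (2h x 2w) x (c/2).
patch_expand_fwd <- function(x, h, w, W) {
  z <- ag_matmul(x, W)
  c2 <- ncol(z$val) %/% 4L
  qs <- lapply(0:3, function(q) ag_cols(z, (q * c2 + 1L):((q + 1L) * c2)))
  ag_rows(ag_rbind(qs), ix_expand(h, w))
}

# Full backbone forward on bound parameter nodes.
swin_backbone_fwd <- function(img, P, cfg, prefix = "bb.") {
  p <- cfg$patch_size
  H <- dim(img)[1L]
  W <- dim(img)[2L]
  stopifnot(H %% (p * 8L) == 0L, W %% (p * 8L) == 0L)
  tok <- matrix(as.vector(img)[as.vector(t(ix_patch(H, W, p)))],
                ncol = 3L * p * p, byrow = TRUE)
  x <- ag_linear(ag_const(tok), P[[paste0(prefix, "pe.W")]],
                 P[[paste0(prefix, "pe.b")]])
  x <- ag_layernorm(x, P[[paste0(prefix, "pe.ln.g")]],
                    P[[paste0(prefix, "pe.ln.b")]])
  h <- H %/% p
  w <- W %/% p
  ch <- stage_channels(cfg)
  M <- cfg$window
  out <- vector("list", 4L)
  for (s in 1:4) {
    for (l in seq_len(cfg$depths[s])) {
      shift <- if (l %% 2L == 0L) M %/% 2L else 0L
      x <- swin_block_fwd(x, h, w, P, sprintf("%sst%d.bl%d.", prefix, s, l),
                          cfg$heads[s], M, shift, ch[s])
    }
    out[[s]] <- list(node = x, h = h, w = w, stride = as.integer(p * 2^(s - 1)),
                     tag = paste0("U", s))
    if (s < 4L) {
      pb <- sprintf("%smg%d.", prefix, s)
      x <- patch_merge_fwd(x, h, w, P[[paste0(pb, "ln.g")]],
                           P[[paste0(pb, "ln.b")]], P[[paste0(pb, "W")]])
      h <- h %/% 2L
      w <- w %/% 2L
    }
  }
  names(out) <- paste0("U", 1:4)
  out
}

# ---- user-facing functional wrappers (inference, no tape) ------------------

#' Partition an image into flattened raw patches
#'
#' Cuts an H x W x 3 array into non-overlapping `patch_size` patches and
#' flattens each to a 3*patch_size^2 vector (dx fastest, then dy, then
#' channel) -- the token matrix fed to the linear embedding.
#' @param image Numeric H x W x 3 array.
#' @param patch_size Patch side in pixels.
#' @return list(values = tokens x (3 p^2) matrix, h, w, stride).
#' @export
patch_partition <- function(image, patch_size = 4L) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be H x W x 3")
  if (any(d[1:2] %% patch_size != 0L)) {
    ph <- ceiling(d[1L] / patch_size) * patch_size
    pw <- ceiling(d[2L] / patch_size) * patch_size
    padded <- array(0, c(ph, pw, 3L))
    padded[seq_len(d[1L]), seq_len(d[2L]), ] <- image
    image <- padded
    d <- dim(image)
  }
  tok <- matrix(as.vector(image)[as.vector(t(ix_patch(d[1L], d[2L], patch_size)))],
                ncol = 3L * patch_size^2, byrow = TRUE)
  list(values = tok, h = d[1L] %/% patch_size, w = d[2L] %/% patch_size,
       stride = patch_size)
}

#' Patch merging (downsample x2, channels x2)
#'
#' @param fm list(values, h, w) feature map with (h*w) x c values.
#' @param W Linear map 4c x 2c; `ln_g`, `ln_b` layer-norm parameters of
#'   length 4c (defaults: identity norm).
#' @param ln_g,ln_b Layer-norm gain/shift.
#' @return Merged feature map list(values, h, w).
#' @export
patch_merge <- function(fm, W, ln_g = NULL, ln_b = NULL) {
  c4 <- 4L * ncol(fm$values)
  if (is.null(ln_g)) ln_g <- rep(1, c4)
  if (is.null(ln_b)) ln_b <- numeric(c4)
  h <- fm$h
  w <- fm$w
  if (h %% 2L || w %% 2L) stop("h and w must be even (pad first)")
  y <- patch_merge_fwd(ag_const(fm$values), h, w, ag_const(ln_g),
                       ag_const(ln_b), ag_const(W))
  list(values = y$val, h = h %/% 2L, w = w %/% 2L)
}

#' Patch expanding (upsample x2, channels / 2)
#'
#' @param fm list(values, h, w); channel count must be even.
#' @param W Linear map c x 2c.
#' @return Expanded feature map list(values, h, w).
#' @export
patch_expand <- function(fm, W) {
  if (ncol(fm$values) %% 2L) stop("channel count must be even")
  y <- patch_expand_fwd(ag_const(fm$values), fm$h, fm$w, ag_const(W))
  list(values = y$val, h = 2L * fm$h, w = 2L * fm$w)
}

#' Window / shifted-window multi-head self-attention
#'
#' Functional form used by the oracle tests: runs (S)W-MSA on a feature
#' map with explicit q/k/v/projection weights.
#' @param fm list(values, h, w).
#' @param weights list(qkv.W, qkv.b, proj.W, proj.b, bias) as in
#'   [swin_init_params()].
#' @param M Window side; `heads` head count; `shift` cyclic shift
#'   (0 for W-MSA, typically M %/% 2 for SW-MSA).
#' @param heads,shift Head count and shift.
#' @return Feature map list(values, h, w) of the same shape.
#' @export
window_attention <- function(fm, weights, M, heads = 1L, shift = 0L) {
  C <- ncol(fm$values)
  ia <- ix_attn(fm$h, fm$w, M, as.integer(shift))
  x <- ag_const(fm$values)
  qkv <- ag_linear(x, ag_const(weights$qkv.W), ag_const(weights$qkv.b))
  qkvw <- ag_rows(qkv, ia$fwd)
  att <- ag_attention(ag_cols(qkvw, 1:C),
                      ag_cols(qkvw, (C + 1L):(2L * C)),
                      ag_cols(qkvw, (2L * C + 1L):(3L * C)),
                      nwin = ia$nwin, heads = heads,
                      bias_tab = if (!is.null(weights$bias)) ag_const(weights$bias),
                      rel_idx = ix_relpos(M), masks = ia$masks)
  y <- ag_linear(ag_rows(att, ia$bwd), ag_const(weights$proj.W),
                 ag_const(weights$proj.b))
  list(values = y$val, h = fm$h, w = fm$w)
}

#' @rdname window_attention
#' @export
shifted_window_attention <- function(fm, weights, M, heads = 1L,
                                     shift = M %/% 2L) {
  window_attention(fm, weights, M, heads, shift = shift)
}

#' Apply one transformer block (attention + MLP, both residual)
#'
#' @param fm list(values, h, w).
#' @param wts Named list with entries ln1.g, ln1.b, qkv.W, qkv.b, bias,
#'   proj.W, proj.b, ln2.g, ln2.b, mlp.W1, mlp.b1, mlp.W2, mlp.b2.
#' @param M,heads,shift Window side, head count, cyclic shift.
#' @return Feature map of the same shape.
#' @export
swin_block_apply <- function(fm, wts, M, heads = 1L, shift = 0L) {
  P <- bind_params(wts, trainable = FALSE)
  names(P) <- paste0("w.", names(P))
  y <- swin_block_fwd(ag_const(fm$values), fm$h, fm$w, P, "w.",
                      heads, M, as.integer(shift), ncol(fm$values))
  list(values = y$val, h = fm$h, w = fm$w)
}

#' Apply a W-MSA / SW-MSA block pair
#'
#' The canonical paired arrangement: a plain-window block followed by a
#' shifted-window block (shift M %/% 2).
#' @param fm list(values, h, w).
#' @param wts1,wts2 Weight lists for the two blocks (see
#'   [swin_block_apply()]).
#' @param M,heads Window side and head count.
#' @return Feature map of the same shape.
#' @export
swin_block_pair <- function(fm, wts1, wts2, M, heads = 1L) {
  swin_block_apply(swin_block_apply(fm, wts1, M, heads, shift = 0L),
                   wts2, M, heads, shift = M %/% 2L)
}

#' Run the backbone over an image
#'
#' @param image Numeric H x W x 3 array with H, W divisible by 32 (pad
#'   beforehand otherwise).
#' @param params Flat parameter list from [swin_init_params()].
#' @param cfg The matching [swin_config()].
#' @return Named list U1..U4 of list(values, h, w, stride, tag).
#' @export
run_backbone <- function(image, params, cfg) {
  P <- bind_params(params, trainable = FALSE)
  us <- swin_backbone_fwd(image, P, cfg)
  lapply(us, function(u) list(values = u$node$val, h = u$h, w = u$w,
                              stride = u$stride, tag = u$tag))
}

#' Window-attention operation count
#'
#' Closed-form cost of W-MSA on an h x w x C map with window M:
#' 4 h w C^2 + 2 M^2 h w C.
#' @param h,w,C,M Map height, width, channels; window side.
#' @return Numeric operation count.
#' @export
wmsa_cost <- function(h, w, C, M) 4 * h * w * C^2 + 2 * M^2 * h * w * C
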