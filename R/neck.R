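# Feature pyramid neck with balanced enhancement.
#
# The backbone stages U1..U4 are turned into a top-down pyramid: S4 is
# U4 passed through a transformer block; each lower level fuses a
# lateral transformer block of U_i with a patch-expanded (2x resolution,
# half channels) copy of the level above, and the sum is processed by a
# further block.  All levels are then projected to a common channel
# width D.  The balance-enhancement step resizes every level to the S2
# resolution (bilinear up for coarser levels, max-pool down for S1),
# averages them (each level contributes 1/L), refines the average with
# an embedded-Gaussian non-local block (attention across all spatial
# positions, similarity exp(theta(x_i)' phi(x_j))), and redistributes
# the refined map back onto every level by resize-and-add, giving
# P1..P4 for the detection head.

#' Neck hyper-parameters
#'
#' @param D Common channel width of the projected pyramid levels
#'   (default 256; the reduced test profile uses 32).
#' @param lateral_blocks Transformer blocks on each lateral path
#'   (default 1).
#' @param expand_blocks Blocks inside each patch-expand step, applied at
#'   the coarser resolution before the rearrangement (default 2).
#' @param fuse_blocks Blocks after each lateral + top-down fusion
#'   (default 1).
#' @return A `neck_config` list.
#' @export
neck_config <- function(D = 256L, lateral_blocks = 1L, expand_blocks = 2L,
                        fuse_blocks = 1L) {
  stopifnot(D >= 1L, D %% 2L == 0L)
  structure(list(D = as.integer(D),
                 lateral_blocks = as.integer(lateral_blocks),
                 expand_blocks = as.integer(expand_blocks),
                 fuse_blocks = as.integer(fuse_blocks)),
            class = "neck_config")
}

block_param_set <- function(P, prefix, C, M, heads, mlp_ratio) {
  P[[paste0(prefix, "ln1.g")]] <- rep(1, C)
  P[[paste0(prefix, "ln1.b")]] <- numeric(C)
  P[[paste0(prefix, "qkv.W")]] <- rnorm_mat(C, 3L * C)
  P[[paste0(prefix, "qkv.b")]] <- numeric(3L * C)
  P[[paste0(prefix, "bias")]] <- matrix(0, (2L * M - 1L)^2, heads)
  P[[paste0(prefix, "proj.W")]] <- rnorm_mat(C, C)
  P[[paste0(prefix, "proj.b")]] <- numeric(C)
  P[[paste0(prefix, "ln2.g")]] <- rep(1, C)
  P[[paste0(prefix, "ln2.b")]] <- numeric(C)
  hid <- round(C * mlp_ratio)
  P[[paste0(prefix, "mlp.W1")]] <- rnorm_mat(C, hid)
  P[[paste0(prefix, "mlp.b1")]] <- numeric(hid)
  P[[paste0(prefix, "mlp.W2")]] <- rnorm_mat(hid, C)
  P[[paste0(prefix, "mlp.b2")]] <- numeric(C)
  P
}

#' Initialise neck parameters
#'
#' @param cfg Backbone [swin_config()] (fixes per-level channel counts,
#'   window and head counts).
#' @param ncfg A [neck_config()].
#' @param prefix Name prefix (default `"nk."`).
#' @return Named list of numeric arrays.
#' @export
neck_init_params <- function(cfg, ncfg, prefix = "nk.") {
  P <- list()
  ch <- stage_channels(cfg)
  M <- cfg$window
  mr <- cfg$mlp_ratio
  for (k in seq_len(ncfg$fuse_blocks)) {
    P <- block_param_set(P, sprintf("%ss4blk.bl%d.", prefix, k), ch[4L], M,
                         cfg$heads[4L], mr)
  }
  for (i in 1:3) {
    for (k in seq_len(ncfg$lateral_blocks)) {
      P <- block_param_set(P, sprintf("%slat%d.bl%d.", prefix, i, k), ch[i], M,
                           cfg$heads[i], mr)
    }
    for (k in seq_len(ncfg$expand_blocks)) {
      P <- block_param_set(P, sprintf("%sexp%d.bl%d.", prefix, i, k), ch[i + 1L],
                           M, cfg$heads[i + 1L], mr)
    }
    P[[sprintf("%sexp%d.W", prefix, i)]] <- rnorm_mat(ch[i + 1L], 2L * ch[i + 1L])
    for (k in seq_len(ncfg$fuse_blocks)) {
      P <- block_param_set(P, sprintf("%sfuse%d.bl%d.", prefix, i, k), ch[i], M,
                           cfg$heads[i], mr)
    }
  }
  D <- ncfg$D
  for (i in 1:4) {
    P[[sprintf("%sproj%d.W", prefix, i)]] <- rnorm_mat(ch[i], D)
    P[[sprintf("%sproj%d.b", prefix, i)]] <- numeric(D)
  }
  D2 <- D %/% 2L
  P[[paste0(prefix, "nl.theta.W")]] <- rnorm_mat(D, D2)
  P[[paste0(prefix, "nl.phi.W")]] <- rnorm_mat(D, D2)
  P[[paste0(prefix, "nl.g.W")]] <- rnorm_mat(D, D2)
  P[[paste0(prefix, "nl.out.W")]] <- rnorm_mat(D2, D)
  P[[paste0(prefix, "nl.out.b")]] <- numeric(D)
  P
}

nk_block_seq <- function(x, h, w, P, prefix, nblocks, heads, M, C) {
  for (l in seq_len(nblocks)) {
    shift <- if (l %% 2L == 0L) M %/% 2L else 0L
    x <- swin_block_fwd(x, h, w, P, sprintf("%sbl%d.", prefix, l),
                        heads, M, shift, C)
  }
  x
}

# Resize a token-grid node to a target grid: max-pool down (integer
# factor), bilinear (half-pixel centres) up, identity when equal.
resize_node <- function(x, h, w, h2, w2) {
  if (h == h2 && w == w2) return(x)
  if (h > h2) {
    stopifnot(h %% h2 == 0L, w %% w2 == 0L, h %/% h2 == w %/% w2)
    return(ag_maxpool(x, h, w, h %/% h2))
  }
  ag_sparse_linear(mk_bilinear(h, w, h2, w2), x)
}

# S-pyramid on parameter nodes; returns list of levels with D channels.
neck_pyramid_fwd <- function(us, P, cfg, ncfg, prefix = "nk.") {
  ch <- stage_channels(cfg)
  M <- cfg$window
  S <- vector("list", 4L)
  s4 <- nk_block_seq(us[[4L]]$node, us[[4L]]$h, us[[4L]]$w, P,
                     paste0(prefix, "s4blk."), ncfg$fuse_blocks,
                     cfg$heads[4L], M, ch[4L])
  S[[4L]] <- list(node = s4, h = us[[4L]]$h, w = us[[4L]]$w,
                  stride = us[[4L]]$stride, tag = "S4")
  for (i in 3:1) {
    up <- S[[i + 1L]]
    top <- nk_block_seq(up$node, up$h, up$w, P, sprintf("%sexp%d.", prefix, i),
                        ncfg$expand_blocks, cfg$heads[i + 1L], M, ch[i + 1L])
    top <- patch_expand_fwd(top, up$h, up$w, P[[sprintf("%sexp%d.W", prefix, i)]])
    lat <- nk_block_seq(us[[i]]$node, us[[i]]$h, us[[i]]$w, P,
                        sprintf("%slat%d.", prefix, i), ncfg$lateral_blocks,
                        cfg$heads[i], M, ch[i])
    fused <- ag_add(lat, top)
    fused <- nk_block_seq(fused, us[[i]]$h, us[[i]]$w, P,
                          sprintf("%sfuse%d.", prefix, i), ncfg$fuse_blocks,
                          cfg$heads[i], M, ch[i])
    S[[i]] <- list(node = fused, h = us[[i]]$h, w = us[[i]]$w,
                   stride = us[[i]]$stride, tag = paste0("S", i))
  }
  for (i in 1:4) {
    S[[i]]$node <- ag_linear(S[[i]]$node, P[[sprintf("%sproj%d.W", prefix, i)]],
                             P[[sprintf("%sproj%d.b", prefix, i)]])
  }
  names(S) <- paste0("S", 1:4)
  S
}

balance_integrate_fwd <- function(S, ref = 2L) {
  L <- length(S)
  h2 <- S[[ref]]$h
  w2 <- S[[ref]]$w
  acc <- NULL
  for (i in seq_len(L)) {
    r <- resize_node(S[[i]]$node, S[[i]]$h, S[[i]]$w, h2, w2)
    acc <- if (is.null(acc)) r else ag_add(acc, r)
  }
  list(node = ag_scale(acc, 1 / L), h = h2, w = w2, stride = S[[ref]]$stride,
       tag = "balanced")
}

nonlocal_fwd <- function(x, P, prefix = "nk.nl.") {
  th <- ag_matmul(x, P[[paste0(prefix, "theta.W")]])
  ph <- ag_matmul(x, P[[paste0(prefix, "phi.W")]])
  g <- ag_matmul(x, P[[paste0(prefix, "g.W")]])
  d <- ncol(th$val)
  # embedded-Gaussian similarity has no 1/sqrt(d) factor: pre-scale the
  # query to cancel the attention op's internal scaling
  y <- ag_attention(ag_scale(th, sqrt(d)), ph, g, nwin = 1L, heads = 1L)
  ag_add(x, ag_linear(y, P[[paste0(prefix, "out.W")]],
                      P[[paste0(prefix, "out.b")]]))
}

redistribute_fwd <- function(balanced, S) {
  lapply(S, function(s) {
    r <- resize_node(balanced$node, balanced$h, balanced$w, s$h, s$w)
    list(node = ag_add(s$node, r), h = s$h, w = s$w, stride = s$stride,
         tag = sub("S", "P", s$tag))
  })
}

neck_fwd <- function(us, P, cfg, ncfg, prefix = "nk.") {
  S <- neck_pyramid_fwd(us, P, cfg, ncfg, prefix)
  bal <- balance_integrate_fwd(S)
  bal$node <- nonlocal_fwd(bal$node, P, paste0(prefix, "nl."))
  Pl <- redistribute_fwd(bal, S)
  names(Pl) <- paste0("P", 1:4)
  Pl
}

# ---- user-facing functional wrappers ---------------------------------------

fm_wrap <- function(x) list(node = ag_const(x$values), h = x$h, w = x$w,
                            stride = x$stride %||% NA_integer_, tag = x$tag %||% "")
fm_unwrap <- function(x) list(values = x$node$val, h = x$h, w = x$w,
                              stride = x$stride, tag = x$tag)

#' Build the projected top-down pyramid S1..S4
#'
#' @param us Named list U1..U4 as returned by [run_backbone()].
#' @param params Neck parameter list from [neck_init_params()].
#' @param cfg,ncfg Backbone and neck configurations.
#' @return Named list S1..S4, each list(values, h, w, stride, tag) with
#'   the common channel width `ncfg$D`.
#' @export
build_topdown_pyramid <- function(us, params, cfg, ncfg) {
  P <- bind_params(params, trainable = FALSE)
  S <- neck_pyramid_fwd(lapply(us, fm_wrap), P, cfg, ncfg)
  lapply(S, fm_unwrap)
}

#' Resize-and-average pyramid integration
#'
#' Every level is resized to the resolution of the reference level
#' (bilinear interpolation up, max pooling down) and the levels are
#' averaged with equal weight 1/L.
#' @param S Named list of pyramid levels (common channel count).
#' @param ref Reference level index (default 2).
#' @return list(values, h, w, stride, tag = "balanced").
#' @export
balance_integrate <- function(S, ref = 2L) {
  if (length(S) != 4L) stop("expected 4 pyramid levels, got ", length(S))
  fm_unwrap(balance_integrate_fwd(lapply(S, fm_wrap), ref))
}

#' Embedded-Gaussian non-local refinement
#'
#' Attention across all spatial positions with similarity
#' exp(theta(x_i)' phi(x_j)), softmax-normalised, value map g, output
#' projection and residual connection.
#' @param fm list(values, h, w, ...) balanced feature map.
#' @param nl list(theta.W, phi.W, g.W, out.W, out.b).
#' @return Refined feature map of the same shape.
#' @export
nonlocal_refine <- function(fm, nl) {
  P <- bind_params(nl, trainable = FALSE)
  names(P) <- paste0("nl.", names(P))
  y <- nonlocal_fwd(ag_const(fm$values), P, "nl.")
  out <- fm
  out$values <- y$val
  out
}

#' Redistribute the balanced map onto every pyramid level
#'
#' @param balanced Output of [balance_integrate()] (optionally refined).
#' @param S The pyramid levels the map is fused back onto.
#' @return Named list P1..P4.
#' @export
redistribute <- function(balanced, S) {
  out <- redistribute_fwd(fm_wrap(balanced), lapply(S, fm_wrap))
  out <- lapply(out, fm_unwrap)
  names(out) <- sub("^S", "P", names(S))
  out
}

#' Full neck: pyramid, balance, non-local refinement, redistribution
#'
#' @inheritParams build_topdown_pyramid
#' @return Named list P1..P4 of enhanced pyramid levels.
#' @export
run_neck <- function(us, params, cfg, ncfg) {
  P <- bind_params(params, trainable = FALSE)
  lapply(neck_fwd(lapply(us, fm_wrap), P, cfg, ncfg), fm_unwrap)
}
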