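# Synthetic UAV-like forest scenes.
#
# Tiles emulate nadir RGB imagery of closed canopy: a textured green
# background, live crowns as irregular green blobs, and standing dead
# trees as sparse gray-brown crowns built from a union of jittered disks
# with radial branch strokes (a defoliated crown skeleton).  Optional
# confusers -- discoloured live crowns and bare-soil patches whose
# colour is close to dead wood -- reproduce the error sources typical of
# real imagery.  Only dead crowns are annotated; boxes are the tight
# axis-aligned envelope of each crown's visible rendered support.

#' Synthetic scene configuration
#'
#' Defaults describe a 512 x 512 tile matching the field imagery the
#' generator emulates; [scene_config_easy()] is the reduced high-contrast
#' profile used for desk-scale training runs.
#'
#' @param image_size Tile side in pixels (>= 64).
#' @param n_dead Range (length-2) of dead-crown counts per scene.
#' @param n_live Range of live-crown counts.
#' @param crown_radius_small Radius range (px) of the small dead-crown
#'   population (boxes land under the 32 x 32 small-object threshold).
#' @param crown_radius_large Radius range of the large population.
#' @param small_fraction Probability a dead crown is drawn from the
#'   small population.
#' @param dead_color,live_color list(mean = RGB triple, sd = scalar):
#'   colour models (values in \[0, 1\]) for dead and live crowns.
#' @param confuser_rate Fraction of live crowns rendered discoloured,
#'   and the per-scene probability of a bare-soil patch.
#' @param overlap_prob Probability a dead crown is placed overlapping
#'   an existing one.
#' @param texture_noise Amplitude of the per-pixel background noise.
#' @param seed Scene seed (determinism contract: same seed, same scene).
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = 512L,
                         n_dead = c(1L, 4L), n_live = c(6L, 12L),
                         crown_radius_small = c(4, 9),
                         crown_radius_large = c(50, 70),
                         small_fraction = 0.3,
                         dead_color = list(mean = c(0.58, 0.47, 0.36), sd = 0.04),
                         live_color = list(mean = c(0.13, 0.35, 0.12), sd = 0.04),
                         confuser_rate = 0.3, overlap_prob = 0.15,
                         texture_noise = 0.03, seed = 1L) {
  stopifnot(image_size >= 64L, all(crown_radius_small > 0),
            all(crown_radius_large > 0),
            small_fraction >= 0, small_fraction <= 1,
            confuser_rate >= 0, confuser_rate <= 1,
            overlap_prob >= 0, overlap_prob <= 1)
  if (max(crown_radius_large) >= image_size / 2) {
    stop("crown radius exceeds half the image size")
  }
  structure(list(image_size = as.integer(image_size), n_dead = n_dead,
                 n_live = n_live, crown_radius_small = crown_radius_small,
                 crown_radius_large = crown_radius_large,
                 small_fraction = small_fraction, dead_color = dead_color,
                 live_color = live_color, confuser_rate = confuser_rate,
                 overlap_prob = overlap_prob, texture_noise = texture_noise,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' @rdname scene_config
#' @param ... Overrides passed on to [scene_config()].
#' @export
scene_config_easy <- function(image_size = 128L, ...) {
  defaults <- list(image_size = image_size, n_dead = c(2L, 4L),
                   n_live = c(4L, 8L), crown_radius_small = c(5, 9),
                   crown_radius_large = c(10, 16), small_fraction = 0.4,
                   dead_color = list(mean = c(0.72, 0.58, 0.45), sd = 0.02),
                   live_color = list(mean = c(0.10, 0.32, 0.10), sd = 0.03),
                   confuser_rate = 0, overlap_prob = 0, texture_noise = 0.02)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

rint <- function(rg) if (length(rg) == 1L) as.integer(rg) else
  sample(seq.int(rg[1L], rg[2L]), 1L)
runifr <- function(rg) stats::runif(1L, rg[1L], rg[2L])

# Irregular blob mask on the full grid: radius modulated by two angular
# harmonics.
blob_mask <- function(n, cx, cy, r, wobble = 0.25) {
  xs <- rep(seq_len(n), each = n)   # column (x) of each column-major entry
  ys <- rep(seq_len(n), times = n)  # row (y)
  dx <- xs - cx
  dy <- ys - cy
  th <- atan2(dy, dx)
  rr <- r * (1 + wobble * (0.6 * sin(2 * th + stats::runif(1, 0, 2 * pi)) +
                             0.4 * sin(5 * th + stats::runif(1, 0, 2 * pi))))
  matrix(sqrt(dx^2 + dy^2) <= rr, n, n)
}

# Dead crown: union of jittered disks plus radial branch strokes.
dead_crown_mask <- function(n, cx, cy, r) {
  m <- matrix(FALSE, n, n)
  xs <- rep(seq_len(n), each = n)   # column (x) of each column-major entry
  ys <- rep(seq_len(n), times = n)  # row (y)
  ndisk <- sample(3:7, 1L)
  for (k in seq_len(ndisk)) {
    ox <- cx + stats::runif(1, -0.45, 0.45) * r
    oy <- cy + stats::runif(1, -0.45, 0.45) * r
    rk <- stats::runif(1, 0.35, 0.7) * r
    m <- m | matrix((xs - ox)^2 + (ys - oy)^2 <= rk^2, n, n)
  }
  nbr <- sample(5:9, 1L)
  angs <- stats::runif(nbr, 0, 2 * pi)
  tt <- seq(0, 1, length.out = max(8L, ceiling(2.4 * r)))
  for (a in angs) {
    px <- round(cx + tt * 1.15 * r * cos(a))
    py <- round(cy + tt * 1.15 * r * sin(a))
    ok <- px >= 1 & px <= n & py >= 1 & py <= n
    m[cbind(py[ok], px[ok])] <- TRUE
    ok2 <- ok & py < n
    m[cbind(py[ok2] + 1L, px[ok2])] <- TRUE
  }
  m
}

paint <- function(img, mask, color, jitter = 0.02) {
  idx <- which(mask)
  if (length(idx) == 0L) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- pmin(pmax(color[ch] + stats::rnorm(length(idx), 0, jitter), 0), 1)
    img[, , ch] <- plane
  }
  img
}

#' Generate one synthetic forest scene
#'
#' Deterministic given `config$seed`.  Live crowns and confusers are
#' rendered but never annotated; each dead crown yields one annotation
#' box tight to its visible support, with a size class from the box
#' area (small < 32^2 px^2 < medium < 96^2 px^2 < large).
#' @param config A [scene_config()].
#' @return A `synthetic_scene`: list(tile = list(pixels, tile_id,
#'   source_id, center_coord), boxes = n x 4 matrix (x1, y1, x2, y2;
#'   0-based half-open), size_class = character vector, n_live,
#'   n_confuser).
#' @export
generate_scene <- function(config) {
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old))
  set.seed(config$seed)
  n <- config$image_size
  img <- array(0, c(n, n, 3L))
  # textured green background: base colour + two low-frequency waves +
  # white noise
  gx <- matrix(rep(seq_len(n), times = n), n, n)
  gy <- matrix(rep(seq_len(n), each = n), n, n)
  wave <- 0.5 * sin(2 * pi * gx / stats::runif(1, n / 3, n) +
                      stats::runif(1, 0, 6)) +
    0.5 * sin(2 * pi * gy / stats::runif(1, n / 4, n) + stats::runif(1, 0, 6))
  base <- config$live_color$mean * 0.85
  for (ch in 1:3) {
    img[, , ch] <- pmin(pmax(base[ch] * (1 + 0.15 * wave) +
                               stats::rnorm(n * n, 0, config$texture_noise), 0), 1)
  }
  n_conf_soil <- if (stats::runif(1) < config$confuser_rate) sample(1:2, 1L) else 0L
  for (k in seq_len(n_conf_soil)) {
    r <- stats::runif(1, 0.05, 0.12) * n
    m <- blob_mask(n, stats::runif(1, r, n - r), stats::runif(1, r, n - r), r, 0.4)
    img <- paint(img, m, c(0.55, 0.44, 0.30), 0.03)
  }
  n_live <- rint(config$n_live)
  n_confuser <- 0L
  for (k in seq_len(n_live)) {
    r <- stats::runif(1, 0.04, 0.10) * n
    cx <- stats::runif(1, 1, n)
    cy <- stats::runif(1, 1, n)
    discol <- stats::runif(1) < config$confuser_rate
    if (discol) n_confuser <- n_confuser + 1L
    col <- if (discol) c(0.45, 0.46, 0.20) else
      pmin(pmax(config$live_color$mean +
                  stats::rnorm(3, 0, config$live_color$sd), 0), 1)
    img <- paint(img, blob_mask(n, cx, cy, r), col, 0.025)
  }
  n_dead <- rint(config$n_dead)
  masks <- vector("list", n_dead)
  centers <- matrix(0, 0L, 2L)
  radii <- numeric(0)
  for (k in seq_len(n_dead)) {
    small <- stats::runif(1) < config$small_fraction
    r <- runifr(if (small) config$crown_radius_small else config$crown_radius_large)
    placed <- FALSE
    for (try in 1:25) {
      if (k > 1L && stats::runif(1) < config$overlap_prob) {
        j <- sample.int(k - 1L, 1L)
        cx <- centers[j, 1L] + stats::runif(1, -1, 1) * (radii[j] + r) * 0.7
        cy <- centers[j, 2L] + stats::runif(1, -1, 1) * (radii[j] + r) * 0.7
      } else {
        cx <- stats::runif(1, 1.3 * r, n - 1.3 * r)
        cy <- stats::runif(1, 1.3 * r, n - 1.3 * r)
      }
      cx <- min(max(cx, 1.3 * r), n - 1.3 * r)
      cy <- min(max(cy, 1.3 * r), n - 1.3 * r)
      clash <- FALSE
      if (k > 1L) {
        dd <- sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)
        clash <- any(dd < (radii + r) * 0.8)
      }
      if (!clash || stats::runif(1) < config$overlap_prob) {
        placed <- TRUE
        break
      }
    }
    if (!placed) next
    centers <- rbind(centers, c(cx, cy))
    radii <- c(radii, r)
    masks[[length(radii)]] <- dead_crown_mask(n, cx, cy, r)
  }
  masks <- masks[seq_along(radii)]
  col_dead <- function() pmin(pmax(config$dead_color$mean +
                                     stats::rnorm(3, 0, config$dead_color$sd), 0), 1)
  for (k in seq_along(masks)) img <- paint(img, masks[[k]], col_dead(), 0.02)
  # visible support: pixels of crown k not overwritten by a later crown
  boxes <- matrix(0, 0L, 4L)
  keep_cls <- character(0)
  for (k in seq_along(masks)) {
    vis <- masks[[k]]
    if (k < length(masks)) {
      for (j in seq.int(k + 1L, length(masks))) vis <- vis & !masks[[j]]
    }
    idx <- which(vis, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    # rows are y, cols are x; convert to 0-based half-open
    b <- c(min(idx[, 2L]) - 1L, min(idx[, 1L]) - 1L, max(idx[, 2L]), max(idx[, 1L]))
    boxes <- rbind(boxes, b)
    area <- (b[3] - b[1]) * (b[4] - b[2])
    keep_cls <- c(keep_cls, if (area < 32^2) "small" else
      if (area > 96^2) "large" else "medium")
  }
  rownames(boxes) <- NULL
  structure(list(
    tile = list(pixels = img, tile_id = sprintf("synth_%08d", config$seed),
                source_id = "synthetic", center_coord = c(n / 2, n / 2)),
    boxes = boxes, size_class = keep_cls,
    n_live = n_live, n_confuser = n_confuser
  ), class = "synthetic_scene")
}

# Deterministic per-scene seed fan-out from a master seed.
scene_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 16807) %% 2147483646 + 1)
}

#' Generate a synthetic dataset (scenes in memory, optionally on disk)
#'
#' @param config A [scene_config()]; the per-scene seed is derived
#'   deterministically from `config$seed` and the scene index.
#' @param n_scenes Number of scenes (>= 1).
#' @param out_dir Optional directory: writes `scene_*.png` tiles plus
#'   `annotations.json` (COCO).
#' @return list(scenes, coco, summary) where summary counts the
#'   realised small/medium/large annotations.
#' @export
generate_dataset <- function(config, n_scenes, out_dir = NULL) {
  stopifnot(n_scenes >= 1L)
  scenes <- lapply(seq_len(n_scenes), function(i) {
    cfg <- config
    cfg$seed <- scene_seed(config$seed, i)
    sc <- generate_scene(cfg)
    sc$tile$tile_id <- sprintf("scene_%04d", i)
    sc
  })
  images <- list()
  annotations <- list()
  aid <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    images[[i]] <- list(id = i, file_name = paste0(sc$tile$tile_id, ".png"),
                        width = config$image_size, height = config$image_size)
    if (nrow(sc$boxes) > 0L) {
      for (b in seq_len(nrow(sc$boxes))) {
        aid <- aid + 1L
        bx <- sc$boxes[b, ]
        annotations[[aid]] <- list(
          id = aid, image_id = i, category_id = 1L,
          bbox = c(bx[1], bx[2], bx[3] - bx[1], bx[4] - bx[2]),
          area = (bx[3] - bx[1]) * (bx[4] - bx[2]), iscrowd = 0L)
      }
    }
  }
  coco <- list(images = images, annotations = annotations,
               categories = list(list(id = 1L, name = "sdt")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sc in scenes) {
      write_image(sc$tile$pixels,
                  file.path(out_dir, paste0(sc$tile$tile_id, ".png")))
    }
    write_coco(coco, file.path(out_dir, "annotations.json"))
  }
  cls <- unlist(lapply(scenes, function(s) s$size_class))
  summary <- c(small = sum(cls == "small"), medium = sum(cls == "medium"),
               large = sum(cls == "large"))
  list(scenes = scenes, coco = coco, summary = summary)
}
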