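# Imagery and annotation I/O.
#
# Conventions: images are H x W x 3 arrays in [0, 1]; boxes are
# (x1, y1, x2, y2), 0-based half-open, pixel units; COCO output uses the
# standard (x, y, w, h) bbox.  PNG and TIFF are supported; an optional
# geotransform (origin + pixel size) converts tile centres to
# geographic coordinates.

#' Read an image file as an H x W x 3 array in \[0, 1\]
#'
#' PNG and (Geo)TIFF pixel data are supported; extra channels beyond the
#' first three (e.g. alpha) are dropped, single-channel images are
#' replicated to three channels.
#' @param path Image path.
#' @return Numeric H x W x 3 array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an H x W x 3 array to PNG
#' @param img Numeric array with values in \[0, 1\]; `path` output file.
#' @param path Output path (.png).
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
}

#' Crop an orthomosaic into non-overlapping tiles
#'
#' Grid tiling of the largest tileable region; residual margins smaller
#' than one tile are dropped.  Each tile records the centre pixel
#' coordinate of its crop in mosaic coordinates (and, when a
#' geotransform is supplied, in geographic coordinates).
#' @param mosaic H x W x C array (C >= 3; extra channels dropped).
#' @param tile_size Tile side in pixels (>= 32, default 512).
#' @param source_id Identifier stored on every tile.
#' @param geotransform Optional list(origin_x, origin_y, px_x, px_y):
#'   geographic position of pixel (0, 0) and per-pixel step.
#' @return List of tiles: list(pixels, tile_id, source_id, center_coord,
#'   center_geo?).  A mosaic smaller than one tile gives an empty list
#'   with a warning.
#' @export
tile_orthomosaic <- function(mosaic, tile_size = 512L, source_id = "mosaic",
                             geotransform = NULL) {
  stopifnot(tile_size >= 32L)
  d <- dim(mosaic)
  if (length(d) != 3L || d[3L] < 3L) stop("mosaic must have >= 3 channels")
  if (d[3L] > 3L) mosaic <- mosaic[, , 1:3, drop = FALSE]
  nr <- d[1L] %/% tile_size
  nc <- d[2L] %/% tile_size
  if (nr == 0L || nc == 0L) {
    warning("mosaic smaller than one tile; no tiles produced")
    return(list())
  }
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      rows <- ((i - 1L) * tile_size + 1L):(i * tile_size)
      cols <- ((j - 1L) * tile_size + 1L):(j * tile_size)
      center <- c((j - 1L) * tile_size + tile_size / 2,
                  (i - 1L) * tile_size + tile_size / 2)
      tl <- list(pixels = mosaic[rows, cols, , drop = FALSE],
                 tile_id = sprintf("%s_r%03d_c%03d", source_id, i, j),
                 source_id = source_id, center_coord = center)
      if (!is.null(geotransform)) {
        tl$center_geo <- c(geotransform$origin_x + center[1L] * geotransform$px_x,
                           geotransform$origin_y + center[2L] * geotransform$px_y)
      }
      tiles[[k]] <- tl
    }
  }
  tiles
}

#' Re-stitch a tile grid into one array
#'
#' Inverse of [tile_orthomosaic()] over the covered region (used to
#' check that tiling is lossless).
#' @param tiles List of tiles with `pixels` and `center_coord`.
#' @return H x W x 3 array covering the tiled region.
#' @export
stitch_tiles <- function(tiles) {
  stopifnot(length(tiles) > 0L)
  ts <- dim(tiles[[1L]]$pixels)[1L]
  cx <- vapply(tiles, function(t) t$center_coord[1L], 0)
  cy <- vapply(tiles, function(t) t$center_coord[2L], 0)
  W <- max(cx) + ts / 2
  H <- max(cy) + ts / 2
  out <- array(0, c(H, W, 3L))
  for (t in tiles) {
    r0 <- t$center_coord[2L] - ts / 2
    c0 <- t$center_coord[1L] - ts / 2
    out[(r0 + 1):(r0 + ts), (c0 + 1):(c0 + ts), ] <- t$pixels
  }
  out
}

# ---- Labelme -> COCO -------------------------------------------------------

#' Convert Labelme-style records to a COCO annotation document
#'
#' Each record: list(image_path, height, width, shapes) with shapes
#' list(label, points = n x 2 matrix, shape_type).  Rectangles use their
#' two corner points; polygons their axis-aligned envelope.  Shapes with
#' fewer than two points are rejected and reported.
#' @param records List of Labelme-style records.
#' @return list(coco = COCO document, errors = data.frame(record,
#'   shape, reason)).
#' @export
convert_labelme_to_coco <- function(records) {
  images <- list()
  annotations <- list()
  errors <- list()
  aid <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    images[[i]] <- list(id = i, file_name = basename(rec$image_path),
                        width = rec$width, height = rec$height)
    for (s in seq_along(rec$shapes)) {
      sh <- rec$shapes[[s]]
      pts <- sh$points
      if (!is.matrix(pts)) pts <- do.call(rbind, pts)
      if (NROW(pts) < 2L) {
        errors[[length(errors) + 1L]] <-
          data.frame(record = i, shape = s, reason = "fewer than 2 points")
        next
      }
      x1 <- min(pts[, 1L]); x2 <- max(pts[, 1L])
      y1 <- min(pts[, 2L]); y2 <- max(pts[, 2L])
      aid <- aid + 1L
      annotations[[aid]] <- list(id = aid, image_id = i, category_id = 1L,
                                 bbox = c(x1, y1, x2 - x1, y2 - y1),
                                 area = (x2 - x1) * (y2 - y1), iscrowd = 0L)
    }
  }
  list(coco = list(images = images, annotations = annotations,
                   categories = list(list(id = 1L, name = "sdt"))),
       errors = if (length(errors)) do.call(rbind, errors) else
         data.frame(record = integer(0), shape = integer(0),
                    reason = character(0)))
}

#' Write / read a COCO annotation document
#' @param coco COCO list (images, annotations, categories).
#' @param path JSON path.
#' @export
write_coco <- function(coco, path) {
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @export
read_coco <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# ---- augmentation ----------------------------------------------------------

flip_h_img <- function(a) a[, dim(a)[2L]:1L, , drop = FALSE]
flip_v_img <- function(a) a[dim(a)[1L]:1L, , , drop = FALSE]
rot_cw_img <- function(a) aperm(a, c(2L, 1L, 3L))[, dim(a)[1L]:1L, , drop = FALSE]

flip_h_box <- function(b, W, H) cbind(W - b[, 3L], b[, 2L], W - b[, 1L], b[, 4L])
flip_v_box <- function(b, W, H) cbind(b[, 1L], H - b[, 4L], b[, 3L], H - b[, 2L])
rot_cw_box <- function(b, W, H) cbind(H - b[, 4L], b[, 1L], H - b[, 2L], b[, 3L])

#' Exact box remap under flips and 90-degree rotations
#'
#' hflip sends (x1, y1, x2, y2) to (W - x2, y1, W - x1, y2); vflip
#' mirrors y; "rot90" applies `k` clockwise quarter turns (the image
#' dimensions swap on odd `k`).
#' @param box Length-4 or n x 4 boxes; `op` one of "hflip", "vflip",
#'   "rot90"; `width`, `height` the image size the boxes live on.
#' @param op,width,height,k Operation, image size, rotation count.
#' @return Remapped boxes (same shape as input).
#' @export
remap_box <- function(box, op, width, height, k = 1L) {
  b <- if (is.matrix(box)) box else matrix(box, ncol = 4L)
  out <- switch(op,
    hflip = flip_h_box(b, width, height),
    vflip = flip_v_box(b, width, height),
    rot90 = {
      cw <- width; ch <- height
      for (i in seq_len(k)) {
        b <- rot_cw_box(b, cw, ch)
        tmp <- cw; cw <- ch; ch <- tmp
      }
      b
    },
    stop("unknown augmentation op: ", op))
  if (is.matrix(box)) out else as.numeric(out)
}

#' Geometry-preserving dataset augmentation
#'
#' Expands tiles and boxes by horizontal flip, vertical flip and random
#' k * 90-degree rotation, with exact box remaps.  Augmented copies
#' carry provenance (`source_tile`) and ids `<tile_id>_<op>`.
#' @param tiles List of tiles (list(pixels, tile_id, ...)).
#' @param annotations data.frame(tile_id, x1, y1, x2, y2).
#' @param ops Subset of c("hflip", "vflip", "rot90k").
#' @param seed Seed for the random rotation count.
#' @return list(tiles, annotations) containing originals plus one
#'   augmented copy per tile per op.
#' @export
augment_dataset <- function(tiles, annotations,
                            ops = c("hflip", "vflip", "rot90k"), seed = 1L) {
  bad <- setdiff(ops, c("hflip", "vflip", "rot90k"))
  if (length(bad)) stop("unknown augmentation op: ", paste(bad, collapse = ", "))
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old))
  set.seed(seed)
  out_tiles <- tiles
  out_ann <- annotations
  for (tl in tiles) {
    d <- dim(tl$pixels)
    H <- d[1L]; W <- d[2L]
    ann <- annotations[annotations$tile_id == tl$tile_id, , drop = FALSE]
    bx <- as.matrix(ann[, c("x1", "y1", "x2", "y2")])
    for (op in ops) {
      k <- if (op == "rot90k") sample(1:3, 1L) else 1L
      img <- tl$pixels
      b <- bx
      cw <- W; ch <- H
      if (op == "hflip") {
        img <- flip_h_img(img)
        if (nrow(b)) b <- flip_h_box(b, W, H)
      } else if (op == "vflip") {
        img <- flip_v_img(img)
        if (nrow(b)) b <- flip_v_box(b, W, H)
      } else {
        for (r in seq_len(k)) {
          img <- rot_cw_img(img)
          if (nrow(b)) b <- rot_cw_box(b, cw, ch)
          tmp <- cw; cw <- ch; ch <- tmp
        }
      }
      nid <- paste0(tl$tile_id, "_", op)
      nt <- tl
      nt$pixels <- img
      nt$tile_id <- nid
      nt$source_tile <- tl$tile_id
      out_tiles[[length(out_tiles) + 1L]] <- nt
      if (nrow(b)) {
        out_ann <- rbind(out_ann,
                         data.frame(tile_id = nid, x1 = b[, 1L], y1 = b[, 2L],
                                    x2 = b[, 3L], y2 = b[, 4L]))
      }
    }
  }
  list(tiles = out_tiles, annotations = out_ann)
}

# ---- splits and manifests --------------------------------------------------

#' Deterministic train/validation/test split
#'
#' Source tiles are permuted by the seed and allocated
#' floor(n * f_train) / floor(n * f_val) / remainder.  Augmented copies
#' (identified through `source_of`) inherit their source tile's split,
#' except that augmented copies of test tiles are excluded entirely
#' (the test split is never augmented).
#' @param tile_ids Character vector of tile ids.
#' @param fractions Length-3 proportions summing to 1 (default
#'   0.7 / 0.1 / 0.2).
#' @param seed Permutation seed.
#' @param source_of Optional named character vector mapping an
#'   augmented tile id to its source tile id.
#' @return Named character vector tile_id -> "train" | "val" | "test";
#'   excluded augmented-of-test ids are reported in
#'   `attr(, "excluded")`.
#' @export
split_dataset <- function(tile_ids, fractions = c(0.7, 0.1, 0.2), seed = 1L,
                          source_of = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  src_ids <- setdiff(tile_ids, names(source_of))
  n <- length(src_ids)
  if (n < 3L) {
    warning("fewer source tiles than splits; assigning all to train")
    asg <- stats::setNames(rep("train", length(tile_ids)), tile_ids)
    attr(asg, "excluded") <- character(0)
    return(asg)
  }
  old <- .Random.seed__save()
  on.exit(.Random.seed__restore(old))
  set.seed(seed)
  perm <- sample(src_ids)
  n_tr <- floor(n * fractions[1L])
  n_va <- floor(n * fractions[2L])
  split <- stats::setNames(c(rep("train", n_tr), rep("val", n_va),
                             rep("test", n - n_tr - n_va)), perm)
  excluded <- character(0)
  out <- character(0)
  for (id in tile_ids) {
    src <- if (!is.null(source_of) && id %in% names(source_of))
      source_of[[id]] else id
    s <- split[[src]]
    if (!identical(id, src) && s == "test") {
      excluded <- c(excluded, id)
    } else {
      out[id] <- s
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Dataset manifest
#'
#' @param per_site_image_counts,per_site_label_counts Non-negative
#'   integer vectors (one entry per acquisition site).
#' @param split_fractions Length-3 proportions; `split_assignment` a
#'   tile_id -> split vector from [split_dataset()].
#' @param split_assignment Split assignment vector.
#' @return A `dataset_manifest` list.
#' @export
create_manifest <- function(per_site_image_counts, per_site_label_counts,
                            split_fractions = c(0.7, 0.1, 0.2),
                            split_assignment = character(0)) {
  structure(list(per_site_image_counts = per_site_image_counts,
                 per_site_label_counts = per_site_label_counts,
                 split_fractions = split_fractions,
                 split_assignment = as.list(split_assignment)),
            class = "dataset_manifest")
}

#' Totals of a dataset manifest
#'
#' @param manifest A [create_manifest()] result (or compatible list).
#' @return list(images, labels): exact sums of the per-site counts.
#' @export
summarize_manifest <- function(manifest) {
  ic <- manifest$per_site_image_counts
  lc <- manifest$per_site_label_counts
  if (any(ic < 0) || any(lc < 0)) stop("negative count in manifest")
  list(images = sum(ic), labels = sum(lc))
}

#' Write / read a manifest as YAML
#' @param manifest A manifest; `path` YAML file path.
#' @param path YAML path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  structure(m, class = "dataset_manifest")
}
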