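# Training: AdamW with linear learning-rate decay, gradient
# accumulation over the batch, periodic dynamic-state updates and early
# stopping on the validation loss.

#' Training hyper-parameters
#'
#' @param lr Initial learning rate (default 1e-4, decayed linearly to 0
#'   across `epochs`).
#' @param batch_size Images per optimiser step (default 4); gradients
#'   are averaged over the batch.
#' @param epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 20).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param beta1,beta2,eps Adam moment coefficients and denominator
#'   floor.
#' @param val_fraction Fraction of the training scenes held out for the
#'   validation loss when no explicit validation set is given
#'   (default 0.1).
#' @param seed Seed for shuffling and sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 4L, epochs = 100L,
                         patience = 20L, weight_decay = 0.01,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         val_fraction = 0.1, seed = 1L) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 eps = eps, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, st, lr, tc) {
  st$t <- st$t + 1L
  bc1 <- 1 - tc$beta1^st$t
  bc2 <- 1 - tc$beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- tc$beta1 * st$m[[nm]] + (1 - tc$beta1) * g
    st$v[[nm]] <- tc$beta2 * st$v[[nm]] + (1 - tc$beta2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + tc$eps)
    params[[nm]] <- params[[nm]] - lr * (upd + tc$weight_decay * params[[nm]])
  }
  list(params = params, st = st)
}

#' Train a snag detector
#'
#' The classic fitting entry point: takes a list of training scenes
#' (each `list(pixels = H x W x 3 array in [0, 1], boxes = n x 4
#' matrix)`), runs mini-batch AdamW over the combined RPN + RoI loss
#' with dynamic IoU-threshold assignment and dynamic smooth-L1, and
#' returns a fitted `snag_model`.
#'
#' @param scenes Training scenes (see above); [as_training_scenes()]
#'   converts synthetic scenes and COCO datasets.
#' @param model A `snag_model` to start from (default: fresh
#'   [snag_model()] with the supplied configurations).
#' @param tc A [train_config()].
#' @param val_scenes Optional explicit validation scenes; otherwise
#'   `tc$val_fraction` of `scenes` is held out.
#' @param verbose Print one line per epoch.
#' @return The fitted `snag_model`, with `$log` (one row per optimiser
#'   step: losses, `T_now`, `beta_now`, learning rate), `$val_trace`
#'   and `$epochs_run` filled in.
#' @export
snag_train <- function(scenes, model = snag_model(), tc = train_config(),
                       val_scenes = NULL, verbose = FALSE) {
  if (length(scenes) == 0L) stop("empty training split")
  if (!is.null(scenes[[1L]]$tile)) scenes <- as_training_scenes(scenes)
  if (!is.null(val_scenes) && length(val_scenes) > 0L &&
      !is.null(val_scenes[[1L]]$tile)) {
    val_scenes <- as_training_scenes(val_scenes)
  }
  set.seed(tc$seed)
  if (is.null(val_scenes)) {
    nval <- max(1L, floor(length(scenes) * tc$val_fraction))
    if (length(scenes) > nval) {
      vi <- sample.int(length(scenes), nval)
      val_scenes <- scenes[vi]
      scenes <- scenes[-vi]
    } else {
      val_scenes <- scenes
    }
  }
  params <- model$params
  dyn <- model$dyn
  opt <- adamw_init(params)
  log_rows <- list()
  val_trace <- numeric(0)
  best_val <- Inf
  best_params <- params
  best_dyn <- dyn
  since_best <- 0L
  it <- 0L
  for (ep in seq_len(tc$epochs)) {
    lr_ep <- tc$lr * (1 - (ep - 1) / tc$epochs)
    ord <- sample.int(length(scenes))
    bstarts <- seq(1L, length(ord), by = tc$batch_size)
    for (bs in bstarts) {
      bidx <- ord[bs:min(bs + tc$batch_size - 1L, length(ord))]
      grads <- NULL
      parts_acc <- c(rpn_obj = 0, rpn_reg = 0, roi_cls = 0, roi_reg = 0)
      iou_stats <- numeric(0)
      err_stats <- numeric(0)
      for (bi in bidx) {
        sc <- scenes[[bi]]
        ag_tape_start()
        P <- bind_params(params, trainable = TRUE)
        l <- image_loss_fwd(sc$pixels, sc$boxes, P, model$cfg, dyn)
        ag_backward(ag_scale(l$total, 1 / length(bidx)))
        ag_tape_stop()
        g <- lapply(P, function(p) p$grad)
        grads <- if (is.null(grads)) g else {
          mapply(function(a, b) {
            if (is.null(a)) b else if (is.null(b)) a else a + b
          }, grads, g, SIMPLIFY = FALSE)
        }
        parts_acc <- parts_acc + l$parts / length(bidx)
        iou_stats <- c(iou_stats, l$iou_stat)
        err_stats <- c(err_stats, l$reg_errors)
      }
      res <- adamw_step(params, grads, opt, lr_ep, tc)
      params <- res$params
      opt <- res$st
      dyn <- record_dynamic_stats(dyn, iou_stats, err_stats)
      it <- it + 1L
      if (dyn$iter %% dyn$interval == 0L && dyn$iter > 0L) {
        dyn <- update_dynamic_state(dyn)
      }
      log_rows[[it]] <- data.frame(epoch = ep, iter = it,
                                   loss = sum(parts_acc),
                                   rpn_obj = parts_acc[["rpn_obj"]],
                                   rpn_reg = parts_acc[["rpn_reg"]],
                                   roi_cls = parts_acc[["roi_cls"]],
                                   roi_reg = parts_acc[["roi_reg"]],
                                   T_now = dyn$T_now,
                                   beta_now = dyn$beta_now, lr = lr_ep)
    }
    vl <- dataset_loss(val_scenes, params, model$cfg, dyn)
    val_trace <- c(val_trace, vl)
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %.4f  T_now %.3f  beta %.3f",
                      ep, sum(parts_acc), vl, dyn$T_now, dyn$beta_now))
    }
    if (vl < best_val - 1e-6) {
      best_val <- vl
      best_params <- params
      best_dyn <- dyn
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= tc$patience) break
    }
    model$epochs_run <- ep
  }
  model$params <- best_params
  model$dyn <- best_dyn
  model$log <- do.call(rbind, log_rows)
  model$val_trace <- val_trace
  model$best_val <- best_val
  model
}

#' Convert synthetic scenes or a COCO dataset to training scenes
#'
#' @param x A list of `synthetic_scene` objects, or a COCO annotation
#'   list (from [read_coco()]) together with `image_dir`.
#' @param image_dir Directory holding the COCO images (PNG).
#' @return List of `list(pixels, boxes)` training scenes.
#' @export
as_training_scenes <- function(x, image_dir = NULL) {
  if (length(x) > 0L && !is.null(x[[1L]]$tile)) {
    return(lapply(x, function(sc) {
      list(pixels = sc$tile$pixels, boxes = sc$boxes)
    }))
  }
  stopifnot(!is.null(x$images), !is.null(image_dir))
  lapply(x$images, function(im) {
    pix <- read_image(file.path(image_dir, im$file_name))
    anns <- Filter(function(a) a$image_id == im$id, x$annotations)
    boxes <- if (length(anns) > 0L) {
      do.call(rbind, lapply(anns, function(a) {
        bb <- as.numeric(unlist(a$bbox))
        c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4])
      }))
    } else matrix(0, 0L, 4L)
    list(pixels = pix, boxes = boxes)
  })
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.snag_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0))
  cat("Snag detector (shifted-window attention backbone + balanced pyramid)\n")
  cat(sprintf("  backbone: C=%d depths=(%s) window=%d\n",
              x$cfg$swin$channels, paste(x$cfg$swin$depths, collapse = ","),
              x$cfg$swin$window))
  cat(sprintf("  neck: D=%d   parameters: %s\n", x$cfg$neck$D,
              format(np, big.mark = ",")))
  cat(sprintf("  dynamic state: T_now=%.3f beta_now=%.3f\n",
              x$dyn$T_now, x$dyn$beta_now))
  if (!is.null(x$log)) {
    cat(sprintf("  trained: %d steps, %d epochs, best val loss %.4f\n",
                nrow(x$log), x$epochs_run, x$best_val))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
summary.snag_model <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("\nLoss components (last 5 steps):\n")
    print(utils::tail(object$log[, c("iter", "loss", "rpn_obj", "rpn_reg",
                                     "roi_cls", "roi_reg", "T_now",
                                     "beta_now")], 5L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.snag_model <- function(object, ...) {
  unlist(object$params, use.names = TRUE)
}

#' Predict method: run detection on one image or a list of images
#' @param object A fitted `snag_model`.
#' @param newdata An H x W x 3 array or a list of such arrays (or
#'   training scenes with `$pixels`).
#' @param ... Passed to [detect()] (`score_thr`, `nms_thr`).
#' @return A detections data.frame, or a list of them.
#' @export
predict.snag_model <- function(object, newdata, ...) {
  one <- function(im) {
    if (is.list(im) && !is.null(im$pixels)) im <- im$pixels
    detect(im, object, ...)
  }
  if (is.list(newdata) && !is.array(newdata)) lapply(newdata, one)
  else one(newdata)
}

#' Plot the training trace (loss and dynamic parameters)
#' @param x A fitted `snag_model`; `...` ignored.
#' @param ... Unused.
#' @export
plot.snag_model <- function(x, ...) {
  if (is.null(x$log)) stop("model has no training log")
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$log$iter, x$log$loss, type = "l", xlab = "step",
                 ylab = "training loss")
  graphics::plot(x$log$iter, x$log$T_now, type = "l", col = "forestgreen",
                 ylim = range(c(x$log$T_now, x$log$beta_now)),
                 xlab = "step", ylab = "dynamic parameters")
  graphics::lines(x$log$iter, x$log$beta_now, col = "firebrick")
  graphics::legend("topright", legend = c("T_now", "beta_now"),
                   col = c("forestgreen", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
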