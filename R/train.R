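# ---------------------------------------------------------------------------
# Desk-scale training loop: SGD with momentum, linear warm-up and decay,
# per-epoch validation metrics and early stopping.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the study protocol: 200 epochs with patience 50, batch 8,
#' SGD with lr0 = 0.01 decaying linearly to lr0*lrf, momentum 0.937, weight
#' decay 5e-4, 3 warm-up epochs, mosaic augmentation available but disabled
#' by default (`close_mosaic` controls how many final epochs run without it
#' when it is enabled).
#'
#' @param epochs,patience,batch,workers,close_mosaic counts.
#' @param lr0,lrf,momentum,weight_decay,warmup_epochs scalars.
#' @param optimizer optimiser name (`"SGD"`).
#' @param seed RNG seed controlling init, data order and augmentation draws.
#' @param mosaic enable online mosaic augmentation.
#' @param eval_every validate every this many epochs.
#' @return list of class `wb_train_config`.
#' @export
train_config <- function(epochs = 200, patience = 50, batch = 8, workers = 8,
                         close_mosaic = 10, lr0 = 0.01, lrf = 0.01,
                         momentum = 0.937, weight_decay = 5e-4,
                         warmup_epochs = 3.0, optimizer = "SGD", seed = 0,
                         mosaic = FALSE, eval_every = 1) {
  if (optimizer != "SGD") stop("invalid config: only SGD is implemented")
  structure(as.list(environment()), class = "wb_train_config")
}

# flat-tree SGD-with-momentum state and update
sgd_step <- function(model, grads, state, lr, momentum, wd) {
  for (i in seq_along(model$nodes)) {
    g <- grads[[i]]
    if (is.null(g)) next
    key0 <- paste0("n", i, "/")
    model$nodes[[i]]$mod <- map_params(model$nodes[[i]]$mod, g,
      function(p, gp, key) {
        if (is.null(gp)) return(p)
        full <- paste0(key0, key)
        decay <- if (endsWith(full, "/w") || endsWith(full, "w")) wd else 0
        gv <- gp + decay * p
        v <- state$v[[full]]
        v <- if (is.null(v)) gv else momentum * v + gv
        state$v[[full]] <- v
        p - lr * v
      })
  }
  model
}

# assemble a batch: input array and pixel-space targets
make_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(length(samples), 3, d[1], d[2]))
  targets <- list()
  for (i in seq_along(samples)) {
    x[i, , , ] <- image_to_input(samples[[i]]$image)[1, , , ]
    targets[[i]] <- labels_to_pixel_boxes(samples[[i]]$labels, d[1], d[2])
  }
  list(x = x, targets = targets)
}

# 2x2 mosaic of four samples at the original resolution
mosaic_sample <- function(samples) {
  d <- dim(samples[[1]]$image)
  h <- d[1]; w <- d[2]
  out <- array(0L, d)
  labs <- list()
  half <- function(img) img[seq(1, dim(img)[1], by = 2),
                            seq(1, dim(img)[2], by = 2), , drop = FALSE]
  offs <- list(c(0, 0), c(0, w %/% 2), c(h %/% 2, 0), c(h %/% 2, w %/% 2))
  for (k in 1:4) {
    sm <- samples[[k]]
    hi <- half(sm$image)
    oh <- offs[[k]][1]; ow <- offs[[k]][2]
    out[oh + seq_len(dim(hi)[1]), ow + seq_len(dim(hi)[2]), ] <- hi
    if (nrow(sm$labels) > 0) {
      l <- sm$labels
      labs[[k]] <- data.frame(class_id = l$class_id,
                              cx = l$cx / 2 + ow / w, cy = l$cy / 2 + oh / h,
                              w = l$w / 2, h = l$h / 2)
    }
  }
  labels <- if (length(labs) > 0) do.call(rbind, labs) else empty_labels()
  image_sample(out, labels, paste0(samples[[1]]$id, "_mosaic"))
}

#' Train a detector
#'
#' Optimises the composite detection loss (CIoU box + distribution-focal +
#' binary cross-entropy with task-aligned assignment) with SGD, recording
#' per-epoch loss and validation precision/recall/mAP, and stopping early
#' when mAP@0.5 has not improved for `patience` epochs.
#'
#' @param model a built model.
#' @param train_set,val_set lists of `wb_sample` (all images one size,
#'   divisible by 32).
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights by val mAP@0.5), `history`
#'   (data frame of per-epoch metrics), `epochs_run`.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        verbose = TRUE) {
  stopifnot(inherits(cfg, "wb_train_config"))
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("invalid input: datasets must be non-empty")
  for (s in train_set) validate_labels(s$labels)
  set.seed(cfg$seed)
  state <- new.env(parent = emptyenv())
  state$v <- list()
  nb <- ceiling(length(train_set) / cfg$batch)
  warmup_iters <- max(1, round(cfg$warmup_epochs * nb))
  it <- 0
  hist <- NULL
  best_map <- -Inf
  best_model <- model
  stale <- 0
  epochs_run <- 0
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(train_set))
    ep_loss <- 0
    use_mosaic <- isTRUE(cfg$mosaic) && ep <= cfg$epochs - cfg$close_mosaic
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * cfg$batch + 1):min(bi * cfg$batch,
                                                length(train_set))]
      batch <- train_set[idx]
      if (use_mosaic && length(batch) >= 4)
        batch[[1]] <- mosaic_sample(batch[sample(seq_along(batch), 4)])
      mb <- make_batch(batch)
      fw <- model_forward(model, mb$x, train = TRUE)
      model <- fw$model
      ls <- detection_loss(fw$levels, mb$targets, strides = model$strides,
                           reg_max = model$cfg$reg_max %||% 16,
                           nc = model$cfg$num_classes)
      bw <- model_backward(model, fw, ls$glevels)
      it <- it + 1
      lf <- (1 - (ep - 1) / cfg$epochs) * (1 - cfg$lrf) + cfg$lrf
      lr <- cfg$lr0 * lf * min(1, it / warmup_iters)
      model <- sgd_step(model, bw$grads, state, lr, cfg$momentum,
                        cfg$weight_decay)
      ep_loss <- ep_loss + ls$loss
      rm(fw, bw)
    }
    ep_loss <- ep_loss / nb
    row <- data.frame(epoch = ep, loss = ep_loss, precision = NA_real_,
                      recall = NA_real_, map50 = NA_real_,
                      map5095 = NA_real_)
    if (ep %% cfg$eval_every == 0 || ep == cfg$epochs) {
      ev <- evaluate_dataset(model, val_set)
      row$precision <- ev$precision
      row$recall <- ev$recall
      row$map50 <- ev$map50
      row$map5095 <- ev$map5095
      if (!is.na(ev$map50) && ev$map50 > best_map + 1e-9) {
        best_map <- ev$map50
        best_model <- model
        stale <- 0
      } else stale <- stale + cfg$eval_every
    }
    hist <- rbind(hist, row)
    epochs_run <- ep
    if (verbose)
      message(sprintf(
        "epoch %d/%d loss %.4f map50 %s", ep, cfg$epochs, ep_loss,
        ifelse(is.na(row$map50), "-", sprintf("%.3f", row$map50))))
    if (stale >= cfg$patience) break
  }
  list(model = best_model, history = hist, epochs_run = epochs_run,
       best_map50 = best_map)
}
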