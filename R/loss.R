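# ---------------------------------------------------------------------------
# Composite anchor-free detection loss: task-aligned assignment, complete-IoU
# box regression, distribution-focal regression and binary cross-entropy
# classification.  This is the baseline detector's standard convention; the
# gradients are hand-derived (the assignment is treated as constant, and the
# CIoU aspect-ratio trade-off coefficient is detached, as is standard).
# ---------------------------------------------------------------------------

# vectorised CIoU between rows of pred and target [n, 4] (xyxy)
ciou_terms <- function(p, t) {
  eps <- 1e-9
  pw <- p[, 3] - p[, 1]; ph <- p[, 4] - p[, 2]
  tw <- t[, 3] - t[, 1]; th <- t[, 4] - t[, 2]
  ix1 <- pmax(p[, 1], t[, 1]); iy1 <- pmax(p[, 2], t[, 2])
  ix2 <- pmin(p[, 3], t[, 3]); iy2 <- pmin(p[, 4], t[, 4])
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  union <- pw * ph + tw * th - inter + eps
  iou <- inter / union
  cw <- pmax(p[, 3], t[, 3]) - pmin(p[, 1], t[, 1])
  ch <- pmax(p[, 4], t[, 4]) - pmin(p[, 2], t[, 2])
  c2 <- cw^2 + ch^2 + eps
  rho2 <- ((p[, 1] + p[, 3] - t[, 1] - t[, 3])^2 +
           (p[, 2] + p[, 4] - t[, 2] - t[, 4])^2) / 4
  q <- atan(tw / pmax(th, eps)) - atan(pw / pmax(ph, eps))
  v <- (4 / pi^2) * q^2
  alpha <- v / (1 - iou + v + eps)
  list(iou = iou, ciou = iou - rho2 / c2 - alpha * v,
       pw = pw, ph = ph, tw = tw, th = th, iw = iw, ih = ih,
       inter = inter, union = union, cw = cw, ch = ch, c2 = c2,
       rho2 = rho2, q = q, v = v, alpha = alpha)
}

# gradient of (1 - ciou) w.r.t. pred coordinates; returns [n, 4]
ciou_grad <- function(p, t, tm) {
  eps <- 1e-9
  n <- nrow(p)
  g <- matrix(0, n, 4)
  pos <- tm$inter > 0
  # d inter / d coord
  dI <- matrix(0, n, 4)
  dI[, 1] <- ifelse(pos & p[, 1] > t[, 1], -tm$ih, 0)
  dI[, 2] <- ifelse(pos & p[, 2] > t[, 2], -tm$iw, 0)
  dI[, 3] <- ifelse(pos & p[, 3] < t[, 3], tm$ih, 0)
  dI[, 4] <- ifelse(pos & p[, 4] < t[, 4], tm$iw, 0)
  # d area_p / d coord
  dA <- cbind(-tm$ph, -tm$pw, tm$ph, tm$pw)
  for (k in 1:4) {
    dU <- dA[, k] - dI[, k]
    dIoU <- (dI[, k] * tm$union - tm$inter * dU) / tm$union^2
    # rho2 term
    drho <- if (k %in% c(1, 3)) (p[, 1] + p[, 3] - t[, 1] - t[, 3]) / 2
            else (p[, 2] + p[, 4] - t[, 2] - t[, 4]) / 2
    dc2 <- switch(k,
                  ifelse(p[, 1] < t[, 1], -2 * tm$cw, 0),
                  ifelse(p[, 2] < t[, 2], -2 * tm$ch, 0),
                  ifelse(p[, 3] > t[, 3], 2 * tm$cw, 0),
                  ifelse(p[, 4] > t[, 4], 2 * tm$ch, 0))
    dpen <- (drho * tm$c2 - tm$rho2 * dc2) / tm$c2^2
    # aspect term (alpha detached)
    denom <- tm$pw^2 + tm$ph^2 + eps
    dv <- switch(k,
                 (8 / pi^2) * tm$q * (tm$ph / denom),        # d pw = -1
                 (8 / pi^2) * tm$q * (-tm$pw / denom),       # d ph = -1
                 (8 / pi^2) * tm$q * (-tm$ph / denom),       # d pw = +1
                 (8 / pi^2) * tm$q * (tm$pw / denom))        # d ph = +1
    g[, k] <- -(dIoU - dpen - tm$alpha * dv)
  }
  g
}

# task-aligned assignment for one sample
tal_assign <- function(pred_scores, pred_boxes, anchors, gt_boxes, gt_labels,
                       topk = 10, alpha = 0.5, beta = 6.0) {
  A <- nrow(anchors)
  M <- nrow(gt_boxes)
  out <- list(fg = logical(A), gt_idx = integer(A),
              target_scores = matrix(0, A, ncol(pred_scores)))
  if (M == 0) return(out)
  inside <- matrix(FALSE, A, M)
  iou_m <- matrix(0, A, M)
  for (j in seq_len(M)) {
    b <- gt_boxes[j, ]
    inside[, j] <- anchors[, 1] > b[1] & anchors[, 1] < b[3] &
      anchors[, 2] > b[2] & anchors[, 2] < b[4]
    iou_m[, j] <- iou_one_many(b, pred_boxes)
  }
  metric <- matrix(0, A, M)
  for (j in seq_len(M)) {
    sc <- pred_scores[, gt_labels[j] + 1L]
    metric[, j] <- (sc^alpha) * (pmax(iou_m[, j], 0)^beta) * inside[, j]
  }
  # top-k candidates per gt
  cand <- matrix(FALSE, A, M)
  for (j in seq_len(M)) {
    pos <- which(metric[, j] > 0)
    if (length(pos) == 0) next
    ord <- pos[order(-metric[pos, j])]
    cand[utils::head(ord, topk), j] <- TRUE
  }
  # resolve anchors claimed by several gts: keep the highest-IoU gt
  assigned <- rep(0L, A)
  for (a in which(rowSums(cand) > 0)) {
    js <- which(cand[a, ])
    assigned[a] <- js[which.max(iou_m[a, js])]
  }
  fg <- assigned > 0
  # normalised target scores
  ts <- matrix(0, A, ncol(pred_scores))
  for (j in seq_len(M)) {
    aj <- which(assigned == j)
    if (length(aj) == 0) next
    mmax <- max(metric[aj, j])
    imax <- max(iou_m[aj, j])
    val <- if (mmax > 0) metric[aj, j] / mmax * imax else rep(0, length(aj))
    ts[cbind(aj, rep(gt_labels[j] + 1L, length(aj)))] <- val
  }
  list(fg = fg, gt_idx = assigned, target_scores = ts)
}

# assemble per-level matrices for one sample
level_to_mat <- function(y, n, ch) {
  d <- dim(y)
  a <- y[n, ch, , , drop = FALSE]
  matrix(aperm(a, c(3, 4, 2, 1)), nrow = d[3] * d[4])
}

mat_to_level <- function(m, h, w) {
  a <- array(m, c(h, w, ncol(m), 1))
  aperm(a, c(4, 3, 1, 2))
}

#' Detection loss and its gradient
#'
#' @param levels per-level raw prediction maps from
#'   `model_forward(..., train = TRUE)$levels`.
#' @param targets list (length = batch) of pixel ground-truth data frames
#'   with columns `x1, y1, x2, y2, class_id`.
#' @param strides per-level strides.
#' @param reg_max distribution bins.
#' @param nc classes.
#' @param w_box,w_cls,w_dfl loss term weights.
#' @param assignments optional per-sample assignment list from a previous
#'   call, to evaluate the loss under a frozen assignment (the assignment is
#'   always treated as a constant by the gradient).
#' @return list with `loss` (total), components, `glevels` (gradients
#'   shaped like `levels`) and `assignments`.
#' @export
detection_loss <- function(levels, targets, strides = c(8, 16, 32),
                           reg_max = 16, nc = 1,
                           w_box = 7.5, w_cls = 0.5, w_dfl = 1.5,
                           assignments = NULL) {
  nlev <- length(levels)
  N <- dim(levels[[1]])[1]
  hw <- lapply(levels, function(y) dim(y)[3:4])
  A_per <- vapply(hw, prod, 0)
  A <- sum(A_per)
  anchors <- NULL
  stride_vec <- NULL
  for (l in seq_len(nlev)) {
    anchors <- rbind(anchors, anchor_points(hw[[l]][1], hw[[l]][2], strides[l]))
    stride_vec <- c(stride_vec, rep(strides[l], A_per[l]))
  }
  glevels <- lapply(levels, function(y) array(0, dim(y)))
  asn_out <- vector("list", N)
  loss_box <- 0; loss_cls <- 0; loss_dfl <- 0
  for (n in seq_len(N)) {
    dist_mat <- NULL; cls_mat <- NULL
    for (l in seq_len(nlev)) {
      dm <- level_to_mat(levels[[l]], n, seq_len(4 * reg_max))
      cm <- level_to_mat(levels[[l]], n, 4 * reg_max + seq_len(nc))
      dist_mat <- rbind(dist_mat, dm)
      cls_mat <- rbind(cls_mat, cm)
    }
    # softmax expectation per side, all anchors at once
    dl <- array(t(dist_mat), c(reg_max, 4, A))   # bin fastest
    dm2 <- matrix(dl, nrow = reg_max)
    cm2 <- dm2[1, ]
    for (r in seq_len(reg_max)[-1]) cm2 <- pmax(cm2, dm2[r, ])
    e <- exp(dm2 - rep(cm2, each = reg_max))
    ssum <- colSums(e)
    pmat <- e / rep(ssum, each = reg_max)        # [reg_max, 4*A]
    expect <- colSums(pmat * (0:(reg_max - 1)))  # [4*A], side fastest
    ex <- matrix(expect, nrow = 4)               # [4, A]
    pred_boxes <- cbind(anchors[, 1] - ex[1, ] * stride_vec,
                        anchors[, 2] - ex[2, ] * stride_vec,
                        anchors[, 1] + ex[3, ] * stride_vec,
                        anchors[, 2] + ex[4, ] * stride_vec)
    pred_sig <- 1 / (1 + exp(-cls_mat))
    tg <- targets[[n]]
    gtb <- as.matrix(tg[, c("x1", "y1", "x2", "y2"), drop = FALSE])
    gtl <- if (nrow(tg) > 0) tg$class_id else integer(0)
    asn <- if (!is.null(assignments)) assignments[[n]]
           else tal_assign(pred_sig, pred_boxes, anchors, gtb, gtl)
    asn_out[[n]] <- asn
    ts <- asn$target_scores
    tss <- max(sum(ts), 1)
    # classification: BCE over all anchors/classes
    lcls <- -(ts * log(pred_sig + 1e-12) +
                (1 - ts) * log(1 - pred_sig + 1e-12))
    loss_cls <- loss_cls + sum(lcls) / tss
    g_cls <- (pred_sig - ts) / tss * w_cls
    g_dist <- matrix(0, A, 4 * reg_max)
    fg <- which(asn$fg)
    if (length(fg) > 0) {
      wgt <- rowSums(ts)[fg]
      tb <- gtb[asn$gt_idx[fg], , drop = FALSE]
      # grid-unit boxes for the regression terms
      pb_g <- pred_boxes[fg, , drop = FALSE] / stride_vec[fg]
      tb_g <- tb / stride_vec[fg]
      tm <- ciou_terms(pb_g, tb_g)
      loss_box <- loss_box + sum((1 - tm$ciou) * wgt) / tss
      gci <- ciou_grad(pb_g, tb_g, tm) * (wgt / tss) * w_box
      # chain to ltrb expectations: x1 = ax - lt_x etc. (grid units)
      g_ex <- cbind(-gci[, 1], -gci[, 2], gci[, 3], gci[, 4])
      # distribution-focal term
      ax_g <- anchors[fg, , drop = FALSE] / stride_vec[fg]
      ltrb <- cbind(ax_g[, 1] - tb_g[, 1], ax_g[, 2] - tb_g[, 2],
                    tb_g[, 3] - ax_g[, 1], tb_g[, 4] - ax_g[, 2])
      ltrb <- pmin(pmax(ltrb, 0), reg_max - 1 - 0.01)
      lo <- floor(ltrb)
      hi <- lo + 1
      wl <- hi - ltrb
      wh <- ltrb - lo
      for (side in 1:4) {
        cols <- (side - 1) * reg_max + seq_len(reg_max)
        z <- dist_mat[fg, cols, drop = FALSE]
        zm <- apply(z, 1, max)
        ez <- exp(z - zm)
        pz <- ez / rowSums(ez)
        exps <- as.numeric(pz %*% (0:(reg_max - 1)))
        # dfl cross-entropy on the two adjacent bins
        pl <- pz[cbind(seq_len(nrow(pz)), lo[, side] + 1L)]
        ph_ <- pz[cbind(seq_len(nrow(pz)), hi[, side] + 1L)]
        loss_dfl <- loss_dfl +
          sum((-wl[, side] * log(pl + 1e-12) -
                 wh[, side] * log(ph_ + 1e-12)) * wgt) / (4 * tss)
        tgt <- matrix(0, nrow(pz), reg_max)
        tgt[cbind(seq_len(nrow(pz)), lo[, side] + 1L)] <- wl[, side]
        tgt[cbind(seq_len(nrow(pz)), hi[, side] + 1L)] <-
          tgt[cbind(seq_len(nrow(pz)), hi[, side] + 1L)] + wh[, side]
        g_dfl <- (pz - tgt) * (wgt / (4 * tss)) * w_dfl
        # box-loss path through the softmax expectation
        g_exp <- g_ex[, side]
        bins <- matrix(0:(reg_max - 1), nrow(pz), reg_max, byrow = TRUE)
        g_soft <- pz * (bins - exps) * g_exp
        g_dist[fg, cols] <- g_dist[fg, cols] + g_dfl + g_soft
      }
    }
    # scatter gradients back into the level arrays
    at <- 0
    for (l in seq_len(nlev)) {
      idx <- at + seq_len(A_per[l])
      h <- hw[[l]][1]; w <- hw[[l]][2]
      gl <- mat_to_level(cbind(g_dist[idx, , drop = FALSE],
                               g_cls[idx, , drop = FALSE]), h, w)
      glevels[[l]][n, , , ] <- glevels[[l]][n, , , ] + gl[1, , , ]
      at <- at + A_per[l]
    }
  }
  total <- (w_box * loss_box + w_cls * loss_cls + w_dfl * loss_dfl) / N
  for (l in seq_len(nlev)) glevels[[l]] <- glevels[[l]] / N
  list(loss = total, box = loss_box / N, cls = loss_cls / N,
       dfl = loss_dfl / N, glevels = glevels, assignments = asn_out)
}
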