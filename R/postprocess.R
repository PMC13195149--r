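# ---------------------------------------------------------------------------
# Detection decoding and non-maximum suppression.
# ---------------------------------------------------------------------------

#' Intersection over union of two boxes
#'
#' @param a,b boxes as `c(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("invalid input: degenerate box")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# vectorised IoU of one box against a matrix of boxes [n, 4]
iou_one_many <- function(a, B) {
  iw <- pmax(0, pmin(a[3], B[, 3]) - pmax(a[1], B[, 1]))
  ih <- pmax(0, pmin(a[4], B[, 4]) - pmax(a[2], B[, 2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Construct a detection record
#'
#' @param box numeric `c(x1, y1, x2, y2)` in pixels.
#' @param score confidence in `[0, 1]`.
#' @param class_id zero-based class index.
#' @return A one-row data frame.
#' @export
detection <- function(box, score, class_id = 0L) {
  if (box[3] <= box[1] || box[4] <= box[2])
    stop("invalid input: box must satisfy x2 > x1, y2 > y1")
  if (score < 0 || score > 1) stop("invalid input: score must be in [0,1]")
  data.frame(x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4],
             score = score, class_id = as.integer(class_id))
}

empty_detections <- function()
  data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
             y2 = numeric(0), score = numeric(0), class_id = integer(0))

# greedy per-class NMS on a detection data frame
nms_detections <- function(det, iou_thresh) {
  if (nrow(det) == 0) return(det)
  keep <- logical(nrow(det))
  for (cl in unique(det$class_id)) {
    idx <- which(det$class_id == cl)
    idx <- idx[order(-det$score[idx])]
    while (length(idx) > 0) {
      i <- idx[1]
      keep[i] <- TRUE
      idx <- idx[-1]
      if (length(idx) > 0) {
        B <- as.matrix(det[idx, c("x1", "y1", "x2", "y2")])
        ious <- iou_one_many(as.numeric(det[i, c("x1", "y1", "x2", "y2")]), B)
        idx <- idx[ious <= iou_thresh]
      }
    }
  }
  out <- det[keep, , drop = FALSE]
  out[order(-out$score), , drop = FALSE]
}

#' Decode raw predictions and apply non-maximum suppression
#'
#' Boxes are decoded from the distribution-focal expectation at every anchor,
#' candidates below `conf_thresh` are dropped, and greedy per-class NMS keeps
#' the highest-scoring box among mutually overlapping ones.
#'
#' @param raw list of per-level raw prediction maps (one sample, i.e.
#'   `model_forward()$levels` with batch size 1, or pick one sample).
#' @param conf_thresh confidence threshold in `[0, 1]`.
#' @param iou_thresh NMS IoU threshold in `[0, 1]`.
#' @param strides per-level strides.
#' @param reg_max number of distribution bins.
#' @param nc number of classes.
#' @param n sample index within the batch.
#' @return A detection data frame sorted by descending score.
#' @export
decode_and_nms <- function(raw, conf_thresh = 0.25, iou_thresh = 0.45,
                           strides = c(8, 16, 32), reg_max = 16, nc = 1,
                           n = 1) {
  if (conf_thresh < 0 || conf_thresh > 1 || iou_thresh < 0 || iou_thresh > 1)
    stop("invalid config: thresholds must be in [0,1]")
  dec <- decode_raw(raw, strides, reg_max, nc, n)
  best_cl <- max.col(dec$scores) - 1L
  best_sc <- dec$scores[cbind(seq_len(nrow(dec$scores)), best_cl + 1L)]
  sel <- which(best_sc >= conf_thresh &
                 dec$boxes[, 3] > dec$boxes[, 1] &
                 dec$boxes[, 4] > dec$boxes[, 2])
  if (length(sel) == 0) return(empty_detections())
  det <- data.frame(x1 = dec$boxes[sel, 1], y1 = dec$boxes[sel, 2],
                    x2 = dec$boxes[sel, 3], y2 = dec$boxes[sel, 4],
                    score = best_sc[sel], class_id = best_cl[sel])
  nms_detections(det, iou_thresh)
}
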