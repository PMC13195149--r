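# ---------------------------------------------------------------------------
# Functional operator surface over the low-level kernels.
# ---------------------------------------------------------------------------

check_feature_map <- function(x) {
  if (!is.numeric(x) || length(dim(x)) != 4)
    stop("invalid input: a feature map must be a 4-D numeric array [N, C, H, W]")
  if (any(!is.finite(x))) stop("invalid input: feature map must be finite")
  invisible(x)
}

#' Expand a feature map into receptive-field space
#'
#' Every k x k sliding window (zero-padded outside the image) becomes a
#' column of the output: the result has dimensions `[N, C*k^2, H', W']` with
#' `H' = floor((H + 2*pad - k)/stride) + 1`, and is viewable as
#' `[N, C, k, k, H', W']` (channel index varying fastest within each window
#' block).
#'
#' @param x feature map `[N, C, H, W]`.
#' @param k odd window size.
#' @param stride sampling step.
#' @param pad zero-padding width.
#' @return The receptive-field tensor with attributes `k`, `stride`, `pad`.
#' @export
expand_to_receptive_field <- function(x, k, stride = 1, pad = k %/% 2) {
  check_feature_map(x)
  if (k < 1 || stride < 1 || k %% 2 != 1)
    stop("invalid config: k must be odd positive and stride positive")
  if (pad < 0) stop("invalid config: pad must be >= 0")
  y <- cpp_rf_expand(x, as.integer(k), as.integer(stride), as.integer(pad))
  attr(y, "k") <- k
  attr(y, "stride") <- stride
  attr(y, "pad") <- pad
  y
}

#' Directional receptive-field attention map
#'
#' Computes the coordinate-attention weights of an RFCA block for a given
#' expanded receptive-field map: horizontal and vertical average pooling,
#' shared squeeze, and two sigmoid branches.  Weights are strictly in (0, 1)
#' and broadcast onto the expanded map.
#'
#' @param block an RFCA block created by [new_rfca_conv()].
#' @param e expanded receptive-field map `[N, C, kH', kW']` (the tiled
#'   layout produced inside the block).
#' @return list with `a_h` (`[N, C, kH', 1]`) and `a_w` (`[N, C, 1, kW']`).
#' @export
rfca_attention <- function(block, e) {
  stopifnot(inherits(block, "wb_rfca"))
  check_feature_map(e)
  if (dim(e)[2] != block$cfg$c1)
    stop("invalid config: channel mismatch with configured block")
  at <- rfca_attention_fw(block, e, train = FALSE)
  list(a_h = at$ah, a_w = aperm(at$awt, c(1, 2, 4, 3)))
}

#' Predict CARAFE reassembly kernels
#'
#' Runs the kernel-prediction branch of a CARAFE block: channel compression
#' to Cm, content encoding to `sigma^2 * Kup^2` coefficients per source
#' position, pixel-shuffle to the up-sampled grid and per-position softmax
#' over the `Kup^2` taps.
#'
#' @param block a CARAFE block created by [new_carafe()].
#' @param x feature map `[N, C, H, W]`.
#' @return Kernel field `[N, Kup^2, sigma*H, sigma*W]`; the `Kup^2` weights
#'   at every output position are non-negative and sum to one.
#' @export
carafe_predict_kernels <- function(block, x) {
  stopifnot(inherits(block, "wb_carafe"))
  check_feature_map(x)
  if (dim(x)[2] != block$cfg$c)
    stop("invalid config: channel mismatch with configured block")
  r1 <- mod_fw(block$sub$comp, x, FALSE)
  r2 <- mod_fw(block$sub$enc, r1$y, FALSE)
  softmax_k(carafe_shuffle(r2$y, block$cfg$kup^2, block$cfg$sigma))
}

#' Content-aware feature reassembly
#'
#' Computes `Y(l) = sum_{j in N(l)} w_l(j) X(j)` where `N(l)` is the
#' `K_up x K_up` neighbourhood of the source position of output location
#' `l`, and the kernel `w_l` is shared by all channels at that location.
#'
#' @param x feature map `[N, C, H, W]`.
#' @param kernels kernel field `[N, K_up^2, sigma*H, sigma*W]`.
#' @param sigma integer up-sampling ratio.
#' @param kup odd reassembly kernel size.
#' @return Up-sampled feature map `[N, C, sigma*H, sigma*W]`.
#' @export
carafe_reassemble <- function(x, kernels, sigma, kup) {
  check_feature_map(x)
  if (length(dim(kernels)) != 4)
    stop("invalid input: kernel field must be 4-D")
  cpp_carafe_fw(x, kernels, as.integer(sigma), as.integer(kup))
}

#' Apply a single RFCA convolution
#'
#' Convenience wrapper: builds an RFCA block (weights drawn from the current
#' RNG state) and applies it in inference mode.
#'
#' @param x feature map `[N, C, H, W]`.
#' @param out_channels output channels.
#' @param k window size; `stride` sampling step.
#' @param stride sampling step.
#' @return Feature map `[N, out_channels, ceil(H/stride), ceil(W/stride)]`.
#' @export
rfca_conv <- function(x, out_channels, k = 3, stride = 1) {
  check_feature_map(x)
  blk <- new_rfca_conv(dim(x)[2], out_channels, k = k, stride = stride)
  mod_fw(blk, x, FALSE)$y
}

#' Apply large separable kernel attention
#'
#' @param x feature map `[N, C, H, W]`.
#' @param K large-kernel size; `d` dilation of the decomposition.
#' @param d dilation.
#' @return Feature map of the same shape, `x` multiplied by its attention.
#' @export
lska <- function(x, K = 7, d = 2) {
  check_feature_map(x)
  blk <- new_lska(dim(x)[2], K, d)
  mod_fw(blk, x, FALSE)$y
}
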