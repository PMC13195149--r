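# ---------------------------------------------------------------------------
# Detector assembly: baseline backbone/neck/head plus the four flagged
# substitutions (RFCA backbone, SPPF-LSKA, BiFPN-P2 neck, CARAFE up-sampling).
# ---------------------------------------------------------------------------

#' Variant flags for the detector
#'
#' Each flag swaps one architectural component relative to the unmodified
#' baseline: `use_rfca` replaces the backbone stage-transition convolutions
#' and C2f blocks with their receptive-field coordinate-attention versions;
#' `use_sppf_lska` adds large separable kernel attention to the spatial
#' pyramid pooling stage; `use_bifpn_p2` replaces the PAN neck with a
#' P2-augmented bidirectional feature pyramid; `use_carafe` replaces
#' nearest-neighbour up-sampling in the neck with content-aware reassembly.
#' All 16 combinations are legal.
#'
#' @param use_rfca,use_sppf_lska,use_bifpn_p2,use_carafe logical flags.
#' @return An object of class `wb_variant_flags`.
#' @export
variant_flags <- function(use_rfca = FALSE, use_sppf_lska = FALSE,
                          use_bifpn_p2 = FALSE, use_carafe = FALSE) {
  structure(list(use_rfca = isTRUE(use_rfca),
                 use_sppf_lska = isTRUE(use_sppf_lska),
                 use_bifpn_p2 = isTRUE(use_bifpn_p2),
                 use_carafe = isTRUE(use_carafe)),
            class = "wb_variant_flags")
}

#' Block hyper-parameters
#'
#' Defaults are the configuration used throughout: receptive-field window
#' k = 3; coordinate-attention reduction 2 with a floor of 8 channels; LSKA
#' decomposition K = 7, d = 2; CARAFE compressed channels Cm = 60, encoder
#' kernel 3, reassembly kernel 5, up-sampling ratio 2.
#'
#' @param k receptive-field window size (odd).
#' @param rfca_reduction,rfca_floor coordinate-attention squeeze reduction and
#'   minimum squeeze width.
#' @param lska_K,lska_d large-kernel size and dilation of the separable
#'   decomposition.
#' @param carafe_Cm,carafe_Kup,carafe_Kenc,carafe_sigma CARAFE compressed
#'   channels, reassembly kernel, encoder kernel and up-sampling ratio.
#' @return An object of class `wb_block_config`.
#' @export
block_config <- function(k = 3, rfca_reduction = 2, rfca_floor = 8,
                         lska_K = 7, lska_d = 2,
                         carafe_Cm = 60, carafe_Kup = 5, carafe_Kenc = 3,
                         carafe_sigma = 2) {
  vals <- c(k, rfca_reduction, rfca_floor, lska_K, lska_d, carafe_Cm,
            carafe_Kup, carafe_Kenc, carafe_sigma)
  if (any(vals < 1) || any(vals != round(vals)))
    stop("invalid config: block parameters must be positive integers")
  if (k %% 2 != 1) stop("invalid config: k must be odd")
  lska_kernel_sizes(lska_K, lska_d)
  structure(list(k = k, rfca_reduction = rfca_reduction,
                 rfca_floor = rfca_floor, lska_K = lska_K, lska_d = lska_d,
                 carafe_Cm = carafe_Cm, carafe_Kup = carafe_Kup,
                 carafe_Kenc = carafe_Kenc, carafe_sigma = carafe_sigma),
            class = "wb_block_config")
}

#' Model configuration
#'
#' @param num_classes number of object classes (default 1, a single bird
#'   class).
#' @param depth_multiple,width_multiple compound scaling fractions; the
#'   defaults give the "n"-scale model.
#' @param input_size nominal square input side in pixels; must be divisible
#'   by 32.
#' @param flags a [variant_flags()] object.
#' @param blocks a [block_config()] object.
#' @param bifpn_width unified hidden width of the BiFPN-P2 neck.
#' @param reg_max number of distribution-focal bins of the box head.
#' @return An object of class `wb_model_config`.
#' @export
model_config <- function(num_classes = 1, depth_multiple = 0.33,
                         width_multiple = 0.25, input_size = 640,
                         flags = variant_flags(), blocks = block_config(),
                         bifpn_width = NULL, reg_max = 16) {
  if (input_size %% 32 != 0)
    stop("invalid config: input_size must be divisible by 32")
  if (num_classes < 1) stop("invalid config: num_classes must be >= 1")
  if (reg_max < 2) stop("invalid config: reg_max must be >= 2")
  if (is.null(bifpn_width))
    bifpn_width <- if (width_multiple == 0.25) 59L
                   else max(4L, 2L * round(236 * width_multiple / 2))
  structure(list(num_classes = num_classes, depth_multiple = depth_multiple,
                 width_multiple = width_multiple, input_size = input_size,
                 flags = flags, blocks = blocks,
                 bifpn_width = as.integer(bifpn_width),
                 reg_max = as.integer(reg_max)),
            class = "wb_model_config")
}

scaled_widths <- function(cfg) {
  base <- c(64, 128, 256, 512, 1024) * cfg$width_multiple
  pmax(4, 2 * round(base / 2))
}

scaled_depths <- function(cfg) {
  pmax(1, round(c(3, 6, 6, 3) * cfg$depth_multiple))
}

#' Build a detector
#'
#' Assembles the full computation graph for the configured variant.  The
#' baseline (all flags `FALSE`) is a CSP backbone with stem plus four
#' stride-2 stages, SPPF context pooling, a PAN neck and a decoupled
#' anchor-free head with distribution focal box regression at strides
#' 8/16/32.
#'
#' @param cfg a [model_config()] object.
#' @return An object of class `wb_model`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "wb_model_config"))
  fl <- cfg$flags
  bc <- cfg$blocks
  w <- scaled_widths(cfg)
  dn <- scaled_depths(cfg)
  red <- bc$rfca_reduction
  flo <- bc$rfca_floor

  nodes <- list()
  addn <- function(mod, from, name) {
    nodes[[length(nodes) + 1]] <<- list(mod = mod, from = from, name = name)
    length(nodes)
  }
  stage_conv <- function(c1, c2) {
    if (fl$use_rfca) new_rfca_conv(c1, c2, k = bc$k, stride = 2,
                                   reduction = red, mip_floor = flo)
    else new_conv(c1, c2, 3, stride = 2)
  }
  stage_c2f <- function(c1, c2, n)
    new_c2f(c1, c2, n, shortcut = TRUE, rfca = fl$use_rfca,
            reduction = red, mip_floor = flo)

  # --- backbone ---
  stem <- addn(new_conv(3, w[1], 3, stride = 2), 0L, "stem")
  p2c <- addn(stage_conv(w[1], w[2]), stem, "down_p2")
  p2 <- addn(stage_c2f(w[2], w[2], dn[1]), p2c, "stage_p2")
  p3c <- addn(stage_conv(w[2], w[3]), p2, "down_p3")
  p3 <- addn(stage_c2f(w[3], w[3], dn[2]), p3c, "stage_p3")
  p4c <- addn(stage_conv(w[3], w[4]), p3, "down_p4")
  p4 <- addn(stage_c2f(w[4], w[4], dn[3]), p4c, "stage_p4")
  p5c <- addn(stage_conv(w[4], w[5]), p4, "down_p5")
  p5 <- addn(stage_c2f(w[5], w[5], dn[4]), p5c, "stage_p5")
  sppf <- addn(new_sppf(w[5], w[5], 5, lska = fl$use_sppf_lska,
                        lska_K = bc$lska_K, lska_d = bc$lska_d), p5, "sppf")

  up_mod <- function(c) {
    if (fl$use_carafe)
      new_carafe(c, cm = bc$carafe_Cm, kenc = bc$carafe_Kenc,
                 kup = bc$carafe_Kup, sigma = bc$carafe_sigma)
    else new_upsample(2)
  }

  if (!fl$use_bifpn_p2) {
    # --- PAN neck ---
    u1 <- addn(up_mod(w[5]), sppf, "up1")
    c1n <- addn(new_concat(), c(u1, p4), "cat1")
    t4 <- addn(new_c2f(w[5] + w[4], w[4], dn[4]), c1n, "td_p4")
    u2 <- addn(up_mod(w[4]), t4, "up2")
    c2n <- addn(new_concat(), c(u2, p3), "cat2")
    t3 <- addn(new_c2f(w[4] + w[3], w[3], dn[4]), c2n, "td_p3")
    d1 <- addn(new_conv(w[3], w[3], 3, stride = 2), t3, "down1")
    c3n <- addn(new_concat(), c(d1, t4), "cat3")
    b4 <- addn(new_c2f(w[4] + w[3], w[4], dn[4]), c3n, "bu_p4")
    d2 <- addn(new_conv(w[4], w[4], 3, stride = 2), b4, "down2")
    c4n <- addn(new_concat(), c(d2, sppf), "cat4")
    b5 <- addn(new_c2f(w[5] + w[4], w[5], dn[4]), c4n, "bu_p5")
    heads <- c(t3, b4, b5)
    head_ch <- c(w[3], w[4], w[5])
  } else {
    # --- BiFPN-P2 neck: unified hidden width, sum fusion, P2 branch ---
    W <- cfg$bifpn_width
    neck_c2f <- function() new_c2f(W, W, 1, rfca = TRUE, reduction = red,
                                   mip_floor = flo)
    p2r <- addn(new_rfca_conv(w[2], W, k = bc$k, reduction = red,
                              mip_floor = flo), p2, "p2_recal")
    l3 <- addn(new_conv(w[3], W, 1), p3, "lat_p3")
    l4 <- addn(new_conv(w[4], W, 1), p4, "lat_p4")
    l5 <- addn(new_conv(w[5], W, 1), sppf, "lat_p5")
    u5 <- addn(up_mod(W), l5, "up5")
    f4 <- addn(new_add(), c(l4, u5), "fuse_td4")
    t4 <- addn(neck_c2f(), f4, "td_p4")
    u4 <- addn(up_mod(W), t4, "up4")
    f3 <- addn(new_add(), c(l3, u4), "fuse_td3")
    t3 <- addn(neck_c2f(), f3, "td_p3")
    u3 <- addn(new_upsample(2), t3, "up3")   # P2 edge keeps nearest-neighbour
    f2 <- addn(new_add(), c(p2r, u3), "fuse_td2")
    t2 <- addn(neck_c2f(), f2, "td_p2")
    dn2 <- addn(new_conv(W, W, 3, stride = 2), t2, "down_td2")
    f3b <- addn(new_add(), c(l3, t3, dn2), "fuse_bu3")
    b3 <- addn(neck_c2f(), f3b, "bu_p3")
    dn3 <- addn(new_conv(W, W, 3, stride = 2), b3, "down_bu3")
    f4b <- addn(new_add(), c(l4, t4, dn3), "fuse_bu4")
    b4 <- addn(neck_c2f(), f4b, "bu_p4")
    dn4 <- addn(new_conv(W, W, 3, stride = 2), b4, "down_bu4")
    f5b <- addn(new_add(), c(l5, dn4), "fuse_bu5")
    b5 <- addn(neck_c2f(), f5b, "bu_p5")
    heads <- c(b3, b4, b5)
    head_ch <- c(W, W, W)
  }

  strides <- c(8, 16, 32)
  det <- addn(new_detect(head_ch, cfg$num_classes, reg_max = cfg$reg_max,
                         strides = strides),
              heads, "detect")
  model <- structure(list(nodes = nodes, cfg = cfg, detect_idx = det,
                          strides = strides),
                     class = "wb_model")
  model <- init_head_bias(model)
  model
}

#' Count trainable parameters
#'
#' Exact integer sum of trainable parameter elements over the whole model
#' (convolution weights and biases; the normalisation layers are affine-free
#' and the distribution-focal projection is a fixed buffer, so neither
#' contributes).
#'
#' @param model a [build_model()] result.
#' @param millions if `TRUE`, return millions rounded to 2 decimals.
#' @return integer count (or numeric millions).
#' @export
count_parameters <- function(model, millions = FALSE) {
  n <- sum(vapply(model$nodes, function(nd) n_params(nd$mod), 0))
  if (millions) round(n / 1e6, 2) else as.integer(n)
}

# flops accounting hook ------------------------------------------------------

.wb_flops <- new.env(parent = emptyenv())
.wb_flops$acc <- NULL

#' Estimate inference FLOPs
#'
#' Counts 2 x multiply-accumulates of every convolution during a single
#' batch-1 forward pass at the stated input size.  Informational; pooling,
#' normalisation and activation costs are not included.
#'
#' @param model a [build_model()] result.
#' @param input_size square input side in pixels.
#' @return FLOPs in G (1e9).
#' @export
estimate_flops <- function(model, input_size = model$cfg$input_size) {
  x <- array(0, c(1, 3, input_size, input_size))
  .wb_flops$acc <- 0
  on.exit(.wb_flops$acc <- NULL)
  model_forward(model, x, train = FALSE)
  .wb_flops$acc / 1e9
}

# graph execution ------------------------------------------------------------

#' Run the detector forward
#'
#' @param model a [build_model()] result.
#' @param x input feature map `[N, 3, H, W]` with H, W divisible by 32.
#' @param train if `TRUE`, batch statistics are used and caches are kept for
#'   backpropagation.
#' @return A list with `levels` (per-level raw prediction maps
#'   `[N, 4*reg_max + nc, H_l, W_l]`) and, when `train = TRUE`, the state
#'   needed by [model_backward()].
#' @export
model_forward <- function(model, x, train = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[2] != 3)
    stop("invalid input: expected [N, 3, H, W]")
  if (d[3] %% 32 != 0 || d[4] %% 32 != 0)
    stop("invalid input: spatial dims must be divisible by 32")
  n <- length(model$nodes)
  outs <- vector("list", n)
  caches <- if (train) vector("list", n) else NULL
  for (i in seq_len(n)) {
    nd <- model$nodes[[i]]
    inp <- if (length(nd$from) == 1) {
      if (nd$from == 0) x else outs[[nd$from]]
    } else lapply(nd$from, function(f) outs[[f]])
    r <- mod_fw(nd$mod, inp, train)
    outs[[i]] <- r$y
    if (train) {
      caches[[i]] <- r$cache
      if (identical(nd$from, 0L))
        caches[[i]]$.no_gx <- TRUE   # no consumer for the input gradient
      model$nodes[[i]]$mod <- r$mod
    }
    # free outputs that no later node consumes, unless training
    if (!train && i < n) {
      still <- unlist(lapply(model$nodes[(i + 1):n], `[[`, "from"))
      for (j in seq_len(i - 1))
        if (!(j %in% still)) outs[j] <- list(NULL)
    }
  }
  list(levels = outs[[n]], outs = if (train) outs else NULL,
       caches = caches, model = model)
}

#' Backpropagate through the detector
#'
#' @param model the (possibly buffer-updated) model returned inside
#'   [model_forward()]'s result.
#' @param fw the full result of `model_forward(..., train = TRUE)`.
#' @param glevels gradient of the loss w.r.t. each raw prediction level.
#' @return list with `grads` (per-node gradient trees).
#' @export
model_backward <- function(model, fw, glevels) {
  n <- length(model$nodes)
  gouts <- vector("list", n)
  grads <- vector("list", n)
  gouts[[n]] <- glevels
  for (i in rev(seq_len(n))) {
    nd <- model$nodes[[i]]
    g <- gouts[[i]]
    if (is.null(g)) next
    r <- mod_bw(nd$mod, fw$caches[[i]], g)
    grads[[i]] <- r$grads
    gx <- r$gx
    if (length(nd$from) == 1) {
      f <- nd$from
      if (f > 0)
        gouts[[f]] <- if (is.null(gouts[[f]])) gx else gouts[[f]] + gx
    } else {
      for (k in seq_along(nd$from)) {
        f <- nd$from[k]
        gouts[[f]] <- if (is.null(gouts[[f]])) gx[[k]] else gouts[[f]] + gx[[k]]
      }
    }
    gouts[i] <- list(NULL)
  }
  list(grads = grads)
}
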