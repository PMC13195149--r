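#' @useDynLib wetbird, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network engine: modules are plain lists holding parameter
# arrays, running-stat buffers and sub-modules.  Every module class implements
# mod_fw() (returns output + cache) and mod_bw() (returns input gradient +
# a gradient tree parallel to the module tree).  Gradient correctness is
# checked against finite differences in the test suite.
# ---------------------------------------------------------------------------

new_module <- function(class, params = list(), buffers = list(),
                       sub = list(), cfg = list()) {
  structure(list(params = params, buffers = buffers, sub = sub, cfg = cfg),
            class = c(class, "wb_module"))
}

is_module <- function(x) inherits(x, "wb_module")

mod_fw <- function(mod, x, train = FALSE) UseMethod("mod_fw")
mod_bw <- function(mod, cache, gy) UseMethod("mod_bw")

mod_fw.default <- function(mod, x, train = FALSE)
  stop("no forward for class ", class(mod)[1])
mod_bw.default <- function(mod, cache, gy)
  stop("no backward for class ", class(mod)[1])

`%||%` <- function(a, b) if (is.null(a)) b else a

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(params = mapply(function(x, y) x + y, a$params, b$params, SIMPLIFY = FALSE),
       sub = mapply(add_grads, a$sub, b$sub, SIMPLIFY = FALSE))
}

# flat list of parameter arrays, names joined by "/"
flatten_params <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params))
    out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  for (nm in names(mod$sub))
    out <- c(out, flatten_params(mod$sub[[nm]], paste0(prefix, nm, "/")))
  out
}

flatten_grads <- function(g, prefix = "") {
  out <- list()
  for (nm in names(g$params))
    out[[paste0(prefix, nm)]] <- g$params[[nm]]
  for (nm in names(g$sub))
    out <- c(out, flatten_grads(g$sub[[nm]], paste0(prefix, nm, "/")))
  out
}

# apply fn(param, grad, key) -> new param over the whole tree
map_params <- function(mod, grads, fn, prefix = "") {
  for (nm in names(mod$params)) {
    key <- paste0(prefix, nm)
    mod$params[[nm]] <- fn(mod$params[[nm]], grads$params[[nm]], key)
  }
  for (nm in names(mod$sub))
    mod$sub[[nm]] <- map_params(mod$sub[[nm]], grads$sub[[nm]], fn,
                                paste0(prefix, nm, "/"))
  mod
}

n_params <- function(mod) sum(vapply(flatten_params(mod), length, 0L))

# ---- weight initialisation (uniform Kaiming-style, as in common practice) ----

init_conv_w <- function(cout, cin_g, kh, kw) {
  fan_in <- cin_g * kh * kw
  bound <- sqrt(1 / fan_in)
  array(stats::runif(cout * cin_g * kh * kw, -bound, bound),
        dim = c(cout, cin_g, kh, kw))
}

init_conv_b <- function(cout, fan_in) {
  bound <- sqrt(1 / fan_in)
  stats::runif(cout, -bound, bound)
}

# ---------------------------------------------------------------------------
# conv block: conv2d (+bias) -> optional affine-free batch norm -> activation
# ---------------------------------------------------------------------------

new_conv <- function(c1, c2, k = 1, stride = 1, pad = NULL, dilation = 1,
                     groups = 1, act = "silu", norm = TRUE, bias = TRUE,
                     kh = NULL, kw = NULL) {
  kh <- kh %||% k
  kw <- kw %||% k
  if (is.null(pad)) pad <- (max(kh, kw) %/% 2) * dilation
  if (c1 %% groups != 0 || c2 %% groups != 0)
    stop("invalid config: channels not divisible by groups")
  params <- list(w = init_conv_w(c2, c1 %/% groups, kh, kw))
  if (bias) params$b <- init_conv_b(c2, (c1 %/% groups) * kh * kw)
  buffers <- if (norm) list(rmean = numeric(c2), rvar = rep(1, c2)) else list()
  new_module("wb_conv", params, buffers,
             cfg = list(c1 = c1, c2 = c2, kh = kh, kw = kw, stride = stride,
                        pad = pad, dilation = dilation, groups = groups,
                        act = act, norm = norm, bias = bias))
}

act_code <- function(act)
  switch(act, none = 0L, silu = 1L, relu = 2L, sigmoid = 3L,
         stop("unknown activation ", act))

mod_fw.wb_conv <- function(mod, x, train = FALSE) {
  cfg <- mod$cfg
  if (dim(x)[2] != cfg$c1)
    stop("invalid config: expected ", cfg$c1, " channels, got ", dim(x)[2])
  b <- if (cfg$bias) mod$params$b else numeric(0)
  fwr <- cpp_conv2d_fw2(x, mod$params$w, b, cfg$stride, cfg$pad, cfg$dilation,
                        cfg$groups, train)
  z <- fwr$y
  if (!is.null(.wb_flops$acc)) {
    dz <- dim(z)
    .wb_flops$acc <- .wb_flops$acc +
      2 * cfg$kh * cfg$kw * (cfg$c1 / cfg$groups) * cfg$c2 * dz[3] * dz[4]
  }
  ac <- act_code(cfg$act)
  if (cfg$norm) {
    bn <- cpp_bnact_fw(z, mod$buffers$rmean, mod$buffers$rvar, 1e-5, 0.03,
                       train, ac)
    if (train) {
      mod$buffers$rmean <- bn$rmean
      mod$buffers$rvar <- bn$rvar
    }
    cache <- list(xdim = dim(x), cols = if (train) fwr$cols,
                  x = if (!train) x,
                  xhat = bn$xhat, invstd = bn$invstd, train = train)
    y <- bn$y
  } else {
    y <- cpp_act_fw(z, ac)
    cache <- list(xdim = dim(x), cols = if (train) fwr$cols,
                  x = if (!train) x, z = z)
  }
  list(y = y, cache = cache, mod = mod)
}

mod_bw.wb_conv <- function(mod, cache, gy) {
  cfg <- mod$cfg
  ac <- act_code(cfg$act)
  g <- if (cfg$norm)
    cpp_bnact_bw(gy, cache$xhat, cache$invstd, cache$train, ac)
  else cpp_act_bw(gy, cache$z, ac)
  r <- cpp_conv2d_bw(cache$x %||% numeric(0), cache$xdim, mod$params$w, g,
                     cfg$stride, cfg$pad, cfg$dilation, cfg$groups,
                     is.null(cache$.no_gx), cfg$bias, cache$cols)
  grads <- list(params = list(w = r$gw), sub = list())
  if (cfg$bias) grads$params$b <- as.numeric(r$gb)
  list(gx = r$gx, grads = grads)
}

# ---------------------------------------------------------------------------
# max pooling, nearest up-sampling, concat, elementwise sum
# ---------------------------------------------------------------------------

#' Max-pooling block
#' @param k pooling kernel size.
#' @param stride,pad step and zero padding.
#' @return a pooling module usable with [mod_fw()].
#' @export
new_maxpool <- function(k, stride = 1, pad = k %/% 2)
  new_module("wb_maxpool", cfg = list(k = k, stride = stride, pad = pad))

mod_fw.wb_maxpool <- function(mod, x, train = FALSE) {
  r <- cpp_maxpool_fw(x, mod$cfg$k, mod$cfg$stride, mod$cfg$pad)
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)), mod = mod)
}

mod_bw.wb_maxpool <- function(mod, cache, gy)
  list(gx = cpp_maxpool_bw(cache$idx, gy, cache$xdim),
       grads = list(params = list(), sub = list()))

#' Nearest-neighbour up-sampling block
#' @param s integer up-sampling ratio.
#' @return an up-sampling module usable with [mod_fw()].
#' @export
new_upsample <- function(s = 2) new_module("wb_upsample", cfg = list(s = s))

mod_fw.wb_upsample <- function(mod, x, train = FALSE)
  list(y = cpp_upnn_fw(x, mod$cfg$s), cache = list(), mod = mod)

mod_bw.wb_upsample <- function(mod, cache, gy)
  list(gx = cpp_upnn_bw(gy, mod$cfg$s),
       grads = list(params = list(), sub = list()))

new_concat <- function() new_module("wb_concat")

mod_fw.wb_concat <- function(mod, x, train = FALSE) {
  stopifnot(is.list(x))
  chans <- vapply(x, function(a) dim(a)[2], 0)
  d <- dim(x[[1]])
  y <- array(0, c(d[1], sum(chans), d[3], d[4]))
  at <- 0
  for (a in x) {
    y[, at + seq_len(dim(a)[2]), , ] <- a
    at <- at + dim(a)[2]
  }
  list(y = y, cache = list(chans = chans), mod = mod)
}

mod_bw.wb_concat <- function(mod, cache, gy) {
  gx <- list()
  at <- 0
  for (i in seq_along(cache$chans)) {
    idx <- at + seq_len(cache$chans[i])
    g <- gy[, idx, , , drop = FALSE]
    dim(g) <- c(dim(gy)[1], cache$chans[i], dim(gy)[3], dim(gy)[4])
    gx[[i]] <- g
    at <- at + cache$chans[i]
  }
  list(gx = gx, grads = list(params = list(), sub = list()))
}

new_add <- function() new_module("wb_add")

mod_fw.wb_add <- function(mod, x, train = FALSE) {
  y <- x[[1]]
  for (i in seq_along(x)[-1]) y <- y + x[[i]]
  list(y = y, cache = list(n = length(x)), mod = mod)
}

mod_bw.wb_add <- function(mod, cache, gy)
  list(gx = rep(list(gy), cache$n),
       grads = list(params = list(), sub = list()))

new_identity <- function() new_module("wb_identity")
mod_fw.wb_identity <- function(mod, x, train = FALSE)
  list(y = x, cache = list(), mod = mod)
mod_bw.wb_identity <- function(mod, cache, gy)
  list(gx = gy, grads = list(params = list(), sub = list()))

# ---------------------------------------------------------------------------
# helpers to run a named sequence of sub-modules
# ---------------------------------------------------------------------------

seq_fw <- function(mod, names, x, train) {
  caches <- list()
  for (nm in names) {
    r <- mod_fw(mod$sub[[nm]], x, train)
    mod$sub[[nm]] <- r$mod
    caches[[nm]] <- r$cache
    x <- r$y
  }
  list(y = x, caches = caches, mod = mod)
}

seq_bw <- function(mod, names, caches, gy, grads) {
  for (nm in rev(names)) {
    r <- mod_bw(mod$sub[[nm]], caches[[nm]], gy)
    grads$sub[[nm]] <- add_grads(grads$sub[[nm]], r$grads)
    gy <- r$gx
  }
  list(gx = gy, grads = grads)
}
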