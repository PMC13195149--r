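# ---------------------------------------------------------------------------
# Checkpointing: a single-file checkpoint embeds the model configuration and
# every parameter and running-statistics buffer; loading rebuilds the graph
# from the embedded configuration and verifies shapes.
# ---------------------------------------------------------------------------

collect_state <- function(mod, prefix = "") {
  out <- flatten_params(mod, prefix)
  for (nm in names(mod$buffers))
    out[[paste0(prefix, ".buf.", nm)]] <- mod$buffers[[nm]]
  for (nm in names(mod$sub))
    out <- c(out, collect_state(mod$sub[[nm]], paste0(prefix, nm, "/")))
  out
}

restore_state <- function(mod, state, prefix = "") {
  for (nm in names(mod$params)) {
    key <- paste0(prefix, nm)
    v <- state[[key]]
    if (is.null(v))
      stop("checkpoint mismatch: missing parameter ", key)
    if (!identical(dim(v) %||% length(v), dim(mod$params[[nm]]) %||%
                   length(mod$params[[nm]])))
      stop("checkpoint shape mismatch at ", key,
           " (was the model built with different variant flags?)")
    mod$params[[nm]] <- v
  }
  for (nm in names(mod$buffers)) {
    v <- state[[paste0(prefix, ".buf.", nm)]]
    if (!is.null(v)) mod$buffers[[nm]] <- v
  }
  for (nm in names(mod$sub))
    mod$sub[[nm]] <- restore_state(mod$sub[[nm]], state,
                                   paste0(prefix, nm, "/"))
  mod
}

#' Save model weights
#'
#' @param model a built model.
#' @param path checkpoint file.
#' @export
save_weights <- function(model, path) {
  state <- list()
  for (i in seq_along(model$nodes))
    state <- c(state, collect_state(model$nodes[[i]]$mod,
                                    paste0("n", i, "/")))
  saveRDS(list(cfg = model$cfg, state = state), path)
  invisible(path)
}

#' Load model weights
#'
#' Rebuilds the model from the embedded configuration (or verifies an
#' explicitly supplied one) and restores every parameter bitwise.
#'
#' @param path checkpoint file.
#' @param cfg optional [model_config()]; when given, the checkpoint must
#'   match its architecture (a variant-flag mismatch raises a shape error).
#' @return The restored model.
#' @export
load_weights <- function(path, cfg = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- tryCatch(readRDS(path),
                 error = function(e) stop("corrupt checkpoint: ", path))
  if (!is.list(ck) || is.null(ck$state)) stop("corrupt checkpoint: ", path)
  model <- build_model(cfg %||% ck$cfg)
  for (i in seq_along(model$nodes))
    model$nodes[[i]]$mod <- restore_state(model$nodes[[i]]$mod, ck$state,
                                          paste0("n", i, "/"))
  model
}
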