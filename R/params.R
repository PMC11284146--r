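#' Count trainable parameters
#'
#' @param model a model or module with a `params` list.
#' @return total number of trainable scalars.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$v), numeric(1)))
}

#' Per-module parameter breakdown
#'
#' Groups the flat parameter names by their first dotted component
#' (convnext, vit, ham, frd, unet, ...) and reports counts per group plus
#' the total.
#' @param model a model with a `params` list.
#' @return data.frame with columns `module`, `n_params`, `millions`.
#' @export
count_params <- function(model) {
  ns <- vapply(model$params, function(p) length(p$v), numeric(1))
  grp <- sub("\\..*$", "", names(model$params))
  agg <- tapply(ns, grp, sum)
  df <- data.frame(module = names(agg), n_params = as.numeric(agg),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(module = "total", n_params = sum(ns)))
  df$millions <- round(df$n_params / 1e6, 3)
  df
}

#' Extract the model state dictionary
#'
#' @param model a model with a `params` list (batch-norm running statistics
#'   are included under `<bn name>.running_mean` / `.running_var`).
#' @return named list of numeric arrays.
#' @export
state_dict <- function(model) {
  sd <- lapply(model$params, function(p) p$v)
  for (st in find_bn_states(model)) {
    nm <- sub("\\.gamma$", "", st$gamma$name)
    sd[[paste0(nm, ".running_mean")]] <- st$rmean
    sd[[paste0(nm, ".running_var")]] <- st$rvar
  }
  sd
}

#' Load a state dictionary into a model by name
#'
#' Matching tensors are copied in place; a shape mismatch is an error
#' naming the first offending tensor; keys present on only one side are
#' reported via `message()` and returned invisibly.
#' @param model target model.
#' @param sd named list of arrays (e.g. from [state_dict()] or an RDS
#'   checkpoint).
#' @return invisibly, list with `unmatched_model` and `unmatched_file` key
#'   vectors.
#' @export
load_state_dict <- function(model, sd) {
  pn <- names(model$params)
  bn_states <- find_bn_states(model)
  bn_keys <- unlist(lapply(bn_states, function(st) {
    nm <- sub("\\.gamma$", "", st$gamma$name)
    paste0(nm, c(".running_mean", ".running_var"))
  }))
  for (nm in intersect(pn, names(sd))) {
    p <- model$params[[nm]]
    v <- sd[[nm]]
    if (length(v) != length(p$v))
      stop("shape mismatch for tensor '", nm, "': model ",
           paste(dim(p$v), collapse = "x"), " vs checkpoint ",
           paste(if (is.null(dim(v))) length(v) else dim(v), collapse = "x"))
    dim(v) <- dim(p$v)
    p$v <- v
  }
  for (st in bn_states) {
    nm <- sub("\\.gamma$", "", st$gamma$name)
    if (!is.null(sd[[paste0(nm, ".running_mean")]]))
      st$rmean <- as.numeric(sd[[paste0(nm, ".running_mean")]])
    if (!is.null(sd[[paste0(nm, ".running_var")]]))
      st$rvar <- as.numeric(sd[[paste0(nm, ".running_var")]])
  }
  res <- list(unmatched_model = setdiff(pn, names(sd)),
              unmatched_file = setdiff(names(sd), c(pn, bn_keys)))
  if (length(res$unmatched_model))
    message("tensors not found in checkpoint: ",
            paste(utils::head(res$unmatched_model, 5), collapse = ", "),
            if (length(res$unmatched_model) > 5) " ...")
  if (length(res$unmatched_file))
    message("checkpoint keys not used: ",
            paste(utils::head(res$unmatched_file, 5), collapse = ", "),
            if (length(res$unmatched_file) > 5) " ...")
  invisible(res)
}

# locate batch-norm state environments by walking the parameter closures:
# every bn layer's gamma param environment is referenced from an mk_bn state
# env; we register them at build time instead, via an attribute-free scan of
# param names and the closures that own them.  Simpler: bn layers are
# discoverable because their params are named "*.gamma" with a sibling
# "*.beta" and their enclosing environment (captured by op_bn) carries the
# running stats; we track them in a registry keyed by the gamma tensor.
find_bn_states <- function(model) {
  out <- list()
  for (nm in names(model$params)) {
    if (!grepl("\\.bn[0-9]*\\.gamma$", nm)) next
    p <- model$params[[nm]]
    st <- attr(p, "bn_state", exact = TRUE)
    if (!is.null(st)) out[[length(out) + 1L]] <- st
  }
  out
}

save_checkpoint <- function(model, path, extra = list()) {
  obj <- c(list(state = state_dict(model), config = model$config,
                class = class(model)), extra)
  saveRDS(obj, path)
  invisible(path)
}

deep_copy_state <- function(model) lapply(state_dict(model), identity)
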