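# Layer constructors.  A layer/module is a plain list with a named `params`
# list (flat, "module.sub.tensor" names) and an `fwd` closure.  Parameter
# tensors are tnsr environments, so optimizer updates are visible to every
# closure that captured them.

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

new_param <- function(name, dims, init = c("trunc", "he", "zeros", "ones"),
                      fan_in = NULL, const = NULL) {
  init <- match.arg(init)
  n <- prod(dims)
  v <- switch(init,
    trunc = trunc_normal(n),
    he = stats::rnorm(n) * sqrt(2 / fan_in),
    zeros = rep(0, n),
    ones = rep(1, n)
  )
  if (!is.null(const)) v <- rep(const, n)
  dim(v) <- dims
  tnsr(v, param = TRUE, name = name)
}

mk_conv <- function(name, cin, cout, k, stride = 1L, pad = 0L, groups = 1L,
                    bias = TRUE, init = "trunc") {
  force(k); force(stride); force(pad); force(groups); force(cout)
  cin_pg <- cin / groups
  stopifnot(cin_pg == round(cin_pg), cout %% groups == 0)
  w <- new_param(paste0(name, ".w"), c(k, k, cin_pg, cout), init = init,
                 fan_in = k * k * cin_pg)
  b <- if (bias) new_param(paste0(name, ".b"), c(cout, 1, 1, 1), init = "zeros") else NULL
  params <- c(stats::setNames(list(w), paste0(name, ".w")),
              if (bias) stats::setNames(list(b), paste0(name, ".b")))
  list(params = params, w = w, b = b,
       fwd = function(x) op_conv(x, w, b, stride = stride, pad = pad, groups = groups))
}

mk_convtr <- function(name, cin, cout, k, stride, groups = 1L, bias = TRUE,
                      init = "trunc") {
  force(k); force(stride); force(groups); force(cin)
  cout_pg <- cout / groups
  stopifnot(cout_pg == round(cout_pg), cin %% groups == 0)
  w <- new_param(paste0(name, ".w"), c(k, k, cout_pg, cin), init = init,
                 fan_in = k * k * cin / groups)
  b <- if (bias) new_param(paste0(name, ".b"), c(cout, 1, 1, 1), init = "zeros") else NULL
  params <- c(stats::setNames(list(w), paste0(name, ".w")),
              if (bias) stats::setNames(list(b), paste0(name, ".b")))
  list(params = params, w = w, b = b,
       fwd = function(x) op_convtr(x, w, b, stride = stride, groups = groups))
}

mk_bn <- function(name, C, momentum = 0.1, eps = 1e-5) {
  layer <- new.env(parent = emptyenv())
  layer$gamma <- new_param(paste0(name, ".gamma"), c(C, 1, 1, 1), init = "ones")
  layer$beta <- new_param(paste0(name, ".beta"), c(C, 1, 1, 1), init = "zeros")
  layer$rmean <- rep(0, C)
  layer$rvar <- rep(1, C)
  layer$momentum <- momentum
  layer$eps <- eps
  attr(layer$gamma, "bn_state") <- layer   # for checkpointing running stats
  list(params = stats::setNames(list(layer$gamma, layer$beta),
                                paste0(name, c(".gamma", ".beta"))),
       state = layer,
       fwd = function(x, training = FALSE) op_bn(x, layer, training))
}

mk_ln <- function(name, C, eps = 1e-6) {
  gamma <- new_param(paste0(name, ".gamma"), c(C, 1, 1, 1), init = "ones")
  beta <- new_param(paste0(name, ".beta"), c(C, 1, 1, 1), init = "zeros")
  list(params = stats::setNames(list(gamma, beta),
                                paste0(name, c(".gamma", ".beta"))),
       fwd = function(x) op_ln_ch(x, gamma, beta, eps))
}

# base convolutional module: conv3x3 -> batch norm -> leaky ReLU
mk_base_conv <- function(name, cin, cout, slope = 0.01, init = "he") {
  conv <- mk_conv(paste0(name, ".conv"), cin, cout, k = 3L, pad = 1L,
                  bias = FALSE, init = init)
  bn <- mk_bn(paste0(name, ".bn"), cout)
  list(params = c(conv$params, bn$params), bn = bn,
       fwd = function(x, training = FALSE)
         op_lrelu(bn$fwd(conv$fwd(x), training), slope))
}

collect_params <- function(...) {
  ps <- unlist(lapply(list(...), function(m) {
    if (is.null(m)) return(NULL)
    if (!is.null(m$params)) m$params else m
  }), recursive = FALSE)
  if (anyDuplicated(names(ps))) stop("duplicated parameter names")
  ps
}

# batch-norm state environments of a module tree (for checkpointing)
collect_bn_states <- function(modules) {
  out <- list()
  for (m in modules) if (!is.null(m$state)) out[[length(out) + 1L]] <- m$state
  out
}
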