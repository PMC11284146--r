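# Reverse-mode automatic differentiation on 4-D image tensors.
#
# A tensor node ("tnsr") is an environment holding the value `v` (a numeric
# array, layout (H, W, C, N)), an accumulated gradient `grad`, the parent
# nodes it was computed from and a backward closure `bw` that maps the
# node's gradient to a list of parent gradients.  Operations executed while
# the tape is recording append their output node to the tape; `backward()`
# walks the tape in reverse creation order, which is a valid reverse
# topological order because execution is eager.

.dfa <- new.env(parent = emptyenv())
.dfa$tape <- list()
.dfa$n <- 0L
.dfa$on <- FALSE

tape_on <- function() {
  .dfa$tape <- vector("list", 4096L)
  .dfa$n <- 0L
  .dfa$on <- TRUE
  invisible(NULL)
}

tape_off <- function() {
  .dfa$tape <- list()
  .dfa$n <- 0L
  .dfa$on <- FALSE
  invisible(NULL)
}

tape_recording <- function() .dfa$on

#' Evaluate an expression with gradient recording enabled
#'
#' @param expr expression to evaluate while the autodiff tape records.
#' @return the value of `expr`.
#' @keywords internal
with_tape <- function(expr) {
  tape_on()
  on.exit(tape_off())
  expr
}

tnsr <- function(v, parents = NULL, bw = NULL, param = FALSE, name = NULL) {
  node <- new.env(parent = emptyenv())
  node$v <- v
  node$grad <- NULL
  node$param <- param
  node$name <- name
  if (.dfa$on && !is.null(bw)) {
    node$parents <- parents
    node$bw <- bw
    n <- .dfa$n + 1L
    if (n > length(.dfa$tape)) .dfa$tape <- c(.dfa$tape, vector("list", length(.dfa$tape)))
    .dfa$tape[[n]] <- node
    .dfa$n <- n
  } else {
    node$parents <- NULL
    node$bw <- NULL
  }
  class(node) <- "tnsr"
  node
}

#' @export
print.tnsr <- function(x, ...) {
  cat("<tnsr", paste(dim4(x$v), collapse = "x"),
      if (isTRUE(x$param)) paste0("param ", x$name) else "", ">\n")
  invisible(x)
}

is_tnsr <- function(x) inherits(x, "tnsr")

as_tnsr <- function(x) {
  if (is_tnsr(x)) return(x)
  tnsr(x)
}

dim4 <- function(v) {
  d <- dim(v)
  if (is.null(d)) stop("tensor value must be a dim-ed array")
  if (length(d) == 4L) return(d)
  stop("expected a 4-d (H, W, C, N) array, got ", length(d), " dims")
}

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backward pass over the recorded tape
#'
#' Seeds the given node with gradient 1 (or `seed`) and accumulates
#' gradients into every upstream node, including parameters.
#' @param node output node (typically a scalar loss).
#' @param seed gradient seed, defaults to 1.
#' @keywords internal
backward <- function(node, seed = 1) {
  if (!.dfa$on && .dfa$n == 0L) stop("backward() called without a recorded tape")
  node$grad <- array(seed, dim = dim(node$v))
  for (i in rev(seq_len(.dfa$n))) {
    nd <- .dfa$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (!is.null(gs[[j]])) acc_grad(ps[[j]], gs[[j]])
    }
    if (!isTRUE(nd$keep_grad)) nd$grad <- NULL  # free intermediates as we go
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ------------------------------------------------------------------ ops ----

op_conv <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xd <- dim4(x$v)
  wd <- dim(w$v)
  k <- wd[1]
  cout <- wd[4]
  bias <- if (is.null(b)) NULL else as.numeric(b$v)
  y <- cpp_conv_fwd(x$v, as.integer(xd), w$v, bias, as.integer(k),
                    as.integer(stride), as.integer(pad), as.integer(groups),
                    as.integer(cout))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tnsr(y, parents, function(g) {
    r <- cpp_conv_bwd(x$v, as.integer(xd), w$v, g, as.integer(k),
                      as.integer(stride), as.integer(pad), as.integer(groups),
                      as.integer(cout), !is.null(b))
    gw <- r$gw; dim(gw) <- wd
    if (is.null(b)) list(r$gx, gw) else {
      gb <- r$gb; dim(gb) <- dim(b$v)
      list(r$gx, gw, gb)
    }
  })
}

op_convtr <- function(x, w, b = NULL, stride = 1L, groups = 1L) {
  xd <- dim4(x$v)
  wd <- dim(w$v)            # (k, k, cout_pg, cin)
  k <- wd[1]
  cout <- wd[3] * groups
  bias <- if (is.null(b)) NULL else as.numeric(b$v)
  y <- cpp_convtr_fwd(x$v, as.integer(xd), w$v, bias, as.integer(k),
                      as.integer(stride), as.integer(groups), as.integer(cout))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tnsr(y, parents, function(g) {
    r <- cpp_convtr_bwd(x$v, as.integer(xd), w$v, g, as.integer(k),
                        as.integer(stride), as.integer(groups),
                        as.integer(cout), !is.null(b))
    gw <- r$gw; dim(gw) <- wd
    if (is.null(b)) list(r$gx, gw) else {
      gb <- r$gb; dim(gb) <- dim(b$v)
      list(r$gx, gw, gb)
    }
  })
}

op_bilinear <- function(x, hout, wout) {
  xd <- dim4(x$v)
  if (xd[1] == hout && xd[2] == wout) return(x)  # exact identity at same size
  y <- cpp_bilinear_fwd(x$v, as.integer(xd), as.integer(hout), as.integer(wout))
  tnsr(y, list(x), function(g) {
    list(cpp_bilinear_bwd(g, as.integer(dim(g)), as.integer(xd[1]),
                          as.integer(xd[2])))
  })
}

op_maxpool2 <- function(x) {
  xd <- dim4(x$v)
  r <- cpp_maxpool2_fwd(x$v, as.integer(xd))
  tnsr(r$y, list(x), function(g) {
    list(cpp_maxpool2_bwd(g, as.integer(dim(g)), r$idx, as.integer(xd[1]),
                          as.integer(xd[2])))
  })
}

op_ln_ch <- function(x, gamma, beta, eps = 1e-6) {
  xd <- dim4(x$v)
  r <- cpp_ln_ch_fwd(x$v, as.integer(xd), as.numeric(gamma$v),
                     as.numeric(beta$v), eps)
  tnsr(r$y, list(x, gamma, beta), function(g) {
    b <- cpp_ln_ch_bwd(x$v, as.integer(xd), g, as.numeric(gamma$v),
                       r$mu, r$istd)
    gg <- b$ggamma; dim(gg) <- dim(gamma$v)
    gb <- b$gbeta; dim(gb) <- dim(beta$v)
    list(b$gx, gg, gb)
  })
}

# Batch norm: `layer` is the environment created by mk_bn(); running
# statistics are updated in place when training.
op_bn <- function(x, layer, training) {
  xd <- dim4(x$v)
  r <- cpp_bn_fwd(x$v, as.integer(xd), as.numeric(layer$gamma$v),
                  as.numeric(layer$beta$v), layer$rmean, layer$rvar,
                  isTRUE(training), layer$momentum, layer$eps)
  if (isTRUE(training)) {
    layer$rmean <- r$rmean
    layer$rvar <- r$rvar
  }
  tnsr(r$y, list(x, layer$gamma, layer$beta), function(g) {
    b <- cpp_bn_bwd(x$v, as.integer(xd), g, as.numeric(layer$gamma$v),
                    r$save_mean, r$save_istd, isTRUE(training))
    gg <- b$ggamma; dim(gg) <- dim(layer$gamma$v)
    gb <- b$gbeta; dim(gb) <- dim(layer$beta$v)
    list(b$gx, gg, gb)
  })
}

op_gelu <- function(x) {
  v <- x$v
  tnsr(cpp_gelu_fwd(v), list(x), function(g) list(cpp_gelu_bwd(v, g)))
}

op_lrelu <- function(x, slope = 0.01) {
  v <- x$v
  tnsr(cpp_lrelu_fwd(v, slope), list(x), function(g)
    list(cpp_lrelu_bwd(v, g, slope)))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  tnsr(y, list(x), function(g) list(g * y * (1 - y)))
}

op_add <- function(x, y) {
  tnsr(x$v + y$v, list(x, y), function(g) list(g, g))
}

op_mul <- function(x, y) {
  tnsr(x$v * y$v, list(x, y), function(g) list(g * y$v, g * x$v))
}

# per-channel scale (ConvNeXt layer scale); gamma has length C
op_chanscale <- function(x, gamma) {
  xd <- dim4(x$v)
  y <- cpp_chanscale_fwd(x$v, as.integer(xd), as.numeric(gamma$v))
  tnsr(y, list(x, gamma), function(g) {
    r <- cpp_chanscale_bwd(x$v, as.integer(xd), as.numeric(gamma$v), g)
    gg <- r$ggamma
    dim(gg) <- dim(gamma$v)
    list(r$gx, gg)
  })
}

op_concat_ch <- function(xs) {
  vs <- lapply(xs, function(x) x$v)
  dims <- lapply(vs, dim4)
  cs <- vapply(dims, function(d) d[3], numeric(1))
  d1 <- dims[[1]]
  y <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(vs)) {
    y[, , at + seq_len(cs[i]), ] <- vs[[i]]
    at <- at + cs[i]
  }
  tnsr(y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      gi <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      dim(gi) <- dims[[i]]
      out[[i]] <- gi
      at <- at + cs[i]
    }
    out
  })
}

op_slice_ch <- function(x, channels) {
  xd <- dim4(x$v)
  y <- x$v[, , channels, , drop = FALSE]
  tnsr(y, list(x), function(g) {
    gx <- array(0, dim = xd)
    gx[, , channels, ] <- g
    list(gx)
  })
}

# softmax over all spatial positions of a 1-channel map, per sample
op_softmax_spatial <- function(x) {
  xd <- dim4(x$v)
  if (xd[3] != 1L) stop("op_softmax_spatial expects a single-channel map")
  S <- xd[1] * xd[2]
  m <- matrix(x$v, S, xd[4])
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  w <- sweep(e, 2, colSums(e), "/")
  y <- array(w, dim = xd)
  tnsr(y, list(x), function(g) {
    gm <- matrix(g, S, xd[4])
    dot <- colSums(gm * w)
    gx <- w * sweep(gm, 2, dot)
    dim(gx) <- xd
    list(gx)
  })
}

# broadcast-multiply a 1-channel map over all channels of x
op_mul_bcast_ch <- function(map, x) {
  xd <- dim4(x$v)
  mv <- as.vector(map$v)
  S <- xd[1] * xd[2]
  # expand map (S, N) across channels
  mm <- matrix(mv, S, xd[4])
  expand <- function(m) {
    a <- array(0, dim = xd)
    for (n in seq_len(xd[4])) a[, , , n] <- array(rep(m[, n], xd[3]), dim = xd[1:3])
    a
  }
  mb <- expand(mm)
  y <- x$v * mb
  tnsr(y, list(map, x), function(g) {
    gmap <- apply(g * x$v, c(1, 2, 4), sum)
    dim(gmap) <- dim4(map$v)
    gx <- g * mb
    list(gmap, gx)
  })
}

# scaled dot-product multi-head attention over flattened spatial tokens
op_attention <- function(q, k, v, heads) {
  qd <- dim4(q$v)
  S <- qd[1] * qd[2]
  C <- qd[3]
  N <- qd[4]
  if (C %% heads != 0) stop("attention: channels (", C, ") not divisible by heads (", heads, ")")
  dk <- C / heads
  scl <- 1 / sqrt(dk)
  y <- array(0, dim = qd)
  As <- vector("list", N * heads)
  Qm <- function(x, n) matrix(x[, , , n], S, C)
  for (n in seq_len(N)) {
    Q <- Qm(q$v, n); K <- Qm(k$v, n); V <- Qm(v$v, n)
    O <- matrix(0, S, C)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dk + seq_len(dk)
      sc <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scl
      sc <- sc - apply(sc, 1, max)
      e <- exp(sc)
      A <- e / rowSums(e)
      As[[(n - 1) * heads + h]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    y[, , , n] <- array(O, dim = qd[1:3])
  }
  tnsr(y, list(q, k, v), function(g) {
    gq <- array(0, dim = qd); gk <- array(0, dim = qd); gv <- array(0, dim = qd)
    for (n in seq_len(N)) {
      Q <- Qm(q$v, n); K <- Qm(k$v, n); V <- Qm(v$v, n)
      GO <- matrix(g[, , , n], S, C)
      GQ <- matrix(0, S, C); GK <- matrix(0, S, C); GV <- matrix(0, S, C)
      for (h in seq_len(heads)) {
        cols <- (h - 1) * dk + seq_len(dk)
        A <- As[[(n - 1) * heads + h]]
        GOv <- GO[, cols, drop = FALSE]
        GV[, cols] <- t(A) %*% GOv
        GA <- GOv %*% t(V[, cols, drop = FALSE])
        GS <- A * (GA - rowSums(GA * A))
        GQ[, cols] <- (GS %*% K[, cols, drop = FALSE]) * scl
        GK[, cols] <- (t(GS) %*% Q[, cols, drop = FALSE]) * scl
      }
      gq[, , , n] <- array(GQ, qd[1:3])
      gk[, , , n] <- array(GK, qd[1:3])
      gv[, , , n] <- array(GV, qd[1:3])
    }
    list(gq, gk, gv)
  })
}

# attention weight matrices (for inspection/tests): list over samples of
# per-head row-stochastic (S x S) matrices
attention_weights <- function(qv, kv, heads) {
  qd <- dim4(qv)
  S <- qd[1] * qd[2]; C <- qd[3]; N <- qd[4]
  dk <- C / heads
  scl <- 1 / sqrt(dk)
  out <- vector("list", N)
  for (n in seq_len(N)) {
    Q <- matrix(qv[, , , n], S, C); K <- matrix(kv[, , , n], S, C)
    ws <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dk + seq_len(dk)
      sc <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scl
      sc <- sc - apply(sc, 1, max)
      e <- exp(sc)
      ws[[h]] <- e / rowSums(e)
    }
    out[[n]] <- ws
  }
  out
}

# channel self-attention (Gram-matrix softmax, residual): rows of the C x C
# weight matrix are softmax-normalized so it acts as a stochastic mixer
op_channel_attn <- function(x) {
  xd <- dim4(x$v)
  S <- xd[1] * xd[2]; C <- xd[3]; N <- xd[4]
  y <- array(0, dim = xd)
  Fs <- vector("list", N); As <- vector("list", N)
  for (n in seq_len(N)) {
    Fm <- t(matrix(x$v[, , , n], S, C))      # C x S
    G <- Fm %*% t(Fm)
    G <- G - apply(G, 1, max)
    e <- exp(G)
    A <- e / rowSums(e)
    Fs[[n]] <- Fm; As[[n]] <- A
    y[, , , n] <- array(t(A %*% Fm + Fm), xd[1:3])
  }
  tnsr(y, list(x), function(g) {
    gx <- array(0, dim = xd)
    for (n in seq_len(N)) {
      Fm <- Fs[[n]]; A <- As[[n]]
      GO <- t(matrix(g[, , , n], S, C))      # C x S
      GF <- t(A) %*% GO + GO
      GA <- GO %*% t(Fm)
      GG <- A * (GA - rowSums(GA * A))
      GF <- GF + (GG + t(GG)) %*% Fm
      gx[, , , n] <- array(t(GF), xd[1:3])
    }
    list(gx)
  })
}

# channel-attention weight matrix for a single-sample map (inspection)
channel_attn_weights <- function(xv) {
  xd <- dim4(xv)
  S <- xd[1] * xd[2]; C <- xd[3]
  Fm <- t(matrix(xv[, , , 1], S, C))
  G <- Fm %*% t(Fm)
  G <- G - apply(G, 1, max)
  e <- exp(G)
  e / rowSums(e)
}

# mean over images of per-image soft Dice loss
op_dice_loss <- function(prob, truth, eps = 1e-6) {
  pd <- dim4(prob$v)
  N <- pd[4]
  tv <- truth
  if (is_tnsr(tv)) tv <- tv$v
  I <- numeric(N); U <- numeric(N)
  for (n in seq_len(N)) {
    p <- prob$v[, , , n]; t <- tv[, , , n]
    I[n] <- sum(p * t)
    U[n] <- sum(p) + sum(t)
  }
  loss <- mean(1 - (2 * I + eps) / (U + eps))
  tnsr(array(loss, dim = c(1, 1, 1, 1)), list(prob), function(g) {
    gp <- array(0, dim = pd)
    gs <- as.numeric(g)[1] / N
    for (n in seq_len(N)) {
      t <- tv[, , , n]
      den <- U[n] + eps
      gp[, , , n] <- gs * (-(2 * t * den - (2 * I[n] + eps)) / den^2)
    }
    list(gp)
  })
}

# sum of x over a fixed binary mask (Grad-CAM score)
op_sum_masked <- function(x, mask) {
  s <- sum(x$v * mask)
  tnsr(array(s, dim = c(1, 1, 1, 1)), list(x), function(g) {
    list(array(as.numeric(g)[1] * mask, dim = dim4(x$v)))
  })
}
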