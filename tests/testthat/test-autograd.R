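# The autodiff engine: analytic gradients of every operation are checked
# against central finite differences on small random tensors.

grad_matches <- function(build, xdim, wdims = list(), tol = 1e-6, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(prod(xdim)), xdim)
  ws <- lapply(wdims, function(d) array(rnorm(prod(d)) * 0.3, d))
  wt <- NULL
  lossfun <- function(xv, wvs) {
    dfaunet:::tape_off()
    out <- build(dfaunet:::tnsr(xv), lapply(wvs, dfaunet:::tnsr))
    sum(out$v * wt)
  }
  dfaunet:::tape_on()
  xn <- dfaunet:::tnsr(x)
  wn <- lapply(ws, dfaunet:::tnsr)
  out <- build(xn, wn)
  set.seed(seed + 1)
  wt <- array(rnorm(length(out$v)), dim = dim(out$v))
  dfaunet:::backward(dfaunet:::op_sum_masked(out, wt))
  gx <- xn$grad
  gws <- lapply(wn, function(w) w$grad)
  dfaunet:::tape_off()
  gx_num <- num_grad(function(z) lossfun(z, ws), x)
  expect_lt(max(abs(gx - gx_num)) / max(1e-8, max(abs(gx_num))), tol)
  for (j in seq_along(ws)) {
    gw_num <- num_grad(function(z) {
      ws2 <- ws; ws2[[j]] <- z; lossfun(x, ws2)
    }, ws[[j]])
    expect_lt(max(abs(gws[[j]] - gw_num)) / max(1e-8, max(abs(gw_num))), tol)
  }
}

test_that("convolution family gradients match finite differences", {
  grad_matches(function(x, w) dfaunet:::op_conv(x, w[[1]], w[[2]], stride = 1, pad = 1),
               c(5, 6, 3, 2), list(c(3, 3, 3, 4), c(4, 1, 1, 1)))
  grad_matches(function(x, w) dfaunet:::op_conv(x, w[[1]], w[[2]]),
               c(4, 4, 3, 2), list(c(1, 1, 3, 5), c(5, 1, 1, 1)))
  grad_matches(function(x, w) dfaunet:::op_conv(x, w[[1]], w[[2]], pad = 1, groups = 4),
               c(5, 5, 4, 2), list(c(3, 3, 1, 4), c(4, 1, 1, 1)))
  grad_matches(function(x, w) dfaunet:::op_conv(x, w[[1]], w[[2]], stride = 4),
               c(8, 8, 3, 1), list(c(4, 4, 3, 4), c(4, 1, 1, 1)))
  grad_matches(function(x, w) dfaunet:::op_convtr(x, w[[1]], w[[2]], stride = 2),
               c(3, 4, 4, 2), list(c(2, 2, 3, 4), c(3, 1, 1, 1)))
  grad_matches(function(x, w) dfaunet:::op_convtr(x, w[[1]], w[[2]], stride = 4, groups = 3),
               c(3, 3, 3, 2), list(c(4, 4, 1, 3), c(3, 1, 1, 1)))
})

test_that("resampling, pooling and normalization gradients match", {
  grad_matches(function(x, w) dfaunet:::op_bilinear(x, 7, 9), c(3, 4, 2, 2))
  grad_matches(function(x, w) dfaunet:::op_bilinear(x, 2, 2), c(8, 8, 2, 2))
  grad_matches(function(x, w) dfaunet:::op_maxpool2(x), c(4, 6, 3, 2))
  grad_matches(function(x, w) dfaunet:::op_ln_ch(x, w[[1]], w[[2]]),
               c(3, 3, 5, 2), list(c(5, 1, 1, 1), c(5, 1, 1, 1)))
  grad_matches(function(x, w) {
    layer <- new.env()
    layer$gamma <- w[[1]]; layer$beta <- w[[2]]
    layer$rmean <- rep(0, 4); layer$rvar <- rep(1, 4)
    layer$momentum <- 0.1; layer$eps <- 1e-5
    dfaunet:::op_bn(x, layer, TRUE)
  }, c(3, 3, 4, 2), list(c(4, 1, 1, 1), c(4, 1, 1, 1)))
})

test_that("activation, attention and loss gradients match", {
  grad_matches(function(x, w) dfaunet:::op_gelu(x), c(4, 4, 3, 2))
  grad_matches(function(x, w) dfaunet:::op_lrelu(x, 0.1), c(4, 4, 3, 2))
  grad_matches(function(x, w) dfaunet:::op_chanscale(x, w[[1]]),
               c(3, 4, 3, 2), list(c(3, 1, 1, 1)))
  grad_matches(function(x, w) {
    a <- dfaunet:::op_slice_ch(x, 1:2)
    b <- dfaunet:::op_slice_ch(x, 3:4)
    dfaunet:::op_concat_ch(list(b, a))
  }, c(3, 3, 4, 2))
  grad_matches(function(x, w)
    dfaunet:::op_mul_bcast_ch(dfaunet:::op_softmax_spatial(dfaunet:::op_slice_ch(x, 1)), x),
    c(3, 3, 3, 2))
  grad_matches(function(x, w) {
    q <- dfaunet:::op_conv(x, w[[1]], NULL)
    k <- dfaunet:::op_conv(x, w[[2]], NULL)
    v <- dfaunet:::op_conv(x, w[[3]], NULL)
    dfaunet:::op_attention(q, k, v, 2L)
  }, c(3, 3, 4, 2), list(c(1, 1, 4, 4), c(1, 1, 4, 4), c(1, 1, 4, 4)))
  grad_matches(function(x, w) dfaunet:::op_channel_attn(x), c(3, 3, 4, 2))

  set.seed(2)
  tr <- array(rbinom(32, 1, 0.4), c(4, 4, 1, 2))
  p0 <- array(runif(32), c(4, 4, 1, 2))
  dfaunet:::tape_on()
  pn <- dfaunet:::tnsr(p0)
  dfaunet:::backward(dfaunet:::op_dice_loss(dfaunet:::op_sigmoid(pn), tr))
  g <- pn$grad
  dfaunet:::tape_off()
  gn <- num_grad(function(z) {
    as.numeric(dfaunet:::op_dice_loss(dfaunet:::op_sigmoid(dfaunet:::tnsr(z)), tr)$v)
  }, p0)
  expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-6)
})

test_that("forward-only mode records no tape and backward frees gradients", {
  x <- dfaunet:::tnsr(array(1, c(2, 2, 1, 1)))
  y <- dfaunet:::op_sigmoid(x)
  expect_null(y$bw)                      # nothing recorded outside a tape
  dfaunet:::tape_on()
  x2 <- dfaunet:::tnsr(array(0.3, c(2, 2, 1, 1)), param = TRUE)
  y2 <- dfaunet:::op_sigmoid(x2)
  dfaunet:::backward(dfaunet:::op_sum_masked(y2, array(1, c(2, 2, 1, 1))))
  expect_false(is.null(x2$grad))
  expect_null(y2$grad)                   # intermediate freed
  dfaunet:::tape_off()
})
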