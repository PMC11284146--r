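# ViT stream: patch grid shapes, the scaled dot-product attention oracle,
# feed-forward contracts and the triple residual sum.

test_that("patchify produces the stated token grids and unpatchify inverts the shape", {
  vit <- cached("vit16", build_vit_stream(16L, heads = 2L))
  half <- array(rnorm(64 * 64 * 8), c(64, 64, 8, 1))
  t4 <- patchify(vit, half, branch = 1)        # P = 4
  expect_equal(dim(t4), c(16, 16, 8, 1))
  t16 <- patchify(vit, half, branch = 2)       # P = 16
  expect_equal(dim(t16), c(4, 4, 8, 1))
  expect_equal(dim(unpatchify(vit, t4, branch = 1)), dim(half))
  expect_equal(dim(unpatchify(vit, t16, branch = 2)), dim(half))
  expect_error(patchify(vit, half[, 1:62, , , drop = FALSE], branch = 1),
               "divisible")
})

test_that("attention matches a hand-computed softmax(QK^T/sqrt(dk)) V oracle", {
  # 3 tokens in a 3x1 grid, 2 channels, one head (dk = 2), identity Q/K/V
  Q <- matrix(c(1, 0.5, -1, 0, 2, 1), nrow = 3)          # tokens x channels
  K <- matrix(c(0.3, -0.2, 0.8, 1, 0.4, -0.5), nrow = 3)
  V <- matrix(c(2, -1, 0.5, 1, 3, -2), nrow = 3)
  qa <- array(as.vector(Q), c(3, 1, 2, 1))
  ka <- array(as.vector(K), c(3, 1, 2, 1))
  va <- array(as.vector(V), c(3, 1, 2, 1))
  # explicit-loop oracle
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(2)
  W <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  O <- W %*% V
  res <- multi_head_attention(qa, ka, va, heads = 1L, return_weights = TRUE)
  expect_equal(res$weights[[1]][[1]], W, tolerance = 1e-12)
  expect_equal(matrix(res$out, 3, 2), O, tolerance = 1e-12)
})

test_that("attention weights are row-stochastic and degenerate cases are exact", {
  set.seed(3)
  q <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  k <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  v <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  res <- multi_head_attention(q, k, v, heads = 4L, return_weights = TRUE)
  for (ws in res$weights) for (W in ws)
    expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-5)
  # single token: weight exactly 1, output = V
  one <- multi_head_attention(q[1, 1, , , drop = FALSE], k[1, 1, , , drop = FALSE],
                              v[1, 1, , , drop = FALSE], heads = 2L,
                              return_weights = TRUE)
  expect_equal(one$out, v[1, 1, , , drop = FALSE])
  expect_equal(one$weights[[1]][[1]][1, 1], 1)
  # K = 0: uniform weights, output = per-head mean of V
  kz <- array(0, dim = dim(k))
  unif <- multi_head_attention(q, kz, v, heads = 1L, return_weights = TRUE)
  Tn <- 16
  expect_equal(unif$weights[[1]][[1]], matrix(1 / Tn, Tn, Tn), tolerance = 1e-12)
  vm <- mean(v[, , 1, 1])
  expect_equal(unif$out[, , 1, 1], matrix(vm, 4, 4), tolerance = 1e-12)
  expect_error(multi_head_attention(q, k, v, heads = 3L), "divisible")
})

test_that("feed-forward is two conv-bn-lrelu blocks preserving shape with a leaky slope", {
  vit <- cached("vit16", build_vit_stream(16L, heads = 2L))
  env <- environment(vit$fwd)
  x <- dfaunet:::as_tnsr(array(rnorm(8 * 8 * 16), c(8, 8, 16, 1)))
  y <- env$ff2$fwd(env$ff1$fwd(x), FALSE)
  expect_equal(dim(y$v), dim(x$v))
  # leaky (not hard-zero) negatives: an identity-like 1-channel conv
  bc <- dfaunet:::mk_base_conv("t.ff", 1L, 1L, slope = 0.01)
  bc$params$t.ff.conv.w$v[] <- 0
  bc$params$t.ff.conv.w$v[2, 2, 1, 1] <- 1       # delta kernel
  xin <- dfaunet:::as_tnsr(array(c(-4, -2, 1, 3), c(2, 2, 1, 1)))
  out <- bc$fwd(xin, FALSE)$v
  expect_true(any(out < 0))                       # negatives survive
  expect_gt(min(out), -4.1 * 0.011)               # at the leaky slope scale
})

test_that("the stream output is the triple residual sum with F1's shape", {
  vit <- cached("vit16", build_vit_stream(16L, heads = 2L))
  f1 <- dfaunet:::as_tnsr(array(rnorm(64 * 64 * 16), c(64, 64, 16, 1)))
  out <- vit$fwd(f1)
  expect_equal(dim(out$fv$v), dim(f1$v))
  expect_equal(out$fv$v, f1$v + out$f_mha$v + out$f_ff$v, tolerance = 1e-12)
  # zeroing both sub-branch contributions makes the stream the identity
  vit0 <- build_vit_stream(16L, heads = 2L)
  for (nm in grep("unpatch|ff[12]\\.conv", names(vit0$params), value = TRUE))
    vit0$params[[nm]]$v[] <- 0
  out0 <- vit0$fwd(f1)
  expect_equal(out0$fv$v, f1$v, tolerance = 1e-12)
  expect_error(build_vit_stream(15L), "even")
})

test_that("the ViT stream is under 1% of the assembled model's parameters", {
  model <- cached("dfa128", dfa_unet(base_width = 128L, seed = 1))
  vit_n <- sum(vapply(model$params[grep("^vit\\.", names(model$params))],
                      function(p) length(p$v), numeric(1)))
  expect_lt(vit_n / n_params(model), 0.01)
})
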