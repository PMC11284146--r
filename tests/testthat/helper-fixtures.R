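# Shared fixtures.  Tiny models and datasets are built once per test run
# and cached; the expensive synthetic training benchmark is cached too so
# the accuracy and Grad-CAM checks reuse the same trained models.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a small dual-stream model: C = 8, one block per stage, 64 x 64 inputs
tiny_dfa <- function() cached("tiny_dfa", {
  dfa_unet(base_width = 8L, stage_depths = c(1L, 1L, 1L, 1L), vit_heads = 2L,
           seed = 42L)
})

tiny_images <- function(n = 2L, size = 64L, seed = 7L) {
  set.seed(seed)
  array(stats::runif(size * size * 3 * n), c(size, size, 3, n))
}

tiny_dataset <- function(n = 8L, size = 64L, seed = 11L) {
  key <- sprintf("ds_%d_%d_%d", n, size, seed)
  cached(key, generate_synthetic_dataset(
    synth_config(n_images = n, image_size = size, seed = seed)))
}

# central-difference numerical gradient of f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# all-pairs directed Hausdorff-quantile oracle on point-set matrices
directed_q_oracle <- function(A, B, q = 0.95) {
  d <- vapply(seq_len(nrow(A)), function(i)
    sqrt(min((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2)), numeric(1))
  stats::quantile(d, q, names = FALSE, type = 7)
}

hd95_oracle <- function(pm, tm, points = c("boundary", "foreground"), q = 0.95) {
  points <- match.arg(points)
  bfun <- function(m) {
    # independent boundary definition: fg pixel with a 4-neighbor outside fg
    H <- nrow(m); W <- ncol(m)
    out <- matrix(FALSE, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < H) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < W) m[i, j + 1] else FALSE)
      out[i, j] <- !all(nb)
    }
    out
  }
  pmat <- pm > 0; tmat <- tm > 0
  if (points == "boundary") { pmat <- bfun(pmat); tmat <- bfun(tmat) }
  A <- which(pmat, arr.ind = TRUE) * 1.0
  B <- which(tmat, arr.ind = TRUE) * 1.0
  max(directed_q_oracle(B, A, q), directed_q_oracle(A, B, q))
}

random_blob <- function(S = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(0, S, S)
  cx <- runif(1, S * 0.3, S * 0.7); cy <- runif(1, S * 0.3, S * 0.7)
  r <- runif(1, 2, S * 0.35)
  for (i in seq_len(S)) for (j in seq_len(S))
    m[i, j] <- as.numeric((i - cy)^2 + (j - cx)^2 <= r^2)
  m
}

disk_mask <- function(S, r, cx = (S + 1) / 2, cy = (S + 1) / 2) {
  ys <- matrix(seq_len(S), S, S)
  xs <- t(ys)
  ((ys - cy)^2 + (xs - cx)^2 <= r^2) * 1
}

# cached scaled-down training runs used by the accuracy, ablation and
# Grad-CAM acceptance checks
bench_run <- function(model, seed) {
  cached(sprintf("bench_%s_%d", model, seed),
         synthetic_benchmark(seed = seed, model = model))
}
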