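# Synthetic pseudo-color elastography generator, fold bookkeeping, the
# online augmentation policy and image/mask I/O.
#
# Strain elastography overlays a stiffness pseudo-color on the B-mode
# image: soft tissue renders green, hard tissue blue, intermediate mixes
# reddish.  The generator emulates that appearance: one smooth blob-shaped
# lesion per image (a Fourier-perturbed ellipse), an interior blue/green
# stiffness field whose blue-dominant fraction is controlled by
# `hardness_mix`, a green/red background texture, Gaussian-blurred
# low-contrast boundaries and multiplicative speckle noise.

#' Synthetic dataset configuration
#'
#' @param n_images number of images.
#' @param image_size square image side in pixels.
#' @param node_radius_range lesion radius range in pixels; default scales
#'   with the image (11%-25% of the side).
#' @param boundary_blur_sigma Gaussian sigma (px) of the lesion boundary
#'   blur.
#' @param speckle_strength multiplicative speckle amplitude in \[0, 1).
#' @param hardness_mix mean fraction of blue-dominant (stiff) area inside
#'   lesions; per-image targets are drawn around this value.
#' @param seed RNG seed; the generator is fully deterministic given the
#'   configuration.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_images = 263L, image_size = 256L,
                         node_radius_range = NULL, boundary_blur_sigma = 2.5,
                         speckle_strength = 0.25, hardness_mix = 0.5,
                         seed = 1L) {
  if (is.null(node_radius_range))
    node_radius_range <- round(image_size * c(0.11, 0.25))
  stopifnot(n_images >= 1, image_size >= 16,
            all(node_radius_range > 0),
            speckle_strength >= 0, speckle_strength < 1,
            hardness_mix > 0, hardness_mix < 1)
  if (max(node_radius_range) > image_size / 2)
    stop("node radius ", max(node_radius_range),
         " exceeds half the image size ", image_size)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 node_radius_range = node_radius_range,
                 boundary_blur_sigma = boundary_blur_sigma,
                 speckle_strength = speckle_strength,
                 hardness_mix = hardness_mix, seed = as.integer(seed)),
            class = "synth_config")
}

# separable Gaussian blur via banded matrix products (replicate padding
# implicit through kernel renormalization at the edges)
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n <- nrow(m)
  r <- ceiling(3 * sigma)
  off <- -r:r
  kern <- exp(-off^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (d in seq_along(off)) {
    i <- seq_len(n)
    j <- i + off[d]
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + kern[d]
  }
  K <- K / rowSums(K)
  K %*% m %*% t(K)
}

smooth_field <- function(n, sigma) {
  f <- gauss_blur(matrix(stats::rnorm(n * n), n, n), sigma)
  (f - mean(f)) / stats::sd(f)
}

# rasterize a Fourier-perturbed ellipse; returns binary (H, W) matrix
random_blob_mask <- function(S, radius_range) {
  r0 <- stats::runif(1, radius_range[1], radius_range[2])
  cx <- S / 2 + stats::runif(1, -0.08, 0.08) * S
  cy <- S / 2 + stats::runif(1, -0.08, 0.08) * S
  aspect <- stats::runif(1, 0.7, 1.3)
  rot <- stats::runif(1, 0, pi)
  nharm <- 4L
  amp <- stats::runif(nharm, 0, 0.12) / seq_len(nharm)
  phase <- stats::runif(nharm, 0, 2 * pi)
  ys <- matrix(seq_len(S) - cy, S, S)
  xs <- matrix(seq_len(S) - cx, S, S, byrow = TRUE)
  xr <- cos(rot) * xs + sin(rot) * ys
  yr <- -sin(rot) * xs + cos(rot) * ys
  xr <- xr / aspect
  yr <- yr * aspect
  rad <- sqrt(xr^2 + yr^2)
  ang <- atan2(yr, xr)
  rb <- r0 * (1 + Reduce(`+`, lapply(seq_len(nharm), function(k)
    amp[k] * cos((k + 1) * ang + phase[k]))))
  (rad <= rb) * 1
}

generate_one <- function(cfg, id) {
  S <- cfg$image_size
  mask <- random_blob_mask(S, cfg$node_radius_range)
  # per-image stiffness target around the configured mix
  blue_target <- min(0.95, max(0.05, stats::rnorm(1, cfg$hardness_mix, 0.08)))
  stiff <- smooth_field(S, S / 16)
  inside <- mask > 0
  thr <- stats::quantile(stiff[inside], 1 - blue_target, names = FALSE)
  blue_w <- 1 / (1 + exp(-(stiff - thr) * 8))   # smooth blue-vs-green mix
  col_blue <- c(0.20, 0.25, 0.85)
  col_green <- c(0.25, 0.80, 0.35)
  col_bg_green <- c(0.30, 0.72, 0.38)
  col_bg_red <- c(0.82, 0.38, 0.30)
  bg_w <- (smooth_field(S, S / 12) > 0) * 1
  bg_w <- gauss_blur(bg_w, 2)
  alpha <- gauss_blur(mask, cfg$boundary_blur_sigma)
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    fgc <- blue_w * col_blue[ch] + (1 - blue_w) * col_green[ch]
    bgc <- bg_w * col_bg_red[ch] + (1 - bg_w) * col_bg_green[ch]
    img[, , ch] <- alpha * fgc + (1 - alpha) * bgc
  }
  if (cfg$speckle_strength > 0) {
    g1 <- gauss_blur(matrix(stats::rnorm(S * S), S, S), 1)
    g2 <- gauss_blur(matrix(stats::rnorm(S * S), S, S), 1)
    v <- stats::var(as.vector(g1))
    ray <- (g1^2 + g2^2) / (2 * v)              # unit-mean speckle
    spk <- (1 - cfg$speckle_strength) + cfg$speckle_strength * ray
    for (ch in 1:3) img[, , ch] <- img[, , ch] * spk
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  blue_frac <- mean((img[, , 3] > img[, , 2])[inside])
  list(image_id = sprintf("synth_%04d", id), image = img, mask = mask,
       label = if (blue_frac > 0.5) "malignant" else "benign",
       blue_fraction = blue_frac)
}

#' Generate a synthetic elastography dataset
#'
#' @param cfg configuration from [synth_config()].
#' @return list of samples; each has `image_id`, `image` (H, W, 3 array in
#'   \[0, 1\]), binary `mask` (H, W), a benign/malignant `label` derived
#'   from the realized stiff-area fraction, and the measured
#'   `blue_fraction`.
#' @export
generate_synthetic_dataset <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_images), function(i) generate_one(cfg, i))
}

#' Deterministic k-fold plan
#'
#' Splits `n` sample indices into `k` folds whose sizes differ by at most
#' one, by a seeded uniform random permutation.
#' @param n number of samples.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return object of class `fold_plan`: list with `n_samples`, `k`,
#'   `fold_of` (integer vector in 0..k-1) and `seed`.
#' @export
make_fold_plan <- function(n, k = 6L, seed = 1L) {
  if (n < k) stop("need at least k = ", k, " samples, got ", n)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of <- integer(n)
  at <- 0L
  for (f in seq_len(k)) {
    fold_of[perm[at + seq_len(sizes[f])]] <- f - 1L
    at <- at + sizes[f]
  }
  structure(list(n_samples = n, k = as.integer(k), fold_of = fold_of,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Train/test indices for one held-out fold
#'
#' @param plan object from [make_fold_plan()].
#' @param test_fold fold index in 0..k-1.
#' @return list with integer vectors `train` and `test`.
#' @export
fold_split <- function(plan, test_fold = 0L) {
  if (!(test_fold %in% 0:(plan$k - 1))) stop("test_fold out of range")
  test <- which(plan$fold_of == test_fold)
  list(train = setdiff(seq_len(plan$n_samples), test), test = test)
}

# rotate (H, W) matrix about its center by `angle` degrees using inverse
# mapping; bilinear for continuous data, nearest-neighbor otherwise;
# out-of-range pixels are filled with 0
rotate_plane <- function(m, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yo <- matrix(seq_len(H) - cy, H, W)
  xo <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  # inverse rotation of output coordinates into the source frame
  ys <- cos(th) * yo - sin(th) * xo + cy
  xs <- sin(th) * yo + cos(th) * xo + cx
  out <- matrix(0, H, W)
  if (interp == "nearest") {
    yi <- round(ys); xi <- round(xs)
    ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
    out[ok] <- m[cbind(yi[ok], xi[ok])]
  } else {
    y0 <- floor(ys); x0 <- floor(xs)
    dy <- ys - y0; dx <- xs - x0
    for (oy in 0:1) for (ox in 0:1) {
      yi <- y0 + oy; xi <- x0 + ox
      wgt <- (if (oy) dy else 1 - dy) * (if (ox) dx else 1 - dx)
      ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W & wgt > 0
      out[ok] <- out[ok] + wgt[ok] * m[cbind(yi[ok], xi[ok])]
    }
  }
  out
}

#' Online training augmentation
#'
#' With probability `p` applies a vertical flip, and independently with
#' probability `p` a rotation by an angle drawn from `angle_choices`
#' (degrees), identically to image and mask.  Image rotation is bilinear
#' with black fill; mask rotation is nearest-neighbor and stays binary.
#'
#' @param sample list with `image` (H, W, 3) and `mask` (H, W).
#' @param p per-transform probability.
#' @param angle_choices candidate rotation angles in degrees; set
#'   `uniform_range = TRUE` to instead draw uniformly from
#'   `[min(angle_choices), max(angle_choices)]`.
#' @param uniform_range see above.
#' @return the augmented sample.
#' @export
augment <- function(sample, p = 0.5, angle_choices = c(-30, 30),
                    uniform_range = FALSE) {
  img <- sample$image
  msk <- sample$mask
  if (stats::runif(1) < p) {                       # vertical flip
    img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  if (stats::runif(1) < p) {
    ang <- if (uniform_range)
      stats::runif(1, min(angle_choices), max(angle_choices))
    else angle_choices[sample.int(length(angle_choices), 1)]
    for (ch in 1:3) img[, , ch] <- rotate_plane(img[, , ch], ang, "bilinear")
    msk <- rotate_plane(msk, ang, "nearest")
  }
  sample$image <- img
  sample$mask <- msk
  sample
}

# nearest-neighbor resize of a matrix
nn_resize <- function(m, hout, wout) {
  H <- nrow(m); W <- ncol(m)
  yi <- pmin(H, pmax(1, floor((seq_len(hout) - 0.5) * H / hout) + 1))
  xi <- pmin(W, pmax(1, floor((seq_len(wout) - 0.5) * W / wout) + 1))
  m[yi, xi, drop = FALSE]
}

#' Resize a sample to a square size
#'
#' Images are bilinearly resized; masks use nearest-neighbor and are
#' re-binarized.
#' @param sample list with `image` and `mask`.
#' @param size target side in pixels.
#' @return the resized sample.
#' @export
resize_to <- function(sample, size = 256L) {
  d <- dim(sample$image)
  if (d[1] == size && d[2] == size) return(sample)
  x <- sample$image
  dim(x) <- c(d[1], d[2], 3, 1)
  y <- cpp_bilinear_fwd(x, as.integer(dim(x)), as.integer(size), as.integer(size))
  dim(y) <- c(size, size, 3)
  sample$image <- y
  sample$mask <- (nn_resize(sample$mask, size, size) > 0.5) * 1
  sample
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package")
    e <- EBImage::readImage(path)
    img <- aperm(array(as.numeric(e), dim(e)), c(2, 1, 3))
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
  img
}

#' Load an image/mask dataset from paired files
#'
#' Pairs files by stem name: for every image in `image_dir` a mask with the
#' same stem must exist in `mask_dir` (single-channel PNG, foreground 255).
#' Images missing a mask are skipped and listed in the returned error
#' report.
#'
#' @param image_dir directory of PNG/JPEG images.
#' @param mask_dir directory of mask PNGs.
#' @param size target square size (all samples are resized).
#' @return list with `samples` and a data.frame `errors`.
#' @export
load_dataset <- function(image_dir, mask_dir, size = 256L) {
  imgs <- list.files(image_dir, pattern = "\\.(png|jpg|jpeg)$",
                     ignore.case = TRUE, full.names = TRUE)
  samples <- list()
  errors <- data.frame(image = character(), reason = character())
  for (f in imgs) {
    stem <- tools::file_path_sans_ext(basename(f))
    mf <- file.path(mask_dir, paste0(stem, ".png"))
    if (!file.exists(mf)) {
      errors <- rbind(errors, data.frame(image = basename(f),
                                         reason = "missing mask"))
      next
    }
    img <- read_image_file(f)
    mk <- png::readPNG(mf)
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    s <- list(image_id = stem, image = img, mask = (mk > 0.5) * 1,
              label = NA_character_)
    samples[[length(samples) + 1L]] <- resize_to(s, size)
  }
  list(samples = samples, errors = errors)
}

#' Write a dataset to disk (PNG images, 0/255 PNG masks, CSV manifest)
#'
#' @param samples list of samples.
#' @param dir output directory; `images/` and `masks/` subdirectories are
#'   created.
#' @param fold_plan optional [make_fold_plan()] result recorded in the
#'   manifest.
#' @return invisibly, the manifest data.frame.
#' @export
write_dataset <- function(samples, dir, fold_plan = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    ip <- file.path(dir, "images", paste0(s$image_id, ".png"))
    mp <- file.path(dir, "masks", paste0(s$image_id, ".png"))
    png::writePNG(s$image, ip)
    png::writePNG(s$mask, mp)
    data.frame(image_id = s$image_id, image_path = ip, mask_path = mp,
               label = if (is.null(s$label)) NA_character_ else s$label,
               fold = if (is.null(fold_plan)) NA_integer_
                      else fold_plan$fold_of[i])
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
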