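#' Assemble the dual-stream feature-fusion attention U-Net
#'
#' Builds the full segmentation network: ConvNeXt convolutional stream,
#' lightweight ViT stream on F1, hybrid attention bottleneck and
#' feature-enhanced residual decoder with a sigmoid head.  The reference
#' configuration is `base_width = 128` with ConvNeXt-Base stage depths
#' (3, 3, 27, 3) and 256 x 256 inputs; smaller widths give proportionally
#' scaled models for desk-scale experiments.
#'
#' @param base_width encoder base width C (128 for the reference model).
#' @param stage_depths ConvNeXt blocks per stage.
#' @param vit_heads attention heads in the ViT stream.
#' @param patch_sizes the two ViT patch sizes.
#' @param leaky_slope negative slope for leaky-ReLU activations.
#' @param decoder_blocks base conv blocks per decoder stage (1 or 2).
#' @param patch_proj ViT patch projection type, see [build_vit_stream()].
#' @param pretrained_weights optional state-dictionary path for the
#'   convolutional stream.
#' @param seed optional RNG seed for weight initialization.
#' @return object of classes `dfa_unet`, `seg_model`: a list with `params`,
#'   `forward(images, training)`, the submodules, `stages` (Grad-CAM
#'   registry) and `config`.
#' @examples
#' m <- dfa_unet(base_width = 16, stage_depths = c(1, 1, 1, 1), seed = 1)
#' p <- predict(m, array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
#' dim(p$prob)
#' @export
dfa_unet <- function(base_width = 128L, stage_depths = c(3L, 3L, 27L, 3L),
                     vit_heads = 4L, patch_sizes = c(4L, 16L),
                     leaky_slope = 0.01, decoder_blocks = 1L,
                     patch_proj = "depthwise",
                     pretrained_weights = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- as.integer(base_width)
  enc <- build_convnext_encoder(C, stage_depths,
                                pretrained_weights = pretrained_weights)
  vit <- build_vit_stream(C, heads = vit_heads, patch_sizes = patch_sizes,
                          leaky_slope = leaky_slope, patch_proj = patch_proj)
  ham <- build_ham(C)
  frd <- build_frd(C, dims = C * c(1L, 2L, 4L, 8L),
                   decoder_blocks = decoder_blocks, leaky_slope = leaky_slope)
  params <- c(enc$params, vit$params, ham$params, frd$params)

  forward <- function(images, training = FALSE) {
    if (!is_tnsr(images)) images <- as_image_batch(images)
    x <- as_tnsr(images)
    xd <- dim4(x$v)
    pyr <- enc$fwd(x, training)
    vs <- vit$fwd(pyr$f1, training)
    hs <- ham$fwd(vs$fv, pyr$f4)
    ds <- frd$fwd(hs$fcv, pyr, xd[1], xd[2], training)
    c(pyr, vs, list(fcv = hs$fcv, ff = hs$ff), ds)
  }

  stages <- list(decoder2 = function(st) st$fo[[3]],
                 decoder3 = function(st) st$fo[[2]],
                 decoder4 = function(st) st$fo[[1]])

  structure(list(params = params, forward = forward, encoder = enc,
                 vit = vit, ham = ham, frd = frd, stages = stages,
                 config = list(base_width = C, stage_depths = stage_depths,
                               vit_heads = vit_heads, patch_sizes = patch_sizes,
                               leaky_slope = leaky_slope,
                               decoder_blocks = decoder_blocks,
                               patch_proj = patch_proj)),
            class = c("dfa_unet", "seg_model"))
}

#' Full forward pass returning all intermediates
#'
#' Runs the assembled network without gradient recording and returns the
#' decoder state: feature pyramid, ViT output, bottleneck feature, fused
#' decoder features, stage outputs, logits, probability map and the
#' thresholded binary mask.
#' @param model a `dfa_unet` model.
#' @param images array (H, W, 3, N), H and W divisible by 32.
#' @param threshold binarization threshold (probability >= threshold is
#'   foreground).
#' @return named list of arrays.
#' @export
dfa_unet_forward <- function(model, images, threshold = 0.5) {
  st <- model$forward(images, training = FALSE)
  lapply2 <- function(x) if (is_tnsr(x)) x$v else if (is.list(x)) lapply(x, lapply2) else x
  out <- lapply(st, lapply2)
  out$pred_mask <- (out$prob >= threshold) * 1
  out
}

#' Predict segmentation probability maps and masks
#'
#' @param object a `seg_model` (`dfa_unet` or `unet_baseline`).
#' @param newdata array (H, W, 3, N), a single (H, W, 3) image, or a list of
#'   samples from the data module.
#' @param threshold binarization threshold.
#' @param batch_size images per forward pass.
#' @param ... unused.
#' @return list with `prob` and `mask` arrays of shape (H, W, 1, N).
#' @export
predict.seg_model <- function(object, newdata, threshold = 0.5,
                              batch_size = 8L, ...) {
  x <- as_image_batch(newdata)
  N <- dim(x)[4]
  prob <- array(0, c(dim(x)[1], dim(x)[2], 1, N))
  for (at in seq(1, N, by = batch_size)) {
    idx <- at:min(N, at + batch_size - 1L)
    st <- object$forward(x[, , , idx, drop = FALSE], training = FALSE)
    prob[, , , idx] <- st$prob$v
  }
  list(prob = prob, mask = (prob >= threshold) * 1)
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<", class(x)[1], "> base width ", x$config$base_width,
      ", parameters: ", format(n_params(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

# coerce samples / single image / batch array to an (H, W, 3, N) array
as_image_batch <- function(x) {
  if (is.list(x) && !is.null(x[[1]]$image)) {
    imgs <- lapply(x, function(s) s$image)
    d <- dim(imgs[[1]])
    out <- array(0, c(d[1], d[2], 3, length(imgs)))
    for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
    return(out)
  }
  d <- dim(x)
  if (length(d) == 3) {
    dim(x) <- c(d, 1)
    return(x)
  }
  if (length(d) == 4) return(x)
  stop("cannot interpret input as an image batch")
}

as_mask_batch <- function(x) {
  if (is.list(x) && !is.null(x[[1]]$mask)) {
    ms <- lapply(x, function(s) s$mask)
    d <- dim(ms[[1]])
    out <- array(0, c(d[1], d[2], 1, length(ms)))
    for (i in seq_along(ms)) out[, , 1, i] <- ms[[i]]
    return(out)
  }
  d <- dim(x)
  if (length(d) == 2) { dim(x) <- c(d, 1, 1); return(x) }
  if (length(d) == 3) { dim(x) <- c(d[1], d[2], 1, d[3]); return(x) }
  x
}
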