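#' Build the plain U-Net reference baseline
#'
#' The standard encoder-decoder U-Net used as the ablation baseline: four
#' down stages of double 3x3 convolutions (batch norm, ReLU-family
#' activation) with 2x2 max pooling, doubling channels from `base_width` to
#' `16 * base_width` at the bottleneck, and four up stages with 2x2
#' transposed-convolution upsampling and skip concatenations, ending in a
#' 1x1 convolution and sigmoid.  With `base_width = 64` the trainable
#' parameter count is 31,037,633 (31.04 M).
#'
#' @param base_width channels of the first double conv (64 for the
#'   reference configuration).
#' @param in_ch input channels.
#' @param seed optional RNG seed for weight initialization.
#' @return object of classes `unet_baseline`, `seg_model`.
#' @export
build_unet_baseline <- function(base_width = 64L, in_ch = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- as.integer(base_width)
  widths <- W * c(1L, 2L, 4L, 8L, 16L)

  mk_double <- function(name, cin, cout) {
    c1 <- mk_conv(paste0(name, ".conv1"), cin, cout, k = 3L, pad = 1L,
                  bias = FALSE, init = "he")
    b1 <- mk_bn(paste0(name, ".bn1"), cout)
    c2 <- mk_conv(paste0(name, ".conv2"), cout, cout, k = 3L, pad = 1L,
                  bias = FALSE, init = "he")
    b2 <- mk_bn(paste0(name, ".bn2"), cout)
    list(params = c(c1$params, b1$params, c2$params, b2$params),
         fwd = function(x, training = FALSE) {
           h <- op_lrelu(b1$fwd(c1$fwd(x), training), 0)
           op_lrelu(b2$fwd(c2$fwd(h), training), 0)
         })
  }

  inc <- mk_double("unet.inc", in_ch, widths[1])
  downs <- lapply(1:4, function(i)
    mk_double(sprintf("unet.down%d", i), widths[i], widths[i + 1]))
  ups <- lapply(1:4, function(i) {
    cin <- widths[6 - i]; cout <- widths[5 - i]
    upc <- mk_convtr(sprintf("unet.up%d.upconv", i), cin, cout, k = 2L,
                     stride = 2L, init = "he")
    dc <- mk_double(sprintf("unet.up%d", i), cin, cout)
    list(params = c(upc$params, dc$params), upc = upc, dc = dc)
  })
  outc <- mk_conv("unet.outc", widths[1], 1L, k = 1L, init = "trunc")

  params <- inc$params
  for (d in downs) params <- c(params, d$params)
  for (u in ups) params <- c(params, u$params)
  params <- c(params, outc$params)

  forward <- function(images, training = FALSE) {
    if (!is_tnsr(images)) images <- as_image_batch(images)
    x <- as_tnsr(images)
    skips <- vector("list", 5L)
    h <- inc$fwd(x, training)
    skips[[1]] <- h
    for (i in 1:4) {
      h <- downs[[i]]$fwd(op_maxpool2(h), training)
      skips[[i + 1]] <- h
    }
    fo <- vector("list", 4L)
    for (i in 1:4) {
      h <- ups[[i]]$upc$fwd(h)
      h <- ups[[i]]$dc$fwd(op_concat_ch(list(skips[[5 - i]], h)), training)
      fo[[i]] <- h
    }
    logits <- outc$fwd(h)
    list(fo = fo, logits = logits, prob = op_sigmoid(logits))
  }

  stages <- list(decoder2 = function(st) st$fo[[2]],
                 decoder3 = function(st) st$fo[[3]],
                 decoder4 = function(st) st$fo[[4]])

  structure(list(params = params, forward = forward, stages = stages,
                 config = list(base_width = W, in_ch = in_ch)),
            class = c("unet_baseline", "seg_model"))
}
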