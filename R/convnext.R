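#' Build the convolutional encoder stream (ConvNeXt)
#'
#' Constructs a ConvNeXt feature-pyramid backbone: a 4x4/stride-4 patchify
#' stem followed by four stages of blocks (7x7 depthwise convolution,
#' channel LayerNorm, inverted bottleneck with x4 expansion and GELU, layer
#' scale, residual), with 2x2/stride-2 downsampling between stages.  The
#' four stage outputs F1..F4 have `base_width * c(1, 2, 4, 8)` channels at
#' 1/4, 1/8, 1/16 and 1/32 of the input resolution.  No classification head
#' is attached.
#'
#' The reference configuration (`base_width = 128`, `stage_depths =
#' c(3, 3, 27, 3)`) is the ConvNeXt-Base design.
#'
#' @param base_width channel count C of the first stage (must be even).
#' @param stage_depths integer vector of length 4, blocks per stage.
#' @param in_ch input channels (3 for RGB).
#' @param layer_scale_init initial value of the per-channel layer-scale.
#' @param pretrained_weights optional path to a serialized state-dictionary
#'   (RDS of a named list of arrays); weights load by name and unmatched
#'   keys are reported via message().
#' @return an object of class `convnext_encoder` with elements `params`
#'   (named parameter tensors), `fwd(x, training)` and `config`.
#' @export
build_convnext_encoder <- function(base_width = 128L, stage_depths = c(3L, 3L, 27L, 3L),
                                   in_ch = 3L, layer_scale_init = 1e-6,
                                   pretrained_weights = NULL) {
  if (base_width %% 2 != 0) stop("base_width must be divisible by 2")
  if (length(stage_depths) != 4L) stop("stage_depths must have 4 entries")
  dims <- base_width * c(1L, 2L, 4L, 8L)

  blocks <- list()
  stem_conv <- mk_conv("convnext.stem.conv", in_ch, dims[1], k = 4L, stride = 4L)
  stem_ln <- mk_ln("convnext.stem.ln", dims[1])
  params <- c(stem_conv$params, stem_ln$params)

  mk_block <- function(name, C) {
    dw <- mk_conv(paste0(name, ".dwconv"), C, C, k = 7L, pad = 3L, groups = C)
    ln <- mk_ln(paste0(name, ".ln"), C)
    pw1 <- mk_conv(paste0(name, ".pw1"), C, 4L * C, k = 1L)
    pw2 <- mk_conv(paste0(name, ".pw2"), 4L * C, C, k = 1L)
    gamma <- new_param(paste0(name, ".gamma"), c(C, 1, 1, 1), init = "zeros",
                       const = layer_scale_init)
    list(params = c(dw$params, ln$params, pw1$params, pw2$params,
                    stats::setNames(list(gamma), paste0(name, ".gamma"))),
         fwd = function(x) {
           h <- dw$fwd(x)
           h <- ln$fwd(h)
           h <- pw1$fwd(h)
           h <- op_gelu(h)
           h <- pw2$fwd(h)
           h <- op_chanscale(h, gamma)
           op_add(x, h)
         })
  }

  stages <- vector("list", 4L)
  downs <- vector("list", 3L)
  for (st in 1:4) {
    stages[[st]] <- lapply(seq_len(stage_depths[st]), function(b)
      mk_block(sprintf("convnext.stage%d.block%d", st, b), dims[st]))
    for (bl in stages[[st]]) params <- c(params, bl$params)
    if (st < 4) {
      ln <- mk_ln(sprintf("convnext.down%d.ln", st), dims[st])
      cv <- mk_conv(sprintf("convnext.down%d.conv", st), dims[st], dims[st + 1],
                    k = 2L, stride = 2L)
      downs[[st]] <- list(ln = ln, conv = cv)
      params <- c(params, ln$params, cv$params)
    }
  }

  fwd <- function(x, training = FALSE) {
    xd <- dim4(if (is_tnsr(x)) x$v else x)
    if (xd[1] %% 32 != 0) stop("input height ", xd[1], " not divisible by 32")
    if (xd[2] %% 32 != 0) stop("input width ", xd[2], " not divisible by 32")
    x <- as_tnsr(x)
    h <- stem_ln$fwd(stem_conv$fwd(x))
    fs <- vector("list", 4L)
    for (st in 1:4) {
      for (bl in stages[[st]]) h <- bl$fwd(h)
      fs[[st]] <- h
      if (st < 4) h <- downs[[st]]$conv$fwd(downs[[st]]$ln$fwd(h))
    }
    names(fs) <- paste0("f", 1:4)
    fs
  }

  enc <- structure(list(params = params, fwd = fwd,
                        config = list(base_width = base_width,
                                      stage_depths = stage_depths,
                                      in_ch = in_ch)),
                   class = "convnext_encoder")
  if (!is.null(pretrained_weights)) {
    sd <- readRDS(pretrained_weights)
    load_state_dict(enc, sd)
  }
  enc
}

#' Run the convolutional encoder and return the feature pyramid
#'
#' @param encoder object from [build_convnext_encoder()].
#' @param images numeric array (H, W, 3, N) with values in \[0, 1\], or an
#'   internal tensor node.
#' @param training logical; unused by this encoder (no batch norm) but kept
#'   for interface symmetry.
#' @return list with tensors `f1`..`f4`; F_i has `base_width * 2^(i-1)`
#'   channels at 1/2^(i+1) of the input resolution.
#' @export
forward_pyramid <- function(encoder, images, training = FALSE) {
  encoder$fwd(images, training)
}
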