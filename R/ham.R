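# Hybrid attention module at the bottleneck.  The ViT-stream output Fv is
# bilinearly resized to the F4 grid, concatenated with F4 (9C channels) and
# reduced to 9C/4 channels by a 1x1 convolution, giving Ff.  Channel
# attention (row-softmax of the C' x C' Gram matrix acting as a stochastic
# mixer, plus residual) and spatial attention (1x1 conv to one channel,
# softmax over all positions, broadcast product, plus residual) are applied
# in parallel; their sum is restored to 8C channels by a second 1x1
# convolution, producing Fcv.

#' Build the hybrid attention bottleneck
#'
#' @param C encoder base width; Fv has C channels and F4 has 8C.
#' @return object of class `ham_module` with `params`, `fwd(fv, f4)` and
#'   `config`.  `fwd` returns `list(fcv, ff, fc, fs)`.
#' @export
build_ham <- function(C) {
  cat_ch <- 9L * C
  if (cat_ch %% 4L != 0) stop("9C must be divisible by 4, got C = ", C)
  cp <- cat_ch %/% 4L
  fuse <- mk_conv("ham.fuse", cat_ch, cp, k = 1L, init = "he")
  sa <- mk_conv("ham.sa", cp, 1L, k = 1L, init = "he")
  restore <- mk_conv("ham.restore", cp, 8L * C, k = 1L, init = "he")
  params <- c(fuse$params, sa$params, restore$params)

  fwd <- function(fv, f4) {
    fvd <- dim4(fv$v)
    f4d <- dim4(f4$v)
    if (fvd[3] != C || f4d[3] != 8L * C)
      stop("channel mismatch: expected Fv with ", C, " and F4 with ", 8L * C,
           " channels, got ", fvd[3], " and ", f4d[3])
    fv_small <- op_bilinear(fv, f4d[1], f4d[2])
    ff <- fuse$fwd(op_concat_ch(list(fv_small, f4)))
    fc <- op_channel_attn(ff)
    wmap <- op_softmax_spatial(sa$fwd(ff))
    fs <- op_add(op_mul_bcast_ch(wmap, ff), ff)
    fcv <- restore$fwd(op_add(fc, fs))
    list(fcv = fcv, ff = ff, fc = fc, fs = fs)
  }

  structure(list(params = params, fwd = fwd,
                 config = list(C = C, reduced_channels = cp)),
            class = "ham_module")
}

#' Fuse the two encoder streams into the reduced bottleneck feature
#'
#' @param ham object from [build_ham()].
#' @param fv array or tensor (H/4, W/4, C, N).
#' @param f4 array or tensor (H/32, W/32, 8C, N).
#' @return the fused feature Ff as an array with 9C/4 channels on the F4 grid.
#' @export
fuse_streams <- function(ham, fv, f4) {
  env <- environment(ham$fwd)
  fv <- as_tnsr(fv); f4 <- as_tnsr(f4)
  f4d <- dim4(f4$v)
  fv_small <- op_bilinear(fv, f4d[1], f4d[2])
  env$fuse$fwd(op_concat_ch(list(fv_small, f4)))$v
}

#' Channel self-attention (Gram-matrix softmax with residual)
#'
#' @param ff array (H, W, C', N).
#' @return array of the same shape.
#' @export
channel_attention <- function(ff) op_channel_attn(as_tnsr(ff))$v

#' Spatial attention (position softmax with residual)
#'
#' Uses the given 1x1 convolution weights `w` (C' x 1) and bias `b` to
#' produce the single-channel score map, softmax-normalizes it over all
#' positions and applies the residual broadcast product.
#' @param ff array (H, W, C', N).
#' @param w weight array (1, 1, C', 1); defaults to an average.
#' @param b scalar bias.
#' @return array of the same shape.
#' @export
spatial_attention <- function(ff, w = NULL, b = 0) {
  xd <- dim4(ff)
  if (is.null(w)) w <- array(1 / xd[3], c(1, 1, xd[3], 1))
  x <- as_tnsr(ff)
  a <- op_conv(x, as_tnsr(w), as_tnsr(array(b, c(1, 1, 1, 1))))
  wmap <- op_softmax_spatial(a)
  op_add(op_mul_bcast_ch(wmap, x), x)$v
}

#' Run the hybrid attention module
#'
#' @param ham object from [build_ham()].
#' @param fv,f4 arrays or tensors (see [fuse_streams()]).
#' @return the enhanced bottleneck feature Fcv as an array (H/32, W/32, 8C, N).
#' @export
ham_forward <- function(ham, fv, f4) {
  ham$fwd(as_tnsr(fv), as_tnsr(f4))$fcv$v
}
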