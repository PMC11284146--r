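# Feature-enhanced residual decoder.  The bottleneck feature Fcv is fused
# into every encoder scale: F'di = Conv1x1(Up(Conv1x1(Fcv)) + Fi), with all
# fused maps converted to C/2 channels.  Decoding then runs three stages
# (i = 3, 2, 1), each combining three branches:
#   branch 1: base conv block on the channel concatenation of F'di and the
#             upsampled previous output Fup;
#   branch 2: the spatial-attention weight map of Fup (1x1 conv + spatial
#             softmax, weight only - residuals are added explicitly here)
#             broadcast-multiplied with F'di;
#   branch 3: Fup itself (residual).
# The last stage output is mapped to one channel, upsampled x4 and passed
# through a sigmoid to give the foreground probability map.

build_frd <- function(C, dims, decoder_blocks = 1L, leaky_slope = 0.01) {
  half <- C %/% 2L
  params <- list()
  inner <- vector("list", 4L); outer <- vector("list", 4L)
  for (i in 1:4) {
    inner[[i]] <- mk_conv(sprintf("frd.fuse%d.inner", i), 8L * C, dims[i],
                          k = 1L, init = "he")
    outer[[i]] <- mk_conv(sprintf("frd.fuse%d.outer", i), dims[i], half,
                          k = 1L, init = "he")
    params <- c(params, inner[[i]]$params, outer[[i]]$params)
  }
  stages <- vector("list", 3L)
  for (i in 3:1) {
    nm <- sprintf("frd.dec%d", i)
    convs <- list(mk_base_conv(paste0(nm, ".convs1"), 2L * half, half,
                               slope = leaky_slope))
    if (decoder_blocks >= 2L)
      convs <- c(convs, list(mk_base_conv(paste0(nm, ".convs2"), half, half,
                                          slope = leaky_slope)))
    sa <- mk_conv(paste0(nm, ".sa"), half, 1L, k = 1L, init = "he")
    stages[[i]] <- list(convs = convs, sa = sa)
    for (cv in convs) params <- c(params, cv$params)
    params <- c(params, sa$params)
  }
  head <- mk_conv("frd.head", half, 1L, k = 1L, init = "trunc")
  params <- c(params, head$params)

  fuse_one <- function(fcv, fi, i) {
    fid <- dim4(fi$v)
    up <- op_bilinear(inner[[i]]$fwd(fcv), fid[1], fid[2])
    outer[[i]]$fwd(op_add(up, fi))
  }

  dec_one <- function(fdp_i, prev, i, training) {
    d <- dim4(fdp_i$v)
    up <- op_bilinear(prev, d[1], d[2])
    h <- op_concat_ch(list(fdp_i, up))
    for (cv in stages[[i]]$convs) h <- cv$fwd(h, training)
    wmap <- op_softmax_spatial(stages[[i]]$sa$fwd(up))
    att <- op_mul_bcast_ch(wmap, fdp_i)
    op_add(op_add(h, up), att)
  }

  fwd <- function(fcv, pyramid, out_h, out_w, training = FALSE) {
    fdp <- lapply(1:4, function(i) fuse_one(fcv, pyramid[[i]], i))
    prev <- fdp[[4]]
    fo <- vector("list", 3L)
    for (i in 3:1) {
      prev <- dec_one(fdp[[i]], prev, i, training)
      fo[[i]] <- prev
    }
    logits <- op_bilinear(head$fwd(fo[[1]]), out_h, out_w)
    prob <- op_sigmoid(logits)
    list(fd_prime = fdp, fo = fo, logits = logits, prob = prob)
  }

  structure(list(params = params, fwd = fwd, fuse_one = fuse_one,
                 dec_one = dec_one,
                 config = list(C = C, dims = dims,
                               decoder_blocks = decoder_blocks)),
            class = "frd_module")
}

#' Fuse the bottleneck feature into one encoder scale
#'
#' Computes `Conv1x1(Up(Conv1x1(Fcv)) + Fi)` with the built decoder's
#' weights, returning the C/2-channel fused map at scale `i`.
#' @param frd object of class `frd_module` (from a built model).
#' @param fcv array or tensor (H/32, W/32, 8C, N).
#' @param fi encoder feature at scale `i`.
#' @param i scale index 1..4.
#' @export
fuse_bottleneck <- function(frd, fcv, fi, i) {
  if (!(i %in% 1:4)) stop("unknown pyramid index i = ", i, "; must be 1..4")
  frd$fuse_one(as_tnsr(fcv), as_tnsr(fi), i)$v
}

#' Run one decoder stage
#'
#' @param frd object of class `frd_module`.
#' @param fd_prime_i fused feature at stage `i`.
#' @param previous decoder output of stage `i + 1` (or `fd_prime_4` for the
#'   bottom stage).
#' @param i stage index 3, 2 or 1.
#' @export
decoder_block <- function(frd, fd_prime_i, previous, i) {
  frd$dec_one(as_tnsr(fd_prime_i), as_tnsr(previous), i, FALSE)$v
}

#' Map the last decoder stage to the output probability map
#'
#' 1x1 convolution to one channel, bilinear x4 upsampling and sigmoid.
#' @param frd object of class `frd_module`.
#' @param fo_1 decoder output at the highest resolution (C/2, H/4, W/4).
#' @param threshold binarization threshold for the predicted mask.
#' @return list with `prob_map` and binary `pred_mask` arrays (H, W, 1, N).
#' @export
segmentation_head <- function(frd, fo_1, threshold = 0.5) {
  env <- environment(frd$fwd)
  x <- as_tnsr(fo_1)
  d <- dim4(x$v)
  logits <- op_bilinear(env$head$fwd(x), 4L * d[1], 4L * d[2])
  prob <- op_sigmoid(logits)$v
  list(prob_map = prob, pred_mask = (prob >= threshold) * 1)
}
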