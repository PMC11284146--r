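# Lightweight vision-transformer stream operating on the first encoder
# scale F1.  F1 is split into two channel halves; each half is reduced to a
# token grid by a learned linear projection over non-overlapping P x P
# patches (P = 4 for one half, P = 16 for the other), passed through
# convolutional-QKV multi-head attention, and projected back to the F1
# resolution by the inverse linear map.  The halves are re-concatenated to
# form F_MHA, a two-block convolutional feed-forward gives F_FF, and the
# stream output is the triple residual sum Fv = F1 + F_MHA + F_FF.

#' Build the ViT encoder stream
#'
#' @param C channel count of F1 (must be even; the stream works on C/2
#'   channel halves).
#' @param heads number of attention heads (must divide C/2).
#' @param patch_sizes two patch sizes, one per channel half.
#' @param leaky_slope negative slope of the leaky-ReLU in the feed-forward.
#' @param patch_proj `"depthwise"` (default): the patch projection is a
#'   per-channel linear map over each P x P patch, keeping the stream
#'   lightweight (about 0.5% of the full model); `"full"` uses a dense
#'   linear map over all channels of the patch.
#' @return object of class `vit_stream` with `params`, `fwd(f1, training)`
#'   and `config`.
#' @export
build_vit_stream <- function(C, heads = 4L, patch_sizes = c(4L, 16L),
                             leaky_slope = 0.01, patch_proj = c("depthwise", "full")) {
  patch_proj <- match.arg(patch_proj)
  if (C %% 2 != 0) stop("channel split requires even C, got ", C)
  half <- C %/% 2L
  if (half %% heads != 0) stop("heads (", heads, ") must divide C/2 (", half, ")")

  branches <- vector("list", length(patch_sizes))
  params <- list()
  for (b in seq_along(patch_sizes)) {
    P <- as.integer(patch_sizes[b])
    g <- if (patch_proj == "depthwise") half else 1L
    nm <- sprintf("vit.branch%d", b)
    patch <- mk_conv(paste0(nm, ".patch"), half, half, k = P, stride = P,
                     groups = g, init = "he")
    unpatch <- mk_convtr(paste0(nm, ".unpatch"), half, half, k = P, stride = P,
                         groups = g, init = "he")
    qc <- mk_conv(paste0(nm, ".q"), half, half, k = 3L, pad = 1L, init = "he")
    kc <- mk_conv(paste0(nm, ".k"), half, half, k = 3L, pad = 1L, init = "he")
    vc <- mk_conv(paste0(nm, ".v"), half, half, k = 3L, pad = 1L, init = "he")
    branches[[b]] <- list(P = P, patch = patch, unpatch = unpatch,
                          qc = qc, kc = kc, vc = vc)
    params <- c(params, patch$params, unpatch$params, qc$params, kc$params,
                vc$params)
  }
  ff1 <- mk_base_conv("vit.ff1", C, C, slope = leaky_slope)
  ff2 <- mk_base_conv("vit.ff2", C, C, slope = leaky_slope)
  params <- c(params, ff1$params, ff2$params)

  fwd <- function(f1, training = FALSE) {
    xd <- dim4(f1$v)
    halves <- list(op_slice_ch(f1, seq_len(half)),
                   op_slice_ch(f1, half + seq_len(half)))
    outs <- vector("list", length(branches))
    for (b in seq_along(branches)) {
      br <- branches[[b]]
      if (xd[1] %% br$P != 0 || xd[2] %% br$P != 0)
        stop("F1 spatial size (", xd[1], "x", xd[2],
             ") not divisible by patch size ", br$P)
      tok <- br$patch$fwd(halves[[b]])
      q <- br$qc$fwd(tok); k <- br$kc$fwd(tok); v <- br$vc$fwd(tok)
      att <- op_attention(q, k, v, heads)
      outs[[b]] <- br$unpatch$fwd(att)
    }
    f_mha <- op_concat_ch(outs)
    f_ff <- ff2$fwd(ff1$fwd(f_mha, training), training)
    fv <- op_add(op_add(f1, f_mha), f_ff)
    list(fv = fv, f_mha = f_mha, f_ff = f_ff)
  }

  structure(list(params = params, fwd = fwd,
                 config = list(C = C, heads = heads, patch_sizes = patch_sizes,
                               leaky_slope = leaky_slope, patch_proj = patch_proj)),
            class = "vit_stream")
}

#' Patchify a feature-map half into a token grid
#'
#' Applies the learned P x P / stride-P linear projection of a built ViT
#' branch to a (H, W, C/2, N) array, returning the (H/P, W/P, C/2, N) token
#' grid.  Exposed mainly for inspection and testing; `fwd` of the stream
#' uses it internally.
#' @param vit object from [build_vit_stream()].
#' @param f1_half array or tensor of the channel half.
#' @param branch which branch's projection to use (1 or 2).
#' @return token grid array.
#' @export
patchify <- function(vit, f1_half, branch = 1L) {
  br <- environment(vit$fwd)$branches[[branch]]
  xd <- dim4(if (is_tnsr(f1_half)) f1_half$v else f1_half)
  if (xd[1] %% br$P != 0 || xd[2] %% br$P != 0)
    stop("spatial size not divisible by patch size ", br$P)
  br$patch$fwd(as_tnsr(f1_half))$v
}

#' @rdname patchify
#' @param tokens token grid from [patchify()].
#' @export
unpatchify <- function(vit, tokens, branch = 1L) {
  br <- environment(vit$fwd)$branches[[branch]]
  br$unpatch$fwd(as_tnsr(tokens))$v
}

#' Scaled dot-product multi-head attention over a token grid
#'
#' Computes softmax(Q K^T / sqrt(dk)) V per head over the flattened token
#' positions.  Q, K and V must have the same (H, W, C, N) shape; dk is the
#' per-head channel count C/heads.
#'
#' @param q,k,v arrays (H, W, C, N).
#' @param heads number of heads; must divide C.
#' @param return_weights if TRUE also return the per-sample, per-head
#'   row-stochastic attention matrices.
#' @return the attended array, or a list `(out, weights)`.
#' @export
multi_head_attention <- function(q, k, v, heads = 4L, return_weights = FALSE) {
  out <- op_attention(as_tnsr(q), as_tnsr(k), as_tnsr(v), heads)$v
  if (!return_weights) return(out)
  list(out = out, weights = attention_weights(q, k, heads))
}
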