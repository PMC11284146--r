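# Grad-CAM for the segmentation decoder.  The target score is the sum of
# logits over the predicted foreground; channel weights are the
# global-average-pooled gradients of that score with respect to a decoder
# stage's feature map, and the heatmap is the ReLU of the weighted channel
# sum, upsampled to the input resolution and min-max normalized.

jet_map <- function(v) {
  cl <- function(x) pmin(1, pmax(0, x))
  cbind(cl(1.5 - abs(4 * v - 3)), cl(1.5 - abs(4 * v - 2)),
        cl(1.5 - abs(4 * v - 1)))
}

#' Grad-CAM heatmap of a decoder stage
#'
#' @param model a `seg_model` with a `stages` registry (decoder2 is the
#'   lowest-resolution decoder output, decoder4 the highest).
#' @param image one (H, W, 3) image.
#' @param stage stage name; see `names(model$stages)`.
#' @param threshold probability threshold defining the predicted foreground
#'   whose logit sum is the explained score; if the predicted mask is
#'   empty, all pixels are used.
#' @return object of class `cam_result`: list with `stage`, `heatmap`
#'   ((H, W), values in \[0, 1\]), `overlay` ((H, W, 3) blend with a jet
#'   colormap), and `constant` (TRUE when the raw map had no range, in
#'   which case the heatmap is all zeros).
#' @export
grad_cam <- function(model, image, stage = "decoder4", threshold = 0.5) {
  if (!stage %in% names(model$stages))
    stop("unknown stage '", stage, "'; registered stages: ",
         paste(names(model$stages), collapse = ", "))
  x <- as_image_batch(image)
  if (dim(x)[4] != 1) stop("grad_cam expects a single image")
  tape_on()
  st <- model$forward(x, training = FALSE)
  node <- model$stages[[stage]](st)
  node$keep_grad <- TRUE
  mask <- (st$prob$v >= threshold) * 1
  if (sum(mask) == 0) mask <- array(1, dim(mask))
  score <- op_sum_masked(st$logits, mask)
  backward(score)
  g <- node$grad
  act <- node$v
  tape_off()
  wts <- apply(g[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (c in seq_along(wts)) cam <- cam + wts[c] * act[, , c, 1]
  cam[cam < 0] <- 0
  dim(cam) <- c(dim(cam), 1, 1)
  H <- dim(x)[1]; W <- dim(x)[2]
  cam <- cpp_bilinear_fwd(cam, as.integer(dim(cam)), as.integer(H), as.integer(W))
  cam <- cam[, , 1, 1]
  rng <- range(cam)
  constant <- (rng[2] - rng[1]) <= 0
  heat <- if (constant) matrix(0, H, W) else (cam - rng[1]) / (rng[2] - rng[1])
  cols <- jet_map(as.vector(heat))
  overlay <- array(0, c(H, W, 3))
  for (ch in 1:3)
    overlay[, , ch] <- 0.5 * x[, , ch, 1] + 0.5 * matrix(cols[, ch], H, W)
  structure(list(stage = stage, heatmap = heat, overlay = overlay,
                 constant = constant),
            class = "cam_result")
}

#' Grad-CAM across several decoder stages
#'
#' @param model,image,threshold see [grad_cam()].
#' @param stages character vector of stage names (default: all registered).
#' @return named list of `cam_result`s, all at the input resolution.
#' @export
grad_cam_stages <- function(model, image, stages = names(model$stages),
                            threshold = 0.5) {
  stats::setNames(lapply(stages, function(s)
    grad_cam(model, image, stage = s, threshold = threshold)), stages)
}

#' Fraction of images whose Grad-CAM mass concentrates inside the lesion
#'
#' For each sample, computes the decoder heatmap and compares its mean
#' value inside the true mask with the mean outside; returns the fraction
#' of samples where inside > outside.
#' @param model a trained `seg_model`.
#' @param samples labelled samples.
#' @param stage decoder stage to explain.
#' @return list with `fraction` and the per-sample logical vector.
#' @export
gradcam_inside_fraction <- function(model, samples, stage = "decoder4") {
  inside_gt <- vapply(samples, function(s) {
    cam <- grad_cam(model, s$image, stage = stage)
    m <- s$mask > 0
    if (cam$constant || !any(m) || all(m)) return(NA)
    mean(cam$heatmap[m]) > mean(cam$heatmap[!m])
  }, logical(1))
  list(fraction = mean(inside_gt, na.rm = TRUE), inside = inside_gt)
}
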