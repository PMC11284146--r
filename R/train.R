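# Training loop (Adam with decoupled weight decay, step learning-rate
# decay, online augmentation, Dice loss), evaluation and k-fold
# cross-validation.

adam_new <- function(params, lr = 1e-4, weight_decay = 0.1,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) array(0, dim(p$v)))
  st$u <- lapply(params, function(p) array(0, dim(p$v)))
  st$t <- 0L
  st$lr <- lr
  st$wd <- weight_decay
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, lr = st$lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$u[[i]] <- st$beta2 * st$u[[i]] + (1 - st$beta2) * g * g
    step <- lr * (st$m[[i]] / bc1) / (sqrt(st$u[[i]] / bc2) + st$eps)
    p$v <- p$v - step - lr * st$wd * p$v
  }
  invisible(NULL)
}

#' Learning rate at a given epoch under step decay
#'
#' @param epoch 1-based epoch number.
#' @param lr initial learning rate.
#' @param lr_step decay interval in epochs.
#' @param lr_gamma multiplicative decay factor.
#' @return the learning rate used during `epoch`.
#' @export
lr_at_epoch <- function(epoch, lr = 1e-4, lr_step = 90L, lr_gamma = 0.1) {
  lr * lr_gamma^((epoch - 1) %/% lr_step)
}

# hard-Dice validation score (mean over samples)
mean_val_dice <- function(model, samples, batch_size = 8L) {
  pr <- predict(model, samples, batch_size = batch_size)
  tm <- as_mask_batch(samples)
  N <- dim(tm)[4]
  mean(vapply(seq_len(N), function(n) {
    cs <- confusion_counts(pr$mask[, , , n], tm[, , , n])
    overlap_metrics(cs)$dice
  }, numeric(1)))
}

#' Fit a segmentation model
#'
#' Trains with the Dice loss and Adam (decoupled weight decay), applying
#' the online augmentation policy (vertical flip and +-30 degree rotation,
#' each with probability 0.5) per iteration, and decaying the learning
#' rate by `lr_gamma` every `lr_step` epochs.  When validation samples are
#' given, the parameter state with the best validation Dice is kept and
#' restored at the end.  A non-finite loss aborts training and restores the
#' last finite state.
#'
#' @param model a `seg_model` (modified in place and returned inside the
#'   fit object).
#' @param train_samples list of samples (`image`, `mask`).
#' @param val_samples optional validation samples.
#' @param epochs,lr,weight_decay,lr_step,lr_gamma,batch_size training
#'   protocol; the defaults are the full-scale protocol (190 epochs,
#'   lr 1e-4, weight decay 0.1, decay 0.1x every 90 epochs, batch 8).
#' @param warmup_epochs linear learning-rate warmup over this many initial
#'   epochs (0 disables).  Dice-trained networks can saturate to an
#'   all-background prediction if early Adam steps overshoot; a short
#'   warmup prevents the collapse.
#' @param augment_p per-transform augmentation probability (0 disables).
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param verbose print per-epoch progress.
#' @return object of class `seg_fit`.
#' @export
fit_segmenter <- function(model, train_samples, val_samples = NULL,
                          epochs = 190L, lr = 1e-4, weight_decay = 0.1,
                          lr_step = 90L, lr_gamma = 0.1, batch_size = 8L,
                          warmup_epochs = 0L, augment_p = 0.5, seed = 1L,
                          verbose = FALSE) {
  set.seed(seed)
  opt <- adam_new(model$params, lr = lr, weight_decay = weight_decay)
  n <- length(train_samples)
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     val_dice = numeric())
  best <- list(dice = -Inf, state = NULL, epoch = NA_integer_)
  last_good <- NULL
  aborted <- FALSE

  for (ep in seq_len(epochs)) {
    lr_e <- lr_at_epoch(ep, lr, lr_step, lr_gamma)
    if (warmup_epochs > 0) lr_e <- lr_e * min(1, ep / warmup_epochs)
    ord <- sample.int(n)
    losses <- c()
    for (at in seq(1, n, by = batch_size)) {
      idx <- ord[at:min(n, at + batch_size - 1L)]
      batch <- lapply(train_samples[idx], function(s)
        if (augment_p > 0) augment(s, p = augment_p) else s)
      x <- as_image_batch(batch)
      y <- as_mask_batch(batch)
      zero_grads(model$params)
      tape_on()
      st <- model$forward(x, training = TRUE)
      loss <- op_dice_loss(st$prob, y)
      lv <- as.numeric(loss$v)
      if (!is.finite(lv)) {
        tape_off()
        aborted <- TRUE
        warning("non-finite loss at epoch ", ep,
                "; restoring last finite parameter state")
        if (!is.null(last_good)) load_state_dict(model, last_good)
        break
      }
      backward(loss)
      tape_off()
      adam_step(opt, lr = lr_e)
      losses <- c(losses, lv)
    }
    if (aborted) break
    last_good <- deep_copy_state(model)
    vd <- NA_real_
    if (!is.null(val_samples)) {
      vd <- mean_val_dice(model, val_samples, batch_size)
      if (vd > best$dice) best <- list(dice = vd, state = last_good, epoch = ep)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   lr = lr_e, val_dice = vd))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.2e  val dice %s", ep,
                      mean(losses), lr_e,
                      if (is.na(vd)) "-" else sprintf("%.4f", vd)))
  }
  if (!is.null(best$state)) load_state_dict(model, best$state)
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 best_val_dice = if (is.finite(best$dice)) best$dice else NA,
                 aborted = aborted,
                 config = list(epochs = epochs, lr = lr,
                               weight_decay = weight_decay, lr_step = lr_step,
                               lr_gamma = lr_gamma, batch_size = batch_size,
                               warmup_epochs = warmup_epochs,
                               augment_p = augment_p, seed = seed)),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat("<seg_fit> ", class(x$model)[1], ", ", nrow(x$history), " epochs",
      if (x$aborted) " (aborted on non-finite loss)", "\n", sep = "")
  if (nrow(x$history)) {
    cat("  final training Dice loss:",
        sprintf("%.4f", utils::tail(x$history$loss, 1)), "\n")
    if (!all(is.na(x$history$val_dice)))
      cat("  best validation Dice:", sprintf("%.4f", x$best_val_dice),
          "at epoch", x$best_epoch, "\n")
  }
  invisible(x)
}

#' @export
summary.seg_fit <- function(object, ...) {
  print(object)
  print(utils::tail(object$history, 5))
  invisible(object)
}

#' @export
plot.seg_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "mean Dice loss", ...)
  if (!all(is.na(h$val_dice))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_dice, type = "l", col = "blue", axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4, col.axis = "blue")
    graphics::mtext("validation Dice", 4, line = -1.5, col = "blue")
  }
  invisible(x)
}

#' @export
predict.seg_fit <- function(object, newdata, ...) predict(object$model, newdata, ...)

#' Evaluate a model on labelled samples
#'
#' @param model a `seg_model` or `seg_fit`.
#' @param samples list of samples with `mask`s.
#' @param threshold binarization threshold.
#' @param hd95_backend point sets for HD95, see [hd95()].
#' @param batch_size forward batch size.
#' @param write_dir optional directory: predicted masks are written as
#'   0/255 PNGs.
#' @return list with `per_image` (data.frame keyed by image_id),
#'   `aggregate` (mean/sd per metric; HD95 averaged over defined values)
#'   and `n_hd95_undefined`.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5,
                           hd95_backend = "boundary", batch_size = 8L,
                           write_dir = NULL) {
  if (inherits(model, "seg_fit")) model <- model$model
  if (length(samples) == 0) stop("empty evaluation set")
  pr <- predict(model, samples, threshold = threshold, batch_size = batch_size)
  rows <- lapply(seq_along(samples), function(i) {
    pm <- pr$mask[, , 1, i]
    r <- metrics_report(pm, samples[[i]]$mask, hd95_backend = hd95_backend)
    cbind(data.frame(image_id = samples[[i]]$image_id), r)
  })
  per_image <- do.call(rbind, rows)
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(samples))
      png::writePNG(pr$mask[, , 1, i],
                    file.path(write_dir, paste0(samples[[i]]$image_id, "_pred.png")))
  }
  mets <- c("dice", "iou", "precision", "specificity")
  agg <- data.frame(metric = c(mets, "hd95"),
                    mean = c(vapply(mets, function(m) mean(per_image[[m]]), 0),
                             mean(per_image$hd95, na.rm = TRUE)),
                    sd = c(vapply(mets, function(m) stats::sd(per_image[[m]]), 0),
                           stats::sd(per_image$hd95, na.rm = TRUE)))
  list(per_image = per_image, aggregate = agg,
       n_hd95_undefined = sum(per_image$hd95_undefined))
}

#' k-fold cross-validation
#'
#' Trains one model per held-out fold and reports per-fold and pooled
#' metrics.
#'
#' @param samples full dataset (list of samples).
#' @param builder function(seed) returning a fresh untrained `seg_model`.
#' @param k number of folds.
#' @param seed seed for the fold plan and per-fold training.
#' @param ... passed to [fit_segmenter()] (epochs, lr, ...).
#' @return list with `fold_plan`, `per_fold` (data.frame of fold-level
#'   means) and `pooled` (means over folds).
#' @export
cross_validate <- function(samples, builder, k = 6L, seed = 1L, ...) {
  if (k > length(samples)) stop("k exceeds the number of samples")
  plan <- make_fold_plan(length(samples), k = k, seed = seed)
  rows <- list()
  for (f in 0:(k - 1)) {
    sp <- fold_split(plan, f)
    model <- builder(seed + f)
    fit <- fit_segmenter(model, samples[sp$train], seed = seed + f, ...)
    ev <- evaluate_model(fit, samples[sp$test])
    m <- stats::setNames(ev$aggregate$mean, ev$aggregate$metric)
    rows[[f + 1]] <- data.frame(fold = f, n_train = length(sp$train),
                                n_test = length(sp$test), t(m))
  }
  per_fold <- do.call(rbind, rows)
  pooled <- colMeans(per_fold[, -(1:3), drop = FALSE], na.rm = TRUE)
  list(fold_plan = plan, per_fold = per_fold, pooled = pooled)
}

#' Scaled-down synthetic training benchmark
#'
#' The desk-scale counterpart of the full protocol: 80 synthetic
#' pseudo-color elastography images at 128 x 128 (64 train / 16 held out
#' via a seeded 5-fold plan), a width-reduced model (DFA-UNet with C = 32,
#' or the U-Net baseline width-reduced by the same factor to base 16),
#' 30 epochs of Adam at lr 1e-3 with weight decay 1e-2 and a 4-epoch
#' linear warmup, batch 8, and the standard augmentation policy.
#'
#' @param seed seed for data generation, folds and training.
#' @param model `"dfa"` or `"unet"`.
#' @param epochs training epochs.
#' @param n_images total synthetic images (64/16 split when 80).
#' @param image_size image side in pixels.
#' @param verbose print progress.
#' @return list with `fit`, `eval` (held-out metrics), `mean_dice`,
#'   `train_idx`, `test_idx` and the generated `samples`.
#' @export
synthetic_benchmark <- function(seed = 1L, model = c("dfa", "unet"),
                                epochs = 30L, n_images = 80L,
                                image_size = 128L, verbose = FALSE) {
  model <- match.arg(model)
  cfg <- synth_config(n_images = n_images, image_size = image_size,
                      seed = seed)
  samples <- generate_synthetic_dataset(cfg)
  plan <- make_fold_plan(n_images, k = 5L, seed = seed)
  sp <- fold_split(plan, 0L)
  net <- if (model == "dfa") dfa_unet(base_width = 32L, seed = seed)
         else build_unet_baseline(base_width = 16L, seed = seed)
  fit <- fit_segmenter(net, samples[sp$train], val_samples = samples[sp$test],
                       epochs = epochs, lr = 1e-3, weight_decay = 1e-2,
                       lr_step = 90L, lr_gamma = 0.1, batch_size = 8L,
                       warmup_epochs = 4L, augment_p = 0.5, seed = seed,
                       verbose = verbose)
  ev <- evaluate_model(fit, samples[sp$test])
  list(fit = fit, eval = ev,
       mean_dice = ev$aggregate$mean[ev$aggregate$metric == "dice"],
       train_idx = sp$train, test_idx = sp$test, samples = samples)
}
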