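# Training loop, scheduler, evaluation and cross-validation bookkeeping.

smoke_fit <- function() cached("smoke_fit", {
  fit_segmenter(dfa_unet(base_width = 32L, seed = 5), tiny_dataset(16, 64, seed = 31),
                epochs = 5L, lr = 1e-3, weight_decay = 1e-2, batch_size = 8L,
                seed = 5)
})

test_that("a short smoke run reduces the training Dice loss", {
  fit <- smoke_fit()
  expect_s3_class(fit, "seg_fit")
  expect_equal(nrow(fit$history), 5)
  expect_lt(fit$history$loss[5], fit$history$loss[1])
  expect_false(fit$aborted)
})

test_that("the step scheduler follows the decay-every-90-epochs protocol", {
  expect_equal(lr_at_epoch(1), 1e-4)
  expect_equal(lr_at_epoch(90), 1e-4)
  expect_equal(lr_at_epoch(91), 1e-5)              # gamma x initial lr
  expect_equal(lr_at_epoch(180), 1e-5)
  expect_equal(lr_at_epoch(181), 1e-6)
  expect_equal(lr_at_epoch(40, lr = 2e-3, lr_step = 10, lr_gamma = 0.5),
               2e-3 * 0.5^3)
})

test_that("training is reproducible under a fixed seed", {
  ds <- tiny_dataset(8, 64, seed = 33)
  f1 <- fit_segmenter(dfa_unet(base_width = 8L, stage_depths = c(1L, 1L, 1L, 1L),
                               vit_heads = 2L, seed = 9),
                      ds, epochs = 1L, lr = 1e-3, seed = 4)
  f2 <- fit_segmenter(dfa_unet(base_width = 8L, stage_depths = c(1L, 1L, 1L, 1L),
                               vit_heads = 2L, seed = 9),
                      ds, epochs = 1L, lr = 1e-3, seed = 4)
  expect_identical(f1$history$loss[1], f2$history$loss[1])
})

test_that("evaluation handles perfect, empty and missing predictions", {
  ds <- tiny_dataset(4, 64, seed = 35)
  # oracle model: returns the truth as its prediction
  oracle <- structure(list(
    forward = NULL, params = list(),
    config = list(base_width = 0)), class = c("mock", "seg_model"))
  oracle$forward <- local({
    ds_local <- ds
    function(x, training = FALSE) {
      n <- dim(x)[4]
      idx <- vapply(seq_len(n), function(i) {
        which(vapply(ds_local, function(s)
          isTRUE(all.equal(s$image, x[, , , i])), logical(1)))[1]
      }, integer(1))
      pm <- array(0, c(dim(x)[1], dim(x)[2], 1, n))
      for (i in seq_len(n)) pm[, , 1, i] <- ds_local[[idx[i]]]$mask
      list(prob = dfaunet:::as_tnsr(pm),
           logits = dfaunet:::as_tnsr(pm * 20 - 10))
    }
  })
  ev <- evaluate_model(oracle, ds)
  expect_equal(ev$aggregate$mean[ev$aggregate$metric == "dice"], 1)
  expect_equal(ev$aggregate$mean[ev$aggregate$metric == "hd95"], 0)
  # the all-background model scores zero Dice with flagged HD95
  zero <- oracle
  zero$forward <- function(x, training = FALSE) {
    pm <- array(0, c(dim(x)[1], dim(x)[2], 1, dim(x)[4]))
    list(prob = dfaunet:::as_tnsr(pm), logits = dfaunet:::as_tnsr(pm - 10))
  }
  ev0 <- evaluate_model(zero, ds)
  expect_equal(ev0$aggregate$mean[ev0$aggregate$metric == "dice"], 0)
  expect_equal(ev0$n_hd95_undefined, 4)
  expect_error(evaluate_model(zero, list()), "empty")
})

test_that("cross-validation produces one report per fold and a pooled row", {
  ds <- tiny_dataset(8, 64, seed = 37)
  res <- cross_validate(ds,
                        builder = function(s)
                          dfa_unet(base_width = 8L, stage_depths = c(1L, 1L, 1L, 1L),
                                   vit_heads = 2L, seed = s),
                        k = 2L, seed = 3, epochs = 1L, lr = 1e-3)
  expect_equal(nrow(res$per_fold), 2)
  expect_equal(res$per_fold$n_train, c(4, 4))
  expect_equal(res$per_fold$n_test, c(4, 4))
  # every sample tested exactly once
  expect_setequal(unlist(lapply(0:1, function(f) fold_split(res$fold_plan, f)$test)),
                  1:8)
  # equal-sized folds: pooled mean is the unweighted mean of fold means
  expect_equal(unname(res$pooled["dice"]), mean(res$per_fold$dice))
})

test_that("fit objects expose the standard modelling methods", {
  fit <- smoke_fit()
  expect_output(print(fit), "seg_fit")
  expect_output(summary(fit), "epoch")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  ds <- tiny_dataset(16, 64, seed = 31)
  pr <- predict(fit, ds[1:2])
  expect_equal(dim(pr$prob), c(64, 64, 1, 2))
  expect_true(all(pr$mask %in% c(0, 1)))
})

test_that("checkpoints restore a trained model exactly", {
  fit <- smoke_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  dfaunet:::save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  ds <- tiny_dataset(16, 64, seed = 31)
  expect_identical(predict(back, ds[1:2])$prob, predict(fit, ds[1:2])$prob)
})
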