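# Loss and metric suite: Dice loss arithmetic, confusion counting against
# enumeration, overlap identities and HD95 against an all-pairs oracle.

test_that("dice loss reproduces hand-computed values", {
  m <- matrix(0, 4, 4)
  t4 <- m; t4[2:3, 2:3] <- 1                      # 4 foreground px
  p2 <- m; p2[2, 2:3] <- 1                        # 2 px inside the truth
  expect_equal(dice_loss(p2, t4, eps = 0), 1 - 2 * 2 / (4 + 2))
  expect_equal(dice_loss(t4, t4, eps = 0), 0)
  disj <- m; disj[1, 1:4] <- 1                    # equal area, disjoint
  expect_equal(dice_loss(disj, t4, eps = 0), 1)
  expect_equal(dice_loss(m, m), 0)                # both empty with eps > 0
  # soft probabilities: differentiable interpolation between the extremes
  p_soft <- m + 0.25
  expect_lt(dice_loss(p_soft, t4), 1)
  expect_error(dice_loss(p_soft * 5, t4), "\\[0, 1\\]")
})

test_that("moving probability mass into the truth region lowers the loss", {
  set.seed(8)
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64, 0.2, 0.4), 8, 8)
  p_better <- p
  p_better[t == 1] <- p_better[t == 1] + 0.2
  expect_lt(dice_loss(p_better, t), dice_loss(p, t))
})

test_that("confusion counts agree with per-pixel enumeration", {
  pm <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  tm <- matrix(c(1, 0, 0, 0, 1, 1, 0, 0, 0), 3, 3)
  cs <- confusion_counts(pm, tm)
  # brute force over all 9 pixels
  ref <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in 1:9) {
    ref["tp"] <- ref["tp"] + (pm[i] == 1 && tm[i] == 1)
    ref["fp"] <- ref["fp"] + (pm[i] == 1 && tm[i] == 0)
    ref["fn"] <- ref["fn"] + (pm[i] == 0 && tm[i] == 1)
    ref["tn"] <- ref["tn"] + (pm[i] == 0 && tm[i] == 0)
  }
  expect_equal(unlist(cs), ref[c("tp", "fp", "tn", "fn")],
               ignore_attr = TRUE)
  expect_equal(cs$tp + cs$fp + cs$tn + cs$fn, 9)
  same <- confusion_counts(tm, tm)
  expect_equal(same$fp + same$fn, 0)
  comp <- confusion_counts(1 - tm, tm)
  expect_equal(comp$tp + comp$tn, 0)
  expect_error(confusion_counts(pm * 0.5, tm), "not binary")
})

test_that("overlap metrics satisfy their algebraic identities", {
  om <- overlap_metrics(list(tp = 2, fp = 1, tn = 5, fn = 1))
  expect_equal(om$dice, 2 / 3)
  expect_equal(om$iou, 1 / 2)
  expect_equal(om$precision, 2 / 3)
  expect_equal(om$specificity, 5 / 6)
  perfect <- overlap_metrics(list(tp = 7, fp = 0, tn = 2, fn = 0))
  expect_equal(unlist(perfect[c("dice", "iou", "precision", "specificity")]),
               c(dice = 1, iou = 1, precision = 1, specificity = 1))
  set.seed(4)
  for (i in 1:20) {
    cs <- as.list(setNames(rpois(4, 10), c("tp", "fp", "tn", "fn")))
    om <- overlap_metrics(cs)
    expect_equal(om$dice, 2 * om$iou / (1 + om$iou), tolerance = 1e-12)
    expect_gte(om$dice, om$iou)
  }
  empty <- overlap_metrics(list(tp = 0, fp = 0, tn = 9, fn = 0))
  expect_equal(empty$dice, 1)
  expect_true(empty$empty)
  miss <- overlap_metrics(list(tp = 0, fp = 0, tn = 5, fn = 4))
  expect_equal(miss$dice, 0)
})

test_that("hd95 reproduces known distances and undefined flags", {
  m <- matrix(0, 8, 8)
  a <- m; a[1, 1] <- 1
  b <- m; b[4, 5] <- 1                             # offset (3, 4): distance 5
  expect_equal(hd95(a, b), 5)
  expect_equal(hd95(b, b), 0)
  out <- hd95(a, m)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
  # a square vs the same square shifted by 2 px, against the oracle
  sq <- matrix(0, 16, 16); sq[4:13, 4:13] <- 1
  sh <- matrix(0, 16, 16); sh[6:15, 4:13] <- 1
  expect_equal(hd95(sq, sh), hd95_oracle(sq, sh, "boundary"))
  expect_equal(hd95(sq, sh, backend = "foreground"),
               hd95_oracle(sq, sh, "foreground"))
})

test_that("hd95 is symmetric, translation invariant and oracle-equivalent", {
  exact_directed_max <- function(A, B) {
    max(vapply(seq_len(nrow(A)), function(i)
      sqrt(min((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2)), numeric(1)))
  }
  for (trial in 1:50) {
    a <- random_blob(12, seed = trial)
    b <- random_blob(12, seed = trial + 100)
    if (!any(a > 0) || !any(b > 0)) next
    h1 <- hd95(a, b)
    expect_equal(h1, hd95(b, a))
    expect_equal(h1, hd95_oracle(a, b, "boundary"), tolerance = 1e-12)
    expect_equal(hd95(a, b, backend = "foreground"),
                 hd95_oracle(a, b, "foreground"), tolerance = 1e-12)
    # hd95 never exceeds the exact directed-max Hausdorff distance
    A <- which(dfaunet:::mask_boundary(a > 0), arr.ind = TRUE) * 1.0
    B <- which(dfaunet:::mask_boundary(b > 0), arr.ind = TRUE) * 1.0
    hmax <- max(exact_directed_max(A, B), exact_directed_max(B, A))
    expect_lte(h1, hmax + 1e-12)
    # joint translation leaves the distance unchanged
    big_a <- matrix(0, 20, 20); big_a[5:16, 6:17] <- a
    big_b <- matrix(0, 20, 20); big_b[5:16, 6:17] <- b
    expect_equal(hd95(big_a, big_b), h1, tolerance = 1e-12)
  }
})

test_that("metrics_report aggregates per-image values", {
  t <- disk_mask(32, 8)
  p <- disk_mask(32, 8, cx = 18)
  r <- metrics_report(p, t)
  expect_true(all(c("dice", "iou", "precision", "specificity", "hd95") %in%
                    names(r)))
  expect_lt(r$dice, 1)
  expect_false(r$hd95_undefined)
})
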