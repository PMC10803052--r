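test_that("binary cross-entropy matches closed forms and a hand-summed case", {
  expect_lt(bce_loss(matrix(1, 2, 2), matrix(1, 2, 2)), 1e-6)
  expect_equal(bce_loss(matrix(1, 2, 2), matrix(0.5, 2, 2)), log(2),
               tolerance = 1e-12)
  tr <- matrix(c(1, 0, 0, 1), 2, 2)
  pr <- matrix(c(0.9, 0.3, 0.2, 0.8), 2, 2)   # by column
  hand <- -mean(c(log(0.9), log(1 - 0.3), log(1 - 0.2), log(0.8)))
  expect_equal(bce_loss(tr, pr), hand, tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), pr), "binary")
})

test_that("soft Dice matches its closed forms", {
  m <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(dice_loss(m, m), 0.2)          # smoothing keeps it near 0
  expect_lt(dice_loss(m, m, smooth = 1e-9), 1e-8)
  expect_gt(dice_loss(m, 1 - m, smooth = 1e-9), 1 - 1e-8)
  # 4x4, 4 true positives, uniform soft prediction 0.5: 1 - 4/12 = 2/3
  tr <- matrix(0, 4, 4); tr[1:2, 1:2] <- 1
  pr <- matrix(0.5, 4, 4)
  expect_equal(dice_loss(tr, pr, smooth = 1e-12), 2 / 3, tolerance = 1e-9)
})

test_that("compound loss is exactly half BCE plus Dice", {
  set.seed(40)
  tr <- matrix(rbinom(64, 1, 0.4), 8, 8)
  pr <- matrix(runif(64), 8, 8)
  expect_equal(combined_loss(tr, pr),
               0.5 * bce_loss(tr, pr) + dice_loss(tr, pr), tolerance = 0)
  expect_lt(combined_loss(tr, tr), 0.01)
  expect_gte(combined_loss(tr, pr), 0)
})

test_that("IoU and F1 match enumeration on toy masks", {
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1              # 4 px
  b <- matrix(0, 4, 4); b[1, 3:4] <- 1; b[2, 1:2] <- 1  # 4 px, overlap 2
  expect_equal(iou_score(a, b), 2 / 6)
  expect_equal(f1_score(a, b), 0.5)
  expect_equal(iou_score(a, a), 1)
  d <- matrix(0, 4, 4); d[4, ] <- 1
  expect_equal(iou_score(a, d), 0)
  expect_equal(f1_score(a, d), 0)
  z <- matrix(0, 4, 4)
  expect_equal(iou_score(z, z), 1)   # both-empty convention
  expect_equal(f1_score(z, z), 1)
})

test_that("F1 equals 2*IoU/(1+IoU) and scores are permutation invariant", {
  set.seed(41)
  for (k in 1:200) {
    a <- matrix(rbinom(36, 1, runif(1)), 6, 6)
    b <- matrix(rbinom(36, 1, runif(1)), 6, 6)
    iou <- iou_score(a, b)
    expect_equal(f1_score(a, b), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
  a <- matrix(rbinom(36, 1, 0.5), 6, 6)
  b <- matrix(rbinom(36, 1, 0.5), 6, 6)
  p <- sample(36)
  ap <- matrix(a[p], 6, 6); bp <- matrix(b[p], 6, 6)
  expect_equal(iou_score(ap, bp), iou_score(a, b))
  expect_equal(f1_score(ap, bp), f1_score(a, b))
  expect_equal(bce_loss(ap, pmin(pmax(bp, 0.1), 0.9)),
               bce_loss(a, pmin(pmax(b, 0.1), 0.9)))
})

test_that("Dice loss of a binary prediction is the F1 complement", {
  set.seed(42)
  for (k in 1:20) {
    tr <- matrix(rbinom(64, 1, 0.4), 8, 8)
    pm <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (sum(tr) + sum(pm) == 0) next
    expect_equal(dice_loss(tr, pm, smooth = 1e-12) + f1_score(tr, pm), 1,
                 tolerance = 1e-8)
  }
})

test_that("mask evaluation aggregates per-image means and writes reports", {
  tr <- list(matrix(c(1, 1, 0, 0), 2, 2), matrix(0, 2, 2))
  pr <- list(matrix(c(0.9, 0.2, 0.1, 0.1), 2, 2), matrix(0.1, 2, 2))
  rep <- evaluate_masks(tr, pr, ids = c("a", "b"))
  expect_equal(nrow(rep$per_image), 2)
  expect_equal(rep$aggregate[["mean_iou"]], mean(rep$per_image$iou))
  expect_equal(rep$per_image$iou[1], 0.5)   # 1 of 2 positives found
  expect_equal(rep$per_image$f1[2], 1)      # both empty after thresholding
  dir <- tempfile()
  paths <- write_metrics(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["csv"]])
  expect_equal(back$iou, rep$per_image$iou)
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$mean_f1, rep$aggregate[["mean_f1"]])
})
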