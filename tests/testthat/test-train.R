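test_that("splits have rounded-ratio sizes, are disjoint and cover", {
  samples <- as.list(letters[1:10])
  sp <- split_dataset(samples, c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(lengths(sp), c(train = 7, val = 2, test = 1))
  expect_setequal(unlist(sp), letters[1:10])
  expect_equal(anyDuplicated(unlist(sp)), 0)
  sp2 <- split_dataset(samples, c(0.7, 0.2, 0.1), seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(samples, c(0.7, 0.2, 0.1), seed = 2)
  expect_false(identical(sp, sp3))
  expect_error(split_dataset(samples[1:2], c(0.7, 0.2, 0.1), 1), "at least 3")
  expect_error(split_dataset(samples, c(0.5, 0.5, 0.5), 1), "summing to 1")
})

test_that("a zero-epoch run returns an empty history and no checkpoint", {
  ds <- generate_dataset(synthetic_config(n_images = 4, image_size = c(16, 16),
                                          seed = 1))
  rec <- train(net_config(depth = 1, base_channels = 4, in_channels = 1,
                          dropout_rate = 0),
               train_config(split = c(1, 0, 0), epochs = 0, seed = 1), ds)
  expect_equal(nrow(rec$history), 0)
  expect_true(is.na(rec$best_epoch))
  expect_null(rec$best_state)
})

test_that("the initial loss sits at the random-prediction closed form", {
  ds <- generate_dataset(synthetic_config(n_images = 4, image_size = c(16, 16),
                                          seed = 2))
  mc <- net_config(depth = 1, base_channels = 4, in_channels = 1,
                   dropout_rate = 0)
  rec <- train(mc, train_config(split = c(1, 0, 0), epochs = 1, max_steps = 1,
                                batch_size = 4, seed = 3, lr = 0), ds)
  # the zero-initialised head emits p = 0.5 everywhere at step 0, so the
  # loss is 0.5*ln 2 plus the Dice of a uniform half prediction
  f <- mean(vapply(ds, function(s) mean(s$mask), numeric(1)))
  predicted <- 0.5 * log(2) + 1 - f / (f + 0.5)
  expect_lt(abs(rec$history$train_loss[1] - predicted), 0.02)
})

test_that("a short run reduces the training loss", {
  ds <- generate_dataset(synthetic_config(n_images = 6, image_size = c(16, 16),
                                          seed = 4, radius_range = c(0.2, 0.35)))
  mc <- net_config(depth = 1, base_channels = 4, in_channels = 1,
                   dropout_rate = 0)
  rec <- train(mc, train_config(split = c(1, 0, 0), epochs = 80, max_steps = 80,
                                batch_size = 6, seed = 5, lr = 5e-3,
                                lr_schedule = "constant"), ds)
  expect_lt(min(rec$history$train_loss), rec$history$train_loss[1] * 0.5)
  expect_true(all(is.finite(rec$history$train_loss)))
})

test_that("checkpoints round-trip bit-exactly", {
  ds <- generate_dataset(synthetic_config(n_images = 4, image_size = c(16, 16),
                                          seed = 6))
  mc <- net_config(depth = 1, base_channels = 4, in_channels = 1,
                   dropout_rate = 0)
  rec <- train(mc, train_config(split = c(1, 0, 0), epochs = 5, batch_size = 4,
                                seed = 7, lr = 1e-3), ds)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(rec$model, path)
  back <- load_checkpoint(path)
  p1 <- predict_prob(rec$model, ds[[1]]$image)
  p2 <- predict_prob(back, ds[[1]]$image)
  expect_identical(p1, p2)
})

test_that("evaluation conventions: perfect, empty and padded inputs", {
  ds <- generate_dataset(synthetic_config(n_images = 3, image_size = c(16, 16),
                                          seed = 8))
  truths <- lapply(ds, function(s) s$mask)
  # ground truth as its own prediction
  rep1 <- evaluate_masks(truths, truths)
  expect_equal(unname(rep1$aggregate), c(1, 1))
  # constant-zero predictor on nonempty masks
  zeros <- lapply(truths, function(m) m * 0)
  rep0 <- evaluate_masks(truths, zeros)
  expect_equal(unname(rep0$aggregate), c(0, 0))
  # report means equal hand-computed means of the per-image table
  expect_equal(rep0$aggregate[["mean_f1"]], mean(rep0$per_image$f1))

  # evaluate() reflect-pads sizes that violate divisibility
  set.seed(9)
  model <- cm_unet(net_config(depth = 1, base_channels = 4, in_channels = 1,
                              dropout_rate = 0))   # divisor 8
  odd <- list(structure(list(image = array(runif(20 * 12), c(20, 12, 1)),
                             mask = matrix(0, 20, 12), id = "odd"),
                        class = "segmentation_sample"))
  expect_message(rep <- evaluate(model, odd), "reflect-padded")
  expect_equal(nrow(rep$per_image), 1)
})

test_that("two runs with one seed are identical; different seeds differ", {
  ds <- generate_dataset(synthetic_config(n_images = 6, image_size = c(16, 16),
                                          seed = 10))
  mc <- net_config(depth = 1, base_channels = 4, in_channels = 1,
                   dropout_rate = 0)
  tc <- train_config(split = c(1, 0, 0), epochs = 5, batch_size = 6, seed = 11,
                     lr = 1e-3)
  r1 <- train(mc, tc, ds)
  r2 <- train(mc, tc, ds)
  expect_identical(r1$history, r2$history)
  expect_identical(mlpunet:::model_state(r1$model),
                   mlpunet:::model_state(r2$model))
  tc2 <- train_config(split = c(1, 0, 0), epochs = 5, batch_size = 6,
                      seed = 12, lr = 1e-3)
  r3 <- train(mc, tc2, ds)
  expect_false(identical(r1$history, r3$history))
})

test_that("the command-line interface surfaces the package operations", {
  out <- capture.output(status <- cli(c("count", "--depth", "2", "--base", "8")))
  expect_equal(status, 0L)
  expect_true(any(grepl("parameters", out)))
  d1 <- tempfile(); d2 <- tempfile()
  capture.output({
    s1 <- cli(c("generate", "--out", d1, "--n", "3", "--seed", "4", "--size", "16"))
    s2 <- cli(c("generate", "--out", d2, "--n", "3", "--seed", "4", "--size", "16"))
  })
  expect_equal(c(s1, s2), c(0L, 0L))
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, sort(f1)))
  h2 <- tools::md5sum(file.path(d2, sort(f1)))
  expect_identical(unname(h1), unname(h2))
  expect_equal(suppressMessages(cli(c("bogus"))), 1L)
  expect_equal(suppressMessages(cli(c("eval", "--data"))), 1L)
})

test_that("generate, train and eval chain end-to-end through the CLI", {
  data_dir <- tempfile(); run_dir <- tempfile(); met_dir <- tempfile()
  out <- capture.output(suppressMessages({
    s1 <- cli(c("generate", "--out", data_dir, "--n", "4", "--seed", "3",
                "--size", "16"))
    s2 <- cli(c("train", "--data", data_dir, "--out", run_dir,
                "--depth", "1", "--base", "4", "--epochs", "2",
                "--batch", "2", "--seed", "3", "--lr", "0.001"))
    s3 <- cli(c("eval", "--checkpoint", file.path(run_dir, "best.rds"),
                "--data", data_dir, "--out", met_dir))
  }))
  expect_equal(c(s1, s2, s3), c(0L, 0L, 0L))
  expect_true(file.exists(file.path(run_dir, "history.csv")))
  expect_true(file.exists(file.path(met_dir, "metrics.csv")))
})
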