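test_that("learning-rate schedule decays stepwise by direct evaluation", {
  cfg <- train_config()  # 500 epochs, 1/8 intervals of 62.5 epochs
  expect_equal(lr_schedule(0, cfg), 3e-4)
  expect_equal(lr_schedule(62, cfg), 3e-4)   # floor(62 / 62.5) = 0
  expect_equal(lr_schedule(63, cfg), 1.5e-4) # first boundary crossed
  expect_equal(lr_schedule(125, cfg), 3e-4 * 0.5^2)  # floor(125/62.5) = 2
  trace <- lr_schedule(0:499, cfg)
  expect_true(all(diff(trace) <= 0))
  expect_lte(length(unique(trace)), 9)
  expect_error(train_config(epochs = 4L, interval_fraction = 1 / 8),
               "interval")
})

test_that("binary cross-entropy matches closed form and a loop oracle", {
  gt <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(bce_loss(matrix(0.5, 2, 2), gt), log(2), tolerance = 1e-12)
  # near-perfect prediction approaches zero loss from above
  expect_lt(bce_loss(gt * 0.9999999 + 1e-7, gt), 1e-5)
  for (seed in 1:5) {
    p <- maunet:::with_seed(seed, matrix(runif(16, 0.01, 0.99), 4, 4))
    y <- maunet:::with_seed(seed + 9, matrix(rbinom(16, 1, 0.5), 4, 4))
    acc <- 0
    for (i in 1:4) for (j in 1:4)
      acc <- acc - (y[i, j] * log(p[i, j]) +
                    (1 - y[i, j]) * log(1 - p[i, j]))
    expect_equal(bce_loss(p, y), acc / 16, tolerance = 1e-10)
    expect_gte(bce_loss(p, y), 0)
  }
})

test_that("training records history, follows the schedule and checkpoints", {
  ps <- tiny_patch_set(4)
  cfg <- train_config(lr0 = 1e-3, batch_size = 4L, epochs = 3L,
                      interval_fraction = 1, patience = 50L, seed = 9L,
                      dropout = 0.1)
  fit <- maunet(ps, ps, spec = maunet_spec(width_scale = 0.05), config = cfg)
  expect_s3_class(fit, "maunet")
  expect_lte(nrow(fit$history), 3)
  expect_equal(fit$history$lr, lr_schedule(fit$history$epoch, cfg))
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_true(all(c("train_loss", "val_loss", "val_precision", "val_recall",
                    "val_f1", "val_mean_iou") %in% names(fit$history)))
  # best epoch maximizes validation F1 over the recorded history
  expect_equal(fit$history$val_f1[fit$best_epoch + 1L],
               max(fit$history$val_f1))
  # checkpoint contract: re-evaluating the stored best weights reproduces
  # the recorded best metric
  re <- evaluate_network(fit$network, ps, batch_size = 4L)
  expect_equal(re$f1, fit$best_metrics$f1, tolerance = 1e-6)
  expect_equal(re$mean_iou, fit$best_metrics$mean_iou, tolerance = 1e-6)
  # reproducibility: identical config and data, identical history
  fit2 <- maunet(ps, ps, spec = maunet_spec(width_scale = 0.05),
                 config = cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(coef(fit), coef(fit2))
})

test_that("a frozen model triggers early stopping after patience epochs", {
  ps <- tiny_patch_set(2)
  cfg <- train_config(lr0 = 0, batch_size = 2L, epochs = 10L,
                      interval_fraction = 1, patience = 1L,
                      weight_decay = 0, dropout = 0, seed = 4L)
  fit <- maunet(ps, ps, spec = maunet_spec(width_scale = 0.05), config = cfg)
  # epoch 0 establishes the best; epoch 1 cannot improve -> stop
  expect_equal(nrow(fit$history), 2)
})

test_that("model methods expose coefficients, predictions and history", {
  ps <- tiny_patch_set(2)
  cfg <- train_config(batch_size = 2L, epochs = 2L,
                      interval_fraction = 1, patience = 50L, seed = 12L)
  viz <- withr::local_tempdir()
  fit <- maunet(ps, ps, spec = maunet_spec(width_scale = 0.05), config = cfg,
                viz_dir = viz)
  # the optional visualization callback wrote one panel per epoch
  expect_length(list.files(viz, pattern = "^epoch_.*\\.png$"),
                nrow(fit$history))
  expect_named(coef(fit)["output.conv.w"], "output.conv.w")
  prob <- predict(fit, ps)
  expect_equal(dim(prob), c(64, 64, 2, length(ps)))
  cls <- predict(fit, ps, type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
  expect_output(print(fit), "trainable parameters")
  expect_output(summary(fit), "Per-layer")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
})

test_that("whole-image stitching averages overlapping patch predictions", {
  rec <- generate_sample(synth_config(height = 192L, width = 192L,
                                      n_nuclei = 6L, seed = 31L))
  ps <- tiny_patch_set(2)
  fit <- maunet(ps, ps, spec = maunet_spec(width_scale = 0.05),
                config = train_config(batch_size = 2L, epochs = 1L,
                                      interval_fraction = 1, patience = 50L,
                                      seed = 5L))
  seg <- segment_image(fit, rec, ada_params(k = 128L, s = 64L))
  expect_equal(dim(seg$prob), c(192, 192))
  expect_true(all(seg$prob >= 0 & seg$prob <= 1))
  expect_true(all(seg$mask %in% c(0L, 1L)))
})
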