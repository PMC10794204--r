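test_that("joint loss decomposes as CE + gamma * MSE", {
  set.seed(31)
  n <- 8L
  logits <- matrix(rnorm(n * 3), n)
  kp <- matrix(runif(n * 12), n)
  tgt <- matrix(runif(n * 12), n)
  y <- sample(0:2, n, replace = TRUE)
  for (gamma in c(0, 0.01, 0.5)) {
    jl <- joint_loss(logits, kp, tgt, y, gamma = gamma)
    expect_equal(jl$total, jl$ce + gamma * jl$mse, tolerance = 1e-12)
  }
  # gamma = 0 leaves pure cross-entropy
  jl0 <- joint_loss(logits, kp, tgt, y, gamma = 0)
  expect_equal(jl0$total, jl0$ce)
  # doubling gamma doubles the regression share
  j1 <- joint_loss(logits, kp, tgt, y, gamma = 0.02)
  expect_equal(j1$total - j1$ce, 2 * (joint_loss(logits, kp, tgt, y,
                                                 gamma = 0.01)$total - j1$ce),
               tolerance = 1e-12)
  # hand-computable case: confident correct logits, perfect keypoints
  jl2 <- joint_loss(matrix(c(10, 0, 0), 1), matrix(0.5, 1, 12),
                    matrix(0.5, 1, 12), 0L)
  expect_equal(jl2$mse, 0)
  expect_equal(jl2$ce, log1p(2 * exp(-10)), tolerance = 1e-12)
  # pixel-scale MSE via coord_scale
  jl3 <- joint_loss(logits, kp, tgt, y, gamma = 0.01, coord_scale = 10)
  expect_equal(jl3$mse, 100 * joint_loss(logits, kp, tgt, y)$mse,
               tolerance = 1e-12)
  expect_error(joint_loss(logits, kp, tgt, y, gamma = -1), "gamma")
})

test_that("training log preserves the loss decomposition at every step", {
  cfg <- tiny_generator(seed = 41L)
  tr <- vhsnet:::samples_to_inputs(generate_samples(cfg, 40), 32L)
  va <- vhsnet:::samples_to_inputs(generate_samples(cfg, 12, seed = 42L), 32L)
  va$ids <- paste0("v_", va$ids)
  model <- rvt_model(tiny_config(), seed = 1)
  tc <- train_config("desk", steps = 25L, eval_every = 25L, patience = 0L,
                     batch_size = 8L)
  fit <- rvt_train(model, tr, va, tc, quiet = TRUE)
  expect_equal(fit$log$loss, fit$log$ce + tc$gamma * fit$log$mse,
               tolerance = 1e-6)
})

test_that("training descends and is reproducible under a fixed seed", {
  cfg <- tiny_generator(seed = 43L)
  tr <- vhsnet:::samples_to_inputs(generate_samples(cfg, 60), 32L)
  va <- vhsnet:::samples_to_inputs(generate_samples(cfg, 15, seed = 44L), 32L)
  va$ids <- paste0("v_", va$ids)
  run <- function() {
    model <- rvt_model(tiny_config(), seed = 2)
    tc <- train_config("desk", steps = 120L, eval_every = 60L,
                       patience = 0L, batch_size = 8L)
    rvt_train(model, tr, va, tc, quiet = TRUE)
  }
  f1 <- run()
  expect_lt(mean(tail(f1$log$loss, 10)), mean(head(f1$log$loss, 10)))
  f2 <- run()
  expect_identical(f1$log$loss, f2$log$loss)   # bit-identical trajectories
  # tidy/glance accessors
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(glance(f1)), 1L)
  expect_error(rvt_train(rvt_model(tiny_config(), seed = 1), tr, tr,
                         train_config("desk")), "overlap")
})

test_that("gradients flow through the orthogonal layer inside the full loss", {
  model <- rvt_model(tiny_config(), seed = 9)
  B <- 2L
  X <- random_pixel_batch(B, model$config$input_size)
  y <- c(1L, 2L)
  tgt <- matrix(runif(B * 12), B)
  fw <- rvt_forward(model, X, B)
  ce <- ad_ce(fw$tape, fw$logits, y)
  mse <- ad_mse(fw$tape, fw$keypoints, tgt)
  loss <- ad_axpby(fw$tape, ce, mse, 1, 1)
  ad_backward(fw$tape, loss)
  # the twelve-unit head receives gradient through the projection; the
  # y4 unit (column 8) is rerouted through the slope formula to x3, y3,
  # x4 and the A/B coordinates, so its own column gets no direct gradient
  # while every other unit does
  g <- fw$params[["head.Wkp"]]$grad
  expect_true(all(colSums(abs(g))[-8] > 0))
  expect_equal(unname(colSums(abs(g))[8]), 0)
})

test_that("few-shot bootstrap emits parseable in-bounds coarse records", {
  cfg <- tiny_generator(seed = 51L)
  labeled <- vhsnet:::samples_to_inputs(generate_samples(cfg, 24), 32L)
  unl <- lapply(generate_samples(cfg, 6, seed = 52L), `[[`, "image")
  unl <- lapply(unl, vhsnet:::resize_bilinear, 32L)
  names(unl) <- sprintf("u%02d", seq_along(unl))
  tc <- train_config("desk", ce_weight = 0, gamma = 1, steps = 60L,
                     eval_every = 30L, patience = 0L, batch_size = 8L)
  bs <- few_shot_bootstrap(labeled, unl, tc, tiny_config(),
                           quiet = TRUE)
  expect_equal(nrow(bs$records), 6L)
  expect_true(all(bs$records$status == "coarse"))
  m <- as.matrix(bs$records[, vhsnet:::kp_flat_names])
  expect_true(all(is.finite(m)))
  expect_true(all(m >= -0.1 * 32 & m <= 1.1 * 32))
  expect_true(is.finite(bs$holdout_error_px))
  # records survive the annotation round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(bs$records, path)
  expect_equal(nrow(suppressWarnings(read_annotations(path))), 6L)
  # empty unlabeled set is a warning, not an error
  expect_warning(few_shot_bootstrap(labeled, list(), tc, tiny_config(),
                                    quiet = TRUE), "nothing to bootstrap")

  # a directory with one unreadable file: that file is skipped with a
  # warning, the rest are labeled
  dir <- withr::local_tempdir()
  png::writePNG(unl[[1]], file.path(dir, "good.png"))
  writeLines("not a png", file.path(dir, "broken.png"))
  expect_warning(bs2 <- few_shot_bootstrap(labeled, dir, tc, tiny_config(),
                                           quiet = TRUE), "skipped")
  expect_equal(nrow(bs2$records), 1L)
  expect_equal(bs2$n_skipped, 1L)
})
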