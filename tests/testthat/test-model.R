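test_that("config validation catches inconsistent shapes", {
  expect_error(rvt_config("desk", dims = c(32L, 65L)), "divisible")
  expect_error(rvt_config("desk", patch_sizes = c(7L, 2L)), "patch size")
  expect_error(rvt_config("desk", sr_ratios = c(5L, 2L)), "reduction ratio")
  expect_error(rvt_config("desk", head_mode = "zzz"), "head_mode")
  expect_s3_class(rvt_config("full"), "rvt_config")
  # full preset follows the /4 /8 /16 /32 pyramid
  expect_equal(rvt_grids(rvt_config("full")), c(128L, 64L, 32L, 16L))
})

test_that("forward pass obeys the end-to-end shape law and batch stacking", {
  model <- rvt_model(tiny_config(), seed = 2)
  for (B in c(1L, 3L)) {
    X <- random_pixel_batch(B, model$config$input_size)
    fw <- rvt_forward(model, X, B)
    expect_equal(dim(fw$keypoints$val), c(B, 12L))
    expect_equal(dim(fw$logits$val), c(B, 3L))
    grids <- rvt_grids(model$config)
    for (i in seq_along(grids))
      expect_equal(f32_dims(fw$features[[i]]$val),
                   c(B * grids[i]^2, model$config$dims[i]))
  }
  # per-image results do not depend on batch composition
  set.seed(8)
  X3 <- random_pixel_batch(3L, model$config$input_size)
  fw3 <- rvt_forward(model, X3, 3L)
  kp3 <- fw3$keypoints$val
  n1 <- model$config$input_size^2
  fw1 <- rvt_forward(model, X3[seq_len(n1), , drop = FALSE], 1L)
  expect_equal(fw1$keypoints$val[1, ], kp3[1, ], tolerance = 1e-5)
})

test_that("a desk-config forward pass is subsecond on one core", {
  model <- rvt_model(rvt_config("desk"), seed = 1)
  X <- random_pixel_batch(1L, model$config$input_size)
  rvt_forward(model, X, 1L)   # warm the caches
  t0 <- Sys.time()
  fw <- rvt_forward(model, X, 1L)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  expect_equal(dim(fw$keypoints$val), c(1L, 12L))
})

test_that("sigmoid head emits (0,1) coordinates and 3 logits", {
  model <- rvt_model(tiny_config(use_orthogonal_layer = FALSE), seed = 3)
  X <- random_pixel_batch(2L, model$config$input_size)
  fw <- rvt_forward(model, X, 2L)
  expect_true(all(fw$keypoints$val > 0 & fw$keypoints$val < 1))
  expect_equal(ncol(fw$logits$val), 3L)
})

test_that("all four ablation variants are pure configuration", {
  for (ff in c(TRUE, FALSE)) for (orth in c(TRUE, FALSE)) {
    model <- rvt_model(tiny_config(use_feature_fusion = ff,
                                   use_orthogonal_layer = orth), seed = 4)
    X <- random_pixel_batch(2L, model$config$input_size)
    fw <- rvt_forward(model, X, 2L)
    expect_equal(dim(fw$keypoints$val), c(2L, 12L))
    if (orth) {
      for (i in 1:2) {
        kp <- kp_unflatten(fw$keypoints$val[i, ], validate = FALSE)
        expect_lt(abs(vhsnet:::kp_axes_abs_cos(kp)), 1e-9)
      }
    }
  }
  # attention-bias switch too
  m2 <- rvt_model(tiny_config(use_attention_bias = FALSE), seed = 4)
  X <- random_pixel_batch(1L, m2$config$input_size)
  expect_equal(dim(rvt_forward(m2, X, 1L)$keypoints$val), c(1L, 12L))
})

test_that("predictions decode geometry consistently", {
  model <- rvt_model(tiny_config(), seed = 5)
  S <- model$config$input_size
  imgs <- replicate(3, matrix(runif(S * S), S), simplify = FALSE)
  p <- predict(model, imgs)
  expect_equal(nrow(p), 3L)
  probs <- as.matrix(p[, c("p_small", "p_normal", "p_large")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  # pixel keypoints are the normalized ones scaled by the input size
  expect_equal(as.matrix(p[, vhsnet:::kp_flat_names]),
               as.matrix(p[, paste0("n", vhsnet:::kp_flat_names)]) * S,
               ignore_attr = TRUE)
  # the reported class always agrees with the VHS measurement
  expect_identical(p$class, classify_vhs(pmax(p$vhs, 1e-12)))
  # orthogonal layer holds in pixel space
  for (i in 1:3) {
    kp <- kp_unflatten(as.numeric(p[i, vhsnet:::kp_flat_names]),
                       validate = FALSE)
    expect_lt(abs(vhsnet:::kp_axes_abs_cos(kp)), 1e-7)
  }
  expect_error(predict(model, list(matrix(0.5, 8, 8))), "resize")
})

test_that("soft_vhs head mode derives logits from geometry alone", {
  model <- rvt_model(tiny_config(head_mode = "soft_vhs",
                                 soft_vhs_temperature = 2), seed = 6)
  X <- random_pixel_batch(2L, model$config$input_size)
  fw <- rvt_forward(model, X, 2L)
  kp <- fw$keypoints$val
  S <- 1  # normalized coordinates; VHS is scale-free
  for (i in 1:2) {
    v <- vhs_score(kp_unflatten(kp[i, ], validate = FALSE))
    expected <- -(v - model$config$vhs_midpoints)^2 / 2
    expect_equal(fw$logits$val[i, ], expected, tolerance = 1e-9)
  }
})

test_that("checkpoints round-trip exactly", {
  model <- rvt_model(tiny_config(), seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  rvt_save(model, path)
  back <- rvt_load(path)
  expect_identical(back$config[names(back$config) != "thresholds"],
                   model$config[names(model$config) != "thresholds"])
  S <- model$config$input_size
  img <- list(matrix(runif(S * S), S))
  expect_identical(predict(model, img), predict(back, img))
  expect_error(rvt_load(withr::local_tempfile(fileext = ".rds",
                                              lines = "x")))
})

test_that("relative-bias offset codes tile the query-key grid", {
  rb <- rel_bias_index(8L, 2L)
  expect_equal(dim(rb$idx), c(64L, 16L))
  expect_true(all(rb$idx >= 1 & rb$idx <= rb$n))
  expect_setequal(unique(as.vector(rb$idx)), seq_len(rb$n))
  # translation equivariance: same offset code wherever the relative
  # displacement is the same
  rb1 <- rel_bias_index(4L, 1L)
  expect_equal(rb1$idx[1, 1], rb1$idx[2, 2])
})
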