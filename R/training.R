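#' Training configuration
#'
#' The objective is the joint loss `L = w_ce * CE(class logits, y) +
#' gamma * MSE(keypoints, targets)` averaged over the mini-batch and
#' optimized with Adam. The MSE is computed on pixel-scale coordinates
#' (normalized outputs times the model input size): with `gamma = 0.01`
#' this balances the two tasks the way a pixel-coordinate regression
#' pipeline does, and the balance carries over between image sizes
#' through the gamma * size^2 equivalence. `gamma = 0` reproduces the
#' cross-entropy-only training mode, and `ce_weight = 0` with `gamma = 1`
#' trains a pure keypoint regressor (used by the few-shot bootstrap).
#'
#' Two presets: `"desk"` — step-count-based training sized for one CPU core
#' (constant lr 1e-3, 2000 steps, early stopping on validation
#' R-accuracy with patience 600 steps); `"full"` — the full-scale recipe
#' (lr 3e-5, batch 16, 1000 epochs, no early stop).
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... Named overrides: `lr`, `batch_size`, `gamma`, `ce_weight`,
#'   `steps`, `epochs` (overrides `steps` when set), `seed`, `eval_every`,
#'   `patience` (0 disables early stopping), `beta1`, `beta2`, `eps`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(lr = 1e-3, batch_size = 16L, gamma = 0.01, ce_weight = 1,
         steps = 2000L, epochs = NULL, seed = 1L, eval_every = 100L,
         patience = 600L, warmup = 100L, clip = 5)
  } else {
    list(lr = 3e-5, batch_size = 16L, gamma = 0.01, ce_weight = 1,
         steps = NULL, epochs = 1000L, seed = 1L, eval_every = 500L,
         patience = 0L, warmup = 0L, clip = 0)
  }
  cfg <- utils::modifyList(cfg, list(beta1 = 0.9, beta2 = 0.999,
                                     eps = 1e-8, preset = preset))
  cfg <- utils::modifyList(cfg, list(...))
  if (cfg$gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (cfg$batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(cfg, class = "train_config")
}

#' Joint classification + regression loss
#'
#' `L = ce_weight * CE(logits, y) + gamma * MSE(keypoints, targets)`, each
#' term averaged over the batch. CE uses softmax cross-entropy on the
#' three class logits; MSE is the mean squared error over all 12
#' normalized coordinates.
#'
#' @param class_logits n x 3 matrix of logits.
#' @param keypoints n x 12 matrix of normalized coordinates.
#' @param target_points n x 12 matrix of normalized targets.
#' @param target_class Integer vector of class labels 0..2.
#' @param gamma Balance factor (>= 0).
#' @param ce_weight Weight of the cross-entropy term (default 1).
#' @param coord_scale Factor applied to coordinates before squaring (pass
#'   the model input size to get pixel-scale MSE from normalized
#'   coordinates; the training loop does this).
#' @return List with `total`, `ce`, `mse`.
#' @export
joint_loss <- function(class_logits, keypoints, target_points, target_class,
                       gamma = 0.01, ce_weight = 1, coord_scale = 1) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  stopifnot(nrow(class_logits) == length(target_class),
            all(dim(keypoints) == dim(target_points)))
  mx <- apply(class_logits, 1L, max)
  lse <- mx + log(rowSums(exp(class_logits - mx)))
  ce <- mean(lse - class_logits[cbind(seq_along(target_class),
                                      target_class + 1L)])
  mse <- mean((coord_scale * (keypoints - target_points))^2)
  list(total = ce_weight * ce + gamma * mse, ce = ce, mse = mse)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

## ---- accuracy helpers ------------------------------------------------------

# build the (B*H*W) x 3 stacked pixel matrix for a set of image matrices,
# with the row-major pixel convention of the encoder
pixel_stack <- function(images) {
  do.call(rbind, lapply(images, function(im) {
    v <- as.vector(t(im))
    matrix(v, nrow = length(v), ncol = 3L)
  }))
}

#' Classification accuracy of a model on loaded inputs
#'
#' `mode = "regression"` derives the class from the predicted VHS via
#' [classify_vhs()] (the R-accuracy of a jointly trained model);
#' `mode = "classifier"` uses the argmax of the classifier head's logits
#' (the C-accuracy of a cross-entropy-trained model).
#'
#' @param model An [rvt_model()].
#' @param inputs A `model_inputs` object (see [load_model_inputs()]).
#' @param mode `"regression"` or `"classifier"`.
#' @param batch_size Forward batch size.
#' @return Accuracy in `[0,1]`.
#' @export
rvt_accuracy <- function(model, inputs, mode = c("regression", "classifier"),
                         batch_size = 16L) {
  mode <- match.arg(mode)
  pred <- predict(model, inputs$images, batch_size = batch_size)
  yhat <- if (mode == "regression") {
    pred$class
  } else {
    max.col(as.matrix(pred[, c("p_small", "p_normal", "p_large")])) - 1L
  }
  mean(yhat == inputs$classes)
}

## ---- the training loop -----------------------------------------------------

#' Train the regressive vision transformer
#'
#' Runs seeded mini-batch Adam on the joint objective. Every
#' `eval_every` steps the validation R-accuracy (class derived from
#' predicted VHS) is computed and the best parameters are checkpointed;
#' with `patience > 0` training stops early once no improvement has been
#' seen for that many steps. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model An [rvt_model()] (initial parameters; not modified).
#' @param train_inputs,val_inputs `model_inputs` objects (see
#'   [load_model_inputs()] / in-memory generation).
#' @param cfg A [train_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `rvt_fit`: `model` (best-validation
#'   parameters), `final_model`, `log` (per-step tibble), `best_val_acc`,
#'   `steps_run`, `config`.
#' @export
rvt_train <- function(model, train_inputs, val_inputs, cfg = train_config(),
                      quiet = FALSE) {
  stopifnot(inherits(model, "rvt_model"), inherits(cfg, "train_config"))
  n <- length(train_inputs$images)
  if (n < 1 || length(val_inputs$images) < 1)
    stop("empty training or validation split", call. = FALSE)
  if (length(intersect(train_inputs$ids, val_inputs$ids)) > 0)
    stop("training and validation splits overlap", call. = FALSE)
  B <- min(cfg$batch_size, n)
  steps <- if (!is.null(cfg$epochs)) {
    as.integer(cfg$epochs * max(1L, floor(n / B)))
  } else {
    cfg$steps
  }
  set.seed(cfg$seed)
  pix <- lapply(train_inputs$images, function(im) {
    v <- as.vector(t(im))
    matrix(v, nrow = length(v), ncol = 3L)
  })
  params <- model$params
  st <- adam_init(params)
  best <- list(acc = -Inf, params = params, step = 0L)
  log <- vector("list", steps)
  order_pool <- integer(0)
  t_start <- Sys.time()
  work <- structure(list(config = model$config, params = params,
                         cache = model$cache), class = "rvt_model")
  for (step in seq_len(steps)) {
    if (length(order_pool) < B) order_pool <- c(order_pool, sample.int(n))
    sel <- order_pool[seq_len(B)]
    order_pool <- order_pool[-seq_len(B)]
    X <- do.call(rbind, pix[sel])
    work$params <- params
    fw <- rvt_forward(work, X, B)
    ce <- ad_ce(fw$tape, fw$logits, train_inputs$classes[sel])
    mse_norm <- ad_mse(fw$tape, fw$keypoints,
                       train_inputs$targets[sel, , drop = FALSE])
    S2 <- as.numeric(model$config$input_size)^2   # pixel-scale MSE
    loss <- ad_axpby(fw$tape, ce, mse_norm, cfg$ce_weight, cfg$gamma * S2)
    mse <- list(val = mse_norm$val * S2)
    if (!is.finite(loss$val))
      stop("training diverged at step ", step, ": loss = ", loss$val,
           " (ce = ", ce$val, ", mse = ", mse$val, ")", call. = FALSE)
    ad_backward(fw$tape, loss)
    grads <- lapply(fw$params, function(nd) nd$grad)
    if (cfg$clip > 0) {
      gnorm <- sqrt(sum(vapply(grads, function(g)
        if (is.null(g)) 0 else sum(g * g), numeric(1))))
      if (is.finite(gnorm) && gnorm > cfg$clip)
        grads <- lapply(grads, function(g)
          if (is.null(g)) NULL else g * (cfg$clip / gnorm))
    }
    lr_t <- if (cfg$warmup > 0L) cfg$lr * min(1, step / cfg$warmup) else cfg$lr
    upd <- adam_step(params, grads, st, lr_t, cfg$beta1, cfg$beta2,
                     cfg$eps)
    params <- upd$params
    st <- upd$state
    val_acc <- NA_real_
    if (step %% cfg$eval_every == 0L || step == steps) {
      work$params <- params
      val_acc <- rvt_accuracy(work, val_inputs, "regression")
      if (val_acc > best$acc)
        best <- list(acc = val_acc, params = params, step = step)
      if (!quiet)
        message(sprintf("step %d/%d  loss %.4f (ce %.4f mse %.5f)  val R-acc %.3f",
                        step, steps, loss$val, ce$val, mse$val, val_acc))
    }
    log[[step]] <- c(step = step, loss = loss$val, ce = ce$val,
                     mse = mse$val, val_acc = val_acc)
    if (cfg$patience > 0L && best$step > 0L &&
        (step - best$step) >= cfg$patience) break
  }
  log <- tibble::as_tibble(do.call(rbind, log[!vapply(log, is.null,
                                                      logical(1))]))
  log$elapsed_s <- as.numeric(Sys.time() - t_start)
  best_model <- structure(list(config = model$config, params = best$params,
                               cache = model$cache), class = "rvt_model")
  final_model <- structure(list(config = model$config, params = params,
                                cache = model$cache), class = "rvt_model")
  structure(list(model = best_model, final_model = final_model, log = log,
                 best_val_acc = best$acc, best_step = best$step,
                 steps_run = max(log$step), config = cfg),
            class = "rvt_fit")
}

#' @export
print.rvt_fit <- function(x, ...) {
  cat(sprintf("<rvt_fit> %d steps, best val R-accuracy %.3f at step %d\n",
              x$steps_run, x$best_val_acc, x$best_step))
  invisible(x)
}

#' Tidy the training log
#'
#' @param x An `rvt_fit`.
#' @param ... Unused.
#' @return The per-step log as a tibble (`step`, `loss`, `ce`, `mse`,
#'   `val_acc`).
#' @export
tidy.rvt_fit <- function(x, ...) x$log

#' One-row training summary
#'
#' @param x An `rvt_fit`.
#' @param ... Unused.
#' @export
glance.rvt_fit <- function(x, ...) {
  tibble::tibble(steps = x$steps_run,
                 final_loss = x$log$loss[nrow(x$log)],
                 final_ce = x$log$ce[nrow(x$log)],
                 final_mse = x$log$mse[nrow(x$log)],
                 best_val_acc = x$best_val_acc,
                 best_step = x$best_step,
                 elapsed_s = x$log$elapsed_s[1],
                 n_params = sum(vapply(x$model$params, length, integer(1))))
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a versioned header carrying the full model
#' configuration next to the weights.
#'
#' @param model An [rvt_model()] (or the `model` of an `rvt_fit`).
#' @param path Destination file.
#' @export
rvt_save <- function(model, path) {
  stopifnot(inherits(model, "rvt_model"))
  saveRDS(list(format = "vhsnet-checkpoint", version = 1L,
               config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname rvt_save
#' @export
rvt_load <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "vhsnet-checkpoint"))
    stop("not a vhsnet checkpoint: ", path, call. = FALSE)
  structure(list(config = ck$config, params = ck$params,
                 cache = new.env(parent = emptyenv())),
            class = "rvt_model")
}

## ---- few-shot bootstrap ----------------------------------------------------

#' Bootstrap coarse labels from a small labeled set
#'
#' Trains a base keypoint regressor (the desk transformer with the
#' cross-entropy term switched off) on a small labeled split, reports the
#' held-out mean per-point pixel error, and emits coarse keypoint
#' annotations (status `"coarse"`) for every unlabeled image, for later
#' human verification. This is the label-acceleration workflow: a few
#' hundred hand-labeled images bootstrap approximate landmarks for the
#' rest of a collection.
#'
#' @param labeled A `model_inputs` object with ground-truth keypoints.
#' @param unlabeled_images A named list of image matrices, or a directory
#'   of PNGs. Unreadable files are skipped with a warning.
#' @param cfg A [train_config()]; defaults to a regression-only desk
#'   recipe (`ce_weight = 0`, `gamma = 1`).
#' @param model_config An [rvt_config()] for the base regressor.
#' @param holdout_frac Fraction of the labeled set held out for the error
#'   report.
#' @param quiet Suppress progress messages.
#' @return A list: `records` (coarse annotation tibble with per-image VHS
#'   and class), `holdout_error_px` (mean per-point pixel error at model
#'   input scale), `fit` (the training fit), `n_skipped`.
#' @export
few_shot_bootstrap <- function(labeled, unlabeled_images,
                               cfg = NULL, model_config = rvt_config("desk"),
                               holdout_frac = 0.25, quiet = FALSE) {
  stopifnot(inherits(labeled, "model_inputs"))
  n <- length(labeled$images)
  if (n < 2L) stop("need at least 2 labeled images", call. = FALSE)
  if (is.null(cfg))
    cfg <- train_config("desk", ce_weight = 0, gamma = 1, steps = 1200L,
                        eval_every = 200L, patience = 0L)
  set.seed(cfg$seed)
  idx_hold <- sort(sample.int(n, max(1L, round(holdout_frac * n))))
  take <- function(ix) {
    structure(list(images = labeled$images[ix],
                   targets = labeled$targets[ix, , drop = FALSE],
                   classes = labeled$classes[ix],
                   vhs = labeled$vhs[ix],
                   ids = labeled$ids[ix], n_skipped = 0L,
                   input_size = labeled$input_size),
              class = "model_inputs")
  }
  tr <- take(setdiff(seq_len(n), idx_hold))
  ho <- take(idx_hold)
  base <- rvt_model(model_config, seed = cfg$seed)
  fit <- rvt_train(base, tr, ho, cfg, quiet = quiet)

  S <- model_config$input_size
  pred_ho <- predict(fit$model, ho$images)
  err <- per_point_error_px(as.matrix(pred_ho[, kp_flat_names]),
                            ho$targets * S)
  # resolve unlabeled inputs
  n_skipped <- 0L
  if (is.character(unlabeled_images)) {
    paths <- list.files(unlabeled_images, pattern = "\\.png$",
                        full.names = TRUE)
    imgs <- list()
    for (p in paths) {
      im <- tryCatch(png::readPNG(p), error = function(e) NULL)
      if (is.null(im)) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (length(dim(im)) == 3L) im <- im[, , 1]
      imgs[[tools::file_path_sans_ext(basename(p))]] <-
        resize_bilinear(im, S)
    }
    if (n_skipped > 0)
      warning("skipped ", n_skipped, " unreadable unlabeled image(s)",
              call. = FALSE)
    unlabeled_images <- imgs
  }
  if (length(unlabeled_images) == 0L) {
    warning("no unlabeled images; nothing to bootstrap", call. = FALSE)
    return(list(records = tibble::tibble(), holdout_error_px = err,
                fit = fit, n_skipped = n_skipped))
  }
  ids <- names(unlabeled_images)
  if (is.null(ids)) ids <- sprintf("unlabeled_%05d",
                                   seq_along(unlabeled_images))
  pred <- predict(fit$model, unlabeled_images)
  records <- dplyr::bind_cols(
    tibble::tibble(image_id = ids),
    tibble::as_tibble(as.matrix(pred[, kp_flat_names])),
    tibble::tibble(status = "coarse", vhs = pred$vhs, class = pred$class))
  list(records = records, holdout_error_px = err, fit = fit,
       n_skipped = n_skipped)
}

# mean Euclidean error per keypoint, pixels
per_point_error_px <- function(pred_px, true_px) {
  d <- pred_px - true_px
  mean(sqrt(d[, seq(1, 11, 2)]^2 + d[, seq(2, 12, 2)]^2))
}
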