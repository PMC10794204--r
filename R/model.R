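#' Configuration of the regressive vision transformer
#'
#' Describes the pyramid encoder (stages, embedding dims, attention heads,
#' spatial-reduction ratios, block depths), the feature-fusion pair, the head
#' and the geometric constraint layer.
#'
#' Two presets are provided. `"desk"` is a two-stage model at 96 px input,
#' small enough to train on one CPU core in minutes; `"full"` mirrors the
#' full-scale four-stage geometry at 512 px input (patch strides /4, /8,
#' /16, /32).
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... Named overrides of any config field (e.g.
#'   `use_orthogonal_layer = FALSE`, `use_feature_fusion = FALSE` for
#'   ablation variants; `head_mode = "soft_vhs"` for a purely
#'   geometry-derived classifier).
#' @return A list of class `rvt_config`.
#' @details Fields:
#' * `input_size`: square model input in pixels.
#' * `patch_sizes`, `dims`, `heads`, `sr_ratios`, `depths`: per-stage
#'   encoder shape; `dims[i]` must be divisible by `heads[i]` and each
#'   stage's token grid by its reduction ratio.
#' * `mlp_ratio`: width multiplier of each block's two-layer MLP.
#' * `low_stage`, `high_stage`: encoder stages whose feature maps feed the
#'   fusion module (texture-level and shape-level features).
#' * `fusion_channels`: channels each fused map is projected to by its
#'   3x3 convolutional unit.
#' * `head_hidden`: width of the head MLP between pooled features and the
#'   twelve coordinate units.
#' * `head_mode`: `"aux_head"` (parallel 3-unit linear classifier on pooled
#'   features) or `"soft_vhs"` (logits derived from predicted VHS as
#'   negative squared distances to class-interval midpoints over a
#'   temperature).
#' * `use_orthogonal_layer`, `use_feature_fusion`, `use_attention_bias`:
#'   ablation switches (the P / P+F / P+O / P+F+O variants).
#' @export
rvt_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(input_size = 96L, patch_sizes = c(8L, 2L), dims = c(32L, 64L),
         heads = c(1L, 2L), sr_ratios = c(4L, 2L), depths = c(2L, 2L),
         mlp_ratio = 2, low_stage = 1L, high_stage = 2L)
  } else {
    list(input_size = 512L, patch_sizes = c(4L, 2L, 2L, 2L),
         dims = c(64L, 128L, 320L, 512L), heads = c(1L, 2L, 5L, 8L),
         sr_ratios = c(8L, 4L, 2L, 1L), depths = c(2L, 2L, 6L, 2L),
         mlp_ratio = 4, low_stage = 1L, high_stage = 2L)
  }
  cfg <- utils::modifyList(cfg, list(
    fusion_channels = 32L, head_hidden = 64L,
    head_mode = "aux_head", use_orthogonal_layer = TRUE,
    use_feature_fusion = TRUE, use_attention_bias = TRUE,
    vhs_factor = 6, thresholds = vhs_thresholds(),
    vhs_midpoints = c(7.35, 9.1, 11.5), soft_vhs_temperature = 1,
    orth_eps = 1e-6, preset = preset))
  cfg <- utils::modifyList(cfg, list(...))
  validate_rvt_config(structure(cfg, class = "rvt_config"))
}

validate_rvt_config <- function(cfg) {
  ns <- length(cfg$dims)
  if (length(cfg$patch_sizes) != ns || length(cfg$heads) != ns ||
      length(cfg$sr_ratios) != ns || length(cfg$depths) != ns)
    stop("per-stage fields (patch_sizes, dims, heads, sr_ratios, depths) ",
         "must all have the same length", call. = FALSE)
  if (any(cfg$dims %% cfg$heads != 0))
    stop("each stage's dim must be divisible by its head count",
         call. = FALSE)
  if (!cfg$head_mode %in% c("aux_head", "soft_vhs"))
    stop("head_mode must be 'aux_head' or 'soft_vhs'", call. = FALSE)
  g <- cfg$input_size
  for (i in seq_len(ns)) {
    if (g %% cfg$patch_sizes[i] != 0)
      stop("stage ", i, ": grid ", g, " not divisible by patch size ",
           cfg$patch_sizes[i], call. = FALSE)
    g <- g %/% cfg$patch_sizes[i]
    if (g %% cfg$sr_ratios[i] != 0)
      stop("stage ", i, ": token grid ", g, "x", g,
           " not divisible by reduction ratio R=", cfg$sr_ratios[i],
           call. = FALSE)
  }
  if (!(cfg$low_stage %in% seq_len(ns)) || !(cfg$high_stage %in% seq_len(ns)))
    stop("low_stage/high_stage out of range", call. = FALSE)
  cfg
}

#' @export
print.rvt_config <- function(x, ...) {
  cat("<rvt_config> preset:", x$preset, "\n")
  cat("  input", x$input_size, "px;",
      length(x$dims), "stages; dims", paste(x$dims, collapse = "/"),
      "; heads", paste(x$heads, collapse = "/"),
      "; R", paste(x$sr_ratios, collapse = "/"),
      "; depths", paste(x$depths, collapse = "/"), "\n")
  cat("  fusion:", x$use_feature_fusion,
      " orthogonal layer:", x$use_orthogonal_layer,
      " head:", x$head_mode, "\n")
  invisible(x)
}

# per-stage token grid sizes
rvt_grids <- function(cfg) {
  g <- cfg$input_size
  vapply(seq_along(cfg$dims), function(i) {
    g <<- g %/% cfg$patch_sizes[i]
    g
  }, integer(1))
}

## ---- index builders (token bookkeeping) ------------------------------------

# gather indices for non-overlapping p x p patches on a g x g grid, stacked
# over B images; column k walks the patch row-major
idx_patch <- function(g, p, B) {
  go <- g %/% p
  oy <- rep(0:(go - 1L), each = go)
  ox <- rep.int(0:(go - 1L), go)
  one <- matrix(0L, go * go, p * p)
  k <- 0L
  for (dy in 0:(p - 1L)) for (dx in 0:(p - 1L)) {
    k <- k + 1L
    one[, k] <- (oy * p + dy) * g + (ox * p + dx) + 1L
  }
  do.call(rbind, lapply(seq_len(B) - 1L, function(b) one + b * g * g))
}

# 3x3 same-padding conv indices on a g x g grid (NA = zero pad)
idx_conv3 <- function(g, B) {
  oy <- rep(0:(g - 1L), each = g)
  ox <- rep.int(0:(g - 1L), g)
  one <- matrix(NA_integer_, g * g, 9L)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    iy <- oy + dy
    ix <- ox + dx
    ok <- iy >= 0L & iy < g & ix >= 0L & ix < g
    col <- rep(NA_integer_, g * g)
    col[ok] <- iy[ok] * g + ix[ok] + 1L
    one[, k] <- col
  }
  do.call(rbind, lapply(seq_len(B) - 1L, function(b) {
    m <- one + b * g * g
    m[is.na(one)] <- NA_integer_
    m
  }))
}

# 1-D bilinear interpolation matrix from nin to nout grid positions
bilinear_matrix_1d <- function(nout, nin) {
  U <- matrix(0, nout, nin)
  for (i in 0:(nout - 1L)) {
    src <- (i + 0.5) * nin / nout - 0.5
    lo <- floor(src)
    w <- src - lo
    l0 <- min(max(lo, 0), nin - 1L)
    l1 <- min(max(lo + 1L, 0), nin - 1L)
    U[i + 1L, l0 + 1L] <- U[i + 1L, l0 + 1L] + (1 - w)
    U[i + 1L, l1 + 1L] <- U[i + 1L, l1 + 1L] + w
  }
  U
}

# relative-offset codes between a gq x gq query grid and its gq/R x gq/R
# reduced key grid (offsets measured to neighborhood centers, in half-pixel
# units so they are exact integers); returns list(idx = Nq x Nk codes,
# n = number of distinct offsets)
rel_bias_index <- function(gq, R) {
  gk <- gq %/% R
  q <- 0:(gq - 1L)
  k <- 0:(gk - 1L)
  # 2*q - (2*k*R + R - 1): twice the offset from key-neighborhood center
  o1 <- outer(2L * q, 2L * k * R + (R - 1L), "-")
  u <- sort(unique(as.vector(o1)))
  i1 <- matrix(match(o1, u), gq, gk)
  nu <- length(u)
  qy <- rep(0:(gq - 1L), each = gq) + 1L
  qx <- rep.int(0:(gq - 1L), gq) + 1L
  ky <- rep(0:(gk - 1L), each = gk) + 1L
  kx <- rep.int(0:(gk - 1L), gk) + 1L
  iy <- i1[cbind(rep(qy, times = gk * gk), rep(ky, each = gq * gq))]
  ix <- i1[cbind(rep(qx, times = gk * gk), rep(kx, each = gq * gq))]
  idx <- matrix((iy - 1L) * nu + ix, gq * gq, gk * gk)
  list(idx = idx, n = nu * nu)
}

## ---- parameters ------------------------------------------------------------

# Glorot-scaled normal init: appropriate for the narrow embedding dims of
# the desk model (a fixed small sd would shrink signals at every layer)
rnorm_mat <- function(nr, nc, sd = sqrt(2 / (nr + nc))) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}
zeros_row <- function(nc) matrix(0, 1L, nc)
ones_row <- function(nc) matrix(1, 1L, nc)

#' Instantiate a regressive vision transformer
#'
#' Allocates and initializes all learnable parameters for a given
#' configuration (truncated-normal weights, unit layer-norm gains, zero
#' biases and attention-bias tables).
#'
#' @param config An [rvt_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `rvt_model` holding `config` and a flat named
#'   list `params` of weight matrices.
#' @export
rvt_model <- function(config = rvt_config(), seed = 1L) {
  stopifnot(inherits(config, "rvt_config"))
  set.seed(seed)
  P <- list()
  grids <- rvt_grids(config)
  Cprev <- 3L
  for (i in seq_along(config$dims)) {
    C <- config$dims[i]
    p <- config$patch_sizes[i]
    H <- config$heads[i]
    R <- config$sr_ratios[i]
    g <- grids[i]
    pre <- paste0("s", i, ".")
    P[[paste0(pre, "pe.W")]] <- rnorm_mat(p * p * Cprev, C)
    P[[paste0(pre, "pe.b")]] <- zeros_row(C)
    P[[paste0(pre, "pe.lng")]] <- ones_row(C)
    P[[paste0(pre, "pe.lnb")]] <- zeros_row(C)
    P[[paste0(pre, "pos")]] <- rnorm_mat(g * g, C)
    nbias <- if (config$use_attention_bias) rel_bias_index(g, R)$n else 0L
    for (j in seq_len(config$depths[i])) {
      bp <- paste0(pre, "b", j, ".")
      P[[paste0(bp, "ln1g")]] <- ones_row(C)
      P[[paste0(bp, "ln1b")]] <- zeros_row(C)
      P[[paste0(bp, "Wq")]] <- rnorm_mat(C, C)
      P[[paste0(bp, "bq")]] <- zeros_row(C)
      if (R > 1L) {
        P[[paste0(bp, "Ws")]] <- rnorm_mat(R * R * C, C)
        P[[paste0(bp, "bs")]] <- zeros_row(C)
        P[[paste0(bp, "srlng")]] <- ones_row(C)
        P[[paste0(bp, "srlnb")]] <- zeros_row(C)
      }
      P[[paste0(bp, "Wk")]] <- rnorm_mat(C, C)
      P[[paste0(bp, "bk")]] <- zeros_row(C)
      P[[paste0(bp, "Wv")]] <- rnorm_mat(C, C)
      P[[paste0(bp, "bv")]] <- zeros_row(C)
      P[[paste0(bp, "Wo")]] <- rnorm_mat(C, C)
      P[[paste0(bp, "bo")]] <- zeros_row(C)
      if (config$use_attention_bias)
        P[[paste0(bp, "abias")]] <- matrix(0, nbias, H)
      P[[paste0(bp, "ln2g")]] <- ones_row(C)
      P[[paste0(bp, "ln2b")]] <- zeros_row(C)
      m <- round(config$mlp_ratio * C)
      P[[paste0(bp, "W1")]] <- rnorm_mat(C, m)
      P[[paste0(bp, "b1")]] <- zeros_row(m)
      P[[paste0(bp, "W2")]] <- rnorm_mat(m, C)
      P[[paste0(bp, "b2")]] <- zeros_row(C)
    }
    P[[paste0(pre, "lng")]] <- ones_row(C)
    P[[paste0(pre, "lnb")]] <- zeros_row(C)
    Cprev <- C
  }
  fc <- config$fusion_channels
  if (config$use_feature_fusion) {
    P[["ff.lowW"]] <- rnorm_mat(9L * config$dims[config$low_stage], fc)
    P[["ff.lowb"]] <- zeros_row(fc)
    P[["ff.highW"]] <- rnorm_mat(9L * config$dims[config$high_stage], fc)
    P[["ff.highb"]] <- zeros_row(fc)
    Cpool <- 2L * fc
  } else {
    Cpool <- config$dims[config$high_stage]
  }
  hh <- config$head_hidden
  P[["head.W1"]] <- rnorm_mat(Cpool, hh)
  P[["head.b1"]] <- zeros_row(hh)
  # Output layer: small weights plus a logit-space anatomical prior, so the
  # initial prediction is a plausible constellation (long axis well away
  # from horizontal). This keeps the slope of the orthogonal projection
  # bounded from the first step; with a zero init the predicted A and B can
  # share a y-coordinate and the projection slope explodes.
  P[["head.Wkp"]] <- rnorm_mat(hh, 12L, sd = 0.01)
  prior <- c(0.45, 0.28, 0.70, 0.71,   # A, B: carina -> apex, tilted
             0.43, 0.57, 0.72, 0.42,   # C, D: short axis
             0.30, 0.17, 0.78, 0.19)   # E, F: vertebral reference
  P[["head.bkp"]] <- matrix(log(prior / (1 - prior)), 1L)
  if (config$head_mode == "aux_head") {
    P[["head.Wcls"]] <- rnorm_mat(Cpool, 3L)
    P[["head.bcls"]] <- zeros_row(3L)
  }
  structure(list(config = config, params = P,
                 cache = new.env(parent = emptyenv())),
            class = "rvt_model")
}

#' @export
print.rvt_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<rvt_model>", format(np, big.mark = ","), "parameters\n")
  print(x$config)
  invisible(x)
}

#' Number of trainable parameters
#' @param model An [rvt_model()].
#' @export
rvt_n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# precomputed per-batch index structures, cached on the model
rvt_indices <- function(model, B) {
  key <- paste0("B", B)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  cfg <- model$config
  grids <- rvt_grids(cfg)
  gin <- c(cfg$input_size, grids[-length(grids)])
  ix <- list(stages = vector("list", length(grids)))
  for (i in seq_along(grids)) {
    st <- list(patch = idx_patch(gin[i], cfg$patch_sizes[i], B))
    if (cfg$sr_ratios[i] > 1L)
      st$sr <- idx_patch(grids[i], cfg$sr_ratios[i], B)
    if (cfg$use_attention_bias)
      st$bias <- rel_bias_index(grids[i], cfg$sr_ratios[i])
    ix$stages[[i]] <- st
  }
  if (cfg$use_feature_fusion) {
    gl <- grids[cfg$low_stage]
    gh <- grids[cfg$high_stage]
    ix$conv_low <- idx_conv3(gl, B)
    ix$conv_high <- idx_conv3(gh, B)
    if (gl != gh) {
      U1 <- bilinear_matrix_1d(gl, gh)
      ix$upsample <- f32_new(kronecker(U1, U1))   # persistent f32 constant
    }
  }
  model$cache[[key]] <- ix
  ix
}

## ---- forward graph ---------------------------------------------------------

# Build the full differentiable graph for a stacked image batch.
# X: (B*input_size^2) x 3 pixel matrix in [0,1], images stacked image-major,
# pixels row-major. The encoder runs on float32 kernels; pooled features are
# bridged to double precision for the head, orthogonal layer and losses.
# Returns tape, parameter leaf nodes, and output nodes.
rvt_forward <- function(model, X, B) {
  cfg <- model$config
  arena_reset()   # recycle activation memory of the previous step
  tp <- ad_tape()
  Pn <- lapply(model$params, function(v) ad_param(tp, v))
  ix <- rvt_indices(model, B)
  grids <- rvt_grids(cfg)

  x <- adf_leaf(tp, X)
  feats <- vector("list", length(grids))
  for (i in seq_along(grids)) {
    pre <- paste0("s", i, ".")
    st <- ix$stages[[i]]
    C <- cfg$dims[i]
    H <- cfg$heads[i]
    dh <- C %/% H
    R <- cfg$sr_ratios[i]
    x <- adf_gather_cbind(tp, x, st$patch)
    x <- adf_linear(tp, x, Pn[[paste0(pre, "pe.W")]],
                    Pn[[paste0(pre, "pe.b")]])
    x <- adf_layernorm(tp, x, Pn[[paste0(pre, "pe.lng")]],
                       Pn[[paste0(pre, "pe.lnb")]])
    x <- adf_posadd(tp, x, Pn[[paste0(pre, "pos")]], B)
    for (j in seq_len(cfg$depths[i])) {
      bp <- paste0(pre, "b", j, ".")
      h <- adf_layernorm(tp, x, Pn[[paste0(bp, "ln1g")]],
                         Pn[[paste0(bp, "ln1b")]])
      q <- adf_linear(tp, h, Pn[[paste0(bp, "Wq")]], Pn[[paste0(bp, "bq")]])
      src <- h
      if (R > 1L) {
        src <- adf_gather_cbind(tp, h, st$sr)
        src <- adf_linear(tp, src, Pn[[paste0(bp, "Ws")]],
                          Pn[[paste0(bp, "bs")]])
        src <- adf_layernorm(tp, src, Pn[[paste0(bp, "srlng")]],
                             Pn[[paste0(bp, "srlnb")]])
      }
      k <- adf_linear(tp, src, Pn[[paste0(bp, "Wk")]], Pn[[paste0(bp, "bk")]])
      v <- adf_linear(tp, src, Pn[[paste0(bp, "Wv")]], Pn[[paste0(bp, "bv")]])
      att <- if (cfg$use_attention_bias) {
        adf_attention(tp, q, k, v, B, H, dh,
                      bias = Pn[[paste0(bp, "abias")]],
                      bias_idx = st$bias$idx)
      } else {
        adf_attention(tp, q, k, v, B, H, dh)
      }
      att <- adf_linear(tp, att, Pn[[paste0(bp, "Wo")]], Pn[[paste0(bp, "bo")]])
      x <- adf_add(tp, x, att)
      h2 <- adf_layernorm(tp, x, Pn[[paste0(bp, "ln2g")]],
                          Pn[[paste0(bp, "ln2b")]])
      m <- adf_linear(tp, h2, Pn[[paste0(bp, "W1")]], Pn[[paste0(bp, "b1")]])
      m <- adf_gelu(tp, m)
      m <- adf_linear(tp, m, Pn[[paste0(bp, "W2")]], Pn[[paste0(bp, "b2")]])
      x <- adf_add(tp, x, m)
    }
    x <- adf_layernorm(tp, x, Pn[[paste0(pre, "lng")]],
                       Pn[[paste0(pre, "lnb")]])
    feats[[i]] <- x
  }

  if (cfg$use_feature_fusion) {
    gl <- grids[cfg$low_stage]
    flow <- adf_gather_cbind(tp, feats[[cfg$low_stage]], ix$conv_low)
    flow <- adf_gelu(tp, adf_linear(tp, flow, Pn[["ff.lowW"]],
                                    Pn[["ff.lowb"]]))
    fhigh <- adf_gather_cbind(tp, feats[[cfg$high_stage]], ix$conv_high)
    fhigh <- adf_gelu(tp, adf_linear(tp, fhigh, Pn[["ff.highW"]],
                                     Pn[["ff.highb"]]))
    if (!is.null(ix$upsample))
      fhigh <- adf_interp(tp, fhigh, ix$upsample, B)
    fused <- adf_cbind2(tp, flow, fhigh)
    pooled <- adf_mean_pool(tp, fused, B, gl * gl)
  } else {
    gh <- grids[cfg$high_stage]
    pooled <- adf_mean_pool(tp, feats[[cfg$high_stage]], B, gh * gh)
  }
  pooled <- adf_to_double(tp, pooled)

  hid <- ad_gelu(tp, ad_bias(tp, ad_mm(tp, pooled, Pn[["head.W1"]]),
                             Pn[["head.b1"]]))
  kp <- ad_sigmoid(tp, ad_bias(tp, ad_mm(tp, hid, Pn[["head.Wkp"]]),
                               Pn[["head.bkp"]]))
  if (cfg$use_orthogonal_layer)
    kp <- ad_orth(tp, kp, eps = cfg$orth_eps)

  logits <- if (cfg$head_mode == "aux_head") {
    ad_bias(tp, ad_mm(tp, pooled, Pn[["head.Wcls"]]), Pn[["head.bcls"]])
  } else {
    ad_softvhs_logits(tp, ad_vhs(tp, kp, factor = cfg$vhs_factor),
                      cfg$vhs_midpoints, cfg$soft_vhs_temperature)
  }

  list(tape = tp, params = Pn, keypoints = kp, logits = logits,
       features = feats, pooled = pooled)
}

## ---- prediction ------------------------------------------------------------

# stack a list of HxWx3 (or HxW) arrays into the (B*H*W) x 3 pixel matrix
stack_images <- function(images, input_size) {
  mats <- lapply(images, function(im) {
    if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(dim(im), 3L))
    if (dim(im)[1] != input_size || dim(im)[2] != input_size)
      stop("image is ", dim(im)[1], "x", dim(im)[2],
           " but the model expects ", input_size, "x", input_size,
           "; resize on load", call. = FALSE)
    # rows are pixels in row-major (y-major) order
    matrix(c(t(im[, , 1]), t(im[, , 2]), t(im[, , 3])), ncol = 3L)
  })
  do.call(rbind, mats)
}

#' Predict keypoints, VHS and cardiomegaly class for images
#'
#' Runs the forward pass and decodes the twelve regressed coordinates into
#' pixel keypoints, the VHS score and the three-class grade. The reported
#' `class` is always derived from the predicted VHS via [classify_vhs()], so
#' the geometric measurement and the diagnosis cannot disagree; the
#' classifier head's softmax probabilities are reported alongside.
#'
#' @param object An [rvt_model()].
#' @param images A list of images (`H x W` grayscale or `H x W x 3` arrays
#'   in `[0,1]`, already at the model's input size).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A tibble with one row per image: normalized coordinates
#'   (`nax`...`nfy`), pixel coordinates (`ax`...`fy`), `vhs`, `class`,
#'   `class_name` and class probabilities `p_small`, `p_normal`, `p_large`.
#' @export
predict.rvt_model <- function(object, images, batch_size = 16L, ...) {
  cfg <- object$config
  n <- length(images)
  out <- vector("list", ceiling(n / batch_size))
  for (ci in seq_along(out)) {
    sel <- ((ci - 1L) * batch_size + 1L):min(ci * batch_size, n)
    X <- stack_images(images[sel], cfg$input_size)
    fw <- rvt_forward(object, X, length(sel))
    out[[ci]] <- list(kp = fw$keypoints$val,
                      probs = row_softmax(fw$logits$val))
  }
  kp <- do.call(rbind, lapply(out, `[[`, "kp"))
  probs <- do.call(rbind, lapply(out, `[[`, "probs"))
  px <- kp * cfg$input_size
  colnames(kp) <- paste0("n", kp_flat_names)
  colnames(px) <- kp_flat_names
  seg <- function(c1, c2) sqrt((px[, c1[1]] - px[, c2[1]])^2 +
                               (px[, c1[2]] - px[, c2[2]])^2)
  # guarded against transiently collapsed EF in untrained models
  vhs <- cfg$vhs_factor * (seg(c(1, 2), c(3, 4)) + seg(c(5, 6), c(7, 8))) /
    pmax(seg(c(9, 10), c(11, 12)), 1e-9)
  cls <- classify_vhs(pmax(vhs, .Machine$double.eps), cfg$thresholds)
  tibble::tibble(
    image = seq_len(n),
    tibble::as_tibble(kp), tibble::as_tibble(px),
    vhs = vhs, class = cls,
    class_name = vhs_class_labels()[cls + 1L],
    p_small = probs[, 1], p_normal = probs[, 2], p_large = probs[, 3])
}
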