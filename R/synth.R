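#' Configuration of the synthetic radiograph generator
#'
#' The generator emulates the geometry that defines VHS scoring on a lateral
#' thoracic radiograph: a bright, gently curved vertebral column of repeated
#' segments along the top of the field, and an elliptical cardiac silhouette
#' whose major axis runs carina-to-apex with the minor axis perpendicular at
#' the widest point. Keypoints A-F are known exactly by construction, VHS is
#' controllable, and each image carries Gaussian noise, a smooth
#' illumination gradient, and a random rotation/translation of the whole
#' scene.
#'
#' @param image_size Square image side in pixels (default 96; use 512 to
#'   mirror the full-scale input contract).
#' @param class_proportions Probability of each class (small, normal,
#'   large); defaults to the 208/573/619 training mix of the reference
#'   dataset statistics.
#' @param vhs_ranges List of per-class VHS sampling intervals, consistent
#'   with [vhs_thresholds()].
#' @param noise_sd Additive Gaussian noise, intensity units of `[0,1]`.
#' @param max_rotation Maximum absolute scene rotation in degrees.
#' @param seed Integer seed used by [generate_dataset()].
#' @param thresholds A [vhs_thresholds()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(image_size = 96L,
                             class_proportions = c(208, 573, 619) / 1400,
                             vhs_ranges = list(small = c(6.5, 8.2),
                                               normal = c(8.2, 10),
                                               large = c(10, 13)),
                             noise_sd = 0.03,
                             max_rotation = 8,
                             seed = 1L,
                             thresholds = vhs_thresholds()) {
  if (length(class_proportions) != 3L || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (image_size < 48L)
    stop("image_size below 48 px leaves no room for the anatomy",
         call. = FALSE)
  rng <- vhs_ranges
  if (!all(c("small", "normal", "large") %in% names(rng)))
    stop("vhs_ranges needs small/normal/large entries", call. = FALSE)
  if (rng$small[2] > thresholds$low || rng$normal[1] < thresholds$low ||
      rng$normal[2] > thresholds$high || rng$large[1] < thresholds$high)
    stop("vhs_ranges inconsistent with thresholds", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 class_proportions = class_proportions,
                 vhs_ranges = rng, noise_sd = noise_sd,
                 max_rotation = max_rotation, seed = as.integer(seed),
                 thresholds = thresholds),
            class = "generator_config")
}

# smooth 0..1 ramp of a signed distance over an edge width
soft_edge <- function(s, width) pmin(pmax(s / width + 0.5, 0), 1)

# distance from points (x, y) to segment p1-p2
dist_to_segment <- function(x, y, p1, p2) {
  dx <- p2[1] - p1[1]
  dy <- p2[2] - p1[2]
  len2 <- dx * dx + dy * dy
  t <- ((x - p1[1]) * dx + (y - p1[2]) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (p1[1] + t * dx))^2 + (y - (p1[2] + t * dy))^2)
}

#' Generate one synthetic radiograph with exact keypoints
#'
#' Draws the scene geometry in a canonical frame, solves the cardiac axis
#' lengths so that `6 * (|AB| + |CD|) / |EF|` equals the requested VHS given
#' a random short/long aspect ratio in `[0.6, 0.85]`, applies a random
#' rotation and translation to the whole scene (keypoints transformed
#' identically), and renders vertebrae and cardiac silhouette with soft
#' edges, an illumination gradient and Gaussian noise.
#'
#' Uses the current R random number generator state; seed it (or call via
#' [generate_dataset()]) for reproducibility.
#'
#' @param cfg A [generator_config()].
#' @param target_class Class label 0/1/2 (VHS drawn uniformly in that
#'   class's range). Ignored when `target_vhs` is given.
#' @param target_vhs Exact VHS to realize; must lie in its class's range.
#' @return A list of class `synthetic_sample`: `image` (H x W matrix in
#'   `[0,1]`), `keypoints` ([keypoint_set()] in pixel coordinates),
#'   `vhs`, `class`, and `meta` (realized nuisance parameters).
#' @export
generate_sample <- function(cfg, target_class = NULL, target_vhs = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(target_vhs)) {
    if (is.null(target_class))
      target_class <- sample(0:2, 1L, prob = cfg$class_proportions)
    stopifnot(target_class %in% 0:2)
    r <- cfg$vhs_ranges[[target_class + 1L]]
    target_vhs <- stats::runif(1, r[1], r[2])
    # keep off the open boundary of the small class
    if (target_class == 0L && target_vhs >= cfg$thresholds$low)
      target_vhs <- r[1] + 0.999 * (cfg$thresholds$low - r[1])
  } else {
    cls <- classify_vhs(target_vhs, cfg$thresholds)
    if (!is.null(target_class) && cls != target_class)
      stop("target_vhs ", target_vhs, " is inconsistent with target_class ",
           target_class, " under the configured thresholds", call. = FALSE)
    target_class <- cls
    r <- cfg$vhs_ranges[[target_class + 1L]]
    if (target_vhs < r[1] - 1e-9 || target_vhs > r[2] + 1e-9)
      stop("target_vhs ", target_vhs, " outside the configured range [",
           r[1], ", ", r[2], "] of its class", call. = FALSE)
  }

  S <- cfg$image_size
  nseg <- 11L
  x0 <- 0.06 * S
  v <- 0.08 * S                       # vertebral unit (per-segment length)
  y_base <- (0.16 + stats::runif(1, -0.02, 0.02)) * S
  curv <- stats::runif(1, -0.18, 0.18) / S
  spine_y <- function(x) y_base + curv * (x - S / 2)^2

  # vertebral reference: E at cranial edge of segment 4, F caudal edge of 9
  xE <- x0 + 3 * v
  xF <- x0 + 9 * v
  E <- c(xE, spine_y(xE))
  F_ <- c(xF, spine_y(xF))
  L_ef <- segment_length(E, F_)

  # cardiac ellipse solved against the realized |EF| chord
  aspect <- stats::runif(1, 0.6, 0.85)
  ab <- target_vhs * L_ef / (6 * (1 + aspect))   # |AB|
  cd <- aspect * ab                              # |CD|
  phi <- stats::runif(1, 20, 40) * pi / 180      # apex tilt from vertical
  u <- c(sin(phi), cos(phi))                     # carina -> apex direction
  uperp <- c(u[2], -u[1])
  xA <- (0.40 + stats::runif(1, -0.04, 0.04)) * S
  A <- c(xA, spine_y(xA) + 0.09 * S)
  B <- A + ab * u
  ctr <- (A + B) / 2
  C <- ctr - (cd / 2) * uperp
  D <- ctr + (cd / 2) * uperp

  # rigid transform of the whole scene; translation clamped so that all
  # keypoints stay inside the field with a margin
  theta <- stats::runif(1, -cfg$max_rotation, cfg$max_rotation) * pi / 180
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  cen <- c(S / 2, S / 2)
  pts <- list(A = A, B = B, C = C, D = D, E = E, F = F_)
  rot <- lapply(pts, function(p) as.numeric(Rm %*% (p - cen)) + cen)
  spine_ends <- lapply(list(c(x0, spine_y(x0)),
                            c(x0 + nseg * v, spine_y(x0 + nseg * v))),
                       function(p) as.numeric(Rm %*% (p - cen)) + cen)
  allp <- do.call(rbind, c(rot, spine_ends))
  mar <- 0.04 * S
  want <- stats::runif(2, -0.04, 0.04) * S
  tx <- pmin(pmax(want[1], mar - min(allp[, 1])), S - mar - max(allp[, 1]))
  ty <- pmin(pmax(want[2], mar - min(allp[, 2])), S - mar - max(allp[, 2]))
  shift <- c(tx, ty)
  kps <- new_keypoint_set(lapply(rot, function(p) p + shift))

  # render by inverse-transforming pixel centers into the canonical frame
  px <- rep(seq_len(S) - 0.5, times = S)        # x varies fastest
  py <- rep(seq_len(S) - 0.5, each = S)
  qx <- px - cen[1] - shift[1]
  qy <- py - cen[2] - shift[2]
  cx <- cos(theta) * qx + sin(theta) * qy + cen[1]
  cy <- -sin(theta) * qx + cos(theta) * qy + cen[2]

  img <- rep(0.12, S * S)
  grad_dir <- stats::runif(1, 0, 2 * pi)
  grad_amp <- stats::runif(1, 0.02, 0.08)
  img <- img + grad_amp * ((cos(grad_dir) * px + sin(grad_dir) * py) / S)

  # heart: approximate signed distance from the ellipse boundary
  dxh <- cx - (ctr[1])
  dyh <- cy - (ctr[2])
  tu <- dxh * u[1] + dyh * u[2]
  tv <- dxh * uperp[1] + dyh * uperp[2]
  qval <- (tu / (ab / 2))^2 + (tv / (cd / 2))^2
  sdist <- (1 - qval) * (cd / 4)
  img <- pmax(img, 0.52 * soft_edge(sdist, 1.5))

  # vertebrae: capsules along the curved spine with small gaps
  gap <- 0.18 * v
  for (i in seq_len(nseg)) {
    xs <- x0 + (i - 1) * v + gap / 2
    xe <- x0 + i * v - gap / 2
    d <- dist_to_segment(cx, cy, c(xs, spine_y(xs)), c(xe, spine_y(xe)))
    img <- pmax(img, 0.88 * soft_edge(0.024 * S - d, 1.0))
  }

  img <- img + stats::rnorm(S * S, 0, cfg$noise_sd)
  img <- matrix(pmin(pmax(img, 0), 1), nrow = S, ncol = S, byrow = TRUE)

  true_vhs <- vhs_score(kps)
  structure(list(image = img, keypoints = kps, vhs = true_vhs,
                 class = classify_vhs(true_vhs, cfg$thresholds),
                 meta = list(target_vhs = target_vhs, aspect = aspect,
                             rotation_deg = theta * 180 / pi,
                             noise_sd = cfg$noise_sd)),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %dx%d  VHS %.3f  class %d (%s)\n",
              nrow(x$image), ncol(x$image), x$vhs, x$class,
              vhs_class_labels()[x$class + 1L]))
  invisible(x)
}

#' Generate a list of synthetic samples in memory
#'
#' Classes are drawn from `cfg$class_proportions`; see [generate_sample()].
#' Seeds the R generator from `cfg$seed` unless `seed` is given.
#'
#' @param cfg A [generator_config()].
#' @param n Number of samples.
#' @param seed Overrides `cfg$seed`.
#' @return List of `synthetic_sample` objects.
#' @export
generate_samples <- function(cfg, n, seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed else seed)
  classes <- sample(0:2, n, replace = TRUE, prob = cfg$class_proportions)
  lapply(classes, function(cl) generate_sample(cfg, target_class = cl))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` grayscale PNGs plus an annotation CSV (see
#' [write_annotations()]) and a YAML manifest with realized per-class
#' counts. Classes are a multinomial draw under `cfg$class_proportions`
#' with `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @param n Number of images (>= 3).
#' @param out_dir Output directory (created if missing).
#' @param prefix Image id prefix.
#' @return Invisibly, the manifest list (`n`, `counts`, paths).
#' @export
generate_dataset <- function(cfg, n, out_dir, prefix = "synth") {
  stopifnot(inherits(cfg, "generator_config"), n >= 3L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  samples <- generate_samples(cfg, n)
  ids <- sprintf("%s_%05d", prefix, seq_len(n))
  for (i in seq_len(n))
    png::writePNG(samples[[i]]$image,
                  file.path(out_dir, paste0(ids[i], ".png")))
  ann <- purrr::map2_dfr(samples, ids, function(s, id) {
    kv <- kp_flatten(s$keypoints)
    tibble::tibble(image_id = id, !!!as.list(kv), status = "ground_truth",
                   vhs = s$vhs, class = s$class)
  })
  ann_path <- file.path(out_dir, "annotations.csv")
  write_annotations(ann, ann_path)
  counts <- vapply(0:2, function(k) sum(ann$class == k), integer(1))
  manifest <- list(n = n, counts = list(small = counts[1],
                                        normal = counts[2],
                                        large = counts[3]),
                   image_size = cfg$image_size, seed = cfg$seed,
                   noise_sd = cfg$noise_sd,
                   max_rotation = cfg$max_rotation,
                   annotations = "annotations.csv")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}

#' Plot a synthetic sample with its keypoints
#'
#' Renders the image with the long axis (A-B), short axis (C-D) and
#' vertebral reference (E-F) overlaid.
#'
#' @param object A `synthetic_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_sample <- function(object, ...) {
  S <- nrow(object$image)
  df <- tidyr::expand_grid(y = seq_len(S), x = seq_len(S))
  df$value <- as.vector(t(object$image))
  kv <- kp_flatten(object$keypoints)
  segs <- tibble::tibble(
    axis = c("long (AB)", "short (CD)", "vertebral (EF)"),
    x = kv[c("ax", "cx", "ex")], y = kv[c("ay", "cy", "ey")],
    xend = kv[c("bx", "dx", "fx")], yend = kv[c("by", "dy", "fy")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       colour = .data$axis),
                          linewidth = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("VHS %.2f (%s)", object$vhs,
                                  vhs_class_labels()[object$class + 1L]),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
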