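#' Six-point cardiac keypoint set
#'
#' Container for the six anatomical landmarks used in vertebral heart scale
#' (VHS) measurement on a lateral thoracic radiograph:
#' * `A`, `B` — endpoints of the heart's long axis, drawn from the carina
#'   (tracheal bifurcation) to the apex of the cardiac silhouette;
#' * `C`, `D` — endpoints of the short axis, the widest heart dimension,
#'   perpendicular to the long axis;
#' * `E`, `F` — endpoints of the vertebral reference segment, from the
#'   cranial aspect of the fourth thoracic vertebra (T4) to the caudal end
#'   of the ninth vertebra (six vertebral lengths).
#'
#' Coordinates are pixels in the source image, origin at the top-left,
#' `x` increasing rightward and `y` increasing downward.
#'
#' @param A,B,C,D,E,F Numeric length-2 vectors `c(x, y)` in pixels.
#' @return An object of class `keypoint_set`: a named list of six points.
#' @examples
#' kp <- keypoint_set(A = c(0, 0), B = c(0, 6), C = c(0, 0),
#'                    D = c(4, 0), E = c(0, 0), F = c(12, 0))
#' vhs_score(kp)
#' @export
keypoint_set <- function(A, B, C, D, E, F) {
  pts <- list(A = A, B = B, C = C, D = D, E = E, F = F)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2L || !all(is.finite(p)))
      stop("keypoint ", nm, " must be a finite length-2 numeric (x, y)",
           call. = FALSE)
    pts[[nm]] <- p
  }
  for (pair in list(c("A", "B"), c("C", "D"), c("E", "F"))) {
    if (identical(pts[[pair[1]]], pts[[pair[2]]]))
      stop("segment ", pair[1], pair[2], " has zero length", call. = FALSE)
  }
  new_keypoint_set(pts)
}

# internal constructor without distinctness checks (orthogonal projection may
# in principle collapse a segment; downstream scoring still validates EF)
new_keypoint_set <- function(pts) {
  structure(pts, class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat("<keypoint_set>\n")
  for (nm in names(x))
    cat(sprintf("  %s: (%.3f, %.3f)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' @export
format.keypoint_set <- function(x, ...) {
  paste0("keypoint_set[", paste(
    vapply(names(x), function(nm) sprintf("%s=(%.4g,%.4g)", nm,
                                          x[[nm]][1], x[[nm]][2]), ""),
    collapse = " "), "]")
}

#' Euclidean length of a segment
#'
#' @param p,q Numeric length-2 points `c(x, y)`.
#' @return Non-negative scalar distance in the units of the inputs.
#' @examples
#' segment_length(c(0, 0), c(3, 4)) # 5
#' @export
segment_length <- function(p, q) {
  stopifnot(is.finite(p), is.finite(q), length(p) == 2L, length(q) == 2L)
  sqrt(sum((p - q)^2))
}

#' Vertebral heart scale from a keypoint set
#'
#' Computes `VHS = factor * (|AB| + |CD|) / |EF|`: the summed long- and
#' short-axis lengths of the heart expressed in vertebral units. The factor 6
#' converts the vertebral segment E–F (which spans six vertebrae, T4–T9) into
#' single-vertebra units, giving the conventional clinical scale.
#'
#' The score is a ratio of lengths, hence invariant under rotation,
#' translation and uniform scaling of all six points.
#'
#' @param kps A [keypoint_set()].
#' @param factor Vertebrae spanned by E–F. Default 6.
#' @param eps Degeneracy tolerance on `|EF|` in pixels.
#' @return Positive scalar VHS in vertebral units.
#' @export
vhs_score <- function(kps, factor = 6, eps = 1e-9) {
  stopifnot(inherits(kps, "keypoint_set"))
  ef <- segment_length(kps$E, kps$F)
  if (!is.finite(ef) || ef <= eps)
    stop("degenerate geometry: |EF| = ", format(ef),
         " is below tolerance; VHS undefined", call. = FALSE)
  factor * (segment_length(kps$A, kps$B) + segment_length(kps$C, kps$D)) / ef
}

#' VHS classification thresholds
#'
#' Cut points separating small, normal and large hearts on the VHS scale.
#' Defaults follow the clinically tuned values 8.2 and 10: scores below 8.2
#' are small, between 8.2 and 10 inclusive normal, above 10 large
#' (cardiomegaly).
#'
#' @param low,high Threshold values in VHS units, `0 < low < high`.
#' @return A named list of class `vhs_thresholds`.
#' @export
vhs_thresholds <- function(low = 8.2, high = 10) {
  if (!is.numeric(low) || !is.numeric(high) || !(low > 0) || !(low < high))
    stop("thresholds must satisfy 0 < low < high", call. = FALSE)
  structure(list(low = low, high = high), class = "vhs_thresholds")
}

#' Classify a VHS score as small / normal / large
#'
#' Boundary values belong to the normal class: class 0 for `vhs < low`,
#' class 1 for `low <= vhs <= high`, class 2 for `vhs > high`.
#'
#' @param vhs Numeric vector of positive VHS scores.
#' @param thresholds A [vhs_thresholds()].
#' @return Integer vector of class labels in `{0, 1, 2}`.
#' @examples
#' classify_vhs(c(8.1, 8.2, 10, 10.1)) # 0 1 1 2
#' @export
classify_vhs <- function(vhs, thresholds = vhs_thresholds()) {
  stopifnot(inherits(thresholds, "vhs_thresholds"))
  if (!is.numeric(vhs) || any(!is.finite(vhs)) || any(vhs <= 0))
    stop("vhs must be positive and finite", call. = FALSE)
  ifelse(vhs < thresholds$low, 0L, ifelse(vhs <= thresholds$high, 1L, 2L))
}

#' Human-readable class names
#'
#' @return Character vector indexed by `class + 1`.
#' @export
vhs_class_labels <- function() c("small", "normal", "large")

#' Project the short axis perpendicular to the long axis
#'
#' The clinical VHS convention requires the short axis CD to meet the long
#' axis AB at a right angle. `orthogonalize` enforces this by replacing the
#' y-coordinate of D: with points numbered A = 1, B = 2, C = 3, D = 4, the
#' perpendicular slope is `s = -(x1 - x2)/(y1 - y2)` and the new coordinate
#' is `y4_hat = s * (x4 - x3) + y3`, so that C–D' lies on the line through C
#' with slope `s`. Only D changes (and only its y, except in the degenerate
#' branch); A, B, C, E, F are untouched.
#'
#' When AB is horizontal (`|y1 - y2| < eps`) the perpendicular is vertical
#' and a slope does not exist; the symmetric rule is applied instead: D's
#' x-coordinate is replaced by C's, keeping D's y. Both branches give an
#' exactly perpendicular AB–CD pair, and the map is idempotent.
#'
#' @param kps A [keypoint_set()] with `A != B`.
#' @param eps Degeneracy tolerance on `|y1 - y2|` in pixels.
#' @return A `keypoint_set` with AB perpendicular to CD.
#' @examples
#' kp <- keypoint_set(A = c(0, 0), B = c(0, 2), C = c(1, 1), D = c(3, 5),
#'                    E = c(0, 10), F = c(12, 10))
#' orthogonalize(kp)$D # (3, 1)
#' @export
orthogonalize <- function(kps, eps = 1e-6) {
  stopifnot(inherits(kps, "keypoint_set"))
  x1 <- kps$A[1]; y1 <- kps$A[2]
  x2 <- kps$B[1]; y2 <- kps$B[2]
  x3 <- kps$C[1]; y3 <- kps$C[2]
  x4 <- kps$D[1]; y4 <- kps$D[2]
  pts <- unclass(kps)
  if (abs(y1 - y2) < eps) {
    pts$D <- c(x3, y4)                       # AB horizontal: CD made vertical
  } else {
    s <- -(x1 - x2) / (y1 - y2)
    pts$D <- c(x4, s * (x4 - x3) + y3)
  }
  new_keypoint_set(pts)
}

kp_point_names <- c("A", "B", "C", "D", "E", "F")

kp_flat_names <- c("ax", "ay", "bx", "by", "cx", "cy",
                   "dx", "dy", "ex", "ey", "fx", "fy")

#' Flatten a keypoint set to a 12-vector and back
#'
#' The flat ordering is `(Ax, Ay, Bx, By, Cx, Cy, Dx, Dy, Ex, Ey, Fx, Fy)`,
#' matching the twelve output units of the regression head.
#'
#' @param kps A [keypoint_set()].
#' @return `kp_flatten`: a named numeric vector of length 12.
#' @export
kp_flatten <- function(kps) {
  stopifnot(inherits(kps, "keypoint_set"))
  stats::setNames(unlist(kps[kp_point_names], use.names = FALSE),
                  kp_flat_names)
}

#' @rdname kp_flatten
#' @param v Numeric vector of length 12 in flat ordering.
#' @param validate Check segment non-degeneracy (disable for raw model
#'   output, which may transiently collapse a segment).
#' @return `kp_unflatten`: a `keypoint_set`.
#' @export
kp_unflatten <- function(v, validate = TRUE) {
  v <- as.numeric(v)
  if (length(v) != 12L)
    stop("expected a 12-vector (Ax,Ay,...,Fx,Fy); got length ", length(v),
         call. = FALSE)
  if (any(!is.finite(v)))
    stop("keypoint vector contains non-finite values", call. = FALSE)
  pts <- stats::setNames(
    lapply(seq_len(6L), function(i) v[c(2L * i - 1L, 2L * i)]),
    kp_point_names)
  if (validate) do.call(keypoint_set, pts) else new_keypoint_set(pts)
}

# dot product of AB and CD; zero iff axes perpendicular
kp_axes_dot <- function(kps) {
  ab <- kps$B - kps$A
  cd <- kps$D - kps$C
  sum(ab * cd)
}

# |cos angle(AB, CD)|, guarding zero-length segments
kp_axes_abs_cos <- function(kps) {
  ab <- kps$B - kps$A
  cd <- kps$D - kps$C
  nab <- sqrt(sum(ab^2)); ncd <- sqrt(sum(cd^2))
  if (nab == 0 || ncd == 0) return(NA_real_)
  abs(sum(ab * cd)) / (nab * ncd)
}
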