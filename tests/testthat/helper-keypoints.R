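# Random valid keypoint sets for property tests.
random_keypoint_set <- function(span = 100) {
  repeat {
    v <- stats::runif(12, 0, span)
    kp <- try(kp_unflatten(v), silent = TRUE)
    if (!inherits(kp, "try-error") &&
        abs(kp$A[2] - kp$B[2]) > 1e-3 &&
        segment_length(kp$E, kp$F) > 1)
      return(kp)
  }
}

# apply a similarity transform (rotation theta, uniform scale, translation)
# to every point of a keypoint set
transform_keypoint_set <- function(kps, theta, scale, shift) {
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  pts <- lapply(unclass(kps), function(p) as.numeric(scale * Rm %*% p + shift))
  vhsnet:::new_keypoint_set(pts)
}
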