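# Keypoint annotation I/O. The canonical on-disk format is a plain CSV with
# one row per image:
#   image_id,ax,ay,bx,by,cx,cy,dx,dy,ex,ey,fx,fy,status[,vhs,class]
# Coordinates are pixels in the stored image (origin top-left, y down);
# status is one of ground_truth / coarse / verified, mirroring the labeling
# workflow (model-proposed coarse points later verified by a human). A JSON
# mirror is provided for interchange.

ann_required_cols <- c("image_id", "ax", "ay", "bx", "by", "cx", "cy",
                       "dx", "dy", "ex", "ey", "fx", "fy", "status")
ann_statuses <- c("ground_truth", "coarse", "verified")

#' Read or write keypoint annotation files
#'
#' `write_annotations()` writes a tibble of annotation records to CSV with
#' 6-decimal coordinates; `read_annotations()` reads one back, validating
#' structure (all coordinate columns present, unique ids, finite values)
#' and internal consistency: when a `vhs` column is stored it must agree
#' with the VHS recomputed from the row's keypoints to 1e-4 (a warning
#' lists offending ids), and a stored `class` must equal
#' `classify_vhs(vhs)`.
#'
#' @param records A data frame with columns
#'   `image_id, ax, ay, ..., fx, fy, status` and optionally `vhs`, `class`.
#' @param path File path.
#' @return `read_annotations()`: a tibble of records.
#' @export
write_annotations <- function(records, path) {
  records <- tibble::as_tibble(records)
  miss <- setdiff(ann_required_cols, names(records))
  if (length(miss) > 0)
    stop("annotation records missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- dplyr::mutate(records, dplyr::across(
    dplyr::all_of(c(kp_flat_names,
                    intersect("vhs", names(records)))),
    function(x) sprintf("%.6f", x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path,
                               call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(ann_required_cols, names(df))
  if (length(miss) > 0)
    stop("annotation file ", path, " missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cc in kp_flat_names) df[[cc]] <- as.numeric(df[[cc]])
  bad <- !stats::complete.cases(df[kp_flat_names]) |
    !apply(is.finite(as.matrix(df[kp_flat_names])), 1L, all)
  if (any(bad))
    stop("non-finite coordinates in rows: ",
         paste(which(bad), collapse = ", "), " (ids ",
         paste(df$image_id[bad], collapse = ", "), ")", call. = FALSE)
  dup <- duplicated(df$image_id)
  if (any(dup))
    stop("duplicate image ids in ", path, ": ",
         paste(unique(df$image_id[dup]), collapse = ", "), call. = FALSE)
  if (!all(df$status %in% ann_statuses))
    stop("invalid status values: ",
         paste(setdiff(unique(df$status), ann_statuses), collapse = ", "),
         call. = FALSE)
  if ("vhs" %in% names(df)) {
    recomputed <- annotation_vhs(df)
    off <- which(abs(df$vhs - recomputed) > 1e-4)
    if (length(off) > 0)
      warning("stored vhs disagrees with keypoints (>1e-4) for ids: ",
              paste(df$image_id[off], collapse = ", "), call. = FALSE)
    if ("class" %in% names(df)) {
      offc <- which(df$class != classify_vhs(pmax(df$vhs, 1e-9)))
      if (length(offc) > 0)
        warning("stored class disagrees with classify_vhs(vhs) for ids: ",
                paste(df$image_id[offc], collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Recompute VHS for each annotation row
#'
#' @param records Annotation tibble (pixel keypoint columns `ax`...`fy`).
#' @param factor Vertebral factor, default 6.
#' @return Numeric vector of VHS scores.
#' @export
annotation_vhs <- function(records, factor = 6) {
  m <- as.matrix(records[kp_flat_names])
  seg <- function(c1, c2) sqrt((m[, c1[1]] - m[, c2[1]])^2 +
                               (m[, c1[2]] - m[, c2[2]])^2)
  factor * (seg(c(1, 2), c(3, 4)) + seg(c(5, 6), c(7, 8))) /
    pmax(seg(c(9, 10), c(11, 12)), 1e-9)
}

#' Keypoint sets from annotation rows
#'
#' @param records Annotation tibble.
#' @return A list of [keypoint_set()] objects, named by `image_id`.
#' @export
annotation_keypoints <- function(records) {
  m <- as.matrix(records[kp_flat_names])
  out <- lapply(seq_len(nrow(m)), function(i)
    kp_unflatten(m[i, ], validate = FALSE))
  stats::setNames(out, records$image_id)
}

#' JSON mirror of the annotation format
#'
#' @inheritParams write_annotations
#' @export
write_annotations_json <- function(records, path) {
  jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Bind annotation records to an image directory as a named split
#'
#' Asserts that every record's image exists and ids are unique.
#'
#' @param name Split name: training / validation / test (free-form allowed
#'   for ad-hoc splits).
#' @param records Annotation tibble.
#' @param image_dir Directory containing `<image_id>.png` files.
#' @return A list of class `dataset_split`.
#' @export
dataset_split <- function(name, records, image_dir) {
  records <- tibble::as_tibble(records)
  if (anyDuplicated(records$image_id))
    stop("duplicate ids in split ", name, call. = FALSE)
  paths <- file.path(image_dir, paste0(records$image_id, ".png"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("split ", name, ": missing image files for ids ",
         paste(utils::head(records$image_id[missing], 5), collapse = ", "),
         if (sum(missing) > 5) " ..." else "", call. = FALSE)
  structure(list(name = name, records = records, image_dir = image_dir),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %s: %d records in %s\n",
              x$name, nrow(x$records), x$image_dir))
  invisible(x)
}

#' Partition annotation records into disjoint named splits
#'
#' @param records Annotation tibble.
#' @param image_dir Image directory shared by the splits.
#' @param fractions Named numeric vector summing to 1, e.g.
#'   `c(training = 0.7, validation = 0.1, test = 0.2)`.
#' @param seed Shuffling seed.
#' @return Named list of [dataset_split()]s with pairwise-disjoint ids.
#' @export
split_records <- function(records, image_dir,
                          fractions = c(training = 0.7, validation = 0.1,
                                        test = 0.2),
                          seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  n <- nrow(records)
  set.seed(seed)
  ord <- sample.int(n)
  sizes <- floor(fractions * n)
  sizes[1] <- n - sum(sizes[-1])
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  out <- purrr::pmap(list(names(fractions), starts, stops),
                     function(nm, a, b) {
                       dataset_split(nm, records[ord[seq(a, b)], ],
                                     image_dir)
                     })
  names(out) <- names(fractions)
  ids <- lapply(out, function(s) s$records$image_id)
  stopifnot(length(Reduce(intersect, ids)) == 0)
  out
}

# bilinear resize of a single-channel image matrix to sq x sq
resize_bilinear <- function(img, sq) {
  if (nrow(img) == sq && ncol(img) == sq) return(img)
  Uy <- bilinear_matrix_1d(sq, nrow(img))
  Ux <- bilinear_matrix_1d(sq, ncol(img))
  Uy %*% img %*% t(Ux)
}

#' Load a split as model-ready tensors
#'
#' Reads each image, converts to grayscale if needed, resizes
#' (anisotropically for non-square sources) to `input_size x input_size`,
#' and normalizes keypoint targets to `[0,1]` by the *original* image
#' width/height — the same fractional coordinates the resized image
#' represents. Unreadable images are skipped with a warning and counted.
#'
#' @param split A [dataset_split()].
#' @param input_size Square model input in pixels.
#' @return A list of class `model_inputs`: `images` (list of matrices),
#'   `targets` (n x 12 normalized coordinates), `classes` (integer,
#'   derived via [classify_vhs()] when not stored), `ids`, `n_skipped`.
#' @export
load_model_inputs <- function(split, input_size) {
  stopifnot(inherits(split, "dataset_split"))
  rec <- split$records
  images <- vector("list", nrow(rec))
  keep <- logical(nrow(rec))
  targets <- matrix(NA_real_, nrow(rec), 12L,
                    dimnames = list(NULL, kp_flat_names))
  for (i in seq_len(nrow(rec))) {
    path <- file.path(split$image_dir, paste0(rec$image_id[i], ".png"))
    img <- tryCatch(png::readPNG(path), error = function(e) NULL)
    if (is.null(img)) next
    if (length(dim(img)) == 3L) img <- img[, , 1]
    h0 <- nrow(img)
    w0 <- ncol(img)
    images[[i]] <- resize_bilinear(img, input_size)
    kv <- as.numeric(rec[i, kp_flat_names])
    targets[i, ] <- kv / rep(c(w0, h0), 6L)     # x by width, y by height
    keep[i] <- TRUE
  }
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    warning("skipped ", n_skipped, " unreadable image(s) in split ",
            split$name, call. = FALSE)
  vhs <- annotation_vhs(rec[keep, ])
  classes <- if ("class" %in% names(rec)) {
    as.integer(rec$class[keep])
  } else {
    classify_vhs(pmax(vhs, 1e-9))
  }
  structure(list(images = images[keep],
                 targets = targets[keep, , drop = FALSE],
                 classes = classes, vhs = vhs,
                 ids = rec$image_id[keep], n_skipped = n_skipped,
                 input_size = input_size),
            class = "model_inputs")
}

# in-memory counterpart of load_model_inputs for generated samples
samples_to_inputs <- function(samples, input_size = NULL) {
  S <- nrow(samples[[1]]$image)
  if (is.null(input_size)) input_size <- S
  targets <- do.call(rbind, lapply(samples, function(s)
    kp_flatten(s$keypoints) / S))
  images <- lapply(samples, function(s)
    resize_bilinear(s$image, input_size))
  structure(list(images = images, targets = targets,
                 classes = vapply(samples, `[[`, integer(1), "class"),
                 vhs = vapply(samples, `[[`, numeric(1), "vhs"),
                 ids = sprintf("mem_%05d", seq_along(samples)),
                 n_skipped = 0L, input_size = input_size),
            class = "model_inputs")
}

#' @export
print.model_inputs <- function(x, ...) {
  cat(sprintf("<model_inputs> %d images at %dx%d (%d skipped)\n",
              length(x$images), x$input_size, x$input_size, x$n_skipped))
  invisible(x)
}
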