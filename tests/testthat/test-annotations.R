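make_records <- function(n, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n), function(i) {
    kp <- random_keypoint_set(span = 48)
    kv <- kp_flatten(kp)
    tibble::tibble(image_id = sprintf("img_%03d", i), !!!as.list(kv),
                   status = "ground_truth",
                   vhs = vhs_score(kp),
                   class = classify_vhs(max(vhs_score(kp), 1e-9)))
  })
}

test_that("annotation write/read round-trips to 1e-6", {
  rec <- make_records(10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(rec, path)
  back <- suppressWarnings(read_annotations(path))
  expect_equal(nrow(back), 10)
  for (cc in vhsnet:::kp_flat_names)
    expect_equal(back[[cc]], rec[[cc]], tolerance = 1e-6)
  expect_identical(back$status, rec$status)
})

test_that("malformed annotation files are rejected with named offenders", {
  rec <- make_records(3)
  path <- withr::local_tempfile(fileext = ".csv")

  write_annotations(rec, path)
  txt <- readLines(path)
  # drop one coordinate column entirely
  broken <- gsub("^image_id,ax,", "image_id,zz,", txt)
  writeLines(broken, path)
  expect_error(read_annotations(path), "missing columns")

  # non-finite coordinate names the row
  rec2 <- rec
  rec2$ax[2] <- NA_real_
  readr::write_csv(rec2, path, progress = FALSE)
  expect_error(read_annotations(path), "img_002")

  # duplicate ids
  rec3 <- rec
  rec3$image_id[2] <- rec3$image_id[1]
  write_annotations(rec3, path)
  expect_error(read_annotations(path), "duplicate")

  # stored vhs inconsistent with points -> warning listing the id
  rec4 <- rec
  rec4$vhs[3] <- rec4$vhs[3] + 1
  write_annotations(rec4, path)
  w <- capture_warnings(read_annotations(path))
  expect_true(any(grepl("img_003", w)))
})

test_that("load_model_inputs rescales and normalizes coordinates", {
  dir <- withr::local_tempdir()
  # non-square source image: 40 wide x 30 tall
  img <- matrix(runif(30 * 40), 30, 40)
  png::writePNG(img, file.path(dir, "one.png"))
  rec <- tibble::tibble(image_id = "one",
                        ax = 20, ay = 15, bx = 40, by = 30, cx = 10,
                        cy = 10, dx = 30, dy = 20, ex = 5, ey = 5,
                        fx = 35, fy = 25, status = "ground_truth")
  split <- dataset_split("t", rec, dir)
  inp <- load_model_inputs(split, 16L)
  expect_equal(dim(inp$images[[1]]), c(16L, 16L))
  # centre point (20,15) of a 40x30 image -> (0.5, 0.5); corner -> (1, 1)
  expect_equal(unname(inp$targets[1, c("ax", "ay")]), c(0.5, 0.5))
  expect_equal(unname(inp$targets[1, c("bx", "by")]), c(1, 1))
  # classes derived via classify_vhs when absent
  expect_identical(inp$classes,
                   classify_vhs(pmax(annotation_vhs(rec), 1e-9)))

  # unreadable image is skipped with a warning, not an error
  writeLines("not a png", file.path(dir, "bad.png"))
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec, image_id = "bad"))
  split2 <- dataset_split("t2", rec2, dir)
  expect_warning(inp2 <- load_model_inputs(split2, 16L), "skipped")
  expect_length(inp2$images, 1)
  expect_equal(inp2$n_skipped, 1L)
})

test_that("normalize/denormalize round-trips pixels for any image size", {
  set.seed(3)
  for (i in 1:20) {
    w <- sample(20:200, 1)
    h <- sample(20:200, 1)
    px <- runif(12, 0, rep(c(w, h), 6))
    norm <- px / rep(c(w, h), 6)
    expect_equal(norm * rep(c(w, h), 6), px, tolerance = 1e-6)
  }
})

test_that("split_records yields disjoint splits covering all records", {
  dir <- withr::local_tempdir()
  rec <- make_records(20)
  for (id in rec$image_id)
    png::writePNG(matrix(runif(16 * 16), 16), file.path(dir, paste0(id, ".png")))
  sp <- split_records(rec, dir, c(training = 0.7, validation = 0.1,
                                  test = 0.2), seed = 4)
  ids <- lapply(sp, function(s) s$records$image_id)
  expect_equal(sort(unname(unlist(ids))), sort(rec$image_id))
  expect_length(intersect(ids$training, ids$validation), 0)
  expect_length(intersect(ids$training, ids$test), 0)
  expect_length(intersect(ids$validation, ids$test), 0)
  # missing image file is caught
  expect_error(dataset_split("x", dplyr::mutate(rec, image_id = paste0(image_id, "_nope")), dir),
               "missing image files")
})

test_that("JSON mirror writes parseable records", {
  rec <- make_records(4)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations_json(rec, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back), 4)
  expect_equal(back$ax, rec$ax, tolerance = 1e-9)
})
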