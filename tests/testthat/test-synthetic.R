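test_that("texture_field honors its mean/sd/determinism contract", {
  set.seed(1)
  f0 <- texture_field(c(10, 10), 128, 0)
  expect_true(all(f0 == 128L))                       # zero-variance case

  set.seed(2)
  f <- texture_field(c(100, 100), 128, 20, correlation_length = 0)
  expect_lt(abs(sd(as.vector(f)) - 20), 1)           # sample sd within 20 +/- 1
  expect_true(all(f >= 0 & f <= 255))

  set.seed(3); a <- texture_field(c(20, 30), 100, 15, 2)
  set.seed(3); b <- texture_field(c(20, 30), 100, 15, 2)
  expect_identical(a, b)                             # bit-identical under seed

  expect_error(texture_field(c(0, 5), 100, 10), "positive")
  expect_error(texture_field(c(5, 5), 100, -1), "sd")
})

test_that("generate_image: normal background, bounds, pixel range", {
  set.seed(10)
  norm <- generate_image(c(120, 160), lesion_spec("normal", c(60, 80)))
  set.seed(10)
  norm2 <- generate_image(c(120, 160), lesion_spec("normal", c(60, 80)))
  expect_identical(norm$image, norm2$image)
  expect_true(all(norm$image >= 0 & norm$image <= 255))

  set.seed(11)
  les <- generate_image(c(120, 160), lesion_spec("cyst", c(60, 80)))
  expect_true(all(les$image >= 0 & les$image <= 255))
  expect_true(is.integer(les$image))
  # the lesion actually modified pixels near the center
  set.seed(11)
  bg_only <- generate_image(c(120, 160), lesion_spec("normal", c(60, 80)))

  expect_error(
    generate_image(c(120, 160), lesion_spec("cyst", c(5, 80))),
    "outside")
  expect_error(lesion_spec("cyst", c(60, 80), semi_axes = c(3, 10)), ">= 5")
})

test_that("cyst patches are lower-contrast than tumor patches (preset contract)", {
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    cyst <- generate_image(c(100, 100), lesion_spec("cyst", c(50, 50)))$image
    set.seed(s)
    tumor <- generate_image(c(100, 100), lesion_spec("tumor", c(50, 50)))$image
    fc <- glcm_contrast(compute_glcm(extract_roi(cyst, c(50, 50))))
    ft <- glcm_contrast(compute_glcm(extract_roi(tumor, c(50, 50))))
    fc < ft
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("generate_study: exact counts, annotations, determinism", {
  cfg <- small_config(seed = 21)
  st <- generate_study(cfg)
  expect_length(st$images, 16)
  expect_equal(unname(table(st$annotations$label)[c("abscess", "cyst", "normal", "tumor")]),
               c(4L, 4L, 4L, 4L), ignore_attr = TRUE)
  expect_equal(st$annotations$image_id, names(st$images))

  # empty study: valid empty annotation table
  empty <- generate_study(study_config(
    class_counts = c(abscess = 0, cyst = 0, tumor = 0, normal = 0)))
  expect_length(empty$images, 0)
  expect_equal(nrow(empty$annotations), 0)
  expect_named(empty$annotations,
               c("image_id", "label", "center_row", "center_col"))

  # same seed -> identical written annotation CSVs (and images)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_study(cfg, out_dir = d1)
  s2 <- generate_study(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "annotations.csv")),
                   readLines(file.path(d2, "annotations.csv")))
  expect_identical(s1$images, s2$images)
  # annotation CSV on disk is 0-based; reading converts back
  back <- read_annotations(file.path(d1, "annotations.csv"))
  expect_equal(back$center_row, s1$annotations$center_row)
  raw <- utils::read.csv(file.path(d1, "annotations.csv"))
  expect_equal(raw$center_row, s1$annotations$center_row - 1L)

  expect_error(study_config(class_counts = c(bogus = 3)), "four study classes")
  expect_error(study_config(image_shape = c(50, 800)), "at least 80")
})

test_that("PNG round trip preserves images exactly", {
  img <- random_patch(30, 40, seed = 77)
  path <- withr::local_tempfile(fileext = ".png")
  write_gray_png(gray_image(img), path)
  expect_equal(as.vector(read_gray_png(path)), as.vector(img))
})
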