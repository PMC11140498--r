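test_that("domain_spec validates its parameter ranges", {
  expect_s3_class(domain_spec(), "domain_spec")
  expect_error(domain_spec(lesion_rate = 1.5), "lesion_rate")
  expect_error(domain_spec(head_axes_range = c(0.4, 0.2)), "ordered")
  expect_error(domain_spec(contrast_gamma = 0), "contrast_gamma")
  expect_error(domain_spec(tissue_mean = 0.9, lesion_intensity_offset = 0.3),
               "exceeds 1")
})

test_that("head images are bounded, finite, and masks mark lesions exactly", {
  spec <- tiny_spec()
  set.seed(1)
  for (i in 1:5) {
    hi <- make_head_image(spec, size = 32L, force_positive = (i %% 2 == 0))
    expect_true(all(is.finite(hi$image)))
    expect_true(all(hi$image >= 0 & hi$image <= 1))
    expect_true(all(hi$mask %in% c(0L, 1L)))
    expect_identical(dim(hi$image), dim(hi$mask))
    if (i %% 2 == 0) expect_gt(sum(hi$mask), 0)
  }
})

test_that("lesion_rate zero and no forcing yields an empty mask", {
  spec <- tiny_spec(lesion_rate = 0)
  set.seed(2)
  hi <- make_head_image(spec, size = 32L)
  expect_identical(sum(hi$mask), 0L)
})

test_that("generation is bit-identical under the same seed", {
  spec <- tiny_spec()
  set.seed(99); a <- make_head_image(spec, size = 32L, force_positive = TRUE)
  set.seed(99); b <- make_head_image(spec, size = 32L, force_positive = TRUE)
  expect_identical(a, b)
})

test_that("forced lesions are at least as large as the smallest rasterized disc", {
  # brute-force oracle: the fewest pixels a disc of the minimum radius can
  # cover, over sub-pixel center placements
  min_disc_pixels <- function(radius) {
    shifts <- seq(0, 1, by = 0.1)
    counts <- outer(shifts, shifts, Vectorize(function(sr, sc) {
      g <- expand.grid(r = -10:10, c = -10:10)
      sum((g$r - sr)^2 + (g$c - sc)^2 <= radius^2)
    }))
    min(counts)
  }
  oracle <- min_disc_pixels(3)
  spec <- tiny_spec(lesion_rate = 1, lesion_radius_range = c(3, 3),
                    lesion_count_max = 1L)
  set.seed(5)
  for (i in 1:5) {
    hi <- make_head_image(spec, size = 48L, force_positive = TRUE)
    expect_gte(sum(hi$mask), oracle)
  }
})

test_that("exam labels are sound: label iff any positive mask pixel", {
  spec <- tiny_spec()
  set.seed(3)
  for (positive in c(TRUE, FALSE)) {
    ex <- make_exam(spec, n_images = 3L, positive = positive, size = 32L)
    any_pos <- any(vapply(ex$masks, function(m) any(m == 1L), logical(1)))
    expect_identical(ex$exam_label, any_pos)
    expect_identical(ex$exam_label, positive)
    expect_length(ex$images, 3L)
    expect_length(ex$masks, 3L)
  }
  expect_error(make_exam(spec, n_images = 0L), "n_images")
})

test_that("domain datasets hit the requested positive count exactly", {
  spec <- tiny_spec()
  set.seed(4)
  ds <- make_domain_dataset(spec, n_exams = 10L, positive_fraction = 0.3,
                            n_images = 1L, size = 32L)
  expect_length(ds, 10L)
  expect_identical(sum(vapply(ds, `[[`, logical(1), "exam_label")), 3L)
  # the canonical positivity-rate arithmetic: 26.9% of 457 exams is 123
  expect_identical(round(0.269 * 457), 123)
  ds0 <- make_domain_dataset(spec, n_exams = 5L, positive_fraction = 0,
                             n_images = 1L, size = 32L)
  expect_false(any(vapply(ds0, `[[`, logical(1), "exam_label")))
})

test_that("the study corpus is disjoint, reproducible, and hides unlabeled masks", {
  cfg <- tiny_study_config()
  c1 <- make_study_corpus(cfg)
  c2 <- make_study_corpus(cfg)
  expect_identical(c1, c2)
  expect_length(c1$labeled, cfg$n_labeled)
  expect_length(c1$unlabeled, cfg$n_unlabeled)
  expect_length(c1$validation, cfg$n_validation)
  expect_length(c1$ood_test, cfg$n_ood)
  ids <- unlist(lapply(c(c1$labeled, c1$unlabeled, c1$validation, c1$ood_test),
                       `[[`, "exam_id"))
  expect_false(anyDuplicated(ids) > 0)
  # public interface must not leak unlabeled annotations
  expect_error(exam_masks(c1$unlabeled[[1]]), "withheld")
  expect_true(is.na(c1$unlabeled[[1]]$exam_label))
  # while the private reference stays available for Oracle modes
  ref <- private_reference(c1$unlabeled[[1]])
  expect_length(ref$masks, cfg$n_images)
  expect_true(all(ref$image_labels %in% 0:1))
})

test_that("the out-of-distribution shift is statistically detectable", {
  corpus <- make_study_corpus(default_study_config(
    n_labeled = 5L, n_unlabeled = 1L, n_validation = 1L, n_ood = 5L))
  lab_imgs <- unlist(lapply(corpus$labeled, function(ex)
    vapply(ex$images, mean, 0)))[1:20]
  ood_imgs <- unlist(lapply(corpus$ood_test, function(ex)
    vapply(ex$images, mean, 0)))[1:20]
  expect_lt(t.test(lab_imgs, ood_imgs)$p.value, 0.01)
  # high-frequency noise differs too: lag-difference variance per image
  hf <- function(im) stats::var(as.numeric(diff(im)))
  lab_hf <- unlist(lapply(corpus$labeled, function(ex) vapply(ex$images, hf, 0)))[1:20]
  ood_hf <- unlist(lapply(corpus$ood_test, function(ex) vapply(ex$images, hf, 0)))[1:20]
  expect_lt(t.test(lab_hf, ood_hf)$p.value, 0.01)
})

test_that("corpus round-trips through the on-disk layout", {
  corpus <- tiny_corpus()
  dir <- tempfile("corpus")
  manifest <- write_corpus(corpus, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "study.yaml")))
  expect_identical(nrow(manifest),
                   length(corpus$labeled) + length(corpus$unlabeled) +
                   length(corpus$validation) + length(corpus$ood_test))
  expect_true(all(is.na(manifest$mask_path[manifest$split == "unlabeled"])))
  back <- read_corpus(dir)
  expect_length(back$labeled, length(corpus$labeled))
  expect_equal(back$labeled[[1]]$images[[1]], corpus$labeled[[1]]$images[[1]],
               tolerance = 1e-6)
  expect_identical(back$labeled[[1]]$masks[[2]], corpus$labeled[[1]]$masks[[2]])
  expect_null(back$unlabeled[[1]]$masks)
  expect_identical(read_study_config(file.path(dir, "study.yaml"))$seed,
                   corpus$config$seed)
  unlink(dir, recursive = TRUE)
})
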