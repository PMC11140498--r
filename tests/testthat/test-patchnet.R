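test_that("patch labels ignore IGNORE pixels and catch single positives", {
  m <- matrix(TRI_NEG, 4, 4)
  expect_identical(patch_label(m), 0L)
  m[2, 3] <- TRI_POS
  expect_identical(patch_label(m), 1L)
  allig <- matrix(TRI_IGNORE, 4, 4)
  expect_identical(patch_label(allig), 0L)
})

test_that("grid patch extraction tiles the image and labels agree with recount", {
  set.seed(20)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(rbinom(64 * 64, 1, 0.02), 64, 64)

  whole <- extract_patches(img, mask, crop_size = 64L, sampler = "grid")
  expect_length(whole, 1L)
  expect_identical(whole[[1]]$image_patch, img)

  tiles <- extract_patches(img, mask, crop_size = 32L, sampler = "grid")
  expect_length(tiles, 4L)
  covered <- matrix(0L, 64, 64)
  for (p in tiles) {
    o <- p$offset
    covered[o[1]:(o[1] + 31L), o[2]:(o[2] + 31L)] <-
      covered[o[1]:(o[1] + 31L), o[2]:(o[2] + 31L)] + 1L
    expect_identical(p$patch_label, as.integer(any(p$mask_patch == 1L)))
  }
  expect_true(all(covered == 1L))

  # non-divisible side: last tiles align to the edge, full coverage
  img2 <- img[1:50, 1:50]; mask2 <- mask[1:50, 1:50]
  tiles2 <- extract_patches(img2, mask2, crop_size = 32L, sampler = "grid")
  expect_length(tiles2, 4L)
  expect_error(extract_patches(img2, mask2, crop_size = 64L), "crop_size")
})

test_that("random patch sampling recounts labels correctly", {
  set.seed(21)
  img <- matrix(runif(48 * 48), 48, 48)
  mask <- matrix(rbinom(48 * 48, 1, 0.05), 48, 48)
  ps <- extract_patches(img, mask, crop_size = 16L, sampler = "random", n = 25L)
  for (p in ps)
    expect_identical(p$patch_label, as.integer(sum(p$mask_patch == 1L) > 0))
})

test_that("an untrained model outputs exactly 0.5 everywhere", {
  m <- noisystudent:::patchnet_init(4L, seed = 1L)
  out <- forward(m, matrix(runif(256), 16, 16))
  expect_equal(out$class_prob, 0.5)
  expect_true(all(out$prob_map == 0.5))
  expect_identical(dim(out$prob_map), c(16L, 16L))
})

test_that("evaluation forward is deterministic and bounded", {
  m <- quick_model()
  x <- matrix(runif(256), 16, 16)
  a <- forward(m, x); b <- forward(m, x)
  expect_identical(a, b)
  expect_true(a$class_prob >= 0 && a$class_prob <= 1)
  expect_true(all(a$prob_map >= 0 & a$prob_map <= 1))
})

test_that("masked pixel loss honors the ignore contract and the ln 2 value", {
  p <- matrix(0.5, 4, 4)
  half <- matrix(c(rep(TRI_POS, 8), rep(TRI_NEG, 8)), 4, 4)
  expect_equal(masked_pixel_loss(p, half), log(2), tolerance = 1e-12)

  target <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_lt(masked_pixel_loss(ifelse(target == 1, 1, 0), target), 1e-6)

  allig <- matrix(TRI_IGNORE, 4, 4)
  expect_identical(masked_pixel_loss(p, allig), 0)

  # flipping probabilities under IGNORE pixels never changes the loss
  tri <- matrix(c(TRI_POS, TRI_IGNORE, TRI_NEG, TRI_IGNORE), 2, 2)
  p1 <- matrix(c(0.9, 0.1, 0.2, 0.99), 2, 2)
  p2 <- p1; p2[tri == TRI_IGNORE] <- runif(2)
  expect_identical(masked_pixel_loss(p1, tri), masked_pixel_loss(p2, tri))
})

test_that("classification loss matches BCE and its symmetry", {
  expect_lt(classification_loss(1, 1), 1e-6)
  expect_lt(classification_loss(0, 0), 1e-6)
  expect_equal(classification_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(classification_loss(0.3, 1), classification_loss(0.7, 0),
               tolerance = 1e-12)
  expect_error(classification_loss(0.5, 2), "label")
})

test_that("mixed minibatches respect the configured ratio", {
  lab <- replicate(5, list(image = matrix(0, 4, 4),
                           mask = matrix(0L, 4, 4)), simplify = FALSE)
  pse <- replicate(7, list(image = matrix(0, 4, 4),
                           mask = matrix(0L, 4, 4)), simplify = FALSE)
  set.seed(30)
  b <- mixed_minibatch(lab, pse, mixing_ratio = 0.6, batch_size = 16L)
  src <- vapply(b, `[[`, "", "source")
  expect_identical(sum(src == "labeled"), 10L)   # round(0.6 * 16) = 10
  expect_identical(sum(src == "pseudo"), 6L)

  b2 <- mixed_minibatch(lab, pse, mixing_ratio = 0.5, batch_size = 10L)
  src2 <- vapply(b2, `[[`, "", "source")
  expect_identical(sum(src2 == "labeled"), 5L)

  # mixing_ratio 1 never samples pseudo data
  b3 <- mixed_minibatch(lab, pse, mixing_ratio = 1, batch_size = 12L)
  expect_true(all(vapply(b3, `[[`, "", "source") == "labeled"))

  # long-run realized ratio concentrates on the configured one
  set.seed(31)
  tally <- replicate(2000, {
    src <- vapply(mixed_minibatch(lab, pse, 0.6, 16L), `[[`, "", "source")
    sum(src == "labeled")
  })
  expect_equal(mean(tally) / 16, 10 / 16, tolerance = 0.01)
  expect_error(mixed_minibatch(list(), pse, 0.5, 8L), "empty")
})

test_that("training reduces the objective and learns an easy detection task", {
  model <- quick_model()
  log <- attr(model, "train_log")
  expect_gt(nrow(log), 1L)
  expect_lt(log$objective[nrow(log)], log$objective[1])
  ev <- evaluate_model(model, easy_corpus()$validation)
  expect_gte(ev$exam_auc, 0.95)
})

test_that("training is bit-reproducible under a fixed seed", {
  corpus <- easy_corpus()
  cfg <- quick_train_config(seed = 5L)
  m1 <- train_patchnet(corpus$labeled[1:4], config = cfg)
  m2 <- train_patchnet(corpus$labeled[1:4], config = cfg)
  expect_identical(m1$weights, m2$weights)
  probe <- corpus$validation[[1]]
  expect_identical(predict_exam(m1, probe), predict_exam(m2, probe))
})

test_that("perturbing pixels under IGNORE states leaves the objective unchanged", {
  # direct recomputation of the training objective on one batch
  set.seed(40)
  m <- noisystudent:::patchnet_init(4L, seed = 2L)
  m$weights$Wseg[] <- rnorm(4, 0, 0.5)
  img <- matrix(runif(256), 16, 16)
  tri <- matrix(sample(c(TRI_NEG, TRI_POS, TRI_IGNORE), 256, replace = TRUE),
                16, 16)
  objective <- function(mask) {
    out <- forward(m, img)
    masked_pixel_loss(out$prob_map, mask) +
      classification_loss(out$class_prob, patch_label(mask))
  }
  base <- objective(tri)
  # IGNORE pixels: underlying value irrelevant by construction; also check
  # the loss path sees no difference when we recompute via the tri mask
  tri2 <- tri  # same states; perturb the *probabilities* under IGNORE
  out <- forward(m, img)
  pm2 <- out$prob_map
  pm2[tri == TRI_IGNORE] <- runif(sum(tri == TRI_IGNORE))
  expect_identical(
    masked_pixel_loss(out$prob_map, tri),
    masked_pixel_loss(pm2, tri))
  expect_identical(base, objective(tri2))
})

test_that("exam prediction aggregates by the any-positive-image maximum", {
  m <- quick_model()
  corpus <- easy_corpus()
  exam <- corpus$ood_test[[1]]
  pred <- predict_exam(m, exam)
  expect_s3_class(pred, "exam_prediction")
  expect_equal(pred$exam_score, max(pred$image_probs))
  expect_length(pred$prob_maps, length(exam$images))
  for (pm in pred$prob_maps)
    expect_true(all(pm >= 0 & pm <= 1))
  # identical images produce identical per-image probabilities
  same <- exam
  same$images <- rep(exam$images[1], 3)
  same$masks <- rep(exam$masks[1], 3)
  p2 <- predict_exam(m, same)
  expect_true(all(abs(p2$image_probs - p2$image_probs[1]) < 1e-12))
})

test_that("checkpoints round-trip weights, config and provenance", {
  m <- quick_model()
  path <- tempfile(fileext = ".ckpt")
  write_checkpoint(m, path)
  back <- read_checkpoint(path)
  expect_identical(back$weights, m$weights)
  expect_identical(back$config, m$config)
  expect_identical(attr(back, "provenance"), attr(m, "provenance"))
  probe <- easy_corpus()$validation[[1]]
  expect_identical(predict_exam(back, probe), predict_exam(m, probe))
  unlink(path)
})
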