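#' Specification of one imaging "institution" (domain)
#'
#' A `domain_spec` parameterizes the appearance of synthetic head phantoms
#' produced for one institution: head geometry, tissue intensity and texture,
#' lesion prevalence and contrast, acquisition noise, and a global gamma that
#' shifts the overall contrast curve. Differences between the specs of two
#' domains are what creates a controllable domain shift between splits.
#'
#' @param name character, domain label stored on every generated exam.
#' @param head_axes_range length-2 numeric, ellipse semi-axes as fractions of
#'   the image side (ordered, within (0, 0.5]).
#' @param aspect_jitter length-2 numeric, multiplicative jitter range applied
#'   independently to each semi-axis.
#' @param tissue_mean,tissue_sd mean intensity and per-pixel texture standard
#'   deviation of brain tissue, on the [0, 1] intensity scale.
#' @param lesion_rate probability in [0, 1] that an image of a positive
#'   examination carries at least one lesion.
#' @param lesion_count_max maximum number of lesions per image.
#' @param lesion_radius_range length-2 numeric, lesion radius range in pixels.
#' @param lesion_intensity_offset positive intensity added inside lesions
#'   (acute blood is hyperdense, so lesions are bright).
#' @param noise_sd standard deviation of additive acquisition noise.
#' @param contrast_gamma exponent applied to the whole image after noise;
#'   values away from 1 shift the domain's appearance.
#' @param distractor_rate probability in [0, 1] that an image carries small
#'   bright non-lesion foci (calcification/artifact mimics). Distractors are
#'   never part of the lesion mask; discriminating them from true lesions by
#'   size is what makes detection non-trivial and what generates
#'   false-positive pseudo labels for the ranker to suppress.
#' @param distractor_count_max maximum number of distractors per image.
#' @param distractor_radius_range distractor radius range in pixels; should
#'   sit below `lesion_radius_range` so the classes are separable by size.
#' @param distractor_intensity_offset intensity added inside distractors.
#'
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(name = "domain",
                        head_axes_range = c(0.28, 0.38),
                        aspect_jitter = c(0.9, 1.1),
                        tissue_mean = 0.45,
                        tissue_sd = 0.05,
                        lesion_rate = 0.8,
                        lesion_count_max = 3L,
                        lesion_radius_range = c(2, 6),
                        lesion_intensity_offset = 0.25,
                        noise_sd = 0.04,
                        contrast_gamma = 1.0,
                        distractor_rate = 0.5,
                        distractor_count_max = 2L,
                        distractor_radius_range = c(0.8, 1.6),
                        distractor_intensity_offset = 0.3) {
  stopifnot(is.character(name), length(name) == 1L)
  check_range <- function(r, what, positive = TRUE) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(sprintf("'%s' must be an ordered length-2 numeric range", what))
    if (positive && r[1] <= 0)
      stop(sprintf("'%s' must be positive", what))
  }
  check_range(head_axes_range, "head_axes_range")
  check_range(aspect_jitter, "aspect_jitter")
  check_range(lesion_radius_range, "lesion_radius_range")
  if (head_axes_range[2] > 0.5) stop("head semi-axes must fit inside the image")
  if (lesion_rate < 0 || lesion_rate > 1) stop("'lesion_rate' must be in [0, 1]")
  if (lesion_count_max < 1) stop("'lesion_count_max' must be >= 1")
  if (tissue_mean < 0 || tissue_mean > 1) stop("'tissue_mean' must be in [0, 1]")
  if (tissue_sd < 0 || noise_sd < 0) stop("standard deviations must be >= 0")
  if (lesion_intensity_offset <= 0) stop("'lesion_intensity_offset' must be > 0")
  if (tissue_mean + lesion_intensity_offset > 1 + 1e-9)
    stop("expected lesion intensity exceeds 1; lower tissue_mean or the offset")
  if (contrast_gamma <= 0) stop("'contrast_gamma' must be > 0")
  check_range(distractor_radius_range, "distractor_radius_range")
  if (distractor_rate < 0 || distractor_rate > 1)
    stop("'distractor_rate' must be in [0, 1]")
  structure(list(
    name = name,
    head_axes_range = as.numeric(head_axes_range),
    aspect_jitter = as.numeric(aspect_jitter),
    tissue_mean = tissue_mean,
    tissue_sd = tissue_sd,
    lesion_rate = lesion_rate,
    lesion_count_max = as.integer(lesion_count_max),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_intensity_offset = lesion_intensity_offset,
    noise_sd = noise_sd,
    contrast_gamma = contrast_gamma,
    distractor_rate = distractor_rate,
    distractor_count_max = as.integer(distractor_count_max),
    distractor_radius_range = as.numeric(distractor_radius_range),
    distractor_intensity_offset = distractor_intensity_offset
  ), class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat("Domain spec '", x$name, "':\n", sep = "")
  cat(sprintf("  head semi-axes %.2f-%.2f of side, aspect jitter %.2f-%.2f\n",
              x$head_axes_range[1], x$head_axes_range[2],
              x$aspect_jitter[1], x$aspect_jitter[2]))
  cat(sprintf("  tissue %.2f +/- %.2f, noise sd %.3f, gamma %.2f\n",
              x$tissue_mean, x$tissue_sd, x$noise_sd, x$contrast_gamma))
  cat(sprintf("  lesions: rate %.2f, <=%d per image, radius %g-%g px, offset %.2f\n",
              x$lesion_rate, x$lesion_count_max, x$lesion_radius_range[1],
              x$lesion_radius_range[2], x$lesion_intensity_offset))
  cat(sprintf("  distractors: rate %.2f, <=%d per image, radius %g-%g px, offset %.2f\n",
              x$distractor_rate, x$distractor_count_max,
              x$distractor_radius_range[1], x$distractor_radius_range[2],
              x$distractor_intensity_offset))
  invisible(x)
}

# Rasterize a filled ellipse on an nr x nc grid; returns a logical matrix.
# (row, col) coordinates, origin top-left.
rasterize_ellipse <- function(nr, nc, center_r, center_c, semi_r, semi_c) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - center_r) / semi_r)^2 + ((c - center_c) / semi_c)^2 <= 1
}

#' Generate one synthetic head image with its lesion mask
#'
#' Draws an elliptical "head" of textured tissue on a dark background,
#' optionally places bright elliptical lesions fully inside the head, adds
#' acquisition noise, applies the domain's contrast gamma, and clips to
#' [0, 1]. Consumes the global RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param spec a [domain_spec()].
#' @param size image side in pixels (square images).
#' @param force_positive if `TRUE`, the mask is guaranteed to contain at least
#'   one lesion pixel.
#' @return A list with `image` (numeric matrix in [0, 1]) and `mask`
#'   (integer matrix, 1 exactly on lesion pixels).
#' @export
make_head_image <- function(spec, size = 64L, force_positive = FALSE) {
  stopifnot(inherits(spec, "domain_spec"), size >= 16L)
  nr <- nc <- as.integer(size)

  # head geometry: jittered ellipse near the image center
  center_r <- nr / 2 + stats::runif(1, -0.03, 0.03) * nr
  center_c <- nc / 2 + stats::runif(1, -0.03, 0.03) * nc
  base_ax <- stats::runif(2, spec$head_axes_range[1], spec$head_axes_range[2]) * nr
  jit <- stats::runif(2, spec$aspect_jitter[1], spec$aspect_jitter[2])
  semi_r <- base_ax[1] * jit[1]
  semi_c <- base_ax[2] * jit[2]
  head <- rasterize_ellipse(nr, nc, center_r, center_c, semi_r, semi_c)

  img <- matrix(0.05, nr, nc)
  img[head] <- spec$tissue_mean + stats::rnorm(sum(head), 0, spec$tissue_sd)

  mask <- matrix(0L, nr, nc)
  want_lesions <- force_positive || stats::runif(1) < spec$lesion_rate
  if (want_lesions) {
    n_lesions <- sample.int(spec$lesion_count_max, 1L)
    placed <- 0L
    for (i in seq_len(n_lesions)) {
      les <- place_lesion(spec, nr, nc, center_r, center_c, semi_r, semi_c)
      if (!is.null(les)) {
        # per-lesion conspicuity jitter: hemorrhage density varies, so some
        # lesions are faint and genuinely hard to detect
        img[les] <- img[les] +
          spec$lesion_intensity_offset * stats::runif(1, 0.5, 1.2)
        mask[les] <- 1L
        placed <- placed + 1L
      }
    }
    if (placed == 0L && force_positive)
      stop("could not place a lesion inside the head; domain spec geometry is infeasible")
  }

  # small bright non-lesion foci; never enter the mask
  if (spec$distractor_rate > 0 && stats::runif(1) < spec$distractor_rate) {
    dspec <- spec
    dspec$lesion_radius_range <- spec$distractor_radius_range
    for (i in seq_len(sample.int(spec$distractor_count_max, 1L))) {
      dd <- place_lesion(dspec, nr, nc, center_r, center_c, semi_r, semi_c)
      if (!is.null(dd)) {
        px <- dd & mask == 0L
        img[px] <- img[px] + spec$distractor_intensity_offset
      }
    }
  }

  img <- img + stats::rnorm(nr * nc, 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  img <- img^spec$contrast_gamma
  list(image = img, mask = mask)
}

# Try to place one lesion ellipse fully inside the head ellipse; bounded
# rejection sampling. Returns a logical matrix or NULL if every try failed.
place_lesion <- function(spec, nr, nc, center_r, center_c, semi_r, semi_c,
                         max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    rad <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    ax <- c(rad, rad)
    if (ax[1] >= semi_r || ax[2] >= semi_c) next
    # sample the lesion center uniformly in the shrunken head ellipse so the
    # lesion stays inside the head
    u <- stats::runif(1); theta <- stats::runif(1, 0, 2 * pi)
    rr <- sqrt(u)
    lc_r <- center_r + rr * (semi_r - ax[1]) * sin(theta)
    lc_c <- center_c + rr * (semi_c - ax[2]) * cos(theta)
    les <- rasterize_ellipse(nr, nc, lc_r, lc_c, ax[1], ax[2])
    if (any(les)) return(les)
  }
  NULL
}

#' Generate one synthetic examination
#'
#' Stacks `n_images` draws of [make_head_image()]. Negative examinations are
#' generated with lesions suppressed so the examination-level label is sound;
#' positive examinations force at least one image positive and let the
#' remaining images carry lesions at the domain's `lesion_rate`.
#'
#' @param spec a [domain_spec()].
#' @param n_images number of images in the stack (>= 1).
#' @param positive logical examination-level label to realize.
#' @param exam_id identifier string.
#' @param size image side in pixels.
#' @return An `exam_record`: list with `exam_id`, `images`, `masks`,
#'   `exam_label`, `domain_name`.
#' @export
make_exam <- function(spec, n_images = 4L, positive = FALSE,
                      exam_id = "exam", size = 64L) {
  if (n_images < 1L) stop("'n_images' must be >= 1")
  n_images <- as.integer(n_images)
  images <- vector("list", n_images)
  masks <- vector("list", n_images)
  if (positive) {
    forced <- sample.int(n_images, 1L)
    for (i in seq_len(n_images)) {
      hi <- make_head_image(spec, size = size, force_positive = (i == forced))
      images[[i]] <- hi$image; masks[[i]] <- hi$mask
    }
  } else {
    neg_spec <- spec
    neg_spec$lesion_rate <- 0
    for (i in seq_len(n_images)) {
      hi <- make_head_image(neg_spec, size = size, force_positive = FALSE)
      images[[i]] <- hi$image; masks[[i]] <- hi$mask
    }
  }
  label <- any(vapply(masks, function(m) any(m == 1L), logical(1)))
  structure(list(exam_id = exam_id, images = images, masks = masks,
                 exam_label = label, domain_name = spec$name),
            class = "exam_record")
}

#' @export
print.exam_record <- function(x, ...) {
  cat(sprintf("Exam '%s' [%s]: %d image(s) %dx%d, label %s, masks %s\n",
              x$exam_id, x$domain_name, length(x$images),
              nrow(x$images[[1]]), ncol(x$images[[1]]),
              if (isTRUE(x$exam_label)) "positive" else
                if (identical(x$exam_label, FALSE)) "negative" else "withheld",
              if (is.null(x$masks)) "withheld" else "present"))
  invisible(x)
}

#' Reference masks of an examination
#'
#' Public accessor for the per-pixel reference masks. For examinations whose
#' annotations are withheld (the unlabeled split of a study corpus) this
#' errors: unlabeled data must not leak pixel labels into training code.
#'
#' @param exam an `exam_record`.
#' @return List of integer mask matrices.
#' @export
exam_masks <- function(exam) {
  stopifnot(inherits(exam, "exam_record"))
  if (is.null(exam$masks))
    stop("masks are withheld for exam '", exam$exam_id,
         "' (unlabeled split); use private_reference() only for Oracle modes ",
         "or evaluation")
  exam$masks
}

#' Private reference annotations of a withheld examination
#'
#' Oracle benchmark modes and experiment analysis need the true labels of the
#' unlabeled split; they are stored out of the public field and retrieved only
#' through this explicitly named accessor.
#'
#' @param exam an `exam_record`.
#' @return List with `masks`, `image_labels` (0/1 per image) and `exam_label`.
#' @export
private_reference <- function(exam) {
  stopifnot(inherits(exam, "exam_record"))
  masks <- if (!is.null(exam$masks)) exam$masks else attr(exam, "private_masks")
  if (is.null(masks)) stop("no reference annotations stored for this exam")
  labels <- vapply(masks, function(m) as.integer(any(m == 1L)), integer(1))
  list(masks = masks, image_labels = labels, exam_label = any(labels == 1L))
}

# Strip the public annotations from an exam, keeping them privately.
withhold_annotations <- function(exam) {
  attr(exam, "private_masks") <- exam$masks
  attr(exam, "private_label") <- exam$exam_label
  exam$masks <- NULL
  exam$exam_label <- NA
  exam
}

#' Generate a dataset of examinations for one domain
#'
#' Exactly `round(positive_fraction * n_exams)` examinations are positive;
#' the order of examinations is shuffled.
#'
#' @param spec a [domain_spec()].
#' @param n_exams number of examinations.
#' @param positive_fraction fraction of positive examinations in [0, 1].
#' @param n_images images per examination.
#' @param size image side in pixels.
#' @param id_prefix prefix for exam identifiers.
#' @return List of `exam_record`s.
#' @export
make_domain_dataset <- function(spec, n_exams, positive_fraction = 0.3,
                                n_images = 4L, size = 64L,
                                id_prefix = spec$name) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("'positive_fraction' must be in [0, 1]")
  if (n_exams < 1L) stop("'n_exams' must be >= 1")
  n_pos <- round(positive_fraction * n_exams)
  flags <- c(rep(TRUE, n_pos), rep(FALSE, n_exams - n_pos))
  flags <- flags[sample.int(n_exams)]
  lapply(seq_len(n_exams), function(i) {
    make_exam(spec, n_images = n_images, positive = flags[i],
              exam_id = sprintf("%s_%04d", id_prefix, i), size = size)
  })
}

#' Default three-institution study configuration
#'
#' The study emulates three institutions: a small pixel-labeled training
#' domain, a large unlabeled domain with a mild appearance shift, and an
#' out-of-distribution test domain with noticeably different noise level,
#' contrast curve and head aspect ratio. Split sizes default to a desk-scale
#' corpus (40 labeled / 100 unlabeled / 20 validation / 60 OOD test exams of
#' 4 images each, 64x64 pixels), CPU-trainable in minutes.
#'
#' @param image_size image side in pixels.
#' @param n_images images per examination.
#' @param n_labeled,n_unlabeled,n_validation,n_ood split sizes in exams.
#' @param positive_fraction fraction of positive exams in every split.
#' @param seed integer seed making the corpus fully reproducible.
#' @return A named list accepted by [make_study_corpus()].
#' @export
default_study_config <- function(image_size = 64L, n_images = 4L,
                                 n_labeled = 40L, n_unlabeled = 100L,
                                 n_validation = 20L, n_ood = 60L,
                                 positive_fraction = 0.3, seed = 20240301L) {
  list(
    image_size = as.integer(image_size),
    n_images = as.integer(n_images),
    n_labeled = as.integer(n_labeled),
    n_unlabeled = as.integer(n_unlabeled),
    n_validation = as.integer(n_validation),
    n_ood = as.integer(n_ood),
    positive_fraction = positive_fraction,
    seed = as.integer(seed),
    domains = list(
      labeled = domain_spec(
        name = "siteA", noise_sd = 0.04, contrast_gamma = 1.0,
        aspect_jitter = c(0.9, 1.1), tissue_mean = 0.45,
        distractor_rate = 0.7, distractor_count_max = 3L,
        distractor_radius_range = c(1.0, 2.2),
        distractor_intensity_offset = 0.30),
      unlabeled = domain_spec(
        name = "siteB", noise_sd = 0.07, contrast_gamma = 0.85,
        aspect_jitter = c(0.85, 1.15), tissue_mean = 0.43,
        distractor_rate = 0.7, distractor_count_max = 3L,
        distractor_radius_range = c(1.0, 2.2),
        distractor_intensity_offset = 0.30),
      ood = domain_spec(
        name = "siteC", noise_sd = 0.12, contrast_gamma = 0.5,
        aspect_jitter = c(0.7, 1.3), tissue_mean = 0.38,
        distractor_rate = 0.7, distractor_count_max = 3L,
        distractor_radius_range = c(1.0, 2.2),
        distractor_intensity_offset = 0.30)
    )
  )
}

#' Generate the full three-institution study corpus
#'
#' Produces four disjoint splits: `labeled` and `validation` from the labeled
#' domain, `unlabeled` from the unlabeled domain (with public annotations
#' withheld; the true masks remain available only through
#' [private_reference()] for Oracle modes and evaluation), and `ood_test`
#' from the out-of-distribution domain. Pure: writes nothing. Regenerating
#' with the same configuration reproduces a bit-identical corpus.
#'
#' @param config list as produced by [default_study_config()].
#' @return A `study_corpus`: list with `labeled`, `unlabeled`, `validation`,
#'   `ood_test`, `config`.
#' @export
make_study_corpus <- function(config = default_study_config()) {
  needed <- c("image_size", "n_images", "n_labeled", "n_unlabeled",
              "n_validation", "n_ood", "positive_fraction", "seed", "domains")
  missing <- setdiff(needed, names(config))
  if (length(missing)) stop("config is missing: ", paste(missing, collapse = ", "))
  doms <- config$domains
  stopifnot(all(c("labeled", "unlabeled", "ood") %in% names(doms)))
  dn <- vapply(doms[c("labeled", "unlabeled", "ood")], `[[`, "", "name")
  if (anyDuplicated(dn)) stop("the three domain specs must have distinct names")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  gen <- function(spec, n, prefix) {
    make_domain_dataset(spec, n, positive_fraction = config$positive_fraction,
                        n_images = config$n_images, size = config$image_size,
                        id_prefix = prefix)
  }
  labeled <- gen(doms$labeled, config$n_labeled, "train")
  validation <- gen(doms$labeled, config$n_validation, "val")
  unlabeled <- lapply(gen(doms$unlabeled, config$n_unlabeled, "unl"),
                      withhold_annotations)
  ood_test <- gen(doms$ood, config$n_ood, "ood")

  ids <- c(vapply(labeled, `[[`, "", "exam_id"),
           vapply(validation, `[[`, "", "exam_id"),
           vapply(unlabeled, `[[`, "", "exam_id"),
           vapply(ood_test, `[[`, "", "exam_id"))
  if (anyDuplicated(ids)) stop("internal error: exam ids across splits overlap")

  structure(list(labeled = labeled, unlabeled = unlabeled,
                 validation = validation, ood_test = ood_test,
                 config = config),
            class = "study_corpus")
}

#' @export
print.study_corpus <- function(x, ...) {
  cat("Synthetic study corpus (seed ", x$config$seed, "):\n", sep = "")
  for (s in c("labeled", "unlabeled", "validation", "ood_test")) {
    exams <- x[[s]]
    dom <- if (length(exams)) exams[[1]]$domain_name else "-"
    cat(sprintf("  %-11s %4d exams x %d images [%s]%s\n", s, length(exams),
                x$config$n_images, dom,
                if (s == "unlabeled") " (annotations withheld)" else ""))
  }
  invisible(x)
}

#' Persist a study corpus to disk
#'
#' Writes one NIfTI image volume per exam (and one mask volume where public
#' masks exist), a CSV manifest (exam_id, split, domain, exam_label, paths)
#' and the generating configuration as YAML.
#'
#' @param corpus a `study_corpus`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "study_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("labeled", "unlabeled", "validation", "ood_test")) {
    for (exam in corpus[[split]]) {
      img_arr <- simplify2array(exam$images)
      img_path <- file.path(dir, paste0(exam$exam_id, "_image.nii.gz"))
      RNifti::writeNifti(img_arr, img_path)
      mask_path <- NA_character_
      if (!is.null(exam$masks)) {
        mask_path <- file.path(dir, paste0(exam$exam_id, "_mask.nii.gz"))
        RNifti::writeNifti(simplify2array(exam$masks), mask_path)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        exam_id = exam$exam_id, split = split, domain = exam$domain_name,
        exam_label = if (is.na(exam$exam_label)) NA_integer_
                     else as.integer(exam$exam_label),
        image_path = basename(img_path),
        mask_path = if (is.na(mask_path)) NA_character_ else basename(mask_path),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(config_to_yaml(corpus$config), file.path(dir, "study.yaml"))
  invisible(manifest)
}

# domain_spec objects flattened for YAML round-tripping
config_to_yaml <- function(config) {
  config$domains <- lapply(config$domains, unclass)
  config
}

#' Read a study configuration from YAML
#'
#' @param path YAML file written by [write_corpus()] or hand-authored with the
#'   same fields as [default_study_config()].
#' @return A study configuration list.
#' @export
read_study_config <- function(path) {
  config <- yaml::read_yaml(path)
  config$domains <- lapply(config$domains, function(d) do.call(domain_spec, d))
  for (f in c("image_size", "n_images", "n_labeled", "n_unlabeled",
              "n_validation", "n_ood", "seed"))
    config[[f]] <- as.integer(config[[f]])
  config
}

#' Read a persisted corpus back from disk
#'
#' @param dir directory written by [write_corpus()].
#' @return A `study_corpus`; unlabeled exams come back without public masks.
#' @export
read_corpus <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  config <- read_study_config(file.path(dir, "study.yaml"))
  splits <- list(labeled = list(), unlabeled = list(), validation = list(),
                 ood_test = list())
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    arr <- as.array(RNifti::readNifti(file.path(dir, row$image_path)))
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    images <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    masks <- NULL
    if (!is.na(row$mask_path)) {
      marr <- as.array(RNifti::readNifti(file.path(dir, row$mask_path)))
      if (length(dim(marr)) == 2L) marr <- array(marr, c(dim(marr), 1L))
      masks <- lapply(seq_len(dim(marr)[3]), function(k) {
        m <- marr[, , k]; storage.mode(m) <- "integer"; m
      })
    }
    exam <- structure(list(
      exam_id = row$exam_id, images = images, masks = masks,
      exam_label = if (is.na(row$exam_label)) NA else row$exam_label == 1L,
      domain_name = row$domain), class = "exam_record")
    splits[[row$split]] <- c(splits[[row$split]], list(exam))
  }
  structure(c(splits, list(config = config)), class = "study_corpus")
}
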