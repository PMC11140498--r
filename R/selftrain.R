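#' Ranker configuration
#'
#' The ranker suppresses false-positive pseudo labels: unlabeled images are
#' ordered by predicted lesion probability and only the top `C` percent are
#' declared positive. On positive images, pixels with confidence above
#' `K_pos` become positive, below `K_neg` negative, and values in between
#' are ignored (they generate no loss during training).
#'
#' @param C percentile threshold in (0, 100); the canonical sweep is
#'   `{5, 10, 15, 20, 25, 30}`, default 10.
#' @param K_pos,K_neg pixel confidence thresholds, defaults 0.7 and 0.3,
#'   with `0 <= K_neg < K_pos <= 1`.
#' @return An object of class `ranker_config`.
#' @export
ranker_config <- function(C = 10, K_pos = 0.7, K_neg = 0.3) {
  if (C <= 0 || C >= 100) stop("'C' must be in (0, 100)")
  if (!(K_neg >= 0 && K_neg < K_pos && K_pos <= 1))
    stop("need 0 <= K_neg < K_pos <= 1")
  structure(list(C = C, K_pos = K_pos, K_neg = K_neg),
            class = "ranker_config")
}

#' Rank images by predicted lesion probability
#'
#' Descending stable sort: ties keep their original relative order.
#'
#' @param image_probs numeric vector of finite probabilities.
#' @return Integer permutation ordering `image_probs` from high to low.
#' @export
rank_images <- function(image_probs) {
  if (any(!is.finite(image_probs))) stop("probabilities must be finite")
  order(-image_probs)   # radix sort: stable, ties keep original order
}

#' Select the pseudo-positive images
#'
#' Exactly `floor(C/100 * N)` images are selected: the top of the ranking.
#' All remaining images are considered negative.
#'
#' @param image_probs numeric vector of predicted probabilities.
#' @param C percentile threshold in (0, 100).
#' @return Integer vector of selected indices (possibly empty, with a
#'   warning).
#' @export
select_positives <- function(image_probs, C) {
  if (C <= 0 || C >= 100) stop("'C' must be in (0, 100)")
  n_sel <- floor(C / 100 * length(image_probs))
  if (n_sel == 0L) {
    warning("percentile threshold selects no images; all pseudo labels negative")
    return(integer(0))
  }
  rank_images(image_probs)[seq_len(n_sel)]
}

#' Trinarize a probability map into a tri-state pseudo mask
#'
#' Pixels with probability strictly above `K_pos` become positive, strictly
#' below `K_neg` negative; everything in between (boundaries included) is
#' ignored.
#'
#' @param prob_map numeric matrix in [0, 1].
#' @param ranker a [ranker_config()].
#' @return Integer matrix over `{TRI_NEG, TRI_POS, TRI_IGNORE}`.
#' @export
trinarize <- function(prob_map, ranker = ranker_config()) {
  stopifnot(inherits(ranker, "ranker_config"))
  out <- matrix(TRI_IGNORE, nrow(prob_map), ncol(prob_map))
  out[prob_map > ranker$K_pos] <- TRI_POS
  out[prob_map < ranker$K_neg] <- TRI_NEG
  storage.mode(out) <- "integer"
  out
}

#' Build the pseudo-labeled dataset from a trained teacher
#'
#' The teacher predicts every image of the unlabeled split; images are pooled
#' across examinations and ranked globally; [select_positives()] marks the
#' top `C` percent pseudo-positive, whose probability maps are trinarized.
#' All other images are considered negative with every pixel set to negative.
#' With `use_ranker = FALSE` (ablation) every image is treated as positive
#' and trinarized, bypassing the percentile selection.
#'
#' @param teacher a trained `patchnet`.
#' @param unlabeled list of `exam_record`s (annotations withheld).
#' @param ranker a [ranker_config()].
#' @param use_ranker set `FALSE` for the no-ranker ablation.
#' @return A `pseudo_dataset`: list with `samples` (image, tri-state mask,
#'   image_label, exam_id, image_index) and `provenance` (teacher checkpoint
#'   id, ranker used).
#' @export
build_pseudo_dataset <- function(teacher, unlabeled,
                                 ranker = ranker_config(),
                                 use_ranker = TRUE) {
  stopifnot(inherits(teacher, "patchnet"), inherits(ranker, "ranker_config"))
  if (length(unlabeled) == 0L) stop("unlabeled set is empty")
  preds <- lapply(unlabeled, function(ex) predict_exam(teacher, ex))
  entries <- list()
  for (e in seq_along(unlabeled)) {
    for (i in seq_along(unlabeled[[e]]$images)) {
      entries[[length(entries) + 1L]] <- list(
        exam = e, image = i,
        prob = preds[[e]]$image_probs[i],
        prob_map = preds[[e]]$prob_maps[[i]])
    }
  }
  probs <- vapply(entries, `[[`, 0, "prob")
  pos_idx <- if (use_ranker) select_positives(probs, ranker$C)
             else seq_along(entries)
  is_pos <- seq_along(entries) %in% pos_idx

  n_flagged <- 0L
  samples <- vector("list", length(entries))
  for (j in seq_along(entries)) {
    en <- entries[[j]]
    img <- unlabeled[[en$exam]]$images[[en$image]]
    if (is_pos[j]) {
      m <- trinarize(en$prob_map, ranker)
      if (!any(m == TRI_POS)) n_flagged <- n_flagged + 1L
      lab <- 1L
    } else {
      m <- matrix(TRI_NEG, nrow(img), ncol(img))
      storage.mode(m) <- "integer"
      lab <- 0L
    }
    samples[[j]] <- list(image = img, mask = m, image_label = lab,
                         exam_id = unlabeled[[en$exam]]$exam_id,
                         image_index = en$image, whole_image = FALSE)
  }
  if (n_flagged > 0L)
    message(n_flagged, " pseudo-positive image(s) have no positive pixel ",
            "after trinarization; patch labels derive from the mask")
  structure(list(samples = samples,
                 provenance = list(teacher = checkpoint_id(teacher),
                                   ranker = unclass(ranker),
                                   use_ranker = use_ranker)),
            class = "pseudo_dataset")
}

#' @export
print.pseudo_dataset <- function(x, ...) {
  labs <- vapply(x$samples, `[[`, 0L, "image_label")
  cat(sprintf("Pseudo-labeled dataset: %d images, %d pseudo-positive (C = %g)\n",
              length(labs), sum(labs), x$provenance$ranker$C))
  cat(sprintf("  teacher %s, ranker %s\n", x$provenance$teacher,
              if (x$provenance$use_ranker) "on" else "off (ablation)"))
  invisible(x)
}

#' Run the complete noisy-student workflow
#'
#' (a) trains a teacher on the labeled split only, without noise; (b)-(d) the
#' teacher pseudo-labels the unlabeled split through the ranker; (e) trains a
#' student initialized from the teacher's weights on mixed minibatches of
#' labeled and pseudo-labeled data with augmentation noise.
#'
#' @param corpus a `study_corpus`.
#' @param teacher_config,student_config [train_config()]s for the two stages.
#' @param ranker a [ranker_config()].
#' @param augment an [augment_config()] noising the student.
#' @param use_ranker set `FALSE` for the no-ranker ablation student.
#' @param teacher optional pre-trained teacher to reuse across variants.
#' @return List with `teacher`, `student`, `pseudo` (the `pseudo_dataset`).
#' @export
run_noisy_student <- function(corpus,
                              teacher_config = train_config(),
                              student_config = teacher_config,
                              ranker = ranker_config(),
                              augment = augment_config(),
                              use_ranker = TRUE,
                              teacher = NULL) {
  stopifnot(inherits(corpus, "study_corpus"))
  if (length(corpus$unlabeled) == 0L)
    stop("corpus has no unlabeled split; nothing to pseudo-label")
  if (is.null(teacher))
    teacher <- train_patchnet(corpus$labeled, config = teacher_config,
                              augment = NULL)
  pseudo <- build_pseudo_dataset(teacher, corpus$unlabeled, ranker,
                                 use_ranker = use_ranker)
  student <- train_patchnet(corpus$labeled, pseudo,
                            config = student_config, augment = augment,
                            init = teacher)
  list(teacher = teacher, student = student, pseudo = pseudo)
}

#' Train the image-label Oracle benchmark
#'
#' A benchmark trained with extra labels unavailable in a true
#' semi-supervised setting: pixel loss is active on the labeled split only,
#' while each unlabeled examination's images enter as whole-image patches
#' supervised through the classification loss by their true image-level
#' labels (taken from the corpus's private reference).
#'
#' @param corpus a `study_corpus`.
#' @param config a [train_config()].
#' @param augment optional [augment_config()].
#' @param init optional initialization weights.
#' @return A trained `patchnet`.
#' @export
run_oracle_image <- function(corpus, config = train_config(),
                             augment = augment_config(), init = NULL) {
  stopifnot(inherits(corpus, "study_corpus"))
  pool <- list()
  for (exam in corpus$unlabeled) {
    ref <- private_reference(exam)
    for (i in seq_along(exam$images)) {
      img <- exam$images[[i]]
      m <- matrix(TRI_IGNORE, nrow(img), ncol(img))  # no pixel loss
      storage.mode(m) <- "integer"
      pool[[length(pool) + 1L]] <- list(
        image = img, mask = m, label_override = ref$image_labels[i],
        whole_image = TRUE)
    }
  }
  train_patchnet(corpus$labeled, pool, config = config, augment = augment,
                 init = init)
}

#' Train the pixel Oracle benchmark
#'
#' The upper-bound benchmark: on the unlabeled split the teacher's tri-state
#' pseudo masks are kept for images whose true image label is positive, and
#' overridden to all-negative for images whose true label is negative
#' (suppressing every false-positive pseudo label). Pixel loss is active on
#' both splits; training otherwise matches the student.
#'
#' @param corpus a `study_corpus`.
#' @param pseudo a `pseudo_dataset` built by [build_pseudo_dataset()].
#' @param config a [train_config()].
#' @param augment optional [augment_config()].
#' @param init optional initialization weights.
#' @return A trained `patchnet`.
#' @export
run_oracle_pixel <- function(corpus, pseudo, config = train_config(),
                             augment = augment_config(), init = NULL) {
  stopifnot(inherits(corpus, "study_corpus"), inherits(pseudo, "pseudo_dataset"))
  refs <- lapply(corpus$unlabeled, private_reference)
  names(refs) <- vapply(corpus$unlabeled, `[[`, "", "exam_id")
  pool <- lapply(pseudo$samples, function(s) {
    true_lab <- refs[[s$exam_id]]$image_labels[s$image_index]
    if (is.null(true_lab)) stop("private labels unavailable for ", s$exam_id)
    if (true_lab == 0L) {
      m <- matrix(TRI_NEG, nrow(s$image), ncol(s$image))
      storage.mode(m) <- "integer"
      s$mask <- m
      s$image_label <- 0L
    }
    s
  })
  train_patchnet(corpus$labeled, pool, config = config, augment = augment,
                 init = init)
}
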