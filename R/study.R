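#' Default training configurations for the three-institution study
#'
#' The teacher (which doubles as the labeled-only baseline) trains from
#' scratch for 24 epochs of 30 steps at learning rate 0.015 — long enough
#' that its probability maps are confident, which the pixel-confidence
#' trinarization depends on. The student trains for 24 epochs at the lower
#' rate 0.008: it starts from the teacher's weights, so training is a gentle
#' fine-tune that adds robustness from the pseudo pool and the augmentation
#' noise without destroying the teacher's ranking. Both use batch size 16,
#' 32-pixel crops and the 0.6:0.4 labeled-to-pseudo minibatch mix.
#'
#' @param seed integer seed.
#' @return A [train_config()].
#' @export
default_teacher_config <- function(seed = 0L) {
  train_config(epochs = 24L, steps_per_epoch = 30L, lr = 0.015, seed = seed)
}

#' @rdname default_teacher_config
#' @export
default_student_config <- function(seed = 0L) {
  train_config(epochs = 24L, steps_per_epoch = 30L, lr = 0.008, seed = seed)
}

#' Run one seed of the semi-supervised study
#'
#' Generates (or reuses) the default study corpus, trains the labeled-only
#' baseline (= teacher), runs the noisy-student workflow, optionally also
#' the no-ranker ablation student, and evaluates every model on the
#' out-of-distribution test split.
#'
#' @param seed integer seed controlling all training stages.
#' @param corpus optional pre-built `study_corpus`; the default corpus is
#'   generated when omitted.
#' @param include_noranker also train the ablation student that bypasses the
#'   percentile ranker.
#' @param ranker a [ranker_config()].
#' @param augment an [augment_config()].
#' @return List with `baseline`, `student` (and optionally `noranker`)
#'   evaluation lists (as returned by [evaluate_model()]), plus `models` and
#'   `pseudo`.
#' @export
run_study_seed <- function(seed, corpus = NULL, include_noranker = FALSE,
                           ranker = ranker_config(),
                           augment = augment_config()) {
  if (is.null(corpus)) corpus <- make_study_corpus(default_study_config())
  tc <- default_teacher_config(seed)
  sc <- default_student_config(seed)
  teacher <- train_patchnet(corpus$labeled, config = tc, augment = NULL)
  ns <- run_noisy_student(corpus, teacher_config = tc, student_config = sc,
                          ranker = ranker, augment = augment,
                          teacher = teacher)
  out <- list(
    baseline = evaluate_model(teacher, corpus$ood_test),
    student = evaluate_model(ns$student, corpus$ood_test),
    models = list(teacher = teacher, student = ns$student),
    pseudo = ns$pseudo)
  if (include_noranker) {
    nr <- suppressMessages(run_noisy_student(
      corpus, teacher_config = tc, student_config = sc, ranker = ranker,
      augment = augment, teacher = teacher, use_ranker = FALSE))
    out$noranker <- evaluate_model(nr$student, corpus$ood_test)
    out$models$noranker <- nr$student
  }
  out
}
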