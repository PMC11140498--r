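# Small, fast fixtures shared across the suite. Everything is generated in
# code under fixed seeds; heavier artifacts are memoized per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a permissive spec for tiny 24-32 px test images; ... overrides defaults
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(name = "tiny", head_axes_range = c(0.3, 0.4),
         lesion_radius_range = c(2, 3), lesion_count_max = 2L,
         distractor_rate = 0),
    list(...))
  do.call(domain_spec, args)
}

# a small study config that generates in ~1 s and trains in a few seconds
tiny_study_config <- function(seed = 11L) {
  cfg <- default_study_config(image_size = 32L, n_images = 2L,
                              n_labeled = 6L, n_unlabeled = 8L,
                              n_validation = 4L, n_ood = 6L, seed = seed)
  cfg
}

tiny_corpus <- function() memo("tiny_corpus", make_study_corpus(tiny_study_config()))

# an easy linearly-separable corpus: bright discs, no distractors, low noise
easy_corpus <- function() memo("easy_corpus", {
  spec <- domain_spec(name = "easy", noise_sd = 0.03, distractor_rate = 0,
                      lesion_radius_range = c(3, 5),
                      lesion_intensity_offset = 0.35)
  cfg <- default_study_config(image_size = 32L, n_images = 2L,
                              n_labeled = 10L, n_unlabeled = 8L,
                              n_validation = 6L, n_ood = 6L, seed = 7L)
  cfg$domains$labeled <- spec
  cfg$domains$unlabeled <- domain_spec(name = "easyB", noise_sd = 0.04,
                                       distractor_rate = 0,
                                       lesion_radius_range = c(3, 5),
                                       lesion_intensity_offset = 0.35)
  cfg$domains$ood <- domain_spec(name = "easyC", noise_sd = 0.05,
                                 distractor_rate = 0,
                                 lesion_radius_range = c(3, 5),
                                 lesion_intensity_offset = 0.35)
  make_study_corpus(cfg)
})

quick_train_config <- function(seed = 0L, ...) {
  args <- utils::modifyList(
    list(epochs = 8L, steps_per_epoch = 15L, crop_size = 16L,
         channels = 6L, seed = seed),
    list(...))
  do.call(train_config, args)
}

# a quickly trained model on the easy corpus, reused by several files
quick_model <- function() memo("quick_model", {
  train_patchnet(easy_corpus()$labeled, config = quick_train_config())
})
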