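# The five-seed directional experiment shared by the end-to-end acceptance
# checks. Memoized: trained once per test session, consumed by both the
# student-vs-baseline and the ranker-ablation blocks.

study_experiment <- function(seeds = 1:5) {
  memo("study_experiment", {
    corpus <- make_study_corpus(default_study_config())
    lapply(seeds, function(s) {
      res <- suppressMessages(
        run_study_seed(s, corpus = corpus, include_noranker = TRUE))
      list(seed = s,
           baseline = res$baseline[c("exam_auc", "dice", "pixel_ap")],
           student = res$student[c("exam_auc", "dice", "pixel_ap")],
           noranker = res$noranker[c("exam_auc", "dice", "pixel_ap")])
    })
  })
}
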