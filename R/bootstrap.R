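#' Paired bootstrap distribution of a metric difference
#'
#' Each replicate resamples unit indices with replacement and applies the
#' *same* indices to both models (paired resampling), then records
#' `delta = metric(B) - metric(A)` on the resample. Replicates whose
#' references contain a single class (so the metric is undefined) are
#' redrawn; the redraw count is recorded as an attribute.
#'
#' @param metric_fn function of `(scores, references)` for resampled units;
#'   for pixel-level metrics the unit is an image and scores/references are
#'   lists of maps.
#' @param preds_a,preds_b per-unit scores (numeric vectors) or lists of
#'   per-unit maps, aligned with `references`.
#' @param references per-unit references (binary vector or list of masks).
#' @param n_boot number of bootstrap sets (1000 in the canonical design).
#' @param needs_both_classes whether a resample must contain both reference
#'   classes (TRUE for AUC-type metrics).
#' @return Numeric vector of `n_boot` deltas, attribute `redraws`.
#' @export
bootstrap_deltas <- function(metric_fn, preds_a, preds_b, references,
                             n_boot = 1000L, needs_both_classes = TRUE) {
  n <- length(references)
  stopifnot(length(preds_a) == n, length(preds_b) == n, n_boot >= 1L)
  is_listy <- is.list(references)
  unit_has_class <- if (is_listy) {
    vapply(references, function(m) any(as.numeric(m) > 0.5), logical(1))
  } else references > 0.5
  deltas <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (!needs_both_classes ||
          (any(unit_has_class[idx]) && any(!unit_has_class[idx]))) break
      redraws <- redraws + 1L
      if (redraws > 1000L * n_boot)
        stop("could not draw a two-class bootstrap resample")
    }
    if (is_listy) {
      deltas[b] <- metric_fn(preds_b[idx], references[idx]) -
                   metric_fn(preds_a[idx], references[idx])
    } else {
      deltas[b] <- metric_fn(preds_b[idx], references[idx]) -
                   metric_fn(preds_a[idx], references[idx])
    }
  }
  attr(deltas, "redraws") <- redraws
  deltas
}

#' Kolmogorov-Smirnov normality check of bootstrap deltas
#'
#' One-sample KS test of the standardized deltas (mean and SD estimated from
#' the sample) against the standard normal; the asymptotic p-value is
#' returned. With sample-estimated parameters the test is conservative (the
#' Lilliefors caveat); it gates a warning, never the analysis.
#'
#' @param deltas numeric vector, at least 8 values.
#' @return p-value, or `NA` with a `degenerate` attribute if the deltas have
#'   zero variance.
#' @export
ks_normality <- function(deltas) {
  if (length(deltas) < 8L) stop("need at least 8 values")
  s <- stats::sd(deltas)
  if (s == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (deltas - mean(deltas)) / s
  suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
}

#' Z statistic and two-sided p-value for a metric difference
#'
#' `Z = delta_point / sigma` with `sigma` the empirical SD of the bootstrap
#' deltas; the two-sided p-value is `2 * Phi(-|Z|)`.
#'
#' @param delta_point metric difference on the full unresampled set.
#' @param sigma empirical SD of the bootstrap deltas (>= 0).
#' @return List with `Z` and `p`.
#' @export
z_test <- function(delta_point, sigma) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) {
    if (delta_point == 0) return(list(Z = 0, p = 1))
    warning("zero bootstrap variance with a nonzero difference")
    return(list(Z = sign(delta_point) * Inf, p = 0))
  }
  Z <- delta_point / sigma
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Percentile confidence interval
#'
#' Empirical percentiles with linear interpolation (quantile type 7).
#'
#' @param values numeric vector.
#' @param lo,hi percentile bounds (default 2.5 and 97.5).
#' @return Numeric `c(lower, upper)`.
#' @export
percentile_ci <- function(values, lo = 2.5, hi = 97.5) {
  stopifnot(length(values) >= 1L, lo < hi)
  unname(stats::quantile(values, c(lo, hi) / 100, type = 7))
}

#' Compare two models with the paired bootstrap
#'
#' Full comparison machinery: paired bootstrap deltas, KS normality check
#' (gating a warning only), `Z = delta/sigma` with its two-sided p-value,
#' and the 2.5th/97.5th percentile confidence interval. The point estimate
#' is the difference on the full unresampled set; the mean bootstrap delta
#' is also reported.
#'
#' @param preds_a,preds_b aligned per-unit predictions (model A is the
#'   baseline: positive deltas favor model B).
#' @param references aligned per-unit references.
#' @param metric `"auc"`, `"dice"` or `"ap"`.
#' @param unit label recorded in the result (`"exam"` or `"image"`).
#' @param n_boot number of bootstrap sets.
#' @param seed integer seed for the resampling.
#' @param dice_threshold binarization threshold for the Dice metric.
#' @return A `bootstrap_comparison` with fields `metric_name`, `unit`,
#'   `delta_point`, `delta_boot_mean`, `deltas`, `sigma`, `Z`, `p`, `ci`,
#'   `ks_p`, `n_boot`, `redraws`, `seed`.
#' @export
compare_models <- function(preds_a, preds_b, references,
                           metric = c("auc", "dice", "ap"),
                           unit = c("exam", "image"),
                           n_boot = 1000L, seed = 0L,
                           dice_threshold = 0.5) {
  metric <- match.arg(metric)
  unit <- match.arg(unit)
  metric_fn <- switch(metric,
    auc = function(s, r) roc_auc(s, unlist_refs(r)),
    dice = function(s, r) pooled_dice(s, r, dice_threshold),
    ap = function(s, r) pixel_average_precision(s, r))
  needs_both <- metric == "auc"

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  delta_point <- metric_fn(preds_b, references) - metric_fn(preds_a, references)
  deltas <- bootstrap_deltas(metric_fn, preds_a, preds_b, references,
                             n_boot = n_boot, needs_both_classes = needs_both)
  sigma <- stats::sd(deltas)
  zt <- z_test(delta_point, sigma)
  ks_p <- if (length(deltas) >= 8L) ks_normality(deltas) else NA_real_
  if (!is.na(ks_p) && ks_p < 0.05)
    warning("bootstrap deltas deviate from normality (KS p = ",
            signif(ks_p, 3), "); the Z-based p-value may be unreliable")
  structure(list(metric_name = metric, unit = unit,
                 delta_point = delta_point,
                 delta_boot_mean = mean(deltas),
                 deltas = as.numeric(deltas), sigma = sigma,
                 Z = zt$Z, p = zt$p,
                 ci = percentile_ci(deltas),
                 ks_p = ks_p, n_boot = as.integer(n_boot),
                 redraws = attr(deltas, "redraws"),
                 seed = as.integer(seed)),
            class = "bootstrap_comparison")
}

unlist_refs <- function(r) if (is.list(r)) unlist(r) else r

# global Dice over the pooled pixels of a set of images
pooled_dice <- function(prob_maps, ref_masks, threshold = 0.5) {
  a <- unlist(lapply(prob_maps, as.numeric)) >= threshold
  b <- unlist(lapply(ref_masks, as.numeric)) > 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("Paired bootstrap comparison (%s, unit = %s, %d sets):\n",
              toupper(x$metric_name), x$unit, x$n_boot))
  cat(sprintf("  delta = %.4f (bootstrap mean %.4f), sigma = %.4f\n",
              x$delta_point, x$delta_boot_mean, x$sigma))
  cat(sprintf("  Z = %.3f, two-sided p = %.4g, 95%% CI [%.4f, %.4f]\n",
              x$Z, x$p, x$ci[1], x$ci[2]))
  cat(sprintf("  KS normality p = %s%s\n",
              ifelse(is.na(x$ks_p), "NA", signif(x$ks_p, 3)),
              if (!is.na(x$ks_p) && x$ks_p < 0.05) "  [non-normal!]" else ""))
  invisible(x)
}

#' @export
summary.bootstrap_comparison <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Paired t-test for test-retest designs
#'
#' Standard paired t statistic with n - 1 degrees of freedom and two-sided
#' p-value, for comparing two models across repeated reference segmentations.
#'
#' @param values_a,values_b aligned numeric vectors, length >= 2.
#' @return List with `t`, `df`, `p`; if the paired differences have zero
#'   variance, `degenerate = TRUE` and `t`, `p` are `NA`.
#' @export
paired_ttest <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2L)
  d <- values_b - values_a
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                degenerate = TRUE))
  tt <- stats::t.test(values_b, values_a, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
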