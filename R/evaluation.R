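#' Pixel-level confusion counts
#'
#' Tallies true/false positives and negatives between a predicted and a
#' reference binary mask, optionally restricted to non-ignored pixels (e.g.
#' padding).  Counts are stored as doubles because gigapixel slides overflow
#' 32-bit integers.
#'
#' @param pred,gt Binary 0/1 matrices of identical dimensions.
#' @param ignore Optional binary matrix; pixels with 1 are excluded.
#' @return A `confusion_counts` tibble row with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(pred, gt, ignore = NULL) {
  pred <- as_binary_mask(pred, "pred")
  gt <- as_binary_mask(gt, "gt")
  if (!all(dim(pred) == dim(gt))) {
    abort(sprintf("Mask dimensions differ: %dx%d vs %dx%d.",
                  nrow(pred), ncol(pred), nrow(gt), ncol(gt)))
  }
  if (!is.null(ignore)) {
    keep <- ignore == 0
    pred <- pred[keep]
    gt <- gt[keep]
  }
  out <- tibble(tp = sum(pred == 1 & gt == 1) + 0,
                tn = sum(pred == 0 & gt == 0) + 0,
                fp = sum(pred == 1 & gt == 0) + 0,
                fn = sum(pred == 0 & gt == 1) + 0)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Segmentation metrics from confusion counts
#'
#' Computes precision `TP/(TP+FP)`, recall (sensitivity) `TP/(TP+FN)`,
#' F-measure `2TP/(2TP+FP+FN)`, Jaccard index `TP/(TP+FP+FN)` and specificity
#' `TN/(TN+FP)`.  Whenever all are defined, `jaccard == f_measure /
#' (2 - f_measure)`.
#'
#' Degenerate slides need a convention.  In `"reporting"` mode (the default,
#' matching common benchmark tables): a slide with no reference positives gets
#' recall `NaN` (excluded from group means), and when positive mass is absent
#' altogether (`TP + FP + FN == 0`) precision, F-measure and Jaccard are
#' recorded as 0.  In `"strict"` mode every 0/0 ratio propagates as `NaN`.
#' The `convention_fired` column records whether a convention was applied.
#'
#' @param counts A `confusion_counts` row (or anything with tp/tn/fp/fn).
#' @param convention `"reporting"` or `"strict"`.
#' @return A one-row tibble: precision, recall, f_measure, jaccard,
#'   specificity, convention_fired.
#' @examples
#' seg_metrics(tibble::tibble(tp = 50, tn = 900, fp = 25, fn = 25))
#' @export
seg_metrics <- function(counts, convention = c("reporting", "strict")) {
  convention <- match.arg(convention)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) abort("Confusion counts must be >= 0.")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f_measure <- ratio(2 * tp, 2 * tp + fp + fn)
  jaccard <- ratio(tp, tp + fp + fn)
  specificity <- ratio(tn, tn + fp)
  fired <- FALSE
  if (convention == "reporting" && tp + fp + fn == 0) {
    # no positive mass anywhere: score the positive-class metrics as 0,
    # keep recall NaN so slides without reference positives drop out of means
    precision <- 0; f_measure <- 0; jaccard <- 0
    fired <- TRUE
  }
  tibble(precision = precision, recall = recall, f_measure = f_measure,
         jaccard = jaccard, specificity = specificity,
         convention_fired = fired)
}

#' Evaluate a predicted mask against ground truth
#'
#' Convenience wrapper: [confusion()] then [seg_metrics()].
#'
#' @inheritParams confusion
#' @inheritParams seg_metrics
#' @return One-row metrics tibble.
#' @export
evaluate_mask <- function(pred, gt, ignore = NULL,
                          convention = c("reporting", "strict")) {
  seg_metrics(confusion(pred, gt, ignore), convention)
}

#' Combine precision and recall into F-measure and Jaccard
#'
#' The harmonic-mean identity `F = 2PR/(P+R)` and the equivalence
#' `J = F/(2-F)`; e.g. precision 0.66 and recall 0.72 give F-measure 0.69 and
#' Jaccard 0.53 at two decimals.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return Tibble with `precision`, `recall`, `f_measure`, `jaccard`.
#' @export
combine_pr <- function(precision, recall) {
  f <- 2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f_measure = f,
         jaccard = f / (2 - f))
}

#' Aggregate per-slide metrics into group summaries
#'
#' `"macro"` mode (default) averages per-slide metric values within each
#' group, excluding `NaN` recalls (slides without reference positives);
#' benchmark tables for slide cohorts are commonly reported this way, and
#' macro means generally do not satisfy the `J = F/(2-F)` identity.
#' `"micro"` mode pools the confusion counts of a group first and computes
#' one metric set from the pooled counts.
#'
#' @param per_slide Tibble with one row per slide holding metric columns
#'   (macro) or tp/tn/fp/fn columns (micro), plus optional grouping columns.
#' @param group Optional column name (string) to group by; a `"All"` row over
#'   every slide is always included.
#' @param mode `"macro"` or `"micro"`.
#' @return Tibble of group summaries with `n_slides`.
#' @export
aggregate_metrics <- function(per_slide, group = NULL,
                              mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  if (nrow(per_slide) == 0) abort("Need at least one slide.")
  summarize_group <- function(df, label) {
    if (mode == "macro") {
      out <- dplyr::summarise(
        df,
        dplyr::across(dplyr::any_of(c("precision", "recall", "f_measure",
                                      "jaccard", "specificity")),
                      ~ mean(.x[!is.nan(.x)])))
    } else {
      pooled <- dplyr::summarise(df, dplyr::across(dplyr::all_of(
        c("tp", "tn", "fp", "fn")), sum))
      out <- seg_metrics(pooled)
      out$convention_fired <- NULL
    }
    dplyr::mutate(out, group = label, n_slides = nrow(df), .before = 1)
  }
  rows <- list(summarize_group(per_slide, "All"))
  if (!is.null(group)) {
    for (g in unique(per_slide[[group]])) {
      rows[[length(rows) + 1]] <-
        summarize_group(per_slide[per_slide[[group]] == g, ], g)
    }
  }
  dplyr::bind_rows(rows)
}

#' Fisher's least significant difference pairwise comparisons
#'
#' One-way ANOVA across methods provides the pooled error mean square; each
#' method pair is then compared with a t statistic using the pooled variance:
#' `SE = sqrt(MSE * (1/n_I + 1/n_J))`, two-sided p-value and confidence
#' interval from the t distribution on `N - k` degrees of freedom.  No
#' multiplicity adjustment is applied (that is what distinguishes the LSD
#' procedure); unbalanced groups are allowed.
#'
#' @param scores Long tibble/data.frame with one score per slide and method.
#' @param value,method Column names (strings) of the score and the method
#'   label.
#' @param conf_level Confidence level of the intervals (default 0.95).
#' @return An `lsd_test` tibble: one row per ordered pair with
#'   `method_i`, `method_j`, `mean_difference`, `std_error`, `statistic`,
#'   `p_value`, `ci_low`, `ci_high`; attributes `mse`, `df`, `conf_level`.
#' @examples
#' scores <- tidyr::expand_grid(slide = 1:6, method = c("a", "b"))
#' scores$score <- ifelse(scores$method == "a", 0.9, 0.5) +
#'   seq(-0.05, 0.05, length.out = 12)
#' lsd_test(scores, "score", "method")
#' @export
lsd_test <- function(scores, value = "score", method = "method",
                     conf_level = 0.95) {
  x <- scores[[value]]
  gr <- as.character(scores[[method]])
  if (is.null(x) || is.null(gr)) abort("`value`/`method` columns not found.")
  keep <- !is.na(x)
  x <- x[keep]; gr <- gr[keep]
  lv <- unique(gr)
  if (length(lv) < 2) abort("Need >= 2 methods.")
  ns <- table(gr)[lv]
  if (any(ns < 2)) {
    abort(sprintf("Every method needs >= 2 scores; short: %s.",
                  paste(lv[ns < 2], collapse = ", ")))
  }
  means <- tapply(x, gr, mean)[lv]
  n_total <- length(x)
  k <- length(lv)
  df <- n_total - k
  mse <- sum(tapply(x, gr, function(v) sum((v - mean(v))^2))) / df
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  pairs <- utils::combn(lv, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    diff <- unname(means[a] - means[b])
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tstat <- if (se == 0) 0 else diff / se
    tibble(method_i = a, method_j = b, mean_difference = diff,
           std_error = se, statistic = tstat,
           p_value = 2 * pt(-abs(tstat), df),
           ci_low = diff - tcrit * se, ci_high = diff + tcrit * se)
  })
  structure(out, mse = mse, df = df, conf_level = conf_level,
            class = c("lsd_test", class(out)))
}

#' @rdname lsd_test
#' @param x An `lsd_test` result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lsd_test <- function(x, ...) {
  as_tibble(x)
}

#' @rdname lsd_test
#' @exportS3Method generics::glance
glance.lsd_test <- function(x, ...) {
  tibble(mse = attr(x, "mse"), df = attr(x, "df"),
         conf_level = attr(x, "conf_level"), n_comparisons = nrow(x))
}

#' Throughput and projected processing time
#'
#' Floor-integer patch-rate arithmetic: `throughput()` is the number of pixels
#' processed per second, `floor(patch_w * patch_h / seconds_per_patch)`;
#' `project_time()` scales a per-patch time to a full slide,
#' `floor(total_pixels / (patch_w * patch_h) * seconds_per_patch)`.  A
#' 1392 x 1040 patch at 0.07 s/patch gives 20,681,142 pixels/s, and a
#' 99,600 x 45,552 slide projects to 219 s.
#'
#' @param patch_w,patch_h Patch dimensions in pixels (> 0).
#' @param seconds_per_patch Seconds to process one patch (> 0).
#' @param total_pixels Total pixels of the projected slide.
#' @return An integer-valued double.
#' @export
throughput <- function(patch_w, patch_h, seconds_per_patch) {
  check_number(seconds_per_patch, "seconds_per_patch")
  if (seconds_per_patch <= 0) abort("`seconds_per_patch` must be > 0.")
  if (patch_w <= 0 || patch_h <= 0) abort("Patch dimensions must be > 0.")
  floor(patch_w * patch_h / seconds_per_patch)
}

#' @rdname throughput
#' @export
project_time <- function(total_pixels, patch_w, patch_h, seconds_per_patch) {
  if (seconds_per_patch <= 0) abort("`seconds_per_patch` must be > 0.")
  if (patch_w <= 0 || patch_h <= 0) abort("Patch dimensions must be > 0.")
  floor(total_pixels / (patch_w * patch_h) * seconds_per_patch)
}
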