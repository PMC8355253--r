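test_that("confusion counts match a per-pixel tally", {
  set.seed(2)
  pred <- matrix(rbinom(400, 1, 0.4), 20, 20)
  gt <- matrix(rbinom(400, 1, 0.3), 20, 20)
  cc <- confusion(pred, gt)
  orc <- oracle_confusion(pred, gt)
  expect_identical(c(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn), orc)
  expect_identical(sum(unlist(cc[c("tp", "tn", "fp", "fn")])), 400)

  perfect <- confusion(gt, gt)
  expect_identical(perfect$fp + perfect$fn, 0)
  flipped <- confusion(1L - gt, gt)
  expect_identical(flipped$tp + flipped$tn, 0)
})

test_that("ignored pixels are excluded from the tally", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)
  gt <- matrix(c(1, 1, 0, 0), 2, 2)
  ign <- matrix(c(0, 0, 1, 1), 2, 2)
  cc <- confusion(pred, gt, ign)
  expect_identical(unlist(cc), c(tp = 1, tn = 0, fp = 0, fn = 1))
})

test_that("mask validation rejects mismatches and non-binary input", {
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
  expect_error(confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the F-measure/Jaccard identity holds on random counts", {
  set.seed(8)
  for (k in 1:25) {
    cc <- tibble::tibble(tp = sample(0:500, 1), tn = sample(0:500, 1),
                         fp = sample(0:500, 1), fn = sample(0:500, 1))
    m <- seg_metrics(cc)
    if (cc$tp + cc$fp + cc$fn > 0) {
      expect_equal(m$jaccard, m$f_measure / (2 - m$f_measure))
      expect_equal(m$jaccard, cc$tp / (cc$tp + cc$fp + cc$fn))
    }
    if (!is.nan(m$jaccard) && !is.nan(m$recall) && !is.nan(m$precision)) {
      expect_lte(m$jaccard, m$f_measure + 1e-12)
      expect_lte(m$jaccard, min(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("combining precision 0.66 and recall 0.72 gives 0.69 and 0.53", {
  m <- combine_pr(0.66, 0.72)
  expect_identical(round(m$f_measure, 2), 0.69)
  expect_identical(round(m$jaccard, 2), 0.53)
})

test_that("a single true positive gives all positive-class metrics of 1", {
  m <- seg_metrics(tibble::tibble(tp = 1, tn = 0, fp = 0, fn = 0))
  expect_identical(unlist(m[c("precision", "recall", "f_measure", "jaccard")]),
                   c(precision = 1, recall = 1, f_measure = 1, jaccard = 1))
})

test_that("degenerate-slide conventions fire as documented", {
  empty <- tibble::tibble(tp = 0, tn = 100, fp = 0, fn = 0)
  rep_mode <- seg_metrics(empty, "reporting")
  expect_true(is.nan(rep_mode$recall))
  expect_identical(unlist(rep_mode[c("precision", "f_measure", "jaccard")]),
                   c(precision = 0, f_measure = 0, jaccard = 0))
  expect_true(rep_mode$convention_fired)
  expect_identical(rep_mode$specificity, 1)

  strict <- seg_metrics(empty, "strict")
  expect_true(all(is.nan(unlist(
    strict[c("precision", "recall", "f_measure", "jaccard")]))))
  expect_error(seg_metrics(tibble::tibble(tp = -1, tn = 0, fp = 0, fn = 0)),
               ">= 0")
})

test_that("swapping prediction and reference swaps precision and recall", {
  set.seed(5)
  pred <- matrix(rbinom(900, 1, 0.4), 30, 30)
  gt <- matrix(rbinom(900, 1, 0.5), 30, 30)
  m1 <- evaluate_mask(pred, gt)
  m2 <- evaluate_mask(gt, pred)
  expect_equal(m1$precision, m2$recall)
  expect_equal(m1$recall, m2$precision)
  expect_equal(m1$f_measure, m2$f_measure)
  expect_equal(m1$jaccard, m2$jaccard)
})

test_that("aggregation averages groups with NaN-recall exclusion", {
  per_slide <- tibble::tibble(
    grade = c("hsil", "hsil", "neg"),
    precision = c(0.9, 0.7, 0),
    recall = c(0.8, 0.6, NaN),
    f_measure = c(0.85, 0.64, 0),
    jaccard = c(0.7, 0.5, 0),
    specificity = c(1, 0.9, 1))
  out <- aggregate_metrics(per_slide, group = "grade")
  all_row <- out[out$group == "All", ]
  expect_equal(all_row$recall, mean(c(0.8, 0.6)))
  expect_equal(all_row$precision, mean(c(0.9, 0.7, 0)))
  expect_identical(out$group, c("All", "hsil", "neg"))
  expect_true(is.nan(out$recall[out$group == "neg"]))
  one <- aggregate_metrics(per_slide[1, ])
  expect_equal(one$jaccard, 0.7)
  # permutation invariance
  shuffled <- aggregate_metrics(per_slide[c(3, 1, 2), ], group = "grade")
  expect_equal(all_row$precision, shuffled$precision[shuffled$group == "All"])
  expect_error(aggregate_metrics(per_slide[0, ]), "at least one")
})

test_that("micro aggregation pools counts before computing metrics", {
  counts <- tibble::tibble(tp = c(10, 0), tn = c(80, 100), fp = c(5, 0),
                           fn = c(5, 0))
  out <- aggregate_metrics(counts, mode = "micro")
  expect_equal(out$precision, 10 / 15)
  expect_equal(out$jaccard, 10 / 20)
})

test_that("LSD comparisons match the textbook pooled-MSE formulas", {
  scores <- tibble::tibble(
    method = rep(c("proposed", "unet", "segnet"), times = c(5, 4, 5)),
    score = c(0.93, 0.90, 0.95, 0.88, 0.92,
              0.15, 0.22, 0.12, 0.19,
              0.26, 0.31, 0.22, 0.28, 0.24))
  got <- lsd_test(scores, "score", "method")
  orc <- oracle_lsd(scores$score, scores$method)
  for (r in seq_len(nrow(orc))) {
    g <- got[got$method_i == orc$method_i[r] &
               got$method_j == orc$method_j[r], ]
    expect_equal(g$mean_difference, orc$mean_difference[r], tolerance = 1e-12)
    expect_equal(g$std_error, orc$std_error[r], tolerance = 1e-12)
    expect_equal(g$p_value, orc$p_value[r], tolerance = 1e-12)
    expect_equal(c(g$ci_low, g$ci_high), c(orc$ci_low[r], orc$ci_high[r]),
                 tolerance = 1e-12)
  }
  expect_true(all(got$ci_low <= got$mean_difference &
                    got$mean_difference <= got$ci_high))
})

test_that("LSD on balanced groups equals pooled-variance pairwise t-tests", {
  set.seed(6)
  scores <- tibble::tibble(method = rep(c("a", "b", "c"), each = 6),
                           score = rnorm(18, rep(c(0.8, 0.5, 0.55), each = 6),
                                         0.05))
  got <- lsd_test(scores, "score", "method")
  fit <- stats::aov(score ~ method, data = scores)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfr <- summary(fit)[[1]]["Residuals", "Df"]
  expect_equal(attr(got, "mse"), mse, tolerance = 1e-12)
  expect_identical(attr(got, "df"), as.integer(dfr))
  ab <- got[got$method_i == "a" & got$method_j == "b", ]
  se <- sqrt(mse * (1 / 6 + 1 / 6))
  expect_equal(ab$std_error, se, tolerance = 1e-12)
  tt <- ab$mean_difference / se
  expect_equal(ab$p_value, 2 * pt(-abs(tt), dfr), tolerance = 1e-12)
})

test_that("identical groups and constant shifts behave as expected", {
  scores <- tibble::tibble(method = rep(c("a", "b"), each = 3),
                           score = rep(c(0.2, 0.5, 0.8), 2))
  got <- lsd_test(scores, "score", "method")
  expect_identical(got$mean_difference, 0)
  expect_identical(got$p_value, 1)

  shifted <- scores
  shifted$score[shifted$method == "a"] <-
    shifted$score[shifted$method == "a"] + 0.3
  got2 <- lsd_test(shifted, "score", "method")
  expect_equal(got2$mean_difference, 0.3)
  expect_equal(got2$std_error, got$std_error)

  expect_error(lsd_test(scores[1:4, ], "score", "method"), ">= 2 scores")
  expect_error(lsd_test(scores[scores$method == "a", ], "score", "method"),
               ">= 2 methods")
  expect_identical(nrow(glance(got)), 1L)
  expect_identical(nrow(tidy(got)), 1L)
})

test_that("throughput arithmetic uses exact floor-integer formulas", {
  expect_identical(throughput(1392, 1040, 0.07), 20681142)
  expect_identical(project_time(99600 * 45552, 1392, 1040, 0.07), 219)
  for (k in c(1, 7, 480)) expect_identical(throughput(k, 1, k), 1)
  expect_error(throughput(1392, 1040, 0), "> 0")
  expect_error(project_time(100, 0, 10, 1), "> 0")
})
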