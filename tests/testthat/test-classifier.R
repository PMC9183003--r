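test_that("pooled confusion counts reproduce the published per-subject metrics", {
  m <- compute_metrics(list(tp = 9, fn = 2, fp = 0, tn = 11))
  expect_equal(round(unname(m), 2), c(90.91, 100.00, 81.82, 90.00))
  expect_equal(unname(compute_metrics(list(tp = 11, fn = 0, fp = 0,
                                           tn = 11))),
               rep(100, 4))
  # consistency with a second published row: (8,3,3,8) -> 72.73 everywhere
  m2 <- compute_metrics(list(tp = 8, fn = 3, fp = 3, tn = 8))
  expect_equal(round(unname(m2), 2), c(72.73, 72.73, 72.73, 72.73))
})

test_that("degenerate denominators return zero with a warning", {
  w <- capture_warnings(m <- compute_metrics(list(tp = 0, fn = 11, fp = 0,
                                                  tn = 11)))
  expect_length(w, 2)  # precision and f1 are both degenerate here
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(unname(m), c(50, 0, 0, 0))
})

test_that("cohort aggregation uses population SD and the >70% subset", {
  entries <- data.frame(subject_id = LETTERS[1:10],
                        accuracy = table3_accuracies,
                        precision = table3_accuracies,
                        recall = table3_accuracies,
                        f1 = table3_accuracies,
                        auc_roc = table3_accuracies)
  rep <- aggregate_report(entries)
  expect_equal(rep$average$accuracy, c(70.91, 13.67), tolerance = 5e-4)
  expect_equal(rep$n_above_70, 5)
  expect_equal(rep$subset_above_70$accuracy, c(82.73, 8.33),
               tolerance = 5e-4)
  one <- aggregate_report(entries[2, , drop = FALSE])
  expect_equal(one$average$accuracy, c(90.91, 0), tolerance = 5e-4)
  expect_error(aggregate_report(list()), "no subject")
})

test_that("stratified folds balance classes and sizes", {
  y <- rep(c(0, 1), each = 11)
  fold <- stratified_folds(y, k = 10, seed = 4)
  sizes <- as.integer(table(fold))
  expect_equal(sort(sizes), c(rep(2, 8), 3, 3))
  # every fold keeps both classes when it has >= 2 members
  for (f in unique(fold))
    expect_true(all(table(y[fold == f]) >= 1) || sum(fold == f) < 2)
  expect_identical(stratified_folds(y, 10, seed = 4), fold)
  expect_error(stratified_folds(rep(c(0, 1), 2), k = 10), "folds")
})

test_that("recursive elimination keeps a planted separating feature", {
  fm <- planted_feature_matrix(signal_cols = 42, gap = 8, seed = 2)
  fn <- attr(fm, "feature_names")
  X <- as.matrix(as.data.frame(fm)[, fn])
  sel <- rfe_select(X, fm$label, seed = 5)
  expect_true("feat_042" %in% sel)
  expect_true(all(sel %in% fn))
  expect_identical(rfe_select(X, fm$label, seed = 5), sel)
  expect_error(rfe_select(X[c(1, 2, 12), ], fm$label[c(1, 2, 12)]),
               "per class")
})

test_that("a label-equal feature yields a perfect evaluation", {
  fm <- planted_feature_matrix(p = 40, seed = 3)
  fm$feat_007 <- fm$label  # one column equals the label
  ev <- evaluate_subject(fm, seed = 9)
  expect_equal(unname(ev$metrics["accuracy"]), 100)
  expect_equal(ev$auc_roc, 100)
  expect_equal(ev$counts, list(tp = 11, tn = 11, fp = 0, fn = 0))
})

test_that("pooled predictions cover every sample exactly once", {
  fm <- planted_feature_matrix(p = 30, signal_cols = 1:3, gap = 2, seed = 6)
  ev <- evaluate_subject(fm, seed = 13)
  expect_equal(sum(unlist(ev$counts)), nrow(fm))
  expect_false(anyNA(ev$predictions$pred))
  expect_equal(sum(ev$fold_sizes), nrow(fm))
  expect_equal(sort(ev$fold_sizes), c(rep(2L, 8), 3L, 3L))
  # metrics recomputable from counts
  expect_equal(unname(ev$metrics["accuracy"]),
               100 * (ev$counts$tp + ev$counts$tn) / nrow(fm))
})

test_that("the rank-based AUC oracle agrees with the reported AUC", {
  set.seed(17)
  labels <- rep(c(0, 1), each = 11)
  scores <- round(runif(22, 0, 1) + 0.3 * labels, 1)  # forces ties
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc_roc(labels, scores), 100 * mean(cmp), tolerance = 1e-9)
})

test_that("pipeline accuracy rises from null to strong synthetic effects", {
  mean_acc <- function(eff) {
    cohort <- generate_cohort(2, base_seed = 77, effect_range = eff)
    run <- suppressWarnings(suppressMessages(
      run_cohort_analysis(cohort, seed = 78)))
    mean(run$report$per_subject$accuracy)
  }
  null_acc <- mean_acc(0)
  strong_acc <- mean_acc(1)
  expect_gt(strong_acc, null_acc + 20)
  expect_gte(strong_acc, 90)
  expect_lt(null_acc, 75)
})
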