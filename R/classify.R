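#' Random-forest classifier specification
#'
#' The classifier settings used throughout: 10 trees, `sqrt(p)` candidate
#' features per split, Gini impurity, minimum node size for splitting of 2.
#'
#' @param n_trees Number of trees.
#' @param max_features_rule Features considered per split; only `"sqrt"`.
#' @param split_criterion Only `"gini"`.
#' @param min_samples_split Minimum samples needed to split a node.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(n_trees = 10, max_features_rule = "sqrt",
                            split_criterion = "gini",
                            min_samples_split = 2) {
  max_features_rule <- match.arg(max_features_rule, "sqrt")
  split_criterion <- match.arg(split_criterion, "gini")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (min_samples_split < 2) stop("min_samples_split must be >= 2")
  structure(list(n_trees = as.integer(n_trees),
                 max_features_rule = max_features_rule,
                 split_criterion = split_criterion,
                 min_samples_split = as.integer(min_samples_split)),
            class = "classifier_spec")
}

# one RF fit under the spec; X matrix, y factor with levels c("0","1")
fit_forest <- function(X, y, spec, seed = NULL, ntree = NULL) {
  if (!is.null(seed)) set.seed(seed)
  randomForest::randomForest(
    X, y, ntree = if (is.null(ntree)) spec$n_trees else ntree,
    mtry = max(1L, floor(sqrt(ncol(X)))),
    nodesize = max(1L, spec$min_samples_split - 1L))
}

as_label_factor <- function(y) factor(y, levels = c(0, 1))

# deterministic seed derivation: keeps everything below 2^31 - 1
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Stratified k-fold assignment
#'
#' Splits sample indices into `k` folds preserving class proportions. Each
#' class is shuffled and dealt round-robin; the classes place their
#' remainder samples on different folds, so 22 balanced samples in 10 folds
#' give 8 folds of 2 and 2 folds of 3.
#'
#' @param y Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < k) && k > min(counts) * length(classes))
    stop(sprintf("cannot form %d folds from class counts (%s)",
                 k, paste(counts, collapse = ", ")))
  set.seed(seed)
  fold <- integer(length(y))
  for (ci in seq_along(classes)) {
    idx <- sample(which(y == classes[ci]))
    n <- length(idx)
    base <- n %/% k
    extra <- n %% k
    sizes <- rep(base, k)
    if (extra > 0) {
      # offset remainder placement per class so fold sizes stay even
      extra_folds <- ((ci - 1) + seq_len(extra) - 1) %% k + 1
      sizes[extra_folds] <- sizes[extra_folds] + 1
    }
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  fold
}

#' Recursive feature elimination with cross-validated count selection
#'
#' Builds an elimination path on the training set by repeatedly refitting
#' the random forest and dropping the feature with the lowest impurity
#' (mean decrease in Gini) importance, one feature per step. Every feature
#' count along the path is then scored by stratified 5-fold accuracy on the
#' training set only, and the best-scoring count is returned (ties go to
#' the smaller count). The selected count therefore varies from fold to
#' fold of the outer cross-validation.
#'
#' The ranking forests use the same classifier family but `ranking_trees`
#' trees (50 by default): with only 10 trees a strongly predictive feature
#' can receive zero importance by never being drawn as a split candidate,
#' which would eliminate it on a tie. Scoring always uses the classifier
#' exactly as specified.
#'
#' @param X Numeric matrix or data frame of training features (named
#'   columns).
#' @param y Binary labels (0/1) for the training rows.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed; elimination and internal folds are
#'   deterministic given it.
#' @param internal_k Internal stratified fold count for scoring.
#' @param ranking_trees Trees used for the importance-ranking forests.
#' @return Character vector of selected feature names (subset of
#'   `colnames(X)`).
#' @export
rfe_select <- function(X, y, spec = classifier_spec(), seed = 1,
                       internal_k = 5, ranking_trees = 50) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  yf <- as_label_factor(y)
  if (any(table(yf) < 2))
    stop("need at least 2 training samples per class")
  p <- ncol(X)
  # elimination order: last entry of `order` is dropped first
  active <- colnames(X)
  drop_order <- character(0)
  step <- 0L
  while (length(active) > 1) {
    step <- step + 1L
    rf <- fit_forest(X[, active, drop = FALSE], yf, spec,
                     seed = derive_seed(seed, step), ntree = ranking_trees)
    imp <- rf$importance[, "MeanDecreaseGini"]
    worst <- names(imp)[which.min(imp)]
    drop_order <- c(worst, drop_order)   # head = dropped last = best-ranked
    active <- setdiff(active, worst)
  }
  ranking <- c(active, drop_order)       # best feature first
  fold <- stratified_folds(as.integer(as.character(yf)), k = internal_k,
                           seed = derive_seed(seed, 7001))
  acc <- numeric(p)
  for (k_feats in seq_len(p)) {
    feats <- ranking[seq_len(k_feats)]
    correct <- 0L
    for (f in seq_len(internal_k)) {
      tr <- fold != f
      te <- !tr
      if (!any(te)) next
      rf <- fit_forest(X[tr, feats, drop = FALSE], yf[tr], spec,
                       seed = derive_seed(seed, 10000 + k_feats * 10 + f))
      pred <- predict(rf, X[te, feats, drop = FALSE])
      correct <- correct + sum(pred == yf[te])
    }
    acc[k_feats] <- correct / length(yf)
  }
  ranking[seq_len(which.max(acc))]       # which.max breaks ties low
}

#' Classification metrics from pooled confusion counts
#'
#' Accuracy, precision, recall and F1 in percent, with cognitive fatigue as
#' the positive class. Degenerate denominators (e.g. no positive
#' predictions) yield 0 with a warning rather than NaN.
#'
#' @param counts List or vector with elements `tp`, `fn`, `fp`, `tn`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`
#'   (percent).
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  fp <- counts[["fp"]]; tn <- counts[["tn"]]
  total <- tp + fn + fp + tn
  if (total <= 0) stop("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("degenerate denominator for %s; returning 0", what))
      0
    } else num / den
  }
  accuracy <- (tp + tn) / total
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("degenerate denominator for f1; returning 0")
    0
  } else 2 * precision * recall / (precision + recall)
  100 * c(accuracy = accuracy, precision = precision,
          recall = recall, f1 = f1)
}

#' AUC-ROC from pooled scores (rank / trapezoid formula)
#'
#' Computed with trapezoidal integration over the ROC curve; ties in the
#' scores are handled by rank averaging (equivalent to the Mann-Whitney
#' statistic). Delegates to \pkg{pROC}.
#'
#' @param labels Binary labels (0/1).
#' @param scores Positive-class scores in `[0, 1]`.
#' @return AUC in percent.
#' @export
auc_roc <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  100 * as.numeric(pROC::auc(r))
}

#' Evaluate one subject with stratified 10-fold cross-validation
#'
#' For each outer fold: run [rfe_select()] on the training split, fit the
#' random forest on the selected features, and predict labels and
#' positive-class vote fractions on the held-out split. Predictions from
#' all folds are pooled; confusion counts, the four rate metrics and the
#' AUC-ROC are computed on the pooled predictions.
#'
#' @param fm An `fnirs_features` data frame (windows x features + label).
#' @param spec A [classifier_spec()].
#' @param k Number of outer folds.
#' @param seed Master seed; per-fold seeds are derived deterministically.
#' @param select_features Run recursive feature elimination per fold
#'   (default `TRUE`)? With `FALSE` all features are used.
#' @return A list of class `subject_evaluation`: `subject_id`, `counts`
#'   (tp/fn/fp/tn), `metrics` (percent), `auc_roc`, `fold_sizes`,
#'   `selected_features` (per fold), and the pooled `predictions` data
#'   frame (`truth`, `pred`, `score`).
#' @export
evaluate_subject <- function(fm, spec = classifier_spec(), k = 10,
                             seed = 1, select_features = TRUE) {
  feat_names <- attr(fm, "feature_names")
  if (is.null(feat_names))
    feat_names <- setdiff(names(fm), c("label", "subject_id"))
  X <- as.matrix(as.data.frame(fm)[, feat_names, drop = FALSE])
  y <- fm$label
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (min(table(y)) * 2 < k)
    stop(sprintf("cannot run %d folds with class counts (%s)",
                 k, paste(table(y), collapse = ", ")))
  fold <- stratified_folds(y, k = k, seed = derive_seed(seed, 0))
  truth <- pred <- score <- rep(NA_real_, length(y))
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    feats <- if (select_features) {
      rfe_select(X[tr, , drop = FALSE], y[tr], spec,
                 seed = derive_seed(seed, 100 + f))
    } else feat_names
    selected[[f]] <- feats
    rf <- fit_forest(X[tr, feats, drop = FALSE], as_label_factor(y[tr]),
                     spec, seed = derive_seed(seed, 200 + f))
    te <- which(!tr)
    votes <- predict(rf, X[te, feats, drop = FALSE], type = "vote",
                     norm.votes = TRUE)
    score[te] <- votes[, "1"]
    pred[te] <- as.numeric(as.character(
      predict(rf, X[te, feats, drop = FALSE])))
    truth[te] <- y[te]
  }
  stopifnot(!anyNA(pred))
  counts <- list(tp = sum(pred == 1 & truth == 1),
                 tn = sum(pred == 0 & truth == 0),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1))
  structure(list(
    subject_id = if (!is.null(fm$subject_id)) fm$subject_id[1] else "S",
    counts = counts,
    metrics = suppressWarnings(compute_metrics(counts)),
    auc_roc = auc_roc(truth, score),
    fold_sizes = as.integer(table(fold)),
    selected_features = selected,
    predictions = data.frame(truth = truth, pred = pred, score = score)),
    class = "subject_evaluation")
}

#' @export
print.subject_evaluation <- function(x, ...) {
  cat(sprintf("<subject_evaluation> %s: acc %.2f%%, prec %.2f%%, rec %.2f%%, F1 %.2f%%, AUC %.2f%%\n",
              x$subject_id, x$metrics["accuracy"], x$metrics["precision"],
              x$metrics["recall"], x$metrics["f1"], x$auc_roc))
  invisible(x)
}

#' Aggregate per-subject evaluations into a cohort report
#'
#' Builds the per-subject metric table plus aggregate rows: mean and
#' population standard deviation (ddof = 0) of each metric over all
#' subjects, and the same over the subset of subjects whose accuracy is
#' strictly above 70%.
#'
#' @param entries List of `subject_evaluation` objects, or a data frame
#'   with columns `subject_id`, `accuracy`, `precision`, `recall`, `f1`,
#'   `auc_roc`.
#' @return List of class `evaluation_report`: `per_subject` (data frame),
#'   `average` (mean/sd rows over all subjects), `subset_above_70`
#'   (mean/sd over the accuracy > 70% subset, or NULL if empty).
#' @export
aggregate_report <- function(entries) {
  if (length(entries) == 0) stop("no subject evaluations to aggregate")
  per <- if (is.data.frame(entries)) entries else do.call(rbind, lapply(
    entries, function(e) data.frame(
      subject_id = e$subject_id,
      accuracy = unname(e$metrics["accuracy"]),
      precision = unname(e$metrics["precision"]),
      recall = unname(e$metrics["recall"]),
      f1 = unname(e$metrics["f1"]),
      auc_roc = e$auc_roc)))
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc_roc")
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  agg <- function(rows) {
    m <- vapply(metric_cols, function(cn) mean(rows[[cn]]), numeric(1))
    s <- vapply(metric_cols, function(cn) sd_pop(rows[[cn]]), numeric(1))
    data.frame(stat = c("mean", "sd"), rbind(m, s), row.names = NULL)
  }
  sub <- per[per$accuracy > 70, , drop = FALSE]
  structure(list(
    per_subject = per,
    average = agg(per),
    subset_above_70 = if (nrow(sub)) agg(sub) else NULL,
    n_subjects = nrow(per),
    n_above_70 = nrow(sub)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d subjects (%d with accuracy > 70%%)\n",
              x$n_subjects, x$n_above_70))
  print(x$per_subject, digits = 4)
  a <- x$average
  cat(sprintf("Average accuracy: %.2f +/- %.2f %%\n",
              a$accuracy[1], a$accuracy[2]))
  if (!is.null(x$subset_above_70))
    cat(sprintf("Subset (>70%%) accuracy: %.2f +/- %.2f %%\n",
                x$subset_above_70$accuracy[1], x$subset_above_70$accuracy[2]))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits the per-subject metric CSV (Table-3-style columns), one confusion
#' matrix text file per subject, and a JSON manifest with the seed and the
#' features selected per fold.
#'
#' @param report An `evaluation_report`.
#' @param entries The list of `subject_evaluation` objects that produced
#'   it (for confusion matrices and the manifest); optional.
#' @param dir Output directory (created if absent).
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, entries = NULL, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_subject,
                   file.path(dir, "per_subject_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$average, file.path(dir, "average_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$subset_above_70))
    utils::write.csv(report$subset_above_70,
                     file.path(dir, "subset_above70_metrics.csv"),
                     row.names = FALSE)
  if (!is.null(entries)) {
    for (e in entries) {
      con <- file.path(dir, sprintf("confusion_%s.txt", e$subject_id))
      writeLines(c(
        sprintf("subject: %s", e$subject_id),
        "            pred_fatigue  pred_no_fatigue",
        sprintf("fatigue     %12d  %15d", e$counts$tp, e$counts$fn),
        sprintf("no_fatigue  %12d  %15d", e$counts$fp, e$counts$tn)), con)
    }
    manifest <- list(
      seed = seed,
      subjects = lapply(entries, function(e) list(
        subject_id = e$subject_id,
        fold_sizes = e$fold_sizes,
        n_selected_per_fold = vapply(e$selected_features, length,
                                     integer(1)),
        selected_features = e$selected_features)))
    jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
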