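# Evaluation machinery: confusion-matrix metrics, a reconciliation solver
# for printed metric tables, stratified resampling schemes, and binomial
# subgroup tests with Bonferroni correction.

#' Construct a confusion matrix
#'
#' @param TP,FP,TN,FN non-negative integer counts
#' @return object of class `confusion_matrix`
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != round(v))) stop_usage("counts must be non-negative integers")
  structure(as.list(as.integer(v)), names = names(v), class = "confusion_matrix")
}

#' Tabulate predictions against truth
#'
#' @param predicted,truth character vectors of "mutation"/"artefact" calls
#' @param positive the class counted as positive (default "mutation")
#' @return a [confusion_matrix()]
#' @export
confusion_from_predictions <- function(predicted, truth, positive = "mutation") {
  stopifnot(length(predicted) == length(truth))
  confusion_matrix(TP = sum(predicted == positive & truth == positive),
                   FP = sum(predicted == positive & truth != positive),
                   TN = sum(predicted != positive & truth != positive),
                   FN = sum(predicted != positive & truth == positive))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1 in their standard binary-classification
#' definitions. Precision is undefined (reported as `NA`) when `TP + FP = 0`,
#' recall when `TP + FN = 0`, and F1 when either is undefined or both are 0.
#'
#' @param cm a [confusion_matrix()]
#' @return object of class `metrics_report`: named list with `accuracy`,
#'   `precision`, `recall`, `f1`
#' @export
compute_metrics <- function(cm) {
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0) stop_usage("empty confusion matrix")
  precision <- if (cm$TP + cm$FP == 0) NA_real_ else cm$TP / (cm$TP + cm$FP)
  recall <- if (cm$TP + cm$FN == 0) NA_real_ else cm$TP / (cm$TP + cm$FN)
  structure(list(accuracy = (cm$TP + cm$TN) / total,
                 precision = precision, recall = recall,
                 f1 = f1_from_pr(precision, recall)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %s  recall %s  f1 %s\n",
              x$accuracy, format(round(x$precision, 3)),
              format(round(x$recall, 3)), format(round(x$f1, 3))))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`; `NA` (undefined) when either input
#' is `NA` or both are zero. Vectorised.
#'
#' @param precision,recall numeric values in \[0, 1\]
#' @return F1 score(s)
#' @export
f1_from_pr <- function(precision, recall) {
  out <- ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
                NA_real_,
                2 * precision * recall / (precision + recall))
  unname(out)
}

#' Reconcile printed metrics with an integer confusion matrix
#'
#' Exhaustively searches `TP in [0, n_pos]`, `FP in [0, n_neg]` for integer
#' confusion matrices whose precision and recall round (half-up, at the
#' given number of decimals) to the printed values. Useful for recovering
#' the exact confusion matrix behind a published three-decimal table row.
#'
#' @param n_pos,n_neg total positives and negatives
#' @param precision_printed,recall_printed the printed (rounded) values
#' @param decimals decimals the table was printed with (default 3)
#' @return list with `feasible` (logical), `unique` (logical), and
#'   `solutions`, a data.frame of TP/FP/TN/FN rows (empty when infeasible)
#' @export
solve_confusion <- function(n_pos, n_neg, precision_printed, recall_printed,
                            decimals = 3) {
  if (n_pos <= 0 || n_neg <= 0) stop_usage("n_pos and n_neg must be positive")
  h <- 0.5 * 10^(-decimals)
  safe_seq <- function(a, b) if (a > b) integer(0) else seq.int(a, b)
  # TP values whose recall rounds to the printed one
  tp_lo <- ceiling(n_pos * (recall_printed - h))
  tp_hi <- ceiling(n_pos * (recall_printed + h)) - 1  # TP/n_pos < r + h
  tps <- safe_seq(max(0, tp_lo), min(n_pos, tp_hi))
  sol <- list()
  for (tp in tps) {
    if (tp == 0) {
      # precision 0/FP = 0 for FP > 0; undefined for FP = 0
      if (round_half_up(0, decimals) == precision_printed) {
        fps <- seq_len(n_neg)
      } else fps <- integer(0)
    } else {
      # TP/(TP+FP) in [p-h, p+h)  =>  TP+FP in (TP/(p+h), TP/(p-h)]
      denom_lo <- floor(tp / (precision_printed + h)) + 1
      denom_hi <- if (precision_printed - h <= 0) tp + n_neg
                  else floor(tp / (precision_printed - h))
      fps <- safe_seq(max(0, denom_lo - tp), min(n_neg, denom_hi - tp))
    }
    for (fp in fps) {
      pr <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
      if (!is.na(pr) &&
          round_half_up(pr, decimals) == precision_printed &&
          round_half_up(tp / n_pos, decimals) == recall_printed) {
        sol[[length(sol) + 1]] <- data.frame(TP = tp, FP = fp,
                                             TN = n_neg - fp, FN = n_pos - tp)
      }
    }
  }
  solutions <- if (length(sol)) do.call(rbind, sol)
               else data.frame(TP = integer(0), FP = integer(0),
                               TN = integer(0), FN = integer(0))
  list(feasible = nrow(solutions) > 0, unique = nrow(solutions) == 1,
       solutions = solutions)
}

# ---------------------------------------------------------------------------
# learners: a learner is function(train_data, test_data) -> character vector
# of predicted classes for test_data

#' CNN learner for the resampling schemes
#'
#' Returns a closure suitable for [stratified_cv()], [random_splits()] and
#' [subsample_study()]: it builds the pinned architecture on the training
#' data's shape, trains it, and predicts hard classes on the test set.
#'
#' @param spec a [model_spec()]
#' @param config a [train_config()]; its seed is combined with the fold
#'   index by the resampling scheme
#' @return a learner function
#' @export
cnn_learner <- function(spec = model_spec(), config = train_config()) {
  force(spec); force(config)
  function(train_data, test_data) {
    samples <- sample_list(train_data)
    shape <- dim(samples[[1]]$values)
    model <- build_model(spec, shape, seed = config$seed)
    model <- train_cnn(model, train_data, config)
    predict(model, test_data)$class
  }
}

dataset_labels <- function(data) {
  vapply(sample_list(data), function(s) s$label %||% NA_character_, character(1))
}

subset_data <- function(data, idx) {
  if (inherits(data, "labelled_dataset")) {
    data$samples <- data$samples[idx]
    data$meta <- data$meta[idx, , drop = FALSE]
    data
  } else data[idx]
}

# per-class round-robin fold assignment after a seeded shuffle: fold class
# counts differ by at most 1 from exact proportionality
make_stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop_data("class '", cl, "' has ", length(idx),
                " member(s); need at least k = ", k)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the data into `k` folds preserving class proportions (within
#' one count per fold), trains the learner on each training split, and
#' reports per-fold metrics of the validation predictions together with
#' their unweighted averages. Fold assignment is reproducible for a fixed
#' seed.
#'
#' @param data a `labelled_dataset` or list of labelled samples
#' @param k number of folds (default 5)
#' @param seed seed for the fold assignment
#' @param learner a `function(train_data, test_data)` returning predicted
#'   classes, e.g. [cnn_learner()]
#' @return list with `folds` (per-sample fold index), `per_fold`
#'   (data.frame of metrics), `average` (unweighted mean metrics),
#'   `predictions` (per-sample validation predictions, in dataset order)
#' @export
stratified_cv <- function(data, k = 5, seed = NULL, learner = cnn_learner()) {
  labels <- dataset_labels(data)
  if (anyNA(labels)) stop_data("all samples must be labelled")
  fold <- make_stratified_folds(labels, k, seed)
  preds <- character(length(labels))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    p <- learner(subset_data(data, train_idx), subset_data(data, test_idx))
    preds[test_idx] <- p
    m <- compute_metrics(confusion_from_predictions(p, labels[test_idx]))
    rows[[f]] <- data.frame(fold = f, n = length(test_idx),
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1)
  }
  per_fold <- do.call(rbind, rows)
  average <- colMeans(per_fold[, c("accuracy", "precision", "recall", "f1")])
  list(folds = fold, per_fold = per_fold, average = average,
       predictions = preds)
}

#' Repeated random stratified train/test splits
#'
#' @param data a `labelled_dataset` or list of labelled samples
#' @param n_splits number of independent splits (default 100)
#' @param test_fraction fraction of each class held out (default 0.2)
#' @param seed seed for the split draws
#' @param learner as in [stratified_cv()]
#' @return list with `per_split` (data.frame of metrics) and `average`
#' @export
random_splits <- function(data, n_splits = 100, test_fraction = 0.2,
                          seed = NULL, learner = cnn_learner()) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_usage("test_fraction must lie in (0, 1)")
  labels <- dataset_labels(data)
  if (anyNA(labels)) stop_data("all samples must be labelled")
  classes <- unique(labels)
  for (cl in classes) {
    n_cl <- sum(labels == cl)
    if (round(n_cl * test_fraction) < 1 || round(n_cl * test_fraction) >= n_cl)
      stop_data("class '", cl, "' cannot be stratified at test_fraction ",
                test_fraction)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    test_idx <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      test_idx <- c(test_idx, sample(idx, round(length(idx) * test_fraction)))
    }
    train_idx <- setdiff(seq_along(labels), test_idx)
    p <- learner(subset_data(data, train_idx), subset_data(data, test_idx))
    m <- compute_metrics(confusion_from_predictions(p, labels[test_idx]))
    rows[[s]] <- data.frame(split = s, n_test = length(test_idx),
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1)
  }
  per_split <- do.call(rbind, rows)
  average <- colMeans(per_split[, c("accuracy", "precision", "recall", "f1")])
  list(per_split = per_split, average = average)
}

#' Geometric subsampling study
#'
#' Repeatedly shrinks the dataset by `shrink_factor` (sizes
#' `round(n0 * shrink_factor^-j)`, half-up, stopping at `min_size`), draws
#' each subset stratified, and runs k-fold cross-validation at every size.
#' Mirrors learning-curve studies that probe how validation performance
#' degrades with fewer training examples.
#'
#' @param data a `labelled_dataset` or list of labelled samples
#' @param shrink_factor geometric step (default `sqrt(2)`)
#' @param min_size smallest subset size to evaluate (must be >= 2k)
#' @param k folds per size
#' @param seed seed (subset draws and fold assignment)
#' @param learner as in [stratified_cv()]
#' @return data.frame with one row per size: `n`, `accuracy`, `precision`,
#'   `recall`, `f1` (fold averages)
#' @export
subsample_study <- function(data, shrink_factor = sqrt(2), min_size,
                            k = 5, seed = NULL, learner = cnn_learner()) {
  if (min_size < 2 * k)
    stop_usage("min_size must be at least 2k = ", 2 * k)
  labels <- dataset_labels(data)
  n0 <- length(labels)
  if (n0 < min_size) stop_usage("dataset smaller than min_size")
  sizes <- subsample_sizes(n0, shrink_factor, min_size)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    idx <- stratified_subsample(labels, n)
    cv <- stratified_cv(subset_data(data, idx), k = k,
                        seed = if (!is.null(seed)) seed + i,
                        learner = learner)
    rows[[i]] <- data.frame(n = n, accuracy = cv$average["accuracy"],
                            precision = cv$average["precision"],
                            recall = cv$average["recall"],
                            f1 = cv$average["f1"], row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Sizes visited by the geometric subsampling ladder
#'
#' @param n0 starting size
#' @param shrink_factor geometric step
#' @param min_size smallest admissible size
#' @return integer vector `round(n0 * shrink_factor^-j) >= min_size`
#' @export
subsample_sizes <- function(n0, shrink_factor = sqrt(2), min_size) {
  sizes <- integer(0)
  j <- 0
  repeat {
    n <- as.integer(round_half_up(n0 * shrink_factor^(-j)))
    if (n < min_size) break
    sizes <- c(sizes, n)
    j <- j + 1
  }
  unique(sizes)
}

# proportional stratified subsample of the given total size
stratified_subsample <- function(labels, n) {
  classes <- unique(labels)
  counts <- table(labels)[classes]
  take <- round_half_up(as.numeric(counts) * n / length(labels))
  # largest-remainder fixup so the total is exactly n
  while (sum(take) > n) take[which.max(take)] <- take[which.max(take)] - 1
  while (sum(take) < n) take[which.min(take)] <- take[which.min(take)] + 1
  idx <- integer(0)
  for (i in seq_along(classes))
    idx <- c(idx, sample(which(labels == classes[i]), take[i]))
  sort(idx)
}

#' Binomial subgroup tests of classification accuracy
#'
#' For each level of a grouping attribute, tests (exact two-sided binomial)
#' whether the group's correct-classification count is compatible with the
#' overall accuracy, and Bonferroni-corrects across the groups of the
#' scheme. Used to probe whether the classifier is biased with respect to
#' reference base, alternative base, base pair, mutation class, or VAF bin.
#'
#' @param predictions,labels character vectors of predicted and true classes
#' @param metadata data.frame with per-sample columns `ref_base`,
#'   `alt_base`, `mutation_class`, `vaf` (as available)
#' @param grouping one of "ref_base", "alt_base", "ref_alt_pair",
#'   "mutation_class", "vaf_bin"
#' @param alpha family-wise significance level (default 0.05)
#' @param vaf_breaks optional breaks for the VAF bins; defaults to dataset
#'   quartiles
#' @return data.frame with one row per group: `grouping`, `group`, `n`,
#'   `successes`, `accuracy`, `p_value`, `p_adjusted`, `significant`
#' @export
subgroup_binomial_tests <- function(predictions, labels, metadata,
                                    grouping = c("ref_base", "alt_base",
                                                 "ref_alt_pair",
                                                 "mutation_class", "vaf_bin"),
                                    alpha = 0.05, vaf_breaks = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(length(predictions) == length(labels),
            nrow(metadata) == length(labels))
  correct <- predictions == labels
  overall <- mean(correct)
  group <- switch(grouping,
    ref_base = metadata$ref_base,
    alt_base = metadata$alt_base,
    ref_alt_pair = paste0(metadata$ref_base, ">", metadata$alt_base),
    mutation_class = metadata$mutation_class,
    vaf_bin = {
      v <- metadata$vaf
      br <- vaf_breaks %||% unique(quantile(v, c(0, .25, .5, .75, 1),
                                            na.rm = TRUE))
      if (length(br) < 2) {  # degenerate VAF distribution: one bin
        ifelse(is.na(v), NA_character_, "all")
      } else {
        as.character(cut(v, breaks = br, include.lowest = TRUE))
      }
    })
  if (anyNA(group)) {
    warning(sum(is.na(group)), " sample(s) with missing '", grouping,
            "' skipped")
    keep <- !is.na(group)
    group <- group[keep]; correct <- correct[keep]
  }
  levels_ <- sort(unique(group))
  m <- length(levels_)
  rows <- lapply(levels_, function(g) {
    n <- sum(group == g)
    x <- sum(correct[group == g])
    p <- binom.test(x, n, p = overall, alternative = "two.sided")$p.value
    data.frame(grouping = grouping, group = g, n = n, successes = x,
               accuracy = x / n, p_value = p,
               p_adjusted = min(1, p * m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  attr(out, "overall_accuracy") <- overall
  out
}
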