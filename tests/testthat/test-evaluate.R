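# metrics, the confusion-matrix reconciliation solver, resampling schemes,
# and the binomial subgroup tests

oracle_learner <- function(train_data, test_data) {
  vapply(pileupCNN:::sample_list(test_data), `[[`, character(1), "label")
}

majority_learner <- function(train_data, test_data) {
  labs <- vapply(pileupCNN:::sample_list(train_data), `[[`, character(1),
                 "label")
  maj <- names(sort(table(labs), decreasing = TRUE))[1]
  rep(maj, length(pileupCNN:::sample_list(test_data)))
}

toy_data <- function(n, p_mut = 0.5, seed = 1) {
  set.seed(seed)
  labs <- sample(rep(c("mutation", "artefact"),
                     c(round(n * p_mut), n - round(n * p_mut))))
  lapply(seq_len(n), function(i)
    structure(list(values = array(0, c(1, 1, 1)), site = NULL,
                   label = labs[i], tracks = "x"),
              class = "composite_sample"))
}

test_that("compute_metrics implements the four standard formulas", {
  m <- compute_metrics(confusion_matrix(TP = 500, FP = 7, TN = 1375, FN = 203))
  expect_equal(round(m$accuracy, 3), 0.899)
  expect_equal(round(m$precision, 3), 0.986)
  expect_equal(round(m$recall, 3), 0.711)
  expect_equal(round(m$f1, 3), 0.826)

  sym <- compute_metrics(confusion_matrix(25, 25, 25, 25))
  expect_equal(unlist(sym[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = .5, precision = .5, recall = .5, f1 = .5))

  edge <- compute_metrics(confusion_matrix(TP = 0, FP = 0, TN = 10, FN = 10))
  expect_true(is.na(edge$precision))
  expect_equal(edge$recall, 0)
  expect_true(is.na(edge$f1))
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(42)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(0:200, 1), sample(0:200, 1),
                           sample(1:200, 1), sample(0:200, 1))
    m <- compute_metrics(cm)
    total <- cm$TP + cm$FP + cm$TN + cm$FN
    if (!is.na(m$precision) && !is.na(m$recall) && !is.na(m$f1))
      expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
    specificity <- cm$TN / (cm$FP + cm$TN)
    if (!is.na(m$recall))
      expect_equal(m$accuracy,
                   (m$recall * (cm$TP + cm$FN) +
                    specificity * (cm$FP + cm$TN)) / total)
  }
})

test_that("f1_from_pr reproduces published precision/recall/F1 triples", {
  # rule-based filtering rows and the cross-facility holdout paragraph
  expect_equal(round(f1_from_pr(0.986, 0.711), 3), 0.826)
  expect_equal(round(f1_from_pr(0.939, 0.882), 3), 0.910)
  expect_equal(round(f1_from_pr(0.948, 0.995), 3), 0.971)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_true(is.na(f1_from_pr(0, 0)))
})

test_that("solve_confusion reconciles printed tables and flags infeasibility", {
  s1 <- solve_confusion(703, 1382, 0.986, 0.711, 3)
  expect_true(s1$feasible && s1$unique)
  expect_equal(s1$solutions$TP, 500)
  expect_equal(s1$solutions$FP, 7)

  s2 <- solve_confusion(703, 1382, 0.939, 0.882, 3)
  expect_true(s2$unique)
  expect_equal(s2$solutions$TP, 620)
  expect_equal(s2$solutions$FP, 40)

  s3 <- solve_confusion(10, 10, 0.999, 0.999, 3)
  expect_false(s3$feasible)
  expect_equal(nrow(s3$solutions), 0)
})

test_that("solve_confusion round-trips with compute_metrics", {
  set.seed(7)
  for (i in 1:20) {
    n_pos <- sample(50:400, 1); n_neg <- sample(50:400, 1)
    tp <- sample(0:n_pos, 1); fp <- sample(0:n_neg, 1)
    if (tp + fp == 0) next
    m <- compute_metrics(confusion_matrix(tp, fp, n_neg - fp, n_pos - tp))
    sol <- solve_confusion(n_pos, n_neg, round_half_up(m$precision, 3),
                           round_half_up(m$recall, 3), 3)
    expect_true(sol$feasible)
    # the true matrix is among the solutions, and every solution rounds back
    expect_true(any(sol$solutions$TP == tp & sol$solutions$FP == fp))
    for (j in seq_len(nrow(sol$solutions))) {
      mj <- compute_metrics(do.call(confusion_matrix, as.list(sol$solutions[j, ])))
      expect_equal(round_half_up(mj$precision, 3), round_half_up(m$precision, 3))
      expect_equal(round_half_up(mj$recall, 3), round_half_up(m$recall, 3))
    }
  }
})

test_that("stratified folds partition the data with balanced labels", {
  data <- toy_data(10, 0.5)
  cv <- stratified_cv(data, k = 5, seed = 1, learner = oracle_learner)
  labs <- vapply(data, `[[`, character(1), "label")
  for (f in 1:5) {
    expect_equal(sum(cv$folds == f & labs == "mutation"), 1)
    expect_equal(sum(cv$folds == f & labs == "artefact"), 1)
  }
  # union of folds is the dataset; folds are disjoint by construction
  expect_equal(sort(unlist(lapply(1:5, function(f) which(cv$folds == f)))),
               1:10)
  # same seed -> same assignment
  cv2 <- stratified_cv(data, k = 5, seed = 1, learner = oracle_learner)
  expect_identical(cv$folds, cv2$folds)
  # perfect predictions give perfect metrics
  expect_equal(unname(cv$average["accuracy"]), 1)
  # class smaller than k errors out
  expect_error(stratified_cv(toy_data(6, 1 / 3), k = 5,
                             learner = oracle_learner), "at least k")
})

test_that("fold class proportions stay within one count of global", {
  data <- toy_data(103, 0.33, seed = 9)
  labs <- vapply(data, `[[`, character(1), "label")
  cv <- stratified_cv(data, k = 5, seed = 4, learner = oracle_learner)
  for (cl in c("mutation", "artefact")) {
    per_fold <- vapply(1:5, function(f) sum(cv$folds == f & labs == cl),
                       numeric(1))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("random_splits produces stratified, averaged reports", {
  data <- toy_data(60, 0.5)
  rs <- random_splits(data, n_splits = 2, test_fraction = 0.2, seed = 3,
                      learner = oracle_learner)
  expect_equal(nrow(rs$per_split), 2)
  expect_equal(rs$per_split$n_test, c(12, 12))
  expect_equal(unname(rs$average["accuracy"]),
               mean(rs$per_split$accuracy))
  # a perfect oracle classifier is perfect on every split
  expect_true(all(rs$per_split$accuracy == 1))
  # majority learner: accuracy equals the majority share of the test split
  rs2 <- random_splits(toy_data(60, 0.5), n_splits = 3, seed = 3,
                       learner = majority_learner)
  expect_true(all(rs2$per_split$accuracy <= 1))
  expect_error(random_splits(data, 2, test_fraction = 0), "test_fraction")
})

test_that("subsample ladder follows round-half-up geometric sizes", {
  expect_equal(subsample_sizes(2048, sqrt(2), 500),
               c(2048, 1448, 1024, 724, 512))
  expect_equal(subsample_sizes(2048, 2, 100),
               c(2048, 1024, 512, 256, 128))
  st <- subsample_study(toy_data(64, 0.5), shrink_factor = 2, min_size = 16,
                        k = 5, seed = 2, learner = oracle_learner)
  expect_equal(st$n, c(64, 32, 16))
  expect_true(all(st$accuracy == 1))
  expect_error(subsample_study(toy_data(64), min_size = 5, k = 5,
                               learner = oracle_learner), "min_size")
})

test_that("binomial subgroup tests match an exact tail-sum oracle", {
  # exact two-sided binomial p-value by direct enumeration
  exact_binom_p <- function(x, n, p0) {
    d <- dbinom(0:n, n, p0)
    sum(d[d <= dbinom(x, n, p0) * (1 + 1e-7)])
  }
  n <- 400
  meta <- data.frame(ref_base = rep(c("A", "C", "G", "T"), each = 100),
                     alt_base = "G", mutation_class = "exonic",
                     vaf = runif(n))
  labels <- rep("mutation", n)
  predictions <- labels
  # group A: 50/100 correct; groups C,G,T: 80/100 (close to overall)
  predictions[which(meta$ref_base == "A")[1:50]] <- "artefact"
  for (g in c("C", "G", "T"))
    predictions[which(meta$ref_base == g)[1:20]] <- "artefact"
  res <- subgroup_binomial_tests(predictions, labels, meta, "ref_base")
  expect_equal(nrow(res), 4)
  overall <- mean(predictions == labels)  # 0.725
  for (i in seq_len(nrow(res))) {
    g <- res$group[i]
    expect_equal(res$p_value[i],
                 exact_binom_p(res$successes[i], res$n[i], overall),
                 tolerance = 1e-9)
    expect_equal(res$p_adjusted[i], min(1, res$p_value[i] * 4))
    expect_gte(res$p_adjusted[i], res$p_value[i])
  }
  expect_true(res$significant[res$group == "A"])
  expect_false(any(res$significant[res$group != "A"]))

  # deviant group vs near-ceiling overall accuracy
  labels2 <- rep("mutation", 2000)
  pred2 <- labels2
  pred2[1:100][1:50] <- "artefact"     # group "g1": 50/100
  pred2[101:2000][1:5] <- "artefact"   # rest: 1895/1900
  meta2 <- data.frame(ref_base = rep(c("g1", "g2"), c(100, 1900)),
                      alt_base = "G", mutation_class = "exonic", vaf = 0.5)
  res2 <- subgroup_binomial_tests(pred2, labels2, meta2, "ref_base")
  expect_lt(res2$p_value[res2$group == "g1"], 1e-10)
  expect_true(res2$significant[res2$group == "g1"])

  # compatible group is not significant
  pred3 <- labels2
  pred3[sample(2000, 100)] <- "artefact"  # overall 0.95
  meta3 <- meta2
  res3 <- subgroup_binomial_tests(pred3, labels2, meta3, "ref_base")
  big <- res3[res3$group == "g2", ]
  expect_gt(big$p_value, 0.05)

  # single group: adjusted p equals raw p
  meta4 <- data.frame(ref_base = "A", alt_base = "G",
                      mutation_class = "exonic", vaf = 0.5)[rep(1, 50), ]
  res4 <- subgroup_binomial_tests(rep("mutation", 50),
                                  rep(c("mutation", "artefact"), c(45, 5)),
                                  meta4, "ref_base")
  expect_equal(res4$p_adjusted, res4$p_value)
})

test_that("vaf binning and grouping schemes cover the metadata", {
  set.seed(11)
  n <- 120
  meta <- data.frame(ref_base = sample(c("A", "C"), n, TRUE),
                     alt_base = sample(c("G", "T"), n, TRUE),
                     mutation_class = sample(c("exonic", "UTR3"), n, TRUE),
                     vaf = runif(n))
  labels <- sample(c("mutation", "artefact"), n, TRUE)
  predictions <- ifelse(runif(n) < 0.9, labels,
                        ifelse(labels == "mutation", "artefact", "mutation"))
  for (g in c("ref_base", "alt_base", "ref_alt_pair", "mutation_class",
              "vaf_bin")) {
    res <- subgroup_binomial_tests(predictions, labels, meta, g)
    expect_equal(sum(res$n), n)
    expect_true(all(res$p_adjusted <= 1))
    expect_true(all(res$p_adjusted >= res$p_value))
  }
  expect_equal(nrow(subgroup_binomial_tests(predictions, labels, meta,
                                            "vaf_bin")), 4)
})
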