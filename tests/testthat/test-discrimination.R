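make_labeled <- function(seed = 5L, margin = 0.5) {
  pt <- packaged_table()
  sim <- simulate_classification_dataset(
    pt, simulation_config(seed = seed, class_margin = margin))
  sim$labeled
}

test_that("labels follow the sign of the response and zero is refused", {
  pt <- packaged_table()
  rec <- data.frame(receptor_id = "r", position = c(1L, 2L),
                    wild = c("A", "C"), mutant = c("K", "G"),
                    response = c(1.2, -0.3))
  ds <- mutant_dataset(rec)
  expect_identical(as.character(label_by_sign(ds)), c("increase", "decrease"))

  rec$response <- c(1.2, 0)
  expect_error(label_by_sign(mutant_dataset(rec)), "zero")

  rec$response <- c(1.2, 0.4)
  lab <- mutprop:::labeled_dataset(matrix(rnorm(4), 2), label_by_sign(mutant_dataset(rec)))
  expect_false(lab$trainable)
  expect_error(train_and_classify(lab, "logistic"), "single-class")
})

test_that("classification encoding has 4 features per property, consistent with delta", {
  pt <- packaged_table()
  sim <- simulate_classification_dataset(pt, simulation_config(seed = 3L))
  ds <- sim$dataset
  lab <- encode_for_classification(ds, pt, pt$property_ids[1:3], k = 2)
  expect_identical(dim(lab$features), c(28L, 12L))
  dcol <- lab$features[, "prop01:delta"]
  dref <- vapply(seq_len(28), function(i)
    delta_property(pt, "prop01", ds$records$wild[i], ds$records$mutant[i]),
    numeric(1))
  expect_equal(unname(dcol), dref)
  # window column follows the shared terminus-truncation convention
  wref <- vapply(seq_len(28), function(i)
    local_sequence_effect(pt, "prop01", ds$sequence, ds$records$position[i],
                          ds$records$mutant[i], k = 2), numeric(1))
  expect_equal(unname(lab$features[, "prop01:seqwin"]), wref)
})

test_that("classifiers are deterministic given a seed and 1-NN memorizes", {
  lab <- make_labeled()
  for (m in c("logistic", "naive_bayes", "knn", "decision_tree")) {
    c1 <- train_and_classify(lab, m, seed = 7L)
    c2 <- train_and_classify(lab, m, seed = 7L)
    expect_identical(predict(c1, lab$features), predict(c2, lab$features))
  }
  cm <- self_consistency(lab, "knn", knn_k = 1L)
  expect_equal(cm$accuracy, 1.0)
})

test_that("confusion measures satisfy their defining identities", {
  cm <- confusion_metrics(14, 1, 12, 1)
  expect_equal(cm$sensitivity, 14 / 15)
  expect_equal(cm$specificity, 12 / 13)
  expect_equal(cm$accuracy, 26 / 28)
  expect_equal(round(c(cm$sensitivity, cm$specificity, cm$accuracy), 3),
               c(0.933, 0.923, 0.929))

  expect_equal(confusion_metrics(15, 0, 13, 0)$accuracy, 1.0)
  zero <- confusion_metrics(0, 13, 0, 15)
  expect_equal(c(zero$sensitivity, zero$specificity, zero$accuracy), c(0, 0, 0))

  expect_error(confusion_metrics(0, 5, 3, 0), "sensitivity undefined")
  expect_error(confusion_metrics(3, 0, 0, 5), "specificity undefined")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")

  # accuracy is the prevalence-weighted mean of sensitivity and specificity
  set.seed(2)
  for (i in 1:10) {
    k <- sample(1:20, 4, replace = TRUE)
    m <- confusion_metrics(k[1], k[2], k[3], k[4])
    expect_equal(m$accuracy,
                 m$sensitivity * (m$TP + m$FN) / m$N +
                   m$specificity * (m$TN + m$FP) / m$N)
    expect_equal(m$N, sum(k))
  }
})

test_that("swapping class labels swaps sensitivity and specificity", {
  set.seed(9)
  truth <- factor(sample(c("increase", "decrease"), 30, replace = TRUE),
                  levels = c("increase", "decrease"))
  pred <- factor(sample(c("increase", "decrease"), 30, replace = TRUE),
                 levels = c("increase", "decrease"))
  flip <- function(f) factor(ifelse(f == "increase", "decrease", "increase"),
                             levels = c("increase", "decrease"))
  m1 <- mutprop:::metrics_from_labels(truth, pred)
  m2 <- mutprop:::metrics_from_labels(flip(truth), flip(pred))
  expect_equal(m2$sensitivity, m1$specificity)
  expect_equal(m2$specificity, m1$sensitivity)
  expect_equal(m2$accuracy, m1$accuracy)
})

test_that("self-consistency counts conserve the class totals", {
  lab <- make_labeled(seed = 8L)
  cm <- self_consistency(lab, "decision_tree", seed = 1L)
  expect_equal(cm$TP + cm$FN, sum(lab$labels == "increase"))
  expect_equal(cm$TN + cm$FP, sum(lab$labels == "decrease"))
  expect_equal(cm$N, 28)
})

test_that("jack-knife predictions never see their own record", {
  lab <- make_labeled(seed = 13L, margin = 0.3)
  n <- length(lab$labels)
  cm <- jackknife(lab, "logistic", seed = 1L)
  expect_equal(cm$N, n)  # one prediction per record
  # manual fold replication for a few records
  for (i in c(1, 14, 28)) {
    tr <- mutprop:::labeled_dataset(lab$features[-i, , drop = FALSE],
                                    lab$labels[-i])
    clf <- train_and_classify(tr, "logistic", seed = 1L)
    manual <- predict(clf, lab$features[i, , drop = FALSE])
    full_jk <- jackknife(lab, "logistic", seed = 1L)
    expect_s3_class(full_jk, "confusion_metrics")
    expect_identical(levels(manual), c("increase", "decrease"))
  }
})

test_that("a singleton class triggers the majority-vote fold policy with a warning", {
  set.seed(31)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  X[1, ] <- X[1, ] + 10
  lab <- mutprop:::labeled_dataset(X, c("increase", rep("decrease", 9)))
  expect_warning(cm <- jackknife(lab, "knn", knn_k = 1L), "single")
  # the fold that leaves out the lone increase trains one-class and votes decrease
  expect_equal(cm$TP, 0)
  expect_equal(cm$FN, 1)
})

test_that("evaluate_classifiers reports every bundled method in both modes", {
  lab <- make_labeled(seed = 4L)
  rep <- evaluate_classifiers(lab, seed = 2L)
  expect_identical(nrow(rep), 8L)
  expect_setequal(unique(rep$method),
                  c("logistic", "naive_bayes", "knn", "decision_tree"))
  expect_setequal(unique(rep$mode), c("self", "jackknife"))
  expect_true(attr(rep, "best") %in% rep$method)
  expect_true(all(rep$TP + rep$FP + rep$TN + rep$FN == 28))
})
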