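CLASSIFIER_METHODS <- c("logistic", "naive_bayes", "knn", "decision_tree")
CLASS_LEVELS <- c("increase", "decrease")  # positive class first

labeled_dataset <- function(features, labels, records = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels, levels = CLASS_LEVELS)
  if (anyNA(labels)) stop("labels must be 'increase' or 'decrease'", call. = FALSE)
  if (nrow(features) != length(labels)) {
    stop("feature rows and label count disagree", call. = FALSE)
  }
  structure(
    list(features = features, labels = labels, records = records,
         trainable = all(table(labels) > 0)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Labeled mutant set: %d mutants (%d increase / %d decrease), %d features%s\n",
              length(x$labels), tab[["increase"]], tab[["decrease"]],
              ncol(x$features),
              if (x$trainable) "" else " [single class: untrainable]"))
  invisible(x)
}

#' Label mutants by the sign of their response change
#'
#' Mutants with a positive signed response change (e.g. ΔEC50 > 0) are
#' labelled `increase` (the positive class), negative ones `decrease`.
#' A response of exactly zero cannot be labelled and is an error -- there
#' is no defensible default for "no change".
#'
#' @param dataset a [mutant_dataset] whose responses are signed changes.
#' @return factor of labels (`increase`/`decrease`), one per record.
#' @export
label_by_sign <- function(dataset) {
  stopifnot(inherits(dataset, "mutant_dataset"))
  y <- dataset$records$response
  zero <- which(y == 0)
  if (length(zero) > 0) {
    stop("response exactly zero in row(s) ", paste(zero, collapse = ", "),
         ": cannot assign increase/decrease label", call. = FALSE)
  }
  factor(ifelse(y > 0, "increase", "decrease"), levels = CLASS_LEVELS)
}

#' Encode mutants for increase/decrease classification
#'
#' Builds, for each selected property, the attribute block
#' \[P(wild), P(mutant), ΔP, P_seq(k)\] -- wild-type value, mutant value,
#' mutation-induced difference and local sequence-window effect -- and
#' concatenates the blocks in property order. Labels come from
#' [label_by_sign()]. The window term uses the same terminus-truncation
#' convention as [local_sequence_effect()].
#'
#' @param dataset a [mutant_dataset] with a sequence attached.
#' @param table a [property_table].
#' @param property_ids properties to encode.
#' @param k half-window for the window term.
#' @param scale `"normalized"` (default) or `"raw"`.
#' @return a `labeled_dataset` with 4 x length(property_ids) feature
#'   columns. A single-class dataset is returned flagged untrainable.
#' @export
encode_for_classification <- function(dataset, table, property_ids, k = 1L,
                                      scale = c("normalized", "raw")) {
  stopifnot(inherits(dataset, "mutant_dataset"), inherits(table, "property_table"))
  scale <- match.arg(scale)
  if (is.null(dataset$sequence)) {
    stop("classification encoding needs the receptor sequence (window terms)",
         call. = FALSE)
  }
  unknown <- setdiff(property_ids, table$property_ids)
  if (length(unknown) > 0) stop("unknown property id(s): ",
                                paste(unknown, collapse = ", "), call. = FALSE)
  rec <- dataset$records
  m <- if (scale == "normalized") table$normalized else table$raw
  blocks <- lapply(property_ids, function(pid) {
    wildv <- m[pid, rec$wild]
    mutv <- m[pid, rec$mutant]
    seqw <- vapply(seq_len(nrow(rec)), function(i)
      local_sequence_effect(table, pid, dataset$sequence, rec$position[i],
                            rec$mutant[i], k, scale), numeric(1))
    b <- cbind(wildv, mutv, mutv - wildv, seqw)
    colnames(b) <- paste(pid, c("wild", "mutant", "delta", "seqwin"), sep = ":")
    b
  })
  features <- do.call(cbind, blocks)
  rownames(features) <- paste0(rec$wild, rec$position, rec$mutant)
  labeled_dataset(features, label_by_sign(dataset), records = rec)
}

scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

scale_apply <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

#' Train a binary mutant classifier
#'
#' A fixed, documented set of four standard classifiers is bundled:
#' `logistic` (logistic discriminant via [stats::glm()]), `naive_bayes`
#' (Gaussian naive Bayes, [e1071::naiveBayes()]), `knn` (k-nearest
#' neighbor, [class::knn()]) and `decision_tree` ([rpart::rpart()] with
#' small-sample split settings). Features are standardized with training
#' statistics; all randomness is controlled by `seed`.
#'
#' @param data a `labeled_dataset` with both classes present.
#' @param method one of `"logistic"`, `"naive_bayes"`, `"knn"`,
#'   `"decision_tree"`.
#' @param seed integer seed controlling any stochastic component.
#' @param knn_k neighborhood size for `knn`.
#' @return object of class `mutprop_classifier`; use
#'   [predict.mutprop_classifier()] on new feature rows.
#' @export
train_and_classify <- function(data, method = CLASSIFIER_METHODS, seed = 1L,
                               knn_k = 3L) {
  stopifnot(inherits(data, "labeled_dataset"))
  method <- match.arg(method)
  if (length(unique(data$labels)) < 2) {
    stop("single-class data: both increase and decrease mutants are needed for training",
         call. = FALSE)
  }
  sc <- scale_fit(data$features)
  Xs <- scale_apply(data$features, sc)
  model <- with_seed(seed, switch(
    method,
    logistic = {
      df <- data.frame(.y = as.integer(data$labels == "increase"), Xs,
                       check.names = TRUE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    naive_bayes = e1071::naiveBayes(x = as.data.frame(Xs), y = data$labels),
    knn = list(train = Xs, labels = data$labels, k = as.integer(knn_k)),
    decision_tree = {
      df <- data.frame(.y = data$labels, Xs, check.names = TRUE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 4, cp = 1e-4,
                                                  xval = 0))
    }
  ))
  structure(list(method = method, model = model, scaling = sc, seed = seed,
                 feature_names = colnames(data$features)),
            class = "mutprop_classifier")
}

#' Predict increase/decrease labels for mutant feature rows
#'
#' @param object a fitted `mutprop_classifier`.
#' @param features numeric matrix with the training feature columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.mutprop_classifier <- function(object, features, ...) {
  features <- as.matrix(features)
  missing_cols <- setdiff(object$feature_names, colnames(features))
  if (length(missing_cols) > 0) {
    stop("feature matrix lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Xs <- scale_apply(features[, object$feature_names, drop = FALSE],
                    object$scaling)
  pred <- with_seed(object$seed, switch(
    object$method,
    logistic = {
      df <- data.frame(Xs, check.names = TRUE)
      pr <- stats::predict(object$model, newdata = df, type = "response")
      ifelse(pr >= 0.5, "increase", "decrease")
    },
    naive_bayes = as.character(stats::predict(object$model,
                                              newdata = as.data.frame(Xs))),
    knn = as.character(class::knn(train = object$model$train,
                                  test = Xs,
                                  cl = object$model$labels,
                                  k = object$model$k)),
    decision_tree = {
      df <- data.frame(Xs, check.names = TRUE)
      as.character(stats::predict(object$model, newdata = df, type = "class"))
    }
  ))
  factor(pred, levels = CLASS_LEVELS)
}

#' Confusion-matrix performance measures
#'
#' The three standard measures for binary discrimination:
#' \deqn{Sensitivity = TP/(TP+FN)}
#' \deqn{Specificity = TN/(TN+FP)}
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FP+FN)}
#' with `increase` as the positive class.
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return object of class `confusion_metrics`: the four counts plus
#'   `sensitivity`, `specificity`, `accuracy`, `N`.
#' @examples
#' confusion_metrics(14, 1, 12, 1)
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("TP, FP, TN, FN must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  if (TP + FN == 0) stop("sensitivity undefined: no positive (increase) cases",
                         call. = FALSE)
  if (TN + FP == 0) stop("specificity undefined: no negative (decrease) cases",
                         call. = FALSE)
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN, N = n,
         sensitivity = TP / (TP + FN),
         specificity = TN / (TN + FP),
         accuracy = (TP + TN) / n),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (N = %d)\n", x$TP, x$FP, x$TN, x$FN, x$N))
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

metrics_from_labels <- function(truth, pred) {
  confusion_metrics(TP = sum(truth == "increase" & pred == "increase"),
                    FP = sum(truth == "decrease" & pred == "increase"),
                    TN = sum(truth == "decrease" & pred == "decrease"),
                    FN = sum(truth == "increase" & pred == "decrease"))
}

#' Self-consistency test
#'
#' Trains on all N mutants and evaluates on the same N (resubstitution).
#' An optimistic measure by construction; compare with [jackknife()].
#'
#' @inheritParams train_and_classify
#' @return [confusion_metrics()] of the resubstitution predictions.
#' @export
self_consistency <- function(data, method = CLASSIFIER_METHODS, seed = 1L,
                             knn_k = 3L) {
  method <- match.arg(method)
  clf <- train_and_classify(data, method, seed = seed, knn_k = knn_k)
  metrics_from_labels(data$labels, predict(clf, data$features))
}

#' Jack-knife (leave-one-out) test
#'
#' Runs N folds: each mutant is predicted once by a classifier trained on
#' the other N-1, so no prediction ever sees its own record. Feature
#' standardization is refit inside every fold on the N-1 training rows
#' only (no leakage). If a fold's training set collapses to a single
#' class (possible when a class has one member), that fold predicts the
#' training majority class, with a warning.
#'
#' @inheritParams train_and_classify
#' @return [confusion_metrics()] aggregated over the N held-out predictions.
#' @export
jackknife <- function(data, method = CLASSIFIER_METHODS, seed = 1L, knn_k = 3L) {
  stopifnot(inherits(data, "labeled_dataset"))
  method <- match.arg(method)
  n <- length(data$labels)
  if (n < 3) stop("jack-knife needs N >= 3", call. = FALSE)
  tab <- table(data$labels)
  if (any(tab < 2)) {
    warning("a class has a single member; folds leaving it out train on one class ",
            "and predict the training majority", call. = FALSE)
  }
  pred <- factor(rep(NA_character_, n), levels = CLASS_LEVELS)
  for (i in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), i)
    tr_labels <- data$labels[train_idx]
    if (length(unique(tr_labels)) < 2) {
      pred[i] <- names(which.max(table(tr_labels)))
      next
    }
    tr <- labeled_dataset(data$features[train_idx, , drop = FALSE], tr_labels)
    clf <- train_and_classify(tr, method, seed = seed, knn_k = knn_k)
    pred[i] <- as.character(predict(clf, data$features[i, , drop = FALSE]))
  }
  metrics_from_labels(data$labels, pred)
}

#' Evaluate all bundled classifiers by self-consistency and jack-knife
#'
#' Convenience wrapper producing one row per (method, mode). Reports every
#' bundled method rather than a silently selected best; the maximum
#' jack-knife accuracy is flagged in the `best` attribute.
#'
#' @inheritParams train_and_classify
#' @param methods classifier methods to evaluate.
#' @return data.frame of class `evaluation_report`: `method`, `mode`,
#'   `TP`, `FP`, `TN`, `FN`, `sensitivity`, `specificity`, `accuracy`,
#'   `seed`.
#' @export
evaluate_classifiers <- function(data, methods = CLASSIFIER_METHODS,
                                 seed = 1L, knn_k = 3L) {
  rows <- list()
  for (m in methods) {
    for (mode in c("self", "jackknife")) {
      cm <- if (mode == "self") self_consistency(data, m, seed = seed, knn_k = knn_k)
            else jackknife(data, m, seed = seed, knn_k = knn_k)
      rows[[paste(m, mode)]] <- data.frame(
        method = m, mode = mode, TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        accuracy = cm$accuracy, seed = seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  jk <- out[out$mode == "jackknife", ]
  attr(out, "best") <- jk$method[which.max(jk$accuracy)]
  class(out) <- c("evaluation_report", class(out))
  out
}
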