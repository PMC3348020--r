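#' Pearson product-moment correlation
#'
#' The single correlation coefficient
#' \deqn{r = \frac{N\sum X Y - \sum X \sum Y}
#'   {\sqrt{[N\sum X^2 - (\sum X)^2][N\sum Y^2 - (\sum Y)^2]}}}
#' between a feature column X and the experimental response Y, with
#' explicit validation: both vectors must have equal length N >= 3 and be
#' non-constant (a constant vector leaves r undefined).
#'
#' @param x,y numeric vectors of equal length.
#' @return a single value in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)), call. = FALSE)
  }
  if (length(x) < 3) stop("need N >= 3 observations for a correlation", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Correlate every feature column with the response
#'
#' Computes the single correlation coefficient of each feature column
#' against the response and ranks columns by absolute correlation.
#' Constant columns (for which r is undefined) are reported in the
#' `skipped` component rather than silently dropped.
#'
#' @param features numeric matrix (e.g. from [build_feature_matrix()]),
#'   columns named.
#' @param y numeric response vector, one value per row.
#' @return list of class `correlation_report` with `results` (data.frame:
#'   `column`, `r`, `abs_r`, `N`, sorted by `abs_r` descending) and
#'   `skipped` (character vector of constant columns).
#' @export
correlate_all <- function(features, y) {
  features <- as.matrix(features)
  if (nrow(features) != length(y)) {
    stop("feature matrix rows and response length disagree", call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("col", seq_len(ncol(features)))
  }
  constant <- apply(features, 2L, function(v) stats::sd(v) == 0)
  keep <- colnames(features)[!constant]
  r <- vapply(keep, function(cn) pearson_r(features[, cn], y), numeric(1))
  res <- data.frame(column = keep, r = unname(r), abs_r = abs(unname(r)),
                    N = length(y), stringsAsFactors = FALSE)
  res <- res[order(-res$abs_r, res$column), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, skipped = colnames(features)[constant]),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, n = 10, ...) {
  cat(sprintf("Single-property correlations (N = %d, %d columns, %d skipped as constant)\n",
              x$results$N[1], nrow(x$results) + length(x$skipped), length(x$skipped)))
  print(utils::head(x$results, n))
  invisible(x)
}

#' Multiple linear regression on a property subset
#'
#' Ordinary least squares with intercept. The multiple correlation
#' coefficient R is reported as the (non-negative) Pearson correlation
#' between fitted and observed responses. Because the method is routinely
#' applied to very small mutant sets, the fit refuses saturated designs
#' (N < p + 2) unless `allow_saturated = TRUE`; N and p are always
#' reported alongside R so the fitting regime is visible.
#'
#' @param X numeric matrix N x p of selected feature columns.
#' @param y numeric response vector.
#' @param allow_saturated allow fits with N < p + 2 (near-saturated
#'   designs give inflated R; use only to reproduce small-sample
#'   protocols).
#' @return object of class `subset_fit`: `column_ids`, `coefficients`
#'   (intercept first), `R`, `fitted`, `N`, `p`.
#' @export
fit_multiple_regression <- function(X, y, allow_saturated = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("col", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X rows and y length disagree", call. = FALSE)
  if (n < p + 2 && !allow_saturated) {
    stop(sprintf(paste0("insufficient data: N = %d < p + 2 = %d; a fit this ",
                        "saturated is unreliable (set allow_saturated = TRUE ",
                        "to force it)"), n, p + 2), call. = FALSE)
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    dep_idx <- qrX$pivot[(qrX$rank + 1):(p + 1)] - 1  # shift past intercept
    dep <- colnames(X)[dep_idx[dep_idx >= 1]]
    stop("collinear feature columns (linearly dependent): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  fv <- unname(fitted(fit))
  R <- if (stats::sd(fv) == 0) 0 else abs(stats::cor(fv, y))
  structure(
    list(column_ids = colnames(X),
         coefficients = setNames(unname(coef(fit)), c("(Intercept)", colnames(X))),
         R = R, fitted = fv, N = n, p = p),
    class = "subset_fit"
  )
}

#' @export
print.subset_fit <- function(x, ...) {
  cat(sprintf("Subset regression: %d propert%s, N = %d, R = %.4f\n",
              x$p, if (x$p == 1) "y" else "ies", x$N, x$R))
  cat("  columns: ", paste(x$column_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict responses from a fitted subset regression
#'
#' @param object a `subset_fit`.
#' @param features numeric matrix containing (at least) the model's
#'   columns, by name.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.subset_fit <- function(object, features, ...) {
  features <- as.matrix(features)
  missing_cols <- setdiff(object$column_ids, colnames(features))
  if (length(missing_cols) > 0) {
    stop("feature matrix lacks model column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Xm <- features[, object$column_ids, drop = FALSE]
  drop(object$coefficients[1] + Xm %*% object$coefficients[-1])
}

#' Exhaustive best-subset regression search
#'
#' Fits every combination of feature columns of each requested subset size
#' and ranks the combinations by the multiple correlation coefficient R.
#' The search is exhaustive -- no heuristic pruning -- so the reported best
#' subset is the global optimum over the requested sizes. Ties are broken
#' deterministically: higher R, then smaller subset, then lexicographic
#' column order. Subset sizes follow the three-to-five-property protocol
#' of small-sample mutant analysis but any sizes in 1..5 (and beyond) are
#' accepted; each size s must satisfy N >= s + 2 unless `allow_saturated`.
#'
#' The inner loop runs in compiled code on centred cross-products, so the
#' full search over 49 properties at sizes up to 5 (about 2.1 million
#' fits) takes seconds.
#'
#' @param features numeric matrix (mutants x columns), columns named.
#' @param y numeric response vector.
#' @param sizes integer vector of subset sizes to search (default `1:3`).
#' @param top_m how many top-ranked combinations to return refitted with
#'   coefficients.
#' @param allow_saturated permit sizes with N < s + 2.
#' @param max_fits refusal ceiling on the search-space size (number of
#'   combinations); guards against accidental combinatorial blow-ups.
#' @return object of class `search_report`: `results` (list of
#'   [fit_multiple_regression()] fits, best first), `best` (the top fit),
#'   `search_space` (total combinations), `n_fitted`, `n_skipped`
#'   (rank-deficient subsets), `sizes`, `N`.
#' @export
exhaustive_subset_search <- function(features, y, sizes = 1:3, top_m = 10,
                                     allow_saturated = FALSE,
                                     max_fits = 5e6) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("col", seq_len(ncol(features)))
  }
  n <- nrow(features); p <- ncol(features)
  if (length(y) != n) stop("feature rows and response length disagree", call. = FALSE)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1)) stop("subset sizes must be >= 1", call. = FALSE)
  if (any(sizes > p)) stop("subset size exceeds number of columns", call. = FALSE)
  bad_sizes <- sizes[n < sizes + 2]
  if (length(bad_sizes) > 0 && !allow_saturated) {
    stop(sprintf(paste0("insufficient data for subset size(s) %s: N = %d < s + 2 ",
                        "(set allow_saturated = TRUE to force)"),
                 paste(bad_sizes, collapse = ", "), n), call. = FALSE)
  }
  space <- sum(choose(p, sizes))
  if (space > max_fits) {
    stop(sprintf(paste0("search space of %.0f combinations exceeds the ceiling ",
                        "of %.0f; raise max_fits to proceed"), space, max_fits),
         call. = FALSE)
  }
  raw <- .subset_search_cpp(features, as.numeric(y), sizes, as.integer(top_m))
  results <- lapply(raw$subsets, function(idx) {
    fit_multiple_regression(features[, idx, drop = FALSE], y,
                            allow_saturated = TRUE)
  })
  structure(
    list(results = results,
         best = if (length(results) > 0) results[[1]] else NULL,
         search_space = space,
         n_fitted = raw$n_fitted,
         n_skipped = raw$n_skipped,
         sizes = sizes, N = n, p = p,
         allow_saturated = allow_saturated),
    class = "search_report"
  )
}

#' @export
print.search_report <- function(x, n = 5, ...) {
  cat(sprintf("Exhaustive subset search: %d columns, sizes {%s}, %d mutants\n",
              x$p, paste(x$sizes, collapse = ","), x$N))
  cat(sprintf("  %.0f combinations fitted (%.0f skipped as rank-deficient)\n",
              x$n_fitted, x$n_skipped))
  for (i in seq_len(min(n, length(x$results)))) {
    f <- x$results[[i]]
    cat(sprintf("  %d. R = %.4f  [%s]\n", i, f$R,
                paste(f$column_ids, collapse = ", ")))
  }
  invisible(x)
}
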