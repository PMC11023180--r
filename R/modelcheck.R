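#' Majority-class baseline classifier
#'
#' Predicts the most frequent training class for every sample; a 50/50 tie
#' predicts class 0. Used as the baseline the boosted models must beat.
#'
#' @return a classifier function `f(x_train, y_train)` returning a predictor
#'   `g(x_test) -> 0/1 labels`.
#' @export
majority_classifier <- function() {
  function(x_train, y_train) {
    maj <- if (mean(y_train == 1) > 0.5) 1L else 0L
    function(x_test) rep(maj, nrow(x_test))
  }
}

#' Predictor from the majority class of a trait
#'
#' @param trait a `trait_table` or 0/1 vector of training labels.
#' @return function mapping any sample count (or matrix) to predicted labels.
#' @export
baseline_predict <- function(trait) {
  y <- if (inherits(trait, "trait_table")) trait$class else as.integer(trait)
  y <- y[!is.na(y)]
  if (length(y) == 0) stop("no training labels")
  maj <- if (mean(y == 1) > 0.5) 1L else 0L
  function(newdata) {
    n <- if (is.matrix(newdata) || is.data.frame(newdata)) nrow(newdata)
         else if (length(newdata) == 1 && is.numeric(newdata)) newdata
         else length(newdata)
    rep(maj, n)
  }
}

xgb_classifier <- function(spec) {
  force(spec)
  function(x_train, y_train) {
    b <- fit_xgb(x_train, y_train, spec, seed = sum(y_train) + nrow(x_train))
    function(x_test) predict_class(b, x_test)
  }
}

as_classifier <- function(obj) {
  if (inherits(obj, "model_spec")) return(xgb_classifier(obj))
  if (is.function(obj)) return(obj)
  stop("expected a model_spec or a classifier function")
}

#' 5x2cv paired t-test between two classifiers
#'
#' Dietterich's procedure: five replications of 2-fold cross-validation.
#' In replication i the samples are split into two folds (stratified by
#' class); each classifier is trained on one fold and tested on the other,
#' giving accuracy differences d_i1 and d_i2 (model minus baseline) and the
#' replication variance s_i^2 = (d_i1 - dbar_i)^2 + (d_i2 - dbar_i)^2. The
#' statistic is t = d_11 / sqrt(mean of the five s_i^2), referred to a t
#' distribution with 5 degrees of freedom (two-sided).
#'
#' Degenerate cases: all ten differences zero gives t = 0, p = 1; zero
#' variance with nonzero d_11 gives p = 0 with a warning.
#'
#' @param x a [genotype_matrix] or feature matrix.
#' @param trait a `trait_table` or 0/1 labels.
#' @param model a `model_spec` (fitted per fold) or a classifier function
#'   `f(x_train, y_train) -> g(x_test)`.
#' @param baseline same forms as `model`; default [majority_classifier()].
#' @param seed seed for the fold assignments.
#' @return list of class `cv52_result`: `t_statistic`, `p_value`, `df` (5),
#'   `fold_differences` (5x2 matrix), `significant` (p < 0.05).
#' @export
cv52_ttest <- function(x, trait, model, baseline = majority_classifier(),
                       seed = 1) {
  xy <- as_xy(x, trait)
  if (min(table(xy$y)) < 2) stop("need at least 2 samples per class")
  fit_a <- as_classifier(model)
  fit_b <- as_classifier(baseline)
  d <- matrix(NA_real_, 5, 2)
  set.seed(seed)
  for (i in 1:5) {
    fold <- stratified_folds(xy$y)
    for (j in 1:2) {
      tr <- which(fold == j); te <- which(fold != j)
      pa <- fit_a(xy$x[tr, , drop = FALSE], xy$y[tr])
      pb <- fit_b(xy$x[tr, , drop = FALSE], xy$y[tr])
      acc_a <- mean(pa(xy$x[te, , drop = FALSE]) == xy$y[te])
      acc_b <- mean(pb(xy$x[te, , drop = FALSE]) == xy$y[te])
      d[i, j] <- acc_a - acc_b
    }
  }
  s2 <- apply(d, 1, function(r) sum((r - mean(r))^2))
  v <- mean(s2)
  if (v == 0) {
    if (d[1, 1] == 0) {
      t <- 0; p <- 1
    } else {
      warning("degenerate variance in 5x2cv t-test; reporting p = 0")
      t <- sign(d[1, 1]) * Inf; p <- 0
    }
  } else {
    t <- d[1, 1] / sqrt(v)
    p <- 2 * stats::pt(-abs(t), df = 5)
  }
  structure(list(t_statistic = t, p_value = p, df = 5L,
                 fold_differences = d, significant = p < 0.05),
            class = "cv52_result")
}

#' @exportS3Method base::print
print.cv52_result <- function(x, ...) {
  cat(sprintf("5x2cv paired t-test: t = %.3f, p = %.4f (df = 5)%s\n",
              x$t_statistic, x$p_value,
              if (x$significant) "  *" else ""))
  invisible(x)
}

# two stratified folds: within each class, samples alternate between folds
# after a random shuffle
stratified_folds <- function(y) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(1:2, length(ix))
  }
  fold
}

#' Summarise held-out accuracies across resampled fits
#'
#' @param fits list of fit records from [resample_fit()], or a numeric
#'   vector of accuracies.
#' @return named vector: mean, min, q1, median, q3, max, n.
#' @export
accuracy_distribution <- function(fits) {
  acc <- if (is.numeric(fits)) fits
         else vapply(fits, `[[`, numeric(1), "accuracy")
  if (length(acc) == 0) stop("no fits")
  q <- stats::quantile(acc, c(0.25, 0.5, 0.75), names = FALSE)
  c(mean = mean(acc), min = min(acc), q1 = q[1], median = q[2], q3 = q[3],
    max = max(acc), n = length(acc))
}
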