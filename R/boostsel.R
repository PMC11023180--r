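#' Gradient-boosted classifier specification
#'
#' The six tuned hyperparameters of the binary gradient-boosted tree
#' classifier plus the fixed number of boosting rounds. Missing dosages are
#' passed to the learner as missing values and routed by its default
#' direction mechanism.
#'
#' @param learning_rate shrinkage per round (eta), > 0.
#' @param max_depth maximum tree depth, >= 1.
#' @param min_child_weight minimum hessian sum per leaf.
#' @param gamma minimum loss reduction to make a split.
#' @param subsample row subsampling per round, in (0, 1].
#' @param colsample_bytree feature subsampling per tree, in (0, 1].
#' @param nrounds number of boosting rounds (fixed, not tuned; default 100).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(learning_rate = 0.1, max_depth = 6,
                       min_child_weight = 1, gamma = 0, subsample = 1,
                       colsample_bytree = 1, nrounds = 100) {
  stopifnot(learning_rate > 0, max_depth >= 1,
            subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1,
            min_child_weight >= 0, gamma >= 0, nrounds >= 1)
  structure(list(learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight, gamma = gamma,
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 nrounds = as.integer(nrounds)),
            class = "model_spec")
}

#' Default hyperparameter search ranges
#'
#' Conventional ranges bracketing the library defaults: learning rate
#' log-uniform on \[0.01, 0.3\], depth 2..10, min_child_weight \[1, 10\],
#' gamma \[0, 5\], subsample and colsample_bytree \[0.5, 1\].
#'
#' @return list of ranges consumed by [tune_model()].
#' @export
default_tuning_ranges <- function() {
  list(learning_rate = c(0.01, 0.3), max_depth = c(2L, 10L),
       min_child_weight = c(1, 10), gamma = c(0, 5),
       subsample = c(0.5, 1), colsample_bytree = c(0.5, 1))
}

sample_model_spec <- function(ranges, nrounds) {
  model_spec(
    learning_rate = exp(stats::runif(1, log(ranges$learning_rate[1]),
                                     log(ranges$learning_rate[2]))),
    max_depth = sample(seq(ranges$max_depth[1], ranges$max_depth[2]), 1),
    min_child_weight = stats::runif(1, ranges$min_child_weight[1],
                                    ranges$min_child_weight[2]),
    gamma = stats::runif(1, ranges$gamma[1], ranges$gamma[2]),
    subsample = stats::runif(1, ranges$subsample[1], ranges$subsample[2]),
    colsample_bytree = stats::runif(1, ranges$colsample_bytree[1],
                                    ranges$colsample_bytree[2]),
    nrounds = nrounds)
}

xgb_params <- function(spec, seed = 0L) {
  list(objective = "binary:logistic", nthread = 1L, tree_method = "hist",
       max_bin = 8L,   # dosages take 3 values; small histograms are exact
       eta = spec$learning_rate, max_depth = spec$max_depth,
       min_child_weight = spec$min_child_weight, gamma = spec$gamma,
       subsample = spec$subsample, colsample_bytree = spec$colsample_bytree,
       seed = as.integer(seed))
}

fit_xgb <- function(x_train, y_train, spec, seed = 0L) {
  dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train)
  xgboost::xgb.train(xgb_params(spec, seed), dtrain, nrounds = spec$nrounds,
                     verbose = 0)
}

predict_class <- function(booster, x) {
  as.integer(stats::predict(booster, xgboost::xgb.DMatrix(x)) > 0.5)
}

# held-out 80/20 split indices; redraws (advancing the seed) if either part
# would be single-class, returning the seed actually used
split_8020 <- function(y, seed) {
  n <- length(y)
  repeat {
    set.seed(seed)
    train <- sort(sample.int(n, floor(0.8 * n)))
    test <- setdiff(seq_len(n), train)
    if (length(unique(y[train])) == 2 && length(test) > 0) {
      return(list(train = train, test = test, seed = seed))
    }
    message("single-class training split at seed ", seed, "; redrawing")
    seed <- seed + 1L
  }
}

#' Tune the classifier by random search
#'
#' Samples `budget` hyperparameter configurations from
#' [default_tuning_ranges()] and evaluates each by held-out accuracy on a
#' single 80/20 split of the trait's samples; the best configuration (ties:
#' first seen) is returned and frozen for all subsequent resampled refits.
#' Deterministic for a fixed seed.
#'
#' @param x a [genotype_matrix] or plain dosage matrix.
#' @param trait a `trait_table` (or 0/1 vector matching rows of `x`).
#' @param budget number of configurations to evaluate (default 100).
#' @param seed integer seed controlling the split and the search.
#' @param ranges search ranges, see [default_tuning_ranges()].
#' @param nrounds boosting rounds per evaluated configuration (default 100).
#' @return the best `model_spec`, with attributes `accuracy` (its held-out
#'   accuracy) and `budget`.
#' @export
tune_model <- function(x, trait, budget = 100, seed = 1, ranges = default_tuning_ranges(),
                       nrounds = 100) {
  xy <- as_xy(x, trait)
  if (length(unique(xy$y)) < 2) stop("trait has a single class")
  sp <- split_8020(xy$y, seed)
  set.seed(seed)
  best <- NULL; best_acc <- -Inf
  for (i in seq_len(budget)) {
    spec <- sample_model_spec(ranges, nrounds)
    b <- fit_xgb(xy$x[sp$train, , drop = FALSE], xy$y[sp$train], spec,
                 seed = seed)
    acc <- mean(predict_class(b, xy$x[sp$test, , drop = FALSE]) ==
                  xy$y[sp$test])
    if (acc > best_acc) { best_acc <- acc; best <- spec }
  }
  attr(best, "accuracy") <- best_acc
  attr(best, "budget") <- budget
  best
}

as_xy <- function(x, trait) {
  if (inherits(x, "genotype_matrix")) {
    if (x$coding == "heatmap_minus1") x <- recode_genotypes(x, "additive_NA")
    if (inherits(trait, "trait_table")) return(align_trait(x, trait))
    return(list(x = x$dosage, y = as.integer(trait)))
  }
  y <- if (inherits(trait, "trait_table")) {
    trait$class[match(rownames(x), trait$sample_id)]
  } else as.integer(trait)
  list(x = as.matrix(x), y = y)
}

#' Refit the tuned classifier on resampled training sets
#'
#' For each of `n_fits` seeds the samples are split 80/20, the classifier is
#' fitted with the frozen `spec` on the 80% and evaluated on the held-out
#' 20%, and the per-variant split-gain map of the fitted model is recorded.
#' A variant "appears" in a fit when it is used in at least one tree split
#' (i.e. has an entry in the gain map). Splits that would leave a
#' single-class training set are redrawn with the next seed.
#'
#' @param x a [genotype_matrix] or dosage matrix.
#' @param trait a `trait_table` or 0/1 vector.
#' @param spec a `model_spec`, e.g. from [tune_model()].
#' @param n_fits number of resampled fits (default 100).
#' @param base_seed seed of the first fit; fit i uses `base_seed + i - 1`
#'   (advanced past redraws).
#' @return list of `fit_record`s: each has `seed`, `accuracy` and
#'   `gain_scores` (named numeric vector, total split gain per variant used).
#' @export
resample_fit <- function(x, trait, spec, n_fits = 100, base_seed = 1) {
  stopifnot(n_fits >= 1, inherits(spec, "model_spec"))
  xy <- as_xy(x, trait)
  fits <- vector("list", n_fits)
  seed <- as.integer(base_seed)
  for (i in seq_len(n_fits)) {
    sp <- split_8020(xy$y, seed)
    b <- fit_xgb(xy$x[sp$train, , drop = FALSE], xy$y[sp$train], spec,
                 seed = sp$seed)
    acc <- mean(predict_class(b, xy$x[sp$test, , drop = FALSE]) ==
                  xy$y[sp$test])
    fits[[i]] <- structure(list(seed = sp$seed, accuracy = acc,
                                gain_scores = gain_map(b)),
                           class = "fit_record")
    seed <- sp$seed + 1L
  }
  fits
}

# total split gain per feature actually used by the booster
gain_map <- function(booster) {
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  tr <- tr[tr$Feature != "Leaf", , drop = FALSE]
  if (nrow(tr) == 0) return(stats::setNames(numeric(0), character(0)))
  g <- tapply(tr$Gain, tr$Feature, sum)
  stats::setNames(as.numeric(g), names(g))
}

#' Select variants by appearance frequency across resampled fits
#'
#' A variant's appearance count is the number of fits whose gain map
#' contains it; variants with count strictly greater than `threshold` are
#' selected (so with the default threshold of 20 a variant must appear in at
#' least 21 of 100 fits).
#'
#' @param fits list of fit records from [resample_fit()].
#' @param threshold strict appearance-count cutoff (default 20); must be
#'   below the number of fits.
#' @param variant_ids optional full variant-id universe; defaults to the ids
#'   seen in any gain map.
#' @return a `selection_result` data frame (`variant_id`,
#'   `appearance_count`, `total_gain`, `selected`) ordered by decreasing
#'   count, with attributes `threshold` and `n_fits`.
#' @export
select_variants <- function(fits, threshold = 20, variant_ids = NULL) {
  if (length(fits) == 0) stop("empty fit list")
  if (threshold >= length(fits)) stop("threshold must be below n_fits")
  maps <- lapply(fits, `[[`, "gain_scores")
  ids <- if (is.null(variant_ids)) unique(unlist(lapply(maps, names)))
         else variant_ids
  counts <- stats::setNames(integer(length(ids)), ids)
  gains <- stats::setNames(numeric(length(ids)), ids)
  for (m in maps) {
    hit <- intersect(names(m), ids)
    counts[hit] <- counts[hit] + 1L
    gains[hit] <- gains[hit] + m[hit]
  }
  out <- data.frame(variant_id = ids, appearance_count = unname(counts),
                    total_gain = unname(gains),
                    selected = unname(counts) > threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$appearance_count, out$variant_id), ]
  rownames(out) <- NULL
  structure(out, class = c("selection_result", "data.frame"),
            threshold = threshold, n_fits = length(fits))
}

#' Write fit records as JSON lines
#'
#' @param fits list of fit records.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fit_records <- function(fits, path) {
  lines <- vapply(fits, function(f)
    jsonlite::toJSON(list(seed = f$seed, accuracy = f$accuracy,
                          gain_scores = as.list(f$gain_scores)),
                     auto_unbox = TRUE, digits = NA), "")
  writeLines(lines, path)
  invisible(path)
}
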