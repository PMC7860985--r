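#' Fit a regression random forest
#'
#' Bagged CART regression trees: each tree is grown on a bootstrap
#' sample, considering `mtry` randomly drawn features per split, with
#' variance-reduction split selection and a minimum leaf size.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Numeric response, one value per row of `x`.
#' @param n_trees Number of trees, default 200.
#' @param mtry Features considered per split; default
#'   `max(1, floor(p / 3))`.
#' @param min_leaf Minimum samples per leaf, default 1.
#' @param seed Integer seed; fits are deterministic given it.
#' @return An object of class `cytofp_rf` (trees plus the fit
#'   settings and training column names).
#' @export
rf_fit <- function(x, y, n_trees = 200L, mtry = NULL, min_leaf = 1L,
                   seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  mtry <- as.integer(mtry %||% max(1L, floor(ncol(x) / 3)))
  mtry <- min(max(mtry, 1L), ncol(x))
  trees <- with_seed(seed, rf_fit_cpp(x, as.numeric(y),
                                      as.integer(n_trees), mtry,
                                      as.integer(min_leaf)))
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 mtry = mtry, min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed), columns = colnames(x)),
            class = "cytofp_rf")
}

#' Predict from a fitted regression forest
#'
#' @param object A `cytofp_rf` fit.
#' @param newdata Numeric matrix with the training columns (matched by
#'   name when both are named).
#' @param ... Unused.
#' @return Numeric vector of predictions (mean over trees).
#' @export
predict.cytofp_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(newdata))) {
    if (!all(object$columns %in% colnames(newdata)))
      stop_cytofp("cytofp_alignment_error",
                  "prediction columns do not cover the training columns")
    newdata <- newdata[, object$columns, drop = FALSE]
  } else if (length(object$columns) &&
             ncol(newdata) != length(object$columns)) {
    stop_cytofp("cytofp_alignment_error",
                "expected %d columns, got %d",
                length(object$columns), ncol(newdata))
  }
  as.numeric(rf_predict_cpp(object$trees, newdata))
}

#' Randomized hyperparameter search specification
#'
#' The two searched hyperparameters: the maximum number of features
#' considered at a split (uniform on `{1, ..., n_features}`) and the
#' minimum samples per leaf (uniform on `{1, ..., 5}`). Candidates are
#' drawn independently, duplicates allowed, and scored by K-fold
#' cross-validated R-squared.
#'
#' @param n_candidates Number of random combinations, default 100.
#' @param cv_folds Cross-validation folds, default 5.
#' @param min_samples_leaf_range Integer set for the leaf-size draw,
#'   default `1:5`.
#' @param max_features_range Integer set for the mtry draw; `NULL`
#'   (default) means `1:n_features` at fit time.
#' @param n_trees Trees per forest, default 200.
#' @param seed Integer seed for candidate draws, folds and tree
#'   bootstraps.
#' @return A list of class `rf_search_spec`.
#' @export
rf_search_spec <- function(n_candidates = 100L, cv_folds = 5L,
                           min_samples_leaf_range = 1:5,
                           max_features_range = NULL,
                           n_trees = 200L, seed = 1L) {
  stopifnot(n_candidates >= 1L, cv_folds >= 2L,
            length(min_samples_leaf_range) >= 1L)
  structure(list(n_candidates = as.integer(n_candidates),
                 cv_folds = as.integer(cv_folds),
                 min_samples_leaf_range = as.integer(min_samples_leaf_range),
                 max_features_range = max_features_range,
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "rf_search_spec")
}

#' Fit a diversity regressor on fingerprints
#'
#' Randomized hyperparameter search with K-fold cross-validation: the
#' candidate with the best mean CV R-squared is refit on all training
#' data.
#'
#' @param train_fingerprints A relative [count_table()].
#' @param train_targets Numeric diversity targets, one per sample, or
#'   a [diversity_table()]-style data frame restricted to a single
#'   `q` (columns `sample_id`, `value`).
#' @param spec An [rf_search_spec()].
#' @return A list of class `rf_bundle`: `model` (the refit
#'   `cytofp_rf`), `best` (chosen hyperparameters and CV score),
#'   `cv_table` (one row per candidate) and `spec`.
#' @export
fit_diversity_regressor <- function(train_fingerprints, train_targets,
                                    spec = rf_search_spec()) {
  stopifnot(inherits(train_fingerprints, "count_table"),
            inherits(spec, "rf_search_spec"))
  x <- train_fingerprints$counts
  y <- diversity_targets(train_targets, rownames(x))
  n <- nrow(x)
  if (n < spec$cv_folds)
    stop_cytofp("cytofp_configuration_error",
                "%d samples cannot support %d-fold CV", n, spec$cv_folds)
  mf_range <- spec$max_features_range %||% seq_len(ncol(x))
  cand <- with_seed(child_seed(spec$seed, 0L), data.frame(
    mtry = sample(mf_range, spec$n_candidates, replace = TRUE),
    min_leaf = sample(spec$min_samples_leaf_range, spec$n_candidates,
                      replace = TRUE)))
  folds <- with_seed(child_seed(spec$seed, 1L),
                     sample(rep_len(seq_len(spec$cv_folds), n)))
  cand$cv_r2 <- vapply(seq_len(spec$n_candidates), function(ci) {
    scores <- vapply(seq_len(spec$cv_folds), function(f) {
      hold <- folds == f
      fit <- rf_fit(x[!hold, , drop = FALSE], y[!hold],
                    n_trees = spec$n_trees, mtry = cand$mtry[ci],
                    min_leaf = cand$min_leaf[ci],
                    seed = child_seed(spec$seed, 100L + ci * 31L + f))
      r_squared(y[hold], predict(fit, x[hold, , drop = FALSE]))
    }, 0)
    mean(scores)
  }, 0)
  best_i <- which.max(cand$cv_r2)
  model <- rf_fit(x, y, n_trees = spec$n_trees,
                  mtry = cand$mtry[best_i],
                  min_leaf = cand$min_leaf[best_i],
                  seed = child_seed(spec$seed, 2L))
  structure(list(model = model,
                 best = cand[best_i, , drop = FALSE],
                 cv_table = cand, spec = spec),
            class = "rf_bundle")
}

#' @export
print.rf_bundle <- function(x, ...) {
  cat(sprintf(
    "<rf_bundle> best of %d candidates: mtry = %d, min_leaf = %d (CV R2 = %.3f)\n",
    nrow(x$cv_table), x$best$mtry, x$best$min_leaf, x$best$cv_r2))
  invisible(x)
}

#' Predict diversity for new fingerprints
#'
#' @param bundle An `rf_bundle` from [fit_diversity_regressor()].
#' @param test_fingerprints A relative [count_table()] with the
#'   training columns.
#' @return A data frame `sample_id`, `value`.
#' @export
predict_diversity <- function(bundle, test_fingerprints) {
  stopifnot(inherits(bundle, "rf_bundle"),
            inherits(test_fingerprints, "count_table"))
  x <- test_fingerprints$counts
  data.frame(sample_id = rownames(x),
             value = predict(bundle$model, x))
}

# accept either a bare numeric vector or a (sample_id, value) frame
diversity_targets <- function(targets, sample_ids) {
  if (is.data.frame(targets)) {
    if (length(unique(targets$q %||% 0)) > 1L)
      stop_cytofp("cytofp_invalid_input",
                  "targets mix several q orders; filter to one")
    y <- targets$value[match(sample_ids, targets$sample_id)]
    if (anyNA(y))
      stop_cytofp("cytofp_alignment_error",
                  "targets missing for some fingerprint samples")
    y
  } else {
    if (length(targets) != length(sample_ids))
      stop_cytofp("cytofp_alignment_error",
                  "%d targets for %d samples",
                  length(targets), length(sample_ids))
    as.numeric(targets)
  }
}
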