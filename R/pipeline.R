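# Run `code` under its own seed without disturbing the caller's RNG
# stream (fold assignment happens inside optimizer fitness calls).
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stratified k-fold assignment: within each class, samples are
# shuffled and dealt round-robin into folds.
stratified_folds <- function(y, folds, seed) {
  if (folds < 2) stop("`cv_folds` must be at least 2", call. = FALSE)
  if (folds > min(table(y))) {
    stop("`cv_folds` (", folds, ") exceeds the smallest class count (",
         min(table(y)), ")", call. = FALSE)
  }
  assignment <- integer(length(y))
  local_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      assignment[idx] <- rep_len(seq_len(folds),
                                 length(idx))[sample.int(length(idx))]
    }
  })
  assignment
}

# Collapse the 0..4 Cleveland label to normal/abnormal.
binarize_class <- function(x) {
  factor(ifelse(as.numeric(as.character(x)) == 0, "normal", "abnormal"),
         levels = c("normal", "abnormal"))
}

# Cross-validated LDA error rate on the masked feature columns; pure
# matrix path, no data-frame overhead (this sits inside the optimizer
# loop).
cv_error <- function(X, y, mask, folds, assignment) {
  Xm <- X[, mask == 1, drop = FALSE]
  wrong <- 0L
  for (f in seq_len(folds)) {
    test <- assignment == f
    # stratified folds guarantee every class is present in training
    core <- lda_core(Xm[!test, , drop = FALSE], y[!test])
    scores <- Xm[test, , drop = FALSE] %*% core$projection
    pred <- nearest_centroid(scores, core$centroids)
    wrong <- wrong + sum(levels(y)[pred] != as.character(y[test]))
  }
  wrong / length(y)
}

#' Wrapper fitness of a feature mask
#'
#' The quantity the optimizer minimizes: stratified cross-validated
#' error rate of the discriminant classifier restricted to the masked
#' features, plus a sparsity penalty `gamma * popcount(mask) /
#' n_features`. The all-zeros mask (no features) returns the finite
#' worst case `1 + gamma` so the optimizer never needs a special case.
#'
#' @param mask Integer 0/1 vector over the feature columns.
#' @param data Data frame of features plus the label column.
#' @param outcome Label column name.
#' @param cv_folds Number of stratified folds (default 5).
#' @param gamma Sparsity penalty weight (default 0.01, small enough
#'   that accuracy dominates).
#' @param inner_seed Seed for the fold assignment.
#' @param collapse Collapse a 0–4 Cleveland label to normal/abnormal
#'   before scoring (default `TRUE` when the column is numeric 0–4).
#' @return A scalar fitness; smaller is better.
#' @export
wrapper_fitness <- function(mask, data, outcome = "class", cv_folds = 5,
                            gamma = 0.01, inner_seed = 1, collapse = TRUE) {
  parts <- split_features(data, outcome)
  y <- if (collapse && all(as.character(parts$y) %in% as.character(0:4))) {
    binarize_class(parts$y)
  } else {
    parts$y
  }
  n_feat <- ncol(parts$X)
  if (length(mask) != n_feat) {
    stop("mask length ", length(mask), " does not match ", n_feat,
         " feature columns", call. = FALSE)
  }
  stopifnot(all(mask %in% c(0, 1)), gamma >= 0)
  if (sum(mask) == 0) {
    return(1 + gamma)
  }
  assignment <- stratified_folds(y, cv_folds, inner_seed)
  cv_error(parts$X, y, mask, cv_folds, assignment) +
    gamma * sum(mask) / n_feat
}

#' Fit the MALO-LDA classifier with wrapper feature selection
#'
#' Runs the binary modified ant lion optimizer over feature masks,
#' scoring each candidate with [wrapper_fitness()] (cross-validated
#' discriminant error plus a sparsity penalty), then refits the
#' discriminant on the winning mask using all training rows. Fitness
#' values are memoized per mask, so the optimizer's many revisits of
#' the same subset cost nothing. Should the optimizer end on the empty
#' mask, the best nonzero mask encountered is used instead (with a
#' message).
#'
#' @param data Data frame of features plus the label column.
#' @param outcome Label column name (default `"class"`).
#' @param n_ants,max_iters Colony size and iteration budget of the
#'   optimizer.
#' @param cv_folds,gamma,inner_seed Passed to [wrapper_fitness()].
#' @param collapse Collapse 0–4 labels to normal/abnormal.
#' @param seed Master seed; drives both the optimizer and the fold
#'   assignment (via `inner_seed`, which defaults to `seed`).
#' @param ... Further arguments to [malo_config()].
#' @return An object of class `malo_lda`: the selected mask, the
#'   fitted [fisher_lda()] model on the selected features, the
#'   optimizer trace and the configuration.
#' @examples
#' \donttest{
#' d <- simulate_cleveland(n_samples = 150, n_informative = 2,
#'                         n_noise = 4, missing_rate = 0, seed = 2)
#' fit <- fit_malo_lda(d, n_ants = 8, max_iters = 10, seed = 2)
#' fit$selected_features
#' }
#' @export
fit_malo_lda <- function(data, outcome = "class", n_ants = 20,
                         max_iters = 40, cv_folds = 5, gamma = 0.01,
                         inner_seed = NULL, collapse = TRUE, seed = 1, ...) {
  parts <- split_features(data, outcome)
  if (is.null(inner_seed)) inner_seed <- seed
  feat_names <- colnames(parts$X)
  n_feat <- length(feat_names)

  y_fit <- if (collapse &&
               all(as.character(parts$y) %in% as.character(0:4))) {
    binarize_class(parts$y)
  } else {
    parts$y
  }
  assignment <- stratified_folds(y_fit, cv_folds, inner_seed)

  cache <- new.env(parent = emptyenv())
  best_nonzero <- NULL
  best_nonzero_fit <- Inf
  # same quantity as wrapper_fitness(), with folds and features
  # prepared once outside the optimizer loop
  fitness <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    f <- if (sum(mask) == 0) 1 + gamma else {
      cv_error(parts$X, y_fit, mask, cv_folds, assignment) +
        gamma * sum(mask) / n_feat
    }
    cache[[key]] <- f
    if (sum(mask) > 0 && f < best_nonzero_fit) {
      best_nonzero_fit <<- f
      best_nonzero <<- mask
    }
    f
  }

  cfg <- malo_config(n_dims = n_feat, n_ants = n_ants,
                     max_iters = max_iters, seed = seed, ...)
  res <- run_malo(fitness, cfg)
  mask <- res$best_mask
  if (sum(mask) == 0) {
    message("optimizer returned the empty mask; ",
            "falling back to the best nonzero mask seen")
    mask <- best_nonzero
  }

  sel <- feat_names[mask == 1]
  train_df <- tibble::as_tibble(as.data.frame(parts$X[, sel, drop = FALSE]))
  y <- if (collapse && all(as.character(parts$y) %in% as.character(0:4))) {
    binarize_class(parts$y)
  } else {
    parts$y
  }
  train_df$.class <- y
  lda_fit <- fisher_lda(train_df, outcome = ".class")

  structure(
    list(selected_mask = stats::setNames(as.integer(mask), feat_names),
         selected_features = sel, lda = lda_fit, malo = res,
         outcome = outcome, collapse = collapse, feature_names = feat_names,
         config = list(n_ants = n_ants, max_iters = max_iters,
                       cv_folds = cv_folds, gamma = gamma,
                       inner_seed = inner_seed, seed = seed)),
    class = "malo_lda"
  )
}

#' Predict with a fitted MALO-LDA model
#'
#' Masks the selected feature columns and delegates to the underlying
#' discriminant's nearest-centroid rule.
#'
#' @param object A `malo_lda` model from [fit_malo_lda()].
#' @param new_data Data frame (or matrix) with the original, unmasked
#'   feature columns.
#' @param ... Unused.
#' @return A factor of predicted labels.
#' @export
predict.malo_lda <- function(object, new_data, ...) {
  X <- if (is.matrix(new_data)) {
    if (ncol(new_data) != length(object$feature_names)) {
      stop("expected ", length(object$feature_names), " feature columns, got ",
           ncol(new_data), call. = FALSE)
    }
    new_data[, object$selected_mask == 1, drop = FALSE]
  } else {
    missing_cols <- setdiff(object$selected_features, names(new_data))
    if (length(missing_cols) > 0) {
      stop("new data lacks selected feature columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    as.matrix(new_data[, object$selected_features, drop = FALSE])
  }
  predict(object$lda, X)
}

#' @export
print.malo_lda <- function(x, ...) {
  cat("MALO-LDA classifier\n")
  cat("  selected", length(x$selected_features), "of",
      length(x$feature_names), "features:",
      paste(x$selected_features, collapse = ", "), "\n")
  cat("  wrapper fitness:", format(x$malo$best_fitness, digits = 4), "\n")
  invisible(x)
}

#' Tidy the selection result of a MALO-LDA fit
#'
#' @param x A `malo_lda` model.
#' @param ... Unused.
#' @return A tibble with one row per original feature: `term`,
#'   `selected`, and the LD1 `loading` (NA for unselected features).
#' @method tidy malo_lda
#' @export
tidy.malo_lda <- function(x, ...) {
  loadings <- stats::setNames(rep(NA_real_, length(x$feature_names)),
                              x$feature_names)
  loadings[rownames(x$lda$projection)] <- x$lda$projection[, 1]
  tibble::tibble(
    term = x$feature_names,
    selected = x$selected_mask == 1,
    loading = unname(loadings)
  )
}

#' One-row summary of a MALO-LDA fit
#'
#' @param x A `malo_lda` model.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance malo_lda
#' @export
glance.malo_lda <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_selected = length(x$selected_features),
    best_fitness = x$malo$best_fitness,
    evaluations = x$malo$evaluations,
    cv_folds = x$config$cv_folds,
    gamma = x$config$gamma
  )
}

#' Nested cross-validated evaluation of the MALO-LDA pipeline
#'
#' Honest evaluation with feature selection re-run inside every outer
#' training fold: for each outer fold the full [fit_malo_lda()] runs on
#' the training portion and predicts the held-out portion; pooled
#' predictions are then scored per class with the confusion-matrix
#' suite, each class taken as positive in turn.
#'
#' @param data Data frame of features plus the label column.
#' @param outcome Label column name.
#' @param outer_folds Number of outer stratified folds (at least 2).
#' @param f_variant F-score variant, see [metric_suite()].
#' @param seed Master seed (outer folds, optimizer and inner folds all
#'   derive from it).
#' @param ... Passed to [fit_malo_lda()] (`n_ants`, `max_iters`,
#'   `cv_folds`, `gamma`, ...).
#' @return A `metric_report` tibble (one row per class) with attribute
#'   `"predictions"` holding the pooled truth/estimate tibble.
#' @export
evaluate_malo_lda <- function(data, outcome = "class", outer_folds = 5,
                              f_variant = c("standard", "as_printed"),
                              seed = 1, ...) {
  f_variant <- match.arg(f_variant)
  parts <- split_features(data, outcome)
  collapse <- all(as.character(parts$y) %in% as.character(0:4))
  y <- if (collapse) binarize_class(parts$y) else parts$y
  assignment <- stratified_folds(y, outer_folds, seed = seed)

  truth <- character(length(y))
  estimate <- character(length(y))
  feature_cols <- setdiff(names(data), outcome)
  for (f in seq_len(outer_folds)) {
    test <- assignment == f
    fit <- fit_malo_lda(data[!test, , drop = FALSE], outcome = outcome,
                        collapse = collapse, seed = seed + f, ...)
    pred <- predict(fit, data[test, feature_cols, drop = FALSE])
    truth[test] <- as.character(y[test])
    estimate[test] <- as.character(pred)
  }
  report <- classification_report(truth, estimate, f_variant = f_variant)
  attr(report, "predictions") <- tibble::tibble(truth = truth,
                                                estimate = estimate)
  report
}
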