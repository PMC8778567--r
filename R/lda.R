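#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

# Pull (X, y) out of a data frame: every column except `outcome` is a
# numeric feature, `outcome` becomes a factor. Shared by the LDA and
# pipeline front ends.
split_features <- function(data, outcome) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  if (!outcome %in% names(data)) {
    stop("outcome column `", outcome, "` not found", call. = FALSE)
  }
  X <- as.matrix(dplyr::select(data, -dplyr::all_of(outcome)))
  storage.mode(X) <- "double"
  if (anyNA(X) || !all(is.finite(X))) {
    stop("feature columns contain missing or non-finite values; impute first",
         call. = FALSE)
  }
  y <- factor(data[[outcome]])
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) < 1)) stop("every class needs at least one sample",
                              call. = FALSE)
  list(X = X, y = y)
}

# Core scatter computation on a numeric matrix and factor labels.
# Within-class: sum over classes of centered cross-products; between:
# count-weighted outer products of class-mean deviations from the grand
# mean, so that between + within = total scatter about the grand mean.
scatter_core <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  grand <- colMeans(X)
  lev <- levels(y)
  within <- matrix(0, p, p)
  between <- matrix(0, p, p)
  class_means <- matrix(NA_real_, length(lev), p,
                        dimnames = list(lev, colnames(X)))
  counts <- integer(length(lev))
  for (j in seq_along(lev)) {
    Xj <- X[y == lev[j], , drop = FALSE]
    counts[j] <- nrow(Xj)
    mu <- colMeans(Xj)
    class_means[j, ] <- mu
    centered <- sweep(Xj, 2, mu)
    within <- within + crossprod(centered)
    d <- mu - grand
    between <- between + counts[j] * tcrossprod(d)
  }
  dimnames(within) <- dimnames(between) <- list(colnames(X), colnames(X))
  list(between = between, within = within, class_means = class_means,
       grand_mean = grand, counts = stats::setNames(counts, lev))
}

#' Between- and within-class scatter matrices
#'
#' Computes the two scatter matrices at the heart of Fisher discriminant
#' analysis. The within-class scatter is the sum of per-class centered
#' cross-product matrices; the between-class scatter is the
#' count-weighted sum of outer products of class-mean deviations from
#' the grand mean, so the two add up to the total scatter about the
#' grand mean.
#'
#' @param data A data frame of numeric features plus a label column.
#' @param outcome Name of the label column (default `"class"`).
#' @return An object of class `scatter_matrices`: list with `between`,
#'   `within` (symmetric PSD matrices), `class_means`, `grand_mean`
#'   and `counts`.
#' @examples
#' d <- tibble::tibble(x = c(0, 0, 4, 4), y = c(0, 2, 0, 2),
#'                     class = c(1, 1, 2, 2))
#' scatter_matrices(d)$between
#' @export
scatter_matrices <- function(data, outcome = "class") {
  parts <- split_features(data, outcome)
  out <- scatter_core(parts$X, parts$y)
  class(out) <- "scatter_matrices"
  out
}

#' Fisher criterion of a projection
#'
#' The determinant ratio `|Y' B Y| / |Y' W Y|` of projected
#' between-class to projected within-class scatter; the LDA projection
#' maximizes it. A ridge added to the within matrix guards against a
#' singular denominator.
#'
#' @param Y Projection matrix (features x directions) or a vector for a
#'   single direction.
#' @param scatter A [scatter_matrices()] object.
#' @param ridge Nonnegative ridge added to the diagonal of the
#'   within-class scatter before inverting; 0 uses it as-is.
#' @return The criterion value (a scalar).
#' @export
fisher_criterion <- function(Y, scatter, ridge = 0) {
  stopifnot(inherits(scatter, "scatter_matrices"), ridge >= 0)
  Y <- as.matrix(Y)
  W <- scatter$within + diag(ridge, nrow(scatter$within))
  denom <- det(crossprod(Y, W %*% Y))
  if (abs(denom) < .Machine$double.xmin) {
    stop("projected within-class scatter is singular (condition number ~ ",
         format(kappa(W)), "); use a positive ridge", call. = FALSE)
  }
  det(crossprod(Y, scatter$between %*% Y)) / denom
}

# Generalized symmetric eigenproblem B y = lambda (W + ridge I) y via
# Cholesky whitening of the regularized within matrix.
generalized_eigen <- function(B, W) {
  R <- chol(W)
  Rinv <- backsolve(R, diag(nrow(W)))
  A <- crossprod(Rinv, B %*% Rinv)
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  vectors <- Rinv %*% es$vectors
  list(values = es$values, vectors = vectors)
}

# Unit length, first nonzero component positive.
fix_sign <- function(v, tol = 1e-10) {
  v <- v / sqrt(sum(v^2))
  nz <- which(abs(v) > tol)
  if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
  v
}

# Matrix fast path shared by fisher_lda() and the cross-validation
# loop of the wrapper fitness: no data-frame plumbing.
lda_core <- function(X, y, ridge = NULL) {
  sc <- scatter_core(X, y)
  p <- ncol(X)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(sc$within)) / p
  W <- sc$within + diag(ridge, p)
  ge <- generalized_eigen(sc$between, W)
  rank_b <- qr(sc$between)$rank
  d <- max(1L, min(nlevels(y) - 1L, rank_b))
  keep <- seq_len(d)
  projection <- vapply(keep, function(j) fix_sign(ge$vectors[, j]),
                       numeric(p))
  projection <- matrix(projection, nrow = p,
                       dimnames = list(colnames(X), paste0("LD", keep)))
  list(projection = projection, eigenvalues = pmax(ge$values[keep], 0),
       centroids = sc$class_means %*% projection, ridge = ridge,
       scatter = sc, d = d)
}

# Nearest projected centroid; ties go to the first (lowest) class.
nearest_centroid <- function(scores, centroids) {
  d2 <- outer(rowSums(scores^2), rowSums(centroids^2), `+`) -
    2 * scores %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Fit a Fisher linear discriminant model
#'
#' Solves the generalized eigenproblem `B y = lambda (W + ridge I) y`
#' for the between- and within-class scatter of `data`, retaining the
#' `min(R - 1, rank B)` leading discriminant directions (R classes).
#' Classification is by nearest projected class centroid. Eigenvectors
#' are normalized to unit length with the first nonzero component
#' positive, and eigenvalues sorted descending, so fits are
#' reproducible.
#'
#' @param data Data frame of numeric features plus a label column.
#' @param outcome Name of the label column (default `"class"`).
#' @param ridge Ridge added to the within-class scatter; `NULL` (the
#'   default) uses `1e-6 * tr(W) / p`, which keeps ill-conditioned
#'   clinical data (correlated features) solvable without noticeably
#'   biasing the directions.
#' @return An object of class `fisher_lda` with the projection matrix,
#'   eigenvalues, projected class centroids, scatter matrices, ridge
#'   and training metadata.
#' @examples
#' d <- simulate_cleveland(n_samples = 120, seed = 1)
#' fit <- fisher_lda(d)
#' table(predict(fit, d), d$class)
#' @export
fisher_lda <- function(data, outcome = "class", ridge = NULL) {
  parts <- split_features(data, outcome)
  X <- parts$X
  y <- parts$y
  R_classes <- nlevels(y)
  if (nrow(X) <= R_classes) {
    stop("need more samples than classes", call. = FALSE)
  }
  if (!is.null(ridge) && ridge <= 0 &&
      min(eigen(scatter_core(X, y)$within, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    stop("within-class scatter is singular; provide a positive ridge",
         call. = FALSE)
  }
  core <- lda_core(X, y, ridge)
  scores <- X %*% core$projection

  structure(
    list(projection = core$projection, eigenvalues = core$eigenvalues,
         centroids = core$centroids,
         scatter = structure(core$scatter, class = "scatter_matrices"),
         ridge = core$ridge, class_levels = levels(y),
         feature_names = colnames(X), d = core$d, outcome = outcome,
         scores = tibble::as_tibble(as.data.frame(scores)) |>
           dplyr::mutate(!!outcome := y)),
    class = "fisher_lda"
  )
}

#' Project data onto the discriminant directions
#'
#' @param model A fitted [fisher_lda()] model.
#' @param data Data frame (or matrix) with the training feature columns.
#' @return A tibble of discriminant scores (columns `LD1`, ...).
#' @export
lda_project <- function(model, data) {
  stopifnot(inherits(model, "fisher_lda"))
  X <- if (is.matrix(data)) data else {
    cols <- model$feature_names
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols) > 0) {
      stop("data lacks feature columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    as.matrix(data[, cols, drop = FALSE])
  }
  if (ncol(X) != nrow(model$projection)) {
    stop("feature dimension mismatch: model expects ",
         nrow(model$projection), " columns, got ", ncol(X), call. = FALSE)
  }
  storage.mode(X) <- "double"
  tibble::as_tibble(as.data.frame(X %*% model$projection))
}

#' Predict classes from a Fisher LDA model
#'
#' Assigns each sample to the class whose projected centroid is nearest
#' in Euclidean distance; ties break toward the lowest class index.
#'
#' @param object A fitted [fisher_lda()] model.
#' @param new_data Data frame or matrix of features.
#' @param ... Unused.
#' @return A factor of predicted class labels.
#' @export
predict.fisher_lda <- function(object, new_data, ...) {
  scores <- as.matrix(lda_project(object, new_data))
  cent <- object$centroids
  d2 <- outer(rowSums(scores^2), rowSums(cent^2), `+`) -
    2 * scores %*% t(cent)
  idx <- apply(d2, 1, which.min) # which.min takes the first (lowest) index
  factor(object$class_levels[idx], levels = object$class_levels)
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat("Fisher LDA model:", length(x$class_levels), "classes,",
      nrow(x$projection), "features,", x$d, "discriminant direction(s)\n")
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  cat("  ridge:", format(x$ridge, digits = 4), "\n")
  invisible(x)
}

#' Tidy the discriminant loadings
#'
#' @param x A `fisher_lda` model.
#' @param ... Unused.
#' @return A tibble with one row per feature x direction: columns
#'   `term`, `direction`, `loading`.
#' @method tidy fisher_lda
#' @export
tidy.fisher_lda <- function(x, ...) {
  as.data.frame(x$projection) |>
    tibble::rownames_to_column("term") |>
    tidyr::pivot_longer(-"term", names_to = "direction",
                        values_to = "loading") |>
    dplyr::arrange(.data$direction, .data$term)
}

#' One-row summary of a Fisher LDA fit
#'
#' @param x A `fisher_lda` model.
#' @param ... Unused.
#' @return A one-row tibble with dimensionality, leading eigenvalue,
#'   Fisher criterion of the fitted projection, and ridge.
#' @method glance fisher_lda
#' @export
glance.fisher_lda <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$projection),
    n_classes = length(x$class_levels),
    n_directions = x$d,
    lambda_1 = x$eigenvalues[1],
    criterion = fisher_criterion(x$projection, x$scatter, ridge = x$ridge),
    ridge = x$ridge
  )
}

#' Discriminant-score plot
#'
#' One discriminant direction gives per-class density of LD1 scores;
#' two or more give an LD1 x LD2 scatter colored by class.
#'
#' @param object A `fisher_lda` model.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fisher_lda
#' @export
autoplot.fisher_lda <- function(object, ...) {
  sc <- object$scores
  cls <- rlang::sym(object$outcome)
  if (object$d == 1) {
    ggplot2::ggplot(sc, ggplot2::aes(x = .data$LD1, fill = !!cls)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::labs(title = "Discriminant scores") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(sc, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                     colour = !!cls)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(title = "Discriminant scores") +
      ggplot2::theme_minimal()
  }
}
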