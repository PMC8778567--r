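# Table-1 attribute roles used across preprocessing and simulation.
cleveland_continuous <- c("age", "trestbps", "chol", "thalach", "oldpeak")
cleveland_discrete <- c("sex", "cp", "fbs", "restecg", "exang",
                        "slope", "ca", "thal")
cleveland_attributes <- c("age", "sex", "cp", "trestbps", "chol", "fbs",
                          "restecg", "thalach", "exang", "oldpeak",
                          "slope", "ca", "thal", "class")

# Majority vote with ties broken toward the lowest value.
mode_lowest <- function(x) {
  tab <- table(x)
  vals <- suppressWarnings(as.numeric(names(tab)))
  winners <- names(tab)[tab == max(tab)]
  if (!anyNA(vals)) {
    as.numeric(min(as.numeric(winners)))
  } else {
    sort(winners)[1]
  }
}

# Band a continuous column into quintiles computed from observed values.
quintile_band <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0) return(rep(NA_integer_, length(x)))
  qs <- unique(stats::quantile(obs, probs = seq(0, 1, 0.2), names = FALSE))
  findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Fill missing Cleveland attributes from matching patients
#'
#' Each missing cell is filled from the patients who match the
#' incomplete record on age group (decade), resting blood pressure band
#' and cholesterol band (quintile bands): the majority value for
#' discrete attributes, the median for continuous ones. When no banded
#' match exists the global majority/median steps in. Observed values
#' are never altered, so the operation is idempotent.
#'
#' @param records Data frame in the Cleveland schema; `NA` marks a
#'   missing value.
#' @return A tibble with no missing attribute values.
#' @export
impute_cleveland <- function(records) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  fields <- names(records)[vapply(records, is.numeric, logical(1))]
  bands <- tibble::tibble(
    age_band = if ("age" %in% fields) records$age %/% 10 else NA_integer_,
    bps_band = if ("trestbps" %in% fields) quintile_band(records$trestbps)
               else NA_integer_,
    chol_band = if ("chol" %in% fields) quintile_band(records$chol)
                else NA_integer_
  )
  for (f in fields) {
    miss <- which(is.na(records[[f]]))
    if (length(miss) == 0) next
    if (length(miss) == nrow(records)) {
      stop("attribute `", f, "` is missing in every record", call. = FALSE)
    }
    fill_from <- function(idx) {
      cand <- !is.na(records[[f]])
      for (b in names(bands)) {
        key <- bands[[b]][idx]
        if (!is.na(key)) cand <- cand & !is.na(bands[[b]]) & bands[[b]] == key
      }
      vals <- records[[f]][cand]
      if (length(vals) == 0) vals <- records[[f]][!is.na(records[[f]])]
      if (f %in% c(cleveland_discrete, "class")) mode_lowest(vals) else
        stats::median(vals)
    }
    records[[f]][miss] <- vapply(miss, fill_from, numeric(1))
  }
  records
}

#' Remove duplicate rows and constant columns
#'
#' Redundancy here is structural: exact duplicate records carry no new
#' information and constant columns cannot discriminate anything.
#' Relevance-based pruning is deliberately left to the wrapper feature
#' selection.
#'
#' @param records A data frame.
#' @return A list with `data` (the pruned tibble) and `report` (a
#'   tibble describing what was removed: `what`, `detail`, `n`).
#' @export
remove_redundant <- function(records) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  dup <- duplicated(records)
  deduped <- records[!dup, , drop = FALSE]
  constant <- names(deduped)[vapply(deduped, function(x) {
    length(unique(x[!is.na(x)])) <= 1 && nrow(deduped) > 1
  }, logical(1))]
  report <- dplyr::bind_rows(
    tibble::tibble(what = "duplicate_rows", detail = "exact copies",
                   n = sum(dup)),
    if (length(constant) > 0) {
      tibble::tibble(what = "constant_column", detail = constant, n = 1L)
    }
  )
  list(
    data = dplyr::select(deduped, -dplyr::all_of(constant)),
    report = report
  )
}

#' Partition records by chest-pain type
#'
#' Splits patients into the four chest-pain groups: typical angina (1),
#' atypical angina (2), non-anginal pain (3) and asymptomatic (4). The
#' groups are disjoint and jointly exhaustive.
#'
#' @param records Data frame with a complete `cp` column in `{1..4}`.
#' @return A named list of four tibbles: `typical`, `atypical`,
#'   `non_anginal`, `asymptomatic`.
#' @export
separate_by_chest_pain <- function(records) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  if (!"cp" %in% names(records)) stop("`cp` column required", call. = FALSE)
  cp <- records$cp
  if (nrow(records) > 0 && (anyNA(cp) || !all(cp %in% 1:4))) {
    stop("`cp` must be complete with values in 1..4", call. = FALSE)
  }
  groups <- c(typical = 1, atypical = 2, non_anginal = 3, asymptomatic = 4)
  purrr::map(groups, function(g) records[which(cp == g), , drop = FALSE])
}

#' Min-max scale continuous columns to \[0, 1\]
#'
#' Continuous columns are affinely mapped onto \[0, 1\] using their
#' training-set minima and maxima; a constant column maps to 0. The
#' fitted scaler travels with the result (attribute `"scaler"`) so test
#' data can be transformed with [apply_scaler()] and originals
#' recovered with [invert_scaler()].
#'
#' @param records A data frame with imputed (complete) columns.
#' @param cols Columns to scale; defaults to the Cleveland continuous
#'   attributes present, or all numeric columns if none of them are.
#' @return A tibble with scaled columns and a `"scaler"` attribute.
#' @export
scale_minmax <- function(records, cols = NULL) {
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  if (is.null(cols)) {
    cols <- intersect(cleveland_continuous, names(records))
    if (length(cols) == 0) {
      cols <- names(records)[vapply(records, is.numeric, logical(1))]
    }
  }
  scaler <- tibble::tibble(
    column = cols,
    min = vapply(cols, function(cl) min(records[[cl]]), numeric(1)),
    max = vapply(cols, function(cl) max(records[[cl]]), numeric(1))
  )
  out <- apply_scaler(records, scaler, warn_clip = FALSE)
  attr(out, "scaler") <- scaler
  out
}

#' Apply a fitted min-max scaler to new data
#'
#' @param records A data frame holding the scaler's columns.
#' @param scaler A scaler tibble from [scale_minmax()].
#' @param warn_clip Warn when values fall outside the training range
#'   (they are clipped to \[0, 1\]).
#' @return The transformed tibble.
#' @export
apply_scaler <- function(records, scaler, warn_clip = TRUE) {
  records <- tibble::as_tibble(records)
  clipped <- FALSE
  for (i in seq_len(nrow(scaler))) {
    cl <- scaler$column[i]
    lo <- scaler$min[i]
    hi <- scaler$max[i]
    x <- records[[cl]]
    scaled <- if (hi == lo) rep(0, length(x)) else (x - lo) / (hi - lo)
    if (any(scaled < 0 | scaled > 1, na.rm = TRUE)) clipped <- TRUE
    records[[cl]] <- pmin(pmax(scaled, 0), 1)
  }
  if (clipped && warn_clip) {
    warning("values outside the training range were clipped to [0, 1]",
            call. = FALSE)
  }
  records
}

#' Invert a min-max scaler
#'
#' @param records Scaled data frame.
#' @param scaler A scaler tibble from [scale_minmax()].
#' @return A tibble on the original measurement scales.
#' @export
invert_scaler <- function(records, scaler) {
  records <- tibble::as_tibble(records)
  for (i in seq_len(nrow(scaler))) {
    cl <- scaler$column[i]
    records[[cl]] <- records[[cl]] * (scaler$max[i] - scaler$min[i]) +
      scaler$min[i]
  }
  records
}
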