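# Enumerated domains of the discrete Table-1 attributes, used for
# row-level validation on read.
cleveland_domains <- list(
  sex = c(0, 1), cp = 1:4, fbs = c(0, 1), restecg = 0:2,
  exang = c(0, 1), slope = 1:3, ca = 0:3, thal = c(3, 6, 7),
  class = 0:4
)

#' Canonical Cleveland attribute names
#'
#' The 14 attribute names of the Cleveland heart-disease extract, in
#' canonical column order (13 predictors plus `class`).
#'
#' @return A character vector of length 14.
#' @export
cleveland_attr_names <- function() cleveland_attributes

#' Read a Cleveland-dialect heart-disease CSV
#'
#' Parses the 14-attribute comma-separated dialect used for the UCI
#' Cleveland heart-disease extract: `"?"` marks a missing value and the
#' canonical file has no header. Headered files are auto-detected by
#' sniffing whether the first cell is numeric; pass `header` explicitly
#' for ambiguous files. Each row is validated against the attribute
#' domains (e.g. `cp` in 1–4, `class` in 0–4) and errors name the
#' offending field and row.
#'
#' @param path Path to the CSV file.
#' @param header `TRUE`, `FALSE`, or `NULL` to auto-detect.
#' @return A tibble with the 14 named attribute columns; missing
#'   values are `NA`.
#' @export
read_cleveland <- function(path, header = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (is.null(header)) {
    first_cell <- strsplit(first, ",")[[1]][1]
    header <- is.na(suppressWarnings(as.numeric(first_cell))) &&
      first_cell != "?"
  }
  raw <- utils::read.csv(path, header = header, na.strings = "?",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) != length(cleveland_attributes)) {
    stop("expected 14 columns, found ", ncol(raw), " (line 1)",
         call. = FALSE)
  }
  names(raw) <- cleveland_attributes
  offset <- if (header) 1L else 0L
  parsed <- purrr::imap(raw, function(col, nm) {
    col[col == "?"] <- NA
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric value '", col[bad[1]], "' in field `", nm,
           "` at row ", bad[1] + offset, call. = FALSE)
    }
    dom <- cleveland_domains[[nm]]
    if (!is.null(dom)) {
      viol <- which(!is.na(num) & !num %in% dom)
      if (length(viol) > 0) {
        stop("value ", num[viol[1]], " outside the domain of `", nm,
             "` at row ", viol[1] + offset, call. = FALSE)
      }
    }
    num
  })
  tibble::as_tibble(parsed)
}

#' Write records in the Cleveland CSV dialect
#'
#' Writes a headered CSV with `"?"` for missing values, so the file
#' round-trips through [read_cleveland()].
#'
#' @param records A data frame in the Cleveland schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleveland <- function(records, path) {
  out <- as.data.frame(records)
  out[] <- lapply(out, function(x) ifelse(is.na(x), "?", as.character(x)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-class metric report as CSV
#'
#' Columns are `Class, Accuracy, Precision, Recall, Specificity,
#' F-Score` in that fixed order; an undefined metric is written as the
#' literal string `NA`, never as 0.
#'
#' @param report A `metric_report` tibble (from
#'   [classification_report()] or [evaluate_malo_lda()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  out <- data.frame(
    Class = report$class,
    Accuracy = report$accuracy,
    Precision = report$precision,
    Recall = report$recall,
    Specificity = report$specificity,
    `F-Score` = report$f_score,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a metric report written by [write_report()]
#'
#' @param path Path to the CSV.
#' @return A `metric_report` tibble.
#' @export
read_report <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  out <- tibble::tibble(
    class = as.character(raw$Class),
    accuracy = raw$Accuracy,
    precision = raw$Precision,
    recall = raw$Recall,
    specificity = raw$Specificity,
    f_score = raw$`F-Score`
  )
  class(out) <- c("metric_report", class(out))
  out
}

#' Serialize a MALO-LDA model to a flat JSON artifact
#'
#' Stores everything prediction needs (mask, selected features,
#' projection, centroids, class levels, ridge) plus the run
#' configuration, as plain text. Restore with [read_malo_lda()].
#'
#' @param model A `malo_lda` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_malo_lda <- function(model, path) {
  stopifnot(inherits(model, "malo_lda"))
  obj <- list(
    type = "malo_lda",
    feature_names = model$feature_names,
    selected_mask = unname(model$selected_mask),
    selected_features = model$selected_features,
    class_levels = model$lda$class_levels,
    projection = model$lda$projection,
    centroids = model$lda$centroids,
    eigenvalues = model$lda$eigenvalues,
    ridge = model$lda$ridge,
    best_fitness = model$malo$best_fitness,
    config = model$config
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a MALO-LDA model written by [write_malo_lda()]
#'
#' The restored object supports [predict.malo_lda()]; the optimizer
#' trace is reduced to the stored best fitness.
#'
#' @param path Path to the JSON artifact.
#' @return A `malo_lda` model.
#' @export
read_malo_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "malo_lda")) {
    stop("not a malo_lda artifact: ", path, call. = FALSE)
  }
  as_mat <- function(x, nr, dn) {
    m <- if (is.matrix(x)) x else matrix(unlist(x), nrow = nr, byrow = TRUE)
    dimnames(m) <- dn
    m
  }
  ld_names <- paste0("LD", seq_along(obj$eigenvalues))
  projection <- as_mat(obj$projection, length(obj$selected_features),
                       list(obj$selected_features, ld_names))
  centroids <- as_mat(obj$centroids, length(obj$class_levels),
                      list(obj$class_levels, ld_names))
  lda <- structure(
    list(projection = projection, eigenvalues = obj$eigenvalues,
         centroids = centroids, ridge = obj$ridge,
         class_levels = obj$class_levels,
         feature_names = obj$selected_features,
         d = length(obj$eigenvalues), outcome = ".class", scores = NULL),
    class = "fisher_lda"
  )
  structure(
    list(selected_mask = stats::setNames(as.integer(obj$selected_mask),
                                         obj$feature_names),
         selected_features = obj$selected_features, lda = lda,
         malo = list(best_fitness = obj$best_fitness),
         outcome = "class", collapse = TRUE,
         feature_names = obj$feature_names, config = obj$config),
    class = "malo_lda"
  )
}
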