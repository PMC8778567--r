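# Marginal categorical distributions for the discrete Cleveland
# attributes, approximating the published attribute mix.
cleveland_marginals <- list(
  sex = list(values = c(0, 1), probs = c(0.32, 0.68)),
  cp = list(values = 1:4, probs = c(0.08, 0.17, 0.28, 0.47)),
  fbs = list(values = c(0, 1), probs = c(0.85, 0.15)),
  restecg = list(values = 0:2, probs = c(0.50, 0.01, 0.49)),
  exang = list(values = c(0, 1), probs = c(0.67, 0.33)),
  slope = list(values = 1:3, probs = c(0.46, 0.46, 0.08)),
  ca = list(values = 0:3, probs = c(0.59, 0.21, 0.13, 0.07)),
  thal = list(values = c(3, 6, 7), probs = c(0.55, 0.06, 0.39))
)

# Realistic location/scale used to place continuous features on their
# clinical measurement scales (affine, so standardized separations are
# preserved exactly).
cleveland_scales <- list(
  age = c(54, 9), trestbps = c(131, 17), chol = c(246, 52),
  thalach = c(150, 23), oldpeak = c(1.0, 1.1)
)

#' Simulate Cleveland-schema heart-disease records with planted signal
#'
#' Generates a tabular dataset shaped like the 14-attribute Cleveland
#' heart-disease extract, with a known ground truth for benchmarking
#' feature selection. Informative features are continuous with a
#' standardized class-mean gap `effect_size` (unit variance before
#' rescaling to clinical units); noise features are class-independent —
#' continuous Gaussians or categorical draws matching the published
#' attribute mix. Missing values are injected completely at random.
#'
#' Feature naming follows the Cleveland attribute order: informative
#' features take the continuous attribute names first (`age`,
#' `trestbps`, `chol`, `thalach`, `oldpeak`), noise features the
#' remaining attribute names, and features beyond the 13 predictors are
#' numbered `x14`, `x15`, ... The label column `class` is 0 for normal
#' and 1–4 for increasing disease severity.
#'
#' @param n_samples Number of records.
#' @param n_informative Number of class-informative features.
#' @param n_noise Number of class-independent features.
#' @param effect_size Standardized class-mean gap on each informative
#'   feature.
#' @param missing_rate Per-cell probability of a missing feature value
#'   (completely at random); the 5% default leaves enough complete
#'   records for banded imputation.
#' @param class_balance Proportion of abnormal (diseased) records.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A tibble with the feature columns and `class`, carrying
#'   attributes `informative` (character vector of informative feature
#'   names) and `truth_mask` (0/1 vector over the feature columns).
#' @examples
#' d <- simulate_cleveland(n_samples = 100, missing_rate = 0, seed = 7)
#' attr(d, "informative")
#' @export
simulate_cleveland <- function(n_samples = 400, n_informative = 4,
                               n_noise = 10, effect_size = 2,
                               missing_rate = 0.05, class_balance = 0.5,
                               seed = 1) {
  stopifnot(
    n_samples >= 2, n_informative >= 0, n_noise >= 0,
    n_informative + n_noise >= 1, effect_size >= 0,
    missing_rate >= 0, missing_rate < 1,
    class_balance > 0, class_balance < 1
  )
  set.seed(seed)
  n_feat <- n_informative + n_noise

  cont_names <- names(cleveland_scales)
  disc_names <- names(cleveland_marginals)
  informative <- c(cont_names, paste0("x", 14:99))[seq_len(n_informative)]
  remaining <- c(setdiff(c(cont_names, disc_names), informative),
                 paste0("x", 14:99))
  remaining <- setdiff(remaining, informative)
  noise <- remaining[seq_len(n_noise)]
  feat_names <- c(informative, noise)

  abnormal <- stats::rbinom(n_samples, 1, class_balance)
  # severity 1..4 follows the published class mix among diseased records
  severity <- sample(1:4, n_samples, replace = TRUE,
                     prob = c(55, 36, 35, 13))
  class_lab <- ifelse(abnormal == 1, severity, 0)

  draw_feature <- function(name, is_informative) {
    if (is_informative) {
      z <- stats::rnorm(n_samples,
                        mean = (abnormal - 0.5) * effect_size)
    } else if (name %in% disc_names) {
      m <- cleveland_marginals[[name]]
      return(sample(m$values, n_samples, replace = TRUE, prob = m$probs))
    } else {
      z <- stats::rnorm(n_samples)
    }
    if (name %in% cont_names) {
      sc <- cleveland_scales[[name]]
      sc[1] + sc[2] * z
    } else {
      z
    }
  }

  cols <- purrr::map(seq_along(feat_names), function(i) {
    draw_feature(feat_names[i], i <= n_informative)
  })
  names(cols) <- feat_names
  data <- tibble::as_tibble(cols)

  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n_samples * n_feat) < missing_rate,
                   nrow = n_samples)
    for (j in seq_len(n_feat)) {
      data[[j]][mask[, j]] <- NA
    }
  }
  data$class <- class_lab
  attr(data, "informative") <- informative
  attr(data, "truth_mask") <- as.integer(feat_names %in% informative)
  data
}

#' Simulate a stream of vital-sign samples with injected abnormalities
#'
#' Draws each sample's signals from inside the normal clinical bands,
#' then injects abnormalities at the requested per-flag rates by
#' sampling outside the relevant band. Generator bands and the
#' screening-rule bands coincide by construction, so the rules recover
#' the injected truth exactly. Bradycardia/tachycardia (and the blood
#' pressure states) are mutually exclusive, so their rates are treated
#' as one categorical draw; the other flags are independent.
#'
#' @param n_samples Number of samples.
#' @param rates Named list/vector of injection rates in \[0, 1\] for
#'   `bradycardia`, `tachycardia`, `arrhythmia`, `av_block`, `fever`,
#'   `elevated_bp`, `stage1_hypertension`, `hypoxemia`; omitted flags
#'   default to 0.
#' @param seed Integer seed.
#' @return A tibble of vitals columns plus logical `truth_<flag>`
#'   columns and `truth_overall` (`"normal"`/`"abnormal"`).
#' @examples
#' v <- simulate_vitals(50, rates = list(hypoxemia = 0.2), seed = 3)
#' table(screen_vitals(v)$overall, v$truth_overall)
#' @export
simulate_vitals <- function(n_samples,
                            rates = list(),
                            seed = 1) {
  all_flags <- c("bradycardia", "tachycardia", "arrhythmia", "av_block",
                 "fever", "elevated_bp", "stage1_hypertension", "hypoxemia")
  r <- stats::setNames(rep(0, length(all_flags)), all_flags)
  rates <- unlist(rates)
  if (length(rates) > 0) {
    bad <- setdiff(names(rates), all_flags)
    if (length(bad) > 0) {
      stop("unknown flag rate(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    r[names(rates)] <- rates
  }
  if (any(r < 0 | r > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (r["bradycardia"] + r["tachycardia"] > 1 ||
      r["elevated_bp"] + r["stage1_hypertension"] > 1) {
    stop("mutually exclusive flag rates must not sum above 1",
         call. = FALSE)
  }
  stopifnot(n_samples >= 1)
  set.seed(seed)

  runifv <- function(lo, hi) stats::runif(n_samples, lo, hi)
  hr_state <- sample(c("bradycardia", "tachycardia", "normal"), n_samples,
                     replace = TRUE,
                     prob = c(r["bradycardia"], r["tachycardia"],
                              1 - r["bradycardia"] - r["tachycardia"]))
  heart_rate <- dplyr::case_when(
    hr_state == "bradycardia" ~ runifv(40, 59.5),
    hr_state == "tachycardia" ~ runifv(100.5, 160),
    TRUE ~ runifv(60, 100)
  )
  bp_state <- sample(c("elevated_bp", "stage1_hypertension", "normal"),
                     n_samples, replace = TRUE,
                     prob = c(r["elevated_bp"], r["stage1_hypertension"],
                              1 - r["elevated_bp"] -
                                r["stage1_hypertension"]))
  systolic <- dplyr::case_when(
    bp_state == "elevated_bp" ~ runifv(120, 129.4),
    bp_state == "stage1_hypertension" ~ runifv(130, 139),
    TRUE ~ runifv(100, 119.4)
  )
  diastolic <- dplyr::case_when(
    bp_state == "stage1_hypertension" ~ runifv(80, 89),
    TRUE ~ runifv(60, 79.4)
  )
  fever <- stats::runif(n_samples) < r["fever"]
  temperature <- ifelse(fever, runifv(100.5, 103.5), runifv(97.5, 100.3))
  hypox <- stats::runif(n_samples) < r["hypoxemia"]
  spo2 <- ifelse(hypox, runifv(86, 94.4), runifv(95, 100))
  av_block <- stats::runif(n_samples) < r["av_block"]
  pr_interval <- ifelse(av_block, runifv(0.21, 0.32), runifv(0.12, 0.2))
  arrhythmia <- stats::runif(n_samples) < r["arrhythmia"]

  truth <- tibble::tibble(
    truth_bradycardia = hr_state == "bradycardia",
    truth_tachycardia = hr_state == "tachycardia",
    truth_arrhythmia = arrhythmia,
    truth_av_block = av_block,
    truth_fever = fever,
    truth_elevated_bp = bp_state == "elevated_bp",
    truth_stage1_hypertension = bp_state == "stage1_hypertension",
    truth_hypoxemia = hypox
  )
  dplyr::bind_cols(
    tibble::tibble(
      heart_rate = heart_rate, systolic = systolic, diastolic = diastolic,
      temperature = temperature, spo2 = spo2, pr_interval = pr_interval,
      rhythm_regular = !arrhythmia
    ),
    truth,
    tibble::tibble(
      truth_overall = ifelse(rowSums(truth) > 0, "abnormal", "normal")
    )
  )
}
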