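#' Heart-rate and rhythm screening rules
#'
#' Resting heart rate outside 60–100 bpm flags bradycardia (< 60) or
#' tachycardia (> 100); the 60 and 100 boundaries are normal. An
#' irregular rhythm flags arrhythmia, and a PR interval above 0.2 s
#' flags atrioventricular block.
#'
#' @param heart_rate Beats per minute (required).
#' @param pr_interval PR interval in seconds, or `NA` if unmeasured.
#' @param rhythm_regular Logical, or `NA` if unmeasured.
#' @return Character vector of flags (possibly empty).
#' @examples
#' screen_heart(55)               # bradycardia
#' screen_heart(80, pr_interval = 0.25) # av_block
#' @export
screen_heart <- function(heart_rate, pr_interval = NA_real_,
                         rhythm_regular = NA) {
  if (is.na(heart_rate)) stop("`heart_rate` is required", call. = FALSE)
  if (heart_rate <= 0 || heart_rate >= 300) {
    stop("heart rate ", heart_rate, " bpm is outside the physiologic range",
         call. = FALSE)
  }
  flags <- character(0)
  if (heart_rate < 60) flags <- c(flags, "bradycardia")
  if (heart_rate > 100) flags <- c(flags, "tachycardia")
  if (isFALSE(rhythm_regular)) flags <- c(flags, "arrhythmia")
  if (!is.na(pr_interval) && pr_interval > 0.2) flags <- c(flags, "av_block")
  flags
}

#' Body-temperature screening rule
#'
#' Flags fever strictly above 100.4 degrees Fahrenheit; 100.4 itself is
#' not flagged.
#'
#' @param temperature Degrees Fahrenheit.
#' @return Character vector of flags.
#' @export
screen_temperature <- function(temperature) {
  if (is.na(temperature)) stop("`temperature` is required", call. = FALSE)
  if (temperature <= 80 || temperature >= 115) {
    stop("temperature ", temperature,
         " °F is outside the physiologic range", call. = FALSE)
  }
  if (temperature > 100.4) "fever" else character(0)
}

#' Blood-pressure screening rules
#'
#' Normal is systolic < 120 and diastolic < 80 mmHg. Elevated blood
#' pressure is systolic 120–129 with diastolic still < 80. Stage-1
#' hypertension (or higher) is flagged whenever systolic reaches 130 or
#' diastolic reaches 80.
#'
#' @param systolic,diastolic Pressures in mmHg.
#' @return Character vector of flags.
#' @export
screen_bp <- function(systolic, diastolic) {
  if (is.na(systolic) || is.na(diastolic)) {
    stop("both `systolic` and `diastolic` are required", call. = FALSE)
  }
  if (systolic <= 0 || systolic >= 300 || diastolic <= 0 || diastolic >= 200) {
    stop("blood pressure ", systolic, "/", diastolic,
         " mmHg is outside the physiologic range", call. = FALSE)
  }
  flags <- character(0)
  if (systolic >= 130 || diastolic >= 80) {
    flags <- c(flags, "stage1_hypertension")
  } else if (systolic >= 120) {
    flags <- c(flags, "elevated_bp")
  }
  flags
}

#' Oxygen-saturation screening rule
#'
#' Flags hypoxemia below 95 percent; 95 itself is in the normal band.
#'
#' @param spo2 Peripheral oxygen saturation in percent.
#' @return Character vector of flags.
#' @export
screen_spo2 <- function(spo2) {
  if (is.na(spo2)) stop("`spo2` is required", call. = FALSE)
  if (spo2 < 0 || spo2 > 100) {
    stop("SpO2 ", spo2, "% is outside [0, 100]", call. = FALSE)
  }
  if (spo2 < 95) "hypoxemia" else character(0)
}

# Screen one sample; values may be NA (signal absent).
screen_one <- function(heart_rate, systolic, diastolic, temperature,
                       spo2, pr_interval, rhythm_regular) {
  present <- c(!is.na(heart_rate), !is.na(systolic) && !is.na(diastolic),
               !is.na(temperature), !is.na(spo2))
  if (!any(present)) {
    stop("a vitals sample must carry at least one signal", call. = FALSE)
  }
  flags <- character(0)
  if (!is.na(heart_rate)) {
    flags <- c(flags, screen_heart(heart_rate, pr_interval, rhythm_regular))
  }
  if (!is.na(systolic) && !is.na(diastolic)) {
    flags <- c(flags, screen_bp(systolic, diastolic))
  }
  if (!is.na(temperature)) flags <- c(flags, screen_temperature(temperature))
  if (!is.na(spo2)) flags <- c(flags, screen_spo2(spo2))
  sort(unique(flags))
}

#' Screen a table of vital-sign samples
#'
#' Applies every per-signal rule ([screen_heart()], [screen_bp()],
#' [screen_temperature()], [screen_spo2()]) to each row and unions the
#' flags. A sample is `abnormal` exactly when at least one flag fires.
#' Missing columns or `NA` cells simply skip that signal's rules, but
#' each row must carry at least one signal.
#'
#' @param data Data frame with any of the columns `heart_rate` (bpm),
#'   `systolic`/`diastolic` (mmHg), `temperature` (Fahrenheit), `spo2`
#'   (percent), `pr_interval` (seconds), `rhythm_regular` (logical).
#' @return The input as a tibble plus `findings` (list-column of
#'   sorted flag vectors) and `overall` (`"normal"`/`"abnormal"`).
#' @examples
#' screen_vitals(tibble::tibble(heart_rate = c(72, 55), systolic = 118,
#'                              diastolic = 76, temperature = 98.6,
#'                              spo2 = 98))
#' @export
screen_vitals <- function(data) {
  stopifnot(is.data.frame(data))
  col <- function(name, default) {
    if (name %in% names(data)) data[[name]] else rep(default, nrow(data))
  }
  findings <- purrr::pmap(
    list(col("heart_rate", NA_real_), col("systolic", NA_real_),
         col("diastolic", NA_real_), col("temperature", NA_real_),
         col("spo2", NA_real_), col("pr_interval", NA_real_),
         col("rhythm_regular", NA)),
    screen_one
  )
  tibble::as_tibble(data) |>
    dplyr::mutate(
      findings = findings,
      overall = ifelse(lengths(findings) > 0, "abnormal", "normal")
    )
}
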