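#' IIDR programming settings
#'
#' An instantaneous input dynamic range (IIDR) setting maps the acoustic
#' levels between T-SPL and C-SPL onto the implant's electrical output
#' range. The study presets are `default` (T-SPL/C-SPL 25/65 dB, width
#' 40 dB) and `wide` (25/80 dB, width 55 dB).
#'
#' @param label One of `"default"` or `"wide"` for [iidr_preset()], or any
#'   label for a custom [iidr_setting()].
#' @param t_spl Acoustic level (dB SPL) mapped to the electrical threshold
#'   (T) level.
#' @param c_spl Acoustic level (dB SPL) mapped to the loud-but-comfortable
#'   (C) level. Must exceed `t_spl`.
#' @return An object of class `iidr_setting` with fields `label`, `t_spl`,
#'   `c_spl`.
#' @examples
#' iidr_width(iidr_preset("default"))  # 40
#' iidr_width(iidr_preset("wide"))     # 55
#' @export
iidr_setting <- function(label, t_spl, c_spl) {
  stopifnot(is.character(label), length(label) == 1L)
  t_spl <- as.numeric(t_spl)
  c_spl <- as.numeric(c_spl)
  if (!is.finite(t_spl) || !is.finite(c_spl)) {
    stop("t_spl and c_spl must be finite sound pressure levels (dB SPL)")
  }
  if (c_spl <= t_spl) {
    stop("invalid IIDR setting: c_spl (", c_spl,
         ") must exceed t_spl (", t_spl, ")")
  }
  structure(list(label = label, t_spl = t_spl, c_spl = c_spl),
            class = "iidr_setting")
}

#' @rdname iidr_setting
#' @export
iidr_preset <- function(label = c("default", "wide")) {
  label <- match.arg(label)
  switch(label,
         default = iidr_setting("default", 25, 65),
         wide    = iidr_setting("wide", 25, 80))
}

#' @rdname iidr_setting
#' @param setting An `iidr_setting`.
#' @export
iidr_width <- function(setting) {
  stopifnot(inherits(setting, "iidr_setting"))
  setting$c_spl - setting$t_spl
}

#' @export
print.iidr_setting <- function(x, ...) {
  cat(sprintf("IIDR setting '%s': T-SPL/C-SPL %g/%g dB (width %g dB)\n",
              x$label, x$t_spl, x$c_spl, iidr_width(x)))
  invisible(x)
}

# Item counts per speech material: 25-word lists; 15-sentence lists scored
# over 60 morphemes.
MATERIALS <- c(word = 25L, sentence = 60L)
GROUPS <- c("preCSPL65", "preCSPL80")
IIDR_LABELS <- c("default", "wide")
NOISE_SNR_DB <- 10

#' Expected item count for a speech material
#'
#' @param material `"word"` (25 scored words) or `"sentence"` (60 scored
#'   morphemes across 15 sentences).
#' @return Integer item count.
#' @export
items_per_list <- function(material) {
  material <- match.arg(material, names(MATERIALS), several.ok = TRUE)
  unname(MATERIALS[material])
}

#' A speech test condition
#'
#' A condition is one cell of the test matrix: material (word or sentence
#' list) crossed with environment (quiet, or speech-weighted noise at
#' +10 dB SNR) and presentation level (65 or 80 dB SPL). The IIDR setting
#' under which the list was administered is tracked separately via the
#' `iidr` column of a cohort table.
#'
#' @param material `"word"` or `"sentence"`.
#' @param environment `"quiet"` or `"noise"`.
#' @param level_db_spl Presentation level in dB SPL (65 or 80 for the study
#'   presets).
#' @param snr_db Signal-to-noise ratio in dB; required in noise (study
#'   preset +10), must be `NA` in quiet.
#' @return A one-row data frame of class `test_condition`.
#' @export
test_condition <- function(material, environment, level_db_spl,
                           snr_db = if (environment == "noise") NOISE_SNR_DB else NA_real_) {
  material <- match.arg(material, names(MATERIALS))
  environment <- match.arg(environment, c("quiet", "noise"))
  if (environment == "quiet" && !is.na(snr_db)) {
    stop("snr_db must be absent (NA) in quiet conditions")
  }
  if (environment == "noise" && is.na(snr_db)) {
    stop("snr_db is required in noise conditions")
  }
  out <- data.frame(material = material, environment = environment,
                    snr_db = as.numeric(snr_db),
                    level_db_spl = as.numeric(level_db_spl),
                    stringsAsFactors = FALSE)
  class(out) <- c("test_condition", class(out))
  out
}

#' The eight study test conditions
#'
#' Word and sentence lists, in quiet and in +10 dB SNR noise, presented at
#' the conversational (65 dB SPL) and loud (80 dB SPL) speech levels.
#'
#' @return A data frame with columns `material`, `environment`, `snr_db`,
#'   `level_db_spl`; 8 rows.
#' @export
study_conditions <- function() {
  grid <- expand.grid(material = names(MATERIALS),
                      environment = c("quiet", "noise"),
                      level_db_spl = c(65, 80),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$snr_db <- ifelse(grid$environment == "noise", NOISE_SNR_DB, NA_real_)
  grid[order(grid$level_db_spl, grid$material, grid$environment),
       c("material", "environment", "snr_db", "level_db_spl")]
}

# Stable single-string key for a condition cell (used for seed streams and
# joins); row-wise over equal-length vectors.
condition_key <- function(material, environment, level_db_spl,
                          iidr = NULL) {
  key <- paste(material, environment, level_db_spl, sep = ":")
  if (!is.null(iidr)) key <- paste(key, iidr, sep = ":")
  key
}
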