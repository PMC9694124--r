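#' Generator configuration for synthetic cohorts
#'
#' The generator emulates the study design: two preference groups of
#' unilateral CI users (preCSPL65 n = 5, preCSPL80 n = 6), each subject
#' tested under both IIDR settings in all eight conditions, with word
#' lists of 25 binary items and sentence lists of 60 binary morpheme
#' items. Items are independent Bernoulli draws; between-subject
#' heterogeneity is a logit-normal subject effect shared across cells.
#'
#' @param n_per_group Named integer vector: subjects per group.
#' @param accuracy Data frame with columns `group`, `material`,
#'   `environment`, `level_db_spl`, `iidr`, `p`: the base success
#'   probability of each group-by-cell combination, in \[0, 1\].
#' @param subject_sd Standard deviation (logit scale, >= 0) of the
#'   per-subject effect added to every cell's base logit. Base
#'   probabilities of exactly 0 or 1 bypass the logit transform.
#' @param seed Integer seed; the single source of randomness.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_group, accuracy, subject_sd = 0.2,
                             seed = 1L) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) >= 1L,
            !is.null(names(n_per_group)), all(n_per_group >= 1))
  accuracy <- as.data.frame(accuracy)
  needed <- c("group", "material", "environment", "level_db_spl", "iidr", "p")
  if (!all(needed %in% names(accuracy))) {
    stop("accuracy table must have columns: ", paste(needed, collapse = ", "))
  }
  if (any(accuracy$p < 0 | accuracy$p > 1)) {
    stop("base probabilities must lie in [0, 1]")
  }
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (!all(names(n_per_group) %in% accuracy$group)) {
    stop("every group needs rows in the accuracy table")
  }
  structure(list(n_per_group = n_per_group,
                 accuracy = accuracy,
                 subject_sd = as.numeric(subject_sd),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' The study calibration preset
#'
#' Loads the bundled calibration table: per-group, per-condition,
#' per-IIDR mean percent scores as published for the two preference
#' groups, divided by 100 to give Bernoulli success probabilities
#' (e.g. preCSPL65 words-in-noise at 65 dB: 0.704 under the default
#' IIDR, 0.776 under the wide IIDR; preCSPL80 words-in-noise at 80 dB:
#' 0.007 and 0.313). Group sizes are preCSPL65 = 5, preCSPL80 = 6.
#'
#' @param seed Integer seed for [generate_cohort()].
#' @param subject_sd Logit-scale between-subject SD (default 0.2).
#' @return A [generator_config()].
#' @export
study_preset <- function(seed = 1L, subject_sd = 0.2) {
  path <- system.file("extdata", "study_preset.json", package = "iidrperm",
                      mustWork = TRUE)
  preset <- jsonlite::fromJSON(path)
  cfg <- generator_config(
    n_per_group = unlist(preset$n_per_group),
    accuracy = preset$accuracy,
    subject_sd = subject_sd,
    seed = seed)
  cfg
}

#' Draw one list of binary item outcomes
#'
#' `n_items` independent Bernoulli(p) draws using the current RNG state.
#'
#' @param p Success probability in \[0, 1\].
#' @param n_items Positive item count (25 words or 60 morphemes for the
#'   study lists).
#' @return Integer vector of 0/1 of length `n_items`.
#' @export
generate_item_responses <- function(p, n_items) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]")
  }
  if (n_items < 1) stop("n_items must be positive")
  stats::rbinom(n_items, 1L, p)
}

# Deterministic sub-seed from a base seed and a character tag, so each
# subject effect and each subject-by-cell list has its own stream: adding
# a condition or subject never perturbs other cells' draws.
derive_seed <- function(seed, tag) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 69069 + code) %% 2147483647
  }
  as.integer(h)
}

#' Generate a synthetic cohort
#'
#' For each subject s of group g, a subject effect u_s ~ Normal(0,
#' subject_sd) on the logit scale is drawn once; the effective success
#' probability of each cell is `plogis(qlogis(p) + u_s)`, except that base
#' probabilities of exactly 0 or 1 are kept as-is (floor and ceiling cells
#' stay degenerate). Item responses are then independent Bernoulli draws.
#' Each subject effect and each subject-by-cell list uses a private RNG
#' stream derived from the config seed, so generation is bitwise
#' reproducible and cells are mutually independent.
#'
#' @param config A [generator_config()].
#' @return A validated [as_cohort()] cohort, fully crossed over the cells
#'   in the accuracy table.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config must be a generator_config")
  }
  acc <- config$accuracy
  rows <- vector("list", 0L)
  subject_no <- 0L
  for (g in names(config$n_per_group)) {
    acc_g <- acc[acc$group == g, , drop = FALSE]
    if (nrow(acc_g) == 0L) stop("no accuracy rows for group ", g)
    for (i in seq_len(config$n_per_group[[g]])) {
      subject_no <- subject_no + 1L
      sid <- sprintf("S%02d", subject_no)
      set.seed(derive_seed(config$seed, paste0("subject-effect|", sid)))
      u <- if (config$subject_sd > 0) {
        stats::rnorm(1L, 0, config$subject_sd)
      } else 0
      for (r in seq_len(nrow(acc_g))) {
        cell <- acc_g[r, ]
        p_base <- cell$p
        p_eff <- if (p_base <= 0 || p_base >= 1) p_base else {
          stats::plogis(stats::qlogis(p_base) + u)
        }
        n_items <- MATERIALS[[cell$material]]
        key <- condition_key(cell$material, cell$environment,
                             cell$level_db_spl, cell$iidr)
        set.seed(derive_seed(config$seed, paste0("items|", sid, "|", key)))
        resp <- generate_item_responses(p_eff, n_items)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g,
          material = cell$material, environment = cell$environment,
          snr_db = if (cell$environment == "noise") NOISE_SNR_DB else NA_real_,
          level_db_spl = cell$level_db_spl, iidr = cell$iidr,
          item_index = seq_len(n_items) - 1L, correct = resp,
          stringsAsFactors = FALSE)
      }
    }
  }
  as_cohort(do.call(rbind, rows))
}
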