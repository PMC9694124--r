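#' The default comparison matrix
#'
#' All comparisons the study runs over a fully crossed cohort:
#' within-IIDR comparisons (default vs wide) for each of the 8 conditions
#' in 3 groupings (all subjects, preCSPL65, preCSPL80) — 24 tests — and
#' between-group comparisons (preCSPL65 vs preCSPL80) for each condition
#' at each fixed IIDR — 16 tests; 40 rows total.
#'
#' @return Data frame with columns `comparison`, `axis`, `grouping`,
#'   `fixed_iidr`, `material`, `environment`, `level_db_spl`.
#' @export
comparison_matrix <- function() {
  conds <- study_conditions()
  within <- do.call(rbind, lapply(c("all", GROUPS), function(g) {
    data.frame(axis = "within_iidr", grouping = g, fixed_iidr = NA_character_,
               conds[c("material", "environment", "level_db_spl")],
               stringsAsFactors = FALSE)
  }))
  between <- do.call(rbind, lapply(IIDR_LABELS, function(s) {
    data.frame(axis = "between_group", grouping = "all", fixed_iidr = s,
               conds[c("material", "environment", "level_db_spl")],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(within, between)
  out$comparison <- ifelse(
    out$axis == "within_iidr",
    paste("within", out$grouping,
          condition_key(out$material, out$environment, out$level_db_spl),
          sep = ":"),
    paste("between", out$fixed_iidr,
          condition_key(out$material, out$environment, out$level_db_spl),
          sep = ":"))
  rownames(out) <- NULL
  out[c("comparison", "axis", "grouping", "fixed_iidr", "material",
        "environment", "level_db_spl")]
}

#' Per-condition mean percent scores
#'
#' The unweighted mean over the selected subjects of each subject's
#' percent score, for every condition-by-IIDR cell.
#'
#' @param cohort A cohort.
#' @param grouping `"all"` or a group label.
#' @return Data frame with one row per (material, environment,
#'   level_db_spl, iidr) and columns `n_subjects`, `mean_score`.
#' @export
summarize_means <- function(cohort, grouping = "all") {
  scores <- cohort_scores(cohort)
  if (grouping != "all") scores <- scores[scores$group == grouping, ]
  if (nrow(scores) == 0L) stop("empty selection: grouping ", grouping)
  agg <- stats::aggregate(
    score ~ material + environment + level_db_spl + iidr,
    data = scores, FUN = mean)
  cnt <- stats::aggregate(
    score ~ material + environment + level_db_spl + iidr,
    data = scores, FUN = length)
  agg$n_subjects <- cnt$score
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg <- agg[order(agg$level_db_spl, agg$material, agg$environment,
                   agg$iidr, method = "radix"), ]
  rownames(agg) <- NULL
  agg
}

#' Run the full study comparison matrix
#'
#' Executes every comparison of [comparison_matrix()] on a cohort: pools
#' the item outcomes of each cell with [pool_cell()] and tests the mean
#' difference with [mc_permutation_test()]. Each comparison runs on its
#' own RNG stream derived from `seed` and the comparison label, so the
#' report is bitwise reproducible and insensitive to row order.
#'
#' Within-IIDR comparisons use `alternative` (default `"greater"`, i.e.
#' wide improves on default); between-group comparisons use
#' `between_alternative` (default `"two_sided"`, since the group contrast
#' has no a-priori direction under the permutation null).
#'
#' @param cohort A fully crossed cohort holding all 16 cells per subject.
#' @param n_resamples Resamples per test (study default 100,000).
#' @param seed Integer seed.
#' @param alternative Sidedness for within-IIDR tests.
#' @param between_alternative Sidedness for between-group tests.
#' @return A `study_report` data frame: one row per comparison with
#'   `mean_a`, `mean_b` (percent), `observed_diff` (percentage points),
#'   `p_value`, significance flags at 0.05 and 0.01 (strict `<`),
#'   `n_resamples` and `seed`.
#' @export
run_study <- function(cohort, n_resamples = 100000L, seed = 1L,
                      alternative = "greater",
                      between_alternative = "two_sided") {
  cohort <- as_cohort(cohort)
  required <- study_conditions()
  have <- unique(condition_key(cohort$material, cohort$environment,
                               cohort$level_db_spl, cohort$iidr))
  want <- as.vector(outer(
    condition_key(required$material, required$environment,
                  required$level_db_spl),
    IIDR_LABELS, paste, sep = ":"))
  missing_cells <- setdiff(want, have)
  if (length(missing_cells)) {
    stop("cohort is missing cell(s): ", paste(missing_cells, collapse = ", "))
  }

  matrix_df <- comparison_matrix()
  rows <- lapply(seq_len(nrow(matrix_df)), function(i) {
    cmp <- matrix_df[i, ]
    sides <- pool_cell(cohort, cmp$material, cmp$environment,
                       cmp$level_db_spl, axis = cmp$axis,
                       grouping = cmp$grouping, fixed_iidr = cmp$fixed_iidr)
    alt <- if (cmp$axis == "within_iidr") alternative else between_alternative
    res <- mc_permutation_test(sides$a, sides$b, n_resamples = n_resamples,
                               seed = derive_seed(seed, cmp$comparison),
                               alternative = alt)
    data.frame(cmp,
               mean_a = 100 * mean(sides$a),
               mean_b = 100 * mean(sides$b),
               observed_diff = res$observed_statistic,
               p_value = res$p_value,
               sig_05 = res$p_value < 0.05,
               sig_01 = res$p_value < 0.01,
               alternative = alt,
               n_resamples = res$n_resamples,
               seed = res$seed,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "base_seed") <- as.integer(seed)
  class(report) <- c("study_report", "data.frame")
  report
}

#' Significance pattern of a study report
#'
#' Which comparisons reject at `alpha` (strict `p < alpha`, matching the
#' convention of reporting "p < 0.05" / "p < 0.01"). Optionally diffs the
#' observed pattern against an expected one, e.g. the published pattern,
#' for calibration checks.
#'
#' @param report A [run_study()] report.
#' @param alpha Significance threshold.
#' @param expected Optional named logical vector keyed by `comparison`
#'   label; comparisons absent from `expected` are ignored in the diff.
#' @return Data frame with `comparison`, `p_value`, `significant`, and —
#'   when `expected` is given — `expected` and `match` columns.
#' @export
significance_pattern <- function(report, alpha = 0.05, expected = NULL) {
  out <- data.frame(comparison = report$comparison,
                    p_value = report$p_value,
                    significant = report$p_value < alpha,
                    stringsAsFactors = FALSE)
  if (!is.null(expected)) {
    out <- out[out$comparison %in% names(expected), , drop = FALSE]
    out$expected <- unname(expected[out$comparison])
    out$match <- out$significant == out$expected
    rownames(out) <- NULL
  }
  out
}

#' Published significance pattern for the all-subjects within-IIDR tests
#'
#' The reported outcome of the wide-vs-default comparisons over all 11
#' subjects: significant improvement in every condition except sentences
#' in quiet at 65 dB SPL. Used to check that calibrated synthetic cohorts
#' reproduce the qualitative result.
#'
#' @param alpha Threshold the pattern refers to (0.05).
#' @return Named logical vector keyed by comparison label.
#' @export
expected_pattern_all_subjects <- function(alpha = 0.05) {
  conds <- study_conditions()
  key <- paste("within", "all",
               condition_key(conds$material, conds$environment,
                             conds$level_db_spl), sep = ":")
  expected <- rep(TRUE, length(key))
  names(expected) <- key
  expected[key == "within:all:sentence:quiet:65"] <- FALSE
  expected
}
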