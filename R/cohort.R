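#' Cohorts of item-level speech test responses
#'
#' A cohort is a long-format table with one row per scored item: columns
#' `subject_id`, `group` (`preCSPL65` or `preCSPL80`), `material`,
#' `environment`, `snr_db`, `level_db_spl`, `iidr` (`default` or `wide`),
#' `item_index` (0-based, purely positional) and `correct` (0/1). Item
#' granularity is canonical because the permutation test resamples at item
#' level; per-subject percent scores are always derived, never stored.
#'
#' `as_cohort()` validates a data frame and returns it in canonical row
#' order with class `iidr_cohort`. Validation enforces: all columns
#' present; `correct` strictly binary (violations reported with row
#' numbers); one group label per subject; and, within every
#' subject-by-condition-by-IIDR cell, a contiguous 0-based `item_index`
#' run of exactly 25 items (words) or 60 items (sentence morphemes).
#' Every subject must hold the same set of cells (a fully crossed design
#' over the cells the cohort contains).
#'
#' @param x A data frame in the long format above.
#' @return `x`, row-ordered canonically, with class `iidr_cohort`.
#' @export
as_cohort <- function(x) {
  required <- c("subject_id", "group", "material", "environment", "snr_db",
                "level_db_spl", "iidr", "item_index", "correct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[required]
  x$subject_id <- as.character(x$subject_id)
  x$group <- as.character(x$group)
  x$material <- as.character(x$material)
  x$environment <- as.character(x$environment)
  x$iidr <- as.character(x$iidr)
  x$snr_db <- as.numeric(x$snr_db)
  x$level_db_spl <- as.numeric(x$level_db_spl)
  x$item_index <- as.integer(x$item_index)

  if (nrow(x) == 0L) {
    x$correct <- as.integer(x$correct)
    class(x) <- c("iidr_cohort", "data.frame")
    return(x)
  }

  bad <- which(!(x$correct %in% c(0, 1)))
  if (length(bad)) {
    stop("validation error: non-binary 'correct' value on row ", bad[1L],
         " (value: ", x$correct[bad[1L]], ")")
  }
  x$correct <- as.integer(x$correct)

  bad_mat <- setdiff(unique(x$material), names(MATERIALS))
  if (length(bad_mat)) {
    stop("validation error: unknown material: ",
         paste(bad_mat, collapse = ", "))
  }

  grp <- tapply(x$group, x$subject_id, function(g) length(unique(g)))
  if (any(grp > 1L)) {
    stop("validation error: conflicting group labels for subject(s): ",
         paste(names(grp)[grp > 1L], collapse = ", "))
  }

  # canonical order: subject, level, material, environment, iidr, item
  ord <- order(x$subject_id, x$level_db_spl, x$material, x$environment,
               x$iidr, x$item_index, method = "radix")
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL

  cell <- paste(x$subject_id,
                condition_key(x$material, x$environment, x$level_db_spl,
                              x$iidr),
                sep = "|")
  cells <- split(seq_len(nrow(x)), cell)
  for (nm in names(cells)) {
    idx <- cells[[nm]]
    expected <- MATERIALS[[x$material[idx[1L]]]]
    run <- x$item_index[idx]
    if (length(idx) != expected || !identical(run, seq_len(expected) - 1L)) {
      stop("validation error: cell ", nm, " has ", length(idx),
           " item row(s); expected a contiguous 0-based run of ",
           expected)
    }
  }

  # fully crossed over the cells present
  per_subj <- tapply(condition_key(x$material, x$environment,
                                   x$level_db_spl, x$iidr),
                     x$subject_id, function(k) sort(unique(k)))
  ref <- per_subj[[1L]]
  same <- vapply(per_subj, identical, logical(1L), y = ref)
  if (!all(same)) {
    stop("validation error: cohort not fully crossed; subject(s) ",
         paste(names(per_subj)[!same], collapse = ", "),
         " hold a different cell set than ", names(per_subj)[1L])
  }

  class(x) <- c("iidr_cohort", "data.frame")
  x
}

#' @export
print.iidr_cohort <- function(x, ...) {
  cat(sprintf(
    "Item-response cohort: %d subjects, %d cells/subject, %d item rows\n",
    length(unique(x$subject_id)),
    if (nrow(x)) length(unique(condition_key(x$material, x$environment,
                                             x$level_db_spl, x$iidr))) else 0L,
    nrow(x)))
  if (nrow(x)) {
    tab <- table(unique(x[c("subject_id", "group")])$group)
    cat("Groups:", paste(names(tab), tab, sep = " n=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write a long-format response table
#'
#' CSV interchange (RFC-4180, header required) for cohorts; the round trip
#' `read_responses(write_responses(cohort))` reproduces the cohort exactly.
#' In quiet conditions the `snr_db` field is empty.
#'
#' @param path File path.
#' @return For `read_responses`, a validated [as_cohort()] object.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("subject_id", "group", "material", "environment", "snr_db",
                "level_db_spl", "iidr", "item_index", "correct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw)) {
    num_ok <- function(v) v == "" | !is.na(suppressWarnings(as.numeric(v)))
    for (col in c("snr_db", "level_db_spl", "item_index", "correct")) {
      bad <- which(!num_ok(raw[[col]]))
      if (length(bad)) {
        stop("validation error: non-numeric '", col, "' value on row ",
             bad[1L], " (value: ", raw[[col]][bad[1L]], ")")
      }
    }
    raw$snr_db <- ifelse(raw$snr_db == "", NA_real_, as.numeric(raw$snr_db))
    raw$level_db_spl <- as.numeric(raw$level_db_spl)
    raw$item_index <- as.integer(raw$item_index)
    raw$correct <- as.numeric(raw$correct)
  } else {
    raw$snr_db <- numeric(0)
    raw$level_db_spl <- numeric(0)
    raw$item_index <- integer(0)
    raw$correct <- integer(0)
  }
  as_cohort(raw)
}

#' @rdname read_responses
#' @param cohort A validated cohort.
#' @export
write_responses <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Percent-correct score of one item response vector
#'
#' Word lists are scored as percent of 25 words correct; sentence lists as
#' percent of 60 morphemes correct. Scores live on the 0-100 scale.
#'
#' @param responses Binary vector of item outcomes (1 = correct).
#' @return Percent correct in \[0, 100\].
#' @examples
#' score_percent(c(rep(1, 18), rep(0, 7)))  # 72
#' @export
score_percent <- function(responses) {
  if (length(responses) == 0L) stop("empty response vector")
  if (!all(responses %in% c(0, 1))) stop("responses must be binary (0/1)")
  100 * sum(responses) / length(responses)
}

#' Per-subject percent scores for every cell of a cohort
#'
#' @param cohort A cohort.
#' @return Data frame with one row per subject x condition x IIDR cell and
#'   a `score` column in percent.
#' @export
cohort_scores <- function(cohort) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0L) {
    return(data.frame(subject_id = character(0), group = character(0),
                      material = character(0), environment = character(0),
                      snr_db = numeric(0), level_db_spl = numeric(0),
                      iidr = character(0), score = numeric(0)))
  }
  agg <- stats::aggregate(
    correct ~ subject_id + group + material + environment + level_db_spl + iidr,
    data = cohort, FUN = function(v) 100 * mean(v))
  agg$snr_db <- ifelse(agg$environment == "noise", NOISE_SNR_DB, NA_real_)
  names(agg)[names(agg) == "correct"] <- "score"
  agg <- agg[order(agg$subject_id, agg$level_db_spl, agg$material,
                   agg$environment, agg$iidr, method = "radix"),
             c("subject_id", "group", "material", "environment", "snr_db",
               "level_db_spl", "iidr", "score")]
  rownames(agg) <- NULL
  agg
}
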