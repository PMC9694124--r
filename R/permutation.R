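check_binary <- function(x, what) {
  if (length(x) == 0L) stop(what, " must be non-empty")
  if (!all(x %in% c(0, 1))) stop(what, " must be binary (0/1)")
  as.integer(x)
}

#' Observed mean-score difference between two item collections
#'
#' The test statistic: the difference of mean percent-correct scores,
#' oriented as comparison minus reference. By convention `a` is the
#' reference side (default IIDR, or the preCSPL65 group) and `b` the
#' comparison side (wide IIDR, or the preCSPL80 group).
#'
#' @param a,b Non-empty binary vectors of item outcomes.
#' @return `100 * (mean(b) - mean(a))`, in percentage points.
#' @examples
#' observed_mean_difference(rep(0, 25), rep(1, 25))  # +100
#' @export
observed_mean_difference <- function(a, b) {
  a <- check_binary(a, "a")
  b <- check_binary(b, "b")
  100 * (mean(b) - mean(a))
}

new_permutation_result <- function(observed, n_resamples, extreme_count,
                                   total, p_value, alternative, seed, mode) {
  structure(list(observed_statistic = observed,
                 n_resamples = n_resamples,
                 extreme_count = extreme_count,
                 total_enumerated = total,
                 p_value = p_value,
                 alternative = alternative,
                 seed = seed,
                 mode = mode),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s permutation test (%s)\n",
              if (x$mode == "exact") "Exact" else "Monte Carlo",
              x$alternative))
  cat(sprintf("  observed mean difference: %+.3f percentage points\n",
              x$observed_statistic))
  denom <- if (x$mode == "exact") x$total_enumerated else x$n_resamples
  cat(sprintf("  extreme resamples: %s of %s\n",
              format(x$extreme_count, big.mark = ","),
              format(denom, big.mark = ",")))
  p_str <- if (x$mode == "monte_carlo" && x$p_value == 0) {
    sprintf("< %g", 1 / x$n_resamples)
  } else format(x$p_value)
  cat("  p-value:", p_str, "\n")
  invisible(x)
}

#' Monte Carlo permutation test of a mean-score difference
#'
#' Pools the two sides and, in each of `n_resamples` independent
#' iterations, draws without replacement a pseudo-"b" of size
#' `length(b)` (the leftover forms the pseudo-"a"), recomputes the mean
#' difference, and counts the iteration as extreme when the permuted
#' difference is `>=` the observed one (`alternative = "greater"`), or
#' when its absolute value is `>=` the observed absolute value
#' (`"two_sided"`). The p-value is `extreme_count / n_resamples`, with no
#' continuity correction, so a p of exactly 0 is possible and is printed
#' as `< 1/n_resamples`. Fully reproducible from `seed`.
#'
#' Extremity is decided in integer arithmetic on success counts (see the
#' compiled kernel), so tied permuted differences are counted exactly.
#'
#' @param a,b Non-empty binary item-outcome vectors (reference,
#'   comparison).
#' @param n_resamples Number of resampling iterations (study default
#'   100,000).
#' @param seed Integer seed.
#' @param alternative `"greater"` (comparison exceeds reference) or
#'   `"two_sided"`.
#' @return A `permutation_result` with the observed statistic, extreme
#'   count, p-value, and provenance fields.
#' @examples
#' mc_permutation_test(c(0, 0, 0), c(1, 1, 1), n_resamples = 1e4, seed = 1)
#' @export
mc_permutation_test <- function(a, b, n_resamples = 100000L, seed = 1L,
                                alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- check_binary(a, "a")
  b <- check_binary(b, "b")
  n_resamples <- as.integer(n_resamples)
  if (is.na(n_resamples) || n_resamples < 1L) {
    stop("n_resamples must be a positive integer")
  }
  observed <- 100 * (mean(b) - mean(a))
  pooled <- c(a, b)
  set.seed(seed)
  extreme <- mc_extreme_count(pooled, length(b), n_resamples,
                              sum(b), alternative == "two_sided")
  new_permutation_result(observed, n_resamples, extreme, NA_real_,
                         extreme / n_resamples, alternative,
                         as.integer(seed), "monte_carlo")
}

#' Exact permutation test by complete enumeration
#'
#' The correctness oracle for [mc_permutation_test()]: enumerates every
#' distinct assignment of the pooled values to a pseudo-"b" of size
#' `length(b)`. For binary data the permuted difference depends only on
#' the number k of successes assigned to pseudo-"b", so the enumeration
#' iterates over k and weights each value by its multiplicity
#' `choose(K, k) * choose(n - K, nb - k)` (a hypergeometric mass). The
#' p-value is the exactly-computed fraction of extreme assignments under
#' the same inclusive extremity rule as the Monte Carlo test.
#'
#' @inheritParams mc_permutation_test
#' @param max_enum Refuse enumeration when the number of assignments
#'   `choose(n, nb)` exceeds this cap (default 1e7); the error advises
#'   Monte Carlo mode. Raise (e.g. `Inf`) to force the closed-form path
#'   at any size.
#' @return A `permutation_result` with `mode = "exact"`.
#' @examples
#' exact_permutation_test(c(0, 0, 0), c(1, 1, 1))$p_value  # 1/20
#' @export
exact_permutation_test <- function(a, b,
                                   alternative = c("greater", "two_sided"),
                                   max_enum = 1e7) {
  alternative <- match.arg(alternative)
  a <- check_binary(a, "a")
  b <- check_binary(b, "b")
  n <- length(a) + length(b)
  nb <- length(b)
  total <- choose(n, nb)
  if (total > max_enum) {
    stop("exact enumeration of ", format(total), " assignments exceeds the ",
         "cap (", format(max_enum), "); use mc_permutation_test or raise ",
         "max_enum")
  }
  K <- sum(a) + sum(b)
  kb_obs <- sum(b)
  observed <- 100 * (mean(b) - mean(a))

  k <- max(0L, nb - (n - K)):min(nb, K)
  log_w <- lchoose(K, k) + lchoose(n - K, nb - k) - lchoose(n, nb)
  extreme_k <- if (alternative == "greater") {
    k >= kb_obs
  } else {
    abs(k * n - K * nb) >= abs(kb_obs * n - K * nb)
  }
  p <- sum(exp(log_w[extreme_k]))
  p <- min(max(p, 0), 1)
  extreme_count <- sum(choose(K, k[extreme_k]) * choose(n - K, nb - k[extreme_k]))
  new_permutation_result(observed, NA_integer_, extreme_count, total, p,
                         alternative, NA_integer_, "exact")
}

#' Pool the item outcomes of a comparison cell
#'
#' Builds the two pooled binary vectors a permutation test compares,
#' concatenating item responses across the selected subjects in stable
#' subject order. Two axes exist:
#' \describe{
#'   \item{within_iidr}{fixed condition; side a = default IIDR items,
#'     side b = wide IIDR items, over the subjects of `grouping`.}
#'   \item{between_group}{fixed condition and IIDR; side a = preCSPL65
#'     items, side b = preCSPL80 items.}
#' }
#'
#' @param cohort A cohort.
#' @param material,environment,level_db_spl The condition cell.
#' @param axis `"within_iidr"` or `"between_group"`.
#' @param grouping `"all"` or a group label (within_iidr axis only).
#' @param fixed_iidr IIDR label, required on the between_group axis.
#' @return `list(a = , b = )` of binary integer vectors.
#' @export
pool_cell <- function(cohort, material, environment, level_db_spl,
                      axis = c("within_iidr", "between_group"),
                      grouping = "all", fixed_iidr = NULL) {
  axis <- match.arg(axis)
  cohort <- as_cohort(cohort)
  sel <- cohort$material == material &
    cohort$environment == environment &
    cohort$level_db_spl == level_db_spl
  cond <- cohort[sel, , drop = FALSE]

  take <- function(rows, why) {
    if (nrow(rows) == 0L) {
      stop("empty selection for ", why, " in cell ",
           condition_key(material, environment, level_db_spl))
    }
    rows <- rows[order(rows$subject_id, rows$item_index, method = "radix"), ]
    rows$correct
  }

  if (axis == "within_iidr") {
    if (grouping != "all") cond <- cond[cond$group == grouping, , drop = FALSE]
    list(a = take(cond[cond$iidr == "default", , drop = FALSE],
                  paste0("default IIDR, grouping ", grouping)),
         b = take(cond[cond$iidr == "wide", , drop = FALSE],
                  paste0("wide IIDR, grouping ", grouping)))
  } else {
    if (is.null(fixed_iidr)) {
      stop("between_group comparisons need fixed_iidr")
    }
    cond <- cond[cond$iidr == fixed_iidr, , drop = FALSE]
    list(a = take(cond[cond$group == "preCSPL65", , drop = FALSE],
                  paste0("group preCSPL65 at ", fixed_iidr, " IIDR")),
         b = take(cond[cond$group == "preCSPL80", , drop = FALSE],
                  paste0("group preCSPL80 at ", fixed_iidr, " IIDR")))
  }
}
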