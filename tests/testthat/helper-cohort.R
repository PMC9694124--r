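# In-code fixtures: tiny hand-built cohorts independent of the generator.

# One subject-by-cell block of long-format rows.
cell_rows <- function(subject_id, group, material, environment,
                      level_db_spl, iidr, correct) {
  n <- iidrperm::items_per_list(material)
  stopifnot(length(correct) == n)
  data.frame(subject_id = subject_id, group = group, material = material,
             environment = environment,
             snr_db = if (environment == "noise") 10 else NA_real_,
             level_db_spl = level_db_spl, iidr = iidr,
             item_index = seq_len(n) - 1L, correct = as.integer(correct),
             stringsAsFactors = FALSE)
}

# Two subjects (one per group), word-in-quiet 65 under both IIDRs, with
# fixed deterministic response patterns.
mini_cohort_df <- function() {
  rbind(
    cell_rows("S01", "preCSPL65", "word", "quiet", 65, "default",
              rep(c(1L, 0L), length.out = 25)),
    cell_rows("S01", "preCSPL65", "word", "quiet", 65, "wide",
              rep(c(1L, 1L, 0L), length.out = 25)),
    cell_rows("S02", "preCSPL80", "word", "quiet", 65, "default",
              rep(c(0L, 1L), length.out = 25)),
    cell_rows("S02", "preCSPL80", "word", "quiet", 65, "wide",
              rep(1L, 25)))
}

# A small fully crossed generator config: 1+1 subjects, two conditions.
tiny_config <- function(seed = 1L, subject_sd = 0, p65 = 0.8, p80 = 0.3) {
  grid <- expand.grid(group = c("preCSPL65", "preCSPL80"),
                      material = c("word", "sentence"),
                      environment = "quiet", level_db_spl = 65,
                      iidr = c("default", "wide"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$p <- ifelse(grid$group == "preCSPL65", p65, p80)
  iidrperm::generator_config(c(preCSPL65 = 1L, preCSPL80 = 1L), grid,
                             subject_sd = subject_sd, seed = seed)
}

# Brute-force permutation oracle: enumerates every subset of the pooled
# vector of size |b| via utils::combn and counts extreme assignments by
# recomputing the mean difference directly. Only feasible for tiny inputs.
brute_force_p <- function(a, b, alternative = "greater") {
  pooled <- c(a, b)
  n <- length(pooled)
  nb <- length(b)
  obs <- 100 * (mean(b) - mean(a))
  idx <- utils::combn(n, nb)
  diffs <- apply(idx, 2, function(j) {
    100 * (mean(pooled[j]) - mean(pooled[-j]))
  })
  eps <- 1e-9
  if (alternative == "greater") {
    mean(diffs >= obs - eps)
  } else {
    mean(abs(diffs) >= abs(obs) - eps)
  }
}

random_binary_pair <- function(max_side = 8L) {
  na <- sample(2:max_side, 1L)
  nb <- sample(2:max_side, 1L)
  list(a = sample(0:1, na, replace = TRUE),
       b = sample(0:1, nb, replace = TRUE))
}
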