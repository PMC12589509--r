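# Shared fixtures: built once per test run, all seeded.

# small default-world cohort reused by several test files
small_cfg <- function(seed = 101, ...) {
  cohort_config(n_subjects = 200, n_features_limbic = 6,
                n_features_nonlimbic = 10, n_sites = 3, seed = seed, ...)
}

.fixture_env <- new.env()

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_cfg())
  }
  .fixture_env$cohort
}

# hand-built cross-sectional table for matching / QC tests
toy_cohort <- function(subject_id, sex, age, etiv, euler) {
  data.frame(subject_id = subject_id, session = "baseline", sex = sex,
             age_months = age, etiv_mm3 = etiv, euler = euler,
             site_id = "site01", family_id = subject_id,
             stringsAsFactors = FALSE)
}

# brute-force optimal 1:1 assignment: enumerate every injective mapping of
# references to candidates, keep only feasible complete assignments, and
# return the one minimizing total |eTIV difference|
brute_force_match <- function(cohort, spec) {
  euler_sd <- sd(cohort$euler)
  ref <- cohort[cohort$sex == spec$reference_sex, ]
  cand <- cohort[cohort$sex != spec$reference_sex, ]
  feasible <- function(i, j) {
    abs(ref$age_months[i] - cand$age_months[j]) <= spec$max_age_diff_months &&
      abs(ref$etiv_mm3[i] - cand$etiv_mm3[j]) / ref$etiv_mm3[i] <=
        spec$max_etiv_rel_diff &&
      (euler_sd == 0 ||
         abs(ref$euler[i] - cand$euler[j]) <= spec$max_euler_diff_sd * euler_sd)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (assign in perms(seq_len(nrow(cand)))) {
    if (all(mapply(feasible, seq_len(nrow(ref)), assign))) {
      cost <- sum(abs(ref$etiv_mm3 - cand$etiv_mm3[assign]))
      if (cost < best_cost) {
        best_cost <- cost
        best <- assign
      }
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(reference_subject_id = ref$subject_id,
             matched_subject_id = cand$subject_id[best],
             stringsAsFactors = FALSE)
}

# exhaustive Mann-Whitney AUC: concordant pairs + half ties
auc_by_pairs <- function(probs, labels) {
  y <- as.numeric(labels == "F" | labels == 1)
  pos <- probs[y == 1]
  neg <- probs[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up, written independently of p.adjust
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
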