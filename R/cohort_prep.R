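# Euler-number quality control and constrained 1:1 female-male matching.

#' Euler-number quality control
#'
#' Excludes observations whose surface Euler number lies more than `n_sd`
#' standard deviations *below* the cohort mean (one-sided: only the
#' poor-quality tail is removed; unusually good reconstructions are kept).
#' Mean and SD are computed on the input cohort as a whole, not per site.
#'
#' @param cohort cohort data frame with an `euler` column.
#' @param n_sd exclusion threshold in SD units (default 3).
#' @return list with `cohort` (filtered) and `excluded` (the removed rows).
#' @export
euler_qc <- function(cohort, n_sd = 3) {
  .assert_cohort(cohort, "subject_id")
  if (!"euler" %in% names(cohort)) stop("cohort has no euler column")
  if (nrow(cohort) < 2) stop("need at least 2 observations for QC")
  m <- mean(cohort$euler)
  s <- sd(cohort$euler)
  if (s == 0) {
    message("euler_qc: all Euler numbers identical; nothing excluded")
    keep <- rep(TRUE, nrow(cohort))
  } else {
    keep <- cohort$euler >= m - n_sd * s
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "truth") <- attr(cohort, "truth")
  list(cohort = out, excluded = cohort[!keep, , drop = FALSE])
}

#' Matching criteria for 1:1 female-male pairing
#'
#' Defaults follow the conventional caliper set for head-size-controlled sex
#' comparisons: age within 12 months, harmonized eTIV within 3% (relative to
#' the reference subject), Euler number within 1 SD (SD taken over the full
#' input cohort).
#'
#' @param max_age_diff_months age caliper, months.
#' @param max_etiv_rel_diff eTIV caliper as a fraction of the reference
#'   subject's eTIV.
#' @param max_euler_diff_sd Euler caliper in cohort-SD units.
#' @param reference_sex which sex seeds the pairing (`"F"`: each female is
#'   matched with one male).
#' @param iteration_order `"by_id"` (deterministic, ascending subject id) or
#'   `"random"` (seeded shuffle, for sensitivity analysis).
#' @param seed used only when `iteration_order = "random"`.
#' @return a `match_spec` list.
#' @export
match_spec <- function(max_age_diff_months = 12, max_etiv_rel_diff = 0.03,
                       max_euler_diff_sd = 1, reference_sex = c("F", "M"),
                       iteration_order = c("by_id", "random"), seed = 1L) {
  reference_sex <- match.arg(reference_sex)
  iteration_order <- match.arg(iteration_order)
  if (max_age_diff_months <= 0 || max_etiv_rel_diff <= 0 ||
      max_euler_diff_sd <= 0) {
    stop("matching thresholds must be positive")
  }
  structure(list(max_age_diff_months = max_age_diff_months,
                 max_etiv_rel_diff = max_etiv_rel_diff,
                 max_euler_diff_sd = max_euler_diff_sd,
                 reference_sex = reference_sex,
                 iteration_order = iteration_order, seed = as.integer(seed)),
            class = "match_spec")
}

#' Greedy 1:1 female-male matching on age, eTIV and Euler number
#'
#' Iterates over reference-sex subjects (ascending id by default), and for
#' each one selects, among unmatched opposite-sex candidates satisfying all
#' three calipers, the candidate with the smallest absolute eTIV difference.
#' Unmatched reference subjects are reported, not an error. The input must be
#' cross-sectional (one row per subject); match on harmonized eTIV.
#'
#' @param cohort cross-sectional cohort data frame.
#' @param spec a [match_spec()].
#' @return a `matched_sample`: list with `pairs` (reference id, match id and
#'   realized differences), `cohort` (the matched 50/50 subset) and
#'   `unmatched` (reference ids with no admissible candidate).
#' @export
match_pairs <- function(cohort, spec = match_spec()) {
  .assert_cohort(cohort, c("subject_id", "sex", "age_months", "etiv_mm3",
                           "euler"))
  if (anyDuplicated(cohort$subject_id) > 0) {
    stop("match_pairs needs a cross-sectional cohort (one row per subject)")
  }
  euler_sd <- sd(cohort$euler)
  ref <- cohort[cohort$sex == spec$reference_sex, , drop = FALSE]
  cand <- cohort[cohort$sex != spec$reference_sex, , drop = FALSE]

  ord <- order(ref$subject_id)
  if (spec$iteration_order == "random") {
    set.seed(spec$seed)
    ord <- sample(ord)
  }

  used <- rep(FALSE, nrow(cand))
  pairs <- vector("list", nrow(ref))
  unmatched <- character(0)
  for (i in ord) {
    age_d <- abs(cand$age_months - ref$age_months[i])
    etiv_d <- abs(cand$etiv_mm3 - ref$etiv_mm3[i])
    etiv_rel <- etiv_d / ref$etiv_mm3[i]
    eul_d <- abs(cand$euler - ref$euler[i])
    ok <- !used & age_d <= spec$max_age_diff_months &
      etiv_rel <= spec$max_etiv_rel_diff &
      (euler_sd == 0 | eul_d <= spec$max_euler_diff_sd * euler_sd)
    if (!any(ok)) {
      unmatched <- c(unmatched, ref$subject_id[i])
      next
    }
    j <- which(ok)[order(etiv_d[ok], cand$subject_id[ok])][1]
    used[j] <- TRUE
    pairs[[i]] <- data.frame(reference_subject_id = ref$subject_id[i],
                             matched_subject_id = cand$subject_id[j],
                             age_diff_months = age_d[j],
                             etiv_rel_diff = etiv_rel[j],
                             euler_diff = eul_d[j],
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(reference_subject_id = character(0),
                        matched_subject_id = character(0),
                        age_diff_months = numeric(0),
                        etiv_rel_diff = numeric(0), euler_diff = numeric(0))
  }
  keep_ids <- c(pairs$reference_subject_id, pairs$matched_subject_id)
  out <- cohort[cohort$subject_id %in% keep_ids, , drop = FALSE]
  attr(out, "truth") <- attr(cohort, "truth")
  structure(list(pairs = pairs, cohort = out, unmatched = unmatched,
                 spec = spec, euler_sd = euler_sd),
            class = "matched_sample")
}

#' Covariate balance of a matched sample
#'
#' Welch two-sample t-tests comparing females and males on age, eTIV and
#' Euler number. Diagnostics only; no filtering is performed.
#'
#' @param matched a [match_pairs()] result.
#' @return data frame with one row per variable: group means, Welch t, df, p.
#' @export
balance_check <- function(matched) {
  stopifnot(inherits(matched, "matched_sample"))
  co <- matched$cohort
  if (nrow(co) == 0) stop("matched sample is empty")
  if (min(table(co$sex)) < 2) {
    stop("balance_check needs at least 2 subjects per sex")
  }
  vars <- c("age_months", "etiv_mm3", "euler")
  rows <- lapply(vars, function(v) {
    f <- co[[v]][co$sex == "F"]
    m <- co[[v]][co$sex == "M"]
    if (sd(f) == 0 && sd(m) == 0) {
      # constant groups: Welch statistic undefined; report balance directly
      same <- isTRUE(all.equal(mean(f), mean(m)))
      return(data.frame(variable = v, mean_F = mean(f), mean_M = mean(m),
                        t = 0, df = NA_real_, p = as.numeric(same)))
    }
    tt <- t.test(f, m)
    data.frame(variable = v, mean_F = mean(f), mean_M = mean(m),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Re-validate a pair list against its matching criteria
#'
#' Checks, from the pair list alone, that every pair satisfies the calipers
#' it was formed under and that no subject appears twice.
#'
#' @param matched a `matched_sample`.
#' @return TRUE invisibly; stops with a message on any violation.
#' @export
validate_pairs <- function(matched) {
  stopifnot(inherits(matched, "matched_sample"))
  p <- matched$pairs
  s <- matched$spec
  ids <- c(p$reference_subject_id, p$matched_subject_id)
  if (anyDuplicated(ids) > 0) stop("a subject appears in more than one pair")
  bad <- p$age_diff_months > s$max_age_diff_months |
    p$etiv_rel_diff > s$max_etiv_rel_diff |
    (matched$euler_sd > 0 &
       p$euler_diff > s$max_euler_diff_sd * matched$euler_sd)
  if (any(bad)) {
    stop(sum(bad), " pair(s) violate the matching criteria")
  }
  invisible(TRUE)
}
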