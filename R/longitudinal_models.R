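# Mixed-effects association batteries on the brain-sex continuum.
#
# Four model families relate class probabilities to age, pubertal
# development, menarche onset and mental health, always within one sex and
# one feature set, with a per-subject random intercept for the repeated
# sessions. Sequential (type I) F-tests follow the fixed formula order;
# marginal (type II) tests evaluate each term after every other term that
# does not contain it. Estimation is by maximum likelihood (nlme), so
# sequential comparisons across nested fixed-effect sets are coherent;
# denominator degrees of freedom follow nlme's containment convention.

#' Average Pubertal Development Scale score
#'
#' The PDS has five items scored 1--4 (1 = not started ... 4 = completed);
#' the menstruation item is binary, No = 1 / Yes = 4. The stage score is the
#' arithmetic mean of the available items.
#'
#' @param x a numeric vector of item scores, or a puberty table with columns
#'   `p1..p5` (in which case a column `average_score` is added).
#' @return the mean score, or the augmented table.
#' @export
pds_average <- function(x) {
  if (is.numeric(x)) {
    if (all(is.na(x))) stop("all PDS items missing")
    return(mean(x, na.rm = TRUE))
  }
  items <- as.matrix(x[, c("p1", "p2", "p3", "p4", "p5")])
  if (any(rowSums(!is.na(items)) == 0)) stop("row(s) with all PDS items missing")
  x$average_score <- rowMeans(items, na.rm = TRUE)
  x
}

#' Menarche onset grouping
#'
#' Splits females with both sessions by their menstruation answers:
#' No at both sessions = `no_no`; No at baseline, Yes at follow-up = `onset`
#' (menarche between sessions); any other combination (or a missing session)
#' = `excluded`.
#'
#' @param puberty puberty table with `subject_id`, `session`, `menarche`.
#' @return data frame `subject_id, group` (females only), with group counts
#'   in attribute `counts`.
#' @export
menarche_groups <- function(puberty) {
  fem <- puberty[!is.na(puberty$menarche), , drop = FALSE]
  base <- fem[fem$session == "baseline", c("subject_id", "menarche")]
  fup <- fem[fem$session == "followup", c("subject_id", "menarche")]
  ids <- unique(fem$subject_id)
  b <- base$menarche[match(ids, base$subject_id)]
  f <- fup$menarche[match(ids, fup$subject_id)]
  group <- rep("excluded", length(ids))
  group[!is.na(b) & !is.na(f) & b == "no" & f == "no"] <- "no_no"
  group[!is.na(b) & !is.na(f) & b == "no" & f == "yes"] <- "onset"
  out <- data.frame(subject_id = ids, group = group, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(group,
                                      levels = c("no_no", "onset", "excluded")))
  out
}

#' Drop observations from under-represented sites
#'
#' @param data data frame with a `site_id` column.
#' @param min_n minimum observations a site must contribute (default 20);
#'   sites with fewer are removed from the analysis stratum.
#' @return filtered data; dropped sites are reported via `message()`.
#' @export
site_filter <- function(data, min_n = 20) {
  if (!"site_id" %in% names(data)) stop("data has no site_id column")
  counts <- table(data$site_id)
  small <- names(counts)[counts < min_n]
  if (length(small) > 0) {
    message("site_filter: dropping site(s) ", paste(small, collapse = ", "))
  }
  out <- data[!(data$site_id %in% small), , drop = FALSE]
  if (nrow(out) == 0) stop("site filter removed every observation")
  out
}

#' Specification of one association model
#'
#' Fixed-effect terms are listed in the exact order used for sequential
#' (type I) ANOVA. All `*_lme` models add a per-subject random intercept;
#' `age_lm_training` is the cross-sectional linear model for the training
#' cohort. `include_site` inserts the site covariate after the Euler term.
#'
#' @param id one of `age_lm_training`, `age_lme`, `pds_lme`, `menarche_lme`,
#'   `mh_lme`.
#' @param include_site add `site_id` as a covariate.
#' @return a `model_spec` list with `outcome`, ordered `terms`, `random`.
#' @export
model_spec <- function(id = c("age_lme", "pds_lme", "menarche_lme", "mh_lme",
                              "age_lm_training"),
                       include_site = FALSE) {
  id <- match.arg(id)
  site <- if (include_site) "site_id" else NULL
  terms <- switch(id,
    age_lm_training = c("age_months", "euler", site),
    age_lme = c("age_months", "session", "euler", site,
                "age_months:session"),
    pds_lme = c("pds_average", "age_months", "euler", site,
                "pds_average:age_months"),
    menarche_lme = c("menarche_onset", "age_months", "session", "euler", site,
                     "menarche_onset:age_months", "menarche_onset:session"),
    mh_lme = c("mh_score", "age_months", "session", "euler", site,
               "mh_score:age_months", "mh_score:session"))
  structure(list(id = id, outcome = "p_female", terms = terms,
                 random = if (id == "age_lm_training") NULL else "subject_id",
                 include_site = include_site),
            class = "model_spec")
}

.spec_formula <- function(outcome, terms) {
  as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
}

.fit_engine <- function(spec, data, terms = spec$terms) {
  fml <- .spec_formula(spec$outcome, terms)
  if (is.null(spec$random)) {
    return(lm(fml, data = data))
  }
  random <- as.formula(paste0("~ 1 | ", spec$random))
  try_fit <- function(ctrl) {
    nlme::lme(fixed = fml, random = random, data = data, method = "ML",
              na.action = na.omit, control = ctrl)
  }
  fit <- tryCatch(
    try_fit(nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                             returnObject = FALSE)),
    error = function(e1) tryCatch(
      try_fit(nlme::lmeControl(maxIter = 200, msMaxIter = 200, opt = "optim",
                               returnObject = FALSE)),
      error = function(e2) {
        warning("lme did not fully converge; returning best fit (",
                conditionMessage(e1), ")")
        try_fit(nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                 returnObject = TRUE))
      }))
  fit
}

#' Fit one association model
#'
#' Refuses pooled sexes: these analyses are run within one sex because the
#' expected effect directions are opposite between sexes and the classifier
#' separates the sexes by construction.
#'
#' @param spec a [model_spec()].
#' @param data one analysis stratum: columns `p_female`, the spec's
#'   predictors, `subject_id`, and (if present) a single-valued `sex`.
#' @return a `brainsex_fit` wrapping the fitted model, spec and data.
#' @export
fit_lme <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if ("sex" %in% names(data) && length(unique(data$sex)) > 1) {
    stop("pooled sexes: association models must be fit within one sex")
  }
  vars <- unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))
  missing <- setdiff(c(spec$outcome, vars), names(data))
  if (length(missing) > 0) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  keep <- complete.cases(data[, c(spec$outcome, vars), drop = FALSE])
  dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  fit <- .fit_engine(spec, data)
  structure(list(fit = fit, spec = spec, data = data,
                 n_dropped_incomplete = dropped),
            class = "brainsex_fit")
}

# one sequential anova table, as a tidy data frame in term order
.anova_table <- function(fit_obj, terms) {
  fit <- .fit_engine(fit_obj$spec, fit_obj$data, terms)
  if (inherits(fit, "lme")) {
    tab <- anova(fit)
    tab <- tab[rownames(tab) != "(Intercept)", , drop = FALSE]
    data.frame(term = rownames(tab), num_df = tab$numDF, den_df = tab$denDF,
               F = tab$`F-value`, p = tab$`p-value`,
               stringsAsFactors = FALSE)
  } else {
    tab <- anova(fit)
    res_df <- tab["Residuals", "Df"]
    tab <- tab[rownames(tab) != "Residuals", , drop = FALSE]
    data.frame(term = rownames(tab), num_df = tab$Df, den_df = res_df,
               F = tab$`F value`, p = tab$`Pr(>F)`, stringsAsFactors = FALSE)
  }
}

# variables of a term
.term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]
# does term b contain term a (strictly)?
.contains <- function(a, b) {
  va <- .term_vars(a); vb <- .term_vars(b)
  all(va %in% vb) && length(vb) > length(va)
}

#' Sequential (type I) ANOVA of an association model
#'
#' Conditional F-tests in the fixed formula order, denominator df by the
#' containment convention.
#'
#' @param fit_obj a [fit_lme()] result.
#' @return data frame `term, num_df, den_df, F, p, anova_type`.
#' @export
anova_sequential <- function(fit_obj) {
  stopifnot(inherits(fit_obj, "brainsex_fit"))
  out <- .anova_table(fit_obj, fit_obj$spec$terms)
  # anova() reports terms in fit order; restore the spec's naming/order
  out$anova_type <- "I"
  out
}

#' Marginal (type II) ANOVA of an association model
#'
#' Each term is tested after every other term except those containing it
#' (interactions involving a main effect are excluded when testing that main
#' effect); interactions are tested last. Implemented by reordering the
#' formula so the target term is the last admissible one and reading its
#' sequential F — the textbook type II construction, which inherits nlme's
#' containment denominator df.
#'
#' @param fit_obj a [fit_lme()] result.
#' @return data frame `term, num_df, den_df, F, p, anova_type`, in the
#'   spec's term order.
#' @export
anova_marginal <- function(fit_obj) {
  stopifnot(inherits(fit_obj, "brainsex_fit"))
  terms <- fit_obj$spec$terms
  rows <- lapply(terms, function(t) {
    containing <- terms[vapply(terms, function(b) .contains(t, b), logical(1))]
    others <- setdiff(terms, c(t, containing))
    tab <- .anova_table(fit_obj, c(others, t, containing))
    tab[tab$term == t, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out$anova_type <- "II"
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment within declared families
#'
#' @param results tidy results (needs a `p` column).
#' @param family columns defining one correction family; defaults to
#'   everything except feature set and term, i.e. the three feature-set
#'   models x all terms of one analysis / sex / cohort are corrected jointly.
#' @return `results` with a `p_adj` column.
#' @export
adjust_pvalues <- function(results,
                           family = c("analysis", "cohort", "sex",
                                      "anova_type")) {
  if (nrow(results) == 0) stop("empty result set")
  if (any(results$p < 0 | results$p > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]")
  }
  keys <- intersect(family, names(results))
  if (length(keys) == 0) {
    results$p_adj <- p.adjust(results$p, method = "BH")
    return(results)
  }
  grp <- interaction(results[keys], drop = TRUE)
  results$p_adj <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    results$p_adj[idx] <- p.adjust(results$p[idx], method = "BH")
  }
  results
}

#' Run one association battery across sexes and feature sets
#'
#' Joins the class-probability table with the cohort metadata (and puberty /
#' mental-health tables as needed), applies the small-site filter when site
#' is modelled, fits the analysis model per sex x feature set, computes both
#' ANOVA types and BH-adjusts p-values within each analysis / sex /
#' ANOVA-type family across feature sets and terms.
#'
#' @param analysis `"age"`, `"pds"`, `"menarche"`, `"mh"`, or
#'   `"age_training"` (the cross-sectional linear model for the training
#'   cohort: no session term, no random intercept).
#' @param probs class-probability table (`subject_id, session, feature_set,
#'   p_female`), typically stacked over the three feature sets.
#' @param cohort cohort table supplying `sex, age_months, euler, site_id`.
#' @param puberty puberty table (required for `pds` / `menarche`).
#' @param mh_scores data frame `subject_id, session, mh_score` (for `"mh"`).
#' @param include_site `"auto"` (model site when >= 2 sites survive the
#'   filter), `TRUE` or `FALSE`.
#' @param min_site_n small-site threshold (default 20 observations).
#' @param cohort_name label stored in the results.
#' @return tidy data frame: one row per sex x feature set x term x ANOVA
#'   type, with `F`, dfs, `p` and `p_adj`.
#' @export
run_association <- function(analysis = c("age", "pds", "menarche", "mh",
                                         "age_training"),
                            probs, cohort, puberty = NULL, mh_scores = NULL,
                            include_site = "auto", min_site_n = 20,
                            cohort_name = "validation") {
  analysis <- match.arg(analysis)
  .assert_cohort(cohort, c("subject_id", "session", "sex", "age_months",
                           "euler"))
  meta <- cohort[, intersect(.meta_cols, names(cohort)), drop = FALSE]
  probs <- probs[, setdiff(names(probs), c("sex", "outer_fold")), drop = FALSE]
  join_keys <- if (analysis == "age_training") "subject_id" else
    c("subject_id", "session")
  base <- merge(probs, meta, by = join_keys)
  if (nrow(base) < 0.5 * nrow(probs)) {
    warning("join lost more than half of the probability rows (",
            nrow(probs), " -> ", nrow(base), ")")
  }

  if (analysis == "pds") {
    if (is.null(puberty)) stop("pds analysis needs a puberty table")
    pub <- pds_average(puberty)[, c("subject_id", "session", "average_score")]
    names(pub)[3] <- "pds_average"
    base <- merge(base, pub, by = c("subject_id", "session"))
  } else if (analysis == "menarche") {
    if (is.null(puberty)) stop("menarche analysis needs a puberty table")
    grp <- menarche_groups(puberty)
    grp <- grp[grp$group %in% c("no_no", "onset"), , drop = FALSE]
    base <- merge(base, grp, by = "subject_id")
    base$menarche_onset <- factor(base$group, levels = c("no_no", "onset"))
    base <- base[base$sex == "F", , drop = FALSE]
  } else if (analysis == "mh") {
    if (is.null(mh_scores)) stop("mh analysis needs mental-health scores")
    base <- merge(base, mh_scores, by = c("subject_id", "session"))
  }
  if (analysis != "age_training") {
    base$session <- factor(base$session, levels = c("baseline", "followup"))
  }

  spec_id <- switch(analysis, age = "age_lme", pds = "pds_lme",
                    menarche = "menarche_lme", mh = "mh_lme",
                    age_training = "age_lm_training")
  sexes <- sort(unique(base$sex))
  sets <- unique(probs$feature_set)
  out <- list()
  for (sx in sexes) {
    for (fs in sets) {
      d <- base[base$sex == sx & base$feature_set == fs, , drop = FALSE]
      if (nrow(d) == 0) next
      use_site <- if (identical(include_site, "auto")) {
        length(unique(d$site_id)) > 1
      } else isTRUE(include_site)
      if (use_site) {
        d <- site_filter(d, min_site_n)
        use_site <- length(unique(d$site_id)) > 1
      }
      spec <- model_spec(spec_id, include_site = use_site)
      fit <- fit_lme(spec, d)
      tab <- rbind(anova_sequential(fit), anova_marginal(fit))
      tab$sex <- sx
      tab$feature_set <- fs
      tab$analysis <- analysis
      tab$cohort <- cohort_name
      tab$n_obs <- nrow(fit$data)
      out[[paste(sx, fs)]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  adjust_pvalues(res)
}
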