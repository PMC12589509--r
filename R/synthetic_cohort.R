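# Synthetic longitudinal morphometry cohorts with known ground truth.
#
# The generator writes down, feature by feature, the data-generating model the
# downstream analyses assume:
#
#   vol_ijs = mu_j + sigma_j * z_ijs + b_j * (eTIV_i - mean eTIV)
#   z_ijs   = s_j * [ d_class * I(F) + slope_sex * age_years_c
#                     + puberty_effect_j * dir_sex * stage_is_c ]
#           + shift_{site,j} + scale_{site,j} * (u_i + e_ijs)
#
# where s_j in {-1, +1} is the feature's female-typical direction, stage_is is
# a logistic function of age with sex-specific onset, u_i is a subject random
# intercept and e_ijs is measurement noise. Everything injected is recorded in
# a "truth" attribute so tests can score recovery.

#' Configuration for the synthetic cohort generator
#'
#' All effect magnitudes are in units of the per-feature residual SD
#' (`noise_sd`), so e.g. `sex_effect_sd_units = c(limbic = 0.5, ...)` shifts
#' every limbic feature by 0.5 residual SDs between the sexes (in the
#' feature's female-typical direction). Defaults were chosen once, from the
#' closed-form separability of independent equal shifts, so that a matched
#' training sample is classifiable at roughly the AUC range reported for
#' adolescent morphometry (~0.8), and an unmatched validation cohort --
#' where pooled eTIV residualization partially absorbs the sex effect --
#' lands near ~0.7.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject (2 = baseline + followup).
#' @param session_gap_months mean gap between sessions, months.
#' @param age_range_months numeric length-2, baseline age range in months.
#' @param n_sites number of acquisition sites.
#' @param n_features_limbic,n_features_nonlimbic partition sizes.
#' @param etiv_male_female_ratio mean male/female eTIV ratio; the commonly
#'   reported male head-size advantage is 8--15%, default 1.10.
#' @param sex_effect_sd_units named numeric `c(limbic=, nonlimbic=)`,
#'   standardized female-male shift per feature.
#' @param age_slope_sd_units_per_year named numeric `c(F=, M=)`: drift per
#'   year toward the subject's own-sex-typical direction (females toward
#'   female-typical, males toward male-typical).
#' @param puberty_effect_sd_units standardized effect of latent pubertal stage.
#' @param menarche_step_sd_units additional step shift (females only, same
#'   target features as the puberty effect) once the latent stage crosses the
#'   menarche threshold; default 0 (the continuous stage effect is the base
#'   world; menarche-specific scenarios switch this on).
#' @param puberty_targets `"limbic"` (default), `"all"` or `"none"`: which
#'   features receive the puberty effect.
#' @param puberty_male_scale multiplier for the puberty effect in males
#'   (negative: pubertal males drift toward male-typical).
#' @param male_onset_age_months mean age of male pubertal onset (logistic
#'   midpoint), months.
#' @param female_onset_shift_months how much earlier female onset is; girls
#'   typically begin puberty 1--2 years before boys, default 18 months.
#' @param onset_jitter_sd_months subject-level SD of onset age.
#' @param puberty_scale_months logistic slope parameter of the stage curve.
#' @param menarche_stage_threshold latent stage beyond which menarche has
#'   occurred. Menarche is a late-pubertal milestone (median age ~12.5-12.8
#'   years, roughly two years after pubertal onset); the default 0.8 places
#'   it ~21 months after the stage midpoint.
#' @param site_shift_sd_units SD of additive per-(site, feature) shifts.
#' @param site_scale_range length-2 range of multiplicative per-(site,
#'   feature) residual scale factors.
#' @param subject_re_sd SD of the subject random intercept.
#' @param noise_sd residual SD (the unit of all standardized effects).
#' @param euler_mean,euler_sd Euler number distribution (quality proxy,
#'   more negative = worse).
#' @param euler_contamination fraction of observations with a heavy negative
#'   Euler tail, so quality control has outliers to find.
#' @param distress_limbic_coupling in females, target correlation between the
#'   latent distress factor and the subject's limbic female-typicality.
#' @param distress_stability cross-session correlation of latent distress.
#' @param n_items questionnaire item count.
#' @param seed integer; fully determines all generated tables.
#' @param feature_seed seed of the feature registry (baseline volumes, eTIV
#'   scaling, female-typical directions). Kept separate from `seed` and
#'   constant by default so that independently simulated cohorts share the
#'   same "anatomy" -- a model trained on one cohort is then applicable to
#'   another, as with real segmentations.
#' @return a validated `brainsex_config` list.
#' @export
cohort_config <- function(n_subjects = 600,
                          n_sessions = 2,
                          session_gap_months = 24,
                          age_range_months = c(108, 168),
                          n_sites = 4,
                          n_features_limbic = 20,
                          n_features_nonlimbic = 40,
                          etiv_male_female_ratio = 1.10,
                          sex_effect_sd_units = c(limbic = 0.5, nonlimbic = 0.25),
                          age_slope_sd_units_per_year = c(F = 0.05, M = 0.02),
                          puberty_effect_sd_units = 0.3,
                          menarche_step_sd_units = 0,
                          puberty_targets = c("limbic", "all", "none"),
                          puberty_male_scale = -0.5,
                          male_onset_age_months = 150,
                          female_onset_shift_months = 18,
                          onset_jitter_sd_months = 12,
                          puberty_scale_months = 15,
                          menarche_stage_threshold = 0.8,
                          site_shift_sd_units = 0.3,
                          site_scale_range = c(0.9, 1.1),
                          subject_re_sd = 0.5,
                          noise_sd = 1,
                          euler_mean = -50,
                          euler_sd = 15,
                          euler_contamination = 0.03,
                          distress_limbic_coupling = 0,
                          distress_stability = 0.5,
                          n_items = 15,
                          seed = 1L,
                          feature_seed = 20251L) {
  puberty_targets <- match.arg(puberty_targets)
  cfg <- as.list(environment())
  counts <- c(n_subjects = n_subjects, n_sessions = n_sessions,
              n_sites = n_sites, n_features_limbic = n_features_limbic,
              n_features_nonlimbic = n_features_nonlimbic, n_items = n_items)
  if (any(counts <= 0)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  if (etiv_male_female_ratio <= 0) stop("etiv_male_female_ratio must be > 0")
  if (length(age_range_months) != 2 || diff(age_range_months) <= 0) {
    stop("age_range_months must be c(min, max) with min < max")
  }
  sds <- c(site_shift_sd_units, subject_re_sd, noise_sd,
           onset_jitter_sd_months, sex_effect_sd_units,
           puberty_effect_sd_units)
  if (any(sds < 0)) stop("all SD parameters must be >= 0")
  if (abs(distress_limbic_coupling) > 1) {
    stop("distress_limbic_coupling must be in [-1, 1]")
  }
  if (!all(c("F", "M") %in% names(age_slope_sd_units_per_year))) {
    stop("age_slope_sd_units_per_year needs named entries F and M")
  }
  if (!all(c("limbic", "nonlimbic") %in% names(sex_effect_sd_units))) {
    stop("sex_effect_sd_units needs named entries limbic and nonlimbic")
  }
  cfg$seed <- as.integer(seed)
  cfg$feature_seed <- as.integer(feature_seed)
  class(cfg) <- "brainsex_config"
  cfg
}

#' Extract the hidden-truth record of a generated table
#'
#' @param x a table produced by [generate_cohort()], [generate_puberty()] or
#'   [generate_questionnaire()].
#' @return the list of injected effects (or latent values) used to build `x`.
#' @export
cohort_truth <- function(x) attr(x, "truth")

#' Generate a longitudinal morphometric cohort
#'
#' Simulates subject-by-session volume tables with a configurable sex effect,
#' sex-specific age drift, puberty effects concentrated on the limbic
#' partition, additive/multiplicative site effects, subject random intercepts
#' and eTIV scaling. The full set of injected effects is attached as the
#' `truth` attribute (see [cohort_truth()]).
#'
#' @param config a [cohort_config()] object.
#' @return data frame with metadata columns and one column per feature
#'   (`limbic_*`, `nonlimbic_*`), volumes in mm^3.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "brainsex_config"))
  cfg <- config
  set.seed(.sub_seed(cfg$seed, "cohort"))

  n <- cfg$n_subjects
  p_l <- cfg$n_features_limbic
  p_n <- cfg$n_features_nonlimbic
  p <- p_l + p_n
  feat_names <- c(sprintf("limbic_%03d", seq_len(p_l)),
                  sprintf("nonlimbic_%03d", seq_len(p_n)))
  feat_class <- rep(c("limbic", "nonlimbic"), c(p_l, p_n))

  subject_id <- sprintf("sub%05d", seq_len(n))
  sex <- rep(c("F", "M"), length.out = n)[sample.int(n)]
  site_id <- sprintf("site%02d", sample.int(cfg$n_sites, n, replace = TRUE))
  family_id <- sprintf("fam%05d", seq_len(n))  # generated, never modelled
  age_base <- runif(n, cfg$age_range_months[1], cfg$age_range_months[2])

  # eTIV: constant within subject, male mean larger by the configured ratio
  etiv_f_mean <- 1450000
  etiv_sd <- 95000
  etiv <- rnorm(n, mean = ifelse(sex == "M",
                                 etiv_f_mean * cfg$etiv_male_female_ratio,
                                 etiv_f_mean),
                sd = etiv_sd)
  etiv <- pmax(etiv, 900000)

  # per-feature "anatomy": drawn from the feature-registry seed so that all
  # cohorts of the same dimensions share it (models transfer across cohorts)
  set.seed(cfg$feature_seed)
  s_j <- sample(c(-1, 1), p, replace = TRUE)          # female-typical direction
  mu_j <- runif(p, 1500, 8000)                        # baseline volume, mm^3
  sigma_j <- 0.05 * mu_j                              # biological SD, mm^3
  b_j <- mu_j / etiv_f_mean * runif(p, 0.5, 1.5)      # eTIV scaling, mm^3/mm^3
  set.seed(.sub_seed(cfg$seed, "cohort_sample"))
  d_j <- ifelse(feat_class == "limbic",
                cfg$sex_effect_sd_units[["limbic"]],
                cfg$sex_effect_sd_units[["nonlimbic"]])
  pub_j <- switch(cfg$puberty_targets,
                  limbic = ifelse(feat_class == "limbic",
                                  cfg$puberty_effect_sd_units, 0),
                  all = rep(cfg$puberty_effect_sd_units, p),
                  none = rep(0, p))

  site_levels <- sort(unique(site_id))
  shift_sj <- matrix(rnorm(length(site_levels) * p, 0, cfg$site_shift_sd_units),
                     nrow = length(site_levels),
                     dimnames = list(site_levels, feat_names))
  scale_sj <- matrix(runif(length(site_levels) * p,
                           cfg$site_scale_range[1], cfg$site_scale_range[2]),
                     nrow = length(site_levels),
                     dimnames = list(site_levels, feat_names))

  u_i <- rnorm(n, 0, cfg$subject_re_sd)
  onset_i <- ifelse(sex == "F",
                    cfg$male_onset_age_months - cfg$female_onset_shift_months,
                    cfg$male_onset_age_months) +
    rnorm(n, 0, cfg$onset_jitter_sd_months)

  sessions <- c("baseline", "followup")[seq_len(min(cfg$n_sessions, 2))]
  if (cfg$n_sessions > 2) {
    stop("generator currently supports at most 2 sessions")
  }

  rows <- vector("list", length(sessions))
  mid_age <- mean(cfg$age_range_months)
  for (k in seq_along(sessions)) {
    age <- age_base + (k - 1) * (cfg$session_gap_months + rnorm(n, 0, 1.5))
    stage <- plogis((age - onset_i) / cfg$puberty_scale_months)
    slope <- ifelse(sex == "F",
                    cfg$age_slope_sd_units_per_year[["F"]],
                    -cfg$age_slope_sd_units_per_year[["M"]])
    pub_dir <- ifelse(sex == "F", 1, cfg$puberty_male_scale)
    agec_yr <- (age - mid_age) / 12

    step_j <- switch(cfg$puberty_targets,
                     limbic = ifelse(feat_class == "limbic",
                                     cfg$menarche_step_sd_units, 0),
                     all = rep(cfg$menarche_step_sd_units, p),
                     none = rep(0, p))
    post_menarche <- as.numeric(sex == "F" & stage > cfg$menarche_stage_threshold)
    fixed <- outer(as.numeric(sex == "F"), s_j * d_j) +
      outer(slope * agec_yr, s_j) +
      sweep(outer(pub_dir * (stage - 0.5), s_j), 2, pub_j, `*`) +
      sweep(outer(post_menarche, s_j), 2, step_j, `*`)
    eps <- matrix(rnorm(n * p, 0, cfg$noise_sd), n, p)
    z <- fixed + scale_sj[site_id, , drop = FALSE] * (u_i + eps) +
      shift_sj[site_id, , drop = FALSE]

    vols <- sweep(sweep(z, 2, sigma_j, `*`), 2, mu_j, `+`) +
      outer(etiv - etiv_f_mean, b_j)
    vols <- pmax(vols, 1)

    euler <- rnorm(n, cfg$euler_mean, cfg$euler_sd)
    bad <- runif(n) < cfg$euler_contamination
    euler[bad] <- euler[bad] - abs(rnorm(sum(bad), 0, 8 * cfg$euler_sd))

    df <- data.frame(subject_id = subject_id, session = sessions[k],
                     sex = sex, age_months = age, etiv_mm3 = etiv,
                     euler = round(euler), site_id = site_id,
                     family_id = family_id, stringsAsFactors = FALSE)
    df[feat_names] <- vols
    rows[[k]] <- list(df = df, stage = stage)
  }
  cohort <- do.call(rbind, lapply(rows, `[[`, "df"))
  rownames(cohort) <- NULL

  stage_mat <- do.call(cbind, lapply(rows, `[[`, "stage"))
  colnames(stage_mat) <- sessions

  # subject-level limbic female-typicality: mean signed deviation over limbic
  # features at baseline, in SD units (used to couple distress to brain sex)
  z_base <- sweep(sweep(.feature_matrix(rows[[1]]$df, feat_names), 2, mu_j, `-`),
                  2, sigma_j, `/`) -
    outer(rows[[1]]$df$etiv_mm3 - etiv_f_mean, b_j / sigma_j)
  limbic_proxy <- as.numeric(z_base[, feat_class == "limbic", drop = FALSE] %*%
                               (s_j[feat_class == "limbic"] / p_l))

  truth <- list(config = cfg, feature_class = setNames(feat_class, feat_names),
                female_direction = setNames(s_j, feat_names),
                sex_effect = setNames(d_j, feat_names),
                puberty_effect = setNames(pub_j, feat_names),
                menarche_step = setNames(step_j, feat_names),
                etiv_slope = setNames(b_j, feat_names),
                site_shift = shift_sj, site_scale = scale_sj,
                subject_re = setNames(u_i, subject_id),
                onset_age_months = setNames(onset_i, subject_id),
                puberty_stage = stage_mat,
                limbic_proxy = setNames(limbic_proxy, subject_id))
  attr(cohort, "truth") <- truth
  cohort
}

#' Generate Pubertal Development Scale responses for a cohort
#'
#' The latent pubertal stage is a logistic function of age with a
#' subject-specific onset (earlier in girls by
#' `config$female_onset_shift_months`). Items 1--4 are monotone
#' discretizations of the stage (1 = not started ... 4 = completed) with
#' subject-by-item noise that is constant across sessions, so scores never
#' regress with age. The menstruation item is binary (No = 1, Yes = 4) and
#' turns "yes" once the stage crosses a fixed threshold; it never reverts.
#'
#' @param cohort a [generate_cohort()] table (its truth record supplies the
#'   per-subject onset ages).
#' @param config the [cohort_config()] used to build `cohort`.
#' @return data frame `subject_id, session, p1..p5, menarche, reporter` with a
#'   `truth` attribute carrying the latent stages.
#' @export
generate_puberty <- function(cohort, config) {
  .assert_cohort(cohort, c("subject_id", "session", "sex", "age_months"))
  truth <- cohort_truth(cohort)
  if (is.null(truth)) stop("cohort has no truth record; use generate_cohort()")
  cfg <- config
  set.seed(.sub_seed(cfg$seed, "puberty"))

  subjects <- unique(cohort$subject_id)
  onset <- truth$onset_age_months[subjects]
  # item disagreement modelled as a per-subject-per-item timing shift
  # (months), constant across sessions: items stay monotone in age and stay
  # at the scale floor far below onset
  item_shift <- matrix(rnorm(length(subjects) * 5, 0, 6),
                       nrow = length(subjects),
                       dimnames = list(subjects, NULL))

  stage <- plogis((cohort$age_months - onset[cohort$subject_id]) /
                    cfg$puberty_scale_months)
  items <- matrix(NA_integer_, nrow(cohort), 4)
  for (j in 1:4) {
    val <- plogis((cohort$age_months - onset[cohort$subject_id] +
                     item_shift[cohort$subject_id, j]) /
                    cfg$puberty_scale_months)
    items[, j] <- 1L + findInterval(val, c(0.25, 0.5, 0.75))
  }
  menarche <- ifelse(cohort$sex == "F",
                     ifelse(stage > cfg$menarche_stage_threshold, "yes", "no"), NA_character_)
  val5 <- plogis((cohort$age_months - onset[cohort$subject_id] +
                    item_shift[cohort$subject_id, 5]) /
                   cfg$puberty_scale_months)
  p5 <- ifelse(cohort$sex == "F",
               ifelse(menarche == "yes", 4L, 1L),
               1L + findInterval(val5, c(0.25, 0.5, 0.75)))

  out <- data.frame(subject_id = cohort$subject_id, session = cohort$session,
                    p1 = items[, 1], p2 = items[, 2], p3 = items[, 3],
                    p4 = items[, 4], p5 = p5, menarche = menarche,
                    reporter = "self", stringsAsFactors = FALSE)
  attr(out, "truth") <- list(stage = stage, onset_age_months = onset)
  out
}

#' Generate questionnaire items loading on a latent distress factor
#'
#' One latent distress value per subject-session drives all items through
#' positive loadings plus item noise. In females, distress is constructed to
#' correlate `config$distress_limbic_coupling` with the supplied brain-sex
#' proxy (e.g. true limbic female-typicality, or a fitted limbic class
#' probability); in males the coupling is zero. Distress is stable across
#' sessions with correlation `config$distress_stability`.
#'
#' @param cohort a cohort table.
#' @param proxy numeric vector, one value per subject (named by subject id) or
#'   one per cohort row; defaults to the truth limbic proxy when available.
#' @param config the [cohort_config()].
#' @return data frame `subject_id, session, item_1..item_k`, with latent
#'   distress in the `truth` attribute.
#' @export
generate_questionnaire <- function(cohort, proxy = NULL, config) {
  .assert_cohort(cohort, c("subject_id", "session", "sex"))
  cfg <- config
  cpl <- cfg$distress_limbic_coupling
  if (abs(cpl) > 1) stop("distress_limbic_coupling must be in [-1, 1]")
  set.seed(.sub_seed(cfg$seed, "questionnaire"))

  subjects <- unique(cohort$subject_id)
  if (is.null(proxy)) {
    truth <- cohort_truth(cohort)
    if (is.null(truth)) stop("no proxy supplied and cohort has no truth record")
    proxy <- truth$limbic_proxy
  }
  if (is.null(names(proxy))) {
    if (length(proxy) == nrow(cohort)) {
      proxy <- tapply(proxy, cohort$subject_id, mean)[subjects]
    } else stop("proxy must be named by subject or aligned to cohort rows")
  }
  px <- as.numeric(scale(proxy[subjects]))
  sex_s <- cohort$sex[match(subjects, cohort$subject_id)]

  # session-level distress: coupled to the proxy in females (so the observed
  # corr(distress, proxy) targets the config value directly), with a stable
  # subject component giving cross-session correlation ~ distress_stability
  st <- cfg$distress_stability
  base <- rnorm(length(subjects))
  cpl_i <- ifelse(sex_s == "F", cpl, 0)
  row_cpl <- cpl_i[match(cohort$subject_id, subjects)]
  stable_part <- (sqrt(st) * base)[match(cohort$subject_id, subjects)] +
    sqrt(1 - st) * rnorm(nrow(cohort))
  distress <- row_cpl * px[match(cohort$subject_id, subjects)] +
    sqrt(pmax(1 - row_cpl^2, 0)) * stable_part
  subj_part <- cpl_i * px + sqrt(pmax(1 - cpl_i^2, 0)) * sqrt(st) * base

  loadings <- runif(cfg$n_items, 0.4, 0.8)
  items <- outer(distress, loadings) +
    matrix(rnorm(nrow(cohort) * cfg$n_items, 0, 0.8), ncol = cfg$n_items)
  colnames(items) <- sprintf("item_%02d", seq_len(cfg$n_items))

  out <- data.frame(subject_id = cohort$subject_id, session = cohort$session,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(items))
  attr(out, "truth") <- list(distress = distress, loadings = loadings,
                             subject_distress = setNames(subj_part, subjects))
  out
}
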