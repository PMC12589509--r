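# PDS scoring, menarche grouping, site filtering, LME fitting and the two
# ANOVA types, against OLS and hand-computed oracles.

test_that("pds_average follows the 1-4 item coding", {
  expect_equal(pds_average(c(1, 1, 1, 1, 1)), 1)
  expect_equal(pds_average(c(3, 3, 3, 3, 4)), 3.2)  # menstruation Yes = 4
  expect_equal(pds_average(c(2, 3, 3, 2, 4)), 2.8)
  expect_equal(pds_average(c(2, NA, 4)), 3)
  expect_error(pds_average(c(NA_real_, NA_real_)), "missing")
})

test_that("menarche grouping matches the two-group definition", {
  pub <- data.frame(
    subject_id = rep(c("a", "b", "c", "d", "e"), each = 2),
    session = rep(c("baseline", "followup"), 5),
    menarche = c("no", "no",   # a: no_no
                 "no", "yes",  # b: onset
                 "yes", "yes", # c: excluded
                 "yes", "no",  # d: excluded (reversion never generated)
                 "no", NA),    # e: excluded (missing follow-up)
    stringsAsFactors = FALSE)
  pub$menarche[10] <- NA
  g <- menarche_groups(pub)
  expect_identical(g$group[match(c("a", "b", "c", "d"), g$subject_id)],
                   c("no_no", "onset", "excluded", "excluded"))
  counts <- attr(g, "counts")
  expect_equal(unname(counts[c("no_no", "onset")]), c(1, 1),
               ignore_attr = TRUE)
})

test_that("site filter boundary sits exactly at min_n", {
  d <- data.frame(site_id = rep(c("big", "edge", "small"), c(30, 20, 19)),
                  x = 1)
  expect_message(out <- site_filter(d), "small")
  expect_setequal(unique(out$site_id), c("big", "edge"))
  expect_error(site_filter(d[d$site_id == "small", ][0, ]), "every")
})

test_that("model specs carry the fixed term orders", {
  expect_identical(model_spec("age_lme")$terms,
                   c("age_months", "session", "euler", "age_months:session"))
  expect_identical(model_spec("pds_lme", include_site = TRUE)$terms,
                   c("pds_average", "age_months", "euler", "site_id",
                     "pds_average:age_months"))
  expect_identical(model_spec("menarche_lme")$terms,
                   c("menarche_onset", "age_months", "session", "euler",
                     "menarche_onset:age_months", "menarche_onset:session"))
  expect_identical(model_spec("mh_lme")$terms,
                   c("mh_score", "age_months", "session", "euler",
                     "mh_score:age_months", "mh_score:session"))
  expect_null(model_spec("age_lm_training")$random)
})

test_that("pooled sexes are refused", {
  d <- data.frame(subject_id = rep(1:10, each = 2),
                  session = rep(c("baseline", "followup"), 10),
                  sex = rep(c("F", "M"), each = 10),
                  p_female = runif(20), age_months = rnorm(20, 130, 10),
                  euler = rnorm(20, -50, 5))
  expect_error(fit_lme(model_spec("age_lme"), d), "pooled sexes")
})

make_long_data <- function(n = 60, re_sd = 0, age_beta = 0, seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%03d", seq_len(n))
  age_b <- runif(n, 110, 160)
  u <- rnorm(n, 0, re_sd)
  d <- data.frame(
    subject_id = rep(subj, 2),
    session = factor(rep(c("baseline", "followup"), each = n),
                     levels = c("baseline", "followup")),
    sex = "F",
    age_months = c(age_b, age_b + 24),
    euler = rnorm(2 * n, -50, 8),
    stringsAsFactors = FALSE)
  d$p_female <- 0.5 + age_beta * (d$age_months - 135) +
    rep(u, 2) + rnorm(2 * n, 0, 0.08)
  d
}

test_that("with null subject variance the LME reduces to OLS", {
  d <- make_long_data(n = 300, re_sd = 0, age_beta = 0.002, seed = 2)
  fit <- fit_lme(model_spec("age_lme"), d)
  re_var <- as.numeric(nlme::VarCorr(fit$fit)[1, 1])
  res_var <- fit$fit$sigma^2
  # boundary ML estimate: small relative to residual variance, and far below
  # the estimate under a genuinely present random intercept
  expect_lt(re_var, 0.15 * res_var)  # ~2 sampling SDs of the null ICC
  d_re <- make_long_data(n = 300, re_sd = 0.3, age_beta = 0.002, seed = 2)
  fit_re <- fit_lme(model_spec("age_lme"), d_re)
  expect_gt(as.numeric(nlme::VarCorr(fit_re$fit)[1, 1]), 20 * re_var)

  ols <- lm(p_female ~ age_months + session + euler + age_months:session,
            data = d)
  expect_equal(unname(nlme::fixef(fit$fit)), unname(coef(ols)),
               tolerance = 0.02)
  # sequential F for the first term against the OLS anova oracle
  tab <- anova_sequential(fit)
  ols_tab <- anova(ols)
  expect_equal(tab$F[tab$term == "age_months"],
               ols_tab["age_months", "F value"], tolerance = 0.05)
})

test_that("single fixed effect with zero RE variance matches OLS F closely", {
  set.seed(3)
  n <- 50
  d <- data.frame(subject_id = sprintf("s%02d", 1:n), session = "baseline",
                  sex = "F", age_months = runif(n, 100, 200),
                  euler = rnorm(n, -50, 5), stringsAsFactors = FALSE)
  d$p_female <- 0.4 + 0.001 * d$age_months + rnorm(n, 0, 0.05)
  spec <- model_spec("age_lm_training")  # lm path: exact OLS
  fit <- fit_lme(spec, d)
  tab <- anova_sequential(fit)
  oracle <- anova(lm(p_female ~ age_months + euler, data = d))
  expect_equal(tab$F, oracle$`F value`[1:2], tolerance = 1e-6)
  expect_equal(tab$p, oracle$`Pr(>F)`[1:2], tolerance = 1e-6)
})

test_that("type I depends on formula order, type II does not", {
  set.seed(4)
  n <- 120
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + 0.6 * rnorm(n)  # correlated predictors
  d <- data.frame(subject_id = sprintf("s%03d", 1:n), session = "baseline",
                  sex = "F", p_female = 0.3 * x1 + rnorm(n, 0, 1),
                  age_months = x1, euler = x2, stringsAsFactors = FALSE)
  spec_a <- model_spec("age_lm_training")          # age before euler
  spec_b <- spec_a
  spec_b$terms <- rev(spec_b$terms)                # euler before age
  fa <- fit_lme(spec_a, d)
  fb <- fit_lme(spec_b, d)
  t1a <- anova_sequential(fa)
  t1b <- anova_sequential(fb)
  expect_gt(abs(t1a$F[t1a$term == "age_months"] -
                  t1b$F[t1b$term == "age_months"]), 1)
  t2a <- anova_marginal(fa)
  t2b <- anova_marginal(fb)
  expect_equal(t2a$F[t2a$term == "age_months"],
               t2b$F[t2b$term == "age_months"], tolerance = 1e-8)
})

test_that("orthogonal balanced designs give identical type I and II tables", {
  set.seed(5)
  n <- 64
  d <- data.frame(subject_id = sprintf("s%03d", 1:n), session = "baseline",
                  sex = "F",
                  age_months = rep(c(-1, 1), each = n / 2),
                  euler = rep(c(-1, 1), times = n / 2),
                  stringsAsFactors = FALSE)
  d$p_female <- 0.2 * d$age_months - 0.1 * d$euler + rnorm(n, 0, 0.5)
  fit <- fit_lme(model_spec("age_lm_training"), d)
  t1 <- anova_sequential(fit)
  t2 <- anova_marginal(fit)
  expect_equal(t1$F, t2$F, tolerance = 1e-8)
})

test_that("F statistics are invariant to affine outcome rescaling", {
  d <- make_long_data(n = 50, re_sd = 0.1, age_beta = 0.002, seed = 6)
  f1 <- anova_sequential(fit_lme(model_spec("age_lme"), d))
  d2 <- d
  d2$p_female <- 10 * d$p_female - 3
  f2 <- anova_sequential(fit_lme(model_spec("age_lme"), d2))
  expect_equal(f1$F, f2$F, tolerance = 1e-5)
})

test_that("LME recovers a known age slope in most seeds", {
  hits <- 0
  for (seed in 1:10) {
    d <- make_long_data(n = 80, re_sd = 0.1, age_beta = 0.003, seed = seed)
    fit <- fit_lme(model_spec("age_lme"), d)
    est <- nlme::fixef(fit$fit)[["age_months"]]
    se <- sqrt(diag(fit$fit$varFix))[["age_months"]]
    if (est > 0 && abs(est - 0.003) < 2.5 * se) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("BH adjustment equals step-up arithmetic", {
  res <- data.frame(term = letters[1:4], p = c(0.01, 0.02, 0.03, 0.04))
  adj <- adjust_pvalues(res, family = character(0))
  expect_equal(adj$p_adj, rep(0.04, 4))
  expect_equal(adjust_pvalues(data.frame(p = 0.3), character(0))$p_adj, 0.3)
  expect_equal(adjust_pvalues(data.frame(p = rep(1, 5)), character(0))$p_adj,
               rep(1, 5))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(12)
    got <- adjust_pvalues(data.frame(p = p), character(0))$p_adj
    expect_equal(got, bh_by_hand(p))
  }
  expect_error(adjust_pvalues(data.frame(p = 1.2), character(0)), "outside")
})
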