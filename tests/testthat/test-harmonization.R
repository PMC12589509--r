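# ComBat-style harmonization: closed-form cases, fit/apply contracts, and
# preservation of covariate effects.

make_sites <- function(n_per_site, shifts, seed = 1, p = 3) {
  set.seed(seed)
  n <- n_per_site * length(shifts)
  site <- rep(sprintf("site%02d", seq_along(shifts)), each = n_per_site)
  X <- matrix(rnorm(n * p), n, p) + shifts[rep(seq_along(shifts),
                                               each = n_per_site)]
  colnames(X) <- paste0("feat_", seq_len(p))
  df <- data.frame(subject_id = sprintf("s%04d", seq_len(n)),
                   session = "baseline", sex = rep_len(c("F", "M"), n),
                   age_months = runif(n, 100, 200),
                   etiv_mm3 = rnorm(n, 1.5e6, 1e5), euler = rnorm(n, -50, 10),
                   site_id = site, family_id = NA, stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X))
}

test_that("single site is an identity model (with a warning)", {
  co <- make_sites(40, shifts = 0)
  expect_warning(m <- fit_combat(co, covariates = character(0)), "one site")
  out <- apply_combat(m, co)
  expect_equal(as.matrix(out[, feature_names(out)]),
               as.matrix(co[, feature_names(co)]), tolerance = 1e-10)
})

test_that("a pure mean shift between two sites is removed", {
  co <- make_sites(60, shifts = c(0, 10), seed = 2)
  # location/scale estimates without shrinkage: exact closed-form removal
  m <- fit_combat(co, covariates = character(0), eb = FALSE)
  out <- apply_combat(m, co)
  for (f in feature_names(out)) {
    means <- tapply(out[[f]], out$site_id, mean)
    expect_lt(abs(diff(means)), 1e-6)
  }
  # with EB shrinkage the removal is exact when every feature carries the
  # same standardized shift (identical columns), and near-exact otherwise
  co2 <- make_sites(60, shifts = c(0, 10), seed = 2, p = 1)
  co2$feat_2 <- co2$feat_1
  co2$feat_3 <- co2$feat_1
  m2 <- fit_combat(co2, covariates = character(0))
  out2 <- apply_combat(m2, co2)
  expect_lt(abs(diff(tapply(out2$feat_1, out2$site_id, mean))), 1e-6)
  m3 <- fit_combat(co, covariates = character(0))
  out3 <- apply_combat(m3, co)
  for (f in feature_names(out3)) {
    expect_lt(abs(diff(tapply(out3[[f]], out3$site_id, mean))), 0.5)
  }
})

test_that("covariate effects survive harmonization", {
  # equal-size sex effect at both sites, sex declared as covariate
  set.seed(3)
  co <- make_sites(250, shifts = c(0, 5), seed = 3)
  sex_eff <- 0.8
  for (f in feature_names(co)) {
    co[[f]] <- co[[f]] + sex_eff * (co$sex == "F")
  }
  m <- fit_combat(co, covariates = "sex")
  out <- apply_combat(m, co)
  for (f in feature_names(out)) {
    before <- coef(lm(co[[f]] ~ co$sex + co$site_id))[["co$sexM"]]
    after <- coef(lm(out[[f]] ~ out$sex + out$site_id))[["out$sexM"]]
    expect_lt(abs(after - before) / abs(before), 0.1)
  }
})

test_that("apply contracts: refit consistency, empty input, unseen site", {
  co <- make_sites(30, shifts = c(0, 4), seed = 4)
  m <- fit_combat(co, covariates = character(0))
  out1 <- apply_combat(m, co)
  out2 <- apply_combat(m, co)
  expect_identical(out1, out2)
  expect_warning(apply_combat(m, out1), "already")

  empty <- co[0, , drop = FALSE]
  out0 <- apply_combat(m, empty)
  expect_equal(nrow(out0), 0)
  expect_identical(names(out0), names(co))

  co_bad <- co
  co_bad$site_id[1] <- "siteXX"
  expect_error(apply_combat(m, co_bad), "siteXX")
})

test_that("rank-deficient covariates are reported by name", {
  co <- make_sites(30, shifts = c(0, 4), seed = 5)
  co$age_copy <- co$age_months
  co <- co[, c(setdiff(names(co), feature_names(co))[1:8], "age_copy",
               grep("feat_", names(co), value = TRUE))]
  names(co)[1:8] <- c("subject_id", "session", "sex", "age_months",
                      "etiv_mm3", "euler", "site_id", "family_id")
  expect_error(fit_combat(co, covariates = c("age_months", "age_copy")),
               "age_copy")
})

test_that("variance is preserved within a factor of two", {
  co <- make_sites(100, shifts = c(0, 3, -2), seed = 6)
  m <- fit_combat(co, covariates = character(0))
  out <- apply_combat(m, co)
  for (f in feature_names(out)) {
    v_in <- mean(tapply(co[[f]], co$site_id, var))  # within-site variance
    v_out <- var(out[[f]])
    expect_gt(v_out / v_in, 0.5)
    expect_lt(v_out / v_in, 2)
  }
})

test_that("longitudinal variant removes site shifts without inflating variance", {
  set.seed(7)
  n <- 120
  subj <- rep(sprintf("s%03d", seq_len(n)), each = 2)
  site <- rep(sample(c("A", "B"), n, replace = TRUE), each = 2)
  u <- rep(rnorm(n, 0, 2), each = 2)
  x <- 5 * (site == "B") + u + rnorm(2 * n)
  co <- data.frame(subject_id = subj,
                   session = rep(c("baseline", "followup"), n),
                   sex = rep(rep_len(c("F", "M"), n), each = 2),
                   age_months = 120, etiv_mm3 = 1.5e6, euler = -50,
                   site_id = site, family_id = NA, feat_a = x,
                   feat_b = x + rnorm(2 * n), stringsAsFactors = FALSE)
  m <- fit_combat(co, covariates = character(0), variant = "longitudinal")
  out <- apply_combat(m, co)
  means <- tapply(out$feat_a, out$site_id, mean)
  expect_lt(abs(diff(means)), 0.5)  # shift of 5 removed up to noise
  # subject intercepts restored: within-subject correlation preserved
  expect_gt(cor(out$feat_a[c(TRUE, FALSE)], out$feat_a[c(FALSE, TRUE)]), 0.5)
  # no variance inflation from the round trip
  expect_lt(var(out$feat_a) / var(co$feat_a - 5 * (co$site_id == "B")), 1.5)
})

test_that("combat model survives a JSON round trip", {
  co <- make_sites(30, shifts = c(0, 4), seed = 8)
  m <- fit_combat(co, covariates = "sex")
  path <- withr::local_tempfile(fileext = ".json")
  write_combat(m, path)
  m2 <- read_combat(path)
  expect_equal(apply_combat(m2, co), apply_combat(m, co), tolerance = 1e-8)
})

test_that("null simulation: harmonization does not fabricate site effects", {
  # no true site effect; after harmonization the ANOVA site term should be
  # significant in at most ~10% of seeds (it is conservative in practice)
  hits <- 0
  for (seed in 1:20) {
    co <- make_sites(60, shifts = c(0, 0), seed = 100 + seed)
    m <- fit_combat(co, covariates = character(0))
    out <- apply_combat(m, co)
    p <- anova(lm(out$feat_1 ~ out$site_id))[["Pr(>F)"]][1]
    if (p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 2)
})
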