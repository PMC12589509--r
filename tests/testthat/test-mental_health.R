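# PCA distress score: fit, projection, orientation, cross-session
# correlation -- against hand-computed linear algebra.

make_items <- function(n, k, loading, noise_sd, seed = 1,
                       sessions = c("baseline", "followup")) {
  set.seed(seed)
  subj <- sprintf("s%03d", seq_len(n))
  out <- lapply(sessions, function(ss) {
    f <- rnorm(n)
    items <- outer(f, rep(loading, k)) + matrix(rnorm(n * k, 0, noise_sd),
                                                n, k)
    colnames(items) <- sprintf("item_%02d", seq_len(k))
    cbind(data.frame(subject_id = subj, session = ss,
                     stringsAsFactors = FALSE), as.data.frame(items))
  })
  do.call(rbind, out)
}

test_that("two perfectly correlated items give a rank-1 PC1", {
  it <- make_items(40, 2, loading = 1, noise_sd = 0, seed = 2)
  m <- fit_pc1(it)
  expect_equal(m$explained, 1, tolerance = 1e-10)
  expect_equal(abs(unname(m$loadings[1])), abs(unname(m$loadings[2])),
               tolerance = 1e-10)
})

test_that("explained variance matches the closed-form one-factor value", {
  # unit-loading factor + noise: communality = 1 / (1 + noise_sd^2), and PC1
  # of k standardized items explains (1 + (k-1) * rho) / k with
  # rho = communality
  k <- 8
  noise_sd <- 1
  rho <- 1 / (1 + noise_sd^2)
  expected <- (1 + (k - 1) * rho) / k
  it <- make_items(500, k, loading = 1, noise_sd = noise_sd, seed = 3)
  m <- fit_pc1(it)
  expect_lt(abs(m$explained - expected), 0.05)
})

test_that("orientation rule is deterministic and positive", {
  it <- make_items(60, 5, loading = 0.8, noise_sd = 0.5, seed = 4)
  m <- fit_pc1(it)
  expect_true(all(m$loadings > 0))
  # score correlates positively with every item
  base <- it[it$session == "baseline", ]
  for (col in m$items) {
    expect_gt(cor(m$scores$mh_score, base[[col]]), 0)
  }
})

test_that("projection identities", {
  it <- make_items(50, 4, loading = 0.7, noise_sd = 0.6, seed = 5)
  m <- fit_pc1(it)
  self <- project_pc1(m, it[it$session == "baseline", ])
  expect_equal(self$mh_score, m$scores$mh_score, tolerance = 1e-12)

  # answering exactly the baseline item means scores 0
  means_row <- it[1, , drop = FALSE]
  means_row[m$items] <- as.list(m$mean)
  expect_equal(project_pc1(m, means_row)$mh_score, 0, tolerance = 1e-12)

  # 2-item toy: equal loadings 1/sqrt(2), standardized responses (1, -1)
  it2 <- make_items(30, 2, loading = 1, noise_sd = 0.4, seed = 6)
  m2 <- fit_pc1(it2)
  row <- it2[1, , drop = FALSE]
  row$item_01 <- m2$mean[1] + m2$sd[1]
  row$item_02 <- m2$mean[2] - m2$sd[2]
  expect_equal(project_pc1(m2, row)$mh_score,
               unname(m2$loadings[1] - m2$loadings[2]), tolerance = 1e-10)
  expect_equal(unname(abs(m2$loadings)), rep(1 / sqrt(2), 2),
               tolerance = 0.05)
})

test_that("scores are invariant to item column order", {
  it <- make_items(40, 5, loading = 0.8, noise_sd = 0.5, seed = 7)
  m1 <- fit_pc1(it)
  shuffled <- it[, c("subject_id", "session", sample(m1$items))]
  m2 <- fit_pc1(shuffled)
  expect_equal(m2$scores$mh_score, m1$scores$mh_score, tolerance = 1e-10)
})

test_that("zero-variance item is an error, by name", {
  it <- make_items(30, 3, loading = 0.7, noise_sd = 0.5, seed = 8)
  it$item_02 <- 1
  expect_error(fit_pc1(it), "item_02")
})

test_that("session correlation equals the covariance-formula oracle", {
  b <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  f <- c(0.8, -0.2, 0.6, 1.5, -0.9)
  got <- session_correlation(b, f)
  r <- sum((b - mean(b)) * (f - mean(f))) /
    sqrt(sum((b - mean(b))^2) * sum((f - mean(f))^2))
  t <- r * sqrt(3 / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$t, t, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t), 3), tolerance = 1e-12)

  ident <- session_correlation(b, b)
  expect_equal(ident$r, 1)
  expect_error(session_correlation(b, rep(1, 5)), "zero variance")
  expect_error(session_correlation(b[1:2], f[1:2]), "at least 3")
})

test_that("cross-session stability propagates through the projection", {
  cfg <- cohort_config(n_subjects = 300, n_features_limbic = 4,
                       n_features_nonlimbic = 4, distress_stability = 0.5,
                       seed = 9)
  co <- generate_cohort(cfg)
  it <- generate_questionnaire(co, config = cfg)
  m <- fit_pc1(it)
  fup <- project_pc1(m, it[it$session == "followup", ])
  r <- session_correlation(m$scores, fup)$r
  expect_gt(r, 0.35)
  expect_lt(r, 0.65)
})

test_that("stronger distress-limbic coupling raises the limbic mh F in females", {
  # one cohort and one probability readout; only the questionnaire varies
  base_cfg <- function(cpl) {
    cohort_config(n_subjects = 400, n_sites = 2, n_features_limbic = 8,
                  n_features_nonlimbic = 8, distress_limbic_coupling = cpl,
                  distress_stability = 0.9,  # mostly subject-stable distress
                  seed = 55)
  }
  co <- generate_cohort(base_cfg(0))
  truth <- cohort_truth(co)
  # stand-in limbic readout: noisy monotone transform of the true signature
  set.seed(99)
  proxy <- truth$limbic_proxy + rnorm(length(truth$limbic_proxy), 0, 0.3)
  probs <- data.frame(subject_id = co$subject_id, session = co$session,
                      feature_set = "limbic",
                      p_female = plogis(proxy[co$subject_id] +
                                          1.5 * (co$sex == "F") - 0.75 +
                                          rnorm(nrow(co), 0, 0.3)))
  Fs <- vapply(c(0, 0.3, 0.6), function(cpl) {
    it <- generate_questionnaire(co, proxy = proxy, config = base_cfg(cpl))
    pc <- fit_pc1(it)
    mh <- rbind(pc$scores, project_pc1(pc, it[it$session == "followup", ]))
    res <- suppressMessages(suppressWarnings(
      run_association("mh", probs, co, mh_scores = mh)))
    res$F[res$term == "mh_score" & res$anova_type == "I" & res$sex == "F"]
  }, numeric(1))
  expect_true(all(diff(Fs) > 0))
})
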