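# Location/scale multi-site harmonization with empirical-Bayes shrinkage.
#
# Standard parametric ComBat: per-feature standardization against a covariate
# model fitted jointly with site indicators, per-(feature, site) location
# (gamma) and scale (delta^2) estimates shrunk toward normal / inverse-gamma
# priors by the usual iterative conditional scheme, then back-transformation.
# The longitudinal variant removes an estimated subject intercept (the
# subject's deviation from its site mean, after covariates) before the site
# estimation and restores it afterwards, so repeated measures do not inflate
# the site scale estimates.

# iterative EB solution for one site (gamma*, delta*^2)
.combat_it_sol <- function(z_site, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                           conv = 1e-8) {
  n <- colSums(!is.na(z_site))
  g_old <- g_hat
  d_old <- d_hat
  repeat {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums(sweep(z_site, 2, g_new, `-`)^2, na.rm = TRUE)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(g_star = g_new, d_star = d_new)
}

.combat_aprior <- function(d_hat) {
  m <- mean(d_hat); s2 <- var(d_hat)
  (2 * s2 + m^2) / s2
}
.combat_bprior <- function(d_hat) {
  m <- mean(d_hat); s2 <- var(d_hat)
  (m * s2 + m^3) / s2
}

.covariate_design <- function(cohort, covariates) {
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  }
  missing <- setdiff(covariates, names(cohort))
  if (length(missing) > 0) {
    stop("covariate column(s) not in cohort: ", paste(missing, collapse = ", "))
  }
  fml <- as.formula(paste("~", paste(covariates, collapse = " + ")))
  mm <- model.matrix(fml, data = cohort)
  mm[, -1, drop = FALSE]  # drop intercept; handled by site means
}

# estimated subject intercepts: subject mean residual minus site mean residual
.subject_intercepts <- function(resid_mat, subject_id, site_id) {
  subj_mean <- apply(resid_mat, 2, function(v) ave(v, subject_id))
  site_mean <- apply(resid_mat, 2, function(v) ave(v, site_id))
  subj_mean - site_mean
}

#' Fit a ComBat harmonization model
#'
#' Estimates per-feature, per-site location and scale adjustments with
#' empirical-Bayes shrinkage, preserving the effects of the given covariates.
#' The `longitudinal` variant first absorbs a subject-level intercept so that
#' repeated sessions of the same subject do not masquerade as site variance.
#'
#' @param cohort cohort data frame (see [feature_names()]).
#' @param covariates character vector of metadata columns whose effects must
#'   be preserved (e.g. `c("sex", "age_months")`).
#' @param variant `"cross_sectional"` or `"longitudinal"`.
#' @param eb use empirical-Bayes shrinkage of the site parameters (default);
#'   `FALSE` uses the raw per-site location/scale estimates, which removes a
#'   pure mean shift exactly.
#' @return a `combat_model` object; pass to [apply_combat()].
#' @export
fit_combat <- function(cohort, covariates = c("sex", "age_months"),
                       variant = c("cross_sectional", "longitudinal"),
                       eb = TRUE) {
  variant <- match.arg(variant)
  .assert_cohort(cohort, c("subject_id", "site_id"))
  feats <- feature_names(cohort)
  X <- .feature_matrix(cohort, feats)
  site <- as.character(cohort$site_id)
  sites <- sort(unique(site))
  n_obs <- nrow(X)

  single_site <- length(sites) < 2
  if (single_site) {
    warning("only one site present; fitting an identity harmonization model")
  } else if (min(table(site)) < 2) {
    stop("every site needs at least 2 observations")
  }

  C <- .covariate_design(cohort, covariates)
  site_mm <- 1 * outer(site, sites, `==`)  # one-hot, no contrasts machinery
  colnames(site_mm) <- sites
  design <- cbind(site_mm, C)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[seq.int(qrd$rank + 1, ncol(design))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrd, X)
  B_cov <- B[-seq_along(sites), , drop = FALSE]

  cov_part <- if (ncol(C) > 0) C %*% B_cov else matrix(0, n_obs, length(feats))
  resid0 <- X - cov_part  # covariate-adjusted data (site + subject + noise)

  subj_int <- NULL
  if (variant == "longitudinal") {
    subj_int <- .subject_intercepts(resid0, cohort$subject_id, site)
    resid0 <- resid0 - subj_int
  }

  # site locations, grand mean and pooled variance on the (possibly
  # subject-centered) covariate-adjusted data, so the scale step measures
  # exactly the variation it will restore
  n_site <- as.numeric(table(factor(site, levels = sites)))
  site_means <- apply(resid0, 2, function(v) tapply(v, factor(site, sites), mean))
  if (length(sites) == 1) site_means <- matrix(site_means, nrow = 1)
  dimnames(site_means) <- list(sites, feats)
  alpha <- crossprod(n_site / n_obs, site_means)[1, ]
  var_pooled <- colSums((resid0 - site_means[site, , drop = FALSE])^2) / n_obs
  var_pooled[var_pooled <= 0] <- 1e-12

  Z <- sweep(sweep(resid0, 2, alpha, `-`), 2, sqrt(var_pooled), `/`)

  gamma_star <- matrix(0, length(sites), length(feats),
                       dimnames = list(sites, feats))
  delta_star <- matrix(1, length(sites), length(feats),
                       dimnames = list(sites, feats))
  if (!single_site) {
    for (s in sites) {
      zs <- Z[site == s, , drop = FALSE]
      g_hat <- colMeans(zs)
      d_hat <- apply(zs, 2, var)
      d_hat[!is.finite(d_hat) | d_hat <= 0] <- 1e-8
      if (eb && length(feats) >= 2 && var(g_hat) > 0) {
        sol <- .combat_it_sol(zs, g_hat, d_hat,
                              g_bar = mean(g_hat), t2 = var(g_hat),
                              a_prior = .combat_aprior(d_hat),
                              b_prior = .combat_bprior(d_hat))
        gamma_star[s, ] <- sol$g_star
        delta_star[s, ] <- sol$d_star
      } else {
        gamma_star[s, ] <- g_hat
        delta_star[s, ] <- d_hat
      }
    }
  }

  model <- list(variant = variant, eb = eb, covariates = covariates,
                sites = sites,
                features = feats, alpha = alpha, var_pooled = var_pooled,
                B_cov = B_cov, gamma_star = gamma_star,
                delta_star = delta_star, single_site = single_site)
  class(model) <- "combat_model"
  model
}

#' Apply a fitted ComBat model to a cohort
#'
#' Adjusts the feature columns; all metadata is returned untouched. Applying
#' a model to an already-harmonized table raises a warning (harmonization is
#' not idempotent). Sites unseen at fit time are an error.
#'
#' @param model a [fit_combat()] model.
#' @param cohort cohort data frame containing the model's features.
#' @return harmonized cohort with attribute `harmonized = TRUE`.
#' @export
apply_combat <- function(model, cohort) {
  stopifnot(inherits(model, "combat_model"))
  if (isTRUE(attr(cohort, "harmonized"))) {
    warning("cohort appears to be harmonized already; applying again")
  }
  if (nrow(cohort) == 0) {
    out <- cohort
    attr(out, "harmonized") <- TRUE
    return(out)
  }
  missing <- setdiff(model$features, names(cohort))
  if (length(missing) > 0) {
    stop("cohort lacks model feature(s): ", paste(missing, collapse = ", "))
  }
  site <- as.character(cohort$site_id)
  unseen <- setdiff(unique(site), model$sites)
  if (length(unseen) > 0) {
    stop("site(s) unseen at fit time: ", paste(unseen, collapse = ", "))
  }

  X <- .feature_matrix(cohort, model$features)
  C <- .covariate_design(cohort, model$covariates)
  cov_part <- if (ncol(C) > 0) C %*% model$B_cov else
    matrix(0, nrow(X), length(model$features))
  resid0 <- X - cov_part

  subj_int <- NULL
  if (model$variant == "longitudinal") {
    subj_int <- .subject_intercepts(resid0, cohort$subject_id, site)
    resid0 <- resid0 - subj_int
  }

  Z <- sweep(sweep(resid0, 2, model$alpha, `-`), 2,
             sqrt(model$var_pooled), `/`)
  Zadj <- (Z - model$gamma_star[site, , drop = FALSE]) /
    sqrt(model$delta_star[site, , drop = FALSE])
  Xadj <- sweep(sweep(Zadj, 2, sqrt(model$var_pooled), `*`), 2,
                model$alpha, `+`) + cov_part
  if (!is.null(subj_int)) Xadj <- Xadj + subj_int

  out <- cohort
  out[model$features] <- Xadj
  attr(out, "harmonized") <- TRUE
  attr(out, "truth") <- attr(cohort, "truth")
  out
}

#' Serialize / restore a ComBat model as JSON
#'
#' @param model a `combat_model`.
#' @param path file path.
#' @return `read_combat` returns the restored model.
#' @export
write_combat <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_combat
#' @export
read_combat <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  # column-major serialization reads back transposed
  for (nm in c("gamma_star", "delta_star")) {
    m[[nm]] <- matrix(t(m[[nm]]), nrow = length(m$sites),
                      dimnames = list(m$sites, m$features))
  }
  m$B_cov <- if (length(m$B_cov) == 0) {
    matrix(numeric(0), 0, length(m$features),
           dimnames = list(NULL, m$features))
  } else {
    matrix(t(m$B_cov), ncol = length(m$features),
           dimnames = list(NULL, m$features))
  }
  m$alpha <- setNames(as.numeric(m$alpha), m$features)
  m$var_pooled <- setNames(as.numeric(m$var_pooled), m$features)
  class(m) <- "combat_model"
  m
}
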