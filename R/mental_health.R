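# General distress score: PC1 of questionnaire items at baseline, projected
# to follow-up with the baseline loadings and standardization moments.

#' Fit the baseline principal component model
#'
#' Items are standardized by their baseline means and SDs (correlation PCA:
#' the instruments pooled here use different response scales), PC1 is taken
#' as the general score, and its sign is oriented so the score correlates
#' positively with the items (the loading-sum rule; for a one-factor battery
#' all loadings then come out positive).
#'
#' @param items item table (`subject_id, session, item_*`); only rows with
#'   `session == "baseline"` are used, listwise-complete.
#' @return a `pc_model`: baseline moments, unit-norm PC1 loadings, explained
#'   variance fraction, and `scores` (data frame for the fitted rows).
#' @export
fit_pc1 <- function(items) {
  item_cols <- grep("^item_", names(items), value = TRUE)
  if (length(item_cols) < 2) stop("need at least 2 items")
  base <- items[items$session == "baseline", , drop = FALSE]
  cc <- complete.cases(base[, item_cols])
  if (sum(!cc) > 0) {
    message("fit_pc1: dropping ", sum(!cc), " incomplete baseline row(s)")
  }
  base <- base[cc, , drop = FALSE]
  if (nrow(base) < 3) stop("need at least 3 complete baseline rows")
  X <- as.matrix(base[, item_cols])
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  zero <- item_cols[sdev == 0]
  if (length(zero) > 0) {
    stop("zero-variance item(s): ", paste(zero, collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu, `-`), 2, sdev, `/`)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation[, 1]
  if (sum(loadings) < 0) loadings <- -loadings  # deterministic orientation
  scores <- as.numeric(Z %*% loadings)
  explained <- pc$sdev[1]^2 / sum(pc$sdev^2)
  model <- structure(list(items = item_cols, mean = mu, sd = sdev,
                          loadings = loadings, explained = explained),
                     class = "pc_model")
  model$scores <- data.frame(subject_id = base$subject_id,
                             session = base$session, mh_score = scores,
                             stringsAsFactors = FALSE)
  model
}

#' Project items onto the baseline component
#'
#' Standardizes with the *baseline* means/SDs (never refit), then takes the
#' dot product with the stored loadings. Projecting the baseline rows
#' reproduces the fit-time scores exactly.
#'
#' @param model a [fit_pc1()] model.
#' @param items item table for any session.
#' @return data frame `subject_id, session, mh_score`.
#' @export
project_pc1 <- function(model, items) {
  stopifnot(inherits(model, "pc_model"))
  missing <- setdiff(model$items, names(items))
  if (length(missing) > 0) {
    stop("item(s) absent: ", paste(missing, collapse = ", "))
  }
  cc <- complete.cases(items[, model$items])
  if (sum(!cc) > 0) {
    message("project_pc1: dropping ", sum(!cc), " incomplete row(s)")
  }
  items <- items[cc, , drop = FALSE]
  Z <- sweep(sweep(as.matrix(items[, model$items]), 2, model$mean, `-`),
             2, model$sd, `/`)
  data.frame(subject_id = items$subject_id, session = items$session,
             mh_score = as.numeric(Z %*% model$loadings),
             stringsAsFactors = FALSE)
}

#' Cross-session correlation of component scores
#'
#' Pearson correlation between baseline and follow-up scores paired by
#' subject, with the exact t-test (`t = r * sqrt((n - 2) / (1 - r^2))`).
#'
#' @param baseline,followup score tables (`subject_id, mh_score`) or numeric
#'   vectors already paired.
#' @return list `r, t, p, n`.
#' @export
session_correlation <- function(baseline, followup) {
  if (is.data.frame(baseline)) {
    ids <- intersect(baseline$subject_id, followup$subject_id)
    b <- baseline$mh_score[match(ids, baseline$subject_id)]
    f <- followup$mh_score[match(ids, followup$subject_id)]
  } else {
    if (length(baseline) != length(followup)) stop("unpaired score vectors")
    b <- baseline; f <- followup
  }
  n <- length(b)
  if (n < 3) stop("need at least 3 paired scores")
  if (sd(b) == 0 || sd(f) == 0) stop("zero variance in a score vector")
  r <- cor(b, f)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), df = n - 2)
  list(r = r, t = t, p = p, n = n)
}
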