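# Gradient-boosted sex classification with nested cross-validation.
#
# The boosting backend is a second-order (Newton) tree booster with logistic
# loss implemented in C++ (src/boost.cpp). The nested scheme: the outer
# 5-fold loop yields out-of-fold class probabilities and the cross-validated
# AUC; within each outer training split an inner 5-fold loop tracks the
# validation log-loss per boosting iteration, and the iteration minimizing
# the mean inner curve becomes that fold's round count. The final model is
# refit on all data for the median of the per-fold optima.

#' Boosting hyperparameters
#'
#' Only the learning rate and the initial round count are first-class study
#' parameters; the remaining knobs are backend defaults, recorded verbatim in
#' the fitted model so a run is fully reproducible.
#'
#' @param eta learning rate (default 0.01).
#' @param initial_rounds boosting iterations explored by the inner loop
#'   (default 1000).
#' @param outer_folds,inner_folds cross-validation folds (default 5 / 5).
#' @param max_depth tree depth (backend default 3).
#' @param lambda L2 leaf regularization (backend default 1).
#' @param min_child_weight minimum hessian per leaf (backend default 1).
#' @param seed governs fold assignment.
#' @return a `training_params` list.
#' @export
training_params <- function(eta = 0.01, initial_rounds = 1000,
                            outer_folds = 5, inner_folds = 5,
                            max_depth = 3, lambda = 1, min_child_weight = 1,
                            seed = 1L) {
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  if (initial_rounds < 1) stop("initial_rounds must be >= 1")
  if (outer_folds < 2 || inner_folds < 2) stop("folds must be >= 2")
  structure(list(eta = eta, initial_rounds = as.integer(initial_rounds),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 max_depth = as.integer(max_depth), lambda = lambda,
                 min_child_weight = min_child_weight, seed = as.integer(seed)),
            class = "training_params")
}

# stratified fold ids: both classes represented in every fold
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.encode_labels <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.numeric(sex))
  }
  if (!all(sex %in% c("F", "M"))) stop("sex labels must be 'F'/'M' (or 0/1)")
  as.numeric(sex == "F")  # males = 0, females = 1
}

.fit_booster <- function(X, y, params, nrounds, Xval = NULL, yval = NULL) {
  .boost_train_cpp(X, y, as.integer(nrounds), params$eta, params$max_depth,
                   params$lambda, params$min_child_weight, Xval, yval)
}

#' Train a sex classifier with nested cross-validation
#'
#' @param cohort residualized cohort (one row per subject) or a numeric
#'   feature matrix.
#' @param labels optional labels; defaults to `cohort$sex`. Coded males = 0,
#'   females = 1.
#' @param params a [training_params()].
#' @param feature_set label stored in the model (e.g. `"limbic"`).
#' @return a `sex_model`: fitted ensemble, `optimal_rounds`, per-outer-fold
#'   round optima, fold assignment, out-of-fold probability table (`oof`) and
#'   cross-validated AUC (`cv_auc`).
#' @export
train_nested_cv <- function(cohort, labels = NULL, params = training_params(),
                            feature_set = "whole_brain") {
  if (is.data.frame(cohort)) {
    labels <- labels %||% cohort$sex
    X <- .feature_matrix(cohort)
    ids <- cohort$subject_id %||% as.character(seq_len(nrow(X)))
  } else {
    X <- as.matrix(cohort)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  if (is.null(labels)) stop("labels required")
  y <- .encode_labels(labels)
  n <- length(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (n < params$outer_folds) stop("fewer rows than outer folds")

  outer_fold <- .stratified_folds(y, params$outer_folds,
                                  .sub_seed(params$seed, "outer"))
  oof <- rep(NA_real_, n)
  best_rounds <- integer(params$outer_folds)
  for (f in seq_len(params$outer_folds)) {
    tr <- which(outer_fold != f)
    te <- which(outer_fold == f)
    inner_fold <- .stratified_folds(y[tr], params$inner_folds,
                                    .sub_seed(params$seed, paste0("inner", f)))
    loss <- matrix(NA_real_, params$initial_rounds, params$inner_folds)
    for (g in seq_len(params$inner_folds)) {
      itr <- tr[inner_fold != g]
      iva <- tr[inner_fold == g]
      fit <- .fit_booster(X[itr, , drop = FALSE], y[itr], params,
                          params$initial_rounds,
                          X[iva, , drop = FALSE], y[iva])
      loss[, g] <- fit$val_loss
    }
    best_rounds[f] <- which.min(rowMeans(loss))
    fit_f <- .fit_booster(X[tr, , drop = FALSE], y[tr], params, best_rounds[f])
    oof[te] <- .boost_predict_cpp(fit_f$trees, X[te, , drop = FALSE],
                                  params$eta, best_rounds[f])
  }
  optimal_rounds <- as.integer(round(stats::median(best_rounds)))
  final <- .fit_booster(X, y, params, optimal_rounds)

  oof_table <- data.frame(subject_id = ids, feature_set = feature_set,
                          p_female = oof, sex = ifelse(y == 1, "F", "M"),
                          outer_fold = outer_fold, stringsAsFactors = FALSE)
  gain <- setNames(final$feature_gain, colnames(X))
  structure(list(trees = final$trees, eta = params$eta,
                 optimal_rounds = optimal_rounds, best_rounds = best_rounds,
                 params = params, features = colnames(X),
                 feature_set = feature_set, label_coding = c(M = 0, F = 1),
                 feature_gain = gain, oof = oof_table,
                 cv_auc = roc_auc(oof, y)),
            class = "sex_model")
}

#' Predict the brain-sex continuum for new scans
#'
#' Rows are scored independently (longitudinal sessions of one subject are
#' scored separately, with no pooling).
#'
#' @param object a `sex_model`.
#' @param cohort cohort data frame (or matrix) carrying the model's features.
#' @param ... unused.
#' @return data frame `subject_id, session, feature_set, p_female`.
#' @export
predict.sex_model <- function(object, cohort, ...) {
  if (is.data.frame(cohort)) {
    feats <- feature_names(cohort)
    ids <- cohort$subject_id %||% as.character(seq_len(nrow(cohort)))
    session <- cohort$session %||% rep(NA_character_, nrow(cohort))
  } else {
    feats <- colnames(cohort)
    ids <- rownames(cohort) %||% as.character(seq_len(nrow(cohort)))
    session <- rep(NA_character_, nrow(cohort))
  }
  missing <- setdiff(object$features, feats)
  extra <- setdiff(feats, object$features)
  if (length(missing) > 0) {
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  }
  if (is.data.frame(cohort) && length(extra) > 0) {
    cohort <- cohort[, c(intersect(.meta_cols, names(cohort)),
                         object$features), drop = FALSE]
  } else if (!is.data.frame(cohort) && length(extra) > 0) {
    stop("extra feature(s): ", paste(extra, collapse = ", "))
  }
  X <- if (is.data.frame(cohort)) .feature_matrix(cohort, object$features)
       else as.matrix(cohort)[, object$features, drop = FALSE]
  p <- .boost_predict_cpp(object$trees, X, object$eta, object$optimal_rounds)
  data.frame(subject_id = ids, session = session,
             feature_set = object$feature_set, p_female = p,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability via midranks, so tied
#' scores contribute 1/2.
#'
#' @param probs numeric scores (higher = more female-like).
#' @param labels 0/1 or "M"/"F".
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probs, labels) {
  y <- .encode_labels(labels)
  if (length(unique(y)) < 2) stop("AUC undefined with a single class")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gain-based feature contributions
#'
#' Total split gain accumulated per feature across the final ensemble,
#' normalized to sum to one, in descending order.
#'
#' @param model a `sex_model`.
#' @return data frame `feature, gain_share`, descending.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "sex_model"))
  g <- model$feature_gain
  if (sum(g) <= 0) {
    share <- rep(0, length(g))
  } else {
    share <- g / sum(g)
  }
  out <- data.frame(feature = names(g), gain_share = as.numeric(share),
                    stringsAsFactors = FALSE)
  out[order(-out$gain_share, out$feature), , drop = FALSE]
}

#' Top-k overlap between two importance rankings
#'
#' @param rank_a,rank_b character vectors of feature names in rank order (or
#'   [feature_importance()] tables).
#' @param k depth of the comparison.
#' @return fraction of shared features among the top k, in \[0, 1\].
#' @export
importance_overlap <- function(rank_a, rank_b, k) {
  if (is.data.frame(rank_a)) rank_a <- rank_a$feature
  if (is.data.frame(rank_b)) rank_b <- rank_b$feature
  if (length(rank_a) == 0 || length(rank_b) == 0) stop("empty ranking")
  if (k > min(length(rank_a), length(rank_b))) {
    stop("k exceeds the shared feature universe")
  }
  length(intersect(head(rank_a, k), head(rank_b, k))) / k
}
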