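# Limbic / non-limbic feature partition and per-feature eTIV residualization.

#' Build a feature partition
#'
#' A partition assigns every feature to exactly one of two disjoint classes,
#' `limbic` or `nonlimbic`; `whole_brain` is their union.
#'
#' @param limbic,nonlimbic character vectors of feature names.
#' @return a `feature_partition` object.
#' @export
feature_partition <- function(limbic, nonlimbic) {
  if (length(intersect(limbic, nonlimbic)) > 0) {
    stop("limbic and nonlimbic sets overlap: ",
         paste(intersect(limbic, nonlimbic), collapse = ", "))
  }
  if (anyDuplicated(c(limbic, nonlimbic)) > 0) stop("duplicate feature names")
  structure(list(limbic = limbic, nonlimbic = nonlimbic,
                 whole_brain = c(limbic, nonlimbic)),
            class = "feature_partition")
}

#' The default whole-brain partition registry
#'
#' The volumetric segmentation stack this package targets yields 493 regional
#' volumes, of which 160 belong to the limbic system (hormone-receptor-rich,
#' emotion-related structures: hippocampal and amygdalar subfields, limbic
#' cortex, thalamic nuclei, ...) and 333 do not. The anatomical names live in
#' the segmentation atlases; this registry ships placeholder names of the
#' right sizes so code paths that depend only on set structure are exercised.
#'
#' @param n_limbic,n_nonlimbic set sizes; defaults 160 / 333.
#' @return a [feature_partition()].
#' @export
default_partition <- function(n_limbic = 160, n_nonlimbic = 333) {
  feature_partition(sprintf("limbic_%03d", seq_len(n_limbic)),
                    sprintf("nonlimbic_%03d", seq_len(n_nonlimbic)))
}

#' Partition implied by a cohort's feature names
#'
#' Uses the `limbic_*` / `nonlimbic_*` naming convention of the synthetic
#' generator (or a truth record when present).
#'
#' @param cohort cohort data frame.
#' @return a [feature_partition()].
#' @export
partition_from_cohort <- function(cohort) {
  feats <- feature_names(cohort)
  truth <- cohort_truth(cohort)
  if (!is.null(truth$feature_class)) {
    cls <- truth$feature_class[feats]
    return(feature_partition(feats[cls == "limbic"], feats[cls == "nonlimbic"]))
  }
  feature_partition(grep("^limbic_", feats, value = TRUE),
                    grep("^nonlimbic_", feats, value = TRUE))
}

#' Regress head size out of every feature
#'
#' Ordinary least squares of each feature on {1, eTIV} within the given
#' cohort; residuals replace the feature values and the eTIV column is kept
#' as metadata. Fit per cohort by default; pass a previously fitted `model`
#' to transfer coefficients instead (sensitivity mode).
#'
#' @param cohort cohort data frame with `etiv_mm3`.
#' @param model optional `residualization_model` to apply instead of refitting.
#' @return list with `cohort` (residualized) and `model` (per-feature
#'   intercept and eTIV slope).
#' @export
residualize_etiv <- function(cohort, model = NULL) {
  .assert_cohort(cohort, "subject_id")
  if (!"etiv_mm3" %in% names(cohort)) stop("cohort has no etiv_mm3 column")
  feats <- feature_names(cohort)
  X <- .feature_matrix(cohort, feats)
  if (is.null(model)) {
    if (sd(cohort$etiv_mm3) == 0) {
      stop("eTIV has zero variance; slope undefined")
    }
    D <- cbind(1, cohort$etiv_mm3)
    qrd <- qr(D)
    B <- qr.coef(qrd, X)
    R <- qr.resid(qrd, X)
    model <- structure(list(intercept = B[1, ], slope = B[2, ],
                            features = feats),
                       class = "residualization_model")
  } else {
    stopifnot(inherits(model, "residualization_model"))
    missing <- setdiff(model$features, feats)
    if (length(missing) > 0) {
      stop("cohort lacks model feature(s): ", paste(missing, collapse = ", "))
    }
    feats <- model$features
    X <- .feature_matrix(cohort, feats)
    R <- X - outer(rep(1, nrow(X)), model$intercept) -
      outer(cohort$etiv_mm3, model$slope)
  }
  out <- cohort
  out[feats] <- R
  attr(out, "truth") <- attr(cohort, "truth")
  attr(out, "residualized") <- TRUE
  list(cohort = out, model = model)
}

#' Restrict a cohort to one feature set
#'
#' @param cohort cohort data frame.
#' @param partition a [feature_partition()].
#' @param set_id `"limbic"`, `"nonlimbic"` or `"whole_brain"`.
#' @return the cohort with metadata plus only that set's feature columns.
#' @export
select_features <- function(cohort, partition,
                            set_id = c("limbic", "nonlimbic", "whole_brain")) {
  stopifnot(inherits(partition, "feature_partition"))
  set_id <- match.arg(set_id)
  wanted <- partition[[set_id]]
  missing <- setdiff(wanted, names(cohort))
  if (length(missing) > 0) {
    stop("feature(s) absent from cohort: ", paste(missing, collapse = ", "))
  }
  out <- cohort[, c(intersect(.meta_cols, names(cohort)), wanted),
                drop = FALSE]
  attr(out, "truth") <- attr(cohort, "truth")
  attr(out, "residualized") <- attr(cohort, "residualized")
  out
}
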