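# Shared internal helpers.

# Metadata columns every cohort table carries; everything else is a feature.
.meta_cols <- c("subject_id", "session", "sex", "age_months", "etiv_mm3",
                "euler", "site_id", "family_id")

#' Feature column names of a cohort table
#'
#' A cohort table is an ordinary data frame with a fixed set of metadata
#' columns (`subject_id`, `session`, `sex`, `age_months`, `etiv_mm3`, `euler`,
#' `site_id`, `family_id`); every other column is treated as a morphometric
#' feature (volume in mm^3, or its residual after head-size correction).
#'
#' @param cohort cohort data frame.
#' @return character vector of feature column names, in table order.
#' @export
feature_names <- function(cohort) {
  setdiff(names(cohort), .meta_cols)
}

.assert_cohort <- function(cohort, need = c("subject_id", "session", "sex")) {
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing required column(s): ", paste(missing, collapse = ", "))
  }
  invisible(cohort)
}

.feature_matrix <- function(cohort, features = feature_names(cohort)) {
  as.matrix(cohort[, features, drop = FALSE])
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stage label.
.sub_seed <- function(seed, label) {
  offset <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) + offset * 1009) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
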