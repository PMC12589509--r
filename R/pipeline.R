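# End-to-end study replica on synthetic data:
# simulate -> harmonize -> QC -> match -> residualize -> train -> predict
# longitudinally -> association batteries -> mental health -> report.

#' Configuration of a full pipeline run
#'
#' The training cohort emulates a pooled cross-sectional multi-site sample
#' (wide age range); the validation cohort is simulated as a distinct
#' two-session longitudinal study with its own sites and a narrower age
#' range, so external validation is genuinely out-of-distribution.
#'
#' @param gen_train,gen_valid [cohort_config()]s for the two cohorts; sensible
#'   defaults are derived from `seed` when omitted.
#' @param match a [match_spec()].
#' @param train a [training_params()].
#' @param analyses which association batteries to run.
#' @param seed global seed; sub-seeds for every stage derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(gen_train = NULL, gen_valid = NULL,
                       match = match_spec(), train = NULL,
                       analyses = c("age", "pds", "menarche", "mh"),
                       seed = 1L) {
  seed <- as.integer(seed)
  gen_train <- gen_train %||% cohort_config(
    n_subjects = 600, n_sessions = 1, n_sites = 5,
    age_range_months = c(96, 264), seed = .sub_seed(seed, "train_cohort"))
  gen_valid <- gen_valid %||% cohort_config(
    n_subjects = 400, n_sessions = 2, n_sites = 3,
    age_range_months = c(108, 168), distress_limbic_coupling = 0.4,
    seed = .sub_seed(seed, "valid_cohort"))
  train <- train %||% training_params(seed = .sub_seed(seed, "train"))
  structure(list(gen_train = gen_train, gen_valid = gen_valid, match = match,
                 train = train, analyses = analyses, seed = seed),
            class = "run_config")
}

.stage_log <- function(log, stage, n_in, n_out, note = "") {
  entry <- sprintf("%-12s in=%-6d out=%-6d %s", stage, n_in, n_out, note)
  message(entry)
  c(log, entry)
}

#' Run the full pipeline
#'
#' Executes all stages in order and, when `out_dir` is given, writes every
#' intermediate table as CSV plus a markdown report. Deterministic given the
#' config (same seed reproduces every table bit-identically).
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return (invisibly) a list with the matched sample, the three fitted
#'   models, per-session validation AUCs, association results, the
#'   mental-health model and cross-session correlation, and the stage log.
#' @export
run_full <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)

  # --- training cohort: simulate, harmonize, QC, match, residualize
  train_raw <- generate_cohort(config$gen_train)
  log <- .stage_log(log, "simulate", config$gen_train$n_subjects,
                    nrow(train_raw), "training cohort")
  cb_train <- fit_combat(train_raw, c("sex", "age_months"),
                         variant = "cross_sectional")
  train_h <- apply_combat(cb_train, train_raw)
  qc <- euler_qc(train_h)
  log <- .stage_log(log, "euler_qc", nrow(train_h), nrow(qc$cohort),
                    paste(nrow(qc$excluded), "excluded"))
  matched <- match_pairs(qc$cohort, config$match)
  log <- .stage_log(log, "match", nrow(qc$cohort), nrow(matched$cohort),
                    paste(length(matched$unmatched), "unmatched"))
  balance <- balance_check(matched)
  res_train <- residualize_etiv(matched$cohort)
  partition <- partition_from_cohort(train_raw)

  # --- three classifiers
  sets <- c("limbic", "nonlimbic", "whole_brain")
  models <- lapply(sets, function(fs) {
    train_nested_cv(select_features(res_train$cohort, partition, fs),
                    params = config$train, feature_set = fs)
  })
  names(models) <- sets
  log <- .stage_log(log, "train", nrow(res_train$cohort), length(models),
                    paste("cv_auc:", paste(sprintf("%s=%.3f", sets,
                      vapply(models, `[[`, 0, "cv_auc")), collapse = " ")))

  # --- validation cohort: simulate, longitudinal harmonization, QC, predict
  valid_raw <- generate_cohort(config$gen_valid)
  cb_valid <- fit_combat(valid_raw, c("sex", "age_months"),
                         variant = "longitudinal")
  valid_h <- apply_combat(cb_valid, valid_raw)
  qc_v <- euler_qc(valid_h)
  res_valid <- residualize_etiv(qc_v$cohort)  # refit pooled over sessions
  probs <- do.call(rbind, lapply(models, function(m) {
    predict(m, select_features(res_valid$cohort, partition, m$feature_set))
  }))
  rownames(probs) <- NULL
  log <- .stage_log(log, "predict", nrow(res_valid$cohort), nrow(probs))

  auc_tab <- do.call(rbind, lapply(sets, function(fs) {
    do.call(rbind, lapply(c("baseline", "followup"), function(ss) {
      rows <- probs$feature_set == fs & probs$session == ss
      sx <- res_valid$cohort$sex[match(probs$subject_id[rows],
                                       res_valid$cohort$subject_id)]
      data.frame(feature_set = fs, session = ss,
                 auc = roc_auc(probs$p_female[rows], sx))
    }))
  }))

  # --- covariate tables and association batteries
  puberty <- generate_puberty(valid_raw, config$gen_valid)
  puberty <- puberty[puberty$subject_id %in% qc_v$cohort$subject_id, ]
  # distress couples to the limbic brain-sex continuum readout itself
  lim <- probs[probs$feature_set == "limbic", ]
  proxy <- tapply(lim$p_female, lim$subject_id, mean)
  items <- generate_questionnaire(qc_v$cohort, proxy = proxy,
                                  config = config$gen_valid)
  pc <- fit_pc1(items)
  mh_base <- pc$scores
  mh_fup <- project_pc1(pc, items[items$session == "followup", ])
  mh_scores <- rbind(mh_base, mh_fup)
  mh_cor <- session_correlation(mh_base, mh_fup)

  results <- list()
  oof <- do.call(rbind, lapply(models, `[[`, "oof"))
  results[["age_training"]] <- run_association(
    "age_training", oof, matched$cohort, cohort_name = "synthetic_training",
    min_site_n = 1)  # cross-sectional lm keeps all sites as covariate levels
  for (an in config$analyses) {
    results[[an]] <- run_association(an, probs, qc_v$cohort,
                                     puberty = puberty, mh_scores = mh_scores,
                                     cohort_name = "synthetic_validation")
    log <- .stage_log(log, paste0("assoc_", an), nrow(probs),
                      nrow(results[[an]]))
  }
  association <- do.call(rbind, results)
  rownames(association) <- NULL

  run <- list(config = config, matched = matched, balance = balance,
              models = models, partition = partition, probs = probs,
              auc = auc_tab, puberty = puberty, mh_model = pc,
              mh_scores = mh_scores, mh_cor = mh_cor,
              association = association, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(matched$pairs, file.path(out_dir, "pairs.csv"),
              row.names = FALSE)
    write.csv(balance, file.path(out_dir, "balance.csv"), row.names = FALSE)
    write.csv(probs, file.path(out_dir, "class_probabilities.csv"),
              row.names = FALSE)
    write.csv(auc_tab, file.path(out_dir, "auc.csv"), row.names = FALSE)
    write.csv(association, file.path(out_dir, "association.csv"),
              row.names = FALSE)
    write.csv(mh_scores, file.path(out_dir, "mh_scores.csv"),
              row.names = FALSE)
    writeLines(c("# brainsex run report", "",
                 sprintf("- seed: %d", config$seed),
                 sprintf("- matched sample: %d subjects (%d pairs)",
                         nrow(matched$cohort), nrow(matched$pairs)),
                 sprintf("- CV AUC: %s",
                         paste(sprintf("%s %.3f", names(models),
                                       vapply(models, `[[`, 0, "cv_auc")),
                               collapse = ", ")),
                 "",
                 "## Validation AUC per session",
                 utils::capture.output(print(auc_tab, row.names = FALSE)),
                 "",
                 sprintf("- mental-health PC1: %.1f%% variance, r(sessions) = %.2f",
                         100 * pc$explained, mh_cor$r),
                 "", "## Stage log", log),
               file.path(out_dir, "report.md"))
  }
  invisible(run)
}

#' Write / read a cohort table as CSV
#'
#' The hidden-truth record (when present) goes to a JSON sidecar next to the
#' CSV so generated data remain auditable.
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @return `read_cohort` returns the data frame (truth is not restored).
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  truth <- cohort_truth(cohort)
  if (!is.null(truth)) {
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, paste0(path, ".truth.json"), digits = NA,
                         auto_unbox = TRUE, force = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
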