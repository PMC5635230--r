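#' Decision thresholds for the rule-based AF classifier
#'
#' Defaults are conventional AF-detector operating points; they can be
#' replaced by [calibrate_thresholds()].
#'
#' @param tau_cv RR coefficient-of-variation threshold.
#' @param tau_rmssd normalized RMSSD threshold.
#' @param tau_p P-score threshold below which P waves count as absent.
#' @return an object of class `af_thresholds`.
#' @export
af_thresholds <- function(tau_cv = 0.12, tau_rmssd = 0.10, tau_p = 0.5) {
  assert_scalar_number(tau_cv, "tau_cv", 0)
  assert_scalar_number(tau_rmssd, "tau_rmssd", 0)
  assert_scalar_number(tau_p, "tau_p", 0, 1)
  structure(list(tau_cv = tau_cv, tau_rmssd = tau_rmssd, tau_p = tau_p),
            class = "af_thresholds")
}

#' Rule-based AF decision
#'
#' The deployed rule: a record is called AF if and only if the RR intervals
#' are irregular (`rr_cv >= tau_cv` or `rr_rmssd_norm >= tau_rmssd`) AND the
#' P waves are absent (`p_score < tau_p`). Atrial or ventricular premature
#' complexes are deliberately not detected or reported: the output is binary.
#' Grade-3 records and records with too few beats are `UNGRADABLE`.
#'
#' @param features an [extract_features()] result.
#' @param grade optional [grade_quality()] result (grade `"3"` forces
#'   `UNGRADABLE`).
#' @param thresholds an [af_thresholds()].
#' @param rule `"conjunction"` (the deployed rule) or `"rr_only"` (RR
#'   irregularity alone, for false-positive comparisons).
#' @return an object of class `af_decision`: `call` (`"AF"`, `"NOT_AF"` or
#'   `"UNGRADABLE"`), `rr_irregular`, `p_absent`, `thresholds`.
#' @export
classify_af <- function(features, grade = NULL,
                        thresholds = af_thresholds(),
                        rule = c("conjunction", "rr_only")) {
  rule <- match.arg(rule)
  ungradable <- (!is.null(grade) && grade$grade == "3") ||
    isTRUE(features$insufficient) || is.na(features$rr_cv)
  if (ungradable) {
    return(structure(list(call = "UNGRADABLE", rr_irregular = NA,
                          p_absent = NA, thresholds = thresholds),
                     class = "af_decision"))
  }
  rr_irregular <- features$rr_cv >= thresholds$tau_cv ||
    features$rr_rmssd_norm >= thresholds$tau_rmssd
  p_absent <- features$p_score < thresholds$tau_p
  positive <- if (rule == "conjunction") rr_irregular && p_absent else rr_irregular
  structure(
    list(call = if (positive) "AF" else "NOT_AF",
         rr_irregular = rr_irregular, p_absent = p_absent,
         thresholds = thresholds),
    class = "af_decision"
  )
}

#' Classify every row of a feature table
#'
#' Applies [classify_af()] to a per-record feature data frame (as produced
#' by [features_to_df()], optionally with a `grade` column), so different
#' thresholds or rules can be compared without reprocessing the signals.
#'
#' @param features_df data frame with `rr_cv`, `rr_rmssd_norm`, `p_score`
#'   and optionally `grade`.
#' @param thresholds an [af_thresholds()].
#' @param rule `"conjunction"` or `"rr_only"`.
#' @return character vector of calls, one per row.
#' @export
classify_af_df <- function(features_df, thresholds = af_thresholds(),
                           rule = c("conjunction", "rr_only")) {
  rule <- match.arg(rule)
  vapply(seq_len(nrow(features_df)), function(i) {
    row <- features_df[i, ]
    feats <- list(rr_cv = row$rr_cv, rr_rmssd_norm = row$rr_rmssd_norm,
                  p_score = row$p_score,
                  insufficient = is.na(row$rr_cv) || is.na(row$p_score))
    grade <- if ("grade" %in% names(row)) list(grade = row$grade) else NULL
    classify_af(feats, grade, thresholds, rule)$call
  }, character(1))
}

#' Calibrate classifier thresholds on a labelled cohort
#'
#' Deterministic grid search over `(tau_cv, tau_rmssd, tau_p)` maximizing
#' Youden's J (sensitivity + specificity - 1) against the ground-truth AF
#' labels; ties resolve to the first grid point in lexicographic order.
#'
#' @param features_df data frame with columns `rr_cv`, `rr_rmssd_norm`,
#'   `p_score` and a logical `is_af` reference label; rows with `NA`
#'   features are ignored.
#' @param grid_cv,grid_rmssd,grid_p candidate threshold grids.
#' @return the selected [af_thresholds()], with attribute `youden_j`.
#' @export
calibrate_thresholds <- function(features_df,
                                 grid_cv = seq(0.06, 0.30, by = 0.02),
                                 grid_rmssd = seq(0.06, 0.30, by = 0.02),
                                 grid_p = seq(0.25, 0.75, by = 0.05)) {
  need <- c("rr_cv", "rr_rmssd_norm", "p_score", "is_af")
  if (!all(need %in% names(features_df))) {
    stop_data_error("features_df must have rr_cv, rr_rmssd_norm, p_score, is_af")
  }
  df <- features_df[stats::complete.cases(features_df[, need]), need]
  if (length(unique(df$is_af)) < 2) {
    stop(errorCondition("calibration requires both AF and non-AF records",
                        class = c("afscreen_calibration_error", "error", "condition")))
  }
  best <- NULL
  best_j <- -Inf
  for (tcv in grid_cv) for (trm in grid_rmssd) for (tp in grid_p) {
    pos <- (df$rr_cv >= tcv | df$rr_rmssd_norm >= trm) & df$p_score < tp
    sens <- mean(pos[df$is_af])
    spec <- mean(!pos[!df$is_af])
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best <- c(tcv, trm, tp)
    }
  }
  structure(af_thresholds(best[1], best[2], best[3]), youden_j = best_j)
}
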