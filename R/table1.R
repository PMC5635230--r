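#' Published study counts used for the reconstruction
#'
#' The community screening study reported, after excluding the two grade-3
#' recordings: 965 gradable ECGs (526 aged <= 65, 439 aged > 65), 22
#' physician-confirmed AF (4 / 18 by stratum), exactly 1 false negative
#' (in the > 65 stratum, since the <= 65 sensitivity was 100%), 22 false
#' positives overall, and stratum PPVs of 36.4% and 53.1%. Resident-level
#' denominators: 496 / 426 / 922 with the same 4 / 18 / 22 AF subjects.
#'
#' @return list with the printed counts: `n_ecg`, `n_af`, `fn`, `fp_overall`,
#'   `ppv_pct` (stratum PPVs in percent) and `residents`, each split by
#'   stratum (`le`, `gt`, `overall`) where applicable.
#' @export
study_counts <- function() {
  list(
    n_ecg = c(le = 526, gt = 439, overall = 965),
    n_af = c(le = 4, gt = 18, overall = 22),
    fn = c(le = 0, gt = 1, overall = 1),
    fp_overall = 22,
    ppv_pct = c(le = 36.4, gt = 53.1),
    residents_n = c(le = 496, gt = 426, overall = 922),
    residents_af = c(le = 4, gt = 18, overall = 22)
  )
}

#' Recover a stratum false-positive count from its printed PPV
#'
#' The stratum false positives were not printed; with `tp` true positives
#' and a PPV of `ppv_pct` percent, the number of test positives is
#' `round(100 * tp / ppv_pct)` and the false positives follow by
#' subtraction.
#'
#' @param tp stratum true positives.
#' @param ppv_pct stratum PPV in percent.
#' @return integer false-positive count.
#' @export
recover_fp_from_ppv <- function(tp, ppv_pct) {
  as.integer(round(100 * tp / ppv_pct) - tp)
}

#' Confusion tables reconstructed from the published counts
#'
#' Builds the per-stratum and overall confusion tables from the printed
#' summary numbers, recovering the unprinted stratum false positives from
#' the printed PPVs and cross-checking that they sum to the printed overall
#' false-positive count.
#'
#' @param counts the printed counts, by default [study_counts()].
#' @return list with `tables` (confusion tables `le`, `gt`, `overall`) and
#'   `residents` (per-stratum `c(af, n)` subject counts).
#' @export
study_confusion_tables <- function(counts = study_counts()) {
  tp <- counts$n_af - counts$fn
  fp <- c(
    le = recover_fp_from_ppv(tp[["le"]], counts$ppv_pct[["le"]]),
    gt = recover_fp_from_ppv(tp[["gt"]], counts$ppv_pct[["gt"]])
  )
  if (sum(fp) != counts$fp_overall) {
    stop_data_error(sprintf(
      "derived stratum false positives (%d + %d) do not sum to the overall %d",
      fp[["le"]], fp[["gt"]], counts$fp_overall
    ))
  }
  fp <- c(fp, overall = as.integer(counts$fp_overall))
  mk <- function(s, label) {
    confusion_table(
      tp = as.integer(tp[[s]]), fn = as.integer(counts$fn[[s]]),
      fp = as.integer(fp[[s]]),
      tn = as.integer(counts$n_ecg[[s]] - counts$n_af[[s]] - fp[[s]]),
      stratum = label
    )
  }
  list(
    tables = list(le = mk("le", "age <=65"), gt = mk("gt", "age >65"),
                  overall = mk("overall", "overall")),
    residents = list(
      le = c(counts$residents_af[["le"]], counts$residents_n[["le"]]),
      gt = c(counts$residents_af[["gt"]], counts$residents_n[["gt"]]),
      overall = c(counts$residents_af[["overall"]], counts$residents_n[["overall"]])
    )
  )
}

fmt_pct1 <- function(x) {
  if (is.na(x)) "--" else sprintf("%.1f", round_half_up(x, 1))
}

fmt_rate_ci <- function(point, ci, level = 0.95) {
  if (is.na(point)) return("--")
  if (any(is.na(ci))) return(fmt_pct1(point))
  sprintf("%s (%.0f%% CI %s%%-%s%%)", fmt_pct1(point), 100 * level,
          fmt_pct1(ci[1]), fmt_pct1(ci[2]))
}

fmt_prev <- function(pct, counts) {
  if (is.na(pct)) "--" else sprintf("%s (%d/%d)", fmt_pct1(pct), counts[1], counts[2])
}

#' Render an age-stratified performance table
#'
#' Formats per-stratum [performance_report()]s as the familiar screening
#' table: rows sensitivity / specificity / PPV / NPV / prevalence by ECG /
#' prevalence by resident; columns age <= split, age > split, overall.
#' Percentages carry one decimal (ties rounded up) and intervals print as
#' `"x.x (95% CI y.y%-z.z%)"`; undefined rates print as `"--"` and rates
#' without a defined interval print bare.
#'
#' @param reports named list of [performance_report()]s (`le`, `gt`,
#'   `overall`).
#' @param age_split age boundary used in the column headers.
#' @return data frame of formatted strings, one row per measure.
#' @export
render_table1 <- function(reports, age_split = 65) {
  if (!all(c("le", "gt", "overall") %in% names(reports))) {
    stop_data_error("`reports` must contain strata le, gt, overall")
  }
  col <- function(rep) {
    c(
      fmt_rate_ci(rep$rates$sensitivity, rep$ci$sensitivity, rep$level),
      fmt_rate_ci(rep$rates$specificity, rep$ci$specificity, rep$level),
      fmt_rate_ci(rep$rates$ppv, rep$ci$ppv, rep$level),
      fmt_rate_ci(rep$rates$npv, rep$ci$npv, rep$level),
      fmt_prev(rep$prevalence_by_ecg, rep$prevalence_by_ecg_counts),
      if (is.na(rep$prevalence_by_resident)) "--" else
        fmt_prev(rep$prevalence_by_resident, rep$prevalence_by_resident_counts)
    )
  }
  out <- data.frame(
    measure = c("Sensitivity, % (95% CI)", "Specificity, % (95% CI)",
                "Positive predictive value, % (95% CI)",
                "Negative predictive value, % (95% CI)",
                "Disease prevalence (by ECG numbers), % (n/N)",
                "Disease prevalence (by screening resident numbers), % (n/N)"),
    stringsAsFactors = FALSE
  )
  out[[sprintf("age_le%d", age_split)]] <- col(reports$le)
  out[[sprintf("age_gt%d", age_split)]] <- col(reports$gt)
  out$overall <- col(reports$overall)
  out
}

#' Reconstruct the published performance table from printed counts
#'
#' Runs the whole evaluation stage on the printed study counts: rebuilds the
#' per-stratum confusion tables, computes rates, Clopper-Pearson intervals
#' for sensitivity/specificity and standard logit intervals for the
#' predictive values, and renders the formatted table.
#'
#' @param counts printed counts, by default [study_counts()].
#' @return list with `tables`, `reports` and the rendered `table` data frame.
#' @export
reconstruct_table1 <- function(counts = study_counts()) {
  sc <- study_confusion_tables(counts)
  reports <- list(
    le = performance_report(sc$tables$le, residents = sc$residents$le),
    gt = performance_report(sc$tables$gt, residents = sc$residents$gt),
    overall = performance_report(sc$tables$overall, residents = sc$residents$overall)
  )
  list(tables = sc$tables, reports = reports,
       table = render_table1(reports))
}
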