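#' Confusion table for one stratum
#'
#' @param tp,fn,fp,tn non-negative counts (reference positives are
#'   `tp + fn`; test positives are `tp + fp`).
#' @param stratum stratum label.
#' @return an object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn, stratum = "overall") {
  for (nm in c("tp", "fn", "fp", "tn")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      stop_invalid(sprintf("`%s` must be a non-negative integer count", nm))
    }
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 total = tp + fn + fp + tn, stratum = stratum),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> %s: TP %d, FN %d, FP %d, TN %d (n = %d)\n",
              x$stratum, x$tp, x$fn, x$fp, x$tn, x$total))
  invisible(x)
}

#' Tabulate classifier calls against reference labels, by age stratum
#'
#' Records with an excluded quality grade or an `UNGRADABLE` call are removed
#' before tabulation (the screening analysis excludes grade-3 artifacts).
#' Strata are age <= `age_split`, age > `age_split`, and overall.
#'
#' @param calls data frame with columns `call` (`"AF"/"NOT_AF"/"UNGRADABLE"`),
#'   `is_af` (logical reference label), `age`, and `grade`.
#' @param exclude_grades grade tokens removed before tabulation.
#' @param age_split age boundary in years (boundary age goes to the lower
#'   stratum).
#' @return named list of [confusion_table()]s: `le`, `gt`, `overall`.
#' @export
build_confusion <- function(calls, exclude_grades = "3", age_split = 65) {
  need <- c("call", "is_af", "age")
  if (!all(need %in% names(calls))) {
    stop_data_error("`calls` must have columns call, is_af, age")
  }
  if (any(is.na(calls$is_af))) {
    stop_data_error("missing reference label (is_af) for some records")
  }
  keep <- calls$call != "UNGRADABLE"
  if ("grade" %in% names(calls)) keep <- keep & !(calls$grade %in% exclude_grades)
  df <- calls[keep, , drop = FALSE]
  tab <- function(d, stratum) {
    pos <- d$call == "AF"
    confusion_table(
      tp = sum(pos & d$is_af), fn = sum(!pos & d$is_af),
      fp = sum(pos & !d$is_af), tn = sum(!pos & !d$is_af),
      stratum = stratum
    )
  }
  list(
    le = tab(df[df$age <= age_split, , drop = FALSE],
             sprintf("age <=%d", age_split)),
    gt = tab(df[df$age > age_split, , drop = FALSE],
             sprintf("age >%d", age_split)),
    overall = tab(df, "overall")
  )
}

#' Screening performance rates from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and prevalence `(tp+fn)/total`, in percent. A zero
#' denominator yields `NA` (an undefined-rate marker), not an error.
#'
#' @param t a [confusion_table()].
#' @return list of rates in percent (unrounded; use [round_half_up()] for
#'   reporting to one decimal).
#' @export
rates <- function(t) {
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(
    sensitivity = frac(t$tp, t$tp + t$fn),
    specificity = frac(t$tn, t$tn + t$fp),
    ppv = frac(t$tp, t$tp + t$fp),
    npv = frac(t$tn, t$tn + t$fn),
    prevalence = frac(t$tp + t$fn, t$total)
  )
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,n binomial counts, `0 <= successes <= n`, `n >= 1`.
#' @param level confidence level.
#' @return `c(lower, upper)` in percent.
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (!is.numeric(n) || n < 1 || n != round(n)) stop_invalid("`n` must be >= 1")
  if (!is.numeric(successes) || successes < 0 || successes > n ||
      successes != round(successes)) {
    stop_invalid("`successes` must lie in [0, n]")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  100 * c(lower = lower, upper = upper)
}

#' Standard logit confidence interval for predictive values
#'
#' PPV and NPV intervals via the delta method on the logit scale
#' (Mercaldo-type): `logit(PPV) = log(se) - log(1 - sp) + logit(prev)` has
#' variance `(1-se)/(se * n1) + sp/((1-sp) * n0)` with `n1 = tp + fn`
#' reference positives and `n0 = fp + tn` reference negatives (and the
#' symmetric expression for NPV). Degenerate tables -- a perfect sensitivity
#' for the NPV, a perfect specificity for the PPV, or empty margins -- have
#' infinite logit variance and return `c(NA, NA)`: the point estimate is
#' reported without an interval.
#'
#' @param t a [confusion_table()].
#' @param which `"ppv"` or `"npv"`.
#' @param level confidence level.
#' @return `c(lower, upper)` in percent, or `c(NA, NA)` when undefined.
#' @export
predictive_value_ci <- function(t, which = c("ppv", "npv"), level = 0.95) {
  which <- match.arg(which)
  n1 <- t$tp + t$fn
  n0 <- t$fp + t$tn
  if (n1 == 0 || n0 == 0) return(c(lower = NA_real_, upper = NA_real_))
  se <- t$tp / n1
  sp <- t$tn / n0
  if (which == "ppv") {
    den <- t$tp + t$fp
    if (den == 0 || se == 0 || sp == 1) return(c(lower = NA_real_, upper = NA_real_))
    p <- t$tp / den
    v <- (1 - se) / (se * n1) + sp / ((1 - sp) * n0)
  } else {
    den <- t$tn + t$fn
    if (den == 0 || sp == 0 || se == 1) return(c(lower = NA_real_, upper = NA_real_))
    p <- t$tn / den
    v <- se / ((1 - se) * n1) + (1 - sp) / (sp * n0)
  }
  if (p == 0 || p == 1) return(c(lower = NA_real_, upper = NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  lg <- log(p / (1 - p)) + c(-1, 1) * z * sqrt(v)
  100 * stats::setNames(1 / (1 + exp(-lg)), c("lower", "upper"))
}

#' Performance report for one stratum
#'
#' Point rates with 95% intervals: Clopper-Pearson for sensitivity and
#' specificity, standard logit for PPV and NPV. Prevalence is reported per
#' recording and, when resident counts are supplied, per screened resident.
#'
#' @param t a [confusion_table()].
#' @param residents optional `c(af, n)` subject-level counts for the
#'   by-resident prevalence row.
#' @param level confidence level.
#' @return an object of class `performance_report`.
#' @export
performance_report <- function(t, residents = NULL, level = 0.95) {
  r <- rates(t)
  ci <- list(
    sensitivity = if (t$tp + t$fn > 0)
      exact_binomial_ci(t$tp, t$tp + t$fn, level) else c(NA, NA),
    specificity = if (t$tn + t$fp > 0)
      exact_binomial_ci(t$tn, t$tn + t$fp, level) else c(NA, NA),
    ppv = predictive_value_ci(t, "ppv", level),
    npv = predictive_value_ci(t, "npv", level)
  )
  prev_resident <- if (!is.null(residents)) 100 * residents[1] / residents[2] else NA_real_
  structure(
    list(table = t, rates = r, ci = ci,
         prevalence_by_ecg = r$prevalence,
         prevalence_by_ecg_counts = c(t$tp + t$fn, t$total),
         prevalence_by_resident = prev_resident,
         prevalence_by_resident_counts = residents,
         level = level),
    class = "performance_report"
  )
}
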