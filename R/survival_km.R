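# Kaplan-Meier estimation and log-rank comparisons of escape+ vs escape-
# within immune categories and cancer types. Estimation is delegated to the
# survival package (survfit / survdiff) behind a stable tabular interface.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator S(t) = prod_{t_i <= t} (1 - d_i / n_i); censored
#' observations decrement the risk set without dropping the curve. The
#' median is the first time with S <= 0.5 (undefined when the curve never
#' reaches 0.5).
#'
#' @param records data.frame with `survival_time` (> 0) and `event` (1 =
#'   death, 0 = censored).
#' @return List of class `survival_curve`: `times` (event times),
#'   `survival`, `at_risk`, `n_events`, `median_survival`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0) stop("no records")
  if (any(records$survival_time <= 0)) stop("nonpositive survival times")
  fit <- survival::survfit(
    survival::Surv(survival_time, event) ~ 1,
    data = records, conf.type = "none"
  )
  keep <- fit$n.event > 0
  med <- unname(summary(fit)$table["median"])
  structure(
    list(
      times = fit$time[keep], survival = fit$surv[keep],
      at_risk = fit$n.risk[keep], n_events = fit$n.event[keep],
      n = fit$n, median_survival = if (is.na(med)) NA_real_ else med
    ),
    class = "survival_curve"
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank: observed minus expected events summed over distinct
#' event times with hypergeometric variance, chi-square on 1 df. Symmetric
#' in group order.
#'
#' @param records_a,records_b data.frames as in [km_estimate()].
#' @return List with `chi2`, `p`, `obs`, `exp` (per group), or
#'   `undefined = TRUE` when there are no events (zero variance).
#' @export
logrank_test <- function(records_a, records_b) {
  if (nrow(records_a) == 0 || nrow(records_b) == 0) {
    stop("both groups must be nonempty")
  }
  df <- rbind(
    data.frame(survival_time = records_a$survival_time,
               event = records_a$event, grp = "A",
               stringsAsFactors = FALSE),
    data.frame(survival_time = records_b$survival_time,
               event = records_b$event, grp = "B",
               stringsAsFactors = FALSE)
  )
  if (sum(df$event) == 0) {
    return(list(chi2 = NA_real_, p = NA_real_, undefined = TRUE))
  }
  sd <- survival::survdiff(
    survival::Surv(survival_time, event) ~ grp, data = df, rho = 0
  )
  list(
    chi2 = unname(sd$chisq),
    p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    obs = unname(sd$obs), exp = unname(sd$exp), undefined = FALSE
  )
}

#' Stratified escape+ vs escape- survival comparison
#'
#' Per stratum (immune category, cancer type, or their interaction):
#' Kaplan-Meier curves per escape arm and a log-rank test, with BH
#' adjustment across strata. Strata with fewer than `min_per_arm` patients
#' in either arm are skipped with a recorded reason.
#'
#' @param clinical Clinical table (`patient_id`, `survival_time`, `event`,
#'   `immune_category`, `cancer_type`).
#' @param labels Escape labels ([classify_point_mutation()]).
#' @param by Stratifying column(s): subset of
#'   `c("immune_category", "cancer_type")`.
#' @param min_per_arm Minimum patients per arm (default 5).
#' @return List with `tests` (data.frame: stratum, n per arm, chi2, p, q,
#'   skipped/reason) and `curves` (named list of per-arm
#'   `survival_curve`s).
#' @export
stratified_survival <- function(clinical, labels, by = "immune_category",
                                min_per_arm = 5L) {
  status <- stats::setNames(labels$status, labels$patient_id)
  clin <- clinical[clinical$patient_id %in% names(status), , drop = FALSE]
  clin$status <- status[clin$patient_id]
  strata_key <- interaction(clin[by], drop = TRUE, sep = "/")
  curves <- list()
  rows <- lapply(levels(strata_key), function(s) {
    sub <- clin[strata_key == s, , drop = FALSE]
    a <- sub[sub$status == "escape_neg", , drop = FALSE]
    b <- sub[sub$status == "escape_pos", , drop = FALSE]
    base <- data.frame(stratum = s, n_neg = nrow(a), n_pos = nrow(b),
                       stringsAsFactors = FALSE)
    if (nrow(a) < min_per_arm || nrow(b) < min_per_arm) {
      return(cbind(base, chi2 = NA_real_, p = NA_real_, skipped = TRUE,
                   reason = sprintf("fewer than %d patients in an arm",
                                    min_per_arm)))
    }
    lr <- logrank_test(a, b)
    curves[[paste0(s, "/escape_neg")]] <<- km_estimate(a)
    curves[[paste0(s, "/escape_pos")]] <<- km_estimate(b)
    cbind(base, chi2 = lr$chi2 %||% NA_real_, p = lr$p,
          skipped = FALSE,
          reason = if (isTRUE(lr$undefined)) "no events" else "")
  })
  tests <- do.call(rbind, rows)
  tests$q <- NA_real_
  ok <- !tests$skipped & !is.na(tests$p)
  tests$q[ok] <- stats::p.adjust(tests$p[ok], method = "BH")
  rownames(tests) <- NULL
  list(tests = tests, curves = curves)
}

#' Export survival curves as a long table
#' @param curves Named list of `survival_curve` (e.g. from
#'   [stratified_survival()]).
#' @return data.frame `stratum_arm`, `time`, `survival`, `at_risk`.
#' @export
survival_curve_table <- function(curves) {
  out <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    if (length(cv$times) == 0) return(NULL)
    data.frame(stratum_arm = nm, time = cv$times, survival = cv$survival,
               at_risk = cv$at_risk, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(stratum_arm = character(0),
                                      time = numeric(0),
                                      survival = numeric(0),
                                      at_risk = numeric(0))
  out
}
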