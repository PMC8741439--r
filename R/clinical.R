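#' Paired pre/post-treatment changes for one biomarker
#'
#' Builds one change record per eligible patient: baseline (core biopsy, Bx),
#' post (surgical specimen, Sx), their difference, and the natural-log ratio
#' `ln(post/baseline)` (missing unless both values are strictly positive).
#' For ROR, patients missing either measurement are excluded; Ki67 is measured
#' on all patients.
#'
#' @param records clinical data.frame from [read_clinical_table()].
#' @param measure `"ki67"` or `"ror"`.
#' @return data.frame `patient_id, baseline, post, delta, log_ratio`, input
#'   order preserved.
#' @export
paired_changes <- function(records, measure = c("ki67", "ror")) {
  measure <- match.arg(measure)
  cols <- switch(measure,
                 ki67 = c("ki67_bx", "ki67_sx"),
                 ror = c("ror_bx", "ror_sx"))
  baseline <- records[[cols[1]]]
  post <- records[[cols[2]]]
  keep <- !(is.na(baseline) | is.na(post))
  baseline <- baseline[keep]; post <- post[keep]
  lr <- ifelse(baseline > 0 & post > 0, log(post / baseline), NA_real_)
  data.frame(patient_id = records$patient_id[keep],
             baseline = baseline, post = post,
             delta = post - baseline, log_ratio = lr,
             stringsAsFactors = FALSE)
}

#' Count strict decreases among paired changes
#'
#' Ties (`delta == 0`) are not decreases.
#'
#' @param changes data.frame from [paired_changes()].
#' @return `list(n_decrease, n_total)`.
#' @export
count_decreases <- function(changes) {
  if (nrow(changes) == 0L) stop_("no paired changes supplied")
  list(n_decrease = sum(changes$delta < 0), n_total = nrow(changes))
}

#' Percentage change in the geometric mean
#'
#' `100 * (exp(mean(ln(post/baseline))) - 1)`: the percent change of the
#' geometric mean from baseline to post-treatment.
#'
#' @param changes data.frame from [paired_changes()]; all values must be
#'   strictly positive.
#' @return percent change (negative for a decrease).
#' @export
geometric_mean_percent_change <- function(changes) {
  bad <- is.na(changes$log_ratio)
  if (any(bad))
    stop_("non-positive value for patient(s): %s",
          paste(changes$patient_id[bad], collapse = ", "))
  100 * (exp(mean(changes$log_ratio)) - 1)
}

#' Paired t-test on log-transformed measurements
#'
#' Two-tailed paired t-test on `ln(post) - ln(baseline)`, i.e. the one-sample
#' t-test of the log ratios against zero, with the sample (n-1) standard
#' deviation and `df = n - 1`.
#'
#' @param changes data.frame from [paired_changes()], `n >= 2`, all log ratios
#'   defined.
#' @return `list(statistic, df, p_two_tailed)`.
#' @export
paired_log_ttest <- function(changes) {
  d <- changes$log_ratio
  if (anyNA(d)) stop_("log ratios undefined for some patients (non-positive values)")
  n <- length(d)
  if (n < 2L) stop_("need at least 2 paired observations")
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(statistic = 0, df = n - 1L, p_two_tailed = 1))
    stop_("zero variance with non-zero mean: t statistic undefined")
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(statistic = tstat, df = n - 1L,
       p_two_tailed = 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE))
}

#' Select prototypical responders from ROR changes
#'
#' A patient is a responder when their ROR change is more than one standard
#' deviation below the mean change of the whole cohort:
#' `delta < mean(delta) - sd(delta)` (sample sd, strict inequality).
#'
#' @param ror_changes data.frame from [paired_changes()] with `measure="ror"`;
#'   at least 3 rows.
#' @return patient ids, sorted by delta ascending (largest decrease first).
#' @export
select_responders <- function(ror_changes) {
  if (nrow(ror_changes) < 3L) stop_("need at least 3 paired ROR changes")
  d <- ror_changes$delta
  cut <- mean(d) - sd(d)
  sel <- ror_changes[d < cut, , drop = FALSE]
  sel$patient_id[order(sel$delta)]
}

#' Select prototypical non-responders
#'
#' The `k` patients with the smallest absolute ROR change; ties broken by
#' patient id.
#'
#' @param ror_changes data.frame from [paired_changes()].
#' @param k number of non-responders (default 3).
#' @return `k` patient ids ordered by `|delta|` then patient id.
#' @export
select_nonresponders <- function(ror_changes, k = 3) {
  n <- nrow(ror_changes)
  if (k > n) stop_("k = %d exceeds the number of changes (%d)", k, n)
  ord <- order(abs(ror_changes$delta), ror_changes$patient_id)
  ror_changes$patient_id[ord[seq_len(k)]]
}

#' Direction-concordance kappa between two paired biomarkers
#'
#' Joins the two change tables on patient id, dichotomizes each measure as
#' increase (`delta > 0`) vs non-increase, excludes patients with a zero delta
#' on the second axis (by convention the ROR axis; zero deltas on the first
#' axis count as non-increase) and computes Cohen's kappa on the resulting
#' 2x2 table.
#'
#' @param changes_a,changes_b change tables from [paired_changes()]
#'   (conventionally Ki67 and ROR).
#' @return `list(n_pairs, observed_agreement, expected_agreement, kappa, table)`;
#'   `kappa` is `NA` when the expected agreement is 1.
#' @export
direction_kappa <- function(changes_a, changes_b) {
  common <- intersect(changes_a$patient_id, changes_b$patient_id)
  a <- changes_a$delta[match(common, changes_a$patient_id)]
  b <- changes_b$delta[match(common, changes_b$patient_id)]
  keep <- b != 0
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop_("fewer than 2 usable pairs after exclusions")
  xa <- factor(a > 0, levels = c(FALSE, TRUE), labels = c("non_increase", "increase"))
  xb <- factor(b > 0, levels = c(FALSE, TRUE), labels = c("non_increase", "increase"))
  tab <- table(a = xa, b = xb)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(n_pairs = n, observed_agreement = po, expected_agreement = pe,
       kappa = kappa, table = tab)
}
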