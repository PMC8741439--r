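#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator for one group of right-censored survival
#' records. Individuals censored exactly at an event time are counted as at
#' risk for that time (events precede censorings at ties).
#'
#' @param records data.frame with columns `time` (> 0) and `event` (1 = event,
#'   0 = censored).
#' @return data.frame of class `km_curve` with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival` (non-increasing, starting
#'   below 1 only after the first event). Zero rows when there are no events
#'   (survival identically 1).
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0L) stop_("no survival records supplied")
  if (any(records$time <= 0)) stop_("survival times must be positive")
  if (!all(records$event %in% c(0, 1))) stop_("event must be 0 or 1")
  etimes <- sort(unique(records$time[records$event == 1]))
  n_risk <- vapply(etimes, function(t) sum(records$time >= t), numeric(1))
  n_event <- vapply(etimes, function(t) sum(records$time == t & records$event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' At every distinct event time the observed events in group 1 are compared
#' with their hypergeometric expectation given the risk sets; the squared
#' standardized sum is referred to the chi-square distribution with 1 degree
#' of freedom (two-sided).
#'
#' @param records data.frame with columns `time`, `event` and `group` (exactly
#'   two distinct groups).
#' @return `list(chi_square, df = 1, p_two_sided, observed, expected)` of
#'   class `logrank_result`; `observed`/`expected` are per-group event counts.
#' @export
logrank_test <- function(records) {
  groups <- sort(unique(as.character(records$group)))
  if (length(groups) != 2L)
    stop_("log-rank test needs exactly two groups (got %d)", length(groups))
  if (any(records$time <= 0)) stop_("survival times must be positive")
  g1 <- records$group == groups[1]
  etimes <- sort(unique(records$time[records$event == 1]))
  if (length(etimes) == 0L) stop_("no events in either group")

  O1 <- E1 <- V <- 0
  for (t in etimes) {
    at_risk <- records$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(records$time == t & records$event == 1)
    d1 <- sum(records$time == t & records$event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O1 - E1)^2 / V else 0
  Otot <- sum(records$event == 1)
  structure(list(chi_square = chi, df = 1L,
                 p_two_sided = pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = setNames(c(O1, Otot - O1), groups),
                 expected = setNames(c(E1, Otot - E1), groups)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f, df = 1, p = %.4g\n",
              x$chi_square, x$p_two_sided))
  print(data.frame(group = names(x$observed), observed = as.numeric(x$observed),
                   expected = as.numeric(x$expected)), row.names = FALSE)
  invisible(x)
}
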