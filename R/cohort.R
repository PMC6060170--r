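#' Detection table by cancer type and stage group
#'
#' Per (cancer type, early I-II / advanced III-IV) group: number of patients,
#' number CNA-detected, detection rate in percent (one decimal, half-up as
#' presented in clinical tables), and the median / min / max total CNA size
#' in Mb among detected patients (absent when no patient was detected).
#'
#' @param records Cohort data.frame with `cancer_type`, `stage_group`,
#'   `cna_positive`, `total_cna_mb` (as from [read_cohort()] or pipeline
#'   reports).
#' @return data.frame with one row per group.
#' @export
detection_table <- function(records) {
  if (nrow(records) == 0) stop("empty cohort")
  if (!all(records$cancer_type %in% .CANCER_TYPES))
    stop("unknown cancer_type: ",
         paste(unique(setdiff(records$cancer_type, .CANCER_TYPES)),
               collapse = ", "))
  groups <- expand.grid(cancer_type = .CANCER_TYPES,
                        stage_group = c("early", "advanced"),
                        stringsAsFactors = FALSE)
  groups <- groups[order(match(groups$cancer_type, .CANCER_TYPES),
                         match(groups$stage_group, c("early", "advanced"))), ]
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- records$cancer_type == groups$cancer_type[g] &
      records$stage_group == groups$stage_group[g]
    n <- sum(sel)
    det <- sel & records$cna_positive %in% TRUE
    k <- sum(det)
    sizes <- records$total_cna_mb[det]
    data.frame(
      cancer_type = groups$cancer_type[g],
      stage_group = groups$stage_group[g],
      n_patients = n, n_detected = k,
      rate_pct = if (n > 0) round_half_up(100 * k / n, 1) else NA_real_,
      median_cna_mb = if (k > 0) median(sizes) else NA_real_,
      min_cna_mb = if (k > 0) min(sizes) else NA_real_,
      max_cna_mb = if (k > 0) max(sizes) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[out$n_patients > 0 | !is.na(out$rate_pct), ]
}

# Half-up decimal rounding (41.666... -> 41.7), as printed in clinical tables;
# base round() is banker's rounding.
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Pooled detection rates by stage group and overall
#'
#' @param records Cohort data.frame (see [detection_table()]).
#' @return data.frame with rows `early`, `advanced`, `overall`.
#' @export
pooled_detection_rates <- function(records) {
  mk <- function(label, sel) {
    n <- sum(sel); k <- sum(sel & records$cna_positive %in% TRUE)
    data.frame(group = label, n_patients = n, n_detected = k,
               rate_pct = round_half_up(100 * k / n, 1))
  }
  rbind(mk("early", records$stage_group == "early"),
        mk("advanced", records$stage_group == "advanced"),
        mk("overall", rep(TRUE, nrow(records))))
}

#' Compare two detection rates
#'
#' Two-sided exact test on the 2x2 table (Fisher by default; sum of
#' hypergeometric table probabilities at or below the observed one), with a
#' chi-square option.
#'
#' @param k1,n1 Detected / total in group 1.
#' @param k2,n2 Detected / total in group 2.
#' @param method "fisher" (default) or "chisq".
#' @return Two-sided p-value.
#' @export
compare_rates <- function(k1, n1, k2, n2, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (method == "fisher") stats::fisher.test(tab)$p.value
  else stats::chisq.test(tab, correct = FALSE)$p.value
}

#' Mann-Whitney U test
#'
#' U from midranks (ties allowed). Exact two-sided p by enumerating all
#' group-label assignments when `n1 + n2 <= 12` (correct under ties); normal
#' approximation with the tie-corrected variance otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (for `x`) and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  U <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (N <= 12) {
    combos <- utils::combn(N, n1)
    us <- apply(combos, 2, u_of)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = min(p, 1))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (subjects censored at an event time remain at risk
#' for that event). Delegates to `survival::survfit`.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, class `survival_curve`.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Survival probability at given times from a curve
#'
#' Step-function evaluation of a [km_curve()] (right-continuous, S(0) = 1).
#' @param curve A `survival_curve`.
#' @param at Times to evaluate.
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(curve, at) {
  ev <- curve[curve$n_event > 0, , drop = FALSE]
  vapply(at, function(t) {
    past <- ev$time <= t
    if (!any(past)) 1 else ev$survival[max(which(past))]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic (sum of observed minus
#' expected over pooled event times with hypergeometric variance), p from
#' chi-square(1). Delegates to `survival::survdiff`.
#'
#' @param times_a,events_a Group A follow-up times and event indicators.
#' @param times_b,events_b Group B.
#' @return List with `chisq` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}
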