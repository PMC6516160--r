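# Classical survival comparisons: Kaplan-Meier curves, log-rank tests,
# median lifespan with confidence intervals, and the maximum-lifespan
# proportion test (sex difference in reaching the pooled 90%-mortality age).

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate under right censoring; censored animals leave the
#' risk set after their censoring age, tied deaths are removed
#' simultaneously.
#'
#' @param ages Ages at death or censoring (days).
#' @param statuses "died"/"censored" (or logical/0-1 event indicator).
#' @return A `km_curve`: data.frame `time`, `n_risk`, `n_event`, `surv`,
#'   `var_log_surv`, with the underlying `survfit` object as attribute.
#' @export
km_curve <- function(ages, statuses) {
  stopifnot(length(ages) >= 1)
  ev <- .event_indicator(statuses)
  sf <- survival::survfit(survival::Surv(ages, ev) ~ 1, conf.type = "log")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, surv = sf$surv,
                    var_log_surv = sf$std.err^2)
  structure(out, survfit = sf, class = c("km_curve", "data.frame"))
}

.event_indicator <- function(statuses) {
  if (is.logical(statuses)) return(as.integer(statuses))
  if (is.numeric(statuses)) return(as.integer(statuses != 0))
  as.integer(as.character(statuses) == "died")
}

#' Median lifespan with confidence interval
#'
#' Median = smallest age at which the KM estimate falls to or below 0.5; the
#' CI inverts the pointwise log-transformed confidence band of S(t), with
#' the variance of the cumulative hazard from the Greenwood estimator
#' (default) or the Aalen (Tsiatis) estimator.
#'
#' @param ages,statuses As in [km_curve()].
#' @param conf_level Confidence level (default 0.95).
#' @param variance "greenwood" or "aalen".
#' @return List `median_days`, `ci_lower_days`, `ci_upper_days`, `method`;
#'   entries are `NA` (flagged by `defined = FALSE`) if S never reaches 0.5.
#' @export
median_with_ci <- function(ages, statuses, conf_level = 0.95,
                           variance = c("greenwood", "aalen")) {
  variance <- match.arg(variance)
  ev <- .event_indicator(statuses)
  sf <- survival::survfit(survival::Surv(ages, ev) ~ 1,
                          conf.type = "log", conf.int = conf_level)
  # log-scale pointwise band exp(log S +/- z * se(H)), inverted at 0.5;
  # the cumulative-hazard variance is Greenwood's sum d/(n(n-d)) or the
  # Aalen (Tsiatis) sum d/n^2
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  var_H <- if (variance == "greenwood") {
    cumsum(ifelse(sf$n.risk > sf$n.event,
                  sf$n.event / (sf$n.risk * (sf$n.risk - sf$n.event)), Inf))
  } else {
    cumsum(sf$n.event / sf$n.risk^2)
  }
  se <- sqrt(var_H)
  s_lo <- ifelse(sf$surv == 0, 0, exp(log(sf$surv) - zq * se))
  s_hi <- ifelse(sf$surv == 0, 0, exp(log(sf$surv) + zq * se))
  first_at <- function(svals) {
    i <- which(svals <= 0.5)
    if (length(i) == 0) NA_real_ else sf$time[min(i)]
  }
  med <- first_at(sf$surv)
  lo <- first_at(s_lo)   # lower S bound falls to 0.5 earliest
  hi <- first_at(s_hi)
  list(median_days = med, ci_lower_days = lo, ci_upper_days = hi,
       method = paste0("km-log-", variance), defined = !is.na(med))
}

#' Log-rank test between two groups
#'
#' One-degree-of-freedom log-rank statistic over shared event times.
#'
#' @param ages_a,statuses_a,ages_b,statuses_b Per-group inputs.
#' @return List `chi_square`, `p`, `df`.
#' @export
logrank <- function(ages_a, statuses_a, ages_b, statuses_b) {
  ev_a <- .event_indicator(statuses_a)
  ev_b <- .event_indicator(statuses_b)
  if (sum(ev_a) + sum(ev_b) == 0) stop("log-rank undefined: no events")
  grp <- c(rep("A", length(ages_a)), rep("B", length(ages_b)))
  sd <- survival::survdiff(
    survival::Surv(c(ages_a, ages_b), c(ev_a, ev_b)) ~ grp, rho = 0)
  list(chi_square = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE), df = 1)
}

#' Maximum-lifespan proportion test
#'
#' Operationalizes "maximum lifespan" as the age by which the pooled
#' population (both sexes) reaches the given mortality quantile (default
#' 90%), estimated from the pooled KM curve so censoring is handled
#' consistently. Within each sex, animals censored before that age are
#' excluded (their status there is unknown) and the proportion still alive
#' is compared between sexes by a two-sided Fisher exact test, with
#' Clopper-Pearson CIs per sex.
#'
#' @param cohort A `cohort_table` with both sexes.
#' @param mortality_quantile Pooled mortality level defining the threshold.
#' @param conf_level Level of the per-sex proportion CIs.
#' @return List `threshold_age_days`, per-sex `counts` (alive, dead,
#'   excluded), `proportions` with CIs, and `fisher_p`.
#' @export
max_lifespan_test <- function(cohort, mortality_quantile = 0.90,
                              conf_level = 0.95) {
  km <- km_curve(cohort$age_days, cohort$status)
  target <- 1 - mortality_quantile
  idx <- which(km$surv <= target)
  if (length(idx) == 0)
    stop("pooled survival never reaches the requested mortality quantile")
  threshold <- km$time[min(idx)]

  res <- lapply(c(F = "F", M = "M"), function(s) {
    sub <- cohort[cohort$sex == s, , drop = FALSE]
    excluded <- sub$status == "censored" & sub$age_days <= threshold
    sub <- sub[!excluded, , drop = FALSE]
    alive <- sum(sub$age_days > threshold)
    dead <- nrow(sub) - alive
    if (nrow(sub) == 0)
      stop("degenerate maximum-lifespan table: no classifiable animals of sex ", s)
    ci <- stats::binom.test(alive, alive + dead,
                            conf.level = conf_level)$conf.int
    list(alive = alive, dead = dead, excluded = sum(excluded),
         proportion = alive / (alive + dead),
         ci_lower = ci[1], ci_upper = ci[2])
  })
  tab <- matrix(c(res$F$alive, res$F$dead, res$M$alive, res$M$dead),
                nrow = 2, byrow = TRUE,
                dimnames = list(sex = c("F", "M"), c("alive", "dead")))
  fp <- stats::fisher.test(tab)$p.value
  list(threshold_age_days = threshold, counts = tab,
       proportions = res, fisher_p = fp,
       mortality_quantile = mortality_quantile)
}

#' Per-sex survival summary of a cohort
#'
#' Medians with CIs per sex, the sex log-rank test, and the
#' maximum-lifespan comparison, as one machine-readable list.
#'
#' @param cohort A `cohort_table` with both sexes.
#' @param conf_level Confidence level.
#' @param variance Median-CI variance estimator (see [median_with_ci()]).
#' @return Nested list of the three analyses.
#' @export
survival_summary <- function(cohort, conf_level = 0.95,
                             variance = "greenwood") {
  f <- cohort[cohort$sex == "F", ]
  m <- cohort[cohort$sex == "M", ]
  if (nrow(f) == 0 || nrow(m) == 0)
    stop("between-sex comparison needs both sexes present")
  list(
    median = list(
      F = median_with_ci(f$age_days, f$status, conf_level, variance),
      M = median_with_ci(m$age_days, m$status, conf_level, variance)
    ),
    logrank = logrank(f$age_days, f$status, m$age_days, m$status),
    max_lifespan = max_lifespan_test(cohort, conf_level = conf_level)
  )
}
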