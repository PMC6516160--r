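# Cox proportional-hazards models with a sex-by-site interaction, and
# age-stratified linear regressions of lifespan on bodyweight with
# standardized coefficients and interaction terms.

#' Cox model of survival on sex, site, and their interaction
#'
#' Partial-likelihood fit with the Efron tie correction. Factors are
#' dummy-coded with reference levels F (sex) and TJL (site); the interaction
#' block is tested by a likelihood-ratio test against the model without it.
#'
#' @param cohort A `cohort_table`.
#' @param interaction Include the sex-by-site interaction (default TRUE).
#' @return A `cox_result`: list with a per-term data.frame `terms`
#'   (coefficient, se, hazard_ratio, p), log-likelihoods, and the
#'   interaction LRT (`lrt_statistic`, `lrt_df`, `lrt_p`), plus the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(cohort, interaction = TRUE) {
  df <- as.data.frame(cohort)
  df$event <- .event_indicator(df$status)
  for (v in c("sex", "site")) {
    lv <- droplevels(factor(df[[v]]))
    if (nlevels(lv) < 2)
      stop("factor '", v, "' needs >= 2 observed levels")
    df[[v]] <- stats::relevel(lv, ref = if (v == "sex") "F" else "TJL")
  }
  if (sum(df$event) == 0) stop("no events: Cox model not estimable")

  full_f <- if (interaction) survival::Surv(age_days, event) ~ sex * site
            else survival::Surv(age_days, event) ~ sex + site
  fit <- survival::coxph(full_f, data = df, ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop("degenerate covariate (separation or confounded term): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  terms <- data.frame(
    name = rownames(sm$coefficients),
    coefficient = sm$coefficients[, "coef"],
    se = sm$coefficients[, "se(coef)"],
    hazard_ratio = sm$coefficients[, "exp(coef)"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  res <- list(terms = terms, loglik_full = fit$loglik[2],
              fit = fit)
  if (interaction) {
    reduced <- survival::coxph(survival::Surv(age_days, event) ~ sex + site,
                               data = df, ties = "efron")
    lrt <- 2 * (fit$loglik[2] - reduced$loglik[2])
    df_lrt <- length(stats::coef(fit)) - length(stats::coef(reduced))
    res$loglik_reduced <- reduced$loglik[2]
    res$lrt_statistic <- max(lrt, 0)
    res$lrt_df <- df_lrt
    res$lrt_p <- stats::pchisq(max(lrt, 0), df_lrt, lower.tail = FALSE)
  }
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards model (Efron ties)\n")
  print(transform(x$terms,
                  hazard_ratio = signif(hazard_ratio, 4),
                  coefficient = signif(coefficient, 4),
                  se = signif(se, 3), p = signif(p, 3)), row.names = FALSE)
  if (!is.null(x$lrt_p))
    cat(sprintf("Interaction LRT: chi2 = %.3f on %d df, p = %.3g\n",
                x$lrt_statistic, x$lrt_df, x$lrt_p))
  invisible(x)
}

#' Lifespan-on-bodyweight regression within an age stratum
#'
#' Ordinary least squares of lifespan (days) on weight (grams) among animals
#' with a weight at the given measurement age, optionally stratified by sex.
#' The standardized coefficient is `beta * sd(weight) / sd(lifespan)`; in
#' this univariate fit its square equals R-squared.
#'
#' @param joined Output of [join_weights()] (died animals only).
#' @param age_months One of 6, 12, 18, 24.
#' @param stratify_by_sex Fit per sex (default) or pooled.
#' @return data.frame with one row per stratum: `stratum`, `age_months`,
#'   `n`, `coefficient` (days/g), `se`, `p`, `r_squared`,
#'   `standardized_coefficient`.
#' @export
weight_regression <- function(joined, age_months, stratify_by_sex = TRUE) {
  sub <- joined[joined$age_months == age_months, , drop = FALSE]
  strata <- if (stratify_by_sex) split(sub, droplevels(factor(sub$sex)))
            else list(pooled = sub)
  rows <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    if (nrow(s) < 3)
      stop("stratum '", nm, "' at ", age_months, " months has < 3 animals")
    if (stats::sd(s$weight_g) == 0)
      stop("zero weight variance in stratum '", nm, "'")
    fit <- stats::lm(lifespan_days ~ weight_g, data = s)
    sm <- summary(fit)
    beta <- sm$coefficients["weight_g", ]
    data.frame(
      stratum = nm, age_months = age_months, n = nrow(s),
      coefficient = unname(beta["Estimate"]),
      se = unname(beta["Std. Error"]),
      p = unname(beta["Pr(>|t|)"]),
      r_squared = sm$r.squared,
      standardized_coefficient = unname(beta["Estimate"]) *
        stats::sd(s$weight_g) / stats::sd(s$lifespan_days)
    )
  })
  do.call(rbind, rows)
}

#' Weight-by-moderator interaction regression of lifespan
#'
#' OLS of lifespan on weight, a categorical moderator (sex or site), and
#' their product terms, within one weight-measurement age. The interaction
#' block is tested with a partial F-test against the main-effects model.
#'
#' @param joined Output of [join_weights()].
#' @param age_months One of 6, 12, 18, 24.
#' @param moderator "sex" or "site".
#' @return List with `terms` (coefficient table), `interaction_f`,
#'   `interaction_df`, `interaction_p`, and the `lm` fit.
#' @export
interaction_regression <- function(joined, age_months,
                                   moderator = c("sex", "site")) {
  moderator <- match.arg(moderator)
  sub <- joined[joined$age_months == age_months, , drop = FALSE]
  sub$mod <- droplevels(factor(sub[[moderator]]))
  if (nlevels(sub$mod) < 2)
    stop("moderator '", moderator, "' needs >= 2 observed levels")
  if (stats::sd(sub$weight_g) == 0) stop("zero weight variance")
  full <- stats::lm(lifespan_days ~ weight_g * mod, data = sub)
  main <- stats::lm(lifespan_days ~ weight_g + mod, data = sub)
  an <- stats::anova(main, full)
  sm <- summary(full)$coefficients
  list(
    terms = data.frame(name = rownames(sm),
                       coefficient = sm[, "Estimate"],
                       se = sm[, "Std. Error"],
                       p = sm[, "Pr(>|t|)"], row.names = NULL),
    interaction_f = an$F[2],
    interaction_df = c(an$Df[2], an$Res.Df[2]),
    interaction_p = an$`Pr(>F)`[2],
    fit = full
  )
}

#' Weight-regression tables across all measurement ages
#'
#' Convenience wrapper producing the pooled (one row per age) and per-sex
#' (two rows per age) regression tables.
#'
#' @param joined Output of [join_weights()].
#' @param ages Measurement ages to include.
#' @return List `pooled`, `by_sex`, each a data.frame.
#' @export
weight_regression_tables <- function(joined, ages = c(6, 12, 18, 24)) {
  ages <- ages[ages %in% unique(joined$age_months)]
  list(
    pooled = do.call(rbind, lapply(ages, function(a)
      weight_regression(joined, a, stratify_by_sex = FALSE))),
    by_sex = do.call(rbind, lapply(ages, function(a)
      weight_regression(joined, a, stratify_by_sex = TRUE)))
  )
}
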