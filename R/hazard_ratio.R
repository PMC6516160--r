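# Age-specific male:female hazard-ratio curve with bootstrap confidence
# bands, and the peak/convergence summary of its shape.

#' Point estimate of the male:female hazard-ratio curve
#'
#' Fits the P-spline hazard smoother separately to each sex with identical
#' settings and takes the ratio on a common age grid, restricted to ages
#' where both sexes have positive person-time. By default each sex's
#' log-hazard receives a twicing (double-smoothing) bias correction before
#' the ratio is formed: the penalty attenuates curvature extremes, and the
#' ratio of two penalized fits inherits that attenuation at the mid-life
#' peak; refitting the smoother to its own fitted counts estimates the
#' self-attenuation, which is subtracted. The correction is identically
#' zero when the fit lies in the penalty null space.
#'
#' @param cohort A `cohort_table` with both sexes.
#' @param grid_step Grid resolution in days (default 5).
#' @param bin_width_days,n_knots,degree,penalty_order,lambda Smoother
#'   settings shared by both sexes (see [fit_smoothed_hazard()]).
#' @param grid Optional explicit age grid (clipped to common support).
#' @param min_at_risk Upper grid limit: largest age at which both sexes still
#'   have at least this many animals at risk (default 10). The hazard ratio
#'   in the extreme tail, where the risk set empties and the spline
#'   extrapolates, is not interpretable.
#' @param tail_quantile Additional upper grid limit: the curve stops at this
#'   empirical quantile of each sex's observed exit ages (default 0.95).
#'   Beyond it only a few percent of a sex remains at risk: the spline's
#'   right boundary is informed by a handful of deaths, the point estimate
#'   wanders, and bootstrap replicates (resamples of the same few animals)
#'   wander with it, so percentile bands undercover there. Survival and
#'   hazard displays are conventionally truncated before this regime.
#' @param bias_correct Apply the twicing correction (default TRUE).
#' @return data.frame `age_days`, `hr`, plus attributes `fit_m`, `fit_f`
#'   (per-sex fit summaries: `lambda`, `effective_df`, `theta`, `span`).
#' @export
hazard_ratio_curve <- function(cohort, grid_step = 5, bin_width_days = 30,
                               n_knots = 31, degree = 1, penalty_order = 2,
                               lambda = "auto", grid = NULL,
                               min_at_risk = 10, tail_quantile = 0.95,
                               bias_correct = TRUE) {
  for (s in c("F", "M")) {
    sub <- cohort[cohort$sex == s, , drop = FALSE]
    if (nrow(sub) == 0 || sum(sub$status == "died") == 0)
      stop("hazard ratio needs events in both sexes; missing stratum: ", s)
  }
  entry <- attr(cohort, "weaning_age_days") %||% 21
  fits <- lapply(c(F = "F", M = "M"), function(s) {
    sel <- cohort$sex == s
    core <- .fit_core(.bin_core(cohort$age_days[sel],
                                cohort$status[sel] == "died",
                                bin_width_days, entry),
                      lambda, n_knots, degree, penalty_order, 1)
    theta <- if (bias_correct) .twice_theta(core) else core$fit$theta
    list(theta = theta, span = core$span, lambda = core$lambda,
         effective_df = core$fit$edf)
  })
  # common support: ages where both sexes retain a meaningful risk set
  lo <- entry
  sex_cap <- function(a) {
    k <- min(min_at_risk, length(a))
    min(sort(a, decreasing = TRUE)[k],
        stats::quantile(a, tail_quantile, type = 1, names = FALSE))
  }
  hi <- min(sex_cap(cohort$age_days[cohort$sex == "F"]),
            sex_cap(cohort$age_days[cohort$sex == "M"]))
  if (is.null(grid)) grid <- seq(lo, hi, by = grid_step)
  grid <- grid[grid >= lo & grid <= hi]
  eta <- lapply(fits, function(f)
    drop(bspline_basis(grid, n_knots, degree, range = f$span) %*% f$theta))
  structure(data.frame(age_days = grid, hr = exp(eta$M - eta$F)),
            fit_m = fits$M, fit_f = fits$F,
            class = c("hr_curve", "data.frame"))
}

#' Bootstrap confidence bands for the hazard-ratio curve
#'
#' Resamples animals with replacement within each sex, recomputes the HR
#' curve per replicate on the common grid (the smoothing parameter is
#' re-selected within each replicate unless `lambda` is fixed), and forms
#' pointwise percentile bands. Replicates in which one sex draws no events
#' are redrawn and counted.
#'
#' @param cohort A `cohort_table`.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; the whole band is reproducible given it.
#' @param conf_level Band level (default 0.95).
#' @param keep_replicates Store the replicate curves (matrix) in the result.
#' @param grid Optional explicit age grid (e.g. a single age of interest);
#'   defaults to the point-estimate curve's grid.
#' @param ... Smoother settings passed to [hazard_ratio_curve()].
#' @return An `hr_band`: data.frame `age_days`, `hr`, `band_lo`, `band_hi`,
#'   with attributes `n_bootstrap`, `n_redraws`, `replicates` (optional),
#'   and the summary fields of [hr_summary()].
#' @export
bootstrap_hr <- function(cohort, B = 1000, seed = 1L, conf_level = 0.95,
                         keep_replicates = FALSE, grid = NULL, ...) {
  stopifnot(B >= 2)
  point <- hazard_ratio_curve(cohort, grid = grid, ...)
  grid <- point$age_days

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  entry <- attr(cohort, "weaning_age_days") %||% 21
  dots <- list(...)
  bw <- dots$bin_width_days %||% 30
  nk <- dots$n_knots %||% 31
  dg <- dots$degree %||% 1
  po <- dots$penalty_order %||% 2
  lam <- dots$lambda %||% "auto"
  bias_correct <- dots$bias_correct %||% TRUE

  lam0_f <- min(attr(point, "fit_f")$lambda, 1e6)
  lam0_m <- min(attr(point, "fit_m")$lambda, 1e6)
  age_f <- cohort$age_days[cohort$sex == "F"]
  died_f <- cohort$status[cohort$sex == "F"] == "died"
  age_m <- cohort$age_days[cohort$sex == "M"]
  died_m <- cohort$status[cohort$sex == "M"] == "died"
  nf <- length(age_f); nm <- length(age_m)

  reps <- matrix(NA_real_, nrow = B, ncol = length(grid))
  n_redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      tf <- sample.int(nf, nf, replace = TRUE)
      tm <- sample.int(nm, nm, replace = TRUE)
      if (any(died_f[tf]) && any(died_m[tm])) break
      n_redraws <- n_redraws + 1L
    }
    # replicate-level smoothing warnings (unconverged lambda iterations at
    # their cap) are routine and would swamp the session; the point-estimate
    # fit above still surfaces them
    # warm-start each replicate's smoothing selection at the original
    # sample's selected lambda: same fixed point, far fewer iterations
    suppressWarnings({
      cf <- .fit_core(.bin_core(age_f[tf], died_f[tf], bw, entry),
                      lam, nk, dg, po, 1, lambda0 = lam0_f)
      cm <- .fit_core(.bin_core(age_m[tm], died_m[tm], bw, entry),
                      lam, nk, dg, po, 1, lambda0 = lam0_m)
    })
    th_f <- if (bias_correct) .twice_theta(cf) else cf$fit$theta
    th_m <- if (bias_correct) .twice_theta(cm) else cm$fit$theta
    hi_b <- min(cf$span[2], cm$span[2])
    on_grid <- grid <= hi_b
    g <- grid[on_grid]
    ef <- drop(bspline_basis(g, nk, dg, range = cf$span) %*% th_f)
    em <- drop(bspline_basis(g, nk, dg, range = cm$span) %*% th_m)
    reps[b, on_grid] <- exp(em - ef)
  }
  alpha <- (1 - conf_level) / 2
  # inverse-ECDF quantiles (type 1), so small-B bands take the replicate
  # extremes rather than interpolating between them
  band <- apply(reps, 2, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE, type = 1)
  out <- data.frame(age_days = grid, hr = point$hr,
                    band_lo = band[1, ], band_hi = band[2, ])
  out <- structure(out, n_bootstrap = B, n_redraws = n_redraws,
                   replicates = if (keep_replicates) reps else NULL,
                   class = c("hr_band", "hr_curve", "data.frame"))
  summ <- hr_summary(out)
  attr(out, "peak_age_days") <- summ$peak_age_days
  attr(out, "peak_hr") <- summ$peak_hr
  attr(out, "convergence_age_days") <- summ$convergence_age_days
  out
}

#' Summarize a hazard-ratio curve: peak and convergence
#'
#' The peak is the argmax of the point-estimate HR (first grid age on ties);
#' the curve is flagged as having no distinct peak when its total range is
#' below 0.05. The convergence age is the smallest grid age after the peak
#' from which the confidence band contains 1 at every later grid age —
#' sustained indistinguishability of the sexes, not a single touch.
#'
#' @param curve An `hr_band` (or `hr_curve`; then convergence is `NA`).
#' @return List `peak_age_days`, `peak_hr`, `convergence_age_days` (`NA` if
#'   the band never permanently contains 1), `no_distinct_peak`.
#' @export
hr_summary <- function(curve) {
  i <- which.max(curve$hr)
  flat <- (max(curve$hr) - min(curve$hr)) < 0.05
  peak_age <- curve$age_days[i]
  conv <- NA_real_
  if (!is.null(curve$band_lo)) {
    post <- which(curve$age_days > peak_age)
    contains1 <- curve$band_lo <= 1 & curve$band_hi >= 1
    # smallest post-peak age from which the band contains 1 ever after
    ok <- post[vapply(post, function(j) all(contains1[j:nrow(curve)]),
                      logical(1))]
    if (length(ok) > 0) conv <- curve$age_days[min(ok)]
  }
  list(peak_age_days = peak_age, peak_hr = curve$hr[i],
       convergence_age_days = conv, no_distinct_peak = flat)
}

#' @export
print.hr_band <- function(x, ...) {
  s <- hr_summary(x)
  cat("Male:female hazard-ratio curve with bootstrap band\n")
  cat(sprintf("  %d replicates; grid %g-%g d\n", attr(x, "n_bootstrap"),
              min(x$age_days), max(x$age_days)))
  cat(sprintf("  peak HR = %.2f at %g d; convergence at %s d\n",
              s$peak_hr, s$peak_age_days,
              ifelse(is.na(s$convergence_age_days), "never",
                     format(s$convergence_age_days))))
  invisible(x)
}
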