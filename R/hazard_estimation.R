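# Smoothed age-specific mortality via a penalized B-spline Poisson model on
# binned person-time (a P-spline hazard smoother). Deaths d_j and exposure
# R_j (animal-days) per age bin are sufficient: d_j ~ Poisson(R_j * h_j) with
# log h_j a B-spline in age, penalized by squared p-th order differences of
# the coefficients. The smoothing parameter is either fixed or selected by a
# variance-component (mixed-model) iteration.

#' Bin deaths and person-time by age
#'
#' Animals enter observation at `entry_age` (left truncation at weaning) and
#' contribute person-time equal to the overlap of `(entry_age, age_days]`
#' with each bin. Bins are half-open `[e_j, e_{j+1})` except the last, which
#' is closed, so a death exactly at the upper boundary is counted.
#'
#' @param cohort A `cohort_table` (or data.frame with `age_days`, `status`).
#' @param bin_width_days Positive bin width (default 30).
#' @param entry_age Age at study entry in days; defaults to the cohort's
#'   weaning age attribute, else 21.
#' @param bin_edges Optional explicit increasing edge vector overriding
#'   `bin_width_days`.
#' @return An `exposure_table`: data.frame with `bin_lo`, `bin_hi`, `mid`,
#'   `d` (deaths), `R` (animal-days), plus attributes `n_animals`,
#'   `n_events`, `entry_age`.
#' @export
bin_exposure <- function(cohort, bin_width_days = 30, entry_age = NULL,
                         bin_edges = NULL) {
  if (is.null(entry_age))
    entry_age <- attr(cohort, "weaning_age_days") %||% 21
  .bin_core(cohort$age_days, cohort$status == "died",
            bin_width_days, entry_age, bin_edges)
}

# vector-level binning core shared with the bootstrap fast path
.bin_core <- function(age, died, bin_width_days = 30, entry_age = 21,
                      bin_edges = NULL) {
  if (any(age < entry_age))
    stop("age_days below entry_age: left truncation violated")
  if (is.null(bin_edges)) {
    if (bin_width_days <= 0) stop("bin_width_days must be positive")
    top <- max(age)
    bin_edges <- seq(entry_age, top + bin_width_days, by = bin_width_days)
  }
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be increasing")
  J <- length(bin_edges) - 1
  lo <- bin_edges[-(J + 1)]
  hi <- bin_edges[-1]

  # person-time: overlap of (entry_age, age] with each bin, in O(n + J):
  # full width for every bin an animal outlives, a partial width in the bin
  # where it exits, nothing later. All animals share entry_age, at or below
  # the first edge (exposure before the first edge is outside the table).
  start <- max(entry_age, lo[1])
  age_cap <- pmin(age, hi[J])
  exit_bin <- findInterval(age_cap, bin_edges, rightmost.closed = TRUE)
  n_exit <- tabulate(exit_bin, nbins = J)
  n_alive_into <- length(age) - c(0, cumsum(n_exit))[seq_len(J)]
  sum_exit_age <- numeric(J)
  agg <- rowsum(age_cap, exit_bin)
  sum_exit_age[as.integer(rownames(agg))] <- agg
  R <- (n_alive_into - n_exit) * (hi - lo) + (sum_exit_age - n_exit * lo)
  R[1] <- R[1] - n_alive_into[1] * (start - lo[1])
  # deaths: half-open bins [lo, hi) except last bin closed
  idx <- findInterval(age[died], bin_edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= J]
  d <- tabulate(idx, nbins = J)

  out <- data.frame(bin_lo = lo, bin_hi = hi, mid = (lo + hi) / 2,
                    d = d, R = R)
  structure(out,
            n_animals = length(age), n_events = sum(died),
            entry_age = entry_age, bin_edges = bin_edges,
            class = c("exposure_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' B-spline basis over an age grid
#'
#' Equally spaced interior knots over the grid range, with boundary knots at
#' the range ends; evaluated via the standard spline design so that rows form
#' a partition of unity.
#'
#' @param age_grid Evaluation ages (days), inside the knot span.
#' @param n_knots Number of interior knots (>= 2 segments overall).
#' @param degree Spline degree (>= 0; 0 gives bin indicators).
#' @param range Optional length-2 span; defaults to `range(age_grid)`.
#' @return Matrix (length(age_grid) x n basis functions) with attributes
#'   `knots` (full knot vector) and `degree`.
#' @export
bspline_basis <- function(age_grid, n_knots = 12, degree = 3, range = NULL) {
  if (degree < 0) stop("degree must be >= 0")
  if (is.null(range)) range <- base::range(age_grid)
  if (any(age_grid < range[1] - 1e-9) || any(age_grid > range[2] + 1e-9))
    stop("age_grid outside knot range")
  inner <- if (n_knots > 0)
    seq(range[1], range[2], length.out = n_knots + 2)[-c(1, n_knots + 2)]
  else numeric(0)
  knots <- c(rep(range[1], degree + 1), inner, rep(range[2], degree + 1))
  x <- pmin(pmax(age_grid, range[1]), range[2])
  # splineDesign treats the support as right-open; nudge the right boundary in
  x[x >= range[2]] <- range[2] - 1e-9 * max(1, abs(range[2]))
  B <- splines::splineDesign(knots, x, ord = degree + 1)
  structure(B, knots = knots, degree = degree, span = range)
}

# order-p difference penalty matrix for q coefficients
.diff_penalty <- function(q, p) {
  D <- diff(diag(q), differences = p)
  D
}

#' Fit the penalized B-spline Poisson hazard model
#'
#' Maximizes `sum_j [d_j log(h_j R_j) - h_j R_j] - (lambda/2) ||D_p theta||^2`
#' with `log h_j = B(mid_j) theta`, by penalized iteratively reweighted least
#' squares. Pointwise confidence bands come from the penalized-information
#' covariance of the linear predictor, `B (B'WB + lambda P)^-1 B'`, on the
#' log-hazard scale.
#'
#' @param exposure An `exposure_table` from [bin_exposure()].
#' @param lambda Positive smoothing parameter, or `"auto"` to select it via
#'   [select_smoothing()].
#' @param n_knots,degree Basis settings; the defaults (31 interior knots,
#'   linear B-splines) mirror common practice for penalized hazard
#'   smoothing, where a rich low-degree basis carries flexibility and the
#'   difference penalty carries smoothness.
#' @param penalty_order Difference order of the penalty (default 2, so
#'   infinite smoothing tends to a Gompertz, i.e. log-linear, hazard).
#' @param phi Overdispersion; 1 (default) or `"pearson"` to estimate.
#' @param grid_step Output grid resolution in days (default 1).
#' @param conf_level Pointwise confidence level (default 0.95).
#' @return A `hazard_curve`: data.frame `age_days`, `hazard`, `se_log`,
#'   `ci_lo`, `ci_hi`, with attributes `lambda`, `effective_df`, `theta`,
#'   `n_events`, `n_animals`, `phi`, and the fit internals.
#' @export
fit_smoothed_hazard <- function(exposure, lambda = "auto", n_knots = 31,
                                degree = 1, penalty_order = 2, phi = 1,
                                grid_step = 1, conf_level = 0.95) {
  core <- .fit_core(exposure, lambda, n_knots, degree, penalty_order, phi)
  fit <- core$fit
  span <- core$span
  phi <- core$phi
  lambda <- core$lambda

  grid <- seq(span[1], span[2], by = grid_step)
  Bg <- bspline_basis(grid, n_knots = n_knots, degree = degree, range = span)
  eta <- drop(Bg %*% fit$theta)
  se <- sqrt(phi * rowSums((Bg %*% fit$Hinv) * Bg))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  out <- data.frame(age_days = grid, hazard = exp(eta), se_log = se,
                    ci_lo = exp(eta - zq * se), ci_hi = exp(eta + zq * se))
  structure(out,
            lambda = lambda, effective_df = fit$edf, theta = fit$theta,
            phi = phi, n_events = attr(exposure, "n_events"),
            n_animals = attr(exposure, "n_animals"),
            basis = list(n_knots = n_knots, degree = degree, span = span,
                         penalty_order = penalty_order),
            class = c("hazard_curve", "data.frame"))
}

# Shared fitting core: basis construction, lambda resolution, IRLS, phi.
.fit_core <- function(exposure, lambda, n_knots, degree, penalty_order, phi,
                      lambda0 = 10) {
  if (sum(exposure$d) == 0) stop("no events: hazard not estimable")
  keep <- exposure$R > 0
  mid <- exposure$mid[keep]
  d <- exposure$d[keep]
  R <- exposure$R[keep]
  span <- c(min(exposure$bin_lo), max(exposure$bin_hi))

  B <- bspline_basis(mid, n_knots = n_knots, degree = degree, range = span)
  if (identical(lambda, "auto")) {
    sel <- select_smoothing(exposure, n_knots = n_knots, degree = degree,
                            penalty_order = penalty_order, phi = phi,
                            lambda0 = lambda0)
    lambda <- sel$lambda
  }
  fit <- .pirls_poisson(B, d, R, lambda, penalty_order)
  if (!fit$converged)
    stop("P-spline IRLS failed to converge; max coefficient change trace: ",
         paste(signif(utils::tail(fit$trace, 5), 3), collapse = ", "))
  if (identical(phi, "pearson")) {
    mu <- R * exp(drop(B %*% fit$theta))
    phi <- sum((d - mu)^2 / mu) / max(1, length(d) - fit$edf)
  }
  list(fit = fit, span = span, lambda = lambda, phi = phi,
       n_knots = n_knots, degree = degree, B = B, d = d, R = R,
       penalty_order = penalty_order)
}

# Twicing (double-smoothing) bias correction: refit the smoother to its own
# fitted event counts; the difference estimates the penalty's self-
# attenuation, which is then subtracted. Exact zero for any fit in the
# penalty null space (e.g. Gompertz log-linear truth).
.twice_theta <- function(core) {
  fit <- core$fit
  d_star <- core$R * exp(pmin(drop(core$B %*% fit$theta), 0))
  refit <- .pirls_poisson(core$B, d_star, core$R, core$lambda,
                          core$penalty_order, start = fit$theta)
  2 * fit$theta - refit$theta
}

# Penalized IRLS for d ~ Poisson(R * exp(B theta)).
.pirls_poisson <- function(B, d, R, lambda, penalty_order,
                           tol = 1e-8, maxit = 100, start = NULL,
                           DtD = NULL) {
  q <- ncol(B)
  if (is.null(DtD)) DtD <- crossprod(.diff_penalty(q, penalty_order))
  P <- lambda * DtD
  if (is.null(start)) {
    # start at the log of the overall occurrence/exposure rate
    theta <- rep(log(max(sum(d), 0.5) / sum(R)), q)
  } else theta <- start
  eta <- drop(B %*% theta)
  trace <- numeric(maxit)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- R * exp(eta)
    w <- mu
    z <- eta + (d - mu) / mu
    Mw <- crossprod(B, w * B)
    H <- Mw + P
    # tiny ridge (on the data-information scale, so it cannot perturb the
    # penalty null space even at extreme lambda) guards against numerically
    # empty basis support in sparse resamples
    diag(H) <- diag(H) + 1e-9 * max(diag(Mw))
    cho <- chol(H)
    rhs <- crossprod(B, w * z)
    theta_new <- drop(backsolve(cho, backsolve(cho, rhs, transpose = TRUE)))
    delta <- max(abs(theta_new - theta))
    trace[it] <- delta
    theta <- theta_new
    eta <- pmin(pmax(drop(B %*% theta), -30), 0)
    if (delta < tol) { converged <- TRUE; break }
  }
  # at convergence the last factorization is current to within tol
  Hinv <- chol2inv(cho)
  edf <- sum(Hinv * (H - P))   # tr(Hinv M), both symmetric
  list(theta = theta, Hinv = Hinv, edf = edf, converged = converged,
       trace = trace[seq_len(it)])
}

#' Select the smoothing parameter by variance components
#'
#' Treats the penalized coefficients as random effects with variance
#' `sigma2 = phi / lambda` and alternates: (i) fit the P-spline given
#' `lambda`; (ii) update `sigma2` as the mean of the squared p-th differences
#' of the coefficients plus the trace correction from the coefficient
#' covariance; stop when the relative change in `lambda` is below `tol`.
#'
#' @param exposure An `exposure_table`.
#' @param n_knots,degree,penalty_order As in [fit_smoothed_hazard()].
#' @param phi Overdispersion (fixed value; default 1).
#' @param lambda0 Starting value.
#' @param tol Relative-change convergence tolerance on `lambda`.
#' @param maxit Maximum outer iterations.
#' @return List with `lambda`, `effective_df`, `converged`, `iterations`.
#' @export
select_smoothing <- function(exposure, n_knots = 31, degree = 1,
                             penalty_order = 2, phi = 1,
                             lambda0 = 10, tol = 1e-4, maxit = 50) {
  keep <- exposure$R > 0
  mid <- exposure$mid[keep]
  d <- exposure$d[keep]
  R <- exposure$R[keep]
  span <- c(min(exposure$bin_lo), max(exposure$bin_hi))
  B <- bspline_basis(mid, n_knots = n_knots, degree = degree, range = span)
  q <- ncol(B)
  D <- .diff_penalty(q, penalty_order)
  m <- nrow(D)

  DtD <- crossprod(D)
  lambda_max <- 1e8   # smoothing boundary: the fit is the penalty-null limit
  update <- function(lambda, theta) {
    fit <- .pirls_poisson(B, d, R, lambda, penalty_order, start = theta,
                          DtD = DtD)
    u <- drop(D %*% fit$theta)
    # E||D theta||^2 = ||D theta_hat||^2 + tr(D Cov(theta) D')
    sigma2 <- (sum(u^2) + phi * sum((D %*% fit$Hinv) * D)) / m
    list(lambda = phi / sigma2, fit = fit)
  }

  lambda <- lambda0
  converged <- FALSE
  fit <- NULL
  theta <- NULL
  dz_prev <- r_prev <- NA_real_
  for (it in seq_len(maxit)) {
    step <- update(lambda, theta)
    fit <- step$fit
    theta <- fit$theta
    lambda_new <- step$lambda
    if (abs(lambda_new - lambda) / lambda < tol) {
      lambda <- lambda_new
      converged <- TRUE
      break
    }
    # Aitken acceleration on log(lambda): the update map contracts toward an
    # interior fixed point (or, when the log-hazard lies in the penalty null
    # space, drifts geometrically toward the smoothing boundary); once the
    # step ratio stabilizes, extrapolate to skip the slow tail
    dz <- log(lambda_new) - log(lambda)
    jumped <- FALSE
    if (is.finite(dz_prev) && abs(dz_prev) > 0) {
      r <- dz / dz_prev
      if (is.finite(r) && r > 0 && is.finite(r_prev) &&
          abs(r - r_prev) < 0.05) {
        zeta_acc <- if (r < 1) log(lambda_new) + dz * r / (1 - r)
                    else log(lambda_max)
        lambda_new <- min(exp(zeta_acc), lambda_max)
        jumped <- TRUE
      }
      r_prev <- r
    }
    dz_prev <- if (jumped) NA_real_ else dz
    if (jumped) r_prev <- NA_real_
    lambda <- lambda_new
    if (lambda >= lambda_max) {
      # boundary: the curve has collapsed to the penalty-null limit and no
      # longer changes with lambda
      lambda <- lambda_max
      fit <- .pirls_poisson(B, d, R, lambda, penalty_order, start = theta,
                            DtD = DtD)
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("smoothing-parameter iteration unconverged after ", maxit,
            " iterations; returning last iterate")
  list(lambda = lambda, effective_df = fit$edf,
       converged = converged, iterations = it)
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat("Smoothed hazard curve\n")
  cat(sprintf("  ages %g-%g d; %d events / %d animals\n",
              min(x$age_days), max(x$age_days),
              attr(x, "n_events"), attr(x, "n_animals")))
  cat(sprintf("  lambda = %.4g, effective df = %.2f\n",
              attr(x, "lambda"), attr(x, "effective_df")))
  invisible(x)
}

#' Evaluate a fitted hazard curve at arbitrary ages
#' @param curve A `hazard_curve`.
#' @param age_days Ages within the fitted span.
#' @return Hazard per day at each age.
#' @export
eval_hazard <- function(curve, age_days) {
  b <- attr(curve, "basis")
  Bg <- bspline_basis(age_days, n_knots = b$n_knots, degree = b$degree,
                      range = b$span)
  drop(exp(Bg %*% attr(curve, "theta")))
}
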