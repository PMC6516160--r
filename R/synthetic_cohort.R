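# Synthetic cohorts with the statistical structure the downstream analyses
# assume: a Gompertz female baseline, a smooth mid-life bump in the male:female
# hazard ratio that closes by a convergence age, male-only site multipliers,
# cage-level censoring of males, and a shared per-animal frailty that drives
# both mortality and bodyweight.

#' Build a simulation configuration
#'
#' All structure of the generator is parameterized here. The female hazard is
#' Gompertz, `h_F(t) = a * exp(b * t)` (per day); the male hazard is
#' `m_site * h_F(t) * r(t)` where `log r(t) = log(peak_ratio) * B(t)` and `B`
#' is a smooth piecewise-cubic bump equal to 0 at weaning, 1 at
#' `hr_peak_age_days`, and 0 from `hr_convergence_age_days` onward. A
#' standard-normal frailty `z` per animal multiplies its hazard by
#' `exp(frailty_hazard_coupling_sex * z)` and shifts its adult bodyweight
#' asymptote by `frailty_weight_coupling_sex * z` grams, producing the
#' weight-lifespan correlation. Male cages (3 animals) are censored with
#' probability `cage_censor_prob_m` at an age uniform between weaning and the
#' cage's earliest death, emulating whole-cage removal after fight injuries.
#'
#' @param n_per_sex_per_site Animals per sex per site.
#' @param sites Named numeric vector of male hazard multipliers per site.
#' @param cohorts Integer vector of cohort years to cycle animals over.
#' @param gompertz_a,gompertz_b Female Gompertz baseline (per-day scale and
#'   slope). If `gompertz_a` is `NULL` it is solved so that the female median
#'   lifespan equals `target_median_f_days`.
#' @param target_median_f_days Female median used to calibrate `gompertz_a`.
#' @param hr_peak_age_days,hr_peak_ratio,hr_convergence_age_days Shape of the
#'   male excess-mortality bump (ratio >= 1; weaning < peak < convergence).
#' @param weaning_age_days Study entry age (days).
#' @param cage_size_m,cage_size_f Animals per cage.
#' @param cage_censor_prob_m Probability a male cage is censored.
#' @param admin_censor_age_days Optional administrative censoring age.
#' @param weight_model List of bodyweight-model parameters; see
#'   [simulate_weights()].
#' @param frailty_hazard_coupling Named vector (F, M) of log-hazard loadings
#'   on the frailty.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_sex_per_site = 600,
                       sites = c(TJL = 1, UM = 0.75, UT = 1),
                       cohorts = 2004:2009,
                       gompertz_a = NULL,
                       gompertz_b = 0.004,
                       target_median_f_days = 893,
                       hr_peak_age_days = 350,
                       hr_peak_ratio = 2.2,
                       hr_convergence_age_days = 800,
                       weaning_age_days = 21,
                       cage_size_m = 3,
                       cage_size_f = 4,
                       cage_censor_prob_m = 0.06,
                       admin_censor_age_days = NULL,
                       weight_model = list(
                         mu_asymptote_f_g = 32,
                         mu_asymptote_m_g = 42,
                         growth_rate_k = 0.012,
                         frailty_weight_coupling_f = 0.8,
                         frailty_weight_coupling_m = 1.5,
                         terminal_loss_fraction = 0.10,
                         terminal_window_days = 90,
                         measurement_noise_sd_g = 1.5
                       ),
                       frailty_hazard_coupling = c(F = 0.2, M = 0.2),
                       seed = 1L) {
  stopifnot(hr_peak_ratio >= 1,
            hr_convergence_age_days > hr_peak_age_days,
            hr_peak_age_days > weaning_age_days,
            cage_censor_prob_m >= 0, cage_censor_prob_m <= 1,
            gompertz_b > 0, all(sites > 0))
  if (is.null(gompertz_a)) {
    # closed-form Gompertz median from entry at weaning:
    # (a/b) * (exp(b*t_med) - exp(b*t0)) = log 2
    gompertz_a <- gompertz_b * log(2) /
      (exp(gompertz_b * target_median_f_days) -
         exp(gompertz_b * weaning_age_days))
  }
  cfg <- list(
    n_per_sex_per_site = n_per_sex_per_site,
    sites = sites, cohorts = cohorts,
    gompertz_a = gompertz_a, gompertz_b = gompertz_b,
    hr_peak_age_days = hr_peak_age_days,
    hr_peak_ratio = hr_peak_ratio,
    hr_convergence_age_days = hr_convergence_age_days,
    weaning_age_days = weaning_age_days,
    cage_size_m = cage_size_m, cage_size_f = cage_size_f,
    cage_censor_prob_m = cage_censor_prob_m,
    admin_censor_age_days = admin_censor_age_days,
    weight_model = weight_model,
    frailty_hazard_coupling = frailty_hazard_coupling,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Paper-like preset configuration
#'
#' Calibrated so that the simulated females have a median lifespan near 887
#' days, the male:female hazard ratio peaks near 2.2 around 350 days and
#' converges by about 800 days, males at UM carry a reduced hazard, and male
#' bodyweight is more lifespan-predictive than female with a sign reversal at
#' the 24-month measurement.
#'
#' @param n_per_sex_per_site Animals per sex per site.
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
paper_like_config <- function(n_per_sex_per_site = 600, seed = 1L, ...) {
  sim_config(n_per_sex_per_site = n_per_sex_per_site, seed = seed, ...)
}

#' Null preset: no sex, site, or coupling differences
#'
#' Males and females share one hazard and one weight model; used for type-I
#' error calibration of the downstream tests.
#'
#' @param n_per_sex_per_site Animals per sex per site.
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(n_per_sex_per_site = 600, seed = 1L, ...) {
  sim_config(n_per_sex_per_site = n_per_sex_per_site, seed = seed,
             sites = c(TJL = 1, UM = 1, UT = 1),
             hr_peak_ratio = 1,
             cage_censor_prob_m = 0,
             weight_model = list(
               mu_asymptote_f_g = 37, mu_asymptote_m_g = 37,
               growth_rate_k = 0.012,
               frailty_weight_coupling_f = 1.0,
               frailty_weight_coupling_m = 1.0,
               terminal_loss_fraction = 0.10,
               terminal_window_days = 90,
               measurement_noise_sd_g = 1.5
             ),
             frailty_hazard_coupling = c(F = 0.2, M = 0.2),
             ...)
}

# Smooth unimodal bump: two cubic Hermite "smoothstep" segments with zero
# slope at weaning, peak, and convergence; identically 0 outside
# (weaning, convergence).
.hr_bump <- function(t, weaning, peak, convergence) {
  b <- numeric(length(t))
  up <- t > weaning & t <= peak
  s <- (t[up] - weaning) / (peak - weaning)
  b[up] <- 3 * s^2 - 2 * s^3
  dn <- t > peak & t < convergence
  u <- (convergence - t[dn]) / (convergence - peak)
  b[dn] <- 3 * u^2 - 2 * u^3
  b
}

#' True hazard of the generator
#'
#' Deterministic in the configuration; the marginal (frailty-free) hazard.
#'
#' @param config A `sim_config`.
#' @param sex "F" or "M".
#' @param site Site label present in `config$sites`.
#' @param age_days Ages (days), all at or above weaning.
#' @return Hazard per day at each age.
#' @export
true_hazard <- function(config, sex, site, age_days) {
  if (any(age_days < config$weaning_age_days))
    stop("age below weaning: hazard undefined before study entry")
  h <- config$gompertz_a * exp(config$gompertz_b * age_days)
  if (sex == "M") {
    m <- config$sites[[site]]
    r <- exp(log(config$hr_peak_ratio) *
               .hr_bump(age_days, config$weaning_age_days,
                        config$hr_peak_age_days,
                        config$hr_convergence_age_days))
    h <- m * h * r
  }
  h
}

#' True male:female hazard ratio of the generator
#' @param config A `sim_config`.
#' @param age_days Ages (days).
#' @param site Site label (default the first configured site).
#' @return Dimensionless ratio at each age.
#' @export
true_hr <- function(config, age_days, site = names(config$sites)[1]) {
  true_hazard(config, "M", site, age_days) /
    true_hazard(config, "F", site, age_days)
}

# Cumulative hazard from weaning on a 1-day grid, extended analytically in
# the Gompertz tail (the bump is 0 beyond convergence, so the male hazard is
# proportional to the female Gompertz there). Returns an inverter:
# death age such that integrated hazard from weaning equals a given value.
.cum_hazard_inverter <- function(config, sex, site) {
  t0 <- config$weaning_age_days
  tc <- config$hr_convergence_age_days
  a <- config$gompertz_a; b <- config$gompertz_b
  grid <- seq(t0, max(tc + 200, 1500), by = 1)
  h <- true_hazard(config, sex, site, grid)
  H <- c(0, cumsum((h[-1] + h[-length(h)]) / 2 * diff(grid)))
  tail_t <- grid[length(grid)]
  tail_H <- H[length(H)]
  tail_m <- if (sex == "M") config$sites[[site]] else 1
  function(target) {
    out <- numeric(length(target))
    inside <- target <= tail_H
    out[inside] <- stats::approx(H, grid, xout = target[inside],
                                 ties = "ordered")$y
    if (any(!inside)) {
      # invert tail_H + (m*a/b) * (exp(b*t) - exp(b*tail_t)) = target
      ex <- (target[!inside] - tail_H) * b / (tail_m * a) + exp(b * tail_t)
      out[!inside] <- log(ex) / b
    }
    out
  }
}

# Derived per-site seed so each site block can be regenerated independently.
.site_seed <- function(seed, site_index) {
  as.integer((as.numeric(seed) * 1009 + 7907 * site_index) %% 2147483647)
}

#' Simulate a cohort of lifespans under the configured hazards
#'
#' Each animal draws a standard-normal frailty `z`; its death age inverts the
#' cumulative marginal hazard scaled by `exp(coupling_sex * z)`, starting at
#' weaning. Males are then grouped into cages; each male cage is censored
#' with probability `cage_censor_prob_m`, all members at a common age drawn
#' uniformly between weaning and the cage's earliest death. Administrative
#' censoring, if configured, truncates every survivor at a fixed age.
#' Bit-reproducible given the seed.
#'
#' @param config A `sim_config`.
#' @return A list of class `simulated_cohort` with elements `cohort`
#'   (a [cohort_table()]), `weights` (see [simulate_weights()]), and `truth`
#'   (per-animal frailty and pre-censoring death age, plus a grid of the true
#'   hazards and HR).
#' @export
simulate_cohort <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  site_names <- names(config$sites)
  blocks <- list()
  for (si in seq_along(site_names)) {
    set.seed(.site_seed(config$seed, si))
    site <- site_names[si]
    for (sex in c("F", "M")) {
      n <- config$n_per_sex_per_site
      z <- stats::rnorm(n)
      coup <- config$frailty_hazard_coupling[[sex]]
      inv <- .cum_hazard_inverter(config, sex, site)
      e <- stats::rexp(n)
      death <- inv(e / exp(coup * z))
      blocks[[length(blocks) + 1]] <- data.frame(
        mouse_id = sprintf("%s_%s_%04d", site, sex, seq_len(n)),
        sex = sex, site = site,
        cohort = rep_len(config$cohorts, n),
        death_age = death, frailty = z,
        stringsAsFactors = FALSE
      )
    }
  }
  an <- do.call(rbind, blocks)

  age <- an$death_age
  status <- rep("died", nrow(an))
  cage <- rep(NA_character_, nrow(an))

  # male cage-level censoring, per site
  set.seed(.site_seed(config$seed, length(site_names) + 1L))
  for (site in site_names) {
    im <- which(an$sex == "M" & an$site == site)
    if (length(im) == 0) next
    cage_idx <- ceiling(seq_along(im) / config$cage_size_m)
    cage[im] <- sprintf("%s_M_c%03d", site, cage_idx)
    for (cg in unique(cage_idx)) {
      members <- im[cage_idx == cg]
      if (stats::runif(1) < config$cage_censor_prob_m) {
        first_death <- min(an$death_age[members])
        cage_age <- stats::runif(1, config$weaning_age_days, first_death)
        age[members] <- cage_age
        status[members] <- "censored"
      }
    }
  }
  # female cages (no censoring mechanism, labels only)
  for (site in site_names) {
    ifem <- which(an$sex == "F" & an$site == site)
    cage[ifem] <- sprintf("%s_F_c%03d", site,
                          ceiling(seq_along(ifem) / config$cage_size_f))
  }
  if (!is.null(config$admin_censor_age_days)) {
    adm <- config$admin_censor_age_days
    over <- age > adm
    age[over] <- adm
    status[over] <- "censored"
  }

  records <- data.frame(
    mouse_id = an$mouse_id, sex = an$sex, site = an$site,
    cohort = an$cohort, age_days = age, status = status,
    cage_id = cage, stringsAsFactors = FALSE
  )
  cohort <- cohort_table(records, provenance = "simulated",
                         weaning_age_days = config$weaning_age_days)

  weights <- simulate_weights(config, data.frame(
    mouse_id = an$mouse_id, sex = an$sex,
    frailty = an$frailty, death_age = an$death_age,
    observed_age = age, stringsAsFactors = FALSE
  ))

  grid <- seq(config$weaning_age_days, 1200, by = 5)
  truth_hazard <- data.frame(
    age_days = grid,
    hazard_f = true_hazard(config, "F", site_names[1], grid),
    hazard_m = true_hazard(config, "M", site_names[1], grid),
    hr = true_hr(config, grid)
  )
  structure(list(
    cohort = cohort,
    weights = weights,
    truth = list(
      animals = data.frame(mouse_id = an$mouse_id, frailty = an$frailty,
                           true_death_age = an$death_age,
                           stringsAsFactors = FALSE),
      hazard_grid = truth_hazard
    ),
    config = config
  ), class = "simulated_cohort")
}

#' Simulate scheduled bodyweight measurements
#'
#' Weight at measurement age `a` (days) for animal `i`:
#' `W_i(a) = A_i * (1 - exp(-k * a)) - loss * A_i * max(0, 1 - (death - a)/window) + noise`,
#' with asymptote `A_i = mu_asymptote_sex + coupling_sex * z_i`. The terminal
#' loss term makes animals close to death lighter, which among 24-month
#' survivors reverses the weight-lifespan slope. Weights are only emitted for
#' animals still under observation at the measurement age.
#'
#' @param config A `sim_config`.
#' @param animals data.frame with `mouse_id`, `sex`, `frailty`, `death_age`,
#'   and `observed_age` (age at death or censoring).
#' @return data.frame of weight records (`mouse_id`, `age_months`,
#'   `weight_g`, `measured_age_days`).
#' @export
simulate_weights <- function(config, animals) {
  wm <- config$weight_model
  set.seed(.site_seed(config$seed, 997L))
  out <- vector("list", length(.WEIGHT_AGES))
  for (k in seq_along(.WEIGHT_AGES)) {
    mo <- .WEIGHT_AGES[k]
    a_days <- mo * DAYS_PER_MONTH
    alive <- animals$observed_age > a_days
    if (!any(alive)) next
    an <- animals[alive, , drop = FALSE]
    mu <- ifelse(an$sex == "M", wm$mu_asymptote_m_g, wm$mu_asymptote_f_g)
    coup <- ifelse(an$sex == "M", wm$frailty_weight_coupling_m,
                   wm$frailty_weight_coupling_f)
    A <- mu + coup * an$frailty
    w <- A * (1 - exp(-wm$growth_rate_k * a_days)) -
      wm$terminal_loss_fraction * A *
        pmax(0, 1 - (an$death_age - a_days) / wm$terminal_window_days) +
      stats::rnorm(nrow(an), sd = wm$measurement_noise_sd_g)
    out[[k]] <- data.frame(
      mouse_id = an$mouse_id, age_months = mo,
      weight_g = pmax(w, 1), measured_age_days = a_days,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Read or write a simulation configuration as YAML
#' @param config A `sim_config`.
#' @param path YAML file path.
#' @return `path` invisibly for write; a `sim_config` for read.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$sites <- as.list(cfg$sites)
  cfg$frailty_hazard_coupling <- as.list(cfg$frailty_hazard_coupling)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$sites <- unlist(cfg$sites)
  cfg$frailty_hazard_coupling <- unlist(cfg$frailty_hazard_coupling)
  cfg <- cfg[names(cfg) %in% names(formals(sim_config))]
  do.call(sim_config, cfg)
}
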