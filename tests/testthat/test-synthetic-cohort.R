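test_that("true_hazard has the configured bump structure", {
  cfg <- sim_config(hr_peak_age_days = 350, hr_peak_ratio = 2.2,
                    hr_convergence_age_days = 800)
  # ratio is exactly peak_ratio at the peak and exactly 1 from convergence on
  expect_equal(true_hr(cfg, 350), 2.2)
  expect_equal(true_hr(cfg, c(800, 900, 1200)), c(1, 1, 1))
  # bump vanishes when peak_ratio = 1: male/female ratio is the site multiplier
  cfg1 <- sim_config(hr_peak_ratio = 1, sites = c(TJL = 1.3, UM = 1, UT = 1))
  ages <- seq(30, 1000, by = 10)
  expect_equal(true_hazard(cfg1, "M", "TJL", ages) /
                 true_hazard(cfg1, "F", "TJL", ages),
               rep(1.3, length(ages)))
  # female hazard is Gompertz
  expect_equal(true_hazard(cfg, "F", "TJL", 500),
               cfg$gompertz_a * exp(cfg$gompertz_b * 500))
  expect_error(true_hazard(cfg, "F", "TJL", 5), "weaning")
})

test_that("true HR curve is unimodal with its maximum at the peak age", {
  cfg <- sim_config()
  grid <- seq(21, 1100, by = 1)
  hr <- true_hr(cfg, grid)
  expect_equal(grid[which.max(hr)], cfg$hr_peak_age_days)
  d <- diff(hr)
  up <- grid[-1] <= cfg$hr_peak_age_days
  expect_true(all(d[up] >= 0))
  expect_true(all(d[!up] <= 1e-12))
})

test_that("simulation is seed-deterministic and respects censoring switches", {
  cfg <- sim_config(n_per_sex_per_site = 50, seed = 9)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(s1$cohort), as.data.frame(s2$cohort))
  expect_identical(s1$weights, s2$weights)
  # no censoring mechanisms -> all died
  cfg0 <- sim_config(n_per_sex_per_site = 40, cage_censor_prob_m = 0, seed = 2)
  s0 <- simulate_cohort(cfg0)
  expect_true(all(s0$cohort$status == "died"))
  # all animals enter at weaning or later
  expect_true(all(s0$cohort$age_days >= cfg0$weaning_age_days))
  # administrative censoring truncates
  cfga <- sim_config(n_per_sex_per_site = 40, cage_censor_prob_m = 0,
                     admin_censor_age_days = 600, seed = 2)
  sa <- simulate_cohort(cfga)
  expect_true(all(sa$cohort$age_days <= 600))
  expect_true(any(sa$cohort$status == "censored"))
})

test_that("cage censoring censors whole male cages before their first death", {
  cfg <- sim_config(n_per_sex_per_site = 300, cage_censor_prob_m = 0.5,
                    seed = 4)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  cen <- co[co$status == "censored", ]
  expect_gt(nrow(cen), 0)
  expect_true(all(cen$sex == "M"))
  truth <- sim$truth$animals
  for (cg in unique(cen$cage_id)) {
    rows <- co[!is.na(co$cage_id) & co$cage_id == cg, ]
    # all members share one censoring age below the cage's earliest death
    expect_true(all(rows$status == "censored"))
    expect_equal(length(unique(rows$age_days)), 1)
    first_death <- min(truth$true_death_age[match(rows$mouse_id,
                                                  truth$mouse_id)])
    expect_lt(rows$age_days[1], first_death)
  }
})

test_that("female simulated median matches the closed-form Gompertz median", {
  cfg <- sim_config(n_per_sex_per_site = 1667, cage_censor_prob_m = 0,
                    frailty_hazard_coupling = c(F = 0, M = 0), seed = 31)
  co <- simulate_cohort(cfg)$cohort
  t_half <- log(log(2) * cfg$gompertz_b / cfg$gompertz_a +
                  exp(cfg$gompertz_b * cfg$weaning_age_days)) / cfg$gompertz_b
  emp <- median(co$age_days[co$sex == "F"])
  expect_lt(abs(emp - t_half), 15)
})

test_that("paper-like preset reproduces the calibrated survival structure", {
  cfg <- paper_like_config(n_per_sex_per_site = 1667, seed = 13)
  co <- simulate_cohort(cfg)$cohort
  med_f <- median(co$age_days[co$sex == "F"])
  med_m <- median(co$age_days[co$sex == "M"])
  expect_gt(med_f, 850)
  expect_lt(med_f, 925)
  expect_lt(med_m, med_f)
  # empirical survival is non-increasing per stratum (monotone survival)
  for (s in c("F", "M")) {
    ages <- sort(co$age_days[co$sex == s])
    surv <- 1 - seq_along(ages) / length(ages)
    expect_true(all(diff(surv) <= 0))
  }
})

test_that("null preset shows no sex difference beyond sampling noise", {
  rejections <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(null_config(n_per_sex_per_site = 667,
                                      seed = 100 + s))$cohort
    lr <- logrank(co$age_days[co$sex == "F"], co$status[co$sex == "F"],
                  co$age_days[co$sex == "M"], co$status[co$sex == "M"])
    rejections <- rejections + (lr$p < 0.05)
  }
  # log-rank at alpha=0.05 should reject in roughly 5% of null cohorts
  expect_lte(rejections, 0.10 * n_seeds + 1)
})

test_that("simulated weights implement the growth/terminal-loss model", {
  # degenerate: no noise, no coupling, no loss -> one curve per sex
  cfg <- sim_config(n_per_sex_per_site = 30, cage_censor_prob_m = 0, seed = 5,
                    weight_model = list(
                      mu_asymptote_f_g = 32, mu_asymptote_m_g = 42,
                      growth_rate_k = 0.012,
                      frailty_weight_coupling_f = 0, frailty_weight_coupling_m = 0,
                      terminal_loss_fraction = 0, terminal_window_days = 60,
                      measurement_noise_sd_g = 0))
  sim <- simulate_cohort(cfg)
  w <- sim$weights
  co <- as.data.frame(sim$cohort)
  w$sex <- co$sex[match(w$mouse_id, co$mouse_id)]
  for (s in c("F", "M")) for (a in unique(w$age_months)) {
    vals <- w$weight_g[w$sex == s & w$age_months == a]
    if (length(vals) > 1) expect_lt(diff(range(vals)), 1e-9)
  }
  # exact curve value
  mu <- 42 * (1 - exp(-0.012 * 6 * 30.44))
  expect_equal(unique(w$weight_g[w$sex == "M" & w$age_months == 6]), mu,
               tolerance = 1e-12)
  # weights only for animals alive at measurement
  expect_true(all(co$age_days[match(w$mouse_id, co$mouse_id)] >
                    w$measured_age_days))
})

test_that("weight-lifespan slopes show the negative-then-positive reversal", {
  # large single cohort so the signs reflect the generator's design, not one
  # seed's sampling noise; per-seed slope variance is dominated by a few
  # high-leverage early deaths, so only the sign pattern is asserted
  cfg <- paper_like_config(n_per_sex_per_site = 2000, seed = 17)
  sim <- simulate_cohort(cfg)
  j <- join_weights(sim$cohort, sim$weights)
  t6 <- weight_regression(j, 6)
  expect_lt(t6$coefficient[t6$stratum == "M"], 0)
  expect_lt(t6$coefficient[t6$stratum == "F"], 0)
  t24 <- weight_regression(j, 24)
  expect_gt(t24$coefficient[t24$stratum == "M"], 0)
  expect_gt(t24$coefficient[t24$stratum == "F"], 0)
  # pooled tables reproduce the study-shaped pattern at 6 vs 24 months
  tp <- weight_regression_tables(j)$pooled
  expect_lt(tp$coefficient[tp$age_months == 6], 0)
  expect_gt(tp$coefficient[tp$age_months == 24], 0)
})

test_that("sim_config round-trips through YAML", {
  cfg <- paper_like_config(n_per_sex_per_site = 10, seed = 3)
  p <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2$gompertz_a, cfg$gompertz_a)
  expect_equal(cfg2$sites, cfg$sites)
  c1 <- simulate_cohort(cfg)$cohort
  c2 <- simulate_cohort(cfg2)$cohort
  expect_identical(c1$mouse_id, c2$mouse_id)
  # YAML serializes doubles at 15 significant digits; ages agree to that
  expect_equal(c1$age_days, c2$age_days, tolerance = 1e-9)
})
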