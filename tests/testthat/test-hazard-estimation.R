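test_that("bin_exposure computes overlap person-time and half-open bins", {
  # one animal, entry 0, death at 75, bins [0,50),[50,100]
  co <- cohort_table(data.frame(
    mouse_id = "a", sex = "F", site = "TJL", cohort = 2004L,
    age_days = 75, status = "died", cage_id = NA, stringsAsFactors = FALSE),
    weaning_age_days = 0)
  ex <- bin_exposure(co, bin_edges = c(0, 50, 100), entry_age = 0)
  expect_equal(ex$R, c(50, 25))
  expect_equal(ex$d, c(0, 1))

  # censoring exactly at an edge: person-time all in the lower bin
  co2 <- cohort_table(data.frame(
    mouse_id = "a", sex = "F", site = "TJL", cohort = 2004L,
    age_days = 50, status = "censored", cage_id = NA,
    stringsAsFactors = FALSE), weaning_age_days = 0)
  ex2 <- bin_exposure(co2, bin_edges = c(0, 50, 100), entry_age = 0)
  expect_equal(ex2$R, c(50, 0))
  expect_equal(ex2$d, c(0, 0))

  # a death at the top edge lands in the last (closed) bin
  co3 <- cohort_table(data.frame(
    mouse_id = "a", sex = "F", site = "TJL", cohort = 2004L,
    age_days = 100, status = "died", cage_id = NA, stringsAsFactors = FALSE),
    weaning_age_days = 0)
  ex3 <- bin_exposure(co3, bin_edges = c(0, 50, 100), entry_age = 0)
  expect_equal(ex3$d, c(0, 1))

  expect_error(bin_exposure(co, bin_width_days = -1), "positive")
})

test_that("bin_exposure sums match direct summation on random cohorts", {
  set.seed(8)
  n <- 200
  co <- cohort_table(data.frame(
    mouse_id = sprintf("r%03d", 1:n), sex = "F", site = "TJL", cohort = 2004L,
    age_days = 21 + rexp(n, 1 / 600),
    status = sample(c("died", "censored"), n, TRUE, prob = c(0.9, 0.1)),
    cage_id = NA, stringsAsFactors = FALSE), weaning_age_days = 21)
  ex <- bin_exposure(co, bin_width_days = 30)
  expect_equal(sum(ex$R), sum(co$age_days - 21), tolerance = 1e-9)
  expect_equal(sum(ex$d), sum(co$status == "died"))
  expect_true(all(ex$d[ex$R == 0] == 0))
})

test_that("bspline_basis is a partition of unity matching Cox-de Boor", {
  grid <- seq(0, 100, by = 0.5)
  B <- bspline_basis(grid, n_knots = 7, degree = 3)
  expect_equal(rowSums(B), rep(1, length(grid)), tolerance = 1e-12)
  expect_true(all(B >= 0))

  # against the textbook recursion at interior points
  knots <- attr(B, "knots")
  pts <- c(12.5, 33, 47.5, 61, 88)
  Bo <- sapply(seq_len(ncol(B)), function(i)
    sapply(pts, function(x) cox_de_boor(knots, x, 3, i)))
  Bi <- bspline_basis(pts, n_knots = 7, degree = 3, range = c(0, 100))
  expect_equal(unclass(Bi), Bo, tolerance = 1e-12, ignore_attr = TRUE)

  # degree 0 with knots at the bin edge gives indicators
  B0 <- bspline_basis(c(10, 60), n_knots = 1, degree = 0, range = c(0, 100))
  expect_equal(unclass(B0), matrix(c(1, 0, 0, 1), 2), ignore_attr = TRUE)

  expect_error(bspline_basis(c(-5, 50), n_knots = 3, degree = 3,
                             range = c(0, 100)), "outside")
})

test_that("saturated limit: lambda 0, degree 0, one basis per bin gives d/R", {
  set.seed(3)
  ages <- rexp(2000, 1 / 800)
  ages <- ages[ages <= 1000][1:400]   # keep bins contiguous and occupied
  co <- cohort_table(data.frame(
    mouse_id = sprintf("s%03d", 1:400), sex = "F", site = "TJL",
    cohort = 2004L, age_days = ages, status = "died", cage_id = NA,
    stringsAsFactors = FALSE), weaning_age_days = 0)
  ex <- bin_exposure(co, bin_edges = seq(0, 1000, 200), entry_age = 0)
  expect_true(all(ex$d > 0))
  fit <- fit_smoothed_hazard(ex, lambda = 0, n_knots = 4, degree = 0,
                             penalty_order = 1, grid_step = 100)
  got <- eval_hazard(fit, ex$mid)
  expect_equal(got, ex$d / ex$R, tolerance = 1e-6)
})

test_that("single bin with lambda 0 returns the occurrence/exposure rate", {
  ex <- data.frame(bin_lo = 0, bin_hi = 100, mid = 50, d = 3, R = 1000)
  ex <- structure(ex, n_events = 3, n_animals = 3,
                  class = c("exposure_table", "data.frame"))
  fit <- fit_smoothed_hazard(ex, lambda = 0, n_knots = 0, degree = 0,
                             penalty_order = 1, grid_step = 50)
  expect_equal(eval_hazard(fit, 50), 0.003, tolerance = 1e-8)
})

test_that("constant-hazard data are recovered within 10% over mid ages", {
  co <- make_exponential_cohort(2000, 800, seed = 12)
  ex <- bin_exposure(co, bin_width_days = 30, entry_age = 0)
  fit <- suppressWarnings(fit_smoothed_hazard(ex))
  sub <- fit[fit$age_days >= 200 & fit$age_days <= 1000, ]
  expect_true(all(abs(sub$hazard - 1.25e-3) / 1.25e-3 < 0.10))
  # CI ordering and positivity
  expect_true(all(fit$ci_lo <= fit$hazard & fit$hazard <= fit$ci_hi))
  expect_true(all(fit$hazard > 0))
  edf <- attr(fit, "effective_df")
  expect_gte(edf, 2)
  expect_lte(edf, 33)   # penalty-null dimension to basis size
})

test_that("infinite-smoothing limit matches the log-linear Poisson GLM", {
  co <- make_exponential_cohort(800, 600, seed = 21)
  ex <- bin_exposure(co, bin_width_days = 60, entry_age = 0)
  keep <- ex$R > 0
  fit <- fit_smoothed_hazard(ex, lambda = 1e8, penalty_order = 2,
                             grid_step = 10)
  glm_fit <- stats::glm(d ~ mid + offset(log(R)), family = stats::poisson(),
                        data = as.data.frame(ex)[keep, ])
  eta_glm <- stats::predict(glm_fit,
                            newdata = data.frame(mid = ex$mid[keep],
                                                 R = 1))
  eta_ps <- log(eval_hazard(fit, ex$mid[keep]))
  expect_equal(eta_ps, unname(eta_glm), tolerance = 1e-3)
})

test_that("exposure-scaling invariance: scaling R by c divides the hazard by c", {
  co <- make_exponential_cohort(500, 700, seed = 33)
  ex <- bin_exposure(co, bin_width_days = 90, entry_age = 0)
  ex2 <- ex
  ex2$R <- ex2$R * 10
  f1 <- fit_smoothed_hazard(ex, lambda = 50, grid_step = 30)
  f2 <- fit_smoothed_hazard(ex2, lambda = 50, grid_step = 30)
  expect_equal(f2$hazard * 10, f1$hazard, tolerance = 1e-6)
})

test_that("the fit depends on the data only through the exposure table", {
  # two different cohorts with identical exposure tables -> identical curves
  co1 <- make_exponential_cohort(300, 500, seed = 1)
  ex <- bin_exposure(co1, bin_width_days = 100, entry_age = 0)
  ex_copy <- ex
  attr(ex_copy, "provenance") <- "other cohort"
  f1 <- fit_smoothed_hazard(ex, lambda = 10)
  f2 <- fit_smoothed_hazard(ex_copy, lambda = 10)
  expect_identical(f1$hazard, f2$hazard)
})

test_that("select_smoothing keeps constant-hazard fits near the penalty null", {
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    co <- make_exponential_cohort(2000, 800, seed = 300 + s)
    ex <- bin_exposure(co, bin_width_days = 30, entry_age = 0)
    sel <- suppressWarnings(select_smoothing(ex))
    hits <- hits + (sel$effective_df >= 2 && sel$effective_df <= 4)
  }
  expect_gte(hits, 0.8 * n_seeds)
})

test_that("select_smoothing spends more df on structured than flat hazards", {
  # bimodal hazard via a mixture of early and late deaths
  set.seed(77)
  n <- 2000
  early <- rnorm(n / 2, 300, 60)
  late <- rnorm(n / 2, 900, 60)
  ages <- pmax(25, c(early, late))
  co_bi <- cohort_table(data.frame(
    mouse_id = sprintf("b%04d", 1:n), sex = "F", site = "TJL", cohort = 2004L,
    age_days = ages, status = "died", cage_id = NA, stringsAsFactors = FALSE),
    weaning_age_days = 21)
  co_flat <- make_exponential_cohort(n, 800, seed = 77)
  sel_bi <- suppressWarnings(select_smoothing(
    bin_exposure(co_bi, 30, entry_age = 21)))
  sel_flat <- suppressWarnings(select_smoothing(
    bin_exposure(co_flat, 30, entry_age = 0)))
  expect_gt(sel_bi$effective_df, sel_flat$effective_df)
})

test_that("a user-fixed lambda bypasses selection", {
  co <- make_exponential_cohort(300, 600, seed = 5)
  ex <- bin_exposure(co, bin_width_days = 60, entry_age = 0)
  f_fixed <- fit_smoothed_hazard(ex, lambda = 123)
  expect_equal(attr(f_fixed, "lambda"), 123)
  f_again <- fit_smoothed_hazard(ex, lambda = 123)
  expect_identical(f_fixed$hazard, f_again$hazard)
})

test_that("degenerate inputs are rejected with informative errors", {
  ex <- data.frame(bin_lo = c(0, 50), bin_hi = c(50, 100), mid = c(25, 75),
                   d = c(0, 0), R = c(100, 100))
  ex <- structure(ex, n_events = 0, n_animals = 2,
                  class = c("exposure_table", "data.frame"))
  expect_error(fit_smoothed_hazard(ex, lambda = 1), "no events")
})
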