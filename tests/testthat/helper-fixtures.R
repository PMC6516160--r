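# Shared fixture builders. All data are generated in code; files are written
# to tempdir() as needed.

# minimal valid cohort data.frame
make_cohort_df <- function(n = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    mouse_id = sprintf("m%03d", seq_len(n)),
    sex = rep_len(c("F", "M"), n),
    site = rep_len(c("TJL", "UM", "UT"), n),
    cohort = rep_len(2004:2006, n),
    age_days = round(stats::runif(n, 400, 1100), 1),
    status = rep_len(c("died", "died", "censored"), n),
    cage_id = rep_len(c("c1", "c2"), n),
    stringsAsFactors = FALSE
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# exponential-lifespan cohort (constant hazard 1/mean), no censoring
make_exponential_cohort <- function(n, mean_days, seed = 1, entry = 0) {
  set.seed(seed)
  cohort_table(data.frame(
    mouse_id = sprintf("e%05d", seq_len(n)),
    sex = rep_len(c("F", "M"), n),
    site = "TJL",
    cohort = 2004L,
    age_days = entry + stats::rexp(n, 1 / mean_days),
    status = "died",
    cage_id = NA_character_,
    stringsAsFactors = FALSE
  ), weaning_age_days = entry)
}

# independent Cox-de Boor recursive B-spline evaluation (oracle)
cox_de_boor <- function(knots, x, degree, i) {
  if (degree == 0)
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  w1 <- if (knots[i + degree] > knots[i])
    (x - knots[i]) / (knots[i + degree] - knots[i]) else 0
  w2 <- if (knots[i + degree + 1] > knots[i + 1])
    (knots[i + degree + 1] - x) / (knots[i + degree + 1] - knots[i + 1]) else 0
  w1 * cox_de_boor(knots, x, degree - 1, i) +
    w2 * cox_de_boor(knots, x, degree - 1, i + 1)
}

# brute-force KM by risk-set enumeration (oracle)
km_oracle <- function(ages, event) {
  times <- sort(unique(ages[event == 1]))
  s <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (k in seq_along(times)) {
    t <- times[k]
    n_risk <- sum(ages >= t)
    d <- sum(ages == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}

# log-rank by per-event-time hypergeometric tables (oracle)
logrank_oracle <- function(ages_a, ev_a, ages_b, ev_b) {
  ages <- c(ages_a, ages_b); ev <- c(ev_a, ev_b)
  grp <- c(rep(0, length(ages_a)), rep(1, length(ages_b)))
  times <- sort(unique(ages[ev == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- ages >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(ages == t & ev == 1)
    d1 <- sum(ages == t & ev == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# two-sided Fisher p by full hypergeometric enumeration (oracle)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
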