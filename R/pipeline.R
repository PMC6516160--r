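# End-to-end orchestration: simulate or ingest a cohort, then run hazard
# smoothing, the bootstrapped HR band, the survival comparisons, the Cox
# model, and the weight regressions, writing all tables plus a manifest.

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; each writes its tables under `out_dir`
#' and contributes to a structured summary (`summary.json`) and a run
#' manifest (`manifest.json`: config hash, seed, file checksums).
#' Re-running with an identical config reproduces identical outputs.
#'
#' @param config A list (or YAML path readable by [read_run_config()]) with
#'   elements: `sim` (a [sim_config()]; used unless `cohort_csv` /
#'   `weights_csv` are given), `stages` (character subset of "simulate",
#'   "hazard", "hr", "survtest", "cox", "weightreg"), `bootstrap_B`,
#'   `seed`, `grid_step`, `bin_width_days`, and `out_dir`.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% "murihaz_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c("simulate", "hazard", "hr", "survtest", "cox", "weightreg")
  seed <- as.integer(config$seed %||% 1L)
  bw <- config$bin_width_days %||% 30
  gs <- config$grid_step %||% 5
  B <- config$bootstrap_B %||% 200

  summary <- list(seed = seed, stages = stages)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  # --- input: simulate or ingest -------------------------------------------
  if ("simulate" %in% stages || is.null(config$cohort_csv)) {
    simc <- config$sim %||% paper_like_config(seed = seed)
    sim <- simulate_cohort(simc)
    cohort <- sim$cohort
    weights <- sim$weights
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_weights(weights, file.path(out_dir, "weights.csv"))
    put(sim$truth$animals, "truth.csv")
    put(sim$truth$hazard_grid, "truth_hazard.csv")
    files <- c(files, file.path(out_dir, c("cohort.csv", "weights.csv")))
    summary$n_animals <- nrow(cohort)
  } else {
    cohort <- read_cohort(config$cohort_csv)
    weights <- if (!is.null(config$weights_csv))
      read_weights(config$weights_csv) else NULL
    summary$n_animals <- nrow(cohort)
  }

  # --- smoothed hazards per sex --------------------------------------------
  if ("hazard" %in% stages) {
    haz <- lapply(c(F = "F", M = "M"), function(s) {
      sub <- cohort[cohort$sex == s, , drop = FALSE]
      fit_smoothed_hazard(bin_exposure(sub, bin_width_days = bw),
                          grid_step = gs)
    })
    tab <- do.call(rbind, lapply(names(haz), function(s)
      cbind(as.data.frame(haz[[s]]), group = s)))
    put(tab, "hazard.csv")
    summary$hazard <- lapply(haz, function(h)
      list(lambda = attr(h, "lambda"), effective_df = attr(h, "effective_df"),
           n_events = attr(h, "n_events")))
  }

  # --- HR curve with bootstrap band ----------------------------------------
  if ("hr" %in% stages) {
    hrb <- bootstrap_hr(cohort, B = B, seed = seed,
                        bin_width_days = bw, grid_step = gs)
    put(as.data.frame(hrb), "hr.csv")
    summary$hr <- hr_summary(hrb)
  }

  # --- classical survival comparisons --------------------------------------
  if ("survtest" %in% stages) {
    ss <- survival_summary(cohort)
    summary$survival <- list(
      median_f = ss$median$F, median_m = ss$median$M,
      logrank_p = ss$logrank$p,
      max_lifespan = list(
        threshold_age_days = ss$max_lifespan$threshold_age_days,
        fisher_p = ss$max_lifespan$fisher_p,
        proportion_f = ss$max_lifespan$proportions$F$proportion,
        proportion_m = ss$max_lifespan$proportions$M$proportion)
    )
  }

  # --- Cox sex x site -------------------------------------------------------
  if ("cox" %in% stages) {
    cx <- cox_fit(cohort)
    put(cx$terms, "cox_terms.csv")
    summary$cox <- list(lrt_statistic = cx$lrt_statistic,
                        lrt_p = cx$lrt_p,
                        terms = stats::setNames(as.list(cx$terms$hazard_ratio),
                                                cx$terms$name))
  }

  # --- weight regressions ---------------------------------------------------
  if ("weightreg" %in% stages && !is.null(weights)) {
    joined <- join_weights(cohort, weights)
    write_exclusion_report(joined, file.path(out_dir, "exclusions.csv"))
    files <- c(files, file.path(out_dir, "exclusions.csv"))
    tabs <- weight_regression_tables(joined)
    put(tabs$pooled, "weightreg_pooled.csv")
    put(tabs$by_sex, "weightreg_by_sex.csv")
    inter <- interaction_regression(joined, 6, moderator = "sex")
    summary$weightreg <- list(
      pooled = tabs$pooled, by_sex = tabs$by_sex,
      sex_weight_interaction_p_6mo = inter$interaction_p
    )
  }

  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  files <- c(files, sj)
  manifest <- list(
    package_version = as.character(utils::packageVersion("murihaz")),
    seed = seed,
    config_hash = .config_hash(config),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
             collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Read a pipeline run configuration from YAML
#' @param path YAML file with the fields of [run_pipeline()]'s config.
#' @return Config list (with `sim` promoted to a `sim_config` if present).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    if (!is.null(sim$sites)) sim$sites <- unlist(sim$sites)
    if (!is.null(sim$frailty_hazard_coupling))
      sim$frailty_hazard_coupling <- unlist(sim$frailty_hazard_coupling)
    sim <- sim[names(sim) %in% names(formals(sim_config))]
    cfg$sim <- do.call(sim_config, sim)
  }
  cfg
}
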