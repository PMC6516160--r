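# Closed vocabularies for the cohort schema
.SEXES  <- c("F", "M")
.SITES  <- c("TJL", "UM", "UT")
.STATUS <- c("died", "censored")
.WEIGHT_AGES <- c(6, 12, 18, 24)

# Nominal length of a month in days, used when a weight record carries no
# measured_age_days (average Gregorian month).
DAYS_PER_MONTH <- 30.44

#' Read a cohort table of per-animal survival records
#'
#' Parses a headered CSV with one row per animal and validates it against the
#' cohort schema: `mouse_id`, `sex` (F/M), `site` (TJL/UM/UT), `cohort`
#' (year), `age_days` (age at death or censoring), `status` (died/censored),
#' and optionally `cage_id`. Animals are observed from weaning, so every
#' age must be positive and at least the weaning age for hazard analyses.
#'
#' @param path Path to a CSV file with a header row.
#' @param weaning_age_days Age at study entry in days (default 21).
#' @return A `cohort_table`: a data.frame of validated records with
#'   attributes `provenance` and `weaning_age_days`.
#' @export
read_cohort <- function(path, weaning_age_days = 21) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("mouse_id", "sex", "site", "cohort", "age_days", "status")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("cohort schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"cage_id" %in% names(raw)) raw$cage_id <- NA_character_

  age <- suppressWarnings(as.numeric(raw$age_days))
  bad_age <- which(is.na(age) | age <= 0)
  if (length(bad_age) > 0)
    stop("cohort row error: unparseable or non-positive age_days at data line(s) ",
         paste(bad_age, collapse = ", "))
  yr <- suppressWarnings(as.integer(raw$cohort))
  bad_yr <- which(is.na(yr))
  if (length(bad_yr) > 0)
    stop("cohort row error: unparseable cohort year at data line(s) ",
         paste(bad_yr, collapse = ", "))
  bad_sex <- which(!raw$sex %in% .SEXES)
  if (length(bad_sex) > 0)
    stop("cohort row error: sex outside {F, M} at data line(s) ",
         paste(bad_sex, collapse = ", "))
  bad_site <- which(!raw$site %in% .SITES)
  if (length(bad_site) > 0)
    stop("cohort row error: site outside {TJL, UM, UT} at data line(s) ",
         paste(bad_site, collapse = ", "))
  bad_status <- which(!raw$status %in% .STATUS)
  if (length(bad_status) > 0)
    stop("cohort row error: status outside {died, censored} at data line(s) ",
         paste(bad_status, collapse = ", "))
  dup <- unique(raw$mouse_id[duplicated(raw$mouse_id)])
  if (length(dup) > 0)
    stop("cohort validation error: duplicate mouse_id: ",
         paste(dup, collapse = ", "))

  out <- data.frame(
    mouse_id = raw$mouse_id,
    sex      = factor(raw$sex, levels = .SEXES),
    site     = factor(raw$site, levels = .SITES),
    cohort   = yr,
    age_days = age,
    status   = factor(raw$status, levels = .STATUS),
    cage_id  = raw$cage_id,
    stringsAsFactors = FALSE
  )
  cohort_table(out, provenance = path,
               weaning_age_days = weaning_age_days)
}

#' Construct a cohort table from a data.frame
#'
#' @param records data.frame with the cohort schema columns.
#' @param provenance Free-text label recording where the records came from.
#' @param weaning_age_days Study entry age in days.
#' @return A `cohort_table` object.
#' @export
cohort_table <- function(records, provenance = "in-memory",
                         weaning_age_days = 21) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!is.factor(records$sex))
    records$sex <- factor(records$sex, levels = .SEXES)
  if (!is.factor(records$site))
    records$site <- factor(records$site, levels = .SITES)
  if (!is.factor(records$status))
    records$status <- factor(records$status, levels = .STATUS)
  structure(records,
            provenance = provenance,
            weaning_age_days = weaning_age_days,
            class = c("cohort_table", "data.frame"))
}

#' Write a cohort table back to CSV
#'
#' Inverse of [read_cohort()]: all parsed field values round-trip exactly.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df <- df[, c("mouse_id", "sex", "site", "cohort", "age_days",
               "status", "cage_id")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-animal bodyweight measurements
#'
#' Expects a headered CSV with columns `mouse_id`, `age_months` (one of
#' 6/12/18/24, the scheduled measurement ages), `weight_g`, and optionally
#' `measured_age_days` (exact age at measurement).
#'
#' @param path Path to a CSV file.
#' @return data.frame of weight records.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mouse_id", "age_months", "weight_g")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("weights schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"measured_age_days" %in% names(raw))
    raw$measured_age_days <- NA_real_
  bad <- which(!raw$age_months %in% .WEIGHT_AGES)
  if (length(bad) > 0)
    stop("weights row error: age_months outside {6, 12, 18, 24} at data line(s) ",
         paste(bad, collapse = ", "))
  bad_w <- which(is.na(raw$weight_g) | raw$weight_g <= 0)
  if (length(bad_w) > 0)
    stop("weights row error: non-positive weight_g at data line(s) ",
         paste(bad_w, collapse = ", "))
  raw
}

#' Write weight records to CSV
#' @param weights data.frame of weight records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  df <- weights[, c("mouse_id", "age_months", "weight_g",
                    "measured_age_days")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Join bodyweights to survival records with study exclusion rules
#'
#' Applies the bodyweight-analysis filters: weights of censored animals are
#' dropped (their lifespans are incomplete), weights recorded after the
#' animal's death are flagged as erroneous and dropped, and weights whose
#' `mouse_id` does not resolve against the cohort are dropped with a warning.
#' When `measured_age_days` is missing, the nominal age of the scheduled
#' measurement (`age_months * 30.44`) is used for the post-mortem check.
#'
#' @param cohort A `cohort_table`.
#' @param weights data.frame of weight records.
#' @return A data.frame with one row per retained weight measurement,
#'   carrying the animal's `sex`, `site`, `cohort` and lifespan
#'   (`lifespan_days`), plus an `exclusions` attribute: a keyed table of
#'   counts per rule and sex.
#' @export
join_weights <- function(cohort, weights) {
  co <- as.data.frame(cohort)
  idx <- match(weights$mouse_id, co$mouse_id)
  orphan <- is.na(idx)
  if (any(orphan))
    warning(sum(orphan), " weight record(s) reference unknown mouse_id; excluded")

  sex      <- co$sex[idx]
  status   <- co$status[idx]
  age_days <- co$age_days[idx]
  meas_age <- weights$measured_age_days
  nominal  <- weights$age_months * DAYS_PER_MONTH
  meas_age[is.na(meas_age)] <- nominal[is.na(meas_age)]

  censored    <- !orphan & status == "censored"
  post_mortem <- !orphan & !censored & meas_age > age_days
  keep <- !orphan & !censored & !post_mortem

  excl <- rbind(
    data.frame(rule = "censored", sex = .SEXES,
               count = vapply(.SEXES, function(s)
                 sum(censored & sex == s, na.rm = TRUE), integer(1))),
    data.frame(rule = "post_mortem", sex = .SEXES,
               count = vapply(.SEXES, function(s)
                 sum(post_mortem & sex == s, na.rm = TRUE), integer(1))),
    data.frame(rule = "orphan", sex = "unknown", count = sum(orphan))
  )
  rownames(excl) <- NULL

  out <- data.frame(
    mouse_id          = weights$mouse_id[keep],
    age_months        = weights$age_months[keep],
    weight_g          = weights$weight_g[keep],
    measured_age_days = meas_age[keep],
    sex               = sex[keep],
    site              = co$site[idx][keep],
    cohort            = co$cohort[idx][keep],
    lifespan_days     = age_days[keep],
    stringsAsFactors  = FALSE
  )
  attr(out, "exclusions") <- excl
  out
}

#' Remove unusually heavy animals from a joined weight table
#'
#' Sensitivity filter: drops rows with `weight_g` above a threshold and
#' reports how many were removed. Idempotent for a fixed threshold.
#'
#' @param joined Output of [join_weights()].
#' @param threshold_g Positive weight cutoff in grams.
#' @return The filtered table with attribute `n_excluded`.
#' @export
heavy_animal_filter <- function(joined, threshold_g) {
  stopifnot(is.numeric(threshold_g), threshold_g > 0)
  drop <- joined$weight_g > threshold_g
  out <- joined[!drop, , drop = FALSE]
  for (s in .SEXES) {
    if (any(joined$sex == s, na.rm = TRUE) &&
        !any(out$sex == s, na.rm = TRUE))
      warning("heavy-animal filter removed every row of sex ", s,
              " (degenerate stratum)")
  }
  attr(out, "exclusions") <- attr(joined, "exclusions")
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Write an exclusion report as a keyed text table
#' @param joined Output of [join_weights()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(joined, path) {
  excl <- attr(joined, "exclusions")
  utils::write.csv(excl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
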