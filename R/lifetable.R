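# Cohort life tables under the combined hazard, and the summary
# estimators: fraction of radiation-induced deaths (REID), life
# expectancy, reductions of life expectancy, survival after diagnosis.

#' Build a cohort life table
#'
#' Follows a cohort from the age at diagnosis to `max_age` in steps of
#' `step_years`.  Within each interval the hazard is held constant at its
#' midpoint value, so the
#' death probability is `q = 1 - exp(-mu * step)`; deaths are attributed
#' to background, radiation and disease proportionally to the hazard
#' components (the standard competing-risks partition).  Life expectancy
#' uses the half-interval (trapezoid) convention, with survivors at
#' `max_age` treated as dying there.
#'
#' The radiation and disease hazards can each be switched off to obtain
#' the counterfactual tables needed for reductions of life expectancy.
#'
#' @param patient A [patient_profile()].
#' @param history An `exposure_history` for the patient (ignored when
#'   `include_radiation = FALSE`).
#' @param background All-cause `rate_table`.
#' @param cancer_rates Site-labelled baseline cancer mortality
#'   `rate_table`.
#' @param disease_hazard A `disease_hazard` or `NULL`.
#' @param params,config Passed to [excess_mortality_rate()].
#' @param include_radiation,include_disease Switch hazard components.
#' @param max_age Closing age of the table (years).
#' @param step_years Interval length; 1 (annual, default) or finer.
#' @return A list of class `"life_table_result"`: `table` (per-interval
#'   ages, hazards, survival `l`, death probability `q`, deaths `d` and
#'   cause-attributed deaths), `summary` (list with `reid`,
#'   `life_expectancy_years`, `survivor_at_max_age`), and the inputs'
#'   descriptors.
#' @export
build_life_table <- function(patient, history, background, cancer_rates,
                             disease_hazard = NULL,
                             params = err_parameters(),
                             config = risk_config(),
                             include_radiation = TRUE,
                             include_disease = !is.null(disease_hazard),
                             max_age = 110, step_years = 1) {
  stopifnot(inherits(patient, "patient_profile"))
  if (step_years <= 0) stop("step_years must be > 0")
  a0 <- patient$age_at_diagnosis
  if (a0 >= max_age) stop("age at diagnosis must be below max_age")
  if (max(background$age) < max_age - 1) {
    stop("background table does not cover ages up to ", max_age)
  }
  ages <- seq(a0, max_age - step_years / 2, by = step_years)
  # hazards are taken as constant over each interval at their midpoint
  # value, which keeps annual and finer-step tables in close agreement
  mid <- ages + step_years / 2
  mu_bg <- rate_at(background, mid, patient$sex)
  mu_rad <- if (include_radiation && !is.null(history)) {
    excess_mortality_rate(mid, patient$sex, history, cancer_rates,
                          params = params, config = config)
  } else {
    numeric(length(ages))
  }
  mu_dis <- if (include_disease && !is.null(disease_hazard)) {
    disease_hazard_rate(disease_hazard, mid - a0)
  } else {
    numeric(length(ages))
  }
  mu <- mu_bg + mu_rad + mu_dis
  q <- 1 - exp(-mu * step_years)
  l <- cumprod(c(1, 1 - q))
  l_end <- l[length(l)]
  l <- l[-length(l)]
  d <- l * q
  frac <- function(cmp) ifelse(mu > 0, cmp / mu, 0)
  tab <- data.frame(age = ages, mu_background = mu_bg, mu_radiation = mu_rad,
                    mu_disease = mu_dis, mu_total = mu, l = l, q = q, d = d,
                    d_background = d * frac(mu_bg),
                    d_radiation = d * frac(mu_rad),
                    d_disease = d * frac(mu_dis))
  # person-years by the half-interval convention; tail dies at max_age
  le <- sum(l * (1 - q / 2)) * step_years
  res <- list(table = tab,
              summary = list(reid = sum(tab$d_radiation),
                             life_expectancy_years = le,
                             survivor_at_max_age = l_end),
              patient = patient, step_years = step_years, max_age = max_age,
              include_radiation = include_radiation,
              include_disease = include_disease)
  class(res) <- "life_table_result"
  total <- sum(tab$d_background) + sum(tab$d_radiation) +
    sum(tab$d_disease) + l_end
  if (abs(total - 1) > 1e-9) {
    stop("life table does not conserve the cohort (total = ", total, ")")
  }
  res
}

#' Fraction of radiation-induced deaths (REID)
#'
#' The probability that a cohort member eventually dies of a
#' radiation-induced cancer: the sum over ages of deaths attributed to the
#' radiation hazard component.
#'
#' @param result A `life_table_result`.
#' @return Fraction in `[0, 1]`.
#' @export
reid <- function(result) {
  stopifnot(inherits(result, "life_table_result"))
  result$summary$reid
}

#' Life expectancy at diagnosis
#'
#' @param result A `life_table_result`.
#' @return Expected years of life remaining at the age of diagnosis,
#'   conditional on being alive at diagnosis.
#' @export
life_expectancy <- function(result) {
  stopifnot(inherits(result, "life_table_result"))
  result$summary$life_expectancy_years
}

#' Survival probability a given time after diagnosis
#'
#' @param result A `life_table_result`.
#' @param years Horizon in years after diagnosis; must fall on the life
#'   table's age grid.
#' @return Probability of being alive `years` after diagnosis.
#' @export
survival_after <- function(result, years) {
  stopifnot(inherits(result, "life_table_result"))
  target <- result$patient$age_at_diagnosis + years
  tab <- result$table
  if (target >= result$max_age - 1e-9) return(result$summary$survivor_at_max_age)
  i <- which(abs(tab$age - target) < 1e-9)
  if (length(i) != 1L) {
    stop("horizon ", years, " years does not fall on the life-table grid")
  }
  tab$l[i]
}

#' Reduction of life expectancy between two life tables
#'
#' @param full `life_table_result` including the hazard of interest.
#' @param counterfactual Same patient and inputs with that hazard removed.
#' @return Difference in life expectancy, counterfactual minus full, in
#'   days (365.25 days/year); nonnegative whenever the removed hazard is
#'   nonnegative.
#' @export
delta_life_expectancy <- function(full, counterfactual) {
  (life_expectancy(counterfactual) - life_expectancy(full)) * 365.25
}

#' Cohort risk summary over the standard patient categories
#'
#' Runs the full pipeline (protocol realization, ERR-based excess
#' mortality, life tables) for every age category and sex of a disease
#' cohort: ages 0, 1, 5, 10, 15 at diagnosis for paediatric HD; 55, 65, 75
#' for adult DLBCL.  For each category it reports the fraction of
#' radiation-induced deaths, life expectancy at diagnosis, radiation-,
#' disease- and total reductions of life expectancy, and survival at the
#' disease horizon (10 years for HD, 5 for DLBCL), plus unweighted means
#' over the age categories by sex.
#'
#' With `corrected = TRUE` the life table includes the disease-related
#' hazard (calibrated via [calibrate_disease_hazard()]); with
#' `corrected = FALSE` only background and radiation hazards enter and the
#' disease-related reduction is not applicable.
#'
#' @param disease `"HD"` or `"DLBCL"`.
#' @param background,cancer_rates Mortality inputs (see
#'   [make_background_table()], [make_cancer_rate_tables()],
#'   [load_rate_table()]).
#' @param dose_table An `organ_dose_table`.
#' @param params,config Risk model inputs.
#' @param corrected Include disease-related mortality?
#' @param ages Age categories at diagnosis; defaults to the standard set
#'   for the disease.
#' @param sexes Sexes to evaluate.
#' @param max_age,step_years Life-table grid.
#' @return A list of class `"cohort_summary"`: `results` (one row per
#'   category and sex) and `averages` (unweighted means over age
#'   categories, by sex).
#' @export
summarize_cohort <- function(disease, background, cancer_rates,
                             dose_table = load_dose_table(),
                             params = err_parameters(),
                             config = risk_config(),
                             corrected = TRUE, ages = NULL,
                             sexes = c("male", "female"),
                             max_age = 110, step_years = 1) {
  disease <- match.arg(disease, c("HD", "DLBCL"))
  if (is.null(ages)) {
    ages <- if (disease == "HD") c(0, 1, 5, 10, 15) else c(55, 65, 75)
  }
  spec <- disease_survival_spec(disease)
  horizon <- spec$horizon_years
  dz <- if (corrected) calibrate_disease_hazard(disease) else NULL
  protocol <- standard_protocol(disease)
  rows <- list()
  for (sex in sexes) {
    for (age in ages) {
      pt <- patient_profile(sex, age, disease)
      hist <- realize_history(protocol, pt, dose_table)
      lt <- function(rad, dis) {
        build_life_table(pt, hist, background, cancer_rates,
                         disease_hazard = dz, params = params,
                         config = config, include_radiation = rad,
                         include_disease = dis && corrected,
                         max_age = max_age, step_years = step_years)
      }
      full <- lt(TRUE, TRUE)
      norad <- lt(FALSE, TRUE)
      bg_only <- lt(FALSE, FALSE)
      dle_dis <- if (corrected) {
        nodis <- lt(TRUE, FALSE)
        delta_life_expectancy(full, nodis)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        disease = disease, age_at_diagnosis = age, sex = sex,
        corrected = corrected,
        cumulative_effective_dose_mSv = cumulative_effective_dose(hist)$mSv,
        reid = reid(full),
        life_expectancy_years = life_expectancy(full),
        dle_radiation_days = delta_life_expectancy(full, norad),
        dle_disease_days = dle_dis,
        dle_total_days = delta_life_expectancy(full, bg_only),
        horizon_years = horizon,
        survival_at_horizon = survival_after(full, horizon),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  num <- c("cumulative_effective_dose_mSv", "reid", "life_expectancy_years",
           "dle_radiation_days", "dle_disease_days", "dle_total_days",
           "survival_at_horizon")
  averages <- do.call(rbind, lapply(split(results, results$sex), function(g) {
    out <- data.frame(disease = disease, sex = g$sex[1], corrected = corrected,
                      n_categories = nrow(g), stringsAsFactors = FALSE)
    for (v in num) out[[v]] <- mean(g[[v]])
    out
  }))
  rownames(averages) <- NULL
  structure(list(results = results, averages = averages, config = config),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort risk summary (", x$results$disease[1],
      if (x$results$corrected[1]) ", corrected for disease-related mortality"
      else ", no disease-related mortality", ")\n", sep = "")
  print(x$results, digits = 4)
  cat("\nUnweighted averages over age categories:\n")
  print(x$averages, digits = 4)
  invisible(x)
}

#' Published risk-table values
#'
#' The published per-category risk results (fractions of radiation-induced
#' deaths, life expectancies, reductions of life expectancy in days and
#' survival at the disease horizon) as printed, for consistency checks and
#' side-by-side comparison with computed cohort summaries.
#'
#' @return Data frame with one row per disease, age category, sex and
#'   correction status.
#' @export
published_risk_tables <- function() {
  path <- system.file("extdata", "published_risk_tables.csv",
                      package = "lymphorad", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
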