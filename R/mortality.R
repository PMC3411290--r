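# Mortality rate tables (background all-cause and baseline cancer), the
# calibrated disease-related hazard, and the combined three-source hazard.

#' Construct and validate a mortality rate table
#'
#' A rate table holds mortality rates (per person-year) on a contiguous
#' integer age grid 0..max_age for both sexes, optionally stratified by
#' cancer site.  All loaders and generators funnel through this validator.
#'
#' @param df Data frame with columns `age`, `sex`, `rate` and optionally
#'   `site`.
#' @param strict If `TRUE` (default), gaps in the age grid are an error;
#'   if `FALSE`, gaps are forward-filled from the last available age.
#' @return The validated data frame with class `"rate_table"`.
#' @export
rate_table <- function(df, strict = TRUE) {
  need <- c("age", "sex", "rate")
  if (!all(need %in% names(df))) {
    stop("rate table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!df$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (any(!is.finite(df$rate))) stop("rates must be finite")
  if (any(df$rate < 0)) {
    i <- which(df$rate < 0)[1]
    stop("negative rate at age ", df$age[i], " (", df$sex[i], ")")
  }
  if (any(df$age != floor(df$age)) || any(df$age < 0)) {
    stop("ages must be non-negative integers")
  }
  has_site <- "site" %in% names(df)
  groups <- if (has_site) split(df, list(df$sex, df$site), drop = TRUE) else
    split(df, df$sex)
  filled <- lapply(groups, function(g) {
    g <- g[order(g$age), , drop = FALSE]
    if (anyDuplicated(g$age)) stop("duplicated ages in rate table")
    full <- seq(min(g$age), max(g$age))
    gap <- setdiff(full, g$age)
    if (length(gap)) {
      if (strict) {
        stop("rate table has gaps at age(s) ",
             paste(utils::head(gap, 5), collapse = ", "),
             if (length(gap) > 5) ", ..." else "",
             " (", g$sex[1], if (has_site) paste0(", ", g$site[1]), ")")
      }
      idx <- findInterval(full, g$age)
      g2 <- data.frame(age = full, sex = g$sex[1], rate = g$rate[idx],
                       stringsAsFactors = FALSE)
      if (has_site) g2$site <- g$site[1]
      g <- g2
    }
    g
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  if (max(out$age) < 100) {
    stop("rate table must extend to at least age 100 (max age found: ",
         max(out$age), ")")
  }
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Load a mortality rate table from CSV
#'
#' @param path CSV with columns `age`, `sex`, `rate` and optionally
#'   `site` (for baseline cancer mortality by site).
#' @inheritParams rate_table
#' @return A validated `rate_table`.
#' @export
load_rate_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("rate table file not found: ", path)
  rate_table(utils::read.csv(path, stringsAsFactors = FALSE), strict = strict)
}

#' Look up rates at (possibly fractional) ages
#'
#' Rates are treated as piecewise constant over each year of age, so a
#' fractional age uses the rate of its completed year.
#'
#' @param table A `rate_table`.
#' @param ages Ages in years (vectorized).
#' @param sex `"male"` or `"female"`.
#' @param site Site label for site-stratified tables, `NULL` otherwise.
#' @return Numeric vector of rates per person-year.
#' @export
rate_at <- function(table, ages, sex, site = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  sub <- table[table$sex == sex, , drop = FALSE]
  if (!is.null(site)) {
    if (!"site" %in% names(sub)) stop("rate table has no site column")
    sub <- sub[sub$site == site, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no rates for site: ", site)
  }
  a <- floor(ages + 1e-9)
  if (any(a > max(sub$age)) || any(a < min(sub$age))) {
    stop("age outside rate table range [", min(sub$age), ", ",
         max(sub$age), "]")
  }
  sub$rate[match(a, sub$age)]
}

#' Built-in disease survival specifications
#'
#' Published overall survival anchoring the disease-related hazard:
#' 10-year survival of 94% for paediatric HD, 5-year survival of 58% for
#' adult DLBCL.
#'
#' @param disease `"HD"` or `"DLBCL"`.
#' @return List with `disease`, `horizon_years`, `survival_fraction`.
#' @export
disease_survival_spec <- function(disease) {
  disease <- match.arg(disease, c("HD", "DLBCL"))
  if (disease == "HD") {
    list(disease = "HD", horizon_years = 10, survival_fraction = 0.94)
  } else {
    list(disease = "DLBCL", horizon_years = 5, survival_fraction = 0.58)
  }
}

#' Calibrate the disease-related excess hazard
#'
#' Converts a disease-specific survival anchor S(T) into a constant excess
#' hazard h = -log(S(T))/T.  By default the hazard acts for the remaining
#' lifetime: the disease-specific survival exp(-h t) multiplies background
#' survival at every time since diagnosis and equals exactly S(T) at the
#' horizon.  The lifelong default is what reproduces published corrected
#' life expectancies and disease-related reductions of life expectancy for
#' these cohorts; setting `cure_after_years` (e.g. to `horizon_years`)
#' instead gives a cure model in which the excess hazard vanishes after
#' that time.
#'
#' @param disease Optional: `"HD"` or `"DLBCL"` selects the built-in
#'   anchor from [disease_survival_spec()].
#' @param horizon_years,survival_fraction Explicit anchor overriding the
#'   built-in; `survival_fraction` must be in (0, 1].
#' @param cure_after_years Time since diagnosis after which the excess
#'   hazard is zero; `Inf` (default) for a lifelong hazard.
#' @return A list of class `"disease_hazard"` with elements `rate` (per
#'   year) and `cure_after_years`.
#' @export
#' @examples
#' hz <- calibrate_disease_hazard("HD")
#' exp(-hz$rate * 10)  # recovers 0.94
calibrate_disease_hazard <- function(disease = NULL, horizon_years = NULL,
                                     survival_fraction = NULL,
                                     cure_after_years = Inf) {
  if (!is.null(disease)) {
    spec <- disease_survival_spec(disease)
    if (is.null(horizon_years)) horizon_years <- spec$horizon_years
    if (is.null(survival_fraction)) survival_fraction <- spec$survival_fraction
  }
  if (is.null(horizon_years) || is.null(survival_fraction)) {
    stop("either a disease or an explicit (horizon_years, survival_fraction) ",
         "anchor is required")
  }
  if (survival_fraction <= 0 || survival_fraction > 1) {
    stop("survival_fraction must be in (0, 1]")
  }
  if (horizon_years <= 0) stop("horizon_years must be > 0")
  if (cure_after_years < 0) stop("cure_after_years must be >= 0")
  structure(list(rate = -log(survival_fraction) / horizon_years,
                 cure_after_years = cure_after_years),
            class = "disease_hazard")
}

#' Disease hazard at times since diagnosis
#'
#' @param hazard A `disease_hazard`, or `NULL` for no disease mortality.
#' @param t_since_dx Years since diagnosis (vectorized).
#' @return Excess hazard per year: `rate` on `[0, cure_after_years]`,
#'   0 afterwards.
#' @export
disease_hazard_rate <- function(hazard, t_since_dx) {
  if (is.null(hazard)) return(numeric(length(t_since_dx)))
  stopifnot(inherits(hazard, "disease_hazard"))
  ifelse(t_since_dx >= 0 & t_since_dx < hazard$cure_after_years,
         hazard$rate, 0)
}

#' Combined three-source mortality hazard
#'
#' Total hazard at attained age `a` is the sum of background all-cause
#' mortality, radiation-induced excess mortality from the exposure
#' history, and the disease-related excess hazard at `a - age at
#' diagnosis`.  The components are returned separately so that deaths can
#' be attributed by cause.
#'
#' @param ages Attained ages (years, vectorized).
#' @param sex `"male"` or `"female"`.
#' @param age_at_diagnosis Age at diagnosis (years).
#' @param background All-cause `rate_table`.
#' @param cancer_rates Site-labelled baseline cancer mortality
#'   `rate_table`.
#' @param disease_hazard A `disease_hazard` or `NULL`.
#' @param history An `exposure_history` or `NULL`.
#' @param params,config Passed to [excess_mortality_rate()].
#' @return Data frame with columns `age`, `background`, `radiation`,
#'   `disease`, `total` (per person-year).
#' @export
combined_hazard <- function(ages, sex, age_at_diagnosis, background,
                            cancer_rates, disease_hazard = NULL,
                            history = NULL, params = err_parameters(),
                            config = risk_config()) {
  bg <- rate_at(background, ages, sex)
  rad <- excess_mortality_rate(ages, sex, history, cancer_rates,
                               params = params, config = config)
  dis <- disease_hazard_rate(disease_hazard, ages - age_at_diagnosis)
  data.frame(age = ages, background = bg, radiation = rad, disease = dis,
             total = bg + rad + dis)
}
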