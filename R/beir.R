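# Excess-relative-risk (ERR) models for radiation-induced solid-cancer and
# leukaemia mortality, and their aggregation over an exposure history into
# an age-dependent excess mortality rate.

#' ERR model fit parameters
#'
#' Loads the site-specific ERR fit parameters for cancer mortality.  For
#' each solid-cancer site the model is
#' \deqn{ERR = \beta_s \, d \, e^{\gamma e^*} (a/60)^\eta}
#' with dose \eqn{d} in Gy, age at exposure \eqn{e}, attained age \eqn{a},
#' and \eqn{e^* = \min((e-30)/10, 0)}.  For leukaemia the model is
#' linear-quadratic in dose,
#' \deqn{ERR = \beta_s d (1 + \theta d)
#'   \exp[\gamma e^* + \delta \log((a-e)/25) + \phi e^* \log((a-e)/25)].}
#' Sex-specific sites carry `NA` for the non-applicable sex.  The bundled
#' table transcribes the BEIR VII committee's preferred ERR fits;
#' `dose_organ` maps each risk site to the organ dose row that drives it
#' (bone marrow for leukaemia).
#'
#' The thyroid row carries incidence-model parameters (no attained-age
#' term), applied here to baseline thyroid cancer mortality as an
#' approximation since no thyroid mortality ERR fit is published; see
#' [risk_config()] for alternatives.
#'
#' @param path Optional CSV overriding the bundled parameter table; must
#'   have the same columns.
#' @return Data frame with columns `site`, `dose_organ`, `beta_male`,
#'   `beta_female`, `gamma`, `eta`, `theta`, `delta`, `phi`.
#' @export
#' @examples
#' err_parameters()[, c("site", "beta_male", "beta_female")]
err_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "err_parameters_beir.csv",
                        package = "lymphorad", mustWork = TRUE)
  }
  par <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "dose_organ", "beta_male", "beta_female", "gamma",
            "eta", "theta", "delta", "phi")
  if (!all(need %in% names(par))) {
    stop("parameter table missing columns: ",
         paste(setdiff(need, names(par)), collapse = ", "))
  }
  if (!"leukemia" %in% par$site) stop("parameter table must include a leukemia row")
  bad <- setdiff(par$dose_organ, organ_sites())
  if (length(bad)) stop("dose_organ not in organ list: ", paste(bad, collapse = ", "))
  par
}

#' Risk-model configuration
#'
#' Modelling constants for the conversion of an exposure history into an
#' excess mortality rate.
#'
#' @param ddref Dose and dose-rate effectiveness factor (>= 1) dividing
#'   solid-cancer ERR at these low acute doses; leukaemia is not divided
#'   (dose-rate effects are already in its linear-quadratic form).
#' @param latency_solid_years,latency_leukemia_years Minimum years between
#'   exposure and expression of radiogenic risk.
#' @param thyroid_mode `"incidence"` applies the thyroid incidence-model
#'   parameters to baseline thyroid cancer mortality (default);
#'   `"other"` treats the thyroid site with the other-solid parameters;
#'   `"drop"` excludes thyroid from the risk sum.
#' @return A list of class `"risk_config"`.
#' @export
risk_config <- function(ddref = 1.5, latency_solid_years = 5,
                        latency_leukemia_years = 2,
                        thyroid_mode = c("incidence", "other", "drop")) {
  thyroid_mode <- match.arg(thyroid_mode)
  if (!is.numeric(ddref) || ddref < 1) stop("ddref must be >= 1")
  if (latency_solid_years < 0 || latency_leukemia_years < 0) {
    stop("latencies must be >= 0")
  }
  structure(list(ddref = ddref,
                 latency_solid_years = latency_solid_years,
                 latency_leukemia_years = latency_leukemia_years,
                 thyroid_mode = thyroid_mode),
            class = "risk_config")
}

#' Age-at-exposure transform of the ERR models
#'
#' @param e Age at exposure in years (vectorized).
#' @return `(e - 30) / 10` for `e < 30`, 0 for `e >= 30` (exposures past
#'   age 30 share the age-30 risk modifier).
#' @export
#' @examples
#' exposure_age_star(c(0, 15, 30, 45))
exposure_age_star <- function(e) {
  if (any(e < 0)) stop("age at exposure must be >= 0")
  pmin((e - 30) / 10, 0)
}

.check_ages <- function(age_exposure, age_attained) {
  if (any(age_attained <= age_exposure)) {
    stop("attained age must exceed age at exposure")
  }
}

.beta_for_sex <- function(par_row, sex) {
  b <- if (sex == "male") par_row$beta_male else par_row$beta_female
  b
}

#' Solid-cancer mortality ERR for one site and one exposure
#'
#' Evaluates \eqn{\beta_s d \exp(\gamma e^*) (a/60)^\eta}, returning 0 at
#' zero dose or within the minimum latency.  Vectorized over attained age.
#'
#' @param site Site identifier matching a row of [err_parameters()].
#' @param dose_Gy Absorbed organ dose in Gy.
#' @param sex `"male"` or `"female"`.
#' @param age_exposure Age at exposure (years).
#' @param age_attained Attained age(s), strictly greater than
#'   `age_exposure`.
#' @param params Parameter table from [err_parameters()].
#' @param latency_years Minimum latency; attained ages closer than this to
#'   the exposure contribute 0.
#' @return Dimensionless ERR, same length as `age_attained`.  No DDREF
#'   division is applied here.
#' @export
#' @examples
#' err_solid("lung", 0.1, "female", 10, 50)
err_solid <- function(site, dose_Gy, sex, age_exposure, age_attained,
                      params = err_parameters(), latency_years = 0) {
  sex <- match.arg(sex, c("male", "female"))
  if (dose_Gy < 0) stop("dose must be >= 0")
  .check_ages(age_exposure, age_attained)
  row <- params[params$site == site, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown or duplicated site: ", site)
  beta <- .beta_for_sex(row, sex)
  if (is.na(beta)) stop("site ", site, " has no ERR parameter for ", sex)
  estar <- exposure_age_star(age_exposure)
  err <- beta * dose_Gy * exp(row$gamma * estar) * (age_attained / 60)^row$eta
  err[age_attained - age_exposure < latency_years] <- 0
  err
}

#' Leukaemia mortality ERR for one exposure
#'
#' Evaluates the linear-quadratic leukaemia model
#' \eqn{\beta_s d (1+\theta d) \exp[\gamma e^* + \delta L + \phi e^* L]}
#' with \eqn{L = \log((a-e)/25)}, using the bone-marrow dose.  Returns 0 at
#' zero dose or within the minimum latency.  Vectorized over attained age.
#'
#' @inheritParams err_solid
#' @param dose_Gy Absorbed bone-marrow dose in Gy.
#' @return Dimensionless ERR, same length as `age_attained`.
#' @export
err_leukemia <- function(dose_Gy, sex, age_exposure, age_attained,
                         params = err_parameters(), latency_years = 0) {
  sex <- match.arg(sex, c("male", "female"))
  if (dose_Gy < 0) stop("dose must be >= 0")
  .check_ages(age_exposure, age_attained)
  row <- params[params$site == "leukemia", , drop = FALSE]
  beta <- .beta_for_sex(row, sex)
  estar <- exposure_age_star(age_exposure)
  tsl <- log((age_attained - age_exposure) / 25)
  err <- beta * dose_Gy * (1 + row$theta * dose_Gy) *
    exp(row$gamma * estar + row$delta * tsl + row$phi * estar * tsl)
  err[age_attained - age_exposure < latency_years] <- 0
  err
}

# sites restricted to one sex; others apply to both
.sex_specific_sites <- c(breast = "female", uterus = "female",
                         ovary = "female", prostate = "male")

.site_applies <- function(site, sex) {
  restricted <- .sex_specific_sites[site]
  is.na(restricted) || restricted == sex
}

#' Radiation-induced excess mortality rate at attained ages
#'
#' Transports the summed ERR of all exposures to the baseline cancer
#' mortality rates:
#' \deqn{M_{rad}(a) = \sum_s \lambda_s(a, \mathrm{sex})
#'       \sum_i ERR_s(d_{i,s}, e_i, a)}
#' with solid-site ERR divided by the DDREF.  Exposures combine additively
#' on the ERR scale; events at or after the attained age, or within the
#' minimum latency, contribute nothing.  Sex-specific sites contribute only
#' for the matching sex.
#'
#' @param ages Attained ages (years, vectorized).
#' @param sex `"male"` or `"female"`.
#' @param history An `exposure_history` from [realize_history()] (organ
#'   doses in mSv, treated numerically as absorbed dose in mGy for these
#'   photon exposures).
#' @param cancer_rates A site-labelled `rate_table` of baseline cancer
#'   mortality rates (per person-year), e.g. from
#'   [make_cancer_rate_tables()] or [load_rate_table()].
#' @param params ERR parameter table from [err_parameters()].
#' @param config A [risk_config()].
#' @return Numeric vector of excess mortality rates (per person-year),
#'   same length as `ages`.
#' @export
excess_mortality_rate <- function(ages, sex, history, cancer_rates,
                                  params = err_parameters(),
                                  config = risk_config()) {
  sex <- match.arg(sex, c("male", "female"))
  out <- numeric(length(ages))
  if (is.null(history) || nrow(history) == 0L) return(out)
  sites <- params$site
  if (config$thyroid_mode == "drop") sites <- setdiff(sites, "thyroid")
  rate_sites <- unique(cancer_rates$site)
  for (site in sites) {
    if (!.site_applies(site, sex)) next
    par_site <- if (site == "thyroid" && config$thyroid_mode == "other") {
      "other_solid"
    } else {
      site
    }
    row <- params[params$site == par_site, , drop = FALSE]
    if (is.na(.beta_for_sex(row, sex))) next
    if (!site %in% rate_sites) {
      stop("baseline cancer mortality rates missing for site: ", site)
    }
    organ <- params$dose_organ[params$site == site]
    latency <- if (site == "leukemia") config$latency_leukemia_years else
      config$latency_solid_years
    err_tot <- numeric(length(ages))
    for (i in seq_len(nrow(history))) {
      e <- history$age_at_exposure[i]
      d <- history[[organ]][i] / 1000  # mSv -> Gy (photon exposure)
      if (d == 0) next
      ok <- ages > e
      if (!any(ok)) next
      err_i <- numeric(length(ages))
      if (site == "leukemia") {
        err_i[ok] <- err_leukemia(d, sex, e, ages[ok], params = params,
                                  latency_years = latency)
      } else {
        err_i[ok] <- err_solid(par_site, d, sex, e, ages[ok], params = params,
                               latency_years = latency) / config$ddref
      }
      err_tot <- err_tot + err_i
    }
    lam <- rate_at(cancer_rates, ages, sex, site = site)
    out <- out + lam * err_tot
  }
  out
}
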