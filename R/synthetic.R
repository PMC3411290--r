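# Synthetic mortality inputs: Gompertz-Makeham background all-cause
# mortality, power-law-above-onset baseline cancer mortality by site, and
# a tiny hand-checkable worked example.

#' Gompertz-Makeham parameters for synthetic background mortality
#'
#' The all-cause hazard is modelled as
#' \deqn{\mu(a) = c + A e^{b a}}
#' with a Makeham (age-independent) term `c` and Gompertz senescent terms
#' `A`, `b`.  The defaults are calibrated so that life expectancy at birth
#' is about 76 years for males and 82 years for females, the range typical
#' of contemporary European populations.
#'
#' @return Named list per sex with elements `makeham`, `gompertz_scale`,
#'   `gompertz_rate`.
#' @export
#' @examples
#' gompertz_makeham_params()$male
gompertz_makeham_params <- function() {
  list(
    male   = list(makeham = 8e-4, gompertz_scale = 4.0e-5, gompertz_rate = 0.092),
    female = list(makeham = 5e-4, gompertz_scale = 1.8e-5, gompertz_rate = 0.096)
  )
}

#' Generate a synthetic background all-cause mortality table
#'
#' Deterministic given the parameters; optional multiplicative log-normal
#' noise (for robustness experiments) requires an explicit seed so the
#' table is reproducible.
#'
#' @param params Per-sex Gompertz-Makeham parameters
#'   (see [gompertz_makeham_params()]).
#' @param max_age Last age of the table.
#' @param noise_sd Standard deviation of log-normal multiplicative noise;
#'   0 (default) for the deterministic table.
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @return A `rate_table` with ages `0..max_age` for both sexes.
#' @export
#' @examples
#' bg <- make_background_table()
#' head(bg)
make_background_table <- function(params = gompertz_makeham_params(),
                                  max_age = 110, noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed)) {
    stop("stochastic perturbation requires an explicit seed")
  }
  if (!is.null(seed)) set.seed(seed)
  ages <- 0:max_age
  out <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    p <- params[[sx]]
    stopifnot(p$makeham >= 0, p$gompertz_scale >= 0, p$gompertz_rate >= 0)
    mu <- p$makeham + p$gompertz_scale * exp(p$gompertz_rate * ages)
    if (noise_sd > 0) {
      mu <- mu * exp(stats::rnorm(length(mu), sd = noise_sd))
    }
    data.frame(age = ages, sex = sx, rate = mu, stringsAsFactors = FALSE)
  }))
  tab <- rate_table(out)
  attr(tab, "seed") <- seed
  attr(tab, "noise_sd") <- noise_sd
  tab
}

#' Power-law shapes for synthetic baseline cancer mortality
#'
#' Each site's mortality rate rises from an onset age as a power law,
#' \deqn{\lambda_s(a) = r_{70} \left(\frac{a - a_0}{70 - a_0}\right)^p}
#' for `a > a_0` and 0 before, parameterized by the rate at age 70
#' (`rate_at_70`, per person-year), the onset age and the power.  Defaults
#' approximate contemporary Euro-American site-specific cancer mortality:
#' lifetime cancer mortality of roughly 29% (male) and 19% (female),
#' lung and "other solid" dominating, breast with an earlier onset and
#' shallower rise, leukaemia with a small mostly flat childhood-inclusive
#' rate, and the sex-specific sites (breast, uterus, ovary, prostate)
#' present only for the applicable sex.
#'
#' @return Data frame with columns `sex`, `site`, `rate_at_70`,
#'   `onset_age`, `power`.
#' @export
cancer_rate_shapes <- function() {
  m <- data.frame(
    sex = "male",
    site = c("lung", "other_solid", "colon", "prostate", "stomach", "liver",
             "bladder", "leukemia", "thyroid", "breast", "uterus", "ovary"),
    rate_at_70 = c(2.6e-3, 2.4e-3, 1.1e-3, 1.1e-3, 5e-4, 4.5e-4,
                   3.5e-4, 3.5e-4, 3e-5, 0, 0, 0),
    onset_age = c(30, 30, 30, 45, 30, 30, 30, 0, 20, 30, 30, 30),
    power = c(2.5, 2.5, 2.5, 5, 2.5, 2.5, 2.5, 1.5, 2, 2.5, 2.5, 2.5),
    stringsAsFactors = FALSE)
  f <- data.frame(
    sex = "female",
    site = c("lung", "other_solid", "breast", "colon", "ovary", "stomach",
             "liver", "uterus", "bladder", "leukemia", "thyroid", "prostate"),
    rate_at_70 = c(8e-4, 1.4e-3, 8.5e-4, 7e-4, 3.5e-4, 2.5e-4,
                   2.2e-4, 2.2e-4, 1.1e-4, 2.5e-4, 4e-5, 0),
    onset_age = c(30, 30, 25, 30, 30, 30, 30, 30, 30, 0, 20, 30),
    power = c(2.5, 2.5, 2.0, 2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 1.5, 2, 2.5),
    stringsAsFactors = FALSE)
  rbind(m, f)
}

#' Generate synthetic baseline cancer mortality tables by site
#'
#' Evaluates the power-law shapes on the background table's age grid and
#' validates the consistency constraint that summed cancer mortality stays
#' below all-cause mortality at every age.
#'
#' @param shapes Shape table as from [cancer_rate_shapes()].
#' @param background All-cause `rate_table` used for the age grid and the
#'   sum constraint.
#' @return A site-labelled `rate_table` covering every organ-risk site
#'   (including leukaemia) for both sexes.
#' @export
make_cancer_rate_tables <- function(shapes = cancer_rate_shapes(),
                                    background = make_background_table()) {
  need <- c("leukemia", organ_sites())
  need <- setdiff(need, "bone_marrow")  # leukaemia is the marrow-driven site
  for (sx in c("male", "female")) {
    miss <- setdiff(need, shapes$site[shapes$sex == sx])
    if (length(miss)) {
      stop("cancer rate shapes missing site(s) for ", sx, ": ",
           paste(miss, collapse = ", "))
    }
  }
  ages <- sort(unique(background$age))
  out <- do.call(rbind, lapply(seq_len(nrow(shapes)), function(i) {
    s <- shapes[i, ]
    if (s$rate_at_70 < 0) stop("negative rate_at_70 for site ", s$site)
    rel <- pmax(0, (ages - s$onset_age) / (70 - s$onset_age))
    data.frame(age = ages, sex = s$sex, site = s$site,
               rate = s$rate_at_70 * rel^s$power, stringsAsFactors = FALSE)
  }))
  tab <- rate_table(out)
  for (sx in c("male", "female")) {
    tot <- tapply(tab$rate[tab$sex == sx], tab$age[tab$sex == sx], sum)
    bg <- rate_at(background, as.numeric(names(tot)), sx)
    bad <- which(as.numeric(tot) >= bg)
    if (length(bad)) {
      stop("summed cancer mortality reaches all-cause mortality at age ",
           names(tot)[bad[1]], " (", sx, ")")
    }
  }
  tab
}

#' Tiny worked example for hand-checkable oracle tests
#'
#' A deliberately small bundle: a three-site parameter set (lung, breast,
#' leukaemia), flat three-age mortality tables, a two-event exposure
#' history and a configuration with no DDREF and no latency, for a female
#' patient followed over three one-year intervals.  Every downstream
#' quantity (excess mortality rates, life-table decomposition, REID, life
#' expectancy) is small enough to be recomputed by explicit arithmetic.
#'
#' @return List with `patient`, `history`, `params`, `background`,
#'   `cancer_rates`, `config`, `max_age` and `disease_hazard`.
#' @export
make_toy_worked_example <- function() {
  patient <- patient_profile("female", 60, "DLBCL")
  history <- data.frame(
    age_at_exposure = c(58, 60),
    exam = "WB_CT",
    effective_dose = c(10, 10),
    stringsAsFactors = FALSE)
  for (org in organ_sites()) history[[org]] <- 0
  history$lung <- c(12, 10)
  history$breast <- c(9, 8)
  history$bone_marrow <- c(10, 11)
  class(history) <- c("exposure_history", "data.frame")
  attr(history, "sex") <- "female"
  params <- data.frame(
    site = c("lung", "breast", "leukemia"),
    dose_organ = c("lung", "breast", "bone_marrow"),
    beta_male = c(0.32, NA, 1.1),
    beta_female = c(1.40, 0.51, 1.2),
    gamma = c(-0.30, 0.00, -0.40),
    eta = c(-1.4, -2.0, NA),
    theta = c(NA, NA, 0.87),
    delta = c(NA, NA, -0.48),
    phi = c(NA, NA, 0.42),
    stringsAsFactors = FALSE)
  ages <- 0:110
  background <- rate_table(do.call(rbind, lapply(c("male", "female"),
    function(sx) data.frame(age = ages, sex = sx, rate = 0.02,
                            stringsAsFactors = FALSE))))
  cancer_rates <- rate_table(do.call(rbind, lapply(c("male", "female"),
    function(sx) do.call(rbind, lapply(c("lung", "breast", "leukemia"),
      function(st) data.frame(age = ages, sex = sx, site = st,
                              rate = c(lung = 4e-3, breast = 2e-3,
                                       leukemia = 1e-3)[[st]],
                              stringsAsFactors = FALSE))))))
  list(patient = patient, history = history, params = params,
       background = background, cancer_rates = cancer_rates,
       config = risk_config(ddref = 1, latency_solid_years = 0,
                            latency_leukemia_years = 0),
       disease_hazard = calibrate_disease_hazard(horizon_years = 5,
                                                 survival_fraction = 0.58),
       max_age = 63)
}
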