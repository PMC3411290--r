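# Shared fixtures, built once per test run.  All synthetic inputs are
# generated in code; nothing is read from disk beyond the bundled tables.

.shared <- new.env(parent = emptyenv())

shared_background <- function() {
  if (is.null(.shared$bg)) .shared$bg <- make_background_table()
  .shared$bg
}

shared_cancer_rates <- function() {
  if (is.null(.shared$cr)) {
    .shared$cr <- make_cancer_rate_tables(background = shared_background())
  }
  .shared$cr
}

shared_cohort <- function(disease, corrected) {
  key <- paste0(disease, "_", corrected)
  if (is.null(.shared[[key]])) {
    .shared[[key]] <- summarize_cohort(disease, shared_background(),
                                       shared_cancer_rates(),
                                       corrected = corrected)
  }
  .shared[[key]]
}

# Independent re-derivation of the toy worked example: plain loops and the
# model formulas typed out, no package internals.  Hazards are evaluated
# at interval midpoints (60.5, 61.5, 62.5), the life table's convention.
toy_oracle <- function(toy, include_disease = FALSE) {
  ages <- 60:62 + 0.5
  par <- toy$params
  m_rad <- sapply(ages, function(a) {
    tot <- 0
    for (i in seq_len(nrow(toy$history))) {
      e <- toy$history$age_at_exposure[i]
      if (a <= e) next
      estar <- if (e < 30) (e - 30) / 10 else 0
      for (site in par$site) {
        p <- par[par$site == site, ]
        d <- toy$history[[p$dose_organ]][i] / 1000
        lam <- toy$cancer_rates$rate[toy$cancer_rates$sex == "female" &
                                     toy$cancer_rates$site == site &
                                     toy$cancer_rates$age == floor(a)][1]
        err <- if (site == "leukemia") {
          L <- log((a - e) / 25)
          p$beta_female * d * (1 + p$theta * d) *
            exp(p$gamma * estar + p$delta * L + p$phi * estar * L)
        } else {
          p$beta_female * d * exp(p$gamma * estar) * (a / 60)^p$eta
        }
        tot <- tot + lam * err
      }
    }
    tot
  })
  mu_dis <- if (include_disease) rep(toy$disease_hazard$rate, 3) else rep(0, 3)
  mu <- 0.02 + m_rad + mu_dis
  q <- 1 - exp(-mu)
  l <- cumprod(c(1, 1 - q))[1:3]
  list(reid = sum(l * q * m_rad / mu),
       le = sum(l * (1 - q / 2)),
       survivor = prod(1 - q))
}

# flat all-cause table: the same constant hazard at every age, both sexes
constant_rate_table <- function(rate, max_age = 110) {
  ages <- 0:max_age
  rate_table(do.call(rbind, lapply(c("male", "female"), function(sx) {
    data.frame(age = ages, sex = sx, rate = rate, stringsAsFactors = FALSE)
  })))
}
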