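test_that("age-at-exposure transform plateaus at age 30", {
  expect_equal(exposure_age_star(30), 0)
  expect_equal(exposure_age_star(0), -3)
  expect_equal(exposure_age_star(45), 0)
  expect_equal(exposure_age_star(c(10, 20)), c(-2, -1))
  expect_error(exposure_age_star(-1))
})

test_that("solid-cancer ERR obeys its closed-form identities", {
  par <- err_parameters()
  # zero dose
  expect_equal(err_solid("lung", 0, "male", 10, 50, par), 0)
  # at attained age 60 with exposure at 30 both modifiers are unity
  for (site in c("stomach", "colon", "lung", "bladder")) {
    row <- par[par$site == site, ]
    expect_equal(err_solid(site, 0.05, "male", 30, 60, par),
                 row$beta_male * 0.05)
    expect_equal(err_solid(site, 0.05, "female", 30, 60, par),
                 row$beta_female * 0.05)
  }
  # linear in dose
  e1 <- err_solid("colon", 0.01, "female", 5, 40, par)
  e2 <- err_solid("colon", 0.02, "female", 5, 40, par)
  expect_equal(e2, 2 * e1)
  # exposures at ages past 30 share the same risk modifier
  expect_equal(err_solid("lung", 0.1, "male", 35, 70, par),
               err_solid("lung", 0.1, "male", 45, 70, par))
  # latency zeroes the early years only
  v <- err_solid("lung", 0.1, "male", 10, c(12, 14, 16), par,
                 latency_years = 5)
  expect_equal(v[1:2], c(0, 0))
  expect_gt(v[3], 0)
  expect_error(err_solid("lung", 0.1, "male", 50, 50, par), "attained age")
  expect_error(err_solid("breast", 0.1, "male", 10, 50, par), "no ERR")
  expect_error(err_solid("spleen", 0.1, "male", 10, 50, par), "unknown")
})

test_that("leukaemia ERR matches its linear-quadratic closed form", {
  par <- err_parameters()
  row <- par[par$site == "leukemia", ]
  expect_equal(err_leukemia(0, "male", 10, 30, par), 0)
  # at 25 years since exposure with exposure past 30 all modifiers vanish
  d <- 0.2
  expect_equal(err_leukemia(d, "female", 35, 60, par),
               row$beta_female * d * (1 + row$theta * d))
  # upward curvature: doubling dose more than doubles ERR
  r <- err_leukemia(2 * d, "male", 35, 60, par) /
    err_leukemia(d, "male", 35, 60, par)
  expect_equal(r, 2 * (1 + 2 * row$theta * d) / (1 + row$theta * d))
  expect_gt(r, 2)
  # latency
  expect_equal(err_leukemia(d, "male", 10, 11, par, latency_years = 2), 0)
  expect_error(err_leukemia(d, "male", 50, 49, par), "attained age")
})

test_that("excess mortality rate aggregates sites and exposures additively", {
  toy <- make_toy_worked_example()
  ages <- 61:80
  m1 <- excess_mortality_rate(ages, "female", toy$history, toy$cancer_rates,
                              toy$params, toy$config)
  expect_true(all(m1 >= 0))
  # empty history contributes nothing
  expect_equal(excess_mortality_rate(ages, "female", toy$history[0, ],
                                     toy$cancer_rates, toy$params,
                                     toy$config),
               numeric(length(ages)))
  # duplicating every exposure doubles the rate
  hist2 <- rbind(toy$history, toy$history)
  class(hist2) <- class(toy$history)
  m2 <- excess_mortality_rate(ages, "female", hist2, toy$cancer_rates,
                              toy$params, toy$config)
  expect_equal(m2, 2 * m1)
  # single exposure, single site, ddref 1: the one-term product
  h1 <- toy$history[1, ]
  class(h1) <- class(toy$history)
  one <- excess_mortality_rate(70, "female", h1,
                               toy$cancer_rates[toy$cancer_rates$site == "lung", ],
                               toy$params[toy$params$site == "lung", ],
                               toy$config)
  lam <- rate_at(toy$cancer_rates, 70, "female", site = "lung")
  expect_equal(one, lam * err_solid("lung", h1$lung / 1000, "female",
                                    h1$age_at_exposure, 70, toy$params))
})

test_that("vectorized excess mortality matches a brute-force triple loop", {
  toy <- make_toy_worked_example()
  par <- toy$params
  ages <- seq(60.5, 100.5, by = 1)
  for (sex in c("male", "female")) {
    got <- excess_mortality_rate(ages, sex, toy$history, toy$cancer_rates,
                                 par, risk_config(ddref = 1.5,
                                                  latency_solid_years = 5,
                                                  latency_leukemia_years = 2))
    # independent re-derivation: plain loops and the model formulas typed out
    expected <- numeric(length(ages))
    for (k in seq_along(ages)) {
      a <- ages[k]
      tot <- 0
      for (i in seq_len(nrow(toy$history))) {
        e <- toy$history$age_at_exposure[i]
        estar <- if (e < 30) (e - 30) / 10 else 0
        for (site in par$site) {
          if (site == "breast" && sex == "male") next
          p <- par[par$site == site, ]
          beta <- if (sex == "male") p$beta_male else p$beta_female
          d <- toy$history[[p$dose_organ]][i] / 1000
          lam <- toy$cancer_rates$rate[toy$cancer_rates$sex == sex &
                                       toy$cancer_rates$site == site &
                                       toy$cancer_rates$age == floor(a)][1]
          if (site == "leukemia") {
            if (a - e < 2) next
            L <- log((a - e) / 25)
            err <- beta * d * (1 + p$theta * d) *
              exp(p$gamma * estar + p$delta * L + p$phi * estar * L)
          } else {
            if (a - e < 5) next
            err <- beta * d * exp(p$gamma * estar) * (a / 60)^p$eta / 1.5
          }
          tot <- tot + lam * err
        }
      }
      expected[k] <- tot
    }
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("excess mortality is monotone under dose scaling and zero pre-exposure", {
  toy <- make_toy_worked_example()
  ages <- c(30, 45, 55, 58.5, 61, 70, 90)
  m <- excess_mortality_rate(ages, "female", toy$history, toy$cancer_rates,
                             toy$params, toy$config)
  # nothing before the first exposure at 58 (and within leukaemia latency)
  expect_equal(m[ages <= 58], rep(0, sum(ages <= 58)))
  scaled <- toy$history
  for (org in c("lung", "breast", "bone_marrow")) {
    scaled[[org]] <- scaled[[org]] * 3
  }
  class(scaled) <- class(toy$history)
  m3 <- excess_mortality_rate(ages, "female", scaled, toy$cancer_rates,
                              toy$params, toy$config)
  expect_true(all(m3 >= m))
  expect_true(all(m3[ages > 61] > m[ages > 61]))
})
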