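test_that("life table matches the hand-computed three-age worked example", {
  toy <- make_toy_worked_example()
  lt <- build_life_table(toy$patient, toy$history, toy$background,
                         toy$cancer_rates, disease_hazard = NULL,
                         params = toy$params, config = toy$config,
                         max_age = toy$max_age)
  oracle <- toy_oracle(toy)
  expect_equal(reid(lt), oracle$reid, tolerance = 1e-12)
  expect_equal(life_expectancy(lt), oracle$le, tolerance = 1e-12)
  expect_equal(lt$summary$survivor_at_max_age, oracle$survivor,
               tolerance = 1e-12)

  # adding the disease hazard strictly decreases REID
  lt_dis <- build_life_table(toy$patient, toy$history, toy$background,
                             toy$cancer_rates,
                             disease_hazard = toy$disease_hazard,
                             params = toy$params, config = toy$config,
                             max_age = toy$max_age)
  oracle_dis <- toy_oracle(toy, include_disease = TRUE)
  expect_equal(reid(lt_dis), oracle_dis$reid, tolerance = 1e-12)
  expect_lt(reid(lt_dis), reid(lt))

  # zeroing every dose zeroes REID
  zero <- toy$history
  for (org in organ_sites()) zero[[org]] <- 0
  class(zero) <- class(toy$history)
  lt0 <- build_life_table(toy$patient, zero, toy$background,
                          toy$cancer_rates, params = toy$params,
                          config = toy$config, max_age = toy$max_age)
  expect_equal(reid(lt0), 0)
})

test_that("life table conserves the cohort and attributes every death", {
  toy <- make_toy_worked_example()
  lt <- build_life_table(toy$patient, toy$history, toy$background,
                         toy$cancer_rates, disease_hazard = toy$disease_hazard,
                         params = toy$params, config = toy$config,
                         max_age = 110)
  tab <- lt$table
  expect_equal(tab$d, tab$d_background + tab$d_radiation + tab$d_disease,
               tolerance = 1e-12)
  expect_equal(sum(tab$d) + lt$summary$survivor_at_max_age, 1,
               tolerance = 1e-9)
  expect_true(all(diff(tab$l) <= 0))
  expect_equal(tab$l[1], 1)
})

test_that("no radiation and no disease reduces to the background life table", {
  bg <- shared_background()
  cr <- shared_cancer_rates()
  pt <- patient_profile("male", 5, "HD")
  hist <- realize_history(standard_protocol("HD"), pt)
  lt <- build_life_table(pt, hist, bg, cr, include_radiation = FALSE,
                         include_disease = FALSE)
  expect_equal(reid(lt), 0)
  expect_equal(lt$table$mu_total, lt$table$mu_background)
  full <- build_life_table(pt, hist, bg, cr)
  expect_lt(life_expectancy(full), life_expectancy(lt))
  expect_equal(delta_life_expectancy(lt, lt), 0)
  expect_gt(delta_life_expectancy(full, lt), 0)
})

test_that("constant-hazard life expectancy matches the exponential oracle", {
  m <- 0.01
  bg <- constant_rate_table(m)
  pt <- patient_profile("male", 0, "HD")
  lt <- build_life_table(pt, NULL, bg, shared_cancer_rates(),
                         include_radiation = FALSE, include_disease = FALSE)
  # exact geometric-series value of the discrete trapezoid estimator
  q <- 1 - exp(-m)
  p <- 1 - q
  closed <- (1 - q / 2) * (1 - p^110) / q
  expect_equal(life_expectancy(lt), closed, tolerance = 1e-12)
  # and the continuous-time lifetime integral it approximates
  tt <- seq(0, 110, by = 1 / 512)
  continuous <- sum(exp(-m * tt)) / 512
  expect_equal(life_expectancy(lt), continuous, tolerance = 1e-3)
})

test_that("with a single hazard source all deaths are radiation deaths", {
  toy <- make_toy_worked_example()
  lt <- build_life_table(toy$patient, toy$history, constant_rate_table(0),
                         toy$cancer_rates, params = toy$params,
                         config = toy$config, max_age = 110)
  expect_equal(reid(lt), 1 - lt$summary$survivor_at_max_age,
               tolerance = 1e-12)
  expect_equal(sum(lt$table$d_background), 0)
})

test_that("REID is monotone under scaling of all organ doses", {
  bg <- shared_background()
  cr <- shared_cancer_rates()
  pt <- patient_profile("female", 10, "HD")
  hist <- realize_history(standard_protocol("HD"), pt)
  reids <- sapply(c(0.5, 1, 2, 4), function(k) {
    h <- hist
    for (org in organ_sites()) h[[org]] <- h[[org]] * k
    class(h) <- class(hist)
    reid(build_life_table(pt, h, bg, cr))
  })
  expect_true(all(diff(reids) > 0))
})

test_that("annual and monthly life tables agree closely", {
  bg <- shared_background()
  cr <- shared_cancer_rates()
  pt <- patient_profile("female", 5, "HD")
  hist <- realize_history(standard_protocol("HD"), pt)
  dz <- calibrate_disease_hazard("HD")
  annual <- build_life_table(pt, hist, bg, cr, disease_hazard = dz)
  monthly <- build_life_table(pt, hist, bg, cr, disease_hazard = dz,
                              step_years = 1 / 12)
  expect_equal(reid(monthly), reid(annual), tolerance = 5e-3)
  expect_equal(life_expectancy(monthly), life_expectancy(annual),
               tolerance = 5e-3)
})

test_that("survival horizons must lie on the life-table grid", {
  toy <- make_toy_worked_example()
  lt <- build_life_table(toy$patient, toy$history, toy$background,
                         toy$cancer_rates, params = toy$params,
                         config = toy$config, max_age = 110)
  expect_equal(survival_after(lt, 0), 1)
  expect_lt(survival_after(lt, 5), 1)
  expect_error(survival_after(lt, 2.31), "grid")
})

test_that("cohort summaries preserve the sex and correction orderings", {
  for (dz in c("HD", "DLBCL")) {
    corr <- shared_cohort(dz, TRUE)$results
    uncorr <- shared_cohort(dz, FALSE)$results
    key <- function(d) paste(d$age_at_diagnosis, d$sex)
    expect_equal(key(corr), key(uncorr))
    # disease correction strictly lowers REID and the radiation-induced
    # loss of life expectancy in every category
    expect_true(all(corr$reid < uncorr$reid))
    expect_true(all(corr$dle_radiation_days < uncorr$dle_radiation_days))
    # female REID exceeds male REID for the identical schedule
    for (d in list(corr, uncorr)) {
      w <- reshape(d[, c("age_at_diagnosis", "sex", "reid")],
                   direction = "wide", idvar = "age_at_diagnosis",
                   timevar = "sex")
      expect_true(all(w$reid.female > w$reid.male))
    }
  }
})

test_that("single-category cohort averages equal that category", {
  s <- summarize_cohort("DLBCL", shared_background(), shared_cancer_rates(),
                        ages = 65, sexes = "male")
  expect_equal(s$averages$reid, s$results$reid)
  expect_equal(s$averages$life_expectancy_years,
               s$results$life_expectancy_years)
  expect_equal(s$averages$n_categories, 1)
})
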