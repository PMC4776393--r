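test_that("config validation rejects impossible worlds", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(frag_mean_d2 = 1.0), ">= 1")
  expect_error(simulation_config(noise_sd = -1))
  cfg <- simulation_config(seed = 5)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(sum(cfg$embryos_per_patient), 1)
})

test_that("noise-free symmetric division reproduces exact geometry", {
  cfg <- simulation_config(n_patients = 1, asymmetry = 0, noise_sd = 0,
                           frag_mean_d2 = 0, frag_extra_d3 = 0,
                           n_d2_target = 4, n_d2_sd = 0, n_d3_target = 8,
                           n_d3_sd = 0, misgrade_rate = 0, seed = 8)
  sim <- simulate_embryo(cfg)
  d1 <- sim$latent$day1_diameter
  expect_equal(sim$measurements$day2_diameters,
               rep(d1 * 4^(-1 / 3), 4), tolerance = 1e-12)
  f <- derive_cass_features(sim$measurements)
  expect_equal(f$cod_d2, 1.0)
  expect_equal(f$cod_d3, 1.0)
  expect_equal(f$frag_d2, 0, tolerance = 1e-9)
  expect_equal(f$frag_d3, 0, tolerance = 1e-9)
  expect_equal(sim$grades$frag_cat_d2, 0L)
  expect_equal(sim$grades$symmetry_d2, 0L)
})

test_that("generator-analyzer round trip recovers the drawn fragmentation", {
  cfg <- simulation_config(n_patients = 1, noise_sd = 0, asymmetry = 0.2,
                           frag_mean_d2 = 0.30, frag_conc = 1e6,
                           frag_extra_d3 = 0, misgrade_rate = 0, seed = 9)
  for (i in 1:5) {
    sim <- simulate_embryo(cfg, rng = embryoselect:::.new_rng(100 + i))
    f <- derive_cass_features(sim$measurements)
    expect_equal(f$frag_d2, 0.30, tolerance = 0.02)
    expect_equal(f$frag_d2, sim$latent$frag_d2, tolerance = 0.02)
    # SSS category from the realized fraction: 0.30 is in the 20-50% band
    expect_equal(sim$grades$frag_cat_d2, 3L)
  }
})

test_that("fragmentation 15 percent maps to visual category 2", {
  cfg <- simulation_config(n_patients = 1, noise_sd = 0,
                           frag_mean_d2 = 0.15, frag_conc = 1e6,
                           frag_extra_d3 = 0, misgrade_rate = 0, seed = 10)
  sim <- simulate_embryo(cfg)
  expect_equal(sim$grades$frag_cat_d2, 2L)
})

test_that("volume bookkeeping holds for every simulated embryo (property)", {
  cfg <- simulation_config(n_patients = 40, noise_sd = 0, seed = 11)
  co <- simulate_cohort(cfg)
  for (i in seq_along(co$measurements)) {
    m <- co$measurements[[i]]
    v1 <- blastomere_volume(m$day1_diameter)
    for (day in c("day2_diameters", "day3_diameters")) {
      total <- sum(blastomere_volume(m[[day]]))
      # blastomeres + fragments account for Day-1 volume (dust < 1 um lost)
      expect_lt(abs(total - v1) / v1, 1e-5)
    }
  }
})

test_that("same config and seed reproduce the cohort byte-identically", {
  cfg <- simulation_config(n_patients = 50, seed = 12)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a, b)
  c2 <- suppressWarnings(simulate_cohort(simulation_config(n_patients = 50,
                                                           seed = 13)))
  expect_false(identical(a$outcome, c2$outcome))
})

test_that("intercept-only truth at logit 0 gives prevalence one half", {
  cfg <- simulation_config(n_patients = 2000, seed = 14,
                           outcome_model = c("(Intercept)" = 0))
  co <- suppressWarnings(simulate_cohort(cfg))
  expect_lt(abs(mean(co$outcome) - 0.5), 2 * sqrt(0.25 / 2000))
  # prevalence tracks the logistic expectation of the latent score
  cfg2 <- simulation_config(n_patients = 2000, seed = 15)
  co2 <- suppressWarnings(simulate_cohort(cfg2))
  expected <- mean(plogis(co2$latent_score))
  sd3 <- 3 * sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(mean(co2$outcome) - expected), sd3)
})

test_that("the latent score is the best ranker in expectation", {
  gaps <- vapply(1:5, function(i) {
    cfg <- simulation_config(n_patients = 600, seed = 20 + i)
    co <- suppressWarnings(simulate_cohort(cfg))
    ft <- cohort_feature_table(co, "CASS")
    fit <- fit_logistic(as.matrix(ft[, c("n_d2", "frag_d2", "male_age")]),
                        ft$outcome)
    roc_auc(co$latent_score, co$outcome)$auc -
      roc_auc(predict(fit, ft), ft$outcome)$auc
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("SSS grades reflect geometry and honour the mis-grading rate", {
  cfg0 <- simulation_config(n_patients = 150, misgrade_rate = 0,
                            noise_sd = 0, seed = 16)
  co0 <- suppressWarnings(simulate_cohort(cfg0))
  ft <- cohort_feature_table(co0, "CASS")
  cats <- vapply(co0$grades, `[[`, integer(1), "frag_cat_d2")
  expect_equal(cats, fragmentation_category(pmin(ft$frag_d2, 1)),
               tolerance = 0)
  # with heavy mis-grading the grades decouple from geometry
  cfg4 <- simulation_config(n_patients = 150, misgrade_rate = 0.9,
                            seed = 16)
  co4 <- suppressWarnings(simulate_cohort(cfg4))
  cats4 <- vapply(co4$grades, `[[`, integer(1), "frag_cat_d2")
  expect_gt(sum(cats != cats4), 30)
})

test_that("recovery experiment reports LR coverage and MARS knots", {
  cfg <- simulation_config(
    n_patients = 500, seed = 17,
    outcome_model = c("(Intercept)" = 1.2, frag_d2 = -6, male_age = -0.04))
  rep_lr <- suppressWarnings(recovery_experiment(cfg, "LR",
                                                 n_validation = 100))
  expect_equal(rep_lr$model, "LR")
  expect_equal(nrow(rep_lr$coefficients), 3L)
  expect_true(all(c("truth", "estimate", "se", "covered") %in%
                    names(rep_lr$coefficients)))
  expect_true(is.finite(rep_lr$auc_gap))
  rep_m <- suppressWarnings(recovery_experiment(cfg, "MARS",
                                                n_validation = 100))
  expect_s3_class(rep_m$fit, "mars_model")
  expect_true(is.finite(rep_m$auc_validation))
})
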