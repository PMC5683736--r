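test_that("config validation enforces the documented invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(stage_probs = c(normal = 0.5, expansion = 0.2,
                                             replacement = 0.2,
                                             excluded_infarct = 0.2,
                                             unclassified = 0)),
               "sum to 1")
  expect_error(cohort_config(stage_hazards = c(normal = -0.1, expansion = 0.03,
                                               replacement = 0.07,
                                               excluded_infarct = 0.03,
                                               unclassified = 0.03)),
               "non-negative")
  expect_error(cohort_config(followup_window = c(3, 2)), "window")
  expect_error(cohort_config(hct = c(mean = NA, sd = 0.03, lower = 0.25,
                                     upper = 0.55)),
               "non-finite")
})

test_that("generation is reproducible and respects trivial configs", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # different seed changes the draw
  expect_false(identical(a, generate_cohort(small_config(seed = 43))))
  # empty cohort
  empty <- generate_cohort(cohort_config(n_controls = 0, n_as = 0))
  expect_equal(nrow(empty), 0)
  # zero hazards: everyone censored
  zero <- generate_cohort(cohort_config(
    n_controls = 10, n_as = 50, seed = 3,
    stage_hazards = c(normal = 0, expansion = 0, replacement = 0,
                      excluded_infarct = 0, unclassified = 0),
    control_hazard = 0))
  expect_equal(sum(zero$death), 0)
})

test_that("generated records satisfy structural and censoring sanity", {
  cfg <- small_config(seed = 99)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), cfg$n_controls + cfg$n_as)
  ctl <- coh[coh$arm == "control", ]
  expect_true(all(as.matrix(ctl[paste0("lge_s", 1:6)]) == "none"))
  expect_true(all(is.na(ctl$latent_stage)))
  expect_true(all(coh$followup_years <= cfg$followup_window[2] + 1e-12))
  expect_true(all(coh$followup_years > 0))
  expect_true(all(coh$hematocrit >= 0.25 & coh$hematocrit <= 0.55))
  # replacement patients carry mid-wall LGE; infarct-excluded carry infarct LGE
  lge <- as.matrix(coh[paste0("lge_s", 1:6)])
  rep_rows <- which(coh$latent_stage == "replacement")
  expect_true(all(apply(lge[rep_rows, , drop = FALSE], 1,
                        function(r) any(r == "midwall"))))
  inf_rows <- which(coh$latent_stage == "excluded_infarct")
  expect_true(all(apply(lge[inf_rows, , drop = FALSE], 1,
                        function(r) any(r == "infarct"))))
  # AS-death implies death
  expect_true(all(coh$death[coh$as_death == 1] == 1))
})

test_that("arm-level iECV means match the calibration at large n", {
  cfg <- cohort_config(n_controls = 5000, n_as = 5000, seed = 7)
  coh <- generate_cohort(cfg)
  m <- compute_cohort_metrics(coh)
  ctl <- m$iecv_ml_m2[m$arm == "control"]
  expect_lt(abs(mean(ctl) - 16.1), 3 * sd(ctl) / sqrt(length(ctl)))
  asv <- m$iecv_ml_m2[m$arm == "as" & m$metrics_available]
  expect_lt(abs(mean(asv) - 23.6), 3 * sd(asv) / sqrt(length(asv)))
})

test_that("biopsy subset: degenerate link, bounds, and sampling correlation", {
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  # degenerate link: slope 0, no noise -> all values at the intercept
  cfg_flat <- small_config(biopsy_link = list(intercept = 10, slope = 0,
                                              noise_sd = 0))
  b0 <- generate_biopsy_subset(coh, cfg_flat)
  expect_equal(b0$fibrosis_pct, rep(10, cfg$biopsy_n))
  # truncation bound under huge noise
  cfg_noisy <- small_config(biopsy_link = list(intercept = 10, slope = 1,
                                               noise_sd = 300))
  bn <- generate_biopsy_subset(coh, cfg_noisy)
  expect_true(all(bn$fibrosis_pct >= 0 & bn$fibrosis_pct <= 100))
  # large-subset sample correlation matches the closed-form population value
  big <- cohort_config(n_controls = 0, n_as = 3000, seed = 11, biopsy_n = 2000)
  bc <- generate_cohort(big)
  bb <- generate_biopsy_subset(bc, big)
  rho <- biopsy_link_correlation(sd(bb$iecv_ml_m2), big$biopsy_link)
  r <- correlate(bb$iecv_ml_m2, bb$fibrosis_pct)$estimate
  se_r <- (1 - rho^2) / sqrt(2000 - 1)
  expect_lt(abs(r - rho), 3 * se_r)
  expect_error(generate_biopsy_subset(coh[coh$arm == "control", ][0, ], cfg),
               "empty")
  expect_error(generate_biopsy_subset(coh, small_config(biopsy_n = 10000)),
               "exceeds")
})

test_that("cohort and config round-trip through CSV and YAML", {
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  tmp <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, tmp)
  back <- read_cohort_csv(tmp)
  expect_equal(back$latent_iecv, coh$latent_iecv, tolerance = 1e-12)
  expect_identical(back$lge_s1, coh$lge_s1)
  ycfg <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, ycfg)
  cfg2 <- read_config_yaml(ycfg)
  expect_equal(cfg2$stage_probs, cfg$stage_probs, tolerance = 1e-12)
  expect_equal(cfg2$iecv, cfg$iecv, tolerance = 1e-9)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
  unlink(c(tmp, ycfg))
})
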