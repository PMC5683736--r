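test_that("mortality rate is 1000 x deaths / person-years", {
  expect_equal(mortality_rate(2, 250), 8)
  expect_equal(mortality_rate(0, 123.4), 0)
  expect_equal(mortality_rate(14, 1000), 14)
  expect_error(mortality_rate(2, 0), "positive")
  expect_error(mortality_rate(-1, 10), "non-negative")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  # no censoring: empirical survival
  km <- km_fit(1:4, rep(1, 4))
  expect_equal(km$curve$survival, c(0.75, 0.5, 0.25, 0))
  # all censored: S(t) = 1 everywhere
  km0 <- km_fit(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km0$curve), 0)
  expect_equal(km_survival(km0, c(0.5, 2, 10)), c(1, 1, 1))
  # tied deaths with earlier censoring: 1 x (1 - 2/3) = 1/3 at t = 2
  km2 <- km_fit(c(1, 2, 2, 3), c(0, 1, 1, 0))
  expect_equal(km2$curve$survival, 1 / 3)
  expect_equal(km_survival(km2, 2.5), 1 / 3)
  # censoring at an event time: censored subject still at risk (tie convention)
  km3 <- km_fit(c(2, 2, 4), c(1, 0, 1))
  expect_equal(km3$curve$survival, c(2 / 3, 0))
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(101)
  for (i in 1:5) {
    time <- round(rexp(40, 0.3), 2) + 0.01
    event <- rbinom(40, 1, 0.6)
    km <- km_fit(time, event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    ref <- summary(sf, times = km$curve$time)
    expect_equal(km$curve$survival, ref$surv, tolerance = 1e-12)
  }
})

test_that("log-rank: symmetry, df, and error cases", {
  t <- c(1, 2, 3, 4)
  ev <- c(1, 0, 1, 1)
  lr <- logrank_test(c(t, t), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1)
  lr3 <- logrank_test(c(t, t + 0.5, t + 1), c(ev, ev, ev),
                      rep(c("a", "b", "c"), each = 4))
  expect_equal(lr3$df, 2)
  expect_error(logrank_test(t, c(0, 0, 0, 0), c("a", "a", "b", "b")), "censored")
  expect_error(logrank_test(t, ev, rep("a", 4)), "2 non-empty groups")
})

test_that("log-rank agrees with an independent implementation across all relabelings", {
  skip_if_not_installed("survival")
  for (fx in surv_fixtures()) {
    for (g in relabelings_2g(fx$group)) {
      if (sum(fx$event) == 0) next
      mine <- logrank_test(fx$time, fx$event, g)$statistic
      ref <- survdiff_chisq(fx$time, fx$event, g)
      expect_equal(mine, ref, tolerance = 1e-8)
    }
  }
})

test_that("chi-square p is consistent with the exhaustive permutation null", {
  # small-sample check: the permutation p of the statistic and the chi-square
  # tail agree within a documented approximation band
  fx <- surv_fixtures()[[3]]  # n = 10
  obs <- logrank_test(fx$time, fx$event, fx$group)$statistic
  perms <- relabelings_2g(fx$group)
  stats <- vapply(perms, function(g) logrank_test(fx$time, fx$event, g)$statistic,
                  numeric(1))
  p_perm <- mean(stats >= obs - 1e-12)
  p_chisq <- pchisq(obs, 1, lower.tail = FALSE)
  expect_lt(abs(p_perm - p_chisq), 0.15)
})

test_that("time rescaling leaves the log-rank statistic unchanged and scales rates", {
  fx <- surv_fixtures()[[1]]
  a <- logrank_test(fx$time, fx$event, fx$group)
  b <- logrank_test(fx$time * 3.7, fx$event, fx$group)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(mortality_rate(5, 100) / 3.7, mortality_rate(5, 370))
})

test_that("stage_outcomes bookkeeping: person-years, totals, cause-specific", {
  staged <- data.frame(
    stage = rep(c("normal", "expansion", "replacement"), c(71, 31, 37)),
    followup_years = rep(2.5, 139),
    death = c(rep(1, 2), rep(0, 69), rep(1, 4), rep(0, 27), rep(1, 8), rep(0, 29)),
    as_death = c(rep(0, 71), rep(1, 4), rep(0, 27), rep(1, 6), rep(0, 2),
                 rep(0, 29)))
  out <- stage_outcomes(staged)
  expect_equal(out$total_deaths, 14)
  tab <- out$table[match(c("normal", "expansion", "replacement"), out$table$group), ]
  expect_equal(tab$deaths, c(2, 4, 8))
  expect_equal(tab$person_years, c(71, 31, 37) * 2.5)
  expect_equal(tab$rate_per_1000py, 1000 * c(2, 4, 8) / (c(71, 31, 37) * 2.5))
  # no AS-related deaths in the normal group => rate exactly 0
  expect_equal(tab$as_rate_per_1000py[1], 0)
  expect_equal(sum(tab$as_deaths), 10)
})

test_that("zero-member stages are reported with n = 0 and dropped from the test", {
  staged <- data.frame(
    stage = factor(rep(c("normal", "replacement"), each = 10),
                   levels = c("normal", "expansion", "replacement")),
    followup_years = rep(2, 20),
    death = rep(c(0, 1), each = 10))
  out <- stage_outcomes(staged)
  expect_equal(out$table$n[out$table$group == "expansion"], 0)
  expect_equal(out$logrank$df, 1)
})

test_that("KM/rate consistency: -log S(t) / t approximates the hazard", {
  set.seed(404)
  h <- 0.2
  cens <- runif(4000, 3, 6)
  td <- rexp(4000, h)
  time <- pmin(td, cens)
  event <- as.integer(td <= cens)
  km <- km_fit(time, event)
  expect_equal(-log(km_survival(km, 2)) / 2, h, tolerance = 0.1)
  expect_equal(mortality_rate(sum(event), sum(time)) / 1000, h, tolerance = 0.05)
})
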