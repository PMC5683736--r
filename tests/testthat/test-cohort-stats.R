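test_that("group summaries choose the right test and handle degenerate input", {
  set.seed(21)
  d <- data.frame(
    grp = rep(c("a", "b"), each = 40),
    gauss = rnorm(80, 5, 1),
    skewed = rexp(80, 1),
    cat = sample(c("x", "y"), 80, replace = TRUE),
    flat = 1)
  s <- summarize_groups(d, "grp")
  expect_setequal(s$variable, c("gauss", "skewed", "cat", "flat"))
  expect_equal(s$test[s$variable == "gauss"], "Welch t")
  expect_equal(s$test[s$variable == "skewed"], "Mann-Whitney")
  expect_equal(s$test[s$variable == "cat"], "chi-square")
  expect_equal(s$kind[s$variable == "flat"], "constant")
  expect_true(is.na(s$p_value[s$variable == "flat"]))
  # identical groups: exact tests give p = 1
  d2 <- data.frame(grp = rep(c("a", "b"), each = 6),
                   v = rep(c(1, 2, 3, 4, 5, 6), 2))
  s2 <- summarize_groups(d2, "grp", "v")
  expect_equal(s2$p_value, 1, tolerance = 1e-9)
})

test_that("binary prevalence formatting matches half-up integer percent", {
  d <- data.frame(grp = rep("as", 166),
                  midwall = rep(c("yes", "no"), c(44, 122)),
                  ref = rep(c("yes", "no"), c(83, 83)))
  # 44/166 -> 27% with half-up rounding
  expect_equal(round_half_up(100 * 44 / 166), 27)
  s <- summarize_groups(rbind(d, within(d, grp <- "ctl")), "grp", "midwall")
  expect_match(s$as[s$variable == "midwall"], "yes 44 \\(27%\\)")
})

test_that("two-group t test has the configured power on a known alternative", {
  set.seed(33)
  n <- 5000
  delta <- 0.06  # power ~ 0.85 at sd 1: z = delta/sqrt(2/n)*...
  rej <- vapply(1:60, function(i) {
    d <- data.frame(g = rep(c("a", "b"), each = n),
                    v = c(rnorm(n), rnorm(n, delta)))
    summarize_groups(d, "g", "v")$p_value < 0.05
  }, logical(1))
  power <- power.t.test(n = n, delta = delta, sd = 1)$power
  expect_equal(mean(rej), power, tolerance = 3 * sqrt(power * (1 - power) / 60) + 0.02)
})

test_that("tertiles split distinct values into near-equal lower-inclusive groups", {
  d161 <- data.frame(iecv = sample(seq_len(161)))
  t161 <- tertile_stratify(d161, "iecv")
  expect_equal(unname(as.numeric(t161$sizes)), c(54, 54, 53))
  d9 <- data.frame(v = sample(1:9))
  t9 <- tertile_stratify(d9, "v")
  expect_equal(sort(d9$v[t9$assignments == "T1"]), 1:3)
  expect_equal(sort(d9$v[t9$assignments == "T2"]), 4:6)
  expect_equal(sort(d9$v[t9$assignments == "T3"]), 7:9)
  # sizes n, n, n +/- 1 across lengths
  for (n in c(10, 11, 12, 47)) {
    tt <- tertile_stratify(data.frame(v = sample(seq_len(n))), "v")
    expect_lte(diff(range(tt$sizes)), 1)
  }
  expect_warning(tertile_stratify(data.frame(v = rep(3, 12)), "v"), "degenerate")
  expect_error(tertile_stratify(data.frame(v = c(1, 2)), "v"), "at least 3")
})

test_that("correlate matches identities and cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  expect_equal(correlate(x, x)$estimate, 1)
  expect_equal(correlate(x, -x)$estimate, -1)
  y <- c(2.0, 1.1, 3.9, 4.2, 2.8, 0.4)
  mine <- correlate(x, y)
  ref <- cor.test(x, y)
  expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  sp <- correlate(x, y, method = "spearman")
  expect_equal(sp$estimate, unname(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("logistic IRLS matches the 2x2 closed form, glm, and a grid search", {
  # 2x2 table: exposed 30/70 events, unexposed 10/90
  d <- data.frame(x = rep(c(1, 0), each = 100),
                  y = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)))
  fit <- fit_logistic(y ~ x, d)
  or_closed <- (30 * 90) / (70 * 10)
  expect_equal(unname(fit$odds_ratio["x"]), or_closed, tolerance = 1e-6)
  ref <- glm(y ~ x, binomial, d, control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-6)
  # likelihood grid oracle on a small dataset
  set.seed(8)
  ds <- data.frame(x = rnorm(30))
  ds$y <- rbinom(30, 1, plogis(0.5 + 0.8 * ds$x))
  sm <- fit_logistic(y ~ x, ds)
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * ds$x)
    sum(ds$y * log(p) + (1 - ds$y) * log(1 - p))
  }
  grid <- expand.grid(b0 = seq(coef(sm)[1] - 1, coef(sm)[1] + 1, 0.01),
                      b1 = seq(coef(sm)[2] - 1, coef(sm)[2] + 1, 0.01))
  grid_ll <- mapply(ll, grid$b0, grid$b1)
  expect_gte(sm$log_lik + 1e-10, max(grid_ll))
  best <- grid[which.max(grid_ll), ]
  expect_equal(unname(coef(sm)), c(best$b0, best$b1), tolerance = 0.011)
})

test_that("logistic error handling: separation and degenerate designs", {
  sep <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2),
                    y = c(0, 0, 0, 1, 1, 1))
  expect_error(fit_logistic(y ~ x, sep), "separation")
  const <- data.frame(x = rep(1, 20), y = rbinom(20, 1, 0.5))
  expect_error(fit_logistic(y ~ x, const), "rank-deficient")
})

test_that("linear fit: exact recovery, orthogonality, lm agreement", {
  d <- data.frame(x = 1:10)
  d$y <- 2 * d$x + 1
  fit <- fit_linear(y ~ x, d)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  # residuals orthogonal to the design
  set.seed(12)
  d2 <- data.frame(a = rnorm(50), b = rnorm(50))
  d2$y <- 1 + 0.5 * d2$a - 0.3 * d2$b + rnorm(50)
  f2 <- fit_linear(y ~ a + b, d2)
  X <- model.matrix(y ~ a + b, d2)
  expect_lt(max(abs(crossprod(X, residuals(f2)))), 1e-8)
  ref <- lm(y ~ a + b, d2)
  expect_equal(unname(coef(f2)), unname(coef(ref)), tolerance = 1e-9)
  expect_equal(unname(f2$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-9)
  # orthogonal (centred, uncorrelated) predictors reproduce univariable slopes
  a <- c(-1, 1, -1, 1); b <- c(-1, -1, 1, 1)
  d3 <- data.frame(a = a, b = b, y = c(0.2, 1.1, -0.7, 0.9))
  f3 <- fit_linear(y ~ a + b, d3)
  expect_equal(unname(coef(f3)["a"]), unname(coef(fit_linear(y ~ a, d3))["a"]),
               tolerance = 1e-10)
  expect_equal(unname(coef(f3)["b"]), unname(coef(fit_linear(y ~ b, d3))["b"]),
               tolerance = 1e-10)
})
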