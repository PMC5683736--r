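# Shared fixtures and independent oracles for the test suite.

# Build compute_ecv_metrics() arguments that realise a requested ECV fraction
# and LV mass, solving the post-contrast myocardial T1 from the lambda chain
# (independent of the generator's internals).
make_panel_args <- function(ecv = 0.27, hct = 0.41, lv_mass_g = 150,
                            bsa_m2 = 1.9, native = rep(1180, 6),
                            lge = rep("none", 6),
                            blood_native = 1880, blood_post = 450) {
  lambda <- ecv / (1 - hct)
  dr1_blood <- 1 / blood_post - 1 / blood_native
  usable <- lge != "infarct"
  post_mean <- 1 / (lambda * dr1_blood + 1 / mean(native[usable]))
  list(native_t1 = native, post_t1 = rep(post_mean, 6), lge = lge,
       blood_native = blood_native, blood_post = blood_post,
       hematocrit = hct, lv_mass_g = lv_mass_g, bsa_m2 = bsa_m2)
}

# Small right-censored survival fixtures (n <= 10) with ties and censoring.
surv_fixtures <- function() {
  list(
    list(time = c(1, 2, 2, 3, 1.5, 2.5, 3.5, 4),
         event = c(1, 1, 0, 1, 1, 0, 1, 0),
         group = rep(c("a", "b"), each = 4)),
    list(time = c(2, 2, 2, 4, 5, 1, 3, 3),
         event = c(1, 1, 1, 0, 1, 1, 1, 0),
         group = rep(c("a", "b"), each = 4)),
    list(time = c(1, 4, 6, 7, 9, 2, 3, 5, 8, 10),
         event = c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1),
         group = rep(c("a", "b"), each = 5)))
}

# All distinct 2-group relabelings preserving group sizes.
relabelings_2g <- function(group) {
  lv <- unique(group)
  n <- length(group)
  k <- sum(group == lv[1])
  picks <- utils::combn(n, k)
  lapply(seq_len(ncol(picks)), function(j) {
    g <- rep(lv[2], n)
    g[picks[, j]] <- lv[1]
    g
  })
}

# Independent log-rank implementation (survival package) for cross-checks.
survdiff_chisq <- function(time, event, group) {
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  unname(fit$chisq)
}

small_config <- function(seed = 42, ...) {
  fibrostage::cohort_config(n_controls = 20, n_as = 60, seed = seed, ...)
}
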