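GEN_GROUPS <- c("control", STAGE_LEVELS)  # parameter groups for the generator

#' Build a synthetic-cohort configuration
#'
#' Returns the generator configuration, defaulting to the study conditions the
#' package emulates: a 37-control / 166-patient two-arm cohort, latent fibrosis
#' stages mixed as 71/31/37 classifiable patients plus 22 infarct-LGE
#' exclusions and 5 with incomplete T1 data, stage-wise iECV of 18.3 +/- 2.5,
#' 25.4 +/- 3.1 and 30.4 +/- 8.2 ml/m^2 (controls 16.1 +/- 3.2), stage-wise
#' all-cause hazards of 0.008/0.036/0.071 events per person-year, uniform
#' administrative censoring over 1.3-4.5 years (mean 2.9), and an 11-subject
#' biopsy subset whose histology link reproduces the 8.9/12.4/22.4 percent
#' stage means and an iECV-histology correlation in the 0.87 regime.
#'
#' Latent normal-stage iECV is truncated below the 22.5 ml/m^2 anchor and
#' expansion-stage iECV above it, so noise-free staging can recover the latent
#' stage exactly. The iECV mean of the infarct-excluded group is solved at
#' config-build time (closed-form truncated-normal means) so the population
#' mean over all AS patients with computable metrics equals `target_as_mean`.
#'
#' @param n_controls,n_as arm sizes.
#' @param seed master integer seed; per-subject streams are derived from it.
#' @param stage_probs named probabilities over latent stages
#'   (normal/expansion/replacement/excluded_infarct/unclassified); must sum
#'   to 1. The unclassified probability is the missing-T1 rate and the
#'   excluded_infarct probability the infarct-LGE rate.
#' @param severity_mix marginal mild/moderate/severe mix (sums to 1).
#' @param threshold_anchor iECV truncation boundary between latent normal and
#'   expansion stages (ml/m^2).
#' @param target_as_mean population mean iECV over AS patients with computable
#'   metrics, used to calibrate the excluded-group mean.
#' @param stage_hazards named all-cause hazards (events/person-year) per
#'   latent stage; `control_hazard` for the control arm.
#' @param control_hazard control-arm hazard.
#' @param followup_window min/max of the uniform censoring window (years).
#' @param biopsy_n size of the biopsy subset.
#' @param biopsy_link list with `intercept`, `slope`, `noise_sd` mapping iECV
#'   (ml/m^2) to histological percent fibrosis.
#' @param ... overrides for the remaining distribution blocks (`iecv`, `ecv`,
#'   `hct`, `native_t1`, `blood_native`, `blood_post`, `seg_jitter_native`,
#'   `seg_jitter_post`, `age`, `sex_male_prob`, `height_male`, `height_female`,
#'   `bmi_control`, `bmi_as`, `edvi`, `ln_tni`, `ln_bnp`, `walk`,
#'   `severity_by_stage`, `p_as_death`, `density`); see the package vignette
#'   for their meaning.
#' @return list of class `"cohort_config"` (validated).
#' @export
cohort_config <- function(n_controls = 37, n_as = 166, seed = 20260101,
                          stage_probs = c(normal = 71, expansion = 31,
                                          replacement = 37,
                                          excluded_infarct = 22,
                                          unclassified = 5) / 166,
                          severity_mix = c(mild = 34, moderate = 45,
                                           severe = 87) / 166,
                          threshold_anchor = 22.5,
                          target_as_mean = 23.6,
                          stage_hazards = c(normal = 0.008, expansion = 0.036,
                                            replacement = 0.071,
                                            excluded_infarct = 0.030,
                                            unclassified = 0.030),
                          control_hazard = 0.005,
                          followup_window = c(1.3, 4.5),
                          biopsy_n = 11,
                          biopsy_link = list(intercept = 1.015, slope = 0.4326,
                                             noise_sd = 1.76),
                          ...) {
  # (mean, sd, lower, upper) rows per generator group
  dist4 <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("mean", "sd", "lower", "upper")
    m
  }
  cfg <- list(
    n_controls = n_controls, n_as = n_as, seed = seed,
    stage_probs = stage_probs, severity_mix = severity_mix,
    threshold_anchor = threshold_anchor, target_as_mean = target_as_mean,
    stage_hazards = stage_hazards, control_hazard = control_hazard,
    followup_window = followup_window,
    biopsy_n = biopsy_n, biopsy_link = biopsy_link,
    density = 1.05,
    # iECV (ml/m^2); excluded/unclassified mean NA = solve from target_as_mean
    iecv = dist4(control = c(16.1, 3.2, 5, Inf),
                 normal = c(18.3, 2.5, 5, threshold_anchor),
                 expansion = c(25.4, 3.1, threshold_anchor, Inf),
                 replacement = c(30.4, 8.2, 5, Inf),
                 excluded_infarct = c(NA, 7.0, 5, Inf),
                 unclassified = c(NA, 7.0, 5, Inf)),
    # ECV fraction; LV mass index follows as iECV * density / ECV
    ecv = dist4(control = c(0.265, 0.013, 0.15, 0.45),
                normal = c(0.265, 0.015, 0.15, 0.45),
                expansion = c(0.275, 0.020, 0.15, 0.45),
                replacement = c(0.291, 0.024, 0.15, 0.45),
                excluded_infarct = c(0.280, 0.025, 0.15, 0.45),
                unclassified = c(0.280, 0.025, 0.15, 0.45)),
    hct = c(mean = 0.41, sd = 0.03, lower = 0.25, upper = 0.55),
    native_t1 = dist4(control = c(1166, 27, 1000, 1450),
                      normal = c(1170, 35, 1000, 1450),
                      expansion = c(1185, 35, 1000, 1450),
                      replacement = c(1230, 45, 1000, 1450),
                      excluded_infarct = c(1190, 40, 1000, 1450),
                      unclassified = c(1190, 40, 1000, 1450)),
    blood_native = c(mean = 1880, sd = 90, lower = 1500, upper = 2300),
    blood_post = c(mean = 450, sd = 40, lower = 300, upper = 620),
    seg_jitter_native = 25, seg_jitter_post = 15,
    age = c(mean = 70, sd = 8, lower = 45, upper = 95),
    sex_male_prob = c(control = 0.65, normal = 0.56, expansion = 0.81,
                      replacement = 0.76, excluded_infarct = 0.69,
                      unclassified = 0.69),
    height_male = c(mean = 175, sd = 7, lower = 150, upper = 200),
    height_female = c(mean = 162, sd = 7, lower = 140, upper = 190),
    bmi_control = c(mean = 27.0, sd = 3.6, lower = 16, upper = 50),
    bmi_as = c(mean = 28.9, sd = 4.8, lower = 16, upper = 50),
    edvi = c(mean = 69, sd = 12, lower = 35, upper = 130),
    ln_tni = rbind(control = c(mean = 1.13, sd = 0.80),
                   normal = c(1.43, 0.96), expansion = c(2.02, 0.93),
                   replacement = c(2.60, 0.90),
                   excluded_infarct = c(2.16, 0.90),
                   unclassified = c(2.16, 0.90)),
    ln_bnp = rbind(control = c(mean = 2.25, sd = 0.90),
                   normal = c(2.95, 1.00), expansion = c(3.06, 0.96),
                   replacement = c(3.41, 1.10),
                   excluded_infarct = c(3.20, 1.00),
                   unclassified = c(3.20, 1.00)),
    walk = dist4(control = c(430, 60, 50, 700),
                 normal = c(406, 74, 50, 700),
                 expansion = c(385, 95, 50, 700),
                 replacement = c(359, 138, 50, 700),
                 excluded_infarct = c(380, 120, 50, 700),
                 unclassified = c(380, 120, 50, 700)),
    # severity given latent stage; excluded/unclassified get the residual mix
    severity_by_stage = rbind(normal = c(24, 18, 29) / 71,
                              expansion = c(7, 10, 14) / 31,
                              replacement = c(2, 11, 24) / 37,
                              excluded_infarct = c(1, 6, 20) / 27,
                              unclassified = c(1, 6, 20) / 27),
    # probability a death is AS-related, given death, per latent stage
    p_as_death = c(normal = 0, expansion = 1, replacement = 0.75,
                   excluded_infarct = 0.5, unclassified = 0.5))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  colnames(cfg$severity_by_stage) <- c("mild", "moderate", "severe")
  cfg <- calibrate_excluded_iecv(cfg)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

# Solve the infarct-excluded iECV mean so the population mean over AS patients
# with computable metrics (classifiable + infarct-excluded) hits target_as_mean.
calibrate_excluded_iecv <- function(cfg) {
  iv <- cfg$iecv
  if (!is.na(iv["excluded_infarct", "mean"])) {
    if (is.na(iv["unclassified", "mean"])) {
      cfg$iecv["unclassified", "mean"] <- iv["excluded_infarct", "mean"]
    }
    return(cfg)
  }
  p <- cfg$stage_probs
  tmean <- function(g) etnorm(iv[g, "mean"], iv[g, "sd"], iv[g, "lower"], iv[g, "upper"])
  cls <- c("normal", "expansion", "replacement")
  p_avail <- sum(p[cls]) + p[["excluded_infarct"]]
  if (p[["excluded_infarct"]] <= 0 || p_avail <= 0) {
    # no excluded group to calibrate; its (unused) parameters default to target
    cfg$iecv["excluded_infarct", "mean"] <- cfg$target_as_mean
    cfg$iecv["unclassified", "mean"] <- cfg$target_as_mean
    return(cfg)
  }
  mix_cls <- sum(p[cls] * vapply(cls, tmean, numeric(1)))
  target_sum <- cfg$target_as_mean * p_avail
  # invert the truncated-normal mean in the untruncated parameter by bisection
  want <- (target_sum - mix_cls) / p[["excluded_infarct"]]
  g <- "excluded_infarct"
  f <- function(mu) etnorm(mu, iv[g, "sd"], iv[g, "lower"], iv[g, "upper"]) - want
  mu <- stats::uniroot(f, c(want - 20, want + 20), tol = 1e-10)$root
  cfg$iecv["excluded_infarct", "mean"] <- mu
  cfg$iecv["unclassified", "mean"] <- mu
  cfg
}

#' Validate a cohort configuration
#'
#' @param cfg a configuration list as built by [cohort_config()].
#' @return the config, invisibly; errors on any violated invariant
#'   (probabilities outside \[0,1\] or not summing to 1, negative SDs or
#'   hazards, non-finite values).
#' @export
validate_cohort_config <- function(cfg) {
  chk_num <- function(x, what, allow_inf = FALSE) {
    x <- unlist(x)
    bad <- if (allow_inf) is.na(x) | is.nan(x) else !is.finite(x)
    if (any(bad)) stop("config validation: non-finite value in ", what, call. = FALSE)
  }
  if (cfg$n_controls < 0 || cfg$n_as < 0) {
    stop("config validation: arm sizes must be non-negative", call. = FALSE)
  }
  chk_num(cfg$seed, "seed")
  for (p in list(cfg$stage_probs, cfg$severity_mix)) {
    chk_num(p, "probabilities")
    if (any(p < 0 | p > 1)) stop("config validation: proportions must lie in [0,1]", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9) stop("config validation: proportions must sum to 1", call. = FALSE)
  }
  chk_num(cfg$severity_by_stage, "severity_by_stage")
  if (any(abs(rowSums(cfg$severity_by_stage) - 1) > 1e-9)) {
    stop("config validation: severity_by_stage rows must sum to 1", call. = FALSE)
  }
  chk_num(c(cfg$stage_hazards, cfg$control_hazard), "hazards")
  if (any(c(cfg$stage_hazards, cfg$control_hazard) < 0)) {
    stop("config validation: hazards must be non-negative", call. = FALSE)
  }
  for (blk in c("iecv", "ecv", "native_t1", "walk")) {
    m <- cfg[[blk]]
    chk_num(m[, c("mean", "sd")], blk)
    if (any(m[, "sd"] < 0)) stop("config validation: negative SD in ", blk, call. = FALSE)
  }
  for (blk in c("hct", "blood_native", "blood_post", "age", "height_male",
                "height_female", "bmi_control", "bmi_as", "edvi")) {
    chk_num(cfg[[blk]][c("mean", "sd")], blk)
    if (cfg[[blk]][["sd"]] < 0) stop("config validation: negative SD in ", blk, call. = FALSE)
  }
  chk_num(unlist(cfg$biopsy_link), "biopsy_link")
  if (cfg$biopsy_link$noise_sd < 0) {
    stop("config validation: biopsy noise SD must be non-negative", call. = FALSE)
  }
  chk_num(cfg$followup_window, "followup_window")
  if (cfg$followup_window[1] < 0 || diff(cfg$followup_window) < 0) {
    stop("config validation: follow-up window must be 0 <= min <= max", call. = FALSE)
  }
  if (any(cfg$p_as_death < 0 | cfg$p_as_death > 1) ||
      any(cfg$sex_male_prob < 0 | cfg$sex_male_prob > 1)) {
    stop("config validation: probabilities must lie in [0,1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic AS cohort config: %d controls + %d AS patients, seed %d\n",
              x$n_controls, x$n_as, x$seed))
  cat("  stage mix:", paste(sprintf("%s %.3f", names(x$stage_probs), x$stage_probs),
                            collapse = ", "), "\n")
  cat(sprintf("  hazards /py: %s; censoring U(%.1f, %.1f) yrs\n",
              paste(sprintf("%.3f", x$stage_hazards), collapse = "/"),
              x$followup_window[1], x$followup_window[2]))
  invisible(x)
}

cohort_columns <- function() {
  c("subject_id", "arm", "severity", "latent_stage", "latent_iecv",
    "age", "sex", "height_cm", "weight_kg", "hematocrit", "lvmi_g_m2",
    "edvi_ml_m2",
    paste0("native_t1_s", 1:6), paste0("post_t1_s", 1:6), paste0("lge_s", 1:6),
    "blood_native_t1", "blood_post_t1",
    "hs_ctni_ng_l", "bnp_pg_ml", "walk_6min_m",
    "followup_years", "death", "as_death")
}

# One subject record from the group-specific parameter rows.
generate_subject <- function(cfg, id, arm, stage) {
  g <- if (arm == "control") "control" else stage
  severity <- if (arm == "control") NA_character_ else {
    sample(c("mild", "moderate", "severe"), 1, prob = cfg$severity_by_stage[stage, ])
  }
  sex <- if (stats::runif(1) < cfg$sex_male_prob[[g]]) "male" else "female"
  age <- rtnorm(1, cfg$age[["mean"]], cfg$age[["sd"]], cfg$age[["lower"]], cfg$age[["upper"]])
  hpar <- if (sex == "male") cfg$height_male else cfg$height_female
  height <- rtnorm(1, hpar[["mean"]], hpar[["sd"]], hpar[["lower"]], hpar[["upper"]])
  bpar <- if (arm == "control") cfg$bmi_control else cfg$bmi_as
  bmi <- rtnorm(1, bpar[["mean"]], bpar[["sd"]], bpar[["lower"]], bpar[["upper"]])
  weight <- bmi * (height / 100)^2
  hct <- rtnorm(1, cfg$hct[["mean"]], cfg$hct[["sd"]], cfg$hct[["lower"]], cfg$hct[["upper"]])
  iv <- cfg$iecv[g, ]
  iecv <- rtnorm(1, iv[["mean"]], iv[["sd"]], iv[["lower"]], iv[["upper"]])
  ev <- cfg$ecv[g, ]
  ecv <- rtnorm(1, ev[["mean"]], ev[["sd"]], ev[["lower"]], ev[["upper"]])
  lvmi <- iecv * cfg$density / ecv
  lambda <- ecv / (1 - hct)
  bn <- rtnorm(1, cfg$blood_native[["mean"]], cfg$blood_native[["sd"]],
               cfg$blood_native[["lower"]], cfg$blood_native[["upper"]])
  bp <- rtnorm(1, cfg$blood_post[["mean"]], cfg$blood_post[["sd"]],
               cfg$blood_post[["lower"]], cfg$blood_post[["upper"]])
  tv <- cfg$native_t1[g, ]
  nat_mean <- rtnorm(1, tv[["mean"]], tv[["sd"]], tv[["lower"]], tv[["upper"]])
  lge <- rep("none", 6)
  if (arm == "as" && stage == "replacement") {
    k <- 1 + stats::rbinom(1, 4, 0.3)
    lge[sample.int(6, k)] <- "midwall"
  } else if (arm == "as" && stage == "excluded_infarct") {
    k <- 1 + stats::rbinom(1, 2, 0.5)
    lge[sample.int(6, k)] <- "infarct"
  }
  usable <- which(lge != "infarct")
  jn <- stats::rnorm(6, 0, cfg$seg_jitter_native)
  native <- nat_mean + jn - mean(jn[usable])  # usable-segment mean is exact
  dr1_blood <- 1 / bp - 1 / bn
  post_mean <- 1 / (lambda * dr1_blood + 1 / mean(native[usable]))
  jp <- stats::rnorm(6, 0, cfg$seg_jitter_post)
  post <- post_mean + jp - mean(jp[usable])
  if (arm == "as" && stage == "unclassified") post <- rep(NA_real_, 6)
  tni <- exp(stats::rnorm(1, cfg$ln_tni[g, "mean"], cfg$ln_tni[g, "sd"]))
  bnp <- exp(stats::rnorm(1, cfg$ln_bnp[g, "mean"], cfg$ln_bnp[g, "sd"]))
  wk <- cfg$walk[g, ]
  walk <- rtnorm(1, wk[["mean"]], wk[["sd"]], wk[["lower"]], wk[["upper"]])
  edvi <- rtnorm(1, cfg$edvi[["mean"]], cfg$edvi[["sd"]], cfg$edvi[["lower"]],
                 cfg$edvi[["upper"]])
  haz <- if (arm == "control") cfg$control_hazard else cfg$stage_hazards[[stage]]
  cens <- stats::runif(1, cfg$followup_window[1], cfg$followup_window[2])
  t_death <- if (haz > 0) stats::rexp(1, haz) else Inf
  death <- as.integer(t_death <= cens)
  p_as <- if (arm == "control") 0 else cfg$p_as_death[[stage]]
  as_death <- as.integer(death == 1L && stats::runif(1) < p_as)
  rec <- data.frame(
    subject_id = id, arm = arm, severity = severity,
    latent_stage = if (arm == "control") NA_character_ else stage,
    latent_iecv = iecv, age = age, sex = sex, height_cm = height,
    weight_kg = weight, hematocrit = hct, lvmi_g_m2 = lvmi,
    edvi_ml_m2 = edvi, stringsAsFactors = FALSE)
  rec[paste0("native_t1_s", 1:6)] <- as.list(native)
  rec[paste0("post_t1_s", 1:6)] <- as.list(post)
  rec[paste0("lge_s", 1:6)] <- as.list(lge)
  rec$blood_native_t1 <- bn
  rec$blood_post_t1 <- bp
  rec$hs_ctni_ng_l <- tni
  rec$bnp_pg_ml <- bnp
  rec$walk_6min_m <- walk
  rec$followup_years <- min(t_death, cens)
  rec$death <- death
  rec$as_death <- as_death
  rec[cohort_columns()]
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n_controls` healthy volunteers and `n_as` aortic-stenosis patients.
#' For each AS patient a latent fibrosis stage is drawn first, then a
#' segmental T1 panel, haematocrit, LV mass and body-size inputs consistent
#' with that stage, so that [compute_ecv_metrics()] recovers the latent iECV
#' to float precision and [fibrosis_staging()] can recover the latent stage.
#' Follow-up is exponential event times under the stage hazard with uniform
#' administrative censoring. Controls carry no LGE and are drawn from the
#' control distribution. Identical config (including seed) gives an identical
#' table; per-subject random streams are derived from the master seed.
#'
#' @param config a [cohort_config()] object.
#' @return data frame, one row per subject, columns as in `cohort_columns()`:
#'   identifiers and arm, demographics, haematocrit, LV mass index, six
#'   native/post T1 segment pairs with per-segment LGE flags
#'   (none/midwall/infarct), blood-pool T1 pair, biomarkers, 6-min walk,
#'   follow-up years and death/AS-death indicators, plus the latent stage and
#'   latent iECV used to generate the record.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_controls = 5, n_as = 10, seed = 1))
#' nrow(cohort)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_controls + config$n_as
  if (n == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cohort_columns())))
    names(out) <- cohort_columns()
    return(out)
  }
  set.seed(config$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, n)
  stages <- if (config$n_as > 0) {
    sample(STAGE_LEVELS, config$n_as, replace = TRUE, prob = config$stage_probs)
  } else character(0)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subseeds[i])
    if (i <= config$n_controls) {
      rows[[i]] <- generate_subject(config, sprintf("HV%04d", i), "control", NA)
    } else {
      j <- i - config$n_controls
      rows[[i]] <- generate_subject(config, sprintf("AS%04d", j), "as", stages[j])
    }
  }
  do.call(rbind, rows)
}

#' Sample a biopsy subset with linked histological fibrosis
#'
#' Samples `biopsy_n` AS patients and assigns each a histological
#' percent-fibrosis value through the linear link
#' `intercept + slope * iECV + Normal(0, noise_sd)`, truncated to \[0, 100\].
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param config the [cohort_config()] used (supplies `biopsy_n`,
#'   `biopsy_link` and the seed).
#' @return data frame with `subject_id`, `iecv_ml_m2` (latent), and
#'   `fibrosis_pct`.
#' @export
generate_biopsy_subset <- function(cohort, config) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  as_rows <- which(cohort$arm == "as")
  if (config$biopsy_n > length(as_rows)) {
    stop("biopsy_n exceeds the number of AS patients", call. = FALSE)
  }
  set.seed((config$seed + 777) %% (.Machine$integer.max - 1L))
  pick <- sample(as_rows, config$biopsy_n)
  iecv <- cohort$latent_iecv[pick]
  lk <- config$biopsy_link
  fib <- lk$intercept + lk$slope * iecv + stats::rnorm(length(pick), 0, lk$noise_sd)
  fib <- pmin(pmax(fib, 0), 100)
  data.frame(subject_id = cohort$subject_id[pick], iecv_ml_m2 = iecv,
             fibrosis_pct = fib, stringsAsFactors = FALSE)
}

#' Population iECV-histology correlation implied by the biopsy link
#'
#' Closed form for the Pearson correlation between iECV and percent fibrosis
#' under the linear link with Gaussian noise:
#' `r = slope * sd_iecv / sqrt(slope^2 sd_iecv^2 + noise_sd^2)` (truncation at
#' 0/100 ignored; it essentially never binds at the default calibration).
#'
#' @param sd_iecv SD of iECV in the sampled population (ml/m^2).
#' @param link the `biopsy_link` list (`slope`, `noise_sd`).
#' @return the implied population correlation.
#' @export
biopsy_link_correlation <- function(sd_iecv, link) {
  s <- link$slope * sd_iecv
  s / sqrt(s^2 + link$noise_sd^2)
}

#' Write / read a cohort CSV
#'
#' Plain-CSV serialisation of the documented cohort schema.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @return `write_cohort_csv` the path invisibly; `read_cohort_csv` the
#'   cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (cc in names(out)) {
    if (is.double(out[[cc]])) {
      # 17 significant digits: doubles survive the CSV round trip exactly
      v <- formatC(out[[cc]], digits = 17, format = "g")
      v[is.na(out[[cc]])] <- NA
      out[[cc]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(cohort_columns(), names(df))
  if (length(miss)) {
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write / read a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @return `write_config_yaml` the path invisibly; `read_config_yaml` a
#'   validated `cohort_config`.
#' @export
write_config_yaml <- function(config, path) {
  plain <- lapply(unclass(config), function(x) {
    if (is.matrix(x)) {
      apply(x, 1, as.list, simplify = FALSE)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)  # named vectors must become YAML maps to keep their names
    } else x
  })
  yaml::write_yaml(plain, path, precision = 17)  # exact double round-trip
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- cohort_config()
  for (nm in names(raw)) {
    if (is.matrix(base[[nm]])) {
      m <- do.call(rbind, lapply(raw[[nm]], function(r) unlist(r)))
      rownames(m) <- names(raw[[nm]])
      raw[[nm]] <- m
    } else if (is.list(base[[nm]]) && nm != "biopsy_link") {
      raw[[nm]] <- unlist(raw[[nm]])
    } else if (!is.null(names(base[[nm]])) && !is.list(base[[nm]])) {
      raw[[nm]] <- unlist(raw[[nm]])
    }
  }
  cfg <- unclass(cohort_config())
  cfg[names(raw)] <- raw
  cfg <- calibrate_excluded_iecv(cfg)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}
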