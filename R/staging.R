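STAGE_LEVELS <- c("normal", "expansion", "replacement",
                  "excluded_infarct", "unclassified")
CLASSIFIED_STAGES <- c("normal", "expansion", "replacement")

#' Construct an iECV upper-limit-of-normal threshold
#'
#' The reference-range rule: threshold = control mean + 2 x control SD. With
#' the healthy-volunteer statistics (mean 16.1, SD 3.2 ml/m^2) this gives the
#' 22.5 ml/m^2 upper limit of normal used to define extracellular expansion.
#'
#' @param control_mean,control_sd mean and SD of control iECV (ml/m^2).
#' @param n_controls number of control subjects the statistics came from.
#' @param k SD multiplier (default 2).
#' @return object of class `"iecv_threshold"`.
#' @export
iecv_threshold <- function(control_mean, control_sd, n_controls, k = 2) {
  stopifnot_finite(c(control_mean, control_sd, k), "threshold inputs")
  if (control_sd < 0) stop("control_sd must be non-negative", call. = FALSE)
  if (n_controls < 2) stop("need at least 2 control subjects", call. = FALSE)
  structure(
    list(control_mean = control_mean, control_sd = control_sd,
         k = k, threshold = control_mean + k * control_sd,
         n_controls = as.integer(n_controls)),
    class = "iecv_threshold")
}

#' Derive the iECV threshold from control values
#'
#' Computes the control mean and sample SD (n - 1 denominator) and returns the
#' mean + 2 SD upper limit of normal.
#'
#' @param control_iecvs numeric vector of control iECV values (ml/m^2), at
#'   least 2 finite values.
#' @param k SD multiplier (default 2).
#' @return object of class `"iecv_threshold"`.
#' @export
derive_iecv_threshold <- function(control_iecvs, k = 2) {
  x <- control_iecvs[is.finite(control_iecvs)]
  if (length(x) < 2) {
    stop("need at least 2 finite control iECV values", call. = FALSE)
  }
  iecv_threshold(mean(x), stats::sd(x), length(x), k = k)
}

#' @export
print.iecv_threshold <- function(x, ...) {
  cat(sprintf(
    "iECV upper limit of normal: %.1f ml/m2 (control mean %.1f + %g SD x %.1f, n = %d)\n",
    x$threshold, x$control_mean, x$k, x$control_sd, x$n_controls))
  invisible(x)
}

#' Classify a subject into a fibrosis stage
#'
#' The staging hierarchy: infarct-pattern LGE anywhere excludes the patient
#' from the diffuse-fibrosis analysis; unavailable metrics leave the patient
#' unclassified; mid-wall LGE defines replacement fibrosis regardless of iECV;
#' otherwise iECV at or above the threshold is extracellular expansion and
#' below it normal myocardium.
#'
#' @param iecv subject iECV (ml/m^2), or `NA` when metrics are unavailable.
#' @param lge_status patient-level LGE pattern: `"none"`, `"midwall"` or
#'   `"infarct"`.
#' @param threshold an [iecv_threshold()] object or a single numeric threshold.
#' @return factor with levels normal, expansion, replacement,
#'   excluded_infarct, unclassified; vectorised over `iecv`/`lge_status`.
#' @export
classify_stage <- function(iecv, lge_status, threshold) {
  thr <- if (inherits(threshold, "iecv_threshold")) threshold$threshold else threshold
  if (!is.finite(thr)) stop("threshold must be finite", call. = FALSE)
  lge_status <- as.character(lge_status)
  n <- max(length(iecv), length(lge_status))
  iecv <- rep_len(iecv, n)
  lge_status <- rep_len(lge_status, n)
  out <- character(n)
  out[lge_status == "infarct"] <- "excluded_infarct"
  rest <- lge_status != "infarct"
  out[rest & !is.finite(iecv)] <- "unclassified"
  rest <- rest & is.finite(iecv)
  out[rest & lge_status == "midwall"] <- "replacement"
  rest <- rest & lge_status != "midwall"
  out[rest & iecv >= thr] <- "expansion"
  out[rest & iecv < thr] <- "normal"
  factor(out, levels = STAGE_LEVELS)
}

#' Stage counts and proportions
#'
#' Tabulates the three classifiable stages and reports integer-rounded
#' percentages among classifiable patients, with exclusions tallied separately.
#'
#' @param stages factor/character vector of stages as from [classify_stage()].
#' @return list with `counts`, `proportions_pct` (half-up integer percent of
#'   the classifiable denominator), `n_classifiable`, `exclusions`.
#' @export
stage_table <- function(stages) {
  stages <- factor(as.character(stages), levels = STAGE_LEVELS)
  counts <- table(stages)[CLASSIFIED_STAGES]
  excl <- table(stages)[c("excluded_infarct", "unclassified")]
  n_class <- sum(counts)
  props <- if (n_class > 0) {
    round_half_up(100 * as.numeric(counts) / n_class)
  } else {
    warning("no classifiable subjects; proportions undefined", call. = FALSE)
    rep(NA_real_, length(counts))
  }
  names(props) <- CLASSIFIED_STAGES
  list(counts = counts, proportions_pct = props,
       n_classifiable = n_class, exclusions = excl)
}

#' Fit the control-anchored fibrosis staging model to a cohort
#'
#' The central estimator of the package. Computes per-subject ECV metrics from
#' the segmental T1 panels, derives the iECV upper limit of normal from the
#' healthy-control arm (mean + 2 SD), and classifies every aortic-stenosis
#' patient into normal myocardium, extracellular expansion, or replacement
#' fibrosis, with infarct-pattern LGE and incomplete T1 data handled as
#' exclusions. Controls are never staged.
#'
#' @param cohort cohort data frame in the package schema (see
#'   [generate_cohort()]); must contain an `arm` column with values
#'   `"control"`/`"as"`.
#' @param threshold optional fixed threshold (numeric or [iecv_threshold()]);
#'   when `NULL` the threshold is derived from the control arm.
#' @param k SD multiplier for a derived threshold.
#' @param density myocardial density (g/ml) for the mass-to-volume conversion.
#' @return object of class `"fibrosis_staging"` with components `threshold`,
#'   `metrics` (per-subject metric table), `staged` (AS patients with their
#'   stage), `table` (counts/proportions from [stage_table()]) and `call`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' cfg <- cohort_config(n_controls = 30, n_as = 120, seed = 7)
#' fit <- fibrosis_staging(generate_cohort(cfg))
#' fit
#' coef(fit)
#' @export
fibrosis_staging <- function(cohort, threshold = NULL, k = 2, density = 1.05) {
  cl <- match.call()
  if (!"arm" %in% names(cohort)) stop("cohort must have an 'arm' column", call. = FALSE)
  metrics <- compute_cohort_metrics(cohort, density = density)
  if (is.null(threshold)) {
    ctrl <- metrics$iecv_ml_m2[metrics$arm == "control"]
    threshold <- derive_iecv_threshold(ctrl, k = k)
  } else if (!inherits(threshold, "iecv_threshold")) {
    if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
      stop("threshold must be a single finite number or an iecv_threshold", call. = FALSE)
    }
    threshold <- structure(
      list(control_mean = NA_real_, control_sd = NA_real_, k = k,
           threshold = threshold, n_controls = NA_integer_),
      class = "iecv_threshold")
  }
  as_idx <- metrics$arm == "as"
  staged <- metrics[as_idx, , drop = FALSE]
  keep <- intersect(c("followup_years", "death", "as_death", "severity",
                      "latent_stage"), names(cohort))
  if (length(keep)) staged <- cbind(staged, cohort[as_idx, keep, drop = FALSE])
  staged$stage <- classify_stage(staged$iecv_ml_m2, staged$patient_lge, threshold)
  structure(
    list(call = cl, threshold = threshold, metrics = metrics, staged = staged,
         table = if (nrow(staged)) stage_table(staged$stage) else NULL,
         n_controls = sum(metrics$arm == "control"), n_as = sum(as_idx)),
    class = "fibrosis_staging")
}

#' @export
print.fibrosis_staging <- function(x, ...) {
  cat("Fibrosis staging of", x$n_as, "AS patients against",
      x$n_controls, "controls\n")
  print(x$threshold)
  if (is.null(x$table)) {
    cat("No AS patients to stage.\n")
    return(invisible(x))
  }
  tb <- x$table
  cat(sprintf("  normal myocardium      %4d (%s%%)\n  extracellular expansion%4d (%s%%)\n  replacement fibrosis   %4d (%s%%)\n",
              tb$counts[["normal"]], format(tb$proportions_pct[["normal"]]),
              tb$counts[["expansion"]], format(tb$proportions_pct[["expansion"]]),
              tb$counts[["replacement"]], format(tb$proportions_pct[["replacement"]])))
  cat(sprintf("  excluded: infarct LGE n = %d, incomplete T1 n = %d\n",
              tb$exclusions[["excluded_infarct"]], tb$exclusions[["unclassified"]]))
  invisible(x)
}

#' @export
coef.fibrosis_staging <- function(object, ...) {
  th <- object$threshold
  c(control_mean = th$control_mean, control_sd = th$control_sd,
    threshold = th$threshold)
}

#' @rdname fibrosis_staging
#' @param object,x a `fibrosis_staging` fit.
#' @param newdata cohort data frame of new subjects to classify with the
#'   fitted threshold.
#' @param ... unused.
#' @export
predict.fibrosis_staging <- function(object, newdata, ...) {
  m <- compute_cohort_metrics(newdata)
  classify_stage(m$iecv_ml_m2, m$patient_lge, object$threshold)
}

#' @rdname fibrosis_staging
#' @export
summary.fibrosis_staging <- function(object, ...) {
  st <- object$staged
  by_stage <- NULL
  if (!is.null(st) && nrow(st)) {
    cls <- st[st$stage %in% CLASSIFIED_STAGES, ]
    by_stage <- do.call(rbind, lapply(CLASSIFIED_STAGES, function(s) {
      v <- cls$iecv_ml_m2[cls$stage == s]
      data.frame(stage = s, n = length(v),
                 iecv_mean = if (length(v)) mean(v) else NA_real_,
                 iecv_sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))
  }
  outcomes <- NULL
  if (!is.null(st) && all(c("followup_years", "death") %in% names(st))) {
    cls <- st[st$stage %in% CLASSIFIED_STAGES, ]
    cls$stage <- factor(as.character(cls$stage), levels = CLASSIFIED_STAGES)
    if (nrow(cls) && sum(cls$death) > 0) {
      outcomes <- stage_outcomes(cls)
    }
  }
  structure(list(fit = object, by_stage = by_stage, outcomes = outcomes),
            class = "summary.fibrosis_staging")
}

#' @export
print.summary.fibrosis_staging <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$by_stage)) {
    cat("\nStage-wise iECV (ml/m2):\n")
    bs <- x$by_stage
    for (i in seq_len(nrow(bs))) {
      cat(sprintf("  %-12s n = %3d  %.1f +/- %.1f\n", bs$stage[i], bs$n[i],
                  bs$iecv_mean[i], bs$iecv_sd[i]))
    }
  }
  if (!is.null(x$outcomes)) {
    cat("\n")
    print(x$outcomes)
  }
  invisible(x)
}

#' @rdname fibrosis_staging
#' @export
plot.fibrosis_staging <- function(x, ...) {
  st <- x$staged
  if (is.null(st) || !all(c("followup_years", "death") %in% names(st))) {
    stop("no follow-up data to plot", call. = FALSE)
  }
  cls <- st[st$stage %in% CLASSIFIED_STAGES, ]
  cols <- c(normal = "forestgreen", expansion = "orange", replacement = "firebrick")
  graphics::plot(NULL, xlim = c(0, max(cls$followup_years)), ylim = c(0, 1),
                 xlab = "Years of follow-up", ylab = "Survival",
                 main = "All-cause mortality by fibrosis stage", ...)
  for (s in CLASSIFIED_STAGES) {
    g <- cls[cls$stage == s, ]
    if (!nrow(g)) next
    km <- km_fit(g$followup_years, g$death)
    graphics::lines(c(0, km$curve$time, max(g$followup_years)),
                    c(1, km$curve$survival, min(c(1, km$curve$survival))),
                    type = "s", col = cols[[s]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = CLASSIFIED_STAGES,
                   col = cols[CLASSIFIED_STAGES], lwd = 2, bty = "n")
  invisible(x)
}
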