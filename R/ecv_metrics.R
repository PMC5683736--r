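#' Body surface area by the Du Bois formula
#'
#' BSA = 0.007184 * weight^0.425 * height^0.725, with height in centimetres and
#' weight in kilograms. Used throughout to index LV mass and extracellular
#' volume to body size.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @return body surface area in m^2; vectorised over both arguments.
#' @examples
#' bsa_du_bois(180, 70)  # ~1.886 m^2
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be finite and positive", call. = FALSE)
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Select segments usable for T1/ECV analysis
#'
#' Mid-cavity segments with no LGE or with mid-wall (non-ischaemic) LGE are
#' retained; segments with infarct-pattern subendocardial LGE are excluded from
#' the diffuse-fibrosis analysis. Segments with missing T1 values are unusable.
#'
#' @param lge_flags character vector of per-segment flags, each one of
#'   `"none"`, `"midwall"`, `"infarct"`.
#' @param native_t1,post_t1 optional per-segment T1 values (ms); segments with
#'   a missing value in either map are dropped.
#' @return integer indices of usable segments (possibly empty).
#' @export
select_usable_segments <- function(lge_flags, native_t1 = NULL, post_t1 = NULL) {
  lge_flags <- as.character(lge_flags)
  bad <- setdiff(unique(lge_flags), c("none", "midwall", "infarct"))
  if (length(bad)) {
    stop("unknown LGE flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ok <- lge_flags %in% c("none", "midwall")
  if (!is.null(native_t1)) ok <- ok & is.finite(native_t1)
  if (!is.null(post_t1)) ok <- ok & is.finite(post_t1)
  which(ok)
}

#' Contrast partition coefficient (lambda)
#'
#' The ratio of the contrast-induced relaxation-rate change in myocardium to
#' that in the blood pool:
#' lambda = (1/T1_myo_post - 1/T1_myo_native) / (1/T1_blood_post - 1/T1_blood_native).
#'
#' @param native_myo,post_myo mean myocardial T1 (ms) before / ~20 min after
#'   gadolinium contrast.
#' @param blood_native,blood_post blood-pool T1 (ms) before / after contrast.
#' @return dimensionless lambda (> 0).
#' @export
partition_coefficient <- function(native_myo, post_myo, blood_native, blood_post) {
  vals <- c(native_myo, post_myo, blood_native, blood_post)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all T1 values must be finite and positive", call. = FALSE)
  }
  if (any(post_myo >= native_myo)) {
    stop("post-contrast myocardial T1 must be below native T1", call. = FALSE)
  }
  dr1_blood <- 1 / blood_post - 1 / blood_native
  if (any(dr1_blood <= 0)) {
    stop("non-physiologic contrast kinetics: blood delta-R1 must be positive",
         call. = FALSE)
  }
  (1 / post_myo - 1 / native_myo) / dr1_blood
}

#' Extracellular volume fraction
#'
#' ECV = lambda * (1 - haematocrit): the partition coefficient scaled by the
#' plasma fraction of blood, giving the fraction of myocardial tissue volume
#' that is extracellular.
#'
#' @param lambda partition coefficient (> 0).
#' @param hematocrit haematocrit as a fraction in \[0, 1).
#' @return ECV as a fraction.
#' @export
ecv_fraction <- function(lambda, hematocrit) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("lambda must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(hematocrit)) || any(hematocrit < 0) || any(hematocrit >= 1)) {
    stop("hematocrit must be a fraction in [0, 1)", call. = FALSE)
  }
  lambda * (1 - hematocrit)
}

#' Per-subject ECV metrics from a segmental T1 panel
#'
#' Averages native and post-contrast T1 over the usable mid-cavity segments
#' (mean of T1 before conversion to R1), computes lambda and the ECV fraction,
#' converts LV mass to end-diastolic myocardial volume with a density of
#' 1.05 g/ml, and derives the fibrosis volume (ECV x myocardial volume) and the
#' indexed extracellular volume iECV = fibrosis volume / BSA (ml/m^2).
#'
#' @param native_t1,post_t1 numeric vectors of per-segment myocardial T1 (ms),
#'   typically 6 mid-cavity segments.
#' @param lge character vector of per-segment LGE flags
#'   (`"none"`/`"midwall"`/`"infarct"`).
#' @param blood_native,blood_post blood-pool T1 (ms).
#' @param hematocrit haematocrit fraction.
#' @param lv_mass_g LV myocardial mass (g).
#' @param bsa_m2 body surface area (m^2).
#' @param density myocardial density in g/ml used for the mass-to-volume
#'   conversion (default 1.05).
#' @return a list with class `"ecv_metrics"`: `available` (logical), and when
#'   available `n_segments_used`, `native_t1_mean`, `post_t1_mean`, `lambda`,
#'   `ecv_fraction`, `myocardial_volume_ml`, `fibrosis_volume_ml`,
#'   `iecv_ml_m2`. When no segment is usable, `available` is `FALSE` and the
#'   metric fields are `NA` (consumed by staging as "unclassified").
#' @export
compute_ecv_metrics <- function(native_t1, post_t1, lge, blood_native, blood_post,
                                hematocrit, lv_mass_g, bsa_m2, density = 1.05) {
  if (length(native_t1) != length(post_t1) || length(native_t1) != length(lge)) {
    stop("native_t1, post_t1 and lge must have equal length", call. = FALSE)
  }
  if (!is.finite(lv_mass_g) || lv_mass_g <= 0) stop("lv_mass_g must be positive", call. = FALSE)
  if (!is.finite(bsa_m2) || bsa_m2 <= 0) stop("bsa_m2 must be positive", call. = FALSE)
  use <- select_usable_segments(lge, native_t1, post_t1)
  unavailable <- structure(
    list(available = FALSE, n_segments_used = 0L,
         native_t1_mean = NA_real_, post_t1_mean = NA_real_, lambda = NA_real_,
         ecv_fraction = NA_real_, myocardial_volume_ml = NA_real_,
         fibrosis_volume_ml = NA_real_, iecv_ml_m2 = NA_real_),
    class = "ecv_metrics")
  if (length(use) == 0L) return(unavailable)
  if (!is.finite(blood_native) || !is.finite(blood_post)) return(unavailable)
  nat <- mean(native_t1[use])
  post <- mean(post_t1[use])
  lam <- partition_coefficient(nat, post, blood_native, blood_post)
  ecv <- ecv_fraction(lam, hematocrit)
  myo_vol <- lv_mass_g / density
  fib_vol <- ecv * myo_vol
  structure(
    list(available = TRUE, n_segments_used = length(use),
         native_t1_mean = nat, post_t1_mean = post, lambda = lam,
         ecv_fraction = ecv, myocardial_volume_ml = myo_vol,
         fibrosis_volume_ml = fib_vol, iecv_ml_m2 = fib_vol / bsa_m2),
    class = "ecv_metrics")
}

#' @export
print.ecv_metrics <- function(x, ...) {
  if (!x$available) {
    cat("ECV metrics unavailable (no usable segments)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "ECV metrics (%d segments): native T1 %.0f ms, post T1 %.0f ms\n  lambda %.3f, ECV %.1f%%, fibrosis volume %.1f ml, iECV %.1f ml/m2\n",
    x$n_segments_used, x$native_t1_mean, x$post_t1_mean, x$lambda,
    100 * x$ecv_fraction, x$fibrosis_volume_ml, x$iecv_ml_m2))
  invisible(x)
}

# Worst patient-level LGE pattern across segments: infarct > midwall > none.
patient_lge <- function(lge_flags) {
  lge_flags <- as.character(lge_flags)
  if (any(lge_flags == "infarct")) "infarct"
  else if (any(lge_flags == "midwall")) "midwall"
  else "none"
}

#' Compute ECV metrics for every subject in a cohort table
#'
#' Applies [compute_ecv_metrics()] row-wise to a cohort data frame in the
#' package's cohort schema (see [generate_cohort()] for the column layout).
#'
#' @param cohort cohort data frame with segmental T1 columns
#'   `native_t1_s1..s6`, `post_t1_s1..s6`, LGE flag columns `lge_s1..s6`,
#'   `blood_native_t1`, `blood_post_t1`, `hematocrit`, `lvmi_g_m2`,
#'   `height_cm`, `weight_kg`.
#' @param density myocardial density (g/ml).
#' @return data frame, one row per subject: `subject_id`, `arm`, BSA, the
#'   metric fields of [compute_ecv_metrics()], `metrics_available`, and the
#'   patient-level LGE pattern `patient_lge`.
#' @export
compute_cohort_metrics <- function(cohort, density = 1.05) {
  req <- c(paste0("native_t1_s", 1:6), paste0("post_t1_s", 1:6),
           paste0("lge_s", 1:6), "blood_native_t1", "blood_post_t1",
           "hematocrit", "lvmi_g_m2", "height_cm", "weight_kg")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  bsa <- bsa_du_bois(cohort$height_cm, cohort$weight_kg)
  nat <- as.matrix(cohort[paste0("native_t1_s", 1:6)])
  post <- as.matrix(cohort[paste0("post_t1_s", 1:6)])
  lge <- as.matrix(cohort[paste0("lge_s", 1:6)])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- compute_ecv_metrics(nat[i, ], post[i, ], lge[i, ],
                             cohort$blood_native_t1[i], cohort$blood_post_t1[i],
                             cohort$hematocrit[i],
                             cohort$lvmi_g_m2[i] * bsa[i], bsa[i],
                             density = density)
    out[[i]] <- data.frame(
      metrics_available = m$available, n_segments_used = m$n_segments_used,
      native_t1_mean = m$native_t1_mean, post_t1_mean = m$post_t1_mean,
      lambda = m$lambda, ecv_fraction = m$ecv_fraction,
      myocardial_volume_ml = m$myocardial_volume_ml,
      fibrosis_volume_ml = m$fibrosis_volume_ml, iecv_ml_m2 = m$iecv_ml_m2)
  }
  res <- do.call(rbind, out)
  data.frame(
    subject_id = cohort$subject_id,
    arm = cohort$arm,
    bsa_m2 = bsa,
    res,
    patient_lge = apply(lge, 1, patient_lge),
    stringsAsFactors = FALSE)
}
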