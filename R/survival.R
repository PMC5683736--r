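#' Crude mortality rate per 1,000 patient-years
#'
#' @param deaths number of deaths (>= 0).
#' @param person_years total follow-up in years (> 0).
#' @return rate per 1,000 patient-years.
#' @examples
#' mortality_rate(2, 250)  # 8 per 1,000 patient-years
#' @export
mortality_rate <- function(deaths, person_years) {
  if (any(!is.finite(deaths)) || any(deaths < 0)) {
    stop("deaths must be a non-negative count", call. = FALSE)
  }
  if (any(!is.finite(person_years)) || any(person_years <= 0)) {
    stop("person_years must be positive", call. = FALSE)
  }
  1000 * deaths / person_years
}

#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival-curve estimate under right censoring, with the
#' standard tie convention that deaths precede censorings at equal times (a
#' subject censored at t is still at risk for a death at t).
#'
#' @param time follow-up times (> 0).
#' @param event event indicator (1/TRUE = death, 0/FALSE = censored).
#' @return object of class `"km_fit"`: `curve` is a data frame over distinct
#'   event times with `time`, `n_risk`, `n_event`, `survival`; `n`, `n_events`.
#'   With no events the curve has zero rows and S(t) = 1 everywhere.
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0) stop("empty survival data", call. = FALSE)
  event <- as.integer(as.logical(event))
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  ts <- sort(unique(time[event == 1]))
  n_risk <- vapply(ts, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ts, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    list(curve = data.frame(time = ts, n_risk = n_risk, n_event = n_event,
                            survival = surv),
         n = length(time), n_events = sum(event)),
    class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param km a [km_fit()] object.
#' @param t times at which to evaluate the step function.
#' @return S(t), right-continuous, with S(0) = 1.
#' @export
km_survival <- function(km, t) {
  cv <- km$curve
  vapply(t, function(tt) {
    i <- which(cv$time <= tt)
    if (length(i)) cv$survival[max(i)] else 1
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$n_events))
  if (nrow(x$curve)) print(x$curve, row.names = FALSE)
  else cat("No events; S(t) = 1 everywhere.\n")
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(c(0, cv$time), c(1, cv$survival), type = "s",
                 xlab = "Time", ylab = "Survival", ylim = c(0, 1), ...)
  invisible(x)
}

#' K-group log-rank test
#'
#' The standard log-rank chi-square from observed-vs-expected event counts at
#' each distinct event time, with the hypergeometric variance and a chi-square
#' reference distribution on K - 1 degrees of freedom. Groups with no members
#' are dropped.
#'
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @param group group labels (>= 2 non-empty groups).
#' @return list of class `"logrank_test"`: `statistic`, `df`, `p.value`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.integer(as.logical(event))
  group <- droplevels(factor(group))
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (sum(event) == 0) {
    stop("all observations censored; log-rank test undefined", call. = FALSE)
  }
  ts <- sort(unique(time[event == 1]))
  obs <- exp <- numeric(k)
  V <- matrix(0, k, k)
  gi <- as.integer(group)
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- tabulate(gi[at_risk], nbins = k)
    dead <- time == t & event == 1
    d <- sum(dead)
    dj <- tabulate(gi[dead], nbins = k)
    obs <- obs + dj
    exp <- exp + d * nj / n
    if (n > 1) {
      # hypergeometric covariance of the group-wise death counts at this time
      V <- V + d * (n - d) / (n - 1) * (diag(nj / n, k) - tcrossprod(nj / n))
    }
  }
  u <- (obs - exp)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vk, u)), error = function(e) {
    # singular variance (e.g. a group always at zero risk): generalised inverse
    ev <- eigen(Vk, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    drop(t(u) %*% ev$vectors[, pos, drop = FALSE] %*%
           diag(1 / ev$values[pos], sum(pos)) %*%
           t(ev$vectors[, pos, drop = FALSE]) %*% u)
  })
  names(obs) <- names(exp) <- levels(group)
  structure(
    list(statistic = stat, df = k - 1L,
         p.value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
         observed = obs, expected = exp),
    class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = x$expected), row.names = FALSE)
  invisible(x)
}

#' Stage-wise outcome summary
#'
#' Per-stage deaths, person-years and crude rates per 1,000 patient-years,
#' Kaplan-Meier curves, and the K-group log-rank test, for all-cause death and
#' (when an `as_death` column is present) for aortic-stenosis-related death
#' with non-AS deaths treated as censorings (naive cause-specific analysis; no
#' competing-risks estimator).
#'
#' @param staged a data frame with columns `stage` (or a grouping factor given
#'   via `group_col`), `followup_years`, `death`, optionally `as_death`; or a
#'   `fibrosis_staging` fit, in which case its classifiable staged patients
#'   are used.
#' @param group_col name of the grouping column (default `"stage"`).
#' @return object of class `"stage_outcomes"`: `table` (group, n, deaths,
#'   person_years, rate_per_1000py, and AS-related columns when available),
#'   `km` (list of [km_fit()] per group), `logrank`, `logrank_as`,
#'   `total_deaths`.
#' @export
stage_outcomes <- function(staged, group_col = "stage") {
  if (inherits(staged, "fibrosis_staging")) {
    staged <- staged$staged
    staged <- staged[staged$stage %in% CLASSIFIED_STAGES, , drop = FALSE]
    staged$stage <- droplevels(staged$stage)
  }
  req <- c(group_col, "followup_years", "death")
  miss <- setdiff(req, names(staged))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  # zero-member levels of an input factor stay in the table
  g <- staged[[group_col]]
  g <- if (is.factor(g)) g else factor(g)
  has_cause <- "as_death" %in% names(staged)
  rows <- lapply(levels(g), function(s) {
    d <- staged[g == s, ]
    py <- sum(d$followup_years)
    out <- data.frame(group = s, n = nrow(d), deaths = sum(d$death),
                      person_years = py,
                      rate_per_1000py = if (py > 0) mortality_rate(sum(d$death), py) else NA_real_)
    if (has_cause) {
      out$as_deaths <- sum(d$as_death)
      out$as_rate_per_1000py <- if (py > 0) mortality_rate(sum(d$as_death), py) else NA_real_
    }
    out
  })
  tab <- do.call(rbind, rows)
  lv_used <- levels(g)[tab$n > 0]
  km <- lapply(lv_used, function(s) {
    d <- staged[g == s, ]
    km_fit(d$followup_years, d$death)
  })
  names(km) <- lv_used
  nonempty <- g %in% lv_used
  lr <- if (sum(staged$death) > 0 && length(lv_used) >= 2) {
    logrank_test(staged$followup_years[nonempty], staged$death[nonempty],
                 g[nonempty])
  } else NULL
  lr_as <- if (has_cause && sum(staged$as_death) > 0 && length(lv_used) >= 2) {
    logrank_test(staged$followup_years[nonempty], staged$as_death[nonempty],
                 g[nonempty])
  } else NULL
  structure(
    list(table = tab, km = km, logrank = lr, logrank_as = lr_as,
         total_deaths = sum(staged$death)),
    class = "stage_outcomes")
}

#' @export
print.stage_outcomes <- function(x, ...) {
  cat("Outcomes by group (", x$total_deaths, " deaths in total)\n", sep = "")
  tab <- x$table
  tab$person_years <- round(tab$person_years, 1)
  tab$rate_per_1000py <- round_half_up(tab$rate_per_1000py, 1)
  if ("as_rate_per_1000py" %in% names(tab)) {
    tab$as_rate_per_1000py <- round_half_up(tab$as_rate_per_1000py, 1)
  }
  print(tab, row.names = FALSE)
  if (!is.null(x$logrank)) {
    cat("All-cause: ")
    print(x$logrank)
  }
  if (!is.null(x$logrank_as)) {
    cat("AS-related (non-AS deaths censored): ")
    print(x$logrank_as)
  }
  invisible(x)
}

#' Tidy Kaplan-Meier curves for a set of groups
#'
#' @param outcomes a [stage_outcomes()] object.
#' @return data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival` (long format, suitable for CSV export).
#' @export
km_curves_frame <- function(outcomes) {
  do.call(rbind, lapply(names(outcomes$km), function(s) {
    cv <- outcomes$km[[s]]$curve
    if (!nrow(cv)) return(NULL)
    cbind(data.frame(group = s), cv)
  }))
}
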