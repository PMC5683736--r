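#' Group-wise descriptive summary with appropriate tests
#'
#' For each requested variable: numeric variables are tested for normality per
#' group (Shapiro-Wilk at 0.05) and summarised as mean +/- SD with a t test
#' (2 groups) / one-way ANOVA (K groups) when normal in every group, otherwise
#' as median (IQR) with a Mann-Whitney / Kruskal-Wallis test. Categorical
#' variables are summarised as counts (percent) and compared with the
#' chi-square test. Constant variables are flagged and left untested.
#'
#' @param cohort data frame.
#' @param grouping name of the grouping column (>= 2 non-empty groups).
#' @param variables character vector of columns to summarise; defaults to all
#'   columns except the grouping one that are numeric, character, factor or
#'   logical.
#' @param shapiro_alpha alpha for the normality decision (default 0.05).
#' @return data frame of class `"group_summary"`: one row per variable with
#'   `variable`, `kind` (normal/nonnormal/categorical/constant), one summary
#'   column per group, `test`, `statistic`, `p_value`.
#' @export
summarize_groups <- function(cohort, grouping, variables = NULL,
                             shapiro_alpha = 0.05) {
  if (!grouping %in% names(cohort)) stop("grouping column not found", call. = FALSE)
  g <- droplevels(factor(cohort[[grouping]]))
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (is.null(variables)) {
    variables <- setdiff(names(cohort), grouping)
    variables <- variables[vapply(cohort[variables], function(x)
      is.numeric(x) || is.character(x) || is.factor(x) || is.logical(x), logical(1))]
  }
  lv <- levels(g)
  fmt_num <- function(x, normal) {
    x <- x[is.finite(x)]
    if (!length(x)) return("-")
    if (normal) sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
    else sprintf("%.2f (%.2f-%.2f)", stats::median(x),
                 stats::quantile(x, 0.25, names = FALSE),
                 stats::quantile(x, 0.75, names = FALSE))
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    base <- data.frame(variable = v, stringsAsFactors = FALSE)
    if (is.numeric(x)) {
      xs <- split(x[is.finite(x)], g[is.finite(x)])
      if (any(vapply(xs, function(z) length(unique(z)) <= 1, logical(1))) ||
          length(unique(x[is.finite(x)])) <= 1) {
        for (l in lv) base[[l]] <- fmt_num(xs[[l]] %||% numeric(0), TRUE)
        base$kind <- "constant"; base$test <- "none (constant)"
        base$statistic <- NA_real_; base$p_value <- NA_real_
        return(base)
      }
      normal <- all(vapply(xs, function(z) {
        if (length(z) < 3) return(TRUE)
        stats::shapiro.test(z[seq_len(min(length(z), 5000))])$p.value > shapiro_alpha
      }, logical(1)))
      for (l in lv) base[[l]] <- fmt_num(xs[[l]], normal)
      if (normal) {
        if (nlevels(g) == 2) {
          tt <- stats::t.test(xs[[1]], xs[[2]], var.equal = FALSE)
          base$kind <- "normal"; base$test <- "Welch t"
          base$statistic <- unname(tt$statistic); base$p_value <- tt$p.value
        } else {
          av <- stats::oneway.test(x ~ g)
          base$kind <- "normal"; base$test <- "one-way ANOVA"
          base$statistic <- unname(av$statistic); base$p_value <- av$p.value
        }
      } else {
        if (nlevels(g) == 2) {
          wt <- suppressWarnings(stats::wilcox.test(xs[[1]], xs[[2]]))
          base$kind <- "nonnormal"; base$test <- "Mann-Whitney"
          base$statistic <- unname(wt$statistic); base$p_value <- wt$p.value
        } else {
          kt <- stats::kruskal.test(x ~ g)
          base$kind <- "nonnormal"; base$test <- "Kruskal-Wallis"
          base$statistic <- unname(kt$statistic); base$p_value <- kt$p.value
        }
      }
    } else {
      x <- factor(x)
      tab <- table(x, g)
      for (l in lv) {
        cnt <- tab[, l]
        base[[l]] <- paste(sprintf("%s %d (%d%%)", rownames(tab), cnt,
                                   round_half_up(100 * cnt / max(sum(cnt), 1))),
                           collapse = "; ")
      }
      if (nrow(tab) < 2) {
        base$kind <- "constant"; base$test <- "none (constant)"
        base$statistic <- NA_real_; base$p_value <- NA_real_
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        base$kind <- "categorical"; base$test <- "chi-square"
        base$statistic <- unname(ct$statistic); base$p_value <- ct$p.value
      }
    }
    base
  })
  out <- do.call(rbind, lapply(rows, function(r) r[c("variable", "kind", lv,
                                                     "test", "statistic", "p_value")]))
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Stratify a cohort into tertiles of a variable
#'
#' Boundaries are the empirical 1/3 and 2/3 points; assignment is
#' lower-boundary-inclusive (values equal to a boundary go to the lower
#' tertile), so for distinct values group sizes differ by at most one, with
#' any extras in the lower tertiles (e.g. 161 subjects give 54/54/53).
#'
#' @param cohort data frame (rows with a missing stratification value are
#'   dropped, with a note in the result).
#' @param variable name of the numeric column to stratify on.
#' @param summary_vars optional columns to summarise per tertile via
#'   [summarize_groups()].
#' @return list of class `"tertile_stratification"`: `assignments` (factor
#'   `T1`/`T2`/`T3` aligned to the retained rows), `data` (retained rows with
#'   a `tertile` column), `boundaries`, `sizes`, `n_missing`, and `summary`
#'   when `summary_vars` given. Heavy ties collapsing a boundary produce a
#'   warning and unequal sizes.
#' @export
tertile_stratify <- function(cohort, variable, summary_vars = NULL) {
  x <- cohort[[variable]]
  if (is.null(x)) stop("variable not found in cohort", call. = FALSE)
  keep <- is.finite(x)
  d <- cohort[keep, , drop = FALSE]
  x <- x[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 non-missing values", call. = FALSE)
  sizes0 <- floor(n / 3) + c(n %% 3 >= 1, n %% 3 >= 2, 0)
  xs <- sort(x)
  b1 <- xs[sizes0[1]]
  b2 <- xs[sizes0[1] + sizes0[2]]
  tert <- factor(ifelse(x <= b1, "T1", ifelse(x <= b2, "T2", "T3")),
                 levels = c("T1", "T2", "T3"))
  sizes <- table(tert)
  if (b1 == b2 || any(sizes == 0)) {
    warning(sprintf("degenerate tertiles under heavy ties (sizes %s)",
                    paste(sizes, collapse = "/")), call. = FALSE)
  }
  d$tertile <- tert
  out <- list(variable = variable, assignments = tert, data = d,
              boundaries = c(lower = b1, upper = b2),
              sizes = sizes, n_missing = sum(!keep))
  if (!is.null(summary_vars)) {
    out$summary <- summarize_groups(d, "tertile", summary_vars)
  }
  class(out) <- "tertile_stratification"
  out
}

#' @export
print.tertile_stratification <- function(x, ...) {
  cat(sprintf("Tertiles of %s: n = %s (boundaries %.2f / %.2f; %d missing)\n",
              x$variable, paste(x$sizes, collapse = "/"),
              x$boundaries[["lower"]], x$boundaries[["upper"]], x$n_missing))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Pearson or Spearman correlation with a p-value
#'
#' Pearson r with the t transform p-value on n - 2 df; Spearman rho as the
#' Pearson correlation of the ranks with the same t approximation (documented
#' approximation for tied/small samples).
#'
#' @param x,y paired numeric vectors (n >= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `"cor_result"`: `estimate`, `statistic` (t),
#'   `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(min(r, 1), -1)
  tstat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  structure(list(estimate = r, statistic = tstat, p_value = p, n = n,
                 method = method), class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (t = %.3g, n = %d, p = %.3g)\n",
              x$method, x$estimate, x$statistic, x$n, x$p_value))
  invisible(x)
}

# Shared design-matrix plumbing for the two fitters.
build_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  list(y = stats::model.response(mf), X = stats::model.matrix(formula, mf))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit written out as IRLS over the weighted
#' normal equations (QR-solved), reporting per-unit odds ratios with Wald
#' confidence intervals. Perfect separation is detected and raised as an
#' error rather than silently diverging.
#'
#' @param formula model formula with a binary (0/1 or logical) outcome.
#' @param data data frame.
#' @param max_iter,tol IRLS iteration cap and deviance-change tolerance.
#' @param conf_level confidence level for the Wald intervals.
#' @return object of class `"fibro_logit"`: `coefficients`, `se`,
#'   `odds_ratio` with `or_ci`, `log_lik`, `deviance`, `fitted`, `iter`,
#'   `converged`, `n`.
#' @export
fit_logistic <- function(formula, data, max_iter = 50, tol = 1e-10,
                         conf_level = 0.95) {
  d <- build_design(formula, data)
  y <- as.numeric(d$y)
  X <- d$X
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("more parameters than observations", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank-deficient (e.g. a constant predictor)", call. = FALSE)
  }
  beta <- rep(0, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) {
      if (max(abs(beta)) > 15) {
        stop("perfect separation detected: fitted probabilities reached 0/1 ",
             "with diverging coefficients", call. = FALSE)
      }
      w <- pmax(w, 1e-12)
    }
    z <- eta + (y - mu) / w
    wsq <- sqrt(w)
    fit <- qr(X * wsq)
    beta <- qr.coef(fit, z * wsq)
    mu_new <- stats::plogis(drop(X %*% beta))
    dev <- -2 * sum(y * log(pmax(mu_new, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu_new, 1e-300)))
    if (is.finite(dev_old) && abs(dev_old - dev) < tol) { converged <- TRUE; break }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (!converged && max(abs(beta)) > 15) {
    stop("perfect separation detected: likelihood has no finite maximiser",
         call. = FALSE)
  }
  W <- mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  se <- sqrt(diag(solve(info)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  structure(
    list(coefficients = stats::setNames(drop(beta), colnames(X)),
         se = stats::setNames(se, colnames(X)),
         odds_ratio = exp(drop(beta)),
         or_ci = cbind(lower = exp(drop(beta) - zq * se),
                       upper = exp(drop(beta) + zq * se)),
         log_lik = ll, deviance = -2 * ll, fitted = mu,
         iter = it, converged = converged, n = length(y)),
    class = "fibro_logit")
}

#' @export
print.fibro_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (IRLS, %d obs, %d iterations, logLik %.3f)\n",
              x$n, x$iter, x$log_lik))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    OR = x$odds_ratio, x$or_ci)
  print(round(tab, 4))
  invisible(x)
}

#' Ordinary least squares by QR decomposition
#'
#' Linear model fit through the QR factorisation of the design matrix, with
#' classical standard errors and t-based confidence intervals.
#'
#' @param formula model formula with a continuous outcome.
#' @param data data frame.
#' @param conf_level confidence level for the intervals.
#' @return object of class `"fibro_lm"`: `coefficients`, `se`, `ci`,
#'   `sigma`, `df_residual`, `fitted`, `residuals`, `r_squared`, `n`.
#' @export
fit_linear <- function(formula, data, conf_level = 0.95) {
  d <- build_design(formula, data)
  y <- as.numeric(d$y)
  X <- d$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank-deficient", call. = FALSE)
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df_res <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(coefficients = stats::setNames(drop(beta), colnames(X)),
         se = stats::setNames(se, colnames(X)),
         ci = cbind(lower = drop(beta) - tq * se, upper = drop(beta) + tq * se),
         sigma = sqrt(sigma2), df_residual = df_res,
         fitted = fitted, residuals = res,
         r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
         n = length(y)),
    class = "fibro_lm")
}

#' @export
print.fibro_lm <- function(x, ...) {
  cat(sprintf("Linear fit (OLS, %d obs, sigma %.4g, R^2 %.3f)\n",
              x$n, x$sigma, x$r_squared))
  print(round(data.frame(coef = x$coefficients, se = x$se, x$ci), 4))
  invisible(x)
}

#' @export
coef.fibro_logit <- function(object, ...) object$coefficients

#' @export
coef.fibro_lm <- function(object, ...) object$coefficients

#' @export
residuals.fibro_lm <- function(object, ...) object$residuals
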