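#' Kaplan-Meier survival curves
#'
#' Product-limit estimates per group with Greenwood variance and median
#' survival with log-log 95% CI. A median that is never reached is reported
#' as `NA` with `median_reached = FALSE`, never as a number.
#'
#' @param data a `clinical_table` (columns `os_time`, `os_event`).
#' @param group optional per-sample group labels; one curve per group.
#' @return a `km_curves` object: list with the underlying
#'   [survival::survfit()] fit and a `medians` data frame (group, n,
#'   events, median, ci_low, ci_high, median_reached).
#' @export
km_fit <- function(data, group = NULL) {
  stopifnot(all(c("os_time", "os_event") %in% names(data)))
  if (is.null(group)) group <- rep("all", nrow(data))
  group <- droplevels(as.factor(group))
  if (nrow(data) == 0 || nlevels(group) == 0)
    stop("empty group in Kaplan-Meier fit")
  df <- data.frame(time = data$os_time, event = data$os_event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("all", names(tab)))
  med <- data.frame(group = sub("^group=", "", rownames(tab)),
                    n = tab[, "records"], events = tab[, "events"],
                    median = tab[, "median"],
                    ci_low = tab[, "0.95LCL"], ci_high = tab[, "0.95UCL"],
                    median_reached = !is.na(tab[, "median"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, medians = med), class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  m <- x$medians
  for (i in seq_len(nrow(m)))
    cat(sprintf("%s: n=%d, events=%d, median %s (95%% CI [%s, %s])\n",
                m$group[i], m$n[i], m$events[i],
                if (m$median_reached[i]) sprintf("%.2f", m$median[i]) else "not reached",
                ifelse(is.na(m$ci_low[i]), "NR", sprintf("%.2f", m$ci_low[i])),
                ifelse(is.na(m$ci_high[i]), "NR", sprintf("%.2f", m$ci_high[i]))))
  invisible(x)
}

#' Log-rank comparison of survival curves
#'
#' @param data a `clinical_table`.
#' @param group per-sample group labels (at least two non-empty groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(data, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("log-rank test requires at least two groups")
  df <- data.frame(time = data$os_time, event = data$os_event, group = group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd_$n) - 1
  list(chisq = sd_$chisq, df = dfree,
       p = stats::pchisq(sd_$chisq, dfree, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Fits a Cox PH model by partial likelihood with Efron tie handling and
#' reports per-covariate hazard ratios with Wald 95% CIs and the model-level
#' likelihood-ratio test against the null.
#'
#' @param data a `clinical_table` whose extra columns hold covariates.
#' @param covariates character vector of covariate column names, or a
#'   one-sided formula.
#' @param ties tie-handling method (default `"efron"`).
#' @return a `cox_fit` object: list with `coefficients` data frame
#'   (term, coef, hr, ci_low, ci_high, se, wald_p), `lrt_p`, `n`,
#'   `n_events` and the underlying [survival::coxph()] fit.
#' @export
cox_fit <- function(data, covariates, ties = "efron") {
  stopifnot(all(c("os_time", "os_event") %in% names(data)))
  rhs <- if (inherits(covariates, "formula")) {
    paste(deparse(covariates[[2]]), collapse = "")
  } else paste(covariates, collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~", rhs))
  warnings_seen <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = as.data.frame(data), ties = ties),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("infinite", warnings_seen)) ||
      any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(fit$var)) > 100 * (abs(stats::coef(fit)) + 1))) {
    bad <- names(stats::coef(fit))[!is.finite(stats::coef(fit)) |
                                     sqrt(diag(fit$var)) > 100 * (abs(stats::coef(fit)) + 1)]
    if (!length(bad)) bad <- names(stats::coef(fit))
    stop("Cox fit did not converge (monotone likelihood?) for covariate(s): ",
         paste(bad, collapse = ", "))
  }
  for (w in warnings_seen) warning(w, call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  coefs <- data.frame(term = rownames(co), coef = co[, "coef"],
                      hr = co[, "exp(coef)"],
                      ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
                      se = co[, "se(coef)"], wald_p = co[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, lrt_p = unname(sm$logtest["pvalue"]),
                 n = sm$n, n_events = sm$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n = ", x$n, ", events = ", x$n_events,
      "; LRT p = ", format.pval(x$lrt_p, digits = 3), "\n", sep = "")
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %s: HR %.3g (95%% CI [%.3g, %.3g]), p = %s\n",
                co$term[i], co$hr[i], co$ci_low[i], co$ci_high[i],
                format.pval(co$wald_p[i], digits = 3)))
  invisible(x)
}

#' Sign-based risk grouping of signature scores
#'
#' High-risk iff the (orientation-corrected) signature score is strictly
#' positive; a score of exactly zero is low-risk.
#'
#' @param scores numeric per-sample signature scores (oriented per the
#'   signature orientation rule).
#' @return factor with levels low / high.
#' @export
assign_risk_groups <- function(scores) {
  factor(ifelse(scores > 0, "high", "low"), levels = c("low", "high"))
}

#' Multivariate linear model of histology features on the CGC
#'
#' Ordinary least squares of the CGC on all histological features jointly,
#' with per-coefficient two-sided t-tests — the model used to ask which
#' scored features carry independent information about the methylation
#' grade.
#'
#' @param features data frame (samples x features) of numeric or factor
#'   histology scores.
#' @param cgc numeric CGC per sample.
#' @return data frame: term, estimate, se, t, p (intercept included).
#' @export
histology_cgc_model <- function(features, cgc) {
  features <- as.data.frame(features)
  if (nrow(features) <= ncol(features) + 1)
    stop("need more samples than features + 1")
  df <- cbind(.cgc = cgc, features)
  fit <- stats::lm(.cgc ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
}
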