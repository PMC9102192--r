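#' Kaplan-Meier curves with a log-rank group comparison
#'
#' Product-limit estimator per group plus the log-rank test between groups.
#' With a single group only the curve is returned (`p = NA`).
#'
#' @param time Follow-up time in days, > 0.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param group Grouping vector (e.g. lactate cluster 1/2).
#' @return List with `fit` (a [survival::survfit] object), `p` (log-rank,
#'   two-group or k-group), and `n_events`.
#' @export
#' @examples
#' sim <- gen_cohort(sim_config(seed = 1, n_patients = 100))
#' km <- km_logrank(sim$cohort$time, sim$cohort$event, sim$truth$cluster)
#' km$p
km_logrank <- function(time, event, group) {
  if (any(time <= 0)) stop("`time` must be positive", call. = FALSE)
  if (sum(event) < 1L) stop("need at least one event", call. = FALSE)
  d <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (nlevels(d$group) < 2L)
    return(list(fit = fit, p = NA_real_, n_events = sum(event)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  list(fit = fit, p = p, n_events = sum(event))
}

#' Stepwise Cox proportional hazards model
#'
#' Partial-likelihood Cox fit (Efron tie handling) of overall survival on
#' the candidate covariates, followed by bidirectional stepwise selection
#' by AIC starting from the full model - the study's strategy for testing
#' whether the lactate-gene cluster predicts survival independently of pN,
#' stage, p16, grade and smoking. Covariates on which the full model fails
#' to converge or separates completely (unbounded coefficients) are flagged
#' and dropped before selection, which then continues without them.
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param covariates Candidate covariate names.
#' @param time,event Column names of follow-up time and event indicator.
#' @return An object of class `caf_cox`: list with `model` (the selected
#'   [survival::coxph] fit), `retained` (covariate names), `hr` (data frame
#'   with hazard ratios, 95% CIs and p-values per retained covariate),
#'   `flagged` (covariates excluded for non-convergence/separation), and
#'   `aic`.
#' @export
#' @examples
#' sim <- gen_cohort(sim_config(seed = 1, n_patients = 200))
#' d <- sim$cohort
#' d$cluster <- factor(sim$truth$cluster)
#' cox_stepwise(d, c("cluster", "pN", "stage", "p16", "smoking"))
cox_stepwise <- function(data, covariates, time = "time", event = "event") {
  if (!all(c(time, event) %in% names(data)))
    stop("`data` needs `", time, "` and `", event, "` columns", call. = FALSE)
  n_events <- sum(data[[event]])
  if (n_events < 10L)
    stop("need at least 10 events for stepwise Cox selection (got ",
         n_events, ")", call. = FALSE)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0L)
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)

  surv_str <- sprintf("survival::Surv(%s, %s)", time, event)
  fit_full <- function(covs) {
    f <- stats::as.formula(paste(surv_str, "~",
                                 paste(sprintf("`%s`", covs), collapse = "+")))
    survival::coxph(f, data = data, ties = "efron", model = TRUE)
  }

  # flag covariates the full fit cannot estimate (separation shows up as
  # huge |coef| or SE; non-convergence as a warning)
  covs <- covariates
  flagged <- character(0)
  repeat {
    warned <- FALSE
    full <- withCallingHandlers(
      fit_full(covs),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") }
    )
    co <- stats::coef(full)
    se <- sqrt(diag(full$var))
    bad_terms <- names(co)[!is.finite(co) | abs(co) > 15 | se > 100]
    if (length(bad_terms) == 0L && !warned) break
    if (length(bad_terms) == 0L && warned) break  # converged enough for AIC
    bad_cov <- unique(unlist(lapply(covs, function(v) {
      if (any(startsWith(bad_terms, v) | startsWith(bad_terms, paste0("`", v)))) v
    })))
    if (length(bad_cov) == 0L) break
    flagged <- c(flagged, bad_cov)
    covs <- setdiff(covs, bad_cov)
    if (length(covs) == 0L)
      stop("all candidate covariates were flagged as inestimable",
           call. = FALSE)
  }

  scope_full <- stats::as.formula(
    paste("~", paste(sprintf("`%s`", covs), collapse = "+")))
  sel <- MASS::stepAIC(full, direction = "both", trace = 0,
                       scope = list(lower = ~1, upper = scope_full))
  retained_terms <- attr(stats::terms(sel), "term.labels")
  retained <- gsub("`", "", retained_terms)

  hr <- NULL
  if (length(retained) > 0L) {
    s <- summary(sel)
    hr <- data.frame(term = rownames(s$coefficients),
                     hr = s$coefficients[, "exp(coef)"],
                     lower95 = s$conf.int[, "lower .95"],
                     upper95 = s$conf.int[, "upper .95"],
                     p = s$coefficients[, "Pr(>|z|)"],
                     row.names = NULL)
  }
  structure(list(model = sel, retained = retained, hr = hr,
                 flagged = flagged, aic = stats::AIC(sel),
                 n_events = n_events),
            class = "caf_cox")
}

#' @export
print.caf_cox <- function(x, ...) {
  cat(sprintf("Stepwise Cox model (Efron ties, AIC both directions): %d events\n",
              x$n_events))
  if (length(x$retained) == 0L) {
    cat("  no covariate retained (null model)\n")
  } else {
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
    hr <- x$hr
    for (i in seq_len(nrow(hr)))
      cat(sprintf("    %-18s HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                  hr$term[i], hr$hr[i], hr$lower95[i], hr$upper95[i],
                  hr$p[i]))
  }
  if (length(x$flagged) > 0L)
    cat("  flagged (separation/non-convergence):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
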