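#' Pooled cause-specific survival from multiply imputed causes of death
#'
#' The package's main fitting function. Runs the full pipeline on a cohort
#' with partially missing causes of death: (1) multiple imputation of
#' causes and incomplete covariates by chained equations
#' (\code{\link{mice_impute}}); (2) per-dataset cause-specific estimation —
#' Kaplan-Meier censoring other-cause deaths and/or the competing-risks
#' cumulative-incidence complement; (3) pooling of the m curves by Rubin's
#' rules after complementary log-log transformation
#' (\code{\link{pool_curves}}). The all-cause Kaplan-Meier curve is always
#' computed, and a Pohar-Perme net-survival curve is added when a
#' population life table is supplied.
#'
#' @param data a \code{\link{cohort}} (or a data.frame coercible to one).
#' @param m number of imputations (default 20).
#' @param maxit chained-equation iterations per chain (default 20).
#' @param estimator per-dataset estimators to pool: any of \code{"km"}
#'   (cause-specific Kaplan-Meier) and \code{"cr"} (competing-risks
#'   survival, \code{1 - CIF}).
#' @param life_table optional \code{\link{life_table}} for the net-survival
#'   comparison.
#' @param report_times times (days) at which \code{summary()} tabulates the
#'   curves; default 1, 3, 5 and 10 years.
#' @param seed integer seed controlling all randomness.
#' @param ... passed to \code{\link{mice_impute}} (e.g.
#'   \code{predictor_matrix}, \code{donors}, \code{visit}).
#' @return object of class \code{"misurv"} with components
#'   \code{imputation} (the \code{"mice_fit"}), \code{pooled} (named list
#'   of \code{"pooled_curve"}s), \code{overall} (all-cause KM),
#'   \code{net} (Pohar-Perme curve or \code{NULL}) and \code{report_times}.
#' @export
#' @examples
#' coh <- generate_cohort(n = 300, seed = 42)$cohort
#' fit <- misurv(coh, m = 3, maxit = 3, seed = 1)
#' summary(fit)
misurv <- function(data, m = 20L, maxit = 20L,
                   estimator = c("km", "cr"), life_table = NULL,
                   report_times = round(c(1, 3, 5, 10) * 365.25),
                   seed = NULL, ...) {
  cl <- match.call()
  data <- cohort(data)
  estimator <- match.arg(estimator, several.ok = TRUE)
  imp <- mice_impute(data, m = m, maxit = maxit, seed = seed, ...)
  pooled <- list()
  if ("km" %in% estimator) {
    kms <- lapply(imp$imputations, function(d)
      cs_km_curve(d$followup_days, d$dead, d$cause))
    pooled$km <- pool_curves(kms)
  }
  if ("cr" %in% estimator) {
    crs <- lapply(imp$imputations, function(d)
      cuminc_curves(d$followup_days, d$dead, d$cause)$surv)
    pooled$cr <- pool_curves(crs)
  }
  overall <- km_curve(data$followup_days, data$dead)
  net <- NULL
  if (!is.null(life_table))
    net <- pohar_perme(data$followup_days, data$dead,
                       data$age_at_diagnosis, data$diagnosis_year,
                       data$sex, life_table)
  structure(list(call = cl, imputation = imp, pooled = pooled,
                 overall = overall, net = net,
                 report_times = report_times),
            class = "misurv")
}

#' @export
print.misurv <- function(x, ...) {
  cat("Pooled cause-specific survival after multiple imputation\n")
  cat(sprintf("  n = %d patients, %d deaths (%d with missing cause), m = %d\n",
              nrow(x$imputation$data), sum(x$imputation$data$dead),
              sum(x$imputation$where[, "cause"]), x$imputation$m))
  for (nm in names(x$pooled)) {
    lab <- c(km = "cause-specific KM", cr = "competing risks")[nm]
    s <- pooled_at(x$pooled[[nm]], max(x$report_times))
    cat(sprintf("  pooled %s at %g y: %.3f [%.3f-%.3f]\n", lab,
                round(max(x$report_times) / 365.25), s$S, s$ci_low,
                s$ci_high))
  }
  if (!is.null(x$net))
    cat("  net survival (Pohar-Perme) included\n")
  invisible(x)
}

#' Survival summary table at the report times
#'
#' One row per report time with the overall Kaplan-Meier survival, the
#' Pohar-Perme net survival (when a life table was supplied) and the pooled
#' cause-specific estimates with their 95 percent confidence bounds.
#'
#' @param object a \code{"misurv"}.
#' @param times report times in days (default: the fit's).
#' @param ... unused.
#' @return data.frame.
#' @export
summary.misurv <- function(object, times = object$report_times, ...) {
  out <- data.frame(time = times, years = round(times / 365.25, 2))
  ov <- eval_curve(object$overall, times)
  out$overall <- ov$estimate
  se <- sqrt(ov$variance)
  out$overall_low <- pmax(ov$estimate - 1.96 * se, 0)
  out$overall_high <- pmin(ov$estimate + 1.96 * se, 1)
  if (!is.null(object$net)) {
    nv <- eval_curve(object$net, times)
    out$net <- nv$estimate
    nse <- sqrt(nv$variance)
    out$net_low <- pmax(nv$estimate - 1.96 * nse, 0)
    out$net_high <- nv$estimate + 1.96 * nse
  }
  for (nm in names(object$pooled)) {
    p <- pooled_at(object$pooled[[nm]], times)
    out[[nm]] <- p$S
    out[[paste0(nm, "_low")]] <- p$ci_low
    out[[paste0(nm, "_high")]] <- p$ci_high
  }
  out
}

#' Pooled survival at arbitrary times
#'
#' @param object a \code{"misurv"}.
#' @param times evaluation times (days).
#' @param estimator \code{"km"} or \code{"cr"}.
#' @param ... unused.
#' @return data.frame with \code{time}, \code{S}, \code{ci_low},
#'   \code{ci_high}.
#' @export
predict.misurv <- function(object, times = object$report_times,
                           estimator = names(object$pooled)[1L], ...) {
  pooled_at(object$pooled[[estimator]], times)
}

#' Overlay plot of the fitted curves
#'
#' All-cause Kaplan-Meier, pooled cause-specific curve(s) with confidence
#' band, and net survival when present.
#'
#' @param x a \code{"misurv"}.
#' @param ... passed to \code{plot}.
#' @export
plot.misurv <- function(x, ...) {
  tmax <- max(x$overall$time, unlist(lapply(x$pooled, function(p)
    max(p$time))))
  graphics::plot(c(0, x$overall$time), c(1, x$overall$estimate), type = "s",
                 xlim = c(0, tmax), ylim = c(0, 1.1), xlab = "days",
                 ylab = "survival", col = "grey40", ...)
  cols <- c(km = "firebrick", cr = "steelblue")
  for (nm in names(x$pooled)) {
    p <- x$pooled[[nm]]
    graphics::lines(c(0, p$time), c(1, p$S), type = "s", col = cols[nm])
    graphics::lines(c(0, p$time), c(1, p$ci_low), type = "s", lty = 3L,
                    col = cols[nm])
    graphics::lines(c(0, p$time), c(1, p$ci_high), type = "s", lty = 3L,
                    col = cols[nm])
  }
  if (!is.null(x$net))
    graphics::lines(c(0, x$net$time), c(1, x$net$estimate), type = "s",
                    col = "darkgreen")
  graphics::abline(h = 1, lty = 3L, col = "grey70")
  leg <- c("overall KM",
           c(km = "pooled cause-specific KM",
             cr = "pooled competing risks")[names(x$pooled)],
           if (!is.null(x$net)) "net (Pohar-Perme)")
  graphics::legend("bottomleft", legend = leg, lty = 1L,
                   col = c("grey40", cols[names(x$pooled)],
                           if (!is.null(x$net)) "darkgreen"), bty = "n")
  invisible(x)
}

#' Age-stratified survival summary
#'
#' Refits the pipeline within age strata and tabulates the summary of each
#' stratum (the conventional presentation: overall, net, pooled KM and
#' pooled competing risks by age class).
#'
#' @param data a cohort.
#' @param breaks age-class boundaries (default 56/65/70/Inf, i.e. classes
#'   [56,65], (65,70], (70,Inf)).
#' @param ... passed to \code{\link{misurv}}.
#' @return named list of summary data.frames, one per stratum.
#' @export
age_stratified_summary <- function(data, breaks = c(56, 65, 70, Inf),
                                   ...) {
  data <- cohort(data)
  strata <- cut(data$age_at_diagnosis, breaks, include.lowest = TRUE)
  out <- lapply(levels(strata), function(s) {
    sub <- data[strata == s, , drop = FALSE]
    class(sub) <- class(data)
    fit <- misurv(sub, ...)
    cbind(stratum = s, n = nrow(sub), summary(fit))
  })
  names(out) <- levels(strata)
  out
}
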