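# Nonparametric survival curves on one (completed) cohort. The per-dataset
# estimation goes through the standard engines (survival::survfit for the
# product-limit estimator, cmprsk::cuminc for competing risks); curves are
# stored in a light container holding the event-time grid, pointwise
# estimates and variances that downstream pooling consumes.

#' Survival-curve container
#'
#' A \code{"survcurve"} is a right-continuous step function over the
#' distinct event times of a cohort, with the implicit value 1 (variance 0)
#' before the first event time. \code{time} is in days.
#'
#' @param time strictly increasing event times.
#' @param estimate pointwise estimate in [0, 1] (survival scale, or a CIF
#'   when \code{kind = "cif"}).
#' @param variance pointwise variance (>= 0).
#' @param n_risk,n_event at-risk and event counts per time.
#' @param kind one of \code{"overall-km"}, \code{"cause-specific-km"},
#'   \code{"cif"}, \code{"cr-survival"}, \code{"net-pp"}.
#' @return object of class \code{"survcurve"}.
#' @export
survcurve <- function(time, estimate, variance,
                      n_risk = NA_real_, n_event = NA_real_,
                      kind = "overall-km") {
  stopifnot(!is.unsorted(time, strictly = TRUE),
            length(estimate) == length(time),
            length(variance) == length(time))
  # net survival may legitimately exceed 1; KM/CIF curves may not
  upper <- if (identical(kind, "net-pp")) Inf else 1
  if (any(estimate < -1e-12 | estimate > upper + 1e-12, na.rm = TRUE))
    stop("estimates outside the admissible range for kind ", kind,
         call. = FALSE)
  structure(list(time = as.numeric(time),
                 estimate = pmin(pmax(estimate, 0), upper),
                 variance = pmax(variance, 0),
                 n_risk = rep_len(n_risk, length(time)),
                 n_event = rep_len(n_event, length(time)),
                 kind = kind),
            class = "survcurve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' Right-continuous, last-value-carried-forward evaluation; before the first
#' event time the curve is 1 with variance 0 (0 for a CIF).
#'
#' @param curve a \code{"survcurve"}.
#' @param times evaluation times.
#' @return data.frame with \code{time}, \code{estimate}, \code{variance}.
#' @export
eval_curve <- function(curve, times) {
  left <- if (identical(curve$kind, "cif")) 0 else 1
  data.frame(time = times,
             estimate = step_eval(curve$time, curve$estimate, times, left),
             variance = step_eval(curve$time, curve$variance, times, 0))
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimator at each distinct event time; censorings tied
#' with an event time are handled after the events. The variance is
#' Greenwood's. With no events the curve is flat at 1 with zero variance.
#'
#' @param time follow-up durations (days, >= 1).
#' @param event 0/1 event indicator.
#' @return a \code{"survcurve"} of kind \code{"overall-km"}.
#' @export
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))$estimate  # 2/3, 1/3, 0
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 1),
            all(event %in% c(0, 1)))
  if (!any(event == 1))
    return(survcurve(numeric(0), numeric(0), numeric(0),
                     kind = "overall-km"))
  f <- survival::survfit(survival::Surv(time, event) ~ 1, se.fit = TRUE)
  keep <- f$n.event > 0
  v <- (f$surv * f$std.err)^2
  v[!is.finite(v)] <- 0        # S = 0 at the last event time
  survcurve(f$time[keep], f$surv[keep], v[keep],
            n_risk = f$n.risk[keep], n_event = f$n.event[keep],
            kind = "overall-km")
}

#' Cause-specific Kaplan-Meier curve
#'
#' Kaplan-Meier estimate of survival from the cause of interest, censoring
#' deaths from other causes at their death time. Requires a completed
#' cohort: every deceased subject must have a cause.
#'
#' @param time follow-up durations (days).
#' @param dead 0/1 vital status.
#' @param cause factor/character with \code{"prostate"}/\code{"other"}
#'   (\code{NA} allowed only for the alive).
#' @param cause_of_interest level treated as the event (default
#'   \code{"prostate"}).
#' @return a \code{"survcurve"} of kind \code{"cause-specific-km"}.
#' @export
cs_km_curve <- function(time, dead, cause, cause_of_interest = "prostate") {
  dead <- as.integer(dead)
  cause <- as.character(cause)
  if (any(dead == 1L & is.na(cause)))
    stop("missing cause of death among the deceased; impute first",
         call. = FALSE)
  event <- as.integer(dead == 1L & cause == cause_of_interest)
  event[is.na(event)] <- 0L
  out <- km_curve(time, event)
  out$kind <- "cause-specific-km"
  out
}

#' Competing-risks cumulative incidence (Aalen-Johansen)
#'
#' Estimates the cumulative incidence function of each cause with deaths
#' from the other cause as competing events (via \code{cmprsk::cuminc},
#' whose pointwise variance is the standard competing-risks delta-method
#' estimator), together with the all-cause Kaplan-Meier curve. The
#' "competing-risks survival" for the cause of interest is returned as
#' \code{1 - CIF} with the CIF's variance.
#'
#' @inheritParams cs_km_curve
#' @return list with \code{"survcurve"} components \code{cif} (cause of
#'   interest), \code{cif_competing}, \code{surv} (\code{1 - CIF}, kind
#'   \code{"cr-survival"}) and \code{overall} (all-cause KM), all on the
#'   union grid of death times.
#' @export
cuminc_curves <- function(time, dead, cause, cause_of_interest = "prostate") {
  dead <- as.integer(dead)
  cause <- as.character(cause)
  if (any(dead == 1L & is.na(cause)))
    stop("missing cause of death among the deceased; impute first",
         call. = FALSE)
  status <- ifelse(dead == 0L, "censored", cause)
  overall <- km_curve(time, dead)
  grid <- sort(unique(time[dead == 1L]))
  causes <- setdiff(unique(status), "censored")
  zero <- survcurve(grid, rep(0, length(grid)), rep(0, length(grid)),
                    kind = "cif")
  if (length(causes) == 0L)
    return(list(cif = zero, cif_competing = zero,
                surv = survcurve(grid, rep(1, length(grid)),
                                 rep(0, length(grid)), kind = "cr-survival"),
                overall = overall))
  ci <- cmprsk::cuminc(ftime = time, fstatus = status, cencode = "censored")
  tp <- cmprsk::timepoints(ci, times = grid)
  get_cif <- function(cz) {
    row <- grep(paste0(" ", cz, "$"), rownames(tp$est))
    if (!length(row)) return(zero)
    est <- unname(tp$est[row, ])
    var <- unname(tp$var[row, ])
    est[is.na(est)] <- 0; var[is.na(var)] <- 0
    survcurve(grid, est, var, kind = "cif")
  }
  cif_main <- get_cif(cause_of_interest)
  competing <- setdiff(causes, cause_of_interest)
  cif_comp <- if (length(competing)) get_cif(competing[1L]) else zero
  surv <- survcurve(grid, 1 - cif_main$estimate, cif_main$variance,
                    kind = "cr-survival")
  list(cif = cif_main, cif_competing = cif_comp, surv = surv,
       overall = overall)
}

#' @export
print.survcurve <- function(x, ...) {
  cat(sprintf("Survival curve (%s): %d event times", x$kind,
              length(x$time)))
  if (length(x$time))
    cat(sprintf(", range %g-%g days, final estimate %.4f",
                min(x$time), max(x$time), x$estimate[length(x$estimate)]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.survcurve <- function(x, ...) {
  data.frame(time = x$time, estimate = x$estimate, variance = x$variance,
             n_risk = x$n_risk, n_event = x$n_event)
}

#' @export
plot.survcurve <- function(x, conf = FALSE, xlab = "days",
                           ylab = "survival", ...) {
  t0 <- c(0, x$time)
  e0 <- c(if (identical(x$kind, "cif")) 0 else 1, x$estimate)
  graphics::plot(t0, e0, type = "s", xlab = xlab, ylab = ylab,
                 ylim = c(0, max(1, e0)), ...)
  if (conf) {
    se <- sqrt(c(0, x$variance))
    graphics::lines(t0, pmin(e0 + 1.96 * se, Inf), type = "s", lty = 2L)
    graphics::lines(t0, pmax(e0 - 1.96 * se, 0), type = "s", lty = 2L)
  }
  invisible(x)
}

#' Export a curve as delimited text
#'
#' @param curve a \code{"survcurve"}.
#' @param path output path.
#' @param sep separator.
#' @export
write_curve <- function(curve, path, sep = "\t") {
  utils::write.table(as.data.frame(curve), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
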