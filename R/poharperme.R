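# Pohar-Perme net survival, implemented from the estimator's definition:
# each subject's at-risk and event contributions are weighted by the
# inverse of that subject's expected (population) survival, the cumulative
# excess hazard is the weighted observed cumulative hazard minus the
# weighted expected one, and net survival is exp(-cumulative excess
# hazard). The variance is the Poisson-type estimator (sum of squared
# event weights over the squared weighted at-risk total).

# per-subject cumulative population hazard as a piecewise-linear function
# of follow-up days; the hazard is constant within 1-year age x 1-year
# period cells, and the subject ages along the diagonal (attained age and
# calendar time advance together)
subject_cumhaz_knots <- function(age0, year0, sex, lt, tmax) {
  yrs <- tmax / 365.25
  k <- seq_len(ceiling(yrs) + 1L) - 1L
  crossings <- c(365.25 * (k + 1L),                       # calendar years
                 365.25 * (ceiling(age0 + 1e-9) - age0 + k))  # birthdays
  br <- sort(unique(c(0, crossings[crossings < tmax], tmax)))
  mid <- (br[-length(br)] + br[-1L]) / 2
  h <- pop_hazard(lt, sex, age0 + mid / 365.25, year0 + mid / 365.25,
                  per = "day")
  list(x = br, y = c(0, cumsum(h * diff(br))))
}

#' Pohar-Perme net survival
#'
#' Net survival is the survival that would be observed if the disease under
#' study were the only possible cause of death; it is estimable without
#' cause-of-death information by referencing a population life table. This
#' estimator weights every subject's contribution at time t by the inverse
#' of the subject's expected survival from the life table; the weighted
#' expected hazard is subtracted from the weighted observed hazard and the
#' cumulative excess hazard is exponentiated. Estimates can exceed 1 when
#' the cohort's mortality falls below the population expectation.
#'
#' @param time follow-up durations (days).
#' @param dead 0/1 vital status (all-cause).
#' @param age_at_diagnosis age in years at diagnosis.
#' @param diagnosis_year calendar year at diagnosis.
#' @param sex \code{"male"}/\code{"female"} per subject (recycled).
#' @param lt a \code{\link{life_table}}.
#' @param precision maximum integration-interval width in days for the
#'   expected-hazard term (default 30).
#' @return a \code{"survcurve"} of kind \code{"net-pp"} over the distinct
#'   death times.
#' @export
pohar_perme <- function(time, dead, age_at_diagnosis, diagnosis_year,
                        sex = "male", lt, precision = 30) {
  n <- length(time)
  dead <- as.integer(dead)
  stopifnot(length(dead) == n, length(age_at_diagnosis) == n,
            length(diagnosis_year) == n)
  sex <- rep_len(sex, n)
  if (!any(dead == 1L))
    return(survcurve(numeric(0), numeric(0), numeric(0), kind = "net-pp"))
  tmax <- max(time)
  # integration breakpoints: every distinct follow-up time, refined so no
  # interval exceeds `precision` days
  br <- sort(unique(c(0, time, seq(0, tmax, by = precision), tmax)))
  mids <- (br[-length(br)] + br[-1L]) / 2
  pts <- c(br, mids)
  ord <- order(pts)
  # cumulative population hazard of every subject at every needed point
  C <- matrix(0, n, length(pts))
  for (i in seq_len(n)) {
    kn <- subject_cumhaz_knots(age_at_diagnosis[i], diagnosis_year[i],
                               sex[i], lt, tmax)
    C[i, ] <- stats::approx(kn$x, kn$y, xout = pts, rule = 2L)$y
  }
  W <- exp(C)                        # 1 / S_pop,i
  i_br <- seq_along(br)
  i_mid <- length(br) + seq_along(mids)

  # expected (population) term: exact per-subject integral of w * lambda_pop
  # over each interval (it telescopes to the increment of 1/S_pop), divided
  # by the weighted at-risk total evaluated at the interval midpoint
  d_lambda_pop <- numeric(length(mids))
  at_risk_upper <- outer(time, br[-1L], ">=")   # n x intervals
  for (k in seq_along(mids)) {
    r <- at_risk_upper[, k]
    if (!any(r)) break
    num <- sum(W[r, i_br[k + 1L]] - W[r, i_br[k]])
    den <- sum(W[r, i_mid[k]])
    d_lambda_pop[k] <- num / den
  }

  event_times <- sort(unique(time[dead == 1L]))
  d_lambda_obs <- numeric(length(event_times))
  d_var <- numeric(length(event_times))
  n_risk <- integer(length(event_times))
  n_event <- integer(length(event_times))
  for (j in seq_along(event_times)) {
    t <- event_times[j]
    col <- i_br[match(t, br)]
    risk <- time >= t
    ev <- risk & dead == 1L & time == t
    wden <- sum(W[risk, col])
    d_lambda_obs[j] <- sum(W[ev, col]) / wden
    d_var[j] <- sum(W[ev, col]^2) / wden^2
    n_risk[j] <- sum(risk)
    n_event[j] <- sum(ev)
  }
  cum_pop <- cumsum(d_lambda_pop)
  pop_at <- stats::approx(br[-1L], cum_pop, xout = event_times,
                          rule = 2L)$y
  lambda_excess <- cumsum(d_lambda_obs) - pop_at
  est <- exp(-lambda_excess)
  variance <- est^2 * cumsum(d_var)
  survcurve(event_times, est, variance, n_risk = n_risk,
            n_event = n_event, kind = "net-pp")
}
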