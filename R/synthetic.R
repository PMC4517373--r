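# Synthetic cohort generator with known ground truth. Emulates a
# screening-detected prostate-cancer cohort: men aged 56-78 diagnosed
# 2003-2011, roughly a decade of administrative follow-up, ~11% deceased,
# about one third of observed deaths from prostate cancer, and (by
# default) half of the causes of death masked. Cause-specific event times
# follow constant per-subject hazards with log-linear covariate effects,
# which keeps the generating cause-specific survival computable exactly.

#' Generator configuration
#'
#' Returns the default generator settings; override any field via
#' \code{...}. Baseline hazards are per day; covariate effects are
#' log-linear. The default missingness mechanism masks 50 percent of the
#' causes of death completely at random with an exact count, mirroring a
#' registry in which recent deaths have not yet had their causes coded.
#'
#' @param n cohort size (default 2844).
#' @param ... overrides of the listed defaults.
#' @return list of generator settings.
#' @export
generator_config <- function(n = 2844, ...) {
  cfg <- list(
    n = n,
    age_range = c(56, 78), age_mean = 66, age_sd = 6,
    years = 2003:2011,
    end_year = 2013.5,                    # administrative end of follow-up
    max_followup = 3624,                  # days
    # cause-specific baseline hazards (per day) and log-linear effects
    base_hazard_prostate = 9e-6,
    base_hazard_other = 3e-5,
    beta_prostate = c(age = 0.05, gleason_high = 1.6,
                      gleason_intermediate = 0.7, metastatic = 2.0),
    beta_other = c(age = 0.09),
    mechanism = "MCAR", missing_fraction = 0.5, exact_count = TRUE,
    # MAR: log-odds of masking increases with diagnosis year (recent
    # deaths not yet coded); MNAR: depends on the true cause
    mar_year_slope = 0.8, mnar_prostate_shift = 1.5,
    covariate_missing = c(psa_diag = 0.06, cT = 0.21, cN = 0.64,
                          cM = 0.14, first_treatment = 0.10,
                          gleason_group = 0.05, psa_post = 0.27,
                          pT = 0.06, pN = 0.40))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

truncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates, cause-specific latent event times (constant
#' per-subject hazards with covariate effects), administrative censoring,
#' assigns the cause of the earliest event, then masks causes of death by
#' the configured mechanism and (optionally) punches MAR holes in the
#' covariates. Returns both the masked cohort and the full truth.
#'
#' @param n cohort size, or a full config from \code{\link{generator_config}}
#'   passed as \code{config}.
#' @param config generator configuration (overrides \code{n}).
#' @param seed integer seed; the generator is fully seed-deterministic.
#' @param missing_covariates punch MAR missingness into the clinical
#'   covariates at the configured per-variable rates (default \code{TRUE};
#'   set \code{FALSE} for a complete-covariate cohort).
#' @return list with \code{cohort} (masked), \code{complete} (no masking),
#'   \code{truth} (per-subject hazards, true causes, and
#'   \code{true_cs_survival}, a vectorized function of time in days giving
#'   the exact generating cause-specific survival; see Details).
#' @details The true cause-specific survival is the large-sample limit of
#'   the cause-specific Kaplan-Meier estimator under independent censoring:
#'   \code{S(t) = exp(-int_0^t hbar_p(u) du)} with \code{hbar_p(u)} the
#'   at-risk-weighted average prostate hazard, computed by numerical
#'   integration over the drawn cohort (exact given the constant
#'   per-subject hazards).
#' @export
generate_cohort <- function(n = 2844, config = NULL, seed = NULL,
                            missing_covariates = TRUE) {
  cfg <- config %||% generator_config(n)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  age <- truncnorm1(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1L],
                    cfg$age_range[2L])
  year <- sample(cfg$years, n, replace = TRUE)
  psa <- exp(stats::rnorm(n, log(8), 0.75))
  # Gleason group, loosely PSA-linked
  p_high <- stats::plogis(-2.2 + 0.5 * log(psa / 8))
  p_int <- stats::plogis(-0.4 + 0.3 * log(psa / 8))
  u <- stats::runif(n)
  gleason <- ifelse(u < p_high, "high",
                    ifelse(u < p_high + p_int * (1 - p_high),
                           "intermediate", "low"))
  # clinical stage: screening-era cohorts are dominated by cT1c/cT2
  ct_levels <- c("1a", "1b", "1c", "2a", "2b", "2c", "3a", "3b", "4")
  base_p <- c(0.01, 0.01, 0.48, 0.14, 0.08, 0.08, 0.12, 0.05, 0.03)
  shift <- ifelse(gleason == "high", 2, ifelse(gleason == "intermediate",
                                               0.5, -0.5))
  cT <- vapply(shift, function(s) {
    w <- base_p * exp(s * (seq_along(base_p) - 3) / 6)
    sample(ct_levels, 1L, prob = w / sum(w))
  }, "")
  advanced <- cT %in% c("3a", "3b", "4")
  cN <- stats::rbinom(n, 1L, stats::plogis(-3.6 + 1.6 * advanced +
                                             0.8 * (gleason == "high")))
  cM <- stats::rbinom(n, 1L, stats::plogis(-4.2 + 1.8 * advanced +
                                             0.9 * (gleason == "high")))
  risk_high <- gleason == "high" | psa > 20 | advanced | cN == 1L | cM == 1L
  treat <- mapply(function(hi, a) {
    p <- if (a >= 72) c(0.25, 0.30, 0.25, 0.20)
    else if (hi) c(0.45, 0.30, 0.20, 0.05)
    else c(0.60, 0.15, 0.05, 0.20)
    sample(TREATMENT_LEVELS, 1L, prob = p)
  }, risk_high, age)
  surgery <- treat == "surgery"
  # pathological stage for the surgical subgroup: clinical stage with
  # upstaging noise
  pt_map <- c("1a" = "2a", "1b" = "2a", "1c" = "2a", "2a" = "2a",
              "2b" = "2b", "2c" = "2c", "3a" = "3a", "3b" = "3b", "4" = "4")
  pT <- rep(NA_character_, n)
  up <- stats::runif(n) < 0.25
  pt_levels <- c("2a", "2b", "2c", "3a", "3b", "4")
  pT[surgery] <- pt_map[cT[surgery]]
  idx_up <- surgery & up & pT != "4"
  pT[idx_up] <- pt_levels[pmin(match(pT[idx_up], pt_levels) + 1L, 6L)]
  pN <- rep(NA_integer_, n)
  pN[surgery] <- stats::rbinom(sum(surgery), 1L,
                               stats::plogis(-3 + 2.5 * cN[surgery]))
  psa_post <- ifelse(surgery, exp(stats::rnorm(n, log(0.05), 0.8)),
                     exp(stats::rnorm(n, log(1.5), 1.0)))
  # cause-specific hazards (constant per subject)
  lp_p <- cfg$beta_prostate["age"] * (age - cfg$age_mean) +
    cfg$beta_prostate["gleason_high"] * (gleason == "high") +
    cfg$beta_prostate["gleason_intermediate"] * (gleason == "intermediate") +
    cfg$beta_prostate["metastatic"] * (cM == 1L)
  lp_o <- cfg$beta_other["age"] * (age - cfg$age_mean)
  lambda_p <- cfg$base_hazard_prostate * exp(lp_p)
  lambda_o <- cfg$base_hazard_other * exp(lp_o)
  t_p <- stats::rexp(n, lambda_p)
  t_o <- stats::rexp(n, lambda_o)
  entry <- stats::runif(n)                       # fraction into the year
  cens <- pmin((cfg$end_year - year - entry) * 365.25, cfg$max_followup)
  cens <- pmax(cens, 1)
  t_event <- pmin(t_p, t_o)
  time <- pmax(1, ceiling(pmin(t_event, cens)))
  dead <- as.integer(t_event <= cens)
  true_cause <- ifelse(dead == 1L,
                       ifelse(t_p <= t_o, "prostate", "other"),
                       NA_character_)
  complete <- cohort(data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age_at_diagnosis = age, psa_diag = psa, cT = cT, cN = cN, cM = cM,
    first_treatment = treat, gleason_group = gleason, pT = pT, pN = pN,
    psa_post = psa_post, followup_days = time, dead = dead,
    cause = true_cause, sex = "male", diagnosis_year = year,
    stringsAsFactors = FALSE))
  truth <- list(lambda_p = lambda_p, lambda_o = lambda_o, cens = cens,
                true_cause = true_cause,
                true_cs_survival = make_true_cs_survival(lambda_p, lambda_o,
                                                         cens))
  masked <- mask_causes(complete, truth, mechanism = cfg$mechanism,
                        fraction = cfg$missing_fraction,
                        exact_count = cfg$exact_count,
                        mar_year_slope = cfg$mar_year_slope,
                        mnar_prostate_shift = cfg$mnar_prostate_shift)
  if (missing_covariates)
    masked <- mask_covariates(masked, cfg$covariate_missing)
  list(cohort = masked, complete = complete, truth = truth, config = cfg)
}

# exact generating cause-specific survival: S(t) = exp(-int hbar_p), with
# hbar_p(u) the average prostate hazard among subjects still at risk
# (event-free and uncensored) at u
make_true_cs_survival <- function(lambda_p, lambda_o, cens,
                                  resolution = 601L) {
  tot <- lambda_p + lambda_o
  tmax <- max(cens)
  grid <- seq(0, tmax, length.out = resolution)
  hbar <- vapply(grid, function(u) {
    w <- exp(-tot * u) * (cens >= u)
    sw <- sum(w)
    if (sw <= 0) return(NA_real_)
    sum(lambda_p * w) / sw
  }, numeric(1L))
  hbar[is.na(hbar)] <- hbar[which(!is.na(hbar))[sum(!is.na(hbar))]]
  dg <- diff(grid)
  cum <- c(0, cumsum((hbar[-1L] + hbar[-length(hbar)]) / 2 * dg))
  function(t) {
    exp(-stats::approx(grid, cum, xout = pmin(t, tmax), rule = 2L)$y)
  }
}

#' Mask causes of death by a configurable missingness mechanism
#'
#' Masks the cause of death of a configurable fraction of the deceased.
#' \code{"MCAR"} masks uniformly at random; \code{"MAR"} makes the masking
#' log-odds increase with the (observed) diagnosis year, emulating a
#' registry whose recent causes have not yet been coded; \code{"MNAR"}
#' makes masking depend on the (unobserved) true cause. Under
#' \code{exact_count} the achieved number of masked causes is exact;
#' otherwise it is binomial around the target.
#'
#' @param cohort a cohort whose deceased have observed causes.
#' @param truth truth list from \code{\link{generate_cohort}} (needed for
#'   MNAR; optional otherwise).
#' @param mechanism \code{"MCAR"}, \code{"MAR"} or \code{"MNAR"}.
#' @param fraction target fraction of masked causes among the dead.
#' @param exact_count mask exactly \code{round(fraction * deaths)} causes.
#' @param mar_year_slope,mnar_prostate_shift mechanism parameters (log-odds
#'   scale).
#' @return the cohort with masked causes; masked ids in
#'   \code{attr(, "masked_ids")}.
#' @export
mask_causes <- function(cohort, truth = NULL, mechanism = "MCAR",
                        fraction = 0.5, exact_count = TRUE,
                        mar_year_slope = 0.8, mnar_prostate_shift = 1.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  dead_idx <- which(cohort$dead == 1L & !is.na(cohort$cause))
  k <- round(fraction * length(dead_idx))
  if (k == 0L) {
    attr(cohort, "masked_ids") <- character(0)
    return(cohort)
  }
  if (k > length(dead_idx))
    stop("more causes to mask than observed deaths", call. = FALSE)
  w <- switch(mechanism,
              MCAR = rep(1, length(dead_idx)),
              MAR = {
                yr <- cohort$diagnosis_year[dead_idx]
                exp(mar_year_slope * (yr - stats::median(yr)))
              },
              MNAR = {
                stopifnot(!is.null(truth))
                tc <- truth$true_cause[dead_idx]
                exp(mnar_prostate_shift * (tc == "prostate"))
              },
              stop("unknown mechanism: ", mechanism, call. = FALSE))
  sel <- if (exact_count) {
    dead_idx[sample.int(length(dead_idx), k, prob = w)]
  } else {
    p <- pmin(1, fraction * w / mean(w))
    dead_idx[stats::runif(length(dead_idx)) < p]
  }
  cohort$cause[sel] <- NA
  attr(cohort, "masked_ids") <- cohort$id[sel]
  cohort
}

# punch MAR missingness into covariates: masking log-odds tied to the
# always-observed age and diagnosis year
mask_covariates <- function(cohort, rates) {
  n <- nrow(cohort)
  z <- scale(cohort$age_at_diagnosis)[, 1L] * 0.4 +
    scale(cohort$diagnosis_year)[, 1L] * 0.4
  surgery <- !is.na(cohort$first_treatment) &
    cohort$first_treatment == "surgery"
  for (v in names(rates)) {
    domain <- if (v %in% c("pT", "pN")) surgery else rep(TRUE, n)
    r <- rates[[v]]
    if (r <= 0) next
    lo <- stats::qlogis(r)
    p <- stats::plogis(lo + z)
    hit <- domain & stats::runif(n) < p
    cohort[[v]][hit] <- NA
  }
  # keep the structural invariant: treatment missing makes pT/pN unusable
  cohort$pT[is.na(cohort$first_treatment)] <- NA
  cohort$pN[is.na(cohort$first_treatment)] <- NA
  cohort
}

#' Tabulate a population life table
#'
#' @param ages,years integer grids.
#' @param rate_fn function of (age, year) returning a rate per person-year,
#'   or a preset name: \code{"zero"} (all rates 0) or \code{"gompertz"}
#'   (male-like exponential age increase,
#'   \code{0.012 * exp(0.085 (age - 60))}).
#' @param sex sex label for the table.
#' @return a \code{\link{life_table}}.
#' @export
generate_life_table <- function(ages = 50:100, years = 2000:2015,
                                rate_fn = "gompertz", sex = "male") {
  f <- if (is.function(rate_fn)) rate_fn
  else switch(rate_fn,
              zero = function(age, year) rep(0, length(age)),
              gompertz = function(age, year) 0.012 * exp(0.085 * (age - 60)),
              stop("unknown preset: ", rate_fn))
  g <- expand.grid(age = ages, year = years)
  life_table(data.frame(sex = sex, age = g$age, year = g$year,
                        rate = pmax(0, f(g$age, g$year))))
}

#' Simulate deaths exactly at population rates
#'
#' Draws death times from the life-table hazard along the age/period
#' diagonal (piecewise-constant inversion). Useful for checking that the
#' net-survival estimator is centred at 1 when cohort mortality matches
#' the population expectation.
#'
#' @param age,year vectors of ages and diagnosis years.
#' @param lt a \code{\link{life_table}}.
#' @param sex sex label.
#' @param horizon administrative censoring (days).
#' @return data.frame with \code{time} (days) and \code{dead}.
#' @export
simulate_population_deaths <- function(age, year, lt, sex = "male",
                                       horizon = 3650) {
  n <- length(age)
  time <- numeric(n)
  dead <- integer(n)
  for (i in seq_len(n)) {
    kn <- subject_cumhaz_knots(age[i], year[i], sex, lt, horizon)
    e <- stats::rexp(1L)
    if (e >= kn$y[length(kn$y)]) {
      time[i] <- horizon; dead[i] <- 0L
    } else {
      time[i] <- stats::approx(kn$y, kn$x, xout = e, ties = "ordered")$y
      dead[i] <- 1L
    }
  }
  data.frame(time = pmax(1, ceiling(time)), dead = dead)
}
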