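# fixtures built in code: tiny hand-checkable cohorts and design matrices

toy_cohort <- function() {
  cohort(data.frame(
    id = paste0("T", 1:6),
    age_at_diagnosis = c(60, 65, 70, 62, 68, 74),
    psa_diag = c(5, 12, 25, 8, 15, 30),
    cT = c("1c", "2a", "3a", "1c", "2b", "4"),
    cN = c(0L, 0L, 1L, 0L, 0L, 1L),
    cM = c(0L, 0L, 0L, 0L, 0L, 1L),
    first_treatment = c("surgery", "radiotherapy", "hormone+chemo",
                        "surgery", "surveillance+HIFU", "hormone+chemo"),
    gleason_group = c("low", "intermediate", "high", "low",
                      "intermediate", "high"),
    pT = c("2a", NA, NA, "2b", NA, NA),
    pN = c(0L, NA, NA, 0L, NA, NA),
    psa_post = c(0.02, 1.5, 4, 0.05, 2, 8),
    followup_days = c(100, 200, 300, 400, 500, 600),
    dead = c(0L, 1L, 1L, 0L, 1L, 1L),
    cause = c(NA, "other", "prostate", NA, "other", "prostate"),
    sex = "male",
    diagnosis_year = c(2004, 2005, 2006, 2007, 2008, 2009),
    stringsAsFactors = FALSE))
}

# hand product-limit computation, independent of survival::survfit
hand_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = et, surv = NA_real_, var = NA_real_)
  gw <- 0
  for (k in seq_along(et)) {
    n_risk <- sum(time >= et[k])
    d <- sum(time == et[k] & event == 1)
    s <- s * (1 - d / n_risk)
    if (n_risk > d) gw <- gw + d / (n_risk * (n_risk - d))
    out$surv[k] <- s
    out$var[k] <- s^2 * gw
  }
  out
}

# hand Aalen-Johansen cumulative incidence for cause `k`
hand_cif <- function(time, status, k) {
  et <- sort(unique(time[status != 0]))
  s_prev <- 1
  cif <- 0
  out <- data.frame(time = et, cif = NA_real_)
  for (j in seq_along(et)) {
    n_risk <- sum(time >= et[j])
    d_all <- sum(time == et[j] & status != 0)
    d_k <- sum(time == et[j] & status == k)
    cif <- cif + s_prev * d_k / n_risk
    s_prev <- s_prev * (1 - d_all / n_risk)
    out$cif[j] <- cif
  }
  out
}
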