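# Sensitivity-analysis protocols for the imputation model. Each protocol
# deliberately masks causes of death, re-imputes them with the same model,
# pools the per-dataset cause-specific curves, and measures how often the
# "true" curve lies inside the pooled 95% confidence band (pointwise, over
# the pooled grid). The coverage scalar is this package's summary of what
# is usually judged visually from overlaid curves.

# impute -> cause-specific KM per completed dataset -> pool
run_mi_pool <- function(cohort, m = 20L, maxit = 20L, seed = NULL, ...) {
  fit <- mice_impute(cohort, m = m, maxit = maxit, seed = seed, ...)
  curves <- lapply(fit$imputations, function(d)
    cs_km_curve(d$followup_days, d$dead, d$cause))
  list(fit = fit, pooled = pool_curves(curves))
}

coverage_fraction <- function(true_curve, pooled, tol = 1e-9) {
  tr <- eval_curve(true_curve, pooled$time)$estimate
  mean(tr >= pooled$ci_low - tol & tr <= pooled$ci_high + tol)
}

new_sensitivity_run <- function(protocol, fraction, seed, true_curve,
                                pooled) {
  structure(list(protocol = protocol, fraction = fraction, seed = seed,
                 true_curve = true_curve, pooled = pooled,
                 coverage = coverage_fraction(true_curve, pooled)),
            class = "sensitivity_run")
}

#' @export
print.sensitivity_run <- function(x, ...) {
  cat(sprintf("Sensitivity run [%s]%s: coverage %.3f over %d grid points\n",
              x$protocol,
              if (is.na(x$fraction)) "" else
                sprintf(" (%.0f%% masked)", 100 * x$fraction),
              x$coverage, length(x$pooled$time)))
  invisible(x)
}

#' Sub-cohort for the random-removal protocol
#'
#' Keeps every deceased patient with a known cause of death together with a
#' simple random sample of half of the patients still alive, preserving a
#' dead/alive ratio comparable to the full cohort's.
#'
#' @param cohort a cohort.
#' @param seed integer seed.
#' @return a cohort.
#' @export
build_subcohort <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dead_known <- which(cohort$dead == 1L & !is.na(cohort$cause))
  alive <- which(cohort$dead == 0L)
  keep <- c(dead_known, sample(alive, floor(length(alive) / 2)))
  out <- cohort[sort(keep), , drop = FALSE]
  class(out) <- class(cohort)
  out
}

#' Sensitivity protocol 1: random removal of known causes
#'
#' Starting from a cohort whose deceased all have a known cause of death,
#' masks each listed fraction of causes uniformly at random (MCAR by
#' construction), re-imputes with the standard model, pools, and compares
#' the pooled curve with the true cause-specific curve of the unmasked
#' cohort.
#'
#' @param complete_cohort cohort with zero missing causes among the dead.
#' @param fractions masking fractions in (0, 1)
#'   (default \code{c(.1, .3, .5, .7, .9)}).
#' @param m,maxit imputation settings.
#' @param seed integer seed.
#' @param ... passed to \code{\link{mice_impute}}.
#' @return list of \code{"sensitivity_run"}, one per fraction.
#' @export
protocol_random_removal <- function(complete_cohort,
                                    fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                    m = 20L, maxit = 20L, seed = NULL,
                                    ...) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie in (0, 1)", call. = FALSE)
  if (any(complete_cohort$dead == 1L & is.na(complete_cohort$cause)))
    stop("complete_cohort must have no missing causes among the dead",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  true_curve <- cs_km_curve(complete_cohort$followup_days,
                            complete_cohort$dead, complete_cohort$cause)
  lapply(fractions, function(f) {
    masked <- mask_causes(complete_cohort, mechanism = "MCAR", fraction = f)
    res <- run_mi_pool(masked, m = m, maxit = maxit, ...)
    new_sensitivity_run("random-removal", f, seed, true_curve, res$pooled)
  })
}

#' Sensitivity protocol 2: re-impute the originally observed causes
#'
#' For each first-level completed dataset, deletes the causes of death that
#' were \emph{observed} in the original data, keeps the first-level imputed
#' causes as pseudo-truth, re-imputes the deleted set with the same model
#' and compares the pooled curve against that completed dataset's own
#' cause-specific curve. The MAR assumption is preserved if the original
#' mechanism was MAR.
#'
#' @param fit a first-level \code{"mice_fit"} on a cohort with genuinely
#'   missing causes.
#' @param m,maxit second-level imputation settings (default: the
#'   first-level settings).
#' @param seed integer seed.
#' @param datasets indices of first-level datasets to process (default
#'   all).
#' @param ... passed to \code{\link{mice_impute}}.
#' @return list of \code{"sensitivity_run"}, one per first-level dataset.
#' @export
protocol_reimpute_original <- function(fit, m = NULL, maxit = NULL,
                                       seed = NULL, datasets = NULL, ...) {
  stopifnot(inherits(fit, "mice_fit"))
  if (!is.null(seed)) set.seed(seed)
  m <- m %||% fit$m
  maxit <- maxit %||% fit$maxit
  datasets <- datasets %||% seq_len(fit$m)
  observed_cause <- fit$data$dead == 1L & !is.na(fit$data$cause)
  if (!any(observed_cause))
    stop("no originally observed causes to delete", call. = FALSE)
  lapply(datasets, function(i) {
    d <- complete_data(fit, i)
    true_curve <- cs_km_curve(d$followup_days, d$dead, d$cause)
    masked <- d
    masked$cause[observed_cause] <- NA
    res <- run_mi_pool(cohort(masked), m = m, maxit = maxit, ...)
    new_sensitivity_run("reimpute-original-missing", NA_real_, seed,
                        true_curve, res$pooled)
  })
}

#' Sensitivity protocol 3: cross-validation by random re-masking
#'
#' Like protocol 2, but instead of deleting the originally observed causes,
#' a uniform random draw of \code{n_mask} causes among all deceased
#' subjects of each completed dataset is deleted and re-imputed.
#'
#' @inheritParams protocol_reimpute_original
#' @param n_mask number of causes to mask per completed dataset (default:
#'   the number of originally missing causes).
#' @return list of \code{"sensitivity_run"}, one per first-level dataset.
#' @export
protocol_cross_validation <- function(fit, n_mask = NULL, m = NULL,
                                      maxit = NULL, seed = NULL,
                                      datasets = NULL, ...) {
  stopifnot(inherits(fit, "mice_fit"))
  if (!is.null(seed)) set.seed(seed)
  m <- m %||% fit$m
  maxit <- maxit %||% fit$maxit
  datasets <- datasets %||% seq_len(fit$m)
  n_mask <- n_mask %||% sum(fit$where[, "cause"])
  lapply(datasets, function(i) {
    d <- complete_data(fit, i)
    dead_idx <- which(d$dead == 1L)
    if (n_mask > length(dead_idx))
      stop("n_mask exceeds the number of deaths", call. = FALSE)
    true_curve <- cs_km_curve(d$followup_days, d$dead, d$cause)
    masked <- d
    if (n_mask > 0L)
      masked$cause[sample(dead_idx, n_mask)] <- NA
    res <- run_mi_pool(cohort(masked), m = m, maxit = maxit, ...)
    new_sensitivity_run("cross-validation", NA_real_, seed, true_curve,
                        res$pooled)
  })
}

#' Export a sensitivity run as delimited text
#'
#' Writes the pooled grid with the truth, the pooled estimate, the
#' confidence bounds and an inside-CI flag.
#'
#' @param run a \code{"sensitivity_run"}.
#' @param path output path.
#' @param sep separator.
#' @export
write_sensitivity_run <- function(run, path, sep = "\t") {
  tr <- eval_curve(run$true_curve, run$pooled$time)$estimate
  out <- data.frame(time = run$pooled$time, truth = tr,
                    pooled = run$pooled$S, ci_low = run$pooled$ci_low,
                    ci_high = run$pooled$ci_high,
                    inside = as.integer(tr >= run$pooled$ci_low &
                                          tr <= run$pooled$ci_high))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
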