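# Missing-mechanism screening in the style of Dixon's MCAR test battery:
# the cohort is split by the missingness indicator of a target variable and
# each companion variable is compared between the two groups
# (Mann-Whitney-Wilcoxon for continuous companions, Fisher's exact test for
# categorical ones). A significant comparison is evidence against MCAR
# (the data are then MAR or MNAR; MAR vs MNAR is untestable).

#' Dixon-style MCAR screening battery
#'
#' Splits the cohort by the missingness indicator of \code{target} and
#' tests every companion variable for a distributional difference between
#' the target-missing and target-observed groups: Mann-Whitney-Wilcoxon for
#' continuous companions, Fisher's exact test for categorical ones (exact
#' for 2x2; Monte-Carlo for larger tables when the network algorithm runs
#' out of workspace). P-values are adjusted for repeat testing
#' (Bonferroni by default) before the verdict.
#'
#' @param data a cohort (or any data.frame).
#' @param target variable whose missingness is screened.
#' @param companions character vector of companion variables.
#' @param alpha significance level for the verdict (default 0.05).
#' @param p_adjust multiplicity rule: \code{"bonferroni"} (default),
#'   \code{"holm"} or \code{"none"}.
#' @param subset optional logical vector restricting to the rows on which
#'   \code{target} is defined (defaults to the deceased when
#'   \code{target = "cause"}).
#' @return object of class \code{"missingness_report"}: a data.frame of
#'   per-companion tests plus a \code{verdict} attribute,
#'   \code{"consistent-with-MCAR"} or \code{"evidence-against-MCAR"}.
#' @export
dixon_battery <- function(data, target, companions, alpha = 0.05,
                          p_adjust = c("bonferroni", "holm", "none"),
                          subset = NULL) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(subset) && identical(target, "cause") &&
      !is.null(data$dead))
    subset <- data$dead == 1L
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  miss <- is.na(data[[target]])
  if (!any(miss) || all(miss))
    stop("target must have both missing and observed values", call. = FALSE)
  rows <- lapply(companions, function(v) {
    x <- data[[v]]
    cc <- !is.na(x)
    if (length(unique(x[cc])) < 2L)
      return(data.frame(companion = v, test = "skipped",
                        statistic = NA_real_, p_value = NA_real_,
                        note = "constant companion"))
    if (is.numeric(x) && !is_binary01(x)) {
      tst <- suppressWarnings(stats::wilcox.test(x[cc & miss], x[cc & !miss]))
      data.frame(companion = v, test = "mann-whitney",
                 statistic = unname(tst$statistic), p_value = tst$p.value,
                 note = "")
    } else {
      tab <- table(droplevels(factor(x[cc])), miss[cc])
      tst <- tryCatch(stats::fisher.test(tab, workspace = 2e6),
                      error = function(e)
                        stats::fisher.test(tab, simulate.p.value = TRUE,
                                           B = 10000L))
      data.frame(companion = v, test = "fisher-exact",
                 statistic = NA_real_, p_value = tst$p.value, note = "")
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  verdict <- if (any(out$p_adjusted < alpha, na.rm = TRUE))
    "evidence-against-MCAR" else "consistent-with-MCAR"
  structure(out, target = target, alpha = alpha, verdict = verdict,
            class = c("missingness_report", "data.frame"))
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("Missingness screen for '%s' (alpha = %g)\n",
              attr(x, "target"), attr(x, "alpha")))
  print.data.frame(x, digits = 3L, row.names = FALSE)
  cat("verdict:", attr(x, "verdict"), "\n")
  invisible(x)
}

#' Baseline covariate distribution by missingness of a target
#'
#' For each covariate, tabulates counts and percents among the rows where
#' \code{target} is observed, missing, and overall, with a chi-square test
#' of the observed-vs-missing contrast. An explicit \code{"missing"} level
#' captures covariate missingness itself.
#'
#' @inheritParams dixon_battery
#' @param covariates character vector of categorical covariates.
#' @return data.frame with one row per covariate level and a chi-square
#'   p-value per covariate.
#' @export
baseline_by_missingness <- function(data, target, covariates,
                                    subset = NULL) {
  if (is.null(subset) && identical(target, "cause") && !is.null(data$dead))
    subset <- data$dead == 1L
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  miss <- is.na(data[[target]])
  out <- lapply(covariates, function(v) {
    x <- as.character(data[[v]])
    x[is.na(x)] <- "missing"
    lev <- unique(x)
    tab <- table(factor(x, levels = lev), miss)
    obs <- tab[, "FALSE"]; mis <- tab[, "TRUE"]
    p <- tryCatch(suppressWarnings(
      stats::chisq.test(tab[, c("FALSE", "TRUE")])$p.value),
      error = function(e) NA_real_)
    data.frame(covariate = v, level = lev,
               n_observed = as.integer(obs),
               pct_observed = round_half_up(100 * obs / sum(obs), 1),
               n_missing = as.integer(mis),
               pct_missing = round_half_up(100 * mis / sum(mis), 1),
               n_total = as.integer(obs + mis),
               pct_total = round_half_up(100 * (obs + mis) /
                                           sum(obs + mis), 1),
               chisq_p = p, row.names = NULL)
  })
  do.call(rbind, out)
}
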