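# Fully conditional specification (chained equations) for the prostate
# cohort data model: per-variable methods, conditional imputation domains
# (cause of death among the deceased, pT/pN among surgical patients),
# passive derived variables, and Gelman-Rubin convergence statistics.

IMPUTABLE <- c("psa_diag", "cT", "cN", "cM", "gleason_group",
               "first_treatment", "pT", "pN", "psa_post", "cause")
PASSIVE_VARS <- c("T_new", "N_new", "damico_group")

default_methods <- function() {
  c(psa_diag = "pmm", cT = "multinomial", cN = "logistic", cM = "logistic",
    gleason_group = "multinomial", first_treatment = "multinomial",
    pT = "multinomial", pN = "logistic", psa_post = "pmm",
    cause = "logistic")
}

# clinical chronological visiting order
default_visit <- function() {
  c("psa_diag", "cT", "cN", "cM", "gleason_group", "first_treatment",
    "pT", "pN", "psa_post", "cause")
}

# imputation domains: where is each variable defined at all?
domain_of <- function(data, var) {
  switch(var,
         cause = !is.na(data$dead) & data$dead == 1L,
         pT = ,
         pN = !is.na(data$first_treatment) &
           data$first_treatment == "surgery",
         rep(TRUE, nrow(data)))
}

#' Default predictor matrix for a cohort
#'
#' Builds a \code{\link{quickpred}} screen over the imputable clinical
#' variables, age, the passive derived variables and (optionally) follow-up
#' time, the event indicator and a Nelson-Aalen cumulative-hazard transform
#' of time, then applies the structural overrides: passive and complete
#' variables receive no imputation model of their own (all-zero rows), and
#' \code{pT}/\code{pN} are never used as predictors (they are undefined
#' outside the surgical subgroup; \code{T_new}/\code{N_new} carry their
#' information everywhere).
#'
#' @param data a cohort.
#' @param mincor,minpuc \code{\link{quickpred}} thresholds (defaults 0.1 and
#'   0.4).
#' @param use_outcome also offer follow-up time, the event indicator and the
#'   Nelson-Aalen cumulative hazard as candidate predictors (default
#'   \code{FALSE}).
#' @return 0/1 matrix over the imputation variable set; edit rows freely
#'   before passing it to \code{\link{mice_impute}}.
#' @export
cohort_predictor_matrix <- function(data, mincor = 0.1, minpuc = 0.4,
                                    use_outcome = FALSE) {
  data <- add_derived(data)
  cols <- c(IMPUTABLE, "age_at_diagnosis", PASSIVE_VARS)
  d <- as.data.frame(data)[cols]
  if (use_outcome) {
    d$followup_days <- data$followup_days
    d$dead <- data$dead
    d$nelson_aalen <- nelson_aalen_predictor(data$followup_days, data$dead)
  }
  m <- quickpred(d, mincor = mincor, minpuc = minpuc)
  m[c("age_at_diagnosis", PASSIVE_VARS), ] <- 0L
  if (use_outcome) m[c("followup_days", "dead", "nelson_aalen"), ] <- 0L
  m[, c("pT", "pN")] <- 0L
  # a passive variable must never predict a variable it derives from:
  # that would feed a target's own current imputations back into its
  # imputation model (for surgical rows T_new *is* pT) and the chains lock
  # into self-reinforcing states instead of mixing
  derives_from <- list(
    T_new = c("cT", "pT", "first_treatment"),
    N_new = c("cN", "pN", "first_treatment"),
    damico_group = c("psa_diag", "gleason_group", "cT", "cN", "cM"))
  for (pv in names(derives_from))
    m[derives_from[[pv]], pv] <- 0L
  m
}

# marginal Nelson-Aalen cumulative hazard at each subject's follow-up time,
# an optional imputation-model predictor for survival outcomes
nelson_aalen_predictor <- function(time, event) {
  f <- survival::survfit(survival::Surv(time, event) ~ 1)
  H <- cumsum(f$n.event / f$n.risk)
  step_eval(f$time, H, time, left = 0)
}

#' Multiple imputation of a cohort by chained equations
#'
#' Creates \code{m} completed cohorts by fully conditional specification.
#' Missing values are initialized by random draws from the observed
#' marginals; each of \code{maxit} iterations then sweeps the visiting
#' sequence, re-imputing every incomplete variable from its current
#' predictors with the method registered for it (predictive mean matching
#' for continuous variables, logistic regression for binary ones, a
#' multinomial logit for unordered categories). Cause of death is imputed
#' only for the deceased, and \code{pT}/\code{pN} only where the (current)
#' first treatment is surgery; the derived variables \code{T_new},
#' \code{N_new} and the d'Amico group are recomputed passively after every
#' update. Chain means and variances of the imputed values are recorded at
#' every iteration for convergence assessment via \code{\link{rhat}}.
#'
#' @param data a cohort (see \code{\link{cohort}}).
#' @param m number of imputed datasets (default 20).
#' @param maxit iterations per chain (default 20).
#' @param predictor_matrix 0/1 matrix as from
#'   \code{\link{cohort_predictor_matrix}} (the default).
#' @param method named character vector overriding the per-variable methods.
#' @param visit visiting sequence (variable names); default is the clinical
#'   chronological order ending with cause of death.
#' @param donors donor-pool size for predictive mean matching.
#' @param seed integer seed; fixed seeds give bit-identical results.
#' @param verbose print per-chain progress.
#' @return object of class \code{"mice_fit"}: completed cohorts
#'   (\code{$imputations}), the missingness map (\code{$where}), chain
#'   statistics and the call parameters. Use \code{\link{complete_data}} to
#'   extract a completed cohort and \code{\link{rhat}} /
#'   \code{\link{compare_observed_imputed}} for diagnostics.
#' @export
#' @examples
#' coh <- generate_cohort(n = 200, seed = 7)$cohort
#' fit <- mice_impute(coh, m = 2, maxit = 2, seed = 1)
#' rhat(fit)
mice_impute <- function(data, m = 20L, maxit = 20L,
                        predictor_matrix = NULL, method = NULL,
                        visit = NULL, donors = 5L, seed = NULL,
                        verbose = FALSE) {
  data <- cohort(data)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(predictor_matrix))
    predictor_matrix <- cohort_predictor_matrix(data)
  meth <- default_methods()
  if (!is.null(method)) meth[names(method)] <- method
  visit <- visit %||% default_visit()
  stopifnot(all(visit %in% IMPUTABLE), !anyDuplicated(visit))

  base <- add_derived(as.data.frame(data))
  where <- sapply(IMPUTABLE, function(v) is.na(base[[v]]) & domain_of(base, v))
  active <- visit[colSums(where[, visit, drop = FALSE]) > 0L]
  n_iter_used <- if (length(active)) maxit else 0L

  chain_mean <- array(NA_real_, c(length(active), maxit, m),
                      dimnames = list(active, NULL, NULL))
  chain_sd <- chain_mean
  imputations <- vector("list", m)

  for (chain in seq_len(m)) {
    cur <- init_missing(base, where, active)
    for (it in seq_len(n_iter_used)) {
      for (v in active) {
        cur <- impute_one(cur, v, where[, v], predictor_matrix, meth[v],
                          donors)
        cur <- refresh_domains(cur, base, where)
        cur <- add_derived(cur)
      }
      for (v in active) {
        vals <- num_code(cur[[v]])[where[, v]]
        chain_mean[v, it, chain] <- mean(vals)
        chain_sd[v, it, chain] <- stats::sd(vals)
      }
    }
    imputations[[chain]] <- cur
    if (verbose) message(sprintf("chain %d/%d done", chain, m))
  }
  structure(list(data = data, where = where, m = m, maxit = maxit,
                 method = meth, visit = visit, active = active,
                 predictor_matrix = predictor_matrix, seed = seed,
                 imputations = imputations,
                 chain_mean = chain_mean, chain_sd = chain_sd),
            class = "mice_fit")
}

# initialize: fill every to-impute position with a random draw from the
# observed marginal of its variable (restricted to the variable's domain)
init_missing <- function(base, where, active) {
  cur <- base
  for (v in active) {
    obs <- cur[[v]][!is.na(cur[[v]])]
    if (!length(obs)) stop("no observed values to initialize ", v)
    idx <- which(where[, v])
    cur[[v]][idx] <- obs[sample.int(length(obs), length(idx),
                                    replace = TRUE)]
  }
  add_derived(cur)
}

# keep conditional domains coherent when first_treatment itself changes:
# pT/pN must be defined exactly on the current surgical subgroup
refresh_domains <- function(cur, base, where) {
  surgery <- !is.na(cur$first_treatment) & cur$first_treatment == "surgery"
  for (v in c("pT", "pN")) {
    obs <- !is.na(base[[v]])
    off <- !surgery & !obs
    cur[[v]][off] <- base[[v]][off]           # NA outside the domain
    need <- surgery & !obs & is.na(cur[[v]])
    if (any(need)) {                          # entered the domain this sweep
      pool <- cur[[v]][surgery & !is.na(cur[[v]])]
      if (length(pool))
        cur[[v]][need] <- pool[sample.int(length(pool), sum(need),
                                          replace = TRUE)]
    }
  }
  dead <- !is.na(cur$dead) & cur$dead == 1L
  cur$cause[!dead & is.na(base$cause)] <- base$cause[!dead &
                                                       is.na(base$cause)]
  cur
}

# one conditional-imputation update of variable v on its current domain
impute_one <- function(cur, v, targets, pm, method, donors) {
  dom <- domain_of(cur, v)
  todo <- targets & dom
  if (!any(todo)) return(cur)
  preds <- colnames(pm)[pm[v, ] == 1L]
  obs <- dom & !targets & !is.na(cur[[v]])
  X <- build_design(cur, preds, obs | todo)
  X_obs <- X[obs[obs | todo], , drop = FALSE]
  X_mis <- X[todo[obs | todo], , drop = FALSE]
  y_obs <- cur[[v]][obs]
  imp <- switch(method,
                pmm = impute_pmm(y_obs, X_obs, X_mis, donors),
                logistic = impute_logistic(y_obs, X_obs, X_mis),
                multinomial = impute_multinomial(as_factor(y_obs), X_obs,
                                                 X_mis),
                stop("unknown imputation method: ", method))
  if (is.factor(cur[[v]]) && !is.factor(imp))
    imp <- factor(as.character(imp), levels = levels(cur[[v]]))
  if (is.integer(cur[[v]])) imp <- as.integer(as.character(imp))
  cur[[v]][todo] <- imp
  cur
}

as_factor <- function(x) if (is.factor(x)) x else factor(x)

# model matrix over the requested predictor columns on the given rows;
# drops predictors that are missing or constant on those rows
build_design <- function(cur, preds, rows) {
  d <- cur[rows, preds, drop = FALSE]
  usable <- vapply(d, function(col) {
    !anyNA(col) && length(unique(col)) > 1L
  }, TRUE)
  d <- d[, usable, drop = FALSE]
  d <- droplevels(d)
  if (ncol(d) == 0L)
    return(matrix(1, sum(rows), 1L, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., data = d)
}

#' Extract one completed cohort
#'
#' @param fit a \code{"mice_fit"}.
#' @param i imputation index in \code{1..m}.
#' @return the i-th completed cohort (with derived columns).
#' @export
complete_data <- function(fit, i = 1L) {
  stopifnot(inherits(fit, "mice_fit"), i >= 1L, i <= fit$m)
  fit$imputations[[i]]
}

#' Gelman-Rubin potential scale reduction of the imputation chains
#'
#' Computes the potential-scale-reduction statistic on the per-iteration
#' chain means of the imputed values for each variable: with \code{W} the
#' mean within-chain variance of those means over iterations and \code{B/n}
#' the between-chain variance, \code{Rhat = sqrt(((n-1)/n W + B/n) / W)}.
#' Values below 1.1 are conventionally read as convergence of the chained
#' equations. Chains with zero within-variance (degenerate imputations)
#' return 1 with a warning.
#'
#' @param fit a \code{"mice_fit"}, or a numeric matrix (iterations x chains)
#'   of chain summaries.
#' @return named numeric vector of per-variable statistics (or a scalar for
#'   a matrix input).
#' @export
rhat <- function(fit) {
  if (is.matrix(fit)) return(gelman_rhat(fit))
  stopifnot(inherits(fit, "mice_fit"))
  if (fit$m < 2L || fit$maxit < 2L)
    stop("rhat needs at least 2 chains and 2 iterations", call. = FALSE)
  out <- vapply(fit$active, function(v)
    gelman_rhat(fit$chain_mean[v, , , drop = TRUE]), numeric(1L))
  names(out) <- fit$active
  out
}

gelman_rhat <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  n <- nrow(x)
  w <- mean(apply(x, 2L, stats::var))
  b_over_n <- stats::var(colMeans(x))
  if (!is.finite(w) || w <= 0) {
    warning("zero within-chain variance; Rhat set to 1", call. = FALSE)
    return(1)
  }
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Compare observed and imputed distributions of a variable
#'
#' For a categorical variable, tabulates the observed category counts and
#' the minimum / mean / median / maximum of the imputed category counts
#' across the m completed datasets, together with a chi-square test of the
#' observed distribution against the mean imputed one. For a continuous
#' variable, returns quantile summaries of observed versus pooled imputed
#' values with a Kolmogorov-Smirnov style quantile overlay.
#'
#' @param fit a \code{"mice_fit"}.
#' @param variable name of an imputed variable.
#' @return list with components \code{table} (the comparison) and
#'   \code{p_value}.
#' @export
compare_observed_imputed <- function(fit, variable) {
  stopifnot(inherits(fit, "mice_fit"))
  if (!variable %in% fit$active)
    stop(variable, " was not imputed", call. = FALSE)
  w <- fit$where[, variable]
  base <- fit$data
  obs <- base[[variable]][!is.na(base[[variable]])]
  imp_list <- lapply(fit$imputations, function(d) d[[variable]][w])
  if (is.factor(obs) || is_binary01(obs)) {
    lev <- if (is.factor(obs)) levels(droplevels(obs)) else sort(unique(obs))
    tab_obs <- table(factor(obs, levels = lev))
    counts <- sapply(imp_list, function(v) table(factor(v, levels = lev)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                               dimnames = list(lev))
    tab <- data.frame(
      level = lev,
      observed = as.integer(tab_obs),
      observed_pct = round_half_up(100 * as.integer(tab_obs) /
                                     sum(tab_obs), 1),
      imputed_min = apply(counts, 1L, min),
      imputed_mean = rowMeans(counts),
      imputed_median = apply(counts, 1L, stats::median),
      imputed_max = apply(counts, 1L, max),
      row.names = NULL)
    exp_counts <- rowMeans(counts)
    p <- tryCatch(suppressWarnings(
      stats::chisq.test(cbind(as.integer(tab_obs), exp_counts))$p.value),
      error = function(e) NA_real_)
    list(table = tab, p_value = p)
  } else {
    qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
    imp_all <- unlist(imp_list)
    tab <- data.frame(quantile = qs,
                      observed = stats::quantile(obs, qs, names = FALSE),
                      imputed = stats::quantile(imp_all, qs, names = FALSE))
    p <- tryCatch(suppressWarnings(
      stats::ks.test(obs, imp_all)$p.value), error = function(e) NA_real_)
    list(table = tab, p_value = p)
  }
}

#' @export
print.mice_fit <- function(x, ...) {
  cat("Chained-equations imputation\n")
  cat(sprintf("  n = %d patients, m = %d imputations, %d iterations\n",
              nrow(x$data), x$m, x$maxit))
  cat("  imputed:", paste(x$active, collapse = ", "), "\n")
  if (x$m >= 2L && x$maxit >= 2L) {
    r <- rhat(x)
    cat(sprintf("  max Rhat = %.3f (%s)\n", max(r),
                if (max(r) < 1.1) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
summary.mice_fit <- function(object, ...) {
  r <- if (object$m >= 2L && object$maxit >= 2L) rhat(object) else NULL
  miss <- colSums(object$where[, object$active, drop = FALSE])
  out <- data.frame(variable = object$active,
                    method = unname(object$method[object$active]),
                    n_missing = as.integer(miss),
                    rhat = if (is.null(r)) NA_real_ else unname(r),
                    row.names = NULL)
  class(out) <- c("summary.mice_fit", "data.frame")
  out
}

#' Trace plot of imputation chain means
#'
#' @param x a \code{"mice_fit"}.
#' @param variables variables to plot (default: all imputed).
#' @param ... passed to \code{matplot}.
#' @export
plot.mice_fit <- function(x, variables = NULL, ...) {
  variables <- variables %||% x$active
  variables <- intersect(variables, x$active)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)))
  on.exit(graphics::par(old))
  for (v in variables)
    graphics::matplot(x$chain_mean[v, , ], type = "l", lty = 1L,
                      xlab = "iteration", ylab = "mean of imputed values",
                      main = v, ...)
  invisible(x)
}
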