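# Pooling of m survival curves by Rubin's rules on the complementary
# log-log scale. Per-imputation survival probabilities are transformed by
# Q = log(-log(1 - S)); their variances are carried to the transformed
# scale by the delta method, pooled as within-variance Ubar plus
# between-variance B into the total T = Ubar + (1 + 1/m) B, and the pooled
# estimate and its normal-theory confidence bounds are back-transformed by
# S = 1 - exp(-exp(Q)).

#' Complementary log-log transform of a survival probability
#'
#' \code{cll_transform(S) = log(-log(1 - S))}; strictly increasing on
#' (0, 1). \code{cll_back} is its inverse, \code{1 - exp(-exp(Q))}.
#'
#' @param S survival probability in (0, 1) (values in [0, 1] are accepted;
#'   the endpoints map to -Inf/Inf).
#' @param Q transformed value.
#' @return transformed value(s) / probability(ies).
#' @export
#' @examples
#' cll_back(cll_transform(0.3))  # 0.3
cll_transform <- function(S) {
  if (any(S < 0 | S > 1, na.rm = TRUE))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  log(-log1p(-S))
}

#' @rdname cll_transform
#' @export
cll_back <- function(Q) -expm1(-exp(Q))

#' Delta-method variance on the complementary log-log scale
#'
#' Carries the variance of a survival estimate to the transformed scale:
#' \code{Var[Q] ~ Var[S] / (log(1 - S) * (1 - S))^2}.
#'
#' @param S survival probability in (0, 1).
#' @param var_S variance of the survival estimate (>= 0).
#' @return transformed-scale variance.
#' @export
delta_variance <- function(S, var_S) {
  if (any(S < 0 | S > 1, na.rm = TRUE))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (any(var_S < 0, na.rm = TRUE))
    stop("variances must be nonnegative", call. = FALSE)
  var_S / (log1p(-S) * (1 - S))^2
}

#' Rubin's rules
#'
#' Pools m per-imputation estimates \code{Q_hats} and their variances
#' \code{Us}: pooled estimate \code{Q_bar = mean(Q_hats)}, within-variance
#' \code{U_bar = mean(Us)}, between-variance \code{B} (the sample variance
#' of the \code{Q_hats}) and total variance
#' \code{T = U_bar + (1 + 1/m) B}.
#'
#' @param Q_hats numeric vector of m estimates (m >= 2).
#' @param Us numeric vector of m variances.
#' @return list with \code{Q_bar}, \code{U_bar}, \code{B}, \code{T_total},
#'   \code{m}.
#' @export
#' @examples
#' rubin_pool(c(0, 2), c(1, 1))  # Q_bar 1, U_bar 1, B 2, T 4
rubin_pool <- function(Q_hats, Us) {
  m <- length(Q_hats)
  if (m < 2L)
    stop("Rubin's rules need m >= 2 imputations", call. = FALSE)
  stopifnot(length(Us) == m, all(is.finite(Q_hats)), all(is.finite(Us)))
  Q_bar <- mean(Q_hats)
  U_bar <- mean(Us)
  B <- sum((Q_hats - Q_bar)^2) / (m - 1)
  list(Q_bar = Q_bar, U_bar = U_bar, B = B,
       T_total = U_bar + (1 + 1 / m) * B, m = m)
}

#' Pool m survival curves on the complementary log-log scale
#'
#' Builds the union grid of the input curves' event times, evaluates every
#' curve right-continuously on it (survival 1 with variance 0 before a
#' curve's first event), transforms estimates and variances to the
#' complementary log-log scale, pools by Rubin's rules, and back-transforms
#' the pooled estimate and its normal-quantile confidence bounds. Grid
#' points at which every curve still equals 1 are reported as survival 1
#' with the degenerate interval [1, 1]. Estimates are clamped to
#' \code{[eps, 1 - eps]} before the transform and the transformed-scale
#' variance is floored at \code{var_floor}.
#'
#' @param curves list of m \code{"survcurve"} objects of a common kind
#'   (m >= 2).
#' @param conf confidence level (default 0.95; the 0.975 normal quantile
#'   1.96 as conventionally printed).
#' @param eps clamping tolerance at the [0, 1] boundary.
#' @param var_floor floor for transformed-scale variances.
#' @param df_correction apply the Barnard-Rubin small-m degrees-of-freedom
#'   correction to the quantile (off by default; the conventional normal
#'   quantile is used otherwise).
#' @return object of class \code{"pooled_curve"}: a data.frame-backed grid
#'   with \code{time}, pooled survival \code{S}, \code{ci_low},
#'   \code{ci_high}, and the transformed-scale components \code{Q_bar},
#'   \code{U_bar}, \code{B}, \code{T_total}.
#' @export
pool_curves <- function(curves, conf = 0.95, eps = 1e-10,
                        var_floor = 1e-12, df_correction = FALSE) {
  m <- length(curves)
  if (m < 2L) stop("need at least 2 curves to pool", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, TRUE, "survcurve")))
  kinds <- unique(vapply(curves, function(cv) cv$kind, ""))
  if (length(kinds) != 1L)
    stop("curves of inconsistent kinds: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  grid <- sort(unique(unlist(lapply(curves, function(cv) cv$time))))
  if (!length(grid))
    stop("no event times in any curve", call. = FALSE)
  S <- sapply(curves, function(cv) step_eval(cv$time, cv$estimate, grid, 1))
  V <- sapply(curves, function(cv) step_eval(cv$time, cv$variance, grid, 0))
  if (is.null(dim(S))) { S <- matrix(S, nrow = 1L); V <- matrix(V, nrow = 1L) }
  all_one <- rowSums(S < 1) == 0L
  Sc <- pmin(pmax(S, eps), 1 - eps)
  Q <- cll_transform(Sc)
  U <- pmax(delta_variance(Sc, V), var_floor)
  Q_bar <- rowMeans(Q)
  U_bar <- rowMeans(U)
  B <- apply(Q, 1L, stats::var)
  T_total <- U_bar + (1 + 1 / m) * B
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (df_correction) {
    # Barnard-Rubin adjusted degrees of freedom, t quantile per grid point
    lam <- (1 + 1 / m) * B / T_total
    df_old <- (m - 1) / pmax(lam^2, 1e-12)
    z <- stats::qt(1 - (1 - conf) / 2, pmin(df_old, 1e6))
  }
  S_bar <- cll_back(Q_bar)
  ci_low <- cll_back(Q_bar - z * sqrt(T_total))
  ci_high <- cll_back(Q_bar + z * sqrt(T_total))
  S_bar[all_one] <- 1; ci_low[all_one] <- 1; ci_high[all_one] <- 1
  Q_bar[all_one] <- NA; U_bar[all_one] <- NA
  B[all_one] <- NA; T_total[all_one] <- NA
  structure(list(time = grid, S = S_bar, ci_low = ci_low, ci_high = ci_high,
                 Q_bar = Q_bar, U_bar = U_bar, B = B, T_total = T_total,
                 m = m, conf = conf, kind = kinds),
            class = "pooled_curve")
}

#' Relative efficiency of an m-imputation analysis
#'
#' \code{RE = 1 / (1 + gamma / m)} with
#' \code{gamma = (B + B/m) / T_total}, the fraction of missing information;
#' reported per grid point and averaged over the grid.
#'
#' @param x a \code{"pooled_curve"}, or the between-variance \code{B} with
#'   \code{U_bar} and \code{m} supplied.
#' @param U_bar,m within-variance and imputation count (scalar interface).
#' @return list with \code{mean} (average over the grid) and \code{by_time}.
#' @export
relative_efficiency <- function(x, U_bar = NULL, m = NULL) {
  if (inherits(x, "pooled_curve")) {
    B <- x$B; T_total <- x$T_total; m <- x$m
  } else {
    B <- x
    stopifnot(!is.null(U_bar), !is.null(m))
    T_total <- U_bar + (1 + 1 / m) * B
  }
  gamma <- (B + B / m) / T_total
  re <- 1 / (1 + gamma / m)
  list(mean = mean(re, na.rm = TRUE), by_time = re)
}

#' Evaluate a pooled curve at arbitrary times
#'
#' Right-continuous, last-value-carried-forward; survival 1 with the
#' degenerate interval before the first grid point.
#'
#' @param pooled a \code{"pooled_curve"}.
#' @param times evaluation times (days).
#' @return data.frame with \code{time}, \code{S}, \code{ci_low},
#'   \code{ci_high}.
#' @export
pooled_at <- function(pooled, times) {
  data.frame(time = times,
             S = step_eval(pooled$time, pooled$S, times, 1),
             ci_low = step_eval(pooled$time, pooled$ci_low, times, 1),
             ci_high = step_eval(pooled$time, pooled$ci_high, times, 1))
}

#' @export
print.pooled_curve <- function(x, ...) {
  cat(sprintf("Pooled %s curve (m = %d, %d grid times)\n", x$kind, x$m,
              length(x$time)))
  yrs <- c(1, 3, 5, 10) * 365.25
  yrs <- yrs[yrs <= max(x$time) * 1.05]
  if (length(yrs)) {
    s <- pooled_at(x, yrs)
    s$year <- round(s$time / 365.25)
    cat(paste(sprintf("  %2d y: %.3f [%.3f-%.3f]", s$year, s$S, s$ci_low,
                      s$ci_high), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pooled_curve <- function(x, ...) {
  data.frame(time = x$time, S = x$S, ci_low = x$ci_low,
             ci_high = x$ci_high, U_bar = x$U_bar, B = x$B,
             T_total = x$T_total)
}

#' @export
plot.pooled_curve <- function(x, xlab = "days", ylab = "pooled survival",
                              ...) {
  graphics::plot(c(0, x$time), c(1, x$S), type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  graphics::lines(c(0, x$time), c(1, x$ci_low), type = "s", lty = 2L)
  graphics::lines(c(0, x$time), c(1, x$ci_high), type = "s", lty = 2L)
  invisible(x)
}

#' Export a pooled curve as delimited text
#'
#' @param pooled a \code{"pooled_curve"}.
#' @param path output path.
#' @param sep separator.
#' @export
write_pooled <- function(pooled, path, sep = "\t") {
  utils::write.table(as.data.frame(pooled), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
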