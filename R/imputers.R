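# Elementary imputation draws used inside the chained-equations sweeps.
# All three follow standard fully-conditional-specification practice: fit
# the conditional model on the observed cases, perturb the coefficients by
# a draw from their (approximate) posterior, then draw imputations from the
# resulting predictive distribution.

# Bayesian-flavoured linear regression draw. Returns the ML fit and one
# posterior draw of (beta, sigma). Ridge term (scaled to the diagonal of
# X'X) guards rank-deficient designs.
norm_draw <- function(y, X, ridge = 1e-5) {
  n <- length(y)
  p <- ncol(X)
  xtx <- crossprod(X)
  pen <- diag(pmax(diag(xtx), 1) * ridge, p)
  v <- tryCatch(chol2inv(chol(xtx + pen)), error = function(e) {
    MASS::ginv(xtx + pen)
  })
  beta_hat <- v %*% crossprod(X, y)
  res <- y - X %*% beta_hat
  df <- max(n - p, 1L)
  sigma2_star <- sum(res^2) / stats::rchisq(1L, df)
  sv <- svd(v)
  half <- sv$u %*% (sqrt(pmax(sv$d, 0)) * t(sv$v))
  beta_star <- beta_hat + sqrt(sigma2_star) * (half %*% stats::rnorm(p))
  list(beta_hat = beta_hat, beta_star = beta_star,
       sigma_star = sqrt(sigma2_star))
}

#' Predictive mean matching imputation
#'
#' Draws regression coefficients from their approximate posterior, predicts
#' the incomplete cases, and for each one donates the observed value of one
#' of the \code{donors} complete cases with the closest predicted mean
#' (type-1 matching: observed cases are ranked by their maximum-likelihood
#' predictions, incomplete cases by the perturbed ones). Imputed values are
#' therefore always elements of \code{y_obs}.
#'
#' @param y_obs numeric outcomes of the complete cases.
#' @param X_obs,X_mis design matrices (including intercept) for complete and
#'   incomplete cases.
#' @param donors size of the donor pool (default 5).
#' @param ridge ridge fallback strength for singular designs.
#' @return numeric vector of length \code{nrow(X_mis)}.
#' @export
impute_pmm <- function(y_obs, X_obs, X_mis, donors = 5L, ridge = 1e-5) {
  stopifnot(length(y_obs) == nrow(X_obs), ncol(X_obs) == ncol(X_mis))
  if (nrow(X_mis) == 0L) return(numeric(0))
  if (length(y_obs) <= ncol(X_obs))
    warning("fewer complete cases than predictors; ridge-regularized fit",
            call. = FALSE)
  donors <- max(1L, min(donors, length(y_obs)))
  fit <- norm_draw(y_obs, X_obs, ridge)
  eta_obs <- drop(X_obs %*% fit$beta_hat)
  eta_mis <- drop(X_mis %*% fit$beta_star)
  # donor search on the sorted predictions: the `donors` nearest observed
  # predictions bracket the insertion point of each missing prediction
  ord <- order(eta_obs, stats::runif(length(eta_obs)))  # random tie order
  eo <- eta_obs[ord]
  n_obs <- length(eo)
  pos <- findInterval(eta_mis, eo)
  picks <- vapply(seq_along(eta_mis), function(j) {
    lo <- max(1L, pos[j] - donors)
    hi <- min(n_obs, pos[j] + donors)
    cand <- lo:hi
    d <- abs(eo[cand] - eta_mis[j])
    pool <- cand[order(d)[seq_len(min(donors, length(cand)))]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1L))
  y_obs[ord[picks]]
}

# observed-information covariance of the multinomial-logit coefficients
# (reference category first), assembled blockwise: block (k, l) of the
# information matrix is X' diag(p_k (delta_kl - p_l)) X. Coefficient order
# is outcome-major, matching as.vector(t(coef)).
multinom_vcov <- function(X, p_fit, y, ridge = 0) {
  if (is.null(dim(p_fit))) p_fit <- cbind(1 - p_fit, p_fit)
  K <- ncol(p_fit)
  p <- ncol(X)
  q <- (K - 1L) * p
  info <- matrix(0, q, q)
  for (k in 2L:K) {
    for (l in k:K) {
      w <- if (k == l) p_fit[, k] * (1 - p_fit[, k])
      else -p_fit[, k] * p_fit[, l]
      blk <- crossprod(X * w, X)
      ri <- (k - 2L) * p + seq_len(p)
      ci <- (l - 2L) * p + seq_len(p)
      info[ri, ci] <- blk
      if (k != l) info[ci, ri] <- t(blk)
    }
  }
  # decay contributes 2*ridge to the curvature; the relative term guards
  # against numerically singular information matrices
  info <- info + diag(2 * ridge, q) + diag(1e-8 * pmax(diag(info), 1), q)
  tryCatch(chol2inv(chol(info)), error = function(e) NULL)
}

# logistic IRLS with a ridge penalty acting as a weakly-informative
# normal prior on the (scale-standardized) coefficients; always returns
# finite coefficients and a covariance, even under separation or near-
# saturated designs. The default 0.16 corresponds to a N(0, 2.5^2) prior,
# negligible against the likelihood for large samples but stabilizing the
# posterior draws when events are few relative to the predictors.
fit_logistic_ridge <- function(X, y, ridge = 0.16, maxit = 25L) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(ridge * pmax(colMeans(X^2), 1), p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(X, X * w) + pen
    beta_new <- tryCatch(drop(solve(xtwx, crossprod(X, w * z))),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- tryCatch(chol2inv(chol(crossprod(X, X * w) + pen)),
                   error = function(e) MASS::ginv(crossprod(X, X * w) + pen))
  if (max(abs(beta)) > 15 && length(unique(y)) > 1L)
    warning("(quasi-)separation detected; ridge-penalized fit used",
            call. = FALSE)
  list(beta = beta, vcov = vcov)
}

#' Logistic regression imputation of a binary variable
#'
#' Fits a (lightly ridge-penalized) logistic regression on the observed
#' cases, draws coefficients from their asymptotic normal posterior,
#' computes success probabilities for the incomplete cases and draws
#' Bernoulli outcomes. If only one class is observed the imputation is
#' degenerate to that class, with a warning.
#'
#' @param y_obs observed outcomes: 0/1 vector or two-level factor.
#' @param X_obs,X_mis design matrices (including intercept).
#' @param ridge penalty weight of the weakly-informative coefficient prior
#'   (default 0.16, a N(0, 2.5^2) prior per standardized coefficient).
#' @return vector of imputed outcomes on the same coding as \code{y_obs}.
#' @export
impute_logistic <- function(y_obs, X_obs, X_mis, ridge = 0.16) {
  if (nrow(X_mis) == 0L) return(y_obs[0L])
  fac <- is.factor(y_obs)
  lev <- if (fac) levels(y_obs) else sort(unique(y_obs))
  y01 <- if (fac) as.integer(y_obs) - 1L else as.integer(y_obs == max(lev))
  recode <- function(z01) {
    if (fac) factor(lev[z01 + 1L], levels = lev)
    else if (is.integer(y_obs)) as.integer(lev[z01 + 1L])
    else lev[z01 + 1L]
  }
  if (length(unique(y01)) == 1L) {
    warning("single observed class; degenerate imputation", call. = FALSE)
    return(rep(y_obs[1L], nrow(X_mis)))
  }
  fit <- fit_logistic_ridge(X_obs, y01, ridge)
  beta_star <- MASS::mvrnorm(1L, fit$beta, fit$vcov)
  p_mis <- stats::plogis(drop(X_mis %*% beta_star))
  recode(stats::rbinom(nrow(X_mis), 1L, p_mis))
}

#' Multinomial-logit imputation of an unordered categorical variable
#'
#' Multinomial analogue of \code{\link{impute_logistic}}: fits a multinomial
#' logit on the observed cases (via \code{nnet::multinom}), perturbs the
#' coefficient vector by a draw from its asymptotic normal posterior,
#' computes category probabilities for the incomplete cases and draws
#' categories. Draws respect the observed category support. When the
#' Hessian is numerically singular the posterior perturbation falls back to
#' the maximum-likelihood probabilities with a warning.
#'
#' @param y_obs observed factor.
#' @param X_obs,X_mis design matrices (including intercept).
#' @param decay weight-decay (ridge) penalty of the multinomial fit,
#'   matching the logistic imputer's weakly-informative prior.
#' @return factor of imputed categories with the levels of \code{y_obs}.
#' @export
impute_multinomial <- function(y_obs, X_obs, X_mis, decay = 0.16) {
  stopifnot(is.factor(y_obs))
  if (nrow(X_mis) == 0L) return(y_obs[0L])
  obs_lev <- levels(droplevels(y_obs))
  if (length(obs_lev) == 1L) {
    warning("single observed class; degenerate imputation", call. = FALSE)
    return(factor(rep(obs_lev, nrow(X_mis)), levels = levels(y_obs)))
  }
  yd <- droplevels(y_obs)
  dat <- data.frame(.y = yd, X_obs[, -1L, drop = FALSE])
  # weight decay = the same weakly-informative ridge prior as the logistic
  fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 200L,
                        decay = decay)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L)
  cvec <- as.vector(t(cf))              # outcome-major, coefs within outcome
  vc <- multinom_vcov(X_obs, stats::fitted(fit), yd, ridge = decay)
  if (!is.null(vc) && all(is.finite(vc)) &&
      nrow(vc) == length(cvec)) {
    ev <- eigen((vc + t(vc)) / 2, symmetric = TRUE)
    vc <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    cvec <- drop(MASS::mvrnorm(1L, cvec, vc))
  } else {
    warning("singular Hessian in multinomial fit; using ML probabilities",
            call. = FALSE)
  }
  cf_star <- matrix(cvec, nrow = nrow(cf), byrow = TRUE)
  eta <- cbind(0, X_mis %*% t(cf_star))  # reference category first
  eta <- eta - apply(eta, 1L, max)
  pr <- exp(eta) / rowSums(exp(eta))
  idx <- apply(pr, 1L, function(p) sample.int(length(p), 1L, prob = p))
  factor(obs_lev[idx], levels = levels(y_obs))
}
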