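#' Automatic predictor-matrix construction
#'
#' Screens candidate predictors for every incomplete variable by combining
#' two statistics computed on numerically coded values (factor levels as
#' integer codes): the absolute pairwise-complete Pearson correlation of the
#' predictor with (a) the target's values and (b) the target's missingness
#' indicator, of which the maximum is taken; and the proportion of usable
#' cases, i.e. the fraction of target-missing rows on which the predictor is
#' observed. A predictor is retained when the maximum correlation is at
#' least \code{mincor} \emph{and} the usable-case proportion is at least
#' \code{minpuc}. Rows of complete variables are all zero and the diagonal
#' is zero. The returned matrix is a starting point meant to be reviewed
#' and edited (e.g. by clinicians) before imputation.
#'
#' @param data data.frame of candidate variables (targets and predictors).
#' @param mincor minimum absolute correlation (default 0.1).
#' @param minpuc minimum proportion of usable cases (default 0.4).
#' @param include,exclude character vectors of predictor columns forced in /
#'   out after screening.
#' @return square 0/1 integer matrix; entry \code{[target, predictor]} = 1
#'   when the predictor is used to impute the target.
#' @export
#' @examples
#' d <- data.frame(a = c(1, 2, NA, 4), b = c(1, 2, 3, 4), c = c(0, 1, 0, 1))
#' quickpred(d, mincor = 0.1, minpuc = 0)
quickpred <- function(data, mincor = 0.1, minpuc = 0.4,
                      include = NULL, exclude = NULL) {
  stopifnot(is.data.frame(data), ncol(data) >= 2L)
  vars <- names(data)
  num <- vapply(data, num_code, numeric(nrow(data)))
  sds <- apply(num, 2L, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0 | vapply(data, function(c)
    sum(!is.na(c)) < 2L, TRUE)
  if (any(constant))
    warning("constant variable(s) excluded as predictors: ",
            paste(vars[constant], collapse = ", "), call. = FALSE)
  p <- length(vars)
  mat <- matrix(0L, p, p, dimnames = list(vars, vars))
  miss <- is.na(data)
  for (tg in vars) {
    if (!any(miss[, tg])) next
    for (pr in setdiff(vars, tg)) {
      if (constant[pr]) next
      cv <- suppressWarnings(
        abs(stats::cor(num[, tg], num[, pr], use = "pairwise.complete.obs")))
      cr <- suppressWarnings(
        abs(stats::cor(as.numeric(miss[, tg]), num[, pr],
                       use = "pairwise.complete.obs")))
      maxcor <- suppressWarnings(max(cv, cr, na.rm = TRUE))
      if (!is.finite(maxcor)) maxcor <- 0
      puc <- mean(!miss[miss[, tg], pr])
      if (maxcor >= mincor && puc >= minpuc) mat[tg, pr] <- 1L
    }
    if (!is.null(include))
      mat[tg, setdiff(intersect(include, vars), tg)] <- 1L
    if (!is.null(exclude))
      mat[tg, intersect(exclude, vars)] <- 0L
  }
  mat
}
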