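# canonical category levels for the prostate-cohort data model
cT_LEVELS <- c("1a", "1b", "1c", "2a", "2b", "2c", "3a", "3b", "4")
pT_LEVELS <- c("2a", "2b", "2c", "3a", "3b", "4")
TREATMENT_LEVELS <- c("surgery", "radiotherapy", "hormone+chemo",
                      "surveillance+HIFU")
GLEASON_LEVELS <- c("low", "intermediate", "high")
CAUSE_LEVELS <- c("prostate", "other")
DAMICO_LEVELS <- c("low", "intermediate", "high+locally advanced", "N+M+")

# columns a cohort must carry, with coercion targets
COHORT_COLUMNS <- c("id", "age_at_diagnosis", "psa_diag", "cT", "cN", "cM",
                    "first_treatment", "gleason_group", "pT", "pN",
                    "psa_post", "followup_days", "dead", "cause", "sex",
                    "diagnosis_year")

#' Construct and validate a patient cohort
#'
#' A cohort is a plain \code{data.frame} (class \code{"cohort"}) with one row
#' per patient and a fixed set of clinical columns: follow-up time in days,
#' vital status, cause of death (\code{"prostate"}/\code{"other"}, possibly
#' missing), and staging/treatment covariates. Pathological staging
#' (\code{pT}, \code{pN}) is defined only for surgically treated patients and
#' cause of death only for the deceased; \code{validate_cohort()} enforces
#' these structural rules.
#'
#' @param data a data.frame containing the columns listed in
#'   \code{misurv::COHORT_COLUMNS} (missing optional columns are added as
#'   all-\code{NA}).
#' @param validate logical; check invariants (default \code{TRUE}).
#' @return \code{data} coerced to canonical types with class
#'   \code{c("cohort", "data.frame")}.
#' @export
#' @examples
#' coh <- generate_cohort(n = 50, seed = 1)$cohort
#' validate_cohort(coh)
cohort <- function(data, validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in COHORT_COLUMNS)
    if (is.null(data[[col]])) data[[col]] <- NA
  data$id <- as.character(data$id)
  for (col in c("age_at_diagnosis", "psa_diag", "psa_post"))
    data[[col]] <- as.numeric(data[[col]])
  data$followup_days <- as.integer(round(as.numeric(data$followup_days)))
  data$diagnosis_year <- as.integer(data$diagnosis_year)
  data$dead <- as.integer(data$dead)
  for (col in c("cN", "cM", "pN"))
    data[[col]] <- as.integer(data[[col]])
  data$cT <- check_levels(data$cT, cT_LEVELS, "cT")
  data$pT <- check_levels(data$pT, pT_LEVELS, "pT")
  data$first_treatment <- check_levels(data$first_treatment,
                                       TREATMENT_LEVELS, "first_treatment")
  data$gleason_group <- check_levels(data$gleason_group, GLEASON_LEVELS,
                                     "gleason_group")
  data$cause <- check_levels(data$cause, CAUSE_LEVELS, "cause")
  data$sex <- ifelse(is.na(data$sex), "male", as.character(data$sex))
  data <- data[c(COHORT_COLUMNS,
                 setdiff(names(data), COHORT_COLUMNS))]
  class(data) <- c("cohort", "data.frame")
  if (validate) validate_cohort(data)
  data
}

check_levels <- function(x, levels, name) {
  if (is.factor(x)) x <- as.character(x)
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad))
    stop(sprintf("unknown level(s) for %s: %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  factor(x, levels = levels)
}

#' @rdname cohort
#' @param x a cohort.
#' @export
validate_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  if (anyDuplicated(x$id))
    stop("duplicate patient ids", call. = FALSE)
  if (any(is.na(x$followup_days)) || any(x$followup_days < 1))
    stop("followup_days must be >= 1 for every record", call. = FALSE)
  if (!all(x$dead %in% c(0L, 1L)))
    stop("dead must be 0/1", call. = FALSE)
  if (any(!is.na(x$cause) & x$dead == 0L))
    stop("cause of death present for a patient not recorded as dead",
         call. = FALSE)
  surgery <- !is.na(x$first_treatment) & x$first_treatment == "surgery"
  if (any((!is.na(x$pT) | !is.na(x$pN)) & !surgery))
    stop("pT/pN present for a patient whose first treatment is not surgery",
         call. = FALSE)
  invisible(x)
}

#' Read a cohort from a delimited text file
#'
#' Reads a comma- or tab-delimited patient table, renames columns according
#' to \code{col_map}, coerces categories, and applies the record-level
#' filtering rule: records with non-positive follow-up (date of last news
#' equal to the date of diagnosis) are excluded and counted, mirroring the
#' usual registry exclusion of zero-duration records.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) sniffs comma vs tab
#'   from the header line.
#' @param na_strings strings read as missing.
#' @param col_map optional named character vector mapping file column names
#'   to cohort field names, e.g. \code{c(psa = "psa_diag")}.
#' @return a \code{cohort}; the number of excluded zero-follow-up records is
#'   attached as \code{attr(, "n_excluded")} and reported via \code{message()}.
#' @export
#' @examples
#' path <- system.file("extdata", "cohort-synthetic-example.csv",
#'                     package = "misurv")
#' coh <- read_cohort(path)
#' missingness_summary(coh)
read_cohort <- function(path, sep = NULL, na_strings = c("", "NA"),
                        col_map = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    hit <- match(names(col_map), names(raw))
    if (anyNA(hit))
      stop("col_map names absent from file: ",
           paste(names(col_map)[is.na(hit)], collapse = ", "), call. = FALSE)
    names(raw)[hit] <- unname(col_map)
  }
  missing_cols <- setdiff(c("id", "followup_days", "dead"), names(raw))
  if (length(missing_cols))
    stop("required column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  fu <- suppressWarnings(as.numeric(raw$followup_days))
  bad <- which(is.na(fu))
  if (length(bad))
    stop("unparseable followup_days in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  keep <- fu >= 1
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(sprintf("read_cohort: excluded %d record(s) with followup_days < 1",
                    n_excluded))
  out <- cohort(raw[keep, , drop = FALSE])
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a cohort to delimited text
#'
#' @param x a cohort.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_cohort <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x)[COHORT_COLUMNS], path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Follow-up duration from two ISO-8601 dates
#'
#' @param diagnosis_date,end_date character or \code{Date}.
#' @return integer days (\code{end_date - diagnosis_date}).
#' @export
followup_days <- function(diagnosis_date, end_date) {
  as.integer(as.Date(end_date) - as.Date(diagnosis_date))
}

#' Code a cause of death to the prostate/other/missing trichotomy
#'
#' A death is coded \code{"prostate"} when the underlying cause is prostate
#' cancer \emph{or} prostate cancer is mentioned in part 1 of the death
#' certificate; \code{"other"} when any other underlying cause is observed;
#' and missing (\code{NA}) when no cause is available.
#'
#' @param raw_cause character vector of underlying causes (\code{NA} when
#'   absent).
#' @param part1_mentions_cancer 0/1 vector: prostate cancer mentioned in
#'   part 1 of the certificate.
#' @param prostate_codes values of \code{raw_cause} counted as prostate
#'   cancer.
#' @return factor with levels \code{c("prostate", "other")}, \code{NA} when
#'   missing.
#' @export
#' @examples
#' code_cause_of_death(c("prostate", "cardiac", NA), c(0, 1, 0))
code_cause_of_death <- function(raw_cause, part1_mentions_cancer,
                                prostate_codes = "prostate") {
  part1 <- as.integer(part1_mentions_cancer)
  stopifnot(length(raw_cause) == length(part1))
  out <- ifelse(!is.na(raw_cause) & raw_cause %in% prostate_codes |
                  (!is.na(part1) & part1 == 1L), "prostate",
                ifelse(!is.na(raw_cause), "other", NA_character_))
  factor(out, levels = CAUSE_LEVELS)
}

#' d'Amico-style risk grouping
#'
#' Deterministic four-level prognostic grouping from PSA at diagnosis,
#' Gleason group and clinical stage. Nodal or metastatic disease
#' (\code{cN = 1} or \code{cM = 1}) overrides the others; next,
#' high/locally-advanced risk is PSA > \code{psa_high} or high Gleason or
#' stage 2c and above; low risk requires PSA <= \code{psa_low}, low Gleason
#' and stage 2a or below; everything else is intermediate. The stage
#' cut-points are exposed so the grouping can be re-tabulated against local
#' urological practice.
#'
#' @param psa_diag PSA at diagnosis (ng/ml).
#' @param gleason_group factor/character in
#'   \code{c("low","intermediate","high")}.
#' @param cT clinical T stage in \code{c("1a",...,"4")}.
#' @param cN,cM 0/1 nodal / metastatic status.
#' @param psa_low,psa_high PSA cut-points (ng/ml).
#' @param low_stages,high_stages stage sets for the low and high groups.
#' @return factor with levels \code{"low"}, \code{"intermediate"},
#'   \code{"high+locally advanced"}, \code{"N+M+"}; \code{NA} where a needed
#'   input is missing.
#' @export
damico_group <- function(psa_diag, gleason_group, cT, cN, cM,
                         psa_low = 10, psa_high = 20,
                         low_stages = c("1a", "1b", "1c", "2a"),
                         high_stages = c("2c", "3a", "3b", "4")) {
  gleason_group <- as.character(gleason_group)
  cT <- as.character(cT)
  nm <- !is.na(cN) & !is.na(cM) & (cN == 1L | cM == 1L)
  high <- (!is.na(psa_diag) & psa_diag > psa_high) |
    (!is.na(gleason_group) & gleason_group == "high") |
    (!is.na(cT) & cT %in% high_stages)
  low <- (!is.na(psa_diag) & psa_diag <= psa_low) &
    (!is.na(gleason_group) & gleason_group == "low") &
    (!is.na(cT) & cT %in% low_stages)
  incomplete <- is.na(psa_diag) | is.na(gleason_group) | is.na(cT) |
    is.na(cN) | is.na(cM)
  out <- ifelse(nm, "N+M+",
                ifelse(high, DAMICO_LEVELS[3L],
                       ifelse(low, "low", "intermediate")))
  # N+/M+ and high are decidable from partial data; low/intermediate are not
  out[incomplete & !nm & !high] <- NA_character_
  factor(out, levels = DAMICO_LEVELS)
}

#' Derived covariates: T_new, N_new and the d'Amico group
#'
#' \code{T_new}/\code{N_new} equal the pathological stage (\code{pT},
#' \code{pN}) when the first treatment is surgery and the clinical stage
#' (\code{cT}, \code{cN}) otherwise; the d'Amico group is computed by
#' \code{\link{damico_group}}. These are \emph{passive} variables: they are
#' recomputed after every imputation update rather than imputed themselves.
#' A surgical record whose \code{pT} (or \code{pN}) is missing falls back to
#' \code{NA} for \code{T_new} (\code{N_new}).
#'
#' @param x a cohort.
#' @param ... passed to \code{\link{damico_group}}.
#' @return data.frame with columns \code{T_new} (factor over the union of
#'   cT/pT levels), \code{N_new} (integer 0/1), \code{damico_group}.
#' @export
derive_covariates <- function(x, ...) {
  surgery <- !is.na(x$first_treatment) & x$first_treatment == "surgery"
  t_lev <- union(cT_LEVELS, pT_LEVELS)
  T_new <- ifelse(surgery, as.character(x$pT), as.character(x$cT))
  N_new <- ifelse(surgery, x$pN, x$cN)
  data.frame(
    T_new = factor(T_new, levels = t_lev),
    N_new = as.integer(N_new),
    damico_group = damico_group(x$psa_diag, x$gleason_group, x$cT,
                                x$cN, x$cM, ...),
    stringsAsFactors = FALSE)
}

# append/refresh the derived columns in place
add_derived <- function(x, ...) {
  d <- derive_covariates(x, ...)
  x$T_new <- d$T_new
  x$N_new <- d$N_new
  x$damico_group <- d$damico_group
  x
}

#' Per-variable missing-data summary
#'
#' Counts missing values per clinical variable with the conventional
#' denominators: all patients for most variables, the deceased for cause of
#' death, and surgically treated patients for \code{pT}/\code{pN}. Percents
#' are half-up rounded to one decimal.
#'
#' @param x a cohort.
#' @return data.frame with columns \code{variable}, \code{denominator},
#'   \code{n_missing}, \code{percent}.
#' @export
missingness_summary <- function(x) {
  n <- nrow(x)
  dead <- x$dead == 1L
  surgery <- !is.na(x$first_treatment) & x$first_treatment == "surgery"
  rows <- list(
    cause = list(x$cause[dead], sum(dead)),
    psa_diag = list(x$psa_diag, n),
    cT = list(x$cT, n),
    cN = list(x$cN, n),
    cM = list(x$cM, n),
    first_treatment = list(x$first_treatment, n),
    gleason_group = list(x$gleason_group, n),
    psa_post = list(x$psa_post, n),
    pT = list(x$pT[surgery], sum(surgery)),
    pN = list(x$pN[surgery], sum(surgery)))
  out <- data.frame(
    variable = names(rows),
    denominator = vapply(rows, function(r) r[[2L]], 0),
    n_missing = vapply(rows, function(r) sum(is.na(r[[1L]])), 0),
    stringsAsFactors = FALSE)
  out$percent <- round_half_up(ifelse(out$denominator > 0,
                                      100 * out$n_missing / out$denominator,
                                      0), 1)
  rownames(out) <- NULL
  out
}
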