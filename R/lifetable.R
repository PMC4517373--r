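#' Population life table
#'
#' Stores expected mortality rates of the general population indexed by
#' sex, integer age and calendar year. Rates are supplied per person-year
#' and converted to per person-day internally (365.25 days/year). Lookups
#' outside the covered age/year span clamp to the nearest covered cell
#' (with a one-time warning), so adding cells outside a cohort's coverage
#' never changes an estimate.
#'
#' @param data data.frame with columns \code{sex}, \code{age}, \code{year},
#'   \code{rate} (per person-year, >= 0).
#' @return object of class \code{"life_table"}.
#' @export
life_table <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("sex", "age", "year", "rate") %in% names(data)))
  if (any(data$rate < 0)) stop("negative hazard in life table", call. = FALSE)
  data$sex <- as.character(data$sex)
  data$age <- as.integer(data$age)
  data$year <- as.integer(data$year)
  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  sexes <- sort(unique(data$sex))
  arr <- array(NA_real_, c(length(ages), length(years), length(sexes)),
               dimnames = list(ages, years, sexes))
  arr[cbind(match(data$age, ages), match(data$year, years),
            match(data$sex, sexes))] <- data$rate
  if (anyNA(arr))
    stop("life table must cover the full age x year x sex grid",
         call. = FALSE)
  structure(list(rate = arr, ages = ages, years = years, sexes = sexes),
            class = "life_table")
}

#' Read / write a life table as delimited text
#'
#' @param path file path with header \code{sex, age, year, rate}.
#' @param sep separator (sniffed from the header when \code{NULL}).
#' @return a \code{"life_table"}.
#' @export
read_life_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  life_table(utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE))
}

#' @rdname read_life_table
#' @param lt a \code{"life_table"}.
#' @export
write_life_table <- function(lt, path, sep = ",") {
  g <- expand.grid(age = lt$ages, year = lt$years, sex = lt$sexes,
                   stringsAsFactors = FALSE)
  g$rate <- lt$rate[cbind(match(g$age, lt$ages), match(g$year, lt$years),
                          match(g$sex, lt$sexes))]
  utils::write.table(g[c("sex", "age", "year", "rate")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population hazard lookup
#'
#' @param lt a \code{"life_table"}.
#' @param sex,age,year vectors (recycled); \code{age}/\code{year} are
#'   floored to integers and clamped to the covered span.
#' @param per one of \code{"year"} or \code{"day"}.
#' @return expected mortality rate.
#' @export
pop_hazard <- function(lt, sex, age, year, per = c("day", "year")) {
  per <- match.arg(per)
  n <- max(length(sex), length(age), length(year))
  sex <- rep_len(as.character(sex), n)
  age <- floor(rep_len(age, n))
  year <- floor(rep_len(year, n))
  clamped <- age < min(lt$ages) | age > max(lt$ages) |
    year < min(lt$years) | year > max(lt$years)
  if (any(clamped))
    warn_once("life-table lookup outside coverage; clamped to nearest cell")
  age <- pmin(pmax(age, min(lt$ages)), max(lt$ages))
  year <- pmin(pmax(year, min(lt$years)), max(lt$years))
  si <- match(sex, lt$sexes)
  if (anyNA(si)) stop("sex not present in life table", call. = FALSE)
  r <- lt$rate[cbind(match(age, lt$ages), match(year, lt$years), si)]
  if (per == "day") r / 365.25 else r
}

warn_once <- local({
  seen <- new.env(parent = emptyenv())
  function(msg) {
    if (is.null(seen[[msg]])) {
      assign(msg, TRUE, envir = seen)
      warning(msg, call. = FALSE)
    }
    invisible(NULL)
  }
})

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages %d-%d, years %d-%d, sex: %s\n",
              min(x$ages), max(x$ages), min(x$years), max(x$years),
              paste(x$sexes, collapse = ", ")))
  invisible(x)
}
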