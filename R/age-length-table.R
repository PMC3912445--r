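# Year x age tables of survey mean lengths, the raw material of the
# cohort analysis. Rows are observation years, columns are age classes;
# a cohort born in year b appears along the diagonal (year = b + age).

#' Year-by-age table of mean lengths
#'
#' Construct the container for survey data: a matrix of mean length per
#' (observation year, age class), optionally paired with an abundance
#' matrix of identical shape. Missing cells are `NA`.
#'
#' @param lengths Numeric matrix, one row per year, one column per age;
#'   all present values must be positive.
#' @param years Strictly increasing integer year labels, one per row.
#' @param ages Strictly increasing, contiguous integer age labels, one per
#'   column.
#' @param abundance Optional numeric matrix of counts, same shape as
#'   `lengths`.
#' @param unit Length-unit tag.
#' @return An object of class `age_length_table`.
#' @examples
#' tab <- age_length_table(
#'   rbind(c(10, 18, 24), c(11, 19, 25), c(12, 20, 26)),
#'   years = 2000:2002, ages = 1:3
#' )
#' @export
age_length_table <- function(lengths, years, ages, abundance = NULL, unit = "mm") {
  if (!is.matrix(lengths) || !is.numeric(lengths)) {
    stop_unusable("`lengths` must be a numeric matrix")
  }
  years <- as.integer(years)
  ages <- as.integer(ages)
  if (nrow(lengths) != length(years) || ncol(lengths) != length(ages)) {
    stop_unusable("`lengths` dimensions must match `years` x `ages`")
  }
  if (length(years) && any(diff(years) <= 0)) stop_unusable("`years` must be strictly increasing")
  if (length(ages) && any(diff(ages) != 1L)) stop_unusable("`ages` must be contiguous increasing integers")
  if (any(lengths[!is.na(lengths)] <= 0)) stop_unusable("all present lengths must be > 0")
  if (!is.null(abundance)) {
    if (!is.matrix(abundance) || !identical(dim(abundance), dim(lengths))) {
      stop_unusable("`abundance` must be a matrix of the same shape as `lengths`")
    }
    if (any(abundance[!is.na(abundance)] < 0)) stop_unusable("abundances must be >= 0")
  }
  dimnames(lengths) <- list(year = years, age = ages)
  structure(
    list(lengths = lengths, years = years, ages = ages,
         abundance = abundance, unit = unit),
    class = "age_length_table"
  )
}

#' @export
print.age_length_table <- function(x, ...) {
  cat(sprintf("Age-length table: %d years (%d-%d) x %d ages (%d-%d), unit %s%s\n",
              length(x$years), min(x$years), max(x$years),
              length(x$ages), min(x$ages), max(x$ages), x$unit,
              if (is.null(x$abundance)) "" else ", with abundances"))
  print(x$lengths)
  invisible(x)
}

#' One cohort's length-at-age series
#'
#' A year-class traced along the diagonal of an [age_length_table()]:
#' the mean length of fish born in `birth_year` at each observed age.
#' Ages need not start at 1 nor be gap-free; only consecutive ages yield
#' increments.
#'
#' @param birth_year Integer birth year of the cohort.
#' @param ages Increasing integer ages with observations.
#' @param lengths Mean length at each age.
#' @param unit Length-unit tag.
#' @return An object of class `cohort_series`.
#' @export
cohort_series <- function(birth_year, ages, lengths, unit = "mm") {
  ages <- as.integer(ages)
  if (length(ages) != length(lengths)) stop_unusable("`ages` and `lengths` must align")
  if (anyDuplicated(ages)) stop_unusable("duplicate ages in cohort series")
  if (is.unsorted(ages, strictly = TRUE)) stop_unusable("`ages` must be increasing")
  structure(
    list(birth_year = as.integer(birth_year), ages = ages,
         lengths = as.numeric(lengths), unit = unit),
    class = "cohort_series"
  )
}

#' @export
print.cohort_series <- function(x, ...) {
  cat(sprintf("Cohort born %d: ages %s, lengths (%s) %s\n", x$birth_year,
              paste(x$ages, collapse = ","), x$unit,
              paste(signif(x$lengths, 5), collapse = ", ")))
  invisible(x)
}

#' Extract year-class series from a year-by-age table
#'
#' Read each cohort off the table's diagonal: the cohort born in year `b`
#' has age `a` in observation year `b + a`. Cohorts observed at fewer than
#' two ages are dropped (they can yield no increment).
#'
#' @param table An [age_length_table()].
#' @return List of [cohort_series()], ordered by birth year.
#' @export
extract_cohorts <- function(table) {
  if (!inherits(table, "age_length_table")) stop_unusable("`table` must be an age_length_table")
  if (length(table$years) < 2L || length(table$ages) < 2L) {
    stop_unusable("need at least 2 years and 2 ages to trace any cohort")
  }
  birth_years <- seq(min(table$years) - max(table$ages),
                     max(table$years) - min(table$ages))
  out <- list()
  for (b in birth_years) {
    ages <- table$ages[(b + table$ages) %in% table$years]
    if (!length(ages)) next
    lens <- vapply(ages, function(a) {
      table$lengths[match(b + a, table$years), match(a, table$ages)]
    }, numeric(1))
    keep <- !is.na(lens)
    if (sum(keep) < 2L) next
    out[[length(out) + 1L]] <- cohort_series(b, ages[keep], lens[keep], unit = table$unit)
  }
  out
}

#' Re-tabulate cohort series onto a year-by-age grid
#'
#' Inverse of [extract_cohorts()]: lay a list of cohorts back onto the
#' (year, age) grid they came from. Cells not covered by any cohort are
#' `NA`.
#'
#' @param cohorts List of [cohort_series()].
#' @return An [age_length_table()].
#' @export
tabulate_cohorts <- function(cohorts) {
  if (!length(cohorts)) stop_unusable("no cohorts to tabulate")
  yrs <- sort(unique(unlist(lapply(cohorts, function(s) s$birth_year + s$ages))))
  ages <- range(unlist(lapply(cohorts, `[[`, "ages")))
  ages <- seq(ages[1], ages[2])
  yrs <- seq(min(yrs), max(yrs))
  m <- matrix(NA_real_, length(yrs), length(ages))
  for (s in cohorts) {
    for (i in seq_along(s$ages)) {
      m[match(s$birth_year + s$ages[i], yrs), match(s$ages[i], ages)] <- s$lengths[i]
    }
  }
  age_length_table(m, yrs, ages, unit = cohorts[[1]]$unit)
}
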