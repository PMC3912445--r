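# Delimited-text I/O for age-length tables. Layout: tab-separated, first
# column "year", remaining headers are the age labels, cells are mean
# lengths ("NA" or empty = missing). Numbers are written with 17
# significant digits so a write/read round trip is bit-exact. A sidecar
# key-value config declares the unit and an optional abundance file.

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write an age-length table to delimited text
#'
#' @param table An [age_length_table()].
#' @param path Output file for the length matrix.
#' @param config_path Optional sidecar config file; records `unit`, `step`
#'   and (when abundances are present) the abundance file written next to
#'   `path` with suffix `.abundance`.
#' @return `path`, invisibly.
#' @export
write_age_length_table <- function(table, path, config_path = NULL) {
  if (!inherits(table, "age_length_table")) stop_unusable("`table` must be an age_length_table")
  header <- paste(c("year", table$ages), collapse = "\t")
  rows <- vapply(seq_along(table$years), function(i) {
    paste(c(table$years[i], fmt_num(table$lengths[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  abundance_path <- NULL
  if (!is.null(table$abundance)) {
    abundance_path <- paste0(path, ".abundance")
    arows <- vapply(seq_along(table$years), function(i) {
      paste(c(table$years[i], fmt_num(table$abundance[i, ])), collapse = "\t")
    }, character(1))
    writeLines(c(header, arows), abundance_path)
  }
  if (!is.null(config_path)) {
    cfg <- c(sprintf("unit: %s", table$unit))
    if (!is.null(abundance_path)) {
      cfg <- c(cfg, sprintf("abundance: %s", basename(abundance_path)))
    }
    writeLines(cfg, config_path)
  }
  invisible(path)
}

parse_table_file <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !nzchar(trimws(lines[1]))) {
    stop_malformed(sprintf("%s: empty or missing header at line 1", path))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || tolower(header[1]) != "year") {
    stop_malformed(sprintf("%s: line 1 must be 'year<TAB>age...' header", path))
  }
  ages <- suppressWarnings(as.integer(header[-1]))
  if (any(is.na(ages))) {
    bad <- which(is.na(ages))[1] + 1L
    stop_malformed(sprintf("%s: line 1, column %d: age label is not an integer", path, bad))
  }
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (!length(body)) stop_malformed(sprintf("%s: no data rows after the header", path))
  years <- integer(length(body))
  m <- matrix(NA_real_, length(body), length(ages))
  for (i in seq_along(body)) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(cells) != length(ages) + 1L) {
      stop_malformed(sprintf("%s: line %d has %d fields, expected %d",
                             path, i + 1L, length(cells), length(ages) + 1L))
    }
    y <- suppressWarnings(as.integer(cells[1]))
    if (is.na(y)) stop_malformed(sprintf("%s: line %d, column 1: year is not an integer", path, i + 1L))
    years[i] <- y
    vals <- cells[-1]
    vals[!nzchar(trimws(vals))] <- "NA"
    num <- suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals)))
    bad <- which(is.na(num) & vals != "NA")
    if (length(bad)) {
      stop_malformed(sprintf("%s: line %d, column %d: '%s' is not a number (%s)",
                             path, i + 1L, bad[1] + 1L, vals[bad[1]], what))
    }
    m[i, ] <- num
  }
  list(years = years, ages = ages, values = m)
}

read_table_config <- function(config_path) {
  lines <- readLines(config_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) {
    stop_malformed(sprintf("%s: line %d is not 'key: value'", config_path, bad[1]))
  }
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, 2L, FUN.VALUE = character(1)))
}

#' Read an age-length table from delimited text
#'
#' Inverse of [write_age_length_table()]; the round trip is bit-exact.
#' Malformed input raises an error naming the offending line and column.
#'
#' @param path Length-matrix file.
#' @param config_path Optional sidecar config declaring `unit` and an
#'   `abundance` file (relative paths resolve against `path`'s directory).
#' @return An [age_length_table()].
#' @export
read_age_length_table <- function(path, config_path = NULL) {
  if (!file.exists(path)) stop_malformed(sprintf("%s: no such file", path))
  parsed <- parse_table_file(path, "mean length")
  unit <- "mm"
  abundance <- NULL
  if (!is.null(config_path)) {
    cfg <- read_table_config(config_path)
    if (!is.null(cfg$unit)) unit <- cfg$unit
    if (!is.null(cfg$abundance)) {
      apath <- if (file.exists(cfg$abundance)) cfg$abundance
               else file.path(dirname(path), cfg$abundance)
      if (!file.exists(apath)) stop_malformed(sprintf("%s: abundance file not found", apath))
      ap <- parse_table_file(apath, "abundance")
      if (!identical(ap$years, parsed$years) || !identical(ap$ages, parsed$ages)) {
        stop_malformed(sprintf("%s: abundance grid does not match the length grid", apath))
      }
      abundance <- ap$values
    }
  }
  age_length_table(parsed$values, parsed$years, parsed$ages,
                   abundance = abundance, unit = unit)
}
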