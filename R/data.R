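#' Age-inhibin B measurement collections
#'
#' An `ib_data` object is a data frame of (age, level) measurements with a
#' provenance tag per record. It is the common currency of the package:
#' readers, the synthetic generator and the two augmentation steps all
#' produce one, and the fitting, validation and centile functions consume
#' one.
#'
#' Columns:
#' \describe{
#'   \item{`age_years`}{decimal age in years. Negative ages are allowed only
#'     for conception-anchor records (the gestation interval before birth).}
#'   \item{`inhibin_pg_ml`}{serum inhibin B in pg/mL, non-negative.}
#'   \item{`source`}{one of `"extracted"`, `"conception_anchor"`,
#'     `"imputed_adult"`, `"synthetic"`. Anchor records must have level 0.}
#' }
#'
#' @param age_years numeric vector of ages in decimal years.
#' @param inhibin_pg_ml numeric vector of levels in pg/mL.
#' @param source provenance tag, recycled; see above.
#' @param label optional free-text label stored as an attribute.
#' @param conception_age age assigned to conception, in years (negative).
#' @param max_age maximum admissible age in years.
#' @return an object of class `ib_data` (a data frame).
#' @examples
#' ib_data(c(0.1, 5, 17), c(250, 80, 300))
#' @export
ib_data <- function(age_years, inhibin_pg_ml,
                    source = "extracted", label = "",
                    conception_age = -0.75, max_age = 35) {
  age_years <- as.numeric(age_years)
  inhibin_pg_ml <- as.numeric(inhibin_pg_ml)
  if (length(age_years) != length(inhibin_pg_ml))
    stopf("age and level vectors differ in length (%d vs %d)",
          length(age_years), length(inhibin_pg_ml))
  source <- rep_len(as.character(source), length(age_years))
  x <- data.frame(age_years = age_years,
                  inhibin_pg_ml = inhibin_pg_ml,
                  source = source,
                  stringsAsFactors = FALSE)
  attr(x, "label") <- label
  attr(x, "conception_age") <- conception_age
  attr(x, "max_age") <- max_age
  class(x) <- c("ib_data", "data.frame")
  validate_ib_data(x)
  x
}

ib_sources <- c("extracted", "conception_anchor", "imputed_adult", "synthetic")

validate_ib_data <- function(x) {
  ca <- attr(x, "conception_age") %||% -0.75
  ma <- attr(x, "max_age") %||% 35
  bad <- which(!is.finite(x$age_years) | !is.finite(x$inhibin_pg_ml))
  if (length(bad))
    stopf("non-numeric or missing value in row %d", bad[1L])
  bad <- which(x$inhibin_pg_ml < 0)
  if (length(bad))
    stopf("negative inhibin B level in row %d", bad[1L])
  bad <- which(!(x$source %in% ib_sources))
  if (length(bad))
    stopf("unknown source tag '%s' in row %d", x$source[bad[1L]], bad[1L])
  bad <- which(x$age_years < ca | x$age_years > ma)
  if (length(bad))
    stopf("age %.4g in row %d outside [%g, %g]",
          x$age_years[bad[1L]], bad[1L], ca, ma)
  anchor <- x$source == "conception_anchor"
  if (any(anchor & x$inhibin_pg_ml != 0))
    stopf("conception-anchor record with nonzero level in row %d",
          which(anchor & x$inhibin_pg_ml != 0)[1L])
  invisible(x)
}

# observational records: real or simulated measurements, as opposed to the
# boundary constraints (anchors) and the adult-range imputation
is_observational <- function(x) x$source %in% c("extracted", "synthetic")

# records entering goodness-of-fit assessment: anchors are excluded,
# imputed adult records are included
is_assessable <- function(x) x$source != "conception_anchor"

#' @export
print.ib_data <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<ib_data> %d records%s\n", nrow(x),
              if (nzchar(lab %||% "")) paste0(" - ", lab) else ""))
  tab <- table(factor(x$source, levels = ib_sources))
  for (s in names(tab)) if (tab[[s]] > 0) cat(sprintf("  %-17s %d\n", s, tab[[s]]))
  if (nrow(x)) {
    obs <- x[is_observational(x), , drop = FALSE]
    if (nrow(obs))
      cat(sprintf("  age range %.3g-%.3g y, median %.3g y (observational records)\n",
                  min(obs$age_years), max(obs$age_years),
                  stats::median(obs$age_years)))
  }
  invisible(x)
}

#' Summary statistics of a measurement collection
#'
#' Sample size, median age and age range, computed over the observational
#' records only (extracted or synthetic); conception anchors and imputed
#' adult values are constraints, not measurements, and are excluded.
#'
#' @param object an [ib_data] object.
#' @param ... unused.
#' @return a list of class `ib_summary` with fields `name`, `n`,
#'   `median_age_years`, `age_min_years`, `age_max_years`.
#' @export
summary.ib_data <- function(object, ...) {
  obs <- object[is_observational(object), , drop = FALSE]
  if (nrow(obs) == 0L) stop("empty dataset: no observational records")
  out <- list(name = attr(object, "label") %||% "",
              n = nrow(obs),
              median_age_years = stats::median(obs$age_years),
              age_min_years = min(obs$age_years),
              age_max_years = max(obs$age_years))
  class(out) <- "ib_summary"
  out
}

#' @export
print.ib_summary <- function(x, ...) {
  cat(sprintf("n = %d, median age %.3g y, range %.3g-%.3g y\n",
              x$n, x$median_age_years, x$age_min_years, x$age_max_years))
  invisible(x)
}

#' Read age-inhibin B pairs from CSV
#'
#' The canonical format is two numeric columns `age_years, inhibin_pg_ml`
#' with an optional third `source` column; a header row is detected
#' automatically. Rows that fail to parse, or carry a negative level, abort
#' the read with a message naming the offending row.
#'
#' @param path path to a CSV file.
#' @param label optional dataset label; defaults to the file name.
#' @param conception_age,max_age admissible age window, see [ib_data].
#' @return an [ib_data] object, rows in file order.
#' @export
read_ib_csv <- function(path, label = basename(path),
                        conception_age = -0.75, max_age = 35) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records: file is empty", call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(cells[[1L]][1:2])))
  has_header <- any(is.na(first))
  if (has_header) {
    cells <- cells[-1L]
    if (length(cells) == 0L) stop("no records: header only", call. = FALSE)
  }
  n <- length(cells)
  age <- level <- numeric(n)
  src <- character(n)
  for (i in seq_len(n)) {
    row <- trimws(cells[[i]])
    file_row <- i + has_header
    if (length(row) < 2L)
      stopf("row %d: expected at least 2 columns", file_row)
    v <- suppressWarnings(as.numeric(row[1:2]))
    if (any(is.na(v)))
      stopf("row %d: non-numeric cell '%s'", file_row, row[1:2][is.na(v)][1L])
    if (v[2L] < 0)
      stopf("row %d: negative inhibin B level %g", file_row, v[2L])
    age[i] <- v[1L]; level[i] <- v[2L]
    src[i] <- if (length(row) >= 3L && nzchar(row[3L])) row[3L] else "extracted"
  }
  ib_data(age, level, src, label = label,
          conception_age = conception_age, max_age = max_age)
}

#' Write an `ib_data` object to CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip preserves every record, and its source tag, exactly.
#'
#' @param x an [ib_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ib_csv <- function(x, path) {
  stopifnot(inherits(x, "ib_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("age_years,inhibin_pg_ml,source", con)
  if (nrow(x))
    writeLines(paste(formatC(x$age_years, digits = 17, format = "g"),
                     formatC(x$inhibin_pg_ml, digits = 17, format = "g"),
                     x$source, sep = ","), con)
  invisible(path)
}

#' Append conception anchors
#'
#' Inhibin B at conception is zero; appending replicated zero-level records
#' at the conception age forces fitted curves through that point. The
#' anchors take part in fitting but are excluded whenever goodness of fit
#' is assessed. The input is not modified.
#'
#' @param x an [ib_data] object.
#' @param count number of anchor records to append (default 20).
#' @param conception_age anchor abscissa in years; the default -0.75 places
#'   conception a full-term gestation before birth.
#' @return a new [ib_data] with `count` extra `conception_anchor` records.
#' @export
add_conception_anchors <- function(x, count = 20, conception_age = -0.75) {
  stopifnot(inherits(x, "ib_data"))
  if (!is.numeric(count) || count < 1) stop("'count' must be >= 1")
  count <- as.integer(count)
  out <- rbind(strip_ib(x),
               data.frame(age_years = rep(conception_age, count),
                          inhibin_pg_ml = 0,
                          source = "conception_anchor",
                          stringsAsFactors = FALSE))
  keep_attrs(out, x, conception_age = conception_age)
}

#' Impute adult reference values
#'
#' Appends `n_adult` records at `adult_age_years` whose levels are drawn
#' from a zero-truncated Gaussian on the square-root scale, calibrated so
#' the implied median and interquartile range match the adult reference
#' (median 170 pg/mL, IQR 125-215 pg/mL). These records anchor the fitted
#' curve beyond age 17 and are included when goodness of fit is assessed.
#'
#' @param x an [ib_data] object.
#' @param n_adult number of records to impute (default 300).
#' @param adult_age_years age assigned to the imputed records (default 30).
#' @param seed integer seed; the draw is reproducible from it.
#' @param median_pg_ml,iqr_pg_ml adult reference median and IQR in pg/mL.
#' @return a new [ib_data] with `n_adult` extra `imputed_adult` records.
#' @export
impute_adult_values <- function(x, n_adult = 300, adult_age_years = 30, seed,
                                median_pg_ml = 170, iqr_pg_ml = c(125, 215)) {
  stopifnot(inherits(x, "ib_data"))
  if (!is.numeric(n_adult) || n_adult < 1) stop("'n_adult' must be >= 1")
  if (missing(seed)) stop("'seed' is required for reproducible imputation")
  if (length(iqr_pg_ml) != 2L || diff(iqr_pg_ml) <= 0)
    stop("invalid calibration: IQR bounds must be ordered")
  n_adult <- as.integer(n_adult)
  mu <- sqrt(median_pg_ml)
  # normal IQR = 2 * qnorm(0.75) * sd
  sd <- (sqrt(iqr_pg_ml[2L]) - sqrt(iqr_pg_ml[1L])) / (2 * stats::qnorm(0.75))
  z <- with_seed(seed, rtrunc_norm0(n_adult, mu, sd))
  out <- rbind(strip_ib(x),
               data.frame(age_years = rep(as.numeric(adult_age_years), n_adult),
                          inhibin_pg_ml = z^2,
                          source = "imputed_adult",
                          stringsAsFactors = FALSE))
  keep_attrs(out, x)
}

# zero-truncated Gaussian draw (resampling; truncation mass is tiny at the
# calibrated mean/sd but the draw is exact either way)
rtrunc_norm0 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

keep_attrs <- function(df, template, conception_age = NULL) {
  attr(df, "label") <- attr(template, "label")
  attr(df, "conception_age") <- conception_age %||% attr(template, "conception_age")
  attr(df, "max_age") <- attr(template, "max_age")
  class(df) <- c("ib_data", "data.frame")
  validate_ib_data(df)
  df
}

strip_ib <- function(x) {
  d <- data.frame(age_years = x$age_years,
                  inhibin_pg_ml = x$inhibin_pg_ml,
                  source = x$source,
                  stringsAsFactors = FALSE)
  d
}
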