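# Canonical column order of the per-site input file.
.input_columns <- c("Date", "Doy", "lon", "lat", "PREC", "TG", "TN", "TX",
                    "PET", "RG", "AET", "SM_top", "SM_full")

#' Read a per-site input CSV
#'
#' Parses the published per-site input layout (`Date, Doy, lon, lat,
#' PREC, TG, TN, TX, PET, RG, AET, SM_top, SM_full`), validates the
#' calendar (daily, contiguous) and basic unit sanity (`PREC >= 0`,
#' soil moisture in `[0, 1]`), and returns typed series.
#'
#' Columns beyond `Date` and `PREC` may be absent or empty depending on
#' what a command needs; validation applies to whatever is present.
#'
#' @param path CSV file path.
#' @param strict if `TRUE`, out-of-range values are an error; if
#'   `FALSE` (default) they become `NA` with a warning.
#' @return list with `table` (the raw `data.frame`), `lat`, `lon`, and
#'   one [daily_series()] per recognized numeric variable (`prec`,
#'   `tg`, `tn`, `tx`, `pet`, `rg`, `aet`, `sm_top`, `sm_full`; `NULL`
#'   when the column is missing).
#' @export
read_site_input <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("Date", "PREC")) {
    if (!col %in% names(df)) {
      stop(sprintf("read_site_input: missing mandatory column '%s'", col))
    }
  }
  dates <- as.Date(df$Date)
  if (anyNA(dates)) stop("read_site_input: unparseable Date entries")
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L)) {
    stop("read_site_input: dates must be contiguous daily steps")
  }
  sanitize <- function(x, lo, hi, name) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) {
      msg <- sprintf("%s: %d value(s) outside [%g, %g]", name, sum(bad), lo, hi)
      if (strict) stop("read_site_input: ", msg)
      warning("read_site_input: ", msg, "; set to NA", call. = FALSE)
      x[bad] <- NA_real_
    }
    x
  }
  grab <- function(col, units = "", lo = -Inf, hi = Inf) {
    if (!col %in% names(df)) return(NULL)
    v <- suppressWarnings(as.numeric(df[[col]]))
    daily_series(dates, sanitize(v, lo, hi, col), units = units)
  }
  list(table = df,
       lat = if ("lat" %in% names(df)) df$lat[1] else NA_real_,
       lon = if ("lon" %in% names(df)) df$lon[1] else NA_real_,
       prec = grab("PREC", "mm", lo = 0),
       tg = grab("TG", "degC"), tn = grab("TN", "degC"),
       tx = grab("TX", "degC"),
       pet = grab("PET", "mm", lo = 0), rg = grab("RG", "MJ m-2 day-1", lo = 0),
       aet = grab("AET", "mm", lo = 0),
       sm_top = grab("SM_top", "dimensionless", lo = 0, hi = 1),
       sm_full = grab("SM_full", "dimensionless", lo = 0, hi = 1))
}

#' Write a per-site input CSV
#'
#' Writes a site table (e.g. from [generate_site()]) in the canonical
#' column order, dates ISO-8601, missing values as empty fields.
#'
#' @param table `data.frame` with the input-layout columns.
#' @param path output path.
#' @param digits decimal places for numeric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_site_input <- function(table, path, digits = 4) {
  miss <- setdiff(.input_columns, names(table))
  if (length(miss) > 0) {
    stop("write_site_input: missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- table[.input_columns]
  out$Date <- format(as.Date(out$Date), "%Y-%m-%d")
  for (nm in setdiff(.input_columns, c("Date", "Doy"))) {
    out[[nm]] <- round(out[[nm]], digits)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write index tables in the published per-site file layout
#'
#' Emits `SPI_[site].csv`, `SPEI_[site].csv` and/or `SSMI_[site].csv`
#' into `dir`, each with a `Date` column plus the index columns
#' (`SPI_5 ... SPI_720`, or `SSMI_top`/`SSMI_full`). Missing values are
#' empty fields; numbers use fixed decimal formatting.
#'
#' @param site_name site identifier used in the file names.
#' @param tables named list of `sdi_table`s; names among `"SPI"`,
#'   `"SPEI"`, `"SSMI"` (defaults to each table's own index attribute).
#' @param dir output directory (created if needed).
#' @param digits decimal places (default 4).
#' @return character vector of the paths written, invisibly.
#' @export
write_index_files <- function(site_name, tables, dir = ".", digits = 4) {
  if (inherits(tables, "sdi_table")) tables <- list(tables)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    stopifnot(inherits(tab, "sdi_table"))
    index <- if (!is.null(names(tables)) && nzchar(names(tables)[i])) {
      names(tables)[i]
    } else attr(tab, "index")
    path <- file.path(dir, sprintf("%s_%s.csv", index, site_name))
    out <- as.data.frame(tab)
    out$Date <- format(out$Date, "%Y-%m-%d")
    for (nm in setdiff(names(out), "Date")) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          formatC(out[[nm]], format = "f", digits = digits))
    }
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read an index CSV written by [write_index_files()]
#'
#' @param path CSV path.
#' @return an `sdi_table`.
#' @export
read_index_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("index file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"Date" %in% names(df)) stop("read_index_file: missing 'Date' column")
  dates <- as.Date(df$Date)
  cols <- setdiff(names(df), "Date")
  index <- sub("_.*$", "", cols[1])
  vals <- lapply(df[cols], as.numeric)
  new_sdi_table(dates, vals, index)
}
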