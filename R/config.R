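#' Package configuration defaults
#'
#' Every tunable knob of the pipeline in one place, overridable from a
#' plain `key = value` text file via [read_sdi_config()].
#'
#' @param ... overrides of the defaults below.
#' @return named list with:
#' \describe{
#'   \item{min_sample_size}{minimum cross-year climatology size (30).}
#'   \item{min_frac}{rolling-window completeness threshold (0.9).}
#'   \item{wet_threshold}{precipitation at or below this is a dry day
#'     (0 mm).}
#'   \item{hargreaves_coef}{PET coefficient (0.00023).}
#'   \item{nrmse_normalization}{`"sd"`, `"mean"` or `"range"`.}
#'   \item{window_days}{rolling-correlation window (14).}
#'   \item{centered_window}{centered instead of trailing windows (FALSE).}
#'   \item{season}{months of the correlation-field season (5:9).}
#'   \item{digits}{decimal places in output files (4).}
#'   \item{pool_days}{half-width of optional neighbouring-day pooling of
#'     climatologies (0 = strict per-day samples).}
#'   \item{fraction_or_worse}{drought-area counting convention (TRUE).}
#' }
#' @export
sdi_config <- function(...) {
  cfg <- list(min_sample_size = 30L, min_frac = 0.9, wet_threshold = 0,
              hargreaves_coef = 0.00023, nrmse_normalization = "sd",
              window_days = 14L, centered_window = FALSE, season = 5:9,
              digits = 4L, pool_days = 0L, fraction_or_worse = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("sdi_config: unknown option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Read configuration overrides from a plain text file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Values are parsed as numbers or
#' logicals where possible, else kept as strings; comma-separated
#' values become vectors.
#'
#' @param path text file path.
#' @return a full configuration list (defaults plus overrides).
#' @export
read_sdi_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("read_sdi_config: malformed line: ", ln)
    key <- trimws(kv[1])
    raw <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      val <- if (all(toupper(raw) %in% c("TRUE", "FALSE"))) {
        as.logical(raw)
      } else raw
    }
    over[[key]] <- val
  }
  do.call(sdi_config, over)
}
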