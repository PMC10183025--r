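# The three published drought-category schemes. Each is an ordered set
# of (upper bound, label) pairs on the SDI scale; a value belongs to the
# most severe category whose bound it lies strictly below. Bounds use
# strict "<": an index exactly on a boundary falls to the milder class.
.schemes <- list(
  mckee = data.frame(
    bound = c(-2.0, -1.5, -1.0, 0.0),
    label = c("extreme", "severe", "moderate", "mild"),
    stringsAsFactors = FALSE),
  agnew = data.frame(
    bound = c(-1.65, -1.28, -0.84),
    label = c("extreme", "severe", "moderate"),
    stringsAsFactors = FALSE),
  usdm = data.frame(
    bound = c(-2.00, -1.65, -1.28, -0.84, -0.50),
    label = c("D4", "D3", "D2", "D1", "D0"),
    stringsAsFactors = FALSE)
)

#' Drought classification scheme
#'
#' Returns the ordered thresholds of one of the three published
#' schemes: McKee's original deviation-anchored classes, Agnew's
#' probability-anchored classes, or the U.S. Drought Monitor D0-D4
#' categories.
#'
#' @param name `"mckee"`, `"agnew"` or `"usdm"`.
#' @param agnew_mild if `TRUE`, adds Agnew's optional mild class
#'   (bound -0.5 at nominal probability 0.3) to the `agnew` scheme.
#' @return a `data.frame` with columns `bound` (strictly increasing SDI
#'   upper bounds) and `label`.
#' @export
classification_scheme <- function(name = c("mckee", "agnew", "usdm"),
                                  agnew_mild = FALSE) {
  name <- match.arg(name)
  sc <- .schemes[[name]]
  if (name == "agnew" && agnew_mild) {
    sc <- rbind(sc, data.frame(bound = -0.5, label = "mild"))
  }
  sc
}

#' Classify index values into drought categories
#'
#' Each finite SDI value is assigned the most severe category whose
#' upper bound it lies strictly below; values at or above every bound
#' (in particular all nonnegative values) are `"no drought"`.
#'
#' @param sdi numeric index values (`NA` yields `NA`).
#' @param scheme scheme name or a `data.frame` from
#'   [classification_scheme()].
#' @return character vector of category labels.
#' @examples
#' classify_sdi(c(-2.5, -1.0, 0.5), "mckee") # extreme, mild, no drought
#' @export
classify_sdi <- function(sdi, scheme = "mckee") {
  if (is.character(scheme)) scheme <- classification_scheme(scheme)
  stopifnot(is.data.frame(scheme), all(c("bound", "label") %in% names(scheme)))
  if (is.unsorted(scheme$bound, strictly = TRUE)) {
    stop("classify_sdi: scheme bounds must be strictly increasing")
  }
  out <- rep(NA_character_, length(sdi))
  ok <- !is.na(sdi)
  # findInterval counts bounds <= sdi, so a value equal to a bound is
  # pushed to the milder class — exactly the strict "<" convention.
  pos <- findInterval(sdi[ok], scheme$bound) + 1L
  labels <- c(scheme$label, "no drought")
  out[ok] <- labels[pmin(pos, length(labels))]
  out
}

#' Fraction of sites in drought per day
#'
#' Given one index value per site and day, computes the share of sites
#' whose index is at the given category or worse. Sites with a missing
#' index on a day are excluded from that day's denominator; days with
#' no valid site at all are `NA`.
#'
#' @param sdi_matrix numeric matrix, sites in rows, days in columns
#'   (column names may carry the dates).
#' @param scheme scheme name or `data.frame`.
#' @param category label of the category of interest (default the most
#'   severe one).
#' @param or_worse if `TRUE` (default) counts the category or any more
#'   severe one; if `FALSE` counts the exact category only.
#' @return numeric vector of fractions in `[0, 1]`, one per day.
#' @export
drought_area_fraction <- function(sdi_matrix, scheme = "mckee",
                                  category = NULL, or_worse = TRUE) {
  if (is.character(scheme)) scheme <- classification_scheme(scheme)
  if (is.data.frame(sdi_matrix)) sdi_matrix <- as.matrix(sdi_matrix)
  if (!is.matrix(sdi_matrix)) stop("sdi_matrix must be a sites x days matrix")
  if (is.null(category)) category <- scheme$label[1]
  ci <- match(category, scheme$label)
  if (is.na(ci)) stop(sprintf("unknown category '%s' for this scheme", category))
  valid <- !is.na(sdi_matrix)
  if (or_worse) {
    hit <- valid & sdi_matrix < scheme$bound[ci]
  } else {
    lower <- if (ci == 1L) -Inf else scheme$bound[ci - 1L]
    hit <- valid & sdi_matrix < scheme$bound[ci] & sdi_matrix >= lower
  }
  denom <- colSums(valid)
  frac <- colSums(hit) / denom
  frac[denom == 0] <- NA_real_
  frac
}
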