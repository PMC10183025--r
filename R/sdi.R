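# Rational normal-quantile approximation constants (Abramowitz & Stegun
# 26.2.23 form). These exact printed values are part of the method
# definition, not tunables.
.ns_const <- list(C0 = 2.515517, C1 = 0.802853, C2 = 0.010328,
                  d1 = 1.432788, d2 = 0.189269, d3 = 0.001308)

#' Equiprobability transformation to a standardized drought index
#'
#' Maps a non-exceedance probability `F` to the standard-normal score
#' with the same probability, using the classical rational approximation
#' of the normal quantile (absolute error < 4.5e-4):
#'
#' for `F <= 0.5`, `W = sqrt(-2 ln F)` and
#' `SDI = -(W - (C0 + C1 W + C2 W^2) / (1 + d1 W + d2 W^2 + d3 W^3))`;
#' for `F > 0.5` the mirrored branch with `W = sqrt(-2 ln(1 - F))` and a
#' positive sign. Thus `SDI < 0` exactly when `F < 0.5`: drier than the
#' median maps to negative scores, as in every drought classification
#' table.
#'
#' @param f non-exceedance probabilities, strictly inside (0, 1)
#'   (vectorized). `NA` propagates.
#' @return standard-normal scores.
#' @export
probability_to_sdi <- function(f) {
  bad <- !is.na(f) & (f <= 0 | f >= 1)
  if (any(bad)) {
    stop("probability_to_sdi: probabilities must lie strictly in (0, 1)")
  }
  k <- .ns_const
  lower <- !is.na(f) & f <= 0.5
  p <- ifelse(lower, f, 1 - f)
  w <- sqrt(-2 * log(p))
  core <- w - (k$C0 + k$C1 * w + k$C2 * w^2) /
    (1 + k$d1 * w + k$d2 * w^2 + k$d3 * w^3)
  ifelse(lower, -core, core)
}

#' Probability clipping bound for a finite climatology
#'
#' A target far outside the observed sample has an estimated probability
#' of essentially 0 or 1 and would map to an infinite score. With a
#' sample of size `n` the probability is clipped to
#' `[1/(2(n+1)), 1 - 1/(2(n+1))]`, so e.g. `n = 72` bounds the index to
#' about +/- 2.46.
#'
#' @param f probabilities.
#' @param n climatological sample size.
#' @return clipped probabilities.
#' @export
clip_probability <- function(f, n) {
  eps <- 1 / (2 * (n + 1))
  pmin(pmax(f, eps), 1 - eps)
}

#' Zero-inflated distribution model for precipitation
#'
#' Precipitation has an atom at zero that a plain kernel estimate
#' smears across the boundary. The mixture
#' `F(x) = q + (1 - q) * F_pos(x)` keeps the dry-day probability `q` as
#' a separate empirical mass and fits the kernel model on the strictly
#' positive values only; all dry days share the single probability `q`.
#'
#' @param sample numeric vector of nonnegative values (the
#'   climatological sample of aggregated precipitation).
#' @param wet_threshold values `<= wet_threshold` count as zero
#'   (default exactly 0).
#' @param bandwidth optional fixed bandwidth for the positive-part model.
#' @return object of class `zi_cdf` with fields `q`, `positive_model`
#'   (a [kde_model()], or `NULL` when fewer than 2 distinct positive
#'   values exist), `n`.
#' @export
zero_inflated_model <- function(sample, wet_threshold = 0, bandwidth = NULL) {
  sample <- as.numeric(sample)
  if (anyNA(sample)) stop("zero_inflated_model: sample must not contain NA")
  if (any(sample < 0)) stop("zero_inflated_model: precipitation must be >= 0")
  n <- length(sample)
  zero <- sample <= wet_threshold
  q <- sum(zero) / n
  if (q >= 1) {
    stop("zero_inflated_model: degenerate sample (no wet days at all)")
  }
  pos <- sample[!zero]
  pm <- if (length(unique(pos)) >= 2L) {
    kde_model(pos, bandwidth = bandwidth)
  } else {
    NULL # single repeated positive value; cdf degenerates to a step
  }
  structure(list(q = q, positive_model = pm, positive_values = pos, n = n),
            class = "zi_cdf")
}

#' Zero-inflated cumulative distribution
#'
#' Evaluates `F(x) = q + (1 - q) * F_pos(x)` for `x > 0` and `F(0) = q`.
#'
#' @param model a [zero_inflated_model()].
#' @param x nonnegative evaluation points (vectorized).
#' @return probabilities, nondecreasing in `x`, with `F(x) >= q`.
#' @export
zero_inflated_cdf <- function(model, x) {
  stopifnot(inherits(model, "zi_cdf"))
  if (any(!is.na(x) & x < 0)) {
    stop("zero_inflated_cdf: x must be >= 0")
  }
  fpos <- if (!is.null(model$positive_model)) {
    kde_cdf(model$positive_model, x)
  } else {
    as.numeric(x >= model$positive_values[1]) # degenerate step cdf
  }
  out <- model$q + (1 - model$q) * fpos
  out[!is.na(x) & x == 0] <- model$q
  out
}

#' Standardized index of a target value against a climatological sample
#'
#' One-shot version of the per-day standardization: estimate the
#' distribution of `sample` (zero-inflated kernel mixture for
#' precipitation, plain kernel model otherwise), evaluate the
#' non-exceedance probability of `target`, clip it to the finite-sample
#' bounds, and transform to a standard-normal score.
#'
#' @param sample numeric climatological sample (no `NA`).
#' @param target value(s) to standardize (vectorized).
#' @param kind `"precipitation"` (zero-inflated pathway),
#'   `"water_balance"` or `"soil_moisture"` (plain pathway).
#' @param min_sample_size minimum `length(sample)` (default 30).
#' @param wet_threshold passed to [zero_inflated_model()].
#' @return standard-normal scores, monotone in `target`.
#' @export
sdi_from_sample <- function(sample, target,
                            kind = c("precipitation", "water_balance",
                                     "soil_moisture"),
                            min_sample_size = 30L, wet_threshold = 0) {
  kind <- match.arg(kind)
  sample <- as.numeric(sample)
  if (anyNA(sample)) stop("sdi_from_sample: sample must not contain NA")
  if (length(sample) < min_sample_size) {
    stop(sprintf("sdi_from_sample: sample size %d below minimum %d",
                 length(sample), min_sample_size))
  }
  n <- length(sample)
  if (kind == "precipitation") {
    m <- zero_inflated_model(sample, wet_threshold = wet_threshold)
    f <- zero_inflated_cdf(m, target)
  } else {
    m <- kde_model(sample)
    f <- kde_cdf(m, target)
  }
  probability_to_sdi(clip_probability(f, n))
}
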