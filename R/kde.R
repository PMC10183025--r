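#' Gaussian kernel density model
#'
#' Wraps a finite sample and a bandwidth into a fitted density model
#' with exact pdf and cdf evaluation. The bandwidth comes from
#' least-squares cross-validation by default (see [select_bandwidth()]).
#'
#' @param sample numeric vector of finite values.
#' @param bandwidth positive bandwidth; if `NULL` (default), selected by
#'   [select_bandwidth()].
#' @param min_sample_size minimum sample size (default 2 here; the index
#'   pipeline enforces its own climatological minimum upstream).
#' @return object of class `kde_model` with fields `sample`,
#'   `bandwidth`, `method` (`"cv"`, `"silverman-fallback"` or `"fixed"`),
#'   `n`.
#' @export
kde_model <- function(sample, bandwidth = NULL, min_sample_size = 2L) {
  sample <- as.numeric(sample)
  if (anyNA(sample) || any(is.infinite(sample))) {
    stop("kde_model: sample must contain only finite values")
  }
  if (length(sample) < min_sample_size) {
    stop(sprintf("kde_model: sample size %d below minimum %d",
                 length(sample), min_sample_size))
  }
  if (is.null(bandwidth)) {
    sel <- select_bandwidth(sample)
    bandwidth <- sel$bandwidth
    method <- sel$method
  } else {
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      stop("kde_model: bandwidth must be a positive number")
    }
    method <- "fixed"
  }
  structure(list(sample = sample, bandwidth = bandwidth, method = method,
                 n = length(sample)),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("<kde_model> n = %d, h = %.6g (%s)\n", x$n, x$bandwidth,
              x$method))
  invisible(x)
}

#' Kernel density estimate
#'
#' `f(x) = (1/(n h)) * sum_i phi((x - x_i)/h)` with `phi` the standard
#' normal density.
#'
#' @param model a [kde_model()].
#' @param x evaluation points (vectorized).
#' @return nonnegative densities.
#' @export
kde_pdf <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  vapply(x, function(xx) {
    mean(stats::dnorm((xx - model$sample) / model$bandwidth)) / model$bandwidth
  }, numeric(1))
}

#' Kernel distribution function
#'
#' `F(x) = (1/n) * sum_i Phi((x - x_i)/h)`: the exact cdf of the Gaussian
#' mixture, strictly increasing in `x`.
#'
#' @inheritParams kde_pdf
#' @return probabilities in (0, 1).
#' @export
kde_cdf <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  vapply(x, function(xx) {
    mean(stats::pnorm((xx - model$sample) / model$bandwidth))
  }, numeric(1))
}

#' Least-squares cross-validation criterion
#'
#' `CV(h) = int f(x|h)^2 dx - (2/n) * sum_i f_{-i}(x_i|h)` where
#' `f_{-i}` is the leave-one-out estimator with divisor `n - 1`. For the
#' Gaussian kernel both terms are available in closed form from the
#' pairwise differences: the squared-density integral is a normal
#' density sum at scale `h*sqrt(2)`.
#'
#' @param sample numeric vector, `n >= 2`, not all values identical.
#' @param h bandwidth(s), positive; vectorized over `h`.
#' @return `CV(h)`, one value per bandwidth (smaller is better).
#' @export
cv_score <- function(sample, h) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 2L) stop("cv_score: need at least 2 sample values")
  if (anyNA(sample) || any(is.infinite(sample))) {
    stop("cv_score: sample must be finite")
  }
  if (stats::var(sample) == 0) {
    stop("cv_score: degenerate sample (all values identical)")
  }
  if (any(!is.finite(h) | h <= 0)) stop("cv_score: h must be positive")
  d2 <- as.vector(outer(sample, sample, "-")^2) # n^2 values incl. diagonal
  vapply(h, function(hh) {
    # int f^2: (1/n^2) sum_{i,l} N(x_i - x_l; 0, 2 h^2)
    int_f2 <- sum(exp(-d2 / (4 * hh^2))) / (n^2 * hh * 2 * sqrt(pi))
    # sum_i f_{-i}(x_i): off-diagonal kernel sum with divisor (n-1)
    off <- sum(exp(-d2 / (2 * hh^2))) - n # diagonal terms are exp(0) = 1
    loo <- off / ((n - 1) * hh * sqrt(2 * pi))
    int_f2 - (2 / n) * loo
  }, numeric(1))
}

#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`; when the IQR is zero (heavily
#' tied data) the sd alone is used.
#'
#' @param sample numeric vector with positive variance.
#' @return positive bandwidth.
#' @export
silverman_bandwidth <- function(sample) {
  n <- length(sample)
  s <- stats::sd(sample)
  if (!is.finite(s) || s == 0) {
    stop("silverman_bandwidth: degenerate sample (zero variance)")
  }
  iqr <- stats::IQR(sample) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  0.9 * spread * n^(-1 / 5)
}

#' Cross-validated bandwidth selection
#'
#' Minimizes [cv_score()] over a log-spaced grid of `grid_size` points in
#' `[h_silverman/10, 10*h_silverman]`, then refines with golden-section
#' search between the grid neighbours of the minimum. If the grid
#' minimum sits on a boundary (CV monotone over the search range, which
#' happens for small or heavily tied samples) the Silverman rule is
#' returned instead and tagged `"silverman-fallback"`.
#'
#' @param sample numeric vector with at least 2 distinct values.
#' @param grid_size number of grid points (default 101).
#' @param tol relative tolerance of the golden-section refinement.
#' @return list with `bandwidth` and `method` (`"cv"` or
#'   `"silverman-fallback"`).
#' @export
select_bandwidth <- function(sample, grid_size = 101L, tol = 1e-4) {
  # work on the standardized sample: the CV criterion is exactly scale
  # equivariant, so this costs nothing and makes the selected bandwidth
  # scale with the data to floating precision
  s <- stats::sd(sample)
  if (!is.finite(s) || s == 0) {
    stop("select_bandwidth: degenerate sample (zero variance)")
  }
  z <- (sample - mean(sample)) / s
  h0 <- silverman_bandwidth(z)
  grid <- exp(seq(log(h0 / 10), log(10 * h0), length.out = grid_size))
  scores <- cv_score(z, grid)
  i <- which.min(scores)
  if (i == 1L || i == grid_size) {
    return(list(bandwidth = s * h0, method = "silverman-fallback"))
  }
  h <- golden_section(function(hh) cv_score(z, hh),
                      grid[i - 1L], grid[i + 1L], tol = tol)
  list(bandwidth = s * h, method = "cv")
}

# Deterministic derivative-free minimizer on [a, b].
golden_section <- function(f, a, b, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  c <- b - gr * (b - a)
  d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while ((b - a) > tol * (abs(a) + abs(b))) {
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}
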