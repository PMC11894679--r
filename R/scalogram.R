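#' Remove a least-squares linear trend
#'
#' @param x Numeric vector, length >= 2.
#' @return `x` minus its least-squares straight line; mean approximately 0.
#' @examples
#' detrend_linear(c(1, 2, 3))  # ~ c(0, 0, 0)
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to detrend", call. = FALSE)
  i <- seq_len(n)
  # closed-form simple regression; avoids lm() overhead in the hot path
  ibar <- (n + 1) / 2
  xbar <- mean(x)
  slope <- sum((i - ibar) * (x - xbar)) / sum((i - ibar)^2)
  x - (xbar + slope * (i - ibar))
}

#' Default largest scalogram scale
#'
#' Scales range from a one-sample neighbour separation up to half the window
#' length: `L = ceiling(N / 2) - 1`.
#'
#' @param n Window length in samples (>= 3).
#' @return Number of scales `L`.
#' @export
max_scale_default <- function(n) {
  if (n < 3L) stop("window must have at least 3 samples", call. = FALSE)
  as.integer(ceiling(n / 2) - 1)
}

#' Largest scale needed for a minimum plausible heart rate
#'
#' Truncates the scalogram to scales corresponding to heart rates at or above
#' `hr_min`: a periodic pulse of period `T` samples is resolved at scales up
#' to `T / 2`, and `T <= fs * 60 / hr_min` when the heart rate is at least
#' `hr_min`, giving `L = min(max_scale_default(n), ceiling(fs * 60 / (2 *
#' hr_min)))`.
#'
#' @param fs Sampling frequency (Hz, > 0).
#' @param hr_min Minimum plausible heart rate (bpm, > 0), or `NULL` for no
#'   truncation.
#' @param n Window length in samples.
#' @return Number of scales `L`.
#' @export
max_scale_for_hrmin <- function(fs, hr_min, n) {
  if (is.null(hr_min)) return(max_scale_default(n))
  stopifnot(fs > 0, hr_min > 0)
  as.integer(min(max_scale_default(n), ceiling(fs * 60 / (2 * hr_min))))
}

#' Compute a local maxima (or minima) scalogram
#'
#' The local maxima scalogram (LMS) is a boolean scale-by-sample matrix:
#' entry `(k, i)` is `TRUE` when sample `i` is strictly higher than both its
#' neighbours at separation `k` (`x[i] > x[i - k]` and `x[i] > x[i + k]`).
#' For the minima polarity the same test is applied to the negated signal,
#' so flagged columns are local troughs (pulse onsets). Ties never flag, so
#' flat segments are extremum-free by construction.
#'
#' Two computation methods are provided: `"loops"`, the direct nested
#' iteration over scales and samples, and `"vectorised"`, which evaluates each
#' scale's comparisons with vector operations. They produce bit-identical
#' matrices; `"vectorised"` is the faster formulation in R and is the preset
#' default.
#'
#' @param x Numeric sample vector.
#' @param L Number of scales (rows); at most `max_scale_default(length(x))`.
#' @param polarity `"maxima"` (pulse peaks) or `"minima"` (pulse onsets).
#' @param method `"vectorised"` or `"loops"`.
#' @return Object of class `lms`: list with `flags` (L x N logical matrix),
#'   `polarity`, `n`.
#' @examples
#' s <- compute_lms(c(0, 2, 1, 3, 0), L = 2)
#' which(s$flags[1, ])  # columns 2 and 4
#' @export
compute_lms <- function(x, L, polarity = c("maxima", "minima"),
                        method = c("vectorised", "loops")) {
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  n <- length(x)
  if (L < 1L || L > max_scale_default(n)) {
    stop("L must lie in [1, ceiling(n/2) - 1]", call. = FALSE)
  }
  y <- if (polarity == "minima") -x else x
  flags <- matrix(FALSE, nrow = L, ncol = n)
  if (method == "loops") {
    for (k in seq_len(L)) {
      for (i in (k + 1L):(n - k)) {
        if (y[i] > y[i - k] && y[i] > y[i + k]) flags[k, i] <- TRUE
      }
    }
  } else {
    for (k in seq_len(L)) {
      idx <- (k + 1L):(n - k)
      flags[k, idx] <- y[idx] > y[idx - k] & y[idx] > y[idx + k]
    }
  }
  structure(list(flags = flags, polarity = polarity, n = n), class = "lms")
}

#' @export
print.lms <- function(x, ...) {
  cat(sprintf("<lms> %s polarity, %d scales x %d samples, %d flags\n",
              x$polarity, nrow(x$flags), x$n, sum(x$flags)))
  invisible(x)
}

#' Per-scale extremum counts and the selected scale
#'
#' `gamma[k]` counts the flagged columns in scalogram row `k`; the selected
#' scale `lambda` is the row in which most points are classified as extrema.
#' Ties break to the smallest scale, favouring the finest resolution.
#'
#' @param lms An [compute_lms()] scalogram.
#' @return List with `gamma` (integer vector) and `lambda` (selected scale).
#' @export
scale_counts <- function(lms) {
  stopifnot(inherits(lms, "lms"))
  gamma <- as.integer(rowSums(lms$flags))
  list(gamma = gamma, lambda = which.max(gamma))
}

#' Extract extrema surviving all scales up to the selected one
#'
#' A sample is an extremum when it is flagged on every scalogram row
#' `k <= lambda`.
#'
#' @param lms An [compute_lms()] scalogram.
#' @param lambda Selected scale, `1 <= lambda <= nrow(lms$flags)`.
#' @return Ascending integer sample indices (1-based).
#' @export
extract_extrema <- function(lms, lambda) {
  stopifnot(inherits(lms, "lms"))
  if (lambda < 1L || lambda > nrow(lms$flags)) {
    stop("lambda out of range", call. = FALSE)
  }
  if (lambda == 1L) {
    which(lms$flags[1L, ])
  } else {
    which(colSums(lms$flags[seq_len(lambda), , drop = FALSE]) == lambda)
  }
}

#' One-polarity multiscale extremum detection on a raw vector
#'
#' Convenience composition: scalogram, scale selection, extraction.
#'
#' @inheritParams compute_lms
#' @return Ascending extremum indices (1-based).
#' @keywords internal
lms_extrema <- function(x, L, polarity, method = "vectorised") {
  s <- compute_lms(x, L, polarity, method)
  sc <- scale_counts(s)
  extract_extrema(s, sc$lambda)
}
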