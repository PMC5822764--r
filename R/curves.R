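#' Construct a time-intensity curve
#'
#' The elementary object of the kinetic analysis: one pixel's (or one
#' region's) fluorescence intensity sampled over the acquisition. Frame
#' times are seconds from the first frame; intensities are arbitrary
#' fluorescence units (A.U.). Spacing is nominally uniform (5 s in the
#' acquisition protocol) but need not be.
#'
#' @param times Numeric vector of frame times in seconds, strictly
#'   increasing, length >= 4.
#' @param intensities Numeric vector of fluorescence intensities (A.U.),
#'   same length as `times`, all finite.
#' @return An object of class `intensity_curve`: a list with elements
#'   `times` and `intensities`.
#' @export
intensity_curve <- function(times, intensities) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop("`times` and `intensities` must have equal length", call. = FALSE)
  }
  if (length(times) < 4L) {
    stop("an intensity curve needs at least 4 samples", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("`intensities` must be finite", call. = FALSE)
  }
  structure(list(times = times, intensities = intensities),
            class = "intensity_curve")
}

#' @export
print.intensity_curve <- function(x, ...) {
  cat(sprintf("<intensity_curve> %d samples, t = [%g, %g] s, I = [%g, %g] A.U.\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# Centered moving average; the window shrinks symmetrically at the edges so
# the smoothed series has the same length and no phase shift. Used only for
# landmark (onset/peak) detection, never for reported parameter values.
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Trapezoid quadrature weights for (possibly non-uniform) sample times:
# integral(f) == sum(w * f). Also the weighting of the first temporal
# moment used for MTT.
trapezoid_weights <- function(times) {
  n <- length(times)
  d <- diff(times)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}
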