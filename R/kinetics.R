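#' Kinetics extraction configuration
#'
#' Tunable settings for the time-intensity curve parameterization.
#'
#' @param smooth_window Odd integer; width (frames) of the centered moving
#'   average used only to locate the onset and peak landmarks. Default 3.
#' @param onset_fraction Fraction of the smoothed net peak that defines the
#'   curve onset (first smoothed sample at or above this level). Default 0.10.
#' @param noise_floor_k Validity threshold: a curve whose net maximum is
#'   below `noise_floor_k` times the pre-onset standard deviation is flagged
#'   `low-signal`. Set 0 to disable. Default 5.
#' @param mtt_reference Time origin for the mean transit time: `"acquisition"`
#'   (seconds from the first frame, the default) or `"onset"` (seconds from
#'   the detected onset).
#' @return A list of class `kinetics_config`.
#' @export
kinetics_config <- function(smooth_window = 3L,
                            onset_fraction = 0.10,
                            noise_floor_k = 5,
                            mtt_reference = c("acquisition", "onset")) {
  mtt_reference <- match.arg(mtt_reference)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("`smooth_window` must be a positive odd integer", call. = FALSE)
  }
  if (onset_fraction <= 0 || onset_fraction >= 1) {
    stop("`onset_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (noise_floor_k < 0) stop("`noise_floor_k` must be >= 0", call. = FALSE)
  structure(list(smooth_window = smooth_window,
                 onset_fraction = onset_fraction,
                 noise_floor_k = noise_floor_k,
                 mtt_reference = mtt_reference),
            class = "kinetics_config")
}

#' Estimate the pre-bolus baseline of a time-intensity curve
#'
#' The basal fluorescence level is the mean of all samples strictly before a
#' provisional onset, defined on the raw curve as the first sample whose
#' intensity exceeds `min + 0.10 * (max - min)`. If that sample is the very
#' first one, the baseline falls back to the raw minimum. This one-pass rule
#' breaks the circularity between baseline estimation and onset detection.
#'
#' @param curve An [intensity_curve()].
#' @param config A [kinetics_config()].
#' @return List with `baseline` (A.U.), `provisional_onset` (index, NA for a
#'   constant curve), `noise_sd` (SD of the pre-onset raw samples, used for
#'   the low-signal validity check) and `flag` (`"ok"` or `"constant"`).
#' @export
estimate_baseline <- function(curve, config = kinetics_config()) {
  stopifnot(inherits(curve, "intensity_curve"))
  y <- curve$intensities
  rng <- range(y)
  if (rng[1] == rng[2]) {
    return(list(baseline = rng[1], provisional_onset = NA_integer_,
                noise_sd = 0, flag = "constant"))
  }
  thr <- rng[1] + 0.10 * (rng[2] - rng[1])
  idx <- which(y > thr)[1]
  if (idx == 1L) {
    baseline <- rng[1]
    pre <- numeric(0)
  } else {
    pre <- y[seq_len(idx - 1L)]
    baseline <- mean(pre)
  }
  noise_sd <- if (length(pre) >= 3L) {
    stats::sd(pre)
  } else {
    # too few pre-onset samples for a direct SD: fall back to the SD of
    # successive differences of the whole curve (robust to the slow trend)
    stats::sd(diff(y)) / sqrt(2)
  }
  list(baseline = baseline, provisional_onset = idx,
       noise_sd = noise_sd, flag = "ok")
}

invalid_params <- function(reason, baseline = NA_real_) {
  structure(list(baseline = baseline, onset_time = NA_real_,
                 peak_time = NA_real_, i_max = NA_real_, t_rising = NA_real_,
                 bfi = NA_real_, mtt = NA_real_, auc = NA_real_,
                 valid = FALSE, reason = reason),
            class = "kinetic_params")
}

#' Extract the vascular tracer parameters from one time-intensity curve
#'
#' Implements the bolus-transit curve parameterization: after subtracting
#' the basal intensity ([estimate_baseline()]) and clipping at zero, the net
#' curve yields
#' \itemize{
#'   \item `i_max` — maximum of the (unsmoothed) net curve, A.U.; blood
#'     volume surrogate;
#'   \item `t_rising` — time from curve onset to the peak, s;
#'   \item `bfi` — blood flow index, `i_max / t_rising`, A.U./s;
#'   \item `auc` — trapezoidal integral of the net curve over the whole
#'     acquisition window, A.U.·s;
#'   \item `mtt` — mean transit time, the trapezoid-weighted first temporal
#'     moment of the net curve, s.
#' }
#' A moving-average smoothed copy of the net curve is used only to locate
#' the landmarks: the peak time is the earliest sample attaining the
#' smoothed maximum and the onset is the earliest sample at or above
#' `onset_fraction` of the smoothed peak. All reported amplitudes and
#' integrals come from the unsmoothed data. Ties resolve to the earliest
#' sample throughout.
#'
#' @param curve An [intensity_curve()].
#' @param config A [kinetics_config()].
#' @return An object of class `kinetic_params`: list with `baseline`,
#'   `onset_time`, `peak_time`, `i_max`, `t_rising`, `bfi`, `mtt`, `auc`,
#'   `valid`, `reason`. Invalid curves (reasons `"constant"`,
#'   `"degenerate-rise"`, `"low-signal"`, `"zero-mass"`) carry NA parameters.
#' @export
extract_params <- function(curve, config = kinetics_config()) {
  stopifnot(inherits(curve, "intensity_curve"), inherits(config, "kinetics_config"))
  bl <- estimate_baseline(curve, config)
  if (bl$flag == "constant") return(invalid_params("constant", bl$baseline))

  t <- curve$times
  net <- pmax(curve$intensities - bl$baseline, 0)
  if (all(net == 0)) return(invalid_params("zero-mass", bl$baseline))

  sm <- moving_average(net, config$smooth_window)
  speak <- max(sm)
  peak_idx <- which(sm == speak)[1]
  onset_idx <- which(sm >= config$onset_fraction * speak)[1]

  i_max <- max(net)
  if (config$noise_floor_k > 0 && i_max < config$noise_floor_k * bl$noise_sd) {
    return(invalid_params("low-signal", bl$baseline))
  }

  onset_time <- t[onset_idx]
  peak_time <- t[peak_idx]
  t_rising <- peak_time - onset_time
  if (t_rising <= 0) return(invalid_params("degenerate-rise", bl$baseline))

  w <- trapezoid_weights(t)
  mass <- sum(w * net)
  if (mass <= 0) return(invalid_params("zero-mass", bl$baseline))
  t_ref <- if (config$mtt_reference == "onset") t - onset_time else t
  mtt <- sum(w * t_ref * net) / mass
  auc <- pracma::trapz(t, net)

  structure(list(baseline = bl$baseline, onset_time = onset_time,
                 peak_time = peak_time, i_max = i_max, t_rising = t_rising,
                 bfi = i_max / t_rising, mtt = mtt, auc = auc,
                 valid = TRUE, reason = "ok"),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<kinetic_params> invalid (%s)\n", x$reason))
  } else {
    cat(sprintf(paste0("<kinetic_params> baseline %.4g, onset %.4g s, peak %.4g s, ",
                       "I_max %.4g, T_rising %.4g s, BFI %.4g, MTT %.4g s, AUC %.4g\n"),
                x$baseline, x$onset_time, x$peak_time, x$i_max, x$t_rising,
                x$bfi, x$mtt, x$auc))
  }
  invisible(x)
}

#' Coerce kinetic parameters to a one-row data frame
#' @param x A `kinetic_params` object.
#' @param ... Unused.
#' @export
as.data.frame.kinetic_params <- function(x, ...) {
  data.frame(baseline = x$baseline, onset_time = x$onset_time,
             peak_time = x$peak_time, i_max = x$i_max, t_rising = x$t_rising,
             bfi = x$bfi, mtt = x$mtt, auc = x$auc, valid = x$valid,
             reason = x$reason, stringsAsFactors = FALSE)
}

map_param_names <- c("baseline", "onset_time", "peak_time", "i_max",
                     "t_rising", "bfi", "mtt", "auc")

#' Per-pixel parameter maps over a masked image stack
#'
#' Applies [extract_params()] to the time vector of every pixel inside the
#' mask, producing one 2-D grid per tracer parameter. Invalid pixels (and
#' pixels outside the mask) carry `NaN`, never zero, so map statistics are
#' not biased toward the background.
#'
#' @param stack A `frame_stack` (see [frame_stack()]).
#' @param mask Logical or 0/1 matrix with the stack's frame dimensions;
#'   pixels to analyze.
#' @param config A [kinetics_config()].
#' @return An object of class `parameter_map`: list with one matrix per
#'   parameter (`i_max`, `t_rising`, `bfi`, `mtt`, `auc`, `baseline`,
#'   `onset_time`, `peak_time`), a logical `valid` matrix, the `mask`, and a
#'   `summary` data frame of pixel counts by validity reason.
#' @export
map_stack <- function(stack, mask, config = kinetics_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  dm <- dim(stack$frames)[1:2]
  mask <- mask_as_logical(mask, dm)
  if (!any(mask)) stop("empty mask: no pixels to analyze", call. = FALSE)
  idx <- which(mask)
  nt <- dim(stack$frames)[3]
  if (nt < 4L) stop("need at least 4 frames", call. = FALSE)

  maps <- lapply(map_param_names, function(p) {
    m <- matrix(NaN, dm[1], dm[2])
    m
  })
  names(maps) <- map_param_names
  valid <- matrix(FALSE, dm[1], dm[2])
  reasons <- character(length(idx))

  # pixel-major view: rows = pixels, cols = frames
  Y <- matrix(stack$frames, nrow = prod(dm), ncol = nt)[idx, , drop = FALSE]
  for (k in seq_along(idx)) {
    kp <- extract_params(intensity_curve(stack$times, Y[k, ]), config)
    reasons[k] <- kp$reason
    if (kp$valid) {
      valid[idx[k]] <- TRUE
      for (p in map_param_names) maps[[p]][idx[k]] <- kp[[p]]
    }
  }
  summary <- as.data.frame(table(reason = reasons), stringsAsFactors = FALSE)
  names(summary) <- c("reason", "n_pixels")
  structure(c(maps, list(valid = valid, mask = mask, summary = summary,
                         pixel_size_mm = stack$pixel_size_mm)),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %d x %d px, %d analyzed, %d valid\n",
              nrow(x$valid), ncol(x$valid), sum(x$mask), sum(x$valid)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

mask_as_logical <- function(mask, dm) {
  if (is.logical(mask)) m <- mask else m <- mask != 0
  if (!identical(dim(m), as.integer(dm))) {
    stop("mask dimensions do not match the frame dimensions", call. = FALSE)
  }
  m
}
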