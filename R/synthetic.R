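#' Bolus-transit curve model parameters
#'
#' The forward curve family: flat baseline `b` until arrival `t0`, a smooth
#' half-cosine rise of amplitude `A` over `Tr` seconds, then exponential
#' washout with time constant `tau` toward a retained plateau fraction
#' `rho` of the amplitude. `A` and `Tr` map one-to-one onto the extracted
#' I_max and T_rising, so ground truth is exact rather than fitted.
#'
#' @param b Baseline (A.U., >= 0).
#' @param t0 Bolus arrival time (s, >= 0).
#' @param A Net amplitude, the target I_max (A.U., >= 0).
#' @param Tr Rise time, the target T_rising (s, > 0).
#' @param tau Washout time constant (s, > 0).
#' @param rho Retained plateau fraction in [0, 1).
#' @return List of class `curve_model_params`.
#' @export
curve_model_params <- function(b, t0, A, Tr, tau, rho) {
  stopifnot(is.finite(b), b >= 0, is.finite(t0), t0 >= 0,
            is.finite(A), A >= 0, is.finite(Tr), Tr > 0,
            is.finite(tau), tau > 0, is.finite(rho), rho >= 0, rho < 1)
  structure(list(b = b, t0 = t0, A = A, Tr = Tr, tau = tau, rho = rho),
            class = "curve_model_params")
}

#' Evaluate the noiseless bolus-transit model curve
#'
#' @param p A [curve_model_params()] (or plain list with the same fields).
#' @param times Sample times (s, >= 0).
#' @return An [intensity_curve()].
#' @export
model_curve <- function(p, times) {
  if (any(times < 0)) stop("model support starts at t = 0", call. = FALSE)
  intensity_curve(times, model_values(times, p$b, p$t0, p$A, p$Tr, p$tau, p$rho))
}

# Vectorized over both times and parameters (equal-length parameter
# vectors recycle against `t`).
model_values <- function(t, b, t0, A, Tr, tau, rho) {
  u <- t - t0
  rise <- (1 - cospi(pmin(pmax(u / Tr, 0), 1))) / 2
  s <- pmax(u - Tr, 0)
  wash <- rho + (1 - rho) * exp(-s / tau)
  phase <- ifelse(u <= Tr, rise, wash)
  b + A * ifelse(u <= 0, 0, phase)
}

#' Closed-form moments of the noiseless net model curve
#'
#' Exact window-limited integrals of the net (baseline-free) model curve
#' over `[0, t_end]`: the zeroth moment (AUC) and first temporal moment,
#' hence the mean transit time. Used as generator ground truth; the tests
#' check it against an independent fine-grid numerical oracle.
#'
#' @param p A [curve_model_params()].
#' @param t_end End of the acquisition window (s); must exceed `t0 + Tr`.
#' @return List with `auc` (A.U.*s), `mtt` (s, from acquisition start),
#'   `i_max` (= A), `t_rising` (= Tr), `bfi` (= A/Tr).
#' @export
model_curve_moments <- function(p, t_end) {
  with(p, {
    if (t_end <= t0 + Tr) stop("window must contain the full rise", call. = FALSE)
    S <- t_end - t0 - Tr
    E <- exp(-S / tau)
    m0 <- A * (Tr / 2 + rho * S + (1 - rho) * tau * (1 - E))
    t1 <- t0 + Tr
    m1_rise <- A * (t0 * Tr / 2 + Tr^2 / 4 + Tr^2 / pi^2)
    m1_plateau <- A * rho * (t_end^2 - t1^2) / 2
    m1_decay <- A * (1 - rho) * (t1 * tau * (1 - E) + tau^2 * (1 - E) - tau * S * E)
    list(auc = m0, mtt = (m1_rise + m1_plateau + m1_decay) / m0,
         i_max = A, t_rising = Tr, bfi = A / Tr)
  })
}

#' Simulate a noisy sampled curve from the model
#'
#' Noise is additive Gaussian with shot-like scaling: at intensity `I` the
#' standard deviation is `noise_level * sqrt(I)`.
#'
#' @param p A [curve_model_params()].
#' @param times Sample times (s).
#' @param noise_level Shot-noise coefficient (A.U.^(1/2) units); 0 gives
#'   the noiseless curve.
#' @return An [intensity_curve()].
#' @export
simulate_curve <- function(p, times, noise_level = 0) {
  y <- model_values(times, p$b, p$t0, p$A, p$Tr, p$tau, p$rho)
  if (noise_level > 0) {
    y <- y + stats::rnorm(length(y), 0, noise_level * sqrt(pmax(y, 0)))
  }
  intensity_curve(times, y)
}

# ---- group profiles -------------------------------------------------------

# Solve the washout time constant so the model's window-limited net AUC per
# unit amplitude equals `dur_target` (= AUC / I_max), given t0, Tr, rho.
# When the target exceeds what any bounded curve can deliver in the window
# the constant clamps at `tau_max` (the printed clinical summary statistics
# are not all jointly attainable; amplitude and rise time take priority).
calibrate_tau <- function(dur_target, t0, Tr, rho, t_end,
                          tau_range = c(10, 3000)) {
  dur <- function(tau) {
    S <- t_end - t0 - Tr
    Tr / 2 + rho * S + (1 - rho) * tau * (1 - exp(-S / tau)) - dur_target
  }
  if (dur(tau_range[2]) < 0) return(tau_range[2])
  if (dur(tau_range[1]) > 0) return(tau_range[1])
  stats::uniroot(dur, tau_range, tol = 1e-6)$root
}

# Calibrate the model rise time (and, when an AUC target is present, the
# washout constant) against the extractor itself: the fractional-peak onset
# definition detects onset ~20% into the half-cosine ramp and the 5-s
# sampling quantizes both landmarks, so the model Tr that yields a target
# extracted T_rising is found by a deterministic grid search, averaging the
# noiseless extraction over the arrival-time distribution.
calibrate_cell <- function(cell, times, t0_sd = 6, b = 100) {
  t_end <- times[length(times)]
  t0s <- pmax(cell$t0 + stats::qnorm(seq(0.1, 0.9, by = 0.2)) * t0_sd, 8)
  mean_extracted <- function(tr_model, tau, what) {
    vals <- vapply(t0s, function(t0) {
      y <- model_values(times, b, t0, cell$imax, tr_model, tau, cell$rho)
      kp <- extract_params(intensity_curve(times, y))
      if (kp$valid) kp[[what]] else NA_real_
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  mean_extracted_tr <- function(tr_model, tau) {
    mean_extracted(tr_model, tau, "t_rising")
  }
  pick_tr <- function(tau) {
    hi <- min(cell$tr * 1.8, t_end - max(t0s) - 30)
    grid <- seq(cell$tr * 0.9, max(hi, cell$tr * 0.95),
                by = max(0.25, cell$tr * 0.01))
    errs <- vapply(grid, function(trm) {
      abs(mean_extracted_tr(trm, tau) - cell$tr)
    }, 0)
    grid[which.min(errs)]
  }
  tau <- if (!is.null(cell$tau)) cell$tau else
    calibrate_tau(cell$auc / cell$imax, cell$t0, cell$tr, cell$rho, t_end)
  tr_model <- pick_tr(tau)
  if (is.null(cell$tau)) {
    tau <- calibrate_tau(cell$auc / cell$imax, cell$t0, tr_model, cell$rho, t_end)
    tr_model <- pick_tr(tau)
  }
  # amplitude factor compensating the slight downward bias of the
  # baseline-then-max extraction on smooth noiseless curves
  imax_raw <- mean_extracted(tr_model, tau, "i_max")
  imax_cal <- cell$imax / imax_raw
  # predicted noiseless extraction for the central limb (closure targets)
  predicted <- list(i_max = imax_raw * imax_cal,
                    t_rising = mean_extracted(tr_model, tau, "t_rising"),
                    mtt = mean_extracted(tr_model, tau, "mtt"),
                    auc = mean_extracted(tr_model, tau, "auc") * imax_cal)
  predicted$bfi <- predicted$i_max / predicted$t_rising
  list(tr_model = tr_model, tau = tau, imax_cal = imax_cal,
       predicted = predicted)
}

#' Default group kinetic profiles
#'
#' Kinetic parameter distributions per study group — C (control), D
#' (diabetes without complications), M (diabetes with microvascular
#' complications) — per limb (foot/hand) and region (digit/dorsum),
#' calibrated so that extracted parameters over a cohort approximate the
#' reference clinical foot means and SDs. Amplitude `A` targets the I_max
#' mean/SD directly; rise time `Tr` targets the I_max/BFI ratio; the
#' washout constant is solved from the AUC target ([curve_model_params()]
#' family), so MTT and AUC are emergent. Hand values (no reference table)
#' are chosen at the same order of magnitude with group ordering preserved.
#'
#' Stimulation response: per-subject post/pre BFI ratios are lognormal
#' around a group-specific center — controls respond (ratio well above 1),
#' the D group responds heterogeneously (some hands decrease), the M group
#' does not respond (ratio centered on 1 with a tight spread).
#'
#' @param noise_level Shot-noise coefficient for generated stacks
#'   (default 1.5, i.e. about 1.5 percent of peak at the control toe
#'   amplitude).
#' @param pixel_size_mm Pixel size of generated stacks (default 0.5).
#' @param n_frames,dt_s Acquisition protocol (default 120 frames at 5 s).
#' @return Nested list of class `group_profile`.
#' @export
group_profiles <- function(noise_level = 1.5, pixel_size_mm = 0.5,
                           n_frames = 120L, dt_s = 5) {
  t_end <- (n_frames - 1) * dt_s
  # reference foot summary values: mean I_max / SD / mean BFI / AUC target
  foot <- list(
    C = list(digit  = list(imax = 8967.7, imax_sd = 2700.0, bfi = 199.4,
                           auc = 2736757, rho = 0.30, t0 = 25),
             dorsum = list(imax = 4750.4, imax_sd = 1092.9, bfi = 52.8,
                           auc = 1917892, rho = 0.50, t0 = 25)),
    D = list(digit  = list(imax = 3519.3, imax_sd = 1139.8, bfi = 17.1,
                           auc = 1448562, rho = 0.50, t0 = 35),
             dorsum = list(imax = 2907.3, imax_sd = 729.9, bfi = 10.6,
                           auc = 1309075, rho = 0.85, t0 = 35)),
    M = list(digit  = list(imax = 5798.9, imax_sd = 2742.9, bfi = 124.0,
                           auc = 1774164, rho = 0.30, t0 = 25),
             dorsum = list(imax = 3313.4, imax_sd = 960.9, bfi = 24.0,
                           auc = 1362036, rho = 0.50, t0 = 25))
  )
  # hands: no reference values; same ordering, rise times kept well above the frame
  # interval so BFI quantization noise stays small relative to responses
  hand <- list(
    C = list(digit  = list(imax = 9000, imax_sd = 2500, bfi = 9000 / 35,
                           tau = 150, rho = 0.30, t0 = 20),
             dorsum = list(imax = 5000, imax_sd = 1300, bfi = 5000 / 70,
                           tau = 200, rho = 0.45, t0 = 20)),
    D = list(digit  = list(imax = 4500, imax_sd = 1400, bfi = 4500 / 60,
                           tau = 400, rho = 0.50, t0 = 28),
             dorsum = list(imax = 3000, imax_sd = 800, bfi = 3000 / 150,
                           tau = 500, rho = 0.60, t0 = 28)),
    M = list(digit  = list(imax = 6500, imax_sd = 2600, bfi = 6500 / 50,
                           tau = 200, rho = 0.35, t0 = 20),
             dorsum = list(imax = 3500, imax_sd = 1000, bfi = 3500 / 100,
                           tau = 250, rho = 0.50, t0 = 20))
  )

  times <- (seq_len(n_frames) - 1) * dt_s
  finish_cell <- function(cell) {
    cell$tr <- cell$imax / cell$bfi
    cal <- calibrate_cell(cell, times, t0_sd = 6)
    cell$tr_model <- cal$tr_model
    cell$imax_cal <- cal$imax_cal
    cell$predicted <- cal$predicted
    if (is.null(cell$tau)) cell$tau <- cal$tau
    # truncation bounds: physiologic plausibility clip at +-(2, 2.5) SD
    cell$imax_lo <- max(0.2 * cell$imax, cell$imax - 2 * cell$imax_sd)
    cell$imax_hi <- cell$imax + 2.5 * cell$imax_sd
    cell
  }
  foot <- lapply(foot, function(g) lapply(g, finish_cell))
  hand <- lapply(hand, function(g) lapply(g, finish_cell))

  structure(list(
    foot = foot, hand = hand,
    baseline = list(mean = 100, sd = 10, lo = 50, hi = 150),
    t0_sd = 6, t0_lo = 8, t0_hi = 60,
    tr_cv_subject = 0.27, tr_cv_limb = 0.13,
    # share of the amplitude variance placed between subjects (the rest
    # varies limb to limb)
    subject_var_share = 0.8,
    responder = list(C = list(mean = 1.6, sd = 0.30),
                     D = list(mean = 1.25, sd = 0.45),
                     M = list(mean = 1.00, sd = 0.05)),
    responder_alpha = 0.6,   # share of the BFI response carried by I_max
    # within-region fields: amplitude varies with local vessel density;
    # timing varies only slightly (shared arterial supply), which also
    # keeps the region mean curve's peak sharp
    field_amp = list(A = 0.15, Tr = 0.04, b = 0.05, t0_sd_s = 0.8),
    field_sigma_px = 4,
    noise_level = noise_level, pixel_size_mm = pixel_size_mm,
    n_frames = as.integer(n_frames), dt_s = dt_s
  ), class = "group_profile")
}

# ---- geometry -------------------------------------------------------------

#' Desk-scale limb label geometry
#'
#' A scaled-down limb layout (default 64 x 96 pixels, an 1/8-scale version
#' of the 512 x 768 acquisition format): five digit strips (label 1) above
#' a rectangular dorsum block (label 2) on background 0.
#'
#' @param rows,cols Image dimensions (pixels).
#' @return Integer label matrix.
#' @export
limb_label_image <- function(rows = 64L, cols = 96L) {
  if (rows < 32L || cols < 48L) stop("geometry too small for the limb layout", call. = FALSE)
  labels <- matrix(0L, rows, cols)
  # five digits of uneven width and length, as on a real foot/hand — the
  # irregularity also keeps the scene free of strict spatial periodicity
  strip_w <- pmax(3L, round(cols / 12 * c(0.7, 0.95, 1.0, 0.9, 0.75)))
  starts <- round(seq(cols * 0.18, cols * 0.72, length.out = 5) +
                    cols / 96 * c(0, 1.5, 0, -1.5, 1))
  top <- max(2L, round(rows * 0.06))
  len <- round(rows * c(0.13, 0.16, 0.17, 0.15, 0.12))
  for (k in 1:5) {
    labels[seq(top + (k %% 2L), top + len[k]),
           starts[k]:(starts[k] + strip_w[k] - 1L)] <- 1L
  }
  dorsum_rows <- seq(round(rows * 0.31), round(rows * 0.88))
  dorsum_cols <- seq(round(cols * 0.25), round(cols * 0.75))
  labels[dorsum_rows, dorsum_cols] <- 2L
  labels
}

# Smooth zero-mean unit-SD Gaussian random field (FFT convolution of white
# noise with an isotropic Gaussian kernel).
gaussian_field <- function(rows, cols, sigma) {
  w <- matrix(stats::rnorm(rows * cols), rows, cols)
  kx <- stats::dnorm(pmin(0:(cols - 1), cols - (0:(cols - 1))), sd = sigma)
  ky <- stats::dnorm(pmin(0:(rows - 1), rows - (0:(rows - 1))), sd = sigma)
  K <- outer(ky, kx)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) / (rows * cols)
  (f - mean(f)) / stats::sd(f)
}

# Truncated-normal draws via inverse-CDF (deterministic under the seed).
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# ---- stack generation -----------------------------------------------------

#' Generate one synthetic bolus-transit image stack
#'
#' Draws per-pixel curve-model parameters from the group's region
#' distributions (amplitude, rise time, arrival) modulated by smooth
#' within-region spatial fields, evaluates the noiseless model curves, adds
#' seeded shot-like Gaussian noise, and returns the stack together with its
#' ground-truth label image and per-pixel generator parameters.
#'
#' @param profile A [group_profiles()] object.
#' @param group `"C"`, `"D"` or `"M"`.
#' @param limb `"foot"` or `"hand"`.
#' @param side `"left"` or `"right"`.
#' @param geometry `c(rows, cols)` of the generated frames (default 64 x 96).
#' @param seed Integer seed; the stack is bit-reproducible from
#'   `(profile, arguments, seed)`.
#' @param noise_level Override the profile's noise level (0 = noiseless).
#' @param subject_effects Optional list of subject/limb-level effects per
#'   region (internal use by [generate_cohort()]): `A_factor`, `Tr_factor`,
#'   `t0_shift`. When supplied, the region's central values are scaled by
#'   these instead of drawing fresh between-limb variation, so cohort
#'   variance is governed entirely by the cohort's random-effect structure.
#' @param meta Extra metadata stored in the stack.
#' @param frames_eval If `FALSE`, skip frame evaluation (ground truth only;
#'   `stack` is `NULL`).
#' @return List with `stack` (a [frame_stack()]), `regions` (a
#'   [region_set()]), and `truth` (list: per-pixel parameter matrices,
#'   `region_truth` data frame of closed-form region-mean parameters,
#'   `seed`).
#' @export
generate_stack <- function(profile, group = c("C", "D", "M"),
                           limb = c("foot", "hand"),
                           side = c("left", "right"),
                           geometry = c(64L, 96L), seed = 1L,
                           noise_level = NULL,
                           subject_effects = NULL, meta = list(),
                           frames_eval = TRUE) {
  stopifnot(inherits(profile, "group_profile"))
  group <- match.arg(group)
  limb <- match.arg(limb)
  side <- match.arg(side)
  if (is.null(noise_level)) noise_level <- profile$noise_level
  rows <- geometry[1]; cols <- geometry[2]
  set.seed(seed)

  labels <- limb_label_image(rows, cols)
  rset <- region_set(labels, limb = limb, side = side)
  times <- (seq_len(profile$n_frames) - 1) * profile$dt_s
  t_end <- times[length(times)]

  # per-pixel parameter matrices
  b_m <- A_m <- Tr_m <- t0_m <- tau_m <- rho_m <- matrix(0, rows, cols)
  region_truth <- NULL
  fa <- profile$field_amp

  for (rg in c("digit", "dorsum")) {
    cell <- profile[[limb]][[group]][[rg]]
    mask <- if (rg == "digit") rset$digit_mask else rset$dorsum_mask
    eff <- subject_effects[[rg]]

    if (is.null(eff)) {
      # standalone stack: draw the limb's central values from the cell's
      # full (truncated) distribution
      A0 <- rtnorm(1, cell$imax, cell$imax_sd, cell$imax_lo, cell$imax_hi)
      cv_tr <- sqrt(profile$tr_cv_subject^2 + profile$tr_cv_limb^2)
      sT <- sqrt(log(1 + cv_tr^2))
      Tr0 <- cell$tr_model * exp(sT * stats::rnorm(1) - sT^2 / 2)
      t00 <- rtnorm(1, cell$t0, profile$t0_sd, profile$t0_lo, profile$t0_hi)
    } else {
      # cohort stack: the cohort's subject/limb effects carry the variance
      A0 <- cell$imax * eff$A_factor
      Tr0 <- cell$tr_model * eff$Tr_factor
      t00 <- min(max(cell$t0 + eff$t0_shift, profile$t0_lo), profile$t0_hi)
    }
    A0 <- max(A0, 0.1 * cell$imax)
    Tr0 <- max(Tr0, 2 * profile$dt_s)
    Tr0 <- min(Tr0, t_end - t00 - 4 * profile$dt_s)
    b0 <- rtnorm(1, profile$baseline$mean, profile$baseline$sd,
                 profile$baseline$lo, profile$baseline$hi)

    fA <- gaussian_field(rows, cols, profile$field_sigma_px)
    fT <- gaussian_field(rows, cols, profile$field_sigma_px)
    fb <- gaussian_field(rows, cols, profile$field_sigma_px)
    f0 <- gaussian_field(rows, cols, profile$field_sigma_px)

    # model amplitude carries the calibration factor; A0 itself is the
    # target (extractor-facing) I_max recorded as ground truth
    A_m[mask] <- A0 * cell$imax_cal * pmax(1 + fa$A * fA[mask], 0.2)
    Tr_m[mask] <- pmax(Tr0 * (1 + fa$Tr * fT[mask]), profile$dt_s)
    b_m[mask] <- b0 * pmax(1 + fa$b * fb[mask], 0.5)
    t0_m[mask] <- pmin(pmax(t00 + fa$t0_sd_s * f0[mask], 2), profile$t0_hi + 10)
    tau_m[mask] <- cell$tau
    rho_m[mask] <- cell$rho

    # clamp so the rise always completes inside the window
    Tr_m[mask] <- pmin(Tr_m[mask], t_end - t0_m[mask] - 4 * profile$dt_s)

    mom <- model_curve_moments(
      list(b = b0, t0 = t00, A = A0, Tr = Tr0, tau = cell$tau, rho = cell$rho),
      t_end)
    # t_rising truth is the extractor-facing rise interval: the fractional
    # onset definition shortens the model ramp by the calibrated ratio
    tr_det <- Tr0 * cell$tr / cell$tr_model
    region_truth <- rbind(region_truth, data.frame(
      region = rg, b = b0, t0 = t00, A = A0, Tr_model = Tr0,
      tau = cell$tau, rho = cell$rho,
      i_max = mom$i_max, t_rising = tr_det, bfi = A0 / tr_det,
      mtt = mom$mtt, auc = mom$auc, n_pixels = sum(mask),
      stringsAsFactors = FALSE))
  }

  # the off-limb background is much darker than limb tissue (only tissue
  # reflects/autofluoresces under NIR illumination), so the scene has
  # persistent edges before dye arrival — what registration locks onto in
  # real pre-bolus frames
  bg <- 0.3 * profile$baseline$mean
  b_m[labels == 0] <- bg

  truth <- list(params = list(b = b_m, t0 = t0_m, A = A_m, Tr = Tr_m,
                              tau = tau_m, rho = rho_m),
                region_truth = region_truth, labels = labels, seed = seed)
  if (!frames_eval) {
    return(list(stack = NULL, regions = rset, truth = truth))
  }

  # evaluate all pixel curves (compiled kernel; pixels x frames)
  Y <- .synth_frames(times, as.vector(b_m), as.vector(t0_m), as.vector(A_m),
                     as.vector(Tr_m), as.vector(tau_m), as.vector(rho_m),
                     which(labels != 0) - 1L, noise_level)

  stack <- frame_stack(array(Y, dim = c(rows, cols, length(times))), times,
                       profile$pixel_size_mm,
                       meta = c(list(group = group, limb = limb, side = side,
                                     seed = seed), meta))
  list(stack = stack, regions = rset, truth = truth)
}

#' Rigidly translate frames to inject a motion artifact
#'
#' @param stack A [frame_stack()].
#' @param displacements Data frame or matrix with integer columns `dy`,
#'   `dx` (rows, columns; one row per frame): the translation applied to
#'   each frame. Vacated edges are filled with the frame's background
#'   (minimum) level.
#' @return The translated [frame_stack()].
#' @export
inject_motion <- function(stack, displacements) {
  stopifnot(inherits(stack, "frame_stack"))
  displacements <- as.matrix(displacements)
  nt <- dim(stack$frames)[3]
  if (nrow(displacements) != nt) {
    stop("need one displacement per frame", call. = FALSE)
  }
  if (any(displacements != round(displacements))) {
    stop("displacements must be integer pixels", call. = FALSE)
  }
  nr <- dim(stack$frames)[1]; nc <- dim(stack$frames)[2]
  if (any(abs(displacements[, 1]) >= nr) || any(abs(displacements[, 2]) >= nc)) {
    stop("displacement moves the limb outside the frame", call. = FALSE)
  }
  out <- stack$frames
  for (i in seq_len(nt)) {
    dy <- displacements[i, 1]; dx <- displacements[i, 2]
    if (dy == 0 && dx == 0) next
    f <- stack$frames[, , i]
    g <- matrix(min(f), nr, nc)
    src_r <- seq_len(nr) - dy
    src_c <- seq_len(nc) - dx
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    g[ok_r, ok_c] <- f[src_r[ok_r], src_c[ok_c]]
    out[, , i] <- g
  }
  stack$frames <- out
  stack
}

# ---- cohorts --------------------------------------------------------------

#' Generate a synthetic study cohort
#'
#' One stack per subject x side x condition, with subject-level random
#' effects shared across a subject's limbs and, for the post-stimulus
#' condition, a per-subject vascular responder ratio applied to the digit
#' inflow (split between amplitude and rise time so I_max and T_rising both
#' respond). Stacks are not materialized: each manifest row records its own
#' seed and [cohort_stack()] regenerates any stack bit-for-bit on demand
#' (or `out_dir` writes them all as TIFF + YAML).
#'
#' @param profile A [group_profiles()].
#' @param n_subjects Named vector of subjects per group (default
#'   `c(C = 14, D = 11, M = 16)`).
#' @param limb `"foot"` or `"hand"` (one cohort per limb type).
#' @param sides Character vector of sides (default both).
#' @param conditions `"rest"` and/or `"post"`.
#' @param geometry `c(rows, cols)` per stack.
#' @param seed Master integer seed.
#' @param truth Materialize the region-level ground-truth table (default
#'   `TRUE`; skip for large replicate studies that only need the analyzed
#'   output).
#' @param out_dir If non-NULL, write every stack (TIFF + YAML sidecar), the
#'   label image and `manifest.csv` there.
#' @return Object of class `icg_cohort`: `manifest` (data frame keyed by
#'   subject/group/limb/side/condition with per-item seeds and, if written,
#'   paths), `truth` (per-item region-level ground truth), `profile`,
#'   `geometry`, `responders` (per-subject ratios), `seed`.
#' @export
generate_cohort <- function(profile,
                            n_subjects = c(C = 14, D = 11, M = 16),
                            limb = c("foot", "hand"),
                            sides = c("left", "right"),
                            conditions = "rest",
                            geometry = c(64L, 96L),
                            seed = 1L, truth = TRUE, out_dir = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  limb <- match.arg(limb)
  stopifnot(all(conditions %in% c("rest", "post")))
  set.seed(seed)

  subjects <- NULL
  for (g in names(n_subjects)) {
    ng <- n_subjects[[g]]
    if (ng < 1) next
    ids <- sprintf("%s%02d", g, seq_len(ng))
    # lognormal subject/limb effects preserving the cell's mean amplitude
    # (cv split between the subject and limb levels)
    subjects <- rbind(subjects, data.frame(
      subject = ids, group = g,
      zA = stats::rnorm(ng), zTr = stats::rnorm(ng),
      t0_shift = stats::rnorm(ng, 0, profile$t0_sd),
      responder = exp(stats::rnorm(ng,
        log(profile$responder[[g]]$mean),
        profile$responder[[g]]$sd / profile$responder[[g]]$mean)),
      stringsAsFactors = FALSE))
  }

  grid <- expand.grid(condition = conditions, side = sides,
                      subject = subjects$subject,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject", "side", "condition")]
  grid <- merge(grid, subjects[, c("subject", "group")], by = "subject",
                sort = FALSE)
  grid <- grid[order(grid$subject, grid$side, grid$condition), ]
  grid$limb <- limb
  grid$item_id <- sprintf("%s_%s_%s_%s", grid$subject, limb, grid$side,
                          grid$condition)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  # limb-level (side) jitter seeds drawn per subject x side, shared across
  # conditions so rest and post differ only by the response + noise
  limb_key <- paste(grid$subject, grid$side)
  uk <- unique(limb_key)
  limb_z <- stats::rnorm(length(uk)); names(limb_z) <- uk
  limb_zTr <- stats::rnorm(length(uk)); names(limb_zTr) <- uk
  limb_rj <- stats::rnorm(length(uk), 0, 0.05); names(limb_rj) <- uk
  grid$limb_zA <- limb_z[limb_key]
  grid$limb_zTr <- limb_zTr[limb_key]
  grid$limb_rjit <- limb_rj[limb_key]

  cohort <- structure(list(manifest = grid, subjects = subjects,
                           profile = profile, geometry = geometry,
                           limb = limb, seed = seed, out_dir = out_dir),
                      class = "icg_cohort")

  # region-level ground truth per item (regenerating each stack's truth)
  if (truth) {
    cohort$truth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      gs <- cohort_stack(cohort, i, noise_level = 0, frames = FALSE)
      tr <- gs$truth$region_truth
      cbind(grid[rep(i, nrow(tr)),
                 c("item_id", "subject", "group", "limb", "side", "condition")],
            tr, row.names = NULL)
    }))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      gs <- cohort_stack(cohort, i)
      paths[i] <- file.path(out_dir, paste0(grid$item_id[i], ".tif"))
      write_stack(gs$stack, paths[i])
    }
    write_region_labels(limb_label_image(geometry[1], geometry[2]) ,
                        file.path(out_dir, "labels.png"))
    cohort$manifest$path <- paths
    utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  cohort
}

#' Materialize one cohort stack from its manifest row
#'
#' @param cohort An `icg_cohort` from [generate_cohort()].
#' @param i Manifest row index (or item_id string).
#' @param noise_level Optional override (0 for the noiseless stack).
#' @param frames If `FALSE`, skip frame evaluation and return ground truth
#'   only (fast).
#' @return As [generate_stack()].
#' @export
cohort_stack <- function(cohort, i, noise_level = NULL, frames = TRUE) {
  stopifnot(inherits(cohort, "icg_cohort"))
  m <- cohort$manifest
  if (is.character(i)) i <- match(i, m$item_id)
  row <- m[i, ]
  prof <- cohort$profile
  subj <- cohort$subjects[match(row$subject, cohort$subjects$subject), ]
  share <- prof$subject_var_share

  effects <- list()
  for (rg in c("digit", "dorsum")) {
    cell <- prof[[row$limb]][[row$group]][[rg]]
    cv <- cell$imax_sd / cell$imax
    sA <- sqrt(log(1 + cv^2))
    sT_s <- sqrt(log(1 + prof$tr_cv_subject^2))
    sT_l <- sqrt(log(1 + prof$tr_cv_limb^2))
    zA_tot <- sqrt(share) * subj$zA + sqrt(1 - share) * row$limb_zA
    # plausibility clip on the amplitude effect (mirrors the truncation
    # bounds of the standalone draw)
    zA_tot <- min(max(zA_tot, -2), 2.2)
    A_factor <- exp(sA * zA_tot - sA^2 / 2)
    Tr_factor <- exp(sT_s * subj$zTr + sT_l * row$limb_zTr -
                       (sT_s^2 + sT_l^2) / 2)
    t0_shift <- subj$t0_shift
    if (row$condition == "post") {
      r <- subj$responder * exp(row$limb_rjit)
      a <- prof$responder_alpha
      A_factor <- A_factor * r^a
      Tr_factor <- Tr_factor * r^(a - 1)   # BFI post/pre ratio == r
    }
    effects[[rg]] <- list(A_factor = A_factor, Tr_factor = Tr_factor,
                          t0_shift = t0_shift)
  }

  if (!frames) {
    # truth-only path: reuse generate_stack's deterministic draws but on a
    # minimal geometry to avoid evaluating frames
    gs <- generate_stack(prof, row$group, row$limb, row$side,
                         geometry = cohort$geometry, seed = row$seed,
                         noise_level = 0, subject_effects = effects,
                         meta = list(subject = row$subject,
                                     condition = row$condition),
                         frames_eval = FALSE)
    return(gs)
  }
  generate_stack(prof, row$group, row$limb, row$side,
                 geometry = cohort$geometry, seed = row$seed,
                 noise_level = noise_level, subject_effects = effects,
                 meta = list(subject = row$subject, condition = row$condition))
}

#' @export
print.icg_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<icg_cohort> %s, %d stacks (%d subjects; conditions: %s), %d x %d px, seed %d\n",
              x$limb, nrow(m), length(unique(m$subject)),
              paste(unique(m$condition), collapse = "/"),
              x$geometry[1], x$geometry[2], x$seed))
  invisible(x)
}
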