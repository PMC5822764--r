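test_that("baseline is the mean of the flat pre-bolus segment", {
  cv <- intensity_curve(0:4, c(10, 10, 10, 110, 60))
  bl <- estimate_baseline(cv)
  expect_equal(bl$baseline, 10)
  expect_equal(bl$provisional_onset, 4L)
})

test_that("constant curves take the degenerate baseline path", {
  cv <- intensity_curve(0:3, c(7, 7, 7, 7))
  bl <- estimate_baseline(cv)
  expect_equal(bl$baseline, 7)
  expect_identical(bl$flag, "constant")
  kp <- extract_params(cv)
  expect_false(kp$valid)
  expect_identical(kp$reason, "constant")
})

test_that("baseline recovers the generator level exactly on a noiseless curve", {
  # rise starts at frame 12 (t = 55 s) and is steep enough that the first
  # post-arrival sample crosses the 10%-range provisional threshold
  p <- curve_model_params(b = 100, t0 = 55, A = 1000, Tr = 20,
                          tau = 120, rho = 0.3)
  cv <- model_curve(p, protocol_times())
  bl <- estimate_baseline(cv)
  expect_equal(bl$baseline, 100, tolerance = 1e-9)
})

test_that("symmetric triangular pulses put MTT at the apex", {
  # steep flank: first rising sample exceeds the threshold, baseline = 0
  cv <- triangle_curve(lead = 20, half = 8, height = 100, dt = 1, total = 60)
  kp <- extract_params(cv, kinetics_config(noise_floor_k = 0))
  expect_true(kp$valid)
  expect_equal(kp$baseline, 0)
  expect_equal(kp$i_max, 100)
  expect_equal(kp$peak_time, 28)
  expect_equal(kp$mtt, 28, tolerance = 0.5 / 28)

  # shallow 50-s flanks: the sub-threshold ramp biases the baseline, but
  # symmetry still forces the first moment to the apex exactly
  cv2 <- triangle_curve(lead = 0, half = 50, height = 100, dt = 1, total = 100)
  kp2 <- extract_params(cv2, kinetics_config(noise_floor_k = 0))
  expect_equal(kp2$mtt, 50, tolerance = 1e-12)
  expect_equal(kp2$peak_time, 50)
})

test_that("rectangular pulse AUC converges to height x width", {
  for (dt in c(0.5, 0.1)) {
    t <- seq(0, 200, by = dt)
    y <- ifelse(t >= 100 & t <= 120, 10, 0)
    kp <- extract_params(intensity_curve(t, y), kinetics_config(noise_floor_k = 0))
    expect_true(kp$valid)
    expect_equal(kp$auc, 200, tolerance = 2 * dt * 10 / 200)
    expect_equal(kp$mtt, 110, tolerance = 1e-6)
  }
})

test_that("bfi * t_rising equals i_max for every valid extraction", {
  set.seed(42)
  times <- protocol_times()
  for (k in 1:200) {
    p <- curve_model_params(b = runif(1, 50, 150), t0 = runif(1, 10, 60),
                            A = runif(1, 200, 8000), Tr = runif(1, 15, 150),
                            tau = runif(1, 50, 500), rho = runif(1, 0, 0.8))
    cv <- simulate_curve(p, times, noise_level = runif(1, 0, 3))
    kp <- extract_params(cv)
    if (kp$valid) {
      expect_equal(kp$bfi * kp$t_rising, kp$i_max, tolerance = 1e-9)
      expect_lte(kp$onset_time, kp$peak_time)
      expect_gte(kp$t_rising, 0)
      expect_gte(kp$auc, 0)
      expect_true(kp$mtt >= 0 && kp$mtt <= max(times))
      expect_lte(kp$auc, kp$i_max * max(times))
    }
  }
})

test_that("intensity scaling is equivariant", {
  p <- curve_model_params(b = 100, t0 = 40, A = 1500, Tr = 45,
                          tau = 150, rho = 0.3)
  cv <- model_curve(p, protocol_times())
  kp <- extract_params(cv)
  for (c_ in c(2, 3.7, 0.25)) {
    kps <- extract_params(intensity_curve(cv$times, cv$intensities * c_))
    expect_equal(kps$i_max, kp$i_max * c_, tolerance = 1e-12)
    expect_equal(kps$bfi, kp$bfi * c_, tolerance = 1e-12)
    expect_equal(kps$auc, kp$auc * c_, tolerance = 1e-12)
    expect_equal(kps$baseline, kp$baseline * c_, tolerance = 1e-12)
    expect_identical(kps$t_rising, kp$t_rising)
    expect_identical(kps$onset_time, kp$onset_time)
    expect_identical(kps$peak_time, kp$peak_time)
    expect_equal(kps$mtt, kp$mtt, tolerance = 1e-12)
  }
})

test_that("time shifts move landmarks and MTT, leaving amplitudes alone", {
  # steep rise (first post-arrival sample crosses the provisional
  # threshold, so the baseline window holds only flat samples) and compact
  # support (washout decayed to numerical zero well before the window end)
  times <- protocol_times()
  p <- curve_model_params(b = 100, t0 = 60, A = 1000, Tr = 20,
                          tau = 25, rho = 0)
  kp <- extract_params(model_curve(p, times))
  for (k in c(2, 5, 10)) {
    ps <- curve_model_params(b = 100, t0 = 60 + k * 5, A = 1000, Tr = 20,
                             tau = 25, rho = 0)
    kps <- extract_params(model_curve(ps, times))
    expect_equal(kps$onset_time, kp$onset_time + k * 5)
    expect_equal(kps$peak_time, kp$peak_time + k * 5)
    expect_equal(kps$mtt, kp$mtt + k * 5, tolerance = 1e-6)
    expect_equal(kps$i_max, kp$i_max, tolerance = 1e-7)
    expect_identical(kps$t_rising, kp$t_rising)
    expect_equal(kps$bfi, kp$bfi, tolerance = 1e-7)
    expect_equal(kps$auc, kp$auc, tolerance = 1e-6)
  }
})

test_that("MTT and AUC agree with the fine-grid brute-force oracle", {
  p <- curve_model_params(b = 100, t0 = 60, A = 1000, Tr = 40,
                          tau = 120, rho = 0.4)
  fun <- function(t) model_curve(p, t)$intensities
  # dense sampling: quadrature error under 0.1%
  t_dense <- seq(0, 595, by = 0.1)
  kp <- extract_params(intensity_curve(t_dense, fun(t_dense)))
  orc <- oracle_moments(fun, kp$baseline, 595)
  expect_equal(kp$auc, orc$auc, tolerance = 1e-3)
  expect_equal(kp$mtt, orc$mtt, tolerance = 1e-3)
  # protocol sampling: within 2%
  t5 <- protocol_times()
  kp5 <- extract_params(intensity_curve(t5, fun(t5)))
  orc5 <- oracle_moments(fun, kp5$baseline, 595)
  expect_equal(kp5$auc, orc5$auc, tolerance = 0.02)
  expect_equal(kp5$mtt, orc5$mtt, tolerance = 0.02)
})

test_that("onset-relative MTT reference subtracts the onset time", {
  p <- curve_model_params(b = 100, t0 = 60, A = 1000, Tr = 40,
                          tau = 120, rho = 0.4)
  cv <- model_curve(p, protocol_times())
  a <- extract_params(cv, kinetics_config(mtt_reference = "acquisition"))
  o <- extract_params(cv, kinetics_config(mtt_reference = "onset"))
  expect_equal(o$mtt, a$mtt - a$onset_time, tolerance = 1e-12)
})

test_that("a curve already at peak is flagged degenerate-rise", {
  cv <- intensity_curve(0:5, c(100, 60, 30, 10, 5, 0))
  kp <- extract_params(cv, kinetics_config(noise_floor_k = 0))
  expect_false(kp$valid)
  expect_identical(kp$reason, "degenerate-rise")
})

test_that("bumps below the noise floor are rejected as low-signal", {
  # flat fluctuating background with a small bump: i_max (14 A.U.) sits
  # well under 5x the successive-difference noise estimate, so the pixel
  # is flagged rather than producing a spurious BFI
  y <- 100 + rep(c(4, -4), 60)
  y[60:62] <- y[60:62] + 10
  kp <- extract_params(intensity_curve(protocol_times(), y))
  expect_false(kp$valid)
  expect_identical(kp$reason, "low-signal")
  # the same bump scaled x40 clears the floor and is extracted
  y2 <- 100 + rep(c(4, -4), 60)
  y2[60:62] <- y2[60:62] + 400
  kp2 <- extract_params(intensity_curve(protocol_times(), y2))
  expect_true(kp2$valid)
  # disabling the floor admits the weak bump
  kp0 <- extract_params(intensity_curve(protocol_times(), y),
                        kinetics_config(noise_floor_k = 0))
  expect_true(kp0$valid)
})

test_that("map_stack broadcasts a shared curve and separates sub-regions", {
  times <- (0:19) * 5
  p <- curve_model_params(b = 50, t0 = 20, A = 800, Tr = 15, tau = 60, rho = 0.2)
  y <- model_curve(p, times)$intensities
  fr <- array(rep(y, each = 36), dim = c(6, 6, 20))
  st <- frame_stack(fr, times, 0.5)
  pm <- map_stack(st, matrix(TRUE, 6, 6))
  kp <- extract_params(intensity_curve(times, y))
  expect_true(all(pm$valid))
  expect_equal(unique(as.vector(pm$i_max)), kp$i_max)
  expect_equal(unique(as.vector(pm$mtt)), kp$mtt)

  # two sub-regions with different amplitudes -> bimodal i_max map
  y2 <- model_curve(curve_model_params(b = 50, t0 = 20, A = 400, Tr = 15,
                                       tau = 60, rho = 0.2), times)$intensities
  fr2 <- fr
  for (j in 4:6) for (i in 1:6) fr2[i, j, ] <- y2
  pm2 <- map_stack(frame_stack(fr2, times, 0.5), matrix(TRUE, 6, 6))
  vals <- sort(unique(round(as.vector(pm2$i_max), 6)))
  expect_length(vals, 2)
  expect_equal(diff(vals), 400, tolerance = 1e-6)
})

test_that("all-constant stacks yield fully invalid maps, empty masks error", {
  fr <- array(7, dim = c(4, 4, 10))
  st <- frame_stack(fr, (0:9) * 5, 0.5)
  pm <- map_stack(st, matrix(TRUE, 4, 4))
  expect_false(any(pm$valid))
  expect_true(all(is.nan(pm$i_max)))
  expect_identical(pm$summary$reason, "constant")
  expect_error(map_stack(st, matrix(FALSE, 4, 4)), "empty mask")
})
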