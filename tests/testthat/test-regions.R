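make_tiny_stack <- function(curves_by_pixel, times = (0:19) * 5) {
  # curves_by_pixel: rows x cols list-matrix of intensity vectors
  dm <- dim(curves_by_pixel)
  fr <- array(0, dim = c(dm[1], dm[2], length(times)))
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    fr[i, j, ] <- curves_by_pixel[[i, j]]
  }
  frame_stack(fr, times, 0.5)
}

test_that("region sets validate label codes and emptiness", {
  lab <- matrix(0L, 8, 8)
  lab[2:3, 2:5] <- 1L
  lab[5:7, 2:7] <- 2L
  rs <- region_set(lab)
  expect_equal(sum(rs$digit_mask), 8)
  expect_equal(sum(rs$dorsum_mask), 18)
  expect_false(any(rs$digit_mask & rs$dorsum_mask))

  expect_error(region_set(matrix(0L, 4, 4)), "no regions")
  bad <- lab; bad[1, 1] <- 7L
  expect_error(region_set(bad), "unknown region labels")
  only_digit <- lab; only_digit[only_digit == 2L] <- 0L
  expect_warning(rs2 <- region_set(only_digit), "empty")
  expect_true("empty-dorsum" %in% rs2$flags)
})

test_that("label images round-trip through PNG and TIFF", {
  lab <- limb_label_image(64, 96)
  for (ext in c("png", "tiff")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_region_labels(lab, f)
    rs <- load_region_set(f)
    expect_identical(rs$labels, lab)
  }
})

test_that("region curve is the spatial mean: identical pixels reproduce the single curve", {
  times <- (0:19) * 5
  y <- model_curve(curve_model_params(b = 50, t0 = 20, A = 800, Tr = 15,
                                      tau = 60, rho = 0.2), times)$intensities
  cb <- matrix(list(), 3, 3)
  for (k in seq_len(9)) cb[[k]] <- y
  st <- make_tiny_stack(cb, times)
  rp <- region_params(st, matrix(TRUE, 3, 3), pixel_dispersion = TRUE,
                      min_valid_pixels = 5L)
  kp <- extract_params(intensity_curve(times, y))
  expect_equal(rp$params$i_max, kp$i_max)
  expect_equal(rp$params$mtt, kp$mtt)
  expect_equal(rp$n_valid_pixels, 9L)
  # dispersion over identical pixels is zero
  expect_true(all(rp$dispersion$sd[rp$dispersion$parameter == "i_max"] == 0))
})

test_that("the mean curve is linear: two pixels with peaks 100 and 300 give 200", {
  times <- (0:19) * 5
  mk <- function(A) model_curve(curve_model_params(b = 0, t0 = 20, A = A,
                                                   Tr = 15, tau = 60,
                                                   rho = 0.2), times)$intensities
  cb <- matrix(list(mk(100), mk(300)), 1, 2)
  st <- make_tiny_stack(cb, times)
  rp <- region_params(st, matrix(TRUE, 1, 2), kinetics_config(noise_floor_k = 0),
                      pixel_dispersion = FALSE)
  expect_equal(rp$params$i_max, extract_params(
    intensity_curve(times, (mk(100) + mk(300)) / 2),
    kinetics_config(noise_floor_k = 0))$i_max)
  expect_equal(rp$params$i_max, 200, tolerance = 0.02)
})

test_that("union of two disjoint equal-size regions averages their curves", {
  set.seed(5)
  times <- (0:19) * 5
  fr <- array(runif(6 * 6 * 20, 50, 150), dim = c(6, 6, 20))
  st <- frame_stack(fr, times, 0.5)
  m1 <- matrix(FALSE, 6, 6); m1[, 1:3] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[, 4:6] <- TRUE
  c1 <- icgdyn:::region_mean_curve(st, m1)
  c2 <- icgdyn:::region_mean_curve(st, m2)
  cu <- icgdyn:::region_mean_curve(st, m1 | m2)
  expect_equal(cu, (c1 + c2) / 2, tolerance = 1e-12)
})

test_that("sparse regions are flagged low-confidence", {
  times <- (0:19) * 5
  y <- model_curve(curve_model_params(b = 50, t0 = 20, A = 800, Tr = 15,
                                      tau = 60, rho = 0.2), times)$intensities
  cb <- matrix(list(), 2, 2)
  for (k in 1:4) cb[[k]] <- y
  st <- make_tiny_stack(cb, times)
  rp <- region_params(st, matrix(TRUE, 2, 2), min_valid_pixels = 10L)
  expect_true("low-confidence" %in% rp$flags)
})

test_that("noiseless central-limb extraction reproduces the calibrated targets", {
  prof <- group_profiles()
  central <- list(digit = list(A_factor = 1, Tr_factor = 1, t0_shift = 0),
                  dorsum = list(A_factor = 1, Tr_factor = 1, t0_shift = 0))
  # average over several arrival times (t0 jitter), as in the calibration
  shifts <- c(-6, -3, 0, 3, 6)
  got <- matrix(0, length(shifts), 2,
                dimnames = list(NULL, c("i_max", "bfi")))
  for (s in seq_along(shifts)) {
    eff <- central
    eff$digit$t0_shift <- shifts[s]
    gs <- generate_stack(prof, "C", "foot", seed = 100 + s, noise_level = 0,
                         subject_effects = eff)
    rp <- region_params(gs$stack, gs$regions$digit_mask,
                        pixel_dispersion = FALSE)
    got[s, ] <- c(rp$params$i_max, rp$params$bfi)
  }
  tgt <- prof$foot$C$digit$predicted
  expect_equal(mean(got[, "i_max"]), tgt$i_max, tolerance = 0.02)
  expect_equal(mean(got[, "bfi"]), tgt$bfi, tolerance = 0.05)
})
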