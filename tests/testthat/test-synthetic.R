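test_that("the model curve honors its anatomy", {
  t <- seq(0, 600, by = 0.5)
  # zero amplitude: constant at baseline
  p0 <- curve_model_params(b = 100, t0 = 60, A = 0, Tr = 40, tau = 120, rho = 0.3)
  expect_true(all(model_curve(p0, t)$intensities == 100))
  # net maximum A at t0 + Tr
  p <- curve_model_params(b = 100, t0 = 60, A = 1000, Tr = 40, tau = 120, rho = 0.3)
  cv <- model_curve(p, t)
  expect_equal(max(cv$intensities) - 100, 1000)
  expect_equal(t[which.max(cv$intensities)], 100)
  # continuity across the rise/washout junction
  eps <- model_curve(p, c(99.998, 99.999, 100, 100.001))$intensities
  expect_lt(max(abs(diff(eps))), 0.01)
  expect_error(model_curve(p, c(-1, 0, 5)), "support")
})

test_that("closed-form moments match the fine-grid oracle", {
  for (pars in list(c(100, 60, 1000, 40, 120, 0.4),
                    c(80, 25, 5000, 57, 190, 0.3),
                    c(120, 35, 3000, 268, 1500, 0.5))) {
    p <- curve_model_params(pars[1], pars[2], pars[3], pars[4], pars[5], pars[6])
    mom <- model_curve_moments(p, 595)
    orc <- oracle_moments(function(t) model_curve(p, t)$intensities,
                          baseline = pars[1], t_end = 595)
    expect_equal(mom$auc, orc$auc, tolerance = 1e-3)
    expect_equal(mom$mtt, orc$mtt, tolerance = 1e-3)
  }
})

test_that("stack generation is bit-reproducible and noiseless pixels equal the model", {
  prof <- group_profiles_cached()
  a <- generate_stack(prof, "D", "foot", seed = 33)
  b <- generate_stack(prof, "D", "foot", seed = 33)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  c_ <- generate_stack(prof, "D", "foot", seed = 34)
  expect_false(identical(a$stack$frames, c_$stack$frames))

  g0 <- generate_stack(prof, "C", "foot", seed = 5, noise_level = 0)
  px <- which(g0$regions$digit_mask, arr.ind = TRUE)[7, ]
  tp <- lapply(g0$truth$params, function(m) m[px[1], px[2]])
  ref <- model_values(g0$stack$times, tp$b, tp$t0, tp$A, tp$Tr, tp$tau, tp$rho)
  expect_equal(g0$stack$frames[px[1], px[2], ], ref, tolerance = 1e-12)
})

test_that("noise level zero is exact and recovery error grows with noise", {
  prof <- group_profiles_cached()
  p <- curve_model_params(b = 100, t0 = 30, A = 5000, Tr = 57, tau = 190, rho = 0.3)
  times <- protocol_times()
  truth <- extract_params(model_curve(p, times))$i_max
  rmse <- vapply(c(0.5, 2, 8), function(nl) {
    set.seed(77)
    errs <- vapply(1:60, function(k) {
      kp <- extract_params(simulate_curve(p, times, nl))
      if (kp$valid) kp$i_max - truth else NA_real_
    }, 0)
    sqrt(mean(errs^2, na.rm = TRUE))
  }, 0)
  expect_true(all(diff(rmse) > 0))
})

test_that("cohort manifests have the full subject x side x condition grid", {
  prof <- group_profiles_cached()
  co <- generate_cohort(prof, limb = "hand", conditions = c("rest", "post"),
                        seed = 3)
  expect_equal(nrow(co$manifest), (14 + 11 + 16) * 2 * 2)
  expect_equal(anyDuplicated(co$manifest$item_id), 0L)
  # determinism of the manifest and ground truth
  co2 <- generate_cohort(prof, limb = "hand", conditions = c("rest", "post"),
                         seed = 3)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$truth, co2$truth)
  # and of a materialized stack
  expect_identical(cohort_stack(co, 17)$stack$frames,
                   cohort_stack(co2, 17)$stack$frames)
})

test_that("post-condition digit BFI truth scales by the responder ratio", {
  prof <- group_profiles_cached()
  co <- generate_cohort(prof, limb = "hand", conditions = c("rest", "post"),
                        seed = 9)
  tr <- co$truth[co$truth$region == "digit", ]
  wide <- merge(tr[tr$condition == "rest", c("subject", "side", "bfi")],
                tr[tr$condition == "post", c("subject", "side", "bfi")],
                by = c("subject", "side"), suffixes = c("_pre", "_post"))
  sub <- co$subjects
  ratio <- wide$bfi_post / wide$bfi_pre
  r_subj <- sub$responder[match(wide$subject, sub$subject)]
  # limb jitter is lognormal with sd 0.05 around the subject ratio
  expect_true(all(abs(log(ratio / r_subj)) < 0.25))
  grp <- sub$group[match(wide$subject, sub$subject)]
  expect_gt(mean(ratio[grp == "C"]), mean(ratio[grp == "M"]))
  expect_equal(mean(ratio[grp == "M"]), 1, tolerance = 0.1)
})

test_that("motion injection is exact, reversible at zero, and bounded", {
  prof <- group_profiles_cached()
  gs <- generate_stack(prof, "C", "foot", seed = 2)
  st <- gs$stack
  zero <- matrix(0L, length(st$times), 2)
  expect_identical(inject_motion(st, zero)$frames, st$frames)
  big <- zero; big[5, ] <- c(999L, 0L)
  expect_error(inject_motion(st, big), "outside the frame")
  frac <- zero; frac[5, ] <- c(1L, 2L); frac[5, 1] <- 1L
  frac2 <- matrix(c(0.5, 0), 120, 2, byrow = TRUE)
  expect_error(inject_motion(st, frac2), "integer")
})

test_that("injected early drift is excluded, late drift is not", {
  prof <- group_profiles_cached()
  gs <- generate_stack(prof, "C", "foot", seed = 21)
  n <- length(gs$stack$times)
  # 25 px at 0.5 mm/px = 1.25 cm, from t = 90 s
  early <- matrix(0L, n, 2); early[gs$stack$times >= 90, 1] <- 25L
  mp <- estimate_displacement(inject_motion(gs$stack, early))
  expect_identical(movement_exclusion(mp)$decision, "exclude")
  # same drift applied only after t = 200 s passes the windowed rule
  late <- matrix(0L, n, 2); late[gs$stack$times >= 200, 1] <- 25L
  mp2 <- estimate_displacement(inject_motion(gs$stack, late))
  expect_identical(movement_exclusion(mp2)$decision, "pass")
})

test_that("washout calibration hits attainable AUC targets and clamps impossible ones", {
  # attainable: solved tau reproduces the requested net duration
  tau <- icgdyn:::calibrate_tau(305, t0 = 25, Tr = 45, rho = 0.3, t_end = 595)
  S <- 595 - 25 - 45
  dur <- 45 / 2 + 0.3 * S + 0.7 * tau * (1 - exp(-S / tau))
  expect_equal(dur, 305, tolerance = 1e-6)
  # impossible: requested duration exceeds Tr/2 + S -> clamp at the cap
  expect_equal(icgdyn:::calibrate_tau(1000, 25, 45, 0.99, 595), 3000)
})
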