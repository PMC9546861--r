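test_that("double referencing is the (meas - ref) - (blank difference) contract", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  set <- simulate_fps_trace(gt, 1e-6, noise_sd = 0)
  zero <- function(tr) { tr$signal <- 0 * tr$signal; tr }
  # all correction channels zero -> identity
  corr <- double_reference(set$measurement, zero(set$reference),
                           zero(set$blank_measurement), zero(set$blank_reference))
  expect_equal(corr$signal, set$measurement$signal)
  expect_identical(corr$phase, set$measurement$phase)
  # null experiment: meas = blank_meas, ref = blank_ref -> identically zero
  null <- double_reference(set$measurement, set$reference,
                           set$measurement, set$reference)
  expect_true(all(null$signal == 0))
})

test_that("double referencing removes common drift and is linear", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  drifted <- simulate_fps_trace(gt, 1e-6, noise_sd = 0, drift = 0.05)
  clean <- simulate_fps_trace(gt, 1e-6, noise_sd = 0, drift = 0)
  corr <- double_reference_set(drifted)
  expect_equal(corr$signal, clean$measurement$signal, tolerance = 1e-10)
  # additivity in the measurement channel
  m2 <- drifted$measurement
  m2$signal <- m2$signal + 3
  corr2 <- double_reference(m2, drifted$reference,
                            drifted$blank_measurement, drifted$blank_reference)
  expect_equal(corr2$signal, corr$signal + 3)
})

test_that("misaligned grids are rejected rather than interpolated", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  set <- simulate_fps_trace(gt, 1e-6)
  short <- simulate_fps_trace(gt, 1e-6, t_assoc = 150)
  expect_error(double_reference(set$measurement, short$reference,
                                set$blank_measurement, set$blank_reference),
               class = "multikin_alignment_error")
})

test_that("single-curve fit recovers a planted k_obs and flags flat traces", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  tr <- double_reference_set(simulate_fps_trace(gt, 1e-6, noise_sd = 0))
  fit <- fit_single_curve(tr)
  expect_equal(fit$k_obs, 0.101, tolerance = 1e-6)
  expect_equal(fit$k_off, 1e-3, tolerance = 1e-4)
  expect_identical(fit$flag, "ok")

  flat <- sensor_trace(time = 0:99, signal = rep(0, 100),
                       phase = rep("association", 100))
  ffit <- fit_single_curve(flat)
  expect_identical(ffit$flag, "not_determinable")
  expect_true(is.na(ffit$A) || abs(ffit$A) < 1e-6)

  tiny <- sensor_trace(time = 0:5, signal = rep(0, 6),
                       phase = rep("association", 6))
  expect_error(fit_single_curve(tiny), ">= 10")
})

test_that("single-curve fit is accurate under relative noise (Monte Carlo)", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  errs <- vapply(1:25, function(s) {
    tr <- double_reference_set(simulate_fps_trace(gt, 1e-6, noise_sd = 1,
                                                  seed = s))
    abs(fit_single_curve(tr)$k_obs - 0.101) / 0.101
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("global fit recovers planted rates exactly on noiseless curves", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  trs <- fps_curves(gt)
  fit <- fit_global(trs)
  expect_lt(abs(fit$k_on - 1e5) / 1e5, 1e-3)
  expect_lt(abs(fit$k_off - 1e-3) / 1e-3, 1e-3)
  expect_equal(fit$K_D, fit$k_off / fit$k_on)
  expect_identical(fit$flag, "ok")
  expect_identical(fit$n_curves, 3L)
  # duplicating a curve leaves the estimates unchanged
  fit2 <- fit_global(c(trs[1], trs[1], trs[2:3]))
  expect_equal(fit2$k_on, fit$k_on, tolerance = 1e-6)
  expect_equal(fit2$k_off, fit$k_off, tolerance = 1e-6)
})

test_that("global fit refuses a single concentration without dissociation", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  set <- simulate_fps_trace(gt, 1e-6, t_dissoc = 1, dt = 1)
  tr <- double_reference_set(set)
  assoc_only <- tr[tr$phase != "dissociation", ]
  tr2 <- sensor_trace(assoc_only$time, assoc_only$signal, assoc_only$phase,
                      analyte_conc = 1e-6)
  expect_error(fit_global(list(tr2)), "dissociation")
})

test_that("fitted k_obs regresses linearly on concentration (noiseless)", {
  gt <- ground_truth_kinetics(2e5, 5e-3)
  concs <- c(1e-7, 5e-7, 1e-6, 2e-6, 4e-6)
  kobs <- vapply(concs, function(C) {
    tr <- double_reference_set(simulate_fps_trace(gt, C, noise_sd = 0))
    fit_single_curve(tr)$k_obs
  }, numeric(1))
  fit <- lm(kobs ~ concs)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
  expect_equal(unname(coef(fit)[2]), 2e5, tolerance = 1e-3)
  expect_equal(unname(coef(fit)[1]), 5e-3, tolerance = 1e-2)
})

test_that("association level is the tail mean, ordered and concentration-monotone", {
  gt <- ground_truth_kinetics(1e5, 1e-3)
  # saturated curve: level within 1% of the fitted amplitude times the
  # plateau fraction reached
  tr <- double_reference_set(simulate_fps_trace(gt, 1e-5, amplitude = 100,
                                                t_assoc = 300))
  lvl <- association_level(tr)
  s_eq <- 100 * 1e-5 / (1e-5 + gt$K_D)
  expect_equal(lvl$level, s_eq, tolerance = 0.01)
  expect_equal(lvl$fitted_amplitude, s_eq, tolerance = 0.01)
  # constant trace: level equals the constant
  const <- sensor_trace(0:49, rep(7, 50), rep("association", 50))
  expect_equal(association_level(const)$level, 7)
  # amplitude ordering carries through
  lo <- simulate_fps_trace(gt, 1e-5, amplitude = 50)
  expect_lt(association_level(double_reference_set(lo))$level, lvl$level)
  # monotone in analyte concentration for fixed kinetics
  lvls <- vapply(c(1e-7, 1e-6, 1e-5), function(C) {
    association_level(double_reference_set(simulate_fps_trace(gt, C)))$level
  }, numeric(1))
  expect_true(all(diff(lvls) > 0))
  expect_error(association_level(sensor_trace(0:5, rep(1, 6),
                                              rep("association", 6))), ">= 10")
})

test_that("rate maps join fits to architectures and drop non-determinable fits", {
  lib <- generate_library(valencies = c(2, 8), epitope_lengths = c(5, 8),
                          linker_grid = c("J", "JOJ"))
  kin <- plant_library_kinetics(lib, seed = 3)
  fits <- lapply(seq_len(nrow(kin)), function(i) {
    structure(list(k_on = kin$k_on[i], k_off = kin$k_off[i],
                   K_D = kin$K_D[i], flag = "ok", id = kin$id[i]),
              class = "kinetic_fit")
  })
  fits[[1]]$flag <- "not_determinable"
  rm <- build_rate_map(fits, lib)
  expect_identical(nrow(rm), nrow(kin) - 1L)
  expect_identical(attr(rm, "iso_affinity_M"), c(1e-5, 1e-6, 1e-7))
  expect_equal(rm$K_D, rm$k_off / rm$k_on)
  # octamer centroid K_D below dimer centroid
  cent <- tapply(log(rm$K_D), rm$valency, mean)
  expect_lt(cent[["8"]], cent[["2"]])
  # duplicate ids rejected
  expect_error(build_rate_map(c(fits[2], fits[2]), lib), "duplicate")
})
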