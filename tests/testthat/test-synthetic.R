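test_that("zero modulation reproduces the base ellipse rasterization", {
  spec <- synth_plan_spec(n_control_points = 6, base_aperture = c(20, 15),
                          modulation_amplitude_mm = 0, seed = 1)
  p <- generate_plan(spec)
  expect_identical(validate_plan(p), character(0))
  geom <- p$beams[[1]]$geometry
  bnd <- geom$boundaries
  yc <- (bnd[-1] + bnd[-length(bnd)]) / 2
  expected_half <- ifelse(abs(yc) < 15, 20 * sqrt(pmax(0, 1 - (yc / 15)^2)), 0)
  for (cp in p$beams[[1]]$control_points) {
    expect_equal(cp$bank_B, expected_half, tolerance = 1e-12)
    expect_equal(cp$bank_A, -expected_half, tolerance = 1e-12)
  }
})

test_that("identical specs give byte-identical serialized plans", {
  spec <- synth_plan_spec(n_control_points = 8, modulation_amplitude_mm = 3,
                          seed = 123)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_plan_json(generate_plan(spec), f1)
  write_plan_json(generate_plan(spec), f2)
  expect_identical(readBin(f1, raw(), file.size(f1)),
                   readBin(f2, raw(), file.size(f2)))
  # a different seed changes the plan
  spec2 <- synth_plan_spec(n_control_points = 8, modulation_amplitude_mm = 3,
                           seed = 124)
  f3 <- withr::local_tempfile(fileext = ".json")
  write_plan_json(generate_plan(spec2), f3)
  expect_false(identical(readBin(f1, raw(), file.size(f1)),
                         readBin(f3, raw(), file.size(f3))))
})

test_that("generated plans always validate across the modulation range", {
  for (sm in c(0, 1, 4, 8, 15)) {
    p <- generate_plan(synth_plan_spec(n_control_points = 6,
                                       modulation_amplitude_mm = sm,
                                       seed = 400 + sm))
    expect_identical(validate_plan(p), character(0))
  }
  expect_error(generate_plan(synth_plan_spec(base_aperture = c(199, 20))),
               "travel range")
})

test_that("noise-free logs record the plan exactly", {
  p <- generate_plan(synth_plan_spec(n_control_points = 6,
                                     modulation_amplitude_mm = 2, seed = 2))
  log <- simulate_log(p, synth_log_spec(seed = 5))
  s <- mechanical_errors(p, log)
  expect_equal(c(s$mlc_error_mm, s$gantry_error_deg, s$mu_error), c(0, 0, 0))
})

test_that("Gaussian leaf noise is recovered as the folded-normal mean", {
  # >= 1e4 leaf-control-point samples: 60 pairs x 2 banks x 90 CPs = 10800
  p <- generate_plan(synth_plan_spec(n_control_points = 90,
                                     modulation_amplitude_mm = 0, seed = 3))
  log <- simulate_log(p, synth_log_spec(sigma_mlc_mm = 0.1, seed = 11))
  s <- mechanical_errors(p, log)
  expect_equal(s$mlc_error_mm, 0.1 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("coupled MLC noise tracks per-plan mean leaf speed", {
  errs <- c(); speeds <- c()
  for (i in 1:10) {
    sm <- c(0.5, 1, 2, 4, 8)[((i - 1) %% 5) + 1]
    p <- generate_plan(synth_plan_spec(n_control_points = 12,
                                       modulation_amplitude_mm = sm,
                                       seed = 500 + i))
    log <- simulate_log(p, synth_log_spec(sigma_mlc_mm = 0.05,
                                          mlc_error_coupling = TRUE,
                                          seed = 600 + i))
    beam <- p$beams[[1]]
    np <- beam$geometry$n_pairs
    A <- t(vapply(beam$control_points, function(cp) cp$bank_A, numeric(np)))
    B <- t(vapply(beam$control_points, function(cp) cp$bank_B, numeric(np)))
    speeds <- c(speeds, mean(abs(diff(A))) + mean(abs(diff(B))))
    errs <- c(errs, mechanical_errors(p, log)$mlc_error_mm)
  }
  expect_gt(spearman_cor(speeds, errs)$r, 0)
})

test_that("clean dose planes pass gamma fully; shifts on gradients fail it", {
  p <- generate_plan(synth_plan_spec(n_control_points = 8,
                                     base_aperture = c(15, 12),
                                     modulation_amplitude_mm = 4, seed = 8))
  fmap <- crop_fluence(integrate_fluence(p))
  clean <- simulate_dose_planes(fmap, blur_sigma_mm = 2, noise_percent = 0,
                                shift_mm = 0, seed = 1)
  for (crit in list(gamma_criteria(2, 2), gamma_criteria(1, 1))) {
    expect_equal(gamma_analysis(clean$reference, clean$measured,
                                crit)$passing_rate, 100)
  }
  shifted <- simulate_dose_planes(fmap, blur_sigma_mm = 2, noise_percent = 0,
                                  shift_mm = 3, seed = 1)
  expect_lt(gamma_analysis(shifted$reference, shifted$measured,
                           gamma_criteria(2, 2))$passing_rate, 100)
  expect_error(simulate_dose_planes(fmap, blur_sigma_mm = -1), "blur")
})

test_that("more measurement noise never helps the expected passing rate", {
  p <- generate_plan(synth_plan_spec(n_control_points = 8,
                                     base_aperture = c(12, 10),
                                     modulation_amplitude_mm = 2, seed = 9))
  fmap <- crop_fluence(integrate_fluence(p))
  rates <- sapply(c(0.5, 3, 8), function(np) {
    mean(sapply(1:3, function(s) {
      pl <- simulate_dose_planes(fmap, blur_sigma_mm = 2, noise_percent = np,
                                 shift_mm = 0, seed = s)  # paired seeds
      gamma_analysis(pl$reference, pl$measured,
                     gamma_criteria(2, 2))$passing_rate
    }))
  })
  expect_true(all(diff(rates) <= 0))
})

test_that("run_study is seed-deterministic and structurally complete", {
  st1 <- run_study(n_plans = 10, sigma_grid = c(0, 4), seed = 5,
                   n_control_points = 10,
                   gamma_criteria_list = list(gamma_criteria(2, 2)))
  st2 <- run_study(n_plans = 10, sigma_grid = c(0, 4), seed = 5,
                   n_control_points = 10,
                   gamma_criteria_list = list(gamma_criteria(2, 2)))
  expect_identical(st1$features, st2$features)
  expect_identical(st1$measures, st2$measures)
  expect_identical(st1$panel$r, st2$panel$r)
  expect_equal(nrow(st1$features), 10L * 18L)
  expect_setequal(unique(st1$measures$measure),
                  c("gamma_2_2", "mlc_error_mm", "gantry_error_deg",
                    "mu_error"))
  expect_equal(nrow(st1$panel), 18L * 4L)
})

test_that("sinusoidal meterset weighting stays valid and shifts fluence", {
  spec_u <- synth_plan_spec(n_control_points = 12, base_aperture = c(15, 12),
                            modulation_amplitude_mm = 3, seed = 77)
  spec_s <- synth_plan_spec(n_control_points = 12, base_aperture = c(15, 12),
                            modulation_amplitude_mm = 3,
                            mu_pattern = "sinusoidal", seed = 77)
  pu <- generate_plan(spec_u)
  ps <- generate_plan(spec_s)
  expect_identical(validate_plan(ps), character(0))
  wu <- sapply(pu$beams[[1]]$control_points,
               function(cp) cp$cumulative_meterset_weight)
  ws <- sapply(ps$beams[[1]]$control_points,
               function(cp) cp$cumulative_meterset_weight)
  expect_equal(range(ws), c(0, 1))
  expect_false(isTRUE(all.equal(wu, ws)))
  # same apertures, different meterset shares: the fluence must differ
  fu <- integrate_fluence(pu)
  fs <- integrate_fluence(ps, grid = fu$grid)
  expect_gt(max(abs(fu$values - fs$values)), 0)
  # but the total delivered meterset-weighted area is conserved per plan
  expect_equal(sum(fu$values > 0), sum(fs$values > 0))
})
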