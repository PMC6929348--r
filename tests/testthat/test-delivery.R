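flat_plane <- function(value, n = 20) dose_plane(matrix(value, n, n),
                                                 y_origin = n - 1)

test_that("identical planes give gamma 0 everywhere and 100% passing", {
  set.seed(44)
  ref <- dose_plane(matrix(runif(400, 0.5, 2), 20, 20), y_origin = 19)
  res <- gamma_analysis(ref, ref, gamma_criteria(2, 2))
  expect_equal(res$passing_rate, 100)
  expect_equal(max(res$gamma_map, na.rm = TRUE), 0)
  expect_equal(res$n_evaluated, 400L)
})

test_that("a uniform +2% offset on a flat field hits the closed form", {
  ref <- flat_plane(1)
  meas <- flat_plane(1.02)
  r22 <- gamma_analysis(ref, meas, gamma_criteria(2, 2))
  expect_equal(r22$passing_rate, 100)
  expect_equal(unique(round(as.vector(r22$gamma_map), 10)), 1)
  r12 <- gamma_analysis(ref, meas, gamma_criteria(1, 2))
  expect_equal(r12$passing_rate, 0)
  expect_equal(unique(round(as.vector(r12$gamma_map), 10)), 2)
})

test_that("points below the 10% low-dose cutoff are excluded", {
  vals <- matrix(1, 10, 10)
  vals[1:3, ] <- 0.05  # 5% of max: below the default 10% cutoff
  ref <- dose_plane(matrix(1, 10, 10), y_origin = 9)
  meas <- dose_plane(vals, y_origin = 9)
  res <- gamma_analysis(ref, meas, gamma_criteria(2, 2))
  expect_equal(res$n_evaluated, 70L)
  expect_true(all(is.nan(res$gamma_map[1:3, ])))
})

test_that("global gamma is invariant to a common dose scale", {
  set.seed(8)
  base <- matrix(runif(225, 0.2, 1), 15, 15)
  ref <- dose_plane(base, y_origin = 14)
  meas <- dose_plane(base * (1 + 0.015 * sin(seq_len(225))), y_origin = 14)
  r1 <- gamma_analysis(ref, meas, gamma_criteria(2, 2))
  r2 <- gamma_analysis(dose_plane(5 * ref$values, y_origin = 14),
                       dose_plane(5 * meas$values, y_origin = 14),
                       gamma_criteria(2, 2))
  expect_equal(r1$gamma_map, r2$gamma_map, tolerance = 1e-12)
  expect_equal(r1$passing_rate, r2$passing_rate)
})

test_that("loosening either gamma criterion never lowers the passing rate", {
  set.seed(13)
  p <- generate_plan(synth_plan_spec(n_control_points = 10,
                                     base_aperture = c(15, 12),
                                     modulation_amplitude_mm = 4, seed = 60))
  fmap <- crop_fluence(integrate_fluence(p))
  pl <- simulate_dose_planes(fmap, blur_sigma_mm = 2, noise_percent = 2,
                             shift_mm = 1, seed = 3)
  pr <- function(dp, mm) {
    gamma_analysis(pl$reference, pl$measured, gamma_criteria(dp, mm))$passing_rate
  }
  p22 <- pr(2, 2); p21 <- pr(2, 1); p12 <- pr(1, 2); p11 <- pr(1, 1)
  expect_gte(p22, p12); expect_gte(p12, p11)
  expect_gte(p22, p21); expect_gte(p21, p11)
})

test_that("gamma matches the exhaustive interpolation oracle", {
  set.seed(21)
  p <- generate_plan(synth_plan_spec(n_control_points = 8,
                                     base_aperture = c(12, 10),
                                     modulation_amplitude_mm = 3, seed = 77))
  fmap <- crop_fluence(integrate_fluence(p))
  pl <- simulate_dose_planes(fmap, blur_sigma_mm = 2, noise_percent = 1.5,
                             shift_mm = 0.7, seed = 5)
  crit <- gamma_criteria(2, 2)
  mine <- gamma_analysis(pl$reference, pl$measured, crit)
  oracle <- bf_gamma(pl$reference, pl$measured, crit)
  expect_equal(mine$n_evaluated, oracle$n_evaluated)
  expect_lt(max(abs(mine$gamma_map - oracle$gamma_map), na.rm = TRUE), 1e-3)
  expect_equal(mine$passing_rate, oracle$passing_rate, tolerance = 0.01)
})

test_that("degenerate gamma inputs are rejected", {
  ref <- flat_plane(1)
  far <- dose_plane(matrix(1, 5, 5), x_origin = 1000, y_origin = 1000)
  expect_error(gamma_analysis(ref, far, gamma_criteria(2, 2)), "disjoint")
  expect_error(gamma_analysis(flat_plane(0), ref, gamma_criteria(2, 2)),
               "zero")
})

test_that("mechanical errors recover identity, offsets and the circle", {
  p <- make_simple_plan(n_cp = 4)
  rec <- record_from_plan(p)
  s <- mechanical_errors(p, rec)
  expect_equal(c(s$mlc_error_mm, s$gantry_error_deg, s$mu_error), c(0, 0, 0))

  s1 <- mechanical_errors(p, record_from_plan(p, mlc_offset = 0.1))
  expect_equal(s1$mlc_error_mm, 0.1)
  s2 <- mechanical_errors(p, record_from_plan(p, mlc_offset = -0.1))
  expect_equal(s2$mlc_error_mm, 0.1)  # symmetric in sign
  s3 <- mechanical_errors(p, record_from_plan(p, mlc_offset = 0.3))
  expect_equal(s3$mlc_error_mm, 3 * s1$mlc_error_mm)  # linear in magnitude

  # gantry differences wrap on the circle
  rec_wrap <- record_from_plan(p)
  rec_wrap$beams[[1]]$snapshots[[1]]$gantry_angle <-
    (p$beams[[1]]$control_points[[1]]$gantry_angle + 359.8) %% 360
  sw <- mechanical_errors(p, rec_wrap)
  expect_equal(sw$gantry_error_deg, 0.2 / 4, tolerance = 1e-9)
})

test_that("mismatched geometries are rejected", {
  p <- make_simple_plan()
  rec <- record_from_plan(p)
  rec$geometry <- leaf_geometry(c(-5, 0, 5), "other")
  expect_error(mechanical_errors(p, rec), "mismatch")
})

test_that("summaries average component-wise and order-invariantly", {
  s <- function(a, b, c) structure(list(mlc_error_mm = a,
                                        gantry_error_deg = b, mu_error = c),
                                   class = "mechanical_error_summary")
  one <- s(0.1, 0.2, 0.3)
  expect_equal(average_summaries(list(one)), one)
  m <- average_summaries(list(s(0.1, 0, 0), s(0.3, 0, 0)))
  expect_equal(m$mlc_error_mm, 0.2)
  ab <- average_summaries(list(s(1, 2, 3), s(5, 6, 7)))
  ba <- average_summaries(list(s(5, 6, 7), s(1, 2, 3)))
  expect_equal(ab, ba)
  expect_error(average_summaries(list()), "empty")
})

test_that("resampling a fine log onto control points recovers the plan", {
  p <- make_simple_plan(n_cp = 5)
  # a fine record: 3x oversampled in cumulative MU, linear in everything
  beam <- p$beams[[1]]
  mu_fine <- seq(0, beam$total_mu, length.out = 13)
  np <- beam$geometry$n_pairs
  snaps <- lapply(seq_along(mu_fine), function(k) {
    t <- mu_fine[k] / beam$total_mu
    list(index = k - 1, cumulative_mu = mu_fine[k],
         gantry_angle = (180 + 10 + t * 40) %% 360,
         bank_A = rep(-10, np), bank_B = rep(10, np))
  })
  rec <- delivery_record(p$plan_id, beam$geometry, list(list(snapshots = snaps)))
  rs <- resample_record(rec, p)
  expect_length(rs$beams[[1]]$snapshots, 5L)
  s <- mechanical_errors(p, rs)
  expect_equal(s$mlc_error_mm, 0)
  expect_equal(s$mu_error, 0, tolerance = 1e-9)
})

test_that("spearman handles perfect, worked and degenerate cases", {
  x <- 1:8
  expect_equal(spearman_cor(x, x + 3)$r, 1)
  expect_equal(spearman_cor(x, rev(x))$r, -1)
  s <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$r, 0.8)  # 1 - 6*4 / (5*24)
  expect_error(spearman_cor(rep(1, 5), 1:5), "undefined correlation")
  # invariant to monotone transforms
  set.seed(2)
  a <- runif(12); b <- runif(12)
  expect_equal(spearman_cor(a, b)$r, spearman_cor(exp(a), b^3)$r)
  expect_equal(spearman_cor(a, b)$p, spearman_cor(exp(a), b^3)$p)
})

test_that("small-sample p-values equal the exact permutation enumeration", {
  set.seed(6)
  for (n in c(4, 5, 6)) {
    for (rep in 1:3) {
      x <- sample(100, n); y <- sample(100, n)
      s <- spearman_cor(x, y)
      expect_equal(s$r, bf_spearman_r(x, y), tolerance = 1e-12)
      expect_equal(s$p, bf_spearman_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("large-sample p-values match the t approximation of cor.test", {
  set.seed(10)
  x <- rnorm(25); y <- x + rnorm(25)
  s <- spearman_cor(x, y)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(s$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(s$p, ct$p.value, tolerance = 1e-10)
})

test_that("the correlation panel joins, flags and counts correctly", {
  set.seed(20)
  plans <- sprintf("p%02d", 1:15)
  features <- do.call(rbind, lapply(plans, function(id) {
    data.frame(plan_id = id, feature = rep(c("ASM", "entropy"), each = 3),
               d = rep(c(1, 5, 10), 2), value = runif(6))
  }))
  # one measure duplicates the ASM d=10 column exactly
  asm10 <- features$value[features$feature == "ASM" & features$d == 10]
  measures <- rbind(
    data.frame(plan_id = plans, measure = "copy_of_asm10", value = asm10),
    data.frame(plan_id = plans, measure = "noise", value = runif(15)))
  panel <- correlation_panel(features, measures)
  expect_equal(nrow(panel), 6L * 2L)
  hit <- panel[panel$feature == "ASM" & panel$d == 10 &
               panel$measure == "copy_of_asm10", ]
  expect_equal(hit$r, 1)
  expect_true(hit$significant)
  counts <- significance_counts(panel)
  expect_gte(counts$n_significant[counts$feature == "ASM" & counts$d == 10], 1)
  expect_error(correlation_panel(features[features$plan_id %in% plans[1:2], ],
                                 measures), "at least 3")
})
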