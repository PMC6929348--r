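# Synthetic arc plans with a controllable modulation degree, delivery logs
# with controllable mechanical noise, and dose-plane pairs, so the whole
# feature -> delivery-accuracy correlation study runs without clinical data.

#' Specification of a synthetic arc plan
#'
#' The generator traces an elliptical base aperture with every leaf pair
#' whose row intersects it and adds a smooth random leaf-tip perturbation
#' of standard deviation `modulation_amplitude_mm` (the modulation knob: 0
#' gives a static conformal arc, larger values mimic increasingly
#' modulated plans whose fluence maps lose homogeneity).  The perturbation
#' field is Gaussian noise smoothed by a moving average of half-width
#' `modulation_correlation` along both the control-point and leaf axes, so
#' low-frequency modulation resembles clinically smooth MLC trajectories.
#'
#' @param n_control_points Number of control points (>= 2, default 48).
#' @param geometry A [leaf_geometry()] (default HD 120).
#' @param base_aperture Numeric `c(semi_x, semi_y)` ellipse semi-axes in mm
#'   (default 30 x 25).
#' @param modulation_amplitude_mm Leaf-tip perturbation SD sigma_m in mm.
#' @param modulation_correlation Moving-average half-width (control points
#'   / leaf pairs) of the perturbation smoothing, default 2.
#' @param total_mu Total beam monitor units (default 400).
#' @param mu_pattern `"uniform"` meterset increments (default) or
#'   `"sinusoidal"`, which modulates the per-interval meterset by one full
#'   sine period over the arc (exercising the MU-weighting code paths).
#' @param seed RNG seed; identical specs give identical plans.
#' @return A list of class `synth_plan_spec`.
#' @export
synth_plan_spec <- function(n_control_points = 48L,
                            geometry = varian_mlc_geometry("hd120"),
                            base_aperture = c(30, 25),
                            modulation_amplitude_mm = 0,
                            modulation_correlation = 2L,
                            total_mu = 400,
                            mu_pattern = c("uniform", "sinusoidal"),
                            seed = 1L) {
  if (!is_count(n_control_points, min = 2)) {
    stop("n_control_points must be an integer >= 2")
  }
  if (modulation_amplitude_mm < 0) stop("modulation_amplitude_mm must be >= 0")
  if (any(base_aperture <= 0)) stop("base_aperture semi-axes must be > 0")
  structure(
    list(n_control_points = as.integer(n_control_points), geometry = geometry,
         base_aperture = as.numeric(base_aperture),
         modulation_amplitude_mm = modulation_amplitude_mm,
         modulation_correlation = as.integer(modulation_correlation),
         total_mu = total_mu, mu_pattern = match.arg(mu_pattern),
         seed = as.integer(seed)),
    class = "synth_plan_spec"
  )
}

#' Delivery-log noise specification
#'
#' @param sigma_mlc_mm SD of Gaussian noise added to every recorded leaf
#'   position (mm).
#' @param sigma_gantry_deg SD of gantry-angle noise (degrees).
#' @param sigma_mu SD of cumulative-MU noise (MU).
#' @param mlc_error_coupling If `TRUE`, MLC noise at each control point is
#'   scaled by the mean leaf travel (mm) since the previous control point,
#'   so `sigma_mlc_mm` becomes the noise SD per mm of leaf travel and
#'   faster-moving deliveries record larger errors.
#' @param seed RNG seed.
#' @return A list of class `synth_log_spec`.
#' @export
synth_log_spec <- function(sigma_mlc_mm = 0, sigma_gantry_deg = 0,
                           sigma_mu = 0, mlc_error_coupling = FALSE,
                           seed = 1L) {
  if (sigma_mlc_mm < 0 || sigma_gantry_deg < 0 || sigma_mu < 0) {
    stop("noise scales must be >= 0")
  }
  structure(
    list(sigma_mlc_mm = sigma_mlc_mm, sigma_gantry_deg = sigma_gantry_deg,
         sigma_mu = sigma_mu, mlc_error_coupling = isTRUE(mlc_error_coupling),
         seed = as.integer(seed)),
    class = "synth_log_spec"
  )
}

# moving-average smoothing of a matrix along both dimensions with edge
# replication; half-width h (window 2h+1)
smooth_matrix <- function(m, h) {
  if (h < 1L) return(m)
  k <- rep(1 / (2 * h + 1), 2 * h + 1)
  pad_filter <- function(v) {
    vp <- c(rep(v[1], h), v, rep(v[length(v)], h))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(h + 1):(h + length(v))])
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

#' Generate a synthetic arc plan
#'
#' See [synth_plan_spec()] for the generative model.  Cumulative meterset
#' weights are uniform across control points; the gantry sweeps one full
#' arc (181 deg through 0 to 179 deg).  Closed leaf pairs (rows outside
#' the base ellipse) stay parked.  Perturbed pairs that would cross are
#' collapsed to their midpoint, keeping gaps nonnegative, and tips are
#' clipped to the +/-200 mm travel range.
#'
#' @param spec A [synth_plan_spec()].
#' @return An [rt_plan()] that passes [validate_plan()].
#' @export
generate_plan <- function(spec) {
  stopifnot(inherits(spec, "synth_plan_spec"))
  geom <- spec$geometry
  ax <- spec$base_aperture[1]; ay <- spec$base_aperture[2]
  if (ax > 195) stop("base aperture exceeds the +/-200 mm leaf travel range")
  n_cp <- spec$n_control_points
  np <- geom$n_pairs
  yc <- (geom$boundaries[-1] + geom$boundaries[-(np + 1)]) / 2
  half_w <- ifelse(abs(yc) < ay, ax * sqrt(pmax(0, 1 - (yc / ay)^2)), 0)
  open <- half_w > 0

  A <- matrix(rep(-half_w, each = n_cp), n_cp, np)
  B <- -A
  if (spec$modulation_amplitude_mm > 0 && any(open)) {
    with_seed(spec$seed, {
      for (bank in 1:2) {
        noise <- matrix(stats::rnorm(n_cp * np), n_cp, np)
        noise <- smooth_matrix(noise, spec$modulation_correlation)
        sd_now <- stats::sd(as.vector(noise[, open, drop = FALSE]))
        if (sd_now > 0) {
          noise <- noise * spec$modulation_amplitude_mm / sd_now
        }
        noise[, !open] <- 0
        if (bank == 1L) A <- A + noise else B <- B + noise
      }
    })
    crossed <- A > B
    mid <- (A + B) / 2
    A[crossed] <- mid[crossed]; B[crossed] <- mid[crossed]
    A <- pmax(pmin(A, 200), -200); B <- pmax(pmin(B, 200), -200)
  }

  jaw_x <- min(max(ax + 3 * spec$modulation_amplitude_mm + 10, ax + 10), 200)
  jaw_y <- min(ay + 10, 200)
  jaws <- c(-jaw_x, jaw_x, -jaw_y, jaw_y)
  if (identical(spec$mu_pattern, "sinusoidal")) {
    inc <- 1 + 0.5 * sin(2 * pi * seq_len(n_cp - 1) / (n_cp - 1))
    w <- c(0, cumsum(inc) / sum(inc))
  } else {
    w <- seq(0, 1, length.out = n_cp)
  }
  gantry <- (181 + (0:(n_cp - 1)) * 358 / (n_cp - 1)) %% 360
  cps <- lapply(seq_len(n_cp), function(k) {
    control_point(index = k - 1L, cumulative_meterset_weight = w[k],
                  gantry_angle = gantry[k], bank_A = A[k, ], bank_B = B[k, ],
                  jaws = jaws)
  })
  plan <- rt_plan(sprintf("synth-s%g-seed%d", spec$modulation_amplitude_mm,
                          spec$seed),
                  list(rt_beam(cps, total_mu = spec$total_mu,
                               geometry = geom)))
  stop_if_invalid(plan)
  plan
}

#' Simulate a machine delivery log for a plan
#'
#' Recorded values are the planned values plus independent Gaussian noise
#' per field.  With `mlc_error_coupling`, leaf noise at each control point
#' is scaled by that control point's mean leaf travel relative to the beam
#' average, emulating speed-dependent MLC tracking errors.
#'
#' @param plan An [rt_plan()].
#' @param spec A [synth_log_spec()].
#' @return A [delivery_record()] with one snapshot per control point.
#' @export
simulate_log <- function(plan, spec) {
  stopifnot(inherits(spec, "synth_log_spec"))
  stop_if_invalid(plan)
  geom <- plan$beams[[1]]$geometry
  with_seed(spec$seed, {
    beams <- lapply(plan$beams, function(beam) {
      np <- beam$geometry$n_pairs
      n_cp <- length(beam$control_points)
      A <- t(vapply(beam$control_points, function(cp) cp$bank_A, numeric(np)))
      B <- t(vapply(beam$control_points, function(cp) cp$bank_B, numeric(np)))
      scale_cp <- rep(1, n_cp)
      if (spec$mlc_error_coupling && n_cp > 1L) {
        # noise SD per control point proportional to the mean leaf travel
        # (mm) since the previous control point: sigma_mlc_mm is then the
        # SD per mm of travel, and faster-moving plans record larger errors
        scale_cp <- rowMeans(abs(rbind(0, diff(A))) +
                             abs(rbind(0, diff(B)))) / 2
      }
      An <- A + stats::rnorm(length(A), 0, spec$sigma_mlc_mm) * scale_cp
      Bn <- B + stats::rnorm(length(B), 0, spec$sigma_mlc_mm) * scale_cp
      g <- vapply(beam$control_points, function(cp) cp$gantry_angle,
                  numeric(1)) +
           stats::rnorm(n_cp, 0, spec$sigma_gantry_deg)
      mu <- vapply(beam$control_points,
                   function(cp) cp$cumulative_meterset_weight, numeric(1)) *
            beam$total_mu +
            stats::rnorm(n_cp, 0, spec$sigma_mu)
      mu <- cummax(mu)  # delivered MU counter is physically nondecreasing
      list(snapshots = lapply(seq_len(n_cp), function(k) {
        list(index = k - 1L, cumulative_mu = mu[k],
             gantry_angle = g[k] %% 360,
             bank_A = An[k, ], bank_B = Bn[k, ])
      }))
    })
    delivery_record(plan$plan_id, geom, beams)
  })
}

# separable Gaussian blur with edge replication; sigma in pixels
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-h, h), sd = sigma_px)
  k <- k / sum(k)
  pad_filter <- function(v) {
    vp <- c(rep(v[1], h), v, rep(v[length(v)], h))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(h + 1):(h + length(v))])
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

#' Simulate a reference/measured dose-plane pair from a fluence map
#'
#' Stands in for a planar QA measurement: the reference is the fluence map
#' blurred by a Gaussian of `blur_sigma_mm` and scaled at 1 MU-pixel = 1
#' cGy; the measured plane is the reference sampled with a rigid in-plane
#' shift of `shift_mm` (along x) and multiplied by Gaussian noise of SD
#' `noise_percent` percent.  Gamma under global normalization is invariant
#' to the absolute dose scale.
#'
#' @param fmap A nonzero `fluence_map`.
#' @param blur_sigma_mm Gaussian blur SD in mm (>= 0).
#' @param noise_percent Multiplicative noise SD in percent (>= 0).
#' @param shift_mm Rigid x-shift of the measured plane in mm.
#' @param seed RNG seed for the noise.
#' @return List with elements `reference` and `measured`, both
#'   [dose_plane()]s on the fluence grid.
#' @export
simulate_dose_planes <- function(fmap, blur_sigma_mm = 2, noise_percent = 0,
                                 shift_mm = 0, seed = 1L) {
  if (blur_sigma_mm < 0) stop("blur_sigma_mm must be >= 0")
  if (noise_percent < 0) stop("noise_percent must be >= 0")
  if (max(fmap$values) <= 0) stop("fluence map is zero everywhere")
  g <- fmap$grid
  ref_vals <- gaussian_blur(fmap$values, blur_sigma_mm / g$spacing_mm) / 100
  reference <- dose_plane(ref_vals, grid = g)
  xs <- grid_x_centers(g); ys <- grid_y_centers(g)
  X <- matrix(xs, g$ny, g$nx, byrow = TRUE)
  Y <- matrix(ys, g$ny, g$nx)
  shifted <- interp_plane(g, ref_vals, as.vector(X) - shift_mm, as.vector(Y))
  shifted[is.na(shifted)] <- 0
  meas <- matrix(shifted, g$ny, g$nx)
  if (noise_percent > 0) {
    meas <- with_seed(seed, {
      meas * (1 + stats::rnorm(length(meas), 0, noise_percent / 100))
    })
    meas <- pmax(meas, 0)
  }
  list(reference = reference, measured = dose_plane(meas, grid = g))
}

#' Run the full synthetic correlation study
#'
#' Generates `n_plans` arc plans whose modulation amplitudes cycle through
#' `sigma_grid`, simulates one delivery log and one reference/measured
#' dose-plane pair per plan, computes the 18-value texture panel, the four
#' global gamma passing rates, and the mechanical errors, then correlates
#' every feature against every measure with Spearman statistics.
#'
#' Under `log_rule = "coupled"` the MLC log-noise SD grows linearly with
#' the plan's modulation amplitude
#' (`sigma_mlc = 0.02 + 0.03 * sigma_m` mm, spanning the few-hundredths to
#' few-tenths of a mm range reported for clinical Varian deliveries), and
#' measurement noise grows with it too, emulating the empirical link
#' between modulation and delivery error; `"independent"` holds all log
#' noise fixed so every feature-vs-error correlation is null.
#'
#' @param n_plans Number of plans (>= 10, default 40).
#' @param sigma_grid Modulation amplitudes in mm cycled over plans
#'   (default `c(0, 1, 2, 4, 8)`).
#' @param log_rule `"coupled"` or `"independent"`.
#' @param seed Master seed; everything downstream derives from it.
#' @param n_control_points,geometry,total_mu Plan-generator settings.
#' @param gamma_criteria_list List of [gamma_criteria()] evaluated per plan
#'   (default 2%/2mm, 2%/1mm, 1%/2mm, 1%/1mm).
#' @param cfg [texture_config()] for the feature panel.
#' @return A list of class `texqa_study`: `features`, `measures` (long
#'   `data.frame`s), `panel` (a [correlation_panel()]) and `meta`.
#' @export
run_study <- function(n_plans = 40L,
                      sigma_grid = c(0, 1, 2, 4, 8),
                      log_rule = c("coupled", "independent"),
                      seed = 1L,
                      n_control_points = 48L,
                      geometry = varian_mlc_geometry("hd120"),
                      total_mu = 400,
                      gamma_criteria_list = list(
                        gamma_criteria(2, 2), gamma_criteria(2, 1),
                        gamma_criteria(1, 2), gamma_criteria(1, 1)),
                      cfg = texture_config()) {
  log_rule <- match.arg(log_rule)
  if (!is_count(n_plans, min = 10)) stop("n_plans must be an integer >= 10")
  feats <- list(); meas <- list()
  for (i in seq_len(n_plans)) {
    sm <- sigma_grid[((i - 1L) %% length(sigma_grid)) + 1L]
    pseed <- as.integer(seed) * 1000L + i
    # mild size variety so plans at equal modulation are not clones
    ax <- 24 + 4 * ((i - 1L) %% 4L)
    ay <- 20 + 3 * ((i - 1L) %% 3L)
    plan <- generate_plan(synth_plan_spec(
      n_control_points = n_control_points, geometry = geometry,
      base_aperture = c(ax, ay), modulation_amplitude_mm = sm,
      total_mu = total_mu, seed = pseed))

    fmap <- crop_fluence(integrate_fluence(plan),
                         margin_mm = cfg$crop_margin_mm)
    gmap <- quantize(fmap, n_levels = cfg$n_levels)
    feats[[i]] <- panel_from_graymap(gmap, cfg, plan$plan_id)

    if (log_rule == "coupled") {
      lspec <- synth_log_spec(sigma_mlc_mm = 0.02 + 0.03 * sm,
                              sigma_gantry_deg = 0.05, sigma_mu = 0.1,
                              seed = pseed + 1L)
      noise_pct <- 0.5 + 0.2 * sm
    } else {
      lspec <- synth_log_spec(sigma_mlc_mm = 0.1, sigma_gantry_deg = 0.05,
                              sigma_mu = 0.1, seed = pseed + 1L)
      noise_pct <- 1
    }
    log <- simulate_log(plan, lspec)
    merr <- mechanical_errors(plan, log)

    planes <- simulate_dose_planes(fmap, blur_sigma_mm = 2,
                                   noise_percent = noise_pct,
                                   shift_mm = 0.3, seed = pseed + 2L)
    gpr <- vapply(gamma_criteria_list, function(cr) {
      gamma_analysis(planes$reference, planes$measured, cr)$passing_rate
    }, numeric(1))
    gnames <- vapply(gamma_criteria_list, function(cr) {
      sprintf("gamma_%g_%g", cr$dose_percent, cr$dta_mm)
    }, character(1))
    meas[[i]] <- data.frame(
      plan_id = plan$plan_id,
      measure = c(gnames, "mlc_error_mm", "gantry_error_deg", "mu_error"),
      value = c(gpr, merr$mlc_error_mm, merr$gantry_error_deg, merr$mu_error))
  }
  features <- do.call(rbind, feats)
  measures <- do.call(rbind, meas)
  panel <- correlation_panel(features, measures)
  structure(list(features = features, measures = measures, panel = panel,
                 meta = list(n_plans = n_plans, sigma_grid = sigma_grid,
                             log_rule = log_rule, seed = seed,
                             n_control_points = n_control_points)),
            class = "texqa_study")
}

#' @export
print.texqa_study <- function(x, ...) {
  cat(sprintf("<texqa_study> %d plans, sigma_m in {%s} mm, log noise %s\n",
              x$meta$n_plans, paste(x$meta$sigma_grid, collapse = ", "),
              x$meta$log_rule))
  sig <- significance_counts(x$panel)
  cat(sprintf("  %d/%d panel cells significant at alpha = %g\n",
              sum(x$panel$significant, na.rm = TRUE), nrow(x$panel),
              attr(x$panel, "alpha")))
  invisible(x)
}
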