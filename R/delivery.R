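# Delivery-accuracy measures: global 2D gamma analysis of absolute dose
# planes, plan-vs-log mechanical errors, and the Spearman correlation panel
# linking texture features to them.

#' 2D absolute-dose plane
#'
#' @param values Matrix of absolute doses in Gy (finite, >= 0); row 1 is
#'   the top (largest y) row, as for fluence maps.
#' @param grid A [fluence_grid()], or `NULL` to build one from
#'   `spacing_mm`, `x_origin`, `y_origin`.
#' @param spacing_mm,x_origin,y_origin Grid parameters used when `grid` is
#'   `NULL`.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(values, grid = NULL, spacing_mm = 1,
                       x_origin = 0, y_origin = 0) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("dose values must be finite and >= 0")
  }
  if (is.null(grid)) {
    grid <- fluence_grid(spacing_mm, x_origin, y_origin,
                         nx = ncol(values), ny = nrow(values))
  }
  stopifnot(grid$ny == nrow(values), grid$nx == ncol(values))
  structure(list(grid = grid, values = values), class = "dose_plane")
}

#' Gamma-analysis criteria
#'
#' @param dose_percent Dose-difference criterion as a percentage of the
#'   global maximum of the reference plane (global normalization).
#' @param dta_mm Distance-to-agreement criterion in mm.
#' @param low_dose_cutoff_percent Points whose measured dose is below this
#'   percentage of the reference global maximum are excluded (default 10).
#' @return A list of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent, dta_mm,
                           low_dose_cutoff_percent = 10) {
  if (!is_number(dose_percent) || dose_percent <= 0 ||
      !is_number(dta_mm) || dta_mm <= 0 ||
      !is_number(low_dose_cutoff_percent) || low_dose_cutoff_percent <= 0) {
    stop("gamma criteria must all be strictly positive")
  }
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 low_dose_cutoff_percent = low_dose_cutoff_percent,
                 normalization = "global"),
            class = "gamma_criteria")
}

# Bilinear interpolation of plane values at arbitrary (xq, yq); NA outside.
interp_plane <- function(grid, values, xq, yq) {
  s <- grid$spacing_mm
  cx <- (xq - grid$x_origin) / s + 1
  ry <- (grid$y_origin - yq) / s + 1
  out <- rep(NA_real_, length(xq))
  ok <- cx >= 1 & cx <= grid$nx & ry >= 1 & ry <= grid$ny
  if (!any(ok)) return(out)
  cx <- cx[ok]; ry <- ry[ok]
  i0 <- pmin(floor(ry), grid$ny - 1L); i0[grid$ny == 1L] <- 1L
  j0 <- pmin(floor(cx), grid$nx - 1L); j0[grid$nx == 1L] <- 1L
  fr <- ry - i0; fc <- cx - j0
  i1 <- pmin(i0 + 1L, grid$ny); j1 <- pmin(j0 + 1L, grid$nx)
  v <- (1 - fr) * (1 - fc) * values[cbind(i0, j0)] +
       (1 - fr) * fc       * values[cbind(i0, j1)] +
       fr       * (1 - fc) * values[cbind(i1, j0)] +
       fr       * fc       * values[cbind(i1, j1)]
  out[ok] <- v
  out
}

plane_extent <- function(g) {
  s <- g$spacing_mm
  c(xmin = g$x_origin, xmax = g$x_origin + (g$nx - 1L) * s,
    ymin = g$y_origin - (g$ny - 1L) * s, ymax = g$y_origin)
}

#' Global 2D gamma analysis
#'
#' For every measured point at or above the low-dose cutoff, the gamma
#' index is the minimum over reference positions within `cap_ratio * dta`
#' of \eqn{\sqrt{\Delta r^2/\Delta_{dta}^2 + \Delta D^2/(\delta D_{max})^2}}
#' with \eqn{D_{max}} the global maximum of the reference plane (global
#' normalization) and the reference field interpolated bilinearly on a
#' search grid of step `step_ratio * dta`.  The passing rate is the
#' percentage of evaluated points with gamma <= 1.
#'
#' The search enumerates offsets in order of increasing radius and stops
#' updating a point once its current gamma cannot be improved by any larger
#' radius, which is exact for the discretized search.  Points whose final
#' gamma exceeds `cap_ratio` might attain their true minimum outside the
#' search cap and are flagged in `capped`.
#'
#' @param reference,measured [dose_plane()]s; grids must overlap.
#' @param crit A [gamma_criteria()].
#' @param cap_ratio Search radius in units of the DTA (default 3).
#' @param step_ratio Search step in units of the DTA (default 0.1).
#' @return A list of class `gamma_result`: `gamma_map` (matrix shaped like
#'   the measured plane, `NaN` at excluded points), `passing_rate` in
#'   percent, `n_evaluated`, `capped` (logical matrix), `criteria`.
#' @export
gamma_analysis <- function(reference, measured, crit,
                           cap_ratio = 3, step_ratio = 0.1) {
  stopifnot(inherits(reference, "dose_plane"), inherits(measured, "dose_plane"),
            inherits(crit, "gamma_criteria"))
  dmax <- max(reference$values)
  if (dmax <= 0) stop("reference plane is zero everywhere")
  er <- plane_extent(reference$grid); em <- plane_extent(measured$grid)
  if (er["xmin"] > em["xmax"] || em["xmin"] > er["xmax"] ||
      er["ymin"] > em["ymax"] || em["ymin"] > er["ymax"]) {
    stop("reference and measured grids are spatially disjoint")
  }
  dta <- crit$dta_mm
  tol_d <- crit$dose_percent / 100 * dmax
  cutoff <- crit$low_dose_cutoff_percent / 100 * dmax

  gm <- measured$grid
  xs <- grid_x_centers(gm); ys <- grid_y_centers(gm)
  X <- matrix(xs, gm$ny, gm$nx, byrow = TRUE)
  Y <- matrix(ys, gm$ny, gm$nx)
  Dm <- measured$values

  eval_mask <- Dm >= cutoff
  gamma_map <- matrix(NaN, gm$ny, gm$nx)
  idx <- which(eval_mask)
  n_eval <- length(idx)
  if (n_eval == 0L) {
    return(structure(list(gamma_map = gamma_map, passing_rate = NaN,
                          n_evaluated = 0L,
                          capped = matrix(FALSE, gm$ny, gm$nx),
                          criteria = crit),
                     class = "gamma_result"))
  }
  xpt <- X[idx]; ypt <- Y[idx]; dpt <- Dm[idx]

  step <- dta * step_ratio
  cap <- dta * cap_ratio
  k <- seq(-round(cap / step), round(cap / step))
  offs <- expand.grid(dx = k * step, dy = k * step)
  r2 <- offs$dx^2 + offs$dy^2
  keep <- r2 <= cap^2 + 1e-9
  offs <- offs[keep, ]; r2 <- r2[keep]
  ord <- order(r2)
  offs <- offs[ord, ]; r2 <- r2[ord]

  g2 <- rep(Inf, n_eval)
  active <- seq_len(n_eval)
  for (o in seq_len(nrow(offs))) {
    rterm <- r2[o] / dta^2
    # points whose current gamma^2 <= (r/dta)^2 can no longer improve
    active <- active[g2[active] > rterm]
    if (!length(active)) break
    dref <- interp_plane(reference$grid, reference$values,
                         xpt[active] + offs$dx[o], ypt[active] + offs$dy[o])
    ok <- !is.na(dref)
    if (!any(ok)) next
    cand <- rterm + ((dref[ok] - dpt[active][ok]) / tol_d)^2
    ai <- active[ok]
    g2[ai] <- pmin(g2[ai], cand)
  }
  gam <- sqrt(g2)
  gamma_map[idx] <- gam
  capped <- matrix(FALSE, gm$ny, gm$nx)
  capped[idx] <- gam > cap_ratio
  structure(
    list(gamma_map = gamma_map,
         passing_rate = 100 * sum(gam <= 1 + 1e-12) / n_eval,
         n_evaluated = n_eval, capped = capped, criteria = crit),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: passing %.1f%% (%d points)\n",
              x$criteria$dose_percent, x$criteria$dta_mm,
              x$passing_rate, x$n_evaluated))
  invisible(x)
}

#' Plan-vs-log mechanical errors
#'
#' Compares a plan with a delivery-log record sampled at its control
#' points: the mean absolute leaf-position difference over all leaves of
#' both banks and all control points, the mean absolute gantry-angle
#' difference (minimal difference on the circle), and the mean absolute
#' cumulative-MU difference (planned cumulative MU is the meterset weight
#' times the beam's total MU).
#'
#' @param plan An [rt_plan()].
#' @param record A [delivery_record()] with one snapshot per control point.
#' @param moving_leaves_only If `TRUE`, restrict the MLC average to leaf
#'   pairs that move or are open at some control point of the beam.
#' @return A list of class `mechanical_error_summary` with fields
#'   `mlc_error_mm`, `gantry_error_deg`, `mu_error`.
#' @export
mechanical_errors <- function(plan, record, moving_leaves_only = FALSE) {
  if (length(plan$beams) != length(record$beams)) {
    stop("plan and record have different numbers of beams")
  }
  mlc <- c(); gan <- c(); mu <- c()
  for (bi in seq_along(plan$beams)) {
    beam <- plan$beams[[bi]]
    snaps <- record$beams[[bi]]$snapshots
    np <- beam$geometry$n_pairs
    if (record$geometry$n_pairs != np) {
      stop("beam ", bi, ": leaf-pair count mismatch between plan and record")
    }
    if (length(snaps) != length(beam$control_points)) {
      stop("beam ", bi, ": snapshot count != control point count")
    }
    A_p <- t(vapply(beam$control_points, function(cp) cp$bank_A, numeric(np)))
    B_p <- t(vapply(beam$control_points, function(cp) cp$bank_B, numeric(np)))
    A_r <- t(vapply(snaps, function(s) s$bank_A, numeric(np)))
    B_r <- t(vapply(snaps, function(s) s$bank_B, numeric(np)))
    if (moving_leaves_only) {
      moving <- apply(A_p, 2, function(v) any(v != v[1])) |
                apply(B_p, 2, function(v) any(v != v[1])) |
                colSums(B_p - A_p) > 0
      if (!any(moving)) moving <- rep(TRUE, np)
      A_p <- A_p[, moving, drop = FALSE]; B_p <- B_p[, moving, drop = FALSE]
      A_r <- A_r[, moving, drop = FALSE]; B_r <- B_r[, moving, drop = FALSE]
    }
    mlc <- c(mlc, abs(A_p - A_r), abs(B_p - B_r))
    g_p <- vapply(beam$control_points, function(cp) cp$gantry_angle, numeric(1))
    g_r <- vapply(snaps, function(s) s$gantry_angle, numeric(1))
    gan <- c(gan, circ_diff_deg(g_p, g_r))
    mu_p <- vapply(beam$control_points,
                   function(cp) cp$cumulative_meterset_weight, numeric(1)) *
            beam$total_mu
    mu_r <- vapply(snaps, function(s) s$cumulative_mu, numeric(1))
    mu <- c(mu, abs(mu_p - mu_r))
  }
  structure(list(mlc_error_mm = mean(mlc),
                 gantry_error_deg = mean(gan),
                 mu_error = mean(mu)),
            class = "mechanical_error_summary")
}

#' Average several mechanical-error summaries
#'
#' Component-wise arithmetic mean, as used to pool the summaries from
#' repeated QA delivery sessions of the same plan.
#'
#' @param summaries Non-empty list of `mechanical_error_summary` objects.
#' @return A `mechanical_error_summary`.
#' @export
average_summaries <- function(summaries) {
  if (!length(summaries)) stop("cannot average an empty list of summaries")
  take <- function(f) mean(vapply(summaries, function(s) s[[f]], numeric(1)))
  structure(list(mlc_error_mm = take("mlc_error_mm"),
                 gantry_error_deg = take("gantry_error_deg"),
                 mu_error = take("mu_error")),
            class = "mechanical_error_summary")
}

# Resample a finely-sampled delivery record onto the plan's control points
# by linear interpolation in cumulative meterset.
#' Resample a delivery record at a plan's control points
#'
#' Logs recorded on a fine time base are aligned to the plan by linear
#' interpolation of every recorded quantity against cumulative MU,
#' evaluated at the plan's per-control-point cumulative MU.
#'
#' @param record A [delivery_record()] (snapshots on any cumulative-MU grid).
#' @param plan The [rt_plan()] to align to.
#' @return A [delivery_record()] with one snapshot per plan control point.
#' @export
resample_record <- function(record, plan) {
  beams <- lapply(seq_along(plan$beams), function(bi) {
    beam <- plan$beams[[bi]]
    snaps <- record$beams[[bi]]$snapshots
    mu_r <- vapply(snaps, function(s) s$cumulative_mu, numeric(1))
    mu_t <- vapply(beam$control_points,
                   function(cp) cp$cumulative_meterset_weight, numeric(1)) *
            beam$total_mu
    np <- record$geometry$n_pairs
    A <- t(vapply(snaps, function(s) s$bank_A, numeric(np)))
    B <- t(vapply(snaps, function(s) s$bank_B, numeric(np)))
    g <- vapply(snaps, function(s) s$gantry_angle, numeric(1))
    # unwrap gantry so linear interpolation crosses 0/360 correctly
    gu <- g[1] + c(0, cumsum(((diff(g) + 180) %% 360) - 180))
    interp <- function(y) stats::approx(mu_r, y, xout = mu_t, rule = 2)$y
    Ai <- apply(A, 2, interp); Bi <- apply(B, 2, interp)
    gi <- interp(gu) %% 360
    list(snapshots = lapply(seq_along(mu_t), function(k) {
      list(index = k - 1L, cumulative_mu = mu_t[k], gantry_angle = gi[k],
           bank_A = Ai[k, ], bank_B = Bi[k, ])
    }))
  })
  delivery_record(record$plan_id, record$geometry, beams)
}

# ---- Spearman correlation --------------------------------------------------

# all permutations of 1..n as an (n! x n) matrix; n <= 9 in practice
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) p[, seq_len(i - 1L), drop = FALSE] else NULL
    right <- if (i <= n - 1L) p[, i:(n - 1L), drop = FALSE] else NULL
    out[[i]] <- cbind(left, n, right)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Ranks with midranks for ties; `r` is the Pearson correlation of the
#' ranks.  The two-sided p-value is computed by exact enumeration of all
#' `n!` permutations of one variable for `n <= 9` (probability of
#' `|r| >= |r_observed|` under the permutation null) and by the
#' t-approximation `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3, not constant.
#' @param alpha Significance threshold recorded in the result (default
#'   0.05).
#' @return A list of class `spearman_cor`: `r`, `p`, `n`, `significant`.
#' @export
spearman_cor <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("undefined correlation: constant input")
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    rc <- rx - mean(rx)
    sy <- ry - mean(ry)
    # r for every permutation of the y-ranks
    num <- matrix(sy[perms], nrow(perms), n) %*% rc
    den <- sqrt(sum(rc^2) * sum(sy^2))
    r_perm <- as.vector(num) / den
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
  } else {
    r2 <- min(r^2, 1)
    if (1 - r2 < 1e-15) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(r = r, p = p, n = n, significant = p < alpha),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("<spearman_cor> r = %.3f, p = %.4g, n = %d%s\n",
              x$r, x$p, x$n, if (x$significant) " *" else ""))
  invisible(x)
}

#' Feature-vs-measure correlation panel
#'
#' Computes one Spearman correlation per (feature, d, measure) between a
#' long-format feature table and a long-format measure table, joined on
#' `plan_id`.  Non-significant cells are flagged, not dropped.  By default
#' significance is raw `p < alpha` with no multiple-testing correction;
#' `adjust = "BH"` applies Benjamini-Hochberg across the panel instead.
#'
#' @param features `data.frame` with columns `plan_id`, `feature`, `d`,
#'   `value` (the output of [feature_panel()], possibly row-bound over
#'   plans).
#' @param measures `data.frame` with columns `plan_id`, `measure`, `value`.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `data.frame` of class `correlation_panel` with columns
#'   `feature`, `d`, `measure`, `r`, `p`, `n`, `significant`.  Cells whose
#'   correlation is undefined (constant input) carry `NA`.
#' @seealso [significance_counts()] for the per-feature significant-cell
#'   counts.
#' @export
correlation_panel <- function(features, measures, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(nm, " table lacks column(s): ", paste(miss, collapse = ", "))
    }
  }
  need(features, c("plan_id", "feature", "d", "value"), "features")
  need(measures, c("plan_id", "measure", "value"), "measures")
  shared <- intersect(unique(features$plan_id), unique(measures$plan_id))
  if (length(shared) < 3L) {
    stop("need at least 3 plans shared between features and measures")
  }
  fkeys <- unique(features[, c("feature", "d")])
  mkeys <- unique(measures$measure)
  rows <- list()
  for (fi in seq_len(nrow(fkeys))) {
    fsub <- features[features$feature == fkeys$feature[fi] &
                     features$d == fkeys$d[fi], ]
    fv <- fsub$value[match(shared, fsub$plan_id)]
    for (mk in mkeys) {
      msub <- measures[measures$measure == mk, ]
      mv <- msub$value[match(shared, msub$plan_id)]
      res <- tryCatch(spearman_cor(fv, mv, alpha = alpha),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = fkeys$feature[fi], d = fkeys$d[fi], measure = mk,
        r = if (is.null(res)) NA_real_ else res$r,
        p = if (is.null(res)) NA_real_ else res$p,
        n = if (is.null(res)) length(shared) else res$n,
        significant = if (is.null(res)) NA else res$significant)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  }
  class(out) <- c("correlation_panel", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Count significant cells per (feature, d)
#'
#' @param panel A [correlation_panel()].
#' @return `data.frame` with columns `feature`, `d`, `n_significant`.
#' @export
significance_counts <- function(panel) {
  agg <- stats::aggregate(significant ~ feature + d, data = panel,
                          FUN = function(v) sum(v, na.rm = TRUE))
  names(agg)[names(agg) == "significant"] <- "n_significant"
  agg[order(agg$feature, agg$d), ]
}
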