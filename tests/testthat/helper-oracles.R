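# Independent brute-force oracles and tiny fixture builders used across the
# suite.  These deliberately share no code with the package internals.

# ---- GLCM by explicit double loop ------------------------------------------

bf_offset <- function(d, theta) {
  switch(as.character(theta),
         "0" = c(d, 0), "45" = c(d, -d), "90" = c(0, -d), "135" = c(-d, -d))
}

bf_glcm <- function(m, d, theta, n_levels, symmetric = TRUE,
                    normalized = TRUE) {
  off <- bf_offset(d, theta)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      r2 <- r + off[2]; c2 <- c + off[1]
      if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m)) {
        i <- m[r, c] + 1; j <- m[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  if (normalized) counts / sum(counts) else counts
}

# ---- Haralick features by explicit summation -------------------------------

bf_haralick <- function(p, log_base = 10) {
  n <- nrow(p)
  asm <- 0; idm <- 0; contrast <- 0; entropy <- 0; sij <- 0
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(n - 1)) * px); muy <- sum((0:(n - 1)) * py)
  varx <- 0; vary <- 0
  for (i in 0:(n - 1)) {
    varx <- varx + (i - mux)^2 * px[i + 1]
    vary <- vary + (i - muy)^2 * py[i + 1]
    for (j in 0:(n - 1)) {
      pij <- p[i + 1, j + 1]
      asm <- asm + pij^2
      idm <- idm + pij / (1 + (i - j)^2)
      contrast <- contrast + (i - j)^2 * pij
      sij <- sij + i * j * pij
      if (pij > 0) entropy <- entropy - pij * log(pij, base = log_base)
    }
  }
  corr <- if (varx * vary > 0) (sij - mux * muy) / sqrt(varx * vary) else NaN
  list(ASM = asm, IDM = idm, contrast = contrast, variance = varx,
       correlation = corr, entropy = entropy)
}

# ---- aperture rasterization by fine subsampling ----------------------------

bf_rasterize <- function(cp, geometry, grid, mu_weight, sub = 0.1) {
  s <- grid$spacing_mm
  xs <- grid$x_origin + (seq_len(grid$nx) - 1) * s
  ys <- grid$y_origin - (seq_len(grid$ny) - 1) * s
  nsub <- round(s / sub)
  offs <- (seq_len(nsub) - 0.5) / nsub * s - s / 2
  vals <- matrix(0, grid$ny, grid$nx)
  bnd <- geometry$boundaries
  open_x <- function(x, y) {
    i <- findInterval(y, bnd)
    if (i < 1 || i > geometry$n_pairs) return(FALSE)
    x >= cp$bank_A[i] && x <= cp$bank_B[i] &&
      x >= cp$jaws[1] && x <= cp$jaws[2] &&
      y >= cp$jaws[3] && y <= cp$jaws[4]
  }
  for (r in seq_len(grid$ny)) {
    for (c in seq_len(grid$nx)) {
      hits <- 0
      for (ox in offs) for (oy in offs) {
        if (open_x(xs[c] + ox, ys[r] + oy)) hits <- hits + 1
      }
      vals[r, c] <- mu_weight * hits / nsub^2
    }
  }
  vals
}

# ---- exhaustive gamma search (pracma interpolation, no early exit) ---------

bf_gamma <- function(reference, measured, crit, cap_ratio = 3,
                     step_ratio = 0.1) {
  dmax <- max(reference$values)
  tol_d <- crit$dose_percent / 100 * dmax
  dta <- crit$dta_mm
  cutoff <- crit$low_dose_cutoff_percent / 100 * dmax
  gr <- reference$grid
  xr <- gr$x_origin + (seq_len(gr$nx) - 1) * gr$spacing_mm
  yr_desc <- gr$y_origin - (seq_len(gr$ny) - 1) * gr$spacing_mm
  # pracma::interp2 wants ascending y; flip rows accordingly
  yr <- rev(yr_desc)
  Zr <- reference$values[rev(seq_len(gr$ny)), , drop = FALSE]
  gm <- measured$grid
  xm <- gm$x_origin + (seq_len(gm$nx) - 1) * gm$spacing_mm
  ym <- gm$y_origin - (seq_len(gm$ny) - 1) * gm$spacing_mm
  step <- dta * step_ratio
  cap <- dta * cap_ratio
  k <- seq(-round(cap / step), round(cap / step)) * step
  offs <- expand.grid(dx = k, dy = k)
  offs <- offs[offs$dx^2 + offs$dy^2 <= cap^2 + 1e-9, ]
  gmap <- matrix(NaN, gm$ny, gm$nx)
  X <- matrix(xm, gm$ny, gm$nx, byrow = TRUE)
  Y <- matrix(ym, gm$ny, gm$nx)
  idx <- which(measured$values >= cutoff)
  xpt <- X[idx]; ypt <- Y[idx]; dpt <- measured$values[idx]
  g2 <- rep(Inf, length(idx))
  # exhaustive: every offset evaluated for every point, no early exit
  for (o in seq_len(nrow(offs))) {
    xq <- xpt + offs$dx[o]; yq <- ypt + offs$dy[o]
    inside <- xq >= min(xr) & xq <= max(xr) & yq >= min(yr) & yq <= max(yr)
    if (!any(inside)) next
    dref <- pracma::interp2(xr, yr, Zr, xq[inside], yq[inside])
    cand <- (offs$dx[o]^2 + offs$dy[o]^2) / dta^2 +
            ((dref - dpt[inside]) / tol_d)^2
    g2[inside] <- pmin(g2[inside], cand)
  }
  gmap[idx] <- sqrt(g2)
  n_eval <- sum(!is.nan(gmap))
  list(gamma_map = gmap,
       passing_rate = 100 * sum(gmap <= 1 + 1e-12, na.rm = TRUE) / n_eval,
       n_evaluated = n_eval)
}

# ---- Spearman oracles (no ties) --------------------------------------------

bf_spearman_r <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exact two-sided permutation p by plain recursive enumeration
bf_spearman_p <- function(x, y) {
  n <- length(x)
  robs <- abs(bf_spearman_r(x, y))
  ry <- rank(y)
  hits <- 0L; total <- 0L
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      total <<- total + 1L
      if (abs(bf_spearman_r(x, ry[prefix])) >= robs - 1e-12) {
        hits <<- hits + 1L
      }
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      recurse(c(prefix, remaining[i]), remaining[-i])
    }
  }
  recurse(integer(0), seq_len(n))
  hits / total
}

# ---- fixture builders ------------------------------------------------------

# small rectangular-field plan on a coarse custom MLC
make_simple_plan <- function(n_cp = 3, n_pairs = 4, half_x = 10,
                             total_mu = 100, plan_id = "fixture") {
  geom <- leaf_geometry(seq(-n_pairs * 2.5, n_pairs * 2.5, by = 5),
                        name = "toy")
  w <- seq(0, 1, length.out = n_cp)
  cps <- lapply(seq_len(n_cp), function(k) {
    control_point(index = k - 1, cumulative_meterset_weight = w[k],
                  gantry_angle = (180 + 10 * k) %% 360,
                  bank_A = rep(-half_x, n_pairs),
                  bank_B = rep(half_x, n_pairs))
  })
  rt_plan(plan_id, list(rt_beam(cps, total_mu = total_mu, geometry = geom)))
}

# delivery record that mirrors a plan exactly
record_from_plan <- function(plan, mlc_offset = 0) {
  beams <- lapply(plan$beams, function(beam) {
    list(snapshots = lapply(beam$control_points, function(cp) {
      list(index = cp$index,
           cumulative_mu = cp$cumulative_meterset_weight * beam$total_mu,
           gantry_angle = cp$gantry_angle,
           bank_A = cp$bank_A + mlc_offset,
           bank_B = cp$bank_B + mlc_offset)
    }))
  })
  delivery_record(plan$plan_id, plan$beams[[1]]$geometry, beams)
}

random_levels <- function(nr, nc, n_levels) {
  matrix(sample.int(n_levels, nr * nc, replace = TRUE) - 1L, nr, nc)
}
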