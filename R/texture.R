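# Gray-level co-occurrence matrices and the six Haralick texture features
# (ASM, IDM, contrast, variance, correlation, entropy), direction-averaged
# at displacement distances d in {1, 5, 10} pixels.

FEATURE_NAMES <- c("ASM", "IDM", "contrast", "variance", "correlation",
                   "entropy")

#' Texture-analysis configuration
#'
#' @param distances Displacement distances d in pixels (default
#'   `c(1, 5, 10)`; on the 1 mm fluence grid these are 1/5/10 mm along the
#'   axes and sqrt(2)/5*sqrt(2)/10*sqrt(2) mm diagonally).
#' @param angles Search directions in degrees, a subset of
#'   `c(0, 45, 90, 135)`.
#' @param n_levels Number of gray levels (default 128).
#' @param symmetric Count each pixel pair in both orders (default `TRUE`),
#'   making the GLCM transpose-symmetric and its marginals equal.
#' @param normalized Divide counts by the number of pairs so the GLCM is a
#'   probability distribution (default `TRUE`; features require it).
#' @param log_base Base of the logarithm in entropy (default 10).
#' @param variance_mean `"marginal"` (default) computes variance about the
#'   marginal mean of p_x; `"joint"` uses the mean of the two marginal
#'   means (identical under symmetry).
#' @param nan_policy For degenerate directions where correlation is
#'   undefined: `"omit"` (default) averages the defined directions,
#'   `"propagate"` returns NaN.
#' @param crop_margin_mm Margin kept around the nonzero fluence support
#'   before quantization (see [crop_fluence()]).
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(distances = c(1L, 5L, 10L),
                           angles = c(0, 45, 90, 135),
                           n_levels = 128L,
                           symmetric = TRUE,
                           normalized = TRUE,
                           log_base = 10,
                           variance_mean = c("marginal", "joint"),
                           nan_policy = c("omit", "propagate"),
                           crop_margin_mm = 0) {
  if (any(distances < 1) || any(distances != round(distances))) {
    stop("distances must be integers >= 1")
  }
  if (!all(angles %in% c(0, 45, 90, 135))) {
    stop("angles must be a subset of {0, 45, 90, 135}")
  }
  structure(
    list(distances = as.integer(distances), angles = angles,
         n_levels = as.integer(n_levels), symmetric = isTRUE(symmetric),
         normalized = isTRUE(normalized), log_base = log_base,
         variance_mean = match.arg(variance_mean),
         nan_policy = match.arg(nan_policy),
         crop_margin_mm = crop_margin_mm),
    class = "texture_config"
  )
}

# (col, row) pixel offset of one (d, theta); row index increases downward.
glcm_offset <- function(d, theta) {
  switch(as.character(theta),
    "0"   = c(d, 0),
    "45"  = c(d, -d),
    "90"  = c(0, -d),
    "135" = c(-d, -d),
    stop("unsupported angle: ", theta)
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs `(img[r, c], img[r + dr, c + dc])` over all pixels where
#' both ends fall inside the image, with `(dc, dr)` the offset of
#' displacement `d` at angle `theta` (0 deg: `(d, 0)`; 45: `(d, -d)`;
#' 90: `(0, -d)`; 135: `(-d, -d)`; row index increasing downward).  In
#' symmetric mode each pair is also counted in reverse order; in normalized
#' mode counts are divided by the total pair count.
#'
#' @param img A `gray_level_map` or an integer matrix of levels in
#'   `0 .. n_levels - 1`.
#' @param d Displacement distance in pixels (>= 1).
#' @param theta Angle in degrees, one of 0, 45, 90, 135.
#' @param cfg A [texture_config()].
#' @return An object of class `glcm` with fields `p` (the, possibly
#'   normalized, matrix), `counts` (raw integer counts), `d`, `theta`,
#'   `pair_count`.
#' @export
glcm <- function(img, d, theta, cfg = texture_config()) {
  m <- if (inherits(img, "gray_level_map")) img$levels else img
  if (!is.matrix(m)) stop("img must be a matrix or gray_level_map")
  n <- cfg$n_levels
  if (min(m) < 0 || max(m) >= n) {
    stop("gray levels out of range [0, ", n - 1L, "]")
  }
  off <- glcm_offset(d, theta)
  dc <- off[1L]; dr <- off[2L]
  nr <- nrow(m); nc <- ncol(m)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 > r2 || c1 > c2) {
    stop(sprintf("no pairs: image %dx%d smaller than offset (%d, %d)",
                 nr, nc, dc, dr))
  }
  rows <- r1:r2
  cols <- c1:c2
  i <- m[rows, cols, drop = FALSE]
  j <- m[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(as.vector(i) * n + as.vector(j) + 1L, nbins = n * n)
  counts <- matrix(counts, n, n, byrow = TRUE)  # counts[i+1, j+1]
  if (cfg$symmetric) counts <- counts + t(counts)
  pair_count <- sum(counts)
  p <- if (cfg$normalized) counts / pair_count else counts
  structure(list(p = p, counts = counts, d = as.integer(d), theta = theta,
                 pair_count = pair_count,
                 normalized = cfg$normalized, symmetric = cfg$symmetric),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> d=%d theta=%g deg, %d pairs, %s%s\n",
              x$d, x$theta, x$pair_count,
              if (x$symmetric) "symmetric, " else "",
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Haralick features of one GLCM
#'
#' With `p(i, j)` the normalized GLCM over gray levels `i, j = 0 .. n-1`,
#' marginal `p_x(i) = sum_j p(i, j)` with mean `mu_x` and standard
#' deviation `sigma_x` (and `p_y`, `mu_y`, `sigma_y` by column):
#' \deqn{ASM = \sum p^2,\quad IDM = \sum \frac{p}{1 + (i-j)^2},\quad
#'       contrast = \sum (i-j)^2 p,}
#' \deqn{variance = \sum_i (i - \mu_x)^2 p_x(i),\quad
#'       correlation = \frac{\sum i j\, p - \mu_x \mu_y}{\sigma_x \sigma_y},
#'       \quad entropy = -\sum p \log p.}
#' Logarithms default to base 10.  When `sigma_x * sigma_y = 0` (a
#' degenerate single-column distribution) correlation is `NaN` and the
#' result carries `correlation_defined = FALSE`; all other features are
#' still computed.
#'
#' @param g A normalized [glcm()].
#' @param log_base Entropy logarithm base (default 10).
#' @param variance_mean See [texture_config()].
#' @return A list of class `texture_features` with the six features plus
#'   `d`, `theta` and `correlation_defined`.
#' @export
haralick_features <- function(g, log_base = 10,
                              variance_mean = c("marginal", "joint")) {
  variance_mean <- match.arg(variance_mean)
  if (!isTRUE(g$normalized)) {
    stop("haralick_features requires a normalized GLCM")
  }
  p <- g$p
  n <- nrow(p)
  v <- seq_len(n) - 1
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(v * px); muy <- sum(v * py)
  sx2 <- sum((v - mux)^2 * px); sy2 <- sum((v - muy)^2 * py)
  D2 <- outer(v, v, "-")^2
  asm <- sum(p^2)
  idm <- sum(p / (1 + D2))
  contrast <- sum(D2 * p)
  variance <- if (variance_mean == "marginal") {
    sx2
  } else {
    mu <- (mux + muy) / 2
    sum(outer((v - mu)^2, rep(1, n)) * p)
  }
  denom <- sqrt(sx2 * sy2)
  if (denom > 0) {
    correlation <- (sum(outer(v, v) * p) - mux * muy) / denom
    corr_defined <- TRUE
  } else {
    correlation <- NaN
    corr_defined <- FALSE
  }
  pz <- p[p > 0]
  entropy <- -sum(pz * log(pz, base = log_base))
  structure(
    list(ASM = asm, IDM = idm, contrast = contrast, variance = variance,
         correlation = correlation, entropy = entropy,
         d = g$d, theta = g$theta, correlation_defined = corr_defined),
    class = "texture_features"
  )
}

#' Direction-averaged texture features
#'
#' Computes one GLCM per configured angle at displacement `d` and averages
#' each feature arithmetically over the directions.  A direction whose
#' correlation is undefined (degenerate GLCM) is omitted from the
#' correlation average under the default NaN policy; the number of defined
#' directions is recorded.
#'
#' @param img A `gray_level_map` or level matrix.
#' @param d Displacement distance in pixels.
#' @param cfg A [texture_config()].
#' @return A `texture_features` list with `theta = NA`, an attribute
#'   `"directions"` holding the per-direction feature sets, and
#'   `n_defined_directions` for the correlation average.
#' @export
direction_averaged_features <- function(img, d, cfg = texture_config()) {
  per_dir <- lapply(cfg$angles, function(th) {
    haralick_features(glcm(img, d, th, cfg), log_base = cfg$log_base,
                      variance_mean = cfg$variance_mean)
  })
  take <- function(f) vapply(per_dir, function(x) x[[f]], numeric(1))
  corr <- take("correlation")
  defined <- !is.nan(corr)
  corr_avg <- if (cfg$nan_policy == "omit") {
    if (any(defined)) mean(corr[defined]) else NaN
  } else {
    mean(corr)
  }
  out <- structure(
    list(ASM = mean(take("ASM")), IDM = mean(take("IDM")),
         contrast = mean(take("contrast")),
         variance = mean(take("variance")),
         correlation = corr_avg, entropy = mean(take("entropy")),
         d = as.integer(d), theta = NA_real_,
         correlation_defined = any(defined),
         n_defined_directions = sum(defined)),
    class = "texture_features"
  )
  attr(out, "directions") <- per_dir
  out
}

panel_from_graymap <- function(gmap, cfg, plan_id) {
  rows <- lapply(cfg$distances, function(d) {
    f <- direction_averaged_features(gmap, d, cfg)
    data.frame(plan_id = plan_id,
               feature = FEATURE_NAMES,
               d = d,
               value = vapply(FEATURE_NAMES, function(nm) f[[nm]], numeric(1)),
               n_defined_directions = ifelse(
                 FEATURE_NAMES == "correlation",
                 f$n_defined_directions, length(cfg$angles)),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Texture feature panel of a plan
#'
#' The end-to-end texture pipeline: integrate the plan's fluence, crop to
#' the nonzero support, quantize to `n_levels` gray levels and compute
#' direction-averaged features at every configured displacement.  With the
#' defaults (6 features x 3 distances) the panel has 18 values per plan.
#'
#' @param plan An [rt_plan()] with nonzero fluence.
#' @param cfg A [texture_config()].
#' @param grid Optional explicit [fluence_grid()] (default: plan-derived).
#' @param mu_weighting Meterset sharing rule, see [integrate_fluence()].
#' @return A long-format `data.frame` with columns `plan_id`, `feature`,
#'   `d`, `value`, `n_defined_directions` and the configuration in
#'   attribute `"config"`.
#' @export
feature_panel <- function(plan, cfg = texture_config(), grid = NULL,
                          mu_weighting = "trapezoid") {
  fmap <- integrate_fluence(plan, grid = grid, mu_weighting = mu_weighting)
  fmap <- crop_fluence(fmap, margin_mm = cfg$crop_margin_mm)
  gmap <- quantize(fmap, n_levels = cfg$n_levels)
  out <- panel_from_graymap(gmap, cfg, plan$plan_id)
  attr(out, "config") <- cfg
  out
}

#' Export a GLCM as a CSV matrix (for debugging / inspection)
#'
#' @param g A [glcm()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_glcm_csv <- function(g, path) {
  utils::write.table(g$p, file = path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
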