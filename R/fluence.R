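# Fluence-map construction: rasterize MU-weighted MLC apertures per control
# point and superpose them into an integrated fluence map, then quantize to
# gray levels 0..127 for texture analysis.
#
# Grid convention: pixel (row r, col c) has center
#   x = x_origin + (c-1) * spacing,   y = y_origin - (r-1) * spacing,
# i.e. row 1 is the top (largest y) row, matching image conventions.

#' Fluence-map pixel grid
#'
#' @param spacing_mm Pixel size in mm (default 1, the resolution used for
#'   all texture analysis).
#' @param x_origin,y_origin mm coordinates of the center of pixel (row 1,
#'   col 1); rows run downward in y.
#' @param nx,ny Grid dimensions (columns, rows).
#' @return An object of class `fluence_grid`.
#' @export
fluence_grid <- function(spacing_mm = 1, x_origin = 0, y_origin = 0,
                         nx = 1L, ny = 1L) {
  if (!is_number(spacing_mm) || spacing_mm <= 0) stop("spacing_mm must be > 0")
  if (!is_count(nx) || !is_count(ny)) stop("grid dimensions must be >= 1")
  structure(list(spacing_mm = spacing_mm, x_origin = x_origin,
                 y_origin = y_origin, nx = as.integer(nx),
                 ny = as.integer(ny)),
            class = "fluence_grid")
}

grid_x_centers <- function(g) g$x_origin + (seq_len(g$nx) - 1L) * g$spacing_mm
grid_y_centers <- function(g) g$y_origin - (seq_len(g$ny) - 1L) * g$spacing_mm

#' Construct a fluence map
#'
#' @param grid A [fluence_grid()].
#' @param values `ny` x `nx` matrix of nonnegative finite pixel values (MU).
#' @return An object of class `fluence_map`.
#' @export
fluence_map <- function(grid, values) {
  stopifnot(nrow(values) == grid$ny, ncol(values) == grid$nx)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("fluence values must be finite and nonnegative")
  }
  structure(list(grid = grid, values = values), class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %dx%d px @ %g mm, range [%g, %g] MU\n",
              x$grid$ny, x$grid$nx, x$grid$spacing_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

# Overlap length of [lo, hi] with pixel intervals centered at `centers`
# with half-width `half`; vectorized over centers.
interval_overlap <- function(lo, hi, centers, half) {
  pmax(0, pmin(hi, centers + half) - pmax(lo, centers - half))
}

# Accumulate one aperture into a plain matrix (fast path used by
# integrate_fluence); returns the ny x nx contribution matrix.
aperture_values <- function(cp, geometry, grid, mu_weight,
                            partial = TRUE) {
  s <- grid$spacing_mm
  half <- s / 2
  xs <- grid_x_centers(grid)
  ys <- grid_y_centers(grid)
  vals <- matrix(0, grid$ny, grid$nx)
  if (mu_weight == 0) return(vals)
  bnd <- geometry$boundaries
  jx1 <- cp$jaws[1]; jx2 <- cp$jaws[2]; jy1 <- cp$jaws[3]; jy2 <- cp$jaws[4]
  for (i in seq_len(geometry$n_pairs)) {
    a <- max(cp$bank_A[i], jx1); b <- min(cp$bank_B[i], jx2)
    if (b <= a) next
    ylo <- max(bnd[i], jy1); yhi <- min(bnd[i + 1L], jy2)
    if (yhi <= ylo) next
    if (partial) {
      fx <- interval_overlap(a, b, xs, half) / s
      fy <- interval_overlap(ylo, yhi, ys, half) / s
    } else {
      fx <- as.numeric(xs >= a & xs < b)
      fy <- as.numeric(ys >= ylo & ys < yhi)
    }
    if (!any(fx > 0) || !any(fy > 0)) next
    vals <- vals + mu_weight * outer(fy, fx)
  }
  vals
}

# bounding box (xmin,xmax,ymin,ymax) of the open, jaw-clipped aperture of
# one control point; NULL if fully closed.
aperture_bbox <- function(cp, geometry) {
  bnd <- geometry$boundaries
  open <- which(cp$bank_B > cp$bank_A)
  if (!length(open)) return(NULL)
  a <- pmax(cp$bank_A[open], cp$jaws[1])
  b <- pmin(cp$bank_B[open], cp$jaws[2])
  ylo <- pmax(bnd[open], cp$jaws[3])
  yhi <- pmin(bnd[open + 1L], cp$jaws[4])
  keep <- b > a & yhi > ylo
  if (!any(keep)) return(NULL)
  c(min(a[keep]), max(b[keep]), min(ylo[keep]), max(yhi[keep]))
}

#' Fluence of a single MLC aperture
#'
#' Rasterizes one control point's aperture onto `grid`.  The pixel value is
#' `mu_weight` times the open fraction of the pixel; the open region of
#' leaf-pair row *i* is the band between its leaf boundaries, between the
#' two leaf tips, intersected with the jaw rectangle.  Partial pixels are
#' scored by area-weighted coverage (exact for these axis-aligned
#' rectangles); `partial = FALSE` selects a faster center-in-region test.
#'
#' @param cp A [control_point()].
#' @param geometry The beam's [leaf_geometry()].
#' @param grid A [fluence_grid()]; must cover the jaw-clipped aperture.
#' @param mu_weight Monitor units attributed to this control point (>= 0).
#' @param partial Use area-weighted partial-pixel coverage (default) or a
#'   center-in test.
#' @return A `fluence_map`.
#' @export
aperture_fluence <- function(cp, geometry, grid, mu_weight, partial = TRUE) {
  if (!is_number(mu_weight) || mu_weight < 0) stop("mu_weight must be >= 0")
  bb <- aperture_bbox(cp, geometry)
  if (!is.null(bb)) {
    s <- grid$spacing_mm
    gx1 <- grid$x_origin - s / 2; gx2 <- grid$x_origin + (grid$nx - 0.5) * s
    gy2 <- grid$y_origin + s / 2; gy1 <- grid$y_origin - (grid$ny - 0.5) * s
    if (bb[1] < gx1 - 1e-9 || bb[2] > gx2 + 1e-9 ||
        bb[3] < gy1 - 1e-9 || bb[4] > gy2 + 1e-9) {
      stop(sprintf(
        "grid [%g,%g]x[%g,%g] mm does not cover aperture [%g,%g]x[%g,%g] mm",
        gx1, gx2, gy1, gy2, bb[1], bb[2], bb[3], bb[4]))
    }
  }
  fluence_map(grid, aperture_values(cp, geometry, grid, mu_weight,
                                    partial = partial))
}

#' Default grid for a plan
#'
#' The union of jaw-clipped aperture bounding boxes over all control points
#' of all beams, padded by `pad_mm`, with pixel edges aligned to multiples
#' of `spacing_mm`.
#'
#' @param plan An [rt_plan()].
#' @param spacing_mm Pixel size (default 1 mm).
#' @param pad_mm Padding around the aperture union (default 5 mm).
#' @return A [fluence_grid()].
#' @export
default_plan_grid <- function(plan, spacing_mm = 1, pad_mm = 5) {
  boxes <- list()
  for (beam in plan$beams) {
    for (cp in beam$control_points) {
      bb <- aperture_bbox(cp, beam$geometry)
      if (!is.null(bb)) boxes[[length(boxes) + 1L]] <- bb
    }
  }
  if (!length(boxes)) stop("plan has no open apertures; fluence is empty")
  m <- do.call(rbind, boxes)
  s <- spacing_mm
  left  <- floor((min(m[, 1]) - pad_mm) / s) * s
  right <- ceiling((max(m[, 2]) + pad_mm) / s) * s
  bot   <- floor((min(m[, 3]) - pad_mm) / s) * s
  top   <- ceiling((max(m[, 4]) + pad_mm) / s) * s
  fluence_grid(spacing_mm = s,
               x_origin = left + s / 2, y_origin = top - s / 2,
               nx = round((right - left) / s), ny = round((top - bot) / s))
}

# Per-control-point meterset share.  "trapezoid" splits each meterset
# interval between its two bounding apertures (symmetric, sums to total_mu);
# "left" assigns each interval wholly to its starting control point.
delta_mu <- function(beam, mu_weighting = c("trapezoid", "left")) {
  mu_weighting <- match.arg(mu_weighting)
  w <- vapply(beam$control_points,
              function(cp) cp$cumulative_meterset_weight, numeric(1))
  n <- length(w)
  if (mu_weighting == "trapezoid") {
    wext <- c(w[1L], w, w[n])
    share <- (wext[3:(n + 2L)] - wext[1:n]) / 2
  } else {
    share <- c(diff(w), 0)
  }
  beam$total_mu * share
}

#' Integrated fluence map of a plan
#'
#' Superposes the MU-weighted aperture fluences of every control point of
#' every beam onto one map (all beams of a plan are pooled).  Each control
#' point's meterset share is, by default, the trapezoidal split of its
#' adjacent cumulative-meterset intervals, so shares sum exactly to the
#' beam's total MU.
#'
#' @param plan An [rt_plan()]; must pass [validate_plan()].
#' @param grid A [fluence_grid()], or `NULL` for [default_plan_grid()].
#' @param spacing_mm,pad_mm Passed to [default_plan_grid()] when `grid` is
#'   `NULL`.
#' @param mu_weighting `"trapezoid"` (default) or `"left"`.
#' @param partial Partial-pixel scoring, see [aperture_fluence()].
#' @return A `fluence_map` whose pixel values are in MU.
#' @export
integrate_fluence <- function(plan, grid = NULL, spacing_mm = 1, pad_mm = 5,
                              mu_weighting = c("trapezoid", "left"),
                              partial = TRUE) {
  stop_if_invalid(plan)
  mu_weighting <- match.arg(mu_weighting)
  if (is.null(grid)) {
    grid <- default_plan_grid(plan, spacing_mm = spacing_mm, pad_mm = pad_mm)
  }
  vals <- matrix(0, grid$ny, grid$nx)
  for (beam in plan$beams) {
    dmu <- delta_mu(beam, mu_weighting)
    for (k in seq_along(beam$control_points)) {
      if (dmu[k] <= 0) next
      # reuse aperture_fluence for its coverage check on the first pass
      fm <- aperture_fluence(beam$control_points[[k]], beam$geometry, grid,
                             dmu[k], partial = partial)
      vals <- vals + fm$values
    }
  }
  fluence_map(grid, vals)
}

#' Crop a fluence map to its nonzero support
#'
#' Background zeros inflate every GLCM feature, so texture analysis crops
#' to the bounding box of strictly positive fluence, expanded by
#' `margin_mm`.
#'
#' @param fmap A `fluence_map` (or `gray_level_map`).
#' @param margin_mm Margin retained around the nonzero bounding box, in mm.
#' @return The cropped map (same class as the input).
#' @export
crop_fluence <- function(fmap, margin_mm = 0) {
  vals <- if (inherits(fmap, "gray_level_map")) fmap$levels else fmap$values
  nz <- which(vals > 0, arr.ind = TRUE)
  if (!nrow(nz)) stop("cannot crop an all-zero map")
  mpx <- round(margin_mm / fmap$grid$spacing_mm)
  r1 <- max(1L, min(nz[, 1]) - mpx); r2 <- min(nrow(vals), max(nz[, 1]) + mpx)
  c1 <- max(1L, min(nz[, 2]) - mpx); c2 <- min(ncol(vals), max(nz[, 2]) + mpx)
  g <- fmap$grid
  newgrid <- fluence_grid(
    spacing_mm = g$spacing_mm,
    x_origin = g$x_origin + (c1 - 1L) * g$spacing_mm,
    y_origin = g$y_origin - (r1 - 1L) * g$spacing_mm,
    nx = c2 - c1 + 1L, ny = r2 - r1 + 1L)
  out <- fmap
  out$grid <- newgrid
  if (inherits(fmap, "gray_level_map")) {
    out$levels <- vals[r1:r2, c1:c2, drop = FALSE]
  } else {
    out$values <- vals[r1:r2, c1:c2, drop = FALSE]
  }
  out
}

#' Quantize a fluence map to integer gray levels
#'
#' Normalizes pixel values to integer gray levels `0 .. n_levels - 1` by
#' `round_half_up((n_levels - 1) * value / max)`, so every nonzero map has
#' maximum level `n_levels - 1` (127 by default) and zeros stay 0.
#' Quantization is invariant to positive rescaling of the map.
#'
#' @param fmap A `fluence_map` with at least one strictly positive pixel.
#' @param n_levels Number of gray levels (default 128).
#' @return An object of class `gray_level_map` with integer `levels`.
#' @export
quantize <- function(fmap, n_levels = 128L) {
  if (!is_count(n_levels, min = 2)) stop("n_levels must be an integer >= 2")
  mx <- max(fmap$values)
  if (mx <= 0) stop("cannot quantize an all-zero fluence map")
  lv <- floor((n_levels - 1) * fmap$values / mx + 0.5)  # round half up
  structure(list(grid = fmap$grid,
                 levels = matrix(as.integer(lv), nrow(lv), ncol(lv)),
                 n_levels = as.integer(n_levels)),
            class = "gray_level_map")
}

#' @export
print.gray_level_map <- function(x, ...) {
  cat(sprintf("<gray_level_map> %dx%d px, levels 0..%d (max %d)\n",
              x$grid$ny, x$grid$nx, x$n_levels - 1L, max(x$levels)))
  invisible(x)
}

# ---- CSV + sidecar I/O -----------------------------------------------------

grid_sidecar_path <- function(path) paste0(path, ".grid.json")

#' Write / read a scalar map as a CSV matrix with a grid sidecar
#'
#' The matrix is written row-by-row (row 1 = top of the map); a JSON
#' sidecar `<path>.grid.json` records spacing, origin and the map kind so
#' the file round-trips.
#'
#' @param map A `fluence_map`, `gray_level_map` or `dose_plane`.
#' @param path CSV file path.
#' @return `read_map_csv` returns the reconstructed object;
#'   `write_map_csv` returns `path` invisibly.
#' @export
write_map_csv <- function(map, path) {
  vals <- if (inherits(map, "gray_level_map")) map$levels else map$values
  kind <- class(map)[1L]
  utils::write.table(vals, file = path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  g <- map$grid
  jsonlite::write_json(
    list(kind = kind, spacing_mm = g$spacing_mm, x_origin = g$x_origin,
         y_origin = g$y_origin, nx = g$nx, ny = g$ny,
         n_levels = map$n_levels),
    grid_sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- grid_sidecar_path(path)
  if (!file.exists(side)) stop("missing grid sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  g <- fluence_grid(meta$spacing_mm, meta$x_origin, meta$y_origin,
                    meta$nx, meta$ny)
  switch(meta$kind,
    fluence_map = fluence_map(g, vals),
    gray_level_map = structure(
      list(grid = g, levels = matrix(as.integer(vals), nrow(vals), ncol(vals)),
           n_levels = as.integer(meta$n_levels %||% 128L)),
      class = "gray_level_map"),
    dose_plane = dose_plane(vals, grid = g),
    stop("unknown map kind in sidecar: ", meta$kind)
  )
}

#' Write / read maps as TIFF or PNG images
#'
#' Fluence and dose maps export as single-channel 32-bit float TIFF;
#' gray-level maps as 8-bit PNG.  Both carry the same JSON grid sidecar as
#' [write_map_csv()].  These need the `tiff` / `png` packages.
#'
#' @param map A `fluence_map`, `dose_plane` (TIFF) or `gray_level_map`
#'   (PNG).
#' @param path Output file path.
#' @return The written `path`, invisibly; readers return the object.
#' @export
write_map_tiff <- function(map, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("write_map_tiff requires the 'tiff' package")
  }
  if (inherits(map, "gray_level_map")) {
    stop("use write_gray_png for gray-level maps")
  }
  vals <- map$values
  # TIFF samples live in [0, 1]; the physical scale goes in the sidecar
  value_scale <- max(vals, 1e-300)
  tiff::writeTIFF(vals / value_scale, path, bits.per.sample = 32L)
  g <- map$grid
  jsonlite::write_json(
    list(kind = class(map)[1L], spacing_mm = g$spacing_mm,
         x_origin = g$x_origin, y_origin = g$y_origin, nx = g$nx, ny = g$ny,
         value_scale = value_scale),
    grid_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("read_map_tiff requires the 'tiff' package")
  }
  meta <- jsonlite::read_json(grid_sidecar_path(path), simplifyVector = TRUE)
  vals <- tiff::readTIFF(path) * (meta$value_scale %||% 1)
  g <- fluence_grid(meta$spacing_mm, meta$x_origin, meta$y_origin,
                    meta$nx, meta$ny)
  if (identical(meta$kind, "dose_plane")) dose_plane(vals, grid = g)
  else fluence_map(g, vals)
}

#' @rdname write_map_tiff
#' @export
write_gray_png <- function(map, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("write_gray_png requires the 'png' package")
  }
  stopifnot(inherits(map, "gray_level_map"))
  png::writePNG(map$levels / 255, path)  # 8-bit gray, levels stored 1:1
  g <- map$grid
  jsonlite::write_json(
    list(kind = "gray_level_map", spacing_mm = g$spacing_mm,
         x_origin = g$x_origin, y_origin = g$y_origin, nx = g$nx, ny = g$ny,
         n_levels = map$n_levels),
    grid_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_gray_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("read_gray_png requires the 'png' package")
  }
  meta <- jsonlite::read_json(grid_sidecar_path(path), simplifyVector = TRUE)
  lv <- round(png::readPNG(path) * 255)
  structure(
    list(grid = fluence_grid(meta$spacing_mm, meta$x_origin, meta$y_origin,
                             meta$nx, meta$ny),
         levels = matrix(as.integer(lv), nrow(lv), ncol(lv)),
         n_levels = as.integer(meta$n_levels)),
    class = "gray_level_map")
}
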