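# Domain types for VMAT plans, MLC leaf geometry and delivery-log records,
# plus the plain-JSON exchange format used throughout the test fixtures.
#
# Coordinate convention: leaf-tip positions in mm at the isocenter plane,
# IEC 61217 beam-limiting-device coordinates.  bank_A is the left
# (negative-direction) bank, so bank_A[i] <= bank_B[i] for an open pair.

PLAN_SCHEMA_VERSION <- "1.0"

#' MLC leaf geometry
#'
#' Leaf-pair boundaries along the axis orthogonal to leaf travel (mm at
#' isocenter).  `n_pairs` leaf pairs are delimited by `n_pairs + 1` strictly
#' increasing boundary coordinates.
#'
#' @param boundaries Numeric vector of leaf-edge coordinates in mm, strictly
#'   increasing.
#' @param name Label for the geometry (e.g. `"millennium120"`).
#' @return An object of class `leaf_geometry` with fields `name`,
#'   `boundaries` and `n_pairs`.
#' @seealso [varian_mlc_geometry()] for the two stock Varian MLC models.
#' @export
#' @examples
#' g <- leaf_geometry(seq(-30, 30, by = 5), name = "toy")
#' g$n_pairs
leaf_geometry <- function(boundaries, name = "custom") {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) {
    stop("leaf_geometry: need at least two leaf boundaries")
  }
  if (any(!is.finite(boundaries)) || any(diff(boundaries) <= 0)) {
    stop("leaf_geometry: boundaries must be finite and strictly increasing")
  }
  structure(
    list(name = as.character(name)[1L],
         boundaries = boundaries,
         n_pairs = length(boundaries) - 1L),
    class = "leaf_geometry"
  )
}

#' Stock Varian MLC geometries
#'
#' The Millennium 120 MLC has 40 central 5 mm leaf pairs flanked by 10 + 10
#' outer 10 mm pairs; the high-definition (HD) 120 MLC has 32 central 2.5 mm
#' pairs flanked by 14 + 14 outer 5 mm pairs.  Both have 60 pairs.
#'
#' @param model `"millennium120"` or `"hd120"`.
#' @return A [leaf_geometry()] object.
#' @export
varian_mlc_geometry <- function(model = c("millennium120", "hd120")) {
  model <- match.arg(model)
  b <- switch(model,
    millennium120 = c(seq(-200, -100, by = 10), seq(-95, 95, by = 5),
                      seq(100, 200, by = 10)),
    hd120 = c(seq(-110, -45, by = 5), seq(-40, 40, by = 2.5),
              seq(45, 110, by = 5))
  )
  leaf_geometry(b, name = model)
}

#' Control point of a VMAT beam
#'
#' One snapshot of the delivery sequence: both MLC bank positions, gantry
#' angle, jaw settings and the cumulative meterset weight (delivered
#' fraction in \[0, 1\]).
#'
#' @param index 0-based ordinal of the control point within its beam.
#' @param cumulative_meterset_weight Delivered meterset fraction in \[0, 1\].
#' @param gantry_angle Gantry angle in degrees.
#' @param bank_A,bank_B Per-pair leaf-tip positions in mm; `bank_A` is the
#'   left (negative) bank, so `bank_A[i] <= bank_B[i]`.
#' @param jaws Numeric `c(x1, x2, y1, y2)` jaw positions in mm; defaults to
#'   a non-clipping +/-200 mm.
#' @return A list of class `control_point`.
#' @export
control_point <- function(index, cumulative_meterset_weight, gantry_angle,
                          bank_A, bank_B,
                          jaws = c(-200, 200, -200, 200)) {
  structure(
    list(index = as.integer(index),
         cumulative_meterset_weight = as.numeric(cumulative_meterset_weight),
         gantry_angle = as.numeric(gantry_angle),
         bank_A = as.numeric(bank_A),
         bank_B = as.numeric(bank_B),
         jaws = as.numeric(jaws)),
    class = "control_point"
  )
}

#' Treatment beam
#'
#' @param control_points List of [control_point()]s, ordered by index.
#' @param total_mu Total monitor units of the beam (> 0).
#' @param geometry The beam's [leaf_geometry()].
#' @return A list of class `rt_beam`.
#' @export
rt_beam <- function(control_points, total_mu, geometry) {
  structure(
    list(control_points = control_points,
         total_mu = as.numeric(total_mu),
         geometry = geometry),
    class = "rt_beam"
  )
}

#' Treatment plan
#'
#' @param plan_id Character label for the plan.
#' @param beams List of [rt_beam()]s (at least one).
#' @return A list of class `rt_plan`.
#' @export
rt_plan <- function(plan_id, beams) {
  structure(
    list(plan_id = as.character(plan_id)[1L], beams = beams),
    class = "rt_plan"
  )
}

#' @export
print.rt_plan <- function(x, ...) {
  ncp <- vapply(x$beams, function(b) length(b$control_points), integer(1))
  mu <- vapply(x$beams, function(b) b$total_mu, numeric(1))
  cat(sprintf("<rt_plan> %s: %d beam(s), %s control points, %.1f MU total\n",
              x$plan_id, length(x$beams),
              paste(ncp, collapse = "+"), sum(mu)))
  invisible(x)
}

#' Delivery-log record
#'
#' Machine-log counterpart of a plan: one snapshot per plan control point
#' carrying the *recorded* cumulative MU, gantry angle and bank positions.
#' Snapshots use absolute cumulative MU (not the planned fraction).
#'
#' @param plan_id Label of the plan this log records.
#' @param geometry [leaf_geometry()] (must match the plan's).
#' @param beams List with one element per beam, each a list with a
#'   `snapshots` list; each snapshot has fields `index`, `cumulative_mu`,
#'   `gantry_angle`, `bank_A`, `bank_B`.
#' @return A list of class `delivery_record`.
#' @export
delivery_record <- function(plan_id, geometry, beams) {
  for (b in beams) {
    mu <- vapply(b$snapshots, function(s) s$cumulative_mu, numeric(1))
    if (any(diff(mu) < 0)) {
      stop("delivery_record: snapshot cumulative MU must be nondecreasing")
    }
  }
  structure(
    list(plan_id = as.character(plan_id)[1L], geometry = geometry,
         beams = beams),
    class = "delivery_record"
  )
}

#' Validate a plan against its type invariants
#'
#' Checks every invariant of the plan model and returns a character vector
#' of human-readable violations (empty when the plan is well formed).  The
#' validator always returns; it never raises.
#'
#' Checked: at least one beam; each beam has >= 2 control points, positive
#' total MU and consistent bank lengths; cumulative meterset weights start
#' at 0, end at 1 and are nondecreasing; no crossed leaf pairs
#' (`bank_A[i] > bank_B[i]`); leaf boundaries strictly increasing.
#'
#' @param plan An [rt_plan()].
#' @return Character vector of violation descriptions, `character(0)` if
#'   the plan is valid.  Each violation names the beam, control point and
#'   leaf pair(s) concerned.
#' @export
validate_plan <- function(plan) {
  v <- character(0)
  if (!inherits(plan, "rt_plan")) {
    return("not an rt_plan object")
  }
  if (length(plan$beams) < 1L) {
    return("plan has no beams")
  }
  for (bi in seq_along(plan$beams)) {
    beam <- plan$beams[[bi]]
    geom <- beam$geometry
    if (!inherits(geom, "leaf_geometry") || any(diff(geom$boundaries) <= 0)) {
      v <- c(v, sprintf("beam %d: invalid leaf geometry", bi))
      next
    }
    np <- geom$n_pairs
    if (length(beam$control_points) < 2L) {
      v <- c(v, sprintf("beam %d: fewer than 2 control points", bi))
    }
    if (!is_number(beam$total_mu) || beam$total_mu <= 0) {
      v <- c(v, sprintf("beam %d: total_mu must be > 0", bi))
    }
    w <- vapply(beam$control_points,
                function(cp) cp$cumulative_meterset_weight, numeric(1))
    if (length(w)) {
      if (abs(w[1L]) > 1e-9) {
        v <- c(v, sprintf("beam %d: first cumulative meterset weight is %g, not 0",
                          bi, w[1L]))
      }
      if (abs(w[length(w)] - 1) > 1e-9) {
        v <- c(v, sprintf("beam %d: last cumulative meterset weight is %g, not 1",
                          bi, w[length(w)]))
      }
      if (any(w < -1e-9 | w > 1 + 1e-9)) {
        v <- c(v, sprintf("beam %d: cumulative meterset weights outside [0,1]", bi))
      }
      bad <- which(diff(w) < -1e-9)
      if (length(bad)) {
        v <- c(v, sprintf(
          "beam %d: cumulative meterset weight decreases at control point %d",
          bi, bad[1L]))
      }
    }
    for (ci in seq_along(beam$control_points)) {
      cp <- beam$control_points[[ci]]
      if (length(cp$bank_A) != np || length(cp$bank_B) != np) {
        v <- c(v, sprintf(
          "beam %d control point %d: bank length != %d leaf pairs", bi, ci - 1L, np))
        next
      }
      crossed <- which(cp$bank_A > cp$bank_B + 1e-9)
      if (length(crossed)) {
        v <- c(v, sprintf(
          "beam %d control point %d: crossed leaves at pair(s) %s",
          bi, ci - 1L, paste(crossed, collapse = ",")))
      }
      if (length(cp$jaws) != 4L || cp$jaws[1] > cp$jaws[2] ||
          cp$jaws[3] > cp$jaws[4]) {
        v <- c(v, sprintf("beam %d control point %d: invalid jaws", bi, ci - 1L))
      }
    }
  }
  v
}

stop_if_invalid <- function(plan) {
  v <- validate_plan(plan)
  if (length(v)) {
    stop("invalid plan:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(plan)
}

# ---- JSON exchange format --------------------------------------------------

cp_to_list <- function(cp) {
  list(index = cp$index,
       cumulative_meterset_weight = cp$cumulative_meterset_weight,
       gantry_angle = cp$gantry_angle,
       bank_A = I(cp$bank_A), bank_B = I(cp$bank_B), jaws = I(cp$jaws))
}

#' Write / read a plan in the JSON exchange format
#'
#' A versioned plain-text schema mirroring the plan model, used as the
#' DICOM-free fixture format.  `read_plan_json(write_plan_json(p))` is the
#' identity field-for-field.  Schema violations are reported with the path
#' of the offending field.
#'
#' @param plan An [rt_plan()].
#' @param path File path.
#' @return `read_plan_json` returns an [rt_plan()]; `write_plan_json`
#'   returns `path` invisibly.
#' @export
write_plan_json <- function(plan, path) {
  stop_if_invalid(plan)
  beams <- lapply(plan$beams, function(b) {
    list(total_mu = b$total_mu,
         geometry = list(name = b$geometry$name,
                         leaf_boundaries = I(b$geometry$boundaries)),
         control_points = lapply(b$control_points, cp_to_list))
  })
  obj <- list(schema_version = PLAN_SCHEMA_VERSION,
              plan_id = plan$plan_id, beams = beams)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

json_need <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop(sprintf("plan JSON: missing field '%s' at %s", field, where),
         call. = FALSE)
  }
  x[[field]]
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  json_need(obj, "schema_version", "top level")
  plan_id <- json_need(obj, "plan_id", "top level")
  beams_raw <- json_need(obj, "beams", "top level")
  if (length(beams_raw) < 1L) stop("plan JSON: 'beams' is empty")
  beams <- lapply(seq_along(beams_raw), function(bi) {
    b <- beams_raw[[bi]]
    where <- sprintf("beams[%d]", bi)
    gm <- json_need(b, "geometry", where)
    geom <- leaf_geometry(unlist(json_need(gm, "leaf_boundaries", where)),
                          name = if (is.null(gm$name)) "custom" else gm$name)
    cps_raw <- json_need(b, "control_points", where)
    cps <- lapply(seq_along(cps_raw), function(ci) {
      cp <- cps_raw[[ci]]
      cw <- sprintf("%s.control_points[%d]", where, ci)
      a <- as.numeric(unlist(json_need(cp, "bank_A", cw)))
      bb <- as.numeric(unlist(json_need(cp, "bank_B", cw)))
      crossed <- which(a > bb + 1e-9)
      if (length(crossed)) {
        stop(sprintf("plan JSON: bank_A > bank_B at %s pair %d",
                     cw, crossed[1L]), call. = FALSE)
      }
      control_point(
        index = json_need(cp, "index", cw),
        cumulative_meterset_weight =
          json_need(cp, "cumulative_meterset_weight", cw),
        gantry_angle = json_need(cp, "gantry_angle", cw),
        bank_A = a, bank_B = bb,
        jaws = if (is.null(cp$jaws)) c(-200, 200, -200, 200)
               else as.numeric(unlist(cp$jaws))
      )
    })
    rt_beam(cps, total_mu = json_need(b, "total_mu", where), geometry = geom)
  })
  plan <- rt_plan(plan_id, beams)
  stop_if_invalid(plan)
  plan
}

#' Write / read a delivery-log record in JSON
#'
#' @param record A [delivery_record()].
#' @param path File path.
#' @return `read_log_json` returns a [delivery_record()]; `write_log_json`
#'   returns `path` invisibly.
#' @export
write_log_json <- function(record, path) {
  beams <- lapply(record$beams, function(b) {
    list(snapshots = lapply(b$snapshots, function(s) {
      list(index = s$index, cumulative_mu = s$cumulative_mu,
           gantry_angle = s$gantry_angle,
           bank_A = I(s$bank_A), bank_B = I(s$bank_B))
    }))
  })
  obj <- list(schema_version = PLAN_SCHEMA_VERSION,
              plan_id = record$plan_id,
              geometry = list(name = record$geometry$name,
                              leaf_boundaries = I(record$geometry$boundaries)),
              beams = beams)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_log_json
#' @export
read_log_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  gm <- json_need(obj, "geometry", "top level")
  geom <- leaf_geometry(unlist(json_need(gm, "leaf_boundaries", "geometry")),
                        name = if (is.null(gm$name)) "custom" else gm$name)
  beams <- lapply(json_need(obj, "beams", "top level"), function(b) {
    list(snapshots = lapply(b$snapshots, function(s) {
      list(index = s$index,
           cumulative_mu = as.numeric(s$cumulative_mu),
           gantry_angle = as.numeric(s$gantry_angle),
           bank_A = as.numeric(unlist(s$bank_A)),
           bank_B = as.numeric(unlist(s$bank_B)))
    }))
  })
  delivery_record(json_need(obj, "plan_id", "top level"), geom, beams)
}
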