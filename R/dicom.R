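# Minimal DICOM-RT Plan I/O.
#
# Reads the subset of a DICOM RT Plan needed for fluence reconstruction:
# BeamSequence -> ControlPointSequence -> BeamLimitingDevicePositionSequence
# (MLCX) plus LeafPositionBoundaries, CumulativeMetersetWeight, GantryAngle
# and the per-beam meterset from the FractionGroupSequence.  Supports
# explicit and implicit VR little endian.  The writer emits explicit VR
# little endian with a standard file meta group; it exists so fixtures and
# round-trip tests need no external data.

UID_RTPLAN   <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_EXPL_LE  <- "1.2.840.10008.1.2.1"
UID_IMPL_LE  <- "1.2.840.10008.1.2"

# VRs for the tags touched when parsing implicit VR streams.
DICOM_DICT <- c(
  "00020010" = "UI", "00080016" = "UI", "00080018" = "UI", "00080060" = "CS",
  "300A0002" = "LO", "300A0070" = "SQ", "300A0071" = "IS", "300A0078" = "IS",
  "300A0080" = "IS", "300C0004" = "SQ", "300A0086" = "DS", "300C0006" = "IS",
  "300A00B0" = "SQ", "300A00B6" = "SQ", "300A00B8" = "CS", "300A00BC" = "IS",
  "300A00BE" = "DS", "300A00C0" = "IS", "300A00C2" = "LO", "300A00C4" = "CS",
  "300A00C6" = "CS", "300A00CE" = "CS", "300A010E" = "DS", "300A0110" = "IS",
  "300A0111" = "SQ", "300A0112" = "IS", "300A011A" = "SQ", "300A011C" = "DS",
  "300A011E" = "DS", "300A0134" = "DS"
)

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                "SH", "ST", "TM", "UC", "UI", "UR", "UT")

# ---- low-level byte helpers ------------------------------------------------

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
u32le <- function(x) {
  # writeBin() of R integers cannot express values >= 2^31; the only such
  # length used in DICOM is the "undefined length" sentinel 0xFFFFFFFF.
  if (identical(x, 0xFFFFFFFF)) return(as.raw(c(0xff, 0xff, 0xff, 0xff)))
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}
rd_u16 <- function(buf, pos) {
  sum(as.integer(buf[pos:(pos + 1L)]) * c(1, 256))
}
rd_u32 <- function(buf, pos) {
  sum(as.numeric(buf[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L) c(r, pad) else r
}

dcm_str <- function(values, ui = FALSE) {
  pad_even(charToRaw(paste(values, collapse = "\\")),
           pad = if (ui) as.raw(0x00) else as.raw(0x20))
}

dcm_ds <- function(values) dcm_str(sprintf("%.10g", values))

# One explicit-VR-little-endian element.
dcm_el <- function(group, elem, vr, value_raw) {
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), u32le(length(value_raw)), value_raw)
  } else {
    c(head, u16le(length(value_raw)), value_raw)
  }
}

dcm_item <- function(content) {
  c(u16le(0xFFFE), u16le(0xE000), u32le(length(content)), content)
}

dcm_sq <- function(group, elem, items) {
  body <- do.call(c, c(items, list(raw(0))))
  dcm_el(group, elem, "SQ", body)
}

# ---- writer ----------------------------------------------------------------

#' Write a plan as a DICOM-RT Plan file
#'
#' Serializes an [rt_plan()] to a DICOM RT Plan (explicit VR little endian)
#' with BeamSequence, per-control-point MLC positions (MLCX), jaws, gantry
#' angles, cumulative meterset weights, and a FractionGroupSequence carrying
#' each beam's meterset.  Intended for fixtures and interoperability tests.
#'
#' @param plan An [rt_plan()].
#' @param path Output file path.
#' @param omit_repeated If `TRUE`, control points after the first omit
#'   gantry angle, jaws and MLC positions that are unchanged from the
#'   previous control point, exercising the standard DICOM
#'   inherit-from-previous semantics on read.
#' @return `path`, invisibly.
#' @export
write_dicom_rtplan <- function(plan, path, omit_repeated = FALSE) {
  stop_if_invalid(plan)
  sop_instance <- paste0("1.2.826.0.1.3680043.9.7297.",
                         format(as.integer(Sys.time()) %% 100000000L), ".1")

  beam_items <- lapply(seq_along(plan$beams), function(bi) {
    beam <- plan$beams[[bi]]
    geom <- beam$geometry
    bld_items <- list(
      dcm_item(c(dcm_el(0x300A, 0x00B8, "CS", dcm_str("X")),
                 dcm_el(0x300A, 0x00BC, "IS", dcm_str("1")))),
      dcm_item(c(dcm_el(0x300A, 0x00B8, "CS", dcm_str("Y")),
                 dcm_el(0x300A, 0x00BC, "IS", dcm_str("1")))),
      dcm_item(c(dcm_el(0x300A, 0x00B8, "CS", dcm_str("MLCX")),
                 dcm_el(0x300A, 0x00BC, "IS", dcm_str(geom$n_pairs)),
                 dcm_el(0x300A, 0x00BE, "DS", dcm_ds(geom$boundaries))))
    )
    cp_items <- lapply(seq_along(beam$control_points), function(ci) {
      cp <- beam$control_points[[ci]]
      prev <- if (ci > 1L) beam$control_points[[ci - 1L]] else NULL
      same <- function(field) {
        omit_repeated && !is.null(prev) &&
          isTRUE(all.equal(cp[[field]], prev[[field]], tolerance = 0))
      }
      body <- dcm_el(0x300A, 0x0112, "IS", dcm_str(cp$index))
      pos_items <- list()
      if (!(same("jaws"))) {
        pos_items <- c(pos_items, list(
          dcm_item(c(dcm_el(0x300A, 0x00B8, "CS", dcm_str("X")),
                     dcm_el(0x300A, 0x011C, "DS", dcm_ds(cp$jaws[1:2])))),
          dcm_item(c(dcm_el(0x300A, 0x00B8, "CS", dcm_str("Y")),
                     dcm_el(0x300A, 0x011C, "DS", dcm_ds(cp$jaws[3:4]))))))
      }
      if (!(same("bank_A") && same("bank_B"))) {
        pos_items <- c(pos_items, list(
          dcm_item(c(dcm_el(0x300A, 0x00B8, "CS", dcm_str("MLCX")),
                     dcm_el(0x300A, 0x011C, "DS",
                            dcm_ds(c(cp$bank_A, cp$bank_B)))))))
      }
      if (length(pos_items)) {
        body <- c(body, dcm_sq(0x300A, 0x011A, pos_items))
      }
      if (!same("gantry_angle")) {
        body <- c(body, dcm_el(0x300A, 0x011E, "DS",
                               dcm_ds(cp$gantry_angle %% 360)))
      }
      body <- c(body, dcm_el(0x300A, 0x0134, "DS",
                             dcm_ds(cp$cumulative_meterset_weight)))
      dcm_item(body)
    })
    dcm_item(c(
      dcm_sq(0x300A, 0x00B6, bld_items),
      dcm_el(0x300A, 0x00C0, "IS", dcm_str(bi)),
      dcm_el(0x300A, 0x00C2, "LO", dcm_str(sprintf("Beam%d", bi))),
      dcm_el(0x300A, 0x00C4, "CS", dcm_str("DYNAMIC")),
      dcm_el(0x300A, 0x00C6, "CS", dcm_str("PHOTON")),
      dcm_el(0x300A, 0x00CE, "CS", dcm_str("TREATMENT")),
      dcm_el(0x300A, 0x010E, "DS", dcm_ds(1)),
      dcm_el(0x300A, 0x0110, "IS", dcm_str(length(beam$control_points))),
      dcm_sq(0x300A, 0x0111, cp_items)
    ))
  })

  refbeam_items <- lapply(seq_along(plan$beams), function(bi) {
    dcm_item(c(dcm_el(0x300A, 0x0086, "DS",
                      dcm_ds(plan$beams[[bi]]$total_mu)),
               dcm_el(0x300C, 0x0006, "IS", dcm_str(bi))))
  })
  fg_item <- dcm_item(c(
    dcm_el(0x300A, 0x0071, "IS", dcm_str(1)),
    dcm_el(0x300A, 0x0078, "IS", dcm_str(1)),
    dcm_el(0x300A, 0x0080, "IS", dcm_str(length(plan$beams))),
    dcm_sq(0x300C, 0x0004, refbeam_items)
  ))

  dataset <- c(
    dcm_el(0x0008, 0x0016, "UI", dcm_str(UID_RTPLAN, ui = TRUE)),
    dcm_el(0x0008, 0x0018, "UI", dcm_str(sop_instance, ui = TRUE)),
    dcm_el(0x0008, 0x0060, "CS", dcm_str("RTPLAN")),
    dcm_el(0x300A, 0x0002, "LO", dcm_str(plan$plan_id)),
    dcm_sq(0x300A, 0x0070, list(fg_item)),
    dcm_sq(0x300A, 0x00B0, beam_items)
  )

  meta_body <- c(
    dcm_el(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_el(0x0002, 0x0002, "UI", dcm_str(UID_RTPLAN, ui = TRUE)),
    dcm_el(0x0002, 0x0003, "UI", dcm_str(sop_instance, ui = TRUE)),
    dcm_el(0x0002, 0x0010, "UI", dcm_str(UID_EXPL_LE, ui = TRUE)),
    dcm_el(0x0002, 0x0012, "UI",
           dcm_str("1.2.826.0.1.3680043.9.7297.1.1", ui = TRUE))
  )
  meta <- c(dcm_el(0x0002, 0x0000, "UL", u32le(length(meta_body))), meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

# ---- parser ----------------------------------------------------------------

# Parse the element stream in buf[pos..end] into a named list keyed by
# "GGGGEEEE"; SQ values become lists of such lists.  Returns list(data, pos).
parse_elements <- function(buf, pos, end, explicit) {
  out <- list()
  while (pos <= end - 7L) {
    group <- rd_u16(buf, pos); elem <- rd_u16(buf, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE && elem %in% c(0xE00D, 0xE0DD)) {
      # item / sequence delimiter consumed by the caller's logic
      pos <- pos + 4L
      break
    }
    vr <- NULL
    if (explicit) {
      vr <- rawToChar(buf[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- rd_u32(buf, pos + 4L); pos <- pos + 8L
      } else {
        len <- rd_u16(buf, pos + 2L); pos <- pos + 4L
      }
    } else {
      len <- rd_u32(buf, pos); pos <- pos + 4L
      vr <- unname(DICOM_DICT[sprintf("%04X%04X", group, elem)])
      if (is.na(vr) || is.null(vr)) {
        vr <- if (len == 0xFFFFFFFF) "SQ" else "UN"
      }
    }
    key <- sprintf("%04X%04X", group, elem)
    if (identical(vr, "SQ")) {
      parsed <- parse_sequence(buf, pos, len, explicit)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else if (len == 0xFFFFFFFF) {
      stop("DICOM parse error: undefined length on non-sequence element ", key)
    } else {
      val_raw <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      out[[key]] <- decode_value(val_raw, vr)
    }
  }
  list(data = out, pos = pos)
}

parse_sequence <- function(buf, pos, len, explicit) {
  items <- list()
  seq_end <- if (len == 0xFFFFFFFF) length(buf) else pos + len - 1L
  while (pos <= seq_end - 7L) {
    g <- rd_u16(buf, pos); e <- rd_u16(buf, pos + 2L)
    ilen <- rd_u32(buf, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD) break        # sequence delimiter
    if (!(g == 0xFFFE && e == 0xE000)) {
      stop("DICOM parse error: expected sequence item tag")
    }
    if (ilen == 0xFFFFFFFF) {
      parsed <- parse_elements(buf, pos, length(buf), explicit)
    } else {
      parsed <- parse_elements(buf, pos, pos + ilen - 1L, explicit)
      parsed$pos <- pos + ilen
    }
    items[[length(items) + 1L]] <- parsed$data
    pos <- parsed$pos
    if (len != 0xFFFFFFFF && pos > seq_end) break
  }
  if (len != 0xFFFFFFFF) pos <- max(pos, seq_end + 1L)
  list(items = items, pos = pos)
}

decode_value <- function(val_raw, vr) {
  if (vr %in% STRING_VRS) {
    s <- rawToChar(val_raw[val_raw != as.raw(0)])
    parts <- strsplit(s, "\\", fixed = TRUE)[[1L]]
    trimws(parts)
  } else if (vr == "UL") {
    rd_u32(val_raw, 1L)
  } else if (vr == "US") {
    rd_u16(val_raw, 1L)
  } else if (vr == "FL") {
    readBin(val_raw, "double", n = length(val_raw) %/% 4L, size = 4L,
            endian = "little")
  } else if (vr == "FD") {
    readBin(val_raw, "double", n = length(val_raw) %/% 8L, size = 8L,
            endian = "little")
  } else {
    val_raw
  }
}

dcm_num <- function(ds, key) {
  v <- ds[[key]]
  if (is.null(v)) NULL else as.numeric(v)
}

#' Read a DICOM-RT Plan file
#'
#' Parses a DICOM RT Plan (explicit or implicit VR little endian) into an
#' [rt_plan()].  One beam is produced per treatment beam; setup and imaging
#' beams (`TreatmentDeliveryType != "TREATMENT"`) are excluded.  Control
#' points that omit gantry angle, jaw or MLC positions inherit them from the
#' previous control point, per standard DICOM-RT semantics; the first
#' control point of a beam must carry MLC positions.  Cumulative meterset
#' weights are normalized by the beam's final cumulative meterset weight.
#'
#' @param path Path to a DICOM RT Plan file.
#' @return An [rt_plan()].
#' @export
read_dicom_rtplan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 140L ||
      !identical(rawToChar(buf[129:132]), "DICM")) {
    stop("not a DICOM file (missing DICM preamble): ", path)
  }
  # file meta group is always explicit VR little endian
  pos <- 133L
  meta <- list()
  while (pos <= length(buf) - 7L && rd_u16(buf, pos) == 0x0002) {
    parsed <- parse_one_explicit(buf, pos)
    meta[[parsed$key]] <- parsed$value
    pos <- parsed$pos
  }
  ts <- meta[["00020010"]]
  if (is.null(ts)) stop("DICOM file has no transfer syntax UID")
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2"   = FALSE,
    stop("unsupported transfer syntax: ", ts)
  )
  ds <- parse_elements(buf, pos, length(buf), explicit)$data

  sop <- ds[["00080016"]]
  if (is.null(sop) || !identical(sop, UID_RTPLAN)) {
    stop("not an RT Plan (SOP class ", if (is.null(sop)) "absent" else sop,
         "): ", path)
  }

  # beam number -> meterset from the fraction group
  metersets <- list()
  for (fg in ds[["300A0070"]] %||% list()) {
    for (rb in fg[["300C0004"]] %||% list()) {
      bn <- dcm_num(rb, "300C0006")
      if (!is.null(bn)) metersets[[as.character(bn)]] <- dcm_num(rb, "300A0086")
    }
  }

  beams <- list()
  for (bitem in ds[["300A00B0"]] %||% list()) {
    dtype <- bitem[["300A00CE"]]
    if (!is.null(dtype) && !identical(toupper(dtype), "TREATMENT")) next
    bn <- dcm_num(bitem, "300A00C0")
    geom <- NULL
    for (bld in bitem[["300A00B6"]] %||% list()) {
      if (identical(toupper(bld[["300A00B8"]]), "MLCX")) {
        geom <- leaf_geometry(dcm_num(bld, "300A00BE"), name = "dicom_mlcx")
      }
    }
    if (is.null(geom)) {
      stop("beam ", bn, ": no MLCX device in BeamLimitingDeviceSequence")
    }
    np <- geom$n_pairs
    cps_raw <- bitem[["300A0111"]]
    if (is.null(cps_raw) || !length(cps_raw)) {
      stop("beam ", bn, ": no control points")
    }
    prev <- list(gantry = NULL, jaws = c(-200, 200, -200, 200),
                 A = NULL, B = NULL)
    cps <- vector("list", length(cps_raw))
    for (ci in seq_along(cps_raw)) {
      cpi <- cps_raw[[ci]]
      gantry <- dcm_num(cpi, "300A011E") %||% prev$gantry
      if (is.null(gantry)) {
        stop("beam ", bn, " control point ", ci - 1L, ": no gantry angle")
      }
      A <- prev$A; B <- prev$B; jaws <- prev$jaws
      for (bld in cpi[["300A011A"]] %||% list()) {
        typ <- toupper(bld[["300A00B8"]])
        v <- dcm_num(bld, "300A011C")
        if (typ == "MLCX") {
          if (length(v) != 2L * np) {
            stop("beam ", bn, " control point ", ci - 1L,
                 ": MLCX has ", length(v), " values, expected ", 2L * np)
          }
          A <- v[seq_len(np)]; B <- v[np + seq_len(np)]
        } else if (typ %in% c("X", "ASYMX")) {
          jaws[1:2] <- v
        } else if (typ %in% c("Y", "ASYMY")) {
          jaws[3:4] <- v
        }
      }
      if (is.null(A)) {
        stop("beam ", bn, ": first control point carries no MLC positions")
      }
      w <- dcm_num(cpi, "300A0134")
      if (is.null(w)) {
        stop("beam ", bn, " control point ", ci - 1L,
             ": no cumulative meterset weight")
      }
      cps[[ci]] <- control_point(
        index = dcm_num(cpi, "300A0112") %||% (ci - 1L),
        cumulative_meterset_weight = w,
        gantry_angle = gantry, bank_A = A, bank_B = B, jaws = jaws)
      prev <- list(gantry = gantry, jaws = jaws, A = A, B = B)
    }
    w <- vapply(cps, function(cp) cp$cumulative_meterset_weight, numeric(1))
    if (any(diff(w) < -1e-9)) {
      stop("beam ", bn, ": cumulative meterset weights are not nondecreasing")
    }
    final <- dcm_num(bitem, "300A010E") %||% w[length(w)]
    if (final <= 0) stop("beam ", bn, ": final cumulative meterset weight <= 0")
    for (ci in seq_along(cps)) {
      cps[[ci]]$cumulative_meterset_weight <- w[ci] / final
    }
    mu <- metersets[[as.character(bn)]]
    if (is.null(mu)) {
      stop("beam ", bn, ": no BeamMeterset in FractionGroupSequence")
    }
    beams[[length(beams) + 1L]] <- rt_beam(cps, total_mu = mu, geometry = geom)
  }
  if (!length(beams)) stop("RT Plan contains no treatment beams: ", path)
  plan_id <- ds[["300A0002"]] %||% basename(path)
  plan <- rt_plan(plan_id, beams)
  stop_if_invalid(plan)
  plan
}

# parse a single explicit-VR element (used for the file meta group)
parse_one_explicit <- function(buf, pos) {
  group <- rd_u16(buf, pos); elem <- rd_u16(buf, pos + 2L)
  vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
  if (vr %in% LONG_VRS) {
    len <- rd_u32(buf, pos + 8L); pos <- pos + 12L
  } else {
    len <- rd_u16(buf, pos + 6L); pos <- pos + 8L
  }
  val <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
  list(key = sprintf("%04X%04X", group, elem),
       value = decode_value(val, vr), pos = pos + len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
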