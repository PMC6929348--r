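test_that("JSON plan serialization round-trips field-for-field", {
  p <- generate_plan(synth_plan_spec(n_control_points = 5,
                                     modulation_amplitude_mm = 2, seed = 42))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan_json(p, path)
  p2 <- read_plan_json(path)
  expect_equal(p2$plan_id, p$plan_id)
  expect_equal(length(p2$beams), length(p$beams))
  expect_equal(p2$beams[[1]]$total_mu, p$beams[[1]]$total_mu)
  expect_equal(p2$beams[[1]]$geometry$boundaries,
               p$beams[[1]]$geometry$boundaries)
  for (k in seq_along(p$beams[[1]]$control_points)) {
    expect_equal(p2$beams[[1]]$control_points[[k]],
                 p$beams[[1]]$control_points[[k]])
  }
})

test_that("JSON reader reports missing fields with their path", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": "1.0", "plan_id": "x"}', path)
  expect_error(read_plan_json(path), "beams")
  writeLines('{"schema_version": "1.0", "beams": []}', path)
  expect_error(read_plan_json(path), "plan_id")
})

test_that("JSON reader rejects crossed banks, naming the leaf pair", {
  # write a structurally valid file, then corrupt one bank value
  p <- make_simple_plan()
  path <- withr::local_tempfile(fileext = ".json")
  write_plan_json(p, path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$beams[[1]]$control_points[[2]]$bank_A[[3]] <- 50
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_plan_json(path), "pair 3")
})

test_that("validate_plan flags each invariant exactly once", {
  good <- make_simple_plan()
  expect_identical(validate_plan(good), character(0))

  bad_mu <- make_simple_plan()
  bad_mu$beams[[1]]$total_mu <- -10
  v <- validate_plan(bad_mu)
  expect_length(v, 1L)
  expect_match(v, "total_mu")

  crossed <- make_simple_plan()
  crossed$beams[[1]]$control_points[[1]]$bank_A[2] <- 99
  v <- validate_plan(crossed)
  expect_length(v, 1L)
  expect_match(v, "crossed leaves")
  expect_match(v, "pair\\(s\\) 2")

  nonmono <- make_simple_plan(n_cp = 4)
  nonmono$beams[[1]]$control_points[[3]]$cumulative_meterset_weight <- 0.1
  v <- validate_plan(nonmono)
  expect_length(v, 1L)
  expect_match(v, "decreases")
})

test_that("cumulative weights [0, 0.5, 0.4] fail monotonicity on read", {
  p <- make_simple_plan(n_cp = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan_json(p, path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$beams[[1]]$control_points[[2]]$cumulative_meterset_weight <- 0.5
  obj$beams[[1]]$control_points[[3]]$cumulative_meterset_weight <- 0.4
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_plan_json(path), "meterset weight")
})

test_that("DICOM round trip preserves the plan and 60-pair HD geometry", {
  p <- generate_plan(synth_plan_spec(n_control_points = 2,
                                     geometry = varian_mlc_geometry("hd120"),
                                     modulation_amplitude_mm = 1, seed = 9))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_rtplan(p, path)
  p2 <- read_dicom_rtplan(path)
  expect_length(p2$beams, 1L)
  expect_length(p2$beams[[1]]$control_points, 2L)
  expect_identical(p2$beams[[1]]$geometry$n_pairs, 60L)
  expect_equal(p2$beams[[1]]$total_mu, p$beams[[1]]$total_mu)
  for (k in 1:2) {
    expect_equal(p2$beams[[1]]$control_points[[k]]$bank_A,
                 p$beams[[1]]$control_points[[k]]$bank_A, tolerance = 1e-8)
    expect_equal(p2$beams[[1]]$control_points[[k]]$cumulative_meterset_weight,
                 p$beams[[1]]$control_points[[k]]$cumulative_meterset_weight,
                 tolerance = 1e-8)
  }
})

test_that("control points omitting static fields inherit from the previous", {
  p <- generate_plan(synth_plan_spec(n_control_points = 4,
                                     modulation_amplitude_mm = 0, seed = 1))
  full <- withr::local_tempfile(fileext = ".dcm")
  sparse <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_rtplan(p, full)
  write_dicom_rtplan(p, sparse, omit_repeated = TRUE)
  expect_lt(file.size(sparse), file.size(full))
  pf <- read_dicom_rtplan(full)
  ps <- read_dicom_rtplan(sparse)
  for (k in seq_along(pf$beams[[1]]$control_points)) {
    expect_equal(ps$beams[[1]]$control_points[[k]],
                 pf$beams[[1]]$control_points[[k]])
  }
})

test_that("DICOM and JSON readers agree on equivalent content", {
  p <- generate_plan(synth_plan_spec(n_control_points = 3,
                                     modulation_amplitude_mm = 3, seed = 7))
  dcm <- withr::local_tempfile(fileext = ".dcm")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_dicom_rtplan(p, dcm)
  write_plan_json(p, jsn)
  pd <- read_dicom_rtplan(dcm)
  pj <- read_plan_json(jsn)
  for (k in seq_along(pj$beams[[1]]$control_points)) {
    cpd <- pd$beams[[1]]$control_points[[k]]
    cpj <- pj$beams[[1]]$control_points[[k]]
    expect_equal(cpd$bank_A, cpj$bank_A, tolerance = 1e-8)
    expect_equal(cpd$bank_B, cpj$bank_B, tolerance = 1e-8)
    expect_equal(cpd$gantry_angle, cpj$gantry_angle, tolerance = 1e-8)
    expect_equal(cpd$cumulative_meterset_weight,
                 cpj$cumulative_meterset_weight, tolerance = 1e-8)
  }
})

test_that("non-RT-Plan DICOM input is rejected as a format error", {
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 200)), path)
  expect_error(read_dicom_rtplan(path), "not a DICOM file")
})

test_that("pydicom independently parses and regenerates our DICOM files", {
  p <- generate_plan(synth_plan_spec(n_control_points = 2,
                                     modulation_amplitude_mm = 2, seed = 21))
  ours <- withr::local_tempfile(fileext = ".dcm")
  theirs_expl <- withr::local_tempfile(fileext = ".dcm")
  theirs_impl <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_rtplan(p, ours)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pydicom",
    "from pydicom.uid import ImplicitVRLittleEndian",
    "src, dst_e, dst_i = sys.argv[1:4]",
    "ds = pydicom.dcmread(src)",
    "assert ds.SOPClassUID == '1.2.840.10008.5.1.4.1.1.481.5'",
    "b = ds.BeamSequence[0]",
    "print(float(b.ControlPointSequence[1].CumulativeMetersetWeight))",
    "print(float(ds.FractionGroupSequence[0]",
    "      .ReferencedBeamSequence[0].BeamMeterset))",
    "print(float(b.ControlPointSequence[0]",
    "      .BeamLimitingDevicePositionSequence[2].LeafJawPositions[30]))",
    "ds.save_as(dst_e, write_like_original=False)",
    "ds.file_meta.TransferSyntaxUID = ImplicitVRLittleEndian",
    "ds.is_implicit_VR = True",
    "ds.save_as(dst_i, write_like_original=False)"
  ), script)
  out <- system2("python", c(script, ours, theirs_expl, theirs_impl),
                 stdout = TRUE)
  vals <- as.numeric(out)
  cp0 <- p$beams[[1]]$control_points[[1]]
  expect_equal(vals[1], 1, tolerance = 1e-8)             # weight of CP 1
  expect_equal(vals[2], p$beams[[1]]$total_mu)
  expect_equal(vals[3], cp0$bank_A[31], tolerance = 1e-8)
  # our reader must parse the pydicom-written files (both transfer syntaxes)
  for (f in c(theirs_expl, theirs_impl)) {
    p2 <- read_dicom_rtplan(f)
    expect_equal(p2$beams[[1]]$control_points[[2]]$bank_B,
                 p$beams[[1]]$control_points[[2]]$bank_B, tolerance = 1e-8)
  }
})
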