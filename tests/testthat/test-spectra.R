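# PRM run I/O, XIC integration, annotation and identification.

test_that("spectrum and run constructors enforce their invariants", {
  expect_error(prm_spectrum(1, 500, c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(prm_spectrum(1, 500, c(2, 1), c(1, 1)), "increasing")
  expect_error(prm_spectrum(1, 500, c(1, 2), c(1, -1)), "non-negative")
  s1 <- prm_spectrum(2, 500, 100, 10, "a")
  s2 <- prm_spectrum(1, 500, 100, 10, "a")
  sched <- data.frame(channel = "a", precursor_mz = 500, rt_center = 1.5,
                      rt_half_width = 0.5)
  expect_error(prm_run(list(s1, s2), sched), "offending indices: 2")
  expect_error(prm_run(list(s2), data.frame(channel = "b", precursor_mz = 1,
                                            rt_center = 1, rt_half_width = 0.5)),
               "unknown channel")
})

test_that("the fixture-JSON dialect round-trips a run losslessly", {
  cfg <- synth_config(conc_ugl = c(PFOS = 5, PFHxA = 2), baseline_mean = 80,
                      baseline_sd = 20, area_cv = 0.02, mz_jitter_ppm = 0.5,
                      seed = 3)
  g <- generate_run(cfg, REG)
  p <- withr::local_tempfile(fileext = ".json")
  write_prm_run(g$run, p)
  r2 <- read_prm_run(p)
  expect_length(r2$spectra, length(g$run$spectra))
  for (i in c(1, 7, length(r2$spectra))) {
    expect_equal(r2$spectra[[i]]$mz, g$run$spectra[[i]]$mz, tolerance = 1e-12)
    expect_equal(r2$spectra[[i]]$intensity, g$run$spectra[[i]]$intensity,
                 tolerance = 1e-12)
    expect_identical(r2$spectra[[i]]$channel, g$run$spectra[[i]]$channel)
  }
  expect_equal(r2$schedule$precursor_mz, g$run$schedule$precursor_mz)
  expect_error(read_prm_run(withr::local_tempfile()), "not found")
})

test_that("an empty run is valid but downstream identification refuses it", {
  sched <- data.frame(channel = character(0), precursor_mz = numeric(0),
                      rt_center = numeric(0), rt_half_width = numeric(0))
  run <- prm_run(list(), sched)
  expect_s3_class(run, "prm_run")
  expect_error(identify_compounds(run, REG), "no spectra")
})

test_that("mzML files read into the same run structure (write-then-read oracle)", {
  skip_if_not_installed("mzR")
  pks <- list(cbind(mz = c(79.9574, 498.9302), intensity = c(1000, 400)),
              cbind(mz = c(79.9574, 498.9302), intensity = c(5000, 2000)),
              cbind(mz = c(79.9574, 498.9302), intensity = c(900, 350)))
  hdr <- data.frame(seqNum = 1:3, acquisitionNum = 1:3, msLevel = 2L,
    polarity = 0L, peaksCount = 2L, totIonCurrent = c(1400, 7000, 1250),
    retentionTime = c(526, 523, 520), basePeakMZ = 79.9574,
    basePeakIntensity = c(1000, 5000, 900), collisionEnergy = 38,
    ionisationEnergy = 0, lowMZ = 79, highMZ = 499, precursorScanNum = 0L,
    precursorMZ = 498.9302, precursorCharge = 1L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 50,
    filterString = NA_character_, spectrumId = paste0("scan=", 1:3),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = 498.9302, isolationWindowLowerOffset = 0.75,
    isolationWindowUpperOffset = 0.75, scanWindowLowerLimit = 79,
    scanWindowUpperLimit = 499)
  f <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(pks, f, header = hdr)
  run <- read_prm_run(f, dialect = "mzML")
  expect_length(run$spectra, 3)
  rts <- vapply(run$spectra, `[[`, numeric(1), "rt")
  expect_false(is.unsorted(rts))          # sorted even though written reversed
  expect_equal(run$spectra[[1]]$intensity, c(900, 350))   # the rt 520 s scan
  expect_equal(run$spectra[[3]]$intensity, c(1000, 400))  # the rt 526 s scan
  expect_equal(run$spectra[[1]]$mz, c(79.9574, 498.9302), tolerance = 1e-6)
  expect_equal(run$schedule$precursor_mz, 498.9302, tolerance = 1e-6)
})

test_that("XIC integration recovers a known Gaussian area within trapezoid error", {
  run <- gaussian_run(area = 1e5)
  x <- extract_xic(run, 512.960039, 468.970210, rt_range = c(8.55, 9.55))
  expect_true(x$found)
  expect_equal(x$area, 1e5, tolerance = 0.01)
  expect_equal(x$apex_rt, 9.05, tolerance = 1.5 / 60)
  expect_gte(x$n_points, 8)   # PRM design: > 8 data points per peak
  # linearity: scaling every intensity scales the area by the same factor
  run2 <- gaussian_run(area = 3.7e5)
  x2 <- extract_xic(run2, 512.960039, 468.970210, rt_range = c(8.55, 9.55))
  expect_equal(x2$area / x$area, 3.7, tolerance = 1e-6)
})

test_that("flat and empty traces are flagged, not errors", {
  run <- gaussian_run(area = 0)
  x <- extract_xic(run, 512.960039, 468.970210)
  expect_false(x$found)
  expect_equal(x$area, 0)
  # no spectra in the window at all
  x2 <- extract_xic(run, 512.960039, 468.970210, rt_range = c(2, 3))
  expect_true(x2$empty)
  expect_false(x2$found)
})

test_that("the larger of two resolved peaks is integrated; ties go to the earlier", {
  times <- seq(8.0, 9.0, by = 1.5 / 60)
  two <- function(h1, h2) {
    tr <- h1 * dnorm(times, 8.25, 0.05) + h2 * dnorm(times, 8.75, 0.05)
    spectra <- lapply(seq_along(times), function(i)
      prm_spectrum(times[i], 500, 200, tr[i], "c"))
    prm_run(spectra, data.frame(channel = "c", precursor_mz = 500,
                                rt_center = 8.5, rt_half_width = 0.5))
  }
  x <- extract_xic(two(1, 2), 500, 200)
  expect_equal(x$apex_rt, 8.75, tolerance = 0.03)
  x2 <- extract_xic(two(2, 1), 500, 200)
  expect_equal(x2$apex_rt, 8.25, tolerance = 0.03)
  xtie <- extract_xic(two(1, 1), 500, 200)
  expect_equal(xtie$apex_rt, 8.25, tolerance = 0.03)
})

test_that("annotation matches by smallest mass error and is input-order independent", {
  frags <- predict_fragments("PFDA", REG)
  mz <- sort(frags$mz)
  spec <- prm_spectrum(9.05, 512.960039, mz, seq_along(mz) * 10)
  ann <- annotate_spectrum(spec, frags, tol_ppm = 5)
  expect_equal(nrow(ann), nrow(frags))
  expect_true(all(abs(ann$delta_ppm) < 1e-9))
  # permuting the prediction table changes nothing
  ann2 <- annotate_spectrum(spec, frags[sample(nrow(frags)), ], tol_ppm = 5)
  expect_setequal(ann2$label, ann$label)
  # the documented pair: precursor + decarboxylation product at 5 ppm
  spec2 <- prm_spectrum(9.05, 512.960039, c(468.9701, 512.9600), c(100, 50))
  ann3 <- annotate_spectrum(spec2, frags, tol_ppm = 5)
  expect_setequal(ann3$label, c("[M-H]-", "[M-H-CO2]-"))
  # 21 ppm away from the nearest prediction: unannotated
  spec3 <- prm_spectrum(9.05, 512.960039, 468.9800, 100)
  expect_equal(nrow(annotate_spectrum(spec3, frags, tol_ppm = 5)), 0)
})

test_that("identification needs both the quantifier peak and a confirming fragment", {
  g <- generate_run(synth_config(conc_ugl = c(PFOS = 5), seed = 42), REG)
  id <- identify_compounds(g$run, REG)
  expect_identical(id$name[id$detected], "PFOS")
  expect_equal(sum(id$detected), 1)
  # blank channel: scheduled but signal-free
  blank <- generate_run(synth_config(conc_ugl = c(PFOS = 0), seed = 42), REG)
  idb <- identify_compounds(blank$run, REG)
  expect_equal(sum(idb$detected), 0)
  # quantifier-only run: strip every ion except the quantifier from spectra
  tr <- diagnostic_transition("PFOS", REG)
  stripped <- g$run
  stripped$spectra <- lapply(stripped$spectra, function(s) {
    keep <- abs(ppm_error(s$mz, tr$product_mz_theo)) <= 5
    prm_spectrum(s$rt, s$precursor_mz, s$mz[keep], s$intensity[keep], s$channel)
  })
  idq <- identify_compounds(stripped, REG)
  expect_false(idq$detected[idq$name == "PFOS"])
  expect_true(idq$quantifier_only[idq$name == "PFOS"])
})
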