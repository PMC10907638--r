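test_that("trace specs validate geometry and sampling", {
  expect_s3_class(synth_trace_spec(), "synth_trace_spec")
  expect_error(synth_trace_spec(apd50_ms = 400, apd80_ms = 380), "exceed")
  expect_error(synth_trace_spec(beat_rate_bpm = 120, apd80_ms = 600,
                                apd50_ms = 500), "period")
  expect_error(synth_trace_spec(duration_s = 0.5, fps = 50), "50 samples")
  ## repolarization span incompatible with the rise time
  expect_error(synth_trace_spec(beat_rate_bpm = 110, apd50_ms = 170,
                                apd80_ms = 289), "infeasible")
})

test_that("generated traces have the advertised size, seed determinism and truth", {
  sp <- synth_trace_spec(beat_rate_bpm = 60, duration_s = 8, fps = 50,
                         noise_sd = 0.03, seed = 7)
  tr <- synth_optical_trace(sp)
  expect_equal(nrow(tr), 400)
  expect_identical(tr$V_mV, synth_optical_trace(sp)$V_mV)
  sp2 <- synth_trace_spec(beat_rate_bpm = 60, noise_sd = 0.03, seed = 8)
  expect_false(identical(tr$V_mV, synth_optical_trace(sp2)$V_mV))
  truth <- trace_metadata(tr)$truth
  expect_equal(truth$apd50_ms, 300)
  expect_equal(truth$beat_rate_bpm, 60)
})

test_that("the noiseless pipeline recovers the closed-form biomarkers", {
  sp <- synth_trace_spec(beat_rate_bpm = 60, apd50_ms = 300, apd80_ms = 380,
                         noise_sd = 0, drift_per_s = 0)
  bm <- glance(biomarkers(synth_optical_trace(sp)))
  expect_lt(abs(bm$apd50_ms - 300), 10)
  expect_lt(abs(bm$apd80_ms - 380), 10)
  expect_lt(abs(bm$beat_rate_bpm - 60), 0.5)
})

test_that("a synthetic study has the full design grid with reproducible truth", {
  spec <- synth_study_spec(wells_per_arm = 4, seed = 7)
  st <- synth_study(spec)
  expect_equal(length(st$traces), 3 * 4 * 7)
  expect_equal(nrow(st$design), 84)
  expect_equal(nrow(st$truth), 84)
  ## same seed regenerates the identical study
  st2 <- synth_study(spec)
  expect_identical(st$truth, st2$truth)
  expect_identical(st$traces[[13]]$V_mV, st2$traces[[13]]$V_mV)
  ## control-arm truth is constant over time within each well
  ctrl <- dplyr::filter(st$truth, .data$arm == "control")
  spread <- dplyr::summarise(dplyr::group_by(ctrl, .data$well),
                             s = diff(range(.data$apd50_ms)))
  expect_true(all(spread$s < 1e-9))
})

test_that("study files round-trip through the on-disk layout", {
  td <- withr::local_tempdir()
  spec <- synth_study_spec(wells_per_arm = 2, seed = 3)
  st <- synth_study(spec, dir = td)
  expect_true(file.exists(file.path(td, "design.csv")))
  expect_true(file.exists(file.path(td, "truth.csv")))
  f <- file.path(td, st$design$file[[1]])
  expect_true(file.exists(f))
  back <- read_trace(f)
  expect_equal(back$V_mV, st$traces[[1]]$V_mV, tolerance = 1e-12)
})

test_that("the recovered study reproduces the drug arms' direction and recovery", {
  st <- synth_study(synth_study_spec(wells_per_arm = 4, seed = 7))
  tb <- biomarker_table(st$traces)
  des <- dplyr::mutate(st$design,
                       label = sprintf("%s/%s_%gh", arm, well, timepoint_h))
  j <- dplyr::inner_join(des, tb, by = "label")
  med <- dplyr::summarise(
    dplyr::group_by(j, .data$arm, .data$timepoint_h),
    apd50 = stats::median(.data$apd50_ms, na.rm = TRUE), .groups = "drop"
  )
  base <- function(a) med$apd50[med$arm == a & med$timepoint_h == 0]
  at <- function(a, t) med$apd50[med$arm == a & med$timepoint_h == t]
  ## low dose: suppressed at 2 h, recovering by 16 h
  expect_lt(at("0.1uM", 2), 0.8 * base("0.1uM"))
  expect_gt(at("0.1uM", 16), at("0.1uM", 2))
  expect_gt(at("0.1uM", 16), 0.9 * base("0.1uM"))
  ## high dose: still suppressed at 16 h
  expect_lt(at("1uM", 16), 0.8 * base("1uM"))
  ## control flat within noise
  expect_lt(abs(at("control", 16) - base("control")), 15)
})

test_that("effect curves can be taken from simulated block experiments", {
  tb <- tibble::tibble(
    timepoint_h = c(0, 2, 4), n = c(1, 2, 2.2),
    apd50_ms = c(260, 240, 255), apd80_ms = c(270, 250, 262),
    beat_rate_bpm = c(33, 35, 34), n_beats = 5L, flags = ""
  )
  fake <- structure(list(biomarker_table = tb), class = "block_experiment")
  ec <- effect_curves_from_block(list(`0.1uM` = fake))
  expect_setequal(unique(ec$arm), c("control", "0.1uM"))
  expect_equal(nrow(ec), 6)
  spec <- synth_study_spec(wells_per_arm = 2, arms = c("control", "0.1uM"),
                           timepoints_h = c(0, 2, 4),
                           effect_curves = ec, seed = 1)
  expect_s3_class(spec, "synth_study_spec")
  ## incomplete grids are rejected
  expect_error(synth_study_spec(effect_curves = ec), "grid")
})
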