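#' Specification of one synthetic optical voltage trace
#'
#' Describes an optical-style action-potential recording built from a
#' closed-form template: a half-cosine upstroke of configurable rise
#' time, a flat plateau, and a half-cosine repolarization whose span is
#' solved so that the template's APD50 and APD80 match the requested
#' values exactly (threshold crossings of the template are analytic).
#' Gaussian noise, a linear baseline drift, arbitrary amplitude/offset
#' and optional polarity inversion emulate optical recordings (8 s at
#' 50 frames per second by default).
#'
#' @param beat_rate_bpm Beat rate, beats per minute.
#' @param apd50_ms,apd80_ms Target action-potential durations, ms
#'   (`apd80_ms` must exceed `apd50_ms` and fit inside the beat period).
#' @param duration_s Recording length, s (default 8).
#' @param fps Sampling rate, frames per second (default 50).
#' @param noise_sd Additive Gaussian noise, as a fraction of amplitude.
#' @param drift_per_s Linear baseline drift, fraction of amplitude per
#'   second.
#' @param rise_ms Upstroke rise time, ms.
#' @param amplitude,baseline Output scale and offset (arbitrary units).
#' @param invert Flip polarity (upstrokes negative), as optical dyes may.
#' @param first_upstroke_ms Time of the first upstroke (max-slope point).
#' @param seed Integer seed for the noise.
#' @return An object of class `synth_trace_spec`.
#' @export
synth_trace_spec <- function(beat_rate_bpm = 60, apd50_ms = 300,
                             apd80_ms = 380, duration_s = 8, fps = 50,
                             noise_sd = 0, drift_per_s = 0, rise_ms = 20,
                             amplitude = 1, baseline = 0, invert = FALSE,
                             first_upstroke_ms = 150, seed = 1L) {
  spec <- list(beat_rate_bpm = beat_rate_bpm, apd50_ms = apd50_ms,
               apd80_ms = apd80_ms, duration_s = duration_s, fps = fps,
               noise_sd = noise_sd, drift_per_s = drift_per_s,
               rise_ms = rise_ms, amplitude = amplitude,
               baseline = baseline, invert = invert,
               first_upstroke_ms = first_upstroke_ms, seed = seed)
  validate_synth_trace_spec(spec)
  structure(spec, class = "synth_trace_spec")
}

validate_synth_trace_spec <- function(s) {
  if (s$beat_rate_bpm <= 0) stop("beat rate must be positive", call. = FALSE)
  period <- 60000 / s$beat_rate_bpm
  if (s$apd80_ms <= s$apd50_ms) {
    stop("apd80_ms must exceed apd50_ms", call. = FALSE)
  }
  if (s$apd80_ms >= period) {
    stop("apd80_ms must be shorter than the beat period (",
         round(period), " ms)", call. = FALSE)
  }
  if (s$fps * s$duration_s < 50) {
    stop("fps * duration must give at least 50 samples", call. = FALSE)
  }
  geom <- template_geometry(s)
  if (geom$t_rep <= 0 ||
      geom$t_plateau_end + geom$t_rep >= period - 10) {
    stop("infeasible template: APD values incompatible with rise time ",
         "and beat period", call. = FALSE)
  }
  if (geom$t_plateau_end < geom$t_plateau_start) {
    stop("infeasible template: repolarization would begin before the ",
         "upstroke ends; increase apd50_ms, narrow the APD50-APD80 gap ",
         "or decrease rise_ms", call. = FALSE)
  }
  invisible(s)
}

## Solve plateau end (tp) and repolarization span (Trep) so that the
## template's APD50/APD80 equal the requested values exactly.
## Template (relative time s from beat start, baseline 0, peak 1):
##   upstroke  [0, r]:        (1 - cos(pi s / r)) / 2
##   plateau   [r, tp]:       1
##   repol     [tp, tp+Trep]: (1 + cos(pi (s - tp) / Trep)) / 2
## Crossing of fraction f (level 1 - f):
##   rising  at r * acos(2 f - 1) / pi
##   falling at tp + Trep * acos(1 - 2 f) / pi
template_geometry <- function(s) {
  r <- s$rise_ms
  a <- function(f) acos(1 - 2 * f) / pi   # falling coefficient
  b <- function(f) acos(2 * f - 1) / pi   # rising coefficient
  k <- (a(0.8) - a(0.5))                  # == b(0.5) - b(0.8)
  t_rep <- (s$apd80_ms - s$apd50_ms) / k - r
  tp <- s$apd50_ms + r * b(0.5) - t_rep * a(0.5)
  list(t_plateau_start = r, t_plateau_end = tp, t_rep = t_rep,
       rising_coef = b, falling_coef = a)
}

## Evaluate the noiseless template at relative beat time s (vectorized).
template_value <- function(s_rel, rise, tp, t_rep) {
  v <- numeric(length(s_rel))
  i1 <- s_rel >= 0 & s_rel < rise
  v[i1] <- (1 - cos(pi * s_rel[i1] / rise)) / 2
  i2 <- s_rel >= rise & s_rel < tp
  v[i2] <- 1
  i3 <- s_rel >= tp & s_rel < tp + t_rep
  v[i3] <- (1 + cos(pi * (s_rel[i3] - tp) / t_rep)) / 2
  v
}

#' Generate a synthetic optical voltage trace with exact ground truth
#'
#' @param spec A [synth_trace_spec()].
#' @return A trace ([as_trace()]) whose `metadata` carries a `truth` list
#'   with the exact APD50, APD80, beat rate and upstroke times of the
#'   noiseless template.
#' @examples
#' tr <- synth_optical_trace(synth_trace_spec(beat_rate_bpm = 60))
#' trace_metadata(tr)$truth$apd50_ms
#' @export
synth_optical_trace <- function(spec) {
  stopifnot(inherits(spec, "synth_trace_spec"))
  s <- spec
  period <- 60000 / s$beat_rate_bpm
  geom <- template_geometry(s)
  n <- round(s$fps * s$duration_s)
  t <- (seq_len(n) - 1) * 1000 / s$fps
  beat_start0 <- s$first_upstroke_ms - s$rise_ms / 2
  s_rel <- (t - beat_start0) %% period
  s_rel[t < beat_start0] <- -1            # before the first beat: baseline
  v <- template_value(s_rel, geom$t_plateau_start, geom$t_plateau_end,
                      geom$t_rep)
  v <- v + s$drift_per_s * (t / 1000)
  if (s$noise_sd > 0) {
    v <- v + local_seed(s$seed, stats::rnorm(n, 0, s$noise_sd))
  }
  v <- s$baseline + s$amplitude * v
  if (s$invert) v <- -v
  ups <- seq(s$first_upstroke_ms, max(t), by = period)
  ups <- ups[ups <= max(t)]
  as_trace(
    tibble::tibble(time_ms = t, V_mV = v),
    metadata = list(
      source = "synthetic_optical",
      spec = unclass(s),
      truth = list(apd50_ms = s$apd50_ms, apd80_ms = s$apd80_ms,
                   beat_rate_bpm = s$beat_rate_bpm, upstroke_ms = ups)
    )
  )
}

## evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic drug-study dataset
#'
#' Emulates the structure of an optical drug study on cardiomyocyte
#' microtissues: per-well recordings (8 s at 50 fps) for a control arm
#' and two blocker doses, at baseline and 2, 4, 6, 8, 13 and 16 hours
#' after dosing, with well-level variability, noise and baseline drift,
#' plus tables of the generating ("truth") biomarkers.
#'
#' @param wells_per_arm Number of wells per study arm.
#' @param arms Arm labels; the default matches a control plus 0.1 uM and
#'   1 uM nifedipine design.
#' @param timepoints_h Recording times in hours; 0 is the pre-dose
#'   baseline.
#' @param effect_curves Per-arm biomarker trajectories: a tibble with
#'   columns `arm`, `timepoint_h`, `apd50_ms`, `apd80_ms`,
#'   `beat_rate_bpm`. Defaults to [default_effect_curves()], a
#'   parametric exponential-recovery family; curves exported from a
#'   model run can be supplied via [effect_curves_from_block()].
#' @param well_sd_frac Standard deviation of the per-well multiplicative
#'   random effect (applied to APDs and rate).
#' @param noise_sd,drift_per_s Per-trace noise and drift (see
#'   [synth_trace_spec()]).
#' @param duration_s,fps Recording geometry.
#' @param seed Integer master seed; the whole study is reproducible from
#'   it.
#' @return An object of class `synth_study_spec`.
#' @export
synth_study_spec <- function(wells_per_arm = 4,
                             arms = c("control", "0.1uM", "1uM"),
                             timepoints_h = c(0, 2, 4, 6, 8, 13, 16),
                             effect_curves = NULL,
                             well_sd_frac = 0.04,
                             noise_sd = 0.02, drift_per_s = 0.01,
                             duration_s = 8, fps = 50, seed = 1L) {
  if (wells_per_arm < 1) stop("need at least one well per arm", call. = FALSE)
  if (is.null(effect_curves)) {
    effect_curves <- default_effect_curves(arms, timepoints_h)
  }
  need <- c("arm", "timepoint_h", "apd50_ms", "apd80_ms", "beat_rate_bpm")
  if (!all(need %in% names(effect_curves))) {
    stop("effect_curves must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::expand_grid(arm = arms, timepoint_h = timepoints_h)
  if (nrow(dplyr::anti_join(grid, effect_curves,
                            by = c("arm", "timepoint_h"))) > 0) {
    stop("effect_curves must cover the full arm x timepoint grid",
         call. = FALSE)
  }
  structure(
    list(wells_per_arm = wells_per_arm, arms = arms,
         timepoints_h = timepoints_h, effect_curves = effect_curves,
         well_sd_frac = well_sd_frac, noise_sd = noise_sd,
         drift_per_s = drift_per_s, duration_s = duration_s, fps = fps,
         seed = as.integer(seed)),
    class = "synth_study_spec"
  )
}

#' Parametric per-arm biomarker trajectories
#'
#' The default effect curves of the synthetic study: the control arm is
#' flat; the blocker arms suppress APD50/APD80 and raise the beat rate
#' immediately after dosing, with an exponential return toward control
#' that is nearly complete for the low dose and leaves a residual
#' deficit for the high dose -- the qualitative time course of a
#' calcium-channel blocker whose efficacy wanes as channel expression
#' compensates.
#'
#' @param arms,timepoints_h As in [synth_study_spec()].
#' @param ctrl Named list of control biomarker values.
#' @return Tibble with columns `arm`, `timepoint_h`, `apd50_ms`,
#'   `apd80_ms`, `beat_rate_bpm`.
#' @export
default_effect_curves <- function(arms = c("control", "0.1uM", "1uM"),
                                  timepoints_h = c(0, 2, 4, 6, 8, 13, 16),
                                  ctrl = list(apd50_ms = 300,
                                              apd80_ms = 380,
                                              beat_rate_bpm = 45)) {
  suppression <- function(arm, t) {
    switch(arm,
      "control" = rep(0, length(t)),
      "0.1uM" = ifelse(t <= 0, 0, 0.35 * exp(-t / 5)),
      "1uM" = ifelse(t <= 0, 0, 0.30 + 0.40 * exp(-t / 4)),
      rep(0, length(t))
    )
  }
  purrr::map_dfr(arms, function(a) {
    s <- suppression(a, timepoints_h)
    tibble::tibble(
      arm = a, timepoint_h = timepoints_h,
      apd50_ms = ctrl$apd50_ms * (1 - s),
      apd80_ms = ctrl$apd80_ms * (1 - s),
      beat_rate_bpm = ctrl$beat_rate_bpm * (1 + 0.6 * s)
    )
  })
}

#' Effect curves taken from simulated drug-block experiments
#'
#' Converts the biomarker tables of [block_experiment()] runs into the
#' effect-curve format of [synth_study_spec()], so the synthetic study
#' can embody the regulated model's own predicted time course.
#'
#' @param blocks Named list of `block_experiment` objects; names are the
#'   arm labels.
#' @param control_label Label for the control arm (built from the
#'   pre-dose rows).
#' @return An effect-curve tibble.
#' @export
effect_curves_from_block <- function(blocks, control_label = "control") {
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  first <- blocks[[1]]$biomarker_table
  ctrl_row <- dplyr::filter(first, .data$timepoint_h == 0)
  tps <- sort(unique(first$timepoint_h))
  ctrl <- tibble::tibble(
    arm = control_label, timepoint_h = tps,
    apd50_ms = ctrl_row$apd50_ms, apd80_ms = ctrl_row$apd80_ms,
    beat_rate_bpm = ctrl_row$beat_rate_bpm
  )
  dosed <- purrr::imap_dfr(blocks, function(b, nm) {
    tb <- b$biomarker_table
    tb$apd50_ms[tb$timepoint_h == 0] <- ctrl_row$apd50_ms
    tb$apd80_ms[tb$timepoint_h == 0] <- ctrl_row$apd80_ms
    tb$beat_rate_bpm[tb$timepoint_h == 0] <- ctrl_row$beat_rate_bpm
    tibble::tibble(arm = nm, timepoint_h = tb$timepoint_h,
                   apd50_ms = tb$apd50_ms, apd80_ms = tb$apd80_ms,
                   beat_rate_bpm = tb$beat_rate_bpm)
  })
  dplyr::bind_rows(ctrl, dosed)
}

#' Generate a synthetic drug-study dataset
#'
#' Draws one trace per well and timepoint following the arm's effect
#' curve plus a per-well multiplicative random effect, and returns the
#' traces with their design and ground-truth biomarker tables. With
#' `dir` set, traces are also written as CSV files in the layout
#' `<dir>/<arm>/<well>_<timepoint>.csv` alongside `design.csv` and
#' `truth.csv`.
#'
#' @param spec A [synth_study_spec()].
#' @param dir Optional output directory.
#' @return A list of class `synth_study`: `traces` (named list),
#'   `design` and `truth` tibbles, and the spec.
#' @export
synth_study <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_study_spec"))
  wells <- sprintf("w%02d", seq_len(spec$wells_per_arm))
  grid <- tidyr::expand_grid(arm = spec$arms, well = wells,
                             timepoint_h = spec$timepoints_h)
  ## per-well random effects, one draw per arm x well, fixed across time
  wgrid <- tidyr::expand_grid(arm = spec$arms, well = wells)
  eff <- local_seed(spec$seed, {
    tibble::tibble(
      wgrid,
      apd_mult = pmax(0.6, stats::rnorm(nrow(wgrid), 1, spec$well_sd_frac)),
      rate_mult = pmax(0.6, stats::rnorm(nrow(wgrid), 1, spec$well_sd_frac))
    )
  })
  grid <- dplyr::left_join(grid, eff, by = c("arm", "well"))
  grid <- dplyr::left_join(grid, spec$effect_curves,
                           by = c("arm", "timepoint_h"))
  grid <- dplyr::mutate(
    grid,
    apd50_true = .data$apd50_ms * .data$apd_mult,
    apd80_true = .data$apd80_ms * .data$apd_mult,
    rate_true = .data$beat_rate_bpm * .data$rate_mult,
    trace_seed = spec$seed + seq_len(nrow(grid)),
    file = file.path(.data$arm, sprintf("%s_%gh.csv", .data$well,
                                        .data$timepoint_h)),
    id = sprintf("%s/%s_%gh", .data$arm, .data$well, .data$timepoint_h)
  )
  traces <- purrr::pmap(
    list(grid$apd50_true, grid$apd80_true, grid$rate_true,
         grid$trace_seed),
    function(a50, a80, rate, sd_) {
      synth_optical_trace(synth_trace_spec(
        beat_rate_bpm = rate, apd50_ms = a50, apd80_ms = a80,
        duration_s = spec$duration_s, fps = spec$fps,
        noise_sd = spec$noise_sd, drift_per_s = spec$drift_per_s,
        seed = sd_
      ))
    }
  )
  names(traces) <- grid$id
  design <- dplyr::select(grid, "arm", "well", "timepoint_h", "file",
                          "trace_seed")
  truth <- dplyr::select(grid, "arm", "well", "timepoint_h",
                         apd50_ms = "apd50_true", apd80_ms = "apd80_true",
                         beat_rate_bpm = "rate_true")
  if (!is.null(dir)) {
    for (i in seq_len(nrow(grid))) {
      path <- file.path(dir, grid$file[i])
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      write_trace(traces[[i]], path)
    }
    readr::write_csv(design, file.path(dir, "design.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  structure(list(traces = traces, design = design, truth = truth,
                 spec = spec),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study>", length(x$traces), "traces:",
      length(x$spec$arms), "arms x", x$spec$wells_per_arm, "wells x",
      length(x$spec$timepoints_h), "timepoints\n")
  invisible(x)
}
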