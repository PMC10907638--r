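#' Detect action-potential upstrokes in a voltage trace
#'
#' Excursions are defined by crossings of 50\% of the per-trace amplitude
#' (after polarity normalization and optional moving-average smoothing);
#' the upstroke time of each excursion is the time of maximal positive
#' finite-difference slope on its rising limb. Detections closer than the
#' refractory guard to the previous one are discarded. Works on model
#' traces (mV) and optical traces (arbitrary units, either polarity)
#' alike, because the trace is reduced to normalized amplitude first.
#'
#' @param trace A trace ([as_trace()]) with at least 10 samples.
#' @param smooth_n Moving-average window in samples; `NULL` picks 5 for
#'   optical-style sampling (intervals of 10 ms or more) and no smoothing
#'   for densely sampled model traces.
#' @param refractory_ms Minimum spacing between detections (default
#'   200 ms).
#' @param noise_mult Amplitude must exceed `noise_mult` times the robust
#'   sample-to-sample noise estimate (after any smoothing), otherwise the
#'   trace is declared quiescent.
#' @return Numeric vector of upstroke times (ms); empty with attribute
#'   `quiescent = TRUE` for flat traces.
#' @export
detect_beats <- function(trace, smooth_n = NULL, refractory_ms = 200,
                         noise_mult = 10) {
  stopifnot(is.data.frame(trace))
  if (nrow(trace) < 10) {
    stop("beat detection needs at least 10 samples", call. = FALSE)
  }
  t <- trace$time_ms
  ## quiescence is judged on the raw signal: smoothing both shrinks the
  ## amplitude and lets waveform slopes leak into the noise estimate
  v_raw <- normalize_voltage(trace$V_mV, smooth_n = 0)
  amp_raw <- max(v_raw) - min(v_raw)
  noise <- stats::mad(diff(v_raw)) / sqrt(2)
  if (amp_raw <= 0 || amp_raw < noise_mult * noise) {
    out <- numeric(0)
    attr(out, "quiescent") <- TRUE
    return(out)
  }
  v <- normalize_voltage(trace$V_mV, smooth_n = pick_smooth_n(t, smooth_n))
  amp <- max(v) - min(v)
  th <- min(v) + 0.5 * amp
  above <- v >= th
  rises <- which(diff(above) == 1)        # index i: crossing in (i, i+1)
  falls <- which(diff(above) == -1)
  ups <- numeric(0)
  for (r in rises) {
    f <- falls[falls > r]
    end <- if (length(f)) f[1] else length(v) - 1
    ## steepest rising interval from just before the crossing to excursion end
    lo <- max(1, r - 5)
    seg <- lo:min(end, length(v) - 1)
    sl <- (v[seg + 1] - v[seg]) / (t[seg + 1] - t[seg])
    k <- seg[which.max(sl)]
    ups <- c(ups, (t[k] + t[k + 1]) / 2)
  }
  if (length(ups) > 1) {
    keep <- c(TRUE, diff(ups) > refractory_ms)
    while (!all(keep)) {
      ups <- ups[keep]
      keep <- c(TRUE, diff(ups) > refractory_ms)
    }
  }
  attr(ups, "quiescent") <- FALSE
  ups
}

## Polarity-normalize (upstrokes positive) and optionally smooth; returns
## a unitless signal on the original time base. Inversion is declared
## only when two independent cues agree: the sharpest sample-to-sample
## transition points downward (upstrokes are usually the steepest edge)
## AND the signal dwells in the upper half of its range (APs dwell at
## the diastolic baseline). Requiring both keeps upright traces with an
## unusually steep repolarization or a high duty cycle unflipped.
normalize_voltage <- function(v, smooth_n = 0) {
  if (smooth_n > 1) {
    k <- rep(1 / smooth_n, smooth_n)
    v <- as.numeric(stats::filter(v, k, sides = 2))
    ## fill the ends left NA by the centred filter
    n <- length(v)
    half <- floor(smooth_n / 2)
    v[seq_len(half)] <- v[half + 1]
    v[(n - half + 1):n] <- v[n - half]
  }
  dv <- diff(v)
  slope_says_flip <- length(dv) > 0 && max(dv) < -min(dv)
  dwell_says_flip <- stats::median(v) > mean(range(v))
  if (slope_says_flip && dwell_says_flip) v <- -v
  v
}

pick_smooth_n <- function(t, smooth_n) {
  if (!is.null(smooth_n)) return(smooth_n)
  if (length(t) < 2) return(0)
  if (stats::median(diff(t)) >= 10) 5 else 0
}

#' Per-beat action-potential duration at an amplitude fraction
#'
#' For each upstroke, the beat's baseline is the minimum between
#' consecutive upstrokes (the last beat uses the trailing window) and the
#' peak the maximum after the upstroke. APD at fraction `f` is the time
#' between the rising and falling crossings of
#' `peak - f * (peak - baseline)`, located by linear interpolation
#' between samples. A beat whose falling crossing lies beyond the end of
#' the trace is dropped (returned as `NA` and flagged).
#'
#' @inheritParams detect_beats
#' @param upstrokes Upstroke times from [detect_beats()].
#' @param fraction Repolarization fraction in (0, 1); 0.5 gives APD50,
#'   0.8 APD80.
#' @return Numeric vector of per-beat durations (ms), `NA` for dropped
#'   beats, with attribute `dropped` (count).
#' @export
apd <- function(trace, upstrokes, fraction, smooth_n = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length(upstrokes) < 1) {
    stop("`apd` needs at least one upstroke", call. = FALSE)
  }
  t <- trace$time_ms
  ## crossings are interpolated on a lightly smoothed signal at optical
  ## sampling rates (3-sample window: noise reduction with negligible
  ## curvature bias); the wider detection smoothing would bias crossing
  ## times on the curved repolarization tail
  apd_smooth <- if (is.null(smooth_n)) {
    if (length(t) >= 2 && stats::median(diff(t)) >= 10) 3 else 0
  } else min(smooth_n, 3)
  v <- normalize_voltage(trace$V_mV, smooth_n = 0)
  ## falling crossings use a lightly smoothed copy (noise reduction on the
  ## shallow repolarization tail); rising crossings stay on the raw signal
  ## because smoothing smears the steep upstroke
  vs <- if (apd_smooth > 1) normalize_voltage(trace$V_mV,
                                              smooth_n = apd_smooth) else v
  nb <- length(upstrokes)
  out <- rep(NA_real_, nb)
  rising <- rep(NA_real_, nb)
  falling <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    up <- upstrokes[k]
    nxt <- if (k < nb) upstrokes[k + 1] else max(t) + 1
    win <- t >= up & t < nxt
    if (!any(win)) next
    ## peak and baseline from the smoothed copy: raw extremes inflate
    ## with the noise tails and bias the thresholds
    peak_i <- which(win)[which.max(vs[win])]
    peak <- vs[peak_i]
    prev_win <- t >= (if (k > 1) upstrokes[k - 1] else min(t)) & t < up
    baseline <- min(vs[win | prev_win])
    th <- peak - fraction * (peak - baseline)
    ## rising crossing: walk back from the peak to the last upward crossing
    ## within the upstroke window. Spontaneously depolarizing cells can
    ## pre-cross low thresholds on the diastolic ramp; in that case the
    ## upstroke (activation) time is the rising reference instead.
    lo_i <- max(1L, findInterval(up - 100, t))
    ri <- NA_real_
    if (peak_i - 1 >= lo_i) {
      for (i in seq(peak_i - 1, lo_i, by = -1L)) {
        if (v[i] < th && v[i + 1] >= th) {
          ri <- t[i] + (th - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
          break
        }
      }
    }
    if (is.na(ri) && v[lo_i] >= th) ri <- up
    ## falling crossing: walk forward from the peak on the smoothed copy
    fi <- NA_real_
    hi_i <- length(t) - 1
    i <- peak_i
    while (i <= hi_i) {
      if (vs[i] >= th && vs[i + 1] < th) {
        fi <- t[i] + (vs[i] - th) / (vs[i] - vs[i + 1]) * (t[i + 1] - t[i])
        break
      }
      i <- i + 1
    }
    rising[k] <- ri; falling[k] <- fi
    if (!is.na(ri) && !is.na(fi)) out[k] <- fi - ri
  }
  attr(out, "dropped") <- sum(is.na(out))
  attr(out, "rising_ms") <- rising
  attr(out, "falling_ms") <- falling
  out
}

#' Beat rate from upstroke times
#'
#' @param upstrokes Numeric vector of upstroke times, ms.
#' @return Beats per minute (`60000 / mean inter-upstroke interval`);
#'   `NA` with attribute `flag = "too_few_beats"` when fewer than two
#'   upstrokes are available.
#' @examples
#' beat_rate(c(0, 800, 1600, 2400)) # 75 bpm
#' @export
beat_rate <- function(upstrokes) {
  if (length(upstrokes) < 2) {
    out <- NA_real_
    attr(out, "flag") <- "too_few_beats"
    return(out)
  }
  60000 / mean(diff(upstrokes))
}

#' Extract the biomarker set of one trace
#'
#' Computes APD50, APD80 and beat rate with per-beat detail. The summary
#' statistic across beats is the median, which is robust to a clipped
#' first or last beat. Biomarkers are invariant to affine rescaling of
#' the voltage channel (optical traces carry arbitrary units).
#'
#' @inheritParams detect_beats
#' @param fractions Repolarization fractions to report (default 0.5 and
#'   0.8).
#' @return An object of class `biomarker_set`: summary values, per-beat
#'   tibble, beat count and quality flags. Use [generics::glance()] for a
#'   one-row summary and [generics::tidy()] for per-beat rows.
#' @export
biomarkers <- function(trace, fractions = c(0.5, 0.8), smooth_n = NULL,
                       refractory_ms = 200) {
  ups <- detect_beats(trace, smooth_n = smooth_n,
                      refractory_ms = refractory_ms)
  flags <- character(0)
  if (isTRUE(attr(ups, "quiescent"))) flags <- c(flags, "quiescent")
  per_beat <- tibble::tibble(beat = seq_along(ups), upstroke_ms = as.numeric(ups))
  vals <- list()
  ## process fractions in increasing order and keep the per-beat rising
  ## reference non-increasing across fractions, so APD at a deeper
  ## repolarization level can never undercut a shallower one when the
  ## diastolic-ramp fallback is in play
  rising_floor <- NULL
  for (f in sort(fractions)) {
    nm <- sprintf("apd%d_ms", round(100 * f))
    if (length(ups) >= 1) {
      d <- apd(trace, ups, f, smooth_n = smooth_n)
      ris <- attr(d, "rising_ms"); fal <- attr(d, "falling_ms")
      if (!is.null(rising_floor)) {
        ris <- pmin(ris, rising_floor, na.rm = TRUE)
        d2 <- fal - ris
        d <- ifelse(is.na(d), NA_real_, d2)
      }
      rising_floor <- ris
      per_beat[[nm]] <- as.numeric(d)
      vals[[nm]] <- stats::median(d, na.rm = TRUE)
      if (sum(is.na(d)) > 0) flags <- c(flags, paste0(nm, "_dropped_beats"))
    } else {
      vals[[nm]] <- NA_real_
    }
  }
  br <- beat_rate(ups)
  if (!is.null(attr(br, "flag"))) flags <- c(flags, attr(br, "flag"))
  structure(
    list(
      apd50_ms = vals[["apd50_ms"]] %||% NA_real_,
      apd80_ms = vals[["apd80_ms"]] %||% NA_real_,
      beat_rate_bpm = as.numeric(br),
      n_beats = length(ups),
      per_beat = per_beat,
      flags = unique(flags)
    ),
    class = "biomarker_set"
  )
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<biomarker_set>\n")
  cat(sprintf("  beats %d | APD50 %s ms | APD80 %s ms | rate %s bpm\n",
              x$n_beats, format(x$apd50_ms, digits = 4),
              format(x$apd80_ms, digits = 4),
              format(x$beat_rate_bpm, digits = 4)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
glance.biomarker_set <- function(x, ...) {
  tibble::tibble(
    apd50_ms = x$apd50_ms, apd80_ms = x$apd80_ms,
    beat_rate_bpm = x$beat_rate_bpm, n_beats = x$n_beats,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @export
tidy.biomarker_set <- function(x, ...) x$per_beat

#' Biomarker table over a set of traces
#'
#' @param traces Named list of traces; names become row labels.
#' @param ... Passed to [biomarkers()].
#' @return A tibble with one row per trace (ordered by label):
#'   `label`, `apd50_ms`, `apd80_ms`, `beat_rate_bpm`, `n_beats`,
#'   `flags`. Per-trace failures are recorded as flagged rows rather than
#'   aborting the table.
#' @export
biomarker_table <- function(traces, ...) {
  stopifnot(is.list(traces))
  labels <- names(traces)
  if (is.null(labels) || any(labels == "")) {
    stop("`traces` must be a fully named list", call. = FALSE)
  }
  rows <- purrr::map(sort(labels), function(lb) {
    res <- tryCatch(glance(biomarkers(traces[[lb]], ...)),
                    error = function(e) {
                      tibble::tibble(apd50_ms = NA_real_, apd80_ms = NA_real_,
                                     beat_rate_bpm = NA_real_, n_beats = 0L,
                                     flags = paste0("error: ",
                                                    conditionMessage(e)))
                    })
    dplyr::bind_cols(tibble::tibble(label = lb), res)
  })
  dplyr::bind_rows(rows)
}
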