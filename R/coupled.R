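#' Coupled simulation of channel-expression regulation and the beating cell
#'
#' Integrates the slow expression-regulation dynamics coupled to the
#' spontaneously beating cell model over minutes-to-hours of model time.
#' Two regulation variants are supported: the two-equation mRNA/protein
#' model (`"two_ode"`) and the bounded scalar model (`"bounded"`), and two
#' integration methods:
#'
#' * `"direct"` integrates the fully coupled stiff system with the
#'   instantaneous cytosolic calcium entering the regulation equations.
#'   Exact but slow; practical when the regulation time scale is
#'   compressed.
#' * `"averaged"` exploits the slow-fast gap (expression changes unfold
#'   over hours, one action potential lasts well under a second): it
#'   alternates short cell simulations at frozen channel count with
#'   explicit updates of the slow variables driven by the cycle-averaged
#'   calcium in place of the instantaneous one. The slow step adapts so
#'   the channel count moves by at most `dn_target` per step. The method
#'   refuses to run when the slow-fast precondition (per-cycle change in
#'   `n` below `precondition_dn`) is violated, advising direct
#'   integration instead.
#'
#' @param model A [cell_model()].
#' @param regulation `"two_ode"` or `"bounded"`.
#' @param params A [regulation_params()]; an unset `c_target_mM` is
#'   filled in with [compute_target_calcium()].
#' @param drug A [drug_block()] applied as a step at t = 0.
#' @param t_end_ms Simulation horizon, ms.
#' @param snapshot_times_h Times (hours, non-decreasing) at which a
#'   one-cycle voltage/calcium snapshot and window biomarkers are
#'   recorded.
#' @param method `"averaged"` (default) or `"direct"`.
#' @param initial List with components `m`, `n` (slow initial values) and
#'   optionally `state` (cell state). A missing `state` is equilibrated
#'   with [limit_cycle_init()] at `n` fixed and no drug, matching the
#'   protocol of starting experiments from a pre-run at the initial
#'   channel count.
#' @param dn_target Maximum change of `n` per averaged slow step.
#' @param relax_ms,window_ms Cell relaxation and averaging window of each
#'   averaged measurement, ms.
#' @param dt_slow_min_ms,dt_slow_max_ms Bounds on the adaptive slow step.
#' @param precondition_dn Per-cycle change of `n` above which the
#'   averaged method refuses to run.
#' @param dt_ms Dense output interval for cell integrations, ms.
#' @param rtol Relative solver tolerance.
#' @param calibrate_c_target Recompute the calcium setpoint with the
#'   averaged method's own measurement operator before the run (default
#'   `TRUE`). This cancels the small estimator bias between the
#'   setpoint and the in-loop cycle averages, so the no-drug fixed
#'   point sits at `n = 1` exactly rather than within estimator noise.
#' @return An object of class `coupled_sim` with the slow trajectory
#'   (tibble `slow`), snapshot traces, snapshot biomarkers, the calcium
#'   target and provenance. See [tidy.coupled_sim()] and
#'   [glance.coupled_sim()].
#' @export
simulate_coupled <- function(model,
                             regulation = c("bounded", "two_ode"),
                             params = regulation_params(),
                             drug = drug_block(0),
                             t_end_ms,
                             snapshot_times_h = numeric(),
                             method = c("averaged", "direct"),
                             initial = list(m = 1, n = 1, state = NULL),
                             dn_target = 0.08,
                             relax_ms = 6000, window_ms = 10000,
                             dt_slow_min_ms = 30000,
                             dt_slow_max_ms = 7.2e6,
                             precondition_dn = 0.01,
                             dt_ms = 2, rtol = 1e-6,
                             calibrate_c_target = TRUE) {
  regulation <- match.arg(regulation)
  method <- match.arg(method)
  stopifnot(inherits(model, "cell_model"), inherits(drug, "drug_block"))
  if (!is.numeric(t_end_ms) || t_end_ms <= 0) {
    stop("`t_end_ms` must be positive", call. = FALSE)
  }
  if (is.unsorted(snapshot_times_h, strictly = TRUE) &&
      length(snapshot_times_h) > 1) {
    stop("`snapshot_times_h` must be strictly increasing", call. = FALSE)
  }
  if (any(snapshot_times_h * 3.6e6 > t_end_ms + 1e-6)) {
    stop("snapshot times must lie within the horizon", call. = FALSE)
  }
  params <- fill_c_target(params, model)
  m0 <- initial$m %||% 1
  n0 <- initial$n %||% 1
  state0 <- initial$state
  if (is.null(state0)) {
    state0 <- limit_cycle_init(model, n_fixed = n0, drug = drug_block(0))
  }
  if (method == "direct") {
    coupled_direct(model, regulation, params, drug, t_end_ms,
                   snapshot_times_h, m0, n0, state0, dt_ms, rtol)
  } else {
    if (calibrate_c_target) {
      params$c_target_mM <- averaged_c_target(model, relax_ms, window_ms,
                                              dt_ms, rtol)
    }
    coupled_averaged(model, regulation, params, drug, t_end_ms,
                     snapshot_times_h, m0, n0, state0, dn_target,
                     relax_ms, window_ms, dt_slow_min_ms, dt_slow_max_ms,
                     precondition_dn, dt_ms, rtol)
  }
}

fill_c_target <- function(params, model) {
  if (is.na(params$c_target_mM)) {
    params$c_target_mM <- as.numeric(compute_target_calcium(model))
  }
  params
}

coupled_result <- function(slow, snapshots, snapshot_biomarkers, params,
                           regulation, method, drug, provenance) {
  structure(
    list(slow = slow, snapshots = snapshots,
         snapshot_biomarkers = snapshot_biomarkers,
         c_target_mM = params$c_target_mM, params = params,
         regulation = regulation, method = method, drug = drug,
         provenance = provenance),
    class = "coupled_sim"
  )
}

## ---- direct integration -------------------------------------------------

coupled_direct <- function(model, regulation, params, drug, t_end_ms,
                           snapshot_times_h, m0, n0, state0, dt_ms, rtol) {
  mode <- if (regulation == "two_ode") 1 else 2
  y0 <- c(unclass(state0)[model$state_names],
          if (mode == 1) c(m = m0, n = n0) else c(n = n0))
  parms <- hpcm_parms_vector(model, b_drug = drug$block_factor,
                             mode = mode, reg = params)
  atol <- state_atol(model,
                     extra = if (mode == 1) c(m = 1e-8, n = 1e-8)
                             else c(n = 1e-8))
  times <- seq(0, t_end_ms, by = dt_ms)
  out <- deSolve::ode(y = y0, times = times, parms = parms,
                      func = model$derivfunc, dllname = model$dll,
                      initfunc = model$initfunc, method = "bdf",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    stop("coupled integration failed near t = ", max(out[, 1]), " ms",
         call. = FALSE)
  }
  keep <- seq(1, nrow(out), by = max(1, floor(nrow(out) / 4000)))
  slow <- tibble::tibble(
    time_ms = out[keep, "time"],
    time_h = out[keep, "time"] / 3.6e6,
    m = if (mode == 1) out[keep, "m"] else NA_real_,
    n = out[keep, "n"],
    cbar_mM = NA_real_
  )
  snaps <- list(); snap_bm <- NULL
  for (th in snapshot_times_h) {
    t_target <- th * 3.6e6
    sel <- out[, "time"] >= max(0, t_target - 15000) &
      out[, "time"] <= min(t_end_ms, t_target + 15000)
    tr <- as_trace(tibble::tibble(time_ms = out[sel, "time"],
                                  V_mV = out[sel, "V"],
                                  c_mM = out[sel, "c"]))
    snaps[[format_h(th)]] <- cut_last_cycle(tr)
    bm <- glance(biomarkers(tr))
    n_at <- stats::approx(out[, "time"], out[, "n"], xout = t_target)$y
    snap_bm <- dplyr::bind_rows(
      snap_bm, dplyr::bind_cols(tibble::tibble(timepoint_h = th, n = n_at), bm)
    )
  }
  coupled_result(slow, snaps, snap_bm, params, regulation, "direct", drug,
                 list(rtol = rtol, dt_ms = dt_ms,
                      cdev_sup_mM = max(abs(params$c_target_mM -
                                              out[, "c"]))))
}

## ---- cycle-averaged accelerator ----------------------------------------

coupled_averaged <- function(model, regulation, params, drug, t_end_ms,
                             snapshot_times_h, m0, n0, state0, dn_target,
                             relax_ms, window_ms, dt_slow_min_ms,
                             dt_slow_max_ms, precondition_dn, dt_ms, rtol) {
  cstar <- params$c_target_mM
  snap_times_ms <- snapshot_times_h * 3.6e6
  t <- 0; m <- m0; n <- n0
  state <- unclass(state0)[model$state_names]
  slow_rows <- list(); snaps <- list(); snap_bm <- NULL
  max_steps <- 5000
  step <- 0
  repeat {
    step <- step + 1
    if (step > max_steps) stop("averaged method exceeded step budget",
                               call. = FALSE)
    meas <- measure_cycle_stats(model, n, drug, state, relax_ms, window_ms,
                                dt_ms, rtol)
    state <- meas$state_end
    cbar <- meas$cbar_mM
    ## slow rates at the current point, using cbar in place of c
    if (regulation == "two_ode") {
      rate_m <- (cstar - cbar) / params$tau_m_mM_ms
      rate_n <- (m - n) / params$tau_n_traffic_ms
      rate <- max(abs(rate_m), abs(rate_n) *
                    min(1, params$tau_n_traffic_ms / 1e5))
      rate_for_precond <- abs(rate_m) + abs(rate_n)
    } else {
      rate_m <- NA_real_
      rate_n <- bounded_scalar_rhs(n, cbar, params)
      rate <- abs(rate_n)
      rate_for_precond <- abs(rate_n)
    }
    cyc_ms <- if (is.finite(meas$rate_bpm) && meas$rate_bpm > 0) {
      60000 / meas$rate_bpm
    } else 2000
    if (rate_for_precond * cyc_ms > precondition_dn) {
      stop("slow-fast precondition violated (per-cycle change in n = ",
           format(rate_for_precond * cyc_ms, digits = 3),
           " > ", precondition_dn,
           "); use method = \"direct\" for this parameter regime",
           call. = FALSE)
    }
    slow_rows[[step]] <- tibble::tibble(
      time_ms = t, time_h = t / 3.6e6, m = m, n = n, cbar_mM = cbar
    )
    ## snapshot exactly at requested times (steps are cut to land on them)
    hit <- which(abs(snap_times_ms - t) < 1)
    if (length(hit)) {
      th <- snapshot_times_h[hit[1]]
      snaps[[format_h(th)]] <- cut_last_cycle(meas$trace)
      bm <- glance(biomarkers(meas$trace))
      snap_bm <- dplyr::bind_rows(
        snap_bm,
        dplyr::bind_cols(tibble::tibble(timepoint_h = th, n = n), bm)
      )
    }
    if (t >= t_end_ms - 1) break
    dt_slow <- if (rate > 0) dn_target / rate else dt_slow_max_ms
    dt_slow <- min(max(dt_slow, dt_slow_min_ms), dt_slow_max_ms)
    nxt <- snap_times_ms[snap_times_ms > t + 1]
    if (length(nxt)) dt_slow <- min(dt_slow, nxt[1] - t)
    dt_slow <- min(dt_slow, t_end_ms - t)
    ## explicit update of the slow variables over dt_slow with cbar frozen
    if (regulation == "two_ode") {
      a <- (cstar - cbar) / params$tau_m_mM_ms
      tau <- params$tau_n_traffic_ms
      m_new <- m + a * dt_slow
      n_new <- m_new - a * tau + (n - m + a * tau) * exp(-dt_slow / tau)
      m <- m_new; n <- n_new
    } else {
      sol <- deSolve::ode(
        y = c(n = n), times = c(0, dt_slow),
        func = function(tt, y, p) {
          list(bounded_scalar_rhs(y[1], cbar, params))
        },
        parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10
      )
      n <- unname(sol[nrow(sol), "n"])
    }
    t <- t + dt_slow
  }
  slow <- dplyr::bind_rows(slow_rows)
  coupled_result(slow, snaps, snap_bm, params, regulation, "averaged",
                 drug,
                 list(rtol = rtol, dt_ms = dt_ms, relax_ms = relax_ms,
                      window_ms = window_ms, dn_target = dn_target))
}

## The calcium setpoint as seen by the averaged method's own measurement
## operator (same relaxation and window), so that the regulated
## equilibrium sits exactly at the restored default current. Differs from
## compute_target_calcium() by well under 1%.
averaged_c_target <- function(model, relax_ms, window_ms, dt_ms, rtol) {
  key <- rlang::hash(list("avg_cstar", model$variant, model$pars, relax_ms,
                          window_ms, dt_ms, rtol))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  st <- limit_cycle_init(model, n_fixed = 1, drug = drug_block(0))
  ## run the measurement twice back-to-back and keep the second, so the
  ## setpoint carries the same warm-start state as in-loop measurements
  m1 <- measure_cycle_stats(model, 1, drug_block(0), st, relax_ms,
                            window_ms, dt_ms, rtol)
  m2 <- measure_cycle_stats(model, 1, drug_block(0), m1$state_end,
                            relax_ms, window_ms, dt_ms, rtol)
  cache_set(key, m2$cbar_mM)
}

## One averaged-method measurement: relax the cell at frozen n, then
## average calcium over complete cycles of the trailing window.
measure_cycle_stats <- function(model, n, drug, state, relax_ms, window_ms,
                                dt_ms = 2, rtol = 1e-6) {
  out <- hpcm_integrate(model, n, drug, relax_ms + window_ms, state,
                        dt_ms = dt_ms, rtol = rtol)
  sel <- out[, "time"] >= relax_ms
  tr <- as_trace(tibble::tibble(time_ms = out[sel, "time"] - relax_ms,
                                V_mV = out[sel, "V"], c_mM = out[sel, "c"]))
  cbar <- cycle_average_calcium(tr)
  ups <- detect_beats(tr)
  list(
    state_end = out[nrow(out), -1],
    trace = tr,
    cbar_mM = as.numeric(cbar),
    quiescent = isTRUE(attr(cbar, "quiescent")),
    rate_bpm = as.numeric(beat_rate(ups))
  )
}

## Last full upstroke-delimited cycle of a trace (falls back to the whole
## trace when fewer than two upstrokes exist), times re-zeroed.
cut_last_cycle <- function(trace) {
  ups <- detect_beats(trace)
  if (length(ups) >= 2) {
    a <- ups[length(ups) - 1]; b <- ups[length(ups)]
    sel <- trace$time_ms >= a & trace$time_ms <= b
    out <- trace[sel, ]
    out$time_ms <- out$time_ms - out$time_ms[1]
    as_trace(out, metadata = trace_metadata(trace))
  } else {
    trace
  }
}

format_h <- function(h) sprintf("%gh", h)

#' @export
print.coupled_sim <- function(x, ...) {
  cat("<coupled_sim>", x$regulation, "regulation,", x$method, "method\n")
  cat(sprintf("  drug b = %g | c* = %s mM\n", x$drug$block_factor,
              format(x$c_target_mM, digits = 5)))
  fin <- x$slow[nrow(x$slow), ]
  cat(sprintf("  horizon %.2f h | final n = %.4f\n", fin$time_h, fin$n))
  if (length(x$snapshots)) {
    cat("  snapshots:", paste(names(x$snapshots), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy the slow trajectory of a coupled simulation
#'
#' @param x A `coupled_sim`.
#' @param ... Unused.
#' @return Tibble with columns `time_ms`, `time_h`, `m`, `n`, `cbar_mM`.
#' @export
tidy.coupled_sim <- function(x, ...) x$slow

#' One-row summary of a coupled simulation
#'
#' @param x A `coupled_sim`.
#' @param ... Unused.
#' @return Tibble with the final slow state and run descriptors.
#' @export
glance.coupled_sim <- function(x, ...) {
  fin <- x$slow[nrow(x$slow), ]
  tibble::tibble(
    regulation = x$regulation, method = x$method,
    block_factor = x$drug$block_factor,
    t_end_h = fin$time_h, n_final = fin$n,
    m_final = fin$m, c_target_mM = x$c_target_mM,
    n_steps = nrow(x$slow)
  )
}

#' Plot the slow trajectory of a coupled simulation
#'
#' @param object A `coupled_sim`.
#' @param ... Unused.
#' @return A ggplot of m(t) and n(t) over hours.
#' @export
autoplot.coupled_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$slow, cols = c("m", "n"),
                            names_to = "variable", values_to = "value")
  df <- dplyr::filter(df, !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "relative expression",
                  colour = NULL)
}

## ---- drug-block experiment ----------------------------------------------

#' Calcium-channel-blocker experiment with expression regulation
#'
#' Applies a blocker dose as a step at t = 0 from the equilibrated default
#' limit cycle (`n = 1`), integrates the regulated model over the study
#' horizon, and reports one-cycle snapshots plus APD50, APD80 and beat
#' rate at each requested timepoint together with a pre-dose control row.
#'
#' @inheritParams simulate_coupled
#' @param dose `"0.1uM"`, `"1uM"`, a numeric dose in uM known to
#'   [drug_block()], or a `drug_block` object for an explicit block
#'   factor.
#' @param timepoints_h Sampling times after dosing, hours.
#' @param ... Passed to [simulate_coupled()].
#' @return An object of class `block_experiment`: the biomarker table
#'   (control plus one row per timepoint), the underlying `coupled_sim`,
#'   and the control snapshot trace.
#' @export
block_experiment <- function(model,
                             params = regulation_params(),
                             dose = "0.1uM",
                             timepoints_h = c(2, 4, 6, 8, 13, 16),
                             regulation = "bounded",
                             method = "averaged",
                             ...) {
  drug <- parse_dose(dose)
  params <- fill_c_target(params, model)
  ## pre-dose control measurement at the default limit cycle
  st0 <- limit_cycle_init(model, n_fixed = 1, drug = drug_block(0))
  ctrl <- measure_cycle_stats(model, 1, drug_block(0), st0,
                              relax_ms = 2000, window_ms = 10000)
  ctrl_row <- dplyr::bind_cols(
    tibble::tibble(timepoint_h = 0, n = 1),
    glance(biomarkers(ctrl$trace))
  )
  sim <- simulate_coupled(
    model, regulation = regulation, params = params, drug = drug,
    t_end_ms = max(timepoints_h) * 3.6e6,
    snapshot_times_h = timepoints_h, method = method,
    initial = list(m = 1, n = 1, state = st0), ...
  )
  table <- dplyr::bind_rows(ctrl_row, sim$snapshot_biomarkers)
  structure(
    list(biomarker_table = table, sim = sim, dose = dose, drug = drug,
         control_trace = cut_last_cycle(ctrl$trace),
         control_cbar_mM = ctrl$cbar_mM),
    class = "block_experiment"
  )
}

parse_dose <- function(dose) {
  if (inherits(dose, "drug_block")) return(dose)
  if (is.character(dose)) {
    key <- tolower(gsub("\\s", "", dose))
    if (key %in% c("0.1um", "0.1")) return(drug_block(0.1))
    if (key %in% c("1um", "1")) return(drug_block(1))
    stop("unknown dose label '", dose,
         "'; supply a drug_block() with an explicit block factor",
         call. = FALSE)
  }
  drug_block(dose)
}

#' @export
print.block_experiment <- function(x, ...) {
  cat("<block_experiment> dose", format(x$dose),
      sprintf("(b = %g)\n", x$drug$block_factor))
  print(x$biomarker_table, n = Inf)
  invisible(x)
}

#' @export
tidy.block_experiment <- function(x, ...) x$biomarker_table

#' @export
glance.block_experiment <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(dose = format(x$dose)), glance(x$sim))
}

#' Plot a drug-block experiment
#'
#' @param object A `block_experiment`.
#' @param ... Unused.
#' @return A ggplot of APD50, APD80 and beat rate over the study
#'   timepoints; the dashed line marks the pre-dose control value.
#' @export
autoplot.block_experiment <- function(object, ...) {
  tb <- object$biomarker_table
  long <- tidyr::pivot_longer(
    tb, cols = c("apd50_ms", "apd80_ms", "beat_rate_bpm"),
    names_to = "biomarker", values_to = "value"
  )
  ctrl <- dplyr::filter(long, .data$timepoint_h == 0)
  ggplot2::ggplot(dplyr::filter(long, .data$timepoint_h > 0),
                  ggplot2::aes(x = .data$timepoint_h, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(data = ctrl,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~biomarker, scales = "free_y") +
    ggplot2::labs(x = "time after dose (h)", y = NULL)
}
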