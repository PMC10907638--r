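#' Read a voltage/calcium trace from CSV
#'
#' Expects a header `time_ms,V_mV` with an optional `c_mM` column. The
#' written/read round trip is lossless to double precision.
#'
#' @param path CSV file path.
#' @return A trace ([as_trace()]).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  prb <- readr::problems(df)
  if (nrow(prb) > 0) {
    stop("malformed trace file ", path, ": expected ", prb$expected[1],
         " at line ", prb$row[1], call. = FALSE)
  }
  if (!all(c("time_ms", "V_mV") %in% names(df))) {
    stop("trace file must have header time_ms,V_mV[,c_mM]: ", path,
         call. = FALSE)
  }
  bad <- which(diff(df$time_ms) <= 0)
  if (length(bad)) {
    stop("non-increasing time in ", path, " at line ", bad[1] + 2,
         call. = FALSE)
  }
  keep <- intersect(c("time_ms", "V_mV", "c_mM"), names(df))
  as_trace(df[keep], metadata = list(source = path))
}

#' Write a trace to CSV (with optional JSON metadata sidecar)
#'
#' @param trace A trace.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` with the trace metadata.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = FALSE) {
  stopifnot(is.data.frame(trace))
  keep <- intersect(c("time_ms", "V_mV", "c_mM"), names(trace))
  readr::write_csv(tibble::as_tibble(trace)[keep], path)
  if (sidecar) {
    md <- trace_metadata(trace)
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

## ---- run configuration --------------------------------------------------

default_run_config <- function() {
  list(
    cell_model = list(
      variant = "hpcm1",
      scale_factors = list()
    ),
    regulation = list(
      tau_m_mM_ms = 400,
      tau_n_traffic_ms = 1000,
      tau_scalar_mM_ms = 400,
      c_target_mM = NA_real_,
      n_minus = 0.1,
      n_plus = 3,
      eps_n = 0.01,
      eps_c_mM = 1e-7
    ),
    drug = list(
      dose_table_uM = list(`0` = 1.0, `0.1` = 0.45, `1` = 0.12)
    ),
    solver = list(
      method = "bdf",
      rtol = 1e-6,
      atol_voltage = 1e-8,
      atol_calcium_mM = 1e-10
    ),
    experiment = list(
      horizon_h = 16,
      snapshot_times_h = c(2, 4, 6, 8, 13, 16),
      seed = 1L
    ),
    output = list(dir = ".")
  )
}

#' Load (and validate) a run configuration
#'
#' YAML configuration with sections `cell_model`, `regulation`, `drug`,
#' `solver`, `experiment` and `output`; keys carry their units in their
#' names (e.g. `tau_m_mM_ms`) so the two different time constants that
#' share a symbol in the literature cannot be confused. Missing sections
#' and keys take the package defaults; unknown sections or keys are
#' rejected by name. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      stop("unknown config section(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (sec in names(user)) {
      badkey <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badkey)) {
        stop("unknown key(s) in section `", sec, "`: ",
             paste(badkey, collapse = ", "), call. = FALSE)
      }
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  r <- cfg$regulation
  do.call(regulation_params, list(
    tau_m_mM_ms = r$tau_m_mM_ms,
    tau_n_traffic_ms = r$tau_n_traffic_ms,
    tau_scalar_mM_ms = r$tau_scalar_mM_ms,
    c_target_mM = if (is.null(r$c_target_mM)) NA_real_ else r$c_target_mM,
    n_minus = r$n_minus, n_plus = r$n_plus,
    eps_n = r$eps_n, eps_c_mM = r$eps_c_mM
  ))
  if (!is.numeric(cfg$solver$rtol) || cfg$solver$rtol <= 0) {
    stop("solver rtol must be positive", call. = FALSE)
  }
  bvals <- unlist(cfg$drug$dose_table_uM)
  if (any(bvals <= 0 | bvals > 1)) {
    stop("drug dose table entries must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Regulation parameters from a run configuration
#'
#' @param config A `run_config` from [load_config()].
#' @return A [regulation_params()].
#' @export
config_regulation_params <- function(config) {
  r <- config$regulation
  regulation_params(
    tau_m_mM_ms = r$tau_m_mM_ms,
    tau_n_traffic_ms = r$tau_n_traffic_ms,
    tau_scalar_mM_ms = r$tau_scalar_mM_ms,
    c_target_mM = if (is.null(r$c_target_mM)) NA_real_ else r$c_target_mM,
    n_minus = r$n_minus, n_plus = r$n_plus,
    eps_n = r$eps_n, eps_c_mM = r$eps_c_mM
  )
}
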