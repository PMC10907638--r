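#' Effect of a protein-density change on average cytosolic calcium
#'
#' Applies a multiplicative scale to one protein type's membrane density
#' at t = 0 from the default limit cycle, integrates for `settle_ms` with
#' the channel count fixed (no expression regulation), then averages the
#' cytosolic calcium by quadrature over the following `average_ms` and
#' reports the percent change relative to the default model's matching
#' average.
#'
#' @param model A [cell_model()].
#' @param protein A protein-type label from [protein_types()].
#' @param scale Multiplicative density factor (default 1.2, a 20\%
#'   increase).
#' @param settle_ms Equilibration after the parameter change, ms
#'   (default 1000 s).
#' @param average_ms Averaging window, ms (default 10 s).
#' @param reference Optional precomputed reference average (mM) for the
#'   default model under the same protocol; computed (and cached) when
#'   missing.
#' @param dt_ms,rtol Solver settings.
#' @return A one-row tibble: `protein`, `scale`, `cbar_mM`,
#'   `reference_mM`, `percent_change`, `quiescent`.
#' @export
perturb_and_measure <- function(model, protein, scale = 1.2,
                                settle_ms = 1e6, average_ms = 1e4,
                                reference = NULL, dt_ms = 2, rtol = 1e-6) {
  stopifnot(inherits(model, "cell_model"))
  if (!protein %in% protein_types(model)) {
    stop("unknown protein type '", protein, "'; available: ",
         paste(protein_types(model), collapse = ", "), call. = FALSE)
  }
  st0 <- limit_cycle_init(model, n_fixed = 1, drug = drug_block(0))
  if (is.null(reference)) {
    reference <- sensitivity_reference(model, settle_ms, average_ms,
                                       dt_ms, rtol, st0)
  }
  pert <- model
  pert$pars$scale[[protein]] <- model$pars$scale[[protein]] * scale
  res <- windowed_average(pert, st0, settle_ms, average_ms, dt_ms, rtol)
  tibble::tibble(
    protein = protein, scale = scale,
    cbar_mM = res$cbar, reference_mM = reference,
    percent_change = 100 * (res$cbar - reference) / reference,
    quiescent = res$quiescent
  )
}

## average calcium over [settle, settle + window] starting from state0
windowed_average <- function(model, state0, settle_ms, average_ms, dt_ms,
                             rtol) {
  out <- hpcm_integrate(model, 1, drug_block(0), settle_ms + average_ms,
                        state0, dt_ms = dt_ms, rtol = rtol)
  sel <- out[, "time"] >= settle_ms
  tr <- as_trace(tibble::tibble(time_ms = out[sel, "time"],
                                V_mV = out[sel, "V"], c_mM = out[sel, "c"]))
  val <- cycle_average_calcium(tr)
  list(cbar = as.numeric(val), quiescent = isTRUE(attr(val, "quiescent")))
}

sensitivity_reference <- function(model, settle_ms, average_ms, dt_ms,
                                  rtol, st0) {
  key <- rlang::hash(list("sens_ref", model$variant, model$pars, settle_ms,
                          average_ms, dt_ms, rtol))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  ref <- windowed_average(model, st0, settle_ms, average_ms, dt_ms, rtol)
  cache_set(key, ref$cbar)
}

#' Protein-type sensitivity panel
#'
#' Scales each protein type separately (keeping all others at their
#' default density) and reports the percent change of the average
#' cytosolic calcium concentration, with the default-model comparator
#' computed once and shared.
#'
#' @inheritParams perturb_and_measure
#' @param proteins Protein-type labels; default all types of the model.
#' @return A tibble of class `sensitivity_panel`, one row per protein.
#'   Per-protein errors are captured in an `error` column so the panel
#'   always completes.
#' @export
sensitivity_panel <- function(model, proteins = NULL, scale = 1.2,
                              settle_ms = 1e6, average_ms = 1e4,
                              dt_ms = 2, rtol = 1e-6) {
  stopifnot(inherits(model, "cell_model"))
  if (is.null(proteins)) proteins <- protein_types(model)
  if (length(proteins) == 0) {
    out <- tibble::tibble(protein = character(), scale = numeric(),
                          cbar_mM = numeric(), reference_mM = numeric(),
                          percent_change = numeric(), quiescent = logical(),
                          error = character())
    class(out) <- c("sensitivity_panel", class(out))
    return(out)
  }
  st0 <- limit_cycle_init(model, n_fixed = 1, drug = drug_block(0))
  reference <- sensitivity_reference(model, settle_ms, average_ms, dt_ms,
                                     rtol, st0)
  rows <- purrr::map(proteins, function(pr) {
    tryCatch(
      dplyr::mutate(
        perturb_and_measure(model, pr, scale = scale, settle_ms = settle_ms,
                            average_ms = average_ms, reference = reference,
                            dt_ms = dt_ms, rtol = rtol),
        error = NA_character_
      ),
      error = function(e) {
        tibble::tibble(protein = pr, scale = scale, cbar_mM = NA_real_,
                       reference_mM = reference, percent_change = NA_real_,
                       quiescent = NA, error = conditionMessage(e))
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_panel", class(out))
  out
}

#' Plot a sensitivity panel
#'
#' @param object A [sensitivity_panel()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of percent change in average cytosolic
#'   calcium per protein type.
#' @export
autoplot.sensitivity_panel <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      !is.na(.data$percent_change))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$protein, -.data$percent_change),
    y = .data$percent_change
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "average cytosolic calcium change (%)")
}
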