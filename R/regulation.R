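#' Parameters of the channel-expression regulation models
#'
#' Bundles the time scales, calcium target and bound/gate parameters shared
#' by the two-equation regulation model and its bounded scalar refinement.
#' Two distinct quantities are conventionally written with the same symbol
#' \eqn{\tau_n} but carry different units; they are kept apart here:
#' `tau_n_traffic_ms` (ms) is the protein-trafficking time scale of the
#' two-equation model, while `tau_scalar_mM_ms` (mM ms) is the time scale
#' of the bounded scalar model.
#'
#' @param tau_m_mM_ms Time scale of the mRNA equation, in mM ms. Default 400.
#' @param tau_n_traffic_ms Time scale of the protein equation of the
#'   two-equation model, in ms. Default 1000.
#' @param tau_scalar_mM_ms Time scale of the bounded scalar model, in mM ms.
#'   Default 400.
#' @param c_target_mM Target cytosolic calcium concentration \eqn{c^*} in mM,
#'   the cycle-averaged calcium of the default cell model. `NA` means "fill
#'   in later from a cell model" (see [compute_target_calcium()]).
#' @param n_minus Lower bound on the relative channel count. Default 0.1.
#' @param n_plus Upper bound on the relative channel count. Default 3.
#' @param eps_n Gate steepness in the n direction (dimensionless).
#'   Default 0.01.
#' @param eps_c_mM Gate steepness in the calcium direction, in mM.
#'   Default 1e-7.
#'
#' @return An object of class `regulation_params` (a validated named list).
#' @examples
#' regulation_params(c_target_mM = 2e-4)
#' @export
regulation_params <- function(tau_m_mM_ms = 400,
                              tau_n_traffic_ms = 1000,
                              tau_scalar_mM_ms = 400,
                              c_target_mM = NA_real_,
                              n_minus = 0.1,
                              n_plus = 3,
                              eps_n = 0.01,
                              eps_c_mM = 1e-7) {
  p <- list(
    tau_m_mM_ms = tau_m_mM_ms,
    tau_n_traffic_ms = tau_n_traffic_ms,
    tau_scalar_mM_ms = tau_scalar_mM_ms,
    c_target_mM = c_target_mM,
    n_minus = n_minus,
    n_plus = n_plus,
    eps_n = eps_n,
    eps_c_mM = eps_c_mM
  )
  validate_regulation_params(p)
  structure(p, class = "regulation_params")
}

validate_regulation_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1
  for (nm in c("tau_m_mM_ms", "tau_n_traffic_ms", "tau_scalar_mM_ms",
               "eps_n", "eps_c_mM")) {
    if (!num1(p[[nm]]) || !is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("regulation parameter `", nm, "` must be a strictly positive number",
           call. = FALSE)
    }
  }
  if (!num1(p$n_minus) || !num1(p$n_plus) ||
      !(p$n_minus > 0) || !(p$n_minus < p$n_plus)) {
    stop("bounds must satisfy 0 < n_minus < n_plus", call. = FALSE)
  }
  if (!num1(p$c_target_mM) ||
      (!is.na(p$c_target_mM) && p$c_target_mM <= 0)) {
    stop("c_target_mM must be a positive number (or NA to fill in later)",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.regulation_params <- function(x, ...) {
  cat("<regulation_params>\n")
  cat(sprintf("  tau_m            %g mM ms\n", x$tau_m_mM_ms))
  cat(sprintf("  tau_n (traffic)  %g ms\n", x$tau_n_traffic_ms))
  cat(sprintf("  tau   (scalar)   %g mM ms\n", x$tau_scalar_mM_ms))
  cat(sprintf("  c*               %s mM\n",
              ifelse(is.na(x$c_target_mM), "<unset>",
                     format(x$c_target_mM, digits = 5))))
  cat(sprintf("  n bounds         [%g, %g], eps_n %g, eps_c %g mM\n",
              x$n_minus, x$n_plus, x$eps_n, x$eps_c_mM))
  invisible(x)
}

needs_c_target <- function(params) {
  if (is.na(params$c_target_mM)) {
    stop("c_target_mM is unset; compute it with compute_target_calcium() ",
         "or supply it to regulation_params()", call. = FALSE)
  }
  params$c_target_mM
}

#' Smooth switching gate
#'
#' The elementary tanh gate
#' \deqn{h(a, b, \varepsilon) = \tfrac12\left(1 +
#'   \tanh\frac{a - b}{\varepsilon}\right),}
#' a smooth approximation of the indicator of \eqn{a > b}. It satisfies the
#' complement identity `sigmoid_gate(a, b, e) + sigmoid_gate(b, a, e) == 1`
#' exactly (tanh is odd).
#'
#' @param a,b Numeric vectors (recycled).
#' @param eps Strictly positive steepness; smaller values give a sharper
#'   switch.
#' @return Values in (0, 1).
#' @examples
#' sigmoid_gate(1, 1, 0.01) # 0.5
#' @export
sigmoid_gate <- function(a, b, eps) {
  if (!is.numeric(eps) || any(!is.finite(eps)) || any(eps <= 0)) {
    stop("`eps` must be strictly positive", call. = FALSE)
  }
  0.5 * (1 + tanh((a - b) / eps))
}

#' Expression gate of the bounded regulation model
#'
#' The gate
#' \deqn{H(c, n) = h(n, n_-, \varepsilon_n)\, h(c, c^*, \varepsilon_c) +
#'   h(n_+, n, \varepsilon_n)\, h(c^*, c, \varepsilon_c)}
#' equals 1 everywhere except that it falls to 0 where the regulation would
#' push the channel count out of \eqn{[n_-, n_+]}: when \eqn{n > n_+} and
#' \eqn{c < c^*} (growth demanded at the upper bound), and when
#' \eqn{n < n_-} and \eqn{c > c^*} (decay demanded at the lower bound).
#'
#' @param c Cytosolic calcium concentration, mM (vectorized).
#' @param n Relative channel count (vectorized).
#' @param params A [regulation_params()] with `c_target_mM` set.
#' @return Gate values in \[0, 1\].
#' @export
expression_gate <- function(c, n, params) {
  cstar <- needs_c_target(params)
  sigmoid_gate(n, params$n_minus, params$eps_n) *
    sigmoid_gate(c, cstar, params$eps_c_mM) +
    sigmoid_gate(params$n_plus, n, params$eps_n) *
    sigmoid_gate(cstar, c, params$eps_c_mM)
}

#' Right-hand side of the two-equation regulation model
#'
#' \deqn{\tau_m \, dm/dt = c^* - c, \qquad \tau_n \, dn/dt = m - n,}
#' where `m` and `n` are the relative mRNA and expressed-protein counts
#' (both 1 in the default cell) and `c` the instantaneous cytosolic calcium.
#'
#' @param m,n Relative mRNA and channel counts (vectorized).
#' @param c Cytosolic calcium, mM.
#' @inheritParams expression_gate
#' @return A list with components `dm_dt` and `dn_dt`, in 1/ms.
#' @export
two_ode_rhs <- function(m, n, c, params) {
  cstar <- needs_c_target(params)
  list(
    dm_dt = (cstar - c) / params$tau_m_mM_ms,
    dn_dt = (m - n) / params$tau_n_traffic_ms
  )
}

#' Right-hand side of the bounded scalar regulation model
#'
#' \deqn{\tau \, dn/dt = (c^* - c)\, H(c, n),}
#' the scalar reduction of the two-equation model with the expression gate
#' [expression_gate()] confining `n` to \eqn{[n_-, n_+]}.
#'
#' @inheritParams two_ode_rhs
#' @return `dn/dt` in 1/ms.
#' @export
bounded_scalar_rhs <- function(n, c, params) {
  cstar <- needs_c_target(params)
  (cstar - c) * expression_gate(c, n, params) / params$tau_scalar_mM_ms
}

#' Gronwall envelope for the mRNA/protein deviation
#'
#' Along any trajectory of the two-equation model the deviation
#' \eqn{p(t) = |m(t) - n(t)|} is bounded by
#' \deqn{p(t) \le e^{-t/\tau_n}\left(p(0) -
#'   \frac{\tau_n}{\tau_m}\,\sup|c^* - c|\right) +
#'   \frac{\tau_n}{\tau_m}\,\sup|c^* - c|,}
#' which tends to \eqn{(\tau_n/\tau_m)\,\sup|c^* - c|} as
#' \eqn{t \to \infty}. This is the estimate that justifies collapsing the
#' two equations to a scalar model in `n`.
#'
#' @param t Time since the initial condition, ms (vectorized,
#'   non-negative).
#' @param p0 Initial deviation `|m(0) - n(0)|`.
#' @param cdev_sup Supremum of `|c* - c|` along the trajectory, mM.
#' @inheritParams expression_gate
#' @return The envelope value (dimensionless).
#' @export
gronwall_bound <- function(t, p0, cdev_sup, params) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative", call. = FALSE)
  }
  if (any(cdev_sup < 0)) stop("`cdev_sup` must be non-negative", call. = FALSE)
  asym <- (params$tau_n_traffic_ms / params$tau_m_mM_ms) * cdev_sup
  exp(-t / params$tau_n_traffic_ms) * (p0 - asym) + asym
}

#' Predicted equilibrium channel count under single-channel block
#'
#' With a fraction `block_factor` = b of single-channel current remaining,
#' whole-cell L-type current is restored to its default strength exactly
#' when the product n b equals 1 -- the only way the cycle-averaged calcium
#' can reattain its target. The unbounded model therefore equilibrates at
#' n = 1/b; the bounded model saturates at `n_plus` if 1/b exceeds it.
#'
#' @param block_factor Single-channel scaling b in (0, 1\].
#' @param n_plus Upper channel-count bound (may be `Inf` for the unbounded
#'   model).
#' @return The predicted equilibrium `min(1/block_factor, n_plus)`.
#' @examples
#' predicted_equilibrium_n(0.1, Inf) # 10
#' predicted_equilibrium_n(0.1, 3)   # 3
#' @export
predicted_equilibrium_n <- function(block_factor, n_plus = Inf) {
  if (!is.numeric(block_factor) || any(block_factor <= 0) ||
      any(block_factor > 1)) {
    stop("`block_factor` must lie in (0, 1]", call. = FALSE)
  }
  pmin(1 / block_factor, n_plus)
}
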