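# Inverse problems at the resting (balanced) state: impermeant-osmolyte
# properties from electroneutrality + osmotic balance, and channel
# permeabilities from the three steady-state flux equations, which are
# linear in (pna, pk, pcl) once the resting potential is given.

#' A resting-state measurement
#'
#' Measured characteristics of cells equilibrated with a given medium:
#' intracellular concentrations, water content per unit impermeant osmolyte,
#' and the pump rate coefficient.
#'
#' @param na_i,k_i,cl_i Intracellular concentrations (mM), > 0.
#' @param v_over_a Cell water per unit A, V/A (ml/mmol), > 0.
#' @param beta Pump rate coefficient (min^-1).
#' @param medium The [medium()] the cells are balanced with.
#' @param osor_measured Optional measured OSOR (ouabain-sensitive to
#'   -resistant K+ influx ratio), kept for reference.
#' @return An object of class `pl_measurement`.
#' @examples
#' u937_measurement()
#' @export
resting_measurement <- function(na_i, k_i, cl_i, v_over_a, beta,
                                medium = medium_rpmi(),
                                osor_measured = NULL) {
  stopifnot(inherits(medium, "pl_medium"))
  m <- structure(list(
    na_i = check_scalar(na_i, "na_i", 0, strict = TRUE),
    k_i  = check_scalar(k_i,  "k_i",  0, strict = TRUE),
    cl_i = check_scalar(cl_i, "cl_i", 0, strict = TRUE),
    v_over_a = check_scalar(v_over_a, "v_over_a", 0, strict = TRUE),
    beta = check_scalar(beta, "beta", 0),
    medium = medium,
    osor_measured = if (is.null(osor_measured)) NULL
                    else check_scalar(osor_measured, "osor_measured", 0)),
    class = "pl_measurement")
  m
}

#' @export
print.pl_measurement <- function(x, ...) {
  cat(sprintf(
    "Resting measurement: [Na]i %g, [K]i %g, [Cl]i %g mM; V/A %g ml/mmol; beta %g min^-1\n",
    x$na_i, x$k_i, x$cl_i, x$v_over_a, x$beta))
  print(x$medium)
  invisible(x)
}

#' Impermeant-osmolyte properties from a resting measurement
#'
#' Inverts electroneutrality and osmotic balance for the concentration and
#' mean valence of the intracellular membrane-impermeant osmolytes:
#' `a_conc = osmolarity - (na_i + k_i + cl_i)` and
#' `z = (cl_i - na_i - k_i) / a_conc`.
#'
#' @param m A [resting_measurement()].
#' @return Named list with `z` (dimensionless) and `a_conc` (mM).
#' @examples
#' impermeant_properties(u937_measurement())   # z = -1.75, a_conc = 80
#' @export
impermeant_properties <- function(m) {
  stopifnot(inherits(m, "pl_measurement"))
  osm <- osmolarity(m$medium)
  a_conc <- osm - (m$na_i + m$k_i + m$cl_i)
  if (a_conc <= 0)
    stop_param(sprintf(
      "inconsistent measurement: internal ions (%g mM) reach or exceed medium osmolarity (%g mOsm)",
      m$na_i + m$k_i + m$cl_i, osm))
  list(z = (m$cl_i - m$na_i - m$k_i) / a_conc, a_conc = a_conc)
}

#' Channel permeabilities for a balanced resting state
#'
#' Given the cotransporter rate coefficients and the resting dimensionless
#' potential `u`, the three steady-state conditions dq/dt = 0 are linear in
#' the channel permeabilities and are solved directly:
#' each permeability equals the flux the channel must carry (balancing pump
#' and cotransport) divided by its GHK concentration factor.
#'
#' @inheritParams impermeant_properties
#' @param inc,ikc,inkcc Cotransporter rate coefficients (>= 0).
#' @param u Resting dimensionless membrane potential (non-zero).
#' @param gamma Pump stoichiometry, default 1.5.
#' @return A list with `pna`, `pk`, `pcl`, `feasible` (logical) and, when
#'   infeasible or indeterminate, `problem` naming the offending ion(s).
#'   A permeability is indeterminate (NA) when its channel carries no flux
#'   and its gradient term vanishes (e.g. Cl at Donnan equilibrium with no
#'   Cl-coupled cotransport).
#' @examples
#' fit_permeabilities(u937_measurement(), inc = 7e-5, ikc = 8e-5,
#'                    inkcc = 8e-9, u = -45/26.7)
#' @export
fit_permeabilities <- function(m, inc = 0, ikc = 0, inkcc = 0, u,
                               gamma = 1.5) {
  stopifnot(inherits(m, "pl_measurement"))
  u <- check_scalar(u, "u")
  if (u == 0) stop_param("'u' must be non-zero for the permeability fit")
  inc <- check_scalar(inc, "inc", 0); ikc <- check_scalar(ikc, "ikc", 0)
  inkcc <- check_scalar(inkcc, "inkcc", 0)
  gamma <- check_scalar(gamma, "gamma", 0, strict = TRUE)
  md <- m$medium
  jnc   <- inc   * (md$na0 * md$cl0 - m$na_i * m$cl_i)
  jkc   <- ikc   * (md$k0  * md$cl0 - m$k_i  * m$cl_i)
  jnkcc <- inkcc * (md$na0 * md$k0 * md$cl0^2 - m$na_i * m$k_i * m$cl_i^2)
  w <- u_over_g(u)
  # required channel net flux / per-unit-permeability GHK factor
  need <- c(na = m$beta * m$na_i - jnc - jnkcc,
            k  = -m$beta * m$na_i / gamma - jkc - jnkcc,
            cl = -jnc - jkc - 2 * jnkcc)
  fac <- c(na = w * (m$na_i * exp(u) - md$na0),
           k  = w * (m$k_i  * exp(u) - md$k0),
           cl = w * (m$cl_i - md$cl0 * exp(u)))
  p <- need / fac
  eps <- 1e-12
  indet <- abs(fac) < eps & abs(need) < eps
  p[indet] <- NA_real_
  neg <- !is.na(p) & p < 0
  feasible <- !any(neg) && !any(indet)
  problem <- NULL
  if (any(neg) || any(indet))
    problem <- names(p)[neg | indet]
  list(pna = unname(p["na"]), pk = unname(p["k"]), pcl = unname(p["cl"]),
       feasible = feasible, problem = problem)
}

#' Fit the pump-leak model to a resting measurement
#'
#' The central model constructor.  Given a resting measurement, an assigned
#' set of cotransporter rate coefficients and the resting membrane potential,
#' it (i) recovers the impermeant-osmolyte concentration and mean valence
#' from electroneutrality and osmotic balance, (ii) solves the three linear
#' steady-state equations for the channel permeabilities, and (iii) packages
#' the resulting state, medium and parameters as a fitted model object.  The
#' fitted state is an exact fixed point of the dynamics (up to the potential
#' solver tolerance).
#'
#' @param measurement A [resting_measurement()].
#' @param inc,ikc,inkcc Cotransporter rate coefficients.
#' @param U Resting membrane potential (mV); converted to `u = U/26.7`.
#' @param gamma Pump stoichiometry, default 1.5 (3Na:2K).
#' @param kb Linear pump-decay coefficient (min^-1), default 0.
#' @return An object of class `pump_leak` with components `measurement`,
#'   `params` ([transport_params()]), `medium`, `state` ([cell_state()]),
#'   `z`, `a_conc`, `u`, `U`, `fit` (the [fit_permeabilities()] result).
#'   Supported methods: `print`, `summary`, `coef`, `residuals`, `predict`,
#'   `simulate`, `plot`.
#' @examples
#' mod <- fit_pump_leak(u937_measurement(), inc = 7e-5, ikc = 8e-5,
#'                      inkcc = 8e-9, U = -45.0)
#' coef(mod)
#' @export
fit_pump_leak <- function(measurement, inc = 0, ikc = 0, inkcc = 0, U,
                          gamma = 1.5, kb = 0) {
  stopifnot(inherits(measurement, "pl_measurement"))
  U <- check_scalar(U, "U")
  u <- U / RTF_MV
  imp <- impermeant_properties(measurement)
  fit <- fit_permeabilities(measurement, inc = inc, ikc = ikc,
                            inkcc = inkcc, u = u, gamma = gamma)
  if (!fit$feasible)
    stop_param("permeability fit infeasible for ion(s): ",
               paste(fit$problem, collapse = ", "))
  params <- transport_params(fit$pna, fit$pk, fit$pcl,
                             beta = measurement$beta, gamma = gamma,
                             inc = inc, ikc = ikc, inkcc = inkcc, kb = kb)
  state <- cell_state(na = measurement$na_i, k = measurement$k_i,
                      cl = measurement$cl_i, v = measurement$v_over_a,
                      z = imp$z, a = 1)
  structure(list(measurement = measurement, params = params,
                 medium = measurement$medium, state = state,
                 z = imp$z, a_conc = imp$a_conc, u = u, U = U, fit = fit),
            class = "pump_leak")
}

#' @export
print.pump_leak <- function(x, ...) {
  cat("Pump-leak cell model (balanced-state fit)\n")
  cat(sprintf("  resting U %.1f mV; z %.4g; [A] %.4g mM; V/A %.4g ml/mmol\n",
              x$U, x$z, x$a_conc, x$state$v))
  print(x$params)
  invisible(x)
}

#' @export
summary.pump_leak <- function(object, ...) {
  x <- object
  ft <- flux_table(x$state, x$params, x$medium)
  res <- structure(list(model = x, flux_table = ft,
                        osor = compute_osor(ft),
                        residuals = residuals(x),
                        potential = solve_potential(x$state, x$params,
                                                    x$medium)),
                   class = "summary.pump_leak")
  res
}

#' @export
print.summary.pump_leak <- function(x, ...) {
  print(x$model)
  cat(sprintf("  re-solved U %.2f mV; OSOR %.3f\n",
              x$potential$U, x$osor))
  cat(sprintf("  steady-state residuals (dq/dt): %.2e %.2e %.2e\n",
              x$residuals[1], x$residuals[2], x$residuals[3]))
  print(x$flux_table)
  invisible(x)
}

#' @export
coef.pump_leak <- function(object, ...) {
  p <- object$params
  c(pna = p$pna, pk = p$pk, pcl = p$pcl, beta = p$beta, gamma = p$gamma,
    inc = p$inc, ikc = p$ikc, inkcc = p$inkcc, kb = p$kb,
    z = object$z, a_conc = object$a_conc)
}

#' @export
residuals.pump_leak <- function(object, ...) {
  content_derivatives(object$state, object$params, object$medium,
                      u = object$u)
}

#' Predict the cell state in a new medium
#'
#' `type = "jump"` returns the immediate post-transition state (osmotic
#' re-equilibration at fixed contents); `type = "balanced"` integrates the
#' dynamics in the new medium, either for a fixed `duration` (min) or, when
#' `duration = NULL`, to flux equilibrium via [find_balanced_state()].
#'
#' @param object A fitted `pump_leak` model.
#' @param medium The new [medium()]; defaults to the fitting medium.
#' @param type `"balanced"` or `"jump"`.
#' @param duration Integration time (min) for `type = "balanced"`;
#'   `NULL` integrates to convergence.
#' @param multipliers Optional named parameter multipliers applied at the
#'   transition.
#' @param dt Integration step (min).
#' @param ... Unused.
#' @return A `pl_state`; for `type = "balanced"` with attributes `U` (mV,
#'   re-solved at the returned state), `t_end` and `balanced`.
#' @export
predict.pump_leak <- function(object, medium = object$medium,
                              type = c("balanced", "jump"),
                              duration = 240, multipliers = list(),
                              dt = 0.01, ...) {
  type <- match.arg(type)
  st <- apply_medium_jump(object$state, medium)
  if (type == "jump") return(st)
  params <- apply_multipliers(object$params, multipliers)
  if (is.null(duration)) {
    fb <- find_balanced_state(st, params, medium, dt = dt)
    out <- fb$state; t_end <- fb$t_end; bal <- fb$balanced
  } else {
    res <- run_core(st, params, medium, duration, dt,
                    record_every = max(1L, as.integer(round(duration / dt))))
    out <- core_state_at(res, length(res$t), st)
    t_end <- res$t_end; bal <- NA
  }
  attr(out, "U") <- solve_potential(out, params, medium)$U
  attr(out, "t_end") <- t_end
  attr(out, "balanced") <- bal
  out
}

#' Simulate trajectories from a fitted model
#'
#' A thin wrapper around [simulate_trajectory()] starting from the fitted
#' resting state.  The model is deterministic, so `nsim` and `seed` are
#' accepted for generic consistency only; `nsim > 1` returns identical
#' replicates.
#'
#' @param object A fitted `pump_leak` model.
#' @param nsim Number of (identical) trajectories.
#' @param seed Ignored (deterministic model).
#' @param protocol A [protocol_segment()] or list of them; default: 240 min
#'   in the fitting medium.
#' @param verbose Log segment events.
#' @param ... Unused.
#' @return A `pl_trajectory` (or a list of them when `nsim > 1`).
#' @export
simulate.pump_leak <- function(object, nsim = 1, seed = NULL,
                               protocol = protocol_segment(240),
                               verbose = FALSE, ...) {
  one <- simulate_trajectory(object$state, object$params, object$medium,
                             protocol, verbose = verbose)
  if (nsim == 1) one else replicate(nsim, one, simplify = FALSE)
}

#' @export
plot.pump_leak <- function(x, protocol = protocol_segment(240), ...) {
  plot(simulate.pump_leak(x, protocol = protocol), ...)
}
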