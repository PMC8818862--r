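# Zero-current closure: the membrane potential is not a dynamical variable
# but is pinned at every instant by the condition that channels plus pump
# carry zero net charge (cotransporters are electroneutral by stoichiometry).

#' Net charge flux through electrogenic pathways
#'
#' The summed charge flux at dimensionless potential `u`:
#' `J_Na,channel + J_K,channel - J_Cl,channel - beta*[Na]i*(1 - 1/gamma)`.
#' Cotransporters are excluded (they carry no net charge); the pump term is
#' the unbalanced 3Na:2K charge transfer.
#'
#' @param u Dimensionless membrane potential.
#' @param state A [cell_state()] object.
#' @param params A [transport_params()] object.
#' @param medium A [medium()] object.
#' @return Signed charge flux (umol min^-1 (ml cell water)^-1, positive
#'   outward-cation-deficit, i.e. positive means net positive charge enters).
#' @export
net_charge_flux <- function(u, state, params, medium) {
  stopifnot(inherits(state, "pl_state"), inherits(params, "pl_params"),
            inherits(medium, "pl_medium"))
  ci <- concentrations(state)
  vapply(u, function(ui) {
    jna <- channel_fluxes(params$pna, ui, ci[["na"]], medium$na0, +1)$net
    jk  <- channel_fluxes(params$pk,  ui, ci[["k"]],  medium$k0,  +1)$net
    jcl <- channel_fluxes(params$pcl, ui, ci[["cl"]], medium$cl0, -1)$net
    jna + jk - jcl - params$beta * ci[["na"]] * (1 - 1 / params$gamma)
  }, 0)
}

#' Solve the membrane potential from the zero-current condition
#'
#' Finds the root of [net_charge_flux()] in `u` with a guaranteed bracketing
#' (Brent) method.  The default bracket `u` in `[-10, +5]` spans `U` in
#' `[-267, +133]` mV, well beyond physiological potentials; if the charge
#' flux does not change sign over the bracket it is widened once by a factor
#' of two before failing.
#'
#' @inheritParams net_charge_flux
#' @param bracket Length-2 numeric search interval for `u`.
#' @param tol Convergence tolerance on `u`.
#' @return A list of class `pl_potential` with `u` (dimensionless), `U` (mV),
#'   `residual` (charge flux at the root) and `iterations`.
#' @examples
#' s <- cell_state(na = 38, k = 147, cl = 45, v = 12.5, z = -1.75)
#' p <- transport_params(0.0017, 0.0115, 0.011, beta = 0.039,
#'                       inc = 7e-5, ikc = 8e-5, inkcc = 8e-9)
#' solve_potential(s, p, medium_rpmi())$U   # about -45 mV
#' @export
solve_potential <- function(state, params, medium,
                            bracket = c(-10, 5), tol = 1e-12) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  f <- function(u) net_charge_flux(u, state, params, medium)
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {  # widen once about the centre
    mid <- (lo + hi) / 2; half <- (hi - lo)
    lo <- mid - half; hi <- mid + half
    flo <- f(lo); fhi <- f(hi)
    if (flo * fhi > 0)
      stop_param(sprintf(
        "no sign change of net charge flux over u in [%g, %g]: f = %g, %g",
        lo, hi, flo, fhi))
  }
  if (flo == 0) root <- list(root = lo, f.root = 0, iter = 0L)
  else if (fhi == 0) root <- list(root = hi, f.root = 0, iter = 0L)
  else root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                              tol = tol)
  structure(list(u = root$root, U = RTF_MV * root$root,
                 residual = root$f.root, iterations = root$iter),
            class = "pl_potential")
}

#' @export
print.pl_potential <- function(x, ...) {
  cat(sprintf("Membrane potential U = %.4f mV (u = %.6f), residual %.3g\n",
              x$U, x$u, x$residual))
  invisible(x)
}
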