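# Flux laws: GHK channel electrodiffusion, Na/K pump, cation-chloride
# cotransport; electrochemical potential differences and driving forces.
#
# All fluxes are in umol min^-1 (ml cell water)^-1.  Influxes are >= 0,
# effluxes <= 0, net = influx + efflux.

# u/(1 - e^u) with a 3-term series at the removable singularity u = 0:
# 1 - e^u = -u (1 + u/2 + u^2/6 + u^3/24 + ...), so
# u/(1-e^u) = -1/(1 + u/2 + u^2/6 + u^3/24).
u_over_g <- function(u) {
  small <- abs(u) < 1e-4
  out <- u
  out[small] <- -1 / (1 + u[small]/2 + u[small]^2/6 + u[small]^3/24)
  out[!small] <- u[!small] / (1 - exp(u[!small]))
  out
}

#' Channel (Goldman-Hodgkin-Katz) fluxes
#'
#' Electrodiffusive flux of a monovalent ion through its channel at
#' dimensionless membrane potential `u = U/26.7`.  For a cation the net flux
#' is `p*u*(ci*e^u - co)/g` with `g = 1 - e^u`; for an anion (valence -1) it
#' is `p*u*(ci - co*e^u)/g`.  The unidirectional decomposition assigns the
#' term proportional to the external concentration to the influx and the term
#' proportional to the internal concentration to the efflux.  At `u = 0` the
#' removable singularity is evaluated by series, giving `p*(ci - co)`.
#'
#' @param p Permeability rate coefficient (min^-1), >= 0.
#' @param u Dimensionless membrane potential.
#' @param ci,co Internal and external concentrations (mM), >= 0.
#' @param valence +1 for Na+/K+, -1 for Cl-.
#' @return Named list with `influx` (>= 0), `efflux` (<= 0) and
#'   `net = influx + efflux`.
#' @examples
#' channel_fluxes(0.0115, -45/26.7, 147, 5.8, +1)  # K+ at rest
#' @export
channel_fluxes <- function(p, u, ci, co, valence = +1) {
  p  <- check_scalar(p,  "p",  0)
  ci <- check_scalar(ci, "ci", 0)
  co <- check_scalar(co, "co", 0)
  u  <- check_scalar(u,  "u")
  if (!valence %in% c(-1, 1)) stop_param("'valence' must be +1 or -1")
  w <- u_over_g(u)  # u/g; negative for all real u
  if (valence == 1) {
    influx <- -p * w * co
    efflux <-  p * w * ci * exp(u)
  } else {
    influx <- -p * w * co * exp(u)
    efflux <-  p * w * ci
  }
  list(influx = influx, efflux = efflux, net = influx + efflux)
}

#' Na/K pump fluxes
#'
#' Pump-mediated Na efflux `-beta*[Na]i` and K influx `beta*[Na]i/gamma`.
#'
#' @param beta Pump rate coefficient (min^-1), >= 0.
#' @param nai Intracellular Na+ concentration (mM), >= 0.
#' @param gamma Na:K stoichiometry (> 0), default 1.5 (3Na:2K).
#' @return Named list with `na_efflux` (<= 0) and `k_influx` (>= 0).
#' @examples
#' pump_fluxes(0.039, 38)    # resting pump turnover
#' @export
pump_fluxes <- function(beta, nai, gamma = 1.5) {
  beta <- check_scalar(beta, "beta", 0)
  nai  <- check_scalar(nai, "nai", 0)
  gamma <- check_scalar(gamma, "gamma", 0, strict = TRUE)
  list(na_efflux = -beta * nai, k_influx = beta * nai / gamma)
}

#' Cation-chloride cotransporter fluxes
#'
#' Net fluxes through the electroneutral cotransporters,
#' `J_NC = inc*([Na]o[Cl]o - [Na]i[Cl]i)`,
#' `J_KC = ikc*([K]o[Cl]o - [K]i[Cl]i)` and
#' `J_NKCC = inkcc*([Na]o[K]o[Cl]o^2 - [Na]i[K]i[Cl]i^2)`,
#' decomposed into an influx (product of external concentrations) and an
#' efflux (product of internal concentrations).  Every ion carried by a
#' cotransporter moves with the same net flux; Cl- counts twice for NKCC.
#'
#' @param params A [transport_params()] object (only `inc`, `ikc`, `inkcc`
#'   are used).
#' @param medium A [medium()] object.
#' @param state A [cell_state()] object with `v > 0`.
#' @return Named list `nc`, `kc`, `nkcc`, each with `influx`, `efflux`, `net`.
#' @export
cotransporter_fluxes <- function(params, medium, state) {
  stopifnot(inherits(params, "pl_params"), inherits(medium, "pl_medium"),
            inherits(state, "pl_state"))
  ci <- concentrations(state)
  mk <- function(coef, ext, int) {
    influx <- coef * ext
    efflux <- -coef * int
    list(influx = influx, efflux = efflux, net = influx + efflux)
  }
  list(
    nc   = mk(params$inc,   medium$na0 * medium$cl0, ci[["na"]] * ci[["cl"]]),
    kc   = mk(params$ikc,   medium$k0  * medium$cl0, ci[["k"]]  * ci[["cl"]]),
    nkcc = mk(params$inkcc, medium$na0 * medium$k0 * medium$cl0^2,
              ci[["na"]] * ci[["k"]] * ci[["cl"]]^2))
}

#' Electrochemical potential differences and cotransporter driving forces
#'
#' Transmembrane electrochemical potential differences (mV),
#' `mu_na = 26.7*ln([Na]i/[Na]o) + U`, `mu_k = 26.7*ln([K]i/[K]o) + U`,
#' `mu_cl = 26.7*ln([Cl]i/[Cl]o) - U`, and the cotransporter driving forces
#' as the sums over carried ions: `mu_nc = mu_na + mu_cl`,
#' `mu_kc = mu_k + mu_cl`, `mu_nkcc = mu_na + mu_k + 2*mu_cl`.
#'
#' @param state A [cell_state()] object.
#' @param medium A [medium()] object.
#' @param U Membrane potential (mV).
#' @return Named vector `mu_na, mu_k, mu_cl, mu_nc, mu_kc, mu_nkcc` (mV).
#' @examples
#' s <- cell_state(na = 38, k = 147, cl = 45, v = 12.5, z = -1.75)
#' electrochemical_potentials(s, medium_rpmi(), U = -45)
#' @export
electrochemical_potentials <- function(state, medium, U) {
  stopifnot(inherits(state, "pl_state"), inherits(medium, "pl_medium"))
  U <- check_scalar(U, "U")
  ci <- concentrations(state)
  if (any(ci <= 0) || medium$na0 <= 0 || medium$k0 <= 0 || medium$cl0 <= 0)
    stop_param("electrochemical potentials need all six concentrations > 0")
  mu_na <- RTF_MV * log(ci[["na"]] / medium$na0) + U
  mu_k  <- RTF_MV * log(ci[["k"]]  / medium$k0)  + U
  mu_cl <- RTF_MV * log(ci[["cl"]] / medium$cl0) - U
  c(mu_na = mu_na, mu_k = mu_k, mu_cl = mu_cl,
    mu_nc = mu_na + mu_cl, mu_kc = mu_k + mu_cl,
    mu_nkcc = mu_na + mu_k + 2 * mu_cl)
}

#' Rates of change of cell ion contents
#'
#' The right-hand sides of the content ODEs: each derivative is `v` times the
#' sum of that ion's pathway net fluxes per ml cell water.  Na sums channel,
#' pump, NC and NKCC; K sums channel, pump, KC and NKCC; Cl sums channel, NC,
#' KC and twice NKCC.
#'
#' @inheritParams cotransporter_fluxes
#' @param u Dimensionless membrane potential (usually from
#'   [solve_potential()]).
#' @param t Time since the start of pump decay (min), used only when
#'   `params$kb > 0`.
#' @return Named vector `c(qna, qk, qcl)` of d(content)/dt
#'   (umol min^-1 (mmol A)^-1).
#' @export
content_derivatives <- function(state, params, medium, u, t = 0) {
  ft <- flux_table(state, params, medium, u = u, t = t)
  tot <- attr(ft, "total_net")
  state$v * c(qna = tot[["na"]], qk = tot[["k"]], qcl = tot[["cl"]])
}

#' Per-pathway flux decomposition
#'
#' Builds the full unidirectional/net flux decomposition for the three ions
#' across the five pathways (channel, pump, NC, KC, NKCC) at a given state,
#' in the layout of the worked flux tables.  If `u` is not supplied the
#' membrane potential is first solved from the zero-net-charge-flux
#' condition.
#'
#' @inheritParams content_derivatives
#' @param u Dimensionless membrane potential; solved if `NULL`.
#' @return A data frame of class `pl_fluxes` with columns `ion`, `pathway`,
#'   `influx`, `efflux`, `net`, and attributes `u`, `U` (mV), `mu` (the
#'   [electrochemical_potentials()] vector), `total_net` (named per-ion sum
#'   of pathway nets) and `osor`.
#' @examples
#' s <- cell_state(na = 38, k = 147, cl = 45, v = 12.5, z = -1.75)
#' p <- transport_params(0.0017, 0.0115, 0.011, beta = 0.039,
#'                       inc = 7e-5, ikc = 8e-5, inkcc = 8e-9)
#' flux_table(s, p, medium_rpmi())
#' @export
flux_table <- function(state, params, medium, u = NULL, t = 0) {
  stopifnot(inherits(state, "pl_state"), inherits(params, "pl_params"),
            inherits(medium, "pl_medium"))
  beta_t <- beta_at(params, t)
  if (is.null(u)) {
    p_eff <- params; p_eff$beta <- beta_t; p_eff$kb <- 0
    u <- solve_potential(state, p_eff, medium)$u
  }
  ci <- concentrations(state)
  ch_na <- channel_fluxes(params$pna, u, ci[["na"]], medium$na0, +1)
  ch_k  <- channel_fluxes(params$pk,  u, ci[["k"]],  medium$k0,  +1)
  ch_cl <- channel_fluxes(params$pcl, u, ci[["cl"]], medium$cl0, -1)
  pump  <- pump_fluxes(beta_t, ci[["na"]], params$gamma)
  co    <- cotransporter_fluxes(params, medium, state)

  zero <- list(influx = 0, efflux = 0, net = 0)
  pumpN <- list(influx = 0, efflux = pump$na_efflux, net = pump$na_efflux)
  pumpK <- list(influx = pump$k_influx, efflux = 0, net = pump$k_influx)
  dbl <- function(f) lapply(f, `*`, 2)

  rows <- list(
    k  = list(channel = ch_k,  pump = pumpK, kc = co$kc, nkcc = co$nkcc),
    na = list(channel = ch_na, pump = pumpN, nc = co$nc, nkcc = co$nkcc),
    cl = list(channel = ch_cl, nc = co$nc, kc = co$kc, nkcc = dbl(co$nkcc)))

  df <- do.call(rbind, lapply(names(rows), function(ion) {
    do.call(rbind, lapply(names(rows[[ion]]), function(pw) {
      f <- rows[[ion]][[pw]]
      data.frame(ion = ion, pathway = pw, influx = f$influx,
                 efflux = f$efflux, net = f$net, stringsAsFactors = FALSE)
    }))
  }))
  rownames(df) <- NULL
  total_net <- vapply(rows, function(r) sum(vapply(r, `[[`, 0, "net")), 0)
  mu <- if (all(ci > 0) && medium$na0 > 0 && medium$k0 > 0 && medium$cl0 > 0)
    electrochemical_potentials(state, medium, U = RTF_MV * u) else NULL
  structure(df, class = c("pl_fluxes", "data.frame"),
            u = u, U = RTF_MV * u, mu = mu, total_net = total_net,
            osor = osor_from_rows(df))
}

osor_from_rows <- function(df) {
  pump_in <- df$influx[df$ion == "k" & df$pathway == "pump"]
  passive <- sum(df$influx[df$ion == "k" & df$pathway != "pump"])
  if (passive == 0) {
    if (pump_in == 0) NA_real_ else Inf
  } else pump_in / passive
}

#' @export
print.pl_fluxes <- function(x, digits = 4, ...) {
  cat(sprintf("Flux decomposition at U = %.1f mV (u = %.4f)\n",
              attr(x, "U"), attr(x, "u")))
  df <- as.data.frame(x)
  df[c("influx", "efflux", "net")] <- lapply(df[c("influx", "efflux", "net")],
                                             round, digits)
  print(df, row.names = FALSE)
  tot <- attr(x, "total_net")
  cat(sprintf("Total net: Na %.4f, K %.4f, Cl %.4f; OSOR %.3g\n",
              tot[["na"]], tot[["k"]], tot[["cl"]], attr(x, "osor")))
  mu <- attr(x, "mu")
  if (!is.null(mu))
    cat(sprintf("mu (mV): Na %.1f, K %.1f, Cl %.1f | NC %.1f, KC %.1f, NKCC %.1f\n",
                mu[["mu_na"]], mu[["mu_k"]], mu[["mu_cl"]],
                mu[["mu_nc"]], mu[["mu_kc"]], mu[["mu_nkcc"]]))
  invisible(x)
}

#' Ouabain-sensitive to ouabain-resistant K+ influx ratio (OSOR)
#'
#' The ratio of pump-mediated K+ influx to the total passive K+ influx
#' (channel + KC + NKCC), the model counterpart of the experimental
#' ouabain-sensitive / ouabain-resistant Rb+ uptake ratio.
#'
#' @param ft A `pl_fluxes` table from [flux_table()].
#' @return A single number; `Inf` when all K+ influx is pump-mediated, `NA`
#'   when there is no K+ influx at all.
#' @export
compute_osor <- function(ft) {
  stopifnot(inherits(ft, "pl_fluxes"))
  osor_from_rows(as.data.frame(ft))
}
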