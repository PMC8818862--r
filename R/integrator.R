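# Time integration: medium jumps, single steps, protocols, trajectories,
# balanced-state search.  The inner loop (per-step zero-current solve plus
# explicit Euler/RK4 content update) is compiled; see src/integrate.cpp.

#' Instantaneous osmotic re-equilibration after a medium change
#'
#' Water moves much faster than ions, so a change of external osmolarity
#' re-equilibrates the cell water volume essentially instantaneously while
#' ion contents (and the impermeant osmolyte) are unchanged:
#' `v = (qna + qk + qcl + 1000*a) / osmolarity(new_medium)`.
#'
#' @param state A [cell_state()] object.
#' @param new_medium The [medium()] after the switch.
#' @return The post-jump `pl_state` (same contents, new `v`).
#' @examples
#' s <- cell_state(na = 38, k = 147, cl = 45, v = 12.5, z = -1.75)
#' apply_medium_jump(s, medium_nacl100())$v   # 7.60 ml/mmol
#' @export
apply_medium_jump <- function(state, new_medium) {
  stopifnot(inherits(state, "pl_state"), inherits(new_medium, "pl_medium"))
  osm <- osmolarity(new_medium)
  if (osm <= 0) stop_param("new medium osmolarity must be > 0")
  state$v <- (state$qna + state$qk + state$qcl + 1000 * state$a) / osm
  state
}

scheme_code <- function(scheme) {
  switch(match.arg(scheme, c("euler", "rk4")), euler = 0L, rk4 = 1L)
}

run_core <- function(state, params, medium, duration, dt, record_every,
                     stop_tol = 0, t0 = 0, scheme = "euler") {
  .pl_integrate_cpp(c(state$qna, state$qk, state$qcl), state$z, state$a,
                    params_vec(params), medium_vec(medium),
                    duration, dt, as.integer(record_every), stop_tol, t0,
                    scheme_code(scheme))
}

core_state_at <- function(res, i, template) {
  cell_state(qna = res$qna[i], qk = res$qk[i], qcl = res$qcl[i],
             v = res$v[i], z = template$z, a = template$a)
}

#' Advance the cell state by one integration step
#'
#' Solves the membrane potential, advances the ion contents by `dt` with the
#' chosen explicit scheme, and recomputes the water volume from osmotic
#' balance.
#'
#' @inheritParams apply_medium_jump
#' @param params A [transport_params()] object.
#' @param medium A [medium()] object.
#' @param t Time since the start of pump decay (min), used when `kb > 0`.
#' @param dt Step length (min).
#' @param scheme `"euler"` (default) or `"rk4"`.
#' @return The advanced `pl_state`.
#' @export
step_state <- function(state, params, medium, t = 0, dt = 0.01,
                       scheme = "euler") {
  stopifnot(inherits(state, "pl_state"), inherits(params, "pl_params"),
            inherits(medium, "pl_medium"))
  res <- run_core(state, params, medium, duration = dt, dt = dt,
                  record_every = 1L, t0 = t, scheme = scheme)
  core_state_at(res, length(res$t), state)
}

#' Protocol segments
#'
#' A protocol is an ordered list of segments; each segment optionally
#' switches the external medium (applied as an instantaneous osmotic jump),
#' applies multiplicative factors to named transport parameters at its start,
#' and then integrates for `duration` minutes with step `dt`, recording every
#' `hp`-th step (plus the post-jump state and the endpoint).
#'
#' @param duration Segment length (min), > 0.
#' @param medium Optional [medium()]; `NULL` keeps the current medium.
#' @param multipliers Named list/vector of factors (> 0) applied to
#'   parameters in [transport_params()] (e.g. `list(inc = 3)`); applied once
#'   at segment start and persisting into later segments.
#' @param dt Integration step (min).
#' @param hp Number of internal steps between recorded outputs.
#' @param scheme `"euler"` or `"rk4"`.
#' @return An object of class `pl_segment`.
#' @seealso [simulate_trajectory()]
#' @export
protocol_segment <- function(duration, medium = NULL, multipliers = list(),
                             dt = 0.01, hp = 100, scheme = "euler") {
  duration <- check_scalar(duration, "duration", 0, strict = TRUE)
  dt <- check_scalar(dt, "dt", 0, strict = TRUE)
  hp <- as.integer(check_scalar(hp, "hp", 1))
  if (!is.null(medium)) stopifnot(inherits(medium, "pl_medium"))
  multipliers <- as.list(multipliers)
  if (length(multipliers)) {
    if (is.null(names(multipliers)) || any(!nzchar(names(multipliers))))
      stop_param("all multipliers must be named")
    bad <- setdiff(names(multipliers),
                   c("pna", "pk", "pcl", "beta", "gamma", "inc", "ikc",
                     "inkcc", "kb"))
    if (length(bad))
      stop_param("unknown parameter in multipliers: ",
                 paste(bad, collapse = ", "))
    vals <- unlist(multipliers)
    if (any(!is.finite(vals) | vals <= 0))
      stop_param("all multipliers must be finite and > 0")
  }
  structure(list(duration = duration, medium = medium,
                 multipliers = multipliers, dt = dt, hp = hp,
                 scheme = match.arg(scheme, c("euler", "rk4"))),
            class = "pl_segment")
}

apply_multipliers <- function(params, multipliers) {
  for (nm in names(multipliers))
    params[[nm]] <- params[[nm]] * multipliers[[nm]]
  params
}

#' Simulate a protocol of medium changes and parameter events
#'
#' Runs the pump-leak model through an ordered list of
#' [protocol_segment()]s.  At each segment start the medium jump (osmotic
#' re-equilibration at fixed contents) and parameter multipliers are applied
#' instantaneously; the content ODEs are then integrated with the membrane
#' potential re-solved at every step.  The recorded trajectory includes the
#' post-jump (t = 0+) state of every segment.  The computation is fully
#' deterministic.
#'
#' @inheritParams step_state
#' @param protocol A single `pl_segment` or a list of them.
#' @param verbose Log segment events to stderr.
#' @return A data frame of class `pl_trajectory`: columns `t_min`,
#'   `V_over_A`, `U_mV`, `na_i`, `k_i`, `cl_i`, `qna`, `qk`, `qcl`, the
#'   per-ion, per-pathway `influx`/`efflux`/`net` columns of the flux
#'   decomposition, the electrochemical potentials `mu_*`, and `osor`.
#'   Attributes: `final_state` (a `pl_state`), `final_params`,
#'   `final_medium`, `segments` (per-segment metadata).
#' @examples
#' mod <- u937_model()
#' traj <- simulate_trajectory(mod$state, mod$params, mod$medium,
#'                             protocol_segment(60, medium_nacl100()))
#' @export
simulate_trajectory <- function(state, params, medium, protocol,
                                verbose = FALSE) {
  stopifnot(inherits(state, "pl_state"), inherits(params, "pl_params"),
            inherits(medium, "pl_medium"))
  if (inherits(protocol, "pl_segment")) protocol <- list(protocol)
  if (!length(protocol) || !all(vapply(protocol, inherits, TRUE, "pl_segment")))
    stop_param("'protocol' must be a pl_segment or a list of them")

  t_offset <- 0
  recs <- list()
  meta <- list()
  nseg <- length(protocol)
  for (si in seq_len(nseg)) {
    seg <- protocol[[si]]
    if (!is.null(seg$medium)) {
      medium <- seg$medium
      state <- apply_medium_jump(state, medium)
      if (verbose)
        message(sprintf("t = %g min: medium -> %g mOsm", t_offset,
                        osmolarity(medium)))
    }
    if (length(seg$multipliers)) {
      params <- apply_multipliers(params, seg$multipliers)
      if (verbose)
        message(sprintf("t = %g min: multipliers %s", t_offset,
                        paste(names(seg$multipliers), unlist(seg$multipliers),
                              sep = "x", collapse = ", ")))
    }
    res <- run_core(state, params, medium, seg$duration, seg$dt, seg$hp,
                    t0 = 0, scheme = seg$scheme)
    n <- length(res$t)
    idx <- seq_len(n)
    # when another segment follows, its post-jump record replaces this
    # segment's endpoint (same contents, new medium) to keep t increasing
    if (si < nseg) idx <- idx[-n]
    rows <- lapply(idx, function(i) {
      st <- core_state_at(res, i, state)
      trajectory_row(t_offset + res$t[i], st, params, medium, res$u[i])
    })
    recs <- c(recs, rows)
    state <- core_state_at(res, n, state)
    meta[[si]] <- list(t_start = t_offset, duration = seg$duration,
                       medium = medium, params = params, dt = seg$dt,
                       hp = seg$hp, scheme = seg$scheme)
    t_offset <- t_offset + res$t[n]
  }
  out <- do.call(rbind, recs)
  structure(out, class = c("pl_trajectory", "data.frame"),
            final_state = state, final_params = params,
            final_medium = medium, segments = meta)
}

# one trajectory record: state summary + flux decomposition + potentials
trajectory_row <- function(t, state, params, medium, u) {
  ft <- flux_table(state, params, medium, u = u)
  ci <- concentrations(state)
  base <- data.frame(t_min = t, V_over_A = state$v, U_mV = RTF_MV * u,
                     na_i = ci[["na"]], k_i = ci[["k"]], cl_i = ci[["cl"]],
                     qna = state$qna, qk = state$qk, qcl = state$qcl)
  fd <- as.data.frame(ft)
  fx <- as.data.frame(as.list(stats::setNames(
    c(t(as.matrix(fd[c("influx", "efflux", "net")]))),
    paste(rep(paste(fd$ion, fd$pathway, sep = "_"), each = 3),
          c("influx", "efflux", "net"), sep = "_"))))
  mu <- attr(ft, "mu")
  mus <- if (is.null(mu))
    stats::setNames(rep(NA_real_, 6),
                    c("mu_na", "mu_k", "mu_cl", "mu_nc", "mu_kc", "mu_nkcc"))
  else mu
  cbind(base, fx, as.data.frame(as.list(mus)),
        data.frame(osor = attr(ft, "osor")))
}

#' @export
print.pl_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Pump-leak trajectory: %d records, t = %g .. %g min\n",
              n, x$t_min[1], x$t_min[n]))
  cols <- c("t_min", "V_over_A", "U_mV", "na_i", "k_i", "cl_i")
  show <- unique(round(seq(1, n, length.out = min(n, 8))))
  print(round(as.data.frame(x)[show, cols], 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.pl_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t_min, x$V_over_A, type = "l", xlab = "t (min)",
                 ylab = "V/A (ml/mmol)", main = "Cell water")
  graphics::plot(x$t_min, x$U_mV, type = "l", xlab = "t (min)",
                 ylab = "U (mV)", main = "Membrane potential")
  graphics::matplot(x$t_min, cbind(x$na_i, x$k_i, x$cl_i), type = "l",
                    lty = 1, col = c(2, 3, 4), xlab = "t (min)",
                    ylab = "mM", main = "[Na]i, [K]i, [Cl]i")
  graphics::legend("right", c("Na", "K", "Cl"), col = c(2, 3, 4), lty = 1,
                   bty = "n")
  graphics::matplot(x$t_min, cbind(x$mu_nc, x$mu_kc, x$mu_nkcc), type = "l",
                    lty = 1, col = c(2, 3, 4), xlab = "t (min)",
                    ylab = "mV", main = "Cotransporter driving forces")
  graphics::legend("right", c("NC", "KC", "NKCC"), col = c(2, 3, 4), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Integrate to a balanced (flux-equilibrated) state
#'
#' Advances the state in a fixed medium until the largest relative content
#' change per minute falls below `tol`, or `t_max` is reached.
#'
#' @inheritParams step_state
#' @param tol Convergence threshold on max |dq/dt|/q (min^-1).
#' @param t_max Give up after this many minutes.
#' @param dt Integration step (min).
#' @param scheme `"euler"` or `"rk4"`.
#' @return A list with `state` (the final `pl_state`), `balanced` (logical),
#'   and `t_end` (min of integration used).
#' @export
find_balanced_state <- function(state, params, medium, tol = 1e-8,
                                t_max = 5000, dt = 0.01, scheme = "euler") {
  stopifnot(inherits(state, "pl_state"), inherits(params, "pl_params"),
            inherits(medium, "pl_medium"))
  res <- run_core(state, params, medium, duration = t_max, dt = dt,
                  record_every = max(1L, as.integer(round(1 / dt))),
                  stop_tol = tol, scheme = scheme)
  n <- length(res$t)
  list(state = core_state_at(res, n, state),
       balanced = isTRUE(res$converged),
       t_end = res$t_end)
}

#' Write / read a trajectory as CSV
#'
#' Columns are written in the fixed layout of [simulate_trajectory()] with
#' full (15 significant digit) precision so that a round trip loses nothing
#' beyond printed precision.
#'
#' @param traj A `pl_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a data frame with the trajectory
#'   columns.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pl_trajectory"))
  df <- as.data.frame(traj)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
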