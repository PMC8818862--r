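# Domain types: external medium, transport parameters, cell state.
# All are validated plain lists with S3 classes; contents are scalar doubles.

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("'%s' must be a single finite number", name))
  x <- as.numeric(x)
  if (strict && x <= min)
    stop_param(sprintf("'%s' must be > %g (got %g)", name, min, x))
  if (!strict && x < min)
    stop_param(sprintf("'%s' must be >= %g (got %g)", name, min, x))
  x
}

#' External medium composition
#'
#' Concentrations of the major monovalent ions and of membrane-impermeant
#' non-electrolytes (sucrose, mannitol, ...) in the extracellular medium.
#'
#' @param na0,k0,cl0 External Na+, K+ and Cl- concentrations (mM).
#' @param b0 External membrane-impermeant non-electrolyte concentration (mM).
#' @return An object of class `pl_medium`.
#' @examples
#' m <- medium(140, 5.8, 116, 48.2)   # standard 310 mOsm RPMI-like medium
#' osmolarity(m)
#' @seealso [medium_rpmi()], [apply_medium_jump()]
#' @export
medium <- function(na0, k0, cl0, b0 = 0) {
  m <- structure(list(
    na0 = check_scalar(na0, "na0", 0),
    k0  = check_scalar(k0,  "k0",  0),
    cl0 = check_scalar(cl0, "cl0", 0),
    b0  = check_scalar(b0,  "b0",  0)), class = "pl_medium")
  if (osmolarity(m) <= 0) stop_param("medium osmolarity must be > 0")
  m
}

#' @rdname medium
#' @param x A `pl_medium` object.
#' @return `osmolarity()`: total external osmolarity (mOsm), the sum of all
#'   four concentrations (all species treated as ideal and fully dissociated
#'   ions counted individually).
#' @export
osmolarity <- function(x) {
  stopifnot(inherits(x, "pl_medium"))
  x$na0 + x$k0 + x$cl0 + x$b0
}

#' Standard media used in the worked examples
#'
#' `medium_rpmi()` is the normal 310 mOsm medium (na0 140, k0 5.8, cl0 116,
#' B0 48.2 mM). `medium_nacl100()` adds 100 mM NaCl (510 mOsm) and
#' `medium_sucrose180()` adds 180 mM sucrose (490 mOsm) to it.
#'
#' @return A `pl_medium` object.
#' @export
medium_rpmi <- function() medium(140, 5.8, 116, 48.2)

#' @rdname medium_rpmi
#' @export
medium_nacl100 <- function() medium(240, 5.8, 216, 48.2)

#' @rdname medium_rpmi
#' @export
medium_sucrose180 <- function() medium(140, 5.8, 116, 228.2)

#' @export
print.pl_medium <- function(x, ...) {
  cat(sprintf("External medium: Na %g, K %g, Cl %g, B %g mM (%g mOsm)\n",
              x$na0, x$k0, x$cl0, x$b0, osmolarity(x)))
  invisible(x)
}

#' Membrane transport parameters
#'
#' Rate coefficients of the five transport pathways of the pump-leak model.
#'
#' @param pna,pk,pcl Channel permeability rate coefficients (min^-1), the
#'   Goldman-type coefficients of electrodiffusion through Na+, K+ and Cl-
#'   channels.
#' @param beta Na/K pump rate coefficient (min^-1): Na efflux through the pump
#'   is `-beta * [Na]i`.
#' @param gamma Na:K pump flux stoichiometry (dimensionless); the default 1.5
#'   is the canonical 3Na:2K cycle.
#' @param inc,ikc NC (1Na:1Cl) and KC (1K:1Cl) cotransport rate coefficients
#'   (ml umol^-1 min^-1).
#' @param inkcc NKCC (1Na:1K:2Cl) cotransport rate coefficient
#'   (ml^3 umol^-3 min^-1).
#' @param kb Linear pump-decay coefficient (min^-1): the effective pump rate
#'   at time t is `max(0, beta * (1 - kb*t))`.
#' @return An object of class `pl_params`.
#' @export
transport_params <- function(pna, pk, pcl, beta, gamma = 1.5,
                             inc = 0, ikc = 0, inkcc = 0, kb = 0) {
  structure(list(
    pna   = check_scalar(pna,   "pna",   0),
    pk    = check_scalar(pk,    "pk",    0),
    pcl   = check_scalar(pcl,   "pcl",   0),
    beta  = check_scalar(beta,  "beta",  0),
    gamma = check_scalar(gamma, "gamma", 0, strict = TRUE),
    inc   = check_scalar(inc,   "inc",   0),
    ikc   = check_scalar(ikc,   "ikc",   0),
    inkcc = check_scalar(inkcc, "inkcc", 0),
    kb    = check_scalar(kb,    "kb",    0)), class = "pl_params")
}

#' @rdname transport_params
#' @param params A `pl_params` object.
#' @param t Time since the start of pump decay (min).
#' @return `beta_at()`: the effective pump rate coefficient at time `t`,
#'   clamped at zero.
#' @export
beta_at <- function(params, t) {
  stopifnot(inherits(params, "pl_params"))
  pmax(0, params$beta * (1 - params$kb * t))
}

#' @export
print.pl_params <- function(x, ...) {
  cat("Transport parameters:\n")
  cat(sprintf("  channels  pna %g, pk %g, pcl %g (min^-1)\n", x$pna, x$pk, x$pcl))
  cat(sprintf("  pump      beta %g min^-1, gamma %g", x$beta, x$gamma))
  if (x$kb > 0) cat(sprintf(", kb %g min^-1", x$kb))
  cat("\n")
  cat(sprintf("  cotransport  inc %g, ikc %g (ml/umol/min), inkcc %g (ml^3/umol^3/min)\n",
              x$inc, x$ikc, x$inkcc))
  invisible(x)
}

#' Intracellular state
#'
#' Cell state expressed as ion contents per unit of impermeant intracellular
#' osmolyte A.  With `a = 1` mmol the contents `qna, qk, qcl` (umol/mmol A)
#' are numerically the mmol/mol-A contents of the worked tables, and `v` is
#' the cell water volume per mmol A (ml/mmol), i.e. V/A.  Concentrations
#' follow as `[X]i = qX / v` (mM).
#'
#' Either the contents (`qna`, `qk`, `qcl`) or the concentrations (`na`, `k`,
#' `cl`, together with `v`) may be given.
#'
#' @param qna,qk,qcl Ion contents per unit A (umol/mmol A).
#' @param na,k,cl Alternatively, intracellular concentrations (mM); converted
#'   using `v`.
#' @param v Cell water volume per unit A, V/A (ml/mmol); if omitted it is
#'   recomputed from osmotic balance with `balance_with`.
#' @param z Mean valence of the impermeant osmolytes (dimensionless,
#'   typically negative).
#' @param a Impermeant osmolyte content (mmol); the normalisation unit,
#'   default 1.
#' @param balance_with Optional `pl_medium`; when given and `v` is missing,
#'   `v` is set so that internal and external osmolarities match.
#' @return An object of class `pl_state`.
#' @examples
#' s <- cell_state(na = 38, k = 147, cl = 45, v = 12.5, z = -1.75)
#' concentrations(s)
#' @export
cell_state <- function(qna = NULL, qk = NULL, qcl = NULL,
                       na = NULL, k = NULL, cl = NULL,
                       v = NULL, z, a = 1, balance_with = NULL) {
  a <- check_scalar(a, "a", 0, strict = TRUE)
  z <- check_scalar(z, "z")
  from_conc <- !is.null(na)
  if (from_conc) {
    if (is.null(v)) stop_param("'v' is required when concentrations are given")
    v <- check_scalar(v, "v", 0, strict = TRUE)
    qna <- check_scalar(na, "na", 0) * v
    qk  <- check_scalar(k,  "k",  0) * v
    qcl <- check_scalar(cl, "cl", 0) * v
  } else {
    qna <- check_scalar(qna, "qna", 0)
    qk  <- check_scalar(qk,  "qk",  0)
    qcl <- check_scalar(qcl, "qcl", 0)
    if (is.null(v)) {
      if (is.null(balance_with))
        stop_param("give 'v' or 'balance_with' to fix the water volume")
      v <- (qna + qk + qcl + 1000 * a) / osmolarity(balance_with)
    }
    v <- check_scalar(v, "v", 0, strict = TRUE)
  }
  structure(list(qna = qna, qk = qk, qcl = qcl, a = a, z = z, v = v),
            class = "pl_state")
}

#' @rdname cell_state
#' @param state A `pl_state` object.
#' @return `concentrations()`: named vector `c(na, k, cl)` of intracellular
#'   concentrations (mM).
#' @export
concentrations <- function(state) {
  stopifnot(inherits(state, "pl_state"))
  c(na = state$qna / state$v, k = state$qk / state$v, cl = state$qcl / state$v)
}

#' @rdname cell_state
#' @return `electroneutrality_residual()`: the relative residual of the
#'   electroneutrality condition `qna + qk - qcl + z*1000*a = 0`, scaled by
#'   the total ion content.  Zero for a consistent state.
#' @export
electroneutrality_residual <- function(state) {
  stopifnot(inherits(state, "pl_state"))
  abs(state$qna + state$qk - state$qcl + state$z * 1000 * state$a) /
    (state$qna + state$qk + state$qcl)
}

#' @export
print.pl_state <- function(x, ...) {
  ci <- concentrations(x)
  cat(sprintf("Cell state (per mmol A, a = %g mmol, z = %g):\n", x$a, x$z))
  cat(sprintf("  contents  Na %.4g, K %.4g, Cl %.4g umol/mmol A\n",
              x$qna, x$qk, x$qcl))
  cat(sprintf("  V/A %.4g ml/mmol;  [Na]i %.4g, [K]i %.4g, [Cl]i %.4g mM\n",
              x$v, ci[["na"]], ci[["k"]], ci[["cl"]]))
  invisible(x)
}

# internal: params/medium as unnamed numeric vectors for the C++ core
params_vec <- function(p) c(p$pna, p$pk, p$pcl, p$beta, p$gamma,
                            p$inc, p$ikc, p$inkcc, p$kb)
medium_vec <- function(m) c(m$na0, m$k0, m$cl0, m$b0)
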