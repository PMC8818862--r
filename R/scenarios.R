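# Preset scenario library: hyperosmolar transitions of the U937-like cell
# model (iso 310 mOsm -> +100 mM NaCl or +180 mM sucrose), with optional
# parameter multipliers applied at the moment of transition, and an
# RVI/AVD phenotype classifier on the balanced-to-post-jump volume ratio.

#' The U937-like resting measurement and fitted models
#'
#' `u937_measurement()` returns the reference resting measurement of
#' U937-like cells in a normal 310 mOsm medium: \[Na\]i 38, \[K\]i 147,
#' \[Cl\]i 45 mM, V/A 12.5 ml/mmol, beta 0.039 min^-1 (measured OSOR 3.89).
#' `u937_model()` fits the pump-leak model to it for one of the four
#' cotransporter sets, using the set's resting potential and cotransporter
#' rate coefficients.
#'
#' @return `u937_measurement()`: a `pl_measurement`;
#'   `u937_model()`: a fitted [fit_pump_leak()] object.
#' @examples
#' coef(u937_model("NC"))
#' @export
u937_measurement <- function() {
  resting_measurement(na_i = 38, k_i = 147, cl_i = 45, v_over_a = 12.5,
                      beta = 0.039, medium = medium_rpmi(),
                      osor_measured = 3.89)
}

# cotransporter sets with their assigned coefficients and resting potentials
u937_sets <- function() {
  list(
    "NC"           = list(inc = 3e-5,    ikc = 0,    inkcc = 0,    U = -44.7),
    "NC+KC"        = list(inc = 4.87e-5, ikc = 6e-5, inkcc = 0,    U = -49.3),
    "NC+NKCC"      = list(inc = 3e-5,    ikc = 0,    inkcc = 7e-9, U = -37.6),
    "NC+KC+NKCC"   = list(inc = 7e-5,    ikc = 8e-5, inkcc = 8e-9, U = -45.0))
}

#' @rdname u937_measurement
#' @param set Cotransporter set: `"NC+KC+NKCC"` (default, the full set),
#'   `"NC"`, `"NC+KC"` or `"NC+NKCC"`.
#' @export
u937_model <- function(set = c("NC+KC+NKCC", "NC", "NC+KC", "NC+NKCC")) {
  set <- match.arg(set)
  s <- u937_sets()[[set]]
  fit_pump_leak(u937_measurement(), inc = s$inc, ikc = s$ikc,
                inkcc = s$inkcc, U = s$U)
}

#' Classify a volume response as RVI, weak RVI, AVD or none
#'
#' Thresholds on the ratio of the final to the immediate post-jump cell
#' volume: RVI above 1.05, weak RVI in (1.005, 1.05\], AVD below 0.995,
#' otherwise none.
#'
#' @param v_ratio Final over post-jump V/A.
#' @return One of `"RVI"`, `"weak RVI"`, `"AVD"`, `"none"`.
#' @export
classify_phenotype <- function(v_ratio) {
  v_ratio <- check_scalar(v_ratio, "v_ratio", 0)
  if (v_ratio > 1.05) "RVI"
  else if (v_ratio > 1.005) "weak RVI"
  else if (v_ratio < 0.995) "AVD"
  else "none"
}

scenario_multiplier_catalog <- function() {
  list(
    incx3     = list(inc = 3),    incx10   = list(inc = 10),
    incx0.2   = list(inc = 0.2),  incx0.1  = list(inc = 0.1),
    ikcx0.01  = list(ikc = 0.01), ikcx10   = list(ikc = 10),
    inkccx0.1 = list(inkcc = 0.1), inkccx10 = list(inkcc = 10),
    inkccx50  = list(inkcc = 50),
    pclx0.1   = list(pcl = 0.1),  pclx10   = list(pcl = 10),
    hicc      = list(pna = 10, pk = 1.6),
    betax0.2  = list(beta = 0.2), betax5   = list(beta = 5))
}

#' Scenario presets
#'
#' Names follow `<medium>` or `<medium>_<modifier>`, where `<medium>` is
#' `nacl100` (+100 mM NaCl, 510 mOsm) or `sucrose180` (+180 mM sucrose,
#' 490 mOsm) and `<modifier>` is either a parameter multiplier applied
#' simultaneously with the osmotic jump (`incx3`, `incx10`, `incx0.2`,
#' `incx0.1`, `ikcx0.01`, `ikcx10`, `inkccx0.1`, `inkccx10`, `inkccx50`,
#' `pclx0.1`, `pclx10`, `hicc`, `betax0.2`, `betax5`) or a cotransporter-set
#' variant of the base model (`NC`, `NC+KC`, `NC+NKCC`).  `hicc` mimics
#' hypertonicity-induced cation channels by multiplying pna by 10 and pk by
#' 1.6.  Pump (`beta`) scenarios run 800 min; all others 240 min.
#'
#' @return Character vector of all preset names.
#' @export
scenario_presets <- function() {
  media <- c("nacl100", "sucrose180")
  # the worked multiplier grid, as published, is asymmetric between media
  mult <- list(
    nacl100 = c("incx3", "incx0.2", "ikcx0.01", "ikcx10", "inkccx0.1",
                "inkccx10", "pclx0.1", "pclx10", "hicc", "betax0.2",
                "betax5"),
    sucrose180 = c("incx10", "incx0.1", "ikcx0.01", "ikcx10", "inkccx0.1",
                   "inkccx50", "pclx0.1", "pclx10", "hicc", "betax0.2",
                   "betax5"))
  sets <- c("NC", "NC+KC", "NC+NKCC")
  unlist(lapply(media, function(m)
    c(m, paste(m, mult[[m]], sep = "_"), paste(m, sets, sep = "_"))),
    use.names = FALSE)
}

parse_scenario_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  med_name <- parts[1]
  if (!med_name %in% c("nacl100", "sucrose180"))
    stop_param("unknown scenario medium '", med_name,
               "'; see scenario_presets()")
  med <- if (med_name == "nacl100") medium_nacl100() else medium_sucrose180()
  set <- "NC+KC+NKCC"; multipliers <- list(); duration <- 240
  if (length(parts) > 1) {
    mod <- paste(parts[-1], collapse = "_")
    cat_ <- scenario_multiplier_catalog()
    if (mod %in% names(cat_)) {
      multipliers <- cat_[[mod]]
      if (startsWith(mod, "beta")) duration <- 800
    } else if (mod %in% c("NC", "NC+KC", "NC+NKCC")) {
      set <- mod
    } else stop_param("unknown scenario modifier '", mod,
                      "'; see scenario_presets()")
  }
  list(name = name, medium = med, set = set, multipliers = multipliers,
       duration = duration)
}

#' Run a hyperosmolar transition scenario
#'
#' Applies the osmotic jump (and any parameter multipliers, simultaneously
#' with the jump) to the fitted resting model, integrates for the scenario
#' duration, and classifies the volume phenotype.  Scenario durations follow
#' the 4-h observation convention (240 min; 800 min for the slow pump-rate
#' scenarios); see [scenario_presets()] for names, or pass the pieces
#' explicitly.
#'
#' @param name A preset name (see [scenario_presets()]); ignored when
#'   `medium` is supplied.
#' @param model A fitted [fit_pump_leak()] model; default chosen by preset.
#' @param medium Explicit target [medium()] (overrides the preset).
#' @param multipliers Explicit named parameter multipliers.
#' @param duration Integration time (min).
#' @param dt Integration step (min).
#' @return An object of class `pl_scenario`: a list with `name`, `model`,
#'   `medium`, `post_jump` and `final` states, `U_mV`, `v_ratio`,
#'   `phenotype`, `concentrations` (mM), `contents`, `content_deltas`
#'   (final minus post-jump) and `duration`.
#' @examples
#' \donttest{
#' run_scenario("nacl100")          # weak RVI, V/A about 7.78
#' }
#' @export
run_scenario <- function(name = NULL, model = NULL, medium = NULL,
                         multipliers = NULL, duration = NULL, dt = 0.01) {
  if (is.null(medium)) {
    if (is.null(name)) stop_param("give a preset 'name' or an explicit 'medium'")
    ps <- parse_scenario_name(name)
    medium <- ps$medium
    if (is.null(multipliers)) multipliers <- ps$multipliers
    if (is.null(duration)) duration <- ps$duration
    if (is.null(model)) model <- u937_model(ps$set)
  } else {
    if (is.null(model)) model <- u937_model()
    if (is.null(multipliers)) multipliers <- list()
    if (is.null(duration)) duration <- 240
    if (is.null(name)) name <- "custom"
  }
  stopifnot(inherits(model, "pump_leak"), inherits(medium, "pl_medium"))

  post <- apply_medium_jump(model$state, medium)
  params <- apply_multipliers(model$params, multipliers)
  res <- run_core(post, params, medium, duration, dt,
                  record_every = max(1L, as.integer(round(duration / dt))))
  final <- core_state_at(res, length(res$t), post)
  U <- solve_potential(final, params, medium)$U
  v_ratio <- final$v / post$v
  structure(list(
    name = name, model = model, medium = medium, params = params,
    post_jump = post, final = final, U_mV = U, v_ratio = v_ratio,
    phenotype = classify_phenotype(v_ratio),
    concentrations = concentrations(final),
    contents = c(na = final$qna, k = final$qk, cl = final$qcl),
    content_deltas = c(na = final$qna - post$qna, k = final$qk - post$qk,
                       cl = final$qcl - post$qcl),
    duration = duration), class = "pl_scenario")
}

#' @export
print.pl_scenario <- function(x, ...) {
  ci <- x$concentrations
  cat(sprintf("Scenario %s (%g min, %g mOsm): %s\n", x$name, x$duration,
              osmolarity(x$medium), x$phenotype))
  cat(sprintf(
    "  V/A %.3g ml/mmol (post-jump %.3g, ratio %.3f); U %.1f mV\n",
    x$final$v, x$post_jump$v, x$v_ratio, x$U_mV))
  cat(sprintf("  [Na]i %.3g, [K]i %.3g, [Cl]i %.3g mM\n",
              ci[["na"]], ci[["k"]], ci[["cl"]]))
  invisible(x)
}

#' Tabulate scenarios in the layout of the worked summary table
#'
#' @param names Character vector of preset names (default: all presets).
#' @param dt Integration step (min).
#' @return A data frame with one row per scenario: concentrations (mM),
#'   contents (umol/mmol A), `na_plus_k` content, `V_over_A`, `V_ratio`,
#'   `phenotype`, and final/post-jump content ratios.
#' @export
scenario_table <- function(names = scenario_presets(), dt = 0.01) {
  rows <- lapply(names, function(nm) {
    s <- run_scenario(nm, dt = dt)
    ci <- s$concentrations
    post <- s$post_jump
    data.frame(
      scenario = nm, na_mM = ci[["na"]], k_mM = ci[["k"]], cl_mM = ci[["cl"]],
      qna = s$contents[["na"]], qk = s$contents[["k"]],
      qcl = s$contents[["cl"]],
      na_plus_k = s$contents[["na"]] + s$contents[["k"]],
      V_over_A = s$final$v, V_ratio = s$v_ratio, phenotype = s$phenotype,
      na_ratio = s$contents[["na"]] / post$qna,
      k_ratio = s$contents[["k"]] / post$qk,
      cl_ratio = s$contents[["cl"]] / post$qcl,
      U_mV = s$U_mV, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
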