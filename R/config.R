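# Flat key-value run configuration (YAML-compatible) using the software
# symbol names of the model: na, k, cl, v, na0, k0, cl0, B0, pna, pk, pcl,
# beta, gamma, inc, ikc, inkcc, kb, kv, hp, dt, duration, U, out.

config_required <- c("na", "k", "cl", "v", "na0", "k0", "cl0", "B0",
                     "pna", "pk", "pcl", "beta")
config_optional <- c("gamma", "inc", "ikc", "inkcc", "kb", "kv", "hp",
                     "dt", "duration", "U", "out", "seed")

#' Load a run configuration
#'
#' Reads a flat YAML (or `key: value`) file whose keys are the model's
#' software symbols: internal concentrations `na, k, cl` (mM) and water
#' content `v` (V/A, ml/mmol); medium `na0, k0, cl0, B0` (mM); parameters
#' `pna, pk, pcl, beta, gamma, inc, ikc, inkcc, kb`; run controls `dt`
#' (min), `hp` (steps between outputs), `duration` (min); optional `U` (mV,
#' used by the permeability fit), `kv` (reported osmolarity ratio; an
#' explicit medium always wins), `out`, `seed`.  Unknown keys are rejected
#' by name; the mean impermeant valence follows from electroneutrality.
#'
#' @param path File path, or the name of a shipped example configuration
#'   (e.g. `"table2_full_set"`).
#' @return An object of class `pl_config`: a list with `state`
#'   ([cell_state()]), `medium` ([medium()]), `params`
#'   ([transport_params()]), `dt`, `hp`, `duration`, `U`, `kv`, `out`,
#'   `seed` and `raw` (the parsed key-value list).
#' @examples
#' cfg <- read_run_config("table2_full_set")
#' cfg$params
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", paste0(path, ".yaml"),
                           package = "pumpleak")
    if (nzchar(shipped)) path <- shipped
    else stop_param("config file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw))
    stop_param("empty config; missing required keys: ",
               paste(config_required, collapse = ", "))
  unknown <- setdiff(names(raw), c(config_required, config_optional))
  if (length(unknown))
    stop_param("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(config_required, names(raw))
  if (length(missing))
    stop_param("missing required key(s): ", paste(missing, collapse = ", "))
  for (k in setdiff(names(raw), c("out"))) {
    val <- raw[[k]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop_param(sprintf("config key '%s' is not a single finite number: %s",
                         k, paste(deparse(val), collapse = "")))
  }
  if (!is.null(raw$kv))
    warning("config gives both 'kv' and an explicit medium; ",
            "the explicit medium wins, kv is recorded only", call. = FALSE)
  g <- function(key, default = NULL)
    if (!is.null(raw[[key]])) raw[[key]] else default
  med <- medium(raw$na0, raw$k0, raw$cl0, raw$B0)
  params <- transport_params(raw$pna, raw$pk, raw$pcl, beta = raw$beta,
                             gamma = g("gamma", 1.5), inc = g("inc", 0),
                             ikc = g("ikc", 0), inkcc = g("inkcc", 0),
                             kb = g("kb", 0))
  # valence from electroneutrality at the configured state
  z <- (raw$cl - raw$na - raw$k) * raw$v / 1000
  state <- cell_state(na = raw$na, k = raw$k, cl = raw$cl, v = raw$v, z = z)
  structure(list(state = state, medium = med, params = params,
                 dt = g("dt", 0.01), hp = as.integer(g("hp", 100)),
                 duration = g("duration", 240), U = g("U"), kv = g("kv"),
                 out = g("out"), seed = g("seed"), raw = raw),
            class = "pl_config")
}

#' @rdname read_run_config
#' @param config A `pl_config` (or the named list of raw keys).
#' @return `write_run_config()`: `path`, invisibly.  Values are written with
#'   17 significant digits so that load -> dump -> load round-trips
#'   bit-for-bit.
#' @export
write_run_config <- function(config, path) {
  raw <- if (inherits(config, "pl_config")) config$raw else as.list(config)
  lines <- vapply(names(raw), function(k) {
    v <- raw[[k]]
    vs <- if (is.numeric(v)) format(v, digits = 17) else as.character(v)
    if (is.double(v) && !grepl("[.e]", vs)) vs <- paste0(vs, ".0")
    paste0(k, ": ", vs)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pl_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$state); print(x$medium); print(x$params)
  cat(sprintf("  dt %g min, hp %d, duration %g min\n", x$dt, x$hp,
              x$duration))
  invisible(x)
}
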