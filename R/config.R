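# Run configuration: one structured YAML file with nested blocks, resolved
# against the package's baseline defaults. Unknown keys are rejected so typos
# cannot silently fall back to defaults.

.default_config <- function() {
  list(
    defaults = "paper",
    dt = 0.01,
    out_dir = ".",
    verbosity = "warn",
    microbial = list(qS_max = 10, K_S = 0.10, Y_XS = 0.09, alpha_P = 0.03,
                     beta_P = 0, k_deg = 0.01, K_inh = 0.01, n_inh = 2),
    electro = list(k_elec = 20, A = 0.10, n_e = 2, E0_an = -0.10,
                   E_cath = 0.90, R_ohm = 0.50, T_K = 298.15, F_C = 96485,
                   R_gas = 8.314, nernst_floor = 1e-9),
    initial = list(X = 0.05, S = 20, P_red = 0, P_ox = 0),
    termination = list(t_max = 200, P_tox_stop = NULL,
                       substrate_floor = NULL),
    cycling = list(V_min = 0.60, t_discharge_max = 1, j_charge = 0.02,
                   t_recharge = 0.25, n_cycles = 20),
    sweep = list(alpha_P_min = 0.003, alpha_P_max = 0.3, n_alpha_P = 15,
                 X0_min = 0.005, X0_max = 0.5, n_X0 = 15,
                 metric = "time_averaged_j", tox_stop_factor = 5),
    sensitivity = list(K_inh_values = c(0.005, 0.01, 0.02),
                       k_deg_values = c(0.005, 0.01, 0.02, 0.05),
                       tox_stop_factor = 5),
    sbml = list(include_capacity = TRUE)
  )
}

#' Default run configuration
#'
#' The fully resolved configuration used when no file is supplied: baseline
#' microbial and electrochemical constants, reconstructed default initial
#' conditions (X0 = 0.05 gDW/L, S0 = 20 mmol/L, empty mediator pools),
#' default cycling protocol, default sweep and sensitivity grids, dt = 0.01 h.
#'
#' @return A `bb_config` (nested named list).
#' @export
default_config <- function() {
  structure(.default_config(), class = "bb_config")
}

# recursive merge of user values over defaults, rejecting unknown keys
.merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("config: unknown key '", here, "'")
    if (is.list(base[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]]))
        stop("config: '", here, "' must be a block of key: value pairs")
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]], here)
    } else {
      base[nm] <- user[nm]   # keeps explicit NULLs
    }
  }
  base
}

#' Load and validate a run configuration file
#'
#' Reads a YAML configuration, checks every key against the known schema
#' (unknown keys are an error), and merges the values over the baseline
#' defaults, so a partial file is enough. `defaults: paper` (the only
#' supported value, and the implicit default) resolves all unset values to
#' the package baseline.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A validated `bb_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.null(user$defaults) && !identical(user$defaults, "paper"))
        stop("config: 'defaults' must be \"paper\"")
      cfg <- .merge_config(cfg, user)
    }
  }
  obj <- structure(cfg, class = "bb_config")
  config_objects(obj)  # side effect: full validation via the constructors
  obj
}

#' Resolve a configuration into parameter objects
#'
#' Constructs the validated parameter objects ([microbial_params()],
#' [electro_params()], [anolyte_state()], [termination_spec()],
#' [cycling_params()], [sweep_spec()]) from a `bb_config`, applying
#' constructor-level validation to every value.
#'
#' @param cfg A `bb_config` from [load_config()] / [default_config()].
#' @return A list with `mp`, `ep`, `init`, `term`, `cp`, `sweep`,
#'   `sensitivity`, `dt`, `out_dir`, `sbml`.
#' @export
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "bb_config") || is.list(cfg))
  mp <- do.call(microbial_params, cfg$microbial)
  ep <- do.call(electro_params, cfg$electro)
  init <- do.call(anolyte_state, cfg$initial)
  term <- termination_spec(t_max = cfg$termination$t_max,
                           P_tox_stop = cfg$termination$P_tox_stop,
                           substrate_floor = cfg$termination$substrate_floor)
  cp <- do.call(cycling_params, cfg$cycling)
  sw <- cfg$sweep
  sweep <- sweep_spec(
    alpha_P_values = 10^seq(log10(sw$alpha_P_min), log10(sw$alpha_P_max),
                            length.out = sw$n_alpha_P),
    X0_values = 10^seq(log10(sw$X0_min), log10(sw$X0_max),
                       length.out = sw$n_X0),
    metric = sw$metric, base_microbial = mp, base_electro = ep,
    termination = termination_spec(t_max = cfg$termination$t_max,
                                   P_tox_stop = sw$tox_stop_factor * mp$K_inh),
    S0 = cfg$initial$S)
  list(mp = mp, ep = ep, init = init, term = term, cp = cp, sweep = sweep,
       sensitivity = cfg$sensitivity, dt = cfg$dt, out_dir = cfg$out_dir,
       sbml = cfg$sbml)
}

#' @export
print.bb_config <- function(x, ...) {
  cat("biobattery run configuration:\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
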