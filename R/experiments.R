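#' Design-space sweep specification
#'
#' Grid specification for the phenazine-production-strength by
#' initial-biomass design sweep. Default grids bracket the baseline
#' production yield (alpha_P = 0.03 mmol gDW^-1) and inoculum
#' (X0 = 0.05 gDW L^-1) by a factor of ten in each direction, log-spaced,
#' 15 x 15 points. Each grid point is one batch simulation, terminated at
#' the toxicity threshold (default 5 * K_inh) or the maximum time.
#'
#' @param alpha_P_values Strictly increasing positive grid of
#'   growth-associated yields, mmol gDW^-1.
#' @param X0_values Strictly increasing positive grid of initial biomass,
#'   gDW L^-1.
#' @param metric Sweep summary metric: `"time_averaged_j"` (default),
#'   `"peak_j"` or `"cumulative_charge"`.
#' @param base_microbial Baseline [microbial_params()]; `alpha_P` is
#'   overridden per grid point.
#' @param base_electro Baseline [electro_params()].
#' @param termination A [termination_spec()]; default 200 h with toxicity
#'   stop at 5 * K_inh of the baseline microbial parameters.
#' @param S0 Initial substrate, mmol L^-1 (default 20).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(alpha_P_values = 10^seq(log10(0.003), log10(0.3),
                                               length.out = 15),
                       X0_values = 10^seq(log10(0.005), log10(0.5),
                                          length.out = 15),
                       metric = c("time_averaged_j", "peak_j",
                                  "cumulative_charge"),
                       base_microbial = microbial_params(),
                       base_electro = electro_params(),
                       termination = NULL, S0 = 20) {
  metric <- match.arg(metric)
  chk_grid <- function(v, nm) {
    if (length(v) < 1L || any(!is.finite(v)) || any(v <= 0))
      stop("sweep_spec: '", nm, "' must be a non-empty positive grid")
    if (is.unsorted(v, strictly = TRUE))
      stop("sweep_spec: '", nm, "' must be strictly increasing")
    v
  }
  if (is.null(termination))
    termination <- termination_spec(t_max = 200,
                                    P_tox_stop = 5 * base_microbial$K_inh)
  stopifnot(inherits(base_microbial, "microbial_params"),
            inherits(base_electro, "electro_params"),
            inherits(termination, "termination_spec"))
  structure(list(alpha_P_values = chk_grid(alpha_P_values, "alpha_P_values"),
                 X0_values = chk_grid(X0_values, "X0_values"),
                 metric = metric, base_microbial = base_microbial,
                 base_electro = base_electro, termination = termination,
                 S0 = S0),
            class = "sweep_spec")
}

#' Design-space sweep over production strength and biomass loading
#'
#' Runs one [simulate_batch()] per grid point of a [sweep_spec()], all
#' settings identical except (alpha_P, X0), and summarises each run with
#' [summary_metrics()]. A grid point that fails to integrate is recorded as
#' `NA` with a diagnostic and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param dt Euler step size, h.
#' @return A `bb_sweep`: a tidy data.frame with one row per grid point
#'   (`alpha_P`, `X0`, `metric`, `avg_j_A_m2`, `peak_j_A_m2`,
#'   `cumulative_charge_Ah_m2`, `duration_h`, `termination_reason`) and
#'   attributes `grid` (metric matrix, alpha_P x X0) and
#'   `termination_reasons` (aligned character matrix).
#' @examples
#' sw <- design_sweep(sweep_spec(alpha_P_values = c(0.01, 0.03),
#'                               X0_values = c(0.05, 0.1)), dt = 0.05)
#' attr(sw, "grid")
#' @export
design_sweep <- function(spec, dt = 0.01) {
  stopifnot(inherits(spec, "sweep_spec"))
  na <- length(spec$alpha_P_values); nx <- length(spec$X0_values)
  grid <- matrix(NA_real_, na, nx,
                 dimnames = list(alpha_P = signif(spec$alpha_P_values, 6),
                                 X0 = signif(spec$X0_values, 6)))
  reasons <- matrix(NA_character_, na, nx, dimnames = dimnames(grid))
  rows <- vector("list", na * nx)
  k <- 0L
  for (ia in seq_len(na)) for (ix in seq_len(nx)) {
    k <- k + 1L
    aP <- spec$alpha_P_values[ia]; X0 <- spec$X0_values[ix]
    mp <- spec$base_microbial
    mp$alpha_P <- aP
    sm <- tryCatch({
      traj <- simulate_batch(anolyte_state(X = X0, S = spec$S0), mp,
                             spec$base_electro, spec$termination, dt)
      c(summary_metrics(traj), list(reason = termination_reason(traj)))
    }, error = function(e) {
      bb_log("warn", "sweep point (alpha_P = ", aP, ", X0 = ", X0,
             ") failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(sm)) {
      rows[[k]] <- data.frame(alpha_P = aP, X0 = X0, metric = NA_real_,
                              avg_j_A_m2 = NA_real_, peak_j_A_m2 = NA_real_,
                              cumulative_charge_Ah_m2 = NA_real_,
                              duration_h = NA_real_,
                              termination_reason = NA_character_)
      next
    }
    metric_val <- switch(spec$metric,
                         time_averaged_j = sm$avg_j_A_m2,
                         peak_j = sm$peak_j_A_m2,
                         cumulative_charge = sm$cumulative_charge_Ah_m2)
    grid[ia, ix] <- metric_val
    reasons[ia, ix] <- sm$reason
    rows[[k]] <- data.frame(alpha_P = aP, X0 = X0, metric = metric_val,
                            avg_j_A_m2 = sm$avg_j_A_m2,
                            peak_j_A_m2 = sm$peak_j_A_m2,
                            cumulative_charge_Ah_m2 = sm$cumulative_charge_Ah_m2,
                            duration_h = sm$duration_h,
                            termination_reason = sm$reason)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("bb_sweep", "data.frame"), grid = grid,
            termination_reasons = reasons, metric = spec$metric, dt = dt)
}

#' One-parameter sensitivity curve under the toxicity-limited protocol
#'
#' Runs one toxicity-limited batch simulation per value of the chosen
#' parameter (`K_inh`, host phenazine tolerance, or `k_deg`, mediator
#' stability), all other settings fixed at the supplied moderate-production
#' design, and returns the time-averaged current density together with the
#' realized horizon and cumulative charge for each run. When `K_inh` is
#' swept and the termination threshold is defined as a multiple of `K_inh`
#' (the default 5x), the threshold moves with the swept value, mirroring a
#' protocol that stops at a fixed degree of growth inhibition.
#'
#' @param parameter `"K_inh"` or `"k_deg"`.
#' @param values Non-empty positive grid of parameter values (model units:
#'   mmol L^-1 for `K_inh`, h^-1 for `k_deg`).
#' @param base_microbial,base_electro Baseline parameter objects.
#' @param X0,S0 Initial biomass and substrate.
#' @param t_max Maximum simulated time, h.
#' @param tox_stop_factor Toxicity termination threshold as a multiple of
#'   the (possibly swept) `K_inh`; default 5.
#' @param dt Euler step size, h.
#' @return A data.frame with columns `parameter`, `value`, `avg_j_A_m2`,
#'   `avg_j_mA_cm2`, `peak_j_A_m2`, `cumulative_charge_Ah_m2`, `horizon_h`,
#'   `termination_reason`.
#' @export
sensitivity_curve <- function(parameter = c("K_inh", "k_deg"), values,
                              base_microbial = microbial_params(),
                              base_electro = electro_params(),
                              X0 = 0.05, S0 = 20, t_max = 200,
                              tox_stop_factor = 5, dt = 0.01) {
  parameter <- match.arg(parameter)
  if (length(values) < 1L || any(!is.finite(values)) || any(values <= 0))
    stop("sensitivity_curve: 'values' must be a non-empty positive grid")
  rows <- lapply(values, function(v) {
    mp <- base_microbial
    mp[[parameter]] <- v
    term <- termination_spec(t_max = t_max,
                             P_tox_stop = tox_stop_factor * mp$K_inh)
    sm <- tryCatch({
      traj <- simulate_batch(anolyte_state(X = X0, S = S0), mp,
                             base_electro, term, dt)
      c(summary_metrics(traj), list(reason = termination_reason(traj)))
    }, error = function(e) {
      bb_log("warn", "sensitivity point ", parameter, " = ", v,
             " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(sm))
      return(data.frame(parameter = parameter, value = v,
                        avg_j_A_m2 = NA_real_, avg_j_mA_cm2 = NA_real_,
                        peak_j_A_m2 = NA_real_,
                        cumulative_charge_Ah_m2 = NA_real_,
                        horizon_h = NA_real_,
                        termination_reason = NA_character_))
    data.frame(parameter = parameter, value = v,
               avg_j_A_m2 = sm$avg_j_A_m2, avg_j_mA_cm2 = sm$avg_j_mA_cm2,
               peak_j_A_m2 = sm$peak_j_A_m2,
               cumulative_charge_Ah_m2 = sm$cumulative_charge_Ah_m2,
               horizon_h = sm$duration_h, termination_reason = sm$reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenazine redox speciation time series
#'
#' Extracts the reduced and oxidized pools and the reduced fraction
#' P_red / (P_red + P_ox) (the mediator's state of charge, by analogy) from
#' a trajectory. The fraction is defined as 0 where the total pool is empty.
#'
#' @param traj A `bb_trajectory` (or data.frame with `t`, `P_red`, `P_ox`).
#' @return A data.frame with columns `t`, `P_red`, `P_ox`,
#'   `reduced_fraction` (all fractions in [0, 1]).
#' @export
speciation_metrics <- function(traj) {
  if (nrow(traj) == 0L) stop("speciation_metrics: empty trajectory")
  tot <- traj$P_red + traj$P_ox
  frac <- ifelse(tot > 0, traj$P_red / tot, 0)
  data.frame(t = traj$t, P_red = traj$P_red, P_ox = traj$P_ox,
             reduced_fraction = frac)
}

#' Reference microbial designs
#'
#' `moderate_design()` is the baseline production strength
#' (alpha_P = 0.03 mmol gDW^-1) at the default inoculum, the centre of the
#' viable ridge of the design space. `high_production_design()` picks the
#' grid point of a peak-current sweep that maximises peak instantaneous
#' current density (an aggressive design near the upper production bound).
#'
#' @param X0 Initial biomass, gDW L^-1.
#' @param base_microbial Baseline [microbial_params()].
#' @return A list with `microbial` (a [microbial_params()]) and `X0`.
#' @export
moderate_design <- function(X0 = 0.05, base_microbial = microbial_params()) {
  list(microbial = base_microbial, X0 = X0)
}

#' @rdname moderate_design
#' @param sweep A `bb_sweep` from [design_sweep()] (any metric; the argmax
#'   of the `peak_j_A_m2` column is used).
#' @export
high_production_design <- function(sweep,
                                   base_microbial = microbial_params()) {
  stopifnot(inherits(sweep, "bb_sweep"))
  i <- which.max(sweep$peak_j_A_m2)
  mp <- base_microbial
  mp$alpha_P <- sweep$alpha_P[i]
  list(microbial = mp, X0 = sweep$X0[i])
}

#' Grid argmax of a sweep
#'
#' Index and coordinates of the maximal metric value of a [design_sweep()]
#' result; used to check that the optimum lies on the interior ridge of the
#' design space rather than at a grid corner.
#'
#' @param sweep A `bb_sweep`.
#' @return A list with `alpha_P`, `X0`, `value`, `i_alpha`, `i_X0`, and
#'   logical `is_corner` (both indices extreme).
#' @export
sweep_argmax <- function(sweep) {
  stopifnot(inherits(sweep, "bb_sweep"))
  g <- attr(sweep, "grid")
  idx <- which(g == max(g, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  na <- nrow(g); nx <- ncol(g)
  list(alpha_P = as.numeric(rownames(g)[idx[1L]]),
       X0 = as.numeric(colnames(g)[idx[2L]]),
       value = g[idx[1L], idx[2L]],
       i_alpha = unname(idx[1L]), i_X0 = unname(idx[2L]),
       is_corner = (idx[1L] %in% c(1L, na)) && (idx[2L] %in% c(1L, nx)))
}

#' Write a sweep result to tidy CSV with metadata sidecar
#'
#' @param sweep A `bb_sweep`.
#' @param path Output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  meta <- list(model = "biobattery design-space sweep",
               metric = attr(sweep, "metric"), dt_h = attr(sweep, "dt"),
               n_points = nrow(sweep), deterministic = TRUE)
  meta$run_id <- .content_id(meta)
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta_path)
}
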