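#' Observation-model parameters
#'
#' Maps the latent function index `F(t)` and population index `P(t)` to
#' measurable series: PERG-style function measurements (e.g. amplitude in
#' microvolts) and OCT/axon-count-style structure measurements. The function
#' channel has a response floor: PERG recordings have a signal-to-noise ratio
#' of about 1 log unit, so once RGC function is gone the measured amplitude
#' settles at roughly 10% of the baseline signal (the noise level) rather
#' than zero. The structure channel has an additive offset for non-RGC
#' contributions to the measured thickness (zero for axon counts).
#'
#' @param function_scale Measurement units per unit of function index (> 0).
#' @param function_noise_sd Additive noise SD on function measurements
#'   (measurement units, >= 0); for `noise_model = "lognormal"` this is the
#'   log-scale SD (dimensionless).
#' @param noise_floor_fraction Floor as a fraction of the baseline function
#'   signal (`0 <= f < 1`; default 0.1, i.e. 1 log unit below baseline).
#' @param structure_scale Structure units per surviving cell (> 0).
#' @param structure_offset Non-RGC residual structure (units, >= 0; default
#'   0, appropriate for axon counts).
#' @param structure_noise_sd Additive noise SD on structure measurements.
#' @param noise_model `"gaussian"` (additive, default) or `"lognormal"`
#'   (multiplicative on the noise-free signal).
#'
#' @return An object of class `observation_params`.
#' @export
observation_params <- function(function_scale = 1, function_noise_sd = 0,
                               noise_floor_fraction = 0.1,
                               structure_scale = 1, structure_offset = 0,
                               structure_noise_sd = 0,
                               noise_model = c("gaussian", "lognormal")) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.numeric(function_scale), is.numeric(structure_scale),
            is.numeric(function_noise_sd), is.numeric(structure_noise_sd),
            is.numeric(noise_floor_fraction), is.numeric(structure_offset))
  if (function_scale <= 0 || structure_scale <= 0) {
    stop("scales must be > 0", call. = FALSE)
  }
  if (function_noise_sd < 0 || structure_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (noise_floor_fraction < 0 || noise_floor_fraction >= 1) {
    stop("noise_floor_fraction must be in [0, 1)", call. = FALSE)
  }
  if (structure_offset < 0) stop("structure_offset must be >= 0", call. = FALSE)
  structure(list(function_scale = function_scale,
                 function_noise_sd = function_noise_sd,
                 noise_floor_fraction = noise_floor_fraction,
                 structure_scale = structure_scale,
                 structure_offset = structure_offset,
                 structure_noise_sd = structure_noise_sd,
                 noise_model = noise_model),
            class = "observation_params")
}

measurement_series <- function(times, values, measure, units, meta = list()) {
  out <- data.frame(time = times, value = values, measure = measure,
                    units = units, stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  class(out) <- c("measurement_series", "data.frame")
  out
}

apply_noise <- function(signal, sd, obs, seed) {
  if (sd == 0) return(signal)
  with_local_seed(seed, {
    if (obs$noise_model == "lognormal") {
      signal * stats::rlnorm(length(signal), meanlog = 0, sdlog = sd)
    } else {
      signal + stats::rnorm(length(signal), mean = 0, sd = sd)
    }
  })
}

#' Observe a trajectory through the function (PERG) channel
#'
#' The noise-free signal is `max(floor, function_scale * F(t))` with
#' `floor = noise_floor_fraction * function_scale * F(0)` (baseline at
#' disease onset, evaluated from the trajectory's generating parameters);
#' noise is then added and the result clipped at the floor, so observed
#' values never fall below it.
#'
#' @param traj An `rgc_trajectory` from [trajectory()].
#' @param obs An [observation_params] object.
#' @param seed Integer seed (`NULL` for the current RNG stream).
#'
#' @return A `measurement_series` data frame (`time`, `value`,
#'   `measure = "function"`, `units`).
#' @export
observe_function <- function(traj, obs, seed = NULL) {
  stopifnot(inherits(traj, "rgc_trajectory"), inherits(obs, "observation_params"))
  base <- attr(traj, "params")
  f0 <- if (!is.null(base)) function_index(0, base) else traj$function_index[1]
  floor_val <- obs$noise_floor_fraction * obs$function_scale * f0
  signal <- pmax(floor_val, obs$function_scale * traj$function_index)
  values <- pmax(floor_val, apply_noise(signal, obs$function_noise_sd, obs, seed))
  measurement_series(traj$time, values, "function", "signal units",
                     meta = list(floor = floor_val, seed = seed,
                                 params = attr(traj, "params"), obs = obs))
}

#' Observe a trajectory through the structure (OCT/axon-count) channel
#'
#' The noise-free signal is `structure_offset + structure_scale * P(t)`;
#' noise is added and the result clipped at the offset (the non-RGC residual
#' that remains once every RGC is lost).
#'
#' @inheritParams observe_function
#' @return A `measurement_series` data frame (`measure = "structure"`).
#' @export
observe_structure <- function(traj, obs, seed = NULL) {
  stopifnot(inherits(traj, "rgc_trajectory"), inherits(obs, "observation_params"))
  signal <- obs$structure_offset + obs$structure_scale * traj$population_index
  values <- pmax(obs$structure_offset,
                 apply_noise(signal, obs$structure_noise_sd, obs, seed))
  measurement_series(traj$time, values, "structure", "structure units",
                     meta = list(offset = obs$structure_offset, seed = seed,
                                 params = attr(traj, "params"), obs = obs))
}

#' Generate a synthetic paired function/structure dataset
#'
#' Emulates a DBA/2J-style natural-history experiment: monthly paired
#' measurements of RGC function (PERG amplitude) and structure (axon counts /
#' inner-retina thickness) from the decay model, with measurement noise and
#' the function-channel floor. Each replicate is an independently seeded
#' noisy realization of the same latent trajectory. The true generating
#' parameters and seed are recorded in the dataset's metadata so parameter
#' recovery can be checked.
#'
#' @param params A [decay_params] object (default [dba2j_params()]).
#' @param obs An [observation_params] object.
#' @param times Sampling grid (time units; default monthly samples, months
#'   2–12, mirroring the age range over which mouse PERG natural history is
#'   measured).
#' @param replicates Number of replicate series per measure (>= 1).
#' @param seed Integer seed; one generator stream drives all replicates.
#'
#' @return A data frame of class `rgc_dataset` with columns `time`, `value`,
#'   `measure` (`"function"`/`"structure"`), `units`, `replicate`; metadata
#'   (generating parameters, observation parameters, seed) in attribute
#'   `meta`.
#' @examples
#' ds <- generate_dataset(seed = 1)
#' head(ds)
#' @export
generate_dataset <- function(params = dba2j_params(),
                             obs = observation_params(),
                             times = 2:12, replicates = 1, seed = 1) {
  stopifnot(inherits(params, "decay_params"), inherits(obs, "observation_params"))
  if (length(times) == 0L) stop("times must be non-empty", call. = FALSE)
  if (!is.numeric(replicates) || replicates < 1) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  traj <- trajectory(params, times)
  pieces <- with_local_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      f <- observe_function(traj, obs, seed = NULL)
      s <- observe_structure(traj, obs, seed = NULL)
      f$replicate <- r
      s$replicate <- r
      rbind(as.data.frame(f), as.data.frame(s))
    })
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "meta") <- list(
    params = params, obs = obs, seed = seed, times = times,
    replicates = replicates,
    floor = obs$noise_floor_fraction * obs$function_scale * function_index(0, params)
  )
  class(out) <- c("rgc_dataset", "data.frame")
  out
}

#' @export
print.rgc_dataset <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("RGC dataset: %d rows, measures: %s\n", nrow(x),
              paste(unique(x$measure), collapse = ", ")))
  if (!is.null(meta$params)) {
    p <- meta$params
    cat(sprintf("  generated from b = %g, tau = %g, d = %g (seed %s)\n",
                p$b, p$tau, p$d, format(meta$seed)))
  }
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
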