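#' Closed-form compartment counts of the RGC decay model
#'
#' The model tracks a cohort of `H0` retinal ganglion cells through three
#' compartments. Healthy cells decay exponentially, a fraction `b` per time
#' unit becoming sick: `H(t) = H0 * (1 - b)^t`. A sick cell survives for
#' exactly `tau` time units and then dies, so the sick compartment is
#' \deqn{S(t) = H0 [1 - (1-b)^t], \quad 0 \le t \le \tau,}
#' \deqn{S(t) = H0 [1 - (1-b)^\tau] (1-b)^{t-\tau}, \quad t > \tau,}
#' and the dead compartment is `D(t) = 0` for `t <= tau` and
#' `D(t) = H0 * [1 - (1-b)^(t-tau)]` afterwards — the unique form for which
#' `H + S + D = H0` at every time. Real-valued `t` and `tau` are supported by
#' evaluating `(1-b)^x` as `exp(x * log(1-b))`.
#'
#' Two derived indices summarize what non-invasive measurements see. The
#' function index `F(t) = H(t) + d * S(t)` is what an electrophysiological
#' measure such as the pattern electroretinogram (PERG) is proportional to:
#' sick cells still contribute, at the reduced capacity `d`. The population
#' index `P(t) = H(t) + S(t)` counts surviving cells and is what a structural
#' measure (OCT inner-retina thickness, axon counts) is proportional to.
#' Because sick cells keep their structure for `tau` time units while already
#' functioning at reduced capacity, function loss anticipates structure loss.
#'
#' @param t Time(s) since disease onset (time units, >= 0; vectorized).
#' @param params A [decay_params] object.
#'
#' @return Compartment counts (cells) or index values (cells-equivalent),
#'   one per element of `t`.
#' @seealso [trajectory()] to evaluate all five quantities on a grid,
#'   [horizontal_window()] and [vertical_gap()] for the derived biomarkers.
#' @examples
#' p <- example_params()
#' healthy_at(0:3, p)    # 100, 70, 49, 34.3
#' sick_at(1, p)         # 30: the example's "30% become sick"
#' dead_at(2, p)         # 0: nothing dies before the lag tau = 2
#' function_index(1, p)  # 85 = 70 + 0.5 * 30
#' population_index(1, p)  # 100: structure unchanged while function is down
#' @name core_model
NULL

#' @rdname core_model
#' @export
healthy_at <- function(t, params) {
  stopifnot(inherits(params, "decay_params"))
  check_time(t)
  params$H0 * pow1mb(params$b, t)
}

#' @rdname core_model
#' @export
sick_at <- function(t, params) {
  stopifnot(inherits(params, "decay_params"))
  check_time(t)
  q_tau <- pow1mb(params$b, params$tau)
  ifelse(t <= params$tau,
         params$H0 * (1 - pow1mb(params$b, t)),
         params$H0 * (1 - q_tau) * pow1mb(params$b, t - params$tau))
}

#' @rdname core_model
#' @export
dead_at <- function(t, params) {
  stopifnot(inherits(params, "decay_params"))
  check_time(t)
  ifelse(t <= params$tau,
         0,
         params$H0 * (1 - pow1mb(params$b, t - params$tau)))
}

#' @rdname core_model
#' @export
function_index <- function(t, params) {
  healthy_at(t, params) + params$d * sick_at(t, params)
}

#' @rdname core_model
#' @export
population_index <- function(t, params) {
  healthy_at(t, params) + sick_at(t, params)
}

#' Evaluate the decay model on a time grid
#'
#' Computes healthy, sick and dead compartment counts together with the
#' function and population indices at each requested time.
#'
#' @param params A [decay_params] object.
#' @param times Non-empty, strictly increasing numeric vector of times >= 0.
#'
#' @return A data frame of class `rgc_trajectory` with columns `time`,
#'   `healthy`, `sick`, `dead`, `function_index`, `population_index`; the
#'   generating parameters are attached as attribute `params`.
#' @examples
#' trajectory(example_params(), 0:4)
#' @export
trajectory <- function(params, times) {
  stopifnot(inherits(params, "decay_params"))
  if (length(times) == 0L) stop("times must be non-empty", call. = FALSE)
  check_time(times)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(
    time = times,
    healthy = healthy_at(times, params),
    sick = sick_at(times, params),
    dead = dead_at(times, params)
  )
  out$function_index <- out$healthy + params$d * out$sick
  out$population_index <- out$healthy + out$sick
  attr(out, "params") <- params
  class(out) <- c("rgc_trajectory", "data.frame")
  out
}

#' @export
print.rgc_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("RGC trajectory: %d time points (H0 = %g, b = %g, tau = %g, d = %g)\n",
              nrow(x), p$H0, p$b, p$tau, p$d))
  print.data.frame(x, ...)
  invisible(x)
}
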