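#' Parameters of the three-compartment RGC decay model
#'
#' Bundles the four parameters of the closed-form healthy/sick/dead model of
#' progressive retinal ganglion cell (RGC) loss: the initial healthy
#' population, the per-time-unit decay fraction at which healthy cells become
#' sick, the lag a cell spends sick before dying, and the residual functional
#' capacity of sick cells.
#'
#' @param H0 Initial number of healthy RGCs at disease onset (cells, > 0).
#' @param b Per-time-unit fraction of remaining healthy cells that become sick
#'   (dimensionless, `0 <= b < 1`). `b = 0` means no decay.
#' @param tau Time lag from entering the sick state to death (time units,
#'   >= 0, real-valued; months in the mouse natural-history application).
#' @param d Dysfunction factor: functional capacity of a sick cell relative to
#'   a healthy one (dimensionless, `0 <= d <= 1`; `d = 1` means sick cells are
#'   functionally indistinguishable from healthy ones).
#'
#' @return An object of class `decay_params`.
#' @examples
#' decay_params(H0 = 100, b = 0.3, tau = 2, d = 0.5)
#' @export
decay_params <- function(H0 = 100, b = 0.3, tau = 2, d = 0.5) {
  stopifnot(is.numeric(H0), length(H0) == 1L, is.finite(H0),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(d), length(d) == 1L, is.finite(d))
  if (H0 <= 0) stop("H0 must be > 0 (initial healthy cell count)", call. = FALSE)
  if (b < 0 || b >= 1) stop("b must satisfy 0 <= b < 1 (per-time-unit decay fraction)", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0 (sick-to-dead lag)", call. = FALSE)
  if (d < 0 || d > 1) stop("d must satisfy 0 <= d <= 1 (dysfunction factor)", call. = FALSE)
  structure(list(H0 = H0, b = b, tau = tau, d = d), class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat("RGC decay model parameters\n")
  cat(sprintf("  H0  = %g cells (healthy at onset)\n", x$H0))
  cat(sprintf("  b   = %g per time unit (healthy -> sick fraction)\n", x$b))
  cat(sprintf("  tau = %g time units (sick -> dead lag)\n", x$tau))
  cat(sprintf("  d   = %g (dysfunction factor of sick cells)\n", x$d))
  invisible(x)
}

#' Worked-example parameter set
#'
#' The illustrative parameterization used throughout the documentation:
#' 100 healthy cells at onset, 30% of remaining healthy cells turning sick
#' per time unit, a two-time-unit sick lifespan, and sick cells functioning
#' at 50% capacity.
#'
#' @return A [decay_params] object with `H0 = 100`, `b = 0.3`, `tau = 2`,
#'   `d = 0.5`.
#' @export
example_params <- function() decay_params(H0 = 100, b = 0.3, tau = 2, d = 0.5)

#' DBA/2J natural-history parameter set
#'
#' Parameters describing the natural history of PERG amplitude and optic
#' nerve axon counts in DBA/2J mouse glaucoma: the same decay fraction and
#' dysfunction factor as the worked example but a 6.5-month sick lifespan.
#' Time unit is months.
#'
#' @return A [decay_params] object with `H0 = 100`, `b = 0.3`, `tau = 6.5`,
#'   `d = 0.5`.
#' @export
dba2j_params <- function() decay_params(H0 = 100, b = 0.3, tau = 6.5, d = 0.5)

# (1-b)^x for real x, stable for b near 0; b = 1 is excluded at construction.
pow1mb <- function(b, x) exp(x * log1p(-b))

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("t must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  invisible(t)
}
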