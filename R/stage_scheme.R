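#' Construct a staged state-transition scheme
#'
#' A `stage_scheme` is a discrete-time Markov transition structure over a set
#' of internal states, each mapped to a named disease stage. Stages carry a
#' function coefficient (the fractional contribution of a cell at that stage
#' to the electrophysiological signal) and a structure flag (whether a cell at
#' that stage is still counted by a structural measurement such as OCT
#' thickness or axon counts). Internal states beyond the stages themselves
#' are used to implement non-geometric residence times (e.g. a fixed
#' sick-to-dead lag as a chain of unit-residence substates).
#'
#' @param stage_labels Character vector of stage names, in disease order.
#' @param transition Square numeric matrix of per-step transition
#'   probabilities over internal states (rows sum to 1).
#' @param state_stage Integer vector mapping each internal state (row of
#'   `transition`) to an index into `stage_labels`.
#' @param function_coefficients Numeric vector, one per stage, in `[0, 1]`:
#'   multiplier on the function contribution of cells at that stage.
#' @param structure_present Logical vector, one per stage: `TRUE` if cells at
#'   that stage are counted by structural measurement (not yet lost).
#' @param step_size Simulation time per step (time units, > 0).
#' @param state_labels Optional character labels for internal states.
#'
#' @return An object of class `stage_scheme`.
#' @seealso [three_state_scheme()], [seven_stage_scheme()],
#'   [simulate_expected()], [simulate_stochastic()].
#' @export
stage_scheme <- function(stage_labels, transition, state_stage,
                         function_coefficients, structure_present,
                         step_size = 1, state_labels = NULL) {
  stage_labels <- as.character(stage_labels)
  n_stage <- length(stage_labels)
  transition <- as.matrix(transition)
  n_state <- nrow(transition)
  if (ncol(transition) != n_state) stop("transition matrix must be square", call. = FALSE)
  if (any(transition < 0)) stop("transition probabilities must be >= 0", call. = FALSE)
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-10)) {
    bad <- which(abs(rs - 1) > 1e-10)
    stop(sprintf("outgoing probabilities must sum to 1 (state%s %s sum to %s)",
                 if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = ", "),
                 paste(signif(rs[bad], 6), collapse = ", ")), call. = FALSE)
  }
  state_stage <- as.integer(state_stage)
  if (length(state_stage) != n_state || any(state_stage < 1L) || any(state_stage > n_stage)) {
    stop("state_stage must map every internal state to a stage", call. = FALSE)
  }
  if (length(function_coefficients) != n_stage ||
      any(function_coefficients < 0) || any(function_coefficients > 1)) {
    stop("function_coefficients must be one value in [0, 1] per stage", call. = FALSE)
  }
  if (length(structure_present) != n_stage || !is.logical(structure_present)) {
    stop("structure_present must be one logical per stage", call. = FALSE)
  }
  if (!is.numeric(step_size) || length(step_size) != 1L || step_size <= 0) {
    stop("step_size must be a single positive number", call. = FALSE)
  }
  if (is.null(state_labels)) state_labels <- stage_labels[state_stage]
  dimnames(transition) <- list(state_labels, state_labels)
  structure(list(
    stage_labels = stage_labels,
    transition = transition,
    state_stage = state_stage,
    state_labels = state_labels,
    function_coefficients = as.numeric(function_coefficients),
    structure_present = structure_present,
    step_size = step_size
  ), class = "stage_scheme")
}

#' @export
print.stage_scheme <- function(x, ...) {
  cat(sprintf("Stage scheme: %d stages (%s), %d internal states, step = %g\n",
              length(x$stage_labels), paste(x$stage_labels, collapse = " > "),
              nrow(x$transition), x$step_size))
  cat("  function coefficients:", paste(signif(x$function_coefficients, 3), collapse = ", "), "\n")
  cat("  structure present:    ", paste(ifelse(x$structure_present, "yes", "no"), collapse = ", "), "\n")
  invisible(x)
}

#' Three-state scheme equivalent to the closed-form decay model
#'
#' Builds the healthy/sick/dead transition scheme whose expected-value
#' propagation reproduces the closed-form model exactly at step times. Each
#' step, a healthy cell becomes sick with probability
#' `1 - (1 - b)^step_size`. The fixed sick-to-dead lag `tau` is implemented
#' as a chain of `tau / step_size` unit-residence substates, so every cell
#' that falls sick dies exactly `tau` time units later (matching the
#' closed-form lag, not a geometric mean-`tau` residence). A geometric
#' residence with mean `tau` is available via `residence = "geometric"` for
#' sensitivity analysis.
#'
#' `tau` must be an integer multiple of `step_size` (for the deterministic
#' residence chain); if it is not, the error message suggests the coarsest
#' step size that divides `tau`.
#'
#' @param params A [decay_params] object.
#' @param step_size Simulation step (time units); must divide 1 time unit and
#'   (for deterministic residence) divide `tau`.
#' @param residence `"deterministic"` (default; exact lag `tau`) or
#'   `"geometric"` (memoryless residence with mean `tau`).
#'
#' @return A `stage_scheme` with stages Healthy, Sick, Dead; the function
#'   coefficients are `(1, d, 0)` and structure counts Healthy and Sick.
#' @examples
#' sch <- three_state_scheme(example_params())       # 2 sick substates
#' three_state_scheme(dba2j_params(), step_size = 0.5)  # 13 sick substates
#' @export
three_state_scheme <- function(params, step_size = 1,
                               residence = c("deterministic", "geometric")) {
  stopifnot(inherits(params, "decay_params"))
  residence <- match.arg(residence)
  if (!is.numeric(step_size) || length(step_size) != 1L || step_size <= 0) {
    stop("step_size must be a single positive number", call. = FALSE)
  }
  inv <- 1 / step_size
  if (abs(inv - round(inv)) > 1e-8) {
    stop("step_size must divide 1 time unit (e.g. 1, 0.5, 0.25)", call. = FALSE)
  }
  p_sick <- 1 - pow1mb(params$b, step_size)

  if (residence == "geometric") {
    # single sick state; per-step death prob gives mean residence tau
    p_die <- if (params$tau > 0) min(1, step_size / params$tau) else 1
    P <- rbind(c(1 - p_sick, p_sick, 0),
               c(0, 1 - p_die, p_die),
               c(0, 0, 1))
    return(stage_scheme(c("Healthy", "Sick", "Dead"), P,
                        state_stage = c(1L, 2L, 3L),
                        function_coefficients = c(1, params$d, 0),
                        structure_present = c(TRUE, TRUE, FALSE),
                        step_size = step_size))
  }

  m_real <- params$tau / step_size
  m <- round(m_real)
  if (abs(m_real - m) > 1e-8) {
    # coarsest step that divides tau (and 1): 1 / ceiling(1/candidate)
    cand <- params$tau / ceiling(params$tau / step_size)
    cand <- 1 / ceiling(1 / cand - 1e-9)
    stop(sprintf(paste0("tau = %g is not an integer multiple of step_size = %g; ",
                        "try step_size = %g"), params$tau, step_size, cand),
         call. = FALSE)
  }
  if (m == 0L) {
    # tau = 0: sick stage is instantaneous, healthy cells die directly
    P <- rbind(c(1 - p_sick, 0, p_sick),
               c(0, 0, 1),
               c(0, 0, 1))
    return(stage_scheme(c("Healthy", "Sick", "Dead"), P,
                        state_stage = c(1L, 2L, 3L),
                        function_coefficients = c(1, params$d, 0),
                        structure_present = c(TRUE, TRUE, FALSE),
                        step_size = step_size))
  }
  n_state <- m + 2L  # healthy, sick_1..sick_m, dead
  P <- matrix(0, n_state, n_state)
  P[1, 1] <- 1 - p_sick
  P[1, 2] <- p_sick
  for (j in seq_len(m)) P[1 + j, 2 + j] <- 1  # sick_j -> sick_{j+1} (or dead)
  P[n_state, n_state] <- 1
  stage_scheme(
    c("Healthy", "Sick", "Dead"), P,
    state_stage = c(1L, rep(2L, m), 3L),
    function_coefficients = c(1, params$d, 0),
    structure_present = c(TRUE, TRUE, FALSE),
    step_size = step_size,
    state_labels = c("Healthy", paste0("Sick_", seq_len(m)), "Dead")
  )
}

#' Seven-stage disease-progression scheme
#'
#' A linear chain over the seven conceptual stages of RGC degeneration —
#' Healthy, At Risk, Sick, Very sick, Dying, Dead, Effaced — with per-step
#' progression probabilities between consecutive stages and the terminal
#' stage absorbing. Function coefficients default to a non-increasing profile
#' in which stages 0–3 still contribute to the electrophysiological signal
#' (with decreasing capacity) and stages 4–6 are at floor (coefficient 0);
#' structural measurement counts stages 0–3 as present and stages 4–6 as
#' lost. The default probabilities and coefficients are illustrative
#' configuration values, not empirical estimates.
#'
#' @param progression Numeric vector of 6 per-step probabilities of advancing
#'   from stage `i` to stage `i+1` (i = 0..5), each in `[0, 1]`.
#' @param function_coefficients Numeric vector of 7 values in `[0, 1]`,
#'   non-increasing; first must be 1 and the last two 0.
#' @param structure_present Logical vector of 7 flags.
#' @param step_size Simulation step (time units, > 0).
#' @param stage_labels Character vector of 7 stage names.
#'
#' @return A `stage_scheme` with 7 stages.
#' @examples
#' seven_stage_scheme()
#' @export
seven_stage_scheme <- function(progression = c(0.3, 0.3, 0.3, 0.5, 0.5, 0.5),
                               function_coefficients = c(1, 0.9, 0.5, 0.25, 0, 0, 0),
                               structure_present = c(rep(TRUE, 4), rep(FALSE, 3)),
                               step_size = 1,
                               stage_labels = c("Healthy", "At Risk", "Sick",
                                                "Very sick", "Dying", "Dead",
                                                "Effaced")) {
  if (length(stage_labels) != 7L) stop("seven stages required", call. = FALSE)
  if (length(progression) != 6L || any(progression < 0) || any(progression > 1)) {
    stop("progression must be 6 probabilities in [0, 1]", call. = FALSE)
  }
  if (length(function_coefficients) != 7L) {
    stop("function_coefficients must have 7 values", call. = FALSE)
  }
  if (any(diff(function_coefficients) > 1e-12)) {
    stop("function_coefficients must be non-increasing across stages", call. = FALSE)
  }
  if (function_coefficients[1] != 1) {
    stop("healthy stage must have function coefficient 1", call. = FALSE)
  }
  if (any(function_coefficients[6:7] != 0)) {
    stop("dead and effaced stages must have function coefficient 0", call. = FALSE)
  }
  P <- diag(7)
  for (i in 1:6) {
    P[i, i] <- 1 - progression[i]
    P[i, i + 1] <- progression[i]
  }
  stage_scheme(stage_labels, P, state_stage = 1:7,
               function_coefficients = function_coefficients,
               structure_present = structure_present,
               step_size = step_size)
}
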