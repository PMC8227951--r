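# Seeded evaluation that never clobbers the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      abs(seed - round(seed)) > 0) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_horizon <- function(scheme, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 0) {
    stop("horizon must be a single number >= 0", call. = FALSE)
  }
  k <- horizon / scheme$step_size
  if (abs(k - round(k)) > 1e-8) {
    stop(sprintf("horizon must be a multiple of step_size = %g", scheme$step_size),
         call. = FALSE)
  }
  as.integer(round(k))
}

counts_result <- function(scheme, state_counts, kind, seed = NULL) {
  n_steps <- nrow(state_counts) - 1L
  times <- seq(0, by = scheme$step_size, length.out = n_steps + 1L)
  n_stage <- length(scheme$stage_labels)
  agg <- matrix(0, nrow(state_counts), n_stage,
                dimnames = list(NULL, scheme$stage_labels))
  for (s in seq_len(n_stage)) {
    cols <- which(scheme$state_stage == s)
    agg[, s] <- if (length(cols) == 1L) state_counts[, cols] else rowSums(state_counts[, cols, drop = FALSE])
  }
  out <- data.frame(time = times, agg, check.names = FALSE)
  attr(out, "scheme") <- scheme
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  class(out) <- c("population_counts", "data.frame")
  out
}

#' Propagate expected stage occupancy
#'
#' Deterministically propagates expected cell counts through a
#' [stage_scheme()]'s transition structure, starting with all `n0` cells in
#' the first internal state. Total population is conserved at every step.
#' For a [three_state_scheme()] with deterministic residence, the expected
#' counts reproduce the closed-form model exactly at step times.
#'
#' @param scheme A `stage_scheme`.
#' @param n0 Initial population size (cells, > 0; real-valued here).
#' @param horizon End time (time units; a multiple of the scheme's step).
#'
#' @return A data frame of class `population_counts`: column `time` plus one
#'   column of expected counts per stage.
#' @examples
#' simulate_expected(three_state_scheme(example_params()), 100, 4)
#' @export
simulate_expected <- function(scheme, n0, horizon) {
  stopifnot(inherits(scheme, "stage_scheme"))
  if (!is.numeric(n0) || length(n0) != 1L || n0 <= 0) {
    stop("n0 must be a single positive number", call. = FALSE)
  }
  n_steps <- check_horizon(scheme, horizon)
  n_state <- nrow(scheme$transition)
  x <- numeric(n_state); x[1] <- n0
  counts <- matrix(0, n_steps + 1L, n_state)
  counts[1, ] <- x
  for (k in seq_len(n_steps)) {
    x <- as.numeric(x %*% scheme$transition)
    counts[k + 1L, ] <- x
  }
  counts_result(scheme, counts, kind = "expected")
}

#' Stochastic population simulation
#'
#' Simulates `n0` cells through a [stage_scheme()] by per-stage multinomial
#' draws: at each step the cells in each internal state are distributed over
#' successor states according to the transition probabilities. Total count is
#' conserved in every replicate, and the same `seed` reproduces the same
#' table. The RNG is local to the call (the caller's `.Random.seed` is
#' untouched).
#'
#' @param scheme A `stage_scheme`.
#' @param n0 Initial population size (positive integer).
#' @param horizon End time (multiple of the scheme's step).
#' @param seed Integer seed for the simulation's own RNG stream.
#'
#' @return A `population_counts` data frame of integer stage counts.
#' @examples
#' simulate_stochastic(three_state_scheme(example_params()), 1000, 4, seed = 1)
#' @export
simulate_stochastic <- function(scheme, n0, horizon, seed) {
  stopifnot(inherits(scheme, "stage_scheme"))
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1 || abs(n0 - round(n0)) > 0) {
    stop("n0 must be a positive integer", call. = FALSE)
  }
  n_steps <- check_horizon(scheme, horizon)
  n_state <- nrow(scheme$transition)
  with_local_seed(seed, {
    x <- integer(n_state); x[1] <- as.integer(n0)
    counts <- matrix(0L, n_steps + 1L, n_state)
    counts[1, ] <- x
    for (k in seq_len(n_steps)) {
      nxt <- integer(n_state)
      for (i in which(x > 0L)) {
        p <- scheme$transition[i, ]
        nz <- which(p > 0)
        if (length(nz) == 1L) {
          nxt[nz] <- nxt[nz] + x[i]
        } else {
          draw <- stats::rmultinom(1, x[i], p[nz])[, 1]
          nxt[nz] <- nxt[nz] + draw
        }
      }
      x <- nxt
      counts[k + 1L, ] <- x
    }
    counts_result(scheme, counts, kind = "stochastic", seed = seed)
  })
}

#' Per-cell stochastic simulation with event logging
#'
#' Walks each cell individually through the scheme's transition structure and
#' logs the time at which it first enters each stage. Useful for checking
#' residence-time properties — e.g. that in the deterministic-lag three-state
#' scheme every cell that dies spent exactly `tau` time units sick.
#'
#' @inheritParams simulate_stochastic
#' @param n_cells Number of cells to simulate (positive integer).
#'
#' @return A data frame with columns `cell`, `stage`, `entry_time` — one row
#'   per stage a cell entered (entry to the initial stage at time 0
#'   included).
#' @examples
#' ev <- simulate_cells(three_state_scheme(example_params()), 50, 20, seed = 1)
#' head(ev)
#' @export
simulate_cells <- function(scheme, n_cells, horizon, seed) {
  stopifnot(inherits(scheme, "stage_scheme"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    stop("n_cells must be a positive integer", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  n_steps <- check_horizon(scheme, horizon)
  n_state <- nrow(scheme$transition)
  n_stage <- length(scheme$stage_labels)
  with_local_seed(seed, {
    state <- rep(1L, n_cells)
    entry <- matrix(NA_real_, n_cells, n_stage)
    entry[, scheme$state_stage[1]] <- 0
    for (k in seq_len(n_steps)) {
      t_now <- k * scheme$step_size
      new_state <- state
      for (i in unique(state)) {
        idx <- which(state == i)
        p <- scheme$transition[i, ]
        nz <- which(p > 0)
        new_state[idx] <- if (length(nz) == 1L) rep(nz, length(idx)) else {
          nz[sample.int(length(nz), length(idx), replace = TRUE, prob = p[nz])]
        }
      }
      state <- new_state
      stg <- scheme$state_stage[state]
      first <- is.na(entry[cbind(seq_len(n_cells), stg)])
      entry[cbind(which(first), stg[first])] <- t_now
      }
    rows <- which(!is.na(entry), arr.ind = TRUE)
    out <- data.frame(cell = rows[, 1],
                      stage = scheme$stage_labels[rows[, 2]],
                      entry_time = entry[rows])
    out <- out[order(out$cell, out$entry_time), ]
    rownames(out) <- NULL
    out
  })
}

#' Derived indices from stage occupancy
#'
#' Computes the function index (stage counts weighted by the scheme's
#' function coefficients) and the structure index (counts summed over stages
#' still visible to structural measurement) for each row of a
#' `population_counts` table.
#'
#' @param counts A `population_counts` data frame from [simulate_expected()]
#'   or [simulate_stochastic()].
#'
#' @return A data frame with columns `time`, `function_index`,
#'   `structure_index`.
#' @export
stage_indices <- function(counts) {
  stopifnot(inherits(counts, "population_counts"))
  scheme <- attr(counts, "scheme")
  m <- as.matrix(counts[, scheme$stage_labels, drop = FALSE])
  data.frame(
    time = counts$time,
    function_index = as.numeric(m %*% scheme$function_coefficients),
    structure_index = as.numeric(m %*% as.numeric(scheme$structure_present))
  )
}

#' @export
print.population_counts <- function(x, ...) {
  cat(sprintf("Stage occupancy (%s run): %d steps of %g time units\n",
              attr(x, "kind"), nrow(x) - 1L, attr(x, "scheme")$step_size))
  print.data.frame(x, ...)
  invisible(x)
}
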