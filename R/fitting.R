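#' Configuration for decay-model fitting
#'
#' @param bounds Named list of `(low, high)` bounds for `b`, `tau`, `d`.
#'   Defaults: `b` in `[0, 0.95]`, `tau` in `[0, 24]`, `d` in `[0, 1]`. The
#'   `tau` upper bound is clamped to the span of the data at fit time.
#' @param n_starts Number of best coarse-grid cells refined by bounded local
#'   optimization (>= 1).
#' @param grid_points Named list of coarse-grid sizes for `b`, `tau`, `d`.
#' @param loss `"ss"` (unweighted sum of squares, default) or `"weighted"`
#'   (inverse-variance weights from an `se` column in the dataset).
#' @param normalize If `TRUE` (default) both series are divided by their
#'   value at the earliest retained time, fixing `H0 = 100` and removing the
#'   measurement scale (and its confounding with `d`) from the problem. If
#'   `FALSE`, per-measure scale factors are profiled out analytically.
#' @param floor_handling `"censor"` (default: function values at or below the
#'   recorded noise floor are dropped — floored measurements no longer track
#'   disease) or `"fit"` (kept, and the model prediction is floored too).
#' @param bootstrap_reps Residual-bootstrap replicates for [bootstrap_ci()]
#'   (0 = no intervals).
#' @param seed Integer seed controlling all stochastic steps of the fit.
#'
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(b = c(0, 0.95), tau = c(0, 24), d = c(0, 1)),
                       n_starts = 5, grid_points = list(b = 12, tau = 15, d = 11),
                       loss = c("ss", "weighted"), normalize = TRUE,
                       floor_handling = c("censor", "fit"),
                       bootstrap_reps = 0, seed = 1) {
  loss <- match.arg(loss)
  floor_handling <- match.arg(floor_handling)
  stopifnot(n_starts >= 1, bootstrap_reps >= 0)
  for (nm in c("b", "tau", "d")) {
    if (is.null(bounds[[nm]]) || length(bounds[[nm]]) != 2L ||
        bounds[[nm]][1] > bounds[[nm]][2]) {
      stop(sprintf("bounds$%s must be (low, high)", nm), call. = FALSE)
    }
  }
  if (bounds$b[1] < 0 || bounds$b[2] >= 1) stop("b bounds must lie in [0, 1)", call. = FALSE)
  if (bounds$tau[1] < 0) stop("tau bounds must be >= 0", call. = FALSE)
  if (bounds$d[1] < 0 || bounds$d[2] > 1) stop("d bounds must lie in [0, 1]", call. = FALSE)
  structure(list(bounds = bounds, n_starts = n_starts, grid_points = grid_points,
                 loss = loss, normalize = normalize,
                 floor_handling = floor_handling,
                 bootstrap_reps = bootstrap_reps, seed = seed),
            class = "fit_config")
}

# Average replicates, censor floored function points, normalize per measure.
prep_fit_data <- function(dataset, config) {
  req <- c("time", "value", "measure")
  miss <- setdiff(req, names(dataset))
  if (length(miss)) {
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  meta <- attr(dataset, "meta")
  out <- list()
  for (ms in c("function", "structure")) {
    sub <- dataset[dataset$measure == ms, , drop = FALSE]
    if (nrow(sub) == 0L) stop(sprintf("dataset has no '%s' series", ms), call. = FALSE)
    agg <- stats::aggregate(value ~ time, data = sub, FUN = mean)
    agg <- agg[order(agg$time), ]
    se <- NULL
    if (config$loss == "weighted" && "se" %in% names(sub)) {
      se_agg <- stats::aggregate(se ~ time, data = sub, FUN = mean)
      se <- se_agg$se[match(agg$time, se_agg$time)]
    }
    floor_val <- if (ms == "function" && !is.null(meta$floor)) meta$floor else NULL
    if (ms == "function" && config$floor_handling == "censor" && !is.null(floor_val)) {
      # clipping at the floor biases group means upward well before the mean
      # itself reaches the floor, so censor once the mean is within two
      # observation SDs of it (SD taken from replicate scatter when present)
      sigma <- 0
      if ("replicate" %in% names(sub) && length(unique(sub$replicate)) > 1L) {
        sds <- stats::aggregate(value ~ time, data = sub, FUN = stats::sd)$value
        sigma <- stats::median(sds, na.rm = TRUE)
        if (!is.finite(sigma)) sigma <- 0
      }
      keep <- agg$value > floor_val + 2 * sigma + 1e-9 * max(floor_val, 1)
      if (sum(keep) < nrow(agg)) {
        agg <- agg[keep, , drop = FALSE]
        if (!is.null(se)) se <- se[keep]
      }
    }
    if (length(unique(agg$time)) < 4L) {
      stop(sprintf(paste0("need >= 4 distinct (uncensored) time points per measure ",
                          "to identify (b, tau, d); '%s' has %d"),
                   ms, length(unique(agg$time))), call. = FALSE)
    }
    out[[ms]] <- list(time = agg$time, y = agg$value, se = se, floor = floor_val)
  }
  # normalization baseline: earliest retained time of each series
  for (ms in names(out)) {
    s <- out[[ms]]
    if (config$normalize) {
      base <- s$y[1]
      if (base <= 0) stop("baseline value must be > 0 for normalization", call. = FALSE)
      s$y <- s$y / base
      if (!is.null(s$se)) s$se <- s$se / base
      if (!is.null(s$floor)) s$floor <- s$floor / base
      s$baseline <- base
    }
    s$w <- if (!is.null(s$se) && all(s$se > 0)) 1 / s$se^2 else rep(1, length(s$y))
    out[[ms]] <- s
  }
  if (max(c(out[["function"]]$time, out[["structure"]]$time)) > config$bounds$tau[2]) {
    # keep default tau bound but never below the data span
  }
  out
}

# Normalized model predictions at the series' own baseline time.
predict_norm <- function(theta, times, measure, t0, floor_norm = NULL,
                         floor_handling = "censor") {
  p <- decay_params(H0 = 100, b = theta[1], tau = theta[2], d = theta[3])
  f <- if (measure == "function") function_index else population_index
  pred <- f(times, p) / f(t0, p)
  if (measure == "function" && floor_handling == "fit" && !is.null(floor_norm)) {
    pred <- pmax(pred, floor_norm)
  }
  pred
}

fit_objective <- function(theta, prep, config) {
  # penalty wall for derivative-free excursions outside the model domain
  viol <- max(0, -theta[1]) + max(0, theta[1] - 0.999) + max(0, -theta[2]) +
    max(0, -theta[3]) + max(0, theta[3] - 1)
  if (viol > 0) return(1e8 * (1 + viol))
  total <- 0
  for (ms in c("function", "structure")) {
    s <- prep[[ms]]
    pred <- predict_norm(theta, s$time, ms, t0 = s$time[1],
                         floor_norm = s$floor,
                         floor_handling = config$floor_handling)
    if (!config$normalize) {
      # profile out the free per-measure scale analytically
      sc <- sum(s$w * s$y * pred) / sum(s$w * pred^2)
      pred <- sc * pred
    }
    total <- total + sum(s$w * (s$y - pred)^2)
  }
  total
}

fit_core <- function(prep, config) {
  bd <- config$bounds
  tmax <- max(prep[["function"]]$time, prep[["structure"]]$time)
  bd$tau[2] <- min(bd$tau[2], tmax)
  gp <- config$grid_points
  grid <- expand.grid(
    b = seq(bd$b[1], bd$b[2], length.out = gp$b),
    tau = seq(bd$tau[1], bd$tau[2], length.out = gp$tau),
    d = seq(bd$d[1], bd$d[2], length.out = gp$d)
  )
  grid$loss <- apply(grid, 1, function(r) {
    fit_objective(c(r[["b"]], r[["tau"]], r[["d"]]), prep, config)
  })
  grid <- grid[order(grid$loss, grid$b), ]
  starts <- utils::head(grid, config$n_starts)
  lower <- c(bd$b[1], bd$tau[1], bd$d[1])
  upper <- c(bd$b[2], bd$tau[2], bd$d[2])
  results <- lapply(seq_len(nrow(starts)), function(i) {
    th0 <- as.numeric(starts[i, c("b", "tau", "d")])
    opt <- try(stats::optim(th0, fit_objective, prep = prep, config = config,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(factr = 1e2, maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) {
      list(par = th0, value = starts$loss[i], convergence = 1L)
    } else opt
  })
  losses <- vapply(results, function(r) r$value, numeric(1))
  bs <- vapply(results, function(r) r$par[1], numeric(1))
  best <- order(losses, bs)[1]
  opt <- results[[best]]
  starts$refined_loss <- losses
  # L-BFGS-B can stop with a line-search failure once the loss hits machine
  # precision; a derivative-free polish settles the point and the flag
  polish <- stats::optim(pmin(pmax(opt$par, lower), upper), fit_objective,
                         prep = prep, config = config, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 2000))
  if (polish$value <= opt$value &&
      all(polish$par >= lower - 1e-12) && all(polish$par <= upper + 1e-12)) {
    opt <- list(par = pmin(pmax(polish$par, lower), upper),
                value = polish$value,
                convergence = max(polish$convergence, 0))
  }
  list(theta = opt$par, loss = opt$value,
       converged = opt$convergence == 0,
       starts = starts)
}

#' Fit the decay model to paired function/structure series
#'
#' Estimates `(b, tau, d)` by least squares: replicate measurements are
#' averaged per time point, each measure is normalized to its earliest value
#' (so `H0` is fixed at 100 and measurement scale drops out), and the summed
#' squared residuals of the normalized function series against
#' `F(t)/F(t0)` and of the normalized structure series against `P(t)/P(t0)`
#' are minimized jointly. Because the sick-to-dead lag enters piecewise the
#' loss surface can be multimodal, so a coarse grid over the parameter box is
#' scanned first and the best cells are refined by bounded local
#' optimization; ties are broken by lower loss, then lower `b`.
#'
#' Function values at or below the dataset's recorded noise floor are
#' censored by default (floored measurements no longer track progression);
#' see [fit_config()].
#'
#' @param dataset An `rgc_dataset` (or any data frame with columns `time`,
#'   `value`, `measure` containing both a `"function"` and a `"structure"`
#'   series, each with at least 4 distinct time points).
#' @param config A [fit_config()].
#'
#' @return An object of class `rgc_fit`: estimated parameters
#'   (`params_hat`), `loss_value`, `converged`, the multistart table
#'   (`starts`), bootstrap `intervals` (if requested), the asymptotic
#'   treatment `window` (see [horizontal_window()]), the dysfunction
#'   `gap_curve` over the data grid (see [vertical_gap()]), and
#'   `diagnostics`.
#' @examples
#' ds <- generate_dataset(dba2j_params(), observation_params(), times = 0:12)
#' fit <- fit_decay(ds)
#' fit$params_hat
#' @export
fit_decay <- function(dataset, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  prep <- prep_fit_data(dataset, config)
  core <- fit_core(prep, config)
  th <- core$theta
  params_hat <- decay_params(H0 = 100, b = th[1], tau = th[2], d = th[3])
  diagnostics <- character()
  if (th[1] <= 1e-6) {
    diagnostics <- c(diagnostics,
                     "series are effectively constant (b ~ 0); tau and d are not identifiable")
  }
  times <- sort(unique(c(prep[["function"]]$time, prep[["structure"]]$time)))
  gap_curve <- data.frame(time = times, gap = vertical_gap(params_hat, times))
  window <- if (th[1] > 1e-6) horizontal_window(params_hat) else NA_real_
  res <- structure(list(
    params_hat = params_hat, loss_value = core$loss, converged = core$converged,
    starts = core$starts, intervals = NULL, window = window,
    gap_curve = gap_curve, diagnostics = diagnostics, config = config
  ), class = "rgc_fit")
  if (config$bootstrap_reps > 0) {
    res$intervals <- bootstrap_ci(dataset, config, fit = res)
  }
  res
}

#' Bootstrap confidence intervals for the fitted parameters
#'
#' Percentile intervals from a seeded bootstrap, refitting from the point
#' estimate on each replicate. Two resampling schemes are available:
#'
#' * `"replicate"` — a case bootstrap at the replicate (animal) level:
#'   whole replicate series are resampled with replacement, preserving the
#'   pairing of function and structure measurements within a replicate. This
#'   is the default whenever the dataset has at least 8 replicates, because
#'   it captures every noise pathway — including the baseline-normalization
#'   error that residual resampling is structurally blind to (after
#'   normalization, baseline noise lies along directions the parameters
#'   absorb, so it perturbs the estimates while leaving almost no residual).
#' * `"residual"` — classical residual resampling within each measure, used
#'   when no replicate structure exists. Residuals are leverage-rescaled
#'   (`r_i / sqrt(1 - h_ii)` from the model Jacobian, with a global
#'   `sqrt(N/(N-3))` fallback), the structurally-zero baseline residual is
#'   excluded from the pool, and each replicate is renormalized at its own
#'   baseline.
#'
#' Intervals are expanded percentile intervals: plain percentile intervals
#' are systematically narrow at small resampling-unit counts, so the
#' quantile levels are widened from `alpha/2` to
#' `pnorm(qt(alpha/2, n-1) * sqrt(n/(n-1)))` with `n` the number of
#' resampling units (replicates, or pooled residuals), the standard
#' small-sample correction. Deterministic given `config$seed`. With
#' noiseless data the intervals have zero width under either scheme.
#'
#' @inheritParams fit_decay
#' @param level Confidence level (default 0.95).
#' @param fit Optional precomputed [fit_decay()] result for this dataset
#'   (avoids refitting).
#' @param method `"auto"` (default: replicate bootstrap when >= 8 replicates
#'   are present), `"replicate"`, or `"residual"`.
#'
#' @return A 3 x 2 matrix (rows `b`, `tau`, `d`; columns `lower`, `upper`)
#'   with the bootstrap parameter draws in attribute `reps`.
#' @export
bootstrap_ci <- function(dataset, config = fit_config(bootstrap_reps = 199),
                         level = 0.95, fit = NULL,
                         method = c("auto", "replicate", "residual")) {
  method <- match.arg(method)
  if (config$bootstrap_reps < 1) stop("bootstrap_reps must be >= 1", call. = FALSE)
  prep <- prep_fit_data(dataset, config)
  if (is.null(fit)) {
    core <- fit_core(prep, config)
    theta <- core$theta
  } else {
    theta <- with(fit$params_hat, c(b, tau, d))
  }
  n_rep <- if ("replicate" %in% names(dataset)) length(unique(dataset$replicate)) else 1L
  if (method == "auto") method <- if (n_rep >= 8L) "replicate" else "residual"
  if (method == "replicate" && n_rep < 2L) {
    stop("replicate bootstrap needs at least 2 replicates", call. = FALSE)
  }
  bd <- config$bounds
  tmax <- max(prep[["function"]]$time, prep[["structure"]]$time)
  bd$tau[2] <- min(bd$tau[2], tmax)
  lower <- c(bd$b[1], bd$tau[1], bd$d[1])
  upper <- c(bd$b[2], bd$tau[2], bd$d[2])
  refit <- function(bprep) {
    opt <- try(stats::optim(theta, fit_objective, prep = bprep, config = config,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(factr = 1e4, maxit = 300)),
               silent = TRUE)
    if (inherits(opt, "try-error")) theta else opt$par
  }

  if (method == "replicate") {
    ids <- unique(dataset$replicate)
    by_id <- split(seq_len(nrow(dataset)), dataset$replicate)
    meta <- attr(dataset, "meta")
    draws <- with_local_seed(config$seed, {
      t(vapply(seq_len(config$bootstrap_reps), function(rep) {
        pick <- sample(ids, length(ids), replace = TRUE)
        star <- dataset[unlist(by_id[as.character(pick)]), , drop = FALSE]
        star$replicate <- rep(seq_along(pick),
                              times = lengths(by_id[as.character(pick)]))
        attr(star, "meta") <- meta
        class(star) <- c("rgc_dataset", "data.frame")
        bprep <- try(prep_fit_data(star, config), silent = TRUE)
        if (inherits(bprep, "try-error")) return(theta)
        refit(bprep)
      }, numeric(3)))
    })
    return(percentile_ci(draws, level, n_units = length(ids), method = method))
  }
  resid <- pred <- list()
  for (ms in c("function", "structure")) {
    s <- prep[[ms]]
    pr <- predict_norm(theta, s$time, ms, t0 = s$time[1], floor_norm = s$floor,
                       floor_handling = config$floor_handling)
    if (!config$normalize) {
      sc <- sum(s$w * s$y * pr) / sum(s$w * pr^2)
      pr <- sc * pr
    }
    pred[[ms]] <- pr
    resid[[ms]] <- s$y - pr
  }
  # leverage-rescale residuals (Davison & Hinkley): r_i / sqrt(1 - h_ii)
  jac_row <- function(ms) {
    s <- prep[[ms]]
    sapply(seq_along(theta), function(j) {
      dx <- pmax(1e-6, abs(theta[j]) * 1e-6)
      tp <- tm <- theta
      tp[j] <- theta[j] + dx; tm[j] <- max(theta[j] - dx, 0)
      (predict_norm(tp, s$time, ms, s$time[1], s$floor, config$floor_handling) -
         predict_norm(tm, s$time, ms, s$time[1], s$floor, config$floor_handling)) /
        (tp[j] - tm[j])
    })
  }
  J <- rbind(jac_row("function"), jac_row("structure"))
  lev <- try({
    h <- rowSums((J %*% solve(crossprod(J))) * J)
    pmin(pmax(h, 0), 0.99)
  }, silent = TRUE)
  n_fun <- length(resid[["function"]])
  n_all <- n_fun + length(resid[["structure"]])
  if (!inherits(lev, "try-error")) {
    scale_all <- 1 / sqrt(1 - lev)
    resid[["function"]] <- resid[["function"]] * scale_all[seq_len(n_fun)]
    resid[["structure"]] <- resid[["structure"]] * scale_all[(n_fun + 1):n_all]
  } else if (n_all > 3) {
    infl <- sqrt(n_all / (n_all - 3))
    resid <- lapply(resid, function(r) r * infl)
  }
  # baseline residual is identically 0 under normalization; drop it from the pool
  if (config$normalize) resid <- lapply(resid, function(r) r[-1])
  draws <- with_local_seed(config$seed, {
    t(vapply(seq_len(config$bootstrap_reps), function(rep) {
      bprep <- prep
      for (ms in c("function", "structure")) {
        r <- resid[[ms]]
        n <- length(pred[[ms]])
        ystar <- pred[[ms]] + sample(r, n, replace = TRUE)
        # push the replicate through the same baseline normalization the
        # estimator applies, so baseline noise propagates coherently
        if (config$normalize) ystar <- ystar / ystar[1]
        bprep[[ms]]$y <- ystar
      }
      refit(bprep)
    }, numeric(3)))
  })
  n_pool <- length(resid[["function"]]) + length(resid[["structure"]])
  percentile_ci(draws, level, n_units = n_pool, method = method)
}

# Expanded percentile interval (small-sample-corrected quantile levels).
percentile_ci <- function(draws, level, n_units, method) {
  colnames(draws) <- c("b", "tau", "d")
  a <- (1 - level) / 2
  n <- max(n_units, 3)
  a_exp <- stats::pnorm(stats::qt(a, df = n - 1) * sqrt(n / (n - 1)))
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a_exp, 1 - a_exp),
                names = FALSE))
  dimnames(ci) <- list(c("b", "tau", "d"), c("lower", "upper"))
  attr(ci, "reps") <- draws
  attr(ci, "method") <- method
  ci
}

#' Horizontal treatment window between function and structure decay
#'
#' The time by which the function curve `F(t)` leads the structure curve
#' `P(t)` in reaching the same fractional loss — an estimate of the lifespan
#' of sick cells, i.e. the window during which a cell is dysfunctional but
#' still alive and potentially rescuable. With `loss_fraction` given, the
#' crossing times of each normalized curve at `1 - loss_fraction` are found
#' by bracketed root-finding and their difference returned. With
#' `loss_fraction = NULL` the deep-loss asymptotic offset
#' `log(d + (1-d)(1-b)^tau) / log(1-b)` is returned: once both curves decay
#' geometrically the horizontal gap is constant.
#'
#' @param params A [decay_params] object with `b > 0`.
#' @param loss_fraction Fractional loss level in `(0, 1)` at which the curves
#'   are read, or `NULL` (default) for the deep-loss asymptote.
#'
#' @return Window in time units (0 when `d = 1`, where the curves coincide).
#' @examples
#' horizontal_window(example_params())  # ~0.83 time units
#' horizontal_window(dba2j_params())    # ~1.68 months
#' @export
horizontal_window <- function(params, loss_fraction = NULL) {
  stopifnot(inherits(params, "decay_params"))
  if (params$d == 1) return(0)
  if (params$b == 0) {
    stop("horizontal window undefined for b = 0 (no decay)", call. = FALSE)
  }
  q <- 1 - params$b
  if (is.null(loss_fraction)) {
    c0 <- params$d + (1 - params$d) * pow1mb(params$b, params$tau)
    return(log(c0) / log(q))
  }
  if (!is.numeric(loss_fraction) || loss_fraction <= 0 || loss_fraction >= 1) {
    stop("loss_fraction must be in (0, 1)", call. = FALSE)
  }
  target <- 1 - loss_fraction
  cross <- function(f) {
    g <- function(t) f(t, params) / params$H0 - target
    hi <- params$tau + 1
    while (g(hi) > 0) hi <- hi * 2
    stats::uniroot(g, lower = 0, upper = hi, tol = 1e-12)$root
  }
  cross(population_index) - cross(function_index)
}

#' Vertical dysfunction gap between structure and function
#'
#' The normalized gap `[P(t) - F(t)] / H0`: the part of the function deficit
#' not explained by cell death, i.e. the recoverable dysfunction of sick but
#' surviving cells. Equals `(1 - d) * S(t) / H0`, so it peaks at `t = tau`
#' and decays with the sick compartment thereafter; it is bounded by
#' `1 - d`.
#'
#' @param params A [decay_params] object.
#' @param t Time(s) >= 0 (vectorized).
#'
#' @return Gap value(s) in `[0, 1 - d]` (normalized cells-equivalent).
#' @examples
#' vertical_gap(example_params(), 1)  # 0.15
#' @export
vertical_gap <- function(params, t) {
  stopifnot(inherits(params, "decay_params"))
  check_time(t)
  (population_index(t, params) - function_index(t, params)) / params$H0
}

#' @export
print.rgc_fit <- function(x, ...) {
  p <- x$params_hat
  cat("Decay-model fit\n")
  cat(sprintf("  b = %.4f, tau = %.4f, d = %.4f (H0 fixed at %g)\n",
              p$b, p$tau, p$d, p$H0))
  cat(sprintf("  loss = %.6g, converged: %s\n", x$loss_value, x$converged))
  if (!is.null(x$intervals)) {
    cat("  95% bootstrap intervals:\n")
    ci <- x$intervals
    attributes(ci) <- attributes(ci)[c("dim", "dimnames")]
    print(round(ci, 4))
  }
  if (!is.na(x$window)) {
    cat(sprintf("  treatment window (deep-loss horizontal offset): %.3f time units\n",
                x$window))
  }
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}
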