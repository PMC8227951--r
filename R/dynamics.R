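#' Contrast-response series
#'
#' Holds a PERG contrast transfer function: response amplitude (and
#' optionally latency) measured at a set of stimulus contrasts.
#'
#' @param contrasts Numeric vector of stimulus contrasts in `(0, 1]`,
#'   strictly increasing.
#' @param amplitudes Numeric vector of response amplitudes (signal units,
#'   >= 0), same length.
#' @param latencies Optional numeric vector of times-to-peak (ms).
#'
#' @return An object of class `contrast_series`.
#' @export
contrast_series <- function(contrasts, amplitudes, latencies = NULL) {
  stopifnot(is.numeric(contrasts), is.numeric(amplitudes))
  if (length(contrasts) != length(amplitudes)) {
    stop("contrasts and amplitudes must have equal length", call. = FALSE)
  }
  if (any(contrasts <= 0) || any(contrasts > 1)) {
    stop("contrasts must lie in (0, 1]", call. = FALSE)
  }
  if (length(contrasts) > 1L && any(diff(contrasts) <= 0)) {
    stop("contrasts must be strictly increasing", call. = FALSE)
  }
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (!is.null(latencies) && length(latencies) != length(contrasts)) {
    stop("latencies must match contrasts in length", call. = FALSE)
  }
  structure(list(contrasts = contrasts, amplitudes = amplitudes,
                 latencies = latencies), class = "contrast_series")
}

#' Contrast gain of a response series
#'
#' Least-squares slope of response versus log10 stimulus contrast, restricted
#' to a contrast range. The amplitude slope is the contrast gain; the latency
#' slope is reported descriptively (steeper latency shortening with contrast
#' reflects different temporal integration).
#'
#' @param series A [contrast_series()].
#' @param range Contrast interval `(low, high)` over which the slope is
#'   taken; defaults to the full series. At least 3 points must fall inside.
#' @param response `"amplitude"` (default) or `"latency"`.
#'
#' @return Slope in response units per log10-contrast.
#' @examples
#' cs <- contrast_series(c(0.1, 0.3, 0.6, 1), 2 + 3 * log10(c(0.1, 0.3, 0.6, 1)))
#' contrast_gain(cs)  # 3
#' @export
contrast_gain <- function(series, range = NULL,
                          response = c("amplitude", "latency")) {
  stopifnot(inherits(series, "contrast_series"))
  response <- match.arg(response)
  y <- if (response == "amplitude") series$amplitudes else series$latencies
  if (is.null(y)) stop("series has no latencies", call. = FALSE)
  if (is.null(range)) range <- range(series$contrasts)
  keep <- series$contrasts >= range[1] & series$contrasts <= range[2]
  if (sum(keep) < 3L) {
    stop("need at least 3 points within the contrast range", call. = FALSE)
  }
  x <- log10(series$contrasts[keep])
  unname(stats::coef(stats::lm(y[keep] ~ x))[2])
}

#' Detect amplitude dips in a contrast transfer function
#'
#' Flags strictly interior local minima of the amplitude series — contrasts
#' at which the response is lower than at both neighboring contrasts, as seen
#' when response generators with different spatio-temporal properties
#' interact and partially cancel. Purely descriptive: no mechanism is
#' modeled.
#'
#' @param series A [contrast_series()] with at least 3 points.
#'
#' @return Numeric vector of contrasts at which dips occur (possibly empty).
#' @export
detect_dip <- function(series) {
  stopifnot(inherits(series, "contrast_series"))
  a <- series$amplitudes
  n <- length(a)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  i <- 2:(n - 1L)
  dips <- i[a[i] < a[i - 1L] & a[i] < a[i + 1L]]
  series$contrasts[dips]
}

#' Adaptation index
#'
#' Fractional reduction of response amplitude under sustained stimulation:
#' `(initial - steady) / initial`, clipped to `[0, 1]`. 0 means no
#' adaptation; 1 means the steady-state response is fully suppressed.
#' Scale-invariant: multiplying both amplitudes by the same positive factor
#' leaves the index unchanged.
#'
#' @param initial_amplitude Response at stimulus onset (> 0).
#' @param steady_amplitude Steady-state response under sustained stimulation
#'   (>= 0).
#'
#' @return Dimensionless index in `[0, 1]`.
#' @examples
#' adaptation_index(2, 1.5)  # 0.25
#' @export
adaptation_index <- function(initial_amplitude, steady_amplitude) {
  if (!is.numeric(initial_amplitude) || initial_amplitude <= 0) {
    stop("initial_amplitude must be > 0", call. = FALSE)
  }
  if (!is.numeric(steady_amplitude) || steady_amplitude < 0) {
    stop("steady_amplitude must be >= 0", call. = FALSE)
  }
  min(1, max(0, (initial_amplitude - steady_amplitude) / initial_amplitude))
}

#' Susceptibility index under a stressor
#'
#' Fractional response reduction under a stressor,
#' `(baseline - stressed) / baseline`, together with a reversibility flag:
#' the reduction counts as reversible when the post-stressor recovery value
#' returns to within `reversibility_tol` (fractional) of baseline.
#' Reversible reduction in an otherwise normal response is the signature of
#' susceptibility probed by provocative tests.
#'
#' @param baseline Pre-stressor amplitude (> 0).
#' @param stressed Amplitude under the stressor.
#' @param recovered Post-stressor amplitude (`NULL` if not measured).
#' @param reversibility_tol Fractional tolerance for calling the response
#'   recovered (default 0.05).
#'
#' @return A list with `index` (dimensionless) and `reversible` (logical, or
#'   `NA` when no recovery measurement was supplied).
#' @examples
#' susceptibility_index(10, 7, 9.8)  # index 0.3, reversible
#' @export
susceptibility_index <- function(baseline, stressed, recovered = NULL,
                                 reversibility_tol = 0.05) {
  if (!is.numeric(baseline) || baseline <= 0) {
    stop("baseline must be > 0", call. = FALSE)
  }
  index <- (baseline - stressed) / baseline
  reversible <- if (is.null(recovered)) NA else {
    abs(recovered - baseline) <= reversibility_tol * baseline
  }
  list(index = index, reversible = reversible)
}

#' Group summary of PERG amplitude
#'
#' @param mean Group mean amplitude.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (>= 1).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(n))
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = n), class = "group_summary")
}

#' Intervention design: paired group summaries before/after an intervention
#'
#' In a `treatment` context, `*_pre`/`*_post` are amplitudes before and after
#' treatment in a control group and a diseased (manifest-pathology) group.
#' In a `stressor` context, `*_pre`/`*_post` are baseline and under-stressor
#' amplitudes; supply the pre-treatment stressor response as the `control`
#' pair and the post-treatment response as the `disease` pair to assess
#' acquired resilience, and optionally a `recovered` summary for the
#' reversibility check.
#'
#' @param control_pre,control_post,disease_pre,disease_post [group_summary]
#'   objects.
#' @param context `"treatment"` or `"stressor"`.
#' @param recovered Optional [group_summary] of the post-stressor recovery.
#'
#' @return An object of class `intervention_design`.
#' @export
intervention_design <- function(control_pre, control_post, disease_pre,
                                disease_post, context = c("treatment", "stressor"),
                                recovered = NULL) {
  context <- match.arg(context)
  for (g in list(control_pre, control_post, disease_pre, disease_post)) {
    if (!inherits(g, "group_summary")) {
      stop("all group summaries must be group_summary objects", call. = FALSE)
    }
  }
  if (!is.null(recovered) && !inherits(recovered, "group_summary")) {
    stop("recovered must be a group_summary", call. = FALSE)
  }
  structure(list(control_pre = control_pre, control_post = control_post,
                 disease_pre = disease_pre, disease_post = disease_post,
                 context = context, recovered = recovered),
            class = "intervention_design")
}

# Welch two-sample p-value from summary statistics.
welch_p <- function(g1, g2) {
  if (g1$sd == 0 && g2$sd == 0) {
    return(if (g1$mean == g2$mean) 1 else 0)
  }
  if (g1$n < 2 || g2$n < 2) return(NA_real_)
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  tstat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Classify an intervention pattern from group summaries
#'
#' Operationalizes the qualitative intervention patterns as decision rules on
#' pre/post group summaries. A group's change counts only when it is both
#' material (relative change at least `effect_threshold`) and statistically
#' supported (Welch two-sample comparison of the summaries at `alpha`).
#'
#' Treatment context: `"enhancement"` when both control and diseased groups
#' improve (the treatment boosts all cells regardless of pathology),
#' `"restoration"` when only the diseased group improves (specific recovery
#' of lost function), `"no_effect"` otherwise.
#'
#' Stressor context: `"susceptibility"` when the test condition (`disease`
#' pair) shows a material, significant, reversible drop under the stressor;
#' `"resilience"` when the reference condition (`control` pair, e.g.
#' pre-treatment) dropped but the test condition's drop is materially
#' reduced; `"no_effect"` otherwise.
#'
#' @param design An [intervention_design()].
#' @param effect_threshold Minimum relative change to count as material
#'   (default 0.1, i.e. 10%).
#' @param alpha Significance level of the Welch comparison (default 0.05).
#' @param reversibility_tol Fractional tolerance of the recovery check in
#'   stressor context (default 0.05).
#'
#' @return A list of class `intervention_class`: `pattern` (character tag),
#'   `effects` (per-group relative change and p-value), `context`.
#' @examples
#' up <- function(m) group_summary(m, 0.5, 10)
#' des <- intervention_design(up(10), up(13), up(6), up(7.8), "treatment")
#' classify_intervention(des)$pattern  # "enhancement"
#' @export
classify_intervention <- function(design, effect_threshold = 0.1, alpha = 0.05,
                                  reversibility_tol = 0.05) {
  stopifnot(inherits(design, "intervention_design"))
  chg <- function(pre, post) (post$mean - pre$mean) / pre$mean
  eff <- data.frame(
    group = c("control", "disease"),
    change = c(chg(design$control_pre, design$control_post),
               chg(design$disease_pre, design$disease_post)),
    p_value = c(welch_p(design$control_pre, design$control_post),
                welch_p(design$disease_pre, design$disease_post))
  )
  sig <- function(i) !is.na(eff$p_value[i]) && eff$p_value[i] < alpha
  if (design$context == "treatment") {
    up <- c(eff$change[1] >= effect_threshold && sig(1),
            eff$change[2] >= effect_threshold && sig(2))
    pattern <- if (all(up)) "enhancement" else if (up[2]) "restoration" else "no_effect"
  } else {
    drop_ref <- -eff$change[1]
    drop_test <- -eff$change[2]
    ref_drops <- drop_ref >= effect_threshold && sig(1)
    test_drops <- drop_test >= effect_threshold && sig(2)
    reversible <- if (is.null(design$recovered)) TRUE else {
      abs(design$recovered$mean - design$disease_pre$mean) <=
        reversibility_tol * design$disease_pre$mean
    }
    pattern <- if (test_drops && reversible) {
      "susceptibility"
    } else if (ref_drops && (drop_test <= drop_ref - effect_threshold || !test_drops)) {
      "resilience"
    } else "no_effect"
  }
  structure(list(pattern = pattern, effects = eff, context = design$context),
            class = "intervention_class")
}

#' @export
print.intervention_class <- function(x, ...) {
  cat(sprintf("Intervention pattern (%s context): %s\n", x$context, x$pattern))
  print(transform(x$effects, change = round(change, 4),
                  p_value = signif(p_value, 3)))
  invisible(x)
}
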