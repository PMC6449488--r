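#' Monte-Carlo December-January gap at a given misreporting share
#'
#' Runs the full pipeline (simulate a benchmark population, inject random MOB
#' errors for a fraction `p`, select on reported age < 60 months, measure the
#' December-January gap) `reps` times and averages.
#'
#' @param p Fraction of children with a random MOB.
#' @param config A [sim_config()]; its `p_random_mob` is overridden by `p`.
#' @param reps Number of independent replications.
#' @param standard Growth standard.
#' @param seed Base seed; replication r uses `seed + r - 1`. `NULL` uses the
#'   current RNG state.
#' @return A list: `gap` (mean over reps), `mc_se` (SD across reps /
#'   sqrt(reps); for `reps = 1` the within-run pooled SE), `gaps`, `p`.
#' @export
simulated_gap <- function(p, config, reps = 1,
                          standard = load_growth_standard(),
                          seed = config$seed) {
  stopifnot(p >= 0, p <= 1, reps >= 1)
  spec <- error_spec(p_random_mob = p,
                     year_start_month = config$year_start_month)
  gaps <- numeric(reps)
  ses <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- if (is.null(seed)) NULL else seed + r - 1
    kids <- simulate_children(cfg, standard)
    kids <- apply_random_mob(kids, spec, standard)
    kids <- apply_age_selection(kids)
    g <- december_january_gap(kids,
                              year_start_month = config$year_start_month)
    gaps[r] <- g$gap
    ses[r] <- g$se
  }
  mc_se <- if (reps > 1) stats::sd(gaps) / sqrt(reps) else ses[1]
  list(gap = mean(gaps), mc_se = mc_se, gaps = gaps, p = p)
}

#' Calibrate the random-MOB share from an observed December-January gap
#'
#' Inverts the monotone map `p -> gap(p)` by bisection on Monte-Carlo
#' evaluations: starting from the bracket `[0, p_upper]` (expanded to 1 if
#' needed), the share is bisected until the simulated gap matches
#' `target_gap` within `tolerance` or the Monte-Carlo noise floor is reached.
#' The confidence interval maps the Monte-Carlo SE of the gap through the
#' locally linear slope of `gap(p)` estimated from the search trace.
#'
#' @param target_gap Observed gap (HAZ units); must be <= 0 and within the
#'   achievable range `[gap(1), 0]`.
#' @param config A [sim_config()] describing the benchmark population.
#' @param tolerance Stop when `|gap - target| < tolerance` (HAZ units).
#' @param reps Replications per evaluation.
#' @param max_iter Maximum bisection steps.
#' @param p_upper Initial upper bracket for the share.
#' @param standard Growth standard.
#' @param seed Base seed for the Monte-Carlo evaluations.
#' @return A `calibration_result`: `p_hat`, `ci` (95% Monte-Carlo interval),
#'   `target_gap`, `achieved_gap`, `trace` (data.frame of p, gap, mc_se),
#'   `converged`.
#' @export
estimate_random_mob_share <- function(target_gap, config,
                                      tolerance = 0.005, reps = 3,
                                      max_iter = 12L, p_upper = 0.5,
                                      standard = load_growth_standard(),
                                      seed = config$seed) {
  if (target_gap > 0) {
    stop("target_gap must be <= 0 (gap = first minus last calendar month)")
  }
  trace <- list()
  evaluate <- function(p, i) {
    g <- simulated_gap(p, config, reps, standard,
                       seed = if (is.null(seed)) NULL else seed + 1000L * i)
    trace[[length(trace) + 1L]] <<- data.frame(p = p, gap = g$gap,
                                               mc_se = g$mc_se)
    g
  }
  if (target_gap == 0) {
    return(.calibration_result(0, c(0, 0), target_gap, 0,
                               data.frame(p = 0, gap = 0, mc_se = 0), TRUE))
  }
  lo <- 0; hi <- p_upper
  g_hi <- evaluate(hi, 0L)
  it <- 1L
  while (g_hi$gap > target_gap && hi < 1) {  # gap not negative enough
    hi <- min(1, 2 * hi)
    g_hi <- evaluate(hi, it)
    it <- it + 1L
  }
  if (g_hi$gap - 2 * g_hi$mc_se > target_gap) {
    stop(sprintf(
      "target gap %.3f is outside the achievable range [%.3f, 0]",
      target_gap, g_hi$gap))
  }
  p_mid <- hi
  g_mid <- g_hi
  converged <- abs(g_hi$gap - target_gap) < tolerance
  while (!converged && it <= max_iter) {
    p_mid <- (lo + hi) / 2
    g_mid <- evaluate(p_mid, it)
    if (abs(g_mid$gap - target_gap) < tolerance) {
      converged <- TRUE
      break
    }
    if (g_mid$gap > target_gap) lo <- p_mid else hi <- p_mid
    it <- it + 1L
  }
  tr <- do.call(rbind, trace)
  # local slope of gap(p) from the trace (gap(0) = 0 is known exactly)
  slope <- stats::coef(stats::lm(gap ~ p + 0,
                                 data = rbind(tr, data.frame(
                                   p = 0, gap = 0, mc_se = NA))))[["p"]]
  half <- 1.96 * g_mid$mc_se / abs(slope)
  ci <- c(max(0, p_mid - half), min(1, p_mid + half))
  .calibration_result(p_mid, ci, target_gap, g_mid$gap, tr, converged)
}

.calibration_result <- function(p_hat, ci, target_gap, achieved_gap, trace,
                                converged) {
  structure(list(p_hat = p_hat, ci = ci, target_gap = target_gap,
                 achieved_gap = achieved_gap, trace = trace,
                 converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> p_hat = %.3f (95%% MC interval %.3f-%.3f)\n",
    x$p_hat, x$ci[1], x$ci[2]))
  cat(sprintf("  target gap %.3f, achieved %.3f after %d evaluations (%s)\n",
              x$target_gap, x$achieved_gap, nrow(x$trace),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Stunting and severe-stunting rates
#'
#' Share of children with HAZ strictly below -2 (stunted) and below -3
#' (severely stunted), on either the true-age or reported-age basis. For the
#' reported basis the reported-age sample selection (< 60 months) is applied
#' first, as in survey practice.
#'
#' @param tab Child table.
#' @param basis `"reported"` or `"true"`.
#' @param cutoffs Two z-score cutoffs, default `c(-2, -3)`.
#' @return Named numeric vector, percentages: `stunting`, `severe`.
#' @export
stunting_rates <- function(tab, basis = c("reported", "true"),
                           cutoffs = c(-2, -3)) {
  basis <- match.arg(basis)
  if (basis == "reported") {
    tab <- apply_age_selection(tab)
    haz <- tab$haz_reported
  } else {
    haz <- tab$haz_true
  }
  haz <- haz[!is.na(haz)]
  c(stunting = 100 * mean(haz < cutoffs[1]),
    severe = 100 * mean(haz < cutoffs[2]))
}
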