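#' Define an in-utero shock scenario
#'
#' A monsoon-type event lasting two adjacent calendar months that harms only
#' children born in those months: exposed children's attained height is
#' reduced by `effect_fraction` of the reference birth length (a fixed cm
#' deduction at every age), and, for the test-score outcome, their raw score
#' is reduced by the same fraction.
#'
#' @param months Ordered pair of adjacent calendar months (e.g. `c(11, 12)`
#'   for November-December).
#' @param outcome `"haz"` or `"test_score"`.
#' @param effect_fraction Fraction of birth length (or raw score) deducted
#'   for exposed children; default 0.03.
#' @param test_score_mean,test_score_sd Raw test-score distribution.
#' @param proportional If `TRUE` the height deduction is `effect_fraction`
#'   of the child's current height rather than of the reference birth
#'   length. This variant implies an age-growing deduction and a much larger
#'   average treatment effect; it is provided for sensitivity analysis only.
#' @return A list of class `shock_scenario`.
#' @export
shock_scenario <- function(months = c(6, 7),
                           outcome = c("haz", "test_score"),
                           effect_fraction = 0.03,
                           test_score_mean = 50, test_score_sd = 10,
                           proportional = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(length(months) == 2, all(months %in% 1:12),
            months[2] == months[1] + 1,  # adjacent within a calendar year
            effect_fraction >= 0, effect_fraction < 1,
            test_score_sd > 0)
  structure(list(months = as.integer(months), outcome = outcome,
                 effect_fraction = effect_fraction,
                 test_score_mean = test_score_mean,
                 test_score_sd = test_score_sd,
                 proportional = proportional),
            class = "shock_scenario")
}

#' Apply an in-utero shock to a simulated population
#'
#' Flags exposure by true and by reported birth month, deducts the shock
#' effect from exposed children's heights, and recomputes both HAZ columns.
#' Can be applied before or after the misreporting operators (the deduction
#' depends only on the true birth month, and [apply_random_mob()] refreshes
#' the reported-exposure flag), but must be applied exactly once.
#'
#' @param tab Child table.
#' @param scenario A [shock_scenario()].
#' @param standard Growth standard used to recompute HAZ (and whose birth
#'   median sets the deduction).
#' @return `tab` with `exposed_true`, `exposed_reported` and updated
#'   `height_cm`, `haz_true`, `haz_reported`.
#' @export
apply_inutero_shock <- function(tab, scenario,
                                standard = load_growth_standard()) {
  stopifnot(inherits(scenario, "shock_scenario"))
  if (!is.null(tab$exposed_true)) {
    stop("shock already applied to this table")
  }
  true_month <- .cal_parts(tab$true_birth_date)$month
  tab$exposed_true <- true_month %in% scenario$months
  if (scenario$proportional) {
    tab$height_cm[tab$exposed_true] <-
      tab$height_cm[tab$exposed_true] * (1 - scenario$effect_fraction)
  } else {
    deduction <- scenario$effect_fraction * gs_median(standard, 0)
    tab$height_cm[tab$exposed_true] <-
      tab$height_cm[tab$exposed_true] - deduction
  }
  tab$haz_true <- compute_haz(standard, tab$height_cm, tab$true_age_days)
  tab$exposed_reported <-
    .cal_parts(tab$reported_birth_date)$month %in% scenario$months
  tab$haz_reported <- .haz_or_na(standard, tab$height_cm,
                                 tab$reported_age_days)
  tab
}

#' Simulate standardized test scores
#'
#' Draws raw scores Normal(`test_score_mean`, `test_score_sd`), reduces
#' exposed children's raw scores by `effect_fraction`, and standardizes by
#' the overall sample mean and SD of the table at hand.
#'
#' @param tab Child table with `exposed_true` (from [apply_inutero_shock()]).
#' @param scenario A [shock_scenario()].
#' @return `tab` with `test_score_raw` and `test_score` (standardized).
#' @export
simulate_test_scores <- function(tab, scenario) {
  stopifnot(inherits(scenario, "shock_scenario"))
  if (is.null(tab$exposed_true)) {
    stop("apply_inutero_shock() must run before simulate_test_scores()")
  }
  raw <- stats::rnorm(nrow(tab), scenario$test_score_mean,
                      scenario$test_score_sd)
  raw[tab$exposed_true] <- raw[tab$exposed_true] *
    (1 - scenario$effect_fraction)
  tab$test_score_raw <- raw
  tab$test_score <- (raw - mean(raw)) / stats::sd(raw)
  tab
}

#' Estimate the exposure effect on an outcome
#'
#' OLS slope of the outcome on the reported-exposure indicator (for a binary
#' regressor this equals the difference in group means). Classification into
#' exposure uses the *reported* birth month, which is where misreporting bias
#' enters.
#'
#' @param tab Child table (post-selection) with `exposed_reported`.
#' @param outcome `"haz"` (uses `haz_reported`) or `"test_score"`.
#' @return A list: `estimate`, `se`, `n`, `n_exposed`.
#' @export
estimate_exposure_effect <- function(tab, outcome = c("haz", "test_score")) {
  outcome <- match.arg(outcome)
  y <- if (outcome == "haz") tab$haz_reported else tab$test_score
  x <- tab$exposed_reported
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  if (all(x) || !any(x)) {
    stop("degenerate exposure: all children ",
         if (all(x)) "exposed" else "unexposed")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(estimate = unname(sm[2, 1]), se = unname(sm[2, 2]),
       n = length(y), n_exposed = sum(x))
}

#' Bias in the estimated shock effect across misreporting rates
#'
#' For each misreporting share `p` runs the full pipeline -- simulate the
#' benchmark population, apply the in-utero shock, inject random MOB errors,
#' select on reported age, (for the test-score outcome) draw scores -- and
#' estimates the exposure effect from the reported classification. The
#' estimate at `p = 0` is the true average treatment effect.
#'
#' @param scenario A [shock_scenario()].
#' @param p_grid Misreporting shares to evaluate.
#' @param config A [sim_config()].
#' @param standard Growth standard.
#' @param n_per_point Children simulated per grid point (default
#'   `config$n_children`).
#' @param common_seed If `TRUE` (default) the same seed is reused across grid
#'   points, so the underlying population is identical and only the error
#'   draw varies (a variance-reduction device for the shape of the curve).
#' @return A `bias_curve`: data.frame `curve` (p, estimate, se, n) plus
#'   `true_effect`, `scenario`.
#' @export
bias_sweep <- function(scenario, p_grid, config,
                       standard = load_growth_standard(),
                       n_per_point = config$n_children,
                       common_seed = TRUE) {
  stopifnot(all(p_grid >= 0), all(p_grid <= 1))
  cfg <- config
  cfg$n_children <- as.integer(n_per_point)
  rows <- lapply(seq_along(p_grid), function(i) {
    p <- p_grid[i]
    cfg$seed <- if (is.null(config$seed)) {
      NULL
    } else if (common_seed) config$seed else config$seed + i
    kids <- simulate_children(cfg, standard)
    kids <- apply_inutero_shock(kids, scenario, standard)
    kids <- apply_random_mob(
      kids, error_spec(p_random_mob = p,
                       year_start_month = cfg$year_start_month), standard)
    kids <- apply_age_selection(kids)
    if (scenario$outcome == "test_score") {
      kids <- simulate_test_scores(kids, scenario)
    }
    est <- estimate_exposure_effect(kids, scenario$outcome)
    data.frame(p = p, estimate = est$estimate, se = est$se, n = est$n)
  })
  curve <- do.call(rbind, rows)
  true_effect <- if (any(p_grid == 0)) {
    curve$estimate[match(0, curve$p)]
  } else {
    NA_real_
  }
  structure(list(curve = curve, true_effect = true_effect,
                 scenario = scenario), class = "bias_curve")
}

#' @export
print.bias_curve <- function(x, ...) {
  cat(sprintf(
    "<bias_curve> %s outcome, shock months %d-%d, true effect %.3f\n",
    x$scenario$outcome, x$scenario$months[1], x$scenario$months[2],
    if (is.na(x$true_effect)) NA else x$true_effect))
  print(utils::head(x$curve, 12))
  invisible(x)
}

#' Misreporting rate at which a shock estimate reverses sign
#'
#' Sweeps the misreporting share on a fine grid and reports the smallest
#' share at which the estimated effect of the shock crosses zero. For a
#' late-year (e.g. November-December) shock the children misclassified as
#' exposed are older and taller than their reported age implies, so the
#' upward bias eventually overturns the true negative effect. The crossing is
#' located by linear interpolation on a least-squares line fitted in a window
#' around the sign change, with a Monte-Carlo band from the estimate SEs
#' mapped through the local slope.
#'
#' @param scenario A [shock_scenario()] (HAZ outcome).
#' @param config A [sim_config()].
#' @param p_max Upper end of the sweep.
#' @param step Grid step (<= 0.01 recommended).
#' @param n_per_point Children per grid point.
#' @param standard Growth standard.
#' @return A list: `p_star` (`NA` when no crossing -- `no_reversal = TRUE`),
#'   `band` (approximate 95% interval), `sweep` (the `bias_curve`).
#' @export
reversal_threshold <- function(scenario, config, p_max = 0.4, step = 0.01,
                               n_per_point = config$n_children,
                               standard = load_growth_standard()) {
  p_grid <- seq(0, p_max, by = step)
  sweep <- bias_sweep(scenario, p_grid, config, standard, n_per_point,
                      common_seed = FALSE)
  cv <- sweep$curve
  pos <- which(cv$estimate > 0)
  if (length(pos) == 0 || pos[1] == 1) {
    no_rev <- length(pos) == 0
    return(list(p_star = if (no_rev) NA_real_ else 0,
                band = c(NA_real_, NA_real_),
                no_reversal = no_rev, sweep = sweep))
  }
  cross <- pos[1]
  win <- cv[abs(cv$p - cv$p[cross]) <= 5 * step + 1e-9, ]
  fit <- stats::lm(estimate ~ p, data = win)
  b <- stats::coef(fit)
  p_star <- unname(-b[1] / b[2])
  se_local <- stats::median(win$se)
  half <- 1.96 * se_local / abs(b[2])
  list(p_star = p_star, band = c(p_star - half, p_star + half),
       no_reversal = FALSE, sweep = sweep)
}
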