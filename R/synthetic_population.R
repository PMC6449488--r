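#' Simulation configuration
#'
#' Collects every parameter of the synthetic survey population in one list.
#' Defaults describe the benchmark study population: girls with true ages
#' uniform over 0-71 completed months (so that children truly older than 59
#' months can enter the under-five sample once mis-aged downward), surveyed
#' uniformly over one calendar year, with heights drawn from the transformed
#' reference curves of [build_benchmark()].
#'
#' @param n_children Number of children to simulate.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param true_age_range_months Half-open interval `[lo, hi)` of true ages in
#'   months; default `c(0, 72)`.
#' @param survey_year Calendar year over which survey dates are uniform.
#' @param n_surveys,clusters_per_survey Survey-structure sizes.
#' @param velocity_reduction,sd_add,sd_mult,sd_order Benchmark transform
#'   parameters, see [build_benchmark()].
#' @param p_random_mob Fraction of children whose reported birth month and day
#'   are random within the true (local) birth year.
#' @param q_round_age Fraction subject to asymmetric round-age rounding.
#' @param year_start_month First month (1-12) of the local calendar year;
#'   1 for the Gregorian calendar, 4 for a Nepali-style calendar.
#' @param wealth_effect_cm,rural_effect_cm Additive effects (cm) of the two
#'   household covariates on height; defaults 0, so covariates carry no
#'   signal unless requested.
#' @param cluster_sd_cm SD (cm) of a cluster-level random height shift;
#'   default 0 (no intra-cluster correlation).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_children = 100000L,
                       seed = NULL,
                       true_age_range_months = c(0, 72),
                       survey_year = 2015L,
                       n_surveys = 1L,
                       clusters_per_survey = 50L,
                       velocity_reduction = c(0.07, 0.21, 0.10),
                       sd_add = 2, sd_mult = 0.85,
                       sd_order = "add_first",
                       p_random_mob = 0,
                       q_round_age = 0,
                       year_start_month = 1L,
                       wealth_effect_cm = 0,
                       rural_effect_cm = 0,
                       cluster_sd_cm = 0) {
  stopifnot(n_children > 0,
            length(true_age_range_months) == 2,
            true_age_range_months[1] >= 0,
            true_age_range_months[2] > true_age_range_months[1],
            p_random_mob >= 0, p_random_mob <= 1,
            q_round_age >= 0, q_round_age <= 1,
            year_start_month %in% 1:12,
            n_surveys >= 1, clusters_per_survey >= 1)
  structure(list(
    n_children = as.integer(n_children), seed = seed,
    true_age_range_months = true_age_range_months,
    survey_year = as.integer(survey_year),
    n_surveys = as.integer(n_surveys),
    clusters_per_survey = as.integer(clusters_per_survey),
    velocity_reduction = velocity_reduction,
    sd_add = sd_add, sd_mult = sd_mult, sd_order = sd_order,
    p_random_mob = p_random_mob, q_round_age = q_round_age,
    year_start_month = as.integer(year_start_month),
    wealth_effect_cm = wealth_effect_cm,
    rural_effect_cm = rural_effect_cm,
    cluster_sd_cm = cluster_sd_cm), class = "sim_config")
}

#' Simulate a cross-sectional child anthropometry survey
#'
#' Draws one synthetic survey population: true ages uniform (by day) over the
#' configured range, survey dates uniform over the survey year, birth dates
#' derived (so the true day of birth is uniform within each month's actual
#' length and the true birth month is independent of age), heights Normal
#' around the benchmark curves, and HAZ computed against the untransformed
#' reference standard. Reported dates are initialised to the truth; the error
#' operators ([apply_random_mob()], [apply_round_age_rounding()]) modify
#' them.
#'
#' @param config A [sim_config()].
#' @param standard A `growth_standard`; default the packaged girls' standard.
#' @return A `data.frame`, one row per child, with columns `child_id`,
#'   `survey_id`, `cluster_id`, `survey_date`, `true_birth_date`,
#'   `reported_birth_date`, `true_age_days`, `reported_age_days`,
#'   `height_cm`, `haz_true`, `haz_reported`, `misreport_flag`, `wealth`,
#'   `rural`.
#' @examples
#' kids <- simulate_children(sim_config(n_children = 1000, seed = 1))
#' mean(kids$haz_true)
#' @export
simulate_children <- function(config, standard = load_growth_standard()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_children
  bm <- build_benchmark(standard, config$velocity_reduction,
                        config$sd_add, config$sd_mult, config$sd_order)

  lo_days <- config$true_age_range_months[1] * DAYS_PER_MONTH
  hi_days <- min(config$true_age_range_months[2] * DAYS_PER_MONTH,
                 standard$max_age_days + 1)
  true_age_days <- as.integer(floor(stats::runif(n, lo_days, hi_days)))

  year0 <- as.Date(sprintf("%d-01-01", config$survey_year))
  ndays_year <- as.integer(as.Date(sprintf("%d-01-01",
                                           config$survey_year + 1)) - year0)
  survey_date <- year0 + as.integer(floor(stats::runif(n) * ndays_year))
  true_birth_date <- survey_date - true_age_days

  tab <- data.frame(
    child_id = seq_len(n),
    survey_date = survey_date,
    true_birth_date = true_birth_date,
    true_age_days = true_age_days)
  tab <- assign_survey_structure(tab, config$n_surveys,
                                 config$clusters_per_survey,
                                 cluster_sd_cm = config$cluster_sd_cm)

  height <- stats::rnorm(n, bm_mu(bm, true_age_days),
                         bm_sigma(bm, true_age_days)) +
    config$wealth_effect_cm * tab$wealth +
    config$rural_effect_cm * tab$rural +
    tab$.cluster_shift_cm
  tab$.cluster_shift_cm <- NULL
  tab$height_cm <- height
  tab$haz_true <- compute_haz(standard, height, true_age_days)
  tab$reported_birth_date <- true_birth_date
  tab$reported_age_days <- true_age_days
  tab$haz_reported <- tab$haz_true
  tab$misreport_flag <- FALSE
  tab
}

#' Partition children into surveys and clusters
#'
#' Randomly assigns children to `n_surveys` surveys and, within each survey,
#' to `clusters_per_survey` enumeration-area clusters, with sizes as equal as
#' possible. Also draws two household covariates (a standard-normal wealth
#' index and a rural indicator) and an optional cluster-level height shift
#' used to induce intra-cluster correlation.
#'
#' @param tab Child table (any data.frame with one row per child).
#' @param n_surveys,clusters_per_survey Sizes, both >= 1.
#' @param rural_share Probability a child lives in a rural cluster.
#' @param cluster_sd_cm SD of the Normal cluster-level height shift (cm);
#'   the shift is returned in column `.cluster_shift_cm` for the caller to
#'   apply to heights.
#' @return `tab` with columns `survey_id`, `cluster_id`, `wealth`, `rural`
#'   and `.cluster_shift_cm` added.
#' @export
assign_survey_structure <- function(tab, n_surveys = 1L,
                                    clusters_per_survey = 50L,
                                    rural_share = 0.35,
                                    cluster_sd_cm = 0) {
  stopifnot(n_surveys >= 1, clusters_per_survey >= 1)
  n <- nrow(tab)
  tab$survey_id <- sample(rep_len(seq_len(n_surveys), n))
  within <- integer(n)
  for (s in seq_len(n_surveys)) {  # balance cluster sizes within each survey
    idx <- which(tab$survey_id == s)
    within[idx] <- sample(rep_len(seq_len(clusters_per_survey), length(idx)))
  }
  tab$cluster_id <- (tab$survey_id - 1L) * clusters_per_survey + within
  tab$wealth <- stats::rnorm(n)
  tab$rural <- stats::rbinom(n, 1L, rural_share)
  n_clusters <- n_surveys * clusters_per_survey
  shift <- if (cluster_sd_cm > 0) {
    stats::rnorm(n_clusters, 0, cluster_sd_cm)
  } else {
    numeric(n_clusters)
  }
  tab$.cluster_shift_cm <- shift[tab$cluster_id]
  tab
}
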