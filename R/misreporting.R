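#' Reporting-error specification
#'
#' Parameters of the two age-misreporting mechanisms: random month of birth
#' within the true (local) birth year, and asymmetric rounding of age down
#' toward completed years.
#'
#' @param p_random_mob Fraction of children whose reported birth month and
#'   day are random within the local calendar year of the true birth date.
#'   The random month is uniform over all 12 months (it may coincide with
#'   the true month, so the effective displacement probability is
#'   `11/12 * p_random_mob`).
#' @param q_round_age Fraction of children whose reported age is their age in
#'   completed years plus `k` months, `k` drawn from `rounding_weights`.
#' @param rounding_weights Probability weights over added months `k = 0..11`;
#'   must be non-increasing (respondents are least likely to add the most
#'   months). Default: linearly declining weights `(12 - k) / 78`.
#' @param year_start_month First month of the local calendar year (1-12).
#' @param redraw_future If `TRUE`, random birth dates falling after the
#'   survey date are redrawn; the default keeps them (the resulting negative
#'   reported age is removed by [apply_age_selection()], mimicking
#'   implausible-record exclusion).
#' @param use_day_15 If `TRUE`, the reported day of a random month is 15
#'   (the DHS convention for unknown days) instead of uniform over the month.
#' @return A list of class `error_spec`.
#' @export
error_spec <- function(p_random_mob = 0,
                       q_round_age = 0,
                       rounding_weights = (12:1) / 78,
                       year_start_month = 1L,
                       redraw_future = FALSE,
                       use_day_15 = FALSE) {
  stopifnot(p_random_mob >= 0, p_random_mob <= 1,
            q_round_age >= 0, q_round_age <= 1,
            length(rounding_weights) == 12,
            all(rounding_weights >= 0),
            year_start_month %in% 1:12)
  rounding_weights <- rounding_weights / sum(rounding_weights)
  if (any(diff(rounding_weights) > 1e-12)) {
    stop("rounding_weights must be non-increasing in added months")
  }
  structure(list(p_random_mob = p_random_mob, q_round_age = q_round_age,
                 rounding_weights = rounding_weights,
                 year_start_month = as.integer(year_start_month),
                 redraw_future = redraw_future, use_day_15 = use_day_15),
            class = "error_spec")
}

# Recompute reported ages, reported HAZ and (when a shock has been applied)
# the reported-exposure flag after reported birth dates changed.
.refresh_reported <- function(tab, standard) {
  tab$reported_age_days <- as.integer(tab$survey_date -
                                        tab$reported_birth_date)
  tab$haz_reported <- .haz_or_na(standard, tab$height_cm,
                                 tab$reported_age_days)
  if (!is.null(tab$exposed_true)) {
    shock_months <- sort(unique(
      .cal_parts(tab$true_birth_date)$month[tab$exposed_true]))
    tab$exposed_reported <-
      .cal_parts(tab$reported_birth_date)$month %in% shock_months
  }
  tab
}

#' Inject random month-of-birth reporting errors
#'
#' A Bernoulli(`p_random_mob`) subset of children is assigned a reported
#' birth month uniform over the 12 months of the local calendar year
#' containing the true birth date, and a reported day uniform within that
#' month's actual length (or day 15 when `use_day_15`). All other children
#' report the truth. Reported ages and reported-age HAZ are recomputed;
#' reported ages outside the reference range yield `NA` HAZ and are removed
#' by [apply_age_selection()].
#'
#' Each child carries at most one reporting error: the subset is drawn among
#' children whose record is still truthful, rescaled so that the *marginal*
#' share of the whole table equals `p_random_mob` even when another error
#' operator ran first. Applying both operators therefore yields a mixture
#' with exact shares, and each artifact is unchanged by the presence of the
#' other.
#'
#' @param tab Child table from [simulate_children()].
#' @param spec An [error_spec()].
#' @param standard The `growth_standard` used for HAZ.
#' @return `tab` with `reported_birth_date`, `reported_age_days`,
#'   `haz_reported` and `misreport_flag` updated.
#' @export
apply_random_mob <- function(tab, spec, standard = load_growth_standard()) {
  stopifnot(inherits(spec, "error_spec"))
  p <- spec$p_random_mob
  if (p > 0 && nrow(tab) > 0) {
    mis <- .draw_error_subset(tab$misreport_flag, p)
    if (any(mis)) {
      tab$reported_birth_date[mis] <-
        .draw_random_birth_date(tab$true_birth_date[mis],
                                tab$survey_date[mis], spec)
      tab$misreport_flag <- tab$misreport_flag | mis
    }
  }
  .refresh_reported(tab, standard)
}

# Bernoulli subset of marginal share `p` drawn among still-truthful records,
# so error operators compose into a mixture with exact shares.
.draw_error_subset <- function(already_flagged, p) {
  free <- !already_flagged
  share_free <- mean(free)
  if (share_free <= 0) return(rep(FALSE, length(free)))
  p_cond <- p / share_free
  if (p_cond > 1) {
    warning("requested error share exceeds the remaining truthful share; ",
            "flagging all remaining records")
    p_cond <- 1
  }
  free & stats::runif(length(free)) < p_cond
}

.draw_random_birth_date <- function(true_birth_date, survey_date, spec) {
  m <- length(true_birth_date)
  parts <- .cal_parts(true_birth_date)
  start_year <- .local_year_start(parts$year, parts$month,
                                  spec$year_start_month)
  draw <- function(idx) {
    k <- sample.int(12L, length(idx), replace = TRUE)
    off <- spec$year_start_month - 1L + k - 1L
    gm <- (off %% 12L) + 1L
    gy <- start_year[idx] + off %/% 12L
    first <- .month_first_day(gy, gm)
    day_off <- if (spec$use_day_15) {
      14L
    } else {
      as.integer(floor(stats::runif(length(idx)) * .month_length(gy, gm)))
    }
    as.Date(first + day_off, origin = "1970-01-01")
  }
  out <- draw(seq_len(m))
  if (spec$redraw_future) {
    for (i in 1:200) {
      bad <- which(out > survey_date)
      if (length(bad) == 0) break
      out[bad] <- draw(bad)
    }
    # children surveyed days into their birth year may have almost no valid
    # (month, day) draws; after the rejection budget they report the truth
    bad <- which(out > survey_date)
    if (length(bad) > 0) out[bad] <- true_birth_date[bad]
  }
  out
}

#' Inject asymmetric round-age rounding
#'
#' A Bernoulli(`q_round_age`) subset reports an age equal to the true age in
#' completed years plus `k` months, with `k` drawn from the non-increasing
#' `rounding_weights`, so ages are rounded down toward completed years and
#' round ages are over-represented. The reported birth date is moved to match
#' the rounded age. This operator reproduces the round-age artifact; it is an
#' extension of the error model beyond the random-MOB mechanism used for the
#' calendar-year calibration.
#'
#' Like [apply_random_mob()], the subset is drawn among still-truthful
#' records with the marginal share rescaled to `q_round_age`, so the two
#' operators compose without diluting each other's artifact.
#'
#' @inheritParams apply_random_mob
#' @return `tab` with reported dates, ages and HAZ updated.
#' @export
apply_round_age_rounding <- function(tab, spec,
                                     standard = load_growth_standard()) {
  stopifnot(inherits(spec, "error_spec"))
  q <- spec$q_round_age
  if (q > 0 && nrow(tab) > 0) {
    sel <- .draw_error_subset(tab$misreport_flag, q)
    if (any(sel)) {
      years <- tab$true_age_days[sel] %/% (12 * DAYS_PER_MONTH)
      k <- sample.int(12L, sum(sel), replace = TRUE,
                      prob = spec$rounding_weights) - 1L
      rep_months <- years * 12 + k
      # ceiling keeps floor(rep_days / days-per-month) == rep_months exactly
      rep_days <- as.integer(ceiling(rep_months * DAYS_PER_MONTH))
      tab$reported_birth_date[sel] <- tab$survey_date[sel] - rep_days
      tab$misreport_flag <- tab$misreport_flag | sel
    }
  }
  .refresh_reported(tab, standard)
}

#' Apply reported-age sample selection
#'
#' Keeps records with `0 <= reported age < max_reported_months`, mirroring
#' survey selection on the *reported* age: children truly 60+ months old stay
#' in the sample when mis-aged downward, children truly under 60 months drop
#' out when mis-aged upward, and implausible records (reported birth after
#' the survey date) are removed.
#'
#' @param tab Child table with `reported_age_days`.
#' @param max_reported_months Upper (open) bound on reported age in months.
#' @return The filtered table.
#' @export
apply_age_selection <- function(tab, max_reported_months = 60) {
  keep <- tab$reported_age_days >= 0 &
    tab$reported_age_days < max_reported_months * DAYS_PER_MONTH
  tab[keep, , drop = FALSE]
}
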