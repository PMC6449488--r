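#' Mean HAZ by reported month of birth
#'
#' Cell means of reported-age HAZ by reported birth month, keyed 1-12 in the
#' local calendar (index 1 = `year_start_month`). Under random-within-year
#' MOB misreporting this profile is an upward straight line ending in a
#' discrete drop from the last month of the calendar to the first.
#'
#' @param tab Child table with `reported_birth_date` and a HAZ column.
#' @param haz_col Name of the HAZ column (default `"haz_reported"`).
#' @param year_start_month First month of the local calendar year.
#' @return A data.frame with columns `month_index` (1-12, local calendar),
#'   `calendar_month` (Gregorian 1-12), `n`, `mean_haz`, `se`. Empty cells
#'   have `NA` mean and are flagged by `n = 0`.
#' @export
mean_haz_by_mob <- function(tab, haz_col = "haz_reported",
                            year_start_month = 1L) {
  if (!haz_col %in% names(tab)) stop("column not found: ", haz_col)
  month <- .cal_parts(tab$reported_birth_date)$month
  idx <- .local_month_index(month, year_start_month)
  .cell_profile(tab[[haz_col]], idx, 12L,
                calendar_month = ((year_start_month - 1L + 0:11) %% 12L) + 1L)
}

.cell_profile <- function(haz, idx, k, calendar_month = NULL) {
  ok <- !is.na(haz)
  n <- tabulate(idx[ok], nbins = k)
  s <- vapply(seq_len(k), function(i) sum(haz[ok][idx[ok] == i]), 0)
  ss <- vapply(seq_len(k), function(i) sum(haz[ok][idx[ok] == i]^2), 0)
  mean_haz <- ifelse(n > 0, s / n, NA_real_)
  v <- ifelse(n > 1, (ss - n * mean_haz^2) / (n - 1), NA_real_)
  out <- data.frame(month_index = seq_len(k), n = n, mean_haz = mean_haz,
                    se = sqrt(pmax(v, 0) / pmax(n, 1)))
  out$se[n < 2] <- NA_real_
  if (!is.null(calendar_month)) {
    out <- cbind(out[1], calendar_month = calendar_month, out[-1])
  }
  out
}

.gap_from_profile <- function(prof, definition) {
  first <- prof[1, ]
  last <- prof[nrow(prof), ]
  if (first$n == 0 || last$n == 0) {
    stop("empty endpoint cell; cannot form a ", definition, " gap")
  }
  # pooled two-sample SE
  se <- if (first$n > 1 && last$n > 1) {
    sp2 <- ((first$n - 1) * (first$se^2 * first$n) +
              (last$n - 1) * (last$se^2 * last$n)) /
      (first$n + last$n - 2)
    sqrt(sp2 * (1 / first$n + 1 / last$n))
  } else {
    NA_real_
  }
  structure(list(gap = first$mean_haz - last$mean_haz, se = se,
                 n_left = first$n, n_right = last$n,
                 definition = definition),
            class = "gap_estimate")
}

#' @export
print.gap_estimate <- function(x, ...) {
  cat(sprintf("<gap_estimate: %s> gap = %.4f (se %.4f), n = %d / %d\n",
              x$definition, x$gap, x$se, x$n_left, x$n_right))
  invisible(x)
}

#' December-January gap in mean HAZ
#'
#' `gap = mean(HAZ | reported MOB = first month of the calendar) -
#' mean(HAZ | reported MOB = last month)`; for the Gregorian calendar this is
#' January minus December, the diagnostic for random-within-year MOB error
#' (negative when misreporting is present).
#'
#' @inheritParams mean_haz_by_mob
#' @return A `gap_estimate`: `gap`, pooled two-sample `se`, endpoint cell
#'   counts `n_left`/`n_right` and a definition tag.
#' @export
december_january_gap <- function(tab, haz_col = "haz_reported",
                                 year_start_month = 1L) {
  prof <- mean_haz_by_mob(tab, haz_col, year_start_month)
  .gap_from_profile(prof, "december_january")
}

#' Mean HAZ by months past a round age
#'
#' Cell means of HAZ by `d = reported age in months mod 12` (d = 0 is a round
#' age: 0, 12, 24, ... months). Asymmetric rounding of ages down toward
#' completed years produces a sawtooth: HAZ steps up at round ages and drifts
#' down toward `d = 11`.
#'
#' @inheritParams mean_haz_by_mob
#' @return A data.frame with `months_past_round` (0-11), `n`, `mean_haz`,
#'   `se`.
#' @export
mean_haz_by_months_past_round <- function(tab, haz_col = "haz_reported") {
  if (!haz_col %in% names(tab)) stop("column not found: ", haz_col)
  d <- (tab$reported_age_days %/% DAYS_PER_MONTH) %% 12
  out <- .cell_profile(tab[[haz_col]], as.integer(d) + 1L, 12L)
  names(out)[names(out) == "month_index"] <- "months_past_round"
  out$months_past_round <- out$months_past_round - 1L
  out
}

#' Round-age gap in mean HAZ
#'
#' `mean(HAZ | d = 0) - mean(HAZ | d = 11)`. Note that unlike the
#' December-January gap this quantity is confounded by genuine growth
#' faltering: it is positive in a faltering population even with perfectly
#' reported ages, because mean HAZ declines with age.
#'
#' @inheritParams mean_haz_by_mob
#' @return A `gap_estimate`.
#' @export
round_age_gap <- function(tab, haz_col = "haz_reported") {
  prof <- mean_haz_by_months_past_round(tab, haz_col)
  .gap_from_profile(prof, "round_age")
}

#' Number of births by reported age in months
#'
#' @param tab Child table with `reported_age_days`.
#' @param max_months Ages counted are `0 .. max_months - 1`.
#' @return A data.frame with `age_months` and `n`. Age heaping at multiples
#'   of 12 shows up as peaks with quasi-linearly declining shoulders.
#' @export
births_by_age_histogram <- function(tab, max_months = 60L) {
  m <- as.integer(tab$reported_age_days %/% DAYS_PER_MONTH)
  n <- tabulate(m[m >= 0 & m < max_months] + 1L, nbins = max_months)
  data.frame(age_months = 0:(max_months - 1L), n = n)
}

#' Myers blended index of terminal-digit preference
#'
#' The classic blended method adapted to ages in months 0-59: counts at each
#' terminal digit are summed over the ten 10-month windows with blending
#' weights `(d + 1)` and `(9 - d)`, and the index is half the sum of absolute
#' deviations of the blended digit distribution from 10%. Ranges from 0 (no
#' digit preference) to 90 (all ages share one terminal digit).
#'
#' @param ages_months Integer vector of ages in months (values outside 0-59
#'   are dropped).
#' @return Index in `[0, 90]`, or `NA` with a warning when fewer than 10
#'   ages are available to assess digit preference.
#' @export
myers_blended_index <- function(ages_months) {
  a <- as.integer(ages_months)
  a <- a[!is.na(a) & a >= 0 & a <= 59]
  if (length(a) < 10) {
    warning("fewer than 10 ages; Myers index undefined")
    return(NA_real_)
  }
  counts <- tabulate(a + 1L, nbins = 60L)
  digit_counts <- matrix(counts, nrow = 10)  # [digit + 1, decade]
  s1 <- rowSums(digit_counts[, 1:5])  # ages 0-49
  s2 <- rowSums(digit_counts[, 2:6])  # ages 10-59
  d <- 0:9
  blended <- (d + 1) * s1 + (9 - d) * s2
  pct <- 100 * blended / sum(blended)
  sum(abs(pct - 10)) / 2
}

#' Regression test for the MOB and round-age artifacts
#'
#' Fits the diagnostic least-squares model for reported-age HAZ: 11 month-of-
#' birth dummies (last calendar month, i.e. December, as reference) and/or 11
#' months-past-round dummies (round age 0 as reference), with optional
#' controls. Model 1 adds no controls, so its MOB coefficients reproduce raw
#' cell-mean differences exactly; Model 2 adds child demographics (age in
#' months, age squared, and sex when a varying `sex` column exists) and
#' survey fixed effects; Model 3 further adds the household covariates
#' (`wealth`, `rural`). Standard errors are clustered at `cluster_id`
#' (CR1 small-sample correction) when at least two clusters are present,
#' classical otherwise. No survey weights are used.
#'
#' @param tab Child table (post-selection).
#' @param model 1, 2 or 3.
#' @param artifacts Which dummy sets to include: `"mob"`, `"round_age"` or
#'   `"both"`.
#' @param haz_col HAZ column used as the outcome.
#' @param year_start_month First month of the local calendar year.
#' @return An object of class `haz_regression` with elements `coefficients`
#'   (data.frame of term, estimate, se), `beta_mob` and `gamma_months`
#'   (named vectors, `NA` for dummies dropped as empty), `model`, `n`,
#'   `vcov_type`.
#' @export
fit_haz_regression <- function(tab, model = 1,
                               artifacts = c("both", "mob", "round_age"),
                               haz_col = "haz_reported",
                               year_start_month = 1L) {
  artifacts <- match.arg(artifacts)
  stopifnot(model %in% 1:3)
  haz <- tab[[haz_col]]
  ok <- !is.na(haz)
  dat <- data.frame(haz = haz[ok])
  terms <- character(0)

  if (artifacts %in% c("both", "mob")) {
    month <- .cal_parts(tab$reported_birth_date)$month[ok]
    idx <- .local_month_index(month, year_start_month)
    # reference: last month of the local calendar (December when Gregorian)
    dat$mob <- factor(idx, levels = c(12L, 1:11))
    terms <- c(terms, "mob")
  }
  if (artifacts %in% c("both", "round_age")) {
    d <- as.integer((tab$reported_age_days %/% DAYS_PER_MONTH) %% 12)[ok]
    dat$months_past_round <- factor(d, levels = 0:11)
    terms <- c(terms, "months_past_round")
  }
  if (model >= 2) {
    age_m <- (tab$reported_age_days / DAYS_PER_MONTH)[ok]
    dat$age_months <- age_m
    dat$age_months_sq <- age_m^2
    terms <- c(terms, "age_months", "age_months_sq")
    if (!is.null(tab$sex) && length(unique(tab$sex[ok])) > 1) {
      dat$sex <- factor(tab$sex[ok])
      terms <- c(terms, "sex")
    }
    if (length(unique(tab$survey_id[ok])) > 1) {
      dat$survey <- factor(tab$survey_id[ok])
      terms <- c(terms, "survey")
    }
  }
  if (model >= 3) {
    dat$wealth <- tab$wealth[ok]
    dat$rural <- tab$rural[ok]
    terms <- c(terms, "wealth", "rural")
  }

  for (v in c("mob", "months_past_round")) {
    if (!is.null(dat[[v]]) && any(table(dat[[v]]) == 0)) {
      warning("dropping empty ", v, " categories")
      dat[[v]] <- droplevels(dat[[v]])
    }
  }

  fml <- stats::reformulate(terms, response = "haz")
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  n_clusters <- length(unique(tab$cluster_id[ok]))
  if (!is.null(tab$cluster_id) && n_clusters >= 2) {
    vc <- sandwich::vcovCL(fit, cluster = tab$cluster_id[ok], type = "HC1")
    vcov_type <- "CR1 (clustered on cluster_id)"
  } else {
    vc <- stats::vcov(fit)
    vcov_type <- "classical"
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se))

  pick <- function(prefix, labels) {
    out <- stats::setNames(rep(NA_real_, length(labels)),
                           paste0(prefix, labels))
    ses <- out
    hit <- paste0(prefix, labels) %in% names(est)
    out[hit] <- est[paste0(prefix, labels)[hit]]
    ses[hit] <- se[paste0(prefix, labels)[hit]]
    list(est = out, se = ses)
  }
  beta <- if (artifacts %in% c("both", "mob")) pick("mob", 1:11) else NULL
  gamma <- if (artifacts %in% c("both", "round_age")) {
    pick("months_past_round", 1:11)
  } else NULL

  structure(list(coefficients = coefs,
                 beta_mob = beta$est, beta_mob_se = beta$se,
                 gamma_months = gamma$est, gamma_months_se = gamma$se,
                 model = model, artifacts = artifacts,
                 n = nrow(dat), n_clusters = n_clusters,
                 vcov_type = vcov_type),
            class = "haz_regression")
}

#' @export
print.haz_regression <- function(x, ...) {
  cat(sprintf("<haz_regression> Model %d (%s dummies), n = %d, SEs: %s\n",
              x$model, x$artifacts, x$n, x$vcov_type))
  if (!is.null(x$beta_mob)) {
    cat(sprintf("  beta_mob[1] (first vs last calendar month): %.4f (se %.4f)\n",
                x$beta_mob[1], x$beta_mob_se[1]))
  }
  invisible(x)
}

#' Per-survey data-quality scan
#'
#' For each survey: the December-January gap, the SD of reported-age HAZ and
#' the Myers blended index; plus, with three or more surveys, the Pearson
#' correlation between the signed gap and SD(HAZ). Surveys where random MOB
#' misreporting is common show large negative gaps *and* inflated SDs, hence
#' a negative correlation.
#'
#' @inheritParams mean_haz_by_mob
#' @return A list with `per_survey` (data.frame: survey_id, n, gap, gap_se,
#'   sd_haz, myers) and `cor_gap_sd` (`NA` with a note when undefined).
#' @export
survey_quality_scan <- function(tab, haz_col = "haz_reported",
                                year_start_month = 1L) {
  ids <- sort(unique(tab$survey_id))
  rows <- lapply(ids, function(s) {
    sub <- tab[tab$survey_id == s, , drop = FALSE]
    g <- tryCatch(december_january_gap(sub, haz_col, year_start_month),
                  error = function(e) list(gap = NA_real_, se = NA_real_))
    data.frame(survey_id = s, n = nrow(sub), gap = g$gap, gap_se = g$se,
               sd_haz = stats::sd(sub[[haz_col]], na.rm = TRUE),
               myers = suppressWarnings(myers_blended_index(
                 sub$reported_age_days %/% DAYS_PER_MONTH)))
  })
  per_survey <- do.call(rbind, rows)
  cor_gap_sd <- NA_real_
  note <- NULL
  if (nrow(per_survey) >= 3) {
    if (stats::sd(per_survey$gap) > 0 && stats::sd(per_survey$sd_haz) > 0) {
      cor_gap_sd <- stats::cor(per_survey$gap, per_survey$sd_haz)
    } else {
      note <- "correlation undefined: no variation across surveys"
    }
  } else {
    note <- "correlation requires at least 3 surveys"
  }
  list(per_survey = per_survey, cor_gap_sd = cor_gap_sd, note = note)
}
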