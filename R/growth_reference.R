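#' @keywords internal
"_PACKAGE"

# days per month used everywhere months are converted to days
DAYS_PER_MONTH <- 30.4375

.pkg_env <- new.env(parent = emptyenv())

#' Load a girls' length/height-for-age growth standard
#'
#' Reads a delimited reference table with columns `age_days`, `median_cm`
#' and `sd_cm` and returns a validated `growth_standard` object with linear
#' interpolation accessors. The packaged default is a daily-resolution
#' reconstruction of the WHO girls' length/height-for-age standard (medians
#' and SDs from the published monthly values, splined to days, continuous
#' across the length/height transition, extended to 72 months).
#'
#' @param path Path to the reference table. `NULL` (default) loads the
#'   table shipped with the package.
#' @return An object of class `growth_standard`: a list with the grid
#'   vectors `age_days`, `median_cm`, `sd_cm` and the scalar `max_age_days`.
#' @examples
#' std <- load_growth_standard()
#' gs_median(std, 730)
#' @export
load_growth_standard <- function(path = NULL) {
  cached <- is.null(path)
  if (cached && !is.null(.pkg_env$default_standard)) {
    return(.pkg_env$default_standard)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "growth_standard_girls.csv",
                        package = "mobhaz", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("growth standard fixture not found: ", path)
  }
  tab <- utils::read.csv(path)
  need <- c("age_days", "median_cm", "sd_cm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("growth standard is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(diff(tab$median_cm) <= 0)
  if (length(bad) > 0) {
    stop("median_cm is not strictly increasing at age_days = ",
         tab$age_days[bad[1] + 1])
  }
  bad <- which(tab$sd_cm <= 0)
  if (length(bad) > 0) {
    stop("sd_cm is not positive at age_days = ", tab$age_days[bad[1]])
  }
  std <- structure(
    list(age_days = tab$age_days,
         median_cm = tab$median_cm,
         sd_cm = tab$sd_cm,
         max_age_days = max(tab$age_days)),
    class = "growth_standard")
  if (cached) .pkg_env$default_standard <- std
  std
}

#' Construct a constant-velocity toy growth standard
#'
#' A linear median curve with constant SD, mainly useful for closed-form
#' checks: with growth velocity `v` cm/month and SD `sigma`, random MOB
#' misreporting of a fraction `p` of children produces a December-January
#' gap of exactly `-11 * p * v / sigma`.
#'
#' @param birth_cm Median length at birth (cm).
#' @param velocity_cm_month Constant growth velocity (cm per month).
#' @param sd_cm Constant SD (cm).
#' @param max_months Upper end of the age grid (months).
#' @return A `growth_standard` object on a daily grid.
#' @export
make_linear_standard <- function(birth_cm = 50, velocity_cm_month = 1,
                                 sd_cm = 2, max_months = 72) {
  age_days <- 0:ceiling(max_months * DAYS_PER_MONTH)
  structure(
    list(age_days = age_days,
         median_cm = birth_cm + velocity_cm_month * age_days / DAYS_PER_MONTH,
         sd_cm = rep(sd_cm, length(age_days)),
         max_age_days = max(age_days)),
    class = "growth_standard")
}

#' @export
print.growth_standard <- function(x, ...) {
  cat("<growth_standard> ", length(x$age_days), " grid points, age 0-",
      x$max_age_days, " days\n", sep = "")
  invisible(x)
}

#' Interpolated median and SD of a growth standard
#'
#' Linear interpolation on the reference grid.
#'
#' @param std A `growth_standard`.
#' @param age_days Ages in days (vectorised); must lie within the grid.
#' @return Numeric vector of medians (`gs_median`) or SDs (`gs_sd`) in cm.
#' @export
gs_median <- function(std, age_days) {
  .check_age_range(std, age_days)
  stats::approx(std$age_days, std$median_cm, xout = age_days)$y
}

#' @rdname gs_median
#' @export
gs_sd <- function(std, age_days) {
  .check_age_range(std, age_days)
  stats::approx(std$age_days, std$sd_cm, xout = age_days)$y
}

.check_age_range <- function(std, age_days) {
  if (anyNA(age_days)) stop("age_days contains NA")
  if (any(age_days < 0) || any(age_days > std$max_age_days)) {
    stop("age_days outside the reference range [0, ", std$max_age_days, "]")
  }
  invisible(TRUE)
}

#' Height-for-age z-score against a growth standard
#'
#' `haz = (height_cm - median(age)) / sd(age)`, the usual z-score with L = 1.
#' Ages outside the reference grid raise an error; callers that need to
#' tolerate out-of-range reported ages should filter first (see
#' [apply_age_selection()]).
#'
#' @param std A `growth_standard`.
#' @param height_cm Height/length in cm (vectorised).
#' @param age_days Age in days (vectorised, recycled against `height_cm`).
#' @return Numeric vector of z-scores (SD units).
#' @examples
#' std <- load_growth_standard()
#' compute_haz(std, gs_median(std, 730), 730)  # 0 by construction
#' @export
compute_haz <- function(std, height_cm, age_days) {
  if (any(height_cm <= 0, na.rm = TRUE)) stop("height_cm must be positive")
  (height_cm - gs_median(std, age_days)) / gs_sd(std, age_days)
}

# HAZ that returns NA (instead of erroring) for out-of-range ages; used by
# the error operators, where a misreported age can fall outside the grid.
.haz_or_na <- function(std, height_cm, age_days) {
  out <- rep(NA_real_, length(age_days))
  ok <- !is.na(age_days) & age_days >= 0 & age_days <= std$max_age_days
  if (any(ok)) {
    out[ok] <- (height_cm[ok] -
                  stats::approx(std$age_days, std$median_cm,
                                xout = age_days[ok])$y) /
      stats::approx(std$age_days, std$sd_cm, xout = age_days[ok])$y
  }
  out
}

#' Build a benchmark population model from a growth standard
#'
#' Transforms a reference standard into the "benchmark" curves a simulated
#' survey population is drawn from: growth velocity is slowed by a fraction
#' `r` within each of three age bands (0-6, 6-24, 24+ months), and the SD
#' curve is inflated and rescaled. Defaults reproduce a DHS-like population:
#' 7%/21%/10% velocity reductions, SD + 2 cm then x 0.85.
#'
#' The benchmark median is accumulated from daily increments,
#' `mu_b(t) = median(0) + sum_d d_median(d) * (1 - r(band(d)))`, so the birth
#' median is preserved. The SD transform order follows the default
#' `"add_first"`: `sigma_b = (sd + sd_add) * sd_mult`; `"mult_first"` gives
#' `sigma_b = sd * sd_mult + sd_add`.
#'
#' @param std A `growth_standard`.
#' @param velocity_reduction Numeric length 3, fractions in `[0, 1)` applied
#'   on age bands 0-6, 6-24 and 24+ months.
#' @param sd_add cm added to the reference SD.
#' @param sd_mult Multiplier applied to the reference SD.
#' @param sd_order `"add_first"` (default) or `"mult_first"`.
#' @return A `benchmark_model`: list with `age_days`, `mu_cm`, `sigma_cm`,
#'   the input standard and the transform parameters.
#' @examples
#' std <- load_growth_standard()
#' bm <- build_benchmark(std)
#' all(bm$mu_cm[-1] < std$median_cm[-1])
#' @export
build_benchmark <- function(std,
                            velocity_reduction = c(0.07, 0.21, 0.10),
                            sd_add = 2, sd_mult = 0.85,
                            sd_order = c("add_first", "mult_first")) {
  sd_order <- match.arg(sd_order)
  stopifnot(length(velocity_reduction) == 3,
            all(velocity_reduction >= 0), all(velocity_reduction < 1),
            sd_mult > 0)
  age <- std$age_days
  band <- findInterval(age, c(-Inf, 6 * DAYS_PER_MONTH, 24 * DAYS_PER_MONTH))
  r <- velocity_reduction[band]
  mu <- if (all(velocity_reduction == 0)) {
    std$median_cm  # identity transform, exact
  } else {
    dmed <- c(0, diff(std$median_cm))
    std$median_cm[1] + cumsum(dmed * (1 - r))
  }
  sigma <- if (sd_order == "add_first") {
    (std$sd_cm + sd_add) * sd_mult
  } else {
    std$sd_cm * sd_mult + sd_add
  }
  structure(
    list(age_days = age, mu_cm = mu, sigma_cm = sigma, standard = std,
         velocity_reduction = velocity_reduction,
         sd_add = sd_add, sd_mult = sd_mult, sd_order = sd_order),
    class = "benchmark_model")
}

#' @export
print.benchmark_model <- function(x, ...) {
  cat("<benchmark_model> velocity reductions ",
      paste(x$velocity_reduction, collapse = "/"),
      ", sigma = ", if (x$sd_order == "add_first") {
        sprintf("(sd + %g) * %g", x$sd_add, x$sd_mult)
      } else {
        sprintf("sd * %g + %g", x$sd_mult, x$sd_add)
      }, "\n", sep = "")
  invisible(x)
}

#' Benchmark median and SD at given ages
#'
#' @param bm A `benchmark_model`.
#' @param age_days Ages in days within the reference grid.
#' @return Numeric vector (cm).
#' @export
bm_mu <- function(bm, age_days) {
  .check_age_range(bm$standard, age_days)
  stats::approx(bm$age_days, bm$mu_cm, xout = age_days)$y
}

#' @rdname bm_mu
#' @export
bm_sigma <- function(bm, age_days) {
  .check_age_range(bm$standard, age_days)
  stats::approx(bm$age_days, bm$sigma_cm, xout = age_days)$y
}
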