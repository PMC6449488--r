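# Shared helpers: a fast toy standard and small config constructors.

toy_standard <- function(v = 1, sigma = 2) {
  make_linear_standard(birth_cm = 50, velocity_cm_month = v, sd_cm = sigma,
                       max_months = 72)
}

# config drawing from the toy standard with no benchmark transforms:
# heights are exactly N(median(age), sigma), so mean HAZ is 0 at every age
toy_config <- function(n, seed = 1, age_range = c(12, 48), ...) {
  sim_config(n_children = n, seed = seed,
             true_age_range_months = age_range,
             velocity_reduction = c(0, 0, 0), sd_add = 0, sd_mult = 1, ...)
}

bench_config <- function(n, seed = 1, ...) {
  sim_config(n_children = n, seed = seed, ...)
}

# small hand-built child table for arithmetic checks
mini_table <- function(haz, month, n_per_cell = 1) {
  k <- length(haz)
  survey <- as.Date("2015-06-15")
  birth <- as.Date(sprintf("2013-%02d-15", month))
  data.frame(
    child_id = seq_len(k), survey_id = 1L, cluster_id = rep(1:2, length.out = k),
    survey_date = survey, true_birth_date = birth,
    reported_birth_date = birth,
    true_age_days = as.integer(survey - birth),
    reported_age_days = as.integer(survey - birth),
    height_cm = 80, haz_true = haz, haz_reported = haz,
    misreport_flag = FALSE, wealth = 0, rural = 0L)
}
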