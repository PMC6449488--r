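test_that("p = 0 and q = 0 are identities", {
  std <- toy_standard()
  kids <- simulate_children(toy_config(5000, seed = 1), std)
  k2 <- apply_random_mob(kids, error_spec(p_random_mob = 0), std)
  expect_equal(k2$reported_birth_date, kids$true_birth_date)
  expect_equal(k2$haz_reported, kids$haz_true)
  k3 <- apply_round_age_rounding(kids, error_spec(q_round_age = 0), std)
  expect_equal(k3$reported_age_days, kids$true_age_days)
  g <- december_january_gap(k2)
  expect_lt(abs(g$gap), 3 * g$se)
})

test_that("random MOB reproduces the closed-form gap on a linear standard", {
  # constant velocity v cm/month, constant SD sigma, births uniform:
  # expected December-January gap is -11 * p * v / sigma
  v <- 1.2; sigma <- 2.5; p <- 0.3
  std <- toy_standard(v, sigma)
  kids <- simulate_children(toy_config(400000, seed = 11), std)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = p), std)
  g <- december_january_gap(kids)
  expect_lt(abs(g$gap - (-11 * p * v / sigma)), 3 * g$se)
  # misreport flag marks the Bernoulli subset
  expect_equal(mean(kids$misreport_flag), p, tolerance = 0.01)
})

test_that("the reported-MOB HAZ profile is linear in month index", {
  v <- 1; sigma <- 2; p <- 0.2
  std <- toy_standard(v, sigma)
  kids <- simulate_children(toy_config(400000, seed = 12), std)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = p), std)
  prof <- mean_haz_by_mob(kids)
  fit <- lm(mean_haz ~ month_index, data = prof)
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_equal(unname(coef(fit)[2]), p * v / sigma, tolerance = 0.1)
})

test_that("random MOB preserves the mean but fattens the tails", {
  std <- toy_standard()
  kids <- simulate_children(toy_config(200000, seed = 13), std)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = 0.25), std)
  expect_equal(mean(kids$haz_reported), mean(kids$haz_true),
               tolerance = 4 * sd(kids$haz_true) / sqrt(nrow(kids)))
  expect_gt(sd(kids$haz_reported), sd(kids$haz_true))
})

test_that("the discrete gap relocates with the local calendar", {
  cfg <- bench_config(400000, seed = 14, year_start_month = 4)
  kids <- simulate_children(cfg)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = 0.2,
                                            year_start_month = 4))
  kids <- apply_age_selection(kids)
  # measured on the Nepali-style April-March calendar: strong negative gap
  g_local <- december_january_gap(kids, year_start_month = 4)
  expect_lt(g_local$gap, -0.3)
  # measured on the Gregorian calendar the Dec-Jan step vanishes: December
  # and January are adjacent within the local year, so their difference is
  # one (small, upward) step of the smooth gradient, not a discrete drop
  g_greg <- december_january_gap(kids, year_start_month = 1)
  expect_gt(g_greg$gap, -3 * g_greg$se)
  expect_lt(g_greg$gap, 0.1)
})

test_that("future-dated random births get negative ages and are dropped", {
  std <- toy_standard()
  cfg <- toy_config(50000, seed = 15, age_range = c(0, 12))
  kids <- simulate_children(cfg, std)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = 0.5), std)
  expect_gt(sum(kids$reported_age_days < 0), 0)
  expect_true(all(is.na(kids$haz_reported[kids$reported_age_days < 0])))
  sel <- apply_age_selection(kids)
  expect_true(all(sel$reported_age_days >= 0))
  expect_false(any(is.na(sel$haz_reported)))
  # redraw option keeps every reported date plausible
  kids2 <- simulate_children(cfg, std)
  kids2 <- apply_random_mob(kids2, error_spec(p_random_mob = 0.5,
                                              redraw_future = TRUE), std)
  expect_true(all(kids2$reported_age_days >= 0))
})

test_that("reported-age selection follows the reported, not true, age", {
  std <- toy_standard()
  survey <- as.Date("2015-06-15")
  tab <- data.frame(
    survey_date = survey,
    true_birth_date = survey - c(62, 58, 30) * 30,
    reported_birth_date = survey - round(c(58, 62, -1) * 30.4375),
    height_cm = 100, misreport_flag = TRUE)
  tab$true_age_days <- as.integer(survey - tab$true_birth_date)
  tab$reported_age_days <- as.integer(survey - tab$reported_birth_date)
  kept <- apply_age_selection(tab)
  # truly 62 months but reported 58: kept; truly 58 reported 62: dropped;
  # reported in the future (negative age): dropped
  expect_equal(nrow(kept), 1)
  expect_equal(kept$true_age_days, 62L * 30L)
})

test_that("round-age rounding heaps ages and is asymmetric", {
  std <- toy_standard()
  cfg <- toy_config(200000, seed = 16, age_range = c(0, 60))
  kids <- simulate_children(cfg, std)
  point_mass <- error_spec(q_round_age = 1,
                           rounding_weights = c(1, rep(0, 11)))
  k_round <- apply_round_age_rounding(kids, point_mass, std)
  m <- k_round$reported_age_days %/% 30.4375
  expect_true(all(m %% 12 == 0))

  spec <- error_spec(q_round_age = 0.3)
  k2 <- apply_round_age_rounding(kids, spec, std)
  k2 <- apply_age_selection(k2)
  hist <- births_by_age_histogram(k2)
  # sawtooth: peaks at round ages, declining shoulders
  round_ages <- hist$n[hist$age_months %in% c(12, 24, 36, 48)]
  just_below <- hist$n[hist$age_months %in% c(11, 23, 35, 47)]
  expect_true(all(round_ages > 1.5 * just_below))
  # reported ages rounded down => HAZ steps up at round ages
  g <- round_age_gap(k2)
  expect_gt(g$gap, 0)
  # and the artifact grows with q
  k1 <- apply_age_selection(
    apply_round_age_rounding(kids, error_spec(q_round_age = 0.15), std))
  expect_gt(g$gap, round_age_gap(k1)$gap)
})

test_that("the two error operators act independently on their gaps", {
  cfg <- bench_config(400000, seed = 17)
  kids <- simulate_children(cfg)
  spec_mob <- error_spec(p_random_mob = 0.15)
  spec_round <- error_spec(q_round_age = 0.25)
  only_mob <- apply_age_selection(apply_random_mob(kids, spec_mob))
  only_round <- apply_age_selection(apply_round_age_rounding(kids, spec_round))
  both <- apply_age_selection(
    apply_round_age_rounding(apply_random_mob(kids, spec_mob), spec_round))

  g_mob <- december_january_gap(only_mob)
  g_both <- december_january_gap(both)
  expect_lt(abs(g_mob$gap - g_both$gap), 3 * sqrt(g_mob$se^2 + g_both$se^2))

  # compare the round-age gap away from the reported-age-0 boundary: in the
  # d = 0 cell at age 0 a random month shift can only make the true age
  # larger, so the MOB operator one-sidedly inflates that single cell; from
  # 12 months on the displacement is symmetric and the artifacts decouple
  older <- function(k) k[k$reported_age_days >= 12 * 30.4375, ]
  r_round <- round_age_gap(older(only_round))
  r_both <- round_age_gap(older(both))
  expect_lt(abs(r_round$gap - r_both$gap),
            3 * sqrt(r_round$se^2 + r_both$se^2))
})

test_that("error_spec validates the rounding distribution", {
  expect_error(error_spec(rounding_weights = c(0:11) / 66), "non-increasing")
  expect_error(error_spec(p_random_mob = 1.2))
  s <- error_spec(rounding_weights = rep(2, 12))
  expect_equal(sum(s$rounding_weights), 1)
})
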