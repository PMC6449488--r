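test_that("cell means and gaps match hand arithmetic", {
  tab <- mini_table(haz = rep(c(-1, -0.9, -0.68), each = 4),
                    month = rep(c(1, 6, 12), each = 4))
  prof <- mean_haz_by_mob(tab)
  expect_equal(prof$mean_haz[prof$month_index == 1], -1.00)
  expect_equal(prof$mean_haz[prof$month_index == 12], -0.68)
  expect_equal(prof$n[prof$month_index == 2], 0)
  expect_true(is.na(prof$mean_haz[prof$month_index == 2]))
  g <- december_january_gap(tab)
  expect_equal(g$gap, -0.32)
  expect_equal(c(g$n_left, g$n_right), c(4L, 4L))

  # identical HAZ everywhere: equal means, zero SE
  tab2 <- mini_table(haz = rep(-1.5, 24), month = rep(1:12, 2))
  prof2 <- mean_haz_by_mob(tab2)
  expect_true(all(prof2$mean_haz == -1.5))
  expect_true(all(prof2$se == 0))
  expect_error(december_january_gap(mini_table(-1, month = 5)),
               "empty endpoint")
})

test_that("births histogram counts exactly and handles empty tables", {
  tab <- mini_table(haz = rep(0, 6), month = rep(c(1, 6), 3))
  h <- births_by_age_histogram(tab)
  expect_equal(sum(h$n), 6)
  expect_equal(nrow(h), 60)
  h0 <- births_by_age_histogram(tab[0, ])
  expect_true(all(h0$n == 0))
})

test_that("Myers blended index matches a brute-force oracle", {
  # uniform terminal digits -> 0
  expect_equal(myers_blended_index(0:59), 0)
  # all one terminal digit -> maximum 90
  expect_equal(myers_blended_index(rep(seq(0, 50, by = 10), 5)), 90)
  expect_warning(idx <- myers_blended_index(c(1, 2, 3)), "undefined")
  expect_warning(myers_blended_index(rep(60:100, 3)), "undefined")
  expect_true(is.na(idx))

  # synthetic heap: 30% extra mass on digit 0
  set.seed(9)
  ages <- sample(0:59, 20000, replace = TRUE)
  heap <- sample(seq(0, 50, 10), 6000, replace = TRUE)
  all_ages <- c(ages, heap)

  # independent direct-summation implementation of the blended method
  brute <- function(a) {
    blended <- numeric(10)
    for (d in 0:9) {
      s1 <- 0; s2 <- 0
      for (i in 0:4) s1 <- s1 + sum(a == 10 * i + d)
      for (i in 1:5) s2 <- s2 + sum(a == 10 * i + d)
      blended[d + 1] <- (d + 1) * s1 + (9 - d) * s2
    }
    pct <- 100 * blended / sum(blended)
    sum(abs(pct - 10)) / 2
  }
  expect_equal(myers_blended_index(all_ages), brute(all_ages))
  expect_gt(myers_blended_index(all_ages), 10)
})

test_that("Model 1 coefficients equal raw cell-mean differences exactly", {
  cfg <- bench_config(60000, seed = 21)
  kids <- simulate_children(cfg)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = 0.2))
  kids <- apply_age_selection(kids)
  r <- fit_haz_regression(kids, model = 1, artifacts = "mob")
  prof <- mean_haz_by_mob(kids)
  dec <- prof$mean_haz[prof$month_index == 12]
  expect_equal(unname(r$beta_mob),
               prof$mean_haz[prof$month_index %in% 1:11] - dec,
               tolerance = 1e-10)
  g <- december_january_gap(kids)
  expect_equal(unname(r$beta_mob[1]), g$gap, tolerance = 1e-12)

  r2 <- fit_haz_regression(kids, model = 1, artifacts = "round_age")
  prof_d <- mean_haz_by_months_past_round(kids)
  expect_equal(unname(r2$gamma_months),
               prof_d$mean_haz[2:12] - prof_d$mean_haz[1],
               tolerance = 1e-10)
})

test_that("without artifacts all dummies are statistically null", {
  std <- toy_standard()
  kids <- simulate_children(toy_config(50000, seed = 22,
                                       age_range = c(0, 60),
                                       n_surveys = 3), std)
  kids <- apply_age_selection(kids)
  for (m in 1:3) {
    r <- fit_haz_regression(kids, model = m)
    expect_true(all(abs(r$beta_mob) < 3.5 * r$beta_mob_se), label =
                  paste("model", m, "mob dummies null"))
  }
  # covariates with zero effect estimate near zero (Model 3)
  r3 <- fit_haz_regression(kids, model = 3)
  wl <- r3$coefficients[r3$coefficients$term == "wealth", ]
  expect_lt(abs(wl$estimate), 3.5 * wl$se)
})

test_that("MOB coefficients are insensitive to the round-age dummies", {
  cfg <- bench_config(300000, seed = 23)
  kids <- simulate_children(cfg)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = 0.15))
  kids <- apply_round_age_rounding(kids, error_spec(q_round_age = 0.2))
  kids <- apply_age_selection(kids)
  r_mob <- fit_haz_regression(kids, model = 1, artifacts = "mob")
  r_both <- fit_haz_regression(kids, model = 1, artifacts = "both")
  expect_lt(max(abs(r_mob$beta_mob - r_both$beta_mob)), 0.05)
})

test_that("clustered SEs exceed classical SEs under intra-cluster correlation", {
  cfg <- bench_config(40000, seed = 24, clusters_per_survey = 40,
                      cluster_sd_cm = 2)
  kids <- simulate_children(cfg)
  kids <- apply_random_mob(kids, error_spec(p_random_mob = 0.2))
  kids <- apply_age_selection(kids)
  r_cl <- fit_haz_regression(kids, model = 1, artifacts = "mob")
  expect_match(r_cl$vcov_type, "CR1")
  kids_flat <- kids
  kids_flat$cluster_id <- 1L  # forces the classical fallback
  r_classical <- fit_haz_regression(kids_flat, model = 1, artifacts = "mob")
  expect_match(r_classical$vcov_type, "classical")
  expect_gt(mean(r_cl$beta_mob_se / r_classical$beta_mob_se), 1)
})

test_that("survey scan links the gap to SD(HAZ) across surveys", {
  shares <- c(0, 0.1, 0.2, 0.3)
  pieces <- lapply(seq_along(shares), function(i) {
    kids <- simulate_children(bench_config(120000, seed = 30 + i))
    kids <- apply_random_mob(kids, error_spec(p_random_mob = shares[i]))
    kids$survey_id <- i
    apply_age_selection(kids)
  })
  tab <- do.call(rbind, pieces)
  scan <- survey_quality_scan(tab)
  expect_equal(nrow(scan$per_survey), 4)
  expect_true(all(diff(scan$per_survey$gap) < 0))     # gap falls with p
  expect_true(all(diff(scan$per_survey$sd_haz) > 0))  # dispersion rises
  expect_lt(scan$cor_gap_sd, 0)

  one <- survey_quality_scan(pieces[[2]])
  expect_true(is.na(one$cor_gap_sd))
  expect_match(one$note, "at least 3")

  # identical surveys: correlation undefined, flagged
  same <- pieces[[1]]
  trip <- rbind(same, transform(same, survey_id = 2),
                transform(same, survey_id = 3))
  scan3 <- survey_quality_scan(trip)
  expect_true(is.na(scan3$cor_gap_sd))
  expect_match(scan3$note, "no variation")
})
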