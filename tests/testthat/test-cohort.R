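test_that("generator output is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_subjects = 80, seed = 123, followup_max = 6)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$long, b$long)
  expect_identical(a$endpoints, b$endpoints)
})

test_that("degenerate and calibrated baseline frequencies", {
  cfg <- cohort_config(n_subjects = 200, sex_prob = 1, seed = 5)
  expect_true(all(simulate_baseline(cfg)$sex == "boy"))
  expect_error(cohort_config(sex_prob = 1.4), "probabilities")
  # goodness of fit of observed counts to the configured probabilities
  cfg2 <- cohort_config(n_subjects = 100000, seed = 11)
  bl <- simulate_baseline(cfg2)
  p_sex <- chisq.test(table(bl$sex), p = c(0.532, 0.468))$p.value
  p_fam <- chisq.test(table(bl$familial_diabetes),
                      p = c(1 - 0.059 - 0.039, 0.059, 0.039))$p.value
  expect_gt(p_sex, 0.01)
  expect_gt(p_fam, 0.01)
  # cohort-scale expectations
  cfg3 <- cohort_config(seed = 2)
  bl3 <- simulate_baseline(cfg3)
  expect_lt(abs(mean(bl3$sex == "boy") - 0.532), 0.025)
  expect_lt(abs(mean(bl3$genetic_risk == "high") - 0.196), 0.02)
})

test_that("trajectories collapse to the fixed-effect curve without noise", {
  spec <- spline_spec()
  tr <- default_truth_jm()
  quiet <- lmm_params(tr$lmm$beta, rep(0, 6), 1e-12)
  cfg <- cohort_config(n_subjects = 25, seed = 3, dropout_hazard = 0,
                       followup_max = 6)
  bl <- simulate_baseline(cfg)
  long <- simulate_trajectories(bl, quiet, spec, cfg)
  X <- bspline_basis(long$age_years, spec)
  expect_equal(long$food_g_day, as.numeric(X %*% tr$lmm$beta),
               tolerance = 1e-4)
  # consumption starts at zero: population curve at 3 months is ~0 g/day
  m025 <- as.numeric(bspline_basis(0.25, spec) %*% tr$lmm$beta)
  expect_lt(abs(m025), 1)
})

test_that("simulated moments match the analytic mixed-model moments", {
  spec <- spline_spec()
  tr <- default_truth_jm()
  cfg <- cohort_config(n_subjects = 2000, seed = 19, dropout_hazard = 0,
                       followup_max = 6, record_attend_prob = 1,
                       include_age5_prob = 0)
  bl <- simulate_baseline(cfg)
  long <- simulate_trajectories(bl, tr$lmm, spec, cfg)
  for (a in c(0.5, 2, 6)) {
    y <- long$food_g_day[abs(long$age_years - a) < 1e-9]
    x <- as.numeric(bspline_basis(a, spec))
    mu <- sum(x * tr$lmm$beta)
    v <- sum(x^2 * tr$lmm$re_var) + tr$lmm$sigma2
    n_eff <- 2000  # three daily values share one subject curve
    se_mu <- sqrt(v / n_eff)
    expect_lt(abs(mean(y) - mu), 3 * se_mu)
    expect_lt(abs(var(y) / v - 1), 0.12)
  }
})

test_that("event times follow the target distribution", {
  spec <- spline_spec()
  tr <- default_truth_jm()
  # exponential limit: alpha = 0, no covariates, constant hazard
  lam <- 0.3
  flat <- jm_params(tr$lmm, numeric(0), 0,
                    hazard_spec(c(1.99, 3.99), 60, rep(log(lam), 3)))
  cfg <- cohort_config(n_subjects = 10000, seed = 21, followup_max = 15)
  bl <- simulate_baseline(cfg)
  tev <- simulate_event_times(bl, flat, spec, seed = 21, followup_max = 60)
  expect_lt(abs(mean(tev[is.finite(tev)]) - 1 / lam) / (1 / lam), 0.05)
  ks <- suppressWarnings(ks.test(tev[is.finite(tev)], pexp, rate = lam))
  expect_gt(ks$p.value, 0.01)
  # vanishing hazard: no events
  none <- jm_params(tr$lmm, tr$gamma, tr$alpha,
                    hazard_spec(c(1.99, 3.99), 6, rep(log(1e-12), 3)))
  tev0 <- simulate_event_times(bl[1:500, ], none, spec, seed = 3)
  expect_true(all(!is.finite(tev0)))
})

test_that("event simulation matches an independent fine-grid CDF oracle", {
  spec <- spline_spec()
  tr <- default_truth_jm(alpha = 0.02)   # strong association magnifies error
  cfg <- cohort_config(n_subjects = 1500, seed = 33, followup_max = 6)
  bl <- simulate_baseline(cfg)
  b <- dietjm:::draw_random_effects(cfg$n_subjects, tr$lmm$re_var,
                                    dietjm:::derive_seed(cfg$seed, 2L))
  tev <- simulate_event_times(bl, tr, spec, cfg$seed, random_effects = b)
  # oracle: mixture CDF over the same subjects, 20001-point grid
  ts <- seq(0, 6, length.out = 10001)
  tb <- pmin(pmax(ts, 0.25), 6)
  Xg <- bspline_basis(tb, spec)
  h0 <- exp(tr$hazard$log_heights)[dietjm:::hazard_interval(pmax(ts, 1e-9),
                                                            tr$hazard)]
  lp <- dietjm:::gamma_linpred(bl, tr$gamma, tr$gamma_names)
  Fm <- numeric(length(ts))
  for (i in seq_len(nrow(bl))) {
    m <- as.numeric(Xg %*% (tr$lmm$beta + b[i, ]))
    lam <- h0 * exp(lp[i] + tr$alpha * m)
    H <- c(0, cumsum(0.5 * (lam[-1] + lam[-length(lam)]) * diff(ts)))
    Fm <- Fm + (1 - exp(-H))
  }
  Fm <- Fm / nrow(bl)
  obs <- tev[is.finite(tev) & tev <= 6]
  Fcond <- approx(ts, Fm / Fm[length(ts)], xout = sort(obs))$y
  ks_d <- max(abs(Fcond - seq_along(obs) / length(obs)),
              abs(Fcond - (seq_along(obs) - 1) / length(obs)))
  expect_lt(ks_d, 1.63 / sqrt(length(obs)))   # alpha = 0.01 critical value
})

test_that("visit censoring brackets the event and flags early events", {
  ep <- apply_visit_censoring(c(3.2, Inf), list(c(1, 2, 3, 4), c(1, 5, 14.9)))
  expect_equal(ep$last_negative_age[1], 3)
  expect_equal(ep$first_positive_age[1], 4)
  expect_equal(ep$midpoint[1], 3.5)
  expect_equal(ep$event, c(1L, 0L))
  expect_equal(ep$censor_age[2], 14.9)
  expect_warning(
    ep2 <- apply_visit_censoring(0.1, list(c(0.25, 0.5))),
    "before the first")
  expect_equal(ep2$last_negative_age, 0)
  expect_true(ep2$before_first_visit)
})

test_that("every simulated midpoint lies strictly inside its interval and
           records never pass the detection age", {
  co <- small_jm_cohort()
  ev <- co$endpoints[co$endpoints$event == 1, ]
  expect_true(all(ev$midpoint > ev$last_negative_age))
  expect_true(all(ev$midpoint < ev$first_positive_age))
  detect <- ifelse(co$endpoints$event == 1, co$endpoints$first_positive_age,
                   co$endpoints$censor_age)
  last_rec <- tapply(co$long$age_years, co$long$subject, max)
  expect_true(all(last_rec <= detect[match(names(last_rec),
                                           co$endpoints$subject)] + 1e-9))
})

test_that("latent-class generator hits the configured class mixture", {
  cfg <- cohort_config(n_subjects = 5545, seed = 13)
  co <- simulate_latent_class_cohort(cfg)
  frac_high <- mean(co$true_class == 2)
  se <- sqrt(1 / 6 * 5 / 6 / 5545)
  expect_lt(abs(frac_high - 1 / 6), 3 * se)
  # single class degenerates cleanly
  tr1 <- default_truth_jlcmm()
  tr1 <- jlcmm_params(tr1$beta[, 1, drop = FALSE], tr1$re_var, tr1$sigma2,
                      setNames(tr1$gamma, tr1$gamma_names),
                      tr1$log_heights[, 1, drop = FALSE], 0, tr1$hazard)
  co1 <- simulate_latent_class_cohort(cohort_config(n_subjects = 50, seed = 2),
                                      truth = tr1)
  expect_true(all(co1$true_class == 1))
})

test_that("class-specific hazard ratio shows up in cumulative incidence", {
  tr <- default_truth_jlcmm(hr = 0.68)
  cfg <- cohort_config(n_subjects = 40000, seed = 17, dropout_hazard = 0)
  co <- simulate_latent_class_cohort(cfg, truth = tr)
  inc <- tapply(is.finite(co$true_event_age), co$true_class, mean)
  # closed-form class-specific incidence from the baseline hazards, averaged
  # over the covariate distribution
  lp <- dietjm:::gamma_linpred(co$baseline, tr$gamma, tr$gamma_names)
  expected <- sapply(1:2, function(g) {
    hz <- hazard_spec(tr$hazard$knots, 15, tr$log_heights[, g])
    H <- dietjm:::baseline_cumhaz(15, hz)
    mean(1 - exp(-exp(lp) * H))
  })
  expect_lt(abs(inc[[1]] - expected[1]), 0.006)
  expect_lt(abs(inc[[2]] - expected[2]), 0.012)
})

test_that("cohorts round-trip through the delimited-text writer", {
  co <- small_jm_cohort()
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("baseline.csv", "long.csv",
                                               "endpoints.csv",
                                               "truth.json")))))
  bl <- read.csv(file.path(dir, "baseline.csv"))
  expect_equal(nrow(bl), nrow(co$baseline))
  lg <- read.csv(file.path(dir, "long.csv"))
  expect_equal(lg$food_g_day, co$long$food_g_day, tolerance = 1e-9)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$model, "JM")
  expect_equal(truth$seed, co$config$seed)
})
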