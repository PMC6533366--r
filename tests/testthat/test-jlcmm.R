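toy_lc_data <- function() {
  spec <- spline_spec()
  long <- data.frame(
    subject = rep(1:4, each = 2),
    age_years = rep(c(1, 3), 4),
    food_g_day = c(4.2, 5.1, 20.3, 24.8, 5.5, 4.7, 19.2, 26.0))
  ep <- data.frame(subject = 1:4, event = c(1L, 0L, 0L, 1L),
                   midpoint = c(2.5, 10, 12, 7.3),
                   censor_age = c(2.5, 10, 12, 7.3))
  bl <- data.frame(subject = 1:4,
                   sex = factor(c("boy", "girl", "boy", "girl"),
                                levels = c("boy", "girl")),
                   genetic_risk = factor(rep("moderate", 4),
                                         levels = c("moderate", "high")),
                   familial_diabetes = factor(rep("no", 4),
                                              levels = c("no", "yes",
                                                         "missing")))
  hz <- hazard_spec(c(1.99, 3.99, 5.99), 15)
  beta <- cbind(curve_to_coef(c(0.25, 1, 6), c(0, 5, 5), spec),
                curve_to_coef(c(0.25, 1, 6), c(0, 5, 25), spec))
  params <- jlcmm_params(beta, re_var = rep(1, 6), sigma2 = 2,
                         gamma = c(girl = -0.3),
                         log_heights = cbind(log(c(0.02, 0.03, 0.02, 0.01)),
                                             log(c(0.015, 0.02, 0.015,
                                                   0.008))),
                         lambda = c(log(4), 0), hazard = hz)
  list(spec = spec, long = long, ep = ep, bl = bl, params = params, hz = hz)
}

test_that("single-class likelihood equals mixed model plus survival exactly", {
  toy <- toy_lc_data()
  p1 <- jlcmm_params(toy$params$beta[, 1, drop = FALSE],
                     toy$params$re_var, toy$params$sigma2,
                     c(girl = -0.3),
                     toy$params$log_heights[, 1, drop = FALSE], 0, toy$hz)
  ll <- jlcmm_loglik(p1, toy$long, toy$ep, toy$bl, toy$spec)
  lmm <- lmm_params(p1$beta[, 1], p1$re_var, p1$sigma2)
  ll_lmm <- lmm_loglik(lmm, toy$long, toy$spec)
  lp <- dietjm:::gamma_linpred(toy$bl, c(girl = -0.3))
  hz1 <- hazard_spec(toy$hz$knots, 15, p1$log_heights[, 1])
  H0 <- dietjm:::baseline_cumhaz(toy$ep$midpoint, hz1)
  h0 <- exp(hz1$log_heights)[dietjm:::hazard_interval(toy$ep$midpoint, hz1)]
  ll_surv <- sum(toy$ep$event * (log(h0) + lp)) - sum(exp(lp) * H0)
  expect_equal(ll, ll_lmm + ll_surv, tolerance = 1e-10)
})

test_that("two identical classes collapse to the single-class likelihood", {
  toy <- toy_lc_data()
  p1 <- jlcmm_params(toy$params$beta[, c(1, 1)],
                     toy$params$re_var, toy$params$sigma2, c(girl = -0.3),
                     toy$params$log_heights[, c(1, 1)],
                     c(0.7, 0), toy$hz)
  psingle <- jlcmm_params(toy$params$beta[, 1, drop = FALSE],
                          toy$params$re_var, toy$params$sigma2,
                          c(girl = -0.3),
                          toy$params$log_heights[, 1, drop = FALSE], 0,
                          toy$hz)
  expect_equal(jlcmm_loglik(p1, toy$long, toy$ep, toy$bl, toy$spec),
               jlcmm_loglik(psingle, toy$long, toy$ep, toy$bl, toy$spec),
               tolerance = 1e-10)
})

test_that("mixture likelihood matches a hand-written evaluation on a
           4-subject toy", {
  toy <- toy_lc_data()
  ll <- jlcmm_loglik(toy$params, toy$long, toy$ep, toy$bl, toy$spec)
  X <- bspline_basis(c(1, 3), toy$spec)
  V <- X %*% diag(toy$params$re_var) %*% t(X) + diag(toy$params$sigma2, 2)
  pi_g <- exp(c(log(4), 0)); pi_g <- pi_g / sum(pi_g)
  lp <- ifelse(toy$bl$sex == "girl", -0.3, 0)
  ll_hand <- 0
  for (i in 1:4) {
    y <- toy$long$food_g_day[toy$long$subject == i]
    li <- 0
    for (g in 1:2) {
      r <- y - as.numeric(X %*% toy$params$beta[, g])
      f_long <- exp(-0.5 * (2 * log(2 * pi) +
                              as.numeric(determinant(V)$modulus) +
                              sum(r * solve(V, r))))
      hzg <- hazard_spec(toy$hz$knots, 15, toy$params$log_heights[, g])
      H <- dietjm:::baseline_cumhaz(toy$ep$midpoint[i], hzg)
      h <- exp(hzg$log_heights)[dietjm:::hazard_interval(toy$ep$midpoint[i],
                                                         hzg)]
      f_surv <- (h * exp(lp[i]))^toy$ep$event[i] * exp(-exp(lp[i]) * H)
      li <- li + pi_g[g] * f_long * f_surv
    }
    ll_hand <- ll_hand + log(li)
  }
  expect_equal(ll, ll_hand, tolerance = 1e-10)
})

test_that("EM increases the likelihood and the fit is labelled by size with
           unit-sum posteriors", {
  fit <- small_lc_fit()
  expect_true(all(diff(fit$em_trace) > -1e-6))
  expect_equal(rowSums(fit$posterior), rep(1, length(fit$subjects)),
               tolerance = 1e-12)
  expect_gte(fit$class_sizes[1], fit$class_sizes[2])
  expect_equal(sum(fit$class_sizes), length(fit$subjects))
  # mean posterior in the modal class is a probability
  expect_true(all(fit$classification >= 0.5 & fit$classification <= 1,
                  na.rm = TRUE))
})

test_that("single-class fit reduces to the mixed model plus closed-form
           survival maximum", {
  co <- small_lc_cohort()
  fit1 <- fit_jlcmm(co$long, co$endpoints, co$baseline, co$spec, G = 1,
                    covariates = character(0),
                    control = jlcmm_control(se = FALSE), seed = 1)
  lfit <- fit_lmm(co$long, co$spec)
  ep <- truncate_endpoints(co$endpoints, 15)
  Tm <- ifelse(ep$event == 1, ep$midpoint, ep$censor_age)
  bounds <- c(0, 1.99, 3.99, 5.99, 15)
  ll_surv <- 0
  for (j in 1:4) {
    expo <- sum(pmax(0, pmin(Tm, bounds[j + 1]) - bounds[j]))
    ev <- sum(ep$event[Tm > bounds[j] & Tm <= bounds[j + 1]])
    if (ev > 0) ll_surv <- ll_surv + ev * log(ev / expo) - ev
    else ll_surv <- ll_surv - 0   # empty interval contributes zero at the MLE
  }
  expect_equal(fit1$loglik, lfit$loglik + ll_surv, tolerance = 1e-4)
})

test_that("piecewise hazard ratios are exactly 1 for identical class
           hazards and reject misaligned intervals", {
  fit <- small_lc_fit()
  fit_eq <- fit
  fit_eq$params$log_heights[, 2] <- fit_eq$params$log_heights[, 1]
  hr <- piecewise_hr(fit_eq)
  expect_equal(hr$hr, rep(1, 4), tolerance = 1e-12)
  expect_true(all(hr$lo <= 1 & hr$hi >= 1))
  expect_error(piecewise_hr(fit, intervals = list(c(0, 3))), "align")
})

test_that("piecewise hazard ratios recover a built-in class hazard ratio", {
  fit <- small_lc_fit()
  truth_ratio <- 0.68    # generator default: proportional classes
  hr <- piecewise_hr(fit)
  # a ratio collapsed onto the zero boundary must carry an infinite SE, not
  # a spuriously tight interval
  expect_true(all(is.infinite(hr$se_log[hr$hr < 1e-6])))
  covered <- hr$lo <= truth_ratio & truth_ratio <= hr$hi
  expect_gte(sum(covered), 3L)
})

test_that("proportional-hazards constraint is a genuine nesting", {
  co <- small_lc_cohort()
  fit <- small_lc_fit()
  pfit <- fit_jlcmm(co$long, co$endpoints, co$baseline, co$spec, G = 2,
                    control = jlcmm_control(n_starts = 3, se = TRUE),
                    proportional = TRUE, seed = 3)
  expect_lte(pfit$loglik, fit$loglik + 1e-3)
  expect_s3_class(pfit$theta, "data.frame")
})

test_that("class-number selection returns the BIC minimizer with
           diagnostics, preferring fewer classes on ties", {
  fake <- function(G, bic) {
    structure(list(G = G, loglik = -bic / 2, bic = bic,
                   posterior = matrix(1 / G, 10, G),
                   class_sizes = rep(10 / G, G),
                   classification = rep(0.9, G), spurious = FALSE,
                   subjects = 1:10), class = "jlcmm_fit")
  }
  sel <- select_num_classes(list(fake(1, 510), fake(2, 490), fake(3, 505)))
  expect_equal(sel$chosen_G, 2)
  expect_equal(nrow(sel$table), 3)
  sel_tie <- select_num_classes(list(fake(1, 500), fake(2, 500 + 1e-9)))
  expect_equal(sel_tie$chosen_G, 1)
})

test_that("model selection prefers one class when the truth has one", {
  spec <- spline_spec()
  trl <- default_truth_jlcmm()
  tr1 <- jlcmm_params(trl$beta[, 1, drop = FALSE], trl$re_var, trl$sigma2,
                      setNames(trl$gamma, trl$gamma_names),
                      trl$log_heights[, 1, drop = FALSE], 0, trl$hazard)
  wins <- 0L
  for (r in 1:2) {
    co <- simulate_latent_class_cohort(
      cohort_config(n_subjects = 400, seed = 600 + r), truth = tr1)
    f1 <- fit_jlcmm(co$long, co$endpoints, co$baseline, spec, G = 1,
                    control = jlcmm_control(se = FALSE), seed = 1)
    f2 <- fit_jlcmm(co$long, co$endpoints, co$baseline, spec, G = 2,
                    control = jlcmm_control(n_starts = 3, se = FALSE),
                    seed = 1)
    wins <- wins + (f1$bic < f2$bic)
  }
  expect_gte(wins, 1L)
})

test_that("delete-5 jackknife: analytic oracle, constant estimator and
           reproducibility", {
  set.seed(12)
  cohort <- list(baseline = data.frame(subject = 1:200, x = rnorm(200)),
                 long = data.frame(subject = 1:200),
                 endpoints = data.frame(subject = 1:200))
  est_mean <- function(bl, lg, ep) mean(bl$x)
  jk <- jackknife_d5(cohort, est_mean, seed = 4, n_resample = 300)
  expect_lt(abs(jk$se - 1 / sqrt(200)) / (1 / sqrt(200)), 0.2)
  jk2 <- jackknife_d5(cohort, est_mean, seed = 4, n_resample = 300)
  expect_identical(jk$se, jk2$se)
  jk0 <- jackknife_d5(cohort, function(bl, lg, ep) 42, seed = 1,
                      n_resample = 50)
  expect_equal(unname(jk0$se), 0)
  expect_error(jackknife_d5(list(baseline = data.frame(subject = 1:10),
                                 long = NULL, endpoints = NULL),
                            est_mean), "at least 50")
})
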