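# brute-force Breslow partial likelihood over counting-process rows
brute_partial_loglik <- function(cp, beta_vec) {
  ev <- cp[cp$event == 1, ]
  ll <- 0
  for (i in seq_len(nrow(ev))) {
    t_ev <- ev$stop[i]
    at_risk <- cp$start < t_ev & cp$stop >= t_ev
    ll <- ll + beta_vec * ev$exposure[i] -
      log(sum(exp(beta_vec * cp$exposure[at_risk])))
  }
  ll
}

test_that("counting process carries exposure forward and places the event
           at the midpoint", {
  long <- data.frame(subject = 1, age_years = c(0.25, 0.5, 1),
                     food_g_day = c(10, 20, 30))
  ep <- data.frame(subject = 1, event = 1, midpoint = 1.5, censor_age = 2)
  cp <- build_counting_process(long, ep)
  expect_equal(cp$start, c(0.25, 0.5, 1))
  expect_equal(cp$stop, c(0.5, 1, 1.5))
  expect_equal(cp$event, c(0L, 0L, 1L))
  expect_equal(cp$exposure, c(10, 20, 30))
})

test_that("censoring exactly at a record age suppresses the zero-length row", {
  long <- data.frame(subject = 1, age_years = c(0.25, 1, 2),
                     food_g_day = c(5, 6, 7))
  ep <- data.frame(subject = 1, event = 0, midpoint = 2, censor_age = 2)
  cp <- build_counting_process(long, ep)
  expect_equal(nrow(cp), 2L)
  expect_equal(cp$stop, c(1, 2))
})

test_that("events before the first record are excluded with a reason", {
  long <- data.frame(subject = c(1, 2), age_years = c(2, 0.25),
                     food_g_day = c(5, 8))
  ep <- data.frame(subject = c(1, 2), event = c(1, 0),
                   midpoint = c(0.8, 3), censor_age = c(0.9, 3))
  cp <- build_counting_process(long, ep)
  expect_equal(unique(cp$subject), 2)
  expect_equal(attr(cp, "excluded")$subject, 1)
})

test_that("total exposure time satisfies the accounting identity", {
  co <- small_jm_cohort()
  ep <- truncate_endpoints(co$endpoints, 6)
  occ <- occasion_means(co$long)
  cp <- build_counting_process(occ, ep, followup_max = 6)
  kept <- !(ep$subject %in% attr(cp, "excluded")$subject)
  first_rec <- tapply(occ$age_years, occ$subject, min)
  endt <- pmin(ifelse(ep$event == 1, ep$midpoint, ep$censor_age), 6)
  expect_equal(sum(cp$stop - cp$start),
               sum(pmax(endt[kept] - first_rec[match(ep$subject[kept],
                                                     names(first_rec))], 0)),
               tolerance = 1e-9)
})

test_that("time-dependent Cox estimate matches brute-force partial
           likelihood maximization", {
  cp <- data.frame(subject = 1:3, start = 0, stop = c(1, 2, 3),
                   event = c(1L, 1L, 0L), exposure = c(1, 0, 1))
  fit <- fit_cox_td(cp, ties = "breslow", increment = 1)
  o <- optimize(function(b) -brute_partial_loglik(cp, b), c(-5, 5))
  expect_equal(fit$coef, o$minimum, tolerance = 1e-3)
  expect_equal(fit$loglik, -o$objective, tolerance = 1e-6)
})

test_that("partial likelihood equals the exhaustive risk-set product on a
           simulated 10-subject instance", {
  co <- small_jm_cohort()
  ep <- truncate_endpoints(co$endpoints, 6)
  ids <- c(ep$subject[ep$event == 1][1:3],
           setdiff(ep$subject, ep$subject[ep$event == 1])[1:7])
  lt <- co$long[co$long$subject %in% ids, ]
  cp <- build_counting_process(occasion_means(lt), ep[ep$subject %in% ids, ])
  fit <- fit_cox_td(cp, ties = "breslow", increment = 1)
  expect_equal(fit$loglik, brute_partial_loglik(cp, fit$coef),
               tolerance = 1e-8)
})

test_that("constant exposure is flagged as unidentifiable", {
  cp <- data.frame(subject = 1:4, start = 0, stop = 1:4,
                   event = c(1L, 0L, 1L, 0L), exposure = 2)
  fit <- fit_cox_td(cp, increment = 1)
  expect_equal(fit$coef, 0)
  expect_true(fit$diverged)
  expect_equal(fit$se, Inf)
})

test_that("Breslow and Efron agree exactly without tied event times", {
  co <- small_jm_cohort()
  ep <- truncate_endpoints(co$endpoints, 6)
  # jitter midpoints to break ties
  set.seed(4)
  ep$midpoint <- ep$midpoint + runif(nrow(ep), 0, 1e-4)
  cp <- build_counting_process(occasion_means(co$long), ep)
  fb <- fit_cox_td(cp, ties = "breslow")
  fe <- fit_cox_td(cp, ties = "efron")
  expect_equal(fb$coef, fe$coef, tolerance = 1e-9)
})

test_that("Rubin pooling follows the variance decomposition", {
  p <- rubin_pool(c(1.0, 1.2, 1.4), rep(0.04, 3))
  expect_equal(p$estimate, 1.2)
  expect_equal(p$se^2, 0.04 + (1 + 1 / 3) * var(c(1, 1.2, 1.4)))
  # identical imputations pool to the single fit
  p0 <- rubin_pool(c(0.7, 0.7), c(0.01, 0.01))
  expect_equal(p0$estimate, 0.7)
  expect_equal(p0$between, 0)
  expect_equal(p0$se, 0.1)
  # pooled SE is never below the mean within-imputation SE
  set.seed(8)
  est <- rnorm(5); va <- runif(5, 0.5, 2)
  expect_gte(rubin_pool(est, va)$se, sqrt(mean(va)) - 1e-12)
  expect_error(rubin_pool(1, 0.1), "at least 2")
})

test_that("energy adjustment divides food by energy row-wise", {
  lt <- data.frame(subject = 1, age_years = 1, food_g_day = c(88, 0),
                   energy_mj_day = c(6, 5))
  adj <- energy_adjust(lt)
  expect_equal(adj$food_g_day, c(88 / 6, 0), tolerance = 1e-9)
  expect_equal(attr(adj, "exposure_unit"), "g_per_MJ")
  lt$energy_mj_day[2] <- 0
  expect_error(energy_adjust(lt), "non-positive")
})

test_that("3-day imputation keeps complete occasions fixed and is
           reproducible", {
  daily <- data.frame(subject = rep(1:2, each = 6),
                      age_years = rep(rep(c(1, 2), each = 3), 2),
                      day = rep(1:3, 4),
                      food_g_day = c(10, 12, 14, 20, 22, 24,
                                     30, 32, 34, 40, NA, NA))
  daily <- daily[!is.na(daily$food_g_day), ]
  imps <- impute_3day_mean(daily, m = 4, seed = 9)
  for (im in imps) {
    expect_equal(im$food_g_day[im$subject == 1 & im$age_years == 1], 12)
    expect_equal(im$food_g_day[im$subject == 2 & im$age_years == 1], 32)
  }
  # incomplete occasion varies across imputations but not across reruns
  v1 <- sapply(imps, function(im)
    im$food_g_day[im$subject == 2 & im$age_years == 2])
  expect_gt(stats::sd(v1), 0)
  imps2 <- impute_3day_mean(daily, m = 4, seed = 9)
  expect_identical(imps, imps2)
})

test_that("imputed-data pooled estimate stays near the complete-data fit
           under day-level MCAR deletion", {
  co <- small_jm_cohort()
  ep <- truncate_endpoints(co$endpoints, 6)
  full_fit <- fit_cox_td(build_counting_process(occasion_means(co$long), ep))
  set.seed(10)
  daily <- co$long
  key <- interaction(daily$subject, daily$age_years, drop = TRUE)
  drop_day <- sapply(split(seq_len(nrow(daily)), key),
                     function(ii) sample(ii, 1))
  daily <- daily[-drop_day, ]
  imps <- impute_3day_mean(daily, m = 5, seed = 10)
  fits <- lapply(imps, function(im)
    fit_cox_td(build_counting_process(im, ep)))
  pooled <- rubin_pool(sapply(fits, `[[`, "coef"),
                       sapply(fits, `[[`, "se")^2)
  expect_lt(abs(pooled$estimate - full_fit$coef), pooled$se)
})
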