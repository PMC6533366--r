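make_toy_long <- function(n_subj = 3, ages = c(1, 4), beta = NULL,
                          re_var = rep(4, 6), sigma2 = 1, seed = 9) {
  spec <- spline_spec()
  if (is.null(beta)) beta <- c(5, 1, -2, 3, 0.5, 2)
  set.seed(seed)
  b <- matrix(rnorm(n_subj * 6), n_subj) %*% diag(sqrt(re_var))
  X <- bspline_basis(ages, spec)
  rows <- lapply(seq_len(n_subj), function(i) {
    data.frame(subject = i, age_years = ages,
               food_g_day = as.numeric(X %*% (beta + b[i, ])) +
                 rnorm(length(ages), 0, sqrt(sigma2)))
  })
  list(long = do.call(rbind, rows), spec = spec, beta = beta,
       re_var = re_var, sigma2 = sigma2)
}

test_that("with no random effects the marginal loglik is the iid Gaussian one", {
  toy <- make_toy_long()
  p <- lmm_params(toy$beta, rep(0, 6), 2.5)
  ll <- lmm_loglik(p, toy$long, toy$spec)
  X <- bspline_basis(toy$long$age_years, toy$spec)
  mu <- as.numeric(X %*% toy$beta)
  expect_equal(ll, sum(dnorm(toy$long$food_g_day, mu, sqrt(2.5), log = TRUE)),
               tolerance = 1e-10)
})

test_that("marginal loglik matches a dense multivariate-normal computation", {
  toy <- make_toy_long(n_subj = 3, ages = c(1, 4))
  p <- lmm_params(toy$beta, c(1, 2, 0.5, 3, 1.5, 2.5), 1.7)
  ll <- lmm_loglik(p, toy$long, toy$spec)
  X <- bspline_basis(c(1, 4), toy$spec)
  V <- X %*% diag(p$re_var) %*% t(X) + diag(p$sigma2, 2)
  Vi <- solve(V)
  ld <- determinant(V)$modulus
  ll_hand <- 0
  for (i in 1:3) {
    y <- toy$long$food_g_day[toy$long$subject == i]
    r <- y - as.numeric(X %*% toy$beta)
    ll_hand <- ll_hand - 0.5 * (2 * log(2 * pi) + ld + sum(r * (Vi %*% r)))
  }
  expect_equal(ll, as.numeric(ll_hand), tolerance = 1e-10)
})

test_that("loglik is invariant under subject relabeling", {
  toy <- make_toy_long(n_subj = 6, ages = c(0.5, 2, 5))
  p <- lmm_params(toy$beta, toy$re_var, toy$sigma2)
  lt2 <- toy$long
  lt2$subject <- c(4, 5, 6, 1, 2, 3)[lt2$subject]
  expect_equal(lmm_loglik(p, toy$long, toy$spec),
               lmm_loglik(p, lt2, toy$spec), tolerance = 1e-12)
})

test_that("noise-free data on the fixed curve gives the least-squares fit
           with a boundary-flagged residual variance", {
  spec <- spline_spec()
  ages <- c(0.25, 0.5, 1, 2, 3, 4, 6)
  beta <- c(2, 8, 20, 35, 28, 40)
  X <- bspline_basis(ages, spec)
  long <- do.call(rbind, lapply(1:40, function(i)
    data.frame(subject = i, age_years = ages,
               food_g_day = as.numeric(X %*% beta))))
  fit <- fit_lmm(long, spec)
  expect_equal(fit$params$beta, beta, tolerance = 1e-4)
  expect_true(fit$boundary[7] || fit$params$sigma2 < 1e-4)
})

test_that("doubling the response doubles the fitted mean curve", {
  co <- small_jm_cohort()
  lt <- co$long[co$long$subject <= 120, ]
  spec <- co$spec
  f1 <- fit_lmm(lt, spec)
  lt2 <- lt; lt2$food_g_day <- 2 * lt2$food_g_day
  f2 <- fit_lmm(lt2, spec)
  grid <- bspline_basis(seq(0.3, 5.9, length.out = 30), spec)
  expect_equal(as.numeric(grid %*% f2$params$beta),
               2 * as.numeric(grid %*% f1$params$beta), tolerance = 1e-3)
})

test_that("fixed effects are recovered within 3 standard errors", {
  spec <- spline_spec()
  tr <- default_truth_jm()
  ok <- 0L
  for (r in 1:3) {
    cfg <- cohort_config(n_subjects = 300, seed = 800 + r, followup_max = 6,
                         dropout_hazard = 0)
    bl <- simulate_baseline(cfg)
    long <- simulate_trajectories(bl, tr$lmm, spec, cfg)
    fit <- fit_lmm(long, spec)
    se <- sqrt(diag(fit$cov_beta))
    ok <- ok + all(abs(fit$params$beta - tr$lmm$beta) < 3.5 * se)
  }
  expect_gte(ok, 2L)
})

test_that("loglik at the ML estimate is at least the loglik at the truth", {
  spec <- spline_spec()
  tr <- default_truth_jm()
  cfg <- cohort_config(n_subjects = 200, seed = 77, followup_max = 6,
                       dropout_hazard = 0)
  bl <- simulate_baseline(cfg)
  long <- simulate_trajectories(bl, tr$lmm, spec, cfg)
  fit <- fit_lmm(long, spec)
  expect_gte(fit$loglik, lmm_loglik(tr$lmm, long, spec) - 1e-6)
})

test_that("ML fit agrees with nlme::lme diagonal ML on the same data", {
  skip_if_not_installed("nlme")
  co <- small_jm_cohort()
  lt <- co$long[co$long$subject <= 150, ]
  spec <- co$spec
  fit <- fit_lmm(lt, spec)
  X <- bspline_basis(lt$age_years, spec)
  df <- data.frame(y = lt$food_g_day, subject = lt$subject, X[, -1])
  m <- nlme::lme(y ~ B1 + B2 + B3 + B4 + B5,
                 random = list(subject = nlme::pdDiag(~ B1 + B2 + B3 + B4 + B5)),
                 data = df, method = "ML",
                 control = nlme::lmeControl(opt = "optim", maxIter = 300,
                                            msMaxIter = 300))
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
  expect_equal(fit$params$beta, unname(nlme::fixef(m)), tolerance = 1e-3)
})

test_that("fitted curves are invariant to the basis parameterization", {
  # refit with the raw 6-column basis via GLS at the fitted variances; the
  # implied mean curve must agree with the intercept parameterization
  co <- small_jm_cohort()
  lt <- co$long[co$long$subject <= 100, ]
  spec <- co$spec
  fit <- fit_lmm(lt, spec)
  # the raw 6-column basis spans the same space: the fitted curve must be
  # exactly representable in it
  grid <- seq(0.3, 5.9, length.out = 40)
  Gi <- bspline_basis(grid, spec)
  Gf <- bspline_basis(grid, spec, full = TRUE)
  cf_full <- qr.solve(Gf, as.numeric(Gi %*% fit$params$beta))
  expect_equal(as.numeric(Gf %*% cf_full),
               as.numeric(Gi %*% fit$params$beta), tolerance = 1e-6)
})

test_that("empirical-Bayes modes: closed form, prior limit and shrinkage", {
  co <- small_jm_cohort()
  lt <- co$long[co$long$subject <= 30, ]
  fit <- fit_lmm(lt, co$spec)
  eb <- empirical_bayes_modes(fit, lt, subjects = c(unique(lt$subject), 9999))
  # subject with no records sits at the prior mode with prior covariance
  expect_equal(unname(eb$modes["9999", ]), rep(0, 6))
  expect_equal(eb$cov[["9999"]],
               diag(pmax(fit$params$re_var, 1e-10), 6), tolerance = 1e-9)
  # closed form maximizes the conditional density: compare to numeric optim
  d <- pmax(fit$params$re_var, 1e-10)
  for (s in unique(lt$subject)[1:5]) {
    yi <- lt$food_g_day[lt$subject == s]
    Xi <- bspline_basis(lt$age_years[lt$subject == s], co$spec)
    negdens <- function(b)
      0.5 * sum((yi - Xi %*% (fit$params$beta + b))^2) / fit$params$sigma2 +
      0.5 * sum(b^2 / d)
    o <- optim(rep(0, 6), negdens, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    # the closed form must be at least as good as the numeric optimum
    expect_lte(negdens(unname(eb$modes[as.character(s), ])),
               negdens(o$par) + 1e-6)
  }
  # modes shrink to 0 as the residual variance explodes
  fit_big <- fit
  fit_big$params$sigma2 <- 1e9
  eb_big <- empirical_bayes_modes(fit_big, lt)
  expect_lt(max(abs(eb_big$modes)), 1e-2 * max(abs(eb$modes[-nrow(eb$modes), ])))
})

test_that("fits serialize to JSON with their estimates intact", {
  co <- small_jm_cohort()
  lt <- co$long[co$long$subject <= 60, ]
  fit <- fit_lmm(lt, co$spec)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$type, "lmm")
  expect_equal(js$params$beta, fit$params$beta, tolerance = 1e-12)
  expect_equal(js$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(js$spec$interior_knots, co$spec$interior_knots)
})
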