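#' Settings for the latent-class joint model fit
#'
#' @param n_starts random EM starts (in addition to a k-means start on
#'   per-subject trajectory features).
#' @param em_short iterations for the short exploratory EM runs.
#' @param em_maxit iteration budget for the final EM run.
#' @param tol absolute log-likelihood convergence tolerance for EM.
#' @param polish quasi-Newton polishing after EM (analytic score).
#' @param polish_maxit iteration budget for the polishing stage.
#' @param se compute the observed-information covariance.
#' @param spurious_frac classes smaller than this fraction of subjects are
#'   flagged as spurious.
#' @return list of class `jlcmm_control`.
#' @export
jlcmm_control <- function(n_starts = 10, em_short = 15, em_maxit = 400,
                          tol = 1e-6, polish = TRUE, polish_maxit = 100,
                          se = TRUE, spurious_frac = 0.01) {
  structure(list(n_starts = n_starts, em_short = em_short,
                 em_maxit = em_maxit, tol = tol, polish = polish,
                 polish_maxit = polish_maxit, se = se,
                 spurious_frac = spurious_frac), class = "jlcmm_control")
}

# ---- data layout -----------------------------------------------------------

# pattern-grouped longitudinal blocks plus survival exposure matrix
jlcmm_data <- function(long_table, endpoints, baseline, spec, hzspec,
                       gamma_names = character(0)) {
  subjects <- endpoints$subject
  lt <- long_table[long_table$subject %in% subjects, , drop = FALSE]
  dat <- lmm_data(lt, spec)
  sub_row <- match(dat$subjects, subjects)       # group subject -> endpoint row
  Tm <- ifelse(endpoints$event == 1, endpoints$midpoint, endpoints$censor_age)
  if (any(Tm > hzspec$followup_max + 1e-9))
    stop("endpoint times exceed the hazard follow-up; truncate first")
  delta <- as.numeric(endpoints$event == 1)
  bounds <- c(0, hzspec$knots, hzspec$followup_max)
  K <- hzspec$n_intervals
  expo <- vapply(seq_len(K), function(j)
    pmax(0, pmin(Tm, bounds[j + 1]) - bounds[j]), numeric(length(Tm)))
  segT <- hazard_interval(pmax(Tm, 1e-9), hzspec)
  W <- if (length(gamma_names))
    baseline_design(baseline[match(subjects, baseline$subject), ,
                             drop = FALSE])[, gamma_names, drop = FALSE]
  else matrix(0, length(subjects), 0)

  # pattern-major flat layout for the compiled kernels
  Xflat <- do.call(rbind, lapply(dat$groups, `[[`, "X"))
  x_off <- cumsum(c(0L, vapply(dat$groups, function(g) nrow(g$X),
                               integer(1))))
  yflat <- unlist(lapply(dat$groups, function(g) as.numeric(t(g$Y))),
                  use.names = FALSE)
  n_per <- unlist(lapply(dat$groups, function(g)
    rep(ncol(g$Y), nrow(g$Y))))
  y_off <- cumsum(c(0L, n_per))
  s_off <- cumsum(c(0L, vapply(dat$groups, function(g) nrow(g$Y),
                               integer(1))))
  row_of <- unlist(lapply(dat$groups, function(g)
    match(g$subjects, subjects))) - 1L

  list(dat = dat, sub_row = sub_row, subjects = subjects, n = length(subjects),
       Tm = Tm, delta = delta, expo = expo, segT = segT, W = W,
       hzspec = hzspec, spec = spec, gamma_names = gamma_names,
       n_obs = dat$n_obs,
       Xflat = Xflat, x_off = as.integer(x_off), yflat = yflat,
       y_off = as.integer(y_off), s_off = as.integer(s_off),
       row_of = as.integer(row_of))
}

# ---- likelihood ------------------------------------------------------------

# per-subject per-class longitudinal loglik matrix (n x G); compiled
# pattern-grouped kernel
jlcmm_long_ll <- function(beta, re_var, sigma2, jd) {
  .jlcmm_longll_cpp(as.matrix(beta), re_var, sigma2, jd$Xflat, jd$x_off,
                    jd$yflat, jd$y_off, jd$s_off, jd$row_of, jd$n)
}

# per-subject per-class survival loglik matrix (n x G)
jlcmm_surv_ll <- function(log_heights, gamma, jd) {
  G <- ncol(log_heights)
  lp <- if (ncol(jd$W)) as.numeric(jd$W %*% gamma) else rep(0, jd$n)
  ll <- matrix(0, jd$n, G)
  for (g in seq_len(G)) {
    H0 <- as.numeric(jd$expo %*% exp(log_heights[, g]))
    ll[, g] <- jd$delta * (log_heights[jd$segT, g] + lp) - exp(lp) * H0
  }
  ll
}

#' Log-likelihood of the joint latent class mixed model
#'
#' Sum over subjects of log sum over classes of pi_g times the marginal
#' Gaussian likelihood of the records under class-g fixed effects (random
#' effects integrate analytically) times the class-g piecewise-exponential
#' survival likelihood scaled by exp(gamma'w).
#'
#' @param params a [jlcmm_params()].
#' @param long_table longitudinal records.
#' @param endpoints endpoint table (truncated to the hazard horizon).
#' @param baseline baseline covariates (when `gamma` is non-empty).
#' @param spec a [spline_spec()].
#' @param include_survival set `FALSE` to drop the survival factor (pure
#'   latent-class mixed model).
#' @return scalar log-likelihood.
#' @export
jlcmm_loglik <- function(params, long_table, endpoints, baseline = NULL,
                         spec = spline_spec(), include_survival = TRUE) {
  jd <- jlcmm_data(long_table, endpoints, baseline, spec, params$hazard,
                   params$gamma_names %||% character(0))
  jlcmm_loglik_jd(params, jd, include_survival)$loglik
}

jlcmm_loglik_jd <- function(params, jd, include_survival = TRUE) {
  ll_long <- jlcmm_long_ll(params$beta, pmax(params$re_var, 1e-10),
                           params$sigma2, jd)
  ll_surv <- if (include_survival)
    jlcmm_surv_ll(params$log_heights, params$gamma, jd)
  else matrix(0, jd$n, params$G)
  lpi <- log(class_probs(params$lambda))
  M <- sweep(ll_long + ll_surv, 2, lpi, "+")
  mx <- apply(M, 1, max)
  li <- mx + log(rowSums(exp(M - mx)))
  w <- exp(M - li)
  list(loglik = sum(li), posterior = w, ll_long = ll_long, ll_surv = ll_surv)
}

# ---- parameter packing -----------------------------------------------------

# layout: beta (p*G) | log d (p) | log s2 | gamma (c) | hazard block | lambda
# (G-1). hazard block: free = xi (K*G column-major); proportional = xi_base
# (K) then log theta (G-1).
jlcmm_pack <- function(params, proportional = FALSE) {
  base <- c(as.numeric(params$beta), log(pmax(params$re_var, 1e-12)),
            log(params$sigma2), params$gamma)
  hzb <- if (proportional) {
    th <- colMeans(params$log_heights[, -1, drop = FALSE] -
                     params$log_heights[, 1])
    c(params$log_heights[, 1], th)
  } else as.numeric(params$log_heights)
  c(base, hzb, params$lambda[-params$G])
}

jlcmm_unpack <- function(th, jd, G, proportional = FALSE) {
  p <- spline_dim(jd$spec); K <- jd$hzspec$n_intervals
  c_ <- ncol(jd$W)
  i <- 0
  beta <- matrix(th[(i + 1):(i + p * G)], p, G); i <- i + p * G
  re_var <- exp(th[(i + 1):(i + p)]); i <- i + p
  sigma2 <- exp(th[i + 1]); i <- i + 1
  gamma <- stats::setNames(if (c_) th[(i + 1):(i + c_)] else numeric(0),
                           jd$gamma_names)
  i <- i + c_
  if (proportional) {
    xi1 <- th[(i + 1):(i + K)]; i <- i + K
    ltheta <- if (G > 1) th[(i + 1):(i + G - 1)] else numeric(0)
    i <- i + G - 1
    lh <- cbind(xi1, if (G > 1) outer(xi1, rep(1, G - 1)) +
                  matrix(ltheta, K, G - 1, byrow = TRUE))
    lh <- matrix(lh, K, G)
  } else {
    lh <- matrix(th[(i + 1):(i + K * G)], K, G); i <- i + K * G
  }
  lambda <- c(if (G > 1) th[(i + 1):(i + G - 1)] else numeric(0), 0)
  jlcmm_params(beta, re_var, sigma2, gamma, lh, lambda, jd$hzspec)
}

spline_dim <- function(spec) spec$n_basis + 1L

# analytic score of the mixture loglik in the packed parameterization
jlcmm_score <- function(th, jd, G, proportional = FALSE) {
  params <- jlcmm_unpack(th, jd, G, proportional)
  p <- spline_dim(jd$spec); K <- jd$hzspec$n_intervals; c_ <- ncol(jd$W)
  ev <- jlcmm_loglik_jd(params, jd)
  w <- ev$posterior
  d <- pmax(params$re_var, 1e-10); s2 <- params$sigma2
  sc <- .jlcmm_scoreacc_cpp(params$beta, d, s2, w, jd$Xflat, jd$x_off,
                            jd$yflat, jd$y_off, jd$s_off, jd$row_of)
  g_beta <- sc$g_beta; g_d <- as.numeric(sc$g_d); g_s2 <- sc$g_s2
  lp <- if (c_) as.numeric(jd$W %*% params$gamma) else rep(0, jd$n)
  elp <- exp(lp)
  Hg <- sapply(seq_len(G), function(g)
    as.numeric(jd$expo %*% exp(params$log_heights[, g])))
  g_gamma <- if (c_)
    as.numeric(t(jd$W) %*% (jd$delta - elp * rowSums(w * Hg)))
  else numeric(0)
  g_xi <- matrix(0, K, G)
  for (g in seq_len(G)) {
    hgt <- exp(params$log_heights[, g])
    for (r in seq_len(K)) {
      g_xi[r, g] <- sum(w[, g] * (jd$delta * (jd$segT == r) -
                                    elp * jd$expo[, r] * hgt[r]))
    }
  }
  pi_g <- class_probs(params$lambda)
  g_lambda <- colSums(w) - jd$n * pi_g
  hz_grad <- if (proportional) {
    c(rowSums(g_xi), if (G > 1) colSums(g_xi[, -1, drop = FALSE]))
  } else as.numeric(g_xi)
  c(as.numeric(g_beta), g_d * d, g_s2 * s2, g_gamma, hz_grad,
    if (G > 1) g_lambda[-G])
}

# ---- EM --------------------------------------------------------------------

# one EM sweep; returns updated params (ev: reusable posterior evaluation
# at `params`)
jlcmm_em_step <- function(params, jd, proportional = FALSE, ev = NULL) {
  p <- spline_dim(jd$spec); K <- jd$hzspec$n_intervals
  G <- params$G; c_ <- ncol(jd$W)
  ev <- ev %||% jlcmm_loglik_jd(params, jd)
  w <- ev$posterior
  d <- pmax(params$re_var, 1e-10); s2 <- params$sigma2

  # class probabilities
  pi_g <- pmax(colMeans(w), 1e-12)
  lambda <- log(pi_g / pi_g[G])

  # weighted GLS for class-specific fixed effects (first compiled pass),
  # then the variance EM update at the new fixed effects (second pass)
  acc <- .jlcmm_emacc_cpp(params$beta, d, s2, w, jd$Xflat, jd$x_off,
                          jd$yflat, jd$y_off, jd$s_off, jd$row_of)
  beta <- sapply(seq_len(G), function(g)
    solve(acc$A[, , g], acc$bv[, g]))
  beta <- matrix(beta, p, G)
  acc2 <- .jlcmm_emacc_cpp(beta, d, s2, w, jd$Xflat, jd$x_off,
                           jd$yflat, jd$y_off, jd$s_off, jd$row_of)
  re_var <- as.numeric(acc2$d_acc) / jd$n
  sigma2 <- acc2$s2_acc / jd$n_obs

  # survival block: closed-form heights given gamma, Newton step for gamma
  gamma <- params$gamma
  lh <- params$log_heights
  for (it in 1:3) {
    lp <- if (c_) as.numeric(jd$W %*% gamma) else rep(0, jd$n)
    elp <- exp(lp)
    if (proportional) {
      # shared shape: theta_g scales class-g hazard
      theta <- c(1, exp(colMeans(lh[, -1, drop = FALSE] - lh[, 1]))[seq_len(max(G - 1, 0))])
      for (inner in 1:3) {
        ev_r <- ex_r <- numeric(K)
        for (r in seq_len(K)) {
          ev_r[r] <- sum(w * (jd$delta * (jd$segT == r)))
          ex_r[r] <- sum(sweep(w, 2, theta, "*") * (elp * jd$expo[, r]))
        }
        xi1 <- log(pmax(ev_r, 1e-8) / pmax(ex_r, 1e-12))
        h1 <- exp(xi1)
        for (g in seq_len(G)[-1]) {
          evg <- sum(w[, g] * jd$delta)
          exg <- sum(w[, g] * elp * as.numeric(jd$expo %*% h1))
          theta[g] <- pmax(evg, 1e-8) / pmax(exg, 1e-12)
        }
      }
      lh <- sapply(seq_len(G), function(g) xi1 + log(theta[g]))
    } else {
      for (g in seq_len(G)) {
        for (r in seq_len(K)) {
          evn <- sum(w[, g] * jd$delta * (jd$segT == r))
          exn <- sum(w[, g] * elp * jd$expo[, r])
          lh[r, g] <- log(pmax(evn, 1e-8) / pmax(exn, 1e-12))
        }
      }
    }
    if (!c_) break
    # one Newton step for gamma under the new heights
    Hg <- sapply(seq_len(G), function(g)
      as.numeric(jd$expo %*% exp(lh[, g])))
    mu <- elp * rowSums(w * Hg)
    sc <- as.numeric(t(jd$W) %*% (jd$delta - mu))
    info <- t(jd$W) %*% (mu * jd$W)
    step <- tryCatch(solve(info, sc), error = function(e) rep(0, c_))
    gamma <- gamma + pmin(pmax(step, -1), 1)
  }
  jlcmm_params(beta, re_var, sigma2,
               stats::setNames(gamma, jd$gamma_names),
               matrix(lh, K, G), lambda, jd$hzspec)
}

jlcmm_run_em <- function(params, jd, maxit, tol, proportional = FALSE) {
  ev <- jlcmm_loglik_jd(params, jd)
  ll_old <- ev$loglik
  trace <- ll_old
  it <- 0L
  for (it in seq_len(maxit)) {
    params_new <- jlcmm_em_step(params, jd, proportional, ev)
    ev_new <- jlcmm_loglik_jd(params_new, jd)
    ll_new <- ev_new$loglik
    if (!is.finite(ll_new) || ll_new < ll_old - 1e-6) break  # guard
    params <- params_new
    ev <- ev_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_old) < tol) { ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  list(params = params, loglik = ll_old, trace = trace, iters = it)
}

# crude moment-based longitudinal starting values (OLS fixed effects,
# residual variance split between the subject level and the day level);
# enough to seed EM when a full likelihood pre-fit is not wanted
ols_lmm_params <- function(long_table, spec) {
  X <- bspline_basis(long_table$age_years, spec)
  beta <- qr.solve(crossprod(X), crossprod(X, long_table$food_g_day))
  r <- long_table$food_g_day - as.numeric(X %*% beta)
  v <- stats::var(r)
  lmm_params(as.numeric(beta), rep(max(v / 8, 1e-3), ncol(X)),
             max(v / 2, 1e-3))
}

# starting values: k-means on per-subject trajectory features plus
# perturbed random starts
jlcmm_starts <- function(jd, G, n_starts, seed) {
  # per-subject features: mean response in age thirds
  feats <- matrix(0, jd$n, 3)
  for (g_ix in seq_along(jd$dat$groups)) {
    grp <- jd$dat$groups[[g_ix]]
    rows <- jd$sub_row[match(grp$subjects, jd$dat$subjects)]
    ages <- grp$ages
    cut_ix <- cut(ages, breaks = c(-Inf, 2, 4, Inf), labels = FALSE)
    for (k in 1:3) {
      sel <- cut_ix == k
      feats[rows, k] <- if (any(sel)) rowMeans(grp$Y[, sel, drop = FALSE])
        else 0
    }
  }
  set.seed(derive_seed(seed, 7L))
  starts <- vector("list", n_starts + 1L)
  km <- tryCatch(stats::kmeans(scale(feats), centers = G, nstart = 5),
                 error = function(e) NULL)
  starts[[1L]] <- if (!is.null(km)) km$cluster else
    sample.int(G, jd$n, replace = TRUE)
  for (s in seq_len(n_starts))
    starts[[s + 1L]] <- sample.int(G, jd$n, replace = TRUE)
  starts
}

# initial parameters from a hard class assignment
jlcmm_init_from_labels <- function(labels, jd, G, base_lmm) {
  p <- spline_dim(jd$spec); K <- jd$hzspec$n_intervals
  beta <- matrix(0, p, G)
  for (g in seq_len(G)) {
    # OLS per class on that class's records
    A <- matrix(0, p, p); bv <- numeric(p)
    for (g_ix in seq_along(jd$dat$groups)) {
      grp <- jd$dat$groups[[g_ix]]
      rows <- jd$sub_row[match(grp$subjects, jd$dat$subjects)]
      sel <- labels[rows] == g
      if (!any(sel)) next
      A <- A + sum(sel) * crossprod(grp$X)
      bv <- bv + as.numeric(crossprod(grp$X, colSums(grp$Y[sel, , drop = FALSE])))
    }
    beta[, g] <- if (rcond(A) > 1e-12) solve(A, bv) else base_lmm$beta
  }
  tab <- tabulate(labels, G)
  pi_g <- pmax(tab / sum(tab), 1e-3)
  rate <- sum(jd$delta) / max(sum(jd$expo), 1e-9)
  jlcmm_params(beta, base_lmm$re_var, base_lmm$sigma2,
               stats::setNames(rep(0, ncol(jd$W)), jd$gamma_names),
               matrix(log(max(rate, 1e-6)), K, G),
               log(pi_g / pi_g[G]), jd$hzspec)
}

# deterministic reporting order: descending class size
jlcmm_relabel <- function(params, posterior) {
  sizes <- colMeans(posterior)
  ord <- order(sizes, decreasing = TRUE)
  if (identical(ord, seq_len(params$G)))
    return(list(params = params, posterior = posterior, order = ord))
  pi_g <- class_probs(params$lambda)[ord]
  params2 <- jlcmm_params(params$beta[, ord, drop = FALSE], params$re_var,
                          params$sigma2,
                          stats::setNames(params$gamma, params$gamma_names),
                          params$log_heights[, ord, drop = FALSE],
                          log(pi_g / pi_g[params$G]), params$hazard)
  list(params = params2, posterior = posterior[, ord, drop = FALSE],
       order = ord)
}

#' Fit the joint latent class mixed model
#'
#' EM (posterior class probabilities; weighted GLS, variance-component,
#' class-probability and piecewise-exponential updates) from a k-means start
#' on trajectory features plus random starts, keeping the best likelihood,
#' followed by quasi-Newton polishing with the analytic score. Classes are
#' reported in decreasing size order.
#'
#' @param long_table longitudinal records.
#' @param endpoints endpoint table; truncated internally to the hazard
#'   horizon.
#' @param baseline baseline covariate table.
#' @param spec a [spline_spec()].
#' @param G number of latent classes.
#' @param hzspec a [hazard_spec()]; default knots (1.99, 3.99, 5.99) to 15
#'   years.
#' @param covariates gamma contrasts shared across classes.
#' @param control a [jlcmm_control()].
#' @param proportional constrain non-reference class hazards to be
#'   proportional to the class-1 hazard (one log ratio per class).
#' @param seed seed for the random starts.
#' @param init longitudinal starting values: `"lmm"` (full ML pre-fit,
#'   default) or `"ols"` (moment-based; cheaper, for replicate studies).
#' @return object of class `jlcmm_fit`: `params`, `loglik`, `bic`,
#'   `posterior`, `modal`, `class_sizes`, `classification`, `vcov`,
#'   `theta` (per extra class when `proportional`), diagnostics.
#' @export
fit_jlcmm <- function(long_table, endpoints, baseline = NULL,
                      spec = spline_spec(), G = 2,
                      hzspec = hazard_spec(c(1.99, 3.99, 5.99), 15),
                      covariates = c("girl", "high_risk", "familial_yes",
                                     "familial_missing"),
                      control = jlcmm_control(), proportional = FALSE,
                      seed = 1, init = c("lmm", "ols")) {
  if (G < 1) stop("G must be at least 1")
  endpoints <- truncate_endpoints(endpoints, hzspec$followup_max)
  jd <- jlcmm_data(long_table, endpoints, baseline, spec, hzspec, covariates)
  base_lmm <- if (match.arg(init) == "lmm") fit_lmm(long_table, spec)$params
    else ols_lmm_params(long_table, spec)

  if (G == 1L) {
    cand <- list(jlcmm_init_from_labels(rep(1L, jd$n), jd, 1L, base_lmm))
  } else {
    starts <- jlcmm_starts(jd, G, control$n_starts, seed)
    short <- lapply(starts, function(lab) {
      init <- jlcmm_init_from_labels(lab, jd, G, base_lmm)
      tryCatch(jlcmm_run_em(init, jd, control$em_short, control$tol,
                            proportional),
               error = function(e) NULL)
    })
    short <- Filter(Negate(is.null), short)
    if (!length(short)) stop("all EM starts failed")
    cand <- list(short[[which.max(vapply(short, `[[`, numeric(1),
                                         "loglik"))]]$params)
  }
  em <- jlcmm_run_em(cand[[1]], jd, control$em_maxit, control$tol,
                     proportional)
  params <- em$params
  ll <- em$loglik

  if (control$polish) {
    th0 <- jlcmm_pack(params, proportional)
    fn <- function(th) {
      v <- tryCatch(
        jlcmm_loglik_jd(jlcmm_unpack(th, jd, G, proportional), jd)$loglik,
        error = function(e) -Inf)
      if (!is.finite(v)) return(1e10)
      -v
    }
    gr <- function(th) {
      g <- tryCatch(jlcmm_score(th, jd, G, proportional),
                    error = function(e) rep(0, length(th)))
      g[!is.finite(g)] <- 0
      -g
    }
    opt <- stats::optim(th0, fn, gr, method = "BFGS",
                        control = list(maxit = control$polish_maxit,
                                       reltol = 1e-10))
    if (-opt$value >= ll) {
      params <- jlcmm_unpack(opt$par, jd, G, proportional)
      ll <- -opt$value
    }
  }

  ev <- jlcmm_loglik_jd(params, jd)
  rel <- jlcmm_relabel(params, ev$posterior)
  params <- rel$params; posterior <- rel$posterior

  modal <- max.col(posterior)
  sizes <- tabulate(modal, G)
  classification <- vapply(seq_len(G), function(g)
    if (sizes[g] > 0) mean(posterior[modal == g, g]) else NA_real_,
    numeric(1))
  p <- spline_dim(spec); K <- hzspec$n_intervals; c_ <- ncol(jd$W)
  npar <- p * G + p + 1 + c_ + (if (proportional) K + (G - 1) else K * G) +
    (G - 1)
  vc <- NULL
  if (control$se) {
    th <- jlcmm_pack(params, proportional)
    Hn <- jlcmm_observed_info(th, jd, G, proportional)
    vc <- tryCatch(solve(Hn), error = function(e) MASS_ginv(Hn))
  }
  theta <- NULL
  if (proportional && G > 1) {
    th <- jlcmm_pack(params, proportional)
    ix <- p * G + p + 1 + c_ + K + seq_len(G - 1)
    lt <- th[ix]
    se_lt <- if (!is.null(vc)) sqrt(pmax(diag(vc)[ix], 0)) else NA_real_
    # a ratio collapsed onto the zero boundary (a class without posterior
    # events) is unidentified: report an infinite SE, not a Wald P
    bdry <- lt < -8 | !is.finite(se_lt)
    se_lt[bdry] <- Inf
    theta <- data.frame(class = seq_len(G)[-1], hr = exp(lt), se_log = se_lt,
                        lo = ifelse(bdry, 0, exp(lt - 1.96 * se_lt)),
                        hi = ifelse(bdry, Inf, exp(lt + 1.96 * se_lt)),
                        p = ifelse(bdry, NA_real_,
                                   2 * stats::pnorm(-abs(lt / se_lt))),
                        boundary = bdry)
  }
  structure(list(
    params = params, loglik = ll, bic = -2 * ll + npar * log(jd$n),
    npar = npar, posterior = posterior, modal = modal,
    class_sizes = sizes, classification = classification,
    vcov = vc, theta = theta, proportional = proportional,
    em_trace = em$trace, converged = is.finite(ll),
    spurious = any(sizes < control$spurious_frac * jd$n),
    subjects = jd$subjects, n_events = sum(jd$delta), G = G,
    spec = spec, hzspec = hzspec, jd = jd
  ), class = "jlcmm_fit")
}

# observed information via central differences of the analytic score
jlcmm_observed_info <- function(th, jd, G, proportional, step_rel = 1e-5) {
  np <- length(th)
  H <- matrix(0, np, np)
  for (j in seq_len(np)) {
    h <- step_rel * max(abs(th[j]), 1)
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    H[, j] <- (jlcmm_score(tp, jd, G, proportional) -
                 jlcmm_score(tm, jd, G, proportional)) / (2 * h)
  }
  -(H + t(H)) / 2
}

#' @export
print.jlcmm_fit <- function(x, ...) {
  cat(sprintf("JLCMM fit: G = %d, %d subjects, %d events, loglik %.2f, BIC %.2f\n",
              x$G, length(x$subjects), x$n_events, x$loglik, x$bic))
  cat("class sizes:", x$class_sizes,
      " mean modal posterior:", round(x$classification, 3), "\n")
  if (!is.null(x$theta)) {
    cat("proportional baseline-hazard ratio (vs class 1):\n")
    print(x$theta, digits = 3)
  }
  invisible(x)
}

#' Choose the number of latent classes
#'
#' Returns the min-BIC class count alongside the discrimination diagnostics
#' the final judgment should weigh (mean modal posterior per class, smallest
#' class share, entropy). Ties within `tol` prefer fewer classes.
#'
#' @param fits list of [fit_jlcmm()] results (e.g. G = 1..4).
#' @param tol BIC tie tolerance.
#' @return list `chosen_G`, `table` (one row per fit), `fits`.
#' @export
select_num_classes <- function(fits, tol = 1e-6) {
  if (length(fits) < 2L) stop("supply at least two candidate fits")
  tab <- do.call(rbind, lapply(fits, function(f) {
    w <- pmax(f$posterior, 1e-300)
    entropy <- -sum(w * log(w)) / length(f$subjects)
    data.frame(G = f$G, loglik = f$loglik, bic = f$bic,
               min_class_share = min(f$class_sizes) / length(f$subjects),
               min_modal_posterior = min(f$classification, na.rm = TRUE),
               entropy = entropy, spurious = f$spurious)
  }))
  best <- min(tab$bic)
  chosen <- min(tab$G[tab$bic <= best + tol])
  list(chosen_G = chosen, table = tab, fits = fits)
}

#' Piecewise hazard ratios between two latent classes
#'
#' For a two-class fit, the hazard ratio of class 2 relative to class 1 on
#' each reporting interval; intervals must align with the baseline-hazard
#' segments (knots 1.99 / 3.99 / 5.99 map onto the reporting ages 2 / 4 /
#' 6). The log ratio is xi_2r - xi_1r, with the delta-method variance from
#' the estimate covariance (linear here, so the delta method is exact given
#' the covariance).
#'
#' @param fit a two-class [fit_jlcmm()] result with a covariance.
#' @param intervals list or matrix of reporting intervals.
#' @return data.frame with interval, events per class, HR, CI, P.
#' @export
piecewise_hr <- function(fit, intervals = list(c(0, 2), c(2, 4), c(4, 6),
                                               c(6, 15))) {
  if (fit$G != 2) stop("piecewise hazard ratios need a two-class fit")
  if (fit$proportional)
    stop("piecewise hazard ratios need the unconstrained (non-proportional) fit")
  if (is.null(fit$vcov)) stop("fit carries no covariance; refit with se = TRUE")
  hz <- fit$hzspec; K <- hz$n_intervals
  bounds <- c(0, hz$knots, hz$followup_max)
  p <- spline_dim(fit$spec); c_ <- ncol(fit$jd$W)
  off <- p * fit$G + p + 1 + c_
  rows <- lapply(intervals, function(iv) {
    r <- which(abs(bounds[-length(bounds)] - iv[1]) < 0.05 &
                 abs(bounds[-1] - iv[2]) < 0.05)
    if (!length(r))
      stop(sprintf("interval (%g, %g] does not align with the hazard knots",
                   iv[1], iv[2]))
    i1 <- off + r          # xi_{r,1}
    i2 <- off + K + r      # xi_{r,2}
    est <- fit$params$log_heights[r, 2] - fit$params$log_heights[r, 1]
    v <- fit$vcov[i1, i1] + fit$vcov[i2, i2] - 2 * fit$vcov[i1, i2]
    se <- sqrt(max(v, 0))
    in_iv <- fit$jd$Tm > iv[1] & fit$jd$Tm <= iv[2] & fit$jd$delta == 1
    # a class height at its zero boundary means no posterior events in the
    # interval: the log ratio is unidentified and the Wald SE meaningless
    boundary <- any(fit$params$log_heights[r, ] < -14)
    if (boundary) se <- Inf
    data.frame(start = iv[1], end = iv[2],
               events_class1 = sum(in_iv & fit$modal == 1),
               events_class2 = sum(in_iv & fit$modal == 2),
               hr = exp(est),
               lo = if (boundary) 0 else exp(est - 1.96 * se),
               hi = if (boundary) Inf else exp(est + 1.96 * se),
               se_log = se,
               p = if (boundary) NA_real_ else
                 2 * stats::pnorm(-abs(est / se)))
  })
  do.call(rbind, rows)
}

#' Overall hazard ratio under proportional class baseline hazards
#'
#' Refits the latent-class model with the non-reference class hazard
#' constrained to a single multiple of the class-1 hazard over the whole
#' follow-up and reports that multiple with its Wald interval.
#'
#' @inheritParams fit_jlcmm
#' @param ... further arguments passed to [fit_jlcmm()] (e.g. `init`).
#' @return the proportional [fit_jlcmm()] object (see its `theta` element).
#' @export
overall_hr_proportional <- function(long_table, endpoints, baseline = NULL,
                                    spec = spline_spec(), G = 2,
                                    hzspec = hazard_spec(c(1.99, 3.99, 5.99),
                                                         15),
                                    covariates = c("girl", "high_risk",
                                                   "familial_yes",
                                                   "familial_missing"),
                                    control = jlcmm_control(), seed = 1,
                                    ...) {
  fit_jlcmm(long_table, endpoints, baseline, spec, G, hzspec, covariates,
            control, proportional = TRUE, seed = seed, ...)
}

#' Delete-d jackknife standard error (d = 5)
#'
#' Repeatedly drops `d` randomly chosen subjects, re-estimates, and applies
#' the delete-d variance scaling ((n - d) / d) x mean squared deviation.
#' Random subsets are used rather than all C(n, d) combinations.
#'
#' @param cohort list with `baseline`, `long`, `endpoints` elements (a
#'   [simulate_cohort()] result works directly).
#' @param estimator function(baseline, long, endpoints) returning a numeric
#'   scalar (or vector).
#' @param seed integer seed.
#' @param d subjects deleted per resample.
#' @param n_resample number of resamples.
#' @return list `se`, `estimates` (resample x statistic matrix),
#'   `n_failed`.
#' @export
jackknife_d5 <- function(cohort, estimator, seed = 1, d = 5,
                         n_resample = 200) {
  subjects <- cohort$baseline$subject
  n <- length(subjects)
  if (n < 50) stop("need at least 50 subjects for a delete-5 jackknife")
  set.seed(derive_seed(seed, 8L))
  ests <- vector("list", n_resample)
  failed <- 0L
  for (r in seq_len(n_resample)) {
    drop_ids <- sample(subjects, d)
    keep_b <- !(cohort$baseline$subject %in% drop_ids)
    keep_l <- !(cohort$long$subject %in% drop_ids)
    keep_e <- !(cohort$endpoints$subject %in% drop_ids)
    est <- tryCatch(
      estimator(cohort$baseline[keep_b, , drop = FALSE],
                cohort$long[keep_l, , drop = FALSE],
                cohort$endpoints[keep_e, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(est) || any(!is.finite(est))) { failed <- failed + 1L; next }
    ests[[r]] <- est
  }
  ests <- do.call(rbind, Filter(Negate(is.null), ests))
  if (is.null(ests) || nrow(ests) < 2)
    stop("too few successful jackknife resamples")
  dev <- sweep(ests, 2, colMeans(ests))
  se <- sqrt((n - d) / d * colMeans(dev^2))
  list(se = se, estimates = ests, n_failed = failed)
}
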