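#' Optimizer settings for the trajectory mixed model
#'
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param grad_tol gradient max-norm tolerance.
#' @param max_iter iteration budget for the variance-parameter optimizer.
#' @param log_var_floor lower bound for log variances; a variance whose log
#'   estimate hits this bound is reported as a boundary (hard zero) fit.
#' @return list of class `lmm_control`.
#' @export
lmm_control <- function(rel_tol = 1e-8, grad_tol = 1e-4, max_iter = 500,
                        log_var_floor = -12) {
  structure(list(rel_tol = rel_tol, grad_tol = grad_tol, max_iter = max_iter,
                 log_var_floor = log_var_floor), class = "lmm_control")
}

# Group a long table into per-subject design blocks, pooling subjects that
# share the same visit-age pattern so marginal covariances are factorized
# once per pattern rather than once per subject.
lmm_data <- function(long_table, spec, value_col = "food_g_day") {
  stopifnot(all(c("subject", "age_years", value_col) %in% names(long_table)))
  ord <- order(long_table$subject, long_table$age_years)
  lt <- long_table[ord, , drop = FALSE]
  subjects <- unique(lt$subject)
  idx <- split(seq_len(nrow(lt)), factor(lt$subject, levels = subjects))
  key <- vapply(idx, function(ii) paste(signif(lt$age_years[ii], 10), collapse = ","),
                character(1))
  patterns <- unique(key)
  groups <- lapply(patterns, function(p) {
    subj_ii <- which(key == p)
    ages <- lt$age_years[idx[[subj_ii[1]]]]
    Y <- t(vapply(subj_ii, function(s) lt[[value_col]][idx[[s]]],
                  numeric(length(ages))))
    list(ages = ages, X = bspline_basis(ages, spec), Y = Y,
         subjects = subjects[subj_ii])
  })
  list(groups = groups, subjects = subjects, n_subjects = length(subjects),
       n_obs = nrow(lt), spec = spec)
}

# marginal loglik given data blocks; theta-free core used by both the
# public loglik and the profiled fit
lmm_loglik_blocks <- function(beta, re_var, sigma2, dat) {
  ll <- 0
  for (g in dat$groups) {
    X <- g$X
    V <- X %*% (re_var * t(X)) + diag(sigma2, nrow(X))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    R <- sweep(g$Y, 2, as.numeric(X %*% beta))   # residual matrix (subj x obs)
    Z <- forwardsolve(t(ch), t(R))               # obs x subj
    qf <- colSums(Z^2)
    n_i <- nrow(X)
    ll <- ll + nrow(g$Y) * (-0.5 * n_i * log(2 * pi) - sum(log(diag(ch)))) -
      0.5 * sum(qf)
  }
  ll
}

#' Exact marginal log-likelihood of the trajectory mixed model
#'
#' Sum over subjects of the Gaussian log density N(y_i; X_i beta,
#' X_i D X_i' + sigma^2 I) with diagonal D.
#'
#' @param params an [lmm_params()].
#' @param long_table long-format data (`subject`, `age_years`,
#'   `food_g_day`).
#' @param spec a [spline_spec()].
#' @param value_col name of the response column.
#' @return scalar log-likelihood.
#' @export
lmm_loglik <- function(params, long_table, spec, value_col = "food_g_day") {
  dat <- lmm_data(long_table, spec, value_col)
  lmm_loglik_blocks(params$beta, params$re_var, params$sigma2, dat)
}

# GLS fixed effects and their covariance for fixed variance parameters
lmm_gls <- function(re_var, sigma2, dat) {
  p <- ncol(dat$groups[[1]]$X)
  A <- matrix(0, p, p); bvec <- numeric(p)
  for (g in dat$groups) {
    X <- g$X
    V <- X %*% (re_var * t(X)) + diag(sigma2, nrow(X))
    Vi <- chol2inv(chol(V))
    XtVi <- t(X) %*% Vi
    A <- A + nrow(g$Y) * (XtVi %*% X)
    bvec <- bvec + as.numeric(XtVi %*% colSums(g$Y))
  }
  beta <- solve(A, bvec)
  list(beta = as.numeric(beta), cov_beta = solve(A))
}

# Profiled negative loglik and its analytic gradient in the log-variance
# parameters theta = (log d_1..d_p, log sigma2). At the GLS beta the
# envelope theorem makes the partial derivative in theta the full profiled
# gradient: dl/dV = -0.5 (V^-1 - V^-1 r r' V^-1), dV/dd_k = x_k x_k',
# dV/dsigma2 = I.
lmm_profile_obj <- function(theta, dat, floor_ = -12) {
  theta <- pmax(pmin(theta, 20), floor_)
  p <- ncol(dat$groups[[1]]$X)
  re_var <- exp(theta[1:p]); sigma2 <- exp(theta[p + 1])
  gls <- tryCatch(lmm_gls(re_var, sigma2, dat), error = function(e) NULL)
  if (is.null(gls))
    return(list(value = 1e10, grad = rep(0, p + 1)))
  beta <- gls$beta
  ll <- 0; gd <- numeric(p); gs <- 0
  for (g in dat$groups) {
    X <- g$X; n_i <- nrow(X); n_g <- nrow(g$Y)
    V <- X %*% (re_var * t(X)) + diag(sigma2, n_i)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = rep(0, p + 1)))
    Vi <- chol2inv(ch)
    R <- sweep(g$Y, 2, as.numeric(X %*% beta))
    RV <- R %*% Vi
    ll <- ll + n_g * (-0.5 * n_i * log(2 * pi) - sum(log(diag(ch)))) -
      0.5 * sum(RV * R)
    XtViX_diag <- colSums(X * (Vi %*% X))
    RVX <- RV %*% X
    gd <- gd - 0.5 * (n_g * XtViX_diag - colSums(RVX^2))
    gs <- gs - 0.5 * (n_g * sum(diag(Vi)) - sum(RV * RV))
  }
  grad <- -c(gd * re_var, gs * sigma2)          # chain rule to log scale
  grad[theta <= floor_ + 1e-12 & grad > 0] <- 0 # stay on the boundary
  list(value = -ll, grad = grad, beta = beta, cov_beta = gls$cov_beta,
       loglik = ll)
}

#' Maximum-likelihood fit of the trajectory mixed model
#'
#' Random intercept + random spline coefficients with diagonal covariance,
#' estimated by ML (not REML: the joint models and BIC comparisons across
#' fixed-effect structures require ML). Fixed effects are profiled out by
#' GLS; the 7 variance parameters are optimized on the log scale by BFGS
#' with a Nelder-Mead fallback.
#'
#' @inheritParams lmm_loglik
#' @param control an [lmm_control()].
#' @return object of class `lmm_fit`: `params` ([lmm_params()]), `cov_beta`,
#'   `cov_logvar`, `loglik`, `bic` (sample size = number of subjects),
#'   `converged`, `boundary` (logical(7): variance at the zero boundary),
#'   `spec`, `n_subjects`, `n_obs`.
#' @export
fit_lmm <- function(long_table, spec, control = lmm_control(),
                    value_col = "food_g_day") {
  dat <- lmm_data(long_table, spec, value_col)
  p <- ncol(dat$groups[[1]]$X)

  # starting values from OLS
  XtX <- matrix(0, p, p); Xty <- numeric(p); yty <- 0; n <- 0
  for (g in dat$groups) {
    XtX <- XtX + nrow(g$Y) * crossprod(g$X)
    Xty <- Xty + as.numeric(crossprod(g$X, colSums(g$Y)))
    yty <- yty + sum(g$Y^2); n <- n + length(g$Y)
  }
  beta0 <- as.numeric(qr.solve(XtX, Xty))
  rss <- max(yty - sum(beta0 * Xty), 1e-8)
  s2 <- rss / n
  theta0 <- c(rep(log(max(s2 / 2, 1e-6)), p), log(max(s2 / 2, 1e-6)))

  floor_ <- control$log_var_floor
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- lmm_profile_obj(theta, dat, floor_)
      cache$key <- key
    }
    cache$res
  }
  obj <- function(theta) eval_cached(theta)$value
  grd <- function(theta) eval_cached(theta)$grad
  opt <- stats::optim(theta0, obj, grd, method = "L-BFGS-B",
                      lower = floor_, upper = 20,
                      control = list(maxit = control$max_iter,
                                     factr = control$rel_tol / 1e-15))
  theta <- pmax(pmin(opt$par, 20), floor_)
  boundary <- theta <= floor_ + 1e-9
  re_var <- exp(theta[1:p]); re_var[boundary[1:p]] <- 0
  sigma2 <- exp(theta[p + 1])
  gls <- lmm_gls(pmax(re_var, 1e-12), sigma2, dat)
  ll <- lmm_loglik_blocks(gls$beta, pmax(re_var, 1e-12), sigma2, dat)
  n_par <- 2L * p + 1L
  H <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  cov_logvar <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)

  structure(list(
    params = lmm_params(gls$beta, re_var, sigma2),
    cov_beta = gls$cov_beta, cov_logvar = cov_logvar,
    loglik = ll,
    bic = -2 * ll + n_par * log(dat$n_subjects),
    converged = opt$convergence == 0 && is.finite(ll) &&
      max(abs(lmm_profile_obj(theta, dat, floor_)$grad[!boundary])) <
        control$grad_tol * max(1, abs(ll)),
    boundary = boundary,
    spec = spec, n_subjects = dat$n_subjects, n_obs = dat$n_obs,
    value_col = value_col
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Trajectory LMM (ML): %d subjects, %d records, loglik %.2f, BIC %.2f%s\n",
              x$n_subjects, x$n_obs, x$loglik, x$bic,
              if (x$converged) "" else " [not converged]"))
  cat("fixed effects:", paste(sprintf("%.3f", x$params$beta), collapse = " "), "\n")
  cat("RE SDs:", paste(sprintf("%.3f", sqrt(x$params$re_var)), collapse = " "),
      " residual SD:", sprintf("%.3f", sqrt(x$params$sigma2)), "\n")
  invisible(x)
}

#' Serialize a model fit to JSON
#'
#' Emits the estimates, their covariance, the log-likelihood and fit
#' diagnostics (plus the spline specification for fits that carry one) as
#' a JSON string, the exchange format used alongside the delimited-text
#' tables.
#'
#' @param fit an [fit_lmm()] or [fit_jm()] result.
#' @return a JSON string.
#' @export
fit_to_json <- function(fit) {
  payload <- if (inherits(fit, "lmm_fit")) {
    list(type = "lmm",
         params = unclass(fit$params),
         cov_beta = fit$cov_beta, loglik = fit$loglik, bic = fit$bic,
         converged = fit$converged, boundary = fit$boundary,
         spec = unclass(fit$spec),
         n_subjects = fit$n_subjects, n_obs = fit$n_obs)
  } else if (inherits(fit, "jm_fit")) {
    list(type = "jm",
         params = list(lmm = unclass(fit$params$lmm),
                       gamma = as.list(fit$params$gamma),
                       alpha = fit$params$alpha,
                       hazard = unclass(fit$params$hazard)),
         vcov = fit$vcov, loglik = fit$loglik,
         alpha_summary = fit$alpha, gamma_table = fit$gamma_table,
         converged = fit$converged, hessian_pd = fit$hessian_pd,
         spec = unclass(fit$spec),
         n_subjects = fit$n_subjects, n_events = fit$n_events)
  } else stop("unsupported fit object")
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Empirical-Bayes random-effect modes and curvatures
#'
#' Closed-form posterior modes of b_i given y_i for the linear Gaussian
#' model: b_hat = (X'X/sigma^2 + D^-1)^-1 X'(y - X beta)/sigma^2, with
#' posterior precision X'X/sigma^2 + D^-1. A subject without observations
#' gets the prior mode 0 with precision D^-1. Zero prior variances are
#' floored at a tiny positive value so the posterior stays proper.
#'
#' @param fit an [fit_lmm()] result.
#' @param long_table the data the fit was computed on.
#' @param subjects optional full subject roster; subjects without records
#'   receive the prior mode 0 and prior covariance D.
#' @return list with `subjects`, `modes` (n x 6), and `cov` (list of
#'   posterior covariance matrices).
#' @export
empirical_bayes_modes <- function(fit, long_table, subjects = NULL) {
  dat <- lmm_data(long_table, fit$spec, fit$value_col)
  d <- pmax(fit$params$re_var, 1e-10)
  s2 <- fit$params$sigma2
  beta <- fit$params$beta
  p <- length(beta)
  roster <- if (is.null(subjects)) dat$subjects else
    unique(c(dat$subjects, subjects))
  modes <- matrix(0, length(roster), p, dimnames = list(roster, NULL))
  covs <- rep(list(diag(d, p)), length(roster)); names(covs) <- roster
  for (g in dat$groups) {
    X <- g$X
    prec <- crossprod(X) / s2 + diag(1 / d, p)
    Sig <- chol2inv(chol(prec))
    R <- sweep(g$Y, 2, as.numeric(X %*% beta))
    B <- R %*% (X %*% Sig) / s2              # subj x p modes
    for (j in seq_along(g$subjects)) {
      s <- as.character(g$subjects[j])
      modes[s, ] <- B[j, ]
      covs[[s]] <- Sig
    }
  }
  list(subjects = roster, modes = modes, cov = covs)
}
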