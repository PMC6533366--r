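#' Configuration of the synthetic birth-cohort generator
#'
#' Defaults emulate a Finnish birth-cohort nutrition study: 3-day food
#' records scheduled at 0.25, 0.5, 1, 2, 3, 4 and 6 years (an extra record
#' at 5 years for a subset), antibody visits every 3 months to age 2, every
#' 6 months to age 6, then yearly to 15; staggered dropout from a constant
#' per-year hazard chosen to give roughly 92/84/68/33% retention at
#' 1/2/6/15 years; baseline covariate frequencies of 53.2% boys, 19.6% high
#' genetic risk, 5.9% familial diabetes (3.9% missing).
#'
#' @param n_subjects number of children.
#' @param sex_prob probability of `boy`.
#' @param high_risk_prob probability of the `high` genetic-risk stratum.
#' @param familial_prob probability of familial diabetes `yes`.
#' @param familial_missing_prob probability the familial status is missing.
#' @param food_record_ages scheduled record ages (years), increasing, in
#'   [0.25, 6].
#' @param include_age5_prob probability a child has the optional 5-year
#'   record.
#' @param record_attend_prob per-occasion attendance probability for food
#'   records (captures the sub-schedule record counts seen in practice).
#' @param antibody_schedule antibody visit ages; default as described above.
#' @param antibody_visit_gap allowed (min, max) gap between antibody visits
#'   in years; the default schedule spans gaps of 0.25 to 1 year.
#' @param dropout_hazard per-year exponential dropout rate.
#' @param followup_max administrative end of follow-up (6 or 15 years).
#' @param days_per_record daily measurements per food-record occasion.
#' @param floor_at_zero if `TRUE`, negative simulated intakes are floored at
#'   0 and flagged; off by default to keep the generator model-faithful.
#' @param seed integer seed; all generator stages derive their streams from
#'   it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 5545,
                          sex_prob = 0.532,
                          high_risk_prob = 0.196,
                          familial_prob = 0.059,
                          familial_missing_prob = 0.039,
                          food_record_ages = c(0.25, 0.5, 1, 2, 3, 4, 6),
                          include_age5_prob = 0.3,
                          record_attend_prob = 0.85,
                          antibody_schedule = c(seq(0.25, 2, by = 0.25),
                                                seq(2.5, 6, by = 0.5),
                                                seq(7, 15, by = 1)),
                          antibody_visit_gap = c(0.25, 1),
                          dropout_hazard = 0.075,
                          followup_max = 15,
                          days_per_record = 3,
                          floor_at_zero = FALSE,
                          seed = 20190523) {
  probs <- c(sex_prob, high_risk_prob, familial_prob, familial_missing_prob,
             include_age5_prob, record_attend_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (familial_prob + familial_missing_prob > 1)
    stop("familial_prob + familial_missing_prob must not exceed 1")
  food_record_ages <- sort(as.numeric(food_record_ages))
  if (any(duplicated(food_record_ages)))
    stop("food_record_ages must be strictly increasing")
  if (min(food_record_ages) < 0.25 || max(food_record_ages) > 6)
    stop("food_record_ages must lie within [0.25, 6]")
  if (followup_max < max(food_record_ages))
    stop("followup_max must cover the last food-record age")
  if (dropout_hazard < 0) stop("dropout_hazard must be nonnegative")
  antibody_schedule <- sort(unique(as.numeric(antibody_schedule)))
  antibody_schedule <- antibody_schedule[antibody_schedule <= followup_max]
  if (length(antibody_schedule) < 1L || min(antibody_schedule) <= 0)
    stop("antibody schedule must contain positive ages")
  gaps <- diff(c(0, antibody_schedule))[-1]
  if (length(gaps) && (min(gaps) < antibody_visit_gap[1] - 1e-9 ||
                       max(gaps) > antibody_visit_gap[2] + 1e-9))
    warning("antibody schedule gaps fall outside antibody_visit_gap")
  structure(list(
    n_subjects = as.integer(n_subjects), sex_prob = sex_prob,
    high_risk_prob = high_risk_prob, familial_prob = familial_prob,
    familial_missing_prob = familial_missing_prob,
    food_record_ages = food_record_ages,
    include_age5_prob = include_age5_prob,
    record_attend_prob = record_attend_prob,
    antibody_schedule = antibody_schedule,
    antibody_visit_gap = antibody_visit_gap,
    dropout_hazard = dropout_hazard, followup_max = followup_max,
    days_per_record = as.integer(days_per_record),
    floor_at_zero = floor_at_zero, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate baseline covariates
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `subject`, `sex` (boy/girl),
#'   `genetic_risk` (moderate/high), `familial_diabetes` (no/yes/missing).
#' @export
simulate_baseline <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  set.seed(derive_seed(config$seed, 1L))
  sex <- ifelse(stats::runif(n) < config$sex_prob, "boy", "girl")
  risk <- ifelse(stats::runif(n) < config$high_risk_prob, "high", "moderate")
  u <- stats::runif(n)
  fam <- ifelse(u < config$familial_prob, "yes",
                ifelse(u < config$familial_prob + config$familial_missing_prob,
                       "missing", "no"))
  data.frame(subject = seq_len(n),
             sex = factor(sex, levels = c("boy", "girl")),
             genetic_risk = factor(risk, levels = c("moderate", "high")),
             familial_diabetes = factor(fam, levels = c("no", "yes", "missing")))
}

# survival design row gamma'w per subject from the named gamma convention
gamma_linpred <- function(baseline, gamma, gamma_names = names(gamma)) {
  if (length(gamma) == 0L) return(rep(0, nrow(baseline)))
  if (is.null(gamma_names)) stop("gamma must carry contrast names")
  W <- baseline_design(baseline)
  miss <- setdiff(gamma_names, colnames(W))
  if (length(miss)) stop("unknown gamma contrasts: ", paste(miss, collapse = ", "))
  as.numeric(W[, gamma_names, drop = FALSE] %*% gamma)
}

# 0/1 contrast matrix for the baseline covariates (reference: boy, moderate,
# familial no)
baseline_design <- function(baseline) {
  cbind(girl = as.numeric(baseline$sex == "girl"),
        high_risk = as.numeric(baseline$genetic_risk == "high"),
        familial_yes = as.numeric(baseline$familial_diabetes == "yes"),
        familial_missing = as.numeric(baseline$familial_diabetes == "missing"))
}

draw_random_effects <- function(n, re_var, seed) {
  set.seed(seed)
  p <- length(re_var)
  matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(re_var), p)
}

# mean total energy intake (MJ/day) by age: rises from ~2 MJ in infancy to
# ~8 MJ at school age
energy_mean_curve <- function(age) {
  stats::approx(c(0.25, 0.5, 1, 2, 3, 4, 5, 6),
                c(2.0, 2.8, 4.0, 5.0, 5.8, 6.5, 7.2, 8.0),
                xout = age, rule = 2)$y
}

#' Simulate longitudinal food-record trajectories
#'
#' Each child's smooth consumption curve is m_i(t) = X(t)(beta + b_i) with
#' b_i ~ N(0, D); each attended record occasion yields `days_per_record`
#' daily values m_i(t) + independent N(0, sigma^2) errors, plus a lognormal
#' daily energy intake about an age-increasing mean.
#'
#' @param baseline output of [simulate_baseline()].
#' @param truth an [lmm_params()] (or a [jm_params()], whose longitudinal
#'   part is used).
#' @param spec a [spline_spec()].
#' @param config a [cohort_config()].
#' @param max_age optional named/per-subject vector limiting record ages
#'   (detection or censoring age); records after it are dropped.
#' @param random_effects optional pre-drawn n x 6 matrix of b_i (to share
#'   random effects with the event generator).
#' @param class_of optional integer class label per subject with `truth` a
#'   [jlcmm_params()]: uses class-specific fixed effects.
#' @return data.frame `subject`, `age_years`, `day`, `food_g_day`,
#'   `energy_mj_day`, `floored`.
#' @export
simulate_trajectories <- function(baseline, truth, spec, config,
                                  max_age = NULL, random_effects = NULL,
                                  class_of = NULL) {
  n <- nrow(baseline)
  if (inherits(truth, "jm_params")) truth_lmm <- truth$lmm
  else if (inherits(truth, "jlcmm_params")) truth_lmm <- NULL
  else truth_lmm <- truth
  re_var <- if (is.null(truth_lmm)) truth$re_var else truth_lmm$re_var
  sigma2 <- if (is.null(truth_lmm)) truth$sigma2 else truth_lmm$sigma2
  p <- length(re_var)
  if (p != spec$n_basis + 1L)
    stop("random-effect dimension does not match the spline spec")
  if (is.null(random_effects))
    random_effects <- draw_random_effects(n, re_var, derive_seed(config$seed, 2L))
  set.seed(derive_seed(config$seed, 3L))
  if (is.null(max_age)) max_age <- rep(config$followup_max, n)

  nd <- config$days_per_record
  sub_v <- age_v <- m_v <- vector("list", n)
  for (i in seq_len(n)) {
    ages <- config$food_record_ages
    keep <- stats::runif(length(ages)) < config$record_attend_prob
    keep[1] <- TRUE                       # enrollment record always exists
    ages <- ages[keep]
    if (stats::runif(1) < config$include_age5_prob && !(5 %in% ages))
      ages <- sort(c(ages, 5))
    ages <- ages[ages <= max_age[i] + 1e-9]
    if (!length(ages)) ages <- config$food_record_ages[1]
    sub_v[[i]] <- rep(baseline$subject[i], length(ages))
    age_v[[i]] <- ages
  }
  subject <- unlist(sub_v, use.names = FALSE)
  age_occ <- unlist(age_v, use.names = FALSE)
  X <- bspline_basis(age_occ, spec)
  occ_of <- rep(seq_len(n), lengths(age_v))
  beta_mat <- if (is.null(truth_lmm)) truth$beta[, class_of[occ_of], drop = FALSE]
    else matrix(truth_lmm$beta, length(truth_lmm$beta), length(occ_of))
  m <- rowSums(X * t(beta_mat + t(random_effects[occ_of, , drop = FALSE])))
  age_rep <- rep(age_occ, each = nd)
  y <- rep(m, each = nd) + stats::rnorm(length(age_rep), 0, sqrt(sigma2))
  energy <- stats::rlnorm(length(y),
                          log(energy_mean_curve(age_rep)) - 0.5 * 0.15^2,
                          0.15)
  floored <- rep(FALSE, length(y))
  if (config$floor_at_zero) {
    floored <- y < 0
    y[floored] <- 0
  }
  out <- data.frame(subject = rep(subject, each = nd), age_years = age_rep,
                    day = rep(seq_len(nd), length(age_occ)),
                    food_g_day = y, energy_mj_day = energy,
                    floored = floored)
  attr(out, "random_effects") <- random_effects
  out
}

#' Simulate true event ages under the shared-random-effects hazard
#'
#' The subject-specific cumulative hazard H_i(t) = int_0^t h_0(s)
#' exp(gamma'w_i + alpha m_i(s)) ds is accumulated by trapezoidal
#' integration on a fine grid and inverted against -log(U) by monotone
#' linear interpolation; children whose -log(U) exceeds H_i(followup) are
#' event-free. The smooth trajectory m_i(s) is clamped to its boundary
#' values outside the basis range.
#'
#' @param baseline output of [simulate_baseline()].
#' @param truth a [jm_params()].
#' @param spec a [spline_spec()].
#' @param seed integer seed.
#' @param random_effects optional pre-drawn b_i matrix (shared with the
#'   trajectory generator).
#' @param followup_max event horizon; defaults to the truth hazard's.
#' @param n_grid inversion grid size (default 2001 points).
#' @return numeric(n): true event age, `Inf` for event-free children.
#' @export
simulate_event_times <- function(baseline, truth, spec, seed,
                                 random_effects = NULL,
                                 followup_max = truth$hazard$followup_max,
                                 n_grid = 2001) {
  stopifnot(inherits(truth, "jm_params"))
  hz <- truth$hazard
  if (any(!is.finite(hz$log_heights))) stop("baseline hazard heights must be positive")
  n <- nrow(baseline)
  if (is.null(random_effects))
    random_effects <- draw_random_effects(n, truth$lmm$re_var,
                                          derive_seed(seed, 2L))
  ts <- seq(0, followup_max, length.out = n_grid)
  tb <- pmin(pmax(ts, spec$boundary[1]), spec$boundary[2])
  Xg <- bspline_basis(tb, spec)
  h0 <- exp(hz$log_heights)[hazard_interval(pmax(ts, 1e-9), hz)]
  lp_w <- gamma_linpred(baseline, truth$gamma, truth$gamma_names)
  set.seed(derive_seed(seed, 4L))
  U <- stats::runif(n)
  target <- -log(U)
  dt <- diff(ts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- as.numeric(Xg %*% (truth$lmm$beta + random_effects[i, ]))
    lam <- h0 * exp(lp_w[i] + truth$alpha * m)
    H <- c(0, cumsum(0.5 * (lam[-1] + lam[-n_grid]) * dt))
    if (target[i] > H[n_grid]) { out[i] <- Inf; next }
    j <- findInterval(target[i], H)          # H[j] <= target < H[j+1]
    out[i] <- ts[j] + (target[i] - H[j]) / max(H[j + 1] - H[j], 1e-300) * dt[j]
  }
  out
}

#' Interval-censor true event ages against attended antibody visits
#'
#' For a child with true event age T the last attended visit before T is the
#' last negative age L and the first attended visit at or after T the first
#' positive age R; the conventional analysis time is the interval midpoint.
#' Children whose event falls after their last attended visit (or who have
#' no event) are censored at the last attended visit.
#'
#' @param event_ages numeric vector of true event ages (`Inf` = no event).
#' @param visits list (one element per subject) of attended visit ages,
#'   strictly increasing, first visit > 0.
#' @param subjects optional subject ids (default seq_along).
#' @return data.frame of class endpoints: `subject`, `last_negative_age`,
#'   `first_positive_age`, `event`, `censor_age`, `midpoint`,
#'   `before_first_visit` flag.
#' @export
apply_visit_censoring <- function(event_ages, visits,
                                  subjects = seq_along(event_ages)) {
  n <- length(event_ages)
  stopifnot(length(visits) == n)
  L <- R <- mid <- cens <- numeric(n)
  ev <- integer(n); flag <- logical(n)
  for (i in seq_len(n)) {
    v <- visits[[i]]
    if (!length(v) || min(v) <= 0 || is.unsorted(v, strictly = TRUE))
      stop("visit ages must be strictly increasing and positive")
    T_i <- event_ages[i]
    detected <- is.finite(T_i) && T_i <= max(v)
    if (detected) {
      R[i] <- v[which(v >= T_i)[1]]
      before <- v[v < T_i]
      if (!length(before)) { L[i] <- 0; flag[i] <- TRUE } else L[i] <- max(before)
      ev[i] <- 1L
      mid[i] <- (L[i] + R[i]) / 2
      cens[i] <- R[i]
    } else {
      L[i] <- max(v); R[i] <- NA_real_; ev[i] <- 0L
      cens[i] <- max(v); mid[i] <- max(v)
    }
  }
  if (any(flag))
    warning(sum(flag), " event(s) before the first attended visit; interval opened at birth")
  data.frame(subject = subjects, last_negative_age = L,
             first_positive_age = R, event = ev, censor_age = cens,
             midpoint = mid, before_first_visit = flag)
}

# attended antibody visits per subject given dropout ages
attended_visits <- function(config, dropout_age) {
  lapply(dropout_age, function(d) {
    v <- config$antibody_schedule[config$antibody_schedule <= min(d, config$followup_max)]
    if (!length(v)) v <- config$antibody_schedule[1]   # enrollment visit
    v
  })
}

draw_dropout <- function(config) {
  set.seed(derive_seed(config$seed, 5L))
  if (config$dropout_hazard <= 0) return(rep(Inf, config$n_subjects))
  stats::rexp(config$n_subjects, config$dropout_hazard)
}

#' Simulate a complete cohort under the shared-random-effects model
#'
#' Draws baseline covariates, subject random effects, dropout, true event
#' ages, interval-censored endpoints and food records (records stop at the
#' detection or censoring age), with trajectory and hazard sharing the same
#' random effects.
#'
#' @param config a [cohort_config()].
#' @param truth a [jm_params()]; defaults to [default_truth_jm()].
#' @param spec a [spline_spec()].
#' @return list of class `cohort`: `baseline`, `long`, `endpoints`, `truth`,
#'   `spec`, `config`, `random_effects`, `true_event_age`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            truth = default_truth_jm(),
                            spec = spline_spec()) {
  baseline <- simulate_baseline(config)
  b <- draw_random_effects(config$n_subjects, truth$lmm$re_var,
                           derive_seed(config$seed, 2L))
  event_age <- simulate_event_times(baseline, truth, spec, config$seed,
                                    random_effects = b)
  dropout <- draw_dropout(config)
  visits <- attended_visits(config, dropout)
  endpoints <- apply_visit_censoring(event_age, visits, baseline$subject)
  detect_age <- ifelse(endpoints$event == 1, endpoints$first_positive_age,
                       endpoints$censor_age)
  long <- simulate_trajectories(baseline, truth, spec, config,
                                max_age = detect_age, random_effects = b)
  structure(list(baseline = baseline, long = long, endpoints = endpoints,
                 truth = truth, spec = spec, config = config,
                 random_effects = b, true_event_age = event_age),
            class = "cohort")
}

#' Simulate a cohort under the latent-class generative model
#'
#' Class labels are drawn from softmax(lambda); trajectories use class-
#' specific fixed effects with shared random-effect variances; event ages
#' come from the class-specific piecewise-constant baseline hazard scaled by
#' exp(gamma'w).
#'
#' @param config a [cohort_config()].
#' @param truth a [jlcmm_params()]; defaults to [default_truth_jlcmm()].
#' @param spec a [spline_spec()].
#' @return list of class `cohort` with additional element `true_class`.
#' @export
simulate_latent_class_cohort <- function(config = cohort_config(),
                                         truth = default_truth_jlcmm(),
                                         spec = spline_spec()) {
  stopifnot(inherits(truth, "jlcmm_params"))
  if (truth$G < 1L) stop("need at least one class")
  baseline <- simulate_baseline(config)
  n <- config$n_subjects
  set.seed(derive_seed(config$seed, 6L))
  pr <- class_probs(truth$lambda)
  cls <- sample.int(truth$G, n, replace = TRUE, prob = pr)
  b <- draw_random_effects(n, truth$re_var, derive_seed(config$seed, 2L))
  # class-specific hazards have no trajectory link: invert the piecewise-
  # linear baseline cumulative hazard through the shared numeric machinery
  event_age <- numeric(n)
  lp_w <- gamma_linpred(baseline, truth$gamma, truth$gamma_names)
  set.seed(derive_seed(config$seed, 4L))
  U <- stats::runif(n)
  bounds <- c(0, truth$hazard$knots, truth$hazard$followup_max)
  class_tab <- lapply(seq_len(truth$G), function(g) {
    hz_g <- hazard_spec(truth$hazard$knots, truth$hazard$followup_max,
                        truth$log_heights[, g])
    list(Hk = baseline_cumhaz(bounds, hz_g), h = exp(hz_g$log_heights))
  })
  target <- -log(U) / exp(lp_w)
  for (i in seq_len(n)) {
    ct <- class_tab[[cls[i]]]
    if (target[i] > ct$Hk[length(bounds)]) { event_age[i] <- Inf; next }
    j <- min(findInterval(target[i], ct$Hk, rightmost.closed = TRUE),
             length(bounds) - 1L)
    event_age[i] <- bounds[j] + (target[i] - ct$Hk[j]) / ct$h[j]
  }
  dropout <- draw_dropout(config)
  visits <- attended_visits(config, dropout)
  endpoints <- apply_visit_censoring(event_age, visits, baseline$subject)
  detect_age <- ifelse(endpoints$event == 1, endpoints$first_positive_age,
                       endpoints$censor_age)
  long <- simulate_trajectories(baseline, truth, spec, config,
                                max_age = detect_age, random_effects = b,
                                class_of = cls)
  structure(list(baseline = baseline, long = long, endpoints = endpoints,
                 truth = truth, spec = spec, config = config,
                 random_effects = b, true_event_age = event_age,
                 true_class = cls),
            class = "cohort")
}

#' Write a simulated cohort to delimited text files
#'
#' Emits `baseline.csv`, `long.csv`, `endpoints.csv` and `truth.json`
#' (ground-truth parameters, spline spec and seed) into `dir`.
#'
#' @param cohort a [simulate_cohort()] / [simulate_latent_class_cohort()]
#'   result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$long[, c("subject", "age_years", "day",
                                   "food_g_day", "energy_mj_day")],
                   file.path(dir, "long.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$endpoints[, c("subject", "last_negative_age",
                                        "first_positive_age", "event",
                                        "censor_age")],
                   file.path(dir, "endpoints.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- cohort$truth
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  payload <- list(model = if (inherits(truth, "jlcmm_params")) "JLCMM" else "JM",
                  params = strip(truth),
                  spec = unclass(cohort$spec), seed = cohort$config$seed)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              na = "null"),
             file.path(dir, "truth.json"))
  invisible(dir)
}
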