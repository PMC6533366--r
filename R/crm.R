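#' Aggregate daily records to 3-day occasion means
#'
#' @param long_table daily-level table (`subject`, `age_years`, `day`,
#'   `food_g_day`, optionally `energy_mj_day`).
#' @return occasion-level table with one row per subject x age carrying the
#'   mean food (and energy) over the recorded days.
#' @export
occasion_means <- function(long_table) {
  if (!"day" %in% names(long_table)) return(long_table)
  key <- interaction(long_table$subject, long_table$age_years, drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  out <- data.frame(
    subject = tapply(long_table$subject, key, function(x) x[1]),
    age_years = as.numeric(agg(long_table$age_years)),
    food_g_day = as.numeric(agg(long_table$food_g_day)))
  if ("energy_mj_day" %in% names(long_table))
    out$energy_mj_day <- as.numeric(agg(long_table$energy_mj_day))
  out <- out[order(out$subject, out$age_years), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Express the exposure per megajoule of energy intake
#'
#' Divides each food value by the energy intake on the same row, switching
#' the reporting increment from 10 g/day to 1 g/MJ. For occasion-level
#' (3-day mean) data this is the ratio of the 3-day means; for daily data it
#' is the daily ratio.
#'
#' @param long_table table with `food_g_day` and `energy_mj_day` columns.
#' @return the table with `food_g_day` replaced by g/MJ values and
#'   attribute `exposure_unit = "g_per_MJ"`.
#' @export
energy_adjust <- function(long_table) {
  if (!"energy_mj_day" %in% names(long_table))
    stop("no energy_mj_day column to adjust by")
  bad <- which(!is.finite(long_table$energy_mj_day) |
                 long_table$energy_mj_day <= 0)
  if (length(bad))
    stop("non-positive energy intake for subject(s): ",
         paste(unique(long_table$subject[bad]), collapse = ", "))
  long_table$food_g_day <- long_table$food_g_day / long_table$energy_mj_day
  attr(long_table, "exposure_unit") <- "g_per_MJ"
  long_table
}

#' Counting-process rows for the step-function Cox model
#'
#' The last recorded 3-day mean is carried forward as a piecewise-constant
#' exposure; the event sits at the interval midpoint of the antibody visits;
#' follow-up is administratively censored at `followup_max` (6 years, the
#' last food-record age, so the Cox and joint analyses cover the same
#' period). Children whose event midpoint precedes their first food record
#' are excluded and listed in the `excluded` attribute.
#'
#' @param long_table occasion- or daily-level records (daily records are
#'   aggregated by [occasion_means()] first).
#' @param endpoints endpoint table with `subject`, `event`, `midpoint`,
#'   `censor_age`.
#' @param baseline optional baseline covariate table merged onto the rows.
#' @param followup_max administrative censoring age.
#' @return data.frame `subject`, `start`, `stop`, `event`, `exposure`, plus
#'   the baseline columns, with attribute `excluded`.
#' @export
build_counting_process <- function(long_table, endpoints, baseline = NULL,
                                   followup_max = 6) {
  occ <- occasion_means(long_table)
  sp_rec <- split(occ, occ$subject)
  ep <- endpoints[match(names(sp_rec), as.character(endpoints$subject)), ]
  rows <- vector("list", length(sp_rec))
  excluded <- list()
  for (i in seq_along(sp_rec)) {
    r <- sp_rec[[i]]
    if (is.na(ep$subject[i])) next
    end_time <- if (ep$event[i] == 1) ep$midpoint[i] else ep$censor_age[i]
    is_event <- ep$event[i] == 1 && end_time <= followup_max
    end_time <- min(end_time, followup_max)
    ages <- r$age_years[r$age_years < end_time - 1e-9]
    if (!length(ages)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        subject = r$subject[1],
        reason = "no food record before event/censoring")
      next
    }
    vals <- r$food_g_day[r$age_years < end_time - 1e-9]
    starts <- ages
    stops <- c(ages[-1L], end_time)
    keep <- stops - starts > 1e-9
    ev <- integer(sum(keep)); if (is_event) ev[length(ev)] <- 1L
    rows[[i]] <- data.frame(subject = r$subject[1], start = starts[keep],
                            stop = stops[keep], event = ev,
                            exposure = vals[keep])
  }
  cp <- do.call(rbind, rows)
  rownames(cp) <- NULL
  if (!is.null(baseline))
    cp <- merge(cp, baseline, by = "subject", sort = FALSE)
  cp <- cp[order(cp$subject, cp$start), , drop = FALSE]
  attr(cp, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
    else data.frame(subject = numeric(0), reason = character(0))
  cp
}

#' Time-dependent-covariate Cox fit on counting-process rows
#'
#' Maximizes the partial likelihood over the (start, stop] rows via
#' [survival::coxph()]. The hazard ratio is reported per `increment` units
#' of the exposure (10 g/day conventionally; 1 g/MJ after energy
#' adjustment).
#'
#' @param cp_table output of [build_counting_process()].
#' @param covariates character vector of baseline covariate columns to
#'   adjust for (e.g. `c("sex", "genetic_risk", "familial_diabetes")`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param increment reporting increment on the exposure scale.
#' @return object of class `cox_fit`: `coef`, `se`, `hr`, `ci`, `p` for the
#'   exposure on the increment scale, the full coefficient vector and
#'   covariance, partial log-likelihood, `ties`, and flags.
#' @export
fit_cox_td <- function(cp_table, covariates = character(0),
                       ties = c("breslow", "efron"), increment = 10) {
  ties <- match.arg(ties)
  if (sum(cp_table$event) < 1) stop("no events in the counting-process table")
  unidentifiable <- stats::var(cp_table$exposure) < 1e-12
  rhs <- c(if (!unidentifiable) "exposure", covariates)
  if (!length(rhs)) rhs <- "1"
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~", paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = cp_table, ties = ties)
  if (unidentifiable) {
    est <- 0; se <- Inf; diverged <- TRUE
  } else {
    est <- unname(stats::coef(fit)["exposure"])
    se <- sqrt(stats::vcov(fit)["exposure", "exposure"])
    diverged <- !is.finite(est) || abs(est) > 50
  }
  z <- est / se
  structure(list(
    coef = est, se = se,
    hr = exp(increment * est),
    ci = exp(increment * (est + c(-1.96, 1.96) * se)),
    p = 2 * stats::pnorm(-abs(z)),
    increment = increment,
    all_coef = if (!unidentifiable) stats::coef(fit) else numeric(0),
    vcov = if (!unidentifiable) stats::vcov(fit) else matrix(0, 0, 0),
    loglik = fit$loglik[length(fit$loglik)],
    n_events = sum(cp_table$event), ties = ties,
    diverged = diverged, coxph = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Step-function Cox fit (%s ties): HR %.3f (%.3f, %.3f) per %g-unit increment, P = %.4g%s\n",
              x$ties, x$hr, x$ci[1], x$ci[2], x$increment, x$p,
              if (x$diverged) " [diverged]" else ""))
  invisible(x)
}

#' Pool estimates across multiple imputations (Rubin's rules)
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @param variances numeric vector of per-imputation squared SEs.
#' @param conf_level confidence level for the normal-reference interval.
#' @return list `estimate`, `se`, `ci`, `within`, `between`, `m`.
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2L) stop("need at least 2 imputations to pool")
  stopifnot(length(variances) == m)
  qbar <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = qbar, se = sqrt(total),
       ci = qbar + c(-z, z) * sqrt(total),
       within = within, between = between, m = m)
}

#' Complete partially observed 3-day records by simple normal imputation
#'
#' A deliberately simple stand-in for a full multiple-imputation chain:
#' each occasion with fewer than `days` observed daily values has the
#' missing days drawn from a normal centred on the occasion's own observed
#' mean with the pooled within-occasion day-to-day SD (estimated from
#' occasions with at least 2 observed days). Occasions with no observed
#' days are an error.
#'
#' @param daily_records daily-level table (`subject`, `age_years`, `day`,
#'   `food_g_day`, optionally `energy_mj_day`).
#' @param m number of completed tables.
#' @param seed integer seed.
#' @param days nominal days per occasion.
#' @return list of `m` occasion-level tables (completed 3-day means).
#' @export
impute_3day_mean <- function(daily_records, m = 5, seed = 1, days = 3) {
  stopifnot("day" %in% names(daily_records))
  key <- interaction(daily_records$subject, daily_records$age_years,
                     drop = TRUE)
  n_obs <- tapply(daily_records$food_g_day, key,
                  function(v) sum(is.finite(v)))
  if (any(n_obs == 0))
    stop("occasion(s) with zero observed days cannot be imputed")
  # pooled day-to-day SD from occasions with >= 2 observed days
  sds <- tapply(daily_records$food_g_day, key, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  pooled_sd <- sqrt(mean(sds^2, na.rm = TRUE))
  if (!is.finite(pooled_sd)) pooled_sd <- 0
  means <- tapply(daily_records$food_g_day, key,
                  function(v) mean(v[is.finite(v)]))
  base <- occasion_means(daily_records[is.finite(daily_records$food_g_day), ])
  out <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(derive_seed(seed, k))
    miss <- days - as.numeric(n_obs)
    extra <- stats::rnorm(length(miss), 0, pooled_sd) *
      sqrt(pmax(miss, 0)) / days    # mean of `miss` iid draws around mu
    completed <- (as.numeric(n_obs) * as.numeric(means) +
                    pmax(miss, 0) * as.numeric(means)) / days + extra
    tab <- base
    ord_key <- interaction(base$subject, base$age_years, drop = TRUE)
    tab$food_g_day <- completed[match(as.character(ord_key), names(means))]
    out[[k]] <- tab
  }
  out
}
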