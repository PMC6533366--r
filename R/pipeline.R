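#' Analysis configuration for the full model battery
#'
#' @param models subset of `"CRM"`, `"JM"`, `"JLCMM"`.
#' @param adjustments subset of `"unadjusted"`, `"adjusted"`,
#'   `"energy"` (energy adjustment applies to CRM and JM only).
#' @param followup_short administrative horizon for CRM/JM (the food-record
#'   window).
#' @param followup_long horizon for the latent-class analysis.
#' @param jlcmm_G number of latent classes for the JLCMM stage.
#' @param covariates baseline contrasts for the adjusted models.
#' @param jm_control,jlcmm_control optimizer settings.
#' @param seed master seed for any stochastic stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(models = c("CRM", "JM"),
                            adjustments = c("unadjusted", "adjusted",
                                            "energy"),
                            followup_short = 6, followup_long = 15,
                            jlcmm_G = 2,
                            covariates = c("girl", "high_risk",
                                           "familial_yes",
                                           "familial_missing"),
                            jm_control = dietjm::jm_control(),
                            jlcmm_control = dietjm::jlcmm_control(),
                            seed = 1) {
  stopifnot(all(models %in% c("CRM", "JM", "JLCMM")),
            all(adjustments %in% c("unadjusted", "adjusted", "energy")),
            followup_long >= followup_short)
  structure(list(models = models, adjustments = adjustments,
                 followup_short = followup_short,
                 followup_long = followup_long, jlcmm_G = jlcmm_G,
                 covariates = covariates, jm_control = jm_control,
                 jlcmm_control = jlcmm_control, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact P by summing, over all tables with the observed margins, the
#' hypergeometric probabilities not exceeding the observed table's (with a
#' small relative tolerance, the usual convention).
#'
#' @param a,b,c,d cell counts: rows are groups, columns
#'   outcome/no-outcome.
#' @return two-sided P value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n)
    stop("degenerate margin: all observations in one row or column")
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Kaplan-Meier curves by group
#'
#' Product-limit estimate with Greenwood standard errors, one curve per
#' group level, on the conventional analysis times (interval midpoints for
#' events, last visit for censorings).
#'
#' @param endpoints endpoint table.
#' @param groups optional factor (one value per endpoint row); a single
#'   overall curve when omitted.
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `surv`, `se`,
#'   `lower`, `upper`.
#' @export
km_estimate <- function(endpoints, groups = NULL) {
  time <- ifelse(endpoints$event == 1, endpoints$midpoint,
                 endpoints$censor_age)
  status <- endpoints$event
  if (is.null(groups)) groups <- rep("overall", nrow(endpoints))
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty group level")
  out <- lapply(levels(groups), function(lv) {
    sel <- groups == lv
    sf <- survival::survfit(survival::Surv(time[sel], status[sel]) ~ 1,
                            conf.type = "plain")
    data.frame(group = lv, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, surv = sf$surv, se = sf$std.err * sf$surv,
               lower = sf$lower, upper = sf$upper)
  })
  do.call(rbind, out)
}

#' Cox model on the baseline factors alone
#'
#' Single proportional-hazards fit including all baseline factors jointly
#' (midpoint analysis times), reported per level against its reference with
#' the reference rows shown at HR 1.
#'
#' @param baseline baseline covariate table.
#' @param endpoints endpoint table.
#' @return data.frame `factor`, `level`, `n`, `n_event`, `hr`, `lo`, `hi`,
#'   `p`, `reference`.
#' @export
baseline_cox_table <- function(baseline, endpoints) {
  stopifnot(nrow(baseline) == nrow(endpoints))
  time <- ifelse(endpoints$event == 1, endpoints$midpoint,
                 endpoints$censor_age)
  df <- data.frame(time = time, status = endpoints$event,
                   sex = baseline$sex, genetic_risk = baseline$genetic_risk,
                   familial_diabetes = baseline$familial_diabetes)
  fit <- survival::coxph(
    survival::Surv(time, status) ~ sex + genetic_risk + familial_diabetes,
    data = df)
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  rows <- list()
  for (f in c("sex", "genetic_risk", "familial_diabetes")) {
    lv <- levels(df[[f]])
    for (l in lv) {
      sel <- df[[f]] == l
      nm <- paste0(f, l)
      is_ref <- l == lv[1]
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, level = l, n = sum(sel),
        n_event = sum(df$status[sel]),
        hr = if (is_ref) 1 else exp(cf[nm]),
        lo = if (is_ref) NA_real_ else exp(cf[nm] - 1.96 * se[nm]),
        hi = if (is_ref) NA_real_ else exp(cf[nm] + 1.96 * se[nm]),
        p = if (is_ref) NA_real_ else
          2 * stats::pnorm(-abs(cf[nm] / se[nm])),
        reference = is_ref)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

# population-level piecewise-exponential hazard estimated from midpoint
# times (occurrence/exposure per interval)
pe_hazard_from_endpoints <- function(endpoints, knots, horizon) {
  Tm <- pmin(ifelse(endpoints$event == 1, endpoints$midpoint,
                    endpoints$censor_age), horizon)
  delta <- endpoints$event == 1 & Tm <= horizon
  bounds <- c(0, knots, horizon)
  lh <- vapply(seq_len(length(bounds) - 1L), function(j) {
    expo <- sum(pmax(0, pmin(Tm, bounds[j + 1]) - bounds[j]))
    ev <- sum(delta & Tm > bounds[j] & Tm <= bounds[j + 1])
    log(max(ev, 0.5) / max(expo, 1e-9))
  }, numeric(1))
  hazard_spec(knots, horizon, lh)
}

# draw an event time inside (L, R] from a piecewise-exponential hazard
draw_in_interval <- function(L, R, hz, u) {
  HL <- baseline_cumhaz(L, hz); HR_ <- baseline_cumhaz(R, hz)
  if (HR_ - HL < 1e-12) return((L + R) / 2)
  target <- HL - log(1 - u * (1 - exp(-(HR_ - HL))))
  bounds <- c(0, hz$knots, hz$followup_max)
  Hk <- baseline_cumhaz(bounds, hz)
  j <- min(findInterval(target, Hk, rightmost.closed = TRUE),
           length(bounds) - 1L)
  t <- bounds[j] + (target - Hk[j]) / exp(hz$log_heights[j])
  min(max(t, L + 1e-9), R)
}

#' Multiple imputation for interval-censored event times
#'
#' Sensitivity companion to the midpoint convention: each event time is
#' drawn from a piecewise-exponential survival distribution conditioned to
#' its (L, R] interval. The hazard is estimated from the midpoint data,
#' refined once on a completed draw, and then used for the `m` production
#' imputations; each completed endpoint table is fed to `fit_fun` and the
#' results pooled by Rubin's rules.
#'
#' @param endpoints endpoint table with `last_negative_age`,
#'   `first_positive_age`, `event`, `censor_age`, `midpoint`.
#' @param fit_fun function(endpoints) returning `list(estimate, variance)`
#'   (scalar, e.g. a log hazard ratio and its squared SE).
#' @param m number of imputations.
#' @param seed integer seed.
#' @param knots hazard knots for the imputation model.
#' @param horizon follow-up horizon for the imputation model.
#' @return list `pooled` (from [rubin_pool()]), `midpoint`
#'   (`fit_fun` on the midpoint data), `imputations` (per-draw estimates).
#' @export
mi_interval_censored <- function(endpoints, fit_fun, m = 10, seed = 1,
                                 knots = c(1.99, 3.99, 5.99),
                                 horizon = max(endpoints$censor_age,
                                               endpoints$midpoint,
                                               na.rm = TRUE)) {
  knots <- knots[knots < horizon]
  hz <- pe_hazard_from_endpoints(endpoints, knots, horizon)
  is_ev <- endpoints$event == 1
  L <- endpoints$last_negative_age; R <- endpoints$first_positive_age
  degenerate <- is_ev & (R - L) < 1e-12
  draw_table <- function(hz, k) {
    set.seed(derive_seed(seed, 100L + k))
    ep <- endpoints
    u <- stats::runif(nrow(ep))
    for (i in which(is_ev)) {
      ep$midpoint[i] <- if (degenerate[i]) L[i] else
        draw_in_interval(L[i], R[i], hz, u[i])
    }
    ep
  }
  # one refinement: re-estimate the hazard on a completed draw
  hz <- pe_hazard_from_endpoints(draw_table(hz, 0L), knots, horizon)
  fits <- lapply(seq_len(m), function(k) fit_fun(draw_table(hz, k)))
  est <- vapply(fits, `[[`, numeric(1), "estimate")
  va <- vapply(fits, `[[`, numeric(1), "variance")
  list(pooled = rubin_pool(est, va),
       midpoint = fit_fun(endpoints),
       imputations = data.frame(imputation = seq_len(m), estimate = est,
                                variance = va))
}

#' Hazard knots placing equal event counts in every interval
#'
#' Knots at the event-time quantiles: with `n_intervals` intervals the
#' j-th knot is the (j/n_intervals)-quantile (type 1, an order statistic)
#' of the event times.
#'
#' @param ev_times event (midpoint) times.
#' @param n_intervals number of hazard intervals wanted.
#' @param horizon follow-up end; knots are kept strictly inside (0,
#'   horizon).
#' @return numeric vector of `n_intervals - 1` knots.
#' @export
equal_event_knots <- function(ev_times, n_intervals, horizon = 6) {
  ev_times <- sort(ev_times)
  if (length(ev_times) < n_intervals)
    stop("too few events to place equal-event knots")
  qs <- seq_len(n_intervals - 1L) / n_intervals
  knots <- unname(stats::quantile(ev_times, qs, type = 1))
  knots <- pmin(pmax(knots, 1e-3), horizon - 1e-3)
  if (any(diff(knots) <= 0)) stop("event quantiles give tied knots")
  knots
}

#' Baseline-hazard knot sensitivity for the joint model
#'
#' Refits the joint model with one hazard knot removed or one added, the
#' new knots placed at event-time quantiles so every interval holds the
#' same number of events, and tabulates the association hazard ratio
#' against the base fit.
#'
#' @param long_table,endpoints,baseline,spec the data of the base fit.
#' @param base_fit a [fit_jm()] result.
#' @param mode `"remove_one"` or `"add_one"`.
#' @param ... passed to [fit_jm()].
#' @return list `knots`, `fit`, `comparison` (data.frame of base vs
#'   variant HR).
#' @export
knot_sensitivity <- function(long_table, endpoints, baseline, spec,
                             base_fit, mode = c("remove_one", "add_one"),
                             ...) {
  mode <- match.arg(mode)
  K_base <- base_fit$hzspec$n_intervals
  K_new <- if (mode == "remove_one") K_base - 1L else K_base + 1L
  if (K_new < 1L) stop("cannot remove a knot from a single-interval hazard")
  ep <- truncate_endpoints(endpoints, base_fit$hzspec$followup_max)
  ev_times <- ep$midpoint[ep$event == 1]
  knots <- equal_event_knots(ev_times, K_new,
                             horizon = base_fit$hzspec$followup_max)
  hz_new <- hazard_spec(knots, base_fit$hzspec$followup_max)
  fit <- fit_jm(long_table, endpoints, baseline, spec, hz_new, ...)
  comparison <- data.frame(
    variant = c("base", mode),
    knots = c(paste(signif(base_fit$hzspec$knots, 4), collapse = "/"),
              paste(signif(knots, 4), collapse = "/")),
    hr = c(base_fit$alpha$hr, fit$alpha$hr),
    lo = c(base_fit$alpha$ci[1], fit$alpha$ci[1]),
    hi = c(base_fit$alpha$ci[2], fit$alpha$ci[2]),
    p = c(base_fit$alpha$p, fit$alpha$p))
  list(knots = knots, fit = fit, comparison = comparison)
}

# one CRM cell of the report
run_crm_cell <- function(long_table, endpoints, baseline, adjustment,
                         config) {
  lt <- occasion_means(long_table)
  increment <- 10
  if (adjustment == "energy") {
    lt <- energy_adjust(lt)
    increment <- 1
  }
  cp <- build_counting_process(lt, endpoints, baseline,
                               followup_max = config$followup_short)
  covs <- if (adjustment == "unadjusted") character(0) else
    c("sex", "genetic_risk", "familial_diabetes")
  fit <- fit_cox_td(cp, covariates = covs, increment = increment)
  data.frame(hr = fit$hr, lo = fit$ci[1], hi = fit$ci[2], p = fit$p)
}

# one JM cell of the report
run_jm_cell <- function(long_table, endpoints, baseline, spec, adjustment,
                        config) {
  lt <- long_table
  increment <- 10
  if (adjustment == "energy") {
    lt <- energy_adjust(lt)
    increment <- 1
  }
  covs <- if (adjustment == "unadjusted") character(0) else config$covariates
  fit <- fit_jm(lt, endpoints, baseline, spec,
                hzspec = hazard_spec(c(1.99, 3.99), config$followup_short),
                covariates = covs, control = config$jm_control,
                increment = increment)
  data.frame(hr = fit$alpha$hr, lo = fit$alpha$ci[1], hi = fit$alpha$ci[2],
             p = fit$alpha$p)
}

#' Run the full food-by-model-by-adjustment analysis
#'
#' Fits every requested combination of food, model (step-function Cox,
#' joint model, latent-class model) and adjustment variant, plus the
#' baseline-factor Cox table, with per-cell failure capture: a failed cell
#' carries its error message instead of halting the run.
#'
#' @param baseline baseline covariate table.
#' @param endpoints endpoint table (primary endpoint).
#' @param foods named list of longitudinal tables, one per food.
#' @param spec a [spline_spec()].
#' @param config an [analysis_config()].
#' @param endpoints_secondary optional second endpoint table; CRM/JM rows
#'   are then produced for both endpoints.
#' @return list of class `analysis_report`: `hr_table` (rows food x model x
#'   adjustment x endpoint), `baseline_table`, `jlcmm` (per food, when
#'   requested), `accounting`, `config`.
#' @export
run_full_analysis <- function(baseline, endpoints, foods,
                              spec = spline_spec(),
                              config = analysis_config(),
                              endpoints_secondary = NULL) {
  stopifnot(is.list(foods), !is.null(names(foods)))
  eps <- list(primary = endpoints)
  if (!is.null(endpoints_secondary)) eps$secondary <- endpoints_secondary
  rows <- list(); jl <- list()
  accounting <- data.frame(food = character(0), n_input = integer(0),
                           n_analyzed = integer(0), n_excluded = integer(0))
  for (food in names(foods)) {
    lt <- foods[[food]]
    n_in <- length(unique(lt$subject))
    n_an <- length(intersect(unique(lt$subject), endpoints$subject))
    accounting <- rbind(accounting, data.frame(
      food = food, n_input = n_in, n_analyzed = n_an,
      n_excluded = n_in - n_an))
    for (ep_name in names(eps)) {
      for (model in intersect(config$models, c("CRM", "JM"))) {
        for (adj in config$adjustments) {
          res <- tryCatch({
            if (model == "CRM")
              run_crm_cell(lt, eps[[ep_name]], baseline, adj, config)
            else
              run_jm_cell(lt, eps[[ep_name]], baseline, spec, adj, config)
          }, error = function(e) data.frame(hr = NA_real_, lo = NA_real_,
                                            hi = NA_real_, p = NA_real_,
                                            status = conditionMessage(e)))
          if (is.null(res$status)) res$status <- "ok"
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(food = food, endpoint = ep_name, model = model,
                       adjustment = adj), res)
        }
      }
    }
    if ("JLCMM" %in% config$models) {
      jl[[food]] <- tryCatch(
        fit_jlcmm(lt, endpoints, baseline, spec, G = config$jlcmm_G,
                  covariates = config$covariates,
                  control = config$jlcmm_control, seed = config$seed),
        error = function(e) conditionMessage(e))
    }
  }
  structure(list(hr_table = do.call(rbind, rows),
                 baseline_table = tryCatch(
                   baseline_cox_table(baseline, endpoints),
                   error = function(e) conditionMessage(e)),
                 jlcmm = jl, accounting = accounting, config = config),
            class = "analysis_report")
}

#' Write an analysis report as CSV and Markdown
#'
#' @param report a [run_full_analysis()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$hr_table, file.path(dir, "hr_table.csv"),
                   row.names = FALSE)
  if (is.data.frame(report$baseline_table))
    utils::write.csv(report$baseline_table,
                     file.path(dir, "baseline_cox.csv"), row.names = FALSE)
  md <- c("# Analysis report", "",
          "## Hazard ratios (per 10 g/day; per 1 g/MJ when energy-adjusted)",
          "",
          "| food | endpoint | model | adjustment | HR | 95% CI | P |",
          "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report$hr_table))) {
    r <- report$hr_table[i, ]
    md <- c(md, sprintf("| %s | %s | %s | %s | %.2f | (%.2f, %.2f) | %.3f |",
                        r$food, r$endpoint, r$model, r$adjustment, r$hr,
                        r$lo, r$hi, r$p))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
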