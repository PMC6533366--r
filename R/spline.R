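#' Cubic B-spline specification for food-consumption trajectories
#'
#' Defines the cubic B-spline space used by the trajectory submodels: two
#' interior knots (enough flexibility for infant-to-childhood intake curves
#' without overfitting the 7-8 scheduled food records) on a boundary fixed at
#' the first and last scheduled record ages. With degree 3 and 2 interior
#' knots the spline space has dimension 6, parameterized as an explicit
#' intercept plus 5 basis columns (the first full-basis column is absorbed
#' into the intercept).
#'
#' @param interior_knots numeric(2), strictly increasing, inside the boundary.
#' @param boundary numeric(2), boundary knots in years; defaults to the
#'   scheduled food-record range 0.25-6 years.
#' @return an object of class `spline_spec` with fields `degree`,
#'   `interior_knots`, `boundary`, `n_basis`.
#' @export
spline_spec <- function(interior_knots = c(1.6, 3.8), boundary = c(0.25, 6)) {
  interior_knots <- as.numeric(interior_knots)
  boundary <- as.numeric(boundary)
  if (length(boundary) != 2L || !boundary[1] < boundary[2])
    stop("`boundary` must be two increasing ages")
  if (length(interior_knots) != 2L)
    stop("exactly 2 interior knots are used (q = 2)")
  if (!(boundary[1] < interior_knots[1] && interior_knots[1] < interior_knots[2] &&
        interior_knots[2] < boundary[2]))
    stop("need boundary_low < knot_1 < knot_2 < boundary_high")
  structure(
    list(degree = 3L, interior_knots = interior_knots, boundary = boundary,
         n_basis = 5L),
    class = "spline_spec"
  )
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf(
    "Cubic B-spline spec: interior knots (%.3g, %.3g) on [%.3g, %.3g], intercept + %d basis columns\n",
    x$interior_knots[1], x$interior_knots[2], x$boundary[1], x$boundary[2],
    x$n_basis))
  invisible(x)
}

#' @rdname spline_spec
#' @param x a `spline_spec`.
#' @export
spline_spec_to_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' @rdname spline_spec
#' @param json JSON string produced by [spline_spec_to_json()].
#' @export
spline_spec_from_json <- function(json) {
  l <- jsonlite::fromJSON(json)
  spline_spec(l$interior_knots, l$boundary)
}

# Full knot vector with boundary knots repeated degree+1 times.
full_knots <- function(spec) {
  c(rep(spec$boundary[1], spec$degree + 1L), spec$interior_knots,
    rep(spec$boundary[2], spec$degree + 1L))
}

#' Trajectory design matrix: intercept + 5 cubic B-spline columns
#'
#' Evaluates the full 6-function clamped cubic B-spline basis (de Boor
#' recursion) at the given ages and reparameterizes it to an intercept plus
#' 5 columns by dropping the first full-basis function, which the partition
#' of unity makes redundant once an intercept is present. Any full-rank
#' reparameterization spans the same space; fitted curves are invariant.
#'
#' @param ages numeric vector of ages in years, inside the boundary.
#' @param spec a [spline_spec()].
#' @param full if `TRUE` return the raw 6-column B-spline basis (rows sum
#'   to 1) instead of the intercept parameterization.
#' @return numeric matrix with `length(ages)` rows and 6 columns.
#' @export
bspline_basis <- function(ages, spec, full = FALSE) {
  ages <- as.numeric(ages)
  eps <- 1e-10
  if (any(ages < spec$boundary[1] - eps | ages > spec$boundary[2] + eps))
    stop(sprintf("ages outside the basis boundary [%g, %g]; refusing to extrapolate",
                 spec$boundary[1], spec$boundary[2]))
  ages <- pmin(pmax(ages, spec$boundary[1]), spec$boundary[2])
  B <- splines::splineDesign(full_knots(spec), ages, ord = spec$degree + 1L,
                             outer.ok = FALSE)
  colnames(B) <- paste0("B", seq_len(ncol(B)))
  if (full) return(B)
  X <- cbind(1, B[, -1L, drop = FALSE])
  colnames(X) <- c("intercept", paste0("B", seq_len(ncol(B) - 1L)))
  X
}

#' Candidate interior-knot positions between scheduled record ages
#'
#' For each adjacent pair of measurement ages (a, b) the four equispaced
#' interior points a + j(b-a)/5, j = 1..4, are candidates, so knots are not
#' restricted to the measurement points themselves.
#'
#' @param measurement_ages numeric vector of >= 3 distinct ages.
#' @return object of class `knot_candidates`: list with `ages`, `candidates`
#'   (sorted numeric vector) and `gaps` (data.frame of the generating pairs).
#' @export
candidate_knots <- function(measurement_ages) {
  ages <- sort(unique(as.numeric(measurement_ages)))
  if (length(ages) < 3L) stop("need at least 3 distinct measurement ages")
  lo <- ages[-length(ages)]; hi <- ages[-1L]
  cand <- unlist(lapply(seq_along(lo), function(i)
    lo[i] + seq_len(4L) * (hi[i] - lo[i]) / 5))
  structure(list(ages = ages, candidates = cand,
                 gaps = data.frame(lower = lo, upper = hi)),
            class = "knot_candidates")
}

#' Admissible interior-knot pairs under the measurement-spacing rule
#'
#' A pair (k1, k2), k1 < k2, is admissible when at least 2 measurement ages
#' fall strictly before k1, strictly between k1 and k2, and strictly after
#' k2 — guaranteeing data support on every spline segment.
#'
#' @param candidates a [candidate_knots()] object.
#' @param measurement_ages ages to apply the rule against; defaults to the
#'   ages the candidates were built from.
#' @return data.frame with columns `k1`, `k2`, ordered by (k1, k2).
#' @export
admissible_knot_pairs <- function(candidates,
                                  measurement_ages = candidates$ages) {
  stopifnot(inherits(candidates, "knot_candidates"))
  ages <- sort(unique(as.numeric(measurement_ages)))
  cv <- candidates$candidates
  pairs <- expand.grid(k1 = cv, k2 = cv)
  pairs <- pairs[pairs$k1 < pairs$k2, , drop = FALSE]
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    k1 <- pairs$k1[i]; k2 <- pairs$k2[i]
    sum(ages < k1) >= 2L && sum(ages > k1 & ages < k2) >= 2L &&
      sum(ages > k2) >= 2L
  }, logical(1))
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no admissible knot pair: relax the measurement schedule or the spacing rule")
  pairs <- pairs[order(pairs$k1, pairs$k2), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' BIC-driven search over admissible interior-knot pairs
#'
#' Fits the linear mixed trajectory model (random intercept + random spline
#' coefficients, diagonal covariance, ML) for every admissible knot pair and
#' returns the pair minimizing BIC. Ties are broken toward the smaller k1,
#' then smaller k2. Individual non-converged fits are recorded and skipped.
#'
#' @param long_table long-format data.frame with columns `subject`,
#'   `age_years`, `food_g_day`.
#' @param measurement_ages the nominal record schedule used to generate and
#'   filter candidates.
#' @param boundary boundary knots passed to [spline_spec()].
#' @param control optimizer settings, see [lmm_control()].
#' @return list with `best_spec` (a [spline_spec()]), `bic_table`
#'   (data.frame k1, k2, loglik, bic, converged) and `n_failed`.
#' @export
knot_search <- function(long_table,
                        measurement_ages = c(0.25, 0.5, 1, 2, 3, 4, 5, 6),
                        boundary = range(measurement_ages),
                        control = lmm_control()) {
  cand <- candidate_knots(measurement_ages)
  pairs <- admissible_knot_pairs(cand)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    spec_i <- spline_spec(c(pairs$k1[i], pairs$k2[i]), boundary = boundary)
    fit <- tryCatch(fit_lmm(long_table, spec_i, control = control),
                    error = function(e) NULL)
    rows[[i]] <- if (is.null(fit)) {
      data.frame(k1 = pairs$k1[i], k2 = pairs$k2[i], loglik = NA_real_,
                 bic = NA_real_, converged = FALSE)
    } else {
      data.frame(k1 = pairs$k1[i], k2 = pairs$k2[i], loglik = fit$loglik,
                 bic = fit$bic, converged = fit$converged)
    }
  }
  bic_table <- do.call(rbind, rows)
  usable <- bic_table[is.finite(bic_table$bic), , drop = FALSE]
  if (nrow(usable) == 0L) stop("all knot-search fits failed")
  # order by bic then k1, k2 makes the tie-break deterministic
  usable <- usable[order(usable$bic, usable$k1, usable$k2), , drop = FALSE]
  best <- usable[1L, ]
  list(best_spec = spline_spec(c(best$k1, best$k2), boundary = boundary),
       bic_table = bic_table,
       n_failed = sum(!is.finite(bic_table$bic)))
}
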