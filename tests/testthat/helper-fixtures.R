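# shared simulated fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_jm_cohort <- function() {
  fixture("jm_small", function()
    simulate_cohort(cohort_config(n_subjects = 250, seed = 42,
                                  followup_max = 6)))
}

small_lc_cohort <- function() {
  fixture("lc_small", function()
    simulate_latent_class_cohort(cohort_config(n_subjects = 500, seed = 7)))
}

small_lc_fit <- function() {
  fixture("lc_fit", function() {
    co <- small_lc_cohort()
    fit_jlcmm(co$long, co$endpoints, co$baseline, co$spec, G = 2,
              control = jlcmm_control(n_starts = 3, se = TRUE), seed = 3)
  })
}

# hand-coded de Boor recursion, independent of splines::splineDesign
deboor_basis <- function(t, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- matrix(0, length(t), n_basis)
  for (i in seq_len(n_basis)) {
    for (j in seq_along(t)) B[j, i] <- deboor_one(t[j], i, degree, knots)
  }
  B
}

deboor_one <- function(x, i, d, knots) {
  if (d == 0) {
    hi <- knots[i + 1]
    # right-closed at the final boundary so the basis sums to 1 there
    if (hi >= max(knots) - 1e-12 && abs(x - hi) < 1e-12) return(1)
    return(as.numeric(x >= knots[i] && x < hi))
  }
  denom1 <- knots[i + d] - knots[i]
  denom2 <- knots[i + d + 1] - knots[i + 1]
  a <- if (denom1 > 0) (x - knots[i]) / denom1 * deboor_one(x, i, d - 1, knots) else 0
  b <- if (denom2 > 0) (knots[i + d + 1] - x) / denom2 *
      deboor_one(x, i + 1, d - 1, knots) else 0
  a + b
}
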