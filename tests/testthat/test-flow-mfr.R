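test_that("flow pipeline recovers truth MFR on noiseless unperturbed studies", {
  # identity extraction isolates the kinetic estimators from the steep
  # extraction inversion; the retention model's residual bias is the
  # documented late-window truncation effect
  em <- extraction_model("identity")
  for (sd in c(50, 3)) {
    pair <- simulate_patient(quiet_pop(extraction = em), "fm", seed = sd)
    truth_tot <- mean(truth_of(pair)$mfr)
    for (model in c("ret", "1cm")) {
      fs <- compute_flow(pair$stress, model, extraction = em)
      fr <- compute_flow(pair$rest, model, extraction = em)
      mfr <- compute_mfr(fs, fr)
      tot <- mfr$territories$mfr[mfr$territories$region == "TOT"]
      expect_lt(abs(tot - truth_tot) / truth_tot, 0.05)
    }
  }
})

test_that("one-compartment flow matches truth closely without noise", {
  pair <- simulate_patient(quiet_pop(), "fm2", seed = 51)
  fr <- compute_flow(pair$rest, "1cm")
  tr <- truth_of(pair)
  expect_equal(fr$segments$mbf, tr$mbf_rest, tolerance = 1e-3)
})

test_that("MFR identities: equal studies give 1, ratios pass through", {
  pair <- simulate_patient(quiet_pop(), "id", seed = 52)
  fr <- compute_flow(pair$rest, "ret")
  # reuse the rest study relabelled as stress: MFR must be exactly 1
  st2 <- dynamic_study("stress", pair$rest$schedule, pair$rest$tacs,
                       blood_fine = pair$rest$blood_fine)
  fs <- compute_flow(st2, "ret")
  mfr <- compute_mfr(fs, fr)
  expect_equal(mfr$segments$mfr, rep(1, 17))
  expect_equal(mfr$territories$mfr, rep(1, 4))
})

test_that("uniform MFR is weight-invariant", {
  seg <- sprintf("seg%02d", 1:17)
  mk_flow <- function(vals, condition) {
    structure(list(
      segments = tibble::tibble(segment = seg, uptake = vals, mbf = vals,
                                flagged = FALSE),
      territories = aggregate_territories(
        tibble::tibble(segment = seg, value = vals)) |>
        dplyr::rename(mbf = "value"),
      condition = condition, model = "ret", patient_id = "w", fit = NULL),
      class = "flow_result")
  }
  w <- aha17_scheme(weights = stats::runif(17, 0.5, 2))
  mfr <- compute_mfr(mk_flow(rep(1.8, 17), "stress"),
                     mk_flow(rep(0.9, 17), "rest"), scheme = w)
  expect_equal(mfr$territories$mfr, rep(2, 4))

  mfr2 <- compute_mfr(mk_flow(c(2, rep(1, 16)), "stress"),
                      mk_flow(rep(1, 17), "rest"))
  expect_equal(mfr2$segments$mfr[1], 2)
})

test_that("low rest flow segments are flagged and excluded from aggregates", {
  seg <- sprintf("seg%02d", 1:17)
  rest_vals <- c(0.01, rep(1, 16))       # segment 1 below the floor
  mk <- function(vals, condition) {
    structure(list(
      segments = tibble::tibble(segment = seg, uptake = vals, mbf = vals,
                                flagged = FALSE),
      territories = aggregate_territories(
        tibble::tibble(segment = seg, value = vals)) |>
        dplyr::rename(mbf = "value"),
      condition = condition, model = "ret", patient_id = "z", fit = NULL),
      class = "flow_result")
  }
  mfr <- compute_mfr(mk(rep(2, 17), "stress"), mk(rest_vals, "rest"))
  expect_true(mfr$segments$flagged[1])
  expect_true(is.na(mfr$segments$mfr[1]))
  expect_equal(mfr$territories$mfr, rep(2, 4))   # renormalised without seg 1
  expect_error(
    compute_mfr(mk(rep(2, 17), "stress"), mk(rep(0.001, 17), "rest")),
    "all segments excluded")
})
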