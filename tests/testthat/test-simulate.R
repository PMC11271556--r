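test_that("forward model limits: zero uptake, pure spillover, constant input", {
  aif <- default_aif()
  sch <- default_sched()
  expect_equal(simulate_true_tac(0, 0.1, 0, aif$fine, sch), rep(0, 23))
  expect_equal(simulate_true_tac(0, 0.1, 1, aif$fine, sch), aif$values,
               tolerance = 1e-12)
  # constant input: closed-form (K1 c / k2)(1 - exp(-k2 t))
  tt <- seq(0, 450, 0.25)
  cb <- rep(2, length(tt))
  k1 <- 0.8; k2 <- 0.15
  num <- onecomp_model(tt, cb, k1, k2, 0)
  cf <- (k1 * 2 / k2) * (1 - exp(-k2 * tt / 60))
  expect_lt(max(abs(num[-1] - cf[-1]) / cf[-1]), 1e-4)
})

test_that("generator is deterministic and honours degenerate configs", {
  pop <- quiet_pop()
  a <- simulate_patient(pop, "d1", seed = 99)
  b <- simulate_patient(pop, "d1", seed = 99)
  expect_identical(a, b)

  # degenerate distributions: every patient identical, truth MFR exact
  pop0 <- population_config(noise_scale = 0, scar_prevalence = 0,
                            rest_mbf_sdlog = 0, mfr_sdlog = 0,
                            segment_sdlog = 0, f_v_sd = 0,
                            k2_range = c(0.05, 0.05), peak_time_sd = 0,
                            tail_fraction_sdlog = 0, bad_bolus_rate = 0,
                            extracardiac_amplitude_sdlog = 0)
  p1 <- simulate_patient(pop0, "x", seed = 1)
  tr <- truth_of(p1)
  expect_equal(tr$mfr, rep(1.85, 17))
  expect_equal(tr$mbf_rest, rep(1, 17))
})

test_that("cohort medians track the configured population", {
  pop <- population_config(n_patients = 120, noise_scale = 0,
                           scar_prevalence = 0, bad_bolus_rate = 0)
  cohort <- simulate_population(pop, seed = 21)
  rest_tot <- vapply(cohort, function(p) mean(truth_of(p)$mbf_rest), 0)
  mfr_tot <- vapply(cohort, function(p) mean(truth_of(p)$mfr), 0)
  expect_lt(abs(stats::median(rest_tot) - pop$rest_mbf_median) /
              pop$rest_mbf_median, 0.10)
  expect_lt(abs(stats::median(mfr_tot) - pop$mfr_median) / pop$mfr_median,
            0.10)
})

test_that("scar patients carry a reduced-flow inferior block", {
  pop <- population_config(scar_prevalence = 1, noise_scale = 0,
                           segment_sdlog = 0, bad_bolus_rate = 0)
  tr <- truth_of(simulate_patient(pop, "s", seed = 5))
  scar_ids <- sprintf("seg%02d", c(4, 10, 15))
  expect_true(all(tr$scar[tr$segment %in% scar_ids]))
  expect_false(any(tr$scar[!tr$segment %in% scar_ids]))
  ratio <- mean(tr$mbf_rest[tr$scar]) / mean(tr$mbf_rest[!tr$scar])
  expect_equal(ratio, 1 - pop$scar_severity, tolerance = 1e-9)
})

test_that("operator perturbation is deterministic and identity at zero SD", {
  pair <- simulate_patient(quiet_pop(), "op", seed = 12)
  p0 <- apply_operator_perturbation(pair, zero_perturbation(), 123)
  expect_equal(p0$rest$tacs, pair$rest$tacs)
  expect_equal(p0$stress$tacs, pair$stress$tacs)

  pc <- perturbation_config()
  a <- apply_operator_perturbation(pair, pc, 77)
  b <- apply_operator_perturbation(pair, pc, 77)
  expect_identical(a, b)
  c2 <- apply_operator_perturbation(pair, pc, 78)
  expect_false(isTRUE(all.equal(a$rest$tacs, c2$rest$tacs)))
})

test_that("inferior contamination touches only RCA segments", {
  pair <- simulate_patient(quiet_pop(), "rc", seed = 13)
  pc <- perturbation_config(valve_plane_sd = 0, axis_sd = 0, motion_sd = 0,
                            inferior_contamination_sd = 0.1)
  pp <- apply_operator_perturbation(pair, pc, 5)
  changed <- vapply(sprintf("seg%02d", 1:17), function(sg)
    !isTRUE(all.equal(pp$rest$tacs[[sg]], pair$rest$tacs[[sg]])), TRUE)
  expect_setequal(which(changed), c(3, 4, 9, 10, 15))
})

test_that("mixing keeps perturbed values within the contributing envelope", {
  pair <- simulate_patient(quiet_pop(), "mx", seed = 14)
  pc <- perturbation_config(motion_sd = 0)  # pure convex mixing
  pp <- apply_operator_perturbation(pair, pc, 31)
  lo <- pmin(do.call(pmin, pair$rest$tacs[sprintf("seg%02d", 1:17)]),
             pair$rest$tacs$blood, pair$rest$tacs$extracardiac)
  hi <- pmax(do.call(pmax, pair$rest$tacs[sprintf("seg%02d", 1:17)]),
             pair$rest$tacs$blood, pair$rest$tacs$extracardiac)
  for (sg in sprintf("seg%02d", 1:17)) {
    expect_true(all(pp$rest$tacs[[sg]] >= lo - 1e-12))
    expect_true(all(pp$rest$tacs[[sg]] <= hi + 1e-12))
  }
})

test_that("same-operator replicates differ less than different operators", {
  pc <- perturbation_config()
  pair <- simulate_patient(quiet_pop(), "ir", seed = 15)
  seg_mat <- function(p) as.matrix(p$rest$tacs[sprintf("seg%02d", 1:17)])
  d_intra <- d_inter <- numeric(20)
  for (i in 1:20) {
    s1 <- derive_seed(1000 + i, "op1"); s2 <- derive_seed(1000 + i, "op2")
    r1 <- apply_operator_perturbation(pair, pc, s1, replicate = 1)
    r2 <- apply_operator_perturbation(pair, pc, s1, replicate = 2)
    o2 <- apply_operator_perturbation(pair, pc, s2, replicate = 1)
    d_intra[i] <- sqrt(mean((seg_mat(r1) - seg_mat(r2))^2))
    d_inter[i] <- sqrt(mean((seg_mat(r1) - seg_mat(o2))^2))
  }
  expect_lt(mean(d_intra), mean(d_inter))
})
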