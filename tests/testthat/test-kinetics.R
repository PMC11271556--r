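test_that("retention formula has its closed forms", {
  sch <- default_sched()
  cfg <- retention_config(beta = 0.15)
  # segment identical to beta * blood: spillover correction cancels exactly
  aif <- default_aif()
  st <- uniform_study(0.15 * aif$values, aif = aif)
  r <- ret_uptake(st, cfg)
  expect_equal(r$uptake, rep(0, 17))
  expect_false(any(r$flagged))

  # beta = 0, constant blood c, constant myocardium h: R = 60 h / (c T0)
  c0 <- 2; h <- 0.5
  tacs <- tibble::as_tibble(stats::setNames(
    lapply(1:17, function(i) rep(h, 23)), sprintf("seg%02d", 1:17)))
  tacs$blood <- rep(c0, 23)
  st2 <- dynamic_study("rest", sch, tacs)
  r2 <- ret_uptake(st2, retention_config(beta = 0))
  expect_equal(r2$uptake, rep(60 * h / (c0 * 210), 17))

  # negative corrected numerator clips at zero and flags
  st3 <- uniform_study(0.5 * 0.15 * aif$values, aif = aif)
  r3 <- ret_uptake(st3, cfg)
  expect_true(all(r3$uptake == 0))
  expect_true(all(r3$flagged))
})

test_that("retention tracks K1 on a noiseless slow-washout segment", {
  aif <- default_aif()
  k1 <- 0.7
  tv <- simulate_true_tac(k1, 0.01, 0.15, aif$fine, aif$schedule)
  st <- uniform_study(tv, aif = aif)
  r <- ret_uptake(st, retention_config(beta = 0.15))
  expect_lt(abs(r$uptake[1] - k1) / k1, 0.05)
})

test_that("retention errors on degenerate blood input", {
  sch <- default_sched()
  tacs <- tibble::as_tibble(stats::setNames(
    lapply(1:17, function(i) rep(1, 23)), sprintf("seg%02d", 1:17)))
  tacs$blood <- rep(0, 23)
  st <- dynamic_study("rest", sch, tacs)
  expect_error(ret_uptake(st), "blood integral")
})

test_that("compartment fit recovers noiseless parameters segment-wise", {
  aif <- default_aif()
  set.seed(41)
  k1 <- stats::runif(17, 0.3, 2.5)
  k2 <- stats::runif(17, 0.05, 0.5)
  fv <- stats::runif(17, 0, 0.5)
  st <- uniform_study(function(i)
    simulate_true_tac(k1[i], k2[i], fv[i], aif$fine, aif$schedule), aif = aif)
  est <- tidy(fit_1cm(st))
  expect_true(all(est$converged))
  expect_lt(stats::median(abs(est$k1 - k1) / k1), 0.005)
  expect_lt(stats::median(abs(est$k2 - k2)), 0.005)
  expect_lt(stats::median(abs(est$f_v - fv)), 0.005)
})

test_that("compartment fit degenerate inputs: pure blood and zero segment", {
  aif <- default_aif()
  st <- uniform_study(function(i)
    if (i == 1) aif$values else rep(0, 23), aif = aif)
  est <- tidy(fit_1cm(st, segments = c("seg01", "seg02")))
  expect_equal(est$f_v[1], 1, tolerance = 1e-3)
  expect_equal(est$k1[1], 0, tolerance = 1e-3)
  expect_equal(est$k1[2], 0)
  expect_error(fit_1cm(uniform_study(rep(1, 23),
    aif = list(values = rep(1, 23), fine = NULL,
               schedule = default_sched()))), "degenerate")
})

test_that("fast exponential convolution matches direct quadrature", {
  aif <- default_aif()
  tt <- aif$fine$time_s
  cb <- aif$fine$value
  k2s <- 0.2 / 60
  fast <- mfrkit:::exp_conv(cb, 0.5, k2s)
  # direct O(n^2) trapezoid of the convolution integral at checkpoints
  for (i in c(51, 201, 601, length(tt))) {
    integrand <- exp(-k2s * (tt[i] - tt[1:i])) * cb[1:i]
    direct <- sum(diff(tt[1:i]) * (integrand[-1] + integrand[-i]) / 2)
    expect_equal(fast[i], direct, tolerance = 1e-4)
  }
})

test_that("kinetic estimates are scale invariant in global intensity", {
  pair <- simulate_patient(quiet_pop(), "sc", seed = 44)
  st <- pair$rest
  scaled_tacs <- st$tacs
  for (cl in names(scaled_tacs)) scaled_tacs[[cl]] <- 3.7 * scaled_tacs[[cl]]
  st2 <- dynamic_study("rest", st$schedule, scaled_tacs,
                       blood_fine = tibble::tibble(
                         time_s = st$blood_fine$time_s,
                         value = 3.7 * st$blood_fine$value))
  expect_equal(ret_uptake(st2)$uptake, ret_uptake(st)$uptake,
               tolerance = 1e-8)
  e1 <- tidy(fit_1cm(st)); e2 <- tidy(fit_1cm(st2))
  expect_equal(e2$k1, e1$k1, tolerance = 1e-5)
  expect_equal(e2$f_v, e1$f_v, tolerance = 1e-5)
})

test_that("global blood admixture shifts retention equally across segments", {
  pair <- simulate_patient(quiet_pop(), "gb", seed = 45)
  st <- pair$rest
  delta <- 0.07
  tacs <- st$tacs
  for (sg in sprintf("seg%02d", 1:17))
    tacs[[sg]] <- tacs[[sg]] + delta * tacs$blood
  st2 <- dynamic_study("rest", st$schedule, tacs, blood_fine = st$blood_fine)
  shift <- ret_uptake(st2)$uptake - ret_uptake(st)$uptake
  expect_lt(diff(range(shift)), 1e-9)
  expect_gt(mean(shift), 0)
})

test_that("extraction model round-trips flow through uptake", {
  em <- extraction_model("renkin_crone", ps = 1.0)
  for (m in c(0.5, 1, 2, 3)) {
    u <- uptake_from_flow(m, em)
    expect_equal(flow_from_uptake(u, em)$mbf, m, tolerance = 1e-6)
  }
  expect_equal(flow_from_uptake(1.23, extraction_model("identity"))$mbf, 1.23)
  expect_equal(flow_from_uptake(0, em)$mbf, 0)
  sat <- flow_from_uptake(0.999, em, upper = 10)
  expect_true(sat$saturated)
  expect_equal(sat$mbf, 10)
  expect_error(flow_from_uptake(-0.1, em), "non-negative")
})

test_that("uptake is strictly increasing in flow (unique inversion)", {
  em <- extraction_model()
  m <- seq(0.05, 5, by = 0.05)
  expect_true(all(diff(uptake_from_flow(m, em)) > 0))
})
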