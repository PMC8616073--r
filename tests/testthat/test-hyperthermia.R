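test_that("session placement respects duration, gap and pairing", {
  rt <- build_rt_schedule("RT1")
  for (proto in c("HT1", "HT2", "HT3")) {
    ht <- build_ht_schedule(proto, rt)
    expect_true(all(ht$sessions$duration == 60 / 1440))
    # every session ends exactly 30 min before some fraction
    ends <- ht$sessions$start + ht$sessions$duration
    gap_to_fraction <- vapply(ends, function(e)
      min(rt$fractions$start[rt$fractions$start >= e] - e), numeric(1))
    expect_equal(gap_to_fraction, rep(30 / 1440, nrow(ht$sessions)))
  }
  expect_equal(nrow(build_ht_schedule("HT0", rt)$sessions), 0)
  expect_equal(nrow(build_ht_schedule("HT1", rt)$sessions), 4)
  expect_equal(nrow(build_ht_schedule("HT2", rt)$sessions), 10)
  expect_equal(nrow(build_ht_schedule("HT3", rt)$sessions), 10)
  # the front-loaded protocol concentrates sessions in the first 10 days
  ht2 <- build_ht_schedule("HT2", rt)
  ht3 <- build_ht_schedule("HT3", rt)
  in10 <- function(ht) sum(ht$sessions$start < 580)
  expect_gt(in10(ht2), in10(ht3))
  expect_error(build_ht_schedule("HT1", NULL), "rt_schedule")
})

test_that("perfusion kinetics reach factor 2 and relax within 30 min", {
  # closed form: theta(t) = 1 - exp(-kperf t) during heating from 0
  n <- 250
  dt <- (30 / 1440) / n   # exactly 30 min of heating
  th <- 0
  for (i in 1:n)
    th <- rk4_step(th, 0, dt, function(t, y) perfusion_rhs(y, TRUE))
  expect_equal(th, 1 - exp(-200 * 30 / 1440), tolerance = 1e-9)
  expect_equal(th, 0.9845, tolerance = 1e-4)
  # sustained heating: fixed point theta = 1, PEF = 2
  expect_equal(perfusion_rhs(1, TRUE), 0)
  # relaxation after heating: below 0.02 within 30 min (tau = 7.2 min)
  th <- 1
  for (i in 1:n)
    th <- rk4_step(th, 0, dt, function(t, y) perfusion_rhs(y, FALSE))
  expect_lt(th, 0.02)
  # no heating ever: stays at baseline
  expect_equal(perfusion_rhs(0, FALSE), 0)
})

test_that("immune stimulation peaks near two-fold at 48 h and decays", {
  # 24 h active window (opened one day after the session start)
  ph <- 0
  dt <- 1e-4
  for (i in 1:round(1 / dt))
    ph <- rk4_step(ph, 0, dt, function(t, y) ims_rhs(y, TRUE))
  expect_equal(ph, 1 - exp(-7), tolerance = 1e-9)
  expect_equal(1 + ph, 2.0, tolerance = 1e-3)   # ISF peak ~ 2 at 48 h
  # decay: ISF back below 1.05 one day after the window closes (72 h)
  for (i in 1:round(1 / dt))
    ph <- rk4_step(ph, 0, dt, function(t, y) ims_rhs(y, FALSE))
  expect_lt(1 + ph, 1.05)
  # no session: identically baseline
  expect_equal(ims_rhs(0, FALSE), 0)
})

test_that("effective parameters apply the sensitization and immune factors", {
  p <- default_parameters()
  # alpha/beta only during a paired fraction's beam-on
  eff <- effective_parameters(p, theta = 0, phi = 0, ht_flags("all"), TRUE)
  expect_equal(eff$alphaT, 0.5488)
  expect_equal(eff$betaT, 0.017)
  eff <- effective_parameters(p, theta = 0, phi = 0, ht_flags("all"), FALSE)
  expect_equal(eff$alphaT, p$alphaT)
  # all flags off: identity
  eff <- effective_parameters(p, theta = 1, phi = 1, ht_flags("none"), TRUE)
  expect_equal(eff$alphaT, p$alphaT)
  expect_equal(eff$kI, p$kI)
  expect_equal(eff$Xact, p$Xact)
  # kI scaled by PEF
  eff <- effective_parameters(p, theta = 1, phi = 0,
                              ht_flags("alpha_beta_kI"), FALSE)
  expect_equal(eff$kI, 20)
  # slow vs fast process for Xact/Lact
  eff_s <- effective_parameters(p, theta = 0.2, phi = 0.8,
                                ht_flags("all", "slow"), FALSE)
  expect_equal(eff_s$Xact, 2 / 1.8)
  expect_equal(eff_s$Lact, 3 / 1.8)
  eff_f <- effective_parameters(p, theta = 0.2, phi = 0.8,
                                ht_flags("all", "fast"), FALSE)
  expect_equal(eff_f$Xact, 2 / 1.2)
  expect_equal(eff_f$Lact, 3 / 1.2)
})

test_that("parameter modification is pure and never compounds", {
  p <- default_parameters()
  fl <- ht_flags("all")
  once <- effective_parameters(p, 0.5, 0.5, fl, TRUE)
  again <- effective_parameters(p, 0.5, 0.5, fl, TRUE)
  expect_identical(once, again)
})

test_that("hyperthermia states stay inside [0, 1] along a treated run", {
  sim <- cached_sim("RT1HT2", "all")
  tr <- sim$trajectory
  expect_true(all(tr$theta >= 0 & tr$theta <= 1))
  expect_true(all(tr$phi >= 0 & tr$phi <= 1))
  expect_true(all(tr$PEF >= 1 & tr$PEF <= 2))
  expect_true(all(tr$ISF >= 1 & tr$ISF <= 2))
  # the slow process is visible at the default 0.1-d recording stride
  expect_gt(max(tr$ISF), 1.9)
  # the 60-min perfusion excursions need fine-resolution recording
  fine <- simulate_protocol("RT1HT2", flag_set = "all", t_end = 571,
                            record_stride = 5)
  expect_gt(max(fine$trajectory$PEF), 1.9)
  expect_true(all(fine$trajectory$PEF <= 2))
})
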