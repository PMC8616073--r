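p_def <- default_parameters()
topo_def <- default_topology()

test_that("single clone without interference balances at its equilibrium", {
  p <- p_def
  p$kmut <- 0
  Tc <- c(306, rep(0, 8))
  d <- tumor_host_rhs(Tc, H = 0, p, topo_def)
  expect_equal(d$dT[1], 0, tolerance = 1e-10)
  # restoring on both sides of the equilibrium
  expect_gt(tumor_host_rhs(c(300, rep(0, 8)), 0, p, topo_def)$dT[1], 0)
  expect_lt(tumor_host_rhs(c(312, rep(0, 8)), 0, p, topo_def)$dT[1], 0)
})

test_that("tumor extinction is absorbing", {
  d <- tumor_host_rhs(rep(0, 9), H = 250, p_def, topo_def)
  expect_identical(d$dT, rep(0, 9))
})

test_that("host line evaluates to the hand-computed rate", {
  d <- tumor_host_rhs(rep(0, 9), H = 250, p_def, topo_def)
  expected <- (p_def$kaH - p_def$keH - p_def$kbH * 250) * 250
  expect_equal(d$dH, expected, tolerance = 1e-6)
})

test_that("mutation follows the printed asymmetry", {
  Tc <- rep(100, 9)
  d0 <- tumor_host_rhs(Tc, 0, p_def, topo_def)
  p0 <- p_def
  p0$kmut <- 0
  dnm <- tumor_host_rhs(Tc, 0, p0, topo_def)
  delta <- d0$dT - dnm$dT
  # founder loses kmut*T11 but gains nothing; children gain kmut*T_parent
  expect_equal(delta[1], -p_def$kmut * 100)
  expect_equal(delta[-1], rep(p_def$kmut * 100, 8))
  # optional per-clone outflow drains every clone with descendants
  dall <- tumor_host_rhs(Tc, 0, p_def, topo_def, mut_outflow_all = TRUE)
  drained <- which(topo_def$has_child == 1)
  # the founder drains in both modes; the other parents only in this one
  extra <- rep(p_def$kmut * 100, length(drained))
  extra[drained == 1] <- 0
  expect_equal((d0$dT - dall$dT)[drained], extra)
})

test_that("damaged-cell pools balance at their closed-form steady states", {
  # tumor pool: inflow keT*T, drain kpn -> Np* = keT*T/kpn = 0.8 at T = 100
  Tc <- c(100, rep(0, 8))
  Np_star <- p_def$keT * 100 / p_def$kpn
  expect_equal(Np_star, 0.8)
  d <- deadcell_rhs(Tc, H = 0, Np = c(Np_star, rep(0, 8)), NpH = 0,
                    N = rep(0, 9), NH = 0, p_def, topo_def)
  expect_equal(d$dNp[1], 0)
  # host pool drains through kpn + kap = 2.5: NpH* = inflow/2.5
  H <- 50
  inflowH <- p_def$keH * H
  d <- deadcell_rhs(rep(0, 9), H, rep(0, 9), NpH = inflowH / 2.5,
                    N = rep(0, 9), NH = 0, p_def, topo_def)
  expect_equal(d$dNpH, 0)
  # empty system is a fixed point
  d <- deadcell_rhs(rep(0, 9), 0, rep(0, 9), 0, rep(0, 9), 0, p_def, topo_def)
  expect_true(all(abs(unlist(d)) == 0))
})

test_that("dead-cell inflow equals the elimination outflow term by term", {
  # mass-flow consistency across random states, dose rates and immune loads
  set.seed(42)
  for (rep in 1:20) {
    Tc <- runif(9, 0, 300)
    H <- runif(1, 0, 250)
    I <- runif(9, 0, 2)
    GT <- runif(1, 0, 2)
    GH <- runif(1, 0, 2)
    R <- sample(c(0, 201.6), 1)
    mc <- match_coefficients(I, topo_def)
    d <- deadcell_rhs(Tc, H, rep(0, 9), 0, rep(0, 9), 0, p_def, topo_def,
                      R = R, GammaT = GT, GammaH = GH,
                      r_clones = mc$r_clones, r_host = mc$r_host)
    # independent recomputation from the kill-rate primitives
    radT <- lq_death_rate(p_def$alphaT, p_def$betaT, GT, R)
    radH <- lq_death_rate(p_def$alphaH, p_def$betaH, GH, R)
    expected <- c((p_def$keT + mc$r_clones * p_def$kIT + radT) * Tc,
                  (p_def$keH + mc$r_host * p_def$kIH + radH) * H)
    expect_equal(d$inflow, expected, tolerance = 1e-12)
  }
})

test_that("host alone recovers its equilibrium within 0.1% by day 560", {
  nt <- no_treatment()
  sim <- simulate_ecosystem(p_def, topo_def, nt$rt, nt$ht, t_end = 560,
                            rt_start = 559,
                            init = initial_state(p_def, topo_def,
                                                 T11 = 0, H = 125))
  Heq <- unname(equilibrium_levels(p_def)["Heq"])
  H560 <- sim$trajectory$H[sim$trajectory$time == 560]
  expect_lt(abs(H560 - Heq) / Heq, 1e-3)
})

test_that("one clone with immune response disabled converges to 306", {
  p <- p_def
  p$kIT <- 0
  p$kIH <- 0
  p$kmut <- 0
  nt <- no_treatment()
  sim <- simulate_ecosystem(p, topo_def, nt$rt, nt$ht, t_end = 650,
                            rt_start = 649,
                            init = initial_state(p, topo_def,
                                                 T11 = 1e-2, H = 0))
  T_end <- sim$trajectory$T_total[sim$trajectory$time == 650]
  expect_lt(abs(T_end - 306) / 306, 1e-3)
})
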