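p_def <- default_parameters()
topo_def <- default_topology()

test_that("one RK4 step integrates linear decay to fifth-order accuracy", {
  y1 <- rk4_step(1, 0, 1e-3, function(t, y) -y)
  expect_lt(abs(y1 - exp(-1e-3)), 1e-13)
})

test_that("the host equilibrium is a fixed point of the engine", {
  nt <- no_treatment()
  sim <- simulate_ecosystem(p_def, topo_def, nt$rt, nt$ht, t_end = 1,
                            rt_start = 0.5,
                            init = initial_state(p_def, topo_def, T11 = 0),
                            record_stride = 100)
  Heq <- unname(equilibrium_levels(p_def)["Heq"])
  expect_lt(max(abs(sim$trajectory$H - Heq)), 1e-10)
})

test_that("engine trajectory matches an adaptive reference integration", {
  nt <- no_treatment()
  sim <- simulate_ecosystem(p_def, topo_def, nt$rt, nt$ht, t_end = 30,
                            rt_start = 29, record_stride = 1000)
  f <- function(t, y, parms)
    list(as.numeric(ecosystem_rhs(y, p_def, topo_def)))
  ref <- deSolve::ode(unname(initial_state(p_def, topo_def)),
                      seq(0, 30, by = 1), f, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  got <- as.matrix(sim$trajectory[sim$trajectory$time %in% seq(0, 30, 1),
                                  state_names(topo_def)])
  want <- ref[, -1]
  rel <- abs(got - want) / pmax(abs(want), 1e-4)
  expect_lt(max(rel), 1e-6)
})

test_that("TCP evaluation follows exp(-nadir) on the post-RT window", {
  expect_equal(evaluate_tcp(
    data.frame(time = c(570, 580), T_total = c(5, 0)), 570)$tcp, 1)
  out <- evaluate_tcp(
    data.frame(time = c(570, 580), T_total = c(5, 0.22314)), 570)
  expect_equal(out$tcp, 0.800, tolerance = 1e-4)
  # regrowth after the nadir does not change the result
  out2 <- evaluate_tcp(
    data.frame(time = c(570, 580, 590, 600),
               T_total = c(5, 0.22314, 10, 300)), 570)
  expect_equal(out2$tcp, out$tcp)
  expect_equal(out2$t_min_time, 580)
  # pre-treatment burden is ignored
  out3 <- evaluate_tcp(
    data.frame(time = c(500, 570, 580), T_total = c(0.01, 5, 1)), 570)
  expect_equal(out3$t_min, 1)
  expect_error(evaluate_tcp(
    data.frame(time = 1, T_total = 1), 570), "window")
})

test_that("trajectory recording has the documented shape", {
  nt <- no_treatment()
  sim <- simulate_ecosystem(p_def, topo_def, nt$rt, nt$ht, t_end = 2,
                            rt_start = 1, record_stride = 100)
  expect_equal(nrow(sim$trajectory), 1 + floor(2 / (1e-3 * 100)))
  expect_true(all(state_names(topo_def) %in% names(sim$trajectory)))
  expect_true(all(c("D", "Y", "Sigma", "PEF", "ISF", "T_total", "R")
                  %in% names(sim$trajectory)))
})

test_that("invalid configurations are rejected with diagnostics", {
  nt <- no_treatment()
  expect_error(simulate_ecosystem(t_end = 100, rt_start = 570), "rt_start")
  bad_topo <- build_topology(matrix(c(1, 0), 1, 2), NA_integer_)
  expect_error(simulate_ecosystem(topology = bad_topo), "9-clone")
  p_bad <- p_def
  p_bad$kTT <- -1
  expect_error(simulate_ecosystem(params = p_bad,
                                  rt = nt$rt, ht = nt$ht), "invalid")
  expect_error(simulate_protocol("RT3HT1"), "protocol")
  # unbounded growth aborts with a non-finite diagnostic
  p_run <- p_def
  p_run$kaH <- 1e80  # overflows within one step
  p_run$kbH <- 0
  p_run$keH <- 0
  expect_error(simulate_ecosystem(params = p_run, rt = nt$rt, ht = nt$ht,
                                  t_end = 1, rt_start = 0.5,
                                  init = initial_state(p_def, topo_def)),
               "non-finite")
})

test_that("identical configurations reproduce bit-identical results", {
  a <- simulate_protocol("RT1HT2", flag_set = "all", t_end = 650)
  b <- simulate_protocol("RT1HT2", flag_set = "all", t_end = 650)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$summary, b$summary)
})

test_that("tidy, glance and autoplot expose the simulation", {
  nt <- no_treatment()
  sim <- simulate_ecosystem(p_def, topo_def, nt$rt, nt$ht, t_end = 2,
                            rt_start = 1, record_stride = 500)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("time", "variable", "class", "value"))
  expect_true(all(c("tumor", "host", "effector", "signal") %in% td$class))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("tcp", "t_min", "scheme") %in% names(gl)))
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(sim, "effectors"), "ggplot")
  expect_s3_class(autoplot(sim, "signals"), "ggplot")
})
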