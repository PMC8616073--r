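topo_def <- default_topology()

test_that("danger signal follows the squared sigmoid with midpoint Lact", {
  expect_equal(danger_signal(c(1, 2), Lact = 3), 0.5)   # S = Lact
  expect_equal(danger_signal(rep(0, 10), Lact = 3), 0)
  expect_equal(danger_signal(9, Lact = 3), 81 / 90)     # hand evaluation
  # midpoint location equals Lact exactly, for any Lact
  for (L in c(0.5, 1, 3, 6, 12)) expect_equal(danger_signal(L, L), 0.5)
})

test_that("antigen signals pool bearer populations with eta/chi weights", {
  z <- rep(0, 10)
  # S_1 = Xact -> midpoint: component 1 borne by T11..T14
  Tc <- c(rep(0.5, 4), rep(0, 5), 0)
  X <- antigen_signals(Tc, z, z, topo_def, eta = 0.5, chi = 0.2, Xact = 2)
  expect_equal(X[1], 0.5)
  expect_equal(antigen_signals(z, z, z, topo_def, 0.5, 0.2, 2), rep(0, 9))
  # S_n = 6, Xact = 2 -> 36/40
  Tc <- c(6, rep(0, 9))
  X <- antigen_signals(Tc, z, z, topo_def, 0.5, 0.2, 2)
  expect_equal(X[1], 0.9)
  # damaged and necrotic cells contribute with their weights
  Np <- c(4, rep(0, 9))   # eta * 4 = 2 = Xact -> midpoint
  X <- antigen_signals(z, Np, z, topo_def, 0.5, 0.2, 2)
  expect_equal(X[1], 0.5)
  # host mass enters only the components the host bears
  Hpop <- c(rep(0, 9), 10)
  X <- antigen_signals(Hpop, z, z, topo_def, 0.5, 0.2, 2)
  expect_true(all(X[c(2, 8, 9)] > 0))
  expect_true(all(X[-c(2, 8, 9)] == 0))
})

test_that("perceptron response saturates and clamps at non-positive drive", {
  expect_equal(perceptron_response(w = 1, X = 3, Yact = 3, xi = 9), 0.5)
  expect_equal(perceptron_response(w = 0, X = 1, Yact = 3), 0)
  expect_equal(perceptron_response(w = -1, X = 1, Yact = 3), 0)  # clamp
  # mixed weights with positive net drive are not clamped
  expect_equal(perceptron_response(w = c(2, -1), X = c(1, 1), Yact = 3),
               1 / (3^9 + 1))
})

test_that("weight learning follows the gated delta rule", {
  expect_equal(weight_rhs(D = 0.4, Y = 0.4, X = runif(9), a = 5), rep(0, 9))
  expect_equal(weight_rhs(D = 1, Y = 0, X = rep(1, 9), a = 5), rep(5, 9))
  expect_equal(weight_rhs(D = 1, Y = 0, X = rep(0, 9), a = 5), rep(0, 9))
})

test_that("match coefficients are pattern dot products", {
  expect_equal(match_coefficients(rep(0, 9), topo_def)$r_clones, rep(0, 9))
  # all-ones effector vector: r equals the number of borne antigens
  mc <- match_coefficients(rep(1, 9), topo_def)
  expect_equal(mc$r_clones,
               unname(colSums(topo_def$P[, 1:9, drop = FALSE])))
  expect_equal(mc$r_host, sum(topo_def$P[, 10]))
  # unit vector on component 1 matches exactly the component-1 bearers
  mc <- match_coefficients(c(1, rep(0, 8)), topo_def)
  expect_equal(mc$r_clones, c(1, 1, 1, 1, rep(0, 5)))
  expect_equal(mc$r_host, 0)
})

test_that("match coefficients are bounded by the total effector mass", {
  set.seed(7)
  for (i in 1:20) {
    I <- runif(9, 0, 5)
    mc <- match_coefficients(I, topo_def)
    expect_true(all(mc$r_clones <= sum(I) + 1e-12))
    expect_true(all(mc$r_clones >= 0))
  }
})

test_that("effector dynamics balance production, decay and consumption", {
  z9 <- rep(0, 9)
  # pure decay
  dI <- effector_rhs(I = rep(2, 9), T_clones = z9, topo_def, Y = 0, X = z9,
                     kI = 10, keI = 1, alphaI = 0.1, betaI = 0.01,
                     GammaI = 0, R = 0, kIT = 1)
  expect_equal(dI, rep(-2, 9))
  # hand-evaluated production term
  dI <- effector_rhs(I = z9, T_clones = z9, topo_def, Y = 0.5,
                     X = rep(0.5, 9), kI = 10, keI = 1, alphaI = 0.1,
                     betaI = 0.01, GammaI = 0, R = 0, kIT = 1)
  expect_equal(dI, rep(2.5, 9))
  # closed-form balance I* = kI Y X / keI with no tumor and no beam
  Y <- 0.3; X <- rep(0.4, 9)
  dI <- effector_rhs(I = 10 * Y * X / 1, T_clones = z9, topo_def, Y, X,
                     kI = 10, keI = 1, alphaI = 0.1, betaI = 0.01,
                     GammaI = 0, R = 0, kIT = 1)
  expect_equal(dI, rep(0, 9))
  # the per-effector consumption decomposes the matched total exactly:
  # sum_n I_n B_n == sum_clones r_c T_c
  set.seed(11)
  I <- runif(9); Tc <- runif(9, 0, 100)
  Pt <- topo_def$P[, 1:9]
  mc <- match_coefficients(I, topo_def)
  expect_equal(sum(I * as.numeric(Pt %*% Tc)), sum(mc$r_clones * Tc))
})

test_that("activation signals are monotone and bounded in [0, 1)", {
  s_grid <- seq(0, 50, by = 0.5)
  D <- vapply(s_grid, danger_signal, numeric(1), Lact = 3)
  expect_true(all(diff(D) >= 0))
  expect_true(all(D >= 0 & D < 1))
  Y <- vapply(s_grid, function(s)
    perceptron_response(w = 1, X = s, Yact = 3, xi = 9), numeric(1))
  expect_true(all(diff(Y) >= 0))
  expect_true(all(Y >= 0 & Y < 1))
})

test_that("perceptron weights converge until the response matches danger", {
  # frozen environment: constant danger and antigen signals
  p <- default_parameters()
  D <- 0.7
  X <- c(0.9, 0.6, rep(0.3, 7))
  w <- rep(0, 9)
  dt <- 0.01
  for (step in 1:20000) {
    w <- rk4_step(w, 0, dt, function(t, w) {
      Y <- perceptron_response(w, X, p$Yact, p$xi)
      weight_rhs(D, Y, X, p$a)
    })
  }
  Y_end <- perceptron_response(w, X, p$Yact, p$xi)
  expect_lt(abs(Y_end - D), 1e-3)
})
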