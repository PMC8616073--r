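#' Danger signal from immune-stimulatory dying cells
#'
#' Squared-sigmoid activation of the danger signal by the total pool of
#' immune-stimulatory necrotic/immunogenic-apoptotic cells:
#' `D = S^2 / (Lact^2 + S^2)` with `S` the summed pool (tumor clones plus
#' host). `Lact` (possibly hyperthermia-lowered) sets the half-activation
#' point: `D = 0.5` exactly at `S = Lact`.
#'
#' @param N_pools numeric vector of immune-stimulatory populations
#'   (any grouping; only the sum enters).
#' @param Lact danger-signal activation level (> 0).
#' @return danger signal in `[0, 1)`.
#' @export
#' @examples
#' danger_signal(c(1, 2), 3)  # 0.5 at the midpoint
danger_signal <- function(N_pools, Lact) {
  stopifnot(Lact > 0)
  S <- sum(N_pools)
  S^2 / (Lact^2 + S^2)
}

#' Antigen signals per pattern component
#'
#' For each antigen component `n`, the populations bearing it contribute
#' their effective antigen-presenting mass `T~ = pop + eta*Np + chi*N`
#' (living cells plus down-weighted damaged and immune-stimulatory cells).
#' The component signal is the squared sigmoid
#' `X_n = S_n^2 / (Xact^2 + S_n^2)`. Host populations contribute to the
#' components the host bears.
#'
#' @param pops living populations, length `n_clones + 1` (host last).
#' @param Np pre-immune-stimulatory pools, same length and order.
#' @param N immune-stimulatory pools, same length and order.
#' @param topology an `ite_topology`.
#' @param eta,chi antigen-presence weights of `Np` and `N` cells.
#' @param Xact pattern-recognition level (> 0, possibly HT-lowered).
#' @return numeric vector of component signals in `[0, 1)`.
#' @export
antigen_signals <- function(pops, Np, N, topology, eta, chi, Xact) {
  stopifnot(Xact > 0)
  n_pop <- topology$n_clones + 1L
  stopifnot(length(pops) == n_pop, length(Np) == n_pop, length(N) == n_pop)
  Ttil <- pops + eta * Np + chi * N
  S <- as.numeric(topology$P %*% Ttil)
  S^2 / (Xact^2 + S^2)
}

#' Perceptron response
#'
#' The trained response `Y` to the weighted antigen sum
#' `Sigma = sum(w * X)`: `Y = Sigma^xi / (Yact^xi + Sigma^xi)` for
#' `Sigma > 0` and `Y = 0` otherwise. The clamp at non-positive `Sigma`
#' gives the negative-weight (immune-suppressive) regime a meaningful zero
#' production rate; with odd `xi` the raw power would be negative.
#'
#' @param w perceptron weights.
#' @param X antigen signals (same length).
#' @param Yact activation level (> 0).
#' @param xi positive integer power (default 9).
#' @return response in `[0, 1)`.
#' @export
perceptron_response <- function(w, X, Yact, xi = 9L) {
  Sigma <- sum(w * X)
  if (Sigma <= 0) return(0)
  Sigma^xi / (Yact^xi + Sigma^xi)
}

#' Perceptron weight learning rule
#'
#' Continuous-time delta rule: each weight moves proportionally to the
#' mismatch between danger signal and current response, gated by its antigen
#' input: `dw_i/dt = a * (D - Y) * X_i`. Weights are unbounded and may turn
#' negative during host regrowth (immune suppression).
#'
#' @param D danger signal.
#' @param Y perceptron response.
#' @param X antigen signals.
#' @param a learning rate (d^-1).
#' @return derivative vector `dw/dt`.
#' @export
weight_rhs <- function(D, Y, X, a) {
  a * (D - Y) * X
}

#' Effector-population match coefficients
#'
#' Dot product of the effector vector with each population's binary antigen
#' pattern column (`P` transposed times `I`). A population is attacked in proportion to
#' the summed effector mass specific for the components it bears.
#'
#' @param I effector populations (length = number of components).
#' @param topology an `ite_topology`.
#' @return list with `r_clones` (per sub-clone) and `r_host`.
#' @export
match_coefficients <- function(I, topology) {
  stopifnot(length(I) == topology$n_components)
  r <- as.numeric(crossprod(topology$P, I))
  list(r_clones = r[seq_len(topology$n_clones)],
       r_host = r[topology$n_clones + 1L])
}

#' Effector-cell dynamics
#'
#' Production driven by the perceptron response gated by each component's
#' antigen signal (`kI * Y * X_n`), first-order elimination plus
#' radiation kill through the effector TBDE
#' (`(keI + (alphaI + 2 betaI GammaI) R) I_n`), and consumption by the
#' immunogenic elimination events the effectors mediate. By default the
#' consumption is `kIT * I_n * sum(T over clones bearing n)`, the
#' component-n share of the total matched kill (exact decomposition of
#' `sum r_ik T_ik` since `r_ik = sum_n I_n P[n, ik]`); set
#' `per_effector = FALSE` for the literal matched-total variant
#' `kIT * sum(r_ik T_ik over clones bearing n)`.
#'
#' @param I effector populations.
#' @param T_clones living tumor sub-clone populations.
#' @param topology an `ite_topology`.
#' @param Y perceptron response.
#' @param X antigen signals.
#' @param kI effector production/migration rate (possibly HT-raised).
#' @param keI effector elimination rate.
#' @param alphaI,betaI effector radio-sensitivity (Gy^-1, Gy^-2).
#' @param GammaI effector TBDE (Gy).
#' @param R dose rate (Gy/d).
#' @param kIT immunogenic tumor elimination rate.
#' @param per_effector logical; consumption variant (see Details).
#' @return derivative vector `dI/dt`.
#' @export
effector_rhs <- function(I, T_clones, topology, Y, X, kI, keI,
                         alphaI, betaI, GammaI, R, kIT,
                         per_effector = TRUE) {
  Pt <- topology$P[, seq_len(topology$n_clones), drop = FALSE]
  if (per_effector) {
    consume <- kIT * I * as.numeric(Pt %*% T_clones)
  } else {
    r <- as.numeric(crossprod(Pt, I))
    consume <- kIT * as.numeric(Pt %*% (r * T_clones))
  }
  kI * Y * X - (keI + (alphaI + 2 * betaI * GammaI) * R) * I - consume
}
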