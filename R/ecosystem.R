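#' Tumor and host population dynamics
#'
#' Right-hand side of the living-population equations. Each sub-clone grows
#' at `kT`, loses cells to baseline elimination `keT`, immune kill
#' `r_ik * kIT`, host interaction `kHT * H`, competition with the total
#' tumor burden `kTT * T`, and radiation kill `(alphaT + 2 betaT Gamma) R`
#' under the dynamic linear-quadratic law. Mutation moves mass along the
#' tree: the founder clone loses `kmut * T11` and every non-founder clone
#' gains `kmut * q[i, l] * T_l` from its parent. The host follows the same
#' structure with growth `kaH`, self-inhibition `kbH * H^2`, tumor
#' competition `kTH * T` and its own radio-sensitivity.
#'
#' @param T_clones living sub-clone populations.
#' @param H host population.
#' @param params parameter list; `alphaT`/`betaT` are used as supplied, so a
#'   hyperthermia-modified snapshot can be passed directly.
#' @param topology an `ite_topology`.
#' @param R dose rate (Gy/d).
#' @param GammaT,GammaH transient biological dose equivalents (Gy).
#' @param r_clones,r_host immune match coefficients (from
#'   [match_coefficients()]).
#' @param mut_outflow_all logical; when `TRUE` every clone with descendants
#'   loses `kmut * T`, instead of the literal founder-only outflow.
#' @return list with `dT` (vector) and `dH`.
#' @export
tumor_host_rhs <- function(T_clones, H, params, topology, R = 0,
                           GammaT = 0, GammaH = 0,
                           r_clones = rep(0, topology$n_clones), r_host = 0,
                           mut_outflow_all = FALSE) {
  stopifnot(length(T_clones) == topology$n_clones,
            length(r_clones) == topology$n_clones)
  Ttot <- sum(T_clones)
  radT <- (params$alphaT + 2 * params$betaT * GammaT) * R
  radH <- (params$alphaH + 2 * params$betaH * GammaH) * R
  grow <- params$kT - params$keT - r_clones * params$kIT -
    params$kHT * H - params$kTT * Ttot - radT
  dT <- grow * T_clones + params$kmut * as.numeric(topology$q %*% T_clones)
  if (mut_outflow_all) {
    dT <- dT - params$kmut * (topology$has_child == 1) * T_clones
  } else {
    dT[1] <- dT[1] - params$kmut * T_clones[1]
  }
  dH <- (params$kaH - params$keH - r_host * params$kIH -
           params$kbH * H - params$kTH * Ttot - radH) * H
  list(dT = dT, dH = dH)
}

#' Dead-cell compartment dynamics
#'
#' Two-step transformation of eliminated cells into danger-signal sources.
#' The inflow into each pre-immune-stimulatory pool `Np` is exactly the
#' elimination outflow of the corresponding living population — baseline
#' death, immune kill and radiation kill; growth, mutation and competition
#' terms do not feed `Np`. `Np` transforms into the immune-stimulatory pool
#' `N` at `kpn`; the host `Np` additionally drains through the
#' non-immune-stimulatory (silently apoptotic) pathway `kap`. `N` is
#' cleared at `kn`.
#'
#' @inheritParams tumor_host_rhs
#' @param Np,NpH pre-immune-stimulatory pools (clones, host).
#' @param N,NH immune-stimulatory pools (clones, host).
#' @return list with `dNp`, `dNpH`, `dN`, `dNH`, and `inflow`
#'   (the per-clone elimination inflow, exposed for mass-flow checks).
#' @export
deadcell_rhs <- function(T_clones, H, Np, NpH, N, NH, params, topology,
                         R = 0, GammaT = 0, GammaH = 0,
                         r_clones = rep(0, topology$n_clones), r_host = 0) {
  radT <- (params$alphaT + 2 * params$betaT * GammaT) * R
  radH <- (params$alphaH + 2 * params$betaH * GammaH) * R
  inflow <- (params$keT + r_clones * params$kIT + radT) * T_clones
  inflowH <- (params$keH + r_host * params$kIH + radH) * H
  list(dNp = inflow - params$kpn * Np,
       dNpH = inflowH - (params$kpn + params$kap) * NpH,
       dN = params$kpn * Np - params$kn * N,
       dNH = params$kpn * NpH - params$kn * NH,
       inflow = c(inflow, inflowH))
}
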