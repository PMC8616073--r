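#' Default model parameterization
#'
#' Returns the full rate-constant set of the immune-tumor ecosystem model:
#' ecosystem interaction rates, pattern-recognition (perceptron) parameters,
#' radiobiological coefficients of the dynamic linear-quadratic model, and
#' the hyperthermia kinetic rates. Populations are normalized to 1e9 cells
#' and all rates are per day; the beam-on dose rate is stored both as
#' entered (Gy/min) and converted once to Gy/d (`R0`).
#'
#' The defaults describe a fast-growing tumor (volume doubling time
#' ~20 days), a host compartment with homeostatic equilibrium
#' `(kaH - keH)/kbH` of about 250 (2.5e11 cells), and a tumor carrying
#' capacity without immune elimination of `(kT - keT)/kTT = 306`.
#'
#' @param dose_rate_gy_min beam-on dose rate in Gy per minute (default 0.14).
#' @return A named list of class `ite_params`.
#' @export
#' @examples
#' p <- default_parameters()
#' equilibrium_levels(p)
default_parameters <- function(dose_rate_gy_min = 0.14) {
  p <- list(
    # ecosystem interactions (d^-1)
    kT   = 3.46e-2,  # tumor growth rate constant (all sub-clones)
    kmut = 1e-3,     # mutation rate constant
    keT  = 4e-3,     # tumor cell elimination (non-immune, non-radiation)
    kTT  = 1e-4,     # tumor growth inhibition (competition, total burden)
    kIT  = 1,        # immunogenic tumor cell elimination
    kHT  = 1e-5,     # host -> tumor interaction
    kTH  = 2.2e-4,   # tumor -> host interaction
    kaH  = 3e-2,     # host cell growth
    kbH  = 1.2e-4,   # host growth self-inhibition
    keH  = 1e-5,     # host cell elimination
    kpn  = 0.5,      # damaged -> immune-stimulatory transformation
    kn   = 5,        # immune-stimulatory cell clearance
    kap  = 2,        # non-immune-stimulatory (apoptotic) host clearance
    kIH  = 1,        # immunogenic host cell elimination
    kI   = 10,       # effector production and migration (HT-susceptible)
    keI  = 1,        # effector elimination
    # pattern recognition / perceptron
    Yact = 3,        # perceptron activation level
    xi   = 9L,       # power of the perceptron response function
    Xact = 2,        # antigen recognition level (HT-susceptible)
    eta  = 0.5,      # antigen weight of pre-immune-stimulatory cells
    chi  = 0.2,      # antigen weight of immune-stimulatory cells
    Lact = 3,        # danger-signal activation level (HT-susceptible)
    a    = 5,        # perceptron learning rate (d^-1)
    # dynamic linear-quadratic radiobiology
    alphaT = 0.28,   # Gy^-1, tumor (HT-susceptible)
    betaT  = 0.05,   # Gy^-2, tumor (HT-susceptible)
    alphaH = 0.05,   # Gy^-1, host
    betaH  = 0.01,   # Gy^-2, host
    alphaI = 0.1,    # Gy^-1, effector cells
    betaI  = 0.01,   # Gy^-2, effector cells
    gammaT = 3,      # d^-1, tumor repair constant
    gammaH = 10,     # d^-1, host repair constant
    gammaI = 2,      # d^-1, effector repair/replacement constant
    dose_rate_gy_min = dose_rate_gy_min,
    R0 = dose_rate_gy_min * 1440,   # Gy/d, used internally
    # hyperthermia sub-models
    kperf1 = 200,    # d^-1, perfusion activation (kperf1/kperf2 = 1)
    kperf2 = 200,    # d^-1, perfusion relaxation
    kims1  = 7,      # d^-1, immune-stimulation activation (kims1/kims2 = 1)
    kims2  = 7,      # d^-1, immune-stimulation relaxation
    alphaT_factor = 1.96,  # alphaT multiplier for HT-paired fractions (42 C)
    betaT_factor  = 0.34   # betaT multiplier for HT-paired fractions (42 C)
  )
  structure(p, class = "ite_params")
}

#' Validate a parameter set
#'
#' Checks the model invariants and returns a character vector of violations
#' (empty when the set is valid). Violations are reported, not raised, so a
#' caller can collect them across a configuration.
#'
#' Checked: all rate constants non-negative; `gammaI > keI` (the effector
#' repair/replacement constant must exceed the effector elimination rate,
#' since replacement of irradiated effectors is part of the "repair");
#' `xi` a positive integer; `eta`, `chi` in `[0, 1]`; positive activation
#' levels; positive hyperthermia factors.
#'
#' @param params a parameter list as from [default_parameters()].
#' @return character vector of violation messages (length 0 when valid).
#' @export
validate_parameters <- function(params) {
  v <- character()
  rates <- c("kT", "kmut", "keT", "kTT", "kIT", "kHT", "kTH", "kaH", "kbH",
             "keH", "kpn", "kn", "kap", "kIH", "kI", "keI", "a",
             "alphaT", "betaT", "alphaH", "betaH", "alphaI", "betaI",
             "gammaT", "gammaH", "gammaI", "R0",
             "kperf1", "kperf2", "kims1", "kims2")
  for (r in rates) {
    val <- params[[r]]
    if (is.null(val) || !is.finite(val)) {
      v <- c(v, sprintf("%s is missing or non-finite", r))
    } else if (val < 0) {
      v <- c(v, sprintf("%s is negative (%g)", r, val))
    }
  }
  if (!is.null(params$gammaI) && !is.null(params$keI) &&
      is.finite(params$gammaI) && is.finite(params$keI) &&
      params$gammaI <= params$keI) {
    v <- c(v, sprintf("gammaI <= keI (%g <= %g): effector TBDE repair must exceed effector elimination",
                      params$gammaI, params$keI))
  }
  xi <- params$xi
  if (is.null(xi) || length(xi) != 1L || !is.finite(xi) || xi <= 0 ||
      xi != round(xi)) {
    v <- c(v, "xi must be a positive integer")
  }
  for (nm in c("eta", "chi")) {
    val <- params[[nm]]
    if (is.null(val) || !is.finite(val) || val < 0 || val > 1)
      v <- c(v, sprintf("%s must lie in [0, 1]", nm))
  }
  for (nm in c("Yact", "Xact", "Lact")) {
    val <- params[[nm]]
    if (is.null(val) || !is.finite(val) || val <= 0)
      v <- c(v, sprintf("%s must be positive", nm))
  }
  for (nm in c("alphaT_factor", "betaT_factor")) {
    val <- params[[nm]]
    if (is.null(val) || !is.finite(val) || val <= 0)
      v <- c(v, sprintf("%s must be positive", nm))
  }
  v
}

#' Analytic equilibrium levels
#'
#' Tumor and host equilibria of the competition system in the absence of
#' immunogenic elimination and treatment: `Teq = (kT - keT)/kTT` and
#' `Heq = (kaH - keH)/kbH`.
#'
#' @inheritParams validate_parameters
#' @return named numeric vector with elements `Teq` and `Heq`
#'   (units of 1e9 cells).
#' @export
#' @examples
#' equilibrium_levels(default_parameters())  # Teq = 306, Heq = 249.9167
equilibrium_levels <- function(params) {
  if (params$kTT == 0 || params$kbH == 0)
    stop("equilibrium undefined: kTT and kbH must be non-zero")
  c(Teq = (params$kT - params$keT) / params$kTT,
    Heq = (params$kaH - params$keH) / params$kbH)
}

#' @export
print.ite_params <- function(x, ...) {
  cat("<ite_params> immune-tumor ecosystem parameter set\n")
  cat(sprintf("  tumor: kT = %g/d, keT = %g/d, kTT = %g/d (Teq = %g)\n",
              x$kT, x$keT, x$kTT, (x$kT - x$keT) / x$kTT))
  cat(sprintf("  host:  kaH = %g/d, keH = %g/d, kbH = %g/d (Heq = %g)\n",
              x$kaH, x$keH, x$kbH, (x$kaH - x$keH) / x$kbH))
  cat(sprintf("  LQ: alphaT = %g/Gy, betaT = %g/Gy^2, gammaT = %g/d, R0 = %g Gy/d\n",
              x$alphaT, x$betaT, x$gammaT, x$R0))
  cat(sprintf("  perceptron: Yact = %g, xi = %d, Xact = %g, Lact = %g, a = %g/d\n",
              x$Yact, x$xi, x$Xact, x$Lact, x$a))
  invisible(x)
}
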