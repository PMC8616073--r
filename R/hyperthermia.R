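#' Build a hyperthermia session schedule
#'
#' Sessions are 60 min at 42 degrees C, ending a fixed gap (default 30 min)
#' before their paired radiotherapy fraction. The named protocols pair
#' sessions with fractions of the given RT schedule:
#' \describe{
#'   \item{HT0}{no sessions.}
#'   \item{HT1}{4 sessions, one per week (fractions 1, 6, 11, 16) — the
#'     sparsest protocol.}
#'   \item{HT2}{10 sessions paired with the first 10 fractions — the
#'     front-loaded (HYCAN-trial-like) protocol, concentrating heating in
#'     the first treatment days.}
#'   \item{HT3}{10 sessions, two per week over five weeks (fractions 1, 3
#'     of each week) — the spread (KSA-bladder-trial-like) protocol.}
#' }
#' Explicit `session_starts` override the protocol.
#'
#' @param protocol `"HT0"`, `"HT1"`, `"HT2"` or `"HT3"`.
#' @param rt_schedule an `ite_rt_schedule`; needed to place sessions
#'   gap-before their paired fractions.
#' @param duration_min session duration in minutes (default 60).
#' @param gap_min gap between session end and fraction start (default 30).
#' @param session_starts optional explicit session start times (d).
#' @return object of class `ite_ht_schedule`: list with `sessions` (tibble:
#'   `start`, `duration` in days) and `protocol`.
#' @export
#' @examples
#' rt <- build_rt_schedule("RT1")
#' ht <- build_ht_schedule("HT2", rt)
#' nrow(ht$sessions)
build_ht_schedule <- function(protocol = c("HT0", "HT1", "HT2", "HT3"),
                              rt_schedule = NULL,
                              duration_min = 60, gap_min = 30,
                              session_starts = NULL) {
  duration <- duration_min / 1440
  gap <- gap_min / 1440
  if (is.null(session_starts)) {
    protocol <- match.arg(protocol)
    paired <- switch(protocol,
      HT0 = integer(0),
      HT1 = c(1L, 6L, 11L, 16L),
      HT2 = 1:10,
      HT3 = c(1L, 3L, 6L, 8L, 11L, 13L, 16L, 18L, 21L, 23L))
    if (length(paired)) {
      if (is.null(rt_schedule))
        stop("rt_schedule required to place protocol sessions")
      if (max(paired) > nrow(rt_schedule$fractions))
        stop("protocol pairs sessions with fractions beyond the RT schedule")
      session_starts <- rt_schedule$fractions$start[paired] - gap - duration
    } else {
      session_starts <- numeric(0)
    }
  } else {
    protocol <- if (is.character(protocol) && length(protocol) == 1L &&
                    protocol %in% c("HT0", "HT1", "HT2", "HT3")) protocol
                else "custom"
    session_starts <- sort(as.numeric(session_starts))
  }
  structure(list(
    sessions = tibble::tibble(
      start = session_starts,
      duration = rep(duration, length(session_starts))
    ),
    protocol = protocol,
    gap = gap
  ), class = "ite_ht_schedule")
}

#' Perfusion kinetics (fast hyperthermia process)
#'
#' First-order activation of the perfusion state during heating:
#' `dtheta/dt = kperf1 - kperf2 * theta` with heating on, pure relaxation
#' `-kperf2 * theta` otherwise. With `kperf1/kperf2 = 1` the fixed point
#' under sustained heating is `theta = 1`, i.e. a perfusion enhancement
#' factor `PEF = 1 + theta` of 2; the default rates (200/d, time constant
#' 7.2 min) reach it within a session and relax back within ~30 min.
#'
#' @param theta perfusion state in `[0, 1]`.
#' @param heating_on logical.
#' @param kperf1,kperf2 activation/relaxation rates (d^-1).
#' @return `dtheta/dt`.
#' @export
perfusion_rhs <- function(theta, heating_on, kperf1 = 200, kperf2 = 200) {
  (if (heating_on) kperf1 else 0) - kperf2 * theta
}

#' Immune-stimulation kinetics (slow hyperthermia process)
#'
#' Same first-order structure as the perfusion model but with slow rates
#' (7/d): `dphi/dt = kims1 - kims2 * phi` while the stimulation window is
#' open, pure decay otherwise. The window opens one day after a session
#' starts and stays open for 24 h, so the immune stimulation factor
#' `ISF = 1 + phi` peaks near 2 about 48 h after heating and returns to
#' baseline by ~72 h (antigen-presentation-like long-term effect).
#'
#' @param phi immune-stimulation state in `[0, 1]`.
#' @param window_on logical.
#' @param kims1,kims2 activation/relaxation rates (d^-1).
#' @return `dphi/dt`.
#' @export
ims_rhs <- function(phi, window_on, kims1 = 7, kims2 = 7) {
  (if (window_on) kims1 else 0) - kims2 * phi
}

#' Hyperthermia modification flags
#'
#' Selects which HT-susceptible parameters are modified and, for `Xact` and
#' `Lact`, whether they follow the slow (ISF) or fast (PEF) process.
#' `set = "all"` enables every modification; `"alpha_beta"` only the
#' radio-sensitization of HT-paired fractions; the other named sets add one
#' immune-side modification each, matching the protocol grid columns.
#'
#' @param set one of `"none"`, `"alpha_beta"`, `"alpha_beta_kI"`,
#'   `"alpha_beta_Xact"`, `"alpha_beta_Lact"`, `"all"`.
#' @param mode `"slow"` (ISF) or `"fast"` (PEF) process for `Xact`/`Lact`.
#' @return named logical list used by [simulate_ecosystem()].
#' @export
ht_flags <- function(set = c("all", "none", "alpha_beta", "alpha_beta_kI",
                             "alpha_beta_Xact", "alpha_beta_Lact"),
                     mode = c("slow", "fast")) {
  set <- match.arg(set)
  mode <- match.arg(mode)
  fast <- mode == "fast"
  list(
    alpha_beta = set != "none",
    kI = set %in% c("alpha_beta_kI", "all"),
    Xact = set %in% c("alpha_beta_Xact", "all"),
    Lact = set %in% c("alpha_beta_Lact", "all"),
    Xact_fast = fast,
    Lact_fast = fast,
    consume_per_effector = TRUE,
    mut_outflow_all = FALSE
  )
}

#' Hyperthermia-effective parameter snapshot
#'
#' Pure function of the base parameters, the hyperthermia state and the
#' flag set; repeated application never compounds. `alphaT`/`betaT` are
#' multiplied by the fixed 42-degree sensitization factors (1.96, 0.34)
#' only during beam-on of an HT-paired fraction; `kI` is scaled by the
#' perfusion enhancement factor continuously; `Xact` and `Lact` are divided
#' by ISF (slow) or PEF (fast) per their mode flags.
#'
#' @param base parameter list ([default_parameters()]).
#' @param theta perfusion state.
#' @param phi immune-stimulation state.
#' @param flags flag list from [ht_flags()].
#' @param fraction_is_ht_paired logical; is the current beam-on window an
#'   HT-paired fraction?
#' @return named list with `alphaT`, `betaT`, `kI`, `Xact`, `Lact`.
#' @export
#' @examples
#' p <- default_parameters()
#' effective_parameters(p, theta = 1, phi = 0, ht_flags("all"), TRUE)
effective_parameters <- function(base, theta, phi, flags,
                                 fraction_is_ht_paired = FALSE) {
  PEF <- 1 + theta
  ISF <- 1 + phi
  list(
    alphaT = if (isTRUE(flags$alpha_beta) && fraction_is_ht_paired)
      base$alphaT_factor * base$alphaT else base$alphaT,
    betaT = if (isTRUE(flags$alpha_beta) && fraction_is_ht_paired)
      base$betaT_factor * base$betaT else base$betaT,
    kI = if (isTRUE(flags$kI)) base$kI * PEF else base$kI,
    Xact = if (isTRUE(flags$Xact))
      base$Xact / (if (isTRUE(flags$Xact_fast)) PEF else ISF) else base$Xact,
    Lact = if (isTRUE(flags$Lact))
      base$Lact / (if (isTRUE(flags$Lact_fast)) PEF else ISF) else base$Lact
  )
}
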