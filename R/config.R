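#' Load a simulation configuration file
#'
#' Reads a YAML configuration with optional sections `parameters`,
#' `topology`, `schedule`, `ht` and `engine`, fills in every default, and
#' returns fully built objects ready for [simulate_ecosystem()]. Unknown
#' sections or keys are rejected by name so typos cannot silently fall back
#' to defaults. An empty file yields the full default configuration
#' (default parameters, default topology, RT1 with no hyperthermia).
#'
#' Recognized keys:
#' \describe{
#'   \item{parameters}{any field of [default_parameters()]
#'     (`dose_rate_gy_min` re-derives `R0`).}
#'   \item{topology}{`n_components` + `populations`
#'     (see [topology_from_list()]).}
#'   \item{schedule}{`scheme`, `start_day`, `n_fractions`, `dose`,
#'     `fraction_days`.}
#'   \item{ht}{`protocol`, `session_starts`, `duration_min`, `gap_min`,
#'     `flag_set`, `mode`.}
#'   \item{engine}{`t_end`, `dt`, `rt_start`, `record_stride`, `T11`, `H0`.}
#' }
#'
#' @param path file path; `NULL` or a missing/empty file gives defaults.
#' @return named list (`params`, `topology`, `rt`, `ht`, `flags`, `engine`).
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("parameters", "topology", "schedule", "ht", "engine")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))

  pc <- cfg$parameters %||% list()
  params <- default_parameters()
  bad <- setdiff(names(pc), names(params))
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  for (k in names(pc)) params[[k]] <- pc[[k]]
  if (!is.null(pc$dose_rate_gy_min) && is.null(pc$R0))
    params$R0 <- params$dose_rate_gy_min * 1440
  if (!is.null(pc$xi)) params$xi <- as.integer(params$xi)
  viol <- validate_parameters(params)
  if (length(viol))
    stop("invalid parameters: ", paste(viol, collapse = "; "))

  topology <- if (is.null(cfg$topology)) default_topology()
              else topology_from_list(cfg$topology)

  sc <- cfg$schedule %||% list()
  bad <- setdiff(names(sc), c("scheme", "start_day", "n_fractions", "dose",
                              "fraction_days"))
  if (length(bad))
    stop("unknown schedule key(s): ", paste(bad, collapse = ", "))
  rt <- build_rt_schedule(scheme = sc$scheme %||% "RT1",
                          start_day = sc$start_day %||% 570,
                          n_fractions = sc$n_fractions %||% 32,
                          dose = sc$dose %||% 2,
                          dose_rate_gy_min = params$dose_rate_gy_min,
                          fraction_days = sc$fraction_days)

  hc <- cfg$ht %||% list()
  bad <- setdiff(names(hc), c("protocol", "session_starts", "duration_min",
                              "gap_min", "flag_set", "mode"))
  if (length(bad))
    stop("unknown ht key(s): ", paste(bad, collapse = ", "))
  ht <- build_ht_schedule(protocol = hc$protocol %||% "HT0",
                          rt_schedule = rt,
                          duration_min = hc$duration_min %||% 60,
                          gap_min = hc$gap_min %||% 30,
                          session_starts = hc$session_starts)
  default_set <- if (nrow(ht$sessions) == 0L) "none" else "all"
  flags <- ht_flags(hc$flag_set %||% default_set, hc$mode %||% "slow")

  ec <- cfg$engine %||% list()
  bad <- setdiff(names(ec), c("t_end", "dt", "rt_start", "record_stride",
                              "T11", "H0"))
  if (length(bad))
    stop("unknown engine key(s): ", paste(bad, collapse = ", "))
  engine <- list(t_end = ec$t_end %||% 1800,
                 dt = ec$dt %||% 1e-3,
                 rt_start = ec$rt_start %||% 570,
                 record_stride = ec$record_stride %||% 100L,
                 T11 = ec$T11 %||% 1e-2,
                 H0 = ec$H0)

  list(params = params, topology = topology, rt = rt, ht = ht,
       flags = flags, engine = engine)
}

#' Run a simulation from a configuration
#'
#' @param config list as returned by [load_config()].
#' @return an `ite_sim` object.
#' @export
run_config <- function(config) {
  init <- initial_state(config$params, config$topology,
                        T11 = config$engine$T11, H = config$engine$H0)
  simulate_ecosystem(config$params, config$topology, config$rt, config$ht,
                     config$flags,
                     t_end = config$engine$t_end, dt = config$engine$dt,
                     rt_start = config$engine$rt_start, init = init,
                     record_stride = config$engine$record_stride)
}

#' Serialize a parameter set to YAML and back
#'
#' Round-trip helpers used for reproducible configs; reloading yields
#' bit-identical values.
#'
#' @param params parameter list.
#' @param path output file.
#' @return `write_parameters` the path invisibly; `read_parameters` the
#'   parameter list.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(lapply(unclass(params), identity), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  p <- yaml::read_yaml(path)
  p$xi <- as.integer(p$xi)
  structure(p, class = "ite_params")
}

#' Write simulation outputs
#'
#' Writes `trajectory.csv` (one row per recorded time point, all state
#' variables and derived signals), `summary.json` (TCP at full precision
#' and rounded to 3 decimals, nadir, dose bookkeeping, protocol echo) and
#' `events.log` (the realized beam/heating/stimulation timeline) into a
#' directory.
#'
#' @param sim an `ite_sim`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj_path <- file.path(dir, "trajectory.csv")
  utils::write.csv(sim$trajectory, traj_path, row.names = FALSE)
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    tcp = sim$summary$tcp,
    tcp_rounded = round(sim$summary$tcp, 3),
    t_min = sim$summary$t_min,
    t_min_time = sim$summary$t_min_time,
    dose_delivered = sim$summary$dose_delivered,
    clipped_mass = sim$summary$clipped_mass,
    scheme = sim$rt$scheme,
    ht_protocol = sim$ht$protocol,
    n_fractions = nrow(sim$rt$fractions),
    n_ht_sessions = nrow(sim$ht$sessions),
    flags = sim$flags,
    t_end = sim$t_end, dt = sim$dt, rt_start = sim$rt_start
  ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_path <- file.path(dir, "events.log")
  ev <- character()
  fr <- sim$rt$fractions
  for (i in seq_len(nrow(fr)))
    ev <- c(ev, sprintf("beam  on %.6f off %.6f dose %.3f Gy",
                        fr$start[i], fr$start[i] + fr$duration[i], fr$dose[i]))
  ss <- sim$ht$sessions
  for (i in seq_len(nrow(ss))) {
    ev <- c(ev, sprintf("heat  on %.6f off %.6f", ss$start[i],
                        ss$start[i] + ss$duration[i]),
            sprintf("ims   on %.6f off %.6f", ss$start[i] + 1,
                    ss$start[i] + 2))
  }
  writeLines(ev[order(as.numeric(sub(".*on ([0-9.]+) .*", "\\1", ev)))],
             log_path)
  invisible(c(traj_path, summary_path, log_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
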