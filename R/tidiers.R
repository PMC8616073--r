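#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation trajectory
#'
#' Long-format trajectory: one row per recorded time point and variable,
#' with the variable's compartment class (`tumor`, `host`, `damaged`,
#' `necrotic`, `effector`, `weight`, `tbde`, `ht_state`, `signal`).
#'
#' @param x an `ite_sim`.
#' @param ... unused.
#' @return tibble with columns `time`, `variable`, `class`, `value`.
#' @method tidy ite_sim
#' @export
tidy.ite_sim <- function(x, ...) {
  nc <- x$topology$n_clones
  lab <- x$topology$labels[seq_len(nc)]
  class_of <- c(
    stats::setNames(rep("tumor", nc), lab), H = "host",
    stats::setNames(rep("damaged", nc + 1), c(paste0("Np_", lab), "Np_H")),
    stats::setNames(rep("necrotic", nc + 1), c(paste0("N_", lab), "N_H")),
    stats::setNames(rep("effector", 9), paste0("I", 1:9)),
    stats::setNames(rep("weight", 9), paste0("w", 1:9)),
    GammaT = "tbde", GammaH = "tbde", GammaI = "tbde",
    theta = "ht_state", phi = "ht_state",
    D = "signal", Sigma = "signal", Y = "signal",
    stats::setNames(rep("signal", 9), paste0("X", 1:9)),
    PEF = "signal", ISF = "signal", T_total = "tumor", R = "signal")
  tidyr::pivot_longer(x$trajectory, -"time", names_to = "variable",
                      values_to = "value") |>
    dplyr::mutate(class = unname(class_of[.data$variable]),
                  .after = "variable")
}

#' One-row simulation summary
#'
#' @param x an `ite_sim`.
#' @param ... unused.
#' @return tibble with the protocol, TCP, nadir and dose bookkeeping.
#' @method glance ite_sim
#' @export
glance.ite_sim <- function(x, ...) {
  tibble::tibble(
    scheme = x$rt$scheme,
    ht_protocol = x$ht$protocol,
    n_fractions = nrow(x$rt$fractions),
    n_ht_sessions = nrow(x$ht$sessions),
    dose_delivered = x$summary$dose_delivered,
    tcp = x$summary$tcp,
    t_min = x$summary$t_min,
    t_min_time = x$summary$t_min_time,
    clipped_mass = x$summary$clipped_mass
  )
}

#' Plot a simulation
#'
#' `what = "populations"` shows total tumor and host burden on a log scale;
#' `"effectors"` the nine effector populations; `"signals"` the danger
#' signal, perceptron response and hyperthermia factors.
#'
#' @param object an `ite_sim`.
#' @param what panel selection.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ite_sim
#' @export
autoplot.ite_sim <- function(object, what = c("populations", "effectors",
                                              "signals"), ...) {
  what <- match.arg(what)
  tr <- object$trajectory
  if (what == "populations") {
    d <- tidyr::pivot_longer(tr[, c("time", "T_total", "H")], -"time")
    ggplot2::ggplot(d, ggplot2::aes(.data$time, pmax(.data$value, 1e-12),
                                    colour = .data$name)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time [d]", y = "population [1e9 cells]",
                    colour = NULL)
  } else if (what == "effectors") {
    d <- tidyr::pivot_longer(tr[, c("time", paste0("I", 1:9))], -"time")
    ggplot2::ggplot(d, ggplot2::aes(.data$time, pmax(.data$value, 1e-12),
                                    colour = .data$name)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time [d]", y = "effector cells [1e9]",
                    colour = NULL)
  } else {
    d <- tidyr::pivot_longer(tr[, c("time", "D", "Y", "PEF", "ISF")], -"time")
    ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~name, scales = "free_y") +
      ggplot2::labs(x = "time [d]", y = NULL)
  }
}

#' @rdname autoplot.ite_sim
#' @param x an `ite_sim`.
#' @export
plot.ite_sim <- function(x, what = "populations", ...) {
  print(autoplot(x, what = what, ...))
}
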