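#' Run the protocol x modification grid
#'
#' Executes every combination of fractionation scheme (RT1, RT2),
#' hyperthermia protocol (HT0-HT3) and hyperthermia modification column
#' (alpha/beta only, plus kI, plus Xact, plus Lact, all) and collects the
#' TCPs into a long tibble. HT0 protocols are run once (no hyperthermia to
#' modify); the remaining columns are marked `"no HT"` by [format_grid()].
#' A failing cell is recorded with its error message and does not abort the
#' grid.
#'
#' @param protocols character vector of `RTxHTy` names; default all 8.
#' @param flag_sets modification columns; default the five grid columns.
#' @param mode `"slow"` or `"fast"` process for `Xact`/`Lact`.
#' @param ... passed to [simulate_ecosystem()] (e.g. `dt`, `t_end`).
#' @return tibble with columns `protocol`, `flag_set`, `mode`, `tcp`,
#'   `t_min`, `error`.
#' @export
run_protocol_grid <- function(protocols = paste0("RT", rep(1:2, each = 4),
                                                 "HT", rep(0:3, 2)),
                              flag_sets = c("alpha_beta", "alpha_beta_kI",
                                            "alpha_beta_Xact",
                                            "alpha_beta_Lact", "all"),
                              mode = "slow", ...) {
  cells <- tidyr::expand_grid(protocol = protocols, flag_set = flag_sets)
  # HT0 rows collapse to a single run
  cells <- cells[!(grepl("HT0$", cells$protocol) &
                     cells$flag_set != flag_sets[1]), ]
  run_cell <- function(protocol, flag_set) {
    fs <- if (grepl("HT0$", protocol)) "none" else flag_set
    tryCatch({
      sim <- simulate_protocol(protocol, flag_set = fs, mode = mode, ...)
      tibble::tibble(tcp = sim$summary$tcp, t_min = sim$summary$t_min,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(tcp = NA_real_, t_min = NA_real_,
                     error = conditionMessage(e))
    })
  }
  res <- purrr::pmap(cells, run_cell)
  dplyr::bind_cols(cells, dplyr::bind_rows(res),
                   tibble::tibble(mode = rep(mode, nrow(cells)))) |>
    dplyr::select("protocol", "flag_set", "mode", "tcp", "t_min", "error")
}

#' Format a protocol grid as a wide table
#'
#' Pivots the long grid from [run_protocol_grid()] into the wide
#' protocol-by-column layout, printing TCPs to three decimals and marking
#' inapplicable hyperthermia columns of the HT0 rows as `"no HT"`.
#'
#' @param grid tibble from [run_protocol_grid()].
#' @param digits decimals for the printed TCP (default 3).
#' @return wide tibble of character cells, one row per protocol.
#' @export
format_grid <- function(grid, digits = 3) {
  flag_sets <- unique(grid$flag_set)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(grid, cell = ifelse(is.na(.data$tcp), .data$error,
                                      sprintf("%.*f", digits, .data$tcp))),
    id_cols = "protocol", names_from = "flag_set", values_from = "cell")
  for (fs in flag_sets)
    wide[[fs]][is.na(wide[[fs]])] <- "no HT"
  wide
}
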