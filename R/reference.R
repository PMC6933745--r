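#' Published reference benefit-incidence shares
#'
#' Benefit-incidence shares (percent of total public subsidy by MPCE class)
#' for NCD-related inpatient and outpatient care among India's elderly,
#' estimated from the 2014 national health-consumption survey and shipped
#' here as a reference layout. Used to exercise the grouped concentration
#' index on real published shares: the grouped index on these shares with
#' equal 25% class population shares reproduces the sign of the
#' corresponding published micro indices (pro-rich inpatient subsidy in
#' both sectors, pro-poor rural outpatient subsidy).
#'
#' @return Tibble with `service` (IP/OP), `sector` (rural/urban/combine),
#'   `mpce_class` (P/LM/UM/R, poorest to richest) and `share_pct`.
#' @export
reference_benefit_shares <- function() {
  readr::read_csv(
    system.file("extdata", "reference_benefit_shares.csv",
      package = "biatools"
    ),
    col_types = "cccd", progress = FALSE
  )
}

#' Grouped concentration index of a benefit-share table
#'
#' Convenience wrapper: applies [grouped_concentration_index()] with equal
#' class population shares to one (service, sector) column of a
#' benefit-share table such as [reference_benefit_shares()] or the
#' `benefit` component of [run_bia()].
#'
#' @param shares_table Tibble with `service`, `sector`, `mpce_class`,
#'   `share_pct`.
#' @param service,sector Which column to use.
#' @return The grouped concentration index.
#' @export
grouped_index_from_table <- function(shares_table, service, sector) {
  s <- shares_table |>
    dplyr::filter(.data$service == !!service, .data$sector == !!sector) |>
    dplyr::arrange(match(.data$mpce_class, MPCE_LEVELS)) |>
    dplyr::pull("share_pct")
  if (length(s) != 4) {
    abort("grouped_index_from_table(): expected exactly the four MPCE classes.")
  }
  grouped_concentration_index(s / sum(s), rep(0.25, 4))
}
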