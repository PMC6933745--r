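# End-to-end orchestration: from a validated survey dataset to the four
# result tables (utilization shares, mean OOPE, benefit incidence,
# concentration indices) plus curves.

prepare_episode_sets <- function(selection, ip_breaks, op_breaks) {
  ncd <- dplyr::bind_rows(
    add_oope_components(selection$ip_ncd),
    add_oope_components(selection$op_ncd)
  )
  if (nrow(ncd) == 0) {
    abort("No elderly NCD episodes after selection.")
  }
  add_stratum_key(ncd, ip_breaks = ip_breaks, op_breaks = op_breaks)
}

#' Run the full benefit-incidence pipeline
#'
#' Chains MPCE classification, elderly/NCD selection, the descriptive
#' tables, the modal private-cost proxy, net subsidies, benefit-incidence
#' shares and the concentration analysis.
#'
#' @param dataset A validated `survey_dataset`.
#' @param ailment_map From [load_ailment_map()]; defaults to the packaged
#'   map.
#' @param age_min Elderly threshold, inclusive (default 60).
#' @param clamp Clamp negative net subsidies at zero (default `TRUE`).
#' @param min_cell_size,ip_bin,op_bin Passed to [modal_private_cost()].
#' @param ip_breaks,op_breaks Duration-band edges (see [duration_band()]).
#' @param rank,se Passed to [concentration_analysis()].
#' @param B,seed Bootstrap resamples and seed for the concentration bands
#'   (`B = 0` disables bands).
#' @param rate_weighted Passed to [benefit_incidence_shares()].
#' @return A `bia_result` list: `classification`, `selection`,
#'   `utilization`, `oope`, `modal_costs`, `subsidies`, `benefit`,
#'   `concentration` (list of `concentration_result` per service.sector)
#'   and `concentration_summary`.
#' @export
run_bia <- function(dataset,
                    ailment_map = load_ailment_map(),
                    age_min = 60,
                    clamp = TRUE,
                    min_cell_size = 5,
                    ip_bin = 500,
                    op_bin = 50,
                    ip_breaks = c(1, 4, 8, 15),
                    op_breaks = c(0, 15, 31, 91),
                    rank = "continuous",
                    se = "hc1",
                    B = 0,
                    seed = NULL,
                    rate_weighted = TRUE) {
  classification <- classify_mpce(dataset)
  selection <- select_elderly_ncd(
    dataset, classification, ailment_map,
    age_min = age_min
  )
  utilization <- utilization_table(selection)
  oope <- mean_oope_table(selection)

  ncd <- prepare_episode_sets(selection, ip_breaks, op_breaks)
  private <- dplyr::filter(ncd, .data$facility == "private")
  public <- dplyr::filter(ncd, .data$facility == "public")
  if (nrow(public) == 0) {
    abort("run_bia(): no public-facility elderly NCD episodes.")
  }
  modal_costs <- modal_private_cost(
    private,
    keys = dplyr::bind_rows(
      dplyr::select(private, dplyr::all_of(LEVEL_KEYS$full)),
      dplyr::select(public, dplyr::all_of(LEVEL_KEYS$full))
    ),
    min_cell_size = min_cell_size, ip_bin = ip_bin, op_bin = op_bin
  )
  subsidies <- net_subsidy(public, modal_costs, clamp = clamp)
  rates <- utilization_rates(subsidies)
  benefit <- benefit_incidence_shares(
    subsidies, rates,
    rate_weighted = rate_weighted
  )

  groups <- subsidies |>
    with_combine_sector() |>
    dplyr::group_by(.data$service, .data$sector)
  keys <- dplyr::group_keys(groups)
  concentration <- dplyr::group_split(groups) |>
    setNames(paste(keys$service, keys$sector, sep = ".")) |>
    lapply(function(df) {
      concentration_analysis(df, rank = rank, se = se, B = B, seed = seed)
    })

  structure(
    list(
      classification = classification,
      selection = selection,
      utilization = utilization,
      oope = oope,
      modal_costs = modal_costs,
      subsidies = subsidies,
      benefit = benefit,
      concentration = concentration,
      concentration_summary = concentration_table(concentration)
    ),
    class = "bia_result"
  )
}

#' @export
print.bia_result <- function(x, ...) {
  cat("<bia_result>\n")
  cat("Benefit-incidence shares (%):\n")
  print(
    x$benefit |>
      dplyr::select("service", "sector", "mpce_class", "share_pct") |>
      tidyr::pivot_wider(
        names_from = "mpce_class", values_from = "share_pct"
      ),
    n = 12
  )
  cat("\nConcentration indices:\n")
  print(x$concentration_summary, n = 6)
  invisible(x)
}

#' Write all pipeline result tables to a directory
#'
#' Writes `table1_utilization.csv`, `table2_oope.csv`,
#' `table3_benefit_incidence.csv`, `modal_costs.csv`,
#' `table4_concentration.csv` and per-(service, sector) curve point files.
#'
#' @param result A `bia_result` from [run_bia()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bia_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_result(result$utilization, file.path(dir, "table1_utilization.csv"))
  write_result(result$oope, file.path(dir, "table2_oope.csv"))
  write_result(
    result$benefit, file.path(dir, "table3_benefit_incidence.csv")
  )
  write_result(result$modal_costs, file.path(dir, "modal_costs.csv"))
  write_result(
    result$concentration_summary, file.path(dir, "table4_concentration.csv")
  )
  for (nm in names(result$concentration)) {
    write_result(
      result$concentration[[nm]]$curve,
      file.path(dir, sprintf("curve_%s.csv", sub("\\.", "_", nm)))
    )
  }
  invisible(dir)
}
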