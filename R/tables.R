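# Survey-weighted descriptive tables: utilization shares by ailment group
# and MPCE class, and mean out-of-pocket expenditure (OOPE) by class, sector
# and facility. All cells are weighted; "combine" pools rural and urban
# records (it is never the average of the two sector columns).

#' Decompose an episode's OOPE into medicine / medical / total
#'
#' `medicine` is spending on medicines alone; `medical` adds other medical
#' care (fees, diagnostics); `total` further adds transport and other
#' non-medical spending (food, escorts, lodging). By construction
#' `medicine <= medical <= total`.
#'
#' @param oope_medicine,oope_other_medical,oope_transport,oope_other_nonmedical
#'   Nonnegative component amounts (INR), vectorized.
#' @return Tibble with columns `medicine`, `medical`, `total`.
#' @examples
#' oope_components(100, 50, 20, 5) # 100, 150, 175
#' @export
oope_components <- function(oope_medicine, oope_other_medical,
                            oope_transport, oope_other_nonmedical) {
  medicine <- oope_medicine
  medical <- medicine + oope_other_medical
  total <- medical + oope_transport + oope_other_nonmedical
  tibble::tibble(medicine = medicine, medical = medical, total = total)
}

add_oope_components <- function(df) {
  comps <- oope_components(
    df$oope_medicine, df$oope_other_medical,
    df$oope_transport, df$oope_other_nonmedical
  )
  dplyr::bind_cols(df, comps)
}

share_panel <- function(episodes, group_col, panel) {
  if (nrow(episodes) == 0) {
    warn(sprintf("Utilization panel `%s`: empty universe, column omitted", panel))
    return(tibble::tibble())
  }
  episodes$group <- episodes[[group_col]]
  episodes |>
    with_combine_sector() |>
    dplyr::group_by(.data$service, .data$sector) |>
    dplyr::group_modify(function(df, key) {
      df |>
        dplyr::group_by(.data$group, .drop = FALSE) |>
        dplyr::summarise(
          n = dplyr::n(), w = sum(.data$weight), .groups = "drop"
        ) |>
        dplyr::mutate(share_pct = 100 * .data$w / sum(.data$w))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(panel = panel, group = as.character(.data$group)) |>
    dplyr::select(
      "panel", "service", "sector", "group", "n", "w", "share_pct"
    )
}

#' Weighted utilization-share table
#'
#' Three panels, each a set of weighted percentage shares whose columns sum
#' to 100 within (panel, service, sector):
#' * `ailment`: shares of CD / NCD / OD among ALL elderly episodes;
#' * `ncd_class`: shares of the four MPCE classes among elderly NCD
#'   episodes;
#' * `ncd_public_class`: class shares among elderly NCD episodes in public
#'   facilities.
#' Utilization is counted per episode/spell (the outpatient unit is the
#' spell, because its OOPE is pooled across visits).
#'
#' @param selection Output of [select_elderly_ncd()].
#' @return A tibble (`panel`, `service`, `sector`, `group`, `n`, `w`,
#'   `share_pct`), sector including `"combine"`.
#' @export
utilization_table <- function(selection) {
  all_eld <- dplyr::bind_rows(
    dplyr::select(
      selection$ip_elderly,
      "service", "sector", "ailment_group", "mpce_class", "weight"
    ),
    dplyr::select(
      selection$op_elderly,
      "service", "sector", "ailment_group", "mpce_class", "weight"
    )
  )
  ncd <- dplyr::bind_rows(
    dplyr::select(
      selection$ip_ncd,
      "service", "sector", "mpce_class", "facility", "weight"
    ),
    dplyr::select(
      selection$op_ncd,
      "service", "sector", "mpce_class", "facility", "weight"
    )
  )
  dplyr::bind_rows(
    share_panel(all_eld, "ailment_group", "ailment"),
    share_panel(ncd, "mpce_class", "ncd_class"),
    share_panel(
      dplyr::filter(ncd, .data$facility == "public"),
      "mpce_class", "ncd_public_class"
    )
  )
}

#' Weighted mean OOPE by MPCE class, sector and facility
#'
#' Cell values are survey-weighted means of the medicine / medical / total
#' OOPE decomposition over elderly NCD episodes in the cell; the `All` row
#' pools the four classes. Empty cells are absent from the output (missing,
#' never zero).
#'
#' @param selection Output of [select_elderly_ncd()].
#' @return Tibble (`service`, `sector`, `facility`, `mpce_class`,
#'   `n_episodes`, `medicine`, `medical`, `total`).
#' @export
mean_oope_table <- function(selection) {
  eps <- dplyr::bind_rows(
    add_oope_components(selection$ip_ncd),
    add_oope_components(selection$op_ncd)
  )
  if (nrow(eps) == 0) {
    return(tibble::tibble())
  }
  cell_means <- function(df) {
    df |>
      dplyr::summarise(
        n_episodes = dplyr::n(),
        medicine = weighted.mean(.data$medicine, .data$weight),
        medical = weighted.mean(.data$medical, .data$weight),
        total = weighted.mean(.data$total, .data$weight),
        .groups = "drop"
      )
  }
  by_class <- eps |>
    dplyr::group_by(
      .data$service, .data$sector, .data$facility, .data$mpce_class
    ) |>
    cell_means() |>
    dplyr::mutate(mpce_class = as.character(.data$mpce_class))
  all_row <- eps |>
    dplyr::group_by(.data$service, .data$sector, .data$facility) |>
    cell_means() |>
    dplyr::mutate(mpce_class = "All")
  dplyr::bind_rows(by_class, all_row) |>
    dplyr::arrange(
      .data$service, .data$sector, .data$facility,
      match(.data$mpce_class, c(MPCE_LEVELS, "All"))
    ) |>
    dplyr::select(
      "service", "sector", "facility", "mpce_class", "n_episodes",
      "medicine", "medical", "total"
    )
}
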