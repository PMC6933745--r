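# Benefit incidence analysis proper: the modal private-cost proxy for the
# cost of public provision, per-episode net subsidies, class utilization
# rates, and benefit-incidence shares.
#
# The cost of providing a service in a public facility is unobserved in
# expenditure surveys; following the BIA literature it is proxied by the
# MODAL private-sector OOPE in the matching stratum (state x sector x MPCE
# class x illness-duration band, per service), the stratification absorbing
# quality, severity and regional price variation. The net subsidy of a
# public episode is that modal cost minus the episode's own user charges.

#' Duration band of an episode
#'
#' Severity is proxied by duration: days of hospital stay for inpatient
#' care, total duration of the ailment for outpatient care. Default band
#' edges: IP `1-3`, `4-7`, `8-14`, `15+` days; OP `0-14`, `15-30`, `31-90`,
#' `91+` days. Band edges are configurable; each edge starts a new band.
#'
#' @param service `"IP"` or `"OP"` (vectorized alongside `days`).
#' @param days Nonnegative days (IP requires >= 1).
#' @param ip_breaks,op_breaks Increasing lower band edges.
#' @return Character band labels such as `"1-3"` or `"15+"`.
#' @export
duration_band <- function(service, days,
                          ip_breaks = c(1, 4, 8, 15),
                          op_breaks = c(0, 15, 31, 91)) {
  if (any(days < 0, na.rm = TRUE)) {
    abort("duration_band(): negative days.")
  }
  band_of <- function(d, breaks) {
    labs <- c(
      paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
      paste0(breaks[length(breaks)], "+")
    )
    labs[findInterval(d, breaks)]
  }
  out <- character(length(days))
  is_ip <- service == "IP"
  if (any(is_ip & days < 1, na.rm = TRUE)) {
    abort("duration_band(): inpatient stays must last at least 1 day.")
  }
  out[is_ip] <- band_of(days[is_ip], ip_breaks)
  out[!is_ip] <- band_of(days[!is_ip], op_breaks)
  out
}

add_stratum_key <- function(episodes, ip_breaks, op_breaks) {
  days <- ifelse(
    episodes$service == "IP",
    episodes$stay_days, episodes$ailment_duration_days
  )
  episodes$duration_band <- duration_band(
    episodes$service, days, ip_breaks = ip_breaks, op_breaks = op_breaks
  )
  episodes
}

POOLING_LEVELS <- c("full", "drop_duration", "drop_class", "drop_state", "global")

LEVEL_KEYS <- list(
  full = c("service", "state", "sector", "mpce_class", "duration_band"),
  drop_duration = c("service", "state", "sector", "mpce_class"),
  drop_class = c("service", "state", "sector"),
  drop_state = c("service", "sector"),
  global = "service"
)

# weighted binned mode: values fall into half-open bins [m*w, (m+1)*w); the
# modal cost is the weighted mean of the values in the bin with the largest
# total weight, ties broken toward the LOWER bin
binned_mode <- function(values, weights, bin_width) {
  b <- floor(values / bin_width)
  wsum <- tapply(weights, b, sum)
  mode_bin <- as.numeric(names(wsum))[wsum == max(wsum)]
  mode_bin <- min(mode_bin)
  inb <- b == mode_bin
  weighted.mean(values[inb], weights[inb])
}

#' Modal private cost per stratum
#'
#' Within every stratum (state x sector x MPCE class x duration band, per
#' service), private-facility total OOPE values are binned into half-open
#' intervals of width `ip_bin` / `op_bin` and the modal cost is the
#' weighted-count-maximizing bin's weighted mean (ties toward the lower
#' bin). A stratum with fewer than `min_cell_size` private episodes is
#' pooled up the fallback ladder `full -> drop_duration -> drop_class ->
#' drop_state -> global`, and the pooling level used is recorded.
#'
#' @param private_episodes Private-facility episodes with `service`,
#'   `state`, `sector`, `mpce_class`, `duration_band`, `total` (total OOPE)
#'   and `weight`.
#' @param keys Optional tibble of stratum keys to resolve (defaults to the
#'   strata present in `private_episodes`).
#' @param min_cell_size Minimum private episodes per stratum (default 5).
#' @param ip_bin,op_bin Bin widths in INR (defaults 500 and 50).
#' @return A `modal_cost_table` tibble: stratum keys plus `modal_cost`,
#'   `n_private`, `pooling_level`.
#' @export
modal_private_cost <- function(private_episodes, keys = NULL,
                               min_cell_size = 5, ip_bin = 500, op_bin = 50) {
  req <- c(LEVEL_KEYS$full, "total", "weight")
  stop_if_missing_cols(private_episodes, req, "`private_episodes`")
  if (nrow(private_episodes) == 0) {
    abort("modal_private_cost(): no private episodes; the cost proxy is undefined.")
  }
  eps <- private_episodes |>
    dplyr::mutate(
      mpce_class = as.character(.data$mpce_class),
      bin_width = ifelse(.data$service == "IP", ip_bin, op_bin)
    )
  if (is.null(keys)) {
    keys <- dplyr::distinct(
      eps, .data$service, .data$state, .data$sector,
      .data$mpce_class, .data$duration_band
    )
  }
  keys <- keys |>
    dplyr::mutate(mpce_class = as.character(.data$mpce_class)) |>
    dplyr::distinct(
      .data$service, .data$state, .data$sector,
      .data$mpce_class, .data$duration_band
    )
  # modal cost and n at every pooling level, joined to the requested keys
  level_tables <- lapply(POOLING_LEVELS, function(level) {
    eps |>
      dplyr::group_by(dplyr::across(dplyr::all_of(LEVEL_KEYS[[level]]))) |>
      dplyr::summarise(
        modal_cost = binned_mode(.data$total, .data$weight, .data$bin_width[1]),
        n_private = dplyr::n(),
        .groups = "drop"
      )
  })
  names(level_tables) <- POOLING_LEVELS
  out <- keys
  out$modal_cost <- NA_real_
  out$n_private <- NA_integer_
  out$pooling_level <- NA_character_
  for (level in POOLING_LEVELS) {
    unresolved <- is.na(out$modal_cost)
    if (!any(unresolved)) break
    lt <- level_tables[[level]]
    hit <- dplyr::left_join(
      out[unresolved, LEVEL_KEYS$full],
      lt,
      by = LEVEL_KEYS[[level]]
    )
    ok <- !is.na(hit$modal_cost) &
      (hit$n_private >= min_cell_size | level == "global")
    idx <- which(unresolved)[ok]
    out$modal_cost[idx] <- hit$modal_cost[ok]
    out$n_private[idx] <- hit$n_private[ok]
    out$pooling_level[idx] <- level
  }
  if (anyNA(out$modal_cost)) {
    # only possible when a requested service has no private episodes at all
    abort("modal_private_cost(): a requested service has no private episodes.")
  }
  n_pooled <- sum(out$pooling_level != "full")
  if (n_pooled > 0) {
    inform(sprintf(
      "Modal costs: %d of %d strata pooled above the full level",
      n_pooled, nrow(out)
    ))
  }
  class(out) <- c("modal_cost_table", class(out))
  out
}

#' Net subsidy of public-facility episodes
#'
#' For each public episode, the net subsidy is the stratum's modal private
#' cost minus the episode's own total OOPE (the user charge),
#' `gamma = modal_cost - total_oope`. With `clamp = TRUE` (default) negative
#' values are set to 0 — under the proxy's own logic a subsidy cannot be
#' negative — and the number of clamped episodes is recorded in the
#' `clamped` column.
#'
#' @param public_episodes Public-facility episodes carrying the stratum key
#'   columns and `total` (total OOPE).
#' @param modal_table From [modal_private_cost()].
#' @param clamp Clamp negative subsidies at zero? Default `TRUE`.
#' @return `public_episodes` with `modal_cost`, `pooling_level`, `gamma`
#'   and logical `clamped` columns added.
#' @export
net_subsidy <- function(public_episodes, modal_table, clamp = TRUE) {
  out <- public_episodes |>
    dplyr::mutate(mpce_class = as.character(.data$mpce_class)) |>
    dplyr::left_join(
      dplyr::select(
        modal_table, dplyr::all_of(LEVEL_KEYS$full),
        "modal_cost", "pooling_level"
      ),
      by = LEVEL_KEYS$full
    )
  if (anyNA(out$modal_cost)) {
    abort("net_subsidy(): some episodes' strata are missing from the modal cost table.")
  }
  out$gamma <- out$modal_cost - out$total
  out$clamped <- clamp & out$gamma < 0
  if (clamp) out$gamma <- pmax(out$gamma, 0)
  if (any(out$clamped)) {
    inform(sprintf(
      "Net subsidy: %d episode(s) clamped at 0", sum(out$clamped)
    ))
  }
  out
}

#' Class utilization rates of public care
#'
#' `delta_j` is MPCE class j's weighted share of all public-facility
#' episodes for the service: the weighted class count over the weighted
#' total. Rates sum to 1 within each (service, sector).
#'
#' @param public_episodes Public episodes with `service`, `sector`,
#'   `mpce_class`, `weight`.
#' @return Tibble (`service`, `sector` incl. `"combine"`, `mpce_class`,
#'   `n_episodes`, `delta`).
#' @export
utilization_rates <- function(public_episodes) {
  if (nrow(public_episodes) == 0) {
    abort("utilization_rates(): empty episode set.")
  }
  public_episodes |>
    dplyr::mutate(
      mpce_class = factor(as.character(.data$mpce_class), levels = MPCE_LEVELS)
    ) |>
    with_combine_sector() |>
    dplyr::group_by(.data$service, .data$sector) |>
    dplyr::group_modify(function(df, key) {
      df |>
        dplyr::group_by(.data$mpce_class, .drop = FALSE) |>
        dplyr::summarise(
          n_episodes = dplyr::n(), w = sum(.data$weight), .groups = "drop"
        ) |>
        dplyr::mutate(delta = .data$w / sum(.data$w)) |>
        dplyr::select(-"w")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(mpce_class = as.character(.data$mpce_class))
}

#' Benefit-incidence shares per MPCE class
#'
#' Implements the benefit-incidence formula: class j's benefit is its
#' utilization rate times the sum of its members' weighted net subsidies,
#' `pi_j = delta_j * sum_{k in j} w_k * gamma_k`, and the benefit-incidence
#' estimate is each class's percentage share of `sum_j pi_j`. The
#' `delta`-weighting counts utilization twice relative to plain subsidy
#' sums; `rate_weighted = FALSE` gives the unweighted sensitivity variant
#' `pi_j = sum_{k in j} w_k * gamma_k`.
#'
#' @param subsidised_episodes Public episodes with `gamma` attached (from
#'   [net_subsidy()]).
#' @param rates From [utilization_rates()]; recomputed if `NULL`.
#' @param rate_weighted Use the printed delta-weighted formula (default
#'   `TRUE`) or the plain subsidy-sum variant.
#' @return A `benefit_table` tibble: (`service`, `sector`, `mpce_class`,
#'   `n_episodes`, `n_clamped`, `subsidy_total`, `delta`, `pi`,
#'   `share_pct`).
#' @export
benefit_incidence_shares <- function(subsidised_episodes, rates = NULL,
                                     rate_weighted = TRUE) {
  if (is.null(rates)) rates <- utilization_rates(subsidised_episodes)
  sums <- subsidised_episodes |>
    dplyr::mutate(
      mpce_class = factor(as.character(.data$mpce_class), levels = MPCE_LEVELS)
    ) |>
    with_combine_sector() |>
    dplyr::group_by(.data$service, .data$sector) |>
    dplyr::group_modify(function(df, key) {
      if (!"clamped" %in% names(df)) df$clamped <- FALSE
      df |>
        dplyr::group_by(.data$mpce_class, .drop = FALSE) |>
        dplyr::summarise(
          n_clamped = sum(.data$clamped),
          subsidy_total = sum(.data$weight * .data$gamma),
          .groups = "drop"
        )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(mpce_class = as.character(.data$mpce_class))
  out <- sums |>
    dplyr::inner_join(rates, by = c("service", "sector", "mpce_class")) |>
    dplyr::mutate(
      pi = if (rate_weighted) {
        .data$delta * .data$subsidy_total
      } else {
        .data$subsidy_total
      }
    ) |>
    dplyr::group_by(.data$service, .data$sector) |>
    dplyr::mutate(
      share_pct = if (sum(.data$pi) > 0) {
        100 * .data$pi / sum(.data$pi)
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "service", "sector", "mpce_class", "n_episodes", "n_clamped",
      "subsidy_total", "delta", "pi", "share_pct"
    )
  if (anyNA(out$share_pct)) {
    warn("benefit_incidence_shares(): zero total subsidy in some (service, sector); shares undefined.")
  }
  class(out) <- c("benefit_table", class(out))
  out
}
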