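# Synthetic survey-data generator with planted, known equity structure.
#
# Emulates the schema-level structure of an NSS-style health-consumption
# survey: a state x sector household frame with lognormal expenditure,
# survey multiplier weights, age-graded NCD morbidity, income-graded
# public/private facility choice, and public OOPE systematically below
# private OOPE. Private costs are drawn from a lognormal re-parameterized
# by its MODE, so the modal-cost proxy estimated downstream has an exact
# recoverable target. Alongside the dataset it returns a TruthRecord with
# the planted stratum cost locations, per-episode true subsidies, class
# benefit shares and the true grouped concentration index.

NCD_CODES <- c(
  "diabetes", "hypertension", "heart_disease", "stroke", "cancer",
  "copd", "asthma", "arthritis", "chronic_kidney", "neuro_psychiatric"
)
CD_CODES <- c(
  "tuberculosis", "malaria", "diarrhoea", "respiratory_infection",
  "typhoid", "hepatitis", "skin_infection", "infectious_fever"
)
OD_CODES <- c(
  "injury", "pregnancy_related", "newborn_illness", "undiagnosed_fever"
)

#' Configuration of the synthetic survey generator
#'
#' All rates are probabilities in \[0, 1\]; monetary quantities are INR.
#' Defaults describe a plausible Indian household-survey setting: an
#' elderly share of 8.2%, age-graded NCD morbidity, per-cell lognormal
#' household expenditure (rural level below urban), private inpatient costs
#' in the tens of thousands of INR and outpatient costs in the hundreds,
#' public OOPE around a third of the private cost location, and survey
#' multiplier weights drawn independently of expenditure.
#'
#' @param n_states Number of states.
#' @param households_per_cell Households per (state, sector) cell.
#' @param base_expenditure Named vector, median household total monthly
#'   expenditure (INR) by sector.
#' @param log_sd_expenditure Log-sd of household expenditure.
#' @param state_expenditure_spread Half-range of the per-state log shift of
#'   expenditure.
#' @param mean_household_size Mean household size (size is 1 + Poisson).
#' @param base_weight Base survey multiplier; weights are
#'   `base_weight * U(0.5, 2)` per household, independent of expenditure.
#' @param elderly_fraction Probability an individual is aged 60+.
#' @param ncd_intercept,ncd_age_slope Log-odds intercept and per-year slope
#'   of NCD morbidity.
#' @param cd_prob,od_prob Probabilities of communicable / other ailments.
#' @param ip_rate,op_rate Probability that an ailing individual records a
#'   hospitalization episode / an outpatient spell.
#' @param mixed_visit_prob Per-visit probability that an outpatient visit's
#'   ailment comes from outside the person's own disease group (exercises
#'   the all-visits-NCD selection rule).
#' @param private_choice_base Baseline probability of choosing a private
#'   facility.
#' @param gradient Planted facility-choice gradient g: log-odds of choosing
#'   private added per MPCE-class step (centred on the class midpoint), so
#'   `gradient > 0` makes richer classes more private-leaning.
#' @param ip_cost_base,op_cost_base Named vectors: private total-OOPE cost
#'   location (the lognormal MODE, INR) by sector, before class, state and
#'   duration multipliers.
#' @param cost_class_ratio Multiplicative cost step per MPCE class (1 = no
#'   class gradient in costs).
#' @param state_cost_spread Half-range of the per-state log cost shift.
#' @param ip_band_factors,op_band_factors Cost multipliers for the four
#'   default duration bands.
#' @param private_noise_mode Named vector (`IP`, `OP`): mode of the
#'   shifted-lognormal noise part of private total OOPE (INR). Private
#'   totals are `location - private_noise_mode + Y` with `Y` lognormal of
#'   mode `private_noise_mode`, so the total's mode is exactly the stratum
#'   location and the within-stratum spread has a fixed ABSOLUTE scale —
#'   keeping the planted mode equally identifiable at every cost level.
#' @param sigma_private Log-sd of the private noise part `Y`.
#' @param public_fraction Mean public total OOPE as a fraction of the
#'   private cost location.
#' @param sigma_public Log-sd of public total OOPE.
#' @param oope_props List with `IP` and `OP` mean component proportions
#'   (medicine, other medical, transport, other non-medical).
#' @param prop_concentration Dirichlet concentration of the component
#'   split.
#' @param stay_geom_prob Geometric parameter of (stay days - 1).
#' @param op_duration_shape,op_duration_scale Gamma parameters of the
#'   outpatient ailment duration (days).
#' @param seed Integer seed; required by [simulate_survey()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_states = 5,
                       households_per_cell = 400,
                       base_expenditure = c(rural = 7000, urban = 13000),
                       log_sd_expenditure = 0.5,
                       state_expenditure_spread = 0.15,
                       mean_household_size = 4.3,
                       base_weight = 100,
                       elderly_fraction = 0.082,
                       ncd_intercept = -4.5,
                       ncd_age_slope = 0.055,
                       cd_prob = 0.05,
                       od_prob = 0.03,
                       ip_rate = 0.15,
                       op_rate = 0.25,
                       mixed_visit_prob = 0.08,
                       private_choice_base = 0.5,
                       gradient = 0.4,
                       ip_cost_base = c(rural = 15000, urban = 20000),
                       op_cost_base = c(rural = 550, urban = 750),
                       cost_class_ratio = 1.15,
                       state_cost_spread = 0.1,
                       ip_band_factors = c(0.7, 1, 1.4, 2),
                       op_band_factors = c(0.8, 1, 1.3, 1.7),
                       private_noise_mode = c(IP = 2500, OP = 250),
                       sigma_private = 0.35,
                       public_fraction = 0.35,
                       sigma_public = 0.3,
                       oope_props = list(
                         IP = c(0.35, 0.45, 0.10, 0.10),
                         OP = c(0.65, 0.20, 0.10, 0.05)
                       ),
                       prop_concentration = 30,
                       stay_geom_prob = 0.17,
                       op_duration_shape = 1.3,
                       op_duration_scale = 55,
                       seed = NULL) {
  cfg <- as.list(environment())
  rates <- c(
    elderly_fraction, cd_prob, od_prob, ip_rate, op_rate,
    mixed_visit_prob, private_choice_base, public_fraction, stay_geom_prob
  )
  if (any(rates < 0 | rates > 1)) {
    abort("sim_config(): all rate parameters must lie in [0, 1].")
  }
  if (households_per_cell < 1 || n_states < 1) {
    abort("sim_config(): need at least one state and one household per cell.")
  }
  if (any(c(
    log_sd_expenditure, op_duration_shape, op_duration_scale,
    prop_concentration
  ) <= 0) || sigma_private < 0 || sigma_public < 0) {
    abort("sim_config(): spreads and shape parameters must be positive.")
  }
  if (any(ip_cost_base <= 0) || any(op_cost_base <= 0) ||
    cost_class_ratio <= 0 || any(private_noise_mode <= 0)) {
    abort("sim_config(): cost parameters must be positive.")
  }
  # the shift of the private-cost distribution must stay positive in the
  # cheapest stratum of each service, else the mode parameterization breaks
  min_state <- exp(-state_cost_spread * (n_states > 1))
  min_cls <- min(1, cost_class_ratio)^3
  min_loc <- c(
    IP = unname(min(ip_cost_base)) * min_state * min(ip_band_factors) * min_cls,
    OP = unname(min(op_cost_base)) * min_state * min(op_band_factors) * min_cls
  )
  if (any(min_loc <= private_noise_mode[names(min_loc)])) {
    abort("sim_config(): private_noise_mode must be below the smallest stratum cost location.")
  }
  structure(cfg, class = "sim_config")
}

# deterministic per-state multipliers (no randomness: part of the truth)
state_shifts <- function(n_states, spread) {
  if (n_states == 1) {
    return(0)
  }
  seq(-spread, spread, length.out = n_states)
}

sim_state_codes <- function(n_states) sprintf("S%02d", seq_len(n_states))

# planted private cost location (the lognormal mode) of a stratum
true_cost_location <- function(config, service, state, sector, class_idx,
                               band_idx) {
  base <- if (service == "IP") {
    config$ip_cost_base[sector]
  } else {
    config$op_cost_base[sector]
  }
  state_idx <- match(state, sim_state_codes(config$n_states))
  state_f <- exp(state_shifts(config$n_states, config$state_cost_spread))
  band_f <- if (service == "IP") {
    config$ip_band_factors[band_idx]
  } else {
    config$op_band_factors[band_idx]
  }
  unname(
    base * state_f[state_idx] *
      config$cost_class_ratio^(class_idx - 1) * band_f
  )
}

# Dirichlet split of totals into the four OOPE components
split_components <- function(total, props, concentration) {
  n <- length(total)
  alpha <- props * concentration
  g <- matrix(rgamma(n * 4, shape = rep(alpha, each = n)), nrow = n)
  p <- g / rowSums(g)
  tibble::tibble(
    oope_medicine = total * p[, 1],
    oope_other_medical = total * p[, 2],
    oope_transport = total * p[, 3],
    oope_other_nonmedical = total * p[, 4]
  )
}

#' Draw OOPE components for episodes of one facility type
#'
#' Private totals are shifted-lognormal with MODE equal to `location`:
#' `total = location - d + Y` where `Y` is lognormal with mode
#' `d = private_noise_mode[service]` and log-sd `sigma_private`, so the
#' within-stratum spread has a fixed absolute scale and the mode is equally
#' identifiable in cheap and expensive strata. In the `sigma_private = 0`
#' limit every private total equals the location exactly. Public totals are
#' lognormal with MEAN `public_fraction * location`, so expected public
#' OOPE sits below expected private OOPE in every stratum whenever
#' `public_fraction < 1`. Totals are split into the four components by a
#' Dirichlet draw around the service's mean proportions.
#'
#' @param n Number of draws.
#' @param location Private cost location (scalar or length-`n`).
#' @param facility `"private"` or `"public"`.
#' @param service `"IP"` or `"OP"` (selects component proportions).
#' @param config A [sim_config()] (spread and fraction parameters).
#' @return Tibble with the four OOPE component columns.
#' @export
draw_oope <- function(n, location, facility = c("private", "public"),
                      service = c("IP", "OP"), config = sim_config()) {
  facility <- match.arg(facility)
  service <- match.arg(service)
  stopifnot(all(location > 0))
  total <- if (facility == "private") {
    s <- config$sigma_private
    d <- config$private_noise_mode[[service]]
    stopifnot(all(location > d))
    location - d + rlnorm(n, meanlog = log(d) + s^2, sdlog = s)
  } else {
    s <- config$sigma_public
    rlnorm(n,
      meanlog = log(config$public_fraction * location) - s^2 / 2, sdlog = s
    )
  }
  split_components(total, config$oope_props[[service]], config$prop_concentration)
}

draw_visit_codes <- function(n_spells, visits, own_codes, other_codes,
                             mixed_prob) {
  total_visits <- sum(visits)
  own <- sample(own_codes, total_visits, replace = TRUE)
  mixed <- runif(total_visits) < mixed_prob
  own[mixed] <- sample(other_codes, sum(mixed), replace = TRUE)
  idx <- factor(rep(seq_len(n_spells), visits), levels = seq_len(n_spells))
  codes <- vapply(
    split(own, idx), paste, character(1), collapse = ";"
  )
  list(
    codes = unname(codes),
    any_foreign = unname(as.vector(tapply(mixed, idx, any)))
  )
}

#' Generate a synthetic survey dataset with planted ground truth
#'
#' Runs the full generative model of [sim_config()] under the config's seed
#' and returns the linked four-table dataset (which always passes
#' [validate_survey()]) together with a `sim_truth` record: planted stratum
#' cost locations, the per-household true MPCE classes, per-episode true net
#' subsidies for the elderly-NCD public episodes, the true class benefit
#' shares and the true grouped concentration index per service and sector.
#' Identical configs (including seed) give identical output.
#'
#' @param config A `sim_config` with a non-`NULL` integer seed.
#' @return List with elements `dataset` (a `survey_dataset`) and `truth`.
#' @export
simulate_survey <- function(config = sim_config(seed = 1)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) {
    abort("simulate_survey(): config must carry an integer seed.")
  }
  with_seed(config$seed, simulate_survey_impl(config))
}

simulate_survey_impl <- function(config) {
  states <- sim_state_codes(config$n_states)
  cells <- expand.grid(
    state = states, sector = SECTORS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n_cells <- nrow(cells)
  hpc <- config$households_per_cell
  n_hh <- n_cells * hpc

  # --- households -----------------------------------------------------------
  hh <- tibble::tibble(
    household_id = sprintf("H%07d", seq_len(n_hh)),
    state = rep(cells$state, each = hpc),
    sector = rep(cells$sector, each = hpc)
  )
  exp_shift <- state_shifts(config$n_states, config$state_expenditure_spread)
  hh$total_monthly_expenditure <- rlnorm(
    n_hh,
    meanlog = log(config$base_expenditure[hh$sector]) +
      exp_shift[match(hh$state, states)],
    sdlog = config$log_sd_expenditure
  )
  hh$household_size <- 1 + rpois(n_hh, config$mean_household_size - 1)
  hh$weight <- config$base_weight * runif(n_hh, 0.5, 2)

  # --- true MPCE classes (the planted classification) -----------------------
  hh$mpce <- equivalized_mpce(hh$total_monthly_expenditure, hh$household_size)
  cuts <- mpce_cutpoints(hh)
  hh_cls <- hh |>
    dplyr::left_join(
      dplyr::select(cuts, "state", "sector", "q25", "q50", "q75"),
      by = c("state", "sector")
    )
  hh$mpce_class <- assign_class(hh_cls$mpce, hh_cls$q25, hh_cls$q50, hh_cls$q75)
  hh$class_idx <- as.integer(hh$mpce_class)

  # --- individuals ----------------------------------------------------------
  n_ind <- sum(hh$household_size)
  hh_row <- rep(seq_len(n_hh), hh$household_size)
  elderly <- runif(n_ind) < config$elderly_fraction
  age <- integer(n_ind)
  age[elderly] <- pmin(60L + as.integer(rexp(sum(elderly), rate = 1 / 8)), 99L)
  age[!elderly] <- sample.int(60L, sum(!elderly), replace = TRUE) - 1L
  ind <- tibble::tibble(
    person_id = sprintf("P%07d", seq_len(n_ind)),
    household_id = hh$household_id[hh_row],
    age = age,
    sex = sample(c("female", "male"), n_ind, replace = TRUE),
    weight = hh$weight[hh_row]
  )

  # --- morbidity ------------------------------------------------------------
  p_ncd <- stats::plogis(config$ncd_intercept + config$ncd_age_slope * age)
  u <- runif(n_ind)
  disease <- ifelse(
    u < p_ncd, "NCD",
    ifelse(u < p_ncd + config$cd_prob, "CD",
      ifelse(u < p_ncd + config$cd_prob + config$od_prob, "OD", "none")
    )
  )

  ill <- which(disease != "none")
  grp <- disease[ill]
  class_idx <- hh$class_idx[hh_row[ill]]
  state_i <- hh$state[hh_row[ill]]
  sector_i <- hh$sector[hh_row[ill]]
  p_private <- stats::plogis(
    stats::qlogis(config$private_choice_base) +
      config$gradient * (class_idx - 2.5)
  )

  code_pool <- list(NCD = NCD_CODES, CD = CD_CODES, OD = OD_CODES)

  # --- inpatient episodes ---------------------------------------------------
  has_ip <- runif(length(ill)) < config$ip_rate
  ipi <- which(has_ip)
  n_ip <- length(ipi)
  ip_facility <- ifelse(runif(n_ip) < p_private[ipi], "private", "public")
  ip_stay <- 1L + rgeom(n_ip, config$stay_geom_prob)
  ip_band_idx <- findInterval(ip_stay, c(1, 4, 8, 15))
  ip_loc <- true_cost_location(
    config, "IP", state_i[ipi], sector_i[ipi], class_idx[ipi], ip_band_idx
  )
  ip_code <- character(n_ip)
  for (g in AILMENT_GROUPS) {
    sel <- grp[ipi] == g
    ip_code[sel] <- sample(code_pool[[g]], sum(sel), replace = TRUE)
  }
  ip_oope <- draw_oope_mixed(n_ip, ip_loc, ip_facility, "IP", config)
  ip <- tibble::tibble(
    episode_id = sprintf("E%07d", seq_len(n_ip)),
    person_id = ind$person_id[ill[ipi]],
    ailment_code = ip_code,
    facility = ip_facility,
    stay_days = ip_stay,
    ip_oope,
    weight = ind$weight[ill[ipi]]
  )

  # --- outpatient spells ----------------------------------------------------
  has_op <- runif(length(ill)) < config$op_rate
  opi <- which(has_op)
  n_op <- length(opi)
  op_facility <- ifelse(runif(n_op) < p_private[opi], "private", "public")
  op_duration <- as.integer(round(
    rgamma(n_op, shape = config$op_duration_shape) * config$op_duration_scale
  ))
  op_band_idx <- findInterval(op_duration, c(0, 15, 31, 91))
  op_loc <- true_cost_location(
    config, "OP", state_i[opi], sector_i[opi], class_idx[opi], op_band_idx
  )
  visits <- 1L + rbinom(n_op, 2L, 0.3)
  op_codes <- character(n_op)
  op_foreign <- logical(n_op)
  for (g in AILMENT_GROUPS) {
    sel <- which(grp[opi] == g)
    if (length(sel) == 0) next
    drawn <- draw_visit_codes(
      length(sel), visits[sel],
      own_codes = code_pool[[g]],
      other_codes = unlist(code_pool[setdiff(AILMENT_GROUPS, g)]),
      mixed_prob = config$mixed_visit_prob
    )
    op_codes[sel] <- drawn$codes
    op_foreign[sel] <- drawn$any_foreign
  }
  op_oope <- draw_oope_mixed(n_op, op_loc, op_facility, "OP", config)
  op <- tibble::tibble(
    spell_id = sprintf("V%07d", seq_len(n_op)),
    person_id = ind$person_id[ill[opi]],
    visit_ailment_codes = op_codes,
    ailment_duration_days = op_duration,
    facility = op_facility,
    op_oope,
    weight = ind$weight[ill[opi]]
  )

  dataset <- survey_dataset(
    dplyr::select(hh, dplyr::all_of(HOUSEHOLD_COLS)), ind, ip, op
  )

  # --- truth record ---------------------------------------------------------
  ip_total <- ip$oope_medicine + ip$oope_other_medical +
    ip$oope_transport + ip$oope_other_nonmedical
  op_total <- op$oope_medicine + op$oope_other_medical +
    op$oope_transport + op$oope_other_nonmedical
  elderly_of <- function(idx) age[ill[idx]] >= 60
  ep_truth <- dplyr::bind_rows(
    tibble::tibble(
      service = "IP", id = ip$episode_id,
      sector = sector_i[ipi], state = state_i[ipi],
      mpce_class = MPCE_LEVELS[class_idx[ipi]],
      facility = ip_facility, weight = ip$weight,
      true_location = ip_loc, total_oope = ip_total,
      elderly = elderly_of(ipi), ncd = grp[ipi] == "NCD",
      all_ncd = grp[ipi] == "NCD"
    ),
    tibble::tibble(
      service = "OP", id = op$spell_id,
      sector = sector_i[opi], state = state_i[opi],
      mpce_class = MPCE_LEVELS[class_idx[opi]],
      facility = op_facility, weight = op$weight,
      true_location = op_loc, total_oope = op_total,
      elderly = elderly_of(opi), ncd = grp[opi] == "NCD",
      all_ncd = grp[opi] == "NCD" & !op_foreign
    )
  )
  ep_truth$true_subsidy <- pmax(ep_truth$true_location - ep_truth$total_oope, 0)

  pub <- ep_truth |>
    dplyr::filter(.data$elderly, .data$all_ncd, .data$facility == "public")
  benefit_truth <- pub |>
    dplyr::mutate(
      mpce_class = factor(.data$mpce_class, levels = MPCE_LEVELS)
    ) |>
    with_combine_sector() |>
    dplyr::group_by(.data$service, .data$sector) |>
    dplyr::group_modify(function(df, key) {
      df |>
        dplyr::group_by(.data$mpce_class, .drop = FALSE) |>
        dplyr::summarise(
          n_episodes = dplyr::n(),
          w = sum(.data$weight),
          subsidy_total = sum(.data$weight * .data$true_subsidy),
          .groups = "drop"
        ) |>
        dplyr::mutate(
          delta = .data$w / sum(.data$w),
          pi = .data$delta * .data$subsidy_total,
          share = .data$pi / sum(.data$pi),
          subsidy_share = .data$subsidy_total / sum(.data$subsidy_total)
        ) |>
        dplyr::select(-"w")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(mpce_class = as.character(.data$mpce_class))

  band_sets <- list(
    IP = c("1-3", "4-7", "8-14", "15+"), OP = c("0-14", "15-30", "31-90", "91+")
  )
  strata <- purrr::map_dfr(SERVICES, function(sv) {
    g <- expand.grid(
      state = states, sector = SECTORS, class_idx = 1:4, band_idx = 1:4,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    tibble::tibble(
      service = sv, state = g$state, sector = g$sector,
      mpce_class = MPCE_LEVELS[g$class_idx],
      duration_band = band_sets[[sv]][g$band_idx],
      true_location = true_cost_location(
        config, sv, g$state, g$sector, g$class_idx, g$band_idx
      )
    )
  })

  truth <- structure(
    list(
      gradient = config$gradient,
      strata = strata,
      households = dplyr::select(
        hh, "household_id", "state", "sector", "mpce", "mpce_class"
      ),
      cutpoints = cuts,
      episodes = ep_truth,
      benefit = benefit_truth
    ),
    class = "sim_truth"
  )
  list(dataset = dataset, truth = truth)
}

# vectorized over mixed facilities: one lognormal draw per episode
draw_oope_mixed <- function(n, location, facility, service, config) {
  total <- numeric(n)
  priv <- facility == "private"
  s <- config$sigma_private
  d <- config$private_noise_mode[[service]]
  total[priv] <- location[priv] - d +
    rlnorm(sum(priv), meanlog = log(d) + s^2, sdlog = s)
  sp <- config$sigma_public
  total[!priv] <- rlnorm(
    sum(!priv),
    meanlog = log(config$public_fraction * location[!priv]) - sp^2 / 2,
    sdlog = sp
  )
  split_components(
    total, config$oope_props[[service]], config$prop_concentration
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf(
    "  gradient g = %.3f; %d strata; %d episodes (%d elderly-NCD public)\n",
    x$gradient, nrow(x$strata), nrow(x$episodes),
    sum(x$episodes$elderly & x$episodes$all_ncd &
      x$episodes$facility == "public")
  ))
  invisible(x)
}

#' True concentration index of the planted subsidy
#'
#' The grouped-formula concentration index over the planted class shares of
#' total subsidy, taken over the subsidy-receiving population (the elderly
#' NCD public-facility episodes). Population shares are the classes'
#' planted weight shares of that recipient population — not fixed quarters,
#' because household size and utilization make the recipient population's
#' class composition differ from the overall population's quartiles. This
#' is exactly the grouped analogue of the micro index estimated by
#' [concentration_analysis()], so it is the recoverable target for
#' parameter-recovery checks. Classes with no planted recipients are
#' dropped (their benefit share is necessarily zero too).
#'
#' @param truth A `sim_truth` from [simulate_survey()].
#' @param service `"IP"` or `"OP"`.
#' @param sector `"rural"`, `"urban"` or `"combine"`.
#' @return The true grouped concentration index.
#' @export
true_concentration_index <- function(truth, service = "IP",
                                     sector = "combine") {
  stopifnot(inherits(truth, "sim_truth"))
  b <- truth$benefit |>
    dplyr::filter(.data$service == !!service, .data$sector == !!sector) |>
    dplyr::arrange(match(.data$mpce_class, MPCE_LEVELS)) |>
    dplyr::filter(.data$delta > 0)
  if (nrow(b) == 0 || anyNA(b$subsidy_share)) {
    abort("true_concentration_index(): no planted benefit shares for this service/sector.")
  }
  grouped_concentration_index(
    b$subsidy_share / sum(b$subsidy_share),
    b$delta / sum(b$delta)
  )
}

#' Write a synthetic dataset (and its truth) to disk
#'
#' Writes the four canonical CSVs plus a `truth.json` summary (stratum
#' locations, class benefit shares, gradient, true indices) into `dir`.
#'
#' @param sim Output of [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  for (nm in names(ds)) {
    readr::write_csv(ds[[nm]], file.path(dir, paste0(nm, ".csv")),
      progress = FALSE
    )
  }
  truth <- sim$truth
  true_ci <- tryCatch(
    list(
      IP = true_concentration_index(truth, "IP", "combine"),
      OP = true_concentration_index(truth, "OP", "combine")
    ),
    error = function(e) NULL
  )
  jsonlite::write_json(
    list(
      gradient = truth$gradient,
      strata = truth$strata,
      benefit = truth$benefit,
      true_concentration_index = true_ci
    ),
    file.path(dir, "truth.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
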