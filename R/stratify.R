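# Socio-economic stratification: equivalized monthly per-capita expenditure
# (MPCE), per-(state, sector) survey-weighted quartile classes, the
# CD/NCD/OD ailment grouping, and the elderly/NCD episode selection rules.

#' Equivalized monthly per-capita expenditure
#'
#' Applies the OECD square-root equivalence scale: household total monthly
#' expenditure divided by the square root of household size,
#' `mpce = T / sqrt(N)`.
#'
#' @param total_expenditure Household total monthly expenditure (T, INR).
#' @param household_size Household size (N, positive integer).
#' @return Numeric MPCE, same length as the inputs.
#' @examples
#' equivalized_mpce(10000, 4) # 5000
#' @export
equivalized_mpce <- function(total_expenditure, household_size) {
  if (any(household_size < 1, na.rm = TRUE)) {
    abort("equivalized_mpce(): household_size must be >= 1.")
  }
  total_expenditure / sqrt(household_size)
}

#' Survey-weighted MPCE quartile cutpoints per (state, sector)
#'
#' Computes cutpoints at cumulative weight shares 0.25/0.50/0.75 of the
#' left-continuous inverse weighted CDF (see [weighted_quantile()]), over
#' HOUSEHOLDS (one record per household), separately within every
#' (state, sector) cell. Cost of living differs across states and between
#' the rural and urban sector, which is why classes are formed within cells
#' rather than nationally.
#'
#' @param households Household table with `state`, `sector`,
#'   `total_monthly_expenditure`, `household_size`, `weight`.
#' @param min_cell Minimum households per cell for the cell to be usable
#'   (default 4, one per quartile).
#' @return Tibble with `state`, `sector`, `q25`, `q50`, `q75`,
#'   `n_households`, `usable`.
#' @export
mpce_cutpoints <- function(households, min_cell = 4) {
  stop_if_missing_cols(households, HOUSEHOLD_COLS, "`households`")
  hh <- households |>
    dplyr::mutate(
      mpce = equivalized_mpce(
        .data$total_monthly_expenditure, .data$household_size
      )
    ) |>
    dplyr::filter(!is.na(.data$mpce), !is.na(.data$weight))
  cuts <- hh |>
    dplyr::group_by(.data$state, .data$sector) |>
    dplyr::summarise(
      n_households = dplyr::n(),
      q25 = if (dplyr::n() >= min_cell) {
        weighted_quantile(.data$mpce, .data$weight, 0.25)
      } else {
        NA_real_
      },
      q50 = if (dplyr::n() >= min_cell) {
        weighted_quantile(.data$mpce, .data$weight, 0.50)
      } else {
        NA_real_
      },
      q75 = if (dplyr::n() >= min_cell) {
        weighted_quantile(.data$mpce, .data$weight, 0.75)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(usable = !is.na(.data$q25))
  if (any(!cuts$usable)) {
    warn(sprintf(
      "%d (state, sector) cell(s) have fewer than %d households; omitted",
      sum(!cuts$usable), min_cell
    ))
  }
  dplyr::select(
    cuts, "state", "sector", "q25", "q50", "q75", "n_households", "usable"
  )
}

#' Assign an MPCE quartile class given cutpoints
#'
#' Labels: `P` if `mpce <= q25`; `LM` if `q25 < mpce <= q50`; `UM` if
#' `q50 < mpce <= q75`; else `R`. Ties go down, so a value exactly at a
#' cutpoint takes the poorer label, and with fully collapsed cutpoints
#' (q25 = q50 = q75) a value at the common cutpoint is `P`.
#'
#' @param mpce Numeric MPCE values.
#' @param q25,q50,q75 Cutpoints (scalars or vectors matching `mpce`).
#' @return Factor with levels `P`, `LM`, `UM`, `R`.
#' @export
assign_class <- function(mpce, q25, q50, q75) {
  lab <- ifelse(mpce <= q25, "P",
    ifelse(mpce <= q50, "LM", ifelse(mpce <= q75, "UM", "R"))
  )
  lab[is.na(mpce) | is.na(q25)] <- NA
  factor(lab, levels = MPCE_LEVELS)
}

#' Classify households (and thus their members) into MPCE classes
#'
#' Households are the classified unit: each household gets an MPCE value and
#' a class from its (state, sector) cutpoints, and members inherit the
#' household's class. Households in cells with too few observations for
#' cutpoints are excluded with a warning count.
#'
#' @param dataset A `survey_dataset`.
#' @param min_cell Passed to [mpce_cutpoints()].
#' @return An `mpce_classification`: list with `cutpoints` and a
#'   `households` tibble (`household_id`, `state`, `sector`, `mpce`,
#'   `mpce_class`).
#' @export
classify_mpce <- function(dataset, min_cell = 4) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cuts <- mpce_cutpoints(dataset$households, min_cell = min_cell)
  hh <- dataset$households |>
    dplyr::mutate(
      mpce = equivalized_mpce(
        .data$total_monthly_expenditure, .data$household_size
      )
    ) |>
    dplyr::left_join(
      dplyr::filter(cuts, .data$usable),
      by = c("state", "sector")
    ) |>
    dplyr::mutate(
      mpce_class = assign_class(.data$mpce, .data$q25, .data$q50, .data$q75)
    )
  n_excluded <- sum(is.na(hh$mpce_class))
  if (n_excluded > 0) {
    warn(sprintf(
      "%d household(s) without a usable (state, sector) cell excluded from classification",
      n_excluded
    ))
  }
  structure(
    list(
      cutpoints = cuts,
      households = dplyr::select(
        hh, "household_id", "state", "sector", "mpce", "mpce_class"
      )
    ),
    class = "mpce_classification"
  )
}

#' @export
print.mpce_classification <- function(x, ...) {
  cat("<mpce_classification>\n")
  cat(sprintf(
    "  %d (state, sector) cells (%d usable), %d households classified\n",
    nrow(x$cutpoints), sum(x$cutpoints$usable),
    sum(!is.na(x$households$mpce_class))
  ))
  invisible(x)
}

#' Load an ailment-code grouping map
#'
#' The map is a JSON object `{"code": "CD"|"NCD"|"OD", ...}` partitioning the
#' configured ailment-code universe into communicable (CD), noncommunicable
#' (NCD) and other (OD) disease groups. Duplicate codes with conflicting
#' groups make the config invalid. The packaged default
#' (`ailment_map_default.json`) is an illustrative grouping of common survey
#' ailment labels, meant to be replaced by the user's own coding frame.
#'
#' @param path Path to the JSON map; default is the packaged map.
#' @return Named character vector `code -> group`.
#' @export
load_ailment_map <- function(path = system.file("extdata",
                               "ailment_map_default.json",
                               package = "biatools"
                             )) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- unlist(raw)
  if (anyDuplicated(names(map)) > 0) {
    dup <- unique(names(map)[duplicated(names(map))])
    conflicting <- vapply(
      dup, function(d) length(unique(map[names(map) == d])) > 1, logical(1)
    )
    if (any(conflicting)) {
      abort(sprintf(
        "Ailment map has overlapping entries with conflicting groups: %s",
        paste(dup[conflicting], collapse = ", ")
      ))
    }
    map <- map[!duplicated(names(map))]
  }
  bad <- setdiff(unique(map), AILMENT_GROUPS)
  if (length(bad) > 0) {
    abort(sprintf(
      "Ailment map contains unknown group(s): %s", paste(bad, collapse = ", ")
    ))
  }
  map
}

#' Classify ailment codes into CD / NCD / OD
#'
#' Deterministic lookup in the ailment map. Codes absent from the map fall
#' into the residual `OD` group (the catch-all for conditions that cannot be
#' classified as NCD or CD) with a warning reporting how many.
#'
#' @param codes Character vector of ailment codes.
#' @param ailment_map Named vector from [load_ailment_map()].
#' @return Factor with levels `CD`, `NCD`, `OD`.
#' @export
classify_ailment <- function(codes, ailment_map) {
  grp <- unname(ailment_map[codes])
  unmapped <- is.na(grp) & !is.na(codes)
  if (any(unmapped)) {
    warn(sprintf(
      "%d ailment code(s) not in the map assigned to residual group OD",
      sum(unmapped)
    ))
    grp[unmapped] <- "OD"
  }
  factor(grp, levels = AILMENT_GROUPS)
}

split_visit_codes <- function(x) strsplit(x, ";", fixed = TRUE)

# group of a multi-visit spell for descriptive tabulations: the common group
# of all visits, else the residual OD group
spell_group <- function(visit_codes, ailment_map) {
  vapply(split_visit_codes(visit_codes), function(codes) {
    g <- unique(as.character(classify_ailment(codes, ailment_map)))
    if (length(g) == 1L) g else "OD"
  }, character(1))
}

annotate_episodes <- function(dataset, classification) {
  ind <- dataset$individuals |>
    dplyr::select("person_id", "household_id", "age")
  hh <- classification$households
  join_person <- function(df) {
    df |>
      dplyr::inner_join(ind, by = "person_id") |>
      dplyr::inner_join(hh, by = "household_id") |>
      dplyr::filter(!is.na(.data$mpce_class))
  }
  list(ip = join_person(dataset$inpatient), op = join_person(dataset$outpatient))
}

#' Select elderly episodes and apply the NCD restriction
#'
#' Annotates inpatient episodes and outpatient spells with age, state,
#' sector, MPCE and class, then applies the study's selection rules:
#' individuals aged `age_min` (default 60) and above; for the NCD subset,
#' inpatient episodes whose ailment maps to NCD, and outpatient spells in
#' which EVERY visit's ailment maps to NCD (a spell carries one pooled OOPE
#' for all its visits, so spells with any non-NCD visit are excluded
#' entirely). Exclusion counts are reported via messages.
#'
#' @param dataset A `survey_dataset`.
#' @param classification From [classify_mpce()].
#' @param ailment_map From [load_ailment_map()].
#' @param age_min Elderly age threshold, inclusive (default 60).
#' @return List of tibbles: `ip_elderly`, `op_elderly` (all elderly episodes
#'   with an `ailment_group` column), `ip_ncd`, `op_ncd` (the NCD subsets).
#' @export
select_elderly_ncd <- function(dataset, classification, ailment_map,
                               age_min = 60) {
  ann <- suppressWarnings(annotate_episodes(dataset, classification))
  ip_elderly <- ann$ip |>
    dplyr::filter(.data$age >= age_min) |>
    dplyr::mutate(
      ailment_group = classify_ailment(.data$ailment_code, ailment_map),
      service = "IP"
    )
  op_elderly <- ann$op |>
    dplyr::filter(.data$age >= age_min) |>
    dplyr::mutate(
      ailment_group = factor(
        spell_group(.data$visit_ailment_codes, ailment_map),
        levels = AILMENT_GROUPS
      ),
      all_ncd = vapply(
        split_visit_codes(.data$visit_ailment_codes),
        function(codes) {
          all(as.character(classify_ailment(codes, ailment_map)) == "NCD")
        },
        logical(1)
      ),
      service = "OP"
    )
  ip_ncd <- dplyr::filter(ip_elderly, .data$ailment_group == "NCD")
  op_ncd <- dplyr::filter(op_elderly, .data$all_ncd)
  inform(sprintf(
    "Elderly selection: %d IP episodes (%d NCD), %d OP spells (%d all-visit NCD, %d excluded by the all-visits rule)",
    nrow(ip_elderly), nrow(ip_ncd), nrow(op_elderly), nrow(op_ncd),
    nrow(op_elderly) - nrow(op_ncd)
  ))
  list(
    ip_elderly = ip_elderly, op_elderly = op_elderly,
    ip_ncd = ip_ncd, op_ncd = op_ncd
  )
}
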