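# Fixture builders shared across test files. Everything is constructed in
# code; nothing is read from disk except files the tests write themselves.

oope_cols <- function(medicine = 0, other_medical = 0, transport = 0,
                      other_nonmedical = 0) {
  tibble::tibble(
    oope_medicine = medicine,
    oope_other_medical = other_medical,
    oope_transport = transport,
    oope_other_nonmedical = other_nonmedical
  )
}

# a tiny fully valid linked dataset: 3 households, 5 individuals (two aged
# 60+), 3 inpatient episodes, 2 outpatient spells
tiny_dataset <- function() {
  households <- tibble::tibble(
    household_id = c("h1", "h2", "h3"),
    state = c("S01", "S01", "S01"),
    sector = c("rural", "rural", "urban"),
    total_monthly_expenditure = c(4000, 16000, 9000),
    household_size = c(4, 4, 1),
    weight = c(2, 1, 1.5)
  )
  individuals <- tibble::tibble(
    person_id = c("p1", "p2", "p3", "p4", "p5"),
    household_id = c("h1", "h1", "h2", "h3", "h3"),
    age = c(70, 30, 64, 59, 61),
    sex = c("female", "male", "male", "female", "female"),
    weight = c(2, 2, 1, 1.5, 1.5)
  )
  inpatient <- dplyr::bind_cols(
    tibble::tibble(
      episode_id = c("e1", "e2", "e3"),
      person_id = c("p1", "p3", "p4"),
      ailment_code = c("diabetes", "tuberculosis", "diabetes"),
      facility = c("public", "private", "public"),
      stay_days = c(5, 2, 10)
    ),
    oope_cols(
      medicine = c(100, 400, 250), other_medical = c(50, 300, 100),
      transport = c(20, 10, 30), other_nonmedical = c(5, 0, 0)
    ),
    tibble::tibble(weight = c(2, 1, 1.5))
  )
  outpatient <- dplyr::bind_cols(
    tibble::tibble(
      spell_id = c("s1", "s2"),
      person_id = c("p1", "p5"),
      visit_ailment_codes = c("diabetes;hypertension", "diabetes;malaria"),
      ailment_duration_days = c(40, 10),
      facility = c("public", "private")
    ),
    oope_cols(
      medicine = c(150, 80), other_medical = c(40, 20),
      transport = c(10, 5), other_nonmedical = c(0, 0)
    ),
    tibble::tibble(weight = c(2, 1.5))
  )
  survey_dataset(households, individuals, inpatient, outpatient)
}

write_dataset_csvs <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(dataset)) {
    readr::write_csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
      progress = FALSE
    )
  }
  survey_paths(
    households = file.path(dir, "households.csv"),
    individuals = file.path(dir, "individuals.csv"),
    inpatient = file.path(dir, "inpatient.csv"),
    outpatient = file.path(dir, "outpatient.csv")
  )
}

# random public-episode fixture for benefit/concentration property tests:
# episodes carrying class, mpce, gamma, weight and household ids
random_subsidy_fixture <- function(n, seed) {
  set.seed(seed)
  cls <- sample(c("P", "LM", "UM", "R"), n, replace = TRUE)
  mpce <- c(P = 1000, LM = 2000, UM = 3000, R = 4000)[cls] + runif(n, 0, 900)
  tibble::tibble(
    service = "IP",
    sector = sample(c("rural", "urban"), n, replace = TRUE),
    state = "S01",
    mpce_class = cls,
    mpce = mpce,
    gamma = rgamma(n, shape = 2, scale = 500),
    weight = runif(n, 0.5, 2),
    clamped = FALSE,
    household_id = sprintf("h%d", sample.int(max(2, n %/% 2), n, replace = TRUE))
  )
}

# independent oracle: the benefit-incidence formula evaluated by explicit
# loops, pi_j = delta_j * sum_{k in j} w_k * gamma_k
brute_force_benefit <- function(episodes) {
  out <- list()
  for (svc in unique(episodes$service)) {
    for (sec in c(unique(episodes$sector), "combine")) {
      sub <- episodes[episodes$service == svc &
        (episodes$sector == sec | sec == "combine"), ]
      if (nrow(sub) == 0) next
      denom <- sum(sub$weight)
      pis <- c()
      for (cl in c("P", "LM", "UM", "R")) {
        members <- sub[sub$mpce_class == cl, ]
        delta <- sum(members$weight) / denom
        pis[cl] <- delta * sum(members$weight * members$gamma)
      }
      out[[paste(svc, sec)]] <- tibble::tibble(
        service = svc, sector = sec, mpce_class = names(pis),
        pi_bf = unname(pis), share_bf = 100 * unname(pis) / sum(pis)
      )
    }
  }
  dplyr::bind_rows(out)
}

# independent oracle: twice the trapezoid area between the diagonal and the
# piecewise-linear concentration curve
trapezoid_index <- function(curve) {
  x <- curve$pop_share
  y <- curve$benefit_share
  n <- length(x)
  2 * sum(diff(x) * ((x[-1] + x[-n]) - (y[-1] + y[-n])) / 2)
}
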