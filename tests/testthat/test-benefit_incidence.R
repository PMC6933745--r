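test_that("duration bands respect their edges and open top", {
  expect_equal(duration_band("IP", 3), "1-3")
  expect_equal(duration_band("IP", 4), "4-7")
  expect_equal(duration_band("OP", 14), "0-14")
  expect_equal(duration_band("OP", 15), "15-30")
  expect_equal(duration_band("IP", 400), "15+")
  expect_error(duration_band("OP", -1), "negative")
  expect_error(duration_band("IP", 0), "at least 1 day")
})

private_fixture <- function(totals, weights = rep(1, length(totals)),
                            band = "1-3", class = "P", sector = "rural",
                            service = "IP") {
  tibble::tibble(
    service = service, state = "S01", sector = sector,
    mpce_class = class, duration_band = band,
    total = totals, weight = weights
  )
}

test_that("modal cost is the weighted mean of the maximal bin, ties to lower", {
  mc <- modal_private_cost(
    private_fixture(c(500, 500, 700)),
    min_cell_size = 1, ip_bin = 100
  )
  expect_equal(mc$modal_cost, 500)
  expect_equal(mc$pooling_level, "full")

  # two singleton bins tie: the lower bin wins
  mc2 <- modal_private_cost(
    private_fixture(c(100, 900)),
    min_cell_size = 1, ip_bin = 100
  )
  expect_equal(mc2$modal_cost, 100)

  # weights decide the maximal bin
  mc3 <- modal_private_cost(
    private_fixture(c(100, 900, 900), weights = c(5, 1, 1)),
    min_cell_size = 1, ip_bin = 100
  )
  expect_equal(mc3$modal_cost, 100)
})

test_that("sparse strata pool up the fallback ladder with recorded provenance", {
  eps <- dplyr::bind_rows(
    private_fixture(c(1000, 1000, 1200, 1300, 1400), band = "1-3"),
    private_fixture(c(5000, 5200), band = "15+")
  )
  mc <- suppressMessages(modal_private_cost(eps, min_cell_size = 5, ip_bin = 500))
  full_row <- mc[mc$duration_band == "1-3", ]
  expect_equal(full_row$pooling_level, "full")
  expect_equal(full_row$modal_cost, mean(c(1000, 1000, 1200, 1300, 1400)[
    floor(c(1000, 1000, 1200, 1300, 1400) / 500) ==
      1000 %/% 500
  ]))
  pooled_row <- mc[mc$duration_band == "15+", ]
  expect_equal(pooled_row$pooling_level, "drop_duration")
  # hand-pooled mode over all 7 values: bin [1000,1500) holds 5 of 7
  expect_equal(
    pooled_row$modal_cost, mean(c(1000, 1000, 1200, 1300, 1400))
  )
  expect_error(
    modal_private_cost(private_fixture(numeric(0))), "no private episodes"
  )
})

test_that("net subsidy subtracts user charges from the modal proxy", {
  mc <- modal_private_cost(
    private_fixture(rep(20000, 6)),
    min_cell_size = 5, ip_bin = 500
  )
  pub <- private_fixture(4374)
  out <- net_subsidy(pub, mc)
  expect_equal(out$gamma, 20000 - 4374)
  expect_false(out$clamped)

  mc_low <- modal_private_cost(
    private_fixture(rep(1000, 6)),
    min_cell_size = 5, ip_bin = 500
  )
  pub2 <- private_fixture(2500)
  clamped <- suppressMessages(net_subsidy(pub2, mc_low, clamp = TRUE))
  expect_equal(clamped$gamma, 0)
  expect_true(clamped$clamped)
  raw <- net_subsidy(pub2, mc_low, clamp = FALSE)
  expect_equal(raw$gamma, -1500)
})

test_that("utilization rates are weighted class shares summing to one", {
  eps <- tibble::tibble(
    service = "IP", sector = "rural",
    mpce_class = c("P", "P", "LM", "UM"),
    weight = c(1, 1, 1, 1)
  )
  # weighted counts (2, 1, 1, 0) over 4
  r <- utilization_rates(eps)
  rural <- r[r$sector == "rural", ]
  expect_equal(
    rural$delta[match(c("P", "LM", "UM", "R"), rural$mpce_class)],
    c(0.5, 0.25, 0.25, 0)
  )
  expect_equal(sum(rural$delta), 1)

  single <- utilization_rates(
    tibble::tibble(
      service = "IP", sector = "rural", mpce_class = "P", weight = 2
    )
  )
  expect_equal(
    single$delta[single$sector == "rural"][
      match(c("P", "LM", "UM", "R"),
        single$mpce_class[single$sector == "rural"])
    ],
    c(1, 0, 0, 0)
  )
  expect_error(utilization_rates(eps[0, ]), "empty")
})

subsidy_fixture <- function(classes, gammas, weights = rep(1, length(classes))) {
  tibble::tibble(
    service = "IP", sector = "rural", mpce_class = classes,
    gamma = gammas, weight = weights, clamped = FALSE
  )
}

test_that("benefit shares implement the rate-weighted formula", {
  # equal subsidy, equal rates: symmetric shares
  b <- benefit_incidence_shares(
    subsidy_fixture(c("P", "LM", "UM", "R"), rep(100, 4))
  )
  rural <- b[b$sector == "rural", ]
  expect_equal(rural$share_pct, rep(25, 4))

  # equal class subsidy sums but delta = (0.4, 0.3, 0.2, 0.1):
  # pi_j is proportional to delta_j, so shares are (40, 30, 20, 10)
  eps <- subsidy_fixture(
    rep(c("P", "LM", "UM", "R"), times = c(4, 3, 2, 1)),
    gammas = rep(c(25, 100 / 3, 50, 100), times = c(4, 3, 2, 1))
  )
  b2 <- benefit_incidence_shares(eps)
  r2 <- b2[b2$sector == "rural", ]
  expect_equal(
    r2$share_pct[match(c("P", "LM", "UM", "R"), r2$mpce_class)],
    c(40, 30, 20, 10)
  )
  # the unweighted variant gives plain subsidy-sum shares (all equal here)
  b2u <- benefit_incidence_shares(eps, rate_weighted = FALSE)
  r2u <- b2u[b2u$sector == "rural", ]
  expect_equal(r2u$share_pct, rep(25, 4))

  # one class holds all subsidy
  b3 <- benefit_incidence_shares(
    subsidy_fixture(c("P", "LM", "R"), c(0, 0, 500))
  )
  r3 <- b3[b3$sector == "rural", ]
  expect_equal(r3$share_pct[r3$mpce_class == "R"], 100)

  # zero total subsidy: shares undefined, with a warning
  expect_warning(
    bz <- benefit_incidence_shares(subsidy_fixture(c("P", "R"), c(0, 0))),
    "undefined"
  )
  expect_true(all(is.na(bz$share_pct)))
})

test_that("pipeline shares equal a brute-force evaluation of the formula", {
  for (seed in 1:5) {
    eps <- random_subsidy_fixture(n = sample(5:30, 1), seed = seed)
    b <- benefit_incidence_shares(eps)
    bf <- brute_force_benefit(eps)
    m <- dplyr::inner_join(
      b, bf,
      by = c("service", "sector", "mpce_class")
    )
    expect_equal(m$pi, m$pi_bf, tolerance = 1e-12)
    expect_equal(m$share_pct, m$share_bf, tolerance = 1e-12)
    sums <- b |>
      dplyr::group_by(.data$service, .data$sector) |>
      dplyr::summarise(s = sum(.data$share_pct), .groups = "drop")
    expect_true(all(abs(sums$s - 100) < 0.01))
    expect_true(all(b$share_pct >= 0 & b$share_pct <= 100))
  }
})
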