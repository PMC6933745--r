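test_that("OOPE decomposition is cumulative: medicine, medical, total", {
  expect_equal(
    as.list(oope_components(100, 50, 20, 5)),
    list(medicine = 100, medical = 150, total = 175)
  )
  expect_equal(unlist(oope_components(0, 0, 0, 0)), c(
    medicine = 0, medical = 0, total = 0
  ))
  expect_equal(
    as.list(oope_components(0, 200, 0, 0)),
    list(medicine = 0, medical = 200, total = 200)
  )
})

make_selection <- function(ip_weights, ip_classes,
                           ip_facility = rep("public", length(ip_weights)),
                           ip_sector = rep("rural", length(ip_weights))) {
  n <- length(ip_weights)
  ip <- dplyr::bind_cols(
    tibble::tibble(
      episode_id = sprintf("e%d", 1:n),
      service = "IP",
      sector = ip_sector,
      state = "S01",
      ailment_group = factor("NCD", levels = c("CD", "NCD", "OD")),
      mpce_class = factor(ip_classes, levels = c("P", "LM", "UM", "R")),
      facility = ip_facility,
      stay_days = 3,
      weight = ip_weights
    ),
    oope_cols(
      medicine = seq(100, by = 50, length.out = n),
      other_medical = 50, transport = 10, other_nonmedical = 5
    )
  )
  empty_op <- ip[0, ]
  list(
    ip_elderly = ip, op_elderly = empty_op,
    ip_ncd = ip, op_ncd = empty_op
  )
}

test_that("utilization shares are weighted and sum to 100", {
  sel <- make_selection(rep(1, 4), c("P", "LM", "UM", "R"))
  tab <- suppressWarnings(utilization_table(sel))
  cls <- dplyr::filter(tab, .data$panel == "ncd_class", .data$sector == "rural")
  expect_equal(cls$share_pct, rep(25, 4))

  sel2 <- make_selection(c(1, 1, 1, 7), c("P", "LM", "UM", "R"))
  tab2 <- suppressWarnings(utilization_table(sel2))
  cls2 <- dplyr::filter(
    tab2, .data$panel == "ncd_class", .data$sector == "rural"
  )
  expect_equal(cls2$share_pct[match(c("P", "LM", "UM", "R"), cls2$group)],
    c(10, 10, 10, 70))
  sums <- tab2 |>
    dplyr::group_by(.data$panel, .data$service, .data$sector) |>
    dplyr::summarise(s = sum(.data$share_pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 0.01))
})

test_that("combine pools rural and urban weights rather than averaging columns", {
  sel <- make_selection(
    c(1, 1, 6, 2), c("P", "R", "P", "R"),
    ip_sector = c("rural", "rural", "urban", "urban")
  )
  tab <- suppressWarnings(utilization_table(sel))
  comb <- dplyr::filter(
    tab, .data$panel == "ncd_class", .data$sector == "combine"
  )
  # pooled weights: P = 1 + 6 = 7 of 10; an average of sector columns would
  # give (50 + 75) / 2 = 62.5 instead
  expect_equal(comb$share_pct[comb$group == "P"], 70)
})

test_that("empty public universe emits a warning and no panel rows", {
  sel <- make_selection(rep(1, 4), c("P", "LM", "UM", "R"),
    ip_facility = rep("private", 4)
  )
  expect_warning(tab <- utilization_table(sel), "empty universe")
  expect_equal(nrow(dplyr::filter(tab, .data$panel == "ncd_public_class")), 0)
})

test_that("mean OOPE cells are weighted means with an All row", {
  sel <- make_selection(c(3, 1, 3, 1), c("P", "P", "R", "R"))
  # override totals: two P episodes with totals 100 and 300, weights 3 and 1
  sel$ip_ncd$oope_medicine <- c(100, 300, 100, 300)
  sel$ip_ncd$oope_other_medical <- 0
  sel$ip_ncd$oope_transport <- 0
  sel$ip_ncd$oope_other_nonmedical <- 0
  tab <- mean_oope_table(sel)
  p_row <- dplyr::filter(tab, .data$mpce_class == "P")
  expect_equal(p_row$total, (3 * 100 + 1 * 300) / 4)
  all_row <- dplyr::filter(tab, .data$mpce_class == "All")
  expect_equal(all_row$total, (3 * 100 + 300 + 3 * 100 + 300) / 8)
  # single episode: weights cancel
  sel1 <- make_selection(3, "P")
  sel1$ip_ncd$oope_medicine <- 100
  sel1$ip_ncd$oope_other_medical <- 50
  sel1$ip_ncd$oope_transport <- 20
  sel1$ip_ncd$oope_other_nonmedical <- 5
  tab1 <- mean_oope_table(sel1)
  expect_equal(
    unlist(tab1[tab1$mpce_class == "P", c("medicine", "medical", "total")]),
    c(medicine = 100, medical = 150, total = 175)
  )
})

test_that("component ordering and weight-scale invariance hold on random fixtures", {
  set.seed(7)
  for (rep_i in 1:5) {
    n <- 20
    sel <- make_selection(
      runif(n, 0.5, 2), sample(c("P", "LM", "UM", "R"), n, replace = TRUE),
      ip_facility = sample(c("public", "private"), n, replace = TRUE),
      ip_sector = sample(c("rural", "urban"), n, replace = TRUE)
    )
    sel$ip_ncd$oope_medicine <- runif(n, 0, 500)
    sel$ip_ncd$oope_other_medical <- runif(n, 0, 500)
    sel$ip_ncd$oope_transport <- runif(n, 0, 100)
    sel$ip_ncd$oope_other_nonmedical <- runif(n, 0, 100)
    sel$ip_elderly <- sel$ip_ncd
    tab <- mean_oope_table(sel)
    expect_true(all(tab$medicine <= tab$medical + 1e-9))
    expect_true(all(tab$medical <= tab$total + 1e-9))

    sel2 <- sel
    sel2$ip_ncd$weight <- sel2$ip_ncd$weight * 2
    sel2$ip_elderly <- sel2$ip_ncd
    expect_equal(mean_oope_table(sel2)$total, tab$total)
    u1 <- suppressWarnings(utilization_table(sel))
    u2 <- suppressWarnings(utilization_table(sel2))
    expect_equal(u1$share_pct, u2$share_pct)
  }
})
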