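test_that("fractional ranks are weighted midpoints with stable ties", {
  expect_equal(fractional_rank(c(10, 20), c(1, 1)), c(0.25, 0.75))
  expect_equal(fractional_rank(c(10, 20), c(1, 3)), c(0.125, 0.625))
  expect_equal(fractional_rank(5, 2), 0.5)
  # ties spread by the stable secondary key, in input order
  expect_equal(fractional_rank(c(7, 7, 7, 7), rep(1, 4)),
    c(0.125, 0.375, 0.625, 0.875))
  # ranks returned in input order
  expect_equal(fractional_rank(c(20, 10), c(1, 1)), c(0.75, 0.25))
})

test_that("covariance-form index matches hand-computed two-point cases", {
  r <- fractional_rank(c(1, 2), c(1, 1))
  expect_equal(concentration_index(c(0, 1), r, c(1, 1)), 0.5)
  expect_equal(concentration_index(c(1, 0), r, c(1, 1)), -0.5)
  expect_equal(concentration_index(c(3, 3), r, c(1, 1)), 0)
  expect_warning(
    ci <- concentration_index(c(0, 0), r, c(1, 1)), "undefined"
  )
  expect_true(is.na(ci))
})

test_that("convenient regression slope equals the covariance form exactly", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(10:200, 1)
    h <- rgamma(n, 2, 1)
    w <- runif(n, 0.5, 2)
    x <- rnorm(n)
    r <- fractional_rank(x, w)
    reg <- convenient_regression(h, r, w)
    expect_equal(reg$index, concentration_index(h, r, w), tolerance = 1e-10)
    expect_true(reg$robust_se >= 0)
    expect_true(reg$p_value >= 0 && reg$p_value <= 1)
  }
  # constant h: slope 0 and no evidence against the null
  r <- fractional_rank(1:10, rep(1, 10))
  reg0 <- suppressWarnings(convenient_regression(rep(2, 10), r, rep(1, 10)))
  expect_equal(reg0$index, 0)
  expect_equal(reg0$p_value, 1)
  # household-clustered SEs are computable and finite
  set.seed(12)
  h <- rgamma(40, 2)
  w <- runif(40, 0.5, 2)
  r <- fractional_rank(rnorm(40), w)
  regc <- convenient_regression(h, r, w, cluster = rep(1:10, each = 4))
  expect_true(is.finite(regc$robust_se))
})

test_that("concentration curve runs (0,0) to (1,1), monotone, and hits published cumulants", {
  set.seed(5)
  h <- rgamma(30, 2)
  x <- rnorm(30)
  w <- runif(30, 0.5, 2)
  cv <- concentration_curve(h, x, w)
  expect_equal(cv$pop_share[1], 0)
  expect_equal(cv$benefit_share[1], 0)
  expect_equal(cv$pop_share[nrow(cv)], 1)
  expect_equal(cv$benefit_share[nrow(cv)], 1)
  expect_true(all(diff(cv$pop_share) >= 0))
  expect_true(all(diff(cv$benefit_share) >= -1e-12))

  # constant h: the curve is the diagonal at every vertex
  cvc <- concentration_curve(rep(1, 10), 1:10, rep(1, 10))
  expect_equal(cvc$benefit_share, cvc$pop_share)

  # all subsidy on the richest record: flat then a jump to 1
  cve <- concentration_curve(c(0, 0, 0, 5), 1:4, rep(1, 4))
  expect_equal(cve$benefit_share, c(0, 0, 0, 0, 1))

  # published reference shares as four grouped pseudo-records: the rural IP
  # curve passes through the cumulated shares
  ref <- reference_benefit_shares()
  s <- ref[ref$service == "IP" & ref$sector == "rural", ]
  s <- s[match(c("P", "LM", "UM", "R"), s$mpce_class), ]
  cvr <- concentration_curve(s$share_pct, 1:4, rep(1, 4))
  expect_equal(cvr$pop_share, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cvr$benefit_share, c(0, 0.0990, 0.3774, 0.6437, 1),
    tolerance = 1e-6
  )
})

test_that("index equals twice the trapezoid area between curve and diagonal", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(c(10, 100, 1000), 1)
    h <- rgamma(n, 2)
    x <- rnorm(n)
    w <- runif(n, 0.5, 2)
    C <- concentration_index(h, fractional_rank(x, w), w)
    expect_equal(C, trapezoid_index(concentration_curve(h, x, w)),
      tolerance = 1e-6
    )
  }
})

test_that("grouped index matches hand-derived extremes and the micro index", {
  expect_equal(grouped_concentration_index(rep(0.25, 4)), 0)
  expect_equal(grouped_concentration_index(c(0, 0, 0, 1)), 0.75)
  expect_equal(grouped_concentration_index(c(1, 0, 0, 0)), -0.75)
  expect_error(grouped_concentration_index(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(grouped_concentration_index(c(-0.5, 0.5, 0.5, 0.5)),
    "nonnegative")

  # group-constant subsidies, contiguous groups: grouped equals micro
  set.seed(31)
  pops <- c(0.3, 0.3, 0.2, 0.2)
  hs <- c(4, 1, 2, 3)
  n_per <- round(pops * 200)
  h <- rep(hs, n_per)
  x <- rep(1:4, n_per)
  w <- rep(1, sum(n_per))
  micro <- concentration_index(h, fractional_rank(x, w), w)
  shares <- hs * pops / sum(hs * pops)
  expect_equal(micro, grouped_concentration_index(shares, pops),
    tolerance = 1e-10
  )
})

test_that("index is scale invariant, bounded, and insensitive to weight rescaling", {
  set.seed(41)
  for (i in 1:5) {
    n <- 50
    h <- rgamma(n, 1.5)
    w <- runif(n, 0.5, 2)
    r <- fractional_rank(rnorm(n), w)
    C <- concentration_index(h, r, w)
    expect_lte(abs(C), 1)
    expect_equal(concentration_index(7.3 * h, r, w), C)
    expect_equal(concentration_index(h, r, 2 * w), C)
  }
})

test_that("the curve side determines the index sign", {
  # poor-first, decreasing subsidy: curve above the diagonal, C < 0
  h <- c(5, 4, 3, 2, 1)
  x <- 1:5
  w <- rep(1, 5)
  cv <- concentration_curve(h, x, w)
  inner <- cv[-c(1, nrow(cv)), ]
  expect_true(all(inner$benefit_share >= inner$pop_share))
  expect_lt(concentration_index(h, fractional_rank(x, w), w), 0)
  # and conversely
  h2 <- rev(h)
  cv2 <- concentration_curve(h2, x, w)
  inner2 <- cv2[-c(1, nrow(cv2)), ]
  expect_true(all(inner2$benefit_share <= inner2$pop_share))
  expect_gt(concentration_index(h2, fractional_rank(x, w), w), 0)
})

test_that("household bootstrap bands are deterministic and honest", {
  eps <- random_subsidy_fixture(80, seed = 13)
  df <- tibble::tibble(
    h = eps$gamma, x = eps$mpce, w = eps$weight,
    household_id = eps$household_id
  )
  b1 <- bootstrap_band(df, B = 100, seed = 5)
  b2 <- bootstrap_band(df, B = 100, seed = 5)
  expect_identical(b1, b2)
  b3 <- bootstrap_band(df, B = 100, seed = 6)
  expect_false(identical(b1, b3))

  # the band contains the point-estimate curve at every grid point
  cv <- concentration_curve(df$h, df$x, df$w)
  est <- stats::approx(cv$pop_share, cv$benefit_share,
    xout = b1$pop_share, rule = 2
  )$y
  expect_true(all(est >= b1$lower - 1e-9 & est <= b1$upper + 1e-9))

  # constant h: zero-width band
  dfc <- df
  dfc$h <- 1
  bc <- bootstrap_band(dfc, B = 100, seed = 5)
  expect_equal(bc$lower, bc$upper)

  # too few households: refuse with a warning
  small <- df[1:5, ]
  small$household_id <- sprintf("h%d", 1:5)
  expect_warning(bs <- bootstrap_band(small, B = 100, seed = 1), "fewer than 10")
  expect_null(bs)
})
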