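# Concentration curves and indices for the distribution of public subsidies
# across the living-standards ranking. The index is the weighted covariance
# form C = (2/mu) * cov_w(h, r), with r the weighted fractional rank of the
# living-standards variable; it equals twice the signed area between the
# concentration curve and the 45-degree line of equality (negative = curve
# above the line = pro-poor). Standard errors come from the "convenient
# regression" of 2*var_w(r)*h/mu on r, whose slope is exactly C, with
# heteroskedasticity-robust (HC1) or household-clustered variance.

#' Weighted fractional ranks
#'
#' Sorts ascending by `x` and assigns each observation the midpoint of its
#' normalized-weight interval: `r_i = sum of earlier normalized weights +
#' half its own`. Ties in `x` are broken by the stable secondary key `ids`
#' (record order by default), so equal values — e.g. a whole MPCE class at
#' one value — spread uniformly within the tied block.
#'
#' @param x Living-standards variable (e.g. equivalized MPCE).
#' @param w Positive weights.
#' @param ids Secondary sort key for ties (default input order).
#' @return Ranks in (0, 1), in the input order of `x`.
#' @export
fractional_rank <- function(x, w, ids = seq_along(x)) {
  if (length(x) == 0) abort("fractional_rank(): empty input.")
  stopifnot(length(w) == length(x), all(w > 0))
  ord <- order(x, ids)
  wn <- w[ord] / sum(w)
  r_sorted <- cumsum(wn) - wn / 2
  r <- numeric(length(x))
  r[ord] <- r_sorted
  r
}

#' Weighted concentration index (covariance form)
#'
#' `C = (2/mu) * sum w~_i (h_i - mu)(r_i - r_bar)` with normalized weights
#' `w~`, `mu` the weighted mean of `h` and `r` the fractional ranks.
#' Bounded in `[-1, 1]` for nonnegative `h` (up to floating tolerance).
#'
#' @param h Nonnegative health/benefit variable (here: net subsidies).
#' @param ranks Fractional ranks from [fractional_rank()].
#' @param w Positive weights.
#' @return The index, or `NA` with a warning when the weighted mean of `h`
#'   is zero (index undefined).
#' @export
concentration_index <- function(h, ranks, w) {
  wn <- w / sum(w)
  mu <- sum(wn * h)
  if (mu == 0) {
    warn("concentration_index(): weighted mean of h is zero; index undefined.")
    return(NA_real_)
  }
  rbar <- sum(wn * ranks)
  (2 / mu) * sum(wn * (h - mu) * (ranks - rbar))
}

#' Concentration index with robust inference (convenient regression)
#'
#' Weighted least squares of `y_i = 2 * var_w(r) * h_i / mu` on the
#' fractional ranks with intercept; the slope equals the covariance-form
#' index exactly. The standard error is heteroskedasticity-robust (HC1) or
#' clustered (CR by `cluster`), and the p-value uses the t distribution
#' with n - 2 degrees of freedom.
#'
#' @inheritParams concentration_index
#' @param cluster Optional cluster ids (e.g. household) for cluster-robust
#'   standard errors; default `NULL` gives HC1.
#' @return List with `index`, `robust_se`, `p_value`, `n_obs`.
#' @export
convenient_regression <- function(h, ranks, w, cluster = NULL) {
  n <- length(h)
  if (n < 3) abort("convenient_regression(): need at least 3 observations.")
  wn <- w / sum(w)
  mu <- sum(wn * h)
  if (mu <= 0) abort("convenient_regression(): weighted mean of h must be > 0.")
  var_r <- weighted_var(ranks, w)
  if (var_r <= 0) abort("convenient_regression(): degenerate rank variable.")
  y <- 2 * var_r * h / mu
  fit <- lm(y ~ ranks, weights = wn)
  vc <- if (is.null(cluster)) {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    sandwich::vcovCL(fit, cluster = cluster, type = "HC1")
  }
  est <- unname(coef(fit)["ranks"])
  se <- sqrt(vc["ranks", "ranks"])
  # a constant h gives a zero-residual fit: slope 0 with no evidence against
  # the null, not a 0/0
  tval <- if (se > 0) est / se else 0
  list(
    index = est,
    robust_se = se,
    p_value = 2 * pt(-abs(tval), df = n - 2),
    n_obs = n
  )
}

#' Concentration curve points
#'
#' After sorting ascending by the living-standards variable, plots the
#' cumulative normalized weight (population share) against the cumulative
#' weighted share of `h`, prepending the origin. The curve is
#' piecewise-linear between points, starts at (0, 0) and ends at (1, 1).
#'
#' @param h Nonnegative benefit variable.
#' @param x Living-standards variable used for ranking.
#' @param w Positive weights.
#' @param ids Tie-break key, as in [fractional_rank()].
#' @return Tibble with `pop_share` and `benefit_share`, first row (0, 0).
#' @export
concentration_curve <- function(h, x, w, ids = seq_along(x)) {
  if (sum(w * h) == 0) {
    abort("concentration_curve(): total benefit is zero; curve undefined.")
  }
  ord <- order(x, ids)
  wn <- w[ord] / sum(w)
  hb <- w[ord] * h[ord]
  tibble::tibble(
    pop_share = c(0, cumsum(wn)),
    benefit_share = c(0, cumsum(hb) / sum(hb))
  )
}

# twice the trapezoid area between the 45-degree line and a piecewise-linear
# concentration curve; used as the geometric cross-check of the index
curve_area_index <- function(curve) {
  x <- curve$pop_share
  y <- curve$benefit_share
  dx <- diff(x)
  # integral of (x - L(x)) dx by trapezoid on the curve's own vertices
  2 * sum(dx * ((x[-1] + x[-length(x)]) / 2 - (y[-1] + y[-length(y)]) / 2))
}

#' Grouped-data concentration index
#'
#' For `T` ordered groups (poorest to richest) with population shares `p`
#' and benefit shares `s` (each summing to 1), the index is
#' `C = sum_{t=1}^{T-1} (P_t * L_{t+1} - P_{t+1} * L_t)` on the cumulative
#' shares `P`, `L`. Equals the micro covariance-form index when the benefit
#' is constant within groups and groups are contiguous in rank.
#'
#' @param benefit_shares Nonnegative group benefit shares, summing to 1.
#' @param population_shares Group population shares, summing to 1; default
#'   equal shares (quartiles).
#' @return The grouped concentration index.
#' @examples
#' grouped_concentration_index(c(0, 0, 0, 1)) # 0.75: all benefit to richest
#' @export
grouped_concentration_index <- function(benefit_shares,
                                        population_shares =
                                          rep(1 / length(benefit_shares),
                                            length(benefit_shares)
                                          )) {
  stopifnot(length(benefit_shares) == length(population_shares))
  if (any(benefit_shares < 0) || any(population_shares <= 0)) {
    abort("grouped_concentration_index(): shares must be nonnegative (population shares positive).")
  }
  if (abs(sum(benefit_shares) - 1) > 1e-6 ||
    abs(sum(population_shares) - 1) > 1e-6) {
    abort("grouped_concentration_index(): shares must each sum to 1.")
  }
  P <- cumsum(population_shares)
  L <- cumsum(benefit_shares)
  t <- seq_len(length(P) - 1)
  sum(P[t] * L[t + 1] - P[t + 1] * L[t])
}

#' Bootstrap band for a concentration curve
#'
#' Households are the resampling unit: `B` resamples of households with
#' replacement, the curve recomputed each time on a fixed grid of
#' population shares, and the band is the pointwise 2.5/97.5 percentile
#' envelope. Deterministic given `seed`.
#'
#' @param episodes Tibble with `h`, `x`, `w` and `household_id`.
#' @param B Number of bootstrap resamples (default 500, minimum 100).
#' @param seed Integer seed (required).
#' @param grid Population-share grid (default 101 points on \[0, 1\]).
#' @return Tibble with `pop_share`, `lower`, `upper`.
#' @export
bootstrap_band <- function(episodes, B = 500, seed,
                           grid = seq(0, 1, length.out = 101)) {
  stopifnot(B >= 100)
  households <- unique(episodes$household_id)
  if (length(households) < 10) {
    warn("bootstrap_band(): fewer than 10 households; band not computed.")
    return(NULL)
  }
  by_hh <- split(seq_len(nrow(episodes)), episodes$household_id)
  curve_on_grid <- function(idx) {
    df <- episodes[idx, ]
    cv <- concentration_curve(df$h, df$x, df$w)
    stats::approx(cv$pop_share, cv$benefit_share, xout = grid, rule = 2)$y
  }
  mat <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      hh <- sample(names(by_hh), length(by_hh), replace = TRUE)
      curve_on_grid(unlist(by_hh[hh], use.names = FALSE))
    }, numeric(length(grid)))
  })
  qs <- apply(mat, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(pop_share = grid, lower = qs[1, ], upper = qs[2, ])
}

#' Full concentration analysis of net subsidies
#'
#' Computes, for one set of public-facility episodes, the concentration
#' index with robust SE and p-value, the concentration curve, and (when
#' `B > 0`) a household-bootstrap 95% band. The default living-standards
#' ranking is the continuous equivalized MPCE with stable tie-breaking; the
#' `"class"` option ranks by the 4-level MPCE class instead (ties then
#' spread uniformly within each class block).
#'
#' @param episodes Public episodes with `gamma`, `mpce`, `mpce_class`,
#'   `weight`, `household_id`.
#' @param rank `"continuous"` (default) or `"class"`.
#' @param se `"hc1"` (default) or `"cluster"` (household-clustered).
#' @param B Bootstrap resamples for the band; 0 disables.
#' @param seed Seed for the bootstrap (required when `B > 0`).
#' @return A `concentration_result`: list with `index`, `robust_se`,
#'   `p_value`, `n_obs`, `curve`, `band`.
#' @export
concentration_analysis <- function(episodes, rank = c("continuous", "class"),
                                   se = c("hc1", "cluster"), B = 0,
                                   seed = NULL) {
  rank <- match.arg(rank)
  se <- match.arg(se)
  xvar <- if (rank == "continuous") {
    episodes$mpce
  } else {
    as.integer(factor(as.character(episodes$mpce_class), levels = MPCE_LEVELS))
  }
  h <- episodes$gamma
  w <- episodes$weight
  r <- fractional_rank(xvar, w)
  reg <- convenient_regression(
    h, r, w,
    cluster = if (se == "cluster") episodes$household_id else NULL
  )
  curve <- concentration_curve(h, xvar, w)
  band <- NULL
  if (B > 0) {
    if (is.null(seed)) abort("concentration_analysis(): seed required when B > 0.")
    band <- bootstrap_band(
      tibble::tibble(
        h = h, x = xvar, w = w, household_id = episodes$household_id
      ),
      B = B, seed = seed
    )
  }
  structure(
    c(reg, list(curve = curve, band = band, rank = rank, se_type = se)),
    class = "concentration_result"
  )
}

#' @export
print.concentration_result <- function(x, ...) {
  cat("<concentration_result>\n")
  cat(sprintf(
    "  C = %.4f (robust SE %.4f, p = %.4f, n = %d, rank = %s, se = %s)\n",
    x$index, x$robust_se, x$p_value, x$n_obs, x$rank, x$se_type
  ))
  invisible(x)
}

#' Concentration-index summary table
#'
#' @param results Named list of `concentration_result` objects; names of the
#'   form `"IP.rural"` become the `service` and `sector` columns.
#' @return Tibble (`service`, `sector`, `n_obs`, `index`, `robust_se`,
#'   `p_value`).
#' @export
concentration_table <- function(results) {
  purrr::imap_dfr(results, function(res, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tibble::tibble(
      service = parts[1], sector = parts[2],
      n_obs = res$n_obs, index = res$index,
      robust_se = res$robust_se, p_value = res$p_value
    )
  })
}

#' Plot a concentration curve with its equality line and bootstrap band
#'
#' @param result A `concentration_result`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_concentration <- function(result, title = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(result$band)) {
    p <- p + ggplot2::geom_ribbon(
      data = result$band,
      ggplot2::aes(
        x = .data$pop_share, ymin = .data$lower, ymax = .data$upper
      ),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line(
      data = result$curve,
      ggplot2::aes(x = .data$pop_share, y = .data$benefit_share),
      linewidth = 0.8
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(
      x = "Cumulative population share (poorest to richest)",
      y = "Cumulative subsidy share",
      title = title
    ) +
    ggplot2::theme_minimal()
}
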