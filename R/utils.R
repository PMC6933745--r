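# Internal helpers shared across modules.

#' Left-continuous weighted quantile
#'
#' Inverse of the weighted empirical CDF: the lowest observed value whose
#' cumulative weight share is at least `p`. No interpolation, so results are
#' always observed values — the behaviour wanted for discrete survey data,
#' where interpolated definitions differ only at ties.
#'
#' @param x Numeric values.
#' @param w Positive weights, same length as `x`.
#' @param probs Probabilities in (0, 1].
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @examples
#' weighted_quantile(1:4, rep(1, 4), c(0.25, 0.5, 0.75))
#' weighted_quantile(1:4, c(10, 1, 1, 1), c(0.25, 0.5, 0.75))
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs > 0 & probs <= 1))
  if (length(x) == 0L) {
    abort("weighted_quantile(): empty input.")
  }
  ord <- order(x)
  x <- x[ord]
  cum <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cum >= p - 1e-12)[1L]], numeric(1))
}

# weighted mean/variance with normalized weights
weighted_var <- function(x, w) {
  wn <- w / sum(w)
  mu <- sum(wn * x)
  sum(wn * (x - mu)^2)
}

# duplicate rows of a sector-labelled table with sector = "combine"
with_combine_sector <- function(df) {
  dplyr::bind_rows(df, dplyr::mutate(df, sector = "combine"))
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(miss, collapse = ", ")
    ))
  }
  invisible(df)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
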