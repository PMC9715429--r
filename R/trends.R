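#' Dominant compositional trend (PC1) of one site series
#'
#' PCA of the site's relative-abundance matrix (covariance-based,
#' column-centred, no unit-variance scaling — abundance columns share a
#' scale) and extraction of the axis explaining most variance.
#'
#' @param series Assemblage table of a single site with at least 3
#'   samples.
#' @return Object of class `trend_series`: list with `site_id`,
#'   `latitude`, `ages`, `scores` (PC1 per sample) and
#'   `variance_fraction`.
#' @export
series_pc1 <- function(series) {
  if (nrow(series) < 3) stop("at least 3 samples are required")
  if (length(unique(series$site_id)) != 1) {
    stop("series must contain a single site")
  }
  ord <- order(series$age_ka)
  series <- series[ord, , drop = FALSE]
  p <- to_relative_abundance(abundance_matrix(series))
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total <= .Machine$double.eps) {
    stop("constant composition: zero assemblage variance at site ",
         series$site_id[1])
  }
  structure(list(site_id = series$site_id[1],
                 latitude = series$latitude[1],
                 ages = series$age_ka,
                 scores = unname(pc$x[, 1]),
                 variance_fraction = pc$sdev[1]^2 / total),
            class = "trend_series")
}

#' Align the polarity of PC1 trends across sites
#'
#' PCA axis signs are arbitrary. For each trend a linear model
#' `score ~ age` is fitted; trends whose slope is positive (scores
#' increasing with age, i.e. decreasing toward the present) are negated so
#' that all sites share the reference convention: scores increase toward
#' the present. An exactly-zero slope is left unflipped with a warning.
#'
#' @param trends List of `trend_series`.
#' @return List of `trend_series` with aligned polarity.
#' @export
align_polarity <- function(trends) {
  lapply(trends, function(tr) {
    slope <- stats::coef(stats::lm(tr$scores ~ tr$ages))[2]
    # numerically-zero slope relative to the data scale
    tol <- 1e-10 * (max(abs(tr$scores)) + 1) / diff(range(tr$ages))
    if (abs(slope) <= tol) {
      warning("exactly-zero trend slope at site ", tr$site_id,
              "; polarity left unchanged")
    } else if (slope > 0) {
      tr$scores <- -tr$scores
    }
    tr
  })
}

#' Interpolate a trend onto a regular age grid
#'
#' Piecewise-linear interpolation at `step`-spaced ages across the common
#' window; the trend must cover the window (no extrapolation), otherwise a
#' coverage error reports the gap. Restricting to the window covered by
#' all series prevents edge effects.
#'
#' @param trend A `trend_series`.
#' @param step Grid step in kyr (default 0.5).
#' @param window Length-2 numeric, the common window in kyr (default
#'   `c(2.5, 23)`).
#' @return A `trend_series` on the regular grid.
#' @export
interpolate_trend <- function(trend, step = 0.5, window = c(2.5, 23)) {
  rng <- range(trend$ages)
  if (rng[1] > window[1] || rng[2] < window[2]) {
    stop("trend at site ", trend$site_id, " covers [", rng[1], ", ", rng[2],
         "] ka and does not span the window [", window[1], ", ", window[2],
         "] ka")
  }
  grid <- seq(window[1], window[2], by = step)
  trend$scores <- stats::approx(trend$ages, trend$scores, xout = grid)$y
  trend$ages <- grid
  trend
}

#' Stacked LOESS trend across sites
#'
#' Pools the (age, score) points of all interpolated trends and fits a
#' single LOESS smoother (span 0.75, local quadratic, tricube weights —
#' the conventional defaults) with a 95% pointwise confidence band from
#' the smoother's standard errors.
#'
#' @param trends List of `trend_series` on a common grid.
#' @param span LOESS span (default 0.75).
#' @param ci Confidence level (default 0.95).
#' @return data.frame of class `stacked_trend` with columns `age`, `fit`,
#'   `lo`, `hi`.
#' @export
stack_loess <- function(trends, span = 0.75, ci = 0.95) {
  if (length(trends) < 2) stop("at least 2 trends are required")
  pooled <- do.call(rbind, lapply(trends, function(tr) {
    data.frame(age = tr$ages, score = tr$scores)
  }))
  fit <- tryCatch(
    stats::loess(score ~ age, data = pooled, span = span, degree = 2),
    error = function(e) stop("LOESS failed (span too small?): ",
                             conditionMessage(e))
  )
  grid <- sort(unique(pooled$age))
  pred <- stats::predict(fit, newdata = data.frame(age = grid), se = TRUE)
  z <- stats::qnorm(1 - (1 - ci) / 2)
  out <- data.frame(age = grid, fit = pred$fit,
                    lo = pred$fit - z * pred$se.fit,
                    hi = pred$fit + z * pred$se.fit)
  class(out) <- c("stacked_trend", "data.frame")
  out
}

.rescale01 <- function(v) {
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps) return(rep(0.5, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Compare the stacked compositional trend with a forcing curve
#'
#' Both curves are min-max rescaled to \[0, 1\] on their overlapping age
#' support so that the shape of compositional change can be compared with
#' the shape of the temperature forcing; the per-age difference of the
#' rescaled curves summarizes lag/mismatch.
#'
#' @param stacked A [stack_loess()] result.
#' @param forcing A [make_forcing()] curve.
#' @return data.frame with columns `age`, `trend`, `forcing` (both
#'   rescaled) and `mismatch` (trend minus forcing).
#' @export
compare_to_forcing <- function(stacked, forcing) {
  rng <- range(forcing$ages)
  keep <- stacked$age >= rng[1] & stacked$age <= rng[2]
  if (!any(keep)) stop("no overlapping age support")
  age <- stacked$age[keep]
  trend01 <- .rescale01(stacked$fit[keep])
  forcing01 <- .rescale01(forcing_at(forcing, age))
  data.frame(age = age, trend = trend01, forcing = forcing01,
             mismatch = trend01 - forcing01)
}
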