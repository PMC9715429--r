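#' Species richness of a sample
#'
#' Number of taxa with strictly positive abundance; a single counted
#' individual counts as presence (no rarity threshold). An optional
#' minimum-proportion detection threshold is available for sensitivity
#' analysis.
#'
#' @param x Abundance vector, matrix (samples in rows) or assemblage
#'   table.
#' @param min_proportion Optional detection threshold on relative
#'   abundance; default 0 (presence = abundance > 0).
#' @return Integer richness (vector for matrix/table input).
#' @export
richness <- function(x, min_proportion = 0) {
  if (is.data.frame(x) && all(.meta_cols %in% names(x))) x <- abundance_matrix(x)
  present <- function(v) {
    if (min_proportion > 0) {
      v <- v / sum(v)
      sum(v > min_proportion)
    } else {
      sum(v > 0)
    }
  }
  if (is.matrix(x)) return(as.integer(apply(x, 1, present)))
  as.integer(present(x))
}

#' Identity-aware species gains and losses against a baseline
#'
#' Gains are the proportion of species present in the sample but absent
#' from the baseline; losses the proportion absent from the sample but
#' present in the baseline; both relative to the total number of species
#' observed in the two samples pooled together. The baseline is normally
#' the oldest sample of the series. Satisfies the exact identity
#' `richness(sample) - richness(baseline) = (gains - losses) * union_size`.
#'
#' @param sample,baseline Abundance vectors on a shared taxonomy.
#' @param min_proportion Optional detection threshold (see [richness()]).
#' @return List with `gains`, `losses` (proportions in \[0, 1\]) and
#'   `union_size`.
#' @export
gains_losses <- function(sample, baseline, min_proportion = 0) {
  if (length(sample) != length(baseline)) {
    stop("sample and baseline must share the taxonomy")
  }
  pres <- function(v) {
    if (min_proportion > 0) v / sum(v) > min_proportion else v > 0
  }
  s <- pres(sample); b <- pres(baseline)
  u <- sum(s | b)
  if (u == 0) stop("degenerate pair: empty pooled species set")
  list(gains = sum(s & !b) / u, losses = sum(!s & b) / u, union_size = u)
}

#' Linear rate of change toward the present
#'
#' Ordinary least-squares slope of a value series against time toward the
#' present (minus age), so a positive slope means an increase through
#' time.
#'
#' @param values Numeric values (e.g. richness, gains, losses).
#' @param ages Ages in kyr BP.
#' @return Slope per kyr.
#' @export
rate_slope <- function(values, ages) {
  if (length(values) != length(ages)) stop("values and ages must match")
  if (length(values) < 3) stop("at least 3 time points are required")
  t_fwd <- -ages
  unname(stats::coef(stats::lm(values ~ t_fwd))[2])
}

#' Per-sample richness, gains and losses of one series
#'
#' @param series Single-site assemblage table.
#' @param min_proportion Optional detection threshold.
#' @return data.frame with one row per sample: `site_id`, `latitude`,
#'   `age_ka`, `richness`, `gains`, `losses`, `union_size`. The baseline
#'   (oldest) sample has gains = losses = 0 against itself.
#' @export
gains_losses_series <- function(series, min_proportion = 0) {
  ord <- order(series$age_ka)
  series <- series[ord, , drop = FALSE]
  ab <- abundance_matrix(series)
  base <- ab[nrow(ab), ]  # oldest sample
  gl <- lapply(seq_len(nrow(ab)), function(i) {
    gains_losses(ab[i, ], base, min_proportion)
  })
  data.frame(site_id = series$site_id, latitude = series$latitude,
             age_ka = series$age_ka,
             richness = richness(ab, min_proportion),
             gains = vapply(gl, `[[`, numeric(1), "gains"),
             losses = vapply(gl, `[[`, numeric(1), "losses"),
             union_size = vapply(gl, `[[`, numeric(1), "union_size"))
}

#' Rates of biodiversity change at one site
#'
#' Fits linear models through the richness, gains and losses series of a
#' site (baseline = oldest sample) and reports their slopes: the rate of
#' richness change in species per kyr, and the rates of gains and losses
#' in proportion per kyr.
#'
#' @param series Single-site assemblage table with at least 3 samples.
#' @param min_proportion Optional detection threshold.
#' @return One-row data.frame: `site_id`, `latitude`, `richness_rate`,
#'   `gains_rate`, `losses_rate`.
#' @export
site_rates <- function(series, min_proportion = 0) {
  if (nrow(series) < 3) stop("at least 3 samples are required")
  gl <- gains_losses_series(series, min_proportion)
  data.frame(site_id = gl$site_id[1], latitude = gl$latitude[1],
             richness_rate = rate_slope(gl$richness, gl$age_ka),
             gains_rate = rate_slope(gl$gains, gl$age_ka),
             losses_rate = rate_slope(gl$losses, gl$age_ka))
}

#' Rates of biodiversity change for every site of a dataset
#'
#' @param x Assemblage table with multiple sites.
#' @param min_proportion Optional detection threshold.
#' @return data.frame with one [site_rates()] row per site.
#' @export
rates_table <- function(x, min_proportion = 0) {
  out <- do.call(rbind, lapply(split_series(x), site_rates,
                               min_proportion = min_proportion))
  rownames(out) <- NULL
  out
}

#' Density summaries and latitude map of biodiversity rates
#'
#' Kernel density (default bandwidth rule `"nrd0"`) and overall mean of
#' each rate, plus the per-site values against latitude for mapping.
#'
#' @param records A [rates_table()] data.frame with at least 2 rows.
#' @param bw Bandwidth passed to [stats::density()].
#' @return List with `means` (named vector), `densities` (list of
#'   `density` objects, absent for degenerate all-equal rates) and `map`
#'   (per-site data.frame).
#' @export
rates_summary <- function(records, bw = "nrd0") {
  if (nrow(records) < 2) stop("at least 2 records are required")
  metrics <- c("richness_rate", "gains_rate", "losses_rate")
  means <- vapply(records[metrics], mean, numeric(1))
  densities <- lapply(metrics, function(m) {
    v <- records[[m]]
    if (diff(range(v)) <= .Machine$double.eps) return(NULL)
    stats::density(v, bw = bw)
  })
  names(densities) <- metrics
  list(means = means, densities = densities,
       map = records[, c("site_id", "latitude", metrics)])
}
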