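#' Shannon entropy of an assemblage
#'
#' `H = -sum(p_i * log(p_i))` over species with positive relative
#' abundance (`0 * log 0 := 0`). Natural logarithm (nats) by default; the
#' higher the value, the more diverse (richer and more even) the
#' assemblage. Bounded by `log(richness)`, with equality for a perfectly
#' even assemblage.
#'
#' @param x Abundance vector, matrix (samples in rows) or assemblage
#'   table; normalized to proportions internally.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Entropy value(s) >= 0.
#' @export
shannon <- function(x, base = exp(1)) {
  if (is.data.frame(x) && all(.meta_cols %in% names(x))) x <- abundance_matrix(x)
  h1 <- function(v) {
    p <- to_relative_abundance(v)
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  }
  if (is.matrix(x)) return(apply(x, 1, h1))
  h1(x)
}

#' Millennial age bins
#'
#' Left-closed bins `[k, k + 1)` kyr anchored at 0 ka, matching the
#' Hovmoller grid convention; every sample falls in exactly one bin.
#'
#' @param ages Ages in kyr BP (>= 0).
#' @return Integer left bin edges.
#' @export
millennial_bin <- function(ages) {
  if (any(ages < 0)) stop("negative ages are not valid")
  as.integer(floor(ages))
}

#' Per-sample diversity records
#'
#' @param x Assemblage table.
#' @return data.frame with `sample_id`, `site_id`, `age_ka`, `latitude`,
#'   `richness` and `shannon` (nats) per sample.
#' @export
diversity_records <- function(x) {
  data.frame(sample_id = .sample_ids(x), site_id = x$site_id,
             age_ka = x$age_ka, latitude = x$latitude,
             richness = richness(x), shannon = shannon(x))
}

#' Latitudinal diversity gradient curves per millennium
#'
#' Pools all samples within each millennial bin and fits a LOESS curve of
#' the diversity metric against latitude (same smoother settings as the
#' trend stack). Bins with fewer points than `min_points` are skipped with
#' a warning; millennia without samples are absent from the output, not
#' zero.
#'
#' @param records A [diversity_records()] frame.
#' @param metric `"richness"` or `"shannon"`.
#' @param span LOESS span (default 0.75).
#' @param min_points Minimum samples per millennium (default 5).
#' @param lat_grid Latitude grid for curve evaluation; default 0.5-degree
#'   steps across the observed range of each bin.
#' @return data.frame with columns `millennium` (left bin edge),
#'   `latitude`, `fit`.
#' @export
ldg_curves <- function(records, metric = c("richness", "shannon"),
                       span = 0.75, min_points = 5, lat_grid = NULL) {
  metric <- match.arg(metric)
  records$millennium <- millennial_bin(records$age_ka)
  out <- lapply(split(records, records$millennium), function(bin) {
    if (nrow(bin) < min_points) {
      warning("millennium [", bin$millennium[1], ", ", bin$millennium[1] + 1,
              ") has fewer than ", min_points, " samples; skipped")
      return(NULL)
    }
    grid <- if (is.null(lat_grid)) {
      seq(min(bin$latitude), max(bin$latitude), by = 0.5)
    } else {
      lat_grid[lat_grid >= min(bin$latitude) & lat_grid <= max(bin$latitude)]
    }
    df <- data.frame(y = bin[[metric]], lat = bin$latitude)
    fit <- stats::loess(y ~ lat, data = df, span = span, degree = 2)
    data.frame(millennium = bin$millennium[1], latitude = grid,
               fit = stats::predict(fit, newdata = data.frame(lat = grid)))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Diversity anomalies relative to each site's LGM mean
#'
#' For every sample, the difference between its diversity metric and the
#' mean of that metric across the site's samples within the LGM window
#' (19-23 ka by default); the anomalies are then gridded at 1 kyr x 2.5
#' degrees. Sites without any LGM-window sample are excluded with a
#' warning.
#'
#' @param x Assemblage table.
#' @param metric `"richness"` or `"shannon"`.
#' @param window LGM window in kyr (default `c(19, 23)`).
#' @param dt,dlat,lat_origin Grid resolution.
#' @return List with `samples` (per-sample records plus `lgm_mean` and
#'   `anomaly`) and `grid` (a `grid_field` of mean anomalies).
#' @export
lgm_anomaly <- function(x, metric = c("richness", "shannon"),
                        window = c(19, 23), dt = 1, dlat = 2.5,
                        lat_origin = 0) {
  metric <- match.arg(metric)
  rec <- diversity_records(x)
  by_site <- split(rec, rec$site_id)
  out <- lapply(by_site, function(s) {
    in_lgm <- s$age_ka >= window[1] & s$age_ka <= window[2]
    if (!any(in_lgm)) {
      warning("site ", s$site_id[1], " has no sample within the LGM window; ",
              "excluded")
      return(NULL)
    }
    s$lgm_mean <- mean(s[[metric]][in_lgm])
    s$anomaly <- s[[metric]] - s$lgm_mean
    s
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  grid <- grid_hovmoller(out$anomaly, out$age_ka, out$latitude,
                         dt = dt, dlat = dlat, lat_origin = lat_origin)
  list(samples = out, grid = grid)
}
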