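#' Distances to the k nearest glacial analogues
#'
#' For each query sample, the Morisita-Horn dissimilarity to every
#' reference (LGM-window) sample is computed and the k smallest distances
#' are returned in ascending order. When a query sample is itself a member
#' of the reference set (same site and age), it is excluded from its own
#' analogue search.
#'
#' @param samples Assemblage table of query samples.
#' @param reference A [build_reference_set()] object (or assemblage
#'   table).
#' @param k Number of nearest analogues (default 3).
#' @return data.frame with `sample_id`, `site_id`, `age_ka`, `latitude`
#'   and distance columns `d_nearest`, `d_second`, `d_third` (then `d4`,
#'   ... for larger k).
#' @export
analogue_distances <- function(samples, reference, k = 3) {
  ref <- if (inherits(reference, "reference_set")) reference$samples else reference
  if (!nrow(ref)) stop("reference set is empty")
  qp <- to_relative_abundance(abundance_matrix(samples))
  rp <- to_relative_abundance(abundance_matrix(ref))
  d <- .mh_cross(qp, rp)
  qid <- .sample_ids(samples)
  rid <- .sample_ids(ref)
  self <- outer(qid, rid, "==")
  d[self] <- Inf
  avail <- rowSums(is.finite(d))
  if (k > min(avail)) {
    stop("rank k = ", k, " exceeds the number of available non-self ",
         "reference samples (", min(avail), ")")
  }
  sorted <- apply(d, 1, function(row) sort(row, partial = k)[seq_len(k)])
  nearest <- if (k == 1) matrix(sorted, ncol = 1) else t(sorted)
  cn <- c("d_nearest", "d_second", "d_third",
          if (k > 3) paste0("d", 4:k))[seq_len(k)]
  colnames(nearest) <- cn
  cbind(data.frame(sample_id = qid, site_id = samples$site_id,
                   age_ka = samples$age_ka, latitude = samples$latitude),
        as.data.frame(nearest), row.names = NULL)
}

#' Self-referential null thresholds for no-analogue detection
#'
#' Within the reference compilation itself, every sample has some distance
#' to its nearest (and 2nd-, 3rd-nearest) non-self analogue; such
#' distances can occur by chance and do not indicate a no-analogue fauna.
#' The stated percentiles of these within-reference distance distributions
#' serve as detection thresholds. Percentiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param reference A [build_reference_set()] object (or assemblage
#'   table).
#' @param percentiles Percentiles in (0, 100\] (default `c(95, 99)`).
#' @param ranks Analogue ranks (default `1:3`).
#' @return Object of class `null_thresholds`: matrix with one row per
#'   percentile and one column per rank; the per-sample rank-r distances
#'   are attached as attribute `distances`.
#' @export
null_thresholds <- function(reference, percentiles = c(95, 99), ranks = 1:3) {
  ref <- if (inherits(reference, "reference_set")) reference$samples else reference
  kmax <- max(ranks)
  if (nrow(ref) < kmax + 1) {
    stop("reference too small: need at least ", kmax + 1, " samples")
  }
  dists <- analogue_distances(ref, ref, k = kmax)
  dmat <- as.matrix(dists[, 4 + ranks, drop = FALSE])
  thr <- t(vapply(percentiles, function(p) {
    apply(dmat, 2, stats::quantile, probs = p / 100, type = 7, names = FALSE)
  }, numeric(length(ranks))))
  dimnames(thr) <- list(paste0("p", percentiles), paste0("rank", ranks))
  structure(thr, distances = dmat, class = c("null_thresholds", "matrix"))
}

#' @export
print.null_thresholds <- function(x, ...) {
  cat("Null analogue-distance thresholds (",
      nrow(attr(x, "distances")), " reference samples):\n", sep = "")
  print(round(unclass(x)[, , drop = FALSE], 4))
  invisible(x)
}

#' Classify no-analogue assemblages
#'
#' A sample is flagged as no-analogue when its distance to the rank-r
#' nearest reference analogue is strictly greater than the threshold
#' (ties at the threshold are not flagged). The nearest-analogue distances
#' are also gridded onto the time x latitude field; a cell is flagged when
#' its aggregated value (mean by default, minimum optionally) exceeds the
#' threshold.
#'
#' @param samples Assemblage table of query samples.
#' @param reference Reference set.
#' @param threshold Distance threshold in (0, 1), typically a
#'   [null_thresholds()] entry.
#' @param rank Analogue rank to classify on (default 1 = nearest).
#' @param dt,dlat,lat_origin Grid resolution (defaults 1 kyr x 2.5 degrees).
#' @param cell_stat `"mean"` (default) or `"min"` — per-cell aggregation
#'   of the distances.
#' @return List with `samples` (the [analogue_distances()] frame plus a
#'   logical `no_analogue` column) and `grid` (a `grid_field` of the
#'   aggregated distance plus a logical `flag` column).
#' @export
classify_no_analogue <- function(samples, reference, threshold, rank = 1,
                                 dt = 1, dlat = 2.5, lat_origin = 0,
                                 cell_stat = c("mean", "min")) {
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie in (0, 1)")
  }
  cell_stat <- match.arg(cell_stat)
  dists <- analogue_distances(samples, reference, k = rank)
  dcol <- dists[[4 + rank]]
  dists$no_analogue <- dcol > threshold
  grid <- grid_hovmoller(dcol, dists$age_ka, dists$latitude,
                         dt = dt, dlat = dlat, lat_origin = lat_origin,
                         aggregator = if (cell_stat == "mean") mean else min)
  grid$flag <- grid$value > threshold
  list(samples = dists, grid = grid)
}

#' False-positive audit of the null threshold
#'
#' Leave-self-out classification of the reference compilation against its
#' own threshold: the fraction of reference samples whose non-self
#' nearest-analogue distance exceeds the stated percentile of that same
#' distribution. By construction this is at most about `1 - p/100` (up to
#' the discreteness of the order statistics).
#'
#' @param reference Reference set.
#' @param percentile Percentile in (0, 100\] (default 99).
#' @param rank Analogue rank (default 1).
#' @return Flagged fraction in \[0, 1\].
#' @export
false_positive_audit <- function(reference, percentile = 99, rank = 1) {
  thr <- null_thresholds(reference, percentiles = percentile, ranks = rank)
  d <- attr(thr, "distances")[, 1]
  mean(d > thr[1, 1])
}
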