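#' Morisita-Horn dissimilarity between two assemblages
#'
#' `C = 1 - 2 * sum(x_i * y_i) / (sum(x_i^2) + sum(y_i^2))`, where `x_i`
#' and `y_i` are the relative abundances of species *i* in the two
#' samples. Ranges from 0 (identical composition) to 1 (no shared
#' species); an abundance-based turnover measure that is relatively
#' insensitive to sample size. Inputs are normalized to proportions
#' internally, so raw counts and proportions give identical results.
#'
#' @param x,y Non-negative abundance vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' morisita_horn(c(0.5, 0.5, 0), c(0.5, 0, 0.5)) # 0.5
#' @export
morisita_horn <- function(x, y) {
  if (length(x) != length(y)) {
    stop("abundance vectors must have the same length")
  }
  x <- to_relative_abundance(as.numeric(x))
  y <- to_relative_abundance(as.numeric(y))
  d <- 1 - 2 * sum(x * y) / (sum(x^2) + sum(y^2))
  min(1, max(0, d))
}

# Morisita-Horn distances between the rows of two proportion matrices.
.mh_cross <- function(px, py) {
  cross <- px %*% t(py)
  denom <- outer(rowSums(px^2), rowSums(py^2), "+")
  d <- 1 - 2 * cross / denom
  d[d < 0] <- 0
  d[d > 1] <- 1
  d
}

.sample_ids <- function(x) paste(x$site_id, round(x$age_ka, 6), sep = "@")

#' Pairwise Morisita-Horn dissimilarity matrix
#'
#' @param x Assemblage table (counts or proportions) or a plain abundance
#'   matrix with samples in rows.
#' @return Square symmetric matrix in \[0, 1\] with zero diagonal; sample
#'   ids (`site@age` for assemblage tables) as dimnames.
#' @export
pairwise_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- .sample_ids(x)
    m <- abundance_matrix(x)
  } else {
    m <- as.matrix(x)
    ids <- rownames(m)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  }
  if (nrow(m) < 2) stop("at least 2 samples are required")
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop("degenerate sample(s) with zero total abundance: ",
         paste(utils::head(ids[rs <= 0], 5), collapse = ", "))
  }
  p <- m / rs
  d <- .mh_cross(p, p)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' PCA of a dissimilarity matrix
#'
#' Treats each sample's row of dissimilarities as its feature vector,
#' column-centres (no scaling to unit variance) and decomposes with
#' [stats::prcomp()]. This follows the matrix-as-data reading of the
#' dimensionality reduction; classical PCoA is deliberately not
#' substituted.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param k Number of axes to keep (default 3).
#' @return List with `scores` (n x k matrix), `explained` (variance
#'   fractions of the kept axes) and `all_fractions` (full spectrum).
#' @export
pca_on_dissimilarity <- function(d, k = 3) {
  if (k < 1) stop("k must be at least 1")
  d <- as.matrix(d)
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total <= .Machine$double.eps) {
    scores <- matrix(0, nrow(d), k,
                     dimnames = list(rownames(d), paste0("PC", seq_len(k))))
    return(list(scores = scores, explained = rep(0, k),
                all_fractions = rep(0, k)))
  }
  fractions <- pc$sdev^2 / total
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (k > rank) {
    warning("requested ", k, " axes but matrix rank is ", rank,
            "; truncating")
    k <- rank
  }
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = fractions[seq_len(k)],
       all_fractions = fractions)
}

#' Map three PCA axes to RGB colours
#'
#' Each axis is min-max rescaled to \[0, 1\] independently over the full
#' sample set and assigned to a colour channel: axis 1 to blue, axis 2 to
#' red, axis 3 to green. Samples with similar scores receive similar
#' colours. A constant axis is fixed at 0.5 with a warning.
#'
#' @param scores n x 3 matrix of PCA scores.
#' @return n x 3 matrix with columns `r`, `g`, `b` in \[0, 1\].
#' @export
scores_to_rgb <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 3) stop("exactly 3 axes are required")
  rescale <- apply(scores, 2, function(v) {
    rng <- range(v)
    if (diff(rng) <= .Machine$double.eps) {
      warning("constant axis rescaled to 0.5")
      return(rep(0.5, length(v)))
    }
    (v - rng[1]) / diff(rng)
  })
  out <- cbind(r = rescale[, 2], g = rescale[, 3], b = rescale[, 1])
  rownames(out) <- rownames(scores)
  out
}

#' Aggregate sample values onto a time x latitude (Hovmoller) grid
#'
#' Bins are left-closed: time bins `[t, t + dt)` anchored at 0 ka and
#' latitude bins `[l, l + dlat)` anchored at `lat_origin`. Cells without
#' samples are absent from the output (missing, not zero); the per-cell
#' sample count is recorded, and counts sum to the number of input
#' samples.
#'
#' @param values Numeric sample values to aggregate.
#' @param ages Sample ages in kyr BP (>= 0).
#' @param latitudes Sample latitudes in degrees N.
#' @param dt Time bin width in kyr (default 1).
#' @param dlat Latitude bin width in degrees (default 2.5).
#' @param lat_origin Anchor of the latitude bins (default 0).
#' @param aggregator Per-cell summary function (default `mean`).
#' @return data.frame of class `grid_field` with columns `time_bin`,
#'   `lat_bin` (left edges), `value`, `n`.
#' @export
grid_hovmoller <- function(values, ages, latitudes, dt = 1, dlat = 2.5,
                           lat_origin = 0, aggregator = mean) {
  n <- length(values)
  if (length(ages) != n || length(latitudes) != n) {
    stop("values, ages and latitudes must have equal length")
  }
  if (any(ages < 0)) stop("sample age outside grid extent (negative age)")
  if (any(latitudes < lat_origin)) {
    stop("sample latitude below the grid origin")
  }
  ti <- floor(ages / dt) * dt
  li <- lat_origin + floor((latitudes - lat_origin) / dlat) * dlat
  key <- paste(ti, li)
  agg <- tapply(values, key, aggregator)
  cnt <- tapply(values, key, length)
  first <- !duplicated(key)
  ord <- order(ti[first], li[first])
  k <- key[first][ord]
  out <- data.frame(time_bin = ti[first][ord], lat_bin = li[first][ord],
                    value = as.numeric(agg[k]), n = as.integer(cnt[k]))
  attr(out, "dt") <- dt
  attr(out, "dlat") <- dlat
  class(out) <- c("grid_field", "data.frame")
  out
}
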