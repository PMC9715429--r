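# Shared fixtures and independent oracles for the test suite.

# Naive Morisita-Horn evaluation, written directly from the formula on
# relative abundances; the independent oracle for the vectorized path.
mh_naive <- function(x, y) {
  x <- x / sum(x)
  y <- y / sum(y)
  1 - 2 * sum(x * y) / (sum(x^2) + sum(y^2))
}

# Minimal assemblage table: one row per sample, three taxa by default.
toy_table <- function(counts, site = "S1", ages = NULL, lat = 45) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sp", seq_len(ncol(counts)))
  }
  if (is.null(ages)) ages <- seq_len(nrow(counts))
  cbind(data.frame(site_id = site, latitude = lat, longitude = -30,
                   age_ka = ages),
        as.data.frame(counts), row.names = NULL)
}

# Random proportion vector over at most 41 species, with structural zeros.
random_proportions <- function(s = sample(2:41, 1)) {
  v <- rexp(s)
  v[sample(s, size = sample(0:(s - 1), 1))] <- 0
  if (all(v == 0)) v[1] <- 1
  v / sum(v)
}

# A two-species seesaw series: composition moves along one line, so the
# per-site PCA must put ~all variance on axis 1.
seesaw_series <- function(n = 10) {
  p <- seq(0.1, 0.9, length.out = n)
  toy_table(cbind(a = p, b = 1 - p), ages = seq(1, 24, length.out = n))
}
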