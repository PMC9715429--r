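#' @name assemblage-table
#' @title Assemblage tables
#' @description
#' The package's working container is a plain data.frame with one row per
#' census sample: metadata columns `site_id`, `latitude`, `longitude`,
#' `age_ka` (calibrated kyr BP, 0 ka = 1950 CE), followed by one numeric
#' column per canonical taxon. Abundances may be raw counts or proportions;
#' [to_relative_abundance()] converts in place. All analysis functions
#' accept this layout, so real (deposited) and synthetic data are
#' interchangeable.
NULL

.meta_cols <- c("site_id", "latitude", "longitude", "age_ka")

#' Extract the abundance matrix from an assemblage table
#'
#' @param x An assemblage table (see [assemblage-table]).
#' @return Numeric matrix, samples in rows, taxa in columns.
#' @export
abundance_matrix <- function(x) {
  taxa <- setdiff(names(x), .meta_cols)
  m <- as.matrix(x[, taxa, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Sample metadata of an assemblage table
#' @param x An assemblage table.
#' @return data.frame with the four metadata columns.
#' @export
sample_meta <- function(x) x[, .meta_cols, drop = FALSE]

.check_meta <- function(x) {
  missing <- setdiff(.meta_cols, names(x))
  if (length(missing)) {
    stop("missing metadata column(s): ", paste(missing, collapse = ", "))
  }
  invisible(x)
}

#' Read an assemblage census table
#'
#' Reads a delimited table (CSV/TSV, inferred from the extension) with
#' metadata columns `site_id`, `latitude`, `longitude`, `age_ka` and one
#' column per taxon, applies taxonomic harmonization (merging and
#' zero-filling), and validates abundances. Species not reported are
#' assumed absent, i.e. zero abundance.
#'
#' @param path File path.
#' @param taxonomy A [foram_taxonomy()]; defaults to the bundled 41-taxon
#'   taxonomy.
#' @param units `"counts"`, `"percent"` or `"proportions"` — how the taxon
#'   columns are expressed. Percent rows must sum to 100 within \[99, 101\]
#'   and are renormalized to proportions; proportion rows must sum to 1.
#' @param unknown_taxa Passed to [harmonize_abundance()].
#' @return An assemblage table (see [assemblage-table]). Proportions (for
#'   `percent`/`proportions` input) are exactly renormalized to sum 1.
#' @export
read_assemblage <- function(path, taxonomy = foram_taxonomy(),
                            units = c("counts", "percent", "proportions"),
                            unknown_taxa = c("error", "drop")) {
  units <- match.arg(units)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    out <- cbind(
      data.frame(site_id = character(), latitude = numeric(),
                 longitude = numeric(), age_ka = numeric()),
      as.data.frame(matrix(numeric(), 0, length(taxonomy$species),
                           dimnames = list(NULL, taxonomy$species)),
                    check.names = FALSE)
    )
    return(out)
  }
  .check_meta(raw)
  ab <- raw[, setdiff(names(raw), .meta_cols), drop = FALSE]
  if (any(as.matrix(ab) < 0, na.rm = TRUE)) {
    stop("negative abundance values are not valid")
  }
  ab <- harmonize_abundance(ab, taxonomy, unknown_taxa)
  if (units == "percent") {
    rs <- rowSums(ab)
    bad <- rs < 99 | rs > 101
    if (any(bad)) {
      stop("percent rows must sum to 100 within [99, 101]; offending row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
    ab <- ab / rs
  } else if (units == "proportions") {
    rs <- rowSums(ab)
    if (any(abs(rs - 1) > 0.01)) {
      stop("proportion rows must sum to 1")
    }
    ab <- ab / rs
  }
  cbind(raw[, .meta_cols, drop = FALSE], as.data.frame(ab, check.names = FALSE),
        row.names = NULL)
}

#' Write an assemblage table to CSV
#'
#' The written file round-trips through [read_assemblage()] (with
#' `units = "counts"` or `"proportions"` as appropriate) to identical
#' values.
#'
#' @param x Assemblage table.
#' @param path Output CSV path.
#' @export
write_assemblage <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert abundances to relative abundances
#'
#' Normalizes each sample to proportions summing to one, preserving zeros.
#' Defined on vectors, matrices (rows = samples) and assemblage tables.
#'
#' @param x Numeric vector, matrix, or assemblage table.
#' @return Same shape as `x`, entries normalized per sample.
#' @export
to_relative_abundance <- function(x) {
  if (is.data.frame(x) && all(.meta_cols %in% names(x))) {
    ab <- abundance_matrix(x)
    x[, colnames(ab)] <- to_relative_abundance(ab)
    return(x)
  }
  if (is.matrix(x)) {
    rs <- rowSums(x)
    if (any(rs <= 0)) {
      stop("degenerate sample: all-zero abundance vector in row(s) ",
           paste(utils::head(which(rs <= 0), 5), collapse = ", "))
    }
    return(x / rs)
  }
  s <- sum(x)
  if (s <= 0) stop("degenerate sample: all-zero abundance vector")
  x / s
}

#' Select samples within a closed time window
#'
#' Membership uses the closed interval `[min_age, max_age]` so that window
#' endpoints (for example samples at exactly 19 or 23 ka for the LGM
#' window) are captured deterministically.
#'
#' @param x Assemblage table.
#' @param min_age,max_age Window bounds in kyr BP; `min_age < max_age`.
#' @return The subset of rows with `min_age <= age_ka <= max_age`.
#' @export
filter_time_window <- function(x, min_age, max_age) {
  if (!(min_age < max_age)) stop("min_age must be less than max_age")
  x[x$age_ka >= min_age & x$age_ka <= max_age, , drop = FALSE]
}

#' Build an LGM analogue reference set
#'
#' Pools externally supplied reference samples (e.g. a glacial census
#' compilation) with the in-window samples of the analysed time series,
#' removing duplicates by `(site_id, age rounded to 1e-6 kyr)` so samples
#' present in both sources are not double-counted.
#'
#' @param series Assemblage table of the analysed time series (may be
#'   `NULL`).
#' @param extra Assemblage table of external reference samples already
#'   within the window (may be `NULL`).
#' @param window Length-2 numeric, the reference window in kyr; default the
#'   19–23 ka Last Glacial Maximum.
#' @return An object of class `reference_set`: list with `samples` (an
#'   assemblage table) and `window`.
#' @export
build_reference_set <- function(series = NULL, extra = NULL,
                                window = c(19, 23)) {
  pool <- list()
  if (!is.null(extra) && nrow(extra)) {
    pool <- c(pool, list(filter_time_window(extra, window[1], window[2])))
  }
  if (!is.null(series) && nrow(series)) {
    pool <- c(pool, list(filter_time_window(series, window[1], window[2])))
  }
  if (!length(pool)) stop("empty reference set: no samples within the window")
  samples <- do.call(rbind, pool)
  key <- paste(samples$site_id, round(samples$age_ka, 6))
  samples <- samples[!duplicated(key), , drop = FALSE]
  rownames(samples) <- NULL
  if (!nrow(samples)) stop("empty reference set: no samples within the window")
  structure(list(samples = samples, window = window), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set:", nrow(x$samples), "samples from",
      length(unique(x$samples$site_id)), "sites, window",
      x$window[1], "-", x$window[2], "ka\n")
  invisible(x)
}

#' Split an assemblage table into per-site series
#'
#' @param x Assemblage table.
#' @return Named list of assemblage tables, one per site, rows ordered by
#'   strictly increasing age. Tied ages within a site are an error.
#' @export
split_series <- function(x) {
  .check_meta(x)
  out <- split(x, x$site_id)
  out <- lapply(out, function(s) {
    s <- s[order(s$age_ka), , drop = FALSE]
    if (anyDuplicated(s$age_ka)) {
      stop("tied sample ages within site ", s$site_id[1])
    }
    rownames(s) <- NULL
    s
  })
  out[order(names(out))]
}
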