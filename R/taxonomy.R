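#' Harmonized planktonic foraminifera taxonomy
#'
#' A taxonomy couples an ordered list of canonical taxon labels with merge
#' rules mapping source labels (as they appear in census tables) onto
#' canonical labels. The default taxonomy ships with the package: 41
#' canonical extant planktonic foraminifera species, with
#' *Globigerinoides ruber ruber* and *G. ruber albus* merged into
#' *Globigerinoides ruber*, and P/D intergrades merged into
#' *Neogloboquadrina incompta*.
#'
#' @param path Path to a taxonomy CSV with columns `source_label` and
#'   `canonical_label`. Defaults to the bundled 41-species table.
#' @return An object of class `foram_taxonomy`: a list with `species`
#'   (character vector of canonical labels, in order) and `merge_rules`
#'   (named character vector, source label -> canonical label).
#' @examples
#' tax <- foram_taxonomy()
#' length(tax$species) # 41
#' @export
foram_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taxonomy_41.csv", package = "foramshift")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source_label", "canonical_label") %in% names(tab))) {
    stop("taxonomy file must have columns 'source_label' and 'canonical_label'")
  }
  species <- unique(tab$canonical_label)
  if (anyDuplicated(species)) stop("canonical labels must be unique")
  rules <- stats::setNames(tab$canonical_label, tab$source_label)
  if (anyDuplicated(names(rules))) {
    stop("each source label must map to exactly one canonical label")
  }
  structure(list(species = species, merge_rules = rules),
            class = "foram_taxonomy")
}

#' @export
print.foram_taxonomy <- function(x, ...) {
  n_merge <- sum(names(x$merge_rules) != unname(x$merge_rules))
  cat("Harmonized taxonomy:", length(x$species), "canonical taxa,",
      n_merge, "merge rule(s)\n")
  invisible(x)
}

#' Apply taxonomic harmonization to an abundance table
#'
#' Renames source columns to canonical labels, sums columns that merge into
#' the same canonical taxon, and fills taxa absent from the input with zero
#' abundance. Harmonization is idempotent and conserves total abundance.
#'
#' @param abundance A numeric matrix or data.frame with one column per
#'   source taxon.
#' @param taxonomy A [foram_taxonomy()] object.
#' @param unknown_taxa `"error"` (default) to reject columns not covered by
#'   the taxonomy, or `"drop"` to warn and discard them.
#' @return A numeric matrix with `length(taxonomy$species)` columns in
#'   canonical order.
#' @export
harmonize_abundance <- function(abundance, taxonomy,
                                unknown_taxa = c("error", "drop")) {
  unknown_taxa <- match.arg(unknown_taxa)
  abundance <- as.matrix(abundance)
  src <- colnames(abundance)
  if (is.null(src)) stop("abundance columns must be named by taxon")
  known <- src %in% names(taxonomy$merge_rules)
  if (any(!known)) {
    bad <- src[!known]
    if (unknown_taxa == "error") {
      stop("unknown taxa not covered by the taxonomy: ",
           paste(bad, collapse = ", "))
    }
    warning("dropping unknown taxa: ", paste(bad, collapse = ", "))
    abundance <- abundance[, known, drop = FALSE]
    src <- src[known]
  }
  canon <- unname(taxonomy$merge_rules[src])
  out <- matrix(0, nrow(abundance), length(taxonomy$species),
                dimnames = list(rownames(abundance), taxonomy$species))
  for (j in seq_along(src)) {
    out[, canon[j]] <- out[, canon[j]] + abundance[, j]
  }
  out
}
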