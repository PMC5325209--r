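# Identification-set summaries: coverage, overlap and Jaccard similarity.

round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

set_comparison <- function(labels, sizes, n_intersect, n_union) {
  stopifnot(n_intersect <= min(sizes), n_union >= max(sizes))
  structure(list(set_labels = labels,
                 cardinalities = stats::setNames(sizes, labels),
                 n_intersect = n_intersect,
                 n_union = n_union,
                 overlap_pct = 100 * n_intersect / max(sizes),
                 jaccard = n_intersect / n_union),
            class = "SetComparison")
}

#' @export
print.SetComparison <- function(x, ...) {
  cat(sprintf("SetComparison [%s]: |int| = %d, |union| = %d, overlap = %.2f%%, J = %.2f\n",
              paste(x$set_labels, collapse = ", "),
              x$n_intersect, x$n_union,
              round_half_up(x$overlap_pct), round_half_up(x$jaccard)))
  invisible(x)
}

#' Compare two or three labeled accession sets
#'
#' Exact set algebra on accession identifiers: cardinalities, n-way
#' intersection and union, the overlap score (intersection relative to
#' the largest set, in percent) and the Jaccard index
#' (intersection over union). Full precision is retained; use
#' [comparison_table()] for the 2-decimal report rounding.
#'
#' @param sets Named list of 2 or 3 non-empty character vectors;
#'   duplicates within a set are collapsed.
#' @param collapse_isoforms Drop a trailing `-<n>` isoform suffix from
#'   accessions before comparing (default FALSE: splice isoforms count as
#'   distinct accessions).
#' @return A `SetComparison` object.
#' @export
compare_sets <- function(sets, collapse_isoforms = FALSE) {
  stopifnot(length(sets) %in% c(2L, 3L))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  if (any(lengths(sets) == 0L)) stop("compare_sets: empty set")
  if (collapse_isoforms)
    sets <- lapply(sets, function(s) sub("-[0-9]+$", "", s))
  sets <- lapply(sets, unique)
  set_comparison(names(sets), lengths(sets),
                 length(Reduce(intersect, sets)),
                 length(Reduce(union, sets)))
}

#' Build a set comparison from printed cardinalities
#'
#' For reproducing published comparison tables where only the
#' cardinalities (not the member lists) are available.
#'
#' @param sizes Named integer vector of set cardinalities (2 or 3 sets).
#' @param n_intersect,n_union Cardinalities of the n-way intersection and
#'   union.
#' @return A `SetComparison` object.
#' @export
compare_counts <- function(sizes, n_intersect, n_union) {
  stopifnot(length(sizes) %in% c(2L, 3L))
  labels <- if (is.null(names(sizes))) LETTERS[seq_along(sizes)]
            else names(sizes)
  set_comparison(labels, as.integer(sizes), as.integer(n_intersect),
                 as.integer(n_union))
}

#' Report row for a set comparison (2-decimal, half-up rounding)
#'
#' @param cmp A `SetComparison`.
#' @return One-row data.frame: labels, cardinalities, intersection,
#'   union, `overlap_pct` and `jaccard` rounded half-up to 2 decimals.
#' @export
comparison_table <- function(cmp) {
  data.frame(sets = paste(cmp$set_labels, collapse = "/"),
             n_intersect = cmp$n_intersect,
             n_union = cmp$n_union,
             overlap_pct = round_half_up(cmp$overlap_pct),
             jaccard = round_half_up(cmp$jaccard))
}

#' Proteome coverage of an identification set
#'
#' `100 * |identified| / reference_size` for each dataset, plus the mean
#' across datasets. Accepts either identifier vectors or pre-computed
#' counts.
#'
#' @param identified List of character vectors (or a numeric vector of
#'   counts), one per dataset.
#' @param reference_size Size of the reference proteome (scalar or one
#'   per dataset).
#' @return A list: `pct` (per dataset, full precision), `pct_rounded`
#'   (half-up, 2 decimals), `mean_pct` (mean of the rounded values,
#'   rounded half-up to 2 decimals, matching printed-table convention).
#' @export
coverage_summary <- function(identified, reference_size) {
  stopifnot(all(reference_size > 0))
  counts <- if (is.numeric(identified)) identified
            else vapply(identified, function(s) length(unique(s)), 0L)
  pct <- 100 * counts / reference_size
  pr <- round_half_up(pct)
  list(pct = pct, pct_rounded = pr,
       mean_pct = round_half_up(mean(pr)))
}
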