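# Data model and IO for triplex SILAC protein-group tables.
#
# The in-memory convention is a single sign convention for the six ratios:
# all four "treated" slots are stored as log2(exposed/sham), regardless of
# which isotope channel carried the exposed sample in a given replicate.
# The two "control" slots compare equally-treated channels and are stored
# as log2 of the raw channel ratio.

#' Ratio slot roles
#'
#' Column names used for the six oriented log2 SILAC ratios of the
#' double-label-swap design: four treated slots (exposed over sham, two per
#' reciprocal labeling experiment) and two control slots (same-condition
#' channels, one per experiment).
#'
#' @name ratio_roles
#' @keywords internal
NULL

RATIO_COLS <- c("treated_r1_HL", "treated_r1_HM",
                "treated_r2_LH", "treated_r2_MH",
                "control_r1", "control_r2")
TREATED_COLS <- RATIO_COLS[1:4]
CONTROL_COLS <- RATIO_COLS[5:6]
NQ_COLS <- paste0("nq_", RATIO_COLS)

#' Construct an exposure dataset
#'
#' Bundles a table of quantified protein groups with experiment metadata.
#' `records` must contain one row per protein group with the identity
#' columns (`group_id`, `leading_accession`, `gene_symbol`, `species`,
#' `n_razor_unique_peptides`, `intensity`, `is_decoy`, `is_contaminant`),
#' the six oriented log2 ratio columns and the six quantitation-event
#' count columns.
#'
#' @param records data.frame of protein groups.
#' @param cell_line character scalar, e.g. `"U2OS"`.
#' @param emf_type one of `"ELF"`, `"UMTS"`, `"WiFi"`, `"synthetic"`.
#' @param normalization_offsets named numeric of per-column median shifts
#'   already applied (log2 units), or `NULL` if unnormalized.
#' @return An object of class `ExposureDataset`.
#' @export
exposure_dataset <- function(records, cell_line = "unknown",
                             emf_type = "synthetic",
                             normalization_offsets = NULL) {
  required <- c("group_id", "leading_accession", "gene_symbol", "species",
                "n_razor_unique_peptides", "intensity",
                "is_decoy", "is_contaminant", RATIO_COLS, NQ_COLS)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$group_id))
    stop("group_id values must be unique")
  if (any(records$intensity < 0, na.rm = TRUE))
    stop("intensity must be non-negative")
  rownames(records) <- NULL
  structure(
    list(records = records,
         cell_line = cell_line,
         emf_type = emf_type,
         normalization_offsets = normalization_offsets),
    class = "ExposureDataset")
}

#' @export
print.ExposureDataset <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("ExposureDataset: %s / %s\n", x$cell_line, x$emf_type))
  cat(sprintf("  %d protein groups (%d decoys, %d contaminants)\n",
              n, sum(x$records$is_decoy), sum(x$records$is_contaminant)))
  cat(sprintf("  complete six-ratio quantifications: %d\n",
              sum(ratio_complete(x))))
  if (!is.null(x$normalization_offsets))
    cat("  ratios median-centered\n")
  invisible(x)
}

#' @export
dim.ExposureDataset <- function(x) dim(x$records)

#' Ratio matrix and completeness helpers
#'
#' `ratio_matrix` extracts the six oriented log2 ratio columns as a numeric
#' matrix (rows = protein groups); `ratio_complete` flags rows with all six
#' slots present.
#'
#' @param ds An `ExposureDataset`.
#' @param cols Which ratio columns to extract.
#' @return Numeric matrix, or logical vector for `ratio_complete`.
#' @export
ratio_matrix <- function(ds, cols = RATIO_COLS) {
  as.matrix(ds$records[, cols, drop = FALSE])
}

#' @rdname ratio_matrix
#' @export
ratio_complete <- function(ds) {
  rowSums(is.na(ratio_matrix(ds))) == 0L
}

subset_dataset <- function(ds, keep) {
  ds$records <- ds$records[keep, , drop = FALSE]
  rownames(ds$records) <- NULL
  ds
}

#' Default column map for the package's MaxQuant-like dialect
#'
#' Maps roles of the internal data model to header names of the
#' tab-delimited dialect written by [write_maxquant_like()]. Ratio cells in
#' the file are linear (unlogged) and kept in raw instrument orientation;
#' the two replicate-2 treated ratios are listed in `invert` because their
#' raw orientation is sham/exposed (the heavy channel carried the sham
#' culture in the second labeling experiment) and must be
#' reciprocal-flipped on read to obtain exposed/sham.
#'
#' @return A list with elements `columns` (named character: role -> header)
#'   and `invert` (roles whose raw ratio is reciprocal to the stored
#'   orientation).
#' @export
maxquant_column_map <- function() {
  list(
    columns = c(
      group_id = "Protein IDs",
      leading_accession = "Majority protein IDs",
      gene_symbol = "Gene names",
      species = "Species",
      n_razor_unique_peptides = "Razor + unique peptides",
      intensity = "Intensity",
      is_decoy = "Reverse",
      is_contaminant = "Potential contaminant",
      treated_r1_HL = "Ratio H/L normalized R1",
      treated_r1_HM = "Ratio H/M normalized R1",
      control_r1 = "Ratio M/L normalized R1",
      treated_r2_LH = "Ratio H/L normalized R2",
      treated_r2_MH = "Ratio H/M normalized R2",
      control_r2 = "Ratio M/L normalized R2",
      nq_treated_r1_HL = "Ratio H/L count R1",
      nq_treated_r1_HM = "Ratio H/M count R1",
      nq_control_r1 = "Ratio M/L count R1",
      nq_treated_r2_LH = "Ratio H/L count R2",
      nq_treated_r2_MH = "Ratio H/M count R2",
      nq_control_r2 = "Ratio M/L count R2"),
    invert = c("treated_r2_LH", "treated_r2_MH"))
}

parse_ratio_column <- function(raw, column_name) {
  x <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & raw != "" & is.na(x)
  if (any(bad))
    warning(sprintf("%d non-numeric cell(s) in ratio column '%s' set to missing",
                    sum(bad), column_name))
  # MaxQuant encodes unquantified ratios as 0, NaN or empty cells
  x[!is.finite(x) | x == 0] <- NA_real_
  x
}

#' Read a MaxQuant-style protein-groups table
#'
#' Parses a tab-delimited protein-group table into an [exposure_dataset()].
#' Linear ratio cells are log2-transformed on read; zero, NaN, empty and
#' non-numeric cells become missing slots; columns named in
#' `column_map$invert` are reciprocal-reoriented so that every treated slot
#' stores log2(exposed/sham).
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row.
#' @param column_map Dialect description, see [maxquant_column_map()].
#' @param cell_line,emf_type Metadata attached to the dataset.
#' @return An `ExposureDataset` (unnormalized).
#' @export
read_protein_groups <- function(path, column_map = maxquant_column_map(),
                                cell_line = "unknown",
                                emf_type = "synthetic") {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           fileEncoding = "UTF-8")
  cmap <- column_map$columns
  core_roles <- c("group_id", "leading_accession", "gene_symbol", "species",
                  "n_razor_unique_peptides", "intensity",
                  "is_decoy", "is_contaminant", RATIO_COLS)
  for (role in core_roles) {
    if (is.na(cmap[role]) || !(cmap[role] %in% names(tab)))
      stop(sprintf("mapped column '%s' (role '%s') not found in %s",
                   cmap[role], role, path))
  }
  rec <- data.frame(
    group_id = tab[[cmap["group_id"]]],
    leading_accession = tab[[cmap["leading_accession"]]],
    gene_symbol = tab[[cmap["gene_symbol"]]],
    species = tab[[cmap["species"]]],
    n_razor_unique_peptides =
      suppressWarnings(as.integer(tab[[cmap["n_razor_unique_peptides"]]])),
    intensity = suppressWarnings(as.numeric(tab[[cmap["intensity"]]])),
    is_decoy = tab[[cmap["is_decoy"]]] == "+",
    is_contaminant = tab[[cmap["is_contaminant"]]] == "+",
    stringsAsFactors = FALSE)
  rec$n_razor_unique_peptides[is.na(rec$n_razor_unique_peptides)] <- 0L
  rec$intensity[is.na(rec$intensity)] <- 0
  for (role in RATIO_COLS) {
    x <- parse_ratio_column(tab[[cmap[role]]], cmap[role])
    lg <- log2(x)
    if (role %in% column_map$invert) lg <- -lg
    rec[[role]] <- lg
  }
  for (role in NQ_COLS) {
    if (!is.na(cmap[role]) && cmap[role] %in% names(tab)) {
      nq <- suppressWarnings(as.integer(tab[[cmap[role]]]))
      nq[is.na(nq)] <- 0L
      rec[[role]] <- nq
    } else {
      rec[[role]] <- ifelse(is.na(rec[[sub("^nq_", "", role)]]), 0L, 1L)
    }
  }
  exposure_dataset(rec, cell_line = cell_line, emf_type = emf_type)
}

#' Write a dataset in the canonical oriented table layout
#'
#' Emits a tab-delimited table with fixed column order: identity columns,
#' flags, peptide count, intensity, the six oriented log2 ratios and the
#' six quantitation-event counts. This is the lossless internal
#' serialization; for the raw-orientation linear dialect see
#' [write_maxquant_like()].
#'
#' @param ds An `ExposureDataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(ds, path) {
  cols <- c("group_id", "leading_accession", "gene_symbol", "species",
            "is_decoy", "is_contaminant", "n_razor_unique_peptides",
            "intensity", RATIO_COLS, NQ_COLS)
  utils::write.table(ds$records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Quality filter for protein groups
#'
#' Removes decoy (reversed-sequence) hits, known contaminants and groups
#' quantified with fewer than `min_peptides` razor and/or unique peptides.
#'
#' @param ds An `ExposureDataset`.
#' @param min_peptides Minimum razor + unique peptide count (default 2).
#' @return The filtered `ExposureDataset`; the per-reason removal counts
#'   are attached as attribute `"removed"` (decoy, contaminant, peptides).
#' @export
filter_quality <- function(ds, min_peptides = 2L) {
  rec <- ds$records
  drop_decoy <- rec$is_decoy
  drop_cont <- !drop_decoy & rec$is_contaminant
  drop_pep <- !drop_decoy & !drop_cont &
    rec$n_razor_unique_peptides < min_peptides
  keep <- !(drop_decoy | drop_cont | drop_pep)
  if (!any(keep)) warning("filter_quality removed every protein group")
  out <- subset_dataset(ds, keep)
  attr(out, "removed") <- c(decoy = sum(drop_decoy),
                            contaminant = sum(drop_cont),
                            peptides = sum(drop_pep))
  out
}

#' Median-center the six ratio columns
#'
#' Subtracts the per-column median (over non-missing entries) from each of
#' the six log2 ratio columns, correcting for unequal protein loading.
#' Columns with fewer than 3 non-missing values are skipped with a
#' warning. The applied offsets are recorded in
#' `normalization_offsets`; applying the function twice is a no-op on the
#' ratios.
#'
#' @param ds An `ExposureDataset`.
#' @return The normalized `ExposureDataset`.
#' @export
normalize_ratios <- function(ds) {
  offsets <- stats::setNames(numeric(length(RATIO_COLS)), RATIO_COLS)
  for (col in RATIO_COLS) {
    x <- ds$records[[col]]
    if (sum(!is.na(x)) < 3L) {
      warning(sprintf("ratio column '%s' has < 3 values; not centered", col))
      next
    }
    offsets[col] <- stats::median(x, na.rm = TRUE)
    ds$records[[col]] <- x - offsets[col]
  }
  prev <- ds$normalization_offsets
  ds$normalization_offsets <-
    if (is.null(prev)) offsets else prev + offsets
  ds
}

#' Quantitation completeness summary
#'
#' Counts protein groups carrying at least one SILAC ratio in the first
#' labeling experiment, at least one in the second, and all six ratios
#' (complete quantification in both replicates), with percentages relative
#' to the number of groups in `ds`.
#'
#' @param ds A filtered `ExposureDataset`.
#' @return data.frame with columns `class`, `n`, `pct`.
#' @export
quantitation_summary <- function(ds) {
  rep1 <- c("treated_r1_HL", "treated_r1_HM", "control_r1")
  rep2 <- c("treated_r2_LH", "treated_r2_MH", "control_r2")
  m <- ratio_matrix(ds)
  n_total <- nrow(m)
  n_rep1 <- sum(rowSums(!is.na(m[, rep1, drop = FALSE])) > 0L)
  n_rep2 <- sum(rowSums(!is.na(m[, rep2, drop = FALSE])) > 0L)
  n_complete <- sum(rowSums(is.na(m)) == 0L)
  data.frame(
    class = c("replicate1", "replicate2", "complete"),
    n = c(n_rep1, n_rep2, n_complete),
    pct = if (n_total > 0) 100 * c(n_rep1, n_rep2, n_complete) / n_total
          else rep(NA_real_, 3))
}
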