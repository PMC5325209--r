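# Shared in-code fixtures: tiny datasets built from explicit ratio matrices.

ratio_cols <- c("treated_r1_HL", "treated_r1_HM", "treated_r2_LH",
                "treated_r2_MH", "control_r1", "control_r2")

# Build an ExposureDataset from a ratio matrix (rows = proteins, 6 cols of
# oriented log2 ratios; NAs allowed).  Other fields get benign defaults
# overridable via ...
make_ds <- function(ratios, is_decoy = FALSE, is_contaminant = FALSE,
                    peptides = 3L, intensity = 1e9, gene = NULL) {
  ratios <- matrix(ratios, ncol = 6,
                   dimnames = list(NULL, ratio_cols))
  n <- nrow(ratios)
  rec <- data.frame(
    group_id = sprintf("g%03d", seq_len(n)),
    leading_accession = sprintf("P%05d", seq_len(n)),
    gene_symbol = if (is.null(gene)) sprintf("GENE%03d", seq_len(n)) else gene,
    species = "human",
    n_razor_unique_peptides = rep_len(peptides, n),
    intensity = rep_len(intensity, n),
    is_decoy = rep_len(is_decoy, n),
    is_contaminant = rep_len(is_contaminant, n),
    stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(ratios))
  for (cc in paste0("nq_", ratio_cols))
    rec[[cc]] <- ifelse(is.na(ratios[, sub("^nq_", "", cc)]), 0L, 2L)
  exposure_dataset(rec)
}

# Null-model dataset used to calibrate detectors: homoscedastic noise, no
# label bias, no regulation, no missingness (see the methods vignette for
# why this is the detectors' calibration null).
null_calibration_params <- function(n, seed, sd = 0.1) {
  simulation_params(n_proteins = n, frac_regulated = 0, s_HL = 0, s_HM = 0,
                    noise_sd_base = sd, noise_intensity_slope = 0,
                    missing_rate = 0, n_decoys = 0, n_contaminants = 0,
                    seed = seed)
}

extdata <- function(f) {
  path <- system.file("extdata", f, package = "silacswap")
  if (path == "") path <- file.path("../../inst/extdata", f)
  path
}
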