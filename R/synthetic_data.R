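# Ground-truth generator for double-label-swap triplex SILAC data.
#
# Measurement model per protein i (all quantities in log2 units):
#   treated_r1_HL = D + b_HL + e     treated_r2_LH = D - b_HL + e
#   treated_r1_HM = D + b_HM + e     treated_r2_MH = D - b_HM + e
#   control_r1 = control_r2 = kappa * (b_HM - b_HL) + e
# where D is the true regulation effect (0 for unregulated proteins),
# b_HL ~ N(0, s_HL^2) and b_HM ~ N(0, s_HM^2) are per-protein
# label-incorporation biases (the H-L pair is the noisier one), and
# e ~ N(0, sigma(I)^2) is intensity-dependent measurement noise with
# sigma(I) = sigma0 * exp(-slope * (logI - median logI)).  The sign of the
# label bias flips between the two reciprocal labeling experiments while
# the treatment effect does not, which is the property the double-swap
# design exploits.

#' Simulation parameters for the triplex SILAC generator
#'
#' Defaults describe a realistic double-swap experiment at the scale of a
#' single cell line x exposure dataset: ~3000 quantified groups of which
#' ~1% are regulated with modest fold changes, label bias stronger for the
#' H-L pair than the H-M pair, mild intensity-dependent ratio noise, and
#' per-slot missingness giving roughly 60% complete six-ratio records.
#'
#' @param n_proteins Number of genuine protein groups.
#' @param frac_regulated Proportion of regulated proteins (pi).
#' @param effect_log2fc_range Interval for the absolute effect |D| in log2
#'   units; signs are +/- with equal probability.
#' @param noise_sd_base sigma0, baseline ratio noise SD (log2 units).
#' @param noise_intensity_slope Shrinkage of sigma with log10 intensity.
#' @param s_HL,s_HM SDs of the per-protein label-bias effects (log2
#'   units); the H-L labeling pair carries the stronger bias.
#' @param kappa Coupling of the control ratios to the label effects
#'   (1 = controls share the label effects; 0 = pure-noise controls).
#' @param missing_rate Independent per-slot missingness probability.
#' @param n_decoys,n_contaminants Decoy and contaminant records appended
#'   with null-model ratios (filters, not statistics, must remove them).
#' @param intensity_meanlog,intensity_sdlog Mean and SD of log10 summed
#'   peak intensity.
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return A list of class `SimulationParams`.
#' @export
simulation_params <- function(n_proteins = 3000L,
                              frac_regulated = 0.01,
                              effect_log2fc_range = log2(c(1.2, 2.8)),
                              noise_sd_base = 0.1,
                              noise_intensity_slope = 0.3,
                              s_HL = 0.3,
                              s_HM = 0.15,
                              kappa = 1,
                              missing_rate = 0.08,
                              n_decoys = round(0.02 * n_proteins),
                              n_contaminants = round(0.025 * n_proteins),
                              intensity_meanlog = 9,
                              intensity_sdlog = 0.8,
                              seed = 1L) {
  stopifnot(frac_regulated >= 0, frac_regulated <= 1,
            s_HL >= s_HM, s_HM >= 0,
            noise_sd_base > 0,
            effect_log2fc_range[1] > 0,
            effect_log2fc_range[2] >= effect_log2fc_range[1],
            missing_rate >= 0, missing_rate < 1,
            kappa >= 0, kappa <= 1)
  structure(as.list(environment()), class = "SimulationParams")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a double-label-swap SILAC dataset with known ground truth
#'
#' Draws per-protein intensities, regulation effects, label-bias effects
#' and intensity-dependent noise under the generator's measurement model
#' (see the package vignette), applies per-slot missingness, and appends
#' decoy and contaminant records whose ratios follow the null model.
#'
#' @param params A [simulation_params()] object.
#' @return A list with elements `dataset` (an `ExposureDataset`) and
#'   `truth` (data.frame: `group_id`, `regulated`, `true_log2fc`,
#'   `true_intensity`).
#' @export
simulate_exposure <- function(params = simulation_params()) {
  stopifnot(inherits(params, "SimulationParams"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_proteins
    n_reg <- round(p$frac_regulated * n)
    if (p$frac_regulated > 0 && n_reg < 1L)
      warning("frac_regulated * n_proteins < 1: no regulated proteins drawn")
    regulated <- rep(FALSE, n)
    if (n_reg >= 1L) regulated[sample.int(n, n_reg)] <- TRUE
    delta <- numeric(n)
    if (n_reg >= 1L)
      delta[regulated] <- sample(c(-1, 1), n_reg, replace = TRUE) *
        stats::runif(n_reg, p$effect_log2fc_range[1], p$effect_log2fc_range[2])

    log_int <- stats::rnorm(n, p$intensity_meanlog, p$intensity_sdlog)
    sigma <- p$noise_sd_base *
      exp(-p$noise_intensity_slope * (log_int - stats::median(log_int)))
    b_hl <- stats::rnorm(n, 0, p$s_HL)
    b_hm <- stats::rnorm(n, 0, p$s_HM)
    eps <- matrix(stats::rnorm(6L * n, 0, sigma), nrow = n, ncol = 6L)
    ctrl <- p$kappa * (b_hm - b_hl)
    ratios <- cbind(
      treated_r1_HL = delta + b_hl + eps[, 1],
      treated_r1_HM = delta + b_hm + eps[, 2],
      treated_r2_LH = delta - b_hl + eps[, 3],
      treated_r2_MH = delta - b_hm + eps[, 4],
      control_r1 = ctrl + eps[, 5],
      control_r2 = ctrl + eps[, 6])
    if (p$missing_rate > 0) {
      drop <- matrix(stats::runif(6L * n) < p$missing_rate, nrow = n)
      ratios[drop] <- NA_real_
    }

    z_int <- (log_int - mean(log_int)) / max(p$intensity_sdlog, 1e-9)
    peptides <- 1L + stats::rpois(n, exp(1.1 + 0.5 * z_int))
    nq <- matrix(ifelse(is.na(ratios), 0L,
                        1L + stats::rpois(6L * n, 2)), nrow = n)

    rec <- data.frame(
      group_id = sprintf("grp%05d", seq_len(n)),
      leading_accession = sprintf("ACC%05d", seq_len(n)),
      gene_symbol = sprintf("GENE%05d", seq_len(n)),
      species = "human",
      n_razor_unique_peptides = peptides,
      intensity = 10^log_int,
      is_decoy = FALSE,
      is_contaminant = FALSE,
      stringsAsFactors = FALSE)
    rec <- cbind(rec, as.data.frame(ratios))
    colnames(nq) <- NQ_COLS
    rec <- cbind(rec, as.data.frame(nq))

    extra <- p$n_decoys + p$n_contaminants
    if (extra > 0) {
      li <- stats::rnorm(extra, p$intensity_meanlog, p$intensity_sdlog)
      si <- p$noise_sd_base *
        exp(-p$noise_intensity_slope * (li - stats::median(log_int)))
      bl <- stats::rnorm(extra, 0, p$s_HL)
      bm <- stats::rnorm(extra, 0, p$s_HM)
      ee <- matrix(stats::rnorm(6L * extra, 0, si), nrow = extra)
      cc <- p$kappa * (bm - bl)
      rx <- cbind(bl + ee[, 1], bm + ee[, 2], -bl + ee[, 3], -bm + ee[, 4],
                  cc + ee[, 5], cc + ee[, 6])
      if (p$missing_rate > 0)
        rx[matrix(stats::runif(6L * extra) < p$missing_rate,
                  nrow = extra)] <- NA_real_
      colnames(rx) <- RATIO_COLS
      is_dec <- seq_len(extra) <= p$n_decoys
      xrec <- data.frame(
        group_id = sprintf("xtr%05d", seq_len(extra)),
        leading_accession = ifelse(is_dec,
                                   sprintf("REV__ACCX%04d", seq_len(extra)),
                                   sprintf("CON__ACCX%04d", seq_len(extra))),
        gene_symbol = ifelse(is_dec, "", sprintf("CONT%04d", seq_len(extra))),
        species = "other",
        n_razor_unique_peptides = 1L + stats::rpois(extra, 2),
        intensity = 10^li,
        is_decoy = is_dec,
        is_contaminant = !is_dec,
        stringsAsFactors = FALSE)
      xrec <- cbind(xrec, as.data.frame(rx))
      xnq <- matrix(ifelse(is.na(rx), 0L, 1L + stats::rpois(6L * extra, 2)),
                    nrow = extra)
      colnames(xnq) <- NQ_COLS
      xrec <- cbind(xrec, as.data.frame(xnq))
      rec <- rbind(rec, xrec)
    }

    truth <- data.frame(
      group_id = sprintf("grp%05d", seq_len(n)),
      regulated = regulated,
      true_log2fc = delta,
      true_intensity = 10^log_int,
      stringsAsFactors = FALSE)
    list(dataset = exposure_dataset(rec, cell_line = "simulated",
                                    emf_type = "synthetic"),
         truth = truth)
  })
}

#' Serialize a dataset in the raw-orientation MaxQuant-like dialect
#'
#' Writes linear (unlogged) ratios with the raw instrument orientation:
#' the replicate-2 treated columns are written as heavy-over-light style
#' sham/exposed ratios (the reciprocal of the stored oriented value), so
#' that [read_protein_groups()] with [maxquant_column_map()] round-trips
#' the oriented log2 ratios. Missing slots serialize as empty cells;
#' decoys carry `"+"` in the Reverse column.
#'
#' @param ds An `ExposureDataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maxquant_like <- function(ds, path) {
  cmap <- maxquant_column_map()
  rec <- ds$records
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = rec$group_id, b = rec$leading_accession, c = rec$gene_symbol,
    d = rec$species, e = rec$n_razor_unique_peptides,
    f = format(rec$intensity, trim = TRUE, scientific = FALSE),
    g = ifelse(rec$is_decoy, "+", ""),
    h = ifelse(rec$is_contaminant, "+", ""))
  names(out) <- unname(cmap$columns[c(
    "group_id", "leading_accession", "gene_symbol", "species",
    "n_razor_unique_peptides", "intensity", "is_decoy", "is_contaminant")])
  for (role in RATIO_COLS) {
    lg <- rec[[role]]
    if (role %in% cmap$invert) lg <- -lg
    lin <- 2^lg
    out[[cmap$columns[role]]] <-
      ifelse(is.na(lin), "", formatC(lin, digits = 17, format = "g"))
  }
  for (role in NQ_COLS) out[[cmap$columns[role]]] <- rec[[role]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Simulate a term-annotation structure with noisy study-set observation
#'
#' Generates a bipartite term-to-item annotation map, activates
#' `n_active` terms, sets the hidden state of every item to the OR of its
#' active annotating terms, and observes a study set in which inactive
#' items enter with false-positive rate `alpha` and active items are
#' missed with false-negative rate `beta`. This is the generative model
#' inverted by [mgsa_enumerate()] / [mgsa_mcmc()].
#'
#' @param n_terms,n_items Numbers of terms and annotatable items.
#' @param items_per_term Average annotation size; realized sizes are
#'   `1 + rpois(items_per_term - 1)`, so every term annotates >= 1 item.
#' @param n_active Number of active (ground-truth) terms.
#' @param alpha,beta Observation noise rates, each in [0, 0.5).
#' @param seed Integer seed.
#' @return A list: `annotations` (data.frame `term`, `item`), `active`
#'   (character), `study_set` (character), `items` (universe).
#' @export
simulate_annotations <- function(n_terms = 20L, n_items = 500L,
                                 items_per_term = 15, n_active = 2L,
                                 alpha = 0.05, beta = 0.2, seed = 1L) {
  stopifnot(alpha >= 0, alpha < 0.5, beta >= 0, beta < 0.5,
            n_active <= n_terms, items_per_term >= 1)
  with_seed(seed, {
    items <- sprintf("item%04d", seq_len(n_items))
    terms <- sprintf("term%03d", seq_len(n_terms))
    sizes <- 1L + stats::rpois(n_terms, items_per_term - 1)
    sizes <- pmin(sizes, n_items)
    anno <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
      data.frame(term = terms[t], item = sample(items, sizes[t]),
                 stringsAsFactors = FALSE)
    }))
    active <- if (n_active > 0) sample(terms, n_active) else character(0)
    hidden_on <- unique(anno$item[anno$term %in% active])
    hidden_off <- setdiff(items, hidden_on)
    observed <- c(hidden_on[stats::runif(length(hidden_on)) >= beta],
                  hidden_off[stats::runif(length(hidden_off)) < alpha])
    list(annotations = anno, active = active,
         study_set = sort(observed), items = items)
  })
}
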