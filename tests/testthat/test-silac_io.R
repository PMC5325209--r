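test_that("reader applies log2, reciprocal reorientation and missingness rules", {
  tmp <- tempfile(fileext = ".tsv")
  cmap <- maxquant_column_map()
  header <- unname(cmap$columns[c("group_id", "leading_accession",
                                  "gene_symbol", "species",
                                  "n_razor_unique_peptides", "intensity",
                                  "is_decoy", "is_contaminant",
                                  "treated_r1_HL", "treated_r1_HM",
                                  "control_r1", "treated_r2_LH",
                                  "treated_r2_MH", "control_r2")])
  rows <- c(
    # r2 H/L raw 2.0 -> oriented log2 = -1; raw 0.5 -> +1
    "g1\tP1\tA\thuman\t3\t1e9\t\t\t2.0\t1.0\t1.0\t2.0\t1.0\t1.0",
    "g2\tP2\tB\thuman\t3\t1e9\t\t\t0.5\t1.0\t1.0\t0.5\t1.0\t1.0",
    # decoy row, empty + zero ratio cells -> missing slots
    "g3\tREV__P3\t\thuman\t2\t1e8\t+\t\t\t0\t1.0\t4.0\t1.0\t1.0",
    # non-numeric ratio cell -> warning + missing
    "g4\tP4\tD\thuman\t3\t1e9\t\t+\tabc\t1.0\t1.0\t1.0\t1.0\t1.0")
  writeLines(c(paste(header, collapse = "\t"), rows), tmp)
  expect_warning(ds <- read_protein_groups(tmp), "non-numeric")

  m <- ratio_matrix(ds)
  expect_equal(unname(m[1, "treated_r1_HL"]), 1)          # log2(2.0)
  expect_equal(unname(m[1, "treated_r2_LH"]), -1)         # inverted
  expect_equal(unname(m[2, "treated_r2_LH"]), 1)          # log2(1/0.5)
  expect_true(is.na(m[3, "treated_r1_HL"]))       # empty cell
  expect_true(is.na(m[3, "treated_r1_HM"]))       # zero cell
  expect_true(is.na(m[4, "treated_r1_HL"]))       # non-numeric cell
  expect_equal(ds$records$is_decoy, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(ds$records$is_contaminant, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(ratio_complete(ds)[3])
  expect_true(ratio_complete(ds)[1])

  # missing mapped column is a hard error naming the column
  bad <- maxquant_column_map()
  bad$columns["intensity"] <- "Nonexistent"
  expect_error(read_protein_groups(tmp, bad), "Nonexistent")
})

test_that("write/read round trip is bit-faithful for mapped fields", {
  sim <- simulate_exposure(simulation_params(n_proteins = 60L, seed = 42,
                                             missing_rate = 0.15))
  tmp <- tempfile(fileext = ".tsv")
  write_maxquant_like(sim$dataset, tmp)
  back <- read_protein_groups(tmp)
  expect_equal(ratio_matrix(back), ratio_matrix(sim$dataset),
               tolerance = 1e-12)
  for (col in c("group_id", "leading_accession", "gene_symbol",
                "is_decoy", "is_contaminant", "n_razor_unique_peptides"))
    expect_identical(back$records[[col]], sim$dataset$records[[col]])
  # decoys serialize with "+"
  raw <- utils::read.delim(tmp, check.names = FALSE)
  expect_identical(raw$Reverse == "+", sim$dataset$records$is_decoy)
  # canonical oriented writer also round-trips
  tmp2 <- tempfile(fileext = ".tsv")
  write_protein_groups(back, tmp2)
  expect_true(file.exists(tmp2))
})

test_that("filter_quality removes decoys, contaminants and low-peptide groups", {
  ds <- make_ds(matrix(0.1, 10, 6),
                is_decoy = c(TRUE, TRUE, rep(FALSE, 8)),
                is_contaminant = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
                peptides = c(3, 3, 3, 1, rep(3, 6)))
  out <- filter_quality(ds)
  expect_equal(nrow(out$records), 6)
  expect_equal(attr(out, "removed"),
               c(decoy = 2, contaminant = 1, peptides = 1))
  expect_equal(sum(attr(out, "removed")) + nrow(out$records),
               nrow(ds$records))

  # min_peptides = 0 on clean input is the identity
  clean <- make_ds(matrix(0.1, 4, 6))
  expect_equal(filter_quality(clean, 0L)$records, clean$records)

  # all-decoy input -> empty + warning
  alld <- make_ds(matrix(0.1, 3, 6), is_decoy = TRUE)
  expect_warning(res <- filter_quality(alld), "every protein group")
  expect_equal(nrow(res$records), 0)
})

test_that("normalize_ratios median-centers, records offsets, is idempotent", {
  m <- matrix(0, 3, 6)
  m[, 1] <- c(0.9, 1.0, 1.1)
  ds <- make_ds(m)
  expect_warning(norm <- normalize_ratios(ds), NA)
  expect_equal(norm$records$treated_r1_HL, c(-0.1, 0, 0.1))
  expect_equal(unname(norm$normalization_offsets["treated_r1_HL"]), 1.0)
  # already-centered column -> zero offset; idempotence
  again <- normalize_ratios(norm)
  expect_equal(ratio_matrix(again), ratio_matrix(norm))
  for (col in colnames(ratio_matrix(again)))
    expect_equal(median(ratio_matrix(again)[, col], na.rm = TRUE), 0,
                 tolerance = 1e-9)
})

test_that("normalization recovers an injected loading shift", {
  sim <- simulate_exposure(simulation_params(n_proteins = 2000L, seed = 5,
                                             missing_rate = 0))
  ds <- sim$dataset
  shift <- 0.4
  ds$records$treated_r1_HL <- ds$records$treated_r1_HL + shift
  norm <- normalize_ratios(ds)
  # SE(median) ~ 1.2533 * sd/sqrt(n)
  se <- 1.2533 * sd(ds$records$treated_r1_HL) / sqrt(2000)
  expect_lt(abs(norm$normalization_offsets["treated_r1_HL"] - shift), 2 * se +
              abs(median(sim$dataset$records$treated_r1_HL)))
})

test_that("quantitation_summary counts replicate and complete quantifications", {
  m <- matrix(0.1, 5, 6)
  m[4, 6] <- NA          # misses replicate-2 control -> not complete
  m[5, c(1, 2, 5)] <- NA # nothing in replicate 1
  ds <- make_ds(m)
  qs <- quantitation_summary(ds)
  expect_equal(qs$n[qs$class == "complete"], 3)
  expect_equal(qs$pct[qs$class == "complete"], 60)
  expect_equal(qs$n[qs$class == "replicate1"], 4)
  expect_equal(qs$n[qs$class == "replicate2"], 5)

  # closed form: complete fraction ~ (1 - m)^6
  sim <- simulate_exposure(simulation_params(n_proteins = 5000L, seed = 8,
                                             missing_rate = 0.2,
                                             n_decoys = 0,
                                             n_contaminants = 0))
  qs2 <- quantitation_summary(sim$dataset)
  p_expect <- 0.8^6
  se <- sqrt(p_expect * (1 - p_expect) / 5000)
  expect_lt(abs(qs2$pct[qs2$class == "complete"] / 100 - p_expect), 3 * se)
})
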