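test_that("bh_adjust matches the hand step-up and is permutation-stable", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))  # dual route
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))
})

test_that("fold-change estimate, magnitude and direction", {
  m <- rbind(c(1, 1, 1, 1, 0, 0),
             rep(c(-0.263, 0), c(4, 2)),
             c(0.5, -0.5, 0.5, -0.5, 0, 0),
             c(1, 1, 1, NA, 0, 0))
  fce <- fold_change_estimate(make_ds(m))
  expect_equal(fce$fc_estimate[1], 2)
  expect_equal(fce$direction[1], "up")
  expect_equal(fce$magnitude[2], 2^0.263, tolerance = 1e-12)  # ~1.2 boundary
  expect_equal(fce$magnitude[3], 1)
  expect_true(is.na(fce$fc_estimate[4]))  # missing treated slot
})

test_that("Z and M scores: centers, hand oracle, and null calibration", {
  vals <- c(1, 2, 3, 4, 100)
  m <- cbind(vals, vals, vals, vals, 0, 0)
  ds <- make_ds(m)
  z <- z_score_test(ds)
  mm <- m_score_test(ds)
  # x at the median -> M = 0; at the mean -> Z = 0
  expect_equal(mm$statistic[3], 0)               # median is 3
  expect_equal(mm$statistic[5], 0.6745 * 97)     # MAD_unscaled = 1
  expect_equal(z$statistic[which.min(abs(vals - mean(vals)))],
               (vals[which.min(abs(vals - mean(vals)))] - mean(vals)) / sd(vals))
  # standard-normal x: fraction |Z| > 1.96 ~ 0.05
  set.seed(50)
  x <- rnorm(10000)
  mn <- cbind(x, x, x, x, 0, 0)
  zz <- z_score_test(make_ds(mn))
  frac <- mean(abs(zz$statistic) > 1.96)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
  # Z == M on a symmetric fixture where sd equals the scaled MAD
  a <- sqrt((4 * 1.4826^2 - 2) / 2)
  xs <- c(-a, -1, 0, 1, a)
  ms <- cbind(xs, xs, xs, xs, 0, 0)
  zs <- z_score_test(make_ds(ms))$statistic
  msc <- m_score_test(make_ds(ms))$statistic
  expect_equal(zs, msc, tolerance = 1e-4)
  # degenerate spread errors
  expect_error(z_score_test(make_ds(matrix(0.2, 5, 6))), "zero dispersion")
  expect_error(m_score_test(make_ds(matrix(0.2, 5, 6))), "zero MAD")
})

test_that("significance B: calibration at the bin median and percentiles", {
  set.seed(61)
  x <- rnorm(4000, 0, 0.2)
  m <- cbind(x, x, x, x, 0, 0)
  ds <- make_ds(m, intensity = runif(4000, 1e6, 1e9))
  sb <- significance_b(ds, min_bin = 4000)      # single bin
  # protein at the bin median has z ~ 0, tail p ~ 0.5
  i_med <- which.min(abs(x - median(x)))
  expect_lt(abs(sb$p_tail[i_med] - 0.5), 0.02)
  # percentile consistency: x = 1.96 * sigma has tail p ~ 0.025
  i_out <- which.min(abs(x - 1.96 * 0.2))
  expect_lt(abs(sb$p_tail[i_out] - 0.025), 0.01)
  # intensity binning: same |x| is less surprising where noise is larger
  x_lo <- rnorm(300, 0, 0.3); x_hi <- rnorm(300, 0, 0.1)
  x2 <- c(x_lo, 0.5, x_hi, 0.5)          # one 0.5 probe per noise regime
  inten <- c(runif(301, 1e6, 1e7), runif(301, 1e8, 1e9))
  ds3 <- make_ds(cbind(x2, x2, x2, x2, 0, 0), intensity = inten)
  sb3 <- significance_b(ds3, min_bin = 301)
  expect_lt(sb3$p_tail[602], sb3$p_tail[301])
})

test_that("rank product agrees with exhaustive enumeration", {
  # independent oracle at n = 6, k = 2: enumerate all 36 rank tuples
  set.seed(2)
  m <- matrix(rnorm(12), ncol = 2)
  res <- rank_product_matrix(m, exact = TRUE)
  g <- expand.grid(r1 = 1:6, r2 = 1:6)
  null_rp <- sqrt(g$r1 * g$r2) / 6
  oracle <- function(rp) sapply(rp, function(r) mean(null_rp <= r + 1e-12))
  expect_equal(res$p_up, oracle(res$rp_up))
  expect_equal(res$p_down, oracle(res$rp_down))
  # protein ranked first in all 4 columns of n = 5: p_up = 1 / 5^4
  m2 <- matrix(rep(5:1, 4), ncol = 4)
  expect_equal(rank_product_matrix(m2, exact = TRUE)$p_up[1], 1 / 5^4)
  # permutation estimate converges to the exact null
  res_perm <- rank_product_matrix(m, n_perm = 4000, seed = 3)
  expect_equal(res_perm$p_up, res$p_up, tolerance = 0.05)
  # identical columns: RP spectrum equals the single-column rank fractions
  v <- c(3, 1, 4, 2)
  m3 <- cbind(v, v, v, v)
  expect_equal(sort(rank_product_matrix(m3, exact = TRUE)$rp_up),
               (1:4) / 4)
})

test_that("fcros statistic: center, monotonicity, extremes", {
  set.seed(9)
  base <- rnorm(200, 0, 0.1)
  m <- cbind(base, base + rnorm(200, 0, 0.02),
             base + rnorm(200, 0, 0.02), base + rnorm(200, 0, 0.02), 0, 0)
  m[1, 1:4] <- 5      # ranked last (largest) everywhere
  ds <- make_ds(m)
  fr <- fcros_test(ds)
  expect_equal(which.max(fr$statistic), 1)
  expect_equal(which.min(fr$p_raw[is.finite(fr$p_raw)]), 1)
  # rbar at 0.5 -> p ~ 1
  i_mid <- which.min(abs(fr$statistic - 0.5))
  expect_gt(fr$p_raw[i_mid], 0.9)
  expect_warning(fcros_test(make_ds(matrix(rnorm(36), 6, 6))), "n < 20")
})

test_that("moderated threshold test matches the limma oracle", {
  # heteroscedastic fixture with label-bias structure
  sim <- simulate_exposure(simulation_params(
    n_proteins = 600L, frac_regulated = 0.02,
    effect_log2fc_range = log2(c(1.5, 2.5)), missing_rate = 0,
    n_decoys = 0, n_contaminants = 0, seed = 71))
  ds <- sim$dataset
  ours <- moderated_treat(ds, tau = 1.2)
  y <- ratio_matrix(ds)     # proteins x 6 "samples"
  design <- cbind(tr = c(1, 1, 1, 1, 0, 0), ct = c(0, 0, 0, 0, 1, 1))
  fit <- limma::lmFit(y, design)
  fit2 <- limma::contrasts.fit(fit, c(1, -1))
  tre <- limma::treat(fit2, lfc = log2(1.2))
  expect_equal(ours$p_raw, unname(tre$p.value[, 1]), tolerance = 0.02)
  expect_gt(cor(-log10(ours$p_raw), -log10(tre$p.value[, 1])), 0.999)
  # tau = 1 reduces to the ordinary moderated t of the contrast
  ours1 <- moderated_treat(ds, tau = 1)
  eb <- limma::eBayes(fit2)
  expect_equal(ours1$p_raw, unname(eb$p.value[, 1]), tolerance = 0.02)
})

test_that("treated/control contrast, not the raw mean, drives the call", {
  # a protein whose treated and control ratios move together (pure label
  # artifact) is not significant; an equal shift with quiet controls is
  set.seed(15)
  n <- 300
  base <- matrix(rnorm(6 * n, 0, 0.1), n, 6)
  base[1, ] <- c(1, 1, 1, 1, 0.95, 1.05)   # artifact
  base[2, ] <- c(1, 1, 1, 1, 0.01, -0.01)  # genuine
  ds <- make_ds(base)
  res <- moderated_treat(ds, tau = 1.2)
  expect_gt(res$p_raw[1], 0.5)
  expect_lt(res$p_raw[2], 1e-4)
})

test_that("ensemble union: provenance, conflicts, tier monotonicity", {
  mk <- function(method, p, fc, dir) {
    structure(data.frame(group_id = sprintf("g%02d", seq_along(p)),
                         fc_estimate = fc, direction = dir,
                         statistic = 0, p_raw = p,
                         p_adj = bh_adjust(p), stringsAsFactors = FALSE),
              method = method, class = c("MethodResult", "data.frame"))
  }
  r1 <- mk("RankProd", c(0.005, 0.8, 0.02), c(1.6, 1.0, 0.6), c("up", "up", "down"))
  r2 <- mk("Z", c(0.5, 0.9, 0.01), c(1.5, 1.0, 1.7), c("up", "up", "up"))
  ens <- ensemble_union(list(r1, r2), fc_tier = 1.2, p_tier = 0.1)
  expect_equal(ens$member, c(TRUE, FALSE, TRUE))
  expect_equal(ens$methods[1], "RankProd")
  expect_true(ens$conflicted[3])           # RankProd down, Z up
  expect_equal(ens$direction[3], "conflicted")
  # non-member has no supporting methods
  expect_equal(ens$n_methods[2], 0)
  # monotonicity: relaxing the tier never removes members
  strict <- ensemble_union(list(r1, r2), p_tier = 0.01)
  loose <- ensemble_union(list(r1, r2), p_tier = 0.2)
  expect_true(all(loose$member[strict$member]))
  # FC-only method membership via the fold-change tier
  rfc <- mk("FC", c(NA, NA, NA), c(1.6, 1.1, 1.0), c("up", "down", "up"))
  ens_fc <- ensemble_union(list(rfc), fc_tier = 1.5)
  expect_equal(ens_fc$member, c(TRUE, FALSE, FALSE))
})

test_that("z_threshold reproduces the two-tailed critical values", {
  expect_equal(z_threshold(0.05), qnorm(0.975))
  expect_equal(round(z_threshold(0.01), 2), 2.58)
})
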