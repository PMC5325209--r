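# Differential-regulation detectors and their ensemble.
#
# Six detectors operate on the oriented log2 ratios:
#   FC        plain fold-change magnitude (no p-value)
#   sigB      intensity-binned, percentile-calibrated outlier probability
#   Z         standard score of the per-protein mean treated ratio
#   M         robust score using median and MAD
#   RankProd  geometric mean of per-column ranks, permutation-calibrated
#   FCROS     mean rank fraction calibrated against a normal null at 0.5
#   TREAT     moderated t against a fold-change threshold, with
#             empirical-Bayes variance shrinkage and the design encoded
#             as a treated-vs-control contrast
# Every statistical detector reports raw two-tailed p-values and
# Benjamini-Hochberg adjusted values.

method_result <- function(method, group_id, fc_estimate, direction,
                          statistic, p_raw) {
  p_adj <- if (all(is.na(p_raw))) p_raw else bh_adjust(p_raw)
  structure(data.frame(group_id = group_id,
                       fc_estimate = fc_estimate,
                       direction = direction,
                       statistic = statistic,
                       p_raw = p_raw,
                       p_adj = p_adj,
                       stringsAsFactors = FALSE),
            method = method, class = c("MethodResult", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs allowed and
#'   preserved).
#' @return Adjusted p-values, monotone in the ranks and capped at 1.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  x <- p[ok]
  n <- length(x)
  if (n > 0) {
    o <- order(x, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(n / (n:1) * x[o]))[ro]
    out[ok] <- adj
  }
  out
}

mean_treated <- function(ds, min_slots = 2L) {
  tm <- ratio_matrix(ds, TREATED_COLS)
  k <- rowSums(!is.na(tm))
  x <- rowMeans(tm, na.rm = TRUE)
  x[k < min_slots] <- NA_real_
  x
}

#' Fold-change estimate from the four treated ratios
#'
#' `fc = 2^mean(treated log2 ratios)`; the thresholdable magnitude is
#' `max(fc, 1/fc)` and the direction is the sign of the mean.
#'
#' @param ds An `ExposureDataset`.
#' @param min_slots Minimum number of present treated slots (default 4:
#'   all four required; proteins below get NA).
#' @return data.frame: `group_id`, `fc_estimate` (linear, > 0),
#'   `magnitude`, `direction`.
#' @export
fold_change_estimate <- function(ds, min_slots = 4L) {
  x <- mean_treated(ds, min_slots = min_slots)
  fc <- 2^x
  data.frame(group_id = ds$records$group_id,
             fc_estimate = fc,
             magnitude = pmax(fc, 1 / fc),
             direction = ifelse(is.na(x), NA_character_,
                                ifelse(x >= 0, "up", "down")),
             stringsAsFactors = FALSE)
}

fc_method_result <- function(ds, min_slots = 4L) {
  fce <- fold_change_estimate(ds, min_slots = min_slots)
  method_result("FC", fce$group_id, fce$fc_estimate, fce$direction,
                statistic = fce$magnitude, p_raw = NA_real_)
}

#' Critical |Z| for a two-tailed normal p-value threshold
#'
#' @param p_tier Two-tailed p-value threshold.
#' @return `qnorm(1 - p_tier / 2)`.
#' @export
z_threshold <- function(p_tier) stats::qnorm(1 - p_tier / 2)

#' Z-score detector
#'
#' Standardizes the per-protein mean treated log2 ratio against the mean
#' and SD over all proteins; two-tailed normal p-values, BH-adjusted.
#'
#' @param ds An `ExposureDataset`.
#' @param min_slots Minimum present treated slots per protein (default 4:
#'   the label bias only cancels in the mean over all four swap slots).
#' @return A `MethodResult` data.frame.
#' @export
z_score_test <- function(ds, min_slots = 4L) {
  x <- mean_treated(ds, min_slots)
  if (sum(!is.na(x)) < 3L) stop("need >= 3 proteins with a mean treated ratio")
  s <- stats::sd(x, na.rm = TRUE)
  if (s == 0) stop("zero dispersion: Z-score undefined")
  z <- (x - mean(x, na.rm = TRUE)) / s
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  method_result("Z", ds$records$group_id, 2^x,
                ifelse(x >= 0, "up", "down"), z, p)
}

#' M-score detector (robust Z)
#'
#' `M = 0.6745 * (x - median(x)) / MAD_unscaled(x)` on the per-protein
#' mean treated log2 ratios; since `0.6745 = 1/1.4826` this equals
#' standardization by the scaled MAD. Two-tailed normal p-values,
#' BH-adjusted.
#'
#' @inheritParams z_score_test
#' @return A `MethodResult` data.frame.
#' @export
m_score_test <- function(ds, min_slots = 4L) {
  x <- mean_treated(ds, min_slots)
  if (sum(!is.na(x)) < 3L) stop("need >= 3 proteins with a mean treated ratio")
  mad0 <- ratio_mad(x, scaled = FALSE)
  if (mad0 == 0) stop("zero MAD: M-score undefined")
  m <- 0.6745 * (x - stats::median(x, na.rm = TRUE)) / mad0
  p <- 2 * stats::pnorm(abs(m), lower.tail = FALSE)
  method_result("M", ds$records$group_id, 2^x,
                ifelse(x >= 0, "up", "down"), m, p)
}

#' Intensity-binned significance B
#'
#' Sorts proteins by summed peak intensity, partitions them into
#' consecutive bins of at least `min_bin` proteins (the last bin absorbs
#' the remainder; a single bin is used when `n < 2 * min_bin`), and
#' calibrates each protein's mean treated log2 ratio against its bin's
#' 15.87/50/84.13 percentiles `r-1, r0, r1`: right-tail
#' `z = (x - r0)/(r1 - r0)`, left-tail `z = (r0 - x)/(r0 - r-1)`. The
#' one-sided tail probability `1 - pnorm(z)` is reported in column
#' `p_tail`; `p_raw` is the two-tailed value `min(1, 2 * p_tail)` used
#' for tiering, BH-adjusted into `p_adj`.
#'
#' @param ds An `ExposureDataset`.
#' @param min_bin Minimum proteins per intensity bin (default 300).
#' @param min_slots Minimum present treated slots per protein.
#' @return A `MethodResult` data.frame with extra column `p_tail`.
#' @export
significance_b <- function(ds, min_bin = 300L, min_slots = 4L) {
  x <- mean_treated(ds, min_slots)
  intensity <- ds$records$intensity
  ok <- !is.na(x)
  idx <- which(ok)[order(intensity[ok])]
  n <- length(idx)
  if (n < 3L) stop("need >= 3 proteins for significance B")
  n_bins <- max(1L, n %/% min_bin)
  sizes <- rep(n %/% n_bins, n_bins)
  if (n_bins > 1L) sizes[n_bins] <- sizes[n_bins] + n %% n_bins
  else sizes <- n
  bin_of <- rep(seq_len(n_bins), sizes)
  z <- rep(NA_real_, length(x))
  for (b in seq_len(n_bins)) {
    ii <- idx[bin_of == b]
    q <- stats::quantile(x[ii], c(0.1587, 0.5, 0.8413), names = FALSE)
    if (q[3] <= q[2] || q[2] <= q[1])
      stop(sprintf(
        "significance B: degenerate percentiles in intensity bin %d; use fewer/larger bins", b))
    xi <- x[ii]
    z[ii] <- ifelse(xi > q[2], (xi - q[2]) / (q[3] - q[2]),
                    (q[2] - xi) / (q[2] - q[1]))
  }
  p_tail <- stats::pnorm(z, lower.tail = FALSE)
  p <- pmin(1, 2 * p_tail)
  res <- method_result("sigB", ds$records$group_id, 2^x,
                       ifelse(x >= 0, "up", "down"), z, p)
  res$p_tail <- p_tail
  res
}

rank_desc <- function(x) rank(-x, ties.method = "average")

rp_values <- function(rank_mat) {
  n <- nrow(rank_mat)
  exp(rowMeans(log(rank_mat / n)))
}

# Exact null CDF of the rank product when each of k columns contributes an
# independent uniform rank on 1..n (the marginal null of independently
# permuted columns).  Returns P(RP_null <= r) for each observed r.
rp_exact_p <- function(rp_obs, n, k) {
  if (n^k > 2e6) stop("exhaustive rank-product null too large; use permutations")
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), k)))
  null_rp <- exp(rowMeans(log(grid / n)))
  sn <- sort(null_rp)
  findInterval(rp_obs + 1e-12, sn) / length(sn)
}

#' Rank-product detector
#'
#' For up-regulation, ranks each treated column in descending order and
#' forms `RP = (prod ranks / n)^(1/4)`; the null is obtained by
#' independently permuting each column's ranks `n_perm` times, pooling the
#' permuted RP values over proteins, and `p_up` is the pooled fraction of
#' null values at or below the observed RP. Down-regulation uses
#' ascending ranks; the two-sided p is `min(1, 2 min(p_up, p_down))`,
#' BH-adjusted. Ties get average ranks. With `exact = TRUE` the
#' permutation null is replaced by exhaustive enumeration of all `n^k`
#' rank tuples (small n only).
#'
#' @param ds An `ExposureDataset`; complete cases of the four treated
#'   columns are used.
#' @param n_perm Number of column permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param exact Use the exhaustive enumeration null instead of
#'   permutations.
#' @return A `MethodResult` data.frame with extra columns `p_up`,
#'   `p_down` (rows without complete treated ratios get NA).
#' @export
rank_product <- function(ds, n_perm = 10000L, seed = 1L, exact = FALSE) {
  tm <- ratio_matrix(ds, TREATED_COLS)
  ok <- rowSums(is.na(tm)) == 0L
  res <- rank_product_matrix(tm[ok, , drop = FALSE], n_perm = n_perm,
                             seed = seed, exact = exact)
  x <- rowMeans(tm)
  fill <- function(v) {
    out <- rep(NA_real_, nrow(tm)); out[ok] <- v; out
  }
  mr <- method_result("RankProd", ds$records$group_id, 2^x,
                      ifelse(x >= 0, "up", "down"),
                      fill(res$rp_up), fill(res$p_two))
  mr$p_up <- fill(res$p_up)
  mr$p_down <- fill(res$p_down)
  mr
}

#' Rank-product core on an arbitrary ratio matrix
#'
#' @param m Numeric matrix (proteins x replicate columns), no NAs.
#' @param n_perm,seed,exact See [rank_product()].
#' @return A list: `rp_up`, `rp_down`, `p_up`, `p_down`, `p_two`.
#' @export
rank_product_matrix <- function(m, n_perm = 10000L, seed = 1L,
                                exact = FALSE) {
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("rank product needs >= 2 rows")
  if (!exact && n_perm < 100L)
    warning("n_perm < 100: rank-product p-values will be coarse")
  ranks_up <- apply(m, 2, rank_desc)
  ranks_dn <- apply(m, 2, rank)          # average ties
  rp_up <- rp_values(ranks_up)
  rp_dn <- rp_values(ranks_dn)
  if (exact) {
    p_up <- rp_exact_p(rp_up, n, k)
    p_dn <- rp_exact_p(rp_dn, n, k)
  } else {
    so_up <- sort(rp_up)
    so_dn <- sort(rp_dn)
    cnt_up <- numeric(n)
    cnt_dn <- numeric(n)
    with_seed(seed, {
      base_ranks <- seq_len(n)
      for (b in seq_len(n_perm)) {
        perm <- matrix(0, n, k)
        for (j in seq_len(k)) perm[, j] <- sample(base_ranks)
        null_rp <- rp_values(perm)
        # counts of null values <= each sorted observed value
        h <- findInterval(so_up + 1e-12, sort(null_rp))
        cnt_up <- cnt_up + h
        h <- findInterval(so_dn + 1e-12, sort(null_rp))
        cnt_dn <- cnt_dn + h
      }
    })
    p_up <- (cnt_up / (as.numeric(n_perm) * n))[rank(rp_up, ties.method = "first")]
    p_dn <- (cnt_dn / (as.numeric(n_perm) * n))[rank(rp_dn, ties.method = "first")]
  }
  list(rp_up = rp_up, rp_down = rp_dn, p_up = p_up, p_down = p_dn,
       p_two = pmin(1, 2 * pmin(p_up, p_dn)))
}

#' Fold-change rank ordering statistic (FCROS-style)
#'
#' Converts each treated column to ascending rank fractions
#' `rank/(n + 1)`, averages them per protein, and calibrates the average
#' `rbar` against a normal null centered at 0.5 whose SD is estimated
#' from the central `trim_central` mass of the sorted `rbar` values (by
#' matching the corresponding interquantile range). The f-value is
#' `pnorm((rbar - 0.5)/sigma)`; the two-sided p is `2 min(f, 1 - f)`,
#' BH-adjusted.
#'
#' @param ds An `ExposureDataset`; complete cases of the four treated
#'   columns are used.
#' @param trim_central Central probability mass used for the null-SD fit.
#' @return A `MethodResult` data.frame with extra column `f_value`.
#' @export
fcros_test <- function(ds, trim_central = 0.8) {
  tm <- ratio_matrix(ds, TREATED_COLS)
  ok <- rowSums(is.na(tm)) == 0L
  n <- sum(ok)
  if (n < 4L) stop("fcros needs >= 4 complete proteins")
  if (n < 20L) warning("fcros: n < 20, null SD estimate is unstable")
  rho <- apply(tm[ok, , drop = FALSE], 2, rank) / (n + 1)
  rbar <- rowMeans(rho)
  tail_p <- (1 - trim_central) / 2
  qs <- stats::quantile(rbar, c(tail_p, 1 - tail_p), names = FALSE)
  sigma <- (qs[2] - qs[1]) / (2 * stats::qnorm(1 - tail_p))
  if (sigma <= 0) stop("fcros: degenerate null SD")
  f <- stats::pnorm((rbar - 0.5) / sigma)
  p <- 2 * pmin(f, 1 - f)
  x <- rowMeans(tm)
  fill <- function(v) { out <- rep(NA_real_, nrow(tm)); out[ok] <- v; out }
  mr <- method_result("FCROS", ds$records$group_id, 2^x,
                      ifelse(x >= 0, "up", "down"), fill(rbar), fill(p))
  mr$f_value <- fill(f)
  mr
}

# Newton inversion of the trigamma function (for the empirical-Bayes
# prior-df fit); monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

fit_variance_prior <- function(s2, df) {
  # moment-match log s^2 against a scaled chi^2_{df} times an
  # inverse-chi^2_{d0} prior: digamma/trigamma relations
  s2 <- s2[is.finite(s2) & s2 > 0]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    warning("variance-prior moment fit degenerate; using pooled variance (d0 = Inf)")
    return(list(d0 = Inf, s0_2 = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated fold-change-threshold test (TREAT-style) with the swap
#' design encoded as a contrast
#'
#' Per protein, fits the linear model in which the four treated slots
#' share mean `theta` and the two control slots share mean `gamma`
#' (residual df 4), so `theta` is the treatment effect purged of the
#' label bias (which cancels across the swap) and `gamma` captures
#' residual technical structure. Residual variances are shrunk toward an
#' empirical-Bayes prior fitted across proteins by moment matching on
#' `log s^2`, giving posterior variances with `d0 + 4` df. The null
#' hypothesis `|theta - gamma| <= log2(tau)` is tested with the
#' two-one-sided construction
#' `p = P(T > (|c| - delta)/se) + P(T > (|c| + delta)/se)`;
#' `tau = 1` reduces to the ordinary moderated t-test of the contrast.
#'
#' @param ds An `ExposureDataset`; complete six-ratio proteins are used.
#' @param tau Fold-change threshold under the null (default 1.2).
#' @return A `MethodResult` data.frame with extra columns `theta`,
#'   `gamma`, `s2`, `df_total`.
#' @export
moderated_treat <- function(ds, tau = 1.2) {
  stopifnot(tau >= 1)
  complete <- ratio_complete(ds)
  tm <- ratio_matrix(ds, TREATED_COLS)
  cm <- ratio_matrix(ds, CONTROL_COLS)
  theta <- rowMeans(tm)
  gam <- rowMeans(cm)
  rss <- rowSums((tm - theta)^2) + rowSums((cm - gam)^2)
  d <- 4
  s2 <- rss / d
  s2[!complete] <- NA_real_
  theta[!complete] <- NA_real_
  gam[!complete] <- NA_real_
  if (sum(complete) < 10L) stop("moderated_treat needs >= 10 complete proteins")
  prior <- fit_variance_prior(s2[complete], d)
  if (is.finite(prior$d0)) {
    s2_post <- (prior$d0 * prior$s0_2 + d * s2) / (prior$d0 + d)
    df_total <- prior$d0 + d
  } else {
    s2_post <- rep(prior$s0_2, length(s2))
    s2_post[!complete] <- NA_real_
    df_total <- Inf
  }
  # Var(theta_hat - gamma_hat) = s2 * (1/4 + 1/2)
  se <- sqrt(s2_post * 0.75)
  cc <- theta - gam
  delta <- log2(tau)
  t_right <- (abs(cc) - delta) / se
  t_left <- (abs(cc) + delta) / se
  p <- stats::pt(t_right, df_total, lower.tail = FALSE) +
    stats::pt(t_left, df_total, lower.tail = FALSE)
  x <- rowMeans(tm)
  mr <- method_result("ModeratedTREAT", ds$records$group_id, 2^cc,
                      ifelse(cc >= 0, "up", "down"),
                      cc / se, p)
  mr$theta <- theta
  mr$gamma <- gam
  mr$s2 <- s2
  mr$df_total <- rep(df_total, nrow(mr))
  mr
}

tier_pass <- function(res, fc_tier, p_tier, use_adjusted, require_fc) {
  method <- attr(res, "method")
  mag <- pmax(res$fc_estimate, 1 / res$fc_estimate)
  if (method == "FC") {
    pass <- !is.na(mag) & mag > fc_tier
  } else {
    p <- if (use_adjusted) res$p_adj else res$p_raw
    pass <- !is.na(p) & p < p_tier
    if (require_fc) pass <- pass & !is.na(mag) & mag > fc_tier
  }
  pass
}

#' Union ensemble over detector results
#'
#' A protein is a member of the ensemble iff any detector calls it at the
#' configured stringency tier: the non-statistical FC detector requires
#' the fold-change tier, statistical detectors require the p-value tier
#' (optionally also the fold-change tier when `require_fc = TRUE`).
#' Direction is taken from the fold-change estimate; proteins whose
#' supporting detectors disagree on direction are flagged conflicted.
#'
#' @param results List of `MethodResult` objects over the same proteins.
#' @param fc_tier Fold-change tier (linear; default 1.2).
#' @param p_tier P-value tier (default 0.05).
#' @param use_adjusted Apply the p tier to BH-adjusted values
#'   (default FALSE: raw p).
#' @param require_fc Statistical detectors must also pass the FC tier.
#' @return data.frame of class `EnsembleResult`: one row per protein with
#'   `member`, `direction`, `conflicted`, `n_methods`, `methods`
#'   (comma-separated provenance).
#' @export
ensemble_union <- function(results, fc_tier = 1.2, p_tier = 0.05,
                           use_adjusted = FALSE, require_fc = FALSE) {
  stopifnot(length(results) >= 1L)
  ids <- sort(unique(unlist(lapply(results, function(r) r$group_id))))
  sup <- matrix(FALSE, length(ids), length(results),
                dimnames = list(ids, vapply(results, attr, "", "method")))
  dirs <- matrix(NA_character_, length(ids), length(results))
  for (j in seq_along(results)) {
    r <- results[[j]]
    pass <- tier_pass(r, fc_tier, p_tier, use_adjusted, require_fc)
    sup[match(r$group_id[pass], ids), j] <- TRUE
    dirs[match(r$group_id, ids), j] <- r$direction
  }
  member <- rowSums(sup) > 0L
  direction <- conflicted <- rep(NA, length(ids))
  direction <- rep(NA_character_, length(ids))
  conflicted <- rep(FALSE, length(ids))
  for (i in which(member)) {
    dd <- unique(stats::na.omit(dirs[i, sup[i, ]]))
    direction[i] <- if (length(dd) == 1L) dd else "conflicted"
    conflicted[i] <- length(dd) > 1L
  }
  methods_str <- apply(sup, 1, function(s)
    paste(colnames(sup)[s], collapse = ","))
  structure(data.frame(group_id = ids,
                       member = member,
                       direction = direction,
                       conflicted = conflicted,
                       n_methods = rowSums(sup),
                       methods = methods_str,
                       stringsAsFactors = FALSE,
                       row.names = NULL),
            fc_tier = fc_tier, p_tier = p_tier,
            use_adjusted = use_adjusted,
            class = c("EnsembleResult", "data.frame"))
}

#' Run the detector battery on a dataset
#'
#' Applies the standard analysis policy of the double-swap design: the
#' outlier and rank detectors (FC, sigB, Z, M, RankProd, FCROS) run on
#' the composite-filtered proteins, while the moderated threshold test
#' encodes the design in its contrast and therefore runs on all complete
#' six-ratio proteins. `filter_mode = "none"` runs every detector on the
#' unfiltered dataset instead.
#'
#' @param ds A quality-filtered, normalized `ExposureDataset`.
#' @param methods Character subset of
#'   `c("FC", "sigB", "Z", "M", "RankProd", "FCROS", "ModeratedTREAT")`.
#' @param filter_mode `"composite"` (default) or `"none"`.
#' @param tau Threshold for the moderated test.
#' @param n_perm,seed Rank-product permutation settings.
#' @return Named list of `MethodResult` objects.
#' @export
run_detectors <- function(ds,
                          methods = c("FC", "sigB", "Z", "M", "RankProd",
                                      "FCROS", "ModeratedTREAT"),
                          filter_mode = c("composite", "none"),
                          tau = 1.2, n_perm = 2000L, seed = 1L) {
  filter_mode <- match.arg(filter_mode)
  sub <- if (filter_mode == "composite") composite_filter(ds)$passed else ds
  out <- list()
  n_sub <- nrow(sub$records)
  for (m in methods) {
    res <- switch(m,
      FC = if (n_sub >= 1) fc_method_result(sub),
      sigB = if (n_sub >= 3) significance_b(sub, min_bin = min(300L, max(3L, n_sub))),
      Z = if (n_sub >= 3) z_score_test(sub),
      M = if (n_sub >= 3) m_score_test(sub),
      RankProd = if (n_sub >= 2) rank_product(sub, n_perm = n_perm, seed = seed),
      FCROS = if (n_sub >= 20) fcros_test(sub),
      ModeratedTREAT = moderated_treat(ds, tau = tau),
      stop("unknown method: ", m))
    if (!is.null(res)) out[[m]] <- res
  }
  out
}
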