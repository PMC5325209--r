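# Swap diagnostics: does the scatter of reciprocal ratios point along the
# treatment axis or along the labeling axis?
#
# Both axes hold oriented (exposed/sham) log2 ratios for one labeling pair,
# one replicate per axis.  A treatment effect has the same sign in both
# replicates (positive correlation); a label-incorporation bias flips sign
# with the swap (negative correlation).

swap_pair_cols <- function(swap_pair = c("H-L", "H-M")) {
  swap_pair <- match.arg(swap_pair)
  if (swap_pair == "H-L") c("treated_r1_HL", "treated_r2_LH")
  else c("treated_r1_HM", "treated_r2_MH")
}

#' Reciprocal-ratio correlation for one labeling pair
#'
#' Pearson correlation between the replicate-1 and replicate-2 oriented
#' treated log2 ratios of a labeling pair, over proteins with both slots
#' present (pairwise-complete deletion). The 95% confidence interval uses
#' the Fisher z transform with scale `1/sqrt(n - 3)`; the two-tailed
#' p-value uses the t approximation with `n - 2` df.
#'
#' @param ds An `ExposureDataset`.
#' @param swap_pair `"H-L"` or `"H-M"`.
#' @return A list of class `CorrelationSummary`: `swap_pair`, `n`, `r`,
#'   `ci95`, `p_value`.
#' @export
reciprocal_correlation <- function(ds, swap_pair = c("H-L", "H-M")) {
  swap_pair <- match.arg(swap_pair)
  cols <- swap_pair_cols(swap_pair)
  x <- ds$records[[cols[1]]]
  y <- ds$records[[cols[2]]]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) stop("need >= 3 proteins with both swap slots present")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance on one axis: correlation undefined")
  r <- stats::cor(x, y)
  z <- atanh(r)
  half <- stats::qnorm(0.975) / sqrt(n - 3)
  ci <- tanh(c(z - half, z + half))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(swap_pair = swap_pair, n = n, r = r, ci95 = ci,
                 p_value = p),
            class = "CorrelationSummary")
}

#' @export
print.CorrelationSummary <- function(x, ...) {
  cat(sprintf("Reciprocal correlation (%s pair): r = %.3f [%.3f, %.3f], n = %d, p = %.3g\n",
              x$swap_pair, x$r, x$ci95[1], x$ci95[2], x$n, x$p_value))
  invisible(x)
}

#' Classify proteins by reciprocal-ratio quadrant
#'
#' With oriented exposed/sham ratios on both axes, consistently
#' up-regulated proteins have both ratios positive and consistently
#' down-regulated proteins both negative; mixed signs (or an exact zero)
#' indicate label- or noise-driven inconsistency. The mapping of the
#' semantic classes onto display quadrant numerals is a presentation
#' concern and configurable via `numerals`.
#'
#' @param ds An `ExposureDataset`.
#' @param swap_pair `"H-L"` or `"H-M"`.
#' @param numerals Named character mapping the four classes to display
#'   numerals.
#' @return data.frame with `group_id`, the two ratios, `class`,
#'   `quadrant`; proteins missing either slot are omitted.
#' @export
classify_quadrants <- function(ds, swap_pair = c("H-L", "H-M"),
                               numerals = c("consistent-up" = "II",
                                            "consistent-down" = "IV",
                                            "inconsistent-a" = "I",
                                            "inconsistent-b" = "III")) {
  swap_pair <- match.arg(swap_pair)
  cols <- swap_pair_cols(swap_pair)
  x <- ds$records[[cols[1]]]
  y <- ds$records[[cols[2]]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  cls <- ifelse(x > 0 & y > 0, "consistent-up",
         ifelse(x < 0 & y < 0, "consistent-down",
         ifelse(x >= 0 & y <= 0, "inconsistent-a", "inconsistent-b")))
  data.frame(group_id = ds$records$group_id[ok],
             x = x, y = y, class = cls,
             quadrant = unname(numerals[cls]),
             stringsAsFactors = FALSE)
}

#' Paired comparison of swap-pair correlation strength
#'
#' Tests whether the H-L labeling pair shows systematically stronger
#' reciprocal association than the H-M pair across experiments: a paired
#' two-tailed t-test on `|r_HL| - |r_HM|`, one pair per experiment.
#'
#' @param pairs A list in which each element holds the two
#'   `CorrelationSummary` objects of one experiment (order H-L, H-M), or a
#'   two-column numeric matrix/data.frame of `(|r_HL|, |r_HM|)` values.
#' @return A list: `mean_diff`, `ci95`, `t`, `df`, `p_value`, `n`.
#' @export
compare_swap_bias <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs) &&
      inherits(pairs[[1]][[1]], "CorrelationSummary")) {
    m <- t(vapply(pairs, function(pp) c(abs(pp[[1]]$r), abs(pp[[2]]$r)),
                  numeric(2)))
  } else {
    m <- as.matrix(pairs)
  }
  if (nrow(m) < 2L) stop("need >= 2 experiments for a paired comparison")
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  list(mean_diff = unname(tt$estimate),
       ci95 = as.numeric(tt$conf.int),
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       n = nrow(m))
}
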