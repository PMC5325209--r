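# Design-aware Boolean filters and MAD-based signal-to-noise estimation.
#
# The double-swap design gives each protein four treated and two control
# ratios.  A real regulation signal shows up as four same-sign treated
# ratios that dominate the control ratios; the composite filter encodes
# exactly that, and the pooled MAD of treated vs control ratios measures
# how much detectable signal a (filtered) dataset carries.

#' Median absolute deviation
#'
#' `median(|x - median(x)|)`, optionally scaled by 1.4826 for consistency
#' with the standard deviation under normality.
#'
#' @param values Numeric vector with at least one finite value; NAs are
#'   dropped.
#' @param scaled Apply the 1.4826 normal-consistency factor (default).
#' @return Non-negative scalar.
#' @export
ratio_mad <- function(values, scaled = TRUE) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("ratio_mad: no finite values")
  m <- stats::median(abs(values - stats::median(values)))
  if (scaled) m * 1.4826 else m
}

filter_report <- function(filter_name, n_in, n_out, treated, control,
                          scaled = TRUE) {
  mad_t <- if (length(treated[is.finite(treated)])) ratio_mad(treated, scaled) else NA_real_
  mad_c <- if (length(control[is.finite(control)])) ratio_mad(control, scaled) else NA_real_
  snr <- if (!is.na(mad_c) && mad_c > 0) mad_t / mad_c else NA_real_
  structure(list(filter_name = filter_name, n_in = n_in, n_out = n_out,
                 mad_treated = mad_t, mad_control = mad_c, snr = snr),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport '%s': %d -> %d; MAD treated %.4f, control %.4f, S/N %.3f\n",
              x$filter_name, x$n_in, x$n_out, x$mad_treated,
              x$mad_control, x$snr))
  invisible(x)
}

all_same_strict_sign <- function(m) {
  # strict: an exact zero in any slot fails both directions
  rowSums(m > 0) == ncol(m) | rowSums(m < 0) == ncol(m)
}

#' Consistency filter on the four treated ratios
#'
#' Splits proteins with all four treated slots present into those whose
#' oriented treated log2 ratios share one strict sign (consistent) and the
#' rest (inconsistent). Proteins missing any treated slot are excluded
#' from both subsets.
#'
#' @param ds An `ExposureDataset`.
#' @return A list: `consistent` and `inconsistent` (`ExposureDataset`s),
#'   `report` (list of two [FilterReport]s), `n_excluded_incomplete`.
#' @export
consistency_filter <- function(ds) {
  tm <- ratio_matrix(ds, TREATED_COLS)
  has_all <- rowSums(is.na(tm)) == 0L
  cons <- has_all & all_same_strict_sign(tm)
  incons <- has_all & !cons
  cm <- ratio_matrix(ds, CONTROL_COLS)
  list(
    consistent = subset_dataset(ds, cons),
    inconsistent = subset_dataset(ds, incons),
    report = list(
      consistent = filter_report("consistent", nrow(tm), sum(cons),
                                 tm[cons, ], cm[cons, ]),
      inconsistent = filter_report("inconsistent", nrow(tm), sum(incons),
                                   tm[incons, ], cm[incons, ])),
    n_excluded_incomplete = sum(!has_all))
}

#' Composite Boolean filter of the double-swap design
#'
#' Passes a protein iff (i) it has a complete six-ratio record, (ii) its
#' four oriented treated log2 ratios share one strict sign, and (iii) its
#' treated magnitudes dominate its control magnitudes. Dominance is
#' `min |treated| > max |control|` under the default `"strict"` rule, or
#' `mean |treated| > mean |control|` under `"mean"`.
#'
#' @param ds An `ExposureDataset`.
#' @param rule `"strict"` (default) or `"mean"`.
#' @return A list: `passed` (`ExposureDataset`), `report`
#'   ([FilterReport]), `n_excluded_incomplete`.
#' @export
composite_filter <- function(ds, rule = c("strict", "mean")) {
  rule <- match.arg(rule)
  complete <- ratio_complete(ds)
  tm <- ratio_matrix(ds, TREATED_COLS)
  cm <- ratio_matrix(ds, CONTROL_COLS)
  cons <- complete & all_same_strict_sign(tm)
  dom <- if (rule == "strict") {
    apply(abs(tm), 1, min) > apply(abs(cm), 1, max)
  } else {
    rowMeans(abs(tm)) > rowMeans(abs(cm))
  }
  pass <- cons & !is.na(dom) & dom
  list(passed = subset_dataset(ds, pass),
       report = filter_report("composite", sum(complete), sum(pass),
                              tm[pass, ], cm[pass, ]),
       n_excluded_incomplete = sum(!complete))
}

#' Pooled MAD signal-to-noise report
#'
#' Pools all treated slots of a (sub)dataset into one vector and all
#' control slots into another, computes the MAD of each, and reports
#' their ratio. The scaling constant cancels in the ratio.
#'
#' @param ds An `ExposureDataset` (typically a filter output).
#' @param filter_name Label recorded in the report.
#' @param scaled Use the 1.4826-scaled MAD (default; does not affect the
#'   S/N ratio).
#' @return A [FilterReport] with `n_in = n_out = nrow(ds$records)`.
#' @export
signal_to_noise <- function(ds, filter_name = "unfiltered", scaled = TRUE) {
  if (sum(ratio_complete(ds)) < 3L)
    stop("signal_to_noise: need >= 3 complete six-ratio proteins")
  tm <- ratio_matrix(ds, TREATED_COLS)
  cm <- ratio_matrix(ds, CONTROL_COLS)
  rep <- filter_report(filter_name, nrow(tm), nrow(tm), as.vector(tm),
                       as.vector(cm), scaled = scaled)
  if (!is.na(rep$mad_control) && rep$mad_control == 0)
    warning("control MAD is zero: S/N undefined")
  rep
}

#' Compare signal-to-noise across the standard filter cascade
#'
#' Convenience wrapper computing the pooled-MAD S/N of the unfiltered,
#' consistent-only and composite-filtered views of a dataset.
#'
#' @param ds A quality-filtered, normalized `ExposureDataset`.
#' @return data.frame with columns `filter_name`, `n`, `mad_treated`,
#'   `mad_control`, `snr`.
#' @export
snr_cascade <- function(ds) {
  cons <- consistency_filter(ds)
  comp <- composite_filter(ds)
  snr_or_na <- function(sub, name) {
    tryCatch(signal_to_noise(sub, name), error = function(e) {
      warning(sprintf("S/N for '%s' undefined: %s", name,
                      conditionMessage(e)))
      filter_report(name, nrow(sub$records), nrow(sub$records),
                    numeric(0), numeric(0))
    })
  }
  reps <- list(snr_or_na(ds, "unfiltered"),
               snr_or_na(cons$consistent, "consistent"),
               snr_or_na(comp$passed, "composite"))
  do.call(rbind, lapply(reps, function(r)
    data.frame(filter_name = r$filter_name, n = r$n_out,
               mad_treated = r$mad_treated, mad_control = r$mad_control,
               snr = r$snr)))
}
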