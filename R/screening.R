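#' Volume-normalised specific fluorescence
#'
#' Single-cell fluorescence scales with cell size, so screening readouts
#' are normalised by a cell-volume surrogate before any comparison:
#' `fluorescence / volume_proxy^exponent`. The default exponent 1 is plain
#' per-volume normalisation; the exponent is configurable because volume
#' surrogates (forward scatter, OD-derived) relate to true volume with
#' instrument-specific power laws.
#'
#' @param fluorescence,volume_proxy Positive numeric vectors (recycled).
#' @param exponent Volume exponent (default 1).
#' @return Numeric vector of specific fluorescences.
#' @examples
#' specific_fluorescence(1000, 2)  # 500
#' @export
specific_fluorescence <- function(fluorescence, volume_proxy, exponent = 1) {
  if (any(is.na(volume_proxy)) || any(volume_proxy <= 0)) {
    stop("specific_fluorescence: volume_proxy must be > 0", call. = FALSE)
  }
  if (any(is.na(fluorescence)) || any(fluorescence <= 0)) {
    stop("specific_fluorescence: fluorescence must be > 0", call. = FALSE)
  }
  fluorescence / volume_proxy^exponent
}

#' Modified Z-scores and robust outlier filtering
#'
#' The modified Z-score of Iglewicz & Hoaglin:
#' `Z_i = 0.6745 (x_i - median) / MAD` with `MAD = median(|x_i - median|)`.
#' When the MAD is 0 (at least half the values tied at the median) the
#' fallback `Z_i = 0.7979 (x_i - median) / meanAD` is used, with meanAD the
#' mean absolute deviation from the median; if that is also 0 the vector is
#' constant and nothing is an outlier. Values with `|Z_i| >` `threshold`
#' (conventionally 3.5) are removed. The scores are invariant under affine
#' transformations of the data, and the filter is idempotent: re-filtering
#' the kept values removes nothing further.
#'
#' @param values Numeric vector (at least 3 values for the filter).
#' @param threshold Absolute modified-Z cutoff (default 3.5).
#' @return `modified_zscore()`: the vector of scores.
#'   `modified_zscore_filter()`: list with `kept` (values retained),
#'   `removed` (data frame `index`, `value`, `score` of the outliers) and
#'   `scores` (all scores).
#' @examples
#' modified_zscore_filter(c(10, 10.2, 9.8, 10.1, 50))$removed
#' @export
modified_zscore <- function(values) {
  if (anyNA(values)) stop("modified_zscore: NA values", call. = FALSE)
  med <- stats::median(values)
  dev <- values - med
  mad_ <- stats::median(abs(dev))
  if (mad_ > 0) {
    0.6745 * dev / mad_
  } else {
    meanad <- mean(abs(dev))
    if (meanad > 0) 0.7979 * dev / meanad else rep(0, length(values))
  }
}

#' @rdname modified_zscore
#' @export
modified_zscore_filter <- function(values, threshold = 3.5) {
  if (length(values) < 3L) {
    stop("modified_zscore_filter: need at least 3 values", call. = FALSE)
  }
  z <- modified_zscore(values)
  out <- abs(z) > threshold
  list(
    kept = values[!out],
    removed = data.frame(index = which(out), value = values[out],
                         score = z[out]),
    scores = z
  )
}

.sig_label <- function(p) {
  if (is.na(p)) "" else if (p <= 0.005) "***" else if (p <= 0.05) "**" else ""
}

#' Significance label for screening comparisons
#'
#' The conventional star labels used in screening figures: `"**"` for
#' p <= 0.05 and `"***"` for p <= 0.005, empty otherwise.
#'
#' @param p P-value (vectorised).
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  vapply(p, .sig_label, character(1))
}

.check_records <- function(records, what, need = c("clone_id", "variant_name",
                                                   "condition", "fluorescence",
                                                   "volume_proxy")) {
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop(sprintf("%s: records missing column(s) %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  records
}

#' Relative fluorescence of a variant versus its in-plate control
#'
#' Implements the screening analysis used for promoter-variant plates:
#' per-clone specific fluorescence ([specific_fluorescence()]), modified
#' Z-score outlier removal applied to each group separately
#' ([modified_zscore_filter()]), per-clone relative fluorescence as percent
#' of the filtered control mean (control average = 100%), a two-sided
#' Student's t-test (pooled variance by default; Welch optionally) of
#' variant versus control, and the conventional significance label.
#'
#' @param variant_records,control_records Data frames of screening records
#'   with columns `clone_id`, `variant_name`, `condition`, `fluorescence`,
#'   `volume_proxy`. Both groups must be measured in the same single
#'   condition; the control group needs at least 3 clones (for the filter).
#' @param volume_exponent Passed to [specific_fluorescence()].
#' @param zscore_threshold Outlier cutoff (default 3.5).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return An `rf_result`: list with `variant_name`, `condition`, `rf`
#'   (per-clone relative fluorescence, %), `mean_rf`, `n_used`,
#'   `n_outliers_removed` (variant + control), `p_value`,
#'   `significance_label`, `control_mean_sf`, and `outlier_log` (per-group
#'   removal report).
#' @export
relative_fluorescence <- function(variant_records, control_records,
                                  volume_exponent = 1, zscore_threshold = 3.5,
                                  var_equal = TRUE) {
  .check_records(variant_records, "relative_fluorescence")
  .check_records(control_records, "relative_fluorescence")
  conds <- unique(c(variant_records$condition, control_records$condition))
  if (length(conds) != 1L) {
    stop(sprintf("relative_fluorescence: condition mismatch (%s)",
                 paste(conds, collapse = " vs ")), call. = FALSE)
  }
  if (nrow(control_records) < 3L) {
    stop("relative_fluorescence: need at least 3 control clones", call. = FALSE)
  }
  v_sf <- specific_fluorescence(variant_records$fluorescence,
                                variant_records$volume_proxy, volume_exponent)
  c_sf <- specific_fluorescence(control_records$fluorescence,
                                control_records$volume_proxy, volume_exponent)
  vf <- if (length(v_sf) >= 3L) modified_zscore_filter(v_sf, zscore_threshold)
        else list(kept = v_sf, removed = data.frame(index = integer(),
                                                    value = numeric(),
                                                    score = numeric()))
  cf <- modified_zscore_filter(c_sf, zscore_threshold)
  if (length(vf$kept) == 0L || length(cf$kept) == 0L) {
    stop("relative_fluorescence: empty group after outlier filtering",
         call. = FALSE)
  }
  ctrl_mean <- mean(cf$kept)
  rf <- 100 * vf$kept / ctrl_mean
  p <- if (length(vf$kept) >= 2L && length(cf$kept) >= 2L &&
           (stats::sd(vf$kept) > 0 || stats::sd(cf$kept) > 0)) {
    stats::t.test(vf$kept, cf$kept, var.equal = var_equal)$p.value
  } else if (isTRUE(all.equal(mean(vf$kept), ctrl_mean))) 1 else NA_real_
  structure(list(
    variant_name = unique(variant_records$variant_name)[1],
    condition = conds,
    rf = rf,
    mean_rf = mean(rf),
    n_used = length(vf$kept),
    n_outliers_removed = nrow(vf$removed) + nrow(cf$removed),
    p_value = p,
    significance_label = .sig_label(p),
    control_mean_sf = ctrl_mean,
    outlier_log = list(variant = vf$removed, control = cf$removed)
  ), class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("<rf_result> %s [%s]: mean RF %.1f%% (n = %d, %d outlier(s) removed), p = %.3g %s\n",
              x$variant_name, x$condition, x$mean_rf, x$n_used,
              x$n_outliers_removed, x$p_value, x$significance_label))
  invisible(x)
}

#' Secreted-protein yield fold-change versus control
#'
#' Product yield is titer related to wet cell weight (`titer / wcw`,
#' mg product per g WCW); each clone's fold-change is its yield divided by
#' the mean of the outlier-filtered control yields. A two-sided Student's
#' t-test of the filtered yields is reported alongside.
#'
#' @param variant_records,control_records Data frames with columns
#'   `titer` and `wcw` (plus the usual record columns).
#' @param zscore_threshold Outlier cutoff applied per group on the yields.
#' @param var_equal Pooled-variance t-test if `TRUE`.
#' @return A list with `fc` (per-clone fold-changes), `mean_fc`, `n_used`,
#'   `n_outliers_removed`, `p_value`, `significance_label`,
#'   `control_mean_yield`.
#' @export
yield_fold_change <- function(variant_records, control_records,
                              zscore_threshold = 3.5, var_equal = TRUE) {
  need <- c("titer", "wcw")
  .check_records(variant_records, "yield_fold_change", need)
  .check_records(control_records, "yield_fold_change", need)
  if (anyNA(variant_records$titer) || anyNA(variant_records$wcw) ||
      anyNA(control_records$titer) || anyNA(control_records$wcw)) {
    stop("yield_fold_change: missing titer or wcw", call. = FALSE)
  }
  v_y <- variant_records$titer / variant_records$wcw
  c_y <- control_records$titer / control_records$wcw
  vf <- if (length(v_y) >= 3L) modified_zscore_filter(v_y, zscore_threshold)
        else list(kept = v_y, removed = data.frame())
  cf <- if (length(c_y) >= 3L) modified_zscore_filter(c_y, zscore_threshold)
        else list(kept = c_y, removed = data.frame())
  ctrl_mean <- mean(cf$kept)
  fc <- vf$kept / ctrl_mean
  p <- if (length(vf$kept) >= 2L && length(cf$kept) >= 2L &&
           (stats::sd(vf$kept) > 0 || stats::sd(cf$kept) > 0)) {
    stats::t.test(vf$kept, cf$kept, var.equal = var_equal)$p.value
  } else NA_real_
  list(fc = fc, mean_fc = mean(fc), n_used = length(vf$kept),
       n_outliers_removed = nrow(vf$removed) + nrow(cf$removed),
       p_value = p, significance_label = .sig_label(p),
       control_mean_yield = ctrl_mean)
}

#' Per-variant screening report for a whole plate
#'
#' Convenience wrapper: splits a screening table by variant, runs
#' [relative_fluorescence()] for every non-control variant against the
#' control group in the same condition, and tabulates the results.
#'
#' @param records Screening table (data frame) for one condition, with an
#'   `is_control` logical column or a `control_name` to identify controls.
#' @param control_name Variant name of the control group (used when
#'   `is_control` is absent).
#' @param condition Condition to analyse (default: the single condition
#'   present).
#' @param ... Passed to [relative_fluorescence()].
#' @return Data frame with one row per variant: `variant_name`, `condition`,
#'   `mean_rf`, `n_used`, `n_outliers_removed`, `p_value`, `significance`.
#' @export
screen_table <- function(records, control_name = NULL, condition = NULL, ...) {
  .check_records(records, "screen_table")
  if (!is.null(condition)) {
    records <- records[records$condition == condition, , drop = FALSE]
  }
  if (is.null(records$is_control)) {
    if (is.null(control_name)) {
      stop("screen_table: give control_name or an is_control column",
           call. = FALSE)
    }
    records$is_control <- records$variant_name == control_name
  }
  ctrl <- records[records$is_control, , drop = FALSE]
  if (nrow(ctrl) < 3L) stop("screen_table: need >= 3 control clones", call. = FALSE)
  vars <- setdiff(unique(records$variant_name[!records$is_control]), NULL)
  rows <- lapply(vars, function(v) {
    r <- relative_fluorescence(records[records$variant_name == v &
                                         !records$is_control, , drop = FALSE],
                               ctrl, ...)
    data.frame(variant_name = v, condition = r$condition, mean_rf = r$mean_rf,
               n_used = r$n_used, n_outliers_removed = r$n_outliers_removed,
               p_value = r$p_value, significance = r$significance_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
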