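#' Scan a promoter for TFBS matches on both strands
#'
#' Every window of every matrix width is scored on the forward and reverse
#' strand; windows with matrix similarity strictly above `threshold` (the
#' conventional 0.75 cutoff for "potentially true" matches) and core
#' similarity of at least `core_threshold` are emitted as hits. Hits may
#' overlap — no masking is applied, because biologically relevant sites of
#' different families frequently co-locate. Reverse-strand hits are reported
#' in forward-strand upstream coordinates (`start` is the 5'-most, most
#' negative, position of the matched window).
#'
#' @param seq A [promoter_sequence()].
#' @param pwms A `pwm` or (optionally named) list of `pwm` objects.
#' @param threshold Matrix-similarity cutoff in \[0, 1\]; hits require a
#'   score strictly greater than this. Default 0.75.
#' @param core_threshold Core-similarity cutoff (hits require `>=`);
#'   `NULL` disables core filtering. Default 0.75.
#' @return A data frame with one row per hit: `matrix_id`, `family_code`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (inclusive upstream positions),
#'   `matrix_similarity`, `core_similarity`; sorted by `start` then
#'   `matrix_id`.
#' @examples
#' set.seed(1)
#' pwms <- make_pwm_set(seed = 1)
#' prom <- make_fixture_promoter(seed = 2, length = 200, constraints = NULL,
#'                               plantings = list(list(pwm = pwms[[1]], position = -100)))
#' scan_sequence(prom, pwms)
#' @export
scan_sequence <- function(seq, pwms, threshold = 0.75, core_threshold = 0.75) {
  stopifnot(is_promoter_sequence(seq))
  if (is_pwm(pwms)) pwms <- list(pwms)
  if (length(pwms) == 0L) stop("scan_sequence: empty PWM set", call. = FALSE)
  if (!all(vapply(pwms, is_pwm, logical(1)))) {
    stop("scan_sequence: pwms must be pwm objects", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("scan_sequence: threshold must be in [0, 1]", call. = FALSE)
  }
  L <- length(seq)
  if (all(vapply(pwms, function(p) p$width, integer(1)) > L)) {
    stop("scan_sequence: sequence shorter than every matrix", call. = FALSE)
  }
  codes <- .base_codes(seq$bases)
  hits <- .scan_codes(codes, pwms, threshold, core_threshold, 1L, L)
  .finish_hits(hits, L)
}

# Core scanner over integer codes; only windows overlapping the index range
# [idx_from, idx_to] are scored. Returns a data.frame keyed by the forward
# 1-based window start index (`start_idx`).
.scan_codes <- function(codes, pwms, threshold, core_threshold,
                        idx_from, idx_to) {
  L <- length(codes)
  res <- vector("list", 2L * length(pwms))
  k <- 0L
  for (p in pwms) {
    w <- p$width
    if (w > L) next
    nwin <- L - w + 1L
    from <- max(1L, idx_from - w + 1L)
    to <- min(nwin, idx_to)
    if (from > to) next
    tb <- .pwm_tables(p)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") {
        .score_windows(codes, tb$wf, tb$denom, tb$core, tb$core_denom, from, to)
      } else {
        .score_windows(codes, tb$wf_rc, tb$denom, tb$core_rc, tb$core_denom, from, to)
      }
      keep <- sc$mss > threshold
      if (!is.null(core_threshold)) keep <- keep & sc$css >= core_threshold
      if (any(keep)) {
        k <- k + 1L
        res[[k]] <- data.frame(
          matrix_id = p$matrix_id,
          family_code = p$family_code,
          strand = strand,
          start_idx = sc$start[keep],
          width = w,
          matrix_similarity = sc$mss[keep],
          core_similarity = sc$css[keep],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) {
    return(data.frame(matrix_id = character(), family_code = character(),
                      strand = character(), start_idx = integer(),
                      width = integer(), matrix_similarity = numeric(),
                      core_similarity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res[seq_len(k)])
}

# Convert index-keyed hits to upstream coordinates and canonical order.
.finish_hits <- function(hits, L) {
  out <- data.frame(
    matrix_id = hits$matrix_id,
    family_code = hits$family_code,
    strand = hits$strand,
    start = hits$start_idx - L - 1L,
    end = hits$start_idx + hits$width - 1L - L - 1L,
    matrix_similarity = hits$matrix_similarity,
    core_similarity = hits$core_similarity,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$matrix_id, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write TFBS hits as TSV or BED6
#'
#' `write_hits_tsv()` writes the hit table as tab-separated text.
#' `write_hits_bed()` writes BED6 (0-based, half-open) against the named
#' sequence, with the matrix similarity scaled to 0-1000 in the score
#' column.
#'
#' @param hits A hit data frame from [scan_sequence()].
#' @param path Output path.
#' @param seq The scanned [promoter_sequence()] (needed to convert upstream
#'   coordinates to BED intervals).
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(hits, seq, path) {
  stopifnot(is_promoter_sequence(seq))
  L <- length(seq)
  if (nrow(hits) > 0) {
    bed <- data.frame(
      chrom = seq$label,
      chromStart = upstream_to_index(hits$start, L) - 1L,
      chromEnd = upstream_to_index(hits$end, L),
      name = hits$matrix_id,
      score = as.integer(round(1000 * hits$matrix_similarity)),
      strand = hits$strand,
      stringsAsFactors = FALSE
    )
  } else {
    bed <- data.frame(chrom = character(), chromStart = integer(),
                      chromEnd = integer(), name = character(),
                      score = integer(), strand = character())
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
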