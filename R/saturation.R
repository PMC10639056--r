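#' Enumerate all single-nucleotide substitution variants of a promoter
#'
#' In silico saturation mutagenesis: every position is exchanged for each of
#' the other three bases, yielding exactly 3L variants for an L-nt sequence
#' (2220 for the canonical 740-nt upstream window). The catalog is ordered
#' deterministically: positions from -L to -1, alternative bases in
#' A < C < G < T order with the reference base skipped.
#'
#' @param reference A [promoter_sequence()].
#' @param include_sequences Build the mutated sequences (default `TRUE`);
#'   with `FALSE` only the mutation table is returned, and sequences can be
#'   materialised later with [snv_sequence()].
#' @return An `snv_catalog`: list with `reference`, `mutations` (data frame
#'   with columns `position`, `ref`, `alt`) and `sequences` (list of
#'   `promoter_sequence`, or `NULL`).
#' @examples
#' cat1 <- enumerate_snvs(promoter_sequence("ACG"))
#' nrow(cat1$mutations)  # 9
#' @export
enumerate_snvs <- function(reference, include_sequences = TRUE) {
  stopifnot(is_promoter_sequence(reference))
  L <- length(reference)
  bases <- c("A", "C", "G", "T")
  pos <- rep(seq(-L, -1L), each = 3L)
  idx <- upstream_to_index(pos, L)
  ref <- reference$bases[idx]
  alt <- unlist(lapply(reference$bases, function(b) setdiff(bases, b)),
                use.names = FALSE)
  muts <- data.frame(position = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  seqs <- NULL
  if (include_sequences) {
    seqs <- vector("list", nrow(muts))
    for (k in seq_len(nrow(muts))) {
      b <- reference$bases
      b[idx[k]] <- alt[k]
      seqs[[k]] <- promoter_sequence(b, label = sprintf("%s_%d%s>%s",
                                                        reference$label,
                                                        pos[k], ref[k], alt[k]))
    }
  }
  structure(list(reference = reference, mutations = muts, sequences = seqs),
            class = "snv_catalog")
}

#' @rdname enumerate_snvs
#' @param catalog An `snv_catalog`.
#' @param i Row index into `catalog$mutations`.
#' @return `snv_sequence()`: the i-th variant as a `promoter_sequence`.
#' @export
snv_sequence <- function(catalog, i) {
  stopifnot(inherits(catalog, "snv_catalog"))
  if (!is.null(catalog$sequences)) return(catalog$sequences[[i]])
  m <- catalog$mutations[i, ]
  apply_mutations(catalog$reference, point_mutation(m$position, m$ref, m$alt))
}

#' @export
print.snv_catalog <- function(x, ...) {
  cat(sprintf("<snv_catalog> %d variants of %s (%d nt)\n",
              nrow(x$mutations), x$reference$label, length(x$reference)))
  invisible(x)
}

.hit_key <- function(hits) {
  if (nrow(hits) == 0L) return(character())
  paste(hits$matrix_id, hits$strand, hits$start, sep = "\r")
}

#' Differential TFBS analysis between two hit sets
#'
#' Compares two hit tables produced with the same PWM set and thresholds.
#' Hit identity is the triple (matrix_id, strand, start): a site that merely
#' shifts by 1 nt therefore counts as one loss plus one gain — a
#' conservative rule that never silently merges distinct placements.
#'
#' @param ref_hits,var_hits Hit data frames from [scan_sequence()].
#' @return A `tfbs_diff`: list with `gained` (rows of `var_hits` absent from
#'   `ref_hits`) and `lost` (rows of `ref_hits` absent from `var_hits`).
#' @export
diff_tfbs <- function(ref_hits, var_hits) {
  rk <- .hit_key(ref_hits)
  vk <- .hit_key(var_hits)
  gained <- var_hits[!vk %in% rk, , drop = FALSE]
  lost <- ref_hits[!rk %in% vk, , drop = FALSE]
  rownames(gained) <- NULL
  rownames(lost) <- NULL
  structure(list(gained = gained, lost = lost), class = "tfbs_diff")
}

#' @export
print.tfbs_diff <- function(x, ...) {
  cat(sprintf("<tfbs_diff> %d gained, %d lost\n", nrow(x$gained), nrow(x$lost)))
  invisible(x)
}

.collapse_families <- function(codes) {
  paste(sort(unique(codes)), collapse = ",")
}

#' Per-position TFBS gain/loss map under saturation mutagenesis
#'
#' Scans the reference once, then every single-nucleotide variant, and
#' records which TFBS families each substitution gains or loses relative to
#' the reference. A substitution can only change hits whose window covers
#' the mutated base, so each variant is rescanned only over those windows;
#' the result is identical to a naive full rescan (property-tested against
#' a brute-force oracle).
#'
#' @inheritParams scan_sequence
#' @param reference A [promoter_sequence()].
#' @return An `effect_map`: data frame with one row per (position, alt)
#'   pair — 3L rows — and columns `position`, `ref`, `alt`,
#'   `families_gained`, `families_lost` (comma-joined sorted family codes,
#'   `""` when none), `n_hits_gained`, `n_hits_lost`. The PWM family codes
#'   used are stored in the `families` attribute, the thresholds in
#'   `threshold`/`core_threshold`, and the hit-identity rule in
#'   `hit_identity`.
#' @export
position_effect_map <- function(reference, pwms, threshold = 0.75,
                                core_threshold = 0.75) {
  stopifnot(is_promoter_sequence(reference))
  if (is_pwm(pwms)) pwms <- list(pwms)
  if (length(pwms) == 0L) stop("position_effect_map: empty PWM set", call. = FALSE)
  L <- length(reference)
  codes <- .base_codes(reference$bases)
  ref_raw <- .scan_codes(codes, pwms, threshold, core_threshold, 1L, L)
  ref_keys <- paste(ref_raw$matrix_id, ref_raw$strand, ref_raw$start_idx, sep = "\r")

  cat3 <- enumerate_snvs(reference, include_sequences = FALSE)
  muts <- cat3$mutations
  n <- nrow(muts)
  fg <- character(n); fl <- character(n)
  ng <- integer(n); nl <- integer(n)
  idx_all <- upstream_to_index(muts$position, L)
  alt_code <- .base_codes(muts$alt)
  for (k in seq_len(n)) {
    j <- idx_all[k]
    vcodes <- codes
    vcodes[j] <- alt_code[k]
    var_loc <- .scan_codes(vcodes, pwms, threshold, core_threshold, j, j)
    # reference hits whose window overlaps the mutated base
    in_range <- ref_raw$start_idx <= j & ref_raw$start_idx + ref_raw$width - 1L >= j
    ref_loc_keys <- ref_keys[in_range]
    var_keys <- paste(var_loc$matrix_id, var_loc$strand, var_loc$start_idx, sep = "\r")
    g <- !var_keys %in% ref_loc_keys
    l <- !ref_loc_keys %in% var_keys
    fg[k] <- .collapse_families(var_loc$family_code[g])
    fl[k] <- .collapse_families(ref_raw$family_code[in_range][l])
    ng[k] <- sum(g)
    nl[k] <- sum(l)
  }
  out <- data.frame(position = muts$position, ref = muts$ref, alt = muts$alt,
                    families_gained = fg, families_lost = fl,
                    n_hits_gained = ng, n_hits_lost = nl,
                    stringsAsFactors = FALSE)
  attr(out, "families") <- sort(unique(vapply(pwms, function(p) p$family_code,
                                              character(1))))
  attr(out, "threshold") <- threshold
  attr(out, "core_threshold") <- core_threshold
  attr(out, "hit_identity") <- "matrix_id+strand+start"
  class(out) <- c("effect_map", "data.frame")
  out
}

#' Select mutations whose only motif effect is one target family
#'
#' Returns the substitutions from a [position_effect_map()] whose effect is
#' exactly the requested family in the requested direction and nothing in
#' the other direction — the "clean" mutations that alter a single TFBS
#' family without collateral gains or losses, the pattern that made the
#' single-CSRE-gain variant the informative one among the engineered point
#' mutations.
#'
#' @param map An `effect_map` from [position_effect_map()].
#' @param target_family Family code, e.g. `"F$CSRE"`.
#' @param mode `"gain"` (the family is gained, nothing lost) or `"loss"`.
#' @return The matching rows of `map` (possibly zero rows).
#' @export
select_clean_mutations <- function(map, target_family, mode = c("gain", "loss")) {
  mode <- match.arg(mode)
  fams <- attr(map, "families")
  if (!is.null(fams) && !target_family %in% fams) {
    stop(sprintf("select_clean_mutations: unknown family code '%s' (known: %s)",
                 target_family, paste(fams, collapse = ", ")), call. = FALSE)
  }
  keep <- if (mode == "gain") {
    map$families_gained == target_family & map$families_lost == ""
  } else {
    map$families_lost == target_family & map$families_gained == ""
  }
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname position_effect_map
#' @param map An `effect_map`.
#' @param path Output path for the tab-separated map.
#' @export
write_effect_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
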