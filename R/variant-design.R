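#' Edit-plan primitives for rational promoter design
#'
#' An edit plan is an ordered list of edits applied left to right by
#' [compose()]. Coordinates inside a plan always refer to the *current*
#' intermediate sequence at that edit's turn, never the original reference;
#' use [project_position()] to carry an original-frame coordinate forward
#' through earlier edits. This "template semantics" means a substitution
#' listed before a duplication is present in every copy of the duplicated
#' segment — exactly how a mutated plasmid used as PCR template propagates
#' its mutation into both copies.
#'
#' @param position,ref,alt As in [point_mutation()].
#' @param start,end Inclusive upstream positions bounding a segment
#'   (`start` more negative).
#' @param copies Total tandem copies after the edit; must be >= 2
#'   (`copies = 1` would be the identity and is rejected).
#' @return An edit object (class `prom_edit`), or for `edit_plan()` a list
#'   of them (class `edit_plan`).
#' @export
edit_substitute <- function(position, ref, alt) {
  m <- point_mutation(position, ref, alt)
  structure(list(type = "substitute", mutation = m), class = "prom_edit")
}

#' @rdname edit_substitute
#' @export
edit_delete <- function(start, end) {
  if (start > end) stop("edit_delete: start must be <= end", call. = FALSE)
  structure(list(type = "delete", start = as.integer(start),
                 end = as.integer(end)), class = "prom_edit")
}

#' @rdname edit_substitute
#' @export
edit_duplicate <- function(start, end, copies = 2L) {
  if (start > end) stop("edit_duplicate: start must be <= end", call. = FALSE)
  copies <- as.integer(copies)
  if (copies < 2L) {
    stop("edit_duplicate: copies must be >= 2 (copies = 1 is the identity)",
         call. = FALSE)
  }
  structure(list(type = "duplicate", start = as.integer(start),
                 end = as.integer(end), copies = copies), class = "prom_edit")
}

#' @rdname edit_substitute
#' @export
edit_duplicate_region <- function(start = -506L, end = -126L) {
  e <- edit_duplicate(start, end, copies = 2L)
  e$type <- "duplicate_region"
  e
}

#' @rdname edit_substitute
#' @param ... Edits (or lists of edits).
#' @export
edit_plan <- function(...) {
  edits <- list(...)
  flat <- list()
  for (e in edits) {
    if (inherits(e, "prom_edit")) {
      flat[[length(flat) + 1L]] <- e
    } else if (is.list(e) && all(vapply(e, inherits, logical(1), "prom_edit"))) {
      flat <- c(flat, e)
    } else {
      stop("edit_plan: arguments must be edits", call. = FALSE)
    }
  }
  structure(flat, class = "edit_plan")
}

.edit_label <- function(e) {
  switch(e$type,
    substitute = paste0("Sub", format_mutation(e$mutation)),
    delete = sprintf("Del%d..%d", e$start, e$end),
    duplicate = sprintf("Dup%d..%dx%d", e$start, e$end, e$copies),
    duplicate_region = sprintf("DRegion%d..%d", e$start, e$end)
  )
}

.apply_edit <- function(seq, e, step) {
  L <- length(seq)
  fail <- function(msg) {
    stop(sprintf("compose: step %d (%s): %s", step, .edit_label(e), msg),
         call. = FALSE)
  }
  if (e$type == "substitute") {
    m <- e$mutation
    if (m$position < -L || m$position > -1L) fail("position out of bounds")
    i <- upstream_to_index(m$position, L)
    if (seq$bases[i] != m$ref) {
      fail(sprintf("reference mismatch at %d (expected %s, found %s)",
                   m$position, m$ref, seq$bases[i]))
    }
    b <- seq$bases
    b[i] <- m$alt
    return(promoter_sequence(b, label = seq$label))
  }
  if (e$start < -L || e$end > -1L) fail("segment out of bounds")
  i <- upstream_to_index(e$start, L)
  j <- upstream_to_index(e$end, L)
  b <- seq$bases
  if (e$type == "delete") {
    return(promoter_sequence(b[-(i:j)], label = seq$label))
  }
  # duplicate / duplicate_region: segment repeated `copies` times in tandem
  seg <- b[i:j]
  extra <- rep(seg, e$copies - 1L)
  head_part <- if (i > 1L) b[1:(i - 1L)] else character()
  promoter_sequence(c(head_part, extra, b[i:length(b)]), label = seq$label)
}

#' Apply an edit plan to a reference promoter
#'
#' Edits are applied in order; any step whose precondition fails (reference
#' mismatch, out-of-bounds segment) aborts with the step index. The variant
#' name is derived deterministically from the plan unless `name` is given;
#' a region-duplication edit prepends the conventional `"D-"` prefix.
#'
#' @param reference A [promoter_sequence()] (or a `designed_variant`, whose
#'   sequence and name are taken as the starting point).
#' @param plan An [edit_plan()] (a single edit is accepted).
#' @param name Optional variant name.
#' @return A `designed_variant`: list with `name`, `seq`
#'   (`promoter_sequence`), `plan` and `reference_label`. Length
#'   bookkeeping (reference length + duplicated nt - deleted nt) is checked
#'   on every call.
#' @examples
#' p <- promoter_sequence(strrep("ACGT", 100))
#' v <- compose(p, edit_plan(edit_duplicate(-261, -232, 2)))
#' length(v$seq) - length(p)  # 30
#' @export
compose <- function(reference, plan, name = NULL) {
  base_name <- NULL
  if (inherits(reference, "designed_variant")) {
    base_name <- reference$name
    reference <- reference$seq
  }
  stopifnot(is_promoter_sequence(reference))
  if (inherits(plan, "prom_edit")) plan <- edit_plan(plan)
  stopifnot(inherits(plan, "edit_plan"))
  seq <- reference
  expected_len <- length(reference)
  for (k in seq_along(plan)) {
    e <- plan[[k]]
    seq <- .apply_edit(seq, e, k)
    if (e$type == "delete") {
      expected_len <- expected_len - (e$end - e$start + 1L)
    } else if (e$type %in% c("duplicate", "duplicate_region")) {
      expected_len <- expected_len + (e$copies - 1L) * (e$end - e$start + 1L)
    }
    if (length(seq) != expected_len) {  # internal invariant
      stop("compose: length bookkeeping violated at step ", k, call. = FALSE)
    }
  }
  if (is.null(name)) {
    if (is.null(base_name)) base_name <- reference$label
    labels <- vapply(plan, .edit_label, character(1))
    dpref <- any(vapply(plan, function(e) e$type == "duplicate_region", logical(1)))
    labels <- labels[!grepl("^DRegion", labels)]
    name <- base_name
    if (length(labels) > 0) name <- paste(c(name, labels), collapse = " ")
    if (dpref) name <- paste0("D-", name)
  }
  seq$label <- name
  structure(list(name = name, seq = seq, plan = plan,
                 reference_label = reference$label),
            class = "designed_variant")
}

#' @export
print.designed_variant <- function(x, ...) {
  cat(sprintf("<designed_variant> %s (%d nt, %d edit%s, from %s)\n",
              x$name, length(x$seq), length(x$plan),
              if (length(x$plan) == 1) "" else "s", x$reference_label))
  invisible(x)
}

#' Project original-frame coordinates through an edit plan
#'
#' Maps upstream positions given in the reference frame to the coordinate
#' they occupy after the plan has been applied. Deleted positions map to
#' `NA`. Positions inside a duplicated segment map to the downstream-most
#' (3') copy, which keeps its original coordinate because upstream
#' positions are anchored at the start codon.
#'
#' @param plan An [edit_plan()].
#' @param positions Integer vector of upstream positions (reference frame).
#' @return Integer vector of projected positions (`NA` where deleted).
#' @export
project_position <- function(plan, positions) {
  if (inherits(plan, "prom_edit")) plan <- edit_plan(plan)
  p <- as.integer(positions)
  for (e in plan) {
    if (e$type == "delete") {
      len <- e$end - e$start + 1L
      p <- ifelse(is.na(p), NA_integer_,
                  ifelse(p >= e$start & p <= e$end, NA_integer_,
                         ifelse(p < e$start, p + len, p)))
    } else if (e$type %in% c("duplicate", "duplicate_region")) {
      len <- e$end - e$start + 1L
      shift <- (e$copies - 1L) * len
      p <- ifelse(!is.na(p) & p < e$start, p - shift, p)
    }
  }
  p
}

#' Sliding-window deletion variants
#'
#' Tiles the requested region with fixed-length deletion windows that
#' overlap their neighbours by `overlap` nt, numbering them from the
#' upstream (most negative) end, and returns one deletion variant per
#' window. The step is `window - overlap`; the window count is
#' `ceiling((region_length - window) / step) + 1`. When the region length
#' is not an exact multiple of the tiling (the canonical -400..-200 region
#' is 201 nt, which 10 windows of 30 nt at uniform 10-nt overlaps cannot
#' tile exactly), the final window is anchored to the downstream end of the
#' region and its overlap with the previous window exceeds `overlap`; this
#' is recorded in the `clipped` column of the `windows` attribute.
#'
#' @param seq A [promoter_sequence()] covering the region.
#' @param region_start,region_end Upstream bounds of the region to tile
#'   (`region_start` more negative). Defaults cover the canonical main
#'   regulatory region -400..-200.
#' @param window Deletion window length in nt (default 30, about three DNA
#'   helical turns, chosen to minimally disturb the phasing of flanking
#'   sites).
#' @param overlap Overlap between adjacent windows in nt (default 10);
#'   must satisfy `0 <= overlap < window`.
#' @param prefix Name prefix (default `"Del"`).
#' @return A list of `designed_variant`s named `Del1..DelN`; the window
#'   table (columns `name`, `start`, `end`, `clipped`) is attached as the
#'   `windows` attribute.
#' @examples
#' p <- promoter_sequence(strrep("ACGT", 185))  # 740 nt
#' dels <- sliding_window_deletions(p)
#' length(dels)  # 10
#' @export
sliding_window_deletions <- function(seq, region_start = -400L,
                                     region_end = -200L, window = 30L,
                                     overlap = 10L, prefix = "Del") {
  stopifnot(is_promoter_sequence(seq))
  window <- as.integer(window)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= window) {
    stop("sliding_window_deletions: need 0 <= overlap < window", call. = FALSE)
  }
  region_len <- region_end - region_start + 1L
  if (region_len < window) {
    stop("sliding_window_deletions: region shorter than window", call. = FALSE)
  }
  step <- window - overlap
  n <- as.integer(ceiling((region_len - window) / step)) + 1L
  starts <- region_start + (seq_len(n) - 1L) * step
  ends <- starts + window - 1L
  clipped <- ends > region_end
  starts[clipped] <- region_end - window + 1L
  ends[clipped] <- region_end
  names_ <- paste0(prefix, seq_len(n))
  wins <- data.frame(name = names_, start = starts, end = ends,
                     clipped = clipped, stringsAsFactors = FALSE)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    out[[k]] <- compose(seq, edit_plan(edit_delete(starts[k], ends[k])),
                        name = names_[k])
  }
  names(out) <- names_
  attr(out, "windows") <- wins
  out
}

#' Tandem duplication of a promoter segment or the main regulatory region
#'
#' `duplicate_segment()` makes the segment appear `copies` times in tandem
#' at its original locus (final length grows by `(copies - 1) *
#' segment_length`). `duplicate_region()` duplicates the main regulatory
#' region (default -506..-126) and prepends `"D-"` to the variant name, the
#' convention for whole-region duplications.
#'
#' @param seq A [promoter_sequence()] or `designed_variant`.
#' @inheritParams edit_substitute
#' @param name Optional variant name.
#' @return A `designed_variant`.
#' @export
duplicate_segment <- function(seq, start, end, copies = 2L, name = NULL) {
  compose(seq, edit_plan(edit_duplicate(start, end, copies)), name = name)
}

#' @rdname duplicate_segment
#' @export
duplicate_region <- function(seq, start = -506L, end = -126L, name = NULL) {
  compose(seq, edit_plan(edit_duplicate_region(start, end)), name = name)
}

#' Named segment presets for the canonical duplications
#'
#' The two key segments identified by sliding-window deletion analysis and
#' their multiplications: `"Dup2-3"` (duplicate -261..-232, the segment
#' shared by deletions 2 and 3), `"Dup5-7"` (duplicate -351..-282, shared
#' by deletions 5-7) and `"Trip2-3"` (three tandem copies of -261..-232).
#' `region_duplication_bounds()` returns the main-regulatory-region bounds:
#' the `"methods"` preset -506..-126 (the cloned construct, the default
#' everywhere) or the `"results"` preset -507..-122 (an alternate printed
#' span).
#'
#' @param name Preset name.
#' @return `segment_preset()`: list with `start`, `end`, `copies`.
#'   `region_duplication_bounds()`: integer vector `c(start, end)`.
#' @export
segment_preset <- function(name = c("Dup2-3", "Dup5-7", "Trip2-3")) {
  name <- match.arg(name)
  switch(name,
    "Dup2-3" = list(start = -261L, end = -232L, copies = 2L),
    "Dup5-7" = list(start = -351L, end = -282L, copies = 2L),
    "Trip2-3" = list(start = -261L, end = -232L, copies = 3L)
  )
}

#' @rdname segment_preset
#' @param which `"methods"` or `"results"`.
#' @export
region_duplication_bounds <- function(which = c("methods", "results")) {
  which <- match.arg(which)
  switch(which,
    methods = c(-506L, -126L),
    results = c(-507L, -122L)
  )
}

#' Write designed variants as multi-FASTA with a manifest
#'
#' @param variants A list of `designed_variant`s.
#' @param fasta_path,manifest_path Output paths; either may be `NULL` to
#'   skip that file.
#' @return The manifest data frame (`name`, `plan`, `length`), invisibly.
#' @export
write_variants <- function(variants, fasta_path = NULL, manifest_path = NULL) {
  if (inherits(variants, "designed_variant")) variants <- list(variants)
  man <- data.frame(
    name = vapply(variants, function(v) v$name, character(1)),
    plan = vapply(variants, function(v)
      paste(vapply(v$plan, .edit_label, character(1)), collapse = "; "),
      character(1)),
    length = vapply(variants, function(v) length(v$seq), integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(fasta_path)) {
    seqs <- lapply(variants, function(v) {
      s <- v$seq
      s$label <- v$name
      s
    })
    write_fasta(seqs, fasta_path)
  }
  if (!is.null(manifest_path)) {
    utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(man)
}
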