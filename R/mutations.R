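#' Parse point-mutation notation
#'
#' Parses the conventional upstream-mutation notation, e.g. `"-453T>C"`:
#' a negative position (both the ASCII hyphen and the typographic minus
#' U+2212 are accepted), the reference base, `>`, the alternative base.
#' Whitespace around `>` is tolerated. Canonical output (see
#' [format_mutation()]) uses the ASCII hyphen and no spaces, so
#' `format_mutation(parse_mutation(x))` round-trips.
#'
#' @param text A single notation string.
#' @return A `point_mutation`: list with `position` (negative integer),
#'   `ref`, `alt` (single bases) and `kind` (`"substitution"`,
#'   `"deletion"` or `"insertion"`; parsed text always yields a
#'   substitution).
#' @examples
#' parse_mutation("-453T > C")
#' format_mutation(parse_mutation("−453T > C"))  # "-453T>C"
#' @export
parse_mutation <- function(text) {
  stopifnot(length(text) == 1L)
  raw <- text
  txt <- gsub("−", "-", text)  # unicode minus -> ASCII hyphen
  m <- regexec("^\\s*(-\\d+)\\s*([ACGTacgt])\\s*>\\s*([ACGTacgt])\\s*$", txt)
  g <- regmatches(txt, m)[[1]]
  if (length(g) != 4L) {
    stop(sprintf("parse_mutation: malformed notation '%s'", raw), call. = FALSE)
  }
  pos <- as.integer(g[2])
  ref <- toupper(g[3])
  alt <- toupper(g[4])
  point_mutation(pos, ref, alt)
}

#' Construct a point mutation
#'
#' @param position Negative upstream position.
#' @param ref Reference base, or `NA` for an insertion.
#' @param alt Alternative base, or `NA` for a deletion.
#' @param kind One of `"substitution"`, `"deletion"`, `"insertion"`;
#'   inferred from `ref`/`alt` when missing.
#' @return A `point_mutation` object.
#' @export
point_mutation <- function(position, ref = NA_character_, alt = NA_character_,
                           kind = NULL) {
  position <- as.integer(position)
  if (is.na(position) || position >= 0L) {
    stop("point_mutation: position must be a negative integer", call. = FALSE)
  }
  chk <- function(b, what) {
    if (!is.na(b) && !b %in% c("A", "C", "G", "T")) {
      stop(sprintf("point_mutation: invalid %s base '%s'", what, b), call. = FALSE)
    }
    b
  }
  ref <- chk(toupper(as.character(ref)), "reference")
  alt <- chk(toupper(as.character(alt)), "alternative")
  if (is.null(kind)) {
    kind <- if (is.na(alt)) "deletion" else if (is.na(ref)) "insertion" else "substitution"
  }
  kind <- match.arg(kind, c("substitution", "deletion", "insertion"))
  if (kind == "substitution") {
    if (is.na(ref) || is.na(alt)) {
      stop("point_mutation: substitution needs both ref and alt", call. = FALSE)
    }
    if (ref == alt) {
      stop(sprintf("point_mutation: ref and alt are both '%s' at %d (no-op substitution)",
                   ref, position), call. = FALSE)
    }
  }
  if (kind == "deletion" && is.na(ref)) {
    stop("point_mutation: deletion needs a ref base", call. = FALSE)
  }
  if (kind == "insertion" && is.na(alt)) {
    stop("point_mutation: insertion needs an alt base", call. = FALSE)
  }
  structure(list(position = position, ref = ref, alt = alt, kind = kind),
            class = "point_mutation")
}

#' @rdname parse_mutation
#' @param mut A `point_mutation`.
#' @export
format_mutation <- function(mut) {
  stopifnot(inherits(mut, "point_mutation"))
  switch(mut$kind,
    substitution = sprintf("%d%s>%s", mut$position, mut$ref, mut$alt),
    deletion     = sprintf("%ddel%s", mut$position, mut$ref),
    insertion    = sprintf("%dins%s", mut$position, mut$alt)
  )
}

#' @export
print.point_mutation <- function(x, ...) {
  cat("<point_mutation>", format_mutation(x), "\n")
  invisible(x)
}

#' Parse a delimited list of mutation notations
#'
#' Splits on commas/semicolons/newlines and parses each token with
#' [parse_mutation()].
#'
#' @param text A string such as `"-453T>C, -449A>G"` (or a character vector
#'   of such strings).
#' @return A list of `point_mutation` objects.
#' @export
parse_mutations <- function(text) {
  toks <- unlist(strsplit(paste(text, collapse = "\n"), "[,;\n]"))
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  lapply(toks, parse_mutation)
}

#' Apply point mutations to a promoter sequence
#'
#' Every mutation's reference base is checked against the sequence before
#' anything is edited; a mismatch aborts with the position, expected and
#' found bases. Positions must be distinct. Substitutions preserve length;
#' each deletion shortens the sequence by 1 nt; an insertion places the new
#' base immediately 5' of the addressed position.
#'
#' @param seq A [promoter_sequence()].
#' @param muts A `point_mutation` or list of them (or a notation string,
#'   which is run through [parse_mutations()]).
#' @return The edited `promoter_sequence`.
#' @examples
#' p <- promoter_sequence("ACGTACGT")
#' as.character(apply_mutations(p, parse_mutations("-4A>G")))
#' @export
apply_mutations <- function(seq, muts) {
  stopifnot(is_promoter_sequence(seq))
  if (is.character(muts)) muts <- parse_mutations(muts)
  if (inherits(muts, "point_mutation")) muts <- list(muts)
  if (length(muts) == 0L) return(seq)
  pos <- vapply(muts, function(m) m$position, integer(1))
  if (anyDuplicated(pos)) {
    stop(sprintf("apply_mutations: duplicate position %d", pos[duplicated(pos)][1]),
         call. = FALSE)
  }
  L <- length(seq)
  idx <- upstream_to_index(pos, L)
  # validate all ref bases before editing
  for (k in seq_along(muts)) {
    m <- muts[[k]]
    if (m$kind %in% c("substitution", "deletion")) {
      found <- seq$bases[idx[k]]
      if (found != m$ref) {
        stop(sprintf(
          "apply_mutations: reference mismatch at %d (expected %s, found %s)",
          m$position, m$ref, found
        ), call. = FALSE)
      }
    }
  }
  bases <- seq$bases
  kinds <- vapply(muts, function(m) m$kind, character(1))
  for (k in which(kinds == "substitution")) bases[idx[k]] <- muts[[k]]$alt
  # indels applied 3'-most first so earlier indices stay valid
  indel <- order(idx, decreasing = TRUE)
  for (k in indel) {
    if (kinds[k] == "deletion") {
      bases <- bases[-idx[k]]
    } else if (kinds[k] == "insertion") {
      bases <- append(bases, muts[[k]]$alt, after = idx[k] - 1L)
    }
  }
  promoter_sequence(bases, label = seq$label)
}
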