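#' Promoter sequence anchored to the start codon
#'
#' A `promoter_sequence` is an upstream regulatory sequence addressed in
#' negative coordinates: position -1 is the base immediately 5' of the A of
#' the start codon, position -L (L = sequence length) is the 5'-most base.
#' This is the coordinate convention used throughout promoter-engineering
#' work ("-453T>C" names the base 453 nt upstream of ATG).
#'
#' @param bases A single string or a character vector of single bases.
#'   Lowercase is normalised to uppercase; only A/C/G/T are allowed.
#' @param label Free-text identifier for the sequence.
#' @return An object of class `promoter_sequence`: a list with elements
#'   `bases` (character vector, one base per element) and `label`.
#' @examples
#' p <- promoter_sequence("ACGTACGT", label = "toy")
#' length(p)
#' as.character(p)
#' @export
promoter_sequence <- function(bases, label = "promoter") {
  if (length(bases) == 1L && nchar(bases[1]) > 1L) {
    bases <- strsplit(bases, "", fixed = TRUE)[[1]]
  }
  bases <- toupper(as.character(bases))
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bases) == 0L) {
    stop("promoter_sequence: empty sequence", call. = FALSE)
  }
  if (length(bad) > 0L) {
    stop(sprintf(
      "promoter_sequence: invalid character '%s' at offset %d (only A/C/G/T allowed)",
      bases[bad[1]], bad[1]
    ), call. = FALSE)
  }
  structure(list(bases = bases, label = as.character(label)[1]),
            class = "promoter_sequence")
}

#' @export
length.promoter_sequence <- function(x) length(x$bases)

#' @export
as.character.promoter_sequence <- function(x, ...) paste(x$bases, collapse = "")

#' @export
print.promoter_sequence <- function(x, ...) {
  s <- as.character(x)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<promoter_sequence> %s (%d nt)\n  %s\n", x$label, length(x), s))
  invisible(x)
}

is_promoter_sequence <- function(x) inherits(x, "promoter_sequence")

#' Convert upstream positions to sequence indices and back
#'
#' Upstream positions are negative integers with -1 the base adjacent to the
#' start codon; sequence indices are the usual 1-based R indices with index 1
#' the 5'-most base. For a sequence of length L the two systems are related
#' by `index = L + position + 1`, a bijection between \{-L..-1\} and
#' \{1..L\}.
#'
#' @param position Integer vector of upstream positions (all negative).
#' @param length Sequence length in nt.
#' @return `upstream_to_index()`: integer vector of 1-based indices.
#'   `index_to_upstream()`: integer vector of upstream positions.
#' @examples
#' upstream_to_index(-1, 740)   # 740
#' upstream_to_index(-740, 740) # 1
#' index_to_upstream(1, 740)    # -740
#' @export
upstream_to_index <- function(position, length) {
  position <- as.integer(position)
  length <- as.integer(length)
  if (any(is.na(position))) stop("upstream_to_index: NA position", call. = FALSE)
  out <- position < -length | position > -1L
  if (any(out)) {
    stop(sprintf(
      "upstream_to_index: position %d out of range [-%d, -1]",
      position[which(out)[1]], length
    ), call. = FALSE)
  }
  length + position + 1L
}

#' @rdname upstream_to_index
#' @param index Integer vector of 1-based sequence indices.
#' @export
index_to_upstream <- function(index, length) {
  index <- as.integer(index)
  length <- as.integer(length)
  if (any(index < 1L | index > length)) {
    stop("index_to_upstream: index out of range", call. = FALSE)
  }
  index - length - 1L
}

#' Extract a sub-region of a promoter by upstream coordinates
#'
#' @param seq A [promoter_sequence()].
#' @param start,end Upstream positions bounding the region, `start` the more
#'   negative (5') bound, inclusive on both sides.
#' @return A `promoter_sequence` covering the region; its `region` attribute
#'   records the original coordinates `c(start, end)`.
#' @export
extract_region <- function(seq, start, end) {
  stopifnot(is_promoter_sequence(seq))
  if (start > end) stop("extract_region: start must be <= end", call. = FALSE)
  i <- upstream_to_index(start, length(seq))
  j <- upstream_to_index(end, length(seq))
  out <- promoter_sequence(seq$bases[i:j],
                           label = sprintf("%s[%d..%d]", seq$label, start, end))
  attr(out, "region") <- c(start, end)
  out
}

#' Read and write promoter sequences in FASTA format
#'
#' Thin wrappers around Biostrings' FASTA I/O that enforce the
#' `promoter_sequence` contract: uppercase A/C/G/T only (ambiguity codes are
#' rejected with the offending offset), non-empty files, unique identifiers,
#' record order preserved.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()`: a named list of [promoter_sequence()] objects.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) stop("read_fasta: no records in ", path, call. = FALSE)
  ids <- names(x)
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate identifier '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  }
  out <- lapply(seq_along(x), function(i) {
    s <- toupper(as.character(x[[i]]))
    bad <- regexpr("[^ACGT]", s)
    if (bad > 0) {
      stop(sprintf("read_fasta: record '%s' has invalid character '%s' at offset %d",
                   ids[i], substr(s, bad, bad), bad), call. = FALSE)
    }
    promoter_sequence(s, label = ids[i])
  })
  names(out) <- ids
  out
}

#' @rdname read_fasta
#' @param seqs A [promoter_sequence()] or list of them.
#' @export
write_fasta <- function(seqs, path) {
  if (is_promoter_sequence(seqs)) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, as.character, character(1)))
  names(ss) <- vapply(seqs, function(s) s$label, character(1))
  Biostrings::writeXStringSet(ss, filepath = path, format = "fasta")
  invisible(path)
}
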