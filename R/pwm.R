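#' Build a position weight matrix from base counts
#'
#' Converts a 4 x W count matrix (rows A, C, G, T) into the PWM
#' representation used by the scanner: per-position base frequencies with a
#' pseudocount, per-position conservation weights, and a core — the run of
#' consecutive positions with the highest summed conservation weight.
#'
#' The conservation weight of position i is the Kullback-Leibler divergence
#' of its base distribution from uniform, `w_i = sum_b f_i(b) * ln(4 f_i(b))`
#' (0-frequency terms contribute 0, the sum is clamped at 0): exactly 0 for
#' an uninformative uniform column and maximal (ln 4) for a single-base
#' column. These weights make conserved positions dominate the similarity
#' score, mirroring how commercial motif scanners weight their matrices.
#'
#' @param counts 4 x W numeric matrix of non-negative base counts; rows in
#'   A, C, G, T order (row names, if present, must be a permutation of
#'   these and are honoured).
#' @param pseudocount Per-base pseudocount added before normalisation
#'   (default 0.8). With pseudocount 0, an all-zero column is an error.
#' @param matrix_id,factor_name,family_code Identifiers carried into hits.
#'   `family_code` uses the conventional `<group>$<FAMILY>` style (e.g.
#'   `"F$CSRE"`, `"Y$MIG"`).
#' @param core_size Number of consecutive positions forming the core
#'   (default 4, clipped to the matrix width); leftmost window on ties.
#' @return A `pwm` object: list with `matrix_id`, `factor_name`,
#'   `family_code`, `counts`, `frequencies` (4 x W, columns sum to 1),
#'   `conservation_weights` (length W), `core_positions`, `width`,
#'   `consensus` (one max base per position).
#' @examples
#' cnt <- matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4,
#'               dimnames = list(c("A", "C", "G", "T"), NULL))
#' pwm <- normalize_pwm(cnt, pseudocount = 0, matrix_id = "toy")
#' pwm$consensus
#' @export
normalize_pwm <- function(counts, pseudocount = 0.8, matrix_id = "pwm",
                          factor_name = matrix_id, family_code = matrix_id,
                          core_size = 4L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) {
    stop("normalize_pwm: counts must have 4 rows (A, C, G, T)", call. = FALSE)
  }
  if (!is.null(rownames(counts))) {
    rn <- toupper(rownames(counts))
    if (!setequal(rn, c("A", "C", "G", "T"))) {
      stop("normalize_pwm: row names must be A, C, G, T", call. = FALSE)
    }
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  } else {
    rownames(counts) <- c("A", "C", "G", "T")
  }
  if (ncol(counts) < 1L) stop("normalize_pwm: matrix has no positions", call. = FALSE)
  if (any(counts < 0)) stop("normalize_pwm: negative counts", call. = FALSE)
  if (pseudocount < 0) stop("normalize_pwm: negative pseudocount", call. = FALSE)
  tot <- colSums(counts) + 4 * pseudocount
  if (any(tot == 0)) {
    stop("normalize_pwm: all-zero column with pseudocount 0", call. = FALSE)
  }
  freq <- sweep(counts + pseudocount, 2, tot, "/")
  w <- apply(freq, 2, function(f) {
    terms <- ifelse(f > 0, f * log(4 * f), 0)
    max(sum(terms), 0)
  })
  cs <- min(as.integer(core_size), ncol(freq))
  if (cs < 1L) stop("normalize_pwm: core_size must be >= 1", call. = FALSE)
  sums <- vapply(seq_len(ncol(freq) - cs + 1L),
                 function(i) sum(w[i:(i + cs - 1L)]), numeric(1))
  core_start <- which.max(sums)  # leftmost maximum
  core <- core_start:(core_start + cs - 1L)
  consensus <- rownames(freq)[apply(freq, 2, which.max)]
  structure(list(
    matrix_id = as.character(matrix_id),
    factor_name = as.character(factor_name),
    family_code = as.character(family_code),
    counts = counts,
    frequencies = freq,
    conservation_weights = unname(w),
    core_positions = core,
    width = ncol(freq),
    consensus = consensus
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s, family %s), width %d, core %d..%d\n  consensus %s\n",
              x$matrix_id, x$factor_name, x$family_code, x$width,
              min(x$core_positions), max(x$core_positions),
              paste(x$consensus, collapse = "")))
  invisible(x)
}

is_pwm <- function(x) inherits(x, "pwm")

# Precompute scoring tables for one PWM on one strand.
# wf[b, i] = w_i * f_i(b); denom = sum_i w_i * max_b f_i(b).
.pwm_tables <- function(pwm) {
  w <- pwm$conservation_weights
  wf <- sweep(pwm$frequencies, 2, w, "*")
  denom <- sum(w * apply(pwm$frequencies, 2, max))
  core <- pwm$core_positions
  core_denom <- sum(w[core] * apply(pwm$frequencies[, core, drop = FALSE], 2, max))
  # reverse-complement tables: complement of code b is 5-b, position mirrored
  wf_rc <- wf[4:1, rev(seq_len(ncol(wf))), drop = FALSE]
  core_rc <- sort(ncol(wf) + 1L - core)
  list(wf = wf, denom = denom, core = core, core_denom = core_denom,
       wf_rc = wf_rc, core_rc = core_rc)
}

.base_codes <- function(bases) match(bases, c("A", "C", "G", "T"))

# Scores of all windows of width w over codes, restricted to window start
# indices [from, to]. Returns list(start, mss, css).
.score_windows <- function(codes, wf, denom, core, core_denom, from, to) {
  w <- ncol(wf)
  starts <- from:to
  n <- length(starts)
  num <- numeric(n)
  for (i in seq_len(w)) {
    num <- num + wf[cbind(codes[starts + i - 1L], i)]
  }
  cnum <- numeric(n)
  for (i in core) {
    cnum <- cnum + wf[cbind(codes[starts + i - 1L], i)]
  }
  mss <- if (denom > 0) num / denom else rep(1, n)
  css <- if (core_denom > 0) cnum / core_denom else rep(1, n)
  list(start = starts, mss = mss, css = css)
}

#' Matrix similarity of a sequence window to a PWM
#'
#' The similarity score is the conservation-weighted frequency ratio
#' `sum_i w_i f_i(b_i) / sum_i w_i max_b f_i(b)`, bounded in \[0, 1\] and
#' equal to 1 exactly when every window base attains its position's maximum
#' frequency (ties allowed, so degenerate matrices can have several
#' perfect-scoring words). `core_similarity()` is the same ratio restricted
#' to the core positions.
#'
#' @param pwm A [normalize_pwm()] object.
#' @param window A string or base vector of exactly the matrix width.
#' @return A number in \[0, 1\].
#' @examples
#' cnt <- matrix(c(8, 1, 1, 0, 0, 9, 1, 0), nrow = 4,
#'               dimnames = list(c("A", "C", "G", "T"), NULL))
#' p <- normalize_pwm(cnt, matrix_id = "toy")
#' matrix_similarity(p, paste(p$consensus, collapse = ""))  # 1
#' @export
matrix_similarity <- function(pwm, window) {
  stopifnot(is_pwm(pwm))
  if (length(window) == 1L && nchar(window[1]) > 1L) {
    window <- strsplit(window, "", fixed = TRUE)[[1]]
  }
  window <- toupper(window)
  if (length(window) != pwm$width) {
    stop(sprintf("matrix_similarity: window length %d != matrix width %d",
                 length(window), pwm$width), call. = FALSE)
  }
  codes <- .base_codes(window)
  if (anyNA(codes)) stop("matrix_similarity: window must be A/C/G/T", call. = FALSE)
  tb <- .pwm_tables(pwm)
  .score_windows(codes, tb$wf, tb$denom, tb$core, tb$core_denom, 1L, 1L)$mss
}

#' @rdname matrix_similarity
#' @export
core_similarity <- function(pwm, window) {
  stopifnot(is_pwm(pwm))
  if (length(window) == 1L && nchar(window[1]) > 1L) {
    window <- strsplit(window, "", fixed = TRUE)[[1]]
  }
  codes <- .base_codes(toupper(window))
  if (length(codes) != pwm$width || anyNA(codes)) {
    stop("core_similarity: window must be A/C/G/T of matrix width", call. = FALSE)
  }
  tb <- .pwm_tables(pwm)
  .score_windows(codes, tb$wf, tb$denom, tb$core, tb$core_denom, 1L, 1L)$css
}

#' Read and write PWMs as JASPAR PFM text
#'
#' The JASPAR position-frequency-matrix text format: a header line
#' `>ID name` followed by four base rows, either `A [ 3 10 2 ... ]` or the
#' bare numbers in A, C, G, T order. Multiple records per file are allowed.
#'
#' @param path Path to a PFM text file.
#' @param pseudocount,core_size Passed to [normalize_pwm()].
#' @param family_codes Optional named character vector mapping matrix IDs to
#'   family codes; unmapped matrices use their ID as family.
#' @return `read_jaspar_pfm()`: a named list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8, core_size = 4L,
                            family_codes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("read_jaspar_pfm: no '>' headers in ", path, call. = FALSE)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    stopline <- if (h < length(heads)) heads[h + 1] - 1L else length(lines)
    body <- lines[(i + 1L):stopline]
    if (length(body) < 4L) {
      stop("read_jaspar_pfm: record with fewer than 4 matrix rows", call. = FALSE)
    }
    hd <- sub("^>\\s*", "", lines[i])
    parts <- strsplit(hd, "\\s+")[[1]]
    id <- parts[1]
    nm <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    rows <- lapply(body[1:4], function(l) {
      l2 <- gsub("^[ACGTacgt]\\s*", "", l)
      l2 <- gsub("[\\[\\]]", " ", l2, perl = TRUE)
      as.numeric(strsplit(trimws(l2), "\\s+")[[1]])
    })
    if (length(unique(vapply(rows, length, integer(1)))) != 1L) {
      stop("read_jaspar_pfm: ragged matrix rows for ", id, call. = FALSE)
    }
    cnt <- do.call(rbind, rows)
    rownames(cnt) <- c("A", "C", "G", "T")
    fam <- if (!is.null(family_codes) && id %in% names(family_codes)) {
      family_codes[[id]]
    } else {
      id
    }
    out[[id]] <- normalize_pwm(cnt, pseudocount = pseudocount, matrix_id = id,
                               factor_name = nm, family_code = fam,
                               core_size = core_size)
  }
  out
}

#' @rdname read_jaspar_pfm
#' @param pwms A `pwm` or list of `pwm` objects.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  if (is_pwm(pwms)) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$matrix_id, p$factor_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a plain count-table PWM
#'
#' A TRANSFAC-like layout: a whitespace-delimited table with one row per
#' matrix position and columns A, C, G, T (header required); an optional
#' leading position column is ignored.
#'
#' @inheritParams read_jaspar_pfm
#' @param matrix_id,factor_name,family_code Passed to [normalize_pwm()].
#' @return A single `pwm` object.
#' @export
read_count_matrix <- function(path, matrix_id = basename(path),
                              factor_name = matrix_id, family_code = matrix_id,
                              pseudocount = 0.8, core_size = 4L) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  names(tab) <- toupper(names(tab))
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(tab))) {
    stop("read_count_matrix: need columns A, C, G, T", call. = FALSE)
  }
  cnt <- t(as.matrix(tab[, need]))
  normalize_pwm(cnt, pseudocount = pseudocount, matrix_id = matrix_id,
                factor_name = factor_name, family_code = family_code,
                core_size = core_size)
}
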