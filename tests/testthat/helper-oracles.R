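# Independent brute-force oracles, deliberately naive: plain loops over
# characters, no shared scoring code with the package internals.

oracle_revcomp <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[rev(chars)])
}

# Conservation weights recomputed from scratch from the frequency matrix.
oracle_weights <- function(freq) {
  apply(freq, 2, function(f) {
    s <- 0
    for (b in seq_len(4)) if (f[b] > 0) s <- s + f[b] * log(4 * f[b])
    max(s, 0)
  })
}

oracle_window_score <- function(freq, window_chars, positions = seq_len(ncol(freq))) {
  w <- oracle_weights(freq)
  num <- 0
  den <- 0
  for (i in positions) {
    num <- num + w[i] * freq[window_chars[i], i]
    den <- den + w[i] * max(freq[, i])
  }
  if (den == 0) 1 else num / den
}

# Exhaustive scanner: every window, both strands, direct definition.
oracle_scan <- function(seq, pwms, threshold = 0.75, core_threshold = 0.75) {
  chars <- seq$bases
  L <- length(chars)
  rows <- list()
  for (p in pwms) {
    w <- p$width
    if (w > L) next
    for (i in seq_len(L - w + 1)) {
      win <- chars[i:(i + w - 1)]
      for (strand in c("+", "-")) {
        wc <- if (strand == "+") win else oracle_revcomp(win)
        mss <- oracle_window_score(p$frequencies, wc)
        css <- oracle_window_score(p$frequencies, wc, p$core_positions)
        ok <- mss > threshold && (is.null(core_threshold) || css >= core_threshold)
        if (ok) {
          rows[[length(rows) + 1]] <- data.frame(
            matrix_id = p$matrix_id, family_code = p$family_code,
            strand = strand, start = i - L - 1, end = i + w - 1 - L - 1,
            matrix_similarity = mss, core_similarity = css,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(matrix_id = character(), family_code = character(),
                      strand = character(), start = integer(), end = integer(),
                      matrix_similarity = numeric(), core_similarity = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$matrix_id, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_same_hits <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a) == 0) return(invisible())
  for (col in c("matrix_id", "strand")) {
    expect_identical(a[[col]], b[[col]])
  }
  for (col in c("start", "end")) {
    expect_equal(as.integer(a[[col]]), as.integer(b[[col]]))
  }
  expect_equal(a$matrix_similarity, b$matrix_similarity, tolerance = tol)
  expect_equal(a$core_similarity, b$core_similarity, tolerance = tol)
}

# Naive saturation-effect oracle: rebuild each variant string and rescan in
# full; family-level gains/losses keyed by (matrix_id, strand, start).
oracle_effect_map <- function(reference, pwms, threshold = 0.75,
                              core_threshold = 0.75) {
  L <- length(reference)
  ref_hits <- oracle_scan(reference, pwms, threshold, core_threshold)
  ref_key <- paste(ref_hits$matrix_id, ref_hits$strand, ref_hits$start)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (pos in seq(-L, -1)) {
    i <- L + pos + 1
    refb <- reference$bases[i]
    for (alt in setdiff(bases, refb)) {
      chars <- reference$bases
      chars[i] <- alt
      var_seq <- promoter_sequence(chars)
      vh <- oracle_scan(var_seq, pwms, threshold, core_threshold)
      vk <- paste(vh$matrix_id, vh$strand, vh$start)
      g <- !vk %in% ref_key
      l <- !ref_key %in% vk
      rows[[length(rows) + 1]] <- data.frame(
        position = pos, ref = refb, alt = alt,
        families_gained = paste(sort(unique(vh$family_code[g])), collapse = ","),
        families_lost = paste(sort(unique(ref_hits$family_code[l])), collapse = ","),
        n_hits_gained = sum(g), n_hits_lost = sum(l),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_promoter <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  promoter_sequence(sample(c("A", "C", "G", "T"), n, replace = TRUE))
}
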