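test_that("pseudocount normalisation and conservation weights follow the definitions", {
  cnt <- matrix(c(10, 0, 0, 0), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  p0 <- normalize_pwm(cnt, pseudocount = 0, core_size = 1)
  expect_equal(p0$frequencies[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(p0$conservation_weights, log(4))  # single-base column maximal

  p1 <- normalize_pwm(cnt, pseudocount = 1, core_size = 1)
  expect_equal(unname(p1$frequencies[, 1]), c(11, 1, 1, 1) / 14)

  unif <- normalize_pwm(matrix(c(5, 5, 5, 5), nrow = 4), pseudocount = 0,
                        core_size = 1)
  expect_equal(unif$conservation_weights, 0)

  expect_error(normalize_pwm(matrix(0, 4, 2), pseudocount = 0), "all-zero")
  # columns always sum to 1 after pseudocounting
  set.seed(3)
  cnt2 <- matrix(rpois(4 * 8, 5), nrow = 4)
  p2 <- normalize_pwm(cnt2, pseudocount = 0.8)
  expect_equal(colSums(p2$frequencies), rep(1, 8), tolerance = 1e-9)
  expect_true(all(p2$core_positions %in% seq_len(8)))
  expect_equal(length(p2$core_positions), 4)
})

test_that("matrix similarity is 1 at consensus, bounded, and matches the closed form", {
  pwms <- make_pwm_set(seed = 9, widths = c(6, 8, 10))
  for (p in pwms) {
    expect_equal(matrix_similarity(p, p$consensus), 1)
    # worst window: the minimum-frequency base at every position
    worst <- rownames(p$frequencies)[apply(p$frequencies, 2, which.min)]
    w <- p$conservation_weights
    expected_min <- sum(w * apply(p$frequencies, 2, min)) /
      sum(w * apply(p$frequencies, 2, max))
    expect_equal(matrix_similarity(p, worst), expected_min)
    # random windows stay in [0, 1] and never beat the consensus
    set.seed(31)
    for (k in 1:25) {
      win <- sample(c("A", "C", "G", "T"), p$width, replace = TRUE)
      s <- matrix_similarity(p, win)
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  }
  expect_error(matrix_similarity(pwms[[1]], "ACGT"), "width")
})

test_that("scanner finds a planted consensus at the planted coordinates", {
  pwms <- make_pwm_set(seed = 2, widths = 9)
  prom <- make_fixture_promoter(seed = 8, length = 400, constraints = NULL,
                                plantings = list(list(pwm = pwms[[1]],
                                                      position = -300)))
  hits <- scan_sequence(prom, pwms, threshold = 0.95, core_threshold = NULL)
  planted <- hits[hits$matrix_id == pwms[[1]]$matrix_id &
                    hits$matrix_similarity > 0.999, ]
  expect_true(any(planted$start == -300 & planted$strand == "+"))
  expect_equal(planted$end[planted$start == -300],
               -300 + pwms[[1]]$width - 1)
})

test_that("scanner equals the exhaustive brute-force oracle", {
  pwms <- make_pwm_set(seed = 4,
                       family_codes = c("F$CSRE", "Y$MIG", "F$GATA", "F$MGCM",
                                        "F$PRES"),
                       widths = c(5, 7, 8, 10, 12),
                       information_levels = c(0.6, 0.7, 0.8, 0.9, 0.95))
  for (seed in c(101, 202)) {
    seqx <- random_promoter(200, seed = seed)
    for (thr in c(0.6, 0.75, 0.9)) {
      got <- scan_sequence(seqx, pwms, threshold = thr, core_threshold = 0.75)
      want <- oracle_scan(seqx, pwms, threshold = thr, core_threshold = 0.75)
      expect_same_hits(got, want)
    }
    # with core filtering disabled too
    got <- scan_sequence(seqx, pwms, threshold = 0.7, core_threshold = NULL)
    want <- oracle_scan(seqx, pwms, threshold = 0.7, core_threshold = NULL)
    expect_same_hits(got, want)
  }
})

test_that("raising the threshold never adds hits (nested hit sets)", {
  pwms <- make_pwm_set(seed = 6, widths = 7, information_levels = 0.7)
  seqx <- random_promoter(300, seed = 77)
  thrs <- c(0.5, 0.65, 0.75, 0.85, 0.95)
  keys <- lapply(thrs, function(t) {
    h <- scan_sequence(seqx, pwms, threshold = t, core_threshold = NULL)
    paste(h$matrix_id, h$strand, h$start)
  })
  for (k in seq_along(thrs)[-1]) {
    expect_true(all(keys[[k]] %in% keys[[k - 1]]))
  }
  # threshold 1.0 on random background with no planted consensus: empty
  h1 <- scan_sequence(seqx, pwms, threshold = 1, core_threshold = NULL)
  expect_equal(nrow(h1), 0)
})

test_that("scanning the reverse complement flips strands and reflects coordinates", {
  pwms <- make_pwm_set(seed = 12, widths = c(6, 9))
  seqx <- random_promoter(150, seed = 55)
  L <- length(seqx)
  rc <- promoter_sequence(oracle_revcomp(seqx$bases), label = "rc")
  fwd <- scan_sequence(seqx, pwms, threshold = 0.6, core_threshold = NULL)
  rev_ <- scan_sequence(rc, pwms, threshold = 0.6, core_threshold = NULL)
  # reflect: a hit [s, e] on seq maps to [-(L+1)-e, -(L+1)-s] on the rc
  reflected <- data.frame(
    matrix_id = fwd$matrix_id,
    strand = ifelse(fwd$strand == "+", "-", "+"),
    start = -(L + 1) - fwd$end,
    end = -(L + 1) - fwd$start,
    mss = fwd$matrix_similarity,
    stringsAsFactors = FALSE)
  key <- function(d, mss) sort(paste(d$matrix_id, d$strand, d$start, d$end,
                                     round(mss, 10)))
  expect_identical(key(rev_, rev_$matrix_similarity),
                   key(reflected, reflected$mss))
})

test_that("PFM text and count tables round-trip through the parsers", {
  pwms <- make_pwm_set(seed = 21, family_codes = c("F$CSRE", "Y$MIG"),
                       widths = c(6, 8))
  tmp <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar_pfm(pwms, tmp)
  back <- read_jaspar_pfm(tmp, family_codes = stats::setNames(
    vapply(pwms, function(p) p$family_code, character(1)),
    vapply(pwms, function(p) p$matrix_id, character(1))))
  expect_equal(length(back), 2)
  for (k in 1:2) {
    expect_equal(unname(back[[k]]$counts), unname(pwms[[k]]$counts))
    expect_identical(back[[k]]$family_code, pwms[[k]]$family_code)
    expect_equal(back[[k]]$frequencies, pwms[[k]]$frequencies)
  }
  # count-table reader agrees with direct construction
  tab <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(t(pwms[[1]]$counts)), tab, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p2 <- read_count_matrix(tab, matrix_id = "M1")
  expect_equal(unname(p2$counts), unname(pwms[[1]]$counts))
})

test_that("hit export writes well-formed TSV and BED6", {
  pwms <- make_pwm_set(seed = 2, widths = 9)
  prom <- make_fixture_promoter(seed = 8, length = 100, constraints = NULL,
                                plantings = list(list(pwm = pwms[[1]],
                                                      position = -50)))
  hits <- scan_sequence(prom, pwms, threshold = 0.9, core_threshold = NULL)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_tsv(hits, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(hits))
  write_hits_bed(hits, prom, bed)
  b <- utils::read.delim(bed, header = FALSE)
  expect_equal(nrow(b), nrow(hits))
  # half-open BED interval length equals motif width
  expect_true(all(b$V3 - b$V2 == hits$end - hits$start + 1))
  expect_true(all(b$V5 >= 0 & b$V5 <= 1000))
})
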