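test_that("sliding windows over -400..-200 give exactly 10 deletion variants", {
  p <- make_fixture_promoter(seed = 1)
  dels <- sliding_window_deletions(p)
  expect_equal(length(dels), 10)
  wins <- attr(dels, "windows")
  expect_identical(wins$name, paste0("Del", 1:10))
  expect_equal(wins$start[1], -400)
  expect_equal(wins$end[10], -200)
  # every variant deletes exactly 30 bp
  for (v in dels) expect_equal(length(v$seq), 740 - 30)
  # interior pairs share exactly `overlap` bp; the final clipped window may share more
  ov <- wins$end[-10] - wins$start[-1] + 1
  expect_true(all(ov[1:8] == 10))
  expect_true(ov[9] >= 10)
  expect_true(wins$clipped[10] && !any(wins$clipped[1:9]))
  # the union of windows covers the region with no gaps
  covered <- sort(unique(unlist(Map(seq, wins$start, wins$end))))
  expect_identical(covered, seq(-400, -200))
})

test_that("window placement reproduces an independent enumeration oracle", {
  oracle_windows <- function(rs, re, w, ov) {
    step <- w - ov
    starts <- integer()
    s <- rs
    while (s + w - 1 <= re) {
      starts <- c(starts, s)
      s <- s + step
    }
    if (length(starts) == 0 || starts[length(starts)] + w - 1 < re) {
      starts <- c(starts, re - w + 1)
    }
    data.frame(start = starts, end = starts + w - 1)
  }
  set.seed(61)
  p <- random_promoter(600)
  for (rep in 1:100) {
    w <- sample(10:40, 1)
    ov <- sample(0:(w - 1), 1)
    rs <- -sample(200:590, 1)
    len <- sample(w:150, 1)
    re <- min(rs + len - 1, -1)
    if (re - rs + 1 < w) next
    dels <- sliding_window_deletions(p, rs, re, window = w, overlap = ov)
    wins <- attr(dels, "windows")
    want <- oracle_windows(rs, re, w, ov)
    expect_equal(wins$start, want$start)
    expect_equal(wins$end, want$end)
  }
  # degenerate: region length equals window -> one variant deleting it all
  one <- sliding_window_deletions(p, -130, -101, window = 30, overlap = 10)
  expect_equal(length(one), 1)
  expect_equal(attr(one, "windows")$start, -130)
  expect_error(sliding_window_deletions(p, -120, -101, window = 30),
               "region shorter")
  expect_error(sliding_window_deletions(p, -200, -101, window = 30,
                                        overlap = 30), "overlap")
})

test_that("segment duplication grows the sequence and places tandem copies", {
  p <- make_fixture_promoter(seed = 3)
  pre <- segment_preset("Dup2-3")
  d <- duplicate_segment(p, pre$start, pre$end, pre$copies)
  expect_equal(length(d$seq), 740 + 30)
  seg <- paste(p$bases[upstream_to_index(-261, 740):upstream_to_index(-232, 740)],
               collapse = "")
  expect_true(grepl(paste0(seg, seg), as.character(d$seq), fixed = TRUE))

  t3 <- duplicate_segment(p, pre$start, pre$end, 3)
  expect_equal(length(t3$seq), 740 + 60)
  # triplication equals duplicate-then-duplicate-the-copy composition
  twice <- compose(p, edit_plan(edit_duplicate(-261, -232, 2),
                                edit_duplicate(-261, -232, 2)))
  expect_identical(as.character(t3$seq), as.character(twice$seq))

  pre57 <- segment_preset("Dup5-7")
  d57 <- duplicate_segment(p, pre57$start, pre57$end)
  expect_equal(length(d57$seq), 740 + 70)

  expect_error(duplicate_segment(p, -800, -700), "out of bounds")
  expect_error(edit_duplicate(-261, -232, copies = 1), "identity")
})

test_that("stale original-frame coordinates after a deletion are caught by content", {
  # deleting a segment then duplicating "the same" coordinates duplicates
  # different bases: the composition must not round-trip to a simple dup
  p <- random_promoter(300, seed = 17)
  del_dup <- compose(p, edit_plan(edit_delete(-150, -121),
                                  edit_duplicate(-150, -121, 2)))
  expect_equal(length(del_dup$seq), 300)  # -30 then +30
  expect_false(identical(as.character(del_dup$seq), as.character(p)))
  # the correct forward projection of the deleted segment start is NA
  expect_true(is.na(project_position(edit_plan(edit_delete(-150, -121)), -130)))
})

test_that("region duplication uses template semantics and the D- prefix", {
  p <- make_fixture_promoter(seed = 5)
  d <- duplicate_region(p)
  expect_equal(length(d$seq), 740 + 381)
  expect_match(d$name, "^D-")
  # a substitution made before the duplication lands in both copies
  mutb <- compose(p, edit_plan(edit_substitute(-453, "T", "C")), name = "MutB")
  dmutb <- duplicate_region(mutb)
  L2 <- length(dmutb$seq)
  expect_identical(dmutb$seq$bases[upstream_to_index(-453, L2)], "C")
  expect_identical(dmutb$seq$bases[upstream_to_index(-453 - 381, L2)], "C")
  expect_match(dmutb$name, "^D-")
  # alternate printed bounds are available as a preset
  expect_identical(region_duplication_bounds("results"), c(-507L, -122L))
  short <- promoter_sequence(strrep("ACGT", 50))
  expect_error(duplicate_region(short), "out of bounds")
})

test_that("compose propagates substitutions into duplicated copies (template semantics)", {
  p <- make_fixture_promoter(seed = 7)
  # MutP then duplicate the Dup2-3 segment: both copies carry the alt base
  v <- compose(p, edit_plan(edit_substitute(-235, "A", "G"),
                            edit_duplicate(-261, -232, 2)))
  L2 <- length(v$seq)
  expect_identical(v$seq$bases[upstream_to_index(-235, L2)], "G")
  expect_identical(v$seq$bases[upstream_to_index(-235 - 30, L2)], "G")
  # string-comparison oracle: sub-then-dup == dup-then-sub-at-both-offsets
  alt_route <- compose(p, edit_plan(edit_duplicate(-261, -232, 2),
                                    edit_substitute(-235, "A", "G"),
                                    edit_substitute(-265, "A", "G")))
  expect_identical(as.character(v$seq), as.character(alt_route$seq))
  # empty plan is the identity
  same <- compose(p, edit_plan())
  expect_identical(as.character(same$seq), as.character(p))
  # a failing step reports its index
  expect_error(compose(p, edit_plan(edit_substitute(-453, "A", "G"))),
               "step 1")
  expect_error(compose(p, edit_plan(edit_substitute(-453, "T", "C"),
                                    edit_delete(-900, -880))),
               "step 2")
})

test_that("length bookkeeping holds over random edit plans", {
  set.seed(83)
  for (rep in 1:25) {
    p <- random_promoter(sample(200:400, 1))
    n_edit <- sample(1:4, 1)
    expected <- length(p)
    plan <- list()
    cur <- p
    for (k in seq_len(n_edit)) {
      L <- expected
      type <- sample(c("del", "dup"), 1)
      s <- -sample(20:L, 1)
      e <- min(s + sample(5:25, 1), -1)
      if (type == "del") {
        plan[[k]] <- edit_delete(s, e)
        expected <- expected - (e - s + 1)
      } else {
        cp <- sample(2:3, 1)
        plan[[k]] <- edit_duplicate(s, e, cp)
        expected <- expected + (cp - 1) * (e - s + 1)
      }
    }
    v <- compose(p, do.call(edit_plan, plan))
    expect_equal(length(v$seq), expected)
  }
})

test_that("variant export writes FASTA plus a consistent manifest", {
  p <- make_fixture_promoter(seed = 9, length = 500,
                             constraints = NULL)
  dels <- sliding_window_deletions(p, -300, -200)
  fa <- withr::local_tempfile(fileext = ".fa")
  man_path <- withr::local_tempfile(fileext = ".tsv")
  man <- write_variants(dels, fa, man_path)
  back <- read_fasta(fa)
  expect_identical(names(back), man$name)
  expect_equal(unname(vapply(back, length, integer(1))), man$length)
  expect_equal(utils::read.delim(man_path)$length, man$length)
})
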