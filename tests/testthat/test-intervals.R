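# Interval engine: construction, BED I/O, merge/intersect/filter/
# consensus against per-base brute-force oracles.

test_that("interval_set validates coordinates", {
  expect_error(interval_set("chr1", 100, 100), "zero- or negative-length")
  expect_error(interval_set("chr1", 200, 100), "zero- or negative-length")
  expect_error(interval_set("chr1", -5, 100), "start must be >= 0")
  expect_error(interval_set("chr 1", 0, 100), "whitespace")
  s <- interval_set("chr1", 0, 100)
  expect_s3_class(s, "IntervalSet")
  expect_equal(n_intervals(s), 1)
})

test_that("read_bed parses dialects and reports malformed rows", {
  p <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100", "chr2\t50\t150"), p)
  s <- read_bed(p, "bed3")
  expect_equal(as.data.frame(s)$start, c(0, 50))
  expect_false(s$canonical)

  writeLines(c("chr1\t0\t100\tpeak1\t7.5\t+"), p)
  s6 <- read_bed(p, "bed6")
  expect_equal(as.data.frame(s6)$name, "peak1")
  expect_equal(as.data.frame(s6)$score, 7.5)

  # narrowPeak: signalValue (col 7) maps to score, not col 5
  writeLines(paste("chr1", 10, 500, "np1", 0, ".", 7.5, 12, 9, 250,
                   sep = "\t"), p)
  np <- read_bed(p, "narrowPeak")
  expect_equal(as.data.frame(np)$score, 7.5)

  writeLines(c("chr1\t0\t100", "chr1\t100\t100"), p)
  expect_error(read_bed(p, "bed3"), "line 2.*zero-length")
  writeLines(c("chr1\t0"), p)
  expect_error(read_bed(p, "bed3"), "line 1")
  writeLines(c("chr1\tzero\t100"), p)
  expect_error(read_bed(p, "bed3"), "line 1.*parse")
})

test_that("write_bed/read_bed round-trips bed3 and bed6", {
  p <- withr::local_tempfile()
  s <- canonicalize(interval_set("chr1", c(0, 500), c(100, 900)))
  write_bed(s, p)
  expect_equal(as.data.frame(read_bed(p, "bed3")), as.data.frame(s))

  s6 <- interval_set("chr1", c(0, 500), c(100, 900),
                     name = c("a", "b"), score = c(1.5, NA))
  write_bed(s6, p)
  back <- read_bed(p, "bed6")
  expect_equal(as.data.frame(back), as.data.frame(s6))

  empty <- interval_set(character(), numeric(), numeric())
  write_bed(empty, p)
  expect_equal(n_intervals(read_bed(p, "bed3")), 0)
})

test_that("merge_intervals follows bedtools gap semantics", {
  s <- set_from_df(data.frame(chrom = "chr1", start = c(0, 90),
                              end = c(100, 200)))
  expect_equal(as.data.frame(merge_intervals(s, 0))$end, 200)
  # book-ended intervals merge at gap 0
  be <- set_from_df(data.frame(chrom = "chr1", start = c(0, 100),
                               end = c(100, 200)))
  expect_equal(n_intervals(merge_intervals(be, 0)), 1)
  # boundary: gap 12500 merges at -d 12500, gap 12501 does not
  g1 <- set_from_df(data.frame(chrom = "chr1", start = c(0, 12600),
                               end = c(100, 12700)))
  g2 <- set_from_df(data.frame(chrom = "chr1", start = c(0, 12601),
                               end = c(100, 12700)))
  expect_equal(n_intervals(merge_intervals(g1, 12500)), 1)
  expect_equal(n_intervals(merge_intervals(g2, 12500)), 2)
  expect_error(merge_intervals(g1, -1), "non-negative")
})

test_that("merge is idempotent and conserves base coverage", {
  set.seed(42)
  for (rep in 1:20) {
    df <- random_intervals(40)
    s <- set_from_df(df)
    for (gap in c(0, 500, 12500)) {
      m1 <- merge_intervals(s, gap)
      m2 <- merge_intervals(m1, gap)
      expect_equal(as.data.frame(m1), as.data.frame(m2))
    }
    expect_equal(covered_bases(merge_intervals(s, 0)),
                 sum(mask_of(df, "chr1", 100000)))
  }
})

test_that("merge/intersect/filter agree with per-base oracles", {
  set.seed(7)
  for (rep in 1:40) {
    a_df <- random_intervals(30)
    b_df <- random_intervals(30)
    gap <- sample(c(0, 100, 5000, 12500), 1)
    got <- as.data.frame(merge_intervals(set_from_df(a_df), gap))
    exp <- oracle_merge(a_df, gap)
    expect_equal(got[c("chrom", "start", "end")], exp,
                 ignore_attr = TRUE)

    a <- canonicalize(set_from_df(a_df))
    b <- canonicalize(set_from_df(b_df))
    got_i <- as.data.frame(intersect_regions(a, b))
    exp_i <- oracle_intersect(as.data.frame(a), as.data.frame(b))
    expect_equal(got_i[c("chrom", "start", "end")], exp_i,
                 ignore_attr = TRUE)

    min_bp <- sample(c(1, 50, 500), 1)
    got_f <- as.data.frame(filter_overlapping(a, b, min_bp))
    exp_f <- oracle_filter(as.data.frame(a), as.data.frame(b), min_bp)
    expect_equal(got_f[c("chrom", "start", "end")],
                 exp_f[c("chrom", "start", "end")], ignore_attr = TRUE)
  }
})

test_that("filter_overlapping honors chromosome identity and min overlap", {
  q <- canonicalize(interval_set("chr1", 0, 100))
  s1 <- canonicalize(interval_set("chr1", 99, 200))
  s2 <- canonicalize(interval_set("chr2", 0, 1000))
  expect_equal(n_intervals(filter_overlapping(q, s1)), 1)  # 1 bp overlap
  expect_equal(n_intervals(filter_overlapping(q, s1, 2)), 0)
  expect_equal(n_intervals(filter_overlapping(q, s2)), 0)
  expect_error(filter_overlapping(q, s1, 0), "min_overlap_bp")
})

test_that("consensus matches enumeration oracle and edge cases", {
  one <- canonicalize(interval_set("chr1", 1000, 2000))
  three <- list(one, one, one)
  expect_equal(n_intervals(consensus_intervals(three, 3)), 1)
  # interval in 2 of 3 sets
  other <- canonicalize(interval_set("chr1", 5000, 6000))
  sets <- list(one, one, other)
  expect_equal(n_intervals(consensus_intervals(sets, 3)), 0)
  expect_equal(n_intervals(consensus_intervals(sets, 2)), 1)
  expect_error(consensus_intervals(sets, 4), "min_samples")
  expect_error(consensus_intervals(sets, 0), "min_samples")

  set.seed(11)
  for (rep in 1:20) {
    dfs <- lapply(1:3, function(i) random_intervals(15))
    csets <- lapply(dfs, function(d) canonicalize(set_from_df(d)))
    cdfs <- lapply(csets, as.data.frame)
    for (ms in 1:3) {
      got <- as.data.frame(consensus_intervals(csets, ms))
      exp <- oracle_consensus(cdfs, ms)
      expect_equal(got[c("chrom", "start", "end")], exp,
                   ignore_attr = TRUE)
    }
    # min_samples = 1 equals pooled merge
    pooled <- merge_intervals(set_from_df(do.call(rbind, dfs)), 0)
    expect_equal(as.data.frame(consensus_intervals(csets, 1)),
                 as.data.frame(pooled))
  }
})

test_that("overlap_report computes fractions and rejects empty query", {
  q <- canonicalize(interval_set("chr1", c(0, 1000, 2000, 3000) * 10,
                                 c(0, 1000, 2000, 3000) * 10 + 100))
  s <- canonicalize(interval_set("chr1", c(0, 10000, 20000),
                                 c(50, 10050, 20050)))
  r <- overlap_report(q, s)
  expect_equal(r$fraction, 0.75)
  expect_equal(r$n_overlapping, 3)
  # subject superset -> 1.0
  all_s <- canonicalize(interval_set("chr1", 0, 1e6))
  expect_equal(overlap_report(q, all_s)$fraction, 1.0)
  empty <- interval_set(character(), numeric(), numeric(),
                        canonical = TRUE)
  expect_error(overlap_report(empty, s), "empty")
})

test_that("canonical preconditions are enforced", {
  raw <- interval_set("chr1", c(0, 50), c(100, 200))
  can <- canonicalize(raw)
  expect_error(intersect_regions(raw, can), "canonical")
  expect_error(filter_overlapping(can, raw), "canonical")
  expect_true(canonicalize(raw)$canonical)
})
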