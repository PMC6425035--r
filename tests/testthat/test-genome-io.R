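test_that("read_bed parses 0-based half-open intervals and validates input", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000", "chr1\t500\t600", "chr2\t10\t20"), path)
  gr <- read_bed(path)
  expect_equal(length(gr), 3)
  expect_equal(GenomicRanges::start(gr), c(1, 501, 11))
  expect_equal(GenomicRanges::end(gr), c(1000, 600, 20))

  writeLines(character(0), path)
  expect_equal(length(read_bed(path)), 0)

  writeLines("chr1\t500\t100", path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\t0\t10", "chr1\tx\t20"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\t5", path)
  expect_error(read_bed(path), "fewer than 3")
})

test_that("BED3 write/read round-trips byte-identically", {
  path <- withr::local_tempfile(fileext = ".bed")
  lines <- c("chr1\t0\t1000", "chr1\t2500\t4000", "chr2\t999\t123456")
  writeLines(lines, path)
  gr <- read_bed(path)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, out)
  expect_identical(readLines(out), lines)
})

test_that("read_bed keeps BED6 names and strands", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tfoo\t0\t+", "chr1\t200\t300\tbar\t0\t-"), path)
  gr <- read_bed(path)
  expect_equal(S4Vectors::mcols(gr)$name, c("foo", "bar"))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
})

test_that("make_bins tiles chromosomes exactly", {
  g <- genome_description("chrA", 10000)
  bins <- make_bins(g, 1000)
  expect_equal(length(bins), 10)
  expect_true(all(GenomicRanges::width(bins) == 1000))

  g2 <- genome_description("chrA", 10500)
  bins2 <- make_bins(g2, 1000)
  expect_equal(length(bins2), 11)
  last <- bins2[11]
  expect_equal(GenomicRanges::start(last) - 1, 10000)
  expect_equal(GenomicRanges::end(last), 10500)

  g3 <- genome_description(c("c1", "c2", "c3"), rep(1e6, 3))
  expect_equal(length(make_bins(g3, 1000)), 3000)
  expect_error(make_bins(g, 0), "width")
})

test_that("promoters are 5 kb TSS-centered, clipped and deduplicated", {
  g <- genome_description("chr1", 2e5)
  tx <- data.frame(chrom = "chr1", tss = c(100000, 1000, 100000))
  pr <- make_promoters(tx, genome = g)
  expect_equal(length(pr), 2)  # duplicate TSS collapsed
  df <- granges_to_df(pr)
  expect_equal(df$start[df$start > 0], 97500)
  expect_equal(df$end[df$start > 0], 102500)
  expect_equal(df$end[df$start > 0] - df$start[df$start > 0], 5000)
  # clipping at chromosome start
  expect_true(any(df$start == 0 & df$end == 3500))
})

test_that("genic regions take the longest transcript span, ties to lower start", {
  tx <- data.frame(gene = c("A", "A", "B", "C", "C"),
                   chrom = "chr1",
                   tss = c(1000, 2000, 5000, 9000, 7000),
                   tes = c(6000, 14000, 8000, 11000, 9000))
  gr <- make_genic_regions(tx)
  df <- granges_to_df(gr)
  df$name <- S4Vectors::mcols(gr)$name
  expect_equal(df$start[df$name == "A"], 2000)   # 12 kb beats 5 kb
  expect_equal(df$end[df$name == "A"], 14000)
  expect_equal(df$start[df$name == "B"], 5000)   # single transcript
  # C: two 2 kb spans tie; lower start wins
  expect_equal(df$start[df$name == "C"], 7000)
  expect_equal(df$end[df$name == "C"], 9000)
})

test_that("refGene reader orients the TSS by strand", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gA\ttx1\tchr1\t+\t1000\t5000",
               "gB\ttx2\tchr1\t-\t2000\t8000"), path)
  tx <- read_refgene(path)
  expect_equal(tx$tss, c(1000, 8000))
  expect_equal(tx$tes, c(5000, 2000))
})

test_that("tag counting follows half-open point semantics and conserves totals", {
  g <- genome_description("chrA", 100)
  tc <- make_tag_collection(list(chrA = c(5, 15, 25)), g)
  iv <- df_to_granges(data.frame(chrom = "chrA", start = 0, end = 20))
  expect_equal(count_tags_in_intervals(tc, iv), 2)

  set.seed(42)
  g2 <- genome_description(c("c1", "c2"), c(5e4, 3e4))
  tags <- random_tags(g2, 5000)
  tc2 <- make_tag_collection(tags, g2)
  bins <- make_bins(g2, 1000)
  counts <- count_tags_in_intervals(tc2, bins)
  expect_equal(sum(counts), tc2$n_target)
})

test_that("tag counting matches a naive double-loop oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- genome_description(c("c1", "c2", "c3"), c(1e5, 5e4, 2e4))
    tags <- random_tags(g, 10000)
    tc <- make_tag_collection(tags, g)
    iv <- random_intervals_df(g, 500, max_width = 5000)
    got <- count_tags_in_intervals(tc, df_to_granges(iv))
    expect_equal(got, oracle_count_tags(tc$tags, iv))
  }
})

test_that("tag collections validate chromosome bounds", {
  g <- genome_description("chrA", 100)
  expect_error(make_tag_collection(list(chrA = c(5, 100)), g), "bounds")
  expect_error(make_tag_collection(list(chrA = -1), g), "bounds")
  expect_error(make_tag_collection(list(chrZ = 5), g), "unknown chromosome")
})

test_that("blacklist filtering removes any-overlap intervals only", {
  iv <- df_to_granges(data.frame(chrom = c("c1", "c1"),
                                 start = c(0, 0), end = c(100, 100)))
  bl1 <- df_to_granges(data.frame(chrom = "c1", start = 50, end = 60))
  expect_equal(length(filter_blacklist(iv[1], bl1)), 0)
  # half-open: blacklist starting exactly at the interval end does not touch
  bl2 <- df_to_granges(data.frame(chrom = "c1", start = 100, end = 200))
  expect_equal(length(filter_blacklist(iv[1], bl2)), 1)

  for (seed in 1:5) {
    set.seed(100 + seed)
    g <- genome_description(c("c1", "c2"), c(1e5, 1e5))
    iv_df <- random_intervals_df(g, 1000, max_width = 2000)
    bl_df <- random_intervals_df(g, 50, max_width = 5000)
    kept <- filter_blacklist(df_to_granges(iv_df), df_to_granges(bl_df))
    expect_equal(length(kept), sum(oracle_blacklist_keep(iv_df, bl_df)))
  }
})

test_that("tags round-trip through BED files with spike totals intact", {
  g <- genome_description(c("c1", "c2"), c(1e4, 1e4))
  set.seed(1)
  tc <- make_tag_collection(random_tags(g, 500), g, n_spike = 42)
  path <- withr::local_tempfile(fileext = ".bed")
  write_tags_bed(tc, path)
  back <- read_tags_bed(path, g, n_spike = 42)
  expect_equal(back$n_target, tc$n_target)
  expect_equal(back$n_spike, 42)
  expect_equal(back$tags, tc$tags[names(back$tags)])
})
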