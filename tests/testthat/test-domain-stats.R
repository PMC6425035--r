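test_that("top-percent score averages the most enriched bins", {
  g <- genome_description("c1", 1e5)
  bins <- make_bins(g, 1000)
  # differences 1..100 after RPKM: counts chosen so chip - input is linear
  chip <- bin_track(bins, 1:100, total_reads = 1e6)
  input <- bin_track(bins, rep(0, 100), total_reads = 1e6)
  # RPKM multiplies counts by 1/(1 * 1e6/1e6) = 1, so diffs are 1..100
  expect_equal(top_percent_score(chip, input, pct = 1), 100)
  expect_equal(top_percent_score(chip, input, pct = 10), mean(91:100))
  # constant difference returns that constant
  flat <- bin_track(bins, rep(7, 100), total_reads = 1e6)
  expect_equal(top_percent_score(flat, input), 7)
})

test_that("top-percent score matches a full-sort oracle on random tracks", {
  g <- genome_description("c1", 1e7)
  bins <- make_bins(g, 1000)
  for (seed in 1:5) {
    set.seed(seed)
    chip <- bin_track(bins, rpois(1e4, 10), total_reads = 1e5)
    input <- bin_track(bins, rpois(1e4, 8), total_reads = 9e4)
    diffs <- rpkm(chip)$values - rpkm(input)$values
    expect_equal(top_percent_score(chip, input), oracle_top_percent(diffs))
  }
})

test_that("read proportions in features hit the boundary cases and the oracle", {
  g <- genome_description(c("c1", "c2"), c(1e5, 1e5))
  set.seed(7)
  tc <- make_tag_collection(random_tags(g, 2000), g)
  whole <- df_to_granges(data.frame(chrom = c("c1", "c2"), start = 0,
                                    end = 1e5))
  expect_equal(proportion_in_features(tc, whole), 1)
  expect_equal(proportion_in_features(tc, GenomicRanges::GRanges()), 0)
  for (seed in 1:5) {
    set.seed(200 + seed)
    feats <- random_intervals_df(g, 50, max_width = 2e4)
    got <- proportion_in_features(tc, df_to_granges(feats))
    # brute force: a tag counts once if any feature contains it
    expect_equal(got, {
      n_in <- 0
      for (ch in names(tc$tags)) {
        p <- tc$tags[[ch]]
        hit <- rep(FALSE, length(p))
        sel <- feats$chrom == ch
        for (i in which(sel)) hit <- hit | (p >= feats$start[i] & p < feats$end[i])
        n_in <- n_in + sum(hit)
      }
      n_in / tc$n_target
    })
  }
})

test_that("difference-plot coordinates follow the processed-count formulas", {
  g <- genome_description("c1", 5e4)
  regions <- make_bins(g, 1e4)  # 5 disjoint regions
  # WT processed counts exactly 4x input in both replicates -> x = 2
  wt <- rep(39, 5); inp <- rep(9, 5)  # (39+1)/T over (9+1)/T = 4
  k27m <- rep(39, 5)
  rec <- diff_plot_coordinates(regions, k27m, 100, list(wt, wt), c(100, 100),
                               list(inp, inp), c(100, 100))
  expect_equal(rec$x, rep(2, 5))
  expect_equal(rec$y, rep(0, 5))  # K27M equals the geometric mean of WTs

  # single-sample form equals the direct log2-ratio oracle
  for (seed in 1:5) {
    set.seed(300 + seed)
    k <- rpois(5, 50); w <- rpois(5, 40); i <- rpois(5, 30)
    tk <- 1e5; tw <- 8e4; ti <- 6e4; rxk <- 1.3; rxw <- 0.8
    rec1 <- diff_plot_coordinates(regions, k, tk, list(w), tw, list(i), ti,
                                  rx_k27m = rxk, rx_wt = rxw)
    px_k <- rxk * (k + 1) / tk; px_w <- rxw * (w + 1) / tw
    px_i <- (i + 1) / ti
    expect_equal(rec1$x, log2(px_w / px_i))
    expect_equal(rec1$y, log2(px_k / px_w))
  }
  expect_error(diff_plot_coordinates(regions, 1:4, 10, list(1:5), 10,
                                     list(1:5), 10), "region")
})

test_that("categorization applies the published thresholds in fixed order", {
  th <- category_thresholds("BT245-CGI")
  pts <- data.frame(x = c(2, 2, -4, 0, 2, 0),
                    y = c(0.5, -1.5, -1, -5, -5, -0.5))
  got <- as.character(categorize(pts, th)$category)
  expect_equal(got, c("Gained", "Retained", "Absent", "Lost", "Lost",
                      "Unclassified"))

  # DIPGXIII Gained and Retained bounds overlap; Gained wins by order
  th2 <- category_thresholds("DIPGXIII-CGI")
  both <- data.frame(x = 1, y = 3)  # y > 2.6 and (y > -2, x > 0.5)
  expect_equal(as.character(categorize(both, th2)$category), "Gained")

  th3 <- category_thresholds("BT245-promoter")
  expect_equal(as.character(categorize(data.frame(x = -3, y = -0.1),
                                       th3)$category), "Absent")
  expect_equal(as.character(categorize(data.frame(x = 0.5, y = -0.1),
                                       th3)$category), "Retained")
})

test_that("the four BT245 CGI category regions are pairwise disjoint", {
  th <- category_thresholds("BT245-CGI")
  grid <- expand.grid(x = seq(-8, 8, by = 0.25), y = seq(-8, 8, by = 0.25))
  hits <- vapply(c("Gained", "Absent", "Lost", "Retained"), function(cc)
    rxdomains:::category_matches(th$bounds[[cc]], grid$x, grid$y),
    logical(nrow(grid)))
  expect_lte(max(rowSums(hits)), 1)
})

test_that("spread windows partition ranked bins into near-equal groups", {
  g <- genome_description("c1", 2e6)
  bins <- make_bins(g, 1000)
  set.seed(11)
  mk <- function(v) bin_track(bins, v, total_reads = 1)
  v <- rnorm(2000)
  sw <- spread_correlation(mk(v), mk(v), mk(rnorm(2000)), n_windows = 1000)
  expect_equal(nrow(sw), 1000)
  expect_true(all(sw$n_bins == 2))
  # identical tracks give identical window means
  expect_equal(sw$mean_k27m_me2, sw$mean_wt_me3)
  # ranking track means are monotone non-increasing
  expect_true(all(diff(sw$mean_k27m_me2) <= 0))

  # uneven split: sizes differ by at most one and conserve the bin count
  g2 <- genome_description("c1", 10007 * 500)
  bins2 <- make_bins(g2, 500)
  v2 <- rnorm(10007)
  mk2 <- function(v) bin_track(bins2, v, total_reads = 1)
  sw2 <- spread_correlation(mk2(v2), mk2(v2), mk2(v2), n_windows = 1000)
  expect_equal(sum(sw2$n_bins), 10007)
  expect_lte(diff(range(sw2$n_bins)), 1)
  expect_error(spread_correlation(mk(v), mk(v), mk(v), n_windows = 3000),
               "fewer bins")
})

test_that("aggregate profiles average signal at offsets from anchor midpoints", {
  g <- genome_description("c1", 1e5)
  bins <- make_bins(g, 500)
  vals <- rep(1, length(bins))
  peak_bins <- 41:60  # positions 20000-30000
  vals[peak_bins] <- 10
  tr <- bin_track(bins, vals, total_reads = 1)
  anchor <- df_to_granges(data.frame(chrom = "c1", start = 24000,
                                     end = 26000))  # midpoint 25000
  prof <- aggregate_profile(tr, anchor, flank = 10000, bin = 500)
  expect_equal(nrow(prof), 40)
  # single anchor: profile equals the signal slice around the midpoint
  expect_equal(prof$mean_signal[prof$offset == 250], 10)
  expect_equal(prof$mean_signal[prof$offset == -9750], 1)
  expect_equal(max(prof$mean_signal), 10)
  # flat track gives a flat profile
  flat <- bin_track(bins, rep(3, length(bins)), total_reads = 1)
  pf <- aggregate_profile(flat, anchor, flank = 5000, bin = 500)
  expect_true(all(pf$mean_signal == 3))
  expect_error(aggregate_profile(tr, GenomicRanges::GRanges(), 5000),
               "empty")
  expect_error(aggregate_profile(tr, anchor, flank = 5300, bin = 500),
               "multiple")
})

test_that("aggregate profiles peak at focal anchors on simulated data", {
  cfg <- small_config(21, peak_width = 4000)
  ann <- simulate_annotations(cfg)
  tc <- simulate_chip_sample(cfg, "K27M", "me3", ann)
  inp <- simulate_chip_sample(cfg, "K27M", "input", ann)
  bins <- make_bins(cfg$genome, 500)
  tr <- input_normalize(count_track(tc, bins), count_track(inp, bins))
  prof <- aggregate_profile(tr, ann$suz12_peaks, flank = 2e4, bin = 500)
  peak_val <- prof$mean_signal[abs(prof$offset) == 250]
  far_val <- prof$mean_signal[abs(prof$offset) > 1.5e4]
  expect_gt(min(peak_val), max(far_val))
  # signal decays within ~peak_width of the center
  expect_gt(mean(prof$mean_signal[abs(prof$offset) < 2000]),
            mean(prof$mean_signal[abs(prof$offset) > 8000]) + 1)
})

test_that("signal matrices cluster regions by k-means with a fixed seed", {
  g <- genome_description("c1", 2e5)
  bins <- make_bins(g, 500)
  vals <- rep(0, length(bins))
  # regions of two well-separated signal classes
  centers <- seq(2e4, 1.8e5, by = 2e4)
  high <- centers[c(1, 3, 5, 7, 9)]
  for (ctr in high) vals[(ctr %/% 500) + (-3:3)] <- 50
  tr <- bin_track(bins, vals, total_reads = 1)
  regions <- df_to_granges(data.frame(chrom = "c1", start = centers - 1000,
                                      end = centers + 1000))
  S4Vectors::mcols(regions)$name <- paste0("r", seq_along(centers))

  res <- signal_matrix_kmeans(tr, regions, flank = 5000, k = 2, seed = 42)
  expect_equal(dim(res$matrix), c(9, 20))
  cl_high <- unique(res$cluster[centers %in% high])
  cl_low <- unique(res$cluster[!centers %in% high])
  expect_equal(length(cl_high), 1)
  expect_equal(length(cl_low), 1)
  expect_false(cl_high == cl_low)
  # determinism under the seed
  res2 <- signal_matrix_kmeans(tr, regions, flank = 5000, k = 2, seed = 42)
  expect_identical(res$cluster, res2$cluster)

  one <- signal_matrix_kmeans(tr, regions, flank = 5000, k = 1)
  expect_true(all(one$cluster == 1))
  expect_lte(length(unique(res$cluster)), 2)
  expect_error(signal_matrix_kmeans(tr, regions, flank = 5000, k = 10),
               "more clusters")
})
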