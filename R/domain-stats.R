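## ---------------------------------------------------------------------------
## Focality and redistribution statistics
##
## The quantitative readouts distinguishing a focal (peaky) from a spread
## mark distribution: top-percentile bin scores, read proportions in
## feature sets, difference-plot coordinates and categories for CGIs and
## promoters, spread-correlation windows, anchor-centered aggregate
## profiles, and clustered region-by-offset signal matrices.
## ---------------------------------------------------------------------------

#' Mean input-subtracted RPKM of the most enriched bins
#'
#' Per-bin RPKM difference (ChIP - input) is sorted descending and the mean
#' of the top `ceil(pct/100 * N)` bins returned. High values indicate a
#' focal distribution concentrating reads in few bins; spread marks score
#' low because no bin stands far above the genome average. Computed on 1-kb
#' bins in the standard analysis.
#'
#' @param chip,input `BinTrack`s of raw counts on the same partition.
#' @param pct Percentage of bins to average (default 1).
#' @return Scalar score.
#' @export
top_percent_score <- function(chip, input, pct = 1.0) {
  check_same_partition(chip, input)
  if (length(chip$values) == 0) stop("empty track")
  d <- rpkm(chip)$values - rpkm(input)$values
  n_top <- ceiling(pct / 100 * length(d))
  ord <- order(d, decreasing = TRUE, method = "radix")
  mean(d[ord[seq_len(n_top)]])
}

#' Proportion of reads falling in a feature set
#'
#' Features are merged (union) before counting so overlapping features do
#' not double-count reads.
#'
#' @param tags A `TagCollection`.
#' @param features GRanges of features (e.g. SUZ12 peaks, CGIs, promoters).
#' @return Fraction of `n_target` reads inside the feature union, in
#'   \[0, 1\].
#' @export
proportion_in_features <- function(tags, features) {
  if (tags$n_target == 0) stop("tag collection has no target reads")
  if (length(features) == 0) return(0)
  merged <- reduce(features, ignore.strand = TRUE)
  sum(count_tags_in_intervals(tags, merged)) / tags$n_target
}

## ---------------------------------------------------------------------------
## Difference plots: per-region (x, y) coordinates and categories
## ---------------------------------------------------------------------------

#' Difference-plot coordinates for CGIs or promoters
#'
#' Processed counts are (raw region count + pseudocount) / library total,
#' multiplied by the sample's ChIP-Rx ratio for ChIP samples only. With one
#' WT sample, x = log2(WT/INPUT) and y = log2(K27M/WT); with two WT
#' replicates both terms average the replicates:
#' x = (log2(WT1/INPUT1) + log2(WT2/INPUT2)) / 2,
#' y = log2(K27M) - (log2(WT1) + log2(WT2)) / 2.
#'
#' @param regions GRanges of regions (already blacklist-filtered; see
#'   [filter_blacklist()]).
#' @param counts_k27m Raw counts per region in the K27M ChIP sample.
#' @param total_k27m Library total of the K27M sample.
#' @param counts_wt List of one or two raw count vectors (WT replicates).
#' @param totals_wt Numeric vector of WT library totals, parallel to
#'   `counts_wt`.
#' @param counts_input List of input count vectors, parallel to
#'   `counts_wt`.
#' @param totals_input Input library totals, parallel to `counts_input`.
#' @param rx_k27m,rx_wt ChIP-Rx ratios (`rx_wt` parallel to `counts_wt`).
#' @param cfg `NormalizationConfig` supplying the pseudocount.
#' @return data.frame with columns `name` (from `regions` when present),
#'   `x`, `y`, and `dna_methylation` when the regions carry it.
#' @export
diff_plot_coordinates <- function(regions, counts_k27m, total_k27m,
                                  counts_wt, totals_wt,
                                  counts_input, totals_input,
                                  rx_k27m = 1, rx_wt = rep(1, length(counts_wt)),
                                  cfg = norm_config()) {
  if (!is.list(counts_wt)) counts_wt <- list(counts_wt)
  if (!is.list(counts_input)) counts_input <- list(counts_input)
  n_wt <- length(counts_wt)
  if (n_wt < 1 || n_wt > 2) stop("one or two WT samples required")
  if (length(counts_input) != n_wt || length(totals_wt) != n_wt ||
      length(totals_input) != n_wt || length(rx_wt) != n_wt)
    stop("WT and input sample lists must be parallel")
  n <- length(regions)
  lens <- c(length(counts_k27m), lengths(counts_wt), lengths(counts_input))
  if (any(lens != n)) stop("count vectors do not match the region list")
  c0 <- cfg$pseudocount
  p_k27m <- rx_k27m * (counts_k27m + c0) / total_k27m
  p_wt <- lapply(seq_len(n_wt), function(i)
    rx_wt[i] * (counts_wt[[i]] + c0) / totals_wt[i])
  p_in <- lapply(seq_len(n_wt), function(i)
    (counts_input[[i]] + c0) / totals_input[i])
  x <- Reduce(`+`, lapply(seq_len(n_wt), function(i)
    log2(p_wt[[i]] / p_in[[i]]))) / n_wt
  y <- log2(p_k27m) - Reduce(`+`, lapply(p_wt, log2)) / n_wt
  out <- data.frame(x = x, y = y)
  if (!is.null(mcols(regions)$name)) out <- cbind(name = mcols(regions)$name, out)
  if (!is.null(mcols(regions)$dna_methylation))
    out$dna_methylation <- mcols(regions)$dna_methylation
  out
}

#' Category threshold presets for the difference plot
#'
#' Each category is a conjunction of half-plane bounds on (x, y). Presets
#' carry the published bounds for the BT245 and DIPGXIII CGI plots and the
#' BT245 promoter plot:
#' \itemize{
#'   \item `BT245-CGI`: Gained y > 0; Absent y < 0 & x < -3.75;
#'     Lost y < -4 & x > -2.5; Retained -3 < y < 0 & x > 1.25.
#'   \item `DIPGXIII-CGI`: Gained y > 2.6; Absent y < 2.5 & x < -5;
#'     Lost y < -2.5 & x > -2.5; Retained y > -2 & x > 0.5.
#'   \item `BT245-promoter`: Gained y > 0; Absent y < 0 & x < -2.5;
#'     Lost y < -4 & x > -2.5; Retained -3 < y < 0 & x > 0.
#' }
#'
#' @param preset Preset name, or `NULL` to supply `bounds` directly.
#' @param bounds Named list of per-category bound lists, each with any of
#'   `x_gt`, `x_lt`, `y_gt`, `y_lt` (strict inequalities).
#' @return List of class `CategoryThresholds`.
#' @export
category_thresholds <- function(preset = c("BT245-CGI", "DIPGXIII-CGI",
                                           "BT245-promoter"),
                                bounds = NULL) {
  if (is.null(bounds)) {
    preset <- match.arg(preset)
    bounds <- switch(preset,
      "BT245-CGI" = list(
        Gained   = list(y_gt = 0),
        Absent   = list(y_lt = 0, x_lt = -3.75),
        Lost     = list(y_lt = -4, x_gt = -2.5),
        Retained = list(y_gt = -3, y_lt = 0, x_gt = 1.25)),
      "DIPGXIII-CGI" = list(
        Gained   = list(y_gt = 2.6),
        Absent   = list(y_lt = 2.5, x_lt = -5),
        Lost     = list(y_lt = -2.5, x_gt = -2.5),
        Retained = list(y_gt = -2, x_gt = 0.5)),
      "BT245-promoter" = list(
        Gained   = list(y_gt = 0),
        Absent   = list(y_lt = 0, x_lt = -2.5),
        Lost     = list(y_lt = -4, x_gt = -2.5),
        Retained = list(y_gt = -3, y_lt = 0, x_gt = 0)))
  } else {
    preset <- "custom"
  }
  need <- c("Gained", "Absent", "Lost", "Retained")
  if (!all(need %in% names(bounds)))
    stop("bounds must define Gained, Absent, Lost and Retained")
  structure(list(preset = preset, bounds = bounds[need]),
            class = "CategoryThresholds")
}

category_matches <- function(b, x, y) {
  ok <- rep(TRUE, length(x))
  if (!is.null(b$x_gt)) ok <- ok & x > b$x_gt
  if (!is.null(b$x_lt)) ok <- ok & x < b$x_lt
  if (!is.null(b$y_gt)) ok <- ok & y > b$y_gt
  if (!is.null(b$y_lt)) ok <- ok & y < b$y_lt
  ok
}

#' Assign difference-plot categories
#'
#' Categories are evaluated in the fixed order Gained, Absent, Lost,
#' Retained with first match winning (the published DIPGXIII Gained and
#' Retained bounds overlap, so an evaluation order is required); points
#' matching no category are labelled `Unclassified` — the published
#' thresholds are deliberately not exhaustive.
#'
#' @param records data.frame with columns `x` and `y` (see
#'   [diff_plot_coordinates()]).
#' @param thresholds A `CategoryThresholds`.
#' @return `records` with a `category` factor column (levels Gained,
#'   Absent, Lost, Retained, Unclassified).
#' @export
categorize <- function(records, thresholds = category_thresholds()) {
  stopifnot(inherits(thresholds, "CategoryThresholds"))
  cats <- c("Gained", "Absent", "Lost", "Retained")
  ## first-match-wins: walk in order, keep earliest assignment
  lab <- rep(NA_character_, nrow(records))
  for (cat in cats) {
    ok <- category_matches(thresholds$bounds[[cat]], records$x, records$y)
    lab[is.na(lab) & ok] <- cat
  }
  lab[is.na(lab)] <- "Unclassified"
  records$category <- factor(lab, levels = c(cats, "Unclassified"))
  records
}

## ---------------------------------------------------------------------------
## Spread-correlation windows
## ---------------------------------------------------------------------------

#' Windowed correlation structure of me2/me3 redistribution
#'
#' 1-kb bins are ranked by input-normalized H3K27me2 enrichment in the K27M
#' state (descending) and grouped into `n_windows` contiguous rank groups of
#' near-equal size (sizes differ by at most one, larger windows first); the
#' per-window means of all three tracks are returned. A stronger
#' across-window correlation of K27M-me2 with WT-me3 than with WT-me2 is
#' the signature of me2 spreading into the former me3 footprint.
#'
#' @param me2_k27m,me3_wt,me2_wt Input-normalized `BinTrack`s on one
#'   partition.
#' @param n_windows Number of rank windows (default 1000).
#' @return data.frame with columns rank, n_bins, mean_k27m_me2,
#'   mean_wt_me3, mean_wt_me2.
#' @export
spread_correlation <- function(me2_k27m, me3_wt, me2_wt, n_windows = 1000) {
  check_same_partition(me2_k27m, me3_wt)
  check_same_partition(me2_k27m, me2_wt)
  n <- length(me2_k27m$values)
  if (n < n_windows) stop("fewer bins than windows")
  ord <- order(me2_k27m$values, decreasing = TRUE, method = "radix")
  base <- n %/% n_windows
  extra <- n %% n_windows
  sizes <- rep(base, n_windows) + rep(c(1L, 0L), c(extra, n_windows - extra))
  win <- rep(seq_len(n_windows), sizes)
  mean_by <- function(v) as.numeric(tapply(v[ord], win, mean))
  data.frame(rank = seq_len(n_windows), n_bins = sizes,
             mean_k27m_me2 = mean_by(me2_k27m$values),
             mean_wt_me3 = mean_by(me3_wt$values),
             mean_wt_me2 = mean_by(me2_wt$values))
}

## ---------------------------------------------------------------------------
## Aggregate profiles and clustered signal matrices
## ---------------------------------------------------------------------------

## signal value at arbitrary positions: value of the covering track bin,
## NA outside the partition. Positions are 0-based bp.
track_value_at <- function(track, chrom, pos) {
  q <- GRanges(chrom, IRanges(pos + 1, pos + 1))
  hits <- findOverlaps(q, track$bins, ignore.strand = TRUE)
  v <- rep(NA_real_, length(q))
  v[queryHits(hits)] <- track$values[subjectHits(hits)]
  v
}

profile_offsets <- function(flank, bin) {
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  seq(-flank, flank - bin, by = bin) + bin / 2
}

#' Anchor-centered aggregate profile
#'
#' For each offset bin in \[-flank, +flank) the signal is averaged over
#' anchors at anchor midpoint + offset, with missing values discarded from
#' the mean. Used with SUZ12 peak centers (+/- 50 kb) or PMD regions (+/-
#' 100 kb, with `scale_body` rescaling each region body to a fixed number
#' of bins while flanks stay absolute).
#'
#' @param track A `BinTrack` of (normalized) values.
#' @param anchors GRanges of anchor regions; profiles center on midpoints.
#' @param flank Flank in bp on each side; must be a multiple of `bin`.
#' @param bin Offset bin width in bp (default 500).
#' @param scale_body If `TRUE`, the region body is rescaled to `body_bins`
#'   bins between the flanks instead of centering on the midpoint.
#' @param body_bins Number of body bins when `scale_body = TRUE`.
#' @return data.frame with columns `offset` (bp from midpoint, or bin index
#'   for scaled bodies), `mean_signal`, `n` (anchors contributing).
#' @export
aggregate_profile <- function(track, anchors, flank, bin = 500,
                              scale_body = FALSE, body_bins = 100) {
  if (length(anchors) == 0) stop("anchor list is empty")
  chrom <- as.character(seqnames(anchors))
  if (!scale_body) {
    offs <- profile_offsets(flank, bin)
    mid <- floor((start(anchors) - 1 + end(anchors)) / 2)
    vals <- vapply(offs, function(o)
      track_value_at(track, chrom, mid + o), numeric(length(anchors)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(anchors))
    data.frame(offset = offs,
               mean_signal = colMeans(vals, na.rm = TRUE),
               n = colSums(!is.na(vals)))
  } else {
    n_fl <- flank / bin
    idx <- seq_len(2 * n_fl + body_bins)
    vals <- t(vapply(seq_along(anchors), function(i) {
      s0 <- start(anchors)[i] - 1; e0 <- end(anchors)[i]
      left <- s0 - flank + (seq_len(n_fl) - 1) * bin + bin / 2
      body <- s0 + (seq_len(body_bins) - 0.5) / body_bins * (e0 - s0)
      right <- e0 + (seq_len(n_fl) - 1) * bin + bin / 2
      track_value_at(track, rep(chrom[i], 2 * n_fl + body_bins),
                     floor(c(left, body, right)))
    }, numeric(2 * n_fl + body_bins)))
    data.frame(offset = idx,
               mean_signal = colMeans(vals, na.rm = TRUE),
               n = colSums(!is.na(vals)))
  }
}

#' Region-by-offset signal matrix with k-means row clustering
#'
#' Builds a matrix of normalized signal around region midpoints (one row
#' per region, one column per offset bin per track; several tracks are
#' concatenated column-wise), imputes missing values as 0, clusters rows by
#' standard k-means (fixed seed, 10 restarts) and orders rows by cluster
#' then decreasing mean signal.
#'
#' @param tracks A `BinTrack` or list of them.
#' @param regions GRanges of regions (e.g. CGIs).
#' @param flank Flank in bp each side of the midpoint.
#' @param bin Offset bin width in bp (default 500).
#' @param k Number of clusters (default 3).
#' @param seed RNG seed for the clustering.
#' @return List with `matrix` (rows named by region name when available),
#'   `cluster` (integer labels parallel to `regions`), and `order` (row
#'   permutation: cluster, then decreasing row mean).
#' @export
signal_matrix_kmeans <- function(tracks, regions, flank, bin = 500, k = 3,
                                 seed = 1) {
  if (inherits(tracks, "BinTrack")) tracks <- list(tracks)
  if (k < 1) stop("k must be >= 1")
  if (k > length(regions)) stop("more clusters than regions")
  chrom <- as.character(seqnames(regions))
  mid <- floor((start(regions) - 1 + end(regions)) / 2)
  offs <- profile_offsets(flank, bin)
  mat <- do.call(cbind, lapply(tracks, function(tr)
    vapply(offs, function(o) track_value_at(tr, chrom, mid + o),
           numeric(length(regions)))))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(regions))
  mat[is.na(mat)] <- 0
  if (!is.null(mcols(regions)$name)) rownames(mat) <- mcols(regions)$name
  set.seed(seed)
  cl <- if (k == 1) rep(1L, nrow(mat))
        else kmeans(mat, centers = k, nstart = 10, iter.max = 50)$cluster
  ord <- order(cl, -rowMeans(mat), method = "radix")
  list(matrix = mat, cluster = as.integer(cl), order = ord)
}
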