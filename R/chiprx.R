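## ---------------------------------------------------------------------------
## ChIP-Rx quantification and track normalization
##
## All formulas operate on BinTrack objects: per-bin counts (or normalized
## values) over a fixed genome partition, plus the library total.
## ---------------------------------------------------------------------------

#' Per-sample mapped-read fractions for spike-in quantification
#'
#' @param n_target Reads mapped to the target genome.
#' @param n_spike Reads mapped to the spike-in (exogenous) genome.
#' @return Object of class `SpikeInStats` with fractions `s` (target) and
#'   `s_spike` (spike-in) of all mapped reads.
#' @export
spike_in_stats <- function(n_target, n_spike) {
  if (n_target <= 0) stop("no target-genome reads")
  if (n_spike <= 0) stop("unusable spike-in: no spike-in reads")
  tot <- n_target + n_spike
  structure(list(s = n_target / tot, s_spike = n_spike / tot,
                 n_target = n_target, n_spike = n_spike),
            class = "SpikeInStats")
}

#' ChIP-Rx ratio of a ChIP sample against its input
#'
#' Rx = (s / s_spike) / (i / i_spike), where s and s_spike are the
#' target-genome and spike-in mapped-read fractions of the ChIP sample and
#' i, i_spike the same for the input. Because spike-in chromatin is added in
#' fixed proportion to target chromatin, Rx tracks the genome-wide abundance
#' of the immunoprecipitated mark and makes tracks comparable across
#' conditions.
#'
#' @param chip,input `SpikeInStats` for the ChIP and input samples (or
#'   anything with `$s` and `$s_spike`).
#' @return Positive scalar Rx.
#' @examples
#' rx_ratio(spike_in_stats(90, 10), spike_in_stats(50, 50))  # 9
#' @export
rx_ratio <- function(chip, input) {
  for (st in list(chip, input))
    if (st$s <= 0 || st$s_spike <= 0)
      stop("unusable spike-in: zero mapped-read fraction")
  (chip$s / chip$s_spike) / (input$s / input$s_spike)
}

#' Normalization constants
#'
#' @param pseudocount Count added to raw bin counts before ratios/logs
#'   (default 1).
#' @param norm_factor Common scale factor applied to depth-normalized tracks
#'   to avoid very small values (default 1e10).
#' @return List of class `NormalizationConfig`.
#' @export
norm_config <- function(pseudocount = 1, norm_factor = 1e10) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (norm_factor <= 0) stop("norm_factor must be positive")
  structure(list(pseudocount = pseudocount, norm_factor = norm_factor,
                 log_base = 2),
            class = "NormalizationConfig")
}

#' Per-bin track over a genome partition
#'
#' @param bins GRanges partition (see [make_bins()]).
#' @param values Numeric vector, one value per bin (raw counts or normalized
#'   values).
#' @param total_reads Library total the counts came from.
#' @return Object of class `BinTrack`.
#' @export
bin_track <- function(bins, values, total_reads = sum(values)) {
  if (length(values) != length(bins))
    stop("values must have one entry per bin")
  structure(list(bins = bins, values = as.numeric(values),
                 total_reads = as.numeric(total_reads)),
            class = "BinTrack")
}

#' @export
print.BinTrack <- function(x, ...) {
  cat("BinTrack:", length(x$values), "bins, total_reads =", x$total_reads,
      "\n")
  invisible(x)
}

#' Count tags into a partition as a BinTrack
#'
#' @param tags A `TagCollection`.
#' @param bins GRanges partition.
#' @return `BinTrack` of raw counts with `total_reads = n_target`.
#' @export
count_track <- function(tags, bins) {
  bin_track(bins, count_tags_in_intervals(tags, bins),
            total_reads = tags$n_target)
}

check_same_partition <- function(a, b) {
  if (length(a$bins) != length(b$bins) ||
      !identical(granges_to_bed0(a$bins), granges_to_bed0(b$bins)))
    stop("tracks are on different partitions")
}

#' Scale a count track by depth, Rx ratio and the common factor
#'
#' value_i = (count_i / total_reads) * Rx * norm_factor. Summed over a
#' partition whose counts exhaust the library, the track totals Rx *
#' norm_factor, so genome-wide sums of Rx-scaled tracks compare global mark
#' abundance across samples.
#'
#' @param track `BinTrack` of raw counts.
#' @param rx ChIP-Rx ratio of the sample (see [rx_ratio()]).
#' @param cfg `NormalizationConfig`.
#' @return `BinTrack` of scaled values.
#' @export
rx_scale_track <- function(track, rx, cfg = norm_config()) {
  if (track$total_reads <= 0) stop("total_reads must be positive")
  bin_track(track$bins, track$values / track$total_reads * rx *
              cfg$norm_factor, total_reads = track$total_reads)
}

#' Input normalization: log2 of depth-normalized ChIP over input
#'
#' value_i = log2( ((Si + c)/TS) / ((Ni + c)/TN) ) with pseudocount c to keep
#' zero-count bins defined.
#'
#' @param chip,input `BinTrack`s of raw counts on the same partition.
#' @param cfg `NormalizationConfig`.
#' @return `BinTrack` of log2 enrichment values.
#' @export
input_normalize <- function(chip, input, cfg = norm_config()) {
  check_same_partition(chip, input)
  c0 <- cfg$pseudocount
  v <- log2(((chip$values + c0) / chip$total_reads) /
              ((input$values + c0) / input$total_reads))
  bin_track(chip$bins, v, total_reads = chip$total_reads)
}

#' Input normalization with ChIP-Rx scaling of the target sample
#'
#' value_i = log2( (Rx * (Si + c)/TS) / ((Ni + c)/TN) ); identically equal to
#' [input_normalize()] plus log2(Rx). The Rx ratio is applied to the ChIP
#' sample only; inputs are never Rx-scaled.
#'
#' @inheritParams input_normalize
#' @param rx ChIP-Rx ratio of the ChIP sample.
#' @return `BinTrack` of log2 values.
#' @export
input_normalize_with_rx <- function(chip, input, rx, cfg = norm_config()) {
  check_same_partition(chip, input)
  c0 <- cfg$pseudocount
  v <- log2((rx * (chip$values + c0) / chip$total_reads) /
              ((input$values + c0) / input$total_reads))
  bin_track(chip$bins, v, total_reads = chip$total_reads)
}

#' Reads per kilobase per million mapped reads, per bin
#'
#' Uses the true width of each bin, so the short last bin of a chromosome is
#' scaled correctly.
#'
#' @param track `BinTrack` of raw counts.
#' @return `BinTrack` of RPKM values.
#' @export
rpkm <- function(track) {
  if (track$total_reads <= 0) stop("total_reads must be positive")
  width_kb <- width(track$bins) / 1000
  bin_track(track$bins,
            track$values / (width_kb * track$total_reads / 1e6),
            total_reads = track$total_reads)
}

## ---------------------------------------------------------------------------
## bedGraph IO
## ---------------------------------------------------------------------------

#' Write a BinTrack as bedGraph
#' @param track `BinTrack`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- granges_to_bed0(track$bins)
  writeLines(paste(df$chrom, df$start, df$end,
                   format(track$values, trim = TRUE, scientific = FALSE),
                   sep = "\t"),
             path)
  invisible(path)
}

#' Read a bedGraph into a BinTrack
#' @param path bedGraph path (chrom, start, end, value).
#' @param total_reads Library total to attach (default: sum of values).
#' @return `BinTrack`.
#' @export
read_bedgraph <- function(path, total_reads = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric",
                                  "numeric"))
  gr <- bed0_to_granges(df$chrom, df$start, df$end)
  if (is.null(total_reads)) total_reads <- sum(df$value)
  bin_track(gr, df$value, total_reads = total_reads)
}

#' Read spike-in read totals from a two-column TSV
#' @param path TSV with columns sample, spike_reads (no header).
#' @return Named numeric vector of spike-in totals.
#' @export
read_spike_totals <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "spike_reads"),
                   colClasses = c("character", "numeric"))
  setNames(df$spike_reads, df$sample)
}
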