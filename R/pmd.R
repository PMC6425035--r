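## ---------------------------------------------------------------------------
## Partially methylated domain (PMD) calling from WGBS methylation calls
##
## Seed-and-extend on 10-kb windows: a window whose mean CpG methylation
## falls below 70% seeds a candidate, which is extended rightward in 10-kb
## increments while the running region mean stays below threshold; merged
## candidates longer than 1 Mb are reported.
## ---------------------------------------------------------------------------

#' PMD caller configuration
#'
#' @param window Seed window size in bp (default 10 kb).
#' @param increment Extension step in bp (default 10 kb).
#' @param threshold Mean-methylation fraction below which a window seeds /
#'   extension continues (default 0.70).
#' @param min_length Minimum reported region length in bp, strict (default
#'   1 Mb).
#' @param min_coverage Minimum CpG read coverage retained by
#'   [filter_cpgs()] (default 5).
#' @return List of class `PMDCallerConfig`.
#' @export
pmd_config <- function(window = 1e4, increment = 1e4, threshold = 0.70,
                       min_length = 1e6, min_coverage = 5) {
  if (window <= 0 || increment <= 0 || min_length <= 0)
    stop("window, increment and min_length must be positive")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(window = window, increment = increment,
                 threshold = threshold, min_length = min_length,
                 min_coverage = min_coverage),
            class = "PMDCallerConfig")
}

#' Filter CpG methylation calls
#'
#' Retains CpGs with coverage of at least `min_coverage` reads, positions
#' not in the SNP exclusion list, and positions outside blacklist regions.
#'
#' @param records data.frame (chrom, pos, coverage, meth_fraction) sorted
#'   by (chrom, pos).
#' @param cfg `PMDCallerConfig`.
#' @param blacklist Optional GRanges of excluded regions.
#' @param snp_positions Optional data.frame (chrom, pos) of excluded CpG
#'   positions, or GRanges of 1-bp exclusions.
#' @return Filtered records.
#' @export
filter_cpgs <- function(records, cfg = pmd_config(), blacklist = NULL,
                        snp_positions = NULL) {
  keep <- records$coverage >= cfg$min_coverage
  if (!is.null(snp_positions)) {
    snp_key <- if (inherits(snp_positions, "GRanges"))
      paste(as.character(seqnames(snp_positions)), start(snp_positions) - 1)
    else paste(snp_positions$chrom, snp_positions$pos)
    keep <- keep & !(paste(records$chrom, records$pos) %in% snp_key)
  }
  if (!is.null(blacklist) && length(blacklist)) {
    gr <- GRanges(records$chrom, IRanges(records$pos + 1, records$pos + 1))
    keep <- keep & !overlapsAny(gr, blacklist, ignore.strand = TRUE)
  }
  records[keep, , drop = FALSE]
}

## mean methylation of CpGs with pos in [from, to); NA when empty.
## `pos` and `meth` are for one chromosome, pos sorted ascending.
window_mean <- function(pos, meth, from, to) {
  i <- findInterval(c(from - 0.5, to - 0.5), pos)
  if (i[2] <= i[1]) return(NA_real_)
  mean(meth[(i[1] + 1):i[2]])
}

#' Seed-window detection for PMD calling
#'
#' Slides a `window`-bp window in `increment`-bp steps across each
#' chromosome and reports windows whose unweighted mean CpG methylation is
#' below `threshold`. Windows without CpGs never seed. Exposed separately
#' so the seed criterion can be examined on its own.
#'
#' @param records Filtered CpG records (see [filter_cpgs()]), sorted by
#'   (chrom, pos).
#' @param cfg `PMDCallerConfig`.
#' @return data.frame (chrom, start, end, mean_meth) of seed windows.
#' @export
pmd_seed_windows <- function(records, cfg = pmd_config()) {
  check_sorted_cpgs(records)
  out <- lapply(split(records, records$chrom), function(rec) {
    pos <- rec$pos; meth <- rec$meth_fraction
    if (length(pos) == 0) return(NULL)
    starts <- seq(0, max(pos), by = cfg$increment)
    m <- vapply(starts, function(s)
      window_mean(pos, meth, s, s + cfg$window), 0)
    sel <- !is.na(m) & m < cfg$threshold
    if (!any(sel)) return(NULL)
    data.frame(chrom = rec$chrom[1], start = starts[sel],
               end = starts[sel] + cfg$window, mean_meth = m[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_meth = numeric(0))
  rownames(out) <- NULL
  out
}

check_sorted_cpgs <- function(records) {
  if (nrow(records) < 2) return(invisible(TRUE))
  o <- order(records$chrom, records$pos, method = "radix")
  if (!identical(o, seq_len(nrow(records))))
    stop("CpG records must be sorted by (chrom, pos)")
  invisible(TRUE)
}

#' Call partially methylated domains
#'
#' Every seed window (mean methylation < `threshold`) starts a candidate
#' region, which is extended rightward in `increment`-bp steps for as long
#' as the mean methylation of each added increment stays below `threshold`;
#' the terminating increment whose mean reaches the threshold is excluded.
#' Increments without CpGs are neutral (they neither stop extension nor
#' alter the region mean). Stopping on the increment mean rather than the
#' cumulative region mean keeps domain boundaries within one window of the
#' true methylation transition; a cumulative rule would drag every
#' boundary far into the methylated flank before the running mean
#' recovers. The mean of every reported domain is still below `threshold`,
#' since the region is assembled entirely from sub-threshold windows.
#' Seeds falling inside an already-extended candidate are skipped;
#' overlapping or bookended candidates are merged; merged regions strictly
#' longer than `min_length` are reported.
#'
#' @param records Filtered CpG records sorted by (chrom, pos).
#' @param cfg `PMDCallerConfig`.
#' @return GRanges of PMDs, sorted and pairwise disjoint.
#' @export
call_pmds <- function(records, cfg = pmd_config()) {
  check_sorted_cpgs(records)
  per_chrom <- lapply(split(records, records$chrom), function(rec) {
    pos <- rec$pos; meth <- rec$meth_fraction
    if (length(pos) == 0) return(NULL)
    chrom_end <- max(pos) + 1
    starts <- seq(0, max(pos), by = cfg$increment)
    cand_start <- numeric(0); cand_end <- numeric(0)
    covered_to <- -Inf
    for (s in starts) {
      if (s < covered_to) next  # inside an already-extended candidate
      m <- window_mean(pos, meth, s, s + cfg$window)
      if (is.na(m) || m >= cfg$threshold) next
      e <- s + cfg$window
      repeat {
        if (e >= chrom_end) break
        e2 <- e + cfg$increment
        m_inc <- window_mean(pos, meth, e, e2)
        if (!is.na(m_inc) && m_inc >= cfg$threshold) break
        e <- e2
      }
      cand_start <- c(cand_start, s); cand_end <- c(cand_end, e)
      covered_to <- e
    }
    if (length(cand_start) == 0) return(NULL)
    data.frame(chrom = rec$chrom[1], start = cand_start, end = cand_end,
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, per_chrom[!vapply(per_chrom, is.null, TRUE)])
  if (is.null(per_chrom)) return(GRanges())
  gr <- bed0_to_granges(per_chrom$chrom, per_chrom$start, per_chrom$end)
  ## merge overlapping or bookended candidates, then strict length filter
  gr <- reduce(sort_granges(gr), min.gapwidth = 1L, ignore.strand = TRUE)
  gr[width(gr) > cfg$min_length]
}

#' Read per-CpG methylation calls from a TSV
#' @param path TSV (chrom, pos, coverage, meth_fraction), no header.
#' @return Sorted data.frame of CpG records.
#' @export
read_cpg_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "pos", "coverage",
                                 "meth_fraction"),
                   colClasses = c("character", "numeric", "numeric",
                                  "numeric"))
  if (any(df$meth_fraction < 0 | df$meth_fraction > 1))
    stop("meth_fraction must lie in [0, 1]")
  df[order(df$chrom, df$pos, method = "radix"), , drop = FALSE]
}

#' Write per-CpG methylation calls to a TSV
#' @param records CpG records data.frame.
#' @param path Output path.
#' @export
write_cpg_table <- function(records, path) {
  write.table(records[, c("chrom", "pos", "coverage", "meth_fraction")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
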