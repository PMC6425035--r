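#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqlengths<- Seqinfo
#' @importFrom stats kmeans rpois runif rbeta rnorm setNames
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## Genome description and coordinate conventions
##
## Intervals are GRanges (1-based closed) everywhere inside the package; BED
## files use 0-based half-open coordinates and are converted at the IO
## boundary.  A genome is a named numeric vector of chromosome lengths.
## ---------------------------------------------------------------------------

#' Describe a genome as named chromosome lengths
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer lengths in bp, one per chromosome.
#' @return Named numeric vector of lengths, the genome description used by
#'   [make_bins()], [make_tag_collection()] and the simulator.
#' @examples
#' genome_description(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_description <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("chrom and length must have equal length")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  setNames(length, chrom)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with columns chrom, length.
#' @return A genome description (named numeric vector).
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  genome_description(df$chrom, df$length)
}

## Convert 0-based half-open coordinates to a GRanges.  `genome` (optional)
## attaches seqlengths and validates bounds.
bed0_to_granges <- function(chrom, start, end, name = NULL, strand = NULL,
                            genome = NULL) {
  if (any(start < 0)) stop("start coordinates must be non-negative")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  st <- if (is.null(strand)) "*" else ifelse(strand %in% c("+", "-"), strand, "*")
  gr <- GRanges(chrom, IRanges(start + 1, end), strand = st)
  if (!is.null(name)) mcols(gr)$name <- name
  if (!is.null(genome)) {
    bad <- !(as.character(seqnames(gr)) %in% names(genome))
    if (any(bad))
      stop("chromosome not in genome description: ",
           paste(unique(as.character(seqnames(gr))[bad]), collapse = ", "))
    if (any(end > genome[as.character(seqnames(gr))]))
      stop("interval end exceeds chromosome length")
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    seqlengths(gr) <- genome
  }
  gr
}

granges_to_bed0 <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L,
             end = end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open; the returned GRanges follows the
#' usual 1-based closed convention. Intervals are sorted by (chrom, start).
#'
#' @param path Path to a BED file (3 or 6 columns, tab-separated, no header).
#' @param genome Optional genome description for bounds validation.
#' @return GRanges, with a `name` metadata column when the file has one.
#' @export
read_bed <- function(path) read_bed_impl(path, genome = NULL)

#' @rdname read_bed
#' @export
read_bed_checked <- function(path, genome) read_bed_impl(path, genome)

read_bed_impl <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("invalid interval at BED line ", bad[1],
         ": need 0 <= start < end, got [", start[bad[1]], ", ", end[bad[1]], ")")
  chrom <- vapply(fields, `[`, "", 1L)
  name <- if (all(nf >= 4)) vapply(fields, `[`, "", 4L) else NULL
  strand <- if (all(nf >= 6)) vapply(fields, `[`, "", 6L) else NULL
  gr <- bed0_to_granges(chrom, start, end, name = name, strand = strand,
                        genome = genome)
  sort_granges(gr)
}

#' Write a GRanges to BED
#'
#' Writes BED3, or BED6 when `name` metadata is present. Coordinates are
#' converted back to 0-based half-open, so [read_bed()] followed by
#' `write_bed()` round-trips a BED3 file byte-identically.
#'
#' @param gr GRanges to write.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- granges_to_bed0(gr)
  if (!is.null(mcols(gr)$name)) {
    df$name <- mcols(gr)$name
    df$score <- 0L
    df$strand <- as.character(strand(gr))
    df$strand[df$strand == "*"] <- "."
  }
  lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## Sort by (chrom in seqlevels order, start, end); stable.
sort_granges <- function(gr) {
  ord <- order(match(as.character(seqnames(gr)), seqlevels(gr)),
               start(gr), end(gr), method = "radix")
  gr[ord]
}

## ---------------------------------------------------------------------------
## Binning and feature construction
## ---------------------------------------------------------------------------

#' Tile a genome into fixed-width bins
#'
#' Every chromosome is tiled left to right with `width`-bp bins; the last bin
#' per chromosome is shortened to the chromosome end when the length is not a
#' multiple of `width`.
#'
#' @param genome Genome description (named lengths, see
#'   [genome_description()]).
#' @param width Bin width in bp, > 0. Typical analyses use 1 kb, 10 kb and
#'   100 kb tilings.
#' @return GRanges partition covering the genome exactly, sorted, with
#'   seqlengths set.
#' @examples
#' make_bins(genome_description("chrA", 10500), 1000)
#' @export
make_bins <- function(genome, width) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a single positive number")
  sl <- setNames(as.integer(genome), names(genome))
  bins <- tileGenome(sl, tilewidth = as.integer(width),
                     cut.last.tile.in.chrom = TRUE)
  bins
}

#' Build promoter intervals around transcription start sites
#'
#' Promoters are regions of `2 * flank` bp centered on the TSS (5 kb at the
#' default), irrespective of strand; the TSS of a minus-strand transcript is
#' its larger genomic coordinate and must be supplied as the `tss` field.
#' Duplicate TSSs (several transcripts sharing one start) yield one promoter.
#' Intervals are clipped at chromosome bounds.
#'
#' @param transcripts data.frame with columns `chrom` and `tss` (0-based bp);
#'   see [read_refgene()].
#' @param flank Half-width in bp (default 2500, giving 5 kb promoters).
#' @param genome Optional genome description for right-side clipping.
#' @return GRanges of promoters sorted by position.
#' @export
make_promoters <- function(transcripts, flank = 2500, genome = NULL) {
  if (flank <= 0) stop("flank must be positive")
  key <- !duplicated(paste(transcripts$chrom, transcripts$tss))
  tx <- transcripts[key, , drop = FALSE]
  start <- pmax(tx$tss - flank, 0)
  end <- tx$tss + flank
  if (!is.null(genome)) end <- pmin(end, genome[as.character(tx$chrom)])
  gr <- bed0_to_granges(tx$chrom, start, end, genome = genome)
  sort_granges(gr)
}

#' Select one genic region per gene
#'
#' For genes with multiple transcripts, the span with the longest
#' |TES - TSS| is kept; ties go to the lower start coordinate.
#'
#' @param transcripts data.frame with columns `gene`, `chrom`, `tss`, `tes`
#'   (0-based bp).
#' @return GRanges with one range per gene, `name` = gene id, sorted.
#' @export
make_genic_regions <- function(transcripts) {
  tx <- transcripts
  tx$span_start <- pmin(tx$tss, tx$tes)
  tx$span_end <- pmax(tx$tss, tx$tes)
  tx$len <- tx$span_end - tx$span_start
  ## stable order: longest span first, then lower start
  ord <- order(tx$gene, -tx$len, tx$span_start, method = "radix")
  tx <- tx[ord, , drop = FALSE]
  tx <- tx[!duplicated(tx$gene), , drop = FALSE]
  gr <- bed0_to_granges(tx$chrom, tx$span_start, tx$span_end, name = tx$gene)
  sort_granges(gr)
}

#' Read a UCSC refGene-style transcript table
#'
#' Expects tab-separated columns gene, transcript, chrom, strand, txStart,
#' txEnd with txStart/txEnd 0-based half-open (the UCSC convention). The TSS
#' is txStart for plus-strand and txEnd for minus-strand transcripts.
#'
#' @param path Path to the table (no header).
#' @return data.frame with columns gene, transcript, chrom, strand, tss, tes.
#' @export
read_refgene <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("gene", "transcript", "chrom", "strand",
                                 "txStart", "txEnd"),
                   colClasses = c("character", "character", "character",
                                  "character", "numeric", "numeric"))
  if (any(!df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tss <- ifelse(df$strand == "+", df$txStart, df$txEnd)
  tes <- ifelse(df$strand == "+", df$txEnd, df$txStart)
  data.frame(gene = df$gene, transcript = df$transcript, chrom = df$chrom,
             strand = df$strand, tss = tss, tes = tes,
             stringsAsFactors = FALSE)
}

#' Drop intervals overlapping a blacklist
#'
#' Any interval sharing at least 1 bp with a blacklist region is removed
#' (any-overlap rule, half-open file coordinates: an interval ending where a
#' blacklist region starts does not overlap it).
#'
#' @param intervals GRanges to filter.
#' @param blacklist GRanges of excluded regions.
#' @return The retained subset of `intervals`.
#' @export
filter_blacklist <- function(intervals, blacklist) {
  if (length(blacklist) == 0) return(intervals)
  hits <- overlapsAny(intervals, blacklist, ignore.strand = TRUE)
  intervals[!hits]
}

## ---------------------------------------------------------------------------
## Tag collections and counting
## ---------------------------------------------------------------------------

#' Bundle aligned-read tags with spike-in totals
#'
#' A tag is the 5' mapping coordinate of one read (0-based bp). Tags are the
#' substrate of all counting; spike-in reads are carried as a total only,
#' since ChIP-Rx uses nothing but mapped-read fractions.
#'
#' @param tags Named list, one sorted-or-sortable numeric vector of 0-based
#'   positions per chromosome.
#' @param genome Genome description; every tag must lie within its
#'   chromosome.
#' @param n_spike Total spike-in (exogenous genome) read count.
#' @return Object of class `TagCollection` with elements `tags`, `genome`,
#'   `n_target`, `n_spike`.
#' @export
make_tag_collection <- function(tags, genome, n_spike = 0) {
  if (is.null(names(tags)) || any(!nzchar(names(tags))))
    stop("tags must be a named list (chromosome -> positions)")
  bad <- setdiff(names(tags), names(genome))
  if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ", "))
  tags <- lapply(tags, function(x) sort(as.numeric(x)))
  for (chr in names(tags)) {
    x <- tags[[chr]]
    if (length(x) && (x[1] < 0 || x[length(x)] >= genome[[chr]]))
      stop("tag position outside chromosome bounds on ", chr)
  }
  structure(list(tags = tags, genome = genome,
                 n_target = sum(lengths(tags)), n_spike = as.numeric(n_spike)),
            class = "TagCollection")
}

#' @export
print.TagCollection <- function(x, ...) {
  cat("TagCollection:", x$n_target, "target reads,", x$n_spike,
      "spike-in reads on", length(x$tags), "chromosome(s)\n")
  invisible(x)
}

tags_as_granges <- function(tags) {
  pos <- unlist(tags$tags, use.names = FALSE)
  if (is.null(pos) || length(pos) == 0) return(GRanges())
  chrom <- rep(names(tags$tags), lengths(tags$tags))
  GRanges(chrom, IRanges(pos + 1, pos + 1))
}

#' Count tags per interval
#'
#' A tag counts in an interval when its 5' coordinate lies in the half-open
#' interval; a tag inside several overlapping intervals counts in each, so
#' counts over a disjoint partition of the genome sum exactly to `n_target`.
#'
#' @param tags A `TagCollection`.
#' @param intervals GRanges of intervals to count in.
#' @return Integer vector of counts, parallel to `intervals`.
#' @export
count_tags_in_intervals <- function(tags, intervals) {
  stopifnot(inherits(tags, "TagCollection"))
  tgr <- tags_as_granges(tags)
  if (length(tgr) == 0) return(integer(length(intervals)))
  countOverlaps(intervals, tgr, ignore.strand = TRUE)
}

#' Write tags as a BED3 file of 1-bp intervals
#' @param tags A `TagCollection`.
#' @param path Output path.
#' @export
write_tags_bed <- function(tags, path) {
  pos <- unlist(tags$tags, use.names = FALSE)
  chrom <- rep(names(tags$tags), lengths(tags$tags))
  df <- data.frame(chrom = chrom, start = pos, end = pos + 1)
  ord <- order(df$chrom, df$start, method = "radix")
  writeLines(paste(df$chrom[ord], df$start[ord], df$end[ord], sep = "\t"),
             path)
  invisible(path)
}

#' Read tags from a BED file of 1-bp intervals
#' @param path BED path (start column is the tag coordinate).
#' @param genome Genome description.
#' @param n_spike Spike-in read total to attach.
#' @return A `TagCollection`.
#' @export
read_tags_bed <- function(path, genome, n_spike = 0) {
  gr <- read_bed(path)
  pos <- start(gr) - 1
  tags <- split(pos, as.character(seqnames(gr)))
  make_tag_collection(tags, genome, n_spike = n_spike)
}
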