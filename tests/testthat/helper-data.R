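# Shared fixtures, built in code at test time.

# Desk-scale configuration used by most unit tests: small enough to
# simulate in well under a second.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed,
    genome = genome_description(c("chrA", "chrB"), c(1e6, 1e6)),
    n_cgi = 40, nucleation_fraction = 0.2, peak_width = 2000,
    spread_length = 2e4,
    pmd_spec = data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), mean_meth = numeric(0)),
    depth = 5e4, spike_fraction = 0.05, abundance_ratio = 0.5,
    n_genes = 200, de_spec = list(n_up = 20, n_down = 5),
    n_blacklist = 2)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

# deterministic CpG grid: one CpG every `spacing` bp with given methylation
cpg_grid <- function(chrom, from, to, meth, spacing = 200, coverage = 30) {
  pos <- seq(from, to - 1, by = spacing)
  data.frame(chrom = chrom, pos = pos, coverage = coverage,
             meth_fraction = rep_len(meth, length(pos)),
             stringsAsFactors = FALSE)
}

sort_cpgs <- function(records)
  records[order(records$chrom, records$pos, method = "radix"), , drop = FALSE]

# random tag list over a genome
random_tags <- function(genome, n) {
  chrom <- sample(names(genome), n, replace = TRUE)
  pos <- floor(runif(n) * genome[chrom])
  split(pos, chrom)
}

# random intervals as a data.frame (0-based half-open)
random_intervals_df <- function(genome, n, max_width = 5e4) {
  chrom <- sample(names(genome), n, replace = TRUE)
  width <- ceiling(runif(n) * max_width)
  start <- floor(runif(n) * (genome[chrom] - width))
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
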