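## ---------------------------------------------------------------------------
## Synthetic-data generator
##
## Emulates the two H3K27 methylation regimes: in the wild-type (WT) state
## H3K27me3 occupies broad domains spreading from large unmethylated CpG
## islands (plus partially methylated domains), while H3K27me2 blankets the
## remaining silent genome; in the K27M state H3K27me3 is confined to sharp
## peaks at the nucleation CGIs and H3K27me2 spreads to occupy the former
## WT-me3 footprint.  Every draw is a pure function of the configuration
## seed, so all downstream stages have exact ground truth.
## ---------------------------------------------------------------------------

#' Configuration of the synthetic dataset
#'
#' Defaults describe a desk-scale genome of two 5-Mb chromosomes carrying
#' 200 CpG islands, of which the widest 20% are unmethylated PRC2 nucleation
#' sites; one 1.5-Mb partially methylated domain; ChIP samples of 2e5
#' expected target reads with a 5% expected spike-in read fraction; and an
#' expression table of 2000 genes with 102 upregulated and 12 downregulated
#' genes concentrated at low parental expression.
#'
#' @param seed Integer seed fixing every draw.
#' @param genome Genome description (see [genome_description()]).
#' @param n_cgi Number of CpG islands to place (non-overlapping).
#' @param nucleation_fraction Fraction of CGIs flagged as large unmethylated
#'   nucleation sites (the widest ones).
#' @param peak_width bp of focal me3 enrichment flanking nucleation CGIs in
#'   the K27M regime.
#' @param spread_length bp of broad WT-me3 domain flanking each nucleation
#'   CGI.
#' @param pmd_spec data.frame (chrom, start, end, mean_meth) of planted
#'   partially methylated domains; also part of the WT-me3 footprint.
#' @param depth Expected target-genome reads per sample.
#' @param spike_fraction Expected fraction of spike-in reads in a sample at
#'   reference abundance.
#' @param abundance_ratio True genome-wide me3 abundance in K27M relative to
#'   WT; implemented by scaling K27M me3 target rates at fixed spike-in
#'   rate, the way global mark loss manifests in ChIP-Rx.
#' @param background_rate,enrichment_rate Relative expected tags per bp
#'   outside/inside enriched regions; the map is rescaled so the expected
#'   target total equals `depth`, so only their ratio matters.
#' @param n_genes Genes in the expression table (one promoter each).
#' @param de_spec List with `n_up`, `n_down`: planted differentially
#'   expressed gene counts.
#' @param low_coverage_fraction Fraction of simulated CpGs given coverage
#'   below 5 to exercise the coverage filter.
#' @param n_blacklist Number of 10-kb blacklist regions.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1,
                       genome = genome_description(c("chr1", "chr2"),
                                                   c(5e6, 5e6)),
                       n_cgi = 200,
                       nucleation_fraction = 0.2,
                       peak_width = 4000,
                       spread_length = 1e5,
                       pmd_spec = data.frame(chrom = "chr1", start = 2e6,
                                             end = 3.5e6, mean_meth = 0.5),
                       depth = 2e5,
                       spike_fraction = 0.05,
                       abundance_ratio = 0.25,
                       background_rate = 0.001,
                       enrichment_rate = 0.04,
                       n_genes = 2000,
                       de_spec = list(n_up = 102, n_down = 12),
                       low_coverage_fraction = 0.1,
                       n_blacklist = 5) {
  frac_ok <- function(x) is.numeric(x) && x > 0 && x < 1
  if (!frac_ok(nucleation_fraction) && nucleation_fraction != 0)
    stop("nucleation_fraction must be in [0, 1)")
  if (!frac_ok(spike_fraction)) stop("spike_fraction must be in (0, 1)")
  if (!(frac_ok(low_coverage_fraction) || low_coverage_fraction == 0))
    stop("low_coverage_fraction must be in [0, 1)")
  if (background_rate < 0 || enrichment_rate < 0) stop("rates must be >= 0")
  if (abundance_ratio <= 0) stop("abundance_ratio must be positive")
  if (de_spec$n_up + de_spec$n_down > n_genes)
    stop("more DE genes than genes")
  if (nrow(pmd_spec)) {
    gr <- bed0_to_granges(pmd_spec$chrom, pmd_spec$start, pmd_spec$end,
                          genome = genome)
    if (length(reduce(gr)) < length(gr))
      stop("pmd_spec regions must be non-overlapping")
  }
  structure(list(seed = as.integer(seed), genome = genome, n_cgi = n_cgi,
                 nucleation_fraction = nucleation_fraction,
                 peak_width = peak_width, spread_length = spread_length,
                 pmd_spec = pmd_spec, depth = depth,
                 spike_fraction = spike_fraction,
                 abundance_ratio = abundance_ratio,
                 background_rate = background_rate,
                 enrichment_rate = enrichment_rate,
                 n_genes = n_genes, de_spec = de_spec,
                 low_coverage_fraction = low_coverage_fraction,
                 n_blacklist = n_blacklist),
            class = "SimulationConfig")
}

## deterministic sub-seeds per generator stage, kept below 2^31
sub_seed <- function(config, offset)
  as.integer((as.numeric(config$seed) * 1000 + offset) %% 2147483647)

clip_to_genome <- function(gr, genome) {
  sl <- genome[as.character(seqnames(gr))]
  start(gr) <- pmax(start(gr), 1)
  end(gr) <- pmin(end(gr), sl)
  gr
}

#' Simulate genome annotations with known ground truth
#'
#' Places non-overlapping CpG islands (one per equal-width slot of each
#' chromosome), flags the widest `nucleation_fraction` as PRC2 nucleation
#' sites (DNA methylation ~0.05 versus ~0.65 elsewhere), and derives SUZ12
#' peaks (= nucleation CGIs), one promoter per gene, a small blacklist, and
#' the WT-me3 domain footprint (nucleation CGIs +/- `spread_length`, union
#' planted PMDs).
#'
#' @param config A `SimulationConfig`.
#' @return List with GRanges `cgis` (mcols: name, nucleation,
#'   dna_methylation), `suz12_peaks`, `promoters` (name = gene id),
#'   `blacklist`, `wt_me3_footprint`, and data.frame `genes`.
#' @export
simulate_annotations <- function(config) {
  set.seed(sub_seed(config, 1L))
  genome <- config$genome
  ## allocate CGIs to chromosomes proportional to length
  n_per <- round(config$n_cgi * genome / sum(genome))
  n_per[length(n_per)] <- config$n_cgi - sum(n_per[-length(n_per)])
  chrom <- character(0); start <- numeric(0); width <- numeric(0)
  for (i in seq_along(genome)) {
    n <- n_per[i]
    if (n == 0) next
    slot <- floor(genome[i] / n)
    w <- pmin(round(stats::rlnorm(n, log(1200), 0.6)), slot - 400)
    w <- pmax(w, 300)
    if (any(w >= slot - 200)) stop("genome too small to place CGIs")
    off <- floor(runif(n) * (slot - w - 200)) + 100
    chrom <- c(chrom, rep(names(genome)[i], n))
    start <- c(start, (seq_len(n) - 1) * slot + off)
    width <- c(width, w)
  }
  n_nuc <- round(config$n_cgi * config$nucleation_fraction)
  nucleation <- rank(-width, ties.method = "first") <= n_nuc
  meth <- ifelse(nucleation, rbeta(config$n_cgi, 2, 38),
                 rbeta(config$n_cgi, 13, 7))
  cgis <- bed0_to_granges(chrom, start, start + width,
                          name = sprintf("CGI_%04d", seq_along(chrom)),
                          genome = genome)
  mcols(cgis)$nucleation <- nucleation
  mcols(cgis)$dna_methylation <- meth
  cgis <- sort_granges(cgis)
  suz12 <- cgis[mcols(cgis)$nucleation]
  mcols(suz12) <- S4Vectors::DataFrame(name = mcols(suz12)$name)

  ## one promoter per gene: unique TSS positions on a 100-bp grid
  gene_chrom <- sample(names(genome), config$n_genes, replace = TRUE,
                       prob = genome / sum(genome))
  tss <- vapply(gene_chrom, function(ch)
    sample.int(floor(genome[[ch]] / 100) - 60, 1) * 100 + 3000, 0)
  genes <- data.frame(gene = sprintf("g%04d", seq_len(config$n_genes)),
                      chrom = gene_chrom, tss = tss,
                      stringsAsFactors = FALSE)
  promoters <- bed0_to_granges(genes$chrom, pmax(genes$tss - 2500, 0),
                               pmin(genes$tss + 2500, genome[gene_chrom]),
                               name = genes$gene, genome = genome)

  bl_chrom <- sample(names(genome), config$n_blacklist, replace = TRUE)
  bl_start <- vapply(bl_chrom, function(ch)
    floor(runif(1) * (genome[[ch]] - 1e4)), 0)
  blacklist <- sort_granges(bed0_to_granges(bl_chrom, bl_start,
                                            bl_start + 1e4, genome = genome))

  footprint <- resize_by_flank(suz12, config$spread_length, genome)
  if (nrow(config$pmd_spec))
    footprint <- c(footprint,
                   bed0_to_granges(config$pmd_spec$chrom,
                                   config$pmd_spec$start,
                                   config$pmd_spec$end, genome = genome))
  footprint <- reduce(sort_granges(footprint), ignore.strand = TRUE)

  list(cgis = cgis, suz12_peaks = suz12, promoters = promoters,
       blacklist = blacklist, wt_me3_footprint = footprint, genes = genes)
}

## widen each range by `flank` bp on both sides, clipped to the genome
resize_by_flank <- function(gr, flank, genome) {
  out <- gr
  start(out) <- pmax(start(gr) - flank, 1)
  end(out) <- pmin(end(gr) + flank, genome[as.character(seqnames(gr))])
  mcols(out) <- NULL
  strand(out) <- "*"
  out
}

## Enriched-region map for one (condition, mark) sample.
sample_rate_regions <- function(config, annotations, condition, mark) {
  genome <- config$genome
  nuc <- annotations$suz12_peaks
  fp <- annotations$wt_me3_footprint
  whole <- bed0_to_granges(names(genome), rep(0, length(genome)), genome,
                           genome = genome)
  switch(paste(condition, mark, sep = "_"),
    WT_input = , K27M_input = GRanges(),
    WT_me3 = fp,
    K27M_me3 = reduce(resize_by_flank(nuc, config$peak_width, genome)),
    WT_me2 = setdiff(whole, fp, ignore.strand = TRUE),
    K27M_me2 = fp,
    WT_suz12 = reduce(resize_by_flank(nuc, 1000, genome)),
    K27M_suz12 = reduce(resize_by_flank(nuc, config$peak_width, genome)),
    stop("unknown condition/mark: ", condition, "/", mark))
}

#' Simulate one spike-in ChIP (or input) sample
#'
#' Tags are drawn per 100-bp generation bin from a Poisson distribution with
#' mean `rate * width`, then placed uniformly within the bin. The rate is
#' `enrichment_rate` inside the mark's enriched regions and
#' `background_rate` elsewhere, rescaled so the expected target total equals
#' `depth` (times `abundance_ratio` for K27M me3, modelling global mark
#' loss at fixed spike-in). Spike-in reads are drawn as a Poisson total with
#' expectation `depth * spike_fraction / (1 - spike_fraction)`, identical
#' across samples.
#'
#' Enriched regions per regime: WT me3 = nucleation CGIs +/- `spread_length`
#' plus PMDs (the WT-me3 footprint); K27M me3 = nucleation CGIs +/-
#' `peak_width`; WT me2 = complement of the WT-me3 footprint; K27M me2 = the
#' WT-me3 footprint itself; SUZ12 = nucleation CGIs with narrow (WT) or
#' `peak_width` (K27M) flanks; input = uniform background.
#'
#' @param config A `SimulationConfig`.
#' @param condition `"WT"` or `"K27M"`.
#' @param mark `"me3"`, `"me2"`, `"input"` or `"suz12"`.
#' @param annotations Output of [simulate_annotations()] (recomputed from
#'   `config` when omitted).
#' @return A `TagCollection` with attribute `expected_spike_fraction`.
#' @export
simulate_chip_sample <- function(config, condition, mark,
                                 annotations = simulate_annotations(config)) {
  condition <- match.arg(condition, c("WT", "K27M"))
  mark <- match.arg(mark, c("me3", "me2", "input", "suz12"))
  enriched <- sample_rate_regions(config, annotations, condition, mark)
  offset <- 100L + 10L * match(condition, c("WT", "K27M")) +
    match(mark, c("me3", "me2", "input", "suz12"))
  set.seed(sub_seed(config, offset))

  genbins <- make_bins(config$genome, 100)
  rate <- rep(config$background_rate, length(genbins))
  if (length(enriched))
    rate[overlapsAny(genbins, enriched, ignore.strand = TRUE)] <-
      config$enrichment_rate
  scale_abund <- if (condition == "K27M" && mark == "me3")
    config$abundance_ratio else 1
  mu <- rate * width(genbins)
  expected_total <- sum(mu)
  if (expected_total <= 0) stop("rate map has zero mass")
  mu <- mu / expected_total * config$depth * scale_abund
  counts <- rpois(length(mu), mu)
  total <- sum(counts)
  pos <- rep(start(genbins) - 1L, counts) +
    floor(runif(total) * rep(width(genbins), counts))
  chrom <- rep(as.character(seqnames(genbins)), counts)
  tags <- split(pos, chrom)
  expected_spike <- config$depth * config$spike_fraction /
    (1 - config$spike_fraction)
  n_spike <- rpois(1, expected_spike)
  tc <- make_tag_collection(tags, config$genome, n_spike = n_spike)
  attr(tc, "expected_spike_fraction") <-
    expected_spike / (expected_spike + config$depth * scale_abund)
  tc
}

#' Simulate a WGBS methylome with planted partially methylated domains
#'
#' One CpG is placed per 100 bp (uniform within each 100-bp cell), coverage
#' is Poisson with mean 30, and the methylated fraction is Beta-distributed
#' with mean 0.85 outside planted PMDs and the region's configured mean
#' inside. A `low_coverage_fraction` of CpGs receive coverage below 5 so the
#' coverage filter is exercised.
#'
#' @param config A `SimulationConfig`.
#' @return data.frame (chrom, pos, coverage, meth_fraction) sorted by
#'   (chrom, pos).
#' @export
simulate_methylome <- function(config) {
  set.seed(sub_seed(config, 200L))
  genome <- config$genome
  out <- lapply(names(genome), function(ch) {
    cells <- seq(0, genome[[ch]] - 100, by = 100)
    pos <- cells + floor(runif(length(cells)) * 100)
    coverage <- rpois(length(pos), 30)
    low <- runif(length(pos)) < config$low_coverage_fraction
    coverage[low] <- floor(runif(sum(low)) * 5)
    conc <- 20
    meth <- rbeta(length(pos), 0.85 * conc, 0.15 * conc)
    spec <- config$pmd_spec
    if (nrow(spec)) {
      spec_ch <- spec[spec$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(spec_ch))) {
        inside <- pos >= spec_ch$start[i] & pos < spec_ch$end[i]
        m <- spec_ch$mean_meth[i]
        meth[inside] <- rbeta(sum(inside), m * conc, (1 - m) * conc)
      }
    }
    data.frame(chrom = ch, pos = pos, coverage = coverage,
               meth_fraction = meth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
}

#' Simulate a differential-expression statistics table
#'
#' Parental expression is log-normal. `de_spec$n_up` genes are planted as
#' upregulated with their identities drawn with weights decaying in parental
#' expression rank, so upregulated genes concentrate in the low-expression
#' deciles; `n_down` downregulated genes are drawn uniformly from the rest.
#' Effects are well separated: planted genes get |log2FC| in [2, 4] and
#' padj <= 1e-3, unchanged genes |log2FC| < 0.8 and padj >= 0.06, so the
#' standard classification thresholds recover the truth exactly.
#'
#' @param config A `SimulationConfig`.
#' @param annotations Optional annotations (for gene ids matching the
#'   promoters); gene ids are regenerated when omitted.
#' @return data.frame (gene, log2fc, padj, parental_expression, de_label)
#'   where de_label is the planted truth in {Up, Down, NS}.
#' @export
simulate_expression <- function(config, annotations = NULL) {
  set.seed(sub_seed(config, 300L))
  n <- config$n_genes
  gene <- if (!is.null(annotations)) annotations$genes$gene
          else sprintf("g%04d", seq_len(n))
  parental <- stats::rlnorm(n, meanlog = 3, sdlog = 1.5)
  r <- rank(parental, ties.method = "first")
  w_up <- exp(-4 * (r - 1) / n)
  up_idx <- sample.int(n, config$de_spec$n_up, prob = w_up)
  rest <- setdiff(seq_len(n), up_idx)
  down_idx <- sample(rest, config$de_spec$n_down)
  label <- rep("NS", n)
  label[up_idx] <- "Up"
  label[down_idx] <- "Down"
  log2fc <- runif(n, -0.8, 0.8)
  log2fc[up_idx] <- runif(length(up_idx), 2, 4)
  log2fc[down_idx] <- -runif(length(down_idx), 2, 4)
  padj <- runif(n, 0.06, 1)
  padj[c(up_idx, down_idx)] <- 10^-runif(length(up_idx) + length(down_idx),
                                         3, 8)
  data.frame(gene = gene, log2fc = log2fc, padj = padj,
             parental_expression = parental, de_label = label,
             stringsAsFactors = FALSE)
}

#' Simulate the complete dataset for both regimes
#'
#' @param config A `SimulationConfig`.
#' @return List of class `SimulatedDataset` with `annotations`, `samples`
#'   (named `<condition>_<mark>` TagCollections for both conditions and
#'   marks me3, me2, input, suz12), `methylome`, `expression`, and `truth`
#'   (the config).
#' @export
simulate_dataset <- function(config = sim_config()) {
  ann <- simulate_annotations(config)
  combos <- expand.grid(condition = c("WT", "K27M"),
                        mark = c("me3", "me2", "input", "suz12"),
                        stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(combos)), function(i)
    simulate_chip_sample(config, combos$condition[i], combos$mark[i],
                         annotations = ann))
  names(samples) <- paste(combos$condition, combos$mark, sep = "_")
  structure(list(annotations = ann, samples = samples,
                 methylome = simulate_methylome(config),
                 expression = simulate_expression(config, ann),
                 truth = config),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat("SimulatedDataset: seed", x$truth$seed, "-",
      length(x$annotations$cgis), "CGIs,", length(x$samples), "samples,",
      nrow(x$methylome), "CpGs,", nrow(x$expression), "genes\n")
  invisible(x)
}

#' Serialize a SimulationConfig as flat YAML
#' @param config A `SimulationConfig`.
#' @param path Output path.
#' @export
write_sim_config <- function(config, path) {
  flat <- list(seed = config$seed,
               genome_chrom = names(config$genome),
               genome_length = unname(config$genome),
               n_cgi = config$n_cgi,
               nucleation_fraction = config$nucleation_fraction,
               peak_width = config$peak_width,
               spread_length = config$spread_length,
               depth = config$depth,
               spike_fraction = config$spike_fraction,
               abundance_ratio = config$abundance_ratio,
               background_rate = config$background_rate,
               enrichment_rate = config$enrichment_rate,
               n_genes = config$n_genes,
               de_up = config$de_spec$n_up,
               de_down = config$de_spec$n_down,
               low_coverage_fraction = config$low_coverage_fraction,
               n_blacklist = config$n_blacklist,
               pmd_chrom = config$pmd_spec$chrom,
               pmd_start = config$pmd_spec$start,
               pmd_end = config$pmd_spec$end,
               pmd_mean_meth = config$pmd_spec$mean_meth)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a SimulationConfig written by [write_sim_config()]
#' @param path YAML path.
#' @return A `SimulationConfig`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  pmd <- if (length(y$pmd_chrom))
    data.frame(chrom = y$pmd_chrom, start = y$pmd_start, end = y$pmd_end,
               mean_meth = y$pmd_mean_meth, stringsAsFactors = FALSE)
  else data.frame(chrom = character(0), start = numeric(0),
                  end = numeric(0), mean_meth = numeric(0))
  sim_config(seed = y$seed,
             genome = genome_description(y$genome_chrom, y$genome_length),
             n_cgi = y$n_cgi, nucleation_fraction = y$nucleation_fraction,
             peak_width = y$peak_width, spread_length = y$spread_length,
             pmd_spec = pmd, depth = y$depth,
             spike_fraction = y$spike_fraction,
             abundance_ratio = y$abundance_ratio,
             background_rate = y$background_rate,
             enrichment_rate = y$enrichment_rate, n_genes = y$n_genes,
             de_spec = list(n_up = y$de_up, n_down = y$de_down),
             low_coverage_fraction = y$low_coverage_fraction,
             n_blacklist = y$n_blacklist)
}
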