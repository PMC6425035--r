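## ---------------------------------------------------------------------------
## File-level pipeline commands
##
## Thin orchestration over the module functions: each run_* command reads
## and writes the plain-text formats the readers and writers define, logs
## to stderr, and drops a manifest of the constants used next to its
## outputs, so a fixed config and seed reproduce every report byte for
## byte.
## ---------------------------------------------------------------------------

log_msg <- function(...) message("[rxdomains] ", ...)

write_manifest <- function(out_dir, entries) {
  yaml::write_yaml(entries, file.path(out_dir, "manifest.yaml"))
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

write_tsv <- function(df, path, col.names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

#' Generate and write a complete synthetic dataset
#'
#' Emits annotations (BED), per-sample tag BEDs with a spike-in totals TSV,
#' the methylome TSV, the expression table, the ground-truth config and a
#' manifest, so the whole pipeline can be driven from files.
#'
#' @param config A `SimulationConfig`.
#' @param out_dir Output directory (created if missing).
#' @return The `SimulatedDataset`, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  ensure_dir(out_dir)
  log_msg("simulating dataset with seed ", config$seed)
  sim <- simulate_dataset(config)
  ann <- sim$annotations
  write_bed(ann$cgis, file.path(out_dir, "cgis.bed"))
  write_tsv(data.frame(name = mcols(ann$cgis)$name,
                       nucleation = mcols(ann$cgis)$nucleation,
                       dna_methylation = mcols(ann$cgis)$dna_methylation),
            file.path(out_dir, "cgi_meta.tsv"))
  write_bed(ann$suz12_peaks, file.path(out_dir, "suz12_peaks.bed"))
  write_bed(ann$promoters, file.path(out_dir, "promoters.bed"))
  write_bed(ann$blacklist, file.path(out_dir, "blacklist.bed"))
  write_bed(ann$wt_me3_footprint, file.path(out_dir, "wt_me3_footprint.bed"))
  writeLines(paste(names(config$genome), config$genome, sep = "\t"),
             file.path(out_dir, "chrom.sizes"))
  spike <- data.frame(sample = names(sim$samples),
                      target_reads = vapply(sim$samples, `[[`, 0, "n_target"),
                      spike_reads = vapply(sim$samples, `[[`, 0, "n_spike"))
  write_tsv(spike, file.path(out_dir, "spike_totals.tsv"))
  for (nm in names(sim$samples))
    write_tags_bed(sim$samples[[nm]],
                   file.path(out_dir, paste0("tags_", nm, ".bed")))
  write_cpg_table(sim$methylome, file.path(out_dir, "methylome.tsv"))
  write_de_table(sim$expression, file.path(out_dir, "expression.tsv"))
  write_sim_config(config, file.path(out_dir, "truth_config.yaml"))
  write_manifest(out_dir, list(command = "simulate", seed = config$seed,
                               n_samples = length(sim$samples),
                               n_cgi = config$n_cgi,
                               depth = config$depth))
  log_msg("wrote ", length(sim$samples), " samples to ", out_dir)
  invisible(sim)
}

#' ChIP comparison report for a simulated (or loaded) dataset
#'
#' Computes, for the me3 mark in both regimes: per-sample ChIP-Rx ratios,
#' top-1% 1-kb bin scores, read proportions in SUZ12 peaks / CGIs /
#' promoters, the CGI difference plot with categories (single-WT form,
#' blacklist-filtered regions), the 1000-window spread-correlation table,
#' and the SUZ12-centered aggregate profile of K27M me3. All tables are
#' written as TSV.
#'
#' @param sim A `SimulatedDataset` (from [run_simulate()] or
#'   [simulate_dataset()]).
#' @param out_dir Output directory.
#' @param thresholds `CategoryThresholds` for the difference plot.
#' @param cfg `NormalizationConfig`.
#' @return Named list of the computed tables, invisibly.
#' @export
run_chip_compare <- function(sim, out_dir,
                             thresholds = category_thresholds("BT245-CGI"),
                             cfg = norm_config()) {
  ensure_dir(out_dir)
  genome <- sim$truth$genome
  ann <- sim$annotations
  need <- c("WT_me3", "K27M_me3", "WT_me2", "K27M_me2", "WT_input",
            "K27M_input")
  miss <- setdiff(need, names(sim$samples))
  if (length(miss)) stop("missing sample(s): ", paste(miss, collapse = ", "))
  s <- sim$samples
  spike_stats <- lapply(s, function(tc) {
    if (tc$n_spike <= 0) stop("missing spike-in totals for a sample")
    spike_in_stats(tc$n_target, tc$n_spike)
  })
  rx <- c(WT_me3 = rx_ratio(spike_stats$WT_me3, spike_stats$WT_input),
          K27M_me3 = rx_ratio(spike_stats$K27M_me3, spike_stats$K27M_input),
          WT_me2 = rx_ratio(spike_stats$WT_me2, spike_stats$WT_input),
          K27M_me2 = rx_ratio(spike_stats$K27M_me2, spike_stats$K27M_input))
  log_msg("Rx ratios: ", paste(names(rx), round(rx, 3), collapse = ", "))
  write_tsv(data.frame(sample = names(rx), rx = unname(rx)),
            file.path(out_dir, "rx_ratios.tsv"))

  bins1kb <- make_bins(genome, 1000)
  tr <- lapply(s[need], count_track, bins = bins1kb)
  top1 <- c(WT = top_percent_score(tr$WT_me3, tr$WT_input),
            K27M = top_percent_score(tr$K27M_me3, tr$K27M_input))
  write_tsv(data.frame(condition = names(top1), top1_score = unname(top1)),
            file.path(out_dir, "top1_scores.tsv"))

  feats <- list(suz12_peaks = ann$suz12_peaks, cgis = ann$cgis,
                promoters = ann$promoters)
  props <- do.call(rbind, lapply(names(feats), function(f)
    data.frame(feature = f,
               WT = proportion_in_features(s$WT_me3, feats[[f]]),
               K27M = proportion_in_features(s$K27M_me3, feats[[f]]))))
  write_tsv(props, file.path(out_dir, "feature_proportions.tsv"))

  cgis <- filter_blacklist(ann$cgis, ann$blacklist)
  diff <- diff_plot_coordinates(
    cgis,
    counts_k27m = count_tags_in_intervals(s$K27M_me3, cgis),
    total_k27m = s$K27M_me3$n_target,
    counts_wt = list(count_tags_in_intervals(s$WT_me3, cgis)),
    totals_wt = s$WT_me3$n_target,
    counts_input = list(count_tags_in_intervals(s$WT_input, cgis)),
    totals_input = s$WT_input$n_target,
    rx_k27m = rx[["K27M_me3"]], rx_wt = rx[["WT_me3"]], cfg = cfg)
  diff <- categorize(diff, thresholds)
  write_tsv(diff, file.path(out_dir, "cgi_diff_plot.tsv"))

  norm <- list(
    me2_k27m = input_normalize(tr$K27M_me2, tr$K27M_input, cfg),
    me3_wt = input_normalize(tr$WT_me3, tr$WT_input, cfg),
    me2_wt = input_normalize(tr$WT_me2, tr$WT_input, cfg))
  spread <- spread_correlation(norm$me2_k27m, norm$me3_wt, norm$me2_wt)
  write_tsv(spread, file.path(out_dir, "spread_windows.tsv"))

  bins500 <- make_bins(genome, 500)
  k27m_norm <- input_normalize_with_rx(count_track(s$K27M_me3, bins500),
                                       count_track(s$K27M_input, bins500),
                                       rx[["K27M_me3"]], cfg)
  prof <- aggregate_profile(k27m_norm, ann$suz12_peaks, flank = 5e4,
                            bin = 500)
  write_tsv(prof, file.path(out_dir, "suz12_profile_k27m_me3.tsv"))

  write_manifest(out_dir, list(command = "chip-compare",
                               thresholds = thresholds$preset,
                               pseudocount = cfg$pseudocount,
                               norm_factor = cfg$norm_factor,
                               top_pct = 1, n_windows = 1000,
                               profile_flank = 5e4, profile_bin = 500))
  invisible(list(rx = rx, top1 = top1, proportions = props, diff = diff,
                 spread = spread, profile = prof))
}

#' Call PMDs from a methylome and write them as BED3
#'
#' @param methylome CpG records data.frame, or path to a CpG TSV.
#' @param out_dir Output directory.
#' @param cfg `PMDCallerConfig`.
#' @param blacklist Optional GRanges excluded before calling.
#' @param snp_positions Optional SNP exclusions (see [filter_cpgs()]).
#' @return GRanges of PMDs, invisibly.
#' @export
run_pmd <- function(methylome, out_dir, cfg = pmd_config(),
                    blacklist = NULL, snp_positions = NULL) {
  ensure_dir(out_dir)
  if (is.character(methylome)) methylome <- read_cpg_table(methylome)
  if (nrow(methylome) == 0) {
    warning("empty methylome: writing empty PMD BED")
    pmds <- GRanges()
  } else {
    kept <- filter_cpgs(methylome, cfg, blacklist, snp_positions)
    log_msg("retained ", nrow(kept), " of ", nrow(methylome), " CpGs")
    pmds <- call_pmds(kept, cfg)
  }
  write_bed(pmds, file.path(out_dir, "pmds.bed"))
  write_manifest(out_dir, list(command = "pmd", window = cfg$window,
                               increment = cfg$increment,
                               threshold = cfg$threshold,
                               min_length = cfg$min_length,
                               min_coverage = cfg$min_coverage,
                               n_pmds = length(pmds)))
  log_msg("called ", length(pmds), " PMD(s)")
  invisible(pmds)
}

#' Transcriptome summaries: DE classification, decile counts, cross-tab
#'
#' @param expression DE records data.frame or path to a DE TSV.
#' @param out_dir Output directory.
#' @param promoter_categories Optional per-gene categories for the
#'   category-by-DE cross-tab.
#' @param lfc_cut,alpha Classification thresholds (see [classify_de()]).
#' @return List with `records`, `deciles`, and `crosstab` (when categories
#'   given), invisibly.
#' @export
run_transcriptome <- function(expression, out_dir,
                              promoter_categories = NULL, lfc_cut = 1,
                              alpha = 0.05) {
  ensure_dir(out_dir)
  if (is.character(expression)) expression <- read_de_table(expression)
  rec <- classify_de(expression, lfc_cut = lfc_cut, alpha = alpha)
  write_de_table(rec, file.path(out_dir, "de_classified.tsv"))
  dec <- decile_counts(rec)
  write_tsv(cbind(decile = 1:10, dec), file.path(out_dir,
                                                 "decile_counts.tsv"))
  ct <- NULL
  if (!is.null(promoter_categories)) {
    ct <- category_de_crosstab(promoter_categories, rec$de_label)
    write_tsv(ct, file.path(out_dir, "category_de_crosstab.tsv"))
  }
  write_manifest(out_dir, list(command = "transcriptome",
                               lfc_cut = lfc_cut, alpha = alpha,
                               n_up = sum(rec$de_label == "Up"),
                               n_down = sum(rec$de_label == "Down")))
  log_msg(sum(rec$de_label == "Up"), " Up / ",
          sum(rec$de_label == "Down"), " Down genes")
  invisible(list(records = rec, deciles = dec, crosstab = ct))
}
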