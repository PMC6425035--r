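## ---------------------------------------------------------------------------
## Downstream transcriptome and viability summaries
## ---------------------------------------------------------------------------

#' Classify differential-expression records
#'
#' Up: log2FC > `lfc_cut` and padj < `alpha`; Down: log2FC < -`lfc_cut` and
#' padj < `alpha`; otherwise NS. Records with missing padj are skipped with
#' a warning giving their count and labelled NS.
#'
#' @param records data.frame with columns `log2fc` and `padj`.
#' @param lfc_cut log2 fold-change threshold (default 1).
#' @param alpha Adjusted p-value threshold (default 0.05).
#' @return `records` with a `de_label` column in {Up, Down, NS}.
#' @export
classify_de <- function(records, lfc_cut = 1, alpha = 0.05) {
  miss <- is.na(records$padj)
  if (any(miss))
    warning(sum(miss), " record(s) with missing padj skipped")
  lab <- rep("NS", nrow(records))
  lab[!miss & records$log2fc > lfc_cut & records$padj < alpha] <- "Up"
  lab[!miss & records$log2fc < -lfc_cut & records$padj < alpha] <- "Down"
  records$de_label <- lab
  records
}

#' Assign genes to expression deciles
#'
#' Deciles are equal-count groups over the parental expression of all
#' genes; ties at a boundary go to the lower decile (genes tied in
#' expression share the decile of the lowest rank among them).
#'
#' @param expression Numeric vector of parental expression values.
#' @return Integer decile 1 (lowest) .. 10 (highest) per gene.
#' @export
expression_deciles <- function(expression) {
  n <- length(expression)
  r <- rank(expression, ties.method = "min") - 1
  as.integer(pmin((r * 10) %/% n + 1, 10))
}

#' Count DE genes per parental-expression decile
#'
#' Deciles are computed from the parental expression of all genes, then DE
#' genes are tallied per decile and direction. Row sums over deciles equal
#' the total Up and Down counts.
#'
#' @param records data.frame with `parental_expression` and `de_label`
#'   columns (see [classify_de()]).
#' @return 10 x 2 data.frame with columns `Up`, `Down`, rows decile 1..10.
#' @export
decile_counts <- function(records) {
  if (nrow(records) < 10) stop("need at least 10 genes to form deciles")
  dec <- expression_deciles(records$parental_expression)
  out <- data.frame(
    Up = vapply(1:10, function(d)
      sum(dec == d & records$de_label == "Up"), 0L),
    Down = vapply(1:10, function(d)
      sum(dec == d & records$de_label == "Down"), 0L))
  rownames(out) <- paste0("decile_", 1:10)
  out
}

#' Cross-tabulate promoter categories with DE direction
#'
#' @param promoter_categories Character/factor of categories per gene, in
#'   {Gained, Absent, Lost, Retained, Unclassified}; names or order must
#'   match `de_labels`.
#' @param de_labels Character of DE labels per gene in {Up, Down, NS}.
#' @return data.frame per category (Gained, Absent, Lost, Retained):
#'   `n_up`, `n_down`, `n_total`, `prop_up`, `prop_down`.
#' @export
category_de_crosstab <- function(promoter_categories, de_labels) {
  cats <- c("Gained", "Absent", "Lost", "Retained")
  pc <- as.character(promoter_categories)
  if (length(pc) != length(de_labels))
    stop("category and label vectors differ in length")
  if (any(!pc %in% c(cats, "Unclassified")))
    stop("unknown category label: ",
         paste(unique(pc[!pc %in% c(cats, "Unclassified")]), collapse = ", "))
  if (any(!de_labels %in% c("Up", "Down", "NS")))
    stop("unknown DE label")
  out <- do.call(rbind, lapply(cats, function(cc) {
    sel <- pc == cc
    n <- sum(sel)
    data.frame(category = cc,
               n_up = sum(sel & de_labels == "Up"),
               n_down = sum(sel & de_labels == "Down"),
               n_total = n,
               prop_up = if (n) sum(sel & de_labels == "Up") / n else 0,
               prop_down = if (n) sum(sel & de_labels == "Down") / n else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cell viability percentage from Alamar Blue absorbances
#'
#' Percentage difference between treated and control cells:
#' 100 * (O2*A1 - O1*A2) / (O2*P1 - O1*P2), with O1 = 80586 and O2 = 117216
#' the molar extinction coefficients of oxidized Alamar Blue at 570 and
#' 600 nm.
#'
#' @param A1,A2 Test-well absorbances at 570 and 600 nm.
#' @param P1,P2 Positive-control (untreated) absorbances at 570 and 600 nm.
#' @param O1,O2 Extinction coefficients (defaults 80586, 117216).
#' @return Viability percentage (100 when test equals control).
#' @export
viability_percent <- function(A1, A2, P1, P2, O1 = 80586, O2 = 117216) {
  den <- O2 * P1 - O1 * P2
  if (any(den == 0)) stop("zero denominator: control absorbances degenerate")
  (O2 * A1 - O1 * A2) / den * 100
}

#' Read a differential-expression table from TSV
#' @param path TSV with header columns gene, log2fc, padj,
#'   parental_expression.
#' @return data.frame of DE records.
#' @export
read_de_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj", "parental_expression")
  if (!all(need %in% names(df)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a differential-expression table to TSV
#' @param records DE records data.frame.
#' @param path Output path.
#' @export
write_de_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
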