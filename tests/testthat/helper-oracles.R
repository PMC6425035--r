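# Independent brute-force oracles. Deliberately naive: plain loops and
# arithmetic on 0-based half-open coordinates, no shared code with the
# package internals.

# tags: named list chrom -> positions; intervals: data.frame(chrom, start, end)
oracle_count_tags <- function(tags, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    p <- tags[[intervals$chrom[i]]]
    if (is.null(p)) return(0L)
    sum(p >= intervals$start[i] & p < intervals$end[i])
  }, integer(1))
}

# both data.frames (chrom, start, end); returns logical keep vector
oracle_blacklist_keep <- function(intervals, blacklist) {
  vapply(seq_len(nrow(intervals)), function(i) {
    for (j in seq_len(nrow(blacklist))) {
      if (intervals$chrom[i] == blacklist$chrom[j] &&
          intervals$start[i] < blacklist$end[j] &&
          blacklist$start[j] < intervals$end[i]) return(FALSE)
    }
    TRUE
  }, logical(1))
}

# full sort then mean of top ceil(pct/100 * N) differences
oracle_top_percent <- function(diffs, pct = 1) {
  s <- sort(diffs, decreasing = TRUE)
  mean(s[seq_len(ceiling(pct / 100 * length(s)))])
}

# decile by counting strictly smaller values
oracle_deciles <- function(x) {
  n <- length(x)
  vapply(x, function(v) {
    r <- sum(x < v)
    as.integer(min((r * 10) %/% n + 1, 10))
  }, integer(1))
}

# Seed-and-extend PMD oracle: every increment-grid window is tested as a
# seed; extension adds increments whose own CpG mean stays below the
# threshold (empty increments neutral); overlapping/bookended candidates
# merged; strict length filter.  Works on one chromosome.
oracle_pmds_one_chrom <- function(pos, meth, cfg) {
  wmean <- function(from, to) {
    sel <- pos >= from & pos < to
    if (!any(sel)) return(NA_real_)
    mean(meth[sel])
  }
  chrom_end <- max(pos) + 1
  grid <- seq(0, max(pos), by = cfg$increment)
  cand <- list()
  covered_to <- -Inf
  for (s in grid) {
    if (s < covered_to) next
    m <- wmean(s, s + cfg$window)
    if (is.na(m) || m >= cfg$threshold) next
    e <- s + cfg$window
    while (e < chrom_end) {
      m_inc <- wmean(e, e + cfg$increment)
      if (!is.na(m_inc) && m_inc >= cfg$threshold) break
      e <- e + cfg$increment
    }
    cand[[length(cand) + 1]] <- c(s, e)
    covered_to <- e
  }
  if (!length(cand)) return(data.frame(start = numeric(0), end = numeric(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1]), , drop = FALSE]
  merged <- list(cand[1, ])
  for (i in seq_len(nrow(cand))[-1]) {
    last <- merged[[length(merged)]]
    if (cand[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], cand[i, 2]))
    } else merged[[length(merged) + 1]] <- cand[i, ]
  }
  merged <- do.call(rbind, merged)
  keep <- (merged[, 2] - merged[, 1]) > cfg$min_length
  data.frame(start = merged[keep, 1], end = merged[keep, 2])
}
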