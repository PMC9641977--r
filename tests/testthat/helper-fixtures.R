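# Shared fixtures and independent oracles, built in code at test time.

# small two-chromosome simulation config used across modules
small_config <- function(seed = 42, ...) {
  sim_config(
    seed = seed, n_chromosomes = 2L, chrom_length = 20000L,
    feature_counts = c(protein_coding = 8L, pseudogene = 2L, transposon = 2L,
                       "repeat" = 2L, miRNA = 3L, rRNA = 1L, tRNA = 1L,
                       ncRNA = 1L),
    piRNA_cluster_layout = data.frame(chrom = "chrI", start = 14000L,
                                      end = 18000L, n_loci = 5L),
    library_size = 1500L,
    samples = default_design(replicates = 2L),
    ...)
}

# brute-force substring search oracle, independent of the Biostrings path:
# every perfect placement of `read` on either strand of `genome`
naive_locate <- function(genome, read) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out <- list()
  for (ch in names(genome)) {
    for (q in list(c(read, "+"), c(rc, "-"))) {
      # scan from each hit + 1 so overlapping occurrences are found too
      all_m <- integer()
      start_at <- 1L
      while (TRUE) {
        hit <- regexpr(q[1], substr(genome[[ch]], start_at,
                                    nchar(genome[[ch]])), fixed = TRUE)
        if (hit < 0) break
        all_m <- c(all_m, start_at + hit - 1L)
        start_at <- start_at + hit
      }
      if (length(all_m))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = all_m, strand = q[2], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), ]
}

# exhaustive per-read, per-feature containment enumeration oracle for
# fractional counting (loops only; no interval trees)
naive_count <- function(placements, features) {
  rows <- list()
  for (rid in unique(placements$read_id)) {
    p <- placements[placements$read_id == rid, , drop = FALSE]
    for (cl in unique(features$class)) {
      f <- features[features$class == cl, , drop = FALSE]
      hits <- list()
      covered_placements <- logical(nrow(p))
      for (i in seq_len(nrow(p))) for (k in seq_len(nrow(f))) {
        if (p$chrom[i] == f$chrom[k] && p$start[i] >= f$start[k] &&
            p$end[i] <= f$end[k]) {
          covered_placements[i] <- TRUE
          hits[[length(hits) + 1L]] <- c(i, k)
        }
      }
      N <- sum(covered_placements)
      for (h in hits) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = rid, sample = p$sample[h[1]],
          feature_id = f$feature_id[h[2]],
          orientation = if (p$strand[h[1]] == f$strand[h[2]]) "sense"
          else "antisense",
          count = 1 / N, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(feature_id = character(), sample = character(),
                      orientation = character(), count = numeric()))
  long <- do.call(rbind, rows)
  stats::aggregate(count ~ sample + feature_id + orientation, data = long,
                   FUN = sum)
}

# exact hypergeometric upper tail P(X >= k) by enumerating all C(N, nA) draws
enum_hyper_p <- function(k, nB, N, nA) {
  draws <- utils::combn(N, nA)
  mean(colSums(draws <= nB) >= k)
}

# exact two-sided Wilcoxon rank-sum p by enumerating all rank assignments
enum_wilcox_p <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  all_w <- apply(utils::combn(n + m, n), 2, function(ix)
    sum(rank(seq_len(n + m))[ix]) - n * (n + 1) / 2)
  mean(abs(all_w - n * m / 2) >= abs(w_obs - n * m / 2) - 1e-9)
}
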