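# Small RNA read and count simulation with truth tables.
#
# Per feature and sample, fragment counts are negative binomial with mean
# baseline x fold-changes x library-size factor and the configured
# dispersion (dispersion 0 = deterministic rounded means).  Reads from
# RdRP-templated classes (protein-coding genes, pseudogenes, repeats,
# transposons) are placed antisense to the feature; microRNA, piRNA and
# structural RNA reads are sense, anchored at the locus 5' end.  The class 5'
# nucleotide signature (G for 22G/26G, T for 21U) is realised by anchoring
# reads at genomic positions whose strand-aware base already carries the
# signature, so every simulated read still aligns perfectly.

# multiplicative fold for one feature in one condition
effect_fold <- function(effect_table, feature_id, class, genotype,
                        temperature) {
  if (is.null(effect_table) || !nrow(effect_table)) return(1)
  sel <- (effect_table$target == feature_id | effect_table$target == class) &
    (is.na(effect_table$genotype) | effect_table$genotype == genotype) &
    (is.na(effect_table$temperature) |
       effect_table$temperature == temperature)
  prod(effect_table$fold[sel])
}

# expected count matrix (features x samples) and the fold table
expected_counts <- function(config, features) {
  base <- unname(config$baseline_mean[features$class])
  if (any(is.na(base)))
    stopf("no baseline_mean for class(es): %s",
          paste(unique(features$class[is.na(base)]), collapse = ", "))
  scale <- config$library_size / sum(base)
  samples <- config$samples
  mu <- matrix(0, nrow(features), nrow(samples),
               dimnames = list(features$feature_id, samples$sample))
  folds <- matrix(1, nrow(features), nrow(samples))
  for (j in seq_len(nrow(samples))) {
    f <- vapply(seq_len(nrow(features)), function(i)
      effect_fold(config$effect_table, features$feature_id[i],
                  features$class[i], samples$genotype[j],
                  samples$temperature[j]), numeric(1))
    folds[, j] <- f
    mu[, j] <- base * f * scale
  }
  list(mu = mu, folds = folds)
}

#' Simulate feature counts only (no reads)
#'
#' Fast count-level path sharing the read simulator's mean/dispersion model:
#' per feature and sample, counts are NB(mean = baseline x fold x library
#' scale, size = 1/dispersion), or deterministically rounded means when
#' `dispersion = 0`.
#'
#' @param config A [sim_config()].
#' @param features Optional feature table; defaults to ids fabricated from
#'   `config$feature_counts` (no genome needed).
#' @return List with `counts` (feature x sample matrix), `mu` (NB means),
#'   `folds` (true fold matrix), `features`, `design`.
#' @export
simulate_counts <- function(config, features = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(features)) {
    fc <- config$feature_counts
    features <- data.frame(
      feature_id = unlist(lapply(names(fc), function(cl)
        sprintf("%s%04d", ID_PREFIXES[[cl]], seq_len(fc[[cl]])))),
      class = rep(names(fc), fc), stringsAsFactors = FALSE)
  }
  ec <- expected_counts(config, features)
  counts <- ec$mu
  if (config$dispersion > 0) {
    counts[] <- stats::rnbinom(length(ec$mu), mu = ec$mu,
                               size = 1 / config$dispersion)
  } else {
    counts[] <- round(ec$mu)
  }
  list(counts = counts, mu = ec$mu, folds = ec$folds, features = features,
       design = config$samples)
}

# draw k reads from one feature; returns start/end/strand/seq
draw_feature_reads <- function(chromseq, f, k, profile) {
  flen <- f$end - f$start + 1L
  antisense <- f$class %in% ANTISENSE_CLASSES
  if (!antisense) {
    # sense read anchored at the locus 5' end
    L <- if (f$class %in% c("miRNA", "piRNA")) rep(flen, k) else
      pmin(sample(profile$lengths, k, replace = TRUE, prob = profile$probs),
           flen)
    if (f$class == "piRNA" && flen != 21L)
      stopf("piRNA locus %s is not 21 bp", f$feature_id)
    if (f$strand == "+") {
      s <- rep(f$start, k); e <- f$start + L - 1L
      seqs <- substring(chromseq, s, e)
    } else {
      e <- rep(f$end, k); s <- f$end - L + 1L
      seqs <- revcomp(substring(chromseq, s, e))
    }
    return(data.frame(start = s, end = e,
                      strand = rep(f$strand, k), seq = seqs,
                      stringsAsFactors = FALSE))
  }
  # antisense read with forced 5' signature via anchor-site selection
  if (min(profile$lengths) > flen)
    stopf("requested read longer than feature %s (%d bp)", f$feature_id, flen)
  fchars <- strsplit(substr(chromseq, f$start, f$end), "", fixed = TRUE)[[1]]
  nt5 <- profile$nt5
  L <- sample(profile$lengths, k, replace = TRUE, prob = profile$probs)
  L[L > flen] <- flen
  if (f$strand == "+") {
    # read on '-': 5' base is comp(base at read end) => genomic base comp(nt5)
    cand <- which(fchars == comp_base(nt5))   # candidate end offsets
    s <- e <- integer(k); strand <- rep("-", k)
    for (i in seq_len(k)) {
      ok <- cand[cand >= L[i]]
      off <- if (length(ok)) sample_one(ok) else sample_one(L[i]:flen)
      e[i] <- f$start + off - 1L
      s[i] <- e[i] - L[i] + 1L
    }
    seqs <- revcomp(substring(chromseq, s, e))
  } else {
    # read on '+': 5' base is the genomic base at the read start
    cand <- which(fchars == nt5)              # candidate start offsets
    s <- e <- integer(k); strand <- rep("+", k)
    for (i in seq_len(k)) {
      ok <- cand[cand <= flen - L[i] + 1L]
      off <- if (length(ok)) sample_one(ok) else sample_one(1:(flen - L[i] + 1L))
      s[i] <- f$start + off - 1L
      e[i] <- s[i] + L[i] - 1L
    }
    seqs <- substring(chromseq, s, e)
  }
  data.frame(start = s, end = e, strand = strand, seq = seqs,
             stringsAsFactors = FALSE)
}

# sample() misbehaves on length-1 vectors
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Simulate per-sample small RNA reads with full truth tables
#'
#' Tropical samples draw reads from the reference genome/annotation;
#' temperate samples from the variant-substituted pseudo-reference and its
#' lifted annotation (features that fail liftover produce no temperate
#' reads).  Per-feature counts follow the NB model of [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @param ag An `annotated_genome` from [simulate_reference()].
#' @param variants Variant table from [simulate_variants()] (or `NULL` for a
#'   single-genome simulation).
#' @return List with `reads` (one row per read: `read_id`, `sample`,
#'   `feature_id`, `feature_class`, `read_class`, `chrom`, `start`, `end`,
#'   `strand`, `seq`), `counts` (observed feature x sample matrix), `mu`
#'   (NB means), `folds`, `design`, and `pseudo` (the temperate
#'   pseudo-reference bundle, when variants were supplied).
#' @export
simulate_reads <- function(config, ag, variants = NULL) {
  set.seed(config$seed + 3L)
  pseudo <- NULL
  if (!is.null(variants) && nrow(variants)) {
    pr <- apply_variants(ag$genome, variants)
    lift <- lift_annotations(ag$features, ag$parts, pr$map, pr$genome)
    pseudo <- list(genome = pr$genome, map = pr$map,
                   features = lift$features, parts = lift$parts,
                   report = lift$report)
  }
  cnt <- simulate_counts(config, ag$features)
  samples <- config$samples
  all_reads <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    temperate <- samples$genotype[j] == "temperate" && !is.null(pseudo)
    feats <- if (temperate) pseudo$features else ag$features
    genome <- if (temperate) pseudo$genome else ag$genome
    rows <- list()
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      k <- cnt$counts[f$feature_id, samples$sample[j]]
      if (is.na(k) || k < 1) next
      profile <- config$class_length_profiles[[f$class]]
      if (is.null(profile)) stopf("no length profile for class %s", f$class)
      r <- draw_feature_reads(genome[[f$chrom]], f, as.integer(k), profile)
      r$feature_id <- f$feature_id
      r$feature_class <- f$class
      r$chrom <- f$chrom
      rows[[i]] <- r
    }
    if (!length(rows)) next
    r <- do.call(rbind, rows)
    r$sample <- samples$sample[j]
    r$read_id <- sprintf("%s.%06d", samples$sample[j], seq_len(nrow(r)))
    all_reads[[j]] <- r
  }
  reads <- do.call(rbind, all_reads)
  rownames(reads) <- NULL
  len <- nchar(reads$seq)
  nt5 <- substr(reads$seq, 1L, 1L)
  reads$read_class <- ifelse(reads$feature_class == "miRNA", "miRNA",
    ifelse(reads$feature_class == "piRNA" & len == 21L & nt5 == "T",
           "piRNA_21U",
    ifelse(len >= 21L & len <= 23L & nt5 == "G", "siRNA_22G",
    ifelse(len >= 25L & len <= 27L & nt5 == "G", "siRNA_26G", "other"))))
  reads <- reads[, c("read_id", "sample", "feature_id", "feature_class",
                     "read_class", "chrom", "start", "end", "strand", "seq")]
  list(reads = reads, counts = cnt$counts, mu = cnt$mu, folds = cnt$folds,
       design = samples, pseudo = pseudo)
}

#' Write the truth tables of a simulation as TSV
#'
#' One file per table: per-read truth, expected (NB mean) counts per feature
#' and sample, and true fold-changes.  Coordinates are 1-based inclusive.
#'
#' @param sim Result of [simulate_reads()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, prefix) {
  p1 <- paste0(prefix, ".truth_reads.tsv")
  p2 <- paste0(prefix, ".truth_means.tsv")
  p3 <- paste0(prefix, ".truth_folds.tsv")
  utils::write.table(sim$reads, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mm <- data.frame(feature_id = rownames(sim$mu), sim$mu, check.names = FALSE)
  utils::write.table(mm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  ff <- data.frame(feature_id = rownames(sim$mu), sim$folds)
  colnames(ff)[-1] <- colnames(sim$mu)
  utils::write.table(ff, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Run the full synthetic pipeline: genome, variants, pseudo-reference, reads
#'
#' @param config A [sim_config()].
#' @param forced_variants Optional forced variant table (see
#'   [simulate_variants()]).
#' @return List with `reference` (`annotated_genome`), `variants`, and all
#'   [simulate_reads()] components.
#' @export
simulate_dataset <- function(config, forced_variants = NULL) {
  ag <- simulate_reference(config)
  variants <- simulate_variants(config, ag, forced = forced_variants)
  sim <- simulate_reads(config, ag, variants)
  c(list(reference = ag, variants = variants), sim)
}
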