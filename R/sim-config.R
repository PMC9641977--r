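#' Simulation configuration for two-strain small RNA experiments
#'
#' Builds the configuration object consumed by [simulate_reference()],
#' [simulate_variants()], [simulate_reads()] and [simulate_counts()].  The
#' defaults describe the study design the generator emulates: two strain
#' genotypes (`tropical`, `temperate`) reared at 14, 20 and 30 degrees C with
#' three replicates each, small RNA classes with their characteristic read
#' length and 5' nucleotide signatures, clustered 21 bp piRNA loci starting
#' with T, and a multiplicative effect table whose default entry is a 2.3-fold
#' reduction of protein-coding-gene antisense 22G-RNAs in the temperate
#' genotype at 30 degrees.
#'
#' @param seed Integer seed governing every random draw made with this config.
#' @param n_chromosomes Number of chromosomes in the toy genome.
#' @param chrom_length Length of each chromosome in bp (scalar or vector).
#' @param feature_counts Named integer vector of features to place per class.
#'   Allowed names: `r paste(FEATURE_CLASSES, collapse = ", ")`.
#' @param piRNA_cluster_layout Data frame with columns `chrom`, `start`,
#'   `end`, `n_loci` describing genomic piRNA clusters.  piRNA loci are placed
#'   only inside these intervals.
#' @param variant_density Named numeric vector `c(snp_per_kb=, indel_per_kb=)`.
#' @param samples Data frame with columns `sample`, `genotype`, `temperature`,
#'   `replicate`.  Defaults to the full 2 x 3 x 3 design.
#' @param library_size Expected fragments per sample.
#' @param baseline_mean Named numeric vector of expected per-feature fragment
#'   weights per class; scaled jointly so per-sample totals match
#'   `library_size`.
#' @param dispersion Negative-binomial dispersion of per-feature counts
#'   (`size = 1/dispersion`); `0` gives deterministic rounded means.
#' @param effect_table Data frame with columns `target` (a feature id or a
#'   feature class name), `genotype`, `temperature`, `fold` of multiplicative
#'   fold-changes (> 0) applied to the NB means.
#' @param class_length_profiles Named list; per class a list with `lengths`,
#'   `probs` and `nt5` (the forced 5' nucleotide, or `NA` for none).
#' @param multimap_fraction Fraction of features per class duplicated to a
#'   second locus so their reads multi-map.
#' @param adapter_3p,adapter_5p Adapter nucleotide strings used when writing
#'   raw (untrimmed) FASTQ.
#' @param barcodes Character vector of unique 4 nt sample barcodes (nine by
#'   default).
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, chrom_length = 20000,
#'                   feature_counts = c(protein_coding = 10, miRNA = 2))
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 50000L,
                       feature_counts = c(protein_coding = 30L, pseudogene = 6L,
                                          transposon = 4L, "repeat" = 4L,
                                          miRNA = 8L, rRNA = 2L, tRNA = 2L,
                                          ncRNA = 2L),
                       piRNA_cluster_layout = data.frame(
                         chrom = "chrI", start = 34000L, end = 44000L,
                         n_loci = 20L),
                       variant_density = c(snp_per_kb = 1, indel_per_kb = 0.2),
                       samples = default_design(),
                       library_size = 20000L,
                       baseline_mean = c(protein_coding = 30, pseudogene = 12,
                                         transposon = 10, "repeat" = 10,
                                         miRNA = 120, piRNA = 6, rRNA = 8,
                                         tRNA = 8, ncRNA = 8),
                       dispersion = 0.05,
                       effect_table = data.frame(
                         target = "protein_coding", genotype = "temperate",
                         temperature = 30, fold = 1 / 2.3),
                       class_length_profiles = default_length_profiles(),
                       multimap_fraction = 0,
                       adapter_3p = "CTGTAGGCACCATCAAT",
                       adapter_5p = "TCTACAGTCCGACGATC",
                       barcodes = default_barcodes()) {
  chrom_length <- rep_len(as.integer(chrom_length), n_chromosomes)
  if (any(chrom_length <= 0L)) stopf("chromosome lengths must be positive")
  if (length(feature_counts)) {
    bad <- setdiff(names(feature_counts), FEATURE_CLASSES)
    if (length(bad)) stopf("unknown feature classes: %s", paste(bad, collapse = ", "))
  }
  if (!all(samples$temperature %in% c(14, 20, 30)))
    stopf("temperatures must be drawn from 14, 20, 30")
  if (!all(samples$genotype %in% c("tropical", "temperate")))
    stopf("genotypes must be 'tropical' or 'temperate'")
  if (nrow(effect_table) && any(effect_table$fold <= 0))
    stopf("fold-changes must be > 0")
  if (any(nchar(barcodes) != 4L)) stopf("barcodes must be 4 nt")
  if (anyDuplicated(barcodes)) stopf("barcodes must be unique")
  if (any(variant_density < 0)) stopf("variant densities must be >= 0")
  if (library_size <= 0) stopf("library_size must be positive")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, feature_counts = feature_counts,
    piRNA_cluster_layout = piRNA_cluster_layout,
    variant_density = variant_density, samples = samples,
    library_size = library_size, baseline_mean = baseline_mean,
    dispersion = dispersion, effect_table = effect_table,
    class_length_profiles = class_length_profiles,
    multimap_fraction = multimap_fraction,
    adapter_3p = adapter_3p, adapter_5p = adapter_5p,
    barcodes = barcodes), class = "sim_config")
}

#' Default 2 genotypes x 3 temperatures x 3 replicates sample design
#'
#' @param genotypes,temperatures,replicates Levels crossed to form the design.
#' @return Data frame with columns `sample`, `genotype`, `temperature`,
#'   `replicate`.
#' @export
default_design <- function(genotypes = c("tropical", "temperate"),
                           temperatures = c(14, 20, 30),
                           replicates = 3L) {
  d <- expand.grid(replicate = seq_len(replicates),
                   temperature = temperatures,
                   genotype = genotypes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("genotype", "temperature", "replicate")]
  d$sample <- sprintf("%s_%d_r%d", substr(d$genotype, 1, 4),
                      d$temperature, d$replicate)
  d[, c("sample", "genotype", "temperature", "replicate")]
}

#' Default per-class read length / 5' nucleotide profiles
#'
#' Antisense siRNA template classes emit mostly 22G-RNAs (21-23 nt, 5' G) with
#' a minor 26G (25-27 nt, 5' G) component; piRNA loci emit exactly 21 nt reads
#' starting with T (U in RNA); microRNA and structural RNA loci emit sense
#' reads anchored at the locus start with no 5' constraint.
#'
#' @return Named list of per-class profiles.
#' @export
default_length_profiles <- function() {
  sirna <- list(lengths = c(21L, 22L, 23L, 25L, 26L, 27L),
                probs = c(0.18, 0.55, 0.18, 0.02, 0.05, 0.02),
                nt5 = "G")
  sense <- list(lengths = 20L:24L, probs = c(0.1, 0.2, 0.4, 0.2, 0.1), nt5 = NA)
  list(protein_coding = sirna, pseudogene = sirna, transposon = sirna,
       "repeat" = sirna,
       miRNA = sense, rRNA = sense, tRNA = sense, ncRNA = sense,
       piRNA = list(lengths = 21L, probs = 1, nt5 = "T"))
}

#' Default panel of nine 4-nucleotide multiplexing barcodes
#' @return Character vector of nine unique 4 nt barcodes.
#' @export
default_barcodes <- function() {
  c("ACGT", "CAGT", "GTCA", "TGAC", "AATC", "CCAG", "GGTA", "TTCG", "AGGA")
}
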