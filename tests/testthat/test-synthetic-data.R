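test_that("reference simulation is deterministic and honours piRNA rules", {
  cfg <- small_config()
  ag <- simulate_reference(cfg)

  pis <- ag$features[ag$features$class == "piRNA", ]
  expect_equal(nrow(pis), 5L)
  expect_true(all(pis$end - pis$start + 1L == 21L))
  first <- ifelse(pis$strand == "+",
                  substr(ag$genome[pis$chrom], pis$start, pis$start),
                  chartr("ACGT", "TGCA",
                         substr(ag$genome[pis$chrom], pis$end, pis$end)))
  expect_true(all(first == "T"))
  # clusters respected
  expect_true(all(pis$chrom == "chrI" & pis$start >= 14000 & pis$end <= 18000))

  # every protein-coding gene has >= 1 exon part; parts partition the gene
  genes <- ag$features[ag$features$class == "protein_coding", ]
  expect_true(all(genes$feature_id %in% ag$parts$feature_id))
  for (g in genes$feature_id) {
    pp <- ag$parts[ag$parts$feature_id == g, ]
    gg <- genes[genes$feature_id == g, ]
    expect_equal(sum(pp$end - pp$start + 1L), gg$end - gg$start + 1L)
  }

  # arm/center/arm partition covers each chromosome exactly
  for (ch in names(ag$genome)) {
    dd <- ag$domains[ag$domains$chrom == ch, ]
    expect_equal(dd$start[1], 1L)
    expect_equal(dd$end[nrow(dd)], nchar(ag$genome[[ch]]))
    expect_true(all(dd$start[-1] == dd$end[-nrow(dd)] + 1L))
    expect_equal(dd$domain, c("arm", "center", "arm"))
  }

  # byte-identical FASTA/GFF3 from the same seed
  d <- withr::local_tempdir()
  write_reference(simulate_reference(cfg), file.path(d, "a"))
  write_reference(simulate_reference(cfg), file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a.fa")),
                   readLines(file.path(d, "b.fa")))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
})

test_that("empty feature config yields unannotated-only territory", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 5000,
                    feature_counts = c(protein_coding = 0L),
                    piRNA_cluster_layout = NULL)
  ag <- simulate_reference(cfg)
  expect_equal(nrow(ag$features), 0L)
  expect_equal(nchar(ag$genome[["chrI"]]), 5000L)
})

test_that("infeasible feature packing raises a capacity error", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 2000,
                    feature_counts = c(protein_coding = 10L),
                    piRNA_cluster_layout = NULL)
  expect_error(simulate_reference(cfg), "capacity|too small")
})

test_that("variant simulation respects densities and forced variants", {
  cfg <- small_config()
  ag <- simulate_reference(cfg)

  # zero density -> empty variant set
  cfg0 <- small_config()
  cfg0$variant_density <- c(snp_per_kb = 0, indel_per_kb = 0)
  expect_equal(nrow(simulate_variants(cfg0, ag)), 0L)

  # counts reproduce the Poisson draws under the same seed
  v1 <- simulate_variants(cfg, ag)
  v2 <- simulate_variants(cfg, ag)
  expect_identical(v1, v2)
  set.seed(cfg$seed + 1L)
  expected_chr1 <- rpois(1L, cfg$variant_density[["snp_per_kb"]] *
                           nchar(ag$genome[[1]]) / 1000)
  expect_gte(expected_chr1, sum(v1$chrom == "chrI" & v1$type == "snp"))

  # REF matches genome; sorted; non-overlapping
  expect_true(all(substr(ag$genome[v1$chrom], v1$pos,
                         v1$pos + nchar(v1$ref) - 1L) == v1$ref))
  for (ch in unique(v1$chrom)) {
    vv <- v1[v1$chrom == ch, ]
    expect_true(all(diff(vv$pos) > 0))
    expect_true(all(vv$pos[-1] > (vv$pos + nchar(vv$ref) - 1L)[-nrow(vv)]))
  }

  # forced SNP at a piRNA first base appears at that coordinate
  pi1 <- ag$features[ag$features$class == "piRNA", ][1, ]
  pos <- if (pi1$strand == "+") pi1$start else pi1$end
  alt <- if (pi1$strand == "+") "C" else "G"
  vf <- simulate_variants(cfg, ag, forced = data.frame(
    chrom = pi1$chrom, pos = pos, alt = alt))
  hit <- vf[vf$chrom == pi1$chrom & vf$pos == pos, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$alt, alt)
})

test_that("zero-dispersion counts equal rounded NB means and respect folds", {
  cfg <- small_config()
  cfg$dispersion <- 0
  sim <- simulate_counts(cfg)
  expect_equal(sim$counts, round(sim$mu))

  # configured 2.3-fold reduction shows up exactly in the means
  des <- sim$design
  genes <- sim$features$feature_id[sim$features$class == "protein_coding"]
  s_ref <- des$sample[des$genotype == "temperate" & des$temperature == 20][1]
  s_eff <- des$sample[des$genotype == "temperate" & des$temperature == 30][1]
  expect_equal(sim$mu[genes, s_ref] / sim$mu[genes, s_eff],
               rep(2.3, length(genes)), ignore_attr = TRUE)

  # per-sample expected totals track the library size (all folds 1 sample)
  s_null <- des$sample[des$genotype == "tropical" & des$temperature == 20][1]
  expect_equal(sum(sim$mu[, s_null]), cfg$library_size, tolerance = 1e-9)
})

test_that("NB sampling matches its mean-variance law", {
  cfg <- sim_config(seed = 9, feature_counts = c(protein_coding = 1L),
                    samples = data.frame(sample = sprintf("s%03d", 1:400),
                                         genotype = "tropical",
                                         temperature = 20, replicate = 1:400),
                    library_size = 500L, dispersion = 0.1,
                    effect_table = data.frame(target = character(),
                                              genotype = character(),
                                              temperature = numeric(),
                                              fold = numeric()))
  sim <- simulate_counts(cfg)
  x <- sim$counts[1, ]
  mu <- sim$mu[1, 1]
  expect_equal(mean(x), mu, tolerance = 0.1)
  expect_equal(stats::var(x), mu + 0.1 * mu^2, tolerance = 0.25)
})

test_that("simulated reads carry correct truth and map back perfectly", {
  cfg <- small_config(seed = 77)
  cfg$library_size <- 600L
  cfg$samples <- default_design(replicates = 1L)
  ag <- simulate_reference(cfg)
  sim <- simulate_reads(cfg, ag, variants = NULL)

  # identical FASTQ bytes from the same seed
  d <- withr::local_tempdir()
  sim2 <- simulate_reads(cfg, ag, variants = NULL)
  write_fastq(sim$reads, file.path(d, "a.fq"))
  write_fastq(sim2$reads, file.path(d, "b.fq"))
  expect_identical(readLines(file.path(d, "a.fq")),
                   readLines(file.path(d, "b.fq")))

  # each read's sequence equals the strand-aware genomic substring
  r <- sim$reads[sim$reads$sample == sim$reads$sample[1], ]
  r <- r[sample.int(nrow(r), 50), ]
  sub <- substr(ag$genome[r$chrom], r$start, r$end)
  expected <- ifelse(r$strand == "-",
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAStringSet(sub))), sub)
  expect_equal(r$seq, unname(expected))

  # antisense classes are antisense to their feature; sense classes sense
  feats <- ag$features
  fs <- feats$strand[match(sim$reads$feature_id, feats$feature_id)]
  anti <- sim$reads$feature_class %in% c("protein_coding", "pseudogene",
                                         "transposon", "repeat")
  expect_true(all(sim$reads$strand[anti] != fs[anti]))
  expect_true(all(sim$reads$strand[!anti] == fs[!anti]))

  # class signatures: antisense-class reads start with G, piRNA reads are 21U
  nt5 <- substr(sim$reads$seq, 1, 1)
  expect_true(mean(nt5[anti] == "G") > 0.99)
  pi <- sim$reads$feature_class == "piRNA"
  expect_true(all(nchar(sim$reads$seq[pi]) == 21L & nt5[pi] == "T"))
})

test_that("duplicated features make their reads multi-map", {
  cfg <- sim_config(seed = 13, n_chromosomes = 1, chrom_length = 30000,
                    feature_counts = c("repeat" = 4L),
                    piRNA_cluster_layout = NULL,
                    multimap_fraction = 0.5, library_size = 200,
                    samples = default_design(replicates = 1L)[1, ])
  ag <- simulate_reference(cfg)
  expect_equal(sum(duplicated(ag$features$family)), 2L)
  sim <- simulate_reads(cfg, ag, variants = NULL)
  idx <- build_index(ag$genome)
  dup_feats <- ag$features$feature_id[
    ag$features$family %in% ag$features$family[duplicated(ag$features$family)]]
  rr <- sim$reads[sim$reads$feature_id %in% dup_feats, ][1:10, ]
  aln <- align_reads(stats::setNames(rr$seq, rr$read_id), idx)
  expect_true(all(aln$placements$n_placements >= 2L))
})
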