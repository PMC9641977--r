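#' Simulate an annotated reference genome
#'
#' Generates random chromosome sequences and places non-overlapping (within
#' class) features of each configured class, plus clustered piRNA loci that
#' are exactly 21 bp and begin with T on their annotated strand (the genome is
#' edited at the locus 5' base to guarantee the signature).  Protein-coding
#' genes carry >= 1 exon part partitioning the gene body.  Each chromosome is
#' partitioned into arm / center / arm recombination domains (boundaries at
#' 25% and 75% of the chromosome length).  When `multimap_fraction > 0`, that
#' fraction of features per class is duplicated by copying a donor feature's
#' sequence over a same-length acceptor locus, so reads from either locus
#' multi-map.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `annotated_genome`: a list with `genome` (named
#'   character vector of chromosome sequences), `features`, `parts` and
#'   `domains` data frames.  All coordinates are 1-based inclusive.
#' @examples
#' ag <- simulate_reference(sim_config(seed = 7, chrom_length = 20000,
#'   feature_counts = c(protein_coding = 5, miRNA = 2)))
#' head(ag$features)
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- chrom_names(config$n_chromosomes)
  genome <- vapply(config$chrom_length, random_dna, character(1))
  names(genome) <- chroms

  prefixes <- ID_PREFIXES
  len_range <- list(protein_coding = c(600L, 1200L), pseudogene = c(300L, 600L),
                    transposon = c(400L, 800L), "repeat" = c(150L, 300L),
                    miRNA = c(22L, 22L), rRNA = c(110L, 130L),
                    tRNA = c(70L, 90L), ncRNA = c(90L, 110L))

  feats <- list(); parts <- list()
  occupied <- lapply(chroms, function(x) list())  # per chrom, per class IRanges
  names(occupied) <- chroms

  place_one <- function(chrom, class, len, lo = 1L, hi = NA_integer_) {
    clen <- nchar(genome[[chrom]])
    hi <- if (is.na(hi)) clen else hi
    if (hi - lo + 1L < len)
      stopf("cannot place a %d bp %s feature on %s: interval too small",
            len, class, chrom)
    occ <- occupied[[chrom]][[class]]
    for (i in seq_len(400L)) {
      s <- sample.int(hi - len - lo + 2L, 1L) + lo - 1L
      e <- s + len - 1L
      if (is.null(occ) || !any(s <= occ[, 2] & e >= occ[, 1])) {
        occupied[[chrom]][[class]] <<- rbind(occ, c(s, e))
        return(c(s, e))
      }
    }
    stopf("capacity error: could not place %s feature of %d bp on %s",
          class, len, chrom)
  }

  counts <- config$feature_counts
  classes <- setdiff(names(counts)[counts > 0], "piRNA")
  for (class in classes) {
    n <- as.integer(counts[[class]])
    rng <- len_range[[class]]
    lens <- sample(rng[1]:rng[2], n, replace = TRUE)
    # duplicated features (multi-mapping donors/acceptors) must share lengths
    ndup <- 0L
    if (config$multimap_fraction > 0 && class %in% ANTISENSE_CLASSES) {
      ndup <- min(floor(config$multimap_fraction * n), n %/% 2L)
      if (ndup > 0) lens[n - ndup + seq_len(ndup)] <- lens[seq_len(ndup)]
    }
    on_chrom <- rep_len(chroms, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      se <- place_one(on_chrom[i], class, lens[i])
      id <- sprintf("%s%04d", prefixes[[class]], i)
      fam <- id
      rows[[i]] <- data.frame(feature_id = id, class = class, family = fam,
                              chrom = on_chrom[i], start = se[1], end = se[2],
                              strand = strand[i], stringsAsFactors = FALSE)
      if (class == "protein_coding") {
        # exon parts partition the gene body
        nex <- sample(1:3, 1L)
        cuts <- sort(unique(c(0L, if (nex > 1)
          sample(seq_len(lens[i] - 1L), nex - 1L), lens[i])))
        parts[[length(parts) + 1L]] <- data.frame(
          part_id = sprintf("%s.e%d", id, seq_len(length(cuts) - 1L)),
          feature_id = id, chrom = on_chrom[i],
          start = se[1] + cuts[-length(cuts)],
          end = se[1] + cuts[-1] - 1L,
          strand = strand[i], stringsAsFactors = FALSE)
      }
    }
    rows <- do.call(rbind, rows)
    if (ndup > 0) {  # copy donor sequence over acceptor loci
      for (k in seq_len(ndup)) {
        don <- rows[k, ]; acc <- rows[nrow(rows) - ndup + k, ]
        donseq <- substr(genome[[don$chrom]], don$start, don$end)
        substr(genome[[acc$chrom]], acc$start, acc$end) <- donseq
        rows$family[nrow(rows) - ndup + k] <- don$feature_id
        rows$strand[nrow(rows) - ndup + k] <- don$strand
      }
    }
    feats[[class]] <- rows
  }

  # piRNA loci: 21 bp, 5' T, inside the configured clusters
  lay <- config$piRNA_cluster_layout
  if (!is.null(lay) && nrow(lay)) {
    pi_rows <- list(); idx <- 0L
    for (ci in seq_len(nrow(lay))) {
      if (!lay$chrom[ci] %in% chroms)
        stopf("piRNA cluster on unknown chromosome %s", lay$chrom[ci])
      for (j in seq_len(lay$n_loci[ci])) {
        idx <- idx + 1L
        se <- place_one(lay$chrom[ci], "piRNA", 21L,
                        lo = lay$start[ci], hi = lay$end[ci])
        strand <- sample(c("+", "-"), 1L)
        # force the strand-aware first base to T
        if (strand == "+") substr(genome[[lay$chrom[ci]]], se[1], se[1]) <- "T"
        else substr(genome[[lay$chrom[ci]]], se[2], se[2]) <- "A"
        pi_rows[[idx]] <- data.frame(
          feature_id = sprintf("pirna%04d", idx), class = "piRNA",
          family = sprintf("pirna%04d", idx), chrom = lay$chrom[ci],
          start = se[1], end = se[2], strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    feats[["piRNA"]] <- do.call(rbind, pi_rows)
  }

  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(feature_id = character(), class = character(),
               family = character(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  rownames(features) <- NULL
  parts <- if (length(parts)) do.call(rbind, parts) else
    data.frame(part_id = character(), feature_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character())
  rownames(parts) <- NULL

  domains <- do.call(rbind, lapply(chroms, function(ch) {
    L <- nchar(genome[[ch]])
    b1 <- floor(0.25 * L); b2 <- floor(0.75 * L)
    data.frame(chrom = ch, start = c(1L, b1 + 1L, b2 + 1L),
               end = c(b1, b2, L),
               domain = c("arm", "center", "arm"), stringsAsFactors = FALSE)
  }))

  structure(list(genome = genome, features = features, parts = parts,
                 domains = domains), class = "annotated_genome")
}

#' Simulate strain variants against a reference
#'
#' Draws per-chromosome SNP and short-indel counts from Poisson distributions
#' at the configured per-kb densities, places them at non-overlapping
#' positions, and returns a sorted variant table whose REF alleles match the
#' reference sequence.  Indels use the VCF anchor-base convention (deletions:
#' REF spans the anchor plus deleted bases; insertions: ALT carries the anchor
#' plus inserted bases).
#'
#' @param config A [sim_config()] object (densities and seed).
#' @param ag An `annotated_genome` from [simulate_reference()].
#' @param forced Optional data frame with columns `chrom`, `pos`, `alt` (and
#'   optionally `ref`, defaulting to the reference base) of variants to force
#'   into the set, e.g. a SNP at a piRNA first base to exercise liftover
#'   retention filters.  Forced variants displace colliding random ones.
#' @return Data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`, `type`,
#'   sorted by chromosome and position.
#' @export
simulate_variants <- function(config, ag, forced = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(ag, "annotated_genome"))
  set.seed(config$seed + 1L)
  dens <- config$variant_density
  out <- list()
  for (ch in names(ag$genome)) {
    L <- nchar(ag$genome[[ch]])
    n_snp <- rpois(1L, dens[["snp_per_kb"]] * L / 1000)
    n_ind <- rpois(1L, dens[["indel_per_kb"]] * L / 1000)
    if (n_snp + n_ind == 0L) next
    pos <- sample(10:(L - 10L), n_snp + n_ind)
    rows <- lapply(seq_along(pos), function(i) {
      p <- pos[i]
      refbase <- substr(ag$genome[[ch]], p, p)
      if (i <= n_snp) {
        data.frame(chrom = ch, pos = p, ref = refbase,
                   alt = sample(setdiff(c("A", "C", "G", "T"), refbase), 1L),
                   type = "snp", stringsAsFactors = FALSE)
      } else if (runif(1) < 0.5) {  # deletion
        dl <- sample(1:5, 1L)
        data.frame(chrom = ch, pos = p,
                   ref = substr(ag$genome[[ch]], p, p + dl),
                   alt = refbase, type = "del", stringsAsFactors = FALSE)
      } else {                       # insertion
        il <- sample(1:5, 1L)
        data.frame(chrom = ch, pos = p, ref = refbase,
                   alt = paste0(refbase, random_dna(il)),
                   type = "ins", stringsAsFactors = FALSE)
      }
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  v <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), type = character())
  if (!is.null(forced) && nrow(forced)) {
    forced$ref <- if (!is.null(forced$ref)) forced$ref else
      substr(ag$genome[forced$chrom], forced$pos, forced$pos)
    forced <- data.frame(chrom = forced$chrom, pos = forced$pos,
                         ref = forced$ref, alt = forced$alt,
                         type = ifelse(nchar(forced$ref) == nchar(forced$alt),
                                       "snp", "indel"),
                         stringsAsFactors = FALSE)
    # forced variants displace overlapping random ones
    keep <- vapply(seq_len(nrow(v)), function(i) {
      f <- forced[forced$chrom == v$chrom[i], , drop = FALSE]
      !any(v$pos[i] <= f$pos + nchar(f$ref) - 1L &
             v$pos[i] + nchar(v$ref[i]) - 1L >= f$pos)
    }, logical(1))
    v <- rbind(v[keep, , drop = FALSE], forced)
  }
  if (nrow(v)) {
    v <- v[order(match(v$chrom, names(ag$genome)), v$pos), , drop = FALSE]
    # drop any later variant whose REF span overlaps an earlier one
    keep <- rep(TRUE, nrow(v)); last_end <- -1L; last_ch <- ""
    for (i in seq_len(nrow(v))) {
      if (v$chrom[i] == last_ch && v$pos[i] <= last_end) keep[i] <- FALSE
      else { last_ch <- v$chrom[i]; last_end <- v$pos[i] + nchar(v$ref[i]) - 1L }
    }
    v <- v[keep, , drop = FALSE]
    bad <- substr(ag$genome[v$chrom], v$pos, v$pos + nchar(v$ref) - 1L) != v$ref
    if (any(bad)) stopf("internal error: simulated REF mismatch at %s:%d",
                        v$chrom[which(bad)[1]], v$pos[which(bad)[1]])
  }
  v$id <- if (nrow(v)) sprintf("var%04d", seq_len(nrow(v))) else character()
  rownames(v) <- NULL
  v[, c("chrom", "pos", "id", "ref", "alt", "type")]
}
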