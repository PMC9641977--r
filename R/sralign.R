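# Perfect full-length placement of small RNA reads on both genome strands,
# with a multi-mapping cap, plus SAM interop.  Primary placements are chosen
# deterministically: first chromosome in genome order, then position, then
# strand (+ before -).

#' Build a searchable genome index
#'
#' @param genome Named character vector / `DNAStringSet` of chromosome
#'   sequences, or a FASTA path.  Alphabet must be ACGTN.
#' @return An object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (!length(genome) || any(nchar(genome) == 0L))
    stopf("genome must be non-empty")
  if (any(grepl("[^ACGTN]", genome)))
    stopf("genome contains non-nucleotide characters (alphabet is ACGTN)")
  structure(list(seqs = Biostrings::DNAStringSet(genome),
                 chroms = names(genome),
                 lengths = nchar(genome)), class = "genome_index")
}

#' Locate all exact occurrences of one pattern on both strands
#'
#' @param index A `genome_index`.
#' @param query Nucleotide string.
#' @return Data frame with `chrom`, `start`, `end`, `strand` (start is the
#'   leftmost genomic coordinate, 1-based).
#' @export
locate_pattern <- function(index, query) {
  align_reads(stats::setNames(query, "q"), index, cap = Inf)$placements[
    , c("chrom", "start", "end", "strand")]
}

#' Align reads by perfect full-length matching
#'
#' Finds every zero-mismatch, ungapped, full-length placement of each read on
#' either strand.  Reads with more than `cap` placements are discarded as
#' too-multimapped; reads with none are unmapped.
#'
#' @param reads Named character vector of read sequences (names = read ids),
#'   or a data frame with `read_id`, `seq` and optionally `sample`.
#' @param index A `genome_index` (or anything [build_index()] accepts).
#' @param cap Maximum retained placements per read (50, mirroring common
#'   multi-map filters).
#' @return List of class `alignment_set`: `placements` (data frame: `read_id`,
#'   `sample`, `seq`, `chrom`, `start`, `end`, `strand`, `n_placements`,
#'   `primary`, `perfect`), plus `unmapped` and `discarded` read-id vectors.
#' @export
align_reads <- function(reads, index, cap = 50L) {
  if (!inherits(index, "genome_index")) index <- build_index(index)
  if (is.data.frame(reads)) {
    samples <- if (!is.null(reads$sample)) reads$sample else NA_character_
    reads_df <- data.frame(read_id = reads$read_id, seq = reads$seq,
                           sample = samples, stringsAsFactors = FALSE)
  } else {
    reads_df <- data.frame(read_id = names(reads), seq = unname(reads),
                           sample = NA_character_, stringsAsFactors = FALSE)
  }
  useq <- unique(reads_df$seq)
  hits <- vector("list", length(useq))  # per unique seq: chrom/start/strand
  widths <- nchar(useq)
  for (w in unique(widths)) {
    ix <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(useq[ix])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ci in seq_along(index$chroms)) {
      subj <- index$seqs[[ci]]
      m_f <- Biostrings::matchPDict(pd_f, subj)
      m_r <- Biostrings::matchPDict(pd_r, subj)
      for (k in seq_along(ix)) {
        s_f <- Biostrings::startIndex(m_f)[[k]]
        s_r <- Biostrings::startIndex(m_r)[[k]]
        if (length(s_f) || length(s_r)) {
          hits[[ix[k]]] <- rbind(hits[[ix[k]]], data.frame(
            chrom = index$chroms[ci],
            start = c(s_f, s_r),
            strand = rep(c("+", "-"), c(length(s_f), length(s_r))),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  n_hits <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h),
                   integer(1))
  status <- ifelse(n_hits == 0L, "unmapped",
                   ifelse(n_hits > cap, "discarded", "mapped"))
  read_status <- status[match(reads_df$seq, useq)]

  placed <- which(read_status == "mapped")
  out <- vector("list", length(placed))
  for (ii in seq_along(placed)) {
    i <- placed[ii]
    h <- hits[[match(reads_df$seq[i], useq)]]
    ord <- order(match(h$chrom, index$chroms), h$start,
                 match(h$strand, c("+", "-")))
    h <- h[ord, , drop = FALSE]
    w <- nchar(reads_df$seq[i])
    out[[ii]] <- data.frame(
      read_id = reads_df$read_id[i], sample = reads_df$sample[i],
      seq = reads_df$seq[i], chrom = h$chrom, start = h$start,
      end = h$start + w - 1L, strand = h$strand, n_placements = nrow(h),
      primary = seq_len(nrow(h)) == 1L, perfect = TRUE,
      stringsAsFactors = FALSE)
  }
  placements <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), sample = character(), seq = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), n_placements = integer(),
               primary = logical(), perfect = logical())
  rownames(placements) <- NULL
  structure(list(placements = placements,
                 unmapped = reads_df$read_id[read_status == "unmapped"],
                 discarded = reads_df$read_id[read_status == "discarded"]),
            class = "alignment_set")
}

#' Write alignments as SAM
#'
#' One record per placement; secondary placements carry flag 0x100, minus
#' strand records store the reverse complement of the read per the SAM
#' convention.  `NM:i:0` and `NH` tags are emitted.
#'
#' @param aln An `alignment_set`.
#' @param index The `genome_index` used (for `@SQ` headers).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(aln, index, path) {
  p <- aln$placements
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", index$chroms,
                   as.integer(index$lengths)))
  if (nrow(p)) {
    flag <- ifelse(p$strand == "-", 16L, 0L) + ifelse(p$primary, 0L, 256L)
    seq_out <- ifelse(p$strand == "-", revcomp(p$seq), p$seq)
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:0\tNH:i:%d",
                    p$read_id, flag, p$chrom, p$start, nchar(p$seq), seq_out,
                    p$n_placements)
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file and flag perfect alignments
#'
#' Parses the 11 fixed SAM columns plus `NM`/`NH` tags.  A record is perfect
#' iff its CIGAR consists only of `M`/`=` operations and either `NM:i:0` is
#' present or the stored sequence equals the genome substring.  Records with
#' `N` (intron gap) operations are excluded from the perfect set and counted
#' in the returned `n_gapped` attribute.  Malformed records raise an error
#' naming the line number.
#'
#' @param path SAM file.
#' @param genome Named character vector of sequences (used when `NM` is
#'   absent); optional if every record carries `NM`.
#' @return An `alignment_set` whose `placements` carry the derived `perfect`
#'   flag; placements are grouped by read name.
#' @export
read_sam <- function(path, genome = NULL) {
  lines <- readLines(path)
  is_rec <- !startsWith(lines, "@")
  recs <- lines[is_rec]
  lineno <- which(is_rec)
  rows <- vector("list", length(recs))
  n_gapped <- 0L
  for (i in seq_along(recs)) {
    f <- strsplit(recs[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stopf("malformed SAM record at line %d (%d fields)", lineno[i], length(f))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos))
      stopf("malformed SAM record at line %d (non-numeric FLAG/POS)", lineno[i])
    if (bitwAnd(flag, 4L) > 0L) next  # unmapped
    cigar <- f[6]
    if (grepl("N", cigar, fixed = TRUE)) { n_gapped <- n_gapped + 1L; }
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    seq_stored <- f[10]
    seq_read <- if (strand == "-") revcomp(seq_stored) else seq_stored
    nm <- sub("^.*\\bNM:i:(-?[0-9]+).*$", "\\1",
              paste(f[-(1:11)], collapse = "\t"))
    nm <- if (grepl("^-?[0-9]+$", nm)) as.integer(nm) else NA_integer_
    ref_len <- cigar_ref_len(cigar, lineno[i])
    only_m <- grepl("^([0-9]+[M=])+$", cigar)
    perfect <- FALSE
    if (only_m) {
      if (!is.na(nm)) perfect <- nm == 0L
      else if (!is.null(genome))
        perfect <- substr(genome[[f[3]]], pos, pos + ref_len - 1L) == seq_stored
    }
    rows[[i]] <- data.frame(
      read_id = f[1], sample = NA_character_, seq = seq_read, chrom = f[3],
      start = pos, end = pos + ref_len - 1L, strand = strand,
      primary = bitwAnd(flag, 256L) == 0L, perfect = perfect,
      stringsAsFactors = FALSE)
  }
  p <- do.call(rbind, rows)
  if (is.null(p))
    p <- data.frame(read_id = character(), sample = character(),
                    seq = character(), chrom = character(), start = integer(),
                    end = integer(), strand = character(), primary = logical(),
                    perfect = logical())
  np <- table(p$read_id)
  p$n_placements <- as.integer(np[p$read_id])
  p <- p[, c("read_id", "sample", "seq", "chrom", "start", "end", "strand",
             "n_placements", "primary", "perfect")]
  rownames(p) <- NULL
  structure(list(placements = p, unmapped = character(),
                 discarded = character(), n_gapped = n_gapped),
            class = "alignment_set")
}

# reference span consumed by a CIGAR string
cigar_ref_len <- function(cigar, lineno = NA) {
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stopf("malformed CIGAR '%s' at line %s", cigar, lineno)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}
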