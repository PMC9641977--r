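# Standard-format readers/writers.  FASTA via Biostrings, GFF3/BED via
# rtracklayer, VCF reading via vcfR.  Coordinates in all files are 1-based
# inclusive (GFF3/VCF convention); BED's 0-based half-open encoding is handled
# by rtracklayer.

#' Write an annotated genome to FASTA + GFF3 + BED
#'
#' @param ag An `annotated_genome`.
#' @param prefix Output path prefix; writes `<prefix>.fa`, `<prefix>.gff3`,
#'   `<prefix>.domains.bed`.
#' @return Invisibly, the three paths written.
#' @export
write_reference <- function(ag, prefix) {
  fa <- paste0(prefix, ".fa")
  gff <- paste0(prefix, ".gff3")
  bed <- paste0(prefix, ".domains.bed")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ag$genome), fa)
  write_gff3(ag$features, ag$parts, gff, chrom_lengths = nchar(ag$genome))
  gr <- GenomicRanges::GRanges(ag$domains$chrom,
                               IRanges::IRanges(ag$domains$start, ag$domains$end),
                               name = ag$domains$domain)
  rtracklayer::export(gr, bed, format = "bed")
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}

#' Write feature annotations as GFF3
#'
#' Feature rows use their class as the GFF3 `type`; exon parts are written as
#' `exon` rows with a `Parent` attribute.
#'
#' @param features,parts Annotation data frames as in `annotated_genome`.
#' @param path Output path.
#' @param chrom_lengths Optional named vector used for `##sequence-region`.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, parts, path, chrom_lengths = NULL) {
  gr_f <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start, features$end),
    strand = features$strand, type = features$class, ID = features$feature_id,
    family = features$family)
  if (nrow(parts)) {
    gr_p <- GenomicRanges::GRanges(
      parts$chrom, IRanges::IRanges(parts$start, parts$end),
      strand = parts$strand, type = "exon", ID = parts$part_id,
      family = NA_character_)
    gr_p$Parent <- parts$feature_id
    gr_f$Parent <- NA_character_
    gr <- c(gr_f, gr_p)
  } else gr <- gr_f
  if (!is.null(chrom_lengths))
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read GFF3 annotations into feature / part tables
#'
#' @param path GFF3 file.
#' @return List with `features` and `parts` data frames.
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  is_part <- df$type == "exon"
  fam <- if (!is.null(df$family)) as.character(df$family) else df$ID
  features <- data.frame(
    feature_id = df$ID[!is_part], class = as.character(df$type)[!is_part],
    family = ifelse(is.na(fam[!is_part]), df$ID[!is_part], fam[!is_part]),
    chrom = as.character(df$seqnames)[!is_part],
    start = df$start[!is_part], end = df$end[!is_part],
    strand = as.character(df$strand)[!is_part], stringsAsFactors = FALSE)
  parent <- if (!is.null(df$Parent)) vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  else rep(NA_character_, nrow(df))
  parts <- data.frame(
    part_id = df$ID[is_part], feature_id = parent[is_part],
    chrom = as.character(df$seqnames)[is_part],
    start = df$start[is_part], end = df$end[is_part],
    strand = as.character(df$strand)[is_part], stringsAsFactors = FALSE)
  rownames(features) <- rownames(parts) <- NULL
  list(features = features, parts = parts)
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' @param variants Variant data frame (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants))
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.", variants$chrom,
            as.integer(variants$pos),
            if (!is.null(variants$id)) variants$id else ".",
            variants$ref, variants$alt)
  else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into the internal variant table
#'
#' @param path VCF file (plain or gzipped).
#' @return Data frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fx))
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character()))
  data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS), id = fx$ID,
             ref = fx$REF, alt = fx$ALT, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' With `raw = TRUE` each record is written as it would come off the
#' sequencer before processing: 4 nt sample barcode + insert + 3' adapter.
#'
#' @param reads Data frame with columns `read_id` and `seq` (and `sample` if
#'   `raw = TRUE` with per-sample barcodes).
#' @param path Output path.
#' @param raw Prepend barcodes and append the 3' adapter.
#' @param barcodes Named character vector (sample -> barcode), used when
#'   `raw = TRUE`.
#' @param adapter_3p 3' adapter appended when `raw = TRUE`.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, raw = FALSE, barcodes = NULL,
                        adapter_3p = "") {
  seqs <- reads$seq
  if (raw) {
    bc <- if (!is.null(barcodes)) unname(barcodes[reads$sample]) else ""
    seqs <- paste0(bc, seqs, adapter_3p)
  }
  writeLines(as.vector(rbind(paste0("@", reads$read_id), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return Data frame with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  if (length(x) %% 4L != 0L) stopf("truncated FASTQ: %s", path)
  ids <- sub("^@", "", x[seq(1L, length(x), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  data.frame(read_id = ids, seq = x[seq(2L, length(x), by = 4L)],
             stringsAsFactors = FALSE)
}

#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Read an arm/center domain BED file
#'
#' @param path BED file with the domain label in the name column.
#' @return Data frame with `chrom`, `start`, `end`, `domain` (1-based).
#' @export
read_domains <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             domain = gr$name, stringsAsFactors = FALSE)
}
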