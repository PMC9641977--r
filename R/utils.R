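# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet reverseComplement writeXStringSet readDNAStringSet
#' @importFrom stats rpois rnbinom p.adjust pt pnorm phyper lm model.matrix vcov coef
#' @importFrom utils adist head
NULL

# vectorised reverse complement on plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single bases (keeps N)
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# chromosome naming: chrI, chrII, ...
chrom_names <- function(n) paste0("chr", as.character(utils::as.roman(seq_len(n))))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

FEATURE_CLASSES <- c("protein_coding", "pseudogene", "transposon", "repeat",
                     "miRNA", "piRNA", "rRNA", "tRNA", "ncRNA")

ID_PREFIXES <- c(protein_coding = "gene", pseudogene = "pseudo",
                 transposon = "tn", "repeat" = "rep", miRNA = "mir",
                 piRNA = "pirna", rRNA = "rrna", tRNA = "trna",
                 ncRNA = "ncrna")

# classes whose small RNAs are templated antisense (RdRP products)
ANTISENSE_CLASSES <- c("protein_coding", "pseudogene", "transposon", "repeat")
SENSE_CLASSES <- setdiff(FEATURE_CLASSES, ANTISENSE_CLASSES)
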