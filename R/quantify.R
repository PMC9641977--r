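# Small RNA taxonomy and fractional feature counting.
#
# Read classes: 22G (21-23 nt, 5' G), 26G (25-27 nt, 5' G), 21U-piRNA (21 nt,
# 5' U/T, sense to an annotated piRNA locus), microRNA (sense to an annotated
# microRNA locus), other.  A placement contributes to a feature iff the read
# interval is fully contained in the feature interval; each contribution is
# 1/N where N is the number of the read's placements overlapping any feature
# of that class.  Placements contained in no annotated feature are pooled
# into a single "unannotated" pseudo-feature.

#' Classify reads by length, 5' nucleotide and annotation context
#'
#' @param alignments An `alignment_set` (only perfect placements are used).
#' @param features Feature annotation data frame.
#' @return Data frame, one row per read: `read_id`, `sample`, `length`,
#'   `nt5`, and logical class columns `is_22G`, `is_26G`, `is_21U`,
#'   `is_miRNA`, plus `class` (first matching label, `other` if none).
#' @export
annotate_reads <- function(alignments, features) {
  p <- alignments$placements
  p <- p[p$perfect, , drop = FALSE]
  reads <- p[!duplicated(p$read_id), c("read_id", "sample", "seq")]
  reads$length <- nchar(reads$seq)
  reads$nt5 <- substr(reads$seq, 1L, 1L)

  sense_class_hit <- function(class) {
    f <- features[features$class == class, , drop = FALSE]
    if (!nrow(f) || !nrow(p)) return(character())
    ov <- contained_pairs(p, f)
    sense <- p$strand[ov$q] == f$strand[ov$s]
    unique(p$read_id[ov$q[sense]])
  }
  mir_ids <- sense_class_hit("miRNA")
  pi_ids <- sense_class_hit("piRNA")

  reads$is_22G <- reads$length >= 21L & reads$length <= 23L & reads$nt5 == "G"
  reads$is_26G <- reads$length >= 25L & reads$length <= 27L & reads$nt5 == "G"
  reads$is_21U <- reads$length == 21L & reads$nt5 == "T" &
    reads$read_id %in% pi_ids
  reads$is_miRNA <- reads$read_id %in% mir_ids
  reads$class <- ifelse(reads$is_miRNA, "miRNA",
                 ifelse(reads$is_21U, "piRNA_21U",
                 ifelse(reads$is_22G, "siRNA_22G",
                 ifelse(reads$is_26G, "siRNA_26G", "other"))))
  rownames(reads) <- NULL
  reads
}

# indexes of (placement, feature) pairs where the placement interval is fully
# contained in the feature interval
contained_pairs <- function(p, f) {
  q <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start, p$end))
  s <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end))
  ov <- GenomicRanges::findOverlaps(q, s, type = "within",
                                    ignore.strand = TRUE)
  list(q = S4Vectors::queryHits(ov), s = S4Vectors::subjectHits(ov))
}

#' Fractional feature counts stratified by length, 5' nucleotide, orientation
#'
#' @param alignments An `alignment_set` carrying all placements per read.
#' @param features Feature annotation data frame (with `feature_id`, `class`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param chrom_lengths Named vector of chromosome lengths (defines the
#'   "unannotated" pseudo-feature's territory; optional, used for metadata
#'   only).
#' @return A `count_tensor`: long data frame with columns `sample`,
#'   `feature_id`, `feature_class`, `chrom`, `orientation`, `length`, `nt5`,
#'   `count`.  Fractional counts of one read within one feature class sum to
#'   at most 1.
#' @export
count_features <- function(alignments, features, chrom_lengths = NULL) {
  p <- alignments$placements
  p <- p[p$perfect, , drop = FALSE]
  if (!nrow(p)) {
    out <- data.frame(sample = character(), feature_id = character(),
                      feature_class = character(), chrom = character(),
                      orientation = character(), length = integer(),
                      nt5 = character(), count = numeric())
    class(out) <- c("count_tensor", class(out))
    return(out)
  }
  p$placement_id <- seq_len(nrow(p))
  p$length <- nchar(p$seq)
  p$nt5 <- substr(p$seq, 1L, 1L)

  pieces <- list()
  covered <- rep(FALSE, nrow(p))  # placement contained in >= 1 feature
  for (cl in unique(features$class)) {
    f <- features[features$class == cl, , drop = FALSE]
    ov <- contained_pairs(p, f)
    if (!length(ov$q)) next
    covered[unique(ov$q)] <- TRUE
    # N per read: placements of that read contained in >= 1 feature of class
    hit_pl <- unique(ov$q)
    n_by_read <- table(p$read_id[hit_pl])
    contrib <- data.frame(
      sample = p$sample[ov$q],
      feature_id = f$feature_id[ov$s],
      feature_class = cl,
      chrom = f$chrom[ov$s],
      orientation = ifelse(p$strand[ov$q] == f$strand[ov$s],
                           "sense", "antisense"),
      length = p$length[ov$q],
      nt5 = p$nt5[ov$q],
      count = 1 / as.numeric(n_by_read[p$read_id[ov$q]]),
      stringsAsFactors = FALSE)
    pieces[[cl]] <- contrib
  }
  # unannotated pseudo-feature: placements contained in no annotated feature
  un <- which(!covered)
  if (length(un)) {
    n_by_read <- table(p$read_id[un])
    pieces[["unannotated"]] <- data.frame(
      sample = p$sample[un], feature_id = "unannotated",
      feature_class = "unannotated", chrom = p$chrom[un],
      orientation = "sense", length = p$length[un], nt5 = p$nt5[un],
      count = 1 / as.numeric(n_by_read[p$read_id[un]]),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, pieces)
  out <- stats::aggregate(count ~ sample + feature_id + feature_class + chrom +
                            orientation + length + nt5, data = long, FUN = sum)
  out <- out[order(out$sample, out$feature_class, out$feature_id,
                   out$orientation, out$length, out$nt5), ]
  rownames(out) <- NULL
  class(out) <- c("count_tensor", class(out))
  out
}

#' Sum fractional counts under read-class / orientation / scope filters
#'
#' @param tensor A `count_tensor`.
#' @param read_class One of `"22G"`, `"26G"`, `"21U"`, `"any"` (length and 5'
#'   nucleotide filter).
#' @param orientation `"sense"`, `"antisense"` or `NULL` for both.
#' @param feature_classes Feature classes to include (`NULL` for all).
#' @param features_subset Feature ids to include (`NULL` for all), e.g. piRNA
#'   loci present in both strains' annotations.
#' @param by Additional grouping column (`"feature_id"` or `"chrom"`), besides
#'   `sample`.
#' @return Data frame of totals per sample (and per `by` group).
#' @export
class_totals <- function(tensor, read_class = "any", orientation = NULL,
                         feature_classes = NULL, features_subset = NULL,
                         by = NULL) {
  x <- tensor
  sel <- rep(TRUE, nrow(x))
  if (read_class == "22G") sel <- sel & x$length >= 21 & x$length <= 23 & x$nt5 == "G"
  else if (read_class == "26G") sel <- sel & x$length >= 25 & x$length <= 27 & x$nt5 == "G"
  else if (read_class == "21U") sel <- sel & x$length == 21 & x$nt5 == "T"
  else if (read_class != "any") stopf("unknown read class '%s'", read_class)
  if (!is.null(orientation)) sel <- sel & x$orientation %in% orientation
  if (!is.null(feature_classes)) sel <- sel & x$feature_class %in% feature_classes
  if (!is.null(features_subset)) sel <- sel & x$feature_id %in% features_subset
  x <- x[sel, , drop = FALSE]
  if (!nrow(x)) {
    warning("empty scope: no counts match the filters", call. = FALSE)
    groups <- c("sample", by)
    out <- data.frame(sample = character(), count = numeric())
    if (!is.null(by)) out[[by]] <- character()
    return(out[, c(groups, "count"), drop = FALSE])
  }
  groups <- c("sample", by)
  stats::aggregate(x["count"], by = x[groups], FUN = sum)
}

#' Per-chromosome totals of a read class using primary placements
#'
#' Mirrors per-chromosome summaries where every read (including those in
#' unannotated territory) is assigned to the chromosome of its primary
#' placement.
#'
#' @param alignments An `alignment_set`.
#' @param read_class As in [class_totals()].
#' @return Data frame `sample`, `chrom`, `count`.
#' @export
chromosome_totals <- function(alignments, read_class = "22G") {
  p <- alignments$placements
  p <- p[p$perfect & p$primary, , drop = FALSE]
  len <- nchar(p$seq); nt5 <- substr(p$seq, 1L, 1L)
  sel <- switch(read_class,
                "22G" = len >= 21 & len <= 23 & nt5 == "G",
                "26G" = len >= 25 & len <= 27 & nt5 == "G",
                "21U" = len == 21 & nt5 == "T",
                "any" = rep(TRUE, nrow(p)),
                stopf("unknown read class '%s'", read_class))
  p <- p[sel, , drop = FALSE]
  out <- stats::aggregate(list(count = rep(1L, nrow(p))),
                          by = list(sample = p$sample, chrom = p$chrom),
                          FUN = sum)
  out[order(out$sample, out$chrom), ]
}

#' Per-window totals (log2 RPM) along chromosomes
#'
#' Windows tile each chromosome from position 1; the last partial window is
#' retained.  Multi-mapped reads are located by their primary placement.
#' RPM uses the per-sample total of perfectly aligned reads; log2 values use
#' a 0.5-read pseudocount before RPM scaling.
#'
#' @param alignments An `alignment_set`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param width Window width in bp.
#' @param read_class As in [class_totals()].
#' @param lib_sizes Optional named per-sample totals; defaults to each
#'   sample's number of perfectly aligned reads.
#' @return Data frame `sample`, `chrom`, `win_start`, `win_end`, `count`,
#'   `log2_rpm`.
#' @export
window_profile <- function(alignments, chrom_lengths, width,
                           read_class = "22G", lib_sizes = NULL) {
  stopifnot(width > 0)
  p <- alignments$placements[alignments$placements$perfect, , drop = FALSE]
  if (is.null(lib_sizes)) {
    tot <- table(p$sample[p$primary])
    lib_sizes <- stats::setNames(as.numeric(tot), names(tot))
  }
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    s <- seq(1L, L, by = width)
    data.frame(chrom = ch, win_start = s, win_end = pmin(s + width - 1L, L),
               stringsAsFactors = FALSE)
  }))
  prim <- p[p$primary, , drop = FALSE]
  len <- nchar(prim$seq); nt5 <- substr(prim$seq, 1L, 1L)
  sel <- switch(read_class,
                "22G" = len >= 21 & len <= 23 & nt5 == "G",
                "26G" = len >= 25 & len <= 27 & nt5 == "G",
                "21U" = len == 21 & nt5 == "T",
                "any" = rep(TRUE, nrow(prim)))
  prim <- prim[sel, , drop = FALSE]
  samples <- sort(unique(alignments$placements$sample))
  out <- do.call(rbind, lapply(samples, function(sm) {
    q <- prim[prim$sample == sm, , drop = FALSE]
    w <- wins
    w$sample <- sm
    w$count <- mapply(function(ch, s, e)
      sum(q$chrom == ch & q$start >= s & q$start <= e),
      w$chrom, w$win_start, w$win_end)
    w$log2_rpm <- log2((w$count + 0.5) / lib_sizes[[sm]] * 1e6)
    w
  }))
  rownames(out) <- NULL
  out[, c("sample", "chrom", "win_start", "win_end", "count", "log2_rpm")]
}

#' Features shared between two strains' annotations
#'
#' Protein-coding genes, pseudogenes and other id-level features are retained
#' iff they transferred completely to the second annotation; repeat and
#' transposon features collapse to their family, retained iff at least one
#' copy of the family is present in both annotations.
#'
#' @param features_a,features_b Feature tables of the two strains (the second
#'   typically from [lift_annotations()]).
#' @return Character vector of shared unit ids (feature ids, or family ids
#'   for repeats/transposons).
#' @export
shared_feature_set <- function(features_a, features_b) {
  unit <- function(f) ifelse(f$class %in% c("repeat", "transposon"),
                             f$family, f$feature_id)
  intersect(unique(unit(features_a)), unique(unit(features_b)))
}

#' Aggregate a count tensor to unit x sample matrix
#'
#' Units are feature ids, except repeats/transposons which aggregate to
#' family level (see [shared_feature_set()]).
#'
#' @param tensor A `count_tensor`, already filtered to the read class and
#'   orientation of interest (see [class_totals()] filters).
#' @param features Feature table supplying the family mapping.
#' @param units Unit ids to keep (rows of the result, in this order).
#' @param samples Sample ids (columns; defaults to those present).
#' @return Numeric matrix units x samples of fractional counts.
#' @export
tensor_to_matrix <- function(tensor, features, units = NULL, samples = NULL) {
  fam <- stats::setNames(ifelse(features$class %in% c("repeat", "transposon"),
                                features$family, features$feature_id),
                         features$feature_id)
  x <- tensor[tensor$feature_id %in% names(fam), , drop = FALSE]
  x$unit <- fam[x$feature_id]
  if (is.null(units)) units <- sort(unique(x$unit))
  if (is.null(samples)) samples <- sort(unique(tensor$sample))
  m <- matrix(0, length(units), length(samples),
              dimnames = list(units, samples))
  x <- x[x$unit %in% units & x$sample %in% samples, , drop = FALSE]
  if (nrow(x)) {
    agg <- stats::aggregate(count ~ unit + sample, data = x, FUN = sum)
    m[cbind(agg$unit, agg$sample)] <- agg$count
  }
  m
}
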