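# Strain pseudo-reference construction: variant substitution into a reference
# genome, a liftover map derived from indel offsets, and annotation transfer
# with class-specific retention filters.

#' Substitute variants into a reference to build a pseudo-reference
#'
#' Replaces each REF span with its ALT allele and accumulates a liftover map
#' of monotone coordinate blocks.  SNPs (length-preserving substitutions) do
#' not break blocks; indels end the current block at the anchor base, leave
#' deleted source positions unmapped, and shift downstream coordinates by the
#' cumulative length difference.  Insertions map the flanking source base to
#' the first target base of the expanded span (chain-file semantics).
#'
#' @param reference Named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`), or a path to a FASTA file.
#' @param variants Variant data frame (`chrom`, `pos`, `ref`, `alt`) or a
#'   path to a VCF file.  Records must be sorted and non-overlapping;
#'   multi-allelic records (comma in ALT) are rejected.
#' @return List with `genome` (pseudo-reference, named character vector) and
#'   `map` (a `liftover_map`).
#' @examples
#' out <- apply_variants(c(chrI = "ACGTACGTAC"),
#'   data.frame(chrom = "chrI", pos = 2L, ref = "C", alt = "T"))
#' out$genome
#' @export
apply_variants <- function(reference, variants) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) reference <- read_genome(reference)
  if (methods::is(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  if (is.character(variants) && length(variants) == 1L)
    variants <- read_vcf(variants)
  if (nrow(variants) && any(grepl(",", variants$alt, fixed = TRUE)))
    stopf("multi-allelic records are not supported (ALT with comma)")
  unknown <- setdiff(unique(variants$chrom), names(reference))
  if (length(unknown))
    stopf("variants on unknown chromosome(s): %s", paste(unknown, collapse = ", "))

  genome <- reference
  map <- list()
  for (ch in names(reference)) {
    src <- reference[[ch]]
    L <- nchar(src)
    v <- variants[variants$chrom == ch, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    if (nrow(v)) {
      ends <- v$pos + nchar(v$ref) - 1L
      if (any(v$pos[-1] <= ends[-length(ends)]))
        stopf("overlapping variants on %s near position %d", ch,
              v$pos[which(v$pos[-1] <= ends[-length(ends)])[1] + 1L])
      mism <- substr(rep(src, nrow(v)), v$pos, ends) != v$ref
      if (any(mism))
        stopf("REF mismatch at %s:%d (expected %s)", ch, v$pos[which(mism)[1]],
              v$ref[which(mism)[1]])
    }
    pieces <- character(); cursor <- 1L
    blocks <- list(); offset <- 0L; blk_start <- 1L
    for (i in seq_len(nrow(v))) {
      p <- v$pos[i]; lr <- nchar(v$ref[i]); la <- nchar(v$alt[i])
      pieces <- c(pieces, substr(src, cursor, p - 1L), v$alt[i])
      cursor <- p + lr
      if (lr != la) {
        # current identity block ends at the anchor base p
        blocks[[length(blocks) + 1L]] <-
          c(blk_start, p, blk_start + offset, p + offset)
        offset <- offset + (la - lr)
        blk_start <- p + lr
      }
    }
    pieces <- c(pieces, substr(src, cursor, L))
    genome[[ch]] <- paste(pieces, collapse = "")
    if (blk_start <= L)
      blocks[[length(blocks) + 1L]] <- c(blk_start, L, blk_start + offset,
                                         L + offset)
    m <- do.call(rbind, blocks)
    map[[ch]] <- data.frame(src_start = m[, 1], src_end = m[, 2],
                            tgt_start = m[, 3], tgt_end = m[, 4])
  }
  structure(list(genome = genome,
                 map = structure(map, class = "liftover_map")),
            class = "pseudo_reference")
}

#' Lift positions through a liftover map
#'
#' Positions falling inside deleted spans (between blocks) are unmapped and
#' return `NA`.
#'
#' @param map A `liftover_map` from [apply_variants()].
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos Integer positions (1-based).
#' @return Integer vector of lifted positions, `NA` where unmapped.
#' @export
lift_position <- function(map, chrom, pos) {
  stopifnot(inherits(map, "liftover_map"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_integer_, n)
  for (ch in unique(chrom)) {
    b <- map[[ch]]
    if (is.null(b)) next
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel], b$src_start)
    ok <- idx >= 1L & idx <= nrow(b)
    ok[ok] <- pos[sel][ok] <= b$src_end[idx[ok]]
    out[sel[ok]] <- b$tgt_start[idx[ok]] + (pos[sel][ok] - b$src_start[idx[ok]])
  }
  out
}

#' Invert a liftover map (target -> source)
#' @param map A `liftover_map`.
#' @return A `liftover_map` mapping pseudo-reference coordinates back.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "liftover_map"))
  structure(lapply(map, function(b)
    data.frame(src_start = b$tgt_start, src_end = b$tgt_end,
               tgt_start = b$src_start, tgt_end = b$src_end)),
    class = "liftover_map")
}

#' Transfer annotations onto a pseudo-reference
#'
#' A feature transfers iff both endpoints map through the liftover.  For
#' features with exon parts, every constituent part must additionally convert
#' completely: both part endpoints map and the lifted part keeps its source
#' length (an internal indel breaks the part and drops the whole feature).
#' piRNA features additionally require the lifted locus to still be 21 bp
#' long and to start with T on its annotated strand in the pseudo-reference.
#' Features on chromosomes absent from the map are dropped with a warning.
#'
#' @param features,parts Annotation tables (as in `annotated_genome`).
#' @param map A `liftover_map`.
#' @param pseudo_genome Named character vector of pseudo-reference sequences.
#' @return List with lifted `features`, `parts`, and `report` (a
#'   `transfer_report`: per-class `n_input`, `n_transferred`, `fraction`, and
#'   a `dropped` table with reasons in `part_failed`, `piRNA_length`,
#'   `piRNA_first_base`).
#' @export
lift_annotations <- function(features, parts, map, pseudo_genome) {
  stopifnot(inherits(map, "liftover_map"))
  unknown <- !(features$chrom %in% names(map))
  if (any(unknown))
    warning(sprintf("%d feature(s) on chromosomes absent from the map dropped",
                    sum(unknown)), call. = FALSE)
  drop <- data.frame(feature_id = features$feature_id[unknown],
                     reason = rep("part_failed", sum(unknown)),
                     stringsAsFactors = FALSE)
  keep <- features[!unknown, , drop = FALSE]

  new_start <- lift_position(map, keep$chrom, keep$start)
  new_end <- lift_position(map, keep$chrom, keep$end)
  p_start <- lift_position(map, parts$chrom, parts$start)
  p_end <- lift_position(map, parts$chrom, parts$end)
  # complete conversion: endpoints map and the part keeps its length
  part_ok <- !(is.na(p_start) | is.na(p_end)) &
    (p_end - p_start == parts$end - parts$start)
  bad_part_features <- unique(parts$feature_id[!part_ok])

  failed <- is.na(new_start) | is.na(new_end) |
    keep$feature_id %in% bad_part_features
  reason <- rep(NA_character_, nrow(keep))
  reason[failed] <- "part_failed"

  is_pi <- keep$class == "piRNA" & !failed
  if (any(is_pi)) {
    plen <- new_end[is_pi] - new_start[is_pi] + 1L
    first <- ifelse(keep$strand[is_pi] == "+",
                    substr(pseudo_genome[keep$chrom[is_pi]],
                           new_start[is_pi], new_start[is_pi]),
                    comp_base(substr(pseudo_genome[keep$chrom[is_pi]],
                                     new_end[is_pi], new_end[is_pi])))
    bad_len <- plen != 21L
    bad_first <- !bad_len & first != "T"
    idx <- which(is_pi)
    reason[idx[bad_len]] <- "piRNA_length"
    reason[idx[bad_first]] <- "piRNA_first_base"
    failed[idx[bad_len | bad_first]] <- TRUE
  }

  drop <- rbind(drop, data.frame(feature_id = keep$feature_id[failed],
                                 reason = reason[failed],
                                 stringsAsFactors = FALSE))
  lifted <- keep[!failed, , drop = FALSE]
  lifted$start <- new_start[!failed]
  lifted$end <- new_end[!failed]
  lifted_parts <- parts[part_ok & parts$feature_id %in% lifted$feature_id, ,
                        drop = FALSE]
  lifted_parts$start <- p_start[part_ok & parts$feature_id %in% lifted$feature_id]
  lifted_parts$end <- p_end[part_ok & parts$feature_id %in% lifted$feature_id]
  rownames(lifted) <- rownames(lifted_parts) <- NULL

  classes <- sort(unique(features$class))
  n_in <- vapply(classes, function(cl) sum(features$class == cl), integer(1))
  n_tr <- vapply(classes, function(cl) sum(lifted$class == cl), integer(1))
  report <- structure(list(
    summary = data.frame(class = classes, n_input = n_in, n_transferred = n_tr,
                         fraction = ifelse(n_in > 0, n_tr / n_in, NA_real_),
                         row.names = NULL, stringsAsFactors = FALSE),
    dropped = drop), class = "transfer_report")
  list(features = lifted, parts = lifted_parts, report = report)
}

#' Percentage of features of a class that transferred
#'
#' @param report A `transfer_report` from [lift_annotations()], or a list /
#'   data frame carrying `n_input` and `n_transferred` directly.
#' @param class Feature class to report (ignored when counts are passed
#'   directly without a class column).
#' @return `100 * n_transferred / n_input`, rounded to one decimal.
#' @examples
#' transfer_rate(list(n_input = 20829, n_transferred = 17038))  # 81.8
#' @export
transfer_rate <- function(report, class = NULL) {
  if (inherits(report, "transfer_report")) report <- report$summary
  report <- as.data.frame(report)
  if (!is.null(class) && "class" %in% names(report))
    report <- report[report$class == class, , drop = FALSE]
  if (nrow(report) != 1L)
    stopf("transfer_rate needs exactly one class; got %d rows", nrow(report))
  if (report$n_input == 0L)
    stopf("transfer rate undefined: n_input is 0")
  round(100 * report$n_transferred / report$n_input, 1)
}
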