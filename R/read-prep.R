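# Pre-alignment read processing: 3' adapter trimming, 5' adapter screening,
# barcode demultiplexing, and final length filtering.  Error counting uses
# edit distance (indels allowed); N bases count as mismatches.

#' Trimming policy
#'
#' @param adapter_3p 3' adapter removed together with everything 3' of it.
#' @param adapter_5p 5' adapter whose 3'-end presence at a read's 5' end
#'   causes the read to be discarded.
#' @param max_error_rate Maximum allowed errors as a fraction of the matched
#'   adapter length.
#' @param min_5p_overlap_discard Minimum 5' adapter overlap (nt) that triggers
#'   a discard.
#' @param min_3p_overlap Minimum matched 3' adapter length for a partial
#'   (read-end) occurrence to count; full occurrences are always eligible.
#' @param post_trim_min,post_trim_max Length bounds applied after 3' trimming
#'   (barcode still attached).
#' @param barcode_length Sample barcode length at the read 5' end.
#' @param final_min,final_max Length bounds applied after barcode removal.
#' @return A list of class `trim_policy`.
#' @export
trim_policy <- function(adapter_3p = "CTGTAGGCACCATCAAT",
                        adapter_5p = "TCTACAGTCCGACGATC",
                        max_error_rate = 0.1,
                        min_5p_overlap_discard = 14L,
                        min_3p_overlap = 3L,
                        post_trim_min = 21L, post_trim_max = 34L,
                        barcode_length = 4L,
                        final_min = 17L, final_max = 30L) {
  stopifnot(max_error_rate >= 0, max_error_rate < 1, final_min <= final_max)
  structure(list(adapter_3p = adapter_3p, adapter_5p = adapter_5p,
                 max_error_rate = max_error_rate,
                 min_5p_overlap_discard = as.integer(min_5p_overlap_discard),
                 min_3p_overlap = as.integer(min_3p_overlap),
                 post_trim_min = as.integer(post_trim_min),
                 post_trim_max = as.integer(post_trim_max),
                 barcode_length = as.integer(barcode_length),
                 final_min = as.integer(final_min),
                 final_max = as.integer(final_max)), class = "trim_policy")
}

# Semi-global DP: align the adapter (or an adapter prefix reaching the read
# end) against read[j..n].  Returns c(matched_length, errors) for the best
# acceptable occurrence starting at j (longest matched adapter, then fewest
# errors), or c(0, Inf) if none.  Acceptable: edit distance <=
# floor(max_error_rate * matched_length); suffix (partial) matches shorter
# than min_overlap are ignored.
adapter_match_len_at <- function(read_chars, j, adapter_chars, max_error_rate,
                                 min_overlap) {
  la <- length(adapter_chars)
  emax <- floor(max_error_rate * la)
  n <- length(read_chars)
  # the alignment consumes at most la + emax read characters
  m <- min(n - j + 1L, la + emax)
  at_end <- (j + m - 1L) == n  # window reaches the read end (suffix case live)
  seg <- read_chars[j + seq_len(m) - 1L]
  prev <- 0:m                          # row i = 0
  best_k <- 0L; best_err <- Inf
  for (i in seq_len(la)) {
    mism <- (adapter_chars[i] != seg) | (adapter_chars[i] == "N") | (seg == "N")
    row <- c(i, pmin(prev[seq_len(m)] + mism,  # diagonal (match/substitution)
                     prev[-1L] + 1L))          # gap in adapter
    row <- cummin_row(row)                     # gap in read, left-to-right
    if (at_end && i >= min_overlap && i > best_k &&
        row[m + 1L] <= floor(max_error_rate * i)) {
      best_k <- i; best_err <- row[m + 1L]
    }
    prev <- row
  }
  if (min(prev) <= emax) {              # full adapter matched (infix)
    best_k <- la; best_err <- min(prev)
  }
  c(best_k, best_err)
}

# enforce row[t] <= row[t-1] + 1 (left-to-right gap propagation)
cummin_row <- function(row) {
  t <- seq_along(row) - 1L
  cummin(row - t) + t
}

#' Trim the 3' adapter from one read
#'
#' The best suffix/infix occurrence of the adapter (error fraction of the
#' matched adapter length <= `max_error_rate`, edit distance) is removed
#' together with everything 3' of it; ties are broken in favour of the
#' longest retained insert.  Reads whose remainder falls outside
#' `[post_trim_min, post_trim_max]` are discarded; untrimmed reads pass
#' through the same length filter.
#'
#' @param read A nucleotide string (ACGTN).
#' @param policy A [trim_policy()].
#' @return List with `seq` (trimmed read or `NA`), `trimmed` (logical) and
#'   `status` in `kept` / `discarded_length`.
#' @export
trim_3p <- function(read, policy = trim_policy()) {
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  ac <- strsplit(policy$adapter_3p, "", fixed = TRUE)[[1]]
  cut <- nchar(read) + 1L  # first removed position; default: nothing removed
  trimmed <- FALSE
  if (length(ac) && nchar(read)) {
    # best occurrence = longest matched adapter stretch, then fewest errors;
    # remaining ties broken by the longest retained insert (largest start).
    # Scanning right to left lets an error-free full match short-circuit.
    best_k <- 0L; best_err <- Inf
    for (j in rev(seq_along(rc))) {
      ke <- adapter_match_len_at(rc, j, ac, policy$max_error_rate,
                                 policy$min_3p_overlap)
      if (ke[1] > best_k || (ke[1] == best_k && ke[2] < best_err)) {
        best_k <- ke[1]; best_err <- ke[2]; cut <- j; trimmed <- TRUE
        if (best_k == length(ac) && best_err == 0) break
      }
    }
  }
  out <- substr(read, 1L, cut - 1L)
  if (nchar(out) < policy$post_trim_min || nchar(out) > policy$post_trim_max)
    list(seq = NA_character_, trimmed = trimmed, status = "discarded_length")
  else list(seq = out, trimmed = trimmed, status = "kept")
}

#' Screen a read's 5' end for the 5' adapter
#'
#' Discards the read iff >= `min_5p_overlap_discard` nt of the 3' end of the
#' 5' adapter match the read's 5' end at an error rate (edit distance over
#' the overlap length) <= `max_error_rate`.
#'
#' @param read A 3'-trimmed read.
#' @param policy A [trim_policy()].
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
filter_5p <- function(read, policy = trim_policy()) {
  la <- nchar(policy$adapter_5p)
  kmax <- min(la, nchar(read))
  ks <- seq_len(kmax)
  ks <- ks[ks >= policy$min_5p_overlap_discard]
  for (k in ks) {
    tail_a <- substr(policy$adapter_5p, la - k + 1L, la)
    head_r <- substr(read, 1L, k)
    if (utils::adist(tail_a, head_r) <= floor(policy$max_error_rate * k))
      return(FALSE)
  }
  TRUE
}

#' Demultiplex reads by exact 5' barcode match
#'
#' @param reads Character vector of barcode-bearing reads.
#' @param barcodes Named character vector mapping sample id -> 4 nt barcode;
#'   duplicates are a configuration error.
#' @param barcode_length Barcode length (4 nt).
#' @return Data frame with `sample` (`NA` for the unassigned bin) and `seq`
#'   (barcode-stripped read).
#' @export
demultiplex <- function(reads, barcodes, barcode_length = 4L) {
  if (anyDuplicated(barcodes)) stopf("duplicate barcodes in table")
  if (any(nchar(barcodes) != barcode_length))
    stopf("all barcodes must be %d nt", barcode_length)
  bc <- substr(reads, 1L, barcode_length)
  hit <- match(bc, barcodes)
  data.frame(sample = names(barcodes)[hit],
             seq = substr(reads, barcode_length + 1L, nchar(reads)),
             stringsAsFactors = FALSE)
}

#' Final insert length filter
#'
#' @param read Barcode-stripped read(s).
#' @param final_min,final_max Retained length bounds (17-30 nt).
#' @return Logical vector: keep iff `final_min <= length <= final_max`.
#' @export
final_length_filter <- function(read, final_min = 17L, final_max = 30L) {
  nchar(read) >= final_min & nchar(read) <= final_max
}

#' Run the full read-preparation cascade
#'
#' Fixed order: 3' adapter trimming -> 5' adapter screen -> barcode
#' demultiplexing -> final length filter.  Every input read ends in exactly
#' one terminal state, so reason counts conserve the input total.
#'
#' @param reads Data frame with `read_id` and `seq` (raw reads), or a FASTQ
#'   path.
#' @param policy A [trim_policy()].
#' @param barcodes Named character vector (sample -> barcode).
#' @return List with `reads` (kept reads: `read_id`, `sample`, `seq`),
#'   `log` (per-read terminal state) and `summary` (state counts).
#' @export
run_read_prep <- function(reads, policy = trim_policy(), barcodes) {
  if (is.character(reads)) reads <- read_fastq(reads)
  n <- nrow(reads)
  state <- character(n)
  seqs <- reads$seq
  t3 <- lapply(seqs, trim_3p, policy = policy)
  seqs <- vapply(t3, `[[`, character(1), "seq")
  state[is.na(seqs)] <- "discarded_trim_length"
  live <- which(is.na(state) | state == "")
  keep5 <- vapply(seqs[live], filter_5p, logical(1), policy = policy)
  state[live[!keep5]] <- "discarded_5p_adapter"
  live <- live[keep5]
  dm <- demultiplex(seqs[live], barcodes, policy$barcode_length)
  state[live[is.na(dm$sample)]] <- "unassigned_barcode"
  assigned <- !is.na(dm$sample)
  flen <- final_length_filter(dm$seq[assigned], policy$final_min,
                              policy$final_max)
  state[live[assigned][!flen]] <- "discarded_final_length"
  kept_idx <- live[assigned][flen]
  state[kept_idx] <- "kept"
  out <- data.frame(read_id = reads$read_id[kept_idx],
                    sample = dm$sample[assigned][flen],
                    seq = dm$seq[assigned][flen], stringsAsFactors = FALSE)
  log <- data.frame(read_id = reads$read_id, state = state,
                    stringsAsFactors = FALSE)
  summary <- as.data.frame(table(state = state), stringsAsFactors = FALSE)
  names(summary)[2] <- "n"
  list(reads = out, log = log, summary = summary)
}
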