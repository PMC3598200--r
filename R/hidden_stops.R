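#' Hidden stop codon detection
#'
#' A hidden stop codon (HSC; also "off-frame stop", OSC) is a stop-codon
#' triplet that appears in the +1 or -1 shifted reading frame of a coding
#' sequence. Under the ambush hypothesis such triplets terminate erroneous
#' frameshifted translation early. This module finds, counts and localizes
#' them, splits counts between gene halves, and scores each codon's
#' capacity to contribute to off-frame stops across dicodon junctions.
#'
#' For a bare linear CDS the +1 frame is realized as triplets starting at
#' nucleotide offset 1 and the -1 frame as triplets starting at offset 2
#' (the standard surrogate: with no upstream context, shifting back one
#' nucleotide visits the same registers as shifting forward two).
#'
#' @name hidden_stops
NULL

.frame_offset <- function(frame) {
  if (identical(frame, 1) || identical(frame, 1L) || identical(frame, "+1"))
    return(1L)
  if (identical(frame, -1) || identical(frame, -1L) || identical(frame, "-1"))
    return(2L)
  stop("frame must be +1 or -1")
}

#' Find hidden stop codons in one shifted frame
#'
#' Scans complete triplets starting at nucleotide offset 1 (+1 frame) or 2
#' (-1 frame), stepping by 3. Triplets containing non-ACGT characters are
#' masked: excluded from both the records and the off-frame position count.
#'
#' @param seq A `coding_sequence` (or nucleotide string).
#' @param code A `genetic_code`.
#' @param frame `+1` or `-1` (numeric or string).
#' @return data.frame with columns `start_nt` (0-based), `triplet`, `frame`,
#'   sorted by `start_nt`; attribute `n_offframe_positions` gives the number
#'   of complete, unmasked off-frame triplets scanned.
#' @export
find_hidden_stops <- function(seq, code, frame) {
  seq <- as_coding_sequences(seq)[[1]]
  stopifnot(inherits(code, "genetic_code"))
  off <- .frame_offset(frame)
  frame_lab <- if (off == 1L) "+1" else "-1"
  s <- seq$sequence
  n <- nchar(s)
  empty <- data.frame(start_nt = integer(0), triplet = character(0),
                      frame = character(0), stringsAsFactors = FALSE)
  if (n < off + 3L) {
    attr(empty, "n_offframe_positions") <- 0L
    return(empty)
  }
  starts0 <- seq.int(off, n - 3L, by = 3L)           # 0-based start offsets
  trips <- substring(s, starts0 + 1L, starts0 + 3L)
  clean <- !grepl("[^ACGT]", trips)
  hit <- clean & trips %in% code$stop_set
  out <- data.frame(start_nt = starts0[hit], triplet = trips[hit],
                    frame = rep(frame_lab, sum(hit)),
                    stringsAsFactors = FALSE)
  attr(out, "n_offframe_positions") <- sum(clean)
  out
}

#' Half-gene split of hidden-stop counts
#'
#' Divides the gene into codons and splits it at floor(n/2): the first half
#' is codons [0, floor(n/2)), the second half the rest. Each hidden stop is
#' assigned to the half containing its starting nucleotide.
#'
#' @param seq A `coding_sequence` (or string).
#' @param code A `genetic_code`.
#' @return 2x2 integer matrix, rows `plus1`/`minus1`, columns
#'   `first_half`/`second_half`.
#' @export
half_gene_analysis <- function(seq, code) {
  seq <- as_coding_sequences(seq)[[1]]
  n <- length(seq$codons)
  if (n < 2L)
    stop("sequence too short for half-gene analysis (need >= 2 codons)")
  split_nt <- 3L * (n %/% 2L)  # first nt of the second half
  m <- matrix(0L, 2, 2, dimnames = list(c("plus1", "minus1"),
                                        c("first_half", "second_half")))
  for (i in 1:2) {
    hits <- find_hidden_stops(seq, code, c(1, -1)[i])
    m[i, 1] <- sum(hits$start_nt < split_nt)
    m[i, 2] <- sum(hits$start_nt >= split_nt)
  }
  m
}

#' Per-codon contribution scores to hidden stops
#'
#' For codon c = n1 n2 n3 the score counts the (stop codon S, junction
#' role) combinations in which c can supply part of an off-frame stop at a
#' dicodon junction:
#' left partner in +1 (n2 n3 = S1 S2), right partner in +1 (n1 = S3),
#' left partner in -1 (n3 = S1), right partner in -1 (n1 n2 = S2 S3).
#' The score depends only on the code's stop set.
#'
#' @param code A `genetic_code`.
#' @return Named integer vector over all 64 codons.
#' @examples
#' codon_contribution_scores(get_genetic_code(1))[c("TTA", "ATA", "CCC")]
#' @export
codon_contribution_scores <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- all_codons()
  stops <- code$stop_set
  score <- integer(64)
  for (S in stops) {
    s1 <- substr(S, 1, 1); s12 <- substr(S, 1, 2)
    s3 <- substr(S, 3, 3); s23 <- substr(S, 2, 3)
    score <- score +
      (substr(codons, 2, 3) == s12) +  # left partner, +1
      (substr(codons, 1, 1) == s3)  +  # right partner, +1
      (substr(codons, 3, 3) == s1)  +  # left partner, -1
      (substr(codons, 1, 2) == s23)    # right partner, -1
  }
  stats::setNames(as.integer(score), codons)
}

#' Per-sequence hidden-stop report
#'
#' @param seq A `coding_sequence` (or string).
#' @param code A `genetic_code`.
#' @return Object of class `hidden_stop_report`: list with `seq_id`,
#'   `records` (data.frame over both frames), per-frame `counts`, `total`,
#'   `n_offframe_positions`, `hsc_frequency` (count per unmasked off-frame
#'   position), and `half_gene` (2x2 matrix, NA if < 2 codons).
#' @export
hidden_stop_report <- function(seq, code) {
  seq <- as_coding_sequences(seq)[[1]]
  plus <- find_hidden_stops(seq, code, 1)
  minus <- find_hidden_stops(seq, code, -1)
  npos <- c(plus1 = attr(plus, "n_offframe_positions"),
            minus1 = attr(minus, "n_offframe_positions"))
  counts <- c(plus1 = nrow(plus), minus1 = nrow(minus))
  half <- if (length(seq$codons) >= 2L) half_gene_analysis(seq, code) else NA
  structure(list(
    seq_id = seq$seq_id,
    records = rbind(plus, minus),
    counts = counts,
    total = sum(counts),
    n_offframe_positions = npos,
    hsc_frequency = ifelse(npos > 0L, counts / npos, NA_real_),
    half_gene = half
  ), class = "hidden_stop_report")
}

#' @export
print.hidden_stop_report <- function(x, ...) {
  cat("HiddenStopReport", x$seq_id, ": total", x$total,
      sprintf("(+1: %d, -1: %d)\n", x$counts["plus1"], x$counts["minus1"]))
  invisible(x)
}

#' Batch hidden-stop summary over many sequences
#'
#' One report per sequence plus an aggregate row; a per-sequence failure is
#' recorded as a flagged row rather than aborting the batch.
#'
#' @param seqs List of `coding_sequence` objects (or character vector).
#' @param code A `genetic_code`.
#' @return List with `reports` (per-sequence `hidden_stop_report`s, NULL
#'   where a sequence failed), `summary` (data.frame: seq_id, hsc_plus1,
#'   hsc_minus1, freq_plus1, freq_minus1, first_half_plus1,
#'   second_half_plus1, first_half_minus1, second_half_minus1, error), and
#'   `total` hidden stops across all successful sequences.
#' @export
hsc_summary <- function(seqs, code) {
  seqs <- as_coding_sequences(seqs)
  if (length(seqs) == 0L) stop("no sequences provided")
  reports <- vector("list", length(seqs))
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rep_i <- tryCatch(hidden_stop_report(seqs[[i]], code),
                      error = function(e) conditionMessage(e))
    if (is.character(rep_i)) {
      rows[[i]] <- data.frame(seq_id = seqs[[i]]$seq_id, hsc_plus1 = NA,
                              hsc_minus1 = NA, freq_plus1 = NA,
                              freq_minus1 = NA, first_half_plus1 = NA,
                              second_half_plus1 = NA, first_half_minus1 = NA,
                              second_half_minus1 = NA, error = rep_i,
                              stringsAsFactors = FALSE)
    } else {
      reports[[i]] <- rep_i
      hg <- rep_i$half_gene
      hg_ok <- is.matrix(hg)
      rows[[i]] <- data.frame(
        seq_id = rep_i$seq_id,
        hsc_plus1 = rep_i$counts["plus1"], hsc_minus1 = rep_i$counts["minus1"],
        freq_plus1 = rep_i$hsc_frequency["plus1"],
        freq_minus1 = rep_i$hsc_frequency["minus1"],
        first_half_plus1 = if (hg_ok) hg["plus1", 1] else NA,
        second_half_plus1 = if (hg_ok) hg["plus1", 2] else NA,
        first_half_minus1 = if (hg_ok) hg["minus1", 1] else NA,
        second_half_minus1 = if (hg_ok) hg["minus1", 2] else NA,
        error = "", stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(reports = reports, summary = summary,
       total = sum(unlist(lapply(reports, function(r)
         if (is.null(r)) 0L else r$total))))
}
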