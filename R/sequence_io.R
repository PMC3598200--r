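#' Reading and validating coding DNA sequences
#'
#' Input is one or more coding DNA sequences, from FASTA or raw strings.
#' Sequences are uppercased, U is transliterated to T, and each sequence is
#' decomposed into in-frame codons starting at position 0. Coordinates are
#' 0-based, half-open throughout the package.
#'
#' @name sequence_io
NULL

.IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' Construct a validated coding sequence
#'
#' @param sequence Nucleotide string (case-insensitive; U allowed and
#'   converted to T; IUPAC ambiguity letters allowed).
#' @param seq_id Identifier string.
#' @return An object of class `coding_sequence`: list with `seq_id`,
#'   `sequence` (uppercase DNA), `codons` (in-frame triplets from position
#'   0), `trailing_len` (0-2 leftover nucleotides, retained in `sequence`
#'   but not in `codons`).
#' @export
coding_sequence <- function(sequence, seq_id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(gsub("[[:space:]]", "", unname(sequence)))
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L)
    stop("record '", seq_id, "' has an empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .IUPAC_LETTERS)
  if (length(bad) > 0L)
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1] - 1L,
         " (0-based) in record '", seq_id, "'")
  n <- nchar(s)
  n_codons <- n %/% 3L
  codons <- if (n_codons > 0L) {
    starts <- seq.int(1L, by = 3L, length.out = n_codons)
    substring(s, starts, starts + 2L)
  } else character(0)
  structure(list(seq_id = seq_id, sequence = s, codons = codons,
                 trailing_len = n - 3L * n_codons),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("CodingSequence", x$seq_id, ":", nchar(x$sequence), "nt,",
      length(x$codons), "codons, trailing", x$trailing_len, "nt\n")
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Record order is preserved. Sequences are uppercased and U is converted
#' to T. A warning is raised for any record whose length is not a multiple
#' of 3 (the trailing partial codon is retained in the sequence but excluded
#' from the codon list).
#'
#' @param path Path to a FASTA file with at least one record.
#' @return List of `coding_sequence` objects, named by record id (first
#'   whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records found in ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  seqs <- as.character(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- coding_sequence(seqs[i], seq_id = ids[i])
    if (out[[i]]$trailing_len != 0L)
      warning("record '", ids[i], "': length not a multiple of 3 (",
              out[[i]]$trailing_len, " trailing nt)", call. = FALSE)
  }
  names(out) <- ids
  out
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs List of `coding_sequence` objects.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_coding_sequences(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "sequence"))
  names(set) <- vapply(seqs, `[[`, "", "seq_id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Accept a single coding_sequence, a list of them, or raw character strings.
as_coding_sequences <- function(x) {
  if (inherits(x, "coding_sequence")) return(list(x))
  if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    return(mapply(coding_sequence, x, ids, SIMPLIFY = FALSE))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "coding_sequence")))
  x
}

#' Validate a coding sequence against a genetic code
#'
#' Report-only: nothing is rejected, because users may submit partial CDSs.
#' Flags (a) length not divisible by 3, (b) internal in-frame stop codons
#' (any stop codon before the final codon) with their codon indices,
#' (c) ambiguity (non-ACGT) characters with a count.
#'
#' @param seq A `coding_sequence`.
#' @param code A `genetic_code`.
#' @return List with `seq_id`, `length`, `n_codons`, `length_multiple_of_3`,
#'   `internal_stop_indices` (0-based codon indices), `n_internal_stops`,
#'   `terminal_stop` (logical), `n_ambiguous`, `n_masked_codons` (codons
#'   containing any non-ACGT character).
#' @export
validate_cds <- function(seq, code) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(code, "genetic_code"))
  codons <- seq$codons
  n <- length(codons)
  internal <- if (n > 1L) {
    which(codons[-n] %in% code$stop_set) - 1L
  } else integer(0)
  list(
    seq_id = seq$seq_id,
    length = nchar(seq$sequence),
    n_codons = n,
    length_multiple_of_3 = seq$trailing_len == 0L,
    internal_stop_indices = internal,
    n_internal_stops = length(internal),
    terminal_stop = n > 0L && codons[n] %in% code$stop_set,
    n_ambiguous = nchar(gsub("[ACGT]", "", seq$sequence)),
    n_masked_codons = sum(grepl("[^ACGT]", codons))
  )
}

#' Write a TSV validation report for a set of sequences
#'
#' @param seqs List of `coding_sequence` objects (or character strings).
#' @param code A `genetic_code`.
#' @param path Output TSV path, or NULL to just return the data.frame.
#' @return data.frame with one row per sequence.
#' @export
validation_report <- function(seqs, code, path = NULL) {
  seqs <- as_coding_sequences(seqs)
  rows <- lapply(seqs, function(s) {
    v <- validate_cds(s, code)
    data.frame(seq_id = v$seq_id, length = v$length, n_codons = v$n_codons,
               internal_stops = v$n_internal_stops,
               masked_codons = v$n_masked_codons,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
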