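#' Codon usage, RSCU, relative adaptiveness and CAI
#'
#' Codon usage frequencies (CUF) are the fraction of in-frame codon
#' occurrences attributable to each codon. RSCU divides a codon's count by
#' the mean count of its synonymous family (1 = no bias). Relative
#' adaptiveness w_i divides a codon's count by the count of the most used
#' synonym in its family, so the preferred codon of each family scores 1.
#' The codon adaptation index (CAI) is the geometric mean of the w_i of a
#' gene's codons: 1 when the gene uses only family-preferred codons, and
#' falling toward 0 as it conforms less to the reference usage.
#'
#' @name codon_metrics
NULL

#' Pooled codon usage of one or more coding sequences
#'
#' Counts all in-frame codons free of non-ACGT characters, pooled across
#' sequences. The terminal codon of a sequence is excluded when it is a
#' stop codon and `exclude_terminal_stop` is set (the default), so that a
#' complete CDS contributes only sense-codon usage.
#'
#' @param seqs List of `coding_sequence` objects (or character vector).
#' @param code A `genetic_code`.
#' @param exclude_terminal_stop Drop each sequence's final codon when it is
#'   a stop (default TRUE).
#' @param w_floor Relative adaptiveness assigned to zero-count codons
#'   (default 0.01); a hard zero would collapse the CAI geometric mean.
#' @param source Free-text provenance label.
#' @return Object of class `codon_usage_table`: list with `counts` and
#'   `frequencies` (named numeric over all 64 codons; frequencies sum to 1
#'   over counted codons), `w` (relative adaptiveness, stop family
#'   excluded), `n_masked` and `source`.
#' @export
codon_usage <- function(seqs, code, exclude_terminal_stop = TRUE,
                        w_floor = 0.01, source = "input sequences") {
  seqs <- as_coding_sequences(seqs)
  stopifnot(inherits(code, "genetic_code"))
  pooled <- character(0)
  n_masked <- 0L
  for (s in seqs) {
    codons <- s$codons
    n <- length(codons)
    if (exclude_terminal_stop && n > 0L && codons[n] %in% code$stop_set)
      codons <- codons[-n]
    clean <- !grepl("[^ACGT]", codons)
    n_masked <- n_masked + sum(!clean)
    pooled <- c(pooled, codons[clean])
  }
  if (length(pooled) == 0L)
    stop("no countable codons in input")
  counts <- table(factor(pooled, levels = all_codons()))
  counts <- stats::setNames(as.numeric(counts), all_codons())
  usage_table_from_counts(counts, code, w_floor = w_floor, source = source)
}

#' Build a codon usage table from raw per-codon counts
#'
#' @param counts Named non-negative numeric vector; names are DNA or RNA
#'   codons (missing codons are taken as 0).
#' @inheritParams codon_usage
#' @return A `codon_usage_table`.
#' @export
usage_table_from_counts <- function(counts, code, w_floor = 0.01,
                                    source = "counts") {
  stopifnot(inherits(code, "genetic_code"), !is.null(names(counts)))
  names(counts) <- chartr("U", "T", toupper(names(counts)))
  if (any(!names(counts) %in% all_codons()))
    stop("unknown codon name(s): ",
         paste(setdiff(names(counts), all_codons()), collapse = ", "))
  if (any(counts < 0)) stop("codon counts must be non-negative")
  full <- stats::setNames(numeric(64), all_codons())
  full[names(counts)] <- counts
  total <- sum(full)
  if (total <= 0) stop("all codon counts are zero")
  tab <- structure(list(counts = full, frequencies = full / total,
                        w = NULL, n_masked = 0L, source = source),
                   class = "codon_usage_table")
  tab$w <- relative_adaptiveness(tab, code, w_floor = w_floor)
  tab
}

#' Read a codon usage table from a codon/count TSV
#'
#' Dialect: two columns `codon<TAB>count`, DNA or RNA letters, optional
#' header row.
#'
#' @param path TSV path.
#' @inheritParams codon_usage
#' @return A `codon_usage_table`.
#' @export
read_codon_usage <- function(path, code, w_floor = 0.01) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("codon", "count"))
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df$count[1]))))
    df <- df[-1, , drop = FALSE]  # header row
  counts <- stats::setNames(as.numeric(df$count), df$codon)
  usage_table_from_counts(counts, code, w_floor = w_floor, source = path)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("CodonUsageTable (", x$source, "): ", sum(x$counts), " codons, ",
      sum(x$counts > 0), "/64 observed\n", sep = "")
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = count(c) / mean count over c's synonymous family. Families
#' with zero total count are reported as NA.
#'
#' @param table A `codon_usage_table`.
#' @param code A `genetic_code`.
#' @return Named numeric over all 64 codons.
#' @export
rscu <- function(table, code) {
  stopifnot(inherits(table, "codon_usage_table"))
  fams <- synonymous_families(code)
  out <- stats::setNames(rep(NA_real_, 64), all_codons())
  for (fam in fams) {
    m <- mean(table$counts[fam])
    if (m > 0) out[fam] <- table$counts[fam] / m
  }
  out
}

#' Relative adaptiveness w of each sense codon
#'
#' w(c) = count(c) / max count in c's family. The preferred codon of every
#' family scores exactly 1; zero-count codons receive `w_floor` instead of
#' 0. Stop codons are excluded (NA). A family with zero total count gets
#' the floor for all members, with a warning.
#'
#' @inheritParams rscu
#' @param w_floor Floor for zero-count codons (default 0.01).
#' @return Named numeric over all 64 codons; NA for stop codons.
#' @export
relative_adaptiveness <- function(table, code, w_floor = 0.01) {
  stopifnot(inherits(table, "codon_usage_table"))
  fams <- synonymous_families(code)
  out <- stats::setNames(rep(NA_real_, 64), all_codons())
  for (aa in names(fams)) {
    if (aa == "*") next
    fam <- fams[[aa]]
    mx <- max(table$counts[fam])
    if (mx == 0) {
      warning("family '", aa, "' has zero total count; w floored at ",
              w_floor, call. = FALSE)
      out[fam] <- w_floor
    } else {
      w <- table$counts[fam] / mx
      w[w == 0] <- w_floor
      out[fam] <- w
    }
  }
  out
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the reference w over the gene's eligible codons,
#' computed in log space to avoid underflow on long genes. Stop codons,
#' single-codon families (Met and Trp under the standard code) and masked
#' codons are excluded, the usual Sharp-Li convention.
#'
#' @param gene A `coding_sequence` (or string).
#' @param reference A `codon_usage_table` giving reference usage.
#' @param code A `genetic_code`.
#' @return CAI in (0, 1].
#' @export
cai <- function(gene, reference, code) {
  gene <- as_coding_sequences(gene)[[1]]
  stopifnot(inherits(reference, "codon_usage_table"),
            inherits(code, "genetic_code"))
  fams <- synonymous_families(code)
  single <- unlist(fams[vapply(fams, length, 1L) == 1L], use.names = FALSE)
  excluded <- c(code$stop_set, single)
  codons <- gene$codons
  codons <- codons[!grepl("[^ACGT]", codons) & !codons %in% excluded]
  if (length(codons) == 0L)
    stop("no eligible codons for CAI (all stop/single-family/masked)")
  w <- reference$w[codons]
  exp(mean(log(w)))
}
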