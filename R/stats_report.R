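#' Correlation analyses and report assembly
#'
#' Two correlation questions drive the analysis. First, is codon usage
#' frequency (CUF) positively correlated with each codon's contribution to
#' hidden stops -- the signature of selection favouring hidden-stop-prone
#' codons? Second, across several genes, is GC content negatively
#' correlated with hidden-stop frequency (stop codons are AT-rich)?
#' Both use Pearson's r with a one-tailed Student t-test,
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom,
#' significant at alpha = 0.05.
#'
#' @name stats_report
NULL

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Pearson r.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' One-tailed t-test for a Pearson correlation
#'
#' t = r * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2. With
#' `alternative = "greater"` the p-value is the upper tail (testing
#' positive correlation); with `"less"`, the lower tail. |r| = 1 yields an
#' infinite t (flagged) and p = 0 in the matching direction.
#'
#' @param r Pearson correlation in [-1, 1].
#' @param n Number of paired observations (>= 3).
#' @param alternative "greater" (default) or "less".
#' @return List with `t_value`, `df`, `p_one_tailed`, `infinite` flag.
#' @export
one_tailed_t <- function(r, n, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 3, abs(r) <= 1 + 1e-12)
  r <- max(-1, min(1, r))
  df <- n - 2
  if (abs(r) == 1) {
    t <- sign(r) * Inf
    p <- if ((alternative == "greater") == (r > 0)) 0 else 1
    return(list(t_value = t, df = df, p_one_tailed = p, infinite = TRUE))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- stats::pt(t, df, lower.tail = (alternative == "less"))
  list(t_value = t, df = df, p_one_tailed = p, infinite = FALSE)
}

.correlation_result <- function(x, y, alternative, alpha = 0.05) {
  r <- pearson(x, y)
  tt <- one_tailed_t(r, length(x), alternative)
  structure(list(r = r, n = length(x), t_value = tt$t_value, df = tt$df,
                 p_one_tailed = tt$p_one_tailed, infinite = tt$infinite,
                 alternative = alternative, alpha = alpha,
                 significant = tt$p_one_tailed < alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d), one-tailed (%s) t = %.4g, p = %.4g%s\n",
              x$r, x$n, x$alternative, x$t_value, x$p_one_tailed,
              if (x$significant) sprintf(" *significant at %.2g*", x$alpha)
              else ""))
  invisible(x)
}

#' Correlation between codon usage and hidden-stop contribution
#'
#' Pairs, over the sense codons of the code, the pooled usage frequency of
#' the input sequences with the codon's hidden-stop contribution score.
#' Codons never observed are retained with frequency 0 (dropping them
#' would bias r on short genes). One-tailed for positive correlation by
#' default (the hypothesis that usage favours hidden-stop-prone codons).
#'
#' @param seqs List of `coding_sequence` objects or character vector.
#' @param code A `genetic_code`.
#' @param alternative Test direction, default "greater".
#' @return A `correlation_result` (r, n, t, one-tailed p, significance at
#'   0.05).
#' @export
cuf_contribution_correlation <- function(seqs, code,
                                         alternative = "greater") {
  usage <- codon_usage(seqs, code)
  sense <- setdiff(all_codons(), code$stop_set)
  contrib <- codon_contribution_scores(code)[sense]
  .correlation_result(as.numeric(usage$frequencies[sense]),
                      as.numeric(contrib), alternative)
}

#' Correlation between GC content and hidden-stop frequency
#'
#' For each of 5 or more sequences, x = (G+C)/(A+C+G+T) over unambiguous
#' bases and y = total hidden-stop frequency (both frames, per unmasked
#' off-frame position). One-tailed for negative correlation by default:
#' stop codons are AT-rich, so GC-rich genes should harbour fewer hidden
#' stops.
#'
#' @param seqs List of >= 5 `coding_sequence` objects or character vector.
#' @param code A `genetic_code`.
#' @param alternative Test direction, default "less".
#' @return A `correlation_result`.
#' @export
gc_hsc_correlation <- function(seqs, code, alternative = "less") {
  seqs <- as_coding_sequences(seqs)
  if (length(seqs) < 5)
    stop("requires 5 or more coding sequences")
  gc <- vapply(seqs, function(s) {
    b <- table(factor(strsplit(s$sequence, "")[[1]],
                      levels = c("A", "C", "G", "T")))
    sum(b[c("C", "G")]) / sum(b)
  }, numeric(1))
  hsc <- vapply(seqs, function(s) {
    r <- hidden_stop_report(s, code)
    r$total / sum(r$n_offframe_positions)
  }, numeric(1))
  .correlation_result(gc, hsc, alternative)
}

#' Assemble the full tabular report bundle
#'
#' Runs every analysis on a set of sequences and writes a deterministic
#' set of TSV tables plus a manifest to `out_dir`: hidden-stop records and
#' summary, half-gene counts, per-codon contribution scores, codon
#' usage/RSCU/w, per-gene CAI, correlation tests, and (optionally) Markov
#' null comparisons.
#'
#' @param seqs List of `coding_sequence` objects or character vector.
#' @param code A `genetic_code`.
#' @param out_dir Output directory (created if absent).
#' @param cai_reference Optional `codon_usage_table` for CAI; defaults to
#'   the pooled usage of the input sequences.
#' @param markov_order If non-NULL, run `hsc_null_comparison` at this
#'   order for every sequence.
#' @param n_sim Simulations per null comparison (default 1000).
#' @param seed Integer seed for the null comparisons (required when
#'   `markov_order` is set).
#' @return Invisibly, the manifest data.frame (file, description).
#' @export
build_report <- function(seqs, code, out_dir, cai_reference = NULL,
                         markov_order = NULL, n_sim = 1000, seed = NULL) {
  seqs <- as_coding_sequences(seqs)
  if (length(seqs) == 0L) stop("no sequences provided")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  wtsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file
  }
  manifest <- list()
  add <- function(file, desc)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, description = desc, stringsAsFactors = FALSE)

  batch <- hsc_summary(seqs, code)
  records <- do.call(rbind, lapply(batch$reports, function(r)
    if (is.null(r) || nrow(r$records) == 0) NULL
    else cbind(seq_id = r$seq_id, r$records)))
  if (is.null(records))
    records <- data.frame(seq_id = character(0), start_nt = integer(0),
                          triplet = character(0), frame = character(0))
  add(wtsv(records, "hidden_stops.tsv"), "per-sequence hidden-stop records")
  add(wtsv(batch$summary, "hsc_summary.tsv"),
      "hidden-stop counts, frequencies and half-gene split per sequence")
  contrib <- codon_contribution_scores(code)
  add(wtsv(data.frame(codon = names(contrib), score = as.integer(contrib)),
           "codon_contribution.tsv"), "per-codon hidden-stop contribution")

  usage <- codon_usage(seqs, code)
  rs <- rscu(usage, code)
  metrics <- data.frame(codon = all_codons(),
                        count = as.numeric(usage$counts),
                        frequency = as.numeric(usage$frequencies),
                        rscu = as.numeric(rs), w = as.numeric(usage$w))
  add(wtsv(metrics, "codon_metrics.tsv"), "usage, RSCU and w per codon")

  ref <- if (is.null(cai_reference)) usage else cai_reference
  cai_rows <- do.call(rbind, lapply(seqs, function(s) {
    v <- tryCatch(cai(s, ref, code), error = function(e) NA_real_)
    data.frame(seq_id = s$seq_id, cai = v, stringsAsFactors = FALSE)
  }))
  add(wtsv(cai_rows, "cai.tsv"), "per-gene codon adaptation index")

  corr_rows <- list()
  cc <- tryCatch(cuf_contribution_correlation(seqs, code),
                 error = function(e) NULL)
  if (!is.null(cc))
    corr_rows$cuf <- data.frame(test = "cuf_vs_contribution", r = cc$r,
                                n = cc$n, t = cc$t_value,
                                p_one_tailed = cc$p_one_tailed,
                                significant = cc$significant)
  gcr <- tryCatch(gc_hsc_correlation(seqs, code), error = function(e) NULL)
  if (!is.null(gcr))
    corr_rows$gc <- data.frame(test = "gc_vs_hsc_frequency", r = gcr$r,
                               n = gcr$n, t = gcr$t_value,
                               p_one_tailed = gcr$p_one_tailed,
                               significant = gcr$significant)
  if (length(corr_rows) > 0)
    add(wtsv(do.call(rbind, corr_rows), "correlations.tsv"),
        "correlation tests with one-tailed t")

  if (!is.null(markov_order)) {
    if (is.null(seed)) stop("seed is required for Markov null comparisons")
    null_rows <- do.call(rbind, lapply(seq_along(seqs), function(i) {
      nc <- hsc_null_comparison(seqs[[i]], code, markov_order,
                                n_sim = n_sim, seed = seed + i - 1L)
      data.frame(seq_id = seqs[[i]]$seq_id, order = nc$order,
                 observed = nc$observed_hsc, sim_mean = nc$sim_mean,
                 sim_sd = nc$sim_sd, z = nc$z_score,
                 empirical_p = nc$empirical_p, seed = nc$seed)
    }))
    add(wtsv(null_rows, "null_comparison.tsv"),
        "observed vs Markov-simulated hidden-stop counts")
  }

  manifest_df <- do.call(rbind, manifest)
  wtsv(manifest_df, "MANIFEST.tsv")
  invisible(manifest_df)
}
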