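#' Bayes coding-phase probability profiles
#'
#' For a window of nucleotides and a reference codon usage table, the
#' likelihood of phase k (window offsets 0, 1, 2) is the product of the
#' usage frequencies of the complete codons read in that phase,
#' f_k = prod_i f(codon_i). Bayes' formula with a uniform phase prior gives
#' the posterior p_k = f_k / (f_1 + f_2 + f_3). Sliding the window along a
#' sequence traces p_1, p_2, p_3 profiles whose peaks mark in-phase coding
#' regions. All products are accumulated as log sums and normalized with
#' the log-sum-exp trick, so long windows cannot underflow.
#'
#' @name phase_model
NULL

.FREQ_FLOOR <- 1e-6  # usage frequency assigned to absent codons before log

.phase_log_f <- function(window, log_freq) {
  n <- nchar(window)
  vapply(0:2, function(off) {
    k <- (n - off) %/% 3L
    if (k < 1L) return(NA_real_)
    starts <- seq.int(off + 1L, by = 3L, length.out = k)
    trips <- substring(window, starts, starts + 2L)
    sum(log_freq[trips[!grepl("[^ACGT]", trips)]])
  }, numeric(1))
}

#' Phase probabilities of a single window
#'
#' @param window Nucleotide string, length >= 5 so every phase contains at
#'   least one complete codon; trailing incomplete codons of a phase are
#'   ignored, as are codons containing non-ACGT characters.
#' @param usage A `codon_usage_table`; frequencies of absent codons are
#'   floored at 1e-6 before taking logs.
#' @return Numeric vector `c(p1, p2, p3)` summing to 1; attribute `log_f`
#'   holds the three log-likelihoods.
#' @export
window_phase_probabilities <- function(window, usage) {
  stopifnot(is.character(window), length(window) == 1L,
            inherits(usage, "codon_usage_table"))
  window <- toupper(window)
  if (nchar(window) < 5L)
    stop("window must be at least 5 nt so all three phases have a codon")
  log_freq <- log(pmax(usage$frequencies, .FREQ_FLOOR))
  lf <- .phase_log_f(window, log_freq)
  m <- max(lf)
  p <- exp(lf - m)
  p <- p / sum(p)
  names(p) <- c("p1", "p2", "p3")
  attr(p, "log_f") <- lf
  p
}

#' Sliding-window phase-probability profile
#'
#' Windows of 3N + 2 nucleotides (so each phase holds exactly N complete
#' codons) start at offsets 0, step_nt, 2*step_nt, ... up to the last
#' offset at which a full window fits.
#'
#' @param seq Nucleotide string or `coding_sequence` of length >= 3N + 2.
#' @param usage A `codon_usage_table`.
#' @param window_len_codons Window length N in codons (default 40).
#' @param step_nt Step between window starts in nucleotides (default 3).
#' @return Object of class `phase_profile`: data.frame with columns
#'   `window_start` (0-based), `log_f1..3`, `p1..3`; attributes
#'   `window_len_codons`, `step_nt`.
#' @export
phase_profile <- function(seq, usage, window_len_codons = 40, step_nt = 3) {
  if (inherits(seq, "coding_sequence")) seq <- seq$sequence
  stopifnot(is.character(seq), length(seq) == 1L,
            window_len_codons >= 1, step_nt >= 1)
  seq <- toupper(seq)
  win_nt <- 3L * as.integer(window_len_codons) + 2L
  n <- nchar(seq)
  if (n < win_nt)
    stop("sequence too short for profile: need at least ", win_nt, " nt")
  starts0 <- seq.int(0L, n - win_nt, by = as.integer(step_nt))
  rows <- lapply(starts0, function(s0) {
    p <- window_phase_probabilities(substr(seq, s0 + 1L, s0 + win_nt), usage)
    lf <- attr(p, "log_f")
    data.frame(window_start = s0, log_f1 = lf[1], log_f2 = lf[2],
               log_f3 = lf[3], p1 = p[1], p2 = p[2], p3 = p[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window_len_codons") <- as.integer(window_len_codons)
  attr(out, "step_nt") <- as.integer(step_nt)
  class(out) <- c("phase_profile", "data.frame")
  out
}
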