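# Independent oracles and fixture builders used across the suite.

# Brute-force hidden-stop scan: slide a width-3 window over EVERY
# nucleotide offset, keep offsets in the requested residue class mod 3.
brute_force_hsc <- function(sequence, stop_set, offset_mod) {
  n <- nchar(sequence)
  if (n < 3) return(data.frame(start_nt = integer(0), triplet = character(0)))
  starts0 <- 0:(n - 3)
  keep <- starts0 %% 3 == offset_mod
  starts0 <- starts0[keep]
  trips <- substring(sequence, starts0 + 1, starts0 + 3)
  ok <- !grepl("[^ACGT]", trips) & trips %in% stop_set
  data.frame(start_nt = starts0[ok], triplet = trips[ok],
             stringsAsFactors = FALSE)
}

# Direct-summation Pearson r (textbook formula, no library call).
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random nucleotide string; optionally salted with ambiguity characters.
random_seq <- function(len, p_ambig = 0) {
  letters <- c("A", "C", "G", "T")
  s <- sample(letters, len, replace = TRUE)
  if (p_ambig > 0) {
    amb <- stats::runif(len) < p_ambig
    s[amb] <- "N"
  }
  paste(s, collapse = "")
}

# k-mer frequency table of a nucleotide string (overlapping windows).
kmer_freqs <- function(sequence, k) {
  n <- nchar(sequence)
  starts <- 1:(n - k + 1)
  km <- substring(sequence, starts, starts + k - 1)
  tab <- table(km)
  as.numeric(tab[match(all_kmers(k), names(tab))]) -> v
  v[is.na(v)] <- 0
  stats::setNames(v / sum(v), all_kmers(k))
}

all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- b
  if (k > 1) for (i in 2:k) out <- as.vector(outer(out, b, paste0))
  sort(out)
}

std_code <- hiddenstops::get_genetic_code(1)
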