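#' Markov-chain nucleotide null models
#'
#' Order-k (k in 0..2) visible-state Markov chains over {A,C,G,T}, trained
#' on coding sequences with additive pseudocounts, capture the uni-, bi-
#' and tri-positional composition of the input. Simulating length-matched
#' sequences from a trained chain gives a compositional null against which
#' the observed hidden-stop count is judged (z-score and add-one empirical
#' p-value). The module also provides the synthetic CDS generator used to
#' build test fixtures with prescribed codon proportions.
#'
#' @name markov
NULL

# run expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# nucleotide string -> list of integer vectors (0..3), split at non-ACGT
.clean_segments <- function(s) {
  segs <- strsplit(gsub("[^ACGT]+", " ", s), " ", fixed = TRUE)[[1]]
  segs <- segs[nchar(segs) > 0]
  lapply(segs, function(x)
    as.integer(chartr("ACGT", "0123", strsplit(x, "")[[1]])))
}

.ctx_labels <- function(order) {
  if (order == 0L) return("")
  b <- c("A", "C", "G", "T")
  labs <- b
  for (i in seq_len(order - 1L)) labs <- as.vector(outer(labs, b, paste0))
  labs
}

# context codes of a 0..3 integer vector v: positions 1..(n-order)
.ctx_codes <- function(v, order) {
  n <- length(v)
  if (order == 0L) return(rep(0L, n))
  if (n < order) return(integer(0))
  ctx <- integer(n - order + 1L)
  for (j in seq_len(order))
    ctx <- ctx + v[j:(n - order + j)] * 4L^(order - j)
  ctx
}

#' Train an order-k Markov chain on coding sequences
#'
#' Maximum-likelihood transition estimates with an additive pseudocount on
#' every (context, base) cell; a context never observed (and pseudocount 0)
#' receives the uniform vector. Transitions never span sequence boundaries,
#' and windows touching non-ACGT characters are skipped.
#'
#' @param seqs List of `coding_sequence` objects or character vector.
#' @param order Chain order, 0, 1 or 2.
#' @param pseudocount Additive pseudocount (default 1).
#' @return Object of class `markov_model`: list with `order`,
#'   `context_probs` (4^order x 4 row-stochastic matrix, rows labelled by
#'   context), `start_probs` (empirical distribution of length-`order`
#'   contexts in the training data), `pseudocount`, `trained_on_len`.
#' @export
train_markov <- function(seqs, order, pseudocount = 1) {
  seqs <- as_coding_sequences(seqs)
  stopifnot(order %in% 0:2, pseudocount >= 0)
  order <- as.integer(order)
  ncx <- 4L^order
  trans <- matrix(0, ncx, 4, dimnames = list(.ctx_labels(order),
                                             c("A", "C", "G", "T")))
  start <- numeric(ncx)
  total_len <- 0L
  for (s in seqs) {
    for (v in .clean_segments(s$sequence)) {
      n <- length(v)
      total_len <- total_len + n
      if (n <= order) next
      ctx <- .ctx_codes(v, order)           # length n - order + 1 (order>0)
      if (order == 0L) {
        trans[1, ] <- trans[1, ] + tabulate(v + 1L, 4L)
        start[1] <- start[1] + n
      } else {
        emit_ctx <- ctx[seq_len(n - order)]  # context preceding each emission
        nxt <- v[(order + 1L):n]
        cell <- emit_ctx * 4L + nxt          # flat (context, base) index
        trans <- trans + matrix(tabulate(cell + 1L, ncx * 4L),
                                ncx, 4, byrow = TRUE)
        start <- start + tabulate(ctx + 1L, ncx)
      }
    }
  }
  if (total_len == 0L) stop("no training data (no clean nucleotides)")
  if (total_len <= order) stop("training data shorter than the chain order")
  trans <- trans + pseudocount
  rs <- rowSums(trans)
  probs <- trans
  probs[rs > 0, ] <- trans[rs > 0, ] / rs[rs > 0]
  probs[rs == 0, ] <- 0.25                   # unseen context, no pseudocount
  if (sum(start) == 0) start <- rep(1 / ncx, ncx) else start <- start / sum(start)
  structure(list(order = order, context_probs = probs,
                 start_probs = stats::setNames(start, .ctx_labels(order)),
                 pseudocount = pseudocount, trained_on_len = total_len),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("MarkovModel order", x$order, "- trained on", x$trained_on_len,
      "nt (pseudocount", x$pseudocount, ")\n")
  invisible(x)
}

#' Save / load a Markov model as plain TSV
#'
#' Columns: context, A, C, G, T transition probabilities; start
#' probabilities in a parallel block prefixed `start:`.
#'
#' @param model A `markov_model`.
#' @param path TSV path.
#' @export
write_markov <- function(model, path) {
  df <- data.frame(context = rownames(model$context_probs),
                   model$context_probs, check.names = FALSE)
  df2 <- data.frame(context = paste0("start:", names(model$start_probs)),
                    A = model$start_probs, C = NA, G = NA, T = NA,
                    check.names = FALSE)
  utils::write.table(rbind(df, df2), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_markov
#' @param order Chain order of the stored model.
#' @export
read_markov <- function(path, order) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  df$context[is.na(df$context)] <- ""       # order-0 empty context
  is_start <- grepl("^start:", df$context)
  tp <- df[!is_start, , drop = FALSE]
  probs <- as.matrix(tp[, c("A", "C", "G", "T")])
  rownames(probs) <- tp$context
  labs <- .ctx_labels(as.integer(order))
  probs <- probs[match(labs, rownames(probs)), , drop = FALSE]
  rownames(probs) <- labs
  sp <- df[is_start, , drop = FALSE]
  start <- stats::setNames(sp$A, sub("^start:", "", sp$context))
  start <- start[match(labs, names(start))]
  names(start) <- labs
  structure(list(order = as.integer(order), context_probs = probs,
                 start_probs = start, pseudocount = NA_real_,
                 trained_on_len = NA_integer_),
            class = "markov_model")
}

#' Simulate nucleotide sequences from a Markov chain
#'
#' The initial context is drawn from the empirical context distribution of
#' the training data; subsequent bases follow the transition matrix.
#' Identical (model, length, n_seqs, seed) give identical output; the
#' caller's RNG state is left untouched.
#'
#' @param model A `markov_model`.
#' @param length Sequence length in nucleotides (>= 1).
#' @param n_seqs Number of sequences (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `n_seqs` strings of exactly `length` nt.
#' @export
simulate_markov <- function(model, length, n_seqs, seed) {
  stopifnot(inherits(model, "markov_model"), length >= 1, n_seqs >= 1)
  length <- as.integer(length); n_seqs <- as.integer(n_seqs)
  k <- model$order
  .with_seed(seed, {
    out <- matrix(0L, n_seqs, length)
    if (k == 0L) {
      out[] <- sample.int(4L, n_seqs * length, replace = TRUE,
                          prob = model$context_probs[1, ]) - 1L
    } else {
      ctx0 <- sample.int(4L^k, n_seqs, replace = TRUE,
                         prob = model$start_probs) - 1L
      # emit the initial context's bases (most significant digit first)
      for (j in seq_len(min(k, length)))
        out[, j] <- (ctx0 %/% 4L^(k - j)) %% 4L
      if (length > k) {
        cum <- t(apply(model$context_probs, 1, cumsum))
        ctx <- ctx0
        for (t in (k + 1L):length) {
          u <- stats::runif(n_seqs)
          rows <- cum[ctx + 1L, , drop = FALSE]
          nxt <- (u > rows[, 1]) + (u > rows[, 2]) + (u > rows[, 3])
          out[, t] <- nxt
          ctx <- (ctx %% 4L^(k - 1L)) * 4L + nxt
        }
      }
    }
    apply(out, 1, function(r) chartr("0123", "ACGT", paste(r, collapse = "")))
  })
}

#' Observed vs simulated hidden-stop counts under a Markov null
#'
#' Trains an order-k chain on the sequence itself, simulates `n_sim`
#' length-matched sequences, counts total hidden stops (both frames) in
#' each, and compares. The empirical p-value is two-sided with the add-one
#' correction (doubled smaller tail, capped at 1), so it is never 0.
#'
#' @param seq A `coding_sequence` (or string).
#' @param code A `genetic_code`.
#' @param order Chain order, 0-2.
#' @param n_sim Number of simulations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param pseudocount Training pseudocount (default 1).
#' @return Object of class `hsc_null_comparison`: list with `observed_hsc`,
#'   `n_sim`, `sim_mean`, `sim_sd`, `z_score` (NA with `degenerate = TRUE`
#'   if the simulations have zero spread), `empirical_p`, `order`, `seed`.
#' @export
hsc_null_comparison <- function(seq, code, order, n_sim = 1000, seed,
                                pseudocount = 1) {
  seq <- as_coding_sequences(seq)[[1]]
  stopifnot(n_sim >= 100)
  model <- train_markov(list(seq), order, pseudocount = pseudocount)
  observed <- hidden_stop_report(seq, code)$total
  sims <- simulate_markov(model, nchar(seq$sequence), n_sim, seed)
  sim_counts <- vapply(sims, function(s)
    hidden_stop_report(coding_sequence(s, "sim"), code)$total, numeric(1),
    USE.NAMES = FALSE)
  mu <- mean(sim_counts); sdev <- stats::sd(sim_counts)
  degenerate <- sdev == 0
  z <- if (degenerate) NA_real_ else (observed - mu) / sdev
  p_hi <- (1 + sum(sim_counts >= observed)) / (n_sim + 1)
  p_lo <- (1 + sum(sim_counts <= observed)) / (n_sim + 1)
  structure(list(observed_hsc = observed, n_sim = as.integer(n_sim),
                 sim_mean = mu, sim_sd = sdev, z_score = z,
                 degenerate = degenerate,
                 empirical_p = min(1, 2 * min(p_hi, p_lo)),
                 order = as.integer(order), seed = seed),
            class = "hsc_null_comparison")
}

#' @export
print.hsc_null_comparison <- function(x, ...) {
  cat("HSC null comparison (order", x$order, "chain,", x$n_sim, "sims)\n")
  cat(sprintf("  observed %d vs simulated %.2f +/- %.2f (z = %s, p = %.4g)\n",
              x$observed_hsc, x$sim_mean, x$sim_sd,
              if (x$degenerate) "NA" else sprintf("%.2f", x$z_score),
              x$empirical_p))
  invisible(x)
}

#' Generate a synthetic coding sequence with prescribed codon weights
#'
#' Codons are drawn i.i.d. from the normalized weights; when
#' `forbid_internal_stops` is set, stop codons are excluded from the draw
#' (equivalent to redrawing every stop), so `validate_cds` reports zero
#' internal stops by construction.
#'
#' @param n_codons Number of codons to draw.
#' @param codon_weights Named non-negative weights over codons; unnamed
#'   codons get weight 0.
#' @param code A `genetic_code`.
#' @param forbid_internal_stops Exclude stop codons from the draw
#'   (default TRUE).
#' @param seed Integer seed.
#' @param seq_id Identifier for the generated sequence.
#' @return A `coding_sequence`.
#' @export
generate_synthetic_cds <- function(n_codons, codon_weights, code,
                                   forbid_internal_stops = TRUE, seed,
                                   seq_id = "synthetic") {
  stopifnot(n_codons >= 1, !is.null(names(codon_weights)),
            all(codon_weights >= 0))
  w <- stats::setNames(numeric(64), all_codons())
  nm <- chartr("U", "T", toupper(names(codon_weights)))
  if (any(!nm %in% all_codons()))
    stop("unknown codon(s) in weights: ",
         paste(setdiff(nm, all_codons()), collapse = ", "))
  w[nm] <- codon_weights
  if (forbid_internal_stops) w[code$stop_set] <- 0
  if (sum(w) <= 0) stop("all usable codon weights are zero")
  codons <- .with_seed(seed,
    sample(all_codons(), n_codons, replace = TRUE, prob = w / sum(w)))
  coding_sequence(paste(codons, collapse = ""), seq_id = seq_id)
}
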