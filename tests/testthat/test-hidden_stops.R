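test_that("hidden stops are found at the hand-enumerated offsets", {
  s <- coding_sequence("ATGTTAAAATGA", "x")
  plus <- find_hidden_stops(s, std_code, 1)
  expect_identical(plus$start_nt, 4L)           # offset-1 triplets TGT TAA AAT
  expect_identical(plus$triplet, "TAA")
  expect_identical(attr(plus, "n_offframe_positions"), 3L)

  minus <- find_hidden_stops(s, std_code, -1)   # offset-2 triplets GTT AAA ATG
  expect_identical(nrow(minus), 0L)

  polyA <- coding_sequence(strrep("A", 9))
  expect_identical(nrow(find_hidden_stops(polyA, std_code, 1)), 0L)
  expect_identical(nrow(find_hidden_stops(polyA, std_code, -1)), 0L)
})

test_that("short sequences give empty scans, not errors", {
  r <- find_hidden_stops(coding_sequence("ATG"), std_code, 1)
  expect_identical(nrow(r), 0L)
  expect_identical(attr(r, "n_offframe_positions"), 0L)
})

test_that("scanner matches the brute-force all-offsets oracle", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_seq(sample(4:600, 1), p_ambig = ifelse(i %% 3 == 0, 0.05, 0))
    cs <- coding_sequence(s)
    for (tid in c(1, 2, 11)) {
      code <- get_genetic_code(tid)
      got_p <- find_hidden_stops(cs, code, 1)
      got_m <- find_hidden_stops(cs, code, -1)
      exp_p <- brute_force_hsc(s, code$stop_set, 1)
      exp_m <- brute_force_hsc(s, code$stop_set, 2)
      expect_identical(got_p$start_nt, as.integer(exp_p$start_nt))
      expect_identical(got_p$triplet, exp_p$triplet)
      expect_identical(got_m$start_nt, as.integer(exp_m$start_nt))
      expect_identical(got_m$triplet, exp_m$triplet)
      # scanned offsets are exactly the {1,2} mod 3 classes, never 0
      expect_true(all(got_p$start_nt %% 3 == 1))
      expect_true(all(got_m$start_nt %% 3 == 2))
    }
  }
})

test_that("stop-set differences between tables drive the counts", {
  # table 2 gains AGA/AGG relative to table 1 but loses TGA (-> Trp), so
  # its count dominates the table-1 count restricted to the shared stops
  set.seed(7)
  t2 <- get_genetic_code(2)
  shared <- intersect(std_code$stop_set, t2$stop_set)  # TAA, TAG
  for (i in 1:20) {
    s <- coding_sequence(random_seq(300))
    hits1 <- rbind(find_hidden_stops(s, std_code, 1),
                   find_hidden_stops(s, std_code, -1))
    n1_shared <- sum(hits1$triplet %in% shared)
    n2 <- nrow(find_hidden_stops(s, t2, 1)) +
          nrow(find_hidden_stops(s, t2, -1))
    expect_gte(n2, n1_shared)
  }
  # direct: off-frame AGA visible only under table 2
  s <- coding_sequence("AAGAAA")   # +1 triplet AGA
  expect_identical(nrow(find_hidden_stops(s, std_code, 1)), 0L)
  expect_identical(find_hidden_stops(s, t2, 1)$triplet, "AGA")
  # and off-frame TGA only under table 1
  s2 <- coding_sequence("ATGAAA")  # +1 triplet TGA
  expect_identical(find_hidden_stops(s2, std_code, 1)$triplet, "TGA")
  expect_identical(nrow(find_hidden_stops(s2, t2, 1)), 0L)
})

test_that("half-gene split assigns stops by starting nucleotide", {
  m <- half_gene_analysis(coding_sequence("ATGTTAAAATGA"), std_code)
  expect_identical(m["plus1", "first_half"], 1L)
  expect_identical(sum(m), 1L)

  expect_error(half_gene_analysis(coding_sequence("ATGA"), std_code),
               "too short")

  # halves always partition the full-frame counts
  set.seed(11)
  for (i in 1:20) {
    s <- coding_sequence(random_seq(sample(6:900, 1)))
    m <- half_gene_analysis(s, std_code)
    expect_identical(sum(m["plus1", ]),
                     nrow(find_hidden_stops(s, std_code, 1)))
    expect_identical(sum(m["minus1", ]),
                     nrow(find_hidden_stops(s, std_code, -1)))
  }
})

test_that("contribution scores match role-enumeration examples", {
  sc <- codon_contribution_scores(std_code)
  expect_identical(unname(sc["TTA"]), 2L)  # suffix TA begins TAA/TAG
  expect_identical(unname(sc["ATA"]), 4L)  # + prefix A ends TAA/TGA
  expect_identical(unname(sc["CCC"]), 0L)  # C absent from standard stops
})

test_that("contribution scores depend only on the stop set", {
  # tables 1 and 11 share {TAA,TAG,TGA} but differ in amino-acid labels
  expect_identical(codon_contribution_scores(std_code),
                   codon_contribution_scores(get_genetic_code(11)))
  # enumeration oracle: count (stop, role) pairs directly
  for (tid in c(1, 2)) {
    code <- get_genetic_code(tid)
    sc <- codon_contribution_scores(code)
    for (c3 in sample(all_codons(), 12)) {
      n <- 0L
      for (S in code$stop_set) {
        if (substr(c3, 2, 3) == substr(S, 1, 2)) n <- n + 1L
        if (substr(c3, 1, 1) == substr(S, 3, 3)) n <- n + 1L
        if (substr(c3, 3, 3) == substr(S, 1, 1)) n <- n + 1L
        if (substr(c3, 1, 2) == substr(S, 2, 3)) n <- n + 1L
      }
      expect_identical(unname(sc[c3]), n)
    }
  }
})

test_that("batch summary aggregates per-sequence reports deterministically", {
  s <- coding_sequence("ATGTTAAAATGA", "x")
  batch <- hsc_summary(list(s), std_code)
  expect_identical(batch$total, 1L)
  expect_identical(nrow(batch$summary), 1L)
  expect_identical(batch$summary$hsc_plus1, 1L)

  expect_error(hsc_summary(list(), std_code), "no sequences")

  two <- hsc_summary(list(s, s), std_code)
  expect_equal(two$summary[1, -1], two$summary[2, -1], ignore_attr = TRUE)

  # frequencies are normalized per off-frame position and bounded
  set.seed(3)
  seqs <- lapply(1:5, function(i) coding_sequence(random_seq(300), paste0("s", i)))
  sm <- hsc_summary(seqs, std_code)$summary
  expect_true(all(sm$freq_plus1 >= 0 & sm$freq_plus1 <= 1))
  expect_true(all(sm$freq_minus1 >= 0 & sm$freq_minus1 <= 1))
})
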