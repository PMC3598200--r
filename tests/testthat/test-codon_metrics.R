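usage_of <- function(...) suppressWarnings(codon_usage(..., code = std_code))

test_that("codon usage counts in-frame codons and pools sequences", {
  u <- usage_of(c("ATGATGAAA"))
  expect_identical(unname(u$counts[c("ATG", "AAA")]), c(2, 1))
  expect_equal(unname(u$frequencies[c("ATG", "AAA")]), c(2 / 3, 1 / 3))
  expect_equal(sum(u$frequencies), 1)

  # terminal stop excluded by default, counted when the flag is off
  expect_identical(unname(usage_of(c("ATGTGA"))$counts["TGA"]), 0)
  u2 <- suppressWarnings(codon_usage(c("ATGTGA"), std_code,
                                     exclude_terminal_stop = FALSE))
  expect_identical(unname(u2$counts["TGA"]), 1)

  # pooling is additive
  a <- usage_of(c("ATGATG"))$counts
  b <- usage_of(c("AAATTT"))$counts
  ab <- usage_of(c("ATGATG", "AAATTT"))$counts
  expect_identical(ab, a + b)

  # masked codons are excluded from counting
  u3 <- usage_of(c("ATGNNNAAA"))
  expect_identical(sum(u3$counts), 2)

  expect_error(suppressWarnings(codon_usage(c("NNN"), std_code)),
               "no countable codons")
})

test_that("RSCU is count over family mean, with family means of 1", {
  u <- suppressWarnings(usage_table_from_counts(c(AAA = 3, AAG = 1, ATG = 5),
                                                std_code))
  rs <- rscu(u, std_code)
  expect_equal(unname(rs[c("AAA", "AAG")]), c(1.5, 0.5))
  expect_equal(unname(rs["ATG"]), 1)          # single-codon family
  expect_true(all(is.na(rs[c("TTT", "TTC")])))  # uncounted family -> missing

  # mean RSCU over every counted family is exactly 1
  set.seed(21)
  counts <- stats::setNames(sample(0:50, 64, replace = TRUE), all_codons())
  counts[counts == 0] <- 1
  u <- usage_table_from_counts(counts, std_code)
  rs <- rscu(u, std_code)
  for (fam in synonymous_families(std_code))
    expect_equal(mean(rs[fam]), 1)
})

test_that("relative adaptiveness is 1 at the family max and floored at 0", {
  u <- suppressWarnings(usage_table_from_counts(c(AAA = 4, AAG = 2), std_code))
  expect_equal(unname(u$w[c("AAA", "AAG")]), c(1, 0.5))
  # zero-count codon within a counted family gets the floor
  u <- suppressWarnings(usage_table_from_counts(c(TTT = 10), std_code))
  expect_equal(unname(u$w["TTC"]), 0.01)
  expect_true(all(is.na(u$w[std_code$stop_set])))
  # uncounted family warns and gets the floor
  expect_warning(relative_adaptiveness(u, std_code), "zero total count")

  # every family max is exactly 1 for a dense random table
  set.seed(22)
  counts <- stats::setNames(sample(1:100, 64, replace = TRUE), all_codons())
  u <- usage_table_from_counts(counts, std_code)
  for (aa in setdiff(names(synonymous_families(std_code)), "*"))
    expect_equal(max(u$w[synonymous_families(std_code)[[aa]]]), 1)
})

test_that("CAI is the geometric mean of w over eligible codons", {
  ref <- suppressWarnings(
    usage_table_from_counts(c(AAA = 1, AAG = 2, TTT = 3), std_code))
  # w(AAA) = 0.5, w(AAG) = 1
  expect_equal(cai("AAAAAG", ref, std_code), sqrt(0.5))
  expect_equal(cai("AAA", ref, std_code), 0.5)  # n = 1 geometric mean
  # family-maximal codons only -> CAI = 1
  expect_equal(cai("AAGAAGTTT", ref, std_code), 1)
  # Met/Trp single-codon families and stops are excluded
  expect_equal(cai("ATGAAGTGGTGA", ref, std_code), 1)
  expect_error(cai("ATGTGG", ref, std_code), "no eligible codons")
})

test_that("CAI is order-invariant and decreases for worse synonyms", {
  set.seed(23)
  counts <- stats::setNames(sample(1:100, 64, replace = TRUE), all_codons())
  ref <- usage_table_from_counts(counts, std_code)
  for (i in 1:10) {
    g <- generate_synthetic_cds(120, counts, std_code, seed = i)
    perm <- coding_sequence(paste(sample(g$codons), collapse = ""))
    v <- cai(g, ref, std_code)
    expect_gt(v, 0); expect_lte(v, 1)
    expect_equal(cai(perm, ref, std_code), v)
  }
  # replace one family-maximal codon by a lower-w synonym: CAI drops
  fams <- synonymous_families(std_code)
  lys <- fams[["K"]]
  best <- lys[which.max(ref$w[lys])]; worse <- lys[which.min(ref$w[lys])]
  g1 <- strrep(best, 10)
  g2 <- paste0(strrep(best, 9), worse)
  expect_lt(cai(g2, ref, std_code), cai(g1, ref, std_code))
})

test_that("usage of a deterministic codon layout recovers exact proportions", {
  s <- paste(rep(c("AAA", "GGG", "ACG", "AAA"), 25), collapse = "")
  u <- usage_of(s)
  expect_equal(unname(u$frequencies[c("AAA", "GGG", "ACG")]),
               c(0.5, 0.25, 0.25))
})

test_that("codon usage TSVs round-trip, with RNA letters accepted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("codon\tcount", "AAA\t30", "AAG\t10", "UUU\t5"), f)
  u <- suppressWarnings(read_codon_usage(f, std_code))
  expect_identical(unname(u$counts[c("AAA", "AAG", "TTT")]), c(30, 10, 5))
  expect_equal(unname(u$w["AAG"]), 1 / 3)
  # headerless dialect
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAA\t30", "AAG\t10"), f2)
  u2 <- suppressWarnings(read_codon_usage(f2, std_code))
  expect_identical(unname(u2$counts["AAA"]), 30)
})
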