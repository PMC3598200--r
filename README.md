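# hiddenstops

Hidden stop codons — stop triplets that appear in the +1 or −1 shifted
reading frame of a coding sequence — are thought to act as a safety net
against translational frameshifts: a ribosome that slips out of frame soon
meets an off-frame stop and terminates before wasting resources on (and
possibly releasing) an aberrant peptide (the "ambush hypothesis").
`hiddenstops` is an R toolkit for molecular and evolutionary biologists
who want to find, count and statistically evaluate these off-frame stops
in coding DNA under any NCBI genetic code.

## What it computes

For one or more CDSs (FASTA or raw strings) and an NCBI translation table:

* **Hidden-stop scan.** Off-frame stop triplets at nucleotide offsets
  ≡ 1 (mod 3) (+1 frame) and ≡ 2 (mod 3) (−1 frame), with positions,
  per-frame counts and frequencies per off-frame position, and a
  half-gene split (first vs second half of the codon sequence).
* **Contribution scores.** For each codon *c* = n₁n₂n₃, the number of
  (stop *S*, junction role) pairs in which *c* can supply part of an
  off-frame stop across a dicodon junction: n₂n₃ = S₁S₂ or n₁ = S₃
  (+1 frame), n₃ = S₁ or n₁n₂ = S₂S₃ (−1 frame).
* **Codon adaptation metrics.** Codon usage frequencies (CUF), RSCU
  (count over synonymous-family mean), relative adaptiveness
  wᵢ = count / family max (preferred codon = 1), and CAI — the geometric
  mean of wᵢ over a gene's codons, computed in log space.
* **Phase probabilities.** For a sliding window, the likelihood of each
  reading phase fₖ = Π f(codonᵢ) and Bayes posteriors
  pₖ = fₖ / (f₁ + f₂ + f₃); peaks of p₁ mark in-phase coding regions.
* **Markov null models.** Order 0–2 nucleotide chains trained on the
  input, length-matched simulation, and an observed-vs-simulated
  hidden-stop comparison (z-score, add-one empirical p).
* **Correlation tests.** Pearson r with the one-tailed t-test
  t = r·√(n−2)/√(1−r²): CUF vs hidden-stop contribution (one-tailed for
  positive correlation) and GC content vs hidden-stop frequency across
  ≥ 5 genes (one-tailed for negative correlation), at α = 0.05.

## Worked example

```r
library(hiddenstops)
code <- get_genetic_code(1)          # standard code; stops TAA TAG TGA

s <- coding_sequence("ATGTTAAAATGA", "demo")
find_hidden_stops(s, code, +1)
#>   start_nt triplet frame
#> 1        4     TAA    +1
```

The only +1-frame triplets are TGT, TAA, AAT; TAA at nucleotide 4
(0-based) is a hidden stop. It falls in codon 1, i.e. the first half of
this 4-codon gene:

```r
half_gene_analysis(s, code)
#>        first_half second_half
#> plus1           1           0
#> minus1          0           0

hidden_stop_report(s, code)$hsc_frequency
#>     plus1    minus1
#> 0.3333333 0.0000000      # 1 hidden stop per 3 off-frame positions in +1
```

Codon metrics from a reference usage table (counts per codon):

```r
u <- usage_table_from_counts(
  c(AAA = 4, AAG = 2, GAA = 6, GAG = 2, TTA = 1, TTG = 3), code)
rscu(u, code)[c("AAA", "AAG", "GAA", "GAG")]
#>   AAA   AAG   GAA   GAG
#> 1.333 0.667 1.500 0.500
cai("AAAGAAAAGGAG", u, code)
#> [1] 0.6389   # geometric mean of w = (1, 1, 0.5, 0.333)
```

Is an observed hidden-stop count unusual given the sequence's nucleotide
composition? A 60× GATTACA repeat contains no hidden stop at all, far
fewer than order-0 composition-matched simulations predict:

```r
rep7 <- coding_sequence(strrep("GATTACA", 60), "rep7")
hsc_null_comparison(rep7, code, order = 0, n_sim = 1000, seed = 42)
#> HSC null comparison (order 0 chain, 1000 sims)
#>   observed 0 vs simulated 24.31 +/- 4.20 (z = -5.79, p = 0.001998)
```

And the headline correlation test — does codon usage favour codons that
contribute to hidden stops?

```r
cuf_contribution_correlation(list(s), code)
#> Pearson r = 0.0959 (n = 61), one-tailed (greater) t = 0.7398, p = 0.2312
```

A command-line front end is installed at `exec/hiddenstops` inside the
installed package (`hiddenstops codes list`, `hiddenstops run --fasta
in.fa --code 1 --out DIR`, `hiddenstops nullcmp ...`); `run` writes the
full TSV report bundle (hidden stops, half-gene, contribution scores,
usage/RSCU/w, CAI, correlations, null comparisons) plus a manifest.

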