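---
title: "Hidden stop codon analysis: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden stop codon analysis: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiddenstops)
```

## The biological question

Translational frameshifts shift the ribosome into the +1 or −1 reading
register. Stop triplets that happen to sit in those shifted registers —
hidden stop codons (HSCs), also called off-frame stop codons — terminate
the frameshifted ribosome early, limiting the metabolic cost and the
cytotoxicity of out-of-frame peptides. If selection exploits this safety
net, codon usage should be biased toward codons whose nucleotides can form
off-frame stops. This package quantifies hidden stops in coding sequences
and provides the statistical machinery to test that hypothesis.

## The scanning model

A CDS is read as in-frame codons from position 0 (0-based, half-open
coordinates everywhere). The +1 frame is scanned as complete triplets
starting at nucleotide offsets 1, 4, 7, ...; the −1 frame as offsets 2, 5,
8, .... For a bare linear CDS with no upstream context, offset +2 is the
standard surrogate for the −1 register: both visit exactly the offsets
≡ 2 (mod 3), and the scanner asserts that the two frames together cover
exactly the nonzero residue classes and never offset 0. Triplets
containing non-ACGT characters are *masked*: excluded from both the hit
list and the denominator. The reported `hsc_frequency` is
count / (number of complete unmasked off-frame triplets), which makes
frequencies comparable across gene lengths; normalizing by raw sequence
length would conflate length remainders with stop density.

Half-gene analysis splits the gene's n codons at floor(n/2): codons
[0, floor(n/2)) form the first half. A hidden stop is assigned to the half
containing its *starting* nucleotide — the unambiguous rule for triplets
that span the split.

### Contribution scores

Each codon's capacity to create hidden stops is scored across a dicodon
junction: codon c = n₁n₂n₃ scores one point for every (stop S, role) pair
among (a) left partner in +1: n₂n₃ = S₁S₂; (b) right partner in +1:
n₁ = S₃; (c) left partner in −1: n₃ = S₁; (d) right partner in −1:
n₁n₂ = S₂S₃. Counting (stop, role) *pairs* rather than distinct stops is a
deliberate operationalization — the score is a capacity, so TTA under the
standard code scores 2 (its TA suffix can begin both TAA and TAG). The
score depends only on the code's stop set, so codes sharing a stop set
(tables 1 and 11) share scores. The literature contains more than one
formalization of codon-level "contribution"; this one is stated precisely
so results can be compared across definitions.

Genetic code tables are the NCBI translation tables (ids 1–6, 9–16,
21–25) as shipped by Biostrings; stop sets differ between tables and the
differences are consequential. Notably, table 2 (vertebrate mitochondrial)
adds AGA/AGG as stops but *reassigns TGA to tryptophan*, so table-2
hidden-stop counts do not dominate table-1 counts in general — only the
counts restricted to the shared stops {TAA, TAG} are ordered.

## Codon adaptation metrics

Usage counts pool all in-frame, unmasked codons across the input; the
terminal codon of each sequence is dropped when it is a stop (default), so
a complete CDS contributes pure sense-codon usage. RSCU is
count / family mean; relative adaptiveness is w = count / family max, so
the preferred codon of each family scores exactly 1. Zero-count codons
receive a floor of w = 0.01 (configurable): a literal 0 would annihilate
any geometric mean containing that codon, while 0.01 preserves "strongly
avoided" semantics. CAI is the geometric mean of w over a gene's codons,
computed as exp(mean(log w)) — the direct product underflows for genes
beyond a few hundred codons. Stop codons and single-codon families (Met,
Trp under the standard code) are excluded from CAI, the convention of
Sharp and Li: codons with no synonym carry no information about
preference. A reference usage table may come from a codon/count TSV
(`read_codon_usage`) or from a reference sequence set (`codon_usage`).

## Phase probabilities

For a window and a usage table, the likelihood that reading phase k
(window offsets 0, 1, 2) is the coding phase is fₖ = Π f(codonᵢ) over the
complete codons of that phase, and the Bayes posterior with a uniform
prior is pₖ = fₖ/(f₁+f₂+f₃). All products are log-sums normalized with
log-sum-exp, and the log-space path is tested against a direct-product
oracle on short windows. Codons absent from the usage table are floored
at frequency 1e-6 before the log — one unobserved codon should penalize,
not annihilate, a phase. Profile windows hold N codons per phase (3N+2
nucleotides); the defaults N = 40 codons and step 3 nt are chosen so a
window spans a biologically meaningful ~120 nt and the step preserves
frame alignment between successive windows (a step that is not a multiple
of 3 rotates which phase is in-frame, which is valid but harder to read).

## Markov null models

Order-k chains (k = 0, 1, 2) capture the uni-, bi- and tri-positional
composition of a sequence with visible states — no hidden states are
needed to model k-mer composition, and the estimation is exact:
transition probabilities are additive-pseudocount MLEs (default
pseudocount 1; contexts never observed fall back to uniform), transitions
never span sequence boundaries, and windows touching ambiguity characters
are skipped. Simulation draws the initial context from the empirical
context distribution of the training data — any fixed start would bias
short-sequence statistics — and is vectorized across sequences, so a
thousand 3-kb simulations take seconds. Reproducibility is bit-for-bit
per seed, and the RNG state of the caller is restored.

`hsc_null_comparison` trains on the query itself, simulates n_sim
length-matched sequences (default 1000), and reports the observed total
HSC count against the simulated mean and SD, a z-score (flagged NA when
the simulations are degenerate with zero spread), and a two-sided
empirical p with the add-one correction of Davison and Hinkley — the
doubled smaller tail of (1 + #{sim ≥ obs}) / (n_sim + 1), capped at 1 —
so finite simulation can never report p = 0.

## Correlation tests

Both headline tests use Pearson's r (the underlying hypotheses are
linear; a rank option is available via the building blocks) with the
one-tailed t-test t = r√(n−2)/√(1−r²) on n−2 degrees of freedom:

* **CUF vs contribution** pairs pooled usage frequency with the
  contribution score over the 61 sense codons; codons never observed are
  retained at frequency 0, since dropping them would bias r on short
  genes. One-tailed for *positive* correlation — the adaptive hypothesis
  is that usage favours hidden-stop-prone codons. The direction is
  switchable.
* **GC vs HSC frequency** requires 5 or more sequences (fewer cannot
  support a meaningful correlation and the function refuses). One-tailed
  for *negative* correlation: stop codons are AT-rich, so GC-rich genes
  have less raw material for off-frame stops. Also switchable.

Calibration is part of the test suite: with usage vectors drawn from a
symmetric Dirichlet(1) independently of the contribution vector, the
one-tailed test at α = 0.05 rejects in 0.05 ± 0.013 of 2000 replicates
(three binomial standard errors). The Dirichlet marginals are not normal,
but at n = 61 the t approximation is comfortably accurate.

## The synthetic CDS generator

`generate_synthetic_cds` draws codons i.i.d. from prescribed weights
(optionally excluding stop codons, so generated CDSs are internally
stop-free by construction). It emulates exactly one feature of real
coding sequences — stationary codon composition — and deliberately not
others: no amino-acid sequence constraint, no positional trends along the
gene, no dinucleotide effects beyond those implied by codon choice, no
untranslated context. Tests built on it therefore demonstrate that the
*measurement machinery* is correct under known composition; they do not
certify biological conclusions about real genomes, which also reflect
selection, phylogeny and GC heterogeneity.

## Problem sizes and numerical choices

The shipped tests run the scanner-vs-brute-force sweep on 1000 random
sequences of 4–3000 nt across tables 1, 2 and 11; the calibration
experiment at 2000 replicates; the closed-form order-0 check (an A/T-only
chain gives exactly P(TAA) = 0.125 per off-frame position under the
standard code) at 1000 simulations of 3000 nt; and k-mer recovery on
resimulation at 1e5 nt against a 3e4-nt training sequence with
pseudocount 0 (a pseudocount would bias the comparison; at these lengths
every context is well observed). Tolerances are 4 standard errors for
sampled quantities, 1e-9 for normalization identities and 1e-10 to 1e-12
for dual-route numerical comparisons.

## Limitations

* A bare CDS has no flanking context, so off-frame triplets spanning the
  true gene boundary are invisible; the ±1 frames are surrogates within
  the given sequence.
* The contribution score is one operationalization among several in the
  literature; compare definitions before comparing numbers.
* The Markov null preserves nucleotide statistics only — simulated
  sequences do not encode the original protein, so the null is
  compositional, not functional.
* Selenocysteine/pyrrolysine recoding and start-codon-dependent
  translation semantics are out of scope; the start sets are
  informational.
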