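Package: hiddenstops
Title: Hidden Stop Codon Analysis in Frameshifted Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies hidden stop codons (stop triplets in
    the +1 and -1 shifted reading frames of coding DNA) under any shipped
    NCBI genetic code. Provides per-codon contribution scores to off-frame
    stops, codon usage frequencies, RSCU, relative adaptiveness and the
    codon adaptation index (CAI), Bayes coding-phase probability profiles
    from sliding windows, order 0-2 Markov-chain null models with sequence
    simulation and empirical significance for observed hidden-stop counts,
    half-gene positional analysis, and correlation reports (codon usage vs
    hidden-stop contribution, GC content vs hidden-stop frequency) with
    one-tailed t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
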