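Package: tucdyn
Title: mRNA Turnover Dynamics from Metabolic RNA Labeling and Bisulfite m5C Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mRNA turnover dynamics from 4-thiouridine metabolic
    labeling experiments read out by nucleotide-conversion sequencing
    (TUC-seq/SLAM-seq style T-to-C data). Estimates per-gene new-to-total RNA
    ratios by a two-component binomial mixture with a grid posterior, converts
    them to half-lives and synthesis rates under steady-state one-compartment
    turnover, corrects 4sU dropout, classifies turnover changes between
    conditions with log2 fold-change plus posterior ROPE gating, quantifies
    transcript buffering (synthesis/stability anticorrelation at constant
    abundance) with bootstrap inference, calls 5-methylcytosine sites from RNA
    bisulfite sequencing site tables with FDR-controlled all-replicate
    consensus lists, and clusters half-life time courses. Ships a ground-truth
    synthetic-data generator emulating 3'-end conversion libraries and BS-seq
    site tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
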