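# tucdyn

mRNA turnover dynamics from 4sU metabolic labeling read out by
nucleotide-conversion sequencing (TUC-seq / SLAM-seq style T-to-C data),
plus m⁵C site calling from RNA bisulfite sequencing site tables.

The package is for transcriptomics analysts who have per-gene read-level
conversion histograms (reads indexed by uridine positions *n* and observed
T→C conversions *k*), gene-level count matrices and, optionally, BS-seq
per-cytosine site tables — and who want half-lives, synthesis rates,
turnover-change classes, transcript-buffering statistics and consensus
methylation sites out the other end. A ground-truthed synthetic-data
generator emulating 3′-end conversion libraries makes every stage testable
without any external download.

## The model

A 4sU pulse of *t* hours labels the new-to-total fraction (NTR) of each
transcript pool. Reads follow a two-component binomial mixture,

> L(π) = ∏ reads [ (1 − π) Binom(k; n, p_err) + π Binom(k; n, p_new) ],

with `p_err` estimated from unlabeled controls and `p_new` by EM on pooled
labeled reads. `estimate_ntr()` evaluates L(π) on a grid in log space
(flat prior) and returns the MAP, the posterior, and a moment-matched Beta
summary. Under steady-state one-compartment turnover,

> δ = −ln(1 − π)/t,  HL = ln 2 / δ,  S = δ·E,  E = S·HL/ln 2,

with E the median-of-ratios-normalized abundance. 4sU dropout (loss of
labeled reads, depleting short-lived transcripts) is corrected by fitting
a one-parameter retention model to the labeled/unlabeled count-ratio trend
and inverting it in closed form. Changes between conditions are classified
by |log₂fc| > 1 **and** a posterior ROPE gate |P(Δ > w) − P(Δ < −w)| >
0.45; buffering is the Spearman anticorrelation of ΔHL and ΔS among
steady-state-stable genes, with bootstrap median-difference tests
(percentile CIs, 20 000 iterations) for distribution shifts. m⁵C sites are
called by one-sided Fisher tests against gene-specific conversion
backgrounds with BH correction and all-replicate consensus at FDR < 0.05.

## Worked example

```r
library(tucdyn)
cfg <- sim_config(n_genes = 300, timepoints = c("d0", "d4"),
                  genotypes = c("WT", "KO"), n_replicates = 2,
                  library_size = 3e5, seed = 42)
exp <- simulate_experiment(cfg)

ctrl <- exp$samples[!vapply(exp$samples, `[[`, TRUE, "labeled")]
lab  <- exp$samples[ vapply(exp$samples, `[[`, TRUE, "labeled")]
p_err <- estimate_error_rate(ctrl)
p_new <- as.numeric(estimate_conversion_rate(lab, p_err))
round(c(p_err = p_err, p_new = p_new), 5)
#>   p_err   p_new
#> 0.00100 0.03993
```

The control-derived background and the EM-fitted labeled conversion rate
recover the generator's truth (0.001 and 0.04). Quantify turnover:

```r
rates  <- global_rates(p_err, p_new)
params <- labeling_params(t = cfg$pulse_hours)
labs <- exp$design$sample[exp$design$labeled]
ntr  <- lapply(setNames(nm = labs), function(s)
  estimate_ntr_table(exp$samples[[s]], rates))
turnover <- quantify(ntr, count_matrix(exp), exp$design, params)
head(as.data.frame(turnover)[, c("gene", "condition", "E_norm",
                                 "HL_hours", "S_per_h")], 3)
#>     gene condition   E_norm  HL_hours  S_per_h
#> 1 G00001     KO.d0 104.8622 16.906434 10.00655
#> 2 G00002     KO.d0 142.5905  1.281173 77.36637
#> 3 G00003     KO.d0 260.2139 15.233048 17.18991
```

Per gene and condition: normalized abundance, half-life in hours, and
synthesis rate in normalized units per hour (median across replicates).
Classify knockout-vs-wild-type changes at day 4 and quantify buffering:

```r
conds <- unique(exp$design$condition[exp$design$labeled])
post <- lapply(setNames(nm = conds), function(cn) {
  smp <- exp$design$sample[exp$design$labeled & exp$design$condition == cn]
  estimate_ntr_table(exp$samples[smp], rates)
})
de <- steady_state_de(count_matrix(exp), exp$design, "WT.d4", "KO.d4")
ch <- turnover_changes(turnover, post, de, "WT.d4", "KO.d4", params,
                       n_draws = 2e4, seed = 1)
table(ch$class)
#> HL_and_S  HL_down    HL_up     none   S_down     S_up
#>       30       12       14      225       10        9

buffering_correlation(ch)[c("R", "p", "n")]
#> $R
#> [1] -0.8748659
#> $p
#> [1] 7.855359e-66
#> $n
#> [1] 205
```

Genes pass into a changed class only when both the fold-change and the
ROPE gate agree; among the 205 steady-state-stable genes the half-life and
synthesis changes are strongly anticorrelated — the transcript-buffering
signature the generator built in. A distribution-level comparison of the
same two conditions:

```r
wt <- turnover[turnover$condition == "WT.d4", "HL_hours"]
ko <- turnover[turnover$condition == "KO.d4", "HL_hours"]
bootstrap_median_difference(wt, ko, iterations = 20000, seed = 1)
#> bootstrap median difference: -0.0703 [ns] (95% CI -1.098..1.141, 20000 iterations)
```

Median half-lives do not differ between the genotypes here (the generator
buffers abundance, and per-gene shifts go both ways), so the bootstrap
correctly reports `ns`.

`run_pipeline(cfg, "out/")` chains all of the above — rate estimation,
NTR posteriors, dropout correction, classification for every contrast,
buffering and bootstrap reports, m⁵C consensus/dependent sites, and
half-life clustering — into tab-delimited tables with a run manifest,
byte-identical on rerun with the same seed.

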