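# noncanomiR

Discovery and classification of **noncanonical small-RNA loci** from
depletion-response small-RNA sequencing.

Most microRNAs are made by Microprocessor (Drosha–DGCR8) cleavage of a
Pol II transcript followed by Dicer processing. A minority are not:
mirtrons bypass Microprocessor via splicing; some loci are transcribed by
RNA polymerase III from internal type-II (tRNA-like) promoters; some need
neither Microprocessor nor Dicer; and some "miRNAs" are misannotated
piRNAs (21 nt, 5′ U) or 26G endo-siRNAs (26 nt, 5′ G). `noncanomiR`
integrates the evidence streams that separate these classes:

* **Spike-in normalized differential abundance** across Microprocessor,
  Dicer and Pol III depletion experiments. Size factors are
  `sf_j = spike_j / mean(spike)`; significance comes from a transparent
  NB Wald test (method-of-moments dispersion on the pooled groups, delta-
  method SE, normal p) with Benjamini–Hochberg adjustment.
* **Hairpin structure**: base pairs inside the precursor are counted from
  dot-bracket structures (supplied, or folded by a built-in, oracle-tested
  Nussinov base-pair maximizer); precursors with < 32 internal pairs are
  flagged *short hairpin*, the mirtron-like signature.
* **Pol III type-II promoter architecture**: IUPAC scans for Box A
  (~79–87 nt upstream of the precursor) and Box B (~35–42 nt upstream),
  plus poly-T terminators — a ≥ 4 T run starting within 10 nt of the
  3p-arm 3′ end and a distal 4–5 T run — all in transcript orientation.
* **Untemplated 3′ tailing / isomiR analysis**: reads are anchored to
  arms (fractional weights for identical paralog arms), split at the
  maximal templated prefix against the genome (genome-mimicking additions
  are conservatively called templated), and summarized as per-arm percent
  A/U/C/G tailing, trimming-isoform tables, and a permutation test for
  the 3p-vs-5p tailing asymmetry that marks precursor-modifying enzymes.
* **Rule-based classification** with an auditable rationale per locus,
  plus the Microprocessor cleavage-efficiency score
  `log2(ΣN_P + 0.1) − log2(ΣN_S + 0.1)`.

A fully deterministic **synthetic study generator** (`sim_config()`,
`build_genome_and_loci()`, `simulate_counts()`, `simulate_reads()`) plants
loci of all six classes with known truth — promoter geometry, stem
lengths, fold changes, tail rates — so the whole pipeline is testable
end-to-end with no external data. See the vignette
(`vignettes/noncanonical-smallrna-classification.Rmd`) for the models,
assumptions and limitations.

## Worked example

Generate the default synthetic study (60 loci, six classes, four
conditions × 3 replicates) and run the full pipeline:

```r
library(noncanomiR)
demo <- make_demo(seed = 42, outdir = "demo")
res  <- run_all(demo$run_config)
table(res$labels$label)
#>            canonical         mirtron_like     misannotated_26G
#>                   10                   10                   10
#>   misannotated_piRNA mp_dicer_independent  polIII_noncanonical
#>                   10                   11                    9
```

59 of 60 loci match the planted truth (one Pol III noncanonical locus
with a borderline Dicer adjusted p lands in the neighboring
MP/Dicer-independent class). Every call carries its evidence trail:

```r
res$labels$rationale[res$labels$locus_id == "sim-polIII_noncanonical-01"]
#> single MP dataset available; MP insensitive (lfc: 0.08); Dicer dependent;
#> PolIII dependent; PolIII promoter architecture present; PolIII ChIP
#> overlap; MP-independent, Dicer-dependent, Pol III-dependent
```

The promoter scan recovers the planted geometry exactly — Box A offset
−79 (in the −87…−79 window), Box B −40 (−42…−35), and a strong 5-T
terminator starting 4 nt downstream of the 3p arm:

```r
res$polIII[res$polIII$locus_id == "sim-polIII_noncanonical-01",
           c("boxA_offset", "boxB_offset", "term_proximal_offset",
             "term_proximal_run", "polIII_architecture")]
#>  boxA_offset boxB_offset term_proximal_offset term_proximal_run
#>          -79         -40                    4                 5
#>  polIII_architecture
#>                 TRUE
```

Tailing profiles recover the planted 10% 3p-arm adenylation:

```r
head(subset(res$tail_profile, arm == "3p" & pct_A > 1,
            c(feature_id, mean_rpm, pct_A, pct_untailed)), 3)
#>                     feature_id mean_rpm  pct_A pct_untailed
#>  sim-polIII_noncanonical-01-3p    10000 10.167        89.83
#>  sim-polIII_noncanonical-02-3p    10000  9.683        90.32
#>  sim-polIII_noncanonical-03-3p    10000  9.200        90.80
```

A locus with 10 normalized product reads and none of the uncleaved
substrate scores `cleavage_score(10, 0)$score` = `6.658211`
(= log2(101)); equal product and substrate score 0.

A thin command-line front end wrapping these functions is installed at
`inst/scripts/noncanomir.R` (`demo`, `run-all`, `fold`, `scan`, `diff`
subcommands).

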