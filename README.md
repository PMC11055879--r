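# paralogGI

Genetic-interaction analysis of multiplex CRISPR knockout screens.

Paralogs — duplicated genes with overlapping function — are systematically
missed by single-gene knockout screens: losing one copy is buffered by the
other. Multiplex CRISPR platforms (dual-guide Cas9/Cas12a libraries, and
longer Cas12a guide arrays) knock out two or more genes at once and reveal
these interactions as *synthetic lethality*: a combined knockout far more
deleterious than the sum of its parts. `paralogGI` implements a complete
analysis stack for such screens, for computational biologists working with
construct-level read counts from pooled fitness screens.

## What it computes

**Normalization.** Raw counts receive a pseudocount (default 5 reads), are
depth-scaled to a target of 500 mean reads per construct, converted to
per-replicate log2 fold changes (LFC) against the plasmid/T0 reference,
and mode-centered per construct group (gene_N, N_gene and A_B constructs
independently, or against designated control constructs), with the mode
estimated by Gaussian kernel density.

**Interaction scoring.** For a pair (g1, g2), single mutant fitness (SMF)
is the mean LFC of gene–control constructs. Under the multiplicative null
(additive in log space):

    expected mean = mu1 + mu2
    expected sd   = sqrt(sd1^2 + sd2^2)
    S_pooled      = sqrt(expected_sd^2 + observed_sd^2) / 2
    Cohen's D     = (expected mean - observed mean) / S_pooled
    dLFC          = observed mean - expected mean

A pair is a synthetic-lethal **hit** when dLFC < −1 and Cohen's D > 0.8
(both strict). A `classical` pooled-SD convention
(`sqrt((sd_e^2 + sd_o^2)/2)`, exactly sqrt(2) smaller D) is available via
`gi_thresholds()`.

**Meta-analysis.** Hit calls from many screens form a tri-state
(hit/miss/unassayed) pair × screen matrix. Each study's *platform weight*
is the median Jaccard coefficient of hit sets over its cell-line pairs;
each pair's *paralog score* is the weighted sum of hits minus the weighted
sum of misses. Pairs with score > 0.25 hit in more than one study are
*gold-standard* synthetic-lethal candidates, and screens can be scored by
their recall against such a reference set.

**Guide-array modeling.** For essential/non-essential titration arrays of
7 guides (all 2^7 masks per pool, 3 pools, exact matching over the 281-nt
spacer+DR region), `fit_additive_model()` regresses normalized fold change
on the binary position-encoding matrix (y ~ Aβ); the β estimate each
position's single-knockout phenotype and predict multi-knockout fitness by
summation. `position_effects()` and `forward_vs_reverse()` quantify the
position-specific loss of editing at late array positions.

**Library design.** `select_pairs()`/`cluster_families()` choose paralog
pairs and families from sequence-identity and expression tables (the
`prototype` and `inzolia` filter profiles); `build_arrays()` lays out
four-guide arrays (two siblings per target); `assemble_oligo()` emits the
synthesis oligo byte-for-byte (212-nt prototype / 208-nt inzolia
templates, three distinct internal direct repeats).

**Screen QC and family calls.** Gene-level fold-change aggregation,
essential calling at fc < −1, precision-recall against reference
essential/non-essential sets, and family GI classification with
synthetic-lethal / masking / none labels — plus an *untestable* label when
the additive expectation falls beyond the screen's observed dynamic range.

**Synthetic data.** Seeded generators (`simulate_screen()`,
`simulate_multi_study()`, `simulate_sevenmer()`,
`simulate_design_inputs()`) emulate the statistical structure of these
screens with planted ground truth, so the full pipeline is testable
without downloads.

## Worked example

```r
library(paralogGI)

sl  <- data.frame(gene1 = c("G010", "G015"), gene2 = c("G020", "G025"),
                  dlfc = -2)                   # planted interactions
cfg <- screen_sim_config(n_genes = 30, sl_pairs = sl, n_null_pairs = 10,
                        seed = 1)
sim <- simulate_screen(cfg)                    # counts + ground truth
fc  <- normalize_counts(sim$counts)            # pseudocount, depth, LFC,
                                               # mode-centering, averaging
gi  <- score_all_pairs(fc)
head(gi[order(gi$dlfc), ], 4)
```

```
 gene1 gene2  smf1  smf2 observed_lfc expected_lfc  dlfc cohens_d   hit
  G015  G025 -0.09  0.26        -1.94         0.18 -2.11     7.85  TRUE
  G010  G020 -0.14  0.02        -1.81        -0.12 -1.69     6.46  TRUE
  G011  G014 -0.02  0.24        -0.05         0.21 -0.27     0.87 FALSE
  G014  G023  0.24 -0.07         0.01         0.17 -0.16     0.57 FALSE
```

The two planted pairs are the only hits: their observed fold change
(~−1.9) is far below the additive expectation of two near-neutral SMFs,
giving dLFC ≈ −2 with a large standardized effect size; the null pairs
sit near dLFC 0 and are correctly rejected by the joint dLFC / Cohen's D
rule.

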