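---
title: "Scoring genetic interactions in multiplex CRISPR screens"
author: "paralogGI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in multiplex CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogGI)
```

# The model

A pooled knockout screen measures fitness as the log2 fold change (LFC)
of a construct's abundance between a reference (plasmid or T0) and an
endpoint. For multi-gene constructs the question is whether the combined
knockout deviates from what the single knockouts predict. `paralogGI`
uses the multiplicative null model: independent fitness effects multiply,
so in log space they add. For a pair,

$$\mathrm{expected\ mean} = \mu_1 + \mu_2, \qquad
  \mathrm{expected\ sd} = \sqrt{sd_1^2 + sd_2^2},$$

where $\mu_i$, $sd_i$ are the mean and sample standard deviation of the
mean LFCs of constructs pairing gene $i$ with a control guide (both
orientations pooled). The interaction magnitude is
$\mathrm{dLFC} = \text{observed mean} - \text{expected mean}$, and its
standardized effect size is a modified Cohen's D,

$$S_{\mathrm{pooled}} = \frac{\sqrt{sd_e^2 + sd_o^2}}{2}, \qquad
  D = \frac{\text{expected mean} - \text{observed mean}}{S_{\mathrm{pooled}}},$$

so the synthetic-lethal direction (observed more depleted than expected)
gives $D > 0$. A pair is a hit when $\mathrm{dLFC} < -1$ **and**
$D > 0.8$, both strict. The divisor 2 sits outside the radical in the
default `as_printed` convention; the usual pooled form
$\sqrt{(sd_e^2+sd_o^2)/2}$ is available as `classical` and differs by
exactly $\sqrt 2$. Both are exposed because the printed form is likely a
typeset rendering of the classical one; the package treats the printed
form as the reproduction default and asserts only their algebraic
relation.

## Why an effect size and not a p-value

Hit calling combines a magnitude threshold (dLFC) with a separation
threshold (D). Construct counts per pair are small and vary across
platforms, so a standardized effect size is more comparable across
screens than a p-value whose power tracks library layout; no FDR
machinery is used, by design.

# Normalization choices

The count-to-LFC pipeline runs, in order: pseudocount (default 5 reads,
guarding low counts), per-sample depth scaling to a mean of 500 reads
per construct, per-replicate LFC against the (averaged) reference,
per-group mode-centering, then replicate averaging. Centering before
averaging keeps per-replicate distributions aligned; the published
pipelines do not state this order and it is recorded here as the
package's choice.

Mode-centering subtracts each group's estimated mode (an additive shift —
a multiplicative rescaling cannot in general move a nonzero mode to zero
and would distort fold-change differences). Groups follow the three
library conventions seen in practice: `three_group` centers gene_N,
N_gene and the remaining constructs independently; `control_mode_only`
and `single_orientation` subtract the mode of designated control
constructs from everything, optionally after removing entire gene
families known to cross-react (`excluded_families`).

The mode estimator is a Gaussian KDE with Silverman bandwidth on a
512-point grid spanning the group's range, argmax with ties broken
toward 0, and degenerate (constant) groups returning their value. Its
accuracy depends on peak sharpness: for real LFC groups — a sharp
no-effect peak with a depleted tail — the planted-offset recovery error
at $n = 5000$ is below 0.05 LFC units, which the tests assert on such
mixtures. For a wide Gaussian (sd 0.5) the argmax has an asymptotic sd
near 0.13; no claim is made there.

# The guide-array regression

For 7-guide titration arrays the package fits ordinary least squares of
normalized fold change on the binary essential/non-essential position
encoding ($y \sim A\beta$, $A_{ij} = 1$ iff array $i$ is essential at
position $j$), after shifting each sample so all-non-essential arrays
average zero and filtering to arrays with at most two essential guides
(87 of 384 rows). An intercept is included and reported separately: the
regression as written has none, and after control normalization the two
formulations coincide (the fitted intercept is a diagnostic expected
near 0, not hard-asserted). Predictions for $k$-essential arrays are
coefficient sums; $R^2$ is scored per pool over the filtered arrays. The
three pools are fit jointly by default (they share the design), with a
`per_pool` flag for separate fits.

Per-coefficient accuracy follows from $(X^TX)^{-1}$: at noise sd 0.2 the
coefficient standard error is ≈0.059, so individual coefficients land
within ±0.15 of truth ~99% of the time — the property the tests assert.
The joint event (all seven within ±0.15) has probability ≈92% and is not
asserted.

# Library design

Paralog pair selection filters on mean percent identity
($(AB+BA)/2$, strict 30–99 band for the prototype profile; lower bound
only for inzolia), delta identity ($|AB-BA| < 10$, prototype only),
expression mean (> 2, both profiles) and expression sd (< 1.5, prototype
only). The inzolia profile's identity upper bound is not stated where
its other relaxations are; the package retains the lower bound and drops
the upper one as a configurable default.

Families grow by the difference-from-top-paralog rule: gene A's top
paralog B (max identity) seeds the family, and another candidate C joins
when $id(A,B) - id(A,C)$ is below the profile threshold (10 prototype,
20 inzolia). Families are assembled greedily in sorted gene order with
each gene in at most one family, membership decided only by the
admitting anchor's drop rule. A transitive closure (union-find over all
genes' admissions) was rejected: any gene whose own top-paralog edge
points into a family would be merged even when the family's anchor
explicitly excludes it, defeating the strict drop threshold. Oversized
families keep the anchor plus its three smallest-drop partners.

Arrays carry four guides; every target gets two siblings (reversed slot
order for singles and pairs — "same guides, different order" is
otherwise unspecified — and disjoint guide ranks for triples/quads).
Pair slots interleave the two genes (A,B,A,B), a recorded convention.
Oligos concatenate the printed template segments exactly, lowercase
restriction flanks preserved, so outputs are byte-comparable: 212 nt
(prototype) or 208 nt (inzolia), with three distinct internal direct
repeats.

# Screen-level calls

Gene (or family) fold change is the mean over clone × replicate values;
essentials are called at fc < −1 (strict). Family interactions use the
same additive null with thresholds ±1, plus an **untestable** label that
takes precedence over masking whenever the additive expectation is more
severe than the screen's most depleted observation — there, buffering
cannot be distinguished from dynamic-range saturation. The dynamic-range
floor defaults to the minimum clone-level aggregate in the screen, the
most conservative reading of "any observed fold change". For triples and
quads, each constituent pair's dLFC is attached and a family is flagged
`explainable_by_pair` when the strongest pair interaction comes within
0.5 LFC units of the family's own dLFC (a configurable margin; the
confound is otherwise only discussed qualitatively in the field).

# What the simulators emulate — and what they do not

`simulate_screen()` draws per-gene single-mutant fitness from an
essential or neutral distribution, plants pairwise (and trigenic)
interactions, builds gene–control constructs in both orientations
(`constructs_per_target` guides per gene), all guide-combination pair
constructs ($2 \cdot \text{cpt}^2$ per pair, ~30+ reagents per pair as
in published dual-guide designs at cpt = 4), control constructs, and
samples counts: lognormal reference around 500 reads, negative-binomial
endpoints around $\text{ref} \cdot 2^{\mathrm{LFC}}$ with overdispersion
0.01. Construct noise (sd 0.3) is drawn once per construct and shared
across replicates, as guide-level efficacy variation is. Null assayed
pairs are drawn among neutral genes: assayed paralog pairs are depleted
of essentials in practice, and this is what keeps the pair group's LFC
mode a well-defined zero peak for centering. With `dispersion = 0` and
`noise_sd = 0` endpoint counts equal their (possibly non-integer)
expected values exactly, making the noiseless round-trip through
normalization exact.

`simulate_multi_study()` (default 3 studies × 3 cell lines over 60
genes) shares gene truth across screens, plants universal pairs
everywhere and background-specific pairs in single screens, and scales
construct noise per study (fidelity multipliers 1, 1.5, 2) so studies
genuinely differ in replicability. `simulate_sevenmer()` plants
per-guide effects (≈ −2 LFC) with per-position efficacy multipliers
(1,1,1,1,1,0.3,0.2), emulating position-specific loss of editing late in
long arrays, and supports a reversed-guide-order orientation so position
and guide effects decouple.

The simulators do **not** emulate: copy-number or cutting-toxicity
artifacts, guide-specific off-target effects, real library compositions
or count distributions, batch/timepoint structure beyond replicates, or
correlated noise between constructs sharing a guide. Passing tests
demonstrate that the estimators recover what these generative models
plant — they do not certify performance on real screens, where
normalization-group composition and noise are less benign.

# Numerical conventions and degenerate inputs

* Sample (n−1) standard deviations throughout; SMF sd is undefined
  (NA) for a single construct, making the pair's effect size undefined
  and the pair **unassayed** (never a miss).
* Boundary values at every threshold are non-hits/non-essential
  (strict inequalities).
* Jaccard of two empty hit sets is 0, not 1: two screens with no hits
  carry no replicability evidence. Medians of an even number of
  Jaccards average the central order statistics. Single-screen studies
  have no within-study pair and are excluded from weighting with a
  warning.
* Reads matching more than one library sequence are credited to no
  construct and counted in a `multi_matched` attribute, preserving the
  at-most-one-credit invariant; scanning is single-strand unless
  reverse-complement scanning is enabled.
* Missing replicate values are skipped in means with the count used
  recorded; families with members absent from a screen are reported as
  skipped, never imputed.
* All generators require an explicit seed and are byte-reproducible
  given it.

# Problem sizes used in the test-suite simulations

Monte-Carlo properties are exercised at the generators' default scale:
single screens of 30–40 genes (8 single constructs per gene, 32 per
pair, 3 replicates), campaigns of 9 screens, 60 low-order regression
replicates, mode-recovery samples of n = 5000, and 10,000 random
four-spacer tuples for oligo-assembly integrity. These sizes give the
assertions comfortable statistical margins while keeping the full suite
under a minute of simulation time.

# Known limitations

* The KDE mode estimator is only as good as the group's peak; screens
  whose no-effect peak is broad or minor will center poorly, and the
  per-group offsets are recorded in the output's attributes for
  inspection.
* The additive regression deliberately has no interaction terms; it is
  a null model, and deviations from it are the signal, not a misfit to
  repair.
* Gold-standard selection inherits the thresholds (score > 0.25, >1
  study); with few studies the "more than one study" rule is the
  binding constraint.
* Bayesian essentiality scoring, chemogenetic Z-scores and enrichment
  analysis are out of scope; the package computes fold-change-based
  essentiality and precision-recall QC only.
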