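---
title: "Methods: methylome and transcriptome comparison of a hybrid trio"
author: "hybridmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome and transcriptome comparison of a hybrid trio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmeth)
```

# The analysis problem

When two related species are crossed, the F1 hybrid carries both parental
chromosome sets, and a long-standing question is whether this "genomic
shock" deregulates transposable elements (TEs) — normally silenced by DNA
methylation — or reshapes gene expression. The desk analysis that answers
it compares three genotypes (an almond-like parent A, a peach-like parent
P, and their hybrid H) on three data layers: whole-genome bisulfite
methylation in the three plant cytosine contexts (CG, CHG, CHH; H = A, C
or T), windowed differential-methylation calling, and RNA-seq expression
of genes and TE families, validated by qPCR. hybridmeth implements that
chain as composable functions over tibbles, plus a synthetic-data
generator with known ground truth so every stage is testable end to end.

Because the hybrid's reads cross-map to either parental genome, the design
quantifies the hybrid *twice* — once on each parental reference — and all
comparisons are made per reference. The simulator mirrors this by emitting
hybrid cytosine reports on both coordinate systems directly, as the 50:50
allelic mixture of the two parental methylation states; bisulfite read
alignment itself is out of scope, and the mixture is exactly the quantity
the aligned hybrid data estimate.

# Methylation quantification

Cytosine context is assigned from the 3-base window starting at each
cytosine on its own strand: `CG` if the next base is G, otherwise `CHG` if
the base after next is G, otherwise `CHH`. Windows truncated by a contig
end fall through the same cascade, so a terminal CG is still CG while an
undecidable window conservatively defaults to CHH (this touches at most
two positions per contig end).

Positions sequenced fewer than three times are discarded
(`filter_positions()`, boundary inclusive). The per-feature, per-context
level is the *weighted* methylation — total methylated calls over total
calls — not the mean of per-position fractions, so a deeply covered
position contributes proportionally more. A feature enters the analysis
when at least 25% of its cytosine positions carry data after filtering.
The published rule is phrased in terms of read coverage of feature
*length*; working from call tables, the closest observable proxy is
coverage of the feature's cytosine positions, and that is what
`coverage_fraction` measures (pooled over contexts, one inclusion decision
per feature). Both strands pool into the feature regardless of feature
orientation: CG and CHG methylation is strand-symmetric and the analysis
does not stratify by strand.

The bisulfite conversion rate is estimated from the chloroplast, which is
biologically unmethylated: every C call there is a conversion failure, so
the rate is the pooled unmethylated fraction. Genotype contrasts per TE
class use an unpaired two-sided Wilcoxon rank-sum test on included
features' levels — unpaired because elements are not strictly paired
across references — with mean differences reported in percentage points.

# DMR calling

The caller follows the fixed-window recipe exactly: adjacent 50-bp tiles
(window = step = 50, partial terminal tiles retained and tested like any
other); per window, counts are pooled over the cytosines of the tested
context that have data in **both** conditions and tested with a two-sided
Fisher's exact test on the 2×2 table (methylated/unmethylated ×
condition). Three filters run before multiple testing: at least 3 context
cytosines, an absolute methylation-proportion difference of at least 0.25,
and an average of at least 8 reads per cytosine (mean of the two
conditions). Benjamini–Hochberg correction is applied per context across
the tested windows; windows with q below the cutoff become candidate bins,
and same-direction bins whose gap is smaller than 300 bp are merged
(`merge_dmr_bins()` is idempotent, and merging never mixes directions or
contexts — merging opposite directions would leave a region's direction
undefined).

Numerical choices: the Fisher p-value is computed by direct hypergeometric
enumeration over the table support, summing probabilities not exceeding
the observed table's probability with the standard `1 + 1e-7` relative
guard against floating-point ties; it matches `stats::fisher.test` to
< 1e-10 over every 2×2 table with margins ≤ 30 (a test asserts this). The
q-value cutoff after BH is not fixed by the published recipe; the package
defaults to 0.05 and exposes it in `dmr_params()`. Where replicate
libraries exist they are pooled per condition before the 2×2 test, which
is what a single Fisher test per window implies.

DMRs are then assigned to every region category they overlap by ≥ 1 bp —
TE classes, genes (ATG to stop, introns included), 1-kb upstream regions —
with deliberate double counting across categories, matching per-row
accounting in direction tables; `family_dmr_summary()` keeps TE families
with at least 5 DMRs (inclusive).

# Expression analysis

The differential engine is intentionally compact and self-contained:
median-of-ratios size factors (geometric-mean reference over features
positive in all samples; total-count fallback otherwise); per-feature
method-of-moments NB dispersions pooled across the two groups, shrunk on
the log scale (weight 0.5) toward a robust `a0 + a1/mu` mean-dispersion
trend and clamped to [1e-8, 5]; a Wald-type statistic on
`log2((mu_b + 0.5) / (mu_a + 0.5))` with the delta-method standard error
`sqrt(sum (mu + alpha mu^2) / (n mu'^2)) / ln 2`. The reference
distribution is t with residual-plus-prior degrees of freedom (prior = 2):
with three replicates a plain normal reference is anticonservative
(empirical type-I ≈ 0.09 at nominal 0.05 in the null simulations the test
suite runs) while the residual-df t overshoots the other way (≈ 0.03);
the moderated df, justified by the information the trend shrinkage
borrows, calibrates to ≈ 0.046. Significance requires both FDR < 0.05 and
|log2FC| ≥ 1 — the fold-change cutoff is part of the significance
definition, not a post-filter. DESeq2, where installed, serves as an
independent cross-check (log2FC correlation > 0.95 on simulated data), and
regularized-log expression is approximated by `log2(normalized + 1)` for
heatmap-style output.

The three pairwise calls per feature (A–P, A–H, P–H) form a triad of
relations in {<, =, >}. Exactly 13 of the 27 triads are induced by a weak
ordering of three genotypes (1 all-tied, 6 one-tie, 6 strict); these map
to canonical pattern strings written as a monotone chain with A's group
first and ties parenthesized in A, H, P order (`A<H<P`, `(A=H)>P`,
`A=H=P`, ...). The coarse class gives transgressive expression precedence:
hybrid-up/down iff H is significantly above/below *both* parents;
otherwise the parental contrast decides peach-up/almond-up; equal means no
contrast separates anything. The 14 order-inconsistent triads (possible
with thresholded tests, e.g. A<P with A=H and P=H) are flagged
`consistent = FALSE` and classed by the A-vs-P contrast — the anchor of
the category system — with the raw relations preserved verbatim in the
fine string so any regrouping remains lossless. The "expressed" universe
that forms the denominator of category percentages is features whose mean
normalized count reaches 5 in at least one genotype (`expressed_features()`,
configurable; the percentage arithmetic itself is reproduced exactly by
`summarize_patterns()` from published category counts in the test suite).

TE-family representatives are the highest-coverage genomic copy of each
family's assembled contig passing a kind-specific length-coverage cutoff —
80% for retrotransposons, 40% for DNA transposons. qPCR is quantified by
2^−ΔΔCt: per-sample ΔCt against the mean of the reference genes, genotype
ΔΔCt against a calibrator genotype, replicate SD propagated as
`2^−(ΔΔCt ± sd)`. The procedure is invariant to a constant plate offset,
and noise-free simulated Ct tables recover fold changes exactly (both are
asserted).

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `divergence` | 0.02 | expected pairwise substitutions/site (20 SNPs/kb) |
| `context_means` | 0.90 / 0.60 / 0.15 | CG / CHG / CHH mean methylation |
| `context_concentration` | 20 / 12 / 30 | beta concentration per context |
| `mean_coverage` | 20 | Poisson reads per cytosine |
| `conversion_rate` | 0.98 | P(unmethylated C reads as T) |
| `spike_delta` | 0.40 | methylation shift of spiked DMRs |
| `nb_dispersion` | 0.05 | NB dispersion of RNA-seq counts |
| `lfc_effect` | 2 | log2 effect size of non-equal patterns |
| `replicates` | 3 | RNA-seq replicates per genotype |
| `pattern_mix` | 78.3/10.7/10.0/0.7/0.3% | coarse-class fractions |

Both parents descend from one ancestral sequence by independent lineage
substitutions; the per-lineage rate p solves `2p − (4/3)p² = divergence`
so the *expected pairwise* difference equals the configured divergence
after double hits. Substitutions only — indels are deliberately off so the
two coordinate systems stay trivially alignable, which is all the
downstream analysis needs. TE copies (four classes, lognormal lengths) and
genes are placed without overlap by stick-breaking the free space; family
sizes follow a truncated-geometric profile; upstream regions are derived
as exactly 1000 bp before each ATG, strand-aware, truncated at contig
edges.

Methylation truth is drawn per block (each TE or gene is a block;
intergenic gaps are blocks) and context from a beta distribution around
the context mean; the parental levels are independent draws, the hybrid is
their midpoint, and the chloroplast is fixed at zero. Observed calls fold
in conversion failure, `E[p_obs] = m + (1 − m)(1 − conversion)`, with
Poisson coverage and binomial methylated counts. Spiked DMRs are placed on
the 50-bp window grid, ≥ 1 kb apart, 300 bp long by default, shifting the
hybrid by ± `spike_delta` in a direction that keeps the level inside
[0, 1] (CG at 0.9 can only spike down at delta 0.4; CHH at 0.15 only up).
Grid alignment makes boundary recovery measurable in whole windows. The
default spike delta is 0.40, the condition under which recovery is
specified.

Counts are NB with genotype means encoding the assigned coarse class at
`lfc_effect`; for parent-up classes the hybrid is intermediate or equal to
either parent with equal probability — the configurations the pattern
taxonomy distinguishes. The recorded truth is derived from the means
actually generated, so a zero effect size collapses every pattern to
"equal". Ct tables follow `Ct = intercept − log2(expression) + noise` with
genotype-constant reference genes.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: read alignment and mapping bias between
diverged genomes, PCR duplicates and coverage overdispersion beyond
Poisson, the bimodal methylation of LINE-like elements (the beta is
unimodal; a concentration < 2 can be set to explore bimodality),
correlated methylation between neighbouring features, indels and
structural variation, and TE transposition itself. Percentages of
covered TEs (Table-1-style outputs) on synthetic data reflect the
simulated coverage model only.

# Problem sizes and determinism

Fixing `seed` fixes every output byte for byte; each stage derives its own
child seed, so stages are independently reproducible. The test suite runs
the whole validation at desk scale: a 150-kb default chromosome (48 TEs,
25 genes), a 1-Mb pair for SNP-density recovery, a 550-kb chromosome
giving > 10,000 CG windows for the null-DMR control (two independent
draws from one generative methylome), a 400-kb chromosome with 20 spiked
DMRs for sensitivity/boundary recovery, and 400-feature count matrices
for pattern recovery. These sizes were chosen so the full suite completes
in about a minute while leaving every estimator comfortably inside its
sampling tolerance; with 48 TEs the mean CG level has a standard error
near 0.9 percentage points, which is the resolution limit of
context-mean recovery at the default scale.

# Known limitations

- The DMR caller tests pooled counts; it has no replicate-aware
  beta-binomial model, no smoothing, and exactly the three published
  filters. Its FDR cutoff default (0.05) is a convention, not a published
  value.
- The DE engine is a compact approximation: moment dispersions with trend
  shrinkage, not maximum likelihood; no outlier refitting; rlog is
  approximated by `log2(normalized + 1)`.
- The 25%-coverage rule is applied at cytosine-position resolution (see
  above); analyses driven from raw alignments could count covered bases
  instead and differ slightly near the boundary.
- Upstream regions may overlap neighbouring features; they are quantified
  as annotated, without masking.
- Pattern classification depends on thresholded significance calls;
  borderline features near |log2FC| = 1 can land in adjacent fine
  patterns, which is why the coarse classes — not the fine strings — are
  the robust unit of reporting.
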