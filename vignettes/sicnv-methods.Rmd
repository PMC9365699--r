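---
title: "Methods: spatially inferred copy number variation with sicnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially inferred copy number variation with sicnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatially barcoded transcriptomics (10x Visium-style arrays) measures pooled
mRNA from ~55 µm capture spots holding roughly 5–10 cells. Because gene
expression scales, on average, with gene dosage, a spot's expression profile
carries a readable imprint of chromosomal gains and losses. `sicnv` turns
spot-level UMI counts into genome-ordered copy-number residual profiles
("siCNVs"), discretizes them into six copy states with a hidden Markov model,
groups spots into clones, and reconstructs clone phylogenies under the
assumption that a copy-number event, once acquired, is never reversed.
Because validation on patient tissue requires controlled-access data, the
package ships a generative tissue simulator whose ground-truth copy numbers
and clone labels exercise every stage end to end.

## The inference model

For spot $i$ and gene $g$ (ordered along the genome within chromosomes):

1. **Filtering.** Genes without a genome position, genes on excluded
   chromosomes (default `chrM`), and genes with mean raw count below
   `gene_mean_cutoff` (default 0.1) are removed. Spots with $\le 500$ total
   UMIs (or fewer than 100 detected genes) fail QC.
2. **Normalization.** Counts are scaled to the median spot total and
   transformed $x = \log_2(1 + \text{count})$.
3. **Reference centring.** The per-gene mean over a *reference set* of spots
   (histologically benign, low inferred burden) is subtracted; values are
   clipped to $\pm 3$.
4. **Smoothing.** Each chromosome is convolved with a pyramidal (triangular)
   moving average over 101 genes; weights rise linearly to the centre and are
   renormalized at chromosome edges so they always sum to 1. Smoothing trades
   single-gene resolution for robustness to the heavy sampling noise of
   ~5–10-cell spots.
5. **Re-centring.** The per-spot median is subtracted (guarding against
   global shifts when a large genome fraction is altered), then the per-gene
   reference mean once more, so reference residuals are exactly zero-mean
   (enforced to $|\mu| < 10^{-8}$).
6. **Denoising (display/burden only by default).** Entries within
   $1.5\,\hat\sigma$ of zero, where $\hat\sigma$ is the pooled standard
   deviation of reference residuals, are set to exactly zero.
7. **HMM.** Per spot (or per clone, averaging member profiles), each
   chromosome's residual sequence is decoded by exact Viterbi over six states
   with Gaussian emissions centred at $\log_2$ of the relative copy levels
   $(0.01, 0.5, 1, 1.5, 2, 3)$ — state 3 is copy-neutral — a shared emission
   SD estimated from the reference residuals, and cross-transition
   probability $10^{-6}$. States map to categories as 1–2 = deletion, 3 =
   neutral, 4–6 = amplification.

All constants are exposed in `inference_config()`. Only the expression
cutoff, the denoise flag and the HMM usage are externally prescribed; the
remaining constants follow the cited inference tool's documented defaults so
that there are no hidden numbers.

**Denoise/HMM order.** Whether decoding should see denoised or raw residuals
is genuinely open; the default decodes raw residuals (denoising discards
sub-threshold evidence that the HMM can still integrate across a run), and
`hmm_on_denoised = TRUE` selects the other order.

## Reference selection and clones

The "pure benign" reference is chosen quantitatively (the original workflow
used visual inspection): benign spots are analysed unsupervised, per-spot
burden is the mean absolute denoised residual, and the selected set is the
largest dendrogram node whose median burden is at most the
`burden_quantile` (default 0.5) quantile of all burdens, requiring at least
10% of the input spots. The *root* node is excluded from candidacy: its
median burden equals the quantile cutoff by construction, so the literal
"largest node" rule would always return the entire input and never exclude
high-burden spots. A corollary is that when every spot carries the same
alteration the selection cannot fail loudly — the alteration simply becomes
the baseline; this is an intrinsic limit of reference-relative inference,
not a detectable error state.

Clones are formed by hierarchical clustering (Ward linkage, Euclidean
distance — a declared default, not a reproduction) of residual rows, cut
either at an explicit list of dendrogram nodes (the hand-curated workflow)
or at a target clone count `k`. Labels `A`, `B`, ... are assigned in
decreasing clone size; clones under 10 spots are masked from display.
Recovery against ground truth uses the adjusted Rand index.

## Clone trees

Each clone's consensus event set $Z$ is built from per-clone HMM region
calls of at least 20 genes, with events unified across clones when their
spans overlap at least 50% reciprocally (arm-level event labels collapse
nearby calls; a numeric rule replaces that judgement). Under no-reversal,
$Z_\text{parent} \subseteq Z_\text{child}$ along every lineage, so the tree
is grown by recursive maximal-shared-subset grouping from an empty-set root;
unobserved ancestors carry the shared intersections. Edges get pixel lengths
$b = 100\log_2(|Z_\text{child}| - |Z_\text{parent}|) + 300$ and observed
clones circles of diameter $d = 10\log_2(s)$ for $s$ spots; both formulas
are taken literally, with no extra figure-layout scaling. A zero-event
difference is an error by design — the additive constant covers "few"
differences, not "none". Edges joining two unobserved ancestors whose
subtree clones are not spatially proximate (minimum inter-clone spot
distance above 4 array pitches by default) are flagged uncertain. A
maximum-parsimony alternative treats genes as multistate characters
(missing calls imputed to diploid state 3): topologies are enumerated
exhaustively up to 8 clones and scored with Fitch small parsimony;
beyond 8, neighbour joining plus NNI hill climbing is used.

## The simulator and what a green test establishes

`simulate_tissue()` is an agent-based model: founder cells placed uniformly
in a rectangular domain move, divide, die, or stay stagnant each step with
fixed probabilities. Offspring inherit the parent genome; with a per-step
mutation probability a division mutates one uniformly chosen contiguous
segment by one copy (clamped to $[0, 6]$). Cells are binned into a square
spot grid (a simplification of the hexagonal Visium lattice), and counts are
drawn multinomially with per-gene intensity proportional to baseline times
relative copy number, at a negative-binomial spot depth (overdispersion is
realistic for UMI data; the depth model is our choice).

Default desk-scale world (chosen once, frozen): 1000×1000 domain, 5
founders, 33 steps, action probabilities (0.05 move, 0.25 divide, 0.05 die,
0.65 stagnate), 600 genes on one artificial chromosome, segment lengths
U(60, 150), spot pitch 12 / diameter 11, mean depth 5,000 UMIs. Seed 1
yields 302 occupied spots at 5.7 cells per spot with 4 mutation events and
3 spot-majority clones.

One deliberate deviation from a scalar mutation probability: under pure
exponential growth, a mutation at population size $n$ founds a clone of
expected final fraction $1/n$, and divisions concentrate at large $n$ — so a
division-uniform mutation rate producing only 3–5 events essentially never
creates clones of visible size. The default therefore confines mutations to
the first 12 steps (probability 0.08 per division, expected ≈ 4 events),
emulating early truncal/branching events; `p_mutation_at_division` accepts a
scalar or per-step vector.

Ground truth follows the rounded-average rule: copy numbers are expressed
relative to diploid (1 = neutral), per-spot and per-clone means over
captured cells are rounded to the nearest integer (ties round half away
from zero — "nearest integer" does not fix the tie rule, so we declare
one), and a gene is deleted below 1, neutral at 1, amplified above 1.
Evaluation computes per-clone category accuracy over the *inferred* clones,
with truth recomputed for those same spot groupings.

What the simulator does **not** emulate: multi-chromosome karyotypes,
stromal/immune admixture, cell-type expression programs, spatial expression
gradients, segment dosage compensation, or SNVs. A green synthetic test
therefore establishes that the pipeline recovers dosage signal and clonal
structure under its own generative assumptions — not that it would do so on
any real tissue.

## Numerical choices and degenerate inputs

* Rounding ties: half away from zero (declared above).
* Smoothing at chromosome edges renormalizes the truncated triangle; a
  single-gene chromosome passes through unchanged.
* Viterbi ties: the first (lowest-index) state wins; with transition
  probability $10^{-6}$ ties are measure-zero in practice.
* `denoise` with a zero reference SD warns and returns the input unchanged.
* An all-identical state matrix yields a star tree with parsimony score 0.
* A population that dies out raises an error naming the extinction step.
* On mutation-free tissue, ≈ 87% (not ≈ 100%) of post-denoise entries are
  exactly zero: a two-sided $1.5\sigma$ band retains the ~13% Gaussian tail
  by construction. The HMM nevertheless decodes > 99.9% of gene-states as
  neutral, which is the operative specificity guarantee.

## Limitations

Expression is a noisy, indirect dosage readout: copy-neutral events are
invisible, focal events below the smoothing scale are attenuated, and
segment boundaries blur by roughly half a window. Spots are cell mixtures,
so small clones may be diluted below detectability, and clone boundaries
inherit spot resolution. The clonal VAF summaries consume externally
produced per-spot allele counts; the ratio convention is ambiguous upstream,
so both alt/(ref+alt) and ref:alt are reported.
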