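---
title: "Methods: mapping human-evolved regulatory elements to target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping human-evolved regulatory elements to target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human accelerated regions (HARs) and human gained/lost enhancers
(HGEs/HLEs) are overwhelmingly noncoding, and a noncoding element's
regulatory target is often not its nearest gene. `evotarget` implements a
chromatin-interaction route to target assignment: each element is placed
in a 10 kb genomic bin, the Hi-C contacts between that anchor bin and
every bin within 1 Mb are tested against a parametric background null,
and significant contacts landing in a gene's promoter (2 kb upstream of
the TSS) nominate that gene as a putative target. Around this core the
package provides the supporting statistics such a study needs: enrichment
of elements in regulatory annotations, cross-species developmental
expression comparisons, and covariate-adjusted gene-set enrichment.

## The Weibull contact null

Contact frequency decays strongly with genomic distance and varies
between chromosomes, so raw contacts are not comparable across bins. The
null model is built from matched random regions: for every element, 40
regions of identical length and GC content (within 5 percentage points)
are drawn from the same chromosome by rejection sampling. The contact
profiles of these control anchors supply background observations for
every (chromosome, distance) cell, and a two-parameter Weibull is fitted
to the strictly positive contacts of each cell by maximum likelihood
(profile likelihood in the shape, closed-form scale). The significance of
an observed contact $x$ is its survival probability
$p = \exp(-(x/\lambda)^\kappa)$ under the matching cell.

Numerical choices:

* **Zeros.** The Weibull support excludes zero, and a zero contact can
  carry no evidence of interaction, so zero contacts receive $p = 1$ and
  never enter the fit. The per-cell zero fraction is recorded in the
  model table.
* **Sparse cells.** Cells with fewer than 30 positive observations are
  pooled with their nearest-distance neighbours on the same chromosome
  (expanding symmetrically) until the minimum is reached, and flagged.
* **Window convention.** Candidates are the 99 bins on each side of the
  anchor — bins strictly within 1 Mb — giving exactly 198 tests for an
  interior anchor. Elements straddling a bin boundary anchor one locus
  per touched bin.
* **Multiple testing.** A single Benjamini–Hochberg pass over the full
  element × candidate family; calls with $q < 0.01$ are significant. The
  inequality is strict, so setting the threshold to 1 does not make the
  boundary $q = 1$ calls significant.

Target assignment has three modes reflecting how the three element
classes are handled: `fetal_full` assigns coding-category elements
(coding exon, UTR, 1 kb promoter, 1 kb downstream flank) directly to
their genes and noncoding elements by interaction; `promoter_split`
splits on 2 kb promoter overlap instead of the coding classification; and
`adult_promoter_only` uses promoter-landing interactions only. Where the
same (element, gene) pair is nominated by both routes the direct evidence
is kept. Elements spanning features of several genes are assigned to all
of them; dropping information seemed strictly worse than a tie-break.
Whether 1 kb-promoter elements should also receive interaction-based
targets is not decidable from first principles; `fetal_full` excludes
them (they are already directly assigned), which maximises consistency
between the two branches.

## Enrichment of elements in annotations

Three routes are implemented, and they are deliberately not collapsed
into one:

1. a binomial (region-based) test where the genome-coverage fraction of
   the annotation is the success probability and the number of
   annotation-overlapping elements is the count — fold enrichment is
   reported as (observed overlap fraction of elements)/(coverage
   fraction), the element-count convention;
2. Fisher's exact test of elements against conserved regions (maximal
   runs of conservation score strictly above 0.40, strictly longer than
   20 bp), which controls for the fact that conserved elements
   preferentially sit in functional territory — the odds ratio reported
   is the sample OR $AD/BC$ with a Woolf CI, Haldane-corrected and
   flagged when a cell is zero, and the exact p is two-sided;
3. an empirical permutation distribution from sets of regions matched to
   the elements in length and mean conservation score (tolerance 0.05),
   with empirical $p = (1 + \#\{OR_{null} \ge OR_{obs}\})/(n + 1)$.

Conservation-matched sets are placed genome-wide. The proposal
distribution mixes uniform placement with placement anchored on scored
runs of the track; without the second component, high-score sources are
essentially unmatchable when scored territory covers a few percent of
the genome. The matching criterion itself is unchanged — only the
proposal is improved — and draws that still fail within the round budget
fall back to the nearest-score candidate with a warning and a flag.

## Cross-species developmental statistics

Per-gene expression is standardized across developmental stages (row
Z-scores), and the human minus macaque Z difference is taken at
event-score-matched stages (0.46↔0.48, 0.54↔0.51, 0.76↔0.77 on the
shared developmental event scale). A positive Δ means the gene is
relatively more stage-enriched in human. The gene-set test is a
two-sample t-test of the pooled set Δ values against the pooled
non-set values: the two-sample form was chosen over a one-sample test
against zero because the comparison of interest is against other genes
measured on the same atlas pair, which cancels any atlas-wide offset.
Breakpoint differences (human − rhesus, negative = earlier in human) and
log2(dN/dS) contrasts are compared between gene sets by two-sided
Wilcoxon rank-sum tests; module membership by Fisher-equivalent 2×2
tests BH-corrected across modules.

Gene-set enrichment with a coding-length covariate fits
`target ~ in_set + log(cds_length + 1)` by binomial GLM; the covariate is
log-transformed for stability since coding lengths span orders of
magnitude. Without the covariate the estimator reduces exactly to the
sample odds ratio. Complete separation is detected and flagged rather
than silently reported or penalized, to keep the estimator a plain
regression. The background gene list is always an explicit argument,
never inferred, because the appropriate background changes per analysis
(all protein-coding genes for exome-derived disease sets, the assayed
genes for module and cross-species sets). Multiple-testing correction
over the element-class × gene-set grid uses BH in one family; the method
is recorded in the output attributes.

## The synthetic-data generator

All inputs are generated with the statistical structure the methods
assume, with planted truths recorded alongside:

* **Genome and elements.** Chromosome sequence with a sinusoidal GC
  landscape (base 0.41, amplitude 0.10, period 2 Mb) so GC matching is
  non-trivial; conservation islands covering ~5% of the genome with
  scores 0.6–0.95 plus low-score decoys; annotation peaks; elements with
  log-normal lengths (median 250 bp, minimum 16 bp) placed so the
  element-vs-conserved-background annotation odds ratio equals a
  configured target (default 3), given the measured background overlap
  rate.
* **Contacts.** Background contacts at bin distance $d$ are Weibull
  draws with scale $\propto d^{-1}$ and shape 4 (CV ≈ 0.28, a tightly
  dispersed map); a distance-increasing fraction of entries (5–25%) is
  zeroed for sparsity. 100 planted element→promoter loops multiply the
  Weibull scale — hence the mean — by 3 and are never zeroed. The
  default suite is therefore well-specified for the caller's parametric
  family by design, separating correctness from robustness; a
  misspecified (log-normal) background can be emulated by feeding custom
  contact tables to the caller.
* **Expression.** Smooth logistic-ramp trajectories with amplitude
  bounded away from zero (|amplitude| in 1–4, transition width 0.12–0.3
  on the (0,1) event scale, stage noise SD 0.2): dynamic genes whose
  stage Z-scores reflect developmental signal rather than noise. The
  macaque latent clock is warped onto the human event scale through the
  matched stage pairs, since event scores are by definition the
  cross-species alignment; matched stages then differ only by noise and
  planted shifts. The planted Δ-Z set (500 of 4125 orthologs, shift
  0.128) is calibrated by a short fixed-point iteration so the shift is
  exact in Z units after re-standardization. Breakpoint (−0.05 on 200
  genes vs 3000), marker (5× in one of six clusters), dN/dS (median 0.2
  vs 0.5) and gene-set (OR 3 with a log-normal coding-length covariate;
  one module at OR 7 among 99 neutral) plantings are direct draws from
  the corresponding models.

What the generator does **not** emulate: sequencing noise, Hi-C
artifacts (fragment effects, balancing bias, translocations),
copy-number structure, batch effects in expression, or realistic
gene/repeat architecture. Passing tests therefore demonstrate that the
implementation recovers truth when the modelling assumptions hold, not
that the assumptions hold for any particular real dataset.

## Problem sizes and determinism

The default simulated study is 2 chromosomes × 20 Mb at 10 kb bins with
1000 elements, 40 matched controls each (~7.9M background observations
across 198 distance cells per chromosome), 100 planted loops, and the
expression scales above; the demonstration pipeline in the test-suite
runs a reduced version (2 × 4 Mb, ~100 elements, 60 permutation sets) and
`run_all()` defaults to 1000 conservation-matched permutation sets —
full 10,000-set permutation runs are supported but not part of the
default demonstration. Every generator and sampler is a pure function of
(config, seed): per-element rejection-sampling streams are derived from
the element's own coordinates, so adding or reordering elements does not
perturb other elements' draws, and reruns with an unchanged config are
cache hits with byte-identical outputs.

## Known limitations

* The Weibull family is an assumption; on real maps the per-cell fit
  should be inspected (`glance()` on the null reports pooling and zero
  fractions) and the calibration property re-checked.
* Cross-chromosomal contacts are out of scope; the caller is strictly
  cis within ±1 Mb.
* One representative TSS per gene (the 5'-most); alternative promoters
  are not modelled.
* The permutation null treats the annotation as fixed and the element
  positions as exchangeable with matched regions; annotations that were
  themselves defined on the elements would violate this.
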