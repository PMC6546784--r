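# evotarget

Assigning human-evolved regulatory elements to their putative target
genes, and characterising what those targets do.

Human accelerated regions (HARs) and human gained/lost enhancers
(HGEs/HLEs) are the genomic elements that changed most on the human
lineage, but almost all of them are noncoding, and a noncoding element's
regulatory target is frequently not its nearest gene. `evotarget`
implements the chromatin-interaction route to target assignment together
with the downstream statistics such a study needs, exercised end-to-end
on synthetic data with planted ground truths.

## The method at its core

Each element is assigned to its 10 kb bin in a Hi-C contact map, and the
contact between that anchor bin and every candidate bin within 1 Mb
(198 candidates for an interior anchor) is tested against a background
null. The null is fitted on GC- and length-matched random regions — 40
per element, same chromosome, GC within 5 percentage points — whose
contact profiles supply background observations for every
(chromosome, distance) cell. Each cell gets a two-parameter Weibull
fitted by maximum likelihood to its positive contacts, and the
significance of an observed contact *x* is its survival probability

> p = exp( −(x/λ)^κ )

with (κ, λ) the shape and scale of the matching cell. P-values are
Benjamini–Hochberg corrected over the full element × candidate family;
contacts with FDR < 0.01 are significant, and significant contacts
landing in a 2 kb promoter nominate that promoter's gene as a target.
Coding elements (exon/UTR/1 kb promoter/1 kb downstream) are assigned
directly by coordinates.

Around the caller the package provides: binomial (region-based),
conservation-controlled Fisher, and matched-permutation enrichment of
elements in regulatory annotations; stage-matched cross-species
expression Z-score differences, breakpoint-shift and dN/dS contrasts,
and module enrichment; gene-set enrichment by logistic regression with a
coding-sequence-length covariate; and a fully seeded synthetic-data
generator (`simulate_genome()`, `simulate_contacts()`,
`simulate_expression()`) that plants loops, enrichments and expression
shifts so every stage is testable without external data.

## Worked example

```r
library(evotarget)
library(dplyr)

cfg <- synth_config(seed = 7, chrom_lengths = c(chrA = 4e6, chrB = 4e6),
                    n_elements = c(HAR = 120), n_genes = 80, n_peaks = 600,
                    n_loops = 15)
sim  <- simulate_genome(cfg)          # genome + genes + conservation + elements
cmap <- simulate_contacts(cfg, sim)   # contact map with 15 planted loops

controls <- sample_gc_length_matched(sim$elements, sim$genome, reps = 40, seed = 7)
#> controls drawn: 4800 | after dedup: 4800

bg   <- locus_profiles(cmap$contacts,
          bin_anchors(rename(controls[c("chrom","start","end","source")],
                             name = "source")))
null <- fit_contact_null(bg[c("chrom", "distance", "contact")])
glance(null)
#>   n_cells n_pooled median_shape mean_zero_frac
#> 1     198        0         3.97          0.151

calls <- correct_and_call(interaction_pvalues(
  locus_profiles(cmap$contacts, bin_anchors(sim$elements)), null), fdr = 0.01)
#> tests: 22480 | significant: 16

targets <- assign_targets(calls, sim$elements, sim$genes,
                          mode = "fetal_full", chrom_sizes = sim$chrom_sizes)
head(targets, 5)
#>   element   gene_id  evidence             q
#> 1 HAR-00005 gene0047 interaction   1.86e- 4
#> 2 HAR-00006 gene0031 interaction   1.82e-12
#> 3 HAR-00007 gene0002 coding_direct NA
#> 4 HAR-00010 gene0054 coding_direct NA
#> 5 HAR-00014 gene0043 coding_direct NA
```

The 198 fitted null cells are the (chromosome, distance) grid; a median
shape near 4 and ~15% zeros match how the map was generated. Of the 16
significant contacts, 10 of the 15 planted loops appear in the target
map (the rest fall below the 3× contact fold at this small scale).
Conservation-controlled enrichment of the same elements in the planted
annotation:

```r
fisher_conserved(sim$elements, sim$annotation, sim$conserved_regions)
#>    A  B  C   D odds_ratio conf.low conf.high p.value
#> 1 24 70 96 664       2.37     1.42      3.95 0.00148
```

where A/C count elements overlapping/missing the annotation and B/D the
conserved-region background. `run_all(cfg, out_dir)` chains every stage
and writes the result tables, a ground-truth JSONL and a provenance
manifest; rerunning with an unchanged config is a cache hit.

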