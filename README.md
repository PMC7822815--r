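# spliceuse

Detecting and explaining transcription-factor-driven differential splicing
from RNA-seq.

Knockdown of a chromatin-binding (fusion) transcription factor can change
not only which genes are transcribed but *how* their transcripts are
spliced. `spliceuse` implements the computational pipeline for this kind of
study end to end: it flattens gene models into disjoint exon bins and a
junction catalog, quantifies bins and exon–exon junctions (EEJs) from
spliced alignments, detects retained introns, calls differentially used
exons and junctions with a gene-relative moderated statistic, classifies
differential junctions into alternative-splicing modes, integrates
epigenetic peak proximity and splicing-factor motif features with a
class-balanced random-forest meta-classifier (with partial-dependence
profiles), contrasts nascent against total RNA to find delayed splicing,
and annotates isoform consequences (ORFs, premature termination codons
under the NMD rule). It is aimed at computational biologists analysing
perturbation RNA-seq (e.g. siRNA knockdown, two conditions with
replicates) together with ChIP-seq/DNase peak tracks.

## The core statistic

Differential *usage* is separated from differential *expression* by
testing each feature against the rest of its gene. For feature *f* of gene
*g* in sample *s*:

    u_fs  =  log2(c_fs + 0.5) − log2(T_gs − c_fs + 0.5)

where `c` is the feature count and `T` the gene total. The usage effect is
the difference of condition means of `u` (proportional gene-level changes
cancel exactly), the statistic divides it by a moderated standard error
(per-feature variance shrunk toward the family mean, prior df 4; p-values
from a t distribution with Satterthwaite effective df), and calls require
**more than 2-fold usage change and BH q < 0.1**. Two calling methods
(moderated t and label permutation) feed union/intersection consensus
bookkeeping, mirroring multi-caller designs.

Around that core: Fisher/χ² categorical enrichment with Haldane-corrected
odds ratios, a decision-ordered splicing-mode classifier
(canonical / cassette skipping / mutually exclusive / alt 5'SS / alt 3'SS /
complex), PWM scanning in four splice-site windows, distance-to-peak
features, and a 1000-run × 1000-tree balanced random forest (scaled-down
configurations preserve its partial-dependence shapes).

## Worked example

Everything below runs on synthetic data with planted truth — no downloads.

```r
library(spliceuse)

cfg <- sim_config(seed = 1)            # 200 genes, 3 vs 3, planted usage shift 2
ann <- simulate_annotation(cfg)        # genome + gene models + truth
sim <- simulate_counts(ann)            # bin/junction/transcript counts

grouping <- setNames(sim$junctions$gene_id, sim$junctions$junction_id)
us <- usage_statistic(sim$junction_counts, grouping,
                      conditions = c("siMM", "siRR"))
calls <- call_differential(us, fc = 2, q_max = 0.1)

head(us[order(us$q), c("feature_id", "usage_log2fc", "stat", "p", "q")], 5)
#>          feature_id usage_log2fc     stat            p            q
#> 715 G0106:3233-1518     1.846686 23.35779 8.635709e-14 1.166684e-10
#> 742 G0110:1238-2029     1.821120 20.77737 5.311066e-13 3.587625e-10
#> 472 G0068:1219-2490     1.701007 19.85652 1.069222e-12 4.756463e-10
#> 848 G0126:2359-3431     1.614488 19.50454 1.408279e-12 4.756463e-10
#> 238 G0034:2561-1821     1.811179 18.38385 3.493619e-12 9.439757e-10

sum(calls$is_differential)
#> [1] 31
mean(ann$truth$diff_junctions %in% calls$feature_id[calls$is_differential])
#> [1] 0.9666667
```

The top features are the planted skip junctions: the generator shifts the
skip transcript's odds by 2^2 = 4, which realizes as a junction-usage
log2 fold change of ~1.6–1.8 (the within-gene denominator co-moves), and
29 of the 30 planted junctions are recovered at the study thresholds among
31 calls.

The one-call orchestrator runs every stage and writes TSV/JSON results and
a checksum manifest:

```r
res <- run_pipeline(sim_config(seed = 1), out_dir = "spliceuse_run")
res$manifest$auroc        # balanced random-forest AUROC (50 runs x 100 trees)
head(res$importance)      # permutation-importance ranking
res$delayed$summary       # nascent vs total medians per junction class
```

See the vignette (`vignettes/spliceuse-methods.Rmd`) for the models,
parameter meanings and generator design.

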