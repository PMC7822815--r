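---
title: "Models and methods behind spliceuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceuse)
```

# Scope

`spliceuse` detects condition-dependent differential splicing from RNA-seq
and then tries to *explain* it: which alternative-splicing mode each
differential junction belongs to, how differential junctions relate to
epigenetic marks (transcription-factor binding, RNA polymerase II, histone
acetylation, open chromatin) and to splicing-factor binding motifs, whether
their splicing is delayed (nascent versus total RNA), and what the affected
isoforms encode (premature termination codons predicting nonsense-mediated
decay). A synthetic-data generator with fully known planted truth backs
every claim the test suite makes.

This vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

# Gene models, bins and junctions

Internally all coordinates are 0-based half-open; GTF input and output
convert from the 1-based inclusive convention at the I/O boundary only.
This makes bin arithmetic (lengths, splits, containment) free of off-by-one
cases.

Counting units are produced by *flattening*: the per-base union of a
gene's exons is split at every position where the set of covering
transcripts changes, giving maximal disjoint sub-intervals (the same idea
DEXSeq uses to build counting bins). Each bin receives a functional type by
classifying every base against the CDS of every covering transcript:
5'-UTR, CDS, 3'-UTR for coding transcripts, "noncoding" for transcripts
without a CDS. A bin whose bases fall into exactly one category gets that
category; any mixture — across bases or across transcripts — is
`multi_type`, which is why `multi_type` exists as a first-class category in
enrichment tables rather than being resolved by majority vote.

The junction catalog contains one record per distinct consecutive-exon pair
across transcripts, deduplicated by (donor, acceptor). The donor is the
last exonic base of the 5' exon and the acceptor the first exonic base of
the 3' exon, both strand-aware genomic positions; "5' splice site" always
means the donor. Junctions with a flanking exon shorter than 25 bp or an
intron shorter than 50 bp are excluded — these are the same minimum-length
filters applied to public mRNA/EST evidence in the study this package
operationalizes.

Retained introns are *not* junctions here: they are additional counting
bins called from coverage. An intron is detected in a condition if, in at
least `k = 2` of that condition's replicates, its mean per-base coverage is
at least `c_abs = 5` and at least `theta = 0.1` times the smaller flanking
exon-bin coverage. These three knobs are exposed because the criterion is a
heuristic: the absolute floor suppresses spurious calls in weakly expressed
genes where the relative criterion alone would fire on noise, and the
relative criterion suppresses calls in deeply covered genes where a few
percent of intronic signal is expected from co-transcriptional reads.

# The gene-relative usage statistic

Differential *usage* must be separated from differential *expression*. For
feature $f$ of gene $g$ in sample $s$ with count $c_{fs}$ and gene total
$T_{gs}$, the usage value is the within-gene log-odds

$$u_{fs} = \log_2(c_{fs} + 0.5) - \log_2(T_{gs} - c_{fs} + 0.5),$$

and the effect size is the difference of condition means of $u$. Because
$u$ is a ratio within the gene, a proportional change of all features
(pure gene-level expression change) cancels exactly — the package asserts
this invariance in its tests. The pseudocount 0.5 keeps the statistic
finite at zero counts and at features carrying the whole gene.

The test statistic divides the effect by a moderated standard error: the
per-feature pooled within-condition variance is shrunk toward the family
mean variance with a fixed prior of $d_0 = 4$ degrees of freedom. The prior
is fixed, not estimated, so results are deterministic and reproducible
without a fitted hyper-parameter. One distributional subtlety matters: when
the shrinkage target is the (essentially noise-free) family mean rather
than a scattered inverse-chi-square prior, the null statistic does not
follow $t_{d_0+d}$; its variance corresponds to the Satterthwaite
effective degrees of freedom

$$d_\mathrm{eff} = \frac{(d_0 + d)^2}{d},$$

which is 16 for a 3 vs 3 design ($d = 4$). Using $t_{d_0+d} = t_8$ makes
the test conservative (measured type-I error ~2.9% at nominal 5%);
$t_{d_\mathrm{eff}}$ restores calibration (measured 4.0–5.0%,
Kolmogorov–Smirnov uniformity not rejected at $\alpha = 0.01$ on 10,000
null negative-binomial features). The package uses $d_\mathrm{eff}$.

Calls use the study thresholds: more than 2-fold usage change **and**
BH-adjusted $q < 0.1$, both strict inequalities. BH adjustment is applied
within each feature family separately (bins, junctions, TSS expression,
TSS usage), because the families differ in size and signal density.

A label-permutation variant of the same statistic (p-value from the
permutation distribution of the usage effect over condition-label
reassignments; all $\binom{6}{3} = 20$ assignments are enumerated for
3 vs 3) serves as a second calling method. The published analysis compared
three external callers whose union/intersection bookkeeping the `consensus`
function preserves; re-implementing those callers was never the goal — the
two in-package methods exercise the identical consensus logic.

Differential TSS analysis groups transcripts whose start positions lie
within 10 bp (single-linkage along the sorted positions), then tests each
TSS group twice: total abundance between conditions (moderated t on
log2-CPM; thresholds at least 2-fold, $p < 0.005$, $q < 0.1$) and usage
within the gene (the usage statistic above; at least 2-fold,
$p < 0.0007$, $q < 0.1$). The fold-change filter in the usage arm is
applied on the usage scale; a flag could equally apply it on the
expression scale — the legends the thresholds come from do not
disambiguate, and usage scale is the self-consistent choice for a usage
test.

# Splicing-mode classification

The classifier receives a junction and the gene's annotated structure and
assigns exactly one mode, in a fixed decision order:

1. annotated (donor, acceptor) pair → `canonical`;
2. both sites are annotated boundaries, the pair is novel, and the spanned
   intron fully contains at least one annotated exon → `cassette_skipping`,
   or `mutually_exclusive` when the skipped exons include two exons that
   never co-occur in any annotated transcript;
3. exactly one novel site → `alt_5ss` (novel donor) or `alt_3ss` (novel
   acceptor), strand-aware;
4. two or more simultaneous deviations — both sites novel, or a shifted
   site combined with skipping — → `complex`.

Two corner cases are decided here rather than left open: a novel pairing of
two annotated boundaries that skips nothing is `complex` (two sites taken
out of their annotated context), and a skipped exon combined with a shifted
site is `complex` by the "two or more events" definition, not
`cassette_skipping`. Mutually-exclusive detection requires annotation
evidence; inferring exclusivity from expression data alone is out of scope.
Intron retention is never assigned to a junction — it is a bin-level call.

The test suite checks the classifier against an independent first-principles
oracle on *every* candidate junction placement (all combinations of
boundary, exon-interior and intron-interior positions) in 3- and 4-exon
genes.

Enrichment of categories (functional exon types, peak overlap) uses the
cross-product odds ratio $ad/bc$ with a Haldane correction of 0.5 added to
all cells when any cell is zero, two-sided Fisher exact or chi-square
(no continuity correction) p-values, and BH adjustment across labels.

# Sequence and epigenetic features

Motif predictors come from position weight matrices parsed from
JASPAR-style count text: counts are converted to probabilities with a
pseudocount of 0.25 per base and to log2-odds against the background
(uniform by default). A *hit* is an offset scoring at least 80% of the
matrix's maximum attainable score. Four strand-aware windows are scanned
per junction: the last 100 nt of the donor exon, the first and last 100 nt
of the intron, and the first 100 nt of the acceptor exon. Window widths are
configuration, not biology: the regions are what matters (splicing-factor
binding concentrates near splice sites), and 100 nt covers the typical
footprint of intronic splicing enhancers/silencers without diluting the
signal. Two summaries per factor and window: frequency (hits per kb) and
strength (maximum score; sentinel −50 when the window is too short to
evaluate any offset). `N` bases contribute a log-odds of 0.

Peak-track predictors are unsigned distances from the donor and acceptor to
the nearest peak edge per mark, 0 inside a peak, with the distance defined
as the coordinate difference to the nearest edge (a site one base away from
a peak has distance 1). A chromosome missing from a track yields an
infinite sentinel, replaced by 10^7 before model fitting. Mark names are
labels; nothing in the code is specific to the four marks of the motivating
study.

# The random-forest meta-classifier

The classifier separating differential from non-differential junctions
faces extreme class imbalance (hundreds of differential junctions against
~10^5 non-differential in the motivating data). The package handles this
with repeated balanced runs: each run keeps every minority-class example
plus an equal-size random sample of the majority class, fits a probability
forest, and evaluates on the untouched majority remainder together with
out-of-bag predictions for the minority class. The reported AUROC is the
mean over runs. The reference configuration is 1000 runs of 1000 trees —
the scale of the published analysis; the test suite and the acceptance
script run the scaled-down 50 x 100 configuration, whose partial-dependence
profiles preserve the full configuration's shape.

Partial dependence sweeps one feature over the deduplicated deciles of its
observed distribution (not a uniform grid — distance features are heavily
right-skewed and a uniform grid would spend most points in empty space),
sets the feature to each grid value for every sample, and averages the
predicted differential-class probability over samples, trees and runs;
probabilities are averaged, not votes. The across-run standard deviation is
reported as the profile's dispersion.

Feature importance is the out-of-bag permutation importance (mean accuracy
decrease when a predictor is permuted), averaged over the balanced runs and
ranked. This is the canonical Breiman estimator and is computed inside each
forest; an alternative — re-scoring AUROC on the held-out majority with one
feature permuted — measures a similar quantity but cannot include the
minority class (whose honest predictions exist only out-of-bag), so the
OOB estimator is used.

Determinism contract: per-run RNG seeds are drawn once from the
configuration seed, so results are independent of execution order and
identical across reruns.

# Delayed splicing and cohort analyses

The nascent-versus-total comparison takes junctions shared between the two
fractions, averages log2-CPM over replicates, and compares the differential
and non-differential classes within each fraction and each class across
fractions with two-sided Mann–Whitney tests. A bimodality score — the
log-likelihood improvement of a 2-component over a 1-component Gaussian
mixture — quantifies the "two populations" shape that a delayed class
produces. Log2-CPM is compositional: thinning one class shifts every other
class's CPM through the library size, which is why the unit tests pin
library sizes when isolating the planted effect.

Junction signatures across cohorts use FastICA (symmetric decorrelation,
logcosh contrast, SVD whitening, seeded deterministic initialization)
implemented in the package. The data matrix is junctions x samples; sources
are independent over junctions (unit-norm loadings), per-sample weights
come from least-squares projection, components are ranked by the
Mann–Whitney p-value separating the two sample groups on their weights, and
a component's signature is the junction set with loading $|z| > 2.5$. The
component count defaults to (number of groups + 3); selection by
separation p-value replaces any scree heuristic. Signed co-expression
edges are Pearson correlations against a seed gene with $|r| \ge 0.5$ and
BH-adjusted correlation-test p-values.

# Isoform consequences

The main open reading frame of a spliced transcript is the longest
AUG-initiated ORF terminating at an in-frame stop; an ORF running off the
transcript end does not qualify, ties go to the 5'-most start, and codons
containing ambiguous bases neither initiate nor terminate. A transcript
whose best ORF encodes fewer than 100 amino acids is called non-coding —
an explicit ORF-length proxy for "no significant open reading frame"
(coding-potential classifiers are out of scope). Premature termination
uses the standard exon-junction-complex rule: the stop codon is premature
iff it lies more than 50 nt upstream of the transcript's last exon-exon
junction (strict inequality; single-exon transcripts are always mature).
Both the 100-codon and the 50-nt constants are configurable. PTC fractions
are compared between differential and non-differential isoforms among
coding transcripts only, with the cross-product odds ratio and Fisher's
exact test; a flag to include non-coding transcripts in the denominator
is deliberately absent — the non-coding class is removed first, mirroring
the classification tree the analysis reports.

Protein identity against a user-supplied reference set uses global
Needleman–Wunsch alignment with identity = matches / alignment length;
the conventional downstream filter keeps hits at 90% or better.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the
reference study conditions used by the acceptance suite:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | genes, one contig each |
| `n_replicates` | 3 | per condition (siMM vs siRR) |
| `depth` | 300 | mean fragments per gene |
| `dispersion` | 0.05 | negative-binomial dispersion |
| `frac_diff_junctions` | 0.15 | genes with a planted usage shift |
| `usage_effect` | 2 | log2-odds shift of the skip transcript |
| `frac_retained_introns` | 0.1 | genes with a planted retained intron |
| `peak_assoc_prob` / `background_prob` | 0.8 / 0.1 | peak near diff donors / per-kb background |
| `assoc_window` | 500 bp | planted peak distance bound |
| `motif_plant_prob` / `motif_background_prob` | 0.8 / 0.1 | consensus planting rates |
| `delayed_frac` / `delay_factor` | 1 / 4 | nascent deficit of the diff class |
| `tss_diff_frac` / `tss_effect` | 0.1 / 4 | alternative-TSS activation |
| `concentration` | 20 | Dirichlet concentration of gene usage profiles |

Every gene carries a full-length transcript plus a cassette-skipping
transcript; half additionally carry an alternative-5'-splice-site
transcript, and a subset an alternative-TSS transcript starting at exon 2.
A real reading frame is written through each gene's CDS exons, so spliced
transcripts translate and exon skipping produces genuine frameshifts and
premature stops. Splicing-factor consensus elements are planted at fixed
offsets starting 12 nt inside the intron downstream of the skip junction's
donor.

Two generator choices deserve explanation:

* **Where the Dirichlet acts.** The isoform usage profile of each gene is
  drawn *once* from Dirichlet(concentration x base proportions) and shared
  by both conditions; per-sample variation is negative-binomial depth plus
  multinomial allocation. Drawing a fresh Dirichlet per sample at
  concentration 20 would put a log-odds standard deviation of ~0.8 on every
  replicate's usage — noise under which no 3 vs 3 design can recover a
  2-unit shift at the study thresholds with sensitivity 0.8. The gene-level
  draw models usage heterogeneity across genes (its intended purpose) while
  keeping replicate noise at the counting level. The cost is a known
  limitation: the generator has no biological replicate-to-replicate usage
  variability, so passing recovery tests bound counting noise, not
  between-replicate biology.

* **What `usage_effect` shifts.** The planted shift multiplies the *skip
  transcript's* odds by `2^usage_effect` in the contrast condition. At the
  junction-usage statistic (feature versus rest-of-gene), this realizes as
  a log2 fold change of about 1.6–1.8 rather than 2: the denominator
  contains all of the gene's junction mass, which co-moves with the shift.
  The generator therefore also reports the *analytic* true usage effect of
  every junction, computed from the planted proportions, in
  `sim$true_usage`. Recovery tests score sensitivity on the planted skip
  junctions and count as false discoveries only calls on truly-unchanged
  junctions (analytic |effect| at most 0.25) — compensatory shifts in
  neighbouring junctions of a perturbed gene and usage shifts induced by
  the planted TSS activation are genuine signal, not errors.

What the generator does *not* emulate: read-level sequence errors and
alignment ambiguity (counts are generated directly; a minimal SAM/BAM
path exists for the alignment-level operations' tests), positional
coverage bias along transcripts, correlated gene networks, and the
biological replicate variability noted above. Recovery results on this
generator therefore demonstrate correctness of the statistical machinery
under its stated model, not performance on real libraries.

# Problem sizes and determinism

The test and acceptance workloads use the reference configuration
(200 genes, ~1300 junctions, 3 vs 3) for recovery, calibration on 10,000
null features, the 50 x 100 random-forest configuration with 20-seed
importance replication, and exhaustive oracle enumerations elsewhere;
these sizes were chosen so the full validation remains a desk-scale
computation. All generators and the full pipeline are deterministic under
a single seed: rerunning `run_pipeline()` with the same configuration
reproduces byte-identical output checksums.

# Known limitations

* The usage statistic tests one feature at a time; coordinated
  multi-junction events are visible only through the event classifier's
  `complex` category, not modelled jointly.
* Percent-spliced-in is not estimated; all effects are on the
  within-gene log-odds scale.
* The RI detector is coverage-based; assembly-based retention evidence is
  not consumed.
* Partial dependence is descriptive, not causal; correlated predictors
  share credit in an unidentifiable way.
* The built-in PWMs are emulations (near-deterministic consensus
  matrices) for six splicing factors; real scans should load measured
  matrices through `read_pwm_jaspar()`.

```{r quick-example, eval = FALSE}
## end-to-end synthetic run at the reference conditions
res <- run_pipeline(sim_config(seed = 1), out_dir = "spliceuse_run")
res$manifest$auroc
head(res$importance)
```
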