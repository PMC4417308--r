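---
title: "Linkage mapping, scaffold anchoring and immunity-gene cataloguing in an outcrossed full-sib family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping, scaffold anchoring and immunity-gene cataloguing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpmap)
```

# The problem

`cpmap` implements the analysis chain behind a SNP-based genetic map for a
highly heterozygous, clonally propagated crop such as cassava: a cross
between two outbred parents produces a full-sib F1 family (a "CP"
population) in which each parent segregates independently. Markers
heterozygous in exactly one parent segregate 1:1 in the progeny; markers
heterozygous in both parents segregate 1:2:1. From genotyping-by-sequencing
(GBS) SNP calls the pipeline

1. classifies and filters markers (`marker_qc_table()`, `filter_markers()`,
   `dedup_cosegregating()`, `annotate_snp()`, `ts_tv()`);
2. estimates pairwise recombination fractions, phases and LOD scores
   (`two_point_table()`, `estimate_two_point()`), partitions markers into
   linkage groups (`group_markers_robust()`), orders each group and assigns
   Kosambi map positions (`order_group()`, `build_map()`, `map_summary()`);
3. anchors and orients assembly scaffolds on the map
   (`anchor_scaffolds()`, `orient_scaffold()`, `coverage()`, `kb_per_cm()`,
   `compare_maps()`, `place_external_locus()`);
4. builds an immunity-related-protein (IRP) catalog from HMMER domain hits
   and detects physical clusters of resistance genes
   (`parse_domain_table()`, `classify_irp()`, `build_catalog()`,
   `map_irps()`, `detect_clusters()`).

A synthetic-data generator (`sim_config()`, `simulate_study()`) produces a
complete study with known ground truth, so every stage is scored against
what it should recover.

# The CP two-point model

For two biallelic markers, each parent carries two haplotypes; whether the
alleles sit in coupling or repulsion (the *phase*) is unknown. Each progeny
genotype is the union of one maternal and one paternal gamete, and each
parent transmits a phase-defined haplotype with per-meiosis recombination
probability $r$. `pair_log_likelihood()` evaluates exactly this generative
model; `estimate_two_point()` maximises it over $r \in [0, 0.5]$ and the at
most four phase configurations (a coarse grid of step 0.01 followed by
golden-section refinement to $10^{-6}$; the log-likelihood is unimodal in
$r$ for each phase, so a finer initial grid would add cost without
precision). The LOD is
$\log_{10} L(\hat r) - \log_{10} L(0.5)$ under the best phase. A
maternal-only × paternal-only pair has no parent heterozygous at both loci
and therefore carries *no* information about recombination: it is returned
as $\hat r = 0.5$ with LOD 0 and flagged. The all-pairs engine is compiled
(`src/twopoint.cpp`) because a default run evaluates ~260,000 pairs; it
also returns the observed Fisher information of $\hat r$ (negative
curvature of the log-likelihood), used later as weights.

Map distances use the Kosambi function
$d = 25\,\ln\frac{1+2r}{1-2r}$ (`kosambi()`, `kosambi_inv()`), the
convention for reported plant maps. The Haldane function
$d = -50\,\ln(1-2r)$ (`haldane()`) appears internally where recombination
fractions spanning many intervals must be *composed*; see below.

# Grouping

Linkage groups are the connected components of the graph with an edge
wherever LOD exceeds a threshold and rf is below 0.5 (`group_markers()`).
The classical per-pair threshold of 3 controls the error of a *single*
test; over $\binom{720}{2} \approx 2.6\times10^5$ pairs a handful of
spurious LOD > 3 edges is expected from binomial sampling alone, and under
single-linkage closure one false edge fuses two chromosomes. Conversely a
marker-sparse region can split a chromosome at a strict threshold.
`group_markers_robust()` therefore works in two stages:

* **strict stage** — components at the Bonferroni-style threshold
  `grouping_lod(n, fwer)`: the $\chi^2_1$ quantile at
  $1 - \mathrm{fwer}/\binom{n}{2}$ divided by $2\ln 10$ (about LOD 7.5 for
  720 markers at the default `fwer = 0.001`);
* **coherent merging** — every pair of groups still linked by an edge
  above the per-pair threshold is tested for *geometric coherence*: cross
  pairs predicted close (distances routed through informative pairs) must
  actually look linked (contradiction fraction < 0.3), and the linkage
  must be visible in **both parents' meioses**. The two-channel requirement
  is the decisive one: a genuine within-chromosome gap is crossed by
  recombination in maternal and paternal meioses alike, whereas a spurious
  bridge is a sampling fluctuation of one parent's transmission pattern,
  echoed by linked neighbours but absent from the other parent's
  informative pairs.

Merges are applied best-first and re-evaluated, so a chromosome split by a
long gap is reunited while chance bridges are rejected. Groups smaller
than `min_size` (default 2) are reported unplaced rather than forced into
the map.

# Ordering and map positions

Ordering uses all informative pairwise distances, not only adjacent ones.
The positions $x$ of a group minimise the weighted stress

$$\sum_{i<j} w_{ij}\,\bigl(|x_i - x_j| - d_{ij}\bigr)^2,$$

where $d_{ij}$ is the two-point distance and
$w_{ij}$ its inverse sampling variance (delta method with the observed
Fisher information, which automatically downweights weakly informative
pair types such as double-heterozygous pairs in repulsion). Given a
candidate order, the signs of $x_i - x_j$ are fixed and the minimiser
solves a weighted-Laplacian linear system whose Cholesky factor is reused
across all candidates. Candidate orders are seeded by greedy chain
extension from every start marker and by a 1-D principal-coordinate
embedding, then refined by ripple passes over windows of three markers,
single-marker reinsertion, 2-opt segment reversal and contiguous-block
reinsertion until the objective stops improving. A classic
sum-of-adjacent-recombination-fractions objective is available as
`order_group(..., objective = "sarf")` and is held to an exhaustive-search
oracle on small groups in the tests.

Three numerical choices matter and were each adopted after the simpler
alternative measurably failed on simulated truth:

* **Additive scale.** Under the Markov (no-interference) model that the
  two-point likelihood already assumes, recombination fractions across
  many intervals compose as
  $r_{13} = r_{12}(1-r_{23}) + r_{23}(1-r_{12})$ — exactly the composition
  under which *Haldane* distances are additive. Kosambi distances are
  sub-additive for such composites: embedding with Kosambi $d_{ij}$
  compressed long-range distances by up to ~30% and systematically
  favoured wrong arrangements of weakly joined blocks. The embedding
  therefore works on the Haldane scale, and each *adjacent fitted
  interval* is converted back to Kosambi centiMorgans via its
  interval-scale rf — the same convention as converting interval
  estimates with the Kosambi function in standard map software.
* **Censoring and the scale refit.** Pairs estimated at rf ≥ 0.45 have
  essentially unbounded distance and are excluded from the stress; but
  near that boundary only downward-fluctuated estimates survive the cut,
  which shortens the longest spans. The final scale fit therefore keeps
  only pairs whose *fitted* separation (pooled over many pairs, hence
  nearly selection-free) is below 60 cM.
* **Censored pairs as one-sided evidence.** A pair observed at rf ≥ 0.45
  still says "these markers are far apart". The ordering score adds the
  approximate one-sided $-2\log$-likelihood of that observation at the
  fitted separation (normal approximation, $z$ capped at 5). This term
  resolves most near-degenerate decisions about which end of a distant
  block faces the rest of the group.

**What two-point information cannot do.** With 132 progeny, adjacent
markers a few cM apart yield $\hat r$ with a standard error comparable to
the marker spacing. Pooling all pairs reduces the positional noise to
roughly 1 cM, so occasional local inversions of close markers are
unavoidable, and for a few groups per run the full objective genuinely
prefers a locally wrong arrangement (refitting from the true order drifts
away from it). Resolving those orders requires multipoint likelihood over
raw genotypes, which is deliberately out of scope; on the default study
design the per-group Kendall agreement with truth averages ≈ 0.95–0.96 but
individual groups can fall to ≈ 0.9 or occasionally lower. The per-record
outputs always allow re-ordering with external software.

`build_map()` defaults to these least-squares positions
(`method = "ls"`); `method = "adjacent"` gives the classical cumulative
sum of adjacent Kosambi intervals over the completed rf matrix
(`completed_rf_matrix()` routes uninformative maternal×paternal
adjacencies through informative pairs; an adjacency with no path at all is
capped at rf 0.499 with a warning).

# Scaffold anchoring

Scaffolds inherit the linkage group(s) of their mapped markers; the
primary group is the majority vote, and a scaffold with markers in two or
more groups keeps all assignments but is flagged as a conflict (its length
still counts once in `coverage()`). Orientation is the sign of the
Spearman correlation between marker bp and cM — robust to non-uniform
marker spacing, and defined only when at least two markers differ in both
coordinates. `kb_per_cm()` summarises physical-to-genetic ratios over
scaffolds with at least three markers and a non-degenerate cM span;
`compare_maps()` matches two maps by exact (scaffold, bp) marker identity
(a bp tolerance argument exists for cross-pipeline coordinate drift) and
reports shared/new scaffolds with the summed length of the new ones;
`place_external_locus()` interpolates an external locus linearly between
the flanking supporting markers in scaffold bp order, extrapolating to the
nearest marker's position (flagged) beyond the outermost marker.

# The IRP catalog

`parse_domain_table()` reads the HMMER3 `--domtblout` layout (columns 1,
2, 4 and 7: target, accession, query, full-sequence e-value), keeps hits
with e-value ≤ 10 — the boundary is inclusive, a documented convention —
and collapses recognised Pfam accessions to the six diagnostic labels
LRR, kinase, LysM, NB-ARC, TIR, WRKY. `classify_irp()` maps each
protein's domain *set* (presence/absence only; architecture order is
ignored) to one of ten immunity classes — LRR (receptor-like proteins),
LRR-kinase (receptor-like kinases), LysM, LysM-kinase, NB-ARC,
NB-ARC-LRR, TIR, TIR-LRR, TIR-NB-ARC-LRR, WRKY (only when WRKY is the
sole domain) — with any other non-empty combination reported as `other`.
Genes are placed genetically at their midpoint through the anchored
scaffolds.

`detect_clusters()` scans each scaffold's genes in bp order and links two
consecutive IRPs when the boundary-to-boundary gap (end of the upstream
gene to start of the downstream one) is at most 200 kb *and* fewer than
eight non-IRP genes lie strictly between them; clusters are maximal
linked runs of at least two genes and never span scaffolds, because
inter-scaffold order is unknown in a draft assembly. The intervening-gene
count uses the full gene complement, so the generator emits every gene,
not only the immunity-related ones. Tests hold the implementation to an
$O(n^2)$ brute-force restatement of the rule on hundreds of random
layouts.

# The synthetic study and what it does (not) show

`sim_config()` defaults describe the emulated study: 18 chromosomes with
the published per-group length profile (36.5–208.5 cM, 2,571 cM in
total), eight scaffolds of 1 Mb per chromosome with five markers each
(~40 per chromosome), 132 progeny, 5% missing calls, no genotyping error
(configurable), and a segregation-type mix of 30/35/34% maternal-1:1 /
paternal-1:1 / both-heterozygous plus 1% monomorphic markers for filter
testing. Transitions are drawn so the marker set's Ts/Tv is ≈ 1.06. Gene
density is 30 per Mb; about 3.5% of genes are immunity-related with class
frequencies proportional to a realistic repertoire (LRR and LRR-kinase
dominating, TIR-LRR rare), and ten three-gene clusters with 50 kb
internal gaps are injected on dedicated scaffolds so their membership is
recoverable exactly.

Meiosis is simulated marker-to-marker as a Markov chain: the transmitted
parental haplotype switches between adjacent markers with probability
equal to the Kosambi inverse of the interval. Adjacent-interval rf is
therefore recoverable exactly in expectation, which is what the recovery
tests assert; long-range rf composes without interference and so deviates
from Kosambi additivity (the reason for the Haldane-scale embedding
above). The generator does not simulate reads, sequencing depth,
genotyping error correlated with depth, segregation distortion from
selection, or assembly errors — so passing recovery tests demonstrate the
*statistical* machinery, not robustness to artefacts of a particular GBS
pipeline.

Problem sizes in the tests (720 markers, 132 progeny for the full run;
10,000 markers for filter calibration; 200 replicates for rf recovery;
200 random layouts for the cluster oracle) were chosen so the whole suite
runs comfortably on a single CPU while keeping Monte-Carlo error well
inside the asserted tolerances.

# Known limitations

* No multipoint likelihood: ordering and distances use two-point
  statistics only (see above for the consequences).
* Linkage-group naming is by smallest member id; correspondence to
  published chromosome numbers is not attempted, and comparisons use
  partitions, not labels.
* Sex-specific (maternal/paternal) maps are not produced, although the
  phase and per-parent information are computed.
* The distortion rule "less than 10% distorted markers" is implemented as
  per-marker χ² filtering at a configurable α (default 0.05) plus a
  reported distorted fraction, with an optional hard abort
  (`abort_if_distorted_frac`) — the fraction-based wording alone does not
  identify *which* markers to drop.
* Promoters default to 2,000 bp upstream of the transcription start when
  the annotation carries no explicit promoter features.
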