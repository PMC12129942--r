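---
title: "Integrative species delimitation: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotodelim)
```

## The problem

Groups like the *Cotoneaster buxifolius* complex combine polyploidy,
apomixis and recurrent hybridization. The result is that morphology,
nuclear phylogeny and plastid phylogeny routinely disagree: nominal
species fail to form clades, admixture analysis shows taxa drawing
ancestry from several gene pools, and plastid capture places taxa next
to their maternal donors rather than their nuclear relatives. cotodelim
implements a delimitation framework that treats these conflicts as
data: every taxon is scored on gene-pool purity, support-thresholded
nuclear monophyly, morphological diagnosability and cytonuclear
concordance, and an ordered rule cascade turns the evidence bundle into
a verdict.

## The admixture model and its EM fit

Ancestry coefficients follow the standard admixture likelihood for
unlinked biallelic dosages $g_{ij} \in \{0,1,2\}$:

$$
\log L(Q, P) = \sum_{ij}\Big[\, g_{ij}\log f_{ij} +
(2-g_{ij})\log(1-f_{ij})\Big], \qquad
f_{ij} = \sum_k q_{ik} p_{kj},
$$

with $q_{ik} \ge 0$, $\sum_k q_{ik} = 1$ and $p_{kj} \in (0,1)$. The
likelihood is the contract; the optimizer is free. We use plain EM with
multiplicative updates (the block-relaxation tricks of production
structure software are unnecessary at the problem sizes this package
targets). The E-step responsibilities fold into closed-form updates, the
log-likelihood is non-decreasing every iteration (asserted in tests),
and iteration stops when the increase falls below
`tol * (|logL| + 1)` (default `tol = 1e-6`) or at `max_iter = 2000`.
Missing dosages are simply skipped in the likelihood and all updates.

Initialization is seeded: $q$ rows from a symmetric Dirichlet(1) draw,
$p$ from global allele frequencies plus a small uniform perturbation.
EM on this likelihood converges to local optima; at the divergence
levels the package simulates ($F \ge 0.15$) label-switching is the only
practical multimodality, handled after the fact by
`align_cluster_labels()`, which maximizes summed column correlation via
an exact assignment solver (a hand-written $O(n^3)$ Hungarian
algorithm, cross-checked against exhaustive permutation search in the
tests).

**Choosing K.** `choose_k_cv()` masks a fraction (default 10%) of the
observed dosages, refits, predicts each masked entry as
$2\sum_k q_{ik}p_{kj}$, and scores mean squared error. The grid search
reports the argmin but never auto-commits a downstream analysis to it:
in real data of this kind the CV curve can stabilize at one K and reach
its minimum at a much larger one, and both resolutions are
scientifically meaningful, so K stays a user choice.

## Purity classes and the override window

A taxon's ancestry profile is the unweighted mean of its samples' $q$
vectors (a population-first average is available via
`by_population = TRUE`). Classes:

* **PURE**: dominant share $q^* \ge 0.95$ — the "single gene pool"
  criterion.
* **SUBTHRESHOLD**: $0.70 \le q^* < 0.95$. This window generalizes a
  documented exception: a taxon can fall short of 95% cohesion yet be
  unambiguously valid when its monophyly is maximally supported and it
  is morphologically diagnosable. Encoding the window as a reusable
  rule, rather than a taxon whitelist, keeps the cascade a pure function
  of evidence.
* **ADMIXED**: $q^* < 0.70$, i.e. material contributions from two or
  more pools. "Contributing" pools are those with mean share
  $\ge 0.05$; the source framework gives no numeric floor for a minor
  contribution, and 5% is the smallest share that survives the kind of
  estimation noise the EM shows at these problem sizes.

## Monophyly with dual supports

Trees carry per-edge (SH-aLRT, UFboot) pairs parsed from Newick node
labels of the form `99.8/100`. Monophyly is assessed in the bipartition
(unrooted) sense — the target leaf set, or its complement, must equal
one side of some bipartition — so root placement is immaterial. The
thresholds are SH-aLRT ≥ 80 and UFboot ≥ 95. Two deliberate
conservatisms: missing support is distinct from support 0 and fails
closed; and single-population taxa, which cannot carry stem support,
pass by waiver (default) unless `waive_singletons = FALSE`. Synthetic
trees built by the package's distance+NJ bootstrap write the bootstrap
percentage into both support slots; SH-aLRT is never simulated — a
documented limitation, since the likelihood-based test has no analogue
in a distance pipeline.

## Diagnosability

A quantitative trait is discontinuous between two taxa iff their
observed $[\min, \max]$ intervals are disjoint; a qualitative trait iff
their observed state sets are disjoint. The framework's criterion is
≥ 2 discontinuous traits. Strict disjointness is the default because
the source framework never quantifies "discontinuous"; a
`gap_fraction` parameter can require a minimum gap as a fraction of the
trait's range. Traits observed in only one taxon are excluded from the
count rather than treated as evidence. Gower distances use
range-normalized quantitative differences and 0/1 state mismatches with
pairwise deletion and renormalization over shared traits; UPGMA merge
heights follow the ultrametric convention (a pair at distance $d$
merges at height $d/2$), so cophenetic distances equal linkage
distances. Trait PCA standardizes integer-coded qualitative traits —
statistically crude but faithful to the source data's coding; constant
traits are excluded with a warning.

## Cytonuclear discordance

Nuclear and plastid backbone clades are matched by the assignment
maximizing the number of concordant populations (optimal assignment on
the label confusion matrix) rather than by assuming a naming
convention; on the study fixture the optimum is exactly NA↔PA, NB↔PB,
NC↔PC. A population is discordant iff its plastid label differs from
the image of its nuclear label; a species is discordant iff any of its
populations is.

## The decision cascade

Rules fire in order; the first match wins:

1. PURE ∧ supported monophyly ∧ diagnosable against every shared-pool
   partner (vacuously true with none) → VALID.
2. PURE-or-SUBTHRESHOLD sharing a pool with a partner against which it
   shows < 2 discontinuous traits → SYNONYM_CANDIDATE for the junior
   name; the senior's diagnosability requirement then ignores that
   junior. Seniority is configuration (nomenclatural priority is not a
   genomic question); the default is map order.
3. SUBTHRESHOLD ∧ supported monophyly ∧ diagnosable →
   VALID_BY_OVERRIDE.
4. ADMIXED ∧ cytonuclear discordance ∧ (non-monophyletic ∨
   morphologically intermediate, operationalized as < 2 discontinuous
   traits against at least one parent-candidate taxon, parent
   candidates being the non-admixed taxa whose pools contribute
   ≥ 5%) → HYBRID.
5. Otherwise UNRESOLVED.

Two design points deserve emphasis. Plastid discordance never vetoes a
pure taxon — discordance in an otherwise coherent species is recorded,
not fatal; it is *required* evidence only on the hybrid path. And
genuinely conflicted taxa (e.g. nuclear affinity to one species,
plastid to a second, morphology to a third) deliberately land in
UNRESOLVED rather than being forced into a category; disabling rule 3
demotes exactly the override taxa to UNRESOLVED, which the tests assert.

After the cascade, `rebuild_without_hybrids()` drops all samples of
HYBRID or ADMIXED taxa (override taxa stay) and re-estimates the
population tree, mirroring the practice of reconstructing backbone
phylogenies from non-admixed populations only.

## The simulator: what it emulates, what it does not

`simulate_scenario()` draws pool allele frequencies from the
Balding–Nichols construction — ancestral $p_0 \sim U(0.05, 0.95)$ per
site, pool frequency $p \sim \mathrm{Beta}(p_0(1-F)/F,\,
(1-p_0)(1-F)/F)$ — and genotypes as
$\mathrm{Binomial}(2, \sum_k q_{ik}p_{kj})$. Taxa are pure (one pool)
or admixed with specified $q$; the plastid layer is emitted as
maternal-pool labels per population, with capture events planted by
pointing a taxon's maternal pool away from its dominant nuclear pool
(in `standard_scenario()`, hybrids carry their minor parent's plastid,
slightly asymmetric 55:45 nuclear mixtures keeping the dominant parent
well-defined). Traits are Normal(taxon mean, SD) per specimen with
fixed qualitative states; pure taxa sit `effect` (default 4)
within-taxon SDs apart, hybrids midway with the major parent's states.

The simulator emulates drift-divergent unlinked SNPs, admixture,
plastid capture and trait effects. It does **not** emulate linkage,
polyploid dosage (the study group is largely polyploid; the package
codes diploid dosages throughout), apomictic clone structure, selection,
isolation by distance, or sequence-level plastome evolution (maternal
pools are emitted as labels, not alignments). Passing tests therefore
show that the estimators and the cascade recover truth under the
model's own assumptions at realistic divergence — not that real
*Cotoneaster* data meet those assumptions.

**Study-condition defaults.** Parameter-recovery checks run at $F=0.2$,
100 samples, 2000 sites (5 seeds); K-selection at $F=0.3$, 3 pools,
24 samples/pool, 1000 sites, grid K=1–6, 10 seeded runs; end-to-end
recovery across 20 seeded scenarios of 3–6 pools, 0–3 hybrids, $F=0.2$,
1200 sites, 10 specimens/taxon, trait effect 4 SD. These sizes make the
whole suite run in minutes on one core while keeping every effect the
checks measure (divergence, admixture, capture, trait gaps) far from
their detection limits.

## The study fixture

`paper_fixture()` encodes the published verbal evidence for 29 taxa
(27 species + 2 infraspecific) across 43 populations: per-taxon K=9
pool compositions, the K=19 assignment table (five shared pools, seven
novel split-off pools, five still-admixed species), per-population
nuclear (NA/NB/NC) and plastid (PA/PB/PC) clades, per-taxon stem
supports, and the hybrid-free rebuilt clade structure over the 20
retained populations. Ancestry magnitudes are stand-ins constrained by
the published inequalities (pure > 0.95, the subthreshold case in
(0.70, 0.95), admixed dominant < 0.70): `fixture_summary()` counts must
be — and are tested to be — invariant to ±0.02 jitter within those
bounds. Population counts per species are mostly unpublished; the
fixture allocates them so that every printed total holds (8+17+18
populations by nuclear clade, 18 discordant populations over 16
species, 20 retained populations). Where the source text is internally
inconsistent (two gene-pool labels swapped between sections; one taxon
listed both as still-admixed and as founding a novel pool), the fixture
follows the discussion-section convention and carries an explicit
novelty flag per K=19 pool, and the encoder's numbers are chosen so
every published count is reproduced by computation, not assignment.

## Numerical choices

* Pool frequencies are clipped to $[10^{-6}, 1-10^{-6}]$ and mixture
  dosage probabilities to $[10^{-12}, 1-10^{-12}]$ before logs.
* LD pruning slides 50-SNP windows in 10-SNP steps over the retained
  site list and repeats sweeps until no window holds a pair with
  $r^2 > 0.1$, so the constraint is directly assertable on the output;
  ties at the maximal $r^2$ drop the largest later index
  (deterministic). $r^2$ is composite LD on dosages, monomorphic sites
  scoring 0. This is one defensible reading of greedy pairwise
  pruning; the exact visit order of the original tool is not published.
* Genotype PCA centers at $2p$ and scales by $\sqrt{2p(1-p)}$,
  mean-imputes missing dosages after centering, and drops monomorphic
  sites (zero information under that scaling).
* Boundary conventions are inclusive exactly as stated: MAF ≥ 0.05,
  MAC ≥ 3, missingness ≤ 0.15, purity ≥ 0.95, supports ≥ 80/95.
* All randomness is seeded; a master seed fans out per stage through
  `stage_seed()` (stable string hash), so stages are individually
  reproducible and independent.

## Known limitations

Diploid dosage coding for polyploid organisms; no linked-site or
haplotype-aware ancestry model; NJ+bootstrap stands in for ML tree
inference, with bootstrap percentages in both support slots; trait PCA
on integer-coded qualitative states inherits that coding's crudeness;
the synonym-seniority rule is configuration, not inference. These are
scope boundaries, not accidents: the package's contribution is the
decision framework and its evidence calculus, with every upstream step
implemented at the fidelity the framework needs.
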