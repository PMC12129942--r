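# cotodelim

Integrative species delimitation for hybrid-rich plant complexes, built
around the *Cotoneaster buxifolius* complex (Rosaceae, tribe Maleae) — a
group in which polyploidy, apomixis and recurrent hybridization blur
species boundaries so badly that no single line of evidence settles them.
The package re-implements, as reusable tested code, a delimitation
framework that weighs four lines of evidence per taxon:

1. **Gene-pool purity.** Ancestry coefficients under the standard
   admixture model: for sample *i*, pool *k*, site *j*, with ancestry
   fractions *q<sub>ik</sub>* (rows summing to 1) and pool allele
   frequencies *p<sub>kj</sub>*, the dosage likelihood is

   L = Σ<sub>ij</sub> [ g<sub>ij</sub> log f<sub>ij</sub> + (2 −
   g<sub>ij</sub>) log(1 − f<sub>ij</sub>) ],  f<sub>ij</sub> =
   Σ<sub>k</sub> q<sub>ik</sub> p<sub>kj</sub>,

   maximized by EM (`em_admixture()`), with K chosen by masked
   cross-validation (`choose_k_cv()`). A taxon whose mean ancestry
   concentrates ≥ 95% in one pool is *pure*; 70–95% is a *subthreshold*
   window where strong phylogenetic and morphological evidence may still
   validate it; anything lower is *admixed* (`classify_purity()`).
2. **Nuclear monophyly** at SH-aLRT ≥ 80% and UFboot ≥ 95%, in the
   bipartition (unrooted) sense, with absent supports failing closed
   (`assess_monophyly()`).
3. **Morphological diagnosability**: at least two discontinuous traits —
   disjoint observed intervals (quantitative) or disjoint state sets
   (qualitative) — against each comparison taxon
   (`count_diagnostic_traits()`, on Gower/UPGMA morphometrics).
4. **Cytonuclear concordance**: nuclear and plastid backbone clades are
   matched by the agreement-maximizing label assignment, and populations
   whose plastid clade departs from that correspondence are flagged
   (`detect_cytonuclear_discordance()`), the classic signature of
   hybridization and plastid capture.

`run_delimitation()` combines these through an ordered rule cascade:
pure + supported monophyly + diagnosable → **VALID**; shared pool without
diagnostic traits → **SYNONYM_CANDIDATE** (junior name); subthreshold
purity rescued by monophyly and diagnosability → **VALID_BY_OVERRIDE**;
admixed + cytonuclear discordance + intermediate/non-monophyletic →
**HYBRID**; otherwise **UNRESOLVED**. `rebuild_without_hybrids()` then
re-estimates the backbone phylogeny from the non-admixed populations
only.

Upstream of the cascade the package reproduces the standard population
genomic plumbing: VCF/dosage input, site filtering (missingness ≤ 15%,
MAC ≥ 3, MAF ≥ 5%), PLINK-style sliding-window LD pruning (50-SNP
windows, 10-SNP steps, r² > 0.1), and dosage PCA. A Balding–Nichols
scenario simulator (`simulate_scenario()`) generates data with known
truth, and `paper_fixture()` encodes the study's published per-taxon
evidence (29 taxa, 43 populations) for end-to-end checks.

## Worked example

Simulate three divergent gene pools (F = 0.2) plus one planted hybrid
(55:45 mixture carrying its minor parent's plastid), estimate ancestry,
build a bootstrap population tree, and run the cascade:

```r
library(cotodelim)

sim <- simulate_scenario(standard_scenario(n_pools = 3, n_hybrids = 1,
                                           F = 0.2, sites = 1500,
                                           seed = 11))
fit  <- em_admixture(sim$genotypes, K = 3, seed = stage_seed(11, "em"))
tree <- bootstrap_supports(sim$genotypes, n_reps = 100,
                           seed = stage_seed(11, "boot"),
                           groups = setNames(sim$map$population,
                                             sim$map$sample))
report <- run_delimitation(fit$Q, sim$map, tree, sim$plastid, sim$traits)
for (r in report$records) print(r)
print(report)
```

```
<delimitation_record> taxon_P1 [species]: VALID (purity PURE q*=1.00)
<delimitation_record> taxon_P2 [species]: VALID (purity PURE q*=0.99)
<delimitation_record> taxon_P3 [species]: VALID (purity PURE q*=1.00)
<delimitation_record> taxon_H1 [species]: HYBRID (purity ADMIXED q*=0.54)
<delimitation_report> 3 valid, 1 hybrid, 0 synonym candidates, 0 unresolved species; 3 gene pools
```

The three pure taxa are validated (each is a supported clade drawing
> 95% ancestry from its own pool); the planted hybrid is admixed
(q* = 0.54), its maternal plastid clade conflicts with its dominant
nuclear pool, its traits are intermediate, and the cascade calls it
HYBRID.

The fixture encoding the published per-taxon evidence reproduces the
study's headline counts from the package's own classifiers:

```r
str(fixture_summary(paper_fixture()))
#> $ pure_species           : int 14
#> $ admixed_species        : int 13
#> $ gene_pools             : int 9
#> $ discordant_populations : int 18
#> $ discordant_species     : int 16
#> $ persistent_discordances: int 3
#> $ k19_shared_pairs       : int 5
#> $ k19_still_admixed      : int 5
#> $ k19_novel_pools        : int 7
```

## Analysis workflow

Numbered drivers under `analysis/` run the whole pipeline on a synthetic
scenario and on the fixture, writing tables under `results/`:

| script | step |
|---|---|
| `01_simulate.R` | generate the reference scenario (4 pools, 2 hybrids) |
| `02_genotype_filtering.R` | site filters, LD pruning, genotype PCA |
| `03_morphometrics.R` | Gower distances, UPGMA, trait PCA, diagnosability |
| `04_ancestry.R` | CV over K, EM ancestry, purity calls |
| `05_phylogeny.R` | bootstrap tree, monophyly, cytonuclear discordance |
| `06_delimitation.R` | decision cascade + hybrid-free rebuild |
| `07_paper_fixture.R` | fixture encoding and summary counts |

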