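---
title: "Mapping the plasma N-glycome onto the circulating proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the plasma N-glycome onto the circulating proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoproteomap)
```

## The problem

Most blood-circulating proteins are N-glycosylated, and the released total
plasma N-glycome — measured by HILIC-UPLC as 36 chromatographic peaks
(GP1–GP36), each expressed as percent of the total integrated area — is a
mixture of the glycoform repertoires of all plasma glycoproteins. If a
protein is a major source of a glycan structure, or an enzyme in its
biosynthesis, the protein's plasma level and that structure's share of the
glycome co-vary across individuals. `glycoproteomap` implements the
statistical machinery to detect and replicate such protein–glycan
associations: trait derivation from peak percentages, rank-based
inverse-normal scaling, an all-pairs Pearson discovery scan under Bonferroni
control, and sign-consistent nominal replication in an independent cohort.

Four mechanisms can underlie an observed correlation: the protein carries
the glycan (source), the protein synthesizes it (enzyme), the glycan
regulates the protein's abundance, or both respond to a shared confounder.
The package's synthetic generator implements the first two as plantable,
recoverable links; the latter two are outside its default model.

## Glycan structures and the trait catalog

Oxford-notation labels are parsed into structural feature records
(`parse_structure()`): family (complex vs high-mannose), antenna count `Ax`,
core fucose (leading `F`, α1–6 on the inner GlcNAc), antennary fucoses
(`F<d>` after the antenna count), bisecting GlcNAc `B`, galactose count `Gx`
(with the arm annotated as in `A2(6)BG1` when a single galactose sits on the
α1–6 arm), and sialic acids `S(…)x` with per-residue α2–3/α2–6 linkages.
Linkage isomers that co-elute are often printed without a linkage list
(`S1`); the parser stores these as *unspecified*, and they match only
linkage-agnostic predicates. Hybrid structures are not representable: the
shipped 36-peak table contains none, and the grammar rejects unknown tokens
loudly rather than mis-parsing them.

Each chromatographic peak may contain several co-eluting structures
(e.g. GP29 = `A3F1G3S(3,3,3)3 + A3F1G3S(3,3,6)3`). Trait membership of a
peak is decided by its **dominant** (first-listed) structure — a
deterministic rule recorded in the annotation table, which is shipped as
plain TSV configuration (`inst/extdata/peak_annotations.tsv`) precisely so
an alternative assignment can be swapped in. The exact published peak
assignment for this peak layout is not redistributable here; the shipped
table is a curated, structure-coherent assignment that places every
individually reported peak at its reported position and is labelled as such.

The catalog (`builtin_catalog()`) derives 113 traits:

* **36 primary traits** (PGP1–PGP36): each peak's percent of total area.
* **Sub-fraction and ratio traits of the core-fucosylated families**
  (PGP37–PGP57), e.g. the mono-sialylation of core-fucosylated
  digalactosylated structures with and without bisecting GlcNAc.
* **The neutral subprofile** (PGP58–PGP75): percentages within "total
  neutral plasma glycans" (GPn) — all peaks whose dominant structure carries
  no sialic acid, including the high-mannose peaks — plus derived neutral
  sub-fractions such as the fucosylation of digalactosylated neutral
  structures.
* **Global composition groups and ratios** (PGP76–PGP113): sialylation and
  galactosylation degrees, branching, core/antennary fucosylation, bisecting
  GlcNAc, and ratios such as trisialylated vs tetrasialylated
  tetragalactosylated structures.

Only part of the 77 derived traits are individually named in published
plasma glycome–proteome work; the rest follow the conventional derived-trait
scheme, and each shipped trait records its provenance (`reported` vs
`scheme`). The 36/77/113 counts and the primary/ratio structural invariants
are enforced by `validate_catalog()`. Ratio traits reference two non-ratio
catalog traits; the catalog is evaluated in two passes (non-ratio traits,
then ratios), which keeps the dependency graph trivially acyclic while
allowing a ratio to cite components defined later in the catalog order.

Numerically, all percent traits live on the 0–100 scale and ratios are
dimensionless. A zero denominator (e.g. no tetrasialylated mass in a
profile) yields a missing value, never an infinity: samples with undefined
traits are dropped pairwise downstream. Because every trait is a function of
the composition only, the whole trait vector is invariant to rescaling of
the raw areas — a property the test suite checks explicitly, alongside an
exact partition identity (the sialylation-degree groups sum to 100) and a
brute-force oracle that re-derives every trait value independently of the
catalog engine.

## Scaling and the discovery–replication scan

Both omics layers are scaled per feature by the rank-based inverse-normal
transform with the Blom offset, mapping rank *r* of *n* to
Φ⁻¹((r − 3/8)/(n + 1/4)). The offset is a parameter; Blom is the common
convention in omics association work, and the choice is immaterial for the
scan since any offset preserves ranks. Ties get average ranks (aptamer
fluorescence units and rounded percentages can tie); constant features are
excluded and reported. Scaling is applied **per cohort**, matching the
independence of the discovery and replication stages. No covariate
adjustment is applied by default — inter-individual diversity is the signal
being probed — though the scaled matrices can be residualized externally
before the scan if desired.

The scan computes, for every protein–glycan pair, the Pearson correlation
over pairwise-complete samples and a two-sided p-value via
t = r·√(n−2)/√(1−r²) on n−2 degrees of freedom. A pair is **discovered**
when p < α/(n_proteins × n_glycans) (strict, α = 0.05 by default: for 1116
proteins × 113 traits, 3.96 × 10⁻⁷), and subsequently **replicated** when
the replication cohort gives p < 0.05 (strict) with the same sign;
significant-but-opposite pairs are flagged **conflicting**, everything else
**not_replicated**. An exactly zero replication correlation has no sign and
cannot replicate. Replication is intentionally nominal — the small
replication cohort cannot carry a Bonferroni cut; false positives are
controlled by the discovery threshold, and the conflicting count serves as
the empirical check on that logic. The replicated pairs are arranged into a
glycan × protein matrix with signed r² entries (sign of the discovery
correlation times its squared value), restricted to rows and columns with
at least one replicated pair. `consistency_report()` tabulates per-pair
effect sizes across cohorts and their sign concordance, and the same
machinery runs with the cohorts' roles swapped (replication-as-discovery)
for reverse-direction checks.

Twin or family relatedness in a replication cohort is not modelled; with
nominal replication on ~46 individuals the impact is limited, but the
p-values there should be read as descriptive.

## The synthetic cohort generator

No real cohort data are distributed, so the generator is the package's
test bed. It implements the mixture model stated above: protein *i* has a
fixed glycoform profile φᵢ on the 36-peak simplex (Dirichlet-drawn,
concentrated on one structure-coherent block — neutral complex,
high-mannose, mono-/di-/tri-/tetra-sialylated — so derived traits inherit
realistic block correlation); sample abundances are log-normal; the raw
glycome is Σᵢ aᵢφᵢ over assayed plus unassayed background proteins; enzyme
links multiply designated peak fractions by aᵢ^γ before renormalization;
each peak receives multiplicative log-normal noise (CV 10% by default); the
emitted peak table is the row-normalized percent composition; and the
protein readout is log-abundance plus Gaussian noise (sd 0.2), a monotone
noisy stand-in for aptamer fluorescence — no saturation is modelled, since
inverse-normal scaling destroys the scale anyway. Discovery (n = 344) and
replication (n = 46) cohorts are drawn from identical parameters with
independent sub-seeds; every run is bit-reproducible from the config seed.

A planted **source** link concentrates the linked protein's profile on its
target peaks (85% of its mass by default) and gives it an elevated
abundance spread. The default link parameters (`abundance_sd = 0.28`,
`mean_log = -0.5`) were calibrated once, by large-sample simulation, so that
the population correlation between the readout and the target peak's primary
trait is ≈ 0.5 on the inverse-normal scale — the middle of the effect-size
range the replication design is powered for (at n = 46 and |r| = 0.5,
nominal replication power is ≈ 0.94 by the Fisher-z approximation). The
`shared_profile` switch makes all profiles identical, removing every
protein-specific glycan signal: the fully null configuration used for
family-wise error studies. `expected_signatures()` propagates planted peaks
through the catalog to expected association signs: positive for traits whose
numerator contains a planted peak, negative for large disjoint composition
groups (compositional complements above a configurable share threshold,
5% by default — smaller complements give effects too weak to call at these
sample sizes), and, only when the link touches neutral peaks, for disjoint
within-neutral traits. Note that mass planted on sialylated peaks cancels
out of the GPn traits entirely — within-neutral percentages are unaffected
by changes outside the neutral subcomposition — so a negative GPn signature
requires a link that feeds the neutral subprofile itself.

What the generator does *not* emulate: chromatographic noise shapes and
integration artefacts, cohort demographics and confounding (age, sex,
disease), assay saturation, and kinship. Passing recovery tests therefore
demonstrate the statistical machinery under the stated mixture model, not
robustness to those real-data features.

## Problem sizes and numerical checks

The package's standard verification runs use: 200 null simulations
(50 proteins × 113 traits, n = 344) for family-wise error, 100 planted-link
simulations (20 assayed + 10 background proteins, n = 344/46) for recovery,
1000 random profiles against the brute-force trait oracle, and 100 small
vectors against permutation p-values (10⁴ permutations each). Tolerances:
trait values match the oracle to 1e-9 relative; the analytic p matches the
permutation p within four Monte-Carlo standard errors plus the small-n
discrepancy between the t reference and the permutation null; the null
family-wise error stays below the binomial 95% band around 5%; recovery of
the planted link is required in ≥ 80% of runs with the planted sign in every
replicated call.

## Limitations

* The shipped peak annotation and the unreported part of the derived-trait
  catalog are conventional reconstructions, not the original laboratory
  assignment; both are configuration files a user can replace.
* Headline counts from published real-cohort analyses depend on non-public
  data and are not reproduced; the pipeline reports the analogous counts for
  synthetic runs in its summary.
* Associations are marginal Pearson correlations; no causal direction is
  implied, and confounder-driven correlations are indistinguishable from
  source/enzyme links without external information.
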