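---
title: "Quantifying mutation-spectrum evolution across a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutation-spectrum evolution across a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spectratree)
```

## The problem

The germline mutation spectrum — the relative abundance of the six
strand-collapsed single-base substitution classes, optionally expanded by
flanking sequence context into 96 (3-mer), 1,536 (5-mer), or 24,576 (7-mer)
k-mer mutation types — is not fixed across species. `spectratree`
implements a pipeline for asking, with polymorphism data from many species
and a species tree, whether mutation spectra evolve along the phylogeny:
whether closely related species accumulate mutations in more similar
sequence contexts than distant ones, whether extended context (5-mer,
7-mer) carries signal beyond the nested shorter context, which individual
motifs are hypermutable relative to their central substitution class, and
how well fixed mutational-signature models (clock-like somatic signatures,
reproductive-aging signatures derived from parental-age regressions)
reconstruct the observed variation.

Because the analysis compares counts across genomes that differ in size,
k-mer composition, diversity, and data quality, most of the machinery is
normalisation and careful null construction rather than the final
correlation.

## The type system

All spectra are indexed by a `spectrum_schema`: an odd context size `k`,
a CpG policy, and a folding flag.

* Strand collapsing maps every mutation onto the representative whose
  central ancestral base is A or C, so `GTT` with a central T>A mutation is
  recorded as `AAC>ATC`.
* Types are ordered by central substitution (A>C, A>G, A>T, C>A, C>G, C>T)
  and then lexicographically by ancestral k-mer. At `k = 3` this matches
  the COSMIC 96-type ordering, so external signature tables align by label.
* CpG transitions (central C>T with a 3' G) can be kept merged, split into
  their own class (`"CpG>TpG"` in the 7-class 1-mer schema), or excluded.
  The classifier always reads at least a 3-mer window so CpG status is
  known even for 1-mer spectra.
* Folding merges each type X>Y with the strand-collapsed form of Y>X,
  removing dependence on ancestral-allele polarization. The folded class is
  labelled by whichever member comes first in the canonical ordering — the
  convention is arbitrary but deterministic and documented; the six 1-mer
  types collapse to four folded classes.

## From VCF to spectra

`classify_variants()` consumes a biallelic-SNP VCF, an ancestral genome
FASTA, and accessible regions (`accessible_regions()` subtracts exclusion
BED masks — low-complexity, repeats, CpG islands, selected regions — from
the chromosome). Key contracts:

* The derived allele is the VCF allele that differs from the ancestral
  genome's base; sites whose ancestral base matches neither REF nor ALT are
  dropped rather than flipped (probabilistic polarization is upstream of
  this package).
* Context is read from the ancestral genome, so the ancestral k-mer is the
  one whose genomic target count normalises the rate.
* A variant shared by several individuals is assigned uniformly at random
  (seeded) to one carrier, so each SNP contributes exactly once.
* Any variant whose context window touches a masked base or an N is
  excluded. The same full-window rule is used by `count_targets()`, so
  numerators and denominators of context-specific rates see the same
  genome. (Whether windows merely *overlapping* masked bases should count
  was genuinely open; using one rule for both sides keeps rates coherent.)

`count_targets()` tabulates, for every strand-collapsed ancestral k-mer,
the number of accessible N-free windows — the target counts `t_m` with
total `T`.

## Normalisation and compositional geometry

Counts are made comparable across species in a fixed order, recorded in
each table's provenance and enforced by the functions themselves:

1. **Rescale** (`rescale_counts()`): `x_r = x * (t_ref/T_ref) / (t_A/T_A)`
   — the count expected if the focal genome had the reference genome's
   k-mer composition at unchanged per-target rates. Rescaled counts stay
   real-valued; nothing downstream needs integers until downsampling.
2. **Downsample** (`downsample_multinomial()`): one multinomial draw per
   genome, by default to the minimum row total, so spectral resolution is
   not confounded with diversity.
3. **Pseudocount** (`add_pseudocount()`, default `c = 1` in every cell of
   every genome): the centred log-ratio is undefined at zero. The
   pseudocount is applied unconditionally, not only to rows containing
   zeros, so all genomes get the identical treatment.
4. **CLR** (`clr()`): `log(p_i) - mean(log p)`. Distances between CLR rows
   (`aitchison_distance_matrix()`) are the compositional (Aitchison)
   distances used everywhere. `ilr()` provides the isometric variant with
   a normalised Helmert-type contrast basis (the basis choice is not
   observable in any distance, which is why the default is simply a
   deterministic orthonormal basis in schema order).

A useful exactness property, verified in the tests to 1e-9: CLR distances
between rescaled spectra do not depend on which reference composition the
counts were rescaled to, because changing the reference multiplies every
genome's counts by one shared positive vector, which CLR turns into a
shared additive offset.

## Phylogenetic signal

* `cophenetic_matrix(tree, sqrt_transform = TRUE)` gives the phylogenetic
  distances. The square root is applied to the *phylogenetic* matrix only:
  under Brownian trait evolution the expected trait distance grows with
  the square root of shared-path distance, so that is the scale on which a
  linear correlation is meaningful.
* `mantel_test()` correlates off-diagonal entries and permutes the labels
  of one matrix, with the bias-corrected estimator
  `p = (1 + b)/(n_perm + 1)`; its floor is `1/(n_perm + 1)` (1e-5 at
  99,999 permutations). The tail defaults to `"greater"` because the
  hypothesis — spectrum distance increases with phylogenetic distance — is
  directional. Pearson correlation on raw off-diagonal entries is used; the
  statistic is invariant to affine rescaling of either matrix, so
  standardising first would change nothing.
* `partial_mantel()` is the phylogenetically aware variant: it correlates
  the residuals of spectrum distance and covariate distance after least
  squares regression on phylogenetic distance, permuting the residual
  matrix labels. When the covariate is fully explained by the phylogeny the
  partial correlation is reported as exactly 0 with a warning.
* `k_mult()` implements the multivariate generalisation of Blomberg's K:
  the ratio of observed to Brownian-expected trait dispersion given the
  tree's tip covariance, normalised so its Brownian expectation is 1;
  significance comes from tip shuffling (default 999 permutations).
* `clr_pca()` (column-centred SVD of CLR rows, dominant loading forced
  positive per component) supports the usual ordination view;
  `scalar_distance_matrix()` and `watterson_theta()` support the
  technical/biological-covariate comparisons.

## Context nesting: signal beyond the (k-2)-mer

A k-mer spectrum inherits phylogenetic signal from its nested (k-2)-mer
spectrum even if the outer bases are irrelevant. `nested_signal_test()`
therefore compares the observed Mantel correlation against control spectra
(`randomize_within_classes()`) in which each genome's counts within every
(k-2)-mer equivalence class are redistributed multinomially according to
the genome's own within-class ancestral-target fractions. This removes any
species-specific dependence on the outer bases while preserving the
(k-2)-mer marginals *exactly*, per genome and per replicate. Controls run
through the identical pseudocount-CLR-distance-correlation chain. The
within-class probabilities use target fractions computed before rescaling
(whether the published analysis randomized before or after rescaling is not
fully specified; here randomization happens at whatever count stage the
caller supplies, and the recommended usage is the same rescaled-and-
downsampled stage the empirical Mantel consumes, so the two pipelines
differ only in the randomization step).

## Motif hypermutability

`fisher_scan()` compares each k-mer type's within-genome rate to its
central 1-mer class rate with a two-sided Fisher's exact test on
`[[x_k, t_k - x_k], [x_b, t_b - x_b]]`, where the background excludes the
focal k-mer from its own class — a type should not be tested against a
background that contains it. The *reported* fold enrichment uses the full
class rate, which is the quantity plotted in enrichment profiles. Raw
counts are required: rescaling or downsampling would distort within-genome
rates for no benefit, since no cross-species comparison is involved.
`cpg_enrichment_threshold()` gives the genome's CpG>TpG enrichment over
the full C>T class rate, and `flag_super_cpg()` keeps
Bonferroni-significant non-CpG types at or above that benchmark.

## Signature models

`fit_exposures()` maximises the multinomial likelihood of each genome's
counts under a fixed linear combination of signatures by EM; the
log-likelihood trace is non-decreasing and checked in tests. (The original
analyses used a Bayesian fitting tool; maximum-likelihood EM with seeded
restarts targets the same likelihood surface with a deterministic
contract. Published wording also describes exposures as maximising cosine
similarity; this package fits the multinomial model and reports cosine
similarity as a diagnostic, which resolves the tension in favour of the
model actually fitted.) `fit_extract_novel()` adds one novel signature
shared across genomes, updated from pooled expected counts in a block EM
with 10 seeded random restarts by default, and reports the novel
signature's cosine similarity to each fixed signature since near-duplicates
are a real failure mode. `build_aging_signatures()` turns per-class
parental-age regression slopes and intercepts into maternal, paternal, and
young-parent (evaluated at puberty, default age 13) signatures over the
six non-CpG 1-mer classes; `strip_cpg()` removes CpG transitions from
spectrum and signatures jointly, renormalising the latter.

## The synthetic-data generator

No real resequencing data ships with or is downloaded by this package.
The generator produces every input the pipeline consumes, with known
truth:

* `simulate_reference_and_ancestral()` — i.i.d. genomes with configurable
  base weights, a substituted reference, and random exclusion masks.
* `evolve_spectra_on_tree()` — per-species mutation-type compositions via
  Brownian motion in CLR space (increments projected to the zero-sum
  subspace; leaves mapped back by softmax, the exact inverse of CLR on
  that subspace), so expected squared Aitchison distance is proportional
  to cophenetic distance by construction.
* `emit_vcf()` — minimal VCFv4.2 records whose sites are placed at genomic
  positions matching each sampled type's ancestral context, with
  derived-allele counts drawn from a 1/i neutral-shaped frequency spectrum
  and at least one carrier per site, plus an exact per-type truth table.
  The end-to-end identity — pipeline spectra equal truth, count for count —
  is asserted in the tests.
* `simulate_signature_mixture()`, `simulate_covariates()`,
  `simulate_target_counts()` — inputs for the signature, confounder, and
  nesting analyses.
* `example_mammal_tree()` — the fixed 13-leaf, 4-clade fixture tree
  (apes, murids on a long stem, carnivores, cetaceans) on a
  substitutions-per-site scale, mirroring the shape of a typical
  mammalian resequencing panel.

What the generator deliberately does **not** emulate: linkage and
coalescent noise, demography, selection and biased gene conversion,
sequencing error, or reference-assembly artefacts. Tests passing on
synthetic data therefore validate the *computations* — type handling,
normalisation algebra, null construction, estimator calibration and power
under the stated models — not the robustness of the biology to those
processes.

## Numerical and design choices

* Tolerances: compositional identities (CLR zero-sum, ILR/CLR distance
  agreement, reference invariance) are asserted at 1e-9; simplex sums at
  1e-9; EM convergence at relative log-likelihood change 1e-10.
* Permutation p-values always use the `(1 + b)/(n + 1)` estimator except
  under exhaustive enumeration, where the exact `b/n!` is reported.
* Degenerate inputs fail loudly: constant distance matrices, all-zero
  spectrum rows, zero-target types with observed counts, non-orthonormal
  ILR bases, singular tip covariances.
* Power properties for the nesting test use an alternative model in which
  the within-class context deviations themselves evolve by CLR-Brownian
  motion on the tree (rate 0.2 per unit branch length, on top of Brownian
  1-mer class compositions at rate 0.5): under that model every species
  pair carries tree-correlated context signal, which is what the test is
  built to detect. Clade-specific rate injections are exercised separately
  as detection cases.
* Problem sizes in the test-suite simulations (genomes of 10-50 kb,
  hundreds of SNPs for identity checks, 10^5-10^6 counts for recovery
  checks, tens to hundreds of replicates for calibration) were chosen as
  the smallest scales at which the asserted statistical properties are
  sharp; every stochastic assertion uses a fixed seed.

## Limitations

* Ancestral-state inference, variant calling and filtering, tree
  inference, and CpG-island/repeat detection are inputs, not features.
* The published "phylogenetically aware Mantel" lives in supplementary
  material not reproduced here; `partial_mantel()` is a standard
  residual-permutation partial Mantel and is documented as this package's
  interpretation.
* Exposure recovery degrades when signatures are nearly collinear (e.g.
  cosine similarity > 0.99); the package reports diagnostics but does not
  attempt identifiability repairs.
* At 7-mer resolution, desk-scale synthetic genomes leave most of the
  24,576 types with tiny target counts; sparse-regime behaviour is real in
  small datasets and should be interpreted with the same caution the
  source analyses apply.
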