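---
title: "Methods: TMT proteomic networks and splice-junction peptides"
author: "tmtsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT proteomic networks and splice-junction peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`tmtsplice` implements the analysis chain of a deep, multiplexed (TMT)
proteomic study of post-mortem brain across control, asymptomatic
Alzheimer's (AsymAD), and Alzheimer's (AD) diagnosis groups, extended with
a proteogenomic layer that quantifies peptides spanning alternative
exon-exon junctions (alt-EEjxn peptides). The pipeline has five analysis
stages — junction-database construction, reporter normalization, cell-type
deconvolution with covariate regression, weighted protein correlation
network analysis (WPCNA), and differential/enrichment statistics — plus a
synthetic-cohort generator that provides complete ground truth for all of
them.

This vignette records the models, the parameter choices and their
rationale, the numerical decisions, and the limits of what the synthetic
benchmarks demonstrate.

# The synthetic cohort: what it emulates

The generator (`gen_tmt_cohort`) reproduces the statistical structure of
an 8-batch, 10-plex TMT experiment with a pooled global internal standard
(GIS) in channel 126 of every batch and 47 samples split 13/14/20 across
control/AsymAD/AD. Its defaults are the study conditions all tests and
benchmarks run under:

* **Intensity model.** Linear-scale reporter intensities are log-normal:
  each feature's log2 intensity is a baseline (mean 14, SD 1.5) plus
  additive planted effects. Effects additive in log2 match the downstream
  log2-ratio analysis exactly.
* **Group effects.** A configurable fraction of features (default 15%)
  carries an AD-vs-control shift drawn from ±[0.5, 1.5] log2 units, with
  AsymAD placed halfway — the intermediate-pathology ordering the design
  assumes.
* **Covariates.** Age is uniform on 70–100 years, post-mortem interval
  (PMI) on 4–20 h, sex is a 0/1 indicator; a fraction of features carries
  slopes on each (age ~0.02 log2/yr scale). These ranges are typical of
  autopsy cohorts of this kind.
* **Module structure.** The leading features form five planted blocks
  (20 features each by default) driven by independent standard-normal
  sample factors with loadings in [0.7, 1.3]; all other features are
  unstructured ("grey").
* **Cell-type mixing.** Forty marker features (ten per cell type:
  microglia, astrocytes, neurons, oligodendroglia) have linear-scale
  abundance equal to a reference profile times the sample's weight vector,
  making digital-sorting-style recovery well-posed by construction.
  Weights are Dirichlet-like draws whose composition shifts with
  diagnosis (more microglia/astrocytes and fewer neurons in AD).
* **Batch structure.** Samples are assigned to batches by randomized
  round-robin within group, so groups stay balanced across batches.
  Feature-by-batch multiplicative effects (log2 SD 0.2 by default) apply
  to samples and GIS alike and therefore cancel exactly in sample/GIS
  ratios — the property the GIS design exists to provide.
* **GIS composition.** The real study pools tissue from multiple cohorts
  for its GIS; its composition relative to the 47 analyzed cases is not
  specified. The simulation models the GIS as the per-feature cohort
  grand mean, which is the idealization that makes "ratio to GIS"
  interpretable as centered log2 abundance. This is an approximation, not
  a claim about the real mixture.
* **PTM splitting and missingness.** A configurable fraction of features
  is emitted as 2–3 modified forms whose linear intensities sum exactly
  to the base signal (testing the summation step), and sample
  measurements are set missing completely at random at the design's
  `missing_rate`.

What the generator does **not** emulate: informative (intensity-dependent)
missingness, co-isolation interference and ratio compression,
chromatographic batch drift, and correlated measurement error. Passing
tests on this cohort therefore demonstrate algorithmic correctness and
statistical calibration under the declared model — not robustness to
every artifact of real TMT data.

# Junction database construction

Junction evidence arrives as per-read records (chromosome, strand, last
exonic base of the 5' exon, first exonic base of the 3' exon, and the
read's exonic overlap on each side). `summarize_junctions` counts a read
as support only when both overlaps are at least 4 nt and keeps junctions
with at least 2 qualifying reads — the support thresholds are read-level
criteria, which is where they belong; peptides are filtered by their own
rule below. `classify_junctions` flags a junction as alternative iff
another junction shares its donor (left) or acceptor (right) end;
singletons and constitutive junctions are excluded from peptide
extraction.

For each alternative junction, `extract_junction_peptides` concatenates up
to `flank_nt = 120` nt of exonic sequence on each side (strand-aware,
truncated at exon boundaries — the flank never runs into intron), then:

* **Reading frame.** When both flanks lie in exons of one annotated gene,
  the annotated CDS frame anchored on the 5' flank is used; otherwise all
  three frames are translated. Translation truncates at the first stop
  codon. The annotated-frame product is always a subset of the 3-frame
  product (a tested invariant), so the 3-frame mode is the conservative
  superset used for oracle comparisons.
* **Digestion.** LysC cleaves C-terminal to every lysine, including K|P
  bonds; because K|P cleavage is incomplete in practice, the digest also
  emits, per K|P site, the form retaining that bond (at most one retained
  bond per peptide by default). Trypsin (cleave after K/R, not before P)
  is provided for cross-method comparison.
* **Spanning rule.** A peptide is a junction peptide only if at least one
  residue is fully encoded on each side of the junction. The 4-nt overlap
  rule is deliberately *not* reused here: one full codon per side is the
  natural amino-acid-level analogue.
* **Length bounds.** 6–50 residues, the range observable by MS.
  `flank_nt = 120` guarantees any 40-residue flank-side segment is
  reachable, so the bound, not the flank, is binding.

`dedupe_and_annotate` removes every copy of a peptide whose exact sequence
arises at two or more genomic loci — quantification cannot attribute a
shared sequence to one locus, so keeping "one representative" would be
wrong — and removes peptides equal to a canonical LysC digest product
(flagged `canonical-duplicate`). Survivors are `novel` and are appended to
the canonical FASTA by `write_search_db` with a documented header grammar.

The whole extraction is checked against an independent brute-force oracle:
enumeration of every substring of every 3-frame translation that satisfies
the digestion-product characterization, the span rule and the length
bounds. Set equality holds on every toy genome tested.

**Coordinates.** All coordinates, internal and external, are 1-based
inclusive — the GFF3 and Bioconductor convention. Keeping one convention
end-to-end removes a conversion layer that would otherwise be a standing
source of off-by-one defects.

# Reporter normalization

Two paths mirror the two data types:

* **Protein path** (`normalize_cohort`): per-batch log2(sample/GIS)
  ratios; entries with |log2 ratio| ≥ log2(100) ≈ 6.64 are excluded as
  extreme outliers (the bound is stored at full precision; the rounded
  6.64 is accepted on input); features with more than 4 of 8 batches
  lacking a usable GIS value, or more than 23 of 47 missing sample
  values, are dropped. The missingness cap generalizes as the largest
  integer strictly below half the sample count.
* **Peptide path** (`normalize_peptides`): modified forms of one base
  peptide are summed on the linear scale (a missing form is unobserved,
  not zero); batches are rescaled so the mean GIS abundance is identical
  across batches; values below 1 are removed (they would go negative in
  log2) and the rest log2-transformed. The input reporter matrices are
  taken as within-batch normalized abundances; equalizing per-channel
  totals upstream of this package is the acquisition software's step, and
  the generator emits data on that scale directly.

No stage imputes: missing stays missing, a tested invariant. On a
noiseless cohort the protein path returns the planted centered log2
abundances to machine precision, and batch GIS means agree to better than
1e-9 relative after scaling.

# Cell-type deconvolution and covariate regression

`estimate_cell_weights` solves, per sample, non-negative least squares of
the marker mixture against a marker-by-cell-type reference profile on the
linear scale, then normalizes weights to sum to one ("digital-sorting
style"). Markers with any missing value are excluded first — weights must
not depend on imputation. Noiseless mixtures are recovered exactly;
at multiplicative noise of SD 0.1 (log2) the mean absolute error across
47 samples is below 0.005.

`bootstrap_regress` fits, per feature, `value ~ age + sex + PMI + group`
on available cases, repeats the fit on 1000 ordinary nonparametric
case-resamples (rank-deficient resamples are redrawn), aggregates
coefficients by their bootstrap mean, and subtracts the nuisance
components evaluated at covariates centered over that feature's observed
cases — so each feature's mean is preserved and the diagnosis-group
component plus residual is retained. Group is always modeled and never
subtracted. Features with fewer observations than model terms + 2 are
left unregressed and flagged rather than forced.

`two_pass_regress` first removes the cell-type weight components, then
age/sex/PMI. The four weights sum to one and are collinear with the
intercept, so three of the four columns enter the model — the same column
space, hence the same removed variance. The fully adjusted matrix serves
differential abundance; the network is built from the covariate-only
regressed matrix, where cell-type covariation is biology the network
should see.

The regression benchmark uses an age-matched cohort (group means of age
equalized), as case-control autopsy series are designed to be; without
matching, the retained group component would re-introduce an age
correlation that no regression retaining group can remove.

# Weighted protein correlation network analysis

The similarity is the biweight midcorrelation (`bicor`): median-centered,
Tukey-biweighted with the standard 9-MAD outlier cutoff, with a
mean-centering (Pearson) fallback for zero-MAD vectors, computed on
pairwise-complete observations (at least 4 pairs).

The signed adjacency is `a = ((1 + bicor)/2)^beta`. The power is chosen
by `pick_beta` as the lowest candidate (steps of 0.5) whose scale-free
fit reaches R² = 0.80; the fit regresses log10 p(k) on log10 k over 10
log-spaced connectivity bins, signed so a power-law (negative) slope is
required. If no candidate reaches the target, the power at the fit
plateau (first step improving by under 0.01) is returned with a message —
the behavior appropriate for cell-type-regressed matrices whose fit
saturates below target. The study default is beta = 8.

Topological overlap uses the mean-connectivity denominator:
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (mean(k_i, k_j) + 1 − a_ij)`.

**Module detection** is a specified simplification of dynamic tree
cutting, with each behavior unit-tested:

1. average-linkage clustering on 1 − TOM, cut *recursively*: each branch
   is cut inside the widest gap of the upper part of its merge-height
   distribution (the region a `deep_split` of 0–4 widens), and every
   resulting branch big enough to hold two modules is cut again. Branch
   joins sit at heterogeneous heights, so a single global cut
   under-splits; recursion separates each branch at its own scale and
   the merge stage re-joins over-splits.
2. clusters below `min_module_size = 17` dissolve to grey;
3. a PAM-like stage reassigns each feature to the module of its highest
   kME when that exceeds its current module's kME (grey features attach
   when their best kME reaches 0.3 — below that, at n = 47, a
   correlation is within noise of zero);
4. modules whose eigenproteins correlate above 1 − 0.07 merge.

Labels are ordered by size (M1 largest; ties broken by first feature id)
and are invariant to feature input order, which is enforced by sorting
features internally before clustering.

**Eigenproteins** are first principal components of the standardized
member submatrix (missing values mean-imputed for the decomposition only
— correlations elsewhere always use pairwise-complete observations),
scaled to unit variance and sign-oriented so mean member correlation is
non-negative. kME is the bicor of a feature with a module eigenprotein.
Module-trait correlations use bicor with a t-based p-value, except MMSE
(a bounded cognitive score where only monotonicity is meaningful), which
uses Spearman.

On the standard benchmark — five planted 40-feature blocks at n = 47 —
detection recovers the partition with adjusted Rand index 1.0 across
seeds, and the merge rule fires exactly when planted eigenprotein
correlation exceeds 1 − 0.07.

# Differential abundance and enrichment

`anova_tukey` is one-way ANOVA per feature with Tukey HSD contrasts via
`stats::aov`/`stats::TukeyHSD`; unequal group sizes (13/14/20) use the
Tukey–Kramer extension automatically. A constant feature gets F = 0,
p = 1 by convention. Under the global null the omnibus F rejects ~5% of
features, and the Tukey-adjusted AsymAD–AD contrast is familywise
controlled — its per-contrast rejection rate stays at or below the
nominal 5% (about 2–3% in practice, since the adjustment spreads the 5%
familywise budget over three contrasts).

`fisher_enrichment` computes the hypergeometric upper tail (one-tailed)
or the sum of outcomes no more probable than observed (two-tailed
overrepresentation, the standard two-sided Fisher exact definition, which
the source material leaves unspecified), with BH correction applied
within the family of tests in one call. One-tailed p-values equal
exhaustive enumeration for all backgrounds up to 60, and both tails match
`stats::fisher.test` (the independent cross-check).

A peptide is **quantifiable** with at least two measurements in at least
two case groups. Peptides are assigned to the module of their highest
kME, with peptides missing more than 25 of 47 values left unassigned to
avoid spurious correlations. Module enrichment for alt-EEjxn peptides is
a per-module one-tailed Fisher test against the background of
module-labeled proteins plus assigned peptides, BH-corrected across
modules. `compare_networks` reports hypergeometric module-overlap
p-values between two labelings on their shared universe.

Two behaviors of the regress-then-test pipeline are worth knowing. First,
marker features genuinely differ by diagnosis group through cell-type
composition alone; they test significant before cell-type adjustment and
drop out after it — the contrast between unadjusted and cell-type-adjusted
differential counts is a feature of the design, exposed by running
`anova_tukey` on either matrix. Second, subtracting fitted nuisance
components slightly deflates within-group residual variance (the usual
two-step overfitting), so post-regression F statistics run marginally
anti-conservative on finite samples; the package reports both matrices
rather than hiding the choice.

# Numerical choices and degenerate inputs

* Outlier bound kept at full precision `log2(100)`; comparisons use ≥.
* `bicor` clamps to [−1, 1] and returns NA below 4 complete pairs;
  zero-denominator cases are NA.
* Rank-deficient bootstrap resamples are redrawn (capped; persistent
  deficiency is an error naming the feature).
* Constant features are an error in network construction (no meaningful
  correlation), a p = 1 convention in ANOVA.
* Eigenprotein sign ties (mean member correlation exactly 0) keep the
  SVD orientation.
* Scale-free fit needs at least 3 populated bins; otherwise NA, and the
  plateau rule governs.
* Module label ties break on the lexicographically smallest member id.

# Problem sizes

The shipped benchmarks are sized for a laptop-class single core: cohorts
of ~240 features x 47 samples, networks of 200–320 features, 1000-feature
null calibrations, 100-feature x 1000-iteration bootstrap regressions,
and 5-gene toy genomes. These sizes are chosen so each property is
measured with comfortable Monte-Carlo margin; all scale linearly (or for
the network, quadratically in features) to study-scale data.

# Known limitations

* The module detector is a specified simplification of dynamic
  tree-cutting; it reproduces the four behaviors it documents (cut,
  dissolve, PAM-like kME reassignment, eigenprotein merge) but is not
  the WGCNA algorithm, and branch-shape-sensitive corner cases will
  differ.
* The DSA-style deconvolution assumes the reference profile and mixture
  share a linear scale; real cross-platform references need calibration
  the package does not attempt.
* The GIS-as-grand-mean idealization makes sample/GIS ratios exactly
  centered; a real pooled standard adds a feature-specific offset that
  cancels in comparisons *across* samples but not in absolute terms.
* Statistical calibration is demonstrated under independent Gaussian
  nulls; correlated features share information and familywise behavior
  on real matrices is correspondingly more conservative.
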