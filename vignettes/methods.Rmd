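---
title: "Reverse virtual screening for PSMA radioligand off-targets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse virtual screening for PSMA radioligand off-targets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmascreen)
```

## The problem

PSMA-targeting radioligands (2-PMPA-like phosphonates and urea-based agents
such as DCFPyL) accumulate strongly in the salivary glands, causing
dose-limiting xerostomia, while PSMA expression in those glands is weak.
One explanation would be an unknown off-target protein binding the ligands.
`psmascreen` implements the in-silico arm of that search as a reverse
virtual screen: instead of screening many ligands against one target, many
candidate proteins are screened against a small set of known ligands, using
a QSAR trained on protein–ligand binding free energies.

## The QSAR model

The response is the free energy of binding ΔG~bind~ in kJ/mol (more
negative = stronger). The predictors are concatenated protein and ligand
descriptors.

**Protein descriptors** (`featurize_proteins()`) cover five sequence-derived
families over the 20-letter alphabet: amino-acid composition (20),
dipeptide composition (400), normalized Moreau-Broto, Moran and Geary
autocorrelation of eight standardized physicochemical scales at lags 1–30
(720), quasi-sequence order (50), and amphiphilic pseudo amino-acid
composition (80) — 1,270 descriptors under the default configuration. The
manifest is fixed by `seqfeat_config()` and hashed, so any two feature
matrices built under one configuration are column-compatible by
construction. Sequences shorter than 30 AA carry too little signal for
composition-of-pairs statistics and are excluded (recorded in a skip log,
never a crash). Published descriptor sets of this kind run to five figures;
we deliberately fix a compact reproducible manifest instead of chasing a
particular dimensionality, because the model consumes principal components,
not raw columns.

Two conventions are worth stating. First, a homopolymer has zero variance
along any property profile, so Moran and Geary autocorrelation (both
variance-normalized) are defined as 0 there; Moreau-Broto needs no
convention (it equals the squared standardized property value). Second,
with the default `max_lag = 30`, a 30-AA sequence has no residue pair at
lag 30; `featurize_proteins()` emits 0 for lags at or beyond the sequence
length so the descriptor width stays fixed, while the standalone kernels
(`compute_autocorrelation()` etc.) reject such calls unless `pad = TRUE`,
which keeps accidental misuse loud.

The physicochemical scales (Kyte-Doolittle hydropathy, Hopp-Woods
hydrophilicity, residue mass, Zamyatnin volume, Grantham polarity,
isoelectric point, net charge, Charton polarizability) ship in
`aa_properties()`, standardized to mean 0 / sd 1 over the 20 residues
before use. The sequence-order distance matrix (`aa_distance_matrix()`)
follows the Schneider-Wrede construction: root-mean-square difference of
standardized hydropathy, hydrophilicity and residue mass. QSO uses weight
0.1 and APAAC 0.05, the conventional defaults of this descriptor
literature.

**Ligand descriptors** (`featurize_ligands()`) are 2D only: OpenBabel
physicochemical estimates (MW, logP, TPSA, molar refractivity, H-bond
donor/acceptor counts), element counts, functional-group counts, ring
counts, and graph-theoretical indices (Wiener, Randić, Zagreb, diameter,
radius, degree spectrum) on the heavy-atom graph — 48 descriptors. All are
functions of the molecular graph, hence invariant to atom-order
permutations of the input SMILES. Descriptors undefined for a molecule are
imputed as 0 so the downstream matrix stays dense. The three bait ligands
(2-PMPA, MUD/DCMC, DCFPyL) are packaged as SMILES resolved from their
chemical names; users can override them.

**Fitting** (`fit_qsar()`): columns are centered and scaled on the training
rows only (constant columns dropped with a message), PCA is fitted on the
training rows only, and a random forest (500 trees, `mtry = ceiling(sqrt(k))`,
no depth limit, seeded) is fitted on the retained component scores. The
default keeps a fixed k = 34 components; a cumulative-variance target
(e.g. 0.708) is available instead. The fitted object stores the
standardizer, loadings, realized variance and seed, so prediction is
deterministic and the leaky path — refitting the standardizer or PCA on
data that includes test rows — is simply not expressible through the API.
Note the realized cumulative variance depends on the data (about 81% on
the synthetic table); a fixed component count is the production choice, the
variance fraction is a diagnostic.

**The split** (`stratified_split()`) is 75/25, stratified on the response in
four equal-count (quantile) bins; quantile rather than equal-width bins
because binding-energy tables are skewed. Each bin contributes
`floor(0.25 * bin_size)` test rows, topped up by largest fractional
remainder (stable bin order on ties) until the test set reaches
`round(0.25 * N)`; within-bin assignment is a seeded shuffle. On a 237-row
table this yields a 178/59 split. Degenerate quantile breaks (mass ties)
merge adjacent bins with a warning.

**Metrics** (`evaluate_metrics()`): RMSE and R² = 1 − SS~res~/SS~tot~ on the
held-out rows; R² is NaN with a warning if the truth is constant. All
energies in this package are kJ/mol throughout (source reports of this
kind of model occasionally mix kcal/kJ labels; we do not).

## Screening, filtering, conservation

`screen_library()` pairs every featurizable library protein with the fixed
screening-ligand vector (2-PMPA by default) and predicts ΔG~bind~. The
candidate set is the top quartile: energies at or below the 25th percentile
of the library, with the percentile computed by linear interpolation
between order statistics (the common statistical default; recorded in the
output's `threshold` attribute). "Top" means most negative. Ties at the
threshold are included; a singleton library is its own candidate with
percentile rank 0.

`apply_salivary_filter()` admits a candidate detected in the salivary
gland (≥ τ~detect~, default 1 in TPM-like units — expression data rarely
define "detected", so the threshold is explicit and configurable) that
satisfies any of: (a) salivary value ≥ 4 × the **maximum** non-salivary
value — maximum rather than mean is the conservative reading of
"compared with other tissues", a mean mode is available; (b) detected in
no other tissue; (c) detected in fewer than a third of all tissues
(salivary included, strict `<`). Exactly 4-fold passes (inclusive ≥).
The filter is idempotent and monotone in the salivary value.

`score_pocket_candidates()` aligns each survivor globally to the FOLH1
reference — Needleman-Wunsch with affine gaps, BLOSUM62, gap open 10,
gap extend 0.5, end gaps penalized, i.e. the defaults of the EMBL-EBI
needle service — and scores identity at 18 pocket positions in four
features: zinc-binding, substrate-binding, structural, and the arginine
patch (R463/R534/R536, which orients the glutamate moiety common to all
PSMA ligands). A gap at a pocket position counts as mismatch. A feature is
conserved when its identity strictly exceeds 60%; "homology" is strict
residue identity by default, with an optional similarity mode (positive
BLOSUM62 score) available. Only five of the 18 canonical positions are
named in the literature source for this pipeline (E424, R463, N519, R534,
R536); the packaged spec fills the remaining 13 with defensible choices
(the canonical zinc ligands and substrate-site residues) and is plain YAML,
so a curated spec can be swapped in. The packaged reference sequence is a
**synthetic stand-in** carrying the expected residues at the canonical
positions — it exists so the default spec is self-consistent and testable,
and it must be replaced with a curated FOLH1 sequence for production use.

`run_pipeline()` composes the stages in the procedure's order
(screen → expression filter → pocket), logs per-stage in/out counts, and
embeds the seed and a configuration hash in the run object.

## The synthetic-data generator

The study-scale inputs (MD-derived energies for 79 proteins × 3 ligands;
a 9,128-protein expression-annotated library) are not reproducible at desk
scale, so `synth_config()` fixes a set of emulation conditions:

* **Proteins**: uniform random sequences, lengths 30–600, 79 by default.
  Uniform composition is the simplest null for descriptor tests; a biased
  mode (residue weights) exists to plant strong-binder compositions.
* **Energies**: ΔG = affine map of five standardized amino-acid-composition
  columns (A, K, D, E, R with coefficients −1, −1, 1, 1, −0.5) plus a
  per-ligand molecular-weight term (weight 0.5) plus Gaussian noise
  (sd 2 kJ/mol), affinely rescaled so the sample median and IQR equal
  −17.935 and 14.62 kJ/mol exactly, then clipped to [−46.085, −1.635]
  (clip count recorded). The signal variance is whatever the envelope
  leaves after the noise — sd ≈ √((IQR/1.349)² − 2²) ≈ 10.6 kJ/mol — so the
  generator has no free strength dial.
* **Expression**: 40 tissues with planted classes — salivary-selective
  (detected only there), 4-fold-enriched (salivary ≥ 4 × every other
  tissue), ubiquitous (detected everywhere, unenriched) and background
  (broadly detected, unenriched). Selective and enriched pass the filter
  by construction; ubiquitous and background fail.

What the generator does **not** emulate: real composition bias and domain
structure of proteins, correlated descriptor noise from docking poses,
dependence of ΔG on the binding pocket rather than global sequence, and
expression measurement noise. Passing tests therefore demonstrate that the
pipeline recovers a planted signal under its stated conditions — not that
the QSAR transfers to laboratory binding data.

## Problem sizes and numerical choices

The test-suite and acceptance workloads run at the study's own scale where
that is desk-feasible (237 pairs, 34 components, 100–120-protein screening
libraries) and at reduced scale where the stated check is combinatorial:
the alignment oracle enumerates **all** global alignments of random
4-letter pairs up to length 8 (a single length-8 pair already visits
~2.7 × 10⁵ alignments), rather than all ~10⁹ such pairs. Quartile selection
is cross-checked against sort-based selection on 1,000 random instances;
descriptor normalization identities are checked to 1e−9 on 500 random
sequences.

Other fixed choices: PCA via `stats::prcomp` on the standardized matrix;
random-forest seeding via `set.seed` immediately before fitting; quantile
type 7 (R's default, linear interpolation) everywhere a percentile is
taken; DP tie-breaking is delegated to the alignment engine and only
scores (which are tie-invariant) are asserted; negative specific uptake is
reported as-is with a noise flag rather than clamped, preserving the
competition-assay arithmetic.

## Known limitations

* Sequence-derived descriptors cannot see post-translational modification,
  expression regulation, or pocket geometry; the model captures global
  sequence resemblance.
* The ligand manifest is 2D-only; conformer- or charge-dependent terms are
  out of scope.
* The packaged pocket reference is synthetic (see above).
* The expression filter is data-source-agnostic (mRNA vs protein atlases)
  and inherits whatever detection semantics the supplied table has.
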