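---
title: "Template-guided CoMFA: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-guided CoMFA: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Comparative molecular field analysis (CoMFA) relates the biological
affinities of a set of aligned small molecules to the interaction fields
they exert on the space around them. For every molecule $i$ and every point
$j$ of a fixed Cartesian lattice, two probe energies are sampled:

* a **steric** Lennard-Jones 6-12 energy,
  $E^{st}_{ij} = \sum_a \varepsilon_{ap}\left[(R_{ap}/r_{aj})^{12} -
  2 (R_{ap}/r_{aj})^{6}\right]$, with $R_{ap} = R^*_a + R^*_p$ and
  $\varepsilon_{ap} = \sqrt{\varepsilon_a \varepsilon_p}$ summed over atoms
  $a$, and
* an **electrostatic** Coulomb energy with distance-dependent dielectric
  $\epsilon(r) = r$,
  $E^{el}_{ij} = 332.0637 \sum_a q_a q_p / r_{aj}^2$ kcal/mol,

where the probe is an sp3 carbon with charge +1 e. The resulting matrix
(molecules x lattice columns, steric block then electrostatic block) is
related to the pAffinity vector $y$ ($-\log_{10}$ molar, higher = more
potent) by partial least squares (PLS), because the columns are far more
numerous than the rows and heavily collinear.

The distinguishing step of *template* CoMFA is how the alignment that
everything else depends on is produced. The inputs are (i) one or more 3D
**templates** whose mutual orientation in one Cartesian frame has already
been decided and (ii) candidate structures known only by their 2D
connectivity. For each candidate:

1. every **anchor bond** of the candidate (acyclic single bonds between
   heavy atoms, in both orientations; all ring bonds as a fallback for pure
   ring systems) is paired with every anchor bond of every template;
2. from each pairing an atom-chain **match** is grown by a breadth-first
   simultaneous walk over the two heavy-atom graphs, producing an injective,
   connectivity-consistent mapping. Compatibility is *topology-only* - any
   heavy element may map onto any heavy element - with same-element pairings
   preferred among simultaneously available neighbours and canonical atom
   ranks fixing the walk order;
3. the best match wins: most matched atoms, then most element-identical
   pairs, then lowest template index, then lowest candidate and template
   anchor position;
4. the template coordinates of all matched atoms are **copied verbatim**
   onto the candidate (even where this strains the candidate's own valence
   geometry - coordinate invariance across the series is the point);
5. remaining heavy atoms are placed by a canonical, purely rule-based
   **topomer-style** completion, and hydrogens are added last.

Because matched atoms of related candidates receive *identical*
coordinates, field variation across the series is confined to lattice
points near genuine structural variation, which is what gives PLS a clean
signal-to-noise ratio.

## Topomer-style completion and the deterministic embedder

The canonical completion used here (and, applied from scratch, the built-in
3D embedder that stands in for an external structure generator) follows
fixed rules with no dependence on input coordinates of unplaced atoms:

* bond lengths are sums of covalent radii, contracted by 0.87/0.78 for
  double/triple bonds; X-H lengths come from a standard table (C-H 1.09 A,
  N-H 1.01 A, O-H 0.96 A);
* bond angles follow hybridisation: 109.47 degrees for sp3, 120 for sp2,
  180 for sp, with hybridisation read off the kekulized bond orders;
* the first torsion at every rotatable acyclic bond is anti-periplanar
  (180 degrees); subsequent branches at an atom fill the remaining ideal
  directions in canonical-rank order, so identical substituents at
  topologically equivalent roots receive identical local geometry;
* ring systems are embedded as planar regular polygons (fused rings share
  edges, the next ring always placed on the far side of the shared edge)
  and attached rigidly, oriented by an attachment torsion of 90 degrees to
  the reference frame of the attachment atom.

Deterministic choices are driven by Morgan-style canonical atom ranks, so
the heavy-atom conformer is a pure function of the attributed graph: two
atom orderings of one molecule embed to identical coordinates. The
`seed` argument of `embed3D()` is recorded in the provenance for interface
stability; the canonical conformer does not vary with it. Planar rings and
single canonical torsions are of course not a conformational model - they
are a reproducible convention, which is exactly what the alignment step
requires.

Partial charges are Gasteiger-Marsili PEOE (6 damped iterations, classical
published parameters, seeded by the formal charges and applied after
explicit-hydrogen expansion); totals are conserved exactly. Neutral
protomers are used throughout: `neutralize()` discharges protonatable and
deprotonatable sites while leaving permanent charges such as quaternary
nitrogen untouched.

## Lattice, fields and pretreatment

`buildRegion()` encloses the training set in its bounding box expanded by
2 A per face and lays a 2 A lattice over it. The lattice is registered to
the absolute frame (every lattice coordinate a multiple of the spacing) so
regions built from different subsets of one alignment share lattice points;
this keeps training, prediction and any externally planted field structure
on one grid. Regions can be trimmed to a sub-box or a maximum point count
(`trimRegion()`), mirroring the manual trimming sometimes needed for very
large tables.

Field conventions, all configurable:

* steric energies are clamped to [0, 30] kcal/mol. The upper cutoff is the
  classical choice; the clamp at zero (discarding the small attractive
  well) keeps the steric block a pure repulsion measure and guarantees the
  documented value range.
* electrostatic energies are clamped to +/-30 kcal/mol and are *not
  evaluated* at points inside the steric envelope (steric at the cutoff);
  those cells are flagged and imputed with the training column mean during
  pretreatment, the classical convention.
* `pretreat()` then drops columns with standard deviation below
  `minSigma = 2` kcal/mol, centres the survivors, and applies
  CoMFA-standard block scaling, which rescales each block so the steric and
  electrostatic blocks carry equal total variance. All bookkeeping
  (imputation means, kept mask, centres, scales) is stored so prediction
  rows are *always* treated with the training parameters, never their own
  (`applyPretreat()`).

## PLS, validation and component choice

`fitPLS()` is single-response NIPALS; scores are mutually orthogonal, fit
metrics are $r^2 = 1 - SS_{res}/SS_{tot}$ and
$s = \sqrt{SS_{res}/(n - \#cp - 1)}$. Leave-one-out cross-validation
(`looCrossvalidate()`) refits per left-out row (the nested structure of
NIPALS components only avoids redundant passes; the semantics equal a
brute-force refit, which the test suite asserts to 1e-8) and reports
$q^2(c) = 1 - PRESS(c)/SS_{tot}$ and $SDEP(c) = \sqrt{PRESS(c)/n}$ for
every component count. The final component count is the *first SDEP
minimum* (ties toward fewer components) - the stopping rule "iteration ends
when the SDEP stops declining" - noting that $q^2$ and SDEP are monotone
transforms of one another, so "SDEP stops declining" and "q^2 stops
increasing" are one condition.

Two conventions deserve emphasis:

* **Pretreatment inside cross-validation.** By default the table is
  pretreated once on the full training set and the folds reuse it - the
  long-standing convention of the commercial implementations. A strict
  mode (`ftRaw =` a raw field table) re-derives imputation, column
  filtering, centring and scaling inside every fold. The strict mode is
  somewhat more honest and somewhat slower; the default keeps the
  conventional semantics and is what the whole-pipeline tests use.
* **Grouped cross-validation.** For very large training sets
  leave-group-out is available (`folds =`), but leave-one-out remains the
  default and is used everywhere in this package's own studies.

Progressive Y-scrambling (`yScramble()`) permutes a fraction $f$ of the
responses within a random subset and repeats the whole analysis; fraction 0
reproduces the unscrambled run exactly, and a real model collapses to
$q^2 \le 0$ at fraction 1.

Prospective performance is summarised by the SE of predictions, the sample
standard deviation of (predicted - actual) over a held-out set; the
uncertainty reduction is null SD - SDEP, where the null SD (the error of
always predicting the mean known affinity) and the molecular-weight
baseline (residual standard error of pAffinity regressed on molecular
weight) are the two negative controls.

## Curation, baselines and classification

Bioactivity tables arrive as (compound, assay, pAffinity) records with
cross-assay duplicates. `pairDuplicates()` tabulates all within-compound
pairs sorted by absolute affinity difference; `filterDiscordant()` drops
every record of any assay that participates in at least `minRepeats = 2`
pairs differing by more than `delta = 2.0` pAffinity units, plus records
lacking a value. Both assay-id and assay-type keying are provided (the two
fields differ in granularity; the default keys on assay id). Train and
prediction sets are split odd/even by 1-based position; remaining
duplicates are resolved per compound by the median.

The structural baseline is a Tanimoto nearest-neighbour predictor over
hashed linear-path fingerprints (paths of 1-7 bonds over the heavy-atom
graph, canonical reading direction, folded into 2048 bits). This is a
behavioural stand-in for commercial 2D fingerprints, not a bit-level
reimplementation of any of them.

Continuous predictions convert to classes by fixed thresholds: active above
4.5, inactive below 3.5, no prediction in between. Contingency summaries
report, per actual class, the predictions attempted and the fraction
correct ("uncertain" predictions count as attempted and false). Template
CoMFA and nearest-neighbour class predictions combine in two ways: OR
(extra true actives found only by template CoMFA, also as a percentage of
the nearest-neighbour method's true actives) and AND (the contingency
restricted to structures where the two methods agree). Model contours
export as stdev*coeff grids - per lattice point, training column SD times
PLS coefficient - written as Gaussian cube files.

## The synthetic-data generator

`makeSeries()` and friends stand in for large public bioactivity downloads.
They emulate:

* congeneric-plus-diverse series: three aromatic scaffold families
  (benzene, pyridine, thiophene) with two substitution slots drawn from a
  20-fragment vocabulary; templates are the dimethyl scaffold parents,
  embedded and centred in a shared frame;
* field-linear activities: `makePlantedGrid()` selects informative steric
  lattice columns (SD >= the pretreatment threshold, so the planted signal
  lives where a model can see it; electrostatic columns are excluded
  because flagged cells are imputed at modelling time and a signal planted
  there would not be exactly representable) and scales random coefficients
  so the planted signal has SD 1.0 pAffinity; `plantActivities()` then adds
  Normal(0, 0.3) measurement noise - 0.3 being the conventional
  within-laboratory repeat SD - around an intercept of 6;
* assay heterogeneity: a configurable fraction (default 0.25) of compounds
  is measured twice, some in a discordant assay shifted by 2.5 pAffinity
  (beyond the 2.0 curation threshold). The construction routes each
  discordant duplicate's base record to a distinct concordant assay so the
  post-filter record count is exactly derivable, which the tests assert;
* decoy mixes: presumed-inactive structures at 10:1 to the actives, built
  from distinct aliphatic scaffold families, assigned pAffinity 2.5
  (below the inactive threshold), with decoy templates added to the
  template set.

Activities are planted on *template-aligned* fields, putting the aligner on
the causal path: if alignment breaks, recovery fails. What passing these
studies shows is that the pipeline recovers a linear field-activity
structure through its own alignment, field and PLS machinery at realistic
noise; what it cannot show is performance on real binding data, whose
activity surface is neither exactly linear in these fields nor free of
activity cliffs, tautomers, or measurement artefacts beyond simple
cross-assay shifts.

Problem sizes used in the package's own studies: the recovery study runs
200 molecules (100 train / 100 predict, 20 seeds), the classification study
20 actives with 200 decoys; these sizes give stable medians while keeping
the full suite quick to run.

## Numerical choices and degenerate inputs

* Energies in kcal/mol, distances in Angstrom, Coulomb constant
  332.0637 kcal A / (mol e^2).
* Molecules with fewer than two heavy atoms cannot be anchored and fail
  alignment explicitly (`status = "failed"`); failed alignments are
  excluded from training and evaluation denominators, with reasons logged.
* Embedding rejects unknown elements and impossible valences with a typed
  `embedFailure` condition; heavy-atom clashes below 0.8 A are rejected.
* Zero-variance responses and over-parameterised component requests are
  errors in `fitPLS()`; constant molecular weight is an error in the MW
  baseline.
* Matching ties are resolved by a total deterministic order; repeated runs
  of the whole pipeline with one seed are byte-identical, which the
  acceptance tests assert on serialized model archives.
* Model archives are full-precision JSON; two identical fits produce
  byte-identical files, and numeric round-trip is exact to the last one or
  two ulps (decimal I/O), asserted at 1e-14.

## Known limitations

* The embedder's planar rings and single canonical conformer are a
  convention, not conformational analysis; molecules whose alignment
  depends on ring pucker or specific rotamers are out of scope.
* Stereochemistry is ignored throughout (2D connectivity drives matching),
  as is tautomer enumeration; protonation handling is limited to the
  neutralisation rules above.
* Topology-only matching can produce chemically counter-intuitive overlays
  by design; that is a property of the method, not a bug, but it means
  individual alignments should not be over-interpreted.
* The fingerprint is a stand-in: no bit-level compatibility with any
  commercial fingerprint is claimed.
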