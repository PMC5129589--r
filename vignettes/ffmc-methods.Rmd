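---
title: "Forcefield transformation and simulation analytics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forcefield transformation and simulation analytics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffmc)
```

## The forcefield transformation

An additive protein forcefield of the AMBER family is a sum of bond,
angle, torsion and nonbonded terms,

$$E = \sum k_b (b - b_0)^2 + \sum k_\theta (\theta - \theta_0)^2 +
\sum k_\phi [\cos(n\phi + \delta) + 1] +
\sum \left( A_{ij} r_{ij}^{-12} - B_{ij} r_{ij}^{-6} +
C q_i q_j r_{ij}^{-1} \right),$$

where 1--4 van der Waals and electrostatic interactions across a torsion
are divided by the SCNB and SCEE scaling factors.  The package's `ffgen`
layer rewrites an FF99-style parameter set into a fast-sampling variant
through four modifications, each implemented as a pure function on the
parsed `FFParamSet`:

1. **C--H bond shortening.**  Equilibrium lengths of aliphatic C--H bonds
   are set to 0.98 Å and aromatic C--H bonds to 0.93 Å, the values
   observed in sub-ångström cryogenic protein structures.  Shorter C--H
   bonds reduce the exaggerated short-range repulsion of the 6--12
   potential with a nonpolarizable charge model.
2. **Zeroing nonperipheral-sp³ torsions.**  Every torsion whose central
   atoms (positions j, k of the quartet i--j--k--l) include an sp³ type
   has its barrier height set to zero.  The record is retained with
   `kphi = 0` rather than deleted, so topology builders never encounter a
   missing parameter; consequently the transformation never changes the
   record count.
3. **Reduced φ/ψ 1--4 scaling.**  Backbone φ and ψ torsion terms receive
   SCNB 1.00 (scaling removed) and SCEE 1.18; all other torsions keep the
   divisors stored in the file (2.00/1.20 in standard files).  Per-term
   `SCEE=`/`SCNB=` divisors are always written in the modern column
   syntax; a legacy global-scaling encoding cannot express φ/ψ-specific
   factors and is therefore not emitted.
4. **Uniform mass reduction.**  With `massScale = 0.1` every atom-type
   mass is multiplied by 0.1 (hydrogen: 1.008 → 0.1008 Da), solvent
   included.  With `massScale = 1` the output is the standard-mass
   variant and masses are untouched.

Dimensional analysis links mass scaling to timestep scaling: holding the
units of length and energy fixed, scaling all masses by $s$ rescales time
by $\sqrt{s}$, so a low-mass simulation integrated at $\Delta t$ of
standard-mass time behaves like a standard-mass simulation at
$\Delta t/\sqrt{s}$.  `equivalentTimestep(1.00, 0.1)` returns 3.16 fs.

**Type-classification tables are configuration, not chemistry inferred
from the file.**  The source conventions name no explicit type lists for
"sp³", "aliphatic C--H" or "aromatic C--H", so
`defaultTransformRules()` ships an editable inference based on FF99
conventions: sp³ central types `{CT, 3C, 2C, C8, N3, S, SH, OH, OS, CX}`
(sulfur included so that disulfide C--S--S--C torsions are zeroed, which
the documented flipping behaviour of the disulfide implies), aliphatic
hydrogens `{HC, H1, H2, H3, HP}` on `CT`-family carbons, aromatic
hydrogens `{HA, H4, H5}` on aromatic carbons, and φ/ψ quartets
`(C,N,CT,C)`/`(N,CT,C,N)` with `CX` variants.  Users with other type
sets pass their own matrices.

## Survival-analysis folding kinetics

A folding event is the first saved time at which the CαβRMSD series
reaches the native cutoff; the cutoff defaults to 1.96 Å (inclusive, so a
value exactly at the cutoff counts as folded) because that is the
separation between genuinely native and native-like β-hairpin
conformations.  Simulations that never reach the cutoff are
right-censored at their last saved time.

* **Kaplan--Meier mean** (`kmFoldingTime`): the restricted mean of the KM
  curve integrated to the largest observed time — the convention of the
  R `survival` package, which also supplies the Greenwood standard error.
  The 95% CI applies ±1.96 SE on the log scale, keeping the interval
  positive.  With no censoring the restricted mean equals the sample
  mean exactly, which the tests assert.
* **Parametric mean** (`parametricFoldingTime`): exponential (default,
  consistent with two-state kinetics) or Weibull maximum likelihood with
  right censoring via `survival::survreg`.  The exponential mean is
  total time / events; the Weibull mean is
  `scale · Γ(1 + 1/shape)` with a delta-method CI on the log scale.
  Fits are refused unless **more than half** of the simulations folded:
  with fewer events the CI becomes uninformatively wide, and the refusal
  is itself the documented signal.
* **Agreement** (`kmParametricAgreement`): the fraction of event-time
  grid points where the parametric curve lies inside the KM 95%
  pointwise band.  No published threshold defines "mostly"; the default
  0.5 is an explicit, configurable choice.
* **Two-state diagnostic** (`twoStateCheck`): OLS of
  `ln`(nonnative fraction remaining just after each event) against event
  time.  Single-exponential kinetics yields a straight line whose slope
  is minus the folding rate.

The SE of an aggregated population (and of helicities, S², B-factors) is
SD/√n over simulations, the standard estimator for a mean of independent
replicates.

## Helicity

A residue is α-helical in a frame when it belongs to a run of ≥ 4
consecutive residues whose φ and ψ are both within 20° (wrapped circular
difference — the convention here; the source is silent on wrap-around) of
(−57°, −47°).  Windows may extend through eligible residues outside the
scored set, but only scored residues (default 1–15; capping groups lack
full φ/ψ and are never scored) enter the average.  The complementary
RMSD route counts conformations within the native cutoff of the
full-helix reference.  On trajectories with frayed termini the torsion
route exceeds the RMSD route by construction: frayed ends inflate the
global RMSD past the cutoff while interior residues remain
torsion-helical.

## NMR and crystallographic observables

* **J-couplings.**  The generic Karplus form
  $J(\theta) = c_2\cos^2(\theta+\Delta) + c_1\cos(\theta+\Delta) + c_0 +
  s_1\sin(\theta+\Delta)$ covers the standard relations; Δ encodes the
  offset between the backbone torsion and the coupling dihedral
  (θ = φ − 60° for ³J(HN,Hα)).  Coefficients are configuration data
  (`inst/extdata/karplus_sets.json` ships the standard literature
  ³J(HN,Hα) sets); coupling ids without configured coefficients fail
  loudly rather than defaulting.  Couplings are averaged over frames
  (mean of J, never J of the mean angle).  The comparison statistic is
  the *mean* square deviation, `chi2 = (1/n) Σ ((J_calc − J_exp)/σ)²`
  (1/n, matching the "mean square deviation" naming; per-residue σ is
  required with no default), alongside the unweighted RMSD.
* **iRED order parameters.**  `iredS2` builds the M×M matrix
  $C_{ij} = \langle P_2(\hat\mu_i\cdot\hat\mu_j)\rangle$ over frames,
  eigendecomposes it, and excludes the 5 largest modes as global
  reorientation (the iRED convention; configurable).  By completeness of
  the eigenbasis, $S^2_i = 1 - \sum_{\text{internal}} \lambda_m e_{mi}^2$
  exactly.  Ties among eigenvalues are broken by the deterministic
  descending order of `eigen`.  Values are clamped to [0, 1] with the
  clamped indices recorded.  For finite M the excluded-mode construction
  carries a known bias of order $(1-S^2)\cdot 5/M$ (the five global modes
  absorb a share of internal fluctuation), which the validation keeps
  below the stated tolerance by using M ≳ 70 vectors.
* **B-factors.**  The two-step procedure aligns all frames onto the
  first (on the Cα or Cγ selection), averages, re-fits every frame onto
  the average, and reports $B = (8\pi^2/3)\langle|\Delta r|^2\rangle$.
  The rigid-body fit absorbs ~6/(3N) of the true variance, so jitter
  validation uses scaffolds of N ≥ 100 atoms where this bias is ≈ 2%.

## Clustering

Conformational clustering is agglomerative average linkage on pairwise
best-fit RMSD, merging while the minimum average inter-cluster distance
is ≤ ε (default 2.0 Å on Cα+Cβ).  Average linkage is monotone, so this
equals cutting the `hclust` dendrogram at ε; the chosen semantics (merge
while ≤ ε, stop strictly above) is asserted against a naive O(n³)
reference in the tests.  Cluster averages are plain coordinate means of
members aligned to the cluster medoid (the member minimising summed
within-cluster RMSD) — no minimisation, and the medoid choice is a
package decision since the procedure's alignment target is otherwise
unspecified.

Disulfide torsion sets (the five consecutive dihedrals spanning
N–CA–CB–SG–SG′–CB′–CA′–N′) are compared with the rule that two sets
differ when **any** of the five torsions differs by ≥ 60° (wrapped).
The rule defines a difference criterion but no algorithm, so the package
uses greedy leader clustering in frame order: deterministic, order
dependent, and documented as such — on well-separated groups the
partition is permutation-stable, which is tested.  Handedness is the
sign of the central CB–SG–SG′–CB′ dihedral, positive = right-handed
spiral (standard stereochemical usage; the configurations are otherwise
defined only pictorially), with 0/±180° labelled indeterminate.

## Z-score ranking of refinement quality scores

For each (model, score) cell over M refinement methods,
classical $Z = (QS - \text{mean})/\text{SD}$ and robust
$Z = (QS - \text{med})/(1.4826\cdot\text{MAD})$.  Missing scores get
Z = 0 *at the score level*, before model averaging; model-level Z is the
equal-weight mean over score names and method-level Z the equal-weight
mean over models.  Cells with SD = 0 or MAD = 0, and cells with a single
available value, yield Z = 0.

Two conventions the published tables leave open are resolved by
`disambiguateZConventions()`, which enumerates the candidate
combinations and keeps the one reproducing the stated method ranking for
both variants: the unrefined reference row is **excluded** from the
per-cell statistics, lower-is-better scores are **sign-flipped** before
standardisation (without the flip no combination can rank refinements
sensibly), and the classical variant uses the **sample** (n−1) SD.
These frozen defaults reproduce every published aggregate to printed
precision:

```{r}
qs <- synthQualityScores()
round(methodZ(robustZ(qs)), 2)
round(methodZ(classicalZ(qs)), 2)
```

## What the synthetic generators emulate — and what they do not

Each `synth*` generator draws from a seeded stream and returns a
manifest with the ground truth its construction guarantees, closing the
loop generator → analysis → manifest in the tests:

* `synthTwoStateRmsd`: exponential first passages between a nonnative
  level (5 Å) and a native level (1 Å) around the 1.96 Å cutoff, with
  post-folding excursions.  It emulates two-state folding statistics,
  not the continuous diffusive dynamics of a real RMSD trace.
* `synthHelixCoil`: frames that are globally helical or globally
  extended with per-residue torsion noise (SD 5°), plus optional frayed
  termini.  Real helix-coil ensembles have partial helices and
  correlated propagation, which the generator deliberately omits — the
  point is a known helicity, not realistic cooperativity.
* `synthConeWobble`: vectors uniform in a cone (inverse-CDF on cos θ, so
  the closed form S² = ((cos θ₀(1+cos θ₀))/2)² holds exactly); no
  global tumbling and no anisotropic motion.
* `synthJitterTrajectory`: i.i.d. isotropic Gaussian atomic jitter with
  optional global rigid motion; real B-factors include correlated and
  anisotropic motion.
* `synthMultiwellTrajectory`: Gaussian clouds around well centres with
  post-fit separations near the requested value; no barrier crossings.

Passing tests therefore demonstrate that the estimators recover known
statistical ground truth under their own assumptions, not that any
forcefield reproduces experiment.

## Problem sizes and numerical choices

The test suite validates at sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances while remaining quick: folding-time
recovery at n = 1000 simulations over 5 seeds; iRED with 72 vectors and
10⁵ frames for the cone check (2 × 10⁴ in the unit tests); B-factors
with 100-atom scaffolds and 300–400 frames; clustering on 60-frame,
3-well fixtures; helicity with 100–400 frames.  Numeric output in
parameter files uses fixed-width canonical formats with enough digits
(4 decimals for masses and bond lengths) that parse → write → parse is
the identity on all stored quantities, which the round-trip tests
assert.  Superposition uses SVD with the determinant sign correction so
the rotation is always proper; degenerate (collinear or < 3 atom)
selections are errors, not silent results.

## Known limitations

* Only the frcmod and parm `.dat` text dialects are read; binary
  trajectory formats are out of scope (multi-model PDB and CSV series
  are the interchange formats).
* The package evaluates none of the energy function itself and builds no
  topologies; it transforms parameters and analyses coordinates already
  produced by a simulation engine.
* Published MD-derived observables (folding times of real miniproteins,
  χ² against measured couplings) require the underlying trajectories;
  the analytics are validated against synthetic ground truth and
  published worked examples (the Z-score tables) instead.
* The external quality scores of the refinement study (GDT-TS, GDT-HA,
  GDC-all, RPF, LDDT, SphereGrinder, CAD) are consumed as a table; only
  the two RMSD-type scores are computed natively.
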