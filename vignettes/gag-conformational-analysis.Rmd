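---
title: "Methods: conformational analysis of glycosaminoglycan ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational analysis of glycosaminoglycan ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and conventions behind each analysis stage, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## The system and its coordinates

Heparin-like chains are represented as tidy atom tables (`gag_structure`):
atom name, element, mass (amu), 1-based residue index with **residue 1 at
the reducing end**, residue type (`"GlcNS(6S)"`, `"IdoA(2S)"`), and
Cartesian coordinates in Ångström. An ensemble (`gag_ensemble`) is an
ordered set of conformers sharing one topology with a frame spacing in ps
(default 100 ps, the typical trajectory write interval at which
5 μs of dynamics yields tens of thousands of frames).

All angles are degrees on (−180°, 180°], with the IUPAC dihedral sign
convention (cis = 0; verified in the tests against bio3d's independent
implementation and a projection-formula oracle). Degenerate torsion
geometry — coincident or collinear defining atoms — raises an error rather
than returning 0 or NaN, so classification code downstream can never
silently mislabel a frame.

## Ring puckering classification

Each pyranose conformer is assigned from two ring dihedrals,
γ = C1–C2–C3–C4 and δ = C1–O5–C5–C4, by circular windows of ±`half_width`
(default 23°, boundary inclusive) around per-state reference values. The
boundary is inclusive because a stated "range of ±23°" has no other
reproducible reading.

**Derived, not transcribed, references.** The reference (γ, δ) values are
computed from idealized rings constructed at the canonical Cremer–Pople
(CP) coordinates of the four states, with ring atoms indexed O5, C1…C5:

| state | θ (°) | φ₂ (°) | γ_ref (°) | δ_ref (°) |
|-------|-------|--------|-----------|-----------|
| ⁴C₁   | 0     | –      | −54.60    | +59.40    |
| ¹C₄   | 180   | –      | +54.60    | −59.40    |
| ²S_O  | 90    | 150    | −45.43    | −50.47    |
| ¹S₃   | 90    | 210    | −22.80    | −26.86    |

The phase assignments on the θ = 90° equator follow IUPAC twist-boat
naming; they were derived (not assumed) by finding, at each candidate
phase, the four exactly coplanar ring atoms and checking which atom pair
lies above/below that plane, with the "above" side fixed by anchoring the
θ ≈ 0 chair of an independently built D-glucopyranose model to its known
⁴C₁ label. The derivation script (`data-raw/derive-pucker-references.R`)
regenerates the frozen constants deterministically, and
`derive_pucker_references()` repeats it at run time; a test asserts both
agree and that the chairs obey exact inversion symmetry
(γ(⁴C₁) = −γ(¹C₄), δ(⁴C₁) = −δ(¹C₄)).

**The ²S_O/¹S₃ window overlap.** The two skew-boats are adjacent on the
pseudorotation equator (Δφ₂ = 60°), and their derived references are
separated by only ~23° in γ and ~24° in δ — a geometric fact, confirmed
both on ideal CP rings and on force-field-optimized iduronate conformers.
Windows of ±23° around them therefore overlap in a corner region; full
pairwise disjointness is unattainable for this state set at this window
width. The package resolves the ambiguity deterministically: a point
inside exactly one window takes that label; a point inside both is
assigned to the **nearest reference** (wrapped Euclidean distance in
(γ, δ)); a point inside none is `"other"` (the noncanonical category).
Construction-time validation rejects reference sets in which one reference
point lies *inside* another's window (which would make the references
themselves ambiguous); the derived set passes, since the skew references
are separated by more than one half-width. All chair pairs are separated
by far more than two half-widths and behave as fully disjoint windows.

Per-residue populations are tabulated as exact counts over frames, so
fractions per residue (including `"other"`) sum to 1.

## Glycosidic linkage analysis

With residue n counted from the reducing end, residue n+1 is the glycosyl
donor: its C1 is bonded to residue n's O4 (checked by an O4–C1 distance
< 1.8 Å), and

* φ = torsion(O5₍ₙ₊₁₎, C1₍ₙ₊₁₎, O4₍ₙ₎, C4₍ₙ₎),
* ψ = torsion(C1₍ₙ₊₁₎, O4₍ₙ₎, C4₍ₙ₎, C3₍ₙ₎).

This indexing direction is the only one compatible with 1→4 linkages. In a
dodecamer the 11 linkages split 6/5 between the IdoA(2S)–GlcNS(6S) and
GlcNS(6S)–IdoA(2S) classes (donor named first); the analysis default pools
same-class linkages into one series, mirroring how per-class population
heatmaps are normally aggregated. Whether terminal linkages should be
pooled with interior ones is left to the user (pass an explicit linkage
table to keep them separate).

Heatmaps bin (φ, ψ) periodically on (−180°, 180°]² with a default bin
width of 5°, which resolves the ~40–60° separations between the known
basins without noise-dominated cells at the ensemble sizes used here
(10³–10⁴ pooled points); the bin width must divide 360. Modes are bins
strictly greater than all 8 neighbours under periodic wrap (a peak on the
±180° seam is found exactly once), reported at bin centers and filtered by
a minimum fraction. Detection is on raw binned fractions by default, for
determinism; an optional 3×3 periodic mean filter (`smooth = TRUE`)
stabilises mode detection on sparse histograms, while reported fractions
always come from the raw bins.

## Shape descriptors

* **RMSD time series** against the first frame, after optimal rigid
  superposition (closed-form Kabsch with a reflection guard; the rotation
  is always proper). Mass weighting is on by default, matching the common
  MD-tool convention; both the weighting and the atom selection are
  exposed because trajectory RMSD conventions vary between tools.
* **Pairwise RMSD matrix** over strided frames, each pair fitted
  independently (so the triangle inequality is not guaranteed — a property
  of pairwise-fitted RMSD, not a defect). The default stride caps the
  matrix at 2000×2000, desk-scale for 5×10⁴-frame trajectories.
* **R_g** and **EED** per frame; EED is the distance between the
  mass-weighted centers of mass of the terminal residues, hydrogens (when
  present) included — pure mass weighting.
* **Inter-residue distance map**: mean COM–COM distances over frames, the
  minimal reading of "inter-residue distances" when no more specific
  methodology is given.
* **Summary statistics** use the sample (n−1) standard deviation by
  default; the convention is configurable because at n ≥ 5×10³ the
  difference is negligible but must be pinned for reproducibility.
* **Correlations** are Pearson, over the three series; a constant column
  is an error (undefined correlation), never a silent NaN.

All descriptors are invariant under a global rigid-body motion applied
uniformly to every frame (property-tested to 1e−9).

## Water model energetics

The pair energy of two placed rigid water molecules is the Coulomb sum
over charged interaction sites plus a single oxygen–oxygen Lennard–Jones
term, E = Σ q_iq_j·k/r_ij + 4ε₀[(σ₀/r_OO)¹² − (σ₀/r_OO)⁶], with
k = 332.0636 kcal Å mol⁻¹ e⁻² making the Gaussian-units e² prefactor
explicit. The form is applied generically to all five registry models
(TIP3P, TIP4P, TIP5P, SPC/E, OPC), each with its own LJ site on oxygen;
site geometries and charges are shipped as a human-readable YAML registry
and come from the models' original parametrizations. Sanity checks:
the LJ term vanishes exactly at r_OO = σ₀; dimer energies match an
independent double-loop summation to 1e−9; and the computed dipole moments
reproduce the reference values (TIP3P 2.35 D, TIP4P 2.18 D, TIP5P 2.29 D,
SPC/E 2.35 D, OPC 2.48 D) to within 0.02 D.

## The synthetic generator: what it emulates, and what it does not

`generate_ensemble()` produces heparin-like ensembles with *known*
ground-truth parameters so that every analysis stage can be validated by
parameter recovery:

* **Rings** are built at exact CP coordinates (default amplitude
  Q = 0.57 Å, a typical pyranose value) with realistic per-bond lengths
  (C–O 1.43–1.44 Å, C–C 1.52 Å). Because the CP z-pattern contains only
  m = 2, 3 Fourier components over the atom index grid, the in-plane
  bond-length refinement provably cannot perturb (Q, θ, φ₂): built rings
  round-trip their CP parameters to 1e−3.
* **Chains** are assembled by internal-coordinate (NeRF) placement, so the
  prescribed φ/ψ are reproduced exactly (tested to 0.5°, achieved to
  ~1e−10). Side-chain substituents (N-sulfo, O-sulfo, carboxylate,
  hydroxyl) are single united pseudo-atoms with the substituent masses,
  placed radially outward in the ring plane — descriptors are
  mass-weighted and the pucker/linkage dihedrals involve only ring atoms
  and O4, so full substituent geometry would add nothing to what the tests
  can validate. The stagger of the glycosidic oxygen at the donor anomeric
  carbon is ±120° off the C2 substituent, with the sign per donor type
  encoding the α-D (GlcNS) versus α-L (IdoA) anomeric configuration; these
  signs are what keep chains clash-free across all pucker states in each
  class's torsion basin.
* **Stochastics.** Per-frame pucker states are drawn iid from per-residue
  probability vectors (defaults: GlcNS(6S) all ⁴C₁, matching the
  observation that its noncanonical fraction is below 1%; IdoA(2S)
  0.65/0.35 between ²S_O and ¹S₃, a typical skew equilibrium). Torsions
  are drawn from wrapped normal distributions per linkage class (defaults
  centred on the literature basins (−70°, 120°) and (60°, 60°) with 12°
  circular SD), optionally as weighted mixtures. Isotropic Gaussian
  Cartesian noise (default σ = 0.05 Å) is added last. States are drawn
  once per frame and never resampled; if a torsion draw produces a steric
  clash (any non-bonded inter-residue contact < 1.5 Å) only the torsions
  are redrawn, so the generated state marginals equal the recipe
  probabilities exactly while the torsion distribution is conditionally
  truncated to clash-free space (a negligible truncation in the default
  basins, where the clash rate is ~0).

What the generator does **not** emulate: thermodynamically realistic
sampling (no force field, no solvent, no kinetics — frames are iid, so
nothing about transition rates or autocorrelation can be validated),
hydrogen positions, counterions, or correlated backbone motions. Passing
recovery tests therefore demonstrates that the *analysis* stages are
correct and self-consistent, not that any particular force field or
solvent model is accurate.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: geometry
oracles on 50 random instances per primitive; pucker-population recovery
on 1000-frame disaccharide ensembles (the ±0.05 tolerance is ~3.5 binomial
standard errors at n = 1000); linkage-mode recovery on 5000-frame
ensembles with 5° bins; two-cluster RMSD matrices on 2×25–30 frames of
hexamers; the headline synthetic dodecamer at 800 frames. Under Cartesian
noise the induced γ/δ jitter is ~13° at σ = 0.1 Å against a 23° window
half-width, so template recovery is asserted at ≥95% for σ ≤ 0.05 Å and as
the modal label at σ = 0.1 Å — a hard 100% recovery claim at that noise
level would be geometrically impossible.

Superposition requires ≥3 non-collinear atoms (rank check at 1e−8);
reflection is guarded by the determinant sign; torsion degeneracy
thresholds are 1e−10 (coincident points) and 1e−8 (collinearity).
Ring-bond refinement runs BFGS to reltol 1e−14 from a deterministic start,
and is cached per CP coordinate.

## Known limitations

* The γ/δ window classifier cannot fully separate ²S_O from ¹S₃ at ±23°
  (see above); the nearest-reference rule is deterministic but points in
  the overlap corner are intrinsically ambiguous in this two-coordinate
  scheme. A full CP (Q, θ, φ₂) assignment would remove the ambiguity and
  is deliberately out of scope.
* Trajectories are assumed whole-molecule (no periodic-boundary
  unwrapping); readers warn about nothing more than format errors, so
  broken molecules would surface as absurd bond lengths in the linkage
  detection step.
* XYZ files carry no residue records; residues are reconstructed from
  repeating atom names, which is lossless only for files the package
  itself wrote.
* Pseudo-atom masses cannot be stored in PDB/XYZ; re-read synthetic
  ensembles get element masses instead, so mass-weighted descriptors
  computed from re-read files differ slightly from those computed on the
  in-memory originals.
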