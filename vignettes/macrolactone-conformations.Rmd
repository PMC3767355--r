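---
title: "Conformational analysis of 18-membered macrolactones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational analysis of 18-membered macrolactones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroconf)
```

## The problem

Macrolide cores are large lactone rings whose chemistry is steered by
conformation: a reagent attacks the less hindered face of a ring-bound
pi system ("peripheral attack"), so knowing which conformers a
macrocycle populates — and how strongly — predicts stereoselectivity.
macroconf studies a model family of 18-membered
alpha,beta-unsaturated macrolactones containing one conjugated ester
(enone) unit and one diene unit separated by two saturated methylene
chains. Two isomers span the family: a symmetric one ("18s", chains of
5 and 5 carbons) and a dissymmetric one ("18d", chains of 4 and 6).
Binding a tricarbonyliron fragment to the diene rigidifies the ring
and blocks one diene face, concentrating the Boltzmann weight into few
conformers; the package quantifies that rigidification.

The pipeline has five stages, each usable on its own:

1. **build** — generate the macrolactone (and optionally the Fe(CO)3
   steric model) from the ring recipe;
2. **search** — Metropolis Monte Carlo in ring-torsion space over a
   simplified molecular-mechanics energy, with quench minimisation;
3. **classify** — assign each conformer one of eight geometric types;
4. **analyze** — convert per-type relative energies into Boltzmann
   populations at a calibrated effective temperature;
5. **report** — TSV/JSON/SDF artifacts, reproducible from one seed.

## The molecular model

`build_macrolactone()` constructs the ring from a template: ester
oxygen O1, carbonyl carbon C2 (exocyclic O19), conjugated ene C3=C4,
n2 methylenes, the four diene carbons, n1 methylenes, closing back
onto O1. This numbering is the one consistent with both labelled
torsions: `phi1` = O19-C2-C3-C4 (the enone single bond) and `phi2` =
the central diene single bond (ring atoms 10-13 for 18s, 11-14 for
18d). Hydrogens are explicit; initial coordinates lay the ring on a
circle with a seeded out-of-plane jitter (±0.35 Å) and are relaxed
under the force field. All double bonds start E, as a planar convex
polygon implies, and stay E throughout (double bonds are never
torsionally moved and carry a high twofold barrier).

The energy is a deliberately small Allinger-style molecular-mechanics
surface, in kcal/mol with Å and degrees:

* harmonic stretch `ks (r - r0)^2` and bend `kb (theta - theta0)^2`;
* three-term cosine torsions; conjugated single bonds (diene centre,
  enone, ester C-O) carry twofold terms sized so the per-bond rotation
  barrier is a literature-typical few kcal/mol (e.g. the diene centre:
  four in-phase quadruples of V2 = 1.25 give roughly a 5 kcal/mol
  barrier, with minima at both s-cis and s-trans);
* Lennard-Jones 6-12 van der Waals excluding 1-2/1-3 pairs. A 6-12
  function replaces the Buckingham-type exponential of the classic
  Allinger surface: it has no spurious short-range collapse, which
  matters when torsion moves create transient clashes;
* restraints: the ring-closure bond is a harmonic distance restraint
  (k = 300 kcal/mol/Å²) rather than a stretch term, so torsion moves
  can treat the ring as an open chain; the complexed diene carries a
  torsional lock `k (1 - cos(phi2))` with k = 50 kcal/mol.

Parameters are generic MM2-like constants packaged as a flat text file
(`system.file("extdata", "mm_params.txt", package = "macroconf")`).
Because no specific reference force-field parameterisation is targeted,
**absolute energies and dipole magnitudes are not meaningful here**;
the meaningful outputs are torsion classes (s-cis/s-trans), relative
energy orderings, type counts, and the population mathematics.

Bond dipoles (C=O, C-O, Csp3-Csp2) are summed for the reported dipole
vector but contribute nothing to the energy, in the Allinger
bond-moment tradition.

The tricarbonyliron fragment is a single pseudo-atom with an enlarged
Lennard-Jones radius (default 2.8 Å) held 1.7 Å above the diene-plane
centroid by four coordination "bonds" (stretch terms only — no
angles/torsions through them), plus the diene s-cis lock. This is a
steric-and-rigidity model only; no electronic structure of the complex
is attempted. Which diene face is occupied is a builder argument
(default +1); the two choices are mirror images.

## Minimisation

`minimize()` is a limited-memory quasi-Newton (L-BFGS) descent with an
Armijo backtracking line search, terminating at a gradient RMS below
`tol` (default 0.01 kcal/mol/Å) or an iteration cap. A quasi-Newton
method was chosen over plain gradient descent because the surface
mixes very stiff stretch terms (k up to 570) with soft torsions; the
line search makes the recorded energy trace monotone non-increasing by
construction, which the tests assert. Divergence (energy above 10^6
and above the starting value) raises a typed error. Analytic gradients
for every term are validated against central finite differences
(h = 1e-5 Å) to better than 1e-4 kcal/mol/Å.

## The conformational search

`run_search()` samples ring-torsion space at 1000 K — the
high-temperature regime conventionally used to generate conformers —
with these defaults: 20 000 steps, one uniformly chosen rotatable
torsion rotated by uniform(-60°, +60°) per step, quench-and-record
every 25 steps, a 6 kcal/mol retention window above the global
minimum, and a 30° torsion-space deduplication threshold (keeping the
lower-energy member of any close pair; the distance is the maximum
circular difference over the 18 ring torsions). Rotatable bonds are
the ring single and ester bonds; double bonds, the closure bond and a
locked complexed diene are excluded. `deltaE = 0` moves are accepted
(documented tie-break).

Two implementation points matter in a *closed* ring:

* **Per-move relaxation.** A rigid single-torsion rotation tears the
  closure restraint apart (hundreds of kcal/mol), so raw-energy
  Metropolis would reject everything. Each proposal is therefore
  relaxed for a capped number of iterations (default 60, loose
  tolerance) before the Metropolis test — Monte Carlo with
  minimisation, in the tradition of macrocycle search protocols.
* **Independent walkers.** Closure couples the torsions: driving the
  diene from s-trans to s-cis needs a concerted multi-torsion motion
  whose constrained barrier far exceeds the ~6 kcal/mol adiabatic one,
  so a single chain essentially never crosses within the step budget.
  The budget is therefore split across `n_walkers` (default 8)
  independent chains, each started from a torsion-randomised,
  quench-minimised copy of the input. Randomised starts land on both
  sides of every rotational barrier, and the chains then explore
  locally. Everything is driven by one seed; two runs with the same
  configuration are identical, and quenched records whose closure
  deviates by more than 0.15 Å are discarded.

Ensemble sizes are implementation-defined; at the default settings the
searches used in the tests record 800 quenched structures and retain a
few dozen distinct conformers inside the window.

## Classification into eight types

Each conformer is reduced to three binary attributes
(`compute_attributes()`):

* **ester conformation**: s-cis if |phi1| < 90°, else s-trans (ties to
  s-trans);
* **diene conformation**: same rule on phi2;
* **plane arrangement**: the diene plane (least-squares plane of the
  four diene carbons) versus the conjugated-ester plane (O19, C2, O1,
  C3). The planes are *pseudoparallel* when their mutual angle is
  below 45° **and** their oriented normals point to the same side;
  otherwise *pseudoantiparallel* (ties at 45° to antiparallel).

Orienting the two normals needs a reference that survives arbitrary
ring folding. Radial references (ring centroid to site centroid) are
ill-conditioned here: for near-parallel site planes on opposite sides
of a macrocycle the outward-oriented normals almost always oppose,
which would empty half the classification. macroconf instead orients
each normal by the site's *winding direction* — the sum of cross
products of consecutive edges of the four site ring atoms traversed in
ring order. This marks, intrinsically, the pi face the ring traversal
winds counter-clockwise around, and it splits real ensembles into both
arrangements.

`assign_type()` maps the 2x2x2 attribute cube onto labels 1–8 through
a frozen table (`type_map()`): even labels are pseudoparallel, odd
pseudoantiparallel, and the (diene, ester) pairs order the label pairs
as (s-cis, s-cis) → 1/2, (s-cis, s-trans) → 3/4, (s-trans, s-cis) →
5/6, (s-trans, s-trans) → 7/8. These label numbers are this package's
own convention; only the even/odd parity is shared with other
labelings of the same eight classes, so cross-study comparisons should
key on rank in the energy table, not on label identity.

`type_census()` reports, per populated type, the minimum energy
relative to the ensemble global minimum (the `deltaE` of the summary
tables), the conformer count, and the representative geometry.

## Boltzmann populations and the effective temperature

Populations follow `p_i = 100 exp(-dE_i/RT) / sum_j exp(-dE_j/RT)`
over one `deltaE` per type (the per-type minimum, matching the
structure of published per-type tables; a partition-sum mode over all
conformers of a type is available via `population_table(mode =
"sum")`).

The temperature of published per-type population tables is often not
stated. `calibrate_rt()` therefore treats RT as a parameter and
recovers it by 1-D bounded least squares (RT in [0.1, 20] kcal/mol)
against observed percentages, with several datasets fitted jointly
(each normalised separately, residuals pooled). `reproduce_tables()`
calibrates one global RT on the sixteen (deltaE, %) pairs of the two
uncomplexed datasets and then *predicts* the two complexed datasets
with no refit; the per-cell error report it returns is the package's
check that a single effective temperature explains all 24 printed
cells. The calibrated value sits near 4.1 kcal/mol — equivalent to
roughly 2070 K, far above both room temperature (0.6) and the 1000 K
sampling temperature (2.0). The package deliberately does not assert a
physical temperature: RT_eff is a descriptive parameter of the printed
tables (a kcal-versus-kJ unit mix at ~500 K would produce the same
number), and the discrepancy is surfaced rather than hidden.

`compare_flexibility()` summarises a table by the number of types
within 1 kcal/mol, the top population, and an evenness index (Shannon
entropy normalised by log of the number of types; 1 = uniform, 0 =
single type by convention). Rigidification by complexation appears as
a higher top population and a lower evenness.

## Dipoles and face accessibility

`dipole_moment()` sums the parameterised bond dipoles. Two honest
limitations follow from the bond-dipole model: magnitudes depend
entirely on generic parameters, and a planar s-trans diene has a
near-zero net site dipole by symmetry, so the plane arrangement can
only influence the total dipole appreciably when the diene is s-cis.
The package's qualitative check of the "pseudoparallel conformers have
the larger dipole" effect therefore compares *matched pairs* — a
conformer and its diene-face-flipped twin (both flanking single bonds
rotated 180°, re-minimised, all other attributes equal) — and asserts
the ordering on the pair aggregate, not for every individual pair.

`face_accessibility()` scores each face of a site plane by the atom
volume inside an approach cylinder (default: lateral 2.5 Å around the
site centroid, heights 0.5–3.0 Å above the plane). The defaults
emulate a small reagent approaching the pi face along its normal: the
cylinder has the footprint of the site itself and stops at van der
Waals contact height. A wider, taller probe would instead count
saturated backbone arcs that fold over the site periphery — real
bulk, but not what blocks a perpendicular approach — and would mask
the pseudo-atom's effect. With the defaults, the Fe-occupied face of
every complexed ensemble conformer scores higher (is more blocked)
than the clear face, and the score difference grows monotonically with
the pseudo-atom radius.

## What the synthetic generator does and does not emulate

The builder generates exactly the two model macrolactones — an
aglycone core with no substituents, no stereocentres, no sugars — in
vacuo. Passing tests therefore demonstrate the *method* (search
coverage, classification logic, population mathematics, rigidification
and face-blocking trends) on a faithful model of this ring
family; they do not certify force-field accuracy for decorated
macrolides, solvent effects, or the electronic structure of the iron
complex. Printed dihedral values and dipole magnitudes from reference
calculations are not reproduction targets for the same reason; their
class content (s-cis/s-trans, ordering) is.

## Numerical choices and degenerate inputs

* Dihedrals use the IUPAC sign convention, range (-180°, 180°];
  collinear triples raise a typed degenerate-geometry error.
* Least-squares planes come from the SVD of centred coordinates;
  collinear clouds raise the same error class. Without an orientation
  reference the normal's largest component is made positive.
* All angle thresholds (90° conformation split, 45° arrangement split)
  resolve ties away from the "special" class: s-trans and
  pseudoantiparallel win.
* The closure restraint (k = 300) and the diene lock (k = 50) are
  stiff enough that every recorded conformer closes within 0.15 Å and
  every complexed conformer keeps |phi2| well under 20°, but soft
  enough not to stall the minimiser.
* Problem sizes in the shipped tests: 45-atom molecules; full-scale
  searches of 20 000 steps (about a minute each) for the search
  acceptance checks, 480–4000-step searches for unit-level properties;
  table reproduction and calibration are closed-form-sized and run in
  milliseconds.

## Known limitations

* One effective RT is a one-parameter summary; it reproduces all 24
  printed cells here, but nothing guarantees that for other tables.
* The search is stochastic-but-seeded; type *counts* below the default
  budget can fluctuate between seeds, which is why qualitative
  assertions (at least 6 of 8 types; complexed strictly fewer) rather
  than exact ensemble reproduction are the test surface.
* The Fe(CO)3 model cannot distinguish electronic preferences between
  diene faces, only steric ones.
* Type labels 1–8 are package-local; only parity is portable.
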