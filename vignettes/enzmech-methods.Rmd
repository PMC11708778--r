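---
title: "Methods and conventions in enzmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions in enzmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzmech)
```

This vignette records the physical model behind each analysis, the unit and
sign conventions, the default parameters and why they were chosen, and the
known limitations of the synthetic data generators. Everything here is a
package-level decision; where a convention is genuinely open (several
defensible choices exist), the alternatives are noted.

## Units

All energies are kcal/mol, distances are ångström (Å), partial charges are
atomic units (e), frequencies are wavenumbers (cm⁻¹), temperatures are
kelvin, and trajectory times are nanoseconds. The physical constants used
throughout are available from `enzmech_constants()`; the two load-bearing
ones are the second radiation constant `c2 = 1.4387769` cm·K (converting a
wavenumber to a vibrational temperature, Θ = c2·ν̃) and the electrostatic
conversion factor `k = 332.0637` kcal·Å/(mol·e²).

## Gibbs free-energy profiles

A catalytic stage is described as a *step table*: a chain of elementary
steps, each with a transition-state label, an activation free energy ΔG‡
and a reaction free energy ΔG_rxn, both quoted from a stated
`reference_label`. The reference need not be the step's starting minimum:
when an intermediate is not a stable free-energy minimum, ΔG‡ of the next
step is more meaningfully quoted from the last stable minimum, and the
table records that choice explicitly.

`assemble_profile()` turns the table into absolute free energies with the
first reactant at G = 0:

* `G(TS) = G(reference) + ΔG‡` and `G(product) = G(reference) + ΔG_rxn`.
* A missing (NA) activation energy marks a **barrierless** step. Its
  transition state is placed degenerate with the *higher* of the two
  flanking minima — the natural limit of a vanishing barrier — and the step
  is listed in `barrierless_steps`.
* A minimum is flagged **Gibbs-unstable** when an adjacent, genuinely
  computed transition state lies at or below its own free energy: the
  structure is a minimum on the potential-energy surface, but the free-energy
  barrier enclosing it has vanished. Transition states that were themselves
  placed by the barrierless convention are skipped in this test; they sit at
  a flanking minimum *by construction*, so counting them would flag every
  product of a barrierless step.

`rate_limiting_barrier()` applies the energetic-span rule: for each
transition state the span is `G(TS) − min G` over all preceding states
(including the reactant), and the rate-limiting transition state maximizes
this span. When two spans tie to within 1e-12 kcal/mol the *later*
transition state is reported, since flux through the network must pass it
last. Reporting the earlier one would be equally defensible; the choice is
fixed here so downstream code is deterministic.

## Harmonic thermochemistry

`gibbs_correction()` implements the rigid-rotor/harmonic-oscillator (RRHO)
treatment on a list of harmonic frequencies:

* Each real mode contributes zero-point energy `R·Θ/2` — **all** real
  modes, regardless of how soft.
* Thermal vibrational energy and entropy are summed only over modes with
  vibrational temperature above `cutoff_K` (default **120 K**, about
  83 cm⁻¹). Very soft modes in enzyme active-site models are poorly
  described as harmonic oscillators — they are hindered rotations and
  librations — and their near-divergent entropy terms would dominate the
  correction with noise. A cutoff near 100 cm⁻¹ (≈ 144 K) is also common;
  120 K was fixed as the package default and is a plain argument.
* Imaginary frequencies (negative wavenumbers) are dropped from all sums
  and counted in `n_imaginary_dropped`; exactly one is the signature of a
  transition state (`classify_stationary_point()`).
* The default temperature is **298.15 K** (standard thermodynamic
  temperature). Mechanistic barriers are conventionally quoted at 298 K
  even when experiments run warmer; the `temperature` argument changes it.
* With `include_trans_rot = TRUE` (requires masses and coordinates), the
  Sackur–Tetrode translational entropy and classical rigid-rotor rotational
  terms are added, with symmetry number 1, at `pressure_atm` (default 1).

The Gibbs correction is `ZPE + E_thermal − T·S` (plus RT-type enthalpy
terms when translation/rotation are included); add it to an electronic
energy to obtain a free energy.

## Structural metrics

* `burgi_dunitz_angle()` is the nucleophile–carbonyl-carbon–carbonyl-oxygen
  angle at the carbon; values near 105–110° indicate a nucleophile poised
  for attack. Coincident atoms are an error, not NaN.
* `hbond_scan()` uses a distance-only criterion on the H···acceptor
  distance (default cutoff 2.5 Å), because mechanism reports quote hydrogen
  bonds as H···A distances; no angular term is applied.
* `kabsch_rmsd()` superposes matched atoms (by `residue_id` + `atom_name`,
  so reordered inputs compare correctly) with the SVD form of the Kabsch
  algorithm, including the determinant correction that excludes improper
  rotations, and reports the residual RMSD.

## Reactive-frame selection

MD snapshots are screened on five near-attack distances, `d1`–`d5`, where
`d3` is the nucleophile-to-carbonyl-carbon attack distance. A frame
*passes* when `d3 < 3.5` Å and each other distance is `< 2.5` Å — strict
inequalities, so a frame sitting exactly on a threshold fails.

Two conventions deserve note:

* The **pass fraction is computed over all frames**, including the
  equilibration window, because it is a statement about how often the
  trajectory visits reactive conformations, not about which frames are
  eligible for selection.
* Selection is restricted to frames with `time ≥ exclude_before_ns`
  (default 20 ns) and picks the passing frame with the smallest distance
  sum `dsum = d1 + … + d5`; ties break toward the earliest frame. An empty
  selection (no qualifying frame) is a legitimate result, returned as a
  zero-row tibble, not an error.

## Residue deletion scan

The environment is a fixed-point-charge model: the interaction energy
between a residue's charges and the QM-region charges is a bare Coulomb
sum, `E = (k/ε) Σᵢ Σⱼ qᵢqⱼ/rᵢⱼ` with ε = 1 (no screening — the scan is a
diagnostic of the raw electrostatic field, and any uniform ε rescales all
contributions without reordering them). Atom pairs closer than 0.5 Å are a
modelling error and are rejected.

A residue's **contribution** is
`E_int(TS) − E_int(reactant)` — *positive means the residue destabilizes
the transition state* and is a mutation target; negative means it
stabilizes the TS and must be preserved. Because deletion of one residue's
charges does not affect any other pair term, contributions are exactly
additive: they sum to the total environment-interaction change.

The **macrodipole metric** Δd of a residue is
`d(residue → positive pole) − d(residue → negative pole)`, measured from a
per-residue reference atom (side-chain charge centers: CZ for Arg, CE for
Lys, CG for Asp, CD for Glu, CB otherwise) to the two poles of the reacting
dipole (for acylation: the serine Oγ as positive pole and the substrate
ester oxygen as negative pole). Δd > 0 means the residue is closer to the
negative pole.

Destabilizers with |contribution| above `relevance_cutoff` (default
1 kcal/mol) receive mutation proposals driven by charge class and Δd:
acidic residues closer to the negative pole get a conservative
charge-removing mutation (Asn/Gln) and aggressive charge-reversing ones
(Lys/Arg); arginine closer to the positive pole gets Gln/His/Met; other
positives closer to the positive pole get conservative Gln/Met and
aggressive Asp/Glu. Stabilizers get no proposals.

## Synthetic generators and their limitations

The generators make the scan and selector testable against known ground
truth; their defaults are the study conditions used by the acceptance
checks.

`make_state_pair()` builds a reactant/TS pair: a 10-atom QM region whose
two pole atoms sit 4 Å apart on the x-axis, and a shell of single-point
pseudo-residues (charges ±1 ionic, ±0.25 polar, 0.05 hydrophobic) placed
at 8–16 Å from the origin, biased toward one pole. The TS transfers
`dipole_shift / 4` e between the poles (planting an exact dipole change of
`dipole_shift` e·Å) plus a zero-sum jitter of 0.01 e on the inner atoms.
Each shell residue's analytic contribution is `k·q·δ·(1/r₊ − 1/r₋)`, which
is exact for the pole transfer and ignores only the jitter. Limitations:
residues are single point charges (no multipoles), the protein is
implicit (ε = 1, no screening), geometries are identical between reactant
and TS (pure charge reorganization), and shell sizes of tens of residues —
chosen to keep every test and the acceptance run under a few seconds on one
CPU — are an order of magnitude below a real first-shell count.

`make_trajectory_series()` plants an exact number of passing frames
(`round(n_frames × pass_fraction)`) at 0.2 ns spacing by constructing
distances on either side of the thresholds; it does not model
autocorrelation, so it tests the bookkeeping of the selector, not MD
statistics.

`make_step_table()` ships two literature-shaped presets,
`"stage1-paper"` (four acylation steps, barrierless final proton transfer,
with the post-INT1 reference quoted from R) and `"stage2-paper"` (two
deacylation steps), plus a generic auto-labelled constructor from any
`(ΔG‡, ΔG_rxn)` table.

## Reproducibility

All generator randomness flows through a single `seed` argument; the global
RNG state is saved and restored around every draw, so calling a generator
never perturbs a user's random stream. `scripts/acceptance.R` recomputes
the headline quantities from a single `--seed` and writes them as a flat
JSON object.
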