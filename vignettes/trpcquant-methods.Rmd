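---
title: "Models and methods behind trpcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trpcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpcquant)
```

# Scope

trpcquant implements the quantitative, desk-scale analyses used when
characterizing how the GTP-locked Gαi3 subunit activates the tetrameric
TRPC5 channel: single-channel open-probability analysis, two-ligand Hill
dose–response surfaces, chelator equilibria for recording solutions,
three-cube FRET, occupancy sorting of symmetry-expanded cryo-EM particle
metadata, and structural comparison metrics. Image-space cryo-EM
processing, atomic model building, MD simulation and whole-cell
statistics are out of scope: the package starts where those pipelines
emit numbers (traces, dose tables, intensity tables, particle metadata,
atomic coordinates).

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions taken where the conventions in the
field are genuinely open. Every figure quoted here is computed by the
package's own tests or examples; nothing is asserted that the code does
not reproduce.

# Single-channel idealization and open probability

## Model

Gating is treated as a two-state continuous-time Markov chain
C ⇌ O with opening rate $k_{co}$ and closing rate $k_{oc}$ (s⁻¹);
the stationary open probability is $k_{co}/(k_{co}+k_{oc})$. Multi-state
bursting and multi-channel (NP_o) analysis are deliberate non-goals:
a single P_o per condition is the quantity of interest, and the
generator and idealizer assume one conducting channel per patch (patch
recordings analyzed this way implicitly make the same assumption).

Idealization follows the half-amplitude (50%) rule: the closed and open
current levels are assigned from the all-point amplitude histogram
(`assignLevels`; the taller of the two dominant density modes is the
baseline/closed level), the threshold is their midpoint, and the state
toggles on threshold crossings. Candidate events shorter than the dead
time

$$\tau_{dead} = \frac{1}{2\pi f_c}$$

(0.159 ms at the standard 1 kHz low-pass cut-off) are *merged into the
surrounding dwell*, shortest first, rather than deleted-and-split; this
matches the practice of ignoring signal changes briefer than the filter
can transmit. The manual step of eyeballing every transition is replaced
by an automated transition report (raw, retained and merged-out
transition counts attached to the returned `DwellSequence`).

Open probability is computed exactly as
$P_o = \sum_i \tau_{o,i} / T_m$, and the sum of dwell durations always
reproduces the record duration to within one sample period.

## Numerical choices

* **Tie-break:** a sample exactly on the threshold keeps the previous
  state (the convention is unstated in common practice; some choice must
  be fixed for determinism).
* **Dead-time comparison** uses strict `<` with a one-ulp guard, so an
  event of exactly the dead time is retained.
* **Noise model:** the generator adds white Gaussian noise shaped by a
  Gaussian FIR low-pass filter with the single-channel convention
  $\sigma_t = 0.1325/f_c$, the standard digital surrogate for the
  recording amplifier's Bessel filter (both are non-ringing and
  approximately linear-phase, and the dead-time relation holds for
  either). The requested `noiseSd` is the *post-filter* standard
  deviation.
* **Continuous-time first:** the generator draws exponential sojourns
  and only then samples at `samplingRate`, avoiding discretization bias
  for dwells near the dead time. Rates above `samplingRate/5` are
  rejected, since dwells spanning fewer than ~5 samples cannot be
  represented faithfully.
* **Defaults** (10 kHz sampling, 1 kHz cut-off, −2 pA unitary current,
  0.25 pA noise) are the standard excised inside-out configuration for
  this channel family.
* **Membrane potential:** $V_{mem} = V_{rev} - V_{cmd}$; a
  liquid-junction potential below 3 mV in magnitude is neglected.
  Larger LJPs are subtracted ($V_{mem} = V_{rev} - V_{cmd} - LJP$, LJP
  expressed as bath minus pipette); recordings with the symmetric
  solutions used here never exercise that branch, so the sign convention
  is documented rather than validated against data.
* **i–V slopes** are fitted by OLS separately to the negative and
  positive driving-force branches (the unitary i–V relation is doubly
  rectifying); points where the open level is indistinguishable from
  baseline are excluded explicitly by the caller.

The windowed consistency check (`windowConsistency`) tiles the record
with windows (default 30 s) and flags any whose P_o falls outside
95–105% of the whole-record P_o. Window placement is a free choice in
manual practice; the package tiles deterministically from the start of
the record so results are reproducible.

# Hill dose–response surfaces and amplification

Single-ligand fits use
$P(x) = A\,x^{n} / (K_d^{n} + x^{n})$
by bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`), initialized at $K_d$ = geometric mean of the
doses, $n = 1$, $A$ = maximum response — a robust start on log-spaced
dose grids. Residuals are taken on the linear response scale (the
weighting convention is unstated in common practice; linear-scale
residuals with optional user weights is the default here). Fits are
*flagged*, not errored, when responses are constant, the optimizer
fails, or the fitted $K_d$ is more than 100-fold outside the dosed
range. Whether the amplitude was floated or fixed to 1 in published
normalized fits is unknowable from the fits alone; the package floats
it by default and exposes `fixAmplitude` (and `fixN`) for the
normalized-data case — the README example shows the fixed-amplitude
variant recovering $K_d^{PIP2}$ = 23.3 → 10.2 µM truth cleanly from
5%-noise data.

The two-ligand surface is fitted column by column (one independent Hill
fit per Gαi3 concentration; no parameter sharing across columns, since
sharing $n$ is another open convention the package leaves to `fixN`).
The $K_d^{PIP2}$ trend across Gαi3 and a monotonicity report quantify
the sensitization effect.

The amplification curve is the ratio of the fitted curve at the highest
activator concentration to the curve at the lowest, evaluated at
requested doses (5, 16 and 50 µM PIP₂ are the canonical picks).
Because the denominator vanishes at low dose, points where it falls
below 1% of the global maximum response are masked — mirroring the
deliberate omission of low-dose points to avoid the numerical
singularity. The observed biphasic shape of empirical amplification
data is treated as a property of data, not an invariant: the ratio of
two Hill curves with equal $n$ and amplitude is monotone, with limits
$(K_{lo}/K_{hi})^n$ at zero dose and 1 at saturating dose, and the
tests assert exactly that.

# Chelator equilibria

`freeIonConcentrations` solves the coupled 1:1 metal–chelator
equilibria

$$[M_i]_{free} = \frac{[M_i]_{tot}}{1+\sum_j K'_{ij}[L_j]_{free}},\qquad
  [L_j]_{free} = \frac{[L_j]_{tot}}{1+\sum_i K'_{ij}[M_i]_{free}}$$

by damped fixed-point iteration (relative tolerance 10⁻¹⁰) followed by
a Newton polish on the chelator-conservation residual, so mass
conservation holds to better than 10⁻¹² relative (machine precision in
practice). A closed-form quadratic solution for the single-metal,
single-chelator case serves as the independent oracle in the tests.

The constants are *apparent* (conditional) association constants, which
absorb the pH, temperature and ionic-strength dependence. The shipped
default table (`egtaConstants`) is stated at pH 7.2, 22 °C, ionic
strength 0.15 M: log K′ = 6.74 for Ca·EGTA (apparent K_d 180 nM) and
1.62 for Mg·EGTA (apparent K_d 24 mM). These are MaxChelator-lineage
values — NIST absolute constants minus the EGTA protonation correction
$\log\alpha_H \approx 3.8$–3.9 at pH 7.2 (`apparentStabilityConstant`
performs this conversion for user-supplied absolute constants).
Published apparent Ca·EGTA constants at these conditions span roughly
100–200 nM depending on the constant set and temperature entered, which
is why the table is user-overridable and why agreement with any
particular calculator should only be expected to within ~25%. With the
defaults, the excised-patch bath recipe (10 mM EGTA, 7.13 mM CaCl₂,
3.31 mM MgCl₂) comes out at 503 nM free Ca²⁺ and 2.99 mM free Mg²⁺.

# Three-cube FRET

The sensitized-emission formalism uses background-corrected intensities
$S_{CUBE}(SPECIMEN)$ for cubes {CFP, YFP, FRET} and specimens
{donor-only D, acceptor-only A, double-labelled DA}:

$$R_{D1}=\frac{S_{FRET}(D)}{S_{CFP}(D)},\quad
  R_{D2}=\frac{S_{YFP}(D)}{S_{CFP}(D)},\quad
  R_{A1}=\frac{S_{FRET}(A)}{S_{YFP}(A)}$$

$$FR=\frac{S_{FRET}(DA)-R_{D1}S_{CFP}(DA)}
          {R_{A1}\,[S_{YFP}(DA)-R_{D2}S_{CFP}(DA)]},\qquad
  E_{EFF}=E\cdot A_b=(FR-1)\,
  \frac{\epsilon_{YFP}(440)}{\epsilon_{CFP}(440)}$$

with the extinction-coefficient ratio defaulting to 0.079 for an
ECFP/EYFP pair excited through a 440-nm-band FRET cube. Design
decisions: the intensity gate $0.5 < I_{CFP}/I_{YFP} < 2.0$ is strict
at both bounds; inputs are assumed background-corrected
(`subtractBackground` is provided for per-cube offsets); the
interpretation of $E_{EFF}$ as $E \cdot A_b$ rests on a presumed 1:1
interaction stoichiometry with YFP on the limiting moiety, so the
decomposition into intrinsic efficiency and bound fraction is left to
the user; and distance conversion $r = R_0(1/E-1)^{1/6}$ requires a
user-supplied Förster radius (≈49–50 Å is typical for ECFP/EYFP, but no
default is shipped because $R_0$ depends on the orientation factor and
medium).

The generator inverts this measurement model exactly: the DA donor
signal is quenched by the transferred fraction and the FRET-cube signal
carries the sensitized emission $R_{A1}\,a\,FR$, so the noiseless round
trip recovers the constants and $E_{EFF}$ to floating-point precision —
the tests assert 10⁻¹² over a grid of efficiencies, bound fractions and
constants. $E_{EFF}$ is affine in FR with slope equal to the extinction
ratio, and FR is invariant under global rescaling of the DA intensities;
both are asserted as properties.

# Occupancy sorting under C4 symmetry

Symmetry expansion replicates each particle by the point-group
rotations so each subunit can be classified independently; focused
classification then assigns each subunit row one of two *bound* classes
(strong ligand density; ids 1, 2) or two *unbound* classes (ids 3, 4).
The sorter (`sortParticles`) traces rows back to original particles,
maps class ids to bound flags, canonicalizes the per-particle flag
tuple under cyclic rotation (lexicographically minimal rotation), drops
the expanded duplicates and reports per-pattern counts and fractions.

Decisions worth recording:

* **Particle identity** is keyed on the image name plus micrograph
  coordinates; the subunit index is recovered by binning each row's
  in-plane rotation offset (relative to the first row of its particle)
  into multiples of 360°/S, falling back to within-particle row order
  when pose angles are absent or do not bin cleanly. The exact key used
  by the original ad-hoc awk workflow is not recoverable, so a
  deterministic rule is defined here instead.
* **Reflections are not applied**: the symmetry is C4, not D4. For
  binary patterns on a 4-ring mirroring happens to change nothing, but
  for general ring sizes it would, and `classifyPattern` supports
  general S (the tests cross-check S = 5, 6 against an enumeration
  oracle).
* **Integrity**: particles without exactly S rows of distinct subunit
  indices are excluded and counted, never repaired; included fractions
  sum to 1 to 10⁻¹².
* Exhaustive enumeration of the 16 binary 4-tuples gives class sizes
  {0: 1, 1: 4, 2-cis: 4, 2-trans: 2, 3: 4, 4: 1} — the invariant the
  implementation is tested against, alongside χ²-style recovery of
  generator frequencies at n = 10⁴.

STAR I/O is a small RELION-dialect reader/writer (no installed R
package provides one): `data_particles` blocks with `loop_` columns,
all columns preserved for round-tripping, floats printed at 12
significant digits so a read–write–read cycle preserves values.

# Structural metrics

Coordinates are read through bio3d (`read.pdb`/`read.cif`), with
alternate locations resolved to the highest occupancy, waters removed
by default, elements inferred from atom names when the element column
is absent, and Bondi-style van der Waals radii assigned from a
documented table (`vdwRadius`; unknown elements fall back to carbon's
1.70 Å).

* **Superposition** pairs atoms by chain/residue number/insertion
  code/atom name (residues missing in either model are dropped and
  counted), then computes the Kabsch least-squares rotation via SVD
  with the determinant correction that enforces a proper rotation.
  Degenerate inputs — fewer than 3 pairs, or collinear point sets — are
  errors. RMSD symmetry and invariance under rigid pre-transforms are
  asserted to 10⁻⁹, and the result is cross-checked against bio3d's
  independent `fit.xyz` implementation.
* **Buried interface area** uses Shrake–Rupley point-sampling SASA with
  a deterministic golden-spiral point set (default 960 points per atom,
  probe 1.4 Å). The reported `buriedPerSide` is
  $(SASA_A + SASA_B - SASA_{AB})/2$ — reading "contact surface" as one
  face of the buried interface — with the total ΔSASA also returned,
  since either convention is defensible. Accuracy: a single atom
  reproduces the analytic sphere area to float precision, two-sphere
  fixtures match the analytic buried-cap area within 2% at 960 points,
  and doubling the point count changes totals by well under 0.5%.
* **Domain rotation** superposes the two models on a rigid frame
  selection (e.g. the transmembrane domain), then decomposes the
  optimal rigid transform carrying one model's domain onto the other's
  into an axis–angle rotation, plus — when a reference axis such as the
  channel's four-fold axis is supplied — the quaternion twist about
  that axis and the translation along it. Constructed screw motions are
  recovered to <0.1° and <0.01 Å. The sign of the twist follows the
  right-hand rule about the supplied axis; "counterclockwise viewed
  from the cytosolic side" corresponds to a positive twist about the
  axis pointing from the membrane toward the cytosol.

The deposited-model comparisons (one Gαi3 chain against the channel
tetramer in 7X6I ≈ 690 Å² per-side buried area; channel-region Cα RMSD
8GVX vs 7E4T ≈ 0.557 Å; the ≈45° coiled-coil rotation between 7X6I and
8GVX) are expressed as an acceptance test that runs whenever the
coordinate files are placed under `inst/extdata/deposited/`; the files
themselves are several megabytes each and are not shipped. The exact
residue ranges behind the published numbers are unstated, so the test
uses the package defaults (Cα atoms of the channel chains) and accepts
either buried-area convention within tolerance.

# What the generators do and do not emulate

The synthetic generators reproduce the *statistical structure* each
stage assumes: exponential two-state dwells with filtered Gaussian
noise; Hill-form responses with additive noise clipped to [0, 1];
intensities satisfying the three-cube model exactly (plus optional
multiplicative noise); particle tables with exact symmetry expansion,
uniformly random rotational phase, and class draws from the specified
pattern frequencies; and point clouds under exact rigid motions. They
do **not** emulate amplifier artifacts (capacitance transients, seal
drift, baseline wander), state-dependent noise, spectral bleed beyond
the three-cube constants, pose-estimation error or per-particle defocus
effects, or real protein geometry. Passing tests therefore demonstrate
correctness of the computations under their stated models, not
robustness to every pathology of real recordings or micrographs.

# Problem sizes and determinism

All generators take an explicit integer seed and are bit-reproducible
under it. The test suite uses sizes chosen to make sampling error small
relative to the asserted tolerances while keeping the default run fast:
100-s records at 10 kHz (10⁶ samples) for open-probability recovery
(five records give a relative standard error of ~0.6%, comfortably
inside the 2% bias bound), 10⁴ particles for fraction recovery (3σ
binomial bands), 200 seeded replicates for noisy Hill recovery, and
960-point SASA spheres. Heavier runs (e.g. 10⁵-particle χ² checks)
reproduce the same behaviour and can be run by increasing the
respective arguments.

# Known limitations

* Two-state gating only; dwell-time distribution fitting, burst
  analysis and missed-event correction beyond dead-time merging are out
  of scope.
* The free-ion solver models 1:1 complexes only (no protonated ternary
  complexes, no ionic-strength recomputation); fidelity to any given
  calculator is bounded by the constant set supplied.
* The STAR parser targets the RELION 3.x particle dialect; cryoSPARC
  native files are assumed converted upstream.
* SASA treats atoms as hard spheres with the shipped radii; hydrogens,
  if present in a model, participate like any other atom, but deposited
  models typically lack them, and the published interface values were
  presumably computed without them.
* mmCIF support is limited by bio3d's reader (which handles
  atom_site-style coordinate tables; heavily annotated files may need
  conversion to PDB first).
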