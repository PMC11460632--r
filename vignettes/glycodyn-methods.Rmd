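---
title: "Methods: dynamic ensembles, docking and binding thermodynamics for modified HA oligosaccharides"
author: "glycodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic ensembles, docking and binding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodyn)
```

This vignette is the package's own account of its models and the choices
behind them: what is computed, under which assumptions, which parameters
matter, and where the limits are.

## 1. The dynamic torsion model

A reducing-end label attached by reductive amination opens the terminal
GlcNAc ring, turning a rigid pyranose into a flexible chain. The solution
behaviour of such a terminus is described here by a *dynamic torsion
model*: each rotatable bond either librates about a single mean
(`torsion_mode(mu, sigma)`, a wrapped-normal distribution in degrees) or
belongs to a *codependent group* whose member torsions switch together
between a small number of joint modes, each mode carrying one (μ, σ) per
torsion and an occupancy π.

The shipped model (`ha4_2aa_model()`) covers the 11 rotatable bonds of
the penultimate GlcA (G3), the opened GlcNAc (T4) and the 2-aminobenzoate
(X5). Its codependent group couples `T4 C2-C3`, `T4 C1-C2` and
`T4 C1-X5 NH11` across five modes with occupancies 0.35, 0.35, 0.22,
0.06 and 0.02 — the experimentally determined behaviour of this
chemistry. The remaining eight torsions are unimodal; their means and
widths (exo-anomeric glycosidic geometry, extended open-chain rotamers, a
planar internally hydrogen-bonded aminobenzoate) are *representative
template values* chosen once for the fixture, because the complete
per-torsion solution parameters live in supplementary material not
shipped with the package. They are stated in `ha4_2aa_model()` and can be
replaced wholesale via the JSON model schema.

Angles are degrees, IUPAC sign, wrapped to (−180, 180], matching how such
torsion tables are printed. Group occupancies must sum to 1: sums within
`1e-6` are renormalised silently (tables print 2-decimal fractions),
anything further is an error; after validation the invariant is enforced
at `1e-9`.

## 2. Conformer construction and sampling

Cartesian conformers are built by sequential internal-coordinate (NeRF)
placement: every atom is positioned from three previously placed
reference atoms by a bond length, bond angle and dihedral. Substituents
that ride on the same rotatable bond share its torsion name plus a fixed
offset, so a hydrogen across a bond from another keeps a constant
geometric offset from the named torsion — the property that makes
Karplus couplings functions of single model torsions (Section 4).

Closed pyranose rings are treated as rigid bodies: their dihedrals are
fixed at idealised ⁴C₁-chair values and standard carbohydrate bond
lengths/angles (C–C 1.52 Å, C–O 1.43 Å, sp³ 109.5°, aromatic 1.39 Å/
120°). Ring-closure bonds are listed but not imposed, which is the usual
trade-off of tree-structured construction; since rings never move, no
test quantity depends on closure accuracy. The glycosidic φ/ψ of the
anchor (closed) region are fixed placeholder values: the bound-state
anchor geometry comes from prior work whose deposited coordinates are not
shipped, and the docking layer accepts user-supplied anchor references
for exactly this reason.

`generate_ensemble(model, topology, n, seed)` draws, per conformer, all
unimodal torsions then each group (one categorical mode draw, then
wrapped-normal libration draws). Draw order is fixed and one RNG stream
is used per ensemble, so ensembles are pure functions of
(model, topology, n, seed) and anchors are bitwise identical across
conformers. The ensemble size used throughout the structural analyses is
250, the size at which per-mode boxplot statistics are reported.

Libration is sampled as a wrapped normal; for σ ≤ 20° this is
indistinguishable from a von Mises with κ = (180/πσ)², and all shipped
widths are ≤ 20°.

Chirality is guarded by signed volumes at three stereocentres of the
opened chain, asserted constant across every sampled conformer.

## 3. The pocket fixture and rigid docking

Docking is deliberately minimal, mirroring a rigid protocol: the
protein groove never moves, the ligand never flexes — poses differ only
through the sampled terminus. `superpose_anchor()` performs a
least-squares rigid fit (SVD/Kabsch with the determinant correction, so
reflections are never used) of the ligand anchor onto the pocket's
anchor reference and reports the residual RMSD.

`score_pose()` decomposes a pose into the three named components:

* **Hydrogen bonding** — a distance-damped well per donor/acceptor–polar
  atom pair: depth 4.0 at 2.9 Å, quadratically damped to zero at 4.5 Å.
  Cation sites pair with carboxylate oxygens only (charge-assisted
  hydrogen bonds, the salt-bridge energetics).
* **Van der Waals** — a soft 4–8 potential against steric sites (clash
  side capped, growing with the inverse-distance eighth power) plus
  shallow attractive 4–8 wells of aromatic/hydrophobic sites against the
  label's aromatic carbons.
* **Torsion strain** — `k(1 − cos(θ − μ_nearest))` with k = 0.5 per
  sampled torsion, μ_nearest the nearest mode mean in the dynamic model.

`total` is their sum; *favorability* = −total, so higher is more
favourable. Absolute values are arbitrary units — only orderings and
per-mode groupings carry meaning, which is why the acceptance of this
layer is ordinal (which mode wins) rather than numeric.

The `link_tsg6_groove` fixture (`make_pocket_fixture()`) is built
deterministically around the mode-2 centroid conformer of the HA6-2AA
template: a cation site (arginine surrogate) at the hydrogen-bond optimum
from the mode-2 carboxylate position, an aromatic shelf and three
hydrophobic spheres framing the aminobenzoate ring, and a steric wall
behind the cation. By construction, mode-2-like reducing-terminal
geometry reaches the cation site (salt-bridge distance ≤ 4 Å, inclusive);
the other modes rotate the carboxylate away from it. The fixture encodes
the qualitative geometry of a Link-module groove — one salt-bridge donor
next to a hydrophobic specificity pocket — not its real coordinates; the
docking layer accepts measured pocket descriptions through the same
interface.

## 4. NMR observables and population recovery

**NOE distances.** `r_eff = (Σ w_i r_i^{-6})^{-1/6}` over conformers,
uniform weights by default (conformers are already drawn from the
occupancies). Short distances dominate; `r_eff` is monotone
non-increasing when any one conformer distance decreases.

**Scalar couplings.** `J(θ) = A cos²θ + B cosθ + C`, averaged linearly
over the ensemble. The default coefficients (9.5, −1.6, 1.8 Hz) are a
standard HCCH parameterisation and are configurable, since Karplus
curves are re-parameterised per coupling pathway.

**Restraint checking.** NOE satisfied iff `r_eff ≤` upper bound; noNOE
iff `r_eff ≥` lower bound; couplings iff within their stated tolerance;
hydrogen-bond records (and temperature-coefficient records carrying a
donor/acceptor pair) are checked geometrically — donor–acceptor ≤ 3.5 Å
and donor-H⋯acceptor angle ≥ 120° in at least half the conformers. A
temperature coefficient is evidence *for* a hydrogen bond, not a
geometric observable, so its stored value (−2.6 ppb/K for the aniline
proton) is provenance; the geometric criterion is the validation
surrogate.

**Population recovery.** `fit_mode_populations()` inverts
population-sensitive observables to the occupancy vector π on the
probability simplex, minimising summed squared violations: coupling
residuals two-sided, NOE/noNOE as one-sided hinges. Because couplings
and r⁻⁶ intensities average linearly in π, per-mode observables are
computed once: coupling rows *analytically* (each shipped pathway rides
exactly one model torsion, so its per-mode expectation is a 1-D
wrapped-normal integral, evaluated by dense quadrature), NOE rows from
single-mode ensembles. The optimiser is deterministic: exhaustive
enumeration at a coarse resolution (default 0.05), an exact
equality-constrained least-squares solve on the coupling rows
(enumerating active sets of zeroed modes; among exact minimisers the
solution closest to uniform is taken), snapping to the target grid
(default 0.01) by largest-remainder rounding, then pairwise
mass-transfer polish at grid resolution with ties broken toward uniform.

Two honest limitations, both consequences of the physics rather than the
implementation:

* *Karplus symmetry.* J is even in cos θ, so J(−60°) = J(+60°): the
  backbone pathways alone cannot distinguish mode 1 from modes 2–3, and
  only the aniline-proton pathways separate all five modes. The
  resulting design matrix has one weakly determined simplex direction
  (fourth singular value ~10⁻² of the leading one). With exact
  (zero-noise) coupling targets the recovery is still exact to the grid;
  with 0.5 Hz coupling noise, errors along the weak direction reach
  0.1–0.2 in occupancy. Real studies break this degeneracy with many
  more restraints (the full sets run to ~144) and heteronuclear
  couplings, which are out of scope here.
* *Finite-ensemble NOE noise.* Simulated NOE bounds are finite-ensemble
  r⁻⁶ averages, a heavy-tailed statistic; they validate self-consistency
  (a generating ensemble satisfies its own zero-noise restraints by
  construction) but add sampling noise to the inverse problem, so the
  exact-recovery check uses coupling-only sets, with `simulate_restraints
  (model = ...)` generating targets as exact ensemble-law expectations.

## 5. Binding thermodynamics

**ITC forward model.** Single-site isotherm with perfusion (overflow)
bookkeeping: after cumulative injected volume v, the cell retains
`exp(−v/V₀)` of its original content, binding sites are
`N·M₀·exp(−v/V₀)`, ligand `X_s·(1 − exp(−v/V₀))`, the bound
concentration is the analytic quadratic root, and injection heats credit
newly formed complex while letting displaced complex leave silently.
Under this convention a few percent of protein is displaced *unbound*
during the pre-saturation injections, so total heat falls slightly short
of the ideal `N·ΔH·(cell protein moles)`; the alternative `"overfill"`
convention (cell volume grows, nothing leaves) satisfies that
conservation bound exactly and is available via
`wiseman_heats(convention = "overfill")`. The default schedule is
18 × 2 μl of 0.29 mM ligand into 200 μl of 0.029 mM protein at 25 °C —
c ≈ 28 for a 1.1 μM site, comfortably inside the 5–500 window where the
isotherm is informative.

**ITC fitting.** The dilution offset is estimated as the mean of the
final three injection heats, as is conventional. Those final injections
still contain a little binding heat at c ≈ 28, so `fit_itc()` applies
the same last-three-mean subtraction to the model prediction inside the
least-squares objective; the estimator is then exact on offset-shifted
forward-model data instead of inheriting a small systematic bias.
Optimisation is Levenberg–Marquardt on (log K_D, ΔH, N) over a
deterministic start grid (K_D ∈ {0.01, 0.1, 1, 10, 100} μM ×
ΔH ∈ {−20, −10, −5, −1} kcal/mol, N = 1); uncertainties come from the
fit covariance with the delta method on log K_D.

**MST.** Responses are `baseline + amplitude · fraction_bound`, with the
fraction bound from the exact 1:1 quadratic (no free-ligand
approximation — immaterial at 10 nM receptor, but exact is free). The
titration emulates a 16-step 1:1 dilution from 5 mM, spanning
0.15 μM–5 mM. Response units are ‰ (per mil), the instrument convention.

**Derived quantities.** `ΔG = RT ln(K_D/1 M)` with
R = 1.98720425×10⁻³ kcal mol⁻¹ K⁻¹ and T = 298.15 K for 25 °C — this
choice reproduces printed free energies to 2 dp from printed K_D values;
`−TΔS = ΔG − ΔH`; `%K_B = 100·K_D(unmodified)/K_D(modified)` (an
association-constant ratio); discrimination = ratio of the two proteins'
%K_B, undefined (NA, not an error) when either is missing. All internal
arithmetic is full precision; rounding happens only at display. Published
tables occasionally disagree with ratios of their own printed values by
1–2 units because they were computed from unrounded per-replicate fits
(e.g. a printed 192 versus 191 from the rounded K_D pair, or a printed ΔG
that matches the replicate-mean ΔG rather than the ΔG of the mean K_D);
the package computes from the supplied precision and the tests treat
those entries as documented near-misses.

## 6. Synthetic data and what passing tests show

Every generator is a pure function of (truth, seed) and serialises a
truth record next to its dataset. Noise defaults: ITC 1% of the largest
heat (plus a constant dilution offset drawn once), MST 2% of the
amplitude, couplings 0.3 Hz — low-noise modern instruments; all
overridable.

The generators emulate the *design* of the real experiments (schedules,
concentrations, series, restraint kinds and counts), not their full
physics: no baseline drift or injection-shape effects in ITC, no
thermophoresis kinetics in MST, no spin diffusion or mixing-time
dynamics behind NOEs, Gaussian noise everywhere. Passing recovery tests
therefore demonstrates that the estimators are correct and well-behaved
under the stated models — not that real data of this quality will yield
parameters this accurate.

## 7. Problem sizes, determinism, degenerate inputs

Test and acceptance runs use: ensembles of 250–300 conformers (250 for
docking, matching the reported ensemble size), 10,000 draws for the
sampling-law check, 50 seeds for the noisy fit studies, 50 conformers
per single-mode ensemble in population recovery (coupling rows are
analytic, so this only feeds the NOE rows), and occupancy grids of 0.05
(coarse) / 0.01 (fine). These sizes keep the default suite fast while
leaving every stochastic assertion comfortably inside its statistical
bound.

Determinism: single seed per generator; ensembles, pockets, rankings and
pipeline outputs are bit-reproducible (manifests record md5 content
hashes; reruns with identical configuration produce identical hashes).
Tie-breaks are explicit everywhere: ranking by conformer index,
population fits toward uniform.

Degenerate inputs are rejected with informative errors: collinear
reference triples and dihedrals, fewer than three superposition
correspondences, all-zero thermograms, flat dose-responses, non-positive
concentrations, occupancy sums beyond tolerance, unknown pocket presets.

## 8. Known limitations

* Anchor φ/ψ and the unimodal torsion parameters are template values
  (Section 1); conclusions about *real* terminal geometry require the
  measured model via the JSON schema.
* The scoring function is a three-component surrogate with documented,
  configurable parameters — suitable for ordinal questions (which mode
  fits the groove), not for binding-energy estimation.
* Ring puckering, ligand flexibility beyond the listed torsions,
  explicit solvent and protein motion are all out of scope by design.
* Population recovery is limited by the identifiability of the restraint
  design (Section 4); the package reports the objective trace so users
  can see flat directions for themselves.
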