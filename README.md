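# glycodyn

Conformer-ensemble modelling, restraint validation, rigid docking and
binding thermodynamics for chemically modified hyaluronan (HA)
oligosaccharides.

## The scientific problem

Short HA oligosaccharides (repeating GlcA–GlcNAc disaccharides) can be
labelled at their reducing end by reductive amination, which opens the
reducing GlcNAc ring and attaches an amine label such as 2-aminobenzoic
acid (2AA). The opened ring gains rotatable bonds, so the labelled
terminus is conformationally dynamic: NMR shows that three of its
backbone torsions move *codependently*, jointly occupying a small number
of librational modes, each with mean angles μ, libration widths σ and an
occupancy π. Whether such a label helps or hurts binding to an HA-binding
protein — for example the Link module of TSG-6 (`Link_TSG6`), whose
groove offers an arginine for a salt bridge to the label's carboxylate,
versus the CD44 HA-binding domain, which binds HA without ionic contacts —
depends on whether the highly populated solution conformers place the
label's functional groups where the protein can use them.

`glycodyn` implements that analysis chain as reusable, tested R:

* **Dynamic torsion model** — unimodal torsions plus codependent
  multimodal groups (μ, σ, π), with a JSON/CSV schema, validation, and a
  shipped five-mode model of the 2AA-modified terminus
  (`ha4_2aa_model()`, occupancies 0.35/0.35/0.22/0.06/0.02).
* **Conformer builder** — internal-coordinate (NeRF) construction of
  Cartesian conformers from topology templates (`ha_topology()`), seeded
  wrapped-normal torsion sampling, rigid closed-ring anchors, and a
  multi-model PDB writer/reader (`generate_ensemble()`,
  `write_ensemble_pdb()`).
* **NMR observables** — r⁻⁶-averaged NOE distances
  (`ensemble_noe_distance()`), Karplus ³J couplings (`karplus_3j`,
  `J = A cos²θ + B cosθ + C`), restraint satisfaction reports
  (`check_restraints()`) and grid-based recovery of mode occupancies from
  restraints (`fit_mode_populations()`).
* **Docking** — least-squares anchored superposition (Kabsch, proper
  rotation only) into a binding-groove pocket, with component scoring
  (hydrogen-bond well, soft 4–8 van der Waals, torsion strain
  `k(1−cos(θ−μ))`), salt-bridge detection (carboxylate O within 4 Å of a
  cation site) and per-mode boxplot statistics (`rank_ensemble()`).
  Scores are arbitrary units; only orderings are meaningful, reported as
  favorability (higher = better).
* **Binding thermodynamics** — single-site Wiseman ITC isotherm with
  perfusion-cell bookkeeping (`wiseman_heats()`, `fit_itc()`), exact 1:1
  MST binding model (`mst_fraction_bound()`, `fit_mst()`),
  `ΔG = RT ln K_D`, `−TΔS = ΔG − ΔH`, percent binding affinity
  `%K_B = 100·K_D(ref)/K_D(mod)` and protein-vs-protein discrimination
  tables (`build_affinity_table()`), alongside the published reference
  dissociation constants (`reference_affinities()`).
* **Synthetic data** — every input simulated with known ground truth and
  a serialised truth record: ITC thermograms (18 × 2 μl of 0.29 mM
  ligand into 200 μl of 0.029 mM protein), 16-step 1:1 MST dilution
  series from 5 mM, restraint sets forward-simulated from ensembles, and
  the deterministic Link-module groove pocket fixture.
* **Pipelines** — `run_structural()` (sample → build → dock → report)
  and `run_thermo()` (fit every titration, replicate mean ± SEM summary),
  each writing a manifest of output hashes for bit-reproducibility.

## Worked example

```r
library(glycodyn)

model <- ha4_2aa_model()
model
#> Dynamic torsion model: 8 unimodal torsion(s), 1 codependent group(s)
#>   group 'T4-X5': 3 torsions x 5 modes; pi = 0.35, 0.35, 0.22, 0.06, 0.02

topo   <- ha_topology(6, "2AA")
pocket <- make_pocket_fixture(topology = topo, model = model)$pocket
ens    <- generate_ensemble(model, topo, n = 250, seed = 1)
rank_ensemble(ens, pocket, model)
#> Docking result: 250 poses; top pose conformer 199 (mode 2),
#>   favorability 11.897, salt bridge: yes
#> Per-mode favorability summary:
#>  mode   n        mean          q1         q3         min        max
#>     1 100 -9.30078520 -21.4968871  0.1584569 -44.4594703  0.6597932
#>     2  86  8.75949207   7.6286642 10.8279332  -6.0147544 11.8971349
#>     3  41 -0.39271792  -3.1758940  3.7848872 -19.3938337  8.2255543
#>     4  17 -0.07009674  -0.4423842 -0.1317878  -0.6669948  3.6052960
#>     5   6  0.44558302   0.2989604  0.5369621   0.1682594  0.7179456
```

The 250-conformer ensemble samples the five modes in proportion to their
occupancies (counts 100/86/41/17/6). Mode 2 — one of the two most
populated solution conformers — docks best on average and supplies the
top-ranked pose, whose 2AA carboxylate sits within salt-bridge distance
of the groove's arginine surrogate: the solution-dominant shape is also
the protein-complementary one.

```r
sim <- simulate_itc(kd = 1.09e-6, dh = -8.29, n = 1.04,
                    noise_sd = 0.01, seed = 1)
fit_itc(sim$data)
#> Binding result: KD = 1.202 uM, dG = -8.08, dH = -8.44,
#>   -TdS = 0.36 kcal/mol, N = 1.046
itc_c_value(1.202e-6, 1.046, sim$data)  # ~25: well inside the 5-500 window
```

A thermogram simulated at 1% heat noise under the standard injection
schedule refits to within a few percent of its generating parameters;
at zero noise the recovery is exact to 0.1%.

```r
ref <- reference_kd_table()
tab <- build_affinity_table(ref)
subset(tab, oligo == "HA6" & modification == "3AA")
#>  oligo modification percent_Link_TSG6 percent_CD44_HABD discrimination
#>    HA6          3AA               218          11.49554       18.96388
#>  hc_substrate
#>            No
```

The 3AA-modified hexasaccharide binds Link_TSG6 at 218% of the
unmodified oligomer while dropping to ~11% for CD44 — a ~19-fold swing
in relative affinity between the two proteins.

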