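---
title: "pH-sensitive protein-protein docking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pH-sensitive protein-protein docking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phdock)
```

## The problem

Protein-protein association depends on solution pH: the side chains of
Asp, Glu, His, Tyr and Lys titrate, and binding can shift their preferred
ionization state — a buried His-carboxylate salt bridge only exists while
the His is charged. A docking algorithm that fixes protonation states at
their pH 7 defaults cannot rank such interfaces correctly, and it cannot
explain pH-dependent affinity switches such as the neonatal Fc receptor
releasing IgG as the environment changes from the acidic gut to the
basic bloodstream.

`phdock` implements a local rigid-body docking protocol that samples
side-chain protonation states *during* the search: every side-chain
packing step chooses jointly over discrete rotamers and ionization
variants at the user-supplied pH. The package also implements the full
evaluation stack used to judge such protocols — CAPRI quality metrics,
docking-funnel discrimination score, N5 and bootstrap resampling — plus a
pH-scan analysis that converts interface-score differences into
equilibrium-constant ratios.

## The protonation model

Each ionizable residue type carries an intrinsic (model-compound) pKa:
Asp 4.0, Glu 4.4, His 6.3, Tyr 10.0, Lys 10.4. Cys (intrinsic pKa 8.5) is
never titrated because its ionization couples to redox equilibrium. The
probability of protonation follows the Henderson-Hasselbalch form

$$P_{\mathrm{prot}} = \frac{1}{1 + 10^{\,\mathrm{pH} - \mathrm{IpKa}}},$$

and the pH score term is the Boltzmann inversion of the state
probability, $E_{\mathrm{pH}} = -k_BT \ln P_{\mathrm{state}}$ with
$k_BT = 0.59$ kcal/mol (298 K). The implementation evaluates this in
log-space, $E_{\mathrm{pH}} = k_BT\,\ln(1 + 10^{\pm(\mathrm{pH}-\mathrm{IpKa})})$,
which is exact, keeps the one-decade-per-pH-unit property to machine
precision, and avoids overflow; a configurable cap (default 15 kcal/mol)
bounds the term at extreme pH. The Henderson-Hasselbalch probability and
its Boltzmann inversion are the package's adopted functional forms for a
protonation potential built from the probability of protonation; they
are stated explicitly here because the forms are part of the model
definition.

States are represented as discrete packer variants: His has two neutral
tautomers (proton on ND1 or NE2) plus the doubly protonated +1 form;
protonated Asp/Glu place the carboxyl proton on either terminal oxygen
(three variants each); Tyr and Lys have two variants each. The tautomer
and proton-placement degeneracy matters because the variants have
identical $E_{\mathrm{pH}}$ but different hydrogen-bonding geometry.

```{r}
enumerate_variants("HIS")
protonation_probability("HIS", 6.3)
ph_energy("HIP", 7.0)   # charged His one pH unit above its pKa
```

## The energy model

The weighted total score combines, over atom pairs within 6 Å (pairs
within a residue or between sequence-adjacent residues are excluded):

* **van der Waals**, a 12-6 Lennard-Jones split at the potential minimum
  into an attractive part (constant at the well depth inside the
  minimum) and a repulsive part (zero outside it);
* **solvation**, an isotropic Lazaridis-Karplus Gaussian-exclusion term
  with per-class $\Delta G_{\mathrm{free}}$, correlation length
  $\lambda$ and volume;
* **hydrogen bonds**, a distance-angle product
  $f(d_{HA})\,g(\theta_{DHA})$ with a well centered at 1.9 Å (zero
  beyond 2.6 Å), an angular ramp from 120° to 180°, and a minimum of
  −1.5 kcal/mol;
* **electrostatics**, Coulomb with a distance-dependent dielectric
  $\varepsilon = 10r$ (constant 332.064 kcal·Å/mol·e²), the distance
  clamped to [1.45, 5.5] Å and the energy shifted to zero at the outer
  edge — the clamp window is common practice for this functional form
  and keeps energies bounded;
* one-body terms: the rotamer-probability term $-\ln p$ over the
  packaged library, and $E_{\mathrm{pH}}$.

The pH-aware weight set is {atr 0.377, rep 0.005, sol 0.225, hb 0.249,
dun 0.080, elec 0.319, pH 0.21}; the pH-blind reference set is
{atr 0.338, rep 0.044, sol 0.242, hb 0.245, dun 0.036, elec 0.026}. The
statistical residue-pair term present in older score functions is absent
(weight 0 in every preset; its role is absorbed by the raised
electrostatics weight). Because the repulsive weight is tiny during
sampling, the repulsive weight is raised to 0.044 during minimization,
and the worst 5% of models by repulsive score are removed before
ranking.

**Parameter provenance.** The per-atom Lennard-Jones radii and well
depths, solvation classes and partial charges are a small packaged
table, not a copy of any production force field: only polar hydrogens
are explicit (the EEF1 united-atom convention that the solvation model
comes from), charges are group-based with integral formal charges on
ionized groups, and solvation reference energies per protonation variant
default to zero (exposed for recalibration). The magnitudes were fixed
once, before the test suite was frozen, by one calibration criterion: a
solvent-exposed His-carboxylate model pair must titrate within about one
pH unit above the His intrinsic pKa, the physically expected behavior
for a weakly coupled salt bridge. With the packaged table the bound
fixture pair flips between pH 6.3 and 6.5. Absolute energies are
therefore not comparable to any production force field; all package
results are relative scores in Rosetta-energy-unit-like units (REU).

## Interface score

The interface score of a two-partner complex is, per term,
$E_i^I = E_i(\mathrm{complex}) - \sum_j E_i(\mathrm{partner}_j)$, where
each separated partner is rescored after repacking its ionizable
interface residues (side chain and protonation) at the solution pH —
separation exposes previously buried residues to solvent and can change
their preferred ionization state. Interface residues are those with any
heavy atom within 4 Å of the other partner. The weighted sum of the
per-term contributions is the interface score (Isc), the package's proxy
for binding free energy.

## The docking protocol

1. **Prepack**: partners are separated beyond interaction range, all
   ionizable side chains packed at the solution pH, and the input
   placement restored.
2. **Initial perturbation**: the ligand is translated by up to 3 Å
   (uniform in the ball) and rotated by up to 8° about the axis joining
   the partner centers — the local-docking starting ensemble.
3. **Low-resolution stage**: side chains are collapsed to centroid
   pseudo-atoms and the ligand makes Gaussian rigid-body moves
   (0.7 Å / 5° defaults) accepted by the Metropolis criterion at 0.8 REU.
   The centroid score is a smooth saturating contact attraction
   (about −1 per cross-partner centroid pair, switching off near 6 Å)
   plus a soft quadratic clash penalty below 3.5 Å. A linear −0.1 per
   contact step function was tried first and rejected: at desk-scale
   interface sizes (a handful of contacts) its energy scale is far below
   the Metropolis temperature and the search diffuses apart; any
   monotone packing-favoring score satisfies this stage's contract, and
   the saturating form gives the search a restoring gradient.
4. **Restore side chains**: rotamers and protonation labels from the
   prepacked structure are placed on the post-centroid rigid-body pose.
5. **High-resolution stage**: cycles of {small rigid-body move → repack
   ionizable interface side chains with protonation sampling → minimize
   rigid-body and chi degrees of freedom with the raised repulsive
   weight → Metropolis check}; the lowest-scoring accepted structure is
   the trajectory's model.
6. **Ranking**: models are ranked by interface score; the worst 5% by
   repulsive score are removed first.

Controls: `mode = "ph7"` forces pH 7.0, and `mode = "fixed-protonation"`
equilibrates once during prepack and freezes the labels afterwards.

### Packing and minimization

The packer optimizes one rotamer-by-protonation choice per designable
residue. The rotamer library is packaged and backbone-independent: ideal
chi wells (gauche±/trans per rotatable bond, at most 81 chi combinations
per residue) with uniform within-well priors, so the rotamer term is
$-\ln(1/n)$; the input conformation is always included as an extra
rotamer. A backbone-dependent library would change the priors but not
the algorithmic contract (discrete sampling with simultaneous variant
choice). Systems with at most 2000 combined combinations are solved by
exhaustive enumeration (ties broken by lowest rotamer index); larger
systems use simulated annealing (geometric cooling, kT 5 → 0.3 over 20
sweeps) with best-visited tracking. Minimization is gradient-free
Nelder-Mead descent over the ligand rigid-body placement and selected
chi angles at 10⁻³ REU-scale tolerance; protonation states stay fixed
during minimization (packing, which runs every cycle, handles state
changes).

## Metrics and funnel statistics

Lrmsd is ligand-CA RMSD after receptor-CA superposition; Irmsd is CA
RMSD over the native-defined interface residues of *both* partners
(<4 Å heavy-atom contact) after superposition on that same set; fnat is
the fraction of native cross-partner residue contacts (<5 Å minimal
heavy-atom distance) recovered. Contact definitions use heavy atoms only
because crystal references typically lack hydrogens. The CAPRI rating
applies, in order: high (fnat ≥ 0.5 and Irmsd ≤ 1 or Lrmsd ≤ 1), medium
(fnat ≥ 0.3 and Irmsd ≤ 2 or Lrmsd ≤ 5), acceptable (fnat ≥ 0.3 and
Irmsd ≤ 4). A strict mode additionally admits the standard wider
acceptable tier (fnat ≥ 0.1 with Lrmsd ≤ 10).

The discrimination score D normalizes interface scores by mapping the
5th/95th linear-interpolation percentiles to 0/1 (normalized scores may
fall outside [0, 1] for extreme models — only the anchors are pinned);
for each Irmsd cutoff in {1, 1.5, 2, 2.5, 3, 4, 6} Å with models on both
sides, the gap is the minimum normalized score below the cutoff minus
the minimum above it, and D is the mean gap over usable cutoffs. Cutoffs
with an empty side are skipped (reducing the cutoff count) rather than
raising an error, since the average is taken over the usable cutoffs.
D ≤ 0 marks a successful funnel. N5 counts models within 4 Å Irmsd among
the five top-scoring models (success at N5 ≥ 3). Both statistics carry
bootstrap case-resampling means and standard deviations (default 1000
resamples).

## The synthetic fixtures

All tests run on deterministic ideal-geometry fixtures; no external
structures are needed. Chains are short poly-Ala alpha-helices
(phi −57°, psi −47°) with substituted interface residues built from
internal-coordinate templates. The salt-bridge dimer places a His on the
receptor and an Asp on the ligand with the ring nitrogen 2.8 Å from the
carboxylate oxygen, so tight binding requires the protonated His — a
synthetic analogue of the His-carboxylate switches that drive
pH-dependent receptor release. The decoy generator produces rigid-body
perturbed copies of a native with realized Irmsd within 15% of requested
targets, giving controlled near-native/non-native mixtures for funnel
tests.

What the fixtures do **not** emulate: real interface sizes (hundreds of
contacts), backbone flexibility, buried cores, water-mediated hydrogen
bonds, or crystallographic noise. Passing tests therefore demonstrate
that the algorithms implement their contracts and reproduce the
qualitative pH physics on controlled systems — not benchmark-scale
accuracy on real complexes.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale runs chosen as
the package's own defaults for its synthetic systems: 100-model funnels
(30 centroid cycles, 4 high-resolution cycles) and 50-model pH scans per
grid point (20/2 cycles); the titration scan grid is
{4.5, 5.5, 6.5, 7.5, 8.5} around the His pKa. Full-size runs (1000
models, 500/50 cycles) are the `dock_config()` defaults. Other
numerical choices: alternate PDB locations resolve to highest occupancy
(ties to the first record); hydrogens present in an input file are kept
when their names match the expected set for the inferred protonation
state and rebuilt at ideal geometry otherwise, so that write/read round
trips preserve coordinates to 10⁻³ Å; chain-initial backbone amide
hydrogens are not built (termini are not titrated); equal-energy
rotamers resolve to the lowest index; the same RNG seed is reused across
pH-scan grid points so that pH is the only varying factor.

## Weight refitting

`fit_weights()` reproduces the reweighting recipe: models in the top 5%
by CAPRI rating (high > medium > acceptable, ties by higher fnat),
restricted to repulsive scores below the 80th percentile, are labeled
near-native; weights separating the classes on per-term interface
values are fitted by non-negativity-constrained logistic regression and
normalized to sum 1. Near-perfect class separation makes the
unpenalized likelihood unbounded, so the implementation uses a
ridge-stabilized path and reports the smallest converged penalty — the
calibration recipe only fixes a generalized linear model maximizing the
class gap, so the ridge path is the package's documented choice.
The reported gap is the mean weighted score difference between classes
(antisymmetric under relabeling).

## Worked example

```{r, eval = FALSE}
native <- make_fixture("salt_bridge_dimer", ph = 4.5)
cfg <- dock_config(ph = 4.5, n_models = 100, lowres_cycles = 30,
                   highres_mcm_cycles = 4, min_iter = 40, seed = 11)
run <- dock(native, native = native, cfg = cfg)
run <- filter_models(run, "phdock")
summary(run)     # D, N5, bootstrap spreads, CAPRI counts
plot(run)        # interface score vs Irmsd funnel
```

The affinity-ratio analysis treats the top-model interface score as a
binding free energy: $K_a/K_b = \exp((I_b - I_a)/k_BT)$, reading REU as
kcal/mol — a convention worth flagging, since REU are not strictly
kcal/mol; only ratios under this convention are meaningful.

```{r}
k_ratio(-13.99, -11.82)   # ~40-fold affinity drop
```

## Known limitations

* Coupled-site titration (mutual pKa shifts solved self-consistently) is
  not modeled; each site chooses its state within the packer.
* Arg, Cys and chain termini never titrate.
* The packaged parameter table is a calibrated stand-in; absolute
  energies are not transferable.
* Backbone flexibility is limited to user-supplied conformer ensembles
  (one conformer chosen per trajectory); there is no backbone
  refinement.
* Global (non-local) docking is out of scope: the search assumes a
  near-native starting placement.
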