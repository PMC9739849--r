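---
title: "Modeling vibronic spectra from MD ensembles with the perturbed matrix method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling vibronic spectra from MD ensembles with the perturbed matrix method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmvib)
```

## The model

`pmmvib` reconstructs absorption and emission spectra of a chromophore (the
*quantum center*, QC) embedded in a classical environment of point charges,
typically snapshots of an explicit-solvent MD trajectory. Three layers make
up the model.

**Perturbed electronic Hamiltonian.** In the basis of the gas-phase
(*unperturbed*) electronic eigenstates, the Hamiltonian at one snapshot is

$$\tilde H_{jl} = \Big(U_j^0 + \sum_N q_{N,j}^0\, V(R_N) + \Delta V\Big)\,
  \delta_{jl} \;-\; \mathbf E(\mathbf r_0)\cdot
  \boldsymbol\mu^0_{jl}\,(1-\delta_{jl}),$$

where $U_j^0$ is the unperturbed electronic energy, $q^0_{N,j}$ the ESP
charge of atom $N$ in state $j$, $V(R_N)$ the environment electric potential
at that atom, $\mathbf E(\mathbf r_0)$ the environment field at the QC mass
center, and $\boldsymbol\mu^0_{jl}$ the electronic dipole matrix elements
(rotated into the lab frame by the mass-weighted superposition of the
reference geometry onto the snapshot coordinates). $\Delta V$ is a
state-independent scalar: it shifts every diagonal element equally and can
never change transition energies or eigenvectors, so it defaults to 0 and is
only reported. Diagonalizing $\tilde H$ per frame yields perturbed energies,
vertical transition frequencies $\nu_i=(E_i-E_0)/h$, transition dipoles
$\mu_{0,i}$, and squared projections of every perturbed state on the
unperturbed basis.

**Vertical spectra from ensemble statistics.** Per-frame vertical
frequencies are histogrammed into bins of width `bin_width`; each occupied
bin contributes a unit-area Gaussian of width `sigma` weighted by its frame
fraction and mean squared transition dipole. The absorption prefactor is the
Einstein absorption coefficient $|\mu|^2/(6\epsilon_0 c \hbar^2)$ with the
photon-energy factor $h\nu$ (so the extinction signal scales as
$\nu|\mu|^2$); the emission prefactor is
$8\pi h |\mu|^2/(6\epsilon_0\hbar^2)$ with the spontaneous-emission factor
$(\nu/c)^3$. A dedicated test pins this $(\nu/c)^3$-versus-$h\nu$ factor
pair through the symbolic emission/absorption intensity ratio.

**Simplified Franck–Condon structure.** Quantum modes of the two electronic
states with near-identical frequencies are treated as *identical* except for
a displaced minimum along the shared mode coordinate. The multi-mode squared
overlap then factorizes into single-mode integrals, and each single-mode
squared overlap between the initial vibrational ground state and the final
$k$-quantum state is the Poisson weight

$$|\langle 0 | k\rangle|^2 = e^{-S}\frac{S^k}{k!},\qquad
  S_n = \tfrac12\,\Delta_n^2,$$

with $\Delta_n$ the dimensionless displacement of mode $n$ (the Huang–Rhys
factor $S_n$). Completeness of the final-state vibrational basis enforces
the sum rule $\sum_m |\langle\phi_{0}|\phi_m\rangle|^2 = 1$, which the
threshold-pruned enumeration reports as its `captured` fraction. Each
vibronic transition contributes a copy of the sub-ensemble vertical spectrum
scaled by its squared overlap and rigidly translated so its maximum sits at

$$\nu_m = \nu_m^0 + \nu_{el} - \nu_{el}^0,$$

with $\nu_m^0$ the (0-0-corrected) unperturbed vibronic frequency,
$\nu_{el}$ the perturbed band maximum and $\nu_{el}^0$ the unperturbed
vertical frequency. Sub-ensemble spectra are summed with their ensemble
weights, then over electronic transitions.

## Mode analysis and the quantum/semiclassical split

Normal modes come from the mass-weighted Cartesian Hessian after explicit
projection of the six translation/infinitesimal-rotation vectors
(Eckart-style; five for linear geometries). Internal modes with vibrational
quantum $h\nu > k_BT$ are *quantum* and carry the Franck–Condon treatment;
modes with $h\nu \le k_BT$ — and any negative-curvature mode, the typical
signature of a cheaper Hessian evaluated at a higher-level minimum — are
*semiclassical*: their broadening is absorbed by the Gaussian width
$\sigma$. Roto-translations are always semiclassical.

The Duschinsky matrix $J = A^\top B$ of inner products between the internal
mode vectors of the two states measures how well the shared-mode assumption
holds. Mode pairing maximizes the total squared element by optimal
assignment (a Hungarian solver; deterministic and order-independent, unlike
greedy matching), and pairs with $J^2$ below `diagonality_threshold`
(default 0.7) are flagged with a warning rather than rejected — the method
assumes near-diagonality but no hard cutoff exists. Dimensionless
displacements use the *final-state* frequency of each pair (excited state
for absorption, ground state for emission); under the identical-mode
assumption the paired frequencies agree, so this choice is second order.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `temperature` | 300 | K | quantum/semiclassical partition ($h\nu$ vs $k_BT$) |
| `sigma` | 4e-4 | frequency a.u. (0.068 eV) | Gaussian broadening of semiclassical motion |
| `bin_width` | `sigma/2` | frequency a.u. | vertical-frequency binning |
| `fc_threshold` | 1e-8 | — | minimum squared overlap retained |
| `max_total_quanta` | 30 | — | cap on excited quanta per transition |
| `identity_threshold` | 0.8 | — | squared projection identifying a perturbed state |
| `exp_00` | none | eV | experimental gas-phase 0-0 anchors |

`sigma` is a configuration constant here; estimating it from semiclassical
sampling of the chromophore is out of scope. `bin_width = sigma/2` keeps the
binned spectrum below the Gaussian resolution: halving the bin width then
changes the broadened spectrum by well under 1% in L1 norm (a tested
property). `identity_threshold = 0.8` reflects the ensemble purity at which
an excited-state ensemble still yields a meaningful emission band. Frames
whose best-projecting state is a configured dark label are discarded
outright ("dark-discard"), mirroring the treatment of rare frames that
project on a spectroscopically inactive state.

## Internal conventions

* **Units.** Everything internal is Hartree atomic units; "frequency atomic
  units" means $\nu$ such that the photon energy is $h\nu = 2\pi\nu$
  Hartree, so $\sigma = 4\times10^{-4}$ a.u. converts to 0.068 eV. I/O
  declares units in headers; readers convert on entry.
* **0-0 line.** State-set energies are unperturbed *vertical* energies at
  the active reference structure. The unperturbed 0-0 frequency is derived
  as $\nu_{el}^0 - \lambda/h$ for absorption ($+\lambda/h$ for emission),
  with $\lambda = \sum_n S_n h\nu_n$ the harmonic reorganization energy over
  final-state quantum modes; `correct_00()` then shifts it onto an
  experimental anchor when one is configured.
* **Determinism.** Eigenvector signs are fixed (largest-magnitude component
  positive); degenerate eigenvalues (gap below 1e-12 Hartree) are flagged
  and ordered by their dominant unperturbed component; enumeration ties are
  broken by lexicographic quanta. Re-running a workflow writes byte-identical
  files.
* **Degenerate/edge inputs.** A single atom yields only roto-translations;
  linear geometries drop one rotation vector; superpositions requiring a
  reflection abort (chirality mismatch); charges within 0.05 nm of a QC atom
  abort with the offending indices; an all-discarded ensemble aborts rather
  than returning an empty spectrum.
* **Explicit uniform field.** Frames may carry a `uniform_field` used only
  in the field term of the Hamiltonian. It is a test device: it makes the
  two-state avoided crossing analytically checkable without constructing
  distant charge pairs. A gauge for the potential of a uniform field would
  be arbitrary, so none is applied.

## What the synthetic generator emulates — and what it does not

`make_toy_stateset()` builds a chromophore whose per-state Hessians share
one internal mode frame constructed at the ground-state reference geometry:
excited states keep the frequencies, one mode pair is mixed by exactly the
requested Duschinsky angle, and excited minima are displaced along their own
quantum modes so targeted Huang–Rhys factors are hit exactly. Because every
toy Hessian is built orthogonal to the *ground-state* roto-translation
space, analyses of toy Hessians use the ground-state geometry for the Eckart
projection; with that convention the generator's parameters are recovered by
the modes module to machine precision, which is what makes the
parameter-recovery tests sharp. (For real data, where each Hessian is
computed at its own minimum, the state's own geometry is the right
projection point, and the workflows do exactly that; the small
rotational-frame mismatch between states is then a genuine feature of the
data, not of the implementation.)

`make_solvent_frames()` scatters neutral water-like charge triads uniformly
in a shell and jitters the QC thermally. It is statistical scenery: no
forces, no trajectory continuity, no hydrogen-bond structure, no
polarization. Passing tests on toy data therefore demonstrate the
correctness of the machinery — Hamiltonian assembly, assignment, overlap
enumeration, spectral bookkeeping — not the realism of any particular
solvent model. Conclusions about a real chromophore still require real
electronic-structure inputs and real MD frames.

## Numerical choices

* Franck–Condon enumeration expands the quanta lattice mode by mode,
  pruning a partial assignment only when its product times the best
  attainable factors of the remaining modes cannot reach the threshold;
  since each per-mode Poisson weight is unimodal, this bound is valid and
  the enumeration provably contains every transition above threshold (also
  guarded by a configurable transition-count cap).
* The quadrature oracle for single-mode overlaps uses Gauss–Hermite nodes;
  since the integrand is a polynomial times the Gaussian weight the rule is
  exact at modest orders, and convergence is asserted across point
  doubling. Its accuracy is absolute (~1e-14): for squared overlaps below
  ~1e-12 cancellation limits the attainable *relative* accuracy, which is
  why oracle comparisons are stated as absolute deviations.
* Vibronic replicas are evaluated exactly (each a translated, rescaled copy
  of the vertical band, with the frequency-dependent factors evaluated at
  the translated argument), so the band-integral conservation
  $\int I_{vib} = (\sum_m f c^2_m)\int I_{vert}$ holds to the grid's
  quadrature accuracy; default grids span the band ±8σ at σ/5 spacing.
* Electrostatics apply the minimum-image convention when a periodic box is
  present and no cutoff otherwise — truncation policy belongs to frame
  preparation, not to the method.

## Problem sizes

The shipped tests and the acceptance script run toy systems of 3–5 atoms,
2–3 electronic states, up to ~9 internal modes, and tens of environment
frames with ~10 charge triads each; the 5-mode sum-rule enumeration at
threshold 1e-12 produces ~1.2×10^4 transitions. These sizes exercise every
code path (including multi-sub-ensemble absorption and coherence-filtered
emission) while keeping the full suite around ten seconds; the same
machinery scales to the tens of thousands of frames and >10^6 transitions
of a production study, where the enumeration threshold and the per-frame
PMM sweep dominate cost.

## Known limitations

* No Duschinsky-rotation (mode-mixing) overlap integrals, no
  frequency-change (distorted-mode) single-mode overlaps, no
  Herzberg–Teller intensity corrections, no hot bands (the initial
  vibrational state is always the ground state).
* Electrostatic embedding is fixed-charge and non-polarizable; the
  perturbation stops at the field–dipole term off-diagonally.
* Perturbation effects on vibrational frequencies are neglected by
  construction.
* The GRO/XTC trajectory pair is not read directly; frames are interchanged
  as extended XYZ with a charge column.
* Conformational clustering of flexible chromophores is out of scope; the
  single-conformer (semi-rigid) assumption is the default, with conformer
  ids accepted as an input partition when present.

## The state-set schema

A single JSON document (`write_stateset()` / `read_stateset()`):

```json
{
  "schema": "pmmvib-stateset-1",
  "units": {"energy": "hartree", "length": "bohr", "charge": "e", "mass": "amu"},
  "elements": ["C", "N", "O", "C"],
  "masses": [12.011, 14.007, 15.999, 12.011],
  "state_labels": ["GS", "Lb", "La"],
  "states": [
    {"label": "GS", "energy": 0.0,
     "charges": [0.1, -0.2, 0.05, 0.05],
     "geometry": [[0.0, 0.0, 0.0], ["..."]],
     "hessian": [["3N x 3N, Hartree/Bohr^2"]]},
    {"label": "Lb", "energy": 0.17, "...": "..."}
  ],
  "dipole_matrix": [["n_states x n_states x 3, a.u., symmetric"]]
}
```

Environment frames use extended XYZ with five columns
(`element x y z charge`): QC atoms first, then environment charges as
element `X`; the comment line carries `frame_index`, `n_qc`, `units` and
optional `box`/`field` tokens.

## A complete toy run

```{r example, eval = FALSE}
ss <- make_toy_stateset(toy_spec(n_atoms = 4, n_states = 3,
                                 displacement_scale = 0.4,
                                 duschinsky_angle = 0.2,
                                 charge_contrast = 0.05, seed = 42))
frames <- make_solvent_frames(ss, n_frames = 200, n_waters = 20, seed = 7)
cfg <- run_config(exp_00 = c(Lb = 4.37, La = 4.54))
ab <- run_absorption(ss, frames, cfg)
summary(ab)
plot(ab)
em <- run_emission(ss, frames, cfg, ensemble_tag = "Lb")
plot(em)
```
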