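---
title: "Survival-yield analysis of gas-phase complex dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-yield analysis of gas-phase complex dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemtwo)
```

## The measurement and the model

In a native electrospray experiment a non-covalent protein–peptide complex
(the *educt*) is transmitted intact into a collision cell, where an
adjustable acceleration voltage — the collision-cell voltage difference
ΔCV — controls how much kinetic energy is converted into internal energy by
collisions with neutral gas. As ΔCV is stepped up, the surviving educt
signal decays and the two product signals (the released protein and
peptide) grow. `itemtwo` turns a series of centroided spectra recorded at
stepped ΔCV into apparent gas-phase kinetic and thermodynamic quantities of
the dissociation reaction.

The pipeline has four stages:

1. **Charge-state envelopes.** Each species appears as a series of
   multiply-charged ions. For every spectrum and species we match peaks at
   the theoretical m/z of each charge state (highest peak within a
   tolerance window, default 0.5 Th, because the propagated quantity is the
   apex *height*) and fit a Gaussian to height versus m/z. The apex
   intensity and apex m/z of the fitted Gaussian summarize the species at
   that step; the intensity-weighted mean charge `sum(z·h)/sum(h)` is
   reported alongside.
2. **Normalization.** At each step the educt fraction is
   `norm_ed = I_ed / (I_ed + mean(I_products))` (the `pairs-mean`
   convention). One dissociated complex yields one of each product, so the
   two product intensities are duplicate measurements of the same
   dissociation extent; averaging them keeps `norm_ed` a ratio-only
   statistic, invariant under uniform intensity scaling. `sum` pooling is
   available as an alternative convention.
3. **Boltzmann survival curve.** The replicate-averaged educt percentage
   versus ΔCV is fitted to the sigmoid
   `y(x) = A2 + (A1 − A2)/(1 + exp((x − x0)/dx))`, with `A1`/`A2` the
   initial/final educt rates (percent), `x0` the midpoint voltage (ΔCV50)
   and `dx` the transition width. Fits are carried out in percent units.
   A fit is flagged (not rejected) when R² < 0.98. The tangent slope at the
   midpoint is analytically `−(A1 − A2)/(4·dx)`, which is also what a
   tangent line drawn along the steep part of the curve measures.
4. **Apparent thermodynamics.** Steps in the steep region of the curve
   (local slope ≥ 50 % of the midpoint slope, i.e. `x0 ± 1.763·dx`) are
   converted pointwise into a pseudo-first-order rate constant
   `k = −ln(S/S0)/τ` (survival referenced to the lowest-voltage step, so
   in-solution pre-dissociation — initial educt rates below 100 % — does
   not masquerade as gas-phase kinetics) and a normalized dissociation
   constant `KD = (norm_prod/2)² / norm_ed`. Regressing `ln k` and `ln KD`
   against the reciprocal collision temperature gives Arrhenius and
   van't Hoff lines; both are evaluated at ambient temperature
   (`T_amb = 298 K`) to yield the apparent zero-external-energy quantities
   `k_m0g#`, `KD_m0g#`, and from the van't Hoff line
   `ΔH_m0g# = −R·slope`, `TΔS_m0g# = T_amb·R·intercept`, and
   `ΔG_m0g# = −R·T_amb·ln KD_m0g#` (R = 8.314 J/(mol·K)). These three
   definitions make the Gibbs–Helmholtz identity `ΔG = ΔH − TΔS` hold at
   `T_amb` by construction; `analyze_series()` verifies it to 0.2 kJ/mol.

### The collision-temperature mapping is an interface, not a claim

Converting ΔCV into an effective ion temperature requires a calibration
that is instrument- and method-specific and is not derivable from the peak
lists themselves. The default `temperature_model()` uses the center-of-mass
collision energy distributed over an effective heat capacity,

`T_coll = T_amb + dof_scale · z·e·ΔCV · m_gas/(m_gas + m_ion) / kB`,

anchored at `T_coll(0) = T_amb` and strictly increasing. `dof_scale`
(default 0.02, i.e. roughly a hundred effective degrees of freedom heated
per activating collision) places the steep region of a typical survival
curve at effective temperatures of ~350–420 K. The mapping is deliberately
pluggable (`fun` argument): every closure identity above is evaluated at
`1/T_amb` and is independent of it, but the *absolute magnitudes* of
`k_m0g#` and `KD_m0g#` do depend on it. The package therefore validates
the parameter-level identities (midpoint-slope identity, Gibbs closure
from KD, ΔH − TΔS consistency) against published benchmark tables, and
makes no claim about reproducing absolute rate or equilibrium magnitudes.

### Other defaults that matter

| parameter | default | unit | why |
|---|---|---|---|
| `mz_tolerance` | 0.5 | Th | typical centroid scatter of Q-ToF peak lists |
| smoothing window / order / cycles | 13 / 2 / 1 | points | Savitzky–Golay; even windows are rounded up (12→13) since the filter needs odd lengths; order 2 is the common instrument-software default |
| `residence_time` τ | 8.8e-5 | s | the pusher period, the only time constant available from a Q-ToF acquisition record |
| collision gas | argon, 39.948 | Da | conventional collision gas of Q-ToF-class instruments |
| R² gate | 0.98 | — | standard acceptance threshold for survival-curve fits |
| species masses | 13708.2 / 11541.9 / 2166.3 | Da | average masses of the RNase S complex, S-protein and S-peptide computed from the public ribonuclease A sequence split at residue 20/21; configuration, never algorithm constants |

Smoothing operates on a uniform m/z grid obtained by linear resampling at
the median peak spacing (the filter assumes uniform sampling; centroided
lists are not uniform) and is mapped back to the original positions,
clamping at zero. Gaussian envelope fits start from amplitude = maximum
height, center = its m/z, sigma = half the span of non-zero points, with
bounded Levenberg–Marquardt iterations — three-to-five-point fits need
stable starts. With fewer than three non-zero charge states the fit
degrades to the raw apex (flagged `degenerate`); an all-zero series is a
flagged `absent` result, never an error, because species absence is data.

## Protonation-pattern sampling

Placing `k` protons on `n` protonatable basic sites (arginine, lysine,
histidine, N-termini) admits `C(n,k)` binary patterns — `C(20,7) = 77,520`
for an RNase-S-sized system at charge 7+. `monte_carlo_minimize()` explores
this space with Metropolis swap moves (one occupied and one unoccupied site
exchange, preserving total charge) scored by the pairwise Coulomb energy
`E = Σ kC/(ε_r·r_ij)` over occupied pairs, `kC = 1389.35 kJ·Å/mol`, vacuum
permittivity by default as appropriate for desolvated ions. Every distinct
pattern visited is recorded with an exactly recomputed energy (no
incremental drift), sorted ascending with lexicographic tie-breaks for
deterministic output. The Metropolis temperature defaults to the median
absolute energy change of 200 probe swaps divided by ln 2, giving ~50 %
acceptance of a typical uphill move; geometric annealing is optional.
`enumerate_patterns()` provides the exhaustive reference for systems with
`C(n,k)` up to ~1e5, and the test suite requires the sampler's minimum to
coincide with the enumerated global minimum.

The MMSA rule (`mmsa_select()`) reflects that arginine is the most basic
side chain: among the 100 lowest-energy patterns it stably re-sorts by
descending count of protonated arginines and keeps the top 10, preserving
energy order within equal counts. Pure Coulomb scoring on fixed coordinates
is the scoring this package defines; force-field geometry optimization,
thermalization dynamics and polar-solvation energies are deliberately out
of scope, and the scoring function is an interface for such extensions.

## Inter-chain contact statistics

For a multi-model structure ensemble, `interchain_contacts()` lists every
peptide-chain/protein-chain atom pair within 4.0 Å (inclusive boundary, by
the usual "≤ 4 Å" contact convention; hydrogens excluded by default to
match all-non-hydrogen X-ray references). Per peptide residue,
`position_to_sum()` counts *positions* (distinct
`(peptide_atom, protein_residue, protein_atom)` triples seen in any model)
and the *sum* (every occurrence across models); the position-to-sum ratio
`sum/positions` is 0 for contact-free residues, exactly 1 when every pair
occurs in a single model, and > 1 when pairs recur across models —
residue-size- and ensemble-size-independent by construction. Residues
unresolved in a reference structure are handled by a residue-range filter.
Distances are computed by exhaustive pairwise evaluation; at the ensemble
sizes involved (thousands of atoms, tens of models) this is fractions of a
second and needs no spatial indexing.

## What the synthetic generators emulate — and what they do not

`generate_cid_series()` renders, per replicate and ΔCV step, three species
as Gaussian-envelope peak heights at the exact theoretical m/z of their
charge states. The educt amplitude follows the planted Boltzmann fraction
`f`; **each** product's amplitude is `(1 − f)` times the base amplitude,
mirroring the stoichiometry that one dissociated complex yields one of each
product — so the educt apex plus the *mean* product apex is conserved
across the series and the default normalization recovers `f` exactly.
(Splitting `(1 − f)/2` per product instead would make the pairs-mean
normalization a distorted, non-sigmoidal transform of the planted truth.)
Noise is multiplicative log-normal with unit mean and configurable
coefficient of variation; the default plan uses the benchmark voltage
schedule (4, 8, 11, 13, 15, 17, 20, 30, 50 V), 3 replicates and 2 % noise,
matching typical acquisition practice for this experiment. Generation is a
pure function of (plan, seed) and every dataset is emitted with its ground
truth.

The generators do **not** emulate isotope structure, adducts, in-source
decay, detector saturation, chemical background, peak-shape asymmetry or
charge-state-dependent transmission. Passing recovery tests therefore
demonstrates correctness of the estimation chain under the stated noise
model, not robustness to every artifact of real spectra. Likewise
`generate_contact_ensemble()` plants contact pairs at 3.5 Å in chosen
models (and > 6 Å otherwise, with ≥ 30 Å between slots so no unplanned
contacts arise) purely for bookkeeping truth — its geometry is synthetic
and stereochemically meaningless, and its fixtures are labelled synthetic.

## Problem sizes and numerical choices

The test suite runs the full recovery study at the study conditions —
100 seeds × 3 replicates × 9 voltage steps with 2 % noise — and the sampler
benchmark at 10 seeds × 50,000 Metropolis steps against exhaustive
enumeration of all 77,520 patterns; both complete in a few minutes on one
core. Nonlinear fits use Levenberg–Marquardt with tight tolerances
(ftol = ptol = 1e-14) so that noiseless round trips recover planted
parameters to 1e-6. Degenerate inputs have defined behavior throughout:
constant survival data raise a no-transition error, rising curves an
orientation error, fully dissociated points an infinite-rate flag that
excludes them from regression, and `k = 0` or `k = n` protonation systems
short-circuit to their single forced pattern.

## Known limitations

- Absolute `k_m0g#`/`KD_m0g#` magnitudes inherit the collision-temperature
  calibration; only parameter-level identities are validated.
- Whether normalization should precede or follow replicate averaging is not
  uniquely determined by the experiment description; the package fits
  envelopes per replicate and averages normalized points, consistent with
  per-replicate mean-charge dispersion being reportable.
- The `pairs-mean` normalization and the mass-action KD construction are
  flagged strategy defaults (the pipeline logs them on every run), each
  replaceable through a function argument.
- Peak lists are assumed centroided; profile-mode processing, deisotoping
  and vendor formats are out of scope (an adapter accepting any
  reader that yields `spectrum` objects covers mzML-style containers).
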