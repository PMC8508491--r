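# itemtwo

Analysis of gas-phase dissociation of non-covalent protein–peptide
complexes from native electrospray mass spectrometry at stepped
collision-cell voltage differences (ΔCV), in the ITEM-TWO style of
survival-yield analysis. The package is aimed at native-MS and structural
proteomics practitioners who record series of centroided spectra of an
intact complex (the *educt*) and its two dissociation products while
ramping ΔCV, and who want apparent kinetic and thermodynamic quantities of
the gas-phase dissociation out the other end.

## The model at the core

The normalized educt survival versus ΔCV follows a Boltzmann sigmoid

    y(x) = A2 + (A1 − A2) / (1 + exp((x − x0)/dx))

with initial/final educt rates A1/A2 (percent), midpoint x0 (ΔCV50) and
width dx; the tangent slope at the midpoint is −(A1 − A2)/(4·dx). Points in
the steep region are converted into pseudo-first-order rate constants
k = −ln(S/S0)/τ and normalized dissociation constants
KD = (norm_prod/2)²/norm_ed, regressed Arrhenius- and van't-Hoff-style
against reciprocal collision temperature, and both lines are evaluated at
ambient temperature (298 K) to give the apparent quantities

    k_m0g#,  KD_m0g#,  ΔG_m0g# = −R·T_amb·ln KD_m0g#,
    ΔH_m0g# = −R·slope,  TΔS_m0g# = T_amb·R·intercept     (R = 8.314 J/(mol·K))

so ΔG = ΔH − TΔS holds at T_amb by construction. The package also ships a
Metropolis Monte-Carlo sampler of protonation patterns (k protons on n
basic sites, Coulomb-scored, with the MMSA arginine-rich selection rule)
and inter-chain atom-contact statistics ("position-to-sum" ratios) over
multi-model PDB ensembles. Synthetic-data generators with known ground
truth cover every input, so the whole pipeline runs without downloads.

## Worked example

Generate a three-replicate CID series at 2 % multiplicative noise from a
known survival curve (A1 = 86, A2 = 8.77, x0 = 12.5, dx = 2.3), run the
pipeline, and compare:

```r
library(itemtwo)

plan    <- series_plan(noise_cv = 0.02, seed = 42)   # defaults: RNase-S-like species
ser     <- generate_cid_series(plan)
species <- lapply(plan$species, function(s) s$def)
an      <- analyze_spectra(ser$spectra, species)
agg  <- aggregate_replicates(an$points)
head(agg, 3)
#>   delta_cv mean_norm_ed sd_norm_ed n single_replicate
#> 1        4        0.841    0.00213 3            FALSE
#> 2        8        0.763    0.00208 3            FALSE
#> 3       11        0.600    0.00232 3            FALSE

fit <- fit_boltzmann(agg$delta_cv, agg$mean_norm_ed * 100)
fit
#> <boltzmann_fit> a1=85.74 a2=8.87 x0=12.52 dx=2.27 R2=1.0000
midpoint_slope(fit)   # percent per volt at the CV50
#> -8.47

analyze_series(agg, temperature_model(mean_charge = an$educt_mean_charge))
#> <thermo_result> at T_amb = 298 K
#>   k_m0g#  = 6.710e+01 1/s
#>   KD_m0g# = 8.512e-05
#>   dG_m0g# = 23.22 kJ/mol
#>   dH_m0g# = 107.87 kJ/mol
#>   TdS_m0g# = 84.65 kJ/mol
```

The fitted curve recovers the planted parameters within the noise (exactly,
at `noise_cv = 0`), and the reported ΔG/ΔH/TΔS close under the
Gibbs–Helmholtz identity. Absolute k/KD magnitudes depend on the pluggable
ΔCV→temperature calibration (see the vignette) — the identities among the
quantities do not.

Protonation sampling on the shipped synthetic 20-site fixture:

```r
sites <- read_site_table(system.file("extdata", "sites_synthetic_20.csv", package = "itemtwo"))
mc  <- monte_carlo_minimize(sites, k = 7, steps = 5e4, seed = 42)
head(mc, 3)          # lowest-Coulomb-energy patterns (kJ/mol)
#>                   bits   energy arg_count
#> 1 00001101100110010000 854.8178         0
#> 2 00000101010110110000 868.4546         0
#> 3 00000101000111110000 868.6019         0
mmsa_select(mc)[1:3, ]   # 100 lowest energies, 10 richest in protonated Arg
#>                   bits   energy arg_count rank
#> 1 10001001000110110000 888.4895         1    1
#> 2 00100101100010110000 888.5044         1    2
#> 3 00100101000010110001 888.9845         1    3
```

File-based runs (`run_analysis()`, `run_protonation()`, `run_contacts()`)
take a YAML/JSON config, write course-parameter and apparent-quantity CSV
tables, JSON diagnostics with a provenance block, and a log of every
flagged default in effect; `inst/scripts/item2.R` wraps them for shell use.

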