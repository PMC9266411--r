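# idpnse

Structure and dynamics of intrinsically disordered proteins (IDPs) in
solution, from small-angle scattering (SAXS/SANS) and neutron spin-echo
(NSE) spectroscopy.

Disordered proteins sample broad conformational ensembles whose *shape*
(radius of gyration R<sub>G</sub>, chain-statistics exponent ν) and
*dynamics* (nanosecond internal chain motions, their amplitudes and the
friction opposing them) respond together to solvent perturbations such as
denaturants.  `idpnse` implements the analysis chain that connects the two
measurements, for structural biophysicists analyzing SAS + NSE campaigns
on IDPs — or validating such analyses on synthetic data:

* **SAS stage** — generalized Gaussian-coil form factor
  P(q) = γ(1/2ν, U)/(ν U<sup>1/2ν</sup>) − γ(1/ν, U)/(ν U<sup>1/ν</sup>),
  U = (2ν+1)(2ν+2)q²R<sub>G</sub>²/6 (the Debye function at ν = ½), with
  weighted Levenberg–Marquardt fitting; self-consistent Guinier analysis
  (q<sub>max</sub>·R ≤ 1.1 or 1.3); Kratky transform; structure factors
  S(q) by concentration division and analytic Percus–Yevick hard-sphere
  fits; the stiff-segment marker q\* = 1.91/l<sub>p</sub>.
* **Zimm / ZIF stage** — the coherent intermediate scattering function of
  the Zimm bead-spring model with mode times
  τ<sub>p</sub> = ηR<sub>e</sub>³/(√(3π) k<sub>B</sub>T)·p<sup>−3ν</sup>,
  optionally with internal friction (τ<sub>p</sub> + τ<sub>i</sub>, the
  ZIF model); effective diffusion D<sub>t</sub>(q) = D<sub>0,t</sub>H/S(q);
  model-free stretched-exponential (KWW) analysis; global multi-q fits of
  NSE spectra with (τ<sub>i</sub>, H) free and the SAS-derived structure
  fixed.
* **Normal-mode stage** — anisotropic-network-model modes on coarse-grained
  Cα chains; multipole-expansion rotational form factors S<sub>l</sub>(q);
  the rigid-body + internal-mode ISF
  (1 − A + A e<sup>−t/τ<sub>NM</sub></sup>)·e<sup>−q²D<sub>t</sub>t</sup>·Σ<sub>l</sub>S<sub>l</sub>e<sup>−l(l+1)D<sub>r</sub>t</sup>/Σ<sub>l</sub>S<sub>l</sub>
  fitted globally for (RMSD, τ<sub>NM</sub>, H); Brownian-oscillator
  reduction ζ = k<sub>B</sub>T·τ/RMSD².
* **Hydrodynamics** — Kirkwood double-sum and Rotne–Prager–Yamakawa
  rigid-body diffusion of bead models, Stokes–Einstein conversions, the
  R<sub>H</sub>/R<sub>G</sub> compactness ratio (sphere 1.29, coil 0.67).
* **Synthetic data** — generators for noisy SAS curves, ZIF- and NM-forward
  NSE datasets with serialized ground truth, tunable-ν chain ensembles, and
  a five-condition denaturant series; `run_pipeline()` ties the stages
  together in campaign order.

File formats: 3-column SAS ASCII (`read_sas`/`write_sas`, 1/Å or 1/nm),
4-column or q-blocked NSE ASCII (`read_nse`/`write_nse`), CA-only
multi-model PDB with population weights in the occupancy column
(`read_pdb_ensemble`/`write_pdb_ensemble`).

## Worked example

Generate a synthetic denaturant titration and run the full chain:

```r
library(idpnse)
series <- make_condition_series(seed = 11)
report <- run_pipeline(series)
print(report)
```

which prints (fitted values; the generating truth is in
`series$manifest`):

```
Pipeline report (per condition):
 label    rg     nu tau_i H_zif chi2_zimm chi2_zif  rmsd tau_nm  H_nm chi2_nm   zeta
    0M 38.59 0.4778 67.66 1.198     172.0   0.6691 4.433  8.530 1.203  0.7037 0.4340
  0.2M 36.65 0.4861 69.44 1.248     164.9   0.6992 3.163  5.139 1.255  0.7963 0.5137
    1M 41.82 0.5294 55.44 1.099     140.4   0.8899 4.552  6.432 1.109  0.8583 0.3104
    4M 45.81 0.5305 44.55 1.044     132.3   0.7848 5.470  6.386 1.056  0.6709 0.2134
    6M 50.70 0.5301 40.37 1.003     127.2   0.8467 6.132  5.870 1.008  0.7913 0.1561
```

Reading the table: across the titration the chain swells (`rg` up, `nu`
0.48 → 0.53); the pure Zimm model fails everywhere (`chi2_zimm` ≫ 1)
while adding internal friction fixes it (`chi2_zif` ≈ 1), with the
internal friction time `tau_i` falling from ~68 ns towards its ~40 ns
floor; the normal-mode reading of the same spectra shows growing mode
amplitudes (`rmsd`, Å) at a roughly constant relaxation time `tau_nm`
(ns), so the Brownian-oscillator friction `zeta`
(k<sub>B</sub>T·ns/Å²) drops — both analyses report the same physics:
structural expansion releases internal friction.

Single stages work standalone, e.g.:

```r
cv  <- make_saxs(rg = 45, nu = 0.53, noise_frac = 0.02, seed = 3)
fit <- fit_gauss_coil(cv)
#> Generalized Gaussian coil fit (120 pts): RG = 44.84 +/- 0.30 A,  nu = 0.530 +/- 0.002
#>   I(0) = 0.9957, background = -1.59e-05, reduced chi^2 = 0.713
```

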