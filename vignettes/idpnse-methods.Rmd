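---
title: "Models and methods: coupled structure and dynamics of disordered proteins from SAS and NSE"
author: "idpnse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpnse)
```

## The scientific problem

Intrinsically disordered proteins (IDPs) sample broad conformational
ensembles, and their biology depends on both the *shape* of that ensemble
(how compact or swollen the chain is) and its *dynamics* (how fast, and
against how much friction, the chain reconfigures).  Small-angle X-ray or
neutron scattering (SAXS/SANS) measures the static side: the radius of
gyration $R_G$ and the scaling exponent $\nu$ of the chain statistics.
Neutron spin-echo spectroscopy (NSE) measures the dynamic side: the
normalized intermediate scattering function $I(q,t)/I(q,0)$ on nanosecond
to hundreds-of-nanoseconds scales, where center-of-mass diffusion, chain
rotation and internal chain modes all contribute.

`idpnse` implements the full analysis chain that connects the two: coil
form factors and Guinier analysis on the SAS side; structure-factor
corrections; Zimm-type polymer fitting of NSE spectra with internal
friction; an alternative rigid-body-plus-normal-mode interpretation on
coarse-grained conformer ensembles; and a Brownian-oscillator reduction of
the fitted mode parameters to an internal friction coefficient.  Because
the original experimental campaign cannot be re-run at a desk, a
first-class synthetic-data module generates every input from the forward
models with known ground truth, which is how the package validates itself:
every fitting stage is tested by parameter recovery against data its own
generators produced.

## Static stage: coil form factors

The SAS stage models the form factor of a disordered chain with arbitrary
scaling exponent $\nu$ as a generalized Gaussian coil,

$$P(q) = \frac{1}{\nu U^{1/(2\nu)}}\gamma\!\left(\tfrac{1}{2\nu}, U\right)
       - \frac{1}{\nu U^{1/\nu}}\gamma\!\left(\tfrac{1}{\nu}, U\right),
\qquad U = \frac{(2\nu+1)(2\nu+2)}{6}\, q^2 R_G^2,$$

with $\gamma(a,x)$ the lower incomplete gamma function.  At $\nu = 1/2$
this is exactly the Debye function $2(e^{-x}+x-1)/x^2$, $x = q^2R_G^2$,
which we use as a closed-form oracle in the tests.  Numerically, the
incomplete gamma is evaluated as `pgamma(x, a) * gamma(a)`, with a series
branch for $U < 10^{-8}$ so that $P(0) = 1$ holds exactly.

Guinier analysis fits $\ln I$ vs $q^2$ in a self-consistent window: the
upper limit shrinks iteratively until $q_{max} R_{Guinier}$ falls below
the configured limit (1.1 for expanded chains, 1.3 for compact states;
at most 50 iterations, converged when $|\Delta R|/R < 10^{-6}$).  On an
exact $\nu = 1/2$ coil curve the Guinier radius at limit 1.1 sits about
4% *below* the true $R_G$ — that bias is intrinsic to the truncated
expansion, and the tests assert it stays below 5% and vanishes
monotonically as the window limit is tightened.

Interparticle interference is estimated by concentration division,
$S(q) = (I_{conc}/c_{conc})/(I_{dil}/c_{dil})$, interpolating the dilute
curve linearly in $\log I$ (never extrapolating; points outside the dilute
support are dropped).  Repulsive excluded-volume interactions are fitted
with the analytic Percus-Yevick hard-sphere solution.  Its small-$qR$
bracket suffers catastrophic cancellation, so below $2qR_{hs} < 0.05$ each
term switches to its Taylor series; the compressibility limit
$S(0) = (1-\phi)^4/(1+2\phi)^2$ is then satisfied to better than
$10^{-8}$.  Charged-sphere (rescaled MSA) structure factors are
deliberately not implemented; the model name is reserved, and compact
low-salt conditions in the synthetic series simply use $S = 1$.

## Dynamic stage I: Zimm model with internal friction

The Zimm model describes the chain as $N$ beads connected by entropic
springs with hydrodynamic interactions.  Mode $p$ relaxes with

$$\tau_p = \frac{\eta R_e^3}{\sqrt{3\pi}\, k_B T}\, p^{-3\nu},$$

where $R_e = \sqrt{(2\nu+1)(2\nu+2)}\,R_G$ is the end-to-end distance and
the bond length is $l = R_e/N^\nu$; $R_G$ and $\nu$ come from the SAS
stage, so the dynamic fits inherit the static structure.  The coherent
ISF is the double sum

$$I(q,t) = e^{-q^2 D_t t}\frac{1}{N}\sum_{n,m}
  e^{-q^2 B(n,m,t)/6},$$

with $B(n,m,t)$ containing the static part $|n-m|^{2\nu} l^2$ plus the
mode relaxation sum.  We evaluate the ratio to the $t = 0$ value, so the
model matches the measured $I(q,t)/I(q,0)$ exactly at $t = 0$ (the
normalization is left implicit in most presentations).  Internal friction
adds a mode-independent time, $\tau_p^{ZIF} = \tau_p + \tau_i$ — the ZIF
model.  Translational diffusion enters as
$D_t(q) = D_{0,t}\,H/S(q)$ with the dilute-limit $D_{0,t}$ fixed from an
external measurement (mirroring how a DLS value is used in practice) and
the hydrodynamic factor $H$ a single $q$-independent fit parameter shared
across the entire dataset of a condition.

Choices worth stating:

* bead number $N = 20$ by default (about 8 residues per bead for a
  169-residue chain); the fits are scale invariant, and the tests verify
  that $N = 20$ and $N = 40$ give $\tau_i$ agreeing within quoted errors;
* the mode eigenfunctions are the discrete bead-spring ones,
  $\cos(\pi p (n - \tfrac12)/N)$, not the continuum $\cos(\pi p n/N)$:
  they agree to $O(1/N)$ but only the discrete form makes the internal
  term vanish identically for a single bead (pure center-of-mass
  diffusion), which we treat as a correctness invariant;
* the mode sum runs to $p_{max} = N$;
* fits are weighted Levenberg-Marquardt (`minpack.lm::nls.lm`) on
  $(\mathrm{data}-\mathrm{model})/\sigma$, reporting reduced
  $\chi^2 = \sum r^2/(n-k)$ everywhere;
* $\tau_i$ is parameterized as $\log\tau_i$ to enforce positivity; a fit
  collapsing to the lower bound is flagged as an upper limit;
* the model is always evaluated on the exact experimental $(q,t)$ points,
  never interpolated;
* points with $I/I_0 \le 0$ are excluded from fits.

Model-free characterization fits $\exp(-(\Gamma t)^\beta)$ per $q$
(amplitude fixed at 1) and reports $D_{eff} = \Gamma/q^2$ and the
unweighted mean $\langle\beta\rangle$ over $q$.  The ideal Zimm forward
model evaluated noise-free over the instrument $q$-range and fitted this
way gives $\langle\beta\rangle \approx 0.85$-$0.88$ (per-$q$ values
0.85-0.90, lowest at intermediate $q R_G$), the canonical signature of
Zimm dynamics; pure diffusion gives $\beta = 1$.

## Dynamic stage II: normal modes on conformer ensembles

The alternative reading of the same NSE data treats the protein as an
ensemble of distinct rigid conformers, each performing translational and
rotational diffusion, decorated with small internal displacements along
low-frequency normal modes:

$$\frac{I(q,t)}{I(q,0)} =
 \left(1 - A(q) + A(q)e^{-t/\tau_{NM}}\right)
 e^{-q^2 D_t t}\,
 \frac{\sum_l S_l(q)\, e^{-l(l+1)D_r t}}{\sum_l S_l(q)}.$$

The rotational term uses the multipole expansion
$S_l(Q) = 4\pi\sum_m |\sum_i b_i j_l(Qr_i) Y_{lm}(\Omega_i)|^2$ in the
orthonormal complex spherical-harmonics convention, with coordinates
re-centered to the scattering-length center of mass (the rotational term
assumes a body-fixed origin; the literature is silent on the centering, so
we state it).  In this normalization $\sum_l S_l$ equals the Debye double
sum exactly, which the tests assert to $10^{-6}$; since only the ratio
enters the ISF, the overall normalization cancels anyway (also tested).
The $l$ cutoff follows $l_{max} = \lceil Q r_{max}\rceil + 10$, capped at
60, where the truncation error is below $10^{-6}$.

Modes come from an anisotropic network model on the C$\alpha$ beads: a
harmonic pair potential on all pairs within a cutoff, eigendecomposition,
six rigid-body null modes verified, and the 10 lowest nontrivial modes
kept with equal weights.  The cutoff default is 15 Å, the common
C$\alpha$ elastic-network choice.  A smaller cutoff proportional to the
bead spacing (e.g. 2.2 bonds) is *not* safe on coarse-grained coils: the
distance-projection Hessian only resists pair-distance changes, so if the
$(i, i{+}3)$ pair falls outside the cutoff on an extended segment, the
torsion about the $(i{+}1,i{+}2)$ bond is a free mechanism and spurious
zero modes appear.  At 15 Å the $i{+}3$ pair (at most $3\times 3.8$ Å
apart) is always inside.  The ANM spring constant is absorbed into the
common mode amplitude $a$: only displacement patterns matter.

The amplitude of the internal-mode contribution is

$$A(q) = \frac{a^2\sum_\alpha F_\alpha(q)}
              {F(q) + a^2\sum_\alpha F_\alpha(q)},
\qquad
F_\alpha(q) = \left\langle\Big|\sum_k b_k e^{i q\cdot r_k}
  (\hat q\cdot e_k^\alpha)\, q\Big|^2\right\rangle_{\hat q},$$

with the orientational average taken on a deterministic spherical
Fibonacci grid (144 directions; doubling the grid changes $A$ by less
than $10^{-4}$, and determinism keeps fits exactly reproducible).  The
fitted amplitude is reported as per-atom RMSD of the summed displacement
field: with unit-normalized eigenvectors and equal amplitudes,
$\mathrm{RMSD} = a\sqrt{n_{modes}/N}$.

Per-chain ISFs are population-averaged — we average full ISFs, not
$A(q)$ or $S_l$ separately, since the literature leaves the order
ambiguous; for the narrow $R_G$ spreads of our ensembles the difference
is far below the fit uncertainties.  The rotational $D_r$ is the
population-weighted rigid-body value of the ensemble and is held fixed in
the fits, as is $D_{0,t}$; the free parameters are $(\mathrm{RMSD},
\tau_{NM}, H)$.

The Brownian-oscillator reduction converts the fit results to a force
constant and friction, $k = k_BT/\mathrm{RMSD}^2$ and
$\zeta = k_BT\,\tau_{NM}/\mathrm{RMSD}^2$, reported in thermal units
(plus SI equivalents).  Growing amplitudes at constant relaxation time
therefore read directly as a loss of internal friction.

## Hydrodynamics

Bead-model hydrodynamics provides diffusion coefficients where no
measurement exists.  Two routes are implemented and cross-checked:

* the Kirkwood double sum
  $D = \frac{k_BT}{6\pi\eta a N} + \frac{k_BT}{6\pi\eta N^2}
  \sum_{i\neq j}\langle 1/r_{ij}\rangle$, cheap and analytic;
* the full Rotne-Prager-Yamakawa route: the $3N\times 3N$ mobility
  supermatrix (overlap branch included), inverted to the grand friction
  matrix, reduced to the $6\times 6$ rigid-body resistance, with the
  translational tensor evaluated at the center of diffusion.

The Kirkwood value is a pre-averaging upper bound; on touching-bead coils
($a = l/2$) it sits 15-25% above the rigid-body value, and the tests
assert both the bound and the 25% band.  Oracles: a filled-sphere bead
model reproduces the Stokes translational diffusion within 5% and the
rotational one within 10%; a touching two-sphere doublet reproduces the
bispherical-solution mean mobility factor 0.724 within 5% at the RPY
level.  A strictly collinear bead set has no resistance to rotation about
its own axis and is rejected with a degenerate-geometry error.  Absolute
diffusion constants from these stand-ins are *inputs* to the NSE fits in
the same way an external measurement would be; the fits never depend on
them being perfect, because $H$ absorbs a constant rescaling.

The compactness ratio $R_H/R_G$ classifies conformations between the
uniform-sphere limit $\sqrt{5/3} = 1.29$ and the random-coil limit 0.67.
The coil constant is itself recomputed by Monte Carlo: $R_H$ from the
Kirkwood double sum and $R_G$ (rms) over freely jointed chains.  The
discrete double sum carries an $O(N^{-1/2})$ bias — at $N = 169$ the raw
ratio is about 0.75, not 0.67 — so the estimator samples
$N \in \{64, 128, 256, 512, 1024\}$ and extrapolates $1/\sqrt{N}\to 0$,
landing at $0.66 \pm 0.01$, consistent with the textbook continuum value
0.665.  Reporting the single-$N$ number would overstate the constant; the
extrapolation is the honest way to estimate the long-chain limit by MC.

## Synthetic data: what it emulates and what it does not

The generators replace the experiment:

* `make_saxs()` — generalized-coil curves with multiplicative Gaussian
  noise (default 2%), $\sigma$ column equal to the noise fraction times
  the exact model, $q \in [0.01, 0.7]$ Å$^{-1}$;
* `make_nse_zif()` / `make_nse_nm()` — forward-model ISFs on an
  instrument-like grid (5 $q$ values 0.05-0.17 Å$^{-1}$, 25 log-spaced
  times 0.1-150 ns) with multiplicative noise and a $\sigma$ floor of
  $10^{-3}$;
* `generate_chain()` / `generate_ensemble()` — fixed-bond (3.8 Å)
  C$\alpha$ walks whose ensembles obey $\langle R_G(N)\rangle \propto
  N^\nu$ within $\pm 0.03$ over $N\in[50,300]$.  For $\nu$ at or above
  the ideal-walk value the bias is a calibrated excluded-volume hard core
  (kinetic growth with restart on dead ends); the calibration
  (1500 chains per point) maps hard-core diameters $\{0, 2, 3, 3.8,
  5.3\}$ Å to effective exponents $\{0.496, 0.514, 0.526, 0.539,
  0.546\}$.  Compact statistics ($\nu < 0.496$) are not reachable by
  repulsion alone, so those targets use a calibrated spherical
  confinement with radius $\propto N^{\nu}$, emulating net intra-chain
  attraction.  Attainable targets span about $[0.45, 0.575]$; outside
  that the generator refuses with the attainable range in the message.
* `make_condition_series()` — a five-condition denaturant titration
  (0/0.2/1/4/6 M labels).  $\nu$ runs 0.48 → 0.53 and $\tau_i$ 70 → 40 ns
  (compact, friction-dominated → swollen, solvent-dominated); $R_G$
  values (39.0, 36.9, 41.8, 45.7, 50.8 Å) were chosen so that the first
  Zimm mode times at the nominal solvent viscosity 1.1 mPa s match the
  70-180 ns scale of the denaturant campaign, including the slight
  compaction dip at the charge-screening condition.  Mode RMSDs grow
  4 → 7 Å at fixed $\tau_{NM} = 7$ ns.  An RMSD of ~2 Å would put the
  internal-mode amplitude $A(q)$ below half a percent across the whole
  $q$-range — undetectable under 2% noise (the fit then correctly
  collapses to the zero-amplitude null) — whereas 4-7 Å gives
  $A(q)$ up to ~0.1 at $q = 0.17$ Å$^{-1}$, matching the clearly visible
  internal-mode contribution in measured IDP spin-echo spectra.

The generators deliberately do **not** emulate: instrument resolution and
wavelength smearing, heteroscedastic counting noise, sequence-specific
local geometry (dihedral libraries), charged-sphere interparticle
attraction, or solvent-viscosity changes with denaturant concentration
(nominal $\eta = 1.1$ mPa s throughout, since the condition-dependent
viscosities are not public).  Passing recovery tests therefore
demonstrates the correctness and identifiability of the estimators under
realistic noise and grids — not robustness to instrument artifacts.

Every generator is a pure function of (parameters, seed), and the ground
truth travels with each dataset and in the series manifest.

## Problem sizes and numerical choices

Test-suite and worked-example sizes were chosen as the smallest that
leave comfortable statistical margins: 300-500 chains for scaling-law
checks, 2000 chains per length for the compactness MC, ensembles of ~20
chains reduced to 3 representatives (k-medoids on $R_G$ via `cluster::pam`,
weights = cluster fractions) for the normal-mode stage, 5 × 25 point NSE
datasets for recovery.  Other numerical policies: q is Å$^{-1}$
everywhere internally (nm$^{-1}$ converted on read); all lengths Å, times
ns, viscosities mPa s; k$_B$ enters only through conversion constants at
the unit boundaries; ties and degenerate inputs (flat Guinier curves,
zero amplitude, collinear geometries, $\phi = 0$) return flagged results
or informative errors rather than numerical noise.

## Known limitations

* The ZIF normalization treats the measured $I(q,t)/I(q,0)$ as exactly
  the model ratio; instrument normalization errors would bias $H$.
* Kirkwood and RPY hydrodynamics are coarse stand-ins for shell-model
  calculations; their absolute values should not be compared against
  precision hydrodynamic software, and the NSE fits take $D_{0,t}$ as an
  external fixed input precisely for that reason.
* The excluded-volume walk matches only global $(R_G, \nu)$ statistics;
  persistence-length-sensitive quantities (Kratky high-$q$ shape, $q^*$
  markers) should not be read off generated chains.
* Rouse dynamics, reptation, per-mode amplitudes and mode-coupling
  corrections are out of scope; $\tau_{NM}$ is shared across modes and
  conformers by construction.
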