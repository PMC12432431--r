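---
title: "Modelling temperature-responsive protein phase behavior with MpipiT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-responsive protein phase behavior with MpipiT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MpipiT)
```

## The model

MpipiT implements a residue-level, implicit-solvent coarse-grained model for
intrinsically disordered proteins whose interactions depend explicitly on
temperature, so that heating can *strengthen* effective attraction — the
signature of LCST (lower critical solution temperature) phase behavior, in
which a protein solution demixes upon heating. Each amino acid is one
spherical bead with a mass, a charge at model pH (D/E = −1, K/R = +1, H
fractional, configurable), and a diameter σ. The potential energy has three
terms:

* **Bonds.** Consecutive beads are joined by harmonic springs,
  $E_b = k (r - r_0)^2$ with defaults $k = 1920$ kcal/mol/nm² and
  $r_0 = 0.381$ nm.
* **Short-range pair interactions** use the Wang–Frenkel potential
  $$\phi_{ij}(r) = \varepsilon_{ij}\,\alpha_{ij}
    \Big[\big(\tfrac{\sigma_{ij}}{r}\big)^{2\mu}-1\Big]
    \Big[\big(\tfrac{R_{ij}}{r}\big)^{2\mu}-1\Big]^{2\nu}, \qquad r < R_{ij},$$
  which vanishes identically at its cutoff $R_{ij} = 3\sigma_{ij}$ — no
  truncation artifacts. The normalizer $\alpha_{ij}$ makes the well depth
  exactly $\varepsilon_{ij}$.
* **Electrostatics** use a Yukawa (screened Coulomb) potential
  $\phi \propto q_i q_j \exp(-\kappa r) / (\epsilon r)$ in which *both* the
  dielectric constant $\epsilon(T)$ and the inverse Debye length
  $\kappa(T)$ are scaled analytically with temperature.

### Temperature-dependent electrostatics

The dielectric constant follows
$\epsilon(T) = 1 + \rho_{\rm solv}(T)\, d(T)$ with the Kell
rational-polynomial density of water and a linear solvent parameter
$d(T) = d_0 + d_1 T$. The shipped coefficients
($d_0 = 165.19998$, $d_1 = -0.29206902\ \mathrm{K}^{-1}$) were obtained by a
minimax fit of this relation against the Malmberg–Maryott tabulated static
permittivity of water over 273–373 K; ordinary least squares leaves a 2.2%
worst-case error whereas the minimax fit keeps the model within 1.52%
everywhere on the liquid range. The inverse Debye length is
$$\kappa^2(T) = \frac{e^2}{\epsilon(T)\,\epsilon_0 k_B T}\sum_j z_j^2 c_j,$$
with ion concentrations converted to number densities (the only
dimensionally consistent reading) and $\epsilon(T)$ taken self-consistently
at the same temperature. The default electrolyte is 150 mM 1:1 salt, which
gives the familiar ~0.78 nm Debye length at 298.15 K. Temperatures outside
273–373 K raise errors rather than extrapolate: the model is built for
liquid water, and hydration is essential to the physics it represents.

### Temperature-dependent pair energies

The central modelling idea is to push all temperature dependence of the
hydrophobic effect into the Wang–Frenkel well depths. For every residue pair
containing at least one of the five hydrophobic residues (A, V, I, L, M) —
the residues enriched in LCST-prone sequences —
$$\varepsilon_{ij}(T) = \tfrac12\big[\varepsilon_{ii} +
  \alpha_i(\mu_i(T) - \mu_i(T_{\rm ref}))\big] +
  \tfrac12\big[\varepsilon_{jj} + \alpha_j(\mu_j(T) - \mu_j(T_{\rm ref}))\big],$$
with $T_{\rm ref} = 298.15$ K and per-residue parabolas
$\mu_X(T) = a_X T^2 + b_X T + c_X$. At $T_{\rm ref}$ this reduces exactly to
the arithmetic mean of the homotypic baseline well depths — a property the
test suite asserts for all 210 residue pairs. Pairs with no hydrophobic
member keep a temperature-independent baseline at every temperature; the
default baseline is the homotypic mean, and an explicit pair matrix can be
supplied via `params$pairEps` when a fully fitted heterotypic table is
available. The nominally enthalpic $\varepsilon_{ij}$ thus absorbs the
entropic cost of hydrating nonpolar residues, which grows with temperature.

### The purely repulsive branch

When the scaling drives $\varepsilon_{ij}$ negative, the canonical
Wang–Frenkel form becomes unboundedly *attractive* at contact, which is
unphysical. The package therefore evaluates negative-well-depth pairs with a
revised branch
$$\phi(r) = \begin{cases} -\phi_{\rm WF}(r) - \varepsilon_{ij} & r < r^* \\
 0 & r \ge r^* \end{cases}$$
where $r^* = R\,[(1+2\nu)/(1 + 2\nu (R/\sigma)^{2\mu})]^{1/(2\mu)}$ is the
interior extremum of the canonical potential. This branch is continuous at
$r^*$, non-negative everywhere, divergent at contact, and preserves the bead
diameter. The closed-form $r^*$ is verified against bracketed numerical
root-finding of $d\phi/dr = 0$ to $10^{-10}$ relative in the tests.

## Shipped parameters are synthetic

The published fitted parameter tables for this class of models (per-residue
masses, diameters, homotypic well depths, and the $(a, b, c, \alpha)$
temperature functionals of three calibration variants) are distributed as
supplementary data files, not printed in any article body, and are not
bundled here. The three shipped YAML files
(`params_model{1,2,3}_synthetic.yaml`) are labelled synthetic: masses and
charges are standard residue values, diameters are HPS-style literature bead
sizes, and the well depths and functionals are plausible constructions in
which hydrophobic pair energies strengthen with temperature (slopes of
0.003–0.006 kcal/mol/K, the LCST-driving direction; the three variants
differ in curvature and scale). Every algorithm is parameter-file-driven:
`loadModelParams()` accepts any file in the same layout, so published
tables drop in without code changes.

## The desk-scale engine

`runLangevin()` integrates Langevin dynamics with the BAOAB splitting (a
velocity-Verlet core plus an exact Ornstein–Uhlenbeck step), a Verlet
neighbour list with a 0.3 nm skin, minimum-image periodic boundaries in all
three dimensions, and 1–2 bonded exclusions. Internal units are nm, ps, amu
and kcal/mol; defaults follow slab-simulation practice (10 fs timestep, 5 ps
thermostat relaxation, samples every 1000 steps), all overridable. With the
thermostat disabled the integrator is plain velocity Verlet and conserves
energy to better than $10^{-4}$ relative over $10^4$ steps in the tests.
Identical seeds give bitwise-identical trajectories; the noise stream is an
internal 64-bit Mersenne Twister, so results do not depend on R's RNG
state. The neighbour-list path is checked against an all-pairs oracle for
exact force equality.

`buildSlab()` mirrors the direct-coexistence protocol: 64 (4×4×4) chain
replicates for sequences shorter than 190 residues, 27 (3×3×3) otherwise,
packed as serpentine lattice conformations into a central dense region at
0.8–1.0 g/cm³ and relaxed by capped-displacement steepest descent, with the
box z-edge extended to meet the target overall concentration. An NPT
compression stage is deliberately not implemented internally — production
slab runs are expected to use the exported engine files, for which
`writeLammpsExport()` writes a data file, one tabulated pair potential per
residue-type pair (2000 nodes, interpolation error verified at export over
the sampled region $r \ge \sigma$), and an input script encoding 50 ns
equilibration + 400 ns production at 10 fs with 5 ps damping.

## Analyses

**CLOUD-FIT.** At experimental (dilute) concentrations, nucleation is rare
but finite-size density fluctuations make incipient condensation visible as
a sharp spike in the slab z-density profile. Scanning stored profiles in
ascending temperature, the cloud point is the first temperature whose
profile spikes. The detector is configurable because "a sharp spike" is
qualitative: default spike factor 3 (max bin density ≥ 3× median bin
density) persisting in ≥ 2 consecutive stored frames. A spike at the lowest
scanned temperature is reported with a boundary warning since the true
onset may lie below the scan. Closed-loop tests with the synthetic profile
generator (spike amplitude 5× baseline, Gaussian bin noise of 0.002 g/cm³)
recover the constructed onset for 20/20 seeds.

**Experimental cloud points** are the first upward crossing of absorbance
$-\log_{10}(0.5) = 0.30103$ (transmittance 0.5), linearly interpolated.
`modelRmsd()` is the objective that ranks parameterizations against
experimental cloud-point sets.

**Flory exponent and theta temperature.** For finite heteropolymers the
package uses the finite-chain relation
$$S = \sqrt{\frac{\gamma(\gamma+1)}{2(\gamma+2\nu)(\gamma+2\nu+1)}}\;
  b\, N^{\nu}$$
with $b = 5.5$ Å (geometric mean of a ~4.0 Å persistence length and the
3.8 Å Cα spacing), $\gamma = 1.1615$ (from the Schultz-distribution
exponent), and $N$ the number of bonds. The printed form of this relation
is ambiguous about grouping in some sources; the grouping above is fixed by
its polymer-physics lineage, and the properties that matter — strict
monotonicity in ν, exact $N^\nu$ scaling, and a round-trip inversion to
better than $10^{-8}$ — are what the tests pin down. `nuFromRg()` inverts by
bracketed root-finding on ν ∈ (0.05, 0.95). The theta temperature is the
linearly interpolated ν = 0.5 crossing (linear, not spline: the exponent
series is short and noisy, and linear interpolation is what the 5–10 K
temperature grids justify); the estimate is reported as an *approximate*
exponent throughout, and the ν(T) trend sign classifies the transition:
decreasing = LCST-like (chains compact on heating), increasing = UCST-like.

**Binodal and critical point.** Coexistence densities come from
time-averaged slab profiles: the dense region is thresholded midway between
the plateau levels, 10% of the dense width is excluded on each side as
interfacial margin, and plateau interiors are averaged (profiles whose
dense slab wraps the periodic boundary are re-centered first). The critical
point is fitted simultaneously to the law of coexistence densities
$\rho_d - \rho_l = A |T - T_c|^{\beta}$ and the law of rectilinear diameters
$(\rho_d + \rho_l)/2 = \rho_c + s |T - T_c|$, with $\beta = 0.325$ (3D
Ising) by default since the exponent is conventionally imposed, not
estimated, at these system sizes. Initialization comes from the
linearization $(\rho_d-\rho_l)^{1/\beta} = a + bT$, refined by
Levenberg–Marquardt on the joint (unweighted) residuals; LCST datasets
constrain all points above $T_c$, UCST below. On noiseless synthetic data
the generator parameters are recovered to numerical precision; under 1%
multiplicative noise the median $|{\hat T_c} - T_c|$ stays below 1 K over
20 seeded replicates.

**Block statistics.** Simulation observables use the 3-block convention:
the series is split into contiguous equal blocks (remainder to the last
block), the value is the mean of block means and the error is
$\mathrm{sd}(\text{block means})/\sqrt{n_{\rm blocks}}$.

## What the synthetic generators do and do not show

The generators (`elpSequence`, `syntheticProfiles`, `syntheticBinodal`,
`syntheticRgCurve`) are first-class, seeded, bit-reproducible code. They
emulate the *structure* of real data — ELP xPxxG repeats, flat-plus-spike
density profiles, scaling-law binodals, smooth ν(T) ramps — but not the
correlated noise, finite sampling, or interfacial physics of real
trajectories. Closed-loop tests (generate → analyze → recover) therefore
validate the analysis machinery, not the force field's predictions: with
synthetic force-field parameters, predicted cloud points are
demonstrations, not reproductions of experimental values.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to give clean
statistics in minutes on one CPU: a harmonic dimer over $10^6$ steps for
equipartition (within 2%); bonds-only chains of 16–128 beads, 8–10
replicates each, for the ideal-chain $\langle R_g^2\rangle \propto N$ check
(log-log slope 1.0 ± 0.05), with bead mass 10 amu, bond stiffness 100
kcal/mol/nm², and the thermostat matched to the slowest entropic Rouse mode
of each chain ($\gamma \approx \omega_1$) — the friction that minimizes the
conformational decorrelation time; 40-residue, 64-chain slabs for the
export and profile plumbing. Production-scale work (hundreds of ns,
27–64 chains of real sequences) is exactly what the LAMMPS export is for.

Other numerical choices: pair matrices are resolved per temperature before
a run (a run is isothermal); bead pairs with exactly zero well depth and no
charge are dropped from the interaction lists; the Yukawa term is plainly
truncated at 3.5 nm (no shift — the screened tail is ~10⁻⁴ kcal/mol there);
force overflows (overlaps) abort with the offending bead index rather than
producing NaNs.

## Known limitations

* Shipped force-field parameters are synthetic placeholders (see above);
  quantitative predictions require the published fitted tables.
* The internal engine is for desk-scale validation and initial-state
  preparation, not production sampling; there is no NPT stage, no replica
  exchange, and no GPU path.
* No pH titration, explicit crowders, folded domains, nucleic acids, or
  post-translational modifications.
* The theta-temperature interpolation is linear and reports the
  lowest-temperature crossing when several exist (flagged with a warning).
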