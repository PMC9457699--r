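---
title: "Methods: protein-water LJ re-balancing and its validation battery"
author: "ffbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-water LJ re-balancing and its validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ffbalance)
```

This vignette documents the models, numerical choices, and design
decisions behind `ffbalance`. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The scaling model

Additive force fields build protein-water van der Waals interactions
from per-type Lennard-Jones parameters via combination rules:
$\varepsilon_{ij} = -\sqrt{\varepsilon_i\varepsilon_j}$ (CHARMM stores
well depths as non-positive numbers; we keep that sign convention for
byte-compatibility with consumer programs) and
$R_{min,ij} = R_{min,i}/2 + R_{min,j}/2$. The re-balancing multiplies
only the cross-term well depth by a scalar $\lambda$:
$\varepsilon_{ij} \to \lambda\,\varepsilon_{ij}$, $R_{min,ij}$
unchanged. $\lambda = 1$ is the unmodified force field; values of
roughly 1.03-1.10 have been proposed in the literature for different
force-field families.

`generate_nbfix()` emits exactly the protein $\times$ water Cartesian
product, in lexicographic pair order for deterministic output. Design
choices:

- Water types default to `OT`/`HT` (the modified TIP3P carries LJ on
  its hydrogen); the protein set defaults to "every parsed type not in
  the water set". Both are configurable because parameter files never
  label which tokens are "protein".
- **Ions are excluded by default.** Whether ions belong to the scaled
  "protein" group is genuinely open; we scale only tokens the caller
  lists (or the complement of the water set, from which a caller can
  remove ion types). A user who wants ions scaled simply lists them.
- 1-4 override parameters are never scaled, and no protein-protein or
  water-water NBFIX line is ever emitted: the model is strictly
  intermolecular.
- Duplicate NBFIX pairs in parsed input resolve last-wins with a
  warning, mirroring how CHARMM readers process streams.

The stream writer uses fixed decimal formatting (six decimals for
$\varepsilon$, four for $R_{min}$), so output is byte-stable and
parsing is a left inverse of writing up to that precision.

## 2. Conformational observables

**Window helicity.** A residue is $\alpha$-helical when it sits in a
run of at least three consecutive residues with
$-100^\circ < \phi < -30^\circ$ and $-67^\circ < \psi < -7^\circ$. The
inequalities are strict (open intervals): boundary values are outside.
The global helix fraction divides by *all* residues of the chain;
residues with undefined dihedrals count as non-helical. The synthetic
backbones carry acetyl/amide-like caps so that every residue of a
capped peptide has defined $\phi$ and $\psi$.

**DSSP-style helicity.** Backbone hydrogen bonds are scored with the
Kabsch-Sander electrostatic energy
$E = 0.084\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\cdot 332$
kcal/mol, a bond existing when $E < -0.5$ kcal/mol. Residue $i$ is
$\alpha$-helical when the four-turns $(i{-}1)\to(i{+}3)$ and
$i\to(i{+}4)$ are both present. Only this $\alpha$ subset is
implemented; bridges, turns, and 3-10/$\pi$ helices are out of scope.
Amide hydrogens, absent from heavy-atom fixtures, are reconstructed
1.0 Å from N opposite the bisector of the C$(i{-}1)$-N-CA angle — the
planar amide direction.

**Superposition.** `kabsch_rmsd()` solves the optimal proper rotation
by SVD with sign correction of the smallest singular vector, so
reflections are rejected. It is implemented natively (rather than
delegated) because the rotation matrix itself is part of the contract;
`bio3d::rmsd` serves as an independent cross-check in the tests, and a
brute-force random-quaternion search is the oracle on small point
sets. RMSF iteratively superposes all frames onto their evolving mean
structure before measuring fluctuations.

**Sizes and populations.** $R_g$ is computed about the geometric
center by default (mass weighting is available but off, since helicity
fixtures carry no masses); the end-to-end distance uses terminal CA
atoms when a topology is given. State populations count frames
*strictly below* a cutoff.

**Sigmoid fit.** Helix fraction vs $\lambda$ is fit to
$f(\lambda) = A/(1+\exp(-(\lambda-B)/C)) + D$ by Levenberg-Marquardt
(`minpack.lm`) from a multi-start grid over both signs and three
magnitudes of $C$. The parameterization has an exact mirror
$(A, C, D) \to (-A, -C, D+A)$; fits are canonicalized to the branch
with $C < 0$ (and $A > 0$) when fractions decrease with $\lambda$,
which is the physically natural reading (helicity lost as
protein-water attraction grows). $B$ is the midpoint:
$f(B) = A/2 + D$.

## 3. Free-energy surfaces from biased sampling

All PMFs use half-open bins $[lo, hi)$ (the top edge of the last bin
included), are masked below a minimum occupancy, and are shifted so
the minimum over reported bins is zero. The minimum-occupancy default
$n_{min} = 20$ is a package choice (no published value exists); it
prevents divergent $-\ln$ terms from near-empty bins. Tests that make
quantitative claims about PMF accuracy raise it to 50-100 so that
every compared bin is statistically meaningful.

**GaMD cumulant reweighting.** A non-negative boost $\Delta V$ is
removed per bin through the cumulant expansion of
$\ln\langle e^{\beta\Delta V}\rangle$; to second order this is
$C_1 + C_2/2$ with $C_1$, $C_2$ the mean and variance of
$\beta\Delta V$ among that bin's samples. Second order is the default
and the only order exposed on the command line; first order is kept
for diagnostics. Within a narrow bin $\Delta V$ varies little, which
is why the truncation is accurate there.

**MBAR.** The solver is native. It minimizes the convex MBAR
objective by Newton's method with a backtracking line search on the
gauge-fixed variables ($f_1 \equiv 0$), then polishes with damped
self-consistent iteration to $\max|\Delta f| < 10^{-8}$. Plain
self-consistent iteration alone converges too slowly when window
overlap is modest; undamped Newton without a line search can diverge
from the zero start — the combination is robust and fast. A warning
fires when the crude adjacent-window overlap estimate falls below 1%.
Unbiased per-sample weights
$w_n \propto 1/\sum_k N_k e^{f_k - u_{kn}}$ feed the weighted
histogram that becomes the PMF.

**Two-step (GaREUS) reweighting.** Step 1 applies the per-window,
per-bin cumulant factor $e^{C_1 + C_2/2}$; step 2 combines windows
with the MBAR weights computed from the harmonic biases alone. With
zero boost the chain reduces exactly to the MBAR PMF, and with a
single zero-force-constant window to the plain histogram — both
degeneracies are tested.

## 4. Free-energy differences

**BAR** solves the Bennett self-consistency equation by a bracketed
root solve; the bracket spans the observed work range widened by
$50\,k_BT$ on both sides, which always contains the root when forward
and reverse distributions overlap at all. Tolerance is $10^{-10}$
kcal/mol; the standard error is the asymptotic maximum-likelihood
variance. Disjoint work distributions raise an error advising more
windows rather than returning a meaningless number.

**Work conventions.** Forward samples are $U_B - U_A$ on state-A
configurations, reverse samples $U_A - U_B$ on state-B configurations.
The Crooks-consistent Gaussian generator draws forward work from
$\mathcal{N}(\Delta F + \beta\sigma^2/2, \sigma^2)$ and reverse from
$\mathcal{N}(-\Delta F + \beta\sigma^2/2, \sigma^2)$, the unique
Gaussian pair satisfying the Crooks relation exactly — so any
consistent estimator must recover $\Delta F$, and at $\Delta F = 0$
the two distributions coincide.

**Block errors** cut the series into contiguous equal blocks (the
remainder joining the last block); SE is the standard deviation of
block means over $\sqrt{n_{blocks}}$, with three blocks the default.

**Schedules.** `validate_schedule()` enforces: paired columns in
$[0,1]$, fully-coupled and fully-decoupled endpoints, monotone
non-increasing columns, and electrostatics fully off before any LJ
decoupling starts (annihilating charge inside an intact LJ cavity
avoids the endpoint catastrophe). The bundled 24-window schedule
switches charges off over the first 11 windows and then removes LJ
with refinement near zero.

## 5. Diffusion corrections

Units are centralized in one constants table (`ff_constants`):
coordinates Å, times ps, energies kcal/mol,
$k_B = 0.0019872041$ kcal/(mol·K); viscosities enter in cP and
diffusion leaves in nm²/ns.

The periodic-boundary correction adopted is the extended Yeh-Hummer
form for a cubic box,
$$D_{PBC} = \frac{k_B T\,\xi}{6\pi\eta L} - \frac{2 k_B T R_h^2}{9\eta L^3},
\qquad \xi = 2.837297,$$
i.e. the point-particle Ewald term plus the leading finite-solute-size
correction. The second term matters at the ~3% level for a 13.86 Å
protein in a 78 Å box and is part of this package's definition of the
correction. The analysis temperature defaults to 300 K and is
configurable.

For crowded solutions the solvent viscosity is replaced by the
Einstein suspension viscosity $\eta_c = \eta(1 + 2.5\phi)$ with
$\phi = N\,\tfrac{4}{3}\pi R_h^3/L^3$ from $N$ spheres of the
protein's hydrodynamic radius; $\phi$ may also be supplied directly.
The Einstein relation is strictly a dilute-suspension result, so a
warning fires above $\phi = 0.1$ and an error above 0.5 — the
correction is used knowingly outside its strict regime, as is standard
in this kind of analysis. Finally $D' = D\,\eta_{sim}/\eta_{expt}$
rescales to the experimental water viscosity (default 0.89 cP vs the
simulated water's 0.35 cP), since simulated water that is too fluid
inflates absolute diffusion coefficients.

MSD curves average over all time origins and all selected particles
(or per-molecule centers of geometry); `fit_diffusion()` takes the
least-squares slope over a caller-chosen lag window divided by 6. The
default pipeline window of 30-50 ns targets the diffusive regime of
μs-scale protein trajectories; the synthetic tests use windows scaled
to their own trajectory lengths.

## 6. Synthetic generators: what they emulate, and what not

Every generator is a pure function of its seed and parameters.

- **Backbones** are built by internal-coordinate (NeRF) construction
  with standard geometry (N-CA 1.458 Å, CA-C 1.525 Å, C-N 1.329 Å,
  angles 111.2°/116.2°/121.7°, $\omega = 180^\circ$), reproducing
  requested $\phi/\psi$ to $10^{-6}$ degrees. They have no side
  chains, no hydrogens, and idealized geometry — sufficient for
  dihedral/H-bond/superposition oracles, not for force-field energies.
- **Brownian trajectories** draw independent Gaussian steps of
  variance $2D\,dt$ per axis, wrapped into the box. There are no
  hydrodynamic interactions, so the finite-size correction is *not*
  present in the fixture; $D_{PBC}$ is validated analytically, and the
  fixture validates only the MSD-slope estimator. A guard refuses
  step sizes above $L/4$, where unwrapping would be unsafe.
- **Langevin samples** use Euler-Maruyama proposals with a Metropolis
  acceptance step (MALA), so the stationary distribution is exactly
  $\propto e^{-\beta U_{total}}$ at any stable time step — the
  estimator tests then measure estimator error, not integrator bias.
- **GaMD boosts** use the lower-bound threshold form
  $\Delta V = \tfrac12 k (E - U)^2$ for $U < E$ with $E$ the maximum
  potential of an equilibration segment and
  $k = k_0/(E - U_{min})$, $k_0 = \min\{1, (\sigma_0/\sigma_U)(E-U_{min})/(E-U_{avg})\}$
  — the one-shot analogue of the iteratively updated production rule,
  guaranteeing $\Delta V \ge 0$ and $\sigma_{\Delta V} \le \sigma_0$
  (default 6 kcal/mol) on the sampled ensemble.
- The **double-well** test landscape is $U(x) = a(x^2-b^2)^2$ with
  $(a,b) = (1, 1.5)$ (kcal/mol, Å): basins at $\pm 1.5$ Å behind a
  5.06 kcal/mol (~8.5 $k_BT$ at 300 K) barrier. The reference
  umbrella schedule `double_well_umbrella_set()` uses eight windows
  with mixed force constants — soft (6 kcal/mol/Å²) in the basins,
  stiff (20-25) at the barrier top and outer walls — because uniform
  soft windows leave the barrier unpopulated while uniform stiff ones
  lose adjacent overlap; mixed schedules are standard practice in
  replica-exchange umbrella sampling. The PMF comparison grid spans
  $[-2, 2]$ Å, covering both basins and the barrier; beyond that the
  potential exceeds ~12 kcal/mol and bins fall below the occupancy
  threshold.

**Problem sizes.** The recovery tests use, per run: $10^4$ work
samples per direction for BAR; eight umbrella windows × 16 000
thinned samples for MBAR ($1.28\times10^5$ total); $2\times10^4$
boosted samples for the GaMD check; and ten seeds × 64 particles ×
200 frames for the diffusion fit. These sizes were chosen so that the
statistical error of each estimator sits comfortably inside the
tolerance it is tested against (e.g. MBAR PMF deviations of
0.03-0.06 kcal/mol against a 0.1 kcal/mol bound across seeds).

## 7. Degenerate inputs and tie-breaks

- Empty PMF bins are masked (`NA`), never printed as $-\infty$.
- CV values exactly on the shared upper edge of the last bin bin
  into that bin (determinism at boundaries).
- The unwrap operation assumes every true per-step displacement is
  below $L/2$ per axis (minimum image); this is unverifiable from
  wrapped data alone and is documented rather than detected.
- `fit_sigmoid` refuses constant fractions (degenerate fit) and
  `bar` refuses non-overlapping work distributions rather than
  returning extrapolations.
- Orthorhombic boxes only; triclinic cells, velocities, and PSF
  topologies are out of scope. Binary DCD reading is deliberately not
  implemented: all supported formats are text.

## 8. Known limitations

- The DSSP subset assigns only $\alpha$-helix; per-frame
  secondary-structure strings are not produced.
- The MBAR overlap diagnostic is a crude screen, not an eigenvalue
  overlap analysis.
- The Einstein viscosity is first order in $\phi$; at the crowding
  levels where it is applied (~0.19) higher-order terms are neglected
  by construction.
- Passing the synthetic battery shows the estimators are correct on
  clean, well-sampled, low-dimensional data; it cannot show that any
  particular λ is right for real proteins — that judgement needs the
  MD campaigns these tools post-process.
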