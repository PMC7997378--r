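---
title: "SAXS-restrained ensembles at hybrid resolution: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAXS-restrained ensembles at hybrid resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metasaxs)
```

## The problem

Flexible multidomain proteins interconvert between compact and extended
conformations on time scales that make any single structure a poor summary.
Small-angle X-ray scattering (SAXS) measures an orientationally and
ensemble-averaged intensity $I(q)$ and is therefore sensitive to the
*population balance* between such states, but it cannot by itself resolve
atomic detail. `metasaxs` implements the ingredients needed to combine the
two sources of information: a molecular prior (here, desk-scale toy
potentials standing in for a force field) is sampled by several replicas
whose *average* back-calculated SAXS intensity is restrained toward the
experimental curve, with all error sources inferred on the fly.

## The forward model

Scattering intensities are computed with the Debye equation over a
coarse-grained bead representation,

$$ I(q) \;=\; \sum_{i=1}^{M}\sum_{j=1}^{M} F_i(q)\,F_j(q)\,
   \frac{\sin(q R_{ij})}{q R_{ij}}, $$

where $R_{ij}$ is the distance between bead centers of mass and $F_i(q)$
the bead form factors. Mapping $N$ atoms onto $M \ll N$ beads reduces the
cost per evaluation from $O(N^2)$ to $O(M^2)$, which is what makes
on-the-fly restraining affordable. The shipped mapping is Martini-2.2
style: one backbone bead (N, CA, C, O) per residue plus zero to four
side-chain beads of roughly four heavy atoms; bead counts are a pure
function of sequence (e.g. the K63-linked diubiquitin construct with a
distal K63R substitution and an appended proximal D77 maps to 328 beads).
Bead form factors are derived by the Single Bead Approximation,
$F_\mathrm{bead}(q) = \langle I_\mathrm{bead}(q)\rangle^{1/2}$, averaging
the internal Debye intensity of each bead's member atoms (Cromer–Mann
atomic factors, in vacuo) over reference geometries. Two deliberate
simplifications: no hydration layer and no excluded-volume solvent term.
Consequently absolute intensities are on an arbitrary scale — which is why
a scale factor $\lambda$ appears in the restraint — and the valid $q$
range is capped at 0.45 Å$^{-1}$ with a warning beyond 0.2 Å$^{-1}$,
where the bead approximation degrades. The analytical coordinate gradient
of $I(q)$ is propagated through the mass-weighted virtual sites to parent
atoms and is verified against central finite differences at $10^{-6}$
relative tolerance.

## The metainference restraint

With $N_r$ replicas $X_r$ and targets $d_i$, the Gaussian-noise
metainference energy implemented here is

$$ E = \sum_{r=1}^{N_r}\sum_{i=1}^{N_d}\left[
  \frac{k_BT\,(\lambda \bar f_i - d_i)^2}{2\sigma_{r,i}^2}
  + \frac{k_BT}{2}\ln\!\big(2\pi\sigma_{r,i}^2\big)\right] + E_\sigma,
  \qquad
  \sigma_{r,i}^2 = \big(\sigma^{Bias}_{r,i}\big)^2 + \big(\sigma^{SEM}_i\big)^2 $$

where $\bar f_i = \sum_r w_r f_i(X_r)$ is the bias-weighted replica
average, $w_r \propto \exp[V_{PB}(X_r)/k_BT]$. The forward-model/data
uncertainty $\sigma^{Bias}$ (one per replica and data point) and the scale
$\lambda$ are sampled by Metropolis Monte Carlo; $\sigma^{SEM}$ is the
standard error of the replica mean, re-estimated over a sliding window of
recent restraint evaluations. Two limits anchor the implementation and are
asserted in the tests: a single replica reproduces the inferential
structure determination (ISD) energy exactly, and $\sigma^{Bias}\to 0$
recovers the replica-averaged maximum-entropy harmonic restraint on the
mean.

Design choices where the underlying formulation leaves freedom:

* **Error prior $E_\sigma$.** A Jeffreys prior $p(\sigma)\propto 1/\sigma$
  on each sampled $\sigma^{Bias}$ plus the explicit Gaussian
  normalization, the standard choice in the metainference literature; a
  uniform prior is available (`sigma_prior = "uniform"`).
* **Scale convention.** $\lambda$ multiplies the *calculated* averages
  ($\lambda\bar f_i$ vs $d_i$); the flat prior is $[0.5, 1.5]$ by default.
* **MC proposals.** $\sigma$ moves are log-space random walks with the
  Jacobian factor in the acceptance ratio (so the chain targets the
  $\sigma$-space posterior); $\lambda$ moves are uniform and rejected
  outright outside the prior. Because the energy is separable in the
  individual $\sigma_{r,i}$ given the replica-averaged mismatch, all
  $\sigma$ updates in a sweep are evaluated independently and vectorized.
  Correctness of the sampler is checked against the closed-form posterior
  (in $u = m/\sigma$ the posterior is a truncated standard normal): the
  Kolmogorov–Smirnov distance at $10^5$ sweeps must stay below 0.01.
* **$\sigma^{SEM}$ window.** 10 restraint evaluations, matching the
  multiple-time-step cadence.
* **Initialization.** $\lambda = 1$; $\sigma^{Bias}$ at 10% of each
  target intensity (scale-aware neutral start); bounds default to
  $[10^{-3}, 10]\times$ the mean target magnitude.

## Restraint preparation

Experimental curves are smoothed with a centered running average (default
21 points; edges truncate symmetrically) and restraint targets are taken
at equally spaced $q$ values (default 11 points in 0.06–0.16 Å$^{-1}$,
the low-noise region of a typical protein curve) by linear interpolation
of the smoothed curve. Whether deposited targets should sit on exact grid
points or be interpolated is underdetermined; linear interpolation is used
because smoothing has already suppressed the noise that higher-order
schemes would chase.

## The toy sampler

The sampler exists to exercise the restraint machinery end to end at desk
scale; it is not an MD engine. Toy systems are point particles with
harmonic bond networks and an optional double-well on the distance between
two group centers of mass — a caricature of a two-domain protein with
compact/extended interconversion. Dynamics is Langevin (BAOA splitting:
kick, half-drift, exact Ornstein–Uhlenbeck velocity refresh, half-drift),
which reduces to symplectic leapfrog at zero friction; units are Å, ps,
Da, kJ/mol with $k_B = 0.008314463$ kJ/mol/K. Restraint forces are
recomputed every `restraint_stride` steps (default 10) and held constant
in between — a zero-order hold justified by the slow temporal fluctuation
of SAXS observables. One R RNG stream drives all replicas: per-step noise
for every replica is drawn as a single block, which gives bit-reproducible
trajectories for a given seed (the replicas advance in lockstep, so
separate per-replica streams would add bookkeeping without changing the
statistics).

Parallel-bias metadynamics deposits one 1-D Gaussian per collective
variable (Rg, centroid distance, switched contact count, or a dihedral of
four centroids) with the well-tempered, parallel-bias height rule
$h_c = h_0\,e^{-V_c/((\gamma-1)k_BT)}\,P_c$,
$P_c \propto e^{-V_c/k_BT}$; defaults $h_0 = 1$ kJ/mol, $\gamma = 30$.
Gaussian widths are fixed per CV (dynamic width adaptation is out of
scope). All walkers read and write one shared pool, and the final pool is
identical whether a deposit schedule is executed by one walker or shared
among several. Free-energy profiles are estimated as
$-\gamma/(\gamma-1)\,V(s)$ using the *time-averaged* bias over the second
half of a run, which removes the Gaussian ripple of the instantaneous
estimator; with a 0.5 Å width the double-well reconstruction matches the
analytic profile (including the $-2k_BT\ln s$ Jacobian term of a distance
CV) to a few tenths of $k_BT$ over the thermally relevant region.

## What the synthetic data emulate — and what they do not

The generators provide (i) poly-alanine toy proteins (self-avoiding
Cα walks with idealized backbone decoration) so the shipped mapping
applies without edge cases; (ii) two-state ensembles drawn from a compact
and an extended geometry with known populations and Gaussian jitter; and
(iii) synthetic SAXS curves as population-weighted Debye intensities with
multiplicative Gaussian noise (mimicking low-q counting statistics;
additive noise available). Ground-truth labels and noise-free curves are
always returned, enabling parameter-recovery tests.

The headline end-to-end check restrains an 8-replica dumbbell simulation
toward a synthetic target generated at a 70:30 compact:extended balance
that the prior potential does not reproduce (its own equilibrium sits
near 25% compact, the extended state being entropically favored); the
restrained run must recover 70% ± 5 while the unrestrained control stays
at the prior mix. The noise level of the recovery target is set by an
identifiability argument, not by taste: with a free scale $\lambda$ and a
handful of restraint points, the $\chi^2$-optimal mixture population
shifts by roughly 4–5 percentage points per 1% of multiplicative noise,
so the recovery study uses 0.5% noise to keep the noise-induced bias on
the recoverable population below ~2% (the generator's general-purpose
default stays at 2%, typical of good beamline data). Two further caveats
documented deliberately: with 8 replicas the instantaneous replica
mixture is quantized at multiples of 1/8, which can bias the recovered
population a few percent above the target, and the jitter of the
generator does not exactly match the thermal width of the sampled wells —
a forward-model imperfection that $\sigma^{Bias}$ absorbs, exactly as
intended. Passing these tests shows
the restraint logic is correct; it does not show that a real protein
ensemble is recovered, which additionally depends on force-field quality,
experimental systematics (hydration layer, interparticle effects) and
sampling convergence — none of which a toy can emulate.

## Validation and analysis conventions

* **$\chi^2$ with scale:** reduced by $N_q$ with no parameter penalty;
  $\lambda^*$ from closed-form weighted least squares, clipped to bounds;
  conventional validation range 0.02–0.20 Å$^{-1}$.
* **Guinier fits** iterate the included set until $qR_g \le 1.3$ is
  stable; a non-negative slope raises a "no Guinier regime" error rather
  than returning a number.
* **Block averaging** reports the maximum of the error-vs-block-length
  curve (the conservative plateau reading) as the standard error of the
  ensemble-mean Rg under time correlation.
* **Clustering** follows the gromos neighbor-counting scheme (ties by
  lowest frame index) on best-fit backbone RMSD (mass-unweighted Kabsch
  superposition); compact pool defined by Cα-Rg below 2.0 nm; populations
  are fractions of the *full* ensemble, so they sum to the compact
  fraction.
* **PRE back-calculation** uses $\langle r^{-6}\rangle$ ensemble averaging
  (the standard treatment; averaging $\Gamma_2$ or $r$ instead would be
  less faithful to the measurement), a ±3 Å distance-uncertainty envelope
  floored at 1 Å, and defaults $\tau = 4$ ns, $\omega/2\pi = 600$ MHz,
  $K = 1.23\times10^{-32}$ cm$^6$s$^{-2}$ — the latter three are
  assumptions that must be set from the experiment at hand.
* **Contact maps** use a 4.5 Å minimum heavy-atom distance; Coulomb
  matrices use $k_e = 1389.35$ kJ Å/mol $e^{-2}$ with a 9 Å cutoff.

## Numerical choices

$\mathrm{sinc}$ and its derivative switch to series branches below
$10^{-6}$ so coincident beads are safe; pairwise distances are double
precision with no cutoff (SAXS is a global observable; $O(M^2)$ is
acceptable at $M \approx 300$); replica weights and the parallel-bias
combination are computed with max-shifts against overflow; degenerate
likelihoods ($\sigma = 0$ with nonzero mismatch) raise errors instead of
returning infinities.

## Problem sizes used in the shipped tests

The suite runs entirely on synthetic inputs: 60 000-step restrained runs
of an 8-replica, 8-particle dumbbell (restraint every 10 steps),
a 200 000-step single-walker metadynamics run for the double-well
reconstruction, $10^5$ Monte-Carlo sweeps for the posterior check, and
$10^4$-frame synthetic ensembles for the block-average oracle. These sizes
were chosen as the smallest at which the statistical assertions have
comfortable margins; all are reproducible from fixed seeds.

## Known limitations

No hydration-layer or excluded-volume corrections; Martini 2.2-style (not
Martini 3) mapping; no mmCIF or compressed-trajectory readers; the toy
sampler has no barostat, constraints or PME and is not intended for real
force fields; PRE assumes a single effective correlation time and no
explicit spin-label rotamers; $q$ unit autodetection (nm$^{-1}$ vs
Å$^{-1}$) is deliberately not attempted.
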