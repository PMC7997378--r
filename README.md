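# metasaxs

Hybrid-resolution SAXS-restrained conformational ensembles in R.

Flexible multidomain proteins populate mixtures of compact and extended
states. Small-angle X-ray scattering (SAXS) measures the ensemble-averaged
intensity I(q) and therefore constrains the population balance, but only if
the simulation that interprets it (a) can afford to back-calculate I(q) at
every restraint step and (b) treats data, forward-model and finite-sampling
errors honestly. `metasaxs` implements both ingredients and the analysis
around them:

* **Coarse-grained Debye forward model.** Martini-style bead mapping (one
  backbone bead plus 0–4 side-chain beads per residue; shipped as an
  editable text table), bead form factors from the Single Bead
  Approximation over reference geometries with Cromer–Mann atomic factors,
  and the Debye sum

  I(q) = Σᵢ Σⱼ Fᵢ(q) Fⱼ(q) sin(qRᵢⱼ)/(qRᵢⱼ)

  over bead centers of mass — O(M²) instead of O(N²) — with analytical
  coordinate gradients (finite-difference verified to 1e-6).

* **Metainference restraint.** Gaussian-noise replica-averaged Bayesian
  energy with per-replica/per-datapoint uncertainties σ^Bias (Monte-Carlo
  sampled under a Jeffreys prior), a sampled intensity scale λ (flat prior
  0.5–1.5), and the replica-averaging standard error σ^SEM estimated over
  a sliding window. One replica reduces exactly to inferential structure
  determination; σ^Bias → 0 recovers maximum-entropy replica restraining.

* **Toy multi-replica sampler.** Langevin dynamics (BAOA splitting) on
  harmonic-network/double-well toy systems, restraints applied on a
  multiple-time-step schedule (default every 10 steps), optional
  well-tempered parallel-bias metadynamics with shared multiple-walker
  Gaussian pools and bias-reweighted replica averaging.

* **Validation suite.** PRE back-calculation with ⟨r⁻⁶⟩ ensemble averaging
  and a ±3 Å distance-uncertainty envelope, Guinier and Kratky analysis,
  χ² with closed-form optimal scale, Rg distributions with block-average
  errors, 2-D free-energy surfaces, gromos clustering of compact states,
  and interdomain contact/Coulomb maps.

## Worked example

Restrain an 8-replica toy dumbbell toward a synthetic SAXS target generated
from a known 70:30 compact:extended ensemble, then measure what the
restraint recovered:

```r
library(metasaxs)

sys <- make_dumbbell_system()                  # extended-start two-domain toy
gA  <- attr(sys, "groupA"); gB <- attr(sys, "groupB")
xc  <- make_dumbbell_system(start = "compact")$x

truth <- make_two_state_ensemble(xc, sys$x, p = 0.7, n_frames = 400,
                                 jitter = 0.3, masses = sys$masses, seed = 11)
q   <- seq(0.05, 0.20, length.out = 7)
syn <- make_synthetic_saxs(truth, q = q, noise_rel = 0.005, seed = 12)
rs  <- structure(list(q = q, intensity = syn$curve$intensity,
                      error = syn$curve$error, window = 1L),
                 class = "restraint_set")

restr <- run_restrained(sys, n_replicas = 8, n_steps = 60000,
                        restraints = rs, restraint_stride = 10,
                        record_stride = 25, seed = 7)
unres <- run_restrained(sys, n_replicas = 8, n_steps = 30000,
                        restraints = NULL, record_stride = 25, seed = 7)

compact_fraction(restr, gA, gB, threshold = 18)   # 0.7049  (truth: 0.70)
compact_fraction(unres, gA, gB, threshold = 18)   # 0.2646  (prior mix)
tail(restr$traces$lambda, 1)                      # 0.998   (sampled scale)
```

The restrained run recovers the 70% compact population the prior misses
(the unrestrained control stays near 26%, the entropy-favored extended
mix), and the sampled scale λ sits at ~1 because target and forward model
share units. The same machinery applies to mapped proteins: for the
K63-linked diubiquitin construct (distal K63R + proximal D77),

```r
count_beads(...)   # 328 beads for the 153-residue construct
```

## Command line

A thin CLI over the same functions lives at `inst/cli/metasaxs.R`
(subcommands `prep-restraints`, `saxs`, `map`, `pre`), e.g.

```sh
Rscript inst/cli/metasaxs.R prep-restraints --saxs curve.dat \
    --n 11 --qmin 0.06 --qmax 0.16 --window 21 --out restraints.dat
```

See `vignettes/ensemble-restraints.Rmd` for the model, parameter and
validation details.
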