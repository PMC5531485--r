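---
title: "An exclusion-process model of cell-line passaging and scratch assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An exclusion-process model of cell-line passaging and scratch assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(hexpassage)
```

## The model

`hexpassage` simulates 2D cell culture as an exclusion process on a hexagonal
lattice. Each site, indexed $(i, j)$ with $1 \le i \le I$, $1 \le j \le J$,
holds at most one cell and has position

$$(x, y) = \big((i - 1)\Delta,\ \sqrt{3}(j - 1)\Delta/2\big) \text{ for even } j,
\qquad \big((i - \tfrac12)\Delta,\ \sqrt{3}(j - 1)\Delta/2\big) \text{ for odd } j,$$

with the spacing $\Delta$ equal to the average cell diameter (24 µm by
default), so every site has six nearest neighbours at distance $\Delta$.

Time advances in steps of duration $\tau$ (default 1/12 h). In each step,
with $N(t)$ the population at the step start:

1. **Motility sweep.** $N(t)$ times, a cell is selected uniformly at random
   *with replacement*; with probability $P_m$ it picks one of its six
   neighbour directions uniformly and moves there. The move is aborted if the
   target is occupied or outside the domain (which realises zero-net-flux
   boundaries).
2. **Proliferation sweep.** Another $N(t)$ selections; the selected cell
   divides with its own probability $P_p$, placing a daughter on a uniformly
   chosen neighbour site, aborted under the same crowding/boundary rule. The
   daughter inherits the mother's $P_p$ exactly. There is no death process.

Heterogeneity enters only through $P_p$: each founder cell draws
$P_p \sim N(\mu_p, \sigma)$ (clipped to $[0,1]$; $\sigma$ is a standard
deviation). $P_m$ is a single global constant — the model deliberately
excludes motility heterogeneity, adhesion, death, and age-structured
inheritance.

The discretisation is calibrated so that the defaults $P_m = 0.35$,
$\mu_p = 0.004$, $\Delta = 24$ µm, $\tau = 1/12$ h correspond to an isolated
-cell diffusivity $D = P_m\Delta^2/(4\tau) = 604.8$ µm²/h (≈600) and an
uncrowded per-capita growth rate $\lambda = \mu_p/\tau = 0.048$ /h (≈0.05),
typical of cultured mesenchymal-like cells:

```{r}
model_parameters()
```

Two prototype populations are studied throughout: **near-homogeneous**
($\sigma = 10^{-4}$) and **heterogeneous** ($\sigma = 10^{-3}$), both with
the same mean $\mu_p = 4 \times 10^{-3}$.

## Passaging

The culture protocol mirrors routine 2D cell culture: seed 15% of lattice
sites uniformly at random, grow until 85% confluence
($N/(IJ) \ge 0.85$, checked after each completed step), then *split*:
sample, uniformly without replacement, enough cells to cover 15% of sites,
and reseed them on an empty lattice. The passage number counts splits;
"passage 0" is the first growth cycle from fresh $P_p$ draws, and every
per-passage record is taken at the moment 85% confluence is reached.

Splitting is mechanically and chemically disruptive, so each transferred
cell's $P_p$ is decremented by an independent draw
$\epsilon \sim N(\mu_\epsilon, \sigma_\epsilon)$, with negative draws set to
zero (damage never *raises* $P_p$) and the result floored at 0. Presets:
`none` ($\epsilon \equiv 0$), `small` ($N(2\times10^{-5}, 2\times10^{-5})$),
`large` ($N(10^{-4}, 10^{-4})$). The mean applied decrement is the rectified
-normal mean $\mu_\epsilon\Phi(\mu_\epsilon/\sigma_\epsilon) +
\sigma_\epsilon\phi(\mu_\epsilon/\sigma_\epsilon)$ — about
$1.083\times10^{-4}$ per passage for the large preset
(`expected_damage(damage_model("large"))`).

Two opposing forces act on the $P_p$ distribution. Faster-dividing cells
over-produce daughters that inherit their $P_p$, so with $\sigma > 0$
selection pushes the distribution up and skews it negatively; damage pushes
it down by a roughly constant amount per passage. Their balance decides
whether the median $P_p$ rises, falls, or rises then falls with passage
number — the model's central result.

```{r, eval = FALSE}
exp <- run_passaging_experiment(
  passaging_protocol(n_passages = 30, damage = damage_model("large")),
  model = model_parameters(population = "heterogeneous"),
  lattice = lattice_config(300, 260), seed = 1)
exp$records[, c("passage", "pp_median", "pp_q1", "pp_q3")]
```

## The scratch assay

The in silico scratch assay reproduces the geometry of an IncuCyte-style
field of view: an 80 × 68 lattice (≈1900 µm × 1400 µm at $\Delta = 24$ µm),
every site independently occupied with probability 0.30, and a vertical
strip of 23 contiguous columns (≈550 µm) vacated at $t = 0$. $P_p$ values
are drawn either from a normal distribution or by resampling, with
replacement, an empirical $P_p$ table harvested from a passaging run —
resampling raw values preserves the selection-induced skewness that a
re-fitted normal would destroy. Re-colonisation is tracked by the column
density $\langle C_i\rangle = \frac1J\sum_{j=1}^{J} C_{i,j}$, averaged over
ensembles of identically prepared realisations (default 100; realisation
$r$ uses seed `base_seed + r`).

```{r, eval = FALSE}
ens <- run_scratch_ensemble(scratch_config(n_realisations = 100),
                            base_seed = 1)
plot_density_profiles(ens)
```

Closure is reported *visually* in the experimental literature; to make it
reproducible, `closure_time()` declares the scratch closed at the first
recorded time when the mean density inside the originally scratched columns
reaches at least 90% (configurable) of the mean density outside them at the
same time. This is a deliberately strict reading: because the ambient
density is itself still growing toward confluence, profiles that already
look flat to the eye can sit below the 0.9 ratio for many hours, and the
measured mean closure time under this criterion (≈80 h for the baseline
20-realisation ensemble computed by `scripts/acceptance.R`) runs past the
≈48–72 h window that visual inspection of snapshots suggests. Users who
want the visual reading can lower `threshold` or compare against the
*initial* ambient density.

## Numerical and design choices

- **Selection pool mid-sweep.** The update fixes the *number* of
  proliferation attempts at $N(t)$ but draws each attempt uniformly from the
  population at the moment of the draw, so daughters born earlier in the
  sweep can be selected — the standard random-sequential-update reading of
  "one at a time, with replacement". The alternative (candidate pool frozen
  at sweep start) is available via `newborns_eligible = FALSE` for
  sensitivity checks; at the default parameters ($P_p \ll 1$) the two are
  practically indistinguishable.
- **Boundaries and directions.** Targets are always drawn from the six
  *geometric* directions with probability 1/6 each and then validity
  -checked; off-domain targets abort the event exactly like crowded ones.
  Direction probabilities therefore never depend on position.
- **Clipping.** Initial $P_p$ draws are clipped to $[0,1]$ (they are
  probabilities); at $\mu_p = 0.004$, $\sigma = 10^{-3}$ a negative draw
  occurs with probability ≈ $3\times10^{-5}$ per cell, so clipping is
  invisible in moments but necessary at flask scale. Damage uses
  $\max(\epsilon, 0)$ per the model's no-rejuvenation assumption.
- **Confluence targets.** `grow_to_confluence()` stops at the first state
  with $N \ge \lceil 0.85\,IJ\rceil$; splits transfer exactly
  $\mathrm{round}(0.15\,IJ)$ cells. A safety cap (default 20000 steps)
  turns a non-growing culture (e.g. $P_p$ damaged to 0) into an explicit
  error rather than a hang.
- **RNG.** Everything flows from R's global RNG; high-level drivers take a
  seed, and ensemble realisation $r$ re-seeds with `base_seed + r`, so any
  run, realisation or figure is bit-reproducible.
- **Quartiles and sd.** Per-passage records use type-7 quantiles and the
  sample (n−1) standard deviation.

## Problem sizes

The printed flask lattice ($I = 4168$, $J = 3610$, ≈15 million sites at
100% confluence) is fully supported, but the package's tests and worked
examples run on proportionally scaled lattices with the same 15%/85%
fractions, because the passaging dynamics are driven by density *fractions*:
the trend direction of the median $P_p$ (flat for near-homogeneous without
damage; increasing for heterogeneous without damage; monotonically
decreasing for near-homogeneous with damage; rise-then-fall for
heterogeneous with large damage) is reproduced from 100 × 87 up. One
quantity is *not* scale-invariant and is worth understanding before
comparing small runs to flask-scale results: the *location* of the
rise-then-fall peak. The selection plateau is set by the largest founder
$P_p$, roughly $\mu_p + \sigma\sqrt{2\ln n_0}$ for $n_0$ founder draws, so
small lattices (fewer founders, shorter upper tail) exhaust their selection
gain sooner and peak earlier: the heterogeneous/large-damage median peaks
near passage 10 on a 300 × 260 lattice (the trajectory computed by
`scripts/acceptance.R`), and the extreme-value argument above implies the
peak moves to later passages as the founder pool grows toward the
flask-scale ≈2.26 million.

## What the generator does and does not emulate

The synthetic populations reproduce the *mechanisms* under study —
volume exclusion, heritable proliferation heterogeneity, fraction-driven
passaging, stochastic non-negative damage — under idealised conditions:
perfectly binary site occupancy, a single global motility rate, no death,
no senescence clock, no adhesion, and damage that is independent across
cells and passages. Passing tests therefore demonstrate internal
consistency with this model class and with its mean-field limits (logistic
growth, random-walk diffusivity), not agreement with any particular real
cell line; real assays add measurement noise, uneven seeding, edge effects
of the physical well, and biology (contact inhibition of mitosis beyond
simple crowding, cell-cycle age structure) that this model excludes by
design.

## Known limitations

- The mean-field logistic solution is used only as a test oracle; no
  spatially resolved continuum (PDE) approximation is provided.
- Closure times are resolved only to the recording cadence (hourly by
  default).
- Flask-scale 30-passage runs are computationally heavy on a single core
  (hours); the package does not parallelise across realisations, though
  ensembles are trivially parallel by seed.
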