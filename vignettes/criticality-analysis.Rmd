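---
title: "Detecting critical dynamics in collective activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting critical dynamics in collective activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivecrit)
```

## The question and the strategy

Colonies of social insects coordinate without central control, and one
influential hypothesis holds that such systems — like cortical networks —
operate near a second-order phase transition, where correlations span the
whole system and fluctuations occur at every scale. `hivecrit` implements a
complete analysis pipeline for testing this idea on movement data: the
activity of every individual is reduced to a scalar time-series, pairwise
Pearson correlations between individuals define a functional network, and
the statistical signatures of that network (heavy-tailed degree
distribution, small-world structure) and of the aggregate activity series
(long-range temporal correlation, measured by the Hurst exponent) are
compared against the two-dimensional Ising model — the canonical system
with a tunable critical point — simulated under exactly the same analysis.

The package has two symmetric halves. The *model side* is self-contained:
a Metropolis Monte Carlo simulator produces spin time-series whose analysis
requires no external data. The *data side* ingests trajectory tables
(individual id, timestamp, x, y); because the original colony recordings
are third-party and not redistributable, the package ships a synthetic
trajectory generator with controllable, known correlation structure, so
every stage of the data side is testable against ground truth.

## Trajectory preprocessing

Raw detections are resampled by linear interpolation onto a uniform grid
(`resample_tracks()`). The sampling interval `dt` defaults to 1 s, the
natural scale of within-hive movement tracking; it is configurable. Grid
points outside an individual's observed detection span are filled by
holding the nearest endpoint but flagged as *not covered*: extrapolation
would invent motion, and the covered fraction is exactly what the
inactivity filter needs. `filter_inactive()` keeps tracks with coverage at
least 0.8 (default) and total path length above a displacement floor
(default 0, i.e. any movement). Both thresholds are exposed because no
principled universal value exists; the defaults express "the individual was
observable for most of the window and actually moved".

Activity is quantified per interval as the squared displacement
\(k_t = \Delta x_t^2 + \Delta y_t^2\) — a massless kinetic-energy proxy.
No mass or 1/2 factor is included, and none is needed: every downstream
statistic (Pearson correlation, the Hurst slope) is invariant to positive
scaling. For the same reason the colony-level series `hive_activity()`
defaults to the arithmetic *mean* across individuals even though a plain
sum is equivalent for inference (a `"sum"` mode exists).

Time windows (`partition_windows()`, `day_night_windows()`) are half-open
`[start, end)`; a sample on the boundary of two abutting windows belongs to
the later one, exactly once.

## The Ising reference model

`simulate_ising()` runs single-site Metropolis dynamics on an `L × L`
torus with `J = 1`, `k_B = 1`, zero field. One sweep is `N = L²` update
attempts at uniformly random sites; a flip of spin `i` with energy change
`dE = 2 s_i Σ_nn s_j` is accepted with probability `min(1, exp(-dE/T))`.
The Hamiltonian counts each nearest-neighbour bond once (`E = -2N` for the
aligned ground state); only `dE` matters to the dynamics, so this is purely
a reporting convention. The protocol is thermalize-then-record: 10000
discarded sweeps, then 2000 recorded configurations separated by one sweep,
at `T = 2.0` (ordered), `T = 2.3` (near-critical for finite lattices;
the exact infinite-lattice value is
\(T_c = 2/\log(1+\sqrt 2) \approx 2.2692\), available as
`ising_critical_temperature()`) and `T = 3.0` (disordered).

**Initialization.** Above \(T_c\) the start state is irrelevant after
thermalization and a hot (random) start is used. Below \(T_c\), however, a
hot start is a quench: the lattice coarsens into domains and, on a torus,
frequently locks into striped metastable states that single-site dynamics
cannot anneal on any practical timescale. Such runs have `|M| ≈ 0`, a
dense web of domain-wall correlations, and look nothing like the ordered
phase the low-temperature simulation is meant to represent. `init = "auto"`
therefore prepares sub-critical runs from the all-up state; at `T = 2.0`
this reproduces the exact spontaneous magnetization (0.911) to within
Monte-Carlo error. The sampler itself is validated against exhaustive
Boltzmann enumeration on 2×2 and 3×3 tori (chi-square, α = 0.01).

## Correlation networks matched on mean degree

`pearson_matrix()` correlates every pair of node series (lattice sites or
individuals). Constant series — frozen sites, motionless individuals —
have undefined correlation; they are assigned r = 0, flagged, and kept as
permanently isolated nodes. Networks are binarised by `r > p` (strict, on
the signed coefficient; an `absolute = TRUE` mode exists but is not the
default, since coordinated activity produces positive correlation).
Because correlation scales differ across systems, networks are compared at
matched *mean degree*: `choose_threshold()` bisects `p` until
`⟨k⟩` is within 1% of the target (110 by default, the regime in which the
model networks remain connected), reporting the achieved value. Isolated
nodes are retained in the node set; path metrics are computed on the giant
component (`giant_component()`, deterministic tie-break).

`path_metrics()` computes the exact diameter always, and the average
shortest-path length exactly up to 2000 nodes; above that it averages
1000 seeded BFS sources (standard error reported; at `n = 10^4` the
estimator error is far below every tolerance used here).
`er_reference()` provides the matched random baseline: `G(n, p)` with
`p = ⟨k⟩/(n-1)` (expected-degree matching; an "equivalent random graph" is
underdetermined, and matching the expected degree is the common reading),
10 graphs by default.

## Degree-distribution fitting

`fit_degree_distribution()` fits three discrete families by maximum
likelihood to the degree tail `k ≥ xmin`: a pure power law (zeta
normalization), a power law with exponential cutoff ("truncated power
law", `P(k) ∝ k^{-α} e^{-λk}`), and an integer-binned log-normal. `xmin`
is selected by Kolmogorov–Smirnov minimization on the power-law family and
shared across candidates so their likelihoods are comparable; an
unrestricted log-normal fit (support from 1) is reported additionally.
Zero-degree nodes are excluded from fitting (their count is reported).

Two numerical conventions matter and are deliberate:

* the cutoff family is constrained to `α > 1`, the convention of the
  standard fitting literature — without it the family mimics bell-shaped
  (rising) distributions with `α < 0` and both the comparison and the
  reported exponent lose meaning;
* the KS statistic uses only the right-continuous ECDF step, since both
  CDFs are step functions on the integers (the continuous two-sided
  variant inflates the distance at large atoms and drags `xmin` upward —
  detectable as bias against a known power-law generator).

Model comparison follows the Clauset-style recipe: the nested
power-law/cutoff pair by a chi-square likelihood-ratio test; non-nested
pairs by the normalized (Vuong) log-likelihood ratio. The cutoff family is
adopted only when it significantly improves on the pure power law, and the
log-normal only when the Vuong test significantly favours it. On tails
selected deep in the distribution all heavy-tailed families become
statistically indistinguishable — the familiar power-law-versus-log-normal
ambiguity — so family recovery is only guaranteed when the fitted support
covers the body of the data.

## Hurst exponent from lag-variance scaling

`estimate_hurst()` transforms a series into its cumulative-deviation
profile \(K_{sum}(t) = \sum_{i \le t} (K_i - \mu)\) and measures
\(\mathrm{Var}(\tau) = \langle (K_{sum}(t+\tau) - K_{sum}(t))^2 \rangle\)
on ~20 log-spaced lags from 2 to n/4. For a self-affine profile
\(\mathrm{Var}(\tau) \propto \tau^{2H}\); `H = 0.5` is memoryless,
`H > 0.5` persistent.

The profile ends at zero by construction (the sample mean is subtracted),
i.e. it is a *bridge*, and bridge increments at large lags are
systematically deflated relative to \(\tau^{2H}\). The naive `slope/2`
estimator therefore reads low — mildly near `H = 0.5`, by ~0.1 at
`H = 0.9`, and no lag cap removes the effect. The default estimator
instead fits `log Var(τ)` to the *exact* expected bridge variance of a
self-affine profile (closed form, computed per lag); the raw OLS slope is
still reported, and `bridge_correction = FALSE` restores the plain
convention. Validated against circulant-embedding fractional Gaussian
noise (`generate_fgn()`, exact target autocovariance): the mean estimate
over 50 replicates of length 2^14 is within 0.05 of the target for
`H ∈ {0.3, 0.5, 0.7, 0.9}`. `shuffle_control()` re-estimates H after a
seeded random permutation; long-memory series drop to ≈ 0.5, the signature
that the original estimate measured temporal structure rather than the
marginal distribution.

## The synthetic hive generator

`generate_hive()` emulates the *shape* of barcode-tracking data — ~1200
individuals, seconds-scale sampling over hours, detection dropouts — with
a deliberately *non-critical* construction: groups carry independent
two-state (burst/quiescent) telegraph activity signals, individual speeds
follow their group's signal plus noise, headings random-walk, and motion
reflects off the walls of a bounded rectangular arena. Within-group energy
series share a driver (high pairwise correlation); across groups they are
independent. A seeded fraction of individuals never activates and a seeded
fraction of detection rows is deleted. This gives the pipeline known
ground truth: group structure must reappear as network blocks with
clustering above the matched random baseline, and correlations must vanish
under shuffling. What passing these tests does *not* show is that real
colony data behave critically — the generator contains no phase
transition by design; the Ising model supplies the genuinely critical
signal.

Defaults (1200 bees, 6 groups, 2 h at 1 s, ~5-minute bursts, 5% inactive,
10% dropout) encode a realistic recording; tests run reduced
configurations for speed, stated explicitly at each call.

## Problem sizes, determinism, limitations

The study-scale analysis uses `L = 100` (10^4 sites), 10000 + 2000 sweeps,
and a 10^4 × 10^4 correlation matrix (~800 MB); one full
temperature chain takes a few minutes on a single core. Tests exercise the
same code mostly at reduced size, plus one full-scale chain per
temperature in the acceptance file. All generators and pipelines are pure
functions of their configuration and seed; note that very large matrix
products computed through multithreaded BLAS can differ in the final bits
between runs, which may flip edges lying exactly at the threshold.

Two scientific limitations deserve emphasis. First, at `T = 2.3` on a
100 × 100 lattice the system is quasi-critical: the equilibrium
magnetization distribution is wide and its relaxation time far
exceeds the 2000-sweep recording window, so the recorded window captures a
single slow excursion and the derived network's path length, diameter and
fitted tail exponent vary substantially from seed to seed (clustering is
much more stable). Any single published value for these quantities should
be read as one draw from a wide distribution. Second, family selection
between cutoff power laws and log-normals on threshold-network degree
tails is frequently statistically insignificant; the package reports the
full comparison table rather than only a winner.
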