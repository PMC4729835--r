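---
title: "A stochastic lattice model of melanoblast colonization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic lattice model of melanoblast colonization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`melanosim` simulates melanoblast colonization of the growing embryonic
trunk as a volume-excluding random walk with proliferation on a
stochastically growing square lattice, and implements the statistics that
connect such a model to cell-tracking data. This vignette records the model,
its assumptions, the numerical conventions, and the design decisions made
where more than one reasonable choice existed.

## Model and assumptions

The dorsoventral integument (the dermal/epidermal layers that support
melanoblast survival, treated as one compartment) is a lattice of
`L_x(t) x L_y(t)` sites of spacing Δ = 38 μm, the diameter of one
melanoblast: a single agent therefore excludes 1,444 μm², and a fully
occupied domain holds ~692 cells/mm². Each site holds at most one agent.
Time is continuous; the process is a Markov chain simulated exactly by the
Gillespie algorithm: with `N` agents, the total propensity is
`R = N (P_m + P_p) + P_ga + P_gd`, waiting times are `Exp(R)`, and the event
class is chosen with probability proportional to its propensity. For
movement and proliferation the agent is chosen uniformly and the target is
one of the four von Neumann neighbours, chosen uniformly (the biological
statement is only "an adjacent site"; the 4-neighbourhood is the standard
exclusion-process choice). An attempt into an occupied or off-lattice site
is **aborted but still consumes the sampled event** — the standard
convention for exclusion processes, and the only reading under which
"the event is aborted" leaves the chain Markovian. Boundaries are zero-flux
(efflux assumed balanced by influx). There is no cell death, no directed
motility, no chemotaxis and no signalling: colonization, stripe formation
and belly spots must emerge from crowding, proliferation and domain growth
alone, which is the hypothesis the model tests.

Domain growth is the "pushing" mechanism: a dorsoventral growth event
inserts one new empty site into *every* axial row, at a column drawn
uniformly and independently per row (the insertion index is uniform on
`1..L_x`, and contents at or beyond it shift one site ventrally, carrying
their occupants). Axial growth is the mirror image. Growth events occur at
constant rates, so the mean extent grows linearly, matching the
morphometric measurements the defaults are built on. Where the text of the
source measurements left open whether the insertion position is shared
across rows, we draw it independently per row; sharing it would translate
entire tissue columns rigidly, which has no biological reading, while
independent insertion is the isotropic-growth limit.

## Parameters

| parameter | symbol | default | units | rationale |
|---|---|---|---|---|
| lattice spacing | Δ | 38 | μm | melanoblast diameter; sets 1,444 μm² exclusion, 692 cells/mm² full density |
| movement attempt rate | P_m | 0.2 | min⁻¹ | see "Anchoring the movement rate" |
| proliferation attempt rate | P_p | ln 2/420 ≈ 0.00165 | min⁻¹ | 7 h unconstrained doubling, the dermal E10.5–E11.5 maximum (6.6 h rounded up) |
| dv growth rate | P_gd | 0.0246 | min⁻¹ | linear mean dorsoventral growth fit |
| axial growth rate | P_ga | 0.00526 | min⁻¹ | linear mean axial growth fit |
| initial extent | L_x(0) × L_y(0) | 31 × 43 | sites | 1,178 × 1,634 μm at E10.5 |
| founders | — | 21 | cells | E10.5 trunk melanoblast count (20.32 ± 5.95) |
| duration | — | 7,200 | min | E10.5 → E15.5, 5 days |

Founders are placed with the weighted empirical distribution: axially, 1/3
of the mass uniform on sites 12–32 and 2/3 on sites 1–11 ∪ 33–43 (the
mid-trunk under-representation seen in reporter embryos); dorsoventrally,
95% uniform on sites 8–17 and 5% on 18–19, which reconciles the two
partially overlapping statements "95% between 8 and 17" and "all between 8
and 19". Collisions are resampled; lineage labels `1..21` are heritable and
immutable.

### Anchoring the movement rate

P_m is the one parameter whose fitted value is not recoverable from the
published material (it was calibrated against unpublished density–diffusion
measurements). We anchor it on the model behaviours that *are* published:
with a 7 h cell cycle the wildtype domain colonizes fully and reaches
~700 cells/mm² mid-domain, while slowing the cycle to 10 h leaves a ventral
belly spot, and colonization probability is far more sensitive to the
cell-cycle time than to two-fold changes in diffusion. In this
implementation those behaviours hold together for P_m between roughly 0.1
and 0.4 min⁻¹ — below that range the colonization front
(speed ~ 2·sqrt(D·P_p)) cannot keep pace with the stretching domain — and we
fix P_m = 0.2 min⁻¹ once (free-agent D = P_mΔ²/4 ≈ 72 μm²/min). The rate
remains a first-class parameter, and `fit_movement_rate()` re-fits it from
any user-supplied density–diffusion table by the least-squares procedure the
original calibration used (common random numbers across candidate rates
stabilize the argmin).

One published observation does not fit this anchor: under the crowded
50 × 50 initialization with 500 distinct lineages (`cheeseman` scenario,
growth off), strong lineage dominance with the two largest clones above 25%
of the final population arises in this implementation only for movement
rates an order of magnitude below the colonizing range (the acceptance
script reports the measured share at the default, ~8–9%). Dominance there is
controlled by how quickly deep layers of the initial block are released by
movement relative to how fast the front proliferates; fast mixing
democratizes the expansion. We report the measured value rather than tune
for it.

## Scenarios

* `wildtype` — 21 weighted founders, full growth; the 5-day colonization.
* `chimera` — founders given ±1 colour labels: balanced (10 or 11 chosen at
  random) or `k` founders +1 versus `21−k` (the "clonal ratio").
* `rare_clone` — one living agent, chosen uniformly at a time drawn
  uniformly on (0, duration), is marked; progeny inherit the mark.
* `cheeseman` — 50 × 50 lattice, 10 dorsal-most columns occupied by 500
  distinct lineages. The source text is ambiguous about domain growth in
  this comparison; we run it growth-free (the cited comparison work used
  dorsoventral-only or no growth, and growth-free is the cleaner contrast
  of initial conditions). This choice matters little: with growth on at the
  default rates the top-2 share moves from ~8% to ~14%, still far from the
  sparse-founder regime.

## Statistics and numerical conventions

**MSD and diffusion.** `msd_time_ensemble()` averages squared displacements
over all tracks and all start times (time-ensemble averaging); tracks must
share one sampling interval. `fit_diffusion()` fits a line through the
origin by unweighted least squares over the **first quarter** of available
lags (at least two) — short lags carry most of the information and the long
lags of time-ensemble MSDs are increasingly correlated and noisy; the
published fits do not state their range. `D = slope/4` in 2D.

**Pair-correlation function.** Non-periodic pair counting in annuli of
width 4 μm (about a tenth of a cell diameter) against the expected count for
a same-size CSR pattern in the same window. The CSR reference is estimated
once by Monte-Carlo sampling of 5 × 10⁵ uniform point *pairs* under a fixed
private seed (the inter-point distance distribution does not depend on n, so
sampling pairs is equivalent to sampling full patterns and far cheaper); the
caller's RNG stream is saved and restored. The default analysis window is
the 256 × 256 μm central image portion used for the experimental patterns.

**Berman Z1.** `Z1 = (Σᵢ Z(xᵢ) − n μ_W)/sqrt(n σ²_W)` with the covariate's
window moments computed on a 201 × 201 quadrature grid and a two-sided
normal p-value. The covariate used in the published test is unstated; we
default to the dorsoventral coordinate, the axis along which any systematic
density gradient would lie. Constant covariates are rejected.

**Orientation uniformity.** One-sample Kolmogorov–Smirnov against
Uniform[0°, 180°): angles are orientations (Feret-angle semantics), not
directions.

**Cell-cycle estimator.** `T_c = T_m / P_mc`, with domain checks
(`0 < P_mc ≤ 1`).

**Clonal signal and stripe intensity.** Site values +1/−1/0 (two colours /
empty) are averaged over the dorsoventral extent of each axial row. Spectra
are two-sided amplitudes `|DFFT|/N` (so Parseval reads
Σ amplitude² = mean signal²); ensemble spectra are averaged after truncating
all signals to the shortest length (replicate domains grow to stochastic
lengths; truncation, unlike padding, adds no spurious power). The **DC
component is excluded** from the dominance search — it measures colour
imbalance, not periodicity — and the search runs to the Nyquist frequency.
"Stripe intensity" is the amplitude at the dominant frequency of the
averaged spectrum.

**Belly spot.** The qualitative figure readout is operationalized as: the
largest 4-connected component of empty sites that touches the ventral
boundary (`i = L_x`) with at least 5 sites (~7,200 μm², several cell areas —
large enough to ignore transient single-site vacancies, small enough to
catch any real patch). `colonization_status()` is its negation.

**Periodic calibration domain.** Density–diffusion and density–cell-cycle
relations are measured on a 17 × 17-site periodic lattice (646 μm — the
microscope field of view), 400 min, move-only for D (density constant).
Tracks are truncated at the first boundary crossing, emulating the loss of
cells that leave the field of view; this conditioning removes the fastest
excursions and biases fitted D downwards by ~5–10% even for a free walker —
a property of the measurement protocol, reproduced deliberately (the tests
verify the unbiased free-walk value 72.2 μm²/min on untruncated walks, and
that truncation only ever biases downwards). The **effective cell-cycle
time** at a density is total observed agent-minutes divided by successful
divisions (the mean inter-division time per agent) over a 240-min window,
short enough that density changes stay modest; how the published emergent
curve was computed is unstated, and this is the estimator with an exact
low-density limit `1/P_p`.

**Sensitivity sweep.** The D axis is implemented as multipliers of P_m
(D ∝ P_m at fixed Δ; D₀ is the default-rate diffusion), the T_c axis as
`P_p = ln 2/(60·T_c)`; each cell's colonization probability is the fraction
of full 5-day runs with no belly spot.

## Synthetic data

The generators provide ground truth for every estimator: Brownian tracks
(Gaussian increments, variance `2 D dt` per axis), ballistic tracks, CSR and
dart-throwing hardcore point patterns (bounded attempt budget of 10⁵; at
test densities dart throwing is adequate and simpler than thinning-based
samplers), perfectly striped grids (square-wave clonal signal with known
fundamental 2/π), and density–diffusion tables generated by the model itself
at a known rate. They emulate none of the artefacts of real imaging — no
segmentation noise, drift, tracking errors or boundary losses beyond the
deliberate truncation above — so green estimator tests certify the
estimators, not robustness to microscopy artefacts. Real cells are also not
lattice walkers: sub-Δ spacings occur in images (the PCF dips below 1 under
~28 μm rather than vanishing), so simulated exclusion signatures are sharper
than experimental ones.

## Ensemble sizes and determinism

Everything is seeded: a realization is bit-reproducible given
`rng_seed`, ensemble replicate `r` uses `base_seed + r` (plus fixed offsets
between experiments), and all randomness in the engine flows through R's
RNG, so `set.seed()` governs C++ and R alike. The test suite and the
acceptance script use 20–100 replicates per ensemble (20 wildtype runs for
lineage and density summaries, 50 crowded-initialization runs, 100
doubling-time and calibration replicates, 12–40 per density in sweeps, a
3 × 3 × 20 sensitivity grid) — sizes chosen so Monte-Carlo standard errors
sit comfortably inside the tolerances being asserted while a full run of
everything stays in the minutes range on one core.

## Known limitations

* Single 2D compartment: the dermal-to-epidermal transition is not
  modelled (the source work declined a 3D hybrid for the same reason).
* No death, chemotaxis, signalling or directed motility; the model tests
  sufficiency of undirected crowding dynamics, not necessity.
* Bulk occupancy saturates below 1: growth dilution balances proliferation
  at `P_p(1−ρ) ≈` relative area-growth rate, giving ρ ≈ 0.87–0.89 at the
  end of a wildtype run (~600 cells/mm², inside the measured
  701 ± 138 cells/mm² but below the lattice maximum).
* The published movement rate is unavailable; P_m = 0.2 min⁻¹ is an anchor
  (see above), and conclusions that depend on the mixing-to-proliferation
  ratio — notably crowded-initialization lineage dominance — vary with it.
* Exact Gillespie simulation is O(events); a full wildtype run executes
  ~10⁷ attempts in a few seconds, but very large domains or rates call for
  approximate (tau-leaping) schemes the package does not provide.
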