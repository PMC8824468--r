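---
title: "Inferring conformational states from LRET lifetimes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring conformational states from LRET lifetimes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lretstates)
```

## The measurement model

Luminescence resonance energy transfer uses a lanthanide donor
(Tb³⁺-chelate) whose excited-state lifetime is on the millisecond scale.
After pulsed excitation and a gating delay (0.2 ms by default), the
donor-sensitized emission of an organic acceptor is recorded; prompt
autofluorescence, directly excited acceptor emission and scatter have
decayed by nanoseconds, so everything that survives the gate is
transfer-mediated.  A complex that samples several conformations in
solution produces a *multi-exponential* sensitized decay: each conformation
places the donor and acceptor at a distance $R_k$, which sets a transfer
efficiency and hence a sensitized lifetime

$$E_k = \frac{1}{1 + (R_k/R_0)^6}, \qquad
  \tau_{DA,k} = \tau_D\,(1 - E_k),$$

where $\tau_D$ is the donor-only lifetime at that probe position and $R_0$
the Förster radius of the dye pair.  Inverting per fitted component,

$$E = 1 - \tau_{DA}/\tau_D, \qquad R = R_0\,(1/E - 1)^{1/6}.$$

Two acceptors with different Förster radii are used on the same probe
pairs: Tb³⁺/Bodipy FL ($R_0 = 44.9$ Å) and Tb³⁺/Cy3 ($R_0 = 61.2$ Å).
The efficiency–distance curve is steep only within roughly
$0.5\,R_0$–$1.5\,R_0$, so the Bodipy channel resolves short separations
(closed, partially open) and the Cy3 channel long ones (partially open,
open).  The partially open state is visible in *both* channels, and the
agreement of the longer Bodipy distance with the shorter Cy3 distance is
what licenses merging the two channel lists into one three-state record.

Assumptions inherited from the measurement design, which this package takes
as given: $R_0$ is a constant of the dye pair (no orientation-factor or
quantum-yield corrections); incomplete labeling and donor-only complexes do
not contribute to the gated acceptor signal; and each decay component
reflects a conformation that persists for at least a few sensitized
lifetimes (states interconverting much faster would average).

## Decay fitting

`fit_decay()` models a trace as $I(t) = \sum_i a_i e^{-t/\tau_i} + b$ with
nonnegative amplitudes and baseline.  Numerical choices:

* **Weighting.**  Residuals are weighted by $1/\sqrt{\max(I, 10^{-4}
  I_{max})}$ by default (`weighting = "poisson"`), the appropriate scheme
  for shot-noise-limited photon detection.  Weighting matters for model
  selection: with unweighted residuals on $\sqrt{I}$-scaled noise, the
  high-variance early-time points let a spurious extra exponential "fit
  the noise" and the selector over-fits.  `weighting = "none"` is provided
  for homoscedastic data.
* **Variable projection.**  For fixed lifetimes the amplitudes and baseline
  are a linear least-squares problem; the nonlinear search therefore runs
  over log-lifetimes only (Nelder–Mead from eight staggered log-spaced
  starting sets spanning $[t_{min}/4,\ 2 t_{max}]$ — the lower end reaches
  the instrument-response scale), followed by a joint bounded
  Levenberg–Marquardt refinement of all parameters.  Final amplitudes come
  from Lawson–Hanson NNLS, so they are nonnegative by construction.
* **Component-count selection.**  With `n_components = "auto"` both the 2-
  and 3-exponential models are fitted and compared by small-sample-corrected
  AIC on the weighted residual sum of squares; the 3-component model must
  improve AICc by at least 2 (`delta_aicc`).  This reproduces the observed
  channel behaviour of the reference system — three exponentials when a
  short separation is present in the channel's window, two otherwise —
  without hard-coding it.
* **Instrument stripping.**  Fitted components faster than
  `strip_threshold` = 0.1 ms are instrument response, not transfer, and are
  moved to the `stripped` slot.  Components with numerically zero amplitude
  (below $10^{-8}$ of the total) are pruned first, so an over-parameterized
  fit collapses cleanly.
* **Degenerate inputs.**  All-zero or non-finite traces, and traces with
  fewer than three points per parameter, raise typed errors; an optimizer
  failure reports the best residual achieved.

Donor-only decays are fitted with exactly two exponentials
(`fit_donor_lifetime()`); the longer lifetime is the $\tau_D$ used for
distance conversion, and a warning is raised when it carries less than 85 %
of the amplitude — the quality rule for accepting a donor lifetime.

## State assignment

`assign_states()` routes the per-channel distance lists (0–2 entries each)
into four cases: both channels full (three states, with the matched
partially open pair kept as two separate channel values), one Bodipy + two
Cy3 with or without a channel match, and single-channel inputs, which get
generic `short`/`long` labels because the data alone cannot say which named
state they represent — an explicit `state_map` lets the user decide.  The
match tolerance defaults to $\max(3\ \text{Å},\ 2\times$ pooled replicate
SD$)$: the reference data contain matched channel pairs differing by up to
~6 Å, so the raw delta is always reported and the tolerance is
configurable rather than silently authoritative.  A Bodipy-channel distance
beyond 80 Å (efficiency below a few percent) is dropped with a warning
rather than assigned: that channel cannot report the open state reliably.

Replicates are aggregated by `tabulate_conditions()` as sample mean ±
sample SD, mirroring how replicate distances are reported in practice;
analytic error propagation through the sixth-root is deliberately not used.
Groups with fewer than three replicates are flagged.

## Docking restraints and model validation

State-resolved distances become unambiguous Cβ–Cβ restraints
(`build_restraints()`).  Mixed pairs are duplicated symmetrically — the
labeling cannot distinguish the protomers, so residue $i$ on chain A to
$j$ on chain B and its mirror are both restrained with identical targets.
Bounds are ±5 Å up to 75 Å and ±7 Å above, where the lifetime sits on the
flat, error-prone tail of the Cy3 transfer curve; the boundary is
inclusive on the ±5 side ("greater than 75 Å" widens).  The partially open
target defaults to the mean of the two channel values, with an option to
emit both as separate restraints — the choice between these was genuinely
open, so both modes exist.  Exports use the CNS/HADDOCK `assign` dialect
with stable ordering, targets printed at 0.01 Å resolution, and a verbatim
pass-through file for interface restraints prepared elsewhere.
`dropout_subsets()` removes every restraint sourced from one probe
position, reproducing the robustness control in which docking is repeated
without each cysteine's restraints.  `validate_model()` measures Euclidean
Cβ–Cβ distances in a PDB model (Cα fallback for glycine, with a warning)
and reports per-restraint deviations and satisfaction at a configurable
threshold; `cluster_consistency()` summarizes the spread of those distances
across cluster-representative models.

## Scattering: Debye profiles and population fitting

Theoretical profiles use the orientationally averaged Debye sum
$I(q) = \sum_{ij} f_i f_j \sin(q r_{ij})/(q r_{ij})$ with uniform unit bead
form factors and no hydration-layer or excluded-volume terms.  This is a
deliberate simplification: absolute χ² values against detector data are
*not* comparable to atomistic form-factor calculators, and no such values
are claimed — only relative state populations on synthetic mixtures, which
the simplification preserves.  χ² is scale-optimized in closed form and
normalized by the number of points $M$ by default ($M-1$ optional, since
conventions differ between fitting programs).

`fit_populations()` exploits the fact that with a free global scale $c$,
the constrained problem ($w \ge 0$, $\sum w = 1$) is linear in $c\,w_k$:
NNLS on σ-whitened profiles, then normalization, gives the exact
constrained optimum deterministically.  When fewer states than supplied
profiles are requested, all subsets are fitted and the best kept.
Numerically identical profiles make the split non-identifiable; this is
detected and flagged rather than silently resolved.  The test suite
cross-checks the NNLS solution against a dense simplex grid search at 0.5 %
resolution.

## Kinetics

`fit_hill_kinetics()` fits $v_0 = V_{max}[S]^n/(K_M^n + [S]^n)$ by
Levenberg–Marquardt with starts $V_{max} = \max v$, $K_M$ at the
half-maximal concentration, $n = 1$; $n$ can be fixed at 1 for the plain
hyperbolic fit.  Ligand depletion is ignored (free ≈ total), valid when the
ligand is in large excess over protein, as in the ATPase titrations this
models.  `fraction_bound()` is the single-site saturation $L/(L+K_D)$; at
2 mM ligand and $K_D = 3\ \mu$M it exceeds 99 %, the regime in which the
distance measurements were made.

## The synthetic generator: what it emulates, and what it does not

`ground_truth()` fixes the study conditions: the reference per-pair,
per-condition state distances (`reference_distance_table()`), a donor
lifetime of 2.0 ms per probe position (donor lifetimes vary with the local
environment of each labeling site and are not published per position;
2.0 ms is a typical Tb³⁺-chelate scale, and the value is configurable
per position), acquisition from 0.2 to 10 ms at 10 µs steps, an
instrument-response component at τ = 0.05 ms with amplitude 0.5, equal
amplitude fractions among visible states (unknown in the real data; a
declared assumption), and Gaussian noise with
$\sigma = \max(\sigma_{floor}, k\sqrt I)$ (Poisson mode optional).

Channel visibility is the load-bearing modelling choice.  A state
contributes a component to a channel only if its transfer efficiency is at
least `e_min` = 0.05 *and* its sensitized lifetime is at least
`min_lifetime` = 0.15 ms.  The first rule blinds the Bodipy channel to the
open state (≈78–85 Å is beyond twice its $R_0$); the second blinds the Cy3
channel to the closed state, whose sensitized lifetime (≈0.1 ms at 37.7 Å)
is subsumed by the instrument response.  These two thresholds reproduce the
observed channel pattern — Bodipy reports closed + partially open, Cy3
reports partially open + open — for *every* row of the reference table,
which is how they were chosen.

The generator does not emulate donor photobleaching, labeling efficiency,
or direct acceptor excitation (the gated measurement is insensitive to
them), nor inter-protomer cross-talk, exchange broadening between states,
or instrument-response *shape* (the IRF is a single fast exponential, and
deconvolution is out of scope).  Passing round-trip tests therefore
demonstrate correctness of the inference chain under the declared
generative model — not robustness to every pathology of real fluorimeter
data.

Toy bead conformers (`build_toy_conformers()`) place two rigid protomer
copies related by a C2 rotation so that every requested probe–probe
distance is met exactly (closed form for identity pairs, least squares for
general targets, with a feasibility error naming the worst-violated
restraint when no embedding exists), then flesh each protomer out with a
deterministic Fibonacci-sphere cloud of body beads so different states
scatter differently.  They stand in for docked structural models in the
validation and scattering paths and are labelled synthetic throughout.

## Problem sizes and tolerances used in the tests

The suite runs the full noiseless round trip over all 25 reference
(pair, condition) rows and asserts recovery within 0.5 Å per state; decay
parameter-recovery statistics use 1000 seeded noisy traces (2 % bias
bound); component-count selection uses 60 seeded well-separated cases
(≥95 % correct); scattering population recovery uses 100 seeded 1 %-noise
mixtures with weights drawn uniformly on the simplex (mean absolute weight
error < 0.02); Debye profiles are checked against a naive double loop at
$10^{-12}$ relative on up to 20 beads.  These sizes were chosen to give
stable statistics for each property while keeping a full test run on the
scale of a coffee break.

## Known limitations

* Distances from efficiencies below ~2 % sit on the flat tail of the
  Förster curve and are flagged low-confidence rather than suppressed.
* Amplitude fractions of decay components are reported but deliberately
  not interpreted as state populations: a two-channel lifetime experiment
  does not constrain a full population inventory, and no such estimate is
  offered.
* The Debye calculator is a coarse-bead model; use it for population
  deconvolution and model ranking on matched profile sets, not for
  absolute comparison with beamline χ² values.
* Global (multi-trace) fitting and maximum-entropy lifetime distributions
  are out of scope; each trace is fitted independently.
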