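---
title: "Methods: simulating and analysing Hebb-Williams navigation training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Hebb-Williams navigation training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwnav)
```

## The system being modelled

`hwnav` models a digital spatial-navigation training programme built on
Hebb–Williams (HW) style mazes: a square arena entered at one corner and
exited at the opposite corner, with thin interior barriers. Training
follows a three-step masking progression per maze — an allocentric
top-view map, a fully sighted egocentric run, a second map view, a run
with half the walls masked, and finally three blindfolded runs guided only
by auditory cues. Each failed trial is repeated until it succeeds, a daily
session spends a fixed navigation budget, and the programme runs daily for
two weeks. The package's purpose is to make every component of that
pipeline — geometry, dynamics, audio code, scoring, scheduling, the
behavioral statistics, and a reduced connectivity analysis — available,
deterministic, and testable on synthetic data.

## Maze geometry

Mazes are `height x width` cell grids (default 6x6, the classic arena
proportions); walls are thin barriers on edges between orthogonally
adjacent cells, and the perimeter is implicitly walled. Movement uses
eight compass headings at 45° increments. Orthogonal steps cost 1 cell
unit, diagonal steps cost √2 and are subject to a *no-corner-cutting*
rule: a diagonal step is legal only when all four wall segments meeting at
the crossed corner are open. We chose the symmetric four-segment rule
(rather than requiring only the two edges incident to the departing cell)
because it keeps passability independent of travel direction, and with it
the shortest-path cost invariant under maze transposition — a property the
test suite asserts.

Shortest paths are computed by Dijkstra's algorithm over the legal-move
graph with a deterministic tie-break (prefer the lexicographically
smallest successor cell), so reference paths are reproducible. The *error
zone* of a maze is the set of cells whose minimum step distance to the
optimal path exceeds a corridor radius (default 1 cell). The radius is a
parameter because the zone geometry of the original application is not
public; the default makes one wrong cell forgivable and two a penalty.

Because the digitized maze set of the original programme is not publicly
available, the package ships a *synthetic stand-in*: twelve seeded 6x6
mazes of graded complexity (2 to 13 interior walls), produced by
`generate_maze()`, which adds random walls while keeping every cell
reachable. The grade was fixed at design time by a ceiling analysis: an
error-free agent completes the default protocol at ≈152 successful trials
per hour, which leaves realistic headroom above trained human-scale
performance (well above the ≈120/hour a trained learner reaches in the
simulations below). These mazes share the layout conventions of the HW
apparatus but are not digitizations of it; conclusions about specific
historical maze numbers cannot be drawn from them.

## Navigation dynamics and the discrete clock

The environment is strictly turn-based: `FORWARD` advances one cell along
the heading (emitting a `FOOTSTEP`) unless the edge ahead is blocked, in
which case the position is unchanged and a `COLLISION` is emitted; the two
`TURN` actions rotate the heading ±45° in place. Every action costs `dt`
seconds (default 2 s), so the 3-minute trial cap corresponds to 90
actions. The discrete clock is a modelling choice: the source programme
reports wall-clock limits but no per-action timing, and a configurable
`dt` both keeps trials finite and lets the synthetic agent produce
realistic per-trial durations (an optimal run on the fixture set takes
16–50 s).

Masking affects *observations only*: the hidden wall subset (drawn once
per trial from the mask seed, `floor(fraction × n_edges)` edges in
`HALF_MASK`) never alters the dynamics, and the test suite checks that
identical policies under different masks produce identical trajectories.
We mask wall edges rather than cells because the walls are the visual cue
the mask is meant to degrade. The mask is static within a trial; whether
the original application re-randomizes mid-trial is unknown, and a static
draw is the simplest reading of a one-shot random mask.

## The auditory code

Wall proximity is sonified by mapping the forward-ray wall distance to a
tone frequency: distance 0 sounds at `f_max`, distances ≥ `d_max` at
`f_min`, strictly decreasing in between. Defaults are `f_min` = 220 Hz,
`f_max` = 880 Hz (a two-octave musical range), `d_max` = 5 cells and a
linear map; a logarithmic map is available for perceptual distance
compression. The true frequency range and mapping shape of the original
programme are unpublished, so these are explicit configuration, and only
the forward ray is sonified by default (no multiplexing scheme is
described in the source material). A clear passage ahead (distance ≥ 1)
additionally emits a footstep cue. Rendering produces pure sine tones
with 10 ms linear ramps and 50 ms broadband clicks for footsteps; the
footstep noise burst is generated from a fixed internal seed so waveforms
are bit-reproducible.

## Scoring and the success rule

The trial score is a reconstruction — the source material names its
inputs (deviation from the path, error-zone entry) but not the formula:

```
score = clamp(100 − w_path · excess · 100 − w_zone · zone_entries
                   − w_coll · collisions, 0, 100)
```

with `excess = (moves − optimal_moves)/optimal_moves` counted over
cell-to-cell moves (turn actions are free — otherwise no trial could reach
100, since even an optimal route requires turns), `zone_entries` the
number of maximal runs of consecutive positions inside the error zone, and
defaults `w_path = 1`, `w_zone = 10`, `w_coll = 2`, chosen so that a
near-optimal run with at most two zone entries stays above the success
cutoff. Success requires reaching the goal within 180 s *and* a score
strictly above 70; the 3-minute limit is enforced as a cap that voids
success rather than aborting the trial, which matches either reading of
the source description while keeping every trial scorable. The daily
training score for a strategy is the number of successful trials divided
by the corresponding training time in hours, which puts trained
performance in the 90–140/hour range on the fixture set.

## Protocol scheduling

The per-maze step sequence (map view → sighted → map view → half-mask →
blindfold ×3) is configuration, not a constant, because the original daily
protocol scheme is available only as unpublished supplementary material;
the default reconstructs the prose description. Map views are logged as
zero-cost allocentric exposure events. Sessions end when the 1500 s
navigation budget is spent or the maze list is exhausted; failed trials
are re-issued with an incremented retry index. Every session draws all
randomness (mask seeds, agent exploration) from one seeded stream, so a
logged session replays bit-identically, and per-day seeds are derived
deterministically from a master seed. With the defaults, the three
blindfold repeats plus retries make the auditory condition consume the
majority of navigation time, consistent with the reported structure of
the original programme (where auditory training was about 63% of training
time); the suite asserts the majority property, not the exact share.

## The synthetic learner

There are deliberately two data generators. The *direct* generator draws
daily scores straight from the two-parameter logarithmic learning model,
`y_x = a·ln(x) + b + N(0, noise_sd)` — this isolates the statistics layer
from the simulator, and its Gaussian noise matches the symmetric-residual
assumption of least-squares fitting. The per-day noise of real training
scores is unpublished; the default `noise_sd = 5` score units is a
stand-in of the right order for rate-type scores near 100/hour. The
*mechanistic* agent navigates the actual environment: with probability
1 − ε it takes the next step of the optimal route (turning first when
needed), otherwise a uniformly random action, with

```
ε = clamp(eps0 · m_condition / (1 + κ · ln(1 + experience / exp_scale)), 0, 1)
```

where `experience` counts completed trials across days and the condition
multipliers (`m_AV ≤ m_A50V ≤ m_A`, defaults 0.75/1.0/1.2) make the
audiovisual strategy easiest and blindfold navigation hardest. The
`exp_scale` parameter (default 45 trials, about one daily session) sets
the *units* of the logarithmic decay. It matters: with raw trial counts
the logarithm saturates within the first session (~45 trials), capping the
fitted day-level slope at about 4.5 score units per ln(day) for any
`(eps0, κ)`; measuring experience in session-sized units lets the decay
unfold across days, which is what produces day-scale logarithmic learning
curves with slopes in the empirically reported range (~11).

`calibrate_agent()` grid-searches `(eps0, κ)` so that the mean daily
overall score across 20 protocol replicates fits a log curve within 15%
of target parameters. The default grids (eps0 0.25–0.45, κ 0.2–0.5) were
set from a coarse map of the score response: on the fixture set a constant
error rate of 0.33 yields ≈92 successes/hour and 0.20 yields ≈120, so the
target curve requires roughly a 1.7-fold error decay over two weeks —
comfortably inside the decay family.

## Learning statistics

`fit_log_curve()` minimizes Σ w_i (y_i − a·ln x_i − b)² by
Levenberg–Marquardt iteration: initialization `b₀` = mean response at the
smallest day, `a₀` = range/ln-span; damping λ starts at 1e-3, ×10 on a
failed step, ÷10 on success; convergence when the relative SSE change or
the parameter step falls below 1e-10, with at most 200 iterations. The
model is linear in its parameters, so the LM solution coincides with
ordinary least squares on `ln(x)` — the test suite uses `lm()` and
`minpack.lm::nlsLM()` as independent oracles, and a 201×201 grid search as
a global check. Confidence intervals are Jacobian-based with a t quantile
at n − 2 degrees of freedom (bootstrap intervals were considered and left
out: for a two-parameter linear-in-parameters model the parametric
intervals are exact under the generator's Gaussian noise, and the
simulated 95% coverage lands in the 93–97% band). `rmse = √(SSE/(n−2))`.
The robust option reweights iteratively with Tukey bisquare (tuning
constant 4.685, scale = median |residual| / 0.6745) and reproduces
`MASS::rlm` to numerical precision; it is off by default since plain
estimates are the primary quantity, but matters when a single corrupted
day would otherwise leverage the fit.

Paired comparisons use the two-sided paired Student's t test with Cohen's
d; the pooled variant `(mean_post − mean_pre)/√((s²_pre + s²_post)/2)` is
the default and the variant is always reported alongside the number. A
post ≡ pre comparison is an exact null (t = 0, p = 1), while a constant
nonzero shift is flagged degenerate rather than given an infinite t.
Spearman correlation is computed definitionally (Pearson on average
ranks) with the t-approximate p value.

## ROI connectivity

The connectivity engine is deliberately reduced to ROI level: voxel-wise
maps, cluster inference and denoising pipelines belong to the established
neuroimaging toolchains and are out of scope. Per-region time series are
bandpass-filtered in the frequency domain (zero-phase by construction);
the default band is 0.01–0.09 Hz, the conventional resting-state band —
chosen because the band printed in the source material ("0.01–0.009 Hz")
is not a valid interval. Connectivity is Pearson correlation per region
pair with Fisher's z transform (|r| capped at 1 − 1e-12 to keep z
finite), and the pre/post contrast is a two-sided paired t test per edge
with Benjamini–Hochberg FDR over the R(R−1)/2 unique edges
(`stats::p.adjust`; the test suite checks it against a brute-force
step-up implementation on 10,000 random p-vectors).

The synthetic generator draws multivariate Gaussian time series from a
baseline covariance (default compound symmetry, off-diagonal 0.1) and a
post-phase covariance with a planted correlation increase on chosen
edges, both verified positive definite. In the reference configuration
(17 subjects, 10 regions, 300 timepoints, Δr = 0.3 on 5 of 45 edges) the
contrast recovers planted edges with sensitivity ≥ 0.8 while null
simulations keep the empirical FDR at the nominal 5%. Gaussianity, zero
autocorrelation and homogeneous subjects are idealizations: passing these
checks demonstrates the statistical machinery is correct, not that real
BOLD data — with autocorrelated noise, motion artifacts and
between-subject heterogeneity — would behave as cleanly.

## What the synthetic data do and do not show

All empirical statements in this package are about synthetic data whose
generating truth is known. That is exactly what makes them useful —
parameter recovery, CI calibration, FDR control and planted-effect
sensitivity are checkable to known tolerances — and exactly what limits
them: the generators encode logarithmic group-level learning, Gaussian
score noise and Gaussian ROI series by construction, so the tests verify
the *machinery*, not the psychological or neural claims. Problem sizes
throughout (200-replicate recovery runs, 1000-replicate coverage runs,
500-replicate null calibrations, 20-seed calibration averages) were
chosen to make Monte-Carlo error comfortably smaller than the tolerances
being asserted.

## Known limitations

- The fixture mazes are synthetic stand-ins, not the historical HW set.
- The trial score formula and its weights are a documented reconstruction.
- The agent is a stationary ε-greedy optimal-router; it has no spatial
  memory model, so masking conditions differ only through the error
  multipliers rather than through information available to a learner.
- Sessions reuse the same maze list each day; there is no novelty
  schedule.
- The connectivity module assumes temporally white Gaussian signals and
  identical regions across subjects.
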