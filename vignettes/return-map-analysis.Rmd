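---
title: "Return-map segmentation and transition syntax of dyadic interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Return-map segmentation and transition syntax of dyadic interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmap)
```

## The problem and the model

Two competitors in a combative sport (the motivating system is kendo
fencing) continuously regulate the distance between them.  The
interpersonal distance (IPD) oscillates: each approach/retreat cycle leaves
a peak, and the sequence of successive peak amplitudes $y_1, y_2, \dots$ is
treated as an observable of a one-dimensional discrete dynamical system,
the *return map* $(y_n, y_{n+1})$.  The working hypothesis is a hybrid
system: a higher discrete module (decision making) switches, at peak
events, the map that the lower continuous module (movement) follows.  Three
map families are postulated:

* linear, $y_{n+1} = c\,y_n + d$, with fixed point $x^* = d/(1-c)$ on the
  identity line.  $0<c<1$: asymptotic attractor (`Aa`); $-1<c<0$:
  rotational attractor (`Ar`); $c>1$: asymptotic repeller (`Ra`); $c<-1$:
  rotational repeller (`Rr`);
* exponential, $y_{n+1} = a e^{b y_n}$ (`Exp`), and
* logarithmic, $y_{n+1} = a + b \log y_n$ (`Log`), both representing
  *intermittency*: slow passage near the identity line without a fixed
  point.

A scene — one engagement from farthest separation to a strike-like close
approach — may switch among several maps; the switching sequence, reduced
to two discrete states (F = "farthest apart"/high velocity, N = "nearest
together"/low velocity), is summarized by second- and third-order Markov
transition probabilities, the "syntax" of the interaction.

## Pipeline stages and their parameters

### From trajectories to the state variable

Head-position trajectories of the two agents (100 Hz, meters) are low-pass
filtered with a 4th-order Butterworth filter, 6 Hz cutoff, applied
zero-phase (forward–backward) so that peak timing is not lag-shifted; the
single-pass variant is available as a flag.  Because forward–backward
filtering with zero initial conditions leaves slowly decaying transients at
the series edges, the implementation pads both ends by odd reflection, with
a pad length chosen from the filter's slowest pole so the transient decays
below 1e-13 inside the pad.

The IPD is $D(t) = \lVert x_A(t)-x_B(t)\rVert$ at each 0.01 s sample.  The
state variable combines position and a velocity surrogate:

* backward delayed difference $\Delta D_\tau(t) = D(t) - D(t-\tau)$.  The
  difference direction is a declared convention (the causal choice); the
  delay $\tau$ defaults to 0.1 s.  `select_tau()` implements the selection
  procedure: over a grid of delays, the variance of $\Delta D_\tau$
  (growing with $\tau$) and the absolute correlation with $D$ (decaying)
  are min–max normalized, and the first crossing is selected — the shortest
  delay whose difference channel carries substantial variance while being
  acceptably independent of $D$.  On oscillatory series with a period near
  2 s this reproduces the 0.1 s default.
* both channels are normalized to $[0,1]$ with bounds computed over the
  *whole match* (never per scene), so peak amplitudes are comparable across
  the scenes of a match, which the per-match histograms below require;
* $S(t) = w\,\tilde D + (1-w)\,\widetilde{\Delta D_\tau}$ with $w = 0.5$.
  The equal-weight convex combination is a declared convention, exposed as
  `weight`; downstream analysis depends only on the ordering and spacing of
  the peaks of $S$, which is robust to $w$ for positively co-varying
  channels.

### Scene selection

Scenes are cut from maximal runs outside caller-supplied exclusion
intervals (stoppages, marker loss; such intervals are manual annotations on
real recordings, and empty for synthetic data).  Alternating positive
(maxima) and negative (minima) IPD peaks are detected; *quick detachments*
— a minimum followed by a maximum more than 1 m higher within less than
1500 ms — are removed, both peaks at once.  Sequences are cut at
*close approaches*: negative peaks below an absolute threshold `close_m`,
or, when none is given, below the 0.25 quantile of the match's
negative-peak IPDs.  The close-approach proxy replaces video-based strike
identification, which is unavailable; it is the one stage whose
operationalization cannot be validated against the original procedure.
Each scene starts at its maximum-distance positive peak and must contain at
least four positive peaks.

Peak detection additionally prunes adjacent extremum pairs whose IPD
difference is below a prominence floor (0.03 m for scene splitting; 0.012
normalized units in the full pipeline; 0 — off — at the module surface).
Band-limited noise riding on flat stretches of a signal produces swarms of
micro-extrema that a smoothing filter alone does not remove; pruning by
prominence is the standard kinematics remedy and leaves genuine
oscillations (≥ 5 cm peak-to-trough) untouched.

### Return-map fitting

Within a scene, $S$ is smoothed with a 2nd-order, 9-point Savitzky–Golay
filter (edges: the same least-squares fit over the truncated window), peaks
of the smoothed normalized distance are detected, and amplitudes are read
from $S$ at those peaks.  Every moving window of $L = 3..6$ consecutive
return-map points is fitted to all three families:

* linear and logarithmic fits are ordinary least squares in closed form;
* the exponential fit profiles out $a(b) = \sum y e^{bx} / \sum e^{2bx}$
  and minimizes the profiled sum of squares over $b$ by Brent search
  started at the log-linearized estimate.  This is deterministic and exact
  at zero residual, where Gauss–Newton solvers fail.

Goodness of fit uses $\chi^2 = \mathrm{SSR}/\sigma^2$ with
$\mathrm{dof} = L-2$ and $Q = Q(\mathrm{dof}/2, \chi^2/2)$, the upper
regularized incomplete gamma (`pchisq(..., lower.tail = FALSE)`).  The
per-point measurement error $\sigma$ is not identifiable from the method
itself; it defaults to 0.02 normalized units, with an `"auto"` mode that
estimates it as 1.4826 × the median absolute residual of all 3-point linear
fits of the match.  $Q$ values are therefore comparable within a
configuration but not across error models.  Candidates with $Q < 0.05$ are
excluded.

Exponential/logarithmic candidates whose *fitted curve crosses the identity
line* are excluded.  The crossing test is evaluated on the state domain
$[0.01, \max(1, \text{window range})]$, not merely on the window's observed
x-range: a curve crossing $y = x$ anywhere in the state space has a fixed
point, which contradicts the intermittency reading of these families.  The
domain-wide test is also what makes the family assignment identifiable —
an exponential through attractor data that converges toward a fixed point
always crosses the identity just beyond the data and is correctly rejected,
while a genuine intermittency channel (clearance above/below the identity)
is kept.

Overlap resolution is greedy: longer windows first (the longer series of
points is preferred); among equal-length overlapping candidates the better
fit wins (higher $Q$; identical to lower $\chi^2$ at equal dof — the
`tie_break` switch exposes both spellings); anything overlapping an
accepted window is dropped.  Accepted linear fits are classified by slope
as above, with $|c|$ within 1e-9 of 1 flagged unclassifiable.

### Transition statistics

Per match, the amplitudes of peaks covered by accepted *linear* fits
(intermittency peaks excluded by default, includable by flag) are binned at
width 0.05 over $[0,1]$; the F/N threshold is the center of the
minimum-count bin strictly between the two largest modes, ties broken
toward the mode midpoint.  Unimodal histograms fall back to a pooled
threshold.  Peaks above the threshold are F, at or below N (the
equal-to-threshold tie rule is declared, not left to float comparison).
Second-order transitions count consecutive within-scene pairs —
never across scene boundaries, which are strikes or stoppages; third-order
transitions condition on the sub-state pair (FF, NF, NN, FN).  Sub-states
with no observations report undefined (NA) probabilities rather than 0/0.
Group contrasts use the two-sided Fisher exact test computed by direct
hypergeometric enumeration with the point-probability rule (every table no
more probable than the observed one, with a 1e-7 relative tie tolerance);
zero-margin tables return p = 1 with a warning.

Marginalizing third-order counts over the leading label reproduces the
second-order counts restricted to pairs that have a predecessor, i.e.
excluding each scene's first pair; the identity is exact on that set and is
asserted in the tests.

## The synthetic generator

Because no recordings are distributed with the original study, every stage
is validated against a generator that plants known dynamics:

* `generate_peak_sequence()` iterates each regime's map exactly; noise is
  observational (added after iteration) by default, with process noise as a
  flag, because the analysis fits maps to *observed* peaks.
* `render_continuous_scene()` realizes peaks as half-cosine arcs, one
  oscillation period (default 2 s) apart, through troughs at a constant
  normalized level (0.22, clipped to 85% of the smaller adjacent peak).
  Constant-level troughs are a deliberate choice: they make the delayed
  difference at a peak an affine function of the peak amplitude, so planted
  slopes and families survive the composite-state transformation exactly
  (fraction-of-peak troughs bend planted linear maps into convex curves at
  the composite stage).  A lead-in rise and tail fall make the first and
  last peaks strict interior maxima.
* `generate_match()` joins scenes with a strike dip to normalized depth
  0.02 over one period and a slow two-period recovery, prepends to each
  scene an *entry peak* 0.05 above the scene's maximum (the post-strike
  retreat to farthest separation, making the scene-start rule recover whole
  scenes even when the planted dynamics grow), scales to meters by
  $\mathrm{IPD} = 0.6 + 1.3\,s$, and factors the IPD into two agents moving
  symmetrically about a drifting, slowly rotating midpoint.

The planted parameter distributions (in `random_regime_spec()`) are the
study conditions for all recovery checks and were fixed once: attractor
slopes $|c| \in (0.5, 0.8)$, repeller slopes $|c| \in (1.4, 1.8)$, fixed
points in $(0.27, 0.68)$; scenes start near maximal amplitude, repeller
scenes are engineered so the final iterate approaches the amplitude cap
(wide return-map ranges are what makes the three families statistically
identifiable at observation noise 0.01 — over a narrow window every family
approximates every other); intermittency regimes keep a 0.08–0.2 clearance
from the identity line with strong curvature ($b \in (1.5, 2.5)$
exponential, $(0.25, 0.4)$ logarithmic).  Multi-regime scenes reject
boundary points closer than 0.12 to either neighboring map, so planted
switches are recoverable rather than coincidental continuations.

What the generator does *not* emulate: referee interruptions and marker
occlusion (exclusion intervals are caller-supplied), true strike kinematics
(a smooth dip stands in for the video-identified strike), irregular
oscillation periods, amplitude-correlated noise, and any feedback from the
opponent's state.  Passing recovery tests therefore demonstrates that the
*pipeline* is correct and well-conditioned under realistic statistics, not
that real competition data satisfy the hybrid-system model.

## Validation problem sizes

The test suite checks, among others: Savitzky–Golay output against a
per-window polynomial least-squares oracle (100 random series, 1e-10);
Fisher p against exhaustive enumeration (all 2×2 tables with margins ≤ 15,
1e-12); classification against a 50-step iteration oracle (1000 random
slopes); family/slope/fixed-point recovery on 200 rendered scenes per
family at noise 0.01; segmentation recovery on 100 scenes with 2–4 planted
regimes; transition recovery from planted chains with ≥ 1000 transitions
per conditioning sub-state; and byte-identical reports for repeated runs of
one configuration.

## Known limitations

* The close-approach scene cut is a proxy for video-identified strikes; on
  real data, `close_m` should be set from domain knowledge.
* $Q$ values depend on the configured $\sigma$ and are not comparable to
  goodness-of-fit probabilities computed under a different error model.
* The composite state compresses the amplitude range (the delayed
  difference at peaks varies little), which lowers family discriminability
  end-to-end relative to scene-level analysis; slopes and classes of linear
  maps are unaffected (affine invariance), but a fraction of steep repeller
  segments can be absorbed by exponential fits in full-match runs.
* Windows never span scene-internal gaps; peaks must be consecutive.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
rgs <- random_scene_regimes(2)            # two planted linear regimes
spec <- synthetic_spec(rgs, noise_sigma = 0.01, seed = 7)
gp <- generate_peak_sequence(spec)
sc <- render_continuous_scene(gp$peaks, spec)
analyze_scene(sc$signal, retmap_config())
```
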