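# retmap

Return-map segmentation and state-transition analysis of dyadic
interaction dynamics.

## What it is for

In combative sports such as kendo, two players continuously regulate the
distance between them.  The interpersonal distance (IPD) computed from
motion-capture trajectories oscillates, and the sequence of successive
oscillation peak amplitudes \(y_1, y_2, \dots\) can be read as a
one-dimensional discrete dynamical system on the *return map*
\((y_n, y_{n+1})\).  `retmap` implements, as tested reusable R functions,
the full analysis from raw two-agent position CSVs to:

1. **Scenes** — engagement segments from farthest separation to a
   strike-like close approach, selected by explicit rules (≥ 4 positive
   peaks, quick detachments of > 1 m in < 1500 ms removed);
2. **A composite state variable** \(S = w\tilde D + (1-w)\widetilde{\Delta
   D_\tau}\) from the unit-normalized IPD and its delayed difference
   (τ = 0.1 s default, selectable from the variance/correlation crossing);
3. **Return-map segmentation** — every moving window of 3–6 map points is
   fitted to \(y_{n+1} = c y_n + d\) (linear), \(a e^{b y_n}\)
   (exponential) and \(a + b\log y_n\) (logarithmic), screened by the
   χ² goodness-of-fit probability \(Q = Q(\mathrm{dof}/2, \chi^2/2)\)
   (upper regularized incomplete gamma, candidates with Q < 0.05 dropped),
   with exponential/logarithmic candidates whose curve crosses the
   identity line excluded and overlaps resolved longest-window-first.
   Accepted linear fits are classified by slope: asymptotic/rotational
   attractors `Aa` (0 < c < 1) / `Ar` (−1 < c < 0), repellers `Ra` (c > 1)
   / `Rr` (c < −1), with fixed point \(d/(1-c)\); exponential/logarithmic
   fits are intermittency (`Exp`, `Log`);
4. **Hierarchical transition statistics** — per-match histograms of
   well-fitted peak amplitudes, an F/N ("farthest apart" / "nearest
   together") threshold at the histogram minimum between the two major
   modes, and second-/third-order conditional transition probabilities
   with two-sided Fisher exact group contrasts computed by exact
   hypergeometric enumeration.

Because the motion-capture recordings behind the original study are not
deposited, the package ships a first-class **synthetic-data module** that
plants known regimes (with ground truth) in continuous two-agent
trajectories, so every stage is verifiable: planted slopes are recovered
end-to-end to 1e-6 without noise, and to ~0.02 median absolute error at
observation noise 0.01.

## Worked example

Plant a scene that switches between two linear regimes, render it as a
continuous signal, and run the scene-level analysis:

```r
library(retmap)
set.seed(1)
rgs  <- random_scene_regimes(2)           # planted: Ar then Aa
spec <- synthetic_spec(rgs, noise_sigma = 0.01, seed = 7)
gp   <- generate_peak_sequence(spec)
sc   <- render_continuous_scene(gp$peaks, spec)
analyze_scene(sc$signal, retmap_config())
#> <segmentation> 2 accepted fit(s) over 13 map points
#> <fit linear/Ar> window 1+6  params (-0.704, 0.8108)  chi2 0.672  Q 0.955  fp 0.476
#> <fit linear/Aa> window 8+6  params (0.6562, 0.1306)  chi2 2.88  Q 0.578  fp 0.380
```

The planted regimes had slopes −0.735 (`Ar`, a rotational attractor: the
players close in by alternating step-towards and step-away moves) and
0.646 (`Aa`, asymptotic attractor); both windows are recovered with the
right class, slope within ~0.03, and a credible fit (Q ≫ 0.05).  The two
fixed points (0.476, 0.380) are the distances the dyad is drawn to in each
phase.

Transition syntax from planted state sequences:

```r
labs <- simulate_markov_labels(c(FF = 0.8, NF = 0.65, NN = 0.3, FN = 0.45),
                               n_scenes = 50, scene_length = 12, seed = 7)
second_order(labs, group = "expert")
#> <transition model, order 2, group expert>
#>        nxt
#> current     F     N
#>       F 0.748 0.252
#>       N 0.342 0.658
```

A full end-to-end run (simulate two groups of matches → filter → scenes →
state variable → segmentation → transitions → Fisher contrasts):

```r
rep <- run_pipeline(pipeline_config(seed = 1))
rep$class_by_length      # accepted fits by class and window length
rep$comparison$second    # expert vs intermediate Fisher contrasts
```

A thin command-line wrapper is installed at `inst/scripts/retmap`
(`simulate`, `run-all`, `make-fixtures`).

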