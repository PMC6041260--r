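---
title: "Models and methods: characterising AHL receiver devices and designing orthogonal channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: characterising AHL receiver devices and designing orthogonal channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahldesign)
```

This vignette documents the models, numerical choices and design decisions
behind `ahldesign`, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open choices were made.

## The transfer-function model

An AHL receiver device converts an extracellular inducer concentration $c$
(molar) into reporter expression. We model the population-mean,
background-subtracted response with the four-parameter logistic curve on a
log10 concentration axis:

$$\mathrm{GFP}(c) = b + \frac{a - b}{1 + 10^{(\log_{10}\mathrm{EC50} - \log_{10} c)\,h}}$$

* $a$ — maximal output (arbitrary units, same scale as the data);
* $b$ — basal (leaky) output;
* $\mathrm{EC50}$ — concentration of half-maximal activation; the curve value
  there is exactly $(a+b)/2$;
* $h$ — Hill slope, controlling how steeply the device switches.

All devices handled here are activators, so the fitter enforces the activator
sign convention: $a \ge b \ge 0$ (lower bound $\max(b, 0)$ on $a$), $h \in
(0, 10]$, and $\mathrm{EC50} \in [10^{-16}, 10^{-2}]$ M — generous brackets
around the physically plausible range, wide enough that they never bind for a
well-determined fit. Repressors (decreasing curves) are out of scope.

## Constrained fitting

`fit_4pl()` minimises the sum of squared residuals in **linear response
space** over log10 concentration (the default behaviour of the standard
curve-fitting tools used for this model family), with:

* **Basal constraint.** $b$ is not a free parameter: it is fixed to the mean
  observed response at a designated near-zero concentration
  (`basal_constraint_conc`, default $10^{-15}$ M — at that dilution the
  inducer is effectively absent). This reflects how such devices are
  characterised in practice: the leak is measured directly, and fixing it
  removes a poorly identified parameter from low-fold-activation curves.
* **Pooled replicates.** Residuals are computed against every replicate point
  rather than per-concentration means. For balanced designs the two give
  nearly identical estimates; pooling uses all information and is the
  documented default (the original characterisation protocol does not state
  which variant its fitting software used, and no weighting scheme is
  applied).
* **Initialisation.** $a_0 = \max(\text{responses})$, $\log_{10}
  \mathrm{EC50}_0$ = midpoint of the tested log-concentration range, $h_0 =
  1$. Deterministic — no restarts, no randomness.
* **Optimiser.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, tight
  `ftol`/`ptol` of $10^{-14}$); if that fails structurally, a bounded
  quasi-Newton fallback (`optim`, L-BFGS-B) runs on the same objective.
  Non-convergence is never silent: the best-effort parameters are returned
  with `converged = FALSE`.

A completely flat series (no activation) is a legitimate input: the fit
converges with $a \approx b$ and unidentifiable $\mathrm{EC50}$ and $h$ (they
remain at their initial values; the curve is insensitive to them when
$a = b$).

### The saturation criterion

Fold activation is $a/b$ *only when the plateau was actually reached in the
tested range*; otherwise the fitted $a$ extrapolates beyond the data and the
convention is to use the observed response at the highest soluble test
concentration ($10^{-4}$ M = 100 µM) divided by $b$. "Plateau reached" is
operationalised as: the device activates at all ($a > b$), the mean observed
response at the highest tested concentration reaches at least 90 % of the
fitted $a$ (`sat_frac = 0.9`), **and** the fitted EC50 sits at least one
decade below the highest tested concentration (`sat_decades = 1`). Both
thresholds are exposed as arguments. The $a > b$ clause is ours: a flat curve
trivially satisfies the 90 % test but has not "saturated" in any meaningful
sense, and flagging it saturated would route its fold activation through an
extrapolated $a$.

### Relative promoter activity

Outputs are calibrated against a constitutive reference standard (J23101 by
convention) measured on the same scale: `relative_activity()` is the plain
ratio, so the reference itself has activity 1 and the measure is linear. The
low/high expression states of a device are the relative activities of the
mean observed responses at $10^{-15}$ M and $10^{-4}$ M.

## The crosstalk database

`crosstalk_db` objects are **complete by construction**: exactly one fitted
parameter record for every (device, inducer) pair, cognate and non-cognate
alike — a 6-device, 6-inducer library therefore always carries 36 records,
and a missing or duplicated pair is a validation *error* naming the pair. The
channel search relies on this: silence about a pair is indistinguishable from
zero crosstalk, which is exactly the assumption the search must not make.

Persistence is plain text (CSV, or a JSON variant) with numerics written at
17 significant digits so a save/load cycle is bit-identical. `import_db()`
adapts foreign parameter tables via a user-supplied column mapping (inline or
as a YAML/JSON file); when the foreign table carries its own cognate column
that *conflicts* with the expected cognate pairing, the import fails loudly
rather than silently overriding either side.

### Fold-change predictions and the basal divisor

`predicted_fold(db, device, inducer, c)` is the pointwise fold change:
the pair's curve value at $c$ divided by the device's basal output. The basal
divisor is taken from the device's **cognate** record by default: leaky
expression is a property of the device (its promoter/TF pair), not of which
inducer happens to be in the medium, and the non-cognate fits measure the
same leak at their low-concentration end. A `basal = "pair"` switch divides
by the record's own $b$ instead, for databases where the per-pair basal
estimates are preferred.

Cognate-normalised summaries (`normalise_to_cognate()`) divide every curve
by the maximum of the device's cognate curve over the evaluation grid, so the
cognate row peaks at 1 (up to grid resolution) and crosstalk reads as a
fraction of cognate activation.

## The channel search

A set of $k$ communication channels is **orthogonal** under a specification
$(k, f_{\mathrm{on}}, f_{\mathrm{off}}, \text{grid})$ when:

1. *(rook condition)* no device and no inducer is used by two channels — the
   placements are exactly the non-attacking rook placements on the
   device × inducer board, $\binom{n_d}{k}\binom{n_i}{k}k!$ of them;
2. *(activation)* each channel's inducer, at any concentration in the
   channel's window, activates its own device at least
   $f_{\mathrm{on}}$-fold;
3. *(crosstalk)* each channel's inducer, at any concentration in the
   channel's window, activates every *other* selected device less than
   $f_{\mathrm{off}}$-fold.

Comparisons default to `fold >= fold_on` and `fold < fold_off` — matching the
usual "more than x-fold activation, less than y-fold crosstalk" phrasing on
the crosstalk side while avoiding float-equality fragility on the activation
side. Both strictness flags are configurable.

### Separability, and why "joint" and "per-channel" windows coincide

A design's windows are defined to be *jointly* feasible: every combination of
one in-window concentration per channel must pass `point_feasible()`. Under
this fold model, however, the constraint set is **separable**: a channel's
own activation depends only on its own concentration, and the crosstalk of
inducer $i$ at concentration $c_i$ onto device $j$ also depends only on
$c_i$ — never on channel $j$'s concentration. The jointly feasible set is
therefore exactly the Cartesian product of per-channel feasible sets, and the
conservative "joint" semantics and the figure-style "per-channel" rendering
give identical windows. The `window_mode` flag is accepted for interface
completeness and documented as a no-op; it would matter only under a model
with combined-inducer effects (see limitations).

This separability is also what makes the search cheap: per assignment, each
channel's feasible grid set is computed independently (with precomputed fold
arrays), an assignment is abandoned as soon as any channel's set is empty,
and feasible sets are reported as maximal contiguous runs on the grid (one
design per combination of runs). At the library's scale (6 × 6 board,
12-point grid, $k \le 6$) the search is exhaustive in well under a second.
`brute_force_oracle()` is the deliberately naive reference — full enumeration
of assignments × grid-point combinations with no pruning, with an internal
assertion that the passing set is a product set — and the test suite checks
`search_designs()` against it on randomised instances.

Results are deduplicated and ordered lexicographically by device ids, inducer
ids and window bounds, so identical inputs give byte-identical outputs; there
is no randomness anywhere in the search. `max_channels()` scans $k$ upward
and stops at the first infeasible size, which is valid because feasibility is
monotone in $k$ (dropping a channel only removes constraints).

### Default concentration grid

Decade steps from $10^{-15}$ M to $10^{-4}$ M (12 points): the lower end is
the conventional "inducer absent" anchor used for the basal constraint, the
upper end the highest soluble concentration in the characterisation medium
(100 µM). Window endpoints are always grid members; a finer grid refines the
windows at linear cost.

## The synthetic-data generator

The generator exists so that every stage — fitting, database validation,
search — is testable against known ground truth without external data.

* `generate_titration()` draws replicate responses as the true curve value
  times a lognormal factor with mean 1 and coefficient of variation `cv`
  (default 3 replicates, 5 % CV). Multiplicative lognormal noise reflects
  that flow-cytometry population means have roughly constant CV across the
  dynamic range; it is a modelling choice of ours, exposed in the
  `noise_model`, not a measured error model.
* `generate_db()` builds a complete database with **planted** orthogonal
  channels: planted pairs get strongly activating curves (EC50 more than a
  decade below the window start, amplitude twice the margin-inflated
  activation threshold), the cross pairs that the planted system's crosstalk
  constraints touch are forced flat, remaining cognate pairs get randomised
  activating curves (fold 16–200, log-uniform EC50, Hill slope 0.8–2), and
  everything else stays flat. **Decoy** cross pairs get curves whose fold
  crosses `fold_off` exactly at a seeded grid point inside a requested range,
  giving window boundaries known in closed form (solving the fold equation
  for EC50). The construction is verified before returning — a decoy that
  blocks a planted channel is a construction *error*, not a silently
  infeasible fixture.
* `random_db()` is the unstructured counterpart (basal 20–200 au, fold 1–100,
  EC50 log-uniform across the grid, slopes 0.5–3) used for
  search-vs-oracle equivalence testing.

What the generator deliberately does **not** emulate: combined-inducer
synergy or antagonism (channels are modelled as independent — the model has
no interaction terms, so neither does the generator), genetic
(promoter-level) crosstalk, autofluorescence and its subtraction, cell-to-
cell heterogeneity within a population, and growth-phase or context effects.
Passing tests therefore demonstrate correctness of the fitting and search
machinery under the stated model, not robustness of the model itself to those
real-data features.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at the study's natural scales:
6 × 6 boards for enumeration (36/450 placements at $k$ = 1/2), 12-point decade
grids, 100 random 3 × 3 instances for oracle equivalence, 50 randomised
planted databases (3–4 devices, 2–3 planted channels) for recovery, and
1000 random parameter draws for the analytic identities. Noiseless round-trip
fits recover $(a, \mathrm{EC50}, h)$ to well below 0.1 %; at 5 % CV with 3
replicates the EC50 is recovered within a factor of ~1.1 in typical seeds
(asserted within a factor of 2).

Numerical conventions worth knowing:

* concentrations are matched within $10^{-9}$ in log10 space (decimal
  representation jitter must not break "is this concentration in the
  series");
* CSV/JSON persistence writes doubles at 17 significant digits
  (bit-identical round trips, byte-identical reruns);
* negative responses are legal inputs (background subtraction can
  overshoot), but fold changes are undefined for $b \le 0$ and error
  explicitly;
* "no feasible design" is an empty result with success status, distinct from
  I/O or schema errors — a scientific answer, not a failure.

## Known limitations

* The model is steady-state and single-inducer; dynamic (time-course)
  behaviour and multi-AHL interaction effects are not modelled.
* Only chemical crosstalk is represented; genetic crosstalk (a transcription
  factor activating a non-cognate promoter) needs a different experiment and
  is not a database field.
* The activator convention excludes repressor-type devices.
* Window feasibility is evaluated on the grid; between grid points the
  constraints are guaranteed only by the monotonicity of each individual
  fold curve, which holds for $a \ge b$ records.
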