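---
title: "Fingerprinting sediment-associated organic matter: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting sediment-associated organic matter: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omfingr)
```

## The problem

Organic matter (OM) deposited on and within river beds consumes dissolved
oxygen as it decays, degrading the habitat that gravel-spawning fish and
benthic invertebrates depend on. Managing the problem requires knowing where
the material comes from. `omfingr` implements a source-fingerprinting
workflow that apportions bed-sediment-associated OM among four catchment
source categories — farmyard manures or slurries, damaged road verges,
decaying instream vegetation, and human septic waste — from measurable
tracer properties: bulk stable isotopes (δ¹³C, δ¹⁵N), elemental contents
(%TOC, %TN) and near-infrared constituent band intensities. It also
implements the companion sediment-oxygen-demand (SOD) computation chain for
laboratory incubations of bed sediment.

Because raw field data of this kind are rarely deposited, the package ships
a synthetic-data generator that emulates the sampling design — four source
categories, composite samples per category per subcatchment, triplicate
sediment mixtures with *known* true proportions — so every stage of the
pipeline is testable end to end against ground truth.

## The model

### Screening: the bracket (mass-conservation) test

A tracer is only usable in a linear mixing model if the sediment values are
reachable as a convex combination of source values. Per subcatchment and
tracer, the test requires the sediment range to lie inside the envelope
(axis-aligned min–max box) of *all* source samples across categories, with
boundary equality counting as a pass. We use the pooled envelope rather
than a convex hull over category medians: the interval test is the standard
operationalization, deterministic, and errs on the permissive side —
genuinely non-conservative tracers are still caught by their range
excursions. Replicate-averaged samples enter the test, consistent with how
the laboratory data are produced (instrument runs in triplicate, averaged
before statistics).

### Composite signatures and discriminatory weightings

Three routes build composite fingerprints from the passing tracers:

* **GA-DFA** — a genetic algorithm searches tracer subsets minimizing the
  Wilks' λ of a linear discriminant fit, subject to every member passing a
  stepwise-entry *F* test at `p_entry = 0.05`. Up to three distinct top
  signatures are returned, ranked by overall classification percentage then
  λ, with ties preferring smaller subsets then lexicographic order.
* **KW-H** — tracers are ranked by the Kruskal–Wallis *H* statistic across
  the four categories (keeping those with `p < 0.05`) and the signature
  grows down the ranking.
* **PCA** — tracers are ranked by their maximum absolute loading on the
  first two principal components of the standardized source matrix (two
  components routinely explain nearly all tracer variance on these panels),
  and the signature grows the same way.

Classification percentages are resubstitution (training-set) accuracy from
`MASS::lda`, the "% classified correctly" a stepwise DFA package reports;
leave-one-out is available via `cv = TRUE` for honest generalization
estimates, but the reported tables use resubstitution. Each tracer's
discriminatory weighting is `W_i = pct_i / min(pct)`, so the weakest tracer
gets exactly 1.00.

Two choices here were genuinely open. First, the growth stopping rule for
KW-H/PCA signatures: we start at three tracers (the smallest set that can
meaningfully constrain four sources) and stop at the first non-improvement
of classification percentage. Second, the GA budget: population 50, 40
generations, uniform crossover 0.7, per-bit mutation 0.02, elitism 2, with
`n_repeats` restarts (200 by default, fewer in the bundled analyses) and a
fitness cache shared across restarts; "repeat iterations" is read as
restarts, which both diversifies the returned top-3 and keeps any single
search cheap. Exhaustive enumeration over small panels serves as the test
oracle for this machinery.

### The weighted mass-balance mixing model

For a signature of $n$ tracers and $m = 4$ sources, the relative
contribution vector $P$ minimizes

$$\sum_{i=1}^{n} W_i \, \overline{SV}_i(P)
  \left(\frac{C_i - \sum_{s=1}^{m} P_s S_{si}}{C_i}\right)^2,
  \qquad P_s \ge 0,\ \sum_s P_s = 1,$$

where $C_i$ and $S_{si}$ are sediment and source medians, $W_i$ the tracer
discriminatory weighting and $SV_{si} = 1/\mathrm{CV}_{si}$ the
within-source variability weighting (tracers with tighter within-source
distributions exert more influence). $\overline{SV}_i(P) = \sum_s P_s
SV_{si}$ collapses the per-source weights to tracer level as the
proportion-weighted mean. An alternative reading places $SV_{si}$ *inside*
the predicted concentration ($\sum_s P_s S_{si} SV_{si}$); that form breaks
mass conservation of the predicted mixture, so it is not the default, but
it is retained behind `literal_eq3 = TRUE` for fidelity comparisons. A
tracer whose group mean is zero (possible for δ values) has an undefined
CV; its SV falls back to a neutral 1 with a warning rather than a shifted
scale, which would silently inflate its influence. A CV of exactly zero is
capped (`sv_cap = 1e6`) to keep the objective finite.

**Numerics.** The simplex is parametrized as $p = x^2 / \lVert x\rVert^2$,
turning the constrained problem into a smooth unconstrained one whose
closed simplex (vertices included) is reachable; `stats::nlminb` with an
analytic gradient runs from five deterministic starts — the centroid and
each vertex smoothed inward by 0.1 (exact vertices are saddle points of the
parametrization). Components below 1e-12 are snapped to the face and the
objective re-evaluated; the best start wins, making the solver
deterministic. Near-duplicate source rows (relative difference < 1e-10)
make the solution non-unique; a valid simplex point is still returned,
flagged and warned. Tests verify the solver never loses to a 0.01-resolution
grid search.

The goodness of fit of any solution is
$\mathrm{GOF} = 1 - \tfrac1n \sum_i |C_i - \hat C_i| / |C_i|$ (absolute
mean relative error, clamped at 0), computed unweighted and on the same
tracers as the objective: it is a separate acceptance check, not the
objective, and squared-error alternatives can rate badly-fitting solutions
as acceptable where AMRE does not.

### Monte Carlo uncertainty

Medians estimated from a handful of composite samples are uncertain, and
most tracers are non-normally distributed within groups, so spread is
estimated robustly: the Rousseeuw–Croux $Q_n$, the $k$-th order statistic
of pairwise absolute differences ($k = \binom{h}{2}$, $h = \lfloor n/2
\rfloor + 1$) scaled by 2.2219 and the Croux–Rousseeuw (1992) finite-sample
factors. The straightforward $O(n^2\log n)$ enumeration is used — group
sizes are tens of samples. (Implementations differ in their small-$n$
correction factors; the tests therefore check against direct enumeration of
the published formula rather than against another library.)

Each Monte Carlo iteration perturbs **all** source and sediment medians
jointly — one row of a Latin hypercube (via `lhs::randomLHS`), each median
drawn from Normal(median, $Q_n$) truncated to that tracer's observed
[min, max] — then solves the mixing model and computes the GOF. Solutions
with GOF > 0.85 are accepted; iterations continue until 5,000 viable
solutions (default) or a cap of 100 × that many draws. The truncated normal
is the simplest $Q_n$-consistent family that respects physical plausibility
bounds; the joint perturbation (rather than one tracer at a time) reflects
that all parameters are uncertain simultaneously, while independent
per-tracer strata avoid imposing spurious correlation. LHS stratification
is within blocks of `batch` draws (default: the acceptance target), so a
run that stops early still has near-uniform marginal coverage. Sediment
perturbation can be frozen (`perturb_sediment = FALSE`) to attribute all
uncertainty to the sources.

Accepted proportions per category are binned into 100 equal intervals on
[0, 1] — 0.01 resolution, matching two-decimal reporting — giving relative
frequencies $F_i$ with midvalues $v_i$, the full uncertainty range, and the
relative frequency-weighted average median contribution $R = \sum_i v_i
F_i$.

### Combining signatures and subcatchments

Five signatures (three GA-DFA, KW-H, PCA) each yield an $R$ vector per
subcatchment. The final apportionment weights signature $k$ by $\alpha_k =
\overline{\mathrm{GOF}}_k \times \mathrm{classification\%}_k$ — the product
is the simplest symmetric way to combine goodness of fit with
discriminatory power, and published combined tables are consistent with
near-equal $\alpha$; when GOFs are unavailable the combination degrades to
equal weights. The GOF aggregate is the mean over accepted solutions.
Catchment-wide figures are unweighted means across subcatchments, reported
as percentages.

## Sediment oxygen demand

For each incubation flask the chain is: interval consumption rates
$(m_1 - m_2)/(t_2 - t_1)$ (mg O₂ day⁻¹, positive when oxygen is consumed)
assigned to interval midpoints; subtraction of the blank flask's
interpolated rates (probe drift correction — the blank must span the
sample); Van't Hoff normalization to 20 °C, $\mathrm{rate} \times
1.065^{20-T}$, valid only for $T \ge 10$ °C (colder inputs error rather
than extrapolate); trapezoidal integration over 0–5 and 0–20 days with
constant extrapolation of the edge midpoint rates to the window boundaries
(this makes a constant-rate series integrate exactly); division by dry
sediment mass. SOC₅/SOC₂₀ integrate the *normalized* rates, since
normalization precedes the consumption totals in the measurement chain.
Negative corrected rates are retained in the rate series as diagnostics,
but SOD is clamped at zero with a warning — demand is physically
non-negative. The module consumes O₂ *mass* directly; probe-signal
conversion is instrument calibration outside the contract, though an
ideal-gas helper (`o2_mass_from_fraction`) covers the common
volume-fraction case.

## What the synthetic generator emulates — and what it does not

The generator mirrors the sampling design: 4 categories × 8 composite
samples per subcatchment (80 subsamples bulked in tens; 40 in fives for
septic waste), triplicate sediment composites, and a 20-tracer panel with
the measured quantities' magnitudes (δ¹³C near −28 ‰, δ¹⁵N near 5 ‰, %TOC
near 30, %TN near 2, NIR bands on arbitrary intensity scales). Category
means are tracer baselines displaced by a fixed ±25 % relative pattern
scaled by `separation` (default 1); within-category scatter has CV 0.08 and
sediment mixtures carry 2 % multiplicative noise — values a field
practitioner would call a well-behaved campaign, and which put
Qn/median at roughly 0.08, i.e. moderate parameter uncertainty. Sediment is
an exact linear mixture of the category *means*, so at zero noise the
mixing model recovers the generating proportions to numerical precision —
the construction guarantees mass conservation.

What it does **not** emulate: tracer transformation in transit (the very
thing the bracket test screens for), inter-tracer correlation structure
within categories (tracers are drawn independently), longitudinal/seasonal
variability, connectivity processes, or continuous NIR spectra (bands are
generated as independent intensities). Passing the recovery tests therefore
demonstrates the machinery is correct under the model's own assumptions; it
does not certify accuracy on field data whose tracers violate them.

## Test and analysis problem sizes

The bundled analyses and the test suite run deliberately scaled-down
configurations, chosen as sensible demonstration sizes: Monte Carlo
acceptance targets of 120–500 solutions (tests) and 500 (analysis scripts)
instead of 5,000, and 2–10 GA restarts instead of 200. The estimators they
exercise are identical; only sampling noise on the posterior summaries
differs, and the parameter-recovery tolerance (±0.1 per category) is wide
relative to that noise. The recovery suite evaluates twenty mixture designs
spread over the simplex (vertex-heavy, balanced, and paired designs) using
the full bracket-passing panel as the signature, which isolates the Monte
Carlo machinery from selection variability; posterior-mean shrinkage toward
the simplex interior is largest for extreme mixtures and is the binding
part of that tolerance.

## Known limitations

* Resubstitution classification percentages are optimistic; they are used
  because that is what the reference tables report, not because they
  estimate generalization.
* The GOF acceptance threshold (0.85) and the posterior bin count (100) are
  conventions, not fitted quantities; `mc_config` exposes both (a threshold
  of 0 disables the filter entirely, which is occasionally useful
  diagnostically).
* The combination weight $\alpha = \mathrm{GOF} \times \mathrm{class\%}$ is
  one defensible reading of "combining goodness of fit and discriminatory
  power"; alternatives (sums, ranks) would shift combined values by at most
  a few hundredths under the near-equal weights seen in practice.
* With fewer tracers than sources minus one, the mixing problem is
  under-determined and posteriors become prior-dominated; the pipeline does
  not currently warn about this beyond the non-uniqueness flag for
  duplicated sources.
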