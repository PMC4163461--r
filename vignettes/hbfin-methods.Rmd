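---
title: "Staged odds-likelihood diagnosis from hemodynamic parameters: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged odds-likelihood diagnosis from hemodynamic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbfin)
```

## The model in one page

`hbfin` implements a staged diagnostic classifier in the tradition of
odds-likelihood expert systems. Its knowledge is a set of universally
quantified implications ("function formulas") over symptom-condition
predicates; its uncertainty calculus is Bayesian updating in odds space with
likelihood-of-sufficiency (LS) and likelihood-of-necessity (LN) multipliers;
its evidence strengths come from fuzzy membership functions fitted to labeled
cohorts. Three layers compose:

1. a **hemodynamics layer** turning pulse-waveform morphology into
   physiological quantities (stroke volume, compliance, resistance);
2. a **symbolic layer** — condition bands and function formulas — that fixes
   *what counts as evidence* and *how evidence chains into hypotheses*;
3. a **probabilistic layer** that propagates belief stage by stage through
   the resulting DAG.

The central assumption inherited from this model family is **conditional
independence of evidence given each hypothesis**: posterior odds are a plain
product of likelihood multipliers. Correlated symptoms (systolic pressure
and mean pressure, say) therefore over-count; the formula author controls
this only through the structure of the rules.

## Hemodynamic formulas

The elastic-cavity solution gives `k = (P̄−Pd)/(Ps−Pd)`,
`SV = 0.28 k² T (Ps−Pd)`, `η = 1 + As/Ad`, `AC = SV/(η(Ps−Pd))`,
`R = (P̄−Pv)/(SV·T)` and `Q = 0.0061 L + 0.0128 Wt − 0.1592`. Three
commitments are worth making explicit:

* The sphygmogram index is implemented as `η = 1 + As/Ad`, the reading
  consistent with its defining ratio `(As+Ad)/Ad`; a literal transcription of
  its second printed form would be the constant 2.
* The constant 0.28 is treated as absorbing unit conversions; units are
  documentation only, no dimensional checking is attempted. The period `T`
  sits in the denominator of `R` as printed, although that is dimensionally
  unusual for a resistance.
* Venous pressure defaults to 0, which reproduces the usual approximation
  `R ≈ P̄/(SV·T)`; callers may supply a measured value.

Degenerate inputs (`Ps = Pd`, `T ≤ 0`, `Ad = 0`, `SV = 0`) raise domain
errors naming the offending field rather than returning non-finite numbers.

## Condition bands

The bundled band table classifies 16 symptoms into pathological-high (`a`),
pathological-low (`b`) and normal (`c`) intervals; five rows have bounds that
are arithmetic expressions over weight `Wt`, height `L` and the body-size
factor `Q`. Four commitments:

* **"approximately" bands.** The source notation `≈x` is undefined; it is
  implemented as the closed interval `x(1±tol)` with `tol` a load-time
  parameter, default 0.10, so that every row is machine-checkable.
* **Range bands** `x~y` are closed on both ends.
* **Overlap resolution.** As published, several rows overlap: the weight row's
  `a` band (`>20`) encloses its normal range `50~80`, and similar nestings
  affect the cardiac-index and erythrocyte rows. Evaluation therefore gives
  two-sided bands (ranges and approx-intervals) precedence over one-sided
  bands; two bands of *equal* specificity may never overlap, which is
  verified at load time over a grid of anthropometrics and rejected as a
  configuration error. This keeps the published table usable verbatim while
  making classification a pure function.
* **The arterial-compliance row** defines only band `a`: its printed normal
  bound duplicates the pathological bound, so no self-consistent normal band
  exists and it is deliberately omitted rather than guessed.

Records may lack the anthropometrics a bound needs (the bundled worked-example
record has no height). Batch classification and net quantification treat such
bands as non-matching/unknown instead of failing; the single-value
`evaluate_condition()` keeps the strict error so configuration mistakes
surface early.

## From grades to statistical parameters

A membership function maps a symptom value to a grade `f ∈ [0,1]` for a
specific diagnosis. Three families are supported — polynomial (clipped to
[0,1]), sigmoid `1/(1+e^{−a(s−b)})`, and quasi-Gaussian
`e^{−((s−a)/2d)²}` (peak 1 at the center, finite support). Outside the
fitted support the boundary value is returned: constant extrapolation avoids
manufacturing confidence where no data existed.

Grades become net parameters by two rules with defaults `α = 100`, `β = 10`
and threshold 0.2 (the boundary inclusive, firing the LS rule):

* `f ≥ 0.2`: evidence probability `f`, `LS = α·f` — present evidence
  confirms in proportion to its grade;
* `f < 0.2`: evidence probability `f`, `LN = β·f` — low-grade evidence
  disconfirms, maximally so at grade 0.

Only one of LS/LN is assigned per symptom; the other defaults to 1
(uninformative), which keeps the odds product well defined. Hypothesis nodes
are quantified by the principle of indifference — prior 0.02, LS 200,
LN 0.01 — unless the user pins values; pinned values always survive.

### Fitting membership functions

The empirical grade per histogram bin is the **labeled fraction**: (records
carrying the diagnosis in the bin)/(all records in the bin), over occupied
bins (≥5 required). Binning defaults to Sturges' rule. The family is chosen
by minimum residual sum of squares across the three candidates, ties broken
polynomial < sigmoid < quasi-Gaussian; the source method names the families
but no selection rule, so minimum residual is this package's reproducible
surrogate, overridable per fit. A fit needs at least 20 labeled values and a
non-degenerate cohort spread. When fitting all symptom nodes of a net
(`fit_net_mfs()`), the positives for a node are the records labeled with
*any* hypothesis downstream of it — so hypotension-labeled records are
positives for the low-blood-volume node that feeds hypotension — and one
function is fitted per symptom node. Nodes that cannot be fitted fall back
to crisp band evidence at diagnosis time.

## Propagation

Nodes are processed in (stage, name) order, so traversal and traces are
deterministic. At each hypothesis node the logic layer collapses the *known*
antecedents into one effective evidence: `P(x|e)` is the min (conjunction) or
max (disjunction) of their current probabilities, and `P(x)` the same
combination of their priors. Then:

* `P(x|e) = 1` (within 1e−9): odds update with LS; `= 0`: with LN;
* strictly between: linear interpolation through the three anchors
  `(0, P(h|x̄))`, `(P(x), P(h))`, `(1, P(h|x))`, the two branches meeting
  continuously at `P(x)`;
* all antecedents unknown: the posterior stays at the prior, and the
  unknownness itself propagates (a hypothesis with no information does not
  masquerade as weak evidence for its consumers).

One LS/LN pair applies per hypothesis node — the node's own — except when a
hypothesis is fed by exactly one symptom, where the symptom's dynamically
assigned rule likelihoods apply. This matches the single-pair-per-node
quantification of the source scheme while letting single-symptom rules keep
their grade-proportional strength.

**The evidence prior of a symptom node is 0.5.** This is a deliberate design
decision at a point where the source model is self-referential: its `P(x)`
for a conjunction is the min over antecedent probabilities, but for symptom
antecedents that *is* `P(x|e)`, which would pin the interpolation to the
prior for every symptom-only rule and make fitted (non-crisp) grades
inert — no posterior could ever move. Treating presence/absence of a binary
evidence as a priori equiprobable (indifference again) gives the
interpolation a fixed, configurable anchor (`quantify_config(symptom_prior=)`)
and restores monotone response to grades. Certain evidence (grades exactly 0
or 1, including all crisp band evidence) is unaffected by this choice.

Every posterior carries a trace entry (branch, prior, applied likelihoods,
`P(x)`, `P(x|e)`); `replay_trace_entry()` recomputes the posterior from the
entry alone and is tested to agree bit for bit, and `explain()` renders the
chain down to the symptom grades.

## The synthetic generator

There is no public cohort for this problem, so the package generates one: for
each class, the symptoms in the class's formula closure are drawn uniformly
inside their required bands, every other symptom inside the normal band, with
rejection sampling guaranteeing the drawn value actually classifies into the
target band under the precedence rules. Unbounded bands are sampled on
`[bound, bound + 3·width]` using shipped per-symptom width hints (the source
table gives no physiological limits). Weight and height default to narrow
adult ranges (58–62 kg, 163–167 cm) so that anthropometric band bounds are
nearly common across the cohort and class separation is carried by the
symptom values; widening these ranges blurs the `Q`-dependent symptoms
across classes and is the first knob to turn when stress-testing. Noise
(resampling from an uninformative global range) and missingness are
per-symptom Bernoulli corruptions.

What the generator does **not** emulate: measurement error structure of real
sphygmograms, correlated symptom physiology, class imbalance, repeated
measurements per patient, or the authors-private hospital distributions.
Passing recovery tests on these cohorts demonstrates that the pipeline is
self-consistent — bands, fitted grades and propagation agree — not that the
bundled rules achieve any particular accuracy on real patients.

## Evaluation protocol and problem sizes

`evaluate_cohort()` follows the hold-out protocol: 75% of each class
(stratified, seeded) fits the membership functions, the rest is diagnosed,
and top-1 recovery is scored among the candidate classes present in the
cohort. Restricting the ranking to candidates is deliberate: intermediate
hypotheses (low blood volume sits upstream of hypotension) otherwise shadow
the classes they feed, since a single strong symptom can push a one-symptom
intermediate above a multi-symptom conclusion.

The shipped tests and the acceptance script use cohorts of 50 records per
class across the six directly-diagnosable classes (300 records; 40 per class
where an exactly-integral 75/25 split is being demonstrated), 200-record
property sweeps for the hemodynamic identities, and exhaustive enumeration
(2⁶ evidence assignments) for engine/oracle equivalence. These sizes keep
the full suite in the tens of seconds while leaving the recovery margin
(≥95% required, 97–100% observed across seeds) well clear of simulation
noise.

## Known limitations

* The conjunction/disjunction collapse discards all but the extreme
  antecedent; two weak symptoms and one strong one behave like the weak one
  alone under conjunction. This is faithful to the model family, not a bug,
  but users adding formulas should prefer small antecedent sets.
* Likelihoods are per-node, not per-edge; a hypothesis consumed by several
  formulas contributes the same posterior to each.
* The indifference constants (0.02/200/0.01) are conventions, not fitted
  quantities; posteriors are comparable within a net but are not calibrated
  probabilities.
* Membership functions are univariate; interactions between symptoms exist
  only through the logic structure.
* The predicate dialect covers the universally quantified Horn fragment with
  one connective per formula — no negation, no existential quantification,
  no mixed and/or antecedents.
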