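---
title: "Linking de-identified fishing injury datasets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking de-identified fishing injury datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishlink)
```

## The linkage problem and its assumptions

Four surveillance datasets record commercial fishing incidents in the
Pacific Northwest without shared identifiers or personally identifiable
information: the Commercial Fishing Incident Database (CFID; vessel
disasters and fatalities, person-level detail), the Vessel Casualty
database (VC; nonfatal vessel casualties, no personnel information), the
Nonfatal Injuries database (NFI; person-level injuries), and the Oregon
Trauma Registry (OTR; person-level trauma admissions). `fishlink`
identifies records across any two of them that describe the same incident.

The method is classical probabilistic record linkage. Every record of one
dataset is compared with every record of the other (a *full index*; at
these sizes, at most ~689,000 pairs, blocking is unnecessary). Each pair
receives a binary agreement vector over the pair's matching variables, and
a classifier maps that vector to a match score. The matching variables are
chosen for independence, reliability and completeness: incident date
(agreement within ±1 day), incident state (exact), vessel official number
(exact, as a normalized string — state registration numbers contain
letters), and latitude/longitude treated as one joint field (both axes
within ±0.5°, roughly 50 km). Pairs involving the trauma registry can use
only date and state: the registry records no vessel information and its
positions are mostly missing. People on board is available as an optional
extra field (`default_matching_specs("people_on_board")`); the default
specs use the per-pair variable sets above, which is what the replication
study calls for.

Agreement is deliberately binary rather than string-similarity based: all
matching variables here are dates, codes and numbers, where agreement is
either within tolerance or not. A field missing on either side is scored
as a disagreement under the default `missing_policy = "disagree"`. That
choice propagates into the thresholds: a true match with one missing field
can end up with a low posterior, which is exactly why the study thresholds
sit far below 0.5 (see below).

## The four classifiers

All four are implemented in the package from first principles and return
classed model objects with `print`, `coef` and `predict` methods.

**Naive Bayes (Fellegi–Sunter form), supervised.** Assuming conditional
independence of fields given match status, the match posterior of a vector
γ is `p Π m_i^γ_i (1-m_i)^(1-γ_i)` against the analogous u-product;
`fit_naive_bayes()` estimates each field's agreement probability among
matches (`m`) and non-matches (`u`) and the prior `p` from a labeled
golden dataset with Laplace smoothing `s = 1`. The smoothing default
matters: golden sets here contain only 4–12 verified matches, so
unsmoothed estimates hit the 0/1 boundary and produce degenerate
posteriors. Parameters are clamped to `[1e-6, 1 - 1e-6]`.

**Expectation/conditional maximization, unsupervised.** The same mixture
estimated without labels: the E-step computes per-pair match posteriors
under current parameters, the conditional M-steps update `p`, `m`, `u`
from the posterior weights. Comparison vectors are collapsed to unique
agreement patterns first, so each iteration costs O(2^k) regardless of the
pair count. Convergence is declared when the observed-data log-likelihood
changes by less than `1e-6` (at most 200 iterations), and the trace is
returned so the EM monotonicity property is checkable. Label switching is
resolved by requiring `m ≥ u` on a majority of fields. Initialization is
the fixed default `m = 0.9, u = 0.1, p = 0.05` — reproducible runs matter
more here than an arbitrary random start — with optional seeded random
restarts (`restarts > 0`) keeping the best log-likelihood, since EM can
land on local maxima.

**Logistic regression, supervised.** Ridge-penalized (`ridge = 1e-4`,
intercept unpenalized) maximum likelihood by Newton/IRLS. The penalty is
not cosmetic: golden datasets are usually linearly separable, where the
unpenalized MLE diverges.

**Linear SVM, supervised.** L2-regularized hinge loss minimized by
seeded, deterministic Pegasos-style subgradient descent
(`regularization = 0.01`, 200 epochs). It is non-probabilistic: output is
0/1 and the decision threshold is fixed at 0.5 — `classify_links()`
refuses any other value for SVM scores. This rigidity is why the SVM is
the weakest performer on these data.

**Thresholds.** A pair is a link iff its score is *strictly* greater than
the threshold. The study defaults are 0.005 for naive Bayes and logistic
regression (0.01 for the NFI–VC pair), 0.5 for ECM (0.2 for OTR–NFI), and
0.5 for the SVM. The very low probabilistic thresholds compensate for
field variability and the missing-equals-disagree policy; they err toward
false positives on purpose, because in datasets this small every missed
match is costly while false positives are removed by verification.

## Golden datasets

Supervised training needs pairs of known status. The package builds them
the way a practitioner would: a *rudimentary proposal rule* (every one of
the pair's matching variables must agree, at the study tolerances, with
missing fields disagreeing) yields a small high-precision candidate list;
candidates are then *verified* — against the planted ground truth in
synthetic mode, or a human review file in real mode, where unreviewed
candidates raise an error rather than being guessed. Non-matches are
manufactured by *scrambling*: each field column is independently permuted
across a sample of real records, preserving marginal distributions while
destroying joint structure; any fake pair that would satisfy the proposal
rule is rejected and redrawn. The default non-match count is
`max(10 × matches, 50)` — the class imbalance must exist but stay bounded
for logistic/SVM stability; the source study does not report its golden
set sizes, so this is an explicit knob.

A design note on the proposal rule: requiring *exact* equality on all
fields would be blind to the very field noise the data exhibit (matched
records differ by up to a day in date and half a degree in position), and
exact equality on continuous coordinates is degenerate. Using the study
tolerances keeps the rule rudimentary — it is still a deterministic
all-fields-agree filter — while letting it find every plantable match
except those with a missing matching variable. On the default synthetic
universe this reproduces the golden match counts
{5, 9, 12, 10, 4, 0} per pair exactly, including the OTR–NFI link that
drops out of the golden set because its state is missing (that match is
later recovered only by naive Bayes at the low threshold).

## The synthetic universe

The real datasets are sensitive and unavailable, so the generator creates
a universe whose *structure* matches the study conditions and whose
ground truth is exact by construction:

* **Sizes and ranges.** CFID 1,315 incidents expanding to 2,966 person
  cases; VC 524 incidents (no persons); NFI 232 person rows; OTR 11
  patients; each with the study's date ranges.
* **Planted overlaps.** Pairwise true matches CFID–OTR 5, CFID–VC 9,
  CFID–NFI 12, OTR–VC 0, OTR–NFI 5, NFI–VC 10 (41 in total), including
  3 CFID–OTR–NFI and 1 CFID–NFI–VC triple overlaps; three multi-person
  CFID–NFI incidents with 3+3+2 persons provide the 8 close matches; four
  OTR cases are unmatched on purpose (two located outside the covered
  region, two recreational). Exactly one OTR–NFI link has its state
  removed on the NFI side, reproducing the match that is hard to find.
* **Field accuracy.** Dates: each dataset's view of a shared incident is
  jittered within a *one-day window* around the latent date (a direction
  is drawn per incident, each view moves by 0 or 1 day in that
  direction). Independent ±1-day jitter would let two views differ by two
  days, contradicting the observed ±1-day relative accuracy of matched
  pairs and silently breaking matches at the ±1 tolerance. Positions:
  per-view uniform jitter of ±0.25° per axis, so two views differ by at
  most ±0.5°. Vessels: a synthetic fleet of 1,500 vessels reused across
  incidents, so the vessel number is discriminating but not unique and
  the date stays essential; 10% of the fleet carries a state registration
  number instead of an official number, *consistently across datasets*,
  because matched records are observed to always agree on the vessel
  field while the official number is sometimes simply unavailable.
  Missingness: positions missing 70% in OTR and 10% elsewhere, states
  missing 1–2%, people on board 3% — the source material says only
  "often"/"rarely missing", so these are config-exposed choices, not
  claims. Miles from shore is redrawn per view and never agrees.
* **Uniqueness.** Non-overlapping incidents are forced to differ jointly
  on (date, vessel): two incidents of the same vessel are at least 4 days
  apart, so at the ±1-day tolerance the planted truth is the unique
  correct answer on the vessel-based pairs. Planted incident dates are
  drawn inside the member datasets' intersected ranges (inset one day so
  jitter cannot leave the range).
* **Presence forcing.** On planted views the matching variables stay
  present (state, position, person count), except for the engineered
  missing-state link. Without this, random missingness would knock a few
  planted matches out of the golden sets and the totals would drift from
  the study conditions. CFID person counts are always present — they
  define the person-level expansion.

One bookkeeping consequence: NFI holds 232 person rows in 227 incidents
(the 8 close-match persons share 3 incidents), so its "incidents" and
"records" counts differ while every linkage-facing count (232, and all
six printed pair-combination totals) is preserved.

Everything derives from a single seed via labeled sub-seeds, so a run is
reproducible byte for byte; the planted totals are seed-invariant by
construction.

What the generator does **not** emulate: realistic narratives, coastline
geometry, reporting compliance or under-reporting, duplicate records
*within* a dataset, and the historical false-positive structure of the
source data. Tests passing on this universe therefore validate the
pipeline's mechanics and bookkeeping — not the historical per-cell
confusion counts, which depend on the unavailable source data and are out
of scope.

## Evaluation and match accounting

Per-pair quality metrics follow the standard definitions — precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, and their harmonic mean f — with the
0/0 convention equal to 0, so zero-link runs report f = 0 rather than
NaN. The evaluation universe is the full cross-product (TN dominates),
and for supervised runs the positive set is the golden matches, which is
how the replica metrics tables are laid out; study reports round f to two
decimals while the study object keeps full precision.

Study-level accounting works on links confirmed against ground truth:

* **Close matches** are links where one record links to ≥2 person records
  of a single incident indistinguishable on all matching variables
  (`flag_close_matches()`); each group counts its unresolvable person
  cases (the larger record set of the two sides) and is reported, never
  resolved. The default universe yields 3 groups and 8 cases.
* **Duplicates** are confirmed matches inside dataset pairs that are
  disjoint by definition (CFID–VC, CFID–NFI): the same case recorded
  twice. Including close-match cases, the default run flags 9 + 20 = 29.
* **Deduplication rule.** The first dataset of each disjointness entry is
  authoritative (these cases belong in CFID only); the partner record is
  purged, and any link whose endpoint was purged disappears with it. A
  CFID–OTR–NFI triple thus keeps its CFID–OTR link but loses the OTR–NFI
  one, and the CFID–NFI–VC case loses its NFI–VC link entirely. The
  source material reports only the resulting numbers; this purge rule is
  the package's reconstruction and is validated by reproducing them:
  remainder 16 = 41 − 21 duplicate links − 4 absorbed, split 5 / 2 / 9
  across CFID–OTR, OTR–NFI and NFI–VC.
* **Multi-dataset cases** are connected components of confirmed links
  spanning ≥3 datasets (4 on the defaults).

## Numerical choices and degenerate inputs

Probabilities clamped to `[1e-6, 1 − 1e-6]`; posteriors computed in log
space; ECM on unique patterns with a degenerate-input error (a single
repeated pattern makes the mixture unidentifiable — reported with the
trace, never silently "converged"); strict `>` at the threshold so a
score exactly at the threshold is a non-link; empty golden classes are
refused by every supervised fitter; scrambling fails loudly after `10 n`
rejected draws; single-record datasets cannot be scrambled. Dataset pair
order is canonicalized (CFID, OTR, VC, NFI) so reports are stable.

On ECM parameter recovery: with mixing proportion 0.01 and 10^5 vectors
only ~1,000 latent matches exist, so per-parameter uncertainty in `m` is
about ±0.01 at one sigma and no estimator can reliably sit within ±0.02
of the truth; the recovery test therefore simulates at mixing proportion
0.05 for the tight ±0.02 bound and checks the 1% case at a 3-sigma
±0.05.

## Problem sizes in the test suite

The unit and acceptance tests run the full-size universe (1.5 million
pair comparisons per study run, a ~30,000-vector ECM recovery in the unit
suite and a 100,000-vector one in the acceptance suite); a complete
six-pair, four-classifier study takes a few seconds, so the default study
conditions are exercised directly rather than scaled down.

## Known limitations

Real mode expects the harmonized CSV schema, not the providers' raw
export formats. Time of day is stored verbatim but never compared (its
recording is too inconsistent to be a matching variable), and narrative
text is carried but not analyzed. Self-deduplication within one dataset
is out of scope (the full index refuses identical dataset ids). The SVM
is linear only. The synthetic universe validates mechanics, not history:
its false-positive counts differ from the unavailable real data's, and
the four unmatched trauma cases are planted analogues, not the real
narratives.
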