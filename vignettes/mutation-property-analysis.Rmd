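---
title: "Relating amino-acid property changes to receptor mutant function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating amino-acid property changes to receptor mutant function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutprop)
```

## The problem

Site-directed mutagenesis of membrane receptors — olfactory receptors in
particular — produces small panels of single amino-acid substitutions,
each with a measured functional readout: a change in EC50, an odorant
response, a cAMP or Ca²⁺ increase. The question this package addresses
is how much of that functional change is explained by the
physicochemical character of the substitution itself: how different the
mutant residue is from the wild type in hydrophobicity, volume, helix
propensity, and so on, and how the residue's sequence and spatial
surroundings modulate that difference.

The analysis has three stages: feature construction from amino-acid
property scales, exhaustive best-subset multiple regression of the
functional readout on those features, and binary discrimination of
mutants that increase versus decrease EC50, validated by leave-one-out.

## The model

### Property normalization

A property scale assigns one number to each of the 20 standard amino
acids. Scales arrive in arbitrary units, so each is min-max normalized,

$$P_{norm}(i) = \frac{P(i) - P_{min}}{P_{max} - P_{min}},$$

with the extrema taken over the 20 standard residues. Every downstream
feature uses the normalized scale by default (a `scale = "raw"` switch
exists for diagnostics). Normalization over the standard alphabet only
is deliberate: non-standard residues (X, B, Z) are rejected at lookup
rather than silently extended. A constant scale is rejected as
degenerate — it carries no information and would divide by zero.

### Per-mutant features

For a mutant at position $i$ with wild-type residue $w$ and mutant
residue $m$, three encodings are available per property:

* **Mutation difference** $\Delta P = P(m) - P(w)$ — antisymmetric in
  the substitution direction, zero for an identity mutation.
* **Sequence-window effect**
  $P_{seq} = \sum_{j=i-k}^{i+k} P_j - P(m)$ — the property total of the
  wild-type segment of $2k+1$ residues around the site, minus the mutant
  value. At $k = 0$ this is exactly $-\Delta P$. Windows are truncated
  at the termini (out-of-range positions contribute nothing) rather
  than dropping terminal mutants, so every record stays usable at every
  $k$; users comparing against a skip-terminal convention should note
  the difference.
* **Structural effect** $P_{str} = P_{sur} - P(m)$, with
  $P_{sur} = \sum_j n_{ij} P_j$ summing the property over all residues
  whose representative coordinate lies within 8 Å of the mutated site.
  We use the Cα atom as the representative point and exclude the site
  itself while keeping sequence-adjacent residues, the convention of the
  surrounding-hydrophobicity literature; both the radius and the
  neighbor rule are arguments, since some protocols count heavy-atom
  contacts instead. PDB numbering is mapped to sequence positions by an
  explicit integer offset; insertion codes and multi-chain selections
  beyond a single named chain are unsupported.

### Best-subset regression

Single-property association uses the Pearson correlation $r$; combined
models are ordinary least squares on a subset of feature columns, scored
by the multiple correlation coefficient $R$ — the correlation between
fitted and observed responses, reported non-negative (single-property
results keep the sign of $r$). Subsets of three to five properties are
found by fitting *all* combinations of the available columns and taking
the highest $R$; no stepwise heuristic is involved, so the winner is the
global optimum for its size range. Ties break toward the smaller subset
and then lexicographic column order, which is deterministic.

The inner loop runs in compiled code on centred cross-products: for a
subset $S$, $R^2 = S_{xy}(S)^\top \beta / S_{yy}$ with
$\beta = S_{xx}(S)^{-1} S_{xy}(S)$, so each candidate costs one
$|S| \times |S|$ solve. The full sweep over 49 properties at sizes 1–4
(231,525 models) takes well under a second on one core; sizes up to 5
(2.1 million models) a few seconds. A configurable ceiling
(`max_fits`, default $5 \times 10^6$) refuses accidental combinatorial
blow-ups, reporting the computed search-space size.

Two honesty guards are built in. First, fits with $N < p + 2$ are
refused unless `allow_saturated = TRUE`: published panels fit up to 5
properties on as few as 7 mutants, and that regime inflates $R$ — the
override reproduces it, and $(N, p)$ is always reported alongside $R$.
Second, no multiple-testing correction is applied across the searched
models (matching standard practice for this analysis), but the report
records the search-space size so a reader can judge selection effects.

### Discrimination of increase vs decrease mutants

Mutants are labelled by the sign of their response change (positive →
`increase`, the positive class; an exact zero is an error rather than a
silent default). The classification features per property are
$[P(w), P(m), \Delta P, P_{seq}(k)]$ — a concrete choice, since the
attribute set of this analysis is conventionally left open. Four
standard classifiers are bundled — logistic discriminant, Gaussian naive
Bayes, k-nearest neighbor, and a decision tree — and *all* are evaluated
and reported, rather than silently selecting a best method after the
fact. Evaluation is by self-consistency (resubstitution) and by the
jack-knife: $N$ leave-one-out folds, each record predicted once by a
model that never saw it, with feature standardization refit inside every
fold on the $N-1$ training rows to avoid leakage. Performance is
$$\textrm{Sensitivity} = \frac{TP}{TP+FN},\quad
  \textrm{Specificity} = \frac{TN}{TN+FP},\quad
  \textrm{Accuracy} = \frac{TP+TN}{N}.$$
If a fold's training set collapses to one class (a singleton class was
left out), the fold predicts the training majority, with a warning.
Property-subset selection is *not* re-run inside folds by default; a
strict nested protocol can be emulated by driving [jackknife()] from a
wrapper, and reports record the seed and settings that produced them.

## What the synthetic generator emulates

Functional measurements for receptor mutant panels live in curated
databases and are rarely tabulated in print, so the package generates
its own study-shaped data: small panels (defaults span 6–30 mutants,
with 28 and a 15/13 increase/decrease split as the classification
default) whose response is a noisy linear function of a few property
features,

$$Y = \beta_0 + \sum_{s \in S} \beta_s f_s + \varepsilon,
  \qquad \varepsilon \sim N(0, (\sigma \cdot SD_{signal})^2).$$

Noise is parameterized relative to the noiseless response SD, so
recovery difficulty is scale-free; additive Gaussian noise is the
minimal assumption consistent with a linear-correlation analysis.
Defaults are $|S| = 3$, $\beta_0 = 0.5$, $\beta = (2, -1.5, 1)$,
$\sigma = 0.05$. Ground truth (subset, coefficients, noise) travels
with every dataset, enabling closed-loop tests: at $\sigma = 0$ the
size-3 search must return the true subset with $R = 1$ and exact
coefficients; at $\sigma = 0.05$ recovery across seeds is the headline
operating characteristic.

For labelled sets, one designated property's $\Delta P$ is the
separating score: `increase` mutants are drawn with
$\Delta P \ge$ `class_margin`, `decrease` with $\Delta P \le -$margin
(normalized units, default 0.5), and the response is $10\,\Delta P$
plus small sign-preserving noise, so `label_by_sign()` reproduces the
construction and the margin directly controls the class gap in feature
space. `class_margin = 0` switches to a null model — labels randomly
permuted against features — whose jack-knife accuracy should sit at
chance; this is the negative control for the whole discrimination
stack. Simulated structures use an ideal α-helix Cα trace (1.5 Å rise,
100° twist, 2.3 Å radius), which gives interior residues ~8 neighbors
at 8 Å, or random packing at a 3.8 Å minimum separation.

What the generator does **not** emulate: real property scales'
correlation structure (the packaged 49-scale table is synthetic — drawn
uniformly and normalized — and clearly labelled as such; the analysis is
table-agnostic and any user TSV drops in), dose–response curve shape
(EC50 values are treated as given scalars), receptor topology, and any
relation between TM/loop location and effect size (location labels are
decorative in synthetic data). Passing closed-loop tests therefore
demonstrates the machinery's correctness and operating characteristics
under the linear model, not biological validity on real panels.

## Numerical choices

* Normalization endpoints are exact by construction; round-trip
  (denormalize ∘ normalize) holds to 1e-10 in tests.
* Subset-search $R^2$ from cross-products is clamped to $[0, 1]$ against
  rounding; rank-deficient candidate subsets are skipped and counted,
  never silently ranked. The refit of the reported top-m uses `lm`, so
  coefficients come from a pivoted QR, not the fast path.
* Ties in the search are broken (size, then lexicographic) by
  enumeration order plus strict-improvement updates — no floating-point
  tie tolerance is introduced.
* k-NN ties are avoided by an odd default $k = 3$; all classifier
  randomness is scoped to an explicit seed and restored afterwards.
* Positions are 1-based everywhere; the ΔEC50 sign convention is
  `value(mutant) − value(wild)`, so `increase` ⇔ positive response. The
  package never infers direction from response labels.

## Problem sizes in the test suite

The suite exercises: equation-level examples (exact, instantaneous);
oracle equivalence against an independent brute-force enumerator on 5
seeded datasets ($N = 20$, 10 columns, sizes 1–3); subset recovery over
100 seeded replicates ($N = 30$, 49 properties, $|S| = 3$, at 5% and 0%
noise); monotonicity of best $R$ in the size budget over 10 seeds; the
15/13 classification closed loop with a 50-seed null; and the full
49-property search at sizes 1–4 and 5. These sizes mirror the intended
application scale of the method.

## Known limitations

* The structural encoding supports a single chain and representative
  point per residue; heavy-atom contact counting is not implemented
  (the neighbor rule is pluggable at the radius level only).
* The logistic discriminant on perfectly separable data sits at the
  parameter-divergence boundary of `glm`; predictions are stable but
  coefficients are not interpretable there.
* The jack-knife does not nest encoding/property selection by default;
  with selection performed on the full data first, its accuracy is
  optimistic relative to a fully nested protocol.
* With $\le 30$ mutants and $\ge 49$ candidate properties, the searched
  model space is enormous relative to the data; $R$ from the search is a
  selected statistic and should be read together with the reported
  search-space size.
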