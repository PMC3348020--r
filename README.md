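# mutprop

Amino-acid property analysis of membrane receptor mutants.

Site-directed mutagenesis panels of olfactory and other membrane
receptors pair each single-residue substitution with a functional
readout — a change in EC50, an odorant response, a cAMP or Ca²⁺
increase. `mutprop` quantifies how much of that functional change is
explained by the physicochemical character of the substitution and its
sequence/structural surroundings. It is aimed at structural
bioinformaticians analyzing small mutant panels (typically 6–30 records)
against libraries of amino-acid property scales.

## Method

For each mutant (wild type *w* → mutant *m* at position *i*) and each
min-max-normalized property scale *P*, three features are available:

- **mutation difference** ΔP = P(m) − P(w);
- **sequence window** P_seq = Σ_{j=i−k}^{i+k} P_j − P(m), the property
  total of the wild-type 2k+1 window minus the mutant value (truncated
  at termini);
- **structural** P_str = P_sur − P(m), where P_sur sums the property
  over residues whose Cα lies within 8 Å of the site.

Single properties are scored by Pearson *r* against the response.
Combinations are found by **exhaustive best-subset regression**: every
combination of properties (typically 3–5 out of 49) is fitted by OLS
and ranked by the multiple correlation coefficient R = cor(fitted,
observed). The search is compiled and exact — 2.1 million candidate
models take seconds — with honest-by-default guards (saturated fits
N < p + 2 refused without an override; search-space size always
reported).

Mutants that increase vs decrease EC50 are discriminated from
[P(w), P(m), ΔP, P_seq] features with four bundled classifiers
(logistic, naive Bayes, k-NN, decision tree), all evaluated by
self-consistency and jack-knife (leave-one-out) tests and scored by
sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy (TP+TN)/N.

A synthetic-data module generates property tables, mutant panels with
known linear ground truth, helical Cα traces and labelled 15/13
increase/decrease sets, so the whole pipeline is testable closed-loop
without any external database. The packaged 49-scale table
(`inst/extdata/aa_properties_synthetic49.tsv`) is synthetic and
user-replaceable — any TSV with `id`, `description` and 20 residue
columns drops in.

## Worked example

```r
library(mutprop)
pt <- load_property_table(system.file("extdata",
        "aa_properties_synthetic49.tsv", package = "mutprop"))

# a 28-mutant panel whose response is linear in 3 properties + 5% noise
cfg <- simulation_config(seed = 42L, n_mutants = 28L, noise_sd = 0.05)
ds  <- simulate_mutation_dataset(pt, cfg)
fm  <- build_feature_matrix(ds, pt, encodings = "delta")

print(correlate_all(fm, ds$records$response), n = 3)
#> Single-property correlations (N = 28, 49 columns, 0 skipped as constant)
#>         column         r     abs_r  N
#> 1 delta:prop01 0.6787311 0.6787311 28
#> 2 delta:prop15 0.5814931 0.5814931 28
#> 3 delta:prop27 0.5351503 0.5351503 28

print(exhaustive_subset_search(fm, ds$records$response, sizes = 1:3), n = 3)
#> Exhaustive subset search: 49 columns, sizes {1,2,3}, 28 mutants
#>   19649 combinations fitted (0 skipped as rank-deficient)
#>   1. R = 0.9993  [delta:prop01, delta:prop02, delta:prop03]
#>   2. R = 0.9395  [delta:prop01, delta:prop02, delta:prop27]
#>   3. R = 0.9328  [delta:prop01, delta:prop02, delta:prop22]
```

The best single property explains r = 0.68 of the response; the
exhaustive size-3 search recovers exactly the three properties the
generator used (prop01–prop03) at R = 0.999 — the closed loop the
synthetic module is built for.

```r
sim <- simulate_classification_dataset(pt,
         simulation_config(seed = 42L, class_margin = 0.5))
rep <- evaluate_classifiers(sim$labeled, seed = 42L)
rep[rep$mode == "jackknife", c("method", "TP", "FP", "TN", "FN", "accuracy")]
#>         method TP FP TN FN accuracy
#>       logistic 15  0 13  0        1
#>    naive_bayes 15  0 13  0        1
#>            knn 15  0 13  0        1
#>  decision_tree 15  0 13  0        1
```

At a class margin of 0.5 normalized units the 15 increase / 13 decrease
panel is cleanly separable and every bundled classifier reaches
jack-knife accuracy 1.0; with `class_margin = 0` (random labels) the
same pipeline sits at chance — the negative control.

## Command line

```sh
Rscript inst/cli/mutprop.R simulate --seed 4 --outdir out/
Rscript inst/cli/mutprop.R search   --config out/run.yaml --sizes 1:4
Rscript inst/cli/mutprop.R classify --config out/run.yaml
```

Each command writes TSV/JSON reports plus a `run_log.yaml` capturing
every setting needed to regenerate the outputs exactly.

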