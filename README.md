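# neuroforecast

Predicting hit songs from neurophysiologic immersion with a
super-learner ensemble.

Neurologic *immersion* is a 1 Hz index of attention and emotional
resonance inferred from cardiac activity. The neuroforecasting idea is
that the immersion responses of a small listening cohort (tens of
people) can classify aggregate market outcomes — which new songs become
*hits* (over 700,000 streams) and which *flop* — better than
self-reported liking can. This package implements that analysis
end-to-end for researchers working with such traces:

1. **Song-level neural statistics.** For each song, the
   cross-participant average series `v_t` (after removing listeners
   already familiar with the song) yields three features:
   - *average immersion*: `mean(v_t)`;
   - *peak immersion*: `Σ_t v_t · 1[v_t > M] / Im`, where
     `M = median(v_t) + SD(all participant-second samples)` and
     `Im = Σ_t v_t`;
   - *retreat*: the summed lowest 20% of `v_t` (the `k = max(1,
     floor(0.2 T))` smallest values) divided by `Im`.
   A first-minute variant truncates traces to `t < 60` first.
2. **Augmentation.** The small song table is inflated to 10,000 rows by
   sequential conditional synthesis (marginal bootstrap for the first
   column, regression-tree donor sampling for the rest), with a
   distributional-fidelity check.
3. **Classification.** A super-learner ensemble of four learners
   (ridge logistic, k-nearest neighbors, a kernel machine, a
   single-hidden-layer network) combined as `Ŷ = Σ_j β_j Ŷ_j`, where the
   simplex weights `β` minimize 5-fold cross-validated squared error of
   the out-of-fold predictions.
4. **Evaluation.** Confusion metrics, exact binomial tests against the
   hit base rate, a 95%-CI bootstrap comparison against a logistic
   baseline, k-fold overfitting checks, and standard effect statistics
   (pooled t, Cohen's d, Pearson r, VIF).

A seeded synthetic-cohort generator (AR(1) noise + class-dependent dip
episodes + participant/song random effects) is calibrated so hit and
flop songs separate with Cohen's d ≈ 0.95 on average immersion and
≈ 0.82 on retreat, which makes every stage testable without access to
proprietary recordings. See the methods vignette
(`vignettes/neuroforecasting-pipeline.Rmd`) for the model, the
calibration, and the design decisions.

## Worked example

```r
library(neuroforecast)

co    <- simulate_cohort(cohort_config(seed = 1))   # 33 listeners x 24 songs
feats <- featurize(co$traces, co$surveys, co$songs)
head(feats, 4)
#>    song_id label avg_immersion peak_immersion   retreat n_participants window
#> 1:     s01   hit      4.258694              0 0.1862835             20   full
#> 2:     s02   hit      4.254955              0 0.1839794             23   full
#> 3:     s03   hit      4.063591              0 0.1869267             27   full
#> 4:     s04   hit      4.280457              0 0.1874800             25   full

syn    <- synthesize_table(feats, synthesis_config(n_rows = 2000, seed = 2))
halves <- split_half(syn, seed = 3)
model  <- fit_ensemble(halves$train, tune = FALSE, seed = 4)
model
#> <nf_ensemble> super-learner on avg_immersion, retreat
#>   logistic  beta = 0.0000  cv risk = 0.2330
#>   knn       beta = 1.0000  cv risk = 0.0000
#>   svm       beta = 0.0000  cv risk = 0.1894
#>   ann       beta = 0.0000  cv risk = 0.1593
#>   ensemble cv risk = 0.0000, threshold = 0.50

confusion_metrics(halves$test$label, predict(model, halves$test, type = "class"))
#> accuracy 1.000 | sensitivity 1.000 | specificity 1.000

logistic_baseline(feats, "model2")$confusion$accuracy
#> [1] 0.7083333
```

The ensemble weights tell the same story as the underlying analysis:
k-nearest neighbors absorbs essentially all the weight (it can exploit
the non-linear class structure and the discreteness of donor-based
synthetic data), while the linear logistic baseline reaches only ~70%
on the 24 observed songs. On held-out synthetic data the ensemble
classifies nearly perfectly — an artifact-friendly upper bound, since
donor synthesis from 24 songs is memorizable; the robust claim, which
the test suite checks across 100 replicates, is that the ensemble beats
the logistic baseline out of sample.

`run_pipeline(pipeline_config(seed = 1))` executes the whole chain
(simulate → featurize → synthesize → split → train → evaluate) and
returns a structured report; with `out_dir` set it writes every table,
the synthetic data and `report.json`. A thin command-line front end
with the same stages lives at `inst/scripts/neuroforecast-cli.R`.

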