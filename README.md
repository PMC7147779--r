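# depscreen

Multimodal depression-screening signals from social-media cohorts.

Depression screening from passively shared social-media content is a
population-health problem: clinicians and epidemiologists would like early,
unobtrusive indicators of depressive symptoms at community scale, where
survey-based instruments under-sample exactly the people most at risk.
`depscreen` implements a complete, testable version of a multimodal screening
pipeline for Twitter-like cohorts: computational-aesthetic features of
profile and shared images, pooled facial-emotion vectors, lexicon-based text
and demographic features (age-disclosure rules, weighted-lexicon age/gender
scores, adult-development age groups), egocentric reply-network metrics,
shadow-feature (Boruta-style) selection, and a second-order gradient-boosted
classifier whose every prediction decomposes into exact additive log-odds
contributions per feature.

Because real annotated cohorts of this kind cannot be redistributed, the
package's first-class component is a **calibrated synthetic cohort
generator**: it emulates the statistical structure such a dataset exhibits —
class sizes 3,981 likely-depressed vs 4,789 control, per-class age/gender
disclosure rates taken from printed counts (822/3981 and 239/4789 for age),
right-skewed ages with class medians 17 and 19, per-class image-aesthetic
class means, facial-presence rates by context, heavy-tailed engagement
counts, and reply networks whose two-hop neighborhoods average ≈84
(depressed) vs ≈154 (control) — so the whole pipeline runs and is verified
end to end with no external data.

## The model at the core

The classifier is a boosted ensemble of regression trees fitted to the
logistic loss by its second-order expansion. With prediction
`ŷᵢ = Σₜ fₜ(xᵢ)` and per-example derivatives `gᵢ = pᵢ − yᵢ`,
`hᵢ = pᵢ(1 − pᵢ)`, each tree minimizes

```
L = Σⱼ [ Gⱼ wⱼ + ½ (Hⱼ + λ) wⱼ² ] + γ k,        wⱼ* = − Gⱼ / (Hⱼ + λ)
```

over its `k` leaves, and splits greedily on the structure-score gain

```
gain = ½ [ G_L²/(H_L+λ) + G_R²/(H_R+λ) − (G_L+G_R)²/(H_L+H_R+λ) ] − γ ,
```

accepting only positive gains. Leaf values are shrunk by `η`. Predictions are
explained by deterministic path attribution: the change in the regularized
node estimate at every traversed split is credited to the split feature, so
`base + Σ deltas` equals the predicted log-odds exactly (a log-odds of 0.31,
for instance, is a 57% chance of the depressed class).

Feature selection follows the shadow-feature scheme: every column gets a
row-permuted copy, a random forest is fitted on the doubled matrix, a feature
scores a hit when it out-ranks the best shadow, and hits over iterations are
referred to an exact two-sided Binomial(n, ½) test.

## Worked example

```r
library(depscreen)

co <- generate_cohort(cohort_config(n_depressed = 120, n_control = 140, seed = 42))
co
#> <cohort> 120 depressed / 140 control users, 43433 interaction edges

facial_presence_stats(co)[, c("context", "rate_depressed", "rate_control")]
#>     context rate_depressed rate_control
#> 1     media          75.83        86.43
#> 2   profile           5.00        11.43
#> 3 not_found          22.50        12.14

blocks <- cohort_feature_blocks(co, images = FALSE)
y <- cohort_labels(co)
cross_validate(blocks, y, booster_params(nrounds = 60), k = 5, seed = 7)
#> <cv_result> 5 folds: specificity 0.921, sensitivity 0.900, f1 0.904, accuracy 0.912

fm <- early_fusion(blocks)
model <- fit_booster(fm$x, y[rownames(fm$x)], booster_params(nrounds = 60))
explain_booster(model, fm$x["u00001", ])
#> log-odds 3.251 (probability 96.3%), base -0.071
#>   +1.3342  avg_tweet_favorite_count
#>   +1.0006  statuses_count
#>   -0.7940  avg_tweet_retweet_count
#>   +0.6902  negemo
#>   ...
```

The presence table shows depressed users revealing faces less often in both
contexts; the cross-validated fused model separates the classes well on the
synthetic cohort; and the waterfall explains one user's score — depressed
users in this cohort have fewer retweets/favourites per tweet on average,
more negative-emotion words, and screen names closer to depression-indicative
terms, and the per-feature log-odds deltas quantify exactly how each signal
moved this particular prediction.

Image features work on any RGB array or PNG:

```r
img <- synthesize_image(image_calibration_targets("depressed", "profile"), seed = 1)
colorfulness(img)   # opponent-channel chroma score
naturalness(img)    # memory-color index in [0, 1]
image_features(img) # the full per-image vector
```

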