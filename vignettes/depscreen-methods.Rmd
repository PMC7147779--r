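---
title: "Methods: multimodal depression screening on synthetic social-media cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal depression screening on synthetic social-media cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

`depscreen` assembles heterogeneous signals about a social-media user —
images, facial affect, text, inferred demographics, engagement counts and
reply networks — into one early-fusion feature vector and classifies
likely-depressed vs control users with an interpretable boosted-tree model.
This vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic cohort does and
does not establish.

## 1. The synthetic cohort

Annotated mental-health cohorts cannot be shared, so the generator is a
first-class, tested component rather than a fixture. It emulates the
*statistical shape* of an 8,770-user annotated Twitter cohort. Calibration
parameters live in `cohort_config()`; the defaults are the study conditions
and are not meant to be tuned per analysis:

* **Class sizes** 3,981 depressed / 4,789 control.
* **Age disclosure** is Bernoulli per user at the printed counts 822/3981
  (depressed) and 239/4789 (control). The control disclosure is sometimes
  quoted as "4%", but 239/4789 is 4.99%; the generator uses the counts, not
  the rounded percentage.
* **Ages** follow a truncated log-normal on [11, 60] (`sdlog` 0.45), with the
  location solved numerically per class so the *integer* median of sampled
  ages is 17 (depressed) and 19 (control); the continuous median is aimed
  0.2 years above target so rounding cannot tip the median to the next
  integer. Right-skew matches the young-user bias such platforms show.
* **Gender** is latent for every user (female share 0.70 / 0.55 by class, so
  the female–depression association has the reported direction) and
  disclosed at rates 937/3981 and 527/4789.
* **Engagement counts** (friends, followers, statuses, favourites, per-tweet
  favorite/retweet averages) are log-normal with the printed per-class means.
  Dispersion is not printed anywhere, so the coefficient of variation is
  fixed at 1 — heavy-tailed, as platform count data always are.
* **Facial presence** is Bernoulli per user and context at the printed rates
  (profile 4%/12%, media 72%/81%); presence forces at least one image in
  that context. Rates are computed over *all* users of a class, and the
  `not_found` row is the complement of (profile ∪ media) presence.
* **Facial emotion** vectors are Dirichlet draws over the six basic emotions
  with the negative components (anger, disgust, fear, sadness) carrying a
  class-dependent share of the concentration mass. A Gaussian copula couples
  the per-user facial-negativity level with the text-negativity level at
  latent correlation `emotion_text_corr` (default 0.6), emulating the
  reported agreement between visual and textual affect channels.
* **Tweets** are templated word streams, not natural language: each word is
  drawn from emotion, gender-flavoured, and age-mix pools whose probabilities
  shift linearly with latent age and with the copula's text channel. Pool
  membership is aligned with the bundled lexica, so lexicon features recover
  the planted signal by construction.
* **Descriptions** embed a disclosed age through exactly one of the three
  disclosure patterns ("I am X years old", "Born in X", "X years old"); all
  other phrase pools are digit-free, so `extract_age()` round-trips 100% of
  planted ages and never fires on non-disclosing users.
* **Reply networks**: each user gets an independent ego neighborhood of
  off-cohort partner accounts — `k1` partners, each with Poisson `k2`
  partners of their own, partner–partner edges with probability `tri`, and
  60% reciprocation. Expected two-hop size is `k1(1+k2)`: 12·7 = 84
  (depressed) vs 14·11 = 154 (control), the reported class means. Only those
  means are printed; the within-class spread is a design choice, and an
  important one: with every user drawn at the exact class parameters, each
  network metric alone separated the classes almost perfectly, contradicting
  the reported ordering in which no single modality approaches the fused
  model. Per-user overdispersion (unit-mean gamma multipliers with cv 0.5 on
  `k1` and `k2`, a beta draw around `tri`) restores a realistic
  unimodal-below-multimodal profile while leaving the class means intact.
  The interconnection probabilities themselves (0.25 vs 0.18) encode the
  reported tendency of depressed users toward smaller, denser, more
  clustered ego nets. A cohort with fewer than two users exports an empty
  edge list.

**Determinism.** Every sub-generator (core indicators, text, faces, network,
each image) draws from its own stream derived from the master seed, so a
fixed configuration reproduces the cohort — and `write_cohort()`'s JSONL,
TSV and PNG output — byte for byte. One stream per *sub-generator*, never
per user: freshly seeded Mersenne–Twister streams with related seeds have
correlated opening draws, which measurably biased disclosure rates and
conditional age medians in an earlier per-user-stream design. `with_seed()`
additionally discards each stream's first 32 draws.

**What passing tests do not show.** The generator plants exactly the
structure the pipeline measures — real language, real photographs, topic
drift, network homophily between cohort members, and annotation noise are
all absent. Green tests certify that the operators compute what they claim
and that the pipeline recovers known structure; they say nothing about
classification performance on real populations, and the package deliberately
does not claim the headline accuracy reported on private data.

## 2. Image features

Images are `h×w×3` arrays in [0,1]; alpha is dropped, grayscale broadcast.
All statistics except sharpness are pixel-permutation invariant.

* **Colorfulness** is the opponent-channel metric on the 0–255 scale:
  `rg = R−G`, `yb = ½(R+G)−B`,
  `sqrt(σ²_rg + σ²_yb) + 0.3·sqrt(μ²_rg + μ²_yb)`. Standard deviations use
  the population divisor so a single pixel is defined (a uniform gray image
  scores exactly 0).
* **Naturalness** is a memory-color index: pixels with Rec.601 luminance in
  [20, 80] on the 0–100 scale and saturation > 0.1 are classified by hue
  into skin [20°,70°), grass [70°,170°) and sky [170°,260°) bands; a band
  with mean saturation `S̄` scores `exp(−½((S̄−μ)/σ)²)` against its
  prototype (skin 0.55/0.19, grass 0.44/0.16, sky 0.43/0.15), and the index
  is the classified-pixel-weighted average, 0 when nothing qualifies. The
  cited construction does not publish its constants; these prototypes are
  this package's documented parameterization, centered on commonly used
  memory-color saturations, and `cni_bands()` exposes them.
* **HSV moments**: hue is angular, so its mean is circular (radians) and its
  variance is `1 − R̄` (one minus the mean resultant length); saturation
  moments are linear. Gray pixels carry hue 0, a documented simplification.
* **Brightness/grayscale mean** are the Rec.601 luminance mean (two table
  names, one quantity), **contrast** its standard deviation.
* **Sharpness** is the variance of the 3×3 Laplacian of luminance — the only
  spatial feature; images smaller than 3×3 score 0.

User-level aggregation averages shared-image features arithmetically and
keeps the profile image as its own block; an absent modality stays `NA` with
a missingness flag — absence is never coded as zero.

## 3. The image synthesizer

`synthesize_image()` must emit pictures whose *measured* features match
requested targets, so it composes pixel populations whose knobs decouple:

1. a sky-band population at the hue-appropriate luminance, whose saturation
   is solved in closed form so the band score equals the naturalness target
   (of the two algebraic roots the higher-saturation one is taken — it needs
   the smallest pixel budget);
2. a high-chroma quartet — yellow/blue spanning the `yb` axis at luminances
   outside the qualifying range, orange/magenta spanning `rg` on hues
   outside every band — which carries opponent-channel energy without
   touching naturalness; its size is found by binary search until measured
   colorfulness meets the target;
3. near-gray filler whose value is solved linearly for the gray-level target
   (luminance or average-RGB, whichever the context specifies), with
   population fractions chosen so the saturation mean is exact.

Infeasible combinations (e.g. colorfulness above the ceiling a saturation
budget allows) fail with the violated bound named. With `jitter = TRUE` each
draw perturbs the targets (4% relative; 0.02 absolute on naturalness, with
the colorfulness multiplier clamped to ±8% and saturated at the feasibility
boundary), emulating a population whose *mean* recovers the targets — the
calibration tests measure exactly that. Calibrated quantities are
colorfulness, naturalness, saturation mean and the gray-level; hue/saturation
variance and channel means are emergent and recorded, not steered. Default
size is 32×32: the features are resolution-invariant population statistics,
so small canvases trade nothing but Laplacian texture. PNG writing quantizes
to 8 bits (≤ 1/255 per channel on re-read).

## 4. Text and demographics

Tokenization lowercases, preserves common emoticons as verbatim tokens, and
splits on non-alphanumerics. Category rates are percentages of tokens
matching an open category lexicon (plus `sixltr`, the share of tokens longer
than six letters). Closed commercial dictionaries cannot be shipped; the
bundled lexicon is a small open stand-in with the familiar categories
(self-references, articles, positive/negative emotion, swear, netspeak,
cognitive, work, money, body, sexual, family). Proprietary summary
composites (analytic thinking, clout, authenticity, tone) have unpublished
formulas and are accepted only as precomputed optional columns.

The demographic score is the weighted-lexicon relative frequency
`Σ_term w(term)·freq(term, doc)/WC(doc) + intercept` — invariant to document
duplication and linear in the weights. The bundled age lexicon is built so
the score is an unbiased age estimate under the generator's word model:
with age-pool probabilities varying linearly in age, weights ±90.9 on the
old/young pools and intercept 35.5 make the expected score equal the latent
age; finite documents add ~6 years of noise, comparable to the moderate
accuracies such lexica achieve in practice. The gender lexicon scores
positive = female (its source convention); tweets and description are
concatenated before scoring, with a flag to exclude the description.

Age extraction applies the three disclosure patterns in order; a 4-digit
number in [1900, year−11] is a birth year; extracted ages outside [11, 60]
are rejected as implausible, and absence is a value, not an error. Age
groups use the left-closed adult-development bins [11,19), [19,23), [23,34),
[34,46), [46,60) — the table-header convention is adopted where the
accompanying prose's "(14,19]" conflicts with it. Screen-name similarity is
the minimum Levenshtein distance to a depression-term lexicon, normalized by
the longer string, after stripping digits and underscores.

## 5. Ego-network metrics

The cited metric names come without formulas, so the definitions in
`ego_metrics()` are authoritative for this package and are verified against
an independent adjacency-matrix recomputation: reciprocity (fraction of
reply partners with exchanges both ways), prestige ratio (replies received /
max(1, replies sent)), density of the undirected two-hop graph, the ego's
local clustering coefficient, embeddedness (mean Jaccard overlap
|N(u)∩N(v)|/|N(u)∪N(v)| over neighbors v, neighborhoods taken within the
ego graph as stated), components of the ego graph with the ego removed, and
two-hop size (node count minus one). Singletons return all-zero metrics with
a degeneracy flag.

## 6. Selection and the boosted model

`boruta_select()` re-permutes one shadow copy of every column per iteration,
fits a random forest (impurity importance via `ranger`; any importance
oracle can be substituted), counts a hit when a real feature out-ranks the
best shadow, and decides per feature with an *exact* two-sided
Binomial(n, ½) test — confirmed above half, rejected below, tentative
otherwise. The printed null in the source algorithm is a garbled normal
approximation to exactly this binomial, so the exact test is used. At least
20 iterations are required for the test to have any resolution. Under a
global null the probability a noise feature beats the best of `p` shadows is
about 1/(p+1) per iteration, so false confirmations are far rarer than the
nominal level; the test suite verifies the type-I bound over 200 null
simulations.

`fit_booster()` implements the second-order boosting objective directly:
logistic loss, `g = p−y`, `h = p(1−p)`, leaf weight `−G/(H+λ)` (optionally
L1-soft-thresholded), exact greedy splits on the structure-score gain with a
`γ` per-leaf penalty, `η`-shrunk leaves, and the class-prior log-odds as
base score. Defaults — η 0.1, depth 3, 100 rounds, λ 1, γ 0 — are the
package's documented choices; the source reports none. Equal-gain ties break
to the lowest feature index, then the lowest threshold, so builds are
bit-reproducible. Candidate thresholds are midpoints between consecutive
distinct values; splits need strictly positive gain.

Explanations use deterministic path attribution rather than sampled Shapley
values: every node carries the same regularized estimate a leaf would get,
and the change at each traversed split is credited to the split feature.
The method is exact (base + Σ deltas ≡ predicted log-odds, tested at 1e-9),
RNG-free, and O(depth) per tree; its known bias — credit assigned along the
taken path only — is acceptable for a screening tool where auditability
matters more than game-theoretic symmetry.

## 7. Evaluation layer

The finite-population sample-size formula `n = n0/(1 + n0/N)` with
`n0 = z²p(1−p)/e²` is exposed with the unrounded value and its ceiling (at
N = 8770, 95%/5% it gives 368.04 → 369). Cohen's kappa, the uncorrected
chi-square with Pearson residuals (their squares sum to the statistic), and
per-feature group contrasts — pooled-variance t by default (Welch behind a
flag), one-way ANOVA F, stars at 0.05 and at the Bonferroni level 0.05/m
with m defaulting to the study-wide 223 features — make up the classical
layer. The emotion-correlation screen masks pairs not significant at
p < 0.05 or undefined on constant columns.

`cross_validate()` is stratified k-fold (default 10) with everything that
learns — fusion standardization and imputation, optional per-fold Boruta,
the booster — fitted inside the training fold only; F1 takes depressed as
the positive class. The fold assignment is seeded and reproducible, and k
must not exceed the minority class count.

## 8. Degenerate inputs and numerical choices

Empty face lists, missing modality blocks, all-faceless cohorts, singleton
ego graphs, empty token lists, constant columns in correlation screens, and
zero-variance groups all return flagged missing/zero results rather than
errors; genuinely contradictory requests (rates outside [0,1], infeasible
image targets, chance agreement of 1, zero expected cell counts) raise
errors naming the violated condition. Standardization guards zero-variance
columns with unit scale. All chi-square statistics are uncorrected
(no continuity correction), matching the worked 2×2 examples.

## 9. Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to keep the full run in a
few minutes while leaving sampling tolerances meaningful: calibration
recovery on a 700/800-user cohort (rates checked at three binomial standard
errors, count means at three standard errors under cv 1), the acceptance
cohort at 1,200/1,400 with a 2,600-user default-scale run reserved for the
acceptance script, 1,000 images per calibration target, 200 null simulations
for the selector's type-I bound, and brute-force oracle comparisons on 8×8
images and ≤12-node graphs. The end-to-end modality comparison uses 150
users per class, 5 folds and 40 rounds.

## 10. Known limitations

* Templated text has no syntax, topics or sarcasm; lexicon features are
  therefore cleaner than on real tweets.
* Synthetic images are population-statistic compositions, not photographs;
  spatial features (sharpness) carry no class signal.
* Ego networks are disjoint star-of-stars constructions — no homophily
  between cohort members, no global community structure.
* The gender lexicon's sign convention and the CNI prototypes are documented
  choices, not community standards.
* Face detection is out of scope by design: the detector interface accepts
  any per-image emotion annotations, and the generator supplies them.
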