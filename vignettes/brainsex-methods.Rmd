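---
title: "Modelling the brain-sex continuum across adolescence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the brain-sex continuum across adolescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural sex differences in the adolescent brain grow with age and pubertal
maturation, and they do so region-specifically: limbic structures — dense in
gonadal-hormone receptors — are a prime candidate for carrying
puberty-related change. A multivariate way to quantify "how female-like or
male-like" a brain looks is to train a classifier of sex assigned at birth on
regional volumes and read its class probability, `P(female)`, as a position
on a male-to-female continuum. Changes of that continuum can then be related
to age, Pubertal Development Scale (PDS) scores, menarche onset, and mental
health, separately per sex and per feature set (limbic / non-limbic / whole
brain).

`brainsex` implements that full analysis pipeline plus a synthetic-cohort
generator with known ground truth, so that every stage — harmonization,
quality control, matching, residualization, classification, mixed-model
inference — is testable without restricted cohort data.

## The generative model

For feature $j$, subject $i$, session $s$:

$$\mathrm{vol}_{ijs} = \mu_j + \sigma_j z_{ijs} + b_j(\mathrm{eTIV}_i - \overline{\mathrm{eTIV}})$$
$$z_{ijs} = s_j\left[d_{c(j)}\,\mathbb{1}(F) + \beta_{\mathrm{sex}}\,\mathrm{age}_{is}
 + \pi_j \delta_{\mathrm{sex}} (\mathrm{stage}_{is} - \tfrac12) + \kappa_j\,\mathbb{1}(\text{post-menarche})\right]
 + \gamma_{kj} + \lambda_{kj}(u_i + \varepsilon_{ijs})$$

where $s_j \in \{-1, +1\}$ is the feature's female-typical direction,
$d_{c(j)}$ the class-specific sex effect, $\mathrm{stage}_{is} =
\mathrm{logit}^{-1}((\mathrm{age} - \mathrm{onset}_i)/\tau)$ the latent
pubertal stage, $\gamma_{kj}, \lambda_{kj}$ additive/multiplicative site
effects, and $u_i$ a subject random intercept. Latent puberty enters the
features *directly*, not only through age: onset ages are jittered per
subject (SD 12 months), so PDS carries variance beyond age — without this the
type-II ANOVA recovery tests would be vacuous.

### Parameter defaults and why

| parameter | default | rationale |
|---|---|---|
| eTIV male/female ratio | 1.10 | middle of the commonly reported 8–15% male head-size advantage |
| female onset shift | 18 months earlier | girls enter puberty 1–2 years before boys |
| sessions | 2, ~24 months apart | two-wave longitudinal designs of the validation cohorts emulated |
| sex effect (SD units) | limbic 0.5, non-limbic 0.25 | see below |
| age drift (SD/yr) | F 0.05, M 0.02 | sex gap grows with age, faster in girls |
| puberty effect | 0.3, limbic features only | the region-specific hypothesis under test |
| menarche threshold | latent stage 0.8 (≈ onset + 21 months, ~12.75 y) | menarche is a late-pubertal milestone, median ~12.5–12.8 years; this placement also reproduces the roughly balanced pre/post-menarche group sizes of two-wave adolescent cohorts |
| site effects | shift SD 0.3, scale 0.9–1.1 | moderate multi-site batch structure |
| subject RE SD / noise SD | 0.5 / 1 | within-subject stability typical of volumetry |

The sex-effect defaults were fixed once from closed-form arithmetic, not
tuned against tests. With $p$ independent features each shifted by $d$
residual SDs, the optimal AUC is $\Phi(d\sqrt{p}/\sqrt{2}\,\sigma_w)$ with
within-class SD $\sigma_w \approx 1.1$. At $p=20$ limbic features and
$d=0.5$ this gives $\approx 0.84$; non-limbic $p=40$, $d=0.25$ gives
$\approx 0.77$ — the training-sample regime reported for adolescent
morphometry. In an *unmatched* validation cohort, pooled eTIV
residualization absorbs the fraction of the sex effect collinear with head
size (about 40–50% at ratio 1.10), which lands external validation near
0.65–0.75, again matching the regime the method is known for. This
attenuation is not a bug: it is precisely why the training sample is matched
on eTIV before residualization.

One deliberate departure from a naive "everything from one seed" design: the
per-feature anatomy (baseline volume $\mu_j$, eTIV slope $b_j$, direction
$s_j$) is drawn from a separate `feature_seed`, constant by default across
cohorts. Real cohorts share their anatomy; without this, a model trained on
one simulated cohort cannot transfer to another, and the external-validation
stage of the pipeline would be meaningless.

### What the generator does *not* emulate

Spatial covariance between neighboring regions (features are conditionally
independent given the shared subject intercept), non-linear age
trajectories, hormone levels, twin/family covariance (a `family_id` is
generated but never modelled, as kinship deliberately stays out of the
association models), scanner software
differences beyond location/scale, and item content of real questionnaires.
A green test therefore establishes that the *procedures* behave correctly
under the stated statistical structure — not that effect sizes in any real
cohort match the defaults.

## Harmonization

Parametric ComBat: features are standardized against a joint site + covariate
model, per-(site, feature) location/scale parameters are shrunk by empirical
Bayes (normal prior for locations, inverse-gamma for scales, solved by the
standard iterative conditional scheme to 1e-8), and the data are
back-transformed with covariate effects restored. `eb = FALSE` disables
shrinkage (useful when sites are few and features many, and for closed-form
verification).

The longitudinal variant absorbs a subject intercept — the subject's mean
deviation from its *site's* mean of covariate-adjusted residuals — before
estimating site parameters, and restores it afterwards. Two numerical
subtleties matter: the intercept must be a deviation from the site mean (a
deviation from the grand mean would absorb and then restore the site shifts
being removed), and the standardization variance must be computed *after*
centering (otherwise the scale step re-inflates centered residuals to full
variance and the restored intercepts double-count subject variance). Random
slopes are deliberately out of scope; the subject-intercept-only contract is
validated by the null-calibration acceptance test.

## QC, matching, residualization

Quality control removes observations with surface Euler numbers more than 3
SD *below* the cohort mean (one-sided; unusually good reconstructions stay).
Matching then pairs each female with one male under three calipers — age
within 12 months, harmonized eTIV within 3% (relative to the reference
subject's eTIV), Euler number within 1 cohort-SD — greedily in ascending
subject-id order, choosing the admissible candidate with the smallest eTIV
difference. Greedy matching is order-dependent; the deterministic id order
makes runs reproducible, and a seeded random order is available for
sensitivity analysis. The reference-sex swap (`reference_sex = "M"`) bounds
the asymmetry of the relative-difference denominator. eTIV is afterwards
regressed out of every feature (OLS per feature, refit within each cohort;
a coefficient-transfer mode exists for sensitivity checks — refit is the
default because harmonization is also per-cohort and scanner scale
differences would otherwise leak through the transferred slopes).

## Classification

A second-order gradient-boosted tree ensemble (logistic loss, exact greedy
splits, leaf regularization $\lambda = 1$, depth 3) with learning rate
$\eta = 0.01$ and an exploration budget of 1000 rounds. Nested 5-fold CV:
inner folds (within each outer training split) track validation log-loss per
iteration; the iteration minimizing the mean inner curve becomes the fold's
round count; the outer loop yields out-of-fold probabilities and the CV AUC;
the final model is refit on everything for the median of the per-fold
optima. Folds are stratified so both classes appear in every fold at small
n. Rows are scored independently — longitudinal sessions are never pooled at
prediction time. AUC is computed as the Mann–Whitney concordance with ties
counting one half. Feature contributions are normalized total split gains.

## Mixed-model association batteries

Four model families on `p_female`, always within one sex (effect directions
are opposite between sexes, and pooling would mostly re-discover the
classifier itself — the fit function refuses pooled sexes):

* age: `p_female ~ age_months + session + euler [+ site] + age_months:session`
* PDS: `p_female ~ pds_average + age_months + euler [+ site] + pds_average:age_months` (no session term: PDS grows with age regardless of wave)
* menarche: `p_female ~ menarche_onset + age_months + session + euler [+ site] + menarche_onset:age_months + menarche_onset:session`, on the two groups No/No ("no_no") and No/Yes ("onset")
* mental health: `p_female ~ mh_score + age_months + session + euler [+ site] + mh_score:age_months + mh_score:session`

plus the cross-sectional training-cohort model
`p_female ~ age_months + euler + site` (no random term), fit on the
out-of-fold probabilities. All longitudinal models carry a per-subject
random intercept and are estimated by maximum likelihood (so sequential
comparisons across nested fixed-effect sets are coherent). Sites
contributing fewer than 20 observations to a stratum are dropped before
site enters a model; if one site remains, the term is omitted.

Sequential (type I) tests follow the formula order above. Marginal (type II)
tests are built by reordering: each term is placed last among the terms that
do not contain it, interactions are tested last, and the sequential F of the
reordered fit is read off — the textbook type II construction, inheriting
the containment denominator degrees of freedom of the mixed-model engine.
(The engine's own "marginal" ANOVA is type III and is not used.)

Multiple comparisons: no single correction procedure is canonical for this
design; Benjamini–Hochberg at 5% is applied within one analysis x sex x
cohort x ANOVA-type family, across feature sets and terms. The family
definition is a documented assumption and is configurable.

## Mental-health score

PCA on standardized questionnaire items at baseline (correlation PCA — the
pooled instruments use different response scales; covariance PCA would let
wide-scaled items dominate). PC1's sign is indeterminate; it is oriented so
the loading sum is positive, which for a one-factor battery makes the score
correlate positively with every item. Follow-up scores are projections onto
the *baseline* loadings after standardizing with the *baseline* moments —
never refit — so the score means the same thing at both waves. Missing items
are handled listwise at fit and projection, with logged counts.

In the synthetic world, the latent distress factor behind the items couples
(in females, at the configured correlation) to the **limbic class
probability itself** — the generator's documented proxy input — rather than
to the hidden anatomical signature. That is the phenomenon under study
("distress tracks the limbic brain-sex readout"), and coupling to the
latent signature instead would silently attenuate every downstream
mental-health effect by the classifier's imperfect readout correlation.

## Numerical choices and degenerate inputs

* Euler SD of the matching caliper is computed on the full input cohort; all-identical Euler values (SD 0) disable that caliper rather than dividing by zero.
* A single-site cohort yields an identity harmonization model with a warning, not an error; applying a model twice warns (harmonization is not idempotent).
* Zero-variance eTIV or zero-variance questionnaire items are errors naming the offender.
* Matching ties (equal eTIV differences) break by ascending candidate id.
* The LME optimizer chain is nlminb, then optim, then a tolerant fit with a warning — small synthetic strata occasionally defeat one optimizer.
* All significance machinery uses F statistics; for single-df terms these are the squared t statistics.

## Known limitations

Greedy matching is not globally optimal (optimal assignment is a non-goal);
probabilities are not calibrated (AUC and F tests are rank/variance based);
the type-I error of containment-df F tests at exactly two sessions per
subject is approximate, which is why the acceptance suite includes an
explicit null-calibration criterion; and the 160/333/493 registry ships with
placeholder names, since the anatomical list belongs to the segmentation
atlases.
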