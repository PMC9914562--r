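---
title: "Chained PLS-DA / PLS authentication of extra virgin olive oil: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chained PLS-DA / PLS authentication of extra virgin olive oil: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliveauth)
```

## The problem

Extra virgin olive oil (EVOO) commands a price several times that of common
seed oils, which makes dilution with safflower, corn, soybean, canola,
sunflower or sesame oil a profitable fraud. A control laboratory receiving a
suspect bottle faces two questions in sequence: *is the oil adulterated, and
if so with what?* — a classification problem — and *at what level?* — a
regression problem. `oliveauth` implements this two-stage decision chain for
rapid spectral measurements (NIR hyperspectral imaging, FTIR, Raman, UV-Vis)
and GC-MS fatty-acid profiles, together with a synthetic-data module that
generates the full measurement campaign in silico so that every statistical
property of the chain can be exercised and tested at desk scale.

## Study design

The emulated campaign blends one EVOO with each of six adulterant oils at
mass fractions 1, 2, 4, 8, 12, 16 and 20 % (plus the pure oils), giving
13 EVOO samples, 6 pure adulterants and 42 blends — 61 samples measured in
triplicate, 183 cases. Classes are defined at the *adulterant* level, not
the level of adulteration: all blends of one oil share the class
"EVOO+oil", because the concentration of an unknown sample submitted for
authentication cannot be known in advance. That yields 13 classes.

```{r design}
design <- build_design()
design
table(design$class_label)[1:4]
```

## The models

Both stages use bilinear latent-variable models fitted by NIPALS with
mean-centering of both blocks (no variance scaling of the spectra by
default). For centered $X$ ($n \times p$) and response block $Y$, each
latent variable extracts a weight vector $w_a$, scores $t_a = X_{a-1}
w_a$, X-loadings $p_a$ and Y-loadings $c_a$, deflating both blocks before
the next component. Predictions use the projection $R = W (P^\top W)^{-1}$,
so that $\hat Y = \bar Y + X_c R_{1:A} C_{1:A}^\top$. With as many latent
variables as the rank of $X_c$ the fit coincides with least squares — the
package's test suite uses `lm` as the independent oracle for exactly this
identity. The inner NIPALS loop converges to $10^{-10}$ on the score
vector within at most 500 iterations and is initialized deterministically
from the $Y$ column of largest variance, so fits are reproducible without
any seed.

PLS-DA one-hot encodes the 13 class labels and fits the same PLS2 model;
a case is assigned to the class with the largest predicted indicator, ties
broken toward the lowest class index. The argmax rule (rather than a 0.5
threshold) is forced by the multi-class design, which needs a single
winner.

## Validation scheme and the one-SE rule

Model complexity (the latent-variable count) is chosen from held-out
performance only. The data are partitioned into 10 random folds **at the
sample level** — the three replicates of a sample always travel together,
otherwise replicate leakage would flatter every model — and the partition
is redrawn 10 times. Within each repetition every fold is the test set
once; the held-out fold is never used to fit anything.

For each candidate latent-variable count the per-repetition performance
(percent correct classification, or RMSEP in mass-%) is averaged and its
standard error across the 10 repetition means computed. The final model is
the *smallest* latent-variable count whose mean performance is within one
standard error of the absolute best model's mean: for classification,
$\overline{CC}_a + SE_a > \overline{CC}_{a^*}$; for regression,
$\overline{RMSEP}_a - SE_a < \overline{RMSEP}_{a^*}$. Two readings of
"one standard error" are possible — the candidate's own SE or the best
model's — the package defaults to the candidate's own (the literal reading
of the inequality) and exposes the alternative behind
`chain_config(se_from = "best")`.

## The chain and error propagation

A 13-class PLS-DA routes each held-out case to a concentration model:
cases predicted "EVOO+j" (or as pure adulterant j) are quantified by the
PLS regression trained on the EVOO+j blends, cases predicted pure EVOO
receive concentration 0, and an *overall* model quantifies adulteration
regardless of type. Because routing uses the predicted class, a
misclassified case is quantified by the wrong model — the package reports
this *PLS-DA-dependent* mode alongside a *known-identity* mode in which
routing uses the true class, isolating the regressions' intrinsic
performance. Per-adulterant training pools include the pure-EVOO cases at
0 % (the calibration range is 0–20 % and the fitted lines should pass near
the origin); pure adulterant samples (100 %) are classified but excluded
from the quantification pools, which would otherwise be dominated by
far-out-of-range cases.

Metrics for both modes are grouped by the **true** blend type, so the
dependent-mode row for "EVOO+sunflower" answers: *how well is sunflower
adulteration quantified when classification errors are allowed to
propagate?* Selection of each regression model's latent variables happens
within the matching pool (cases routed to the model in dependent mode; the
true blends in known-identity mode), which is why the two modes can settle
on different complexities. Reported diagnostics are RMSEP, $R^2 = 1 -
SSE/SST$ on pooled held-out predictions, the residual predictive deviation
$RPD = sd(\text{measured})/RMSEP$ (sample SD; below 2 insufficient,
2–2.5 approximate, 2.5–3 good, above 3 excellent), and the least-squares
line of predicted on measured. Optional training-set cross-validation
metrics (RMSECV, $R^2_{cv}$) come from an inner 5-fold sample-level CV of
each training pool (`compute_cv = TRUE`); the source study does not state
how its training-set CV was computed, so this choice is the package's own.

```{r chain, eval = FALSE}
ds <- simulate_dataset(design, "HSI_NIR", seed = 42)
report <- run_chain(ds, design, chain_config(seed = 42))
report          # classification and regression summaries
plot(report)    # predicted vs measured, overall model
```

## What the simulator emulates — and what it does not

Each oil's noiseless *endmember* spectrum is a sum of Gaussian bands at
the characteristic positions of edible-oil spectra (e.g. Raman bands at
868–1750 cm⁻¹ including the C=C stretch at 1650 cm⁻¹; NIR absorption at
1156–1580 nm; the conjugated-diene UV band at 232 nm). A band's intensity
is a fixed linear form in the oil's reference fatty-acid composition — so
EVOO, rich in oleic acid, dominates the MUFA-linked bands while the seed
oils dominate the linoleic/linolenic-linked ones, and the GC-MS modality
is automatically consistent with the spectral ones. Two further features
reflect what actually distinguishes real oils: a pigment component
(carotenoids/chlorophyll) that gives unrefined EVOO its visible-range
bands, and one minor-constituent fingerprint band per oil plus a small
composition-dependent band-center shift. Fatty acids alone leave canola
almost collinear with EVOO; on such data no method could recover
concentration at realistic noise, which would contradict the clean
separations the real instruments achieve (fatty-acid GC-MS is indeed the
weakest modality in practice). Fingerprint contrasts were fixed once, from
the requirement that the exact-recovery noise floor of the overall HSI
model sit near 0.7 mass-%, and not revisited.

Mixtures are exactly linear in mass fraction:
`(1-f) * evoo + f * adulterant`. Measurement error is i.i.d. additive
Gaussian noise (default `noise_sd = 0.01`, i.e. 1 % of the unit-scale peak
amplitude) plus a random quadratic baseline per case (`drift_sd = 0.01`).
Replicates are independent noise realizations of the same sample. The
simulator does **not** emulate: non-linear detector response, scattering,
heteroscedastic or correlated noise, inter-lot variability of the 13 EVOO
samples (they are exchangeable and identical in the noiseless limit), or
chromatographic artifacts. Passing tests on these data therefore
demonstrate the statistical machinery — partitioning, selection,
propagation, metrics — not field performance on real spectra.

## Numerical choices and degenerate inputs

* **Preprocessing order** is fixed: asymmetric least-squares baseline
  correction (Eilers-style; smoothness `lambda = 1e5`, asymmetry
  `p = 0.01`, on the grid-index scale) then standard normal variate per
  spectrum. Both are per-case operations, so applying them once to the
  whole dataset leaks nothing across folds. GC-MS profiles are normalized
  but not baseline-corrected (they have no baseline to drift). The source
  study names neither algorithm; SNV and ALS are the field-standard
  defaults a reader would assume.
* **Reflectance calibration** is `(I - B) / (W - B)` and refuses any voxel
  where the white and black references coincide.
* **Rank exhaustion**: when NIPALS runs out of usable variance before the
  requested latent-variable count (routine on noiseless, low-rank data)
  extraction stops, the deepest available model is carried forward for the
  remaining candidate counts, and the event is tallied on the report. A
  training pool whose response has no variance (every blend of an
  adulterant in the test fold) predicts its training mean.
* **Missing classes in training**: with 10 folds, a pure-adulterant sample
  (n = 1 per class) is absent from training whenever its fold is held
  out; the classifier then simply cannot predict that class, and the event
  is counted on the report rather than raised.
* **Ties** in the PLS-DA argmax go to the lowest class index; `Inf` RPD is
  reported as such when RMSEP is exactly 0.

## Known limitations

Two properties of the idealized linear simulator deserve emphasis.
First, exactly linear noiseless mixtures make concentration *perfectly*
identifiable — the chain recovers it to numerical precision — but they
make low-level **classification** intrinsically hard: all blends of one
oil lie on a straight ray from the EVOO point, and the least-squares
indicator machinery behind PLS-DA places its argmax crossing near 19 %
along each ray, so 1–16 % blends are predicted as pure EVOO regardless of
latent-variable count. (A margin-based classifier could separate these
classes; least-squares indicator regression provably does not.) Real
spectra, with their nonlinearities and richer class structure, do not
share this degeneracy — which is why laboratory studies report near-perfect
binary classification while this simulator cannot. Second, the one-SE rule
deliberately trades a little accuracy for parsimony; on these data it
typically settles 2–4 latent variables below the RMSEP minimum.

The packaged study sizes (183 cases, 10×10 partitions, up to 35 candidate
latent variables; about one minute for a full HSI run) were chosen so a
complete analysis, including repeated-partition selection curves for seven
regression models in two modes, runs comfortably on a laptop.
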