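---
title: "Discriminating Mg(II) from Mn(II) binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating Mg(II) from Mn(II) binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metallosite)
```

## The problem

Mg(II) and Mn(II) are chemically similar divalent cations, and many
two-metal-ion enzymes accept either — but not indifferently: the identity of
the cofactor can change catalytic rate, fidelity and even product spectrum.
Crystal structures resolve *where* a metal sits but often not *which* metal
a site prefers in solution. The premise of this package is that the
preference is written in the site's surroundings: which amino acids crowd
within ~10 Å of the ion, and how they are arranged. Given a corpus of
structures whose bound metal is known, a linear discriminant over simple
compositional and geometric descriptors both predicts the preference of a
new site and, through its weights, explains it.

## The site descriptor

A metal site is a heteroatom of a requested element (MG or MN by default)
together with its residue neighbourhood. A residue belongs to the
neighbourhood when **any of its heavy atoms** lies within the radius
(default 10 Å); its representative distance and point are those of the
closest heavy atom. This is the most inclusive well-defined reading of
"amino acids within a radius", and it is what `find_metal_sites()`
implements; a stricter Cα-only mode (`mode = "calpha"`) is available for
users who prefer backbone-anchored neighbourhoods. Only the twenty standard
amino acids count — waters, nucleotides, and other heteroatoms are never
neighbours, because the descriptor is a protein-composition summary.

The descriptor has 25 entries, in a fixed, versioned order
(`feature_names()`, schema `metallosite-25/1`):

1. **Positions 1–20** — counts of the standard amino acids, alphabetical by
   three-letter code. Counts are raw, not normalised by neighbourhood size:
   the discriminant's interpretation ("His is more likely near Mn-like
   sites") is about presence, and normalisation would entangle composition
   with shell density.
2. **Positions 21–25** — geometric descriptors: residue count, mean and
   minimum residue-to-metal distance, and mean and maximum pairwise
   distance between residue representative points (Å).

Two of the geometric descriptors — the average distance to the site and the
average pairwise residue distance — are the canonical shape summaries of a
coordination shell; the remaining three (count, minimum distance, maximum
pairwise distance) are simple completions chosen for interpretability, and
the schema is deliberately pluggable: every downstream routine consumes
whatever feature columns it is handed, so a user with a different attribute
table can substitute it wholesale. Distance-type averages are taken over
*residues* (one representative atom each), not over all atoms; the
alternative atom-level averaging weights large residues more and answers a
different question. An empty neighbourhood yields the all-zero vector by
convention rather than NA, keeping batch matrices rectangular.

## The discriminant

With class means $\mu_1, \mu_2$ and scatter matrices
$S_c = \sum_j (x_j - \mu_c)(x_j - \mu_c)^T$, the within-class scatter is
$S_P = S_1 + S_2$ and the between-class scatter is
$S_B = (\mu_1 - \mu_2)(\mu_1 - \mu_2)^T$. The Fisher score

$$J(w) = \frac{w^T S_B w}{w^T S_P w}$$

is maximised in closed form by $w^* = S_P^{-1}(\mu_1 - \mu_2)$, which
`fit_lda()` computes directly — no iterative optimisation, no reliance on a
black-box LDA routine. The test suite holds this solve to three independent
standards: it must beat thousands of random directions, agree with a
gradient-ascent maximiser of $J$ itself, and be parallel to the direction
found by a reference implementation (`MASS::lda`).

Conventions that the literature usually leaves implicit are fixed as
follows:

* **Normalisation and sign.** $w^*$ is stored with unit Euclidean norm,
  oriented so the second listed class (Mn-like by default) has the larger
  mean projection. Histograms of projections then read left = Mg-like,
  right = Mn-like, always.
* **Threshold.** Classification by "nearer projected class centre" is
  exactly the rule $\langle w^*, b\rangle \le \tau$ with
  $\tau = \langle w^*, (\mu_1 + \mu_2)/2\rangle$; the midpoint is stored
  explicitly so single sites can be called without the training data.
* **Posteriors.** The text-book monotone calibration consistent with a
  shared within-class spread: equal-prior Gaussian class-conditionals on
  the projection axis with class-specific means and pooled variance. This
  reduces to a logistic in the projection,
  $p(\text{class 2}\mid b) = \sigma\!\big(\Delta(\langle w^*,b\rangle -
  \tau)/s^2\big)$ with $\Delta$ the projected mean separation and $s$ the
  pooled projected SD, which is how it is computed (numerically stable for
  extreme projections). A logistic-regression calibration would be the
  natural alternative; it needs its own fit and adds nothing monotonicity
  does not already give.
* **Dual calls.** Sites whose posterior falls within 0.05 of 1/2 are
  reported with the dual label `MG/MN` (band configurable via `ambiguity`),
  because a posterior of 0.53 is not a finding; with `ambiguity = 0` an
  exact tie is labelled `ambiguous`.
* **Ridge.** $S_P$ from a small or collinear corpus can be singular, so the
  solve uses $S_P + \epsilon I$ with
  $\epsilon = 10^{-8}\,\mathrm{tr}(S_P)/p$ by default — about eight orders
  of magnitude below the average eigenvalue, negligible for well-posed
  problems, decisive for degenerate ones. The value used is recorded in the
  fitted model; `ridge = FALSE` turns the fallback off, making singularity
  an error that reports the reciprocal condition estimate.
* **Standardisation.** Off by default for classification — the discriminant
  is affine-equivariant, so scaling changes nothing about the decisions.
  For *interpretation* it matters: raw weights of features on different
  scales are not comparable, so `lda_importance()` reports weights on the
  standardised scale (weight × training SD) by default, flagging entries
  below 5% of the largest as neutral.

Validation is leave-one-out: `loo_lda()` refits without each sample and
predicts it, reporting the confusion matrix (predictions in rows, truth in
columns) and per-class accuracies. Each fold is computed by a rank-one
downdate of the per-class crossproduct matrices rather than a full
recompute, so the sweep over $n$ samples costs $n$ solves of a
$p \times p$ system; a fold whose reduced training set is degenerate marks
that one sample unpredictable and is excluded from the counts with a
warning. LOO predictions are invariant to sample order by construction, and
the tests assert it.

## Kinetic models

Three rate laws cover diribonucleotide-synthesis time courses:

| model | equation | parameters |
|---|---|---|
| linear | $y = k_{cat}t$ | $k_{cat}$ (s⁻¹) |
| burst | $y = A(1 - e^{-k_{burst}t}) + k_{cat}t$ | $A$ (product/enzyme), $k_{burst}$, $k_{cat}$ (s⁻¹) |
| single-exponential | $y = A(1 - e^{-k_{obs}t})$ | $A$ (fraction), $k_{obs}$ (s⁻¹) |

The single-turnover exponential carries a free amplitude $A$ even though it
is sometimes written with amplitude fixed at 1: real converted fractions
plateau below unity, and fixing the plateau biases $k_{obs}$. Fitting is
ordinary unweighted least squares — `lm()` through the origin for the linear
law, Levenberg–Marquardt (`minpack.lm::nlsLM`) with rates bounded below by
zero for the nonlinear laws; Levenberg–Marquardt in particular handles the
zero-residual noise-free traces used in round-trip tests, where Gauss–Newton
implementations fail on a singular gradient. Standard errors come from the
local curvature at the optimum; an exact fit reports SE 0. Default starting
values are derived from the data (late-point slope → $k_{cat}$, late-time
intercept → $A$, reciprocal time-to-half-amplitude → rate), so convergence
does not depend on user guesses.

`compare_models()` decides between the nested linear and burst laws the
conservative way: burst wins only if it reduces the residual norm **and**
its amplitude is significant ($A > 2\,SE_A$). Judging by residuals alone
would always favour the richer model. This criterion is a pragmatic stand-in
for the by-inspection model choice a kineticist makes per condition.

## What the synthetic data emulates — and what it does not

`generate_site_structures()` emulates the *compositional* signal of a
metal-bound structure corpus: each toy structure is one metal at the origin
plus 8–14 residues (3–5 heavy atoms each, in randomly oriented plausible
local geometry) at uniform random distances between 1.5 Å and the radius,
with residue types drawn from a background distribution — uniform by
default, since no particular background is canonical — reweighted by a
per-class enrichment factor: His ×3 around Mn-like sites and Lys ×3 around
Mg-like sites by default. The defaults define the reference test
conditions; the 3-fold factor plants a signal strong enough to be
recoverable at a few hundred structures per class yet far from separable,
which is the regime a real corpus occupies. Balance between classes is
exact, and generation is bit-reproducible given a seed.

What these structures do **not** have: real backbone connectivity, rotamer
chemistry, coordination geometry, crystallographic artefacts (altlocs,
partial occupancy, symmetry mates), or correlations between neighbouring
residues. Consequently a passing pipeline test demonstrates that the
machinery — parsing, neighbourhood extraction, featurisation, discriminant,
validation — faithfully recovers a planted compositional difference; it
does not certify any particular accuracy on real crystal structures, which
depends on corpus curation (resolution cutoffs, redundancy filtering) that
is deliberately outside this package.

`generate_gaussian_corpus()` is the calibration instrument for the
discriminant itself: balanced samples from two Gaussians with shared
covariance and means $\mp\Delta/2$ along a planted unit direction. With
identity covariance the Bayes-optimal accuracy is exactly
$\Phi(\Delta/2)$, giving a closed-form target the leave-one-out estimate
must approach ($\Delta = 2 \Rightarrow \Phi(1) \approx 0.841$), and the
planted direction is the ground truth the fitted $w^*$ must align with as
$n$ grows.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately modest sizes —
Gaussian corpora of 200–500 samples per class, structure corpora of up to
300 per class, 20 seeded replicates for the optimiser-equivalence check,
80-point kinetics traces over a 3×3×3 burst-parameter grid — sizes at which
every statistical assertion has comfortable margin (binomial SEs of 1–2
percentage points) while a full run completes in a couple of minutes.
Tolerances follow the quantity: hand-computed geometry to 1e-9 Å,
closed-form-vs-numerical Fisher scores to 1e-6 relative, accuracy
calibrations to 3 binomial SEs, noise-free kinetic round trips to three
significant figures.

Degenerate inputs are handled explicitly rather than by accident: coincident
class means are an error (no direction to find); a class with fewer than
two samples cannot form a scatter matrix; zero pooled projected variance
makes posteriors an error; empty neighbourhoods featurise to zero vectors;
structures without metals yield empty site tables, not errors. Altloc
duplicates are resolved to the highest-occupancy conformer (ties to file
order) *before* site detection, so a metal with alternate positions is one
site, not two.

## Known limitations

* PDB fixed-column input only; mmCIF is a natural extension but unsupported.
* Two classes only — the multi-metal generalisation (multi-class LDA) is out
  of scope, as are quadratic discriminants and kernel variants.
* Hydrogens are ignored throughout; no symmetry expansion, so a neighbour
  contributed by a crystallographic symmetry mate is missed.
* Posterior calibration assumes a shared within-class spread on the
  projection axis; strongly heteroscedastic corpora would need the logistic
  alternative.
* Accuracy figures quoted anywhere in this package refer to synthetic
  corpora with known ground truth; performance on a real Mg/Mn corpus is a
  property of that corpus and its curation.
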