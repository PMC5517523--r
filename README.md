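# metallosite

Does a protein active site prefer Mg(II) or Mn(II)? Many DNA-processing
enzymes — primases, polymerases, topoisomerases — catalyse through a pair of
divalent metal cofactors, and substituting Mn(II) for Mg(II) can change both
rate and fidelity. The residue composition and geometry of the shell around a
bound metal carry enough signal to predict that preference. `metallosite` is
an R package for structural bioinformaticians and enzymologists that

* reads PDB coordinate files, locates divalent-metal heteroatoms, and
  describes each site by a 25-dimensional feature vector (counts of the 20
  standard amino acids with any heavy atom within a radius — 10 Å by
  default — plus five descriptors of neighbourhood geometry);
* fits a Fisher linear discriminant to a labelled corpus of such sites,
  from first principles, and interprets it;
* simulates and fits the kinetic rate laws of primase diribonucleotide
  synthesis (steady-state linear, pre-steady-state burst, single-turnover
  exponential);
* generates synthetic structure and feature corpora so the whole pipeline is
  testable without any downloads.

## The statistical core

Given feature vectors in two classes with means μ₁, μ₂, the within-class
scatter matrix is S_P = S₁ + S₂ with
S_c = Σⱼ (xⱼ − μ_c)(xⱼ − μ_c)ᵀ, and the between-class scatter is
S_B = (μ₁ − μ₂)(μ₁ − μ₂)ᵀ. The discriminant direction maximises the Fisher
score

    J(w) = (wᵀ S_B w) / (wᵀ S_P w)

whose maximiser has the closed form **w\* = S_P⁻¹ (μ₁ − μ₂)** (stored with
unit norm, oriented so the Mn-like class projects higher). A site with
feature vector b is classified by its projection ⟨w\*, b⟩ against the
midpoint threshold τ = ⟨w\*, (μ₁+μ₂)/2⟩ — equivalently, by the nearer
projected class centre — and posterior probabilities follow from equal-prior
Gaussian class-conditionals on the projection axis, monotone in
⟨w\*, b⟩ − τ. Validation is leave-one-out: refit without each sample,
predict it, tabulate the confusion matrix. The entries of w\* of largest
absolute value (on the standardised scale) name the features that drive the
separation, their sign naming the favoured class.

Kinetic traces y(t) are fit by least squares to k_cat·t (linear),
A(1 − e^(−k_burst·t)) + k_cat·t (burst) or A(1 − e^(−k_obs·t))
(single-turnover exponential), with model choice requiring both a residual
improvement and a burst amplitude exceeding twice its standard error.

## Worked example

A synthetic corpus of 300 single-metal structures (150 per class) with
3-fold His enrichment around Mn-like sites and Lys around Mg-like sites:

```r
library(metallosite)

atoms    <- generate_site_structures(n_per_class = 150, enrichment = 3, seed = 42)
features <- extract_features(atoms, elements = c("MG", "MN"), radius = 10)
loo_lda(features)
#> Leave-one-out cross-validation (rows = predicted, cols = true)
#>          true
#> predicted  MG  MN
#>        MG 111  45
#>        MN  39 105
#> per-class accuracy:  MG 74.0%, MN 70.0%

fit <- fit_lda(features)
head(lda_importance(fit), 4)
#> # A tibble: 4 × 5
#>   feature                        weight favored_class neutral  rank
#>   <chr>                           <dbl> <chr>         <lgl>   <int>
#> 1 HIS                             0.521 MN            FALSE       1
#> 2 LYS                            -0.520 MG            FALSE       2
#> 3 mean_residue_to_site_distance  -0.422 MG            FALSE       3
#> 4 mean_pairwise_residue_distance  0.323 MN            FALSE       4
```

Roughly 72% of held-out sites are classified correctly — far above the 50%
chance baseline for a balanced corpus — and the discriminant's two largest
weights recover exactly the planted chemistry: histidine favouring Mn(II),
lysine favouring Mg(II). On a biphasic kinetics trace, model comparison
picks the burst law and recovers its constants:

```r
trace <- simulate_trace("burst", list(A = 0.8, k_burst = 20, k_cat = 0.5),
                        times = seq(0.004, 2, length.out = 60),
                        noise_sd = 0.02, seed = 7)
compare_models(trace)$preferred
#> [1] "burst"
tidy(fit_trace(trace, "burst"))
#> # A tibble: 3 × 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 A          0.816   0.00612
#> 2 k_burst   18.0     0.751
#> 3 k_cat      0.490   0.00498
```

Here A ≈ 0.82 products per enzyme form in a fast first turnover
(k_burst ≈ 18 s⁻¹) before the slow steady state (k_cat ≈ 0.49 s⁻¹) — the
signature of a rate-limiting step after chemistry, such as product release.

`autoplot()` methods draw the projection histograms of a fitted or
cross-validated discriminant and the data-plus-curve view of a kinetic fit;
`plot_importance()` charts the ranked discriminant weights.

## Scope notes

Classification of real crystal-structure corpora (e.g. a balanced
Mg/Mn-bound PDB set) is supported as an offline batch over user-supplied
files — `extract_features()` on a directory, then `fit_lda()`/`loo_lda()` —
but the package does not download structures or curate corpora, and
benchmark accuracies on such corpora depend on that curation. mmCIF input,
coordination-geometry assignment and crystal-symmetry expansion are out of
scope.
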