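---
title: "Methods: paired differential genera, diversity inference, and the clinical screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired differential genera, diversity inference, and the clinical screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oromicro)
```

# The setting

Tissue microbiome studies of oral cancer collect several specimen types per
patient — saliva, a tumor-surface swab, outer tumor tissue, inner tumor
tissue, adjacent normal tissue, and sometimes lymph nodes — and profile
them at genus level from 16S amplicon counts. Two features of such data
drive every design choice in this package:

1. **Ultra-low microbial biomass in tissue.** Genus tables from tissue are
   dominated by sampling noise at the rare end: genera observed in only one
   specimen group, or at trace abundance, are as likely to be contamination
   or stochastic sampling as biology.
2. **Patient-dominant community structure.** Specimens from the same
   patient resemble each other far more than specimens of the same type
   from different patients. Unpaired group comparisons therefore mix a
   large patient effect into the specimen-type signal.

The paired caller addresses both at once: it restricts attention to
predominant genera shared by both groups, and it compares specimens only
within a patient, where the patient effect cancels.

# The paired differential rule

Let $p_A(g)$ and $p_B(g)$ be the relative abundances of genus $g$ in a
patient's group-A and group-B specimens (relative abundance = total-sum
scaling; no rarefaction is used anywhere, because the rule is defined on
compositions and rarefaction only adds noise at these depths).

**Predominance filter.** A genus is kept iff its mean relative abundance is
at least `min_mean_abundance` (default 0.001, i.e. 0.1%) in group A *and*
in group B, and it is detected ($>0$) in at least `min_detection_fraction`
(default 0.5) of the samples of *each* group. Genera failing either
condition — rare genera, and genera specific to one group — are reported as
`filtered_out` and never called. The defaults are deliberately
conservative: 0.1% of a 50k-read library is ~50 reads, comfortably above
the contamination floor, and 50% detection in both groups rules out
one-sided artifacts while tolerating genuine dropout.

**Fold changes.** Per matched pair,
$\mathrm{FC} = (p_A(g) + \varepsilon)/(p_B(g) + \varepsilon)$ with a fixed
additive pseudocount $\varepsilon$ = `pseudocount` (default $10^{-5}$, on
the relative-abundance scale). The pseudocount keeps ratios finite when a
kept genus is absent from one specimen without discarding the pair, so pair
counts stay stable; because it is additive and shared, swapping the groups
maps every ratio to its exact reciprocal.

**Call.** With `fold_threshold` $\tau$ (default 2) and
`majority_fraction` $m$ (default 0.5), genus $g$ is `enriched_in_A` iff the
fraction of pairs with $\mathrm{FC} \ge \tau$ is strictly greater than $m$
*and* the fraction with $\mathrm{FC} \le 1/\tau$ is at most $1-m$
(symmetrically for B); otherwise `not_different`. The strict comparison
makes the default read "more than half of the matched pairs", and the
opposing-direction cap guarantees at most one enrichment direction per
genus. We accept $m \in [0.5, 1)$: $m = 0.5$ is the natural "most pairs"
reading, values approaching 1 demand near-unanimity; $m < 0.5$ would allow
double enrichment and is rejected. No multiple-testing correction is
applied: the rule is descriptive, with no distributional null, and its
error behavior is characterized by simulation instead (below).

Three structural properties are enforced by tests: antisymmetry (swapping
groups flips calls and inverts fold changes), compositional invariance
(scaling any sample's raw counts leaves calls unchanged), and threshold
monotonicity (raising $\tau$ never creates a new enrichment call).

# Diversity and ordination

**Alpha.** Shannon $H = -\sum_{p_i>0} p_i \ln p_i$ in nats. Group contrasts
use a two-sided Mann-Whitney U test: Shannon values over small specimen
groups are not plausibly normal, and a rank test is invariant to monotone
re-expression of diversity. Exact enumeration is used up to 8 untied values
per group, midranks with the normal approximation and tie correction
beyond.

**Beta.** Bray-Curtis dissimilarity on relative abundances (on raw counts
it would measure library size). The matrix is computed with
`vegan::vegdist`; the package's own two-vector `bray_curtis()` closed form
serves as the independent oracle in the tests.

**PCoA.** Classical scaling: double-center $-\tfrac12 D^{(2)}$,
eigendecompose, scale eigenvectors by $\sqrt\lambda$. Bray-Curtis is a
semimetric, so negative eigenvalues occur; they are dropped without
Cailliez/Lingoes correction and their summed magnitude is reported — we
prefer exposing the distortion to silently reshaping the geometry.
`proportion_explained` is relative to the positive-eigenvalue total. The
implementation accepts two samples (the closed-form case: one eigenvalue
$d^2/2$, coordinates $\pm d/2$), though ordination of fewer than ~4 samples
is rarely meaningful.

**PERMANOVA.** One-way pseudo-F
$F = \big(SS_B/(g-1)\big)\big/\big(SS_W/(n-g)\big)$ with
$SS = \sum_{i<j \in \text{set}} d_{ij}^2 / |\text{set}|$, significance by
permuting group labels. This is self-implemented (and cross-checked in the
tests against `vegan::adonis2`, which is never used as the
implementation). The paper-style beta-diversity P values reported by
studies of this design rarely name their test; PERMANOVA is the field
default for Bray-Curtis group contrasts and is what this package commits
to.

**Patient clustering.** The qualitative observation that specimens cluster
by patient is formalized as the statistic
$\bar d_{\text{between}} - \bar d_{\text{within}}$ over patient labels,
with a permutation null. It is location-free and needs no assumption
beyond exchangeability of samples under the null.

All permutation tests use the add-one estimator
$p = (1 + \#\{F^\pi \ge F\})/(1 + P)$, so $p$ is never 0 and never below
$1/(P+1)$; permutation counts default to 999 and seeds are explicit
arguments (default 0) so every result is reproducible.

# The clinical screen

Each clinicopathological variable is cross-tabulated against the
bacterial-culture outcome (rows = outcome, columns = the variable's
declared level order), with missing/unknown values excluded pairwise —
complete-case analysis per variable, no imputation. Tests follow the SPSS
convention: Yates continuity correction at 2×2, Pearson chi-square for
larger tables, $(r-1)(c-1)$ degrees of freedom, two-tailed 0.05. The Yates
choice matters: on the packaged cohort's diabetes table the corrected test
gives p = 0.011 where uncorrected Pearson gives ≈ 0.006, and only the
corrected value matches the published table. Continuous rows use the
pooled-variance two-sample t-test, computable directly from printed
mean ± SD summaries. N staging is screened as the printed four-level table
with no ordinal trend test. No multiplicity correction is applied across
the ~15 variables, mirroring the source analysis; `p_adjust = TRUE` adds
Benjamini-Hochberg values for users who want them.

The packaged fixture stores the published categorical counts and continuous
summaries as TSV. `table1_cohort()` expands the counts into a 218-row
patient-level tibble; because printed marginals cannot recover the joint
distribution across variables, columns are assigned independently within
each culture group, and only per-variable cross-tabulations against the
outcome are meaningful on it — exactly the analyses the printed table
supports.

# What the generator emulates — and what it does not

`simulate_paired_study()` draws, per patient $p$ and specimen type $t$, a
latent log profile
$z = \mu + \eta_p + \delta_t$ where $\mu$ is a fixed base composition
(geometric ramp from ~15% down to ~0.05%), $\eta_p \sim N(0,
\sigma_{\text{pat}}^2)$ per genus is shared by all of that patient's
specimens, and $\delta_t$ collects specimen-type effects plus planted
differentials ($\pm\tfrac12\log f$ on the two contrasted types, so the
expected paired fold change is exactly $f$). Counts are multinomial from
the softmax of $z$ at a log-normal depth (mean 50,000, sdlog 0.5 —
typical amplicon library variation). A designated fraction of the panel
(`rare_genus_rate`, default 0.05) appears only as sporadic per-sample trace
spikes (< 0.05% with probability 0.3), exercising the sampling-bias filter.

This logistic-normal-multinomial construction was chosen over plain
Dirichlet-multinomial because the shared $\eta_p$ induces the
patient-dominant correlation across specimen types that the clustering
test targets; setting `patient_effect_sd = 0` recovers an exchangeable
(DM-like) null used for calibration. Defaults: 10 patients × 3 tissue
types, 40 genera (named after common oral taxa for readable fixtures),
$\sigma_{\text{pat}} = 1$ on the log scale (within-patient specimens then
share most of their composition, as multi-specimen oral studies observe),
and three planted 3-fold differentials (Fusobacterium toward outer tumor,
Streptococcus toward adjacent normal, Prevotella toward inner tumor) —
mirroring the magnitude and direction of effects such studies report.

What it does **not** emulate: taxonomic mis-assignment, reagent
contamination with its batch structure, phylogenetic correlation between
genera, read-level error, or depth-dependent detection bias beyond
multinomial sampling. Passing the recovery tests therefore shows the caller
is correct and well-calibrated *under the stated generative model*, not
that real tissue data meet that model.

`simulate_clinical_cohort()` draws the outcome at a stated prevalence
(default 0.482) and each categorical variable conditionally on outcome with
per-level odds ratios (all 1 ⇒ exact independence), continuous variables as
group normals — a null/alternative bed for the screen's size and power.

# Validation problem sizes and what the tests show

The suite validates, at sizes chosen to make Monte-Carlo bounds tight while
keeping a desk-scale run: PERMANOVA type-I error over 400 null-generator
replicates (999 permutations each) and the patient-clustering test over 400
null replicates (199 permutations), both required to land in [0.03, 0.07]
at α = 0.05; caller recovery over 50 simulated studies with planted 3-fold
effects and 10 pairs (sensitivity ≥ 0.9 required, false-call rate ≤ 0.05 —
observed: 1.00 and 0.00); and patient-dominance rejection in ≥ 90% of 100
default-generator replicates (observed: 100%). Closed-form cases (Shannon,
Bray-Curtis, PCoA geometry) are checked to 10⁻⁹–10⁻⁸, and the published
cohort fixture must reproduce its printed test results exactly (Yates
chi-square 6.50 / p 0.011 for diabetes; Pearson 24.98 / p < 0.001 for T
staging; p 0.040 for metastasis; and no other categorical variable
flagged). Note the Yates correction makes the 2×2 rows conservative: under
outcome-shuffled nulls the screen's pooled rejection rate sits at or below
the nominal 5%.

# Known limitations

- The caller's defaults ("predominant", "most pairs", the pseudocount) are
  reasoned conventions, not estimated quantities; sensitivity to them
  should be explored with the exposed parameters on each dataset.
- Bray-Curtis PCoA without correction can distort geometry when negative
  eigenvalue mass is large; the magnitude is reported, but axes should not
  be over-interpreted when it rivals the positive mass.
- The Mann-Whitney and PERMANOVA choices are field-standard but not the
  only defensible ones; printed P values from studies that do not name
  their test cannot be reproduced exactly and are not asserted.
- The fixture cohort supports only per-variable analyses; any
  cross-variable model (e.g. logistic regression with confounders) needs
  true patient-level data and is out of scope.
- One specimen per patient and type is assumed; duplicates are resolved
  deterministically (lexicographically earliest sample id) with a warning
  rather than modeled.
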