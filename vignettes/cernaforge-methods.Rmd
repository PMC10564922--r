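---
title: "Methods: consensus circRNA detection and ceRNA network analysis"
author: "cernaforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus circRNA detection and ceRNA network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaforge)
```

# Scope and model of the data

`cernaforge` implements the desk side of a case/control plasma circRNA
study: it starts from the outputs of two back-spliced-junction (BSJ)
callers and from count matrices for circRNA, miRNA and mRNA, and ends with
a circRNA–miRNA–mRNA competing-endogenous-RNA (ceRNA) network, gene-set
enrichment of the network mRNAs, and a group-wise comparison of
circRNA–mRNA correlation patterns. Everything upstream of the call tables
and count matrices — trimming, alignment, quantification, the callers
themselves — is out of scope; those tools are run elsewhere and their
outputs are this package's inputs.

The abundance proxy for a circRNA is its BSJ-spanning read count: the
head-to-tail junction is unique to the circular isoform, so reads crossing
it count circles and nothing else. Counts are modelled as negative binomial
with variance $\mu + \alpha\mu^2$, the standard overdispersed model for
RNA-seq counts.

# Consensus calling and the support rule

Two callers disagree substantially on circRNA identification, so only
junctions reported by both enter the analysis (`intersect_callers()`).
Matching is exact by default (`tolerance = 0`); a ±2 bp tolerance can be
enabled for caller wobble, in which case matched junctions are canonicalised
to the elementwise minimum of the two coordinate pairs, keeping the
operation symmetric in its arguments. The retained per-sample count is the
maximum of the two callers' counts: with concordant callers the values are
near-identical, and the maximum is the monotone, caller-symmetric choice
that never discards support. By default the intersection is evaluated
per sample and the per-sample consensuses are unioned; a pooled mode (both
callers anywhere in the study) is exposed as an option.

The support filter retains a circRNA with at least `min_reads = 2` BSJ reads
in *strictly more than half* of the samples. "More than half" is read as a
strict majority of all samples pooled across groups; the same rule,
evaluated within one group, defines group-exclusive expression (a feature
must additionally have zero counts in every sample of the other group).

Annotation assigns exactly one class per circRNA by precedence:
`protein_coding` (both junction endpoints on exons of one coding
transcript) > `sense_intronic` (contained in an intron of a coding
transcript, same strand) > `lncRNA` (overlap with a lncRNA transcript) >
`intergenic`. Unstranded calls match either strand, since one of the
supported callers can emit unstranded junctions.

# Quantification and the group shift

BSJ counts are normalised to reads per million mapped reads
(`bsj_tpm()`): $\mathrm{tpm}_{is} = 10^6 \, c_{is} / N_s$ with $N_s$ the
sample's total mapped reads. No length normalisation enters because the
junction is a point feature. The global case/control shift is assessed on
$\log_{10}(\bar{x}+1)$ of per-feature group means with Welch's two-sample
t-test (`group_shift_test()`); the direction is reported only when the test
is significant at $\alpha = 0.05$. Welch's variant is used because the
design is unbalanced (10 vs 8) and nothing guarantees equal variances.
Fold changes use a pseudocount of $\varepsilon = 0.01$ TPM, which keeps
group-exclusive features finite while ranking them extreme.

# Differential expression

`nb_wald_test()` is a self-contained negative-binomial Wald test:

* **Size factors** are median-of-ratios against the per-feature
  geometric-mean reference, normalised to geometric mean 1. Sparse circRNA
  matrices may contain no feature observed in every sample; the
  documented fallback is library-size ratios, with a warning.
* **Prefilter**: a feature is tested when its mean raw count across all
  samples reaches the class threshold (mRNA 5, circRNA 2, miRNA 50). The
  mean formulation is sample-size independent.
* **Per-feature fit**: NB GLM with log link, a case/control covariate and a
  log size-factor offset. The dispersion is estimated per feature by
  maximising the Cox–Reid-adjusted profile likelihood over
  $\log\alpha \in [\log 10^{-8}, \log 10^3]$ (golden-section search,
  tolerance $10^{-3}$), with $\beta$ refit by IRLS at every candidate
  dispersion; a moment estimator is the fallback if the search fails.
  There is **no information sharing across features**, so results
  approximate, not replicate, shrinkage-based tools.
* **Inference**: the Wald statistic $\beta_1/\mathrm{SE}$ is referred to a
  t distribution with $n - 2$ degrees of freedom. With per-feature
  dispersions and no shrinkage, the normal reference is anti-conservative
  at these sample sizes (empirical size ~0.07–0.08 at $n = 9/9$ in our null
  simulations); the residual-df t reference restores the nominal 5% level
  (~0.05 measured), the usual small-sample remedy when each feature brings
  its own variance estimate.
* **Status rule**: Up requires linear fold change > 1.5 **and** raw
  p < 0.05; Down the reciprocal. The raw p-value gates the call — the BH
  adjusted p-value is always reported alongside but is deliberately not the
  gate, following the protocol this package operationalises. A
  `fc_scale = "log2"` switch applies the threshold on the log2 scale
  instead, since published wording is not always consistent between the
  two conventions.
* Non-converged fits (e.g. a group with all-zero counts, where the MLE is
  at infinity) are flagged: missing p-value, status `NS`.

# Target prediction and duplex energies

`predict_targets()` is a seed-anchored site scanner with a
nearest-neighbour free-energy gate, in the miRanda family but implemented
from scratch:

* **Seed scan** (`scan_sites()`): miRNA positions 2–8 must pair the target
  antiparallel with Watson–Crick pairs plus at most one G:U wobble; no
  seed mismatches or gaps. All overlapping candidates are kept at this
  stage.
* **Energy** (`duplex_energy()`): duplex initiation (+4.09 kcal/mol) plus
  nearest-neighbour stack sums over the seed, a banded dynamic-programming
  extension towards the miRNA 3' end (stacked pairs; single-nucleotide
  bulges on either strand at +3.8 with stacking retained across the bulge;
  1×1 internal loops at +1.5), and one optional pair at miRNA position 1.
  Extensions are only added when they lower the energy. Watson–Crick stack
  parameters are the published Xia et al. (1998) individual
  nearest-neighbour set; G:U-containing stacks use a condensed two-value
  approximation (−1.1 single, −0.3 tandem wobble) rather than the full
  sequence-dependent wobble tables — adequate here because the gate, not
  the third decimal, carries the decision. Terminal AU/GU end penalties are
  omitted for the same reason.
* **Gate and reporting**: one best-energy site per (miRNA, target) pair
  (ties broken by smallest position), reported only when the total energy
  is ≤ −20 kcal/mol. The reported position is the 1-based offset of the
  site's 5'-most paired target base.

Numerical equality with any particular external predictor is explicitly
not a goal: published pair tables print energies for sequences that are not
themselves published, so they serve as format and threshold fixtures, not
as numeric reproduction targets.

# Network assembly

Differential statuses are attached to predicted edges (`attach_status()`;
edges touching a non-significant molecule are dropped), then the
inverse-expression constraint (`inverse_filter()`) retains only edges
joining one Up and one Down molecule — the sponge hypothesis's expectation
for both the circRNA–miRNA and the miRNA–mRNA layer. Applying the filter to
both layers structurally enforces the published directional composition
(down circRNAs — up miRNAs — down mRNAs, or the mirror image).
`assemble_triples()` then forms every (circRNA, miRNA, mRNA) combination
around miRNAs present in both layers; molecules in no triple leave the
network. The percentage of opposite pairs is rounded half away from zero to
one decimal (14 of 24 prints as 58.3).

# Enrichment and correlation patterns

Gene-set enrichment is the upper-tail hypergeometric test
$P(X \ge k)$ with BH adjustment across terms; a term is significant when
both FDR < 0.05 and p < 0.01. The default universe is the annotated genes
present in the expression data. Real GO/KEGG hierarchies are out of scope;
the annotation is a user-supplied table.

The "parallel vs chaotic" contrast between groups' circRNA–mRNA
correlation heatmaps is operationalised as two statistics of the pairwise
correlation matrix computed within each group: `coherence` (mean of the
defined correlations) and `frac_positive` (fraction positive), plus the
correlation between the two groups' vectorised matrices. Pearson
correlation is the default, with Spearman as an option; pairs with a
constant vector are flagged undefined and excluded. This is a documented
surrogate for what is, in the literature, a visual claim.

# The synthetic-study generator

`simulate_study()` produces a complete in-silico study whose defaults are
the targeted design: 10 case and 8 control samples; NB counts with class
means 8 (circRNA BSJ reads), 250 (miRNA), 100 (mRNA) and dispersion 0.2 —
chosen so the class prefilters retain most features; per-feature base means
log-normal (sdlog 0.5) around the class mean; mapped totals log-normal
around $10^6$ so per-million values are O(1)–O(100). Cases receive a
global ×0.5 circRNA down-shift; 10–15% of features per class get a planted
fold-change-4 effect (circRNA effects almost all down, mRNA mostly up,
mirroring the imbalance such studies report); 6 case- and 30
control-exclusive circRNAs are planted with guaranteed within-group support
and hard zeros in the other group. Two caller views drop 12% of circRNAs
each, independently, giving a known true overlap. Planted miRNA response
elements are full-length reverse complements written into target sequences
at recorded, non-overlapping positions. A single seed drives one RNG
stream in a fixed (class, feature, sample) order, so bundles are exactly
reproducible.

What the generator does **not** emulate: linear-vs-circular isoform
competition, sequence composition bias, realistic genome coordinates,
correlated library-size effects, partial or wobbled response elements, and
caller-specific error profiles. Passing the recovery suites therefore
demonstrates the pipeline's correctness on data satisfying its own model
assumptions — not performance on real plasma libraries.

# Problem sizes and numerical choices

The validation suites run at desk scale, chosen to exercise every code
path with comfortable statistical resolution: 2000 null features at
$n = 9/9$ for the type-I check (standard error of the empirical rate
≈ 0.005), the default 300/60/400-feature bundle at $n = 10/8$ for power and
recovery checks, and 80–120-feature bundles in the unit tests. IRLS runs to
a $10^{-8}$ step tolerance with linear-predictor clamping at ±30;
size factors error out on all-zero matrices; degenerate inputs (empty call
sets, empty networks, constant expression vectors) return typed empty
results rather than failing.

# Known limitations

* Per-feature dispersion estimation discards cross-feature information;
  at very small counts the test loses power relative to shrinkage methods.
* The duplex energy model is deliberately reduced (condensed wobble
  parameters, no terminal penalties, no accessibility/conservation terms);
  it ranks and gates sites, it does not predict folding free energies to
  thermodynamic accuracy.
* The correlation-pattern statistics summarise a visual phenomenon; other
  operationalisations are defensible.
* The exclusive-expression rule evaluates support within the candidate
  group, one of two readings of the protocol it follows; the choice is
  documented and configurable through the shared support rule.
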