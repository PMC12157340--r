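---
title: "Two-stage variant-interaction screening in simplex families: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage variant-interaction screening in simplex families: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Common inherited variants individually explain little of the risk of
polygenic conditions such as autism spectrum disorder: a risk allele that
is also carried by unaffected relatives is, by construction, weakly
associated with the phenotype. One response is to look for *statistical
interactions*: pairs of loci whose **joint** carrier status separates
cases from controls even when neither locus does so alone. `episcreen`
implements this search for simplex-family cohorts — father, mother, one
affected child (the proband) and one unaffected sibling — together with
everything needed downstream of it: gene-network mapping, case-status
prediction, subtype clustering, and GO-term overrepresentation.

## The two-stage search

Testing all pairs of variants genome-wide is infeasible (the number of
pairs grows quadratically), so the search is staged:

1. **Screen.** Every variant is tested on its carrier 2x2 table —
   case carriers / non-carriers vs control carriers / non-carriers,
   where "carrier" means at least one alternate allele surviving the
   allele-depth filter — with the uncorrected Pearson chi-square
   $X^2 = n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ on 1 df.
   Variants with $p < p_i$ are preselected. The default
   $p_i = 10^{-3}$ is deliberately permissive: the screen's job is not
   discovery but limiting the quadratic cost of stage 2.
2. **Scan.** Every unordered pair of preselected variants is tested on
   its joint-presence table (a pair is present in a sample iff both
   variants are present). Pairs with $p < p_t$ are reported. The default
   $p_t = 1.3\cdot10^{-5}$ is a fixed conventional threshold;
   `bonferroniAuto = TRUE` derives $p_t = 0.05 / \binom{m}{2}$ from the
   number of pairs actually tested, which is the principled
   family-wise-error alternative.

The scan packs carrier columns into 64-bit words (cases first, then
controls), so a pair's joint-carrier count is a bitwise AND plus a
popcount; this is implemented in C++ and verified bit-for-bit against a
naive per-genotype scan in the test suite.

Two practical rules precede the search. *Reference removal*: a
homozygous-reference genotype contributes absence, and sites left with
no carriers are dropped. *Allele-depth filtering*: a carrier genotype
passes iff its alternate-depth fraction
$\mathrm{AD}_{alt} / (\mathrm{AD}_{ref} + \mathrm{AD}_{alt})$ reaches
the threshold (0 disables; 0.25 is the stringent setting, at which a
genuine heterozygote is more likely kept than not, while low-fraction
somatic-like artifacts are removed). The boundary is inclusive: a
fraction of exactly 0.25 passes. Zero-margin tables are defined as
non-significant, `(0, 1)`, so a monomorphic-after-filter variant can
never be a hit.

**Gender-mismatch policies.** Because case ascertainment is strongly
male-biased while sibling controls are not, sex-chromosome variants can
show spurious association. `applyGenderPolicy()` offers `skip_family`
(drop families whose sibling's sex differs from the proband's) and
`replace_sibling` (designate the same-sex parent as the family's
control; the same-sex choice is ours — the policy exists to fix the sex
imbalance, so the replacement should match the proband's sex), with
`none` leaving the sibling in place. Sex chromosomes are retained and
tagged, never dropped, since dropping them would discard genuinely
sex-linked risk.

## The synthetic cohort generator

Real simplex-family WGS cohorts are access-restricted, so the package
carries a generator (`simulateCohort()`) whose output exercises every
stage: multi-sample VCF with `GT:AD`, PED pedigrees, Mendelian
transmission, de novo events, male-biased ascertainment (86.8% male
probands vs 47.4% male controls, drawn at ascertainment — a
sex-specific liability offset cannot reach an 86.8% proband male
fraction when children's sexes are balanced, since at most three
quarters of within-family choices can be male), somatic-like
low-allele-depth artifact genotypes (alternate fraction strictly below
0.25, so the 25% filter removes them deterministically), and a planted
set of interacting variant pairs with recorded ground truth.

The planted architecture was designed so that the two-stage search, the
predictor and the clustering are all *identifiable at desk scale*
(hundreds of families and thousands of variants, versus thousands of
families and genome-wide variation in a real study). Three choices
matter, and each responds to a measurable failure mode of more naive
designs:

- **Carrier-parent pairs in cis.** Each planted pair occupies two
  adjacent loci on one chromosome; in 95% of families one randomly
  chosen parent is heterozygous at both (a risk haplotype), the other
  parent homozygous reference. Every family is therefore
  transmission-informative in the TDT sense: each child's carrier
  status is an independent transmission coin, and there is no
  between-family allele-frequency variance at risk loci. This is what
  prevents ascertainment from leaking into the sibling through
  enriched parents — under ordinary Hardy-Weinberg draws, conditioning
  the proband into a liability tail enriches the parents and the
  sibling inherits half of that enrichment, which measurably destroys
  the marginal (stage-1) signal. It also keeps each parent a joint
  carrier of only about half the pairs, which is what makes probands
  separable from their parents in the predictor.
- **Partial linkage.** The second member of a pair co-transmits with
  the first with probability 0.2 (otherwise independently). Linkage
  controls the ratio of marginal to joint association: with full
  co-transmission each variant alone carries the pair's whole signal
  (no pair-over-single gain); with none, the sibling tail sheds pairs
  by dropping a single member and the marginal signal halves.
- **Upper-tail liability threshold.** A child's affection is Bernoulli
  in its logistic liability,
  $\mathrm{logit}\,P(\text{affected}) = \mathrm{qlogis}(b) +
  \log(\mathrm{RR}) \cdot \#\{\text{pairs carried}\}$, and the default
  baseline $b$ is auto-calibrated so that the 50% point sits three
  standard deviations above the expected pair load. Affection then
  requires an unusually heavy polygenic burden: the proband is a
  genuine upper tail, while the unaffected sibling and the parents sit
  at the population mean. Families are ascertained simplex — exactly
  one affected child — by rejection sampling, run exactly and cheaply
  on the planted columns only (affection depends on nothing else), with
  the rest of the genome drawn afterwards for accepted families.

With the default configuration (300 families, 2000 variants, 20 planted
pairs, relative risk 150), the two-stage search at $p_i = 10^{-3}$,
$p_t = 1.3\cdot10^{-5}$ preselects essentially all 40 planted variants,
recovers all 20 pairs, and each recovered pair's interaction p-value is
smaller than either member's marginal p-value — the pair-over-single
gain the method exists to demonstrate. Because the marginal and joint
statistics are correlated with overlapping sampling noise, an occasional
planted variant (about one pair in twenty, in under a tenth of seeds)
fluctuates above its pair; the test suite tolerates a single such flip
rather than conditioning on a favourable seed.

What the generator does **not** emulate: linkage disequilibrium beyond
the planted cis-pairs, population stratification, genotyping error
beyond the artifact model, realistic allele-frequency spectra at risk
loci, or epidemiologically calibrated prevalence (the upper-tail
threshold architecture trades prevalence realism for identifiability at
small cohort size). Tests passing on this generator show the machinery
is correct and calibrated, not that any particular real cohort will
yield recoverable pairs.

## A statistical caveat the tests document deliberately

The screen contrasts each proband with a control from the *same family*
(the sibling, or a parent under `replace_sibling`). Sibling carrier
statuses are positively correlated through the shared parents (about
0.46 under dominant coding on the null generator), so the independent-
groups chi-square is conservative under the family-paired null: at
$p_i = 10^{-3}$ over $10^5$ null variants the nominal expectation is
100 retained variants, but the measured retention is an order of
magnitude lower. The suite asserts the nominal-calibration expectation
as stated — and documents that it fails — alongside two properties that
do hold: the paired screen never exceeds nominal (conservative
direction), and the same machinery applied to two unrelated groups of
probands is calibrated to the nominal level almost exactly. The
family-wise error rate of the full two-stage procedure with the
Bonferroni-derived final threshold stays below 0.05, as conservativeness
only reinforces an upper bound.

## Downstream stages

**Gene mapping.** Variants map to genes by interval overlap (full gene
span, 1-based inclusive, matching GFF3; intronic variants are
intra-gene). A position inside two or more non-pseudogene genes maps to
`overlap` and is excluded — there is no statistically neutral way to
pick one gene; a position inside only pseudogenes maps to `pseudogene`
(excluded as biologically inert); pseudogenes do not block mapping to a
real gene. A pair contributes a gene-network edge iff both members map
to unique genes; same-gene pairs form self-edges reported separately.
Region classes (exon, non-coding protein-coding, lncRNA, pseudogene,
intergenic) partition the unique risk variants.

**Inheritance.** A child occurrence of a variant is de novo iff neither
parent carries it after the same AD filter as the search (a
low-fraction parental read does not rescue a de novo call), inherited
iff at least one parent carries it, and unknown under parental
missingness.

**Prediction.** One binary feature per risk variant; all family members
enter with labels proband = 1, everyone else = 0, weighted inversely to
class frequency so both classes carry equal total weight. Families are
split 67:33 by a seeded permutation, whole families to one side only
(no leakage, asserted per cycle), over repeated cycles. The weighted
accuracy equals balanced accuracy analytically; the AUC is the
Mann-Whitney rank statistic on decision scores; per-cycle significance
is the chi-square of the test confusion table, and cycles aggregate by
averaging logarithms (geometric mean), since the p-values span many
orders of magnitude. Three classifier families stand behind one
surface — linear maximum margin (`e1071::svm`, linear kernel, cost 1,
class weights), logistic regression, and naive Bayes — because the
linear margin model is the one the method's conclusions rest on (cases
and controls separable by a hyperplane); others are pluggable.

**Clustering.** Only probands are clustered, on their binary
risk-variant profiles; relatives follow their case. PAM (k-medoids) is
used because medoids are actual samples, interpretable in a genetic
study, where fractional k-means centroids are not. The implementation
is BUILD + steepest-descent SWAP with seeded random restarts (default
5); single-swap descent alone can stall in a local optimum, and the
restarts reliably reach the exhaustive-search optimum on small
instances while remaining an honest local search. The cluster count
comes from the gap statistic over a k range, with the reference
distribution generated by independent column-wise permutation of the
binary matrix — this preserves each feature's marginal frequency while
destroying joint structure, which suits binary profiles better than the
original uniform-box reference. The chosen k is the first interior
local maximum of the gap curve; with none, the largest k is returned
with a warning. Distances default to Hamming; Jaccard is available
because all-zero profiles make the two diverge. No clustering-error
estimate is attempted.

**Per-cluster feature selection.** Within each cluster's samples, a
variant is kept iff its carrier-table chi-square p-value is below an
FPR threshold. The threshold is swept over a grid (default 0.001 to
0.5) with clusters held fixed; for each value, per-cluster predictors
are trained with family-wise splits inside the cluster, and the chosen
FPR maximizes the mean test AUC across clusters (ties to the smaller
threshold). Low FPR removes genuinely informative features; high FPR
overfits small clusters — the sweep's interior maximum reflects that
trade-off.

**Enrichment and triplets.** GO-term overrepresentation uses the
upper-tail hypergeometric test with Benjamini-Hochberg FDR control
(the conventional reading of "FDR correction") at adjusted
$\alpha = 0.05$; the universe is the annotated genes only
(whole-annotation reference semantics), ancestor propagation is applied
when a child-parent term relation is supplied, and very broad terms can
be filtered by a study-gene cap. The triplet finder reports gene
triplets where two genes interact biologically (user-supplied edge
list) and a third interacts statistically with both, plus the pairs
that are directly both biological and statistical.

## Numerical and engineering choices

- Pearson chi-square without the Yates correction by default (the
  correction is available as an option); carrier (dominant) coding
  throughout — "occurrences" count people, not alleles.
- Tiny baseline liabilities are clamped at `1e-300` (not machine
  epsilon) before `qlogis`, so sharp liability thresholds survive.
- Sample rows are partitioned into contiguous case/control blocks
  before bit-packing, so popcounts need no masking.
- Pair output order is genomic (first member, then second); all ties in
  PAM break to the lowest index; every stochastic step flows through a
  single seeded RNG wrapper that restores the caller's RNG state.
- Problem sizes in the test suite (e.g. 300 families / 2000 variants
  for recovery, 200 families / 1e5 variants for null calibration,
  60-point profiles for gap-statistic replicates, 150 families for the
  end-to-end run) were chosen as the smallest at which each property is
  statistically decidable with comfortable margins.

## Known limitations

- The chi-square screen is anti-conservative for unrelated designs with
  population structure and conservative for within-family contrasts
  (see above); it is a screening device, not an inference engine.
- `replace_sibling` designates a parent as control; under architectures
  where parents carry risk haplotypes (including the synthetic
  default), parent controls weaken the carrier contrast. The synthetic
  pipeline therefore defaults to sibling controls — its liability has
  no sex-linked component, so there is nothing for the policy to fix.
- Higher-order (three-way and beyond) interactions, logistic
  interaction terms, permutation nulls, genotype-likelihood calling,
  phasing, imputation and functional consequence prediction are out of
  scope.
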