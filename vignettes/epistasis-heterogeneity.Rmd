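---
title: "Epistasis, heterogeneity and diagnosis: the methods behind epiheter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistasis, heterogeneity and diagnosis: the methods behind epiheter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiheter)
```

## The problem

Complex diseases are often driven by *epistasis* — joint effects of several
SNPs that are invisible to single-marker tests — and by *genetic
heterogeneity*: different patients carry different epistatic patterns, each
causing a clinically indistinguishable subtype of the same disease. A method
that ignores heterogeneity dilutes its association signal across subtypes; a
method that ignores epistasis misses the signal entirely. epiheter analyses
case-control genotype data (biallelic SNPs coded 0/1/2 as minor-allele
counts, binary disease status) in three stages:

1. **Detection.** Every k-SNP combination is scored exhaustively; the Pareto
   non-dominated set under two objectives (maximise mutual information,
   minimise the K2 score) is kept and filtered by a Bonferroni-corrected
   chi-square test.
2. **Subtype discovery (optional).** Case samples are clustered with
   K-means on the detected epistatic SNPs; cases are relabelled by cluster
   to turn the binary problem into a multi-class (control / subtype 1..K)
   problem.
3. **Diagnosis.** A feed-forward neural network with rectifier hidden
   layers, dropout and a softmax output is trained by mini-batch gradient
   descent to predict status (binary mode) or subtype (multi-class mode).

A penetrance-model simulator generates pure (one disease model) and
heterogeneous (two disease models) datasets so that each stage — and the
pipeline end to end — can be validated against known ground truth.

## Stage 1: the three statistics

For a candidate tuple of k SNPs, the genotype combination of a sample is one
of $3^k$ cells, indexed in base 3. All three statistics are computed from
the same $3^k \times 2$ cell-by-class contingency table.

**Mutual information.** With $Y$ the case/control state and
$X_1,\dots,X_k$ the SNPs,
$$I(Y; X_1..X_k) = H(Y) + H(X_1..X_k) - H(Y, X_1..X_k),$$
evaluated with plug-in (maximum-likelihood) entropies and the convention
$0\log 0 = 0$. Entropies are in bits; the statistic is used for ranking, for
which the base is immaterial. Larger is better.

**K2 score.** The negative log marginal likelihood of the class labels
given the genotype cells under a Dirichlet(1, 1) prior per cell:
$$K2 = \sum_{i=1}^{3^k}\left[\log\big((r_i+1)!\big) - \log(r_{i1}!) - \log(r_{i2}!)\right],$$
where $r_i$ is the number of samples in cell $i$ and $r_{ij}$ the number of
those in class $j$. Cell counts are integers, empty cells contribute zero,
and the score is evaluated with log-gamma rather than literal factorials so
that large counts cannot overflow; the unit tests check it against an
exact-integer factorial oracle on small tables. Smaller is better.

**Chi-square filter.** A test of independence on the cell-by-class table,
with expected counts from the row/column margins, cells with an empty
genotype margin dropped, and df = (retained cells − 1). Although the
classical formula is often written as a one-way goodness-of-fit, the
filtering question — "is this combination associated with status?" — is a
two-way independence question, so the two-way form is used. The default
family-wise correction is Bonferroni over the number of combinations the
scan evaluated; if the filter removes every front member the pipeline warns
and falls back to the unfiltered front rather than aborting.

**Pareto front.** Candidate $a$ dominates $b$ iff $mi_a \ge mi_b$ and
$k2_a \le k2_b$ with at least one strict inequality; the front is the set of
non-dominated candidates. Only the first front is returned. MI is maximised
because it measures uncertainty reduction; K2 is minimised because it is a
negative log likelihood.

### A known limitation: the front is usually small

MI and K2 are *concordant* statistics of the same contingency table
(asymptotically $K2 \approx n\,H(Y|X)\ln 2 + \text{occupancy penalty}$), so
a candidate with higher MI almost always has lower K2. Consequently the
first front typically contains one to three members, not a spread of
alternatives. In heterogeneous data both true subtype tuples reliably rank
first and second on *both* objectives, but whichever is slightly stronger
usually dominates the other, so the front captures both subtype patterns
only in the minority of replicates where the MAF-dependent K2 occupancy
penalty disagrees with the MI ordering (roughly 5–10% at equal model
strength, measured over seeded replicates at n = 4000). Multi-objective
selection over these two particular objectives therefore does not, by
itself, solve heterogeneity; a practitioner hunting multiple patterns
should inspect the top-ranked candidates beyond the first front (the
candidate report written by the pipeline contains every scored
combination).

## Stage 2: subtype discovery

Only case samples are clustered — controls are one homogeneous class by
assumption. Features are the raw 0/1/2 codes of the union of SNPs across
all detected candidates, with Euclidean distance; K is a modelling input
(in practice, prior clinical knowledge; for simulated data, the number of
generating models). The implementation is Lloyd's algorithm with k-means++
initialisation, 10 seeded restarts keeping the best inertia, at most 300
iterations, convergence tolerance 1e-4 on squared centroid movement, and an
empty-cluster repair that re-seeds a dead centroid at the point farthest
from its own. Cluster ids are canonicalised by decreasing size (ties to the
cluster containing the smallest sample index) before cases are relabelled
1..K.

### A second known limitation: pure epistasis defeats K-means

For a *pure* epistatic model — penetrance depending only on an XOR-like
pattern, with no marginal effects — the two subtypes have identical
case-conditional genotype distributions at every single SNP; the subtype
signal lives entirely in joint parity structure that centroid geometry
cannot see. Empirically, K-means on raw codes scores an adjusted Rand index
of ~0 against ground-truth subtypes at *any* heritability for the parity
family. Subtype recovery works when the epistatic models carry marginal
effects (e.g. a dominant-dominant model, penetrance high iff every locus
carries a minor allele): there the case centroids of the two subtypes
separate and the ARI reaches ~0.5 at n = 4000. The package's
subtype-recovery tests therefore use the dominant-dominant family; users
should be aware that cluster-based subtyping presupposes marginal-bearing
epistasis.

## Stage 3: the diagnosis network

A fully connected network maps the feature vector (genotype codes scaled to
[0, 1] by dividing by 2) through rectifier hidden layers
($f(a) = \max(0, a)$), each followed by dropout at rate 0.5 during
training, to a softmax output with one node per class. Softmax is computed
in the max-shifted numerically stable form. Two architectures are built in:
the default desk-scale `(64, 32)`, adequate for ~100-SNP inputs, and the
`"paper"` preset `(2048, 1024, 512, 256, 128, 64)` whose widths multiply to
$2^{51}$ — retained for reference, but nothing in the evaluation suggests
that width is load-bearing at this input dimension.

Training minimises softmax cross-entropy with mini-batch Adam (defaults:
batch 32, learning rate 1e-3, at most 200 epochs). After each epoch,
validation loss and accuracy are recorded; training stops after 10 epochs
without validation-loss improvement and the best-validation parameters are
restored. Ties in the output argmax break toward the smaller class index.
All stochastic elements (initialisation, batch shuffling, dropout masks)
derive from explicit seeds, so training is bit-reproducible on a given
platform. The input layer can be either every SNP in the dataset
(`feature_mode = "all_snps"`, the default — robust when detection is
uncertain) or only the detected epistatic SNPs (`"epistatic_snps"` — far
fewer parameters, and the mode used by the package's headline evaluation).

Evaluation reports accuracy $Acc = n/N$, per-class accuracy, and the
confusion matrix; a multi-class model can additionally be scored as a
binary diagnostic by collapsing all subtype labels to "case", which can
only increase accuracy (confusing one subtype for another still counts as a
correct diagnosis).

## The simulator

A disease model is a penetrance table: for k interacting SNPs, the
probability of disease for each of the $3^k$ genotype combinations, plus
the minor allele frequencies of the loci. Under Hardy–Weinberg equilibrium
the table implies a prevalence $K = \sum_g P(g) f_g$ and a broad-sense
heritability $h^2 = \sum_g P(g)(f_g - K)^2 / K(1-K)$.

Two families are built in. The **parity** family assigns `f_high` to
genotype combinations whose summed code is odd and `f_low` otherwise — the
canonical near-pure epistasis family, with almost no marginal effects at
symmetric MAFs. `parity_table_for_heritability()` solves the symmetric
parity model ($f = 0.5 \pm d$) for a requested heritability, so presets can
express effect size on the scale geneticists use. The **explicit** family
takes the $3^k$ probabilities directly and is how the tests build
marginal-bearing models.

Sampling is quota-based: pathogenic genotype combinations are drawn under
HWE at the model MAFs and accepted as case with probability $f_g$ (control
with $1-f_g$) until each class quota is filled, so realised class counts
are exact and low-prevalence models cannot produce unusably small case
groups. Noise SNPs get MAFs drawn uniformly from [0.05, 0.5] and HWE
genotypes. Heterogeneous datasets concatenate two balanced sub-datasets
(default 50/50) with disjoint pathogenic SNP sets and shared noise columns;
each model's pathogenic SNPs appear in the other sub-dataset as plain HWE
noise at that model's MAF, so every pathogenic SNP keeps its population MAF
overall. The generating model and each case's source model are recorded as
ground truth. In a balanced case-control sample the realised pathogenic-SNP
MAF stays within sampling error of the specification because the case and
control enrichments nearly cancel (verified at n = 8000 within 0.02).

Twenty presets (`Pure1..Pure10`, `Hete1..Hete10`) reproduce the standard
evaluation grid: 100 SNPs; sample sizes 1000–8000; one 2- or 3-SNP model at
MAF 0.2 for pure data; two models at MAFs 0.2 and 0.3, each generating 50%
of samples, for heterogeneous data. The grid specifies no effect size, so
preset heritability is a free parameter defaulting to 0.2 — a moderate
effect, strong enough for detection at the grid's sample sizes without
being trivial.

What the simulator does **not** emulate: linkage disequilibrium between
SNPs (all columns independent), missing genotypes, covariates or population
structure, quantitative traits, and real MAF spectra. Tests passing on
these data show the machinery is correct under the stated model; they do
not show robustness to LD-induced score inflation or confounding, which a
real-data analysis must address separately.

## Pipeline orchestration and data hygiene

`run_pipeline()` draws the held-out split *first*: 10% of samples
(stratified by class) become the test set, then 10% of the remainder the
validation set. Detection and clustering see only training + validation
samples; the test set is untouched until the final evaluation. This is a
deliberate design choice — running detection on all samples would leak test
information into feature selection and flatter the reported accuracy. One
consequence: when clustering is on, held-out cases have no cluster label of
their own, so they receive subtype labels by nearest-centroid assignment at
evaluation time. Those labels are derived, not ground truth — multi-class
test accuracy measures agreement with the clustering stage's definition of
subtypes, which is also exactly what a deployed subtype diagnostic would be
asked to reproduce. For simulated data the report additionally retains the
simulator's true subtypes, so clustering quality itself is assessed with
the adjusted Rand index against truth.

One global seed fans out to per-stage seeds through a fixed hash
(`derive_seed(seed, stage)`), so a stage can be re-run in isolation and
reproduce exactly what it did inside the pipeline, and two runs with the
same configuration produce identical reports.

## Numerical and design choices, in brief

- Genotype cells indexed base-3, first SNP most significant; the indexing
  is bijective and tested against enumeration.
- Entropies in bits; K2 via log-gamma; chi-square p-values from the upper
  tail of the $\chi^2$ distribution.
- The scan's per-candidate cost is kept in check by sharing the base-3
  prefix of the cell index across the lexicographic recursion; a full
  order-3 scan of 100 SNPs (161,700 combinations) at n = 1000 runs in
  ~10 s on one core.
- Dominance ties: candidates with exactly equal (MI, K2) are mutually
  non-dominated and all kept; the front is sorted by descending MI, then
  ascending K2, then the SNP tuple.
- K-means restarts and k-means++ draws come from the stage seed;
  `stats::kmeans` (random-start Lloyd) serves as a cross-check in tests,
  never as the implementation, because per-iteration inertia traces and the
  empty-cluster repair rule are part of the contract here.
- Degenerate inputs error early with specific messages: one-class labels,
  empty fronts, K larger than the case count, unfillable class quotas,
  genotype codes outside {0, 1, 2} (named by row and column on file
  input).

## Problem sizes used by the test suite

The suite simulates everything it needs at run time: oracle checks use
30–500-sample tables; detection-recovery properties use 20 replicates of
n = 2000 (pure, order 2) and n = 4000 (heterogeneous); the end-to-end
accuracy check uses 10 replicates of the 1000-sample, 100-SNP, 3-locus
configuration; classifier sanity checks use 5 seeds at n = 1000–2000.
These sizes were chosen so the full suite exercises every claim at
meaningful scale while remaining comfortable to run on a laptop core.
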