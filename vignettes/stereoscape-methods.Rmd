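---
title: "Methods: spatial tumor-microenvironment analysis with stereoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial tumor-microenvironment analysis with stereoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoscape)
```

# Scope and model

`stereoscape` implements the computational core of a combined
single-nucleus RNA-seq and sub-micron spatial transcriptomics analysis of
cervical squamous cell carcinoma (CSCC): how capture spots become analysis
bins, how gene-set activity is scored per bin, how tumor areas are classed
as hyper- or hypometabolic, how cell types are mapped onto tissue regions
by marker-set intersection, and how a myofibroblastic cancer-associated
fibroblast (myCAF) compartment is called from the joint evidence of that
mapping and periostin (*POSTN*) expression. Two clinical side-channels are
included: HPV positivity calling from viral genome coverage, and composite
immunohistochemistry (IHC) scoring with contingency-table association
tests. All stages run on synthetic data with planted ground truth, so every
claim the package makes is testable without the original tissue.

## Spot-to-bin aggregation

The platform modeled here has capture spots 220 nm in diameter at a 500 nm
center-to-center pitch. A square bin of $s \times s$ spots therefore spans

$$ L(s) = (s - 1)\,\mathrm{pitch} + \mathrm{diameter} $$

from outer edge to outer edge: 49.72 µm at $s = 100$ ("bin100") and
99.72 µm at $s = 200$ ("bin200"). Spots are assigned to bins by floor
division of their 0-based lattice coordinates; the bin footprint is the
half-open square $[ks, (k+1)s)$. The origin convention is not dictated by
the platform, so the package uses the simplest auditable choice (0-based,
floor). Binning conserves counts exactly, per gene and globally.

Bin-level quality control removes bins whose UMI total is not strictly
above 200 and flags a whole chip as failing when the median number of
distinct genes per retained bin is not strictly above 1,000. Both
inequalities are strict on purpose: a bin with exactly 200 UMIs goes, a
chip with a median of exactly 1,000 gene types fails. Genes detected in no
retained bin are dropped (threshold configurable). Normalization is
library-size log-normalization, $\ln(10^4 \cdot c / C + 1)$ for count $c$
in a bin with total $C$; downstream scoring explicitly assumes
log-normalized input. A variance-stabilizing model-based normalization
would be an external black box here, and the scoring stages only require
the log scale, so plain log-normalization is the supported path.

## Signature scoring

Two engines compute per-bin (or per-cell) signature scores.

The **module score** follows the control-matched recipe standard in
single-cell toolkits: genes are cut into 24 expression bins by their mean
expression across units (ties broken by gene order), each signature gene
draws 100 control genes with replacement from its own bin, and the score is
the mean signature expression minus the mean over the distinct sampled
controls. The defaults (24 bins, 100 controls) are the documented defaults
of the upstream tool this mirrors. The score is exactly invariant to adding
a constant to all expression values; the control draw is seeded and
reproducible.

The **single-sample rank statistic** (`ssgsea_score`) stands in for
kernel-based gene-set variation analysis, which the original analysis used
as a black box. Genes are ordered by decreasing expression; position $j$
carries the centered rank statistic $r_j = (N - j + 1) - (N+1)/2$. The
score is

$$ \frac{1}{N} \sum_{i=1}^{N} \left( P^{in}_w(i) - P^{out}(i) \right), $$

where $P^{in}_w$ is the in-set ECDF weighted by $|r|^{0.25}$ and $P^{out}$
the unweighted out-set ECDF. Centering the rank statistic makes random
signatures mean-zero while keeping the top-ranked signature maximal among
all same-size signatures (both properties are tested, the latter by brute
force over all 3-subsets of an 8-gene toy). The statistic depends on the
data only through ranks, hence is exactly invariant to monotone
transforms. This is a deliberate substitution: it reproduces the
ordering-level claims the analysis rests on (which areas score higher) and
is fully specified, at the cost of not replicating kernel-GSVA's numeric
values. Tests verify that the two engines agree in rank direction (Spearman
correlation > 0.5) on planted elevations.

## Metabolic classification

Six pathway signatures — hypoxia, lactic acid, glycolysis, lipid
metabolism, pentose phosphate, oxidative phosphorylation — are scored per
bin; per-area scores are plain means over member bins, and the **metabolic
score** of an area is the arithmetic mean of its six pathway scores. Areas
ranked in the top $k$ are hypermetabolic, the bottom $k$ hypometabolic
($k = 20$ by default, matching a 15-slide study scale; it auto-shrinks to
$\lfloor n/2 \rfloor$ with a warning on smaller runs). Ties are broken by
area id, and an all-tied input is flagged as degenerate. Because only ranks
matter, the classification is invariant to any strictly increasing
transform of the scores.

Where area identities are not annotated, tumor areas are taken as
8-connected components of tumor bins — manual annotation in the original
workflow is not formalizable, and connected components are the closest
reproducible surrogate.

Immune contrasts between hyper- and hypometabolic areas default to the
unpaired two-sided Wilcoxon rank-sum test: the two classes are independent
groups of areas, so a paired signed-rank test is not directly applicable
even though the source figure legend names one; t, Kruskal-Wallis, and
signed-rank engines remain selectable so either convention can be
reproduced. The rank-sum engine enumerates all assignments exactly when the
pooled size is at most 10 and otherwise uses the tie-corrected,
continuity-corrected normal approximation.

## Multimodal intersection analysis and the myCAF gate

MIA asks whether a cell type's marker genes (from the dissociated data) and
a region's marker genes (from the spatial data) overlap more than chance in
a shared background of $N$ genes. With set sizes $m$ and $n$ and overlap
$k$, enrichment is the hypergeometric upper tail $P(X \ge k)$ and depletion
the lower tail; $-\log_{10} p$ is the MIA score. The background is the
*intersection* of genes detected in both modalities — the universe must
contain every set member, and the intersection is the smallest universe
that does.

Marker sets are derived by the package's own differential expression with
the standard filters (below), capped at the top 100 genes by fold change so
set sizes stay comparable.

A region is called myCAF-positive only when **both** hold: its
BH-adjusted MIA enrichment p for the myCAF type is below 0.05, and its mean
*POSTN* expression exceeds the 75th percentile of region means. MIA alone
misfires in regions with low RNA abundance, which is exactly where
stroma-adjacent ribbons live; the conjunction is the point, and the gate is
provably monotone (tightening either threshold never flags more regions).
The two cutoffs are configurable; the defaults are the package's own
choices since no numeric thresholds were published.

## Differential expression

Per gene, a two-sided Wilcoxon rank-sum test compares the two groups
(exact enumeration when the pooled size is at most 10, else the
tie-corrected normal approximation with continuity correction). The fold
change is computed on de-logged means with a +1 pseudocount,
$\log_2\!\frac{\overline{\exp(x_1)-1} + 1}{\overline{\exp(x_2)-1} + 1}$,
which is the convention behind the usual 0.25 threshold. A gene passes when
$|\log_2 FC| > 0.25$, it is expressed in more than 25% of the *target*
group's units, and the adjusted p is below 0.05 — all strict. Adjustment is
Benjamini-Hochberg by default (the published analysis says only
"adjusted"; the choice is configurable and recorded in every output
header).

## HPV calling

Coverage is covered length over reference length; effective depth is total
mapped bases over covered length ("covered" means depth at least 1). A
sample is positive for a type only when coverage is strictly above 5% and
effective depth strictly above 50x. Input is a per-base depth table
(2-column or samtools-depth style); alignment itself is out of scope.

## IHC scoring and association tests

Positivity percentage maps to 0-4 (0-5% → 0, 6-25% → 1, 26-50% → 2,
51-75% → 3, >75% → 4; fractional percentages are assigned by value),
intensity to 0-3, and the composite score is their product (0-12;
negative/weak/moderate/strong at 0, 1-4, 5-8, 9-12), dichotomized at
final ≥ 4. Associations with clinical covariates use Pearson's chi-square
with the Yates continuity correction exactly on 2x2 tables — the default
of the statistical environment the original analysis names, and the
convention that reproduces all six published cohort p-values (0.012,
0.270, 0.007, 0.040, 0.030, 0.011) to three decimals from the printed
counts, with plain Pearson on the 3x2 stage table. Samples missing a
covariate are excluded listwise per test, mirroring how the published
table handles its NA rows.

# The synthetic data generator

The generator produces every input the pipeline consumes, with planted
structure:

* **Cells.** Negative binomial counts with variance $\mu + \mu^2/\theta$
  (the standard RNA-count parameterization; Poisson as
  $\theta \to \infty$), a 2,000-gene universe, five cell types (cancer
  squamous, fibroblast, myCAF, immune, glandular), 12-gene marker sets
  whose leading members carry their field names (*SERPINB3*, *LAMA2*,
  *ACTA2*/*POSTN*/*ITGB4*/*FAP*, *PTPRC*, *MUC5B*), and an 8-fold marker
  elevation by default.
* **Chips.** Spots carry whole mixture draws: the expected count of a gene
  at a spot is the region's abundance factor times the
  composition-weighted mixture of type means. No per-spot deconvolution
  ground truth is generated, because the analysis itself treats spatial
  clusters as cell mixtures. Tumor blobs are discs on a jittered grid;
  myCAF annuli are 1-3-bin-wide rings around a configurable subset of
  blobs; inflammation patches and a stroma background complete the layout.
  The tumor abundance factor (3) exceeds stroma (1), emulating the marked
  RNA-richness of tumor areas. Hypermetabolic areas have all six pathway
  signatures' gene means multiplied by the planted fold (4 by default).
* **Viral depth.** Exactly `round(covered_fraction * genome_len)` positions
  get positive depth, drawn as 1 + Poisson(mean_depth − 1).
* **IHC cohorts.** Stage is categorical I-III; the probability of a high
  composite score follows a logistic model in stage with a planted
  log-odds effect; score components are drawn uniformly among combinations
  consistent with the sampled high/low status; missing values are
  injectable.

Region composition fractions are free parameters of the generator, not
estimates of real tissue (none were published); the defaults (e.g. tumor =
70% cancer cells) were chosen once as plausible for a carcinoma and left
alone. What the generator deliberately does **not** model: tissue images,
read-level errors, doublets, ambient RNA, lateral diffusion, batch
effects, and spatially varying dispersion. Passing recovery tests therefore
demonstrate that the pipeline's logic is correct under its stated
assumptions — not that those assumptions hold in any particular tissue.

# Numerical and design choices

* **Seeds.** Every stochastic stage derives a child seed from the single
  run seed by hashing the stage name (Horner scheme modulo $2^{31}-1$), so
  a stage re-run in isolation reproduces the pipeline run exactly.
* **Rank-sum p-values.** Exact enumeration is used at pooled sizes up to
  10 (it handles ties by permuting the observed midranks; two-sided by
  symmetric deviation from the permutation mean). The asymptotic path uses
  the tie-corrected variance with a 0.5 continuity correction. On
  tie-free data at small sizes the approximation tracks enumeration to
  about 0.015 in the worst case — the implementation avoids even that by
  switching to enumeration where it matters.
* **Ties.** Expression-bin assignment in the module score and the
  descending sort in the rank statistic both break ties by stable input
  gene order; metabolic ranking breaks ties by area id. All tie-breaks are
  deterministic and documented.
* **Degenerate inputs.** All-tied metabolic scores are flagged; empty QC
  results return an explicit EMPTY status; zero-coverage profiles get
  effective depth 0 rather than NaN; regions with empty compositions,
  all-NA covariates, sub-2-unit groups, and infeasible hypergeometric
  configurations raise informative errors.
* **Problem sizes.** The bundled recovery suites simulate 100x100-spot
  chips with ten tumor blobs for metabolic recovery, 72x72-spot chips with
  five blobs (two ringed) for the myCAF gate, 20 seeds each, and 500
  null cohorts of 71 samples for the type-I check — desk-scale sizes
  chosen so the full suite runs in minutes while leaving the rank
  statistics enough resolution.

# Known limitations

* The rank-based single-sample score is a stand-in for kernel GSVA: it
  preserves orderings, not numeric score values.
* Tumor "areas" from connected components will merge blobs that touch;
  the generator spaces blobs so this does not occur in the bundled
  layouts.
* The k-of-ranking hyper/hypo rule is tied to cohort scale; with few areas
  the auto-shrunk k makes "hyper" and "hypo" exhaustive and the
  intermediate class empty.
* Whether the published top/bottom-20 ranking pooled areas across samples
  or ranked within sample is unstated; the package ranks jointly across
  everything it is given.
* The chi-square tests use the asymptotic distribution; no exact-test
  fallback is applied (none is needed to reproduce the published table,
  whose smallest expected count is about 5.9).
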