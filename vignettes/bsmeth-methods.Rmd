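---
title: "Comparative WGBS methylome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative WGBS methylome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmeth)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) converts unmethylated cytosines
to thymine, so that cytosines surviving in aligned reads report
methylation. `bsmeth` compares two pooled WGBS methylomes — a control
group and a treated group, each pooled into one sample — through the
standard downstream ladder: per-cytosine calls, context classification,
genome-wide summaries, sequence preference, functional-region profiles,
differentially methylated regions (DMRs), differentially methylated
genes (DMGs), and their association with differentially expressed genes
(DEGs). Read alignment and DEG calling are upstream of the package:
inputs are per-cytosine count tables (CX-report layout), a genome, a
GFF3 gene annotation, and an expression table with DEG flags.

Mammalian methylomes in this regime have high CpG methylation (around
two thirds of CpG calls methylated) and very low CHG/CHH methylation
(well under 1%), which is what the bundled simulator reproduces by
default.

## The binomial model and non-conversion correction

The methylated call count at a cytosine with depth $n$ is modelled as
binomial, $X \sim \mathrm{Bin}(n, p)$. The raw methylation level of a
site or pooled unit is

$$\mathrm{ML} = \frac{mC}{mC + umC}.$$

Bisulfite conversion is imperfect: a truly unmethylated cytosine
escapes conversion with probability $r$ (the non-conversion rate) and
then reads as methylated, so the call-level fraction has expectation
$\mathrm{ML}_{true} + (1 - \mathrm{ML}_{true})\,r$. The rate $r$ is
estimated as the fraction of methylated calls over the cytosine
positions of an unmethylated lambda-phage spike-in, and the level is
corrected by inverting the contamination:

$$\mathrm{ML}_{corr} = \frac{\mathrm{ML} - r}{1 - r},$$

clamped to $[0, 1]$. Clamping is our addition: at very low levels the
plug-in formula can go slightly negative from sampling noise. The
correction is linear in the call-level fraction, so it commutes with
count pooling; we therefore pool raw counts first (within windows,
regions, bins or 9-mer classes) and correct the pooled ratio once.
Whether the original procedure corrected per site or per pooled unit is
not something we could determine; the pooled-first choice is the
numerically stabler of the two and is used everywhere.

Genome-wide levels are estimated in sliding windows of 3,000 bp with a
600 bp step (`window_ml()`); DMR testing uses 1,000 bp windows with a
100 bp step (`window_tests()`). Windows tile each chromosome with full
windows only (`floor((L - w)/step) + 1` starts); a chromosome shorter
than the window contributes one truncated window.

## Context classification

Every genomic cytosine on either strand is classified by the two bases
downstream on its own strand: `CG` if the next base is G, else `CHG` if
the base after that is G, else `CHH` (H = A, C or T). A plus-strand G
marks a minus-strand cytosine, classified on the reverse complement.
Sites lacking two downstream bases on their strand, or with an N in the
defining dinucleotide (CG) or trinucleotide (CHG/CHH), are excluded and
tallied — including a terminal C followed by a final G, a deliberate
simplification that keeps the eligibility rule uniform. CpG sites pair
one-to-one across strands.

## Genome summaries and the "methylated site" rule

Three dataset-level quantities are produced by `genome_summary()`:

* per-context level: pooled corrected ML over all covered sites of the
  context, as a percentage;
* mC percent: the fraction of covered cytosines called methylated;
* composition: the share of methylated sites in each context, summing
  to 100%.

No standard defines when a site counts as "methylated" for the second
and third quantities. Our default calls a site methylated when its
methylated-call count is binomially incompatible with the
non-conversion rate alone (one-sided test of $mC$ out of $n$ against
rate $r$, $p < 0.05$, requiring $mC \ge 1$ and depth $\ge 5$); with
$r = 0$ this reduces to "at least one methylated call". The simpler
$mC \ge 1$ rule is available via `site_rule = "any"`. Sites are
classified hyper-/hypomethylated with strict context thresholds: above
75% for CG, above 25% for CHG/CHH; equality falls to hypo.

## Sequence preference (9-mers)

For every covered cytosine at depth $\ge 5$, the 9-mer with the C at
position 4 (three bases upstream, five downstream, on the site's own
strand) is tabulated and call counts pooled per distinct 9-mer
(`tabulate_ninemers()`). The alternative geometry sometimes described —
the cytosine at position 1 with five following bases — is not a
coherent 9-mer window, so only the position-4 reading is implemented;
the window geometry is a function argument. 9-mers split into high and
low sets at the hyper/hypo threshold of their context, and per-set
position frequency matrices are computed weighted by the number of
contributing sites (`preference_matrices()`): frequent contexts should
dominate the logo, as in standard logo construction; one-vote-per-9-mer
weighting is available.

## Functional regions and metagene profiles

Five element classes are derived from the gene models
(`derive_regions()`): promoter, 5′UTR, exon, intron, 3′UTR. The
promoter is the 2,000 bp immediately upstream of the TSS
(strand-aware); 2 kb is a common convention, configurable, since no
structural definition is given by annotation alone. Introns are the
gene span minus the exons. A site overlapped by intervals of several
classes (across different genes) counts in each class; within one gene
the classes are disjoint by construction.

Metagene profiles (`metagene_profile()`) split every element instance
into 20 equal-width bins in transcript orientation (bin 1 = 5′ end;
minus-strand instances reversed) with bin index
$\lfloor \text{offset} \times 20 / L \rfloor$. Averaging across
instances pools counts (count-weighted) rather than averaging per-gene
means, matching how counts are pooled elsewhere; per-gene averaging
would weight short, shallow genes equally with long, deep ones. A
consequence of floor binning worth knowing: strand reversal reverses a
profile exactly only when the instance length is a multiple of the bin
count; otherwise boundary positions can shift by one bin.

## DMR calling

Per 1,000/100 window and context, methylated/unmethylated calls are
pooled per group into a 2×2 table and tested with a two-sided Fisher
exact test. The two-sided p-value sums hypergeometric probabilities of
all tables with the observed margins whose probability does not exceed
the observed table's (relative slack $10^{-7}$ for floating-point
ties); the implementation is checked against exhaustive enumeration for
all margins up to 30 at $10^{-10}$ absolute tolerance.
Benjamini–Hochberg adjustment is applied within context across all
tested windows genome-wide (via `p.adjust`). Windows are kept when

* BH-adjusted q < 0.05 — the stated "corrected P-value" and "false
  discovery rate" thresholds coincide under BH, so one quantity serves
  both; a Bonferroni alternative can be had by adjusting externally;
* mean per-site depth > 5 in **both** groups — "coverage greater
  than 5" does not say per-group or pooled; requiring both groups is
  the conservative reading and is configurable;
* fold change > 2, computed on corrected levels as
  $\max(\mathrm{ML}_A, \mathrm{ML}_B) / \max(\min(\mathrm{ML}_A,
  \mathrm{ML}_B), 0.001)$ — the 0.001 floor prevents division by zero
  and keeps windows with both levels essentially zero from ever
  passing.

Kept windows of the same context and direction (hyper/hypo of group B
versus group A) merge when overlapping or book-ended (gap 0 by
default); merged-span statistics are recomputed from raw site counts.
A DMR is assigned to every gene whose promoter-through-3′UTR footprint
it overlaps by at least 1 bp; per-gene hyper/hypo counts render as
"↑(k)↓(m)". The minimum to test a window is one covered cytosine per
group; the depth filter does the real gatekeeping.

## Expression association

RPKM is computed from the exon-model length and library size. DEGs are
split into "highly" and "lowly" expressed at the median RPKM of the DEG
set — reading "according to their gene expression level" as an
expression-level split, not an effect-size split; the |log2FC| split is
available behind `split = "abs-log2fc"`. The Pearson association pairs
each gene's promoter methylation difference (group B − group A) with
its log2 fold change; the original variable pair is unstated, and
promoter methylation is the mechanistically standard choice (gene-body
methylation can be substituted by pooling a different region class).
Metagene profiles are additionally computed per expression class,
group, region and context.

## The synthetic-data generator

The generator exists to give every stage a ground truth. Defaults are
the study conditions: per-context baselines CG = 0.6762, CHG = 0.0059,
CHH = 0.0058 (the control-group regime), non-conversion rate 0.005,
mean depth 20, and one pooled sample per group with no replicate
structure. Per-site depth is Poisson around the mean — the standard
shotgun approximation; nothing in the pooled-sample setting identifies
a better choice — with zero-depth sites emitted as zero counts.
Non-conversion acts only on truly unmethylated cytosines (the chemical
mechanism); sequencing error is out of model. Planted DMRs are
context-pure CG intervals, pairwise disjoint, default width 2,000 bp
(a typical DMR scale that guarantees at least one full 1 kb test
window inside each planted region), with group levels 0.6 versus 0.1
in the recovery setting. Read simulation for QC embeds an adapter
literal (TruSeq prefix by default), N stretches above the 10%
threshold, and low-quality tails, and reports ground-truth per-rule
counts computed from the finished reads with the same
adapter-first precedence the filter uses.

What the simulator does not emulate: CpG islands and regional
autocorrelation of methylation, strand-biased coverage, PCR duplicates,
mapping artifacts, replicate-level biological variance. Passing
recovery tests therefore demonstrates correctness of the estimators and
the calling procedure under the stated sampling model, not robustness
to alignment artifacts or inter-animal variability.

## Read QC

Three read-level rules in fixed order, each read attributed to exactly
one: adapter substring present (exact match of a configurable literal,
≥ 8 nt; no mismatch tolerance is specified upstream, so none is
applied); N fraction strictly above 10%; fraction of bases at PHRED ≤ 5
at or above 50%. The low-quality criterion is a whole-read criterion,
so the read is removed rather than trimmed — the description of this
step is ambiguous between trimming and removal, and removal is the
reading consistent with a read-level threshold. PHRED encoding is fixed
to Sanger/Illumina 1.8+ (offset 33). Q20/Q30 are call fractions at or
above PHRED 20/30; GC excludes N from the denominator.

## Numerical choices and degenerate inputs

* Coordinates: 0-based half-open internally; CX report and GFF3 are
  1-based on disk, BED 0-based.
* Zero-depth sites are "missing", never level 0.
* Empty windows are omitted from window tables; windows lacking
  coverage in either group are skipped and tallied before testing.
* `correct_ml` is monotone in the raw level and the identity at r = 0.
* Quantiles of per-DMR levels use the default type-7 interpolation.
* All generators take explicit seeds; `simulate_dataset()` derives
  per-stage seeds from one master seed, and reruns are byte-identical.

## Problem sizes used in the validation suite

The test suite and the acceptance script run on genomes of 100–500 kb
at depth 20: large enough that pooled standard errors make the
3-standard-error recovery checks sharp (about 1.6 million calls at the
Table-2-style regime on 200 kb), small enough to iterate quickly. DMR
recovery uses a 500 kb genome with 50 planted 2 kb CG DMRs (0.6 versus
0.1) over multiple seeds, with matched null runs at equal baselines
expected to produce zero DMRs.

## Known limitations

* One pooled sample per group: no replicate-aware or beta-binomial
  dispersion modelling; the Fisher test treats calls as independent.
* Merging of significant windows is one defensible rule
  (overlap/book-end within direction); other tools merge differently,
  so absolute DMR counts are not comparable across implementations.
* The per-site "methylated" rule, the promoter length, the coverage
  filter reading and the association variable pair are explicit
  package choices where the upstream description is silent; each is a
  documented argument.
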