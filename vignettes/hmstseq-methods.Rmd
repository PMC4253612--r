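---
title: "Models and methods behind hmstseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hmstseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

HMST-seq interrogates every CCGG site (the MspI/HpaII recognition
sequence) with three sequencing libraries per sample:

* **L1** — MspI digestion of untreated DNA. MspI cuts CCGG regardless of
  CpG methylation, so L1 tags count unmodified C + 5mC + 5hmC; L1 is the
  coverage measurement of a site.
* **L2** — MspI digestion of glucosylated DNA. Glucosylation of 5hmC
  blocks MspI, so L2 counts C + 5mC.
* **L3** — HpaII digestion of untreated DNA. HpaII is blocked by any CpG
  modification, so L3 counts unmodified C only.

Writing $(u, m, h)$ for the per-site fractions of unmodified,
methylated, and hydroxymethylated cytosine ($u + m + h = 1$), the
expected normalized tag rates at one site are proportional to $1$,
$1 - h$ and $u$ respectively. The point estimator inverts this:

$$\hat u = \mathrm{clip}\!\left(\frac{n_3}{n_1}\right),\quad
  \hat h = \mathrm{clip}\!\left(1 - \frac{n_2}{n_1}\right),\quad
  \hat m = \mathrm{clip}(1 - \hat u - \hat h),$$

with each ratio clipped to $[0, 1]$ and the triple renormalized to sum
to one. A site with $n_1 = 0$ is a no-call. No pseudocounts are used;
undefined quantities propagate as missing values.

Reads are assigned to sites through a *virtual tag reference*: the
genome is digested in silico with MspI (C^CGG) and NlaIII (CATG^), and
for each MspI site the sequence to the nearest NlaIII cut on either
side forms one reference tag per direction. Tags whose sequence (or
reverse complement) occurs more than once in the tag set are flagged
non-unique and excluded, mirroring the requirement of unambiguous
mapping. Coordinates are 0-based half-open internally, BED on disk.

# Normalization

`grsn_normalize()` works in two stages.

**Across samples, within a library.** Each sample's column is adjusted
toward that library's pseudo-reference (the per-site geometric mean
over samples, on $\log(x+1)$ counts) using a global rank-invariant
site set: sites whose rank in the column stays within a tolerance of
their rank in the reference (starting at 5% of sites and halving over
four iterations). On that set we fit either a single size factor (the
median log-ratio; the default) or a monotone piecewise-linear map
(isotonic regression with unit-slope extension beyond the knots;
`method = "piecewise"`). Within a library the columns measure the same
per-site quantity — coverage times that library's biology — so rank
invariance is a valid anchor for sample effects.

**Across libraries.** The three libraries measure genuinely different
per-site rates ($\propto 1$, $1-h$, $u$), so matching their count
*distributions* would erase the biology. The identifiable anchor the
design provides is the least-modified sites, where all three libraries
carry equal rates. We take the per-site cross-sample mean log-ratio of
L2 (and L3) to L1, locate its upper `anchor_quantile` (default 0.95)
among sites of adequate depth, subtract the expected Poisson noise
spread at that quantile, floor the result at the median ratio (which
makes the anchor exact under a completely unmodified null), and refine
it by iterating a noise-windowed median, whose fixed point is the
center of the unmodified plateau. One global factor per library then
pins that plateau at a ratio of one.

The practical consequences: with a methylome that contains an
unmodified (CpG-island-like) population, the effective per-library
factors recover the true library-size imbalance to within a few
percent; under a complete null the anchor reduces to the median and
the downstream tests stay calibrated.

# Site-level significance

5hmC presence is tested by comparing L1 against L2, and 5mC by L2
against L3, with the exact conditional form of the Poisson rate-ratio
test: conditional on the total, the first count is
$\mathrm{Binomial}(x + y,\; s_x / (s_x + s_y))$ under equal rates,
where $s_x, s_y$ are the effective library-size factors from the
normalization; the one-sided upper tail is the P value. P values are
Benjamini–Hochberg adjusted per sample and per modification. A
significant call requires raw L1 depth above `depth_min` (default 10),
a normalized library ratio above 1, and an adjusted value below `fdr`
(default 0.001). The depth gate is applied to raw L1 because L1
measures locus coverage irrespective of modification state.

# Region detection

`find_regions()` detects differentially methylated (DMR) or
hydroxymethylated (DhMR) regions between a case and a control group by
seed-and-extend. Sites are per-sample modification levels
($\hat m$ or $\hat h$). Scanning each chromosome left to right:

1. A candidate seed is a window of 5 consecutive CCGG sites whose
   adjacent gaps are ≤ 2,000 bp, with at least 4 sites sharing one
   nonzero change trend (sign of case-minus-control mean) and a
   two-sided Wilcoxon rank-sum P below 0.05 on the pooled member-site
   levels (all sites × all samples per group; per-site group means via
   `pool = "site_means"`).
2. The seed extends one downstream site at a time while the next
   site's trend equals the majority trend, its gap is ≤ 2,000 bp, and
   the re-run pooled test on the whole incorporated region keeps
   P < 0.05.
3. The first failing site stops extension; the region is emitted and
   scanning resumes after it, so regions never overlap.

The rank-sum test enumerates exactly when the pooled size is ≤ 12 with
no ties and otherwise uses the tie-corrected normal approximation with
continuity correction. The 2,000-bp gap rule is enforced inside the
seed as well as during extension. Sites observed in fewer than half of
either group's samples cannot seed. Zero-trend sites (exact mean ties)
break extension and count toward neither trend in a seed. We test the
whole incorporated region at each extension step, not the increment,
and regions are emitted with the last passing P value. No region-level
multiplicity correction is applied; emitted regions are raw P < 0.05
windows, and the null rate of emitted regions is therefore driven by
the seed rules, not by any FDR guarantee.

The rank-sum test is used unpaired even though the study design is
matched; that follows the method's named test. Pooling sites × samples
treats member sites as exchangeable replicates, which overstates the
degrees of freedom when neighboring sites are correlated — one reason
the emitted-region count under the null should be read as descriptive.

# Annotation

Promoters default to [TSS − 2,000, TSS + 500) strand-adjusted, a
common convention (the candidate screen below uses its own 5-kb
window). Feature precedence for point sites is promoter > enhancer >
exon > intron > intergenic; a region takes the label covering its
largest fraction, ties broken by the same precedence, each object
counted once. TSS distances are measured from the object midpoint,
signed negative upstream, ties resolved to the smallest absolute
distance then the lexicographically first gene id. Density profiles
bin signed distances over ±40 kb into 80 equal bins normalized to the
regions inside the window.

# Expression, CNV and the candidate screen

Array intensities are compared per gene with the same Wilcoxon
rank-sum machinery; count libraries are compared pairwise with the
two-library exact conditional binomial test (two-sided by the
minimum-likelihood convention), a stand-in for the original external
count-test whose formula is not restated in our sources. A gene is a
DEG when its BH FDR is below 0.05 in at least one group and its
direction agrees across all groups. Up-DEGs overlapping an
amplification and down-DEGs overlapping a deletion (≥ 1 bp of gene
body, any case sample) are removed as dosage-explained.

The tumor-suppressor screen links each remaining DEG to DMRs/DhMRs
within 5 kb upstream of its TSS (strand-adjusted). A gene passes the
sign rule when every linked DMR anti-correlates with expression
(hyper-methylated promoter with a down gene, or hypo with up), every
linked DhMR correlates positively, and, when both kinds are present,
their directions are opposite — the biological expectation since 5hmC
is produced from 5mC. A lone DMR or DhMR suffices with its own
correlation rule.

Pathway enrichment is an upper-tail hypergeometric test per pathway
with BH adjustment; the enrichment rate is the percentage of set genes
belonging to at least one significant pathway.

# The synthetic study generator

`simulate_hmst()` builds a complete, fully deterministic study from one
configuration:

* **Genome.** CCGG sites are laid out as island clusters (default 12
  sites, ~250 bp apart — the CpG-island-like component holding half of
  all sites) interleaved with sparse bulk sites whose jittered gaps
  typically exceed the 2,000-bp adjacency limit; overall density 0.7
  CCGG/kb matches the genome-wide MspI-site rate in human. CATG sites
  sit on an independent jittered grid (4/kb). Background sequence is
  swept so no accidental CCGG/CATG survives; motif positions are
  therefore known exactly.
* **Site states.** Island sites draw (u, m, h) from a Dirichlet around
  (0.88, 0.08, 0.04); bulk sites around (0.35, 0.50, 0.15) — a bimodal
  methylome with overall means near (0.55, 0.35, 0.10). A per-site
  coverage factor (log2-normal, sd 0.6) is shared across libraries and
  samples.
* **Planted regions.** Disjoint runs of consecutive sites (gaps
  ≤ 2,000 bp, a 2-site buffer between regions) are shifted by exactly
  the configured effect size: hyper regions raise the case group, hypo
  regions are implemented by raising the control baseline so the shift
  stays inside the simplex; the other two fractions are rescaled.
  Because eligible runs live in islands, planted regions coincide with
  island units — the promoter-island gain of methylation the screen
  targets.
* **Counts.** $L_1 \sim \mathrm{Pois}(f_1 d)$,
  $L_2 \sim \mathrm{Pois}(f_2 d (1-h))$,
  $L_3 \sim \mathrm{Pois}(f_3 d u)$ with library factors
  (1.0, 0.8, 1.2) to force nontrivial normalization, per-sample depth
  jitter (CV 0.1) and the shared per-site coverage factor; mean depth
  100 per library.
* **Expression and CNV.** Five matched array pairs (log-normal around a
  per-gene baseline, log2 noise sd 0.25) and two matched count pairs
  (Poisson by default; negative-binomial dispersion available as a
  stress switch — the default must keep the global-null DEG set empty
  in expectation under the exact conditional test). Planted TSGs are
  the genes attached to the first hyper-DMRs, dropped 3-fold in cases,
  with baselines drawn above the median so the planted signal is
  detectable at all (a silenced tumor suppressor is by definition
  expressed in control tissue). About 30% of genes are differentially
  expressed in total, mirroring a tumor/normal comparison. CNV
  segments include deliberate amplifications over up-DEGs and
  deletions over non-TSG down-DEGs to exercise the dosage filter;
  random segments avoid TSG bodies so the planted truth stays valid.

Every output is a deterministic function of the configuration and its
seed (each stage derives its own sub-seed).

## What the generator does and does not emulate

It reproduces the features the pipeline's statistics depend on:
three-library Poisson sampling with library-size imbalance, bimodal
methylation with an unmodified island population (the normalization
anchor), clustered site spacing (the gap rule's justification), exact
planted effect sizes, matched-design expression on two platforms, and
dosage-confounded DEGs. It does not emulate read-level artifacts
(sequencing errors, mapping bias, incomplete glucosylation or partial
digestion), site-to-site correlation of methylation beyond the planted
regions, biological within-group heterogeneity of methylation, or
isoform structure. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative model, not
robustness to those real-data artifacts.

# Numerical choices and known limitations

* **Estimator crosstalk.** Clipping followed by renormalization makes
  $\hat h$ shrink asymmetrically between groups at sites where one
  group's $\hat u + \hat h$ tends to exceed 1 (high-$u$ islands) while
  the other's does not (after a methylation gain). At strongly
  hyper-methylated islands this produces apparent hmC gains of a few
  percent, enough for occasional spurious hyper-DhMR calls at
  hyper-DMR islands; through the opposite-direction sign rule these
  cost the candidate screen some recall, and they inflate the apparent
  DhMR–DMR overlap at desk scale well above what a study reports at
  genome scale. We keep the estimator in its simple closed form
  because it is the method's defining arithmetic; a constrained joint
  estimator would remove the artifact at the price of that
  transparency.
* **Power at the strict FDR.** With the exact conditional test at mean
  depth 100, an h = 0.5 site yields a one-sided z of about 4.1 while
  the q < 0.001 gate needs roughly 3.1–3.5 after adjustment, capping
  per-site hmC power near 0.75–0.84. Deeper coverage, not a different
  test, is what buys hmC sensitivity.
* **Per-call fraction noise.** At depth 100 the delta-method standard
  deviation of $\hat u$ is $\sqrt{(u+u^2)/d} \approx 0.09$ mid-simplex,
  so per-call mean absolute errors sit near 0.04–0.06 per component;
  group-pooled estimates (3 samples) drop under 0.05. Tests and the
  acceptance report quote the per-call figure.
* **Boundary behavior.** Extension stops at the first failing site, so
  emitted regions may carry one or two trailing/leading
  noise-concordant sites; with 12-site islands and 10-site planted
  runs the creep is bounded and about three quarters of recovered
  regions are within one site of the planted boundary.
* **Problem sizes.** The shipped tests and the acceptance script run
  the study at desk scale: two chromosomes of 1–3 Mb, 1,400–4,200 CCGG
  sites, 50–100 planted regions, 2,000 genes, chosen so every stage
  exercises its logic with comfortable statistical margins.
* **Degenerate inputs.** All-zero count columns are rejected;
  chromosomes with fewer than 5 sites yield no regions; empty region
  or DhMR lists give NA percentages; features with no inspected sites
  report missing ratios; constant genes get P = 1.
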