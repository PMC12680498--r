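---
title: "Methods: from pan-genome variants to candidate trait genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pan-genome variants to candidate trait genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panvine)
```

# The problem

Some grapevine cultivars flower and fruit continuously through the season
while most concentrate reproduction into one window. `panvine` implements an
integrative strategy for nominating the genes behind such a cultivar-specific
trait. Three independent evidence tracks are combined:

1. **Focal-unique structural variants.** A pan-genome graph built from the
   focal cultivar plus a panel of haplotype-resolved genomes is decomposed
   against the focal genome, yielding a multi-sample VCF. Sequence private to
   the focal cultivar shows up as records where every panel haplotype is
   homozygous for the alternate allele.
2. **Cross-cultivar differential expression.** Single-nucleus RNA-seq of the
   same tissue in the focal cultivar and a control cultivar, clustered into
   cell populations, with per-cluster two-sample tests.
3. **Co-expression of the survivors.** Genes that lie near a focal-unique SV
   *and* are differentially expressed are the candidates; their TPM profiles
   across bulk developmental stages are rank-correlated to expose modules.

A hemizygosity track (genes present on only one haplotype, detected via
fully containing deletions in long-read SV calls) characterizes the focal
genome itself.

# Calling focal-unique SVs

Records are classified by the maximal allele-length difference $d$ across
ALT alleles: $d = 0$ gives SNP (1 bp) or MNP, $0 < d < 50$ an indel, and
$d \ge 50$ bp a structural variant. A record is a **unique SV** when, in
addition, no genotype token carries a reference allele, none is missing
(`.|.`), and every token is exactly `1|1` (or unphased `1/1`). Multi-allelic
records are evaluated whole: tokens such as `2|2` disqualify a record even
though they are fully genotyped, because the uniqueness rule is defined on
the literal all-`1|1` pattern.

Direction deserves emphasis because it inverts naive VCF reading. The VCF is
decomposed **against the focal genome**, so REF is focal sequence: a REF
longer than the query allele is sequence the panel lacks — a focal
**insertion** — and a longer ALT is a focal **deletion**.
`classify_sv_direction()` implements exactly this convention and refuses
equal-length alleles.

Genotype handling choices: phased and unphased separators are equivalent
(the rule is about token content, not phasing); haploid tokens are rejected
with an error since the panel is defined on haplotype samples; QUAL and
FILTER play no role in uniqueness. Overlapping or nested records from graph
decomposition are *not* deduplicated — each VCF row is judged on its own.

# Hemizygous genes

Long-read deletion calls are filtered on five conditions, all inclusive:
`DEL` type, END present, precise breakpoints, $|\mathrm{SVLEN}| \ge 50$ bp,
QUAL $\ge 60$, and read support $\ge 4$. Support is read from the first
available of the INFO keys `SUPPORT`, `RE`, `DV` (caller dialect drift), and
a record stating neither `PRECISE` nor `IMPRECISE` is treated as precise.
The quality bound is applied to the VCF QUAL column.

A gene is called hemizygous when a filtered deletion fully contains the gene
body. The underlying description of the overlap rule is ambiguous about
direction; a whole-gene hemizygote requires the gene inside the deletion, so
`gene_in_deletion` is the default, with the literal converse
(`deletion_in_gene`) selectable for comparison. Containment is computed with
`GenomicRanges` and is verified in the tests against an all-pairs scan.

# SV–gene linking and enrichment

Genes within 5 kb of a unique SV are linked using end-to-end gap distance
(bedtools-window semantics, inclusive at exactly 5000 bp; overlapping or
bookended intervals get distance 0). Strand affects only the
upstream/downstream annotation, never eligibility. Enrichment of any gene
set against a background uses the upper-tail hypergeometric test per
annotation term with Benjamini–Hochberg adjustment; the term map is supplied
by the user as a plain gene-to-term table, keeping the stage free of
ontology-version dependencies.

# The single-nucleus stage

* **QC**: nuclei with 200–7500 detected genes (inclusive) and fewer than
  15 000 UMIs (strict) are retained; genes with zero remaining counts are
  dropped. The filter is idempotent.
* **Normalization**: $\ln(1 + 10^4 \, c_{gj} / C_j)$ per gene $g$ and cell
  $j$ with cell total $C_j$; zeros stay zero and values depend only on
  within-cell proportions.
* **Variable genes**: per sample, genes are ranked by standardized variance
  (variance of trend-standardized values, loess fit of log variance on log
  mean, clipped at $\sqrt{n}$); samples are combined by best rank so a gene
  highly variable in either cultivar is eligible; the top 3000 are kept at
  full scale.
* **Embedding**: anchor-based integration is out of scope here; instead each
  sample's normalized matrix is gene-scaled within sample (removing
  per-sample location and scale) and the pooled cells enter one PCA. A
  precomputed externally integrated embedding can be passed to the
  clustering step unchanged.
* **Component cutoff**: the smallest $j$ whose cumulative variance fraction
  exceeds 90 % while the next component explains under 5 %; if the retained
  spectrum cannot reach the cumulative bound, the first successive
  difference below $10^{-3}$ (the point where the decay stabilizes) is used.
  The $10^{-3}$ value is a configurable choice; no canonical threshold
  exists for the stabilization signal.
* **Clustering**: Euclidean $k$-nearest neighborhoods ($k = 20$, self
  included), Jaccard-weighted shared-neighbor edges pruned below $1/15$,
  Louvain modularity at resolution 0.4, labels ordered by decreasing size.
  These are the conventional defaults of the toolkit this stage mirrors;
  only the resolution is a study-level parameter.
* **Markers and DEGs**: one-vs-rest (markers, positive-only, min.pct 0.25,
  log2FC 0.25) and per-cluster cultivar-vs-cultivar (DEGs, min.pct 0.1,
  |log2FC| 0.25, two-sided) tests share the same mechanics: an
  expression-fraction screen on $\max(pct_1, pct_2)$, fold change
  $\log_2[(\overline{e^{x}-1}_{in}+1)/(\overline{e^{x}-1}_{out}+1)]$ on
  back-transformed normalized means with pseudocount 1, a Wilcoxon rank-sum
  p-value, and Bonferroni adjustment over the genes tested in the
  comparison. Per-cluster DEG rows are consolidated and also deduplicated to
  gene level, direction taken from the largest-|log2FC| cluster, because a
  candidate list is a list of genes while per-cluster rows retain the
  cell-type context; both tallies are reported.

## The rank-sum test

Group sizes in droplet data are large and ties are pervasive, so the
p-value machinery matters. With tie-free groups and $\min(n,m) \le 8$ the
exact Mann–Whitney null distribution is used. Otherwise a normal
approximation with tie-corrected variance and continuity correction is
applied, **plus an Edgeworth term** using the exact kurtosis of $U$,
$\gamma_2 = -\tfrac{6}{5}\,(n^2+m^2+nm+n+m)/(nm(n+m+1))$. The plain
continuity-corrected normal deviates from the exact tail by up to 0.011 at
$n=m=8$; the kurtosis term brings the worst case below $6\times10^{-4}$,
so the two branches agree to well under 0.01 everywhere.

# Integration and co-expression

Candidates are the deduplicated intersection of SV-linked genes and DEGs,
annotated with both evidence tracks. For co-expression, bulk counts over
developmental stages are TPM-normalized
($\mathrm{TPM}_{gs} = 10^6 \, r_{gs} / \sum_g r_{gs}$ with
$r_{gs} = c_{gs}/(\ell_g/1000)$, $\ell_g$ the annotated gene span — no
effective-length correction), genes containing any zero across samples are
removed (the stricter reading of "exclude rows with zero values"; an
all-zero policy is selectable), and pairwise Spearman correlation with
average ranks is computed. Constant profiles yield undefined coefficients
reported as `NA` with a warning. Display order comes from average-linkage
clustering on $1-\rho$.

# What the synthetic cohort emulates

Every input is generated with known truth so the whole pipeline runs
without downloads:

* **Panel VCF**: planted focal-unique SVs (all tokens `1|1`, $\Delta \ge 50$
  bp, alternating direction, each placed near a distinct known gene) among
  five decoy families that each break the uniqueness rule in exactly one
  way — shared (`0|0`), heterozygous (`0|1`), missing (`.|.`), non-1
  alleles (`2|2`), and sub-threshold length ($\Delta = 49$).
* **SV calls**: planted hemizygous genes fully contained in passing DEL
  records; near-miss decoys violating exactly one filter bound (QUAL 59,
  support 3, imprecise, length 49, absent END, partial overlap).
* **Nuclei**: negative-binomial counts (variance $\mu + \phi\mu^2$,
  $\phi = 0.5$) with log-normal library sizes, equal-proportion cell types
  whose markers are elevated $4\times$, cross-cultivar DEGs shifted
  $2\times$ in every type, and planted QC failures that each break exactly
  one bound. Defaults are 1000 genes and 400 good cells per cultivar — a
  deliberate desk-scale stand-in for the tens of thousands of nuclei a real
  run yields, sized so the per-cluster Bonferroni-corrected test retains
  power at the planted effect. Planted effects are drawn on expressed genes
  (four-fold elevated mean): a fold change on a gene the assay cannot
  detect encodes no recoverable truth for any method.
* **Bulk stages**: planted correlated pairs share a geometrically spaced
  monotone latent profile (successive stage ratios 1.35–1.6) with
  multiplicative log-normal noise; with zero noise the pair members are
  exactly proportional, so their TPM values are monotone transforms of each
  other and their Spearman correlation is exactly 1 regardless of the rest
  of the library. The modest profile magnitude keeps TPM compositional
  coupling from inflating background correlations.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects beyond a per-sample location/scale shift, UMI saturation,
gene-length bias in droplet counts, and genuinely nested or overlapping SV
records. Passing tests therefore demonstrate correctness of the rules and
statistics, not robustness to those artifacts.

# Numerical and design notes

* The generator signature exposes separate marker (`marker_log2fc = 2`) and
  DEG (`deg_log2fc = 1`) effect sizes; one shared dial cannot encode both
  stated study conditions.
* Clustering operates on the component scores. Modularity at resolution 0.4
  fragments genuinely 2-dimensional point clouds (the reference toolkit
  behaves identically on the same fixture), so the worked pipeline applies
  a conventional floor of ten components before building the SNN graph:
  the cutoff rule can nominate a spectrally tiny embedding whose
  neighborhoods are too local to cluster stably.
* All randomness is seeded; rerunning any stage with the same configuration
  and seed reproduces results byte-for-byte (tested).
* Problem sizes used by the shipped checks: panels of 30 haplotypes with
  220 records × 3 replicates; 1000 × 1000 random gene/deletion containment
  scans; 1000-gene × 800-cell expression runs × 3 seeds; 8-stage bulk
  tables. These sizes were chosen as the smallest at which every property
  is informative.

# Known limitations

* The uniqueness rule is record-local; a focal-unique region split across
  several graph-decomposition rows is counted once per row (an optional
  overlap merge is deliberately not applied by default).
* Hemizygosity uses deletion containment only; duplication-mediated dosage
  differences are out of scope.
* The joint embedding removes per-sample location/scale but is not an
  anchor integration; strong cultivar-specific composition shifts would
  mix into the leading components.
* Enrichment treats terms independently (no ontology propagation).
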