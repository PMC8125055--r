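---
title: "Methods: mapping a nucleoid-associated protein regulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a nucleoid-associated protein regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Nucleoid-associated proteins (NAPs) of the H-NS/Lsr2 family bind AT-rich DNA
in GC-rich bacterial genomes, oligomerise along and between DNA segments,
and silence horizontally acquired, compositionally atypical regions
(xenogeneic silencing). Characterising such a regulator requires integrating
several data types: where the protein binds (ChIP sites), what changes when
it is deleted (differential expression between mutant and wild type), the
compositional landscape that attracts it (windowed AT content), and —
because these regulators also remodel the cell envelope programme —
phenotypic readouts such as AFM surface roughness. `napregulon` implements
this integration as a set of small, testable stages over standard file
formats, with a synthetic-data generator that reproduces the statistical
structure the analysis assumes so that every stage can be scored against a
known truth.

All coordinates are handled internally as 0-based half-open intervals. GFF3
(1-based inclusive) is converted on read and reconverted on write; BED
passes through unchanged. A single convention applied everywhere removes
the usual off-by-one ambiguity in window, promoter and overlap arithmetic.

## Regulon calling and direct targets

A gene is in the regulon when its expression changes at least 3-fold between
the deletion mutant and the wild type, i.e. |log2FC| > log2(3) = 1.585
(strict inequality). By default an adjusted-p filter (adj_p ≤ 0.05) is
applied as well, because the upstream differential-expression fit reports
moderated adjusted p-values; the filter can be disabled
(`p_threshold = NULL`) to apply the fold-change rule alone.

Direction is encoded once, from the NAP's perspective: log2FC > 0 in the
mutant means the NAP **represses** the gene; log2FC < 0 means it
**activates** it. Summaries also render the complementary vocabulary
(fraction of genes with decreased transcription in the mutant), which is
numerically identical under this encoding. Reported percentages round half
away from zero, the convention that reproduces the usual hand-rounded
figures (51/71 → 72%, 57/124 → 46%).

A regulon gene is a **direct target** when at least one binding-site
interval overlaps, by ≥ 1 bp, the strand-aware promoter window: the 150 bp
immediately 5′ of the start codon, `[start − 150, start)` for `+` genes and
`[end, end + 150)` for `−` genes, clipped at contig edges. A binding site is
an interval, so any-overlap is the natural reading of "binding site within
150 bp upstream"; a midpoint-containment variant would be stricter and is
not what an interval-valued site supports. Assignment never changes regulon
membership, only the direct/indirect mode and the list of supporting sites.

## Binding-site architecture and spacing

Each site is reduced to a reference point — its midpoint,
`floor((start + end)/2)`, by default; start or end are selectable — and
classified against the gene models: *intragenic* if the point lies in a
gene body (ties go to the containing gene with the smallest start), else by
the strands of the nearest flanking genes: tandem (same strand), convergent
(`+`,`−`: 3′ ends facing the site), divergent (`−`,`+`: 5′ ends facing the
site), or *terminal* when only one flank exists. An any-overlap intragenic
mode is available for comparison, since a site straddling a gene boundary
is assigned differently under the two readings.

Nearest-site spacing is midpoint-to-midpoint: per contig, each site
contributes the distance to its closest neighbour, pooled across contigs.
Quartiles use Tukey hinges by default (`stats::fivenum`), i.e. Q1 is the
middle number between the smallest value and the median and Q3 the middle
value between the median and the largest; an interpolated alternative
(`stats::quantile` type 6, the (n+1)p rule) is selectable because the two
differ on small samples (on 1…5: hinges give 2/3/4, interpolation
1.5/3/4.5). The bridged-gene estimate converts the spacing IQR into gene
counts by integer division with the average gene length (946 bp for
*M. smegmatis*): `floor(q/946)` whole genes inside a loop of span `q`, so an
IQR of 1,933–15,390 bp corresponds to 2–16 genes. Chromosomes are treated
as linear by default; a circular mode with wraparound distances exists but
is off, matching the linear-coordinate convention of the analyses this
package reproduces.

## AT landscape and promoter composition

The AT landscape tiles each contig from offset 0 with 500-bp windows at a
500-bp step (both configurable); a trailing fragment shorter than the
window is dropped so every window carries an equal-width statistic. N bases
are excluded from the denominator rather than counted as GC, and an all-N
window gets an undefined fraction. "AT-rich" has no canonical numeric
definition, so the default region-calling threshold is the genome-wide mean
window AT plus two SDs of the window statistic — a documented default, not
a literature value — and maximal runs of consecutive qualifying windows are
merged into regions.

Promoter composition compares per-promoter AT fractions of the directly
regulated genes against `n = 50` randomly chosen promoters (drawn uniformly
without replacement, excluding the regulated set so the null is
uncontaminated; the exclusion can be disabled by passing an empty exclusion
set). Promoter length defaults to 150 bp for consistency with the
direct-target rule. The default test is a two-sided Welch t on the
per-promoter fractions; a pooled-variance t and a permutation test
(≥ 10,000 label shuffles, p = (1 + #extreme)/(1 + #permutations)) are
available. Positional profiles report per-position AT frequency with
position −1 adjacent to the start codon.

## Surface roughness

Ra is the arithmetic mean deviation of a height profile:
Ra = mean(|z − mean(z)|) over the samples of one 500-nm scan line. The
reference is the profile mean; an optional linear detrend handles tilted
scans but is off by default, since the plain arithmetic-mean-deviation
definition makes no detrending assumption. A cell's Ra is the unweighted
mean over its 3–4 lines (line counts differ per cell; no stated weighting
scheme exists, and equal weights are the neutral choice). Strains are
compared with a two-sided two-sample t-test with pooled SD on per-cell Ra
(df = n₁ + n₂ − 2); if both groups are degenerate with zero variance and
equal means, p = 1 by convention.

For Gaussian height noise with SD σ, E[Ra] = σ·√(2/π); the generator
inverts this to draw line noise at σ = Ra·√(π/2) for a target per-cell Ra,
and the test suite checks the closed form to within 2% on 10,000-sample
profiles.

A power remark the test suite makes explicit: at per-cell Ra of
3.33 ± 1.81 nm vs 4.68 ± 1.25 nm with 50 cells per group, the pooled-t
noncentrality is ≈ 4.34 and the probability that a single replicate reaches
the strict p < 0.0005 level is ≈ 0.77 (noncentral-t closed form, matched by
simulation in the tests). A single observed comparison at these parameter
values can be — and here is — significant at that level, but replicates
should be expected to reach it only about three times in four; at the
conventional 0.05 level the separation is detected essentially always.

## The synthetic-data generator

The generator produces desk-scale inputs with the structure the analysis
assumes, plus truth tables sufficient to score every stage. Scale defaults:
one 200-kb contig, 200 genes, 30 direct targets, 150 background sites —
small enough that the full chain runs in seconds. Design choices, each made
once:

* **Genome**: i.i.d. bases at 67% GC (the mycobacterial regime) outside ten
  non-overlapping 2-kb islands whose AT fraction is 0.55 — AT-rich enough
  to stand ~5 SD above the window-AT distribution, while staying in the
  range observed for horizontally acquired DNA in high-GC hosts.
* **Annotation**: non-overlapping genes with lengths drawn around 946 bp
  (SD 250, floor 150) and then rescaled so total coding space is exactly
  `n_genes × 946` — coding density is a fixed property of a genome, and
  without pinning it the intergenic budget would drift with the length
  draw. The remaining space becomes positive intergenic gaps; gaps inside
  AT-rich islands receive 8× the expected width, reflecting the sparser
  annotation of horizontally acquired islands and leaving room for the
  extensive intergenic binding observed there.
* **Sites**: widths 15–40 bp (summit-scale calls), pairwise disjoint with
  ≥ 5 bp separation. Each direct target gets one site wholly inside its
  promoter window; direct targets are drawn with probability ∝
  exp(10 × promoter AT), emulating a silencer that targets AT-rich
  promoters. Background sites are placed by enumerating all feasible slots
  in the free intergenic space (gaps minus the promoter windows of
  regulated genes minus already placed sites) and sampling slots with
  probability ∝ exp(12 × segment AT); 15% of background sites go inside
  gene bodies instead. Regulated genes are chosen with pairwise-disjoint
  promoter windows, and no background site may touch any regulated
  promoter window — together these make the planted direct/indirect split
  exactly recoverable, which the tests require (precision = recall = 1).
* **Expression**: regulated genes get |log2FC| = 1.585 + 0.1 + Γ(2, 2)
  (strictly above the cutoff), repressed with probability 0.9 under the
  default silencer-like mix, and adj_p = 10^−U(4,10); noise genes get
  log2FC ~ N(0, 0.4) truncated to ±1.5 and adj_p ~ U(0,1), so no noise gene
  can cross both thresholds.
* **Roughness**: per-cell target Ra ~ N(group mean, group SD) with defaults
  4.68 ± 1.25 nm (wild type) and 3.33 ± 1.81 nm (mutant), 50 cells per
  group, 3 or 4 lines per cell, 256 samples per line.
* **Seeding**: a master seed fans out to fixed per-component child seeds,
  so regenerating one file never shifts the others; every generator
  restores the caller's RNG state.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level noise and peak-calling uncertainty
(sites are planted, not called), operon structure (each gene is scored by
its own promoter, whereas real regulons propagate through operons),
correlated composition (real AT varies smoothly; the background here is
i.i.d.), condition kinetics (the hypoxia-like comparison differs only in
target counts and sign mix), and any spatial correlation in AFM noise.
Exact direct-target recovery on this generator demonstrates the
correctness of the interval arithmetic and thresholds, not robustness to
real ChIP noise.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full default scale
(200 kb) once and otherwise use 20–100-kb genomes, 100–500-site instances,
10,000-sample Ra profiles, 100–1,000 t-test replicates, and 2,000–10,000
permutation shuffles — sizes chosen so each property is measured with
comfortable margin while the whole suite stays interactive. Other
conventions: auto-assigned site ids are `peak_0001`-style in file order;
empty inputs yield empty outputs with warnings where recoverable and errors
where a statistic would be undefined; percentages are integers (half away
from zero); permutation p-values are never exactly zero by construction.

## Known limitations

Flanking-gene classification considers only the nearest flank on each side,
so nested or overlapping gene models (rare in bacteria) are resolved by the
tie rule rather than modelled; the replicate-intersection helper reports
overlap spans of the first replicate only; and the pipeline treats the
annotation file as authoritative for gene models, making no attempt to
reconcile annotation releases.
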