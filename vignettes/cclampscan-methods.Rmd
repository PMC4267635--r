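---
title: "Methods: degenerate-motif occupancy and co-occurrence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degenerate-motif occupancy and co-occurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Background and scope

LEF/TCF transcription factors carry a High Mobility Group (HMG) box that
recognizes the Wnt Response Element (WRE, `CTTTGWWS` in IUPAC notation),
and E-tail isoforms add a second, zinc-binding DNA-binding domain — the
C-clamp — that recognizes the GC-rich Helper site (`RCCGCC`; short form
`RCCG`). `cclampscan` implements the computational side of asking what
such a secondary domain does to genome-wide occupancy: where the two
motifs co-occur beyond chance, whether Helper copy number tracks
occupancy strength, whether spacing or orientation between the motifs is
constrained, and whether motif content of bound regions predicts which
nearby genes change transcription when the factor is induced.

The package works from called peak lists (BED), sequences (FASTA), a
minimal gene-model table and a per-gene differential-expression table.
Read alignment, peak calling, de novo motif discovery and
differential-expression testing are out of scope; they are consumed as
inputs. Because the genome-scale numbers of any particular experiment
depend on raw reads and external callers, validation here is
property-based: exact small-sample oracles, closed-form background
checks, and recovery of structure planted by the package's own
synthetic-data generator.

## Motif scanning

Scanning is exhaustive and deliberately simple. For a pattern of length
$m$ over a sequence of length $L$, every one of the $L-m+1$ windows is
tested on the forward strand against the pattern and on the reverse
strand against the reverse-complemented pattern; minus-strand hits are
reported with the leftmost coordinate on the forward sequence so that a
single coordinate system serves spacing and positional analyses.
Overlapping occurrences are counted (nothing in the incidence definition
collapses them), and a window matching on both strands counts twice —
scan counts are per-strand binding-site events. In the differential
k-mer analysis, by contrast, each k-mer window counts once for its
canonical (strand-unified) class, because that table is per-site. An `N`
base matches no motif symbol, so assembly gaps can only remove hits.

Per-peak *incidence* is the both-strand occurrence count divided by the
peak length. The positional-weight-matrix scanner scores windows by
log-odds against a nucleotide background (by default estimated from the
scanned sequence set, since no background is otherwise given) and calls
hits at a configurable fraction (default 0.8) of the maximum attainable
score; with a matrix built from a non-degenerate consensus and threshold
1 it reproduces the exact-pattern scan, which is pinned by a test.

## The co-occurrence background model

The central statistic is a Table-style comparison: among the top $K$
peaks, how many contain at least one WRE *and* at least $N$ Helper
sites, versus how many would by chance. Chance is modelled per peak:
with background base frequencies $f$ (estimated from the analyzed peak
sequences, so GC composition is accounted for; uniform and user-supplied
backgrounds are options), a window matches a degenerate pattern with
probability
$$p = \prod_{j=1}^{m} \sum_{b \in S_j} f_b,$$
where $S_j$ is the base set admitted by the $j$-th IUPAC symbol. The
number of occurrences in a peak of length $L$ is approximated as
$X \sim \mathrm{Binomial}\!\left(2(L-m+1),\, p\right)$ — both strands
contribute windows, and windows are treated as independent. For
backgrounds that are not complement-symmetric the forward and
reverse-complement pattern probabilities differ, and the two binomials
are convolved exactly rather than merged.

The per-peak probability of the joint event is
$q_i = P(\mathrm{WRE} \ge 1 \mid L_i)\, P(\mathrm{Helper} \ge N \mid L_i)$,
and the expected count is $\sum_i q_i$. The p-value for the observed
count is the exact upper tail of the Poisson-binomial distribution over
the $q_i$, computed by $O(K^2)$ convolution with clipping to $[0,1]$
after each step; the DP is verified against exhaustive $2^K$ enumeration
to $10^{-12}$. A `fixed_length` switch replaces per-peak lengths with
the mean length, reducing the model to a single binomial, because it is
not knowable whether a given published table used per-peak lengths; the
per-peak variant is the default as the strictly more faithful model.

The known approximation is window dependence: overlapping windows are
not independent, and motif self-overlap slightly clumps occurrences.
The test suite bounds the resulting error two ways: closed-form
containment probabilities agree with 10,000-sequence Monte Carlo within
three standard errors, and on 500 replicated null peak sets (no planted
motifs, 250 peaks of 400 bp at 41% GC) the fraction of co-occurrence
p-values below 0.05 stays within [0.02, 0.09].

## Comparative occupancy

Matched regions between two peak sets are all pairs with at least one
shared base (half-open intervals; adjacency is not overlap). For paired
score tests each first-set peak keeps only its maximum-overlap partner,
avoiding pseudo-replication when one peak spans several in the other
set; all pairs are retained for overlap and spacing outputs. Strength
classes use a symmetric, scale-free ratio band: `a_stronger` at ratio
$\ge 1.5$, `b_stronger` at $\le 1/1.5$, otherwise `similar` (the band is
configurable; no published definition of "similarly enriched" exists to
match). The paired comparison defaults to the Wilcoxon signed-rank test
since scores are matched per region; the unpaired Mann-Whitney variant
is available behind a flag because published legends sometimes name the
unpaired test for such panels. Neither is claimed to reproduce any
specific published p-value.

Both rank tests are implemented in the package with midrank tie
handling: exact permutation enumeration for small samples (pooled
$n \le 12$ for Mann-Whitney, $n \le 15$ pairs for the signed rank) and
the tie-corrected normal approximation (no continuity correction)
otherwise. `stats::wilcox.test` is used in the test suite as an
independent oracle, never as the implementation, so the exact-path
semantics stay under the package's control.

WRE-Helper spacing is measured edge to edge (published descriptions of
composite elements count nucleotides *between* motifs), signed relative
to the WRE hit's strand: positive means the Helper lies 3' of the WRE in
the WRE's orientation. For overlapping hits the gap is still computed
from edges and is negative. Orientation is `same`/`opposite` by strand
equality. Motif-center histograms use integer conventions pinned by
tests: peak center $\lfloor (start+end)/2 \rfloor$, motif center
$start + \lfloor m/2 \rfloor$.

## Annotation

Two promoter definitions coexist deliberately, as both are standard in
this analysis style: a 4 kb window centered on the TSS for feature
annotation, and a $-1000/+100$ bp window for promoter motif-density
comparisons. Feature assignment is decided on the peak center with
precedence promoter > exon > intron > other (near the transcript end) >
intergenic, which guarantees exactly one category per peak; windows are
half-open, so a center exactly at TSS + half-width falls outside. The
precedence order is a declared convention of this package, not a claim
of equivalence to any particular published annotator. Signed TSS
distances flip with gene strand so that positive always means
downstream.

## Expression integration

Regulated genes use strict inequalities (`p < cutoff`,
`log2FC < 0` or `> 0`), so a zero fold change is in neither set. Peaks
link to every gene whose TSS lies within the distance cutoff
(default 30 kb, inclusive) of the peak center, subject to a strict score
cutoff (default 67, matching a "score > 67" selection rule). The
hypergeometric overlap test uses the detected-gene universe (all genes
in the expression table), which avoids inflating significance with
never-detected genes. The gene-set enrichment statistic is the
unweighted running sum (+1/|subset| on hits, −1/(n−|subset|) on misses)
with ES the maximum deviation from zero, and a gene-set permutation
null compared one-sidedly in the direction of the observed ES — the
simplest defensible GSEA variant, chosen because weighting and
permutation scheme are otherwise unconstrained; the permutation p uses
+1 smoothing and an exhaustive-enumeration mode replaces it exactly for
short lists. A gene's motif class is the strongest class among its
linked peaks (none < helper_only < wre_only < both < both_multi_helper,
the last requiring one or more WREs and two or more Helpers in the same
peak), so a single strong composite peak determines the gene's class;
classes with fewer than three genes are reported but never tested.

## The synthetic-data generator

The generator emulates the statistical structure every stage assumes,
with exact ground truth: planting overwrites genome bases, so every
planted motif is recoverable by the scanner at its recorded position
(a property the suite asserts at 100%).

Defaults, chosen once as a plausible two-condition design at desk scale:
a 2 × 1 Mb genome at 41% GC (human-like composition), 200 genes placed
non-overlapping with alternating strands, 1000 peaks per set with
lengths uniform in 300-700 bp, and 60% of regions shared between the
sets. WRE planting is 0.35 per peak in both sets (the primary domain is
intact in both conditions); Helper planting is 0.2 in WT-unique regions
versus 0.05 in mutant-unique regions. Shared regions are planted once,
with the WRE probability of both sets and the *mutant* Helper level, and
the mutant peak inherits whatever falls inside its jittered interval:
co-bound regions model WRE-driven sites, and planting shared regions
independently at the WT Helper level would erase the between-set Helper
contrast that the design exists to create. Helper clusters draw copy
numbers from {1: 0.5, 2: 0.3, 3: 0.12, 4: 0.05, 5: 0.03} and are
anchored at the planted WRE when one exists (signed edge gaps uniform on
±1..11 bp, the flexibility range reported for composite elements),
otherwise near the peak center. Scores are
$\mathrm{base} + 5 \times \mathrm{copies} + \mathcal{N}(0, 3)$, floored
at 1, with the copy coefficient 0 for the mutant set (its secondary
domain cannot read Helpers; base 50 for WT, 35 for the mutant).
Expression is $\log_2 FC = \mu_{\mathrm{class}} + \mathcal{N}(0, 0.3)$
with class means {none: 0, helper_only: −0.05, wre_only: −0.3, both:
−0.6, both_multi_helper: −1.0} and p-values from a two-sided Gaussian
test against the noise SD. Note the implied selection power: at effect
1.0 and SD 0.3 a two-sided 0.02 threshold selects ~84% of affected
genes — not more — and the suite asserts that closed-form value.

What the generator does **not** emulate: read-level noise, peak-calling
artifacts, chromatin state, enhancer looping, motif clustering beyond
the planted composites, and realistic peak sparsity (1000 peaks on 2 Mb
is far denser than a real genome, so nearly every gene has linked
peaks). Passing the recovery tests therefore demonstrates that the
statistics detect the structure they are designed to detect at
realistic effect sizes — not that any particular biological dataset
would reproduce specific values.

## Replicated validation sizes

The statistical acceptance checks run at sizes chosen for adequate
power at desk scale, stated here as the package's own design: scanner
oracle equivalence on 1000 random sequences (lengths 10-500) for all
four built-in motifs; null calibration on 500 replicates of 250 × 400 bp
peaks; planted co-occurrence on 100 replicates of 100 × 500 bp peaks per
condition (20% joint WRE + 2-Helper planting for WT; independent 5%
WRE and 5% Helper planting for the mutant condition, whose excess over
background is then weak by design); copy-number structure recovery on
100 replicates of 250 shared regions; and class-association recovery on
100 replicates of 100 genes per class. The mutant planting choice
follows from a power analysis of the binomial background: at 100 peaks
of 500 bp and 41% GC the expected background co-occurrence count at
$N = 2$ is ~0.2 and the planted contribution ~0.8, so the exact tail
test should usually (but not always) stay above p = 0.001 — mirroring a
condition with a real but weak composite-element excess.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open throughout; 1-based values appear only
in labelled report columns. Peak ranking breaks score ties by (chrom,
start) so top-K selection is deterministic. Probabilities in the
Poisson-binomial DP are clipped to [0,1] each step; comparisons against
enumeration hold to 1e-12. Peaks shorter than a motif contribute zero
containment probability (with a warning) and zero counts. Empty
strata/classes are reported with size 0 and skipped by tests. All
generator randomness derives from a single integer seed with fixed
stage offsets, and the GSEA permutation path saves and restores the
global RNG state, so pipeline reruns are byte-identical.

## Known limitations

The background model ignores window dependence (no Goulden-Jackson
correction) and uses a 0-order nucleotide background; dinucleotide or
Markov backgrounds would better model CpG-depleted genomes. The
annotator ignores UTRs unless exon structure implies them. The GSEA
implementation is the unweighted statistic only. Long-range regulation
is represented only through the distance cutoffs (30/50 kb); genes
regulated from further away are invisible to the linking stage, a
limitation shared with the analysis style it implements.
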