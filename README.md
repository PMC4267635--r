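# cclampscan

Occupancy analytics for transcription factors with two DNA-binding
domains, built around the LEF/TCF system: the HMG box reads the Wnt
Response Element (WRE, `CTTTGWWS`) while the alternatively spliced
C-clamp domain reads the GC-rich Helper site (`RCCGCC`, short form
`RCCG`). Given two ChIP-seq peak sets — a wild-type factor and a
C-clamp DNA-binding mutant — plus sequences, gene models and a
nascent-transcription fold-change table, the package quantifies what
the secondary domain contributes: motif content and incidence,
WRE/Helper co-occurrence beyond chance, occupancy-strength differences
at co-bound regions, motif spacing/orientation, feature annotation, and
the link from motif classes of bound regions to transcriptional
downregulation.

## The core statistic

For each peak of length $L$ and a degenerate pattern of length $m$, the
occurrence count under the background is modelled as

$$X \sim \mathrm{Binomial}\big(2(L-m+1),\ p\big), \qquad
p = \prod_{j=1}^{m} \sum_{b \in S_j} f_b,$$

where $S_j$ is the base set admitted by the $j$-th IUPAC symbol and $f$
the background base frequencies (estimated from the analyzed peaks by
default, so GC content is accounted for). The number of peaks expected
to carry at least one WRE and at least $N$ Helper sites is
$\sum_i q_i$ with
$q_i = P(\mathrm{WRE}\ge 1)\,P(\mathrm{Helper}\ge N)$, and the observed
count is tested against the exact Poisson-binomial upper tail over the
$q_i$ (O(K²) convolution, verified against exhaustive enumeration).
Everything else — rank tests with exact small-sample enumeration,
hypergeometric overlaps, an unweighted peak-score GSEA — supports that
comparison. See `vignettes/cclampscan-methods.Rmd` for the model
assumptions and design choices.

## Worked example

The repository is organised as an analysis workflow over the package:
`analysis/01_simulate.R` … `analysis/06_integrate_expression.R` run the
whole study on a synthetic fixture with exact ground truth (planted
motifs, copy-number-dependent scores, class-dependent downregulation)
and write their tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_cooccurrence.R
```

prints, for the default seed:

```
WT peaks: 1000 (332 with planted WRE, 105 with planted Helper)
mut peaks: 1000 (323 with planted WRE, 53 with planted Helper)
...
   condition n_peaks_with_wre helper_threshold ... expected_both observed_both  p_value
1         WT              496                1          2.40e+01           131 3.62e-55
2         WT              496                2          2.30e+00            38 4.53e-33
```

i.e. 496 of the top 1000 WT peaks contain a WRE; 131 also contain a
Helper site where ~24 would by chance, and the excess grows more
extreme (relative to expectation) at higher Helper copy numbers — the
co-occurrence signature of a functional C-clamp. Stage 4 shows the
occupancy consequence at co-bound regions (score differences grow with
Helper copy number):

```
  bin   n median_diff mean_diff
1   0 564        15.1      15.3
2   1 128        16.3      16.1
3 2-3  40        20.2      19.9
4  4+  16        33.4      29.2
```

and stage 6 stratifies downregulation by the motif class of each gene's
linked peaks (score > 67, TSS within 30 kb), with genes near
WRE + multi-Helper peaks most strongly repressed:

```
        motif_class  n median_log2fc
1 both_multi_helper 39        -0.877
2       helper_only 28        -0.496
```

The same machinery is exposed as functions for real data:
`read_bed()` / `read_fasta()` / `extract_peak_sequences()` →
`profile_peaks()` → `cooccurrence_table()`, `classify_strength()`,
`assign_features()`, `link_peaks_to_genes()`,
`motif_class_association()` — or in one call, `run_pipeline()`.

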