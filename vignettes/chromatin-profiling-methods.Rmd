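---
title: "Methods: spike-in normalized coverage, metagene and exon/intron profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalized coverage, metagene and exon/intron profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromprofiler)
```

# The analysis this package implements

Histone marks deposited co-transcriptionally — H3K36me3 above all — have a
characteristic genomic signature: enrichment over gene bodies rather than
promoters, a skew toward the 3' end of genes, and preferential accumulation
over exons relative to introns. `chromprofiler` implements the downstream
quantification of that signature from aligned ChIP-seq read summaries and
gene models:

1. **Normalized coverage tracks.** Single-end reads are modeled as 5'-anchored
   records extended to a fixed fragment length (150 bp by default, matching
   typical sonicated chromatin fragments sequenced at 50 bp). Depth
   normalization is reads-per-million (factor $10^6/N_\text{primary}$);
   between-sample normalization uses an exogenous spike-in genome (factor
   $10^6/N_\text{spike-in}$), which keeps signal comparable when the global
   mark level itself changes between conditions — precisely the regime where
   per-sample RPM is misleading. A pseudocounted track ratio
   $(x+\varepsilon)/(y+\varepsilon)$ supports histone-density correction
   (e.g. the mark over total H3).

2. **Metagene profiles.** Each selected gene is mapped onto 500 bins: 100
   fixed 20 bp bins over the 2 kb upstream of the TSS, 300 near-equal bins
   over the gene body, 100 fixed bins downstream of the TES. Genes qualify
   when they are protein-coding, at least 600 bp long (so each body bin is at
   least 2 bp), and have no other annotated gene within the 2 kb flanks. The
   profile is the equal-weight mean of per-gene bin means. A scalar summary,
   the *body skew*, is the $\log_2$ ratio of the mean over the 5' half of the
   body bins to the 3' half.

3. **Exon/intron enrichment.** One transcript per protein-coding gene (the
   longest; ties broken by smallest id), with transcripts whose spans overlap
   any other selected transcript removed, strand ignored, both members of a
   pair. Two estimators are computed: the *pooled* average (total signal over
   total length, exons vs introns, and their ratio) and the *per-transcript
   score* (mean exon signal / mean intron signal). Both are reported because
   they weight transcripts differently: the pooled estimator is dominated by
   long features, the per-transcript score treats each transcript equally.

4. **Feature annotation of peaks.** Externally called peaks are assigned to
   {Intergenic, 5UTR, 3UTR, Exon, Intron} by the first category in that
   priority order with nonzero overlap. The priority is applied literally —
   a peak spilling one base past a gene end is Intergenic. This mirrors the
   annotation option order used with broad gene-body marks; because common
   annotators may internally reorder categories, the priority is a
   configurable argument and the default is documented as a deliberate,
   literal contract.

5. **Expression and splicing linkage.** Genes are stratified by TPM
   (protein-coding: low $0<\mathrm{TPM}\le 2$, high $\mathrm{TPM}\ge 4$;
   lncRNA: low $0<\mathrm{TPM}\le 0.1$, high $\mathrm{TPM}\ge 0.5$; silent
   and gap genes in neither), gene-body signal is summarized per stratum as
   Tukey boxplot statistics, and rMATS-format differential-splicing tables
   are filtered at FDR $\le 0.05$ (expression tables additionally at fold
   change $\ge 2$, i.e. $|\log_2\mathrm{FC}|\ge 1$, boundaries inclusive) to
   build Up/Down gene sets whose enrichment scores are compared.

# Coordinate and numerical conventions

* All internal coordinates are 0-based half-open (BED convention); GTF I/O
  converts at the boundary. This keeps bin arithmetic and overlap tests free
  of off-by-one cases.
* Body bin boundaries sit at $\mathrm{round}(i\cdot L/300)$ for
  $i = 0..300$: widths differ by at most 1 bp and a 600 bp gene gets exactly
  2 bp bins. `round()` follows IEC 60559 (ties to even); boundary positions
  are therefore deterministic but not mirror-symmetric for arbitrary $L$ —
  mirror symmetry is exact when $L$ is a multiple of 300, which is how the
  orientation test pins it.
* Normalized values are computed as `depth * 1e6 / n` in one correctly
  rounded division, so integer duplication of all reads and counts reproduces
  a spike-in track bit-for-bit.
* The ratio pseudocount defaults to $\varepsilon = 0.5$ (half a read), shared
  between `ratio_track()` and `body_skew()`; the published track-ratio
  methods do not state a zero-handling rule, so the choice is explicit and
  configurable. Per-transcript enrichment uses no pseudocount by default:
  transcripts with no introns or zero intron signal are counted and excluded
  rather than nudged, because the score is a plain ratio; an
  $\varepsilon$-variant is available for sparse tracks.
* Reads whose extension crosses a chromosome edge are clipped, not rejected.
  Genes whose full $\pm 2$ kb metagene window leaves the chromosome are
  dropped from profiles with a warning; bins that merely cross an edge
  contribute clipped means.
* Tie-breaks: equal-length transcripts resolve to the lexicographically
  smallest id. Quartiles interpolate linearly between order statistics
  (`stats::quantile` type 7, the common plotting default; configurable).
  Whiskers run to the fence values $Q_1 - 1.5\,\mathrm{IQR}$ /
  $Q_3 + 1.5\,\mathrm{IQR}$ capped at the data range.

# The synthetic study conditions

Every stage is exercised against generated data with known ground truth; no
external downloads are involved. The generator was parameterized once, to be
compact enough for routine testing while structurally faithful:

* **Genome**: 2 chromosomes of 3.5 Mb, 300 genes placed sequentially with
  alternating strands; 2–9 exons of 150–900 bp per transcript, introns of
  400–3000 bp, intergenic gaps of 500–8000 bp. Gaps below 4 kb create genuine
  violations of the metagene isolation filter; two nested antisense gene
  pairs give the strand-ignored overlap removal true positives; about 30% of
  genes carry a second, shorter transcript so longest-isoform selection has
  work to do; 10% of genes are lncRNA. Feature lengths sit at the compact end
  of the mammalian distributions (real median exon ≈ 140 bp, median intron
  ≈ 1 kb) so that a full run stays in seconds.
* **Signal**: expected extended-fragment coverage inside a gene is
  $\lambda(x) = d \cdot t_g^{c} \cdot \rho^{[x \in \text{exon}]} \cdot
  (1 + \gamma\,(p(x)/L - 1/2))$ with intron depth $d = 30$, exon:intron ratio
  $\rho$, 5'→3' position $p(x)$, gradient $\gamma \in [-1, 1]$ ($\gamma > 0$
  raises the 3' end, the canonical skew), and optional TPM coupling
  $t_g^{c}$. Intergenic background is $0.05\,d$. Spike-in reads are counts
  only (10% of the total by default) — only the count enters the
  normalization factor, so no spike-in coordinates are simulated.
* **Noise routes.** `noise = "none"` returns $\lambda$ itself, making
  recovery targets exact: every multi-exon transcript scores exactly $\rho$,
  and the pooled ratio is exactly $\rho$. `noise = "poisson"` draws
  independent per-base Poisson counts with mean $\lambda$ — an unbiased
  counting-noise realization of the extended-fragment coverage. A separate
  read-level route (`emit_reads = TRUE`) samples 5'-anchored fragment starts
  at rate $\lambda/\mathrm{ext}$ with random strand; its pileup is $\lambda$
  convolved with the fragment-length kernel, which blurs exon/intron
  boundaries by up to the fragment length. The recovery tests therefore use
  the track-level routes; the read route exercises the pileup code path
  (extension direction, clipping, mass conservation).
* **Skew calibration.** The body-skew tests run at $\rho = 1$: with exon
  enrichment active, asymmetric exon placement contributes its own 5'/3'
  asymmetry, and a zero-gradient profile is legitimately non-flat. At
  $\rho = 1$ the gradient is the only asymmetry, the zero-gradient skew is
  exactly 0, and the skew is strictly monotone in $\gamma$.

What the generator does *not* emulate: mappability and GC artifacts,
duplicate reads, fragment-length variation, chromatin-state autocorrelation
(noise is independent per base), overdispersion beyond Poisson, and
realistic full-length mammalian genes. Passing tests therefore demonstrate
correctness of the estimators and the selection logic under controlled
conditions, not robustness to every artifact of real libraries.

# Problem sizes

Tests run the generator at 30 genes on one 0.6 Mb chromosome; the
acceptance-level checks and the `analysis/` drivers use the full default
(300 genes, 2 × 3.5 Mb), giving ~180 metagene-eligible genes and ~270
selected transcripts — enough for stable medians while a complete run of the
suite plus drivers stays under a few minutes on one core.

# Design choices made where the specification of the published analysis is open

* *"No other genes within −2 kb TSS / +2 kb TES"* is read literally: the
  flank-extended window must not intersect any other gene's annotated span,
  any biotype, either strand; windows are clipped at chromosome bounds before
  the test.
* *"Removed any overlapping transcripts"* removes both members of an
  overlapping pair. Keep-one variants need an arbitrary winner; symmetric
  removal is deterministic and order-free.
* Gene length for the 600 bp filter is annotated span (TES − TSS), not
  summed exon length, because body binning operates on the span.
* Genes are equally weighted in profiles (mean of per-gene bin means), the
  standard metagene convention; no read-count weighting.
* Whether published metagene panels used RPM or spike-in tracks per panel is
  not always stated; every profile records its track's normalization tag and
  the pipeline accepts either.
* Fig-level estimator ambiguity (pooled ratio vs per-transcript score) is
  resolved by implementing both and reporting both.
* Expression-linked signal uses the gene-body mean, not peak-restricted
  signal.

# Known limitations

* Single-end, fixed-extension reads only: no paired-end fragment inference,
  duplicate marking, or mapping-quality filtering.
* Peak calling, alignment, differential expression and splicing testing are
  consumed from external tools, never reproduced.
* The literal Intergenic-first priority can differ from annotators that
  internally re-rank categories; results on peaks straddling gene boundaries
  depend on this choice (it is a parameter).
* Annotation-release-dependent quantities (gene and transcript counts passing
  the filters on a specific reference) are functions of that reference and
  are not targets of the test suite.
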