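---
title: "Comparing two whole-transcriptome RNA-Seq libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two whole-transcriptome RNA-Seq libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarseq)
```

# Scope and model of the data

`tarseq` analyses a pair of strand-specific, rRNA-depleted RNA-Seq
libraries — one per biological state, with no replicates — after
alignment. The motivating design is a trisomic versus euploid
comparison, where one chromosome is present at 1.5 copies in the case
sample, but nothing in the machinery is specific to trisomy: the case
state is simply "sample A".

The unit of input is the *uniquely assigned read* (UAR): an aligned
read with a single accepted genomic location, represented as a
BED-style record (chromosome, 0-based half-open interval, strand,
sample label). Reads that align to exon–exon junction references are
not genomic intervals; they arrive as per-junction count tallies keyed
to a junction library. A read is genome-assigned or junction-assigned,
never both, so no count is duplicated downstream.

All interval data in the package are 0-based and half-open (BED
convention); `GRanges` is used internally for interval arithmetic
only.

# Annotation revision

Overlapping gene models make "the count of gene X" ambiguous.
`revise_annotation()` resolves this by merging same-strand genes with
overlapping spans into a single *family locus* and fragmenting exons
at every exon boundary within the locus. The resulting *elements*
("exons or parts of exons") are pairwise non-overlapping per strand,
each element belongs to exactly one locus, and the union of elements
equals the union of the input exons. Antisense overlaps are kept
separate: the libraries are strand-oriented, so the two strands carry
independent information. The procedure is idempotent, which the test
suite asserts on random annotations.

From the revised model, `derive_nonannotated_regions()` produces
stranded intronic regions (inR: gaps between consecutive elements
inside a locus span) and intergenic regions (igR: the complement of
locus spans), so that elements, inR and igR tile every strand of every
chromosome exactly — this tiling is what makes the read-conservation
check in the pipeline an exact integer identity rather than an
approximation. `apply_annotation_masks()` subtracts external
annotation intervals (e.g. other gene catalogues or a repeat mask)
from these regions; strand-agnostic masks are applied to both strands
because external annotations vary in strand fidelity.

`build_junction_library()` enumerates, per locus with *k* elements,
all *k(k−1)/2* element pairs in transcription order. Pairs that are
consecutive exons of an input transcript are flagged
`annotated_model`; the rest are `combinatorial` and allow detection of
novel exon pairings. On the minus strand the donor coordinate is
genomically to the right of the acceptor, mirroring the plus strand.
No maximum pair distance is imposed: loci here are bounded in size, so
the quadratic enumeration stays small, and restricting it would
silently remove long-range skips.

# Quantification

A read contributes to the unique same-strand element containing its
5′-most base (the leftmost coordinate on +, the rightmost on −). This
start rule, rather than any-overlap counting, keeps the partition of
reads over elements/inR/igR exact. Locus counts are the sum of member
element counts plus the counts of the locus's junctions.

Expression is reported as RPKM,

$$\mathrm{RPKM} = \frac{10^9 \, C}{L \, N},$$

with *C* the locus total count, *L* the gene-model length (sum of
element lengths) and *N* the per-sample library size. *N* is defined
as all reads finally assigned anywhere in the genome plus
junction-assigned reads — "per million mapped reads", not per million
sequenced. A locus is *detected* when RPKM is strictly greater than
0.1. Detected loci fall into five categories; the default bins are
decades — (0.1, 1], (1, 10], (10, 100], (100, 1000], >1000, labelled
very low to very high — chosen because they are reproducible without
reference to any particular dataset; a quantile mode (quintiles of the
detected distribution) is available where relative categories are
preferred.

`chromosome_read_ratio()` is the dosage QC: an extra chromosome copy
should raise that chromosome's A/B mapped-read ratio towards 1.5 while
all others stay near 1. The default normalisation is
median-of-chromosome-ratios rather than total-count: the trisomic
chromosome's own excess (and any strongly expressed differential
genes) inflates the A library total, and dividing by it would drag
every other chromosome visibly below 1. Scaling so that the median
chromosome sits at 1 is robust to both effects; `"total"` and
`"none"` remain available.

`snorna_host_table()` classifies small-RNA loci (snoRNA-like) as
intron-hosted (SHG) when their span lies entirely within an intronic
region of another locus on either strand, and cross-tabulates their
expression category against host status. Small RNAs are supplied as a
separate table rather than as gene-model rows: an intron-hosted
snoRNA's span overlaps its host, and feeding it through the
same-strand merge would fuse it into the host family locus, making
the host/guest distinction unrepresentable.

# Transcriptionally active regions

`refine_tars()` turns intronic/intergenic regions with read signal
into TARs. Each region is tiled with non-overlapping windows of width
*W* (default 500 nt) anchored at the region start; windows with at
least *T* (default 30) pooled read starts qualify; maximal runs of
adjacent qualifying windows merge into one TAR, trimmed to the
outermost read starts inside the run. Tiling (rather than sliding)
windows with run-merging and extent-trimming is the simplest
procedure consistent with fixed (W, T) parameters, and it admits an
exact brute-force oracle: the test suite checks agreement with a
naive per-window scan on hundreds of random instances. Refinement
runs on the pooled samples so that both states are compared on one
common set of regions; per-sample counts and activity (≥ 1 read by
default — activity is presence, quantification is separate) follow in
`quantify_tars()`.

`detect_utr_extensions()` places a fixed window (default 150 nt)
immediately downstream of each locus's annotated 3′ end and upstream
of its 5′ end, strand-oriented, and calls an extension when the
window holds at least `utr_min_reads` (default 5) same-strand read
starts. Five reads is deliberately permissive — the window is small
and flanking signal is sparse; the cross-sample comparison (common
versus sample-specific calls) is where the biology is read.
Same-strand reads are required because an antisense flank signal is a
different phenomenon (antisense transcription), not a UTR extension.

`scan_orfs()` reports open reading frames (start codon to in-frame
stop, length inclusive of the stop codon) of at least 200 nt in TAR
sequences. Intronic TARs are scanned in the three frames of the host
strand — an in-frame hit suggests an unannotated alternative exon —
while intergenic TARs are scanned in all six frames. TARs without a
qualifying ORF, particularly short intergenic ones, are candidate
non-coding RNAs.

# Splicing

Junction tallies against the library feed three calls. A junction is
*reliable* in a sample when it has at least T1 reads (default 5; 3 is
a supported exploratory setting). Alternative-splicing events are
groups of two or more reliable junctions of one locus sharing a donor
(multiple-donor) or acceptor (multiple-acceptor) coordinate; a pair
sharing both yields two events. A junction is *sample-specific* when
it is reliable in one sample and has **zero** reads in the other: any
hit in the other sample, even below T1, disqualifies it, so the call
does not depend on where the threshold happens to sit. Junction
annotation status is assigned by first match against named junction
sets in precedence order (conventionally RefSeq > UCSC > Ensembl);
unmatched junctions are putative novel junctions from the
combinatorial construction.

# Differential expression without replicates

With one library per condition, replicate-based dispersion estimation
is unavailable and count-based packages reduce to two-library
comparisons of a feature's counts against the library totals. The
package implements three self-contained exact tests on
\(X = \text{count}_A\) conditional on \(n = \text{count}_A +
\text{count}_B\):

* **Exact conditional binomial**: under the null of equal relative
  expression, \(X \sim \mathrm{Bin}(n, \pi_0)\) with
  \(\pi_0 = N_A/(N_A+N_B)\); the two-sided p-value sums the
  probabilities of outcomes no more likely than the observed one.
* **Fisher exact** on the 2×2 table of feature versus remaining
  library counts.
* **Exact over-dispersed (NB) test**: each library's count is modelled
  Gamma–Poisson with common over-dispersion φ; conditional on *n*, X
  is beta-binomial with shape \(\pi_0/\varphi\) and
  \((1-\pi_0)/\varphi\). At φ = 0 this collapses exactly to the
  binomial test (asserted to 1e-10 in the tests). The default
  φ = 0.1 injects the biological extra-variance a replicate-aware
  method would estimate; it is the conservative arm of the battery.

Cutoffs follow the two-library convention: 0.1 on the BH-adjusted
q-value of the over-dispersed test (the conservative test gets an FDR
cutoff), 1e-4 on the raw p of the two sharper tests, plus a 1.5
fold-change threshold on the CPM-normalised samples (pseudocount 0.5
per library keeps the fold change finite). Evidence tiers count the
passing tests: 3 = strong, 2 = good, 1 = acceptable (with the fold
change met); features significant in at least one test but below the
fold-change threshold are *weak*; the rest are *no change*. The tiers
partition all tested features. The same machinery applies unchanged
to loci, TARs or any other feature count table.

`ddct()` is the companion qRT-PCR utility,
\(2^{-\Delta\Delta C_t}\), for validating calls on selected genes.

# The synthetic-data generator

`simulate_dataset()` builds the study conditions end to end: a toy
genome of four chromosomes (chr1/2/3 at 800 kb, chr21 at 400 kb)
carrying 30/30/30/12 genes with 1–8 exons (100–400 nt) and introns of
0.3–3 kb; two libraries of nominally 2×10^5 uniquely assigned 50-nt
reads; chr21 at 1.5× dosage in the case sample. Per-gene expression
is lognormal and then rescaled so that the expected gene-derived read
total equals the nominal library size (expression values are
compositional; the rescale is what makes empirical RPKM regress on
true expression with slope ≈ 1, which the tests assert within 5% at
one million reads). Reads are emitted as already-aligned intervals —
alignment is out of scope — with 5′ starts uniform over exonic
positions on the gene strand; strand purity is perfect by default,
with an antisense-contamination rate exposed for QC exercises.

Planted structure, each recorded in a serializable truth set:

* **Differential expression**: four up (×4) / four down (×0.25) genes
  off the dosage chromosome. Each up gene is paired with a
  same-chromosome partner of roughly four times its expected read
  mass, so the added and removed reads cancel and chromosome totals
  stay dosage-dominated — in a ~100-gene genome an unbalanced 4-fold
  plant on a tail gene would otherwise swamp the dosage QC that the
  generator exists to exercise. Plants are drawn from the moderate
  part of the expression distribution for the same reason.
* **TARs**: four intronic and four intergenic clusters, 3 windows
  (1500 nt) wide at a pooled density of 2T per window, placed with
  margins that keep them clear of gene flanks.
* **UTR extensions**: six genes receive exactly 15 flank-window reads
  per called sample (a fixed count, not Poisson — the plant defines
  the truth signal); four common, one specific to each sample.
* **Junctions**: annotated adjacent junctions at ~1% of the host
  gene's reads; four exon-skip junctions (10 reads in both samples)
  planted together with the adjacent junction sharing their donor
  site, guaranteeing a multiple-donor event each; four
  sample-specific junctions at 8 reads in one sample and zero in the
  other.
* **snoRNA-like loci**: six 150-nt intron-hosted features at RPKM
  2000, emitted as a separate small-RNA table (see above). Their
  reads fall in intronic regions of the main annotation and may
  legitimately seed intronic TARs, as real snoRNAs would. Common UTR
  plants can similarly pool to the TAR threshold and appear as small
  intergenic TARs; both are properties of the data, not artefacts.
* A genomic background of 2×10^-5 reads/bp/strand — about 0.01 reads
  per refinement window, far below T/3.

What the generator does **not** emulate: sequencing error and quality,
multi-mapping ambiguity and rescue, coverage non-uniformity (GC,
fragmentation or 3′ bias), antisense leakage (unless enabled), repeat
structure, and isoform mixtures within a locus. Passing tests
therefore demonstrate the correctness of the post-alignment logic
under its stated assumptions, not robustness to alignment artefacts.

# Numerical and degenerate-input choices

* Exact two-sided p-values use the minimum-likelihood convention with
  the customary 1+1e-7 tie tolerance; n = 0 gives p = 1.
* Zero-count features get fold changes through the 0.5 pseudocount;
  an empty library is quantified against a size of 1 (all-zero RPKM)
  rather than aborting the run.
* Detection is strictly greater than 0.1 RPKM; an RPKM of exactly 0.1
  is undetected.
* ORF length counts the stop codon; a 198-nt ORF does not pass the
  200-nt minimum.
* Windows past chromosome ends are clipped; malformed gene-model rows
  are rejected with a reason rather than failing the run; TARs use
  read 5′ starts, so a read dangling into a region from outside does
  not count.
* All randomness flows through the single configuration seed; the
  pipeline stages themselves are deterministic, and re-running with
  the same inputs reproduces every artifact.

Problem sizes in the tests — a ~2.8-Mb genome, ~100 loci, 2×10^5
reads, ten thousand null features for test calibration — were chosen
so the whole suite exercises every stage end to end in well under a
minute per scenario while keeping Monte-Carlo margins (binomial
sampling error on ratios and rates) an order of magnitude smaller
than the tolerances being asserted.

# Known limitations

* No replicate-aware dispersion estimation: φ is supplied, not
  estimated; the NB test's q-values on very small feature sets are
  conservative (Benjamini–Hochberg with small m).
* No transcript-model assembly: TARs and UTR extensions are reported
  as intervals, not stitched into gene models, and junction-based
  isoform reconstruction is out of scope.
* ASE candidates are not filtered by exon-by-exon usage maps; users
  should treat events in repetitive or poorly mappable loci with
  care.
* The expression categories in quantile mode depend on the detected
  set and are not comparable across runs; decade mode is the default
  for that reason.

# Interfaces

Each stage is an exported function over plain data frames, and
`run_pipeline()` chains them, writing BED/TSV/bedGraph artifacts plus
a count report to an output directory; `export_tracks()` emits
genome-browser custom tracks (strand-specific bedGraph coverage,
TAR/UTR/junction BED). `scripts/acceptance.R` reproduces the headline
numbers from a seeded synthetic dataset from the command line. These
functions, together with this vignette, are the package's interface;
there is no separate shell tool.
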