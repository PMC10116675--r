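---
title: "Refining somatic SNV candidates from read pileups: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining somatic SNV candidates from read pileups: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pileupCNN)
```

## The problem

Somatic variant callers applied to tumour/germline pairs emit candidate
lists that still contain a substantial fraction of sequencing artefacts:
strand-biased support, mismatches riding on misaligned reads in
low-complexity regions, scattered low-quality noise, and — most
insidiously — artefacts introduced during library preparation. The last
class is invisible in the tumour/germline pair itself: when the two
samples were prepared in different batches, a preparation artefact in the
tumour library looks exactly like a genuine somatic variant. It can only
be recognised by inspecting *other, biologically unrelated samples that
share the tumour's library preparation*: the same spurious allele shows up
there too. In practice this refinement step is done by trained reviewers
in a genome viewer; `pileupCNN` automates it with a small convolutional
network over an image-like encoding of the pileups, including those
context tracks.

## Input representation

Each candidate SNV is encoded from a symmetric window of `d_window` bases
(default 101) around the locus and up to `d_reads` reads (default 200) per
track. Every (window position, read) cell carries 7 numbers: a one-hot
encoding of the base (A, C, G, T; all zero for `N` or no coverage), the
base quality, the mapping quality of the read, and a reverse-strand flag.
Cells outside a read's aligned span — including deletion gaps — are
exactly zero; insertions consume no window column. Qualities are divided
by fixed caps (42 for base, 60 for mapping quality) and clipped to [0, 1],
so all channels live on comparable scales.

Tracks are encoded independently and concatenated along the channel
dimension in the fixed order *germline, tumour, context_1..context_n*
(default `n_context = 3`, i.e. 5 tracks and 35 channels). The context
tracks are chosen among samples sharing the tumour's library preparation
(see `pick_context_tracks()`); the aligned window positions of all tracks
coincide, so a preparation artefact appears at the same column of every
track that shares the batch.

### Read ordering

The order of reads within a track is not biologically meaningful, and a
convolutional network is not permutation-invariant across rows, so the
choice matters. We sort reads the way a reviewer sorts a genome-viewer
pileup when assessing a candidate: reads supporting the alternative allele
first, then reads carrying another mismatch at the locus, then
reference-matching reads, then reads that do not cover the locus; ties are
broken by alignment start and read name, making the order fully
deterministic. This has two consequences we consider essential. First,
allele support becomes a *contiguous block of rows*, so the allele
fraction is visible to the network as a spatial extent rather than as a
count scattered over rows — max-pooling layers preserve extents but
destroy scattered counts, and in our experiments a start-position ordering
made allele-fraction contrasts practically unlearnable at realistic
training-set sizes while the pileup-sort ordering made them learnable.
Second, when a pileup exceeds `d_reads` and must be truncated, variant
evidence is never the part that is discarded.

### Base scrambling

To prevent the classifier from keying on the identity of specific loci
(homologies, recurrent sites), each sample can be base-scrambled: one of
{identity, A<->T, C<->G, both} is drawn uniformly and applied as a
permutation of the one-hot channel slices of *all* tracks, together with
the site's ref/alt metadata. Swaps stay within purines and pyrimidines so
the transition/transversion distinction survives. Scrambling commutes with
encoding (scrambling the tensor equals encoding letter-substituted reads)
and the two double-swap operations are involutions; both properties are
tested.

## The classifier

The network is deliberately small:

* three 3x3 same-padding convolution blocks with 32, 16, and 32 filters
  (ReLU), each followed by 3x3 max-pooling with stride 3 and floor size
  reduction;
* a 1x1 convolution with 32 filters (ReLU) that replaces a wide dense
  head, forcing complexity into the filters;
* batch normalisation (momentum 0.8) and flattening;
* a dense layer with 10 ReLU units whose out-edges receive dropout 0.2
  during training;
* a 2-unit softmax classification layer.

On a (101, 200, 35) input the three poolings reduce the spatial grid to
3 x 7, the flattened feature vector has 672 entries, and the model stores
exactly 27,312 parameters (including the batch-norm moving statistics) —
small enough to train on a few thousand labelled candidates without
excessive overfitting. Training minimises binary cross-entropy on the
two softmax outputs with label smoothing 0.1 (hard labels (1,0)/(0,1)
become (0.95,0.05)/(0.05,0.95)), using Adam at a constant learning rate of
1e-3, batches of 256, and 50 epochs by default.

The implementation is our own (RcppArmadillo; im2col plus single-precision
GEMM for the convolutions, with analytic gradients for every layer
including batch normalisation). All stochastic elements — weight
initialisation (Glorot uniform), per-epoch shuffling, dropout masks — are
driven by R's RNG, so a fixed seed reproduces training bit for bit on the
same platform.

Numerical choices worth knowing: pooling uses floor ("valid") size
reduction and convolutions same-padding — with five input tracks this is
the unique combination consistent with the 27,312-parameter count; the
parameter total is interpreted as *stored* parameters, i.e. it includes
the 64 batch-norm moving statistics; batch-norm uses eps 1e-3 and the
moving statistics are an exponential average with the stated momentum;
predictions are made in inference mode (moving statistics, no dropout), so
they are invariant to how the input is batched; the hard class is the
softmax argmax, i.e. a 0.5 threshold, as no threshold tuning is specified
for the method.

## Evaluation machinery

`compute_metrics()` implements accuracy, precision, recall and F1 from the
confusion matrix; degenerate denominators yield an explicit `NA` sentinel
rather than 0 or 1. `stratified_cv()` (k = 5 by default) partitions each
class round-robin after a seeded shuffle, so per-fold class counts are
within one of exact proportionality; fold metrics are averaged
unweighted. `random_splits()` repeats seeded stratified train/test splits
(default hold-out fraction 0.2 — the repeated-splits protocol does not pin
one, and 0.2 matches the cross-validation hold-out share).
`subsample_study()` shrinks the dataset geometrically (factor sqrt(2),
half-up rounding) and cross-validates each size, tracing how performance
degrades with fewer labelled candidates.

`subgroup_binomial_tests()` asks whether classification accuracy on a
subgroup (by reference base, alternative base, base pair, mutation class,
or VAF bin) is compatible with the overall accuracy, using the exact
two-sided binomial test with the overall accuracy as the null proportion,
Bonferroni-corrected within each grouping scheme (the family is the set of
groups of that scheme; families are reported separately). VAF bins default
to dataset quartiles. Groups with missing metadata are skipped with a
warning.

`solve_confusion()` inverts printed metric tables: given the class totals
and precision/recall printed to a fixed number of decimals, it enumerates
all integer confusion matrices that round (half-up) to the printed values.
Published three-decimal tables on a ~2000-candidate dataset typically
admit a unique reconstruction, which makes the solver a useful
consistency oracle for reported results.

## The pileup simulator

Because real labelled refinement data require controlled-access sequencing
plus expert annotation, the package ships a seeded simulator that
generates labelled composite samples through the *same* extraction and
encoding path as real BAM data (and can export its reads as valid
BAM/VCF/FASTA fixtures that round-trip bit-identically through the
tensorizer).

A genuine mutation draws, for each locus-covering tumour read, alt-carrier
status i.i.d. with probability `vaf`; germline and context tracks show the
alternative allele only through sequencing errors. The four artefact
classes are:

* `strand_bias`: alt support confined to one read direction;
* `low_complexity_misalignment`: the locus sits in a dinucleotide repeat,
  and alt support rides on short reads with degraded base qualities,
  extra errors near the locus, and reduced mapping quality;
* `random_noise`: scattered low-quality alternative calls at the noise
  rate, with no consistent variant signal;
* `library_prep`: alt support at the target VAF in the tumour *and* in
  every context track sharing the preparation, absent from the germline.
  By construction the tumour/germline sub-tensor of this class is
  distributionally identical to a genuine variant — only the context
  tracks carry the separating signal. This is the property that makes the
  context comparison meaningful, and it is verified by a two-sample test
  in the suite.

Sequencing errors replace a base uniformly and, importantly, carry *low*
base quality (drawn from the noise-quality profile): basecallers flag
miscalls with low phred scores, and a simulator that gives errors
full-quality scores both misrepresents real data and erases the quality
channel's information. Base and mapping qualities are rounded clipped
normals; reads per track are Poisson; read lengths are Poisson with a
floor of 8.

What the simulator does *not* emulate: platform-specific error motifs,
alignment around indels, GC/coverage waves, tumour subclonality, or
contamination. Passing the synthetic studies therefore demonstrates that
the encoding, the optimisation, and the context mechanism work as
designed — not that any particular accuracy level transfers to real
cohorts.

## Study conditions used by the test suite

The heavier statistical checks train networks repeatedly, so they run at a
deliberately reduced desk scale, chosen once:

* encoding `d_window = 27`, `d_reads = 27` — the smallest geometry that
  survives three stride-3 poolings (27 -> 9 -> 3 -> 1);
* simulator `coverage_mean = 40`, `read_length = 50`, `vaf = 0.5`,
  emulating deep targeted sequencing of a clonal variant at high tumour
  purity, so pileups are information-dense at the reduced window;
* training batches of 64 with a correspondingly reduced epoch count: at a
  few thousand samples this keeps the Adam step count in the regime the
  full-scale defaults (batch 256, 50 epochs) produce on a ~2000-candidate
  cohort.

The context study trains the 5-track model and its context-stripped
2-track counterpart on an identical mixture containing library-preparation
artefacts and compares held-out accuracy across seeds; the subsampling
study cross-validates at 2000 and 250 samples. Package defaults remain at
the full scale (window 101, 200 reads, coverage 80, read length 100,
VAF 0.4).

## Known limitations

* The network is not permutation-invariant over reads; the pileup-sort
  ordering is part of the model's contract and must be identical at
  training and prediction time (the tensorizer guarantees this).
* Only biallelic SNVs are handled; indels, multi-allelic sites and
  structural variants are out of scope.
* Training is single-threaded CPU code; it is comfortable at the scales
  used here (seconds to minutes) but not intended for very large cohorts.
* Determinism is guaranteed for a fixed seed on a fixed platform; exact
  bit-reproducibility across BLAS implementations is not.
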