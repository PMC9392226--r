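---
title: "Alignment-free protein phylogenetics with property curves, FFT and fractal dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free protein phylogenetics with property curves, FFT and fractal dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffp)
```

## The method

`ffp` compares protein sequences without aligning them. Each sequence is
turned into a whole-sequence descriptor in four steps, and pairwise
distances between descriptors drive a hierarchical clustering that is read
as a phylogenetic tree.

1. **Property encoding.** Every residue letter is replaced by a numeric
   physicochemical value, giving a "property curve" with one point per
   residue. The default scale is pKa(COOH), the dissociation constant of
   the α-carboxyl group (in pKa units), which reflects the ionization
   state of –COOH in solution and is closely tied to the isoelectric
   point. Alternative scales (hydrophobicity, basicity, relative
   molecular mass, ...) plug in as two-column text files; we ship no
   numeric values for them, since any published variant of those scales
   can be supplied by the user.
2. **Common-length truncation.** All curves in a set are cut to the
   set's minimum length N, keeping the prefix, so every downstream
   object has the same dimension. Truncation to the minimum (rather than
   padding to the maximum) is what makes the per-protein feature length
   equal N − d + 1 for a window width d; the prefix is the natural
   choice for protein sequences, whose N-terminal region is read first.
3. **Iterated magnitude FFT.** The level-1 spectrum is the element-wise
   modulus of the discrete Fourier transform of the curve,
   F(k) = Σₙ pₙ e^(−i2πnk/N); level L ≥ 2 applies that operation L times,
   taking the modulus after each pass, so the signal stays real and the
   length never changes. The default level is 2: one pass measures the
   frequency content of the property curve, the second pass measures the
   structure *of the spectrum itself*, which in practice separates
   closely related sequences better than a single pass. The DC component
   is retained and no windowing, zero-padding or detrending is applied —
   each would inject a modelling choice the descriptor does not need.
4. **Sliding-window Higuchi fractal dimension (HFD).** The spectrum is
   scanned with a width-d window (default d = 9). Within a window
   z(1..d), the stride-m subsample starting at offset n has normalized
   curve length
   H_n(m) = (d−1) / (⌊(d−n)/m⌋ m²) · Σᵢ |z(n+im) − z(n+(i−1)m)|,
   H(m) averages H_n(m) over the offsets n = 1..m, and the window's HFD
   is the least-squares slope of log H(m) on log(1/m) (natural logs;
   the slope is base-invariant). A smooth ramp gives 1, white noise
   approaches 2, so each feature measures the local roughness of the
   spectrum. The feature vector has length N − d + 1.

Similarity between feature vectors A and B is the cosine
C = A·B/(‖A‖‖B‖); the distance is D = 1 − C, so identical directions give
0 and the range is [0, 2]. A similarity would order species backwards and
is inconsistent with near-zero values reported between near-identical
sequences, which is why the 1 − C transform is the package's distance.
The tree is single-linkage agglomeration on D (inter-cluster distance =
minimum member distance), whose merge heights are non-decreasing;
Newick export places each internal node at its merge height and leaves
at height 0, so a child branch is the parent's height minus the child's.

Agreement with a reference distance matrix (e.g. one produced by an
alignment-based workflow) is summarized per species by the Pearson
correlation of matching matrix rows — full rows, zero diagonal included,
so the sample size n is the number of species — classified against the
two-sided critical values of the correlation coefficient,
r\* = √(t²/(t² + n − 2)) with t the two-sided α quantile of t(n−2):
|c| ≤ r\*₀.₀₅ "none", r\*₀.₀₅ < |c| ≤ r\*₀.₀₁ "linear", |c| > r\*₀.₀₁
"strongly linear". For n = 8 these are 0.707 and 0.834; for n = 10,
0.632 and 0.765.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `property_scale` | `"pka_cooh"` | pKa units | ionization-relevant, non-degenerate across the 20 letters |
| `fft_level` | 2 | passes | second pass captures spectrum structure; 1 keeps the plain magnitude spectrum |
| `window_width` (d) | 9 | features | smallest width giving 4 usable strides; larger windows smooth local structure away |
| `m_max` | 4 = ⌊d/2⌋ | strides | guarantees ≥ 2 increments for the n = 1 offset at every stride; standard Higuchi practice |
| `constant_value` | 1.0 | — | a flat window is a smooth 1-D object, so its dimension is 1 |
| `rounding` | 4 | decimals | display only; full precision is kept internally |

## Numerical choices and degenerate inputs

* **Offsets without increments.** For stride m and offset n with
  ⌊(d−n)/m⌋ = 0 there is no increment to sum; such offsets are excluded
  from the H(m) average (divide by the count of valid offsets). With the
  defaults d = 9, m ≤ 4 none occur, so the average is exactly the
  textbook 1/m Σ form.
* **Zero curve lengths.** If H(m) = 0 for some stride of a non-constant
  window, log H(m) is undefined; that stride is dropped from the
  regression, and if fewer than two points remain the window falls back
  to `constant_value`. An entirely flat window returns `constant_value`
  directly.
* **Ties in agglomeration.** Equal minimum distances are resolved
  deterministically by the clustering backend; merge *heights* are
  unique regardless of tie order, and the test suite checks topology
  only on tie-free random matrices.
* **Non-standard letters.** B, J, O, U, X, Z and gap characters are a
  hard error naming the offending positions; an opt-in policy
  substitutes the mean of the 20 scale values. Silent substitution is
  never the default because it changes the curve without warning.
* **Zero feature vectors** make the cosine undefined and are an error;
  they cannot arise from the default pipeline (HFD of a real spectrum is
  never the zero vector with `constant_value` = 1).
* **Determinism.** The same FASTA and configuration give bit-identical
  matrices and Newick strings; the synthetic generator is a pure
  function of its arguments including the seed, and restores the
  caller's random-number state.

## The synthetic generator: what it emulates, what it does not

`synthetic_family()` builds clade-structured families by uniform point
substitution: a random root, one ancestor per clade at `between`
substitutions from the root, each member at `within` substitutions from
its ancestor (replacements always differ from the current letter, so the
counts are exact Hamming distances). It emulates the one property the
distance pipeline must detect — graded sequence divergence with a known
grouping — and nothing else: no indels, no PAM/BLOSUM-weighted
substitution preferences, no rate variation across sites, no
back-mutation bookkeeping between clades. Passing clade-recovery tests
therefore shows the pipeline orders uniform substitution distances
correctly at realistic divergence levels; it does not certify accuracy
on real families shaped by indels or biased substitution processes —
for those, the benchmark accession sets and a reference matrix
comparison are the appropriate check. The validation setting used in the
tests is 3 clades × 3 sequences of length 150 with 2 within- versus 30
between-clade substitutions over seeds 1–20, i.e. roughly 1% versus 20%
divergence — the regime of the curated benchmark families.

## Problem sizes used in the shipped tests

The test suite works at desk scale: transform oracles up to length 64,
single-linkage oracles on 100 random 6-leaf matrices, 10,000
white-noise windows for the Higuchi Monte-Carlo, 20 seeded 9-sequence
families for clade recovery, and the bundled 30-residue worked-example
pair P1/P2. These sizes already exercise every code path; the pipeline
itself runs comfortably on hundreds of sequences of typical protein
length.

## Known limitations

* Truncation discards C-terminal signal beyond the set's minimum
  length; sets with wildly different lengths (or long indels) violate
  the method's comparable-length assumption.
* The descriptor is built from a single scalar property per residue;
  structural information is invisible to it.
* Single linkage chains: two clades bridged by one intermediate
  sequence can merge early. Alternative linkage criteria are outside
  this package's scope.
* Benchmark accession sequences are not bundled; reproducing the
  published distance matrices requires fetching them from NCBI
  (`benchmark_sets()` lists the accessions) and supplying a FASTA file.

## A worked run

```{r example}
fam <- synthetic_family(n_clades = 3, seqs_per_clade = 3, length = 150,
                        within = 2, between = 30, seed = 1)
res <- ffp_pipeline(fam$records)
res
cat(as_newick(res$tree, digits = 4))
cutree(res$tree, k = 3)
```

```{r example-compare}
rep <- correlation_report(res$distance, res$distance)
rep
```
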