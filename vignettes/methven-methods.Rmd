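---
title: "Predicting non-coding SNP effects on CpG methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting non-coding SNP effects on CpG methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methven)
```

## The problem

A methylation quantitative trait locus (meQTL) is a SNP statistically
associated with the methylation level of a CpG site. The association carries
a signed effect size — the slope ($\beta$) — whose sign says whether the
alternative allele raises or lowers methylation and whose magnitude says by
how much. This package predicts both from two inputs: the DNA sequence
around the CpG (with and without the alternative allele) and a per-base
chromatin-accessibility (ATAC-seq) track for the cell population of
interest. Because the accessibility track is an input rather than a fixed
annotation, the same SNP-CpG pair can be scored under different cellular
conditions — the basis of the case/control comparison described below.

Pairs are handled with a divide-and-conquer split by genomic distance:
SNP-CpG pairs closer than 10 kbp form the SMALL class and pairs between
10 kbp and 100 kbp (boundary inclusive on both ends of that interval) form
the LARGE class. Each class trains its own model, because short-range and
long-range regulation involve different sequence context scales.

## From sequence to model input

For each pair a window of length $L$ is extracted, centered on the CpG
cytosine: $L = 20{,}001$ bp for SMALL and $L = 200{,}001$ bp for LARGE. The
window is tiled by the positional-wise cutting plan: a 250 bp terminal cut,
$n$ flanking cuts of 500 bp, a 501 bp central cut whose midpoint is the
CpG, $n$ more flanking cuts, and a final 250 bp terminal cut, with $n = 19$
(SMALL) or $n = 199$ (LARGE), giving $T = 2n + 3$ cuts. The arithmetic is
forced: $2\,(250 + 500\,n) + 501$ equals $20{,}001$ and $200{,}001$ for the
published cut counts, which is why those window lengths are used even
though half-sized figures also circulate; the cut geometry is the
operational definition.

Each cut is embedded per base (the default embedder is one-hot with width
$d = 4$; any external per-base language-model embedding can be adapted via
`external_lm_embedder()`), average-pooled within the cut, and concatenated
as $[\,\text{pre-allele pool} \,\|\, \text{post-allele pool} \,\|\,
\text{mean ATAC}\,]$, one row of width $2d + 1$ per cut. Under mean pooling
a one-hot embedding reduces to the cut's base composition, and the
substituted allele can shift a pooled value by at most $1/250$ — single-base
information survives pooling only through the paired pre/post difference.
Ablation flags zero a block rather than shrink the tensor, so ablated and
full models keep comparable shapes.

Coordinates follow one convention throughout: external records are 1-based
inclusive (meQTL tables, SNP and CpG positions), BED and bedGraph are read
in their native 0-based half-open form, and all internal window arithmetic
is 0-based half-open. Conversion happens once, at the reader boundary.
Windows that would cross a chromosome end are dropped, never padded:
padding would silently shift pooled statistics. CpG positions refer to the
forward-strand cytosine; no reverse-complement handling is applied anywhere
(probe strand normalization is an open question for real array data).

## The dual-task model

Direction (classification) and magnitude (regression) are predicted by two
independently trained models with no shared weights; separating the tasks
keeps the easier direction problem from being polluted by the heavy-tailed
slope distribution. The architecture, implemented in compiled code inside
the package with full backpropagation through time:

* batch normalization of the input per (cut, feature) position — pooled
  composition columns vary on a scale of $\sim 10^{-2}$ while accessibility
  columns vary on a scale of units, and the allele-difference signal is
  smaller still, so per-position normalization is what makes these
  comparable to the optimizer;
* two stacked bidirectional GRU layers over the $T$ cuts;
* a readout concatenating the temporal mean of the top layer's outputs
  (every cut contributes regardless of position) with the output at the
  central timestep — the CpG-centered cut is the method's anchor point and
  gets an undiluted path to the head;
* batch normalization, a two-layer fully connected stack with ReLU and
  dropout, batch normalization again between the layers;
* a single output unit: sigmoid (direction) or linear (slope).

Training uses Adam at learning rate 0.001, binary cross-entropy or mean
squared error, minibatches, and early stopping on validation loss with a
patience of 10 epochs and best-epoch weight restoration. A warmup
(`min_epochs`, default 40) keeps the patience counter from firing on the
noisy plateau that precedes convergence on small datasets; the best epoch
is still tracked from the first epoch. Recurrent weight matrices are
initialized orthogonally per gate, input and dense weights with Glorot
bounds; gradients are clipped at global norm 5. A fixed seed determines
initialization, shuffling, and dropout exactly, so a run is reproducible
bit-for-bit on one machine. `use_recurrent = FALSE` swaps the recurrent
encoder for a flatten-plus-dense encoder of comparable width (the
architecture ablation); hidden-state extraction is then undefined and an
error.

Default sizes (64 recurrent units per direction, fully connected widths 64
and 16, dropout 0.2, batch 64) are deliberately small enough to train on a
CPU in minutes. The heavier analyses in this package's own test battery use
fully connected widths 32/16, batch 32, and at most 150 epochs with an
80-epoch warmup; the direction model uses 32 recurrent units with dropout
0.3 and the slope model 64 units with dropout 0.4 (the regression surface
is noisier and benefits from both the extra capacity and the stronger
regularization). These problem sizes were chosen once as a desk-scale
working point and are used unchanged everywhere.

## Dataset construction

`build_pairs()` drops pairs beyond 100 kbp, excludes slope-zero records
(their direction is undefined), and labels the rest $\pm 1$ by slope sign.
`balance_by_chromosome()` then down-samples the majority direction within
each chromosome to the minority count — done independently within each size
class, since each class trains its own model (whether the original
balancing was per class or global is not documented; per class is the
choice here). Splits are 8:1:1 train/validation/test or 10-fold, both
stratified by direction; stratification is an addition over a plain random
split that reduces variance at small sample sizes without affecting
comparability. All randomized steps take explicit seeds and reproduce
byte-identical partitions.

## Condition comparison and categorization

Given a trained regression model and two accessibility tracks (case and
control), `predict_conditions()` scores a pair twice, with feature tensors
that differ only in the ATAC column. With
$\Delta = |\beta_{case} - \beta_{control}|$, `categorize_affect()` assigns

* UNAFFECTED if $\Delta \le 0.5$;
* otherwise REDUCED if $|\beta_{case}| < |\beta_{control}|$;
* otherwise UP_ENHANCED if $\beta_{control} \ge 0$, else DOWN_ENHANCED.

As printed, the source rule's clauses overlap (a point with
$\Delta > 0.5$, negative control slope, and smaller absolute case slope
satisfies both the down-enhancement and reduction conditions); the rule
here follows the figure-caption semantics in which reduction — the
condition weakening the SNP's effect — takes precedence, and $\Delta$ is an
absolute difference. The published worked example (case slope 0.09, control
slope −1.19) is REDUCED under this order, which is the consistency check
that fixed it. The rule is a total function on the slope plane: every point
receives exactly one category.

Downstream, `map_to_promoters()` assigns each CpG its nearest TSS (ties
broken by lexicographic gene id), with the signed distance oriented by gene
strand, and retains CpGs within 2 kb as promoter-proximal;
`filter_snps_near_peaks()` keeps SNPs within 1 kbp of accessibility peaks.
When no externally called peak set is given, peaks are maximal runs at or
above the 95th percentile of nonzero track values, at least 50 bp long — a
deliberately simple fallback, not a replacement for a real peak caller.

## Hidden-state interpretation

`hidden_states()` exposes the top recurrent layer's per-timestep
activations (both directions concatenated). `activation_profile()`
summarizes them as the mean absolute activation per cut, averaged over
windows and hidden units — the absolute value prevents sign cancellation
between the two directions. `compare_regions()` then tests, for each of the
eight functional-region types (active promoter, strong enhancer,
transcriptional transition, transcriptional elongation, insulator,
heterochromatin, repressed region, repetitive element/CNV), whether cuts
overlapping that type differ in activation from non-overlapping cuts, using
a two-sided Mann-Whitney U test. A cut counts as inside a region on an
overlap of at least 1 bp (configurable); with multiple windows a cut is
inside if it overlaps in any window. Benjamini-Hochberg adjusted p-values
are reported alongside the raw ones.

The U test computes the rank-sum statistic with average ranks for ties. The
p-value is exact — by enumeration of all $\binom{n_x+n_y}{n_x}$ group
assignments, which handles ties without approximation — whenever that count
is at most 20,000, and otherwise uses the normal approximation with
tie-corrected variance and continuity correction. Per-cut activations are
the comparison unit, matching the timestep structure of the encoder;
per-base comparison would require attributing pooled activations back to
bases, which the architecture does not define.

## The synthetic data generator

Real meQTL tables, reference genomes, and accessibility tracks are large
downloads; the generator replaces them with a self-contained world whose
ground truth is known exactly, so that every stage — parsing, windowing,
featurization, training, condition comparison, interpretation — is testable
offline. For a pair at distance $d$ the planted slope is

$$\beta = s \cdot \beta_0 \cdot e^{-\lambda d} \cdot (1 + \gamma \bar a) + \varepsilon$$

with $s \in \{+1, -1\}$ the planted direction, $\beta_0 = 2$ the effect
scale, $\lambda = 1/30{,}000$ per bp the distance decay, $\bar a$ the mean
control accessibility in the cut containing the SNP, $\gamma = 1$ its
weight, and $\varepsilon \sim N(0, 0.3^2)$. Defaults: 3 chromosomes of
600 kb, GC content 0.42, 300 SNPs with 3 CpGs each, distances log-uniform
on [300, 100,000] bp (cis-meQTLs concentrate near their CpG, and both size
classes are populated).

Direction is biologically staged as motif disruption: half the SNPs sit in
a planted copy of a GC-rich 8-mer (`GCCACGCG`) and their alternative allele
is the C→T transition at the motif's CpG ($s = -1$); the other half are
random substitutions at background positions ($s = +1$). Because mean
pooling caps any single-base signal at $1/250$, a disrupted pair also
carries a structural signature at a predictable place: a tandem block of 16
motif copies (128 bp, CpG-island-like) immediately flanking the affected
CpG, i.e. inside the central cut. Accessibility is a sparse background of
low peaks plus one dominant peak over every SNP — mirroring the practice of
analyzing SNPs near peak regions — and each paired CpG carries a co-peak
whose height tracks its SNP's peak (one regulatory unit), so the
accessibility that modulates the effect is visible both at the SNP's cut
and at the central cut. The case track rescales each SNP's regulatory unit
(SNP peak and linked CpG peaks) by $1 \pm 0.5$ with a per-SNP condition
sign, and the truth table records the resulting noise-free case and control
slopes.

`make_separable()` is the noise-free, large-effect variant
($\sigma = 0$, $\beta_0 = 5$) on which direction is a deterministic
function of the motif flag — the learnability benchmark.

What the generator does not emulate, and hence what passing tests cannot
show about real data: linkage disequilibrium between SNPs, methylation
beta-value distributions and probe chemistry, single-cell sparsity,
sequence context beyond base composition (no real motif grammar), and any
discrepancy between planted exponential decay and true distance dependence.
Results on synthetic data demonstrate that the machinery can recover
planted structure of realistic shape and scale — not that the model attains
any particular accuracy on biological data.

## Numerical and design notes

* Overlapping bedGraph intervals resolve last-writer-wins with a warning;
  negative or non-finite signal is an error.
* Slope exactly 0 is excluded from both tasks: its direction is undefined
  and the positive/negative definition is exhaustive only for nonzero
  slopes.
* The decision-tree probe for representation comparison pins its contract
  (Gini impurity, minimum split 2, no cost-complexity pruning, depth cap
  30, fixed fold seed) rather than inheriting any library's drifting
  defaults.
* AUC is computed as the normalized rank-sum statistic with half credit for
  ties — identical to trapezoidal ROC area and simpler to verify against a
  brute-force pair count.
* Ties in top-CpG ranking break by CpG id; nearest-TSS ties break by gene
  id; both make ranked outputs permutation-stable.
* The fallback peak caller and the `log1p` accessibility toggle are
  conveniences, default-off or clearly subordinate to externally supplied
  peaks/normalization.

## Known limitations

The dense-encoder ablation flattens the window, so its parameter count
grows with $T$; comparisons with the recurrent encoder are architecture
comparisons, not parameter-matched ones. LARGE-class training (401
timesteps) is supported but slow on a single CPU at the default sizes.
Fine-tuning reuses the training loop from existing weights and records
provenance, but no layer freezing is offered. The package trains on one
device; no attempt is made to make results identical across BLAS
implementations.
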