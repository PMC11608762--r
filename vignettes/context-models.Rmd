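---
title: "Stochastic context models: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic context models: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmbench)
```

## Why procedurally defined image distributions

Evaluating a generative image model on real biomedical data is hard because
no ground truth exists for a newly generated image: there is no formula for
what a breast slice or a pathology field *ought* to look like. A stochastic
context model (SCM) sidesteps this by prescribing the image distribution
procedurally, so that every contextual rule — feature prevalence, relative
positions, intensity–size relationships, texture — is exactly known and,
crucially, recoverable from the pixels after the fact. An ensemble produced
by any generative model trained on SCM data can then be audited image by
image: every constraint either holds or it does not, and the error rate is a
direct measure of how much domain-relevant structure survived generation.

`scmbench` implements three such models, a simplified anatomical phantom, the
ensemble-level evaluation framework, and — because an analyzer is only
trustworthy if it has been validated — a set of corruption injectors that
plant known violations at known rates so every detector can be calibrated
against ground truth.

## The three context models

**Alphabet model.** A 256×256 realization is an 8×8 grid of 32×32-pixel
letter tiles over the alphabet {H, K, L, V, W, X, Y, Z}. Every realization
contains exactly 24 H, 2 K, 16 L, 1 V, 1 W, 8 X, 8 Y and 4 Z, and the paired
letters occur only inside ordered pairs: every X has Y immediately to its
right, and every K, V and W has Z immediately above it, giving per-image pair
prevalences of 8 (X–Y), 2 (Z–K), 1 (Z–V) and 1 (Z–W). The sampler places the
twelve pair "dominoes" at uniformly random admissible positions in random
order, restarting when a domino has no slot, and fills the remaining forty
cells with a shuffled multiset of H and L — constraints hold by construction,
never by rejection after rendering. Letter placement is otherwise free, which
is what makes distinct realizations diverse.

Recovery is template matching: each tile is scored against all eight glyph
bitmaps by normalized cross-correlation (Pearson correlation of pixel
vectors) and assigned the argmax. The glyph set is a versioned fixture of
block letters whose pairwise scores all lie below 0.8, so the assignment is
unambiguous; on clean renders every score is exactly 1. A realization counts
as *recognizable* only if all 64 best scores reach the rejection threshold
(default 0.9 — the score of a clean tile is 1 and of a wrong or degraded
tile well below 0.8, so any value in between separates them; degraded tiles
are reported individually for audit).

**Voronoi model.** A realization partitions the image into `c` Voronoi
regions around spatially random centers, where `c` ∈ {16, 32, 48, 64} is the
class. Region boundaries are rasterized as one-pixel zero-intensity edges
(a pixel is an edge pixel when its nearest-center label differs from its
right or bottom neighbor — the one-sided convention is what keeps the edge
one pixel wide). Each region takes a constant gray level from a palette of
128 values evenly spaced over [1, 254], assigned so that the Spearman rank
correlation between region area and gray level is exactly 1: a random
`c`-subset of the palette is drawn and sorted against the sorted areas.
Center sampling enforces a minimum pairwise separation of 8 pixels
(rejection sampling); without it, sub-resolution regions defeat the
one-pixel-edge recovery. Area ties, which would make exact rank correlation
unattainable under tie-aware ranks, are removed by resampling centers (they
are rare after rasterization but possible).

Recovery mirrors the construction: a Sauvola local threshold isolates the
dark edge network, Guo–Hall thinning reduces it to a one-pixel skeleton, and
the 4-connected components of the complement are the regions (modal gray,
component area). Two conventions matter here. First, the Sauvola window is
9 pixels with k = 0.2: a larger window darkens a halo up to half the window
width around strong contrasts, and with the palette reaching down to gray 1
a wide halo can swallow an entire small dark region — at window 9 the halo
reach (4 px) stays below the 8-px center separation and the region count is
recovered exactly on clean data (measured zero error over 60 realizations
across all classes; at window 15 up to five regions per image were lost).
Second, the mask is padded with a foreground frame before thinning: walls
that terminate on the image border would otherwise retract (the medial axis
of a thick blob stops short of the border) and silently merge the two
regions they separate.

Implicit context — statistics nobody prescribed but the construction
implies — is summarized by a 7-vector: region count, junction count,
junction density, mean/SD of edge (skeleton branch) lengths, and mean/SD of
region areas. Junctions are clusters of skeleton pixels with ≥ 3 neighbors;
branches are the 8-connected runs between them.

**Flag model.** An eight-class model on a 16×16 grid of 16×16-pixel tiles. A
fixed binary template matrix (256 tile indices × 8 classes) marks each tile
foreground or background; every class has exactly 80 foreground tiles, so
the total foreground pixel count is constant across classes, and 24 indices
are foreground in *no* class ("forbidden" tiles). Pixel intensities are
independent scaled-Beta draws — foreground 152·X+96 with X ~ Beta(4, 2),
background 192·X+8 with X ~ Beta(2, 4) — rounded to integers, so the
supports are [96, 248] and [8, 200] and the means 197.33 and 72. The
template matrix itself is a constrained-random fixture (seed 1 shipped as
plain text); a repair pass guarantees that exactly the 24 drawn forbidden
indices stay never-foreground.

Recovery classifies a tile as foreground when its mean exceeds the midpoint
of the two theoretical tile means, 134.67; the per-tile error probability of
that rule on clean data is below 10⁻⁶, so clean pattern recovery is exact in
practice. Class identity is the argmin of mean absolute error against the
eight template columns (relative MAE = absolute error / 80; ties go to the
lower class id). Texture randomness is checked per tile by Moran's I with
binary rook weights — the null expectation for independently placed variates
is −1/(n−1) = −1/255 — against a [0.5, 99.5] percentile band simulated from
clean tiles. Intensity laws are checked by a chi-squared statistic of the
pooled foreground (and background) pixels against 16 equal-width bins per
support, with bin probabilities computed exactly for the *rounded* variates
from the Beta CDF; an image is acceptable when both statistics are at or
below the 99.5th percentile of a clean reference ensemble (500 images by
default in our tests — smaller references estimate that tail percentile
poorly).

## The phantom fixture

The phantom is a deliberately simplified stand-in for an anatomy-derived
stochastic object model of the breast: it reproduces only the recoverable
properties the evaluation needs, not anatomy. Each 512×512 image has a zero
background; a randomly placed, slightly modulated ellipse as the breast-like
region; a ligament web drawn as the Voronoi ridge network of 30–45 random
seed points clipped to the region; and a fatty/glandular tissue mosaic
obtained by thresholding a smoothed noise field at the quantile that
realizes a target fatty-to-glandular (F/G) pixel ratio. Intensity bands are
disjoint by construction — background 0, glandular [60, 120], fatty
[150, 200], ligament [230, 255] — so global thresholding segments tissues
*exactly* on clean images. The four density classes are defined by disjoint
F/G intervals (fatty [3, 5), scattered [1.5, 3), heterogeneous [0.5, 1.5),
dense [0.1, 0.5)) and allocated 1:4:4:1 across an ensemble by
largest-remainder rounding, i.e. 10/40/40/10 percent.

What the phantom does **not** emulate: attenuation physics, 3-D anatomy and
slicing, intra-tissue intensity gradients, overlap between tissue intensity
distributions, or any clinically meaningful morphology. Tests that pass on
phantoms therefore demonstrate that the *pipeline* is correct and calibrated
on data satisfying its assumptions, not that it would segment real
mammography; on real data the global-threshold segmentation step in
particular would need to be replaced.

## Corruptions and detector calibration

Every analyzer is validated by injecting exactly one violation of a named
kind into a controlled fraction of a clean ensemble and checking that the
matched detector recovers the injected rate. One violation per affected
image keeps recall unambiguous. The modes and their matched detectors:

| model | mode | detector |
|---|---|---|
| alphabet | reversed X–Y pair | pair audit (count + orphans) |
| alphabet | extra Z–K pair | pair audit |
| alphabet | orphaned letter | pair audit |
| alphabet | H→L substitution | exact letter-multiset check |
| voronoi | permuted region intensities | recovered Spearman ρ < 0.9 |
| voronoi | erased edge segment | disjoint-edge signature (below) |
| voronoi | off-class region count (40 or 80) | recovered count > 2 from every class |
| flags | misplaced foreground tile | RMAE error tiles |
| flags | foreground on a forbidden tile | forbidden-index flag |
| flags | wrong foreground intensity law | chi-squared screen |
| phantom | broken ligament | interior skeleton endpoint |

Two detectors deserve comment. An erased Voronoi edge has two possible
signatures depending on the gray contrast of the regions it separated: if
the grays are similar the regions merge in recovery, leaving a recovered
region whose nonzero pixels carry a substantial second gray level (threshold
400 pixels; clean recovery leaks only thin slivers, observed well below
that); if they differ strongly, the bare intensity step is re-detected as a
boundary by the local threshold, leaving a recovered edge segment with no
zero-valued pixel within 10 pixels (clean edges are zero-valued by
construction, and the Sauvola halo keeps clean skeleton pixels within ~5
pixels of a zero pixel). Either signature flags the image. The break is a
16-pixel disc so that both signatures clear their thresholds with margin.

The wrong-intensity-law corruption redraws foreground pixels with the
background Beta *shape* (2, 4) transplanted onto the foreground support
[96, 248]. Redrawing from the literal background law would drop tile means
below the foreground decision threshold and turn the intensity violation
into a pattern violation as well; keeping the support fixes the recovered
pattern and isolates the law violation, which is what the chi-squared screen
is meant to catch. That screen flags ~1% of clean images by construction
(two one-sided 0.5% tests), and its calibration is therefore assessed
against a binomial interval around rate + (1 − rate)·0.01 rather than
exactly.

The ligament-break detector prunes spurs (terminal branches ≤ 4 px) from the
thinned ligament skeleton and flags any remaining endpoint whose
17×17 neighborhood contains no background pixel: clean ridge networks only
terminate at the region boundary, so an interior endpoint is the signature
of a break. Margins (break disc radius 7, interior margin 8) were chosen so
the detector is empirically exact on clean ensembles of several hundred
phantoms.

## The ensemble evaluation framework

Per-image features come in four families: gray-level co-occurrence texture
summaries (contrast, homogeneity, energy, correlation at offsets {1, 2, 4}
in both axial directions, 32 gray levels, averaged over offsets); region
morphology of the glandular mask (mean/SD of area, perimeter, eccentricity,
solidity over 4-connected regions); skeleton statistics of the ligament mask
(branch count, junction count, mean/SD branch length, total length); and the
F/G ratio. Images where a family is uncomputable (an empty skeleton, say)
are flagged and excluded per family.

Features are z-scored by *training* statistics and projected onto principal
components fit on the training rows only — fitting on pooled rows would let
pathologies of the generated set distort the reference axes, which is the
wrong direction of influence for an audit of the generated set. Ten
components feed the similarity analysis: cosine similarity is computed for
10,000 random training–training pairs (distinct indices) and 10,000 random
training–generated pairs, and the two similarity distributions are
summarized by the two-sample Kolmogorov–Smirnov statistic, per family and
over all features. For the scalar F/G family, where cosine similarity
degenerates to a sign, the KS statistic compares the feature distributions
directly. Class-wise coverage and density use k-nearest-neighbor balls in
the top-2 component space with k = 5: coverage is the fraction of real
samples whose k-NN ball contains at least one generated sample, density the
mean number of real balls covering a generated sample, normalized by k.

Two properties anchor the framework's tests. Coverage/density of an ensemble
against an independent draw of itself concentrate near (1, 1) — we verify
this on 250 + 250 phantoms. And the KS summary must respond monotonically to
corruption: we verify median KS (over 10 pair-sampling seeds) is
non-decreasing as 0/10/25/50% of a 100-phantom copy is corrupted. A note on
severity: with 10,000 pairs the KS statistic between two samplings of
*identical* ensembles sits at a noise floor of about 0.02, and a single
subtle ligament break per image moves ensemble features too little to clear
that floor — a finding that itself motivates per-image detectors over
ensemble summaries for rare localized errors. The monotonicity study
therefore corrupts affected images severely (60 break sites each, largely
destroying the ligament web, as opposed to one isolated break).

## Numerical conventions and degenerate inputs

* Coordinates are 1-based row/column, row-major, origin top-left (R matrix
  convention); grids are addressed `(row, col)`.
* Seeds: every sampler takes one integer seed; ensembles derive per-image
  seeds as `seed + index` and never disturb the caller's RNG state.
* Ties: nearest-class ties go to the lower class; RMAE ties to the lower
  class id; modal gray ties to the lower gray value.
* Largest-remainder rounding allocates class counts and integer
  percentages, so reported totals are exact.
* Degenerate inputs: an all-zero image recovers zero Voronoi regions; a
  uniform nonzero image recovers one region; a constant tile has undefined
  Moran's I and is returned flagged rather than as a number; an empty
  glandular mask makes the F/G ratio `NA` with a warning.
* Corruption at rate 0 is a byte-identical no-op; affected counts are
  `round(rate × n)` without replacement.

## Problem sizes used by the test suite

The packaged tests exercise the pipelines at sizes chosen to make every
statistical statement sharp while keeping a full run comfortable on one CPU:
constraint exactness over hundreds of realizations per model; roundtrip
identity on 100 clean images per recovery operation; detector calibration at
rates {0, 0.1, 0.25} over ensembles of 200; coverage/density on 500
phantoms; monotone sensitivity on a 100-phantom training set. All banks are
seeded and shared across test files.

## Known limitations

* The Voronoi recovery conventions (window 9, minimum component area 24)
  are tuned to this generator's contrast regime; heavily blurred or
  low-contrast generated edges would need re-tuned thresholds, as any
  local-threshold pipeline does.
* Region areas are measured after edge-pixel removal, both at generation
  and recovery; analyses that define area including boundary pixels will
  differ by a perimeter-order term.
* The chi-squared intensity screen tests the pooled per-image distribution;
  it cannot localize which tiles violate the law.
* Coverage/density are computed in two dimensions by convention; with
  strongly clustered embeddings the k-NN radii of isolated points grow and
  density can exceed 1.
* The phantom's simplifications listed above bound what phantom-based tests
  can claim about real anatomical data.
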