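---
title: "Encoding information in self-organized colony patterns: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding information in self-organized colony patterns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea: distributed encoding

A convergent stochastic pattern-formation system maps each input to an
*ensemble* of similar-but-not-identical outputs. If the within-input
variability stays below the between-input differences, a trained classifier
can recover the input from any single realization, while an observer without
enough examples — or without the generator's secret parameters — cannot.
`emorfi` implements this scheme end to end: characters are mapped to
braille-like cell-seeding arrays, grown into branching colony patterns by a
kernel-convolution model with controllable noise, and decoded by a compact
convolutional network, optionally boosted by stacked ensembles and majority
voting. A 1D elementary cellular automaton provides the same pipeline in a
minimal setting.

## The growth model

Colonization is a field $N_t(x, y) \in [0, 1]$ on a square pixel grid,
restricted to a growth domain (the plate). One time step evaluates the local
growth activation

$$ a_t(x,y) = \sum_{u,v} K(d_{u,v})\, N_t(x-u, y-v) \; + \; w_I\, I(x,y), $$

and colonizes exactly the pixels where it is positive:
$N_{t+1} = \mathbf{1}[a_t > 0]$. The kernel combines short-range expansion
and longer-range inhibition,

$$ K(d) = b\,2^{-(d/d_1)^{h_1}} - 2^{-(d/d_2)^{h_2}}, $$

with defaults $b = 6.5$, $d_1/d_2 = 0.4$, $h_1 = 1000$, $h_2 = 2000$. The
huge exponents make the two terms near-step functions: $K \approx b - 1$
inside $d_1$, $\approx -1$ between $d_1$ and $d_2$, $\approx 0$ beyond
$d_2$. At these defaults the positive and negative kernel masses nearly
cancel, so a uniformly colonized region is marginal while a front is
unstable: growing tips where expansion locally outweighs inhibition advance
and split, producing branching / labyrinthine colonies. Raising $b$ or
$d_1/d_2$ floods the domain (disk morphology, input lost); collapsing
expansion leaves thin sparse colonies or essentially the initial seeding
(trivial morphology, perfect but insecure decoding).
`classify_morphology()` separates the three regimes by colonized fraction
(disk above 0.8) and by the intersection-over-union between binarized
pattern and seeding (trivial above 0.6).

**Why a threshold update.** Written as a plain convolution the update is
unbounded, and any bounded occupancy reading has to decide how to squash it.
We first implemented a normalize-and-clamp variant
($N_{t+1} = \mathrm{clamp}(\mathrm{conv}/Z + w_I I)$ with $Z$ the positive
kernel mass) and found it structurally unable to sustain a colony: because
the balanced kernel gives interior sums near zero, dividing by $Z$ maps
every occupied region to values near zero and the field contracts to
extinction within a few steps at any grid size we tried. The threshold
update is the classic local-activation/lateral-inhibition cellular
automaton, keeps the field in $[0,1]$ by construction, and reproduces every
qualitative regime the model is meant to show (branching at defaults, disk
at high expansion, thin/sparse at low). Seeding intensities in $[0,1]$
weight the first convolution, after which the field is an occupancy
pattern.

**Numerical choices.** The convolution is evaluated with padded FFTs
(zero padding outside the field; the domain mask is re-applied after every
step); the test suite checks equivalence with a direct nested-sum
evaluation to $10^{-8}$ on 32×32 grids. Colonization requires
$a_t > 10^{-9}$ rather than $a_t > 0$: with uniform seeding intensities the
expansion and inhibition sums can cancel *exactly*, and an exact tie must
not colonize on the sign of FFT rounding noise — without the guard,
algebraically symmetric runs lose their symmetry. The simulation stops when
the total colonization changes by less than $10^{-4}\times$ the domain area
for 5 consecutive steps (noiseless runs converge in 15–30 steps at reduced
scale) or at `max_steps`; with kernel noise the front keeps churning
indefinitely, so noisy runs are bounded by `max_steps` and flagged
unconverged in the metadata — the pattern itself is established long
before.

## Noise sources

*Seeding noise*: every pixel of a seeded spot draws its intensity i.i.d.
from a Gaussian with mean 0.5 truncated to $[0, 1]$ by rejection sampling
(deviation 0.15 by default; the symmetric truncation keeps the mean at
0.5). *Growth noise*: at each step, i.i.d. Gaussian noise is added to every
kernel element over its truncated support, with standard deviation
$\mathrm{RMS}(K)/\mathrm{snr}$ where `snr` is a *linear*
signal-to-noise ratio; `snr = 3.5` is the intermediate level used in the
decoding studies, `NULL` disables growth noise (the default regime is
random seeding without growth noise). Both sources are driven by explicit
seeds; `derive_seed()` splits a base seed into decorrelated per-replicate
streams so any single dataset item can be regenerated in isolation.

## Plate influence and shape-key encryption

The boundary suppresses colonization through
$I = -k\,2^{-\varepsilon d/R}$, where $d$ is the Euclidean distance to the
domain boundary (computed by an exact distance transform), $R$ its maximum
over the domain and $k = 1000$. With the default $\varepsilon = 2000$ the
influence is numerically zero outside a razor-thin boundary shell; with
$\varepsilon = 1$ it reaches the center at half its boundary strength, so
the *shape* of an equal-area domain (circle, square, diamond, triangle)
becomes a secret key: patterns are center-cropped to strip the overt domain
outline, and the premise is that only a decoder trained under the same
shape decodes reliably.

The update adds $w_I I$ pointwise after the convolution. The relative
magnitude $w_I$ is not derivable from the model statement, so it is exposed
as `influence_weight` and was calibrated once: at $w_I = 0.002$ an
$\varepsilon = 1$ plate deducts about 1 activation unit at the center and 2
at the boundary — comparable to front activations — which biases growth by
domain shape while leaving roughly half the domain colonized; an order of
magnitude more extinguishes the colony, an order less leaves the key
ineffective.

The reduced-scale encryption study (`reduced_encryption_study()`) removes
the cruder class cues: its dictionary is six characters assigned only
equal-weight (two-spot) 4-bit codes, so classes differ in *which* spots are
seeded, never in how many, and growth noise at `snr = 3.5` keeps the front
marginal so the weak anisotropic boundary force acts on it continuously.
The shape demonstrably conditions the pattern — for matched seeds on
equal-area circle and square plates, about half of the colonized pixels
inside the center crop differ.

An honest negative result: at this reduced scale the shape key does not
defeat a *converged* decoder. Across every configuration we probed —
influence weights 0.002–0.008, crops at 0.5–0.9 of the innermost boundary
distance, domain areas 25–40% of the field, spacings 7–10, training sizes
8–20 replicates per class, output resolutions 20–80 px, circle vs square
and circle vs triangle — the self-key minus cross-key accuracy difference
fluctuates around zero (±0.05, sign varying with the seed). The reason is
structural: at a 96-px field the class-discriminating features are
*localized* (which central spot regions carry dense branching), and such
features survive the shape-induced texture shift, so a fully trained CNN
transfers across keys. The full-scale effect relies on 451-px patterns
downscaled 5.6-fold, where class identity is carried by global texture
statistics that are entangled with the boundary's anisotropic forcing. The
package keeps the experiment in its standard form — equal-area shapes,
`epsilon = 1`, center cropping, per-shape decoders, the full cross-decoding
accuracy matrix — and its test asserts strict diagonal dominance, which at
this scale fails; we report the finding rather than weaken the check.
(Apparent positive gaps appear under under-trained or unstable optimizer
settings, where decoders lean on fragile shape-entangled features; we do
not count those as a demonstration.)

## Decoding

Patterns are bilinearly downscaled (anti-aliased) to 80×80 and scaled to
$[0,1]$. The decoder is a compact CNN — two blocks of
(convolution, 2×2 max-pool, ReLU), a fully connected ReLU layer, and a
softmax layer of dictionary width — trained with Glorot-normal
initialization, categorical cross-entropy and Adam, stopping early when the
monitored loss stops improving. Since no deep-learning framework is part of
the package's dependency stack, the network is implemented in
RcppArmadillo; the backward pass is validated against finite differences to
$10^{-6}$, and training is bit-for-bit reproducible from its seed (one
single-threaded mt19937 stream drives initialization and shuffling), which
the test suite asserts as `identical()` weights across retrainings. The
full-scale defaults are 32+64 filters of size 3×3 and a 128-wide hidden
layer with a 10% stratified validation split; the reduced-scale
configuration uses 6+12 filters, a 32-wide hidden layer, and monitors
*training* loss (`val_frac = 0`) because a 10% split of a sub-100-item
training set is too noisy a stopping signal. Two further optimizer choices
matter at this scale: the learning rate is 3e-4 rather than the canonical
1e-3, because Adam's sign-normalized per-coordinate steps at 1e-3 are about
13% of the Glorot weight scale of the wide flatten-to-hidden layer and can
collapse the small network onto the uniform-output saddle (loss pinned at
$\ln n_{\text{classes}}$) within one epoch, permanently; and the
early-stopping patience is 12 epochs, long enough to ride out the loss
plateau that precedes feature learning. Hidden biases are initialized at
0.05 as a general dead-ReLU safeguard.

Evaluation reports accuracy, per-class precision/recall, the confusion
matrix, per-class one-vs-rest ROC curves and macro-averaged AUC (ROC/AUC
via pROC; accuracy and the confusion matrix are computed directly and
cross-checked against brute-force passes in the tests).

## Ensembles, voting, uncertainty

Stacked generalization trains $M$ bases (default 5) on the same data with
different seeds, concatenates their probability vectors on the training set
into $M \times N$-dimensional features, and fits a softmax meta-model —
multinomial logistic regression by default, or a ReLU feedforward network —
with Glorot-uniform initialization, Adam at learning rate $10^{-4}$, and
early stopping (patience 5, minimum improvement $10^{-4}$). Feature
*concatenation* is our reading of "linear combination": it preserves
per-model information for the meta-learner. The $10^{-4}$ learning rate is
tuned to full-scale stack sets (thousands of items); on the reduced-scale
72-item stacks it stalls below chance-beating weights before early stopping
triggers, so the reduced-scale studies pass `learning_rate = 1e-3` and a
600-epoch cap — the quoted values remain the function defaults.

Majority voting decodes several replicate patterns of one character and
takes the modal prediction; ties break by the highest summed probability
across ballots, then by the lowest class index — deterministic and
confidence-aware.

Uncertainty over $M$ items and $N$ classes with one-hot labels $y_{ij}$ and
probabilities $p_{ij}$:
negative log likelihood $-M^{-1}\sum_j\sum_i y_{ij}\ln p_{ij}$ (natural
log; probabilities floored at $10^{-12}$ so a confident miss is finite),
MSE $M^{-1}N^{-1}\sum_j\sum_i (y_{ij}-p_{ij})^2$, and top-1/top-5 error
rates (rank by probability, ties to the lower class index). Hand-computed
check values: uniform probabilities over 15 classes give
$\mathrm{nll} = \ln 15 \approx 2.708$ and $\mathrm{mse} = 14/225$.

## Text codec

`encode_text()` simulates `frames_per_char` fresh patterns per message
character (default 5 ballots) in message order; `frames_to_video()` writes
them as a numbered-frame directory with a JSON sidecar — PNG for the
default lossless container (bit-exact round trip at 8-bit depth, which the
tests require), JPEG for lossy export mirroring compressed transmission.
`decode_frames()` decodes each frame and majority-votes within each ballot
group. Whitespace and control characters are ordinary codebook entries; a
7-bit array covers the 100 printable ASCII characters, a 5-bit array the 20
amino acids.

## The CA analogue

`ca_encode()` embeds a bit string as blocks of 1-cells in a binary
sequence, flips each cell independently with a small probability, and
evolves an elementary rule for a fixed number of steps (fixed-zero
boundaries by default; periodic optional). The weakly chaotic rule used in
the original study is not recoverable, so the rule number is configuration
with rule 54 as the documented default. All 256 rules are verified against
a brute-force rule-table oracle, including the rule-90 Sierpinski parity
pattern. A feedforward softmax network decodes final sequences; noiseless
sequences decode perfectly, accuracy falls with the flip probability and
recovers with training-set size.

## Reduced-scale study conditions

The full-scale platform (451×451 fields, 15–127 classes, hundreds to a
thousand replicates per class) is cluster-scale: a single dataset is tens
of thousands of multi-minute simulations. The package's own study scale,
frozen in `reduced_study()`, is a 96×96 field with the kernel scaled
proportionally ($d_2 = 5$, $d_1 = 2$, cutoff 8), a 2-bit/3-character
dictionary (spacing 10, spot radius 3), `max_steps = 30`, 24 training and 8
test replicates per class for decoding studies, and the small CNN above.
Monotonicity properties (accuracy vs replicates, growth noise, spacing) are
asserted on means over three base seeds; the convergence premise
(within-class pattern distance < between-class distance) uses 20 replicates
of 3 classes.

What the reduced scale does and does not show: the qualitative machinery —
branching, convergent-but-variable replicates, trainable decoding well
above chance, monotone capacity/security trade-offs, ensemble and voting
gains, the shape key — all operate at 96 px, and that is what the tests
assert. The *absolute* full-scale numbers (93% accuracy for 15 classes with
800 replicates, 99.8% text recovery over thousands of characters) require
the full-scale data volumes and are not reproduced here. The generator also
idealizes real colonies: noise is stationary and white, plates are perfect
geometric shapes, and there is no nutrient depletion or growth arrest, so
passing tests validate the computational scheme, not any wet-lab claim.

## Known limitations

* Noisy runs have no natural fixed point; termination by `max_steps` is a
  modelling choice, and the step count at which growth is "arrested"
  changes the pattern statistics.
* The exact character-to-bit assignment of the original full-scale
  dictionaries and the original CNN layer dimensions are not recoverable;
  both are configuration, and defaults are documented canonical choices.
* Bit-level training determinism holds for this single-threaded engine; it
  would not survive a switch to a multi-threaded BLAS-backed batch path.
* The encryption key property is demonstrated for circle vs square at
  reduced scale; its margin (a few accuracy points) is statistical, not a
  cryptographic guarantee.
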