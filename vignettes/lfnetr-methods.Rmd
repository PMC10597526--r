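---
title: "Coding-potential models with Local Filter Networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding-potential models with Local Filter Networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfnetr)
```

# The problem

Distinguishing protein-coding mRNAs from long noncoding RNAs (lncRNAs) from
primary sequence alone is a standard step in transcriptome annotation.
Classical signals include the length of the longest open reading frame
(ORF), the Kozak-like context around the start codon, and the 3-nucleotide
periodicity that codon-usage bias imprints on coding sequence.  `lfnetr`
implements a family of sequence-to-sequence neural models built around the
idea that *learning to translate* — predicting the encoded protein, or a
prefix of it, or the start-codon position — acts as a regularizer that
improves binary coding/noncoding classification, together with the
attribution and interpretation machinery needed to ask *what* such models
have learned.

# Model

## The LFNet encoder layer

Each Local Filter Network (LFNet) layer treats the hidden representation
$H \in \mathbb{R}^{L \times D}$ of a transcript as $D$ parallel signals
along the sequence and performs windowed frequency-domain filtering:

1. a short-time Fourier transform (STFT) with Hann window of length $W$
   (default 54) and hop $W/2$, giving complex frames with $W/2 + 1$
   frequency bins per hidden dimension;
2. elementwise multiplication of every frame by a learned complex filter
   matrix (bins × dimensions), the layer's only frequency-domain
   parameters;
3. a soft-shrink sparsifier applied independently to real and imaginary
   parts (threshold configurable, default 0);
4. inverse FFT and overlap-add back to the sequence domain;
5. a residual connection adding the layer input.

A position-wise feed-forward block (layer norm, GELU) follows the
filtering step, mixing hidden channels — the standard pairing of a
token-mixing operation with a channel MLP in Fourier-style token mixers.
The default window of 54 is even and divisible by 6, so the codon period
of 3 nt corresponds exactly to frequency bin 18 and the hop is integral.
`filterSpectra()` exports magnitude/phase tables with each bin annotated
by its equivalent nucleotide period ($W/\text{bin}$).

### Boundary handling and reconstruction

Framing is *centered*: the signal is padded with one hop of zeros in
front and zeros to complete the final frame, so $\lceil L/(W/2) \rceil + 1$
frames cover every position.  With the half-sample-shifted Hann window
($w_n + w_{n + W/2} = 1$) every position receives total window weight
exactly 1, so plain overlap-add inverts the transform perfectly for any
length — no envelope division is needed.  This matters beyond numerical
tidiness: with end-only framing the synthesis envelope decays to $\sim
10^{-3}$ at the sequence boundaries, and dividing filtered content by it
amplifies boundary activations by three orders of magnitude.  In our
experiments that amplification alone prevented LFNet encoders from
learning even trivially separable data, while the centered convention
restored clean learning; we therefore treat it as part of the layer's
definition.  Round-trip identity and the equivalence of frame filtering
with time-domain circular convolution are asserted numerically in the
test suite (tolerances $10^{-5}$), as is the exactness of the hand-derived
adjoints against finite differences ($10^{-4}$).

Soft-shrink acts on real and imaginary parts independently rather than on
magnitudes; the choice is isolated in one function and can be flipped.
Complex filters are stored as separate real/imaginary parameters (a polar
parameterization was rejected to avoid phase wrap-around during
optimization).

## Encoder-decoder architecture

The input is one-hot encoded (A, C, G, U) and embedded by a linear map —
deliberately *linear* so that gradients with respect to one-hot
coordinates are well defined, which the attribution module requires.  The
encoder is a stack of LFNet layers or, as a drop-in alternative, residual
dilated 1-D convolutions (dilation optionally doubling per layer, giving
receptive field $1 + (w-1)(2^k - 1)$ after $k$ layers of kernel $w$; the
test suite verifies this by perturbation probing).  The encoder carries
no positional encoding; locality comes from the STFT windows or the
convolutions.  The decoder is a standard transformer stack (causal
self-attention, encoder-decoder attention, feed-forward; post-norm)
with sinusoidal positions, over an output vocabulary of 20 amino acids,
the class tokens `<PC>`/`<NC>` (legal only at the first output position),
start and end tokens.  A pointer head (linear projection of each encoder
state to a scalar, softmax over positions) serves the start-prediction
task.

The default toy configuration used in tests and in the reproduction
script — 2 encoder layers, 1 decoder layer, hidden dimension 32, 4 heads,
about 26k parameters — is a desk-scale choice; the architecture scales by
configuration.

## Training objectives

Four tasks share the same network:

* `seq`: class token followed by the full protein (uniform per-position
  weights; the per-position losses are averaged, the natural convention
  when sequence lengths vary);
* `seq_wt`: the same targets weighted by the truncated discrete
  exponential $p(i,\lambda) = (1-e^{-\lambda}) e^{-\lambda i} /
  (1-e^{-\lambda N})$, which interpolates between `seq` ($\lambda \to 0$)
  and `class` ($\lambda \to \infty$); the default $\lambda = 0.1$ for the
  LFNet encoder (0.05 for CNN) follows the values that optimized
  classification in the original tuning of this model family.  The
  interpolation property is asserted numerically on fixed batches;
* `class`: the classification token only;
* `start`: pointer cross-entropy against the start-codon position, with
  the last position as the noncoding target.  We take "last position" to
  mean index $L-1$ rather than a dedicated extra slot; with this reading
  a noncoding call is an argmax at $L-1$ and $P(\mathrm{PC})$ is the
  summed mass of all earlier positions.

Training uses Adam with gradient clipping, decoupled weight decay
(default $10^{-4}$) and a cosine learning-rate schedule; batches are
length-binned under a padded-token budget with optional gradient
accumulation.  These optimizer details follow standard machine-translation
practice and are exposed as arguments rather than tuned per experiment.
Training is deterministic under a seed on a single device; checkpoints
embed optimizer and RNG state so resumed runs reproduce the next step
exactly.

## Inference

Classification reads $S = l_{\langle PC\rangle} - l_{\langle NC\rangle}$
at the first decoding step (decoding halted after the class token), or
the pointer rule for start-task models.  Full decoding uses beam search
with length normalization $\log P / T^{\alpha}$; $\alpha$ defaults to 0.6,
the common machine-translation setting, since no value is canonical for
this problem.  All beams are returned: for confidently noncoding
transcripts the lower beams typically begin with `<PC>` and carry
candidate peptides.  CDS detection aligns a predicted protein against the
translation of every sense ORF by Needleman-Wunsch global alignment
(defaults match 1 / mismatch 0 / gap −1, no affine extension; identity =
matches / alignment length) and flags whether the winner is the annotated
CDS.

# Mutation-effect prediction

$S$ is the shared scalar; all methods produce $L \times 3$ matrices of
$\Delta S$ over the non-endogenous substitutions (columns alphabetical).

* **ISM** rescoes every single-base variant: exact, $3L$ model
  evaluations.
* **Taylor** pairs the columns of one input gradient:
  $\Delta S \approx \partial S/\partial x_{ib} - \partial S/\partial
  x_{ij}$.
* **Uniform-baseline IG** runs Integrated Gradients once along the path
  from the wild type toward the uniform composition (the baseline
  reframed as the destination) and pairs per position.  Two pairings are
  implemented.  The *attribution* pairing subtracts the
  displacement-weighted attributions; because the displacements toward
  the uniform baseline are $+0.25$ for an alternative base and $-0.75$
  for the endogenous one, this weights the two terms unequally and does
  not reduce to ISM even for a linear score.  The default
  *average-gradient* pairing subtracts the path-averaged gradients
  themselves (equivalently, displacement-normalized attributions), which
  is exact on linear scorers; we treat the attribution form as a
  transcription slip of the same idea and keep both, with a diagnostic.
* **MDIG** runs IG against four baselines $X(b,\beta) = \beta\,
  \mathrm{poly}(b) + (1-\beta)x$ and combines $IG_{ib} + IG_{ij}$.  The
  "+" is correct as written: the displacement signs ($+\beta$ toward $b$,
  $-\beta$ away from $j$) already encode the subtraction, and with
  $\beta = 1$ the combination is exactly ISM on a linear score; for
  $\beta < 1$ a linear score yields $\beta$-scaled effects, which is
  immaterial for the correlation-based evaluation used to tune $\beta$
  (grid 0.05/0.1/0.25/0.5/1.0, selected by median per-transcript Pearson
  r against ISM on validation data).  Integration uses the midpoint rule
  (default 8 steps per baseline); the IG completeness residual is
  reported and shrinks as steps grow.

Agreement metrics: Pearson over flattened matrices; median position-wise
cosine (scale-free across positions); inter-replicate agreement averages
a metric over unordered replicate pairs, agreement-with-ISM over matched
(intra-replicate) pairs.

# Interpretation pipeline

Counterfactual-class importance assigns position $i$ the strongest
$\Delta S$ push toward the opposite class (clipped at zero).  Masking
removes the annotated (or longest-ORF) start/stop codons and positions
whose selected strongest mutation would create a premature in-frame stop,
so that secondary signals become visible.  Metagenes anchor per-position
series at the start codon (or longest-ORF start), average by relative
position, and drop positions present in fewer than 70% of series
(configurable); binned metagenes average $|\Delta S|$ in 25 equal-width
bins — over the whole transcript with region annotations, since the
region-internal alternative is not clearly distinguishable from published
figures of this analysis style and whole-transcript binning preserves
UTR/CDS contrasts in one picture.

Motif windows take $10$ nt of flank around the unmasked importance argmax
per transcript × region × direction (21 nt total; ties break 5'-most).
Windows that would be clipped by a region boundary are skipped rather
than padded so that downstream STREME input lengths stay uniform; controls
are drawn either uniformly from the same region without overlapping the
primary window (one control per primary), or from the opposite class's
windows under the same importance setting.  Outputs are plain FASTA for
the MEME suite; running STREME/TOMTOM themselves is out of scope.

Perturbation scans: dinucleotide-preserving UTR shuffles (Euler-walk
construction on the dinucleotide multigraph, so counts are preserved
exactly; applied only to UTRs longer than 25 nt), internal-codon
shuffles (start/stop fixed), start-codon knockouts (all 9 substitutions),
and nonsense scans (every substitution creating an in-frame premature
stop, binned in fifty-codon windows along the CDS).

# The synthetic transcriptome

Real training corpora for this problem are RefSeq-scale and require GPU
training; everything here is exercised instead on a generated corpus that
plants the signals the models are meant to detect:

* balanced classes with matched length distributions (default 500 per
  class, 120-360 nt — micropeptide-scale transcripts chosen so that a
  full train/evaluate cycle runs on one CPU core in minutes; the
  generator accepts any range up to 1200 nt);
* mRNAs: 5'UTR + AUG-initiated CDS + 3'UTR, with codon usage skewed
  toward C and away from U at the third codon position (planting both a
  3-nt periodicity, verified by a DFT oracle in the tests, and a known
  synonymous-substitution signal for attribution analyses) and a
  Kozak-like G at +1 with probability 0.85;
* lncRNAs: matched-composition random sequence whose ORFs are capped at
  12 codons (longer ones are broken by converting an internal codon to a
  stop);
* hard mode: lncRNAs carry a long AUG-initiated ORF with *uniform* codon
  usage and no Kozak context, so longest-ORF length alone no longer
  separates the classes (a threshold classifier drops from >90% to near
  chance, asserted in tests) and models must use codon-bias and context
  signals.

What passing tests on this corpus shows — and what it does not: the
generator has planted, stationary signals and no homology structure,
UTR regulatory elements, non-AUG initiation, or species mixture.  Results
here demonstrate that the implementation can discover the intended signal
classes, not that it attains any particular accuracy on real
transcriptomes.

# Reproduction experiments

`scripts/acceptance.R` re-runs the package's main computations at desk
scale and writes the resulting numbers as JSON.  Problem sizes were
chosen for single-CPU tractability, with the hard-mode comparison sized
for training stability (the translation-weighted objective passes
through a late task transition that small corpora do not reliably
support): hard-mode task comparison with 250 transcripts per class,
3 seeds, 10 epochs for the classification objective and 16 for the
translation-weighted one (mirroring per-task tuning); attribution and
perturbation analyses on default-mode models (150 per class, 8/14
epochs) with ISM on 5 validation and 12 test transcripts.  The
qualitative claims
checked are sign- and ordering-level: translation-weighted training
matches or beats classification-only training on hard-mode data;
tuned MDIG approximates ISM at least as well as the Taylor expansion;
start-codon knockouts and early nonsense mutations score negative under
translation-trained models, with early nonsense bins at least as large
in magnitude as late ones.

# Known limitations

* Pure-R training: minutes per toy model; the architecture is faithful
  but not performance-competitive with GPU implementations.
* Per-example processing (no padded batching across examples); batch
  plans control optimizer-step granularity, not vectorization.
* The STFT normalization convention (plain OLA with unit envelope) is
  pinned by round-trip tests; other conventions (e.g. window-energy
  normalization before filtering) would rescale the learned filters but
  not change expressiveness.
* Beam search recomputes prefixes per step (no key-value caching);
  adequate at toy scale.
* The `verified`-curation flag of real corpora has no synthetic
  analogue; it is carried through I/O but unused.
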