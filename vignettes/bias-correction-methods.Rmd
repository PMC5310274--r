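---
title: "Sequence-specific bias correction with recurrent language models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-specific bias correction with recurrent language models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During cDNA library preparation for RNA-seq, random-primer binding
efficiency depends on the local nucleotide sequence, so the probability
that a read starts at a given position is modulated by the bases
surrounding that position. The result is *sequence-specific bias*: read
starts pile up on primer-friendly contexts, and gene-level expression
estimates inherit a distortion that depends on each gene's sequence
composition rather than its abundance.

`rnnbias` corrects this bias by modelling the nucleotide context around
read 5'-ends with character-level recurrent neural network language models
and reweighting read counts by a foreground/background probability ratio.

## The model

Two language models are trained over the alphabet {A, C, G, T}:

* a **foreground** model on `2w+1`-base context windows centred on observed
  read 5'-end positions (by default `w = 10`, i.e. 21-bp windows covering
  the ten bases on either side of the read start), and
* a **background** model on windows centred at randomly offset positions
  near the foreground sites (offsets drawn uniformly from
  ±{1, …, `max_offset`}, default 30, so background sequences stay in the
  same genomic neighbourhood and share its broad composition).

Each model assigns a sequence the probability given by the chain rule,

    p(S) = p(s_1) * prod_t p(s_t | s_1 ... s_{t-1}),

with per-symbol conditionals read off a softmax output layer applied to
the hidden state of a recurrent unit. Three unit types are provided: the
vanilla tanh unit `h_t = tanh(W s_t + U h_{t-1} + b)`, the GRU
(update/reset gates), and the LSTM (input/forget/output gates with a
linear cell-state pathway). Gated units carry both an input-side and a
recurrent-side bias vector per gate; under this convention a GRU with 10
hidden units has exactly 524 parameters and an LSTM with 20 hidden units
2164, the published sizes for these architectures
(`count_parameters()`). The first symbol's probability is produced from
the zero initial state with an all-zero begin-of-sequence input vector,
which keeps the input dimension at four and the parameter counts intact.

The bias weight of a read `r` whose context window is `s` is

    bias(r) = p_fg(s) / p_bg(s),

and bias-corrected expression divides each position's read count by its
weight before FPKM normalisation:

    FPKM(g)      = 1e9 *  sum_i n_i          / (length(g) * N)
    FPKM_corr(g) = 1e9 *  sum_i n_i / bias_i / (length(g) * N)

where the sum runs over the gene's exonic read-start positions and `N` is
the raw total mapped-read count — deliberately *not* renormalised after
reweighting, so the corrected values stay on the raw formula's scale.
Contexts enriched among observed read starts get weights above 1 and are
down-weighted.

## Training and model selection

Models are trained by backpropagation through time over the full
fixed-length windows, minimising the mean per-symbol negative
log-likelihood with mini-batches (default 50) and element-wise gradient
clipping (default ±5). The default optimiser is RMSprop (decay 0.95,
learning rate 2e-3). That choice is deliberate: the discriminating signal
in context windows is largely *positional* (a motif at a fixed offset from
the read start), which the network can only express by encoding the step
number in its hidden trajectory. In our experiments plain SGD at any
learning rate between 0.1 and 1.0 stays pinned at the uniform model
(per-symbol NLL ln 4) on such data, while RMSprop's per-parameter step
scaling breaks the plateau reliably; plain SGD remains available through
`train_config(optimizer = "sgd")` and is perfectly adequate for
content-driven structure such as Markov dependencies. Weights are
initialised i.i.d. uniform on ±0.08, biases at zero.

After every epoch the validation next-symbol prediction error rate is
recorded, and the returned parameters are the checkpoint with the minimum
validation error rate (ties resolved toward the earliest epoch, with the
untrained initialisation included as epoch 0, so selection can never
return something worse than the start). Perplexity is reported per symbol,
`2^(-mean log2 p)`: 4 is chance level for a 4-letter alphabet, and a value
meaningfully below 4 on foreground windows indicates learned context
structure. Model quality is intentionally modest — lightweight models (10
to 20 hidden units) are preferred because the task is discriminating two
closely related distributions, where extra capacity mostly buys
overfitting.

## Numerical choices

* Log-softmax uses max-subtraction; probabilities are never materialised
  below about 1e-300, and all sequence scores are handled in log space.
* Analytic BPTT gradients for all three unit types are verified against
  central finite differences in the test suite (relative error < 1e-4).
* Argmax ties in the prediction error rate are broken in fixed alphabet
  order A < C < G < T.
* Model files are JSON with numbers written at 17 significant digits,
  which round-trips IEEE doubles exactly; save/load is lossless.
* Bias weights are optionally clamped into `[1/clip, clip]`
  (off by default) to guard against ratios driven by vanishing
  probabilities; sites whose window is undefined (contig edge, or an N in
  the reference) receive weight 1 and are flagged rather than dropped.
* Coordinates are 0-based half-open internally; SAM input is converted
  from 1-based on read, and minus-strand windows are reverse-complemented
  so the model always sees the priming-proximal orientation.

## What the simulator emulates

`simulate_dataset()` generates an i.i.d. uniform genome, non-overlapping
forward-strand gene models, log-normal gene abundances (meanlog 0,
sdlog 1, normalised), and read 5'-end positions drawn from a single
categorical distribution over all exonic positions with weight

    abundance(gene) * exp(sum_j M[j, base_j]),

where `M` is a known positional weight matrix (PWM) over the context
window. A read's selection probability therefore depends jointly on
transcript abundance and on the local sequence — the coupling the
correction is designed to undo. The per-gene total is then proportional
to abundance times the gene's *mean PWM weight*, which is exactly the
distortion a perfect correction removes; a two-stage scheme that first
fixes per-gene read totals and only then places reads within the gene
would cancel the injected bias at the gene level and leave nothing for
the correction to recover. With a zero PWM the scheme reduces to uniform
starts within genes and totals proportional to abundance × length, so
FPKM estimates abundance directly.

The log-linear PWM is the simplest mechanism in the class this method
targets and admits closed-form checks (`pwm_weight()` is log-additive and
exactly invertible). The simulator deliberately omits fragment-length
distributions, sequencing errors, PCR duplicates, positional 5'→3' decay
along transcripts, reverse-strand reads and paired ends: passing the
recovery tests therefore demonstrates that the estimator removes
*context-driven* selection bias under ideal mapping, not that it is
robust to every artefact of real libraries.

`example_bias_pwm()` provides the "strong bias" setting used throughout
the tests: one favoured (+ln 3) and one disfavoured (−ln 3) base at each
of the five positions centred on the read start.

## Problem sizes used in the checks

The recovery analyses in the test suite and `scripts/acceptance.R` run a
deliberately scaled-down protocol chosen once for this package: simulator
defaults (200-kb contig, 100 genes × 450 exonic bp, 50,000 reads), 3,000
foreground and background windows (versus 100,000 in a full-size run,
which remains the sampling default in the command-line interface), GRU-10
models trained 12 epochs with RMSprop at learning rate 3e-3. At this
scale the full biased-plus-control analysis completes in about a minute
on one CPU while the injected bias is still recovered on essentially
every seed: corrected FPKM correlates better with the simulated truth
than raw FPKM, and with no injected bias the correction is a near-no-op
(root-mean-square log10 fold change around 0.01).

## Known limitations

* Context windows are extracted in genome space; spliced (transcript
  space) windows for reads near exon junctions are not assembled, and
  windows that run off a contig or contain N are excluded from training
  and left uncorrected (weight 1) at scoring time.
* Bias estimation is marginal, not joint with abundance estimation
  (unlike VLMM-based joint estimators); isoform-level quantification is
  out of scope.
* The corrected FPKM keeps the raw total-read denominator, so corrected
  values are comparable to raw ones but their sum is not re-normalised.
* Single recurrent layers only; the implementation targets the
  lightweight regime (hidden ≤ ~32) and is pure R — adequate for these
  model sizes, not for deep stacks or genome-scale training sets.
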