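---
title: "Modelling spoken-word recognition with dynamically unfolding phonological input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spoken-word recognition with dynamically unfolding phonological input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lexcompnet)
```

## The modelling question

In visual-world experiments, listeners hearing a spoken word in a display
that does not contain the word's referent briefly look at a *phonologically*
related picture first, then shift their gaze to *semantically* and
*visually* related pictures. `lexcompnet` implements a minimal
bottom-up account of this crossover: a gated recurrent unit (GRU) receives a
word's phonology one timestep at a time and learns to produce, and hold, the
word's static semantic, visual, and lexical representations at its output.
There is no feedback from meaning to sound and no explicit attention
mechanism; the time course of the output's similarity to each candidate's
stored representation is itself the attention proxy. If the early
phonological preference emerges here, incremental unfolding of the word is
sufficient to produce it.

## Representations

**Dynamic phonological input.** Every phone is a binary vector of 20
articulatory/phonological features. A word unfolds as a matrix with one row
per timestep: two ramp-up rows out of silence, one row per phone, two
co-articulation rows between consecutive phones, a reserved all-ones
segmentation character marking the word offset, and two ramp-down rows back
to silence. Co-articulation rows interpolate linearly at fractions 0.05 and
0.95, so a feature going from 1 to 0 passes through 0.95 then 0.05; the same
rule leaves features that do not change untouched and handles arbitrary
value pairs. Ramp-up starts from the all-zero silence state (the natural
origin, since padding is also all-zero). A label of $p$ phones occupies
$3(p+1)+2$ rows; with 10 phone slots (the longest word plus the segmentation
character) all trials pad to $3 \cdot 10 + 2 = 32$ rows.

**Static targets.** The lexical representation is the slotted concatenation
of the phone codes plus the segmentation code, zero-padded to
$10 \times 20 = 200$ entries. Semantic and visual representations enter as
real-valued matrices (at full scale, 100-dimensional word-embedding vectors
and 512-dimensional image-network activations) and are preprocessed by
(i) replacing per-dimension outliers — absolute z-score above 2, population
standard-deviation convention — with the dimension median, (ii) for the
visual matrix only, principal-component reduction, and (iii) per-dimension
median binarization, with values equal to the median assigned to the 0 bin
(the tie side is configurable; a median split leaves ties genuinely open).
The training target of an item is the concatenation semantic ‖ visual ‖
lexical; the order is arbitrary but fixed and recorded in checkpoints.

All similarity is the Jaccard index $J(u,v) = |u \cap v| / |u \cup v|$ over
the components equal to 1. Two all-zero vectors are defined to have $J = 1$
(they are identical); the case does not arise in practice.

## Model and training

The GRU follows the standard update/reset-gate equations
$u_t = \sigma(W^u x_t + H^u h_{t-1})$,
$r_t = \sigma(W^r x_t + H^r h_{t-1})$,
$h'_t = \tanh(W x_t + r_t \odot U h_{t-1})$,
$h_t = u_t \odot h_{t-1} + (1-u_t) \odot h'_t$,
with the hidden state itself the model output, so the hidden dimensionality
equals the aggregated target length (450 at full scale). Weights initialize
uniformly in $\pm 1/\sqrt{d_h}$ under a run seed; models trained under
different seeds differ only in this initialization. The initial state of
every trial is zero; no state carries over between trials.

Training is full-batch gradient descent with learning rate 0.4, momentum
0.4, and Nesterov momentum in the standard deep-learning formulation
($v \leftarrow \mu v + g$, step $g + \mu v$). The loss is the mean squared
error between the hidden state and the constant binary target, averaged over
*all* timesteps, dimensions, and items — the target stays active for the
whole trial, including the zero-padded region after the word offset, which
teaches the network to hold its output. A binary cross-entropy alternative
on the $(h+1)/2$ rescaled state is available via `loss_kind = "bce"`.
Gradients come from hand-derived backpropagation through time; the analytic
gradients are verified against central finite differences in the test suite,
and the compiled (RcppArmadillo) training loop is verified to produce
updates identical to the plain-R reference implementation.

Recognition is evaluated at each item's word offset (the last non-padded
row, i.e. the end of the ramp-down after the segmentation character): the
output is binarized at 0.5 — targets are 0/1 and the state is
tanh-bounded, so 0.5 is the natural midpoint; a min/max fuzzy-Jaccard
variant is available — and scored by Jaccard against every item's
semantic-visual and lexical segments separately. The argmax per segment is
the model's answer; ties break deterministically to the lowest item index
and are flagged. Training stops early once the percentage of items with
both constituents correct holds at criterion for a configurable number of
consecutive evaluations (optionally also requiring a loss level).

## Target-absent visual-world simulation

Candidate sets are built from the pairwise Jaccard tables over the full
vocabulary (self-pairs excluded). A pair is semantically or visually
*related* when its index is at or above the 85th percentile of all pairwise
values, *unrelated* at or below the 15th percentile; ties at the threshold
count as satisfying the criterion. Phonological relatedness is sharing the
onset phone; rhyme is the phone sequence from the last vowel to the label
end (a final-$n$-phone alternative is configurable). For every
consonant-onset target the simulator exhaustively enumerates tuples (PREL,
SREL, VREL, UREL) meeting the selection criteria; vocabularies too small or
too uniform to contain such tuples yield zero trials with a warning.

During a trial the target's unfolding input is fed to a trained model and,
at each timestep, the binarized semantic-visual segment of the output is
scored against each candidate's semantic-visual representation (250
dimensions at full scale; the lexical segment plays no role in the display).
The attended candidate is the argmax; relative activations subtract the
unrelated candidate's value, making UREL identically zero. Grand averages
pool trials and model seeds, with bootstrap 95% percentile intervals over
trials, and report the crossover timestep — the first timestep at which mean
SREL relative activation exceeds mean PREL after PREL has led.

## What the synthetic generator emulates

Real corpora supply structure that the model exploits; the generator
reproduces exactly those properties and nothing more:

* **Cohorts.** 60% of consonant onsets concentrate on five onset phones
  (b, k, p, s, t), yielding a few large cohorts and many small ones; 5.5%
  of labels are vowel-initial. Lengths are uniform over 2–9 phones.
* **Inventory.** 26 consonants and 13 vowels with distinct random binary
  codes (never all-ones, which is reserved, and never all-zeros, which
  would be indistinguishable from silence). Real articulatory feature
  geometry is *not* emulated: random codes carry no phonetic similarity
  structure, so phone confusability effects are outside what passing tests
  show.
* **Semantics.** Binary category prototypes (Bernoulli 0.5) with
  per-dimension flip probability 0.1 give within-category Jaccard clearly
  above between-category, mirroring category structure in word embeddings.
  Synthetic semantic matrices are generated directly in binarized form.
* **Vision.** Visual vectors mix the semantic category's visual prototype
  (probability 0.3, the `sem_vis_coupling` default — low enough that
  semantically and visually related candidates remain dissociable, as the
  trial criteria require) with an independently assigned visual cluster's
  prototype, then are continuousized ($2b-1$ plus Gaussian noise, sd 0.5)
  with sparse injected outliers (rate 0.005, magnitude 8) so the full
  outlier-replacement → PCA → binarization pipeline is exercised end to
  end.
* **Lexical forms.** Slotted vectors over variable-length labels reproduce
  the right-skewed pairwise-similarity distribution that slot sharing
  induces (tested as positive skewness across seeds).

What the generator does *not* reproduce: word frequency, age-of-acquisition
structure, real embedding anisotropy, or graded phonetic similarity.
Results on synthetic corpora therefore establish that the *mechanism*
produces the qualitative patterns, not that real-corpus effect sizes are
matched.

## Problem sizes and numerical choices

The full-scale regime (200 items, hidden dimension 450, twenty models,
100,000 epochs) is supported by the code but is not what the bundled tests
run. The package's standard scaled-down study (`scaled_study_config()`,
`run_scaled_study()`) uses 50 items with the generator defaults above,
semantic dimension 24, visual dimension 12 after reduction, and the fixed
lexical 200, giving hidden dimension 236 and 32-row trials. The effective
step size per weight scales inversely with the output dimensionality under
a mean loss, which is why the full-scale regime needs on the order of
$10^5$ epochs while the scaled study converges within a few thousand. The
scaled study trains under the cross-entropy objective: both objectives
reach sustained full recognition at this scale, but cross-entropy keeps
pushing output bits across the decision threshold once squared-error
gradients have flattened (its measured epoch count to criterion is about
2.4 times lower here), and it additionally attains exact binarized-target
recovery at word offset. Squared error remains the package default.

Ordering analyses run multi-seed to stay cheap: the length/cohort
learning-rate splits use five seeds of a 16-item corpus at 6 slots (labels
2–5 phones, with the long/short cut scaled to 4 phones), and the
visual-world crossover trains five model seeds on the engineered 10-item
fixture vocabulary at 4 slots — one trial-bearing vocabulary, many models,
mirroring the full-scale one-vocabulary/twenty-models design. Randomly
generated vocabularies of desk size rarely contain valid candidate tuples:
a tuple needs several jointly rare percentile events, and at 50 items
(about 1,200 pairs) the expected count is near zero, whereas the
full-scale vocabulary's roughly 20,000 pairs make a few hundred trials
findable. The engineered fixture holds exactly the structure the criteria
demand, at the 50% active-bit density that median binarization produces
on real embeddings.

Numerical details worth recording: population (divide-by-$n$) standard
deviation in outlier z-scores; zero-variance dimensions never flag
outliers; `prcomp` on centered, unscaled data for the reduction step, with
variance explained as the eigenvalue ratio; median ties binarize to 0;
quantile thresholds use R's default (type 7) interpolation; argmax ties
resolve to the lowest index everywhere and are flagged where reportable.
Checkpoints serialize weights as decimal text with 17 significant digits,
which round-trips IEEE doubles exactly; a reloaded checkpoint reproduces
the forward pass bit for bit.

## Known limitations

* The attention proxy is raw activation; no saccade generation, latency, or
  picture-preview process is modelled, so simulated time courses align with
  gaze data only qualitatively.
* Recognition binarizes the output at a fixed threshold before Jaccard
  scoring; the alternative fuzzy similarity changes absolute activation
  levels (not orderings) and is provided for sensitivity analysis.
* With small vocabularies the 15th/85th percentile criteria can admit few
  or no valid trial tuples; the engineered fixture generator
  (`gen_vwp_fixture()`) exists precisely to make that path testable.
* Convergence at the stated hyperparameters is slow by design; no adaptive
  optimizer is offered because the optimization regime is part of the
  modelled conditions.
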