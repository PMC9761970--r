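---
title: "Joint and continual entity–relation extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint and continual entity-relation extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical corpora annotate entities (chemicals/drugs, phenotypes/diseases,
proteins/genes) and binary relations between them (adverse drug events,
drug–drug interactions, chemical–protein reactions) — but each corpus covers
only its own slice of the label space. A model meant to feed a growing
knowledge graph must therefore (i) extract entities and relations *jointly*,
(ii) *expand* its label vocabulary as new corpora arrive, and (iii) avoid
*catastrophically forgetting* earlier corpora while learning later ones.

`cerex` implements a joint extractor built from four separable design axes,
each independently switchable so their contributions can be studied in
isolation:

1. **Task decomposition.** Named-entity recognition is split into span
   detection (SP) — token-level BIOES tagging, type-agnostic — and entity
   typing (ET) — classifying each detected span. Relation extraction (RE)
   classifies unordered mention pairs. All three are trained simultaneously
   from the same sentences; at inference the cascade is conditioned:
   ET runs on SP's spans, RE on SP+ET's typed mentions.
2. **Encoder sharing.** The NER branch (serving SP and ET) and the RE branch
   either share one encoder (*hard*), keep private encoders coupled by a
   cross-attention fusion (*soft*), or stay fully independent (*none*, the
   default).
3. **Pair representation.** The vector scored by the RE classifier is built
   by one of four augmentations: plain span sums (*vanilla*), span sums
   interleaved with learned 50-dim type embeddings (*type_embedding*) or
   with frozen type prototypes (*prototype*), or the hidden states at typed
   start-marker tokens inserted into the RE branch's input
   (*entity_marker*, the default).
4. **Classifier heads.** Either conventional single softmax heads, or
   expandable banks of one-vs-rest binary heads (*multi*, the default): one
   binary classifier per label, appended — never retrained from scratch —
   when a new label appears.

## Model

Tokens $x_1..x_n$ are encoded to $d$-dimensional hidden states per branch,
$h_i^{NER}$ and $h_i^{RE}$. Three two-layer feed-forward heads predict

* SP: a 5-way distribution over {B, I, O, E, S} per token from $h_i^{NER}$;
* ET: a type for each span from the *sum* of $h_i^{NER}$ over the span
  (plain sums, not means, throughout);
* RE: a relation (or none) for each mention pair from the pair vector
  $v_{jk}$.

With marker augmentation the RE branch reads the sentence with
`[Type_start]`/`[Type_end]` tokens wrapped around every mention, and
$v_{jk}$ concatenates the two *start-marker* hidden states (dimension
$2d$). Markers come from gold annotation during training and from the
pipeline's own SP/ET predictions during inference — so RE sees exactly the
span/type information the upstream stages can actually deliver.

The joint loss is the weighted sum
$\alpha^{SP} L^{SP} + \alpha^{ET} L^{ET} + \alpha^{RE} L^{RE}$ with
defaults $0.4/0.25/0.35$; in multi-head mode $L^{ET}$ and $L^{RE}$ are
*sums* of per-head binary cross-entropies (the printed summation is
followed, not a mean over heads). Mention pairs with no gold relation are
trained with all relation heads negative (multi) or as an explicit
no-relation class (single). At prediction time, heads above the threshold
$\theta = 0.5$ are candidates and the most confident one wins; ties break
to the lowest vocabulary index, and "more than one positive head" is the
condition that makes the most-confident rule non-vacuous.

### Soft sharing and the fusion product

Under soft sharing each RE-encoder layer output $H^{RE}_l$ is fused with
the NER encoder's final-layer states:
$\mathcal{H} = \mathrm{softmax}(H^{RE}_l {H^{NER}_L}^{\!\top}/\sqrt d)\,
H^{NER}_L \odot H^{RE}_l$. The trailing product is read as *elementwise*: a
matrix product of two $n\times d$ factors would be dimensionally
inconsistent. The fusion *replaces* the layer's output stream. When the RE
loss is backpropagated, the NER states entering the fusion are treated as a
fixed context (stop-gradient): the cross-attention then modulates the RE
stream without letting relation errors destabilise span/type learning, and
each branch's loss trains its own encoder. Both choices are interpretations
of an underspecified operator and are isolated in one function
(`cross_attention_fuse`) should a different reading be wanted.

### The tiny encoder

The default encoder is deliberately small: learned token embeddings plus
sinusoidal positional encodings, followed by two single-head self-attention
blocks with position-wise feed-forward sublayers and residual connections,
$d = 64$. There is no layer normalisation; stability at this depth is
handled by initialising the residual-stream writers (attention output and
FFN second layer) at small scale (sd 0.05) while embeddings start at sd 0.3
so the lexical signal dominates early training. The whole model trains on
one CPU in minutes, which is what makes the learning-paradigm experiments
below routinely reproducible. The encoder abstraction (`encoder_bundle`)
declares a slot for externally pretrained language-model encoders, but none
is bundled: every result in this package is produced by the tiny encoder.
Word-piece pooling concerns therefore do not arise (tokens are atomic); the
marker tokens are registered as indivisible vocabulary items with trainable
embeddings.

Optimisation is AdamW (learning rate 5e-4, batch 8, decoupled weight decay
0.01, biases undecayed). Gradients of all components — both encoders, the
SP head, every bank head, the type-embedding table — are derived and
applied analytically. The optimiser's moment state is *reset* at the start
of each schedule step: parameters carry over between corpora, stale
second-moment estimates do not. Prototype tables are computed once from the
*untrained* encoder (chunked max-pooling of each mention-token vector from
$d$ to 50 dims — the $d\to50$ reduction is unspecified in general, and the
contiguous-chunk maximum is the simplest deterministic max-based choice)
and are frozen thereafter.

## Continual schedules and vocabulary growth

Three paradigms are built by `build_schedule()` over an ordered corpus list:

* **continual** — one step per corpus, in order; step $t{+}1$ initialises
  from step $t$'s selected checkpoint;
* **multi_corpora** — all corpora shuffled into a single step (the
  "everything at once" upper-bound condition);
* **continual_multi_corpora** — corpus $C_i$, entering at step $i$ of $k$,
  is split into $k-i+1$ equal parts; step $t$ mixes part $t-i+1$ of every
  corpus already introduced. For three corpora this is exactly the 3/2/1
  split (step 1: first third of corpus 1; step 2: second third + first half
  of corpus 2; step 3: the remainders + all of corpus 3). Each subset is
  used exactly once — partial data replay without literal repetition.

Before each step, labels or tokens the step introduces trigger vocabulary
expansion: new embedding rows, a new binary head per new label (multi-head
mode) or new output units (single-head mode). Existing parameters are never
reinitialised or renumbered — head isolation is a tested invariant. Within
a step, the epoch with the best validation RE micro-F1 is selected (RE is
the main measure; ties go to the earlier epoch).

## Evaluation protocol

Scoring is propagation-aware and micro-averaged with counts pooled before
any ratio:

* **SP**: token-level over the BIOES tags, with O *excluded* from the
  positive classes by default — counting O would collapse micro-F1 into
  token accuracy and mask boundary errors. The switch `sp_include_o`
  restores the inclusive reading.
* **ET**: a predicted mention is TP only on exact span *and* type; a
  wrong-typed prediction on a correct span counts both an FP and an FN
  (the two counting rules are stated independently and the gold is never
  consumed by a wrong prediction; one-to-one exact-key matching makes this
  deterministic).
* **RE**: a predicted triple is TP only when both endpoints (span and type)
  and the label match; pairs are unordered (the normalised relation labels
  are symmetric).
* **ET+/RE+**: the same matchers applied to gold-conditioned predictions
  (`infer_conditional`): ET on gold spans, RE on gold spans and types with
  markers placed from gold. The gap between a stage's plain and
  gold-conditioned score is exactly the error it inherits from upstream.
* **combined**: counts summed across corpora, then one P/R/F1 — never an
  average of per-corpus F1 values.
* **corpus adaptation**: full-pipeline scoring on a corpus from a different
  annotation effort than any training data, reported separately.

## The synthetic-data generator

`generate_corpus()` emulates the *structure* of the real corpora, not their
language: each synthetic corpus owns a subset of the global entity types
and a single relation label with a fixed admissible argument-type pair
(Drug–Disease for ADE-like, Drug–Drug for DDI-like, Drug–Protein for
CPR-like). Sentences are template instantiations; mention surface forms
come from per-type pseudo-word lexicons with type-characteristic morphology
(so the type signal is lexical, as it largely is in reality), disjoint
across types. Every co-occurring admissible pair is annotated with
probability `relation_prob` (default 0.9 — real annotation is incomplete);
`noise_rate` flips a fraction of mention *type labels* within the corpus's
type set, emulating guideline deviations, and never perturbs spans. A
foreign-corpus variant shifts part of the lexicon to unseen forms, uses
different templates, and can remap a fraction of gold types — the
ingredients of a held-out annotation effort for adaptation tests.

What passing tests on these corpora shows: that the architecture,
optimisation, vocabulary growth and scoring machinery behave as specified
when the mapping from surface to label is learnable. What it cannot show:
performance on real biomedical language (sub-word chemistry, discontinuous
context, genuine annotation ambiguity). The generator is a test instrument,
not a claim about corpus realism.

## Fixed study conditions

Two benchmark setups are frozen in the package (`learnability_benchmark()`,
`forgetting_benchmark()`) so that tests, examples and the reproduction
script measure the same thing:

* **Learnability**: two noise-free corpora (Drug–Disease/ADE and
  Drug–Protein/CPR; `relation_prob = 1`, `noise_rate = 0`) of 350 sentences
  each, partitioned 5/1/1 into 250/50/50 — 500 train, 100 validation, 100
  test in total. Splits of one corpus share a lexicon (as real splits do);
  the partition is by sentence. Multi-corpora schedule, marker
  augmentation, multi-head classifiers, 30 epochs. Expected outcome: SP,
  ET and RE micro-F1 all ≥ 0.90 (typically ≥ 0.99 for SP/ET).
* **Forgetting**: corpora A (Drug–Disease/ADE) and B (Drug–Protein/CPR)
  with disjoint relation labels, 200 sentences each split into 100 train /
  50 validation / 50 test; 20 epochs per step; validation pools both
  corpora's validation parts at every step. Compared on A's test set:
  the checkpoint right after the A-only step, the end of a continual
  A-then-B run, and the end of a continual multi-corpora run. Since B's
  pairs train *all* relation heads negative (B has no A-relations), plain
  sequential training collapses A's relation head — the forgetting drop is
  large by construction — while the replay-mixing schedule keeps A's signal
  in the final step.

These sizes were chosen once as the smallest conditions at which the
phenomena are comfortably away from noise; they are not tuned quantities.

## Numerical and degenerate-input choices

* BIOES decoding is conservative: fragments that do not parse (`I`/`E`
  without an open `B`, an unclosed `B`) yield *no* span rather than a
  repaired one — a fabricated boundary would propagate into ET and RE.
* Overlapping or nested gold mentions are rejected at load time; one tag
  per token cannot represent them.
* Spans whose type aggregation returns no label (no head above $\theta$)
  are dropped from the pipeline's mention output, for the same reason.
* Softmaxes are max-shifted; binary cross-entropy is computed in logit
  space; SP/ET/RE per-sentence losses are averaged over tokens, mentions
  and pairs respectively so the loss weights keep their meaning across
  sentence sizes.
* Relation pairs are canonically ordered by sentence offset for hashing;
  all relation matching is unordered.
* `split_subsets` gives the remainder to the earliest parts (sizes differ
  by at most one); all randomness flows through explicit seeds and every
  generator restores the caller's RNG state.

## Known limitations

* The tiny encoder has no sub-word model; unknown test tokens collapse to a
  single `<unk>` embedding. Out-of-lexicon generalisation is accordingly
  limited — visible in the corpus-adaptation scores, which is what that
  protocol is for.
* Single-head mode grows its softmax output when the vocabulary expands —
  a deliberate relaxation of the usual "a single multi-class head cannot
  expand after training" limitation, since a hard failure would forbid
  single-head continual runs entirely.
* `relation_prob < 1` produces annotation noise that is informationally
  irreducible: no model can reach perfect precision on it. Use
  `relation_prob = 1` for noise-free experiments.
* Training is plain-R matrix arithmetic on one CPU; it is sized for corpora
  of hundreds to a few thousand sentences, not for full-scale pretraining.
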