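---
title: "Two-phase retrieval of treatment-focused biomedical literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase retrieval of treatment-focused biomedical literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrank)
```

## The retrieval problem

A precision-medicine topic describes a patient: a disease, one or more
genetic variants, and demographic information. The retrieval goal is not
merely to find abstracts that mention the disease — it is to find abstracts
that discuss *treatment* of that disease. A term-matching ranker such as
BM25 cannot make that distinction: an abstract about the pathology of
melanoma matches the query "melanoma" just as strongly as a trial report
about treating it. pmrank therefore ranks in two phases:

1. **Initial retrieval.** A fielded Okapi BM25 index returns up to 1000
   candidates per topic, with knowledge-base query expansion and per-field
   boosting tilting the candidate set toward treatment-focused,
   disease-specific documents.
2. **Re-ranking.** Two neural models score every candidate — a
   bidirectional-GRU attention classifier estimates the probability
   $v_1 \in [0,1]$ that the document is treatment-focused, and a
   MatchPyramid matcher produces a disease-relevance score $v_2$ whose sign
   separates disease-relevant from irrelevant documents. Three one-vs-rest
   logistic regressions on $[v_1, v_2, v_1^2, v_2^2]$ fuse the two scores
   into a three-level label (definitely / partially / not relevant), and a
   tiered rule reorders the list: all definitely-relevant documents first,
   then partially relevant, then the rest, preserving BM25 order within a
   tier.

## Initial retrieval

**Text model.** One tokenizer is used everywhere: lowercase, keep maximal
alphanumeric runs. Documents are indexed into a merged `text` field (title,
abstract, chemical list, MeSH terms, other abstract) plus a separate `mesh`
field. All four query fields score against `text`; which document fields
each query clause should target is an open design point and the merged
field is the simplest defensible choice.

**BM25.** Score of document $d$ for term set $T$:
$\sum_{t \in T} \mathrm{idf}(t)\, \frac{f_{t,d}(k_1+1)}{f_{t,d} + k_1(1-b+b\,|d|/\overline{|d|})}$
with $\mathrm{idf}(t) = \ln\!\big(1 + \frac{N-n_t+0.5}{n_t+0.5}\big)$,
$k_1 = 1.2$, $b = 0.75$. The +1 inside the logarithm keeps idf
non-negative. Documents scoring 0 are dropped rather than padded ("up to
1000" permits fewer); ties break by ascending document ID so rankings are
deterministic.

**Query expansion.** A local entity table (diseases and genes with
synonyms, hypernyms, acronyms; any table in that schema works) supplies
variants. The default strategy adds disease synonyms and the fixed
14-keyword treatment vocabulary (surgery, therapy, patient, resistance,
recurrence, therapeutic, prevent, prophylaxis, prophylactic, prognosis,
outcome, survival, treatment, efficacy), and deliberately does *not* expand
the gene field: gene synonym expansion floods the query with gene terms
that treatment articles rarely use, and hypernyms make a specific disease
query more general. Ambiguous surface forms resolve to the
lexicographically smallest entity ID, with a warning.

**Boosting.** Field weights default to disease 1.5, gene 1.5, treatment
1.0, demographic 1.0 — the disease and variant identify the patient case;
treatment keywords and demographics are supporting signal. Scaling all
weights together leaves the ranking unchanged, so only the ratios matter.

## The treatment classifier

Documents are normalized to exactly `h` tokens (default 256): title `SEP`
abstract, lowercased, digit-only tokens replaced by `NUM` (mixed tokens
such as `v600e` are gene-variant names and are kept), padded with `PAD` or
truncated. `SEP`/`NUM`/`PAD`/`UNK` live in an uppercase namespace the
tokenizer cannot produce, so reserved tokens never collide with text.

The encoder is a bidirectional GRU (update gate $z_t$, reset gate $r_t$,
candidate state $\tilde h_t$, $h_t = (1-z_t)\odot h_{t-1} + z_t\odot
\tilde h_t$). PAD steps copy the previous state, so padding can never
alter the encoding — an all-PAD document encodes to a constant matrix.
Per-position forward and backward states are concatenated and pooled by
scaled dot-product attention against a single learned query vector
($\alpha = \mathrm{softmax}(q \cdot x_t / \sqrt d)$, PAD positions masked
out), followed by a 2-class softmax. Training: Adam, cross-entropy, a
seeded 8:1:1 train/dev/test split, early stopping on dev loss (patience 3,
maximum 30 epochs by default), best-dev parameters returned. Embeddings
initialize uniform(−0.05, 0.05) and train end-to-end; no pretrained
vectors are assumed. The affine parameterization inside the gates uses the
standard two-matrix form ($W x_t + U h_{t-1} + b$), and no dropout is
used.

Correctness of the hand-derived backpropagation is established by a
scalar-loop oracle for the cell and a central finite-difference gradient
check at $10^{-4}$ relative error on a tiny model (h = 6, dims = 4).

## The disease matcher

Matcher preprocessing continues from classifier normalization: disease
surface forms found in the entity index are replaced by their entity ID
(longest match first, before stemming, so "malignant melanoma" and
"melanoma" become the same ID token), stopwords (a fixed list shipped with
the package) are removed, and remaining tokens are Porter-stemmed. The
stemmer is the classic five-step 1980 algorithm, implemented here in full.
Because Porter stemming is not idempotent on its own output (agree → agre
→ agr), the preprocessing function recognizes sequences it has already
produced and returns them unchanged; that projection property is what
downstream code relies on.

The matcher scores a query (the disease terms of the expanded query,
de-duplicated) against a document through a matching matrix
$S_{ij} = \alpha_i \cdot \beta_j$ of embedding dot products, with zero
rows/columns at PAD positions. Two same-padding convolution stages (ReLU)
each followed by dynamic max pooling to a fixed grid feed a two-layer
perceptron (tanh hidden, linear scalar out). Disease-grade annotations map
exact matches to 2, broader or narrower matches to 1, non-disease to 0;
training regresses $v_2$ onto grade − 1 with squared error so that the
sign of $v_2$ is meaningful: positive means disease-relevant, which is
exactly what the voting rule needs. Adagrad, seeded 8:1:1 split, early
stopping on dev loss. Whether the original matcher was trained as
classification or regression over the three grades is not determined by
its description; the regression form is this package's choice because the
ensemble consumes a single sign-meaningful scalar.

Two numerical choices matter in practice and are deliberate:

* **Embedding rows are unit-normalized at initialization**, so a token
  self-match is exactly 1 while cross-token products concentrate near zero
  (standard deviation about $1/\sqrt{d}$). The matching matrix then
  carries clean, scale-stable contrast from the first epoch, which the
  convolution stages need to receive gradient; widening the embedding
  sharpens the contrast.
* **Embeddings are frozen by default** (`train_embeddings = FALSE`).
  Co-training the embedding table under Adagrad lets the scale of the
  matching matrix drift during training, which destabilizes the small
  convolution stack; with a stationary matching matrix the conv/MLP
  training is well behaved across seeds. The flag exists for
  experimentation.

The "hierarchical" convolution depth is fixed at two stages, and the
dynamic pooling grid defaults to 5×10 for the reference 30×200 windows so
both stages keep spatial signal.

## Fusing the scores

Each candidate document yields features $[v_1, v_2, v_1^2, v_2^2]$. Three
binary logistic regressions are trained one-vs-rest — LR1 treats
definitely-relevant documents as positive, LR2 partially relevant, LR3 not
relevant — by full-batch Adam on cross-entropy with a mild ridge penalty
(λ = 1 on the summed loss) and early stopping on a seeded 8:1:1 split. The
predicted label is the positive class of the largest probability, ties
resolved toward the higher relevance level. The voting baseline needs no
training: treatment-focused ($v_1 \ge 0.5$) and $v_2 > 0$ is definitely
relevant; not treatment-focused and $v_2 < 0$ is not relevant; everything
else — including $v_2 = 0$ exactly, which satisfies neither strict
inequality — is partially relevant.

A note on expressiveness: differences of the three LR logits are
*separable* quadratics $\varphi(v_1) + \psi(v_2)$ (there is no $v_1 v_2$
cross term in the feature set), so the voting rule's quadrant regions can
only be reproduced away from its decision margins. The consistency test
between the two fusion paths therefore evaluates on a grid that keeps a
margin from $v_1 = 0.5$ and $v_2 = 0$.

The re-ranking rule sorts by (tier, −BM25 score, document ID). It is a
pure permutation: scores are preserved, which both keeps the within-tier
order exactly the BM25 order and makes the operation idempotent. Rank
order, not the score column, is the authority in a re-ranked run file.

## The synthetic benchmark

The generator builds, from one seed, a knowledge base (diseases with
synonym and shared hypernym surfaces, genes with synonyms and acronyms), a
corpus, topics, graded judgments, classifier labels and matcher grades
that are consistent by construction:

* Background text draws from a Zipf(1.1) vocabulary; document lengths are
  uniform on [40, 240] tokens so both the 256-token classifier window and
  the 200-token matcher window regimes are exercised.
* A document is treatment-focused with probability 0.4, in which case 3–6
  of the 14 treatment keywords are inserted at random positions; the
  classifier label records this.
* Each topic selects a disease; 20 documents per topic receive 1–3
  mentions of it, each mention using a non-canonical synonym with
  probability 0.3. Mention documents that are treatment-focused are graded
  2, the others 1. Ten judged distractors per topic mention a *different*
  disease (grade 0), and ten more documents carry the disease's hypernym
  surface, feeding the matcher's broader-term grade-1 cells. Noise tokens
  replace 5% of positions.

These are the generator's fixed defaults, chosen once as a realistic
difficulty: disease mentions are rare enough that BM25 top-10 precision
starts well below 1, treatment keywords appear in relevant and irrelevant
documents alike, and synonym variation forces the entity normalization to
matter. What the generator does **not** emulate: real biomedical syntax,
MEDLINE term statistics, polysemy, or annotation noise — so passing tests
demonstrate that the machinery works and learns the planted structure, not
that the reported effect sizes transfer to real collections.

## Problem sizes and configurations used in the tests

The reference hyperparameters (embedding and hidden width 200, 400 kernels
of size 5, windows 256/30/200, Adam 0.001 batch 128, Adagrad 0.001 batch
64) remain the package defaults. The test suite and the acceptance script
run the synthetic benchmark at reduced width — classifier embedding/hidden
32 at learning rate 0.003, matcher embedding 48 with four 3×3 kernels,
pool grid 3×10, Adagrad 0.05, document window 256 so no planted mention is
truncated — which is this package's reference configuration for corpora of
a few thousand short documents: the planted signal is low-dimensional and
the narrow models train in minutes on one CPU while leaving the
architecture identical. Benchmarks use 1200–2000 documents, 10–15 topics,
and hold out 5 topics (the ensemble trains on the judged documents of the
remaining topics); learnability checks use the models' own held-out test
splits.

## Evaluation

P@10, R-precision and NDCG are computed from TREC-format runs and qrels.
NDCG uses gain $2^g - 1$ and discount $\log_2(i+1)$ at depth 1000 by
default; the original track reported an *inferred* NDCG over stratified
sampled judgments, whose sampling scheme is out of scope here — standard
NDCG is the documented substitute, so absolute NDCG values are not
comparable to track numbers. Unjudged documents count as grade 0; topics
with no relevant documents are excluded from the R-precision mean with a
warning; means over topics are unweighted.

## Known limitations

* The matcher's query side uses disease terms only; gene and demographic
  dimensions are not matched semantically.
* The LR feature set cannot express interactions between $v_1$ and $v_2$
  beyond what the squares allow (no cross term).
* Standard NDCG replaces the track's inferred estimator (above).
* The entity index does exact surface lookup, not entity linking;
  misspellings and unseen surfaces pass through unnormalized.
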