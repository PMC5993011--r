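---
title: "Promoter window extraction and SVM grid search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter window extraction and SVM grid search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacsvm)
```

## The problem

Bacterial promoters of the sigma-70 family carry two short conserved
elements — the −35 box (consensus `TTGACA`) and the −10 box (consensus
`TATAAT`) — separated by a spacer of roughly 15–19 nt. Given a genome and
a table of annotated promoters (operon, sigma factor, absolute genomic
position, binding sequence), `bacsvm` extracts a fixed-length sequence
window per promoter, builds a labeled promoter / non-promoter dataset,
and exhaustively searches support-vector-machine formulations, kernels
and cost/gamma values for the configuration that separates the two
classes best under cross-validation.

## Coordinates and window anchoring

Annotation tables use 1-based inclusive positions (the DBTBS convention);
internally every coordinate is 0-based half-open, and the conversion
happens exactly once, in `read_annotation()`. This removes off-by-one
ambiguity from all downstream arithmetic.

Where the 80-nt window sits relative to the annotated position is a
genuine design choice: annotation sources rarely state it, and it cannot
be recovered from window sequences alone. We anchor the window so the
annotated position is its **first base** (the window covers positions
$p \dots p+79$, 1-based). A signed `anchor_offset` shifts the anchor for
tables that annotate, say, the transcription start rather than the
element start. The synthetic generator plants its elements under the same
convention, so planted truth and extracted windows agree exactly.

## The extraction procedure

For each record:

1. **Position first.** Slice the window at the annotated position. If the
   record also carries a binding sequence, the slice must *contain* it;
   otherwise the position is treated as stale and the record falls
   through to the search step. Positions whose window would run past the
   end of a linear genome are misses (`position_out_of_range`), not
   errors — real tables contain them.
2. **Exact sequence search.** All exact occurrences of the binding
   sequence are collected on the forward strand, then of its reverse
   complement (strand −), each in ascending coordinate order. The first
   viable hit wins, forward strand preferred, lowest coordinate first; a
   record with several hits still yields exactly one window but is listed
   in the report's `ambiguous` table, because a silent arbitrary choice
   would be untestable. On the minus strand the window is placed so that
   the reverse-complemented output sequence *starts* with the query,
   mirroring the forward convention.
3. **Alphabet filter.** Windows containing `N` are dropped to the miss
   list (`ambiguous_base`) by default since the encodings assume a
   4-letter alphabet; `drop_n = FALSE` keeps them.

The search is exact-match only — no mismatches, no IUPAC degeneracy — and
the whole binding string is the query. Whether the original annotations
imply reverse-strand promoters is unknowable from the table alone, so we
search both strands and report the strand rather than guessing. The
report always satisfies `windows + misses = records`.

## Negative examples and encodings

How non-promoter examples should be built is a standing ambiguity in
promoter classification, so both standard constructions are provided and
the choice is explicit:

- `random_window` (default): windows drawn uniformly from the genome,
  rejected if they overlap any positive window's coordinates or contain
  `N`. These are genuine genomic background at the genome's own
  composition. Default ratio 1:1 with the positives.
- `dinucleotide_shuffle`: each positive permuted while preserving its
  exact dinucleotide multiset (Altschul–Erickson walk on the dinucleotide
  multigraph), giving negatives that match the positives' local
  composition and isolate positional signal.

Both are seeded and byte-reproducible.

Two encodings are provided, again because the appropriate one depends on
what signal should be learnable. **One-hot** (default) is
position-aware — four binary channels per position in fixed order
A, C, G, T, dimension $4L$ — and suits the conserved −35/−10 spacing:
the informative columns are the motif positions themselves. **k-mer
frequency** (dimension $4^k$, overlapping counts divided by $L-k+1$,
lexicographic column order, rows summing to 1) is position-free and
serves as a composition-only baseline. The fixed channel and column
orders make encodings bit-reproducible across runs.

## The hyperparameter sweep

The default grid is the exhaustive product of five formulations (C-SVC,
nu-SVC, one-class, epsilon-SVR, nu-SVR) and five kernels (linear,
polynomial, RBF, sigmoid, precomputed) with

- cost $C$: geometric series $0.00390625 \times 16^k$ up to $65536$
  (7 values; $2^{-8}$ to $2^{16}$),
- gamma: $1.52587890625\times10^{-5} \times 16^k$ up to $256$
  (7 values; $2^{-16}$ to $2^8$),

and the remaining libsvm parameters pinned at their defaults: degree 3,
coef0 0, nu 0.5, cache 100 MB, termination tolerance 0.001, shrinking
on, probability estimates off, class weight 1. Series endpoints are
snapped exactly when the maximum is reachable from the minimum by the
factor (relative tolerance $10^{-9}$); an unreachable maximum is a spec
error rather than a silently truncated series. The precomputed kernel is
enumerated only when a Gram matrix is supplied — there is nothing to
compute it from otherwise — and its absence is announced, not hidden.
Without it the full grid has $5 \times 4 \times 7 \times 7 = 980$ cells.

### Validation protocol

Each cell is evaluated by stratified k-fold cross-validation (default
$k = 10$; the desk-scale benchmarks use 5), with fold assignment drawn
once from a caller-supplied seed, and confusion counts pooled over the
held-out folds with *promoter* as the positive class. Choices that the
formulation list forces:

- **One-class** trains on the training fold's promoters only and
  predicts the full held-out fold. Evaluated on positives alone this
  leaves $TN = FP = 0$; specificity is then *undefined* and reported as
  `NA`, never as 0 — a deliberate contract, since 0 would claim the
  classifier rejected every negative when there were none.
- **SVR formulations** regress on labels encoded 0/1 and classify at
  threshold 0.5. Some mapping is needed to include them in a
  classification sweep; this is the declared one.
- **Infeasible cells** (for instance nu-SVC when nu = 0.5 exceeds what an
  imbalanced class ratio admits) are caught, flagged `failed = TRUE` and
  ranked last, so an exhaustive sweep always completes.

Metrics follow the standard confusion-matrix semantics — $FP$ is a
non-promoter predicted promoter, $FN$ a promoter predicted non-promoter —
with $A = (TP+TN)/(TP+TN+FP+FN)$, $S = TN/(TN+FP)$,
$SN = TP/(TP+FN)$. Results are ranked by accuracy with declared
tie-breaks (higher sensitivity, then smaller $C$, then smaller gamma:
prefer the more regularized, smoother model among equals). Whether
accuracy alone should rank is itself a choice; the tie-break chain makes
the ordering total and deterministic.

The SVM backend is libsvm via `e1071` (kernlab's `ksvm` for
precomputed-Gram cells, which e1071 does not accept). The contract is
the grid, the CV protocol, the metrics and determinism under a fixed
seed — not bit-identical decision values across backends.

## The synthetic generator

`synth_spec()` / `generate_genome()` emulate the inputs the pipeline
needs: an i.i.d. background genome at a specified GC content (default
0.43, roughly the *B. subtilis* composition), with promoter elements —
mutated −35 box, uniform-random spacer of 15–19 nt, mutated −10 box —
planted at non-overlapping positions (one per equal-width genome block,
random offset within the block) and an annotation table carrying the
1-based element start and the post-mutation element as binding sequence.
Defaults: 50-kb genome, 20 promoters, per-position substitution rate
0.05. Generation is fully determined by the spec's seed.

Mutation substitutes a position with probability `mutation_rate` by one
of the *other three* bases. A consequence worth stating: at rate 0.5 a
motif position still shows the consensus base half the time versus ~0.25
in background, and the uniform spacer differs compositionally from a
GC-0.43 background, so rate 0.5 does *not* erase the class signal. Under
this mutation model the signal-free construction is rate 0.75 (motif
columns become exactly uniform) with `gc_background = 0.5` (spacer and
background match); that construction is what the no-signal tests use,
alongside label permutation, which destroys signal regardless of the
generator.

What the generator does **not** emulate: genes, operon structure, codon
bias, repeats, strand asymmetry, sigma-factor-specific motif variants
beyond the two configurable boxes, or promoters on the minus strand.
Passing the synthetic benchmarks therefore demonstrates that the
machinery is correct — extraction recovers planted truth, encodings
expose positional signal, the sweep finds separable classes separable —
not that any accuracy figure transfers to real genomes, where negatives
are harder and annotations noisier.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute of CPU: extraction
equivalence on 50-kb genomes with 20 planted promoters (100 randomized
trials in the tests, 20 in the script), and a classifier benchmark of
200 positives / 200 sampled negatives at mutation rate 0.02, swept over
a reduced grid (C-SVC × {linear, RBF} × 3 costs × 3 gammas, subsets of
the full series) with 5-fold CV. An independent nearest-centroid
classifier — class centroids in one-hot space, nearest-centroid
assignment, its own fold logic — accompanies the benchmark as an oracle:
it verifies the benchmark is genuinely separable and gives the SVM a
floor to meet.

Remaining numerical contracts: k-mer rows sum to 1 within $10^{-12}$;
stored metrics are recomputable from stored counts to $10^{-12}$;
exported CSVs print A/S/SN as percentages with two decimals and
re-parse exactly at that precision; `metrics` on an all-zero confusion
matrix is an error, not a 0/0 result. Genomes are linear by default
(`circular = TRUE` enables origin-spanning slices, which
annotation-driven extraction does not normally need).

## Limitations

- The exact-match fallback cannot recover promoters whose annotated
  binding sequence differs from the genome build by even one base;
  such records surface as misses, by design.
- Negative construction and encoding determine what the reported
  accuracies mean; the defaults are declared choices, not recovered
  facts, and alternatives are one argument away.
- One-class evaluation on mixed held-out data and on positives-only data
  answer different questions; both are available, and the specificity
  `NA` convention marks the latter.
- Model persistence uses R serialization plus a plain-text sidecar; the
  serialized object is backend-native and not portable across backend
  major versions.
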