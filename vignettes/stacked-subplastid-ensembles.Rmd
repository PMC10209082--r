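---
title: "Stacked ensembles for subplastid localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensembles for subplastid localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plastids carry proteins encoded in two genomes. Nuclear-encoded proteins are
synthesised in the cytosol and imported through the envelope, guided by an
N-terminal transit peptide; plastid-encoded proteins are synthesised in the
stroma. Within the organelle a protein may reside in the envelope (outer or
inner membrane), the stroma, the thylakoid membrane, or the thylakoid lumen;
lumenal proteins of nuclear origin arrive via one of two routes, Sec or Tat,
each with a characteristic targeting signal (Tat substrates carry a
twin-arginine motif at the start of a weakly hydrophobic stretch). Because
localization constrains function, predicting the compartment — and, for
lumenal proteins, the import pathway — is a central annotation step.

`plastidstack` treats this as an eight-class problem crossing origin with
compartment: `N_E`, `N_TM`, `N_S`, `N_TL_SEC`, `N_TL_TAT`, `P_IM`, `P_TM`,
`P_S`. A fixed mapping collapses the eight fine classes onto origin
(nuclear/plastid) and four generalized compartments; an optional sub-model
splits nuclear-encoded envelope calls into outer and inner membrane.

## The model

### Sequence representation: gapped n-grams

Sequences are represented by the binary presence/absence of short
amino-acid motifs: all unigrams; bigrams with a wildcard gap of 0–3
positions; trigrams with gaps of 0–1 in each of the two slots. The universe
is 20 + 4·400 + 4·8000 = 33,620 patterns. Presence (never counts) keeps the
features comparable across sequence lengths, and matrices are stored
sparse. The trigram gap convention — both slots range over {0, 1},
contiguous trigrams included — is isolated behind a single constant
(`TRIGRAM_GAPS`); the bigram convention likewise includes the contiguous
case alongside gaps 1–3.

### Feature selection: QuiPT

Each lower-level model binarizes the eight classes into its own task and
tests every pattern against that binary target. The statistic is the mutual
information of the 2×2 contingency table (bits). Because permuting the
target changes the statistic only through the overlap count of the two
binary vectors, the full permutation distribution is hypergeometric in the
overlap, and the exact p-value is a hypergeometric tail sum — identical to
exhaustively permuting the target, at a fraction of the cost. Features with
p < 0.01 are retained. Constant columns have statistic 0 and p = 1; an
empty selection falls back to predicting the empirical rate, with a
warning. The brute-force equivalence is asserted in the test suite by
literally enumerating all distinct target permutations at n ≤ 12.

### Lower-level models

The default registry reconstructs an eight-model architecture:

| model | task | algorithm |
|---|---|---|
| Nuclear | all `N_*` vs all `P_*` | random forest |
| Membrane | `N_E`,`N_TM`,`P_IM`,`P_TM` vs rest | random forest + SMOTE |
| Plastid_membrane | `P_IM` vs `P_TM` | random forest |
| N_E_vs_N_TM | `N_E` vs `N_TM` | random forest |
| N_S_vs_other_nuclear | `N_S` vs other nuclear | random forest |
| Nuclear_membrane | `N_E`,`N_TM` vs aqueous nuclear | random forest |
| Sec | Sec signal | profile HMM |
| Tat | Tat signal | profile HMM |

Forests are untuned: 500 trees, `mtry = floor(sqrt(p))`, probability
output, Gini importances (ranger). SMOTE oversamples only the minority
side of a task, interpolating a minority row toward one of its five
nearest minority neighbours under Hamming distance and rounding at 0.5
(ties to 1), which keeps the feature space binary; majority rows are never
altered, and balanced tasks are a no-op. The registry is fully overridable
through `model_spec()` lists, as the exact composition of the original
eight models is a reconstruction from the architecture's factor list.

### Profile HMMs for Sec/Tat signals

Signal alignments (inputs, not computed here) are turned into
Plan7-like profiles: one match/insert/delete state per match column, no
I↔D transitions, begin treated as M0 with an I0 state for N-terminal
inserts. Columns with gap fraction < 0.5 become match states. Emissions
use additive pseudocounts, (count + 1)/(n + 20); the effective sequence
number is the raw row count — no sequence weighting, a deliberate
simplification pinned by a path-enumeration oracle in the tests.
Transitions are estimated from observed per-row state paths with the same
pseudocount; path adjacencies the architecture forbids (I→D, D→I) are
skipped during counting, which never triggers on the gapless-core signal
alignments the generator produces.

Scoring is glocal: the whole profile is aligned by the forward algorithm
against the first 100 residues of the sequence (targeting signals are
N-terminal), with flanking residues absorbed by insert states. The score is
log2 forward probability minus the log2 background probability of the same
window (bits). The null background is uniform (1/20) by default: a signal
alignment is strongly composition-biased (the hydrophobic h-region), so a
null estimated from the alignment itself would absorb exactly the signal
the profile is supposed to score; `background = "msa"` restores the
alignment-frequency null for users who want it. Forward uses per-position
scaling, so scores are finite for any sequence the profile can emit.

### Stacking

An ensemble is a pair (S, G): lower models S and an aggregating model G
(model stacking). Meta-features are one column per lower model — the
positive-class probability for forests and the z-scored log-odds for HMM
scorers (raw bit scores are not on a probability scale; the z-scoring uses
the training task's mean and sd). G is either a 500-tree probability
forest or a multinomial log-linear model fitted by penalized maximum
likelihood with a tiny ridge (decay 1e-6, for separable data), both
untuned.

The higher model is trained on meta-features computed on the same records
the lower models were trained on, which is the protocol the architecture
prescribes; an out-of-fold mode (`out_of_fold = TRUE`) exists for users
concerned about in-sample optimism, default off.

Conditional routing implements expert rules: a guard model's decision
(argmax, threshold 0.5 for binary guards; a tie keeps everything active)
masks a subset of models for that record. Masked cells are set to 0 and a
companion `mask_<model>` indicator column is added — the architecture does
not specify how restricted models' outputs reach G, so this encoding is
the package's recorded choice. Guards may not be guarded by themselves and
the guard graph must be acyclic. The configuration grammar enumerates
lower-level model sets slot-wise (Cartesian product, deduplicated), and
every set crosses with {plain, conditional} × {forest, log-linear},
multiplying the count by four — with 18,600 sets this yields the 74,400
configurations per dataset version. The slot grammar is configurable
because the published slot descriptions are too loose to recover the
printed set counts exactly; the arithmetic, not the slot inventory, is the
tested contract.

## Homology handling

Percent identity comes from exact Needleman–Wunsch global alignments
(BLOSUM62, gap open 10, gap extend 0.5 — needle-style defaults; the
denominators `alignment_length` (needle-like) and `shorter_sequence`
(CD-HIT-like) are both offered). Co-optimal global alignments can differ
in identity count, so `pairwise_identity()` canonicalises the argument
order before aligning; symmetry is then exact by construction. Exact
alignment replaces k-mer prefiltering heuristics entirely: at the
package's design scale (thousands of sequences, not millions) the exact
computation honours the same contract — no retained pair at or above the
threshold — without approximation, so a word-length parameter has nothing
to control.

Homology reduction is greedy incremental clustering at 90% identity,
longest sequence first, applied per class when labels are present.
Homology partitioning builds single-linkage clusters over the ≥ 40%
identity graph and assigns whole clusters, largest first, to the
independent partition whenever that brings the achieved fraction closer to
the 15% target; records never move out of their cluster, so every
cross-partition pair sits strictly below the threshold. The exact
cluster-to-partition heuristic of the original pipeline is not restated in
its description; this greedy is a documented stand-in honouring the stated
constraints. If the greedy pass leaves the independent partition empty,
the cluster whose size fraction best matches the target is moved there; a
single all-covering cluster is an explicit error.

## Evaluation

Stratified five-fold cross-validation repeated five times: each
repetition draws a fresh fold assignment (per class, shuffled round-robin,
so fold proportions are within one record of the overall proportions);
lower models are trained on the k−1 training folds and the higher model on
those folds' meta-features; metrics come from the held-out fold. All 25
fold×repetition cells are pooled for means and standard deviations
(averaging over folds first and repetitions second differs only for
unbalanced folds; pooling is the documented choice). Metrics: Cohen's
kappa ((p_o − p_e)/(1 − p_e), with the degenerate p_e = 1 case defined as
0 with a warning), the Hand–Till average one-vs-one multiclass AUC (AU1U;
ties credited 0.5, pairs with an absent class skipped — it reduces exactly
to the rank-based binary AUC at k = 2), and class-specific accuracy
interpreted as per-class recall — the convention under which an accuracy
of a single class is well-defined; absent classes are reported missing,
never zero. Model selection takes the configuration with the highest mean
CV kappa, breaking exact ties toward fewer lower-level models.

## The synthetic data generator

Real training data for this problem are accession-curated database
downloads; the generator instead emulates the signal structure the method
assumes, so the whole pipeline is testable offline. Defaults, chosen once
as plausible for plastid proteins and documented in `generator_config()`:

* mature regions of 100–240 residues; uniform 1/20 composition for nuclear
  classes; plastid classes shift each of F, I, L up by δ = 0.02 (the
  literature reports distinct compositions between the two origins without
  usable numbers; δ is set to be recoverable but not trivial, and the
  recovery is a tested invariant);
* transit-peptide-like N-terminal regions on nuclear classes: length
  U(30, 80), S+T probability 0.30, D+E probability 0.02;
* thylakoid-lumen classes use a compact stroma-targeting region
  (U(30, 37)) followed by the lumenal signal, modelling a bipartite
  presequence whose signal lies within the scored N-terminal window — the
  Tat twin-arginine therefore always falls within the first 40 residues;
* Sec signals: short n-region, 10-residue strongly hydrophobic h-region,
  AxA cleavage site; Tat signals: S-R-R-x-F-L-K consensus with an
  invariant RR and softly conserved flanks (p = 0.7), a weaker 8-residue
  h-region, AxA. Signals have fixed length per pathway, so generated
  signal sets are gapless-core alignments directly usable as profile
  input;
* membrane classes embed hydrophobic runs of 15–19 residues from
  {A,I,L,V,F,M}: envelope membranes two runs (one for outer-membrane N_E
  records) weighted toward A/V/I, thylakoid membranes three runs weighted
  toward F/L/M — a caricature of the aromatic-rich thylakoid bilayer that
  makes envelope and thylakoid membranes distinguishable, as they are in
  real data.

All randomness flows through one locally seeded generator; identical
configurations produce byte-identical FASTA output.

What passing on this generator does and does not show: the synthetic
classes are separable by construction through the same signal types the
method exploits in real data (composition, targeting signals, hydrophobic
runs), so recovery demonstrates that featurization, selection, the
profiles, stacking and the CV machinery work end to end, and that the
stacked architecture beats a naive multiclass forest — dramatically so
under class imbalance, where the baseline's rare-class recall collapses.
It does not certify real-data accuracy: real plastid proteins have
homology structure, shared domains, and far messier signals than the
generator's caricature.

## Numerical choices and degenerate inputs

* Log base 2 throughout the HMM code; forward uses per-position scaling
  rather than log-space sums.
* QuiPT compares statistics with a 1e-12 slack so hypergeometric ties are
  counted as ties, matching enumeration.
* Argmax ties (class probabilities, guard decisions at exactly 0.5) break
  toward the canonical class order and toward keeping models active,
  respectively.
* Sequences shorter than 10 residues are accepted with a warning (real
  plastid proteins below 50 residues exist); empty sequences, gap
  characters in unaligned input, and duplicate record ids are errors.
  Non-standard residues are filtered, not fatal, and reported per record.
* CV with a class smaller than the fold count warns and stratifies
  best-effort; a task with an empty side refuses to train, naming the
  side.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at 60
records per class (480 sequences), 5-fold × 5-repetition CV, with 50-row
signal alignments — sizes at which the exact-alignment homology tools and
the ensemble CV complete in minutes on a single core while still
exercising every component at its intended operating point.

## Known limitations

* No sequence weighting or Dirichlet mixture priors in profile
  estimation; the HMM is a self-contained scorer, not a drop-in for
  HMMER's calibrated E-values or its file format.
* Exact-alignment homology tools target thousands of sequences, not
  database scale.
* The eight-model registry and the slot grammar are reconstructions;
  both are configuration, not hard-coded truth.
* Multi-compartment (multi-label) proteins are out of scope by design;
  the predictor assumes its input already localizes to the plastid.
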