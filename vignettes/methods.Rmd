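---
title: "Predicting 14-3-3 binding phosphopeptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 14-3-3 binding phosphopeptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phos1433)
```

## The problem

14-3-3 proteins recognize short phosphorylated serine/threonine motifs on
client proteins, most famously an arginine three residues upstream and a
proline two residues downstream of the phosphosite. Because many clients
are intrinsically disordered, structure-based prediction is of limited
use; `phos1433` treats binding-site discovery as supervised sequence
classification on 15-residue windows (`-7 … +7` around the phosphosite).

This vignette documents the modelling choices: what each component
assumes, which parameters matter, and which decisions were genuinely open
and how they were made.

## Data model

A window is 15 tokens from a 23-token alphabet: the 20 canonical amino
acids, `pS`, `pT` and a padding token for positions beyond the protein
termini. Two choices deserve note:

* **Phospho tokens are distinct residues.** `pS` vs `S` is a real
  substitution for every purpose, including edit distance (one edit).
  The alternative — treating them as equal — would let a test window that
  differs from a training window only in phosphorylation state slip
  through the leakage filter.
* **Padding is a token, written `X` in text form.** Padding rows encode
  as all-zero vectors, so the networks see "no residue" rather than any
  particular amino acid.

Labels come either directly from a 0/1 column or from dissociation
constants: a site measured against several 14-3-3 isoforms is labelled by
its strongest (minimum) Kd, binder iff Kd < 200 µM. The threshold is
strict: a Kd of exactly 200 µM is a non-binder. Sequences appearing with
both labels after curation are dropped (conflicting evidence), with a
warning.

## Encodings

Four per-window representations (`encode_onehot`, `encode_token_ids`,
`encode_blosum62`, `encode_descriptors`), all deterministic and pure:

| scheme          | shape   | content |
|-----------------|---------|---------|
| `onehot`        | 15 × 23 | indicator per token |
| `embedding_ids` | 15 × 1  | vocabulary index; vectors learned in-model |
| `blosum62_flag` | 15 × 22 | BLOSUM62 row of the parent residue + pS/pT flag |
| `descriptors`   | 15 × 20 | 18 physico-chemical scales + pS/pT flag |

The BLOSUM62 values are the standard published half-bit scores (taken
from the matrix shipped with Biostrings), unmodified in the encoding.
Phosphorylated residues use their parent residue's substitution row and
are distinguished by the appended flag (`[1, 0]` for pS, `[0, 1]` for
pT); the same flag is appended in the descriptor scheme for consistency.

The 18-descriptor table is a deliberate open point: the package ships a
default of 18 widely used per-residue scales (hydropathy, hydrophilicity,
mass, volume, charge, isoelectric point, polarity, secondary-structure
propensities, flexibility, bulkiness, refractivity, surface area, atom
and H-bond counts, aromaticity; see
`inst/extdata/aa_descriptors_default.csv`) and any complete 20 × 18 table
can be substituted via `read_descriptor_table()`. Descriptor columns are
standardized with training-set statistics only (`descriptor_scaler()`),
computed over non-padding residues, so no information flows from
evaluation data into the representation.

## Classifiers

Three architectures, written as explicit matrix-algebra networks inside
the package (the models are small enough — hundreds of samples, tens of
units — that a framework dependency would buy nothing):

* **MLP**: the encoding is flattened (e.g. 15 × 23 → 345) and passed
  through fully connected ReLU layers (default 64, 32) to a sigmoid
  output. Default pairing: learnable embedding (dimension 8).
* **CNN**: 1-D convolutions slide along the 15-position axis (default 32
  filters, kernel 5), ReLU, global max-pooling per filter, a dense layer
  (16), sigmoid output. Default pairing: flagged BLOSUM62.
* **GRU**: gated recurrent units read the window N- to C-terminus; the
  final hidden state feeds a dense head (16) and sigmoid output. Default
  pairing: flagged BLOSUM62. The shipped configuration stacks two
  recurrent layers of 48 units.

Training minimizes binary cross-entropy with Adam (the de-facto standard
for this model class; the optimizer is not otherwise constrained by the
protocol). After every epoch, validation F1 at the strict 0.5 threshold
is recorded; from the fifth epoch on, training halts after five
consecutive epochs without improvement and the best-F1 epoch's parameters
are restored (`trace_early_stop()` implements exactly this rule and is
unit-tested against hand-traced histories).

### Numerical choices that mattered

Three training details are the package's own engineering, documented here
because they materially affect the recurrent model:

1. **Input scaling.** Raw BLOSUM62 scores span −4 … 11 and saturate
   sigmoid/tanh gates early in training. At the network input (not in the
   encoding), the substitution-score block is z-scored with the global
   mean and standard deviation of the 20 × 20 matrix itself — constants of
   the matrix, not statistics of any dataset, so the transform is
   deterministic and leak-free.
2. **Recurrent initialization.** Orthogonal recurrent weight matrices and
   a negative update-gate bias (−1) slow state turnover, helping the GRU
   retain evidence about residues far from the C-terminal read-out (the
   −3 anchor is ten steps from the final state).
3. **Random restarts.** The GRU loss surface is visibly multimodal at
   this data size: independent runs on identical data spread over several
   balanced-accuracy points. `fit_binding_model()` therefore trains
   `n_restarts` independently initialized runs (GRU default 7, MLP/CNN 1)
   and keeps the one with the highest validation balanced accuracy —
   balanced accuracy being the study's global model-selection criterion,
   while F1 governs early stopping within each run. All restart seeds
   derive deterministically from the configuration seed.

Identical configuration + seed + data reproduce bit-identical models and
predictions; this is asserted in the test suite.

### Ensemble

The ensemble averages the three member probabilities (unweighted — the
members are deliberately heterogeneous but equally trusted) and records a
majority vote: the number of members scoring strictly above 0.5. The
ensemble classification is mean score strictly above 0.5. With three
members, votes cannot tie.

### Hyperparameter search

`tune_hyperparameters()` implements the two-stage scheme: a broad grid
evaluated by mean validation F1 across the split replicates, then a
refinement grid overlaid on the top configurations. Grids are YAML lists
of `model_config()` overrides (examples in `inst/extdata/`), so an
externally specified search — the benchmark of record refined 216
configurations for the GRU, 324 for the MLP and 1500 for the CNN — can be
dropped in without code changes.

## Evaluation protocol

`make_split_plan()` reconciles "10-fold stratified cross-validation" with
67.5/22.5/10 fractions: ten stratified folds; in each replicate one fold
(10%) is the test set and the remaining 90% is stratified 75/25 into
training and validation. Every window is tested exactly once across the
ten replicates, and per-set class counts stay within one window of the
global ratio.

**Leakage filter.** Test windows within edit distance 4 (inclusive) of
any window the models could have learned from are removed from the test
set — removed, not reassigned, so the filter can only shrink the test
set. Two open points were decided as follows: the filter screens against
train ∪ validation (conservative; a `filter_against = "train"` switch
restores the narrower reading), and distances are computed on the full
15-token form with phospho tokens distinct.

Metrics are the standard confusion-matrix quintet (Pr, Rc, Sp, BA, F1) in
percent, with `BA = (Rc + Sp)/2` exactly. A metric with a zero
denominator is reported as `NA` and flagged — never silently zero — and
excluded from replicate aggregation with a warning. Model comparisons use
the two-sided paired Wilcoxon signed-rank test at α = 0.05 over the ten
replicate values, exact for small samples, with zero differences dropped
(Wilcoxon's original treatment); an all-zero contrast returns p = 1.

## Interpretation: positional shuffling

`position_impact()` permutes the residues observed at one window position
across the evaluated peptides (preserving that position's empirical
residue distribution, rather than substituting uniform random residues),
re-predicts, and averages the absolute probability change over 15
shuffles; the per-position values are normalized to percent of the
maximum. The phospho center is never shuffled and carries no impact
value. Absolute change was chosen as the inner statistic because it is
symmetric for both classes; the max-normalization makes profiles
comparable across models. Profiles can be computed per member and for the
ensemble.

## Screening pipeline

`build_candidate_library()` windows every S/T residue of the input
proteins (the count equals an independent S/T regex count — a tested
invariant). Phospho evidence and known binding sites are consumed as
user-supplied CSV tables rather than live database queries: both are
snapshots of external knowledge, and pinning them keeps a screen
reproducible offline. Ranking is vote-major, mean-score-minor, with a
lexicographic tie-break on the formatted sequence (the order must be
total for reproducibility; the spread reported alongside the mean score
is the across-member standard deviation). Known sites are excluded from
ranks but retained, flagged, for audit. `select_validation_panel()` takes
the top 8 candidates and bottom 2 negative controls by default.

## Synthetic data generator

`generate_dataset()` emulates the statistical shape of a curated 14-3-3
training set: 15-mer windows centered on pS/pT (default mix 0.8/0.2,
serine-dominated as in real phosphoproteomes), balanced binary labels,
and a planted binding motif — by default arginine at −3 and proline at
+2, the canonical anchor residues. Motif residues appear with exactly the
class probability (default 0.9 in binders, 0.05 — the background rate —
in non-binders; the background is renormalized when the motif residue is
not drawn, so nominal probabilities are realized frequencies, a tested
invariant). All other positions draw from a uniform background over the
20 amino acids.

With the defaults, the best attainable balanced accuracy (the
"any-anchor" rule) is about 94–95%; the shipped GRU configuration reaches
the low nineties on held-out validation windows, recovering both planted
positions as the top-2 perturbation impacts. Typical problem sizes used
in the tests are 700 windows with the 67.5/22.5/10 split — large enough
for stable training, small enough for fast runs.

What the generator deliberately does **not** emulate: the sequence
correlations of real proteomes (real windows are not i.i.d. over
positions), assay noise and inter-assay heterogeneity in the labels, and
homology structure between peptides (the synthetic leakage filter rarely
fires, whereas on real data it is essential). Passing the synthetic
benchmarks therefore demonstrates that the machinery — encodings,
optimization, selection, perturbation analysis, ranking — works as
specified, not that real-data accuracy will match.

## Known limitations

* Phosphotyrosine is outside the data model (14-3-3 binds pS/pT motifs).
* The classifiers output binding probabilities, not affinities; ranking
  by score is not a Kd prediction.
* The networks run on plain R matrix algebra: ideal for window-scale
  problems and full reproducibility, but not for training on
  proteome-scale corpora.
* UniProt fetching is not built in; sequences arrive as FASTA, and
  phospho-annotation snapshots as CSV, so results depend on the supplied
  snapshot versions.
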