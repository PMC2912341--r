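---
title: "Auditing domain models for transmembrane and signal-peptide contamination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing domain models for SP/TM contamination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domaudit)
```

## The problem

Protein domain libraries (Pfam, SMART) build a profile HMM per family from
a curated seed alignment. When that seed alignment contains transmembrane
(TM) helices or a signal peptide (SP), the model inherits a block of
uniformly hydrophobic match states. Hydrophobic segments align well with
*any* other hydrophobic segment — their similarity reflects the physics of
the lipid bilayer or of the translocation machinery, not common ancestry.
Consequently an unrelated protein carrying a TM anchor can score above the
family's gathering threshold purely through the SP/TM block, producing an
*unjustified* domain annotation; conversely a true family member lacking
the SP/TM context is penalised and can drop below the threshold (a
recoverable false negative).

`domaudit` implements both halves of the corresponding curation workflow:

1. **Detection** — statistical consensus detection of SP/TM regions inside
   a seed alignment from the binary per-residue calls of several
   independent predictors, with calibrated score cutoffs and emission of
   cleaned ("cleanup") alignments.
2. **Triage** — decomposition of a profile-HMM hit score into its SP/TM
   and non-SP/TM parts, estimation of the non-SP/TM share of the gathering
   threshold, and classification of hits into true positives, unjustified
   annotations, recoverable false negatives and no-calls.

## Consensus detection in an alignment

For one category (TM or SP) a battery of `D` predictors produces, for every
sequence, a binary call per residue; the predictors' own scores are
deliberately ignored. At alignment column `j` with depth `n_j` (sequences
that are not gapped there), predictor `d`'s calls are `k_dj` successes of
`n_j` Bernoulli trials. Under the null hypothesis that calls land on a
column by fair chance (`p = 1/2`), the exact one-sided binomial tail

```
p_dj = P(K >= k_dj),  K ~ Binomial(n_j, 1/2)
```

is the type-I error of declaring the column an SP/TM residue. The null is
rejected at `alpha = 0.05`. Because the smallest attainable tail is
`2^-n`, alignments of four or fewer sequences can never reject: the test
requires depth 5 or more, and deeper alignments have more power.

On rejection the expected number of positive calls is estimated by the
observed count (`E_hat = k`), otherwise `E_hat = 0`; the column probability
is `p_hat = max(E_hat / n, epsilon)` with a floor `epsilon = 1e-4` that
keeps logarithms finite. The per-column evidence is summed over predictors,

```
L_j = sum_d ln p_hat_dj   in  [D ln(epsilon), 0],
```

and a column is *positive* when at least one predictor rejects there.
Maximal runs of positive columns are raw predicted segments, scored by the
average log probability `psi` over their predicted columns.

Three category-specific rules follow:

* **TM fragment bridging.** Alignment gaps can split one helix into
  fragments. Per predictor, a union indicator marks columns where any
  sequence is called positive; across the predictors active in a covered
  block, intersection yields a composite indicator. Raw segments
  overlapping the same composite run are united (the union preserves
  continuity within a helix; the intersection keeps distinct helices
  apart), and the united segment's score is the predicted-column-weighted
  mean of its fragments' scores.
* **SP span.** Fragmented SP predictions are assumed to come from one
  signal peptide; a single segment is scored over the smallest region
  containing both the N-terminal column and the C-terminal boundary of the
  most C-terminal fragment.
* **TM regions.** Retained helices separated by fewer than 40 columns are
  concatenated into one TM region — the smallest known globular domains
  exceed 40 residues, so shorter inter-helix stretches are linkers, not
  domains.

Segments are retained when `psi >= -12` (TM) or `psi >= -1` (SP), ties
retained. These defaults correspond to false-positive rates just below 5 %
on labelled helix benchmarks (structural versus membrane helices, and
non-secreted versus secreted proteins); the `calibration` functions
(`rate_table()`, `select_cutoff()`) re-derive such cutoffs from any
labelled score sets at a chosen FP target, counting a tie at the cutoff as
a false positive to match the retention rule. A domain is *problematic*
for a category when at least one segment of it survives the cutoff.

### Parameters

| parameter    | default | units    | meaning |
|--------------|---------|----------|---------|
| `alpha`      | 0.05    | —        | per-column binomial test level |
| `epsilon`    | 1e-4    | —        | floor of the column probability |
| `tm_cutoff`  | −12     | nat-log  | TM segment retention cutoff on `psi` |
| `sp_cutoff`  | −1      | nat-log  | SP segment retention cutoff on `psi` |
| `linker_max` | 40      | columns  | strict TM-region concatenation bound |

Two conventions deserve mention because the quantities are dimensionless
log probabilities: all logarithms in the detector are natural logarithms,
and the cutoffs −12 (with `D = 5` TM predictors) and −1 (with `D = 2` SP
predictors) are interpreted on that scale. `L_j` *sums* over predictors
rather than averaging; an averaging convention would simply rescale the
cutoffs by `D`. The `epsilon` floor is configurable; `1e-4` keeps
`D ln(epsilon)` (≈ −46 for TM, ≈ −18.4 for SP) safely below both cutoffs
so that a non-rejecting predictor is strongly but not infinitely
penalised. With a single sequence (`single_sequence_scores()`) the test
has no power and is bypassed: `p_hat` is the raw call floored at
`epsilon`, everything downstream is unchanged.

The 40-residue linker rule is applied in alignment columns, not ungapped
residues of any particular row; for seed alignments the difference is the
gap content, and columns give a determinate, row-independent rule.

## Score decomposition and the non-SP/TM threshold

The package's profile engine is a minimal plan7-style model: match states
with emission log-odds in bits, insert and delete states, per-node
transitions, begin-entry and end-exit scores, no multi-hit (J) state, no
null2-style composition correction. `viterbi_hmmls()` finds the best
single traversal, global with respect to the model and local with respect
to the query (flanking residues are emitted by the null model at 0 bits).
Ties break deterministically: match over delete over insert, then the
earliest sequence position. E-values follow the Gumbel law
`E = N (1 − exp(−exp(−lambda (S − mu))))` with the model's EVD parameters.

Because the Viterbi score is a sum of path terms, every emission and every
transition can be attributed to a model node; given a mask flagging the
model's validated SP/TM nodes, `partition_score()` splits

```
S_total = S_NG + S_TM + S_const
```

into the non-SP/TM part, the SP/TM part, and the position-independent part
(begin-entry and end-exit). A transition is attributed to the node it
*departs from*, which makes the decomposition exact (additivity to
machine precision) and local to the mask.

To decide how much of the gathering threshold `GA` a hit's non-SP/TM part
must carry, the proportion observed in the seed sequences is assumed to
persist near the threshold. Each seed `i` is scored and partitioned, and a
per-seed scaling factor

```
c_i = (GA − S_const_i) / (S_NG_i + S_TM_i)
```

shifts its position-specific score onto the threshold exactly. The SP/TM
share of the threshold is the seed mean `G_TM = mean(c_i * S_TM_i)` and
the non-SP/TM gathering threshold is `G_NG = GA − G_TM`. Seeds whose
position-specific score is exactly zero cannot be scaled and are excluded
with a warning. With an empty mask this degenerates to `G_NG = GA`
identically.

Hits are then classified by two inequalities:

| `S_total >= GA` | `S_NG >= G_NG` | verdict |
|:---:|:---:|---|
| yes | yes | `true_positive` |
| yes | no  | `unjustified` — carried over GA by the SP/TM match alone |
| no  | yes | `false_negative` — the SP/TM block acted as a penalty |
| no  | no  | `no_call` |

`rescore_without_region()` quantifies the false-negative side: the flagged
nodes are excised, consecutive surviving nodes are rejoined with the
upstream node's own outgoing transitions (the minimal-perturbation
splice), entry/exit are re-anchored at zero cost if the excision removed
them, and the query is rescored — with the *original* model's EVD
parameters, since re-calibration is out of scope.

## Synthetic fixtures: what they emulate and what they do not

All tests and the acceptance script run on generated data; nothing is
downloaded.

`make_alignment()` / `make_masks()` emulate a curated seed alignment with
planted SP/TM blocks: columns inside planted spans draw from a
hydrophobic-enriched composition (I/L/V/F/A/M at 0.78 total weight),
other columns from a uniform background with a 5 % gap rate; planted
spans are kept gap-free so the planted truth is column-aligned. Each
predictor calls planted residues with sensitivity 0.9 and everything else
with a false-positive rate of 0.05, independently across rows and
predictors — the battery is 5 TM predictors and 2 SP predictors, the
reference configuration of the method. The default depth is 30
sequences: at depth `n` the column test rejects at `k >= k_min(n)`, and
`P(Binomial(30, 0.9) >= 20) ≈ 0.9999`, so a planted column passes with
near certainty, whereas at depth 20 the rejection probability (≈ 0.989)
leaves an SP segment within one predictor-dropout of the cutoff. This is
a statement about the fixture's legibility, not about the method: real
shallow alignments genuinely have less power, which is why domains with
four or fewer seeds cannot be audited at all.

The generators do **not** emulate phylogenetic correlation between rows,
predictor-specific biases (calls are i.i.d. given the truth), partial
helices, or composition gradients; passing tests therefore demonstrate
the statistical machinery under the stated error model, not predictor
behaviour on real proteins.

`make_profile()` builds the contaminated-model scenario: an N-terminal
hydrophobic block of 40 match states (flagged in the region mask)
followed by 40 information-rich globular states, each favouring one
*non-hydrophobic* residue at probability 0.6 — the specificity of a real
globular block tends to live on polar and charged positions, and this
choice guarantees a purely hydrophobic run cannot masquerade as the
globular block. Delete transitions are cheap (−0.1 bits), so an
unrelated query whose TM anchor sits near its C-terminus traverses the
globular block as one long deletion at small cost: exactly the "single
large gap with marginal influence on the total score" mechanism by which
real hydrophobic false hits clear gathering thresholds. Members sample
both blocks from the match distributions with random flanks; decoys carry
only the hydrophobic run plus a short tail. The gathering score default
(20 bits) is a typical curated threshold low enough that a clean
hydrophobic-block match (~28 ± 8 bits) frequently reaches it.

## Numerical choices and degenerate inputs

* Exact binomial tails come from the regularised binomial CDF
  (`pbinom`), not a normal approximation; `n = 0` columns return tail 1
  and are never positive.
* `psi` of any segment lies in `[D ln(epsilon), 0]`; all-gap columns
  inside an SP span contribute `D ln(epsilon)` to the span mean.
* Score additivity in the partition is exact by construction; tests and
  the acceptance script enforce `< 1e-9`.
* Viterbi tie-breaks (match > delete > insert, earliest end) make paths
  and therefore partitions reproducible across platforms.
* A query shorter than the model admits no legal traversal; this is an
  explicit error, as is an all-flagged mask in `rescore_without_region()`.
* Stripping columns can leave a row without residues; such rows are
  dropped with a warning naming them.

## Known limitations

* The package consumes predictor *calls*; running DAS-TM, TMHMM, HMMTOP,
  SAPS, Phobius or SignalP themselves, and the BLAST retrieval of
  full-length sequences for second-round SP confirmation, are outside its
  scope (full-length sequences can be supplied directly, and
  `full_length = TRUE` then enforces the N-terminal SP constraint).
* The HMMER2 reader is a best-effort subset (LENG/GA/EVD headers plus the
  per-node score lines), not a validator; the native JSON profile format
  is canonical.
* The profile engine is single-hit and has no forward algorithm, no
  fragment-mode search and no model calibration — EVD parameters are
  inputs.
* Cutoff defaults were calibrated on helix/signal-peptide benchmarks of
  the reference battery; users substituting different predictor batteries
  should re-calibrate with `rate_table()`/`select_cutoff()` on their own
  labelled sets.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use deliberately small, seeded
problem sizes chosen as adequate for their statistical purpose: exhaustive
binomial checks to depth 20; Viterbi-versus-enumeration on models of up to
4 nodes and queries up to 8 residues (hundreds of cases); partition
additivity on hundreds to a thousand fuzzed model/query pairs; planted
recovery on 120-column, depth-30 alignments; and 100–200 null replicates
for the false-flag rate.
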