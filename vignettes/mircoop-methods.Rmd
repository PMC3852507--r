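---
title: "Inferring cooperative miRNA modules from paired expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cooperative miRNA modules from paired expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircoop)
```

## The model

miRNAs repress transcripts post-transcriptionally, and repression is often
combinatorial: several miRNAs converge on a shared target set. `mircoop`
operationalizes "cooperation" as *condition-specific target sharing*: two
miRNAs co-operate in a condition when the targets they actively repress in
that condition overlap more than chance allows.

The pipeline has three inputs per condition: a miRNA expression matrix, an
mRNA expression matrix with matched sample columns, and one static,
sequence-based miRNA→target table shared by all conditions. The
assumptions, in order of importance:

1. **Expression is already normalized.** The package validates only
   finiteness. Normalization pipelines are platform-specific and belong
   upstream; mixing them into network inference would conflate two very
   different sources of variation.
2. **Functional repression shows up as inverse co-expression.** A static
   target pair is counted as active in a condition when the Pearson
   correlation of the two profiles is strictly negative (`r < r_max`,
   default `r_max = 0`). This is a deliberately permissive filter: it
   halves the background (random pairs are negative half the time) while
   never discarding a genuinely repressed target. A stricter one-sided
   correlation test is available via `cor_alpha` for users who prefer
   fewer, cleaner pairs.
3. **Identifiers are comparable as strings.** miRNA and gene ids are
   matched case-insensitively after trimming; species prefixes are kept
   verbatim and never mapped across species. Probe-to-gene and
   orthology mapping are out of scope — aliasing is the user's
   responsibility.

### Edge scores and significance

For miRNAs $i$ and $j$ with condition-specific target sets $T_i$ and
$T_j$, the overlap score is the Jaccard coefficient
$t_{ij} = |T_i \cap T_j| / |T_i \cup T_j|$ (with $t_{ii} = 1$). Its
significance is assessed by randomizing set membership at fixed sizes: the
probability that two random sets of sizes $|T_i|$ and $|T_j|$, drawn from
the condition's target universe of size $N$, overlap at least as much as
observed. That tail has a closed form — the cumulative hypergeometric
distribution — so the default `method = "exact"` evaluates it directly
(in log space, via `lchoose`, so large universes do not overflow). The
`method = "permutation"` route draws the random sets explicitly and
reports the add-one estimate $(\#\{ \text{overlap} \ge \text{obs}\} + 1) /
(n_{perm} + 1)$; it exists as a cross-check and for users who want to
randomize under different constraints later. The two agree within
Monte-Carlo error by construction, and the test suite verifies both
against exhaustive enumeration on small universes.

Two scoping decisions matter here. The randomization universe is the
*condition's* target universe — the union of all condition-specific target
sets — not the genome: the question is whether two miRNAs share more of
the condition-active targets than chance, not whether they target at all.
And edges require `t > 0` **and** `p < alpha_edge` (strict, default 0.05);
the adjacency weight is `1 - p`, a bounded, monotone transform of
significance. `t` and `p` are both stored on every edge so any other
weighting is recoverable.

### Module extraction

Condition networks are merged into a global multigraph (one record per
condition per pair) whose collapsed simple graph is mined with MCODE,
implemented from scratch:

* *Vertex weighting*: weight of $v$ = $k_{max} \times$ density of the
  highest $k$-core of the closed neighborhood $N[v]$, with the loop-free
  density $2E/(n(n-1))$ and weight 0 for isolated vertices.
* *Prediction*: seeds in descending weight order; breadth-first expansion
  admits unassigned neighbors with weight above
  `seed_weight * (1 - vwp)`; one vertex belongs to at most one complex
  during prediction.
* *Post-processing*: complexes lacking a 2-core are dropped; haircut
  iteratively removes members of induced degree < 2; fluff (off by
  default) may add dense outside neighbors.

MCODE runs on the *simple* graph: a pair co-operating in three conditions
is biologically interesting but not three times more connected, so
condition multiplicity stays annotation. Parameters default to the
canonical published values (`vwp = 0.2`, haircut on, fluff off, 2-core
filter). All ties — equal vertex weights, equal module scores — break
lexicographically on miRNA id, which makes runs bit-reproducible and the
output invariant under vertex relabeling. Whether the original algorithm's
run used edge weights is unknowable from the published description;
unweighted is the cited default and is what is implemented.

A module's reported target set is the union of its members'
condition-specific targets over every condition that contributes at least
one intra-module edge.

### Regulator co-occurrence and pathway enrichment

Both characterizations reuse the same hypergeometric kernel. For motifs
with $m_1$ and $m_2$ carriers among $N$ scoped miRNAs and $c'$
co-carriers:

$$P(C \ge c') = \sum_{i=c'}^{\min(m_1, m_2)}
  \frac{\binom{m_1}{i}\binom{N-m_1}{m_2-i}}{\binom{N}{m_2}}$$

Motif pairs are tested within each condition's node scope separately (the
same pair can be regulatorily relevant in one condition only), Bonferroni
correction uses the number of tested pairs in that scope, and the
denominator is recorded in the output. Pathway enrichment is uncorrected
at `p < 0.05` — the regimes are deliberately asymmetric, matching how the
two analyses are conventionally reported, and are not harmonized. The
enrichment background defaults to the genes measured in the contributing
mRNA matrices (the conservative choice; a pathway can only be enriched
relative to what could have been observed), switchable to the pathway
collection's own universe.

### Sequence and structure similarity

Hairpin records are compared at four layers: seed (window on the mature
sequence, default residues 2–8, shiftable to 1–7 or 4–10), mature
sequence, precursor sequence, and precursor secondary structure. Sequence
layers use Needleman–Wunsch global alignment identity (match 1, mismatch
0, linear gap −1; matches / alignment length; deterministic tie-break so
the score is symmetric). The structure layer parses dot-bracket strings
into ordered trees (internal node = base pair, leaf = unpaired position,
virtual root) and computes the Zhang–Shasha ordered tree edit distance
with unit costs. These two in-repo metrics replace external
multiple-alignment and structure-distance programs; the replacement is a
design decision, recorded here, that trades their refinements for
dependency-free reproducibility while preserving the comparison's
structure.

Within-module pairs are pooled over modules and tested one-sided
(rank-sum) against between-module pairs and against random record pairs.
Tree edit distance is negated into a similarity first so "within more
similar" is a single test direction across layers. The unpaired rank-sum
test is used throughout — the distributions being compared are unpaired
pair-score pools, and no natural pairing exists (a signed-rank test is
sometimes named in this context; it presupposes paired observations and is
not applicable). When ids carry species prefixes (`hsa-`, `mmu-`),
`by_species = TRUE` analyzes each species separately.

## The synthetic study and what it does (not) show

`simulate_dataset()` generates the complete input bundle with planted
truth. Defaults — the package's reference study conditions — are 2
conditions, 3 disjoint groups of 5 miRNAs among 60, 400 genes, 12 samples,
shared target fraction 0.8, anti-correlation −0.8, noise sd 0.3:

* **Targets.** Each group draws a pool of `0.8 × 20 = 16` genes; members
  carry the pool plus 4 private targets; background miRNAs carry 20 random
  non-pool targets. Pools are disjoint across groups: planted modules are
  distinct regulatory programs, so recovered module boundaries are
  attributable to the method rather than to pool collisions.
* **Expression.** Linear-Gaussian: each group has a per-sample latent
  activity in its active condition (groups cycle over conditions); members
  track it with sd 0.3, pool genes respond as
  `baseline − slope × activity + noise`, private targets respond to their
  own member. The slope is solved from `anti_corr_strength` and
  `noise_sd` so planted pairs hit the requested expected correlation
  (verified in the tests to within 0.1).
* **Motifs.** Each group plants two motifs carried by its members plus 8
  extra miRNAs (regulatory programs extend beyond a module); with carrier
  sets of 13 among 60 the planted pairs clear the Bonferroni `1e-5`
  regime with large margin, while ~30 background motifs (15% carrier
  rate) stay null.
* **Hairpins.** Each group has a fixed architecture (flank/stem/bulge/
  stem/loop, all 72 nt so length is never a cue); member sequences are
  resampled under the template with compensatory mutation — paired
  positions mutate jointly, preserving complementarity — at rate
  `hairpin_mut_rate`, default 1. At the default the sequence layer is an
  *exact* null (member sequences are random given the architecture) while
  the structure layer carries the full planted signal; lower rates
  interpolate toward literal point mutations. Structures are produced by
  the package's own Nussinov folder (base-pair maximization with a
  minimum loop of 3, Watson–Crick + GU), not an energy model.

What passing on this generator shows: the scoring, significance,
module-detection and comparison machinery do what they claim under a
linear-Gaussian expression model with cleanly planted signal. What it does
not show: robustness to probe effects, saturation, batch structure,
unbalanced replication, annotation noise, or thermodynamically realistic
folds — none of which the generator emulates.

With the defaults, the full pipeline recovers all three planted groups
exactly (`truth_recovery_score = 1`) in 10/10 replicate seeds, and the
negative control (`shared_target_fraction = 0`, which the constructor
accepts precisely for this purpose) collapses recovery to ≈ 0. The
structure layer's within-vs-between p-value is consistently below
`0.01` (typically far below) while the precursor-sequence layer stays
uniform — the planted
analogue of structurally coherent modules whose members are unrelated in
sequence.

## Numerical choices and degenerate inputs

* p-values are compared to thresholds with strict `<`, everywhere.
* Zero-variance expression vectors make correlation undefined; in the
  pair filter they are skipped and counted, at the single-pair interface
  they error.
* A rank-sum test on fully degenerate data (all values identical) returns
  p = 1: no evidence. The exact enumeration branch is used for tie-free
  pooled samples of at most 12; otherwise the normal approximation with
  tie correction (no continuity correction).
* `hypergeom_tail` returns exactly 1 at `c_obs = 0` and accumulates log
  terms with a max-shift, so tails of order `1e-300` come out finite.
* Nussinov traceback prefers pairing the interval's left end with the
  leftmost optimal partner; alignment traceback prefers diagonal, then
  up, then left — both choices exist only to make outputs reproducible.
* Networks with fewer than two eligible miRNAs are valid, edgeless, and
  warn rather than error; empty module tables propagate through
  annotation, enrichment and serialization.

## Problem sizes

The test suite and the acceptance script run the generator at its default
size (60 miRNAs × 400 genes × 12 samples × 2 conditions, about one second
per end-to-end network build), ten replicate seeds for the recovery
property, 2000 replicates for null calibration, and exhaustive
enumeration oracles up to universe size 12 (hypergeometric), 8 vertices
(cores), 6 tree nodes (edit distance) and length 12 (folding). These
sizes were chosen so every oracle is genuinely exhaustive while the whole
suite stays interactive.

## Known limitations

* Pearson correlation only; no partial correlation, mutual information,
  or lagged correlation (relevant for periodic time-course designs).
* The Nussinov folder maximizes pairs and will happily pair loop bases
  that an energy model would leave open; synthetic structure families are
  therefore noisier than miRBase-style annotations, which real analyses
  should supply via the Vienna input.
* One-vertex-one-complex during MCODE prediction means overlapping
  modules arise only through fluff; a miRNA's multiple roles are
  represented through its per-condition edge records instead.
* Bonferroni and "none" are the only multiplicity regimes, mirroring how
  the two annotation analyses are conventionally reported.
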