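---
title: "Methods: network-based drug repurposing by signature reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based drug repurposing by signature reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddnscreen)
```

## The model

`ddnscreen` scores how strongly a drug's transcriptomic effect *opposes* a
disease expression signature, restricted to the part of the pathway
interactome that connects the two. The pipeline has four stages.

**1. Unified pathway graph.** Every input pathway is a signed directed edge
list over gene symbols (+1 activation, -1 suppression). `build_ughp()` takes
the union of all genes and all asserted relations: conceptually a matrix
$U_{ij} \in \{-1, 0, 1\}$, where 0 means no pathway asserts a direct
relation. When two pathways disagree on a sign the edge is kept (only
topology feeds the score), stored as +1, and flagged in `conflict_edges` —
sign is retained for reporting and network figures, not for scoring. A note
on encoding: some pathway resources describe the value set in the order
"activation, suppression" against -1, 1; this package always stores
+1 = activation and validates input signs strictly.

**2. Disease genes.** For a chosen subtype, `select_candidates()` intersects
two evidence arms computed one-vs-rest:

* *Copy-number arm.* A sample is aberrant at a gene when its copy-number
  log-ratio magnitude reaches `amp_threshold` (default 0.5; amplification
  and deletion are pooled). Each gene gets a G-score — aberration frequency
  in the subtype times mean absolute amplitude over aberrant subtype
  samples — and a two-sided Fisher's exact p-value on the
  aberrant-by-subtype 2x2 table. Genes in a common-variant catalogue are
  excluded *before* testing ("aberration but no common variant"), and
  p-values are Benjamini–Hochberg adjusted across the tested genes
  (`adjust = "none"` restores raw p). The arm keeps genes with adjusted
  p <= `alpha` (default 0.05); its size defines N. This is a deliberately
  transparent surrogate for full copy-number segmentation pipelines: the
  two steps retained (G-score, Fisher significance) are the ones that
  matter for gene selection, while peak deconvolution and arm-level scores
  are out of scope.
* *Expression arm.* All genes are ranked by the chi-square statistic of
  their equal-frequency-binned expression (default `n_bins = 3`, no
  continuity correction) against the subtype-vs-rest split; the top N are
  kept. Equal-frequency binning plus a chi-square ranking replaces the full
  Chi2 interval-merging discretization because the ranking, not the
  discretization, is what the selection consumes. Ties are broken by
  statistic then gene symbol, so the arm is deterministic.

The candidates are the intersection of the arms. A triple-negative-style
analysis needs no special mode: labels are always collapsed to
subtype-vs-rest.

**3. Disease signature.** The subtype signature is a robust z-score per
gene, $z = (\mathrm{med}_{in} - \mathrm{med}_{out}) / (1.4826 \cdot
\mathrm{MAD}_{out})$, clipped to $[-10, 10]$ — the same bounded scale as
level-5 perturbation z-scores, positive when the gene is higher in the
subtype. The out-group MAD is floored at $10^{-6}$ times the matrix dynamic
range so flat genes stay finite. The exact normalization used upstream of
published subtype signatures is rarely stated; a median/MAD contrast was
chosen because it is robust to outliers, sign-interpretable, and respects
the required bound. It is invariant under per-gene constant shifts (tested).

**4. Drug–disease network and score.** A drug condition is a
(drug, dose, time) profile of gene z-scores clipped to $[-10, 10]$. Its
*drug genes* are the top `k = 50` genes by $|z|$ (ties lexicographic). Drug
and disease genes are mapped onto the unified graph (unmapped genes are
dropped and counted — drug genes are selected from the full profile first,
then mapped, since restricting before selection would silently change the
meaning of "top 50"). For every (drug gene, disease gene) pair,
`build_ddn()` collects the nodes on *all* minimum-hop paths: node $v$ lies
on a shortest $s \to t$ path iff $d(s,v) + d(v,t) = d(s,t)$, which unions
every tie instead of picking an arbitrary path. Traversal is undirected by
default (subnetworks connect drug and disease genes without an orientation
claim); a directed mode is available. The node count obeys
$|V_{DDN}| \le G_{dr} + G_{di} + G_i$ with equality exactly when no gene
plays two roles; a gene that is both drug and disease gene is categorized
once. Unreachable pairs contribute only their endpoints and are counted.

The repurposing score is the Pearson correlation

$$ r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
            {\sqrt{\sum_i (x_i - \bar x)^2}\sqrt{\sum_i (y_i - \bar y)^2}} $$

over the DDN genes carrying a z-value in **both** the drug profile and the
disease signature (no imputation). Strong *negative* r marks a drug whose
effect reverses the disease signature. The score is *undefined* — excluded
from rankings rather than set to 0, which would fake neutrality — when
fewer than 3 genes survive or either array has zero variance. Rankings sort
ascending with lexicographic tie-breaks on the profile key.

**Condition selection.** Per drug, only the minimum- and maximum-dose
profiles are analysed; the 24 h time point is preferred, and when a chosen
dose lacks 24 h the drug's default time point is used (its most frequent
time point in the input, earliest on ties).

**Drug pairs.** Pair screening assumes additivity: the pair's z on a gene
is $X = X_i + X_j$ over the shared genes, deliberately *not* re-clipped.
The combined profile goes through the same top-50 / DDN / Pearson pipeline.
Each record carries the combined score, both single scores, and all three
ranks. Known drug–drug interactions are removed *after* scoring
(post-verification), so an updated interaction catalogue can be re-applied
without rescoring; blocked severities default to all of minor, moderate,
major, and removals are logged with their severity. `cmd_score_pairs()`
pairs each drug's best-scoring single condition — published repurposing
tables list one condition per drug, and pairing every condition would
square the condition count, not the drug count. Higher-order combinations are not
enumerated (combinatorial cost); the additive machinery generalizes if
needed. The final report keeps pairs strictly more negative than the best
single drug, capped at 100.

## What the synthetic generator emulates

`generate_pathways()`, `generate_cohort()`, `generate_drug_library()` and
`generate_interaction_table()` produce seeded inputs with planted ground
truth for every stage; `simulate_bundle()` writes them in the exact TSV
dialects the pipeline reads plus a YAML manifest. Defaults are the
package's study conditions, chosen once as plausible desk-scale analogues
of the real resources:

* **Pathways**: 200-gene universe, 12 pathways of ~40 signed edges each
  (random spanning tree plus extra edges, 70% activation), covering 80% of
  the universe so unmapped-gene handling is always exercised.
* **Cohort**: 120 samples, 3 subtypes, 20 drivers planted in subtype S1 —
  the same order of magnitude as published per-subtype driver lists.
  Drivers carry a 1.0 log-ratio copy-number shift at 80% penetrance over
  noise sd 0.15, and a subtype-wide expression shift of 4 sd in the same
  direction (drivers are subtype-defining in expression; the copy-number
  lesion has incomplete penetrance). Ten decoy genes get the same
  copy-number lesion but sit in the variant catalogue. 30% of background
  genes are differentially expressed in a random subtype with shift
  ~ N(0, 1), giving the signature realistic spread beyond the drivers.
* **Drug library**: 200 drugs at two doses (0.04, 10 umol) and two times
  (6 h, 24 h). Background drugs are clipped Gaussian noise (sd 2). The
  planted reversal drug has $z = -\text{signature} + N(0, 0.5)$. The
  planted complementary pair each reverses one half of the genes
  (noise elsewhere), with the halves stratified so each member reverses
  half of the planted drivers — that even split *is* the planted ground
  truth for the combination ("catalyzing") effect.

Problem sizes used by the test suite and the acceptance script: the full
200-drug library for single-drug properties, and a 30-drug library for the
quadratic pair screen (435 pairs), generated *without* the full-reversal
drug. The latter is a study-design point, not a shortcut: a library
containing a near-perfect single reverser cannot, by construction, contain
a pair that beats the best single drug, whereas real libraries' best
singles are ordinary drugs (scores around -0.6 to -0.8) — which is exactly
the regime where combination superiority is observable.

What passing these simulations does **not** show: the generator makes no
attempt to match real perturbation marginals, linkage between conditions of
one drug, probe-level artifacts, cohort batch effects, or pharmacology.
Green tests certify the machinery (selection, graph construction, scoring,
filtering, determinism) under known ground truth, not clinical validity of
any ranking on real data.

## Numerical and degenerate-input choices

* All RNG flows through one seed per generator call; generators restore the
  caller's RNG state. Identical configuration + seed gives byte-identical
  output files (tested by checksum).
* Shortest-path node sets come from hop-count distance matrices (igraph),
  cached per traversal mode for graphs up to 3000 nodes; the
  $d(s,v)+d(v,t)=d(s,t)$ criterion is exact for unweighted graphs and
  removes all path-tie nondeterminism.
* Self-loops are dropped at parse time; duplicate edges are collapsed;
  unknown sign tokens and malformed rows fail with the line number.
* `source == target` yields `{source}`; unreachable targets yield both
  endpoints with `reachable = FALSE`.
* Constant genes get chi-square statistic 0; empty candidate sets are a
  warning, not an error; `alpha = 0` legitimately selects nothing.
* Undefined correlations (< 3 genes, zero variance, or a side of the DDN
  that mapped to nothing) are values, never exceptions, and are excluded
  from rankings and reports.
* Every tie anywhere (gene selection, rankings, pair ordering) breaks
  lexicographically, so outputs are stable across platforms.

## Known limitations

* The G-score surrogate does not segment copy-number data or separate
  amplification peaks from deletions; it assumes gene-level log-ratios.
* Additivity is the only combination model; no Bliss/Loewe-style synergy.
* Gene identifiers are case-sensitive symbols with no alias mapping.
* The KGML reader covers only gene–gene activation/inhibition relations.
* Undirected traversal is the default even though pathway edges are
  directed; directed mode changes DDN composition and is exposed via
  configuration rather than silently mixed.
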