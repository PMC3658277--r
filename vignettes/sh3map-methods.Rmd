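---
title: "Models and methods behind sh3map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sh3map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh3map)
```

This vignette documents the statistical models, the parameter choices, and
the numerical conventions used throughout `sh3map`, together with what the
synthetic-data generator does and does not emulate.

## Position weight matrices

A PWM models the binding specificity of one SH3 domain as independent
per-position amino-acid preferences. `build_pwm()` proceeds in five steps:

1. **Counts.** Residues are tabulated per alignment column. A gap is a
   non-specific position: it contributes 1/20 of a count to every residue of
   its column, preserving total column mass without favoring any residue.
2. **Entropy-proportional pseudocount.** Column `j` receives a per-residue
   pseudocount `kappa * H_j / ln 20`, where `H_j` is the Shannon entropy
   (natural log) of the raw column frequencies. The proportionality constant
   is exposed as `kappa` (default 1): a sharp column (`H_j` near 0) is left
   essentially untouched while a non-specific column is smoothed toward
   uniform, which is the desired behavior for phage selections where
   non-specific positions carry sampling noise rather than signal.
3. **Background significance.** Small count fluctuations at non-specific
   positions would otherwise masquerade as preference. Each residue's raw
   integer count (gap-derived fractions rounded down, for the test only) is
   tested against the background frequency 1/20 with a one-sided binomial
   test; residues with p > `alpha` (default 0.05) are replaced by their
   joint mean, preserving column mass.
4. **Normalization.** Columns are renormalized to probabilities and the
   odds matrix is `20 * prob`, so each column's odds average 1 and the score
   of an m-mer, the product of per-position odds, equals the probability
   product normalized by `20^-m`. A completely non-specific PWM therefore
   scores exactly 1 for any peptide — the natural neutral point for the
   motif threshold below.
5. **Flank trimming.** Alignment flanks with normalized entropy
   `H_j / ln 20 >= 0.76` carry no specificity and are removed iteratively
   from both ends, never from the interior. The 0.76 cutoff is interpreted
   on the normalized scale (0 = deterministic, 1 = uniform); at least one
   column (the minimum-entropy one on ties) is always retained.

Unknown residues (`X`, `*`) score a neutral odds factor of 1, so real
proteomes scan without errors. Coordinates are 1-based and inclusive.
Binding motifs are windows with score `>= T`, with `T = 1000` as default;
the threshold sits well above the neutral score of 1 and, on the synthetic
worlds, cleanly above the cross-reactivity scores of unrelated sharp PWMs.

## Specificity similarity and tree

For PWMs `a` and `b` and a relative offset, the two matrices are compared
over the union of their columns; positions where one PWM has no column are
treated as uniform (all residues equally weighted). The distance is the
root-mean-square over union columns of the per-column squared probability
differences,

```
d = sqrt( (1/n) * sum_cols sum_residues (p1 - p2)^2 ),
```

with `n` the union-alignment length; `d_aligned` is the minimum over all
offsets with at least `min_overlap` (default 1) overlapping columns. Whether
the normalization by `n` sits inside or outside the square root is a design
choice; inside was chosen (root-mean-square per column), and since `n`
varies with the offset this means partially overhanging alignments are not
exactly equivalent even against a uniform PWM. Because non-specific columns
make any two PWMs look mildly similar, the background distance
`d_unaligned` (zero overlap, `n = m_a + m_b`) is subtracted:

```
similarity = (d_unaligned - d_aligned) / d_unaligned,
```

clamped to [0, 1] — alignments of anti-correlated PWMs can be *worse* than
the background, and clamping keeps `1 - similarity` a valid dissimilarity
for clustering. Two uniform PWMs are defined maximally similar. The tree is
average-linkage hierarchical clustering on `1 - similarity`; identifiers are
sorted before clustering so tied merges resolve identically regardless of
input order, making the Newick output deterministic.

## Network filtering

A raw Y2H candidate (colony counts summed across screens) enters the
high-confidence network if supported by two independent lines of evidence:

* `multi_colony` — at least two independent positive colonies;
* `literature` — one colony, but the pair appears in a published interaction
  set, a known interolog set, a functional-interaction network, or is
  otherwise literature supported;
* `motif` — one colony, but the prey carries a binding motif matching the
  bait's phage-derived specificity (score >= `T`); only SH3-domain baits
  are eligible, since only they have specificity profiles.

Preys flagged as transcription factors with more than `tf_degree_max = 5`
distinct baits in the kept network are then removed as likely
auto-activating preys. The rule is stated at degree level (rather than as a
fixed list of offending preys) so it transfers to synthetic screens;
evidence-class tallies are reported both before and after the TF pruning
since published counts can be read either way.

The phage/Y2H agreement statistic excludes edges admitted *by* the motif
rule (they would trivially inflate it) and summarizes the remaining edges'
genomic ranks by the normalized area under the cumulative rank curve, which
reduces to `auc = (P + 1 - mean(rank)) / P` for proteome size `P`. The null
assigns each edge a uniform random rank; the p-value uses the add-one
estimator `(1 + #[null >= observed]) / (1 + n_random)` so it is never zero.
`n_random` is configurable (default 1e5) — the statistic stabilizes long
before that at desk scale.

## Cross-species conservation and rewiring

Interactions project between species via a many-to-many ortholog map; all
ortholog combinations are emitted and edges are identified by their
unordered endpoint pair (the bait/prey direction is an assay artifact). The
universe of testable interactions among conserved proteins is
`n_baits * n_preys - n_bp (n_bp - 1) / 2`, the correction removing pairs
counted twice when `n_bp` baits also act as preys. Overlap significance is
the one-sided hypergeometric upper tail (equivalently one-sided Fisher's
exact test) with the reference interactions as successes. The universe is a
caller-supplied argument precisely because reasonable analysts can restrict
it differently; `universe_size()` exposes the formula.

A non-conserved SH3 interaction is classified at binding-site resolution:

* **Specificity conservation**: if both orthologous domains have PWMs, PWM
  similarity >= 0.5; otherwise ungapped domain sequence identity >= 0.5.
  PWM similarity is preferred because it measures function directly;
  sequence identity is the fallback when no profile exists. An ortholog
  without any SH3 domain is not conserved.
* **Motif conservation**: some predicted motif (score >= `T`) on the target
  whose best ungapped match in a target ortholog reaches 50% identity; the
  most conserved motif is used. When the ortholog is shorter than the motif,
  overhanging positions count as mismatches.
* Scenarios: (i) motif conserved only; (ii) specificity conserved only;
  (iii) neither; both conserved means the loss has other causes. Without a
  source PWM, without any motif at `T`, or without ortholog sequence the
  call is `unmappable` rather than guessed.

Ungapped sliding alignment is used for both motif matching and the domain
fallback: the motifs are short linear peptides for which gapped alignment
adds parameters without benefit, and the same convention keeps the two
identity scales comparable.

## Modified k-core function prediction

Given seed proteins of known function, the modified k-core is the maximal
set of non-seed proteins each connected to at least one seed and retaining
at least `k` links to other members or seeds. Pruning removes all failing
nodes simultaneously per round; the fixpoint is unique and order-independent
(tested against an exhaustive-subset oracle). Scores are the maximal `k` of
membership, 0 for network proteins never in a core, and -1 for proteins
outside the network; both -1 and 0 are retained as ROC thresholds.
Cross-validation splits the seeds into 10 folds, scores each held-out fold
against negative examples with the remaining seeds as the conditioning set,
and computes the AUC by the rank formula, which equals trapezoidal
interpolation across tied integer scores. Negatives default to a uniform
sample from the universe minus the seeds. Predictions use `k = 3`, ranked by
score, then seed degree, then identifier.

## Annotation semantic similarity

Term information content is `IC(t) = -ln(n_t / n_root)` with `n_t` the
number of annotation events mapping to `t` or its descendants and `n_root`
the per-namespace total; the measure of term relatedness is the Lin form
`2 IC(MICA) / (IC(a) + IC(b))`, chosen over Resnik because the protein-pair
score is specified to range from 0 to 1 (Resnik is available behind the
`method` flag). A protein pair's score is the maximum over all same-
namespace term pairs; cross-namespace pairs are skipped rather than scored
0 so multi-namespace annotation does not dilute maxima, and unannotated
proteins receive no score rather than 0. The network benchmark rebuilds the
random networks' bait structure (each bait gene gets `per_bait` random
interactors from the universe) and reports four metrics — percent scored,
score sum, average over scored pairs, average over all pairs — against the
empirical null with add-one p-values.

## Motif competition

Predicted sites closer than 10 residues (start to start) describe one
physical binding site; chained runs of close sites are collapsed to their
highest-scoring member. Clustering per protein over the union of interacting
domains' motifs was chosen (a per-domain variant is a one-line change)
because the competition question — how many distinct sites does a target
offer its partners — is a property of the target. Two domains are
*competitive* on a target when their accepted sites overlap in residue span
and *coincident* otherwise. Association between motif count and partner
count uses Spearman's rank correlation with average-rank ties; p-values come
from exhaustive permutation enumeration for n <= 9 and the t approximation
otherwise.

## The synthetic world

`gen_world()` generates a complete study with ground truth, designed so the
pipeline's recovery claims are checkable. Defaults (see `world_config()`):
10 domains with class I/II/atypical structure at anchor sharpness 0.9; 40
phage peptides per domain at 10% per-residue noise (comparable to a real
selection of a few dozen unique peptides per domain); 150 background
proteins with log-normal lengths (median 400, a realistic proteome scale);
a dense functional module (6 baits x 20 preys, 3 edges per prey) plus 30
background edges; zero-truncated Poisson colony counts (mean 2.5);
40 single-colony false positives; 2 sticky TF preys hitting 8 baits each;
90% ortholog coverage; 40 rewired interactions in a fixed scenario mixture
(15/30/40/15% for i/ii/iii/conserved). Class I and II generator PWMs carry
two domain-private "identity" anchor columns in addition to the canonical
proline/basic anchors; without them, motifs of two same-class domains are
nearly identical and binding-site conservation across domains becomes
ill-posed — real SH3 domains likewise differ in flanking preferences beyond
the shared consensus. Planted motifs are sampled from their PWM until they
reach `T` and inserted at least 12 residues apart. One master seed fans out
deterministically (`child_seed()`) so each component can be regenerated
independently; identical seeds give identical worlds.

What the generator does **not** emulate: realistic amino-acid composition
(background residues are uniform), phylogenetic sequence evolution (the
second species is a point-mutated copy with scenario-controlled motif
fates), non-bipartite network structure (all edges are bait-prey), and
ontology scale (a handful of terms in one namespace). Passing recovery
tests on this world therefore demonstrates the correctness of the
algorithms under their stated models, not performance on real proteomes,
where motif discovery is harder (compositional bias, disorder, paralogy).

## Numerical conventions and problem sizes

Ties: window scans and motif matches prefer the smallest start; proteome
ranks use the minimum-rank convention; tree merges resolve by lexicographic
identifier order. Degenerate inputs: proteins shorter than the PWM score 0
with no windows; a peptide set whose columns all exceed the trimming
threshold retains its single most specific column with a warning; constant
vectors make Spearman's rho undefined and raise an error. Column-sum
invariants are enforced at 1e-9 for freshly built PWMs and at the format
precision (about 1e-5) for matrices read from 6-decimal files, which is
what makes file round-trips bit-exact.

The test suite and the pipeline default to desk-scale sizes — 150-protein
proteomes, 10 domains, 1e4 null randomizations, 100 random benchmark
networks at 20-30 interactors per bait — chosen so a complete run finishes
in well under a minute while every statistic is still comfortably inside
its asymptotic regime; all sizes scale up through `world_config()` and the
functions' `n_random` / `n_networks` arguments.
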