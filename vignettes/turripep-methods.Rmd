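---
title: "Methods: peptide libraries in a phylogenetic framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide libraries in a phylogenetic framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turripep)
```

## The problem

Conoidean venom glands express on the order of 200 distinct peptides per
species. The peptides evolve fast: within a gene superfamily the signal
peptide is nearly invariant, the mature region is hypervariable, and only
the cysteine scaffold — the number and spacing of cysteines — is
conserved. The same transcriptomes also contain housekeeping genes (HKG),
mostly ribosomal, that make a convenient neutral marker panel. `turripep`
implements the joint analysis: a species phylogeny from the HKG panel, a
peptide classification from the cysteine framework, HKG-relative
expression for prioritization, and a statistical check that peptide
clades respect genus boundaries.

## Models and procedures

### HKG panel

A contig annotation table (sample, contig, gene label, e-value, TPM) is
filtered at `e_value < 1e-4` — the inequality is strict, so a hit at
exactly the threshold is discarded. The panel is the intersection of
per-sample gene label sets. The choice of representative contig when a
sample has several contigs for one gene is not dictated by any published
rule, so the package fixes one deterministically: smallest e-value, then
largest TPM, then lexicographically smallest contig id. Gene identity is
by annotation label string; no orthology inference is attempted.

### Distances and trees

Per-gene trees come from p-distances under pairwise deletion (sites where
either sequence has a gap, `N` for DNA or `X` for protein, are dropped
per pair), corrected with the Jukes–Cantor map
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, and neighbor joining on the
standard Q criterion. Numerical choices:

* **NJ ties** are broken on the lexicographically smallest pair of
  cluster labels (a cluster is identified by the smallest leaf label it
  contains), so the output is reproducible for degenerate matrices.
* **Negative branch lengths** from the two-point formulas are clamped to
  zero with the deficit moved to the sibling branch (the pairwise path
  length is preserved); the count of clamped branches is recorded on the
  tree.
* **Saturation** (`p >= 0.75`) is an error by default; `cap = TRUE` caps
  at 0.74999 for noisy data.

Midpoint rooting places the root halfway along the longest leaf-to-leaf
path; equal-length diameter paths are resolved toward the
lexicographically smallest endpoint pair, and a midpoint landing exactly
on a node roots at that node. The implementation is checked against a
brute-force diameter search over all leaf pairs.

### Consensus and support

The study-scale inference (per-gene maximum likelihood plus a quartet
summary method) is replaced by bipartition-frequency consensus: every
gene tree contributes its non-trivial bipartitions; a split is kept when
its frequency strictly exceeds `min_frequency` (0.5 by default, i.e.
majority rule); with `greedy = TRUE` remaining splits are added in
decreasing frequency when compatible with what is already accepted, ties
broken on the canonical split string. Node support is the exact fraction
of gene trees containing the split — precisely the semantics reported for
the published consensus tree — stored exactly and displayed to two
decimals. This substitution is the package's central design decision: it
keeps the whole inference self-contained and desk-scale while preserving
the meaning of the numbers at the nodes. Maximum-likelihood inference,
model selection and bootstrap are out of scope.

Support fractions assume complete leaf sets; gene trees with missing taxa
are rejected rather than silently renormalized, since the published
account does not say how fractions were computed in that case.

### Peptide framework analytics

`extract_framework()` reports 1-based cysteine positions, loop lengths
counted *strictly between* consecutive cysteines, and terminal segment
lengths; the reconstruction identity
`nterm + sum(loops) + n_cys + cterm == length` holds for every sanitized
string and is property-tested. Loop-1 (between the first two cysteines)
separates the two major divisions of the P-like turripeptides: length 6
in clades I–II, length 1 in clades III–IV.

The consensus motif rule is invented here, because the published motif is
printed without its derivation rule: per position, residues at frequency
≥ 0.25 are listed alphabetically, a residue alone above 0.5 is written
bare, and `X` marks positions with no qualifying residue. On the packaged
clade I+II records this yields `E(D/E)N(L/R)(E/V)X` — six positions with
the E/N anchor at positions 2–3 and a hypervariable tail, in qualitative
agreement with the published motif; bit-exact agreement is not asserted.

The `ii` variant suffix in toxin names is attached to a second precursor
yielding an identical or near-identical mature peptide; this is inferred
from the printed name pairs, the convention not being stated explicitly.

### Expression

TPM is the standard within-sample normalization
(`1e6 * rate_i / sum(rates)`). The toxin summary statistic is
`log2(toxin_TPM / mean(HKG TPM))` per transcriptome, using the
*arithmetic* mean (the published caption says "mean" without qualifier);
a geometric-mean option exists behind a flag. A zero-TPM toxin is
reported as absent (`NA`) rather than `-Inf` to keep tables finite. The
full panel is used per sample; whether the original figure used all 66
HKGs or a subset is unstated.

### Congruence test

The claim "no peptide clade mixes the two genera" becomes a statistic:
the number of clades whose records span at least two genera. The null
shuffles genus labels over records with clade sizes fixed;
`p = (1 + #{null <= observed}) / (1 + B)` is always in (0, 1]. The
statistic is deliberately the simplest formalization of the claim; a
G-test on the clade-by-genus table would be an extension, not the
default. Every printed report carries the caveat that absence from the
sampled transcriptomes is not evidence of absence in the genus.

## The synthetic world

The generators state one world and keep it fixed:

| knob | default | why |
|---|---|---|
| `n_species` | 13 | the turrid ingroup scale of the study |
| `n_genes` | 66 | the published HKG panel size |
| `n_toxins_per_species` | 200 | "approximately 200 peptides" per venom gland |
| `framework_pattern` | `C-C-C-C-C-C` | six-cysteine P-like scaffold |
| `signal_sub_prob` | 0.02/site, capped at 5% | "very highly conserved" signal, stated without a number; the cap guarantees ≥ 90% pairwise identity |
| `expr_meanlog`, `expr_sdlog` | log(50), 1.5 | log-normal TPM spread typical of venom-gland transcriptomes |
| `discordance_rate` | 0.2 | free knob, not an estimate (see below) |

**Gene-tree discordance** is generated by local topology perturbation,
not by a coalescent: per internal edge of the unrooted species tree, with
probability `discordance_rate` the resolution around that edge is
re-drawn uniformly from the three possibilities. The published account
implies discordance only through support fractions below 1 and gives no
generative model, so the rate is a knob that exercises the consensus
machinery, nothing more. The uniform re-draw (rather than forcing one of
the two alternative resolutions) is what makes full perturbation of a
4-leaf tree land on each resolved topology with frequency 1/3, the
behavior the test suite asserts.

**What a green test establishes.** The synthetic world has no indels, no
codon structure, no rate heterogeneity, no missing taxa, no assembly
noise, and discordance that is topology-only jitter rather than a
population-genetic process. Recovery results on it (species tree
recovered at zero discordance with all supports 1.0; the planted 66-gene
panel found exactly; a planted 8-fold toxin scoring log2 fold 3.0) verify
the *machinery*, not the biology: they show the pipeline is internally
consistent, not that it would resolve a hard real phylogeny.

Two recovery properties intentionally run on simulated gene *trees*, not
on sequences evolved along them: with finite sequences every per-gene NJ
tree is a noisy estimate, so "all supports exactly 1.0 at zero
discordance" can only hold for the tree route. Sequence-route
consistency is tested separately (the Jukes–Cantor estimate at alignment
length 1e5 falls within three standard errors of the simulated
distance).

**Permutation p-value uniformity.** The mixed-clade-count statistic is
discrete, so permutation p-values are sub-uniform with atoms roughly the
size of the null statistic's largest point mass. The uniformity check
(Kolmogorov–Smirnov at α = 0.01) therefore runs on an instance chosen a
priori to make the null rich: 100 clades of 3 records with two balanced
genera, where the null statistic is approximately binomial with standard
deviation ≈ 4.3 and largest atom ≈ 0.09, well under the KS critical
distance at n = 100 replicates. On small instances the same check would
fail for arithmetic reasons, not implementation ones.

## Degenerate inputs and tie-breaks (summary)

* Sanitization strips every non-letter character (whitespace, digits,
  byte-order marks) instead of erroring — the packaged peptide table
  itself contains an invisible character in one cell, kept verbatim so
  the path is exercised on real input.
* "More than 5% N" and "e < 1e-4" are strict inequalities; the boundary
  cases (exactly 5% N, e-value exactly 1e-4) are pinned by tests.
* An empty panel intersection is a valid result with a warning, not an
  error.
* `clade_partition()` on non-binary or single-leaf major branches
  produces fewer than four labels and says so in an attribute; a
  caterpillar tree is the canonical degenerate case.
* The peptide-tree clade recovery on the packaged table is *reported* as
  a concordance table, never asserted: the published clade labels derive
  from a maximum-likelihood tree of full precursors, whereas the package
  only has mature peptides and a distance tree.

## Known limitations

* Neighbor joining and p-distances are a deliberate stand-in for
  likelihood inference; branch lengths and supports are not comparable
  to published ML/bootstrap values.
* The fallback peptide alignment (right-padding, used only when `mafft`
  is absent) is crude; concordance numbers under it are indicative only.
* No cleavage-site prediction: mature peptides come from provided
  boundaries or annotations.
* The congruence test treats absence in the table as absence in the
  venom, which the caveat in every report qualifies.
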