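# turripep

Venom peptide libraries in a phylogenetic framework for turrid snails.

Venom-gland transcriptomes of conoidean snails carry two kinds of signal at
once: a panel of broadly expressed housekeeping genes (HKG) that works as a
neutral phylogenetic marker set, and a hypervariable library of venom
peptides whose cysteine scaffolds group them into families. `turripep`
implements the desk-scale pipeline that joins the two for the P-like
turripeptides of *Turris* and the segregate genus *Purpuraturris*:

1. **Read filtering and IO** — FASTA/newick/TSV readers and writers, plus
   the transcriptome record filter (discard reads shorter than 70 bp or
   with more than 5% ambiguous bases; exactly 5% is kept).
2. **HKG panel** — from per-sample blast annotation tables, keep hits with
   `e < 1e-4` (strict), intersect gene labels across all samples, and pick
   one representative contig per (sample, gene) by best e-value, then
   highest TPM, then contig id.
3. **Phylogenetics** — p-distances with pairwise deletion, the
   Jukes–Cantor correction `d = -(3/4) ln(1 - 4p/3)`, neighbor joining on
   the Q criterion `Q(i,j) = (n-2) d(i,j) - Σ_k d(i,k) - Σ_k d(j,k)` with
   deterministic tie-breaking, midpoint rooting by brute-force-verifiable
   diameter search, and a gene-tree consensus whose node values are the
   *fraction of individual gene trees containing that node's bipartition*
   (majority rule with optional greedy extension).
4. **Peptide analytics** — cysteine-framework extraction (positions,
   inter-cysteine loop lengths, terminal segments), framework census,
   degenerate consensus motifs, toxin nomenclature (`Tba9.3`-style names
   and `ii` variants), duplicate detection, and clade partition of a
   midpoint-rooted peptide tree into up to four clades (I–IV).
5. **Expression** — TPM from counts, and the HKG-relative fold change
   `log2(toxin_TPM / mean HKG_TPM)` per transcriptome, with lead-toxin
   ranking.
6. **Congruence** — the observation that no peptide clade mixes the two
   genera, formalized as the genus-mixed-clade count with a label
   permutation null and add-one-corrected p-value.
7. **Synthetic data** — Yule species trees, gene trees with tunable
   discordance, Jukes–Cantor sequence evolution, toxin precursor
   repertoires (conserved signal, hypervariable mature region, fixed
   cysteine scaffold), annotation and expression tables; every generator
   is a pure function of (inputs, seed).

The package ships, at `inst/extdata/turripeptides_table.tsv`, the published
table of 32 predicted mature P-like turripeptide sequences from nine
species (clades I–IV), transcribed verbatim — including one cell with an
invisible leading byte-order mark that the sanitizer removes.

A deliberate methodological substitution: the original study inferred
per-gene trees by maximum likelihood (GTRGAMMA) and summarized them with
ASTRAL. `turripep` replaces that stage with in-repo neighbor joining plus
bipartition-frequency consensus, which reproduces the reported node-value
semantics (gene-tree support fractions) in a self-contained, testable
form. See the methods vignette for the full rationale.

## Worked example

```r
library(turripep)
recs <- read_toxin_table()        # packaged table, sanitized
framework_census(recs)
#> framework census over 32 records
#>   modal cysteine count: 6
#>   clade I loop-1 length(s): 6
#>   clade II loop-1 length(s): 6
#>   clade III loop-1 length(s): 1
#>   clade IV loop-1 length(s): 1
#>   outliers (n_cys != clade mode): Tba9.4
```

All 32 peptides are classified by their cysteine framework: the modal
count is six cysteines (the P-superfamily arrangement); clades I and II
have six residues between the first two cysteines where clades III and IV
have one; `Tba9.4` is flagged because its cysteine count (5) differs from
its clade's mode — a possible variant framework or typographical artifact,
flagged rather than corrected.

```r
consensus_motif(recs[recs$clade %in% c("I", "II"), ], loop_index = 1)
#> [1] "E(D/E)N(L/R)(E/V)X"
```

The loop-1 consensus of the 17 clade I+II peptides: position-wise
residues at frequency ≥ 0.25 (parenthesized), a bare letter where one
residue reaches 0.5 alone, `X` where nothing qualifies.

```r
exclusivity_permutation_test(recs, n_permutations = 10000, seed = 1)
#> clade-genus exclusivity permutation test
#>   observed genus-mixed clades: 0
#>   null mean: 3.85 over 10000 permutations
#>   p-value: 9.999e-05
```

No clade mixes *Turris* and *Purpuraturris* records (statistic 0), while
random genus labels mix 3.85 clades on average; the add-one-corrected
permutation p-value is 1/10001. The printed report carries the caveat
that absence from the sampled transcriptomes is not proof of absence in
the genus.

End-to-end, with synthetic data:

```r
cfg <- run_config(seed = 1, n_species = 13, n_genes = 66,
                  discordance_rate = 0)
res <- run_pipeline(cfg, "run1")   # writes trees/, tables/, report.txt
robinson_foulds(res$consensus, res$species_tree)   # 0 at zero discordance
```

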