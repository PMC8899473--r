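test_that("simulate_species_tree grows labelled Yule trees deterministically", {
  expect_error(simulate_species_tree(1, seed = 1), "at least 2")

  cherry <- simulate_species_tree(2, seed = 5)
  expect_equal(ape::Ntip(cherry), 2L)
  expect_setequal(cherry$tip.label, c("sp1", "sp2"))

  t1 <- simulate_species_tree(13, seed = 1)
  t2 <- simulate_species_tree(13, seed = 1)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(ape::Ntip(t1), 13L)
  expect_true(ape::is.binary(t1) && ape::is.rooted(t1))

  # regression: two fixed seeds give different topologies
  t3 <- simulate_species_tree(13, seed = 2)
  expect_gt(robinson_foulds(t1, t3), 0L)
})

test_that("simulate_gene_trees: zero discordance copies the species tree", {
  sp <- simulate_species_tree(8, seed = 3)
  gt <- simulate_gene_trees(sp, 66, discordance_rate = 0, seed = 4)
  expect_length(gt, 66L)
  expect_true(all(vapply(gt, robinson_foulds, integer(1), t2 = sp) == 0L))
})

test_that("full discordance on 4 leaves yields ~1/3 per resolved topology", {
  sp <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  gt <- simulate_gene_trees(sp, 3000, discordance_rate = 1, seed = 9,
                            jitter_sd = 0)
  key <- vapply(gt, function(t) bipartitions(t)$keys, character(1))
  freq <- table(key) / length(gt)
  expect_length(freq, 3L)
  expect_true(all(abs(freq - 1 / 3) <= 0.03))
})

test_that("evolve_sequences follows the Jukes-Cantor substitution law", {
  tr <- read_newick("(a:0,b:0);")
  aln <- evolve_sequences(tr, 200, seed = 2)
  expect_identical(aln$residues[1], aln$residues[2])

  # two leaves at distance 0.1: observed p within 3 SE of the closed form
  tr <- read_newick("(a:0.05,b:0.05);")
  L <- 20000L
  aln <- evolve_sequences(tr, L, seed = 7)
  p_obs <- p_distance(aln)["a", "b"]
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  expect_identical(evolve_sequences(tr, 50, seed = 3)$residues,
                   evolve_sequences(tr, 50, seed = 3)$residues)
  no_len <- ape::read.tree(text = "(a,b,c);")
  expect_error(evolve_sequences(no_len, 10, seed = 1), "branch lengths")
})

test_that("simulate_toxin_precursors respects the framework contract", {
  cfg <- simulation_config(n_toxins_per_species = 30, n_superfamilies = 3,
                           seed = 11)
  prec <- simulate_toxin_precursors(c("spA", "spB"), cfg)
  expect_equal(nrow(prec), 60L)

  # every mature peptide carries exactly the six framework cysteines
  n_cys <- vapply(prec$mature, function(m) extract_framework(m)$n_cys,
                  integer(1))
  expect_true(all(n_cys == 6L))

  # cysteine indices identical within a superfamily, across species
  for (sf in unique(prec$superfamily)) {
    sub <- prec[prec$superfamily == sf, ]
    pos <- lapply(sub$mature, function(m) extract_framework(m)$cys_positions)
    expect_length(unique(pos), 1L)
  }

  # pairwise signal identity >= 90% within a superfamily
  for (sf in unique(prec$superfamily)) {
    sub <- prec[prec$superfamily == sf, ]
    sig <- strsplit(sub$signal, "")
    ref <- sig[[1]]
    ident <- vapply(sig, function(s) mean(s == ref), numeric(1))
    expect_true(all(ident >= 0.9))
  }

  # region boundaries reconstruct the precursor
  expect_true(all(prec$signal_end == nchar(prec$signal)))
  expect_true(all(prec$pro_end == nchar(prec$signal) + nchar(prec$pro)))
  expect_true(all(prec$total_length ==
                    nchar(paste0(prec$signal, prec$pro, prec$mature))))

  # forced loop length propagates to the extractor
  cfg1 <- simulation_config(loop_range = c(6L, 6L), seed = 2,
                            n_toxins_per_species = 10)
  prec1 <- simulate_toxin_precursors("spA", cfg1)
  loop1 <- vapply(prec1$mature, function(m) extract_framework(m)$loops[1],
                  integer(1))
  expect_true(all(loop1 == 6L))

  bad <- simulation_config(seed = 1)
  bad$framework_pattern <- "C-X-C"
  expect_error(simulate_toxin_precursors("spA", bad), "framework_pattern")
})

test_that("simulate_expression normalizes to TPM and honors planted folds", {
  cfg <- simulation_config(seed = 5)
  contigs <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 5),
    contig_id = paste0("c", 1:10),
    category = rep(c("hkg", "hkg", "hkg", "toxin", "toxin"), 2),
    stringsAsFactors = FALSE
  )
  expr <- simulate_expression(contigs, cfg, seed = 5,
                              planted_fold = c(c4 = 8))
  sums <- tapply(expr$tpm, expr$sample_id, sum)
  expect_true(all(abs(sums - 1e6) < 1e6 * 1e-6))

  hkg1 <- expr$tpm[expr$sample_id == "s1" & expr$category == "hkg"]
  fold <- hkg_fold_change(expr$tpm[expr$contig_id == "c4"], hkg1)
  expect_equal(fold, 3, tolerance = 1e-12)

  single <- simulate_expression(contigs[1, ], cfg, seed = 1)
  expect_equal(single$tpm, 1e6)

  expect_identical(simulate_expression(contigs, cfg, seed = 9)$tpm,
                   simulate_expression(contigs, cfg, seed = 9)$tpm)
  expect_error(simulate_expression(contigs[0, ], cfg, seed = 1), "empty")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_species_tree(5, seed = 99))
  expect_identical(.Random.seed, before)
})
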