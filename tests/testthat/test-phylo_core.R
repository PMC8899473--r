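test_that("p_distance counts mismatches with pairwise deletion", {
  aln <- c(a = "ACGT", b = "ACGT")
  expect_equal(p_distance(aln)["a", "b"], 0)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
  expect_equal(p_distance(c(a = "AC-T", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "ACNT", b = "ACGA"))["a", "b"], 1 / 3)
  expect_error(p_distance(c(a = "--", b = "AC")), "no comparable sites")
  expect_error(p_distance(c(a = "AC", b = "ACG")), "not aligned")
  # protein mode: N is a residue, X is missing
  expect_equal(p_distance(c(a = "NX", b = "ND"), mode = "protein")["a", "b"], 0)
})

test_that("jc_correct matches the closed form and flags saturation", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.3), -0.75 * log(0.6))
  expect_equal(jc_correct(0.3), 0.38311921, tolerance = 1e-7)
  expect_error(jc_correct(0.75), "saturated")
  expect_equal(jc_correct(0.8, cap = TRUE), jc_correct(0.74999))
})

test_that("neighbor_joining: 3-taxon closed form and determinism on ties", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # terminal branch to A = (d(A,B) + d(A,C) - d(B,C)) / 2 = 1
  bA <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(bA, 1)
  bB <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "B")]
  expect_equal(bB, 2)

  eq <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(eq) <- 0
  t1 <- neighbor_joining(eq)
  t2 <- neighbor_joining(eq)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(length(bipartitions(t1)$keys), 2L)  # resolved

  asym <- d; asym[1, 2] <- 10
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("neighbor_joining is exact on additive matrices (n = 4..8)", {
  for (n in 4:8) {
    for (rep in 1:3) {
      tr <- random_additive_tree(n, seed = n * 100 + rep)
      d <- ape::cophenetic.phylo(tr)
      est <- neighbor_joining(d)
      expect_equal(robinson_foulds(est, tr), 0L)
      # branch lengths recovered: path-length matrix reproduced
      d_est <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
      expect_equal(d_est, d, tolerance = 1e-8)
    }
  }
})

test_that("enumeration oracle: the NJ topology is the unique additive fit", {
  skip_if_not_installed("phangorn")
  for (n in 5:6) {
    tr <- random_additive_tree(n, seed = 17 + n)
    d <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(d)
    all_tops <- phangorn::allTrees(n, rooted = FALSE,
                                   tip.label = rownames(d))
    res <- vapply(all_tops, oracle_ls_residual, numeric(1), d = d)
    zero <- which(res < 1e-8)
    expect_length(zero, 1L)
    expect_equal(robinson_foulds(all_tops[[zero]], est), 0L)
  }
})

test_that("midpoint_root splits the diameter in half", {
  tr <- read_newick("(a:1,b:3);")
  mp <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(mp)
  expect_equal(unname(depths[1:2]), c(2, 2))

  for (seed in 1:10) {
    tr <- random_additive_tree(10, seed = 400 + seed)
    mp <- midpoint_root(tr)
    expect_true(ape::is.rooted(mp))
    diam <- oracle_diameter(tr)
    depths <- ape::node.depth.edgelength(mp)[1:ape::Ntip(mp)]
    # the deepest leaf is at exactly half the diameter
    expect_equal(max(depths), diam / 2, tolerance = 1e-9)
    # the two root subtrees reach equal depth
    root_kids <- mp$edge[mp$edge[, 1] == ape::Ntip(mp) + 1L, 2]
    expect_length(root_kids, 2L)
    # unrooted topology unchanged
    expect_equal(robinson_foulds(mp, tr), 0L)
  }

  # invariant to input leaf order
  tr <- random_additive_tree(10, seed = 31)
  perm <- read_newick(write_newick(ape::rotateConstr(tr,
                                                     sort(tr$tip.label))))
  a <- midpoint_root(tr)
  b <- midpoint_root(perm)
  expect_equal(robinson_foulds(a, b), 0L)
  expect_equal(sort(ape::node.depth.edgelength(a)[1:10]),
               sort(ape::node.depth.edgelength(b)[1:10]),
               tolerance = 1e-9)

  no_len <- ape::read.tree(text = "(a,b,c);")
  expect_error(midpoint_root(no_len), "branch lengths")
})

test_that("bipartitions counts non-trivial splits", {
  expect_length(bipartitions(read_newick("((a,b),(c,d));"))$keys, 1L)
  expect_length(bipartitions(read_newick("(a,b,c,d);"))$keys, 0L)
  for (n in 4:8) {
    tr <- random_additive_tree(n, seed = 600 + n)
    expect_length(bipartitions(tr)$keys, n - 3L)
    expect_setequal(bipartitions(tr)$keys, oracle_split_keys(tr))
  }
})

test_that("consensus_with_support reproduces frequencies and topologies", {
  trees <- list(read_newick("((a,b),(c,(d,e)));"),
                read_newick("((a,b),(d,(c,e)));"),
                read_newick("((a,c),(b,(d,e)));"))
  cons <- consensus_with_support(trees)
  supp <- attr(cons, "split_support")
  expect_equal(unname(supp[["c|d|e"]]), 2 / 3)  # canonical side of {a,b}
  expect_true("0.67" %in% cons$node.label)

  same <- replicate(4, read_newick("((a,b),((c,d),e));"), simplify = FALSE)
  cons <- consensus_with_support(same)
  expect_equal(robinson_foulds(cons, same[[1]]), 0L)
  expect_true(all(attr(cons, "split_support") == 1))

  bad <- list(read_newick("((a,b),(c,d));"), read_newick("((a,b),(c,e));"))
  expect_error(consensus_with_support(bad), "symmetric")
})

test_that("strict majority consensus equals brute-force counting", {
  for (case in 1:8) {
    set.seed(700 + case)
    n_trees <- sample(2:5, 1)
    trees <- lapply(seq_len(n_trees), function(i)
      random_additive_tree(6, seed = 700 + case * 10 + i))
    cons <- consensus_with_support(trees, greedy = FALSE)
    expected <- oracle_majority_splits(trees)
    expect_setequal(bipartitions(cons)$keys, names(expected))
    supp <- attr(cons, "split_support")
    expect_equal(supp[names(expected)], expected, tolerance = 1e-12)
  }
})

test_that("greedy consensus adds compatible minority splits by frequency", {
  trees <- list(read_newick("((a,b),((c,d),e));"),
                read_newick("((a,b),((c,e),d));"),
                read_newick("(((a,b),c),(d,e));"))
  strict <- consensus_with_support(trees, greedy = FALSE)
  greedy <- consensus_with_support(trees, greedy = TRUE)
  expect_true(length(bipartitions(greedy)$keys) >=
                length(bipartitions(strict)$keys))
  # every strict split survives in the greedy tree
  expect_true(all(bipartitions(strict)$keys %in% bipartitions(greedy)$keys))
})

test_that("robinson_foulds matches hand counts and the binary maximum", {
  t1 <- read_newick("((a,b),(c,d));")
  expect_equal(robinson_foulds(t1, t1), 0L)
  t2 <- read_newick("((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t2), 2L)

  skip_if_not_installed("phangorn")
  tops <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
  rf <- outer(seq_along(tops), seq_along(tops),
              Vectorize(function(i, j) robinson_foulds(tops[[i]], tops[[j]])))
  expect_equal(max(rf), 2L * (5L - 3L))
  expect_true(all(diag(rf) == 0L))
})

test_that("gene_tree_summary reports one row per gene", {
  sp <- simulate_species_tree(6, seed = 2)
  gt <- simulate_gene_trees(sp, 5, 0.5, seed = 3)
  cons <- consensus_with_support(gt)
  s <- gene_tree_summary(gt, cons)
  expect_equal(nrow(s), 5L)
  expect_true(all(s$n_taxa == 6L))
  expect_true(all(s$rf_to_consensus >= 0L))
})
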