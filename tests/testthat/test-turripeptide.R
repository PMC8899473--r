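fixture <- read_toxin_table()

test_that("extract_framework reports positions, loops and terminals", {
  tba93 <- fixture$mature[fixture$toxin_name == "Tba9.3"]
  p <- extract_framework(tba93)
  expect_equal(p$cys_positions, c(3L, 10L, 15L, 28L, 32L, 39L))
  expect_equal(p$loops, c(6L, 4L, 12L, 3L, 6L))
  expect_equal(p$n_cys, 6L)
  # reconstruction identity
  expect_equal(p$nterm_len + sum(p$loops) + p$n_cys + p$cterm_len, p$length)

  thd91 <- fixture$mature[fixture$toxin_name == "Thd9.1"]
  expect_equal(extract_framework(thd91)$loops[1], 1L)

  expect_error(extract_framework("ADEF"), "no framework")
  expect_error(extract_framework("ac"), "sanitized")
})

test_that("framework reconstruction holds on random sanitized strings", {
  set.seed(99)
  for (i in 1:50) {
    s <- paste(sample(c(LETTERS), sample(5:60, 1), replace = TRUE),
               collapse = "")
    n_c <- lengths(regmatches(s, gregexpr("C", s)))
    if (n_c < 2) next
    p <- extract_framework(s)
    expect_equal(p$nterm_len + sum(p$loops) + p$n_cys + p$cterm_len,
                 nchar(s))
    expect_length(p$loops, p$n_cys - 1L)
  }
})

test_that("framework_census finds the fixture's mode, loops and outlier", {
  cen <- framework_census(fixture)
  expect_equal(cen$modal_n_cys, 6L)
  expect_equal(cen$clade_loop1[["I"]], 6L)
  expect_equal(cen$clade_loop1[["II"]], 6L)
  expect_equal(cen$clade_loop1[["III"]], 1L)
  expect_equal(cen$clade_loop1[["IV"]], 1L)
  # Tba9.4 carries a non-modal cysteine count and must be flagged, never
  # silently corrected
  expect_true("Tba9.4" %in% cen$outliers$toxin_name)
  expect_equal(cen$table$n_cys[cen$table$toxin_name == "Tba9.4"], 5L)
})

test_that("consensus_motif follows the threshold rules", {
  r <- make_records(paste0("t", 1:5), rep("ACPENC", 5))
  expect_equal(consensus_motif(r, 1), "PEN")

  # 50/50 tie lists both alphabetically
  r <- make_records(paste0("t", 1:4), c("CAC", "CAC", "CGC", "CGC"))
  expect_equal(consensus_motif(r, 1), "(A/G)")

  # no residue reaching the include threshold gives X
  r <- make_records(paste0("t", 1:5),
                    c("CAC", "CDC", "CEC", "CFC", "CGC"))
  expect_equal(consensus_motif(r, 1), "X")

  # deviating loop lengths are named
  r <- make_records(c("short", "long1", "long2"),
                    c("CAC", "CAAC", "CAAC"))
  expect_error(consensus_motif(r, 1), "short")

  expect_error(consensus_motif(make_records(character(), character()), 1),
               "empty")
})

test_that("clade I+II loop-1 motif has six positions anchored on E/N", {
  sub <- fixture[fixture$clade %in% c("I", "II"), ]
  expect_equal(nrow(sub), 17L)
  motif <- consensus_motif(sub, 1)
  segs <- regmatches(motif, gregexpr("\\([A-Z/]+\\)|[A-Z]", motif))[[1]]
  expect_length(segs, 6L)
  expect_true(grepl("E", segs[2]))  # position 2 dominated by E
  expect_equal(segs[3], "N")        # position 3 is N
  expect_equal(segs[6], "X")        # hypervariable last position
})

test_that("assign_name follows the code.index convention and variants", {
  expect_equal(assign_name("Turris babylonia", 9,
                           c("Tba9.1", "Tba9.2")), "Tba9.3")
  expect_equal(assign_name("Purpuraturris cryptorrhaphe",
                           variant_of = "Pcr9.4"), "Pcr9.4ii")
  expect_equal(assign_name("Purpuraturris undosa", 9, character()), "Pun9.1")
  # Pna preferred over Pnd for P. nadaensis
  expect_equal(assign_name("Purpuraturris nadaensis", 9, character()),
               "Pna9.1")
  expect_error(assign_name("Conus magus", 9, character()), "unknown species")
  expect_equal(assign_name("Conus magus", 9, character(), code = "Cma"),
               "Cma9.1")
  # never collides
  existing <- c("Tba9.1", "Tba9.3", "Tba9.10")
  nm <- assign_name("Turris babylonia", 9, existing)
  expect_false(nm %in% existing)
  expect_equal(nm, "Tba9.11")
})

test_that("deduplicate groups identical matures, flags cross-species", {
  dd <- deduplicate(fixture)
  trio <- dd$summary[grepl("Pna9.10", dd$summary$toxin_names), ]
  expect_equal(trio$toxin_names, "Pna9.10,Pna9.10ii,Pun9.4")
  expect_true(trio$cross_species)
  expect_equal(trio$size, 3L)

  # idempotent: grouping again yields the identical partition
  dd2 <- deduplicate(fixture)
  expect_identical(dd$summary, dd2$summary)

  distinct <- make_records(c("a", "b"), c("CAC", "CGC"))
  expect_true(all(deduplicate(distinct)$summary$size == 1L))
})

test_that("clade_partition cuts a rooted tree into up to four clades", {
  balanced <- read_newick(
    "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  part <- clade_partition(balanced)
  expect_setequal(names(part), letters[1:8])
  expect_equal(as.integer(sort(table(part))), c(2L, 2L, 2L, 2L))
  expect_length(unique(part), 4L)
  # leaves of one cherry share a label
  expect_equal(part[["a"]], part[["b"]])

  caterpillar <- read_newick("(a:1,(b:1,(c:1,(d:1,e:1):1):1):1);")
  part <- clade_partition(caterpillar)
  expect_true(length(attr(part, "degenerate")) > 0L)
  expect_lt(length(unique(part)), 4L)

  unrooted <- read_newick("(a:1,b:1,(c:1,d:1):1);")
  expect_error(clade_partition(unrooted), "rooted")
})

test_that("fixture peptide tree clade recovery is reported, not asserted", {
  uniq <- fixture[!duplicated(fixture$mature), ]
  tr <- mature_peptide_tree(uniq)
  expect_true(ape::is.rooted(tr))
  expect_equal(ape::Ntip(tr), nrow(uniq))
  part <- clade_partition(tr)
  ref <- stats::setNames(uniq$clade, uniq$toxin_name)
  conc <- clade_concordance(part, ref)
  expect_true(conc$agreement >= 0 && conc$agreement <= 1)
  expect_equal(sum(conc$table), nrow(uniq))
})

test_that("species_codes covers every fixture species and genus", {
  codes <- species_codes()
  expect_true(all(fixture$species %in% codes$species))
  expect_setequal(unique(fixture$genus), c("Turris", "Purpuraturris"))
  # fixture toxin names start with a code mapped to the right species
  prefix <- substr(fixture$toxin_name, 1, 3)
  hit <- match(prefix, codes$code)
  expect_false(anyNA(hit))
  expect_identical(codes$species[hit], fixture$species)
})
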