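# Synthetic-data generators: species trees, discordant gene trees,
# Jukes-Cantor sequence evolution, toxin precursor repertoires, contig
# annotation tables and expression tables.
#
# The generators emulate the statistical structure the downstream analysis
# assumes -- a shared housekeeping-gene (HKG) panel across venom-gland
# transcriptome samples, gene trees that disagree with the species tree at
# a tunable rate, precursors with conserved signal regions and hypervariable
# mature peptides whose cysteine scaffold is fixed within a superfamily --
# so every pipeline stage is testable without external downloads. All
# generators are pure functions of (inputs, seed).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_NO_CYS <- setdiff(AA20, "C")
DNA4 <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Bundles the knobs shared by the generators. Defaults reflect the scale
#' of a small conoidean transcriptome study: 13 species, a panel of 66
#' housekeeping genes, roughly 200 venom peptides per species, and mature
#' peptides on a six-cysteine scaffold.
#'
#' @param n_species number of species.
#' @param n_genes number of housekeeping genes (gene trees).
#' @param discordance_rate per-internal-edge probability that a gene tree
#'   re-draws the local topology; in `[0, 1]`.
#' @param seq_length bases per gene alignment.
#' @param mutation_rate multiplier applied to branch lengths (expected
#'   substitutions per site per unit branch length).
#' @param n_toxins_per_species venom peptides simulated per species.
#' @param framework_pattern cysteine framework token, e.g. `"C-C-C-C-C-C"`.
#' @param loop_range inclusive range of inter-cysteine loop lengths.
#' @param n_superfamilies number of simulated precursor superfamilies.
#' @param signal_length signal-peptide length in residues.
#' @param signal_sub_prob per-site substitution probability applied to a
#'   superfamily's signal template (capped so that within-superfamily
#'   signal identity stays at or above 90 percent).
#' @param expr_meanlog,expr_sdlog log-normal parameters for raw contig
#'   abundances before TPM normalization.
#' @param seed integer seed.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_species = 13L, n_genes = 66L,
                              discordance_rate = 0.2, seq_length = 500L,
                              mutation_rate = 1, n_toxins_per_species = 200L,
                              framework_pattern = "C-C-C-C-C-C",
                              loop_range = c(1L, 12L),
                              n_superfamilies = 4L, signal_length = 22L,
                              signal_sub_prob = 0.02,
                              expr_meanlog = log(50), expr_sdlog = 1.5,
                              seed = 1L) {
  stopifnot(is_count(n_species, 2), is_count(n_genes), is_count(seq_length),
            is_count(n_toxins_per_species), is_count(n_superfamilies),
            is_count(signal_length, 5))
  if (!is.numeric(discordance_rate) || discordance_rate < 0 ||
      discordance_rate > 1) {
    stop_("`discordance_rate` must be in [0, 1]")
  }
  if (length(loop_range) != 2L || loop_range[1] > loop_range[2] ||
      loop_range[1] < 0) {
    stop_("`loop_range` must be a non-decreasing pair of non-negative counts")
  }
  structure(list(
    n_species = as.integer(n_species), n_genes = as.integer(n_genes),
    discordance_rate = discordance_rate, seq_length = as.integer(seq_length),
    mutation_rate = mutation_rate,
    n_toxins_per_species = as.integer(n_toxins_per_species),
    framework_pattern = framework_pattern,
    loop_range = as.integer(loop_range),
    n_superfamilies = as.integer(n_superfamilies),
    signal_length = as.integer(signal_length),
    signal_sub_prob = signal_sub_prob,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a species tree under a pure-birth (Yule) process
#'
#' Exponential waiting times between speciation events at per-lineage rate
#' `birth_rate`; leaves are labelled `sp1 .. spN`.
#'
#' @param n_species number of extant species (at least 2).
#' @param seed integer seed.
#' @param birth_rate per-lineage speciation rate.
#' @return rooted binary ape `phylo` with branch lengths.
#' @export
simulate_species_tree <- function(n_species, seed, birth_rate = 1) {
  if (!is_count(n_species, 2)) stop_("`n_species` must be at least 2")
  with_seed(seed, {
    birth <- c(0, 0)            # birth time per node id
    children <- list(NULL, NULL)
    split_time <- c(NA_real_, NA_real_)
    active <- c(1L, 2L)
    t <- 0
    while (length(active) < n_species) {
      t <- t + stats::rexp(1, rate = birth_rate * length(active))
      pick <- active[sample.int(length(active), 1L)]
      id1 <- length(birth) + 1L
      id2 <- length(birth) + 2L
      birth <- c(birth, t, t)
      children <- c(children, list(NULL), list(NULL))
      split_time[pick] <- t
      split_time <- c(split_time, NA_real_, NA_real_)
      children[[pick]] <- c(id1, id2)
      active <- c(setdiff(active, pick), id1, id2)
    }
    t_end <- t + stats::rexp(1, rate = birth_rate * n_species)
    labels <- character(length(birth))
    labels[active] <- paste0("sp", seq_len(n_species))
    nwk <- function(id) {
      if (is.null(children[[id]])) {
        paste0(labels[id], ":", fmt_len(t_end - birth[id]))
      } else {
        kids <- vapply(children[[id]], nwk, character(1))
        paste0("(", paste(kids, collapse = ","), "):",
               fmt_len(split_time[id] - birth[id]))
      }
    }
    txt <- paste0("(", nwk(1L), ",", nwk(2L), ");")
    ape::read.tree(text = txt)
  })
}

# One pass of local topology perturbation: for each internal edge of the
# unrooted tree, with probability `rate` the resolution around that edge is
# re-drawn uniformly from the three possibilities (so the expected result
# of rate = 1 on a 4-leaf tree is each resolved topology at frequency 1/3).
perturb_topology <- function(tree, rate) {
  tr <- ape::unroot(tree)
  ntip <- ape::Ntip(tr)
  internal <- which(tr$edge[, 2] > ntip)
  for (e in internal) {
    if (stats::runif(1) >= rate) next
    r <- sample.int(3L, 1L)
    if (r == 1L) next
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    u_kids <- which(tr$edge[, 1] == u & tr$edge[, 2] != v)
    v_kids <- which(tr$edge[, 1] == v)
    if (!length(u_kids) || length(v_kids) < 2L) next
    e_uw <- u_kids[1]
    e_vc <- v_kids[r - 1L]
    # swap the two subtrees, keeping each subtree's pendant length
    tmp_child <- tr$edge[e_uw, 2]
    tmp_len <- tr$edge.length[e_uw]
    tr$edge[e_uw, 2] <- tr$edge[e_vc, 2]
    tr$edge.length[e_uw] <- tr$edge.length[e_vc]
    tr$edge[e_vc, 2] <- tmp_child
    tr$edge.length[e_vc] <- tmp_len
  }
  ape::read.tree(text = ape::write.tree(tr))
}

#' Simulate discordant gene trees
#'
#' Each gene tree starts from the species tree; around every internal edge
#' of the unrooted topology, with probability `discordance_rate` the local
#' resolution is re-drawn uniformly among the three alternatives (a random
#' nearest-neighbor interchange that may keep the original resolution).
#' Branch lengths are then jittered multiplicatively (log-normal,
#' `sdlog = jitter_sd`). All gene trees keep the full leaf set.
#'
#' @param species_tree rooted binary ape `phylo` with branch lengths.
#' @param n_genes number of gene trees.
#' @param discordance_rate per-edge perturbation probability in `[0, 1]`.
#' @param seed integer seed.
#' @param jitter_sd sdlog of the multiplicative branch-length jitter.
#' @return list of ape `phylo` objects of length `n_genes`.
#' @export
simulate_gene_trees <- function(species_tree, n_genes, discordance_rate,
                                seed, jitter_sd = 0.1) {
  stopifnot(inherits(species_tree, "phylo"), is_count(n_genes))
  if (discordance_rate < 0 || discordance_rate > 1) {
    stop_("`discordance_rate` must be in [0, 1]")
  }
  with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      tr <- perturb_topology(species_tree, discordance_rate)
      if (!is.null(tr$edge.length) && jitter_sd > 0) {
        tr$edge.length <- tr$edge.length *
          exp(stats::rnorm(length(tr$edge.length), 0, jitter_sd))
      }
      tr
    })
  })
}

#' Evolve sequences along a tree under the Jukes-Cantor model
#'
#' The root sequence is uniform over A, C, G, T; along each branch of
#' length `b` (times `mutation_rate`), every site substitutes to a
#' uniformly chosen different base with probability
#' `(3/4) (1 - exp(-4 b / 3))`. Output is a gap-free alignment with one
#' record per leaf.
#'
#' @param tree ape `phylo` with branch lengths in expected
#'   substitutions/site.
#' @param seq_length sites to simulate.
#' @param mutation_rate branch-length multiplier.
#' @param seed integer seed.
#' @return data frame with columns `id`, `description`, `residues`.
#' @export
evolve_sequences <- function(tree, seq_length, mutation_rate = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), is_count(seq_length))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop_("tree is missing branch lengths")
  }
  with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- ape::Ntip(tr)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tr$Nnode)
    base_idx <- sample.int(4L, seq_length, replace = TRUE)
    seqs[[root]] <- base_idx
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      b <- tr$edge.length[e] * mutation_rate
      prob <- 0.75 * (1 - exp(-4 * b / 3))
      s <- seqs[[p]]
      hit <- which(stats::runif(seq_length) < prob)
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
      }
      seqs[[ch]] <- s
    }
    res <- vapply(seq_len(ntip), function(i) {
      paste(DNA4[seqs[[i]]], collapse = "")
    }, character(1))
    data.frame(id = tr$tip.label, description = "", residues = res,
               stringsAsFactors = FALSE)
  })
}

random_aa <- function(n, alphabet = AA20) {
  paste(alphabet[sample.int(length(alphabet), n, replace = TRUE)],
        collapse = "")
}

mutate_signal <- function(template, sub_prob) {
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  # cap divergence from the template at 5 percent so that any two signals
  # of the superfamily stay at or above 90 percent pairwise identity
  max_subs <- floor(0.05 * length(ch))
  n_subs <- min(stats::rbinom(1, length(ch), sub_prob), max_subs)
  if (n_subs > 0) {
    pos <- sample.int(length(ch), n_subs)
    ch[pos] <- vapply(pos, function(i) {
      sample(setdiff(AA20, ch[i]), 1L)
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Simulate toxin precursor repertoires
#'
#' Per species, `n_toxins_per_species` precursors organized as signal +
#' pro-region + mature peptide. Within a simulated superfamily the signal
#' is drawn from a shared template with low per-site substitution
#' probability (identity at least 90 percent across species) and the
#' cysteine positions of the mature region are identical; all other mature
#' positions are i.i.d. over the 19 non-cysteine residues, so every mature
#' peptide carries exactly the framework's cysteines.
#'
#' @param species_list character vector of species tokens.
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return data frame with one row per precursor: `species`, `toxin_id`,
#'   `superfamily`, `signal`, `pro`, `mature`, and 0-based half-open
#'   region boundaries `signal_start`, `signal_end`, `pro_end`,
#'   `total_length`.
#' @export
simulate_toxin_precursors <- function(species_list, config,
                                      seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            is.character(species_list), length(species_list) >= 1L)
  toks <- strsplit(config$framework_pattern, "-", fixed = TRUE)[[1]]
  if (!length(toks) || !all(toks == "C")) {
    stop_("`framework_pattern` must be dash-separated 'C' tokens, e.g. ",
          "'C-C-C-C-C-C'")
  }
  n_cys <- length(toks)
  lr <- config$loop_range
  if (lr[1] > lr[2] || lr[1] < 0) stop_("loop-length range infeasible")
  with_seed(seed, {
    sf_profiles <- lapply(seq_len(config$n_superfamilies), function(s) {
      list(
        signal = paste0("M", random_aa(config$signal_length - 1L)),
        loops = {
          lens <- seq(lr[1], lr[2])
          lens[sample.int(length(lens), n_cys - 1L, replace = TRUE)]
        },
        nterm = sample(1:3, 1L),
        cterm = sample(0:3, 1L)
      )
    })
    rows <- vector("list", length(species_list) * config$n_toxins_per_species)
    k <- 0L
    for (sp in species_list) {
      for (tox in seq_len(config$n_toxins_per_species)) {
        sf <- sample.int(config$n_superfamilies, 1L)
        prof <- sf_profiles[[sf]]
        signal <- mutate_signal(prof$signal, config$signal_sub_prob)
        pro <- random_aa(sample(8:25, 1L))
        segs <- c(random_aa(prof$nterm, AA_NO_CYS))
        for (l in prof$loops) {
          segs <- c(segs, "C", if (l > 0) random_aa(l, AA_NO_CYS) else "")
        }
        segs <- c(segs, "C", if (prof$cterm > 0)
          random_aa(prof$cterm, AA_NO_CYS) else "")
        mature <- paste(segs, collapse = "")
        k <- k + 1L
        rows[[k]] <- data.frame(
          species = sp,
          toxin_id = sprintf("%s_t%03d", sp, tox),
          superfamily = paste0("SF", sf),
          signal = signal, pro = pro, mature = mature,
          signal_start = 0L,
          signal_end = nchar(signal),
          pro_end = nchar(signal) + nchar(pro),
          total_length = nchar(signal) + nchar(pro) + nchar(mature),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a per-sample contig annotation table
#'
#' Emulates the blast-annotation table the HKG-panel stage consumes:
#' `n_shared` housekeeping genes present in every sample with strong hits
#' (e-value well below 1e-4, half flagged ribosomal), `n_private`
#' sample-specific genes with strong hits, plus weak decoy hits
#' (e-value at or above 1e-4) for genes present in all samples -- those
#' must be removed by the e-value filter before the intersection.
#'
#' @param n_samples number of samples.
#' @param n_shared number of shared housekeeping genes (ground truth panel
#'   size).
#' @param n_private private genes per sample.
#' @param seed integer seed.
#' @param n_decoy number of weak-hit decoy genes shared by all samples.
#' @return data frame with columns `sample_id`, `contig_id`, `gene_label`,
#'   `e_value`, `tpm`, `is_ribosomal`.
#' @export
simulate_annotation_table <- function(n_samples, n_shared = 66L,
                                      n_private = 5L, seed = 1L,
                                      n_decoy = 3L) {
  stopifnot(is_count(n_samples), is_count(n_shared), n_private >= 0,
            n_decoy >= 0)
  shared <- sprintf("HKG%03d", seq_len(n_shared))
  ribo <- stats::setNames(seq_len(n_shared) <= n_shared / 2, shared)
  decoy <- if (n_decoy > 0) sprintf("DECOY%02d", seq_len(n_decoy)) else
    character()
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_samples)) {
      sid <- paste0("sample", s)
      cid <- 0L
      add <- function(gene, e_value, is_ribo) {
        cid <<- cid + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sid,
          contig_id = sprintf("s%d_c%04d", s, cid),
          gene_label = gene, e_value = e_value,
          tpm = stats::rlnorm(1, log(50), 1),
          is_ribosomal = is_ribo, stringsAsFactors = FALSE
        )
      }
      for (g in shared) {
        n_contigs <- sample(1:2, 1L)
        for (i in seq_len(n_contigs)) {
          add(g, 10^(-stats::runif(1, 5, 50)), ribo[[g]])
        }
      }
      for (p in seq_len(n_private)) {
        add(sprintf("PRIV_%s_%02d", sid, p), 10^(-stats::runif(1, 5, 30)),
            FALSE)
      }
      for (g in decoy) {
        add(g, 10^(-stats::runif(1, 0, 4)) + 1e-4, FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate per-contig expression (TPM)
#'
#' Raw abundances are log-normal; per sample they are scaled so TPM sums
#' to one million. `planted_fold` plants contigs at a fixed multiple of
#' the mean raw abundance of that sample's HKG-category contigs, so the
#' downstream HKG-relative log2 fold change is known exactly (a multiple
#' of 8 yields a fold change of 3).
#'
#' @param contigs data frame with columns `sample_id`, `contig_id`,
#'   `category` (`"hkg"`, `"toxin"` or `"other"`).
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param planted_fold optional named numeric: `contig_id` -> multiple of
#'   the sample's mean HKG raw abundance.
#' @return data frame with columns `sample_id`, `contig_id`, `category`,
#'   `tpm`; each sample's TPM sums to 1e6.
#' @export
simulate_expression <- function(contigs, config, seed = config$seed,
                                planted_fold = NULL) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(contigs))
  if (!nrow(contigs)) stop_("empty contig list")
  need <- c("sample_id", "contig_id", "category")
  if (!all(need %in% names(contigs))) {
    stop_("`contigs` needs columns: ", paste(need, collapse = ", "))
  }
  with_seed(seed, {
    raw <- stats::rlnorm(nrow(contigs), config$expr_meanlog,
                         config$expr_sdlog)
    if (!is.null(planted_fold)) {
      for (cid in names(planted_fold)) {
        i <- which(contigs$contig_id == cid)
        if (!length(i)) stop_("planted contig not found: ", cid)
        for (ii in i) {
          same <- contigs$sample_id == contigs$sample_id[ii] &
            contigs$category == "hkg"
          if (!any(same)) stop_("no HKG contigs in sample ",
                                contigs$sample_id[ii])
          raw[ii] <- planted_fold[[cid]] * mean(raw[same])
        }
      }
    }
    tpm <- numeric(nrow(contigs))
    for (sid in unique(contigs$sample_id)) {
      idx <- contigs$sample_id == sid
      tpm[idx] <- 1e6 * raw[idx] / sum(raw[idx])
    }
    data.frame(sample_id = contigs$sample_id, contig_id = contigs$contig_id,
               category = contigs$category, tpm = tpm,
               stringsAsFactors = FALSE)
  })
}
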