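# P-like turripeptide analysis: cysteine-framework extraction, loop
# metrics, census and consensus motifs, toxin nomenclature, deduplication
# and clade partitioning of a midpoint-rooted peptide tree.
#
# P-like turripeptides are turrid venom peptides with six cysteines in the
# arrangement of the Conus P-superfamily. The mature region is
# hypervariable except for the cysteines, so the framework (cysteine
# positions and the inter-cysteine "loops") is the natural classifier.

#' Species code table for turripeptide nomenclature
#'
#' Three-letter species codes used in toxin names (e.g. `Tba9.3`). Both
#' `Pna` and `Pnd` map to *Purpuraturris nadaensis*; `Pna` is preferred
#' when generating new names.
#'
#' @return data frame with columns `code`, `species`, `genus`,
#'   `preferred`.
#' @export
species_codes <- function() {
  x <- data.frame(
    code = c("Tba", "Tgd", "Thd", "Tnr", "Tsp", "Tdo",
             "Pcr", "Pcs", "Pna", "Pnd", "Pun"),
    species = c("Turris babylonia", "Turris guidopoppei", "Turris hidalgoi",
                "Turris normandavidsoni", "Turris spectabilis",
                "Turris dollyae", "Purpuraturris cryptorrhaphe",
                "Purpuraturris cristata", "Purpuraturris nadaensis",
                "Purpuraturris nadaensis", "Purpuraturris undosa"),
    preferred = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  x$genus <- sub("\\s.*$", "", x$species)
  x[, c("code", "species", "genus", "preferred")]
}

#' Load the packaged P-like turripeptide table
#'
#' The package ships a tab-separated table of predicted mature P-like
#' turripeptide sequences from nine *Turris* and *Purpuraturris* species
#' (32 records, clade labels I-IV). One cell of the published table
#' carries an invisible leading byte-order mark, preserved verbatim in
#' the fixture; sanitization removes it.
#'
#' @param path path to a toxin table; defaults to the packaged fixture.
#' @param sanitize sanitize mature sequences with [sanitize_residues()]
#'   (default `TRUE`).
#' @return data frame with columns `species`, `genus`, `toxin_name`,
#'   `clade`, `mature`.
#' @export
read_toxin_table <- function(path = turripep_fixture(), sanitize = TRUE) {
  x <- read_tsv(path)
  need <- c("species", "genus", "toxin_name", "clade", "mature_sequence")
  if (!all(need %in% names(x))) {
    stop_("toxin table needs columns: ", paste(need, collapse = ", "))
  }
  mature <- if (sanitize) sanitize_residues(x$mature_sequence) else
    x$mature_sequence
  out <- data.frame(species = x$species, genus = x$genus,
                    toxin_name = x$toxin_name, clade = x$clade,
                    mature = mature, stringsAsFactors = FALSE)
  bad_clade <- !(out$clade %in% c(roman_labels(4), ""))
  if (any(bad_clade)) {
    stop_("clade labels must be I-IV (or empty): ",
          paste(unique(out$clade[bad_clade]), collapse = ", "))
  }
  derived_genus <- sub("\\s.*$", "", out$species)
  if (any(derived_genus != out$genus)) {
    warning("genus column inconsistent with species for: ",
            paste(out$toxin_name[derived_genus != out$genus],
                  collapse = ", "), call. = FALSE)
  }
  out
}

#' Path of the packaged turripeptide fixture
#' @return file path of the tab-separated table shipped with the package.
#' @export
turripep_fixture <- function() {
  system.file("extdata", "turripeptides_table.tsv", package = "turripep",
              mustWork = TRUE)
}

#' Extract the cysteine framework of a mature peptide
#'
#' Reports 1-based cysteine positions, the residue counts strictly between
#' consecutive cysteines (loops), and the terminal segment lengths. The
#' identity `nterm + sum(loops) + n_cys + cterm == nchar(mature)` always
#' holds.
#'
#' @param mature sanitized amino-acid string with at least two cysteines.
#' @return object of class `framework_profile`: list with `n_cys`,
#'   `cys_positions`, `loops`, `nterm_len`, `cterm_len`, `length`.
#' @export
extract_framework <- function(mature) {
  stopifnot(is.character(mature), length(mature) == 1L)
  if (grepl("[^A-Z]", mature)) {
    stop_("mature sequence must be sanitized uppercase letters")
  }
  pos <- which(strsplit(mature, "", fixed = TRUE)[[1]] == "C")
  if (length(pos) < 2L) stop_("no framework: fewer than 2 cysteines")
  structure(list(
    n_cys = length(pos),
    cys_positions = pos,
    loops = diff(pos) - 1L,
    nterm_len = pos[1] - 1L,
    cterm_len = nchar(mature) - pos[length(pos)],
    length = nchar(mature)
  ), class = "framework_profile")
}

#' @export
print.framework_profile <- function(x, ...) {
  cat("framework:", x$n_cys, "cysteines at",
      paste(x$cys_positions, collapse = ","),
      "| loops", paste(x$loops, collapse = "-"),
      "| nterm", x$nterm_len, "cterm", x$cterm_len, "\n")
  invisible(x)
}

#' Per-record framework table
#'
#' @param records toxin records ([read_toxin_table()] shape).
#' @return data frame with `toxin_name`, `species`, `genus`, `clade`,
#'   `n_cys`, `loop1`, `length`.
#' @export
framework_table <- function(records) {
  profs <- lapply(records$mature, extract_framework)
  data.frame(
    toxin_name = records$toxin_name, species = records$species,
    genus = records$genus, clade = records$clade,
    n_cys = vapply(profs, `[[`, integer(1), "n_cys"),
    loop1 = vapply(profs, function(p) p$loops[1], integer(1)),
    length = vapply(profs, `[[`, integer(1), "length"),
    stringsAsFactors = FALSE
  )
}

#' Cysteine-framework census
#'
#' Tabulates cysteine counts, reports the modal count, the unique loop-1
#' lengths per clade, and the outlier records whose cysteine count
#' differs from their clade's mode.
#'
#' @param records toxin records.
#' @return object of class `framework_census`: list with `counts` (table
#'   of n_cys), `modal_n_cys`, `clade_loop1` (list clade -> sorted unique
#'   loop-1 lengths), `outliers` (framework-table rows).
#' @export
framework_census <- function(records) {
  ft <- framework_table(records)
  counts <- table(ft$n_cys)
  modal <- as.integer(names(counts)[which.max(counts)])
  clades <- sort(unique(ft$clade))
  clade_loop1 <- lapply(stats::setNames(clades, clades), function(cl) {
    sort(unique(ft$loop1[ft$clade == cl]))
  })
  clade_mode <- vapply(clades, function(cl) {
    tab <- table(ft$n_cys[ft$clade == cl])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  names(clade_mode) <- clades
  outliers <- ft[ft$n_cys != clade_mode[ft$clade], , drop = FALSE]
  rownames(outliers) <- NULL
  structure(list(counts = counts, modal_n_cys = modal,
                 clade_loop1 = clade_loop1, clade_mode = clade_mode,
                 outliers = outliers, table = ft),
            class = "framework_census")
}

#' @export
print.framework_census <- function(x, ...) {
  cat("framework census over", nrow(x$table), "records\n")
  cat("  modal cysteine count:", x$modal_n_cys, "\n")
  for (cl in names(x$clade_loop1)) {
    cat("  clade", cl, "loop-1 length(s):",
        paste(x$clade_loop1[[cl]], collapse = ","), "\n")
  }
  if (nrow(x$outliers)) {
    cat("  outliers (n_cys != clade mode):",
        paste(x$outliers$toxin_name, collapse = ", "), "\n")
  }
  invisible(x)
}

loop_string <- function(mature, loop_index) {
  p <- extract_framework(mature)
  if (loop_index < 1L || loop_index > length(p$loops)) return(NA_character_)
  substr(mature, p$cys_positions[loop_index] + 1L,
         p$cys_positions[loop_index + 1L] - 1L)
}

#' Degenerate consensus motif of an inter-cysteine loop
#'
#' Builds a position-wise motif over the residues of loop `loop_index`
#' (the segment strictly between cysteines `loop_index` and
#' `loop_index + 1`). Per position: residues with frequency at or above
#' `include_threshold` are listed alphabetically in parentheses joined by
#' "/"; a single residue is written bare when it reaches
#' `dominance_threshold` and no other residue passes the include
#' threshold; "X" marks positions where no residue reaches the include
#' threshold.
#'
#' @param records toxin records; all must share the loop length at
#'   `loop_index` (deviants raise an error naming them).
#' @param loop_index 1-based loop number.
#' @param include_threshold minimum frequency for a residue to be listed
#'   (default 0.25).
#' @param dominance_threshold frequency at which a sole qualifying residue
#'   is written without parentheses (default 0.5).
#' @return motif string.
#' @export
consensus_motif <- function(records, loop_index, include_threshold = 0.25,
                            dominance_threshold = 0.5) {
  if (!nrow(records)) stop_("empty record set")
  loops <- vapply(records$mature, loop_string, character(1),
                  loop_index = loop_index, USE.NAMES = FALSE)
  if (anyNA(loops)) {
    stop_("record(s) lack loop ", loop_index, ": ",
          paste(records$toxin_name[is.na(loops)], collapse = ", "))
  }
  len <- unique(nchar(loops))
  if (length(len) != 1L) {
    mode_len <- as.integer(names(sort(table(nchar(loops)),
                                      decreasing = TRUE))[1])
    dev <- records$toxin_name[nchar(loops) != mode_len]
    stop_("loop ", loop_index, " lengths differ; deviants: ",
          paste(dev, collapse = ", "))
  }
  if (len == 0L) return("")
  mat <- matrix(unlist(strsplit(loops, "", fixed = TRUE)),
                nrow = length(loops), byrow = TRUE)
  segs <- vapply(seq_len(len), function(j) {
    freq <- table(mat[, j]) / nrow(mat)
    passers <- sort(names(freq)[freq >= include_threshold])
    if (!length(passers)) return("X")
    if (length(passers) == 1L && freq[[passers]] >= dominance_threshold) {
      return(passers)
    }
    paste0("(", paste(passers, collapse = "/"), ")")
  }, character(1))
  paste(segs, collapse = "")
}

#' Assign a toxin name
#'
#' Names follow the `<species code><framework number>.<index>` convention
#' (e.g. `Tba9.3`); a variant of an existing name gets the suffix `ii`
#' (e.g. `Pcr9.4ii` for a second precursor yielding the same or a
#' near-identical mature peptide).
#'
#' @param species binomial species name present in [species_codes()], or
#'   any species when `code` is supplied.
#' @param framework_number cysteine-framework number (default 9, the
#'   P-like framework).
#' @param existing_names character vector of names already in use.
#' @param variant_of existing name to derive an `ii` variant from.
#' @param code optional explicit species code overriding the lookup.
#' @return the new toxin name, guaranteed not to collide with
#'   `existing_names`.
#' @export
assign_name <- function(species, framework_number = 9L,
                        existing_names = character(), variant_of = NULL,
                        code = NULL) {
  if (!is.null(variant_of)) {
    nm <- paste0(variant_of, "ii")
    if (nm %in% existing_names) stop_("variant name already in use: ", nm)
    return(nm)
  }
  if (is.null(code)) {
    tab <- species_codes()
    hit <- tab[tab$species == species, , drop = FALSE]
    if (!nrow(hit)) {
      stop_("unknown species with no supplied code: ", species)
    }
    hit <- hit[order(!hit$preferred), , drop = FALSE]
    code <- hit$code[1]
  }
  pat <- paste0("^", code, framework_number, "\\.([0-9]+)")
  idx <- suppressWarnings(as.integer(sub(pat, "\\1",
    existing_names[grepl(pat, existing_names)])))
  nxt <- if (length(idx)) max(idx, na.rm = TRUE) + 1L else 1L
  paste0(code, framework_number, ".", nxt)
}

#' Group records sharing an identical mature sequence
#'
#' Partitions the records by exact mature-peptide string (after the
#' sanitization applied on input). Groups spanning more than one species
#' are flagged.
#'
#' @param records toxin records.
#' @return object of class `dedup_groups`: list with `groups` (list of
#'   record subsets) and `summary` (data frame: `group_id`, `size`,
#'   `toxin_names`, `species`, `cross_species`).
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records))
  idx <- split(seq_len(nrow(records)), records$mature)
  # deterministic order: decreasing group size, then first toxin name
  ord <- order(-vapply(idx, length, integer(1)),
               vapply(idx, function(i) min(records$toxin_name[i]),
                      character(1)))
  idx <- idx[ord]
  groups <- lapply(idx, function(i) {
    g <- records[i, , drop = FALSE]
    rownames(g) <- NULL
    g
  })
  summary <- data.frame(
    group_id = seq_along(groups),
    size = vapply(groups, nrow, integer(1)),
    toxin_names = vapply(groups, function(g)
      paste(sort(g$toxin_name), collapse = ","), character(1)),
    species = vapply(groups, function(g)
      paste(sort(unique(g$species)), collapse = ","), character(1)),
    cross_species = vapply(groups, function(g)
      length(unique(g$species)) > 1L, logical(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(groups = unname(groups), summary = summary),
            class = "dedup_groups")
}

#' @export
print.dedup_groups <- function(x, ...) {
  dup <- x$summary[x$summary$size > 1L, , drop = FALSE]
  cat("deduplication:", nrow(x$summary), "distinct mature sequence(s), ",
      nrow(dup), "shared by >1 record\n")
  for (i in seq_len(nrow(dup))) {
    cat("  ", dup$toxin_names[i],
        if (dup$cross_species[i]) " [cross-species]" else "", "\n", sep = "")
  }
  invisible(x)
}

subtree_leaves <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  leaves <- character()
  while (length(todo)) {
    nd <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    leaves <- c(leaves, tree$tip.label[kids[kids <= ntip]])
    todo <- c(todo, kids[kids > ntip])
  }
  leaves
}

#' Partition a rooted peptide tree into clades
#'
#' Cuts a midpoint-rooted tree at the root into two major branches, then
#' cuts each major branch at its own root, yielding up to four leaf sets
#' labelled I-IV. Labels follow depth-first order with the larger major
#' branch first (ties broken on the alphabetically smallest leaf).
#' Degenerate branches (a single leaf, or a non-binary node) receive one
#' label and are reported in the `degenerate` attribute.
#'
#' @param tree rooted ape `phylo` with at least 4 leaves.
#' @param n_levels number of cut levels: 1 gives up to 2 clades, 2
#'   (default) up to 4.
#' @return named character vector mapping leaf label to clade label, with
#'   attribute `degenerate` (character vector of notes, possibly empty).
#' @export
clade_partition <- function(tree, n_levels = 2L) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_("tree must be rooted (midpoint-root it)")
  if (ape::Ntip(tree) < 4L) stop_("need at least 4 leaves")
  if (!n_levels %in% 1:2) stop_("`n_levels` must be 1 or 2")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  notes <- character()
  order_branches <- function(nodes) {
    sets <- lapply(nodes, subtree_leaves, tree = tree)
    ord <- order(-vapply(sets, length, integer(1)),
                 vapply(sets, min, character(1)))
    nodes[ord]
  }
  majors <- order_branches(tree$edge[tree$edge[, 1] == root, 2])
  if (length(majors) != 2L) {
    notes <- c(notes, sprintf("root has %d children (expected 2)",
                              length(majors)))
  }
  blocks <- list()
  for (m in majors) {
    if (n_levels == 1L) {
      blocks[[length(blocks) + 1L]] <- subtree_leaves(tree, m)
      next
    }
    kids <- tree$edge[tree$edge[, 1] == m, 2]
    if (m <= ntip || length(kids) != 2L) {
      blocks[[length(blocks) + 1L]] <- subtree_leaves(tree, m)
      notes <- c(notes, sprintf(
        "major branch {%s} is degenerate (leaf or non-binary); single label",
        paste(utils::head(subtree_leaves(tree, m), 3L), collapse = ",")))
      next
    }
    for (k in order_branches(kids)) {
      blocks[[length(blocks) + 1L]] <- subtree_leaves(tree, k)
    }
  }
  labels <- roman_labels(length(blocks))
  out <- character()
  for (i in seq_along(blocks)) {
    out[blocks[[i]]] <- labels[i]
  }
  out <- out[tree$tip.label]
  attr(out, "degenerate") <- notes
  out
}

#' Align mature peptides
#'
#' Uses the `mafft` aligner when available on the PATH (deterministic,
#' `--auto`); otherwise falls back to right-padding all sequences with
#' gaps to a common length. The fallback is crude and is flagged in the
#' `method` attribute; it is only adequate for closely related peptides.
#'
#' @param records toxin records with `toxin_name` and `mature`.
#' @return data frame `id`/`residues` of equal-length aligned sequences,
#'   with attribute `method` (`"mafft"` or `"pad"`).
#' @export
align_mature <- function(records) {
  ids <- records$toxin_name
  if (nzchar(Sys.which("mafft"))) {
    tmp_in <- tempfile(fileext = ".fasta")
    tmp_out <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(tmp_in, tmp_out)))
    write_fasta(data.frame(id = ids, residues = records$mature), tmp_in)
    status <- system2("mafft", c("--auto", "--quiet", "--amino", tmp_in),
                      stdout = tmp_out, stderr = FALSE)
    if (status == 0L) {
      aln <- read_fasta_aligned(tmp_out)
      aln <- aln[match(ids, aln$id), , drop = FALSE]
      attr(aln, "method") <- "mafft"
      return(aln)
    }
  }
  width <- max(nchar(records$mature))
  res <- vapply(records$mature, function(s) {
    paste0(s, strrep("-", width - nchar(s)))
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(id = ids, residues = res, stringsAsFactors = FALSE)
  attr(out, "method") <- "pad"
  out
}

# FASTA reader that preserves gap characters (the general reader strips
# every non-letter, which would destroy alignments).
read_fasta_aligned <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, ">")
  rec_idx <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], rec_idx[!is_hdr]), paste0,
                 character(1), collapse = "")
  data.frame(id = ids, residues = toupper(unname(seqs)),
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree of mature peptides, midpoint rooted
#'
#' Convenience wrapper: align the mature peptides, compute protein
#' p-distances with pairwise deletion, build the neighbor-joining tree
#' and midpoint-root it.
#'
#' @param records toxin records.
#' @return rooted ape `phylo` with attribute `alignment_method`.
#' @export
mature_peptide_tree <- function(records) {
  aln <- align_mature(records)
  d <- p_distance(aln, mode = "protein")
  tr <- midpoint_root(neighbor_joining(d))
  attr(tr, "alignment_method") <- attr(aln, "method")
  tr
}

#' Concordance table between two clade labelings
#'
#' Cross-tabulates an inferred partition against reference labels and
#' reports the best-case agreement fraction (each inferred clade mapped to
#' its most frequent reference label).
#'
#' @param assigned named character vector (leaf -> label), e.g. from
#'   [clade_partition()].
#' @param reference named character vector of reference labels over the
#'   same leaves.
#' @return list with `table` (contingency matrix) and `agreement`
#'   (fraction in `[0, 1]`).
#' @export
clade_concordance <- function(assigned, reference) {
  common <- intersect(names(assigned), names(reference))
  if (!length(common)) stop_("no shared leaves between labelings")
  tab <- table(assigned = assigned[common], reference = reference[common])
  agreement <- sum(apply(tab, 1L, max)) / sum(tab)
  list(table = tab, agreement = agreement)
}
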