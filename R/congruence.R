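# Clade-genus congruence: formalizes "no peptide clade mixes the two
# genera" as a statistic (the number of genus-mixed clades) with a
# permutation null that shuffles genus labels over records while holding
# clade sizes fixed.

EXCLUSIVITY_CAVEAT <- paste(
  "Absence of a clade from a genus in this table reflects only the",
  "sampled transcriptomes: peptides of that clade may exist undetected in",
  "the other genus, so exclusivity cannot be concluded definitively."
)

#' Genus composition of peptide clades
#'
#' Per-clade counts of records by genus, plus distinct species per
#' (clade, genus).
#'
#' @param records toxin records with `clade`, `species` and `genus`
#'   columns; every record must carry a non-empty genus.
#' @return object of class `clade_composition`: list with `counts`
#'   (clade x genus matrix of record counts) and `species_counts`
#'   (clade x genus matrix of distinct species counts).
#' @export
genus_composition <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("clade", "species", "genus")
  if (!all(need %in% names(records))) {
    stop_("records need columns: ", paste(need, collapse = ", "))
  }
  unmapped <- is.na(records$genus) | !nzchar(records$genus)
  if (any(unmapped)) {
    stop_("species without genus mapping: ",
          paste(unique(records$species[unmapped]), collapse = ", "))
  }
  counts <- table(clade = records$clade, genus = records$genus)
  key <- !duplicated(paste(records$clade, records$genus, records$species,
                           sep = "\r"))
  species_counts <- table(clade = records$clade[key],
                          genus = records$genus[key])
  structure(list(counts = counts, species_counts = species_counts),
            class = "clade_composition")
}

#' @export
print.clade_composition <- function(x, ...) {
  cat("records per (clade, genus):\n")
  print(x$counts)
  cat("distinct species per (clade, genus):\n")
  print(x$species_counts)
  invisible(x)
}

#' Number of genus-mixed clades
#'
#' Clades whose members come from at least two distinct genera. Invariant
#' to record order and to renaming clade labels.
#'
#' @param composition a [genus_composition()] result.
#' @return non-negative integer.
#' @export
mixed_clade_count <- function(composition) {
  stopifnot(inherits(composition, "clade_composition"))
  sum(rowSums(composition$counts > 0) >= 2L)
}

#' Permutation test of clade-genus exclusivity
#'
#' Statistic: the number of genus-mixed clades (lower = more exclusive).
#' Null: genus labels are shuffled over records with clade sizes held
#' fixed. The p-value uses the add-one correction
#' `p = (1 + #\{null <= observed\}) / (1 + n_permutations)` and is
#' therefore always in (0, 1].
#'
#' @param records toxin records with `clade` and `genus` columns (at least
#'   2 clades and 2 genera).
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param seed integer seed (mandatory for reproducibility).
#' @return object of class `exclusivity_test`: list with `statistic`,
#'   `p.value`, `n_permutations`, `null_table` (table of null statistic
#'   values), `composition` and `caveat`.
#' @export
exclusivity_permutation_test <- function(records, n_permutations = 10000L,
                                         seed) {
  stopifnot(is.data.frame(records))
  if (missing(seed)) stop_("`seed` is required")
  if (n_permutations < 0) stop_("`n_permutations` must be non-negative")
  comp <- genus_composition(records)
  n_clades <- nrow(comp$counts)
  n_genera <- ncol(comp$counts)
  if (n_clades < 2L || n_genera < 2L) {
    stop_("degenerate label sets: need at least 2 clades and 2 genera ",
          "(have ", n_clades, " and ", n_genera, ")")
  }
  observed <- mixed_clade_count(comp)
  genus <- as.integer(factor(records$genus))
  clade_idx <- split(seq_len(nrow(records)), records$clade)
  null_stats <- integer(0)
  if (n_permutations > 0) {
    null_stats <- with_seed(seed, {
      perm <- vapply(seq_len(n_permutations), function(b) sample(genus),
                     integer(length(genus)))
      mixed <- integer(n_permutations)
      for (idx in clade_idx) {
        sub <- perm[idx, , drop = FALSE]
        mixed <- mixed +
          (colSums(sub != matrix(sub[1L, ], nrow(sub), ncol(sub),
                                 byrow = TRUE)) > 0L)
      }
      mixed
    })
  }
  p <- (1 + sum(null_stats <= observed)) / (1 + n_permutations)
  structure(list(
    statistic = observed, p.value = p,
    n_permutations = as.integer(n_permutations),
    null_table = table(null_stats),
    null_mean = if (length(null_stats)) mean(null_stats) else NA_real_,
    composition = comp, caveat = EXCLUSIVITY_CAVEAT
  ), class = "exclusivity_test")
}

#' @export
print.exclusivity_test <- function(x, ...) {
  cat("clade-genus exclusivity permutation test\n")
  cat("  observed genus-mixed clades:", x$statistic, "\n")
  cat("  null mean:", format(x$null_mean, digits = 3),
      "over", x$n_permutations, "permutations\n")
  cat("  p-value:", format(x$p.value, digits = 4), "\n")
  cat("  note:", x$caveat, "\n")
  invisible(x)
}
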