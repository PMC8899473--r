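# Housekeeping-gene (HKG) panel construction from per-sample contig
# annotation tables: e-value filtering, intersection of gene labels across
# samples, and per-(sample, gene) representative contig selection.

#' Filter annotation hits by e-value
#'
#' Keeps hits with `e_value` strictly below `e_threshold` (matching the
#' usual "e < 1e-4" convention: a hit at exactly the threshold is
#' discarded).
#'
#' @param contigs data frame with at least columns `sample_id`,
#'   `contig_id`, `gene_label`, `e_value`.
#' @param e_threshold strict upper bound on the e-value, default `1e-4`.
#' @return the kept rows, input order preserved.
#' @export
filter_hits <- function(contigs, e_threshold = 1e-4) {
  stopifnot(is.data.frame(contigs))
  if (!is.numeric(e_threshold) || e_threshold <= 0) {
    stop_("`e_threshold` must be positive")
  }
  if (!nrow(contigs)) return(contigs)
  if (any(contigs$e_value < 0)) stop_("negative e-values in input")
  out <- contigs[contigs$e_value < e_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the shared housekeeping-gene panel
#'
#' The panel's gene set is the intersection, over all samples, of the gene
#' labels each sample carries. For every (sample, gene) with several
#' contigs, the representative is the contig with the smallest e-value;
#' ties are broken by the largest TPM, then the lexicographically smallest
#' contig id. The result is independent of input row order.
#'
#' @param filtered_contigs annotation rows that already passed
#'   [filter_hits()]; columns `sample_id`, `contig_id`, `gene_label`,
#'   `e_value` and optionally `tpm`.
#' @return object of class `hkg_panel`: list with `gene_labels` (sorted),
#'   `representatives` (data frame keyed by sample and gene), `samples`
#'   and `n_samples`.
#' @export
build_panel <- function(filtered_contigs) {
  stopifnot(is.data.frame(filtered_contigs))
  need <- c("sample_id", "contig_id", "gene_label", "e_value")
  if (!all(need %in% names(filtered_contigs))) {
    stop_("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  x <- filtered_contigs
  if (!nrow(x)) stop_("no annotated contigs; need at least one sample")
  if (!"tpm" %in% names(x)) x$tpm <- 0
  key <- paste(x$sample_id, x$contig_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_("duplicate (sample_id, contig_id) pairs: ",
          paste(unique(gsub("\r", "/", key[duplicated(key)]))[1:3],
                collapse = ", "))
  }
  samples <- sort(unique(x$sample_id))
  per_sample <- lapply(samples, function(s) {
    unique(x$gene_label[x$sample_id == s])
  })
  genes <- sort(Reduce(intersect, per_sample))
  if (!length(genes)) {
    warning("no gene is shared by all samples; panel is empty",
            call. = FALSE)
  }
  sub <- x[x$gene_label %in% genes, , drop = FALSE]
  sub <- sub[order(sub$sample_id, sub$gene_label, sub$e_value, -sub$tpm,
                   sub$contig_id), , drop = FALSE]
  reps <- sub[!duplicated(paste(sub$sample_id, sub$gene_label, sep = "\r")),
              c("sample_id", "gene_label", "contig_id", "e_value", "tpm"),
              drop = FALSE]
  rownames(reps) <- NULL
  structure(list(gene_labels = genes, representatives = reps,
                 samples = samples, n_samples = length(samples)),
            class = "hkg_panel")
}

#' @export
print.hkg_panel <- function(x, ...) {
  cat("HKG panel:", length(x$gene_labels), "gene(s) shared by",
      x$n_samples, "sample(s)\n")
  if (length(x$gene_labels)) {
    shown <- utils::head(x$gene_labels, 8L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$gene_labels) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' Export one FASTA file per panel gene
#'
#' Writes, for every gene in the panel, a FASTA file containing the
#' representative contig of each sample, with record ids
#' `"sample|contig"`.
#'
#' @param panel an [build_panel()] result.
#' @param sequences contig sequences: a data frame with columns `id`
#'   (contig ids) and `residues`, or a named character vector.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths (one per gene),
#'   invisibly.
#' @export
export_gene_sets <- function(panel, sequences, dir) {
  stopifnot(inherits(panel, "hkg_panel"))
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$residues, sequences$id)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- panel$representatives
  missing <- !(reps$contig_id %in% names(sequences))
  if (any(missing)) {
    m <- reps[missing, ][1, ]
    stop_("missing sequence for representative contig of (",
          m$sample_id, ", ", m$gene_label, "): ", m$contig_id)
  }
  paths <- character(0)
  for (g in panel$gene_labels) {
    r <- reps[reps$gene_label == g, , drop = FALSE]
    recs <- data.frame(
      id = paste(r$sample_id, r$contig_id, sep = "|"),
      description = g,
      residues = unname(sequences[r$contig_id]),
      stringsAsFactors = FALSE
    )
    safe <- gsub("[^A-Za-z0-9._-]", "_", g)
    p <- file.path(dir, paste0(safe, ".fasta"))
    write_fasta(recs, p)
    paths[g] <- p
  }
  invisible(paths)
}
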