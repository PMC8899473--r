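# FASTA / newick / tab-separated IO and the transcriptome read filter.
#
# Sequence records are plain data frames with columns `id`, `description`
# and `residues`. Residues are sanitized on input: all whitespace, digits
# and other non-letter characters (including byte-order marks that
# occasionally leak into copied sequence cells) are removed and letters
# uppercased. Trees are ape "phylo" objects.

#' Sanitize residue strings
#'
#' Removes every non-letter character (whitespace, digits, punctuation,
#' byte-order marks) and uppercases the remainder. Idempotent; a string
#' already consisting of uppercase letters is returned unchanged.
#'
#' @param x character vector of raw residue strings.
#' @return character vector of uppercase letter-only strings.
#' @export
#' @examples
#' sanitize_residues("da cp1")      # "DACP"
#' sanitize_residues("\ufeffDVCE")  # "DVCE"
sanitize_residues <- function(x) {
  toupper(gsub("[^A-Za-z]+", "", x, perl = TRUE))
}

#' Read a FASTA file
#'
#' Lines beginning with ">" start a record; the first whitespace-delimited
#' token is the id, the remainder the description. Sequence lines are
#' concatenated and sanitized with [sanitize_residues()].
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `id`, `description`, `residues`, in file
#'   order. An empty file yields a zero-row data frame with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # strip a file-level BOM if present
  if (length(lines)) lines[1] <- sub("^\ufeff", "", lines[1])
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE)
  if (!length(lines)) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(empty)
  }
  is_hdr <- startsWith(trimws(lines), ">")
  if (!is_hdr[1]) stop_("malformed FASTA (no leading '>' header): ", path)
  rec_idx <- cumsum(is_hdr)
  headers <- sub("^>", "", trimws(lines[is_hdr]))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s+", "", headers)), "")
  seqs <- vapply(split(lines[!is_hdr], rec_idx[!is_hdr]),
                 paste0, character(1), collapse = "")
  residues <- character(length(ids))
  residues[as.integer(names(seqs))] <- seqs
  residues <- sanitize_residues(residues)
  bad <- !nzchar(ids)
  if (any(bad)) stop_("FASTA record with empty id (record ",
                      which(bad)[1], ")")
  if (anyDuplicated(ids)) {
    stop_("duplicate FASTA ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop_("FASTA record with empty residues: ",
          paste(ids[!nzchar(residues)], collapse = ", "))
  }
  data.frame(id = ids, description = desc, residues = residues,
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path output path.
#' @param line_width maximum sequence-line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop_("duplicate ids: ",
          paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  if (!is_count(line_width)) stop_("`line_width` must be a positive integer")
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i] %||% "")) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Filter nucleotide reads by length and ambiguity
#'
#' Discards records shorter than `min_len` bases and those whose fraction
#' of ambiguous bases (N) exceeds `max_n_fraction`. "Exceeds" is strict:
#' a read with exactly 5\% N is kept under the default threshold.
#'
#' @param records data frame of nucleotide records (`id`, `residues`).
#' @param min_len minimum length in bases (default 70).
#' @param max_n_fraction maximum tolerated N fraction (default 0.05).
#' @return the kept records, input order preserved, with attributes
#'   `n_kept` and `n_discarded`.
#' @export
filter_reads <- function(records, min_len = 70L, max_n_fraction = 0.05) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  bad <- grepl("[^ACGTN]", records$residues)
  if (any(bad)) {
    stop_("non-nucleotide letters in record(s): ",
          paste(records$id[bad], collapse = ", "))
  }
  len <- nchar(records$residues)
  n_count <- nchar(records$residues) - nchar(gsub("N", "", records$residues, fixed = TRUE))
  keep <- len >= min_len & (n_count / pmax(len, 1L)) <= max_n_fraction
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Read a newick tree
#'
#' Parses branch lengths and internal-node support labels (the common
#' dialect where a number after a closing parenthesis is the support of
#' that node). Validates parenthesis balance and leaf-label uniqueness.
#'
#' @param text a newick string, or the path of a file containing one.
#' @return an ape `phylo` object.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- sub("^\ufeff", "", text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_("unbalanced newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop_("unbalanced newick: ", depth, " unclosed '(' at end of text")
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop_("could not parse newick text")
  if (anyDuplicated(tr$tip.label)) {
    stop_("duplicate leaf labels: ",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Write a tree as newick text
#'
#' @param tree an ape `phylo` object.
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers that fix the dialect used throughout the pipeline:
#' a header row, tab separator, no quoting, no row names. `read_tsv()`
#' tolerates a UTF-8 byte-order mark.
#'
#' @param path file path.
#' @return `read_tsv()` a data frame; `write_tsv()` `path`, invisibly.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8-BOM")
}

#' @rdname read_tsv
#' @param x data frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
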