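# Distance computation, neighbor joining, midpoint rooting, bipartition
# machinery and the gene-tree consensus with support fractions.
#
# This is the desk-scale stand-in for a per-gene maximum-likelihood +
# quartet-consensus stage: per-gene trees come from Jukes-Cantor-corrected
# p-distances and neighbor joining, and the species-tree consensus reports,
# at each node, the fraction of individual gene trees containing that
# node's bipartition.

MISSING_DNA <- c("-", "N", "?")
MISSING_AA <- c("-", "X", "?")

#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of differing sites per pair, computed over the sites where
#' neither sequence carries a gap or an ambiguity code (pairwise deletion).
#' Ambiguity codes are `N` for nucleotide alignments and `X` for protein
#' alignments; `-` and `?` are always treated as missing.
#'
#' @param records aligned sequences: a data frame with columns `id` and
#'   `residues`, or a named character vector. All sequences must have
#'   equal length.
#' @param mode `"auto"` (default), `"dna"` or `"protein"`; `"auto"`
#'   classifies the alignment as DNA when it only contains A, C, G, T, N
#'   and gap characters.
#' @return a symmetric numeric matrix with zero diagonal, labels as
#'   dimnames.
#' @export
p_distance <- function(records, mode = c("auto", "dna", "protein")) {
  mode <- match.arg(mode)
  if (is.data.frame(records)) {
    seqs <- stats::setNames(records$residues, records$id)
  } else {
    seqs <- records
  }
  n <- length(seqs)
  if (n < 2L) stop_("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_("sequences must carry unique names")
  }
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop_("sequences are not aligned (unequal lengths)")
  if (mode == "auto") {
    mode <- if (all(grepl("^[ACGTN?-]*$", seqs))) "dna" else "protein"
  }
  missing_chars <- if (mode == "dna") MISSING_DNA else MISSING_AA
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  ok <- !matrix(m %in% missing_chars, nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        stop_("no comparable sites between ", names(seqs)[i], " and ",
              names(seqs)[j])
      }
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    }
  }
  d
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed proportion of differing sites `p` into an expected
#' number of substitutions per site, `-(3/4) * log(1 - 4p/3)`.
#'
#' @param p numeric vector (or matrix) of p-distances in `[0, 0.75)`.
#' @param cap when `TRUE`, saturated values (`p >= 0.75`) are capped at
#'   0.74999 instead of raising an error; intended for noisy data.
#' @return corrected distances with the shape of `p`.
#' @export
jc_correct <- function(p, cap = FALSE) {
  if (any(p < 0, na.rm = TRUE)) stop_("negative p-distance")
  sat <- p >= 0.75
  if (any(sat, na.rm = TRUE)) {
    if (!cap) stop_("saturated distance (p >= 0.75); use cap = TRUE to clamp")
    p[which(sat)] <- 0.74999
  }
  out <- -0.75 * log(1 - 4 * p / 3)
  out
}

#' Jukes-Cantor corrected distance matrix
#'
#' Convenience composition of [p_distance()] and [jc_correct()].
#'
#' @inheritParams p_distance
#' @inheritParams jc_correct
#' @return symmetric corrected distance matrix.
#' @export
jc_distance <- function(records, mode = "auto", cap = FALSE) {
  jc_correct(p_distance(records, mode = mode), cap = cap)
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration on the Q criterion
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, joining the
#' pair minimizing Q. Ties are broken deterministically on the
#' lexicographically smallest pair of cluster labels (each cluster is
#' identified by the smallest leaf label it contains). Terminal branch
#' lengths come from the standard two-point formulas; negative lengths are
#' clamped to zero with the deficit transferred to the sibling branch, and
#' the number of clamped branches is recorded in the `n_negative_clamped`
#' attribute of the result.
#'
#' @param d symmetric numeric matrix with zero diagonal and dimnames, or a
#'   `dist` object.
#' @return unrooted ape `phylo` tree (trifurcating root in the stored
#'   representation).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), is.numeric(d))
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop_("distance matrix needs unique row/column labels")
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop_("distance matrix is not symmetric")
  }
  n <- nrow(d)
  if (n < 3L) stop_("need at least 3 taxa")
  frag <- labels            # newick fragment per active cluster
  rep_lab <- labels         # smallest leaf label per active cluster
  n_clamped <- 0L
  clamp_pair <- function(bi, bj) {
    # keep bi + bj constant; move any negative part onto the sibling
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  while (nrow(d) > 3L) {
    k <- nrow(d)
    r <- rowSums(d)
    q <- (k - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- d[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (k - 2))
    bj <- dij - bi
    if (bi < 0 || bj < 0) n_clamped <- n_clamped + 1L
    b <- clamp_pair(bi, bj)
    new_frag <- paste0("(", frag[i], ":", fmt_len(b[1]), ",",
                       frag[j], ":", fmt_len(b[2]), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- (d[i, ] + d[j, ] - dij) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                   c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
    rownames(d_new) <- colnames(d_new) <- rep_lab
    d <- d_new
  }
  # final three-way join
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(b1, b2, b3) < 0)) n_clamped <- n_clamped + 1L
  b <- pmax(c(b1, b2, b3), 0)
  txt <- paste0("(", frag[1], ":", fmt_len(b[1]), ",",
                frag[2], ":", fmt_len(b[2]), ",",
                frag[3], ":", fmt_len(b[3]), ");")
  tr <- ape::read.tree(text = txt)
  attr(tr, "n_negative_clamped") <- n_clamped
  tr
}

# Adjacency list (neighbor id -> edge length) keyed by node id.
tree_adjacency <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop_("tree is missing branch lengths")
  }
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; len <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  adj
}

# Recursive newick serialization from an adjacency list. Returns the
# fragment for the subtree hanging off `node` away from `parent`, plus an
# extra length to add to the edge above (non-zero when a degree-2 node --
# e.g. the old root of a rooted input -- is collapsed).
subtree_fragment <- function(adj, node, parent, tip_labels) {
  nb <- adj[[node]]
  kids <- nb[nb[, 1] != parent, , drop = FALSE]
  if (nrow(kids) == 0L) return(list(frag = tip_labels[node], add = 0))
  if (nrow(kids) == 1L) {
    sub <- subtree_fragment(adj, kids[1, 1], node, tip_labels)
    return(list(frag = sub$frag, add = kids[1, 2] + sub$add))
  }
  parts <- vapply(seq_len(nrow(kids)), function(i) {
    sub <- subtree_fragment(adj, kids[i, 1], node, tip_labels)
    paste0(sub$frag, ":", fmt_len(kids[i, 2] + sub$add))
  }, character(1))
  list(frag = paste0("(", paste(parts, collapse = ","), ")"), add = 0)
}

adjacency_newick <- function(adj, node, parent, tip_labels) {
  subtree_fragment(adj, node, parent, tip_labels)$frag
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' Finds the tree diameter (ties broken on the lexicographically smallest
#' endpoint pair) and places the root halfway along it. If the midpoint
#' falls exactly on an existing node the tree is rooted at that node.
#'
#' @param tree ape `phylo` with branch lengths.
#' @return rooted ape `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop_("tree is missing branch lengths")
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop_("need at least 2 leaves")
  dmat <- ape::cophenetic.phylo(tree)
  # order rows/cols by label so the tie-break is on labels, not indices
  ord <- order(rownames(dmat))
  dmat <- dmat[ord, ord]
  diam <- max(dmat)
  if (diam <= 0) stop_("tree has zero diameter")
  tol <- 1e-9 * diam
  cand <- which(dmat >= diam - tol, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  # rows are label-sorted, so the first (row, col) pair is lexicographically
  # smallest
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  from_lab <- rownames(dmat)[cand[1, 1]]
  to_lab <- colnames(dmat)[cand[1, 2]]
  from <- match(from_lab, tree$tip.label)
  to <- match(to_lab, tree$tip.label)
  path <- ape::nodepath(tree, from, to)
  adj <- tree_adjacency(tree)
  edge_len <- function(a, b) {
    nb <- adj[[a]]
    nb[nb[, 1] == b, 2][1]
  }
  target <- dmat[from_lab, to_lab] / 2
  cum <- 0
  tip_labels <- c(tree$tip.label, rep("", tree$Nnode))
  for (s in seq_len(length(path) - 1L)) {
    a <- path[s]; b <- path[s + 1L]
    len <- edge_len(a, b)
    if (abs(target - cum) <= tol) {
      # midpoint exactly on node `a`: root there
      txt <- paste0(adjacency_newick(adj, a, 0L, tip_labels), ";")
      return(ape::read.tree(text = txt))
    }
    if (target < cum + len + tol && target > cum) {
      x <- target - cum            # distance from `a` along edge (a, b)
      if (abs(len - x) <= tol) {   # lands on node b
        txt <- paste0(adjacency_newick(adj, b, 0L, tip_labels), ";")
        return(ape::read.tree(text = txt))
      }
      lf <- subtree_fragment(adj, a, b, tip_labels)
      rf <- subtree_fragment(adj, b, a, tip_labels)
      left <- paste0(lf$frag, ":", fmt_len(x + lf$add))
      right <- paste0(rf$frag, ":", fmt_len(len - x + rf$add))
      txt <- paste0("(", left, ",", right, ");")
      return(ape::read.tree(text = txt))
    }
    cum <- cum + len
  }
  stop_("internal error: midpoint not located on the diameter path")
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge; trivial splits (single leaf versus
#' the rest) are excluded. Each bipartition is canonicalized as the side
#' that does not contain the alphabetically smallest leaf label, making
#' set comparisons across trees well defined.
#'
#' @param tree ape `phylo` (rooted or unrooted).
#' @return object of class `split_set`: list with `splits` (list of sorted
#'   label vectors), `keys` (canonical string per split) and `taxa`.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- sort(tree$tip.label)
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  # leaves under each node, accumulated child -> parent
  below <- vector("list", n_nodes)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  splits <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next
    side <- sort(below[[ch]])
    if (taxa[1] %in% side) side <- setdiff(taxa, side)
    if (length(side) < 2L || length(side) > length(taxa) - 2L) next
    splits[[length(splits) + 1L]] <- side
  }
  keys <- vapply(splits, paste, character(1), collapse = "|")
  keep <- !duplicated(keys)
  structure(list(splits = splits[keep], keys = keys[keep], taxa = taxa),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat("split_set:", length(x$keys), "non-trivial bipartition(s) over",
      length(x$taxa), "taxa\n")
  for (k in x$keys) cat(" ", k, "\n")
  invisible(x)
}

# Two splits (canonical sides over the same taxa) are compatible iff some
# quadrant of their contingency is empty.
splits_compatible <- function(a, b, taxa) {
  length(intersect(a, b)) == 0L ||
    all(a %in% b) || all(b %in% a) ||
    length(union(a, b)) == length(taxa)
}

#' Consensus tree with gene-tree support fractions
#'
#' Counts each bipartition's frequency across gene trees, keeps every
#' bipartition with frequency strictly above `min_frequency`
#' (majority rule at the default 0.5) and, when `greedy = TRUE`, extends
#' the set with the remaining bipartitions in decreasing frequency (ties
#' broken on the canonical split string) whenever they are compatible with
#' the splits already included. Each internal node of the consensus is
#' labelled with the fraction of gene trees supporting its bipartition,
#' rounded to two decimals for display; exact fractions are kept in the
#' `split_support` attribute.
#'
#' @param gene_trees list of ape `phylo` objects on one shared leaf set.
#' @param min_frequency inclusion threshold (strict), default 0.5.
#' @param greedy extend majority splits with compatible lower-frequency
#'   splits, default `TRUE`.
#' @return ape `phylo` with `node.label` support values and attributes
#'   `split_support` (named exact frequencies) and `n_trees`.
#' @export
consensus_with_support <- function(gene_trees, min_frequency = 0.5,
                                   greedy = TRUE) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (inherits(gene_trees, "multiPhylo")) gene_trees <- unclass(gene_trees)
  stopifnot(length(gene_trees) >= 1L)
  taxa <- sort(gene_trees[[1]]$tip.label)
  for (i in seq_along(gene_trees)) {
    ti <- sort(gene_trees[[i]]$tip.label)
    if (!identical(ti, taxa)) {
      diff <- c(setdiff(ti, taxa), setdiff(taxa, ti))
      stop_("gene tree ", i, " has a different leaf set; symmetric ",
            "difference: ", paste(diff, collapse = ", "))
    }
  }
  n_trees <- length(gene_trees)
  split_lists <- lapply(gene_trees, bipartitions)
  all_keys <- unlist(lapply(split_lists, `[[`, "keys"), use.names = FALSE)
  counts <- table(all_keys)
  freq <- as.numeric(counts) / n_trees
  names(freq) <- names(counts)
  split_of <- list()
  for (sl in split_lists) {
    for (i in seq_along(sl$keys)) split_of[[sl$keys[i]]] <- sl$splits[[i]]
  }
  ord <- order(-freq, names(freq))
  keys <- names(freq)[ord]
  freq <- freq[ord]
  accepted <- character()
  for (k in keys) {
    if (freq[[k]] > min_frequency) {
      accepted <- c(accepted, k)
    } else if (greedy) {
      ok <- all(vapply(accepted, function(a) {
        splits_compatible(split_of[[a]], split_of[[k]], taxa)
      }, logical(1)))
      if (ok) accepted <- c(accepted, k)
    }
  }
  # Canonical sides all exclude taxa[1], so accepted splits form a laminar
  # family: nest clusters by containment and serialize.
  clusters <- split_of[accepted]
  sizes <- vapply(clusters, length, integer(1))
  c_ord <- order(-sizes)
  clusters <- clusters[c_ord]
  cl_keys <- accepted[c_ord]
  build <- function(members, cluster_idx) {
    inside <- cluster_idx[vapply(cluster_idx, function(i) {
      all(clusters[[i]] %in% members) && length(clusters[[i]]) < length(members)
    }, logical(1))]
    # maximal clusters strictly inside `members`
    maximal <- inside[vapply(inside, function(i) {
      !any(vapply(inside, function(j) {
        j != i && all(clusters[[i]] %in% clusters[[j]])
      }, logical(1)))
    }, logical(1))]
    covered <- unlist(clusters[maximal], use.names = FALSE)
    free <- setdiff(members, covered)
    parts <- character()
    for (i in maximal) {
      sub <- build(clusters[[i]], inside)
      supp <- formatC(freq[[cl_keys[i]]], format = "f", digits = 2)
      parts <- c(parts, paste0(sub, supp))
    }
    parts <- c(parts, sort(free))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(taxa, seq_along(clusters)), ";")
  tr <- ape::read.tree(text = txt)
  attr(tr, "split_support") <- stats::setNames(as.numeric(freq[accepted]),
                                               accepted)
  attr(tr, "n_trees") <- n_trees
  tr
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the two trees' non-trivial
#' bipartition sets.
#'
#' @param t1,t2 ape `phylo` objects on the same leaf set.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  a <- bipartitions(t1)
  b <- bipartitions(t2)
  if (!identical(a$taxa, b$taxa)) {
    diff <- c(setdiff(a$taxa, b$taxa), setdiff(b$taxa, a$taxa))
    stop_("trees have different leaf sets; symmetric difference: ",
          paste(diff, collapse = ", "))
  }
  length(setdiff(a$keys, b$keys)) + length(setdiff(b$keys, a$keys))
}

#' Per-gene run summary against a consensus tree
#'
#' @param gene_trees list of ape `phylo` objects.
#' @param consensus consensus tree on the same leaf set.
#' @return data frame with one row per gene: `gene`, `n_taxa`,
#'   `tree_length` (sum of branch lengths, NA when absent) and
#'   `rf_to_consensus`.
#' @export
gene_tree_summary <- function(gene_trees, consensus) {
  if (inherits(gene_trees, "multiPhylo")) gene_trees <- unclass(gene_trees)
  data.frame(
    gene = seq_along(gene_trees),
    n_taxa = vapply(gene_trees, ape::Ntip, integer(1)),
    tree_length = vapply(gene_trees, function(t) {
      if (is.null(t$edge.length)) NA_real_ else sum(t$edge.length)
    }, numeric(1)),
    rf_to_consensus = vapply(gene_trees, robinson_foulds, integer(1),
                             t2 = consensus)
  )
}
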