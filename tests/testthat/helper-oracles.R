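# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: splits come from ape::prop.part, path lengths
# from an edge-walk, topology enumeration from phangorn.

# Random binary tree with branch lengths bounded away from zero, so
# distance matrices are strictly additive.
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  tr
}

# Canonical split keys via ape::prop.part (independent of bipartitions()).
oracle_split_keys <- function(tree) {
  taxa <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- sort(labs[idx])
    if (taxa[1] %in% side) side <- setdiff(taxa, side)
    if (length(side) < 2L || length(side) > length(taxa) - 2L) return(NA_character_)
    paste(side, collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

# Path length between two tips by walking the edge list (oracle for
# cophenetic distances / diameter search).
oracle_path_length <- function(tree, from_lab, to_lab) {
  from <- match(from_lab, tree$tip.label)
  to <- match(to_lab, tree$tip.label)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  # BFS with distance accumulation (trees: unique paths)
  dist <- rep(NA_real_, n_nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    nb <- adj[[nd]]
    for (i in seq_len(NROW(nb))) {
      if (is.na(dist[nb[i, 1]])) {
        dist[nb[i, 1]] <- dist[nd] + nb[i, 2]
        queue <- c(queue, nb[i, 1])
      }
    }
  }
  dist[to]
}

# Brute-force diameter over all leaf pairs.
oracle_diameter <- function(tree) {
  tips <- tree$tip.label
  best <- 0
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      if (i >= j) next
      d <- oracle_path_length(tree, tips[i], tips[j])
      if (d > best) best <- d
    }
  }
  best
}

# Majority-rule consensus splits by brute-force counting with the oracle
# key extractor.
oracle_majority_splits <- function(trees, min_frequency = 0.5) {
  keys <- unlist(lapply(trees, oracle_split_keys))
  counts <- table(keys)
  freq <- as.numeric(counts) / length(trees)
  names(freq) <- names(counts)
  freq[freq > min_frequency]
}

# Least-squares residual of fitting distance matrix `d` on topology `top`
# (unrooted). Zero residual identifies the generating topology of an
# additive matrix.
oracle_ls_residual <- function(top, d) {
  taxa <- rownames(d)
  tips <- top$tip.label
  stopifnot(setequal(taxa, tips))
  # edge indicator matrix over tip pairs: entry 1 if the edge lies on the
  # path between the pair
  ntip <- ape::Ntip(top)
  n_nodes <- ntip + top$Nnode
  below <- vector("list", n_nodes)
  for (i in seq_len(ntip)) below[[i]] <- tips[i]
  for (e in ape::postorder(top)) {
    p <- top$edge[e, 1]; ch <- top$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  pairs <- t(combn(taxa, 2))
  A <- matrix(0, nrow(pairs), nrow(top$edge))
  for (e in seq_len(nrow(top$edge))) {
    side <- below[[top$edge[e, 2]]]
    in_side <- matrix(pairs %in% side, ncol = 2)
    A[, e] <- xor(in_side[, 1], in_side[, 2])
  }
  y <- d[pairs]
  fit <- stats::lm.fit(A, y)
  sqrt(sum(fit$residuals^2))
}

# Toxin-record data frame builder for constructed cases.
make_records <- function(toxin_name, mature, species = NULL, clade = NULL,
                         genus = NULL) {
  n <- length(mature)
  species <- species %||% rep("Turris babylonia", n)
  genus <- genus %||% sub("\\s.*$", "", species)
  clade <- clade %||% rep("I", n)
  data.frame(species = species, genus = genus, toxin_name = toxin_name,
             clade = clade, mature = mature, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
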