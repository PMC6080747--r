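# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk except the packaged isotope tables.

fixture_family <- function(family = "nifH", seed = 42, ...) {
  simulate_family(family, seed = seed, root_length = 80, n_members = 5,
                  n_extra_members = 3, n_decoys = 2, ...)
}

# a tiny three-family reference panel plus recA, small enough for unit tests
fixture_panel <- function(seed = 42, families = c("nifH", "nifD", "recA"),
                          ...) {
  fams <- lapply(seq_along(families), function(i) {
    fixture_family(families[i], seed = seed + i, ...)
  })
  names(fams) <- families
  fams
}

panel_references <- function(fams) {
  dplyr::bind_rows(lapply(fams, `[[`, "references"))
}

panel_alignments <- function(fams) {
  dplyr::bind_rows(lapply(fams, `[[`, "alignment"))
}

panel_sources <- function(fams, abundance = 0.2, pool = "members") {
  dplyr::bind_rows(lapply(fams, function(f) {
    tibble::tibble(
      label = if (pool == "members") f$family else paste0(f$family, "_decoy"),
      abundance = abundance,
      cds = list(f[[pool]]$cds))
  }))
}

random_peptides <- function(n, lengths, alphabet = c("A", "R", "N", "D")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(lengths, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# independent brute-force Smith-Waterman with affine gaps (gap of length k
# costs open + k * ext), O(mn(m+n)); the oracle for local_align()
sw_oracle <- function(query, target, mat, open = 11, ext = 1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  m <- length(q); n <- length(t)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      diag <- H[i, j] + mat[q[i], t[j]]
      # a gap of length g >= 1 ending here, from any previous cell in the
      # same column/row, costs open + g * ext
      gap_up <- max(H[seq_len(i), j + 1] -
                      (open + ext * (i - seq_len(i) + 1)))
      gap_left <- max(H[i + 1, seq_len(j)] -
                        (open + ext * (j - seq_len(j) + 1)))
      H[i + 1, j + 1] <- max(0, diag, gap_up, gap_left)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# brute-force descendant test: walk the edge list recursively, no ape MRCA
descendant_oracle <- function(tree, reference_leaves, query_leaf) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(children[[as.character(node)]], tips_below))
  }
  ref_idx <- match(reference_leaves, tree$tip.label)
  # MRCA by enumeration: the node with the smallest descendant set
  # containing every reference leaf
  nodes <- c(seq_len(n_tip), n_tip + seq_len(tree$Nnode))
  best <- NULL; best_size <- Inf
  for (nd in nodes) {
    tb <- tips_below(nd)
    if (all(ref_idx %in% tb) && length(tb) < best_size) {
      best <- tb; best_size <- length(tb)
    }
  }
  match(query_leaf, tree$tip.label) %in% best
}

# exhaustive-enumeration oracle for NJ: among all unrooted topologies, find
# the one(s) whose least-squares branch lengths reproduce the distances
# exactly (additivity); requires n <= 7 for budget reasons
enumeration_oracle <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  all_top <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  pair_idx <- t(combn(n, 2))
  fits <- vapply(all_top, function(tr) {
    n_edge <- nrow(tr$edge)
    n_tip <- length(tr$tip.label)
    children <- split(tr$edge[, 2], tr$edge[, 1])
    edge_of <- match(seq_len(n_tip + tr$Nnode), tr$edge[, 2])
    # edges on the path from each tip to the (arbitrary) root
    root <- n_tip + 1L
    path_up <- lapply(seq_len(n_tip), function(tip) {
      p <- integer(0); nd <- tip
      while (nd != root) {
        e <- edge_of[nd]
        p <- c(p, e)
        nd <- tr$edge[e, 1]
      }
      p
    })
    X <- matrix(0, nrow(pair_idx), n_edge)
    y <- numeric(nrow(pair_idx))
    for (r in seq_len(nrow(pair_idx))) {
      i <- match(labels[pair_idx[r, 1]], tr$tip.label)
      j <- match(labels[pair_idx[r, 2]], tr$tip.label)
      sym <- c(setdiff(path_up[[i]], path_up[[j]]),
               setdiff(path_up[[j]], path_up[[i]]))
      X[r, sym] <- 1
      y[r] <- d[pair_idx[r, 1], pair_idx[r, 2]]
    }
    fit <- stats::lsfit(X, y, intercept = FALSE)
    sum(fit$residuals^2)
  }, numeric(1))
  all_top[which(fits < 1e-12)]
}

# random additive distance matrix from a random binary tree; returns the
# generating tree too
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  d <- ape::cophenetic.phylo(tr)
  d <- d[paste0("t", seq_len(n_taxa)), paste0("t", seq_len(n_taxa))]
  list(tree = tr, d = d)
}
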