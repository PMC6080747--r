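# Phylogenetic clade screen: candidate hit peptides are projected into the
# reference multiple alignment's coordinate system, a joint
# neighbor-joining tree over references + hits is built from
# Kimura-corrected protein distances, midpoint-rooted, and each hit is
# called inside/outside the most recent common ancestor of the references.
# The original analysis used approximate-ML trees; NJ on corrected
# distances is used here for determinism, with the clade-membership rule
# itself unchanged.

.dist_cap <- 5.0

#' Align a hit peptide into a reference alignment's coordinates
#'
#' The hit is aligned pairwise (global with free end gaps) to its
#' best-scoring ungapped reference row, then projected through that row's
#' gap pattern into the reference column space. Insertions in the hit
#' relative to the reference are dropped; the projected row always has
#' exactly as many columns as the reference alignment.
#'
#' @param hit_peptide Non-empty peptide string.
#' @param ref_alignment Tibble with columns `seq_id` and `aligned` (gapped
#'   rows of equal length; gap character `-`).
#' @param config A [search_config()] providing the scoring scheme.
#' @return A single gapped string of width `nchar(ref_alignment$aligned[1])`.
#' @export
align_hit_to_reference <- function(hit_peptide, ref_alignment,
                                   config = search_config()) {
  stopifnot(nzchar(hit_peptide), nrow(ref_alignment) >= 1L)
  widths <- unique(nchar(ref_alignment$aligned))
  if (length(widths) != 1L) {
    abort("reference alignment rows have unequal lengths",
          class = "mucinif_input_error")
  }
  ungapped <- gsub("-", "", ref_alignment$aligned, fixed = TRUE)
  mat <- .star_matrix(config$substitution_matrix)
  scores <- vapply(ungapped, function(r) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(hit_peptide), Biostrings::AAString(r),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = config$gap_open, gapExtension = config$gap_extend,
      scoreOnly = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  if (all(scores <= 0)) {
    abort("unalignable hit: no reference row aligns with positive score",
          class = "mucinif_align_error")
  }
  best <- which.max(scores)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(hit_peptide), Biostrings::AAString(ungapped[best]),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  # hit residue (or gap) opposite each reference residue, in ref order
  ref_len <- nchar(ungapped[best])
  per_residue <- rep("-", ref_len)
  sub_start <- Biostrings::start(Biostrings::subject(pa))
  k <- sub_start - 1L
  for (i in seq_along(as_)) {
    if (as_[i] != "-") {
      k <- k + 1L
      per_residue[k] <- ap[i]
    }
  }
  # project through the chosen row's gap pattern
  row_chars <- strsplit(ref_alignment$aligned[best], "")[[1]]
  out <- rep("-", widths)
  out[row_chars != "-"] <- per_residue
  paste(out, collapse = "")
}

#' Kimura-corrected protein distance between two gapped rows
#'
#' Over the columns where both rows are ungapped, with `p` the mismatch
#' fraction, the distance is `-ln(1 - p - 0.2 p^2)`. For `p >= 0.85` the
#' correction is undefined and the distance is capped at 5.0 with a
#' warning.
#'
#' @param row_a,row_b Equal-length gapped strings sharing at least one
#'   ungapped column.
#' @return A non-negative distance.
#' @export
kimura_protein_distance <- function(row_a, row_b) {
  stopifnot(nchar(row_a) == nchar(row_b))
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  shared <- a != "-" & b != "-"
  if (!any(shared)) {
    abort("no shared ungapped columns", class = "mucinif_input_error")
  }
  p <- mean(a[shared] != b[shared])
  if (p >= 0.85) {
    warn(sprintf("mismatch fraction %.2f >= 0.85: distance capped at %.1f",
                 p, .dist_cap))
    return(.dist_cap)
  }
  max(-log(1 - p - 0.2 * p^2), 0)
}

# distance matrix over reference rows and projected query rows; pairs of
# queries sharing < min_shared columns (and any pair sharing none) get the
# cap distance
.joint_distance_matrix <- function(rows, is_query, min_shared = 10L) {
  n <- length(rows)
  chars <- do.call(rbind, strsplit(rows, ""))
  ungapped <- chars != "-"
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- ungapped[i, ] & ungapped[j, ]
      ns <- sum(shared)
      if (ns == 0L || (is_query[i] && is_query[j] && ns < min_shared)) {
        d[i, j] <- d[j, i] <- .dist_cap
        next
      }
      p <- mean(chars[i, shared] != chars[j, shared])
      d[i, j] <- d[j, i] <- if (p >= 0.85) .dist_cap else
        max(-log(1 - p - 0.2 * p^2), 0)
    }
  }
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor joining; any negative branch length is clamped to 0
#' and the deficit moved onto its sister branch, preserving path lengths
#' through the parent node.
#'
#' @param d A symmetric distance matrix with dimnames, or a `dist`.
#' @return An unrooted `phylo` tree over the input labels.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) {
    abort("neighbor joining needs at least 3 labels",
          class = "mucinif_input_error")
  }
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(diag(d) == 0))
  tr <- ape::nj(stats::as.dist(d))
  # clamp negatives, moving the deficit to a sister edge
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sisters) > 0L) {
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
      if (tr$edge.length[sisters[1]] < 0) tr$edge.length[sisters[1]] <- 0
    }
  }
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two deepest leaves are equidistant from the root. If every branch length
#' is zero the tree is rooted (with a warning) on the first edge in
#' traversal order.
#'
#' @param tree An unrooted `phylo` with at least 2 leaves.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  stopifnot(n >= 2L)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (all(tree$edge.length == 0)) {
    warn("all branch lengths are zero: rooting at first edge")
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  if (n == 2L) {
    total <- sum(tree$edge.length)
    out <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
                edge.length = c(total / 2, total / 2),
                tip.label = tree$tip.label, Nnode = 1L)
    class(out) <- "phylo"
    return(out)
  }
  phangorn::midpoint(ape::unroot(tree))
}

#' Is a query leaf inside the clade of the reference leaves?
#'
#' TRUE iff the query is a descendant of the most recent common ancestor
#' of the reference leaves in the rooted tree.
#'
#' @param tree A rooted `phylo`.
#' @param reference_leaves Character vector of >= 2 reference leaf labels.
#' @param query_leaf A single leaf label.
#' @return Logical scalar.
#' @export
inside_reference_clade <- function(tree, reference_leaves, query_leaf) {
  stopifnot(inherits(tree, "phylo"))
  reference_leaves <- unique(reference_leaves)
  if (length(reference_leaves) < 2L) {
    abort("need at least 2 reference leaves", class = "mucinif_input_error")
  }
  if (!all(reference_leaves %in% tree$tip.label)) {
    abort("reference leaf missing from tree", class = "mucinif_input_error")
  }
  if (!query_leaf %in% tree$tip.label) {
    abort(sprintf("query leaf '%s' missing from tree", query_leaf),
          class = "mucinif_input_error")
  }
  mrca <- ape::getMRCA(tree, reference_leaves)
  tips <- phangorn::Descendants(tree, mrca, type = "tips")[[1]]
  match(query_leaf, tree$tip.label) %in% tips
}

.as_alignment_tbl <- function(ref_alignments) {
  if (is.data.frame(ref_alignments)) {
    aln <- as_tibble(ref_alignments)
    stopifnot(all(c("family", "seq_id", "aligned") %in% names(aln)))
    return(aln)
  }
  abort("ref_alignments must be a tibble with columns family, seq_id, aligned",
        class = "mucinif_input_error")
}

#' Classify hits by clade membership in per-family trees
#'
#' For each gene family: project every retained hit peptide into the
#' family's reference alignment, build one joint NJ tree over references
#' plus hits, midpoint-root it, and call each hit inside or outside the
#' clade spanned by the references. One joint tree per family is built per
#' call (per library), and the result is invariant to input hit order.
#'
#' @param hits Hit tibble from [screen_reads()] (needs `read_id`, `family`,
#'   `aligned_query_peptide`).
#' @param ref_alignments Tibble with columns `family`, `seq_id`, `aligned`;
#'   each screened family needs >= 3 reference rows.
#' @param config A [search_config()].
#' @param min_shared Minimum shared reference-coordinate columns for a
#'   query-query distance; sparser pairs get the cap distance 5.0.
#' @return A tibble with `read_id`, `family`, `inside`,
#'   `n_shared_columns` (ungapped projected columns). The per-family
#'   midpoint-rooted trees are attached as `attr(, "trees")`.
#' @export
classify_hits <- function(hits, ref_alignments, config = search_config(),
                          min_shared = 10L) {
  aln <- .as_alignment_tbl(ref_alignments)
  out_empty <- tibble(read_id = character(), family = character(),
                      inside = logical(), n_shared_columns = integer())
  if (nrow(hits) == 0L) {
    attr(out_empty, "trees") <- list()
    return(out_empty)
  }
  stopifnot(all(c("read_id", "family", "aligned_query_peptide") %in% names(hits)))
  trees <- list()
  res <- purrr::map(sort(unique(hits$family)), function(fam) {
    fam_aln <- aln |> filter(.data$family == fam)
    if (nrow(fam_aln) < 3L) {
      abort(sprintf("family '%s' has fewer than 3 reference rows", fam),
            class = "mucinif_input_error")
    }
    fam_hits <- hits |> filter(.data$family == fam) |>
      arrange(.data$read_id)
    proj <- vapply(fam_hits$aligned_query_peptide, function(p) {
      align_hit_to_reference(p, fam_aln, config)
    }, character(1), USE.NAMES = FALSE)
    ref_labels <- paste0("r|", fam_aln$seq_id)
    qry_labels <- paste0("q|", fam_hits$read_id)
    rows <- setNames(c(fam_aln$aligned, proj), c(ref_labels, qry_labels))
    is_query <- c(rep(FALSE, length(ref_labels)), rep(TRUE, length(qry_labels)))
    d <- .joint_distance_matrix(rows, is_query, min_shared)
    tr <- midpoint_root(nj_tree(d))
    trees[[fam]] <<- tr
    inside <- vapply(qry_labels, function(q) {
      inside_reference_clade(tr, ref_labels, q)
    }, logical(1), USE.NAMES = FALSE)
    tibble(read_id = fam_hits$read_id, family = fam, inside = inside,
           n_shared_columns = vapply(proj, function(p) {
             sum(strsplit(p, "")[[1]] != "-")
           }, integer(1), USE.NAMES = FALSE))
  })
  out <- bind_rows(res)
  attr(out, "trees") <- trees
  out
}
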