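# Seed-deterministic simulators for every input the pipelines need:
# reference peptide families with controllable divergence, labelled
# metagenomic reads, and randomized-block isotope field trials with a known
# true fixation fraction. No indels are simulated, so the reference
# alignment is the trivially ungapped one and clade-classification accuracy
# is isolated from aligner quality.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_peptide <- function(length) {
  paste(sample(.aa20, length, replace = TRUE), collapse = "")
}

# Poisson substitutions at `divergence` expected substitutions/site,
# uniform replacement by one of the other 19 residues
.evolve_peptide <- function(peptide, divergence) {
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  n_sub <- rpois(1, divergence * L)
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub, replace = TRUE)
    for (p in pos) {
      chars[p] <- sample(setdiff(.aa20, chars[p]), 1)
    }
  }
  paste(chars, collapse = "")
}

# evolve one sequence per leaf of a rooted guide tree, Poisson substitutions
# along each edge
.evolve_along_tree <- function(root_peptide, tree) {
  n_tip <- length(tree$tip.label)
  seqs <- vector("character", n_tip + tree$Nnode)
  seqs[n_tip + 1L] <- root_peptide
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    seqs[child] <- .evolve_peptide(seqs[parent], ord$edge.length[e])
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

# codon table: amino acid -> synonymous codons (standard code, DNA)
.codon_sets <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Reverse-translate a peptide into a coding nucleotide sequence
#'
#' Each residue gets a codon drawn uniformly from its synonymous set under
#' the standard genetic code, so translating the result in frame +1
#' reproduces the peptide. Uses the current RNG state; wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param peptide Peptide over the 20 standard residues (no `*` or `X`).
#' @return A nucleotide string of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide) {
  chars <- strsplit(peptide, "")[[1]]
  if (any(chars %in% c("*", "X")) || !all(chars %in% .aa20)) {
    abort("peptide must contain only the 20 standard residues",
          class = "mucinif_input_error")
  }
  codons <- vapply(chars, function(aa) {
    set <- .codon_sets[[aa]]
    set[sample.int(length(set), 1)]
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

#' Simulate a reference peptide family
#'
#' Draws a uniform-random root peptide and evolves family members from it
#' along a guide tree by Poisson substitutions (uniform replacement, no
#' indels). The default guide tree is a random coalescent over references
#' plus held-out members, rescaled so every root-to-tip path equals the
#' member divergence: held-out members then nest inside the reference
#' radiation, the way metagenomic reads from real community taxa fall
#' within the known diversity of a gene family. Decoys emulate distant
#' homologs outside that radiation: a decoy root is evolved from the family
#' root at `decoy_divergence`, and decoy sequences from it at the member
#' divergence. Reads for screening tests are drawn from the held-out
#' members (`n_extra_members`), never from the reference peptides
#' themselves, so the member divergence actually matters.
#'
#' @param family_label Gene-family name (see [gene_families()]).
#' @param seed Mandatory integer seed.
#' @param n_members Number of reference sequences (>= 3).
#' @param root_length Root peptide length (residues).
#' @param member_divergence Expected substitutions/site from the root to
#'   every member tip.
#' @param decoy_divergence Expected substitutions/site separating the decoy
#'   root from the family root.
#' @param n_extra_members Held-out member sequences (read sources).
#' @param n_decoys Decoy sequences.
#' @param guide_tree `"coalescent"` (default) or `"star"` (members evolved
#'   independently from the root).
#' @return A list with `family`, `root`, `references` (tibble `family`,
#'   `seq_id`, `residues`), `alignment` (tibble `family`, `seq_id`,
#'   `aligned`; ungapped), `members` and `decoys` (tibbles with `seq_id`,
#'   `residues`, `cds` — the coding sequences used as read sources), and
#'   `decoy_root`.
#' @export
simulate_family <- function(family_label, seed, n_members = 10,
                            root_length = 120, member_divergence = 0.3,
                            decoy_divergence = 1.5, n_extra_members = 5,
                            n_decoys = 4,
                            guide_tree = c("coalescent", "star")) {
  guide_tree <- match.arg(guide_tree)
  stopifnot(n_members >= 3, member_divergence >= 0, decoy_divergence >= 0,
            root_length >= 10)
  withr::local_seed(seed)
  root <- .random_peptide(root_length)
  n_total <- n_members + max(n_extra_members, 0)
  if (guide_tree == "coalescent" && n_total >= 3 && member_divergence > 0) {
    gt <- ape::rcoal(n_total, tip.label = sprintf("t%02d", seq_len(n_total)))
    depth <- max(ape::node.depth.edgelength(gt))
    gt$edge.length <- gt$edge.length / depth * member_divergence
    tips <- .evolve_along_tree(root, gt)
  } else {
    tips <- vapply(seq_len(n_total), function(i) {
      .evolve_peptide(root, member_divergence)
    }, character(1))
  }
  # which tips become references is random: rcoal tip labels are not
  # exchangeable with respect to topology, and held-out members must be
  # interleaved with the references, not a clade of their own
  ref_idx <- sort(sample.int(n_total, n_members))
  refs <- unname(tips[ref_idx])
  members <- if (n_extra_members > 0) {
    unname(tips[setdiff(seq_len(n_total), ref_idx)])
  } else character()
  ref_ids <- sprintf("%s_ref%02d", family_label, seq_len(n_members))
  decoy_root <- .evolve_peptide(root, decoy_divergence)
  decoys <- vapply(seq_len(max(n_decoys, 0)), function(i) {
    .evolve_peptide(decoy_root, member_divergence)
  }, character(1))
  member_tbl <- tibble(
    seq_id = sprintf("%s_mem%02d", family_label, seq_along(members)),
    residues = members,
    cds = vapply(members, reverse_translate, character(1), USE.NAMES = FALSE))
  decoy_tbl <- tibble(
    seq_id = sprintf("%s_decoy%02d", family_label, seq_along(decoys)),
    residues = decoys,
    cds = vapply(decoys, reverse_translate, character(1), USE.NAMES = FALSE))
  list(family = family_label, root = root,
       references = tibble(family = family_label, seq_id = ref_ids,
                           residues = unname(refs)),
       alignment = tibble(family = family_label, seq_id = ref_ids,
                          aligned = unname(refs)),
       members = member_tbl, decoys = decoy_tbl, decoy_root = decoy_root)
}

#' Simulate a metagenomic read library with truth labels
#'
#' Reads are sampled from random windows of source coding sequences (strand
#' chosen uniformly) with per-base substitution errors, or drawn as
#' uniform-random background with the remaining probability mass.
#'
#' @param sources Tibble with columns `label`, `abundance`, and `cds`
#'   (list-column of nucleotide strings). Abundances must sum to <= 1; the
#'   remainder becomes `"background"` reads.
#' @param n_reads Number of reads.
#' @param seed Mandatory integer seed.
#' @param read_length Read length (nt); must not exceed any source CDS
#'   length.
#' @param error_rate Per-base substitution error probability.
#' @return A list with `reads` (tibble `read_id`, `description`,
#'   `sequence`, `quality`) and `truth` (tibble `read_id`, `label`).
#' @export
simulate_metagenome <- function(sources, n_reads, seed, read_length = 150,
                                error_rate = 0.01) {
  stopifnot(all(c("label", "abundance", "cds") %in% names(sources)),
            n_reads >= 0, error_rate >= 0, error_rate <= 1)
  if (sum(sources$abundance) > 1 + 1e-12) {
    abort("source abundances must sum to <= 1", class = "mucinif_input_error")
  }
  short <- purrr::map_lgl(sources$cds, function(v) any(nchar(v) < read_length))
  if (any(short)) {
    abort(sprintf("read_length %d exceeds a CDS length in source '%s'",
                  read_length, sources$label[short][1]),
          class = "mucinif_input_error")
  }
  withr::local_seed(seed)
  nt <- c("A", "C", "G", "T")
  labels <- c(sources$label, "background")
  probs <- c(sources$abundance, max(1 - sum(sources$abundance), 0))
  pick <- sample.int(length(labels), n_reads, replace = TRUE, prob = probs)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (pick[i] == length(labels)) {
      seqs[i] <- paste(sample(nt, read_length, replace = TRUE), collapse = "")
    } else {
      pool <- sources$cds[[pick[i]]]
      cds <- pool[sample.int(length(pool), 1)]
      start <- sample.int(nchar(cds) - read_length + 1L, 1)
      frag <- substr(cds, start, start + read_length - 1L)
      if (runif(1) < 0.5) frag <- reverse_complement(frag)
      if (error_rate > 0) {
        chars <- strsplit(frag, "")[[1]]
        hit <- which(runif(read_length) < error_rate)
        for (p in hit) chars[p] <- sample(setdiff(nt, chars[p]), 1)
        frag <- paste(chars, collapse = "")
      }
      seqs[i] <- frag
    }
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  list(reads = tibble(read_id = ids, description = ids, sequence = seqs,
                      quality = strrep("I", read_length)),
       truth = tibble(read_id = ids, label = labels[pick]))
}

#' Simulate a randomized-block isotope field trial
#'
#' Emulates the statistical structure of an isotope-dilution field
#' experiment: a randomized complete block design with reference
#' (non-fixing) and candidate fixer varieties of known true fixation
#' fraction `f_star`. In natural-abundance mode reference plots measure
#' `soil_value + noise` permil and fixer plots
#' `(1 - f_star) * soil_value + f_star * B + noise`; enrichment mode applies
#' the same mixing to atom% 15N excess. Fixer shoot N is inflated to
#' `reference / (1 - f_star)` so the true fixer-denominator %Ndiff equals
#' `100 * f_star`.
#'
#' @param seed Mandatory integer seed.
#' @param varieties Tibble with `variety`, `role`
#'   (`"reference"`/`"fixer"`), and `f_star` (0 for references). Default:
#'   two reference and two landrace varieties with `f_star = 0.4`.
#' @param n_fields Number of fields.
#' @param n_blocks Replicate blocks per field (default 5).
#' @param mode `"natural"` (delta 15N, permil) or `"enrichment"`
#'   (atom% 15N excess).
#' @param soil_value Soil-derived isotope signal: delta 15N permil
#'   (default 6) in natural mode, or atom% excess (default 0.5) in
#'   enrichment mode.
#' @param noise_sd Plot noise SD on the isotope value (same units).
#' @param B Baseline of air-derived N (natural mode).
#' @param shootn_reference Mean reference shoot N (kg/ha).
#' @param shootn_noise_sd Plot noise SD on shoot N.
#' @return A list with `plots` (tibble `field`, `stage`, `block`,
#'   `variety`, `role`, the isotope column, `shootn`) and `truth` (tibble
#'   `variety`, `f_star`).
#' @export
simulate_field_trial <- function(seed,
                                 varieties = tibble(
                                   variety = c("RefA", "RefB", "SM1", "SM2"),
                                   role = c("reference", "reference",
                                            "fixer", "fixer"),
                                   f_star = c(0, 0, 0.4, 0.4)),
                                 n_fields = 1, n_blocks = 5,
                                 mode = c("natural", "enrichment"),
                                 soil_value = NULL, noise_sd = 0.5, B = 0,
                                 shootn_reference = 30,
                                 shootn_noise_sd = 0) {
  mode <- match.arg(mode)
  stopifnot(all(varieties$f_star >= 0), all(varieties$f_star <= 1),
            noise_sd >= 0, n_blocks >= 1, n_fields >= 1,
            all(varieties$f_star[varieties$role == "fixer"] < 1))
  soil_value <- soil_value %||% if (mode == "natural") 6 else 0.5
  withr::local_seed(seed)
  grid <- tidyr::expand_grid(field = seq_len(n_fields),
                             block = seq_len(n_blocks),
                             variety = varieties$variety) |>
    left_join(varieties, by = "variety") |>
    mutate(stage = "Tassel")
  n <- nrow(grid)
  value <- (1 - grid$f_star) * soil_value + grid$f_star *
    (if (mode == "natural") B else 0) + rnorm(n, 0, noise_sd)
  shootn <- shootn_reference / (1 - grid$f_star) +
    rnorm(n, 0, shootn_noise_sd)
  plots <- grid |>
    mutate(shootn = shootn) |>
    select("field", "stage", "block", "variety", "role", "f_star", "shootn")
  plots[[if (mode == "natural") "delta15n" else "atom15n_excess"]] <- value
  plots <- plots |> select(-"f_star")
  list(plots = plots,
       truth = varieties |> select("variety", "role", "f_star"))
}
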