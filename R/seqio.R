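# Readers/writers for FASTA, FASTQ (Phred-33), newick and delimited plot
# tables. All readers validate strictly and fail loudly: no partially parsed
# result is ever returned. Coordinates are 0-based half-open throughout the
# package; sequences are uppercased on read and 'U' is mapped to 'T' in
# nucleotide data.

.dna_letters <- c("A", "C", "G", "T", "N")
.aa_letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

.validate_letters <- function(seq_lines, line_numbers, allowed, what) {
  pat <- paste0("[^", gsub("\\*", "\\\\*", paste(allowed, collapse = "")), "]")
  bad <- stringr::str_detect(seq_lines, pat)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- stringr::str_extract(seq_lines[i], pat)
    abort(sprintf("invalid %s character '%s' on line %d", what, ch,
                  line_numbers[i]),
          class = "mucinif_parse_error")
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a tibble. Record IDs are
#' the first whitespace-delimited token of the header; the full header is
#' kept as `description`. Sequences are uppercased; in nucleotide data `U`
#' is converted to `T`. The alphabet is auto-detected per file (nucleotide
#' `{A,C,G,T,N,U}` vs amino acid) unless forced.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default), `"dna"`, or `"protein"`.
#' @return A tibble with columns `seq_id`, `description`, `sequence`, in
#'   input order.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines, side = "right")
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warn(sprintf("empty FASTA input: %s", path))
    return(tibble(seq_id = character(), description = character(),
                  sequence = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    abort(sprintf("line %d: FASTA must start with a '>' header", line_no[1]),
          class = "mucinif_parse_error")
  }
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- stringr::str_split_fixed(headers, "\\s+", 2)[, 1]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA ID: '%s'", ids[duplicated(ids)][1]),
          class = "mucinif_parse_error")
  }
  seq_lines <- toupper(lines[!is_hdr])
  seq_line_no <- line_no[!is_hdr]
  joined <- toupper(lines)
  joined[is_hdr] <- ""
  seqs <- vapply(split(joined, grp), paste0, character(1), collapse = "")
  if (any(!nzchar(seqs))) {
    abort(sprintf("FASTA record '%s' has no sequence",
                  ids[which(!nzchar(seqs))[1]]),
          class = "mucinif_parse_error")
  }
  if (alphabet == "auto") {
    all_chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    alphabet <- if (all(all_chars %in% c(.dna_letters, "U"))) "dna" else "protein"
  }
  if (alphabet == "dna") {
    .validate_letters(seq_lines, seq_line_no, c(.dna_letters, "U"), "nucleotide")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  } else {
    .validate_letters(seq_lines, seq_line_no, .aa_letters, "amino-acid")
  }
  tibble(seq_id = ids, description = headers, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `seq_id` and `sequence`; an optional
#'   `description` column is written as the full header when present.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("seq_id", "sequence") %in% names(x)))
  hdr <- if ("description" %in% names(x) && any(nzchar(x$description))) {
    ifelse(nzchar(x$description), x$description, x$seq_id)
  } else {
    x$seq_id
  }
  chunks <- purrr::map2(hdr, x$sequence, function(h, s) {
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Read a FASTQ file (Phred-33)
#'
#' Strict 4-line-record FASTQ reader. Qualities must be Phred-33 printable
#' ASCII; other encodings are rejected. Sequences are uppercased and `U`
#' mapped to `T`.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id`, `description`, `sequence`,
#'   `quality` (Phred-33 string, same length as `sequence`).
#' @seealso [phred_scores()] to decode qualities to integers.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), description = character(),
                  sequence = character(), quality = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record %d (file has %d lines, not a multiple of 4)",
                  length(lines) %/% 4L + 1L, length(lines)),
          class = "mucinif_parse_error")
  }
  idx <- seq(1L, length(lines), by = 4L)
  rec <- seq_along(idx)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  sep <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) {
    abort(sprintf("FASTQ record %d: header does not start with '@'",
                  rec[bad_hdr][1]), class = "mucinif_parse_error")
  }
  bad_sep <- !startsWith(sep, "+")
  if (any(bad_sep)) {
    abort(sprintf("FASTQ record %d: separator line does not start with '+'",
                  rec[bad_sep][1]), class = "mucinif_parse_error")
  }
  mism <- nchar(seqs) != nchar(qual)
  if (any(mism)) {
    abort(sprintf("FASTQ record %d: sequence and quality lengths differ",
                  rec[mism][1]), class = "mucinif_parse_error")
  }
  .validate_letters(seqs, idx + 1L, c(.dna_letters, "U"), "nucleotide")
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad_q <- stringr::str_detect(qual, "[^!-~]")
  if (any(bad_q)) {
    abort(sprintf("FASTQ record %d: quality characters outside Phred-33 range",
                  rec[bad_q][1]), class = "mucinif_parse_error")
  }
  headers <- sub("^@", "", hdr)
  ids <- stringr::str_split_fixed(headers, "\\s+", 2)[, 1]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTQ read ID: '%s'", ids[duplicated(ids)][1]),
          class = "mucinif_parse_error")
  }
  tibble(read_id = ids, description = headers, sequence = seqs, quality = qual)
}

#' Write reads to FASTQ (Phred-33)
#'
#' @param x A tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(x)))
  stopifnot(all(nchar(x$sequence) == nchar(x$quality)))
  hdr <- if ("description" %in% names(x) && any(nzchar(x$description))) {
    ifelse(nzchar(x$description), x$description, x$read_id)
  } else {
    x$read_id
  }
  writeLines(as.vector(rbind(paste0("@", hdr), x$sequence, "+", x$quality)),
             path)
  invisible(path)
}

#' Decode Phred-33 quality strings to integer scores
#'
#' @param quality Character vector of Phred-33 quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) as.integer(utf8ToInt(q)) - 33L)
}

#' Parse a newick string into an `ape` phylo tree
#'
#' Missing branch lengths default to 0; leaf labels must be unique and
#' parentheses balanced. The inverse is [write_newick()].
#'
#' @param text A single newick statement ending in `;`.
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- stringr::str_trim(text)
  if (!endsWith(text, ";")) {
    abort("newick statement must end in ';'", class = "mucinif_parse_error")
  }
  n_open <- stringr::str_count(text, "\\(")
  n_close <- stringr::str_count(text, "\\)")
  if (n_open != n_close) {
    abort("unbalanced parentheses in newick statement",
          class = "mucinif_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("could not parse newick statement", class = "mucinif_parse_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(sprintf("duplicate leaf label: '%s'",
                  tree$tip.label[duplicated(tree$tip.label)][1]),
          class = "mucinif_parse_error")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  tree
}

#' Serialize a phylo tree to a newick string
#'
#' @param tree A `phylo` object.
#' @param path Optional file to write the statement to.
#' @return The newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a delimited plot-level table with schema validation
#'
#' Reads a TSV/CSV with a header row and checks that required columns are
#' present and that declared numeric columns parse; missing cells become
#' `NA`. Used for isotope field-trial tables.
#'
#' @param path Path to a delimited text file.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers.
#' @param delim Field delimiter; `NULL` (default) picks TAB for `.tsv`,
#'   comma otherwise.
#' @return A tibble.
#' @export
read_plot_table <- function(path, required = character(),
                            numeric_cols = character(), delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA"),
                           col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "mucinif_schema_error")
  }
  for (col in intersect(numeric_cols, names(tbl))) {
    raw <- tbl[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0L) {
      abort(sprintf("column '%s': unparseable numeric value '%s' in row %d",
                    col, raw[bad[1]], bad[1]),
            class = "mucinif_schema_error")
    }
    tbl[[col]] <- num
  }
  # columns that look numeric throughout are typed numeric
  for (col in setdiff(names(tbl), numeric_cols)) {
    raw <- tbl[[col]]
    num <- suppressWarnings(as.numeric(raw))
    if (all(is.na(raw) | !is.na(num)) && any(!is.na(num))) {
      tbl[[col]] <- num
    } else if (all(is.na(raw) | raw %in% c("TRUE", "FALSE"))) {
      tbl[[col]] <- as.logical(raw)
    }
  }
  tbl
}
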