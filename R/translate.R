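# Six-frame translation under the standard genetic code (NCBI table 1).
# Frame +k translates the forward strand starting at offset k-1; frame -k
# translates the reverse complement the same way. Trailing partial codons
# are dropped, so each peptide has length floor((len - (|frame|-1)) / 3).

#' Translate reads in all six frames
#'
#' Stop codons are rendered `*`; any codon containing `N` translates to `X`.
#'
#' @param reads A tibble with columns `read_id` and `sequence`
#'   (nucleotides over `A,C,G,T,N`), e.g. from [read_fastq()].
#' @return A tibble with columns `read_id`, `frame` (one of
#'   `+1,+2,+3,-1,-2,-3` as integers), and `peptide`, six rows per read.
#' @export
six_frame_translate <- function(reads) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(), frame = integer(),
                  peptide = character()))
  }
  if (any(nchar(reads$sequence) < 3L)) {
    abort(sprintf("read '%s' is shorter than 3 nt",
                  reads$read_id[nchar(reads$sequence) < 3L][1]),
          class = "mucinif_input_error")
  }
  fwd <- Biostrings::DNAStringSet(reads$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  one_frame <- function(x, offset) {
    w <- Biostrings::width(x)
    aa_len <- pmax((w - offset) %/% 3L, 0L)
    ends <- offset + 3L * aa_len
    sub <- Biostrings::subseq(x, start = offset + 1L, end = ends)
    out <- character(length(x))
    nz <- aa_len > 0L
    if (any(nz)) {
      out[nz] <- as.character(
        Biostrings::translate(sub[nz], if.fuzzy.codon = "X",
                              no.init.codon = TRUE))
    }
    out
  }
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  res <- purrr::map(frames, function(f) {
    x <- if (f > 0L) fwd else rev
    tibble(read_id = reads$read_id, frame = f,
           peptide = one_frame(x, abs(f) - 1L))
  })
  bind_rows(res) |>
    arrange(match(.data$read_id, reads$read_id)) |>
    as_tibble()
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
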