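#' Nucleotide sequence utilities
#'
#' Sequences throughout the package are plain upper-case character strings;
#' assemblies are tibbles with one row per contig (`species`, `contig_id`,
#' `seq`). These helpers cover the small amount of string-level plumbing the
#' pipeline needs.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return `revcomp()` returns the reverse complement(s); `gc_content()` the
#'   GC percentage(s) in `[0, 100]` (`NA` when a sequence has no unambiguous
#'   A/C/G/T base).
#' @examples
#' revcomp("ATGC")
#' gc_content(c("ATGC", "GGCC", "NNN"))
#' @export
revcomp <- function(seq) {
  stringr::str_to_upper(seq) |>
    chartr(old = "ACGTRYSWKMBDHVN", new = "TGCAYRSWMKVHDBN") |>
    vapply(function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' @rdname revcomp
#' @export
gc_content <- function(seq) {
  seq <- stringr::str_to_upper(seq)
  gc <- stringr::str_count(seq, "[GC]")
  at <- stringr::str_count(seq, "[AT]")
  ifelse(gc + at > 0, 100 * gc / (gc + at), NA_real_)
}

#' Genetic-code codon table
#'
#' Codon-to-amino-acid lookup for an NCBI translation table. Table 9
#' (Echinoderm/Flatworm Mitochondrial) is the default used for ORF
#' re-translation downstream; it differs from the standard code (table 1)
#' exactly at AAA (Lys to Asn), AGA/AGG (Arg to Ser) and TGA (stop to Trp).
#'
#' @param code NCBI translation table id (integer or character), e.g. 1 or 9.
#' @return Named character vector of length 64 mapping codons to one-letter
#'   amino acids, with stops as `"*"`.
#' @export
genetic_code <- function(code = 1) {
  Biostrings::getGeneticCode(as.character(code))
}

#' Translate a nucleotide sequence
#'
#' @param nt Single nucleotide sequence; length must be a multiple of 3.
#' @param code NCBI translation table id (default 1, the standard code).
#' @return Protein string, one letter per codon; stop codons become `"*"`
#'   and codons containing ambiguity codes become `"X"`.
#' @examples
#' translate_dna("ATGAAATAA", code = 1) # "MK*"
#' translate_dna("ATGAAATAA", code = 9) # "MN*"
#' @export
translate_dna <- function(nt, code = 1) {
  nt <- stringr::str_to_upper(nt)
  n <- nchar(nt)
  if (n < 3L || n %% 3L != 0L) {
    stop("sequence length must be a positive multiple of 3", call. = FALSE)
  }
  tab <- genetic_code(code)
  starts <- seq(1L, n - 2L, by = 3L)
  aa <- unname(tab[substring(nt, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation with coordinate maps
#'
#' Translates a contig in all six reading frames. Frames +1..+3 read the
#' forward strand at offsets 0..2; frames -1..-3 read the reverse complement
#' likewise. Amino-acid positions in any frame can be mapped back to
#' forward-strand nucleotide intervals with [frame_to_contig()].
#'
#' @param contig Nucleotide sequence (>= 3 nt).
#' @param code NCBI translation table id. The search stage translates under
#'   the standard code; only ORF re-translation uses the mitochondrial table.
#' @return Tibble with columns `frame` (+1..+3, -1..-3) and `protein`.
#' @export
six_frame_translate <- function(contig, code = 1) {
  if (nchar(contig) < 3L) stop("contig shorter than 3 nt", call. = FALSE)
  contig <- stringr::str_to_upper(contig)
  rc <- revcomp(contig)
  tab <- genetic_code(code)
  one <- function(s, off) {
    n_cod <- (nchar(s) - off) %/% 3L
    if (n_cod < 1L) return("")
    starts <- off + seq(1L, by = 3L, length.out = n_cod)
    aa <- unname(tab[substring(s, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  tibble::tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    protein = c(
      one(contig, 0L), one(contig, 1L), one(contig, 2L),
      one(rc, 0L), one(rc, 1L), one(rc, 2L)
    )
  )
}

#' Map frame-local amino-acid coordinates to forward-strand nucleotides
#'
#' @param frame Reading frame in +1..+3, -1..-3.
#' @param aa_start,aa_end 0-based half-open amino-acid interval within the
#'   frame's translation.
#' @param contig_len Contig length in nucleotides.
#' @return List with `start` and `end`: the 0-based half-open forward-strand
#'   nucleotide interval covered by those residues.
#' @export
frame_to_contig <- function(frame, aa_start, aa_end, contig_len) {
  off <- abs(frame) - 1L
  s <- off + 3L * aa_start
  e <- off + 3L * aa_end
  if (frame > 0) {
    list(start = s, end = e)
  } else {
    list(start = contig_len - e, end = contig_len - s)
  }
}
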