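#' Protein scoring scheme
#'
#' Substitution matrix plus affine gap costs and Karlin-Altschul parameters
#' for e-value computation. Defaults are BLOSUM62 with BLAST-style gap costs
#' (a gap of length k costs `gap_open + k * gap_extend`) and the standard
#' published gapped-BLOSUM62 parameters lambda = 0.267, K = 0.041.
#'
#' @param matrix Substitution matrix (defaults to BLOSUM62).
#' @param gap_open,gap_extend Non-negative gap costs as applied.
#' @param lambda,k Karlin-Altschul parameters (nats per score unit;
#'   dimensionless).
#' @return List of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           lambda = 0.267, k = 0.041) {
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, k > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k = k),
            class = "scoring_scheme")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

aln_stats <- function(pattern_chars, subject_chars) {
  both_gap <- pattern_chars == "-" & subject_chars == "-"
  p <- pattern_chars[!both_gap]
  s <- subject_chars[!both_gap]
  cols <- length(p)
  matches <- sum(p == s & p != "-")
  gaps <- sum(p == "-" | s == "-")
  list(columns = cols, matches = matches, mismatches = cols - matches - gaps,
       gaps = gaps,
       pct_identity = if (cols > 0) 100 * matches / cols else NA_real_)
}

pa_to_alignment <- function(pa, type) {
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  st <- aln_stats(pc, sc)
  list(
    score = Biostrings::score(pa),
    pattern_aligned = paste(pc, collapse = ""),
    subject_aligned = paste(sc, collapse = ""),
    # 0-based half-open coordinates on the original sequences
    pattern_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
    pattern_end = Biostrings::end(Biostrings::pattern(pa)),
    subject_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
    subject_end = Biostrings::end(Biostrings::subject(pa)),
    columns = st$columns, matches = st$matches,
    mismatches = st$mismatches, gaps = st$gaps,
    pct_identity = st$pct_identity,
    type = type
  )
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' Exact affine-gap local alignment; desk-scale inputs make exactness
#' affordable, so no seed-and-extend heuristics are involved at this level.
#' A best score of zero or less is reported as "no hit" (`NULL`).
#'
#' @param query,subject Protein strings (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return List with score, aligned strings, 0-based half-open coordinates
#'   on both sequences, match/column counts and percent identity; or `NULL`
#'   when no positive-scoring local alignment exists.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  if (nchar(query) == 0 || nchar(subject) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  if (Biostrings::score(pa) <= 0) return(NULL)
  pa_to_alignment(pa, "local")
}

#' Optimal global (Needleman-Wunsch) protein alignment
#'
#' Affine-gap global alignment with end gaps charged. Defaults follow the
#' pairwise-comparison convention used for the identity matrix: BLOSUM62
#' with gap opening 10 and gap extension 0.2.
#'
#' @inheritParams local_align
#' @param gap_open,gap_extend Gap costs (override the scheme defaults).
#' @param matrix Substitution matrix.
#' @return Same shape as [local_align()] (never `NULL`).
#' @export
global_align <- function(query, subject, gap_open = 10, gap_extend = 0.2,
                         matrix = NULL) {
  if (nchar(query) == 0 || nchar(subject) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  if (is.null(matrix)) matrix <- blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa_to_alignment(pa, "global")
}

#' Percent identity of an alignment, SDT-style
#'
#' Identity is matches over alignment columns where at least one sequence
#' has a residue; columns where both sequences are gapped are excluded, and
#' gap-versus-residue columns count as differences (the p-distance
#' convention of pairwise-comparison distance matrices). Set
#' `ignore_gaps = TRUE` to count only residue-residue columns.
#'
#' @param alignment Result of [local_align()]/[global_align()], or a
#'   two-element character vector of aligned strings.
#' @param ignore_gaps Exclude gap columns from the denominator.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(alignment, ignore_gaps = FALSE) {
  if (is.list(alignment)) {
    strs <- c(alignment$pattern_aligned, alignment$subject_aligned)
  } else {
    strs <- alignment
  }
  stopifnot(length(strs) == 2, nchar(strs[1]) == nchar(strs[2]))
  p <- strsplit(strs[1], "")[[1]]
  s <- strsplit(strs[2], "")[[1]]
  keep <- !(p == "-" & s == "-")
  p <- p[keep]; s <- s[keep]
  if (ignore_gaps) {
    keep2 <- p != "-" & s != "-"
    p <- p[keep2]; s <- s[keep2]
  }
  if (length(p) == 0) stop("alignment has no scorable columns", call. = FALSE)
  100 * sum(p == s & p != "-") / length(p)
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' database of total length `n`.
#'
#' @param raw_score Alignment raw score `S`.
#' @param m Query length (> 0).
#' @param n Database length (> 0).
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return Expectation value (>= 0), vectorised over `raw_score`.
#' @export
evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  if (m <= 0 || n <= 0) stop("m and n must be positive", call. = FALSE)
  scheme$k * m * n * exp(-scheme$lambda * raw_score)
}

bitscore <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$k)) / log(2)
}
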