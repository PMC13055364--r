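scan_orfs_one_strand <- function(s, code_tab, min_len, strand, L) {
  out <- list()
  for (off in 0:2) {
    n_cod <- (nchar(s) - off) %/% 3L
    if (n_cod < 2L) next
    starts <- off + seq(1L, by = 3L, length.out = n_cod)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code_tab[codons])
    aa[is.na(aa)] <- "X"
    is_stop <- aa == "*"
    stops <- which(is_stop)
    if (length(stops) == 0) next
    # segment id = number of stops strictly before the codon
    seg <- cumsum(is_stop) - is_stop
    atg <- which(codons == "ATG")
    if (length(atg) == 0) next
    first_atg <- atg[!duplicated(seg[atg])]
    for (a in first_atg) {
      v <- seg[a]
      if (v + 1L > length(stops)) next       # runs off the contig edge
      stp <- stops[v + 1L]
      nt_len <- 3L * (stp - a + 1L)
      if (nt_len < min_len) next
      start0 <- off + 3L * (a - 1L)
      end0 <- off + 3L * stp
      protein <- paste(aa[a:(stp - 1L)], collapse = "")
      out[[length(out) + 1]] <- tibble::tibble(
        start = if (strand == "+") start0 else L - end0,
        end = if (strand == "+") end0 else L - start0,
        strand = strand, nt_len = nt_len, protein = protein
      )
    }
  }
  out
}

#' Predict open reading frames
#'
#' Finds every maximal ATG-to-stop segment of at least `min_len`
#' nucleotides (stop codon included) in all reading frames of both strands.
#' Within a stop-bounded frame segment the 5'-most ATG defines the reported
#' ORF. ORFs running off the contig edge (no in-frame stop) are excluded.
#' The default minimum of 702 nt is the ~700 nt floor rounded up to a codon
#' multiple.
#'
#' @param contig Nucleotide sequence, or an assembly tibble (`contig_id`,
#'   `seq`) to scan every contig.
#' @param code NCBI translation table (default 9, flatworm mitochondrial).
#' @param min_len Minimum ORF length in nt, stop included (default 702).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return Tibble with `contig_id`, `start`, `end` (0-based half-open,
#'   forward strand), `strand`, `nt_len`, `protein` (stop excluded) and
#'   `code`, sorted by (start, strand).
#' @export
find_orfs <- function(contig, code = 9, min_len = 702, both_strands = TRUE) {
  if (is.data.frame(contig)) {
    return(purrr::map_dfr(seq_len(nrow(contig)), function(i) {
      find_orfs(contig$seq[i], code, min_len, both_strands) |>
        dplyr::mutate(contig_id = contig$contig_id[i], .before = 1)
    }))
  }
  stopifnot(nchar(contig) > 0)
  contig <- stringr::str_to_upper(contig)
  code_tab <- genetic_code(code)
  L <- nchar(contig)
  res <- scan_orfs_one_strand(contig, code_tab, min_len, "+", L)
  if (both_strands) {
    res <- c(res, scan_orfs_one_strand(revcomp(contig), code_tab, min_len,
                                       "-", L))
  }
  if (length(res) == 0) {
    return(tibble::tibble(
      contig_id = character(), start = integer(), end = integer(),
      strand = character(), nt_len = integer(), protein = character(),
      code = integer()
    )[, -1])
  }
  dplyr::bind_rows(res) |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end),
                  nt_len = as.integer(.data$nt_len),
                  code = as.integer(code)) |>
    dplyr::arrange(.data$start, .data$strand)
}

#' Assign a translated hit to its containing ORF
#'
#' Returns the ORF (same contig, same strand) whose interval contains at
#' least `min_containment` of the hit interval; ties break toward the
#' longest ORF, then the smallest start. Hits contained in no qualifying
#' ORF get no assignment -- degraded elements without an intact ORF are
#' dropped rather than repaired.
#'
#' @param hits Hit tibble from [search_ns1()].
#' @param orfs ORF tibble from [find_orfs()] (with `contig_id`).
#' @param min_containment Minimum fraction of the hit interval inside the
#'   ORF (default 0.8).
#' @return `hits` with list-joined ORF columns (`orf_start`, `orf_end`,
#'   `orf_strand`, `nt_len`, `protein`, `code`); unassigned hits are
#'   dropped.
#' @export
assign_orfs <- function(hits, orfs, min_containment = 0.8) {
  if (nrow(hits) == 0) return(dplyr::bind_cols(hits, tibble::tibble(
    orf_start = integer(), orf_end = integer(), orf_strand = character(),
    nt_len = integer(), protein = character(), code = integer()
  )[0, ]))
  rows <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    strand <- if (h$frame > 0) "+" else "-"
    cand <- dplyr::filter(orfs, .data$contig_id == h$contig_id,
                          .data$strand == !!strand)
    if (nrow(cand) == 0) return(NULL)
    ov <- pmax(0L, pmin(cand$end, h$contig_end) - pmax(cand$start, h$contig_start))
    frac <- ov / (h$contig_end - h$contig_start)
    cand <- cand[frac >= min_containment, ]
    if (nrow(cand) == 0) return(NULL)
    cand <- dplyr::arrange(cand, dplyr::desc(.data$nt_len), .data$start)[1, ]
    dplyr::bind_cols(
      h,
      tibble::tibble(orf_start = cand$start, orf_end = cand$end,
                     orf_strand = cand$strand, nt_len = cand$nt_len,
                     protein = cand$protein, code = cand$code)
    )
  })
  if (is.null(rows)) rows <- hits[0, ]
  rows
}

#' Confirm a mined protein against the NS1 panel
#'
#' Best local alignment of the protein against every panel member; reports
#' the top subject with percent identity over alignment columns and
#' coverage as the aligned subject span over the subject length.
#'
#' @param protein Protein string.
#' @param panel Panel tibble or named character vector.
#' @param scheme A [scoring_scheme()].
#' @return One-row tibble: `best_subject`, `confirm_identity`,
#'   `confirm_coverage` (all `NA` if nothing aligns).
#' @export
confirm_ns1 <- function(protein, panel, scheme = scoring_scheme()) {
  panel <- as_panel(panel)
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  stopifnot(nchar(protein) > 0)
  best <- NULL
  for (i in seq_len(nrow(panel))) {
    aln <- local_align(protein, panel$protein[i], scheme = scheme)
    if (is.null(aln)) next
    if (is.null(best) || aln$score > best$score) {
      best <- aln
      best$subject_id <- panel$subject_id[i]
      best$subject_len <- nchar(panel$protein[i])
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(best_subject = NA_character_,
                          confirm_identity = NA_real_,
                          confirm_coverage = NA_real_))
  }
  tibble::tibble(
    best_subject = best$subject_id,
    confirm_identity = best$pct_identity,
    confirm_coverage = 100 * (best$subject_end - best$subject_start) /
      best$subject_len
  )
}

#' Mine NS1 loci from an assembly
#'
#' The full screening loop: six-frame translated search against the panel,
#' ORF prediction under the mitochondrial code on hit contigs, assignment
#' of each hit to its containing ORF, deduplication of hits resolving to
#' the same ORF, and BLASTP-style confirmation of each ORF translation
#' against the panel. Locus ids are `contig_id` (dots replaced by
#' underscores) plus a per-contig ordinal, e.g. `ctg_1_2`.
#'
#' @inheritParams search_ns1
#' @param code Translation table for ORF prediction/re-translation
#'   (default 9).
#' @param min_orf Minimum ORF length in nt (default 702).
#' @param min_containment Hit-in-ORF containment fraction (default 0.8).
#' @return Tibble of NS1 loci: `locus_id`, `species`, `contig_id`, `start`,
#'   `end`, `strand`, `nt_len`, `protein`, `code`, `best_subject`,
#'   `confirm_identity`, `confirm_coverage`, `clade` (NA placeholder).
#' @export
mine_loci <- function(assembly, panel, evalue_max = 1e-5, keep_top = 1,
                      code = 9, min_orf = 702, min_containment = 0.8,
                      scheme = scoring_scheme(), prefilter = TRUE) {
  assembly <- as_assembly(assembly)
  panel <- as_panel(panel)
  hits <- search_ns1(assembly, panel, evalue_max = evalue_max,
                     keep_top = keep_top, scheme = scheme,
                     prefilter = prefilter)
  if (nrow(hits) == 0) return(empty_loci())
  hit_contigs <- dplyr::filter(assembly, .data$contig_id %in% hits$contig_id)
  orfs <- find_orfs(hit_contigs, code = code, min_len = min_orf)
  assigned <- assign_orfs(hits, orfs, min_containment = min_containment)
  if (nrow(assigned) == 0) return(empty_loci())
  loci <- assigned |>
    dplyr::group_by(.data$contig_id, .data$orf_start, .data$orf_end,
                    .data$orf_strand) |>
    dplyr::slice_max(.data$raw_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::select(assembly, "species", "contig_id"),
                     by = "contig_id") |>
    dplyr::arrange(.data$contig_id, .data$orf_start) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::mutate(locus_id = sprintf("%s_%d",
                                     gsub("[.]", "_", .data$contig_id),
                                     dplyr::row_number())) |>
    dplyr::ungroup()
  conf <- purrr::map_dfr(loci$protein, confirm_ns1, panel = panel,
                         scheme = scheme)
  dplyr::bind_cols(
    dplyr::select(loci, "locus_id", "species", "contig_id",
                  start = "orf_start", end = "orf_end",
                  strand = "orf_strand", "nt_len", "protein", "code"),
    conf
  ) |>
    dplyr::mutate(clade = NA_character_)
}

empty_loci <- function() {
  tibble::tibble(
    locus_id = character(), species = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(),
    nt_len = integer(), protein = character(), code = integer(),
    best_subject = character(), confirm_identity = numeric(),
    confirm_coverage = numeric(), clade = character()
  )
}

#' Write mined loci as protein FASTA, BED6 and a confirmation TSV
#'
#' @param loci Locus tibble from [mine_loci()].
#' @param prefix Output path prefix; writes `<prefix>.faa`, `<prefix>.bed`
#'   and `<prefix>.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_loci <- function(loci, prefix) {
  aa <- Biostrings::AAStringSet(setNames(loci$protein, loci$locus_id))
  Biostrings::writeXStringSet(aa, paste0(prefix, ".faa"))
  bed <- tibble::tibble(
    chrom = loci$contig_id, start = loci$start, end = loci$end,
    name = loci$locus_id, score = round(loci$confirm_identity, 1),
    strand = loci$strand
  )
  readr::write_tsv(bed, paste0(prefix, ".bed"), col_names = FALSE)
  readr::write_tsv(dplyr::select(loci, -"protein"), paste0(prefix, ".tsv"))
  invisible(prefix)
}
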