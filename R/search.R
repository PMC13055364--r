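kmer_positions <- function(protein, k) {
  n <- nchar(protein)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  substring(protein, starts, starts + k - 1)
}

# Candidate regions of a frame translation sharing >= min_seeds k-mers with
# the subject. Positions are clustered; each cluster is padded by the
# subject length so the local alignment can extend freely.
seed_regions <- function(frame_protein, subject, k = 6, min_seeds = 2) {
  subj_kmers <- unique(kmer_positions(subject, k))
  if (length(subj_kmers) == 0) return(NULL)
  qk <- kmer_positions(frame_protein, k)
  hits <- which(qk %in% subj_kmers)
  if (length(hits) < min_seeds) return(NULL)
  gap <- nchar(subject)
  cluster <- cumsum(c(TRUE, diff(hits) > gap))
  keep <- split(hits, cluster)
  keep <- keep[vapply(keep, length, integer(1)) >= min_seeds]
  if (length(keep) == 0) return(NULL)
  pad <- nchar(subject) + 20L
  lapply(keep, function(pos) {
    c(start = max(1L, min(pos) - pad),
      end = min(nchar(frame_protein), max(pos) + k - 1L + pad))
  })
}

#' Six-frame translated homology search
#'
#' Searches every contig of an assembly against an NS1 protein panel:
#' contigs are translated in all six frames (standard code -- the panel
#' proteins are standard-code viral sequences), candidate regions are
#' located by a shared k-mer prefilter, scored by exact Smith-Waterman
#' local alignment, assigned Karlin-Altschul e-values, filtered at
#' `evalue_max`, and reduced so that each contig locus retains only its
#' `keep_top` best-scoring subjects (overlapping hits are merged, keeping
#' the higher score; ties break toward the lexicographically smaller
#' subject id).
#'
#' @param assembly Tibble with columns `contig_id`, `seq` (and optionally
#'   `species`), or a named character vector of contigs.
#' @param panel Tibble with columns `subject_id`, `protein`, or a named
#'   character vector of panel proteins.
#' @param evalue_max Maximum e-value retained (default 1e-5).
#' @param keep_top Subjects retained per locus (default 1).
#' @param scheme A [scoring_scheme()].
#' @param code Translation table used for the search-stage translation
#'   (default 1; the mitochondrial table only applies at ORF
#'   re-translation).
#' @param prefilter Use the k-mer prefilter (exact full-frame alignment is
#'   used when `FALSE`; only practical for short contigs).
#' @param k,min_seeds Prefilter parameters: k-mer size and minimum shared
#'   k-mers for a candidate region.
#' @return Tibble of hits: `contig_id`, `frame`, `subject_id`,
#'   `contig_start`/`contig_end` (0-based half-open, forward strand),
#'   `subject_start`/`subject_end` (0-based half-open, amino acids),
#'   `raw_score`, `bitscore`, `evalue`, `pct_identity`, `aln_len`,
#'   `mismatches`, `gaps`.
#' @export
search_ns1 <- function(assembly, panel, evalue_max = 1e-5, keep_top = 1,
                       scheme = scoring_scheme(), code = 1,
                       prefilter = TRUE, k = 6, min_seeds = 2) {
  assembly <- as_assembly(assembly)
  panel <- as_panel(panel)
  if (nrow(assembly) == 0 || nrow(panel) == 0) {
    stop("assembly and panel must be non-empty", call. = FALSE)
  }
  db_len <- sum(nchar(panel$protein))
  hits <- list()
  for (ci in seq_len(nrow(assembly))) {
    contig_id <- assembly$contig_id[ci]
    contig <- assembly$seq[ci]
    L <- nchar(contig)
    frames <- six_frame_translate(contig, code = code)
    for (fi in seq_len(nrow(frames))) {
      fp <- frames$protein[fi]
      frame <- frames$frame[fi]
      if (nchar(fp) == 0) next
      for (si in seq_len(nrow(panel))) {
        subj <- panel$protein[si]
        regions <- if (prefilter) {
          seed_regions(fp, subj, k = k, min_seeds = min_seeds)
        } else {
          list(c(start = 1L, end = nchar(fp)))
        }
        if (is.null(regions)) next
        for (reg in regions) {
          aln <- local_align(substr(fp, reg["start"], reg["end"]), subj,
                             scheme = scheme)
          if (is.null(aln)) next
          ev <- evalue(aln$score, m = nchar(fp), n = db_len, scheme = scheme)
          if (ev > evalue_max) next
          aa_start <- (reg["start"] - 1L) + aln$pattern_start
          aa_end <- (reg["start"] - 1L) + aln$pattern_end
          nt <- frame_to_contig(frame, aa_start, aa_end, L)
          hits[[length(hits) + 1]] <- tibble::tibble(
            contig_id = contig_id, frame = frame,
            subject_id = panel$subject_id[si],
            contig_start = as.integer(nt$start),
            contig_end = as.integer(nt$end),
            subject_start = as.integer(aln$subject_start),
            subject_end = as.integer(aln$subject_end),
            raw_score = aln$score,
            bitscore = bitscore(aln$score, scheme),
            evalue = ev,
            pct_identity = aln$pct_identity,
            aln_len = as.integer(aln$columns),
            mismatches = as.integer(aln$mismatches),
            gaps = as.integer(aln$gaps)
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(empty_hits())
  }
  dplyr::bind_rows(hits) |>
    merge_hits(keep_top = keep_top) |>
    dplyr::arrange(.data$contig_id, .data$contig_start, .data$subject_id)
}

empty_hits <- function() {
  tibble::tibble(
    contig_id = character(), frame = integer(), subject_id = character(),
    contig_start = integer(), contig_end = integer(),
    subject_start = integer(), subject_end = integer(),
    raw_score = numeric(), bitscore = numeric(), evalue = numeric(),
    pct_identity = numeric(), aln_len = integer(),
    mismatches = integer(), gaps = integer()
  )
}

# Greedy per-contig reduction: hits are taken in decreasing score order
# (ties by subject_id) and kept unless they overlap an already-kept hit by
# more than half of the shorter interval, up to keep_top per locus.
merge_hits <- function(hits, keep_top = 1) {
  hits |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, dplyr::desc(.data$raw_score), .data$subject_id)
      kept <- logical(nrow(df))
      for (i in seq_len(nrow(df))) {
        over <- 0L
        for (j in which(kept)) {
          ov <- min(df$contig_end[i], df$contig_end[j]) -
            max(df$contig_start[i], df$contig_start[j])
          shorter <- min(df$contig_end[i] - df$contig_start[i],
                         df$contig_end[j] - df$contig_start[j])
          if (ov > 0.5 * shorter) over <- over + 1L
        }
        if (over < keep_top) kept[i] <- TRUE
      }
      df[kept, ]
    }) |>
    dplyr::ungroup()
}

#' Write hits as BLAST tabular (outfmt 6) TSV
#'
#' Standard 12-column BLAST tabular format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) with 1-based
#' inclusive coordinates in this file only; the in-memory representation
#' stays 0-based half-open.
#'
#' @param hits Hit tibble from [search_ns1()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outfmt6 <- function(hits, path) {
  out <- tibble::tibble(
    qseqid = hits$contig_id, sseqid = hits$subject_id,
    pident = round(hits$pct_identity, 3), length = hits$aln_len,
    mismatch = hits$mismatches, gapopen = hits$gaps,
    qstart = hits$contig_start + 1L, qend = hits$contig_end,
    sstart = hits$subject_start + 1L, send = hits$subject_end,
    evalue = signif(hits$evalue, 3), bitscore = round(hits$bitscore, 1)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

as_assembly <- function(x) {
  if (is.character(x)) {
    x <- tibble::tibble(
      species = NA_character_,
      contig_id = if (is.null(names(x))) paste0("contig_", seq_along(x)) else names(x),
      seq = unname(x)
    )
  }
  stopifnot(all(c("contig_id", "seq") %in% names(x)))
  if (!"species" %in% names(x)) x$species <- NA_character_
  tibble::as_tibble(x)
}

as_panel <- function(x) {
  if (is.character(x)) {
    x <- tibble::tibble(
      subject_id = if (is.null(names(x))) paste0("subject_", seq_along(x)) else names(x),
      protein = unname(x)
    )
  }
  stopifnot(all(c("subject_id", "protein") %in% names(x)))
  tibble::as_tibble(x)
}

#' Read an assembly or protein panel from FASTA
#'
#' Assembly headers of the form `species|contig_id` populate the species
#' column; other headers become contig ids with no species.
#'
#' @param files FASTA file path(s).
#' @return Tibble in the package's assembly/panel shape.
#' @export
read_assembly <- function(files) {
  purrr::map_dfr(files, function(f) {
    x <- Biostrings::readDNAStringSet(f)
    hdr <- names(x)
    has_sp <- grepl("|", hdr, fixed = TRUE)
    tibble::tibble(
      species = ifelse(has_sp, sub("\\|.*$", "", hdr), NA_character_),
      contig_id = ifelse(has_sp, sub("^[^|]*\\|", "", hdr), hdr),
      seq = unname(as.character(x))
    )
  })
}

#' @rdname read_assembly
#' @export
read_panel <- function(files) {
  purrr::map_dfr(files, function(f) {
    x <- Biostrings::readAAStringSet(f)
    tibble::tibble(subject_id = names(x), protein = unname(as.character(x)))
  })
}
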