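#' Pairwise identity matrix over NS1 proteins
#'
#' Aligns every pair globally (BLOSUM62, gap opening 10, gap extension 0.2)
#' and records SDT-style percent identity (gaps count as differences;
#' dual-gap columns excluded). Sequences shorter than `min_len` residues
#' are excluded up front to avoid alignment artifacts from fragments. The
#' display order is the leaf order of a midpoint-rooted neighbour-joining
#' tree on `100 - identity` distances -- presentation plumbing, not a
#' phylogenetic claim.
#'
#' @param proteins Named character vector of proteins, or a locus tibble
#'   with `locus_id` and `protein`.
#' @param min_len Minimum protein length in residues (default 400).
#' @param gap_open,gap_extend Global alignment gap costs.
#' @param ignore_gaps Passed to [pairwise_identity()].
#' @return Object of class `identity_matrix`: `labels`, `values` (symmetric
#'   percent matrix, diagonal 100), `order` (clustering permutation),
#'   `tree` (the ordering `phylo`, or NULL for < 3 sequences).
#' @export
build_identity_matrix <- function(proteins, min_len = 400, gap_open = 10,
                                  gap_extend = 0.2, ignore_gaps = FALSE) {
  if (is.data.frame(proteins)) {
    proteins <- setNames(proteins$protein, proteins$locus_id)
  }
  proteins <- proteins[nchar(proteins) >= min_len]
  n <- length(proteins)
  if (n < 2) stop("fewer than 2 sequences survive the length filter",
                  call. = FALSE)
  labels <- names(proteins)
  values <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(proteins[[i]], proteins[[j]],
                          gap_open = gap_open, gap_extend = gap_extend)
      id <- pairwise_identity(aln, ignore_gaps = ignore_gaps)
      values[i, j] <- id
      values[j, i] <- id
    }
  }
  tree <- NULL
  ord <- labels
  if (n >= 3) {
    tree <- phangorn::midpoint(ape::nj(stats::as.dist(100 - values)))
    tree <- ape::ladderize(tree)
    edge_tips <- tree$edge[tree$edge[, 2] <= n, 2]
    ord <- tree$tip.label[edge_tips]
  }
  structure(list(labels = labels, values = values, order = ord, tree = tree),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("identity matrix over %d sequences (%%)\n", length(x$labels)))
  print(round(x$values[x$order, x$order], 1))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.identity_matrix <- function(x, ...) {
  m <- x$values
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    id_a = rownames(m)[pairs[, 1]],
    id_b = colnames(m)[pairs[, 2]],
    identity = m[pairs]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.identity_matrix <- function(object, ...) {
  m <- object$values[object$order, object$order]
  df <- tibble::as_tibble(as.table(m), .name_repair = ~ c("id_a", "id_b", "identity"))
  df$id_a <- factor(df$id_a, levels = object$order)
  df$id_b <- factor(df$id_b, levels = rev(object$order))
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% identity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' ICTV-style demarcation of a sequence pair
#'
#' Parvoviridae demarcation applied to NS1: the same species requires
#' identity above `species_id` percent with coverage above `species_cov`
#' percent; identity at or above `genus_floor` without meeting the species
#' rule is genus-level relatedness; identity below the genus floor is
#' distinct.
#'
#' @param identity,coverage Percent values in `[0, 100]` (vectorised).
#' @param species_id,species_cov,genus_floor Thresholds (defaults 85, 80,
#'   35; the genus floor default takes the lower end of the published
#'   35-40 percent range).
#' @return Tibble with `identity`, `coverage`, `level` (factor:
#'   same_species, same_genus, distinct).
#' @export
classify_pair <- function(identity, coverage, species_id = 85,
                          species_cov = 80, genus_floor = 35) {
  if (any(identity < 0 | identity > 100 | coverage < 0 | coverage > 100)) {
    stop("identity and coverage must be in [0, 100]", call. = FALSE)
  }
  level <- dplyr::case_when(
    identity > species_id & coverage > species_cov ~ "same_species",
    identity >= genus_floor ~ "same_genus",
    TRUE ~ "distinct"
  )
  tibble::tibble(
    identity = identity, coverage = coverage,
    level = factor(level, levels = c("same_species", "same_genus", "distinct"))
  )
}

#' Flag a putative novel taxon
#'
#' A focal sequence whose maximum identity to every other matrix member
#' falls below `cutoff` percent is flagged as a candidate new species.
#'
#' @param im An `identity_matrix`.
#' @param focal_id Label of the focal sequence.
#' @param cutoff Identity percent (default 75).
#' @return One-row tibble: `focal_id`, `max_identity`, `novel`.
#' @export
flag_novel <- function(im, focal_id, cutoff = 75) {
  if (!focal_id %in% im$labels) stop("focal sequence not in matrix",
                                     call. = FALSE)
  others <- setdiff(im$labels, focal_id)
  mx <- max(im$values[focal_id, others])
  tibble::tibble(focal_id = focal_id, max_identity = mx, novel = mx < cutoff)
}

#' Trim poorly aligned alignment columns
#'
#' Drops columns whose modal non-gap residue occurs in fewer than
#' `min_consensus` percent of the non-gap rows (and all-gap columns),
#' the usual manual-trimming rule for consensus support.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param min_consensus Consensus percent threshold (default 50).
#' @return Trimmed alignment in the same format; attribute `kept` holds the
#'   retained column indices.
#' @export
trim_columns <- function(msa, min_consensus = 50) {
  stopifnot(length(msa) > 0)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) stop("alignment is not rectangular",
                                      call. = FALSE)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  keep <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (length(res) == 0) return(FALSE)
    100 * max(table(res)) / length(res) >= min_consensus
  }, logical(1))
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- setNames(out, names(msa))
  attr(out, "kept") <- which(keep)
  out
}
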