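#' Build a structure model
#'
#' Minimal container for a C-alpha model: ordered residues with one-letter
#' amino acids and coordinates, plus optional model-confidence metadata.
#'
#' @param model_id Identifier.
#' @param sequence Amino-acid string.
#' @param coords n x 3 numeric matrix of C-alpha coordinates (angstroms).
#' @param ptm,iptm Optional predicted-TM confidence scores.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(model_id, sequence, coords, ptm = NA_real_,
                            iptm = NA_real_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == nchar(sequence),
            all(is.finite(coords)))
  structure(list(model_id = model_id, sequence = sequence, coords = coords,
                 ptm = ptm, iptm = iptm),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure model %s: %d residues (pTM %s, ipTM %s)\n",
              x$model_id, nrow(x$coords),
              ifelse(is.na(x$ptm), "-", format(x$ptm)),
              ifelse(is.na(x$iptm), "-", format(x$iptm))))
  invisible(x)
}

#' Read a C-alpha model from PDB/mmCIF
#'
#' Thin wrapper over bio3d's readers; an optional JSON sidecar supplies
#' pTM/ipTM metadata (keys `ptm`, `iptm`).
#'
#' @param path PDB or mmCIF file.
#' @param model_id Identifier (defaults to the file name).
#' @param metadata Optional JSON sidecar path.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, model_id = basename(path), metadata = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("bio3d is required to read structure files", call. = FALSE)
  }
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  ca <- bio3d::atom.select(pdb, "calpha")
  atoms <- pdb$atom[ca$atom, ]
  seq1 <- paste(bio3d::aa321(atoms$resid), collapse = "")
  ptm <- iptm <- NA_real_
  if (!is.null(metadata)) {
    md <- jsonlite::read_json(metadata)
    ptm <- md$ptm %||% NA_real_
    iptm <- md$iptm %||% NA_real_
  }
  structure_model(model_id, seq1,
                  as.matrix(atoms[, c("x", "y", "z")]),
                  ptm = as.numeric(ptm), iptm = as.numeric(iptm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter models on confidence metadata
#'
#' Strict thresholds: models are kept when pTM exceeds `ptm_min` and ipTM
#' exceeds `iptm_min`. Models without metadata are retained with a
#' message -- the filter cannot be applied to them.
#'
#' @param models List of `structure_model`s.
#' @param ptm_min,iptm_min Strict lower bounds (defaults 0.5 and 0.8).
#' @return Filtered list.
#' @export
qc_filter <- function(models, ptm_min = 0.5, iptm_min = 0.8) {
  keep <- vapply(models, function(m) {
    if (is.na(m$ptm) && is.na(m$iptm)) {
      message("model ", m$model_id, ": no confidence metadata, retained")
      return(TRUE)
    }
    (is.na(m$ptm) || m$ptm > ptm_min) && (is.na(m$iptm) || m$iptm > iptm_min)
  }, logical(1))
  models[keep]
}

#' Residue correspondence between two models
#'
#' Global alignment of the two amino-acid sequences; aligned residue pairs
#' (both non-gap) define the matched C-alpha sets used for superposition.
#'
#' @param a,b `structure_model`s.
#' @return Tibble with 1-based residue indices `idx_a`, `idx_b`.
#' @export
residue_correspondence <- function(a, b) {
  if (nchar(a$sequence) == 0 || nchar(b$sequence) == 0) {
    stop("empty model", call. = FALSE)
  }
  aln <- global_align(a$sequence, b$sequence)
  pa <- strsplit(aln$pattern_aligned, "")[[1]]
  sa <- strsplit(aln$subject_aligned, "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(sa != "-")
  both <- pa != "-" & sa != "-"
  out <- tibble::tibble(idx_a = ia[both], idx_b = ib[both])
  if (nrow(out) == 0) stop("no aligned residue pairs", call. = FALSE)
  out
}

#' Kabsch superposition RMSD
#'
#' Closed-form least-squares rigid superposition of paired points:
#' centroids removed, rotation from the SVD of the covariance with the
#' determinant sign corrected so only proper rotations (no reflections)
#' are allowed. No outlier rejection cycles are applied.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (n >= 3).
#' @return List: `rmsd` (angstroms), `rotation` (3 x 3, applied to centred
#'   B), `translation`, `n_pairs`.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  stopifnot(ncol(a) == 3, ncol(b) == 3)
  n <- nrow(a)
  if (n < 3 || nrow(b) != n) stop("need >= 3 paired points", call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(b0, a0))         # rotate B onto A
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  b_fit <- b0 %*% rot
  list(
    rmsd = sqrt(mean(rowSums((a0 - b_fit)^2))),
    rotation = rot,
    translation = ca - cb %*% rot,
    n_pairs = n
  )
}

#' Classify an RMSD into similarity bands
#'
#' At most 2.0 angstroms is highly similar, above 2.0 up to 3.0 moderately
#' similar, above 3.0 significantly divergent.
#'
#' @param rmsd Non-negative RMSD value(s).
#' @return Factor with levels highly_similar, moderately_similar,
#'   significantly_divergent.
#' @export
classify_rmsd <- function(rmsd) {
  if (any(rmsd < 0)) stop("RMSD cannot be negative", call. = FALSE)
  cut(rmsd, breaks = c(-Inf, 2, 3, Inf),
      labels = c("highly_similar", "moderately_similar",
                 "significantly_divergent"))
}

#' Screen a spatial domain around seed residues
#'
#' Selects residues whose C-alpha lies within `cutoff` angstroms of any
#' seed residue's C-alpha, unions the seeds, and prunes non-seed
#' contiguous runs shorter than 3 residues (isolated spatial contacts are
#' not domain evidence).
#'
#' @param model A `structure_model`.
#' @param seed_residues 1-based residue indices.
#' @param cutoff Distance threshold in angstroms (default 5).
#' @return Sorted integer vector of residue indices.
#' @export
screen_domain <- function(model, seed_residues, cutoff = 5) {
  if (length(seed_residues) == 0) stop("empty seed set", call. = FALSE)
  n <- nrow(model$coords)
  stopifnot(all(seed_residues >= 1), all(seed_residues <= n))
  seeds <- unique(as.integer(seed_residues))
  d2 <- vapply(seeds, function(s) {
    rowSums(sweep(model$coords, 2, model$coords[s, ])^2)
  }, numeric(n))
  sel <- sort(unique(c(seeds, which(apply(d2 <= cutoff^2, 1, any)))))
  runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
  keep <- unlist(lapply(runs, function(r) {
    if (length(r) >= 3 || any(r %in% seeds)) r else integer(0)
  }), use.names = FALSE)
  sort(keep)
}

#' Walker-A (P-loop) seed residues
#'
#' Finds G-x(4)-G-K-[T/S] motif matches on a model's sequence -- the
#' canonical ATPase-domain anchor of the SF3 helicase -- and returns the
#' covered residue indices for use as [screen_domain()] seeds.
#'
#' @param model A `structure_model` (or an amino-acid string).
#' @return Integer vector of residue indices (possibly empty).
#' @export
walker_a_seeds <- function(model) {
  seq <- if (inherits(model, "structure_model")) model$sequence else model
  m <- gregexpr("G.{4}GK[TS]", seq)[[1]]
  if (m[1] == -1) return(integer(0))
  unlist(lapply(seq_along(m), function(i) {
    m[i]:(m[i] + attr(m, "match.length")[i] - 1L)
  }))
}

#' Superpose two models globally and per domain
#'
#' Residue correspondence by sequence alignment, global Kabsch RMSD over
#' all matched C-alphas, then per-domain RMSD and similarity class for
#' each labelled residue set.
#'
#' @param a,b `structure_model`s.
#' @param domains Named list of residue-index vectors on model `a` (e.g.
#'   from [screen_domain()]); may be empty.
#' @return Object of class `superposition`: `pair`, `n_pairs`,
#'   `global_rmsd`, `domains` (tibble: domain, n_pairs, rmsd, class).
#' @export
compare_structures <- function(a, b, domains = list()) {
  corr <- residue_correspondence(a, b)
  glob <- kabsch_rmsd(a$coords[corr$idx_a, , drop = FALSE],
                      b$coords[corr$idx_b, , drop = FALSE])
  dom <- purrr::imap_dfr(domains, function(idx, label) {
    sub <- corr[corr$idx_a %in% idx, ]
    if (nrow(sub) < 3) {
      return(tibble::tibble(domain = label, n_pairs = nrow(sub),
                            rmsd = NA_real_, class = NA_character_))
    }
    k <- kabsch_rmsd(a$coords[sub$idx_a, , drop = FALSE],
                     b$coords[sub$idx_b, , drop = FALSE])
    tibble::tibble(domain = label, n_pairs = k$n_pairs, rmsd = k$rmsd,
                   class = as.character(classify_rmsd(k$rmsd)))
  })
  structure(
    list(pair = c(a$model_id, b$model_id), n_pairs = glob$n_pairs,
         global_rmsd = glob$rmsd, domains = dom),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition %s vs %s: global RMSD %.3f A over %d CA (%s)\n",
              x$pair[1], x$pair[2], x$global_rmsd, x$n_pairs,
              as.character(classify_rmsd(x$global_rmsd))))
  if (nrow(x$domains) > 0) print(x$domains)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.superposition <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(domain = "global", n_pairs = x$n_pairs,
                   rmsd = x$global_rmsd,
                   class = as.character(classify_rmsd(x$global_rmsd))),
    x$domains
  )
}
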