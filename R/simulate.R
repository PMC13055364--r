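AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Defaults emulate the
#' study system: multi-contig flatworm-like host scaffolds with planted
#' NS1-like ORFs whose coding regions sit near 41.84% GC, flanked by an
#' AT-rich upstream flank (15.52% GC) and a moderate-GC downstream flank,
#' with 300 bp flanks, paralogous duplicates and lineage divergence on a
#' known tree.
#'
#' @param n_species Number of synthetic host species.
#' @param contigs_per_species Contigs per species.
#' @param contig_length Contig length in nt.
#' @param background_gc Background (host) GC percent.
#' @param ns1_gc Target GC percent of planted NS1 coding regions.
#' @param left_flank_gc,right_flank_gc GC percent of the regenerated flanks,
#'   in ORF orientation (left = upstream of the start codon).
#' @param flank_len Flank length in nt (default 300).
#' @param orf_len ORF length in nt including the stop codon; the default
#'   1947 nt (649 codons) yields 648-residue proteins.
#' @param n_loci Total planted loci across all species.
#' @param n_paralog_groups Number of species whose loci are identical
#'   paralogous copies of a single ORF.
#' @param divergence_tree Newick string or `phylo` for the between-species
#'   NS1 divergence; `NULL` draws a coalescent tree scaled to `tree_depth`.
#' @param tree_depth Root-to-tip depth (substitutions/site) used when
#'   drawing the default tree.
#' @param within_species_rate Extra divergence (subs/site) applied per locus
#'   within a species, so non-paralogous loci are distinct.
#' @param code NCBI translation table governing stop semantics of the
#'   planted ORFs (default 9, flatworm mitochondrial; planted codons are
#'   chosen to translate identically under tables 1 and 9 unless
#'   `dual_code = FALSE`).
#' @param dual_code If `TRUE` (default) planted ORFs avoid the codons whose
#'   meaning differs between tables 1 and 9, so that screening under the
#'   standard code and re-translation under table 9 agree.
#' @param seed Integer seed; a fixed seed makes the whole simulation
#'   byte-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10, contigs_per_species = 2,
                       contig_length = 1e5, background_gc = 40,
                       ns1_gc = 41.84, left_flank_gc = 15.52,
                       right_flank_gc = 44, flank_len = 300,
                       orf_len = 1947, n_loci = 30, n_paralog_groups = 3,
                       divergence_tree = NULL, tree_depth = 0.25,
                       within_species_rate = 0.02, code = 9,
                       dual_code = TRUE, seed = 1) {
  pct <- c(background_gc, ns1_gc, left_flank_gc, right_flank_gc)
  stopifnot(all(pct >= 0 & pct <= 100), orf_len %% 3 == 0, n_loci >= n_species)
  structure(as.list(environment()), class = "sim_config")
}

#' Random background scaffold
#'
#' I.i.d. bases with the GC fraction split evenly between G and C and the
#' AT fraction split evenly between A and T. The simplest null background:
#' no repeats, no isochores.
#'
#' @param length Scaffold length in nt (> 0).
#' @param gc GC percent in `[0, 100]`.
#' @param seed Optional integer seed.
#' @return A nucleotide string.
#' @export
make_scaffold <- function(length, gc, seed = NULL) {
  if (length <= 0) stop("length must be positive", call. = FALSE)
  stopifnot(gc >= 0, gc <= 100)
  g <- gc / 200
  a <- (100 - gc) / 200
  with_seed(seed, paste(
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c(a, a, g, g)),
    collapse = ""
  ))
}

# Shared Poisson substitution engine over an arbitrary alphabet.
evolve_on_tree <- function(root, tree, rate, alphabet) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root_node]] <- strsplit(root, "", fixed = TRUE)[[1]]
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1]
    child <- ord$edge[i, 2]
    s <- seqs[[parent]]
    n_sub <- stats::rpois(1, ord$edge.length[i] * rate * length(s))
    if (n_sub > 0) {
      pos <- sample.int(length(s), n_sub, replace = TRUE)
      for (p in pos) {
        s[p] <- sample(setdiff(alphabet, s[p]), 1)
      }
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, tree$tip.label)
}

#' Evolve sequences along a tree
#'
#' Per-branch substitution counts are Poisson with mean
#' `branch_length * rate * sequence_length`; each substitution replaces a
#' uniformly chosen site with a uniformly chosen different state
#' (Jukes-Cantor-style for nucleotides, the analogous uniform model for
#' amino acids). Used to derive divergent NS1 lineages and null families
#' for the recombination detectors.
#'
#' @param root Root sequence (amino acids for `evolve_protein`, nucleotides
#'   for `evolve_dna`).
#' @param tree Newick string or `phylo` with branch lengths.
#' @param rate Substitutions per site per unit branch length.
#' @param seed Optional seed.
#' @return Named character vector of tip sequences.
#' @export
evolve_protein <- function(root, tree, rate = 1, seed = NULL) {
  stopifnot(nchar(root) > 0)
  with_seed(seed, evolve_on_tree(root, tree, rate, AA20))
}

#' @rdname evolve_protein
#' @export
evolve_dna <- function(root, tree, rate = 1, seed = NULL) {
  stopifnot(nchar(root) > 0)
  with_seed(seed, evolve_on_tree(root, tree, rate, c("A", "C", "G", "T")))
}

# Codons usable for planting: synonymous under the standard code, and (for
# dual_code) translating to the same residue under table 9, i.e. avoiding
# AAA, AGA, AGG and TGA.
planting_codons <- function(dual_code = TRUE) {
  gc1 <- genetic_code(1)
  if (dual_code) {
    gc9 <- genetic_code(9)
    gc1 <- gc1[gc1 == gc9[names(gc1)]]
  }
  split(names(gc1), unname(gc1))
}

# Solve for the per-base GC weight q such that weighted codon choice hits
# the target GC of the coding region. Weights on a codon with k G/C bases
# are q^k (1-q)^(3-k); expected GC is monotone in q.
solve_codon_gc <- function(protein, target_gc, codon_sets) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  counts <- table(aas)
  kgc <- lapply(codon_sets, function(cs) stringr::str_count(cs, "[GC]"))
  exp_gc <- function(q) {
    per_aa <- vapply(names(counts), function(a) {
      k <- kgc[[a]]
      w <- q^k * (1 - q)^(3 - k)
      sum(w * k) / sum(w) / 3
    }, numeric(1))
    sum(per_aa * as.numeric(counts)) / sum(counts)
  }
  lo <- exp_gc(1e-4); hi <- exp_gc(1 - 1e-4)
  target <- min(max(target_gc / 100, lo + 1e-9), hi - 1e-9)
  stats::uniroot(function(q) exp_gc(q) - target, c(1e-4, 1 - 1e-4))$root
}

#' Back-translate a protein into a plantable ORF
#'
#' Chooses synonymous codons with a GC bias calibrated (by root finding on
#' the expected GC) so the coding region lands on `gc` on average, appends
#' a TAA stop, and by default restricts to codons that translate
#' identically under NCBI tables 1 and 9 so the ORF survives both the
#' standard-code screening translation and the mitochondrial re-translation.
#'
#' @param protein Amino-acid string; must start with M.
#' @param gc Target GC percent of the coding region.
#' @param dual_code Restrict to table-1/table-9 compatible codons.
#' @param seed Optional seed.
#' @return Nucleotide string of length `3 * (nchar(protein) + 1)`.
#' @export
backtranslate <- function(protein, gc = 41.84, dual_code = TRUE, seed = NULL) {
  stopifnot(nchar(protein) > 0, startsWith(protein, "M"))
  sets <- planting_codons(dual_code)
  q <- solve_codon_gc(protein, gc, sets[AA20[AA20 %in% names(sets)]])
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    codons <- vapply(aas, function(a) {
      cs <- sets[[a]]
      if (is.null(cs)) stop("cannot encode residue ", a, call. = FALSE)
      if (length(cs) == 1) return(cs)
      k <- stringr::str_count(cs, "[GC]")
      sample(cs, 1, prob = q^k * (1 - q)^(3 - k))
    }, character(1))
    paste(c(codons, "TAA"), collapse = "")
  })
}

check_orf_contract <- function(orf_nt, code) {
  n <- nchar(orf_nt)
  if (n %% 3 != 0 || n < 6) stop("ORF length must be a multiple of 3 (>= 6 nt)",
                                 call. = FALSE)
  aa <- translate_dna(orf_nt, code)
  if (!startsWith(orf_nt, "ATG")) stop("ORF must start with ATG", call. = FALSE)
  if (!endsWith(aa, "*")) stop("ORF must end in a stop codon under table ",
                               code, call. = FALSE)
  if (stringr::str_count(aa, "\\*") != 1) {
    stop("ORF contains an internal stop codon", call. = FALSE)
  }
  invisible(aa)
}

#' Plant an NS1-like ORF into a scaffold
#'
#' Overwrites `[position, position + nchar(orf_nt))` with the ORF (its
#' reverse complement for minus-strand plants) and regenerates `flank_len`
#' nt on either side at the requested flank GC values, oriented relative to
#' the ORF (left = upstream of ATG). The last codon slot of the upstream
#' flank is set to an in-frame TAA so the planted ATG is the 5'-most start
#' of its stop-bounded segment and mined coordinates are exact.
#'
#' @param scaffold Host scaffold string.
#' @param orf_nt ORF nucleotides: ATG start, single terminal stop under
#'   `code`, no internal stops.
#' @param position 0-based forward-strand start of the ORF.
#' @param strand `"+"` or `"-"`.
#' @param flank_len,left_flank_gc,right_flank_gc Flank specification.
#' @param code Translation table for the ORF contract check.
#' @param contig_id,species,paralog_group Metadata copied into the truth
#'   record.
#' @param seed Optional seed for the regenerated flanks.
#' @return List with `contig` (modified scaffold) and `truth` (one-row
#'   tibble: contig_id, species, orf_start, orf_end, strand, protein,
#'   left_flank_gc, right_flank_gc, paralog_group).
#' @export
plant_eve <- function(scaffold, orf_nt, position, strand = "+",
                      flank_len = 300, left_flank_gc = 15.52,
                      right_flank_gc = 44, code = 9,
                      contig_id = "contig_1", species = "species_1",
                      paralog_group = 1L, seed = NULL) {
  orf_len <- nchar(orf_nt)
  L <- nchar(scaffold)
  if (position < flank_len || position + orf_len + flank_len > L) {
    stop("ORF plus flanks does not fit in the scaffold at this position",
         call. = FALSE)
  }
  aa <- check_orf_contract(orf_nt, code)
  protein <- sub("\\*$", "", aa)
  with_seed(seed, {
    left <- make_scaffold(flank_len, left_flank_gc)
    right <- make_scaffold(flank_len, right_flank_gc)
    # in-frame stop guard immediately upstream of the ATG
    substr(left, flank_len - 2, flank_len) <- "TAA"
    insert <- if (strand == "+") {
      paste0(left, orf_nt, right)
    } else {
      paste0(revcomp(right), revcomp(orf_nt), revcomp(left))
    }
    contig <- paste0(
      substr(scaffold, 1, position - flank_len),
      insert,
      substr(scaffold, position + orf_len + flank_len + 1, L)
    )
    list(
      contig = contig,
      truth = tibble::tibble(
        contig_id = contig_id, species = species,
        orf_start = as.integer(position), orf_end = as.integer(position + orf_len),
        strand = strand, protein = protein,
        left_flank_gc = left_flank_gc, right_flank_gc = right_flank_gc,
        paralog_group = as.integer(paralog_group)
      )
    )
  })
}

#' Build a recombinant mosaic of two aligned sequences
#'
#' Segments alternate between the parents starting with parent A; a
#' breakpoint at position `k` (1-based) means positions up to `k` come from
#' the current parent and the switch happens after it.
#'
#' @param parent_a,parent_b Aligned sequences of equal length.
#' @param breakpoints Sorted 1-based positions strictly inside the
#'   alignment; empty means no recombination (parent A returned).
#' @return The mosaic sequence.
#' @export
make_mosaic <- function(parent_a, parent_b, breakpoints = integer(0)) {
  n <- nchar(parent_a)
  if (nchar(parent_b) != n) stop("parents must have equal length", call. = FALSE)
  if (length(breakpoints) == 0) return(parent_a)
  stopifnot(!is.unsorted(breakpoints), all(breakpoints >= 1), all(breakpoints < n))
  bounds <- c(0, breakpoints, n)
  a <- strsplit(parent_a, "", fixed = TRUE)[[1]]
  b <- strsplit(parent_b, "", fixed = TRUE)[[1]]
  out <- a
  for (i in seq_len(length(bounds) - 1)) {
    if (i %% 2 == 0) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      out[idx] <- b[idx]
    }
  }
  paste(out, collapse = "")
}

euler_rotation <- function(angles) {
  cz <- cos(angles[3]); sz <- sin(angles[3])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[1]); sx <- sin(angles[1])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Paired toy C-alpha traces with known superposition RMSD
#'
#' The first set is a random 3.8-angstrom-step chain; the second is the
#' first rotated (Euler angles), translated, and perturbed by i.i.d.
#' Gaussian noise. `expected_rmsd` is the noise RMSD after optimal
#' superposition, `perturb_sd * sqrt(3 * (1 - 2/n))` (superposition fits 6
#' rigid-body parameters, absorbing about 2 coordinate variances per axis).
#'
#' @param n_residues Number of residues (>= 3).
#' @param perturb_sd Per-coordinate Gaussian noise SD in angstroms.
#' @param rotation Euler angles (radians), length 3.
#' @param translation Offset vector, length 3.
#' @param seed Optional seed.
#' @return List with matrices `a`, `b` (n x 3) and `expected_rmsd`.
#' @export
make_structure_pair <- function(n_residues, perturb_sd = 0,
                                rotation = c(0, 0, 0),
                                translation = c(0, 0, 0), seed = NULL) {
  if (n_residues < 3) stop("need at least 3 residues", call. = FALSE)
  with_seed(seed, {
    steps <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 3.8
    a <- apply(steps, 2, cumsum)
    r <- euler_rotation(rotation)
    noise <- matrix(stats::rnorm(3 * n_residues, sd = perturb_sd), ncol = 3)
    b <- a %*% t(r) + matrix(translation, n_residues, 3, byrow = TRUE) + noise
    list(
      a = a, b = b,
      expected_rmsd = perturb_sd * sqrt(3 * max(0, 1 - 2 / n_residues))
    )
  })
}

#' Simulate a full synthetic study
#'
#' Generates host assemblies with planted NS1-like ORFs and the matching
#' ground truth: an NS1 reference panel (root protein plus two diverged
#' relatives), per-species NS1 lineages evolved on a known tree, paralogous
#' duplicate groups, AT-rich upstream flanks and moderate-GC downstream
#' flanks. Each species' loci are planted on its first contig; remaining
#' contigs stay virus-free so false-positive behaviour is measurable.
#'
#' @param config A [sim_config()].
#' @return List with `assembly` (tibble: species, contig_id, seq), `panel`
#'   (tibble: subject_id, protein), `truth` (tibble of planted loci),
#'   `tree` (the divergence `phylo`) and `config`.
#' @export
simulate_assembly <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    species <- sprintf("species_%02d", seq_len(cfg$n_species))
    tree <- if (is.null(cfg$divergence_tree)) {
      tr <- ape::rcoal(cfg$n_species, tip.label = species)
      tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) *
        cfg$tree_depth
      tr
    } else if (is.character(cfg$divergence_tree)) {
      ape::read.tree(text = cfg$divergence_tree)
    } else {
      cfg$divergence_tree
    }
    n_aa <- cfg$orf_len / 3 - 1
    root <- paste(c("M", sample(AA20, n_aa - 1, replace = TRUE)), collapse = "")
    panel_tree <- "(root:0,ref_b:0.3,ref_c:0.6):0;"
    refs <- evolve_protein(root, panel_tree, rate = 1)
    panel <- tibble::tibble(
      subject_id = c("NS1_ref_a", "NS1_ref_b", "NS1_ref_c"),
      protein = unname(c(root, refs["ref_b"], refs["ref_c"]))
    )
    # keep the start codon intact through evolution
    tips <- sub("^.", "M", evolve_protein(root, tree, rate = 1))

    base <- cfg$n_loci %/% cfg$n_species
    extra <- cfg$n_loci %% cfg$n_species
    loci_per_species <- base + as.integer(seq_len(cfg$n_species) <= extra)

    contigs <- tidyr::expand_grid(
      species = species, idx = seq_len(cfg$contigs_per_species)
    ) |>
      dplyr::mutate(contig_id = sprintf("%s_ctg%d", .data$species, .data$idx))
    seqs <- setNames(
      replicate(nrow(contigs),
                make_scaffold(cfg$contig_length, cfg$background_gc)),
      contigs$contig_id
    )

    truth <- list()
    footprint <- cfg$orf_len + 2 * cfg$flank_len
    next_group <- 1L
    for (si in seq_len(cfg$n_species)) {
      sp <- species[si]
      k <- loci_per_species[si]
      if (k == 0) next
      paralogous <- si <= cfg$n_paralog_groups
      prots <- if (paralogous) {
        rep(unname(tips[sp]), k)
      } else {
        vapply(seq_len(k), function(j) {
          repeat {
            p <- sub("^.", "M", evolve_protein(unname(tips[sp]), "(x:1);",
                                               rate = cfg$within_species_rate))
            if (p != tips[sp]) return(unname(p))
          }
        }, character(1))
      }
      uniq <- unique(prots)
      groups <- next_group + match(prots, uniq) - 1L
      next_group <- next_group + length(uniq)
      orf_by_prot <- setNames(
        vapply(uniq, backtranslate, character(1),
               gc = cfg$ns1_gc, dual_code = cfg$dual_code),
        uniq
      )
      ctg <- sprintf("%s_ctg1", sp)
      lo <- cfg$flank_len + 500
      hi <- cfg$contig_length - footprint - 500
      repeat {
        pos <- sort(sample(lo:hi, k))
        if (k == 1 || all(diff(pos) > footprint + 200)) break
      }
      for (j in seq_len(k)) {
        planted <- plant_eve(
          seqs[[ctg]], orf_by_prot[[prots[j]]], pos[j],
          strand = sample(c("+", "-"), 1),
          flank_len = cfg$flank_len, left_flank_gc = cfg$left_flank_gc,
          right_flank_gc = cfg$right_flank_gc, code = cfg$code,
          contig_id = ctg, species = sp, paralog_group = groups[j]
        )
        seqs[[ctg]] <- planted$contig
        truth[[length(truth) + 1]] <- planted$truth
      }
    }

    list(
      assembly = tibble::tibble(
        species = contigs$species,
        contig_id = contigs$contig_id,
        seq = unname(seqs[contigs$contig_id])
      ),
      panel = panel,
      truth = dplyr::bind_rows(truth) |>
        dplyr::arrange(.data$contig_id, .data$orf_start),
      tree = tree,
      config = cfg
    )
  })
}

#' Write a simulated study to disk
#'
#' One FASTA per species (headers `species|contig_id`), a BED-like truth
#' TSV, the reference panel FASTA and a YAML echo of the configuration.
#'
#' @param sim Result of [simulate_assembly()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in unique(sim$assembly$species)) {
    rows <- dplyr::filter(sim$assembly, .data$species == sp)
    x <- Biostrings::DNAStringSet(setNames(rows$seq,
                                           paste(sp, rows$contig_id, sep = "|")))
    Biostrings::writeXStringSet(x, file.path(dir, paste0(sp, ".fasta")))
  }
  readr::write_tsv(
    dplyr::select(sim$truth, "contig_id", "orf_start", "orf_end", "strand",
                  "paralog_group", "protein", "species"),
    file.path(dir, "truth.tsv")
  )
  panel <- Biostrings::AAStringSet(setNames(sim$panel$protein,
                                            sim$panel$subject_id))
  Biostrings::writeXStringSet(panel, file.path(dir, "panel.fasta"))
  cfg <- sim$config
  cfg$divergence_tree <- if (is.null(cfg$divergence_tree)) {
    ape::write.tree(sim$tree)
  } else if (is.character(cfg$divergence_tree)) {
    cfg$divergence_tree
  } else {
    ape::write.tree(cfg$divergence_tree)
  }
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
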