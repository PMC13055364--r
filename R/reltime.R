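tips_below <- function(tree, adj) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cnt <- integer(n_node)
  rec <- function(v) {
    kids <- adj[[v]]
    if (length(kids) == 0) {
      cnt[v] <<- 1L
    } else {
      for (k in kids) rec(k)
      cnt[v] <<- sum(cnt[kids])
    }
  }
  rec(n_tip + 1L)
  cnt
}

subtree_edge_ids <- function(tree, adj, edge_id) {
  child <- tree$edge[edge_id, 2]
  out <- edge_id
  stack <- child
  n_tip <- length(tree$tip.label)
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- adj[[v]]
    if (length(kids) > 0) {
      ids <- match(kids, tree$edge[, 2])
      out <- c(out, ids)
      stack <- c(stack, kids)
    }
  }
  out
}

#' Relative-rate (RelTime-style) node heights and lineage rates
#'
#' Converts branch lengths of a rooted non-clock tree into relative node
#' times by recursive rate normalisation from the root down: at a node
#' with children A and B, each child's lineage length is its stem branch
#' plus the mean tip-path within its (already rate-corrected) subtree;
#' relative rates `r = 2 L / (L_A + L_B)` are assigned and every branch in
#' the child's subtree is divided by its lineage rate before recursing.
#' Node heights are the corrected mean tip-path lengths, normalised so the
#' root is 1. Polytomies are resolved with zero-length branches; the
#' generalisation to k children uses `r = k L / sum(L)`. Confidence
#' intervals are not computed.
#'
#' @param tree Rooted `phylo` (or newick string) with non-negative branch
#'   lengths.
#' @return Object of class `timed_tree`: `tree` (the binary working tree),
#'   `heights` (corrected mean tip-paths per node), `relative_heights`
#'   (root = 1), `rates` (per-edge tibble: parent, child, original and
#'   corrected lengths, lineage rate), `outgroup` and `ages` (NULL until
#'   [exclude_outgroup()]/[calibrate_tree()] are applied).
#' @export
reltime_heights <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths",
                                      call. = FALSE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  adj <- lapply(seq_len(n_node), function(v) tree$edge[tree$edge[, 1] == v, 2])
  ntips <- tips_below(tree, adj)
  el <- tree$edge.length
  rate <- rep(1, nrow(tree$edge))

  mean_tip_path <- function(v) {
    kids <- adj[[v]]
    if (length(kids) == 0) return(0)
    ids <- match(kids, tree$edge[, 2])
    paths <- vapply(seq_along(kids), function(i) {
      el[ids[i]] + mean_tip_path(kids[i])
    }, numeric(1))
    sum(paths * ntips[kids]) / ntips[v]
  }

  correct <- function(v) {
    kids <- adj[[v]]
    if (length(kids) == 0) return(invisible())
    ids <- match(kids, tree$edge[, 2])
    L <- vapply(seq_along(kids), function(i) {
      el[ids[i]] + mean_tip_path(kids[i])
    }, numeric(1))
    if (sum(L) > 0) {
      r <- length(kids) * L / sum(L)
      r[r == 0] <- 1    # zero-length lineages stay zero, rate left at unity
      for (i in seq_along(kids)) {
        sub <- subtree_edge_ids(tree, adj, ids[i])
        el[sub] <<- el[sub] / r[i]
        rate[sub] <<- rate[sub] * r[i]
      }
    }
    for (k in kids) correct(k)
  }
  correct(n_tip + 1L)

  heights <- vapply(seq_len(n_node), mean_tip_path, numeric(1))
  root_h <- heights[n_tip + 1L]
  rel <- if (root_h > 0) heights / root_h else heights
  structure(
    list(
      tree = tree,
      heights = heights,
      relative_heights = rel,
      rates = tibble::tibble(
        parent = tree$edge[, 1], child = tree$edge[, 2],
        original_length = tree$edge.length, corrected_length = el,
        rate = rate
      ),
      outgroup = NULL, timed_nodes = seq_len(n_node),
      ages = NULL, scale = NULL
    ),
    class = "timed_tree"
  )
}

#' Exclude an outgroup from time estimation
#'
#' Ingroup rates are not assumed to apply to the outgroup, so nodes on the
#' outgroup side of the root carry no ages; the ingroup root (MRCA of all
#' non-outgroup tips) and its descendants remain timed.
#'
#' @param tt A `timed_tree`.
#' @param outgroup_tips Tip labels forming a monophyletic outgroup.
#' @return The `timed_tree` with `outgroup` and `timed_nodes` set (any
#'   existing ages outside the timed set are blanked).
#' @export
exclude_outgroup <- function(tt, outgroup_tips) {
  tree <- tt$tree
  n_tip <- length(tree$tip.label)
  if (!all(outgroup_tips %in% tree$tip.label)) {
    stop("outgroup tips not in tree", call. = FALSE)
  }
  ingroup <- setdiff(tree$tip.label, outgroup_tips)
  if (length(ingroup) == 0) stop("outgroup cannot contain all tips",
                                 call. = FALSE)
  if (length(outgroup_tips) > 1 &&
      !ape::is.monophyletic(tree, outgroup_tips)) {
    stop("outgroup is not monophyletic", call. = FALSE)
  }
  ing_mrca <- if (length(ingroup) == 1) {
    match(ingroup, tree$tip.label)
  } else {
    ape::getMRCA(tree, ingroup)
  }
  adj <- lapply(seq_len(n_tip + tree$Nnode),
                function(v) tree$edge[tree$edge[, 1] == v, 2])
  timed <- ing_mrca
  stack <- adj[[ing_mrca]]
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    timed <- c(timed, v)
    stack <- c(stack, adj[[v]])
  }
  tt$outgroup <- outgroup_tips
  tt$timed_nodes <- sort(timed)
  if (!is.null(tt$ages)) {
    tt$ages[setdiff(seq_along(tt$ages), tt$timed_nodes)] <- NA_real_
  }
  tt
}

#' Calibrate relative heights to absolute ages
#'
#' Point calibrations (node ages in MYA at host divergence events) fix the
#' timescale by least squares through the origin:
#' `scale = sum(t_i a_i) / sum(t_i^2)` over calibrated relative heights
#' `t_i` and ages `a_i`. Maximum-age calibrations are checked post hoc and
#' violations reported via warning and the `max_violations` component.
#'
#' @param tt A `timed_tree` (after [exclude_outgroup()] if an outgroup is
#'   present).
#' @param calibrations Tibble with `tip_a`, `tip_b`, `age_mya` and `kind`
#'   (`"point"` or `"max"`); each calibration attaches to the MRCA of the
#'   two tips.
#' @return The `timed_tree` with `ages` (MYA per node; `NA` for untimed
#'   nodes, 0 for timed tips) and `scale` filled in.
#' @export
calibrate_tree <- function(tt, calibrations) {
  stopifnot(all(c("tip_a", "tip_b", "age_mya") %in% names(calibrations)))
  if (!"kind" %in% names(calibrations)) calibrations$kind <- "point"
  tree <- tt$tree
  n_tip <- length(tree$tip.label)
  nodes <- vapply(seq_len(nrow(calibrations)), function(i) {
    ape::getMRCA(tree, c(calibrations$tip_a[i], calibrations$tip_b[i]))
  }, integer(1))
  if (any(!nodes %in% tt$timed_nodes)) {
    stop("calibration attaches to an untimed (outgroup-side) node",
         call. = FALSE)
  }
  pts <- calibrations$kind == "point"
  if (!any(pts)) stop("need at least one point calibration", call. = FALSE)
  t_rel <- tt$relative_heights[nodes]
  if (any(t_rel[pts] <= 0)) stop("point calibration on a zero-height node",
                                 call. = FALSE)
  s <- sum(t_rel[pts] * calibrations$age_mya[pts]) / sum(t_rel[pts]^2)
  ages <- s * tt$relative_heights
  ages[setdiff(seq_along(ages), tt$timed_nodes)] <- NA_real_
  viol <- which(!pts & s * t_rel > calibrations$age_mya)
  if (length(viol) > 0) {
    warning("maximum-age calibration(s) violated: row ",
            paste(viol, collapse = ", "))
  }
  tt$ages <- ages
  tt$scale <- s
  tt$max_violations <- calibrations[viol, , drop = FALSE]
  tt
}

#' @export
print.timed_tree <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  cat(sprintf("timed tree: %d tips, %d internal nodes", n_tip, x$tree$Nnode))
  if (!is.null(x$outgroup)) {
    cat(sprintf(", outgroup of %d tip(s) untimed", length(x$outgroup)))
  }
  if (!is.null(x$scale)) cat(sprintf(", scale %.4g MYA/unit", x$scale))
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.timed_tree <- function(x, ...) {
  tree <- x$tree
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tibble::tibble(
    node = seq_len(n_node),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    type = rep(c("tip", "internal"), c(n_tip, tree$Nnode)),
    relative_height = x$relative_heights,
    age_mya = if (is.null(x$ages)) NA_real_ else x$ages,
    timed = seq_len(n_node) %in% x$timed_nodes
  )
}

#' Write node ages as TSV and an annotated newick
#'
#' @param tt A calibrated `timed_tree`.
#' @param prefix Path prefix; writes `<prefix>_ages.tsv` and
#'   `<prefix>.nwk` (node ages as node labels).
#' @return `prefix`, invisibly.
#' @export
write_timed_tree <- function(tt, prefix) {
  readr::write_tsv(tidy(tt), paste0(prefix, "_ages.tsv"))
  tree <- tt$tree
  if (!is.null(tt$ages)) {
    n_tip <- length(tree$tip.label)
    lab <- tt$ages[(n_tip + 1):length(tt$ages)]
    tree$node.label <- ifelse(is.na(lab), "", sprintf("%.2f", lab))
  }
  ape::write.tree(tree, paste0(prefix, ".nwk"))
  invisible(prefix)
}
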