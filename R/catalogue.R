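#' Deduplicate byte-identical NS1 proteins
#'
#' Groups loci whose protein strings are exactly identical (paralogous
#' copies retained by the host), keeping the lexicographically smallest
#' locus id as the representative of each group.
#'
#' @param loci Locus tibble with `locus_id` and `protein`.
#' @return List of class `dedup_report`: `unique_loci` (tibble of
#'   representatives), `groups` (tibble: representative, member, group_size),
#'   `n_input`, `n_unique`, `n_duplicate_groups`.
#' @export
dedup_identical <- function(loci) {
  stopifnot(all(c("locus_id", "protein") %in% names(loci)))
  grouped <- loci |>
    dplyr::group_by(.data$protein) |>
    dplyr::mutate(representative = min(.data$locus_id),
                  group_size = dplyr::n()) |>
    dplyr::ungroup()
  groups <- grouped |>
    dplyr::select("representative", member = "locus_id", "group_size") |>
    dplyr::arrange(.data$representative, .data$member)
  unique_loci <- grouped |>
    dplyr::filter(.data$locus_id == .data$representative) |>
    dplyr::select(-"representative", -"group_size")
  structure(
    list(
      unique_loci = unique_loci,
      groups = groups,
      n_input = nrow(loci),
      n_unique = nrow(unique_loci),
      n_duplicate_groups = sum(groups$group_size[!duplicated(groups$representative)] > 1)
    ),
    class = "dedup_report"
  )
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("dedup report: %d input, %d unique, %d duplicate group(s)\n",
              x$n_input, x$n_unique, x$n_duplicate_groups))
  invisible(x)
}

#' One-way ANOVA and Tukey HSD over groups
#'
#' Thin tidy wrappers over the classical fixed-effects machinery
#' (`aov`/`TukeyHSD`): between/within mean-square F with its p-value, and
#' studentized-range adjusted p-values for all pairwise group contrasts.
#' Welch correction is deliberately not applied.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @return `one_way_anova()`: one-row tibble with `statistic` (F), `df`,
#'   `df_residual`, `p_value`. `tukey_hsd()`: tibble with one row per group
#'   pair (`pair`, `estimate`, `conf_low`, `conf_high`, `adj_p_value`).
#' @export
one_way_anova <- function(data, value, group) {
  check_groups(data, value, group)
  fit <- aov(stats::reformulate(group, value), data = data)
  s <- summary(fit)[[1]]
  tibble::tibble(
    statistic = s[["F value"]][1], df = s[["Df"]][1],
    df_residual = s[["Df"]][2], p_value = s[["Pr(>F)"]][1]
  )
}

#' @rdname one_way_anova
#' @export
tukey_hsd <- function(data, value, group) {
  check_groups(data, value, group)
  fit <- aov(stats::reformulate(group, value), data = data)
  tk <- TukeyHSD(fit)[[group]]
  tibble::tibble(
    pair = rownames(tk), estimate = tk[, "diff"],
    conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    adj_p_value = tk[, "p adj"]
  )
}

check_groups <- function(data, value, group) {
  stopifnot(value %in% names(data), group %in% names(data))
  data[[group]] <- as.factor(data[[group]])
  n <- table(data[[group]][!is.na(data[[value]])])
  if (length(n) < 2 || any(n < 2)) {
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Clade-level identity/coverage statistics
#'
#' Per-clade descriptive statistics for confirmation identity and coverage
#' plus one-way ANOVA and Tukey HSD for each measure, mirroring the
#' clade-contrast analysis applied to mined NS1 catalogues.
#'
#' @param loci Locus tibble with `clade`, `confirm_identity`,
#'   `confirm_coverage`.
#' @return Object of class `clade_stats` with `summary`, `anova`, `tukey`
#'   components; supports [tidy()], [glance()] and [autoplot()].
#' @export
clade_stats <- function(loci) {
  stopifnot(all(c("clade", "confirm_identity", "confirm_coverage") %in%
                  names(loci)))
  long <- loci |>
    dplyr::select("locus_id", "clade", identity = "confirm_identity",
                  coverage = "confirm_coverage") |>
    tidyr::pivot_longer(c("identity", "coverage"), names_to = "measure")
  summary <- long |>
    dplyr::group_by(.data$measure, .data$clade) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  anova <- long |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(~ one_way_anova(.x, "value", "clade")) |>
    dplyr::ungroup()
  tukey <- long |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(~ tukey_hsd(.x, "value", "clade")) |>
    dplyr::ungroup()
  structure(list(summary = summary, anova = anova, tukey = tukey,
                 data = long),
            class = "clade_stats")
}

#' @export
print.clade_stats <- function(x, ...) {
  cat("clade statistics\n")
  print(x$summary)
  print(x$anova)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clade_stats <- function(x, ...) x$tukey

#' @exportS3Method generics::glance
glance.clade_stats <- function(x, ...) x$anova

#' @exportS3Method ggplot2::autoplot
autoplot.clade_stats <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$clade, y = .data$value,
                               fill = .data$clade)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Assign clade labels by single-linkage clustering of identities
#'
#' Stand-in for an external phylogeny: single-linkage clustering of the
#' pairwise identity matrix, cut at `cutoff` percent identity, labels
#' `clade_1`, `clade_2`, ... in decreasing cluster size.
#'
#' @param im An [build_identity_matrix()] result.
#' @param cutoff Identity percent at which clusters are cut (default 55).
#' @return Tibble with `locus_id` and `clade`.
#' @export
assign_clades <- function(im, cutoff = 55) {
  d <- stats::as.dist(100 - im$values)
  hc <- stats::hclust(d, method = "single")
  cl <- stats::cutree(hc, h = 100 - cutoff)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(paste0("clade_", seq_along(sizes)), names(sizes))
  tibble::tibble(locus_id = names(cl), clade = unname(relabel[as.character(cl)]))
}

#' Taxonomy flow table
#'
#' Counts loci at each (order, family, genus, species) path, the tabular
#' form behind alluvial/flow displays of host taxonomy.
#'
#' @param loci Locus tibble with a `species` column.
#' @param taxonomy Tibble mapping `species` to `order`, `family`, `genus`.
#' @return Tibble `order`, `family`, `genus`, `species`, `n`; attribute
#'   `level_counts` holds the distinct-level cardinalities.
#' @export
taxonomy_table <- function(loci, taxonomy) {
  stopifnot(all(c("species", "order", "family", "genus") %in% names(taxonomy)))
  missing <- setdiff(unique(loci$species), taxonomy$species)
  if (length(missing) > 0) {
    stop("unmapped species: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- loci |>
    dplyr::count(.data$species, name = "n") |>
    dplyr::left_join(taxonomy, by = "species") |>
    dplyr::select("order", "family", "genus", "species", "n") |>
    dplyr::arrange(.data$order, .data$family, .data$genus, .data$species)
  attr(out, "level_counts") <- c(
    orders = dplyr::n_distinct(out$order),
    families = dplyr::n_distinct(out$family),
    genera = dplyr::n_distinct(out$genus),
    species = dplyr::n_distinct(out$species)
  )
  out
}
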