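#' Extract flanking sequences around NS1 loci
#'
#' Pulls `flank_len` nt upstream and downstream of each locus, truncating
#' at contig edges. Flanks follow the ORF's orientation: for minus-strand
#' loci the upstream ("left") flank is the genomic right side,
#' reverse-complemented. GC content is computed for both flanks and the
#' coding region itself (strand-invariant).
#'
#' @param loci Locus tibble (`locus_id`, `contig_id`, `start`, `end`,
#'   `strand`, optionally `species`).
#' @param assembly Assembly tibble (`contig_id`, `seq`).
#' @param flank_len Flank length in nt (default 300).
#' @return Tibble: `locus_id`, `species`, `left_seq`, `right_seq`,
#'   `left_len`, `right_len`, `gc_left`, `gc_ns1`, `gc_right`.
#' @export
extract_flanks <- function(loci, assembly, flank_len = 300) {
  assembly <- as_assembly(assembly)
  seqs <- setNames(assembly$seq, assembly$contig_id)
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    contig <- seqs[[l$contig_id]]
    if (is.null(contig)) stop("contig ", l$contig_id, " not in assembly",
                              call. = FALSE)
    L <- nchar(contig)
    if (l$start < 0 || l$end > L) stop("locus outside contig", call. = FALSE)
    up <- substr(contig, max(1, l$start - flank_len + 1), l$start)
    orf <- substr(contig, l$start + 1, l$end)
    down <- substr(contig, l$end + 1, min(L, l$end + flank_len))
    if (identical(l$strand, "-")) {
      tmp <- up
      up <- revcomp(down)
      down <- revcomp(tmp)
    }
    tibble::tibble(
      locus_id = l$locus_id,
      species = if ("species" %in% names(l)) l$species else NA_character_,
      left_seq = up, right_seq = down,
      left_len = nchar(up), right_len = nchar(down),
      gc_left = gc_content(up), gc_ns1 = gc_content(orf),
      gc_right = gc_content(down)
    )
  })
}

#' Flank-versus-coding GC statistics
#'
#' The integration-evidence contrast: region-wise GC means and SDs, and a
#' paired two-sided t-test of coding-region GC against the upstream flank
#' GC of the same locus. Flanks shorter than `min_flank_len` nt are
#' reported but excluded from the test (short flanks have high-variance
#' GC).
#'
#' @param records Tibble from [extract_flanks()].
#' @param min_flank_len Minimum flank length entering the test (default 50).
#' @return Object of class `flank_stats`: `regions` (per-region n, mean,
#'   sd), `test` (paired t), `by_species` (species x region GC means),
#'   `records`, `n_used`. Supports [tidy()], [glance()], [autoplot()].
#' @export
flank_stats <- function(records, min_flank_len = 50) {
  usable <- records |>
    dplyr::filter(.data$left_len >= min_flank_len,
                  !is.na(.data$gc_left), !is.na(.data$gc_ns1))
  if (nrow(usable) < 2) stop("need at least 2 complete records",
                             call. = FALSE)
  long <- records |>
    dplyr::select("locus_id", "species", left = "gc_left", ns1 = "gc_ns1",
                  right = "gc_right") |>
    tidyr::pivot_longer(c("left", "ns1", "right"), names_to = "region",
                        values_to = "gc") |>
    dplyr::mutate(region = factor(.data$region,
                                  levels = c("left", "ns1", "right")))
  regions <- long |>
    dplyr::filter(!is.na(.data$gc)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$gc),
                     sd = sd(.data$gc), .groups = "drop")
  # paired t computed directly so the degenerate zero-variance case is
  # well-defined (all differences zero -> t = 0, p = 1)
  d <- usable$gc_ns1 - usable$gc_left
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
  }
  tt <- list(statistic = t_stat, parameter = n - 1,
             p.value = if (is.infinite(t_stat)) 0 else
               2 * pt(-abs(t_stat), n - 1),
             estimate = mean(d))
  by_species <- long |>
    dplyr::filter(!is.na(.data$gc), !is.na(.data$species)) |>
    dplyr::group_by(.data$species, .data$region) |>
    dplyr::summarise(mean_gc = mean(.data$gc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "mean_gc")
  structure(
    list(
      regions = regions,
      test = tibble::tibble(
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value, mean_difference = unname(tt$estimate)
      ),
      by_species = by_species, records = records, n_used = nrow(usable)
    ),
    class = "flank_stats"
  )
}

#' @export
print.flank_stats <- function(x, ...) {
  cat("flank GC statistics\n")
  print(x$regions)
  cat(sprintf("paired t (NS1 - left flank): t = %.3f, p = %.3g (n = %d)\n",
              x$test$statistic, x$test$p_value, x$n_used))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flank_stats <- function(x, ...) x$regions

#' @exportS3Method generics::glance
glance.flank_stats <- function(x, ...) x$test

#' @exportS3Method ggplot2::autoplot
autoplot.flank_stats <- function(object, ...) {
  long <- object$records |>
    dplyr::select("locus_id", left = "gc_left", ns1 = "gc_ns1",
                  right = "gc_right") |>
    tidyr::pivot_longer(-"locus_id", names_to = "region", values_to = "gc") |>
    dplyr::mutate(region = factor(.data$region,
                                  levels = c("left", "ns1", "right")))
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$gc,
                                     fill = .data$region)) +
    ggplot2::geom_boxplot(alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "GC content (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write flank records and per-species GC matrix
#'
#' @param fs A `flank_stats` object.
#' @param prefix Path prefix; writes `<prefix>_records.tsv`,
#'   `<prefix>_by_species.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_flanks <- function(fs, prefix) {
  readr::write_tsv(dplyr::select(fs$records, -"left_seq", -"right_seq"),
                   paste0(prefix, "_records.tsv"))
  readr::write_tsv(fs$by_species, paste0(prefix, "_by_species.tsv"))
  invisible(prefix)
}
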