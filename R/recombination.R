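split_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)

# Max chi-square over candidate breakpoints of a 0/1 parental match vector,
# comparing match counts in windows of w sites either side of each
# breakpoint (2x2 chi-square, no continuity correction). Vectorised over
# breakpoints via cumulative sums.
matchvec_maxchi <- function(m, w) {
  n <- length(m)
  w <- min(w, n %/% 2)
  if (w < 1) return(list(stat = 0, k = NA_integer_, window = w))
  cs <- c(0, cumsum(m))
  k <- w:(n - w)
  a1 <- cs[k + 1] - cs[k - w + 1]      # parent-A matches, left window
  a2 <- cs[k + w + 1] - cs[k + 1]      # parent-A matches, right window
  c1 <- a1 + a2
  c2 <- 2 * w - c1
  num <- 2 * w * (a1 * (w - a2) - (w - a1) * a2)^2
  den <- w * w * c1 * c2
  chi <- ifelse(den > 0, num / den, 0)
  best <- which.max(chi)
  list(stat = chi[best], k = k[best], window = w)
}

permutation_p <- function(obs, m, w, n_permutations) {
  ge <- 0L
  for (i in seq_len(n_permutations)) {
    if (matchvec_maxchi(sample(m), w)$stat >= obs) ge <- ge + 1L
  }
  (1 + ge) / (n_permutations + 1)
}

scan_sites <- function(recombinant, parent_a, parent_b, informative_rule) {
  cs <- split_chars(c(recombinant, parent_a, parent_b))
  r <- cs[[1]]; a <- cs[[2]]; b <- cs[[3]]
  if (length(a) != length(r) || length(b) != length(r)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  no_gap <- r != "-" & a != "-" & b != "-"
  keep <- switch(informative_rule,
    maxchi = no_gap & a != b & (r == a | r == b),
    chimaera = no_gap & xor(r == a, r == b)
  )
  list(m = as.integer(r[keep] == a[keep]), pos = which(keep))
}

#' MaxChi recombination detector
#'
#' Over sites where the two parents differ (and the putative recombinant
#' matches one of them), the recombinant's parental-match vector is scanned
#' for the breakpoint maximising the 2x2 chi-square of parent-A versus
#' parent-B matches in `window` sites on either side. Significance is by
#' permutation of site order.
#'
#' @param recombinant,parent_a,parent_b Aligned sequences (equal lengths).
#' @param window Informative sites per side of the candidate breakpoint
#'   (default 10; shrunk when fewer sites are available).
#' @param n_permutations Site-order permutations (default 1000).
#' @param seed Optional seed for the permutations.
#' @return One-row tibble: `breakpoint` (alignment position of the best
#'   split), `statistic` (max chi-square), `p_value`, `n_sites`.
#' @export
maxchi <- function(recombinant, parent_a, parent_b, window = 10,
                   n_permutations = 1000, seed = NULL) {
  sites <- scan_sites(recombinant, parent_a, parent_b, "maxchi")
  if (length(sites$m) == 0) stop("no variable sites between the parents",
                                 call. = FALSE)
  detector_result(sites, window, n_permutations, seed)
}

#' Chimaera recombination detector
#'
#' Like [maxchi()] but the match vector is built only from sites where the
#' recombinant differs from exactly one parent.
#'
#' @inheritParams maxchi
#' @return Same shape as [maxchi()].
#' @export
chimaera <- function(recombinant, parent_a, parent_b, window = 10,
                     n_permutations = 1000, seed = NULL) {
  sites <- scan_sites(recombinant, parent_a, parent_b, "chimaera")
  if (length(sites$m) == 0) stop("no informative sites for the recombinant",
                                 call. = FALSE)
  detector_result(sites, window, n_permutations, seed)
}

detector_result <- function(sites, window, n_permutations, seed) {
  obs <- matchvec_maxchi(sites$m, window)
  p <- with_seed(seed,
                 permutation_p(obs$stat, sites$m, obs$window, n_permutations))
  tibble::tibble(
    breakpoint = if (is.na(obs$k)) NA_integer_ else sites$pos[obs$k],
    statistic = obs$stat, p_value = p, n_sites = length(sites$m)
  )
}

split_contrast <- function(delta) {
  n <- length(delta)
  if (n < 2) return(0)
  cs <- cumsum(delta)
  k <- seq_len(n - 1)
  left <- cs[k] / k
  right <- (cs[n] - cs[k]) / (n - k)
  max(abs(left - right))
}

#' BootScan-like nearest-parent track
#'
#' Window-wise p-distances from the recombinant to each candidate parent;
#' the nearest candidate per window forms a track whose switch points
#' (argmin changes persisting at least two windows) indicate
#' recombination. Significance is by permuting window order: the observed
#' statistic is the largest left/right contrast, over all split points and
#' candidate pairs, in the window-wise difference of distances to the two
#' candidates. Windows are non-overlapping by default so that window order
#' is exchangeable under the no-recombination null; overlapping windows
#' (step < window) give a smoother display track but correlated windows,
#' so the permutation test then refuses to run.
#'
#' @param recombinant Aligned sequence.
#' @param candidates Named character vector of aligned candidates (>= 2).
#' @param window Window width in alignment columns (default 100).
#' @param step Step between window starts (default = `window`,
#'   non-overlapping; steps larger than the window leave coverage gaps,
#'   which are tolerated).
#' @param n_permutations Window-order permutations.
#' @param seed Optional seed.
#' @return List of class `bootscan_track`: `track` (tibble: window_start,
#'   window_mid, per-candidate distance, nearest), `switches` (tibble:
#'   position, from, to), `statistic` (max split contrast), `p_value`
#'   (`NA` when windows overlap).
#' @export
bootscan_like <- function(recombinant, candidates, window = 100,
                          step = window, n_permutations = 1000,
                          seed = NULL) {
  if (length(candidates) < 2) stop("need at least 2 candidates", call. = FALSE)
  len <- nchar(recombinant)
  if (any(nchar(candidates) != len)) stop("sequences must be aligned",
                                          call. = FALSE)
  if (window > len) stop("window exceeds alignment length", call. = FALSE)
  r <- split_chars(recombinant)[[1]]
  cand <- lapply(candidates, function(s) split_chars(s)[[1]])
  starts <- seq(1, len - window + 1, by = step)
  dist_mat <- vapply(cand, function(cc) {
    vapply(starts, function(s) {
      idx <- s:(s + window - 1)
      ok <- r[idx] != "-" & cc[idx] != "-"
      if (!any(ok)) return(NA_real_)
      mean(r[idx][ok] != cc[idx][ok])
    }, numeric(1))
  }, numeric(length(starts)))
  dist_mat <- matrix(dist_mat, nrow = length(starts),
                     dimnames = list(NULL, names(candidates)))
  nearest <- apply(dist_mat, 1, function(d) {
    if (all(is.na(d))) NA_character_ else names(candidates)[which.min(d)]
  })
  track <- tibble::tibble(
    window_start = starts, window_mid = starts + window / 2
  )
  track <- dplyr::bind_cols(track, tibble::as_tibble(dist_mat))
  track$nearest <- nearest

  pairs <- combn(seq_along(cand), 2, simplify = FALSE)
  deltas <- lapply(pairs, function(pr) {
    d <- dist_mat[, pr[1]] - dist_mat[, pr[2]]
    d[!is.na(d)]
  })
  obs <- max(vapply(deltas, split_contrast, numeric(1)))
  p <- NA_real_
  if (step >= window) {
    p <- with_seed(seed, {
      ge <- 0L
      for (i in seq_len(n_permutations)) {
        ord <- sample(nrow(dist_mat))
        perm_stat <- max(vapply(pairs, function(pr) {
          d <- dist_mat[ord, pr[1]] - dist_mat[ord, pr[2]]
          split_contrast(d[!is.na(d)])
        }, numeric(1)))
        if (perm_stat >= obs) ge <- ge + 1L
      }
      (1 + ge) / (n_permutations + 1)
    })
  }
  runs <- rle(nearest[!is.na(nearest)])
  switches <- tibble::tibble(position = numeric(0), from = character(0),
                             to = character(0))
  if (length(runs$values) > 1) {
    mids <- track$window_mid[!is.na(nearest)]
    ends <- cumsum(runs$lengths)
    keep <- which(runs$lengths[-1] >= 2)   # new state persists >= 2 windows
    if (length(keep) > 0) {
      switches <- tibble::tibble(
        position = (mids[ends[keep]] + mids[ends[keep] + 1]) / 2,
        from = runs$values[keep], to = runs$values[keep + 1]
      )
    }
  }
  structure(list(track = track, switches = switches, statistic = obs,
                 p_value = p),
            class = "bootscan_track")
}

#' @export
print.bootscan_track <- function(x, ...) {
  cat(sprintf("bootscan-like track: %d windows, %d switch(es), p = %.3g\n",
              nrow(x$track), nrow(x$switches), x$p_value))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bootscan_track <- function(object, ...) {
  long <- object$track |>
    dplyr::select(-"window_start", -"nearest") |>
    tidyr::pivot_longer(-"window_mid", names_to = "candidate",
                        values_to = "p_distance")
  ggplot2::ggplot(long, ggplot2::aes(.data$window_mid, .data$p_distance,
                                     colour = .data$candidate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$switches$position,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "alignment position", y = "p-distance") +
    ggplot2::theme_minimal()
}

#' Consensus recombination scan over all triplets
#'
#' Enumerates every (recombinant, parent pair) triplet of a deduplicated
#' alignment, applies the three detectors, Bonferroni-corrects across
#' triplets x methods, and accepts an event only when at least
#' `consensus_min` methods are individually significant -- with three
#' detectors and the default `consensus_min = 3`, acceptance requires
#' unanimity.
#'
#' @param seqs Named character vector of aligned sequences (>= 3 after
#'   dedup).
#' @param window MaxChi/Chimaera window (informative sites per side).
#' @param bs_window,bs_step BootScan-like window/step in columns
#'   (non-overlapping by default so its permutation test is valid).
#' @param n_permutations Permutations per detector (default 1000).
#' @param alpha Significance level on corrected p-values (default 0.05).
#' @param consensus_min Methods required for acceptance (default 3).
#' @param seed Optional seed.
#' @return Tibble with one row per triplet: ids, per-method corrected
#'   p-values, MaxChi/Chimaera breakpoints, `n_supporting`, `accepted`.
#' @export
scan_triplets <- function(seqs, window = 10, bs_window = 100,
                          bs_step = bs_window, n_permutations = 1000,
                          alpha = 0.05, consensus_min = 3, seed = NULL) {
  seqs <- seqs[!duplicated(seqs)]
  n <- length(seqs)
  if (n < 3) stop("need at least 3 distinct sequences", call. = FALSE)
  ids <- names(seqs)
  combos <- combn(ids, 2, simplify = FALSE)
  rows <- list()
  with_seed(seed, {
    for (rec in ids) {
      for (pr in combos) {
        if (rec %in% pr) next
        mc <- try(maxchi(seqs[[rec]], seqs[[pr[1]]], seqs[[pr[2]]],
                         window = window, n_permutations = n_permutations),
                  silent = TRUE)
        ch <- try(chimaera(seqs[[rec]], seqs[[pr[1]]], seqs[[pr[2]]],
                           window = window, n_permutations = n_permutations),
                  silent = TRUE)
        bs <- try(bootscan_like(seqs[[rec]], seqs[pr], window = bs_window,
                                step = bs_step,
                                n_permutations = n_permutations),
                  silent = TRUE)
        p_mc <- if (inherits(mc, "try-error")) NA_real_ else mc$p_value
        p_ch <- if (inherits(ch, "try-error")) NA_real_ else ch$p_value
        p_bs <- if (inherits(bs, "try-error")) NA_real_ else bs$p_value
        rows[[length(rows) + 1]] <- tibble::tibble(
          recombinant_id = rec, parent_a = pr[1], parent_b = pr[2],
          breakpoint_maxchi = if (inherits(mc, "try-error")) NA_integer_ else mc$breakpoint,
          breakpoint_chimaera = if (inherits(ch, "try-error")) NA_integer_ else ch$breakpoint,
          p_maxchi = p_mc, p_chimaera = p_ch, p_bootscan = p_bs
        )
      }
    }
  })
  events <- dplyr::bind_rows(rows)
  n_tests <- nrow(events) * 3
  events <- events |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("p_"), ~ pmin(1, .x * n_tests)),
      n_supporting = (!is.na(.data$p_maxchi) & .data$p_maxchi < alpha) +
        (!is.na(.data$p_chimaera) & .data$p_chimaera < alpha) +
        (!is.na(.data$p_bootscan) & .data$p_bootscan < alpha),
      accepted = .data$n_supporting >= consensus_min
    )
  events
}
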