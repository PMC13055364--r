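#' Pipeline configuration
#'
#' Collects thresholds and stage toggles for [run_pipeline()]. With no
#' `genomes`/`panel` inputs the pipeline starts from [simulate_assembly()]
#' using `sim`.
#'
#' @param genomes,panel Optional FASTA paths (directories of per-species
#'   FASTA and a panel FASTA). When `NULL`, synthetic data are generated.
#' @param sim A [sim_config()] used when simulating.
#' @param evalue_max,min_orf,min_protein,flank_len Threshold parameters of
#'   the mining stages.
#' @param code Translation table for ORF mining.
#' @param species_id,species_cov,genus_floor Demarcation thresholds.
#' @param clade_cutoff Single-linkage identity cutoff for clade labels.
#' @param calibrations Optional calibration tibble for [calibrate_tree()].
#' @param outgroup Optional outgroup tip labels for the dating stage.
#' @param stages Character vector of stages to run, in dependency order.
#' @param recomb_permutations Permutations for the recombination scan.
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genomes = NULL, panel = NULL, sim = sim_config(),
                            evalue_max = 1e-5, min_orf = 702,
                            min_protein = 400, flank_len = 300, code = 9,
                            species_id = 85, species_cov = 80,
                            genus_floor = 35, clade_cutoff = 55,
                            calibrations = NULL, outgroup = NULL,
                            stages = c("simulate", "mine", "catalogue",
                                       "matrix", "flanks", "date"),
                            recomb_permutations = 200, seed = 1) {
  stopifnot(evalue_max > 0, min_orf %% 3 == 0, min_protein > 0,
            flank_len >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_done <- function(dir, stage) {
  file.exists(file.path(dir, paste0(".", stage, ".done")))
}
mark_done <- function(dir, stage) {
  file.create(file.path(dir, paste0(".", stage, ".done")))
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end pipeline
#'
#' Executes the stages in dependency order (simulate, mine, catalogue,
#' matrix, flanks, date, recomb), writing per-stage outputs under
#' `out_dir` plus a `summary.json` of headline counts. Stages whose
#' marker file already exists are skipped when `resume = TRUE`, and each
#' stage fails in isolation (downstream stages needing its output fail
#' fast with a clear error).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory.
#' @param resume Skip completed stages.
#' @return Named list of stage results (invisible components: `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run_"),
                         resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    lapply(unclass(config), function(x) {
      if (inherits(x, "sim_config")) unclass(x) else if (is.data.frame(x)) as.list(x) else x
    }),
    file.path(out_dir, "config_echo.yaml")
  )
  res <- list()
  summary <- list(seed = config$seed)

  want <- function(s) s %in% config$stages
  need <- function(value, stage) {
    if (is.null(value)) {
      stop("stage '", stage, "' requires output of a stage that did not run",
           call. = FALSE)
    }
    value
  }

  # --- inputs -------------------------------------------------------------
  if (want("simulate") && is.null(config$genomes)) {
    if (!(resume && stage_done(out_dir, "simulate"))) {
      res$sim <- simulate_assembly(config$sim)
      write_simulation(res$sim, file.path(out_dir, "simulated"))
      mark_done(out_dir, "simulate")
    } else {
      sim_dir <- file.path(out_dir, "simulated")
      res$sim <- list(
        assembly = read_assembly(list.files(sim_dir, "\\.fasta$",
                                            full.names = TRUE) |>
                                   setdiff(file.path(sim_dir, "panel.fasta"))),
        panel = read_panel(file.path(sim_dir, "panel.fasta")),
        truth = readr::read_tsv(file.path(sim_dir, "truth.tsv"),
                                show_col_types = FALSE)
      )
    }
    assembly <- res$sim$assembly
    panel <- res$sim$panel
    summary$n_planted <- nrow(res$sim$truth)
    log_stage("simulate", "%d contigs, %d planted loci",
              nrow(assembly), nrow(res$sim$truth))
  } else {
    assembly <- if (!is.null(config$genomes)) {
      read_assembly(list.files(config$genomes, "\\.(fa|fasta|fna)$",
                               full.names = TRUE))
    }
    panel <- if (!is.null(config$panel)) read_panel(config$panel)
  }

  # --- mine ---------------------------------------------------------------
  if (want("mine")) {
    assembly <- need(assembly, "mine"); panel <- need(panel, "mine")
    res$loci <- mine_loci(assembly, panel, evalue_max = config$evalue_max,
                          code = config$code, min_orf = config$min_orf)
    write_loci(res$loci, file.path(out_dir, "loci"))
    summary$n_loci <- nrow(res$loci)
    log_stage("mine", "%d loci", nrow(res$loci))
  }

  # --- catalogue ----------------------------------------------------------
  if (want("catalogue")) {
    loci <- need(res$loci, "catalogue")
    res$dedup <- dedup_identical(loci)
    summary$n_unique <- res$dedup$n_unique
    summary$n_duplicate_groups <- res$dedup$n_duplicate_groups
    readr::write_tsv(res$dedup$groups, file.path(out_dir, "dedup_groups.tsv"))
    log_stage("catalogue", "%d unique of %d (%d duplicate groups)",
              res$dedup$n_unique, res$dedup$n_input,
              res$dedup$n_duplicate_groups)
  }

  # --- identity matrix + demarcation ---------------------------------------
  if (want("matrix")) {
    uniq <- need(res$dedup, "matrix")$unique_loci
    if (nrow(uniq) >= 2) {
      res$im <- build_identity_matrix(uniq, min_len = config$min_protein)
      readr::write_tsv(
        tibble::as_tibble(res$im$values, rownames = "locus_id"),
        file.path(out_dir, "identity_matrix.tsv")
      )
      if (!is.null(res$im$tree)) {
        ape::write.tree(res$im$tree, file.path(out_dir, "ordering_tree.nwk"))
      }
      calls <- tidy(res$im) |>
        dplyr::mutate(classify_pair(.data$identity, coverage = 100,
                                    species_id = config$species_id,
                                    species_cov = config$species_cov,
                                    genus_floor = config$genus_floor)["level"])
      readr::write_tsv(calls, file.path(out_dir, "demarcation.tsv"))
      res$clades <- assign_clades(res$im, cutoff = config$clade_cutoff)
      res$loci <- res$loci |>
        dplyr::select(-"clade") |>
        dplyr::left_join(res$clades, by = "locus_id")
      summary$n_clades <- dplyr::n_distinct(res$clades$clade)
      log_stage("matrix", "%d x %d matrix, %d clades",
                nrow(res$im$values), ncol(res$im$values), summary$n_clades)
    }
  }

  # --- flanks ---------------------------------------------------------------
  if (want("flanks")) {
    loci <- need(res$loci, "flanks")
    assembly <- need(assembly, "flanks")
    fr <- extract_flanks(loci, assembly, flank_len = config$flank_len)
    res$flanks <- flank_stats(fr)
    write_flanks(res$flanks, file.path(out_dir, "flanks"))
    summary$gc_ns1_mean <- res$flanks$regions$mean[res$flanks$regions$region == "ns1"]
    summary$gc_left_mean <- res$flanks$regions$mean[res$flanks$regions$region == "left"]
    summary$flank_t_p <- res$flanks$test$p_value
    log_stage("flanks", "NS1 GC %.2f%%, left flank GC %.2f%%, paired p %.3g",
              summary$gc_ns1_mean, summary$gc_left_mean, summary$flank_t_p)
  }

  # --- dating ----------------------------------------------------------------
  if (want("date")) {
    im <- need(res$im, "date")
    if (!is.null(im$tree)) {
      tt <- reltime_heights(im$tree)
      if (!is.null(config$outgroup)) {
        tt <- exclude_outgroup(tt, config$outgroup)
      }
      if (!is.null(config$calibrations)) {
        tt <- calibrate_tree(tt, config$calibrations)
        summary$root_age_mya <- max(tt$ages, na.rm = TRUE)
      }
      res$timed <- tt
      write_timed_tree(tt, file.path(out_dir, "timetree"))
      log_stage("date", "relative heights on %d-tip NJ stand-in tree",
                length(im$tree$tip.label))
    }
  }

  # --- recombination ----------------------------------------------------------
  if (want("recomb")) {
    uniq <- need(res$dedup, "recomb")$unique_loci
    lens <- unique(nchar(uniq$protein))
    if (length(lens) == 1 && nrow(uniq) >= 3) {
      res$recomb <- scan_triplets(setNames(uniq$protein, uniq$locus_id),
                                  n_permutations = config$recomb_permutations)
      readr::write_tsv(res$recomb, file.path(out_dir, "recombination.tsv"))
      summary$n_recomb_accepted <- sum(res$recomb$accepted)
      log_stage("recomb", "%d accepted events", summary$n_recomb_accepted)
    } else {
      log_stage("recomb", "skipped: sequences not aligned to equal length")
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res$summary <- summary
  invisible(res)
}
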