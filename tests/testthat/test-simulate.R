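test_that("scaffolds honour GC extremes, the binomial band and the seed", {
  expect_false(grepl("[GC]", make_scaffold(200, 0, seed = 1)))
  expect_false(grepl("[AT]", make_scaffold(200, 100, seed = 1)))
  s <- make_scaffold(1e5, 40, seed = 5)
  # binomial 3-SD band at n = 1e5: 40 +- 3*sqrt(.4*.6/1e5)*100 ~ 40 +- 0.46
  expect_lt(abs(gc_content(s) - 40), 1)
  expect_identical(s, make_scaffold(1e5, 40, seed = 5))
  expect_error(make_scaffold(0, 50), "positive")
})

test_that("protein evolution is Poisson-calibrated and seed-stable", {
  root <- paste(rep("ACDEFGHIKL", 20), collapse = "")
  # zero-length branches leave tips identical to the root
  tips0 <- evolve_protein(root, "(a:0,b:0);", rate = 1, seed = 1)
  expect_true(all(tips0 == root))
  tips_r0 <- evolve_protein(root, "(a:0.4,b:0.7);", rate = 0, seed = 1)
  expect_true(all(tips_r0 == root))
  expect_identical(evolve_protein(root, "(a:0.2,b:0.2);", seed = 9),
                   evolve_protein(root, "(a:0.2,b:0.2);", seed = 9))
  # two tips at total path d: per-site identity ~ P(no substitution hits a
  # site) plus back-coincidences; compare to the analytic Poisson no-hit
  # expectation at small d where collisions are negligible
  d <- 0.1
  set.seed(42)
  ids <- replicate(300, {
    tp <- evolve_protein(root, sprintf("(a:%f,b:%f);", d / 2, d / 2), rate = 1)
    mean(strsplit(tp[[1]], "")[[1]] == strsplit(tp[[2]], "")[[1]])
  })
  expected <- exp(-d)   # no-hit probability per site
  expect_lt(abs(mean(ids) - expected), 0.01)
  expect_error(evolve_protein(root, "(a,b);"), "branch lengths")
})

test_that("planted ORFs round-trip coordinates and protein on both strands", {
  set.seed(21)
  prot <- random_protein(233, first_m = TRUE)
  orf <- backtranslate(prot, gc = 41.84, seed = 2)
  expect_equal(translate_dna(orf, 9), paste0(prot, "*"))
  expect_equal(translate_dna(orf, 1), paste0(prot, "*"))
  sc <- make_scaffold(5000, 40, seed = 3)

  p <- plant_eve(sc, orf, position = 1200, strand = "+", seed = 4)
  expect_equal(p$truth$orf_start, 1200)
  expect_equal(p$truth$orf_end, 1200 + nchar(orf))
  extracted <- substr(p$contig, 1201, 1200 + nchar(orf))
  expect_equal(extracted, orf)
  expect_equal(translate_dna(extracted, 9), paste0(p$truth$protein, "*"))

  pm <- plant_eve(sc, orf, position = 1200, strand = "-", seed = 4)
  expect_equal(pm$truth$strand, "-")
  extracted_m <- substr(pm$contig, 1201, 1200 + nchar(orf))
  expect_equal(revcomp(extracted_m), orf)

  expect_error(plant_eve(sc, orf, position = 100), "does not fit")
  bad <- paste0("CCC", substr(orf, 4, nchar(orf)))
  expect_error(plant_eve(sc, bad, position = 1200), "start with ATG")
})

test_that("mosaics alternate parental segments from parent A", {
  a <- strrep("A", 30)
  b <- strrep("G", 30)
  expect_equal(make_mosaic(a, b), a)
  m1 <- make_mosaic(a, b, 15)
  expect_equal(m1, paste0(strrep("A", 15), strrep("G", 15)))
  m2 <- make_mosaic(a, b, c(10, 20))
  # per-position membership oracle
  expect_equal(strsplit(m2, "")[[1]],
               rep(c("A", "G", "A"), each = 10))
  expect_error(make_mosaic(a, strrep("G", 10)), "equal length")
})

test_that("simulation is byte-reproducible and truth records round-trip", {
  sim <- small_sim()
  sim2 <- simulate_assembly(sim$config)
  expect_identical(sim$assembly, sim2$assembly)
  expect_identical(sim$truth, sim2$truth)

  seqs <- setNames(sim$assembly$seq, sim$assembly$contig_id)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    nt <- substr(seqs[[tr$contig_id]], tr$orf_start + 1, tr$orf_end)
    if (tr$strand == "-") nt <- revcomp(nt)
    expect_equal(translate_dna(nt, sim$config$code), paste0(tr$protein, "*"))
  }
  # planted flank regions sit within 3 SD of their binomial GC expectation
  fl <- extract_flanks(
    dplyr::mutate(sim$truth, locus_id = paste0("t", dplyr::row_number()),
                  start = .data$orf_start, end = .data$orf_end),
    sim$assembly
  )
  sd300 <- function(gc) 100 * sqrt(gc / 100 * (1 - gc / 100) / 300)
  cfg <- sim$config
  expect_true(all(abs(fl$gc_left - cfg$left_flank_gc) <=
                    3 * sd300(cfg$left_flank_gc) + 1))
  expect_true(all(abs(fl$gc_right - cfg$right_flank_gc) <=
                    3 * sd300(cfg$right_flank_gc)))
})

test_that("structure pairs carry their expected superposition RMSD", {
  sp0 <- make_structure_pair(50, perturb_sd = 0, rotation = c(0.4, -0.2, 1),
                             translation = c(3, 4, 5), seed = 6)
  expect_equal(sp0$expected_rmsd, 0)
  expect_lt(kabsch_rmsd(sp0$a, sp0$b)$rmsd, 1e-9)
  sp <- make_structure_pair(500, perturb_sd = 1, seed = 7)
  expect_equal(sp$expected_rmsd, sqrt(3 * (1 - 2 / 500)))
  expect_error(make_structure_pair(2), "at least 3")
})
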